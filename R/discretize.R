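# Adaptive discretization: per-target minimum-variance bipartition (TDT) and
# per-(regulator, target) entropy-minimizing thresholds (RRT).

#' Target discretization threshold (TDT)
#'
#' Splits a gene's expression samples into the two contiguous groups of the
#' sorted value array whose summed (population) variances are minimal, and
#' returns the midpoint between the groups as the discretization threshold.
#' This is the exact solution of a two-cluster k-means on one-dimensional
#' data, solved by a deterministic scan over all split positions.
#'
#' The split scan is unconstrained; if the global optimum isolates fewer
#' than two samples on either side, the gene is flagged `excluded = TRUE`
#' and is dropped from inference for that dataset and delay, since a state
#' supported by a single time point is most likely an outlier.
#'
#' @param samples Numeric vector of at least 4 finite expression values.
#' @return An object of class `tdt_result`: list with `threshold` (numeric,
#'   `NA` when excluded), `excluded` (logical), `split_index` (optimal split
#'   position `e` in the sorted array, lower part is `1..e`) and `objective`
#'   (the minimal summed variance).
#' @examples
#' compute_tdt(c(0, 0, 0, 1, 1, 1))    # threshold 0.5
#' compute_tdt(c(1, 1, 1, 1, 5))       # excluded: the 5 is isolated
#' @export
compute_tdt <- function(samples) {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n < 4L) stop("at least 4 samples are required to set a TDT, got ", n)
  if (any(!is.finite(samples))) stop("non-finite sample values in TDT input")
  L <- sort(samples)
  cs <- cumsum(L)
  cs2 <- cumsum(L * L)
  e <- seq_len(n - 1L)
  # population variances of L[1..e] and L[(e+1)..n] via moment sums
  v1 <- cs2[e] / e - (cs[e] / e)^2
  v2 <- (cs2[n] - cs2[e]) / (n - e) - ((cs[n] - cs[e]) / (n - e))^2
  obj <- pmax(v1, 0) + pmax(v2, 0)   # clamp tiny negative rounding
  e_opt <- which.min(obj)            # ties: smallest split index
  excluded <- e_opt < 2L || e_opt > n - 2L
  structure(
    list(threshold = if (excluded) NA_real_ else (L[e_opt] + L[e_opt + 1L]) / 2,
         excluded = excluded,
         split_index = as.integer(e_opt),
         objective = obj[e_opt]),
    class = "tdt_result")
}

#' @export
print.tdt_result <- function(x, ...) {
  if (x$excluded) {
    cat(sprintf("TDT: gene excluded (optimal split %d isolates <2 samples)\n",
                x$split_index))
  } else {
    cat(sprintf("TDT threshold %g (split %d, objective %g)\n",
                x$threshold, x$split_index, x$objective))
  }
  invisible(x)
}

# Binary Shannon entropy (base 2) of a +1/-1 label vector; H(empty) = 0.
binary_entropy <- function(labels) {
  n <- length(labels)
  if (n == 0L) return(0)
  p <- sum(labels > 0) / n
  if (p == 0 || p == 1) return(0)
  -p * log2(p) - (1 - p) * log2(1 - p)
}

#' Weighted partition entropy of a candidate regulator threshold
#'
#' Splits the samples into `Do` (regulator value <= `threshold`) and `Up`
#' (regulator value > `threshold`) and returns the size-weighted mean of the
#' binary (base-2) entropies of the target-state labels inside each side:
#' `(|Do|/N) H(Do) + (|Up|/N) H(Up)`.  The value is 0 when each side is
#' label-pure (every sample obeys the same rule type) and 1 when both sides
#' hold the two target states in equal proportion.
#'
#' @param regulator_values Numeric vector of the regulator's expression
#'   values over the aligned samples.
#' @param target_states Integer vector over \{-1, +1\}, same length: the
#'   target's discretized states.
#' @param threshold Candidate threshold for the regulator.
#' @return A number in `[0, 1]`.
#' @export
partition_entropy <- function(regulator_values, target_states, threshold) {
  regulator_values <- as.numeric(regulator_values)
  target_states <- as.integer(target_states)
  if (length(regulator_values) != length(target_states))
    stop("regulator values and target states differ in length")
  if (length(regulator_values) == 0L)
    stop("empty sample set")
  do <- regulator_values <= threshold
  n <- length(do)
  (sum(do) / n) * binary_entropy(target_states[do]) +
    (sum(!do) / n) * binary_entropy(target_states[!do])
}

#' Relative regulation threshold (RRT)
#'
#' Considers every distinct observed expression value of the candidate
#' regulator as a potential pair-specific discretization threshold with
#' respect to an already-discretized target gene, and returns the one
#' minimizing the weighted partition entropy ([partition_entropy()]).
#' Candidates leaving either side of the partition empty are skipped (the
#' maximum observed value always leaves `Up` empty); ties are broken toward
#' the smallest threshold value.
#'
#' @inheritParams partition_entropy
#' @return An object of class `rrt_result`: list with `threshold`,
#'   `entropy`, `do_size` and `up_size`.
#' @examples
#' compute_rrt(c(1, 2, 3, 4), c(-1, -1, 1, 1))  # threshold 2, entropy 0
#' @export
compute_rrt <- function(regulator_values, target_states) {
  regulator_values <- as.numeric(regulator_values)
  target_states <- as.integer(target_states)
  if (length(regulator_values) != length(target_states))
    stop("regulator values and target states differ in length")
  if (length(regulator_values) < 4L)
    stop("at least 4 aligned samples are required to set an RRT")
  if (any(!is.finite(regulator_values)))
    stop("non-finite regulator values in RRT input")
  cand <- sort(unique(regulator_values))
  cand <- cand[cand < cand[length(cand)]]   # max value leaves Up empty
  if (length(cand) == 0L)
    stop("no informative threshold: regulator is constant over the samples")
  ent <- vapply(cand, function(t)
    partition_entropy(regulator_values, target_states, t), numeric(1))
  i <- which.min(ent)   # ties: which.min keeps the smallest candidate
  thr <- cand[i]
  do_size <- sum(regulator_values <= thr)
  structure(
    list(threshold = thr, entropy = ent[i],
         do_size = as.integer(do_size),
         up_size = as.integer(length(regulator_values) - do_size)),
    class = "rrt_result")
}

#' @export
print.rrt_result <- function(x, ...) {
  cat(sprintf("RRT threshold %g (entropy %.4f, Do %d / Up %d)\n",
              x$threshold, x$entropy, x$do_size, x$up_size))
  invisible(x)
}

#' Discretize expression values at a threshold
#'
#' A sample is upregulated (+1) when its value is strictly greater than the
#' threshold and downregulated (-1) when lower or equal.
#'
#' @param values Numeric vector of finite expression values.
#' @param threshold Discretization threshold.
#' @return Integer vector over \{-1, +1\} of the same length.
#' @export
discretize_states <- function(values, threshold) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("non-finite values cannot be discretized")
  ifelse(values > threshold, 1L, -1L)
}
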
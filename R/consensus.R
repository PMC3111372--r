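# Multi-dataset rule consensus: a rule survives when it is inferred
# independently, with the same identity (regulator, target, delay, type),
# in at least a given fraction of the input datasets.

#' Minimum number of supporting datasets under an RCA value
#'
#' The Rule Consensus Accuracy (RCA) parameter gives the minimum
#' *proportion* of datasets in which a rule must predict well; with
#' `k_total` datasets the "at least" semantics translates to
#' `ceiling(rca * k_total)` supporting datasets (e.g. 10 datasets at
#' RCA 0.60 require support in at least 6 of them, no matter which).
#'
#' @param rca Rule Consensus Accuracy, in (0, 1].
#' @param k_total Number of datasets.
#' @return Integer support threshold, at least 1.
#' @export
support_threshold <- function(rca, k_total) {
  if (!is.numeric(rca) || length(rca) != 1L || rca <= 0 || rca > 1)
    stop("`rca` must be a single number in (0, 1]")
  k_total <- as.integer(k_total)
  if (k_total < 1L) stop("`k_total` must be at least 1")
  max(1L, as.integer(ceiling(rca * k_total - 1e-9)))
}

#' Consensus of rule sets inferred from several datasets
#'
#' Intersects the per-dataset rule sets delay component by delay component:
#' a rule is kept iff the identical statement (same regulator, target,
#' delay and rule type) was inferred in at least
#' [support_threshold()]`(rca, K)` of the `K` datasets.  Datasets are
#' unweighted.  Each kept rule carries its support count and, as the most
#' conservative choice, the minimum score it achieved across its supporting
#' datasets.  A target excluded by its TDT in some dataset simply
#' contributes no rules there, which counts against support.
#'
#' @param rule_sets A list of `K` per-dataset results: [infer_rules()]
#'   objects or plain data frames with columns `regulator`, `target`,
#'   `delay`, `rule_type`, `score`.
#' @param rca Rule Consensus Accuracy, in (0, 1]; `rca = 1` is the strict
#'   K-way intersection.
#' @return An object of class `consensus_rules`: a list with `rules` (data
#'   frame: `regulator`, `target`, `delay`, `rule_type`, `support`,
#'   `support_fraction`, `consensus_score`), `k_total`, `rca` and
#'   `support_threshold`.
#' @export
consensus_rules <- function(rule_sets, rca = 1) {
  if (inherits(rule_sets, "rule_set")) rule_sets <- list(rule_sets)
  stopifnot(is.list(rule_sets), length(rule_sets) >= 1L)
  k <- length(rule_sets)
  thr <- support_threshold(rca, k)
  tabs <- lapply(rule_sets, function(rs) {
    df <- if (inherits(rs, "rule_set")) rs$rules else as.data.frame(rs)
    need <- c("regulator", "target", "delay", "rule_type", "score")
    if (!all(need %in% names(df)))
      stop("rule table lacks columns: ",
           paste(setdiff(need, names(df)), collapse = ", "))
    df[need]
  })
  all_rules <- do.call(rbind, tabs)
  empty <- data.frame(regulator = character(), target = character(),
                      delay = integer(), rule_type = integer(),
                      support = integer(), support_fraction = numeric(),
                      consensus_score = numeric(), stringsAsFactors = FALSE)
  if (nrow(all_rules) == 0L) {
    return(structure(list(rules = empty, k_total = k, rca = rca,
                          support_threshold = thr),
                     class = "consensus_rules"))
  }
  key <- paste(all_rules$regulator, all_rules$target,
               all_rules$delay, all_rules$rule_type, sep = "\r")
  support <- as.integer(table(key)[key])  # identity unique within a dataset
  min_score <- tapply(all_rules$score, key, min)
  first <- !duplicated(key)
  keep <- first & support >= thr
  out <- all_rules[keep, c("regulator", "target", "delay", "rule_type")]
  out$support <- support[keep]
  out$support_fraction <- out$support / k
  out$consensus_score <- as.numeric(min_score[key[keep]])
  out <- out[order(out$delay, out$regulator, out$target, out$rule_type), ]
  rownames(out) <- NULL
  structure(list(rules = out, k_total = k, rca = rca,
                 support_threshold = thr),
            class = "consensus_rules")
}

#' @export
print.consensus_rules <- function(x, ...) {
  cat(sprintf(
    "consensus_rules: %d rules (K = %d datasets, RCA = %g, support >= %d)\n",
    nrow(x$rules), x$k_total, x$rca, x$support_threshold))
  if (nrow(x$rules) > 0) {
    show <- utils::head(x$rules, 10L)
    show$rule <- rule_string(show$regulator, show$delay, show$target,
                             show$rule_type)
    print(show[, c("rule", "support", "consensus_score")], row.names = FALSE)
    if (nrow(x$rules) > 10L) cat(sprintf("  ... %d more\n", nrow(x$rules) - 10L))
  }
  invisible(x)
}

#' Maximum delay from a regulatory-delay hypothesis
#'
#' Converts a biological hypothesis about the largest plausible regulatory
#' delay (in minutes) into the delay bound `W` in time-point units:
#' `W = min(floor(delta_t_hypothesis / min(sampling_intervals)),
#' min(sample_counts) - 4)`.  The floor reflects that a partial sampling
#' step cannot be inferred; the second term is the largest window leaving 4
#' aligned samples in the shortest dataset.
#'
#' @param delta_t_hypothesis Maximum hypothesized regulatory delay
#'   (minutes, >= 0).
#' @param sampling_intervals Positive sampling intervals of the datasets
#'   (minutes).
#' @param sample_counts Time-point counts of the datasets (each >= 5).
#' @return Integer delay bound `W`.
#' @examples
#' compute_max_delay(30, c(10, 10, 7), c(15, 17, 18))  # 4
#' @export
compute_max_delay <- function(delta_t_hypothesis, sampling_intervals,
                              sample_counts) {
  stopifnot(is.numeric(delta_t_hypothesis), length(delta_t_hypothesis) == 1L,
            delta_t_hypothesis >= 0)
  if (any(!is.finite(sampling_intervals)) || any(sampling_intervals <= 0))
    stop("sampling intervals must be positive")
  sample_counts <- as.integer(sample_counts)
  if (any(sample_counts < 5L))
    stop("every dataset needs at least 5 time points")
  ratio <- as.integer(floor(delta_t_hypothesis / min(sampling_intervals) + 1e-9))
  min(ratio, min(sample_counts) - 4L)
}
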
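# Synthetic multi-dataset expression time series with planted time-lagged
# rules and analytically known thresholds, used as ground truth in recovery
# tests.  Genes are two-level signals (one latent threshold per gene, one
# expression level on each side) rather than smooth curves, so the planted
# TDT/RRT values are exact and the minimum-variance split can never exclude
# a gene by accident.

#' Specify a rule to plant in synthetic data
#'
#' @param regulator,target Gene identifiers (see [generate_synthetic()] for
#'   the default naming, `G01`, `G02`, ...).
#' @param delay Non-negative integer time delay.
#' @param rule_type Non-zero integer in -3..3.
#' @param fidelity Fraction of aligned samples obeying the rule, in (0, 1];
#'   at 1 the rule is perfectly classifiable (score 1) at the planted
#'   thresholds.
#' @return A list of class `planted_rule`.
#' @export
planted_rule <- function(regulator, target, delay, rule_type, fidelity = 1) {
  rule_type <- as.integer(rule_type)
  stopifnot(rule_type %in% c(-3L, -2L, -1L, 1L, 2L, 3L),
            is.numeric(fidelity), fidelity > 0, fidelity <= 1,
            delay >= 0, regulator != target)
  structure(list(regulator = as.character(regulator),
                 target = as.character(target),
                 delay = as.integer(delay), rule_type = rule_type,
                 fidelity = fidelity),
            class = "planted_rule")
}

# Draw a +1/-1 sequence with at least `min_per_side` of each state inside
# positions 1..(m-wmax) and (wmax+1)..m, so that no discretization window
# used at delays up to wmax can degenerate.
draw_states <- function(m, wmax, min_per_side = 2L) {
  head_idx <- seq_len(m - wmax)
  tail_idx <- seq.int(wmax + 1L, m)
  for (i in 1:10000) {
    s <- sample(c(-1L, 1L), m, replace = TRUE)
    ok <- function(idx) sum(s[idx] > 0) >= min_per_side &&
                        sum(s[idx] < 0) >= min_per_side
    if (ok(head_idx) && ok(tail_idx)) return(s)
  }
  stop("could not draw a balanced state sequence; increase m_timepoints")
}

# Target states implied by regulator states under one rule type; positions
# not constrained by a one-sided rule are NA (filled randomly later).
implied_states <- function(reg_states, rule_type) {
  switch(as.character(rule_type),
    `1`  = reg_states,
    `-1` = -reg_states,
    `2`  = ifelse(reg_states > 0,  1L, NA_integer_),
    `3`  = ifelse(reg_states < 0, -1L, NA_integer_),
    `-3` = ifelse(reg_states > 0, -1L, NA_integer_),
    `-2` = ifelse(reg_states < 0,  1L, NA_integer_))
}

#' Generate synthetic time-series datasets with planted lagged rules
#'
#' Builds `k_datasets` replicate expression matrices over a shared gene
#' list.  Every gene has a latent threshold (drawn uniformly in
#' `[-1, 1]`) and emits a two-level signal: threshold plus or minus a
#' margin of `max(1, 4 * noise_sd)` according to its +1/-1 state at each
#' time point, plus Gaussian noise of sd `noise_sd` — so discretization
#' remains recoverable whenever the noise sd stays below a quarter of the
#' margin.  Background genes have independent random state sequences,
#' constrained to show each state at least twice in every window used at
#' delays up to the maximum planted delay.  For each planted rule the
#' target's states at samples `w+1..m` are set from the regulator's states
#' at `1..m-w` according to the rule type, then each constrained position
#' is independently violated with probability `1 - fidelity`.
#'
#' A delay-0 two-sided rule makes the mirrored statement (target as
#' regulator, same type) true by construction; the returned truth table
#' therefore includes it, flagged `implied = TRUE`.  A gene may be the
#' target of at most one planted rule.
#'
#' @param n_genes Number of genes (at least 2).
#' @param m_timepoints Number of time points per dataset (at least 8).
#' @param k_datasets Number of replicate datasets.
#' @param planted List of [planted_rule()] specifications.
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (>= 0).
#' @param margin Half-distance between a gene's two expression levels.
#'   Defaults to `max(1, 4 * noise_sd)`, which keeps the states separable;
#'   fix it (e.g. `margin = 1`) while raising `noise_sd` to study how
#'   recovery degrades once the noise crosses the level gap.
#' @param state_flip_prob Probability that any gene's state at any time
#'   point is flipped after rule propagation (independent measurement-level
#'   corruption, applied to regulators and targets alike); the noiseless
#'   recovery guarantees hold at 0.
#' @param missing_prob Probability that an expression value is replaced by
#'   `NA` (exercises the imputation path; default 0).
#' @param seed Integer seed; regenerating with the same arguments and seed
#'   reproduces the data bit-exactly.
#' @param sampling_interval Sampling interval recorded on each dataset
#'   (minutes).
#' @return An object of class `synthetic_truth`: list with `datasets` (list
#'   of [expression_dataset()]), `rules` (data frame: `regulator`,
#'   `target`, `delay`, `rule_type`, `fidelity`, `regulator_threshold`,
#'   `target_threshold`, `implied`), `thresholds` (named per-gene latent
#'   thresholds) and `seed`.
#' @export
generate_synthetic <- function(n_genes, m_timepoints, k_datasets,
                               planted = list(), noise_sd = 0,
                               state_flip_prob = 0, missing_prob = 0,
                               seed = 1L, sampling_interval = 10,
                               margin = NULL) {
  n <- as.integer(n_genes)
  m <- as.integer(m_timepoints)
  k <- as.integer(k_datasets)
  stopifnot(n >= 2L, k >= 1L, noise_sd >= 0,
            state_flip_prob >= 0, state_flip_prob < 1,
            missing_prob >= 0, missing_prob < 1)
  if (m < 8L) stop("m_timepoints must be at least 8")
  if (inherits(planted, "planted_rule")) planted <- list(planted)
  stopifnot(all(vapply(planted, inherits, logical(1), "planted_rule")))
  genes <- sprintf("G%0*d", max(2L, nchar(n)), seq_len(n))
  for (pr in planted) {
    if (!pr$regulator %in% genes || !pr$target %in% genes)
      stop("planted rule references a gene outside G01..G", n)
    if (pr$delay > m - 4L)
      stop("planted delay ", pr$delay, " exceeds m - 4 = ", m - 4L)
  }
  tgts <- vapply(planted, `[[`, character(1), "target")
  if (anyDuplicated(tgts))
    stop("a gene may be the target of at most one planted rule")
  wmax <- if (length(planted)) max(vapply(planted, `[[`, integer(1), "delay"))
          else 0L

  # isolate the package RNG use from the caller's stream
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  thr <- stats::runif(n, -1, 1)
  names(thr) <- genes
  if (is.null(margin)) margin <- max(1, 4 * noise_sd)
  stopifnot(is.numeric(margin), length(margin) == 1L, margin > 0)
  tp_labels <- sprintf("t%d", seq_len(m))

  datasets <- vector("list", k)
  for (d in seq_len(k)) {
    states <- t(vapply(seq_len(n), function(i) draw_states(m, wmax),
                       integer(m)))
    rownames(states) <- genes
    for (pr in planted) {
      w <- pr$delay
      reg <- states[pr$regulator, seq_len(m - w)]
      for (try in 1:1000) {
        tgt <- rep(NA_integer_, m)
        if (w > 0L) tgt[seq_len(w)] <- sample(c(-1L, 1L), w, replace = TRUE)
        imp <- implied_states(reg, pr$rule_type)
        free <- is.na(imp)
        imp[free] <- sample(c(-1L, 1L), sum(free), replace = TRUE)
        if (pr$fidelity < 1) {
          corrupt <- !free & stats::runif(m - w) > pr$fidelity
          imp[corrupt] <- -imp[corrupt]
        }
        tgt[seq.int(w + 1L, m)] <- imp
        win <- tgt[seq.int(w + 1L, m)]
        if (sum(win > 0) >= 2L && sum(win < 0) >= 2L) break
        if (try == 1000) stop("could not balance a planted target sequence")
      }
      states[pr$target, ] <- tgt
    }
    if (state_flip_prob > 0) {
      flips <- matrix(stats::runif(n * m) < state_flip_prob, n, m)
      states[flips] <- -states[flips]
    }
    values <- thr + states * margin
    if (noise_sd > 0)
      values <- values + matrix(stats::rnorm(n * m, sd = noise_sd), n, m)
    if (missing_prob > 0)
      values[matrix(stats::runif(n * m) < missing_prob, n, m)] <- NA_real_
    dimnames(values) <- list(genes, tp_labels)
    datasets[[d]] <- expression_dataset(
      values, name = sprintf("synth%02d", d),
      sampling_interval = sampling_interval)
  }

  truth_rows <- lapply(planted, function(pr) {
    base <- data.frame(regulator = pr$regulator, target = pr$target,
                       delay = pr$delay, rule_type = pr$rule_type,
                       fidelity = pr$fidelity,
                       regulator_threshold = unname(thr[pr$regulator]),
                       target_threshold = unname(thr[pr$target]),
                       implied = FALSE, stringsAsFactors = FALSE)
    if (pr$delay == 0L && abs(pr$rule_type) == 1L) {
      mirror <- base
      mirror$regulator <- pr$target
      mirror$target <- pr$regulator
      mirror$regulator_threshold <- unname(thr[pr$target])
      mirror$target_threshold <- unname(thr[pr$regulator])
      mirror$implied <- TRUE
      base <- rbind(base, mirror)
    }
    base
  })
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows)
           else data.frame(regulator = character(), target = character(),
                           delay = integer(), rule_type = integer(),
                           fidelity = numeric(),
                           regulator_threshold = numeric(),
                           target_threshold = numeric(), implied = logical(),
                           stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  structure(list(datasets = datasets, rules = truth, thresholds = thr,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  d <- dim(x$datasets[[1]])
  cat(sprintf(
    "synthetic_truth: %d datasets of %d genes x %d time points, %d truth rules (seed %d)\n",
    length(x$datasets), d[1], d[2], nrow(x$rules), x$seed))
  invisible(x)
}

#' Write synthetic datasets and truth rules to a directory
#'
#' One TSV per dataset (via [write_expression()]) plus `truth_rules.tsv` in
#' the [write_rules()] schema with an extra `planted` column (`TRUE` for
#' explicitly planted rules, `FALSE` for delay-0 mirrors implied by
#' construction).
#'
#' @param st A [generate_synthetic()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_synthetic_truth <- function(st, dir) {
  stopifnot(inherits(st, "synthetic_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ds in st$datasets)
    write_expression(ds, file.path(dir, paste0(ds$name, ".tsv")))
  tr <- st$rules
  out <- data.frame(
    regulator = tr$regulator, delay = tr$delay, target = tr$target,
    rule_type = tr$rule_type,
    rule_string = if (nrow(tr)) rule_string(tr$regulator, tr$delay,
                                            tr$target, tr$rule_type)
                  else character(),
    accuracy = tr$fidelity, support_fraction = rep(1, nrow(tr)),
    planted = !tr$implied, stringsAsFactors = FALSE)
  utils::write.table(out, file.path(dir, "truth_rules.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Precision and sensitivity of inferred rules against planted truth
#'
#' Rules are matched on the full identity (regulator, target, delay, rule
#' type).  Precision is the fraction of inferred rules present in the truth
#' table; sensitivity the fraction of truth rules recovered.
#'
#' @param inferred A [consensus_rules()] or [infer_rules()] object, or a
#'   rule data frame.
#' @param truth A [generate_synthetic()] result or its `rules` data frame.
#' @return List with `precision`, `sensitivity`, `n_inferred`, `n_truth`,
#'   `n_matched`.
#' @export
recovery_metrics <- function(inferred, truth) {
  inf_df <- if (inherits(inferred, "consensus_rules") ||
                inherits(inferred, "rule_set")) inferred$rules
            else as.data.frame(inferred)
  tr_df <- if (inherits(truth, "synthetic_truth")) truth$rules
           else as.data.frame(truth)
  key <- function(df) paste(df$regulator, df$target, df$delay, df$rule_type,
                            sep = "\r")
  ik <- unique(key(inf_df))
  tk <- unique(key(tr_df))
  matched <- sum(ik %in% tk)
  list(precision = if (length(ik)) matched / length(ik) else 0,
       sensitivity = if (length(tk)) matched / length(tk) else 0,
       n_inferred = length(ik), n_truth = length(tk), n_matched = matched)
}
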
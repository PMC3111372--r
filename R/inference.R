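# Classifier inference: for each dataset, delay and target gene, assign to
# every candidate regulator the rule type maximizing the predictive-value
# performance function, subject to the Accuracy and SCP filters.

RULE_TYPES <- c(1L, -1L, 2L, 3L, -2L, -3L)  # also the tie-break preference order

#' Inference parameters
#'
#' @param accuracy Minimum performance score a rule must reach to be
#'   emitted, in (0, 1].  0.75 is a robust default: qualitative pairwise
#'   relationships scoring below that level rarely replicate.
#' @param scp Sample Coverage Percentage, in (0, 1]: the minimum fraction of
#'   aligned samples that the single predictive factor of a one-sided rule
#'   (types 2, 3, -2, -3) must cover.  One-sided rules are easily produced
#'   by chance, so the default is close to the maximum (0.95); at `scp = 1`
#'   no one-sided rule is ever emitted.
#' @param max_delay Maximum time delay W (non-negative integer); each
#'   dataset must satisfy `max_delay <= m - 4`.
#' @param allow_self_loops Whether a gene may regulate itself at delays
#'   >= 1 (at delay 0 a self-rule is the identity and is always skipped).
#' @return A list of class `inference_params`.
#' @export
inference_params <- function(accuracy = 0.75, scp = 0.95, max_delay = 0L,
                             allow_self_loops = FALSE) {
  stopifnot(is.numeric(accuracy), length(accuracy) == 1L,
            accuracy > 0, accuracy <= 1,
            is.numeric(scp), length(scp) == 1L, scp > 0, scp <= 1,
            is.numeric(max_delay), length(max_delay) == 1L, max_delay >= 0,
            is.logical(allow_self_loops), length(allow_self_loops) == 1L)
  structure(list(accuracy = accuracy, scp = scp,
                 max_delay = as.integer(max_delay),
                 allow_self_loops = allow_self_loops),
            class = "inference_params")
}

#' Align a regulator and a target series at a time delay
#'
#' For delay `w`, the first `w` time points of the target and the last `w`
#' time points of the regulator are removed, so that regulator sample `j` is
#' paired with target sample `j + w`.  The delay may not exceed `m - 4`,
#' since at least 4 aligned samples are needed to discretize the target.
#'
#' @param regulator_values,target_values Numeric vectors of equal length
#'   `m`.
#' @param w Non-negative integer delay, `w <= m - 4`.
#' @return A list with `regulator` and `target`, both of length `m - w`.
#' @export
align_lagged <- function(regulator_values, target_values, w) {
  m <- length(regulator_values)
  if (length(target_values) != m)
    stop("regulator and target series differ in length")
  w <- as.integer(w)
  if (w < 0L) stop("delay must be non-negative")
  if (w > m - 4L)
    stop(sprintf("delay %d leaves fewer than 4 aligned samples (m = %d)", w, m))
  list(regulator = regulator_values[seq_len(m - w)],
       target = target_values[seq.int(w + 1L, m)])
}

#' Confusion counts of a state pair under a rule type
#'
#' Tabulates the aligned regulator/target state pairs into true/false
#' positives/negatives under the semantics of rule type `c`.  Factor one of
#' the performance function is the precision of the rule's "+" premise and
#' factor two the precision of its "-" premise; the counts are assigned
#' accordingly.  Writing `N(a, b)` for the number of positions with
#' regulator state `a` and target state `b`:
#' \itemize{
#'   \item types 1, 2, 3: `tp = N(+,+)`, `fp = N(+,-)`, `tn = N(-,-)`,
#'     `fn = N(-,+)`;
#'   \item types -1, -2, -3: `tp = N(+,-)`, `fp = N(+,+)`, and for type -1
#'     `tn = N(-,+)`, `fn = N(-,-)`; type -3 keeps `tn = N(-,-)`,
#'     `fn = N(-,+)`; type -2 uses `tn = N(-,+)`, `fn = N(-,-)`.
#' }
#' Only `tp`/`fp` are used downstream for types 2 and -3, and only
#' `tn`/`fn` for types 3 and -2.
#'
#' @param reg_states,tgt_states Integer vectors over \{-1, +1\}, equal
#'   length.
#' @param c Rule type, non-zero integer in -3..3 (type 0 has no defined
#'   confusion counts).
#' @return A list with integer fields `tp`, `fp`, `tn`, `fn` summing to the
#'   number of aligned samples.
#' @export
confusion_counts <- function(reg_states, tgt_states, c) {
  if (length(reg_states) != length(tgt_states))
    stop("state vectors differ in length")
  c <- as.integer(c)
  if (!c %in% RULE_TYPES)
    stop("confusion counts are undefined for rule type ", c)
  rp <- reg_states > 0
  tp_ <- tgt_states > 0
  npp <- sum(rp & tp_)    # N(+,+)
  npm <- sum(rp & !tp_)   # N(+,-)
  nmp <- sum(!rp & tp_)   # N(-,+)
  nmm <- sum(!rp & !tp_)  # N(-,-)
  out <- switch(as.character(c),
    `1`  = c(npp, npm, nmm, nmp),
    `2`  = c(npp, npm, nmm, nmp),
    `3`  = c(npp, npm, nmm, nmp),
    `-1` = c(npm, npp, nmp, nmm),
    `-3` = c(npm, npp, nmm, nmp),
    `-2` = c(npm, npp, nmp, nmm))
  list(tp = as.integer(out[1L]), fp = as.integer(out[2L]),
       tn = as.integer(out[3L]), fn = as.integer(out[4L]))
}

#' Score a rule type from its confusion counts
#'
#' For the two-sided types 1 and -1 the score is the product of the
#' positive and negative predictive values, `tp/(tp+fp) * tn/(tn+fn)`.  For
#' the one-sided types only the corresponding single factor is used
#' (`tp/(tp+fp)` for types 2 and -3, `tn/(tn+fn)` for 3 and -2), and the
#' covered count must additionally reach the Sample Coverage Percentage:
#' `tp/n_samples >= scp` (resp. `tn/n_samples >= scp`).  Any 0/0 factor
#' scores 0.
#'
#' @param counts A [confusion_counts()] result.
#' @param c Rule type (non-zero).
#' @param n_samples Number of aligned samples (the SCP denominator).
#' @param scp Sample Coverage Percentage in (0, 1].
#' @return List with `score` in `[0, 1]` and `passes_scp` (always `TRUE`
#'   for the two-sided types).
#' @export
score_rule <- function(counts, c, n_samples, scp) {
  c <- as.integer(c)
  if (!c %in% RULE_TYPES) stop("cannot score rule type ", c)
  ratio <- function(a, b) if (a + b == 0L) 0 else a / (a + b)
  if (abs(c) == 1L) {
    list(score = ratio(counts$tp, counts$fp) * ratio(counts$tn, counts$fn),
         passes_scp = TRUE)
  } else if (c == 2L || c == -3L) {
    list(score = ratio(counts$tp, counts$fp),
         passes_scp = counts$tp / n_samples >= scp - 1e-12)
  } else {  # c == 3 or c == -2
    list(score = ratio(counts$tn, counts$fn),
         passes_scp = counts$tn / n_samples >= scp - 1e-12)
  }
}

#' Best rule type for an aligned state pair
#'
#' Scores all six non-zero rule types with [score_rule()], discards those
#' failing the SCP filter (one-sided types) or scoring below the accuracy
#' cut-off, and returns the survivor with the maximal score.  When no
#' candidate survives the assignment is type 0 with score 0 (no
#' interaction).  Exact score ties are broken by preferring the two-sided
#' types over the one-sided ones (they constrain both states) and positive
#' codes over negative, i.e. the order 1, -1, 2, 3, -2, -3.
#'
#' @inheritParams confusion_counts
#' @param params An [inference_params()] object.
#' @return List with `rule_type` (integer, possibly 0) and `score`.
#' @export
best_rule_type <- function(reg_states, tgt_states, params) {
  if (length(reg_states) != length(tgt_states))
    stop("state vectors differ in length")
  n <- length(reg_states)
  if (n < 4L) stop("at least 4 aligned samples are required")
  best_c <- 0L
  best_s <- 0
  for (c in RULE_TYPES) {
    cc <- confusion_counts(reg_states, tgt_states, c)
    sr <- score_rule(cc, c, n, params$scp)
    if (!sr$passes_scp) next
    if (sr$score < params$accuracy - 1e-12) next
    if (sr$score > best_s + 1e-12) {
      best_s <- sr$score
      best_c <- c
    }
  }
  list(rule_type = best_c, score = if (best_c == 0L) 0 else best_s)
}

#' Gene-profile classifier for one target at one delay
#'
#' Builds the optimal classifier profile for `target` at delay `w`: target
#' states are obtained by discretizing the last `m - w` samples at the
#' supplied TDT; for every candidate regulator, a pair-specific RRT is
#' computed on its first `m - w` samples against those target states, the
#' regulator is discretized at its RRT, and the best-scoring rule type is
#' assigned ([best_rule_type()]).  Regulators with no informative RRT
#' (constant over the aligned samples) are assigned type 0.
#'
#' @param ds A complete [expression_dataset()].
#' @param target Gene identifier of the target.
#' @param w Non-negative integer delay, `w <= m - 4`.
#' @param params An [inference_params()] object.
#' @param tdt Optional precomputed, non-excluded [compute_tdt()] result for
#'   the target at this delay; computed when omitted.
#' @return A data frame of class `classifier_profile` with one row per
#'   candidate regulator: `regulator`, `rule_type`, `score`,
#'   `rrt_threshold`; attributes `target`, `delay`, `dataset`,
#'   `tdt_threshold`.
#' @export
infer_profile <- function(ds, target, w, params, tdt = NULL) {
  stopifnot(inherits(ds, "expression_dataset"),
            inherits(params, "inference_params"))
  if (anyNA(ds$values))
    stop("dataset '", ds$name, "' has missing values; impute first")
  if (!target %in% ds$genes) stop("unknown target gene: ", target)
  m <- length(ds$timepoints)
  w <- as.integer(w)
  if (w > m - 4L) stop("delay ", w, " exceeds m - 4 = ", m - 4L)
  tgt_vals <- ds$values[target, seq.int(w + 1L, m)]
  if (is.null(tdt)) tdt <- compute_tdt(tgt_vals)
  if (tdt$excluded)
    stop("target '", target, "' is excluded by its TDT at delay ", w)
  tgt_states <- discretize_states(tgt_vals, tdt$threshold)
  regs <- ds$genes
  if (!(params$allow_self_loops && w >= 1L)) regs <- setdiff(regs, target)
  n_r <- length(regs)
  types <- integer(n_r)
  scores <- numeric(n_r)
  rrts <- rep(NA_real_, n_r)
  idx <- seq_len(m - w)
  for (j in seq_len(n_r)) {
    reg_vals <- ds$values[regs[j], idx]
    rrt <- tryCatch(compute_rrt(reg_vals, tgt_states), error = function(e) NULL)
    if (is.null(rrt)) next  # no informative threshold -> type 0
    br <- best_rule_type(discretize_states(reg_vals, rrt$threshold),
                         tgt_states, params)
    types[j] <- br$rule_type
    scores[j] <- br$score
    rrts[j] <- rrt$threshold
  }
  structure(
    data.frame(regulator = regs, rule_type = types, score = scores,
               rrt_threshold = rrts, stringsAsFactors = FALSE),
    class = c("classifier_profile", "data.frame"),
    target = target, delay = w, dataset = ds$name,
    tdt_threshold = tdt$threshold)
}

#' Infer all time-lagged rules from one dataset
#'
#' Runs the classifier inference for every delay `w = 0..max_delay` and
#' every target gene.  The target's TDT is recomputed at each delay on the
#' last `m - w` samples (the first `w` samples are dropped by the temporal
#' shift); targets whose TDT isolates fewer than two samples on a side are
#' excluded at that delay and recorded.  Rules are the non-zero classifier
#' assignments.
#'
#' @param ds A complete [expression_dataset()].
#' @param params An [inference_params()] object.
#' @return A list of class `rule_set` with elements `rules` (data frame:
#'   `dataset`, `delay`, `regulator`, `target`, `rule_type`, `score`,
#'   `rrt_threshold`, `tdt_threshold`), `exclusions` (data frame: `delay`,
#'   `gene`), `dataset` and `params`.
#' @export
infer_rules <- function(ds, params = inference_params()) {
  stopifnot(inherits(ds, "expression_dataset"),
            inherits(params, "inference_params"))
  if (anyNA(ds$values))
    stop("dataset '", ds$name, "' has missing values; impute first")
  m <- length(ds$timepoints)
  if (params$max_delay > m - 4L)
    stop(sprintf("max_delay %d exceeds m - 4 = %d for dataset '%s'",
                 params$max_delay, m - 4L, ds$name))
  rule_rows <- list()
  excl_rows <- list()
  for (w in 0:params$max_delay) {
    for (target in ds$genes) {
      tdt <- compute_tdt(ds$values[target, seq.int(w + 1L, m)])
      if (tdt$excluded) {
        excl_rows[[length(excl_rows) + 1L]] <- data.frame(
          delay = w, gene = target, stringsAsFactors = FALSE)
        next
      }
      prof <- infer_profile(ds, target, w, params, tdt = tdt)
      hit <- prof$rule_type != 0L
      if (any(hit)) {
        rule_rows[[length(rule_rows) + 1L]] <- data.frame(
          dataset = ds$name, delay = w,
          regulator = prof$regulator[hit], target = target,
          rule_type = prof$rule_type[hit], score = prof$score[hit],
          rrt_threshold = prof$rrt_threshold[hit],
          tdt_threshold = tdt$threshold,
          stringsAsFactors = FALSE)
      }
    }
  }
  empty_rules <- data.frame(dataset = character(), delay = integer(),
                            regulator = character(), target = character(),
                            rule_type = integer(), score = numeric(),
                            rrt_threshold = numeric(), tdt_threshold = numeric(),
                            stringsAsFactors = FALSE)
  rules <- if (length(rule_rows)) do.call(rbind, rule_rows) else empty_rules
  exclusions <- if (length(excl_rows)) do.call(rbind, excl_rows)
                else data.frame(delay = integer(), gene = character(),
                                stringsAsFactors = FALSE)
  rownames(rules) <- NULL
  structure(list(rules = rules, exclusions = exclusions,
                 dataset = ds$name, params = params),
            class = "rule_set")
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("rule_set for dataset '%s': %d rules, delays 0..%d\n",
              x$dataset, nrow(x$rules), x$params$max_delay))
  if (nrow(x$exclusions) > 0)
    cat(sprintf("  %d target exclusions (TDT)\n", nrow(x$exclusions)))
  invisible(x)
}
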
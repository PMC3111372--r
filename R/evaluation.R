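# Benchmarking inferred rules against scored reference gene-pair sets.
# Rules are projected to undirected gene pairs (delays, directions and rule
# types collapse) so that predictions and reference sets carry the same
# kind of information and no rule is validated twice through one reference
# match.

canonical_pairs <- function(a, b) {
  ga <- pmin(a, b)
  gb <- pmax(a, b)
  keep <- ga != gb
  unique(data.frame(gene_a = ga[keep], gene_b = gb[keep],
                    stringsAsFactors = FALSE))
}

pair_key <- function(df) paste(df$gene_a, df$gene_b, sep = "\r")

#' Project a rule set to undirected gene pairs
#'
#' Each rule contributes the unordered pair \{regulator, target\};
#' duplicates arising from different delays, directions or rule types
#' collapse to a single pair, and self-pairs are dropped.
#'
#' @param rules A [consensus_rules()] object, an [infer_rules()] object, or
#'   a data frame with `regulator` and `target` columns.
#' @return Data frame with columns `gene_a`, `gene_b`
#'   (lexicographically ordered within each pair).
#' @export
project_pairs <- function(rules) {
  df <- if (inherits(rules, "consensus_rules") || inherits(rules, "rule_set"))
    rules$rules else as.data.frame(rules)
  if (nrow(df) == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  canonical_pairs(df$regulator, df$target)
}

#' Reference gene-pair set
#'
#' @param pairs Data frame with columns `gene_a`, `gene_b` and optionally
#'   `score` (higher = stronger association).  Pairs are canonicalized
#'   (order-free) and self-pairs dropped; duplicated pairs keep their first
#'   score.
#' @return Data frame of class `reference_pairs`.
#' @export
reference_pairs <- function(pairs) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)))
  ga <- pmin(pairs$gene_a, pairs$gene_b)
  gb <- pmax(pairs$gene_a, pairs$gene_b)
  score <- if ("score" %in% names(pairs)) as.numeric(pairs$score)
           else rep(NA_real_, nrow(pairs))
  keep <- ga != gb
  out <- data.frame(gene_a = ga[keep], gene_b = gb[keep],
                    score = score[keep], stringsAsFactors = FALSE)
  out <- out[!duplicated(pair_key(out)), ]
  rownames(out) <- NULL
  class(out) <- c("reference_pairs", "data.frame")
  out
}

#' Read a scored reference pair set from a TSV file
#'
#' Expects columns `gene_a`, `gene_b` and optionally `score` (a header row
#' is required).
#'
#' @param path Path to the TSV file.
#' @return A [reference_pairs()] data frame.
#' @export
read_reference_pairs <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  reference_pairs(df)
}

#' Precision, sensitivity and specificity of predicted gene pairs
#'
#' Compares a predicted pair set against a reference pair set over the
#' search space of all `n (n - 1) / 2` unordered pairs of an `n`-gene
#' universe (both sets are restricted to universe genes first).  With
#' `TP = |predicted intersect reference|`, `FP = |predicted \ reference|`,
#' `FN = |reference \ predicted|` and `TN` the remaining universe pairs:
#' precision `TP/(TP+FP)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`; 0/0 ratios are reported as 0.  `average_score` is the mean
#' reference score over the matched (predicted-and-reference) pairs — the
#' expected value under uniformly random prediction is the reference-set
#' mean; `score_over_predicted` divides the same sum by the number of
#' predicted pairs instead, so unmatched predictions count as 0.
#'
#' @param predicted Data frame of predicted pairs ([project_pairs()]
#'   output) or an object accepted by it.
#' @param reference A [reference_pairs()] data frame (or coercible).
#' @param universe Character vector of the analysis gene universe.
#' @return A list of class `pair_metrics` with fields `precision`,
#'   `sensitivity`, `specificity`, `average_score`,
#'   `score_over_predicted`, `tp`, `fp`, `fn`, `tn`, `n_predicted`,
#'   `n_reference`, `n_universe_pairs`.
#' @examples
#' ref <- reference_pairs(data.frame(gene_a = "A", gene_b = "B", score = 2))
#' pair_metrics(data.frame(gene_a = "A", gene_b = "B"), ref,
#'              universe = c("A", "B", "C"))
#' @export
pair_metrics <- function(predicted, reference, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) < 2L)
    stop("the gene universe must contain at least 2 genes")
  if (!inherits(predicted, "data.frame")) predicted <- project_pairs(predicted)
  if (nrow(predicted) > 0L)
    predicted <- canonical_pairs(predicted$gene_a, predicted$gene_b)
  reference <- reference_pairs(reference)
  in_univ <- function(df) df[df$gene_a %in% universe & df$gene_b %in% universe, ,
                             drop = FALSE]
  predicted <- in_univ(predicted)
  reference <- in_univ(reference)
  n <- length(universe)
  n_pairs <- as.integer(n * (n - 1L) / 2L)
  pk <- pair_key(predicted)
  rk <- pair_key(reference)
  tp <- sum(pk %in% rk)
  fp <- nrow(predicted) - tp
  fn <- nrow(reference) - tp
  tn <- n_pairs - tp - fp - fn
  storage.mode(tp) <- storage.mode(fp) <- "integer"
  storage.mode(fn) <- storage.mode(tn) <- "integer"
  safe <- function(a, b) if (a + b == 0) 0 else a / (a + b)
  matched_scores <- reference$score[rk %in% pk]
  matched_scores <- matched_scores[!is.na(matched_scores)]
  avg <- if (length(matched_scores)) mean(matched_scores) else 0
  over_pred <- if (nrow(predicted)) sum(matched_scores) / nrow(predicted) else 0
  structure(
    list(precision = safe(tp, fp), sensitivity = safe(tp, fn),
         specificity = safe(tn, fp), average_score = avg,
         score_over_predicted = over_pred,
         tp = tp, fp = fp, fn = fn, tn = tn,
         n_predicted = nrow(predicted), n_reference = nrow(reference),
         n_universe_pairs = n_pairs),
    class = "pair_metrics")
}

#' @export
print.pair_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("pair_metrics over %d universe pairs:\n",
           "  precision %.4f  sensitivity %.4f  specificity %.4f\n",
           "  average score %.4f  (predicted %d, reference %d, TP %d)\n"),
    x$n_universe_pairs, x$precision, x$sensitivity, x$specificity,
    x$average_score, x$n_predicted, x$n_reference, x$tp))
  invisible(x)
}

#' Parameter grid for repeated runs
#'
#' Builds the Cartesian product of the supplied parameter vectors, one run
#' per row.  Unsupplied parameters are omitted from the grid.
#'
#' @param accuracy,scp,rca Numeric vectors of parameter values (each
#'   optional, at least one required).
#' @return Data frame with one column per supplied parameter and one row
#'   per combination.
#' @examples
#' nrow(param_grid(accuracy = seq(0.60, 0.90, 0.05),
#'                 scp = seq(0.60, 0.95, 0.05)))    # 56
#' @export
param_grid <- function(accuracy = NULL, scp = NULL, rca = NULL) {
  cols <- list(accuracy = accuracy, scp = scp, rca = rca)
  cols <- cols[!vapply(cols, is.null, logical(1))]
  if (length(cols) == 0L) stop("supply at least one parameter vector")
  grid <- expand.grid(cols, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rownames(grid) <- NULL
  grid
}

#' Run inference and evaluation over a parameter grid
#'
#' For every row of `grid`, rules are inferred from the datasets with that
#' row's parameters (falling back to `base_params` for parameters absent
#' from the grid), combined by consensus, projected to pairs and scored
#' against the reference set.  Per-dataset inference results are cached
#' across rows sharing the same (accuracy, scp), since only the consensus
#' step depends on `rca`.
#'
#' @param datasets List of complete [expression_dataset()] objects over a
#'   common gene universe.
#' @param grid A [param_grid()] data frame.
#' @param reference A [reference_pairs()] set.
#' @param max_delay Delay bound `W` for all runs.
#' @param base_params Default [inference_params()] supplying values for
#'   parameters not varied in the grid; its `rca` analogue defaults to 1.
#' @param rca Default RCA when the grid has no `rca` column.
#' @return Data frame: the grid columns plus `n_rules`, `n_pairs`,
#'   `precision`, `sensitivity`, `specificity`, `average_score`.
#' @export
run_grid <- function(datasets, grid, reference, max_delay = 0L,
                     base_params = inference_params(max_delay = max_delay),
                     rca = 1) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L)
  universe <- Reduce(intersect, lapply(datasets, `[[`, "genes"))
  cache <- new.env(parent = emptyenv())
  infer_at <- function(acc, scp) {
    key <- sprintf("%.10g|%.10g", acc, scp)
    if (!is.null(cache[[key]])) return(cache[[key]])
    p <- inference_params(accuracy = acc, scp = scp, max_delay = max_delay,
                          allow_self_loops = base_params$allow_self_loops)
    res <- lapply(datasets, infer_rules, params = p)
    cache[[key]] <- res
    res
  }
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    acc <- if ("accuracy" %in% names(grid)) grid$accuracy[i] else base_params$accuracy
    scp <- if ("scp" %in% names(grid)) grid$scp[i] else base_params$scp
    r <- if ("rca" %in% names(grid)) grid$rca[i] else rca
    cons <- consensus_rules(infer_at(acc, scp), rca = r)
    pairs <- project_pairs(cons)
    m <- pair_metrics(pairs, reference, universe)
    cbind(grid[i, , drop = FALSE],
          data.frame(n_rules = nrow(cons$rules), n_pairs = nrow(pairs),
                     precision = m$precision, sensitivity = m$sensitivity,
                     specificity = m$specificity,
                     average_score = m$average_score))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
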
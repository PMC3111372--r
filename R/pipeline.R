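# End-to-end drivers wiring the modules together: read -> impute ->
# intersect gene universes -> per-dataset, per-delay inference -> consensus
# -> rule table on disk.  These are also the entry points behind the
# command-line wrapper shipped in inst/cli.

#' Infer consensus time-lagged rules from one or more datasets
#'
#' Full pipeline: datasets are loaded (when given as file paths), missing
#' values handled, gene universes intersected, rules inferred per dataset
#' for every delay `0..max_delay`, and the per-dataset rule sets combined
#' by the RCA-thresholded consensus.  The pipeline is deterministic:
#' identical inputs and parameters give identical output.
#'
#' @param datasets List of [expression_dataset()] objects and/or TSV file
#'   paths accepted by [read_expression()].
#' @param accuracy,scp,rca,max_delay,allow_self_loops See
#'   [inference_params()] and [consensus_rules()].  When `max_delay` is
#'   `NULL` and `delta_t_hypothesis` is given, the bound is derived with
#'   [compute_max_delay()] from the datasets' sampling intervals.
#' @param delta_t_hypothesis Optional maximum hypothesized regulatory delay
#'   in minutes (requires every dataset to carry a `sampling_interval`).
#' @param impute Missing-value policy, see [impute_missing()].
#' @param rules_path Optional path: write the consensus rules as TSV.
#' @param log_path Optional path: write a plain-text run log (parameters,
#'   per-dataset TDT exclusions per delay, per-delay rule counts).
#' @return The [consensus_rules()] object, with an extra `run_info`
#'   element: list of per-dataset exclusion tables and per-delay consensus
#'   rule counts.
#' @examples
#' st <- generate_synthetic(6, 10, 2,
#'                          planted = list(planted_rule("G01", "G02", 1, 1)),
#'                          seed = 7)
#' run_inference(st$datasets, accuracy = 0.75, scp = 0.95, rca = 1,
#'               max_delay = 1)
#' @export
run_inference <- function(datasets, accuracy = 0.75, scp = 0.95, rca = 1,
                          max_delay = NULL, delta_t_hypothesis = NULL,
                          impute = c("drop_gene", "row_mean"),
                          allow_self_loops = FALSE,
                          rules_path = NULL, log_path = NULL) {
  impute <- match.arg(impute)
  if (inherits(datasets, "expression_dataset")) datasets <- list(datasets)
  datasets <- lapply(datasets, function(d) {
    if (is.character(d)) read_expression(d) else d
  })
  stopifnot(length(datasets) >= 1L,
            all(vapply(datasets, inherits, logical(1), "expression_dataset")))
  datasets <- lapply(datasets, impute_missing, method = impute)
  datasets <- intersect_genes(datasets)
  m_k <- vapply(datasets, function(d) length(d$timepoints), integer(1))
  if (is.null(max_delay)) {
    if (is.null(delta_t_hypothesis))
      stop("supply either `max_delay` or `delta_t_hypothesis`")
    ivals <- vapply(datasets, function(d) {
      if (is.null(d$sampling_interval))
        stop("dataset '", d$name, "' has no sampling_interval; ",
             "cannot derive max_delay from delta_t_hypothesis")
      d$sampling_interval
    }, numeric(1))
    max_delay <- compute_max_delay(delta_t_hypothesis, ivals, m_k)
  }
  if (max_delay > min(m_k) - 4L)
    stop(sprintf("max_delay %d exceeds the bound m - 4 = %d of dataset '%s'",
                 max_delay, min(m_k) - 4L,
                 datasets[[which.min(m_k)]]$name))
  params <- inference_params(accuracy = accuracy, scp = scp,
                             max_delay = max_delay,
                             allow_self_loops = allow_self_loops)
  per_ds <- lapply(datasets, infer_rules, params = params)
  cons <- consensus_rules(per_ds, rca = rca)
  per_delay <- vapply(0:max_delay, function(w) sum(cons$rules$delay == w),
                      integer(1))
  names(per_delay) <- sprintf("w%d", 0:max_delay)
  cons$run_info <- list(
    params = params, rca = rca,
    n_genes = length(datasets[[1]]$genes),
    dataset_names = vapply(datasets, `[[`, character(1), "name"),
    exclusions = lapply(per_ds, `[[`, "exclusions"),
    per_dataset_rules = vapply(per_ds, function(x) nrow(x$rules), integer(1)),
    per_delay_consensus = per_delay)
  if (!is.null(rules_path)) write_rules(cons, rules_path)
  if (!is.null(log_path)) writeLines(format_run_log(cons), log_path)
  cons
}

format_run_log <- function(cons) {
  ri <- cons$run_info
  p <- ri$params
  lines <- c(
    "lagrules inference run",
    sprintf("parameters: accuracy=%g scp=%g rca=%g max_delay=%d self_loops=%s",
            p$accuracy, p$scp, ri$rca, p$max_delay, p$allow_self_loops),
    sprintf("gene universe: %d genes; datasets: %s",
            ri$n_genes, paste(ri$dataset_names, collapse = ", ")),
    sprintf("per-dataset rule counts: %s",
            paste(sprintf("%s=%d", ri$dataset_names, ri$per_dataset_rules),
                  collapse = ", ")),
    sprintf("consensus rules per delay: %s",
            paste(sprintf("%s=%d", names(ri$per_delay_consensus),
                          ri$per_delay_consensus), collapse = ", ")))
  for (i in seq_along(ri$exclusions)) {
    ex <- ri$exclusions[[i]]
    if (nrow(ex) == 0) next
    lines <- c(lines, sprintf("TDT exclusions in %s:", ri$dataset_names[i]),
               sprintf("  w=%d gene=%s", ex$delay, ex$gene))
  }
  lines
}

#' Evaluate a rule table against a reference pair set
#'
#' Projects the rules to undirected gene pairs and computes
#' [pair_metrics()] against the reference over the given universe.  Genes
#' appearing in the rules but absent from the universe are dropped with a
#' warning.
#'
#' @param rules A [consensus_rules()] object, rule data frame, or path to a
#'   TSV written by [write_rules()].
#' @param reference A [reference_pairs()] set or path to a reference TSV.
#' @param universe Character vector of universe genes, or path to a
#'   one-gene-per-line text file.
#' @param json_path,tsv_path Optional output paths for the metrics report.
#' @return A [pair_metrics()] object.
#' @export
evaluate_rules <- function(rules, reference, universe,
                           json_path = NULL, tsv_path = NULL) {
  if (is.character(rules) && length(rules) == 1L && file.exists(rules))
    rules <- read_rules(rules)
  if (is.character(reference) && length(reference) == 1L && file.exists(reference))
    reference <- read_reference_pairs(reference)
  if (is.character(universe) && length(universe) == 1L && file.exists(universe))
    universe <- readLines(universe)
  universe <- unique(trimws(as.character(universe)))
  universe <- universe[nzchar(universe)]
  pairs <- project_pairs(rules)
  unknown <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), universe)
  if (length(unknown) > 0)
    warning("rules mention ", length(unknown),
            " gene(s) outside the universe; they are ignored: ",
            paste(utils::head(unknown, 5L), collapse = ", "))
  m <- pair_metrics(pairs, reference, universe)
  if (!is.null(json_path))
    jsonlite::write_json(unclass(m), json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv_path))
    utils::write.table(as.data.frame(unclass(m)), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  m
}
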
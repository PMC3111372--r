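#' Expression time-series dataset
#'
#' Container for one gene-expression time-series matrix: genes in rows,
#' ordered time points in columns, values on a log-ratio scale.  Columns are
#' taken to be in true temporal order and are never reordered.  Missing
#' entries are allowed (`NA`) until imputation; all inference functions
#' require a complete matrix.
#'
#' @param values Numeric matrix, genes x time points.  Row names (or
#'   `genes`) give unique gene identifiers; column names (or `timepoints`)
#'   label the samples.
#' @param name Text label for the dataset.
#' @param genes Optional character vector of gene identifiers overriding row
#'   names.
#' @param timepoints Optional character vector of sample labels overriding
#'   column names.
#' @param sampling_interval Optional positive sampling interval (minutes)
#'   between consecutive time points, used only by [compute_max_delay()].
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `name`, `genes`, `timepoints`, `values` and `sampling_interval`.
#'
#' @details At least 5 time points are required, so that a delay-0 inference
#'   with the minimum of 4 aligned samples remains possible with margin.
#'   Duplicate gene identifiers are rejected rather than aggregated.
#'
#' @seealso [read_expression()], [impute_missing()], [intersect_genes()]
#' @export
expression_dataset <- function(values, name = "dataset", genes = NULL,
                               timepoints = NULL, sampling_interval = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x time points)")
  if (is.null(genes)) genes <- rownames(values)
  if (is.null(timepoints)) timepoints <- colnames(values)
  if (is.null(genes)) genes <- sprintf("gene%d", seq_len(nrow(values)))
  if (is.null(timepoints)) timepoints <- sprintf("t%d", seq_len(ncol(values)))
  genes <- as.character(genes)
  timepoints <- as.character(timepoints)
  if (length(genes) != nrow(values))
    stop("length of `genes` does not match the number of rows")
  if (length(timepoints) != ncol(values))
    stop("length of `timepoints` does not match the number of columns")
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (ncol(values) < 5L)
    stop("at least 5 time points are required, got ", ncol(values))
  if (any(is.infinite(values)))
    stop("non-finite expression values (Inf) are not allowed")
  if (!is.null(sampling_interval)) {
    sampling_interval <- as.numeric(sampling_interval)
    if (length(sampling_interval) != 1L || !is.finite(sampling_interval) ||
        sampling_interval <= 0)
      stop("`sampling_interval` must be a single positive number")
  }
  dimnames(values) <- list(genes, timepoints)
  structure(
    list(name = as.character(name)[1L], genes = genes,
         timepoints = timepoints, values = values,
         sampling_interval = sampling_interval),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset '%s': %d genes x %d time points\n",
              x$name, length(x$genes), length(x$timepoints)))
  n_na <- sum(is.na(x$values))
  if (n_na > 0) cat(sprintf("  %d missing entries\n", n_na))
  if (!is.null(x$sampling_interval))
    cat(sprintf("  sampling interval: %g min\n", x$sampling_interval))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Read an expression matrix from a tab-separated file
#'
#' Expects a header row of time-point labels, a first column of gene
#' identifiers, and numeric cells.  `NA` or empty cells mark missing values.
#' A malformed numeric cell raises an error naming the offending gene and
#' column; duplicate gene identifiers are rejected.
#'
#' @param path Path to a TSV file.
#' @param name Dataset label; defaults to the file name without extension.
#' @inheritParams expression_dataset
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, name = NULL, sampling_interval = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(), quote = "",
                           comment.char = "")
  if (ncol(raw) < 2L) stop("expected a gene-id column plus data columns in ", path)
  genes <- trimws(raw[[1L]])
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  cells <- trimws(cells)
  missing_tok <- cells == "" | toupper(cells) == "NA"
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !missing_tok, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    b <- bad[1L, ]
    stop(sprintf("malformed numeric cell '%s' at gene '%s', column '%s' in %s",
                 cells[b[1L], b[2L]], genes[b[1L]],
                 colnames(raw)[-1L][b[2L]], path))
  }
  expression_dataset(num, name = name, genes = genes,
                     timepoints = colnames(raw)[-1L],
                     sampling_interval = sampling_interval)
}

#' Write an expression dataset to a tab-separated file
#'
#' Values are written with 17 significant digits so that
#' `read_expression(write_expression(ds))` round-trips finite values
#' bit-exactly.  Missing entries are written as `NA`.
#'
#' @param ds An [expression_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(ds, path) {
  stopifnot(inherits(ds, "expression_dataset"))
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  lines <- c(paste(c("gene", ds$timepoints), collapse = "\t"),
             vapply(seq_along(ds$genes), function(i) {
               paste(c(ds$genes[i], fmt(ds$values[i, ])), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Handle missing expression values
#'
#' `drop_gene` (the default) removes every gene with any missing entry, so
#' that no invented value can influence the downstream threshold searches.
#' `row_mean` replaces each missing entry with the mean of the gene's
#' observed entries.
#'
#' @param ds An [expression_dataset()].
#' @param method `"drop_gene"` or `"row_mean"`.
#' @return A complete [expression_dataset()] (no missing entries).
#' @export
impute_missing <- function(ds, method = c("drop_gene", "row_mean")) {
  stopifnot(inherits(ds, "expression_dataset"))
  method <- match.arg(method)
  v <- ds$values
  if (!anyNA(v)) return(ds)
  if (method == "drop_gene") {
    keep <- rowSums(is.na(v)) == 0L
    if (!any(keep)) stop("all genes have missing values in dataset '", ds$name, "'")
    expression_dataset(v[keep, , drop = FALSE], name = ds$name,
                       sampling_interval = ds$sampling_interval)
  } else {
    all_na <- rowSums(!is.na(v)) == 0L
    if (any(all_na))
      stop("gene(s) with all entries missing cannot be mean-imputed: ",
           paste(ds$genes[all_na], collapse = ", "))
    for (i in which(rowSums(is.na(v)) > 0L)) {
      v[i, is.na(v[i, ])] <- mean(v[i, ], na.rm = TRUE)
    }
    expression_dataset(v, name = ds$name,
                       sampling_interval = ds$sampling_interval)
  }
}

#' Restrict datasets to their common gene universe
#'
#' Each returned dataset contains exactly the genes measured in all input
#' datasets, with rows in the sorted common order.  The operation is
#' idempotent and insensitive to the order of the input list.
#'
#' @param datasets A list of [expression_dataset()] objects.
#' @return A list of datasets restricted to the shared, sorted gene list.
#' @export
intersect_genes <- function(datasets) {
  if (inherits(datasets, "expression_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1L,
            all(vapply(datasets, inherits, logical(1), "expression_dataset")))
  common <- Reduce(intersect, lapply(datasets, `[[`, "genes"))
  if (length(common) == 0L)
    stop("no gene is present in all datasets (empty intersection)")
  common <- sort(common)
  lapply(datasets, function(ds) {
    expression_dataset(ds$values[common, , drop = FALSE], name = ds$name,
                       sampling_interval = ds$sampling_interval)
  })
}

#' Render the textual form of a rule
#'
#' Produces the conventional arrow syntax, e.g. type 1 as
#' `"+/- CLB1 3 -> +/- CLB5"` (if CLB1 is above its pair-specific threshold
#' at time j, CLB5 is upregulated at time j+3, and conversely below), type
#' -1 with `-/+` on the right, and the one-sided types 2, 3, -2, -3 with a
#' single `+` or `-` on each side.
#'
#' @param regulator,target Gene identifiers.
#' @param delay Non-negative integer time delay.
#' @param rule_type Integer in -3..3 excluding 0.
#' @return Character vector of rule strings (vectorized over arguments).
#' @export
rule_string <- function(regulator, delay, target, rule_type) {
  stopifnot(all(rule_type %in% c(-3L, -2L, -1L, 1L, 2L, 3L)))
  left <- c(`-3` = "+", `-2` = "-", `-1` = "+/-",
            `1` = "+/-", `2` = "+", `3` = "-")[as.character(rule_type)]
  right <- c(`-3` = "-", `-2` = "+", `-1` = "-/+",
             `1` = "+/-", `2` = "+", `3` = "-")[as.character(rule_type)]
  sprintf("%s %s %d -> %s %s", left, regulator, as.integer(delay), right, target)
}

#' Write a consensus rule set to a tab-separated file
#'
#' One rule per row with columns `regulator`, `delay`, `target`,
#' `rule_type`, `rule_string`, `accuracy` (the minimum score across
#' supporting datasets) and `support_fraction`.  An empty rule set produces
#' a header-only file.
#'
#' @param rules A [consensus_rules()] result (or a data frame with the same
#'   columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rules <- function(rules, path) {
  df <- if (inherits(rules, "consensus_rules")) rules$rules else as.data.frame(rules)
  out <- data.frame(
    regulator = df$regulator,
    delay = as.integer(df$delay),
    target = df$target,
    rule_type = as.integer(df$rule_type),
    rule_string = rule_string(df$regulator, df$delay, df$target, df$rule_type),
    accuracy = if ("consensus_score" %in% names(df)) df$consensus_score else df$score,
    support_fraction = if ("support_fraction" %in% names(df)) df$support_fraction
                       else rep(1, nrow(df)),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a rule table written by [write_rules()]
#'
#' @param path Path to a rules TSV.
#' @return A data frame with the columns written by [write_rules()].
#' @export
read_rules <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
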
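#' Expression matrix container
#'
#' A features-by-samples numeric matrix with an identifier axis and a value
#' kind. `activity` values are per-sample expression probabilities in
#' \[0,1\] (UPC-style), `log2_intensity` are continuous normalized
#' intensities (RMA-style), `fpkm_uq` are upper-quartile normalized RNA-seq
#' units, and `mixed` marks simulated matrices carrying an activity-scale
#' marker track alongside continuous gene intensities (range checks are
#' skipped for `mixed`).
#'
#' @param values numeric matrix with rownames (feature ids) and colnames
#'   (sample ids).
#' @param value_kind one of `"activity"`, `"log2_intensity"`, `"fpkm_uq"`,
#'   `"mixed"`.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values,
                              value_kind = c("activity", "log2_intensity",
                                             "fpkm_uq", "mixed")) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry feature ids (rownames) and sample ids (colnames)")
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  if (anyDuplicated(rownames(values)))
    rownames(values) <- make.unique(rownames(values), sep = "_dup")
  if (any(apply(values, 1, function(r) all(is.na(r)))))
    stop("matrix contains fully-missing feature rows")
  if (value_kind == "activity") {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1)
      stop("activity values must lie in [0,1]; observed range [",
           signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  }
  structure(list(feature_ids = rownames(values),
                 sample_ids = colnames(values),
                 values = values,
                 value_kind = value_kind),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d features x %d samples (%s)\n",
              length(x$feature_ids), length(x$sample_ids), x$value_kind))
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expects a UTF-8 tab-separated file whose header row holds sample ids and
#' whose first column holds feature ids. Duplicate feature ids are kept and
#' disambiguated with a `_dup` suffix; duplicate sample columns are an
#' error naming the offending column.
#'
#' @param path file path.
#' @inheritParams expression_matrix
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path,
                            value_kind = c("activity", "log2_intensity",
                                           "fpkm_uq", "mixed")) {
  value_kind <- match.arg(value_kind)
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2)
    stop("malformed header: need a feature id column plus ",
         "at least one sample column")
  dup <- unique(header[-1][duplicated(header[-1])])
  if (length(dup))  # read.table would silently uniquify these
    stop("duplicate sample column(s): ", paste(dup, collapse = ", "))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  feat <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  nonnum <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(nonnum))
    stop("non-numeric cell(s) in column(s): ", paste(nonnum, collapse = ", "))
  m <- as.matrix(vals)
  rownames(m) <- feat
  expression_matrix(m, value_kind = value_kind)
}

#' Write an expression matrix to TSV
#'
#' @param x an [expression_matrix()].
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(feature_id = x$feature_ids, x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_full(df, path)
  invisible(path)
}

# TSV writer keeping full double precision (%.17g) so round trips are exact.
write_tsv_full <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table from TSV
#'
#' Requires columns `sample_id`, `dfs_time` (non-negative disease-free
#' survival time) and `dfs_event` (0 = censored, 1 = event). Any further
#' columns are carried along as covariates. Missing (`NA`) survival fields
#' are permitted here; downstream harmonization drops those samples with a
#' logged count.
#'
#' @param path file path.
#' @return A data frame of class `clinical_table`.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("sample_id", "dfs_time", "dfs_event")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id(s) in clinical table")
  if (any(df$dfs_time < 0, na.rm = TRUE))
    stop("negative dfs_time values")
  if (!all(df$dfs_event %in% c(0, 1, NA)))
    stop("dfs_event must be 0 (censored) or 1 (event)")
  class(df) <- c("clinical_table", class(df))
  df
}

#' Read a gene set (GMT line or one symbol per line)
#'
#' A line containing tabs is parsed as the GMT dialect
#' (`name<TAB>description<TAB>member...`); otherwise each non-empty line is
#' one gene symbol. Only the first GMT record is used.
#'
#' @param path file path.
#' @param name set name when the file is a plain symbol list.
#' @return A `gene_set`: list with `name` and unique, non-empty `members`.
#' @export
read_geneset <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty gene set file: ", path)
  if (grepl("\t", lines[1])) {
    fields <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) stop("malformed GMT line: need name, ",
                                 "description and at least one member")
    gs <- list(name = fields[1], members = unique(fields[-(1:2)]))
  } else {
    gs <- list(name = name, members = unique(trimws(lines)))
  }
  gs$members <- gs$members[nzchar(gs$members)]
  if (!length(gs$members)) stop("gene set has no members")
  structure(gs, class = "gene_set")
}

#' Intersect expression and clinical data on sample ids
#'
#' Samples are matched by id; samples lacking survival information (missing
#' from the clinical table, or with `NA` time/event) are excluded from the
#' survival-eligible view with a logged count, mirroring standard cohort
#' curation. The full expression matrix is retained for correlation stages.
#'
#' @param expression an [expression_matrix()].
#' @param clinical a `clinical_table`.
#' @return List with `expression` (all matched samples), `clinical`
#'   (survival-eligible rows only, ordered like the expression columns they
#'   match), and `n_dropped` (samples excluded from survival).
#' @export
harmonize_cohort <- function(expression, clinical) {
  stopifnot(inherits(expression, "expression_matrix"))
  common <- intersect(expression$sample_ids, clinical$sample_id)
  if (!length(common)) stop("no overlapping sample ids")
  expr <- expression_matrix(
    expression$values[, common, drop = FALSE],
    value_kind = expression$value_kind)
  cl <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  eligible <- !is.na(cl$dfs_time) & !is.na(cl$dfs_event)
  n_dropped <- (length(expression$sample_ids) - length(common)) +
    sum(!eligible)
  if (n_dropped > 0)
    message(n_dropped, " sample(s) lack survival information and are ",
            "excluded from survival analysis")
  list(expression = expr,
       clinical = cl[eligible, , drop = FALSE],
       n_dropped = n_dropped)
}

#' Pick the marker probe/feature row
#'
#' When a primary probe id is given and present it wins (the study design
#' may fix a probe shared across platforms); otherwise the candidate row
#' with the highest variance across samples is chosen and the choice is
#' logged.
#'
#' @param expression an [expression_matrix()].
#' @param candidates feature ids mapping to the marker.
#' @param primary optional fixed primary probe id.
#' @return The selected feature id.
#' @export
select_marker_probe <- function(expression, candidates, primary = NULL) {
  present <- intersect(candidates, expression$feature_ids)
  if (!length(present)) stop("none of the candidate features are present")
  if (!is.null(primary) && primary %in% present) return(primary)
  if (length(present) == 1) return(present)
  v <- apply(expression$values[present, , drop = FALSE], 1,
             stats::var, na.rm = TRUE)
  pick <- present[which.max(v)]
  message("marker probe unresolved; picked highest-variance feature: ", pick)
  pick
}

#' Write the report tables of a pipeline run
#'
#' Emits the stratification count summary, the top-k correlation table and
#' the per-gene survival screen as TSV files under `dir`.
#'
#' @param results list with any of `stratification`, `correlation`,
#'   `screen` data frames (as produced by [run_pipeline()]).
#' @param dir output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_report_tables <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(df, file) {
    p <- file.path(dir, file)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  if (!is.null(results$stratification))
    paths <- c(paths, emit(results$stratification,
                           "stratification_summary.tsv"))
  if (!is.null(results$correlation))
    paths <- c(paths, emit(results$correlation, "correlation_table.tsv"))
  if (!is.null(results$screen))
    paths <- c(paths, emit(results$screen, "survival_screen.tsv"))
  invisible(paths)
}
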
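#' Expression matrix container
#'
#' Features-by-samples matrix of expression values with a parallel logical
#' detection mask.  This is the central carrier for miRNA microarray
#' intensities (log2 scale) and for normalized count data.  Undetected cells
#' (platform flag absent, or empty/NA cells in a TSV) carry `detected =
#' FALSE`; their numeric value is `NA` until an explicit imputation step.
#'
#' @param values numeric matrix, features in rows, samples in columns, with
#'   unique non-empty dimnames.
#' @param detected logical matrix of the same shape, or `NULL` for all-TRUE.
#' @param scale_tag `"log2"` for log-scale intensities or `"linear_counts"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, detected = NULL,
                              scale_tag = c("log2", "linear_counts")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("'values' must carry feature rownames and sample colnames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup) > 0)
    stopf("duplicated feature id(s): %s", paste(unique(dup), collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup) > 0)
    stopf("duplicated sample id(s): %s", paste(unique(dup), collapse = ", "))
  if (is.null(detected)) {
    detected <- !is.na(values)
  }
  if (!is.matrix(detected) || !is.logical(detected) ||
      !identical(dim(detected), dim(values)))
    stopf("'detected' must be a logical matrix of the same shape as 'values'")
  dimnames(detected) <- dimnames(values)
  if (any(detected & !is.finite(values)))
    stopf("non-finite value in a cell flagged as detected")
  structure(list(values = values, detected = detected, scale_tag = scale_tag),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d features x %d samples [%s], %.1f%% detected\n",
              nrow(x$values), ncol(x$values), x$scale_tag,
              100 * mean(x$detected)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

feature_ids <- function(m) rownames(m$values)
sample_ids <- function(m) colnames(m$values)

# Subset an expression matrix by feature / sample index or name.
em_subset <- function(m, features = NULL, samples = NULL) {
  v <- m$values
  d <- m$detected
  if (!is.null(features)) {
    v <- v[features, , drop = FALSE]
    d <- d[features, , drop = FALSE]
  }
  if (!is.null(samples)) {
    v <- v[, samples, drop = FALSE]
    d <- d[, samples, drop = FALSE]
  }
  expression_matrix(v, d, m$scale_tag)
}

#' Read an expression matrix from tab-separated text
#'
#' Expected layout: a header row of sample ids, first column feature ids,
#' remaining cells numeric.  Empty cells and the literal strings `NA`/`na`
#' mark undetected measurements (microarray exports differ on which they
#' emit); both map to `detected = FALSE`.
#'
#' @param path path of the TSV file.
#' @param scale_tag `"log2"` or `"linear_counts"`.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, scale_tag = c("log2", "linear_counts")) {
  scale_tag <- match.arg(scale_tag)
  lines <- readLines(path)
  if (length(lines) < 2) stopf("expression file '%s' has no data rows", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  n_col <- length(header)
  samples <- header[-1]
  body <- fields[-1]
  widths <- lengths(body)
  # trailing empty cells are dropped by strsplit; re-pad, but flag rows that
  # are genuinely ragged (too long or short beyond trailing blanks is not
  # distinguishable, so only over-long rows are hard errors)
  bad <- which(widths > n_col)
  if (length(bad) > 0)
    stopf("ragged row at line %d of '%s' (%d fields, header has %d)",
          bad[1] + 1L, path, widths[bad[1]], n_col)
  body <- lapply(body, function(f) c(f, rep("", n_col - length(f))))
  cells <- do.call(rbind, body)
  features <- cells[, 1]
  dup <- unique(features[duplicated(features)])
  if (length(dup) > 0)
    stopf("duplicated feature id(s) in '%s': %s", path,
          paste(dup, collapse = ", "))
  raw <- cells[, -1, drop = FALSE]
  undet <- raw == "" | toupper(raw) == "NA"
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  if (any(is.na(vals) & !undet)) {
    idx <- which(is.na(vals) & !undet, arr.ind = TRUE)[1, ]
    stopf("non-numeric cell '%s' at line %d of '%s'",
          raw[idx[1], idx[2]], idx[1] + 1L, path)
  }
  vals[undet] <- NA_real_
  dimnames(vals) <- list(features, samples)
  m <- expression_matrix(vals, !undet, scale_tag)
  stage_log("io", "read %d features x %d samples from %s",
            nrow(vals), ncol(vals), path)
  m
}

#' Write an expression matrix as tab-separated text
#'
#' Undetected cells are written as empty fields so that a read/write cycle
#' round-trips the detection mask.  Values are printed with 15 significant
#' digits, lossless at the precision the pipeline works with.
#'
#' @param m an [expression_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  txt <- matrix(formatC(m$values, format = "g", digits = 15),
                nrow = nrow(m$values))
  txt[!m$detected] <- ""
  lines <- c(paste(c("feature", sample_ids(m)), collapse = "\t"),
             vapply(seq_len(nrow(txt)), function(i) {
               paste(c(feature_ids(m)[i], txt[i, ]), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Tab-separated, one row per sample; must contain a `sample_id` column and
#' may carry `tissue`, `mrna_subtype`, `cms_label`, `msi`, `braf`,
#' `stroma_percent`.  Duplicate sample ids and out-of-range stroma
#' percentages are errors.
#'
#' @param path TSV path.
#' @return A data.frame.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(ann))
    stopf("annotation '%s' lacks a sample_id column", path)
  dup <- unique(ann$sample_id[duplicated(ann$sample_id)])
  if (length(dup) > 0)
    stopf("duplicated sample id(s) in annotation: %s", paste(dup, collapse = ", "))
  if ("stroma_percent" %in% names(ann)) {
    sp <- ann$stroma_percent
    if (any(!is.na(sp) & (sp < 0 | sp > 100)))
      stopf("stroma_percent outside [0, 100]")
  }
  ann
}

#' @rdname read_annotation
#' @param ann annotation data.frame.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
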
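# Internal helpers shared across stages.

# Validate a genes x samples expression matrix: numeric, unique dimnames.
check_expr <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(what, " must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(what, " must carry gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) stop(what, ": duplicated gene ids", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop(what, ": duplicated sample ids", call. = FALSE)
  if (any(!is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

check_metadata <- function(metadata, samples = NULL) {
  if (!is.data.frame(metadata)) stop("metadata must be a data frame", call. = FALSE)
  need <- c("sample_id", "trait")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!all(metadata$trait %in% c(0, 1))) stop("trait must be coded 0/1", call. = FALSE)
  if (anyDuplicated(metadata$sample_id)) stop("duplicated sample_id in metadata", call. = FALSE)
  if (!is.null(samples) && !all(samples %in% metadata$sample_id)) {
    stop("metadata is missing entries for some expression samples", call. = FALSE)
  }
  invisible(metadata)
}

check_square_symmetric <- function(m, what, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop(what, " must be square", call. = FALSE)
  if (max(abs(m - t(m))) > tol) stop(what, " must be symmetric", call. = FALSE)
  invisible(m)
}

# Two-sided p-value for a Pearson correlation via the t transform.
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  df <- n - 2
  t <- abs(r) * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(t, df, lower.tail = FALSE)
}

# Matrix <-> TSV with the gene/sample ids in the first column.
write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  df <- tibble::as_tibble(m, rownames = id_col)
  readr::write_tsv(df, path)
  invisible(path)
}

read_matrix_tsv <- function(path, id_col = "gene_id") {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
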
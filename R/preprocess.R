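#' Filter low-count and low-variability genes
#'
#' Two filters applied in a fixed order. First, a gene is removed when the
#' fraction of samples with a read count below `low_count` exceeds `low_prop`
#' in *both* trait groups — i.e. a gene survives if it is adequately expressed
#' in either group. Second, among survivors only the `ceiling(mad_keep * n)`
#' genes with the largest median absolute deviation (MAD) of TPM across all
#' samples are kept. MAD is computed on raw TPM, before any log transform.
#'
#' @param counts,tpm genes x samples matrices sharing gene and sample ids.
#' @param metadata data frame with `sample_id` and 0/1 `trait`; both groups
#'   must be nonempty among the expression samples.
#' @param low_count count threshold (strict: `count < low_count`).
#' @param low_prop proportion threshold (strict: fraction `> low_prop`).
#' @param mad_keep fraction of surviving genes kept by the MAD filter.
#' @return The TPM matrix restricted to the retained genes (original row
#'   order preserved), with attribute `filter_log` recording the gene counts
#'   after each step.
#' @export
filter_genes <- function(counts, tpm, metadata,
                         low_count = 10, low_prop = 0.9, mad_keep = 0.5) {
  check_expr(counts, "counts"); check_expr(tpm, "tpm")
  if (!identical(dimnames(counts), dimnames(tpm))) {
    stop("counts and tpm must share gene and sample ids", call. = FALSE)
  }
  check_metadata(metadata, colnames(counts))
  md <- metadata[match(colnames(counts), metadata$sample_id), ]
  g1 <- md$trait == 1; g0 <- md$trait == 0
  if (!any(g1) || !any(g0)) stop("both trait groups must be nonempty", call. = FALSE)

  low_in <- function(grp) rowMeans(counts[, grp, drop = FALSE] < low_count) > low_prop
  drop_low <- low_in(g1) & low_in(g0)
  survivors <- rownames(counts)[!drop_low]
  if (!length(survivors)) stop("all genes removed by the count filter", call. = FALSE)

  mads <- apply(tpm[survivors, , drop = FALSE], 1, mad)
  n_keep <- ceiling(mad_keep * length(survivors))
  ord <- order(-mads, survivors)  # ties broken by gene id for determinism
  kept <- survivors[sort(ord[seq_len(n_keep)])]

  out <- tpm[kept, , drop = FALSE]
  attr(out, "filter_log") <- tibble::tibble(
    step = c("input", "count_filter", "mad_filter"),
    n_genes = c(nrow(counts), length(survivors), length(kept))
  )
  out
}

#' Log-transform TPM expression
#'
#' Elementwise `log2(x + 1)`.
#'
#' @param tpm nonnegative genes x samples matrix.
#' @return matrix of the same shape.
#' @export
log_transform <- function(tpm) {
  check_expr(tpm, "tpm")
  if (any(tpm < 0)) stop("log_transform requires nonnegative values", call. = FALSE)
  log2(tpm + 1)
}

#' Estimate and remove surrogate variables by residual PCA
#'
#' A deliberately simple two-step surrogate-variable procedure: (1) regress
#' each gene on the trait plus the known covariates and take the top `n_sv`
#' right singular vectors of the row-standardized residual matrix as
#' surrogate variables (orthonormal over samples); (2) project each gene
#' onto the SV space and
#' subtract that projection, leaving gene means (and the trait signal, which
#' is never regressed out) intact. This captures the residual-PCA idea behind
#' full surrogate variable analysis without its permutation machinery.
#'
#' @param expr genes x samples matrix (log scale).
#' @param metadata data frame with `sample_id`, `trait` and the covariates.
#' @param known_covariates covariate names entering the first-stage design.
#' @param n_sv number of surrogate variables; 0 returns the input unchanged.
#' @return An object of class `surrogate_adjustment`: list with `n_sv`,
#'   `sv` (samples x n_sv orthonormal matrix) and `adjusted` (same shape as
#'   `expr`).
#' @export
remove_surrogates <- function(expr, metadata,
                              known_covariates = c("sex", "age", "bmi", "ischemic_time"),
                              n_sv = 3) {
  check_expr(expr)
  check_metadata(metadata, colnames(expr))
  stopifnot(n_sv >= 0, n_sv == round(n_sv))
  md <- metadata[match(colnames(expr), metadata$sample_id), ]
  covs <- intersect(known_covariates, names(md))
  covs <- covs[vapply(covs, function(v) length(unique(md[[v]])) > 1, logical(1))]
  design <- model.matrix(stats::reformulate(c("trait", covs)),
                         data = cbind(trait = md$trait, md[covs]))
  if (qr(design)$rank < ncol(design)) stop("rank-deficient design", call. = FALSE)
  if (n_sv >= ncol(expr) - qr(design)$rank) {
    stop("n_sv too large for the residual degrees of freedom", call. = FALSE)
  }

  if (n_sv == 0) {
    return(structure(list(n_sv = 0L, sv = matrix(0, ncol(expr), 0),
                          adjusted = expr), class = "surrogate_adjustment"))
  }

  qrd <- qr(design)
  resid <- t(qr.resid(qrd, t(expr)))          # genes x samples
  rs <- apply(resid, 1, sd)
  rs[rs == 0] <- 1                            # constant residual rows carry no signal
  sv <- svd(resid / rs, nu = 0, nv = n_sv)$v   # samples x n_sv, orthonormal
  rownames(sv) <- colnames(expr)
  colnames(sv) <- paste0("SV", seq_len(n_sv))

  centered <- expr - rowMeans(expr)
  adjusted <- expr - (centered %*% sv) %*% t(sv)
  structure(list(n_sv = as.integer(n_sv), sv = sv, adjusted = adjusted),
            class = "surrogate_adjustment")
}

#' @export
print.surrogate_adjustment <- function(x, ...) {
  cat(sprintf("Surrogate adjustment: %d SV(s) removed from %d genes x %d samples\n",
              x$n_sv, nrow(x$adjusted), ncol(x$adjusted)))
  invisible(x)
}

#' @export
tidy.surrogate_adjustment <- function(x, ...) {
  tibble::as_tibble(x$sv, rownames = "sample_id")
}
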
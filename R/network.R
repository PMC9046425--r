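#' Co-expression similarity matrix
#'
#' Unsigned similarity `s_ij = |Pearson cor(x_i, x_j)|` between gene
#' expression profiles, with an exact unit diagonal. A signed variant
#' (`(1 + cor)/2`) is available but the unsigned form is the default used
#' throughout the pipeline.
#'
#' @param expr genes x samples matrix; every gene must vary across samples.
#' @param type `"unsigned"` (default) or `"signed"`.
#' @return symmetric genes x genes matrix in \[0, 1\].
#' @export
cor_similarity <- function(expr, type = c("unsigned", "signed")) {
  type <- match.arg(type)
  check_expr(expr)
  if (ncol(expr) < 3) stop("need at least 3 samples", call. = FALSE)
  v <- apply(expr, 1, var)
  if (any(v == 0)) {
    stop("zero-variance gene(s): ",
         paste(head(rownames(expr)[v == 0], 5), collapse = ", "), call. = FALSE)
  }
  r <- cor(t(expr))
  s <- switch(type, unsigned = abs(r), signed = (1 + r) / 2)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  s
}

#' Soft-threshold selection by the scale-free topology criterion
#'
#' For each candidate power `beta`, the weighted connectivity
#' `k_i = sum_{j != i} s_ij^beta` is computed, `k` is split into `n_bins`
#' equal-count bins, and `log10` of the bin frequency is regressed on
#' `log10` of the bin mean connectivity. The fit index is the signed
#' R-squared `-sign(slope) * R^2`, so only decreasing (power-law-like)
#' degree distributions can score well. The chosen power is the smallest
#' `beta` whose signed R-squared reaches `r2_cut`; if none does, the best-
#' fitting `beta` is returned with a warning.
#'
#' @param s similarity matrix from [cor_similarity()].
#' @param beta_grid candidate integer powers.
#' @param r2_cut signed R-squared threshold (default 0.85).
#' @param n_bins number of equal-count connectivity bins (default 10).
#' @return An object of class `scale_free_fit`: list with `fit` (tibble:
#'   beta, signed_r2, slope, mean_k, median_k, max_k), `chosen_beta`,
#'   `r2_cut`, `n_bins`. `tidy()` returns the per-beta table, `glance()` the
#'   chosen row, `autoplot()` the standard fit/connectivity panels.
#' @export
pick_soft_threshold <- function(s, beta_grid = 1:20, r2_cut = 0.85, n_bins = 10) {
  check_square_symmetric(s, "similarity")
  if (nrow(s) < 20) stop("need at least 20 genes for a meaningful degree fit", call. = FALSE)
  stopifnot(all(beta_grid >= 1))

  fit_one <- function(beta) {
    a <- s^beta
    diag(a) <- 0
    k <- rowSums(a)
    if (diff(range(k)) < 1e-12 * max(k, 1)) {
      stop("degenerate connectivity: all genes have identical k (beta = ",
           beta, ")", call. = FALSE)
    }
    br <- unique(quantile(k, probs = seq(0, 1, length.out = n_bins + 1)))
    bins <- cut(k, breaks = br, include.lowest = TRUE)
    kbar <- tapply(k, bins, mean)
    # equal-count bins: the degree distribution p(k) is the bin density,
    # count / (n * bin width), not the raw (constant) bin frequency
    width <- diff(br)
    freq <- tapply(k, bins, length) / (length(k) * width)
    ok <- !is.na(kbar) & kbar > 0 & is.finite(freq) & freq > 0
    if (sum(ok) < 3) stop("degenerate connectivity binning (beta = ", beta, ")",
                          call. = FALSE)
    reg <- lm(log10(freq[ok]) ~ log10(kbar[ok]))
    slope <- unname(stats::coef(reg)[2])
    r2 <- summary(reg)$r.squared
    tibble::tibble(beta = beta, signed_r2 = -sign(slope) * r2, slope = slope,
                   mean_k = mean(k), median_k = median(k), max_k = max(k))
  }
  fit <- purrr::map_dfr(beta_grid, fit_one)

  hit <- fit$beta[fit$signed_r2 >= r2_cut]
  if (length(hit)) {
    chosen <- min(hit)
  } else {
    chosen <- fit$beta[which.max(fit$signed_r2)]
    warning(sprintf("no beta reached signed R^2 >= %.2f; using best fit beta = %d (R^2 = %.3f)",
                    r2_cut, chosen, max(fit$signed_r2)), call. = FALSE)
  }
  structure(list(fit = fit, chosen_beta = chosen, r2_cut = r2_cut,
                 n_bins = n_bins), class = "scale_free_fit")
}

#' @export
print.scale_free_fit <- function(x, ...) {
  row <- x$fit[x$fit$beta == x$chosen_beta, ]
  cat(sprintf("Scale-free fit: chosen beta = %d (signed R^2 = %.3f, mean k = %.2f)\n",
              x$chosen_beta, row$signed_r2, row$mean_k))
  invisible(x)
}

#' @export
tidy.scale_free_fit <- function(x, ...) x$fit

#' @export
glance.scale_free_fit <- function(x, ...) {
  row <- x$fit[x$fit$beta == x$chosen_beta, ]
  tibble::tibble(chosen_beta = x$chosen_beta, signed_r2 = row$signed_r2,
                 slope = row$slope, mean_k = row$mean_k, r2_cut = x$r2_cut)
}

#' @export
autoplot.scale_free_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$fit, c("signed_r2", "mean_k"),
                            names_to = "metric")
  hline <- tibble::tibble(metric = "signed_r2", y = object$r2_cut)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = .data$value)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_text(ggplot2::aes(label = .data$beta), size = 3) +
    ggplot2::geom_hline(data = hline, ggplot2::aes(yintercept = .data$y),
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "soft threshold (beta)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Power adjacency
#'
#' `a_ij = s_ij^beta`; the diagonal is zeroed, the convention used for
#' connectivity and topological overlap.
#'
#' @param s similarity matrix.
#' @param beta soft-threshold power, `>= 1`.
#' @return symmetric adjacency matrix in \[0, 1\] with zero diagonal and
#'   attribute `beta`.
#' @export
soft_adjacency <- function(s, beta) {
  check_square_symmetric(s, "similarity")
  if (length(beta) != 1 || !is.finite(beta) || beta < 1) {
    stop("beta must be a single number >= 1", call. = FALSE)
  }
  a <- s^beta
  diag(a) <- 0
  attr(a, "beta") <- beta
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` and `k_i = sum_u a_iu`; the diagonal is set to 1
#' so the dissimilarity `1 - TOM` has a zero diagonal for clustering. The
#' shared-neighbor term is computed as a matrix product.
#'
#' @param a adjacency matrix from [soft_adjacency()] (zero or unit diagonal
#'   accepted; the diagonal is ignored).
#' @return list of class `tom_matrix` with elements `tom` and `diss`
#'   (`1 - tom`), both symmetric with the stated diagonal conventions.
#' @export
topological_overlap <- function(a) {
  check_square_symmetric(a, "adjacency")
  if (any(a < 0 | a > 1)) stop("adjacency values must lie in [0, 1]", call. = FALSE)
  a0 <- a
  diag(a0) <- 0
  l <- a0 %*% a0
  k <- rowSums(a0)
  denom <- outer(k, k, pmin) + 1 - a0
  tom <- (l + a0) / denom
  tom <- (tom + t(tom)) / 2
  diag(tom) <- 1
  diss <- 1 - tom
  diag(diss) <- 0
  structure(list(tom = tom, diss = diss, beta = attr(a, "beta")),
            class = "tom_matrix")
}

#' @export
print.tom_matrix <- function(x, ...) {
  off <- x$tom[upper.tri(x$tom)]
  cat(sprintf("TOM: %d genes, off-diagonal range [%.4f, %.4f]%s\n",
              nrow(x$tom), min(off), max(off),
              if (!is.null(x$beta)) sprintf(", beta = %g", x$beta) else ""))
  invisible(x)
}
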
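#' Detect outlier samples via a distance-based sample network
#'
#' Within each trait group, samples form a network whose adjacency is
#' `A_uv = 1 - d_uv / max(d)`, with `d_uv` the Euclidean distance between the
#' samples' expression profiles. The connectivity `k_u = sum_{v != u} A_uv`
#' is standardized within the group (`Z.k`), and samples with
#' `Z.k < cutoff` are flagged. A single pass is made: the report is computed
#' once on the full group, with no re-standardization after removal.
#'
#' @param expr genes x samples matrix (adjusted or log-TPM scale).
#' @param metadata data frame with `sample_id` and 0/1 `trait`.
#' @param cutoff standardized-connectivity threshold (default -2.5).
#' @return An object of class `sample_qc_report`: a tibble with columns
#'   `sample_id`, `group` ("case"/"control"), `k`, `z_k`, `flagged`, plus the
#'   cutoff as an attribute. `autoplot()` draws Z.k per sample.
#' @export
detect_outliers <- function(expr, metadata, cutoff = -2.5) {
  check_expr(expr)
  check_metadata(metadata, colnames(expr))
  md <- metadata[match(colnames(expr), metadata$sample_id), ]

  one_group <- function(ids, group) {
    if (length(ids) < 4) {
      stop("sample-network QC needs at least 4 samples per group", call. = FALSE)
    }
    d <- as.matrix(dist(t(expr[, ids, drop = FALSE])))
    mx <- max(d)
    if (mx == 0) {
      warning("all samples identical in group '", group,
              "'; no outliers can be flagged", call. = FALSE)
      a <- matrix(1, length(ids), length(ids))
    } else {
      a <- 1 - d / mx
    }
    diag(a) <- 0
    k <- rowSums(a)
    s <- sd(k)
    z <- if (s == 0) rep(0, length(k)) else (k - mean(k)) / s
    tibble::tibble(sample_id = ids, group = group, k = k, z_k = z,
                   flagged = z < cutoff)
  }

  out <- dplyr::bind_rows(
    one_group(md$sample_id[md$trait == 1], "case"),
    one_group(md$sample_id[md$trait == 0], "control")
  )
  structure(out, class = c("sample_qc_report", class(out)), cutoff = cutoff)
}

#' @export
autoplot.sample_qc_report <- function(object, ...) {
  cutoff <- attr(object, "cutoff")
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$z_k,
                                   colour = .data$flagged)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed") +
    ggplot2::facet_wrap(~group, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "standardized connectivity Z.k",
                  colour = "flagged") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
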
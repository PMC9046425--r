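#' Detect gene modules from topological overlap dissimilarity
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut statically.
#' With `cut_method = "absolute"` (default) the tree is cut at dissimilarity
#' `cut_height` — the static-cut convention for TOM dissimilarity, whose
#' scale is bounded by 1: co-expressed branches merge well below the cut
#' while background genes chain just under 1. With `cut_method = "quantile"`
#' the cut is placed at the `cut_height` quantile of the merge heights
#' instead. Branches smaller than `min_module_size` are sent to the reserved
#' `"unassigned"` label (the grey-module convention). Remaining modules are
#' relabelled `M1, M2, ...` in decreasing size order, ties broken by the
#' lexicographically smallest member gene, so labels are deterministic given
#' the input. Optionally, modules whose eigengenes correlate above
#' `merge_me_cor` are merged (requires `expr`).
#'
#' @param tom a `tom_matrix` from [topological_overlap()], or a plain
#'   symmetric dissimilarity matrix with zero diagonal.
#' @param min_module_size smallest branch kept as a module (default 30).
#' @param cut_height static cut position (default 0.98): a dissimilarity
#'   when `cut_method = "absolute"`, a quantile of merge heights when
#'   `cut_method = "quantile"`.
#' @param cut_method how `cut_height` is interpreted.
#' @param merge_me_cor if non-`NULL`, modules with eigengene correlation
#'   above this value are merged iteratively.
#' @param expr genes x samples matrix; only needed when `merge_me_cor` is set.
#' @return An object of class `module_assignment`: list with `labels` (named
#'   character vector gene -> module), `sizes` (tibble), `cut_height`,
#'   `min_module_size` and `dendrogram` (the `hclust` tree). `tidy()` returns
#'   a gene/module tibble, `glance()` a one-row summary.
#' @export
detect_modules <- function(tom, min_module_size = 30,
                           cut_height = 0.98,
                           cut_method = c("absolute", "quantile"),
                           merge_me_cor = NULL, expr = NULL) {
  cut_method <- match.arg(cut_method)
  diss <- if (inherits(tom, "tom_matrix")) tom$diss else tom
  check_square_symmetric(diss, "dissimilarity")
  if (max(abs(diag(diss))) > 1e-8) stop("dissimilarity must have a zero diagonal", call. = FALSE)
  n <- nrow(diss)
  if (n < min_module_size) stop("fewer genes than min_module_size", call. = FALSE)
  genes <- rownames(diss)

  hc <- hclust(as.dist(diss), method = "average")
  cut_h <- switch(cut_method,
    absolute = cut_height,
    quantile = unname(quantile(hc$height, cut_height))
  )
  raw <- cutree(hc, h = cut_h)

  tab <- table(raw)
  keep <- names(tab)[tab >= min_module_size]
  labels <- ifelse(raw %in% as.integer(keep), as.character(raw), "unassigned")
  names(labels) <- genes

  relabel <- function(labels) {
    mods <- setdiff(unique(labels), "unassigned")
    if (!length(mods)) return(labels)
    info <- tibble::tibble(
      old = mods,
      size = vapply(mods, function(m) sum(labels == m), integer(1)),
      anchor = vapply(mods, function(m) min(names(labels)[labels == m]), character(1))
    ) |> dplyr::arrange(dplyr::desc(.data$size), .data$anchor)
    map <- setNames(paste0("M", seq_len(nrow(info))), info$old)
    out <- ifelse(labels == "unassigned", "unassigned", map[labels])
    names(out) <- names(labels)
    out
  }
  labels <- relabel(labels)

  if (!is.null(merge_me_cor)) {
    if (is.null(expr)) stop("expr is required when merge_me_cor is set", call. = FALSE)
    repeat {
      mods <- setdiff(unique(labels), "unassigned")
      if (length(mods) < 2) break
      me <- module_eigengenes(expr, new_module_assignment(labels, hc, cut_h, min_module_size))
      cm <- cor(t(me$me))
      diag(cm) <- 0
      if (max(cm) <= merge_me_cor) break
      ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      from <- rownames(cm)[max(ij)]; to <- rownames(cm)[min(ij)]
      labels[labels == from] <- to
      labels <- relabel(labels)
    }
  }

  new_module_assignment(labels, hc, cut_h, min_module_size)
}

new_module_assignment <- function(labels, dendrogram, cut_height, min_module_size) {
  sizes <- tibble::as_tibble(table(module = labels), .name_repair = "minimal")
  names(sizes) <- c("module", "n_genes")
  sizes <- dplyr::arrange(sizes, .data$module == "unassigned",
                          dplyr::desc(.data$n_genes))
  structure(list(labels = labels, sizes = sizes, cut_height = cut_height,
                 min_module_size = min_module_size, dendrogram = dendrogram),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  n_mod <- sum(x$sizes$module != "unassigned")
  cat(sprintf("Module assignment: %d genes in %d modules (+ %d unassigned), cut height %.3f\n",
              length(x$labels), n_mod,
              sum(x$labels == "unassigned"), x$cut_height))
  print(x$sizes)
  invisible(x)
}

#' @export
tidy.module_assignment <- function(x, ...) {
  tibble::tibble(gene_id = names(x$labels), module = unname(x$labels))
}

#' @export
glance.module_assignment <- function(x, ...) {
  real <- x$sizes[x$sizes$module != "unassigned", ]
  tibble::tibble(
    n_genes = length(x$labels),
    n_modules = nrow(real),
    n_unassigned = sum(x$labels == "unassigned"),
    largest_module = if (nrow(real)) max(real$n_genes) else NA_integer_,
    smallest_module = if (nrow(real)) min(real$n_genes) else NA_integer_,
    cut_height = x$cut_height
  )
}

#' Plot the module dendrogram
#'
#' @param x a `module_assignment`.
#' @param ... passed to `plot.hclust()`.
#' @export
plot_dendrogram <- function(x, ...) {
  stopifnot(inherits(x, "module_assignment"))
  plot(x$dendrogram, labels = FALSE, hang = -1,
       main = "Gene clustering on TOM dissimilarity", xlab = "", sub = "", ...)
  graphics::abline(h = x$cut_height, col = "red", lty = 2)
  invisible(x)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' gene-standardized expression across samples, scaled to unit variance and
#' sign-anchored so that its correlation with the module's mean standardized
#' expression is nonnegative. Genes labelled `"unassigned"` get no eigengene.
#'
#' @param expr genes x samples matrix.
#' @param assignment a `module_assignment` (or named gene -> module vector).
#' @return list of class `module_eigengenes`: `me` (modules x samples
#'   matrix), `explained_variance` (named fraction per module).
#' @export
module_eigengenes <- function(expr, assignment) {
  check_expr(expr)
  labels <- if (inherits(assignment, "module_assignment")) assignment$labels else assignment
  if (!all(names(labels) %in% rownames(expr))) {
    stop("assignment refers to genes absent from expr", call. = FALSE)
  }
  mods <- setdiff(unique(labels), "unassigned")
  if (!length(mods)) stop("no modules to summarize", call. = FALSE)
  mods <- mods[order(mods)]

  me <- matrix(0, length(mods), ncol(expr), dimnames = list(mods, colnames(expr)))
  ev <- setNames(numeric(length(mods)), mods)
  for (m in mods) {
    genes <- names(labels)[labels == m]
    x <- expr[genes, , drop = FALSE]
    xs <- t(scale(t(x)))
    xs[!is.finite(xs)] <- 0  # constant genes carry no direction
    if (length(genes) == 1) {
      v1 <- xs[1, ]
      ev[m] <- 1
    } else {
      sv <- svd(xs, nu = 0, nv = 1)
      v1 <- sv$v[, 1]
      ev[m] <- sv$d[1]^2 / sum(sv$d^2)
    }
    s1 <- sd(v1)
    if (s1 > 0) v1 <- v1 / s1
    avg <- colMeans(xs)
    if (sum(v1 * avg) < 0) v1 <- -v1
    me[m, ] <- v1
  }
  structure(list(me = me, explained_variance = ev), class = "module_eigengenes")
}

#' @export
print.module_eigengenes <- function(x, ...) {
  cat(sprintf("Module eigengenes: %d modules x %d samples\n",
              nrow(x$me), ncol(x$me)))
  cat("  explained variance:",
      paste(sprintf("%s %.0f%%", names(x$explained_variance),
                    100 * x$explained_variance), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.module_eigengenes <- function(x, ...) {
  tibble::as_tibble(x$me, rownames = "module") |>
    tidyr::pivot_longer(-"module", names_to = "sample_id", values_to = "eigengene")
}

#' Module-trait and intramodular gene statistics
#'
#' Associates each module eigengene with the binary trait by Pearson
#' (point-biserial) correlation, with the two-sided p-value from the
#' `t = r sqrt((n-2)/(1-r^2))` transform on `n - 2` degrees of freedom.
#' Per gene, computes the gene significance `GS = |cor(x_i, trait)|` (with
#' p-value) and the module membership `MM = cor(ME_m, x_i)` against the
#' gene's own module eigengene; genes are ranked by `|MM|` within their
#' module (intramodular hub ranking). Raw module-trait p-values decide
#' significance (a BH-adjusted column is emitted alongside for reference).
#'
#' @param expr genes x samples matrix.
#' @param me a `module_eigengenes`.
#' @param assignment a `module_assignment` (or named label vector).
#' @param metadata data frame with `sample_id` and 0/1 `trait`.
#' @return list of class `module_trait_stats`: `module_trait` (tibble:
#'   module, n_genes, cor, p_value, p_adjusted) and `gene_stats` (tibble:
#'   gene_id, module, mm, gs, p_gs, hub_rank). `autoplot()` draws the
#'   module-trait association strip.
#' @export
module_trait_stats <- function(expr, me, assignment, metadata) {
  check_expr(expr)
  stopifnot(inherits(me, "module_eigengenes"))
  labels <- if (inherits(assignment, "module_assignment")) assignment$labels else assignment
  check_metadata(metadata, colnames(expr))
  md <- metadata[match(colnames(expr), metadata$sample_id), ]
  trait <- md$trait
  n <- length(trait)
  if (n < 4) stop("need at least 4 samples", call. = FALSE)
  if (length(unique(trait)) < 2) stop("trait is constant", call. = FALSE)

  mods <- rownames(me$me)
  module_trait <- purrr::map_dfr(mods, function(m) {
    r <- cor(me$me[m, ], trait)
    tibble::tibble(module = m,
                   n_genes = sum(labels == m),
                   cor = r,
                   p_value = cor_pvalue(r, n))
  }) |>
    dplyr::mutate(p_adjusted = p.adjust(.data$p_value, "BH")) |>
    dplyr::arrange(.data$p_value)

  assigned <- names(labels)[labels != "unassigned"]
  gene_stats <- purrr::map_dfr(mods, function(m) {
    genes <- intersect(names(labels)[labels == m], rownames(expr))
    x <- expr[genes, , drop = FALSE]
    gs_r <- drop(cor(t(x), trait))
    mm <- drop(cor(t(x), me$me[m, ]))
    tibble::tibble(gene_id = genes, module = m,
                   mm = mm,
                   gs = abs(gs_r),
                   p_gs = cor_pvalue(gs_r, n)) |>
      dplyr::arrange(dplyr::desc(abs(.data$mm))) |>
      dplyr::mutate(hub_rank = dplyr::row_number())
  })

  structure(list(module_trait = module_trait, gene_stats = gene_stats,
                 n_samples = n),
            class = "module_trait_stats")
}

#' @export
print.module_trait_stats <- function(x, ...) {
  cat("Module-trait associations (", x$n_samples, " samples):\n", sep = "")
  print(x$module_trait)
  invisible(x)
}

#' @export
tidy.module_trait_stats <- function(x, ...) x$gene_stats

#' @export
glance.module_trait_stats <- function(x, ...) {
  top <- x$module_trait[1, ]
  tibble::tibble(n_modules = nrow(x$module_trait),
                 top_module = top$module,
                 top_cor = top$cor,
                 top_p_value = top$p_value,
                 n_significant = sum(x$module_trait$p_value <= 0.05))
}

#' @export
autoplot.module_trait_stats <- function(object, ...) {
  df <- object$module_trait
  ggplot2::ggplot(df, ggplot2::aes(x = "trait", y = .data$module, fill = .data$cor)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f\n(%.2g)", .data$cor, .data$p_value)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "cor(ME, trait)") +
    ggplot2::theme_minimal()
}
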
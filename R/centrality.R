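#' Condition-specific module networks
#'
#' For each requested module, rebuilds the co-expression network separately
#' within the case (trait = 1) and control (trait = 0) samples: the module's
#' expression submatrix is taken per group, then similarity, power adjacency
#' with the shared `beta`, and topological overlap are computed on that
#' subset. A gene with zero variance within a group keeps its node but its
#' correlations are set to 0, with a warning.
#'
#' @param expr genes x samples matrix.
#' @param metadata data frame with `sample_id` and 0/1 `trait`.
#' @param assignment a `module_assignment` (or named gene -> module vector).
#' @param beta soft-threshold power shared by both condition networks.
#' @param modules module ids to process; default all non-unassigned modules.
#' @return named list (one element per module) of lists with `module`,
#'   `genes`, `beta`, `tom_case`, `tom_control` (each a `tom_matrix`).
#' @export
condition_networks <- function(expr, metadata, assignment, beta,
                               modules = NULL) {
  check_expr(expr)
  check_metadata(metadata, colnames(expr))
  labels <- if (inherits(assignment, "module_assignment")) assignment$labels else assignment
  md <- metadata[match(colnames(expr), metadata$sample_id), ]
  if (sum(md$trait == 1) < 4 || sum(md$trait == 0) < 4) {
    stop("each trait group needs at least 4 samples", call. = FALSE)
  }
  modules <- modules %||% setdiff(unique(labels), "unassigned")
  missing <- setdiff(modules, unique(labels))
  if (length(missing)) stop("unknown module(s): ", paste(missing, collapse = ", "), call. = FALSE)

  group_tom <- function(genes, samples) {
    x <- expr[genes, samples, drop = FALSE]
    v <- apply(x, 1, var)
    if (any(v == 0)) {
      warning("zero-variance gene(s) within a trait group; correlations set to 0: ",
              paste(head(genes[v == 0], 5), collapse = ", "), call. = FALSE)
      r <- suppressWarnings(cor(t(x)))
      r[!is.finite(r)] <- 0
      s <- abs(r)
      diag(s) <- 1
    } else {
      s <- cor_similarity(x)
    }
    topological_overlap(soft_adjacency(s, beta))
  }

  out <- lapply(modules, function(m) {
    genes <- names(labels)[labels == m]
    if (!length(genes)) stop("module ", m, " has no genes in expr", call. = FALSE)
    list(module = m, genes = genes, beta = beta,
         tom_case = group_tom(genes, md$sample_id[md$trait == 1]),
         tom_control = group_tom(genes, md$sample_id[md$trait == 0]))
  })
  names(out) <- modules
  out
}

#' Weighted betweenness centrality on a TOM network
#'
#' Treats `1 / TOM_ij` as the length of the edge between genes i and j
#' (pairs with `TOM_ij = 0` have no edge) and accumulates, for every node v,
#' the fraction of shortest paths between each unordered pair of other nodes
#' that pass through v (Brandes accumulation over a Dijkstra shortest-path
#' DAG). Two path lengths are considered tied when they agree within a
#' relative tolerance `epsilon_tie`, so equal-weight fixtures count all
#' co-minimal paths.
#'
#' @param tom a `tom_matrix` or a symmetric matrix of TOM values in \[0, 1\].
#' @param epsilon_tie relative tolerance for treating path lengths as equal.
#' @return named numeric vector of betweenness values (unordered-pair
#'   convention: each pair contributes at most 1 in total per intermediary).
#' @examples
#' tom <- matrix(c(1, .5, 0, .5, 1, .5, 0, .5, 1), 3, 3,
#'               dimnames = rep(list(c("a", "b", "c")), 2))
#' tom_betweenness(tom)  # b bridges a and c
#' @export
tom_betweenness <- function(tom, epsilon_tie = 1e-12) {
  m <- if (inherits(tom, "tom_matrix")) tom$tom else tom
  check_square_symmetric(m, "TOM")
  if (any(m < 0 | m > 1)) stop("TOM values must lie in [0, 1]", call. = FALSE)
  n <- nrow(m)
  if (n == 0) stop("empty module", call. = FALSE)
  genes <- rownames(m) %||% as.character(seq_len(n))
  if (n <= 2) return(setNames(numeric(n), genes))

  len <- 1 / m
  diag(len) <- Inf
  len[m == 0] <- Inf
  if (any(len[is.finite(len)] <= 0)) stop("non-finite or nonpositive edge lengths", call. = FALSE)

  bc <- numeric(n)
  for (s in seq_len(n)) {
    dist_v <- rep(Inf, n); dist_v[s] <- 0
    sigma <- numeric(n); sigma[s] <- 1
    preds <- vector("list", n)
    done <- logical(n)
    order_v <- integer(0)
    repeat {
      cand <- which(!done & is.finite(dist_v))
      if (!length(cand)) break
      u <- cand[which.min(dist_v[cand])]
      done[u] <- TRUE
      order_v <- c(order_v, u)
      nb <- which(!done & is.finite(len[u, ]))
      if (length(nb)) {
        nd <- dist_v[u] + len[u, nb]
        ref <- dist_v[nb]
        fin <- is.finite(ref)
        tol <- epsilon_tie * pmax(1, ifelse(fin, abs(ref), 1))
        shorter <- !fin | nd < ref - tol
        tied <- !shorter & abs(nd - ref) <= tol
        for (i in which(shorter)) {
          v <- nb[i]
          dist_v[v] <- nd[i]
          sigma[v] <- sigma[u]
          preds[[v]] <- u
        }
        for (i in which(tied)) {
          v <- nb[i]
          sigma[v] <- sigma[v] + sigma[u]
          preds[[v]] <- c(preds[[v]], u)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_v)) {
      for (p in preds[[w]]) {
        delta[p] <- delta[p] + sigma[p] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  setNames(bc / 2, genes)  # each unordered pair counted once
}

#' Differential betweenness centrality
#'
#' Joins per-gene betweenness from the case and control networks and ranks
#' genes by the absolute change `delta = bc_case - bc_control`, the
#' coordinator-candidate criterion. Ties in `|delta|` are broken by gene id.
#'
#' @param case_bc,control_bc named numeric vectors over the same gene set
#'   (e.g. from [tom_betweenness()] on the two condition networks).
#' @param module optional module id recorded in the output.
#' @return tibble of class `centrality_table` with columns `gene_id`,
#'   `module`, `bc_case`, `bc_control`, `delta`, `rank` (by `|delta|`,
#'   descending).
#' @export
differential_bc <- function(case_bc, control_bc, module = NA_character_) {
  if (is.null(names(case_bc)) || is.null(names(control_bc)) ||
      !setequal(names(case_bc), names(control_bc)) ||
      length(case_bc) != length(control_bc)) {
    stop("case and control betweenness must cover the same gene set", call. = FALSE)
  }
  genes <- sort(names(case_bc))
  out <- tibble::tibble(
    gene_id = genes,
    module = module,
    bc_case = unname(case_bc[genes]),
    bc_control = unname(control_bc[genes]),
    delta = unname(case_bc[genes] - control_bc[genes])
  ) |>
    dplyr::arrange(dplyr::desc(abs(.data$delta)), .data$gene_id) |>
    dplyr::mutate(rank = dplyr::row_number())
  class(out) <- c("centrality_table", class(out))
  out
}

#' Differential centrality for a set of condition networks
#'
#' Convenience wrapper: runs [tom_betweenness()] on both condition networks
#' of every module returned by [condition_networks()] and stacks the
#' [differential_bc()] tables.
#'
#' @param networks result of [condition_networks()].
#' @param epsilon_tie passed to [tom_betweenness()].
#' @return a single `centrality_table` tibble covering all modules.
#' @export
module_centrality <- function(networks, epsilon_tie = 1e-12) {
  out <- purrr::map_dfr(networks, function(nw) {
    differential_bc(tom_betweenness(nw$tom_case, epsilon_tie),
                    tom_betweenness(nw$tom_control, epsilon_tie),
                    module = nw$module)
  })
  class(out) <- c("centrality_table", class(out))
  out
}

#' @export
autoplot.centrality_table <- function(object, top_n = 10, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::group_by(.data$module) |>
    dplyr::slice_min(.data$rank, n = top_n) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$gene_id, abs(.data$delta)),
                                   y = .data$delta)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~module, scales = "free") +
    ggplot2::labs(x = NULL, y = "BC(case) - BC(control)") +
    ggplot2::theme_minimal()
}
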
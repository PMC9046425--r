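#' Read a gene-set collection from a GMT file
#'
#' @param path GMT file (tab-separated: set name, description, member genes).
#' @param source tag recorded on the collection: `"pathway"`, `"tf_targets"`
#'   or `"mirna_targets"`.
#' @return named list of gene-id vectors with attribute `source`.
#' @export
read_gmt <- function(path, source = c("pathway", "tf_targets", "mirna_targets")) {
  source <- match.arg(source)
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets))) stop("duplicated set names in ", path, call. = FALSE)
  if (any(lengths(sets) == 0)) stop("empty gene set in ", path, call. = FALSE)
  attr(sets, "source") <- source
  sets
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the overlap with the query is larger
#' than expected when drawing `|query|` genes from the universe without
#' replacement (one-sided upper-tail hypergeometric test). Sets are
#' intersected with the universe first, then filtered to `min_size`; the
#' Benjamini-Hochberg adjustment runs across all tested sets of the
#' collection (one collection = one multiple-testing family). By default the
#' result is restricted to sets with adjusted p <= `alpha`.
#'
#' @param query character vector of gene ids; must be a subset of `universe`.
#' @param collection named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param universe character vector of background gene ids.
#' @param min_size smallest in-universe set size tested (default 5).
#' @param alpha adjusted-p cutoff applied to the output (default 0.05).
#' @param keep_all return all tested sets instead of only significant ones.
#' @return tibble with columns `set`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p_value`, `p_adjusted`, `genes` (list-column of
#'   overlapping ids), sorted by adjusted then raw p.
#' @export
hypergeom_ora <- function(query, collection, universe,
                          min_size = 5, alpha = 0.05, keep_all = FALSE) {
  query <- unique(query); universe <- unique(universe)
  if (!length(query)) stop("empty query", call. = FALSE)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (!all(query %in% universe)) stop("query must be a subset of the universe", call. = FALSE)
  if (setequal(query, universe)) {
    warning("query equals the universe; every test is degenerate (p = 1)", call. = FALSE)
  }

  sets <- lapply(collection, function(g) intersect(unique(g), universe))
  sets <- sets[lengths(sets) >= min_size]
  if (!length(sets)) {
    return(tibble::tibble(set = character(), overlap = integer(),
                          set_size = integer(), query_size = integer(),
                          universe_size = integer(), p_value = double(),
                          p_adjusted = double(), genes = list()))
  }

  nu <- length(universe); nq <- length(query)
  res <- purrr::map_dfr(names(sets), function(nm) {
    hit <- intersect(sets[[nm]], query)
    k <- length(hit); K <- length(sets[[nm]])
    tibble::tibble(
      set = nm, overlap = k, set_size = K, query_size = nq,
      universe_size = nu,
      # upper tail P(X >= k); k = 0 gives exactly 1
      p_value = phyper(k - 1, K, nu - K, nq, lower.tail = FALSE),
      genes = list(sort(hit))
    )
  }) |>
    dplyr::mutate(p_adjusted = p.adjust(.data$p_value, "BH")) |>
    dplyr::relocate("p_adjusted", .after = "p_value") |>
    dplyr::arrange(.data$p_adjusted, .data$p_value, .data$set)

  if (!keep_all) res <- dplyr::filter(res, .data$p_adjusted <= alpha)
  res
}

#' Assemble a TF-miRNA-mRNA regulatory network
#'
#' Builds a directed graph with typed nodes (`TF`, `miRNA`, `gene`). Every
#' regulator in `tf_sets` / `mirna_sets` contributes one edge to each key
#' gene contained in its target set (evidence `"tf_targets"` /
#' `"mirna_targets"`); curated `extra_edges` are appended with evidence
#' `"literature"` and must reference nodes already present.
#'
#' @param key_genes tibble with columns `gene_id` and optionally `module`,
#'   or a plain character vector of gene ids.
#' @param tf_sets named list: TF -> target gene ids (typically the enriched
#'   sets from [hypergeom_ora()]).
#' @param mirna_sets named list: miRNA -> target gene ids.
#' @param extra_edges optional data frame with columns `from`, `to`.
#' @return object of class `regulatory_network`: list with `graph` (igraph),
#'   `nodes` (tibble: name, type, module) and `edges` (tibble: from, to,
#'   evidence).
#' @export
build_regnet <- function(key_genes, tf_sets = list(), mirna_sets = list(),
                         extra_edges = NULL) {
  if (is.character(key_genes)) {
    key_genes <- tibble::tibble(gene_id = key_genes, module = NA_character_)
  }
  stopifnot(is.data.frame(key_genes), "gene_id" %in% names(key_genes))
  if (!"module" %in% names(key_genes)) key_genes$module <- NA_character_
  genes <- unique(key_genes$gene_id)

  reg_edges <- function(sets, evidence) {
    purrr::map_dfr(names(sets), function(r) {
      tg <- intersect(sets[[r]], genes)
      tg <- setdiff(tg, r)  # no self-loops
      if (!length(tg)) return(NULL)
      tibble::tibble(from = r, to = tg, evidence = evidence)
    })
  }
  edges <- dplyr::bind_rows(
    reg_edges(tf_sets, "tf_targets"),
    reg_edges(mirna_sets, "mirna_targets")
  )

  nodes <- dplyr::bind_rows(
    tibble::tibble(name = genes, type = "gene",
                   module = key_genes$module[match(genes, key_genes$gene_id)]),
    tibble::tibble(name = setdiff(names(tf_sets), genes), type = "TF",
                   module = NA_character_),
    tibble::tibble(name = setdiff(names(mirna_sets), genes), type = "miRNA",
                   module = NA_character_)
  )
  # a key gene that is itself a supplied TF keeps type "gene" but may regulate
  if (!is.null(extra_edges)) {
    stopifnot(all(c("from", "to") %in% names(extra_edges)))
    unknown <- setdiff(c(extra_edges$from, extra_edges$to), nodes$name)
    if (length(unknown)) {
      stop("extra_edges reference unknown node(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    extra <- tibble::tibble(from = extra_edges$from, to = extra_edges$to,
                            evidence = "literature") |>
      dplyr::filter(.data$from != .data$to)
    edges <- dplyr::bind_rows(edges, extra)
  }
  edges <- dplyr::distinct(edges)

  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges else data.frame(from = character(), to = character(),
                                           evidence = character()),
    directed = TRUE, vertices = as.data.frame(nodes)
  )
  structure(list(graph = g, nodes = nodes, edges = edges),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  tt <- table(x$nodes$type)
  cat(sprintf("Regulatory network: %d nodes (%s), %d directed edges\n",
              nrow(x$nodes),
              paste(sprintf("%s %d", names(tt), tt), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

#' @export
tidy.regulatory_network <- function(x, ...) x$edges

#' Write / read a regulatory network
#'
#' `write_regnet()` exports the network both as GraphML and as a SIF file
#' (Cytoscape-compatible; the interaction column carries the evidence tag).
#' `read_sif()` reads the SIF back as an edge tibble.
#'
#' @param net a `regulatory_network`.
#' @param graphml,sif output paths; either may be `NULL` to skip.
#' @return invisibly, the written paths.
#' @export
write_regnet <- function(net, graphml = NULL, sif = NULL) {
  stopifnot(inherits(net, "regulatory_network"))
  if (!is.null(graphml)) igraph::write_graph(net$graph, graphml, format = "graphml")
  if (!is.null(sif)) {
    readr::write_tsv(
      dplyr::select(net$edges, "from", "evidence", "to"),
      sif, col_names = FALSE
    )
  }
  invisible(c(graphml = graphml, sif = sif))
}

#' @rdname write_regnet
#' @param path a SIF file written by [write_regnet()].
#' @export
read_sif <- function(path) {
  df <- readr::read_tsv(path, col_names = c("from", "evidence", "to"),
                        show_col_types = FALSE)
  dplyr::select(df, "from", "to", "evidence")
}
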
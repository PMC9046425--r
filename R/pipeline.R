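#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis. Expression
#' inputs may be given as file paths (TSV, first column gene id) or as
#' in-memory matrices/data frames; gene-set collections as GMT paths or
#' named lists. A configuration can be round-tripped through YAML with
#' [read_pipeline_config()] when all inputs are paths.
#'
#' @param counts,tpm genes x samples count/TPM matrices or TSV paths.
#' @param metadata sample metadata tibble or TSV path (columns `sample_id`,
#'   `trait`, covariates).
#' @param gmt,tf_gmt,mirna_gmt optional gene-set collections (GMT path or
#'   named list) for pathway / TF-target / miRNA-target enrichment.
#' @param ratio,match_covariates cohort matching parameters.
#' @param low_count,low_prop,mad_keep gene-filter parameters.
#' @param n_sv,known_covariates surrogate-adjustment parameters.
#' @param zk_cutoff sample-network outlier threshold.
#' @param beta_grid,r2_cut,n_bins soft-threshold selection parameters.
#' @param min_module_size,cut_height,cut_method module detection parameters.
#' @param trait_p module-trait p-value gate for the centrality stage.
#' @param alpha,min_size enrichment parameters.
#' @param seed integer seed echoed into the manifest (the pipeline itself is
#'   deterministic; the seed also guards any future stochastic options).
#' @param out_dir output directory; `NULL` keeps results in memory only.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, tpm, metadata,
                            gmt = NULL, tf_gmt = NULL, mirna_gmt = NULL,
                            ratio = 2, match_covariates = c("sex", "age", "race"),
                            low_count = 10, low_prop = 0.9, mad_keep = 0.5,
                            n_sv = 3,
                            known_covariates = c("sex", "age", "bmi", "ischemic_time"),
                            zk_cutoff = -2.5,
                            beta_grid = 1:20, r2_cut = 0.85, n_bins = 10,
                            min_module_size = 30, cut_height = 0.98, cut_method = "absolute",
                            trait_p = 0.05, alpha = 0.05, min_size = 5,
                            seed = 1L, out_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(ratio >= 1, low_count >= 0, low_prop >= 0, low_prop <= 1,
            mad_keep > 0, mad_keep <= 1, n_sv >= 0,
            r2_cut > 0, r2_cut <= 1, min_module_size >= 2,
            cut_height > 0,
            trait_p > 0, trait_p <= 1, alpha > 0, alpha <= 1, min_size >= 1)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()] arguments.
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) stop("unknown config key(s): ", paste(extra, collapse = ", "),
                          call. = FALSE)
  do.call(pipeline_config, vals)
}

resolve_matrix <- function(x, what) {
  if (is.character(x) && length(x) == 1) x <- read_matrix_tsv(x)
  if (is.data.frame(x)) {
    m <- as.matrix(x[, -1, drop = FALSE]); rownames(m) <- x[[1]]; x <- m
  }
  check_expr(x, what)
  x
}

resolve_sets <- function(x, source) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1) return(read_gmt(x, source))
  stopifnot(is.list(x), !is.null(names(x)))
  attr(x, "source") <- source
  x
}

#' Run the full co-expression analysis pipeline
#'
#' Executes, in order: optimal cohort matching, low-count/MAD gene
#' filtering, log2(TPM + 1) transform, sample-network outlier removal,
#' surrogate-variable adjustment, soft-threshold selection, TOM
#' construction, module detection, eigengene/trait statistics, differential
#' betweenness centrality on the trait-significant modules (raw module-trait
#' p <= `trait_p`), and -- when collections are supplied -- per-module
#' over-representation analysis and regulatory-network assembly. All stages
#' are pure functions of the inputs and configuration, so reruns with the
#' same config are byte-identical. When `out_dir` is set, result tables are
#' written as TSV and a JSON manifest records parameters and per-stage
#' gene/sample counts.
#'
#' @param config a [pipeline_config()].
#' @return list of class `coex_pipeline` with the per-stage results
#'   (`match`, `filtered`, `adjusted`, `qc`, `sf_fit`, `tom`, `modules`,
#'   `eigengenes`, `trait_stats`, `centrality`, `enrichment`, `regnet`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  counts <- resolve_matrix(config$counts, "counts")
  tpm <- resolve_matrix(config$tpm, "tpm")
  metadata <- if (is.character(config$metadata)) {
    readr::read_tsv(config$metadata, show_col_types = FALSE)
  } else tibble::as_tibble(config$metadata)
  check_metadata(metadata, colnames(counts))
  stages <- list()

  # 1. cohort matching
  match <- match_cohort(metadata, ratio = config$ratio,
                        match_covariates = config$match_covariates)
  keep <- match$retained_sample_ids
  counts <- counts[, keep, drop = FALSE]
  tpm <- tpm[, keep, drop = FALSE]
  metadata <- metadata[metadata$sample_id %in% keep, ]
  stages$match <- list(n_cases = length(match$case_ids),
                       n_controls = length(match$control_ids),
                       n_samples = length(keep))

  # 2-3. gene filtering + log transform
  filtered <- filter_genes(counts, tpm, metadata,
                           low_count = config$low_count,
                           low_prop = config$low_prop,
                           mad_keep = config$mad_keep)
  expr <- log_transform(filtered)
  stages$filter <- as.list(setNames(attr(filtered, "filter_log")$n_genes,
                                    attr(filtered, "filter_log")$step))

  # 4. sample QC on the log-TPM matrix: aberrant samples are removed before
  # latent-structure estimation so they cannot leak into the surrogates
  qc <- detect_outliers(expr, metadata, cutoff = config$zk_cutoff)
  flagged <- qc$sample_id[qc$flagged]
  expr <- expr[, setdiff(colnames(expr), flagged), drop = FALSE]
  metadata <- metadata[!metadata$sample_id %in% flagged, ]
  stages$qc <- list(n_flagged = length(flagged),
                    flagged = as.list(flagged),
                    n_samples = ncol(expr))

  # 5. surrogate adjustment
  adj <- remove_surrogates(expr, metadata,
                           known_covariates = config$known_covariates,
                           n_sv = config$n_sv)
  expr <- adj$adjusted
  stages$surrogates <- list(n_sv = adj$n_sv)

  # 6. network construction
  s <- cor_similarity(expr)
  sf <- pick_soft_threshold(s, beta_grid = config$beta_grid,
                            r2_cut = config$r2_cut, n_bins = config$n_bins)
  tom <- topological_overlap(soft_adjacency(s, sf$chosen_beta))
  stages$network <- list(chosen_beta = sf$chosen_beta,
                         signed_r2 = sf$fit$signed_r2[sf$fit$beta == sf$chosen_beta])

  # 7. modules + trait statistics
  modules <- detect_modules(tom, min_module_size = config$min_module_size,
                            cut_height = config$cut_height,
                            cut_method = config$cut_method)
  me <- module_eigengenes(expr, modules)
  ts <- module_trait_stats(expr, me, modules, metadata)
  stages$modules <- list(n_modules = sum(modules$sizes$module != "unassigned"),
                         n_unassigned = sum(modules$labels == "unassigned"))

  # 8. differential centrality on trait-significant modules
  sig <- ts$module_trait$module[ts$module_trait$p_value <= config$trait_p]
  centrality <- NULL
  networks <- NULL
  if (length(sig)) {
    networks <- condition_networks(expr, metadata, modules, beta = sf$chosen_beta,
                                   modules = sig)
    centrality <- module_centrality(networks)
  }
  stages$centrality <- list(significant_modules = as.list(sig))

  # 9-10. enrichment + regulatory network
  gmt <- resolve_sets(config$gmt, "pathway")
  tf <- resolve_sets(config$tf_gmt, "tf_targets")
  mirna <- resolve_sets(config$mirna_gmt, "mirna_targets")
  universe <- rownames(expr)
  enrichment <- list()
  regnet <- NULL
  if (length(sig)) {
    for (m in sig) {
      q <- names(modules$labels)[modules$labels == m]
      enrichment[[m]] <- list(
        pathway = if (!is.null(gmt))
          hypergeom_ora(q, gmt, universe, config$min_size, config$alpha),
        tf = if (!is.null(tf))
          hypergeom_ora(q, tf, universe, config$min_size, config$alpha),
        mirna = if (!is.null(mirna))
          hypergeom_ora(q, mirna, universe, config$min_size, config$alpha)
      )
    }
    if (!is.null(tf) || !is.null(mirna)) {
      key <- dplyr::filter(ts$gene_stats, .data$module %in% sig,
                           .data$hub_rank <= 10)
      enr_sets <- function(sets, res_name) {
        hits <- unique(unlist(lapply(enrichment, function(e)
          if (!is.null(e[[res_name]])) e[[res_name]]$set)))
        if (is.null(sets)) list() else sets[intersect(names(sets), hits)]
      }
      regnet <- build_regnet(
        dplyr::select(key, "gene_id", "module"),
        tf_sets = enr_sets(tf, "tf"),
        mirna_sets = enr_sets(mirna, "mirna")
      )
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("coexdiff")),
    parameters = config[setdiff(names(config),
                                c("counts", "tpm", "metadata",
                                  "gmt", "tf_gmt", "mirna_gmt", "out_dir"))],
    stages = stages
  )

  result <- structure(list(
    match = match, filtered = filtered, expr = expr, adjustment = adj,
    qc = qc, sf_fit = sf, tom = tom, modules = modules, eigengenes = me,
    trait_stats = ts, networks = networks, centrality = centrality,
    enrichment = enrichment, regnet = regnet, manifest = manifest
  ), class = "coex_pipeline")

  if (!is.null(config$out_dir)) write_pipeline(result, config$out_dir)
  result
}

write_pipeline <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(tidy(result$match), file.path(dir, "match_map.tsv"))
  readr::write_tsv(result$match$balance, file.path(dir, "balance.tsv"))
  write_matrix_tsv(result$expr, file.path(dir, "expression_adjusted.tsv"))
  readr::write_tsv(tibble::as_tibble(result$qc), file.path(dir, "sample_qc.tsv"))
  readr::write_tsv(tidy(result$sf_fit), file.path(dir, "scale_free_fit.tsv"))
  readr::write_tsv(tidy(result$modules), file.path(dir, "modules.tsv"))
  write_matrix_tsv(result$eigengenes$me, file.path(dir, "eigengenes.tsv"),
                   id_col = "module")
  readr::write_tsv(result$trait_stats$module_trait,
                   file.path(dir, "module_trait.tsv"))
  readr::write_tsv(result$trait_stats$gene_stats,
                   file.path(dir, "gene_stats.tsv"))
  if (!is.null(result$centrality)) {
    readr::write_tsv(tibble::as_tibble(result$centrality),
                     file.path(dir, "centrality.tsv"))
  }
  for (m in names(result$enrichment)) {
    for (kind in names(result$enrichment[[m]])) {
      tab <- result$enrichment[[m]][[kind]]
      if (!is.null(tab) && nrow(tab)) {
        tab$genes <- vapply(tab$genes, paste, character(1), collapse = ",")
        readr::write_tsv(tab, file.path(dir, sprintf("enrichment_%s_%s.tsv", m, kind)))
      }
    }
  }
  if (!is.null(result$regnet)) {
    write_regnet(result$regnet,
                 graphml = file.path(dir, "regnet.graphml"),
                 sif = file.path(dir, "regnet.sif"))
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.coex_pipeline <- function(x, ...) {
  st <- x$manifest$stages
  cat("Co-expression pipeline run\n")
  cat(sprintf("  matched cohort: %d cases / %d controls\n",
              st$match$n_cases, st$match$n_controls))
  cat(sprintf("  genes: %d -> %d (count filter) -> %d (MAD filter)\n",
              st$filter$input, st$filter$count_filter, st$filter$mad_filter))
  cat(sprintf("  outliers removed: %d; final samples: %d\n",
              st$qc$n_flagged, st$qc$n_samples))
  cat(sprintf("  soft threshold beta = %d (signed R^2 = %.3f)\n",
              st$network$chosen_beta, st$network$signed_r2))
  cat(sprintf("  modules: %d (+ %d genes unassigned)\n",
              st$modules$n_modules, st$modules$n_unassigned))
  sig <- unlist(st$centrality$significant_modules)
  cat("  trait-significant modules:",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}
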
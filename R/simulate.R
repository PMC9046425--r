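#' Configure a synthetic co-expression dataset
#'
#' Builds the parameter set for [simulate_dataset()]. The generator plants a
#' factor structure: each module is driven by a latent eigengene, one or more
#' eigengenes are coupled to a binary trait, all genes load on hidden
#' surrogate (batch-like) components, and a few samples are shifted to act as
#' outliers. Defaults describe a desk-scale skin-cohort analog: 880 genes,
#' 22 cases and 44 controls, three modules of 120/100/80 genes with mean
#' gene-eigengene correlation 0.8, one module coupled to the trait at r = 0.4,
#' three hidden noise components, and two outlier samples shifted by five
#' times the median inter-sample distance.
#'
#' @param n_genes total number of genes, background included.
#' @param n_cases,n_controls samples per trait group (trait = 1 / trait = 0).
#' @param n_modules number of planted modules.
#' @param module_sizes integer vector of length `n_modules`; must sum to at
#'   most `n_genes`.
#' @param eigengene_trait_cor per-module target correlation between the
#'   latent eigengene and the 0/1 trait, each in \[-1, 1\].
#' @param within_module_cor per-module target *mean* absolute correlation
#'   between member genes and their eigengene, each in (0, 1).
#' @param within_module_cor_spread half-width of the uniform spread of
#'   per-gene loadings around `within_module_cor` (default 0.15): modules mix
#'   tightly and loosely connected genes, which is what makes intramodular
#'   hub ranking meaningful.
#' @param n_surrogates number of hidden noise components.
#' @param surrogate_share fraction of a background gene's variance carried by
#'   the surrogate components (module genes carry 30% of their residual
#'   variance on them).
#' @param n_outliers number of planted aberrant samples.
#' @param outlier_shift outlier displacement as a multiple of the median
#'   inter-sample Euclidean distance on the log scale; 0 disables the shift.
#' @param noise_sd standard deviation multiplier of the i.i.d. Gaussian gene
#'   noise (1 keeps the gene-eigengene correlation calibrated exactly).
#' @param low_gene_frac fraction of background genes given a very low
#'   baseline so that the low-count filter has genuine targets.
#' @param lib_size expected library size used when Poisson counts are drawn
#'   around the TPM profile.
#' @param seed integer seed; the seed fully determines the output.
#'
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 880,
                              n_cases = 22,
                              n_controls = 44,
                              n_modules = 3,
                              module_sizes = c(120, 100, 80),
                              eigengene_trait_cor = c(0.4, 0, 0),
                              within_module_cor = rep(0.8, n_modules),
                              within_module_cor_spread = 0.15,
                              n_surrogates = 3,
                              surrogate_share = 0.5,
                              n_outliers = 2,
                              outlier_shift = 5,
                              noise_sd = 1,
                              low_gene_frac = 0.15,
                              lib_size = 2e6,
                              seed = 1L) {
  cfg <- list(
    n_genes = n_genes, n_cases = n_cases, n_controls = n_controls,
    n_modules = n_modules, module_sizes = as.integer(module_sizes),
    eigengene_trait_cor = eigengene_trait_cor,
    within_module_cor = within_module_cor,
    within_module_cor_spread = within_module_cor_spread,
    n_surrogates = n_surrogates, surrogate_share = surrogate_share,
    n_outliers = n_outliers, outlier_shift = outlier_shift,
    noise_sd = noise_sd, low_gene_frac = low_gene_frac,
    lib_size = lib_size, seed = as.integer(seed)
  )
  num <- unlist(cfg[c("n_genes", "n_cases", "n_controls", "n_modules",
                      "module_sizes", "eigengene_trait_cor",
                      "within_module_cor", "within_module_cor_spread",
                      "n_surrogates", "surrogate_share",
                      "n_outliers", "outlier_shift", "noise_sd",
                      "low_gene_frac", "lib_size")])
  if (any(!is.finite(num))) stop("simulation_config: non-finite value", call. = FALSE)
  if (length(cfg$module_sizes) != n_modules ||
      length(cfg$eigengene_trait_cor) != n_modules ||
      length(cfg$within_module_cor) != n_modules) {
    stop("module_sizes, eigengene_trait_cor and within_module_cor must have length n_modules",
         call. = FALSE)
  }
  if (sum(cfg$module_sizes) > n_genes) {
    stop("sum(module_sizes) exceeds n_genes", call. = FALSE)
  }
  if (any(abs(cfg$eigengene_trait_cor) > 1)) {
    stop("eigengene_trait_cor must lie in [-1, 1]", call. = FALSE)
  }
  if (any(cfg$within_module_cor <= 0 | cfg$within_module_cor >= 1)) {
    stop("within_module_cor must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$outlier_shift < 0 || cfg$noise_sd < 0 ||
      cfg$within_module_cor_spread < 0) {
    stop("outlier_shift, noise_sd and within_module_cor_spread must be nonnegative",
         call. = FALSE)
  }
  if (cfg$n_outliers > n_cases + n_controls) stop("more outliers than samples", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

#' Simulate an expression dataset with planted network structure
#'
#' Draws a genes x samples log-scale expression matrix from the factor model
#' `x_g = b_g * E_m + c_g * S + e`, where `E_m` is the latent eigengene of
#' gene g's module, `S` are hidden surrogate components and `e` is Gaussian
#' noise. The eigengene of a trait-coupled module is constructed as
#' `lambda * z(trait) + sqrt(1 - lambda^2) * g_perp` with `g_perp` drawn
#' orthogonal to the trait, so the realized eigengene-trait correlation
#' equals the target exactly. Loadings `b_g` carry a random sign (modules
#' mix positively and negatively regulated genes; the downstream network is
#' unsigned) and are set so that, at `noise_sd = 1`, the absolute
#' gene-eigengene correlation equals `within_module_cor`.
#' TPM is obtained by exponentiating (base 2) and normalizing each sample to
#' a column sum of one million; counts are Poisson draws around the TPM
#' profile scaled to `lib_size`. Outlier samples are then shifted on the log
#' scale by `outlier_shift` times the median inter-sample distance along a
#' random direction.
#'
#' @param config a [simulation_config()].
#' @return A list of class `coex_sim` with elements `counts`, `tpm`
#'   (genes x samples matrices), `metadata` (tibble: sample_id, trait, sex,
#'   age, race, bmi, ischemic_time) and `truth` (planted structure: tibble
#'   `gene_modules`, `outlier_samples`, `eigengenes`, `surrogates`, `trait`).
#' @examples
#' sim <- simulate_dataset(simulation_config(n_genes = 60, n_cases = 8,
#'   n_controls = 16, module_sizes = c(15, 10, 10), seed = 7))
#' dim(sim$tpm)
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_cases + config$n_controls
  sample_ids <- sprintf("S%03d", seq_len(n))
  trait <- c(rep(1L, config$n_cases), rep(0L, config$n_controls))
  zt <- as.numeric(scale(trait))

  # Latent eigengenes, exactly at the target trait correlation.
  E <- matrix(0, config$n_modules, n)
  dimnames(E) <- list(if (config$n_modules > 0) paste0("M", seq_len(config$n_modules)),
                      sample_ids)
  for (m in seq_len(config$n_modules)) {
    lam <- config$eigengene_trait_cor[m]
    g <- rnorm(n)
    g_perp <- g - zt * sum(g * zt) / sum(zt * zt)
    g_perp <- as.numeric(scale(g_perp))
    E[m, ] <- lam * zt + sqrt(1 - lam^2) * g_perp
  }

  # Hidden surrogate components, standardized rows.
  S <- matrix(rnorm(config$n_surrogates * n), config$n_surrogates, n)
  if (config$n_surrogates > 0) {
    S <- t(apply(S, 1, function(r) as.numeric(scale(r))))
    dim(S) <- c(config$n_surrogates, n)
    dimnames(S) <- list(paste0("SV", seq_len(config$n_surrogates)), sample_ids)
  } else {
    dimnames(S) <- list(character(0), sample_ids)
  }

  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
  labels <- rep("none", config$n_genes)
  idx <- 0
  X <- matrix(0, config$n_genes, n, dimnames = list(gene_ids, sample_ids))
  module_resid_share <- 0.3  # surrogate share of a module gene's residual variance

  for (m in seq_len(config$n_modules)) {
    genes <- idx + seq_len(config$module_sizes[m])
    labels[genes] <- paste0("M", m)
    w <- config$within_module_cor[m]
    for (g in genes) {
      # per-gene loading magnitude spread around the module mean, and a
      # random loading sign: modules mix tightly/loosely connected and
      # positively/negatively regulated genes (the network is unsigned), and
      # balanced signs keep the per-sample TPM normalization from absorbing
      # eigengene signal
      w_mag <- min(max(w + runif(1, -1, 1) * config$within_module_cor_spread,
                       0.05), 0.995)
      resid_var <- 1 - w_mag^2
      cg <- if (config$n_surrogates > 0) {
        sample(c(-1, 1), config$n_surrogates, replace = TRUE) *
          sqrt(module_resid_share * resid_var / config$n_surrogates)
      } else numeric(0)
      e_sd <- sqrt((1 - module_resid_share * (config$n_surrogates > 0)) * resid_var)
      w_g <- sample(c(-1, 1), 1) * w_mag
      X[g, ] <- w_g * E[m, ] +
        (if (length(cg)) drop(cg %*% S) else 0) +
        rnorm(n, sd = e_sd * config$noise_sd)
    }
    idx <- idx + config$module_sizes[m]
  }

  bg <- which(labels == "none")
  for (g in bg) {
    cg <- if (config$n_surrogates > 0) {
      sample(c(-1, 1), config$n_surrogates, replace = TRUE) *
        sqrt(config$surrogate_share / config$n_surrogates)
    } else numeric(0)
    e_sd <- sqrt(max(1 - config$surrogate_share * (config$n_surrogates > 0), 0))
    X[g, ] <- (if (length(cg)) drop(cg %*% S) else 0) +
      rnorm(n, sd = e_sd * config$noise_sd)
  }

  # Baseline abundance and scale; a slice of background genes sits near zero
  # expression so the low-count filter has real work to do.
  n_low <- round(config$low_gene_frac * length(bg))
  low <- if (n_low > 0) sample(bg, n_low) else integer(0)
  mu <- rnorm(config$n_genes, 3, 1.5)
  tau <- runif(config$n_genes, 0.5, 1.5)
  if (length(low)) {
    mu[low] <- rnorm(length(low), -4, 1)
    tau[low] <- 0.3
  }
  X <- mu + tau * X

  # Planted outliers: shift along a random direction on the log scale.
  outlier_ids <- character(0)
  if (config$n_outliers > 0 && config$outlier_shift > 0) {
    # allocate outliers across trait groups in proportion to group size
    # (at least one per group when there are two or more), mirroring the
    # way aberrant samples occur in both arms of a case-control cohort
    n_out_case <- round(config$n_outliers * config$n_cases / n)
    if (config$n_outliers >= 2) {
      n_out_case <- min(max(n_out_case, 1), config$n_outliers - 1)
    }
    out_idx <- sort(c(
      sample(which(trait == 1), n_out_case),
      sample(which(trait == 0), config$n_outliers - n_out_case)
    ))
    outlier_ids <- sample_ids[out_idx]
    med_d <- median(dist(t(X)))
    for (o in out_idx) {
      u <- rnorm(config$n_genes)
      u <- u / sqrt(sum(u^2))
      X[, o] <- X[, o] + config$outlier_shift * med_d * u
    }
  }

  expr_lin <- 2^X
  tpm <- sweep(expr_lin, 2, colSums(expr_lin), "/") * 1e6
  counts <- matrix(rpois(length(tpm), lambda = tpm / 1e6 * config$lib_size),
                   nrow(tpm), ncol(tpm), dimnames = dimnames(tpm))

  metadata <- tibble::tibble(
    sample_id = sample_ids,
    trait = trait,
    sex = ifelse(runif(n) < 0.45 + 0.15 * trait, "M", "F"),
    age = round(rnorm(n, 50 + 5 * trait, 10)),
    race = sample(c("W", "B", "A"), n, replace = TRUE, prob = c(0.7, 0.2, 0.1)),
    bmi = round(rnorm(n, 27 + 3 * trait, 4), 1),
    ischemic_time = round(rnorm(n, 500, 150))
  )

  truth <- list(
    gene_modules = tibble::tibble(gene_id = gene_ids, module = labels),
    outlier_samples = outlier_ids,
    eigengenes = E,
    surrogates = S,
    trait = setNames(trait, sample_ids)
  )
  structure(list(counts = counts, tpm = tpm, metadata = metadata,
                 truth = truth, config = config),
            class = "coex_sim")
}

#' @export
print.coex_sim <- function(x, ...) {
  cat("Synthetic co-expression dataset\n")
  cat("  genes:", nrow(x$tpm), " samples:", ncol(x$tpm),
      sprintf("(%d cases / %d controls)\n", sum(x$metadata$trait == 1),
              sum(x$metadata$trait == 0)))
  sz <- table(x$truth$gene_modules$module)
  cat("  planted modules:",
      paste(sprintf("%s(%d)", names(sz), sz), collapse = " "), "\n")
  cat("  outliers:", if (length(x$truth$outlier_samples))
    paste(x$truth$outlier_samples, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Write / read a simulated dataset as plain-text fixtures
#'
#' `write_fixture()` emits `counts.tsv`, `tpm.tsv`, `metadata.tsv` and
#' `truth.json` into `dir`; `read_fixture()` reconstructs the same structure.
#' The round trip is lossless to TSV formatting precision.
#'
#' @param sim a `coex_sim` from [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @return `write_fixture()`: invisibly, the named file paths;
#'   `read_fixture()`: a `coex_sim`-shaped list.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "coex_sim") || is.list(sim))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    tpm = file.path(dir, "tpm.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_matrix_tsv(sim$counts, paths[["counts"]])
  write_matrix_tsv(sim$tpm, paths[["tpm"]])
  readr::write_tsv(sim$metadata, paths[["metadata"]])
  truth <- sim$truth
  jsonlite::write_json(
    list(
      gene_modules = truth$gene_modules,
      outlier_samples = truth$outlier_samples,
      eigengenes = list(ids = rownames(truth$eigengenes),
                        samples = colnames(truth$eigengenes),
                        values = unname(truth$eigengenes)),
      surrogates = list(ids = rownames(truth$surrogates),
                        samples = colnames(truth$surrogates),
                        values = unname(truth$surrogates)),
      trait = as.list(truth$trait)
    ),
    paths[["truth"]], digits = NA, auto_unbox = TRUE
  )
  invisible(paths)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  counts <- read_matrix_tsv(file.path(dir, "counts.tsv"))
  storage.mode(counts) <- "integer"
  tpm <- read_matrix_tsv(file.path(dir, "tpm.tsv"))
  metadata <- readr::read_tsv(file.path(dir, "metadata.tsv"), show_col_types = FALSE)
  tj <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  unpack <- function(x) {
    m <- if (length(x$values)) as.matrix(x$values) else
      matrix(0, 0, length(x$samples))
    rownames(m) <- x$ids
    colnames(m) <- x$samples
    m
  }
  truth <- list(
    gene_modules = tibble::as_tibble(tj$gene_modules),
    outlier_samples = as.character(tj$outlier_samples %||% character(0)),
    eigengenes = unpack(tj$eigengenes),
    surrogates = unpack(tj$surrogates),
    trait = unlist(tj$trait)
  )
  structure(list(counts = counts, tpm = tpm, metadata = metadata, truth = truth),
            class = "coex_sim")
}

#' Similarity matrix with an exact power-law connectivity profile
#'
#' Builds a gene-gene similarity matrix under a Chung-Lu expected-degree
#' construction: weights `w_i` are drawn from a continuous power law with
#' exponent `gamma`, and `s_ij = w_i w_j / sum(w)` (capped below 1), so the
#' connectivity of node i concentrates at `w_i`. Used to validate the
#' scale-free model-fit statistic: such a network should score a signed
#' R-squared near 1 already at beta = 1.
#'
#' @param n_genes number of nodes.
#' @param gamma power-law exponent of the weight distribution (> 2).
#' @param w_min smallest weight.
#' @param seed integer seed.
#' @return symmetric similarity matrix with unit diagonal.
#' @export
simulate_powerlaw_similarity <- function(n_genes = 300, gamma = 2.5,
                                         w_min = 1, seed = 1L) {
  stopifnot(gamma > 2, n_genes >= 20)
  set.seed(as.integer(seed))
  w <- w_min * (1 - runif(n_genes))^(-1 / (gamma - 1))
  s <- outer(w, w) / sum(w)
  s <- pmin(s, 0.999)
  diag(s) <- 1
  dimnames(s) <- list(sprintf("G%04d", seq_len(n_genes)),
                      sprintf("G%04d", seq_len(n_genes)))
  s
}
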
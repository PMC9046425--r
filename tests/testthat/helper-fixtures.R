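# Shared fixture builders. Small configurations keep unit tests fast; the
# acceptance suite uses the generator defaults (the full desk-scale cohort).

small_sim <- function(seed = 1, ...) {
  simulate_dataset(simulation_config(
    n_genes = 120, n_cases = 10, n_controls = 20,
    module_sizes = c(25, 20, 15), eigengene_trait_cor = c(0.5, 0, 0),
    n_outliers = 0, seed = seed, ...
  ))
}

# Run the preprocessing chain of the pipeline up to the adjusted matrix.
preprocessed_expr <- function(sim, n_sv = 3) {
  m <- match_cohort(sim$metadata)
  f <- filter_genes(sim$counts[, m$retained_sample_ids],
                    sim$tpm[, m$retained_sample_ids], sim$metadata)
  e <- log_transform(f)
  qc <- detect_outliers(e, sim$metadata)
  e <- e[, setdiff(colnames(e), qc$sample_id[qc$flagged]), drop = FALSE]
  remove_surrogates(e, sim$metadata, n_sv = n_sv)$adjusted
}

# Two-condition TOM networks over the same gene set: two internally tight
# gene clusters whose only inter-cluster connection is a bridge gene, and the
# bridge's cluster-spanning edges exist in the case network only (in controls
# the bridge touches one cluster alone, so nothing spans the gap).
bridge_networks <- function(seed, n_per_cluster = 6) {
  set.seed(seed)
  ids <- c(paste0("a", seq_len(n_per_cluster)),
           paste0("b", seq_len(n_per_cluster)), "bridge")
  n <- length(ids)
  clique <- function(m) {
    w <- matrix(runif(m * m, 0.5, 0.9), m)
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
    diag(w) <- 1
    w
  }
  base <- matrix(0, n, n, dimnames = list(ids, ids))
  ia <- seq_len(n_per_cluster); ib <- n_per_cluster + ia
  base[ia, ia] <- clique(n_per_cluster)
  base[ib, ib] <- clique(n_per_cluster)
  diag(base) <- 1
  ctrl <- case <- base
  # bridge reaches both clusters in cases, one cluster in controls
  case[n, c(ia, ib)] <- runif(2 * n_per_cluster, 0.4, 0.8)
  case[c(ia, ib), n] <- case[n, c(ia, ib)]
  ctrl[n, ia] <- runif(n_per_cluster, 0.4, 0.8)
  ctrl[ia, n] <- ctrl[n, ia]
  list(case = case, control = ctrl)
}
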
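two_block_expr <- function(n_per = 35, n_samples = 30, seed = 1) {
  set.seed(seed)
  e1 <- rnorm(n_samples); e2 <- rnorm(n_samples)
  x <- rbind(
    t(replicate(n_per, e1 * runif(1, 0.8, 1.2))),
    t(replicate(n_per, e2 * runif(1, 0.8, 1.2)))
  )
  dimnames(x) <- list(sprintf("g%03d", seq_len(2 * n_per)),
                      sprintf("s%02d", seq_len(n_samples)))
  x
}

test_that("two perfectly correlated blocks give exactly two clean modules", {
  x <- two_block_expr()
  tom <- topological_overlap(soft_adjacency(cor_similarity(x), 6))
  asg <- detect_modules(tom, min_module_size = 30)
  expect_identical(sum(asg$sizes$module != "unassigned"), 2L)
  expect_identical(as.integer(table(asg$labels)[c("M1", "M2")]), c(35L, 35L))
  # block membership is exactly recovered
  expect_length(unique(asg$labels[1:35]), 1L)
  expect_length(unique(asg$labels[36:70]), 1L)
  expect_false(asg$labels[1] == asg$labels[36])
})

test_that("planted modules are recovered from the preprocessed pipeline matrix", {
  sim <- simulate_dataset(simulation_config(seed = 12))
  expr <- preprocessed_expr(sim)
  tom <- topological_overlap(soft_adjacency(cor_similarity(expr), 6))
  asg <- detect_modules(tom)
  expect_gte(ari_vs_truth(asg, sim$truth$gene_modules), 0.8)
})

test_that("pure noise yields no stable planted-module structure", {
  set.seed(99)
  x <- matrix(rnorm(150 * 40), 150, 40,
              dimnames = list(sprintf("g%03d", 1:150), sprintf("s%02d", 1:40)))
  tom <- topological_overlap(soft_adjacency(cor_similarity(x), 6))
  asg <- detect_modules(tom, min_module_size = 30)
  fake_truth <- tibble::tibble(gene_id = rownames(x),
                               module = rep(c("M1", "M2", "M3"), each = 50))
  if (any(asg$labels != "unassigned")) {
    expect_lt(abs(ari_vs_truth(asg, fake_truth)), 0.1)
  } else {
    expect_true(all(asg$labels == "unassigned"))
  }
})

test_that("gene-order permutation permutes the labels identically", {
  x <- two_block_expr(seed = 4)
  tom <- topological_overlap(soft_adjacency(cor_similarity(x), 6))
  asg <- detect_modules(tom, min_module_size = 30)
  perm <- sample(nrow(x))
  tom_p <- topological_overlap(soft_adjacency(cor_similarity(x[perm, ]), 6))
  asg_p <- detect_modules(tom_p, min_module_size = 30)
  expect_identical(asg_p$labels[names(asg$labels)], asg$labels)
})

test_that("the eigengene of identical genes is their shared standardized profile", {
  set.seed(2)
  profile <- rnorm(20)
  x <- matrix(rep(profile, each = 5), 5, 20,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:20)))
  me <- module_eigengenes(x, setNames(rep("M1", 5), paste0("g", 1:5)))
  expect_equal(unname(me$me["M1", ]), as.numeric(scale(profile)), tolerance = 1e-8)
  expect_equal(unname(me$explained_variance["M1"]), 1, tolerance = 1e-10)
})

test_that("eigengenes recover the planted latent factors", {
  sim <- small_sim(seed = 8)
  e <- log_transform(sim$tpm)
  truth <- sim$truth$gene_modules
  labels <- setNames(truth$module, truth$gene_id)
  labels[labels == "none"] <- "unassigned"
  me <- module_eigengenes(e, labels)
  for (m in c("M1", "M2", "M3")) {
    expect_gt(abs(cor(me$me[m, ], sim$truth$eigengenes[m, ])), 0.9)
  }
})

test_that("flipping every gene's sign flips the eigengene but the anchor re-orients", {
  x <- two_block_expr(seed = 6)[1:35, ]
  lab <- setNames(rep("M1", 35), rownames(x))
  me1 <- module_eigengenes(x, lab)
  me2 <- module_eigengenes(-x, lab)
  # anchor: correlation with the mean standardized expression is nonnegative
  xs1 <- t(scale(t(x))); xs2 <- t(scale(t(-x)))
  expect_gte(cor(me1$me["M1", ], colMeans(xs1)), 0)
  expect_gte(cor(me2$me["M1", ], colMeans(xs2)), 0)
  expect_equal(abs(cor(me1$me["M1", ], me2$me["M1", ])), 1, tolerance = 1e-8)
})

test_that("module-trait correlation p-values match the closed-form t transform", {
  # r = 0.5, n = 22: two-sided p from t = r * sqrt(n-2) / sqrt(1-r^2),
  # checked against R's t distribution and against cor.test
  r <- 0.5; n <- 22
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  p_closed <- 2 * pt(t_stat, n - 2, lower.tail = FALSE)
  set.seed(10)
  repeat {   # construct data with exactly this correlation via rotation
    a <- rnorm(n); b <- rnorm(n)
    b <- residuals(lm(b ~ a)); b <- b / sd(b); a <- (a - mean(a)) / sd(a)
    y <- r * a + sqrt(1 - r^2) * b
    if (abs(cor(a, y) - r) < 1e-12) break
  }
  expect_equal(cor.test(a, y)$p.value, p_closed, tolerance = 1e-10)

  sim <- small_sim(seed = 9)
  e <- log_transform(sim$tpm)
  truth <- sim$truth$gene_modules
  labels <- setNames(ifelse(truth$module == "none", "unassigned", truth$module),
                     truth$gene_id)
  asg <- labels
  me <- module_eigengenes(e, asg)
  ts <- module_trait_stats(e, me, asg, sim$metadata)
  for (i in seq_len(nrow(ts$module_trait))) {
    row <- ts$module_trait[i, ]
    expect_equal(row$p_value,
                 cor.test(me$me[row$module, ], sim$metadata$trait)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("degenerate trait statistics behave as required", {
  sim <- small_sim(seed = 1)
  e <- log_transform(sim$tpm)
  lab <- setNames(rep("M1", 10), rownames(e)[1:10])
  me <- module_eigengenes(e, lab)
  # eigengene identical to the trait: r = 1, p ~ 0
  me$me["M1", ] <- sim$metadata$trait + 0  # constant within groups -> r with trait = 1
  me$me["M1", ] <- as.numeric(scale(me$me["M1", ]))
  ts <- module_trait_stats(e, me, lab, sim$metadata)
  expect_equal(ts$module_trait$cor[1], 1, tolerance = 1e-10)
  expect_lt(ts$module_trait$p_value[1], 1e-12)
  # constant trait is rejected
  md0 <- sim$metadata; md0$trait <- 0L
  expect_error(module_trait_stats(e, me, lab, md0), "constant|nonempty")
})

test_that("the trait-coupled module has the top eigengene-trait correlation and GS tracks MM", {
  sim <- simulate_dataset(simulation_config(seed = 15))
  expr <- preprocessed_expr(sim)
  tom <- topological_overlap(soft_adjacency(cor_similarity(expr), 6))
  asg <- detect_modules(tom)
  me <- module_eigengenes(expr, asg)
  md <- sim$metadata[sim$metadata$sample_id %in% colnames(expr), ]
  ts <- module_trait_stats(expr, me, asg, md)
  top <- ts$module_trait$module[which.max(abs(ts$module_trait$cor))]
  planted <- sim$truth$gene_modules
  m1 <- planted$gene_id[planted$module == "M1"]
  tab <- table(asg$labels[intersect(m1, names(asg$labels))])
  tab <- tab[names(tab) != "unassigned"]
  expect_identical(top, names(tab)[which.max(tab)])
})

test_that("GS tracks |MM| inside a strongly trait-driven module", {
  # coupling of gene significance with module membership needs genuine
  # loading heterogeneity and a trait strong enough to rise above the
  # sqrt(n) noise floor of per-gene correlations
  sim <- simulate_dataset(simulation_config(
    n_genes = 400, n_cases = 50, n_controls = 100,
    module_sizes = c(60, 40, 40), eigengene_trait_cor = c(0.7, 0, 0),
    within_module_cor = rep(0.8, 3), within_module_cor_spread = 0.19,
    n_outliers = 0, seed = 15))
  e <- log_transform(sim$tpm)
  truth <- sim$truth$gene_modules
  labels <- setNames(ifelse(truth$module == "none", "unassigned", truth$module),
                     truth$gene_id)
  me <- module_eigengenes(e, labels)
  ts <- module_trait_stats(e, me, labels, sim$metadata)
  expect_identical(ts$module_trait$module[which.max(abs(ts$module_trait$cor))],
                   "M1")
  gs_mm <- ts$gene_stats[ts$gene_stats$module == "M1", ]
  expect_gt(cor(gs_mm$gs, abs(gs_mm$mm), method = "spearman"), 0.5)
})

test_that("explained variance of the eigengene dominates single-gene shares", {
  sim <- small_sim(seed = 3)
  e <- log_transform(sim$tpm)
  truth <- sim$truth$gene_modules
  g <- truth$gene_id[truth$module == "M2"]
  lab <- setNames(rep("M2", length(g)), g)
  me <- module_eigengenes(e, lab)
  expect_gte(me$explained_variance[["M2"]], 1 / length(g))
})
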
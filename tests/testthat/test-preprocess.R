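toy_counts <- function() {
  # 10 genes x 6 samples (3 cases, 3 controls), hand-set for the filter rules
  counts <- rbind(
    g01 = c(0, 0, 0, 0, 0, 0),       # dead in both groups -> removed
    g02 = c(50, 60, 55, 45, 40, 70), # expressed everywhere -> kept
    g03 = c(0, 0, 0, 90, 95, 80),    # dead in cases only -> kept (either-group rule)
    g04 = c(12, 15, 20, 0, 0, 0),    # dead in controls only -> kept
    g05 = c(3, 2, 1, 4, 2, 0),       # below 10 everywhere -> removed
    g06 = c(25, 30, 28, 33, 29, 31),
    g07 = c(9, 9, 9, 9, 9, 9),       # all < 10 -> removed
    g08 = c(100, 5, 5, 5, 5, 5),     # < 10 in 2/3 cases (0.67 <= 0.9) and 3/3 controls: kept
    g09 = c(40, 42, 41, 39, 40, 41),
    g10 = c(11, 10, 12, 10, 11, 13)
  )
  colnames(counts) <- sprintf("s%d", 1:6)
  counts
}

toy_meta <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                           trait = c(1, 1, 1, 0, 0, 0))

test_that("the count and MAD filters match a hand-evaluated oracle", {
  counts <- toy_counts()
  set.seed(1)
  tpm <- counts * 10 + matrix(runif(length(counts)), nrow(counts))
  dimnames(tpm) <- dimnames(counts)
  out <- filter_genes(counts, tpm, toy_meta, mad_keep = 1)
  # count rule only (mad_keep = 1): g01, g05, g07 die; the rest survive
  expect_setequal(rownames(out), c("g02", "g03", "g04", "g06", "g08", "g09", "g10"))
  # with mad_keep = 0.5 keep the ceiling(7/2) = 4 largest MADs of TPM
  out2 <- filter_genes(counts, tpm, toy_meta, mad_keep = 0.5)
  mads <- sort(apply(tpm[rownames(out), ], 1, mad), decreasing = TRUE)
  expect_setequal(rownames(out2), names(mads)[1:4])
  expect_identical(attr(out2, "filter_log")$n_genes, c(10L, 7L, 4L))
})

test_that("the count filter is idempotent and the full filter is at mad_keep = 1", {
  counts <- toy_counts()
  tpm <- counts + 0.5
  once <- filter_genes(counts, tpm, toy_meta, mad_keep = 1)
  twice <- filter_genes(counts[rownames(once), ], once, toy_meta, mad_keep = 1)
  expect_identical(rownames(twice), rownames(once))
  expect_equal(unclass(twice), unclass(once)[rownames(twice), ], ignore_attr = TRUE)
})

test_that("gene filtering is equivariant under sample permutation", {
  sim <- small_sim(seed = 9)
  perm <- sample(ncol(sim$counts))
  a <- filter_genes(sim$counts, sim$tpm, sim$metadata)
  b <- filter_genes(sim$counts[, perm], sim$tpm[, perm], sim$metadata)
  expect_identical(rownames(a), rownames(b))
})

test_that("log transform is exact log2(x + 1)", {
  m <- matrix(c(0, 1, 7, 3), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  lt <- log_transform(m)
  expect_equal(lt["g1", "s1"], 0)
  expect_equal(lt["g2", "s1"], 1)
  expect_equal(lt["g1", "s2"], 3)  # log2(8)
  expect_error(log_transform(m - 5), "nonnegative")
})

test_that("zero surrogate variables returns the input untouched", {
  sim <- small_sim(seed = 1)
  e <- log_transform(sim$tpm)
  adj <- remove_surrogates(e, sim$metadata, n_sv = 0)
  expect_identical(adj$adjusted, e)
  expect_identical(ncol(adj$sv), 0L)
})

test_that("residual PCA recovers strong planted hidden components", {
  sim <- simulate_dataset(simulation_config(
    n_modules = 0, module_sizes = integer(0),
    eigengene_trait_cor = numeric(0), within_module_cor = numeric(0),
    n_surrogates = 2, surrogate_share = 0.7, n_outliers = 0, seed = 21))
  f <- filter_genes(sim$counts, sim$tpm, sim$metadata)
  adj <- remove_surrogates(log_transform(f), sim$metadata, n_sv = 2)
  # recovery is measured against the design-orthogonal part of the planted
  # components: the protected trait/covariate span is excluded by construction
  design <- model.matrix(~ trait + sex + age + bmi + ischemic_time,
                         data = sim$metadata)
  truth_perp <- qr.resid(qr(design), t(sim$truth$surrogates))
  expect_gt(min(cancor(adj$sv, truth_perp)$cor), 0.9)
  # SV columns are orthonormal and the matrix shape is preserved
  expect_equal(unname(crossprod(adj$sv)), diag(2), tolerance = 1e-8)
  expect_identical(dim(adj$adjusted), dim(log_transform(f)))
})

test_that("adjustment preserves constant genes exactly", {
  sim <- small_sim(seed = 6)
  e <- log_transform(sim$tpm)
  e["G0001", ] <- 5
  adj <- remove_surrogates(e, sim$metadata, n_sv = 2)
  expect_equal(unname(adj$adjusted["G0001", ]), rep(5, ncol(e)), tolerance = 1e-10)
})

test_that("adjustment leaves the module-trait signal essentially intact", {
  # the estimated SVs are orthogonal to the trait by construction, so the
  # trait-aligned signal survives; eigengene-trait correlations move only
  # through PC-rotation noise (occasionally ~0.1 on a single draw, small on
  # average)
  d <- vapply(1:10, function(s) {
    sim <- simulate_dataset(simulation_config(seed = s, n_outliers = 0))
    e <- log_transform(sim$tpm)
    adj <- remove_surrogates(e, sim$metadata, n_sv = 3)
    g <- sim$truth$gene_modules$gene_id[sim$truth$gene_modules$module == "M1"]
    lab <- setNames(rep("M1", length(g)), g)
    before <- abs(cor(module_eigengenes(e, lab)$me[1, ], sim$metadata$trait))
    after <- abs(cor(module_eigengenes(adj$adjusted, lab)$me[1, ], sim$metadata$trait))
    abs(before - after)
  }, numeric(1))
  expect_lt(mean(d), 0.05)
  expect_lt(max(d), 0.25)  # gross-failure tripwire; single-draw PC rotation can reach ~0.15
})

test_that("an oversized n_sv is rejected", {
  sim <- small_sim(seed = 1)
  expect_error(remove_surrogates(log_transform(sim$tpm), sim$metadata, n_sv = 40),
               "n_sv too large")
})
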
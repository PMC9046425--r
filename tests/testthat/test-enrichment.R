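universe30 <- sprintf("G%02d", 1:30)

test_that("the fully-overlapping set has the closed-form minimum p-value", {
  # universe 20, set = query of size 5, overlap 5: p = 1 / C(20, 5)
  uni <- universe30[1:20]
  res <- hypergeom_ora(uni[1:5], list(S = uni[1:5]), uni, min_size = 5,
                       keep_all = TRUE)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
})

test_that("a set disjoint from the query has p exactly one", {
  uni <- universe30
  res <- hypergeom_ora(uni[1:5], list(S = uni[6:15]), uni, keep_all = TRUE)
  expect_identical(res$overlap, 0L)
  expect_equal(res$p_value, 1)
})

test_that("query equal to the universe is degenerate and flagged", {
  uni <- universe30[1:10]
  expect_warning(res <- hypergeom_ora(uni, list(S = uni[1:6]), uni,
                                      keep_all = TRUE),
                 "degenerate")
  expect_equal(res$p_value, 1)
  expect_identical(res$overlap, res$set_size)
})

test_that("p-values equal exhaustive hypergeometric enumeration (universe <= 30)", {
  set.seed(123)
  for (rep in 1:25) {
    nu <- sample(8:30, 1)
    uni <- universe30[seq_len(nu)]
    nq <- sample(2:(nu - 1), 1)
    query <- sample(uni, nq)
    sets <- lapply(1:4, function(i) sample(uni, sample(2:nu, 1)))
    names(sets) <- paste0("S", 1:4)
    res <- hypergeom_ora(query, sets, uni, min_size = 1, keep_all = TRUE)
    for (i in seq_len(nrow(res))) {
      expect_equal(
        res$p_value[i],
        oracle_hyper_upper(res$overlap[i], res$set_size[i], nu, nq),
        tolerance = 1e-10
      )
    }
  }
})

test_that("BH adjustment is monotone in raw-p rank and never below raw p", {
  set.seed(7)
  uni <- universe30
  query <- sample(uni, 8)
  sets <- lapply(1:12, function(i) sample(uni, sample(5:20, 1)))
  names(sets) <- paste0("S", 1:12)
  res <- hypergeom_ora(query, sets, uni, keep_all = TRUE)
  ord <- order(res$p_value)
  expect_true(all(diff(res$p_adjusted[ord]) >= -1e-12))
  expect_true(all(res$p_adjusted >= res$p_value - 1e-12))
})

test_that("sets are intersected with the universe before the size filter", {
  uni <- universe30[1:10]
  sets <- list(
    big_outside = c(uni[1:3], sprintf("X%02d", 1:10)),  # in-universe size 3 < 5
    ok = uni[1:6]
  )
  res <- hypergeom_ora(uni[1:4], sets, uni, min_size = 5, keep_all = TRUE)
  expect_identical(res$set, "ok")
  expect_identical(res$set_size, 6L)
})

test_that("empty inputs are rejected", {
  expect_error(hypergeom_ora(character(0), list(S = "a"), "a"), "empty query")
  expect_error(hypergeom_ora("a", list(S = "a"), character(0)), "empty universe")
  expect_error(hypergeom_ora("zzz", list(S = "a"), "a"), "subset")
})

test_that("GMT collections round-trip through the reader", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tG01\tG02\tG03",
               "setB\tanother\tG04\tG05"), gmt)
  sets <- read_gmt(gmt, source = "tf_targets")
  expect_identical(names(sets), c("setA", "setB"))
  expect_identical(sets$setB, c("G04", "G05"))
  expect_identical(attr(sets, "source"), "tf_targets")
})

test_that("the regulatory network wires enriched regulators to their key targets", {
  key <- tibble::tibble(gene_id = c("NCOA6", "EP300", "CREBBP", "RAB5B", "RHOT2"),
                        module = c(rep("M1", 4), "M2"))
  tf <- list(ZBTB17 = c("NCOA6", "RAB5B", "CREBBP", "KHSRP"),
             KLF10 = c("NCOA6", "EP300"))
  mir <- list(`miR-21` = c("EP300", "PPARA"))
  net <- build_regnet(key, tf, mir)
  expect_identical(sum(net$edges$evidence == "tf_targets"), 5L)
  expect_identical(sum(net$edges$evidence == "mirna_targets"), 1L)
  expect_setequal(net$nodes$type, c("gene", "TF", "miRNA"))
  deg <- igraph::degree(net$graph, mode = "out")
  expect_identical(unname(deg["ZBTB17"]), 3)
  expect_error(build_regnet(key, tf, mir,
                            extra_edges = data.frame(from = "nope", to = "NCOA6")),
               "unknown node")
})

test_that("a literature edge completes a miRNA -> TF -> gene regulatory chain", {
  key <- tibble::tibble(gene_id = c("NCOA6", "PPARA"), module = c("M1", NA))
  tf <- list(PPARA = "NCOA6")
  mir <- list(`miR-21` = "PPARA")
  net <- build_regnet(key, tf, mir,
                      extra_edges = data.frame(from = "miR-21", to = "PPARA"))
  d <- igraph::distances(net$graph, v = "miR-21", to = "NCOA6", mode = "out")
  expect_equal(as.numeric(d), 2)
})

test_that("network exports round-trip through GraphML and SIF", {
  key <- tibble::tibble(gene_id = c("A", "B", "C"), module = "M1")
  net <- build_regnet(key, tf_sets = list(T1 = c("A", "B")),
                      mirna_sets = list(m1 = "C"))
  gml <- withr::local_tempfile(fileext = ".graphml")
  sif <- withr::local_tempfile(fileext = ".sif")
  write_regnet(net, graphml = gml, sif = sif)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), nrow(net$nodes))
  expect_equal(igraph::ecount(back), nrow(net$edges))
  eb <- igraph::as_data_frame(back, "edges")
  expect_setequal(paste(eb$from, eb$to), paste(net$edges$from, net$edges$to))
  sb <- read_sif(sif)
  expect_setequal(paste(sb$from, sb$to, sb$evidence),
                  paste(net$edges$from, net$edges$to, net$edges$evidence))
})
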
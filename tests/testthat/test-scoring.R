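test_that("correlation scores match hand-evaluated Pearson", {
  x <- setNames(c(0.5, 0.3, 0.2), c("a", "b", "c"))
  y <- setNames(c(0.2, 0.3, 0.5), c("a", "b", "c"))
  expect_equal(correlation_score(x, y), pearson_by_hand, tolerance = 1e-12)
  expect_equal(correlation_score(x, x), 1)
  two_a <- setNames(c(0.2, 0.8), c("a", "b"))
  two_b <- setNames(c(0.8, 0.2), c("a", "b"))
  expect_equal(correlation_score(two_a, two_b), -1)
  expect_error(correlation_score(setNames(c(.5, .5), c("a", "b")), two_a),
               "degenerate")
  expect_error(correlation_score(x, two_a), "same node index")
  # spearman is rank-based: any monotone distortion leaves it at -1
  expect_equal(correlation_score(x, y^3, method = "spearman"), -1)
})

test_that("hypergeometric upper tail matches hand enumeration", {
  expect_equal(hypergeom_upper(0, 5, 3, 10), 1)
  expect_equal(hypergeom_upper(2, 2, 5, 10), 10 / 45, tolerance = 1e-12)
  expect_equal(hypergeom_upper(3, 3, 3, 6), 1 / 20, tolerance = 1e-12)
  expect_error(hypergeom_upper(3, 2, 5, 10), "inconsistent")
  expect_error(hypergeom_upper(2, 2, 5, 4), "inconsistent")
  # log-space path stays finite where the linear tail underflows
  lp <- hypergeom_upper(300, 300, 300, 1e6, log.p = TRUE)
  expect_true(is.finite(lp) && lp < -2000)
})

test_that("hypergeometric tail equals exhaustive enumeration (small sweep)", {
  for (N in c(5, 8)) {
    for (K in 0:N) {
      for (n in 0:N) {
        for (k in 0:min(n, K)) {
          expect_equal(hypergeom_upper(k, n, K, N),
                       enum_hyper_upper(k, n, K, N), tolerance = 1e-12,
                       info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("fold enrichment is the observed-over-expected ratio", {
  expect_equal(fold_enrichment(1, 2, 5, 10), 1)
  expect_equal(fold_enrichment(2, 2, 5, 10), 2)
  expect_equal(fold_enrichment(0, 5, 3, 10), 0)
  # algebraic identity: enrichment * (K/N) * n = k
  withr::with_seed(1, {
    for (i in 1:20) {
      N <- sample(20:100, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
      k <- sample(0:min(n, K), 1)
      expect_equal(fold_enrichment(k, n, K, N) * (K / N) * n, k,
                   tolerance = 1e-12)
    }
  })
})

test_that("hypergeometric p is monotone nonincreasing in k", {
  ps <- vapply(0:5, function(k) hypergeom_upper(k, 5, 6, 20), numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("prioritization ranks the planted herb first on the benchmark", {
  cfg <- synthetic_config(seed = 11)
  net0 <- generate_network(cfg)
  pd <- plant_disease(net0, cfg)
  gc_ <- generate_catalog(pd$network, pd$disease, cfg)
  cat_ <- suppressMessages(filter_herbs(gc_$catalog))
  rec <- suppressMessages(prioritize(cat_, pd$disease, pd$network))
  expect_s3_class(rec, "prioritization")
  expect_equal(rec$entity[1], gc_$planted)
  expect_true(all(diff(rec$correlation_score) <= 0))
  expect_true(all(rec$overlap_k <= rec$overlap_n))
})

test_that("prioritization is invariant to herb input order", {
  cfg <- synthetic_config(seed = 12, n_herbs = 6)
  net0 <- generate_network(cfg)
  pd <- plant_disease(net0, cfg)
  gc_ <- generate_catalog(pd$network, pd$disease, cfg)
  cat_ <- gc_$catalog
  rev_cat <- herb_catalog(rev(cat_$compounds_of), cat_$targets_of)
  r1 <- suppressMessages(prioritize(cat_, pd$disease, pd$network))
  r2 <- suppressMessages(prioritize(rev_cat, pd$disease, pd$network))
  expect_equal(r1, r2, ignore_attr = TRUE)
})

test_that("single-herb input ranks first; alpha = 1 flags nothing", {
  cat_ <- tiny_catalog()
  one <- herb_catalog(cat_$compounds_of["HerbA"], cat_$targets_of)
  net <- tiny_net()
  dis <- disease_gene_set(c("P4", "P5"))
  rec <- suppressMessages(prioritize(one, dis, net))
  expect_equal(rec$rank, 1L)
  rec2 <- suppressMessages(prioritize(one, dis, net, alpha = 1.0))
  expect_true(all(rec2$significant))  # "significant" = not flagged at alpha 1
})

test_that("capped overlap denominator uses the top-n targets", {
  cat_ <- tiny_catalog()
  net <- tiny_net()
  dis <- disease_gene_set(c("P1", "P2"))
  full <- suppressMessages(prioritize(cat_, dis, net))
  capped <- suppressMessages(prioritize(cat_, dis, net,
                                        overlap_from_top_n = 2))
  a_full <- full[full$entity == "HerbA", ]
  a_cap <- capped[capped$entity == "HerbA", ]
  expect_equal(a_full$overlap_n, 3L)
  expect_equal(a_cap$overlap_n, 2L)
  # top-2 by pathway count are P1, P2 (counts 2, 2)
  expect_equal(a_cap$overlap_k, 2L)
})

test_that("compound ranking returns at most top_m with scorable seeds", {
  cat_ <- tiny_catalog()
  net <- tiny_net()
  dis <- disease_gene_set(c("P1", "P2"))
  rec <- suppressMessages(prioritize_compounds(cat_, "HerbA", dis, net,
                                               top_m = 5))
  expect_equal(nrow(rec), 3L)  # 3 targeted compounds, fewer than top_m
  rec1 <- suppressMessages(prioritize_compounds(cat_, "HerbA", dis, net,
                                                top_m = 1))
  expect_equal(nrow(rec1), 1L)
  expect_equal(rec1$entity, rec$entity[1])

  # a compound with only off-network targets is skipped with a warning
  cat2 <- herb_catalog(list(H = c("C1", "C2", "C3")),
                       list(C1 = "P1", C2 = "P2", C3 = "ZZ"))
  expect_warning(
    rec2 <- suppressMessages(prioritize_compounds(cat2, "H", dis, net)),
    "no on-network targets")
  expect_equal(nrow(rec2), 2L)
})

test_that("prioritization tables serialize with display and full precision", {
  cat_ <- tiny_catalog()
  net <- tiny_net()
  rec <- suppressMessages(prioritize(cat_, disease_gene_set(c("P1", "P2")),
                                     net))
  d <- withr::local_tempdir()
  write_prioritization(rec, file.path(d, "t.tsv"), file.path(d, "t.json"))
  tsv <- read.delim(file.path(d, "t.tsv"))
  expect_equal(tsv$entity, rec$entity)
  expect_match(tsv$overlap[1], "^[0-9]+/[0-9]+$")
  js <- jsonlite::read_json(file.path(d, "t.json"), simplifyVector = TRUE)
  expect_equal(js$correlation_score, rec$correlation_score,
               tolerance = 1e-15)
})
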
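write_tmp_tsv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("herb-compound loading deduplicates, counts, and rejects bad rows", {
  f <- write_tmp_tsv(c("H1\tC1", "H1\tC2", "H2\tC1"))
  expect_message(hc <- load_herb_compound(f), "3 unique")
  expect_length(hc, 2)
  expect_equal(sort(unique(unlist(hc))), c("C1", "C2"))

  f2 <- write_tmp_tsv(c("H1\tC1", "H1\tC1"))
  expect_message(hc2 <- load_herb_compound(f2), "1 unique")
  expect_equal(unname(lengths(hc2)), 1L)

  f3 <- write_tmp_tsv(character())
  expect_error(load_herb_compound(f3), "no associations")
  f4 <- write_tmp_tsv(c("H1\tC1", "H2\t"))
  expect_error(load_herb_compound(f4), "rows 2")
  expect_error(load_herb_compound(tempfile()), "not found")
})

test_that("compound-target loading trims whitespace and keeps orphans", {
  f <- write_tmp_tsv(c("C1\tT1", "C1\t T2 ", "C9\tT3"))
  ct <- load_compound_target(f)
  expect_equal(ct$C1, c("T1", "T2"))
  cat_ <- herb_catalog(list(H1 = c("C1", "Cx")), ct)
  expect_equal(cat_$orphans, "C9")       # targeted but not in any herb
  expect_equal(cat_$untargeted, "Cx")    # referenced but no known target
})

test_that("header rows are recognized only from the configured name set", {
  f <- write_tmp_tsv(c("herb\tcompound", "H1\tC1", "# comment", "H1\tC2"))
  expect_message(hc <- load_herb_compound(f), "2 unique")
  expect_equal(hc$H1, c("C1", "C2"))
})

test_that("filter_herbs counts only target-linked compounds and is idempotent", {
  cat_ <- tiny_catalog()
  filtered <- suppressMessages(filter_herbs(cat_, min_components = 3))
  expect_setequal(filtered$herbs, c("HerbA", "HerbB"))
  expect_equal(attr(filtered, "removed"), "HerbC")

  # herb with 2 target-linked compounds is removed at min 3
  two <- herb_catalog(list(H = c("C1", "C2", "Cu")),
                      list(C1 = "T1", C2 = "T2"))
  expect_error(suppressMessages(filter_herbs(two, 3)), "no herbs")
  # untargeted compounds never count toward the threshold
  mixed <- herb_catalog(list(H = c("C1", "C2", "C3", "U1", "U2")),
                        list(C1 = "T1", C2 = "T2", C3 = "T3"))
  expect_equal(suppressMessages(filter_herbs(mixed, 3))$herbs, "H")

  twice <- suppressMessages(filter_herbs(filtered, min_components = 3))
  expect_identical(twice$herbs, filtered$herbs)
  expect_identical(twice$compounds_of, filtered$compounds_of)

  all_kept <- suppressMessages(filter_herbs(cat_, min_components = 1))
  expect_setequal(all_kept$herbs, c("HerbA", "HerbB", "HerbC"))
})

test_that("pathway_count tallies compounds per target", {
  cat_ <- tiny_catalog()
  pc <- pathway_count(cat_, "HerbA")   # C1:{P1,P2} C2:{P2,P3} C3:{P1}
  expect_equal(pc[c("P1", "P2", "P3")], c(P1 = 2L, P2 = 2L, P3 = 1L))
  expect_equal(unname(pathway_count(cat_, "HerbC")), 1L)
  dup <- herb_catalog(list(H = c("C1", "C2")), list(C1 = "T1", C2 = "T1"))
  expect_equal(pathway_count(dup, "H"), c(T1 = 2L))
  expect_error(pathway_count(cat_, "nope"), "unknown herb")
})

test_that("top_targets ranks by count then id and is prefix-stable", {
  counts <- c(T1 = 2L, T2 = 2L, T3 = 1L)
  expect_equal(top_targets(counts, 50), c("T1", "T2", "T3"))
  expect_equal(top_targets(counts, 2), c("T1", "T2"))
  expect_equal(top_targets(c(T9 = 5L, T2 = 5L), 1), "T2")
  for (n in 1:3) {
    expect_equal(top_targets(counts, n), top_targets(counts, 3)[seq_len(n)])
  }
})

test_that("herb seeds intersect the network and weight uniformly", {
  cat_ <- tiny_catalog()
  net <- tiny_net()
  s <- suppressMessages(herb_seed(cat_, "HerbA", net))
  expect_equal(s$genes, c("P1", "P2", "P3"))
  expect_equal(unname(s$weights), rep(1 / 3, 3))
  expect_equal(sum(s$weights), 1, tolerance = 1e-12)

  off <- herb_catalog(list(H = c("C1", "C2", "C3")),
                      list(C1 = "X1", C2 = "X2", C3 = "X3"))
  expect_error(suppressMessages(herb_seed(off, "H", net)),
               "no on-network targets")
})

test_that("disease gene curation drops excluded tags", {
  f <- write_tmp_tsv(c("gene\tsource\tassociation_type",
                       "P1\tcurated\tgenetic",
                       "P2\ttext_mining\tgenetic",
                       "P3\tcurated\ttherapeutic",
                       "P4\tcurated\tanimal_model"))
  d <- suppressMessages(load_disease_genes(
    f, excluded_association_types = c("therapeutic", "animal_model"),
    excluded_evidence = "text_mining"))
  expect_equal(d$records$gene, "P1")

  plain <- write_tmp_tsv(c("P1", "P2"))
  d2 <- suppressMessages(load_disease_genes(plain))
  expect_equal(d2$records$gene, c("P1", "P2"))

  expect_warning(
    suppressMessages(load_disease_genes(
      f, excluded_association_types = c("genetic", "therapeutic",
                                        "animal_model"))),
    "all disease gene records excluded")
})

test_that("cotarget summary counts distinct herbs per target", {
  cat_ <- tiny_catalog()
  cs <- cotarget_summary(cat_, min_herbs = 2)
  # HerbA targets P1-P3, HerbB P4-P5, HerbC P3 -> P3 hit by two herbs
  expect_equal(cs$target_counts$n_herbs[cs$target_counts$target == "P3"], 2L)
  expect_equal(cs$key_targets, "P3")
  expect_length(cotarget_summary(cat_, min_herbs = 3)$key_targets, 0)

  # herb-target pair reached via two compounds stays one edge
  dup <- herb_catalog(list(H = c("C1", "C2")), list(C1 = "T1", C2 = "T1"))
  expect_equal(nrow(cotarget_summary(dup)$edges), 1L)

  # edge count equals brute-force distinct-pair enumeration
  pairs <- unique(do.call(rbind, lapply(cat_$herbs, function(h)
    expand.grid(h = h, t = names(pathway_count(cat_, h)),
                stringsAsFactors = FALSE))))
  expect_equal(nrow(cs$edges), nrow(pairs))
})

test_that("bundled demo tables load end to end", {
  d <- system.file("extdata", package = "herbnet")
  cat_ <- suppressMessages(load_catalog(
    file.path(d, "demo_herb_compound.tsv"),
    file.path(d, "demo_compound_target.tsv")))
  expect_setequal(cat_$herbs, c("HerbA", "HerbB", "HerbC"))
  net <- suppressMessages(load_network(
    file.path(d, "demo_pp.tsv"), file.path(d, "demo_pf.tsv"),
    file.path(d, "demo_ff.tsv")))
  expect_equal(length(net$proteins), 5L)
})
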
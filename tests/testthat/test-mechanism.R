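# profiles + network reused across mechanism tests
mech_fixture <- function(seed = 21) {
  cfg <- synthetic_config(seed = seed, n_proteins = 60, n_functions = 12,
                          disease_size = 8, n_herbs = 4)
  net0 <- generate_network(cfg)
  pd <- plant_disease(net0, cfg)
  gc_ <- generate_catalog(pd$network, pd$disease, cfg)
  net <- pd$network
  tr <- herbnet:::build_transition(net, rwr_params())
  hseed <- suppressMessages(herb_seed(gc_$catalog, gc_$planted, net))
  hprof <- diffusion_profile(net, hseed, rwr_params(), transition = tr)
  dprof <- diffusion_profile(net, disease_seed(pd$disease, net),
                             rwr_params(), transition = tr)
  list(net = net, hprof = hprof, dprof = dprof,
       targets = hseed$genes, dgenes = pd$disease$records$gene)
}

test_that("top-k selection respects ranks, ties, and exclusions", {
  p <- structure(list(entity = "e",
                      p = setNames(c(0.4, 0.3, 0.2, 0.1, 0.0),
                                   c("n1", "n2", "n3", "n4", "n5")),
                      seeds = "n1"),
                 class = "diffusion_profile")
  expect_equal(top_k_nodes(p, k = 2), c("n2", "n3"))   # seed excluded
  expect_equal(top_k_nodes(p, k = 2, exclude = character()), c("n1", "n2"))
  expect_equal(top_k_nodes(p, k = 99), c("n2", "n3", "n4", "n5"))
  tie <- structure(list(entity = "e",
                        p = setNames(c(0.5, 0.25, 0.25), c("a", "c", "b")),
                        seeds = character()),
                   class = "diffusion_profile")
  expect_equal(top_k_nodes(tie, k = 2), c("a", "b"))   # id tie-break
  expect_equal(top_k_nodes(tie, k = 1), "a")
})

test_that("mechanism extraction links targets, tags roles, flags critical", {
  fx <- mech_fixture()
  mech <- extract_mechanism(fx$hprof, fx$dprof, fx$net, fx$targets,
                            fx$dgenes, k = 10)
  expect_s3_class(mech, "mechanism_subnetwork")
  expect_true(mech$compound %in% mech$nodes$id)
  expect_true(mech$disease %in% mech$nodes$id)
  # retained-node bound
  expect_lte(nrow(mech$nodes),
             2 * 10 + length(fx$targets) + length(fx$dgenes) + 2)
  # every retained compound-target keeps an edge into the subnetwork
  kept <- mech$nodes$id[mech$nodes$role == "compound-target"]
  for (t in kept) {
    expect_true(any(mech$edges$from == t | mech$edges$to == t))
  }
  # the argmax of each profile carries the critical flag
  top_d <- top_k_nodes(fx$dprof, 1)
  expect_true(mech$nodes$critical[mech$nodes$id == top_d])
  expect_equal(sum(mech$nodes$critical), length(unique(
    c(top_k_nodes(fx$hprof, 1), top_d))))
})

test_that("targets isolated from the disease side are excluded", {
  # hand-built: target Tfar is an isolated protein with no multiscale edges
  net <- msnet(pp = data.frame(
    a = c("P1", "P2", "P3", "Tnear"),
    b = c("P2", "P3", "P1", "P1")), proteins = "Tfar")
  tr <- herbnet:::build_transition(net, rwr_params())
  cprof <- diffusion_profile(net, seed_set("cmp", c("Tnear", "Tfar")),
                             rwr_params(), transition = tr)
  dprof <- diffusion_profile(net, seed_set("dis", c("P2", "P3")),
                             rwr_params(), transition = tr)
  mech <- extract_mechanism(cprof, dprof, net,
                            compound_targets = c("Tnear", "Tfar"),
                            disease_genes = c("P2", "P3"), k = 2)
  roles <- setNames(mech$nodes$role, mech$nodes$id)
  expect_equal(unname(roles["Tnear"]), "compound-target")
  expect_false("Tfar" %in% mech$nodes$id)
  # a target that is itself a disease gene is always linked
  mech2 <- extract_mechanism(cprof, dprof, net,
                             compound_targets = c("Tfar", "P2"),
                             disease_genes = c("P2", "P3"), k = 2)
  expect_true("P2" %in% mech2$nodes$id)
})

test_that("extraction is deterministic under input permutations", {
  fx <- mech_fixture(22)
  ref <- extract_mechanism(fx$hprof, fx$dprof, fx$net, fx$targets,
                           fx$dgenes, k = 8)
  for (s in 1:5) {
    perm_t <- withr::with_seed(s, sample(fx$targets))
    perm_d <- withr::with_seed(s + 50, sample(fx$dgenes))
    again <- extract_mechanism(fx$hprof, fx$dprof, fx$net, perm_t,
                               perm_d, k = 8)
    expect_identical(again$nodes, ref$nodes)
    expect_identical(again$edges, ref$edges)
  }
})

test_that("k covering all nodes reduces to the linked induced graph", {
  fx <- mech_fixture(23)
  n_all <- length(msnet_nodes(fx$net))
  mech <- extract_mechanism(fx$hprof, fx$dprof, fx$net, fx$targets,
                            fx$dgenes, k = n_all)
  # with k = #nodes every non-seed node is a candidate: node set is all
  # nodes plus anchors, minus any unlinked targets (none can be unlinked
  # here because every node is disease-side)
  expect_equal(nrow(mech$nodes), n_all + 2)
})

test_that("GraphML export round-trips the subnetwork losslessly", {
  fx <- mech_fixture(24)
  mech <- extract_mechanism(fx$hprof, fx$dprof, fx$net, fx$targets,
                            fx$dgenes, k = 6)
  f <- withr::local_tempfile(fileext = ".graphml")
  export_subnetwork(mech, f, "graphml")
  back <- read_mechanism_graphml(f)
  expect_equal(back$nodes, mech$nodes)
  expect_equal(back$edges, mech$edges)
})

test_that("cytoscape JSON and TSV exports carry role and layer tags", {
  fx <- mech_fixture(25)
  mech <- extract_mechanism(fx$hprof, fx$dprof, fx$net, fx$targets,
                            fx$dgenes, k = 5)
  fj <- withr::local_tempfile(fileext = ".cyjs")
  export_subnetwork(mech, fj, "cytoscape-json")
  cy <- jsonlite::read_json(fj)
  expect_equal(length(cy$elements$nodes), nrow(mech$nodes))
  expect_equal(length(cy$elements$edges), nrow(mech$edges))
  ft <- withr::local_tempfile(fileext = ".tsv")
  export_subnetwork(mech, ft, "tsv")
  tsv <- read.delim(ft)
  expect_named(tsv, c("source", "target", "layer", "role_source",
                      "role_target"))
  expect_equal(nrow(tsv), nrow(mech$edges))
})
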
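test_that("transition distributions follow class-transition weights", {
  # protein with 2 protein neighbors and 1 function neighbor
  net <- msnet(pp = data.frame(a = c("P1", "P1"), b = c("P2", "P3")),
               pf = data.frame(p = "P1", f = "F1"))
  td <- transition_distribution(net, "P1", rwr_params())
  expect_equal(unname(td[c("P2", "P3", "F1")]), rep(1 / 3, 3))

  td2 <- transition_distribution(net, "P1", rwr_params(w_pf = 2))
  expect_equal(unname(td2["F1"]), 1 / 2)
  expect_equal(unname(td2[c("P2", "P3")]), c(1 / 4, 1 / 4))

  iso <- msnet(pp = data.frame(a = "P1", b = "P2"), proteins = "P9")
  expect_length(transition_distribution(iso, "P9", rwr_params()), 0)

  expect_error(transition_distribution(net, "P1", rwr_params(w_pp = 0,
                                                             w_pf = 0,
                                                             w_f_up = 1)),
               "walker trapped")
})

test_that("parameter validation rejects ill-posed walks", {
  expect_error(rwr_params(r = 0), "r must be")
  expect_error(rwr_params(r = 1.2), "r must be")
  expect_error(rwr_params(w_pp = 0, w_pf = 0, w_fp = 0, w_f_up = 0,
                          w_f_down = 0), "at least one positive")
  expect_error(rwr_params(tol = 0), "tol")
})

test_that("two-node chain has the hand-solved fixed point", {
  net <- msnet(pp = data.frame(a = "P1", b = "P2"))
  p <- diffusion_profile(net, seed_set("x", "P1"),
                         rwr_params(r = 0.5, tol = 1e-10))
  # p1 = 1/2 + p2/2, p2 = p1/2  =>  (2/3, 1/3)
  expect_equal(unname(p$p[c("P1", "P2")]), c(2 / 3, 1 / 3),
               tolerance = 1e-7)
})

test_that("restart-only limit returns the seed distribution exactly", {
  net <- tiny_net()
  s <- seed_set("x", c("P1", "P4"))
  p <- diffusion_profile(net, s, rwr_params(r = 1))
  expect_identical(unname(p$p[c("P1", "P4")]), c(0.5, 0.5))
  expect_equal(sum(p$p), 1)
  expect_equal(p$iterations, 0L)
})

test_that("profiles are normalized distributions with small residuals", {
  for (sd_ in 1:6) {
    net <- rand_msnet(sd_)
    s <- rand_seed_set(net, sd_ + 100)
    params <- rwr_params(r = 0.4, w_pf = 1.5, w_f_up = 0.7)
    prof <- diffusion_profile(net, s, params)
    expect_true(all(prof$p >= 0))
    expect_equal(sum(prof$p), 1, tolerance = 1e-9)
    # fixed-point residual under the same operator
    tr <- herbnet:::build_transition(net, params)
    sv <- herbnet:::.seed_vector(s, tr$nodes)
    dang <- if (length(tr$dangling)) sum(prof$p[tr$dangling]) else 0
    rhs <- params$r * sv + (1 - params$r) *
      (as.numeric(tr$M %*% prof$p) + dang * sv)
    expect_lt(sum(abs(prof$p - rhs)), 10 * params$tol)
  }
})

test_that("seed mass grows monotonically toward the restart limit", {
  net <- rand_msnet(42)
  s <- rand_seed_set(net, 43)
  mass <- vapply(c(0.5, 0.9, 0.99), function(r) {
    sum(diffusion_profile(net, s, rwr_params(r = r))$p[s$genes])
  }, numeric(1))
  expect_true(all(diff(mass) > 0))
  expect_gt(mass[3], 0.95)
})

test_that("profiles are equivariant under node relabeling", {
  net <- rand_msnet(5)
  s <- rand_seed_set(net, 6)
  prof <- diffusion_profile(net, s, rwr_params())
  relab <- setNames(paste0("z", rev(msnet_nodes(net))), msnet_nodes(net))
  net2 <- msnet(
    pp = data.frame(a = relab[net$pp$from], b = relab[net$pp$to]),
    pf = data.frame(p = relab[net$pf$protein], f = relab[net$pf$fn]),
    ff = data.frame(c = relab[net$ff$child], p = relab[net$ff$parent]),
    proteins = unname(relab[net$proteins]),
    functions = unname(relab[net$functions]))
  prof2 <- diffusion_profile(net2, seed_set("s", unname(relab[s$genes])),
                             rwr_params())
  expect_equal(unname(prof2$p[relab[names(prof$p)]]), unname(prof$p),
               tolerance = 1e-9)
})

test_that("non-convergence surfaces the residual", {
  net <- rand_msnet(9)
  s <- rand_seed_set(net, 10)
  expect_error(
    diffusion_profile(net, s, rwr_params(r = 0.05, tol = 1e-14,
                                         max_iter = 2)),
    "did not converge")
})

test_that("batch profiles equal per-seed profiles in order", {
  net <- rand_msnet(11)
  seeds <- list(rand_seed_set(net, 1), rand_seed_set(net, 2, n = 3))
  batch <- batch_profiles(net, seeds, rwr_params())
  solo <- lapply(seeds, function(s) diffusion_profile(net, s, rwr_params()))
  expect_equal(lapply(batch, `[[`, "p"), lapply(solo, `[[`, "p"))
  expect_equal(vapply(batch, `[[`, "", "entity"),
               vapply(seeds, `[[`, "", "entity"))
})

test_that("the Monte-Carlo walker is reproducible and matches the fixed point", {
  net <- msnet(pp = data.frame(a = "P1", b = "P2"))
  s <- seed_set("x", "P1")
  f1 <- mc_profile(net, s, rwr_params(r = 0.5), n_steps = 1e5, rng_seed = 7)
  f2 <- mc_profile(net, s, rwr_params(r = 0.5), n_steps = 1e5, rng_seed = 7)
  expect_identical(f1, f2)
  expect_lt(sum(abs(f1 - c(2 / 3, 1 / 3))), 0.01)

  # restart-only: frequencies are empirical seed draws
  r1 <- mc_profile(net, seed_set("x", c("P1", "P2")), rwr_params(r = 1),
                   n_steps = 1e5, rng_seed = 3)
  expect_equal(unname(r1["P1"]), 0.5, tolerance = 0.02)
})

test_that("profile TSV serialization round-trips exactly", {
  net <- tiny_net()
  prof <- diffusion_profile(net, seed_set("x", "P1"), rwr_params())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(prof, net, f)
  back <- read_profile_tsv(f)
  expect_identical(sort(names(back)), sort(names(prof$p)))
  expect_identical(unname(back[names(prof$p)]), unname(prof$p))
})
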
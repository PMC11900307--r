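# Shared fixtures and independent oracles, built in code at test time.

# tiny deterministic catalog: HerbA (3 targeted compounds), HerbB (3),
# HerbC (1) -- HerbC falls to the default component filter
tiny_catalog <- function() {
  herb_catalog(
    compounds_of = list(
      HerbA = c("C1", "C2", "C3"),
      HerbB = c("C4", "C5", "C6"),
      HerbC = c("C7")),
    targets_of = list(
      C1 = c("P1", "P2"), C2 = c("P2", "P3"), C3 = "P1",
      C4 = "P4", C5 = "P5", C6 = c("P4", "P5"), C7 = "P3"))
}

# 5-protein path-plus-chords network with a 3-function hierarchy
tiny_net <- function() {
  msnet(
    pp = data.frame(a = c("P1", "P2", "P3", "P4", "P1", "P2"),
                    b = c("P2", "P3", "P4", "P5", "P3", "P5")),
    pf = data.frame(p = c("P1", "P2", "P3", "P5"),
                    f = c("F1", "F1", "F2", "F2")),
    ff = data.frame(c = c("F1", "F2"), p = c("F3", "F3")))
}

# random small multiscale network (<= 30 nodes), always walkable under the
# default uniform weights; used by the diffusion contract checks
rand_msnet <- function(seed, max_nodes = 30) {
  withr::with_seed(seed, {
    np <- sample(3:max(3, max_nodes - 8), 1)
    nf <- sample(0:min(8, max_nodes - np), 1)
    prot <- sprintf("p%02d", seq_len(np))
    fn <- if (nf > 0) sprintf("f%02d", seq_len(nf)) else character()
    # connected pp backbone: random tree plus extra edges
    pp <- data.frame(a = prot[1], b = prot[2])
    for (i in seq(3, np)) {
      pp <- rbind(pp, data.frame(a = prot[sample(i - 1, 1)], b = prot[i]))
    }
    extra <- sample(np, min(np, 4) * 2, replace = TRUE)
    extra <- matrix(prot[extra], ncol = 2)
    extra <- extra[extra[, 1] != extra[, 2], , drop = FALSE]
    if (nrow(extra)) pp <- rbind(pp, data.frame(a = extra[, 1],
                                                b = extra[, 2]))
    pf <- NULL
    if (nf > 0) {
      pf <- data.frame(p = sample(prot, min(np, 2 + nf), replace = TRUE),
                       f = sample(fn, min(np, 2 + nf), replace = TRUE))
    }
    ff <- NULL
    if (nf > 1) {
      ff <- data.frame(c = fn[seq_len(nf - 1)],
                       p = fn[pmin(nf, seq_len(nf - 1) + 1)])
    }
    msnet(pp = pp, pf = pf, ff = ff, proteins = prot, functions = fn)
  })
}

rand_seed_set <- function(network, seed, n = 2) {
  withr::with_seed(seed, {
    seed_set("s", sample(network$proteins, min(n, length(network$proteins))))
  })
}

# enumeration oracle for the hypergeometric upper tail: exhaustively list
# all size-n draws from 1:N with 1:K marked and count overlaps >= k
enum_hyper_upper <- function(k, n, K, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)
  mean(overlaps >= k)
}

# brute-force BH step-up: adj_(i) = min_{j >= i} p_(j) * m / j, clipped at 1
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(pmin(1, ranked[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# hand-evaluated Pearson correlation for the scoring example
# (0.5,0.3,0.2) vs (0.2,0.3,0.5): r = -39/42
pearson_by_hand <- -39 / 42
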
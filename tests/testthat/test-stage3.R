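make_ref <- function(A, B, positions) {
  list(A = haplotype_panel(A, positions), B = haplotype_panel(B, positions))
}

test_that("LD conditionals are smoothed pairwise counts", {
  pos <- c(100, 200)
  ## 4 haplotypes with pair counts {00:2, 01:0, 10:1, 11:1}
  A <- rbind(c(0, 0), c(0, 0), c(1, 0), c(1, 1))
  ld <- estimate_ld(make_ref(A, A, pos))
  expect_equal(ld$A$cond[1, 1, 1], (2 + 0.5) / (2 + 1))  # cond(0|0)
  expect_equal(ld$A$cond[2, 2, 1], (1 + 0.5) / (2 + 1))  # cond(1|1)
  ## columns of each conditional sum to 1
  expect_equal(ld$A$cond[1, 1, 1] + ld$A$cond[1, 2, 1], 1)
  expect_equal(ld$A$cond[2, 1, 1] + ld$A$cond[2, 2, 1], 1)
})

test_that("LD limits: perfect copying and linkage equilibrium", {
  pos <- c(1, 2)
  n <- 200
  perfect <- cbind(rep(0:1, each = n / 2), rep(0:1, each = n / 2))
  ld <- estimate_ld(make_ref(perfect, perfect, pos))
  expect_equal(ld$A$cond[2, 2, 1], (n / 2 + 0.5) / (n / 2 + 1))
  set.seed(3)
  indep <- matrix(rbinom(2 * n, 1, 0.5), n, 2)
  ld2 <- estimate_ld(make_ref(indep, indep, pos))
  expect_equal(ld2$A$cond[1, 2, 1], 0.5, tolerance = 0.15)
  expect_error(estimate_ld(list(A = haplotype_panel(indep, pos),
                                B = haplotype_panel(indep, pos + 5))),
               "SNP set")
})

test_that("genotype transitions follow LD on ancestry runs and marginals on changes", {
  set.seed(5)
  pos <- c(1, 1000)
  A <- matrix(rbinom(40, 1, 0.6), 20, 2)
  B <- matrix(rbinom(40, 1, 0.25), 20, 2)
  ld <- estimate_ld(make_ref(A, B, pos))
  ## ancestry changed: marginal of the NEW population only
  expect_equal(stage3_transition(0, 1, anc_prev = 0, anc_cur = 1, ld, t = 2),
               ld$B$f[2])
  expect_equal(stage3_transition(1, 1, anc_prev = 0, anc_cur = 1, ld, t = 2),
               ld$B$f[2])
  ## same ancestry: the conditional
  expect_equal(stage3_transition(1, 1, anc_prev = 1, anc_cur = 1, ld, t = 2),
               ld$B$cond[2, 2, 1])
  ## each destination pair sums to 1 either way
  for (ap in 0:1) for (ac in 0:1) for (prev in 0:1) {
    expect_equal(stage3_transition(prev, 0, ap, ac, ld, 2) +
                   stage3_transition(prev, 1, ap, ac, ld, 2), 1,
                 tolerance = 1e-12)
  }
})

test_that("stage-3 emissions reuse the stage-1 matching model", {
  ## same configuration scored through both code paths
  fam <- manual_family(T = 10, N = 2, seed = 21)
  ge <- 0.01
  G <- c(1, 0, 0, 1)
  for (t in c(1, 5, 10)) {
    H <- fam$children[, t]
    direct <- stage1_emission(P = c(0, 0), R = c(0, 1, 1, 0), G = G,
                              H = H, ge = ge)
    ## routes under P=(0,0), R=(0,1,1,0): c1h1 -> father hap1 (G1),
    ## c2h1 -> father hap2 (G2), c1h2 -> mother hap2 (G4),
    ## c2h2 -> mother hap1 (G3)
    imp <- c(G[1], G[4], G[2], G[3])
    manual <- prod(ifelse(imp == H, 1 - ge, ge))
    expect_equal(direct, manual)
  }
})

test_that("unanimous child alleles force the parental call where covered", {
  set.seed(25)
  T <- 30
  positions <- seq(1e5, by = 1e5, length.out = T)
  children <- matrix(0L, 6, T)  # all children all-zero
  ## fix routes so the three children jointly cover all four parental
  ## haplotypes at every site
  s1 <- structure(list(P = matrix(0L, 3, T),
                       R = rbind(matrix(0L, 1, T), matrix(1L, 1, T),
                                 matrix(0L, 1, T),
                                 matrix(0L, 1, T), matrix(1L, 1, T),
                                 matrix(0L, 1, T)),
                       N = 3L), class = "stage1_result")
  anc <- structure(list(labels = matrix(0L, 4, T)), class = "ancestry_call")
  refA <- matrix(rbinom(20 * T, 1, 0.5), 20, T)
  ld <- estimate_ld(make_ref(refA, refA, positions))
  gen <- call_genotypes(children, s1, anc, ld, ge = 1e-4)
  expect_true(all(gen$alleles == 0L))
  expect_true(all(gen$genotypes == 0L))
})

test_that("an untransmitted haplotype falls back to the LD prior", {
  ## N = 1: the untransmitted father haplotype gets no data anywhere
  set.seed(27)
  T <- 25
  positions <- seq(1e5, by = 1e5, length.out = T)
  children <- matrix(rbinom(2 * T, 1, 0.5), 2, T)
  rates <- list(rb = 0, pe = 0, ge = 0.001)
  s1 <- infer_stage1(children, positions, rates)
  f <- runif(T, 0.3, 0.7)
  anc <- infer_ancestry(children, s1, list(fA = f, fB = 1 - f), positions,
                        list(g = 10, fx = 0.5, rb = 1e-8), 0.001)
  refA <- matrix(rbinom(40 * T, 1, 0.5), 40, T)
  ld <- estimate_ld(make_ref(refA, refA, positions))
  gen <- call_genotypes(children, s1, anc, ld, ge = 0.001)
  ## transmitted haplotypes: posterior certainty high; the two
  ## untransmitted ones: strictly below 1
  routes <- unique(as.vector(rbind(
    2L * s1$P[1, ] + s1$R[1, ], 2L * (1L - s1$P[1, ]) + s1$R[2, ])))
  uncovered <- setdiff(0:3, routes)
  expect_length(uncovered, 2)
  bits <- state_bits(4)
  for (h in uncovered) {
    marg1 <- colSums(gen$posterior[bits[, h + 1] == 1L, , drop = FALSE])
    expect_true(all(pmax(marg1, 1 - marg1) < 1 - 1e-6))
  }
})

drop_ld <- function(ld) {
  ## frequency-only variant: every conditional replaced by the marginal
  for (p in c("A", "B")) {
    for (a in 1:2) {
      ld[[p]]$cond[a, 2, ] <- ld[[p]]$f[-1]
      ld[[p]]$cond[a, 1, ] <- 1 - ld[[p]]$f[-1]
    }
  }
  ld
}

test_that("LD-aware calling dominates the frequency-only caller on average", {
  ## regime where LD carries real information: a haplotype anchored by
  ## data on one half of the chromosome and untransmitted on the other,
  ## with a reference panel of two diverged haplotype lineages
  set.seed(71)
  T <- 40
  positions <- seq(5e3, by = 5e3, length.out = T)
  deltas <- replicate(20, {
    protoA <- rbinom(T, 1, 0.5)
    protoB <- 1L - protoA  # maximally distinct lineage
    noisy <- function(h, n) t(replicate(n, ifelse(runif(T) < 0.05, 1L - h, h)))
    ref <- make_ref(rbind(noisy(protoA, 15), noisy(protoB, 15)),
                    noisy(protoA, 30), positions)
    father1 <- ifelse(runif(T) < 0.05, 1L - protoA, protoA)
    father2 <- rbinom(T, 1, 0.5)
    mother1 <- rbinom(T, 1, 0.5)
    ## one child: paternal gamete = father1 left half, father2 right half
    children <- rbind(ifelse(seq_len(T) <= T / 2, father1, father2),
                      mother1)
    s1 <- structure(list(P = matrix(0L, 1, T),
                         R = rbind(as.integer(seq_len(T) > T / 2),
                                   rep(0L, T)),
                         N = 1L), class = "stage1_result")
    anc <- structure(list(labels = matrix(0L, 4, T)),
                     class = "ancestry_call")
    ld <- estimate_ld(ref)
    acc <- function(l) {
      g <- call_genotypes(children, s1, anc, l, ge = 0.001)
      mean(g$alleles[1, ] == father1)  # father hap1, half untransmitted
    }
    acc(ld) - acc(drop_ld(ld))
  })
  expect_gt(mean(deltas), 0)
})
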
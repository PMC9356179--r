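test_that("sim_params validates rates, family sizes and thresholds", {
  expect_s3_class(sim_params(), "sim_params")
  expect_error(sim_params(df = 0.6), "df")
  expect_error(sim_params(pp = 2), "pp")
  expect_error(sim_params(nh = 20, nf = 10), "nh")
  expect_error(sim_params(nk = 0))
  ## the default study conditions
  p <- sim_params()
  expect_equal(p$nh, 400L)
  expect_equal(p$L, 2.59e8)
  expect_equal(p$rho, 1e-8)
  expect_equal(p$t_split, 0.125)
  expect_equal(p$g, 10L)
  expect_equal(c(p$nf, p$nk), c(10L, 3L))
  expect_equal(c(p$df, p$pp), c(0.1, 2e-6))
})

test_that("zero divergence makes the two populations exchangeable", {
  set.seed(5)
  p <- sim_params(t_split = 0, nh = 400, L = 1e7, n_snps = 3000)
  panels <- simulate_ancestral_panels(p)
  d <- abs(panel_freqs(panels$A) - panel_freqs(panels$B))
  ## sampling noise only: SE of a frequency difference at nh/2 = 200
  expect_lt(mean(d), 3 / sqrt(200))
  expect_identical(panels$A$positions, panels$B$positions)
})

test_that("emitted panels reproduce the Balding-Nichols divergence (Hudson FST)", {
  set.seed(17)
  target <- 1 - exp(-0.125)  # 0.1175
  p <- sim_params(t_split = 0.125, nh = 400, L = 2e7, n_snps = 10000)
  fst <- replicate(20, {
    panels <- simulate_ancestral_panels(p)
    hudson_fst(panels$A$alleles, panels$B$alleles)
  })
  se <- sd(fst) / sqrt(length(fst))
  expect_lt(abs(mean(fst) - target), 3 * se + 0.005)
})

test_that("adjacent-SNP association is present and decays with distance", {
  set.seed(23)
  p <- sim_params(t_split = 0, nh = 400, L = 1e6, n_snps = 500)
  panels <- simulate_ancestral_panels(p)
  x <- panels$A$alleles
  f <- colMeans(x)
  poly <- which(f > 0.2 & f < 0.8)
  adj <- poly[which(diff(poly) == 1)]
  r_adj <- mean(vapply(adj, function(t)
    abs(cor(x[, t], x[, t + 1])), 1.0), na.rm = TRUE)
  expect_gt(r_adj, 0.2)  # strong association at ~2 kb spacing
})

test_that("meiosis limits: no recombination and identical parents", {
  set.seed(3)
  pos <- seq(1e5, 1e7, by = 1e5)
  h1 <- rbinom(length(pos), 1, 0.5)
  h2 <- rbinom(length(pos), 1, 0.5)
  m <- meiosis(h1, h2, pos, rho = 0)
  expect_length(m$breakpoints, 0)
  expect_true(identical(m$gamete, h1) || identical(m$gamete, h2))
  m2 <- meiosis(h1, h1, pos, rho = 1e-7)
  expect_identical(m2$gamete, h1)
})

test_that("meiosis crossover count matches its Poisson mean", {
  set.seed(11)
  pos <- c(1, 2.59e8)
  h <- c(0L, 1L)
  n <- 1000
  counts <- replicate(n, length(meiosis(h, h, pos, rho = 1e-8,
                                        L = 2.59e8)$breakpoints))
  mu <- 1e-8 * 2.59e8
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / n))
})

test_that("admixture limits: g = 0 copies founders; rho = 0 gives pure haplotypes", {
  set.seed(29)
  p <- sim_params(nh = 40, nf = 5, L = 1e6, n_snps = 200, g = 0)
  panels <- simulate_ancestral_panels(p)
  adm <- simulate_admixture(panels$A, panels$B, p)
  anc <- attr(adm, "ancestry")
  expect_true(all(anc %in% 0:1))
  ## every founder-copy haplotype has a single-population label track
  expect_true(all(apply(anc, 1, function(r) length(unique(r)) == 1)))
  pool <- rbind(panels$A$alleles, panels$B$alleles)
  expect_true(all(apply(adm$alleles, 1, function(r)
    any(apply(pool, 1, identical, y = r)))))

  p2 <- sim_params(nh = 40, nf = 5, L = 1e6, n_snps = 200, g = 8, rho = 0)
  adm2 <- simulate_admixture(panels$A, panels$B, p2)
  anc2 <- attr(adm2, "ancestry")
  expect_true(all(apply(anc2, 1, function(r) length(unique(r)) == 1)))
})

test_that("ancestry-segment count matches the junction-accumulation expectation", {
  set.seed(41)
  p <- sim_params(nh = 400, L = 2.59e8, n_snps = 2000, g = 10, rho = 1e-8)
  panels <- simulate_ancestral_panels(p)
  segs <- unlist(lapply(1:2, function(i) {
    adm <- simulate_admixture(panels$A, panels$B, p)
    apply(attr(adm, "ancestry"), 1, function(r) length(rle(r)$lengths))
  }))
  ## 50/50 founding: a crossover creates a visible junction when the two
  ## parental chromosomes differ in ancestry there (prob ~ 1/2)
  expected <- 1 + p$g * p$rho * p$L / 2
  expect_lt(abs(mean(segs) - expected) / expected, 0.15)
})

test_that("families have the default cohort shape and replay the truth exactly", {
  set.seed(31)
  p <- sim_params(nh = 100, nf = 10, nk = 3, L = 1e7, n_snps = 500,
                  ge = 0, pp = 0, df = 0)
  panels <- simulate_ancestral_panels(p)
  adm <- simulate_admixture(panels$A, panels$B, p)
  fams <- make_families(adm, p)
  expect_length(fams, 10)
  expect_equal(sum(vapply(fams, function(f) nrow(f$children), 1L)), 60)
  for (f in fams[1:3]) {
    tr <- f$truth
    for (k in seq_along(tr$child_transmissions)) {
      src <- tr$child_transmissions[[k]]
      T <- ncol(f$children)
      replay_p <- tr$father_haps[cbind(src$pat + 1L, seq_len(T))]
      replay_m <- tr$mother_haps[cbind(src$mat + 1L, seq_len(T))]
      expect_identical(f$children[2 * k - 1, ], replay_p)
      expect_identical(f$children[2 * k, ], replay_m)
    }
  }
})

test_that("nk = 1 with rho = 0 transmits single parental haplotypes verbatim", {
  set.seed(37)
  p <- sim_params(nh = 40, nf = 2, nk = 1, L = 1e6, n_snps = 300,
                  rho = 0, ge = 0, g = 2)
  panels <- simulate_ancestral_panels(p)
  adm <- simulate_admixture(panels$A, panels$B, p)
  fams <- make_families(adm, p)
  for (f in fams) {
    expect_true(any(apply(f$truth$father_haps, 1, identical,
                          y = f$children[1, ])))
    expect_true(any(apply(f$truth$mother_haps, 1, identical,
                          y = f$children[2, ])))
  }
})

test_that("phasing-error injection preserves genotypes and its Poisson mean", {
  set.seed(43)
  pos <- sort(sample.int(2.59e8, 300))
  ch <- matrix(rbinom(600, 1, 0.5), 2, 300)
  ## pp = 0: unchanged
  r0 <- inject_phasing_errors(ch, 0, pos, L = 2.59e8)
  expect_identical(r0$children, ch)
  expect_length(r0$switch_positions[[1]], 0)
  ## genotype conservation at any pp
  r1 <- inject_phasing_errors(ch, 2e-6, pos, L = 2.59e8)
  expect_equal(r1$children[1, ] + r1$children[2, ], ch[1, ] + ch[2, ])
  expect_false(identical(r1$children, ch))  # 518 expected switches
  ## Poisson mean over replicates
  n <- 100
  counts <- replicate(n, length(inject_phasing_errors(
    ch, 2e-6, pos, L = 2.59e8)$switch_positions[[1]]))
  mu <- 2e-6 * 2.59e8
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / n))
  expect_error(inject_phasing_errors(ch[1, , drop = FALSE], 1e-6, pos),
               "even")
})

test_that("frequency pruning keeps SNPs by minor-allele-frequency difference", {
  ## |maf| differences 0.05 (dropped) and 0.20 (kept) at df = 0.1
  expect_identical(prune_by_frequency(c(0.50, 0.20), c(0.55, 0.40), 0.1), 2L)
  ## maf folds frequencies above 0.5
  expect_identical(prune_by_frequency(0.9, 0.1, 0.1), integer(0))
  ## monotone: higher df keeps a subset
  set.seed(47)
  fA <- runif(500); fB <- runif(500)
  k1 <- prune_by_frequency(fA, fB, 0.1)
  k3 <- prune_by_frequency(fA, fB, 0.3)
  expect_true(all(k3 %in% k1))
})

test_that("the full dataset generator is seed-deterministic", {
  p <- sim_params(nh = 60, nf = 2, nk = 2, L = 2e6, n_snps = 400,
                  seed = 99)
  d1 <- simulate_family_dataset(p)
  d2 <- simulate_family_dataset(p)
  expect_identical(d1$families, d2$families)
  expect_identical(d1$positions, d2$positions)
  expect_identical(d1$freqs, d2$freqs)
})

test_that("ge = 0 children inherit parental alleles exactly after pruning", {
  p <- sim_params(nh = 60, nf = 2, nk = 2, L = 2e6, n_snps = 400,
                  ge = 0, pp = 0, seed = 7)
  ds <- simulate_family_dataset(p)
  for (f in ds$families) {
    tr <- f$truth
    T <- ncol(f$children)
    for (k in seq_along(tr$child_transmissions)) {
      src <- tr$child_transmissions[[k]]
      expect_identical(f$children[2 * k - 1, ],
                       tr$father_haps[cbind(src$pat + 1L, seq_len(T))])
    }
  }
})
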
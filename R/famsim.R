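#' Simulation parameters for admixed families
#'
#' Defaults describe the study conditions used throughout: two ancestral
#' populations split t_split coalescent units ago, merged 50/50 into an
#' admixed population that evolves g generations under a diploid
#' Wright-Fisher model with recombination, from which nf couples each
#' produce nk children; phasing switch errors are injected into the
#' children at rate pp per bp and SNPs are pruned at minor-allele
#' frequency difference df.
#'
#' @param nh number of ancestral haplotypes (split evenly between the two
#'   populations).
#' @param nc number of chromosomes (one region is simulated per call).
#' @param Ne effective population size.
#' @param L region length in bp (default: human chromosome 1).
#' @param mu mutation rate per generation per bp (kept for completeness;
#'   the frequency-model backend fixes the SNP count via `n_snps`).
#' @param rho recombination rate per generation per bp.
#' @param t_split split time of the ancestral populations, coalescent units.
#' @param g generations since admixture.
#' @param nf number of families.
#' @param nk children per family.
#' @param df frequency-pruning threshold on the minor-allele frequency
#'   difference between the two populations, in [0, 0.5].
#' @param pp phasing error (switch) rate per bp.
#' @param ge genotyping error rate per allele (applied to child alleles
#'   after transmission).
#' @param n_snps number of SNPs to simulate; default scales with L at the
#'   segregating-site density of ~5e-4 per bp seen at whole-chromosome scale.
#' @param rho_ld decay rate (per bp) of the within-population
#'   allele-copying correlation used to put LD into the ancestral panels.
#' @param n_admix number of diploids in the forward-time admixed
#'   population; default `min(Ne, nh/2)` (enough to supply the 4*nf
#'   founder haplotypes without simulating the full Ne).
#' @param seed optional RNG seed; if given, generation is reproducible.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(nh = 400L, nc = 1L, Ne = 10000L, L = 2.59e8,
                       mu = 1e-9, rho = 1e-8, t_split = 0.125, g = 10L,
                       nf = 10L, nk = 3L, df = 0.1, pp = 2e-6,
                       ge = 0.001, n_snps = NULL, rho_ld = 3e-5,
                       n_admix = NULL, seed = NULL) {
  p <- list(nh = as.integer(nh), nc = as.integer(nc), Ne = as.integer(Ne),
            L = as.numeric(L), mu = mu, rho = rho, t_split = t_split,
            g = as.integer(g), nf = as.integer(nf), nk = as.integer(nk),
            df = df, pp = pp, ge = ge,
            n_snps = if (is.null(n_snps)) max(2L, as.integer(round(5e-4 * L)))
                     else as.integer(n_snps),
            rho_ld = rho_ld,
            n_admix = if (is.null(n_admix)) max(as.integer(2L * nf),
                                                min(as.integer(Ne),
                                                    as.integer(nh / 2)))
                      else as.integer(n_admix),
            seed = seed)
  stopifnot(p$nh >= 4 * p$nf, p$nk >= 1, p$g >= 0, p$L > 0,
            p$nh %% 2 == 0)
  for (r in c("mu", "rho", "pp", "ge")) {
    if (p[[r]] < 0 || p[[r]] > 1) stop(r, " must lie in [0, 1] per unit")
  }
  if (p$df < 0 || p$df > 0.5) stop("df must lie in [0, 0.5]")
  if (p$t_split < 0) stop("t_split must be >= 0")
  if (p$n_snps < 2) stop("at least 2 SNPs are required")
  class(p) <- "sim_params"
  p
}

## Ancestral allele frequency draw: neutral-SFS-like density proportional
## to 1/p, truncated to [1/nh, 1 - 1/nh]; inverse-CDF sampling.
rsfs <- function(n, nh) {
  lo <- 1 / nh
  hi <- 1 - lo
  lo * (hi / lo)^stats::runif(n)
}

## Sample a haplotype block with first-order Markov LD: a latent uniform
## u_t persists from site t-1 with probability exp(-rho_ld * gap) and
## allele_t = 1 iff u_t < f_t, so marginals are exact Bernoulli(f_t) and
## adjacent-site association decays with physical distance.
sample_ld_haplotypes <- function(n_hap, freqs, positions, rho_ld) {
  T <- length(freqs)
  out <- matrix(0L, n_hap, T)
  u <- stats::runif(n_hap)
  out[, 1] <- (u < freqs[1]) * 1L
  if (T > 1L) {
    r <- exp(-rho_ld * diff(positions))
    for (t in 2:T) {
      fresh <- stats::runif(n_hap) >= r[t - 1L]
      if (any(fresh)) u[fresh] <- stats::runif(sum(fresh))
      out[, t] <- (u < freqs[t]) * 1L
    }
  }
  out
}

#' Simulate the two differentiated ancestral haplotype panels
#'
#' Frequency-model backend: per-SNP ancestral frequencies follow a 1/p
#' spectrum; the two population frequencies are Balding-Nichols draws
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with divergence `F = 1 - exp(-t_split)`;
#' haplotypes carry first-order Markov LD decaying with distance.
#'
#' @param params a `sim_params` object.
#' @return List with `A` and `B` (each a `haplotype_panel` of nh/2
#'   haplotypes) sharing one SNP set.
#' @export
simulate_ancestral_panels <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_snps
  if (n < 2) stop("requested SNP count must be >= 2")
  positions <- sort(sample.int(params$L, n))
  p <- rsfs(n, params$nh)
  F <- 1 - exp(-params$t_split)
  if (F <= 0) {
    fA <- p
    fB <- p
  } else {
    a <- p * (1 - F) / F
    b <- (1 - p) * (1 - F) / F
    fA <- stats::rbeta(n, a, b)
    fB <- stats::rbeta(n, a, b)
  }
  nh_pop <- params$nh %/% 2L
  A <- sample_ld_haplotypes(nh_pop, fA, positions, params$rho_ld)
  B <- sample_ld_haplotypes(nh_pop, fB, positions, params$rho_ld)
  list(A = haplotype_panel(A, positions, pop_label = rep("A", nh_pop)),
       B = haplotype_panel(B, positions, pop_label = rep("B", nh_pop)))
}

#' One meiosis: recombine a pair of haplotypes into a gamete
#'
#' Crossovers follow a Poisson process of intensity `rho` per bp over
#' `[0, L]` (or, if a cumulative cM map is supplied, intensity 1 per
#' 100 cM along the map). No crossover interference.
#'
#' @param hap1,hap2 equal-length 0/1 allele vectors of the parent.
#' @param positions bp positions of the SNPs.
#' @param rho recombination rate per bp per generation.
#' @param L region length (defaults to max position).
#' @param map_cM optional cumulative genetic map at the SNP positions.
#' @param anc1,anc2 optional companion vectors (e.g. ancestry labels)
#'   spliced with the same breakpoints.
#' @return list: `gamete` (allele vector), `source` (0/1 per site: which
#'   parental haplotype was copied), `breakpoints` (bp positions of
#'   crossovers), and `anc` if companion vectors were given.
#' @export
meiosis <- function(hap1, hap2, positions, rho, L = max(positions),
                    map_cM = NULL, anc1 = NULL, anc2 = NULL) {
  if (length(hap1) != length(hap2)) stop("parental haplotypes differ in length")
  if (is.null(map_cM)) {
    k <- stats::rpois(1, rho * L)
    bp <- sort(stats::runif(k, 0, L))
  } else {
    span <- map_cM[length(map_cM)] - map_cM[1]
    k <- stats::rpois(1, span / 100)
    xc <- sort(stats::runif(k, map_cM[1], map_cM[length(map_cM)]))
    bp <- stats::approx(map_cM, positions, xout = xc, ties = "ordered")$y
  }
  start <- sample(0:1, 1)
  src <- (start + findInterval(positions, bp)) %% 2L
  gam <- ifelse(src == 0L, hap1, hap2)
  out <- list(gamete = gam, source = src, breakpoints = bp)
  if (!is.null(anc1)) out$anc <- ifelse(src == 0L, anc1, anc2)
  out
}

#' Forward Wright-Fisher admixture of the two ancestral panels
#'
#' Merges the two panels 50/50 into `n_admix` founder diploids and
#' evolves them `g` generations of random mating with recombination,
#' tracking the true ancestry label of every site of every haplotype.
#'
#' @param panelA,panelB the two ancestral `haplotype_panel`s (same SNP set).
#' @param params a `sim_params` object.
#' @return A `haplotype_panel` of `2 * n_admix` haplotypes with an
#'   `ancestry` attribute (matrix of 0 = population A / 1 = population B
#'   labels, same shape as the alleles).
#' @export
simulate_admixture <- function(panelA, panelB, params) {
  if (!identical(panelA$positions, panelB$positions)) {
    stop("ancestral panels must share one SNP set")
  }
  positions <- panelA$positions
  pool <- rbind(panelA$alleles, panelB$alleles)
  anc_pool <- matrix(rep(c(0L, 1L), c(nrow(panelA$alleles),
                                      nrow(panelB$alleles))),
                     nrow(pool), ncol(pool))
  n_admix <- params$n_admix
  need <- 2L * n_admix
  idx <- if (need <= nrow(pool)) sample(nrow(pool), need)
         else sample(nrow(pool), need, replace = TRUE)
  alle <- pool[idx, , drop = FALSE]
  anc <- anc_pool[idx, , drop = FALSE]
  if (params$g > 0) {
    for (gen in seq_len(params$g)) {
      new_alle <- matrix(0L, need, ncol(alle))
      new_anc <- matrix(0L, need, ncol(alle))
      for (i in seq_len(n_admix)) {
        parents <- sample(n_admix, 2)
        for (w in 1:2) {
          pr <- parents[w]
          m <- meiosis(alle[2 * pr - 1L, ], alle[2 * pr, ], positions,
                       params$rho, params$L,
                       anc1 = anc[2 * pr - 1L, ], anc2 = anc[2 * pr, ])
          new_alle[2 * i - 2L + w, ] <- m$gamete
          new_anc[2 * i - 2L + w, ] <- m$anc
        }
      }
      alle <- new_alle
      anc <- new_anc
    }
  }
  out <- haplotype_panel(alle, positions)
  attr(out, "ancestry") <- anc
  out
}

#' Draw nf families from the admixed population
#'
#' Selects 4*nf haplotypes without replacement, pairs them into nf
#' couples, and runs one more generation of meiosis to produce nk
#' children per couple, recording full ground truth. Genotyping errors
#' flip child alleles independently at rate `ge`.
#'
#' @param admixed panel from [simulate_admixture()] (with ancestry attribute).
#' @param params a `sim_params` object.
#' @return List of nf family objects. Each has `children` (2*nk x T allele
#'   matrix; rows child1-hap1 (paternal), child1-hap2 (maternal), ...),
#'   `truth`: `father_haps`/`mother_haps` (2 x T), `father_anc`/`mother_anc`
#'   (2 x T labels), `child_transmissions` (per child, 0/1 source vectors
#'   `pat` and `mat`), `breakpoints` (per child per gamete), `child_anc`
#'   (2*nk x T true child ancestry), and `ge_flips`.
#' @export
make_families <- function(admixed, params) {
  anc <- attr(admixed, "ancestry")
  if (is.null(anc)) stop("admixed panel lacks the ancestry truth attribute")
  nf <- params$nf
  if (nrow(admixed$alleles) < 4 * nf) {
    stop("admixed panel has fewer than 4*nf haplotypes")
  }
  positions <- admixed$positions
  T <- length(positions)
  picks <- matrix(sample(nrow(admixed$alleles), 4 * nf), nrow = 4)
  lapply(seq_len(nf), function(f) {
    hv <- picks[, f]
    fh <- admixed$alleles[hv[1:2], , drop = FALSE]
    mh <- admixed$alleles[hv[3:4], , drop = FALSE]
    fa <- anc[hv[1:2], , drop = FALSE]
    ma <- anc[hv[3:4], , drop = FALSE]
    children <- matrix(0L, 2 * params$nk, T)
    child_anc <- matrix(0L, 2 * params$nk, T)
    trans <- vector("list", params$nk)
    bkpt <- vector("list", params$nk)
    flips <- matrix(FALSE, 2 * params$nk, T)
    for (k in seq_len(params$nk)) {
      gp <- meiosis(fh[1, ], fh[2, ], positions, params$rho, params$L,
                    anc1 = fa[1, ], anc2 = fa[2, ])
      gm <- meiosis(mh[1, ], mh[2, ], positions, params$rho, params$L,
                    anc1 = ma[1, ], anc2 = ma[2, ])
      h1 <- gp$gamete
      h2 <- gm$gamete
      if (params$ge > 0) {
        fl1 <- stats::runif(T) < params$ge
        fl2 <- stats::runif(T) < params$ge
        h1 <- ifelse(fl1, 1L - h1, h1)
        h2 <- ifelse(fl2, 1L - h2, h2)
        flips[2 * k - 1L, ] <- fl1
        flips[2 * k, ] <- fl2
      }
      children[2 * k - 1L, ] <- h1
      children[2 * k, ] <- h2
      child_anc[2 * k - 1L, ] <- gp$anc
      child_anc[2 * k, ] <- gm$anc
      trans[[k]] <- list(pat = gp$source, mat = gm$source)
      bkpt[[k]] <- list(pat = gp$breakpoints, mat = gm$breakpoints)
    }
    list(children = children,
         truth = list(father_haps = fh, mother_haps = mh,
                      father_anc = fa, mother_anc = ma,
                      child_transmissions = trans, breakpoints = bkpt,
                      child_anc = child_anc, ge_flips = flips))
  })
}

#' Inject phasing switch errors into a family's children
#'
#' Within each child, switch points fall as a Poisson process of rate
#' `pp` per bp; the two listed haplotypes are swapped on alternating
#' intervals. Site-wise genotypes (unordered allele pairs) are unchanged.
#'
#' @param children 2*nk x T allele matrix (haplotypes paired per child).
#' @param pp phasing error rate per bp.
#' @param positions SNP positions.
#' @param L region length.
#' @return list: `children` (perturbed matrix), `switch_positions` (per
#'   child), `swap` (nk x T logical: TRUE where the pair is swapped).
#' @export
inject_phasing_errors <- function(children, pp, positions, L = max(positions)) {
  if (nrow(children) %% 2 != 0) {
    stop("children matrix must pair haplotypes (even row count)")
  }
  nk <- nrow(children) %/% 2L
  T <- ncol(children)
  out <- children
  sw_pos <- vector("list", nk)
  swap <- matrix(FALSE, nk, T)
  for (k in seq_len(nk)) {
    kk <- stats::rpois(1, pp * L)
    sw <- sort(stats::runif(kk, 0, L))
    sw_pos[[k]] <- sw
    if (kk > 0) {
      sw_here <- findInterval(positions, sw) %% 2L == 1L
      swap[k, ] <- sw_here
      if (any(sw_here)) {
        h1 <- children[2 * k - 1L, ]
        h2 <- children[2 * k, ]
        out[2 * k - 1L, sw_here] <- h2[sw_here]
        out[2 * k, sw_here] <- h1[sw_here]
      }
    }
  }
  list(children = out, switch_positions = sw_pos, swap = swap)
}

#' Frequency-difference pruning
#'
#' Keeps SNP t iff `|maf_A(t) - maf_B(t)| >= df` with
#' `maf = min(f, 1 - f)`.
#'
#' @param fA,fB allele-1 frequency vectors of the two populations.
#' @param df pruning threshold.
#' @return Integer vector of kept SNP indices.
#' @export
prune_by_frequency <- function(fA, fB, df) {
  if (length(fA) != length(fB)) stop("frequency vectors differ in length")
  mafA <- pmin(fA, 1 - fA)
  mafB <- pmin(fB, 1 - fB)
  which(abs(mafA - mafB) >= df)
}

#' Simulate a complete admixed-family dataset with ground truth
#'
#' Orchestrates the whole generative protocol: ancestral panels ->
#' forward-time admixture -> families -> genotyping errors -> phasing
#' switch errors -> frequency pruning, subsetting every downstream
#' structure to the kept SNPs.
#'
#' @param params a `sim_params` object; `params$seed`, if set, seeds the RNG.
#' @return List: `families` (per family: `children` = observed 2*nk x T
#'   matrix after errors, `truth`, `switch_positions`, `swap`), `positions`
#'   (kept), `freqs` (list fA, fB on kept SNPs, empirical panel
#'   frequencies), `ref_panels` (pruned ancestral panels for LD
#'   estimation), `kept` (indices into the simulated SNP set), `params`.
#' @export
simulate_family_dataset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  panels <- simulate_ancestral_panels(params)
  admixed <- simulate_admixture(panels$A, panels$B, params)
  fams <- make_families(admixed, params)
  fA <- panel_freqs(panels$A)
  fB <- panel_freqs(panels$B)
  kept <- prune_by_frequency(fA, fB, params$df)
  if (length(kept) < 2) {
    stop("fewer than 2 SNPs survive pruning at df = ", params$df)
  }
  positions <- panels$A$positions[kept]
  fams <- lapply(fams, function(fam) {
    ph <- inject_phasing_errors(fam$children[, kept, drop = FALSE],
                                params$pp, positions, params$L)
    tr <- fam$truth
    tr$father_haps <- tr$father_haps[, kept, drop = FALSE]
    tr$mother_haps <- tr$mother_haps[, kept, drop = FALSE]
    tr$father_anc <- tr$father_anc[, kept, drop = FALSE]
    tr$mother_anc <- tr$mother_anc[, kept, drop = FALSE]
    tr$child_anc <- tr$child_anc[, kept, drop = FALSE]
    tr$ge_flips <- tr$ge_flips[, kept, drop = FALSE]
    tr$child_transmissions <- lapply(tr$child_transmissions, function(x)
      list(pat = x$pat[kept], mat = x$mat[kept]))
    list(children = ph$children, truth = tr,
         switch_positions = ph$switch_positions, swap = ph$swap)
  })
  list(families = fams, positions = positions,
       freqs = list(fA = fA[kept], fB = fB[kept]),
       ref_panels = list(A = subset_panel(panels$A, kept),
                         B = subset_panel(panels$B, kept)),
       kept = kept, params = params)
}
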
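## Stage 2: 4-bit ancestry HMM. With (Pt, Rt) fixed by stage 1, the
## hidden state is the ancestry configuration (Ctf, Ctm): one bit per
## parental haplotype (0 = population A, 1 = population B), layout
## father-hap1, father-hap2, mother-hap1, mother-hap2 (MSB first).

stage2_spec <- function() {
  bit_group_spec(c("Cf1", "Cf2", "Cm1", "Cm2"), rep(1L, 4))
}

#' Per-haplotype ancestry transition probability
#'
#' The label persists through an interval with non-recombination
#' probability S per generation, compounded over the g generations since
#' admixture; on the complementary event the destination label is drawn
#' from the admixture proportions: same label `S^g + fx_cur*(1-S^g)`,
#' different label `fx_cur*(1-S^g)`. At `fx = 0.5` this reduces to
#' `0.5 +/- 0.5*S^g`.
#'
#' @param prev_bit,cur_bit ancestry bits (0 = population A, 1 = B).
#' @param S per-generation non-recombination probability of the interval.
#' @param g generations since admixture.
#' @param fx admixture proportion of population B (A gets `1 - fx`).
#' @return Transition probability.
#' @export
stage2_transition <- function(prev_bit, cur_bit, S, g, fx = 0.5) {
  Sg <- S^g
  fx_cur <- ifelse(cur_bit == 1, fx, 1 - fx)
  ifelse(prev_bit == cur_bit, Sg + fx_cur * (1 - Sg), fx_cur * (1 - Sg))
}

stage2_factor <- function(S, g, fx) {
  matrix(c(stage2_transition(0, 0, S, g, fx), stage2_transition(1, 0, S, g, fx),
           stage2_transition(0, 1, S, g, fx), stage2_transition(1, 1, S, g, fx)),
         2, 2)
}

#' Stage-2 emission probability of one ancestry configuration
#'
#' Each observed child allele is routed by the fixed (Pt, Rt) to one
#' parental haplotype; its factor is the frequency of the observed allele
#' in the population labeling that haplotype, mixed with the genotyping
#' error rate: `f_obs*(1-ge) + (1-f_obs)*ge`.
#'
#' @param config 4 ancestry bits (father hap1, father hap2, mother hap1,
#'   mother hap2; 0 = A, 1 = B).
#' @param H observed child alleles at the site (length 2N).
#' @param routes parental-haplotype index 0..3 of each allele slot.
#' @param fA,fB allele-1 frequencies of the two populations at the site.
#' @param ge genotyping error rate.
#' @return Emission probability.
#' @export
stage2_emission <- function(config, H, routes, fA, fB, ge) {
  e <- 1
  for (k in seq_along(H)) {
    pop <- config[routes[k] + 1L]
    f1 <- if (pop == 0) fA else fB
    f_obs <- if (H[k] == 1) f1 else 1 - f1
    e <- e * (f_obs * (1 - ge) + (1 - f_obs) * ge)
  }
  e
}

#' Infer the per-site ancestry of the four parental haplotypes
#'
#' 16-state forward-backward with the per-haplotype persistence
#' transitions and frequency emissions, followed by posterior decoding
#' and the tie-trimming caller.
#'
#' @param children 2N x T observed child allele matrix.
#' @param stage1 a `stage1_result` covering the same sites.
#' @param freqs list with `fA` and `fB` allele-1 frequency vectors.
#' @param positions SNP positions (bp).
#' @param model list: `g` (generations since admixture, default 10), `fx`
#'   (admixture proportion of population B, default 0.5), `rb`
#'   (recombination rate /bp/gen, used for S = exp(-dp*rb)).
#' @param ge genotyping error rate.
#' @param map_cM optional genetic map; if given, S = exp(-dc/100).
#' @param tie_tol relative tie tolerance.
#' @return `ancestry_call`: `labels` (4 x T matrix of 0/1 = A/B; rows
#'   father-hap1, father-hap2, mother-hap1, mother-hap2), `posterior`
#'   (16 x T), `tied`, `loglik`, `proportions` (per parent, fraction of
#'   (site, haplotype) slots labeled B).
#' @export
infer_ancestry <- function(children, stage1, freqs, positions,
                           model = list(g = 10, fx = 0.5, rb = 1e-8),
                           ge = 0.001, map_cM = NULL, tie_tol = 1e-9) {
  T <- ncol(children)
  if (ncol(stage1$P) != T) stop("stage-1 result does not cover all sites")
  if (length(freqs$fA) != T || length(freqs$fB) != T) {
    miss <- which(is.na(freqs$fA) | is.na(freqs$fB))
    stop("frequency vectors must cover all ", T, " SNPs",
         if (length(miss)) paste0(" (first missing SNP index: ", miss[1], ")"))
  }
  g <- if (is.null(model$g)) 10 else model$g
  fx <- if (is.null(model$fx)) 0.5 else model$fx
  rb <- if (is.null(model$rb)) 1e-8 else model$rb
  spec <- stage2_spec()
  S_t <- if (is.null(map_cM)) exp(-diff(positions) * rb)
         else exp(-diff(map_cM) / 100)
  kernels <- lapply(S_t, function(S) {
    F <- stage2_factor(S, g, fx)
    rep(list(F), 4)
  })
  routes <- stage1_routes(stage1)
  ## per-site, per-haplotype emission contribution under each label:
  ## product over the slots routed to that haplotype
  contribA <- matrix(1, 4, T)
  contribB <- matrix(1, 4, T)
  for (k in seq_len(nrow(routes))) {
    obs <- children[k, ]
    fAo <- ifelse(obs == 1L, freqs$fA, 1 - freqs$fA)
    fBo <- ifelse(obs == 1L, freqs$fB, 1 - freqs$fB)
    eA <- fAo * (1 - ge) + (1 - fAo) * ge
    eB <- fBo * (1 - ge) + (1 - fBo) * ge
    for (h in 0:3) {
      at_h <- routes[k, ] == h
      if (any(at_h)) {
        contribA[h + 1L, at_h] <- contribA[h + 1L, at_h] * eA[at_h]
        contribB[h + 1L, at_h] <- contribB[h + 1L, at_h] * eB[at_h]
      }
    }
  }
  bits <- state_bits(4L)
  emissions <- matrix(1, 16L, T)
  for (h in 1:4) {
    isB <- bits[, h] == 1L
    emissions[isB, ] <- emissions[isB, , drop = FALSE] *
      rep(contribB[h, ], each = sum(isB))
    emissions[!isB, ] <- emissions[!isB, , drop = FALSE] *
      rep(contribA[h, ], each = sum(!isB))
  }
  fb <- forward_backward(emissions, kernels, spec)
  am <- posterior_argmax(fb, tol = tie_tol)
  cv <- call_vectors(am, K = 4L)
  labels <- t(bits[cv$called + 1L, , drop = FALSE])
  rownames(labels) <- c("father_hap1", "father_hap2",
                        "mother_hap1", "mother_hap2")
  structure(list(labels = labels, posterior = fb$posterior,
                 tied = cv$tied, loglik = fb$loglik,
                 proportions = c(father = mean(labels[1:2, ]),
                                 mother = mean(labels[3:4, ]))),
            class = "ancestry_call")
}
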
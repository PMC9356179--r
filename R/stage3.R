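## Stage 3: 4-bit parental-genotype HMM. With (Pt, Rt) and ancestry
## fixed, the hidden state is the four parental alleles (father hap1,
## father hap2, mother hap1, mother hap2). Transitions use
## within-population LD between adjacent SNPs; emissions reuse the
## stage-1 allele-matching model.

#' Estimate adjacent-SNP LD tables from reference panels
#'
#' For each population and each adjacent SNP pair, the conditional
#' probability `cond(a_t | a_{t-1})`, with pseudocount smoothing so no
#' entry is exactly 0 or 1; marginal allele frequencies are smoothed the
#' same way.
#'
#' @param ref_panels list with `A` and `B` `haplotype_panel`s on the SNP
#'   set of the analysis (each with >= 2 haplotypes).
#' @param pseudocount smoothing constant c in
#'   `(count + c) / (total + 2c)` (default 0.5).
#' @return `ld_panel`: per population, `cond` (2 x 2 x (T-1) array,
#'   `cond[a_prev+1, a_cur+1, t-1]`) and `f` (smoothed allele-1
#'   frequencies, length T).
#' @export
estimate_ld <- function(ref_panels, pseudocount = 0.5) {
  est_one <- function(panel) {
    x <- panel$alleles
    n <- nrow(x)
    if (n < 2) stop("need at least 2 reference haplotypes per population")
    T <- ncol(x)
    c0 <- pseudocount
    f <- (colSums(x) + c0) / (n + 2 * c0)
    if (T < 2) return(list(cond = array(0.5, c(2, 2, 0)), f = f))
    prev <- x[, -T, drop = FALSE]
    cur <- x[, -1, drop = FALSE]
    n11 <- colSums(prev * cur)
    n10 <- colSums(prev * (1 - cur))
    n01 <- colSums((1 - prev) * cur)
    n00 <- colSums((1 - prev) * (1 - cur))
    cond <- array(0, c(2, 2, T - 1))
    cond[1, 1, ] <- (n00 + c0) / (n00 + n01 + 2 * c0)
    cond[1, 2, ] <- (n01 + c0) / (n00 + n01 + 2 * c0)
    cond[2, 1, ] <- (n10 + c0) / (n10 + n11 + 2 * c0)
    cond[2, 2, ] <- (n11 + c0) / (n10 + n11 + 2 * c0)
    list(cond = cond, f = f)
  }
  if (!identical(ref_panels$A$positions, ref_panels$B$positions)) {
    stop("reference panels must share the analysis SNP set")
  }
  structure(list(A = est_one(ref_panels$A), B = est_one(ref_panels$B),
                 positions = ref_panels$A$positions),
            class = "ld_panel")
}

#' Per-haplotype genotype transition probability
#'
#' If the haplotype's ancestry is the same at both sites, the allele
#' follows the LD conditional of that population; if the ancestry
#' changed, the new allele is drawn from the new population's marginal
#' frequency, independent of the previous allele.
#'
#' @param prev_allele,cur_allele alleles (0/1) at sites t-1 and t.
#' @param anc_prev,anc_cur ancestry labels (0 = A, 1 = B) of the
#'   haplotype at the two sites.
#' @param ld an `ld_panel`.
#' @param t site index (>= 2) of the destination site.
#' @return Transition probability.
#' @export
stage3_transition <- function(prev_allele, cur_allele, anc_prev, anc_cur,
                              ld, t) {
  pop <- if (anc_cur == 0) ld$A else ld$B
  if (anc_prev == anc_cur) {
    pop$cond[prev_allele + 1L, cur_allele + 1L, t - 1L]
  } else {
    if (cur_allele == 1) pop$f[t] else 1 - pop$f[t]
  }
}

## 2x2 factor matrix for one haplotype bit over interval (t-1, t)
stage3_factor <- function(anc_prev, anc_cur, ld, t) {
  pop <- if (anc_cur == 0) ld$A else ld$B
  if (anc_prev == anc_cur) {
    pop$cond[, , t - 1L]
  } else {
    f <- pop$f[t]
    matrix(c(1 - f, 1 - f, f, f), 2, 2)
  }
}

#' Call the four parental alleles per site
#'
#' 16-state forward-backward: transitions multiply the four per-haplotype
#' LD factors (conditioned on the called ancestry), emissions are the
#' stage-1 allele-matching model with the routes fixed by (Pt, Rt).
#' Posterior decoding plus tie trimming fixes the alleles.
#'
#' @param children 2N x T observed child allele matrix.
#' @param stage1 a `stage1_result`.
#' @param ancestry an `ancestry_call` from [infer_ancestry()].
#' @param ld an `ld_panel` from [estimate_ld()].
#' @param ge genotyping error rate.
#' @param tie_tol relative tie tolerance.
#' @return `genotype_call`: `alleles` (4 x T; rows father-hap1,
#'   father-hap2, mother-hap1, mother-hap2), `genotypes` (2 x T unordered
#'   per-parent genotype codes 0/1/2 = count of allele 1), `posterior`
#'   (16 x T), `tied`, `loglik`.
#' @export
call_genotypes <- function(children, stage1, ancestry, ld, ge = 0.001,
                           tie_tol = 1e-9) {
  T <- ncol(children)
  if (ncol(stage1$P) != T || ncol(ancestry$labels) != T) {
    stop("stages 1-2 must cover the same sites as the children")
  }
  spec <- bit_group_spec(c("Gf1", "Gf2", "Gm1", "Gm2"), rep(1L, 4))
  lab <- ancestry$labels
  kernels <- lapply(2:T, function(t) {
    lapply(1:4, function(h) stage3_factor(lab[h, t - 1L], lab[h, t], ld, t))
  })
  routes <- stage1_routes(stage1)
  bits <- state_bits(4L)
  ## implied allele of slot k at site t is the G bit of haplotype
  ## routes[k, t]; emission shares the stage-1 matching model
  emissions <- matrix(1, 16L, T)
  for (h in 1:4) {
    hap_bit <- bits[, h]
    m1 <- hap_bit * (1 - ge) + (1 - hap_bit) * ge  # P(obs = 1 | state), length 16
    m0 <- 1 - m1
    for (k in seq_len(nrow(routes))) {
      at_h <- routes[k, ] == h - 1L
      if (!any(at_h)) next
      obs1 <- at_h & children[k, ] == 1L
      obs0 <- at_h & children[k, ] == 0L
      if (any(obs1)) emissions[, obs1] <- emissions[, obs1, drop = FALSE] * m1
      if (any(obs0)) emissions[, obs0] <- emissions[, obs0, drop = FALSE] * m0
    }
  }
  fb <- forward_backward(emissions, kernels, spec)
  am <- posterior_argmax(fb, tol = tie_tol)
  cv <- call_vectors(am, K = 4L)
  alleles <- t(bits[cv$called + 1L, , drop = FALSE])
  rownames(alleles) <- c("father_hap1", "father_hap2",
                         "mother_hap1", "mother_hap2")
  genotypes <- rbind(father = alleles[1, ] + alleles[2, ],
                     mother = alleles[3, ] + alleles[4, ])
  structure(list(alleles = alleles, genotypes = genotypes,
                 posterior = fb$posterior, tied = cv$tied,
                 loglik = fb$loglik),
            class = "genotype_call")
}
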
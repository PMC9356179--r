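## Stage 1: joint HMM over (Pt, Rt, Gt) configurations.
##
## Bit layout of a configuration (MSB first), total width 3N+4:
##   P1..PN    phasing bits: which parent child j's first-listed haplotype
##             currently descends from (0 = father, 1 = mother)
##   R1..RN    source-haplotype index (0/1) of child j's first haplotype
##             within its current parent
##   R'1..R'N  source index of child j's second haplotype within the
##             other parent
##   G1f G2f G1m G2m  the four parental alleles (nuisance group here)

stage1_spec <- function(N) {
  ## the N phasing bits share one per-bit factor and the 2N recombination
  ## bits another, so each set is contracted as one joint group (its
  ## factor is the Kronecker power of the per-bit table)
  bit_group_spec(c("P", "R", "G"), c(N, 2L * N, 4L))
}

## pairwise Hamming distances between all w-bit values
hamming_matrix <- function(w) {
  bits <- state_bits(w)
  tcrossprod(bits, 1L - bits) + tcrossprod(1L - bits, bits)
}

#' Per-bit stage-1 transition factors for one interval
#'
#' @param rates list with `rb` and `pe`.
#' @param dp physical gap (bp) of the interval.
#' @param dc optional genetic gap (cM); if given, the Haldane
#'   recombination fraction replaces `dp*rb`.
#' @return list with `P` (2 x 2 phasing-bit factor) and `T` (2 x 2
#'   recombination-bit factor).
#' @export
stage1_bit_factors <- function(rates, dp, dc = NULL) {
  pr <- if (is.null(dc)) dp * rates$rb else (1 - exp(-2 * dc / 100)) / 2
  if (pr >= 1) {
    stop("recombination fraction dp*rb >= 1 between adjacent SNPs; ",
         "check rb and the SNP spacing")
  }
  q <- min(dp * rates$pe, 1)
  stay <- max(0, 1 - dp * rates$pe)
  Pf <- matrix(c(stay, q, q, stay), 2, 2)
  Pf <- Pf / rowSums(Pf)
  list(P = Pf, T = matrix(c(1 - pr, pr, pr, 1 - pr), 2, 2))
}

#' Per-interval factor tables of the stage-1 transition kernel
#'
#' Recombination bits stay with probability `1 - dp*rb` and switch with
#' `dp*rb`; phasing bits switch with `min(dp*pe, 1)` (the switch factor is
#' clamped to 1 when the interval is long, and the stay factor floored at
#' 0); the 4-bit parental genotype group is uniform (1/16 to every value).
#' With a genetic map, `dp*rb` is replaced by the Haldane recombination
#' fraction `(1 - exp(-2*dc/100)) / 2`.
#'
#' @param rates list with `rb` (recombination rate /bp/gen), `pe` (phasing
#'   error rate /bp) and `ge` (genotyping error rate).
#' @param N number of children.
#' @param dp per-interval physical gaps (bp), length T-1.
#' @param dc optional per-interval genetic gaps (cM).
#' @return List of T-1 kernels, each a list of factor matrices matching
#'   `stage1_spec(N)`.
#' @export
build_stage1_kernel <- function(rates, N, dp, dc = NULL) {
  if (N < 1) stop("need at least one child")
  if (any(dp <= 0)) stop("physical gaps must be positive")
  Gfac <- matrix(1 / 16, 16, 16)
  HP <- hamming_matrix(N)
  HR <- hamming_matrix(2L * N)
  lapply(seq_along(dp), function(i) {
    f <- stage1_bit_factors(rates, dp[i], dc[i])
    ## Kronecker powers of the per-bit tables, in closed form from the
    ## pairwise Hamming distances of the group's bit values
    Pjoint <- f$P[1, 1]^(N - HP) * f$P[1, 2]^HP
    Rjoint <- f$T[1, 1]^(2L * N - HR) * f$T[1, 2]^HR
    list(P = Pjoint, R = Rjoint, G = Gfac)
  })
}

## Implied child alleles for every configuration: a 2^K x 2N matrix.
## Slot 2j-1 is child j's first-listed haplotype, slot 2j the second.
## Child j's first haplotype copies parent Pj's haplotype Rj; the second
## copies parent (1-Pj)'s haplotype R'j; the allele is the corresponding
## G bit (G layout: father hap1, father hap2, mother hap1, mother hap2).
stage1_implied <- function(N) {
  K <- 3L * N + 4L
  bits <- state_bits(K)
  S <- nrow(bits)
  imp <- matrix(0L, S, 2L * N)
  gcol0 <- 3L * N  # G bits occupy columns gcol0+1 .. gcol0+4
  for (j in seq_len(N)) {
    Pj <- bits[, j]
    Rj <- bits[, N + j]
    Rpj <- bits[, 2L * N + j]
    imp[, 2L * j - 1L] <- bits[cbind(seq_len(S), gcol0 + 1L + 2L * Pj + Rj)]
    imp[, 2L * j] <- bits[cbind(seq_len(S), gcol0 + 1L + 2L * (1L - Pj) + Rpj)]
  }
  imp
}

## Emission across all states at one site from an implied-allele matrix:
## product over the 2N child alleles of (1-ge) on match and ge on
## mismatch. Shared by stages 1 and 3.
emission_from_implied <- function(implied, obs, ge) {
  e <- rep(1, nrow(implied))
  for (k in seq_along(obs)) {
    e <- e * ifelse(implied[, k] == obs[k], 1 - ge, ge)
  }
  e
}

#' Stage-1 emission probability of one configuration
#'
#' The configuration's (Pt, Rt) route each of the 2N observed child
#' alleles to one of the four parental alleles in Gt; the emission is the
#' product over all 2N alleles of `1-ge` on match and `ge` on mismatch.
#'
#' @param P,R,G bit vectors of the configuration (lengths N, 2N, 4; the G
#'   order is father hap1, father hap2, mother hap1, mother hap2).
#' @param H observed child alleles at the site, length 2N
#'   (child1-hap1, child1-hap2, child2-hap1, ...).
#' @param ge genotyping error rate.
#' @return Emission probability.
#' @export
stage1_emission <- function(P, R, G, H, ge) {
  N <- length(P)
  stopifnot(length(R) == 2 * N, length(G) == 4, length(H) == 2 * N)
  e <- 1
  for (j in seq_len(N)) {
    a1 <- G[1L + 2L * P[j] + R[j]]
    a2 <- G[1L + 2L * (1L - P[j]) + R[j + N]]
    e <- e * (if (H[2 * j - 1] == a1) 1 - ge else ge)
    e <- e * (if (H[2 * j] == a2) 1 - ge else ge)
  }
  e
}

#' Infer per-site phasing and recombination vectors from child haplotypes
#'
#' Runs the factorized forward-backward over the 2^(3N+4) configuration
#' space, marginalizes the nuisance genotype group out of the posterior,
#' and fixes one (Pt, Rt) per site with the tie-trimming caller.
#'
#' @param children 2N x T matrix of observed phased child alleles (rows
#'   child1-hap1, child1-hap2, ...), or a `haplotype_panel`.
#' @param positions SNP positions (bp); ignored if `children` is a panel.
#' @param rates list with `rb`, `pe`, `ge`.
#' @param map_cM optional cumulative genetic map at the SNPs.
#' @param tie_tol relative tie tolerance for posterior argmax.
#' @return `stage1_result`: `P` (N x T called phasing bits), `R` (2N x T
#'   called recombination bits), `tied` (per-site tie flag), `posterior_pr`
#'   (2^(3N) x T marginal posterior over (P, R)), `loglik`, `N`.
#' @export
infer_stage1 <- function(children, positions = NULL, rates,
                         map_cM = NULL, tie_tol = 1e-9) {
  if (inherits(children, "haplotype_panel")) {
    positions <- children$positions
    if (is.null(map_cM)) map_cM <- children$map_cM
    children <- children$alleles
  }
  if (nrow(children) %% 2 != 0) stop("children rows must pair haplotypes")
  N <- nrow(children) %/% 2L
  T <- ncol(children)
  if (T < 2) stop("need at least 2 sites")
  spec <- stage1_spec(N)
  dp <- diff(positions)
  dc <- if (!is.null(map_cM)) diff(map_cM)
  kernels <- build_stage1_kernel(rates, N, dp, dc)
  imp <- stage1_implied(N)
  S <- nrow(imp)
  ## emission matrix: pick, per allele slot, the per-state match factor
  m1 <- (imp == 1L) * (1 - rates$ge) + (imp == 0L) * rates$ge  # P(obs=1|state)
  m0 <- 1 - m1
  emissions <- matrix(1, S, T)
  for (k in seq_len(2L * N)) {
    is1 <- children[k, ] == 1L
    if (any(is1)) emissions[, is1] <- emissions[, is1, drop = FALSE] * m1[, k]
    if (any(!is1)) emissions[, !is1] <- emissions[, !is1, drop = FALSE] * m0[, k]
  }
  fb <- forward_backward(emissions, kernels, spec)
  ## marginalize the 4 G bits (least significant -> fastest-varying index)
  n_pr <- S %/% 16L
  post_pr <- colSums(array(fb$posterior, c(16L, n_pr, T)), dims = 1)
  am <- posterior_argmax(post_pr, tol = tie_tol)
  cv <- call_vectors(am, K = 3L * N)
  bits <- state_bits(3L * N)
  called_bits <- t(bits[cv$called + 1L, , drop = FALSE])  # (3N) x T
  structure(list(P = called_bits[seq_len(N), , drop = FALSE],
                 R = called_bits[N + seq_len(2L * N), , drop = FALSE],
                 tied = cv$tied, posterior_pr = post_pr,
                 loglik = fb$loglik, N = N),
            class = "stage1_result")
}

## Map a stage-1 result to the parental-haplotype route of every child
## allele slot: a 2N x T matrix of indices 0..3 (father hap1, father hap2,
## mother hap1, mother hap2).
stage1_routes <- function(stage1) {
  N <- stage1$N
  T <- ncol(stage1$P)
  routes <- matrix(0L, 2L * N, T)
  for (j in seq_len(N)) {
    Pj <- stage1$P[j, ]
    routes[2L * j - 1L, ] <- 2L * Pj + stage1$R[j, ]
    routes[2L * j, ] <- 2L * (1L - Pj) + stage1$R[j + N, ]
  }
  routes
}
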
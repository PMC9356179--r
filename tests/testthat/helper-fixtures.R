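## Shared fixture builders. Everything is generated in code at test time.

## Random row-stochastic factor matrices for a given group layout.
random_kernel <- function(widths) {
  lapply(widths, function(w) {
    g <- 2^w
    m <- matrix(runif(g * g, 0.05, 1), g, g)
    m / rowSums(m)
  })
}

## Dense-kernel oracle: the full 2^K x 2^K transition matrix by Kronecker
## product in layout order (first group = most significant bits).
dense_oracle <- function(kernel) Reduce(kronecker, kernel)

## Exhaustive-path posterior oracle for small chains: enumerates all
## S^T hidden paths.
enumerate_posterior <- function(emissions, dense_kernels, init) {
  S <- nrow(emissions)
  T <- ncol(emissions)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), T)))
  w <- apply(paths, 1, function(p) {
    pr <- init[p[1]] * emissions[p[1], 1]
    if (T > 1) for (t in 2:T) {
      pr <- pr * dense_kernels[[t - 1]][p[t - 1], p[t]] * emissions[p[t], t]
    }
    pr
  })
  w <- w / sum(w)
  post <- matrix(0, S, T)
  for (t in seq_len(T)) {
    for (s in seq_len(S)) post[s, t] <- sum(w[paths[, t] == s])
  }
  post
}

## Hudson's two-population FST estimator (ratio of averages), computed
## directly from two allele-count panels; the independent divergence
## oracle for the ancestral-panel generator.
hudson_fst <- function(hapsA, hapsB) {
  nA <- nrow(hapsA)
  nB <- nrow(hapsB)
  fA <- colMeans(hapsA)
  fB <- colMeans(hapsB)
  num <- (fA - fB)^2 - fA * (1 - fA) / (nA - 1) - fB * (1 - fB) / (nB - 1)
  den <- fA * (1 - fB) + fB * (1 - fA)
  keep <- den > 0
  sum(num[keep]) / sum(den[keep])
}

## A small, fast family dataset for pipeline-level tests.
small_dataset <- function(seed, L = 4e6, nf = 3, nk = 3, pp = 0, df = 0.3,
                          n_snps = 2000, ...) {
  simulate_family_dataset(sim_params(L = L, nf = nf, nk = nk, pp = pp,
                                     df = df, n_snps = n_snps,
                                     seed = seed, ...))
}

## Hand-built two-parent family with fully controlled transmissions:
## father/mother haplotype pairs drawn iid Bernoulli(0.5), children
## assembled from explicit per-site source vectors (no phasing errors,
## no genotyping errors).
manual_family <- function(T = 40, N = 2, src = NULL, seed = 1,
                          spacing = 1e5) {
  set.seed(seed)
  positions <- seq(spacing, by = spacing, length.out = T)
  fh <- matrix(rbinom(2 * T, 1, 0.5), 2, T)
  mh <- matrix(rbinom(2 * T, 1, 0.5), 2, T)
  if (is.null(src)) {
    src <- replicate(N, list(pat = rep(0L, T), mat = rep(0L, T)),
                     simplify = FALSE)
  }
  children <- matrix(0L, 2 * N, T)
  for (k in seq_len(N)) {
    children[2 * k - 1, ] <- fh[cbind(src[[k]]$pat + 1L, seq_len(T))]
    children[2 * k, ] <- mh[cbind(src[[k]]$mat + 1L, seq_len(T))]
  }
  list(children = children, positions = positions, father = fh, mother = mh,
       src = src)
}
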
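#' Bit-group layout of a configuration HMM
#'
#' States of the HMMs in this package are fixed-length bit vectors
#' ("configurations"). A layout partitions the K bits into ordered named
#' groups; the first-listed group occupies the most significant bits of
#' the integer state index. State s (0-based) maps to bits via
#' `bit = floor(s / 2^(K - j)) mod 2` for bit position j = 1..K (MSB first).
#'
#' @param names character vector of unique group names.
#' @param widths integer vector of group bit-widths (>= 1).
#' @return An object of class `bit_group_spec` with fields `names`,
#'   `widths`, `offsets` (bits to the right of each group) and `K`.
#' @export
bit_group_spec <- function(names, widths) {
  widths <- as.integer(widths)
  if (length(names) != length(widths)) stop("names and widths differ in length")
  if (anyDuplicated(names)) stop("group names must be unique")
  if (any(widths < 1L)) stop("group widths must be >= 1")
  K <- sum(widths)
  offsets <- rev(cumsum(rev(widths))) - widths  # low-order bits after each group
  structure(list(names = names, widths = widths, offsets = offsets, K = K),
            class = "bit_group_spec")
}

#' Bit matrix of all states
#'
#' @param K number of bits.
#' @return 2^K x K integer matrix; row s+1 holds the bits of state s,
#'   column 1 the most significant bit.
#' @export
state_bits <- function(K) {
  S <- 2L^K
  s <- 0:(S - 1L)
  vapply(seq_len(K), function(j) as.integer((s %/% 2^(K - j)) %% 2), integer(S))
}

## Contract one bit group of a factorized kernel into a state-indexed vector.
## v is indexed by state+1; the group occupies bits with `lo` states below it
## and `hi` states above; F is the 2^w x 2^w factor (rows = previous bits,
## columns = current bits). Returns sum_prev v[prev] * F[prev_g, cur_g] with
## all other bit groups untouched.
contract_group <- function(v, lo, g, hi, F) {
  if (g == 2L) {
    ## single-bit fast path: slice the two half-planes directly
    dim(v) <- c(lo, 2L, hi)
    a0 <- v[, 1L, , drop = FALSE]
    a1 <- v[, 2L, , drop = FALSE]
    v[, 1L, ] <- a0 * F[1L, 1L] + a1 * F[2L, 1L]
    v[, 2L, ] <- a0 * F[1L, 2L] + a1 * F[2L, 2L]
    dim(v) <- NULL
    return(v)
  }
  a <- array(v, dim = c(lo, g, hi))
  a <- aperm(a, c(1L, 3L, 2L))
  m <- matrix(a, ncol = g) %*% F
  a2 <- array(m, dim = c(lo, hi, g))
  as.vector(aperm(a2, c(1L, 3L, 2L)))
}

#' Apply a factorized transition kernel to a state vector
#'
#' The full 2^K x 2^K kernel p(cur | prev) factorizes as a product over
#' bit groups of small per-group tables. This applies
#' `out[cur] = sum_prev vec[prev] * prod_b factor_b(prev_b, cur_b)` by
#' sequential partial contraction, never materializing the dense kernel.
#'
#' @param vec non-negative numeric vector of length 2^K, indexed by state.
#' @param kernel list of per-group factor matrices (2^w_b x 2^w_b, rows =
#'   previous bits, columns = current bits), in group order.
#' @param spec the `bit_group_spec` describing the layout.
#' @param transpose if TRUE, contract with the transposed kernel
#'   (`out[prev] = sum_cur vec[cur] * p(cur | prev)`), as used in the
#'   backward recursion.
#' @return Numeric vector of length 2^K.
#' @export
factorized_transform <- function(vec, kernel, spec, transpose = FALSE) {
  if (length(vec) != 2^spec$K) stop("vec length must be 2^K")
  if (any(vec < 0)) stop("factorized_transform: input vector has negative entries")
  v <- as.numeric(vec)
  for (b in seq_along(spec$widths)) {
    g <- 2L^spec$widths[b]
    lo <- 2L^spec$offsets[b]
    hi <- length(v) %/% (g * lo)
    F <- kernel[[b]]
    if (transpose) F <- t(F)
    v <- contract_group(v, lo, g, hi, F)
  }
  v
}

#' Assemble the dense transition matrix of a factorized kernel
#'
#' Intended for small K only (testing and cross-checks): the Kronecker
#' product of the group factors in layout order.
#'
#' @inheritParams factorized_transform
#' @return 2^K x 2^K matrix with rows = previous state, columns = current.
#' @export
dense_kernel <- function(kernel, spec) {
  Reduce(kronecker, kernel)
}

#' Scaled forward-backward over a factorized-kernel HMM
#'
#' Standard forward-backward with per-site renormalization; posteriors are
#' `posterior_t proportional to alpha_t * beta_t` and the total
#' log-likelihood is the sum of the log scaling factors.
#'
#' @param emissions 2^K x T matrix of per-site emission probabilities.
#' @param kernels either a single kernel (list of group factor matrices,
#'   reused for every interval) or a list of T-1 kernels, one per adjacent
#'   site pair.
#' @param spec the `bit_group_spec`.
#' @param init initial distribution over states at site 1 (defaults to
#'   uniform); must sum to 1.
#' @return A list of class `posterior_result`: `posterior` (2^K x T, each
#'   column summing to 1), `loglik`, `scales`.
#' @export
forward_backward <- function(emissions, kernels, spec, init = NULL) {
  emissions <- as.matrix(emissions)
  S <- 2L^spec$K
  T <- ncol(emissions)
  if (nrow(emissions) != S) stop("emissions must have 2^K rows")
  if (T < 1L) stop("need at least one site")
  if (is.null(init)) init <- rep(1 / S, S)
  if (abs(sum(init) - 1) > 1e-8) stop("init must sum to 1")
  zero_sites <- which(colSums(emissions) == 0)
  if (length(zero_sites)) {
    stop("all-zero emission vector at site ", zero_sites[1],
         ": no configuration is consistent with the data there")
  }
  ## a kernel schedule is a list of kernels, one per interval; a single
  ## kernel (list of matrices) is broadcast to every interval
  per_interval <- is.list(kernels[[1]])
  if (per_interval && length(kernels) != T - 1L) {
    stop("kernel schedule must have T-1 entries")
  }
  kern_at <- function(i) if (per_interval) kernels[[i]] else kernels

  alpha <- matrix(0, S, T)
  scales <- numeric(T)
  a <- init * emissions[, 1]
  scales[1] <- sum(a)
  alpha[, 1] <- a / scales[1]
  if (T > 1L) {
    for (t in 2:T) {
      a <- factorized_transform(alpha[, t - 1L], kern_at(t - 1L), spec) *
        emissions[, t]
      st <- sum(a)
      if (!is.finite(st) || st <= 0) {
        stop("forward recursion degenerated at site ", t)
      }
      scales[t] <- st
      alpha[, t] <- a / st
    }
  }
  posterior <- matrix(0, S, T)
  b <- rep(1, S)
  p <- alpha[, T] * b
  posterior[, T] <- p / sum(p)
  if (T > 1L) {
    for (t in (T - 1L):1L) {
      b <- factorized_transform(emissions[, t + 1L] * b, kern_at(t), spec,
                                transpose = TRUE)
      b <- b / sum(b)
      p <- alpha[, t] * b
      posterior[, t] <- p / sum(p)
    }
  }
  structure(list(posterior = posterior, loglik = sum(log(scales)),
                 scales = scales),
            class = "posterior_result")
}

#' Per-site argmax state sets of a posterior
#'
#' Returns, for each site, all states whose posterior is within a relative
#' tolerance of the site maximum. Exact model symmetries (e.g. parental
#' haplotype relabelings) produce floating-point ties that must be kept.
#'
#' @param posterior matrix of per-site posterior probabilities (states in
#'   rows) or a `posterior_result`.
#' @param tol relative tie tolerance (default 1e-9).
#' @return List (one element per site) of 0-based state indices, ascending.
#' @export
posterior_argmax <- function(posterior, tol = 1e-9) {
  if (inherits(posterior, "posterior_result")) posterior <- posterior$posterior
  lapply(seq_len(ncol(posterior)), function(t) {
    p <- posterior[, t]
    m <- max(p)
    which(p >= m * (1 - tol)) - 1L
  })
}
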
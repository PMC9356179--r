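#' Fix one configuration per site from posterior argmax sets (tie trimming)
#'
#' Posterior decoding can leave several configurations tied at a site
#' (exact model symmetries guarantee it whenever the initial distribution
#' is uniform). This caller fixes one vector per site: sites with a
#' singleton argmax are anchors; scanning forward from each anchor, a tied
#' site takes the argmax member equal to the previously chosen vector,
#' or failing that the member at minimum Hamming distance from it (ties
#' broken by smallest state index). The prefix before the first anchor is
#' resolved by the same rule scanning backward from it. If no site is
#' anchored, the smallest-index argmax at site 1 seeds a forward scan.
#'
#' @param argmax_sets list (one per site) of 0-based tied state indices.
#' @param K bit-width of the states (for Hamming distances).
#' @return list with `called` (0-based state per site) and `tied`
#'   (logical, TRUE where the argmax set had more than one member).
#' @export
call_vectors <- function(argmax_sets, K) {
  T <- length(argmax_sets)
  if (T == 0L) stop("empty argmax set list")
  if (any(vapply(argmax_sets, length, 1L) == 0L)) {
    stop("argmax sets must be non-empty")
  }
  bits <- state_bits(K)
  hamming <- function(a, b) sum(bits[a + 1L, ] != bits[b + 1L, ])
  pick <- function(set, ref) {
    if (ref %in% set) return(ref)
    d <- vapply(set, hamming, 1L, b = ref)
    set[which.min(d)]  # which.min takes the first minimum; sets are ascending
  }
  tied <- vapply(argmax_sets, length, 1L) > 1L
  called <- integer(T)
  anchors <- which(!tied)
  if (length(anchors) == 0L) {
    called[1] <- argmax_sets[[1]][1]
    if (T > 1L) for (t in 2:T) called[t] <- pick(argmax_sets[[t]], called[t - 1L])
    return(list(called = called, tied = tied))
  }
  f1 <- anchors[1]
  called[f1] <- argmax_sets[[f1]][1]
  if (f1 > 1L) {
    for (t in (f1 - 1L):1L) called[t] <- pick(argmax_sets[[t]], called[t + 1L])
  }
  if (f1 < T) {
    for (t in (f1 + 1L):T) {
      if (!tied[t]) {
        called[t] <- argmax_sets[[t]][1]
      } else {
        called[t] <- pick(argmax_sets[[t]], called[t - 1L])
      }
    }
  }
  list(called = called, tied = tied)
}
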
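#' Construct a phased haplotype panel
#'
#' The universal carrier for phased biallelic SNP data in this package:
#' children's haplotypes, parental truth haplotypes, and per-population
#' reference panels are all `haplotype_panel` objects. Alleles are coded
#' 0/1, one row per haplotype, one column per SNP.
#'
#' @param alleles integer or logical matrix of 0/1 alleles,
#'   haplotypes in rows, SNPs in columns.
#' @param positions strictly increasing 1-based physical positions (bp),
#'   one per SNP column.
#' @param map_cM optional non-decreasing cumulative genetic map (cM),
#'   same length as `positions`.
#' @param pop_label optional per-haplotype population tag (one per row).
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, positions, map_cM = NULL, pop_label = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (!all(alleles %in% c(0L, 1L))) {
    stop("alleles must be a 0/1 matrix")
  }
  positions <- as.numeric(positions)
  if (ncol(alleles) != length(positions)) {
    stop("number of SNP columns (", ncol(alleles),
         ") does not match length of positions (", length(positions), ")")
  }
  if (length(positions) > 1 && any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing")
  }
  if (!is.null(map_cM)) {
    map_cM <- as.numeric(map_cM)
    if (length(map_cM) != length(positions)) {
      stop("map_cM must have one entry per SNP")
    }
    if (length(map_cM) > 1 && any(diff(map_cM) < 0)) {
      stop("map_cM must be non-decreasing")
    }
  }
  if (!is.null(pop_label) && length(pop_label) != nrow(alleles)) {
    stop("pop_label must have one entry per haplotype row")
  }
  structure(
    list(alleles = alleles, positions = positions,
         map_cM = map_cM, pop_label = pop_label),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", nrow(x$alleles), "haplotypes x",
      ncol(x$alleles), "SNPs\n")
  cat("  positions:", format(min(x$positions), big.mark = ","), "-",
      format(max(x$positions), big.mark = ","), "bp\n")
  if (!is.null(x$map_cM)) cat("  genetic map: present\n")
  if (!is.null(x$pop_label)) {
    cat("  populations:",
        paste(names(table(x$pop_label)), table(x$pop_label),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset a haplotype panel by SNP index
#'
#' @param panel a `haplotype_panel`.
#' @param snp_idx integer vector of SNP column indices to keep (in order).
#' @return A `haplotype_panel` over the selected SNPs.
#' @export
subset_panel <- function(panel, snp_idx) {
  haplotype_panel(panel$alleles[, snp_idx, drop = FALSE],
                  panel$positions[snp_idx],
                  map_cM = if (!is.null(panel$map_cM)) panel$map_cM[snp_idx],
                  pop_label = panel$pop_label)
}

#' Per-SNP allele-1 frequencies of a panel
#'
#' @param panel a `haplotype_panel`.
#' @return Numeric vector of allele-1 frequencies, one per SNP.
#' @export
panel_freqs <- function(panel) {
  colMeans(panel$alleles)
}
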
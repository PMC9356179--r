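## Readers and writers for the standard formats the tool touches.
## Coordinates are 1-based bp in all files and 0-based indices internally.

meta_header <- function(seed = NULL, config = NULL) {
  ver <- as.character(utils::packageVersion("parmixr"))
  hash <- if (is.null(config)) "none" else {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    saveRDS(config, tmp)
    unname(tools::md5sum(tmp))
  }
  sprintf("##parmixr=%s;config_md5=%s;seed=%s", ver, hash,
          if (is.null(seed)) "NA" else seed)
}

#' Read a phased VCF into a haplotype panel
#'
#' Biallelic SNPs only; multi-allelic records are skipped with a message.
#' All analyzed genotypes must be phased (`|`); any unphased record is a
#' hard error naming the position and sample.
#'
#' @param path path to an (uncompressed or gzipped) VCF.
#' @return A `haplotype_panel` with two haplotype rows per sample, in the
#'   file's sample order (rows sample1-hap1, sample1-hap2, sample2-hap1,
#'   ...).
#' @export
read_phased_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    message("skipping ", sum(multi), " multi-allelic record(s)")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- matrix(gt, nrow = nrow(fix), dimnames = dimnames(gt))
  keep <- !multi
  gt <- gt[keep, , drop = FALSE]
  pos <- as.numeric(fix[keep, "POS"])
  bad_gt <- !grepl("|", gt, fixed = TRUE)
  dim(bad_gt) <- dim(gt)
  unphased <- which(bad_gt, arr.ind = TRUE)
  if (nrow(unphased)) {
    bad <- unphased[1, ]
    stop("unphased genotype(s): first at position ", pos[bad[1]],
         ", sample ", colnames(gt)[bad[2]],
         " (", nrow(unphased), " record(s) total)")
  }
  samples <- colnames(gt)
  n <- length(samples)
  alleles <- matrix(0L, 2L * n, nrow(gt))
  for (s in seq_len(n)) {
    parts <- strsplit(gt[, s], "|", fixed = TRUE)
    alleles[2L * s - 1L, ] <- as.integer(vapply(parts, `[`, "", 1L))
    alleles[2L * s, ] <- as.integer(vapply(parts, `[`, "", 2L))
  }
  panel <- haplotype_panel(alleles, pos)
  attr(panel, "samples") <- samples
  panel
}

#' Write a haplotype panel as a phased VCF
#'
#' @param panel a `haplotype_panel` with an even number of haplotype rows
#'   (pairs of consecutive rows form a sample).
#' @param path output path (plain text).
#' @param sample_names optional sample names (default sample1, ...).
#' @param chrom chromosome name for the CHROM column.
#' @param seed,config recorded in the provenance header line.
#' @export
write_phased_vcf <- function(panel, path, sample_names = NULL, chrom = "1",
                             seed = NULL, config = NULL) {
  if (nrow(panel$alleles) %% 2 != 0) stop("panel rows must pair into samples")
  n <- nrow(panel$alleles) %/% 2L
  if (is.null(sample_names)) sample_names <- paste0("sample", seq_len(n))
  T <- ncol(panel$alleles)
  gt <- vapply(seq_len(n), function(s) {
    paste0(panel$alleles[2L * s - 1L, ], "|", panel$alleles[2L * s, ])
  }, character(T))
  gt <- matrix(gt, nrow = T)
  body <- paste(chrom, format(panel$positions, scientific = FALSE,
                              trim = TRUE),
                paste0("snp", seq_len(T)), "A", "T", ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c("##fileformat=VCFv4.2",
               meta_header(seed, config),
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      paste(sample_names, collapse = "\t")),
               body), path)
  invisible(path)
}

#' Write population allele frequencies as TSV
#'
#' Columns: chrom, pos, f_A, f_B.
#' @param positions SNP positions.
#' @param fA,fB allele-1 frequencies.
#' @param path output path.
#' @param chrom chromosome name.
#' @param seed,config recorded in the provenance header.
#' @export
write_freqs <- function(positions, fA, fB, path, chrom = "1",
                        seed = NULL, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(seed, config), con)
  writeLines("chrom\tpos\tf_A\tf_B", con)
  writeLines(paste(chrom, format(positions, scientific = FALSE, trim = TRUE),
                   fA, fB, sep = "\t"), con)
  invisible(path)
}

#' Read allele frequencies and an optional genetic map
#'
#' The frequency TSV has columns (chrom, pos, f_A, f_B); comment lines
#' starting with `#` are skipped. The map follows the PLINK dialect
#' (chrom, id, cM, bp; or 3 columns without cM). Frequencies are
#' harmonized to `target_pos`; a target SNP missing from the table is a
#' hard error. Map cM values are linearly interpolated to the target
#' positions.
#'
#' @param freq_path path to the frequency TSV.
#' @param map_path optional path to a PLINK-style map.
#' @param target_pos positions of the analyzed SNPs.
#' @return List: `fA`, `fB`, `dp` (bp gaps, length T-1), `dc` (cM gaps or
#'   NULL), `map_cM` (cumulative cM at the targets, or NULL).
#' @export
read_freqs_and_map <- function(freq_path, map_path = NULL, target_pos) {
  tab <- utils::read.table(freq_path, header = TRUE, sep = "\t",
                           comment.char = "#")
  idx <- match(target_pos, tab$pos)
  if (anyNA(idx)) {
    stop("SNP(s) missing from the frequency table: first at position ",
         target_pos[which(is.na(idx))[1]])
  }
  out <- list(fA = tab$f_A[idx], fB = tab$f_B[idx],
              dp = diff(target_pos), dc = NULL, map_cM = NULL)
  if (!is.null(map_path)) {
    map <- utils::read.table(map_path, header = FALSE)
    if (ncol(map) >= 4) {
      cm <- as.numeric(map[[3]])
      bp <- as.numeric(map[[4]])
    } else {
      stop("map file lacks a cM column (PLINK 4-column dialect expected)")
    }
    rng <- range(bp)
    if (min(target_pos) < rng[1] || max(target_pos) > rng[2]) {
      warning("target positions outside the map range; extrapolating ",
              "with the flanking cM values")
    }
    cm_at <- stats::approx(bp, cm, xout = target_pos, rule = 2,
                           ties = "ordered")$y
    out$map_cM <- cm_at
    out$dc <- diff(cm_at)
  }
  out
}

#' Write per-site stage-1 calls as TSV
#' @param stage1 a `stage1_result`.
#' @param positions SNP positions.
#' @param path output path.
#' @param seed,config provenance header fields.
#' @export
write_stage1_tsv <- function(stage1, positions, path,
                             seed = NULL, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(seed, config), con)
  writeLines("site\tpos\tP\tR\ttied", con)
  writeLines(paste(seq_along(positions),
                   format(positions, scientific = FALSE, trim = TRUE),
                   apply(stage1$P, 2, paste, collapse = ""),
                   apply(stage1$R, 2, paste, collapse = ""),
                   as.integer(stage1$tied), sep = "\t"), con)
  invisible(path)
}

#' Write per-site ancestry calls as TSV and segments as BED
#' @param ancestry an `ancestry_call`.
#' @param positions SNP positions.
#' @param tsv_path,bed_path output paths (either may be NULL).
#' @param chrom chromosome name for the BED.
#' @param seed,config provenance header fields.
#' @export
write_ancestry_out <- function(ancestry, positions, tsv_path = NULL,
                               bed_path = NULL, chrom = "1",
                               seed = NULL, config = NULL) {
  lab <- ancestry$labels
  pmax4 <- apply(ancestry$posterior, 2, max)
  if (!is.null(tsv_path)) {
    con <- file(tsv_path, "w")
    writeLines(meta_header(seed, config), con)
    writeLines("pos\tfather_hap1\tfather_hap2\tmother_hap1\tmother_hap2\tposterior_max", con)
    writeLines(paste(format(positions, scientific = FALSE, trim = TRUE),
                     lab[1, ], lab[2, ], lab[3, ], lab[4, ],
                     signif(pmax4, 6), sep = "\t"), con)
    close(con)
  }
  if (!is.null(bed_path)) {
    rows <- character(0)
    for (h in 1:4) {
      r <- rle(lab[h, ])
      ends <- cumsum(r$lengths)
      starts <- c(1L, utils::head(ends, -1) + 1L)
      ## half-open bp intervals [start, end): BED is 0-based half-open
      rows <- c(rows, paste(chrom, positions[starts] - 1,
                            positions[ends],
                            paste0(rownames(lab)[h], ":",
                                   ifelse(r$values == 0, "A", "B")),
                            sep = "\t"))
    }
    writeLines(c(meta_header(seed, config), rows), bed_path)
  }
  invisible(NULL)
}

#' Write parental genotype calls as TSV
#' @param genotype a `genotype_call`.
#' @param positions SNP positions.
#' @param path output path.
#' @param seed,config provenance header fields.
#' @export
write_genotype_tsv <- function(genotype, positions, path,
                               seed = NULL, config = NULL) {
  al <- genotype$alleles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(seed, config), con)
  writeLines("pos\tfather_hap1\tfather_hap2\tmother_hap1\tmother_hap2\tposterior_max", con)
  writeLines(paste(format(positions, scientific = FALSE, trim = TRUE),
                   al[1, ], al[2, ], al[3, ], al[4, ],
                   signif(apply(genotype$posterior, 2, max), 6),
                   sep = "\t"), con)
  invisible(path)
}
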
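#' Three-stage parental inference on in-memory data
#'
#' Runs the full procedure: (1) infer per-child phasing and recombination
#' vectors, (2) infer the four parental haplotype ancestries, (3) call
#' the four parental alleles with LD-aware transitions.
#'
#' @param children 2N x T phased child allele matrix (rows child1-hap1,
#'   child1-hap2, ...) or a `haplotype_panel`.
#' @param positions SNP positions (bp).
#' @param freqs list with `fA`, `fB` population allele-1 frequencies.
#' @param ref_panels list with `A`, `B` reference `haplotype_panel`s for
#'   LD estimation (same SNP set).
#' @param rates list `rb`, `pe`, `ge`.
#' @param model stage-2 settings: `g`, `fx` (`rb` is taken from `rates`).
#' @param map_cM optional cumulative genetic map.
#' @param max_states cap on the stage-1 configuration count 2^(3N+4);
#'   families above it are refused (default 2^17, i.e. N <= 4).
#' @return List with `stage1`, `ancestry`, `genotype`, and
#'   `proportions` (per-parent admixture proportions).
#' @export
parmix_infer <- function(children, positions = NULL, freqs, ref_panels = NULL,
                         rates = list(rb = 1e-8, pe = 2e-6, ge = 0.001),
                         model = list(g = 10, fx = 0.5), map_cM = NULL,
                         max_states = 2^17) {
  if (inherits(children, "haplotype_panel")) {
    positions <- children$positions
    if (is.null(map_cM)) map_cM <- children$map_cM
    children <- children$alleles
  }
  N <- nrow(children) %/% 2L
  n_states <- 2^(3 * N + 4)
  if (n_states > max_states) {
    stop("a family of N = ", N, " children needs 2^(3N+4) = ", n_states,
         " configurations per site, above the supported budget of ",
         max_states, "; the state space is too large to enumerate")
  }
  model$rb <- rates$rb
  s1 <- infer_stage1(children, positions, rates, map_cM = map_cM)
  anc <- infer_ancestry(children, s1, freqs, positions, model = model,
                        ge = rates$ge, map_cM = map_cM)
  gen <- NULL
  if (!is.null(ref_panels)) {
    ld <- estimate_ld(ref_panels)
    gen <- call_genotypes(children, s1, anc, ld, ge = rates$ge)
  }
  list(stage1 = s1, ancestry = anc, genotype = gen,
       proportions = admixture_proportion(anc))
}

#' File-based end-to-end pipeline
#'
#' Reads the children VCF, frequency table, optional map and LD reference
#' VCFs, runs [parmix_infer()], and writes the stage outputs (stage-1
#' TSV, ancestry TSV/BED, genotype TSV) plus a summary JSON to `out_dir`.
#' All outputs carry a provenance header (version, config hash, seed) and
#' a rerun with an identical config is byte-identical.
#'
#' @param config list: `children_vcf`, `freq_tsv`, `out_dir`, optional
#'   `map_file`, `ref_vcf_A`, `ref_vcf_B`, `rates` (rb, pe, ge), `model`
#'   (g, fx), `seed`, `max_states`.
#' @return Invisibly, the in-memory results from [parmix_infer()].
#' @export
run_pipeline <- function(config) {
  for (f in c("children_vcf", "freq_tsv", "out_dir")) {
    if (is.null(config[[f]])) stop("config lacks required field ", f)
  }
  children <- read_phased_vcf(config$children_vcf)
  fm <- read_freqs_and_map(config$freq_tsv, config$map_file,
                           children$positions)
  ref <- NULL
  if (!is.null(config$ref_vcf_A) && !is.null(config$ref_vcf_B)) {
    ref <- list(A = read_phased_vcf(config$ref_vcf_A),
                B = read_phased_vcf(config$ref_vcf_B))
    for (p in c("A", "B")) {
      if (!identical(ref[[p]]$positions, children$positions)) {
        stop("reference panel ", p, " SNP set differs from the children's")
      }
    }
  }
  rates <- if (is.null(config$rates)) {
    list(rb = 1e-8, pe = 2e-6, ge = 0.001)
  } else config$rates
  model <- if (is.null(config$model)) list(g = 10, fx = 0.5) else config$model
  res <- parmix_infer(children$alleles, children$positions,
                      freqs = list(fA = fm$fA, fB = fm$fB),
                      ref_panels = ref, rates = rates, model = model,
                      map_cM = fm$map_cM,
                      max_states = if (is.null(config$max_states)) 2^17
                                   else config$max_states)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sd <- config$seed
  write_stage1_tsv(res$stage1, children$positions,
                   file.path(config$out_dir, "stage1.tsv"), sd, config)
  write_ancestry_out(res$ancestry, children$positions,
                     file.path(config$out_dir, "ancestry.tsv"),
                     file.path(config$out_dir, "ancestry_segments.bed"),
                     seed = sd, config = config)
  if (!is.null(res$genotype)) {
    write_genotype_tsv(res$genotype, children$positions,
                       file.path(config$out_dir, "genotypes.tsv"), sd, config)
  }
  summ <- list(n_children = res$stage1$N,
               n_snps = length(children$positions),
               loglik = list(stage1 = res$stage1$loglik,
                             ancestry = res$ancestry$loglik,
                             genotype = if (!is.null(res$genotype))
                               res$genotype$loglik),
               admixture_proportions = as.data.frame(res$proportions))
  jsonlite::write_json(summ, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Write a simulated dataset to a directory
#'
#' Children and reference panels as phased VCF, frequencies as TSV, and
#' truth tracks (per-site ancestry TSV, switch positions) per family.
#'
#' @param dataset from [simulate_family_dataset()].
#' @param out_dir output directory.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sd <- dataset$params$seed
  pos <- dataset$positions
  write_freqs(pos, dataset$freqs$fA, dataset$freqs$fB,
              file.path(out_dir, "freqs.tsv"), seed = sd)
  write_phased_vcf(dataset$ref_panels$A, file.path(out_dir, "ref_A.vcf"),
                   seed = sd)
  write_phased_vcf(dataset$ref_panels$B, file.path(out_dir, "ref_B.vcf"),
                   seed = sd)
  for (i in seq_along(dataset$families)) {
    fam <- dataset$families[[i]]
    fd <- file.path(out_dir, sprintf("family%02d", i))
    dir.create(fd, showWarnings = FALSE)
    write_phased_vcf(haplotype_panel(fam$children, pos),
                     file.path(fd, "children.vcf"),
                     sample_names = paste0("child", seq_len(nrow(fam$children) / 2)),
                     seed = sd)
    tr <- fam$truth
    con <- file(file.path(fd, "truth_ancestry.tsv"), "w")
    writeLines(meta_header(sd), con)
    writeLines("pos\tfather_hap1\tfather_hap2\tmother_hap1\tmother_hap2", con)
    writeLines(paste(format(pos, scientific = FALSE, trim = TRUE),
                     tr$father_anc[1, ], tr$father_anc[2, ],
                     tr$mother_anc[1, ], tr$mother_anc[2, ], sep = "\t"), con)
    close(con)
    write_phased_vcf(haplotype_panel(rbind(tr$father_haps, tr$mother_haps),
                                     pos),
                     file.path(fd, "truth_parents.vcf"),
                     sample_names = c("father", "mother"), seed = sd)
    sw <- unlist(lapply(seq_along(fam$switch_positions), function(k) {
      sp <- fam$switch_positions[[k]]
      if (length(sp)) paste(k, format(sp, scientific = FALSE, trim = TRUE),
                            sep = "\t")
    }))
    writeLines(c(meta_header(sd), "child\tswitch_pos", sw),
               file.path(fd, "truth_switches.tsv"))
  }
  invisible(out_dir)
}
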
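## Evaluation protocol: best-match accuracy over the 8 parental
## relabelings, the single-site baseline, admixture proportions, and the
## simulate -> infer -> score experiment driver.

## The 8 candidate pairings: swap the two inferred parents (2) x flip the
## haplotype order within each inferred parent (2 x 2). Each row gives
## the permutation of the inferred rows (father_hap1, father_hap2,
## mother_hap1, mother_hap2) laid against the truth rows.
match_up_perms <- function() {
  perms <- list()
  for (swap in 0:1) for (flip1 in 0:1) for (flip2 in 0:1) {
    f <- if (flip1) c(2L, 1L) else c(1L, 2L)
    m <- if (flip2) c(4L, 3L) else c(3L, 4L)
    perm <- if (swap) c(m, f) else c(f, m)
    perms[[length(perms) + 1L]] <- perm
  }
  perms
}

#' Best-match accuracy of inferred parents against simulated truth
#'
#' The model cannot identify which inferred parent is which, nor the
#' haplotype order within a parent, so accuracy is maximized over the 8
#' relabelings (parent swap x within-parent flips). One pairing is chosen
#' by the total (ancestry + genotype) score and applied to both.
#'
#' Ancestry accuracy is the fraction of (site, parental haplotype) slots
#' with the correct population label; genotype accuracy the fraction of
#' (site, parent) slots with the correct unordered genotype.
#'
#' @param inf_anc 4 x T inferred ancestry labels (rows father-hap1,
#'   father-hap2, mother-hap1, mother-hap2); may be NULL.
#' @param inf_geno 4 x T inferred parental alleles (same row order); may
#'   be NULL.
#' @param true_anc,true_geno the matching truth matrices.
#' @return List: `ancestry`, `genotype` (accuracies under the chosen
#'   pairing), `pairing` (the row permutation applied to the inferred
#'   matrices).
#' @export
best_match_accuracy <- function(inf_anc, inf_geno, true_anc, true_geno) {
  ref <- if (!is.null(inf_anc)) inf_anc else inf_geno
  tref <- if (!is.null(true_anc)) true_anc else true_geno
  if (is.null(ref) || is.null(tref)) stop("nothing to score")
  if (ncol(ref) != ncol(tref)) stop("inferred and truth cover different SNP sets")
  best <- list(total = -Inf)
  for (perm in match_up_perms()) {
    a_acc <- if (!is.null(inf_anc)) {
      mean(inf_anc[perm, , drop = FALSE] == true_anc)
    }
    g_acc <- if (!is.null(inf_geno)) {
      gi <- inf_geno[perm, , drop = FALSE]
      mean(c(gi[1, ] + gi[2, ] == true_geno[1, ] + true_geno[2, ],
             gi[3, ] + gi[4, ] == true_geno[3, ] + true_geno[4, ]))
    }
    total <- sum(c(a_acc, g_acc))
    if (total > best$total) {
      best <- list(ancestry = a_acc, genotype = g_acc,
                   pairing = perm, total = total)
    }
  }
  best$total <- NULL
  best
}

#' Single-site baseline caller
#'
#' Per site, independently: if all child alleles are 0 (resp. 1) both
#' parents are called homozygous 00 (resp. 11); if both alleles occur,
#' both parents are called heterozygous, deterministically ordered 01.
#' The ancestry of each called allele is the population in which that
#' allele is more frequent (ties go to A).
#'
#' @param children 2N x T observed child allele matrix.
#' @param fA,fB population allele-1 frequencies.
#' @return List with `alleles` and `ancestry` 4 x T matrices in the
#'   standard parental-haplotype row order (both parents identical).
#' @export
single_site_baseline <- function(children, fA, fB) {
  T <- ncol(children)
  n1 <- colSums(children == 1L)
  hap1 <- ifelse(n1 == nrow(children), 1L, 0L)           # 0 unless all-1
  hap2 <- ifelse(n1 == 0L, 0L, 1L)                       # 1 unless all-0
  alleles <- rbind(hap1, hap2, hap1, hap2)
  anc_of <- function(a) ifelse(a == 1L, (fB > fA) * 1L, (1 - fB > 1 - fA) * 1L)
  ancestry <- rbind(anc_of(hap1), anc_of(hap2), anc_of(hap1), anc_of(hap2))
  rn <- c("father_hap1", "father_hap2", "mother_hap1", "mother_hap2")
  rownames(alleles) <- rn
  rownames(ancestry) <- rn
  list(alleles = alleles, ancestry = ancestry)
}

#' Admixture proportions from an ancestry call
#'
#' Per parent, the fraction of (site, haplotype) slots labeled
#' population B (population A is the complement). Sites are unweighted.
#'
#' @param labels 4 x T ancestry label matrix (or an `ancestry_call`).
#' @return Matrix with rows father/mother and columns A/B.
#' @export
admixture_proportion <- function(labels) {
  if (inherits(labels, "ancestry_call")) labels <- labels$labels
  pB <- c(father = mean(labels[1:2, ]), mother = mean(labels[3:4, ]))
  cbind(A = 1 - pB, B = pB)
}

#' Run the full pipeline on one simulated family
#'
#' Convenience wrapper used by the experiment driver and the tests:
#' stages 1-3 with the dataset's own frequencies and reference panels.
#'
#' @param fam one element of `simulate_family_dataset()$families`.
#' @param dataset the full dataset object (for positions, freqs, panels).
#' @param rates inference rates (default: the generative rates).
#' @param model stage-2 model settings.
#' @return List with `stage1`, `ancestry`, `genotype`, and `accuracy`
#'   (best-match scores against the family truth).
#' @export
infer_family <- function(fam, dataset,
                         rates = NULL, model = NULL) {
  par <- dataset$params
  if (is.null(rates)) {
    rates <- list(rb = par$rho, pe = par$pp, ge = par$ge)
  }
  if (is.null(model)) {
    model <- list(g = par$g, fx = 0.5, rb = rates$rb)
  }
  s1 <- infer_stage1(fam$children, dataset$positions, rates)
  anc <- infer_ancestry(fam$children, s1, dataset$freqs, dataset$positions,
                        model = model, ge = rates$ge)
  ld <- estimate_ld(dataset$ref_panels)
  gen <- call_genotypes(fam$children, s1, anc, ld, ge = rates$ge)
  true_anc <- rbind(fam$truth$father_anc, fam$truth$mother_anc)
  true_hap <- rbind(fam$truth$father_haps, fam$truth$mother_haps)
  acc <- best_match_accuracy(anc$labels, gen$alleles, true_anc, true_hap)
  list(stage1 = s1, ancestry = anc, genotype = gen, accuracy = acc)
}

#' Simulate -> infer -> score over a parameter grid
#'
#' For each grid row and each replicate seed, simulates a dataset, runs
#' the three-stage pipeline on every family, scores best-match accuracy
#' against the truth, and (optionally) scores the single-site baseline on
#' the same data.
#'
#' @param grid data.frame whose columns override `sim_params()` fields
#'   (e.g. `df`, `nk`, `pp`, `L`).
#' @param base_seed integer; replicate r uses seed `base_seed + r - 1`
#'   in every grid row, so rows are compared on matched seeds.
#' @param reps replicates per grid row (default 20).
#' @param baseline also score the single-site baseline (default FALSE).
#' @param ... further fixed overrides passed to `sim_params()`.
#' @return data.frame: one row per (grid row, replicate) with mean
#'   per-family accuracies, SNP counts and, if requested, baseline
#'   accuracies.
#' @export
run_experiment <- function(grid, base_seed = 1L, reps = 20L,
                           baseline = FALSE, ...) {
  fixed <- list(...)
  out <- list()
  for (i in seq_len(nrow(grid))) {
    for (r in seq_len(reps)) {
      seed <- base_seed + r - 1L
      args <- c(as.list(grid[i, , drop = FALSE]), fixed,
                list(seed = seed))
      params <- do.call(sim_params, args)
      ds <- simulate_family_dataset(params)
      acc_a <- acc_g <- base_a <- base_g <- numeric(0)
      for (fam in ds$families) {
        res <- infer_family(fam, ds)
        acc_a <- c(acc_a, res$accuracy$ancestry)
        acc_g <- c(acc_g, res$accuracy$genotype)
        if (baseline) {
          bl <- single_site_baseline(fam$children, ds$freqs$fA, ds$freqs$fB)
          true_anc <- rbind(fam$truth$father_anc, fam$truth$mother_anc)
          true_hap <- rbind(fam$truth$father_haps, fam$truth$mother_haps)
          bacc <- best_match_accuracy(bl$ancestry, bl$alleles,
                                      true_anc, true_hap)
          base_a <- c(base_a, bacc$ancestry)
          base_g <- c(base_g, bacc$genotype)
        }
      }
      row <- data.frame(grid[i, , drop = FALSE], seed = seed,
                        snps = length(ds$positions),
                        ancestry_acc = mean(acc_a),
                        genotype_acc = mean(acc_g),
                        accuracy = mean(c(acc_a, acc_g)))
      if (baseline) {
        row$baseline_ancestry_acc <- mean(base_a)
        row$baseline_genotype_acc <- mean(base_g)
        row$baseline_accuracy <- mean(c(base_a, base_g))
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}
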
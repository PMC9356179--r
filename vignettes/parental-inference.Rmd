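---
title: "Painting the parents: local ancestry and genotypes from children's haplotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Painting the parents: local ancestry and genotypes from children's haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parmixr)
```

## The problem

A child inherits one recombined haplotype from each parent, so the
phased genotypes of even a single child carry half of each parent's
genome — scrambled by meiosis and, in practice, further scrambled by
phasing switch errors introduced when the child's genotypes were
computationally phased. When the parents are admixed (their chromosomes
are mosaics of segments from two ancestral populations, say A and B),
two questions arise that ordinary chromosome painting of the child
cannot answer: *which population does each segment of each parental
haplotype come from*, and *what were the parental genotypes*? parmixr
answers both from the phased haplotypes of a small number (1–3+) of
full siblings, plus standard population-genetic inputs: per-SNP allele
frequencies of the two ancestral populations, the physical (and
optionally genetic) distance between SNPs, and a phased reference panel
per population for linkage disequilibrium.

A single joint model over recombination, phasing errors, ancestry and
genotypes is possible in principle but unwieldy; the state space
explodes and the weakly informed dimensions degrade the strongly
informed ones. parmixr therefore factors the inference into three HMMs
run in sequence, each conditioning on the fixed output of the previous
one:

1. **Phasing and recombination** (`infer_stage1()`): from children's
   haplotypes alone, infer for every SNP which parent each listed child
   haplotype currently descends from (the *phasing vector* $P_t$, one
   bit per child) and which haplotype *within* that parent it copies
   (the *recombination vector* $R_t$, two bits per child).
2. **Ancestry** (`infer_ancestry()`): with $(P_t, R_t)$ fixed, infer
   the population label of each of the four parental haplotypes (the
   *ancestry vector* $C_t$, four bits).
3. **Genotypes** (`call_genotypes()`): with routes and ancestry fixed,
   call the four parental alleles per site (the *genotype vector*
   $G_t$, four bits), using within-population LD between adjacent SNPs.

The data have the most to say about where recombination and phasing
switches happen — apparent "switches" between sibling haplotype
patterns are directly visible at heterozygous parental sites — which is
why that is inferred first.

## Configurations and the factorized kernel

All three models share one mechanical core (`forward_backward()`).
States are fixed-length bit vectors ("configurations"); stage 1 uses
$3N+4$ bits for $N$ children (phasing, recombination, plus a 4-bit
parental-genotype nuisance group), stages 2 and 3 use 4 bits. For
$N=3$ the stage-1 space has $2^{13} = 8192$ configurations per site and
$2^{26}$ site-to-site transitions, far too many to enumerate as a dense
kernel at every interval.

The saving structure is that the transition probability factorizes over
bit groups:

$$p(AC_t \mid AC_{t-1}) \;=\; G^f \cdot G^m \cdot \prod_{j=1}^{N} P_j
\cdot \prod_{j=1}^{N} T_j^f \cdot \prod_{j=1}^{N} T_j^m$$

with each factor depending only on its own bits at the two sites. The
engine never materializes the $2^K \times 2^K$ kernel; it applies each
group's small table as a partial tensor contraction of the state
vector, at cost $O(K \cdot 2^K)$ per transform instead of $O(4^K)$.
Tests verify the contraction against an explicitly assembled dense
kernel for every layout up to $K = 10$, and forward–backward posteriors
against exhaustive path enumeration on short chains.

Per-interval factors, for physical gap $d_p$ bp:

* recombination bit: switch with probability $d_p \cdot r_b$, stay with
  $1 - d_p r_b$ ($r_b$ = recombination rate per bp per generation; a
  gap with $d_p r_b \ge 1$ is rejected as a parameter error). With a
  genetic map, the Haldane recombination fraction
  $(1 - e^{-2 d_c/100})/2$ replaces $d_p r_b$.
* phasing bit: switch with $\min(d_p \cdot p_e, 1)$. The phasing error
  rate $p_e$ can be orders of magnitude above $r_b$, so on long gaps
  the product exceeds 1; the switch factor is clamped to 1 as the model
  prescribes, and we additionally floor the stay factor at 0 and
  renormalize the row (the clamp's complement is otherwise negative —
  the stay-floor is our choice and is flagged as such).
* genotype group (stage 1 only): uniform, $1/16$ to every value. The
  parental genotypes are a nuisance dimension here, marginalized out of
  the posterior before decoding; stage 3 is where genotypes are called.

Emissions compare the $2N$ observed child alleles with the alleles
implied by the configuration (each child allele is routed by
$(P_t, R_t)$ to one of the four parental alleles), multiplying
$1 - g_e$ per match and $g_e$ per mismatch, where $g_e$ is the
genotyping error rate. The same emission code path serves stages 1 and
3; stage 2 replaces the allele comparison with the observed allele's
frequency in the population labeling the routed haplotype, mixed with
$g_e$.

Forward–backward uses per-site renormalization of $\alpha$ and
$\beta$ with stored scale factors; the log-likelihood is the sum of the
log scales, and chains of $10^5$ sites with emissions near $10^{-12}$
decode without underflow. Posterior matrices are stored densely: at the
supported family sizes ($N \le 4$, capped by a configurable state
budget of $2^{17}$ configurations) and realistic chain lengths this is
tens of megabytes. Requests beyond the cap — say $N = 10$, which would
need $2^{34}$ configurations — are refused with an explanatory error.

## Tie trimming (vector calling)

Posterior decoding picks an argmax configuration per site, but exact
model symmetries guarantee ties: with a uniform initial distribution,
swapping the two haplotype labels within a parent (complementing the
corresponding $R_t$ bits) leaves every likelihood unchanged, so for
example $R_t = (0,1,0)$ and $(1,0,1)$ tie exactly in a three-child
model without phasing errors. Ties are detected at a *relative*
tolerance of $10^{-9}$ — wide enough to absorb the $\sim 10^{-13}$
floating-point asymmetries that different summation orders introduce
along a chain, narrow enough never to merge genuinely distinct
posterior values.

The caller (`call_vectors()`) fixes one configuration per site: sites
with a singleton argmax anchor the chain; from each anchor it scans
forward, keeping the previous site's vector wherever it remains among
the ties, otherwise taking the tied member at minimum Hamming distance
(smallest state index on a further tie); the prefix before the first
anchor is resolved by the same rule scanning backward. When no site is
anchored — the usual situation in stage 1, where the within-parent
relabeling symmetry ties *every* site — the smallest-index argmax at
the first site seeds the forward scan. This resolves each unidentifiable
gauge once, globally, instead of letting it flip mid-chromosome; the
evaluation protocol (below) then scores calls up to that gauge.

## The ancestry and genotype models

**Ancestry transitions.** Each parental haplotype's label persists
through an interval with per-generation non-recombination probability
$S$, compounded over the $g$ generations since admixture:

$$p(C_t \mid C_{t-1}) = \begin{cases}
  S^g + f_x (1 - S^g) & C_t = C_{t-1} \\
  f_x (1 - S^g) & C_t \ne C_{t-1}
\end{cases}$$

where $f_x$ is the admixture proportion of the destination population
(0.5 by default, i.e. unknown). At $f_x = 0.5$ this is exactly
$0.5 \pm 0.5\,S^g$. We take $S = e^{-d_p r_b}$, the Poisson
no-crossover probability of the interval (or $e^{-d_c/100}$ from a cM
map — $d_c/100$ Morgans being the expected crossover count); this is
the standard ancestry-HMM form, exposed as a configurable hook since
other decay choices are defensible. The full 16-state kernel is the
product of the four per-haplotype bits; $g$ defaults to 10 generations.

**Genotype transitions.** Where a haplotype's ancestry is the same at
adjacent kept SNPs, its allele follows the conditional
$\mathrm{cond}(a_t \mid a_{t-1})$ of that population, estimated from
the reference panel with pseudocount $c = 0.5$
(`estimate_ld()`; smoothing keeps every transition strictly positive so
no valid path is annihilated). Where the ancestry changes, the new
allele is drawn from the new population's marginal frequency,
independent of $a_{t-1}$ — taken literally from the model definition.

**What LD buys, and when.** The frequency-only alternative (conditional
tables replaced by marginals) coincides with the LD model wherever a
haplotype is either well covered by transmitted data (the data decide)
or untransmitted across the whole region (both reduce to the marginal
prior). LD earns its keep on *partially* covered haplotypes: an
anchored segment propagates through the conditional chain into the
adjacent uncovered region, to a horizon set by the LD decay across the
kept-SNP spacing. The test suite demonstrates the domination in exactly
that regime (a half-transmitted haplotype against a two-lineage
reference panel). After aggressive frequency pruning the kept-SNP
spacing can exceed the LD horizon, and the gain over frequency-only
calling becomes small — consistent with observing that less trimming
favors genotype accuracy.

## The simulator

`simulate_family_dataset()` generates the study conditions end to end,
with complete ground truth (parental haplotypes, per-site ancestry,
per-child transmission vectors, crossover breakpoints, injected switch
positions):

1. **Ancestral panels.** Per-SNP ancestral frequencies follow a
   neutral-SFS-like $1/p$ density truncated to $[1/n_h, 1 - 1/n_h]$;
   the two population frequencies are Balding–Nichols draws
   $\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ with
   $F = 1 - e^{-t_{split}}$ ($t_{split} = 0.125$ coalescent units
   $\Rightarrow F \approx 0.1175$, verified in tests by Hudson's FST
   estimator on the emitted panels). Haplotypes carry first-order
   Markov LD via a latent-uniform copying chain whose correlation
   decays as $e^{-\rho_{ld}\,\Delta bp}$; $\rho_{ld} = 3\times10^{-5}$
   per bp by default, putting the correlation half-distance near 20 kb,
   a realistic scale for common variants. This frequency-model backend
   is fully self-contained; marginals are exact Bernoulli draws at the
   population frequencies.
2. **Admixture.** The two panels merge 50/50 into an admixed
   Wright–Fisher population of `n_admix` diploids (default
   $\min(N_e, n_h/2)$ — enough to supply the $4 n_f$ founder haplotypes
   without simulating all $10^4$ diploids; a full-$N_e$ mode is a
   parameter away) evolving $g$ generations of random mating with
   Poisson recombination (no crossover interference) and full ancestry
   tracking. The emitted mean ancestry-segment count matches the
   junction-accumulation expectation $1 + g \rho L / 2$ within 15% in
   tests.
3. **Families.** $4 n_f$ haplotypes are drawn without replacement and
   paired into $n_f$ couples; one further generation of meiosis yields
   $n_k$ children each. Genotyping errors flip child alleles
   independently at rate $g_e$ (default $10^{-3}$; the error model is
   part of inference, and its simulation value is our choice as none is
   prescribed). Phasing switch errors arrive per child as a Poisson
   process of rate $p_p$ per bp, swapping the two listed haplotypes on
   alternating intervals — site-wise genotypes are provably unchanged.
4. **Pruning.** SNPs with minor-allele-frequency difference
   $|maf_A - maf_B| < d_f$ are removed (read literally as *minor*-allele
   frequencies), and children, truth tracks, frequencies and reference
   panels are subset consistently.

Default parameters are the study conditions: $n_h = 400$ haplotypes,
$N_e = 10^4$, $L = 2.59\times10^8$ bp (human chromosome 1),
$\rho = 10^{-8}$, $t_{split} = 0.125$, $g = 10$, $n_f = 10$ families,
$n_k = 3$ children, $d_f = 0.1$, $p_p = 2\times10^{-6}$. The SNP count
defaults to $5\times10^{-4}$ per bp (the segregating-site density
observed at whole-chromosome scale, $\sim 1.3\times10^5$ SNPs for
chromosome 1).

**What the simulator does not emulate:** coalescent gene genealogies
(LD is first-order Markov, not genealogical), recombination hotspots
(constant $\rho$ unless a map is supplied), multi-chromosome linkage,
selection, migration, or non-constant $N_e$. Passing tests on these
data therefore show that the inference machinery recovers the truth of
a faithful generative model of the *assumed* process; they cannot
certify performance on real cohorts, where map misspecification and
structured phasing errors matter — the misspecification experiments
(`run_experiment()` with inference rates decoupled from generative
ones) are the tool for probing that gap.

## Evaluation protocol

Nothing in the data distinguishes "father" from "mother", nor hap 1
from hap 2 within a parent. `best_match_accuracy()` therefore scores
all 8 relabelings (parent swap × within-parent flips), choosing one
pairing by the total ancestry + genotype score and applying it to both
— a single physical correspondence exists, so the two scores must share
it. Ancestry accuracy is the fraction of (site, parental haplotype)
slots labeled correctly; genotype accuracy the fraction of
(site, parent) slots with the correct unordered genotype (the
granularity is not dictated by the model; haplotype-resolved alleles
are also emitted for evaluators that want ordered scoring).
`single_site_baseline()` implements the per-site comparator (all-0
children $\to$ 00, all-1 $\to$ 11, mixed $\to$ heterozygous — resolved
deterministically as 01, immaterial under unordered scoring; ancestry
by the higher-frequency population) and `admixture_proportion()`
reduces an ancestry call to per-parent proportions (unweighted site
average; an exact identity with the mean of the two haplotype
indicator tracks).

## Validation scales and expectations

The packaged validation runs the full pipeline on a $2\times10^7$ bp
region (about 1/13 of chromosome 1) at trimming threshold 0.3 — roughly
400 kept SNPs and 15–25 s per seed — with 10 families per seed and
10–20 seeds per condition. At this scale, with three children and no
phasing errors, mean best-match accuracy sits in the low 90s
(ancestry ≈ 94–95%, genotypes ≈ 90–92%); injecting phasing errors at
$2\times10^{-6}$ per bp costs roughly 15 points; a single child yields
roughly 75%. Two size-dependent effects make the scaled runs slightly
conservative relative to whole-chromosome runs: with only
$\rho L \approx 0.2$ crossovers per gamete, an entire parental
haplotype is untransmitted to all children noticeably often (each such
haplotype is unidentifiable and scores at chance), and short chains
give the ancestry HMM fewer informative transitions per segment.

## Known limitations

* State count grows as $2^{3N+4}$: four children is the practical
  ceiling of this exact formulation; larger sibships need a different
  inference strategy.
* Two ancestral populations only; the bit-group layout extends to
  $M > 2$ (wider per-haplotype groups) but this is not implemented.
* Ancestry deeper than the parents (grandparental painting) is out of
  scope.
* Phasing-error *correction* is not performed; haplotypes are taken as
  given and the error rate `pe` models residual switches. Accuracy is
  sensitive to misspecified `pe`, so match it to the phasing tool that
  produced the input.
* An untransmitted parental haplotype is unidentifiable from data;
  its calls revert to the prior (and its posterior maxima stay
  visibly below 1 — the output worth checking before trusting a call).
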
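Package: parmixr
Title: Joint Inference of Parental Local Ancestry and Genotypes from
    Children's Phased Haplotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the local ancestry (chromosome painting) and the
    genotypes of two parents from the phased biallelic SNP haplotypes of a
    small number of their full-sib children. The method runs three
    hidden Markov models over bit-vector configurations in sequence:
    first the per-child phasing and recombination vectors, then the
    per-parental-haplotype ancestry labels, then the parental alleles
    using within-population linkage disequilibrium. A factorized
    transition kernel keeps forward-backward tractable over the
    2^(3N+4) configuration space. Includes a two-population
    Wright-Fisher admixture simulator with full ground truth, a
    single-site baseline, and a best-match evaluation protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
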
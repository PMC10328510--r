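Package: chromsim
Title: Chromosome-Scale Coalescent Simulation from a Citable Species Catalog
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Population-genomic simulation at chromosome scale driven by a
    species catalog with per-chromosome mutation and recombination rates,
    provenance citations, and piecewise-constant demographic models with
    per-model mutation-rate overrides. The structured-coalescent engine
    supports crossover recombination under a rate map, eukaryotic gene
    conversion and bacterial non-crossover homologous recombination with
    geometric tract lengths, and discrete-site Jukes-Cantor mutation
    permitting recurrent and multi-allelic variation. Includes summary
    statistics (nucleotide diversity, Watterson's theta, site frequency
    spectrum), a quality-control procedure that compares independently
    specified demographic models, readers for chrom.sizes/.fai and
    HapMap-style genetic maps, and VCF/Newick writers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
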
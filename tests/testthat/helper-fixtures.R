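# Fixtures are built in code: a minimal valid species, and small fixed
# genealogies with known branch masses for mutation/stats oracles.

toySpecies <- function() {
  Species("ToySpe", "Toyus specificus",
    chromosomes = list(
      Chromosome("chr1", length = 1e6, mutationRate = 1e-8,
                 recombinationRate = 1e-8, gcFraction = 0.5,
                 gcLength = 100),
      Chromosome("chrM", length = 2e4, mutationRate = 1e-8,
                 recombinationRate = 0)),
    generationTime = 1, defaultNe = 1e4, ploidy = 2L,
    citations = list(
      Citation("fixture", 2026L, reasons = c(
        "assembly", "mutation_rate", "recombination_rate",
        "gene_conversion", "population_size", "generation_time"))))
}

testContig <- function(L = 1e4, r = 0, mu = 1e-8, gc = FALSE,
                       gcFraction = 0.5, gcLength = 100) {
  makeContig(toySpecies(), "chr1", lengthOverride = L,
             mutationRateOverride = mu, recombinationRateOverride = r,
             geneConversion = gc, gcFractionOverride = gcFraction,
             gcLengthOverride = gcLength)
}

# 4 samples, one tree over [0, 100):
#   ((s0:10,s1:10)n4:10,s2:20)n5:10,s3:30)n6   (caterpillar, TMRCA 30)
# total branch length 90 generations, genomic mass 90 * 100 = 9000 bp*gen
toyGenealogy <- function() {
  nodes <- data.frame(id = 0:6, time = c(0, 0, 0, 0, 10, 20, 30),
                      population = "pop0", stringsAsFactors = FALSE)
  edges <- data.frame(parent = c(4, 4, 5, 5, 6, 6),
                      child = c(0, 1, 4, 2, 5, 3),
                      left = 0, right = 100)
  new("Genealogy", nodes = nodes, edges = edges, samples = 0:3,
      sampleNames = paste0("s", 0:3), contigLength = 100)
}

# 2 samples, single tree of height tmrca over [0, L)
pairGenealogy <- function(tmrca = 50, L = 100) {
  nodes <- data.frame(id = 0:2, time = c(0, 0, tmrca),
                      population = "pop0", stringsAsFactors = FALSE)
  edges <- data.frame(parent = c(2, 2), child = c(0, 1), left = 0,
                      right = L)
  new("Genealogy", nodes = nodes, edges = edges, samples = 0:1,
      sampleNames = c("s0", "s1"), contigLength = L)
}

emptyLogWith <- function(...) {
  log <- new("EventLog",
             counts = c(coalescence = 0, migration = 0, crossover_drawn = 0,
                        crossover_effective = 0, gc_drawn = 0,
                        gc_effective = 0),
             records = data.frame(time = numeric(), type = character()),
             tractLengths = numeric())
  over <- c(...)
  log@counts[names(over)] <- over
  log
}
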
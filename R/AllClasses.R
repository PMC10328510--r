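#' @useDynLib chromsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

.CITE_REASONS <- c("assembly", "mutation_rate", "recombination_rate",
                   "gene_conversion", "demographic_model", "generation_time",
                   "population_size")

#' Citation with provenance tags
#'
#' Records where a catalog parameter comes from. Every numeric parameter in a
#' species entry should be reachable through at least one citation carrying
#' the matching reason tag, so that values can be traced back to published
#' estimates.
#'
#' @slot authors character, author string of the source.
#' @slot year integer publication year (> 1900).
#' @slot doi character, DOI or URL of the source.
#' @slot reasons character vector of tags drawn from
#'   \code{assembly, mutation_rate, recombination_rate, gene_conversion,
#'   demographic_model, generation_time, population_size}.
#' @exportClass Citation
setClass("Citation",
  slots = c(authors = "character", year = "integer", doi = "character",
            reasons = "character"))

setValidity("Citation", function(object) {
  msg <- character()
  if (length(object@reasons) < 1L)
    msg <- c(msg, "citation must carry at least one reason tag")
  bad <- setdiff(object@reasons, .CITE_REASONS)
  if (length(bad))
    msg <- c(msg, paste0("unknown reason tag(s): ", paste(bad, collapse = ", ")))
  if (length(object@year) != 1L || is.na(object@year) || object@year <= 1900L)
    msg <- c(msg, "citation year must be a single integer > 1900")
  if (length(msg)) msg else TRUE
})

#' Citation constructor
#' @param authors author string.
#' @param year publication year.
#' @param doi DOI or URL.
#' @param reasons character vector of reason tags.
#' @return A \linkS4class{Citation}.
#' @export
Citation <- function(authors, year, doi = NA_character_, reasons) {
  new("Citation", authors = as.character(authors), year = as.integer(year),
      doi = as.character(doi), reasons = as.character(reasons))
}

#' Per-chromosome parameters
#'
#' A chromosome in a species catalog entry. Lengths and rates that are not
#' backed by a published value are stored as \code{NA} ("unknown, supply at
#' simulation time"); validity checks apply only to non-missing values.
#' For bacterial/archaeal entries \code{nonCrossoverOnly = TRUE} and
#' \code{recombinationRate} is interpreted as the initiation rate of a
#' non-crossover (gene-conversion-like) tract, with mean tract length
#' \code{gcLength}.
#'
#' @slot id character chromosome name.
#' @slot length numeric length in bp (NA if unknown).
#' @slot mutationRate numeric, mutations per bp per generation.
#' @slot recombinationRate numeric, crossovers (or, for non-crossover-only
#'   chromosomes, tract initiations) per bp per generation.
#' @slot gcFraction numeric in [0,1): fraction of recombination events that
#'   are gene conversions (NA = gene conversion not parameterized).
#' @slot gcLength numeric mean gene-conversion tract length in bp.
#' @slot nonCrossoverOnly logical, bacterial-style recombination without
#'   crossovers.
#' @exportClass Chromosome
setClass("Chromosome",
  slots = c(id = "character", length = "numeric", mutationRate = "numeric",
            recombinationRate = "numeric", gcFraction = "numeric",
            gcLength = "numeric", nonCrossoverOnly = "logical"))

#' Chromosome constructor
#' @param id chromosome name.
#' @param length length in bp, NA if unknown.
#' @param mutationRate mutations per bp per generation, NA if unknown.
#' @param recombinationRate crossovers per bp per generation (tract
#'   initiations per bp per generation when \code{nonCrossoverOnly}).
#' @param gcFraction gene-conversion fraction in [0,1), NA if absent.
#' @param gcLength mean tract length (bp), NA if absent.
#' @param nonCrossoverOnly logical.
#' @return A \linkS4class{Chromosome}.
#' @export
Chromosome <- function(id, length = NA_real_, mutationRate = NA_real_,
                       recombinationRate = NA_real_, gcFraction = NA_real_,
                       gcLength = NA_real_, nonCrossoverOnly = FALSE) {
  new("Chromosome", id = as.character(id), length = as.numeric(length),
      mutationRate = as.numeric(mutationRate),
      recombinationRate = as.numeric(recombinationRate),
      gcFraction = as.numeric(gcFraction), gcLength = as.numeric(gcLength),
      nonCrossoverOnly = isTRUE(nonCrossoverOnly))
}

#' A species catalog entry
#'
#' Genome structure (chromosomes with per-chromosome rates), default effective
#' population size, generation time, ploidy and the citations backing every
#' parameter.
#'
#' @slot id character 6-letter species code (e.g. "AnoGam").
#' @slot name character scientific name.
#' @slot chromosomes list of \linkS4class{Chromosome}.
#' @slot generationTime numeric, years per generation.
#' @slot defaultNe numeric, default effective population size.
#' @slot ploidy integer (1 or 2).
#' @slot citations list of \linkS4class{Citation}.
#' @exportClass Species
setClass("Species",
  slots = c(id = "character", name = "character", chromosomes = "list",
            generationTime = "numeric", defaultNe = "numeric",
            ploidy = "integer", citations = "list"))

#' Species constructor
#' @param id species code.
#' @param name scientific name.
#' @param chromosomes list of \linkS4class{Chromosome}.
#' @param generationTime years per generation (NA if unknown).
#' @param defaultNe default effective population size (NA if unknown).
#' @param ploidy 1 or 2.
#' @param citations list of \linkS4class{Citation}.
#' @return A \linkS4class{Species}.
#' @export
Species <- function(id, name, chromosomes, generationTime = NA_real_,
                    defaultNe = NA_real_, ploidy = 2L, citations = list()) {
  new("Species", id = as.character(id), name = as.character(name),
      chromosomes = chromosomes, generationTime = as.numeric(generationTime),
      defaultNe = as.numeric(defaultNe), ploidy = as.integer(ploidy),
      citations = citations)
}

#' A species catalog
#'
#' Named collection of \linkS4class{Species}, keyed by species id.
#'
#' @slot species named list of \linkS4class{Species}.
#' @slot schemaVersion integer schema version of the serialized form.
#' @exportClass Catalog
setClass("Catalog",
  slots = c(species = "list", schemaVersion = "integer"))

setValidity("Catalog", function(object) {
  ids <- vapply(object@species, function(s) s@id, character(1))
  if (length(ids) && any(duplicated(ids)))
    return(paste0("duplicate species id: ",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (!identical(unname(names(object@species)), unname(ids)) &&
      length(ids) > 0 && !is.null(names(object@species)))
    return("catalog list names must equal species ids")
  TRUE
})

#' Genomic rate map
#'
#' Piecewise-constant per-bp per-generation rates over half-open intervals
#' \code{[breakpoints[i], breakpoints[i+1])}. Breakpoints start at 0 and end
#' at the contig length.
#'
#' @slot breakpoints numeric ascending positions (bp), first 0.
#' @slot rates numeric per-bp per-generation rates, one per interval.
#' @exportClass RateMap
setClass("RateMap", slots = c(breakpoints = "numeric", rates = "numeric"))

setValidity("RateMap", function(object) {
  b <- object@breakpoints; r <- object@rates
  msg <- character()
  if (length(b) < 2L) msg <- c(msg, "need at least two breakpoints")
  if (length(r) != length(b) - 1L)
    msg <- c(msg, "length(rates) must be length(breakpoints) - 1")
  if (length(b) >= 2L) {
    if (b[1] != 0) msg <- c(msg, "first breakpoint must be 0")
    if (any(diff(b) <= 0)) msg <- c(msg, "breakpoints must be strictly ascending")
  }
  if (any(r < 0)) msg <- c(msg, "rates must be non-negative")
  if (length(msg)) msg else TRUE
})

#' RateMap constructor
#' @param breakpoints ascending positions starting at 0, ending at the
#'   sequence length.
#' @param rates one rate per interval.
#' @return A \linkS4class{RateMap}.
#' @export
RateMap <- function(breakpoints, rates) {
  new("RateMap", breakpoints = as.numeric(breakpoints),
      rates = as.numeric(rates))
}

#' Uniform rate map
#' @param rate per-bp per-generation rate.
#' @param length sequence length in bp.
#' @return A \linkS4class{RateMap} with a single interval.
#' @export
uniformRateMap <- function(rate, length) RateMap(c(0, length), rate)

#' A simulation-ready contig
#'
#' One genomic interval cut from a catalog chromosome: length, mutation rate,
#' crossover rate map, gene-conversion parameters and ploidy. Rates are
#' inherited from the source chromosome unless explicitly overridden in
#' \code{\link{makeContig}}.
#'
#' @slot speciesId character.
#' @slot chromosomeId character.
#' @slot length numeric bp.
#' @slot mutationRate numeric per bp per generation (NA = must be supplied
#'   by a demographic-model override).
#' @slot rateMap \linkS4class{RateMap} of crossover rates (all zero for
#'   non-recombining or non-crossover-only contigs).
#' @slot gcFraction numeric in [0,1) or NA.
#' @slot gcLength numeric mean tract length (bp) or NA.
#' @slot nonCrossoverOnly logical; if TRUE, \code{gcInitRate} carries the
#'   tract-initiation rate.
#' @slot gcInitRate numeric per-bp tract-initiation rate used in
#'   non-crossover-only mode (0 otherwise; the eukaryotic gene-conversion
#'   initiation rate is derived from \code{gcFraction} at simulation time).
#' @slot ploidy integer.
#' @exportClass Contig
setClass("Contig",
  slots = c(speciesId = "character", chromosomeId = "character",
            length = "numeric", mutationRate = "numeric", rateMap = "RateMap",
            gcFraction = "numeric", gcLength = "numeric",
            nonCrossoverOnly = "logical", gcInitRate = "numeric",
            ploidy = "integer"))

#' Piecewise-constant demographic model
#'
#' Named populations with initial (present-day) sizes, an ordered event list
#' (instantaneous size changes, pastward splits, migration-rate changes), an
#' optional per-model mutation-rate override, and citations. Time is measured
#' in generations before the present (0 = sampling time), increasing into the
#' past.
#'
#' @slot id character model id.
#' @slot populations character vector of population names.
#' @slot initialSizes named numeric, size of each population at time 0.
#' @slot initialMigration numeric matrix, \code{[i, j]} the per-generation
#'   probability that a lineage in population i migrates (pastward) to j.
#' @slot events data.frame with columns \code{time}, \code{type} (one of
#'   \code{size_change}, \code{split}, \code{migration_change}), \code{pop},
#'   \code{pop2}, \code{value}. For a split, \code{pop} is the derived and
#'   \code{pop2} the ancestral population.
#' @slot mutationRateOverride numeric or NA; supersedes the contig mutation
#'   rate so simulations match the rate the model was inferred under.
#' @slot citations list of \linkS4class{Citation}.
#' @exportClass DemographicModel
setClass("DemographicModel",
  slots = c(id = "character", populations = "character",
            initialSizes = "numeric", initialMigration = "matrix",
            events = "data.frame", mutationRateOverride = "numeric",
            citations = "list"))

#' An ancestry (genealogy) over a contig
#'
#' Node and edge tables encoding all marginal trees, in the tabular style
#' common to coalescent simulators: nodes carry times (generations before
#' present), edges carry a parent, a child and the half-open genomic interval
#' \code{[left, right)} over which the parent-child relation holds. Node ids
#' are 0-based; samples are nodes \code{0..n-1} at time 0 and coordinates are
#' 0-based half-open.
#'
#' @slot nodes data.frame with columns \code{id}, \code{time},
#'   \code{population}.
#' @slot edges data.frame with columns \code{parent}, \code{child},
#'   \code{left}, \code{right}.
#' @slot samples integer vector of sample node ids.
#' @slot sampleNames character vector (defaults \code{s0, s1, ...}).
#' @slot contigLength numeric bp.
#' @exportClass Genealogy
setClass("Genealogy",
  slots = c(nodes = "data.frame", edges = "data.frame", samples = "integer",
            sampleNames = "character", contigLength = "numeric"))

setValidity("Genealogy", function(object) {
  msg <- character()
  e <- object@edges; nd <- object@nodes
  if (nrow(e)) {
    tm <- nd$time[match(e$parent, nd$id)] - nd$time[match(e$child, nd$id)]
    if (any(is.na(tm)) || any(tm <= 0))
      msg <- c(msg, "every edge must have parent time > child time")
    if (any(e$left >= e$right))
      msg <- c(msg, "edge intervals must be non-empty half-open [left, right)")
  }
  if (length(msg)) msg else TRUE
})

#' Event log of an ancestry simulation
#'
#' Counts and timestamped records of coalescence, migration, crossover and
#' non-crossover (gene conversion) events, distinguishing drawn events from
#' those that actually split or merged ancestral material, plus the sampled
#' gene-conversion tract lengths. Supports audits such as checking the drawn
#' gene-conversion:crossover ratio against its configured value.
#'
#' @slot counts named numeric with entries \code{coalescence},
#'   \code{migration}, \code{crossover_drawn}, \code{crossover_effective},
#'   \code{gc_drawn}, \code{gc_effective}.
#' @slot records data.frame with columns \code{time}, \code{type}.
#' @slot tractLengths numeric vector of sampled tract lengths (bp).
#' @exportClass EventLog
setClass("EventLog",
  slots = c(counts = "numeric", records = "data.frame",
            tractLengths = "numeric"))

setValidity("EventLog", function(object) {
  cn <- object@counts
  need <- c("coalescence", "migration", "crossover_drawn",
            "crossover_effective", "gc_drawn", "gc_effective")
  if (!all(need %in% names(cn)))
    return("counts must carry all standard event-count names")
  if (cn[["crossover_effective"]] > cn[["crossover_drawn"]] ||
      cn[["gc_effective"]] > cn[["gc_drawn"]])
    return("effective counts cannot exceed drawn counts")
  TRUE
})

#' Result of an ancestry simulation
#'
#' Bundles the \linkS4class{Genealogy} and its \linkS4class{EventLog};
#' access them with \code{\link{genealogy}} and \code{\link{eventLog}}.
#'
#' @slot genealogy \linkS4class{Genealogy}.
#' @slot eventLog \linkS4class{EventLog}.
#' @exportClass AncestrySimulation
setClass("AncestrySimulation",
  slots = c(genealogy = "Genealogy", eventLog = "EventLog"))

#' Discrete-site variant table
#'
#' Sites (integer positions with ancestral states), the mutations placed on
#' genealogy edges (with derived states and times), and the resulting
#' haplotype matrix. Because mutation is discrete-site, a site may carry
#' several mutations and segregate more than two alleles.
#'
#' @slot sites data.frame with columns \code{position} (0-based bp) and
#'   \code{ancestral}.
#' @slot mutations data.frame with columns \code{site} (1-based index into
#'   sites), \code{parent}, \code{child} (edge), \code{derived}, \code{time}.
#' @slot haplotypes character matrix, samples x sites.
#' @slot contigLength numeric bp.
#' @slot sampleNames character.
#' @exportClass VariantTable
setClass("VariantTable",
  slots = c(sites = "data.frame", mutations = "data.frame",
            haplotypes = "matrix", contigLength = "numeric",
            sampleNames = "character"))

#' Summary statistics of a sample of haplotypes
#'
#' @slot S integer number of segregating (polymorphic) sites.
#' @slot pi numeric mean pairwise diversity per bp.
#' @slot thetaW numeric Watterson estimator per bp.
#' @slot sfs numeric site-frequency spectrum (per derived allele, classes
#'   1..n-1; or folded classes if requested).
#' @slot folded logical.
#' @exportClass SummaryStats
setClass("SummaryStats",
  slots = c(S = "integer", pi = "numeric", thetaW = "numeric",
            sfs = "numeric", folded = "logical"))

#' Model-comparison discrepancy report
#'
#' Output of \code{\link{compareModels}}: one entry per differing field,
#' located by a dot-separated machine-parsable path.
#'
#' @slot entries data.frame with columns \code{path}, \code{value_a},
#'   \code{value_b}, \code{relative_difference}.
#' @slot passed logical; TRUE iff entries is empty.
#' @exportClass DiscrepancyReport
setClass("DiscrepancyReport",
  slots = c(entries = "data.frame", passed = "logical"))

setValidity("DiscrepancyReport", function(object) {
  if (!identical(object@passed, nrow(object@entries) == 0L))
    return("passed must be TRUE iff there are no entries")
  TRUE
})
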
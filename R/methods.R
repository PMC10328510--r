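# Accessor and show methods. Kept together; one-liners do not get
# individual documentation beyond the shared accessors page.

#' @rdname accessors
#' @export
setMethod("speciesId", "Species", function(x) x@id)
#' @rdname accessors
#' @export
setMethod("speciesId", "Contig", function(x) x@speciesId)
#' @rdname accessors
#' @export
setMethod("chromosomes", "Species", function(x) x@chromosomes)
#' @rdname accessors
#' @export
setMethod("generationTime", "Species", function(x) x@generationTime)
#' @rdname accessors
#' @export
setMethod("defaultNe", "Species", function(x) x@defaultNe)
#' @rdname accessors
#' @export
setMethod("ploidy", "Species", function(x) x@ploidy)
#' @rdname accessors
#' @export
setMethod("ploidy", "Contig", function(x) x@ploidy)
#' @rdname accessors
#' @export
setMethod("citations", "Species", function(x) x@citations)
#' @rdname accessors
#' @export
setMethod("citations", "DemographicModel", function(x) x@citations)
#' @rdname accessors
#' @export
setMethod("contigLength", "Contig", function(x) x@length)
#' @rdname accessors
#' @export
setMethod("contigLength", "Genealogy", function(x) x@contigLength)
#' @rdname accessors
#' @export
setMethod("mutationRate", "Contig", function(x) x@mutationRate)
#' @rdname accessors
#' @export
setMethod("mutationRate", "Chromosome", function(x) x@mutationRate)
#' @rdname accessors
#' @export
setMethod("rateMap", "Contig", function(x) x@rateMap)
#' @rdname accessors
#' @export
setMethod("nodes", "Genealogy", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("edges", "Genealogy", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("sampleNodes", "Genealogy", function(x) x@samples)
#' @rdname accessors
#' @export
setMethod("genealogy", "AncestrySimulation", function(x) x@genealogy)
#' @rdname accessors
#' @export
setMethod("eventLog", "AncestrySimulation", function(x) x@eventLog)
#' @rdname accessors
#' @export
setMethod("eventCounts", "EventLog", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("eventCounts", "AncestrySimulation",
          function(x) x@eventLog@counts)
#' @rdname accessors
#' @export
setMethod("tractLengths", "EventLog", function(x) x@tractLengths)
#' @rdname accessors
#' @export
setMethod("tractLengths", "AncestrySimulation",
          function(x) x@eventLog@tractLengths)
#' @rdname accessors
#' @export
setMethod("sites", "VariantTable", function(x) x@sites)
#' @rdname accessors
#' @export
setMethod("mutations", "VariantTable", function(x) x@mutations)
#' @rdname accessors
#' @export
setMethod("haplotypes", "VariantTable", function(x) x@haplotypes)
#' @rdname accessors
#' @export
setMethod("populations", "DemographicModel", function(x) x@populations)
#' @rdname accessors
#' @export
setMethod("events", "DemographicModel", function(x) x@events)
#' @rdname accessors
#' @export
setMethod("initialSizes", "DemographicModel", function(x) x@initialSizes)
#' @rdname accessors
#' @export
setMethod("mutationRateOverride", "DemographicModel",
          function(x) x@mutationRateOverride)
#' @rdname accessors
#' @export
setMethod("entries", "DiscrepancyReport", function(x) x@entries)
#' @rdname accessors
#' @export
setMethod("passed", "DiscrepancyReport", function(x) x@passed)

# -- Catalog list-like behaviour ---------------------------------------------

#' @describeIn loadCatalog number of species in a catalog.
#' @param x a \linkS4class{Catalog}.
#' @export
setMethod("length", "Catalog", function(x) length(x@species))

#' @describeIn loadCatalog species ids.
#' @export
setMethod("names", "Catalog", function(x) names(x@species))

#' @describeIn loadCatalog extract one species by id or index.
#' @param i species id or index.
#' @export
setMethod("[[", "Catalog", function(x, i) {
  if (is.character(i) && !i %in% names(x@species))
    stop("unknown species id: ", i)
  x@species[[i]]
})

# -- show methods ------------------------------------------------------------

setMethod("show", "Species", function(object) {
  cat("Species", object@id, "(", object@name, ")\n")
  cat("  chromosomes:", length(object@chromosomes),
      " ploidy:", object@ploidy, "\n")
  cat("  generation time:", object@generationTime,
      "years; default Ne:", object@defaultNe, "\n")
  cat("  citations:", length(object@citations), "\n")
})

setMethod("show", "Catalog", function(object) {
  cat("Catalog with", length(object@species), "species:",
      paste(names(object@species), collapse = ", "), "\n")
})

setMethod("show", "Contig", function(object) {
  cat("Contig", paste0(object@speciesId, "/", object@chromosomeId),
      "length", object@length, "bp\n")
  cat("  mutation rate:", object@mutationRate, "\n")
  if (object@nonCrossoverOnly) {
    cat("  non-crossover-only; tract initiation rate:", object@gcInitRate,
        " mean tract:", object@gcLength, "bp\n")
  } else {
    cat("  crossover map intervals:", length(object@rateMap@rates),
        " mean rate:", .rateMapMass(object@rateMap) / object@length, "\n")
    if (!is.na(object@gcFraction))
      cat("  gene conversion: fraction", object@gcFraction,
          " mean tract", object@gcLength, "bp\n")
  }
})

setMethod("show", "DemographicModel", function(object) {
  cat("DemographicModel", object@id, "with populations:",
      paste(object@populations, collapse = ", "), "\n")
  cat("  events:", nrow(object@events), "\n")
  if (!is.na(object@mutationRateOverride))
    cat("  mutation-rate override:", object@mutationRateOverride, "\n")
})

setMethod("show", "Genealogy", function(object) {
  cat("Genealogy over", object@contigLength, "bp:",
      nrow(object@nodes), "nodes,", nrow(object@edges), "edges,",
      length(object@samples), "samples\n")
})

setMethod("show", "EventLog", function(object) {
  cat("EventLog:\n")
  print(object@counts)
})

setMethod("show", "AncestrySimulation", function(object) {
  show(object@genealogy)
  show(object@eventLog)
})

setMethod("show", "VariantTable", function(object) {
  cat("VariantTable:", nrow(object@sites), "sites,",
      nrow(object@mutations), "mutations,",
      length(object@sampleNames), "samples\n")
})

setMethod("show", "SummaryStats", function(object) {
  cat("SummaryStats: S =", object@S, " pi =", signif(object@pi, 4),
      " thetaW =", signif(object@thetaW, 4), "\n")
})

setMethod("show", "DiscrepancyReport", function(object) {
  if (object@passed) {
    cat("DiscrepancyReport: PASSED (no discrepancies)\n")
  } else {
    cat("DiscrepancyReport: FAILED,", nrow(object@entries), "entries\n")
    print(object@entries)
  }
})
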
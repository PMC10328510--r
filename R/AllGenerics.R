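#' @name accessors
#' @title Accessors for chromsim classes
#' @description Slot accessors; user code should use these rather than
#'   reaching into slots with \code{@}.
#' @param x an object.
#' @return The corresponding component.
NULL

#' @rdname accessors
#' @export
setGeneric("speciesId", function(x) standardGeneric("speciesId"))
#' @rdname accessors
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))
#' @rdname accessors
#' @export
setGeneric("generationTime", function(x) standardGeneric("generationTime"))
#' @rdname accessors
#' @export
setGeneric("defaultNe", function(x) standardGeneric("defaultNe"))
#' @rdname accessors
#' @export
setGeneric("ploidy", function(x) standardGeneric("ploidy"))
#' @rdname accessors
#' @export
setGeneric("citations", function(x) standardGeneric("citations"))
#' @rdname accessors
#' @export
setGeneric("contigLength", function(x) standardGeneric("contigLength"))
#' @rdname accessors
#' @export
setGeneric("mutationRate", function(x) standardGeneric("mutationRate"))
#' @rdname accessors
#' @export
setGeneric("rateMap", function(x) standardGeneric("rateMap"))
#' @rdname accessors
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))
#' @rdname accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))
#' @rdname accessors
#' @export
setGeneric("sampleNodes", function(x) standardGeneric("sampleNodes"))
#' @rdname accessors
#' @export
setGeneric("genealogy", function(x) standardGeneric("genealogy"))
#' @rdname accessors
#' @export
setGeneric("eventLog", function(x) standardGeneric("eventLog"))
#' @rdname accessors
#' @export
setGeneric("eventCounts", function(x) standardGeneric("eventCounts"))
#' @rdname accessors
#' @export
setGeneric("tractLengths", function(x) standardGeneric("tractLengths"))
#' @rdname accessors
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))
#' @rdname accessors
#' @export
setGeneric("mutations", function(x) standardGeneric("mutations"))
#' @rdname accessors
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))
#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))
#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @rdname accessors
#' @export
setGeneric("initialSizes", function(x) standardGeneric("initialSizes"))
#' @rdname accessors
#' @export
setGeneric("mutationRateOverride", function(x)
  standardGeneric("mutationRateOverride"))
#' @rdname accessors
#' @export
setGeneric("entries", function(x) standardGeneric("entries"))
#' @rdname accessors
#' @export
setGeneric("passed", function(x) standardGeneric("passed"))

#' @rdname summaryStats
#' @export
setGeneric("summaryStats", function(x, ...) standardGeneric("summaryStats"))
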
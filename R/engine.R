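#' Gene-conversion initiation rate from a crossover-relative fraction
#'
#' Eukaryotic gene conversion is parameterized by the fraction \code{f} of
#' recombination events that are gene conversions. The tract-initiation rate
#' is then \code{crossoverRate * f / (1 - f)}, so gc and crossover events are
#' drawn at a ratio of \code{f : (1 - f)}; the crossover rate itself is not
#' reduced. A fraction of 0.83 yields an 83:17 event ratio.
#'
#' @param crossoverRate per-bp per-generation crossover rate.
#' @param fraction fraction of recombination events that are gene
#'   conversions, in [0, 1).
#' @return per-bp per-generation tract-initiation rate.
#' @examples
#' gcInitiationRate(1e-8, 0.83)  # 4.88e-8
#' @export
gcInitiationRate <- function(crossoverRate, fraction) {
  if (!is.numeric(fraction) || any(fraction < 0) || any(fraction >= 1))
    stop("fraction must be in [0, 1)")
  crossoverRate * fraction / (1 - fraction)
}

#' Sample gene-conversion tract lengths
#'
#' Tract lengths are geometric on the positive integers with success
#' probability \code{1/mean}, the memoryless discrete distribution with the
#' requested expectation. \code{mean = 1} degenerates to all-ones.
#'
#' @param mean mean tract length in bp (>= 1).
#' @param n number of draws.
#' @param seed optional integer seed (uses and restores the caller's RNG
#'   stream when NULL).
#' @return integer vector of tract lengths (>= 1).
#' @examples
#' mean(sampleTractLength(518, n = 1e4, seed = 7))
#' @export
sampleTractLength <- function(mean, n = 1L, seed = NULL) {
  if (!is.numeric(mean) || length(mean) != 1L || is.na(mean) || mean < 1)
    stop("mean tract length must be >= 1")
  draw <- function() stats::rgeom(n, prob = 1 / mean) + 1L
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

.demographyArrays <- function(model) {
  pops <- model@populations
  ev <- model@events
  list(
    npop = length(pops),
    sizes = as.numeric(model@initialSizes[pops]),
    mig = {
      m <- model@initialMigration
      diag(m) <- 0
      m
    },
    time = as.numeric(ev$time),
    type = match(ev$type, .EVENT_TYPES) - 1L,
    pop = match(ev$pop, pops) - 1L,
    pop2 = ifelse(is.na(ev$pop2), 0L, match(ev$pop2, pops) - 1L),
    value = ifelse(is.na(ev$value), 0, as.numeric(ev$value)))
}

#' Simulate the ancestry of a sample over a contig
#'
#' Runs a structured-coalescent (Hudson-style) simulation backwards in time.
#' Competing exponential events are: pairwise coalescence within population
#' \code{p} at rate \code{k_p (k_p - 1) / 2 / (ploidy * N_p(t))}, migration
#' per lineage at the current matrix rates, crossover per lineage at the
#' rate-map mass over the lineage's breakable span (strictly between its
#' leftmost and rightmost ancestral coordinates), and non-crossover (gene
#' conversion) initiation over the same span, with tracts extending rightward
#' by a geometric length. Piecewise-constant demography is handled by
#' advancing to each epoch boundary and redrawing waiting times (valid by
#' memorylessness). Events that fail to split ancestral material are logged
#' as drawn but not effective.
#'
#' The diploid convention is pairwise coalescence at rate \code{1/(2 Ne)} per
#' generation, so expected pairwise diversity is \code{4 Ne mu}; haploids
#' (e.g. bacteria) coalesce at \code{1/Ne}.
#'
#' @param samples named integer vector of sample counts per population (an
#'   unnamed scalar samples the model's first population). At least two
#'   sampled sequences in total.
#' @param contig a \linkS4class{Contig} (see \code{\link{makeContig}}).
#' @param model a \linkS4class{DemographicModel}; use
#'   \code{\link{constantSizeModel}} for the single-size default.
#' @param seed integer seed; the run is fully deterministic given
#'   (inputs, seed).
#' @param gcSpan where gene-conversion tracts may initiate:
#'   \code{"breakable"} (the lineage's breakable span; default) or
#'   \code{"contig"} (anywhere on the contig, so tracts missing ancestral
#'   material are drawn-but-ineffective).
#' @param maxEvents safety cap on simulation events.
#' @return An \linkS4class{AncestrySimulation}.
#' @examples
#' sp <- builtinCatalog()[["BosTau"]]
#' ctg <- makeContig(sp, "1", lengthOverride = 1e5)
#' sim <- simulateAncestry(2, ctg, constantSizeModel(1e3), seed = 1)
#' eventCounts(sim)
#' @export
simulateAncestry <- function(samples, contig, model, seed,
                             gcSpan = c("breakable", "contig"),
                             maxEvents = 5e7) {
  stopifnot(is(contig, "Contig"), is(model, "DemographicModel"))
  gcSpan <- match.arg(gcSpan)
  bad <- validateModel(model)
  if (length(bad))
    stop("invalid demographic model: ", paste(bad, collapse = "; "))
  if (contig@length < 1) stop("contig length must be >= 1")

  if (is.null(names(samples))) {
    if (length(samples) != 1L)
      stop("samples must be a named vector (population -> count) or a ",
           "single count")
    samples <- stats::setNames(samples, model@populations[1])
  }
  if (any(samples < 1) || any(samples != floor(samples)))
    stop("sample counts must be positive integers")
  if (!all(names(samples) %in% model@populations))
    stop("unknown population(s): ",
         paste(setdiff(names(samples), model@populations), collapse = ", "))
  if (sum(samples) < 2) stop("need at least two sampled sequences")

  samplePops <- rep(match(names(samples), model@populations) - 1L,
                    times = samples)
  dem <- .demographyArrays(model)

  map <- contig@rateMap
  if (contig@nonCrossoverOnly) {
    gcRate <- contig@gcInitRate
    gcMean <- contig@gcLength
    mapBreaks <- c(0, contig@length)
    mapRates <- 0
  } else {
    mapBreaks <- map@breakpoints
    mapRates <- map@rates
    if (!is.na(contig@gcFraction)) {
      meanX <- .rateMapMass(map) / contig@length
      gcRate <- gcInitiationRate(meanX, contig@gcFraction)
      gcMean <- contig@gcLength
    } else {
      gcRate <- 0
      gcMean <- 1
    }
  }

  raw <- withSeed(seed, .sim_ancestry_cpp(
    as.integer(samplePops), as.numeric(contig@length),
    as.numeric(mapBreaks), as.numeric(mapRates),
    as.numeric(gcRate), as.numeric(gcMean),
    identical(gcSpan, "contig"), as.integer(contig@ploidy),
    dem$npop, dem$sizes, dem$mig, dem$time,
    as.integer(dem$type), as.integer(dem$pop), as.integer(dem$pop2),
    dem$value, as.numeric(maxEvents)))

  n <- length(samplePops)
  nodes <- data.frame(id = seq_along(raw$node_time) - 1L,
                      time = raw$node_time,
                      population = model@populations[raw$node_pop + 1L],
                      stringsAsFactors = FALSE)
  edges <- data.frame(parent = raw$edge_parent, child = raw$edge_child,
                      left = raw$edge_left, right = raw$edge_right)
  g <- new("Genealogy", nodes = nodes, edges = edges,
           samples = seq_len(n) - 1L,
           sampleNames = paste0("s", seq_len(n) - 1L),
           contigLength = contig@length)
  typeNames <- c("coalescence", "migration", "crossover", "gene_conversion")
  log <- new("EventLog", counts = raw$counts,
             records = data.frame(time = raw$rec_time,
                                  type = typeNames[raw$rec_type + 1L],
                                  stringsAsFactors = FALSE),
             tractLengths = raw$tracts)
  new("AncestrySimulation", genealogy = g, eventLog = log)
}

# edges of g covering a position
.edgesAt <- function(g, position) {
  e <- g@edges
  e[e$left <= position & e$right > position, , drop = FALSE]
}

#' Recombination breakpoints of a genealogy
#'
#' Sorted unique interval boundaries of the edge table; consecutive values
#' delimit the genomic intervals sharing one marginal tree.
#'
#' @param g a \linkS4class{Genealogy} or \linkS4class{AncestrySimulation}.
#' @return numeric vector of positions, starting 0 and ending at the contig
#'   length.
#' @export
treeBreakpoints <- function(g) {
  if (is(g, "AncestrySimulation")) g <- g@genealogy
  sort(unique(c(0, g@edges$left, g@edges$right, g@contigLength)))
}

#' Extract the marginal tree at a position
#'
#' The rooted tree with branch lengths in generations spanned by the edges
#' covering \code{position}.
#'
#' @param g a \linkS4class{Genealogy} or \linkS4class{AncestrySimulation}.
#' @param position 0-based position in \code{[0, contigLength)}.
#' @return an \code{ape::phylo} tree whose tip labels are the sample names.
#' @export
marginalTree <- function(g, position) {
  if (is(g, "AncestrySimulation")) g <- g@genealogy
  if (position < 0 || position >= g@contigLength)
    stop("position out of range [0, ", g@contigLength, ")")
  e <- .edgesAt(g, position)
  if (!nrow(e)) stop("no edges cover position ", position,
                     " (incomplete genealogy?)")
  tm <- stats::setNames(g@nodes$time, as.character(g@nodes$id))
  labs <- stats::setNames(g@sampleNames, as.character(g@samples))
  kids <- split(e$child, e$parent)
  root <- setdiff(unique(e$parent), e$child)
  if (length(root) != 1L)
    stop("marginal tree at ", position, " has ", length(root), " roots")
  build <- function(v) {
    ch <- kids[[as.character(v)]]
    if (is.null(ch)) return(labs[[as.character(v)]])
    paste0("(", paste(vapply(ch, function(cc) {
      paste0(build(cc), ":",
             sprintf("%.12g", tm[[as.character(v)]] - tm[[as.character(cc)]]))
    }, character(1)), collapse = ","), ")")
  }
  ape::read.tree(text = paste0(build(root), ";"))
}

#' Time to the most recent common ancestor at a position
#'
#' @param g a \linkS4class{Genealogy} or \linkS4class{AncestrySimulation}.
#' @param position 0-based position (default 0).
#' @return TMRCA in generations (the root time of the marginal tree).
#' @export
tmrcaAt <- function(g, position = 0) {
  if (is(g, "AncestrySimulation")) g <- g@genealogy
  e <- .edgesAt(g, position)
  if (!nrow(e)) stop("no edges cover position ", position)
  root <- setdiff(unique(e$parent), e$child)
  g@nodes$time[match(root, g@nodes$id)]
}
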
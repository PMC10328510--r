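.EVENT_TYPES <- c("size_change", "split", "migration_change")

.emptyEvents <- function() {
  data.frame(time = numeric(), type = character(), pop = character(),
             pop2 = character(), value = numeric(),
             stringsAsFactors = FALSE)
}

#' Construct a piecewise-constant demographic model
#'
#' Time is in generations before the present (0 = sampling time), increasing
#' pastward. Events are instantaneous: \code{sizeChangeEvent} sets a new
#' population size from its time pastward, \code{splitEvent} merges a derived
#' population into its ancestor (looking pastward), and
#' \code{migrationChangeEvent} resets one entry of the migration matrix.
#' Ties at the same time are applied in listed order.
#'
#' @param id model id.
#' @param populations character vector of population names.
#' @param initialSizes named numeric vector of present-day sizes (one per
#'   population; an unnamed scalar is recycled).
#' @param events list of events built with the event constructors below, or a
#'   data.frame in the internal layout.
#' @param initialMigration numeric matrix of per-generation pastward
#'   migration rates (defaults to all zero).
#' @param mutationRateOverride optional per-bp per-generation mutation rate
#'   that supersedes the contig rate when this model is simulated, so that
#'   simulated diversity matches the rate assumed during the model's
#'   inference.
#' @param citations list of \linkS4class{Citation}.
#' @return A \linkS4class{DemographicModel}.
#' @examples
#' m <- DemographicModel("cattle-like", "pop0", c(pop0 = 90),
#'        events = list(sizeChangeEvent(100, "pop0", 62000)),
#'        mutationRateOverride = 9.4e-9)
#' populationSizeAt(m, "pop0", 50)    # 90
#' populationSizeAt(m, "pop0", 100)   # 62000 (boundary is pastward epoch)
#' @export
DemographicModel <- function(id, populations, initialSizes, events = list(),
                             initialMigration = NULL,
                             mutationRateOverride = NA_real_,
                             citations = list()) {
  populations <- as.character(populations)
  np <- length(populations)
  if (length(initialSizes) == 1L && is.null(names(initialSizes)))
    initialSizes <- stats::setNames(rep(as.numeric(initialSizes), np),
                                    populations)
  if (is.null(names(initialSizes)))
    names(initialSizes) <- populations
  initialSizes <- initialSizes[populations]
  if (is.null(initialMigration))
    initialMigration <- matrix(0, np, np,
                               dimnames = list(populations, populations))
  ev <- if (is.data.frame(events)) events else .eventsToFrame(events)
  ev <- ev[order(ev$time), , drop = FALSE]  # stable sort keeps listed order
  rownames(ev) <- NULL
  new("DemographicModel", id = as.character(id), populations = populations,
      initialSizes = initialSizes, initialMigration = initialMigration,
      events = ev, mutationRateOverride = as.numeric(mutationRateOverride),
      citations = citations)
}

.eventsToFrame <- function(events) {
  if (!length(events)) return(.emptyEvents())
  do.call(rbind, lapply(events, function(e) {
    stopifnot(is.data.frame(e))
    e
  }))
}

#' @rdname DemographicModel
#' @param time generations before present.
#' @param pop population name.
#' @param size new size (pastward of \code{time}).
#' @export
sizeChangeEvent <- function(time, pop, size) {
  data.frame(time = as.numeric(time), type = "size_change",
             pop = as.character(pop), pop2 = NA_character_,
             value = as.numeric(size), stringsAsFactors = FALSE)
}

#' @rdname DemographicModel
#' @param derived derived population (exists more recently than the split).
#' @param ancestral population it merges into, looking pastward.
#' @export
splitEvent <- function(time, derived, ancestral) {
  data.frame(time = as.numeric(time), type = "split",
             pop = as.character(derived), pop2 = as.character(ancestral),
             value = NA_real_, stringsAsFactors = FALSE)
}

#' @rdname DemographicModel
#' @param source,dest populations; rate applies to lineages in
#'   \code{source} moving (pastward) to \code{dest}.
#' @param rate per-lineage per-generation migration rate.
#' @export
migrationChangeEvent <- function(time, source, dest, rate) {
  data.frame(time = as.numeric(time), type = "migration_change",
             pop = as.character(source), pop2 = as.character(dest),
             value = as.numeric(rate), stringsAsFactors = FALSE)
}

#' Single-population constant-size model
#'
#' The model used when no demographic model is specified: one population of
#' constant size \code{Ne} at all times.
#'
#' @param Ne effective population size (> 0).
#' @param populationName population name.
#' @return A \linkS4class{DemographicModel}.
#' @examples
#' populationSizeAt(constantSizeModel(6.2e4), "pop0", 1e6)  # 62000
#' @export
constantSizeModel <- function(Ne, populationName = "pop0") {
  if (!is.numeric(Ne) || length(Ne) != 1L || is.na(Ne) || Ne <= 0)
    stop("Ne must be a single value > 0")
  DemographicModel(id = paste0("constant_", format(Ne)),
                   populations = populationName,
                   initialSizes = stats::setNames(Ne, populationName))
}

#' Derive effective population size from nucleotide diversity
#'
#' Inverts the neutral identity \eqn{\theta = 4 \mu N_e} relating expected
#' per-site pairwise diversity to the mutation rate and the (diploid)
#' effective population size. Returns the unrounded value; rounding (e.g. to
#' three significant figures, or down to a round number for a catalog
#' default) is the caller's documented choice.
#'
#' @param theta per-site nucleotide diversity (>= 0).
#' @param mu mutation rate per bp per generation (> 0).
#' @return Ne = theta / (4 mu).
#' @examples
#' signif(deriveNeFromTheta(0.015, 3.5e-9), 3)  # 1.07e6
#' @export
deriveNeFromTheta <- function(theta, mu) {
  if (!is.numeric(mu) || any(mu <= 0)) stop("mu must be > 0")
  if (!is.numeric(theta) || any(theta < 0)) stop("theta must be >= 0")
  theta / (4 * mu)
}

#' Percent discrepancy between two rates
#'
#' How much higher (positive) or lower (negative) \code{rateA} is than the
#' reference \code{rateB}, in percent: \code{(rateA/rateB - 1) * 100}. The
#' rounded form uses round-half-to-even to integer percent, the convention
#' used in the rate-consistency audits.
#'
#' @param rateA rate under scrutiny.
#' @param rateB reference rate (> 0).
#' @param rounded logical; return integer percent.
#' @return percent discrepancy (numeric).
#' @examples
#' rateDiscrepancyPercent(1.2e-8, 9.4e-9)                  # 27.66
#' rateDiscrepancyPercent(1e-8, 9.26e-9, rounded = TRUE)   # 8
#' @export
rateDiscrepancyPercent <- function(rateA, rateB, rounded = FALSE) {
  if (!is.numeric(rateB) || any(rateB <= 0)) stop("rateB must be > 0")
  out <- (rateA / rateB - 1) * 100
  if (rounded) round(out) else out
}

#' Population size at a past time
#'
#' Step-function lookup of a population's size \code{t} generations ago.
#' Epochs are half-open pastward: at an event time exactly, the older
#' (pastward) size applies.
#'
#' @param model a \linkS4class{DemographicModel}.
#' @param pop population name.
#' @param t generations before present (>= 0).
#' @return the population size (numeric).
#' @export
populationSizeAt <- function(model, pop, t) {
  stopifnot(is(model, "DemographicModel"))
  if (!pop %in% model@populations) stop("unknown population: ", pop)
  if (t < 0) stop("t must be >= 0")
  ev <- model@events
  splits <- ev[ev$type == "split" & ev$pop == pop, , drop = FALSE]
  if (nrow(splits) && t >= min(splits$time))
    stop("population ", pop, " is not extant at time ", t,
         " (merged into ", splits$pop2[1], " at time ", min(splits$time), ")")
  sc <- ev[ev$type == "size_change" & ev$pop == pop & ev$time <= t,
           , drop = FALSE]
  if (nrow(sc)) sc$value[nrow(sc)] else model@initialSizes[[pop]]
}

#' Mutation rate in effect for a simulation
#'
#' The model's override when present, else the contig's rate; it is an error
#' for neither to be set.
#'
#' @param model a \linkS4class{DemographicModel}.
#' @param contig a \linkS4class{Contig}.
#' @return mutation rate per bp per generation.
#' @export
effectiveMutationRate <- function(model, contig) {
  stopifnot(is(model, "DemographicModel"), is(contig, "Contig"))
  if (!is.na(model@mutationRateOverride)) return(model@mutationRateOverride)
  if (!is.na(contig@mutationRate)) return(contig@mutationRate)
  stop("no mutation rate available: neither the model override nor the ",
       "contig rate is set")
}

#' Convert generations to years
#'
#' @param t time in generations.
#' @param generationTime years per generation (> 0).
#' @return time in years.
#' @examples
#' generationsToYears(33000, 5)  # 165000
#' @export
generationsToYears <- function(t, generationTime) {
  if (!is.numeric(generationTime) || any(generationTime <= 0))
    stop("generation time must be > 0")
  t * generationTime
}

#' Validate a demographic model
#'
#' Returns a report (character vector of violations, empty when valid):
#' positive sizes, non-negative migration rates and event times, known
#' populations, splits that leave a single (or migration-connected) set of
#' root populations, and no events referring to a population after it merged
#' pastward.
#'
#' @param model a \linkS4class{DemographicModel}.
#' @return character vector of violations.
#' @export
validateModel <- function(model) {
  bad <- character()
  rep <- function(...) bad <<- c(bad, paste0(...))
  pops <- model@populations
  if (any(duplicated(pops))) rep("duplicate population names")
  if (any(is.na(model@initialSizes)) || any(model@initialSizes <= 0))
    rep("initial sizes must all be > 0")
  if (any(model@initialMigration < 0))
    rep("migration rates must be >= 0")
  if (!all(dim(model@initialMigration) == length(pops)))
    rep("migration matrix dimensions must match the number of populations")
  ev <- model@events
  if (nrow(ev)) {
    if (any(ev$time < 0)) rep("event times must be >= 0")
    if (any(!ev$type %in% .EVENT_TYPES))
      rep("unknown event type(s): ",
          paste(setdiff(unique(ev$type), .EVENT_TYPES), collapse = ", "))
    if (any(!ev$pop %in% pops))
      rep("event references unknown population: ",
          paste(setdiff(unique(ev$pop), pops), collapse = ", "))
    two <- ev$type %in% c("split", "migration_change")
    if (any(!ev$pop2[two] %in% pops))
      rep("event references unknown population: ",
          paste(setdiff(unique(ev$pop2[two]), pops), collapse = ", "))
    sc <- ev$type == "size_change"
    if (any(is.na(ev$value[sc])) || any(ev$value[sc] <= 0))
      rep("size changes must set a size > 0")
    mc <- ev$type == "migration_change"
    if (any(is.na(ev$value[mc])) || any(ev$value[mc] < 0))
      rep("migration changes must set a rate >= 0")
    # pastward bookkeeping: a merged population must not act later
    gone <- character(); goneAt <- numeric()
    for (i in seq_len(nrow(ev))) {
      e <- ev[i, ]
      if (e$pop %in% gone && e$time > goneAt[match(e$pop, gone)])
        rep("event at time ", e$time, " references population ", e$pop,
            " after it merged pastward")
      if (e$type == "split") {
        if (identical(e$pop, e$pop2))
          rep("split with identical derived and ancestral population")
        gone <- c(gone, e$pop); goneAt <- c(goneAt, e$time)
      }
    }
    roots <- setdiff(pops, gone)
  } else roots <- pops
  if (length(roots) > 1L) {
    # acceptable only if the oldest-epoch migration connects all roots
    mig <- model@initialMigration
    if (nrow(ev)) {
      mc <- ev[ev$type == "migration_change", , drop = FALSE]
      for (i in seq_len(nrow(mc)))
        mig[mc$pop[i], mc$pop2[i]] <- mc$value[i]
    }
    sub <- (mig + t(mig))[roots, roots, drop = FALSE] > 0
    reach <- stats::setNames(logical(length(roots)), roots)
    reach[1] <- TRUE
    repeat {
      new <- reach | apply(sub & matrix(reach, length(roots), length(roots),
                                        byrow = TRUE), 1, any)
      if (identical(new, reach)) break
      reach <- new
    }
    if (!all(reach))
      rep("more than one root population remains after the oldest split, ",
          "with no migration connecting them (lineages could never ",
          "coalesce)")
  }
  bad
}

#' Number of size epochs per population
#'
#' Convenience view of the piecewise-constant size function: each population
#' has one more epoch than it has size-change events.
#'
#' @param model a \linkS4class{DemographicModel}.
#' @return named integer vector of epoch counts.
#' @export
sizeEpochs <- function(model) {
  stopifnot(is(model, "DemographicModel"))
  ev <- model@events
  vapply(model@populations, function(p)
    sum(ev$type == "size_change" & ev$pop == p) + 1L, integer(1))
}
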
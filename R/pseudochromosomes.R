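#' Group unplaced contigs into pseudo-chromosomes
#'
#' Partial genome builds often consist of many contigs too short to carry
#' realistic linkage. This groups contigs into pseudo-chromosomes whose total
#' lengths approximate a set of target (expected chromosome) lengths, using
#' first-fit-decreasing bin packing: contigs are considered in decreasing
#' length order (ties broken by input order) and placed into the first group
#' they fit; a contig fitting nowhere goes to the group with the most
#' remaining capacity and the overflow is flagged in the \code{warnings}
#' attribute. The assignment is deterministic given the inputs and conserves
#' total length.
#'
#' @param contigLengths positive integer lengths (bp) of the contigs.
#' @param targetLengths positive integer target lengths, one per group.
#' @return A list with one integer vector of contig indices per target, in
#'   target order; attribute \code{warnings} lists overflowed groups.
#' @examples
#' assemblePseudochromosomes(c(40, 30, 20, 10), c(60, 40))
#' @export
assemblePseudochromosomes <- function(contigLengths, targetLengths) {
  contigLengths <- as.numeric(contigLengths)
  targetLengths <- as.numeric(targetLengths)
  if (any(contigLengths <= 0) || any(targetLengths <= 0))
    stop("all lengths must be positive")
  if (length(targetLengths) == 0L) {
    if (length(contigLengths) > 0L)
      stop("no target lengths given for a non-empty contig set")
    return(structure(list(), warnings = character()))
  }
  groups <- rep(list(integer()), length(targetLengths))
  fill <- numeric(length(targetLengths))
  ord <- order(-contigLengths)           # stable: ties keep input order
  for (i in ord) {
    fits <- which(fill + contigLengths[i] <= targetLengths)
    g <- if (length(fits)) fits[1L]
         else which.max(targetLengths - fill)
    groups[[g]] <- c(groups[[g]], i)
    fill[g] <- fill[g] + contigLengths[i]
  }
  over <- which(fill > targetLengths)
  warn <- if (length(over))
    paste0("group ", over, " overflows its target length by ",
           fill[over] - targetLengths[over], " bp") else character()
  structure(groups, warnings = warn)
}
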
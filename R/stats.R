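#' Summary statistics of a haplotype sample
#'
#' Computes the number of segregating sites S, nucleotide diversity per bp
#' (pi: the average over all sample pairs of the per-bp mismatch fraction,
#' mismatches divided by the full contig length L), Watterson's estimator
#' \code{theta_w = S / (a_{n-1} L)} with \code{a_{n-1} = sum_{i=1}^{n-1}
#' 1/i}, and the site frequency spectrum. With discrete-site mutation a site
#' may carry more than one derived allele; each derived allele contributes
#' its own frequency class to the unfolded SFS, while pairwise mismatches
#' count any state difference once.
#'
#' @param x a character matrix (samples x sites) of haplotypes, or a
#'   \linkS4class{VariantTable} (which supplies L and ancestral states).
#' @param L contig length in bp (matrix method; must be >= the number of
#'   sites).
#' @param ancestral optional character vector of per-site ancestral states;
#'   required for the unfolded SFS. Without it the SFS is folded.
#' @param folded logical; fold the spectrum (minor-allele classes).
#' @param ... passed between methods.
#' @return A \linkS4class{SummaryStats}.
#' @examples
#' h <- rbind(s0 = c("A", "A", "C"), s1 = c("T", "A", "C"))
#' summaryStats(h, L = 100)  # S = 1, pi = 0.01
#' @name summaryStats
NULL

.summaryStatsMatrix <- function(h, L, ancestral = NULL, folded = is.null(ancestral)) {
  n <- nrow(h)
  if (is.null(n) || n < 2L) stop("need at least 2 haplotypes")
  ns <- ncol(h)
  if (L < ns) stop("L must be at least the number of sites")
  npairs <- n * (n - 1) / 2
  S <- 0L
  mism <- 0
  sfsLen <- if (folded) floor(n / 2) else n - 1L
  sfs <- numeric(sfsLen)
  for (j in seq_len(ns)) {
    tab <- table(h[, j])
    if (length(tab) < 2L) next          # monomorphic (e.g. fully reverted)
    S <- S + 1L
    mism <- mism + npairs - sum(choose(tab, 2))
    if (folded) {
      # each non-majority allele contributes its folded class
      maj <- which.max(tab)
      for (a in seq_along(tab)) {
        if (a == maj) next
        cls <- min(tab[a], n - tab[a])
        if (cls >= 1) sfs[cls] <- sfs[cls] + 1
      }
    } else {
      ref <- ancestral[j]
      for (a in names(tab)) {
        if (a == ref) next
        cnt <- tab[[a]]
        if (cnt >= 1 && cnt <= n - 1) sfs[cnt] <- sfs[cnt] + 1
      }
    }
  }
  an <- sum(1 / seq_len(n - 1))
  new("SummaryStats", S = S, pi = mism / (npairs * L),
      thetaW = S / (an * L), sfs = sfs, folded = folded)
}

#' @rdname summaryStats
#' @export
setMethod("summaryStats", "matrix",
  function(x, L, ancestral = NULL, folded = is.null(ancestral), ...)
    .summaryStatsMatrix(x, L, ancestral, folded))

#' @rdname summaryStats
#' @export
setMethod("summaryStats", "VariantTable", function(x, folded = FALSE, ...) {
  .summaryStatsMatrix(x@haplotypes, x@contigLength,
                      ancestral = x@sites$ancestral, folded = folded)
})

#' Expected (branch-mode) pairwise diversity of a genealogy
#'
#' The variance-reduced counterpart of site-mode pi: the average over sample
#' pairs and genomic positions of \code{2 * TMRCA(pair, position) * mu}.
#' Conditional on the genealogy this is the expectation of site-mode pi, so
#' the two agree in expectation over replicates.
#'
#' @param g a \linkS4class{Genealogy} or \linkS4class{AncestrySimulation}.
#' @param mu mutation rate per bp per generation (>= 0).
#' @return expected per-bp pairwise diversity (numeric).
#' @export
branchDiversity <- function(g, mu) {
  if (is(g, "AncestrySimulation")) g <- g@genealogy
  if (mu < 0) stop("mu must be >= 0")
  if (mu == 0) return(0)
  bks <- treeBreakpoints(g)
  tm <- stats::setNames(g@nodes$time, as.character(g@nodes$id))
  smp <- g@samples
  n <- length(smp)
  pairsIdx <- utils::combn(n, 2)
  tot <- 0
  for (i in seq_len(length(bks) - 1L)) {
    mid <- bks[i]
    e <- .edgesAt(g, mid)
    if (!nrow(e)) next
    par <- stats::setNames(e$parent, as.character(e$child))
    w <- bks[i + 1L] - bks[i]
    for (pp in seq_len(ncol(pairsIdx))) {
      a <- smp[pairsIdx[1, pp]]
      b <- smp[pairsIdx[2, pp]]
      seen <- as.character(a)
      v <- a
      while (!is.na(par[as.character(v)])) {
        v <- par[[as.character(v)]]
        seen <- c(seen, as.character(v))
      }
      v <- b
      while (!as.character(v) %in% seen)
        v <- par[[as.character(v)]]
      tot <- tot + w * tm[[as.character(v)]]
    }
  }
  2 * mu * tot / (ncol(pairsIdx) * g@contigLength)
}

#' Summarize an event log
#'
#' Counts by event type plus derived fractions; in particular
#' \code{gc_fraction_drawn = gc_drawn / (gc_drawn + crossover_drawn)}, the
#' quantity audited against the configured gene-conversion fraction. The
#' fraction is absent when no recombination-class events were drawn.
#'
#' @param log an \linkS4class{EventLog} or \linkS4class{AncestrySimulation}.
#' @return named list of counts and fractions.
#' @export
eventSummary <- function(log) {
  if (is(log, "AncestrySimulation")) log <- log@eventLog
  stopifnot(is(log, "EventLog"))
  cn <- as.list(log@counts)
  out <- cn
  denom <- cn$gc_drawn + cn$crossover_drawn
  if (denom > 0) out$gc_fraction_drawn <- cn$gc_drawn / denom
  if (length(log@tractLengths))
    out$mean_tract_length <- mean(log@tractLengths)
  out
}

#' Pool event counts from several simulations
#'
#' @param logs list of \linkS4class{EventLog} or
#'   \linkS4class{AncestrySimulation} objects.
#' @return an \linkS4class{EventLog} with summed counts, concatenated tract
#'   lengths and no per-event records.
#' @export
poolEventLogs <- function(logs) {
  logs <- lapply(logs, function(l)
    if (is(l, "AncestrySimulation")) l@eventLog else l)
  counts <- Reduce(`+`, lapply(logs, function(l) l@counts))
  new("EventLog", counts = counts,
      records = data.frame(time = numeric(), type = character(),
                           stringsAsFactors = FALSE),
      tractLengths = unlist(lapply(logs, function(l) l@tractLengths)))
}
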
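.NUC <- c("A", "C", "G", "T")

#' Layer discrete-site Jukes-Cantor mutations onto a genealogy
#'
#' Mutation is finite-sites at integer positions: each edge receives a
#' Poisson number of mutations with mean \code{mu} times the edge's genomic
#' span (bp) times its branch length (generations); each mutation gets a
#' uniform integer site within the edge interval, a uniform time on the
#' branch, and a derived state drawn uniformly from the three nucleotides
#' differing from the state just above it (applied root-to-tip in time
#' order). Several mutations may hit one site, so sites can segregate more
#' than two alleles or revert. Ancestral states are uniform over
#' \code{A,C,G,T} (the Jukes-Cantor stationary distribution) unless
#' \code{fixedAncestral} pins them to \code{"A"} for deterministic fixtures.
#'
#' Use a mutation seed independent of the ancestry seed (see
#' \code{\link{deriveSeeds}}) so mutation layering is reproducible
#' regardless of the genealogy's event interleaving.
#'
#' @param g a \linkS4class{Genealogy} or \linkS4class{AncestrySimulation}.
#' @param mu mutation rate per bp per generation (>= 0).
#' @param seed integer seed for the mutation substream.
#' @param fixedAncestral logical; use ancestral state "A" at every site.
#' @return A \linkS4class{VariantTable}.
#' @examples
#' sp <- builtinCatalog()[["BosTau"]]
#' ctg <- makeContig(sp, "1", lengthOverride = 1e4)
#' sim <- simulateAncestry(4, ctg, constantSizeModel(1e4), seed = 2)
#' v <- throwMutations(sim, 1.2e-8, seed = 3)
#' sites(v)
#' @export
throwMutations <- function(g, mu, seed, fixedAncestral = FALSE) {
  if (is(g, "AncestrySimulation")) g <- g@genealogy
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0)
    stop("mu must be a single value >= 0")
  e <- g@edges
  nd <- g@nodes
  tpar <- nd$time[match(e$parent, nd$id)]
  tchi <- nd$time[match(e$child, nd$id)]
  withSeed(seed, {
    mass <- (e$right - e$left) * (tpar - tchi)
    cnt <- stats::rpois(nrow(e), mu * mass)
    tot <- sum(cnt)
    if (tot == 0L) {
      new("VariantTable",
          sites = data.frame(position = numeric(), ancestral = character(),
                             stringsAsFactors = FALSE),
          mutations = data.frame(site = integer(), parent = integer(),
                                 child = integer(), derived = character(),
                                 time = numeric(), stringsAsFactors = FALSE),
          haplotypes = matrix(character(), nrow = length(g@samples),
                              ncol = 0,
                              dimnames = list(g@sampleNames, NULL)),
          contigLength = g@contigLength, sampleNames = g@sampleNames)
    } else {
      ei <- rep(seq_len(nrow(e)), cnt)
      pos <- e$left[ei] +
        floor(stats::runif(tot) * (e$right[ei] - e$left[ei]))
      pos <- pmin(pos, e$right[ei] - 1)
      mtime <- tchi[ei] + stats::runif(tot) * (tpar[ei] - tchi[ei])
      upos <- sort(unique(pos))
      anc <- if (fixedAncestral) rep("A", length(upos))
             else sample(.NUC, length(upos), replace = TRUE)
      sitesDf <- data.frame(position = upos, ancestral = anc,
                            stringsAsFactors = FALSE)
      mut <- data.frame(site = match(pos, upos), parent = e$parent[ei],
                        child = e$child[ei], derived = NA_character_,
                        time = mtime, stringsAsFactors = FALSE)
      mut <- mut[order(mut$site, mut$child, -mut$time), , drop = FALSE]
      rownames(mut) <- NULL
      res <- .propagateMutations(g, sitesDf, mut, assign = TRUE)
      new("VariantTable", sites = sitesDf, mutations = res$mutations,
          haplotypes = res$haplotypes, contigLength = g@contigLength,
          sampleNames = g@sampleNames)
    }
  })
}

# Root-to-tip state propagation at every site. With assign = TRUE, derived
# states are drawn (uniform over the three non-current nucleotides, applied
# in decreasing-time order within an edge); otherwise stored states are used.
.propagateMutations <- function(g, sitesDf, mut, assign = FALSE) {
  n <- length(g@samples)
  hap <- matrix(NA_character_, nrow = n, ncol = nrow(sitesDf),
                dimnames = list(g@sampleNames,
                                as.character(sitesDf$position)))
  sampleRow <- stats::setNames(seq_len(n), as.character(g@samples))
  for (j in seq_len(nrow(sitesDf))) {
    p <- sitesDf$position[j]
    e <- .edgesAt(g, p)
    if (!nrow(e)) stop("mismatched genealogy: no edges cover site at ", p)
    kids <- split(e$child, e$parent)
    root <- setdiff(unique(e$parent), e$child)
    msel <- which(mut$site == j)
    mutsByChild <- split(msel, mut$child[msel])
    state <- new.env(parent = emptyenv())
    assign(as.character(root), sitesDf$ancestral[j], envir = state)
    stack <- as.character(root)
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      st <- get(v, envir = state)
      for (ch in sort(kids[[v]])) {
        cst <- st
        rows <- mutsByChild[[as.character(ch)]]
        if (!is.null(rows)) {
          # decreasing time = oldest first going down the branch
          rows <- rows[order(-mut$time[rows])]
          for (rr in rows) {
            if (assign) {
              d <- sample(setdiff(.NUC, cst), 1L)
              mut$derived[rr] <- d
            } else {
              d <- mut$derived[rr]
              if (is.na(d)) stop("mutation without a derived state")
            }
            cst <- d
          }
        }
        chKey <- as.character(ch)
        if (!is.null(kids[[chKey]])) {
          assign(chKey, cst, envir = state)
          stack <- c(stack, chKey)
        } else {
          hap[sampleRow[[chKey]], j] <- cst
        }
      }
    }
    if (anyNA(hap[, j]))
      stop("mismatched genealogy: not all samples reached at site ", p)
  }
  list(mutations = mut, haplotypes = hap)
}

#' Recompute the haplotype matrix of a variant table
#'
#' Propagates the stored mutations down each site's marginal tree,
#' root-to-tip: a sample's state is the ancestral state modified by all
#' mutations on its path to the root, applied oldest first.
#'
#' @param v a \linkS4class{VariantTable} produced from \code{g}.
#' @param g the \linkS4class{Genealogy} (or
#'   \linkS4class{AncestrySimulation}) it was produced from.
#' @return character matrix samples x sites.
#' @export
genotypes <- function(v, g) {
  stopifnot(is(v, "VariantTable"))
  if (is(g, "AncestrySimulation")) g <- g@genealogy
  if (!identical(v@contigLength, g@contigLength) ||
      !identical(v@sampleNames, g@sampleNames))
    stop("variant table does not match this genealogy")
  if (!nrow(v@sites)) return(v@haplotypes)
  .propagateMutations(g, v@sites, v@mutations, assign = FALSE)$haplotypes
}
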
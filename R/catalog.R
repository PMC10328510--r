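#' Species-catalog construction, serialization and validation
#'
#' A catalog maps species ids to \linkS4class{Species} entries whose numeric
#' parameters carry provenance citations. Catalogs are stored as versioned
#' YAML; unknown keys are errors (they usually indicate a typo in a citable
#' parameter name), and loading re-validates every entry.
#'
#' @param x path to a catalog YAML file, or the YAML text itself.
#' @return \code{loadCatalog}: a \linkS4class{Catalog}.
#' @examples
#' cat <- builtinCatalog()
#' names(cat)
#' txt <- serializeCatalog(cat)
#' cat2 <- loadCatalog(txt)
#' identical(names(cat), names(cat2))
#' @export
loadCatalog <- function(x) {
  txt <- .slurpText(x)
  doc <- if (nzchar(trimws(txt))) yaml::yaml.load(txt) else NULL
  if (is.null(doc)) return(new("Catalog", species = list(),
                               schemaVersion = .CATALOG_SCHEMA_VERSION))
  .checkKeys(doc, c("schema_version", "species"), "catalog")
  if (is.null(doc$schema_version))
    stop("missing mandatory field: schema_version")
  if (doc$schema_version != .CATALOG_SCHEMA_VERSION)
    stop("unsupported catalog schema_version: ", doc$schema_version)
  entries <- doc$species
  if (is.null(entries)) entries <- list()
  species <- lapply(entries, .speciesFromList)
  ids <- vapply(species, function(s) s@id, character(1))
  if (any(duplicated(ids)))
    stop("duplicate species id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(species) <- ids
  for (sp in species) {
    rep <- validateSpecies(sp)
    if (length(rep))
      stop("invalid species '", sp@id, "': ", paste(rep, collapse = "; "))
  }
  new("Catalog", species = species,
      schemaVersion = as.integer(doc$schema_version))
}

.CATALOG_SCHEMA_VERSION <- 1L

.slurpText <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    return(paste(readLines(x, warn = FALSE), collapse = "\n"))
  paste(x, collapse = "\n")
}

.checkKeys <- function(lst, allowed, where) {
  extra <- setdiff(names(lst), allowed)
  if (length(extra))
    stop("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "))
  invisible(TRUE)
}

.need <- function(lst, field, where) {
  if (is.null(lst[[field]]))
    stop("missing mandatory field: ", field, " (in ", where, ")")
  lst[[field]]
}

.optNum <- function(lst, field) {
  v <- lst[[field]]
  if (is.null(v)) NA_real_ else as.numeric(v)
}

.speciesFromList <- function(e) {
  where <- if (is.null(e$id)) "species entry" else paste0("species ", e$id)
  .checkKeys(e, c("id", "name", "ploidy", "generation_time", "default_Ne",
                  "chromosomes", "citations"), where)
  id <- .need(e, "id", where)
  name <- .need(e, "name", where)
  chroms <- .need(e, "chromosomes", where)
  chromosomes <- lapply(chroms, function(ch) {
    cw <- paste0(where, " chromosome ",
                 if (is.null(ch$id)) "?" else ch$id)
    .checkKeys(ch, c("id", "length", "mutation_rate", "recombination_rate",
                     "gene_conversion_fraction", "gene_conversion_length",
                     "non_crossover_only"), cw)
    Chromosome(id = .need(ch, "id", cw),
               length = .optNum(ch, "length"),
               mutationRate = .optNum(ch, "mutation_rate"),
               recombinationRate = .optNum(ch, "recombination_rate"),
               gcFraction = .optNum(ch, "gene_conversion_fraction"),
               gcLength = .optNum(ch, "gene_conversion_length"),
               nonCrossoverOnly = isTRUE(ch$non_crossover_only))
  })
  cits <- lapply(e$citations, .citationFromList)
  Species(id = id, name = name, chromosomes = chromosomes,
          generationTime = .optNum(e, "generation_time"),
          defaultNe = .optNum(e, "default_Ne"),
          ploidy = if (is.null(e$ploidy)) 2L else as.integer(e$ploidy),
          citations = cits)
}

.citationFromList <- function(cc) {
  .checkKeys(cc, c("authors", "year", "doi", "reasons"), "citation")
  Citation(authors = .need(cc, "authors", "citation"),
           year = .need(cc, "year", "citation"),
           doi = if (is.null(cc$doi)) NA_character_ else cc$doi,
           reasons = .need(cc, "reasons", "citation"))
}

.numOrNull <- function(x) if (is.na(x)) NULL else as.numeric(x)

.speciesToList <- function(sp) {
  chroms <- lapply(sp@chromosomes, function(ch) {
    out <- list(id = ch@id)
    out$length <- .numOrNull(ch@length)
    out$mutation_rate <- .numOrNull(ch@mutationRate)
    out$recombination_rate <- .numOrNull(ch@recombinationRate)
    out$gene_conversion_fraction <- .numOrNull(ch@gcFraction)
    out$gene_conversion_length <- .numOrNull(ch@gcLength)
    out$non_crossover_only <- ch@nonCrossoverOnly
    out
  })
  cits <- lapply(sp@citations, function(ci) {
    out <- list(authors = ci@authors, year = as.integer(ci@year))
    if (!is.na(ci@doi)) out$doi <- ci@doi
    out$reasons <- as.list(ci@reasons)
    out
  })
  out <- list(id = sp@id, name = sp@name, ploidy = as.integer(sp@ploidy))
  out$generation_time <- .numOrNull(sp@generationTime)
  out$default_Ne <- .numOrNull(sp@defaultNe)
  out$chromosomes <- chroms
  if (length(cits)) out$citations <- cits
  out
}

#' @rdname loadCatalog
#' @param catalog a \linkS4class{Catalog}.
#' @return \code{serializeCatalog}: the catalog as YAML text, reparseable by
#'   \code{loadCatalog}.
#' @export
serializeCatalog <- function(catalog) {
  stopifnot(is(catalog, "Catalog"))
  doc <- list(schema_version = as.integer(catalog@schemaVersion),
              species = lapply(unname(catalog@species), .speciesToList))
  yaml::as.yaml(doc, precision = 15L)
}

#' Validate a species entry
#'
#' Checks the catalog invariants and returns a report: a character vector of
#' violations, empty when the entry is well formed. Parameters stored as
#' \code{NA} mean "not established by a published estimate; supply at
#' simulation time" and are skipped by the value checks, but any non-missing
#' parameter must be backed by a citation carrying the matching reason tag.
#'
#' @param sp a \linkS4class{Species}.
#' @return character vector of violations (empty = valid).
#' @examples
#' validateSpecies(builtinCatalog()[["EscCol"]])  # character(0)
#' @export
validateSpecies <- function(sp) {
  bad <- character()
  rep <- function(...) bad <<- c(bad, paste0(...))
  if (nchar(sp@id) != 6L) rep("species id must be a 6-character code")
  if (!sp@ploidy %in% c(1L, 2L)) rep("ploidy must be 1 or 2")
  if (!is.na(sp@defaultNe) && sp@defaultNe <= 0)
    rep("default_Ne must be > 0")
  if (!is.na(sp@generationTime) && sp@generationTime <= 0)
    rep("generation_time must be > 0")
  ids <- vapply(sp@chromosomes, function(ch) ch@id, character(1))
  if (any(duplicated(ids)))
    rep("duplicate chromosome id: ",
        paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (ch in sp@chromosomes) {
    pre <- paste0("chromosome ", ch@id, ": ")
    if (!is.na(ch@length) && ch@length < 1) rep(pre, "length must be >= 1")
    if (!is.na(ch@mutationRate) && ch@mutationRate < 0)
      rep(pre, "mutation_rate must be >= 0")
    if (!is.na(ch@recombinationRate) && ch@recombinationRate < 0)
      rep(pre, "recombination_rate must be >= 0")
    if (!is.na(ch@gcFraction) &&
        (ch@gcFraction < 0 || ch@gcFraction >= 1))
      rep(pre, "gene_conversion_fraction must be in [0, 1)",
          " (1 would imply an infinite initiation rate)")
    if (!is.na(ch@gcLength) && ch@gcLength < 1)
      rep(pre, "gene_conversion_length must be >= 1")
    if (ch@nonCrossoverOnly && is.na(ch@gcLength))
      rep(pre, "non-crossover-only chromosomes need gene_conversion_length")
    if (!is.na(ch@gcFraction) && is.na(ch@gcLength))
      rep(pre, "gene_conversion_fraction requires gene_conversion_length")
  }
  # provenance: every non-missing parameter class needs a matching reason tag
  tags <- unique(unlist(lapply(sp@citations, function(ci) ci@reasons)))
  needTag <- function(present, tag, what) {
    if (present && !tag %in% tags)
      rep("no citation with reason '", tag, "' backs ", what)
  }
  needTag(!is.na(sp@defaultNe), "population_size", "default_Ne")
  needTag(!is.na(sp@generationTime), "generation_time", "generation_time")
  needTag(any(vapply(sp@chromosomes,
                     function(ch) !is.na(ch@mutationRate), logical(1))),
          "mutation_rate", "mutation rates")
  needTag(any(vapply(sp@chromosomes,
                     function(ch) !is.na(ch@recombinationRate), logical(1))),
          "recombination_rate", "recombination rates")
  needTag(any(vapply(sp@chromosomes,
                     function(ch) !is.na(ch@gcFraction) ||
                       !is.na(ch@gcLength), logical(1))),
          "gene_conversion", "gene-conversion parameters")
  bad
}

#' Built-in species entries
#'
#' The embedded catalog carries only parameters with published point values:
#' \describe{
#'   \item{AnoGam}{\emph{Anopheles gambiae}: nuclear mutation rate 3.5e-9
#'     (a Dipteran estimate transferred from \emph{D. melanogaster}),
#'     generation time 1/11 years, default Ne 1e6 (the theta-derived estimate
#'     1.07e6 rounded down; see \code{\link{deriveNeFromTheta}}).}
#'   \item{BosTau}{cattle: mutation rate 1.2e-8 on all chromosomes,
#'     recombination rate 9.26e-9 on all chromosomes except the
#'     mitochondrial genome (rate 0), default Ne 6.2e4, generation time 5 y.}
#'   \item{DroMel}{\emph{D. melanogaster}: gene-conversion fraction 0.83 and
#'     mean tract length 518 b on recombining chromosomes; crossover rates
#'     are not embedded and must be supplied.}
#'   \item{EscCol}{\emph{E. coli}: haploid, non-crossover-only recombination
#'     with tract-initiation rate 8.9e-11 per bp per generation and mean
#'     tract length 542 b.}
#' }
#' Chromosome lengths are never embedded; supply them via
#' \code{\link{readChromSizes}} or \code{lengthOverride} in
#' \code{\link{makeContig}}. Citations of built-ins are descriptive
#' provenance strings.
#'
#' @return \code{builtinCatalog}: a \linkS4class{Catalog} with the four
#'   entries above.
#' @examples
#' builtinCatalog()[["BosTau"]]
#' @export
builtinCatalog <- function() {
  cite <- function(what, year, reasons)
    Citation(authors = what, year = year, reasons = reasons)

  anogamChr <- lapply(c("2L", "2R", "3L", "3R", "X"), function(id)
    Chromosome(id, mutationRate = 3.5e-9))
  anogam <- Species("AnoGam", "Anopheles gambiae",
    chromosomes = c(anogamChr, list(Chromosome("Mt", recombinationRate = 0))),
    generationTime = 1 / 11, defaultNe = 1e6, ploidy = 2L,
    citations = list(
      cite("Genome-wide Dipteran mutation-rate estimate (D. melanogaster)",
           2014L, "mutation_rate"),
      cite("Ag1000G diversity and demography study (Gabon population)",
           2017L, c("population_size", "generation_time",
                    "recombination_rate"))))

  bostauChr <- c(
    lapply(as.character(1:29), function(id)
      Chromosome(id, mutationRate = 1.2e-8, recombinationRate = 9.26e-9)),
    list(Chromosome("X", mutationRate = 1.2e-8,
                    recombinationRate = 9.26e-9),
         Chromosome("MT", mutationRate = 1.2e-8, recombinationRate = 0)))
  bostau <- Species("BosTau", "Bos taurus", chromosomes = bostauChr,
    generationTime = 5, defaultNe = 6.2e4, ploidy = 2L,
    citations = list(
      cite("Cattle pedigree mutation-rate estimate", 2019L, "mutation_rate"),
      cite("Cattle linkage-map recombination-rate estimate", 2015L,
           "recombination_rate"),
      cite("Holstein runs-of-homozygosity demographic inference", 2013L,
           c("population_size", "generation_time", "demographic_model"))))

  dromelChr <- lapply(c("2L", "2R", "3L", "3R", "X"), function(id)
    Chromosome(id, gcFraction = 0.83, gcLength = 518))
  dromel <- Species("DroMel", "Drosophila melanogaster",
    chromosomes = dromelChr, ploidy = 2L,
    citations = list(
      cite("Drosophila gene-conversion fraction and tract-length estimate",
           2012L, "gene_conversion")))

  esccol <- Species("EscCol", "Escherichia coli",
    chromosomes = list(
      Chromosome("chr", recombinationRate = 8.9e-11, gcLength = 542,
                 nonCrossoverOnly = TRUE)),
    ploidy = 1L,
    citations = list(
      cite("E. coli homologous-recombination rate and tract estimate",
           2015L, c("recombination_rate", "gene_conversion"))))

  out <- new("Catalog",
             species = list(AnoGam = anogam, BosTau = bostau,
                            DroMel = dromel, EscCol = esccol),
             schemaVersion = .CATALOG_SCHEMA_VERSION)
  for (sp in out@species) stopifnot(length(validateSpecies(sp)) == 0L)
  out
}

#' Build a simulation-ready contig from a catalog chromosome
#'
#' The contig inherits the chromosome's rates unless explicitly overridden.
#' Chromosomes with recombination rate zero (e.g. mitochondria) yield an
#' all-zero crossover map. Gene conversion is off by default and must be
#' switched on with \code{geneConversion = TRUE} (it is costly to simulate);
#' for non-crossover-only (bacterial) chromosomes it is implied, the
#' crossover map is all zeros and the chromosome's recombination rate is the
#' tract-initiation rate.
#'
#' @param sp a \linkS4class{Species}.
#' @param chromosomeId chromosome id within \code{sp}.
#' @param lengthOverride contig length in bp; mandatory when the chromosome
#'   length is not embedded. Must not exceed a known chromosome length.
#' @param mutationRateOverride per-bp per-generation rate replacing the
#'   chromosome's value.
#' @param recombinationRateOverride per-bp per-generation crossover rate
#'   (tract-initiation rate in non-crossover-only mode) replacing the
#'   chromosome's value.
#' @param rateMap a \linkS4class{RateMap} of crossover rates (e.g. from
#'   \code{\link{readHapmapMap}}); overrides any uniform rate.
#' @param geneConversion logical, enable gene conversion using the
#'   chromosome's fraction/tract parameters (or the overrides below).
#' @param gcFractionOverride,gcLengthOverride gene-conversion parameter
#'   overrides.
#' @return A \linkS4class{Contig}.
#' @examples
#' bt <- builtinCatalog()[["BosTau"]]
#' makeContig(bt, "1", lengthOverride = 1e6)
#' makeContig(bt, "MT", lengthOverride = 16338)
#' @export
makeContig <- function(sp, chromosomeId, lengthOverride = NA,
                       mutationRateOverride = NA,
                       recombinationRateOverride = NA, rateMap = NULL,
                       geneConversion = FALSE, gcFractionOverride = NA,
                       gcLengthOverride = NA) {
  stopifnot(is(sp, "Species"))
  ids <- vapply(sp@chromosomes, function(ch) ch@id, character(1))
  k <- match(chromosomeId, ids)
  if (is.na(k))
    stop("unknown chromosome id '", chromosomeId, "' in species ", sp@id)
  ch <- sp@chromosomes[[k]]

  len <- if (!is.na(lengthOverride)) as.numeric(lengthOverride) else ch@length
  if (is.na(len))
    stop("chromosome length unknown; supply lengthOverride ",
         "(or load lengths from chrom.sizes/.fai)")
  if (len < 1) stop("contig length must be >= 1")
  if (!is.na(ch@length) && len > ch@length)
    stop("length override (", len, ") exceeds chromosome length (",
         ch@length, ")")

  mu <- if (!is.na(mutationRateOverride)) as.numeric(mutationRateOverride)
        else ch@mutationRate

  r <- if (!is.na(recombinationRateOverride))
    as.numeric(recombinationRateOverride) else ch@recombinationRate

  gcFrac <- NA_real_; gcLen <- NA_real_; gcInit <- 0
  if (ch@nonCrossoverOnly) {
    if (is.na(r))
      stop("tract-initiation rate unknown; supply recombinationRateOverride")
    gcInit <- r
    gcLen <- if (!is.na(gcLengthOverride)) as.numeric(gcLengthOverride)
             else ch@gcLength
    if (is.na(gcLen))
      stop("mean tract length unknown; supply gcLengthOverride")
    map <- uniformRateMap(0, len)
  } else {
    if (!is.null(rateMap)) {
      stopifnot(is(rateMap, "RateMap"))
      if (rateMap@breakpoints[length(rateMap@breakpoints)] != len)
        stop("rateMap must end at the contig length")
      map <- rateMap
    } else {
      if (is.na(r))
        stop("recombination rate unknown; supply recombinationRateOverride ",
             "or a rateMap")
      map <- uniformRateMap(r, len)
    }
    if (geneConversion) {
      gcFrac <- if (!is.na(gcFractionOverride))
        as.numeric(gcFractionOverride) else ch@gcFraction
      gcLen <- if (!is.na(gcLengthOverride))
        as.numeric(gcLengthOverride) else ch@gcLength
      if (is.na(gcFrac) || is.na(gcLen))
        stop("gene conversion requested but fraction/tract length are not ",
             "set for chromosome ", ch@id,
             " (supply gcFractionOverride/gcLengthOverride)")
      if (gcFrac < 0 || gcFrac >= 1)
        stop("gene-conversion fraction must be in [0, 1)")
    }
  }

  new("Contig", speciesId = sp@id, chromosomeId = ch@id, length = len,
      mutationRate = mu, rateMap = map, gcFraction = gcFrac,
      gcLength = gcLen, nonCrossoverOnly = ch@nonCrossoverOnly,
      gcInitRate = gcInit, ploidy = sp@ploidy)
}
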
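#' Read chromosome lengths from chrom.sizes or FASTA-index text
#'
#' Accepts 2-column chrom.sizes TSV (name, length) or a 5+-column samtools
#' \code{.fai} FASTA index (columns 1-2 used). Input may be a file path or
#' the text itself.
#'
#' @param x path or text.
#' @return named numeric vector of lengths (bp).
#' @examples
#' readChromSizes("chr1\t1000\nchr2\t500\n")
#' @export
readChromSizes <- function(x) {
  txt <- .slurpText(x)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  out <- numeric()
  nm <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) == 1L) f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (!length(f) %in% c(2L) && length(f) < 5L)
      stop("line ", i, ": expected 2 columns (chrom.sizes) or >= 5 (.fai)")
    len <- suppressWarnings(as.numeric(f[2]))
    if (is.na(len) || len <= 0 || len != floor(len))
      stop("line ", i, ": length must be a positive integer, got '",
           f[2], "'")
    nm <- c(nm, f[1])
    out <- c(out, len)
  }
  if (any(duplicated(nm)))
    stop("duplicate sequence name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  stats::setNames(out, nm)
}

#' Read a HapMap-style genetic map into a RateMap
#'
#' Expects whitespace-separated columns (chromosome, position bp, rate in
#' cM/Mb, cumulative map in cM); a header line is tolerated and the fourth
#' column is optional. Rates convert at 1 cM/Mb = 1e-8 crossovers per bp per
#' generation. Each row's rate applies from its position to the next row's
#' position; positions before the first map point take the first interval's
#' rate and positions after the last point take the last row's rate.
#' Breakpoints are clipped to \code{[0, contigLength)}.
#'
#' @param x path or text.
#' @param contigLength contig length in bp.
#' @return A \linkS4class{RateMap}.
#' @examples
#' readHapmapMap("chr pos rate map\n1 0 1.0 0\n1 1000 0.0 0.001\n", 2000)
#' @export
readHapmapMap <- function(x, contigLength) {
  txt <- .slurpText(x)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty genetic map")
  fields <- strsplit(trimws(lines), "[ \t]+")
  # tolerate one header line (non-numeric position column)
  if (is.na(suppressWarnings(as.numeric(fields[[1]][2]))))
    fields <- fields[-1]
  if (!length(fields)) stop("genetic map has a header but no data rows")
  pos <- vapply(fields, function(f) suppressWarnings(as.numeric(f[2])),
                numeric(1))
  rate <- vapply(fields, function(f) suppressWarnings(as.numeric(f[3])),
                 numeric(1))
  if (anyNA(pos) || anyNA(rate))
    stop("malformed genetic map row(s): ",
         paste(which(is.na(pos) | is.na(rate)), collapse = ", "))
  if (is.unsorted(pos, strictly = TRUE))
    stop("genetic map positions must be strictly increasing")
  if (any(rate < 0)) stop("genetic map rates must be non-negative")
  perbp <- rate * 1e-8
  keep <- pos < contigLength
  pos <- pos[keep]; perbp <- perbp[keep]
  if (!length(pos)) stop("no map positions fall inside the contig")
  # row i's rate covers [pos_i, pos_{i+1}); the first rate also covers the
  # left flank [0, pos_1)
  breaks <- c(0, pos[-1], contigLength)
  if (length(breaks) >= 2 && breaks[2] <= 0)
    breaks <- breaks[-2]
  RateMap(breaks, perbp)
}

#' Write a variant table as VCF 4.2 text
#'
#' Minimal well-formed VCF: positions are converted from the internal
#' 0-based to VCF 1-based coordinates, REF is the ancestral state, and ALT
#' lists the derived alleles observed in the sample in first-appearance
#' order of the mutations that produced them (sites left monomorphic by
#' reverted mutations get ALT "."). Genotypes are haploid by default, one
#' column per sampled sequence; \code{diploid = TRUE} pairs consecutive
#' sequences as phased genotypes.
#'
#' @param v a \linkS4class{VariantTable}.
#' @param sampleNames column names (defaults to the variant table's sample
#'   names; with \code{diploid}, one name per pair).
#' @param contigId CHROM value.
#' @param diploid logical; pair consecutive haplotypes as phased diploids.
#' @param file optional path; when given, the text is also written there.
#' @return VCF text (invisibly when \code{file} is given).
#' @export
writeVCF <- function(v, sampleNames = NULL, contigId = "1", diploid = FALSE,
                     file = NULL) {
  stopifnot(is(v, "VariantTable"))
  h <- v@haplotypes
  nh <- nrow(h)
  if (diploid) {
    if (nh %% 2L != 0L)
      stop("diploid output needs an even number of haplotypes")
    ncolOut <- nh / 2L
    if (is.null(sampleNames))
      sampleNames <- paste0("ind", seq_len(ncolOut) - 1L)
  } else {
    ncolOut <- nh
    if (is.null(sampleNames)) sampleNames <- v@sampleNames
  }
  if (length(sampleNames) != ncolOut)
    stop("expected ", ncolOut, " sample names, got ", length(sampleNames))

  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", contigId, ",length=",
                  format(v@contigLength, scientific = FALSE), ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sampleNames), collapse = "\t"))
  rows <- character(nrow(v@sites))
  for (j in seq_len(nrow(v@sites))) {
    ref <- v@sites$ancestral[j]
    col <- h[, j]
    der <- v@mutations$derived[v@mutations$site == j]
    alts <- unique(der)
    alts <- alts[alts != ref & alts %in% col]
    extra <- setdiff(unique(col), c(ref, alts))
    alts <- c(alts, extra)
    gt <- match(col, c(ref, alts)) - 1L
    gtField <- if (diploid)
      paste(gt[seq(1, nh, by = 2)], gt[seq(2, nh, by = 2)], sep = "|")
    else as.character(gt)
    rows[j] <- paste(c(contigId,
                       format(v@sites$position[j] + 1, scientific = FALSE),
                       ".", ref,
                       if (length(alts)) paste(alts, collapse = ",") else ".",
                       ".", "PASS", ".", "GT", gtField), collapse = "\t")
  }
  txt <- paste0(paste(c(hdr, rows), collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Write a tree as Newick text
#'
#' Branch lengths are in generations. A degenerate single-leaf tree may be
#' given as \code{list(label = "s0", length = 0)} and is written as
#' \code{"s0:0.0;"}.
#'
#' @param tree an \code{ape::phylo} (e.g. from \code{\link{marginalTree}}),
#'   or the degenerate single-leaf list form.
#' @param file optional path.
#' @return Newick text (invisibly when \code{file} is given).
#' @export
writeNewick <- function(tree, file = NULL) {
  txt <- if (inherits(tree, "phylo")) {
    ape::write.tree(tree)
  } else if (is.list(tree) && !is.null(tree$label)) {
    len <- if (is.null(tree$length)) 0 else tree$length
    sprintf("%s:%s;", tree$label,
            format(len, nsmall = if (len == floor(len)) 1 else 0))
  } else stop("tree must be a phylo or list(label=, length=)")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Export an event log's records as TSV
#'
#' @param log an \linkS4class{EventLog} or \linkS4class{AncestrySimulation}.
#' @param file optional path.
#' @return TSV text (invisibly when \code{file} is given).
#' @export
exportEventLog <- function(log, file = NULL) {
  if (is(log, "AncestrySimulation")) log <- log@eventLog
  con <- textConnection("out", "w", local = TRUE)
  utils::write.table(log@records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

# ---- demographic-model files ------------------------------------------------

#' Read or write a demographic-model file
#'
#' Demographic models are stored as versioned YAML listing populations,
#' initial sizes, an optional initial migration matrix, events (size
#' changes, splits, migration changes), an optional mutation-rate override,
#' and citations. Unknown keys are errors.
#'
#' @param x path to a model YAML file, or the YAML text.
#' @return \code{readDemographicModel}: a \linkS4class{DemographicModel}.
#' @export
readDemographicModel <- function(x) {
  doc <- yaml::yaml.load(.slurpText(x))
  .checkKeys(doc, c("schema_version", "id", "populations", "initial_sizes",
                    "initial_migration", "mutation_rate_override", "events",
                    "citations"), "demographic model")
  if (is.null(doc$schema_version) ||
      doc$schema_version != .CATALOG_SCHEMA_VERSION)
    stop("missing or unsupported schema_version")
  pops <- as.character(unlist(.need(doc, "populations", "model")))
  sizes <- unlist(.need(doc, "initial_sizes", "model"))
  mig <- NULL
  if (!is.null(doc$initial_migration)) {
    mig <- do.call(rbind, lapply(doc$initial_migration, as.numeric))
    dimnames(mig) <- list(pops, pops)
  }
  evs <- lapply(doc$events, function(e) {
    ty <- .need(e, "type", "event")
    switch(ty,
      size_change = {
        .checkKeys(e, c("time", "type", "population", "size"), "event")
        sizeChangeEvent(.need(e, "time", "event"),
                        .need(e, "population", "event"),
                        .need(e, "size", "event"))
      },
      split = {
        .checkKeys(e, c("time", "type", "derived", "ancestral"), "event")
        splitEvent(.need(e, "time", "event"),
                   .need(e, "derived", "event"),
                   .need(e, "ancestral", "event"))
      },
      migration_change = {
        .checkKeys(e, c("time", "type", "source", "dest", "rate"), "event")
        migrationChangeEvent(.need(e, "time", "event"),
                             .need(e, "source", "event"),
                             .need(e, "dest", "event"),
                             .need(e, "rate", "event"))
      },
      stop("unknown event type: ", ty))
  })
  cits <- lapply(doc$citations, .citationFromList)
  m <- DemographicModel(
    id = .need(doc, "id", "model"), populations = pops,
    initialSizes = sizes, events = evs, initialMigration = mig,
    mutationRateOverride = if (is.null(doc$mutation_rate_override))
      NA_real_ else as.numeric(doc$mutation_rate_override),
    citations = cits)
  bad <- validateModel(m)
  if (length(bad))
    stop("invalid demographic model '", m@id, "': ",
         paste(bad, collapse = "; "))
  m
}

#' @rdname readDemographicModel
#' @param model a \linkS4class{DemographicModel}.
#' @return \code{writeDemographicModel}: YAML text reparseable by
#'   \code{readDemographicModel}.
#' @export
writeDemographicModel <- function(model) {
  stopifnot(is(model, "DemographicModel"))
  ev <- model@events
  evs <- lapply(seq_len(nrow(ev)), function(i) {
    e <- ev[i, ]
    switch(e$type,
      size_change = list(time = e$time, type = "size_change",
                         population = e$pop, size = e$value),
      split = list(time = e$time, type = "split", derived = e$pop,
                   ancestral = e$pop2),
      migration_change = list(time = e$time, type = "migration_change",
                              source = e$pop, dest = e$pop2, rate = e$value))
  })
  doc <- list(schema_version = .CATALOG_SCHEMA_VERSION, id = model@id,
              populations = as.list(model@populations),
              initial_sizes = as.list(model@initialSizes))
  if (any(model@initialMigration != 0))
    doc$initial_migration <- lapply(seq_len(nrow(model@initialMigration)),
                                    function(i) model@initialMigration[i, ])
  if (!is.na(model@mutationRateOverride))
    doc$mutation_rate_override <- model@mutationRateOverride
  if (length(evs)) doc$events <- evs
  if (length(model@citations))
    doc$citations <- lapply(model@citations, function(ci) {
      out <- list(authors = ci@authors, year = as.integer(ci@year))
      if (!is.na(ci@doi)) out$doi <- ci@doi
      out$reasons <- as.list(ci@reasons)
      out
    })
  yaml::as.yaml(doc, precision = 15L)
}
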
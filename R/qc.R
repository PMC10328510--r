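#' Compare two independently specified demographic models
#'
#' The quality-control step for new catalog entries: a second implementer
#' recreates a model from its source documentation, and an automated
#' comparison of the two specifications must pass before the model is
#' accepted. Population sets, initial sizes, migration matrices, event
#' sequences and mutation-rate overrides are compared; numeric fields with
#' relative tolerance \code{rtol}, structural mismatches (missing
#' populations, unmatched events, override present vs absent) always.
#' Events are aligned by (time, type, populations) keys, with times treated
#' as equal within \code{rtol}.
#'
#' @param a,b \linkS4class{DemographicModel}s.
#' @param rtol relative tolerance (> 0); the default 1e-6 suits transcribed
#'   (citable) constants.
#' @return A \linkS4class{DiscrepancyReport}; \code{passed(x)} is TRUE iff
#'   no discrepancies were found. Entry paths are dot-separated and
#'   machine-parsable.
#' @examples
#' m <- constantSizeModel(62000)
#' passed(compareModels(m, m))  # TRUE
#' @export
compareModels <- function(a, b, rtol = 1e-6) {
  stopifnot(is(a, "DemographicModel"), is(b, "DemographicModel"))
  if (!is.numeric(rtol) || rtol <= 0) stop("rtol must be > 0")
  paths <- character(); va <- character(); vb <- character(); rd <- numeric()
  add <- function(path, x, y, rel = NA_real_) {
    paths <<- c(paths, path)
    va <<- c(va, as.character(x))
    vb <<- c(vb, as.character(y))
    rd <<- c(rd, rel)
  }
  relDiff <- function(x, y) {
    if (x == y) return(0)
    abs(x - y) / max(abs(x), abs(y))
  }
  cmpNum <- function(path, x, y) {
    r <- relDiff(x, y)
    if (r > rtol) add(path, x, y, r)
  }

  onlyA <- setdiff(a@populations, b@populations)
  onlyB <- setdiff(b@populations, a@populations)
  for (p in onlyA) add(paste0("populations.", p), p, "<absent>")
  for (p in onlyB) add(paste0("populations.", p), "<absent>", p)
  common <- intersect(a@populations, b@populations)

  for (p in common)
    cmpNum(paste0("initial_sizes.", p),
           a@initialSizes[[p]], b@initialSizes[[p]])
  for (p in common) for (q in common) {
    if (p == q) next
    cmpNum(paste0("initial_migration.", p, ".", q),
           a@initialMigration[p, q], b@initialMigration[p, q])
  }

  oa <- a@mutationRateOverride; ob <- b@mutationRateOverride
  if (is.na(oa) != is.na(ob))
    add("mutation_rate_override",
        if (is.na(oa)) "<absent>" else oa,
        if (is.na(ob)) "<absent>" else ob)
  else if (!is.na(oa)) cmpNum("mutation_rate_override", oa, ob)

  evKey <- function(e) paste(e$type, e$pop,
                             ifelse(is.na(e$pop2), "", e$pop2), sep = ".")
  ea <- a@events; eb <- b@events
  usedB <- logical(nrow(eb))
  for (i in seq_len(nrow(ea))) {
    key <- evKey(ea[i, ])
    cand <- which(!usedB & evKey(eb) == key &
                  mapply(function(x, y) relDiff(x, y) <= rtol,
                         eb$time, ea$time[i]))
    path <- paste0("events.", key, ".t", format(ea$time[i]))
    if (!length(cand)) {
      add(path, "present", "<unmatched>")
    } else {
      j <- cand[1L]
      usedB[j] <- TRUE
      if (!is.na(ea$value[i]) || !is.na(eb$value[j])) {
        if (is.na(ea$value[i]) != is.na(eb$value[j]))
          add(paste0(path, ".value"), ea$value[i], eb$value[j])
        else cmpNum(paste0(path, ".value"), ea$value[i], eb$value[j])
      }
    }
  }
  for (j in which(!usedB))
    add(paste0("events.", evKey(eb[j, ]), ".t", format(eb$time[j])),
        "<unmatched>", "present")

  entries <- data.frame(path = paths, value_a = va, value_b = vb,
                        relative_difference = rd, stringsAsFactors = FALSE)
  new("DiscrepancyReport", entries = entries, passed = nrow(entries) == 0L)
}

#' Audit rate consistency between a model and its species defaults
#'
#' Demographic models are inferred under assumed mutation and recombination
#' rates; when those differ from the species' catalog defaults, simulations
#' mixing the two produce biased diversity or linkage. For each assumption
#' supplied, this emits the percent discrepancy of the species default
#' relative to the assumed rate. A mutation-rate discrepancy is marked
#' resolved when the model carries a matching override (the override then
#' supersedes the species rate in simulation); recombination-rate
#' discrepancies cannot be resolved by an override (models do not carry one)
#' and are always flagged unresolved.
#'
#' @param model a \linkS4class{DemographicModel}.
#' @param sp the \linkS4class{Species} the model belongs to.
#' @param assumptions named list with optional entries \code{mutation_rate}
#'   and \code{recombination_rate}: the rates assumed during the model's
#'   inference.
#' @return data.frame with columns \code{quantity}, \code{assumed},
#'   \code{species_default}, \code{percent} (rounded, species default
#'   relative to assumed), \code{resolved}, \code{note}; zero rows when no
#'   assumptions are given.
#' @examples
#' bt <- builtinCatalog()[["BosTau"]]
#' m <- DemographicModel("holstein-like", "pop0", c(pop0 = 90),
#'        mutationRateOverride = 9.4e-9)
#' auditRateConsistency(m, bt,
#'   list(mutation_rate = 9.4e-9, recombination_rate = 1e-8))
#' @export
auditRateConsistency <- function(model, sp, assumptions = list()) {
  stopifnot(is(model, "DemographicModel"), is(sp, "Species"))
  modal <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    u <- unique(v)
    u[which.max(tabulate(match(v, u)))]
  }
  out <- data.frame(quantity = character(), assumed = numeric(),
                    species_default = numeric(), percent = numeric(),
                    resolved = logical(), note = character(),
                    stringsAsFactors = FALSE)
  if (!is.null(assumptions$mutation_rate)) {
    assumed <- assumptions$mutation_rate
    spRate <- modal(vapply(sp@chromosomes,
                           function(ch) ch@mutationRate, numeric(1)))
    pc <- rateDiscrepancyPercent(spRate, assumed, rounded = TRUE)
    ov <- model@mutationRateOverride
    resolved <- !is.na(ov) && abs(ov - assumed) <= 1e-6 * abs(assumed)
    note <- if (resolved)
      "model mutation-rate override matches the inference assumption"
    else if (!is.na(ov))
      "model carries an override, but it differs from the assumed rate"
    else
      "no override: simulated diversity will reflect the species rate"
    out <- rbind(out, data.frame(
      quantity = "mutation_rate", assumed = assumed,
      species_default = spRate, percent = pc, resolved = resolved,
      note = note, stringsAsFactors = FALSE))
  }
  if (!is.null(assumptions$recombination_rate)) {
    assumed <- assumptions$recombination_rate
    rates <- vapply(sp@chromosomes,
                    function(ch) ch@recombinationRate, numeric(1))
    spRate <- modal(rates[is.na(rates) | rates > 0])
    pc <- rateDiscrepancyPercent(assumed, spRate, rounded = TRUE)
    out <- rbind(out, data.frame(
      quantity = "recombination_rate", assumed = assumed,
      species_default = spRate, percent = pc, resolved = FALSE,
      note = paste0("models cannot override the recombination rate; ",
                    "simulated linkage may be biased"),
      stringsAsFactors = FALSE))
  }
  out
}
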
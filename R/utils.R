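# Internal helpers.

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# random-number stream.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive independent substream seeds from one root seed
#'
#' One root seed drives a whole run; ancestry simulation and mutation
#' layering use separate derived seeds so that re-throwing mutations does not
#' perturb the genealogy (and vice versa). The map is a fixed affine
#' congruence modulo 2^31 - 1, so derived seeds remain valid 32-bit integers.
#'
#' @param seed integer root seed.
#' @return named list with integer elements \code{ancestry} and
#'   \code{mutation}.
#' @export
deriveSeeds <- function(seed) {
  seed <- as.double(seed)
  m <- 2147483647
  list(ancestry = as.integer(((seed %% m) * 69069 + 12345) %% m),
       mutation = as.integer(((seed %% m) * 40692 + 52774) %% m))
}

# Total rate-map mass (expected events per generation across the map).
.rateMapMass <- function(map, from = NULL, to = NULL) {
  b <- map@breakpoints; r <- map@rates
  if (is.null(from)) from <- b[1]
  if (is.null(to)) to <- b[length(b)]
  lo <- pmin(pmax(b[-length(b)], from), to)
  hi <- pmin(pmax(b[-1], from), to)
  sum((hi - lo) * r)
}

.isCount <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == floor(x)

.emptyEventLog <- function() {
  new("EventLog",
      counts = c(coalescence = 0, migration = 0, crossover_drawn = 0,
                 crossover_effective = 0, gc_drawn = 0, gc_effective = 0),
      records = data.frame(time = numeric(), type = character()),
      tractLengths = numeric())
}
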
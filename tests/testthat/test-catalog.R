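test_that("an empty catalog file yields a catalog with zero species", {
  expect_equal(length(loadCatalog("")), 0L)
  expect_equal(length(loadCatalog("\n# just a comment\n")), 0L)
})

test_that("built-in entries carry the published parameter values", {
  cat <- builtinCatalog()
  ag <- cat[["AnoGam"]]
  nuclear <- Filter(function(ch) ch@id != "Mt", chromosomes(ag))
  expect_true(all(vapply(nuclear, mutationRate, numeric(1)) == 3.5e-9))
  expect_equal(generationTime(ag), 1 / 11)
  expect_equal(defaultNe(ag), 1e6)

  bt <- cat[["BosTau"]]
  expect_equal(defaultNe(bt), 6.2e4)
  expect_equal(generationTime(bt), 5)

  dm <- cat[["DroMel"]]
  expect_true(all(vapply(chromosomes(dm), function(ch) ch@gcFraction,
                         numeric(1)) == 0.83))
  expect_true(all(vapply(chromosomes(dm), function(ch) ch@gcLength,
                         numeric(1)) == 518))

  ec <- cat[["EscCol"]]
  expect_equal(ploidy(ec), 1L)
  ch <- chromosomes(ec)[[1]]
  expect_true(ch@nonCrossoverOnly)
  expect_equal(ch@recombinationRate, 8.9e-11)
  expect_equal(ch@gcLength, 542)

  for (id in names(cat))
    expect_length(validateSpecies(cat[[id]]), 0L)
})

test_that("catalog loading rejects duplicates, unknown keys and missing fields", {
  base <- serializeCatalog(builtinCatalog())
  dup <- paste0("schema_version: 1\nspecies:\n",
                "- {id: BosTau, name: a, chromosomes: [{id: c1}]}\n",
                "- {id: BosTau, name: b, chromosomes: [{id: c1}]}\n")
  expect_error(loadCatalog(dup), "duplicate species id")
  expect_error(loadCatalog("schema_version: 1\ntypo_key: 1\n"),
               "unknown key")
  expect_error(
    loadCatalog(paste0("schema_version: 1\nspecies:\n",
                       "- {id: AbcDef, chromosomes: [{id: c1}]}\n")),
    "name")
  expect_error(
    loadCatalog(paste0("schema_version: 1\nspecies:\n",
                       "- {id: AbcDef, name: x, chromosomes: ",
                       "[{id: c1, mutation_rte: 1e-8}]}\n")),
    "unknown key")
  expect_error(loadCatalog("species: []\n"), "schema_version")
  expect_silent(loadCatalog(base))
})

test_that("serialize/load round trip preserves every field", {
  cat1 <- builtinCatalog()
  cat1@species$ToySpe <- toySpecies()
  names(cat1@species)[length(cat1@species)] <- "ToySpe"
  cat2 <- loadCatalog(serializeCatalog(cat1))
  expect_identical(names(cat1), names(cat2))
  for (id in names(cat1)) {
    a <- cat1[[id]]; b <- cat2[[id]]
    expect_identical(a@name, b@name)
    expect_identical(a@ploidy, b@ploidy)
    expect_equal(a@generationTime, b@generationTime, tolerance = 1e-12)
    expect_equal(a@defaultNe, b@defaultNe, tolerance = 1e-12)
    expect_equal(length(a@chromosomes), length(b@chromosomes))
    for (k in seq_along(a@chromosomes))
      for (sl in c("id", "length", "mutationRate", "recombinationRate",
                   "gcFraction", "gcLength", "nonCrossoverOnly"))
        expect_equal(slot(a@chromosomes[[k]], sl),
                     slot(b@chromosomes[[k]], sl), tolerance = 1e-12)
    expect_equal(length(a@citations), length(b@citations))
    for (k in seq_along(a@citations))
      expect_identical(a@citations[[k]]@reasons, b@citations[[k]]@reasons)
  }
  # and serialization is a fixed point
  expect_identical(serializeCatalog(cat1), serializeCatalog(cat2))
})

test_that("validateSpecies reports invariant violations without erroring", {
  sp <- toySpecies()
  expect_length(validateSpecies(sp), 0L)

  bad <- sp
  bad@chromosomes[[1]]@gcFraction <- 1.0
  expect_match(validateSpecies(bad), "gene_conversion_fraction",
               all = FALSE)

  bad <- sp
  bad@chromosomes[[1]]@mutationRate <- -1e-9
  expect_match(validateSpecies(bad), "mutation_rate", all = FALSE)

  bad <- sp
  bad@chromosomes[[2]]@id <- "chr1"
  expect_match(validateSpecies(bad), "duplicate chromosome", all = FALSE)

  # provenance: dropping the citation orphans every parameter
  bad <- sp
  bad@citations <- list()
  expect_match(validateSpecies(bad), "no citation", all = FALSE)
})

test_that("makeContig inherits, overrides and zeroes rates correctly", {
  bt <- builtinCatalog()[["BosTau"]]
  ctg <- makeContig(bt, "1", lengthOverride = 1e6)
  expect_equal(mutationRate(ctg), 1.2e-8)
  expect_equal(rateMap(ctg)@rates, 9.26e-9)
  expect_equal(rateMap(ctg)@breakpoints, c(0, 1e6))

  mt <- makeContig(bt, "MT", lengthOverride = 16338)
  expect_equal(rateMap(mt)@rates, 0)

  small <- makeContig(bt, "1", lengthOverride = 10000)
  expect_equal(contigLength(small), 10000)
  expect_equal(mutationRate(small), 1.2e-8)

  expect_error(makeContig(bt, "nope", lengthOverride = 1), "unknown chromosome")
  expect_error(makeContig(bt, "1"), "length")

  sp <- toySpecies()
  expect_error(makeContig(sp, "chr1", lengthOverride = 2e6),
               "exceeds chromosome length")

  # gene conversion off by default, on by request
  ctg <- makeContig(sp, "chr1", lengthOverride = 1e4)
  expect_true(is.na(ctg@gcFraction))
  ctg <- makeContig(sp, "chr1", lengthOverride = 1e4, geneConversion = TRUE)
  expect_equal(ctg@gcFraction, 0.5)
  expect_equal(ctg@gcLength, 100)

  # bacterial mode: zero crossover map, initiation rate carried over
  ec <- builtinCatalog()[["EscCol"]]
  bctg <- makeContig(ec, "chr", lengthOverride = 1e5)
  expect_true(bctg@nonCrossoverOnly)
  expect_equal(bctg@gcInitRate, 8.9e-11)
  expect_equal(bctg@gcLength, 542)
  expect_true(all(rateMap(bctg)@rates == 0))
})

test_that("contig lengths can come from chrom.sizes files", {
  lens <- readChromSizes("chr1\t123456\nchrM\t20000\n")
  sp <- toySpecies()
  ctg <- makeContig(sp, "chr1", lengthOverride = lens[["chr1"]])
  expect_equal(contigLength(ctg), 123456)
})
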
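mkModel <- function(size = 62000, override = NA_real_, extraEvent = NULL) {
  ev <- list(sizeChangeEvent(33000, "pop0", size))
  if (!is.null(extraEvent)) ev <- c(ev, list(extraEvent))
  DemographicModel("holstein-like", "pop0", c(pop0 = 90), events = ev,
                   mutationRateOverride = override)
}

test_that("model comparison is reflexive and passes on identical models", {
  m <- mkModel(override = 9.4e-9)
  rep <- compareModels(m, m)
  expect_true(passed(rep))
  expect_equal(nrow(entries(rep)), 0L)
})

test_that("numeric drift beyond rtol is reported with a parsable path", {
  a <- mkModel(62000); b <- mkModel(61999)
  rep <- compareModels(a, b, rtol = 1e-6)
  expect_false(passed(rep))
  expect_equal(nrow(entries(rep)), 1L)
  expect_match(entries(rep)$path, "^events\\.size_change\\.pop0")
  expect_false(passed(compareModels(b, a, rtol = 1e-6)))  # symmetric
  # a looser tolerance accepts the same pair
  expect_true(passed(compareModels(a, b, rtol = 1e-3)))
})

test_that("structural mismatches are always flagged", {
  withOv <- mkModel(override = 9.4e-9)
  without <- mkModel()
  rep <- compareModels(withOv, without)
  expect_false(passed(rep))
  expect_true("mutation_rate_override" %in% entries(rep)$path)

  extra <- mkModel(extraEvent = sizeChangeEvent(100, "pop0", 500))
  rep2 <- compareModels(mkModel(), extra)
  expect_false(passed(rep2))
  expect_match(entries(rep2)$path, "unmatched|events", all = FALSE)

  twoPop <- DemographicModel("x", c("pop0", "p1"), c(pop0 = 90, p1 = 10),
                             events = list(splitEvent(10, "p1", "pop0")))
  rep3 <- compareModels(mkModel(), twoPop)
  expect_false(passed(rep3))
  expect_match(entries(rep3)$path, "populations", all = FALSE)
  # paths are unique and dot-separated
  expect_false(any(duplicated(entries(rep3)$path)))
})

test_that("rate audits reproduce the published cattle discrepancies", {
  bt <- builtinCatalog()[["BosTau"]]
  m <- mkModel(override = 9.4e-9)
  aud <- auditRateConsistency(m, bt,
    list(mutation_rate = 9.4e-9, recombination_rate = 1e-8))
  expect_equal(nrow(aud), 2L)
  mu <- aud[aud$quantity == "mutation_rate", ]
  expect_equal(mu$percent, 28)
  expect_true(mu$resolved)
  rr <- aud[aud$quantity == "recombination_rate", ]
  expect_equal(rr$percent, 8)
  expect_false(rr$resolved)

  # without the override the mutation discrepancy is unresolved
  aud2 <- auditRateConsistency(mkModel(), bt, list(mutation_rate = 9.4e-9))
  expect_false(aud2$resolved[1])

  expect_equal(nrow(auditRateConsistency(m, bt, list())), 0L)
})
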
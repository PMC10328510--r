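test_that("Ne derivation inverts theta = 4 mu Ne", {
  expect_equal(signif(deriveNeFromTheta(0.015, 3.5e-9), 3), 1.07e6)
  expect_equal(deriveNeFromTheta(0, 1e-8), 0)
  for (i in 1:20) {
    N <- runif(1, 1, 1e7)
    mu <- 10^runif(1, -10, -7)
    expect_equal(deriveNeFromTheta(4 * mu * N, mu), N, tolerance = 1e-12)
  }
  expect_error(deriveNeFromTheta(0.01, 0), "mu")
  expect_error(deriveNeFromTheta(-0.01, 1e-8), "theta")
})

test_that("rate discrepancies match the published cattle audits", {
  expect_equal(rateDiscrepancyPercent(1.2e-8, 9.4e-9), 27.66, tolerance = 1e-3)
  expect_equal(rateDiscrepancyPercent(1.2e-8, 9.4e-9, rounded = TRUE), 28)
  expect_equal(rateDiscrepancyPercent(1e-8, 9.26e-9), 7.99, tolerance = 1e-3)
  expect_equal(rateDiscrepancyPercent(1e-8, 9.26e-9, rounded = TRUE), 8)
  expect_equal(rateDiscrepancyPercent(3.3e-9, 3.3e-9), 0)
  # sign follows the direction of the comparison
  for (i in 1:20) {
    a <- runif(1, 1e-9, 1e-7); b <- runif(1, 1e-9, 1e-7)
    expect_equal(rateDiscrepancyPercent(a, b) > 0, a > b)
  }
  expect_error(rateDiscrepancyPercent(1e-8, 0), "rateB")
})

test_that("population size lookup is a pastward step function", {
  m1 <- constantSizeModel(6.2e4)
  for (t in c(0, 1, 1e3, 1e7))
    expect_equal(populationSizeAt(m1, "pop0", t), 62000)

  m <- DemographicModel("steps", "pop0", c(pop0 = 90),
                        events = list(sizeChangeEvent(100, "pop0", 62000)))
  expect_equal(populationSizeAt(m, "pop0", 50), 90)
  expect_equal(populationSizeAt(m, "pop0", 100), 62000)  # boundary is old epoch
  expect_equal(populationSizeAt(m, "pop0", 99.999), 90)
  expect_error(populationSizeAt(m, "nope", 0), "unknown population")

  ms <- DemographicModel("sp", c("a", "b"), c(a = 10, b = 20),
                         events = list(splitEvent(500, "b", "a")))
  expect_equal(populationSizeAt(ms, "b", 499), 20)
  expect_error(populationSizeAt(ms, "b", 500), "not extant")

  expect_equal(sizeEpochs(m), c(pop0 = 2L))
  expect_equal(sizeEpochs(m1), c(pop0 = 1L))
})

test_that("the model mutation-rate override supersedes the contig rate", {
  ctg <- testContig(mu = 1.2e-8)
  m <- DemographicModel("holstein-like", "pop0", c(pop0 = 90),
                        mutationRateOverride = 9.4e-9)
  expect_equal(effectiveMutationRate(m, ctg), 9.4e-9)
  expect_equal(effectiveMutationRate(constantSizeModel(1e4), ctg), 1.2e-8)
  ctgNA <- ctg; ctgNA@mutationRate <- NA_real_
  expect_error(effectiveMutationRate(constantSizeModel(1e4), ctgNA),
               "no mutation rate")
})

test_that("generations convert to years by multiplication", {
  expect_equal(generationsToYears(11260, 1 / 11), 1023.6, tolerance = 1e-4)
  expect_equal(generationsToYears(33000, 5), 165000)
  expect_equal(generationsToYears(0, 42), 0)
  expect_error(generationsToYears(10, 0), "generation time")
})

test_that("model validation reports violations", {
  good <- DemographicModel("two-epoch", "pop0", c(pop0 = 1e4),
                           events = list(sizeChangeEvent(1e3, "pop0", 1e5)))
  expect_length(validateModel(good), 0L)

  zero <- DemographicModel("z", "pop0", c(pop0 = 1e4),
                           events = list(sizeChangeEvent(10, "pop0", 0)))
  expect_match(validateModel(zero), "size", all = FALSE)

  ghost <- DemographicModel("g", c("a", "b"), c(a = 1, b = 1),
                            events = list(splitEvent(5, "b", "c")))
  expect_match(validateModel(ghost), "unknown population", all = FALSE)

  iso <- DemographicModel("iso", c("a", "b"), c(a = 1, b = 1))
  expect_match(validateModel(iso), "root", all = FALSE)

  mig <- DemographicModel("m", c("a", "b"), c(a = 1, b = 1),
    initialMigration = matrix(c(0, 1e-4, 0, 0), 2, 2,
                              dimnames = list(c("a", "b"), c("a", "b"))))
  expect_length(validateModel(mig), 0L)
})

test_that("constant-size models behave and reject bad Ne", {
  expect_equal(populationSizeAt(constantSizeModel(1), "pop0", 1e9), 1)
  expect_error(constantSizeModel(0), "Ne")
  expect_error(constantSizeModel(-5), "Ne")
})

test_that("demographic-model YAML round trips", {
  m <- DemographicModel("rt", c("a", "b"), c(a = 123.5, b = 9.4e3),
    events = list(sizeChangeEvent(100, "a", 62000),
                  migrationChangeEvent(50, "a", "b", 1e-5),
                  splitEvent(500, "b", "a")),
    initialMigration = matrix(c(0, 2e-5, 1e-5, 0), 2, 2,
                              dimnames = list(c("a", "b"), c("a", "b"))),
    mutationRateOverride = 9.4e-9,
    citations = list(Citation("fixture", 2026L,
                              reasons = "demographic_model")))
  m2 <- readDemographicModel(writeDemographicModel(m))
  expect_identical(m2@populations, m@populations)
  expect_equal(m2@initialSizes, m@initialSizes, tolerance = 1e-12)
  expect_equal(m2@initialMigration, m@initialMigration, tolerance = 1e-12)
  expect_equal(m2@mutationRateOverride, 9.4e-9)
  expect_equal(m2@events$time, m@events$time)
  expect_identical(m2@events$type, m@events$type)
  expect_true(passed(compareModels(m, m2)))

  sim <- readDemographicModel(system.file("extdata",
    "model_cattle_synthetic.yaml", package = "chromsim"))
  expect_equal(mutationRateOverride(sim), 9.4e-9)
  expect_equal(populationSizeAt(sim, "pop0", 33000), 62000)
  expect_equal(populationSizeAt(sim, "pop0", 0), 90)
})
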
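test_that("gc initiation rate realizes the crossover-relative fraction", {
  expect_equal(gcInitiationRate(1e-8, 0.83), 1e-8 * 0.83 / 0.17)
  expect_equal(gcInitiationRate(1e-8, 0.83), 4.882e-8, tolerance = 1e-3)
  expect_equal(gcInitiationRate(5e-9, 0), 0)
  expect_equal(gcInitiationRate(5e-9, 0.5), 5e-9)
  expect_error(gcInitiationRate(1e-8, 1), "fraction")
  expect_error(gcInitiationRate(1e-8, -0.1), "fraction")
})

test_that("tract lengths are geometric with the configured mean", {
  x <- sampleTractLength(518, n = 1e4, seed = 7)
  expect_true(all(x >= 1))
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 518), 3 * se)

  expect_true(all(sampleTractLength(1, n = 500, seed = 1) == 1))

  # goodness of fit against the closed-form pmf (1/3)(2/3)^(k-1)
  x <- sampleTractLength(3, n = 1e4, seed = 5)
  kmax <- 12
  obs <- tabulate(pmin(x, kmax + 1), nbins = kmax + 1)
  p <- (1 / 3) * (2 / 3)^(0:(kmax - 1))
  p <- c(p, 1 - sum(p))
  gof <- suppressWarnings(chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.001)

  expect_error(sampleTractLength(0.5), "mean")
})

test_that("zero-recombination runs give one tree and n-1 coalescences", {
  ctg <- testContig(L = 1e4, r = 0)
  m <- constantSizeModel(1e3)
  for (n in c(2, 6)) {
    sim <- simulateAncestry(n, ctg, m, seed = 100 + n)
    g <- genealogy(sim)
    expect_equal(unname(eventCounts(sim)[["coalescence"]]), n - 1)
    expect_equal(treeBreakpoints(g), c(0, 1e4))
    t0 <- marginalTree(g, 0)
    t1 <- marginalTree(g, 1e4 - 1)
    expect_true(ape::all.equal.phylo(t0, t1, use.edge.length = FALSE))
    expect_equal(sort(t0$tip.label), paste0("s", 0:(n - 1)))
  }
})

test_that("mean TMRCA matches 2 * ploidy * Ne * (1 - 1/n)", {
  Ne <- 1e3
  ctg <- testContig(L = 100, r = 0)
  m <- constantSizeModel(Ne)
  nrep <- 2000
  for (n in c(2, 5, 10)) {
    tm <- vapply(seq_len(nrep), function(i)
      tmrcaAt(simulateAncestry(n, ctg, m, seed = n * 100000 + i)),
      numeric(1))
    expected <- 2 * 2 * Ne * (1 - 1 / n)
    se <- sd(tm) / sqrt(nrep)
    expect_lt(abs(mean(tm) - expected), 3 * se)
  }
})

test_that("haploid coalescence uses rate 1/Ne", {
  ec <- builtinCatalog()[["EscCol"]]
  ctg <- makeContig(ec, "chr", lengthOverride = 100)
  m <- constantSizeModel(500)
  tm <- vapply(1:1500, function(i)
    tmrcaAt(simulateAncestry(2, ctg, m, seed = i)), numeric(1))
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 500), 3 * se)
})

test_that("piecewise-constant sizes reproduce the two-epoch closed form", {
  # recent size N1 until T, then N2: E[T2] = 2N1(1 - exp(-T/(2N1)))
  #                                + exp(-T/(2N1)) (T + 2N2)
  N1 <- 100; N2 <- 10000; T <- 150
  m <- DemographicModel("two", "pop0", c(pop0 = N1),
                        events = list(sizeChangeEvent(T, "pop0", N2)))
  ctg <- testContig(L = 100, r = 0)
  tm <- vapply(1:2000, function(i)
    tmrcaAt(simulateAncestry(2, ctg, m, seed = i)), numeric(1))
  lam <- 1 / (2 * N1)
  expected <- (1 / lam) * (1 - exp(-lam * T)) +
    exp(-lam * T) * (T + 2 * N2)
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - expected), 3 * se)
})

test_that("bacterial non-crossover mode logs no crossovers but does recombine", {
  ec <- builtinCatalog()[["EscCol"]]
  # initiation rate scaled up so events actually occur at test scale
  ctg <- makeContig(ec, "chr", lengthOverride = 1e5,
                    recombinationRateOverride = 1e-8)
  m <- constantSizeModel(5e3)
  sim <- simulateAncestry(5, ctg, m, seed = 21)
  cn <- eventCounts(sim)
  expect_equal(unname(cn[["crossover_drawn"]]), 0)
  expect_gt(cn[["gc_drawn"]], 0)
  expect_lte(cn[["gc_effective"]], cn[["gc_drawn"]])
  # tract lengths logged with the configured mean
  tl <- unlist(lapply(1:30, function(i)
    tractLengths(simulateAncestry(5, ctg, m, seed = i))))
  expect_gt(length(tl), 200)
  se <- sd(tl) / sqrt(length(tl))
  expect_lt(abs(mean(tl) - 542), 3 * se)
})

test_that("drawn event-type ratio recovers the gene-conversion fraction", {
  dm <- builtinCatalog()[["DroMel"]]
  ctg <- makeContig(dm, "2L", lengthOverride = 5e4,
                    recombinationRateOverride = 1e-8, mutationRateOverride = 0,
                    geneConversion = TRUE)
  m <- constantSizeModel(1e4)
  pooled <- poolEventLogs(lapply(1:60, function(i)
    simulateAncestry(5, ctg, m, seed = 7000 + i)))
  cn <- eventCounts(pooled)
  tot <- cn[["gc_drawn"]] + cn[["crossover_drawn"]]
  frac <- cn[["gc_drawn"]] / tot
  se <- sqrt(0.83 * 0.17 / tot)
  expect_lt(abs(frac - 0.83), 3 * se)
  expect_equal(eventSummary(pooled)$gc_fraction_drawn, unname(frac))
})

test_that("ancestral material is conserved across recombination and gc", {
  ctg <- testContig(L = 5e3, r = 5e-8, gc = TRUE, gcFraction = 0.6,
                    gcLength = 300)
  m <- constantSizeModel(2e3)
  for (i in 1:10) {
    sim <- simulateAncestry(4, ctg, m, seed = 400 + i)
    g <- genealogy(sim)
    expect_true(validObject(g))
    bks <- treeBreakpoints(g)
    probe <- unique(c(bks[-length(bks)],
                      floor((bks[-length(bks)] + bks[-1]) / 2)))
    for (p in probe) {
      tr <- marginalTree(g, p)   # errors if roots != 1
      expect_equal(sort(tr$tip.label), paste0("s", 0:3))
      expect_true(all(tr$edge.length >= 0))
    }
  }
})

test_that("simulations are bit-identical given the seed", {
  ctg <- testContig(L = 2e4, r = 1e-8, gc = TRUE)
  m <- constantSizeModel(5e3)
  a <- simulateAncestry(6, ctg, m, seed = 99)
  b <- simulateAncestry(6, ctg, m, seed = 99)
  expect_identical(nodes(genealogy(a)), nodes(genealogy(b)))
  expect_identical(edges(genealogy(a)), edges(genealogy(b)))
  expect_identical(eventCounts(a), eventCounts(b))
  c <- simulateAncestry(6, ctg, m, seed = 100)
  expect_false(identical(edges(genealogy(a)), edges(genealogy(c))))
})

test_that("small-sample tree topologies match the coalescent expectation", {
  # n = 3, no recombination: the first coalescence picks each pair with
  # probability 1/3
  ctg <- testContig(L = 10, r = 0)
  m <- constantSizeModel(100)
  nrep <- 5000
  firstPair <- vapply(seq_len(nrep), function(i) {
    g <- genealogy(simulateAncestry(3, ctg, m, seed = i))
    nd <- nodes(g); e <- edges(g)
    first <- nd$id[nd$time > 0][which.min(nd$time[nd$time > 0])]
    paste(sort(e$child[e$parent == first]), collapse = ",")
  }, character(1))
  obs <- table(factor(firstPair, levels = c("0,1", "0,2", "1,2")))
  gof <- chisq.test(obs, p = rep(1 / 3, 3))
  expect_gt(gof$p.value, 0.001)
})

test_that("engine input validation catches bad requests", {
  ctg <- testContig()
  m <- constantSizeModel(1e3)
  expect_error(simulateAncestry(1, ctg, m, seed = 1), "at least two")
  expect_error(simulateAncestry(c(x = 2), ctg, m, seed = 1),
               "unknown population")
  expect_error(simulateAncestry(c(pop0 = 0.5), ctg, m, seed = 1),
               "positive integers")
  bad <- DemographicModel("b", "pop0", c(pop0 = -1))
  expect_error(simulateAncestry(2, ctg, bad, seed = 1), "invalid")
})

test_that("whole-contig gc initiation draws more ineffective events", {
  ctg <- testContig(L = 2e4, r = 1e-8, gc = TRUE, gcFraction = 0.8,
                    gcLength = 200)
  m <- constantSizeModel(5e3)
  sim <- simulateAncestry(4, ctg, m, seed = 31, gcSpan = "contig")
  cn <- eventCounts(sim)
  expect_lte(cn[["gc_effective"]], cn[["gc_drawn"]])
  expect_true(validObject(genealogy(sim)))
})
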
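test_that("summary statistics match hand counts", {
  h <- rbind(s0 = c("A", "C", "G"), s1 = c("T", "C", "T"))
  # 2 mismatching sites out of L = 100... first and third columns differ
  st <- summaryStats(h, L = 100)
  expect_equal(st@S, 2L)
  expect_equal(st@pi, 0.02)

  h2 <- rbind(s0 = rep("A", 3), s1 = rep("A", 3))
  st2 <- summaryStats(h2, L = 50)
  expect_equal(st2@S, 0L)
  expect_equal(st2@pi, 0)
  expect_equal(st2@thetaW, 0)

  # two haplotypes, L = 100, 3 mismatches
  h3 <- cbind(rbind(s0 = c("A", "A", "A"), s1 = c("C", "C", "C")))
  st3 <- summaryStats(h3, L = 100)
  expect_equal(st3@pi, 0.03)
  expect_equal(st3@S, 3L)
  expect_equal(st3@thetaW, 3 / (1 * 100))  # a_1 = 1

  expect_error(summaryStats(h[1, , drop = FALSE], L = 10), "2 haplotypes")
})

test_that("the unfolded SFS counts each derived allele by frequency class", {
  # 4 haplotypes, derived counts (1, 1, 2) -> sfs (2, 1, 0)
  h <- rbind(s0 = c("C", "A", "G"),
             s1 = c("A", "A", "G"),
             s2 = c("A", "T", "A"),
             s3 = c("A", "A", "A"))
  st <- summaryStats(h, L = 10, ancestral = c("A", "A", "A"))
  expect_equal(st@sfs, c(2, 1, 0))
  expect_false(st@folded)
  # a multi-allelic site contributes one entry per derived allele
  h2 <- rbind(s0 = "C", s1 = "G", s2 = "A", s3 = "A")
  st2 <- summaryStats(h2, L = 10, ancestral = "A")
  expect_equal(st2@sfs, c(2, 0, 0))
  expect_equal(st2@S, 1L)
})

test_that("branch diversity equals 2 T mu for a pair and 0 for mu = 0", {
  g <- pairGenealogy(tmrca = 1234, L = 100)
  expect_equal(branchDiversity(g, 1e-6), 2 * 1234 * 1e-6)
  expect_equal(branchDiversity(g, 0), 0)
  # caterpillar: mean pairwise TMRCA = (30*3 + 20*2 + 10)/6
  expect_equal(branchDiversity(toyGenealogy(), 1e-4),
               2 * 1e-4 * (30 * 3 + 20 * 2 + 10) / 6)
})

test_that("site-mode pi agrees with branch-mode pi in expectation", {
  # low per-site theta: at high per-site rates discrete-site saturation
  # (recurrent hits masking differences) pushes site pi below branch pi
  ctg <- testContig(L = 1e3, r = 1e-8, mu = NA)
  m <- constantSizeModel(2e3)
  mu <- 2e-7
  nrep <- 300
  sitePi <- numeric(nrep); branchPi <- numeric(nrep)
  for (i in seq_len(nrep)) {
    sim <- simulateAncestry(4, ctg, m, seed = 3000 + i)
    v <- throwMutations(sim, mu, seed = 4000 + i)
    sitePi[i] <- if (nrow(sites(v))) summaryStats(v)@pi else 0
    branchPi[i] <- branchDiversity(sim, mu)
  }
  d <- sitePi - branchPi
  se <- sd(d) / sqrt(nrep)
  expect_lt(abs(mean(d)), 3 * se)
})

test_that("neutral constant-size expectations hold: pi, S, SFS, thetaW", {
  Ne <- 1e3; mu <- 2.5e-7; L <- 1e4; n <- 10
  theta <- 4 * Ne * mu
  ctg <- testContig(L = L, r = 0, mu = NA)
  m <- constantSizeModel(Ne)
  nrep <- 800
  S <- numeric(nrep); pi <- numeric(nrep); tw <- numeric(nrep)
  sfs <- matrix(0, nrep, n - 1)
  for (i in seq_len(nrep)) {
    sim <- simulateAncestry(n, ctg, m, seed = 50000 + i)
    v <- throwMutations(sim, mu, seed = 60000 + i, fixedAncestral = TRUE)
    st <- summaryStats(v)
    S[i] <- st@S; pi[i] <- st@pi; tw[i] <- st@thetaW
    sfs[i, ] <- st@sfs
  }
  an <- sum(1 / seq_len(n - 1))
  expect_lt(abs(mean(S) - theta * an * L), 3 * sd(S) / sqrt(nrep))
  expect_lt(abs(mean(pi) - theta), 3 * sd(pi) / sqrt(nrep))
  # SFS class means proportional to 1/i
  for (i in 1:(n - 1)) {
    expected <- theta * L / i
    se <- sd(sfs[, i]) / sqrt(nrep)
    expect_lt(abs(mean(sfs[, i]) - expected), 3 * se + 0.02 * expected)
  }
  # Watterson and pi agree in expectation under neutrality
  d <- tw - pi
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(nrep))
})

test_that("event summaries expose the drawn gc fraction when defined", {
  log <- emptyLogWith(gc_drawn = 83, crossover_drawn = 17)
  expect_equal(eventSummary(log)$gc_fraction_drawn, 0.83)

  empty <- emptyLogWith()
  es <- eventSummary(empty)
  expect_null(es$gc_fraction_drawn)
  expect_true(all(unlist(es[c("coalescence", "gc_drawn")]) == 0))

  coalOnly <- emptyLogWith(coalescence = 5)
  expect_null(eventSummary(coalOnly)$gc_fraction_drawn)
})
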
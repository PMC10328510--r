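test_that("mu = 0 yields an empty variant table", {
  v <- throwMutations(toyGenealogy(), 0, seed = 1)
  expect_equal(nrow(sites(v)), 0L)
  expect_equal(dim(haplotypes(v)), c(4L, 0L))
})

test_that("mutation counts follow the Poisson mass of the genealogy", {
  # toy genealogy: total branch length 90 gens over 100 bp -> mass 9000
  g <- toyGenealogy()
  mu <- 1e-3
  cnt <- vapply(1:1000, function(i)
    nrow(mutations(throwMutations(g, mu, seed = i))), numeric(1))
  expected <- mu * 9000
  se <- sd(cnt) / sqrt(length(cnt))
  expect_lt(abs(mean(cnt) - expected), 3 * se)
})

test_that("derived states are uniform over the three other nucleotides", {
  g <- pairGenealogy(tmrca = 50, L = 10000)
  v <- throwMutations(g, 0.01, seed = 8, fixedAncestral = TRUE)
  m <- mutations(v)
  # mutations directly below the root with no older mutation on the same
  # edge and site have parent state exactly "A"
  key <- paste(m$site, m$child)
  oldest <- !duplicated(key)  # rows are sorted oldest-first within edge
  fromA <- m$derived[oldest]
  expect_gt(length(fromA), 3000)
  gof <- chisq.test(table(factor(fromA, levels = c("C", "G", "T"))),
                    p = rep(1 / 3, 3))
  expect_gt(gof$p.value, 0.001)
  expect_false(any(fromA == "A"))
})

test_that("genotypes propagate mutations root-to-tip", {
  g <- toyGenealogy()
  # one mutation on the edge above the (s0, s1) cherry
  sitesDf <- data.frame(position = 10, ancestral = "A",
                        stringsAsFactors = FALSE)
  mut <- data.frame(site = 1L, parent = 5, child = 4, derived = "C",
                    time = 15, stringsAsFactors = FALSE)
  v <- new("VariantTable", sites = sitesDf, mutations = mut,
           haplotypes = matrix(NA_character_, 4, 1,
                               dimnames = list(paste0("s", 0:3), "10")),
           contigLength = 100, sampleNames = paste0("s", 0:3))
  h <- genotypes(v, g)
  expect_equal(unname(h[, 1]), c("C", "C", "A", "A"))

  # two successive mutations on one path (A->C above node 5, C->G above
  # node 4): tips below 4 show G, the other lineage below 5 shows C
  mut2 <- rbind(
    data.frame(site = 1L, parent = 6, child = 5, derived = "C", time = 25,
               stringsAsFactors = FALSE),
    data.frame(site = 1L, parent = 5, child = 4, derived = "G", time = 15,
               stringsAsFactors = FALSE))
  v2 <- v; v2@mutations <- mut2
  h2 <- genotypes(v2, g)
  expect_equal(unname(h2[, 1]), c("G", "G", "C", "A"))
  expect_equal(length(setdiff(unique(h2[, 1]), "A")), 2L)  # multi-allelic

  # no mutations: all ancestral
  v3 <- v; v3@mutations <- mut[0, ]
  expect_true(all(genotypes(v3, g) == "A"))
})

test_that("recurrent mutation keeps allele counts consistent", {
  ctg <- testContig(L = 500, r = 1e-8, mu = NA)
  m <- constantSizeModel(2e4)
  for (i in 1:8) {
    sim <- simulateAncestry(6, ctg, m, seed = 500 + i)
    v <- throwMutations(sim, 5e-7, seed = 600 + i)
    if (!nrow(sites(v))) next
    h <- haplotypes(v)
    nmut <- table(factor(mutations(v)$site, levels = seq_len(nrow(sites(v)))))
    for (j in seq_len(nrow(sites(v)))) {
      alleles <- unique(c(sites(v)$ancestral[j], h[, j]))
      expect_lte(length(alleles), 1 + as.integer(nmut[j]))
    }
    # stored haplotypes are reproducible from the mutation table
    expect_identical(genotypes(v, sim), h)
  }
})

test_that("expected segregating sites equal mu L x total branch length", {
  g <- toyGenealogy()  # mass 9000 bp*gen
  mu <- 5e-4
  S <- vapply(1:800, function(i) {
    v <- throwMutations(g, mu, seed = 2000 + i, fixedAncestral = TRUE)
    summaryStats(v)@S
  }, numeric(1))
  # at this rate nearly every mutation is a distinct segregating site
  expected <- mu * 9000
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expected), 3 * se + 0.05 * expected)
})

test_that("mutation layering is deterministic given its own seed", {
  sim <- simulateAncestry(4, testContig(L = 2e3, r = 1e-8),
                          constantSizeModel(5e3), seed = 77)
  a <- throwMutations(sim, 1e-6, seed = 11)
  b <- throwMutations(sim, 1e-6, seed = 11)
  expect_identical(sites(a), sites(b))
  expect_identical(mutations(a), mutations(b))
  expect_identical(haplotypes(a), haplotypes(b))
  c <- throwMutations(sim, 1e-6, seed = 12)
  expect_false(identical(mutations(a), mutations(c)))
})
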
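test_that("reciprocal overlap uses strict thresholds and is symmetric", {
  a <- makeCallset("chr1", 1000L, 500L, "DEL")
  expect_true(reciprocalOverlap(a, a))

  # [0,1000) vs [500,1500): overlap 500 is not > 0.5*1000
  x <- makeCallset("chr1", 0L, 1000L, "DEL")
  y <- makeCallset("chr1", 500L, 1000L, "DEL")
  expect_false(reciprocalOverlap(x, y))
  expect_true(reciprocalOverlap(x, y, threshold = 0.49))

  expect_false(reciprocalOverlap(makeCallset("chr1", 0L, 100L, "DEL"),
                                 makeCallset("chr2", 0L, 100L, "DEL")))
  expect_false(reciprocalOverlap(makeCallset("chr1", 0L, 100L, "DEL"),
                                 makeCallset("chr1", 0L, 100L, "INS")))
  expect_true(reciprocalOverlap(makeCallset("chr1", 0L, 100L, "DEL"),
                                makeCallset("chr1", 0L, 100L, "INS"),
                                typeAware = FALSE))
})

test_that("reciprocal overlap agrees with brute-force interval arithmetic", {
  set.seed(11)
  for (i in 1:200) {
    s1 <- sample(0:2000, 1); l1 <- sample(50:800, 1)
    s2 <- sample(0:2000, 1); l2 <- sample(50:800, 1)
    t <- runif(1, 0.2, 0.8)
    a <- makeCallset("chr1", s1, l1, "DEL"); b <- makeCallset("chr1", s2, l2, "DEL")
    ov <- max(0, min(s1 + l1, s2 + l2) - max(s1, s2))
    brute <- ov > t * l1 && ov > t * l2
    expect_equal(unname(reciprocalOverlap(a, b, threshold = t)), brute)
    # symmetry and threshold monotonicity
    expect_equal(reciprocalOverlap(a, b, threshold = t),
                 reciprocalOverlap(b, a, threshold = t))
    if (brute) expect_true(reciprocalOverlap(a, b, threshold = t / 2))
  }
})

test_that("callset matching is one-to-one with sane novelty edge cases", {
  cs <- randomCallset(40, c(chr1 = 2e5), seed = 21)
  m <- matchCallsets(cs, cs)
  expect_equal(m$novelty_fraction, 0)
  expect_equal(nrow(m$matches), length(cs))
  expect_false(anyDuplicated(m$matches$query_idx) > 0)
  expect_false(anyDuplicated(m$matches$ref_idx) > 0)

  m0 <- matchCallsets(cs, SVCallset())
  expect_equal(m0$novelty_percent, 100L)
  expect_equal(nrow(m0$matches), 0L)
})

test_that("summaries report counts, medians and footprint correctly", {
  cs <- randomCallset(50, c(chr1 = 3e5), seed = 31,
                      types = c("DEL", "INS", "DUP", "INV"))
  sm <- svSummary(cs, 3e5)
  tp <- svType(cs); ln <- svLength(cs)
  for (t in c("DEL", "INS", "DUP", "INV")) {
    expect_equal(unname(sm$counts[t]), sum(tp == t))
    if (sum(tp == t) > 0) {
      sorted <- sort(ln[tp == t])          # sort-based median oracle
      n <- length(sorted)
      med <- if (n %% 2) sorted[(n + 1) / 2] else mean(sorted[n / 2 + 0:1])
      expect_equal(unname(sm$median_length[t]), med)
    }
  }
  expect_equal(sm$total, 50L)
  gr <- svRanges(cs)
  fp <- sum(GenomicRanges::width(GenomicRanges::reduce(gr[tp != "INS"]))) +
    sum(ln[tp == "INS"])
  expect_equal(sm$affected_bp, fp)

  sme <- svSummary(SVCallset(), 1e6)
  expect_equal(sme$total, 0L)
  expect_true(all(is.na(sme$median_length)))
})

test_that("window densities follow the half-open start convention", {
  cl <- c(chr1 = 1e6)
  cs <- makeCallset("chr1", c(100L, 499999L, 500000L), 100L, "DEL")
  wd <- windowDensity(cs, cl, window = 5e5)
  expect_equal(nrow(wd), 2L)
  expect_equal(wd$total, c(2L, 1L))     # start0 = 500000 falls in window 2

  cs2 <- randomCallset(300, c(chr1 = 1e6, chr2 = 7e5), seed = 41)
  wd2 <- windowDensity(cs2, c(chr1 = 1e6, chr2 = 7e5), window = 1e5)
  s0 <- GenomicRanges::start(svRanges(cs2)) - 1L
  cn <- as.character(GenomicRanges::seqnames(svRanges(cs2)))
  for (ch in c("chr1", "chr2")) {
    oracle <- table(factor(s0[cn == ch] %/% 1e5 + 1L,
                           levels = seq_len(ceiling(c(chr1 = 1e6, chr2 = 7e5)[[ch]] / 1e5))))
    expect_equal(wd2$total[wd2$chrom == ch], unname(as.integer(oracle)))
  }
  bad <- makeCallset("chr1", 2e6, 100L, "DEL")
  expect_error(windowDensity(bad, cl), "beyond")
})

test_that("subtelomeric enrichment is calibrated and extreme cases behave", {
  cl <- c(chr1 = 1e6, chr2 = 1e6)
  cs <- randomCallset(200, cl - 3000L, seed = 51)
  r <- subtelomericEnrichment(cs, cl, margin = 1e5, n_perm = 500L, seed = 2)
  expect_lt(abs(r$fold - 1), 0.5)
  expect_gt(r$p, 0.05)

  # everything inside the margins: maximal fold, minimal p
  ends <- makeCallset("chr1", c(seq(0L, 50000L, by = 5000L)), 100L, "DEL")
  r2 <- subtelomericEnrichment(ends, cl, margin = 1e5, n_perm = 199L, seed = 3)
  expect_equal(r2$p, 1 / 200)
  expect_equal(r2$n_subtelomeric, length(ends))

  # doubling the margin matches a brute-force recount
  r3 <- subtelomericEnrichment(cs, cl, margin = 2e5, n_perm = 1L, seed = 1)
  s0 <- GenomicRanges::start(svRanges(cs)) - 1L
  len <- cl[as.character(GenomicRanges::seqnames(svRanges(cs)))]
  ns <- sum(s0 < 2e5 | s0 >= len - 2e5)
  sub_bp <- sum(pmin(cl, 4e5)); else_bp <- sum(cl) - sub_bp
  expect_equal(r3$fold, (ns / sub_bp) / ((length(cs) - ns) / else_bp))
  expect_equal(r3$n_subtelomeric, ns)

  short <- c(chr1 = 1e6, chrS = 1e5)
  cs1 <- randomCallset(50, c(chr1 = 1e6 - 3000L), seed = 52)
  rs <- subtelomericEnrichment(cs1, short, margin = 1e5, n_perm = 10L, seed = 1)
  expect_equal(rs$flagged_chroms, "chrS")
  expect_error(subtelomericEnrichment(cs, c(chr1 = 1e6), margin = 1e5,
                                      n_perm = 10L, seed = 1),
               "unknown chromosome")
})

test_that("genotype categories partition the callset", {
  tr <- simFixture()$sim$truth
  g <- simulateGenotypes(tr, n_individuals = 5L, fixed_fraction = 0.3,
                         invalidation_rate_repeat_ins = 0.7, seed = 13)
  sm <- genotypeSummary(g)
  expect_equal(sm$n_present + sm$n_invalidated + sm$n_absent, sm$n_total)
  expect_equal(sm$n_fixed + sm$n_polymorphic, sm$n_present)
  # planted fixed rows (all hom-alt) are recovered as fixed
  planted_fixed <- which(apply(g == "1/1", 1L, function(x) all(!is.na(x) & x)))
  expect_equal(sm$n_fixed, length(planted_fixed))
  planted_inval <- which(apply(g, 1L, function(x) all(is.na(x))))
  expect_equal(sm$n_invalidated, length(planted_inval))

  allhom <- matrix("1/1", 10, 4)
  expect_equal(genotypeSummary(allhom)$fixed_pct, 100)

  # carrier rule counts all-het rows as fixed, the hom rule does not
  het <- matrix("0/1", 5, 3)
  expect_equal(genotypeSummary(het)$n_fixed, 0L)
  expect_equal(genotypeSummary(het, fixedRule = "carrier")$n_fixed, 5L)
})
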
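test_that("ancestral genome generation is deterministic with tiled repeats", {
  g1 <- generateAncestralGenome(1L, 2e4, repeat_fraction = 0.3, seed = 5)
  g2 <- generateAncestralGenome(1L, 2e4, repeat_fraction = 0.3, seed = 5)
  expect_identical(as.character(chromSeqs(g1)), as.character(chromSeqs(g2)))

  g0 <- generateAncestralGenome(1L, 1e5, gc = 0.41, repeat_fraction = 0, seed = 1)
  expect_equal(length(repeatAnnotation(g0)), 0L)
  expect_equal(unname(chromLengths(g0)), 1e5)
  af <- Biostrings::alphabetFrequency(chromSeqs(g0), baseOnly = TRUE)
  gc <- sum(af[, c("C", "G")]) / sum(af[, c("A", "C", "G", "T")])
  expect_lt(abs(gc - 0.41), 0.02)

  gr <- generateAncestralGenome(2L, 2e5, gc = 0.41, repeat_fraction = 0.5,
                                seed = 7)
  frac <- sum(GenomicRanges::width(GenomicRanges::reduce(repeatAnnotation(gr)))) /
    sum(chromLengths(gr))
  expect_gte(frac, 0.45); expect_lte(frac, 0.55)

  expect_error(generateAncestralGenome(1L, 2e4, repeat_fraction = 0.97),
               "repeat_fraction")
})

test_that("a single ape-stem deletion shortens exactly the ape genomes", {
  anc <- generateAncestralGenome(1L, 5e4, repeat_fraction = 0, seed = 2)
  specs <- list(branchSpec("ape_ancestor", n_del = 1L,
                           del_len = list(meanlog = log(500), sdlog = 0),
                           subst_rate = 0))
  sim <- evolveGenomes(anc, specs, seed = 3)
  la <- unname(chromLengths(anc))
  lens <- vapply(sim$genomes, function(g) unname(chromLengths(g)), 1)
  expect_equal(unname(lens[c("macaque", "marmoset")]), c(la, la))
  expect_equal(unname(lens[c("human", "chimp", "gorilla", "orangutan", "gibbon")]),
               rep(la - 500, 5))
  expect_equal(length(sim$truth), 1L)
  expect_equal(S4Vectors::mcols(sim$truth)$type, "DEL")
  # macaque and marmoset identical to the ancestor (no other events)
  expect_identical(as.character(chromSeqs(sim$genomes$macaque)),
                   as.character(chromSeqs(anc)))
})

test_that("a macaque-branch deletion separates macaque from apes and outgroup", {
  anc <- generateAncestralGenome(1L, 5e4, repeat_fraction = 0, seed = 2)
  specs <- list(branchSpec("macaque", n_del = 1L,
                           del_len = list(meanlog = log(400), sdlog = 0),
                           subst_rate = 0))
  sim <- evolveGenomes(anc, specs, seed = 3)
  expect_equal(unname(chromLengths(sim$genomes$macaque)),
               unname(chromLengths(anc)) - 400)
  expect_identical(as.character(chromSeqs(sim$genomes$human)),
                   as.character(chromSeqs(anc)))
  expect_identical(as.character(chromSeqs(sim$genomes$marmoset)),
                   as.character(chromSeqs(anc)))
  # ape-centric polarity: macaque's loss is an insertion in the ape frame
  expect_equal(S4Vectors::mcols(sim$truth)$type, "INS")
  expect_equal(S4Vectors::mcols(sim$truth)$event_type, "DEL")
})

test_that("default spec truth table has one row per planted event", {
  sim <- bigSimFixture()$sim
  expect_equal(length(sim$truth), 60L + 40L + 4L * 20L)
  tb <- table(S4Vectors::mcols(sim$truth)$branch)
  expect_equal(unname(tb[c("ape_ancestor", "macaque")]), c(60L, 40L),
               ignore_attr = TRUE)
})

test_that("tip lengths obey conservation and truth projection is exact", {
  fx <- simFixture()
  sim <- fx$sim; anc <- fx$anc
  ev <- sim$events
  paths <- list(human = c("ape_ancestor", "great_ape_ancestor", "human"),
                macaque = "macaque", marmoset = "marmoset")
  for (tp in names(paths)) {
    pe <- ev[ev$branch %in% paths[[tp]], ]
    expected <- sum(chromLengths(anc)) -
      sum(pe$len[pe$type == "DEL"]) + sum(pe$len[pe$type %in% c("INS", "DUP")])
    expect_equal(sum(chromLengths(sim$genomes[[tp]])), expected)
  }
  # every ape-stem DEL's sequence is present verbatim at its macaque coords
  tr <- sim$truth; mc <- S4Vectors::mcols(tr)
  sel <- which(mc$branch == "ape_ancestor" & mc$type == "DEL")
  mac <- sim$genomes$macaque
  for (i in sel) {
    cn <- as.character(GenomicRanges::seqnames(tr))[i]
    expect_identical(substr(as.character(chromSeqs(mac)[[cn]]),
                            GenomicRanges::start(tr)[i],
                            GenomicRanges::end(tr)[i]),
                     mc$seq[i])
  }
})

test_that("identical seeds reproduce the evolved genomes byte for byte", {
  anc <- generateAncestralGenome(1L, 3e4, repeat_fraction = 0.1, seed = 4)
  specs <- defaultBranchSpecs(n_ape_ancestor = 4L, n_macaque = 2L, n_per_tip = 2L)
  s1 <- evolveGenomes(anc, specs, seed = 9)
  s2 <- evolveGenomes(anc, specs, seed = 9)
  expect_identical(lapply(s1$genomes, function(g) as.character(chromSeqs(g))),
                   lapply(s2$genomes, function(g) as.character(chromSeqs(g))))
  expect_identical(s1$events, s2$events)
})

test_that("gapped references conserve bases and invert through findGaps", {
  mac <- simFixture()$sim$genomes$macaque
  g0 <- makeGappedReference(mac, n_gaps = 0L, seed = 1)
  expect_identical(as.character(chromSeqs(g0$genome)),
                   as.character(chromSeqs(mac)))
  expect_equal(length(g0$truth), 0L)

  gp <- makeGappedReference(mac, n_gaps = 10L, gap_len = c(100L, 2000L), seed = 5)
  found <- findGaps(gp$genome)
  expect_equal(length(found), 10L)
  expect_equal(GenomicRanges::start(found), GenomicRanges::start(gp$truth))
  expect_equal(GenomicRanges::end(found), GenomicRanges::end(gp$truth))
  nN <- sum(Biostrings::vcountPattern("N", chromSeqs(gp$genome)))
  expect_equal(nN, sum(GenomicRanges::width(gp$truth)))
  expect_equal(sum(chromLengths(gp$genome)), sum(chromLengths(mac)))
})

test_that("enhancer simulation plants the requested labels and validates", {
  e0 <- simulateEnhancerMatrix(200L, 0, 0, seed = 1)
  expect_true(all(e0$truth == "null"))
  expect_error(simulateEnhancerMatrix(200L, frac_gain = 0.5, frac_loss = 0,
                                      effect_log2fc = 0),
               "non-positive effect")
  e <- simulateEnhancerMatrix(2000L, 0.05, 0.05, c(human = 3L, chimp = 2L,
                                                   macaque = 3L),
                              effect_log2fc = 2, cv = 0.15, seed = 3)
  expect_equal(sum(e$truth == "gain"), 100L)
  expect_equal(sum(e$truth == "loss"), 100L)
  expect_equal(dim(SummarizedExperiment::assay(e$matrix)), c(2000L, 8L))
})

test_that("genotype simulation honours fixation and invalidation", {
  tr <- simFixture()$sim$truth
  g1 <- simulateGenotypes(tr, n_individuals = 5L, fixed_fraction = 1,
                          invalidation_rate_repeat_ins = 0, seed = 2)
  expect_true(all(g1 == "1/1"))

  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:10 * 1000L, width = 100L))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    id = paste0("s", 1:10), type = "INS", svlen = 100L,
    in_repeat = TRUE)
  g2 <- simulateGenotypes(gr, n_individuals = 3L,
                          invalidation_rate_repeat_ins = 1, seed = 2)
  expect_true(all(is.na(g2)))

  gr3 <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq_len(1000L) * 500L, width = 60L))
  S4Vectors::mcols(gr3) <- S4Vectors::DataFrame(
    id = sprintf("s%04d", 1:1000), type = "DEL", svlen = 60L,
    in_repeat = FALSE)
  g3 <- simulateGenotypes(gr3, n_individuals = 5L, fixed_fraction = 0.13,
                          seed = 5)
  n_fixed <- sum(apply(g3 == "1/1", 1L, all))
  ci <- qbinom(c(0.005, 0.995), 1000L, 0.13)
  # fixed count inside the central 99% binomial interval (plus the rare
  # polymorphic draw that happens to be all-hom)
  expect_gte(n_fixed, ci[1]); expect_lte(n_fixed, ci[2] + 5)
})
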
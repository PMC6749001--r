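# The concordance, intersection and outgroup-classification layers, mostly
# exercised against the cached substitution-free simulation.

perApeFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simFixture()$sim
      mac <- sim$genomes$macaque
      cache <<- lapply(sim$genomes[c("human", "chimp", "gorilla", "orangutan")],
                       function(g) callBidirectional(mac, g))
    }
    cache
  }
})

test_that("forward/reverse concordance is a monotone filter", {
  fwd <- perApeFixture()$human
  expect_equal(svID(bidirectionalConcordance(fwd, fwd)), svID(fwd))
  expect_equal(length(bidirectionalConcordance(fwd, SVCallset())), 0L)

  # an injected one-direction artifact is removed, real calls retained
  art <- svRanges(makeCallset("chr1", 180000L, 120L, "DEL", id = "artifact"))
  S4Vectors::mcols(art)$seq <- NA_character_
  S4Vectors::mcols(art)$query_chrom <- "chr1"
  S4Vectors::mcols(art)$query_start <- 180000L
  S4Vectors::mcols(art)$query_end <- 180120L
  fwd_plus <- SVCallset(c(svRanges(fwd), art))
  kept <- bidirectionalConcordance(fwd_plus, fwd)
  expect_setequal(svID(kept), svID(fwd))
})

test_that("reverse-frame projection swaps roles losslessly", {
  sim <- simFixture()$sim
  mac <- sim$genomes$macaque
  rev <- callPairwiseSVs(sim$genomes$human, mac)
  proj <- swapFrame(rev)
  fwd <- callPairwiseSVs(mac, sim$genomes$human)
  m <- matchCallsets(fwd, proj)
  expect_equal(nrow(m$matches), length(fwd))
  # double swap is the identity on coordinates and types
  back <- swapFrame(proj)
  expect_equal(sort(GenomicRanges::start(svRanges(back))),
               sort(GenomicRanges::start(svRanges(rev))))
  expect_equal(table(svType(back)), table(svType(rev)))
})

test_that("cross-ape intersection keeps shared variants only", {
  per_ape <- perApeFixture()
  sim <- simFixture()$sim
  cand <- intersectAcrossApes(per_ape)
  mcC <- S4Vectors::mcols(svRanges(cand))
  expect_true(all(c("support_human", "support_chimp", "support_gorilla",
                    "support_orangutan") %in% colnames(mcC)))
  expect_true(all(!is.na(mcC$support_chimp)))

  tr <- sim$truth; mcT <- S4Vectors::mcols(tr)
  m <- matchCallsets(SVCallset(tr), cand)
  matched <- logical(length(tr)); matched[m$matches$query_idx] <- TRUE
  shared <- mcT$branch %in% c("ape_ancestor", "macaque")
  expect_true(all(matched[shared]))       # all shared events survive
  expect_true(all(!matched[!shared]))     # no single-ape-tip event survives
  expect_equal(length(cand), sum(shared))

  # order independence of the per-ape map
  cand_rev <- intersectAcrossApes(rev(per_ape))
  expect_setequal(svID(cand_rev), svID(cand))

  # a variant absent from one ape set is excluded
  drop_one <- per_ape
  keep <- svID(drop_one$gorilla) != S4Vectors::mcols(svRanges(cand))$support_gorilla[1]
  drop_one$gorilla <- drop_one$gorilla[which(keep)]
  cand2 <- intersectAcrossApes(drop_one)
  expect_equal(length(cand2), length(cand) - 1L)
  expect_error(intersectAcrossApes(per_ape["human"]), "2")
})

test_that("human-coordinate overlay annotates matched calls and flags the rest", {
  per_ape <- perApeFixture()
  cand <- intersectAcrossApes(per_ape)
  ov <- overlayHumanCoordinates(cand, per_ape$human)
  mcO <- S4Vectors::mcols(svRanges(ov))
  expect_true(all(mcO$human_annotated))
  expect_true(all(!is.na(mcO$human_start)))

  ov2 <- overlayHumanCoordinates(cand, SVCallset())
  expect_true(all(!S4Vectors::mcols(svRanges(ov2))$human_annotated))
})

test_that("outgroup classification polarizes shared SVs by branch of origin", {
  sim <- simFixture()$sim
  mac <- sim$genomes$macaque
  cand <- intersectAcrossApes(perApeFixture())
  cand <- classifyOutgroup(cand, mac, sim$genomes$marmoset)
  mcC <- S4Vectors::mcols(svRanges(cand))
  expect_true(all(mcC$identity_prefilter >= 0.85, na.rm = TRUE))

  tr <- sim$truth; mcT <- S4Vectors::mcols(tr)
  m <- matchCallsets(SVCallset(tr), cand)
  cls <- rep(NA_character_, length(tr))
  cls[m$matches$query_idx] <- mcC$outgroup_class[m$matches$ref_idx]
  expect_true(all(cls[mcT$branch == "ape_ancestor"] == "high_confident"))
  expect_true(all(cls[mcT$branch == "macaque"] == "false"))

  # an outgroup whose locus is wholly deleted cannot polarize: uncertain
  one <- cand[1]
  gr1 <- svRanges(one)
  cn <- as.character(GenomicRanges::seqnames(gr1))
  cut <- data.frame(chrom = cn,
                    pos0 = GenomicRanges::start(gr1) - 3000L,
                    type = "DEL",
                    len = GenomicRanges::width(gr1) + 6000L,
                    seq = NA_character_)
  marm_cut <- applySVs(sim$genomes$marmoset, cut, name = "marm_cut")
  one_cls <- classifyOutgroup(one, mac, marm_cut)
  expect_equal(unname(S4Vectors::mcols(svRanges(one_cls))$outgroup_class),
               "uncertain")
})

test_that("gibbon comparison separates ape-wide from great-ape-specific SVs", {
  anc <- generateAncestralGenome(1L, 2e5, repeat_fraction = 0.1, seed = 19)
  specs <- list(
    branchSpec("ape_ancestor", n_del = 4L, n_ins = 2L, subst_rate = 0),
    branchSpec("great_ape_ancestor", n_del = 4L, n_ins = 2L, subst_rate = 0))
  sim <- evolveGenomes(anc, specs, seed = 19)
  mac <- sim$genomes$macaque
  per_ape <- lapply(sim$genomes[c("human", "chimp", "gorilla", "orangutan")],
                    function(g) callBidirectional(mac, g))
  cand <- intersectAcrossApes(per_ape)
  cand <- classifyOutgroup(cand, mac, sim$genomes$marmoset)
  expect_true(all(S4Vectors::mcols(svRanges(cand))$outgroup_class ==
                  "high_confident"))
  cand <- classifyGreatApe(cand, mac, sim$genomes$gibbon)

  tr <- sim$truth; mcT <- S4Vectors::mcols(tr)
  m <- matchCallsets(SVCallset(tr), cand)
  scope <- rep(NA_character_, length(tr))
  scope[m$matches$query_idx] <-
    S4Vectors::mcols(svRanges(cand))$ape_scope[m$matches$ref_idx]
  expect_true(all(scope[mcT$branch == "ape_ancestor"] == "ASSV"))
  # great-ape-stem events are never mislabelled ASSV; loci whose flanks are
  # contaminated by a neighbouring ape-stem event stay uncertain
  ga <- scope[mcT$branch == "great_ape_ancestor"]
  expect_true(all(ga %in% c("GASSV", "uncertain")))
  expect_gte(mean(ga == "GASSV"), 0.8)

  nog <- classifyGreatApe(cand, mac, NULL)
  expect_true(all(S4Vectors::mcols(svRanges(nog))$ape_scope == "uncertain"))
})
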
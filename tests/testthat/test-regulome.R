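test_that("the two-sample test matches the pooled-t closed form", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  r <- twoSampleTest(x, y)
  # independent closed-form oracle
  sp2 <- (var(x) * 2 + var(y) * 2) / 4
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 3))
  p_oracle <- 2 * pt(-abs(tstat), df = 4)
  expect_equal(r$p, p_oracle, tolerance = 1e-12)
  expect_equal(r$direction, -1)

  r2 <- twoSampleTest(y, x)
  expect_equal(r2$p, r$p)
  expect_equal(r2$direction, 1)

  same <- twoSampleTest(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$p, 1)
  expect_equal(same$direction, 0)
  expect_error(twoSampleTest(1, c(1, 2)), "group size")
})

test_that("ADE calls follow the compound same-direction criterion", {
  # vectorized caller equals the scalar test on log2(count+1)
  e <- simulateEnhancerMatrix(50L, 0.2, 0.2, effect_log2fc = 2, cv = 0.2,
                              seed = 8)
  a <- callADEs(e$matrix)
  cnt <- SummarizedExperiment::assay(e$matrix)
  sp <- sampleSpecies(e$matrix)
  for (i in c(1, 17, 42)) {
    lx <- log2(cnt[i, ] + 1)
    expect_equal(a$p_mh[i],
                 twoSampleTest(lx[sp == "macaque"], lx[sp == "human"])$p)
    expect_equal(a$p_hc[i],
                 twoSampleTest(lx[sp == "human"], lx[sp == "chimp"])$p)
  }

  # opposite human/chimp directions can never be an ADE
  m <- rbind(c(10, 10.5, 9.8, 1000, 1010, 100, 101, 99))
  colnames(m) <- c(paste0("human_", 1:3), paste0("chimp_", 1:2),
                   paste0("macaque_", 1:3))
  em <- EnhancerMatrix(m, GenomicRanges::GRanges("chrE", IRanges::IRanges(1, 600)))
  expect_false(callADEs(em)$is_ade)

  # planted effects are detected with the right direction
  e2 <- simulateEnhancerMatrix(300L, 0.1, 0.1, effect_log2fc = 2, cv = 0.1,
                               seed = 12)
  a2 <- callADEs(e2$matrix)
  pl <- e2$truth != "null"
  expect_gt(mean(a2$is_ade[pl] & a2$direction[pl] == e2$truth[pl]), 0.9)
  expect_true(all(a2$direction[a2$is_ade & e2$truth == "gain"] == "gain",
                  na.rm = TRUE))
  # planted gains have positive log2fc near the planted effect
  expect_gt(median(a2$log2fc[e2$truth == "gain"]), 1.5)
})

test_that("ASSV x ADE intersection counts 1-bp overlaps", {
  ades <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1000, 5000), width = 600))
  inside <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1200, width = 100))
  r <- intersectAssvAde(inside, ades)
  expect_equal(nrow(r$pairs), 1L)
  expect_equal(r$n_ades_hit, 1L)

  off <- GenomicRanges::GRanges("chr1", IRanges::IRanges(3000, width = 100))
  expect_equal(nrow(intersectAssvAde(off, ades)$pairs), 0L)

  # random placement matches a brute-force all-pairs scan
  set.seed(33)
  svs <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(sample.int(20000, 100), width = sample(50:500, 100, TRUE)))
  enh <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(sample.int(20000, 30), width = 600))
  r2 <- intersectAssvAde(svs, enh)
  brute <- 0L
  for (i in seq_along(svs)) for (j in seq_along(enh)) {
    if (GenomicRanges::start(svs)[i] <= GenomicRanges::end(enh)[j] &&
        GenomicRanges::start(enh)[j] <= GenomicRanges::end(svs)[i])
      brute <- brute + 1L
  }
  expect_equal(nrow(r2$pairs), brute)

  cs <- makeCallset("chr1", 0L, 100L, "DEL")   # no human frame
  expect_error(intersectAssvAde(cs, ades), "frame mismatch")
})

test_that("gene-window annotation respects the 5 kb window edge", {
  gene <- GenomicRanges::GRanges("chr1", IRanges::IRanges(20000, 30000),
                                 gene_id = "g1")
  near <- GenomicRanges::GRanges("chr1", IRanges::IRanges(15900, width = 100))
  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(13900, width = 100))
  a1 <- annotateNearGenes(near, gene)   # 4 kb upstream: assigned
  expect_equal(unname(unlist(a1$genes)), "g1")
  a2 <- annotateNearGenes(far, gene)    # 6 kb upstream: intergenic
  expect_true(a2$intergenic)

  set.seed(37)
  svs <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(sample.int(50000, 200), width = sample(50:300, 200, TRUE)))
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(sample.int(50000, 20), width = sample(1000:4000, 20, TRUE)),
    gene_id = paste0("g", 1:20))
  ann <- annotateNearGenes(svs, genes, window = 5000L)
  for (i in c(1, 50, 200)) {
    hits <- character()
    for (j in seq_along(genes)) {
      if (GenomicRanges::start(svs)[i] <= GenomicRanges::end(genes)[j] + 5000 &&
          GenomicRanges::start(genes)[j] - 5000 <= GenomicRanges::end(svs)[i])
        hits <- c(hits, paste0("g", j))
    }
    expect_setequal(unlist(ann$genes[[i]]), hits)
  }
})

test_that("paired layer-expression test is pairing-invariant", {
  prof <- sin(seq_len(17)) * 2 + 10
  expect_equal(layerExpressionTest(prof, prof)$p, 1)

  set.seed(41)
  shifted <- prof - 0.5 + rnorm(17, sd = 0.05)
  r <- layerExpressionTest(prof, shifted)
  expect_lt(r$p, 0.05)
  expect_equal(r$direction, 1)

  perm <- sample.int(17)
  r2 <- layerExpressionTest(prof[perm], shifted[perm])
  expect_equal(r2$p, r$p)
  expect_error(layerExpressionTest(prof, prof[-1]), "unequal")
})
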
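test_that("unique anchors tile identical sequences and track strand", {
  set.seed(17)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE), collapse = "")
  ga <- GenomeSequence(c(chr1 = s), name = "a")
  gb <- GenomeSequence(c(chr1 = s), name = "b")
  an <- uniqueAnchors(ga, gb, k = 31L)

  # oracle: canonical k-mers occurring exactly once, counted in R
  k <- 31L
  kms <- substring(s, 1:(nchar(s) - k + 1L), k:nchar(s))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kms)))
  canon <- pmin(kms, rc)
  tab <- table(canon)
  n_unique <- sum(tab == 1L)
  expect_equal(nrow(an), n_unique)
  expect_true(all(an$orient == 1L))
  expect_equal(an$ref_pos, an$query_pos)
  # anchors cover essentially the whole sequence
  cov <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(an$ref_pos + 1L, an$ref_pos + k))))
  expect_gt(cov / nchar(s), 0.99)

  grc <- GenomeSequence(c(chr1 = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))), name = "rc")
  an2 <- uniqueAnchors(ga, grc, k = 31L)
  expect_equal(nrow(an2), n_unique)
  expect_true(all(an2$orient == -1L))

  polyA <- GenomeSequence(c(chr1 = strrep("A", 5000)))
  expect_equal(nrow(uniqueAnchors(polyA, polyA, k = 31L)), 0L)

  expect_error(uniqueAnchors(ga, gb, k = 30L), "odd")
  expect_error(uniqueAnchors(ga, gb, k = 13L), "between")
})

test_that("chaining keeps colinear anchors and splits rearranged blocks", {
  mk <- function(rp, qp) {
    df <- data.frame(ref_chrom = rep("chr1", length(rp)), ref_pos = rp,
                     query_chrom = rep("chr1", length(rp)), query_pos = qp,
                     orient = rep(1L, length(rp)))
    attr(df, "k") <- 31L
    df
  }
  col <- mk(seq(0, 9000, by = 1000), seq(100, 9100, by = 1000))
  ch <- chainAnchors(col)
  expect_equal(length(ch), 1L)
  expect_equal(nrow(ch[[1]]), 10L)

  expect_equal(length(chainAnchors(mk(integer(), integer()))), 0L)

  # LIS agrees with quadratic DP on random permutations
  lis_brute <- function(x) {
    n <- length(x); best <- rep(1L, n)
    for (i in seq_len(n)) for (j in seq_len(i - 1L))
      if (x[j] < x[i]) best[i] <- max(best[i], best[j] + 1L)
    if (n) max(best) else 0L
  }
  set.seed(23)
  for (i in 1:200) {
    n <- sample(2:30, 1)
    qp <- sample.int(1000L, n) * 10L
    a <- mk(seq_len(n) * 50L, qp)
    chains <- chainAnchors(a, max_chain_gap = 1e9)
    expect_equal(nrow(chains[[1]]), lis_brute(qp))
  }

  # a transposed block splits into at least two chains at the breakpoint
  rp <- seq(0, 11) * 2e5
  qp <- c(6:11, 0:5) * 2e5
  chains <- chainAnchors(mk(rp, qp), max_chain_gap = 3e5)
  expect_gte(length(chains), 2L)
  expect_equal(sum(vapply(chains, nrow, 1L)), 12L)
})

test_that("pairwise calling recovers planted events with exact sizes", {
  set.seed(29)
  s <- paste(sample(c("A", "C", "G", "T"), 30000, replace = TRUE), collapse = "")
  ref <- GenomeSequence(c(chr1 = s), name = "ref")

  expect_equal(length(callPairwiseSVs(ref, ref)), 0L)

  # 500 bp excision from the query: one DEL at the excision point
  q_del <- GenomeSequence(c(chr1 = paste0(substr(s, 1, 10000),
                                          substr(s, 10501, 30000))), name = "q")
  calls <- callPairwiseSVs(ref, q_del)
  expect_equal(length(calls), 1L)
  expect_equal(svType(calls), "DEL")
  expect_equal(svLength(calls), 500L)
  expect_lte(abs(GenomicRanges::start(svRanges(calls)) - 10001L), 31L)

  # 300 bp insertion: applying the call at its reported point reconstructs
  # the query exactly (breakpoint placement is ambiguous up to junction
  # homology, so reconstruction is the right equality)
  ins <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  q_ins <- GenomeSequence(c(chr1 = paste0(substr(s, 1, 15000), ins,
                                          substr(s, 15001, 30000))), name = "q2")
  calls2 <- callPairwiseSVs(ref, q_ins)
  expect_equal(svType(calls2), "INS")
  expect_equal(svLength(calls2), 300L)
  p0 <- GenomicRanges::start(svRanges(calls2)) - 1L
  expect_lte(abs(p0 - 15000L), 31L)
  rebuilt <- paste0(substr(s, 1, p0), S4Vectors::mcols(svRanges(calls2))$seq,
                    substr(s, p0 + 1L, nchar(s)))
  expect_identical(rebuilt, as.character(chromSeqs(q_ins)[[1]]))

  # sub-threshold events are not called
  q_small <- GenomeSequence(c(chr1 = paste0(substr(s, 1, 20000),
                                            substr(s, 20040, 30000))), name = "q3")
  expect_equal(length(callPairwiseSVs(ref, q_small, min_len = 50L)), 0L)
})
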
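# Shared fixtures, built in code and cached for the duration of the run.

# Small substitution-free simulation reused across test files.
simFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      anc <- generateAncestralGenome(n_chrom = 1L, chrom_length = 3e5,
                                     repeat_fraction = 0.15, seed = 7)
      specs <- defaultBranchSpecs(subst_rate = 0, n_ape_ancestor = 12L,
                                  n_macaque = 8L, n_per_tip = 4L)
      cache <<- list(anc = anc, sim = evolveGenomes(anc, specs, seed = 11))
    }
    cache
  }
})

# Default-scale substitution-free simulation for the end-to-end checks.
bigSimFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      anc <- generateAncestralGenome(n_chrom = 2L, chrom_length = 1e6,
                                     repeat_fraction = 0.15, seed = 1)
      cache <<- list(
        anc = anc,
        sim = evolveGenomes(anc, defaultBranchSpecs(subst_rate = 0), seed = 1))
    }
    cache
  }
})

# Build an SVCallset from plain vectors (starts are 0-based).
makeCallset <- function(chrom, start0, len, type, id = NULL, seq = NA_character_) {
  n <- length(start0)
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = start0 + 1L, width = len))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = rep_len(type, n), svlen = as.integer(rep_len(len, n)),
    id = id %||% sprintf("t%05d", seq_len(n)),
    seq = rep_len(seq, n))
  SVCallset(gr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Controlled enrichment universe: "hit" SVs sit inside a trait gene, the
# rest far away, so the 2x2 table (subset x gene-hit) is exactly specified.
enrichUniverse <- function(n_hit_in, n_miss_in, n_hit_out, n_miss_out) {
  n <- n_hit_in + n_miss_in + n_hit_out + n_miss_out
  hit <- c(rep(TRUE, n_hit_in), rep(FALSE, n_miss_in),
           rep(TRUE, n_hit_out), rep(FALSE, n_miss_out))
  inset <- c(rep(TRUE, n_hit_in + n_miss_in),
             rep(FALSE, n_hit_out + n_miss_out))
  start0 <- ifelse(hit, 100000L + seq_len(n) * 60L, 900000L + seq_len(n) * 60L)
  cs <- makeCallset("chr1", start0, 50L, "DEL")
  gene <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100000L, 200000L),
                                 gene_id = "trait1")
  list(svs = cs, ids = svID(cs)[inset], gene = gene)
}

# Two-sided Fisher p by explicit hypergeometric enumeration.
fisherOracle <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

# Random callset on the given chromosome lengths.
randomCallset <- function(n, chrom_lengths, seed, types = c("DEL", "INS"),
                          len_range = c(50L, 2000L)) {
  set.seed(seed)
  cn <- sample(names(chrom_lengths), n, replace = TRUE)
  len <- sample(len_range[1L]:len_range[2L], n, replace = TRUE)
  s0 <- vapply(seq_len(n), function(i)
    sample.int(chrom_lengths[[cn[i]]] - len[i] - 1L, 1L), 1L)
  makeCallset(cn, s0, len, sample(types, n, replace = TRUE))
}
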
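#' @useDynLib lineageSV, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importMethodsFrom SummarizedExperiment assay assayNames colData rowRanges
#' @importMethodsFrom S4Vectors metadata mcols
#' @importFrom stats rbinom rlnorm runif rnorm median pt t.test fisher.test
#'   setNames p.adjust
#' @importFrom utils read.delim write.table head
NULL

# Derive a reproducible substream seed from a top-level seed and a stage id.
# Kept below 2^31 so it is a valid R integer seed.
deriveSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.double(seed) + 62047 * as.double(stream)) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random DNA of length n with the given GC content, as a character scalar.
randDNA <- function(n, gc = 0.41) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# N50 of a multiset of segment lengths: the largest L such that segments of
# length >= L sum to at least half the total.
n50 <- function(lengths) {
  if (length(lengths) == 0L) return(NA_integer_)
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}
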
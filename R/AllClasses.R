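#' GenomeSequence: a named set of chromosome sequences
#'
#' Thin wrapper around a [Biostrings::DNAStringSet] holding the chromosomes of
#' one assembly over the alphabet \{A,C,G,T,N\}, with an optional planted
#' repeat annotation carried as a [GenomicRanges::GRanges] (mcol
#' \code{repeat_class}).
#'
#' @slot name single character, the assembly name.
#' @slot seqs \code{DNAStringSet} of chromosomes; names are chromosome names.
#' @slot repeats \code{GRanges} of annotated repeat copies (may be empty).
#'
#' @aliases GenomeSequence-class
#' @exportClass GenomeSequence
setClass("GenomeSequence",
  slots = c(name = "character", seqs = "DNAStringSet", repeats = "GRanges"))

setValidity("GenomeSequence", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
  if (length(object@seqs) == 0L) msg <- c(msg, "no chromosomes")
  nm <- names(object@seqs)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    msg <- c(msg, "all chromosomes must be named")
  else if (anyDuplicated(nm)) msg <- c(msg, "duplicate chromosome names")
  if (any(Biostrings::width(object@seqs) == 0L))
    msg <- c(msg, "empty chromosome sequence")
  af <- Biostrings::alphabetFrequency(object@seqs, baseOnly = TRUE)
  # baseOnly lumps everything outside ACGT into "other"; only N may be there
  nN <- Biostrings::vcountPattern("N", object@seqs)
  if (any(af[, "other"] != nN))
    msg <- c(msg, "sequences contain characters outside {A,C,G,T,N}")
  if (length(object@repeats) > 0L) {
    rl <- setNames(Biostrings::width(object@seqs), nm)
    bad <- !(as.character(GenomicRanges::seqnames(object@repeats)) %in% nm)
    if (any(bad)) msg <- c(msg, "repeat annotation on unknown chromosome")
    else {
      ends <- GenomicRanges::end(object@repeats)
      if (any(ends > rl[as.character(GenomicRanges::seqnames(object@repeats))]) ||
          any(GenomicRanges::start(object@repeats) < 1L))
        msg <- c(msg, "repeat interval outside chromosome bounds")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeSequence
#'
#' @param seqs named \code{DNAStringSet}, or a named character vector of
#'   chromosome sequences.
#' @param name assembly name.
#' @param repeats optional \code{GRanges} repeat annotation with mcol
#'   \code{repeat_class}.
#' @return A \linkS4class{GenomeSequence}.
#' @examples
#' g <- GenomeSequence(c(chr1 = "ACGTACGT"), name = "toy")
#' chromLengths(g)
#' @export
GenomeSequence <- function(seqs, name = "genome", repeats = NULL) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(repeats)) repeats <- GenomicRanges::GRanges()
  new("GenomeSequence", name = name, seqs = seqs, repeats = repeats)
}

#' @describeIn GenomeSequence chromosome names
#' @param x a \code{GenomeSequence}
#' @export
chromNames <- function(x) names(x@seqs)

#' @describeIn GenomeSequence named integer vector of chromosome lengths
#' @export
chromLengths <- function(x) setNames(Biostrings::width(x@seqs), names(x@seqs))

#' @describeIn GenomeSequence the underlying \code{DNAStringSet}
#' @export
chromSeqs <- function(x) x@seqs

#' @describeIn GenomeSequence repeat annotation (\code{GRanges})
#' @export
repeatAnnotation <- function(x) x@repeats

#' @describeIn GenomeSequence assembly name
#' @export
genomeName <- function(x) x@name

# one chromosome as a plain character string
chromString <- function(x, chrom) as.character(x@seqs[[chrom]])

setMethod("show", "GenomeSequence", function(object) {
  cat("GenomeSequence \"", object@name, "\": ", length(object@seqs),
      " chromosome(s), ", format(sum(Biostrings::width(object@seqs)),
      big.mark = ","), " bp", sep = "")
  if (length(object@repeats)) {
    cat(", ", length(object@repeats), " annotated repeats", sep = "")
  }
  cat("\n")
})

#' SVCallset: a set of structural-variant records
#'
#' Holds SV records (>= 50 bp) as a \code{GRanges} in the reference frame of
#' one assembly. Required metadata columns: \code{type} (DEL/INS/DUP/INV),
#' \code{svlen} (bp), \code{id}. Insertions are stored with their anchor
#' point widened to the insertion length (footprint convention), so
#' \code{width(gr) == svlen} for every record; the insertion point is
#' \code{start(gr) - 1} in 0-based coordinates. Optional columns: \code{seq}
#' (inserted or deleted sequence), \code{source}, and \code{query_chrom} /
#' \code{query_start} / \code{query_end} (0-based half-open footprint of the
#' event on the other assembly of a pairwise comparison).
#'
#' @slot gr the underlying \code{GRanges}.
#' @aliases SVCallset-class
#' @exportClass SVCallset
setClass("SVCallset", slots = c(gr = "GRanges"))

setValidity("SVCallset", function(object) {
  gr <- object@gr
  msg <- character()
  mc <- S4Vectors::mcols(gr)
  need <- c("type", "svlen", "id")
  miss <- setdiff(need, colnames(mc))
  if (length(miss)) return(paste("missing mcols:", paste(miss, collapse = ", ")))
  if (length(gr)) {
    if (!all(mc$type %in% c("DEL", "INS", "DUP", "INV")))
      msg <- c(msg, "type must be DEL, INS, DUP or INV")
    if (any(mc$svlen < 50)) msg <- c(msg, "svlen must be >= 50")
    if (any(GenomicRanges::width(gr) != mc$svlen))
      msg <- c(msg, "interval width must equal svlen")
    if (anyDuplicated(mc$id)) msg <- c(msg, "duplicate SV ids")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an SVCallset
#'
#' @param gr \code{GRanges} with mcols \code{type}, \code{svlen}, \code{id}
#'   (see \linkS4class{SVCallset} for conventions), or \code{NULL} for an
#'   empty callset.
#' @param source optional provenance tag recorded as mcol \code{source}.
#' @return An \linkS4class{SVCallset}.
#' @export
SVCallset <- function(gr = NULL, source = NULL) {
  if (is.null(gr)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      type = character(), svlen = integer(), id = character())
  }
  if (!is.null(source))
    S4Vectors::mcols(gr)$source <- rep_len(source, length(gr))
  new("SVCallset", gr = gr)
}

#' @describeIn SVCallset the underlying \code{GRanges}
#' @param x an \code{SVCallset}
#' @export
svRanges <- function(x) x@gr

#' @describeIn SVCallset SV types
#' @export
svType <- function(x) S4Vectors::mcols(x@gr)$type

#' @describeIn SVCallset SV lengths (bp)
#' @export
svLength <- function(x) S4Vectors::mcols(x@gr)$svlen

#' @describeIn SVCallset SV identifiers
#' @export
svID <- function(x) S4Vectors::mcols(x@gr)$id

#' @export
setMethod("length", "SVCallset", function(x) length(x@gr))

#' @export
setMethod("[", "SVCallset", function(x, i, j, ..., drop = TRUE) {
  new("SVCallset", gr = x@gr[i])
})

setMethod("show", "SVCallset", function(object) {
  cat("SVCallset with ", length(object@gr), " record(s)", sep = "")
  if (length(object@gr)) {
    tb <- table(S4Vectors::mcols(object@gr)$type)
    cat(" (", paste(names(tb), as.integer(tb), sep = ":", collapse = ", "),
        ")", sep = "")
  }
  cat("\n")
})

#' @export
setMethod("as.data.frame", "SVCallset", function(x, ...) {
  df <- as.data.frame(x@gr)
  names(df)[names(df) == "seqnames"] <- "chrom"
  df
})

#' EnhancerMatrix: H3K27Ac counts over enhancer intervals
#'
#' A \code{RangedSummarizedExperiment} subclass with one assay
#' (\code{"counts"}), rowRanges giving the enhancer intervals, and colData
#' columns \code{species} and \code{replicate}. The brain-region label is
#' stored in \code{metadata(x)$region}.
#'
#' @aliases EnhancerMatrix-class
#' @exportClass EnhancerMatrix
setClass("EnhancerMatrix",
  contains = "RangedSummarizedExperiment")

setValidity("EnhancerMatrix", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("species", "replicate") %in% colnames(cd)))
    return("colData must have species and replicate")
  tab <- table(cd$species)
  need <- c("human", "chimp", "macaque")
  if (!all(need %in% names(tab)))
    msg <- c(msg, "need human, chimp and macaque samples")
  else if (any(tab[need] < 2L))
    msg <- c(msg, "need >= 2 samples per species for testing")
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' missing")
  else if (any(SummarizedExperiment::assay(object, "counts") < 0))
    msg <- c(msg, "negative counts")
  if (length(msg)) msg else TRUE
})

#' Construct an EnhancerMatrix
#'
#' @param counts numeric matrix, enhancers x samples; column names of the
#'   form \code{species_replicate} (e.g. \code{human_1}) unless
#'   \code{species} is given.
#' @param rowRanges \code{GRanges} of enhancer intervals (one per row).
#' @param species optional character vector of per-column species labels;
#'   parsed from column names when missing.
#' @param region brain-region label (one of PFC, PcGm, OP, CN, Put, CB, WM,
#'   TN, or free text).
#' @return An \linkS4class{EnhancerMatrix}.
#' @export
EnhancerMatrix <- function(counts, rowRanges, species = NULL, region = "PFC") {
  cn <- colnames(counts)
  if (is.null(species)) {
    if (is.null(cn)) stop("need column names of the form species_replicate")
    species <- sub("_[^_]*$", "", cn)
  }
  replicate <- if (!is.null(cn)) sub("^.*_", "", cn) else
    as.character(stats::ave(seq_along(species), species, FUN = seq_along))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowRanges = rowRanges,
    colData = S4Vectors::DataFrame(species = species, replicate = replicate))
  S4Vectors::metadata(se)$region <- region
  new("EnhancerMatrix", se)
}

#' @describeIn EnhancerMatrix per-column species labels
#' @param x an \code{EnhancerMatrix}
#' @export
sampleSpecies <- function(x) SummarizedExperiment::colData(x)$species

#' @describeIn EnhancerMatrix brain-region label
#' @export
brainRegion <- function(x) S4Vectors::metadata(x)$region
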
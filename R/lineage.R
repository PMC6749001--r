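# The ASSV inference engine: unique-k-mer anchors, colinear chaining,
# minimal pairwise SV calling between assemblies, forward/reverse
# concordance, cross-ape intersection, human-coordinate overlay, and
# outgroup classification.

.checkK <- function(k) {
  if (k %% 2L == 0L || k < 15L || k > 31L)
    stop("k must be odd and between 15 and 31")
  as.integer(k)
}

#' Unique k-mer anchors between two genomes
#'
#' An anchor is a k-mer occurring exactly once in each genome, counted in
#' canonical (strand-collapsed) form; its orientation is \code{+} when both
#' occurrences lie on the same strand and \code{-} otherwise. k-mers are
#' packed into 64-bit words, so k is limited to 31.
#'
#' @param genome_a,genome_b \linkS4class{GenomeSequence}s (a is the
#'   reference role).
#' @param k anchor length (odd, 15-31; default 31).
#' @return data.frame sorted by reference position: \code{ref_chrom},
#'   \code{ref_pos}, \code{query_chrom}, \code{query_pos} (0-based k-mer
#'   starts on the forward strands), \code{orient} (+1/-1); attribute
#'   \code{k}.
#' @export
uniqueAnchors <- function(genome_a, genome_b, k = 31L) {
  k <- .checkK(k)
  idx <- .kmer_index_build(as.character(chromSeqs(genome_a)), k)
  .anchorsFromIndex(idx, genome_a, genome_b, k)
}

.anchorsFromIndex <- function(idx, genome_a, genome_b, k) {
  an <- .kmer_index_anchors(idx, as.character(chromSeqs(genome_b)))
  df <- data.frame(
    ref_chrom = chromNames(genome_a)[an$ref_chrom + 1L],
    ref_pos = an$ref_pos,
    query_chrom = chromNames(genome_b)[an$query_chrom + 1L],
    query_pos = an$query_pos,
    orient = an$orient,
    stringsAsFactors = FALSE)
  df <- df[order(df$ref_chrom, df$ref_pos), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "k") <- k
  df
}

#' Chain anchors into colinear synteny blocks
#'
#' Within each (reference chromosome, query chromosome, orientation) group,
#' the maximum-cardinality colinear subset is found by longest-increasing-
#' subsequence on query positions ordered by reference position; chains are
#' split where the inter-anchor distance on either genome exceeds
#' \code{max_chain_gap}.
#'
#' @param anchors anchor table from [uniqueAnchors].
#' @param max_chain_gap split distance in bp (default 100 kb).
#' @return List of chains (data.frames with the anchor columns), ordered by
#'   decreasing anchor count; each carries attribute \code{k}.
#' @export
chainAnchors <- function(anchors, max_chain_gap = 1e5) {
  k <- attr(anchors, "k")
  if (nrow(anchors) == 0L) return(list())
  key <- paste(anchors$ref_chrom, anchors$query_chrom, anchors$orient)
  chains <- list()
  for (kk in unique(key)) {
    rem <- anchors[key == kk, , drop = FALSE]
    rem <- rem[order(rem$ref_pos), , drop = FALSE]
    # successive LIS rounds: each extracts the largest colinear subset of
    # what is left, so rearranged blocks become their own chains
    rounds <- 0L
    while (nrow(rem) > 0L && rounds < 100L) {
      rounds <- rounds + 1L
      keep <- .lis_indices(rem$query_pos * rem$orient[1L])
      if (length(keep) < 2L && nrow(rem) > 1L && rounds > 1L) break
      sub <- rem[keep, , drop = FALSE]
      rem <- rem[-keep, , drop = FALSE]
      brk <- cumsum(c(FALSE, diff(sub$ref_pos) > max_chain_gap |
                             abs(diff(sub$query_pos)) > max_chain_gap))
      for (id in unique(brk)) {
        ch <- sub[brk == id, , drop = FALSE]
        rownames(ch) <- NULL
        attr(ch, "k") <- k
        chains[[length(chains) + 1L]] <- ch
      }
    }
  }
  chains[order(-vapply(chains, nrow, 1L))]
}

#' Call SVs from the anchor chains of one genome pair
#'
#' For each adjacent anchor pair within a forward-orientation chain, with
#' reference gap \code{g_r} and query gap \code{g_q} between anchor
#' footprints, the difference \code{d = g_q - g_r} is an insertion in the
#' query when \code{d >= min_len} (inserted sequence captured from the
#' query) and a deletion in the query when \code{d <= -min_len}.
#' Coordinates are reported in the reference frame; the query-frame
#' footprint is kept in mcols \code{query_chrom}/\code{query_start}/
#' \code{query_end} (0-based half-open) so calls can be projected into the
#' other frame.
#'
#' @param ref,query \linkS4class{GenomeSequence}s.
#' @param k anchor length.
#' @param min_len minimum SV size (default 50 bp).
#' @param max_chain_gap chain split distance.
#' @param source provenance tag.
#' @param anchors optional precomputed [uniqueAnchors] table.
#' @param min_chain_anchors chains with fewer anchors are not used for
#'   calling (stray off-diagonal anchors must not imply giant indels).
#' @return An \linkS4class{SVCallset} in the reference frame.
#' @export
callPairwiseSVs <- function(ref, query, k = 31L, min_len = 50L,
                            max_chain_gap = 1e5,
                            source = paste0(genomeName(ref), "_vs_",
                                            genomeName(query)),
                            anchors = NULL, min_chain_anchors = 5L) {
  k <- .checkK(k)
  if (is.null(anchors)) anchors <- uniqueAnchors(ref, query, k)
  chains <- chainAnchors(anchors, max_chain_gap)
  recs <- list()
  for (ch in chains) {
    if (nrow(ch) < max(2L, min_chain_anchors) || ch$orient[1L] != 1L) next
    rp <- ch$ref_pos; qp <- ch$query_pos
    # inter-anchor gaps between footprints; adjacent anchors overlap by up
    # to k-1 bp, which cancels in d = g_q - g_r (the exact indel size)
    gr_ <- rp[-1L] - (rp[-nrow(ch)] + k)
    gq_ <- qp[-1L] - (qp[-nrow(ch)] + k)
    d <- gq_ - gr_
    cand <- which(abs(d) >= min_len)
    bad <- cand[gr_[cand] < 0L & gq_[cand] < 0L]
    if (length(bad)) {
      warning("skipping ", length(bad),
              " adjacent pair(s) with overlapping anchor footprints")
      cand <- setdiff(cand, bad)
    }
    for (i in cand) {
      rchrom <- ch$ref_chrom[1L]; qchrom <- ch$query_chrom[1L]
      if (d[i] >= min_len) {   # insertion in the query
        p0 <- rp[i] + k        # reference insertion point, 0-based
        q0 <- qp[i] + k
        seq <- substr(chromString(query, qchrom), q0 + 1L, q0 + d[i])
        recs[[length(recs) + 1L]] <- list(
          chrom = rchrom, start = p0 + 1L, end = p0 + d[i], type = "INS",
          svlen = d[i], seq = seq,
          qc = qchrom, qs = q0, qe = q0 + d[i])
      } else {                 # deletion in the query
        s0 <- rp[i] + k; L <- -d[i]
        seq <- substr(chromString(ref, rchrom), s0 + 1L, s0 + L)
        recs[[length(recs) + 1L]] <- list(
          chrom = rchrom, start = s0 + 1L, end = s0 + L, type = "DEL",
          svlen = L, seq = seq,
          qc = qchrom, qs = qp[i] + k, qe = qp[i] + k + L)
      }
    }
  }
  if (length(recs) == 0L) return(SVCallset(source = source))
  gr <- GenomicRanges::GRanges(
    vapply(recs, `[[`, "", "chrom"),
    IRanges::IRanges(start = vapply(recs, `[[`, 1L, "start"),
                     end = vapply(recs, `[[`, 1L, "end")))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = vapply(recs, `[[`, "", "type"),
    svlen = vapply(recs, `[[`, 1L, "svlen"),
    id = sprintf("%s_%04d", source, seq_along(recs)),
    seq = vapply(recs, `[[`, "", "seq"),
    query_chrom = vapply(recs, `[[`, "", "qc"),
    query_start = vapply(recs, `[[`, 1L, "qs"),
    query_end = vapply(recs, `[[`, 1L, "qe"))
  gr <- sort(gr)
  SVCallset(gr, source = source)
}

#' Project a reverse-direction callset into the forward frame
#'
#' A callset from \code{callPairwiseSVs(ref = B, query = A)} is re-expressed
#' in the frame of A using the query-frame footprints its own anchors
#' provided: insertion and deletion swap roles, and the query coordinates
#' become the primary interval.
#'
#' @param callset an \linkS4class{SVCallset} with query-frame mcols.
#' @return An \linkS4class{SVCallset} in the query (now primary) frame.
#' @export
swapFrame <- function(callset) {
  gr <- svRanges(callset)
  if (length(gr) == 0L) return(callset)
  mc <- S4Vectors::mcols(gr)
  out <- GenomicRanges::GRanges(
    mc$query_chrom,
    IRanges::IRanges(start = mc$query_start + 1L, width = mc$svlen))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    type = ifelse(mc$type == "DEL", "INS",
                  ifelse(mc$type == "INS", "DEL", mc$type)),
    svlen = mc$svlen, id = mc$id, seq = mc$seq,
    query_chrom = as.character(GenomicRanges::seqnames(gr)),
    query_start = GenomicRanges::start(gr) - 1L,
    query_end = GenomicRanges::end(gr))
  SVCallset(sort(out))
}

#' Forward/reverse concordance filter
#'
#' Keeps forward-calling records that have a reciprocal-overlap,
#' type-matched partner in the (frame-projected) reverse callset.
#'
#' @param forward forward-calling \linkS4class{SVCallset} (macaque frame).
#' @param reverse reverse-calling callset already projected into the forward
#'   frame (see [swapFrame]).
#' @param threshold reciprocal-overlap fraction (strict >).
#' @return The concordant subset of \code{forward}.
#' @export
bidirectionalConcordance <- function(forward, reverse, threshold = 0.5) {
  m <- matchCallsets(forward, reverse, threshold = threshold, typeAware = TRUE)
  forward[sort(m$matches$query_idx)]
}

#' Bidirectional pairwise SV calling
#'
#' Runs forward calling (\code{ref} vs \code{query}), reverse calling
#' (\code{query} vs \code{ref}) projected back via [swapFrame], and keeps
#' the concordant forward records.
#'
#' Anchors are computed once per genome pair (the unique-k-mer anchor
#' relation is symmetric) and re-used with roles swapped for the reverse
#' direction, where chaining and gap interpretation are re-derived from the
#' query ordering.
#'
#' @inheritParams callPairwiseSVs
#' @param threshold reciprocal-overlap fraction for the concordance filter.
#' @return An \linkS4class{SVCallset} in the \code{ref} frame.
#' @export
callBidirectional <- function(ref, query, k = 31L, min_len = 50L,
                              max_chain_gap = 1e5, threshold = 0.5,
                              anchors = NULL) {
  if (is.null(anchors)) anchors <- uniqueAnchors(ref, query, k)
  fwd <- callPairwiseSVs(ref, query, k, min_len, max_chain_gap,
                         anchors = anchors)
  rev <- callPairwiseSVs(query, ref, k, min_len, max_chain_gap,
                         anchors = .swapAnchors(anchors))
  bidirectionalConcordance(fwd, swapFrame(rev), threshold)
}

#' Intersect per-ape callsets into candidate lineage-specific SVs
#'
#' A candidate survives iff every ape callset contains a reciprocal-overlap,
#' type-matched partner. The representative record comes from the pivot ape
#' (default human); per-ape support ids are recorded in mcols
#' \code{support_<ape>}.
#'
#' @param per_ape named list (>= 2 entries) of \linkS4class{SVCallset}s, all
#'   in the macaque frame.
#' @param threshold reciprocal-overlap fraction (strict >).
#' @param pivot name of the ape providing the representative records.
#' @return An \linkS4class{SVCallset} of candidates with support mcols.
#' @export
intersectAcrossApes <- function(per_ape, threshold = 0.5, pivot = "human") {
  stopifnot(length(per_ape) >= 2L, pivot %in% names(per_ape))
  piv <- per_ape[[pivot]]
  n <- length(piv)
  keep <- rep(TRUE, n)
  support <- list()
  support[[pivot]] <- svID(piv)
  for (ape in setdiff(names(per_ape), pivot)) {
    m <- matchCallsets(piv, per_ape[[ape]], threshold = threshold,
                       typeAware = TRUE)
    sup <- rep(NA_character_, n)
    sup[m$matches$query_idx] <- svID(per_ape[[ape]])[m$matches$ref_idx]
    support[[ape]] <- sup
    keep <- keep & !is.na(sup)
  }
  out <- svRanges(piv)[keep]
  for (ape in names(per_ape)) {
    S4Vectors::mcols(out)[[paste0("support_", ape)]] <- support[[ape]][keep]
  }
  SVCallset(out)
}

#' Overlay a second human-frame coordinate set onto candidate calls
#'
#' Candidates (macaque frame, e.g. from the ZF1-based comparison) matched
#' against a second callset (e.g. from the GRCh38-based comparison) gain
#' that callset's human-frame interval as mcols \code{human_chrom}/
#' \code{human_start}/\code{human_end}; unmatched candidates keep macaque
#' coordinates only and are flagged \code{human_annotated = FALSE}.
#'
#' @param calls candidate \linkS4class{SVCallset} (macaque frame).
#' @param calls_alt \linkS4class{SVCallset} from the second human assembly,
#'   macaque frame with query-frame (human) mcols.
#' @param threshold reciprocal-overlap fraction.
#' @return \code{calls} with the human-frame annotation mcols added.
#' @export
overlayHumanCoordinates <- function(calls, calls_alt, threshold = 0.5) {
  gr <- svRanges(calls)
  n <- length(gr)
  hc <- rep(NA_character_, n); hs <- rep(NA_integer_, n)
  he <- rep(NA_integer_, n)
  m <- matchCallsets(calls, calls_alt, threshold = threshold, typeAware = TRUE)
  if (nrow(m$matches)) {
    mcA <- S4Vectors::mcols(svRanges(calls_alt))
    qi <- m$matches$query_idx; ri <- m$matches$ref_idx
    hc[qi] <- mcA$query_chrom[ri]
    hs[qi] <- mcA$query_start[ri]
    he[qi] <- mcA$query_end[ri]
  }
  S4Vectors::mcols(gr)$human_chrom <- hc
  S4Vectors::mcols(gr)$human_start <- hs
  S4Vectors::mcols(gr)$human_end <- he
  S4Vectors::mcols(gr)$human_annotated <- !is.na(hc)
  SVCallset(gr)
}

# Project the gap-facing boundary of a mapped flank into the target genome.
# side = "end" projects flank coordinate flank_len, side = "start" projects 0.
.flankBoundary <- function(map, flank_len, k, side) {
  ch <- map$chain
  if (side == "end") { j <- which.max(ch$qp); x <- flank_len }
  else { j <- which.min(ch$qp); x <- 0L }
  if (map$orient == 1L) ch$rp[j] - ch$qp[j] + x
  else ch$rp[j] + ch$qp[j] + k - x
}

# Classify candidate calls against one outgroup genome. Returns a list of
# per-call class ("mac_like", "ape_like", "uncertain") plus diagnostics.
.outgroupSpans <- function(calls, macaque, outgroup, flank, min_identity,
                           span_tol, k) {
  k <- .checkK(k)
  idx <- .kmer_index_build(as.character(chromSeqs(outgroup)), k)
  gr <- svRanges(calls)
  mc <- S4Vectors::mcols(gr)
  cl <- chromLengths(macaque)
  n <- length(gr)
  cls <- rep("uncertain", n)
  ident <- rep(NA_real_, n); spans <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cn <- as.character(GenomicRanges::seqnames(gr))[i]
    L <- mc$svlen[i]
    if (mc$type[i] == "DEL") {
      leftB <- GenomicRanges::start(gr)[i] - 1L
      rightB <- GenomicRanges::end(gr)[i]
      mac_span <- L; ape_span <- 0L
    } else if (mc$type[i] == "INS") {
      leftB <- rightB <- GenomicRanges::start(gr)[i] - 1L
      mac_span <- 0L; ape_span <- L
    } else next  # DUP/INV not polarized by the span rule
    lf <- substr(chromString(macaque, cn), max(1L, leftB - flank + 1L), leftB)
    rf <- substr(chromString(macaque, cn), rightB + 1L,
                 min(cl[[cn]], rightB + flank))
    if (nchar(lf) < k || nchar(rf) < k) next
    lm <- .mapFlankChain(idx, lf, k)
    rm_ <- .mapFlankChain(idx, rf, k)
    if (is.null(lm) || is.null(rm_)) next
    id_l <- lm$presence / nchar(lf); id_r <- rm_$presence / nchar(rf)
    ident[i] <- min(id_l, id_r)
    if (lm$ambiguous || rm_$ambiguous) next
    if (ident[i] < min_identity) next
    if (lm$chrom != rm_$chrom || lm$orient != rm_$orient) next
    A <- .flankBoundary(lm, nchar(lf), k, "end")
    B <- .flankBoundary(rm_, nchar(rf), k, "start")
    span <- if (lm$orient == 1L) B - A else A - B
    if (is.na(span) || span < 0) next
    spans[i] <- span
    tol <- max(span_tol * L, span_tol * 50)
    dm <- abs(span - mac_span); da <- abs(span - ape_span)
    if (dm <= tol && dm < da) cls[i] <- "mac_like"
    else if (da <= tol && da < dm) cls[i] <- "ape_like"
  }
  list(class = cls, identity = ident, span = spans)
}

#' Polarize candidate ASSVs against an outgroup genome
#'
#' The SV region plus \code{flank} bp of macaque flanking sequence is
#' located in the outgroup by unique-k-mer anchoring restricted to the
#' flanks. Candidates whose flanks cannot be co-located, map ambiguously, or
#' fall below the \code{min_identity} anchor-coverage pre-filter are
#' \code{uncertain}. Otherwise the inter-flank span in the outgroup is
#' compared against the macaque and ape alleles: a span within the tolerance
#' of the macaque allele means the outgroup retains the ancestral
#' (macaque-like) state, so the SV is ape-derived — \code{high_confident};
#' a span matching the ape allele means the variant exists in the outgroup
#' too — \code{false}; anything intermediate is \code{uncertain}.
#'
#' @param calls candidate \linkS4class{SVCallset} (macaque frame, DEL/INS).
#' @param macaque the macaque \linkS4class{GenomeSequence}.
#' @param outgroup the outgroup genome (marmoset role).
#' @param flank flanking length (default 1 kb).
#' @param min_identity anchor-coverage identity pre-filter (default 0.85).
#' @param span_tol relative span tolerance (default 0.10).
#' @param k anchor length.
#' @return \code{calls} with mcols \code{outgroup_class}
#'   (\code{high_confident}/\code{uncertain}/\code{false}),
#'   \code{identity_prefilter} and \code{outgroup_span} added.
#' @export
classifyOutgroup <- function(calls, macaque, outgroup, flank = 1000L,
                             min_identity = 0.85, span_tol = 0.10, k = 31L) {
  res <- .outgroupSpans(calls, macaque, outgroup, flank, min_identity,
                        span_tol, k)
  gr <- svRanges(calls)
  S4Vectors::mcols(gr)$outgroup_class <- c(
    mac_like = "high_confident", ape_like = "false",
    uncertain = "uncertain")[res$class]
  S4Vectors::mcols(gr)$identity_prefilter <- res$identity
  S4Vectors::mcols(gr)$outgroup_span <- res$span
  SVCallset(gr)
}

#' Distinguish ape-wide from great-ape-specific SVs using a gibbon genome
#'
#' Applies the same local-homology span comparison against the gibbon
#' (lesser ape) genome: gibbon carrying the ape allele means the SV predates
#' the gibbon split (\code{ASSV}); gibbon carrying the macaque-like allele
#' means it arose on the great-ape stem (\code{GASSV}); unresolvable loci
#' are \code{uncertain}. With no gibbon genome every call is
#' \code{uncertain}.
#'
#' @param calls candidate \linkS4class{SVCallset} (macaque frame), normally
#'   the \code{high_confident} subset from [classifyOutgroup].
#' @param gibbon gibbon \linkS4class{GenomeSequence} or NULL.
#' @inheritParams classifyOutgroup
#' @return \code{calls} with mcol \code{ape_scope}
#'   (\code{ASSV}/\code{GASSV}/\code{uncertain}) added.
#' @export
classifyGreatApe <- function(calls, macaque, gibbon, flank = 1000L,
                             min_identity = 0.85, span_tol = 0.10, k = 31L) {
  gr <- svRanges(calls)
  if (is.null(gibbon)) {
    S4Vectors::mcols(gr)$ape_scope <- rep("uncertain", length(gr))
    return(SVCallset(gr))
  }
  res <- .outgroupSpans(calls, macaque, gibbon, flank, min_identity,
                        span_tol, k)
  S4Vectors::mcols(gr)$ape_scope <- c(
    ape_like = "ASSV", mac_like = "GASSV",
    uncertain = "uncertain")[res$class]
  SVCallset(gr)
}
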
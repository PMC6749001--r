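# Assembly quality operations: N-gap detection, flank-anchored gap closure,
# QV scoring and contiguity statistics.

#' Find assembly gaps (runs of N)
#'
#' A gap is a maximal run of N of length >= \code{minRun} (default 2: a lone
#' N is not a gap).
#'
#' @param genome a \linkS4class{GenomeSequence}.
#' @param minRun minimum N-run length counted as a gap.
#' @return \code{GRanges} of gaps sorted by (chrom, start), with mcol
#'   \code{gap_length}.
#' @export
findGaps <- function(genome, minRun = 2L) {
  chs <- character(); sts <- integer(); ws <- integer()
  pat <- sprintf("N{%d,}", minRun)
  for (cn in chromNames(genome)) {
    m <- gregexpr(pat, chromString(genome, cn))[[1L]]
    if (m[1L] != -1L) {
      chs <- c(chs, rep(cn, length(m)))
      sts <- c(sts, as.integer(m))
      ws <- c(ws, attr(m, "match.length"))
    }
  }
  if (length(chs) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$gap_length <- integer()
    return(gr)
  }
  gr <- sort(GenomicRanges::GRanges(chs, IRanges::IRanges(start = sts,
                                                          width = ws)))
  S4Vectors::mcols(gr)$gap_length <- GenomicRanges::width(gr)
  gr
}

#' Assembly quality value from a homozygous-variant count
#'
#' \code{QV = -10 log10(P)} with \code{P} the per-base error probability,
#' estimated as homozygous variants per assembly base.
#'
#' @param n_homozygous_variants number of homozygous variants called against
#'   the assembly (error proxy).
#' @param assembly_size assembly size in bp (> 0).
#' @return List with \code{n_homozygous_variants}, \code{assembly_size},
#'   \code{p_error}, \code{qv} (unrounded), \code{qv_rounded}, and
#'   \code{zero_variants} (TRUE when the QV is an infinite sentinel).
#' @examples
#' computeQV(1110, 1e8)$qv_rounded  # the published-scale worked example: 50
#' @export
computeQV <- function(n_homozygous_variants, assembly_size) {
  stopifnot(assembly_size > 0, n_homozygous_variants >= 0)
  p <- n_homozygous_variants / assembly_size
  qv <- if (p == 0) Inf else -10 * log10(p)
  list(n_homozygous_variants = n_homozygous_variants,
       assembly_size = assembly_size, p_error = p, qv = qv,
       qv_rounded = if (is.finite(qv)) as.integer(round(qv)) else NA_integer_,
       zero_variants = p == 0)
}

#' Contiguity statistics of an assembly
#'
#' Contigs are scaffold segments split at N-runs (length >= 2); N50 is the
#' largest segment length L such that segments >= L sum to at least half the
#' total segment length.
#'
#' @param genome a \linkS4class{GenomeSequence}.
#' @return List with \code{n_scaffolds}, \code{n_contigs},
#'   \code{scaffold_n50}, \code{contig_n50}, \code{total_bases},
#'   \code{ungapped_bases}.
#' @export
assemblyStats <- function(genome) {
  cl <- chromLengths(genome)
  gaps <- findGaps(genome)
  contig_lens <- integer()
  for (cn in chromNames(genome)) {
    g <- gaps[GenomicRanges::seqnames(gaps) == cn]
    if (length(g) == 0L) {
      contig_lens <- c(contig_lens, cl[[cn]])
    } else {
      seg_starts <- c(0L, GenomicRanges::end(g))          # 0-based
      seg_ends <- c(GenomicRanges::start(g) - 1L, cl[[cn]])
      seg <- seg_ends - seg_starts
      contig_lens <- c(contig_lens, seg[seg > 0L])
    }
  }
  list(n_scaffolds = length(cl), n_contigs = length(contig_lens),
       scaffold_n50 = n50(cl), contig_n50 = n50(contig_lens),
       total_bases = sum(cl),
       ungapped_bases = sum(cl) - sum(GenomicRanges::width(gaps)))
}

# Map one flank sequence onto an indexed assembly: unique-k-mer anchors,
# colinear chaining per (assembly chrom, orientation), best chain by flank
# footprint coverage. Returns NULL when nothing maps; otherwise a list with
# the best chain, its unique-anchor coverage, the presence coverage (flank
# footprint of k-mers occurring anywhere in the indexed set, the
# alignment-identity proxy), and an ambiguity flag (a second chain with
# equal best coverage).
.mapFlankChain <- function(index, flank, k, max_chain_gap = 1e5) {
  an <- .kmer_index_anchors(index, flank)
  if (length(an$ref_pos) == 0L) return(NULL)
  pres <- .kmer_index_present(index, flank)
  pres_cov <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(pres + 1L, pres + k))))
  df <- data.frame(rc = an$ref_chrom, rp = an$ref_pos,
                   qp = an$query_pos, o = an$orient)
  chains <- list()
  for (key in unique(paste(df$rc, df$o))) {
    sub <- df[paste(df$rc, df$o) == key, , drop = FALSE]
    sub <- sub[order(sub$qp), , drop = FALSE]
    keep <- .lis_indices(sub$rp * sub$o[1L])
    sub <- sub[keep, , drop = FALSE]
    brk <- c(FALSE, diff(sub$qp) > max_chain_gap |
                    abs(diff(sub$rp)) > max_chain_gap)
    for (id in unique(cumsum(brk))) {
      chains[[length(chains) + 1L]] <- sub[cumsum(brk) == id, , drop = FALSE]
    }
  }
  cov <- vapply(chains, function(ch)
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(ch$qp + 1L, ch$qp + k)))),
    1L)
  best <- which.max(cov)
  ambiguous <- sum(cov == cov[best]) > 1L
  list(chain = chains[[best]], coverage = cov[best], presence = pres_cov,
       ambiguous = ambiguous,
       chrom = chains[[best]]$rc[1L] + 1L, orient = chains[[best]]$o[1L])
}

#' Close reference gaps against a new assembly
#'
#' For each gap in the gapped reference, the up- and downstream flanks
#' (\code{flank} bp, truncated at chromosome ends) are located on the
#' assembly by unique-k-mer anchoring and colinear chaining; a flank maps
#' when its chained anchor footprint covers more than \code{min_aligned} bp
#' of the flank. When both flanks map to the same assembly chromosome in a
#' consistent orientation and order, the assembly boundary coordinates LC
#' (projected end of the upstream flank) and RC (projected start of the
#' downstream flank) are recorded; the gap is closed iff LC < RC and the
#' assembly bases in [LC, RC) contain no N, in which case the closed-gap
#' length is RC - LC and the filled sequence is reported.
#'
#' Status codes: \code{closed}; \code{flank_fail} (neither flank maps, or
#' the best mapping is ambiguous); \code{unclosed} (exactly one flank maps,
#' inconsistent chromosomes/orientations, or RC <= LC).
#'
#' @param gapped_ref the gapped \linkS4class{GenomeSequence}.
#' @param assembly the new assembly to close against.
#' @param flank flank length in bp (default 5000).
#' @param min_aligned minimum chained-anchor footprint on a flank for it to
#'   count as mapped (default 2500).
#' @param k anchor k-mer size (odd, 15-31).
#' @param minRun minimum N-run length defining a gap.
#' @return data.frame with one row per gap: \code{chrom}, \code{start},
#'   \code{end} (1-based gap interval), \code{status}, \code{asm_chrom},
#'   \code{LC}, \code{RC} (0-based assembly boundary coordinates),
#'   \code{closed_length}, \code{filled_sequence}.
#' @export
closeGaps <- function(gapped_ref, assembly, flank = 5000L, min_aligned = 2500L,
                      k = 31L, minRun = 2L) {
  gaps <- findGaps(gapped_ref, minRun = minRun)
  idx <- .kmer_index_build(as.character(chromSeqs(assembly)), k)
  asm_names <- chromNames(assembly)
  cl <- chromLengths(gapped_ref)
  out <- vector("list", length(gaps))
  for (i in seq_along(gaps)) {
    cn <- as.character(GenomicRanges::seqnames(gaps))[i]
    gs <- GenomicRanges::start(gaps)[i] - 1L  # 0-based gap start
    ge <- GenomicRanges::end(gaps)[i]         # 0-based exclusive end
    ref <- chromString(gapped_ref, cn)
    upF <- substr(ref, max(1L, gs - flank + 1L), gs)
    dnF <- substr(ref, ge + 1L, min(cl[[cn]], ge + flank))
    up <- if (nchar(upF) >= k) .mapFlankChain(idx, upF, k) else NULL
    dn <- if (nchar(dnF) >= k) .mapFlankChain(idx, dnF, k) else NULL
    upOK <- !is.null(up) && !up$ambiguous && up$presence > min_aligned
    dnOK <- !is.null(dn) && !dn$ambiguous && dn$presence > min_aligned
    rec <- list(chrom = cn, start = gs + 1L, end = ge, status = "unclosed",
                asm_chrom = NA_character_, LC = NA_integer_, RC = NA_integer_,
                closed_length = NA_integer_, filled_sequence = NA_character_)
    ambiguous <- (!is.null(up) && up$ambiguous) || (!is.null(dn) && dn$ambiguous)
    if (!upOK && !dnOK) {
      rec$status <- "flank_fail"
    } else if (ambiguous) {
      rec$status <- "flank_fail"
    } else if (upOK && dnOK) {
      if (up$chrom == dn$chrom && up$orient == dn$orient) {
        acn <- asm_names[up$chrom]
        if (up$orient == 1L) {
          # nearest-to-gap anchors project the exact flank boundaries
          j <- which.max(up$chain$qp)
          LC <- up$chain$rp[j] - up$chain$qp[j] + nchar(upF)
          j <- which.min(dn$chain$qp)
          RC <- dn$chain$rp[j] - dn$chain$qp[j]
        } else {
          j <- which.max(up$chain$qp)
          LCr <- up$chain$rp[j] + up$chain$qp[j] + k - nchar(upF)
          j <- which.min(dn$chain$qp)
          RCr <- dn$chain$rp[j] + dn$chain$qp[j] + k
          LC <- RCr; RC <- LCr  # reversed locus: downstream flank sits left
        }
        if (!is.na(LC) && !is.na(RC) && LC < RC) {
          fill <- substr(chromString(assembly, acn), LC + 1L, RC)
          if (!grepl("N", fill, fixed = TRUE)) {
            if (up$orient == -1L) fill <- revComp(fill)
            rec$status <- "closed"
            rec$asm_chrom <- acn
            rec$LC <- as.integer(LC); rec$RC <- as.integer(RC)
            rec$closed_length <- as.integer(RC - LC)
            rec$filled_sequence <- fill
          } else rec$status <- "unclosed"
        } else rec$status <- "unclosed"
      } else rec$status <- "unclosed"
    } else {
      rec$status <- "unclosed"  # exactly one flank maps
    }
    out[[i]] <- rec
  }
  do.call(rbind, lapply(out, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}
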
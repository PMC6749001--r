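# SV set algebra and genome-scale summaries: reciprocal-overlap matching,
# novelty, window densities, subtelomeric enrichment, genotype summaries.

#' Reciprocal overlap between paired SV records
#'
#' TRUE iff the two records are on the same chromosome, of the same type
#' (unless \code{typeAware = FALSE}), and the overlap length strictly
#' exceeds \code{threshold} times the length of each record. Insertions
#' participate through their widened footprint (see
#' \linkS4class{SVCallset}).
#'
#' @param a,b \linkS4class{SVCallset}s of equal length; record i of \code{a}
#'   is compared with record i of \code{b}.
#' @param threshold reciprocal-overlap fraction (default 0.5, strict >).
#' @param typeAware require matching SV types.
#' @return Logical vector.
#' @export
reciprocalOverlap <- function(a, b, threshold = 0.5, typeAware = TRUE) {
  ga <- svRanges(a); gb <- svRanges(b)
  stopifnot(length(ga) == length(gb))
  if (length(ga) == 0L) return(logical())
  ov <- pmin(GenomicRanges::end(ga), GenomicRanges::end(gb)) -
        pmax(GenomicRanges::start(ga), GenomicRanges::start(gb)) + 1L
  ok <- as.character(GenomicRanges::seqnames(ga)) ==
        as.character(GenomicRanges::seqnames(gb)) &
        ov > threshold * GenomicRanges::width(ga) &
        ov > threshold * GenomicRanges::width(gb)
  if (typeAware) ok <- ok & svType(a) == svType(b)
  ok
}

# All reciprocal-overlap hit pairs between two callsets, as a data.frame
# (q, r, frac) with frac the smaller of the two mutual overlap fractions.
.recipHits <- function(query, ref, threshold, typeAware) {
  gq <- svRanges(query); gr <- svRanges(ref)
  if (length(gq) == 0L || length(gr) == 0L)
    return(data.frame(q = integer(), r = integer(), frac = numeric()))
  h <- GenomicRanges::findOverlaps(gq, gr, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(h); r <- S4Vectors::subjectHits(h)
  ov <- pmin(GenomicRanges::end(gq)[q], GenomicRanges::end(gr)[r]) -
        pmax(GenomicRanges::start(gq)[q], GenomicRanges::start(gr)[r]) + 1L
  fq <- ov / GenomicRanges::width(gq)[q]
  fr <- ov / GenomicRanges::width(gr)[r]
  keep <- fq > threshold & fr > threshold
  if (typeAware) keep <- keep & svType(query)[q] == svType(ref)[r]
  data.frame(q = q[keep], r = r[keep], frac = pmin(fq, fr)[keep])
}

#' Match a query callset against a reference set
#'
#' Greedy one-to-one matching in decreasing order of (mutual) overlap
#' fraction, ties broken by smaller query start then smaller id. The novelty
#' fraction is the unmatched share of the query.
#'
#' @param query,reference_set \linkS4class{SVCallset}s.
#' @param threshold reciprocal-overlap fraction (strict >).
#' @param typeAware require matching SV types.
#' @return List with \code{matches} (data.frame \code{query_idx},
#'   \code{ref_idx}, \code{fraction}), \code{novelty_fraction}, and
#'   \code{novelty_percent} (nearest integer).
#' @export
matchCallsets <- function(query, reference_set, threshold = 0.5,
                          typeAware = TRUE) {
  hits <- .recipHits(query, reference_set, threshold, typeAware)
  n <- length(query)
  if (nrow(hits)) {
    ord <- order(-hits$frac, GenomicRanges::start(svRanges(query))[hits$q],
                 svID(query)[hits$q])
    hits <- hits[ord, , drop = FALSE]
    usedQ <- logical(n); usedR <- logical(length(reference_set))
    keep <- logical(nrow(hits))
    for (i in seq_len(nrow(hits))) {
      if (!usedQ[hits$q[i]] && !usedR[hits$r[i]]) {
        keep[i] <- TRUE
        usedQ[hits$q[i]] <- TRUE; usedR[hits$r[i]] <- TRUE
      }
    }
    hits <- hits[keep, , drop = FALSE]
  }
  novelty <- if (n == 0L) NA_real_ else (n - nrow(hits)) / n
  list(matches = data.frame(query_idx = hits$q, ref_idx = hits$r,
                            fraction = hits$frac),
       novelty_fraction = novelty,
       novelty_percent = if (is.na(novelty)) NA_integer_ else
         as.integer(round(100 * novelty)))
}

#' Summarise a callset: counts, medians, genome footprint
#'
#' @param callset an \linkS4class{SVCallset}.
#' @param genome_size genome size in bp (> 0).
#' @return List with per-type \code{counts}, \code{percent} (of all SVs),
#'   \code{median_length}, \code{total} count, \code{affected_bp} (union of
#'   DEL/DUP/INV footprints plus insertion lengths), and
#'   \code{fraction_genome}. Medians are NA-flagged for absent types.
#' @export
svSummary <- function(callset, genome_size) {
  stopifnot(genome_size > 0)
  types <- c("DEL", "INS", "DUP", "INV")
  tp <- svType(callset); ln <- svLength(callset)
  counts <- vapply(types, function(t) sum(tp == t), 1L)
  meds <- vapply(types, function(t)
    if (counts[[t]] == 0L) NA_real_ else median(ln[tp == t]), 1)
  gr <- svRanges(callset)
  placed <- gr[tp != "INS"]
  affected <- sum(GenomicRanges::width(GenomicRanges::reduce(placed))) +
    sum(ln[tp == "INS"])
  total <- length(callset)
  list(counts = counts,
       percent = if (total) round(100 * counts / total, 2) else counts * 0,
       median_length = meds, total = total,
       affected_bp = affected,
       fraction_genome = affected / genome_size)
}

#' Per-window SV counts over tiling windows
#'
#' Non-overlapping windows tile each chromosome (the last partial window is
#' kept); an SV is counted in the window containing its start, under the
#' 0-based half-open convention (an SV starting at 0-based 500000 falls in
#' the second 500 kb window).
#'
#' @param callset an \linkS4class{SVCallset}.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param window window size in bp (default 500 kb).
#' @return data.frame with \code{chrom}, \code{window_start} (0-based),
#'   \code{window_end}, per-type counts and \code{total}.
#' @export
windowDensity <- function(callset, chrom_lengths, window = 5e5) {
  gr <- svRanges(callset)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  if (length(gr)) {
    if (!all(chrom %in% names(chrom_lengths)))
      stop("SV on unknown chromosome")
    if (any(start0 >= chrom_lengths[chrom]))
      stop("SV beyond chromosome length")
  }
  out <- list()
  for (cn in names(chrom_lengths)) {
    L <- chrom_lengths[[cn]]
    nw <- as.integer(ceiling(L / window))
    ws <- (seq_len(nw) - 1L) * window
    df <- data.frame(chrom = cn, window_start = ws,
                     window_end = pmin(ws + window, L))
    sel <- chrom == cn
    idx <- start0[sel] %/% window + 1L
    for (t in c("DEL", "INS", "DUP", "INV")) {
      df[[t]] <- tabulate(idx[svType(callset)[sel] == t], nbins = nw)
    }
    df$total <- tabulate(idx, nbins = nw)
    out[[cn]] <- df
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Subtelomeric SV enrichment with a permutation null
#'
#' Fold change between SV density (per bp) in the terminal \code{margin} of
#' each chromosome end and density elsewhere. The null re-draws each SV's
#' start uniformly on its own chromosome (lengths kept); the permutation
#' p-value uses the add-one estimator \code{(1 + #{perm >= obs}) /
#' (1 + n_perm)} and is therefore never 0.
#'
#' @param callset an \linkS4class{SVCallset}.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param margin subtelomeric margin per chromosome end (default 5 Mb).
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return List with \code{fold}, \code{p}, \code{n_subtelomeric},
#'   \code{n_total}, and \code{flagged_chroms} (chromosomes shorter than
#'   twice the margin, whose whole length is subtelomeric).
#' @export
subtelomericEnrichment <- function(callset, chrom_lengths, margin = 5e6,
                                   n_perm = 1000L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  gr <- svRanges(callset)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  if (!all(chrom %in% names(chrom_lengths)))
    stop("SV on unknown chromosome")
  start0 <- GenomicRanges::start(gr) - 1L
  len <- chrom_lengths[chrom]
  flagged <- names(chrom_lengths)[chrom_lengths < 2 * margin]
  sub_bp <- sum(pmin(chrom_lengths, 2 * margin))
  else_bp <- sum(chrom_lengths) - sub_bp
  inSub <- function(s) s < margin | s >= (len - margin)
  foldOf <- function(s) {
    ns <- sum(inSub(s)); ne <- length(s) - ns
    if (else_bp <= 0) return(Inf)
    (ns / sub_bp) / if (ne == 0L) (0.5 / else_bp) else (ne / else_bp)
  }
  obs <- foldOf(start0)
  set.seed(deriveSeed(seed, 6L))
  w <- GenomicRanges::width(gr)
  hi <- pmax(1, len - w + 1)
  perm <- vapply(seq_len(n_perm), function(i)
    foldOf(floor(runif(length(gr)) * hi)), 1)
  p <- (1 + sum(perm >= obs)) / (1 + n_perm)
  list(fold = obs, p = p, n_subtelomeric = sum(inSub(start0)),
       n_total = length(gr), margin = margin, n_perm = n_perm,
       flagged_chroms = flagged)
}

#' Summarise SV genotypes over a panel of individuals
#'
#' Categories: \emph{invalidated} (no valid genotype in any individual),
#' \emph{present} (at least one individual carries at least one alt allele),
#' \emph{absent} (genotyped but no alt allele observed), \emph{fixed}
#' (present and homozygous-alt in every individual under the default
#' \code{fixedRule = "hom"}; \code{"carrier"} instead requires every
#' individual to carry at least one alt), \emph{polymorphic} (present, not
#' fixed). Percentages of present/invalidated are over all SVs; fixed and
#' polymorphic are over present SVs; all reported to 2 decimals.
#'
#' @param genotypes character matrix SV x individual with entries
#'   \code{0/0}, \code{0/1}, \code{1/1} or \code{NA}.
#' @param fixedRule \code{"hom"} or \code{"carrier"}.
#' @return List of counts and percentages.
#' @export
genotypeSummary <- function(genotypes, fixedRule = c("hom", "carrier")) {
  fixedRule <- match.arg(fixedRule)
  stopifnot(is.matrix(genotypes))
  n <- nrow(genotypes)
  invalidated <- apply(genotypes, 1L, function(g) all(is.na(g)))
  carries <- genotypes %in% c("0/1", "1/1")
  dim(carries) <- dim(genotypes)
  present <- apply(carries, 1L, any) & !invalidated
  absent <- !present & !invalidated
  fixed <- if (fixedRule == "hom") {
    apply(genotypes == "1/1", 1L, function(g) all(!is.na(g) & g)) & present
  } else {
    apply(carries | is.na(genotypes), 1L, all) & present &
      !apply(genotypes, 1L, anyNA)
  }
  polymorphic <- present & !fixed
  pct <- function(x, d) if (d == 0L) NA_real_ else round(100 * x / d, 2)
  list(n_total = n, n_present = sum(present), n_invalidated = sum(invalidated),
       n_absent = sum(absent), n_fixed = sum(fixed),
       n_polymorphic = sum(polymorphic),
       present_pct = pct(sum(present), n),
       invalidated_pct = pct(sum(invalidated), n),
       fixed_pct = pct(sum(fixed), sum(present)),
       polymorphic_pct = pct(sum(polymorphic), sum(present)))
}
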
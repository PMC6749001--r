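# Ape-monkey differential enhancer (ADE) calling from H3K27Ac count
# matrices, ASSV x ADE intersection, gene-window annotation, and the
# neocortical-layer expression comparison.

#' Two-sample t test with direction
#'
#' Two-tailed Student t test, pooled variance by default (the chimp group
#' has only two samples, where Welch degrees of freedom are unstable; Welch
#' is available via \code{varEqual = FALSE}). Degenerate zero-variance input
#' yields p = 1 when the groups are identical in mean and p = 0 otherwise.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param varEqual pooled-variance Student t (default) or Welch.
#' @return List with \code{p}, \code{direction} (sign of mean(x) - mean(y)),
#'   \code{statistic}.
#' @export
twoSampleTest <- function(x, y, varEqual = TRUE) {
  if (length(x) < 2L || length(y) < 2L) stop("group size < 2")
  dir <- sign(mean(x) - mean(y))
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(list(p = if (dir == 0) 1 else 0, direction = dir,
                statistic = if (dir == 0) 0 else Inf * dir))
  }
  tt <- t.test(x, y, var.equal = varEqual)
  list(p = unname(tt$p.value), direction = dir,
       statistic = unname(tt$statistic))
}

# Vectorized pooled-variance two-sample t over matrix rows.
.rowPooledT <- function(m, i1, i2) {
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(m[, i1, drop = FALSE]); m2 <- rowMeans(m[, i2, drop = FALSE])
  v1 <- rowSums((m[, i1, drop = FALSE] - m1)^2) / (n1 - 1L)
  v2 <- rowSums((m[, i2, drop = FALSE] - m2)^2) / (n2 - 1L)
  sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  p <- 2 * pt(-abs(t), df = n1 + n2 - 2L)
  p[se == 0] <- ifelse(m1[se == 0] == m2[se == 0], 1, 0)
  list(p = p, diff = m1 - m2)
}

#' Call ape-monkey differential enhancers (ADEs)
#'
#' An enhancer is an ADE when the macaque-human and macaque-chimp
#' comparisons are both significant (p < alpha) in the same direction while
#' the human-chimp comparison is not (p > alpha). Counts are tested on the
#' log2(count + 1) scale; the reported log2 fold change is
#' log2(((mean_human + mean_chimp)/2) / mean_macaque) on the raw count
#' scale.
#'
#' @param em an \linkS4class{EnhancerMatrix}.
#' @param alpha significance level (default 0.05, the raw two-sided
#'   criterion; no multiple-testing correction by default).
#' @param adjust apply Benjamini-Hochberg adjustment to the three p-value
#'   sets before thresholding (off by default).
#' @return data.frame with one row per enhancer: \code{p_mh}, \code{p_mc},
#'   \code{p_hc}, \code{direction} (gain/loss, ape vs macaque),
#'   \code{log2fc}, \code{is_ade}.
#' @export
callADEs <- function(em, alpha = 0.05, adjust = FALSE) {
  counts <- SummarizedExperiment::assay(em, "counts")
  sp <- sampleSpecies(em)
  lm_ <- log2(counts + 1)
  ih <- which(sp == "human"); ic <- which(sp == "chimp")
  im <- which(sp == "macaque")
  mh <- .rowPooledT(lm_, im, ih)
  mc_ <- .rowPooledT(lm_, im, ic)
  hc <- .rowPooledT(lm_, ih, ic)
  p_mh <- mh$p; p_mc <- mc_$p; p_hc <- hc$p
  if (adjust) {
    p_mh <- p.adjust(p_mh, "BH"); p_mc <- p.adjust(p_mc, "BH")
    p_hc <- p.adjust(p_hc, "BH")
  }
  sameDir <- sign(mh$diff) == sign(mc_$diff) & sign(mh$diff) != 0
  is_ade <- p_mh < alpha & p_mc < alpha & p_hc > alpha & sameDir
  mean_h <- rowMeans(counts[, ih, drop = FALSE])
  mean_c <- rowMeans(counts[, ic, drop = FALSE])
  mean_m <- rowMeans(counts[, im, drop = FALSE])
  log2fc <- log2(((mean_h + mean_c) / 2) / mean_m)
  # mh$diff is macaque - ape on the log scale: negative diff = ape gain
  direction <- ifelse(mh$diff < 0 & mc_$diff < 0, "gain",
                      ifelse(mh$diff > 0 & mc_$diff > 0, "loss", NA))
  data.frame(p_mh = p_mh, p_mc = p_mc, p_hc = p_hc,
             direction = direction, log2fc = log2fc, is_ade = is_ade)
}

#' Intersect ASSVs with ADEs in the shared human frame
#'
#' Pairs every ASSV with every ADE its human-frame interval overlaps by at
#' least 1 bp.
#'
#' @param assvs \linkS4class{SVCallset} with human-frame mcols (from
#'   [overlayHumanCoordinates]), or a \code{GRanges} already in the human
#'   frame.
#' @param ades \code{GRanges} of ADE intervals (e.g. the rowRanges of an
#'   \linkS4class{EnhancerMatrix} subset to \code{is_ade} rows).
#' @return List with \code{pairs} (data.frame \code{assv_idx},
#'   \code{ade_idx}), \code{n_ades_hit}, \code{n_assvs_hit}.
#' @export
intersectAssvAde <- function(assvs, ades) {
  if (is(assvs, "SVCallset")) {
    mc <- S4Vectors::mcols(svRanges(assvs))
    if (!"human_chrom" %in% colnames(mc))
      stop("frame mismatch: calls lack human coordinates")
    ok <- !is.na(mc$human_chrom)
    gr <- GenomicRanges::GRanges(
      mc$human_chrom[ok],
      IRanges::IRanges(start = mc$human_start[ok] + 1L,
                       end = pmax(mc$human_end[ok], mc$human_start[ok] + 1L)))
    idx_map <- which(ok)
  } else {
    gr <- assvs
    idx_map <- seq_along(gr)
  }
  h <- GenomicRanges::findOverlaps(gr, ades, ignore.strand = TRUE)
  pairs <- data.frame(assv_idx = idx_map[S4Vectors::queryHits(h)],
                      ade_idx = S4Vectors::subjectHits(h))
  list(pairs = pairs,
       n_ades_hit = length(unique(pairs$ade_idx)),
       n_assvs_hit = length(unique(pairs$assv_idx)))
}

#' Assign SVs to genes within a window
#'
#' An SV is assigned to every gene whose interval, extended by \code{window}
#' bp on both sides, it overlaps; SVs hitting no gene are intergenic.
#'
#' @param svs \code{GRanges} of SV intervals (or an
#'   \linkS4class{SVCallset}).
#' @param genes \code{GRanges} with mcol \code{gene_id}.
#' @param window flanking distance in bp (default 5 kb).
#' @return List with \code{genes} (per-SV list of gene ids) and
#'   \code{intergenic} (logical vector).
#' @export
annotateNearGenes <- function(svs, genes, window = 5000L) {
  if (is(svs, "SVCallset")) svs <- svRanges(svs)
  ext <- genes
  GenomicRanges::start(ext) <- pmax(1L, GenomicRanges::start(genes) - window)
  GenomicRanges::end(ext) <- GenomicRanges::end(genes) + window
  h <- GenomicRanges::findOverlaps(svs, ext, ignore.strand = TRUE)
  ids <- S4Vectors::mcols(genes)$gene_id
  lst <- split(ids[S4Vectors::subjectHits(h)],
               factor(S4Vectors::queryHits(h), levels = seq_along(svs)))
  list(genes = lst, intergenic = lengths(lst) == 0L)
}

#' Paired t test of layer expression profiles between species
#'
#' Two-tailed paired t test across matched laminar sections (16 neocortical
#' layers plus adjacent white matter in the motivating data) between two
#' species mean profiles.
#'
#' @param x,y per-section expression profiles of equal length (paired by
#'   section).
#' @return List with \code{p}, \code{direction} (sign of mean(x - y)),
#'   \code{statistic}.
#' @export
layerExpressionTest <- function(x, y) {
  if (length(x) != length(y)) stop("unequal section counts")
  d <- x - y
  if (stats::var(d) == 0) {
    return(list(p = if (mean(d) == 0) 1 else 0, direction = sign(mean(d)),
                statistic = if (mean(d) == 0) 0 else Inf * sign(mean(d))))
  }
  tt <- t.test(x, y, paired = TRUE)
  list(p = unname(tt$p.value), direction = sign(mean(d)),
       statistic = unname(tt$statistic))
}
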
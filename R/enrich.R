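# Trait-gene-set enrichment of ASSVs: the random-draw permutation null and
# the Fisher's exact alternative.

# Per-SV lists of trait-gene indices hit within +/- window.
.geneHits <- function(svs, genes, window) {
  if (is(svs, "SVCallset")) svs <- svRanges(svs)
  ext <- genes
  GenomicRanges::start(ext) <- pmax(1L, GenomicRanges::start(genes) - window)
  GenomicRanges::end(ext) <- GenomicRanges::end(genes) + window
  h <- GenomicRanges::findOverlaps(svs, ext, ignore.strand = TRUE)
  unname(split(S4Vectors::subjectHits(h),
               factor(S4Vectors::queryHits(h), levels = seq_along(svs))))
}

#' Permutation enrichment of an ASSV subset in a trait gene set
#'
#' The observed statistic is the number of distinct trait genes intersected
#' (within \code{gene_window}) by the ASSV subset. The null redraws
#' \code{|assv_ids|} SVs uniformly without replacement from the full callset
#' and recomputes the statistic; the empirical p-value uses the add-one
#' estimator and is never 0.
#'
#' @param all_svs the SV universe (\linkS4class{SVCallset} or \code{GRanges}
#'   with mcol \code{id}), in the same coordinate frame as \code{genes}.
#' @param assv_ids ids of the ASSV subset (must be a subset of the
#'   universe's ids).
#' @param genes \code{GRanges} of trait genes with mcol \code{gene_id}.
#' @param gene_window flanking window in bp (default 5 kb).
#' @param n_iter number of null draws (>= 100).
#' @param seed integer seed.
#' @param statistic \code{"genes"} counts distinct genes hit (default);
#'   \code{"pairs"} counts SV-gene pairs.
#' @return List with \code{observed}, \code{n_iter}, \code{empirical_p},
#'   \code{null_mean}.
#' @export
permutationEnrichment <- function(all_svs, assv_ids, genes, gene_window = 5000L,
                                  n_iter = 10000L, seed = 1L,
                                  statistic = c("genes", "pairs")) {
  statistic <- match.arg(statistic)
  if (n_iter < 100L) stop("n_iter must be >= 100")
  ids <- if (is(all_svs, "SVCallset")) svID(all_svs) else
    S4Vectors::mcols(all_svs)$id
  if (!all(assv_ids %in% ids)) stop("assv_ids must be a subset of all_svs")
  m <- length(assv_ids)
  if (m > length(ids)) stop("subset larger than universe")
  hits <- .geneHits(all_svs, genes, gene_window)
  stat <- if (statistic == "genes") {
    function(idx) length(unique(unlist(hits[idx], use.names = FALSE)))
  } else {
    function(idx) sum(lengths(hits[idx]))
  }
  obs <- stat(match(assv_ids, ids))
  set.seed(deriveSeed(seed, 7L))
  null <- vapply(seq_len(n_iter), function(i)
    stat(sample.int(length(ids), m)), 1L)
  list(observed = obs, n_iter = n_iter,
       empirical_p = (1 + sum(null >= obs)) / (1 + n_iter),
       null_mean = mean(null))
}

#' Fisher's exact enrichment of an ASSV subset in a trait gene set
#'
#' 2x2 table over the SV universe: membership in the ASSV subset crossed
#' with intersecting a trait gene (within \code{gene_window}); two-sided
#' Fisher's exact test with the sample odds ratio.
#'
#' @inheritParams permutationEnrichment
#' @return List with \code{fisher_p}, \code{odds_ratio}, \code{table}, and
#'   \code{degenerate} (TRUE with an empty margin, where p is 1 by
#'   convention).
#' @export
fisherEnrichment <- function(all_svs, assv_ids, genes, gene_window = 5000L) {
  ids <- if (is(all_svs, "SVCallset")) svID(all_svs) else
    S4Vectors::mcols(all_svs)$id
  if (!all(assv_ids %in% ids)) stop("assv_ids must be a subset of all_svs")
  hits <- .geneHits(all_svs, genes, gene_window)
  inSet <- ids %in% assv_ids
  hitsGene <- lengths(hits) > 0L
  tab <- table(factor(inSet, levels = c(TRUE, FALSE)),
               factor(hitsGene, levels = c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    return(list(fisher_p = 1, odds_ratio = NA_real_, table = tab,
                degenerate = TRUE))
  }
  ft <- fisher.test(tab)
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  list(fisher_p = unname(ft$p.value),
       odds_ratio = (a * d) / (b * c_),
       table = tab, degenerate = FALSE)
}
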
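# End-to-end orchestration: simulate -> assembly QC -> ASSV inference ->
# SV summaries -> differential enhancers -> trait enrichment, with a single
# top-level seed feeding named substreams so partial re-runs reproduce.

#' Build a pipeline configuration
#'
#' Defaults define the desk-scale study conditions: a 2 x 1 Mb ancestral
#' genome at GC 0.41 with 15% diverged repeats, the [defaultBranchSpecs]
#' event load, k = 31 anchors, 0.5 reciprocal-overlap thresholds, 5 kb gap
#' flanks with the 2.5 kb aligned-length rule, 1 kb outgroup flanks with the
#' 0.85 identity pre-filter, 2000 enhancers with 5% planted gains and
#' losses at |log2FC| = 2 and CV 0.15 over (3, 2, 3) samples, a
#' 5-individual genotype panel, and a 100 kb subtelomeric margin (the 5 Mb
#' margin of a full-size genome scaled to the 1 Mb chromosomes).
#'
#' @param seed top-level integer seed; every stage derives its own
#'   substream from it.
#' @param ... overrides for any config field (see the function definition
#'   for the full list).
#' @return A \code{pipelineConfig} list.
#' @export
pipelineConfig <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_chrom = 2L, chrom_length = 1e6, gc = 0.41, repeat_fraction = 0.15,
    repeat_divergence = 0.15, subst_rate = 0.002,
    branch_specs = NULL,
    k = 31L, threshold = 0.5, min_len = 50L, max_chain_gap = 1e5,
    gap_flank = 5000L, min_aligned = 2500L, n_gaps = 20L,
    gap_len = c(100L, 2000L), draft_error_rate = 1.11e-5,
    outgroup_flank = 1000L, min_identity = 0.85, span_tol = 0.10,
    n_enhancers = 2000L, frac_gain = 0.05, frac_loss = 0.05,
    effect_log2fc = 2, cv = 0.15,
    enhancer_samples = c(human = 3L, chimp = 2L, macaque = 3L),
    n_individuals = 5L, fixed_fraction = 0.134,
    invalidation_rate_repeat_ins = 0.6,
    subtelo_margin = 1e5, n_perm = 1000L, n_iter = 2000L,
    gene_window = 5000L, n_genes = 60L, n_private_alt = 5L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (is.null(cfg$branch_specs))
    cfg$branch_specs <- defaultBranchSpecs(subst_rate = cfg$subst_rate)
  structure(cfg, class = "pipelineConfig")
}

.validateConfig <- function(cfg) {
  if (cfg$n_iter < 100L) stop("validation error: n_iter must be >= 100")
  if (cfg$n_perm < 1L) stop("validation error: n_perm must be >= 1")
  if (cfg$threshold <= 0 || cfg$threshold >= 1)
    stop("validation error: threshold must be in (0, 1)")
  .checkK(cfg$k)
  invisible(TRUE)
}

# swap anchor roles (forward <-> reverse calling share one anchor relation)
.swapAnchors <- function(a) {
  df <- data.frame(ref_chrom = a$query_chrom, ref_pos = a$query_pos,
                   query_chrom = a$ref_chrom, query_pos = a$ref_pos,
                   orient = a$orient, stringsAsFactors = FALSE)
  df <- df[order(df$ref_chrom, df$ref_pos), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "k") <- attr(a, "k")
  df
}

# plant substitution errors at the given rate, returning the modified
# genome and the number of planted sites
.plantErrors <- function(genome, rate, seed) {
  set.seed(seed)
  cl <- chromLengths(genome)
  total <- sum(cl)
  n <- rbinom(1L, total, rate)
  raws <- lapply(chromNames(genome), function(cn)
    charToRaw(chromString(genome, cn)))
  names(raws) <- chromNames(genome)
  if (n > 0L) {
    cuml <- c(0, cumsum(as.double(cl)))
    gpos <- sort(sample.int(total, n))
    ci <- findInterval(gpos - 1L, cuml[-length(cuml)])
    pos1 <- as.integer(gpos - cuml[ci])
    for (i in seq_len(n)) {
      ch <- rawToChar(raws[[ci[i]]][pos1[i]])
      alt <- setdiff(c("A", "C", "G", "T"), ch)
      raws[[ci[i]]][pos1[i]] <- charToRaw(alt[sample.int(length(alt), 1L)])
    }
  }
  list(genome = GenomeSequence(vapply(raws, rawToChar, ""),
                               name = paste0(genomeName(genome), "_draft")),
       n_errors = n)
}

#' Run the full synthetic-to-report pipeline
#'
#' Executes simulation, gap closure and QV scoring, bidirectional pairwise
#' SV calling against every ape, cross-ape intersection, human-coordinate
#' overlay, outgroup classification, truth evaluation, SV summaries,
#' genotype summaries, ADE calling with truth evaluation, ASSV x ADE
#' intersection, and trait gene-set enrichment. Every stage draws its
#' randomness from a substream of \code{config$seed}.
#'
#' @param config a [pipelineConfig].
#' @param outdir optional directory; when given, per-stage TSVs and a JSON
#'   report are written there.
#' @return A nested report list (also written as JSON when \code{outdir} is
#'   given).
#' @export
runPipeline <- function(config = pipelineConfig(), outdir = NULL) {
  .validateConfig(config)
  cfg <- config
  seed <- cfg$seed

  ## --- simulate -----------------------------------------------------------
  anc <- generateAncestralGenome(cfg$n_chrom, cfg$chrom_length, cfg$gc,
                                 cfg$repeat_fraction, seed = seed,
                                 repeat_divergence = cfg$repeat_divergence)
  sim <- evolveGenomes(anc, cfg$branch_specs, seed = seed)
  genomes <- sim$genomes
  truth <- sim$truth
  mac <- genomes$macaque

  ## --- assembly QC --------------------------------------------------------
  gp <- makeGappedReference(mac, n_gaps = cfg$n_gaps, gap_len = cfg$gap_len,
                            seed = seed)
  draft <- .plantErrors(mac, cfg$draft_error_rate, deriveSeed(seed, 11L))
  closures <- closeGaps(gp$genome, draft$genome, flank = cfg$gap_flank,
                        min_aligned = cfg$min_aligned, k = cfg$k)
  closed <- closures$status == "closed"
  fill_ident <- NA_real_
  if (any(closed)) {
    tr <- gp$truth
    key <- paste(closures$chrom, closures$start)
    tkey <- paste(as.character(GenomicRanges::seqnames(tr)),
                  GenomicRanges::start(tr))
    match_idx <- match(key, tkey)
    idents <- vapply(which(closed), function(i) {
      ts <- S4Vectors::mcols(tr)$seq[match_idx[i]]
      fs <- closures$filled_sequence[i]
      if (nchar(ts) != nchar(fs)) return(0)
      mean(strsplit(ts, "")[[1L]] == strsplit(fs, "")[[1L]])
    }, 1)
    fill_ident <- mean(idents)
  }
  qv <- computeQV(draft$n_errors, sum(chromLengths(mac)))
  stats <- assemblyStats(gp$genome)

  ## --- lineage: ASSV inference -------------------------------------------
  apes <- c("human", "chimp", "gorilla", "orangutan")
  macIdx <- .kmer_index_build(as.character(chromSeqs(mac)), cfg$k)
  per_ape <- list()
  for (ape in apes) {
    an <- .anchorsFromIndex(macIdx, mac, genomes[[ape]], cfg$k)
    per_ape[[ape]] <- callBidirectional(mac, genomes[[ape]], k = cfg$k,
                                        min_len = cfg$min_len,
                                        max_chain_gap = cfg$max_chain_gap,
                                        threshold = cfg$threshold,
                                        anchors = an)
  }
  candidates <- intersectAcrossApes(per_ape, threshold = cfg$threshold,
                                    pivot = "human")

  # a second human assembly differing by private SVs (GRCh38 stand-in)
  set.seed(deriveSeed(seed, 12L))
  hl <- chromLengths(genomes$human)
  priv <- data.frame(
    chrom = names(hl)[1L],
    pos0 = sort(sample.int(hl[[1L]] - 20000L, cfg$n_private_alt) + 10000L),
    type = "DEL", len = 300L, seq = NA_character_)
  keepPriv <- c(TRUE, diff(priv$pos0) > 1000L)
  priv <- priv[keepPriv, , drop = FALSE]
  human_alt <- applySVs(genomes$human, priv, name = "human_alt")
  an_alt <- .anchorsFromIndex(macIdx, mac, human_alt, cfg$k)
  calls_alt <- callBidirectional(mac, human_alt, k = cfg$k,
                                 min_len = cfg$min_len,
                                 max_chain_gap = cfg$max_chain_gap,
                                 threshold = cfg$threshold, anchors = an_alt)
  candidates <- overlayHumanCoordinates(candidates, calls_alt,
                                        threshold = cfg$threshold)
  candidates <- classifyOutgroup(candidates, mac, genomes$marmoset,
                                 flank = cfg$outgroup_flank,
                                 min_identity = cfg$min_identity,
                                 span_tol = cfg$span_tol, k = cfg$k)
  candidates <- classifyGreatApe(candidates, mac, genomes$gibbon,
                                 flank = cfg$outgroup_flank,
                                 min_identity = cfg$min_identity,
                                 span_tol = cfg$span_tol, k = cfg$k)

  ## --- truth evaluation ---------------------------------------------------
  mcT <- S4Vectors::mcols(truth)
  truth_cs <- SVCallset(truth)
  m <- matchCallsets(truth_cs, candidates, threshold = cfg$threshold)
  matched_class <- rep(NA_character_, length(truth))
  matched_class[m$matches$query_idx] <-
    S4Vectors::mcols(svRanges(candidates))$outgroup_class[m$matches$ref_idx]
  shared_idx <- which(mcT$branch == "ape_ancestor")
  mac_idx <- which(mcT$branch == "macaque")
  sens <- if (length(shared_idx))
    sum(matched_class[shared_idx] %in% "high_confident") / length(shared_idx)
  else NA_real_
  mac_reached <- mac_idx[!is.na(matched_class[mac_idx])]
  false_rate <- if (length(mac_reached))
    mean(matched_class[mac_reached] == "false") else NA_real_
  n_matched_any <- sum(!is.na(matched_class))
  precision <- if (length(candidates))
    nrow(m$matches) / length(candidates) else NA_real_

  ## --- svcore summaries ---------------------------------------------------
  cl_mac <- chromLengths(mac)
  summ <- svSummary(candidates, sum(cl_mac))
  dens <- windowDensity(per_ape$human, cl_mac, window = cfg$subtelo_margin)
  subtelo <- subtelomericEnrichment(per_ape$human, cl_mac,
                                    margin = cfg$subtelo_margin,
                                    n_perm = cfg$n_perm,
                                    seed = deriveSeed(seed, 13L))
  geno <- simulateGenotypes(truth, n_individuals = cfg$n_individuals,
                            fixed_fraction = cfg$fixed_fraction,
                            invalidation_rate_repeat_ins =
                              cfg$invalidation_rate_repeat_ins,
                            seed = seed)
  geno_sum <- genotypeSummary(geno)

  ## --- regulome -----------------------------------------------------------
  hl_all <- chromLengths(genomes$human)
  n_enh <- cfg$n_enhancers
  enh_per_chrom <- ceiling(n_enh / length(hl_all))
  iv_ch <- rep(names(hl_all), each = enh_per_chrom)
  iv_st <- unlist(lapply(names(hl_all), function(cn) {
    step <- (hl_all[[cn]] - 2000L) / enh_per_chrom
    as.integer(floor((seq_len(enh_per_chrom) - 1L) * step)) + 1000L
  }))
  iv <- GenomicRanges::GRanges(iv_ch,
    IRanges::IRanges(start = iv_st, width = 600L))[seq_len(n_enh)]
  enh <- simulateEnhancerMatrix(n_enh, cfg$frac_gain, cfg$frac_loss,
                                cfg$enhancer_samples, cfg$effect_log2fc,
                                cfg$cv, seed = seed, intervals = iv)
  ades <- callADEs(enh$matrix)
  planted <- enh$truth != "null"
  ade_power <- if (any(planted))
    mean(ades$is_ade[planted] &
         ades$direction[planted] == enh$truth[planted], na.rm = TRUE) else NA
  ade_null_rate <- if (any(!planted)) mean(ades$is_ade[!planted]) else NA
  ade_iv <- SummarizedExperiment::rowRanges(enh$matrix)[which(ades$is_ade)]
  axa <- intersectAssvAde(candidates, ade_iv)

  ## --- enrichment ---------------------------------------------------------
  set.seed(deriveSeed(seed, 14L))
  gene_len <- sample(2000:10000, cfg$n_genes, replace = TRUE)
  gene_chrom <- sample(names(hl_all), cfg$n_genes, replace = TRUE, prob = hl_all)
  gene_start <- vapply(seq_len(cfg$n_genes), function(i)
    sample.int(hl_all[[gene_chrom[i]]] - gene_len[i] - 1000L, 1L), 1L)
  genes <- GenomicRanges::GRanges(gene_chrom,
    IRanges::IRanges(start = gene_start, width = gene_len),
    gene_id = sprintf("gene%03d", seq_len(cfg$n_genes)))
  trait_sizes <- round(cfg$n_genes * c(tail_development = 0.30,
                                       brain_size = 0.05,
                                       adducted_thumbs = 0.12,
                                       body_size = 0.53))
  trait_sizes[trait_sizes < 2] <- 2L
  traits <- lapply(trait_sizes, function(sz)
    genes[sample.int(cfg$n_genes, sz)])

  universe <- swapFrame(calls_alt)  # human-frame SV universe
  msub <- matchCallsets(candidates, calls_alt, threshold = cfg$threshold)
  assv_ids <- svID(calls_alt)[msub$matches$ref_idx]
  enrich <- lapply(names(traits), function(tr) {
    pe <- permutationEnrichment(universe, assv_ids, traits[[tr]],
                                gene_window = cfg$gene_window,
                                n_iter = cfg$n_iter,
                                seed = deriveSeed(seed, 15L))
    fe <- fisherEnrichment(universe, assv_ids, traits[[tr]],
                           gene_window = cfg$gene_window)
    list(trait = tr, observed = pe$observed, empirical_p = pe$empirical_p,
         fisher_p = fe$fisher_p, odds_ratio = fe$odds_ratio)
  })
  names(enrich) <- names(traits)

  report <- list(
    config = cfg[setdiff(names(cfg), "branch_specs")],
    simulate = list(
      n_truth = length(truth),
      truth_by_branch = as.list(table(mcT$branch)),
      genome_bp = sum(cl_mac)),
    asmqc = list(
      n_gaps = nrow(closures),
      n_closed = sum(closed),
      closure_rate = if (nrow(closures)) sum(closed) / nrow(closures) else NA,
      fill_identity = fill_ident,
      qv = qv$qv, qv_rounded = qv$qv_rounded,
      contig_n50 = stats$contig_n50, scaffold_n50 = stats$scaffold_n50,
      ungapped_bases = stats$ungapped_bases),
    lineage = list(
      n_per_ape = vapply(per_ape, length, 1L),
      n_candidates = length(candidates),
      n_high_confident = sum(S4Vectors::mcols(svRanges(candidates))$outgroup_class
                             == "high_confident"),
      sensitivity = sens,
      macaque_false_rate = false_rate,
      precision = precision,
      n_truth_matched = n_matched_any),
    svcore = list(
      summary = summ,
      subtelomeric = subtelo[c("fold", "p", "n_subtelomeric", "n_total")],
      genotype = geno_sum),
    regulome = list(
      n_ades = sum(ades$is_ade),
      ade_power = ade_power,
      ade_null_rate = ade_null_rate,
      n_ades_with_assv = axa$n_ades_hit,
      n_assvs_in_ades = axa$n_assvs_hit),
    enrich = enrich)

  if (!is.null(outdir)) writeReport(report, candidates, closures, dens, outdir)
  report
}

#' Write a pipeline report bundle
#'
#' @param report report list from [runPipeline].
#' @param candidates candidate \linkS4class{SVCallset}.
#' @param closures gap-closure data.frame.
#' @param density window-density data.frame.
#' @param outdir output directory (created if needed).
#' @return \code{outdir}, invisibly.
#' @export
writeReport <- function(report, candidates, closures, density, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  writeSVBed(candidates, file.path(outdir, "assv_candidates.tsv"))
  write.table(closures[, setdiff(colnames(closures), "filled_sequence")],
              file.path(outdir, "gap_closures.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(density, file.path(outdir, "window_density.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
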
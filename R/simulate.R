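# Synthetic catarrhine genome simulator.
#
# The generator's job is to produce data with the statistical structure the
# downstream analyses assume: an ancestral genome with diverged repeat
# copies, tip genomes carrying SVs planted on labelled branches of the fixed
# catarrhine topology, an N-gapped "old reference", H3K27Ac count matrices
# with planted ape-specific gains/losses, and SV genotype tables for a small
# panel of individuals. Every function is deterministic given its seed.

BRANCHES <- c("ape_ancestor", "great_ape_ancestor", "human", "chimp",
              "gorilla", "orangutan", "gibbon", "macaque", "marmoset")

# tips below each branch in the fixed topology
# (((((human,chimp),gorilla),orangutan),gibbon),macaque),marmoset
.branchTips <- list(
  ape_ancestor = c("human", "chimp", "gorilla", "orangutan", "gibbon"),
  great_ape_ancestor = c("human", "chimp", "gorilla", "orangutan"),
  human = "human", chimp = "chimp", gorilla = "gorilla",
  orangutan = "orangutan", gibbon = "gibbon",
  macaque = "macaque", marmoset = "marmoset")

# complement lookup on raw bytes (uppercase alphabet; N maps to N)
.compTable <- local({
  tbl <- charToRaw(paste(rep("N", 256), collapse = ""))
  from <- charToRaw("ACGTN"); to <- charToRaw("TGCAN")
  tbl[as.integer(from) + 1L] <- to
  tbl
})

#' Specify the SV and substitution load of one phylogeny branch
#'
#' Default length distributions are log-normal with medians 319 bp
#' (deletions) and 231 bp (insertions) and sigma-log 1, floored at the 50 bp
#' SV size definition and capped at \code{maxLen}.
#'
#' @param branch branch label, one of
#'   \code{ape_ancestor, great_ape_ancestor, human, chimp, gorilla,
#'   orangutan, gibbon, macaque, marmoset}.
#' @param n_del,n_ins,n_dup,n_inv event counts on this branch.
#' @param del_len,ins_len length distributions as
#'   \code{list(meanlog=, sdlog=)}.
#' @param subst_rate substitutions per base on this branch, in [0, 0.05].
#' @param maxLen length cap for drawn events (keeps desk-scale chromosomes
#'   tileable).
#' @return A \code{branchSpec} list.
#' @export
branchSpec <- function(branch, n_del = 0L, n_ins = 0L, n_dup = 0L, n_inv = 0L,
                       del_len = list(meanlog = log(319), sdlog = 1),
                       ins_len = list(meanlog = log(231), sdlog = 1),
                       subst_rate = 0.002, maxLen = 10000L) {
  branch <- match.arg(branch, BRANCHES)
  stopifnot(n_del >= 0, n_ins >= 0, n_dup >= 0, n_inv >= 0,
            subst_rate >= 0, subst_rate <= 0.05)
  structure(list(branch = branch, n_del = as.integer(n_del),
                 n_ins = as.integer(n_ins), n_dup = as.integer(n_dup),
                 n_inv = as.integer(n_inv), del_len = del_len,
                 ins_len = ins_len, subst_rate = subst_rate,
                 maxLen = as.integer(maxLen)), class = "branchSpec")
}

#' Default branch specifications for the study conditions
#'
#' 60 shared ape-stem events (40 DEL + 20 INS, the ~2:1 deletion bias seen in
#' ape-specific SV sets), 40 macaque-branch events (27 DEL + 13 INS), 20 per
#' great-ape tip (13 DEL + 7 INS). The marmoset outgroup and gibbon carry
#' substitution divergence but no planted SVs by default.
#'
#' @param subst_rate substitutions per base per branch applied to every
#'   branch (default 0.002).
#' @param n_ape_ancestor,n_macaque,n_per_tip total event counts for the ape
#'   stem, the macaque branch, and each great-ape tip.
#' @return Named list of [branchSpec] objects covering all branches.
#' @export
defaultBranchSpecs <- function(subst_rate = 0.002, n_ape_ancestor = 60L,
                               n_macaque = 40L, n_per_tip = 20L) {
  split2 <- function(n) c(del = round(n * 2 / 3), ins = n - round(n * 2 / 3))
  aa <- split2(n_ape_ancestor); mq <- split2(n_macaque); tp <- split2(n_per_tip)
  specs <- list(
    branchSpec("ape_ancestor", n_del = aa["del"], n_ins = aa["ins"],
               subst_rate = subst_rate),
    branchSpec("great_ape_ancestor", subst_rate = subst_rate),
    branchSpec("human", n_del = tp["del"], n_ins = tp["ins"],
               subst_rate = subst_rate),
    branchSpec("chimp", n_del = tp["del"], n_ins = tp["ins"],
               subst_rate = subst_rate),
    branchSpec("gorilla", n_del = tp["del"], n_ins = tp["ins"],
               subst_rate = subst_rate),
    branchSpec("orangutan", n_del = tp["del"], n_ins = tp["ins"],
               subst_rate = subst_rate),
    branchSpec("gibbon", subst_rate = subst_rate),
    branchSpec("macaque", n_del = mq["del"], n_ins = mq["ins"],
               subst_rate = subst_rate),
    branchSpec("marmoset", subst_rate = subst_rate))
  setNames(specs, vapply(specs, `[[`, "", "branch"))
}

#' Generate an ancestral genome with diverged repeat copies
#'
#' Background bases are drawn i.i.d. at the requested GC content. A fraction
#' \code{repeat_fraction} of bases is covered by planted copies of two
#' repeat families: a SINE-like 300 bp monomer and a LINE-like element
#' (random-length 1-4 kb fragments of a 4 kb consensus, mimicking 5'
#' truncation). Each copy is independently mutated at
#' \code{repeat_divergence} per base, so copies are recognisable as a family
#' but mostly distinguishable at k-mer scale, as in a real genome's older
#' repeat complement.
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param chrom_length chromosome length in bp (>= 10000).
#' @param gc GC fraction of the non-repeat background.
#' @param repeat_fraction target fraction of bases covered by repeat copies
#'   (<= 0.95).
#' @param seed integer seed.
#' @param repeat_divergence per-base substitution rate applied independently
#'   to each planted copy.
#' @return A \linkS4class{GenomeSequence} named \code{"ancestor"} with repeat
#'   annotation.
#' @export
generateAncestralGenome <- function(n_chrom = 2L, chrom_length = 1e6,
                                    gc = 0.41, repeat_fraction = 0.15,
                                    seed = 1L, repeat_divergence = 0.15) {
  stopifnot(n_chrom >= 1, chrom_length >= 10000, gc >= 0, gc <= 1,
            repeat_fraction >= 0, repeat_fraction <= 1)
  if (repeat_fraction > 0.95) stop("repeat_fraction too high to tile (> 0.95)")
  set.seed(deriveSeed(seed, 1L))
  chrom_length <- as.integer(chrom_length)
  bases <- c("A", "C", "G", "T")
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  chroms <- lapply(seq_len(n_chrom), function(i)
    sample(bases, chrom_length, replace = TRUE, prob = prob))
  names(chroms) <- paste0("chr", seq_len(n_chrom))

  ann <- list()
  if (repeat_fraction > 0) {
    sine <- sample(bases, 300, replace = TRUE, prob = prob)
    line <- sample(bases, 4000, replace = TRUE, prob = prob)
    target <- repeat_fraction * n_chrom * chrom_length
    occ <- lapply(chroms, function(x) logical(chrom_length))
    planted <- 0; fails <- 0L
    while (planted < target) {
      if (fails > 5000L) stop("repeat_fraction too high to tile")
      fam <- if (runif(1) < 0.7) "SINE" else "LINE"
      cp <- if (fam == "SINE") sine else
        line[seq.int(4000 - sample(1000:4000, 1L) + 1L, 4000)]
      L <- length(cp)
      ci <- sample.int(n_chrom, 1L)
      s <- sample.int(chrom_length - L - 1L, 1L)
      if (any(occ[[ci]][s:(s + L - 1L)])) { fails <- fails + 1L; next }
      mut <- which(runif(L) < repeat_divergence)
      if (length(mut)) cp[mut] <- bases[(match(cp[mut], bases) - 1L +
                                         sample.int(3L, length(mut), replace = TRUE)) %% 4L + 1L]
      chroms[[ci]][s:(s + L - 1L)] <- cp
      occ[[ci]][s:(s + L - 1L)] <- TRUE
      ann[[length(ann) + 1L]] <- list(chrom = names(chroms)[ci], start = s,
                                      end = s + L - 1L, class = fam)
      planted <- planted + L
      fails <- 0L
    }
  }
  rep_gr <- if (length(ann)) {
    GenomicRanges::GRanges(
      vapply(ann, `[[`, "", "chrom"),
      IRanges::IRanges(vapply(ann, `[[`, 1L, "start"),
                       vapply(ann, `[[`, 1L, "end")),
      repeat_class = vapply(ann, `[[`, "", "class"))
  } else GenomicRanges::GRanges()
  GenomeSequence(vapply(chroms, paste, "", collapse = ""),
                 name = "ancestor", repeats = sort(rep_gr))
}

# Apply SV events (ancestor-frame coordinates, non-overlapping) to a set of
# raw chromosome vectors. Events applied right-to-left so coordinates stay
# valid. ev: data.frame with chrom, pos0, type, len, seq.
.applyEventsRaw <- function(raws, ev) {
  if (nrow(ev) == 0L) return(raws)
  for (cn in unique(ev$chrom)) {
    e <- ev[ev$chrom == cn, , drop = FALSE]
    e <- e[order(e$pos0, decreasing = TRUE), , drop = FALSE]
    x <- raws[[cn]]
    for (i in seq_len(nrow(e))) {
      s <- e$pos0[i]; L <- e$len[i]
      if (e$type[i] == "DEL") {
        x <- x[-((s + 1L):(s + L))]
      } else if (e$type[i] == "INS") {
        x <- append(x, charToRaw(e$seq[i]), after = s)
      } else if (e$type[i] == "DUP") {
        x <- append(x, x[(s + 1L):(s + L)], after = s + L)
      } else if (e$type[i] == "INV") {
        x[(s + 1L):(s + L)] <- .compTable[as.integer(rev(x[(s + 1L):(s + L)])) + 1L]
      }
    }
    raws[[cn]] <- x
  }
  raws
}

#' Apply structural variants to a genome
#'
#' Utility for constructing perturbed assemblies (e.g. a second human
#' assembly differing by private SVs). Events must not overlap.
#'
#' @param genome a \linkS4class{GenomeSequence}.
#' @param events data.frame with columns \code{chrom}, \code{pos0} (0-based
#'   start / insertion point), \code{type} (DEL/INS/DUP/INV), \code{len},
#'   and \code{seq} (inserted sequence, INS only).
#' @param name name for the derived genome.
#' @return A new \linkS4class{GenomeSequence}.
#' @export
applySVs <- function(genome, events, name = paste0(genomeName(genome), "_sv")) {
  raws <- lapply(chromNames(genome), function(cn) charToRaw(chromString(genome, cn)))
  names(raws) <- chromNames(genome)
  raws <- .applyEventsRaw(raws, events)
  GenomeSequence(vapply(raws, rawToChar, ""), name = name)
}

.drawLen <- function(n, dist, maxLen) {
  if (n == 0L) return(integer())
  pmax(50L, pmin(as.integer(round(rlnorm(n, dist$meanlog, dist$sdlog))), maxLen))
}

#' Evolve tip genomes from an ancestor along the catarrhine topology
#'
#' Plants the SV events and substitutions specified per branch, builds each
#' tip genome by applying its root-to-tip path, and projects the event truth
#' table onto the macaque tip genome (the reference frame of all downstream
#' analysis). Placement rejects any event within 50 bp of a previously
#' placed event on any branch, so truth projection is exact.
#'
#' Event polarity in the truth table is ape-centric: the \code{type} column
#' gives the variant as it appears when an ape assembly is compared against
#' macaque (a deletion event on the ape stem stays \code{DEL}: sequence
#' present in macaque, absent in apes; a deletion event on the macaque branch
#' becomes \code{INS}: sequence present in apes, absent in macaque). The
#' originating event is kept in \code{event_type}.
#'
#' @param ancestor a \linkS4class{GenomeSequence} from
#'   [generateAncestralGenome].
#' @param branch_specs named list of [branchSpec]; branches not listed get
#'   zero events and zero substitutions.
#' @param seed integer seed.
#' @param includeGibbon include the gibbon tip genome.
#' @return A list with \code{genomes} (named list of
#'   \linkS4class{GenomeSequence}), \code{truth} (a \code{GRanges} in the
#'   macaque frame with mcols \code{id}, \code{branch}, \code{type},
#'   \code{event_type}, \code{svlen}, \code{seq}, \code{in_repeat}), and
#'   \code{events} (the ancestor-frame event table).
#' @export
evolveGenomes <- function(ancestor, branch_specs = defaultBranchSpecs(),
                          seed = 1L, includeGibbon = TRUE) {
  nm <- vapply(branch_specs, `[[`, "", "branch")
  if (anyDuplicated(nm)) stop("overlapping branch spec: ",
                              nm[duplicated(nm)][1L])
  names(branch_specs) <- nm
  specs <- lapply(BRANCHES, function(b)
    branch_specs[[b]] %||% branchSpec(b, subst_rate = 0))
  names(specs) <- BRANCHES

  set.seed(deriveSeed(seed, 2L))
  cl <- chromLengths(ancestor)
  cnames <- names(cl)
  reps <- repeatAnnotation(ancestor)
  occ <- lapply(cl, function(L) logical(L))
  end_margin <- 2000L

  ev <- list()
  for (b in BRANCHES) {
    sp <- specs[[b]]
    types <- rep(c("DEL", "INS", "DUP", "INV"),
                 c(sp$n_del, sp$n_ins, sp$n_dup, sp$n_inv))
    lens <- c(.drawLen(sp$n_del, sp$del_len, sp$maxLen),
              .drawLen(sp$n_ins, sp$ins_len, sp$maxLen),
              .drawLen(sp$n_dup, sp$del_len, sp$maxLen),
              .drawLen(sp$n_inv, sp$del_len, sp$maxLen))
    for (j in seq_along(types)) {
      L <- lens[j]; placed <- FALSE
      for (try in seq_len(200L)) {
        ci <- sample.int(length(cl), 1L, prob = cl)
        hi <- cl[ci] - L - end_margin
        if (hi <= end_margin) next
        s <- sample.int(hi - end_margin, 1L) + end_margin  # 0-based start
        lo <- max(1L, s - 49L); hiu <- min(cl[ci], s + L + 50L)
        if (any(occ[[ci]][lo:hiu])) next
        occ[[ci]][(s + 1L):(s + L)] <- TRUE
        inseq <- if (types[j] == "INS") randDNA(L) else NA_character_
        inrep <- if (length(reps)) {
          q <- GenomicRanges::GRanges(cnames[ci], IRanges::IRanges(s + 1L, s + L))
          length(GenomicRanges::findOverlaps(q, reps)) > 0L
        } else FALSE
        ev[[length(ev) + 1L]] <- list(branch = b, type = types[j],
                                      chrom = cnames[ci], pos0 = s, len = L,
                                      seq = inseq, in_repeat = inrep)
        placed <- TRUE
        break
      }
      if (!placed) stop("placement exhaustion after bounded retries (branch ",
                        b, ")")
    }
  }
  events <- if (length(ev)) {
    data.frame(branch = vapply(ev, `[[`, "", "branch"),
               type = vapply(ev, `[[`, "", "type"),
               chrom = vapply(ev, `[[`, "", "chrom"),
               pos0 = vapply(ev, `[[`, 1L, "pos0"),
               len = vapply(ev, `[[`, 1L, "len"),
               seq = vapply(ev, `[[`, "", "seq"),
               in_repeat = vapply(ev, `[[`, TRUE, "in_repeat"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(branch = character(), type = character(), chrom = character(),
               pos0 = integer(), len = integer(), seq = character(),
               in_repeat = logical())
  }
  events$id <- if (nrow(events)) sprintf("sv%04d", seq_len(nrow(events)))
               else character()

  # per-branch substitutions in ancestor coordinates
  total <- sum(cl)
  cuml <- c(0, cumsum(as.double(cl)))
  anc_raws <- lapply(cnames, function(cn) charToRaw(chromString(ancestor, cn)))
  names(anc_raws) <- cnames
  subs <- list()
  for (b in BRANCHES) {
    rate <- specs[[b]]$subst_rate
    n <- if (rate > 0) rbinom(1L, total, rate) else 0L
    if (n == 0L) { subs[[b]] <- NULL; next }
    gpos <- sort(sample.int(total, n))
    ci <- findInterval(gpos - 1L, cuml[-length(cuml)], rightmost.closed = FALSE)
    pos1 <- as.integer(gpos - cuml[ci])
    cur <- as.raw(mapply(function(c_, p_) anc_raws[[c_]][p_], ci, pos1))
    cur_ch <- strsplit(rawToChar(cur), "")[[1L]]
    alt <- vapply(cur_ch, function(ch) {
      pool <- setdiff(c("A", "C", "G", "T"), ch)
      pool[sample.int(length(pool), 1L)]
    }, "")
    subs[[b]] <- data.frame(ci = ci, pos1 = pos1, alt = alt,
                            stringsAsFactors = FALSE)
  }

  tips <- c("human", "chimp", "gorilla", "orangutan",
            if (includeGibbon) "gibbon", "macaque", "marmoset")
  paths <- list(
    human = c("ape_ancestor", "great_ape_ancestor", "human"),
    chimp = c("ape_ancestor", "great_ape_ancestor", "chimp"),
    gorilla = c("ape_ancestor", "great_ape_ancestor", "gorilla"),
    orangutan = c("ape_ancestor", "great_ape_ancestor", "orangutan"),
    gibbon = c("ape_ancestor", "gibbon"),
    macaque = "macaque", marmoset = "marmoset")

  genomes <- list()
  for (tp in tips) {
    raws <- anc_raws
    for (b in paths[[tp]]) {
      sb <- subs[[b]]
      if (!is.null(sb)) for (ci in unique(sb$ci)) {
        sel <- sb$ci == ci
        raws[[ci]][sb$pos1[sel]] <- charToRaw(paste(sb$alt[sel], collapse = ""))
      }
    }
    pe <- events[events$branch %in% paths[[tp]], , drop = FALSE]
    raws <- .applyEventsRaw(raws, pe)
    genomes[[tp]] <- GenomeSequence(vapply(raws, rawToChar, ""), name = tp)
  }

  # projection of ancestor coordinates onto the macaque tip frame
  mev <- events[events$branch == "macaque", , drop = FALSE]
  projM <- function(chrom, x) {
    e <- mev[mev$chrom == chrom, , drop = FALSE]
    if (nrow(e) == 0L) return(x)
    delta <- ifelse(e$type == "DEL", -e$len,
                    ifelse(e$type %in% c("INS", "DUP"), e$len, 0L))
    vapply(x, function(xi) xi + sum(delta[e$pos0 < xi]), 1)
  }

  if (nrow(events)) {
    apeSide <- c("ape_ancestor", "great_ape_ancestor", "human", "chimp",
                 "gorilla", "orangutan", "gibbon")
    tstart <- numeric(nrow(events)); ttype <- character(nrow(events))
    tseq <- character(nrow(events))
    for (i in seq_len(nrow(events))) {
      s <- events$pos0[i]; L <- events$len[i]; cn <- events$chrom[i]
      p <- projM(cn, s)
      anc_sub <- function() substr(chromString(ancestor, cn), s + 1L, s + L)
      if (events$branch[i] %in% apeSide || events$branch[i] == "marmoset") {
        ttype[i] <- events$type[i]
        tseq[i] <- if (events$type[i] == "INS") events$seq[i] else anc_sub()
      } else {  # macaque branch: flip polarity into the ape-centric frame
        ttype[i] <- switch(events$type[i],
                           DEL = "INS", INS = "DEL", DUP = "DEL", INV = "INV")
        tseq[i] <- if (events$type[i] == "DEL") anc_sub() else events$seq[i]
      }
      tstart[i] <- p
    }
    truth <- GenomicRanges::GRanges(
      events$chrom,
      IRanges::IRanges(start = tstart + 1, width = events$len))
    S4Vectors::mcols(truth) <- S4Vectors::DataFrame(
      id = events$id, branch = events$branch, type = ttype,
      event_type = events$type, svlen = events$len, seq = tseq,
      in_repeat = events$in_repeat)
  } else {
    truth <- GenomicRanges::GRanges()
  }

  # project the repeat annotation onto the macaque frame
  if (length(reps)) {
    rs <- GenomicRanges::start(reps) - 1L
    re <- GenomicRanges::end(reps)
    cn <- as.character(GenomicRanges::seqnames(reps))
    ps <- pe <- numeric(length(reps))
    for (ch in unique(cn)) {
      sel <- cn == ch
      ps[sel] <- projM(ch, rs[sel]); pe[sel] <- projM(ch, re[sel])
    }
    keep <- pe - ps >= 1
    mac_reps <- GenomicRanges::GRanges(cn[keep],
      IRanges::IRanges(start = ps[keep] + 1, end = pe[keep]),
      repeat_class = S4Vectors::mcols(reps)$repeat_class[keep])
    genomes$macaque@repeats <- mac_reps
    methods::validObject(genomes$macaque)
  }

  list(genomes = genomes, truth = truth, events = events)
}

#' Introduce N-gaps into a genome, recording the removed truth
#'
#' Each gap replaces a stretch of true sequence with an equal-length run of
#' Ns (run length >= 2). Gaps are placed at least \code{spacing} bp apart and
#' from chromosome ends, leaving room for flank extraction.
#'
#' @param genome a \linkS4class{GenomeSequence}.
#' @param n_gaps number of gaps to place.
#' @param gap_len two-element range; gap lengths are drawn uniformly from it.
#' @param seed integer seed.
#' @param spacing minimum distance between gaps and from chromosome ends
#'   (default 6 kb, room for 5 kb flanks).
#' @return List with \code{genome} (the gapped reference) and \code{truth}
#'   (\code{GRanges} of gap intervals with mcol \code{seq}, the removed
#'   sequence).
#' @export
makeGappedReference <- function(genome, n_gaps = 20L, gap_len = c(100L, 2000L),
                                seed = 1L, spacing = 6000L) {
  set.seed(deriveSeed(seed, 3L))
  cl <- chromLengths(genome)
  raws <- lapply(chromNames(genome), function(cn) charToRaw(chromString(genome, cn)))
  names(raws) <- chromNames(genome)
  placed <- list()
  gaps <- list()
  if (n_gaps > 0) for (j in seq_len(n_gaps)) {
    ok <- FALSE
    for (try in seq_len(500L)) {
      L <- max(2L, sample(gap_len[1L]:gap_len[2L], 1L))
      ci <- sample.int(length(cl), 1L, prob = cl)
      hi <- cl[ci] - L - spacing
      if (hi <= spacing) next
      s <- sample.int(hi - spacing, 1L) + spacing  # 0-based
      clash <- FALSE
      for (g in placed) {
        if (g$ci == ci && s < g$e + spacing && g$s < s + L + spacing) {
          clash <- TRUE; break
        }
      }
      if (clash) next
      placed[[length(placed) + 1L]] <- list(ci = ci, s = s, e = s + L)
      gaps[[length(gaps) + 1L]] <- list(
        chrom = names(cl)[ci], s = s, L = L,
        seq = rawToChar(raws[[ci]][(s + 1L):(s + L)]))
      raws[[ci]][(s + 1L):(s + L)] <- charToRaw(paste(rep("N", L), collapse = ""))
      ok <- TRUE
      break
    }
    if (!ok) stop("cannot satisfy gap spacing")
  }
  truth <- if (length(gaps)) {
    tg <- GenomicRanges::GRanges(
      vapply(gaps, `[[`, "", "chrom"),
      IRanges::IRanges(start = vapply(gaps, `[[`, 1L, "s") + 1L,
                       width = vapply(gaps, `[[`, 1L, "L")))
    S4Vectors::mcols(tg)$seq <- vapply(gaps, `[[`, "", "seq")
    sort(tg)
  } else GenomicRanges::GRanges()
  gapped <- GenomeSequence(vapply(raws, rawToChar, ""),
                           name = paste0(genomeName(genome), "_gapped"),
                           repeats = repeatAnnotation(genome))
  list(genome = gapped, truth = truth)
}

#' Simulate an H3K27Ac enhancer count matrix with planted ape gains/losses
#'
#' Null enhancers draw all samples from one log-normal mean. Gain enhancers
#' multiply the human and chimp means by \code{2^effect_log2fc}; loss
#' enhancers divide. Per-sample multiplicative noise has coefficient of
#' variation \code{cv}.
#'
#' @param n_enhancers number of enhancers.
#' @param frac_gain,frac_loss fractions of enhancers with planted ape gain /
#'   loss (their sum must be <= 1).
#' @param samples named integer vector \code{c(human=, chimp=, macaque=)};
#'   each species needs >= 2 samples.
#' @param effect_log2fc planted |log2 fold change| (> 0 when any enhancers
#'   are labelled).
#' @param cv per-sample coefficient of variation.
#' @param seed integer seed.
#' @param region brain-region label.
#' @param intervals optional \code{GRanges} of enhancer intervals (length
#'   \code{n_enhancers}); defaults to a tiling of a nominal chromosome.
#' @return List with \code{matrix} (an \linkS4class{EnhancerMatrix}) and
#'   \code{truth} (character labels gain/loss/null per enhancer).
#' @export
simulateEnhancerMatrix <- function(n_enhancers = 2000L, frac_gain = 0.05,
                                   frac_loss = 0.05,
                                   samples = c(human = 3L, chimp = 2L, macaque = 3L),
                                   effect_log2fc = 2, cv = 0.15, seed = 1L,
                                   region = "PFC", intervals = NULL) {
  stopifnot(samples["human"] >= 2, samples["chimp"] >= 2,
            samples["macaque"] >= 2, frac_gain + frac_loss <= 1)
  if ((frac_gain > 0 || frac_loss > 0) && effect_log2fc <= 0)
    stop("non-positive effect for labelled enhancers")
  set.seed(deriveSeed(seed, 4L))
  n <- as.integer(n_enhancers)
  n_gain <- round(frac_gain * n); n_loss <- round(frac_loss * n)
  truth <- sample(rep(c("gain", "loss", "null"),
                      c(n_gain, n_loss, n - n_gain - n_loss)))
  base <- rlnorm(n, log(100), 1)
  fac <- ifelse(truth == "gain", 2^effect_log2fc,
                ifelse(truth == "loss", 2^(-effect_log2fc), 1))
  sdl <- sqrt(log(1 + cv^2))
  spc <- rep(c("human", "chimp", "macaque"),
             c(samples["human"], samples["chimp"], samples["macaque"]))
  mu <- cbind(base * fac)[, rep(1L, length(spc)), drop = FALSE]
  mu[, spc == "macaque"] <- base
  noise <- matrix(exp(rnorm(n * length(spc), -sdl^2 / 2, sdl)), n)
  counts <- mu * noise
  colnames(counts) <- paste(spc, unlist(lapply(samples, seq_len)), sep = "_")
  iv <- intervals %||% GenomicRanges::GRanges("chrE",
    IRanges::IRanges(start = (seq_len(n) - 1L) * 3000L + 1L, width = 600L))
  stopifnot(length(iv) == n)
  list(matrix = EnhancerMatrix(counts, iv, region = region), truth = truth)
}

#' Simulate an SV genotype table over a panel of individuals
#'
#' Fixed SVs are homozygous-alt in every individual; the rest segregate at a
#' Uniform(0.1, 0.9) allele frequency with Hardy-Weinberg genotypes.
#' Insertions inside annotated repeats are invalidated (no genotype) with
#' probability \code{invalidation_rate_repeat_ins}, mimicking the failure
#' mode of short-read genotyping over repetitive insertions.
#'
#' @param truth truth \code{GRanges} from [evolveGenomes] (mcols \code{id},
#'   \code{type}, \code{in_repeat}), or any GRanges/SVCallset with those
#'   mcols.
#' @param n_individuals panel size (>= 1).
#' @param fixed_fraction probability a (non-invalidated) SV is fixed.
#' @param invalidation_rate_repeat_ins invalidation probability for
#'   insertions in repeats.
#' @param seed integer seed.
#' @return Character matrix SV x individual with entries \code{0/0},
#'   \code{0/1}, \code{1/1} or \code{NA} (invalidated).
#' @export
simulateGenotypes <- function(truth, n_individuals = 5L, fixed_fraction = 0.134,
                              invalidation_rate_repeat_ins = 0.6, seed = 1L) {
  stopifnot(n_individuals >= 1)
  if (is(truth, "SVCallset")) truth <- svRanges(truth)
  set.seed(deriveSeed(seed, 5L))
  mc <- S4Vectors::mcols(truth)
  n <- length(truth)
  out <- matrix(NA_character_, n, n_individuals,
                dimnames = list(mc$id, paste0("ind_", seq_len(n_individuals))))
  inrep <- if ("in_repeat" %in% colnames(mc)) mc$in_repeat else rep(FALSE, n)
  for (i in seq_len(n)) {
    if (mc$type[i] == "INS" && isTRUE(inrep[i]) &&
        runif(1) < invalidation_rate_repeat_ins) next
    if (runif(1) < fixed_fraction) {
      out[i, ] <- "1/1"
    } else {
      af <- runif(1, 0.1, 0.9)
      out[i, ] <- c("0/0", "0/1", "1/1")[rbinom(n_individuals, 2L, af) + 1L]
    }
  }
  out
}
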
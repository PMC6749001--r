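# Readers/writers for the standard formats used throughout the package.
#
# Coordinate convention: in memory everything lives in GRanges (1-based,
# closed, the Bioconductor convention). BED-like TSVs are 0-based half-open
# and VCF is 1-based with the anchor-base convention; both conversions happen
# only here, at the I/O boundary.

#' Read a FASTA file into a GenomeSequence
#'
#' Bases are uppercased on read. Characters outside \{A,C,G,T,N\} are either
#' rejected or mapped to N.
#'
#' @param path path to a FASTA file.
#' @param name assembly name (defaults to the file name).
#' @param onInvalid \code{"error"} to reject characters outside
#'   \{A,C,G,T,N\}, \code{"to-n"} to map them to N.
#' @return A \linkS4class{GenomeSequence}; record order is preserved.
#' @export
readFasta <- function(path, name = NULL, onInvalid = c("error", "to-n")) {
  onInvalid <- match.arg(onInvalid)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no FASTA records in ", path)
  nm <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(nm)) stop("duplicate record names in ", path)
  if (any(Biostrings::width(raw) == 0L)) stop("empty FASTA record in ", path)
  ch <- toupper(as.character(raw))
  bad <- grepl("[^ACGTN]", ch)
  if (any(bad)) {
    if (onInvalid == "error")
      stop("invalid characters in record(s): ", paste(nm[bad], collapse = ", "))
    ch <- gsub("[^ACGTN]", "N", ch)
  }
  GenomeSequence(setNames(ch, nm), name = name %||% basename(path))
}

#' Write a GenomeSequence to FASTA
#'
#' @param genome a \linkS4class{GenomeSequence}.
#' @param path output path.
#' @param width line-wrap width (default 60 columns).
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(genome, path, width = 60L) {
  Biostrings::writeXStringSet(chromSeqs(genome), path, width = width)
  invisible(path)
}

#' Write an SVCallset as VCF 4.2
#'
#' Deletions and insertions are sequence-resolved (REF/ALT carry the anchor
#' base); duplications and inversions are written as symbolic ALTs. INFO
#' carries SVTYPE, SVLEN (negative for deletions) and END. POS follows the
#' VCF anchor-base convention: for a deletion whose removed interval starts
#' at 0-based position s, POS = s (the 1-based base before the event).
#'
#' @param callset an \linkS4class{SVCallset}; all records must lie within
#'   \code{reference}, insertions must carry mcol \code{seq}.
#' @param reference the \linkS4class{GenomeSequence} the calls are placed on.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSVVcf <- function(callset, reference, path) {
  gr <- svRanges(callset)
  cl <- chromLengths(reference)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=lineageSV",
    sprintf("##contig=<ID=%s,length=%d>", names(cl), unname(cl)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of the SV interval\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  lines <- hdr
  if (length(gr)) {
    chrom <- as.character(GenomicRanges::seqnames(gr))
    if (!all(chrom %in% names(cl))) stop("record on unknown chromosome")
    mc <- S4Vectors::mcols(gr)
    s <- GenomicRanges::start(gr); e <- GenomicRanges::end(gr)
    for (i in seq_along(gr)) {
      L <- mc$svlen[i]; type <- mc$type[i]; cn <- chrom[i]
      if (type == "INS") {
        # stored footprint starts at insertion point + 1 (1-based)
        pos <- s[i] - 1L
        if (pos < 1L) stop("insertion at chromosome start unsupported")
        ins <- mc$seq[i]
        if (is.null(ins) || is.na(ins) || nchar(ins) != L)
          stop("insertion record lacking inserted sequence: ", mc$id[i])
        if (pos > cl[cn]) stop("record outside reference: ", mc$id[i])
        anchor <- substr(chromString(reference, cn), pos, pos)
        ref <- anchor; alt <- paste0(anchor, ins)
        info <- sprintf("SVTYPE=INS;SVLEN=%d;END=%d", L, pos)
      } else {
        pos <- s[i] - 1L
        if (pos < 1L) stop("event at chromosome start unsupported")
        if (e[i] > cl[cn]) stop("record outside reference: ", mc$id[i])
        anchor <- substr(chromString(reference, cn), pos, pos)
        if (type == "DEL") {
          ref <- paste0(anchor,
                        substr(chromString(reference, cn), s[i], e[i]))
          alt <- anchor
          info <- sprintf("SVTYPE=DEL;SVLEN=%d;END=%d", -L, e[i])
        } else {
          ref <- anchor; alt <- paste0("<", type, ">")
          info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d", type, L, e[i])
        }
      }
      lines <- c(lines, sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                                cn, pos, mc$id[i], ref, alt, info))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a structural-variant VCF written by [writeSVVcf]
#'
#' @param path VCF path.
#' @param source provenance tag for the resulting callset.
#' @return An \linkS4class{SVCallset}.
#' @export
readSVVcf <- function(path, source = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) return(SVCallset())
  f <- strsplit(body, "\t", fixed = TRUE)
  getInfo <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
    if (length(m) == 0L) return(NA_character_)
    sub(paste0("^;?", key, "="), "", m)
  }
  rec <- lapply(f, function(x) {
    info <- x[8]
    type <- getInfo(info, "SVTYPE")
    svlen <- abs(as.integer(getInfo(info, "SVLEN")))
    pos <- as.integer(x[2])
    seq <- NA_character_
    if (type == "INS") {
      start1 <- pos + 1L       # footprint starts after the anchor base
      seq <- substr(x[5], 2L, nchar(x[5]))
    } else {
      start1 <- pos + 1L
      if (type == "DEL") seq <- substr(x[4], 2L, nchar(x[4]))
    }
    list(chrom = x[1], start = start1, end = start1 + svlen - 1L,
         id = x[3], type = type, svlen = svlen, seq = seq)
  })
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(rec, `[[`, "", "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(rec, `[[`, 1L, "start"),
      end = vapply(rec, `[[`, 1L, "end")))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = vapply(rec, `[[`, "", "type"),
    svlen = vapply(rec, `[[`, 1L, "svlen"),
    id = vapply(rec, `[[`, "", "id"),
    seq = vapply(rec, `[[`, "", "seq"))
  SVCallset(gr, source = source)
}

#' Write a callset or truth table as a BED6+ TSV
#'
#' Emits 0-based half-open coordinates. Columns: chrom, start, end, id, type,
#' length, then any further metadata columns present (e.g. branch,
#' in_repeat).
#'
#' @param x an \linkS4class{SVCallset} or a \code{GRanges} with SV mcols.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSVBed <- function(x, path) {
  gr <- if (is(x, "SVCallset")) svRanges(x) else x
  mc <- as.data.frame(S4Vectors::mcols(gr))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    id = mc$id, type = mc$type, length = mc$svlen,
    stringsAsFactors = FALSE)
  extra <- mc[, setdiff(colnames(mc), c("type", "svlen", "id")), drop = FALSE]
  if (ncol(extra)) df <- cbind(df, extra)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED6+ TSV written by [writeSVBed]
#'
#' @param path input path.
#' @param source provenance tag.
#' @return An \linkS4class{SVCallset}.
#' @export
readSVBed <- function(path, source = basename(path)) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
  keep <- setdiff(colnames(df), c("chrom", "start", "end", "length"))
  mc <- S4Vectors::DataFrame(df[, keep, drop = FALSE])
  mc$svlen <- df$length
  S4Vectors::mcols(gr) <- mc[, c("type", "svlen", "id",
                                 setdiff(colnames(mc), c("type", "svlen", "id")))]
  SVCallset(gr, source = source)
}

#' Read a counts/genotype/expression TSV
#'
#' Sample columns must be named \code{species_replicate} (e.g.
#' \code{human_1}) for the enhancer schema. Enhancer tables carry 0-based
#' half-open \code{chrom}/\code{start}/\code{end} interval columns;
#' expression and genotype tables are keyed by their first (identifier)
#' column.
#'
#' @param path TSV path with a header row.
#' @param schema one of \code{"enhancer"}, \code{"expression"},
#'   \code{"genotype"}.
#' @param region brain-region label for the enhancer schema.
#' @return An \linkS4class{EnhancerMatrix} for the enhancer schema, otherwise
#'   a matrix (numeric for expression, character genotype codes for
#'   genotype) with row names from the identifier column.
#' @export
readCountsTable <- function(path, schema = c("enhancer", "expression", "genotype"),
                            region = "PFC") {
  schema <- match.arg(schema)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (schema == "enhancer") {
    need <- c("chrom", "start", "end")
    if (!all(need %in% colnames(df)))
      stop("enhancer schema requires columns chrom, start, end")
    samp <- setdiff(colnames(df), need)
    if (nrow(df) == 0L) {
      return(EnhancerMatrix(
        matrix(numeric(), 0L, length(samp), dimnames = list(NULL, samp)),
        GenomicRanges::GRanges(), region = region))
    }
    m <- as.matrix(df[, samp, drop = FALSE])
    .checkNumericCells(m, rownames = paste0("enhancer", seq_len(nrow(df))))
    storage.mode(m) <- "double"
    if (any(m < 0)) stop("negative counts")
    gr <- GenomicRanges::GRanges(df$chrom,
      IRanges::IRanges(start = df$start + 1L, end = df$end))
    EnhancerMatrix(m, gr, region = region)
  } else if (schema == "expression") {
    m <- as.matrix(df[, -1L, drop = FALSE])
    .checkNumericCells(m, rownames = df[[1L]])
    storage.mode(m) <- "double"
    rownames(m) <- df[[1L]]
    m
  } else {
    m <- as.matrix(df[, -1L, drop = FALSE])
    ok <- m %in% c("0/0", "0/1", "1/1", "./.", "", NA) | is.na(m)
    if (!all(ok)) stop("invalid genotype code(s): ",
                       paste(unique(m[!ok]), collapse = ", "))
    m[m %in% c("./.", "")] <- NA_character_
    rownames(m) <- df[[1L]]
    m
  }
}

.checkNumericCells <- function(m, rownames) {
  suppressWarnings(num <- matrix(as.numeric(m), nrow(m), ncol(m)))
  bad <- which(is.na(num) | is.na(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at row '%s', column '%s'",
                 rownames[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  }
  invisible(TRUE)
}
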
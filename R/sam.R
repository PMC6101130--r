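# SAM input and per-read mismatch extraction.
#
# Text SAM is converted to BAM in a temporary directory via Rsamtools and
# parsed with GenomicAlignments; mismatches are recovered from MD/NM tags
# into read-cycle space (cycle 1 = first sequenced base), reverse-strand
# alignments being flipped and complemented accordingly.

#' Read a SAM file of single-end alignments
#'
#' Primary mapped records are returned; unmapped, secondary and
#' supplementary records are excluded but counted in `totals`. A record is
#' "uniquely mapped" if its NH tag equals 1 or, when NH is absent, its
#' MAPQ is at least `mapq_threshold`.
#'
#' @param path Path to a SAM (or BAM) file with header.
#' @param mapq_threshold MAPQ fallback for the uniqueness call (default 10).
#' @return Object of class `aligned_reads`: parallel vectors
#'   (`qname`, `chrom`, `strand`, `pos`, `cigar`, `width`, `seq`, `mapq`,
#'   `dup`, `unique`, `md`, `nm`), a [GenomicRanges::GRangesList] of
#'   alignment blocks, and `totals` (records/mapped/unmapped/secondary).
#' @export
read_sam <- function(path, mapq_threshold = 10L) {
  if (!file.exists(path)) stopf("SAM file not found: %s", path)
  bam <- if (grepl("\\.bam$", path)) {
    path
  } else {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }

  # full-record pass for totals (flags only)
  fl <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = "flag"))[[1L]]$flag
  n_records <- length(fl)
  unmapped <- sum(bitwAnd(fl, 4L) > 0L)
  secondary <- sum(bitwAnd(fl, 256L) > 0L | bitwAnd(fl, 2048L) > 0L)

  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq", "seq"),
    tag = c("NH", "MD", "NM"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  )
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  md <- S4Vectors::mcols(ga)

  cig <- GenomicAlignments::cigar(ga)
  if (any(grepl("[IDHP]", cig))) {
    stopf(paste0("read_sam supports match/splice/soft-clip CIGARs only ",
                 "(M, =, X, N, S); found indel or clip ops"))
  }

  nh <- md$NH
  mapq <- md$mapq
  unique_flag <- if (is.null(nh)) {
    mapq >= mapq_threshold
  } else {
    ifelse(is.na(nh), mapq >= mapq_threshold, nh == 1L)
  }

  has_md <- !is.null(md$MD) && !all(is.na(md$MD))
  nm <- md$NM
  if (!has_md && !is.null(nm) && any(nm > 0, na.rm = TRUE)) {
    stopf(paste0("alignments carry mismatches (NM > 0) but no MD tag; ",
                 "supply MD tags or a reference FASTA via add_md_from_fasta"))
  }

  out <- list(
    qname = as.character(md$qname),
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    strand = as.character(GenomicAlignments::strand(ga)),
    pos = GenomicAlignments::start(ga),     # 1-based leftmost
    end = GenomicAlignments::end(ga),       # 1-based rightmost
    cigar = cig,
    width = GenomicAlignments::qwidth(ga),
    seq = as.character(md$seq),
    mapq = mapq,
    dup = bitwAnd(md$flag, 1024L) > 0L,
    unique = unique_flag,
    md = if (has_md) as.character(md$MD) else rep(NA_character_, length(ga)),
    nm = if (is.null(nm)) rep(NA_integer_, length(ga)) else nm,
    blocks = GenomicAlignments::grglist(ga, drop.D.ranges = TRUE),
    totals = list(records = n_records,
                  mapped = length(ga),
                  unmapped = unmapped,
                  secondary = secondary)
  )
  class(out) <- "aligned_reads"
  out
}

#' @export
print.aligned_reads <- function(x, ...) {
  cat(sprintf(
    "aligned_reads: %d primary mapped (%d records; %d unmapped, %d secondary)\n",
    x$totals$mapped, x$totals$records, x$totals$unmapped, x$totals$secondary))
  cat(sprintf("  unique: %.1f%%  duplicate-flagged: %.1f%%\n",
              100 * mean(x$unique), 100 * mean(x$dup)))
  invisible(x)
}

n_reads <- function(reads) length(reads$qname)

# Parse one MD string into aligned-base offsets (1..n matched bases) and
# reference bases. Substitution-only alignments assumed (no '^' deletions).
parse_md <- function(md) {
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", md))[[1L]]
  apos <- integer(0); ref <- character(0)
  cur <- 0L
  for (t in toks) {
    if (grepl("^[0-9]+$", t)) {
      cur <- cur + as.integer(t)
    } else if (startsWith(t, "^")) {
      stopf("MD deletion ('%s') unsupported; substitution-only input expected", t)
    } else {
      cur <- cur + 1L
      apos <- c(apos, cur)
      ref <- c(ref, t)
    }
  }
  list(apos = apos, ref = ref)
}

#' Per-read mismatch records in read-cycle space
#'
#' Extracts substitutions from MD tags. For reverse-strand alignments the
#' aligned-base offset is flipped (`cycle = read_len + 1 - offset`) and
#' bases are complemented, so `cycle`, `ref` and `alt` always refer to the
#' read as sequenced.
#'
#' @param reads An `aligned_reads` object.
#' @return `data.frame` with columns `read` (index into `reads`), `cycle`,
#'   `ref`, `alt`.
#' @export
mismatch_table <- function(reads) {
  stopifnot(inherits(reads, "aligned_reads"))
  idx <- which(!is.na(reads$md) &
                 grepl("[ACGTN]", reads$md))
  rows <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    p <- parse_md(reads$md[i])
    if (!length(p$apos)) next
    # soft clips shift aligned offsets into SEQ coordinates
    lead_s <- 0L
    if (grepl("^[0-9]+S", reads$cigar[i])) {
      lead_s <- as.integer(sub("^([0-9]+)S.*$", "\\1", reads$cigar[i]))
    }
    seq_pos <- p$apos + lead_s
    alt <- substring(reads$seq[i], seq_pos, seq_pos)
    if (reads$strand[i] == "-") {
      cycle <- reads$width[i] + 1L - seq_pos
      ref <- unname(COMPLEMENT[p$ref])
      altc <- unname(COMPLEMENT[alt])
      rows[[j]] <- data.frame(read = i, cycle = cycle, ref = ref, alt = altc,
                              stringsAsFactors = FALSE)
    } else {
      rows[[j]] <- data.frame(read = i, cycle = seq_pos, ref = p$ref,
                              alt = alt, stringsAsFactors = FALSE)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(read = integer(0), cycle = integer(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Read sequences in sequencing (cycle) order: reverse-strand alignments
# are reverse-complemented back to the read as sequenced.
read_cycle_seqs <- function(reads, subset = NULL) {
  subset <- subset %||% seq_len(n_reads(reads))
  s <- Biostrings::DNAStringSet(reads$seq[subset])
  minus <- reads$strand[subset] == "-"
  if (any(minus)) {
    s[minus] <- Biostrings::reverseComplement(s[minus])
  }
  s
}

# 5'-end genomic position (0-based) of reads relative to a gene strand:
# leftmost aligned base for "+" genes, rightmost for "-" genes.
read_five_prime_pos <- function(reads, gene_strand, subset = NULL) {
  subset <- subset %||% seq_len(n_reads(reads))
  if (gene_strand == "+") reads$pos[subset] - 1L else reads$end[subset] - 1L
}
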
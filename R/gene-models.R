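# Gene models, meta-transcripts and coordinate maps.
#
# Internal convention: all coordinates are 0-based half-open [start, end).
# GTF input/output is 1-based closed and converted at the boundary.

new_gene_model <- function(gene_id, biotype, chrom, strand, transcripts) {
  stopifnot(strand %in% c("+", "-"))
  g <- list(gene_id = gene_id, biotype = biotype, chrom = chrom,
            strand = strand, transcripts = transcripts)
  class(g) <- "gene_model"
  g
}

# Union of possibly overlapping intervals; input/output 2-column matrices
# (start, end), 0-based half-open, output sorted and disjoint.
merge_intervals <- function(mat) {
  if (nrow(mat) == 0L) return(mat)
  mat <- mat[order(mat[, 1L], mat[, 2L]), , drop = FALSE]
  starts <- mat[, 1L]; ends <- mat[, 2L]
  out_s <- numeric(0); out_e <- numeric(0)
  cur_s <- starts[1L]; cur_e <- ends[1L]
  if (nrow(mat) > 1L) {
    for (i in 2:nrow(mat)) {
      if (starts[i] <= cur_e) {
        cur_e <- max(cur_e, ends[i])
      } else {
        out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
        cur_s <- starts[i]; cur_e <- ends[i]
      }
    }
  }
  out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
  cbind(start = out_s, end = out_e)
}

gene_exon_union <- function(gene) {
  ex <- do.call(rbind, lapply(gene$transcripts, function(tx) tx$exons))
  merge_intervals(ex)
}

#' Read an ENSEMBL-dialect GTF into gene models
#'
#' Parses exon and CDS features, groups them per transcript and gene, and
#' converts 1-based closed GTF coordinates to the package's 0-based
#' half-open convention. Biotypes are taken from `gene_biotype` (falling
#' back to `transcript_biotype` or `gene_type`); unknown labels are mapped
#' to `"other"` with a warning.
#'
#' @param path Path to a GTF file.
#' @return An object of class `gene_models`: a named list with one
#'   `gene_model` per `gene_id`, each carrying its transcripts' exon and
#'   CDS intervals.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stopf("GTF file not found: %s", path)
  check_gtf_lines(path)
  first <- readLines(path, n = 50L, warn = FALSE)
  if (!any(nzchar(first) & !startsWith(first, "#"))) {
    return(structure(list(), class = "gene_models"))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("exon", "CDS")
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  if (length(gr) == 0L) {
    out <- structure(list(), class = "gene_models")
    return(out)
  }
  bty_col <- intersect(c("gene_biotype", "transcript_biotype", "gene_type"),
                       colnames(md))
  bty_raw <- if (length(bty_col)) as.character(md[[bty_col[1L]]]) else
    rep(NA_character_, length(gr))
  bty_raw[is.na(bty_raw)] <- "other"
  bty <- normalize_biotype(bty_raw)

  df <- data.frame(
    gene_id = as.character(md$gene_id),
    transcript_id = as.character(md$transcript_id),
    type = as.character(md$type),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = bty,
    stringsAsFactors = FALSE
  )
  if (anyNA(df$gene_id) || anyNA(df$transcript_id)) {
    stopf("GTF features missing gene_id/transcript_id attributes")
  }

  genes <- vector("list", length(unique(df$gene_id)))
  names(genes) <- unique(df$gene_id)
  for (gid in names(genes)) {
    sub <- df[df$gene_id == gid, , drop = FALSE]
    if (length(unique(sub$chrom)) != 1L || length(unique(sub$strand)) != 1L) {
      stopf("gene %s has features on multiple chromosomes/strands", gid)
    }
    txs <- lapply(split(sub, sub$transcript_id), function(s) {
      ex <- s[s$type == "exon", c("start", "end"), drop = FALSE]
      cd <- s[s$type == "CDS", c("start", "end"), drop = FALSE]
      ex <- as.matrix(ex)[order(ex$start), , drop = FALSE]
      list(transcript_id = s$transcript_id[1L],
           exons = ex,
           cds = if (nrow(cd)) as.matrix(cd)[order(cd$start), , drop = FALSE]
                 else NULL)
    })
    genes[[gid]] <- new_gene_model(
      gene_id = gid,
      biotype = sub$biotype[1L],
      chrom = sub$chrom[1L],
      strand = sub$strand[1L],
      transcripts = txs
    )
  }
  structure(genes, class = "gene_models")
}

# Cheap structural validation so malformed lines are reported by number
# (rtracklayer's own errors do not name the line).
check_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L) stopf("malformed GTF line %d: expected 9 fields", i)
    if (is.na(suppressWarnings(as.integer(f[4L]))) ||
        is.na(suppressWarnings(as.integer(f[5L])))) {
      stopf("malformed GTF line %d: non-numeric coordinates", i)
    }
  }
  invisible(TRUE)
}

#' @export
print.gene_models <- function(x, ...) {
  bt <- table(vapply(x, function(g) g$biotype, character(1)))
  cat(sprintf("gene_models: %d genes\n", length(x)))
  if (length(bt)) {
    cat("  biotypes:",
        paste(sprintf("%s=%d", names(bt), as.integer(bt)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Build a gene's meta-transcript
#'
#' The meta-transcript is the union of all annotated transcripts' exons,
#' with overlaps merged, giving a single strand-aware coordinate system:
#' meta-position 0 is the transcript 5' end (genomic left end for `+`
#' genes, genomic right end for `-` genes).
#'
#' @param gene A `gene_model`.
#' @return Object of class `meta_transcript` with merged exon intervals,
#'   total exonic length `L`, and precomputed offsets for coordinate maps.
#' @export
build_meta_transcript <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  ex <- gene_exon_union(gene)
  if (nrow(ex) == 0L) stopf("gene %s has no exons", gene$gene_id)
  widths <- ex[, 2L] - ex[, 1L]
  mt <- list(
    gene_id = gene$gene_id,
    chrom = gene$chrom,
    strand = gene$strand,
    starts = as.numeric(ex[, 1L]),
    ends = as.numeric(ex[, 2L]),
    # exonic bases preceding each interval, in genomic (plus) orientation
    offsets = cumsum(c(0, widths[-length(widths)])),
    L = sum(widths)
  )
  class(mt) <- "meta_transcript"
  mt
}

#' @export
print.meta_transcript <- function(x, ...) {
  cat(sprintf("meta_transcript %s (%s%s): %d intervals, L = %d nt\n",
              x$gene_id, x$chrom, x$strand, length(x$starts), x$L))
  invisible(x)
}

#' Map genomic positions to meta-transcript coordinates
#'
#' Counts only exonic bases, measured from the transcript 5' end; intronic,
#' intergenic or wrong-chromosome positions return `NA`.
#'
#' @param meta A `meta_transcript`.
#' @param chrom Chromosome name (scalar or vector recycled against `pos`).
#' @param pos 0-based genomic positions.
#' @return Numeric vector of meta-positions in `[0, L)`, `NA` where the
#'   position does not fall in the merged exons.
#' @export
genomic_to_meta <- function(meta, chrom, pos) {
  stopifnot(inherits(meta, "meta_transcript"))
  pos <- as.numeric(pos)
  idx <- findInterval(pos, meta$starts)
  ok <- idx >= 1L & (chrom == meta$chrom)
  ok[ok] <- pos[ok] < meta$ends[idx[ok]]
  off <- rep(NA_real_, length(pos))
  off[ok] <- meta$offsets[idx[ok]] + pos[ok] - meta$starts[idx[ok]]
  if (meta$strand == "-") off <- meta$L - 1 - off
  off
}

# Inverse map: meta-interval [m, m + len) -> genomic alignment blocks
# (plus-orientation, 0-based half-open), split across junctions.
meta_to_blocks <- function(meta, m, len) {
  stopifnot(m >= 0, m + len <= meta$L)
  if (meta$strand == "-") {
    a <- meta$L - (m + len)
  } else {
    a <- m
  }
  b <- a + len  # plus-orientation exonic offsets [a, b)
  i1 <- findInterval(a, meta$offsets)
  i2 <- findInterval(b - 1, meta$offsets)
  s <- meta$starts[i1:i2]
  e <- meta$ends[i1:i2]
  s[1L] <- meta$starts[i1] + (a - meta$offsets[i1])
  e[length(e)] <- meta$starts[i2] + (b - 1 - meta$offsets[i2]) + 1
  cbind(start = s, end = e)
}

gc_stats <- function(seq) {
  len <- length(seq)  # seq is a DNAString
  if (len == 0L) {
    return(list(length = 0L, gc = NA_real_, gc_pct = NA_real_))
  }
  gc <- sum(Biostrings::letterFrequency(seq, c("G", "C")))
  list(length = len, gc = gc, gc_pct = 100 * gc / len)
}

extract_seq <- function(genome, chrom, intervals, strand) {
  if (!chrom %in% names(genome)) {
    stopf("missing sequence for chromosome %s", chrom)
  }
  chr <- genome[[chrom]]
  if (any(intervals[, 2L] > length(chr))) {
    bad <- which(intervals[, 2L] > length(chr))[1L]
    stopf("missing sequence for interval %s:%d-%d", chrom,
          intervals[bad, 1L], intervals[bad, 2L])
  }
  parts <- lapply(seq_len(nrow(intervals)), function(i) {
    Biostrings::subseq(chr, intervals[i, 1L] + 1L, intervals[i, 2L])
  })
  s <- do.call(Biostrings::xscat, parts)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  s
}

# Exonic sequence of a meta-transcript in 5'->3' transcript orientation.
meta_sequence <- function(meta, genome) {
  extract_seq(genome, meta$chrom, cbind(meta$starts, meta$ends), meta$strand)
}

#' Transcript features for a gene's longest transcript
#'
#' Computes, for the longest transcript variant (by exonic length; ties
#' broken by transcript_id), the transcript length and GC content; for
#' coding transcripts additionally the cDNA, CDS, 5'UTR and 3'UTR lengths
#' and GC counts/percentages. GC counts G+C bases; %GC = 100 (G+C)/length.
#' Zero-length regions (e.g. a missing UTR) are reported as absent (`NA`),
#' not as 0% GC.
#'
#' @param gene A `gene_model`.
#' @param genome A [Biostrings::DNAStringSet] of chromosome sequences, or a
#'   path to a FASTA file.
#' @return One-row `data.frame` of features.
#' @export
transcript_features <- function(gene, genome) {
  stopifnot(inherits(gene, "gene_model"))
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))

  tx_len <- vapply(gene$transcripts,
                   function(tx) sum(tx$exons[, 2L] - tx$exons[, 1L]), 0)
  ord <- order(-tx_len, names(gene$transcripts))
  tx <- gene$transcripts[[ord[1L]]]

  tx_seq <- extract_seq(genome, gene$chrom, tx$exons, gene$strand)
  tx_stats <- gc_stats(tx_seq)

  out <- data.frame(
    gene_id = gene$gene_id,
    biotype = gene$biotype,
    transcript_id = tx$transcript_id,
    transcript_length = tx_stats$length,
    transcript_gc = tx_stats$gc,
    transcript_gc_pct = tx_stats$gc_pct,
    cdna_length = NA_integer_, cdna_gc = NA_real_, cdna_gc_pct = NA_real_,
    cds_length = NA_integer_, cds_gc = NA_real_, cds_gc_pct = NA_real_,
    utr5_length = NA_integer_, utr5_gc = NA_real_, utr5_gc_pct = NA_real_,
    utr3_length = NA_integer_, utr3_gc = NA_real_, utr3_gc_pct = NA_real_,
    stringsAsFactors = FALSE
  )

  if (!is.null(tx$cds) && nrow(tx$cds) > 0L) {
    regions <- split_cds_utr(tx, gene$strand)
    cdna <- gc_stats(tx_seq)
    out$cdna_length <- cdna$length
    out$cdna_gc <- cdna$gc
    out$cdna_gc_pct <- cdna$gc_pct
    for (reg in c("cds", "utr5", "utr3")) {
      iv <- regions[[reg]]
      if (is.null(iv) || nrow(iv) == 0L) next  # absent region stays NA
      st <- gc_stats(extract_seq(genome, gene$chrom, iv, gene$strand))
      out[[paste0(reg, "_length")]] <- st$length
      out[[paste0(reg, "_gc")]] <- st$gc
      out[[paste0(reg, "_gc_pct")]] <- st$gc_pct
    }
  }
  out
}

# Partition a coding transcript's exons into 5'UTR / CDS / 3'UTR intervals
# (genomic coordinates; 5'/3' resolved by strand).
split_cds_utr <- function(tx, strand = "+") {
  stopifnot(!is.null(tx$cds))
  cds_lo <- min(tx$cds[, 1L]); cds_hi <- max(tx$cds[, 2L])
  left <- list(); right <- list()
  for (i in seq_len(nrow(tx$exons))) {
    s <- tx$exons[i, 1L]; e <- tx$exons[i, 2L]
    if (s < cds_lo) left[[length(left) + 1L]] <- c(s, min(e, cds_lo))
    if (e > cds_hi) right[[length(right) + 1L]] <- c(max(s, cds_hi), e)
  }
  to_mat <- function(l) {
    if (!length(l)) return(matrix(numeric(0), ncol = 2)) else
      matrix(unlist(l), ncol = 2, byrow = TRUE)
  }
  left <- to_mat(left); right <- to_mat(right)
  list(cds = tx$cds,
       utr5 = if (strand == "-") right else left,
       utr3 = if (strand == "-") left else right)
}

#' Compute transcript features for many genes
#'
#' @param models A `gene_models` collection.
#' @param genome DNAStringSet or FASTA path.
#' @return `data.frame` with one row per gene (its longest transcript).
#' @export
feature_table <- function(models, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  do.call(rbind, lapply(models, transcript_features, genome = genome))
}

# GRanges of merged exons per gene, used for read assignment.
models_exon_granges <- function(models) {
  per <- lapply(models, function(g) {
    ex <- gene_exon_union(g)
    GenomicRanges::GRanges(
      seqnames = g$chrom,
      ranges = IRanges::IRanges(start = ex[, 1L] + 1L, end = ex[, 2L]),
      gene_id = g$gene_id
    )
  })
  suppressWarnings(do.call(c, unname(per)))
}
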
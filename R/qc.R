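# Per-sample library metrics, mismatch profiles and group comparison.

#' Assign reads to genes by exon overlap
#'
#' A read is assigned to a gene iff any of its alignment blocks overlaps
#' the gene's merged exons; reads overlapping exons of more than one gene
#' are discarded as ambiguous (and counted).
#'
#' @param reads An `aligned_reads` object.
#' @param models A `gene_models` collection.
#' @return List with `gene_id` (character per read, `NA` if unassigned or
#'   ambiguous), `n_ambiguous`, `n_unassigned`.
#' @export
assign_reads <- function(reads, models) {
  stopifnot(inherits(reads, "aligned_reads"))
  gr <- models_exon_granges(models)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(reads$blocks, gr, ignore.strand = TRUE))
  q <- S4Vectors::queryHits(hits)
  g <- S4Vectors::mcols(gr)$gene_id[S4Vectors::subjectHits(hits)]
  # per read: unique gene set
  key <- paste(q, g)
  dedup <- !duplicated(key)
  q <- q[dedup]; g <- g[dedup]
  ngene <- tabulate(q, nbins = n_reads(reads))
  gene_id <- rep(NA_character_, n_reads(reads))
  uniq <- ngene == 1L
  gene_id[q[uniq[q]]] <- g[uniq[q]]
  list(gene_id = gene_id,
       n_ambiguous = sum(ngene > 1L),
       n_unassigned = sum(ngene == 0L))
}

#' Per-sample library metrics
#'
#' Computes totals, the uniquely-mapped fraction, duplication rate, a
#' per-read GC histogram in 1% bins, chromosome read fractions and (when
#' an annotation or assignment is supplied) the detected gene count.
#'
#' @param reads An `aligned_reads` object.
#' @param sample_id,group Labels carried into the output.
#' @param models Optional `gene_models` for the detected-gene count.
#' @param assignment Optional precomputed [assign_reads()] result.
#' @return Object of class `library_metrics`.
#' @export
library_metrics <- function(reads, sample_id = "sample", group = NA_character_,
                            models = NULL, assignment = NULL) {
  stopifnot(inherits(reads, "aligned_reads"))
  if (reads$totals$records < 1L) stopf("empty SAM: no records")
  n_mapped <- reads$totals$mapped

  seqs <- Biostrings::DNAStringSet(reads$seq)
  gc <- as.vector(Biostrings::letterFrequency(seqs, "GC")) /
    Biostrings::width(seqs)
  gc_bin <- pmin(floor(gc * 100), 99L)
  gc_hist <- tabulate(gc_bin + 1L, nbins = 100L)
  names(gc_hist) <- sprintf("%d", 0:99)

  chrom_tab <- table(reads$chrom)
  chrom_frac <- as.numeric(chrom_tab) / n_mapped
  names(chrom_frac) <- names(chrom_tab)

  detected <- NA_integer_
  if (is.null(assignment) && !is.null(models)) {
    assignment <- assign_reads(reads, models)
  }
  if (!is.null(assignment)) {
    detected <- length(unique(stats::na.omit(assignment$gene_id)))
  }

  out <- list(
    sample_id = sample_id, group = group,
    total_records = reads$totals$records,
    mapped = n_mapped,
    unique_fraction = sum(reads$unique) / n_mapped,
    duplication_rate = sum(reads$dup) / n_mapped,
    gc_histogram = gc_hist,
    chromosome_fractions = chrom_frac,
    detected_genes = detected
  )
  class(out) <- "library_metrics"
  out
}

#' @export
print.library_metrics <- function(x, ...) {
  cat(sprintf("library_metrics [%s%s]\n", x$sample_id,
              if (is.na(x$group)) "" else paste0(", ", x$group)))
  cat(sprintf("  records %d, mapped %d, unique %.3f, duplication %.3f\n",
              x$total_records, x$mapped, x$unique_fraction,
              x$duplication_rate))
  if (!is.na(x$detected_genes)) {
    cat(sprintf("  detected genes: %d\n", x$detected_genes))
  }
  invisible(x)
}

#' Collect scalar metrics from several samples into a table
#'
#' @param metrics_list List of `library_metrics`.
#' @return `data.frame` with one row per sample.
#' @export
metrics_table <- function(metrics_list) {
  do.call(rbind, lapply(metrics_list, function(m) {
    data.frame(sample_id = m$sample_id, group = m$group,
               unique_fraction = m$unique_fraction,
               duplication_rate = m$duplication_rate,
               detected_genes = m$detected_genes,
               stringsAsFactors = FALSE)
  }))
}

#' Signed relative deviation from the cross-sample median
#'
#' For each metric, deviation = (value - median) / median; a sample is
#' flagged as an outlier iff |deviation| >= 0.30 for any metric (the
#' boundary counts as an outlier). Metrics with median 0 are skipped with
#' a warning.
#'
#' @param values Numeric matrix or `data.frame` (rows = samples, columns =
#'   metrics), or a single numeric vector.
#' @param threshold Outlier threshold on |deviation| (default 0.30).
#' @return List with `deviation` (same shape as input) and `outlier`
#'   (logical per sample).
#' @export
deviation_from_median <- function(values, threshold = 0.30) {
  vec_in <- is.null(dim(values))
  if (vec_in) values <- matrix(values, ncol = 1L,
                               dimnames = list(names(values), "metric"))
  values <- as.matrix(values)
  if (nrow(values) < 3L) stopf("need >= 3 samples, got %d", nrow(values))
  dev <- matrix(NA_real_, nrow(values), ncol(values),
                dimnames = dimnames(values))
  for (j in seq_len(ncol(values))) {
    med <- stats::median(values[, j], na.rm = TRUE)
    if (!is.finite(med) || med == 0) {
      warnf("metric '%s' has zero/undefined median; skipped",
            colnames(values)[j] %||% as.character(j))
      next
    }
    dev[, j] <- (values[, j] - med) / med
  }
  outlier <- apply(dev, 1L, function(r) any(abs(r) >= threshold, na.rm = TRUE))
  list(deviation = if (vec_in) dev[, 1L] else dev, outlier = outlier)
}

#' Per-cycle mismatch-rate profile
#'
#' For each of the 12 substitution types and each read cycle,
#' `rate(X>Y, p)` = (number of X>Y mismatches at cycle p) / (number of
#' aligned bases at cycle p whose reference base is X). The denominator is
#' conditional on the source reference base (a rate per opportunity).
#' Duplicate-flagged and non-unique reads are excluded by default.
#'
#' @param reads An `aligned_reads` object.
#' @param include_duplicates Count duplicate-flagged reads (default FALSE).
#' @return Object of class `mismatch_profile`: `rate`, `count` and
#'   denominator matrices (12 x read length) plus the read count used.
#' @export
mismatch_profile <- function(reads, include_duplicates = FALSE) {
  stopifnot(inherits(reads, "aligned_reads"))
  keep <- reads$unique & (include_duplicates | !reads$dup)
  idx <- which(keep)
  if (!length(idx)) stopf("no usable reads for mismatch profiling")
  widths <- reads$width[idx]
  P <- max(widths)

  seqs <- read_cycle_seqs(reads, idx)
  denom_base <- matrix(0, 4, P, dimnames = list(DNA_BASES, NULL))
  for (w in unique(widths)) {
    cm <- Biostrings::consensusMatrix(seqs[widths == w])[DNA_BASES, ,
                                                         drop = FALSE]
    denom_base[, seq_len(w)] <- denom_base[, seq_len(w)] + cm
  }

  mm <- mismatch_table(reads)
  mm <- mm[mm$read %in% idx, , drop = FALSE]
  counts <- matrix(0, 12, P, dimnames = list(mismatch_types(), NULL))
  if (nrow(mm)) {
    tt <- paste0(mm$ref, ">", mm$alt)
    tab <- table(factor(tt, levels = mismatch_types()),
                 factor(mm$cycle, levels = seq_len(P)))
    counts <- counts + unclass(tab)
    # observed base at a mismatch is the read base; the opportunity
    # belongs to the reference base
    for (b in DNA_BASES) {
      alt_rows <- grepl(paste0(">", b, "$"), rownames(counts))
      denom_base[b, ] <- denom_base[b, ] - colSums(counts[alt_rows, ,
                                                          drop = FALSE])
      ref_rows <- grepl(paste0("^", b, ">"), rownames(counts))
      denom_base[b, ] <- denom_base[b, ] + colSums(counts[ref_rows, ,
                                                          drop = FALSE])
    }
  }

  denom <- matrix(0, 12, P, dimnames = list(mismatch_types(), NULL))
  for (t in mismatch_types()) {
    denom[t, ] <- denom_base[substr(t, 1, 1), ]
  }
  rate <- ifelse(denom > 0, counts / denom, 0)

  out <- list(rate = rate, count = counts, denominator = denom,
              read_len = P, n_reads = length(idx))
  class(out) <- "mismatch_profile"
  out
}

#' @export
print.mismatch_profile <- function(x, ...) {
  cat(sprintf("mismatch_profile: %d reads, read length %d\n",
              x$n_reads, x$read_len))
  cat(sprintf("  overall rate: %.2e\n",
              sum(x$count) / max(sum(x$denominator) / 3, 1)))
  invisible(x)
}

#' Compare mismatch profiles between two groups
#'
#' Pooled-variance two-sample t-test on per-sample rates for every
#' (substitution type, cycle) cell, with Benjamini-Hochberg correction
#' across the whole 12 x read-length family. The pooled (equal-variance)
#' form is used because per-sample rates within a comparison come from
#' libraries of matched depth, where the binomial sampling variance is
#' equal across groups by design; with the typical three replicates per
#' group it keeps the residual degrees of freedom (n1 + n2 - 2) that the
#' Welch approximation collapses. Cells with zero variance in both groups
#' and equal means get P = 1 by convention.
#'
#' @param profiles_a,profiles_b Lists of `mismatch_profile` objects
#'   (>= 2 samples per group).
#' @param fdr Significance threshold on the BH q value (default 0.05).
#' @return `data.frame` (type, position, mean_a, mean_b, p_value, q_value,
#'   significant), one row per tested cell.
#' @export
compare_mismatch_profiles <- function(profiles_a, profiles_b, fdr = 0.05) {
  stopifnot(length(profiles_a) >= 2L, length(profiles_b) >= 2L)
  get_rates <- function(pl) {
    P <- max(vapply(pl, `[[`, 0, "read_len"))
    sapply(pl, function(x) {
      r <- matrix(0, 12, P)
      r[, seq_len(ncol(x$rate))] <- x$rate
      as.vector(r)
    })
  }
  ra <- get_rates(profiles_a)  # (12*P) x nA
  rb <- get_rates(profiles_b)
  stopifnot(nrow(ra) == nrow(rb))
  na <- ncol(ra); nb <- ncol(rb)
  ma <- rowMeans(ra); mb <- rowMeans(rb)
  va <- apply(ra, 1L, stats::var); vb <- apply(rb, 1L, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se2 <- sp2 * (1 / na + 1 / nb)
  tstat <- (ma - mb) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df = na + nb - 2)
  zero_se <- se2 == 0 | !is.finite(p)
  p[zero_se] <- ifelse(abs(ma[zero_se] - mb[zero_se]) < 1e-300, 1, 0)
  q <- stats::p.adjust(p, method = "BH")

  P <- nrow(ra) / 12L
  out <- data.frame(
    type = rep(mismatch_types(), times = P),
    position = rep(seq_len(P), each = 12L),
    mean_a = ma, mean_b = mb,
    p_value = p, q_value = q,
    significant = q <= fdr,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Biotype distribution of assigned reads
#'
#' @param reads An `aligned_reads` object.
#' @param models A `gene_models` collection.
#' @param assignment Optional precomputed [assign_reads()] result.
#' @return List with `fractions` (named, over assigned reads),
#'   `n_assigned`, `n_unassigned`.
#' @export
biotype_distribution <- function(reads, models, assignment = NULL) {
  assignment <- assignment %||% assign_reads(reads, models)
  biotype <- vapply(models, function(g) g$biotype, character(1))
  g <- assignment$gene_id
  assigned <- !is.na(g)
  if (!any(assigned)) {
    return(list(fractions = stats::setNames(numeric(0), character(0)),
                n_assigned = 0L, n_unassigned = sum(!assigned)))
  }
  bt <- biotype[g[assigned]]
  tab <- table(bt)
  list(fractions = stats::setNames(as.numeric(tab) / sum(assigned),
                                   names(tab)),
       n_assigned = sum(assigned),
       n_unassigned = sum(!assigned))
}
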
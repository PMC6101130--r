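# Gene-body coverage over 40 meta-transcript bins and cumulative gene
# diversity curves.

#' Select genes in the upper middle quartile of read counts
#'
#' Genes whose read count lies in the [P50, P75) range of the count
#' distribution over expressed genes (count > 0). Percentiles use linear
#' interpolation (type 7); the interval is closed at P50 and open at P75.
#' If P50 equals P75 (e.g. all counts tied), genes at that common value
#' are selected.
#'
#' @param counts Named numeric vector of per-gene read counts.
#' @return Character vector of selected gene ids.
#' @export
select_upper_middle_quartile <- function(counts) {
  expressed <- counts[counts > 0]
  if (length(expressed) < 4L) {
    stopf("need >= 4 expressed genes for quartile selection, got %d",
          length(expressed))
  }
  qs <- stats::quantile(expressed, c(0.5, 0.75), type = 7, names = FALSE)
  sel <- if (qs[1] == qs[2]) {
    expressed == qs[1]
  } else {
    expressed >= qs[1] & expressed < qs[2]
  }
  names(expressed)[sel]
}

# Bin a vector of meta-positions into n_bins equal-length bins (bin 1 at
# the 5' end); positions must lie in [0, L).
bin_meta_positions <- function(m, L, n_bins = 40L) {
  stopifnot(all(m >= 0), all(m < L))
  b <- pmin(floor(n_bins * m / L), n_bins - 1L) + 1L
  tabulate(b, nbins = n_bins)
}

#' Gene-body coverage profile
#'
#' Each assigned read contributes 1 to the bin containing its 5'-end
#' meta-position (strand-aware: bin 1 is the transcript 5' end); bins are
#' aggregated over the gene set and normalised to fractions. Genes shorter
#' than `n_bins` nt are excluded.
#'
#' @param reads An `aligned_reads` object.
#' @param metas Named list of `meta_transcript`s.
#' @param gene_set Character vector of gene ids to profile.
#' @param assignment [assign_reads()] result for `reads`.
#' @param sample_id Label carried into the output.
#' @param include_duplicates Count duplicate-flagged reads (default TRUE,
#'   matching the counting policy).
#' @param n_bins Number of bins (default 40, i.e. 2.5% of gene length each).
#' @return Object of class `coverage_profile`: bin `fractions` (length
#'   `n_bins`, summing to 1), `counts`, `n_genes`, `n_reads`.
#' @export
gene_body_coverage <- function(reads, metas, gene_set, assignment,
                               sample_id = "sample",
                               include_duplicates = TRUE, n_bins = 40L) {
  stopifnot(length(gene_set) >= 1L)
  gene_set <- intersect(gene_set, names(metas))
  short <- vapply(metas[gene_set], function(m) m$L < n_bins, logical(1))
  if (any(short)) {
    warnf("%d gene(s) shorter than %d nt excluded from coverage",
          sum(short), n_bins)
    gene_set <- gene_set[!short]
  }
  if (!length(gene_set)) stopf("no genes long enough to profile")

  keep <- if (include_duplicates) rep(TRUE, n_reads(reads)) else !reads$dup
  bins <- integer(n_bins)
  n_used <- 0L; n_genes <- 0L
  for (gid in gene_set) {
    meta <- metas[[gid]]
    idx <- which(keep & !is.na(assignment$gene_id) &
                   assignment$gene_id == gid)
    if (!length(idx)) next
    p5 <- read_five_prime_pos(reads, meta$strand, idx)
    m <- genomic_to_meta(meta, meta$chrom, p5)
    m <- m[!is.na(m)]
    if (!length(m)) next
    bins <- bins + bin_meta_positions(m, meta$L, n_bins)
    n_used <- n_used + length(m)
    n_genes <- n_genes + 1L
  }
  if (n_used == 0L) stopf("no reads contributed to the coverage profile")
  out <- list(sample_id = sample_id, fractions = bins / n_used,
              counts = bins, n_genes = n_genes, n_reads = n_used,
              n_bins = n_bins)
  class(out) <- "coverage_profile"
  out
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("coverage_profile [%s]: %d reads over %d genes, %d bins\n",
              x$sample_id, x$n_reads, x$n_genes, x$n_bins))
  cat(sprintf("  5' half %.3f / 3' half %.3f\n",
              sum(x$fractions[seq_len(x$n_bins / 2)]),
              sum(x$fractions[-seq_len(x$n_bins / 2)])))
  invisible(x)
}

#' Cumulative gene diversity
#'
#' Genes are sorted by descending read count (ties broken by gene id for
#' determinism); the fraction at rank k is the share of all assigned reads
#' captured by the top k genes. Ranks beyond the number of genes report 1.
#'
#' @param counts Named numeric vector of per-gene read counts.
#' @param ranks Ranks at which to evaluate the curve.
#' @param sample_id Label carried into the output.
#' @return Object of class `diversity_curve`: `fractions` named by rank,
#'   `total_reads`.
#' @export
cumulative_gene_diversity <- function(counts,
                                      ranks = c(10L, 100L, 1000L, 10000L),
                                      sample_id = "sample") {
  stopifnot(all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stopf("all gene counts are zero")
  ord <- order(-counts, names(counts))
  cum <- cumsum(counts[ord])
  frac <- vapply(ranks, function(k) {
    if (k >= length(cum)) 1 else cum[k] / total
  }, 0)
  out <- list(sample_id = sample_id,
              fractions = stats::setNames(frac, as.character(ranks)),
              ranks = ranks, total_reads = total)
  class(out) <- "diversity_curve"
  out
}

#' @export
print.diversity_curve <- function(x, ...) {
  cat(sprintf("diversity_curve [%s]: %g assigned reads\n",
              x$sample_id, x$total_reads))
  cat(" ", paste(sprintf("top %s: %.3f", names(x$fractions), x$fractions),
                 collapse = "  "), "\n")
  invisible(x)
}
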
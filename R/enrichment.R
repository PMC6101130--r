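# Transcript-feature comparisons (Mann-Whitney) and ARE/bias overlap.

#' Mann-Whitney U test
#'
#' Two-tailed rank-sum comparison. The exact null distribution is used
#' when `n1 * n2 <= 400` and there are no ties; otherwise the normal
#' approximation with midranks, tie-corrected variance and continuity
#' correction. The reported U statistic is for the first group.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return List: `U`, `p_value`, `exact` (logical), `n1`, `n2`.
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stopf("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) * length(b) <= 400L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value, exact = exact,
       n1 = length(a), n2 = length(b))
}

# Feature columns compared per biotype stratum. lncRNA features are whole
# transcripts; protein-coding features use the cDNA and its CDS/UTR parts.
stratum_features <- function() {
  list(
    lncRNA = c("transcript_length", "transcript_gc", "transcript_gc_pct"),
    protein_coding = c("cdna_length", "cdna_gc", "cdna_gc_pct",
                       "cds_length", "cds_gc_pct",
                       "utr5_gc_pct", "utr3_gc_pct")
  )
}

#' Compare transcript features of a gene set against the background
#'
#' For each biotype stratum and feature, a two-tailed Mann-Whitney test of
#' the selected genes against all annotated genes of that stratum (the
#' background includes the selected genes by default, matching the
#' all-versus-selected design; set `exclude_de = TRUE` to remove them).
#' Genes with the feature absent (e.g. no 3'UTR) are excluded from that
#' feature's vectors, with the exclusion counted in the output.
#'
#' @param features Feature table from [feature_table()].
#' @param de_genes Character vector of selected (e.g. DE) gene ids.
#' @param strata Named list biotype -> feature columns
#'   (default [stratum_features()]).
#' @param exclude_de Remove the selected genes from the background.
#' @return `data.frame`: stratum, feature, group sizes, medians, U,
#'   p_value, and a `low_power` flag for strata with < 3 selected genes.
#' @export
compare_features <- function(features, de_genes,
                             strata = stratum_features(),
                             exclude_de = FALSE) {
  out <- list()
  for (stratum in names(strata)) {
    bg_rows <- features$biotype == stratum
    de_rows <- bg_rows & features$gene_id %in% de_genes
    if (exclude_de) bg_rows <- bg_rows & !de_rows
    low_power <- sum(de_rows) < 3L
    if (low_power && sum(de_rows) > 0L) {
      warnf("stratum %s has only %d selected gene(s); low power",
            stratum, sum(de_rows))
    }
    if (!sum(de_rows) || !sum(bg_rows)) next
    for (feat in strata[[stratum]]) {
      if (!feat %in% colnames(features)) next
      va <- features[[feat]][de_rows]
      vb <- features[[feat]][bg_rows]
      n_na <- sum(is.na(va)) + sum(is.na(vb))
      va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
      if (!length(va) || !length(vb)) next
      mw <- mann_whitney(va, vb)
      out[[length(out) + 1L]] <- data.frame(
        stratum = stratum, feature = feat,
        n_de = length(va), n_background = length(vb),
        n_excluded_na = n_na,
        median_de = stats::median(va), median_background = stats::median(vb),
        U = mw$U, p_value = mw$p_value, exact = mw$exact,
        low_power = low_power, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    stopf("no comparable strata: check biotypes and feature columns")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Overlap of AU-rich-element annotation and degradation bias
#'
#' Partitions a gene set into ARE-only, bias-only, both and neither. A
#' gene "has ARE" iff its 3'UTR or intron flag is set in the ARE table
#' (genes missing from the table count as no-ARE, logged); it "has bias"
#' iff its bias class is a significant 5' or 3' underrepresentation.
#'
#' @param de_genes Character vector of gene ids.
#' @param are_table `data.frame` with columns `gene_id`, `are_3utr`,
#'   `are_intron` (0/1 or logical).
#' @param bias A `bias_scan` (or its `results` data.frame).
#' @return Object of class `overlap_counts`: the four counts (summing to
#'   the set size) and the per-gene flags.
#' @export
are_overlap <- function(de_genes, are_table, bias) {
  if (inherits(bias, "bias_scan")) bias <- bias$results
  stopifnot(all(c("gene_id", "are_3utr", "are_intron") %in%
                  colnames(are_table)))
  mi <- match(de_genes, are_table$gene_id)
  missing <- sum(is.na(mi))
  if (missing) {
    message(sprintf("%d gene(s) missing from the ARE table; treated as no-ARE",
                    missing))
  }
  has_are <- !is.na(mi) &
    (as.logical(are_table$are_3utr[mi]) | as.logical(are_table$are_intron[mi]))
  has_are[is.na(has_are)] <- FALSE

  bcls <- bias$class[match(de_genes, bias$gene_id)]
  has_bias <- bcls %in% c("five_prime_underrepresented",
                          "three_prime_underrepresented")

  flags <- data.frame(gene_id = de_genes, has_are = has_are,
                      has_bias = has_bias, stringsAsFactors = FALSE)
  counts <- c(
    are_only = sum(has_are & !has_bias),
    bias_only = sum(!has_are & has_bias),
    both = sum(has_are & has_bias),
    neither = sum(!has_are & !has_bias)
  )
  out <- list(counts = counts, flags = flags, n_missing_from_are = missing)
  class(out) <- "overlap_counts"
  out
}

#' @export
print.overlap_counts <- function(x, ...) {
  cat("overlap_counts:",
      paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", "),
      sprintf("(n=%d)\n", sum(x$counts)))
  invisible(x)
}

#' Read an ARE annotation table
#'
#' Expected delimited columns: `gene_id`, `are_3utr`, `are_intron`
#' (0/1). Converters from external ARE databases should emit this schema.
#'
#' @param path Path to a TSV/CSV file.
#' @return `data.frame`.
#' @export
read_are_table <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "are_3utr", "are_intron")
  if (!all(need %in% colnames(df))) {
    stopf("ARE table must have columns: %s", paste(need, collapse = ", "))
  }
  df
}
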
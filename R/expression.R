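# Gene-level counting, FPKM, expression filters and group comparison.

#' Count assigned reads per gene for one sample
#'
#' @param reads An `aligned_reads` object.
#' @param models A `gene_models` collection.
#' @param assignment Optional precomputed [assign_reads()] result.
#' @param include_duplicates Count duplicate-flagged reads (default TRUE;
#'   duplicates are flagged and reported but retained for quantification).
#' @return List: `counts` (named vector over all genes), `n_ambiguous`.
#' @export
count_reads <- function(reads, models, assignment = NULL,
                        include_duplicates = TRUE) {
  assignment <- assignment %||% assign_reads(reads, models)
  g <- assignment$gene_id
  if (!include_duplicates) g[reads$dup] <- NA_character_
  tab <- table(factor(g, levels = names(models)))
  list(counts = stats::setNames(as.numeric(tab), names(models)),
       n_ambiguous = assignment$n_ambiguous)
}

#' Build a gene x sample count matrix
#'
#' @param read_list Named list of `aligned_reads` (names = sample ids).
#' @param models A `gene_models` collection.
#' @param assignments Optional named list of [assign_reads()] results.
#' @param include_duplicates See [count_reads()].
#' @return List: `counts` matrix, `ambiguous` per sample.
#' @export
count_matrix <- function(read_list, models, assignments = NULL,
                         include_duplicates = TRUE) {
  res <- lapply(seq_along(read_list), function(i) {
    count_reads(read_list[[i]], models,
                assignment = assignments[[i]],
                include_duplicates = include_duplicates)
  })
  counts <- do.call(cbind, lapply(res, `[[`, "counts"))
  colnames(counts) <- names(read_list)
  list(counts = counts,
       ambiguous = stats::setNames(vapply(res, `[[`, 0, "n_ambiguous"),
                                   names(read_list)))
}

#' FPKM from counts
#'
#' `FPKM = count * 1e9 / (L * M)` with `L` the gene's meta-transcript
#' length in nt and `M` the sample's total assigned reads (reads assigned
#' to any gene, the library-size convention used throughout the package).
#'
#' @param counts Gene x sample count matrix (or named vector).
#' @param lengths Named vector of meta-transcript lengths (nt).
#' @param M Optional library sizes; default `colSums(counts)`.
#' @return FPKM matrix of the same shape.
#' @export
fpkm <- function(counts, lengths, M = NULL) {
  vec_in <- is.null(dim(counts))
  if (vec_in) counts <- matrix(counts, ncol = 1L,
                               dimnames = list(names(counts), "sample"))
  lengths <- lengths[rownames(counts)]
  if (anyNA(lengths) || any(lengths <= 0)) {
    stopf("missing or non-positive gene length")
  }
  M <- M %||% colSums(counts)
  if (any(M <= 0)) stopf("library size M must be positive for every sample")
  out <- sweep(counts * 1e9 / lengths, 2L, M, "/")
  if (vec_in) out[, 1L] else out
}

#' Expression and biotype filter
#'
#' Keeps genes with FPKM >= 1 in at least one sample (genes below 1 across
#' all samples are considered unexpressed) whose biotype is not a
#' poly(A)-free small-RNA class (ambiguous capture under poly(A)
#' selection).
#'
#' @param fpkm_mat Gene x sample FPKM matrix.
#' @param biotypes Named biotype vector covering the matrix rows.
#' @return Logical vector over rows of `fpkm_mat` (TRUE = keep).
#' @export
filter_expressed <- function(fpkm_mat, biotypes) {
  expressed <- apply(fpkm_mat >= 1, 1L, any)
  polya_ok <- !(biotypes[rownames(fpkm_mat)] %in% polya_free_biotypes())
  expressed & polya_ok
}

#' Abundance class from FPKM
#'
#' high (FPKM > 100), moderate (10-100), low (1-10), extremely low (< 1).
#'
#' @param x Numeric FPKM values.
#' @return Character vector of classes.
#' @export
abundance_class <- function(x) {
  ifelse(x > 100, "high",
         ifelse(x >= 10, "moderate",
                ifelse(x >= 1, "low", "extremely_low")))
}

#' Compare expression between two groups
#'
#' Computes group-mean FPKMs, the squared Pearson correlation of log2
#' group means (over genes with both means > 0), and per-gene folds
#' oriented control / treated, so genes downsampled in the treated group
#' have fold > 1.
#'
#' @param fpkm_mat Filtered gene x sample FPKM matrix.
#' @param groups Named character vector mapping sample id to group.
#' @param control,treated Group labels (defaults: first and second level).
#' @param de_genes Optional gene ids to summarise folds for (e.g. an
#'   external DE list or simulator truth); genes absent from the matrix
#'   are skipped with a warning.
#' @return Object of class `expression_comparison`: `r_squared`, a
#'   per-gene table (group means, fold, abundance class of the control
#'   mean), and a fold summary over `de_genes` when supplied.
#' @export
group_comparison <- function(fpkm_mat, groups, control = NULL,
                             treated = NULL, de_genes = NULL) {
  glev <- unique(unname(groups[colnames(fpkm_mat)]))
  control <- control %||% glev[1L]
  treated <- treated %||% glev[2L]
  a <- fpkm_mat[, groups[colnames(fpkm_mat)] == control, drop = FALSE]
  b <- fpkm_mat[, groups[colnames(fpkm_mat)] == treated, drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L) {
    stopf("need >= 2 samples per group (%s: %d, %s: %d)",
          control, ncol(a), treated, ncol(b))
  }
  mean_c <- rowMeans(a); mean_t <- rowMeans(b)
  both <- mean_c > 0 & mean_t > 0
  r2 <- if (sum(both) >= 3L) {
    stats::cor(log2(mean_c[both]), log2(mean_t[both]))^2
  } else NA_real_

  tab <- data.frame(
    gene_id = rownames(fpkm_mat),
    mean_control = mean_c, mean_treated = mean_t,
    fold = ifelse(mean_t > 0, mean_c / mean_t, NA_real_),
    abundance = abundance_class(mean_c),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL

  de_summary <- NULL
  if (!is.null(de_genes)) {
    missing <- setdiff(de_genes, tab$gene_id)
    if (length(missing)) {
      warnf("%d DE gene(s) absent from the expression table; skipped",
            length(missing))
    }
    de <- tab[tab$gene_id %in% de_genes, , drop = FALSE]
    de_summary <- list(
      genes = de$gene_id,
      folds = stats::setNames(de$fold, de$gene_id),
      median_fold = stats::median(de$fold, na.rm = TRUE),
      fold_range = range(de$fold, na.rm = TRUE)
    )
  }

  out <- list(control = control, treated = treated, r_squared = r2,
              table = tab, de = de_summary)
  class(out) <- "expression_comparison"
  out
}

#' @export
print.expression_comparison <- function(x, ...) {
  cat(sprintf("expression_comparison: %s vs %s, %d genes, R^2(log2 means) = %s\n",
              x$control, x$treated, nrow(x$table),
              formatC(x$r_squared, digits = 4, format = "f")))
  if (!is.null(x$de)) {
    cat(sprintf("  DE folds (%s/%s): median %.2f, range %.2f-%.2f over %d genes\n",
                x$control, x$treated, x$de$median_fold,
                x$de$fold_range[1], x$de$fold_range[2], length(x$de$genes)))
  }
  invisible(x)
}
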
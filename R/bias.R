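# The 40-bin meta-transcript read-count-ratio regression.
#
# For each gene, reads from each sample are binned by the meta-position of
# their 5' end into 40 equal-length bins (bin 1 = 5' end). Per-bin counts
# are averaged within groups, the treated/control ratio is formed in each
# usable bin (control mean > 0), and the ratio is regressed on bin index
# by ordinary least squares. A slope significantly above zero (two-sided
# t-test, P < alpha) means the ratio rises toward the 3' end, i.e. the 5'
# end is underrepresented in the treated group; a negative slope means 3'
# underrepresentation; otherwise the gene is uniformly downsampled.

#' Per-sample bin counts for one gene
#'
#' @param m Meta-positions of assigned read 5' ends, in `[0, L)`.
#' @param L Meta-transcript length (must be >= `n_bins`).
#' @param n_bins Number of bins (default 40).
#' @return Integer vector of length `n_bins`.
#' @export
bin_counts <- function(m, L, n_bins = 40L) {
  if (L < n_bins) stopf("gene shorter than %d nt cannot be binned", n_bins)
  bin_meta_positions(m, L, n_bins)
}

#' Bin-to-bin group ratio profile
#'
#' @param control_mat,treated_mat Sample x bin count matrices.
#' @return List: `ratio` (treated mean / control mean per bin), `usable`
#'   (control mean > 0), `mean_control`, `mean_treated`.
#' @export
ratio_profile <- function(control_mat, treated_mat) {
  stopifnot(ncol(control_mat) == ncol(treated_mat),
            nrow(control_mat) >= 1L, nrow(treated_mat) >= 1L)
  mc <- colMeans(control_mat)
  mt <- colMeans(treated_mat)
  usable <- mc > 0
  ratio <- rep(NA_real_, length(mc))
  ratio[usable] <- mt[usable] / mc[usable]
  list(ratio = ratio, usable = usable, mean_control = mc, mean_treated = mt)
}

#' Classify one gene's ratio profile
#'
#' OLS of ratio on bin index over usable bins, two-sided t-test of
#' slope = 0. Classes: `uniform` (P >= alpha),
#' `five_prime_underrepresented` (P < alpha, slope > 0),
#' `three_prime_underrepresented` (P < alpha, slope < 0). Genes with fewer
#' than `min_usable` usable bins are `unclassifiable`.
#'
#' @param rp A [ratio_profile()] result.
#' @param alpha Significance level (default 0.01).
#' @param min_usable Minimum usable bins to attempt the regression.
#' @return List: `slope`, `intercept`, `p_value`, `n_usable`, `class`.
#' @export
classify_bias <- function(rp, alpha = 0.01, min_usable = 10L) {
  usable <- which(rp$usable)
  n <- length(usable)
  if (n < min_usable) {
    return(list(slope = NA_real_, intercept = NA_real_, p_value = NA_real_,
                n_usable = n, class = "unclassifiable",
                reason = sprintf("only %d usable bins (< %d)", n, min_usable)))
  }
  x <- usable                     # bin index 1..40
  y <- rp$ratio[usable]
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  beta <- sum((x - xbar) * (y - ybar)) / sxx
  alpha0 <- ybar - beta * xbar
  resid <- y - (alpha0 + beta * x)
  rss <- sum(resid^2)
  se <- sqrt(rss / (n - 2) / sxx)
  if (!is.finite(se) || se == 0) {
    # exact line (or constant): P follows the limit convention
    p <- if (abs(beta) < 1e-12) 1 else 0
  } else {
    tval <- beta / se
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  cls <- if (p >= alpha) "uniform" else if (beta > 0) {
    "five_prime_underrepresented"
  } else "three_prime_underrepresented"
  list(slope = beta, intercept = alpha0, p_value = p, n_usable = n,
       class = cls)
}

#' Fit the degradation-bias classifier across genes
#'
#' The main fitting function of the package: for each gene it bins read
#' 5'-end meta-positions per sample, averages within groups, forms the
#' treated/control per-bin ratio and regresses it on bin index, yielding a
#' slope, a P value and a bias class per gene. A BH q value across genes
#' is reported alongside (classification itself uses the per-gene P,
#' matching the per-gene alpha convention).
#'
#' @param read_list Named list of `aligned_reads` (names = sample ids).
#' @param groups Named character vector mapping sample id to group.
#' @param metas Named list of `meta_transcript`s.
#' @param genes Genes to classify (default: all in `metas`).
#' @param assignments Optional named list of [assign_reads()] results
#'   (computed if missing, which requires `models`).
#' @param models `gene_models`, needed only if `assignments` is missing.
#' @param control,treated Group labels (defaults: first two levels).
#' @param alpha Per-gene significance level (default 0.01).
#' @param min_usable Minimum usable bins (default 10).
#' @param include_duplicates Count duplicate-flagged reads (default TRUE).
#' @param n_bins Number of bins (default 40).
#' @return Object of class `bias_scan`; see [summary.bias_scan()].
#' @export
degradation_bias <- function(read_list, groups, metas, genes = NULL,
                             assignments = NULL, models = NULL,
                             control = NULL, treated = NULL,
                             alpha = 0.01, min_usable = 10L,
                             include_duplicates = TRUE, n_bins = 40L) {
  stopifnot(is.list(read_list), length(read_list) >= 2L)
  samples <- names(read_list)
  glab <- groups[samples]
  glev <- unique(unname(glab))
  control <- control %||% glev[1L]
  treated <- treated %||% glev[2L]
  if (is.null(assignments)) {
    if (is.null(models)) stopf("supply either assignments or models")
    assignments <- lapply(read_list, assign_reads, models = models)
  }
  genes <- genes %||% names(metas)

  # per sample per gene: meta-positions of read 5' ends
  bin_mats <- list()
  for (s in samples) {
    reads <- read_list[[s]]
    keep <- if (include_duplicates) rep(TRUE, n_reads(reads)) else !reads$dup
    gid <- assignments[[s]]$gene_id
    mat <- matrix(0L, nrow = length(genes), ncol = n_bins,
                  dimnames = list(genes, NULL))
    for (g in genes) {
      meta <- metas[[g]]
      if (is.null(meta) || meta$L < n_bins) next
      idx <- which(keep & !is.na(gid) & gid == g)
      if (!length(idx)) next
      p5 <- read_five_prime_pos(reads, meta$strand, idx)
      m <- genomic_to_meta(meta, meta$chrom, p5)
      m <- m[!is.na(m)]
      if (length(m)) mat[g, ] <- bin_counts(m, meta$L, n_bins)
    }
    bin_mats[[s]] <- mat
  }

  ctrl_s <- samples[glab == control]
  trt_s <- samples[glab == treated]
  res <- vector("list", length(genes))
  bin_tables <- vector("list", length(genes))
  names(res) <- names(bin_tables) <- genes
  for (g in genes) {
    cm <- do.call(rbind, lapply(bin_mats[ctrl_s], function(m) m[g, ]))
    tm <- do.call(rbind, lapply(bin_mats[trt_s], function(m) m[g, ]))
    if (is.null(metas[[g]]) || metas[[g]]$L < n_bins) {
      res[[g]] <- list(slope = NA_real_, intercept = NA_real_,
                       p_value = NA_real_, n_usable = 0L,
                       class = "unclassifiable",
                       reason = "gene shorter than bin count or unknown")
      next
    }
    rp <- ratio_profile(cm, tm)
    res[[g]] <- classify_bias(rp, alpha = alpha, min_usable = min_usable)
    bin_tables[[g]] <- data.frame(
      bin = seq_len(n_bins),
      mean_control = rp$mean_control,
      mean_treated = rp$mean_treated,
      ratio = rp$ratio
    )
  }

  tab <- data.frame(
    gene_id = genes,
    n_usable = vapply(res, `[[`, 0L, "n_usable"),
    slope = vapply(res, `[[`, 0, "slope"),
    intercept = vapply(res, `[[`, 0, "intercept"),
    p_value = vapply(res, `[[`, 0, "p_value"),
    class = vapply(res, `[[`, character(1), "class"),
    stringsAsFactors = FALSE
  )
  tab$q_value <- stats::p.adjust(tab$p_value, method = "BH")
  rownames(tab) <- NULL

  out <- list(results = tab, bin_tables = bin_tables,
              control = control, treated = treated,
              alpha = alpha, min_usable = min_usable, n_bins = n_bins,
              samples = data.frame(sample_id = samples, group = unname(glab),
                                   stringsAsFactors = FALSE))
  class(out) <- "bias_scan"
  out
}

#' @export
print.bias_scan <- function(x, ...) {
  cls <- table(factor(x$results$class,
                      levels = c("uniform", "five_prime_underrepresented",
                                 "three_prime_underrepresented",
                                 "unclassifiable")))
  cat(sprintf("bias_scan: %d genes, %s vs %s, alpha = %g\n",
              nrow(x$results), x$treated, x$control, x$alpha))
  cat(sprintf("  uniform %d | 5' under %d | 3' under %d | unclassifiable %d\n",
              cls[1], cls[2], cls[3], cls[4]))
  invisible(x)
}

#' @method summary bias_scan
#' @export
summary.bias_scan <- function(object, ...) {
  r <- object$results
  structure(list(
    n_genes = nrow(r),
    class_counts = table(r$class),
    alpha = object$alpha,
    slope_range = range(r$slope, na.rm = TRUE),
    results = r
  ), class = "summary.bias_scan")
}

#' @export
print.summary.bias_scan <- function(x, ...) {
  cat(sprintf("bias_scan of %d genes (alpha = %g)\n", x$n_genes, x$alpha))
  print(x$class_counts)
  cat(sprintf("slope range: %.4g .. %.4g\n",
              x$slope_range[1], x$slope_range[2]))
  invisible(x)
}

#' @method coef bias_scan
#' @export
coef.bias_scan <- function(object, ...) {
  stats::setNames(object$results$slope, object$results$gene_id)
}

#' Plot one gene's bin ratio profile
#'
#' Per-bin group mean counts (top) and the treated/control ratio with the
#' fitted regression line (bottom).
#'
#' @param x A `bias_scan`.
#' @param gene Gene id to plot (default: smallest P value).
#' @param ... Ignored.
#' @method plot bias_scan
#' @export
plot.bias_scan <- function(x, gene = NULL, ...) {
  r <- x$results
  gene <- gene %||% r$gene_id[which.min(r$p_value)]
  bt <- x$bin_tables[[gene]]
  if (is.null(bt)) stopf("no bin table for gene %s", gene)
  fit <- r[r$gene_id == gene, ]
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::matplot(bt$bin, cbind(bt$mean_control, bt$mean_treated),
                    type = "b", pch = c(1, 2), lty = 1,
                    col = c("black", "red3"),
                    xlab = "bin (5' -> 3')", ylab = "mean read count",
                    main = sprintf("%s (%s)", gene, fit$class))
  graphics::legend("topleft", legend = c(x$control, x$treated),
                   col = c("black", "red3"), pch = c(1, 2), bty = "n")
  graphics::plot(bt$bin, bt$ratio, pch = 16,
                 xlab = "bin (5' -> 3')",
                 ylab = sprintf("%s / %s ratio", x$treated, x$control))
  if (is.finite(fit$slope)) {
    graphics::abline(fit$intercept, fit$slope, col = "blue")
    graphics::mtext(sprintf("slope %.4g, P = %.3g", fit$slope, fit$p_value),
                    side = 3, cex = 0.8)
  }
  invisible(x)
}
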
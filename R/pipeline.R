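# End-to-end orchestration: annotation -> QC -> coverage/diversity ->
# expression -> bias -> enrichment (-> qPCR), with all stage outputs
# written as TSV/JSON.

#' Pipeline run configuration
#'
#' @param sam Named character vector of SAM paths (names = sample ids).
#' @param groups Named character vector mapping sample id to group label;
#'   must cover all samples.
#' @param gtf GTF annotation path.
#' @param outdir Output directory.
#' @param fasta Optional genome FASTA (enables transcript features).
#' @param de_list Optional path to a DE gene list (one gene_id per line)
#'   or a character vector of gene ids.
#' @param are_table Optional ARE annotation table path.
#' @param cp_table Optional qPCR Cp table path.
#' @param control,treated Group labels (defaults: first two levels).
#' @param alpha_bias Bias-classifier significance level (default 0.01).
#' @param mismatch_fdr FDR for the mismatch comparison (default 0.05).
#' @param mapq_threshold Uniqueness MAPQ fallback (default 10).
#' @param seed Seed recorded in the run log (no stage is stochastic, but
#'   the seed is logged for provenance).
#' @return Object of class `run_config`.
#' @export
run_config <- function(sam, groups, gtf, outdir, fasta = NULL,
                       de_list = NULL, are_table = NULL, cp_table = NULL,
                       control = NULL, treated = NULL,
                       alpha_bias = 0.01, mismatch_fdr = 0.05,
                       mapq_threshold = 10L, seed = 1L) {
  if (missing(sam) || is.null(sam)) stopf("config field missing: sam")
  if (missing(groups) || is.null(groups)) stopf("config field missing: groups")
  if (missing(gtf) || is.null(gtf)) stopf("config field missing: gtf")
  if (missing(outdir) || is.null(outdir)) stopf("config field missing: outdir")
  if (is.null(names(sam))) names(sam) <- paste0("sample_", seq_along(sam))
  miss <- setdiff(names(sam), names(groups))
  if (length(miss)) {
    stopf("groups do not cover sample(s): %s", paste(miss, collapse = ", "))
  }
  stopifnot(alpha_bias > 0, alpha_bias < 1, mismatch_fdr > 0,
            mismatch_fdr < 1)
  cfg <- list(sam = sam, groups = groups, gtf = gtf, outdir = outdir,
              fasta = fasta, de_list = de_list, are_table = are_table,
              cp_table = cp_table, control = control, treated = treated,
              alpha_bias = alpha_bias, mismatch_fdr = mismatch_fdr,
              mapq_threshold = mapq_threshold, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes annotation loading, per-sample QC, mismatch comparison,
#' coverage and diversity, expression quantification and filtering, the
#' degradation-bias classifier, feature/ARE enrichment (when inputs are
#' given) and qPCR analysis (when a Cp table is given). All stage tables
#' are written under `config$outdir` together with a machine-readable
#' `summary.json`.
#'
#' @param config A [run_config()].
#' @return Object of class `dryqc_report` (invisibly returns all stage
#'   results; the same content is on disk).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  outdir <- config$outdir

  models <- run_stage("annotation", read_gtf(config$gtf))
  metas <- lapply(models, build_meta_transcript)
  biotype <- vapply(models, function(g) g$biotype, character(1))
  lengths <- vapply(metas, function(m) m$L, 0)

  read_list <- run_stage("read_sam", lapply(config$sam, read_sam,
                                            mapq_threshold = config$mapq_threshold))
  assignments <- run_stage("assignment",
                           lapply(read_list, assign_reads, models = models))
  samples <- names(read_list)
  glab <- config$groups[samples]
  glev <- unique(unname(glab))
  control <- config$control %||% glev[1L]
  treated <- if (length(glev) > 1L) config$treated %||% glev[2L] else NULL

  # --- library metrics -------------------------------------------------
  metrics <- run_stage("library_metrics", {
    out <- lapply(samples, function(s) {
      library_metrics(read_list[[s]], sample_id = s, group = glab[[s]],
                      assignment = assignments[[s]])
    })
    names(out) <- samples
    out
  })
  mt <- metrics_table(metrics)
  dev <- NULL
  if (nrow(mt) >= 3L) {
    dev <- deviation_from_median(
      as.matrix(mt[, c("unique_fraction", "duplication_rate",
                       "detected_genes")]))
    mt$outlier <- dev$outlier
  }
  write_tsv(mt, file.path(outdir, "library_metrics.tsv"))

  biotype_dist <- run_stage("biotype_distribution", {
    out <- lapply(samples, function(s) {
      bd <- biotype_distribution(read_list[[s]], models, assignments[[s]])
      data.frame(sample_id = s,
                 biotype = c(names(bd$fractions), "unassigned"),
                 fraction = c(bd$fractions,
                              bd$n_unassigned /
                                max(bd$n_assigned + bd$n_unassigned, 1L)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  write_tsv(biotype_dist, file.path(outdir, "biotype_distribution.tsv"))

  # --- mismatch profiles ----------------------------------------------
  profiles <- run_stage("mismatch_profile",
                        lapply(read_list, mismatch_profile))
  mm_cmp <- NULL
  if (!is.null(treated) && sum(glab == control) >= 2L &&
      sum(glab == treated) >= 2L) {
    mm_cmp <- run_stage("mismatch_comparison", compare_mismatch_profiles(
      profiles[samples[glab == control]],
      profiles[samples[glab == treated]],
      fdr = config$mismatch_fdr))
    write_tsv(mm_cmp, file.path(outdir, "mismatch_comparison.tsv"))
  }

  # --- expression ------------------------------------------------------
  cm <- run_stage("counting", count_matrix(read_list, models, assignments))
  write_tsv(data.frame(gene_id = rownames(cm$counts), cm$counts,
                       check.names = FALSE),
            file.path(outdir, "counts.tsv"))
  fp <- run_stage("fpkm", fpkm(cm$counts, lengths))
  write_tsv(data.frame(gene_id = rownames(fp), fp, check.names = FALSE),
            file.path(outdir, "fpkm.tsv"))
  keep <- filter_expressed(fp, biotype)

  de_genes <- NULL
  if (!is.null(config$de_list)) {
    de_genes <- if (length(config$de_list) == 1L &&
                    file.exists(config$de_list)) {
      readLines(config$de_list, warn = FALSE)
    } else as.character(config$de_list)
    de_genes <- de_genes[nzchar(de_genes)]
  }

  cmp <- NULL
  if (!is.null(treated)) {
    cmp <- run_stage("group_comparison",
                     group_comparison(fp[keep, , drop = FALSE], glab,
                                      control, treated, de_genes))
    write_tsv(cmp$table, file.path(outdir, "expression_comparison.tsv"))
  }

  # --- coverage and diversity -----------------------------------------
  coverage <- run_stage("coverage", {
    out <- lapply(samples, function(s) {
      cnt <- cm$counts[, s]
      umq <- select_upper_middle_quartile(cnt)
      gene_body_coverage(read_list[[s]], metas, umq, assignments[[s]],
                         sample_id = s)
    })
    names(out) <- samples
    out
  })
  cov_df <- do.call(rbind, lapply(coverage, function(cp) {
    data.frame(sample_id = cp$sample_id, bin = seq_len(cp$n_bins),
               fraction = cp$fractions, stringsAsFactors = FALSE)
  }))
  write_tsv(cov_df, file.path(outdir, "coverage.tsv"))

  diversity <- run_stage("diversity", {
    out <- lapply(samples, function(s) {
      cumulative_gene_diversity(cm$counts[, s], sample_id = s)
    })
    names(out) <- samples
    out
  })
  div_df <- do.call(rbind, lapply(diversity, function(d) {
    data.frame(sample_id = d$sample_id, rank = d$ranks,
               fraction = unname(d$fractions), stringsAsFactors = FALSE)
  }))
  write_tsv(div_df, file.path(outdir, "diversity.tsv"))

  # --- degradation bias ------------------------------------------------
  bias <- NULL
  if (!is.null(treated)) {
    bias_genes <- de_genes %||% rownames(fp)[keep]
    bias_genes <- bias_genes[bias_genes %in% names(metas)]
    bias <- run_stage("bias", degradation_bias(
      read_list, glab, metas, genes = bias_genes,
      assignments = assignments, control = control, treated = treated,
      alpha = config$alpha_bias))
    write_tsv(bias$results, file.path(outdir, "bias.tsv"))
    bin_df <- do.call(rbind, lapply(names(bias$bin_tables), function(g) {
      bt <- bias$bin_tables[[g]]
      if (is.null(bt)) return(NULL)
      cbind(gene_id = g, bt)
    }))
    if (!is.null(bin_df)) write_tsv(bin_df, file.path(outdir, "bias_bins.tsv"))
  }

  # --- enrichment ------------------------------------------------------
  features <- enrich <- overlap <- NULL
  if (!is.null(config$fasta)) {
    features <- run_stage("features", feature_table(models, config$fasta))
    write_tsv(features, file.path(outdir, "features.tsv"))
    if (!is.null(de_genes)) {
      enrich <- tryCatch(
        compare_features(features, de_genes),
        error = function(e) NULL)
      if (!is.null(enrich)) {
        write_tsv(enrich, file.path(outdir, "feature_comparison.tsv"))
      }
    }
  }
  if (!is.null(config$are_table) && !is.null(de_genes) && !is.null(bias)) {
    overlap <- run_stage("are_overlap", are_overlap(
      de_genes, read_are_table(config$are_table), bias))
    write_json_stable(as.list(overlap$counts),
                      file.path(outdir, "are_overlap.json"))
  }

  # --- qPCR ------------------------------------------------------------
  qpcr <- NULL
  if (!is.null(config$cp_table)) {
    qpcr <- run_stage("qpcr", {
      tab <- read_cp_table(config$cp_table)
      expr <- qpcr_expression(tab)
      write_tsv(expr, file.path(outdir, "qpcr_expression.tsv"))
      expr
    })
  }

  summary <- list(
    seed = config$seed,
    n_samples = length(samples),
    groups = as.list(table(unname(glab))),
    genes_annotated = length(models),
    genes_expressed = sum(keep),
    metrics = lapply(metrics, function(m) {
      list(sample_id = m$sample_id, unique_fraction = m$unique_fraction,
           duplication_rate = m$duplication_rate,
           detected_genes = m$detected_genes)
    }),
    r_squared = if (!is.null(cmp)) cmp$r_squared else NULL,
    median_de_fold = if (!is.null(cmp) && !is.null(cmp$de)) {
      cmp$de$median_fold
    } else NULL,
    bias_classes = if (!is.null(bias)) {
      as.list(table(bias$results$class))
    } else NULL,
    mismatch_significant = if (!is.null(mm_cmp)) {
      sum(mm_cmp$significant)
    } else NULL,
    are_overlap = if (!is.null(overlap)) as.list(overlap$counts) else NULL
  )
  write_json_stable(summary, file.path(outdir, "summary.json"))

  out <- list(config = config, metrics = metrics, deviations = dev,
              mismatch_comparison = mm_cmp, counts = cm$counts, fpkm = fp,
              expressed = keep, comparison = cmp, coverage = coverage,
              diversity = diversity, bias = bias, features = features,
              feature_comparison = enrich, overlap = overlap, qpcr = qpcr,
              summary = summary)
  class(out) <- "dryqc_report"
  invisible(out)
}

#' @export
print.dryqc_report <- function(x, ...) {
  cat(sprintf("dryqc_report: %d samples, %d genes (%d expressed)\n",
              x$summary$n_samples, x$summary$genes_annotated,
              x$summary$genes_expressed))
  if (!is.null(x$summary$r_squared)) {
    cat(sprintf("  R^2(log2 group means) = %.4f\n", x$summary$r_squared))
  }
  if (!is.null(x$bias)) print(x$bias)
  invisible(x)
}
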
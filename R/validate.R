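# Simulation study designs and the property-validation suite.
#
# Each scenario fixes the generative conditions used to validate one
# aspect of the pipeline; the eval_* functions run the full honest path
# (simulate -> SAM -> parse -> analyse) and return the measured quantity.

#' Null scenario: no degradation, equal expression
#'
#' Protein-coding genes only, equal expression, no decay or cleavage in
#' either group; used to measure the bias classifier's type-I error.
#'
#' @param n_genes Number of genes.
#' @param reads_per_gene Mean reads per gene per sample.
#' @param n_per_group Replicates per group.
#' @param seed Master seed.
#' @return A [sim_config()].
#' @export
scenario_null <- function(n_genes = 400L, reads_per_gene = 100L,
                          n_per_group = 3L, seed = 1L) {
  sim_config(
    seed = seed, n_genes = n_genes,
    biotype_mix = c(protein_coding = 1),
    theta_sdlog = 0,
    depth = n_genes * reads_per_gene,
    groups = list(
      control = list(n = n_per_group, p = 0, lambda = 0),
      treated = list(n = n_per_group, p = 0, lambda = 0)
    )
  )
}

#' Cleavage scenario: one expected cut per molecule in the treated group
#'
#' @param n_genes,reads_per_gene,n_per_group,seed As in [scenario_null()].
#' @param expected_cuts Expected cleavage events per molecule (treated).
#' @return A [sim_config()].
#' @export
scenario_cleavage <- function(n_genes = 100L, reads_per_gene = 200L,
                              n_per_group = 3L, expected_cuts = 1,
                              seed = 1L) {
  sim_config(
    seed = seed, n_genes = n_genes,
    biotype_mix = c(protein_coding = 1),
    theta_sdlog = 0,
    depth = n_genes * reads_per_gene,
    groups = list(
      control = list(n = n_per_group, p = 0, lambda = 0),
      treated = list(n = n_per_group, p = 0, expected_cuts = expected_cuts)
    )
  )
}

#' Uniform-decay scenario: half the genes lose half their molecules
#'
#' `n_decayed` genes carry uniform decay probability `p` in the treated
#' group; an equal number of stable genes of equal expression make up the
#' rest of the library. With a fixed per-sample depth the expected FPKM
#' fold (control/treated) of a decayed gene is `2 - D/T` where `D/T` is
#' the decayed share of library mass (1.5 in this design).
#'
#' @param n_decayed,n_stable Gene counts.
#' @param p Decay probability in the treated group.
#' @param reads_per_gene,n_per_group,seed As in [scenario_null()].
#' @return List: `config` and `decayed_genes` (ids carrying decay).
#' @export
scenario_decay <- function(n_decayed = 50L, n_stable = 50L, p = 0.5,
                           reads_per_gene = 200L, n_per_group = 3L,
                           seed = 1L) {
  n <- n_decayed + n_stable
  p_vec <- c(rep(p, n_decayed), rep(0, n_stable))
  cfg <- sim_config(
    seed = seed, n_genes = n,
    biotype_mix = c(protein_coding = 1),
    theta_sdlog = 0,
    depth = n * reads_per_gene,
    groups = list(
      control = list(n = n_per_group, p = 0, lambda = 0),
      treated = list(n = n_per_group, p = p_vec, lambda = 0)
    )
  )
  list(config = cfg, decayed_genes = sprintf("G%04d", seq_len(n_decayed)))
}

#' Flat-coverage scenario: long genes, no degradation
#'
#' Meta-transcripts of ~30 kb so the 75-nt read footprint is small against
#' the 2.5% bin width (~750 nt), making all 40 bins reachable by 5'-end
#' binning; used to verify coverage flatness under uniform placement.
#'
#' @param n_genes Number of genes.
#' @param depth Reads in the single simulated sample.
#' @param seed Master seed.
#' @return A [sim_config()].
#' @export
scenario_flat_coverage <- function(n_genes = 120L, depth = 450000,
                                   seed = 1L) {
  sim_config(
    seed = seed, n_genes = n_genes,
    biotype_mix = c(protein_coding = 1),
    exon_count_range = c(10L, 10L),
    exon_len_mean = 3000,
    theta_sdlog = 0,
    depth = depth,
    groups = list(control = list(n = 1L, p = 0, lambda = 0))
  )
}

#' Mismatch-excess scenario
#'
#' Adds a substitution excess (default C>T, +0.02) at the first ten read
#' cycles in the treated group on top of a uniform 1e-3 error floor.
#'
#' @param n_genes,reads_per_sample,n_per_group,seed Scenario size.
#' @param type Substitution type.
#' @param positions Read cycles carrying the excess.
#' @param delta Added rate.
#' @return A [sim_config()].
#' @export
scenario_mismatch_shift <- function(n_genes = 40L, reads_per_sample = 1e5,
                                    n_per_group = 3L, type = "C>T",
                                    positions = 1:10, delta = 0.02,
                                    seed = 1L) {
  sim_config(
    seed = seed, n_genes = n_genes,
    biotype_mix = c(protein_coding = 1),
    theta_sdlog = 0,
    depth = reads_per_sample,
    groups = list(
      control = list(n = n_per_group, p = 0, lambda = 0),
      treated = list(n = n_per_group, p = 0, lambda = 0,
                     mismatch_extra = list(type = type,
                                           positions = positions,
                                           delta = delta))
    )
  )
}

# Shared harness: simulate an experiment and parse everything back
# through the SAM path.
run_sim_analysis <- function(config, outdir = tempfile("simexp")) {
  exp <- simulate_experiment(config, outdir)
  read_list <- lapply(stats::setNames(exp$manifest$sam,
                                      exp$manifest$sample_id), read_sam)
  models <- read_gtf(exp$annotation$gtf)
  metas <- lapply(models, build_meta_transcript)
  assignments <- lapply(read_list, assign_reads, models = models)
  groups <- stats::setNames(exp$manifest$group, exp$manifest$sample_id)
  list(exp = exp, read_list = read_list, models = models, metas = metas,
       assignments = assignments, groups = groups)
}

#' Bias-classifier type-I error under the null
#'
#' @param seed Master seed.
#' @param n_genes,reads_per_gene Scenario size.
#' @return List: `fraction` of classifiable genes called non-uniform at
#'   alpha = 0.01, `n_classified`, `n_nonuniform`.
#' @export
eval_bias_type1 <- function(seed = 1L, n_genes = 400L,
                            reads_per_gene = 100L) {
  sa <- run_sim_analysis(scenario_null(n_genes, reads_per_gene, seed = seed))
  bs <- degradation_bias(sa$read_list, sa$groups, sa$metas,
                         assignments = sa$assignments)
  r <- bs$results
  classified <- r$class != "unclassifiable"
  nonuni <- r$class %in% c("five_prime_underrepresented",
                           "three_prime_underrepresented")
  list(fraction = sum(nonuni) / sum(classified),
       n_classified = sum(classified), n_nonuniform = sum(nonuni))
}

#' Bias-classifier power under treated-only cleavage
#'
#' @param seed Master seed.
#' @param n_genes,reads_per_gene Scenario size.
#' @return List: `power` (fraction five_prime), `three_prime_fraction`,
#'   `n_genes`.
#' @export
eval_bias_power <- function(seed = 1L, n_genes = 100L,
                            reads_per_gene = 200L) {
  sa <- run_sim_analysis(scenario_cleavage(n_genes, reads_per_gene,
                                           seed = seed))
  bs <- degradation_bias(sa$read_list, sa$groups, sa$metas,
                         assignments = sa$assignments)
  r <- bs$results
  list(power = mean(r$class == "five_prime_underrepresented"),
       three_prime_fraction = mean(r$class == "three_prime_underrepresented"),
       n_genes = nrow(r))
}

#' Fold recovery under uniform decay
#'
#' @param seed Master seed.
#' @param reads_per_gene Scenario size.
#' @return List: `median_fold` (control/treated over decayed genes),
#'   `nonuniform_fraction` of decayed genes flagged by the bias
#'   classifier.
#' @export
eval_fold_recovery <- function(seed = 1L, reads_per_gene = 200L) {
  sc <- scenario_decay(reads_per_gene = reads_per_gene, seed = seed)
  sa <- run_sim_analysis(sc$config)
  lengths <- vapply(sa$metas, function(m) m$L, 0)
  cm <- count_matrix(sa$read_list, sa$models, sa$assignments)
  fp <- fpkm(cm$counts, lengths)
  biotype <- vapply(sa$models, function(g) g$biotype, character(1))
  keep <- filter_expressed(fp, biotype)
  cmp <- group_comparison(fp[keep, , drop = FALSE], sa$groups,
                          "control", "treated", sc$decayed_genes)
  bs <- degradation_bias(sa$read_list, sa$groups, sa$metas,
                         genes = sc$decayed_genes,
                         assignments = sa$assignments)
  r <- bs$results
  nonuni <- mean(r$class %in% c("five_prime_underrepresented",
                                "three_prime_underrepresented"))
  list(median_fold = cmp$de$median_fold, nonuniform_fraction = nonuni)
}

#' Coverage flatness under uniform placement
#'
#' @param seed Master seed.
#' @param depth Reads in the simulated sample.
#' @return List: `min_bin`, `max_bin` fractions over the 40 bins,
#'   `n_reads` contributing.
#' @export
eval_coverage_flatness <- function(seed = 1L, depth = 450000) {
  sa <- run_sim_analysis(scenario_flat_coverage(depth = depth, seed = seed))
  s <- sa$exp$manifest$sample_id[1L]
  cnt <- count_reads(sa$read_list[[s]], sa$models, sa$assignments[[s]])$counts
  umq <- select_upper_middle_quartile(cnt)
  cp <- gene_body_coverage(sa$read_list[[s]], sa$metas, umq,
                           sa$assignments[[s]], sample_id = s)
  list(min_bin = min(cp$fractions), max_bin = max(cp$fractions),
       n_reads = cp$n_reads, fractions = cp$fractions)
}

#' Recovery of an injected mismatch excess
#'
#' @param seed Master seed.
#' @param reads_per_sample Scenario depth.
#' @return List: `n_recovered` of the 10 injected (C>T, cycle 1-10) cells
#'   significant at 5% BH FDR, `n_significant_total`.
#' @export
eval_mismatch_recovery <- function(seed = 1L, reads_per_sample = 1e5) {
  sa <- run_sim_analysis(scenario_mismatch_shift(
    reads_per_sample = reads_per_sample, seed = seed))
  profiles <- lapply(sa$read_list, mismatch_profile)
  cmp <- compare_mismatch_profiles(
    profiles[names(sa$groups)[sa$groups == "control"]],
    profiles[names(sa$groups)[sa$groups == "treated"]])
  inj <- cmp$type == "C>T" & cmp$position <= 10
  list(n_recovered = sum(cmp$significant[inj]),
       n_significant_total = sum(cmp$significant))
}

#' Null calibration of the mismatch-profile comparison
#'
#' Repetitions draw per-sample rate profiles from the binomial
#' observation model at matched depth (denominator `depth/4` opportunities
#' per cell, base rate 1e-3/3 per substitution type) with no group
#' difference, then run [compare_mismatch_profiles()].
#'
#' @param seed Master seed.
#' @param reps Number of null repetitions.
#' @param n_per_group Samples per group.
#' @param depth Reads per sample (sets the binomial denominators).
#' @param read_len Read length.
#' @return List: `n_reps_with_significant`, `reps`.
#' @export
eval_null_mismatch_fdr <- function(seed = 1L, reps = 100L,
                                   n_per_group = 3L, depth = 1e5,
                                   read_len = 75L) {
  set.seed(derive_seed(seed, 9L))
  D <- round(depth / 4)
  rate0 <- 1e-3 / 3
  ncell <- 12L * read_len
  hits <- 0L
  for (r in seq_len(reps)) {
    mk <- function() {
      p <- list(rate = matrix(stats::rbinom(ncell, D, rate0) / D,
                              nrow = 12L,
                              dimnames = list(mismatch_types(), NULL)),
                read_len = read_len)
      class(p) <- "mismatch_profile"
      p
    }
    pa <- replicate(n_per_group, mk(), simplify = FALSE)
    pb <- replicate(n_per_group, mk(), simplify = FALSE)
    cmp <- compare_mismatch_profiles(pa, pb)
    if (any(cmp$significant)) hits <- hits + 1L
  }
  list(n_reps_with_significant = hits, reps = reps)
}

#' Run the property-validation suite
#'
#' Evaluates the simulator-backed properties (classifier type-I error and
#' power, fold recovery, coverage flatness, mismatch recovery and null
#' FDR, end-to-end determinism) at the standard or a reduced scale and
#' reports observed values against their bounds.
#'
#' @param seed Master seed.
#' @param scale `1` for the standard problem sizes, `< 1` to shrink the
#'   simulations proportionally (bounds on stochastic properties widen by
#'   `1/sqrt(scale)` around their targets).
#' @return `data.frame`: property, observed, bound, pass.
#' @export
validate_pipeline <- function(seed = 1L, scale = 1) {
  stopifnot(scale > 0, scale <= 1)
  w <- 1 / sqrt(scale)
  rows <- list()
  add <- function(property, observed, bound, pass) {
    rows[[length(rows) + 1L]] <<- data.frame(
      property = property, observed = observed, bound = bound, pass = pass,
      stringsAsFactors = FALSE)
  }

  t1 <- eval_bias_type1(seed, n_genes = max(40L, round(400 * scale)))
  add("bias_type1_fraction", t1$fraction,
      sprintf("[%.4f, %.4f]", 0.002 / w, min(0.025 * w, 1)),
      t1$fraction >= 0.002 / w && t1$fraction <= 0.025 * w)

  pw <- eval_bias_power(seed, n_genes = max(20L, round(100 * scale)))
  add("bias_power_five_prime", pw$power, ">= 0.80", pw$power >= 0.80)
  add("bias_power_three_prime_false", pw$three_prime_fraction,
      "<= 0.01 rate", pw$three_prime_fraction <= max(0.01 * w, 1 / pw$n_genes))

  fr <- eval_fold_recovery(seed)
  add("decay_median_fold", fr$median_fold, "[1.35, 1.65]",
      fr$median_fold >= 1.35 && fr$median_fold <= 1.65)
  add("decay_nonuniform_fraction", fr$nonuniform_fraction, "<= 0.10",
      fr$nonuniform_fraction <= 0.10)

  cf <- eval_coverage_flatness(seed, depth = max(2e4, round(450000 * scale)))
  add("coverage_min_bin", cf$min_bin, ">= 0.020", cf$min_bin >= 0.020 / w)
  add("coverage_max_bin", cf$max_bin, "<= 0.030", cf$max_bin <= 0.030 * w)

  mr <- eval_mismatch_recovery(seed,
                               reads_per_sample = max(1e4, 1e5 * scale))
  add("mismatch_recovered_positions", mr$n_recovered, ">= 8",
      mr$n_recovered >= 8)

  nf <- eval_null_mismatch_fdr(seed, reps = max(20L, round(100 * scale)))
  add("mismatch_null_reps_with_hit", nf$n_reps_with_significant,
      sprintf("<= %d", ceiling(0.10 * nf$reps)),
      nf$n_reps_with_significant <= ceiling(0.10 * nf$reps))

  det <- eval_determinism(seed)
  add("determinism_identical_runs", as.numeric(det), "== 1", isTRUE(det))

  do.call(rbind, rows)
}

#' End-to-end determinism check
#'
#' Simulates a small fixed-seed experiment twice and runs the full
#' pipeline on each copy; returns TRUE iff every output file is
#' byte-identical between the two runs.
#'
#' @param seed Master seed.
#' @return Logical.
#' @export
eval_determinism <- function(seed = 1L) {
  cfg <- sim_config(seed = seed, n_genes = 30L, depth = 5000,
                    theta_sdlog = 0.5)
  run_once <- function(d) {
    exp <- simulate_experiment(cfg, file.path(d, "sim"))
    rc <- run_config(
      sam = stats::setNames(exp$manifest$sam, exp$manifest$sample_id),
      groups = stats::setNames(exp$manifest$group, exp$manifest$sample_id),
      gtf = exp$annotation$gtf, fasta = exp$annotation$fasta,
      outdir = file.path(d, "out"), seed = seed)
    run_pipeline(rc)
    file.path(d, "out")
  }
  d1 <- run_once(tempfile("det1"))
  d2 <- run_once(tempfile("det2"))
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  if (!identical(f1, f2)) return(FALSE)
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f2)))
  identical(h1, h2)
}
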
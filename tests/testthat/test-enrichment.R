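# Mann-Whitney machinery, feature comparisons and ARE overlap counts.

test_that("exact Mann-Whitney matches the spec example and symmetry", {
  mw <- mann_whitney(c(5, 6, 7), c(1, 2, 3))
  expect_equal(mw$U, 9)
  expect_equal(mw$p_value, 0.1)
  expect_true(mw$exact)

  # identical multisets: P = 1 (approximate path due to ties)
  mw2 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_false(mw2$exact)
  expect_gt(mw2$p_value, 0.99)

  # strongly shifted groups at n = 20 per side
  set.seed(3)
  a <- rnorm(20) + 100; b <- rnorm(20)
  expect_lt(mann_whitney(a, b)$p_value, 1e-6)

  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("exact P equals the full-enumeration oracle for n1+n2 <= 10", {
  set.seed(17)
  for (n1 in 1:5) {
    for (n2 in n1:(10 - n1)) {
      vals <- sample(seq_len(100), n1 + n2)   # distinct -> no ties
      a <- vals[seq_len(n1)]
      b <- vals[-seq_len(n1)]
      got <- mann_whitney(a, b)
      oracle <- mw_enumeration_oracle(a, b)
      expect_equal(got$U, oracle$U)
      expect_equal(got$p_value, oracle$p_value, tolerance = 1e-12)
    }
  }
})

test_that("feature comparison finds constructed length enrichment", {
  set.seed(29)
  n <- 120
  features <- data.frame(
    gene_id = sprintf("g%03d", 1:n),
    biotype = "lncRNA",
    transcript_length = rlnorm(n, 7, 0.6),
    transcript_gc = rpois(n, 400),
    transcript_gc_pct = runif(n, 30, 60),
    stringsAsFactors = FALSE
  )
  longest <- features$gene_id[order(-features$transcript_length)][1:15]
  cmp <- compare_features(features, longest)
  len_row <- cmp[cmp$feature == "transcript_length", ]
  expect_lt(len_row$p_value, 1e-4)
  expect_equal(len_row$p_value, min(cmp$p_value))
  expect_gt(len_row$median_de, len_row$median_background)
})

test_that("null draws give approximately uniform feature P values", {
  set.seed(41)
  n <- 100
  features <- data.frame(
    gene_id = sprintf("g%03d", 1:n),
    biotype = "lncRNA",
    transcript_length = rlnorm(n, 7, 0.5),
    transcript_gc = rnorm(n, 400, 40),
    transcript_gc_pct = runif(n, 30, 60),
    stringsAsFactors = FALSE
  )
  ps <- replicate(200, {
    de <- sample(features$gene_id, 12)
    cmp <- compare_features(features, de)
    cmp$p_value[cmp$feature == "transcript_length"]
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("absent features are excluded, not treated as zero", {
  features <- data.frame(
    gene_id = sprintf("g%02d", 1:20),
    biotype = "protein_coding",
    cdna_length = rlnorm(20, 7, 0.3),
    cdna_gc = rpois(20, 500),
    cdna_gc_pct = runif(20, 35, 55),
    cds_length = rlnorm(20, 6.5, 0.3),
    cds_gc_pct = runif(20, 35, 55),
    utr5_gc_pct = runif(20, 35, 55),
    utr3_gc_pct = c(rep(NA, 4), runif(16, 35, 55)),
    stringsAsFactors = FALSE
  )
  cmp <- compare_features(features, features$gene_id[1:8])
  u3 <- cmp[cmp$feature == "utr3_gc_pct", ]
  expect_equal(u3$n_de + u3$n_background,
               (8 - 4) + (20 - 4))  # 4 NA genes dropped from both sides
  expect_gt(u3$n_excluded_na, 0)
})

test_that("overlap counts partition the DE set", {
  are <- data.frame(gene_id = c("g1", "g2"),
                    are_3utr = c(1, 0), are_intron = c(0, 1))
  bias <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    class = c("uniform", "five_prime_underrepresented",
              "three_prime_underrepresented", "uniform"),
    stringsAsFactors = FALSE
  )
  ov <- are_overlap(c("g1", "g2", "g3", "g4"), are, bias)
  expect_equal(unname(ov$counts["are_only"]), 1)   # g1
  expect_equal(unname(ov$counts["both"]), 1)       # g2 (intronic ARE counts)
  expect_equal(unname(ov$counts["bias_only"]), 1)  # g3
  expect_equal(unname(ov$counts["neither"]), 1)    # g4
  expect_equal(sum(ov$counts), 4)

  # empty ARE table: everything in bias-only / neither
  empty <- data.frame(gene_id = character(0), are_3utr = numeric(0),
                      are_intron = numeric(0))
  ov2 <- are_overlap(c("g1", "g3"), empty, bias)
  expect_equal(unname(ov2$counts["are_only"] + ov2$counts["both"]), 0)
  expect_equal(sum(ov2$counts), 2)
})

test_that("disjoint decay mechanisms give near-empty 'both' cell", {
  # construction from simulator truth: decayed genes are labelled ARE,
  # cleaved genes are not; bias should hit (mostly) the cleaved ones
  cfg <- sim_config(
    seed = 77L, n_genes = 30L, depth = 24000,
    biotype_mix = c(protein_coding = 1), theta_sdlog = 0,
    groups = list(
      control = list(n = 2L, p = 0, lambda = 0),
      treated = list(n = 2L, p = c(rep(0.5, 15), rep(0, 15)),
                     expected_cuts = c(rep(0, 15), rep(1.2, 15)))
    ))
  exp <- simulate_experiment(cfg, tempfile())
  rl <- lapply(stats::setNames(exp$manifest$sam, exp$manifest$sample_id),
               read_sam)
  models <- read_gtf(exp$annotation$gtf)
  metas <- lapply(models, build_meta_transcript)
  bs <- degradation_bias(rl, stats::setNames(exp$manifest$group,
                                             exp$manifest$sample_id),
                         metas, models = models)
  are <- data.frame(gene_id = sprintf("G%04d", 1:15),
                    are_3utr = 1, are_intron = 0)
  ov <- are_overlap(sprintf("G%04d", 1:30), are, bs)
  expect_lte(unname(ov$counts["both"]), 2)
  expect_gt(unname(ov$counts["bias_only"]), 5)
})
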
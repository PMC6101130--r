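# The degraded-library simulator: determinism, conservation and the
# mechanism contracts, checked against its own truth tables.

test_that("annotation generation is deterministic and honours the mix", {
  cfg <- sim_config(seed = 5L, n_genes = 100L,
                    biotype_mix = c(protein_coding = 0.9, snoRNA = 0.1))
  d1 <- tempfile(); d2 <- tempfile()
  a1 <- generate_annotation(cfg, d1)
  a2 <- generate_annotation(cfg, d2)
  expect_identical(readLines(a1$gtf), readLines(a2$gtf))
  expect_identical(readLines(a1$fasta), readLines(a2$fasta))

  bts <- vapply(a1$models, function(g) g$biotype, character(1))
  n_sno <- sum(bts == "snoRNA")
  # 10% of 100 within 3 binomial SE
  expect_lt(abs(n_sno - 10), 3 * sqrt(100 * 0.1 * 0.9) + 1)
  # both strands and >= 2 chromosomes represented
  expect_setequal(unique(vapply(a1$models, function(g) g$strand,
                                character(1))), c("+", "-"))
  expect_gte(length(unique(vapply(a1$models, function(g) g$chrom,
                                  character(1)))), 2L)
})

test_that("zero genes yield a valid empty annotation", {
  cfg <- sim_config(seed = 1L, n_genes = 0L)
  d <- tempfile()
  ann <- generate_annotation(cfg, d)
  expect_length(ann$models, 0)
  expect_length(read_gtf(ann$gtf), 0)
  expect_gt(sum(Biostrings::width(ann$genome)), 0)
})

test_that("a fixed chromosome length too small for the genes errors", {
  cfg <- sim_config(seed = 1L, n_genes = 50L, chrom_len = 5000L)
  expect_error(generate_annotation(cfg), "too small")
})

test_that("libraries are byte-identical across runs and conserve depth", {
  sa <- shared_sim()
  lib1 <- sa$exp$libraries[[1]]
  ann2 <- generate_annotation(sa$exp$annotation$config, tempfile())
  lib2 <- simulate_library(ann2, lib1$group, 1L, tempfile())
  expect_identical(readLines(lib1$sam), readLines(lib2$sam))

  cfg <- sa$exp$annotation$config
  for (lib in sa$exp$libraries) {
    tr <- lib$reads
    expect_equal(nrow(tr), cfg$depth)
    n_dup <- sum(tr$duplicate == 1)
    expect_equal(n_dup, round(cfg$depth * cfg$dup_rate))
    # every duplicate has an identical-alignment original
    dup_src <- sub("\\.d[0-9]+$", "", tr$read_id[tr$duplicate == 1])
    expect_true(all(dup_src %in% tr$read_id[tr$duplicate == 0]))
  }
})

test_that("full decay of one gene removes all of its reads", {
  cfg <- sim_config(
    seed = 3L, n_genes = 10L, depth = 3000,
    biotype_mix = c(protein_coding = 1), theta_sdlog = 0,
    groups = list(treated = list(n = 1L, p = c(1, rep(0, 9)), lambda = 0))
  )
  exp <- simulate_experiment(cfg, tempfile())
  tr <- exp$libraries[[1]]$genes
  expect_equal(tr$reads[tr$gene_id == "G0001"], 0)
  expect_gt(sum(tr$reads), 0)
})

test_that("without degradation read 5' ends are uniform (KS oracle)", {
  cfg <- sim_config(seed = 9L, n_genes = 4L, depth = 6000,
                    biotype_mix = c(protein_coding = 1), theta_sdlog = 0,
                    groups = list(control = list(n = 1L, p = 0, lambda = 0)))
  exp <- simulate_experiment(cfg, tempfile())
  lib <- exp$libraries[[1]]
  metas <- exp$annotation$metas
  rl <- cfg$read_len
  tr <- lib$reads[lib$reads$duplicate == 0, ]
  for (g in unique(tr$gene_id)) {
    m <- tr$meta5[tr$gene_id == g]
    if (length(m) < 500) next
    L <- metas[[g]]$L
    ks <- suppressWarnings(
      stats::ks.test(m + stats::runif(length(m)), "punif", 0, L - rl + 1))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("cleavage shifts 5' ends 3'-ward (one-sided rank test on truth)", {
  base <- list(n_genes = 4L, depth = 8000,
               biotype_mix = c(protein_coding = 1), theta_sdlog = 0)
  cfg0 <- do.call(sim_config, c(base, list(
    seed = 13L,
    groups = list(g = list(n = 1L, p = 0, lambda = 0)))))
  cfg1 <- do.call(sim_config, c(base, list(
    seed = 13L,
    groups = list(g = list(n = 1L, p = 0, expected_cuts = 1)))))
  e0 <- simulate_experiment(cfg0, tempfile())
  e1 <- simulate_experiment(cfg1, tempfile())
  t0 <- e0$libraries[[1]]$reads
  t1 <- e1$libraries[[1]]$reads
  for (g in intersect(unique(t0$gene_id), unique(t1$gene_id))) {
    m0 <- t0$meta5[t0$gene_id == g]
    m1 <- t1$meta5[t1$gene_id == g]
    if (min(length(m0), length(m1)) < 500) next
    wt <- stats::wilcox.test(m1, m0, alternative = "greater", exact = FALSE)
    expect_lt(wt$p.value, 0.01)
  }
})

test_that("injected positional mismatch rates are recovered from truth", {
  eps <- uniform_mismatch_rates(75L, base_rate = 0)
  eps["C>T", 1:10] <- 0.01
  cfg <- sim_config(seed = 21L, n_genes = 10L, depth = 30000,
                    biotype_mix = c(protein_coding = 1), theta_sdlog = 0,
                    dup_rate = 0, mismatch_rates = eps,
                    groups = list(g = list(n = 1L, p = 0, lambda = 0)))
  exp <- simulate_experiment(cfg, tempfile())
  lib <- exp$libraries[[1]]
  mm <- lib$mismatches
  expect_true(all(mm$ref == "C" & mm$alt == "T"))
  expect_true(all(mm$cycle <= 10))

  # per-cycle C>T rate vs per-cycle C opportunities, from the genome
  metas <- exp$annotation$metas
  genome <- exp$annotation$genome
  tr <- lib$reads
  n_c <- numeric(10)
  for (g in unique(tr$gene_id)) {
    txseq <- as.character(dryqc:::meta_sequence(metas[[g]], genome))
    m <- tr$meta5[tr$gene_id == g]
    for (p in 1:10) {
      n_c[p] <- n_c[p] + sum(substring(txseq, m + p, m + p) == "C")
    }
  }
  for (p in 1:10) {
    obs <- sum(mm$cycle == p) / n_c[p]
    se <- sqrt(0.01 * 0.99 / n_c[p])
    expect_lt(abs(obs - 0.01), 3 * se)
  }
})

test_that("emitted SAM agrees with reference bases (external tag check)", {
  sa <- shared_sim()
  lib <- sa$exp$libraries[[1]]
  fa <- sa$exp$annotation$fasta
  # recompute MD/NM from the genome with samtools and compare byte-for-byte
  out <- system2("samtools", c("calmd", lib$sam, fa), stdout = TRUE,
                 stderr = FALSE)
  out <- out[!grepl("^@", out)]
  orig <- readLines(lib$sam); orig <- orig[!grepl("^@", orig)]
  get_tag <- function(x, tag) sub(paste0(".*\t", tag, ":([^\t]+).*"), "\\1", x)
  expect_identical(get_tag(orig, "MD:Z"), get_tag(out, "MD:Z"))
  expect_identical(get_tag(orig, "NM:i"), get_tag(out, "NM:i"))
})
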
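# Library metrics, outlier rule, mismatch profiling and group comparison.

test_that("library metrics: duplication, chromosomes, GC binning", {
  sq <- c(chr1 = 2000L)
  mk <- function(qname, flag, seq) {
    sprintf("%s\t%d\tchr1\t%d\t50\t%dM\t*\t0\t0\t%s\t%s\tNH:i:1",
            qname, flag, 100 + 10 * seq_along(qname), nchar(seq), seq,
            strrep("I", nchar(seq)))
  }
  seqs <- rep(c("ACGTACGTAC"), 10)
  flags <- c(rep(0L, 6), rep(1024L, 4))
  recs <- vapply(seq_len(10), function(i) {
    sprintf("r%d\t%d\tchr1\t%d\t50\t10M\t*\t0\t0\t%s\tIIIIIIIIII\tNH:i:1",
            i, flags[i], 100 + 10 * i, seqs[i])
  }, character(1))
  r <- read_sam(write_test_sam(recs, sq))
  m <- library_metrics(r, "s1")
  expect_equal(m$duplication_rate, 0.4)
  expect_equal(m$unique_fraction, 1)
  expect_equal(unname(m$chromosome_fractions["chr1"]), 1.0)
  # "ACGTACGTAC" is 50% GC -> bin 50
  expect_equal(sum(m$gc_histogram), 10)
  expect_equal(unname(m$gc_histogram["50"]), 10)
})

test_that("GC histogram puts a 40% GC read in the 40% bin", {
  seq75 <- paste0(strrep("G", 15), strrep("C", 15), strrep("A", 45))
  sam <- write_test_sam(sprintf(
    "r1\t0\tchr1\t100\t50\t75M\t*\t0\t0\t%s\t%s\tNH:i:1", seq75,
    strrep("I", 75)))
  m <- library_metrics(read_sam(sam), "s")
  expect_equal(unname(m$gc_histogram["40"]), 1)
})

test_that("deviation from median flags the 30% boundary as an outlier", {
  d <- deviation_from_median(c(10, 10, 13))
  expect_equal(unname(d$deviation), c(0, 0, 0.30))
  expect_equal(unname(d$outlier), c(FALSE, FALSE, TRUE))

  d2 <- deviation_from_median(c(5, 5, 5, 5))
  expect_true(all(d2$deviation == 0))
  expect_false(any(d2$outlier))

  # the duplication-rate deviation range reported for the real libraries
  d3 <- deviation_from_median(c(8.64, 10, 10.67))
  expect_equal(unname(round(d3$deviation, 3)), c(-0.136, 0, 0.067))
  expect_false(any(d3$outlier))
})

test_that("deviation handles zero medians and too few samples", {
  expect_error(deviation_from_median(c(1, 2)), ">= 3")
  expect_warning(d <- deviation_from_median(cbind(a = c(0, 0, 0),
                                                  b = c(1, 1, 2))),
                 "zero")
  expect_true(all(is.na(d$deviation[, "a"])))
})

test_that("mismatch rates are counts over base-specific opportunities", {
  # 10 reads, all "C" x 10; one read has C>G at cycle 2
  seqs <- c(paste0("C", "G", strrep("C", 8)), rep(strrep("C", 10), 9))
  mds <- c("1C8", rep("10", 9))
  nms <- c(1L, rep(0L, 9))
  recs <- vapply(seq_len(10), function(i) {
    sprintf("r%d\t0\tchr1\t%d\t50\t10M\t*\t0\t0\t%s\tIIIIIIIIII\tNH:i:1\tNM:i:%d\tMD:Z:%s",
            i, 100 + 20 * i, seqs[i], nms[i], mds[i])
  }, character(1))
  r <- read_sam(write_test_sam(recs))
  prof <- mismatch_profile(r)
  expect_equal(unname(prof$rate["C>G", 2]), 0.1)
  expect_equal(unname(prof$denominator["C>G", 2]), 10)   # opportunity = ref C
  expect_equal(sum(prof$count) , 1)
  expect_true(all(prof$rate[, -2] == 0))
})

test_that("a profile with no mismatches is all zero", {
  sa <- shared_sim()
  r <- sa$read_list[[1]]
  # wipe mismatch evidence
  r$md <- as.character(r$width)
  r$nm <- rep(0L, length(r$nm))
  prof <- mismatch_profile(r)
  expect_true(all(prof$rate == 0))
})

test_that("profile recovery: simulator-injected uniform G>A excess", {
  eps <- uniform_mismatch_rates(75L, base_rate = 0)
  eps["G>A", ] <- 0.02
  cfg <- sim_config(seed = 31L, n_genes = 8L, depth = 20000,
                    biotype_mix = c(protein_coding = 1), theta_sdlog = 0,
                    dup_rate = 0, mismatch_rates = eps,
                    groups = list(g = list(n = 1L, p = 0, lambda = 0)))
  exp <- simulate_experiment(cfg, tempfile())
  r <- read_sam(exp$libraries[[1]]$sam)
  prof <- mismatch_profile(r)
  for (p in seq(1, 75, by = 7)) {
    D <- prof$denominator["G>A", p]
    se <- sqrt(0.02 * 0.98 / D)
    expect_lt(abs(prof$rate["G>A", p] - 0.02), 3 * se + 1e-12)
  }
  # invariant: rates unchanged under read order permutation
  perm <- sample(length(r$qname))
  r2 <- r
  for (f in c("qname", "chrom", "strand", "pos", "end", "cigar", "width",
              "seq", "mapq", "dup", "unique", "md", "nm")) {
    r2[[f]] <- r[[f]][perm]
  }
  r2$blocks <- r$blocks[perm]
  expect_equal(mismatch_profile(r2)$rate, prof$rate)
})

test_that("identical groups yield no significant mismatch cells", {
  sa <- shared_sim()
  profs <- lapply(sa$read_list[1:2], mismatch_profile)
  cmp <- compare_mismatch_profiles(profs, profs)
  expect_false(any(cmp$significant))
  expect_true(all(cmp$p_value[cmp$mean_a == cmp$mean_b &
                                cmp$mean_a == 0] == 1))
  expect_equal(nrow(cmp), 12 * 75)
})

test_that("biotype fractions plus unassigned sum to one", {
  sa <- shared_sim()
  for (s in names(sa$read_list)[1:2]) {
    bd <- biotype_distribution(sa$read_list[[s]], sa$models,
                               sa$assignments[[s]])
    expect_equal(sum(bd$fractions), 1, tolerance = 1e-9)
    # simulator capture model: no poly(A)-free biotypes among assigned reads
    expect_false(any(names(bd$fractions) %in% polya_free_biotypes()))
  }
})

test_that("biotype shares match the simulator truth exactly", {
  sa <- shared_sim()
  s <- names(sa$read_list)[1]
  bd <- biotype_distribution(sa$read_list[[s]], sa$models,
                             sa$assignments[[s]])
  tr <- sa$exp$libraries[[s]]$reads
  bt <- vapply(sa$models, function(g) g$biotype, character(1))
  truth <- table(bt[tr$gene_id]) / nrow(tr)
  expect_equal(bd$fractions[sort(names(bd$fractions))],
               c(truth)[sort(names(truth))], tolerance = 1e-12)
})
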
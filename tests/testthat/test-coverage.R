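# Quartile selection, gene-body coverage and cumulative gene diversity.

test_that("upper-middle-quartile selection follows the percentile rule", {
  counts <- stats::setNames(1:8, paste0("g", 1:8))
  expect_setequal(select_upper_middle_quartile(counts), c("g5", "g6"))

  # all tied: everything falls on the degenerate [P50, P75) point
  tied <- stats::setNames(rep(7, 6), paste0("g", 1:6))
  expect_setequal(select_upper_middle_quartile(tied), names(tied))

  # fewer than 4 expressed genes is an error
  sparse <- stats::setNames(c(5, 0, 0, 0, 0), paste0("g", 1:5))
  expect_error(select_upper_middle_quartile(sparse), ">= 4")

  # random tables agree with the longhand oracle
  set.seed(71)
  for (i in 1:20) {
    cnt <- stats::setNames(rpois(50, 20), sprintf("g%02d", 1:50))
    expect_setequal(select_upper_middle_quartile(cnt), umq_oracle(cnt))
  }
})

test_that("coverage puts all mass in bin 1 when reads sit at the 5' end", {
  txs <- list(t1 = list(transcript_id = "t1",
                        exons = cbind(start = 1000, end = 5000), cds = NULL))
  gene <- dryqc:::new_gene_model("g1", "protein_coding", "chr1", "+", txs)
  meta <- build_meta_transcript(gene)
  r <- fake_reads("chr1", pos = rep(1001L, 20), end = rep(1075L, 20))
  asn <- list(gene_id = rep("g1", 20))
  cp <- gene_body_coverage(r, list(g1 = meta), "g1", asn)
  expect_equal(cp$fractions[1], 1)
  expect_equal(sum(cp$fractions), 1, tolerance = 1e-9)
})

test_that("coverage is strand-aware: minus-gene 5' ends at the right edge", {
  txs <- list(t1 = list(transcript_id = "t1",
                        exons = cbind(start = 1000, end = 5000), cds = NULL))
  gene <- dryqc:::new_gene_model("g1", "protein_coding", "chr1", "-", txs)
  meta <- build_meta_transcript(gene)
  # alignments at the genomic right end = transcript 5' end for minus genes
  r <- fake_reads("chr1", pos = rep(4926L, 10), end = rep(5000L, 10),
                  strand = "-")
  asn <- list(gene_id = rep("g1", 10))
  cp <- gene_body_coverage(r, list(g1 = meta), "g1", asn)
  expect_equal(cp$fractions[1], 1)
})

test_that("genes shorter than the bin count are excluded with a warning", {
  txs <- list(t1 = list(transcript_id = "t1",
                        exons = cbind(start = 0, end = 30), cds = NULL))
  short <- build_meta_transcript(
    dryqc:::new_gene_model("s", "protein_coding", "chr1", "+", txs))
  txs2 <- list(t1 = list(transcript_id = "t1",
                         exons = cbind(start = 100, end = 400), cds = NULL))
  ok <- build_meta_transcript(
    dryqc:::new_gene_model("k", "protein_coding", "chr1", "+", txs2))
  r <- fake_reads("chr1", pos = c(101L, 150L), end = c(140L, 189L))
  asn <- list(gene_id = c("k", "k"))
  expect_warning(
    cp <- gene_body_coverage(r, list(s = short, k = ok), c("s", "k"), asn),
    "excluded")
  expect_equal(cp$n_genes, 1L)
})

test_that("cleaved group shows depleted 5' bins relative to 3' bins", {
  sa <- shared_sim()
  s_t <- sa$exp$manifest$sample_id[sa$exp$manifest$group == "treated"][1]
  cnt <- count_reads(sa$read_list[[s_t]], sa$models,
                     sa$assignments[[s_t]])$counts
  umq <- select_upper_middle_quartile(cnt)
  cp <- gene_body_coverage(sa$read_list[[s_t]], sa$metas, umq,
                           sa$assignments[[s_t]], sample_id = s_t)
  expect_lt(mean(cp$fractions[1:10]), mean(cp$fractions[31:40]))
})

test_that("diversity fractions match the sort-and-sum arithmetic", {
  counts <- c(g1 = 50, g2 = 30, g3 = 20)
  dc <- cumulative_gene_diversity(counts, ranks = c(1, 2, 3, 10))
  expect_equal(unname(dc$fractions), c(0.5, 0.8, 1.0, 1.0))

  expect_error(cumulative_gene_diversity(c(a = 0, b = 0)), "zero")

  # scale invariance
  d1 <- cumulative_gene_diversity(counts * 17, ranks = c(1, 2))
  expect_equal(d1$fractions, dc$fractions[1:2])
})

test_that("diversity equals the brute-force oracle on random tables", {
  set.seed(202)
  ranks <- c(10, 100, 1000, 10000)
  for (i in 1:50) {
    n <- sample(c(50, 500, 5000, 20000), 1)
    counts <- stats::setNames(rpois(n, rexp(n, 1 / 20)),
                              sprintf("g%05d", seq_len(n)))
    if (sum(counts) == 0) next
    got <- cumulative_gene_diversity(counts, ranks)
    expect_identical(unname(got$fractions), diversity_oracle(counts, ranks))
  }
})

test_that("coverage profile is stable under 50% subsampling", {
  sa <- shared_sim()
  s <- sa$exp$manifest$sample_id[1]
  reads <- sa$read_list[[s]]
  asn <- sa$assignments[[s]]
  cnt <- count_reads(reads, sa$models, asn)$counts
  umq <- select_upper_middle_quartile(cnt)
  cp_full <- gene_body_coverage(reads, sa$metas, umq, asn)
  set.seed(7)
  half <- sort(sample(length(reads$qname), length(reads$qname) %/% 2))
  r2 <- reads
  for (f in c("qname", "chrom", "strand", "pos", "end", "cigar", "width",
              "seq", "mapq", "dup", "unique", "md", "nm")) {
    r2[[f]] <- reads[[f]][half]
  }
  r2$blocks <- reads$blocks[half]
  asn2 <- list(gene_id = asn$gene_id[half])
  cp_half <- gene_body_coverage(r2, sa$metas, umq, asn2)
  # fractions agree within a few times the subsampling noise scale
  noise <- sqrt(max(cp_full$fractions) / cp_half$n_reads)
  expect_lt(max(abs(cp_full$fractions - cp_half$fractions)), 6 * noise)
})
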
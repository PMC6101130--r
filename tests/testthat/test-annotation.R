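# Gene models, meta-transcripts, coordinate maps and transcript features.

test_that("read_gtf converts 1-based closed GTF to 0-based half-open models", {
  models <- read_gtf(tiny_gtf())
  expect_s3_class(models, "gene_models")
  expect_named(models, c("gA", "gB"))
  ex <- models$gA$transcripts[["gA.t1"]]$exons
  expect_equal(unname(ex[, 1]), c(100, 300))
  expect_equal(unname(ex[, 2]), c(200, 400))
  # poly(A)-free biotype preserved
  expect_equal(models$gB$biotype, "snoRNA")
  expect_equal(models$gB$strand, "-")
})

test_that("read_gtf handles empty files and reports malformed lines", {
  empty <- tempfile(fileext = ".gtf")
  writeLines(character(0), empty)
  expect_length(read_gtf(empty), 0)

  bad <- tempfile(fileext = ".gtf")
  writeLines(c("chr1\tsrc\texon\t1\t10\t.\t+\t.\tgene_id \"g\"; transcript_id \"t\";",
               "chr1\tbroken line"), bad)
  expect_error(read_gtf(bad), "line 2")
})

test_that("unknown biotypes map to 'other' with a warning", {
  dir <- tempfile(); dir.create(dir)
  path <- file.path(dir, "odd.gtf")
  writeLines(paste0("chr1\tt\texon\t1\t100\t.\t+\t.\t",
                    'gene_id "g1"; transcript_id "t1"; gene_biotype "weird_class";'),
             path)
  expect_warning(models <- read_gtf(path), "other")
  expect_equal(models$g1$biotype, "other")
})

test_that("meta-transcript union merges overlaps and sums lengths", {
  mk_gene <- function(exon_list, strand = "+") {
    txs <- lapply(seq_along(exon_list), function(i) {
      list(transcript_id = paste0("t", i), exons = exon_list[[i]], cds = NULL)
    })
    names(txs) <- paste0("t", seq_along(exon_list))
    dryqc:::new_gene_model("g", "protein_coding", "chr1", strand, txs)
  }
  m1 <- build_meta_transcript(mk_gene(list(
    cbind(start = 100, end = 200), cbind(start = 150, end = 300))))
  expect_equal(m1$starts, 100)
  expect_equal(m1$ends, 300)
  expect_equal(m1$L, 200)

  m2 <- build_meta_transcript(mk_gene(list(
    cbind(start = c(0, 200), end = c(100, 250)))))
  expect_equal(m2$L, 150)
  expect_length(m2$starts, 2)

  m3 <- build_meta_transcript(mk_gene(list(cbind(start = 0, end = 75))))
  expect_equal(m3$L, 75)
  expect_equal(m3$starts, 0)

  # idempotence: merging already-merged exons changes nothing
  merged <- cbind(start = m2$starts, end = m2$ends)
  m4 <- build_meta_transcript(mk_gene(list(merged)))
  expect_identical(m4$starts, m2$starts)
  expect_identical(m4$ends, m2$ends)
})

test_that("genomic_to_meta maps exonic bases and rejects the rest", {
  mk_meta <- function(starts, ends, strand) {
    txs <- list(t1 = list(transcript_id = "t1",
                          exons = cbind(start = starts, end = ends),
                          cds = NULL))
    build_meta_transcript(
      dryqc:::new_gene_model("g", "protein_coding", "chr1", strand, txs))
  }
  meta <- mk_meta(c(100, 300), c(200, 400), "+")
  expect_equal(genomic_to_meta(meta, "chr1", 305), 105)
  expect_true(is.na(genomic_to_meta(meta, "chr1", 250)))   # intron
  expect_true(is.na(genomic_to_meta(meta, "chr2", 305)))   # wrong chromosome

  meta_m <- mk_meta(100, 200, "-")
  expect_equal(genomic_to_meta(meta_m, "chr1", 199), 0)    # 5' end on minus
  expect_equal(genomic_to_meta(meta_m, "chr1", 100), 99)
})

test_that("genomic-to-meta is a strand-symmetric bijection onto [0, L)", {
  txs <- list(t1 = list(transcript_id = "t1",
                        exons = cbind(start = c(10, 120, 400),
                                      end = c(60, 200, 430)),
                        cds = NULL))
  g_plus <- dryqc:::new_gene_model("g", "lncRNA", "chr1", "+", txs)
  g_minus <- dryqc:::new_gene_model("g", "lncRNA", "chr1", "-", txs)
  mp <- build_meta_transcript(g_plus)
  mm <- build_meta_transcript(g_minus)
  exonic <- c(10:59, 120:199, 400:429)
  vp <- genomic_to_meta(mp, "chr1", exonic)
  vm <- genomic_to_meta(mm, "chr1", exonic)
  expect_setequal(vp, 0:(mp$L - 1))            # bijection
  expect_equal(vm, mp$L - 1 - vp)              # strand symmetry
  # non-exonic neighbours return NA
  expect_true(all(is.na(genomic_to_meta(mp, "chr1", c(9, 60, 119, 399, 430)))))
})

test_that("transcript features compute lengths and GC per region", {
  # gene on chr1: 5'UTR "AA", CDS "ATGTAA", 3'UTR "GGGG" laid out contiguously
  genome <- Biostrings::DNAStringSet(c(chr1 = "AAATGTAAGGGG"))
  txs <- list(t1 = list(transcript_id = "t1",
                        exons = cbind(start = 0, end = 12),
                        cds = cbind(start = 2, end = 8)))
  gene <- dryqc:::new_gene_model("g", "protein_coding", "chr1", "+", txs)
  ft <- transcript_features(gene, genome)
  expect_equal(ft$utr5_length, 2)
  expect_equal(ft$cds_length, 6)
  expect_equal(ft$utr3_length, 4)
  expect_equal(ft$cdna_length, 12)
  expect_equal(ft$utr5_length + ft$cds_length + ft$utr3_length,
               ft$cdna_length)
  # GC additivity across regions
  expect_equal(ft$utr5_gc + ft$cds_gc + ft$utr3_gc, ft$cdna_gc)

  # plain GC arithmetic: "ATGCGC" has 4 GC in 6 nt
  genome2 <- Biostrings::DNAStringSet(c(chr1 = "ATGCGC"))
  txs2 <- list(t1 = list(transcript_id = "t1",
                         exons = cbind(start = 0, end = 6), cds = NULL))
  g2 <- dryqc:::new_gene_model("g2", "lncRNA", "chr1", "+", txs2)
  ft2 <- transcript_features(g2, genome2)
  expect_equal(ft2$transcript_length, 6)
  expect_equal(ft2$transcript_gc, 4)
  expect_equal(ft2$transcript_gc_pct, 100 * 4 / 6, tolerance = 1e-12)

  # all-AT sequence: 0% GC, not NA
  genome3 <- Biostrings::DNAStringSet(c(chr1 = "ATATAT"))
  g3 <- dryqc:::new_gene_model("g3", "lncRNA", "chr1", "+", txs2)
  expect_equal(transcript_features(g3, genome3)$transcript_gc_pct, 0)
})

test_that("missing chromosome sequence raises a named error", {
  genome <- Biostrings::DNAStringSet(c(chrX = "ACGT"))
  txs <- list(t1 = list(transcript_id = "t1",
                        exons = cbind(start = 0, end = 4), cds = NULL))
  gene <- dryqc:::new_gene_model("g", "lncRNA", "chr1", "+", txs)
  expect_error(transcript_features(gene, genome), "chr1")
})

test_that("longest transcript wins, ties broken by id", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 100)))
  txs <- list(
    tB = list(transcript_id = "tB", exons = cbind(start = 0, end = 100),
              cds = NULL),
    tA = list(transcript_id = "tA", exons = cbind(start = 0, end = 100),
              cds = NULL),
    tS = list(transcript_id = "tS", exons = cbind(start = 0, end = 50),
              cds = NULL)
  )
  gene <- dryqc:::new_gene_model("g", "lncRNA", "chr1", "+", txs)
  expect_equal(transcript_features(gene, genome)$transcript_id, "tA")
})
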
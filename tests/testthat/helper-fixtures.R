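# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# A small mixed-biotype experiment with mild treated-group cleavage,
# shared by the SAM/QC/expression tests.
shared_sim <- function() {
  memo("shared_sim", function() {
    cfg <- sim_config(
      seed = 42L, n_genes = 25L, depth = 5000, theta_sdlog = 0.6,
      groups = list(
        control = list(n = 2L, p = 0, lambda = 0),
        treated = list(n = 2L, p = 0.2, expected_cuts = 0.5)
      )
    )
    dir <- tempfile("shared_sim")
    exp <- simulate_experiment(cfg, dir)
    read_list <- lapply(stats::setNames(exp$manifest$sam,
                                        exp$manifest$sample_id), read_sam)
    models <- read_gtf(exp$annotation$gtf)
    metas <- lapply(models, build_meta_transcript)
    assignments <- lapply(read_list, assign_reads, models = models)
    list(exp = exp, read_list = read_list, models = models, metas = metas,
         assignments = assignments,
         groups = stats::setNames(exp$manifest$group,
                                  exp$manifest$sample_id))
  })
}

# Hand-written two-gene GTF (1-based closed coordinates).
tiny_gtf <- function(dir = tempfile("gtf")) {
  dir.create(dir, showWarnings = FALSE)
  path <- file.path(dir, "tiny.gtf")
  writeLines(c(
    paste0("chr1\ttest\texon\t101\t200\t.\t+\t.\t",
           'gene_id "gA"; transcript_id "gA.t1"; gene_biotype "protein_coding";'),
    paste0("chr1\ttest\texon\t301\t400\t.\t+\t.\t",
           'gene_id "gA"; transcript_id "gA.t1"; gene_biotype "protein_coding";'),
    paste0("chr1\ttest\texon\t501\t560\t.\t-\t.\t",
           'gene_id "gB"; transcript_id "gB.t1"; gene_biotype "snoRNA";')
  ), path)
  path
}

# Minimal aligned_reads object for unit tests that do not need a real SAM.
fake_reads <- function(chrom, pos, end, strand = "+", dup = FALSE,
                       seq = NULL, qname = NULL) {
  n <- length(pos)
  chrom <- rep_len(chrom, n); strand <- rep_len(strand, n)
  dup <- rep_len(dup, n)
  width <- end - pos + 1L
  seq <- seq %||% vapply(width, function(w) strrep("A", w), character(1))
  blocks <- GenomicRanges::GRangesList(lapply(seq_len(n), function(i) {
    GenomicRanges::GRanges(chrom[i], IRanges::IRanges(pos[i], end[i]))
  }))
  out <- list(
    qname = qname %||% sprintf("r%04d", seq_len(n)),
    chrom = chrom, strand = strand, pos = as.integer(pos),
    end = as.integer(end), cigar = sprintf("%dM", width),
    width = as.integer(width), seq = seq,
    mapq = rep(50L, n), dup = dup, unique = rep(TRUE, n),
    md = as.character(width), nm = rep(0L, n),
    blocks = blocks,
    totals = list(records = n, mapped = n, unmapped = 0L, secondary = 0L)
  )
  class(out) <- "aligned_reads"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a small SAM file from header info plus record lines.
write_test_sam <- function(records, sq = c(chr1 = 2000L),
                           path = tempfile(fileext = ".sam")) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq))
  writeLines(c(header, records), path)
  path
}
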
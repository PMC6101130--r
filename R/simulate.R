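# Molecule-level simulator for degraded poly(A)-selected single-end libraries.
#
# Degradation model per molecule of gene g (meta-transcript length L):
#   * uniform decay: the whole molecule is lost with probability p_g;
#   * endonucleolytic cleavage: cut positions form a Poisson process at
#     rate lambda_g per kb along the transcript. Because poly(A) capture
#     retains the fragment that carries the poly(A) tail, only the
#     3'-terminal segment [max cut, L) survives library preparation;
#   * a full-length read of read_len nt is placed with its 5' end uniform
#     over retained positions admitting a complete read; molecules whose
#     retained segment is shorter than the read are dropped (counted).
# Sequencing artifacts: a configurable fraction of emitted records are
# resampled duplicates (SAM flag 0x400) and substitution errors are drawn
# per (reference base, read cycle) from a 12 x read_len rate table.

DNA_BASES <- c("A", "C", "G", "T")

#' The 12 substitution types
#'
#' @return Character vector `"A>C"`, `"A>G"`, ... in fixed order.
#' @export
mismatch_types <- function() {
  out <- character(0)
  for (x in DNA_BASES) for (y in setdiff(DNA_BASES, x)) {
    out <- c(out, paste0(x, ">", y))
  }
  out
}

#' Uniform substitution-error rate table
#'
#' @param read_len Read length in nt.
#' @param base_rate Total per-base error rate; split equally across the
#'   three alternative bases.
#' @return Numeric matrix, 12 substitution types x read cycles.
#' @export
uniform_mismatch_rates <- function(read_len = 75L, base_rate = 1e-3) {
  m <- matrix(base_rate / 3, nrow = 12L, ncol = read_len,
              dimnames = list(mismatch_types(), NULL))
  m
}

#' Simulation configuration
#'
#' Defines the toy annotation and the library-generation conditions for a
#' paired control/treated poly(A)-selected experiment. Defaults emulate
#' the design this package targets: two groups of three replicates,
#' single-end 75-nt reads, multi-exon genes on both strands of two toy
#' chromosomes, a lognormal expression profile and a 10% PCR-duplicate
#' fraction.
#'
#' @param seed Integer master seed; every random draw derives from it.
#' @param n_genes Number of genes.
#' @param biotype_mix Named proportions over biotypes (must sum to 1).
#' @param n_chromosomes Number of toy chromosomes (genes placed round-robin).
#' @param exon_count_range Integer range of exons per multi-exon gene.
#' @param exon_len_mean,intron_len_mean Mean exon/intron lengths (nt).
#' @param gene_gap Minimum intergenic gap (nt).
#' @param chrom_len Optional fixed chromosome length; error if the genes do
#'   not fit. `NULL` sizes chromosomes to the placed genes.
#' @param gc_content Background genome GC fraction.
#' @param theta_meanlog,theta_sdlog Lognormal parameters of per-gene
#'   expression; `theta_sdlog = 0` gives equal expression.
#' @param groups Named list of group specs, each a list with fields
#'   `n` (replicates), `p` (uniform-decay probability, scalar or per-gene),
#'   `lambda` (cleavage events per kb, scalar or per-gene),
#'   `expected_cuts` (optional; per-molecule expected cleavage count,
#'   overrides `lambda` as `lambda = 1000 * expected_cuts / L`), and
#'   `mismatch_extra` (optional `list(type, positions, delta)` adding a
#'   substitution excess for that group).
#' @param read_len Read length (nt).
#' @param depth Total emitted records per sample (uniques + duplicates).
#' @param dup_rate Fraction of emitted records that are duplicates.
#' @param mismatch_rates 12 x read_len base error-rate table
#'   (default [uniform_mismatch_rates()] at 1e-3).
#' @param capture_polya_free If `TRUE`, poly(A)-free small-RNA biotypes are
#'   captured like any gene (useful for testing the expression filter);
#'   default `FALSE`, mirroring poly(A) selection.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 60L,
                       biotype_mix = c(protein_coding = 0.70, lncRNA = 0.15,
                                       pseudogene = 0.05, snoRNA = 0.04,
                                       snRNA = 0.03, scaRNA = 0.02,
                                       miRNA = 0.01),
                       n_chromosomes = 2L,
                       exon_count_range = c(2L, 6L),
                       exon_len_mean = 800,
                       intron_len_mean = 300,
                       gene_gap = 300,
                       chrom_len = NULL,
                       gc_content = 0.45,
                       theta_meanlog = 0,
                       theta_sdlog = 1,
                       groups = list(
                         control = list(n = 3L, p = 0, lambda = 0),
                         treated = list(n = 3L, p = 0, lambda = 0)
                       ),
                       read_len = 75L,
                       depth = 2e4,
                       dup_rate = 0.10,
                       mismatch_rates = NULL,
                       capture_polya_free = FALSE) {
  stopifnot(abs(sum(biotype_mix) - 1) < 1e-8,
            all(biotype_mix >= 0),
            all(names(biotype_mix) %in% known_biotypes()),
            dup_rate >= 0, dup_rate < 1,
            read_len >= 20, depth >= 1)
  if (is.null(mismatch_rates)) {
    mismatch_rates <- uniform_mismatch_rates(read_len)
  }
  stopifnot(nrow(mismatch_rates) == 12L, ncol(mismatch_rates) == read_len)
  for (gname in names(groups)) {
    gs <- groups[[gname]]
    stopifnot(gs$n >= 1)
    p <- gs$p %||% 0; lam <- gs$lambda %||% 0
    if (any(p < 0 | p > 1)) stopf("group %s: p must lie in [0,1]", gname)
    if (any(lam < 0)) stopf("group %s: lambda must be >= 0", gname)
  }
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              biotype_mix = biotype_mix, n_chromosomes = n_chromosomes,
              exon_count_range = exon_count_range,
              exon_len_mean = exon_len_mean,
              intron_len_mean = intron_len_mean, gene_gap = gene_gap,
              chrom_len = chrom_len, gc_content = gc_content,
              theta_meanlog = theta_meanlog, theta_sdlog = theta_sdlog,
              groups = groups, read_len = as.integer(read_len),
              depth = depth, dup_rate = dup_rate,
              mismatch_rates = mismatch_rates,
              capture_polya_free = capture_polya_free)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d genes, %d chromosome(s), read_len %d, depth %g, dup %.2f\n",
    x$n_genes, x$n_chromosomes, x$read_len, x$depth, x$dup_rate))
  for (g in names(x$groups)) {
    gs <- x$groups[[g]]
    cat(sprintf("  group %s: n=%d p=%s lambda=%s cuts=%s\n", g, gs$n,
                paste(format(unique(gs$p %||% 0)), collapse = "/"),
                paste(format(unique(gs$lambda %||% 0)), collapse = "/"),
                paste(format(unique(gs$expected_cuts %||% NA)), collapse = "/")))
  }
  invisible(x)
}

random_dna <- function(n, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = probs), collapse = "")
}

#' Generate a toy genome and annotation
#'
#' Places non-overlapping genes round-robin on the configured chromosomes,
#' on both strands, draws per-gene expression levels, and (optionally)
#' writes the GTF and FASTA. Deterministic for a fixed config seed.
#'
#' @param config A [sim_config()].
#' @param outdir Optional directory; if given, `genes.gtf` and `genome.fa`
#'   are written there.
#' @return Object of class `sim_annotation`: gene models, meta-transcripts,
#'   genome sequence, per-gene expression `theta`, and file paths.
#' @export
generate_annotation <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_genes
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  cursor <- stats::setNames(rep(0, length(chroms)), chroms)

  biotypes <- if (n > 0) {
    sample(names(config$biotype_mix), n, replace = TRUE,
           prob = config$biotype_mix)
  } else character(0)
  strands <- if (n > 0) sample(c("+", "-"), n, replace = TRUE) else character(0)

  genes <- list()
  min_len <- max(config$read_len, 40L)
  for (i in seq_len(n)) {
    bt <- biotypes[i]
    if (bt %in% polya_free_biotypes()) {
      n_ex <- 1L
      ex_lens <- sample(80:300, 1L)
    } else {
      ecr <- config$exon_count_range
      n_ex <- if (ecr[1] == ecr[2]) ecr[1] else sample(ecr[1]:ecr[2], 1L)
      ex_lens <- pmax(50L, round(stats::rlnorm(
        n_ex, log(config$exon_len_mean) - 0.125, 0.5)))
      if (sum(ex_lens) < min_len) ex_lens[n_ex] <- ex_lens[n_ex] + min_len
    }
    in_lens <- if (n_ex > 1) {
      pmax(40L, round(stats::rlnorm(
        n_ex - 1L, log(config$intron_len_mean) - 0.125, 0.5)))
    } else integer(0)
    chrom <- chroms[(i - 1L) %% length(chroms) + 1L]
    gap <- config$gene_gap + sample(0:200, 1L)
    g0 <- cursor[chrom] + gap
    starts <- g0 + cumsum(c(0, ex_lens[-n_ex] + in_lens))
    ends <- starts + ex_lens
    cursor[chrom] <- ends[n_ex]
    gid <- sprintf("G%04d", i)
    tx <- list(transcript_id = paste0(gid, ".T1"),
               exons = cbind(start = starts, end = ends),
               cds = NULL)
    gene <- new_gene_model(gid, bt, chrom, strands[i],
                           stats::setNames(list(tx), paste0(gid, ".T1")))
    # give protein-coding genes a CDS flanked by UTRs (15% / 25% of cDNA)
    if (bt == "protein_coding" && sum(ex_lens) >= 300) {
      meta <- build_meta_transcript(gene)
      u5 <- round(0.15 * meta$L); u3 <- round(0.25 * meta$L)
      cds_len <- meta$L - u5 - u3
      cds_len <- cds_len - (cds_len %% 3)
      blocks <- meta_to_blocks(meta, u5, cds_len)
      gene$transcripts[[1L]]$cds <- blocks
    }
    genes[[gid]] <- gene
  }

  if (!is.null(config$chrom_len) && any(cursor + config$gene_gap >
                                        config$chrom_len)) {
    stopf(paste0("genome too small to place %d genes without overlap; ",
                 "increase chrom_len beyond %d"), n, max(cursor))
  }
  chrom_lens <- if (is.null(config$chrom_len)) {
    pmax(cursor + config$gene_gap, 1000)
  } else rep(config$chrom_len, length(chroms))

  genome <- Biostrings::DNAStringSet(vapply(
    chrom_lens, function(L) random_dna(L, config$gc_content), character(1)))
  names(genome) <- chroms

  theta <- if (config$theta_sdlog == 0) {
    rep(1, n)
  } else {
    stats::rlnorm(n, config$theta_meanlog, config$theta_sdlog)
  }
  names(theta) <- names(genes)

  models <- structure(genes, class = "gene_models")
  metas <- lapply(models, build_meta_transcript)

  ann <- list(models = models, metas = metas, genome = genome,
              theta = theta, config = config,
              gtf = NULL, fasta = NULL)
  class(ann) <- "sim_annotation"
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    ann$gtf <- file.path(outdir, "genes.gtf")
    ann$fasta <- file.path(outdir, "genome.fa")
    write_sim_gtf(models, ann$gtf)
    Biostrings::writeXStringSet(genome, ann$fasta, width = 70L)
  }
  ann
}

#' @export
print.sim_annotation <- function(x, ...) {
  cat(sprintf("sim_annotation: %d genes on %d chromosome(s) (%s bp)\n",
              length(x$models), length(x$genome),
              paste(Biostrings::width(x$genome), collapse = "+")))
  invisible(x)
}

# GTF writer (1-based closed); exon and CDS rows only, sorted by
# chromosome and start for byte-stable output.
write_sim_gtf <- function(models, path) {
  rows <- list()
  for (g in models) {
    for (tx in g$transcripts) {
      feats <- rbind(
        cbind(type = "exon", tx$exons),
        if (!is.null(tx$cds)) cbind(type = "CDS", tx$cds)
      )
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$chrom, type = feats[, "type"],
        start = as.numeric(feats[, "start"]) + 1,
        end = as.numeric(feats[, "end"]),
        strand = g$strand,
        attr = sprintf(
          'gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
          g$gene_id, tx$transcript_id, g$biotype),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$start, df$type), , drop = FALSE]
  lines <- sprintf("%s\tdryqc_sim\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   df$chrom, df$type, as.integer(df$start),
                   as.integer(df$end), df$strand, df$attr)
  writeLines(lines, path)
  invisible(path)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Resolve a group's per-gene decay/cleavage parameters against gene lengths.
group_gene_params <- function(gspec, L) {
  n <- length(L)
  p <- rep_len(gspec$p %||% 0, n)
  if (!is.null(gspec$expected_cuts)) {
    mu <- rep_len(gspec$expected_cuts, n)
    lambda <- 1000 * mu / L
  } else {
    lambda <- rep_len(gspec$lambda %||% 0, n)
    mu <- lambda * L / 1000
  }
  list(p = p, lambda = lambda, mu = mu)
}

#' Simulate one sequencing library
#'
#' Runs the molecule-level model for one sample of one group and writes a
#' coordinate-sorted SAM file plus per-read and per-gene truth tables.
#' Deterministic for a fixed (config seed, group, sample index).
#'
#' @param annotation A `sim_annotation` from [generate_annotation()].
#' @param group Group name (must match `config$groups`).
#' @param sample_index Replicate number within the group (1-based).
#' @param outdir Output directory for the SAM and truth TSVs.
#' @param sample_id Sample label; default `"<group>_<index>"`.
#' @return Object of class `sim_library`: paths plus in-memory truth
#'   (`reads`, `mismatches`, `genes`).
#' @export
simulate_library <- function(annotation, group, sample_index, outdir,
                             sample_id = NULL) {
  stopifnot(inherits(annotation, "sim_annotation"))
  cfg <- annotation$config
  if (!group %in% names(cfg$groups)) stopf("unknown group: %s", group)
  gi <- match(group, names(cfg$groups))
  gspec <- cfg$groups[[gi]]
  sample_id <- sample_id %||% sprintf("%s_%d", group, sample_index)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(derive_seed(cfg$seed, 2L, gi, sample_index))

  models <- annotation$models
  metas <- annotation$metas
  rl <- cfg$read_len
  L_all <- vapply(metas, function(m) m$L, 0)
  biotype <- vapply(models, function(g) g$biotype, character(1))

  captured <- if (cfg$capture_polya_free) rep(TRUE, length(models)) else
    !(biotype %in% polya_free_biotypes())
  captured <- captured & (L_all >= rl)
  gids <- names(models)

  pars <- group_gene_params(gspec, L_all)

  # substitution rates for this group (base table + optional group excess)
  eps <- cfg$mismatch_rates
  if (!is.null(gspec$mismatch_extra)) {
    me <- gspec$mismatch_extra
    eps[me$type, me$positions] <- eps[me$type, me$positions] + me$delta
  }
  # total mismatch probability per (reference base, cycle)
  S <- matrix(0, 4, rl, dimnames = list(DNA_BASES, NULL))
  for (x in DNA_BASES) {
    S[x, ] <- colSums(eps[paste0(x, ">", setdiff(DNA_BASES, x)), , drop = FALSE])
  }

  n_dup <- round(cfg$depth * cfg$dup_rate)
  n_unique <- cfg$depth - n_dup

  theta_c <- annotation$theta * captured
  if (sum(theta_c) == 0) stopf("no captured genes to simulate")
  theta_n <- theta_c / sum(theta_c)
  surv <- sum(theta_n * (1 - pars$p) * exp(-pars$mu * rl / L_all))
  n_mol <- ceiling(n_unique / max(surv, 1e-6) * 1.25) + 200L

  mol_counts <- as.vector(stats::rmultinom(1L, n_mol, theta_n))
  names(mol_counts) <- gids

  gene_read_gene <- integer(0); gene_read_m <- numeric(0)
  decayed <- dropped_short <- stats::setNames(integer(length(gids)), gids)
  for (k in which(mol_counts > 0)) {
    mcount <- mol_counts[k]
    L <- L_all[k]
    keep <- stats::rbinom(1L, mcount, 1 - pars$p[k])
    decayed[k] <- mcount - keep
    if (keep == 0L) next
    ncut <- stats::rpois(keep, pars$mu[k])
    cpos <- numeric(keep)
    has <- ncut > 0
    # max of ncut uniforms on [0, L): inverse-CDF draw
    cpos[has] <- floor(L * stats::runif(sum(has)) ^ (1 / ncut[has]))
    ok <- cpos <= L - rl
    dropped_short[k] <- sum(!ok)
    if (!any(ok)) next
    m <- cpos[ok] + floor(stats::runif(sum(ok)) * (L - rl - cpos[ok] + 1))
    gene_read_gene <- c(gene_read_gene, rep.int(k, length(m)))
    gene_read_m <- c(gene_read_m, m)
  }
  n_avail <- length(gene_read_m)
  if (n_avail > n_unique) {
    sel <- sample.int(n_avail, n_unique)
    gene_read_gene <- gene_read_gene[sel]
    gene_read_m <- gene_read_m[sel]
  } else if (n_avail < n_unique) {
    warnf("sample %s: only %d surviving molecules for %d requested reads",
          sample_id, n_avail, n_unique)
    n_unique <- n_avail
    n_dup <- round(n_unique * cfg$dup_rate / (1 - cfg$dup_rate))
  }
  nu <- length(gene_read_m)

  # reference read sequences in transcript orientation
  ord <- order(gene_read_gene, gene_read_m)
  gene_read_gene <- gene_read_gene[ord]; gene_read_m <- gene_read_m[ord]
  refs <- character(nu)
  for (k in unique(gene_read_gene)) {
    idx <- which(gene_read_gene == k)
    txseq <- as.character(meta_sequence(metas[[k]], annotation$genome))
    refs[idx] <- substring(txseq, gene_read_m[idx] + 1, gene_read_m[idx] + rl)
  }

  # substitution errors, drawn per (reference base, cycle)
  seqs <- refs
  mm_read <- integer(0); mm_cycle <- integer(0)
  mm_ref <- character(0); mm_alt <- character(0)
  chunk <- 50000L
  for (lo in seq(1L, max(nu, 1L), by = chunk)) {
    if (nu == 0L) break
    hi <- min(lo + chunk - 1L, nu)
    nloc <- hi - lo + 1L
    mat <- matrix(unlist(strsplit(refs[lo:hi], "", fixed = TRUE)),
                  nrow = nloc, byrow = TRUE)
    bidx <- match(mat, DNA_BASES)
    pidx <- rep(seq_len(rl), each = nloc)
    prob <- S[cbind(bidx, pidx)]
    hit <- which(stats::runif(nloc * rl) < prob)
    if (length(hit)) {
      h_read <- (hit - 1L) %% nloc + lo
      h_cyc <- (hit - 1L) %/% nloc + 1L
      h_ref <- mat[hit]
      alts <- t(vapply(h_ref, function(x) setdiff(DNA_BASES, x),
                       character(3)))
      tix <- function(a) match(paste0(h_ref, ">", a), rownames(eps))
      pr <- cbind(eps[cbind(tix(alts[, 1]), h_cyc)],
                  eps[cbind(tix(alts[, 2]), h_cyc)],
                  eps[cbind(tix(alts[, 3]), h_cyc)])
      tot <- rowSums(pr)
      r2 <- stats::runif(length(hit)) * tot
      ai <- 1L + (r2 > pr[, 1]) + (r2 > pr[, 1] + pr[, 2])
      h_alt <- alts[cbind(seq_along(hit), ai)]
      for (j in seq_along(hit)) {
        substr(seqs[h_read[j]], h_cyc[j], h_cyc[j]) <- h_alt[j]
      }
      mm_read <- c(mm_read, h_read); mm_cycle <- c(mm_cycle, h_cyc)
      mm_ref <- c(mm_ref, h_ref); mm_alt <- c(mm_alt, h_alt)
    }
  }

  rec <- build_sam_records(gene_read_gene, gene_read_m, seqs, metas, rl,
                           mm_read, mm_cycle, mm_ref, mm_alt)

  # duplicates: resampled copies of emitted records, flag 0x400
  dup_src <- if (n_dup > 0 && nu > 0) sample.int(nu, n_dup, replace = TRUE)
             else integer(0)

  qname_u <- sprintf("r%07d", seq_len(nu))
  qname_d <- if (length(dup_src)) {
    sprintf("r%07d.d%d", dup_src, seq_along(dup_src))
  } else character(0)

  all_idx <- c(seq_len(nu), dup_src)
  flags <- c(rec$flag, rec$flag[dup_src] + 1024L)
  qnames <- c(qname_u, qname_d)
  qual <- strrep("I", rl)
  lines <- sprintf("%s\t%d\t%s\t%d\t50\t%s\t*\t0\t0\t%s\t%s\tNH:i:1\tNM:i:%d\tMD:Z:%s",
                   qnames, flags, rec$chrom[all_idx], rec$pos[all_idx],
                   rec$cigar[all_idx], rec$seq[all_idx], qual,
                   rec$nm[all_idx], rec$md[all_idx])
  chrom_order <- match(rec$chrom[all_idx], names(annotation$genome))
  lines <- lines[order(chrom_order, rec$pos[all_idx])]

  sam_path <- file.path(outdir, paste0(sample_id, ".sam"))
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(annotation$genome),
                      Biostrings::width(annotation$genome)),
              "@PG\tID:dryqc\tPN:dryqc")
  writeLines(c(header, lines), sam_path)

  nmm <- tabulate(mm_read, nbins = max(nu, 1L))
  reads_truth <- data.frame(
    read_id = qnames,
    gene_id = gids[gene_read_gene[all_idx]],
    meta5 = gene_read_m[all_idx],
    duplicate = as.integer(c(rep(0L, nu), rep(1L, length(dup_src)))),
    n_mismatch = c(nmm[seq_len(nu)], nmm[dup_src]),
    stringsAsFactors = FALSE
  )

  mm_truth <- data.frame(read_id = qname_u[mm_read], cycle = mm_cycle,
                         ref = mm_ref, alt = mm_alt,
                         stringsAsFactors = FALSE)

  gene_truth <- data.frame(
    gene_id = gids, biotype = biotype, theta = unname(annotation$theta),
    captured = captured, p = pars$p, lambda = pars$lambda,
    expected_cuts = pars$mu, molecules = as.integer(mol_counts),
    decayed = as.integer(decayed), dropped_short = as.integer(dropped_short),
    reads = as.integer(tabulate(gene_read_gene, nbins = length(gids))),
    stringsAsFactors = FALSE
  )

  truth_path <- file.path(outdir, paste0(sample_id, ".truth.tsv"))
  write_tsv(reads_truth, truth_path)

  out <- list(sample_id = sample_id, group = group, sam = sam_path,
              truth_path = truth_path, reads = reads_truth,
              mismatches = mm_truth, genes = gene_truth)
  class(out) <- "sim_library"
  out
}

# Genomic placement of reads: position, CIGAR, strand flag, SEQ in
# reference-plus orientation, and MD/NM tags.
build_sam_records <- function(gene_idx, m, seqs, metas, rl,
                              mm_read, mm_cycle, mm_ref, mm_alt) {
  n <- length(gene_idx)
  chrom <- character(n); pos <- integer(n); cigar <- character(n)
  flag <- integer(n); out_seq <- character(n)
  md <- rep(as.character(rl), n); nm <- integer(n)

  mm_by_read <- if (length(mm_read)) split(seq_along(mm_read), mm_read) else
    list()

  for (k in unique(gene_idx)) {
    meta <- metas[[k]]
    idx <- which(gene_idx == k)
    minus <- meta$strand == "-"
    a <- if (minus) meta$L - (m[idx] + rl) else m[idx]
    i1 <- findInterval(a, meta$offsets)
    i2 <- findInterval(a + rl - 1, meta$offsets)
    chrom[idx] <- meta$chrom
    flag[idx] <- if (minus) 16L else 0L
    gstart <- meta$starts[i1] + (a - meta$offsets[i1])
    pos[idx] <- as.integer(gstart + 1)  # SAM is 1-based
    single <- i1 == i2
    cigar[idx[single]] <- paste0(rl, "M")
    for (j in which(!single)) {
      blocks <- meta_to_blocks(meta, m[idx[j]], rl)
      ops <- character(0)
      for (b in seq_len(nrow(blocks))) {
        if (b > 1) {
          ops <- c(ops, paste0(blocks[b, 1] - blocks[b - 1, 2], "N"))
        }
        ops <- c(ops, paste0(blocks[b, 2] - blocks[b, 1], "M"))
      }
      cigar[idx[j]] <- paste(ops, collapse = "")
    }
    out_seq[idx] <- if (minus) {
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[idx])))
    } else seqs[idx]
  }

  # MD/NM for reads carrying mismatches (alignment order, reference bases
  # on the genome plus strand)
  for (rid in as.integer(names(mm_by_read))) {
    rows <- mm_by_read[[as.character(rid)]]
    minus <- flag[rid] == 16L
    cyc <- mm_cycle[rows]
    refb <- mm_ref[rows]
    if (minus) {
      apos <- rl + 1L - cyc
      refb <- unname(COMPLEMENT[refb])
    } else {
      apos <- cyc
    }
    o <- order(apos)
    apos <- apos[o]; refb <- refb[o]
    gaps <- diff(c(0L, apos)) - 1L
    md[rid] <- paste0(paste0(gaps, refb, collapse = ""), rl - apos[length(apos)])
    nm[rid] <- length(rows)
  }

  list(chrom = chrom, pos = pos, cigar = cigar, flag = flag,
       seq = out_seq, md = md, nm = nm)
}

#' Simulate a full paired experiment
#'
#' Generates the annotation and one SAM library per replicate of every
#' group, with per-read and per-gene ground truth.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory.
#' @return Object of class `sim_experiment`: the annotation, a sample
#'   manifest (`sample_id`, `group`, `sam`), per-sample truth objects and
#'   the per-gene truth table (including the expected bias class).
#' @export
simulate_experiment <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ann <- generate_annotation(config, outdir)
  libs <- list()
  for (group in names(config$groups)) {
    for (i in seq_len(config$groups[[group]]$n)) {
      lib <- simulate_library(ann, group, i, outdir)
      libs[[lib$sample_id]] <- lib
    }
  }
  manifest <- data.frame(
    sample_id = vapply(libs, `[[`, character(1), "sample_id"),
    group = vapply(libs, `[[`, character(1), "group"),
    sam = vapply(libs, `[[`, character(1), "sam"),
    stringsAsFactors = FALSE, row.names = NULL
  )

  L_all <- vapply(ann$metas, function(m) m$L, 0)
  ref_group <- names(config$groups)[1L]
  cuts <- lapply(config$groups, function(gs) group_gene_params(gs, L_all)$mu)
  extra <- Reduce(pmax, cuts[-1L], rep(0, length(L_all))) - cuts[[ref_group]]
  expected_class <- ifelse(extra > 1e-9, "five_prime_underrepresented",
                           "uniform")
  gene_truth <- libs[[1L]]$genes
  gene_truth$expected_class <- expected_class
  write_tsv(gene_truth, file.path(outdir, "gene_truth.tsv"))
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))

  out <- list(annotation = ann, manifest = manifest, libraries = libs,
              gene_truth = gene_truth, dir = outdir)
  class(out) <- "sim_experiment"
  out
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("sim_experiment: %d samples (%s) in %s\n",
              nrow(x$manifest),
              paste(unique(x$manifest$group), collapse = " vs "), x$dir))
  invisible(x)
}
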
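# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Biotypes excluded from poly(A)-selected quantification
#'
#' Small RNA classes that are transcribed but lack a poly(A) tract, so their
#' capture during poly(A) selection is ambiguous; expression filtering and
#' the simulator's capture model both treat them as not captured.
#'
#' @return Character vector of biotype labels.
#' @export
polya_free_biotypes <- function() {
  c("snRNA", "snoRNA", "scaRNA", "vtRNA", "snaR", "miRNA")
}

# Controlled biotype vocabulary; anything else maps to "other".
known_biotypes <- function() {
  c("protein_coding", "lncRNA", "pseudogene", polya_free_biotypes(), "other")
}

# Common aliases seen in ENSEMBL-dialect GTFs.
normalize_biotype <- function(x, warn = TRUE) {
  alias <- c(
    lincRNA = "lncRNA", vaultRNA = "vtRNA", vault_RNA = "vtRNA",
    processed_pseudogene = "pseudogene", unprocessed_pseudogene = "pseudogene"
  )
  x <- ifelse(x %in% names(alias), alias[x], x)
  bad <- !(x %in% known_biotypes())
  if (any(bad)) {
    if (warn) {
      warning("unknown biotype(s) mapped to 'other': ",
              paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    }
    x[bad] <- "other"
  }
  unname(x)
}

# Deterministic sub-seed derivation (kept below 2^31).
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) s <- (s * 1103 + as.double(k) * 12289 + 1) %% 2147483647
  as.integer(s)
}

# Write a data.frame as TSV with stable formatting (no quotes, no rownames).
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

# JSON writer used by all stages: scalars unboxed, full precision.
write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
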
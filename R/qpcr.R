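# Efficiency-corrected Cp arithmetic: integrity ratios, delta-Cp relative
# expression and paired group tests.
#
# An assay with amplification efficiency E multiplies template by E each
# cycle, so quantity ~ E^-Cp = 2^-(Cp * log2 E). Corrected Cp' = Cp *
# log2(E) places every assay on a common base-2 scale, after which the
# familiar 2^-dCp arithmetic applies.

#' Efficiency-corrected Cp
#'
#' Replicate Cp values are averaged on the Cp scale (geometric mean of
#' quantities), then rescaled: `Cp' = mean(Cp) * log2(E)`.
#'
#' @param cp Numeric Cp replicate values (cycles).
#' @param efficiency Amplification efficiency E in (1, 2].
#' @return Corrected Cp' (scalar).
#' @export
corrected_cp <- function(cp, efficiency) {
  if (!is.numeric(efficiency) || efficiency <= 1 || efficiency > 2) {
    stopf("efficiency must lie in (1, 2], got %s", format(efficiency))
  }
  cp <- cp[!is.na(cp)]
  if (!length(cp)) stopf("no Cp replicate values")
  if (any(cp <= 0)) stopf("Cp values must be positive")
  mean(cp) * log2(efficiency)
}

#' RNA integrity ratio from a 3' and a 5' assay
#'
#' `ratio = 2^-(Cp'3 - Cp'5)`: equal corrected Cps give 1; an excess of 3'
#' template (Cp'3 < Cp'5) gives a ratio above 1, the signature of 5' loss
#' through degradation under oligo(dT) priming.
#'
#' @param cp5,cp3 Replicate Cp values of the 5' and 3' assays (same
#'   sample).
#' @param eff5,eff3 Assay efficiencies (default 2).
#' @return List: `cp5_corrected`, `cp3_corrected`, `delta_cp`, `ratio`.
#' @export
integrity_ratio <- function(cp5, cp3, eff5 = 2, eff3 = 2) {
  if (missing(cp5) || missing(cp3)) stopf("both 5' and 3' assays required")
  c5 <- corrected_cp(cp5, eff5)
  c3 <- corrected_cp(cp3, eff3)
  d <- c3 - c5
  list(cp5_corrected = c5, cp3_corrected = c3, delta_cp = d,
       ratio = 2^(-d))
}

#' Relative expression by the delta-Cp method
#'
#' `expression = 2^-(Cp'target - Cp'reference)`, both efficiency-corrected.
#'
#' @param cp_target,cp_ref Replicate Cp values for target and reference
#'   (same sample).
#' @param eff_target,eff_ref Assay efficiencies (default 2).
#' @return Normalized expression (scalar).
#' @export
relative_expression <- function(cp_target, cp_ref, eff_target = 2,
                                eff_ref = 2) {
  if (missing(cp_ref)) stopf("reference assay required")
  2^(-(corrected_cp(cp_target, eff_target) - corrected_cp(cp_ref, eff_ref)))
}

#' Paired two-sided t-test on grouped values
#'
#' Pairs with a missing member are dropped and reported. With zero
#' variance of the differences the P value degenerates: 1 if the mean
#' difference is 0, otherwise 0 (flagged).
#'
#' @param a,b Numeric vectors of paired values (same order).
#' @return List: `mean_difference`, `p_value`, `n_pairs`, `n_dropped`,
#'   `degenerate`.
#' @export
paired_group_test <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  dropped <- sum(!ok)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2L) stopf("need >= 2 complete pairs, got %d", length(a))
  d <- a - b
  if (stats::sd(d) == 0) {
    return(list(mean_difference = mean(d),
                p_value = if (mean(d) == 0) 1 else 0,
                n_pairs = length(d), n_dropped = dropped,
                degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(mean_difference = unname(tt$estimate), p_value = tt$p.value,
       n_pairs = length(d), n_dropped = dropped, degenerate = FALSE)
}

#' Read a Cp table
#'
#' Delimited text with columns `sample_id`, `group`, `pair_id`, `target`,
#' replicate columns `cp_rep1`, `cp_rep2`, ..., `efficiency`, and
#' optionally `nort_cp` (no-RT control).
#'
#' @param path CSV/TSV path.
#' @return `data.frame` with a list-column-free layout (replicates stay as
#'   separate columns).
#' @export
read_cp_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "target", "efficiency")
  if (!all(need %in% colnames(df))) {
    stopf("Cp table must have columns: %s", paste(need, collapse = ", "))
  }
  if (!any(grepl("^cp_rep", colnames(df)))) {
    stopf("Cp table needs at least one cp_rep<k> column")
  }
  df
}

cp_reps <- function(row) {
  as.numeric(row[grepl("^cp_rep", names(row))])
}

#' Per-sample integrity ratios from a Cp table
#'
#' @param cp_table Table from [read_cp_table()].
#' @param five,three Target names of the 5' and 3' assays.
#' @return `data.frame`: sample, group, corrected Cps, ratio; flags
#'   samples whose no-RT control lies within 5 cycles of the RT Cp.
#' @export
qpcr_integrity <- function(cp_table, five, three) {
  out <- list()
  for (s in unique(cp_table$sample_id)) {
    sub <- cp_table[cp_table$sample_id == s, , drop = FALSE]
    r5 <- sub[sub$target == five, , drop = FALSE]
    r3 <- sub[sub$target == three, , drop = FALSE]
    if (nrow(r5) != 1L || nrow(r3) != 1L) {
      stopf("sample %s: need exactly one row for each of %s and %s",
            s, five, three)
    }
    ir <- integrity_ratio(cp_reps(r5[1, ]), cp_reps(r3[1, ]),
                          r5$efficiency[1], r3$efficiency[1])
    nort_flag <- FALSE
    if ("nort_cp" %in% colnames(sub)) {
      nr <- c(r5$nort_cp[1], r3$nort_cp[1])
      rt <- c(mean(cp_reps(r5[1, ]), na.rm = TRUE),
              mean(cp_reps(r3[1, ]), na.rm = TRUE))
      nort_flag <- any(!is.na(nr) & (nr - rt) < 5)
    }
    out[[s]] <- data.frame(
      sample_id = s, group = r5$group[1],
      cp5_corrected = ir$cp5_corrected, cp3_corrected = ir$cp3_corrected,
      ratio = ir$ratio, nort_warning = nort_flag,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reference-normalized expression from a Cp table
#'
#' Delta-Cp expression of every non-reference target, normalized to the
#' reference assay of the same sample.
#'
#' @param cp_table Table from [read_cp_table()].
#' @param reference Reference target name (e.g. `"ACTB"`).
#' @return `data.frame`: sample, group, target, expression.
#' @export
qpcr_expression <- function(cp_table, reference = "ACTB") {
  out <- list()
  for (s in unique(cp_table$sample_id)) {
    sub <- cp_table[cp_table$sample_id == s, , drop = FALSE]
    ref <- sub[sub$target == reference, , drop = FALSE]
    if (nrow(ref) != 1L) {
      stopf("sample %s: missing reference target %s", s, reference)
    }
    for (i in which(sub$target != reference)) {
      expr <- relative_expression(cp_reps(sub[i, ]), cp_reps(ref[1, ]),
                                  sub$efficiency[i], ref$efficiency[1])
      out[[length(out) + 1L]] <- data.frame(
        sample_id = s, group = sub$group[i], target = sub$target[i],
        expression = expr, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
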
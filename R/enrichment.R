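#' Group design for a spectral-count comparison
#'
#' @param control,treated Character vectors of sample ids (disjoint,
#'   non-empty; the adduct-mapping study used 4 hearts per group).
#' @return A `group_design` object.
#' @export
group_design <- function(control, treated) {
  control <- as.character(control); treated <- as.character(treated)
  if (length(control) < 1L || length(treated) < 1L) {
    stop("each group needs at least one sample")
  }
  if (length(intersect(control, treated)) > 0L) {
    stop("control and treated sample ids overlap: ",
         paste(intersect(control, treated), collapse = ", "))
  }
  if (anyDuplicated(c(control, treated))) stop("duplicated sample ids in design")
  structure(list(control = control, treated = treated), class = "group_design")
}

#' Filter PSM identifications
#'
#' Applies the identification acceptance rules of the adduct-mapping screen:
#' peptide probability strictly greater than `peptide_prob_min`, protein
#' probability strictly greater than `protein_prob_min`, and at least
#' `min_psms` retained PSMs per protein across all samples. Malformed
#' probability values are reported in the rejection log, never silently
#' dropped.
#'
#' @param records PSM table: data.frame with columns `protein_id`,
#'   `sample_id`, `group`, `peptide_probability`, `protein_probability`;
#'   one row per PSM.
#' @param peptide_prob_min Peptide probability cutoff (default 0.9; strict >).
#' @param protein_prob_min Protein probability cutoff (default 0.999; strict >).
#' @param min_psms Minimum retained PSMs per protein (default 2; inclusive).
#' @return List with `psms` (retained rows), `rejected_rows` (rows failing a
#'   probability rule or malformed, with a `reason` column) and `protein_log`
#'   (proteins dropped by the PSM-count rule with their retained counts).
#' @export
filter_identifications <- function(records, peptide_prob_min = 0.9,
                                   protein_prob_min = 0.999, min_psms = 2) {
  check_psm_table(records)
  stopifnot(peptide_prob_min >= 0, peptide_prob_min <= 1,
            protein_prob_min >= 0, protein_prob_min <= 1, min_psms >= 1)
  if (nrow(records) == 0L) {
    warning("empty PSM table; returning empty result")
    return(list(psms = records, rejected_rows = cbind(records, reason = character(0)),
                protein_log = data.frame(protein_id = character(0),
                                         retained_psms = integer(0))))
  }
  pp <- records$peptide_probability
  qq <- records$protein_probability
  malformed <- !is.finite(pp) | !is.finite(qq) | pp < 0 | pp > 1 | qq < 0 | qq > 1
  fail_pep <- !malformed & pp <= peptide_prob_min
  fail_prot <- !malformed & !fail_pep & qq <= protein_prob_min
  reason <- rep(NA_character_, nrow(records))
  reason[malformed] <- "malformed_probability"
  reason[fail_pep] <- "peptide_probability"
  reason[fail_prot] <- "protein_probability"
  keep <- is.na(reason)
  rejected <- cbind(records[!keep, , drop = FALSE], reason = reason[!keep])
  retained <- records[keep, , drop = FALSE]

  counts <- table(retained$protein_id)
  low <- names(counts)[counts < min_psms]
  protein_log <- data.frame(protein_id = low,
                            retained_psms = as.integer(counts[low]),
                            stringsAsFactors = FALSE)
  retained <- retained[!retained$protein_id %in% low, , drop = FALSE]
  rownames(retained) <- NULL; rownames(rejected) <- NULL
  list(psms = retained, rejected_rows = rejected, protein_log = protein_log)
}

check_psm_table <- function(records) {
  needed <- c("protein_id", "sample_id", "group",
              "peptide_probability", "protein_probability")
  if (!is.data.frame(records) || !all(needed %in% names(records))) {
    stop("PSM table must be a data.frame with columns: ",
         paste(needed, collapse = ", "))
  }
  invisible(records)
}

#' Tally PSMs into a protein x sample count matrix
#'
#' @param records PSM table (one row per PSM).
#' @param design A [group_design()]; every sample in `records` must appear in
#'   it. Samples with no PSMs are zero-filled columns.
#' @return Integer matrix, rows proteins, columns samples ordered
#'   control-then-treated.
#' @export
aggregate_counts <- function(records, design) {
  check_psm_table(records)
  stopifnot(inherits(design, "group_design"))
  samples <- c(design$control, design$treated)
  unknown <- setdiff(unique(records$sample_id), samples)
  if (length(unknown) > 0L) {
    stop("sample id(s) not in design: ", paste(unknown, collapse = ", "))
  }
  if (nrow(records) == 0L) {
    return(matrix(0L, nrow = 0, ncol = length(samples),
                  dimnames = list(NULL, samples)))
  }
  tab <- table(factor(records$protein_id),
               factor(records$sample_id, levels = samples))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), samples))
  m
}

#' Spectral-count enrichment and volcano statistics
#'
#' For each protein the per-group PSM totals are computed by summation; a
#' zero total is replaced by `pseudocount` (default 0.1, applied to group
#' totals only, never to the per-sample counts used by the t-test). The
#' enrichment is `x = log2(treated_total_adj / control_total_adj)` and the
#' confidence is `y = -log(p)` (base `log_base_y`, capped at `y_cap`) from a
#' two-sided two-sample t-test on the per-sample counts. Proteins with zero
#' PSMs in both groups are excluded and logged.
#'
#' Degenerate variances: all counts identical across both groups gives
#' `p = 1`; both within-group variances zero with different means gives
#' `p = 0` and `y = y_cap`.
#'
#' @param counts Count matrix from [aggregate_counts()].
#' @param design A [group_design()] naming the matrix columns.
#' @param pseudocount Replacement for a zero group total (default 0.1).
#' @param log_base_y `"log10"` (default; the printed 95% gate y >= 1.3 equals
#'   -log10(0.05)) or `"ln"`.
#' @param y_cap Cap applied to y (default 16).
#' @param test `"student"` (pooled variance, default) or `"welch"`.
#' @return A data.frame (one row per retained protein): `protein_id`,
#'   `control_total`, `treated_total`, `control_adjusted`, `treated_adjusted`,
#'   `x_log2_enrichment`, `p_value`, `y_neglogp`, plus an attribute
#'   `"excluded"` naming proteins with no PSMs in either group.
#' @export
compute_enrichment <- function(counts, design, pseudocount = 0.1,
                               log_base_y = c("log10", "ln"), y_cap = 16,
                               test = c("student", "welch")) {
  log_base_y <- match.arg(log_base_y)
  test <- match.arg(test)
  stopifnot(inherits(design, "group_design"), pseudocount > 0, y_cap > 0)
  if (length(design$control) < 2L || length(design$treated) < 2L) {
    stop("need at least 2 samples per group for the t-test")
  }
  missing_cols <- setdiff(c(design$control, design$treated), colnames(counts))
  if (length(missing_cols) > 0L) {
    stop("count matrix lacks design sample(s): ",
         paste(missing_cols, collapse = ", "))
  }
  cc <- counts[, design$control, drop = FALSE]
  tt <- counts[, design$treated, drop = FALSE]
  ctot <- rowSums(cc); ttot <- rowSums(tt)
  excluded <- rownames(counts)[ctot == 0 & ttot == 0]
  keep <- ctot > 0 | ttot > 0
  cc <- cc[keep, , drop = FALSE]; tt <- tt[keep, , drop = FALSE]
  ctot <- ctot[keep]; ttot <- ttot[keep]

  cadj <- ifelse(ctot == 0, pseudocount, ctot)
  tadj <- ifelse(ttot == 0, pseudocount, ttot)
  x <- log2(tadj / cadj)

  p <- vapply(seq_along(ctot), function(i) {
    two_sample_p(as.numeric(cc[i, ]), as.numeric(tt[i, ]), test)
  }, numeric(1))

  y <- ifelse(p <= 0, y_cap,
              if (log_base_y == "log10") -log10(p) else -log(p))
  y <- pmin(y, y_cap)

  out <- data.frame(
    protein_id = rownames(counts)[keep],
    control_total = as.numeric(ctot), treated_total = as.numeric(ttot),
    control_adjusted = cadj, treated_adjusted = tadj,
    x_log2_enrichment = x, p_value = p, y_neglogp = y,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "log_base_y") <- log_base_y
  out
}

# two-sided two-sample t-test p-value with explicit degenerate handling
two_sample_p <- function(a, b, test = c("student", "welch")) {
  test <- match.arg(test)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    return(if (mean(a) == mean(b)) 1 else 0)
  }
  stats::t.test(b, a, var.equal = (test == "student"))$p.value
}

#' Apply the volcano significance gates
#'
#' A protein is significant when `x >= x_min` and `y >= y_min`, both
#' inclusive; the direction is treated-enriched only (the upper-right
#' quadrant of the volcano). Defaults are the printed gates: at least
#' fourfold enrichment (x >= 2) and confidence over 95% (y >= 1.3).
#'
#' @param rows Data.frame from [compute_enrichment()].
#' @param x_min Enrichment gate on `x_log2_enrichment` (default 2).
#' @param y_min Confidence gate on `y_neglogp` (default 1.3).
#' @return `rows` with a logical `significant` column; attribute `"summary"`
#'   holds the significant / non-significant counts.
#' @export
classify_volcano <- function(rows, x_min = 2, y_min = 1.3) {
  stopifnot(is.data.frame(rows),
            all(c("x_log2_enrichment", "y_neglogp") %in% names(rows)))
  rows$significant <- rows$x_log2_enrichment >= x_min & rows$y_neglogp >= y_min
  attr(rows, "summary") <- c(significant = sum(rows$significant),
                             not_significant = sum(!rows$significant))
  rows
}

#' Full spectral-count enrichment pipeline
#'
#' Filter identifications, tally counts, compute enrichment and apply the
#' volcano gates in one call.
#'
#' @inheritParams filter_identifications
#' @inheritParams compute_enrichment
#' @inheritParams classify_volcano
#' @param design A [group_design()].
#' @return The classified volcano table (see [classify_volcano()]), with the
#'   filter logs attached as attributes `"rejected_rows"` and `"protein_log"`.
#' @export
enrichment_pipeline <- function(records, design,
                                peptide_prob_min = 0.9, protein_prob_min = 0.999,
                                min_psms = 2, pseudocount = 0.1,
                                log_base_y = "log10", y_cap = 16,
                                test = "student", x_min = 2, y_min = 1.3) {
  flt <- filter_identifications(records, peptide_prob_min, protein_prob_min, min_psms)
  counts <- aggregate_counts(flt$psms, design)
  rows <- compute_enrichment(counts, design, pseudocount = pseudocount,
                             log_base_y = log_base_y, y_cap = y_cap, test = test)
  rows <- classify_volcano(rows, x_min = x_min, y_min = y_min)
  attr(rows, "rejected_rows") <- flt$rejected_rows
  attr(rows, "protein_log") <- flt$protein_log
  rows
}
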
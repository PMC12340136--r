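#' Enumerate crosslink / mono-adduct candidates
#'
#' For a `bridge` linker, all unordered pairs of cysteine-containing peptides
#' (including a peptide paired with a second copy of itself) are enumerated
#' with every Cys-by-Cys placement, together with loop-links inside peptides
#' carrying two or more cysteines. For a `mono_adduct` linker, every
#' peptide-by-cysteine placement is enumerated. Fixed modifications are
#' applied to non-bridged cysteines only. The candidate table is
#' deterministically ordered.
#'
#' @param cys_peps Cysteine peptide table from [cysteine_peptides()].
#' @param linker A [linker_spec()].
#' @param fixed_mods List of fixed [modification_spec()]s (applied to
#'   non-bridged target residues).
#' @return A data.frame, one row per candidate: `candidate_id`, `kind`
#'   (`pair`/`loop`/`mono`), peptide a and b coordinates and sequences
#'   (`b` columns `NA` for loop/mono), `cys_a`, `cys_b` (protein coordinates;
#'   `cys_b` `NA` for mono), `linker`, `neutral_mass`.
#' @export
enumerate_candidates <- function(cys_peps, linker, fixed_mods = list()) {
  stopifnot(inherits(linker, "linker_spec"))
  if (nrow(cys_peps) == 0L) {
    if (linker$kind == "bridge") warning("no cysteine-containing peptides; no candidates")
    return(empty_candidate_table())
  }
  # residue-level fixed-mod delta applied per non-bridged target residue
  target <- linker$target_residue
  mod_delta_per_target <- 0
  base_mass <- vapply(cys_peps$sequence, peptide_monoisotopic_mass,
                      numeric(1), USE.NAMES = FALSE)
  for (mod in fixed_mods) {
    stopifnot(inherits(mod, "modification_spec"), identical(mod$mode, "fixed"))
    if (mod$target_residue == target) {
      mod_delta_per_target <- mod_delta_per_target + mod$delta_mass
      # applied per target residue below (bridged residues exempt)
      base_mass <- base_mass + mod$delta_mass * cys_peps$n_cys
    } else {
      nres <- vapply(strsplit(cys_peps$sequence, "", fixed = TRUE),
                     function(r) sum(r == mod$target_residue), integer(1))
      base_mass <- base_mass + mod$delta_mass * nres
    }
  }

  rows <- list(); k <- 0L
  n <- nrow(cys_peps)
  add_row <- function(kind, ia, ib, ca, cb, mass) {
    k <<- k + 1L
    rows[[k]] <<- data.frame(
      kind = kind,
      pep_a_start = cys_peps$start[ia], pep_a_end = cys_peps$end[ia],
      pep_a = cys_peps$sequence[ia],
      pep_b_start = if (is.na(ib)) NA_integer_ else cys_peps$start[ib],
      pep_b_end = if (is.na(ib)) NA_integer_ else cys_peps$end[ib],
      pep_b = if (is.na(ib)) NA_character_ else cys_peps$sequence[ib],
      cys_a = ca, cys_b = cb,
      linker = linker$name, neutral_mass = mass,
      stringsAsFactors = FALSE
    )
  }

  if (linker$kind == "mono_adduct") {
    for (i in seq_len(n)) {
      for (c1 in cys_peps$cys_positions[[i]]) {
        # the adducted cysteine is exempt from fixed capping
        add_row("mono", i, NA_integer_, c1, NA_integer_,
                base_mass[i] - mod_delta_per_target + linker$delta_mass)
      }
    }
  } else {
    for (i in seq_len(n)) {
      cys_i <- cys_peps$cys_positions[[i]]
      # loop-links within one peptide
      if (length(cys_i) >= 2L) {
        cpairs <- utils::combn(cys_i, 2L)
        for (q in seq_len(ncol(cpairs))) {
          add_row("loop", i, NA_integer_, cpairs[1, q], cpairs[2, q],
                  base_mass[i] - 2 * mod_delta_per_target + linker$delta_mass)
        }
      }
      # pairs, including a second copy of the same peptide (i == j)
      for (j in i:n) {
        cys_j <- cys_peps$cys_positions[[j]]
        for (ca in cys_i) for (cb in cys_j) {
          if (i == j && cb < ca) next  # unordered placements for self-pairs
          add_row("pair", i, j, ca, cb,
                  base_mass[i] + base_mass[j] - 2 * mod_delta_per_target +
                    linker$delta_mass)
        }
      }
    }
  }
  if (k == 0L) return(empty_candidate_table())
  out <- do.call(rbind, rows)
  ord <- order(out$pep_a_start, out$pep_a_end,
               ifelse(is.na(out$pep_b_start), -1L, out$pep_b_start),
               ifelse(is.na(out$pep_b_end), -1L, out$pep_b_end),
               out$cys_a, ifelse(is.na(out$cys_b), -1L, out$cys_b), out$kind)
  out <- out[ord, , drop = FALSE]
  out$candidate_id <- sprintf("cand_%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("candidate_id", setdiff(names(out), "candidate_id"))]
}

empty_candidate_table <- function() {
  data.frame(candidate_id = character(0), kind = character(0),
             pep_a_start = integer(0), pep_a_end = integer(0), pep_a = character(0),
             pep_b_start = integer(0), pep_b_end = integer(0), pep_b = character(0),
             cys_a = integer(0), cys_b = integer(0), linker = character(0),
             neutral_mass = numeric(0), stringsAsFactors = FALSE)
}

#' Match spectrum precursors against candidate masses (MS1)
#'
#' The observed neutral mass of each spectrum is `charge * mz - charge *
#' proton`; a candidate matches when `|ppm| <= ppm_tol` with
#' `ppm = 1e6 * (observed - theoretical) / theoretical`. Spectra without a
#' charge are skipped and logged.
#'
#' @param spectra List of spectrum records (see [read_mgf()]): each a list
#'   with `scan_id`, `precursor_mz`, `charge`, `peaks`.
#' @param candidates Candidate table from [enumerate_candidates()].
#' @param ppm_tol Precursor tolerance in ppm (default 10).
#' @return Data.frame `scan_id`, `candidate_id`, `observed_neutral_mass`,
#'   `theoretical_mass`, `ppm_error`, sorted by `|ppm_error|`; attribute
#'   `"skipped"` lists scans lacking a charge.
#' @export
match_precursors <- function(spectra, candidates, ppm_tol = 10) {
  stopifnot(is.data.frame(candidates), ppm_tol > 0)
  if (nrow(candidates) == 0L) stop("no candidates to match against")
  skipped <- character(0)
  res <- list(); k <- 0L
  theo <- candidates$neutral_mass
  for (sp in spectra) {
    if (is.null(sp$charge) || is.na(sp$charge)) {
      skipped <- c(skipped, sp$scan_id)
      next
    }
    obs <- mass_from_mz(sp$precursor_mz, sp$charge)
    ppm <- 1e6 * (obs - theo) / theo
    # 1e-9 ppm slack keeps precursors constructed exactly at +/- tol inclusive
    hit <- which(abs(ppm) <= ppm_tol + 1e-9)
    if (length(hit) > 0L) {
      k <- k + 1L
      res[[k]] <- data.frame(scan_id = sp$scan_id,
                             candidate_id = candidates$candidate_id[hit],
                             observed_neutral_mass = obs,
                             theoretical_mass = theo[hit],
                             ppm_error = ppm[hit], stringsAsFactors = FALSE)
    }
  }
  out <- if (k == 0L) {
    data.frame(scan_id = character(0), candidate_id = character(0),
               observed_neutral_mass = numeric(0), theoretical_mass = numeric(0),
               ppm_error = numeric(0), stringsAsFactors = FALSE)
  } else do.call(rbind, res)
  out <- out[order(abs(out$ppm_error)), , drop = FALSE]
  rownames(out) <- NULL
  if (length(skipped) > 0L) {
    message("skipped ", length(skipped), " spectrum/spectra without charge")
  }
  attr(out, "skipped") <- skipped
  out
}

#' Theoretical b/y fragment ladder of a crosslink candidate
#'
#' Non-cleavable-linker model: for each constituent peptide the b and y
#' series are generated with the partner peptide plus linker treated as a
#' fixed mass appended to the bridged cysteine. For loop-links only fragments
#' spanning neither or both bridged residues are kept (those spanning both
#' carry the linker delta). Fragment charges 1 and 2.
#'
#' @param candidate One row of a candidate table.
#' @param charges Fragment charge states (default 1:2).
#' @param fixed_mods Fixed modifications applied to non-bridged target
#'   residues (must match those used at enumeration).
#' @return Data.frame `peptide` (`a`/`b`), `ion` (e.g. `"b3"`), `charge`,
#'   `mz`.
#' @export
candidate_fragments <- function(candidate, charges = 1:2, fixed_mods = list()) {
  kind <- candidate$kind
  # reconstruct residue-level masses for a peptide, with per-residue fixed mods
  res_masses <- function(seq, bridged_local = integer(0)) {
    r <- strsplit(seq, "", fixed = TRUE)[[1]]
    m <- .RESIDUE_MASS[r]
    for (mod in fixed_mods) {
      idx <- which(r == mod$target_residue)
      idx <- setdiff(idx, bridged_local)
      m[idx] <- m[idx] + mod$delta_mass
    }
    m
  }
  frag_series <- function(m, label) {
    n <- length(m)
    if (n < 2L) return(NULL)
    bneutral <- cumsum(m)[1:(n - 1L)]
    yneutral <- rev(cumsum(rev(m)))[2:n] + WATER_MASS
    rows <- list()
    for (z in charges) {
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = label,
        ion = c(paste0("b", 1:(n - 1L)), paste0("y", (n - 1L):1)),
        charge = z,
        mz = c((bneutral + z * PROTON_MASS) / z,
               (yneutral + z * PROTON_MASS) / z),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }

  if (kind == "pair") {
    la <- candidate$cys_a - candidate$pep_a_start + 1L
    lb <- candidate$cys_b - candidate$pep_b_start + 1L
    ma <- res_masses(candidate$pep_a, la)
    mb <- res_masses(candidate$pep_b, lb)
    mass_a <- sum(ma) + WATER_MASS
    mass_b <- sum(mb) + WATER_MASS
    # linker delta recovered from mass additivity of the candidate
    delta <- candidate$neutral_mass - mass_a - mass_b
    ma[la] <- ma[la] + mass_b + delta
    mb[lb] <- mb[lb] + mass_a + delta
    out <- rbind(frag_series(ma, "a"), frag_series(mb, "b"))
  } else if (kind == "loop") {
    l1 <- candidate$cys_a - candidate$pep_a_start + 1L
    l2 <- candidate$cys_b - candidate$pep_a_start + 1L
    m <- res_masses(candidate$pep_a, c(l1, l2))
    delta <- candidate$neutral_mass - (sum(m) + WATER_MASS)
    n <- length(m)
    full <- frag_series(m, "a")
    if (is.null(full)) return(empty_fragment_table())
    idx <- as.integer(sub("^[by]", "", full$ion))
    is_b <- grepl("^b", full$ion)
    # prefix length spanned by the fragment
    span_lo <- ifelse(is_b, 1L, n - idx + 1L)
    span_hi <- ifelse(is_b, idx, n)
    covers1 <- span_lo <= l1 & l1 <= span_hi
    covers2 <- span_lo <= l2 & l2 <= span_hi
    keep <- (!covers1 & !covers2) | (covers1 & covers2)
    full$mz <- full$mz + ifelse(covers1 & covers2, delta / full$charge, 0)
    out <- full[keep, , drop = FALSE]
  } else { # mono
    la <- candidate$cys_a - candidate$pep_a_start + 1L
    m <- res_masses(candidate$pep_a, la)
    delta <- candidate$neutral_mass - (sum(m) + WATER_MASS)
    m[la] <- m[la] + delta
    out <- frag_series(m, "a")
  }
  if (is.null(out)) return(empty_fragment_table())
  rownames(out) <- NULL
  out
}

empty_fragment_table <- function() {
  data.frame(peptide = character(0), ion = character(0),
             charge = integer(0), mz = numeric(0), stringsAsFactors = FALSE)
}

#' Annotate MS2 fragments of a candidate in a spectrum
#'
#' Generates the theoretical ladder via [candidate_fragments()] and counts
#' theoretical fragments with at least one observed peak within `frag_ppm_tol`.
#' The score is the matched fraction of the theoretical ladder.
#'
#' @param spectrum One spectrum record.
#' @param candidate One row of a candidate table.
#' @param frag_ppm_tol Fragment tolerance in ppm (default 20).
#' @param fixed_mods Fixed modifications (as at enumeration).
#' @return One-row data.frame `scan_id`, `candidate_id`, `matched_fragments`,
#'   `theoretical_fragments`, `score`.
#' @export
annotate_fragments <- function(spectrum, candidate, frag_ppm_tol = 20,
                               fixed_mods = list()) {
  frags <- candidate_fragments(candidate, fixed_mods = fixed_mods)
  ntheo <- nrow(frags)
  peaks_mz <- if (is.null(spectrum$peaks) || nrow(spectrum$peaks) == 0L) {
    numeric(0)
  } else spectrum$peaks$mz
  if (ntheo == 0L || length(peaks_mz) == 0L) {
    return(data.frame(scan_id = spectrum$scan_id,
                      candidate_id = candidate$candidate_id,
                      matched_fragments = 0L, theoretical_fragments = ntheo,
                      score = 0, stringsAsFactors = FALSE))
  }
  sorted <- sort(peaks_mz)
  matched <- vapply(frags$mz, function(mz) {
    tol <- mz * frag_ppm_tol * 1e-6
    i <- findInterval(mz, sorted)
    (i >= 1L && mz - sorted[i] <= tol) ||
      (i < length(sorted) && sorted[i + 1L] - mz <= tol)
  }, logical(1))
  data.frame(scan_id = spectrum$scan_id, candidate_id = candidate$candidate_id,
             matched_fragments = sum(matched), theoretical_fragments = ntheo,
             score = sum(matched) / ntheo, stringsAsFactors = FALSE)
}

#' End-to-end crosslink search
#'
#' Digest, select cysteine peptides, enumerate candidates (bridge pass plus an
#' optional mono-adduct pass), match precursors at MS1, annotate fragments at
#' MS2 and rank the results.
#'
#' @param proteins Named character vector of protein sequences (e.g. from
#'   [read_fasta()]).
#' @param spectra Spectrum list (e.g. from [read_mgf()]).
#' @param linker A [linker_spec()] (the bridge chemistry).
#' @param mono_linker Optional mono-adduct [linker_spec()] for a second pass.
#' @param fixed_mods Fixed modifications for non-bridged cysteines.
#' @param max_missed,min_len,max_len Digestion parameters.
#' @param ms1_ppm,ms2_ppm Precursor / fragment tolerances in ppm.
#' @return Data.frame report, one row per MS1 match annotated at MS2, ranked
#'   by score (descending) then `|ppm_error|`: candidate columns plus
#'   `scan_id`, `observed_neutral_mass`, `ppm_error`, `matched_fragments`,
#'   `theoretical_fragments`, `score`.
#' @export
xl_search <- function(proteins, spectra, linker = sfn_bridge_linker(),
                      mono_linker = NULL, fixed_mods = list(),
                      max_missed = 3, min_len = 4, max_len = 60,
                      ms1_ppm = 10, ms2_ppm = 20) {
  cands <- list()
  for (id in names(proteins)) {
    peps <- digest_trypsin(list(id = id, residues = proteins[[id]]),
                           max_missed = max_missed, min_len = min_len,
                           max_len = max_len)
    cp <- cysteine_peptides(peps)
    if (nrow(cp) == 0L) next
    cands[[length(cands) + 1L]] <- enumerate_candidates(cp, linker, fixed_mods)
    if (!is.null(mono_linker)) {
      cands[[length(cands) + 1L]] <-
        enumerate_candidates(cp, mono_linker, fixed_mods)
    }
  }
  if (length(cands) == 0L) return(empty_search_report())
  candidates <- do.call(rbind, cands)
  candidates$candidate_id <- sprintf("cand_%05d", seq_len(nrow(candidates)))

  ms1 <- match_precursors(spectra, candidates, ppm_tol = ms1_ppm)
  if (nrow(ms1) == 0L) return(empty_search_report())
  spec_by_id <- stats::setNames(spectra, vapply(spectra, `[[`, character(1), "scan_id"))
  ann <- do.call(rbind, lapply(seq_len(nrow(ms1)), function(i) {
    cand <- candidates[candidates$candidate_id == ms1$candidate_id[i], , drop = FALSE]
    annotate_fragments(spec_by_id[[ms1$scan_id[i]]], cand,
                       frag_ppm_tol = ms2_ppm, fixed_mods = fixed_mods)
  }))
  rep <- cbind(ms1, ann[, c("matched_fragments", "theoretical_fragments", "score")])
  rep <- merge(rep, candidates, by = "candidate_id", sort = FALSE)
  rep <- rep[order(-rep$score, abs(rep$ppm_error)), , drop = FALSE]
  rownames(rep) <- NULL
  rep
}

empty_search_report <- function() {
  data.frame(candidate_id = character(0), scan_id = character(0),
             observed_neutral_mass = numeric(0), theoretical_mass = numeric(0),
             ppm_error = numeric(0), matched_fragments = integer(0),
             theoretical_fragments = integer(0), score = numeric(0),
             stringsAsFactors = FALSE)
}
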
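#' Simulation configuration
#'
#' One seeded configuration object drives every generator; each generator
#' draws from its own named stream derived from the master seed, so changing
#' e.g. the spectra parameters never perturbs the count simulation.
#'
#' Count defaults emulate the adduct-mapping screen design: 4 replicates per
#' group, 100 proteins of which 10 are truly enriched at an 8-fold Poisson
#' mean ratio (treated mean 16 vs control mean 2). Spectra defaults emulate
#' desk-scale Orbitrap crosslink runs (5 ppm precursor jitter, 100 noise
#' peaks per spectrum). Decay defaults emulate the SFX-01 inhibition
#' dose series (0.007-1.75 uM).
#'
#' @param seed Master integer seed.
#' @param ... Named overrides of the defaults (see source for fields).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # PSM counts
    n_proteins = 100L, n_enriched = 10L,
    count_model = "poisson", nb_size = 4,
    baseline_mean = 2, fold_change = 8,
    n_replicates_per_group = 4L,
    peptide_prob_fail_fraction = 0.05,
    protein_prob_fail_fraction = 0.02,
    # spectra
    n_planted_crosslinks = 10L, noise_peaks_per_spectrum = 100L,
    ppm_jitter_sd = 5, fragment_dropout_fraction = 0.2,
    n_decoy_spectra = 20L,
    # dose-response
    decay_y0 = 100, decay_plateau = 10, decay_k = 2,
    decay_noise_sd = 1, n_doses = 8L,
    dose_min = 0.007, dose_max = 1.75
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  stopifnot(cfg$n_enriched <= cfg$n_proteins, cfg$baseline_mean > 0,
            cfg$fold_change > 0, cfg$n_replicates_per_group >= 2,
            cfg$decay_k >= 0, cfg$count_model %in% c("poisson", "negative_binomial"))
  structure(cfg, class = "sim_config")
}

# one named pseudo-random stream per generator, derived from the master seed
stream_seed <- function(seed, stream) {
  offset <- c(psm = 1L, fasta = 2L, spectra = 3L, decay = 4L)[[stream]]
  as.integer((as.numeric(seed) * 1009 + offset * 7919) %% 2147483629)
}

#' Simulate a PSM identification table with planted enrichment
#'
#' Per protein per sample, PSM counts are drawn from the configured count
#' model; the `n_enriched` planted proteins use `baseline_mean * fold_change`
#' in the treated group. Peptide probabilities are drawn so that
#' `peptide_prob_fail_fraction` of rows fail the printed >90% filter, and
#' `protein_prob_fail_fraction` of proteins fail the >99.9% filter. The table
#' is expanded to one row per PSM.
#'
#' @param config A [sim_config()].
#' @return List with `psms` (PSM table data.frame), `design` (the
#'   [group_design()]) and `truth` (list with `enriched_protein_ids`).
#' @export
gen_psm_table <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, "psm"))
  nrep <- config$n_replicates_per_group
  design <- group_design(sprintf("ctrl_%d", seq_len(nrep)),
                         sprintf("trt_%d", seq_len(nrep)))
  ids <- sprintf("P%04d", seq_len(config$n_proteins))
  enriched <- ids[seq_len(config$n_enriched)]

  draw <- function(n, mean) {
    if (config$count_model == "poisson") stats::rpois(n, mean)
    else stats::rnbinom(n, size = config$nb_size, mu = mean)
  }

  prot_prob <- ifelse(stats::runif(length(ids)) < config$protein_prob_fail_fraction,
                      stats::runif(length(ids), 0.99, 0.999),
                      stats::runif(length(ids), 0.9991, 1))
  names(prot_prob) <- ids

  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    tmean <- config$baseline_mean *
      (if (id %in% enriched) config$fold_change else 1)
    counts <- c(draw(nrep, config$baseline_mean), draw(nrep, tmean))
    samples <- c(design$control, design$treated)
    groups <- rep(c("control", "treated"), each = nrep)
    npsm <- sum(counts)
    if (npsm == 0L) next
    rows[[i]] <- data.frame(
      protein_id = id,
      sample_id = rep(samples, counts),
      group = rep(groups, counts),
      peptide_probability = NA_real_,
      protein_probability = prot_prob[[id]],
      stringsAsFactors = FALSE
    )
  }
  psms <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  fail <- stats::runif(nrow(psms)) < config$peptide_prob_fail_fraction
  psms$peptide_probability <- ifelse(fail,
                                     stats::runif(nrow(psms), 0.5, 0.9),
                                     stats::runif(nrow(psms), 0.901, 1))
  rownames(psms) <- NULL
  list(psms = psms, design = design,
       truth = list(enriched_protein_ids = enriched))
}

#' Simulate random protein sequences
#'
#' Sequences over the canonical alphabet with a stated expected cysteine
#' fraction (each position is C with probability `cys_fraction`, otherwise
#' drawn uniformly from the other 19 residues). A user-supplied real sequence
#' can be appended as an extra record.
#'
#' @param n Number of random proteins.
#' @param length Sequence length (>= 10).
#' @param cys_fraction Expected fraction of cysteines.
#' @param seed Integer seed.
#' @param include Optional named character vector of extra records to append.
#' @return Named character vector of sequences.
#' @export
gen_protein_fasta <- function(n, length, cys_fraction = 0.02, seed = 1L,
                              include = NULL) {
  stopifnot(length >= 10, cys_fraction >= 0, cys_fraction <= 1)
  set.seed(stream_seed(seed, "fasta"))
  non_cys <- setdiff(canonical_residues(), "C")
  seqs <- vapply(seq_len(n), function(i) {
    res <- sample(non_cys, length, replace = TRUE)
    res[stats::runif(length) < cys_fraction] <- "C"
    paste(res, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("SYN%03d", seq_len(n))
  c(seqs, include)
}

#' Synthetic Shp2-like protein sequence
#'
#' A 593-residue SYNTHETIC stand-in for human Shp2 built for the worked
#' crosslink example: cysteines are placed at the reported coordinates 333,
#' 367 and 459 and tryptic sites are arranged so that the Cys333 and Cys367
#' peptides are distinct and reachable at <= 3 missed cleavages. It is not
#' the real Q06124 sequence; supply a real FASTA via [read_fasta()] to run
#' the search on the canonical protein.
#'
#' @return Named character vector with one record `SHP2_SYNTHETIC`.
#' @export
shp2_like_sequence <- function() {
  n <- 593L
  cys_at <- c(333L, 367L, 459L)
  base_seed <- 573L
  for (attempt in 0:50) {
    set.seed(base_seed + attempt)
    pool <- setdiff(canonical_residues(), c("C", "K", "R", "P"))
    res <- sample(pool, n, replace = TRUE)
    # tryptic sites roughly every 9 residues
    sites <- seq(9L, n - 5L, by = 9L)
    res[sites] <- sample(c("K", "R"), length(sites), replace = TRUE)
    res[cys_at] <- "C"
    seqs <- c(SHP2_SYNTHETIC = paste(res, collapse = ""))
    peps <- digest_trypsin(list(id = "SHP2_SYNTHETIC", residues = seqs[[1]]))
    cp <- cysteine_peptides(peps)
    has333 <- any(vapply(cp$cys_positions, function(p) 333L %in% p, logical(1)))
    has367 <- any(vapply(cp$cys_positions, function(p) 367L %in% p, logical(1)))
    distinct <- any(vapply(seq_len(nrow(cp)), function(i) {
      333L %in% cp$cys_positions[[i]] && !(367L %in% cp$cys_positions[[i]])
    }, logical(1)))
    if (has333 && has367 && distinct) return(seqs)
  }
  stop("failed to construct a synthetic Shp2-like sequence")
}

#' Simulate crosslink MS spectra with planted candidates
#'
#' Digests the supplied proteins, enumerates bridge candidates, plants
#' `n_planted_crosslinks` of them as spectra (precursor at the theoretical
#' m/z plus Gaussian ppm jitter, charge sampled from 2-4, b/y fragment peaks
#' with the configured dropout, uniform noise peaks) and adds
#' `n_decoy_spectra` pure-noise spectra.
#'
#' @param proteins Named character vector of protein sequences.
#' @param linker A bridge [linker_spec()].
#' @param config A [sim_config()].
#' @return List with `spectra` (spectrum list), `truth` (data.frame of
#'   planted scans: `scan_id`, `pep_a`, `pep_b`, `cys_a`, `cys_b`,
#'   `neutral_mass`, `charge`) and `candidates` (the full candidate table).
#' @export
gen_crosslink_spectra <- function(proteins, linker = sfn_bridge_linker(),
                                  config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, "spectra"))
  cands <- list()
  for (id in names(proteins)) {
    peps <- digest_trypsin(list(id = id, residues = proteins[[id]]))
    cp <- cysteine_peptides(peps)
    if (nrow(cp) > 0L) cands[[length(cands) + 1L]] <- enumerate_candidates(cp, linker)
  }
  if (length(cands) == 0L) stop("no crosslink candidates can be planted")
  candidates <- do.call(rbind, cands)
  candidates$candidate_id <- sprintf("cand_%05d", seq_len(nrow(candidates)))
  if (nrow(candidates) < config$n_planted_crosslinks) {
    stop("only ", nrow(candidates), " candidates available; cannot plant ",
         config$n_planted_crosslinks)
  }
  picked <- sort(sample.int(nrow(candidates), config$n_planted_crosslinks))

  spectra <- list()
  truth <- vector("list", length(picked))
  for (i in seq_along(picked)) {
    cand <- candidates[picked[i], , drop = FALSE]
    z <- sample(2:4, 1L)
    jitter_ppm <- stats::rnorm(1L, 0, config$ppm_jitter_sd)
    mz <- mz_from_mass(cand$neutral_mass, z) * (1 + jitter_ppm * 1e-6)
    frags <- candidate_fragments(cand)
    keep <- stats::runif(nrow(frags)) >= config$fragment_dropout_fraction
    fmz <- frags$mz[keep]
    fint <- stats::runif(sum(keep), 1e3, 1e5)
    nz <- config$noise_peaks_per_spectrum
    nmz <- stats::runif(nz, 200, 2000)
    nint <- stats::runif(nz, 10, 1e3)
    ord <- order(c(fmz, nmz))
    scan_id <- sprintf("planted_%03d", i)
    spectra[[length(spectra) + 1L]] <- list(
      scan_id = scan_id, precursor_mz = mz, charge = z,
      peaks = data.frame(mz = c(fmz, nmz)[ord], intensity = c(fint, nint)[ord]))
    truth[[i]] <- data.frame(
      scan_id = scan_id, pep_a = cand$pep_a, pep_b = cand$pep_b,
      cys_a = cand$cys_a, cys_b = cand$cys_b,
      neutral_mass = cand$neutral_mass, charge = z, stringsAsFactors = FALSE)
  }
  for (j in seq_len(config$n_decoy_spectra)) {
    nz <- config$noise_peaks_per_spectrum
    nmz <- sort(stats::runif(nz, 200, 2000))
    spectra[[length(spectra) + 1L]] <- list(
      scan_id = sprintf("decoy_%03d", j),
      precursor_mz = stats::runif(1, 400, 1600),
      charge = sample(2:4, 1L),
      peaks = data.frame(mz = nmz, intensity = stats::runif(nz, 10, 1e3)))
  }
  list(spectra = spectra, truth = do.call(rbind, truth), candidates = candidates)
}

#' Score planted-crosslink recovery
#'
#' A planted scan is recovered when the MS1 match list pairs it with a
#' candidate carrying the same bridged cysteine coordinates.
#'
#' @param report A search report (from [xl_search()]) or MS1 match table
#'   joined to candidates, i.e. containing `scan_id`, `cys_a`, `cys_b`.
#' @param truth Truth table from [gen_crosslink_spectra()].
#' @return Fraction of planted scans recovered.
#' @export
score_crosslink_recovery <- function(report, truth) {
  if (nrow(truth) == 0L) return(NA_real_)
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(report$scan_id == truth$scan_id[i] &
          report$cys_a == truth$cys_a[i] &
          report$cys_b == truth$cys_b[i])
  }, logical(1))
  mean(hit)
}

#' Simulate a one-phase decay dose-response table
#'
#' `Y(c) = plateau + (y0 - plateau) * exp(-k c)` plus Gaussian noise, over a
#' dose series of zero plus log-spaced concentrations.
#'
#' @param config A [sim_config()].
#' @return Data.frame `concentration_uM`, `value`; attribute `"truth"` holds
#'   the generating parameters.
#' @export
gen_dose_response <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, "decay"))
  doses <- c(0, 10^seq(log10(config$dose_min), log10(config$dose_max),
                       length.out = config$n_doses - 1L))
  y <- config$decay_plateau +
    (config$decay_y0 - config$decay_plateau) * exp(-config$decay_k * doses)
  y <- y + stats::rnorm(length(doses), 0, config$decay_noise_sd)
  out <- data.frame(concentration_uM = doses, value = y)
  attr(out, "truth") <- list(y0 = config$decay_y0, plateau = config$decay_plateau,
                             k = config$decay_k)
  out
}
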
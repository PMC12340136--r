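# Crosslink candidate enumeration, MS1 matching, MS2 annotation

cys_peps_of <- function(seq, ...) {
  cysteine_peptides(digest_trypsin(seq, ...))
}

test_that("no cysteines means no candidates, with a warning for bridges", {
  cp <- cys_peps_of("MADEFGKLSTVEGHK", min_len = 1)
  expect_equal(nrow(cp), 0L)
  expect_warning(out <- enumerate_candidates(cp, sfn_bridge_linker()), "no cysteine")
  expect_equal(nrow(out), 0L)
})

test_that("pair neutral mass is the summed peptide masses plus the linker delta", {
  cp <- cys_peps_of("ACDEFKLCSTVK", min_len = 1, max_missed = 0)
  expect_equal(nrow(cp), 2L)
  linker <- linker_spec("test_bridge", 41.956421, "bridge")
  cand <- enumerate_candidates(cp, linker)
  pairs <- cand[cand$kind == "pair" & cand$pep_a != cand$pep_b, ]
  expect_equal(pairs$neutral_mass,
               peptide_monoisotopic_mass("ACDEFK") +
                 peptide_monoisotopic_mass("LCSTVK") + 41.956421,
               tolerance = 1e-9)
  # mass additivity invariant holds for every emitted pair
  for (i in seq_len(nrow(cand))) {
    row <- cand[i, ]
    if (row$kind == "pair") {
      expect_equal(row$neutral_mass - peptide_monoisotopic_mass(row$pep_a) -
                     peptide_monoisotopic_mass(row$pep_b),
                   linker$delta_mass, tolerance = 1e-9)
    }
  }
})

test_that("candidate count for n single-Cys peptides is n(n+1)/2", {
  # independent exhaustive count: pairs i <= j, one Cys each, no loops
  for (seq in list("ACDEFKLCSTVKGCDDWK", "ACDEFKLCSTVK")) {
    cp <- cys_peps_of(seq, min_len = 1, max_missed = 0)
    expect_true(all(cp$n_cys == 1L))
    n <- nrow(cp)
    cand <- enumerate_candidates(cp, sfn_bridge_linker())
    expect_equal(nrow(cand), n * (n + 1) / 2)
    expect_true(all(cand$kind == "pair"))
  }
})

test_that("loop-links are enumerated for peptides with two or more cysteines", {
  cp <- cys_peps_of("ACDCEFCK", min_len = 1, max_missed = 0)
  expect_equal(cp$n_cys, 3L)
  cand <- enumerate_candidates(cp, sfn_bridge_linker())
  loops <- cand[cand$kind == "loop", ]
  expect_equal(nrow(loops), 3L) # choose(3, 2) cys pairs
  expect_true(all(loops$cys_a < loops$cys_b))
  expect_equal(loops$neutral_mass,
               rep(peptide_monoisotopic_mass("ACDCEFCK") +
                     dithiolethione_bridge_mass(), 3),
               tolerance = 1e-9)
})

test_that("mono-adduct enumeration places the delta on each cysteine", {
  cp <- cys_peps_of("ACDCEFK", min_len = 1, max_missed = 0)
  cand <- enumerate_candidates(cp, sfn_monoadduct_linker())
  expect_equal(nrow(cand), 2L)
  expect_true(all(cand$kind == "mono"))
  expect_equal(cand$neutral_mass,
               rep(peptide_monoisotopic_mass("ACDCEFK") + sfn_monoadduct_mass(), 2),
               tolerance = 1e-9)
})

test_that("fixed mods cap non-bridged cysteines only", {
  mal <- maleimide_mod()
  cp <- cys_peps_of("ACDCEFK", min_len = 1, max_missed = 0) # two Cys
  cand <- enumerate_candidates(cp, sfn_monoadduct_linker(), fixed_mods = list(mal))
  # one Cys carries the adduct, the other is capped
  expect_equal(cand$neutral_mass,
               rep(peptide_monoisotopic_mass("ACDCEFK") + sfn_monoadduct_mass() +
                     mal$delta_mass, 2),
               tolerance = 1e-9)
  loop <- enumerate_candidates(cp, sfn_bridge_linker(), fixed_mods = list(mal))
  loop <- loop[loop$kind == "loop", ]
  # both Cys bridged: no capping at all
  expect_equal(loop$neutral_mass,
               peptide_monoisotopic_mass("ACDCEFK") + dithiolethione_bridge_mass(),
               tolerance = 1e-9)
})

make_spectrum <- function(scan_id, mz, charge, peaks_mz = numeric(0),
                          intensity = NULL) {
  if (is.null(intensity)) intensity <- rep(100, length(peaks_mz))
  ord <- order(peaks_mz)
  list(scan_id = scan_id, precursor_mz = mz, charge = charge,
       peaks = data.frame(mz = peaks_mz[ord], intensity = intensity[ord]))
}

test_that("MS1 matching is exact at construction and tight at the tolerance", {
  cp <- cys_peps_of("ACDEFKLCSTVK", min_len = 1, max_missed = 0)
  cand <- enumerate_candidates(cp, sfn_bridge_linker())
  m0 <- cand$neutral_mass[1]
  sp_exact <- make_spectrum("s1", mz_from_mass(m0, 3), 3)
  hit <- match_precursors(list(sp_exact), cand, ppm_tol = 10)
  expect_true(cand$candidate_id[1] %in% hit$candidate_id)
  expect_equal(hit$ppm_error[hit$candidate_id == cand$candidate_id[1]], 0,
               tolerance = 1e-9)

  # +20 ppm offset at 10 ppm tolerance: no match
  sp_off <- make_spectrum("s2", mz_from_mass(m0 * (1 + 20e-6), 3), 3)
  hit <- match_precursors(list(sp_off), cand, ppm_tol = 10)
  expect_false(any(hit$scan_id == "s2" & hit$candidate_id == cand$candidate_id[1]))

  # symmetric and inclusive at +/- tol; exclusive just outside
  for (sgn in c(-1, 1)) {
    at_tol <- make_spectrum("t", mz_from_mass(m0 * (1 + sgn * 10e-6), 2), 2)
    beyond <- make_spectrum("u", mz_from_mass(m0 * (1 + sgn * 10.5e-6), 2), 2)
    expect_true(cand$candidate_id[1] %in%
                  match_precursors(list(at_tol), cand, 10)$candidate_id)
    expect_false(cand$candidate_id[1] %in%
                   match_precursors(list(beyond), cand, 10)$candidate_id)
  }
})

test_that("spectra without charge are skipped and logged", {
  cp <- cys_peps_of("ACDEFKLCSTVK", min_len = 1, max_missed = 0)
  cand <- enumerate_candidates(cp, sfn_bridge_linker())
  sp <- make_spectrum("nochg", 500, NA)
  expect_message(hit <- match_precursors(list(sp), cand), "without charge")
  expect_equal(attr(hit, "skipped"), "nochg")
})

test_that("MS1 recovery equals a brute-force all-pairs ppm scan", {
  set.seed(31)
  prot <- gen_protein_fasta(3, 120, cys_fraction = 0.05, seed = 31)
  cands <- do.call(rbind, lapply(names(prot), function(id) {
    enumerate_candidates(cys_peps_of(prot[[id]]), sfn_bridge_linker())
  }))
  cands$candidate_id <- sprintf("c%04d", seq_len(nrow(cands)))
  # 50 planted precursors (small jitter) among 500 noise precursors
  planted <- sample(nrow(cands), min(50, nrow(cands)))
  spectra <- c(
    lapply(seq_along(planted), function(i) {
      z <- sample(2:4, 1)
      jit <- 1 + rnorm(1, 0, 4e-6)
      make_spectrum(paste0("p", i),
                    mz_from_mass(cands$neutral_mass[planted[i]], z) * jit, z)
    }),
    lapply(1:500, function(i) {
      make_spectrum(paste0("n", i), runif(1, 300, 1500), sample(2:4, 1))
    }))
  got <- match_precursors(spectra, cands, ppm_tol = 10)
  # brute force: every candidate x spectrum comparison
  brute <- list()
  for (sp in spectra) {
    obs <- sp$charge * sp$precursor_mz - sp$charge * PROTON_MASS
    for (i in seq_len(nrow(cands))) {
      ppm <- 1e6 * (obs - cands$neutral_mass[i]) / cands$neutral_mass[i]
      if (abs(ppm) <= 10) {
        brute[[length(brute) + 1L]] <- paste(sp$scan_id, cands$candidate_id[i])
      }
    }
  }
  expect_setequal(paste(got$scan_id, got$candidate_id), unlist(brute))
})

test_that("b/y ladder of a 3-residue pair matches the prefix/suffix oracle", {
  cp <- cys_peps_of("CAKGCK", min_len = 1, max_missed = 0)
  linker <- linker_spec("d", 41.956421, "bridge")
  cand <- enumerate_candidates(cp, linker)
  pair <- cand[cand$kind == "pair" & cand$pep_a == "CAK" & cand$pep_b == "GCK", ]
  expect_equal(nrow(pair), 1L)
  frags <- candidate_fragments(pair)
  mass_a <- peptide_monoisotopic_mass("CAK")
  mass_b <- peptide_monoisotopic_mass("GCK")
  for (z in 1:2) {
    ora <- oracle_by_ladder("CAK", z, extra_on = 1,
                            extra_mass = mass_b + 41.956421)
    fa <- frags[frags$peptide == "a" & frags$charge == z, ]
    expect_equal(fa$mz[grepl("^b", fa$ion)][order(as.integer(sub("b", "", fa$ion[grepl("^b", fa$ion)])))],
                 unname(ora$b), tolerance = 1e-6)
    orb <- oracle_by_ladder("GCK", z, extra_on = 2,
                            extra_mass = mass_a + 41.956421)
    fb <- frags[frags$peptide == "b" & frags$charge == z, ]
    expect_equal(sort(fb$mz[grepl("^y", fb$ion)]), sort(unname(orb$y)),
                 tolerance = 1e-6)
  }
})

test_that("loop-link fragments span neither or both bridged residues", {
  cp <- cys_peps_of("ACDCEFK", min_len = 1, max_missed = 0)
  cand <- enumerate_candidates(cp, sfn_bridge_linker())
  loop <- cand[cand$kind == "loop", ]
  frags <- candidate_fragments(loop)
  idx <- as.integer(sub("^[by]", "", frags$ion))
  is_b <- grepl("^b", frags$ion)
  n <- nchar("ACDCEFK")
  lo <- ifelse(is_b, 1L, n - idx + 1L); hi <- ifelse(is_b, idx, n)
  c1 <- lo <= 2 & 2 <= hi; c2 <- lo <= 4 & 4 <= hi
  expect_true(all((c1 & c2) | (!c1 & !c2)))
  # fragments spanning both carry the bridge delta
  b5 <- frags$mz[frags$ion == "b5" & frags$charge == 1]
  plain_b5 <- sum(residue_masses()[strsplit("ACDCE", "")[[1]]]) + PROTON_MASS
  expect_equal(b5, plain_b5 + dithiolethione_bridge_mass(), tolerance = 1e-6)
})

test_that("a complete noiseless ladder scores 1 and empty peaks score 0", {
  cp <- cys_peps_of("ACDEFKLCSTVK", min_len = 1, max_missed = 0)
  cand <- enumerate_candidates(cp, sfn_bridge_linker())
  pair <- cand[cand$kind == "pair" & cand$pep_a != cand$pep_b, ][1, ]
  frags <- candidate_fragments(pair)
  sp <- make_spectrum("full", mz_from_mass(pair$neutral_mass, 3), 3, frags$mz)
  ann <- annotate_fragments(sp, pair)
  expect_equal(ann$score, 1)
  expect_equal(ann$matched_fragments, ann$theoretical_fragments)

  empty <- make_spectrum("empty", mz_from_mass(pair$neutral_mass, 3), 3)
  ann0 <- annotate_fragments(empty, pair)
  expect_equal(ann0$score, 0)
  expect_equal(ann0$matched_fragments, 0L)
})

test_that("pure-noise spectra score below 0.05 on average at 20 ppm", {
  cp <- cys_peps_of("ACDEFKLCSTVK", min_len = 1, max_missed = 0)
  cand <- enumerate_candidates(cp, sfn_bridge_linker())
  pair <- cand[cand$kind == "pair" & cand$pep_a != cand$pep_b, ][1, ]
  scores <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    noise <- runif(100, 200, 2000)
    sp <- make_spectrum("noise", mz_from_mass(pair$neutral_mass, 3), 3, noise)
    annotate_fragments(sp, pair, frag_ppm_tol = 20)$score
  }, numeric(1))
  expect_lt(mean(scores), 0.05)
})

test_that("end-to-end search ranks a planted crosslink first", {
  prot <- shp2_like_sequence()
  cfg <- sim_config(seed = 5, n_planted_crosslinks = 3L,
                    ppm_jitter_sd = 0, fragment_dropout_fraction = 0,
                    noise_peaks_per_spectrum = 50L, n_decoy_spectra = 5L)
  sim <- gen_crosslink_spectra(prot, config = cfg)
  rep <- xl_search(prot, sim$spectra)
  expect_gt(nrow(rep), 0L)
  top <- rep[1, ]
  expect_true(any(sim$truth$scan_id == top$scan_id &
                    sim$truth$cys_a == top$cys_a &
                    sim$truth$cys_b == top$cys_b))
  expect_equal(top$score, 1)
})

test_that("a search with nothing in tolerance returns an empty report", {
  prot <- c(SYN = "ACDEFKLCSTVK")
  sp <- list(make_spectrum("far", 5000, 2))
  rep <- xl_search(prot, sp, min_len = 1)
  expect_equal(nrow(rep), 0L)
})

test_that("the synthetic Shp2-like search recovers the 333/367 bridge", {
  prot <- shp2_like_sequence()
  peps <- digest_trypsin(list(id = names(prot), residues = prot[[1]]))
  cand <- enumerate_candidates(cysteine_peptides(peps), sfn_bridge_linker())
  bridge <- cand[cand$cys_a == 333 & cand$cys_b == 367, ]
  expect_gte(nrow(bridge), 1L)
  # synthesize a precursor at the bridge mass and find it end to end
  sp <- make_spectrum("bridge_scan", mz_from_mass(bridge$neutral_mass[1], 3), 3,
                      candidate_fragments(bridge[1, ])$mz)
  rep <- xl_search(prot, list(sp))
  expect_true(any(rep$cys_a == 333 & rep$cys_b == 367 &
                    rep$scan_id == "bridge_scan"))
})

test_that("fixed seed gives a byte-identical search report", {
  prot <- shp2_like_sequence()
  cfg <- sim_config(seed = 9, n_planted_crosslinks = 3L, n_decoy_spectra = 3L)
  r1 <- xl_search(prot, gen_crosslink_spectra(prot, config = cfg)$spectra)
  r2 <- xl_search(prot, gen_crosslink_spectra(prot, config = cfg)$spectra)
  f1 <- tempfile(); f2 <- tempfile()
  write_tsv_table(r1, f1); write_tsv_table(r2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
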
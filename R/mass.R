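#' Monoisotopic elemental masses (Da)
#'
#' Masses of the most abundant isotope of each element used in peptide and
#' small-molecule arithmetic, plus the proton mass used for m/z conversion.
#'
#' @format Named numeric vector (Da).
#' @export
ELEMENT_MONO <- c(
  H = 1.00782503207,
  C = 12.0,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

#' @rdname ELEMENT_MONO
#' @export
PROTON_MASS <- 1.007276466879

#' @rdname ELEMENT_MONO
#' @export
WATER_MASS <- 2 * ELEMENT_MONO[["H"]] + ELEMENT_MONO[["O"]]

# Residue elemental compositions (C, H, N, O, S) of the 20 canonical amino
# acid residues (i.e. amino acid minus water, as incorporated in a chain).
.RESIDUE_FORMULA <- list(
  G = c(C = 2,  H = 3,  N = 1, O = 1, S = 0),
  A = c(C = 3,  H = 5,  N = 1, O = 1, S = 0),
  S = c(C = 3,  H = 5,  N = 1, O = 2, S = 0),
  P = c(C = 5,  H = 7,  N = 1, O = 1, S = 0),
  V = c(C = 5,  H = 9,  N = 1, O = 1, S = 0),
  T = c(C = 4,  H = 7,  N = 1, O = 2, S = 0),
  C = c(C = 3,  H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6,  H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6,  H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4,  H = 6,  N = 2, O = 2, S = 0),
  D = c(C = 4,  H = 5,  N = 1, O = 3, S = 0),
  Q = c(C = 5,  H = 8,  N = 2, O = 2, S = 0),
  K = c(C = 6,  H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5,  H = 7,  N = 1, O = 3, S = 0),
  M = c(C = 5,  H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6,  H = 7,  N = 3, O = 1, S = 0),
  F = c(C = 9,  H = 9,  N = 1, O = 1, S = 0),
  R = c(C = 6,  H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9,  H = 9,  N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

#' Mass of an elemental composition
#'
#' @param formula Named integer vector of element counts, names in
#'   `names(ELEMENT_MONO)`.
#' @return Monoisotopic mass in Da.
#' @examples
#' formula_mass(c(C = 6, H = 11, N = 1, O = 1, S = 2)) # sulforaphane
#' @export
formula_mass <- function(formula) {
  stopifnot(all(names(formula) %in% names(ELEMENT_MONO)))
  sum(ELEMENT_MONO[names(formula)] * formula)
}

#' Monoisotopic residue masses of the canonical amino acids
#'
#' @return Named numeric vector of the 20 residue masses in Da, derived from
#'   the elemental table.
#' @export
residue_masses <- function() {
  vapply(.RESIDUE_FORMULA, formula_mass, numeric(1))
}

.RESIDUE_MASS <- vapply(.RESIDUE_FORMULA, formula_mass, numeric(1))

#' Canonical amino-acid alphabet
#' @return Character vector of the 20 one-letter residue codes.
#' @export
canonical_residues <- function() names(.RESIDUE_FORMULA)

#' Monoisotopic mass of a peptide sequence
#'
#' Sum of residue masses plus one water; modifications are added per
#' occurrence of their target residue (fixed mods) or as explicit deltas.
#'
#' @param sequence Peptide string over the canonical alphabet.
#' @param mods Optional list of modification specs (see
#'   [modification_spec()]); `fixed` mods are applied to every occurrence of
#'   their target residue.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_monoisotopic_mass("G") # 75.03203
#' @export
peptide_monoisotopic_mass <- function(sequence, mods = list()) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  unknown <- setdiff(res, names(.RESIDUE_MASS))
  if (length(unknown) > 0L) {
    stop("unknown residue(s) in peptide '", sequence, "': ",
         paste(unknown, collapse = ", "))
  }
  m <- sum(.RESIDUE_MASS[res]) + WATER_MASS
  for (mod in mods) {
    stopifnot(inherits(mod, "modification_spec"))
    if (identical(mod$mode, "fixed")) {
      m <- m + mod$delta_mass * sum(res == mod$target_residue)
    }
  }
  m
}

#' m/z of a neutral mass at a given charge
#'
#' @param neutral_mass Neutral monoisotopic mass (Da).
#' @param charge Positive integer charge state.
#' @return m/z value `(neutral_mass + charge * proton) / charge`.
#' @export
mz_from_mass <- function(neutral_mass, charge) {
  if (any(charge < 1) || any(charge != as.integer(charge))) {
    stop("charge must be a positive integer, got ", paste(charge, collapse = ","))
  }
  (neutral_mass + charge * PROTON_MASS) / charge
}

#' Neutral mass from an observed m/z and charge
#'
#' Inverse of [mz_from_mass()].
#' @param mz Observed m/z.
#' @param charge Positive integer charge state.
#' @return Neutral monoisotopic mass in Da.
#' @export
mass_from_mz <- function(mz, charge) {
  if (any(charge < 1)) stop("charge must be a positive integer")
  charge * mz - charge * PROTON_MASS
}

#' Define a residue modification
#'
#' @param name Modification name.
#' @param delta_mass Mass shift in Da.
#' @param target_residue One-letter code of the modified residue.
#' @param mode `"fixed"` (applied to every target residue) or `"variable"`.
#' @return A `modification_spec` object.
#' @export
modification_spec <- function(name, delta_mass, target_residue, mode = c("fixed", "variable")) {
  mode <- match.arg(mode)
  stopifnot(is.finite(delta_mass), target_residue %in% canonical_residues())
  structure(list(name = name, delta_mass = delta_mass,
                 target_residue = target_residue, mode = mode),
            class = "modification_spec")
}

#' Sulforaphane adduct masses
#'
#' The sulforaphane (SFN) mono-adduct on cysteine corresponds to addition of
#' the full molecule C6H11NOS2 across the thiol (dithiocarbamate adduct). The
#' dithiolethione bridge arises when a second cysteine attacks the
#' dithiocarbamate carbon and the sulforaphane amine leaves: the net change on
#' the two bridged cysteines is +CS -H2.
#'
#' @return Mass in Da.
#' @export
sfn_monoadduct_mass <- function() {
  formula_mass(c(C = 6, H = 11, N = 1, O = 1, S = 2))
}

#' @rdname sfn_monoadduct_mass
#' @export
dithiolethione_bridge_mass <- function() {
  formula_mass(c(C = 1, S = 1)) - 2 * ELEMENT_MONO[["H"]]
}

#' Define a crosslinker / mono-adduct chemistry
#'
#' @param name Linker name.
#' @param delta_mass Mass added to the summed peptide mass(es) in Da.
#' @param kind `"bridge"` (joins two cysteines, possibly within one peptide as
#'   a loop-link) or `"mono_adduct"` (single cysteine).
#' @param target_residue Residue the chemistry targets (default `"C"`).
#' @return A `linker_spec` object.
#' @export
linker_spec <- function(name, delta_mass, kind = c("bridge", "mono_adduct"),
                        target_residue = "C") {
  kind <- match.arg(kind)
  stopifnot(is.finite(delta_mass), target_residue %in% canonical_residues())
  structure(list(name = name, delta_mass = delta_mass, kind = kind,
                 target_residue = target_residue),
            class = "linker_spec")
}

#' Default sulforaphane linker chemistries
#'
#' @return `sfn_bridge_linker()`: the dithiolethione-type bridge;
#'   `sfn_monoadduct_linker()`: the dithiocarbamate mono-adduct.
#' @export
sfn_bridge_linker <- function() {
  linker_spec("dithiolethione", dithiolethione_bridge_mass(), "bridge", "C")
}

#' @rdname sfn_bridge_linker
#' @export
sfn_monoadduct_linker <- function() {
  linker_spec("sfn_dithiocarbamate", sfn_monoadduct_mass(), "mono_adduct", "C")
}

#' Maleimide cysteine alkylation (fixed blocker)
#'
#' N-ethylmaleimide-type thiol capping used to block free cysteines; off by
#' default in the recombinant-protein crosslink search because bridged
#' cysteines cannot be alkylated.
#' @return A fixed `modification_spec` on cysteine (+C4H3NO2 for maleimide
#'   Michael addition, 97.01638 Da).
#' @export
maleimide_mod <- function() {
  modification_spec("maleimide", formula_mass(c(C = 4, H = 3, N = 1, O = 2)),
                    "C", "fixed")
}
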
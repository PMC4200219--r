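# Residue and modification mass constants.
#
# Monoisotopic residue masses follow the most-abundant-isotope elemental
# masses; average masses follow the isotope-abundance-weighted (ExPASy
# convention) values.  All residue masses are *residue* (dehydrated)
# masses: a free peptide adds one water.

.MONO_RESIDUE <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)

.AVG_RESIDUE <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594,
  N = 114.1038, D = 115.0886, Q = 128.1307, K = 128.1741,
  E = 129.1155, M = 131.1926, H = 137.1411, F = 147.1766,
  R = 156.1875, Y = 163.1760, W = 186.2132
)

.WATER <- c(mono = 18.01056, average = 18.0153)
.PROTON <- 1.00728
.CO <- 27.99491
# immonium ion = residue mass - CO + H... expressed as residue - 26.00307
.IMMONIUM_DELTA <- 26.00307

# PTM mass deltas relative to the unmodified free peptide.
.PTM_DELTAS <- list(
  mono = c(amidation = -0.98402, pyroglu_Q = -17.02655,
           pyroglu_E = -18.01056, acetylation = 42.01057,
           met_ox = 15.99491, met_diox = 31.98983),
  average = c(amidation = -0.9847, pyroglu_Q = -17.0265,
              pyroglu_E = -18.0153, acetylation = 42.0367,
              met_ox = 15.9994, met_diox = 31.9988)
)

#' Residue mass table
#'
#' Per-residue masses of the 20 standard amino acids, as residue
#' (dehydrated) masses in Da.  `X` (unknown) is deliberately absent:
#' requesting a mass for a sequence containing `X` is an error.
#'
#' @param convention `"mono"` (monoisotopic) or `"average"`.
#' @return Named numeric vector of 20 residue masses.
#' @examples
#' residue_masses("mono")[["G"]]  # 57.02146
#' @export
residue_masses <- function(convention = c("mono", "average")) {
  convention <- match.arg(convention)
  if (convention == "mono") .MONO_RESIDUE else .AVG_RESIDUE
}

#' Post-translational modification mass deltas
#'
#' Mass changes (Da) applied on top of the unmodified free-acid peptide:
#' C-terminal amidation, N-terminal pyroglutamate formed from Gln or Glu,
#' N-terminal acetylation, and Met (di)oxidation.
#'
#' @inheritParams residue_masses
#' @return Named numeric vector of deltas.
#' @export
ptm_deltas <- function(convention = c("mono", "average")) {
  convention <- match.arg(convention)
  .PTM_DELTAS[[if (convention == "mono") "mono" else "average"]]
}

#' Water and proton mass constants
#'
#' @return Named list with `water` (mono and average) and `proton` masses
#'   in Da.
#' @export
mass_constants <- function() {
  list(water = .WATER, proton = .PROTON, co = .CO)
}

#' Construct a PTM flag set for a peptide
#'
#' Records which post-translational modifications a mature peptide
#' carries.  Validity that depends on the sequence (pyroglutamate needs
#' an N-terminal Q/E, oxidation counts need enough methionines) is
#' checked when the set is paired with a sequence, e.g. in
#' [peptide_mass()].
#'
#' @param c_amidated logical; C-terminal amide (the amidating Gly has
#'   already been removed from the sequence).
#' @param n_pyroglu logical; N-terminal pyroglutamate.
#' @param pyroglu_source `"Q"` or `"E"`; residue the pyroglutamate formed
#'   from.
#' @param n_acetyl logical; N-terminal acetylation.  Mutually exclusive
#'   with `n_pyroglu` (both occupy the N-terminus).
#' @param met_ox,met_diox non-negative integer counts of singly and
#'   doubly oxidised methionines.
#' @return An object of class `ptm_set`.
#' @examples
#' ptm_set(c_amidated = TRUE)
#' @export
ptm_set <- function(c_amidated = FALSE, n_pyroglu = FALSE,
                    pyroglu_source = c("Q", "E"), n_acetyl = FALSE,
                    met_ox = 0L, met_diox = 0L) {
  pyroglu_source <- match.arg(pyroglu_source)
  stopifnot(is.logical(c_amidated), is.logical(n_pyroglu),
            is.logical(n_acetyl), met_ox >= 0, met_diox >= 0)
  if (n_pyroglu && n_acetyl)
    stop("pyroglutamate and N-terminal acetylation are mutually exclusive")
  structure(list(c_amidated = isTRUE(c_amidated),
                 n_pyroglu = isTRUE(n_pyroglu),
                 pyroglu_source = pyroglu_source,
                 n_acetyl = isTRUE(n_acetyl),
                 met_ox = as.integer(met_ox),
                 met_diox = as.integer(met_diox)),
            class = "ptm_set")
}

#' @export
print.ptm_set <- function(x, ...) {
  tags <- ptm_tags(x)
  cat("<ptm_set>", if (nzchar(tags)) tags else "none", "\n")
  invisible(x)
}

# compact "key=value" tag string used in FASTA headers and reports
ptm_tags <- function(ptms) {
  out <- character(0)
  if (ptms$c_amidated) out <- c(out, "amidated")
  if (ptms$n_pyroglu) out <- c(out, paste0("pyroglu:", ptms$pyroglu_source))
  if (ptms$n_acetyl) out <- c(out, "acetyl")
  if (ptms$met_ox > 0) out <- c(out, paste0("met_ox:", ptms$met_ox))
  if (ptms$met_diox > 0) out <- c(out, paste0("met_diox:", ptms$met_diox))
  paste(out, collapse = ",")
}

# validate a ptm_set against a concrete sequence; stops on violation
validate_ptms <- function(sequence, ptms) {
  stopifnot(inherits(ptms, "ptm_set"))
  if (ptms$n_pyroglu) {
    first <- substr(sequence, 1, 1)
    if (first != ptms$pyroglu_source)
      stop("pyroglutamate from ", ptms$pyroglu_source,
           " requires N-terminal ", ptms$pyroglu_source,
           " but sequence starts with ", first)
  }
  n_met <- lengths(regmatches(sequence, gregexpr("M", sequence)))
  if (ptms$met_ox + ptms$met_diox > n_met)
    stop("met_ox + met_diox (", ptms$met_ox + ptms$met_diox,
         ") exceeds number of Met residues (", n_met, ")")
  invisible(TRUE)
}

# split a protein string into residue vector, error on non-massable chars
residue_vector <- function(sequence, table) {
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!res %in% names(table))
  if (length(bad) > 0)
    stop("residue '", res[bad[1]], "' at position ", bad[1],
         " has no defined mass")
  res
}

# summed PTM delta for a ptm_set under one convention
ptm_mass_delta <- function(ptms, convention) {
  d <- ptm_deltas(convention)
  delta <- 0
  if (ptms$c_amidated) delta <- delta + d[["amidation"]]
  if (ptms$n_pyroglu)
    delta <- delta + d[[paste0("pyroglu_", ptms$pyroglu_source)]]
  if (ptms$n_acetyl) delta <- delta + d[["acetylation"]]
  delta + ptms$met_ox * d[["met_ox"]] + ptms$met_diox * d[["met_diox"]]
}

#' Neutral mass of a (modified) peptide
#'
#' Mass of the neutral peptide: sum of residue masses, plus one water,
#' plus the mass deltas of any modifications.  Both monoisotopic and
#' average conventions are first-class because MALDI peptide masses are
#' reported in either depending on resolution.
#'
#' @param sequence protein string over the 20 standard residues.
#' @param ptms a [ptm_set()].
#' @param convention `"mono"` or `"average"`.
#' @return Neutral mass in Da.
#' @examples
#' peptide_mass("FMRF", ptm_set(c_amidated = TRUE))        # 598.305
#' peptide_mass("G")                                       # 75.03 free Gly
#' @export
peptide_mass <- function(sequence, ptms = ptm_set(),
                         convention = c("mono", "average")) {
  convention <- match.arg(convention)
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  validate_ptms(sequence, ptms)
  tab <- residue_masses(convention)
  res <- residue_vector(sequence, tab)
  sum(tab[res]) + .WATER[[convention]] + ptm_mass_delta(ptms, convention)
}

#' m/z of a protonated ion
#'
#' `(M + z * proton) / z` for a neutral mass `M`.  MALDI spectra are
#' dominated by singly protonated ions, so `charge = 1` is the default.
#'
#' @param neutral_mass neutral mass in Da.
#' @param charge positive integer charge.
#' @return m/z in Da per unit charge.
#' @examples
#' ion_mz(598.305)  # [M+H]+ of amidated FMRF
#' @export
ion_mz <- function(neutral_mass, charge = 1L) {
  if (any(charge < 1)) stop("charge must be >= 1")
  (neutral_mass + charge * .PROTON) / charge
}
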
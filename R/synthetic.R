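# Synthetic proteomes with prohormone architecture and matching MALDI
# peak lists, plus recovery scoring against the known ground truth.
# Every pipeline stage is testable from these with no external data.

# residues used for spacers and decoys (no K/R: basic runs are added
# deliberately, never by accident)
.NONBASIC <- c("A","C","D","E","F","G","H","I","L","M","N","P","Q","S",
               "T","V","W","Y")

#' Specification of a synthetic proteome
#'
#' The defaults state the world the generator emulates: a handful of
#' true prohormone precursors (signal peptide, spacers, repeated short
#' amidated peptides flanked by dibasic sites) hidden among decoy
#' proteins free of dibasic runs, and a MALDI peak list with ppm-scale
#' mass error plus uniform noise peaks.
#'
#' @param n_precursors number of implanted precursors (default 5).
#' @param families list of family definitions, each
#'   `list(peptide =, copies = c(min, max))`; recycled over precursors.
#'   Defaults to five repeat peptides modelled on classical molluscan
#'   families (APGW-, FMRF-, tachykinin-, myomodulin- and luqin-like).
#' @param n_decoys number of decoy proteins (default 95).
#' @param decoy_len length range of decoys (default 80..300).
#' @param signal_peptide prepend a signal peptide to precursors.
#' @param hard_decoys give decoys random dibasic runs (but no repeat
#'   structure), to exercise the scan score rather than clean
#'   separability.
#' @param mass_error_ppm half-width of the uniform multiplicative mass
#'   error (default 50 ppm, a well-calibrated reflector MALDI-TOF;
#'   must not exceed the 300 ppm matching tolerance).
#' @param n_noise_peaks noise peaks added uniformly in 600..4000
#'   (default 20).
#' @param seed RNG seed.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_precursors = 5L,
                           families = list(
                             list(name = "APGWamide", peptide = "RPGW",
                                  copies = c(3L, 6L)),
                             list(name = "FMRFamide", peptide = "FMRF",
                                  copies = c(4L, 8L)),
                             list(name = "tachykinin", peptide = "FGFAPMR",
                                  copies = c(2L, 4L)),
                             list(name = "myomodulin", peptide = "GMPMLRL",
                                  copies = c(2L, 5L)),
                             list(name = "luqin", peptide = "APQWRPQGRF",
                                  copies = c(2L, 3L))),
                           n_decoys = 95L, decoy_len = c(80L, 300L),
                           signal_peptide = TRUE, hard_decoys = FALSE,
                           mass_error_ppm = 50, n_noise_peaks = 20L,
                           seed = 1L) {
  stopifnot(n_precursors >= 0, n_decoys >= 0, mass_error_ppm >= 0,
            n_noise_peaks >= 0)
  if (mass_error_ppm > 300)
    stop("mass_error_ppm above the 300 ppm matching tolerance")
  for (f in families) {
    if (!nzchar(f$peptide)) stop("zero-length repeat peptide in spec")
    if (grepl("[KR]", f$peptide) &&
        grepl("[KR][KR]", f$peptide))
      stop("repeat peptide contains a dibasic run: ", f$peptide)
  }
  structure(list(n_precursors = as.integer(n_precursors),
                 families = families, n_decoys = as.integer(n_decoys),
                 decoy_len = as.integer(decoy_len),
                 signal_peptide = isTRUE(signal_peptide),
                 hard_decoys = isTRUE(hard_decoys),
                 mass_error_ppm = mass_error_ppm,
                 n_noise_peaks = as.integer(n_noise_peaks),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# a plausible signal peptide: Met + charged n-region residue, a
# hydrophobic h-region, and a small-residue c-region ending A-x-A
random_signal <- function(len = sample(18:25, 1)) {
  h_len <- len - 7L
  paste0("MK",
         paste(sample(c("L","V","I","A","F"), h_len, replace = TRUE),
               collapse = ""),
         "ASA", sample(c("S","T","G"), 1), "A")
}

# spacer alphabet additionally avoids the small residues (A/G/S/C/T)
# so a spacer can never mimic the -3/-1 fingerprint of the signal
# peptidase site, and never ends the fragment in an amidation Gly
.SPACER <- setdiff(.NONBASIC, c("A", "G", "S", "C", "T"))

random_spacer <- function(len) {
  if (len <= 0) return("")
  paste(sample(.SPACER, len, replace = TRUE), collapse = "")
}

# decoy sequence; `hard` allows isolated dibasic runs
random_decoy <- function(len, hard = FALSE) {
  s <- sample(.NONBASIC, len, replace = TRUE)
  # sprinkle isolated basics (no runs)
  n_basic <- max(1L, len %/% 20L)
  pos <- sample(seq(2, len - 1, by = 3), min(n_basic, len %/% 3))
  s[pos] <- sample(c("K", "R"), length(pos), replace = TRUE)
  if (hard && len > 20) {
    at <- sample(5:(len - 5), 1)
    s[at:(at + 1)] <- sample(c("K", "R"), 2, replace = TRUE)
  }
  seq_str <- paste(s, collapse = "")
  # defensive: forbid accidental runs in soft decoys
  if (!hard) stopifnot(!grepl("[KR][KR]", seq_str))
  seq_str
}

#' Generate a synthetic proteome with ground truth
#'
#' Precursors are assembled as
#' `[signal][spacer]([peptide]G[dibasic])*[spacer]`, so each repeat
#' peptide matures to its amidated form under the standard processing
#' rules.  Decoys carry no dibasic runs (unless `hard_decoys`).
#' Deterministic under the spec seed.
#'
#' @param spec a [synthetic_spec()].
#' @return List of class `synthetic_proteome`: `proteins` (list of
#'   [bio_seq()]), `truth` (list with `proteins` and `peptides`
#'   data.frames).
#' @export
make_proteome <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  proteins <- list()
  prot_rows <- list()
  pep_rows <- list()
  for (k in seq_len(spec$n_precursors)) {
    fam <- spec$families[[(k - 1L) %% length(spec$families) + 1L]]
    id <- sprintf("precursor_%02d_%s", k, fam$name)
    copies <- sample(fam$copies[1]:fam$copies[2], 1)
    signal <- if (spec$signal_peptide) random_signal() else ""
    # N-terminal spacer ends in a dibasic site so the first repeat
    # copy matures exactly like the others
    body <- paste0(random_spacer(sample(8:20, 1)), "KR")
    blocks <- character(copies)
    for (cc in seq_len(copies))
      blocks[cc] <- paste0(fam$peptide, "G",
                           paste(sample(c("KR","KK","RR","RK"), 1)))
    seq_str <- paste0(signal, body, paste(blocks, collapse = ""),
                      random_spacer(sample(5:15, 1)))
    proteins[[length(proteins) + 1L]] <- bio_seq(id, seq_str)
    prot_rows[[length(prot_rows) + 1L]] <- data.frame(
      id = id, is_precursor = TRUE, family = fam$name,
      signal_pos = nchar(signal), stringsAsFactors = FALSE)
    pep_rows[[length(pep_rows) + 1L]] <- data.frame(
      id = id, sequence = fam$peptide, c_amidated = TRUE,
      n_pyroglu = substr(fam$peptide, 1, 1) == "Q",
      copies = copies, family = fam$name, stringsAsFactors = FALSE)
  }
  for (k in seq_len(spec$n_decoys)) {
    id <- sprintf("decoy_%03d", k)
    len <- sample(spec$decoy_len[1]:spec$decoy_len[2], 1)
    proteins[[length(proteins) + 1L]] <- bio_seq(
      id, random_decoy(len, spec$hard_decoys))
    prot_rows[[length(prot_rows) + 1L]] <- data.frame(
      id = id, is_precursor = FALSE, family = NA_character_,
      signal_pos = NA_integer_, stringsAsFactors = FALSE)
  }
  truth <- list(
    proteins = do.call(rbind, prot_rows),
    peptides = if (length(pep_rows) > 0) do.call(rbind, pep_rows) else
      data.frame(id = character(0), sequence = character(0),
                 c_amidated = logical(0), n_pyroglu = logical(0),
                 copies = integer(0), family = character(0)))
  structure(list(proteins = proteins, truth = truth, spec = spec),
            class = "synthetic_proteome")
}

#' @export
print.synthetic_proteome <- function(x, ...) {
  cat("<synthetic_proteome> ", sum(x$truth$proteins$is_precursor),
      " precursors + ", sum(!x$truth$proteins$is_precursor),
      " decoys (seed ", x$spec$seed, ")\n", sep = "")
  invisible(x)
}

#' Simulate a MALDI peak list from ground truth
#'
#' One [M+H]+ peak per distinct implanted peptide (monoisotopic, with
#' its true PTMs), perturbed by a uniform multiplicative error of
#' `mass_error_ppm`, plus uniform noise peaks in the 600-4000 Da
#' acquisition window.  Intensities are log-normal, true peaks one
#' order of magnitude above noise on average.
#'
#' @param proteome a `synthetic_proteome` (or its `truth` component).
#' @param spec the [synthetic_spec()] used (defaults to the proteome's).
#' @return A [peak_list()].
#' @export
make_peaklist <- function(proteome, spec = NULL) {
  truth <- if (inherits(proteome, "synthetic_proteome"))
    proteome$truth else proteome
  if (is.null(spec)) spec <- proteome$spec
  peps <- unique(truth$peptides[, c("sequence", "c_amidated",
                                    "n_pyroglu")])
  if (nrow(peps) == 0) stop("truth table contains no implanted peptides")
  set.seed(spec$seed + 1L)
  mz_true <- vapply(seq_len(nrow(peps)), function(i) {
    ptms <- ptm_set(c_amidated = peps$c_amidated[i],
                    n_pyroglu = peps$n_pyroglu[i])
    ion_mz(peptide_mass(peps$sequence[i], ptms, "mono"))
  }, numeric(1))
  err <- stats::runif(length(mz_true), -spec$mass_error_ppm,
                      spec$mass_error_ppm) * 1e-6
  mz <- mz_true * (1 + err)
  intensity <- stats::rlnorm(length(mz), meanlog = log(1000), sdlog = 0.5)
  if (spec$n_noise_peaks > 0) {
    mz <- c(mz, stats::runif(spec$n_noise_peaks, 600, 4000))
    intensity <- c(intensity,
                   stats::rlnorm(spec$n_noise_peaks, meanlog = log(100),
                                 sdlog = 0.5))
  }
  peak_list(mz, intensity)
}

#' Score pipeline predictions against synthetic ground truth
#'
#' Precursor-level precision/recall (was each true precursor reported,
#' was anything else), peptide-level precision/recall (a predicted
#' mature peptide counts only if sequence and PTM flags match an
#' implanted one exactly; spacer-derived by-products count against
#' precision), and a per-family recovery table.  With no predictions,
#' precision is 1.0 by convention (no false positives were made).
#'
#' @param predicted list of `precursor_annotation` from
#'   [scan_proteome()].
#' @param truth the `truth` component of a `synthetic_proteome`.
#' @return List with `precursor` (precision, recall), `peptide`
#'   (precision, recall), `per_family` data.frame.
#' @export
evaluate_recovery <- function(predicted, truth) {
  pred_ids <- vapply(predicted, function(a) a$protein$id, "")
  true_ids <- truth$proteins$id[truth$proteins$is_precursor]
  tp <- sum(pred_ids %in% true_ids)
  prec_precision <- if (length(pred_ids) == 0) 1.0 else
    tp / length(pred_ids)
  prec_recall <- if (length(true_ids) == 0) 1.0 else tp / length(true_ids)
  # peptide level: exact sequence + PTM flags, per precursor
  key <- function(id, s, am, pg) paste(id, s, am, pg, sep = "|")
  truth_keys <- unlist(lapply(seq_len(nrow(truth$peptides)), function(i)
    rep(key(truth$peptides$id[i], truth$peptides$sequence[i],
            truth$peptides$c_amidated[i], truth$peptides$n_pyroglu[i]),
        truth$peptides$copies[i])))
  pred_keys <- unlist(lapply(predicted, function(a) {
    p <- a$peptides
    if (nrow(p) == 0) return(character(0))
    key(p$precursor_id, p$sequence, p$c_amidated, p$n_pyroglu)
  }))
  # multiset intersection
  inter <- 0L
  tt <- table(truth_keys)
  pt <- table(pred_keys)
  for (k in intersect(names(tt), names(pt)))
    inter <- inter + min(tt[[k]], pt[[k]])
  pep_precision <- if (length(pred_keys) == 0) 1.0 else
    inter / length(pred_keys)
  pep_recall <- if (length(truth_keys) == 0) 1.0 else
    inter / length(truth_keys)
  fams <- unique(truth$peptides$family)
  per_family <- do.call(rbind, lapply(fams, function(f) {
    rows <- truth$peptides[truth$peptides$family == f, , drop = FALSE]
    found <- rows$id %in% pred_ids
    data.frame(family = f, n_true = nrow(rows),
               n_recovered = sum(found), stringsAsFactors = FALSE)
  }))
  list(precursor = c(precision = prec_precision, recall = prec_recall),
       peptide = c(precision = pep_precision, recall = pep_recall),
       per_family = per_family)
}
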
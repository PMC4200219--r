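# Theoretical fragmentation and matching against observed MALDI peaks.
#
# All stored masses are neutral; protons are added only when an m/z is
# produced (ion_mz, fragment series).  Observed peaks are interpreted as
# singly protonated [M+H]+ unless stated otherwise.

#' Construct a peak list
#'
#' @param mz numeric m/z values (> 0).
#' @param intensity non-negative intensities; defaults to 1.
#' @return data.frame of class `peak_list`, sorted ascending by m/z.
#' @export
peak_list <- function(mz, intensity = rep(1, length(mz))) {
  stopifnot(length(mz) == length(intensity))
  if (length(mz) > 0 && (any(mz <= 0) || any(intensity < 0)))
    stop("mz must be > 0 and intensity >= 0")
  ord <- order(mz)
  structure(data.frame(mz = as.numeric(mz[ord]),
                       intensity = as.numeric(intensity[ord])),
            class = c("peak_list", "data.frame"))
}

#' Read a peak list from two-column CSV/TSV
#'
#' Accepts comma, tab or whitespace separated `mz, intensity` rows;
#' lines starting with `#` are comments.  A missing intensity column is
#' filled with 1.
#'
#' @param path file path.
#' @return A [peak_list()].
#' @export
read_peaklist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  # tolerate a single header row (e.g. "mz,intensity")
  if (length(lines) > 0 && grepl("^[A-Za-z]", lines[1]))
    lines <- lines[-1]
  if (length(lines) == 0) return(peak_list(numeric(0), numeric(0)))
  fields <- strsplit(lines, "[,\t ]+")
  mz <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1)))
  int <- vapply(fields, function(f) if (length(f) >= 2) f[2] else "1", "")
  if (anyNA(mz)) stop("non-numeric m/z in ", path)
  peak_list(mz, as.numeric(int))
}

#' Write a peak list as CSV
#' @param peaks a [peak_list()].
#' @param path output file.
#' @export
write_peaklist <- function(peaks, path) {
  utils::write.csv(as.data.frame(peaks), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Theoretical fragment ions of a peptide
#'
#' Singly protonated a-, b- and y-ion series plus immonium masses, the
#' ion types annotated on reflector MALDI MS/MS spectra.  The N-terminal
#' modification delta (pyroglutamate or acetylation) is carried by the
#' b/a series; C-terminal amidation is carried by the y series.
#'
#' @param sequence peptide of length >= 2.
#' @param ptms a [ptm_set()].
#' @return List of class `fragment_set`: numeric vectors `b`, `a`
#'   (indexed by cleavage position, `b[i]` holds the first `i`
#'   residues), `y` (indexed by ion size, `y[k]` holds the last `k`
#'   residues, so `b[i] + y[n-i]` is conserved), each of length
#'   `nchar(sequence) - 1`, and `immonium` (named, one per distinct
#'   residue).
#' @examples
#' fragment_ions("FMRF", ptm_set(c_amidated = TRUE))
#' @export
fragment_ions <- function(sequence, ptms = ptm_set()) {
  n <- nchar(sequence)
  if (n < 2) stop("fragmentation needs length >= 2 (no internal cleavage)")
  validate_ptms(sequence, ptms)
  tab <- residue_masses("mono")
  res <- residue_vector(sequence, tab)
  d <- ptm_deltas("mono")
  nterm_delta <- 0
  if (ptms$n_pyroglu)
    nterm_delta <- nterm_delta + d[[paste0("pyroglu_", ptms$pyroglu_source)]]
  if (ptms$n_acetyl) nterm_delta <- nterm_delta + d[["acetylation"]]
  cterm_delta <- if (ptms$c_amidated) d[["amidation"]] else 0
  masses <- tab[res]
  b <- cumsum(masses)[-n] + nterm_delta + .PROTON     # b_i: first i residues
  a <- b - .CO
  y <- cumsum(rev(masses))[-n] + .WATER[["mono"]] + cterm_delta + .PROTON  # y_k: last k
  imm <- tab[unique(res)] - .IMMONIUM_DELTA
  names(imm) <- unique(res)
  structure(list(sequence = sequence, ptms = ptms,
                 b = unname(b), a = unname(a), y = unname(y),
                 immonium = imm),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("<fragment_set> ", x$sequence, ": ", length(x$b),
      " b/a/y cleavage positions\n", sep = "")
  invisible(x)
}

#' Apply the MALDI detection mass sieve
#'
#' Retains peaks inside the acquisition window (inclusive on both
#' sides); peptides outside it are unobservable in the experiment.
#'
#' @param peaks a [peak_list()].
#' @param low,high window bounds in Da (defaults 600 and 4000).
#' @return Filtered [peak_list()], order preserved.
#' @export
mass_sieve <- function(peaks, low = 600, high = 4000) {
  if (low >= high) stop("sieve bounds must satisfy low < high")
  keep <- peaks$mz >= low & peaks$mz <= high
  peak_list(peaks$mz[keep], peaks$intensity[keep])
}

#' Match observed peaks to candidate peptide masses
#'
#' Compares observed [M+H]+ peaks against theoretical singly protonated
#' masses of candidate peptides under a ppm tolerance.  All pairs within
#' tolerance are reported with their signed ppm error.
#'
#' @param peaks a [peak_list()] of [M+H]+ m/z values.
#' @param candidates data.frame with columns `sequence` and `mono_mass`
#'   (neutral Da), e.g. the `peptides` table of a precursor annotation,
#'   or a named numeric vector of neutral masses.
#' @param tol_ppm tolerance in parts per million (default 300).
#' @return data.frame with columns `peak_mz`, `sequence`,
#'   `theoretical_mz`, `error_ppm`.
#' @export
match_precursor_masses <- function(peaks, candidates, tol_ppm = 300) {
  if (is.numeric(candidates)) {
    candidates <- data.frame(
      sequence = if (is.null(names(candidates)))
        as.character(seq_along(candidates)) else names(candidates),
      mono_mass = unname(candidates), stringsAsFactors = FALSE)
  }
  empty <- data.frame(peak_mz = numeric(0), sequence = character(0),
                      theoretical_mz = numeric(0), error_ppm = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(peaks) == 0 || nrow(candidates) == 0) return(empty)
  theo <- ion_mz(candidates$mono_mass, 1L)
  out <- lapply(seq_len(nrow(candidates)), function(j) {
    err <- (peaks$mz - theo[j]) / theo[j] * 1e6
    hit <- which(abs(err) <= tol_ppm)
    if (length(hit) == 0) return(NULL)
    data.frame(peak_mz = peaks$mz[hit], sequence = candidates$sequence[j],
               theoretical_mz = theo[j], error_ppm = err[hit],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[order(out$peak_mz, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score a peptide against an MS/MS spectrum
#'
#' Transparent stand-in for a database-search score: counts theoretical
#' b/y ions found in the spectrum within `frag_tol` Da, and converts the
#' binomial tail probability of seeing at least that many matches by
#' chance into `-10 * log10(P)`, the familiar search-engine scale, so
#' the conventional "score > 20" significance filter applies directly.
#' The per-ion random match probability is
#' `p = 2 * frag_tol * n_peaks / mass_range`.
#'
#' @param spectrum a [peak_list()] (already sieved).
#' @param sequence peptide sequence.
#' @param ptms a [ptm_set()].
#' @param frag_tol fragment tolerance in Da (default 0.6).
#' @param mass_range width of the m/z region peaks could fall in;
#'   defaults to the observed spectrum span (minimum 100 Da to keep the
#'   null model sane on narrow spectra).
#' @return List with `score`, `n_matched`, `n_ions`, `p_random`.
#' @export
score_spectrum_match <- function(spectrum, sequence, ptms = ptm_set(),
                                 frag_tol = 0.6, mass_range = NULL) {
  if (nrow(spectrum) == 0)
    return(list(score = 0, n_matched = 0L, n_ions = 0L, p_random = 1))
  frags <- fragment_ions(sequence, ptms)
  ions <- c(frags$b, frags$y)
  if (is.null(mass_range))
    mass_range <- max(100, diff(range(spectrum$mz)))
  matched <- vapply(ions, function(m) any(abs(spectrum$mz - m) <= frag_tol),
                    logical(1))
  k <- sum(matched)
  n <- length(ions)
  p <- min(1, 2 * frag_tol * nrow(spectrum) / mass_range)
  # P(X >= k) under Binomial(n, p); k = 0 gives P = 1, score 0
  p_rand <- stats::pbinom(k - 1, n, p, lower.tail = FALSE)
  score <- if (k == 0) 0 else -10 * log10(max(p_rand, .Machine$double.xmin))
  list(score = score, n_matched = as.integer(k), n_ions = as.integer(n),
       p_random = p_rand)
}
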
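# Prohormone precursor mining: signal peptide heuristic, dibasic
# cleavage, in-silico maturation (Gly-amidation, pyroglutamate), repeat
# detection, and proteome-wide candidate scanning.

# Kyte-Doolittle hydropathy index
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
         E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
         M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
         Y = -1.3, V = 4.2)

.SMALL_RESIDUES <- c("A", "G", "S", "C", "T")

#' Heuristic signal peptide prediction
#'
#' Transparent replacement for an external signal-peptide predictor:
#' secretory signal peptides carry a hydrophobic core (h-region) ending
#' a few residues before the cleavage site, and small residues at the
#' -3/-1 positions of the site.  For each candidate cleavage position
#' `pos` (0-based index of the first mature residue) in 15..40, the
#' score is the best mean Kyte-Doolittle hydropathy over 8-residue
#' windows within residues 3..(pos-3), plus `small_bonus` for a small
#' residue (A/G/S/C/T) at each of `pos-3` and `pos-1`.
#'
#' Candidate positions whose best hydrophobic window ends more than
#' `c_max` residues upstream are discarded: the polar c-region linking
#' the h-region to the cleavage site is short, and without this
#' constraint any small residues far downstream (for instance the Gly
#' of amidation signals inside repeat blocks) would mimic a site.
#' Ties are broken toward the most C-terminal position, the peptidase
#' cutting after the complete c-region.
#'
#' Externally produced cleavage positions can be supplied instead via
#' the `signal_tsv` field of [scan_config()].
#'
#' @param protein protein string or [bio_seq()].
#' @param threshold score above which a signal peptide is called
#'   (default 2.0 hydropathy units).
#' @param small_bonus bonus per satisfied -3/-1 small residue (0.5).
#' @param c_max maximal distance (residues) between the end of the
#'   best hydrophobic window and the cleavage site (default 13).
#' @return List of class `signal_prediction`: `present`, `cleavage_pos`
#'   (0-based index of first mature residue, `NA` if absent), `score`.
#' @export
predict_signal <- function(protein, threshold = 2.0, small_bonus = 0.5,
                           c_max = 13L) {
  if (inherits(protein, "bio_seq")) protein <- protein$residues
  n <- nchar(protein)
  if (n < 30)
    return(structure(list(present = FALSE, cleavage_pos = NA_integer_,
                          score = -Inf, reason = "shorter than 30 residues"),
                     class = "signal_prediction"))
  res <- strsplit(protein, "")[[1]]
  kd <- unname(.KD[res])
  kd[is.na(kd)] <- 0  # X and rare letters contribute nothing
  best_score <- -Inf
  best_pos <- NA_integer_
  for (pos in 15:min(40, n - 1)) {
    # 8-residue windows fully inside 0-based residues 3..(pos-3)
    if (pos - 9L < 4L) next
    win_starts <- 4L:(pos - 9L)            # 1-based start indices
    win_means <- vapply(win_starts,
                        function(s) mean(kd[s:(s + 7L)]), numeric(1))
    sc <- max(win_means)
    # 0-based end of the latest window attaining the maximum
    win_end <- win_starts[max(which(win_means >= sc - 1e-9))] + 6L
    if (pos - win_end > c_max) next  # h-region too far upstream
    if (res[pos - 2L] %in% .SMALL_RESIDUES) sc <- sc + small_bonus
    if (res[pos] %in% .SMALL_RESIDUES) sc <- sc + small_bonus
    # ties go to the most C-terminal position: the peptidase cuts
    # after the full c-region, so the last equally good site is it
    if (sc >= best_score) {
      best_score <- sc
      best_pos <- pos
    }
  }
  present <- is.finite(best_score) && best_score >= threshold
  structure(list(present = present,
                 cleavage_pos = if (present) as.integer(best_pos)
                                else NA_integer_,
                 score = best_score),
            class = "signal_prediction")
}

#' @export
print.signal_prediction <- function(x, ...) {
  if (x$present)
    cat("<signal_prediction> present, cleavage at", x$cleavage_pos,
        "(score", round(x$score, 2), ")\n")
  else
    cat("<signal_prediction> absent (score", round(x$score, 2), ")\n")
  invisible(x)
}

#' Find prohormone convertase cleavage sites
#'
#' Every maximal run of >= 2 consecutive basic residues (K/R) yields one
#' site; the whole run is consumed at cleavage, which handles KK, KR,
#' RK, RR and longer runs such as RRRR without double-counting.  An
#' optional monobasic rule (off by default) additionally calls single
#' Arg residues preceded 2, 4 or 6 residues upstream by a basic residue.
#'
#' @param protein protein string or [bio_seq()].
#' @param monobasic enable the monobasic-Arg rule.
#' @return data.frame with columns `position` (0-based index of the
#'   first basic residue), `motif` (`KK`/`KR`/`RK`/`RR` for runs, taken
#'   from the first two residues, or `monobasic-R`), `basic_run_length`.
#' @examples
#' find_cleavage_sites("AAKRAA")
#' @export
find_cleavage_sites <- function(protein, monobasic = FALSE) {
  if (inherits(protein, "bio_seq")) protein <- protein$residues
  stopifnot(nzchar(protein))
  res <- strsplit(protein, "")[[1]]
  basic <- res %in% c("K", "R")
  r <- rle(basic)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= 2L)
  sites <- data.frame(
    position = starts[runs] - 1L,
    motif = vapply(runs, function(i)
      paste0(res[starts[i]], res[starts[i] + 1L]), ""),
    basic_run_length = r$lengths[runs],
    stringsAsFactors = FALSE)
  if (monobasic) {
    singles <- which(r$values & r$lengths == 1L)
    for (i in singles) {
      p <- starts[i]  # 1-based position of the lone basic residue
      if (res[p] != "R") next
      up <- p - c(2L, 4L, 6L)
      up <- up[up >= 1L]
      if (any(res[up] %in% c("K", "R"))) {
        sites <- rbind(sites, data.frame(
          position = p - 1L, motif = "monobasic-R",
          basic_run_length = 1L, stringsAsFactors = FALSE))
      }
    }
  }
  sites <- sites[order(sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Cleave a precursor into raw fragments
#'
#' Fragments are the substrings between the signal cleavage point, the
#' basic cleavage sites, and the sequence ends.  Each maximal basic run
#' is partitioned into dibasic convertase pairs from its start and the
#' pairs are consumed (removed by carboxypeptidase); when the run
#' length is odd the final basic residue is retained at the N-terminus
#' of the downstream fragment.  This is what the processing of R/K-
#' initial repeat peptides (e.g. RPGWa, KPGWa) requires: in
#' `...KR|RPGWG|KR...` the separator and the peptide's initial Arg form
#' a KRR run, of which only the KR pair is removed.  Monobasic sites
#' consume their single residue.  Empty fragments arising from adjacent
#' runs are dropped.
#'
#' @param protein protein string or [bio_seq()].
#' @param signal a `signal_prediction` (or `NULL` for none).
#' @param sites cleavage site table from [find_cleavage_sites()].
#' @return data.frame with columns `sequence`, `start`, `end` (0-based
#'   half-open on the precursor).
#' @export
cleave <- function(protein, signal = NULL, sites = NULL) {
  if (inherits(protein, "bio_seq")) protein <- protein$residues
  if (is.null(sites)) sites <- find_cleavage_sites(protein)
  n <- nchar(protein)
  mature_start <- if (!is.null(signal) && isTRUE(signal$present))
    signal$cleavage_pos else 0L
  # residues consumed per site: full dibasic pairs (or the single
  # residue of a monobasic site); an odd trailing basic is retained
  consumed <- ifelse(sites$basic_run_length == 1L, 1L,
                     2L * (sites$basic_run_length %/% 2L))
  # boundaries: [frag_start, frag_end) between consumed regions
  cut_start <- c(mature_start, sites$position + consumed)
  cut_end <- c(sites$position, n)
  keep <- cut_end > cut_start & cut_start >= mature_start
  out <- data.frame(
    sequence = substring(protein, cut_start[keep] + 1L, cut_end[keep]),
    start = as.integer(cut_start[keep]), end = as.integer(cut_end[keep]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Infer maturation PTMs for a cleaved fragment
#'
#' A fragment ending in Gly that was followed in the precursor by a
#' cleavage site or the C-terminus is the substrate of peptidylglycine
#' alpha-amidation: the Gly is removed and the peptide flagged amidated.
#' An N-terminal Gln cyclises to pyroglutamate (optionally also Glu).
#' Acetylation is never auto-asserted; it remains a search-time variable
#' modification only.
#'
#' @param fragment fragment string from [cleave()].
#' @param precursor_id identifier of the parent protein.
#' @param start 0-based start of the fragment on the precursor.
#' @param pyroglu_from_E also convert N-terminal Glu (default FALSE).
#' @return One-row data.frame with columns `precursor_id`, `sequence`,
#'   `start`, `end`, `c_amidated`, `n_pyroglu`, `pyroglu_source`,
#'   `mono_mass`, `avg_mass`.
#' @examples
#' infer_ptms("FMRFG")   # -> FMRF, amidated, mono 598.305
#' @export
infer_ptms <- function(fragment, precursor_id = NA_character_, start = 0L,
                       pyroglu_from_E = FALSE) {
  stopifnot(nzchar(fragment))
  if (fragment == "G")
    stop("fragment 'G' cannot mature: amidation would leave an empty peptide")
  amidated <- endsWith(fragment, "G")
  sequence <- if (amidated) substr(fragment, 1, nchar(fragment) - 1L)
              else fragment
  first <- substr(sequence, 1, 1)
  pyroglu <- first == "Q" || (pyroglu_from_E && first == "E")
  ptms <- ptm_set(c_amidated = amidated, n_pyroglu = pyroglu,
                  pyroglu_source = if (pyroglu) first else "Q")
  data.frame(precursor_id = precursor_id, sequence = sequence,
             start = as.integer(start),
             end = as.integer(start + nchar(sequence)),
             c_amidated = amidated, n_pyroglu = pyroglu,
             pyroglu_source = if (pyroglu) first else NA_character_,
             mono_mass = peptide_mass(sequence, ptms, "mono"),
             avg_mass = peptide_mass(sequence, ptms, "average"),
             stringsAsFactors = FALSE)
}

# rebuild a ptm_set from a peptide table row
row_ptms <- function(row) {
  ptm_set(c_amidated = row$c_amidated, n_pyroglu = row$n_pyroglu,
          pyroglu_source = if (isTRUE(row$n_pyroglu)) row$pyroglu_source
                           else "Q")
}

#' Most repeated mature peptide of a precursor
#'
#' Repeat copy number is a hallmark of prohormones (many carry the same
#' short bioactive peptide several times).  Ties are broken by shorter
#' peptide, then lexicographic order, for determinism.
#'
#' @param sequences character vector of mature peptide sequences.
#' @return List with `peptide` and `count`.
#' @export
detect_repeats <- function(sequences) {
  stopifnot(length(sequences) >= 1)
  tab <- table(sequences)
  top <- names(tab)[tab == max(tab)]
  top <- top[order(nchar(top), top)][1]
  list(peptide = top, count = as.integer(max(tab)))
}

#' Configuration of the proteome scan
#'
#' @param w_sites,w_repeats,w_motifs,w_signal weights of the candidate
#'   score (defaults 1, 2, 3, 1).
#' @param threshold minimum score for a protein to be reported (4).
#' @param monobasic enable monobasic-Arg cleavage.
#' @param pyroglu_from_E also form pyroglutamate from Glu.
#' @param signal_threshold signal-peptide score threshold.
#' @param signal_tsv optional TSV (`id`, `cleavage_pos`) of externally
#'   predicted signal cleavage positions, overriding the heuristic.
#' @return List of class `scan_config`.
#' @export
scan_config <- function(w_sites = 1, w_repeats = 2, w_motifs = 3,
                        w_signal = 1, threshold = 4, monobasic = FALSE,
                        pyroglu_from_E = FALSE, signal_threshold = 2.0,
                        signal_tsv = NULL) {
  structure(list(w_sites = w_sites, w_repeats = w_repeats,
                 w_motifs = w_motifs, w_signal = w_signal,
                 threshold = threshold, monobasic = monobasic,
                 pyroglu_from_E = pyroglu_from_E,
                 signal_threshold = signal_threshold,
                 signal_tsv = signal_tsv),
            class = "scan_config")
}

# load external signal predictions, if configured
external_signals <- function(config) {
  if (is.null(config$signal_tsv)) return(NULL)
  tab <- utils::read.delim(config$signal_tsv, stringsAsFactors = FALSE)
  stats::setNames(as.integer(tab$cleavage_pos), tab$id)
}

#' Annotate one protein as a putative prohormone precursor
#'
#' Runs signal prediction, cleavage-site detection, cleavage and PTM
#' inference, and summarises the result (peptide count, amidated /
#' pyroglutamate counts, top repeat).
#'
#' @param protein a [bio_seq()] or protein string.
#' @param config a [scan_config()].
#' @param motif_library optional [motif_library()] for family tagging.
#' @return Object of class `precursor_annotation` with fields `protein`,
#'   `signal`, `sites`, `peptides` (data.frame of mature peptides),
#'   `summary`, `score`.
#' @export
annotate_precursor <- function(protein, config = scan_config(),
                               motif_library = NULL) {
  if (!inherits(protein, "bio_seq"))
    protein <- bio_seq("query", protein)
  ext <- external_signals(config)
  if (!is.null(ext) && protein$id %in% names(ext)) {
    signal <- structure(list(present = TRUE,
                             cleavage_pos = ext[[protein$id]],
                             score = NA_real_),
                        class = "signal_prediction")
  } else {
    signal <- predict_signal(protein, threshold = config$signal_threshold)
  }
  sites <- find_cleavage_sites(protein, monobasic = config$monobasic)
  frags <- cleave(protein$residues, signal, sites)
  frags <- frags[frags$sequence != "G", , drop = FALSE]  # unmaturable
  peptides <- if (nrow(frags) == 0) {
    infer_ptms("A")[0, , drop = FALSE]
  } else {
    do.call(rbind, lapply(seq_len(nrow(frags)), function(i)
      infer_ptms(frags$sequence[i], protein$id, frags$start[i],
                 pyroglu_from_E = config$pyroglu_from_E)))
  }
  peptides$family <- NA_character_
  if (!is.null(motif_library) && nrow(peptides) > 0) {
    peptides$family <- vapply(seq_len(nrow(peptides)), function(i)
      assign_motif_family(peptides$sequence[i],
                          amidated = peptides$c_amidated[i],
                          library = motif_library),
      NA_character_)
  }
  top <- if (nrow(peptides) > 0) detect_repeats(peptides$sequence)
         else list(peptide = NA_character_, count = 0L)
  summary <- list(n_peptides = nrow(peptides),
                  n_amidated = sum(peptides$c_amidated),
                  n_acetylated = 0L,
                  n_pyroglu = sum(peptides$n_pyroglu),
                  has_signal = isTRUE(signal$present),
                  top_repeat = top)
  n_motif <- if (is.null(motif_library)) 0L else sum(!is.na(peptides$family))
  score <- config$w_sites * nrow(sites) +
    config$w_repeats * max(top$count - 1L, 0L) +
    config$w_motifs * n_motif +
    config$w_signal * as.integer(isTRUE(signal$present))
  structure(list(protein = protein, signal = signal, sites = sites,
                 peptides = peptides, summary = summary, score = score),
            class = "precursor_annotation")
}

#' @export
print.precursor_annotation <- function(x, ...) {
  s <- x$summary
  cat("<precursor_annotation> ", x$protein$id, ": ", s$n_peptides,
      " peptides (", s$n_amidated, " amidated, ", s$n_pyroglu,
      " pyroGlu), signal=", s$has_signal, ", score=", x$score, "\n",
      sep = "")
  if (s$n_peptides > 0)
    cat("  top repeat: ", s$top_repeat$peptide, " x",
        s$top_repeat$count, "\n", sep = "")
  invisible(x)
}

#' Scan a proteome for prohormone precursor candidates
#'
#' Annotates every protein and retains those whose candidate score
#' reaches the threshold.  The score rewards the hallmarks of
#' prohormones: dibasic cleavage sites, repeated identical peptides,
#' peptides matching known family motifs, and a predicted signal
#' peptide:
#' `score = w1 * n_sites + w2 * (max_repeat - 1) + w3 * n_motif_hits +
#'  w4 * has_signal`.
#'
#' @param proteins list of [bio_seq()] (e.g. from [read_fasta()]).
#' @param motif_library a [motif_library()]; `NULL` disables the motif
#'   term.
#' @param config a [scan_config()].
#' @return List of `precursor_annotation`, sorted by decreasing score
#'   (stable order for ties).
#' @export
scan_proteome <- function(proteins, motif_library = default_motif_library(),
                          config = scan_config()) {
  if (length(proteins) == 0) return(list())
  anns <- lapply(proteins, annotate_precursor, config = config,
                 motif_library = motif_library)
  scores <- vapply(anns, `[[`, numeric(1), "score")
  keep <- scores >= config$threshold
  anns <- anns[keep]
  anns[order(-scores[keep])]
}
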
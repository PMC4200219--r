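# Sequence containers, FASTA I/O and six-frame ORF extraction.

.PROTEIN_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N",
                       "P","Q","R","S","T","V","W","Y","X","*")
.NUC_ALPHABET <- c("A","C","G","T","N")

#' Construct a biological sequence
#'
#' Light-weight container for a single protein or nucleotide sequence.
#' Residues are upper-cased and checked against the declared alphabet;
#' the first violation is reported with its position.  `N` in nucleotide
#' sequences translates to `X`; `X` carries no mass and is rejected by
#' mass computations.
#'
#' @param id sequence identifier (no whitespace).
#' @param residues sequence string.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return Object of class `bio_seq` with fields `id`, `residues`,
#'   `alphabet`.
#' @examples
#' bio_seq("a", "FMRF")
#' @export
bio_seq <- function(id, residues, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  residues <- toupper(as.character(residues))
  if (!nzchar(residues)) stop("sequence '", id, "' is empty")
  allowed <- if (alphabet == "protein") .PROTEIN_ALPHABET else .NUC_ALPHABET
  chars <- strsplit(residues, "")[[1]]
  bad <- which(!chars %in% allowed)
  if (length(bad) > 0)
    stop("record '", id, "': character '", chars[bad[1]],
         "' at position ", bad[1], " not in ", alphabet, " alphabet")
  structure(list(id = as.character(id), residues = residues,
                 alphabet = alphabet),
            class = "bio_seq")
}

#' @export
print.bio_seq <- function(x, ...) {
  cat("<bio_seq ", x$alphabet, "> ", x$id, " (", nchar(x$residues),
      " residues)\n", sep = "")
  invisible(x)
}

#' Read a FASTA file
#'
#' Wraps `Biostrings::readBStringSet()` for the actual parsing (wrapped
#' or unwrapped lines), then validates each record against the declared
#' alphabet.  Identifiers are the header up to the first whitespace.
#'
#' @param path FASTA file.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return List of [bio_seq()] objects, input order preserved.  An empty
#'   file yields an empty list with a warning.
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    if (length(readLines(path, warn = FALSE)) == 0)
                      return(Biostrings::BStringSet())
                    stop(e)
                  })
  if (length(set) == 0) {
    warning("empty FASTA file: ", path)
    return(list())
  }
  ids <- sub("\\s.*$", "", names(set))
  mapply(function(id, s) bio_seq(id, s, alphabet),
         ids, as.character(set), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequences to FASTA
#'
#' @param seqs list of [bio_seq()] (or named character vector).
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.character(seqs)) {
    set <- Biostrings::BStringSet(seqs)
  } else {
    set <- Biostrings::BStringSet(vapply(seqs, `[[`, "", "residues"))
    names(set) <- vapply(seqs, `[[`, "", "id")
  }
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# reverse complement of an ACGTN string
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# translate an in-frame nucleotide string with the standard code;
# incomplete trailing codon dropped; N-containing codons -> X
translate_nt <- function(nt) {
  n <- nchar(nt) %/% 3
  if (n == 0) return("")
  codons <- substring(nt, 3 * seq_len(n) - 2, 3 * seq_len(n))
  code <- Biostrings::GENETIC_CODE
  aa <- ifelse(grepl("N", codons), "X",
               unname(code[codons]))
  paste(aa, collapse = "")
}

#' Find open reading frames in all six frames
#'
#' ORFs are stop-to-stop segments of each translated frame; with
#' `require_atg = TRUE` (the default) each segment is truncated at its
#' first Met and segments lacking one are dropped.  Coordinates are
#' 0-based half-open on the forward strand and include the trailing stop
#' codon when one terminates the ORF, so `(end - start)` is always a
#' multiple of 3.
#'
#' @param dna a nucleotide [bio_seq()].
#' @param min_aa minimum protein length in residues (default 60, chosen
#'   to admit the shortest precursors of interest; not a biological
#'   constant).
#' @param require_atg require and start at an ATG.
#' @return data.frame with columns `parent_id`, `frame` (+1..+3,
#'   -1..-3), `start`, `end`, `protein`.
#' @examples
#' find_orfs(bio_seq("x", "ATGAAACGATAA", "nucleotide"), min_aa = 3)
#' @export
find_orfs <- function(dna, min_aa = 60L, require_atg = TRUE) {
  stopifnot(inherits(dna, "bio_seq"), dna$alphabet == "nucleotide",
            min_aa >= 1)
  L <- nchar(dna$residues)
  empty <- data.frame(parent_id = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      protein = character(0), stringsAsFactors = FALSE)
  if (L < 3) return(empty)
  out <- list()
  for (strand in c(1L, -1L)) {
    nt <- if (strand == 1L) dna$residues else revcomp(dna$residues)
    for (shift in 0:2) {
      aa <- translate_nt(substr(nt, shift + 1, L))
      if (!nzchar(aa)) next
      # stop-to-stop segments as [aa_start, aa_end) codon index ranges
      stops <- c(0L, which(strsplit(aa, "")[[1]] == "*"), nchar(aa) + 1L)
      for (k in seq_len(length(stops) - 1L)) {
        seg_start <- stops[k]            # codon index (0-based) of first aa
        seg_end <- stops[k + 1L] - 1L    # codon index past last aa
        if (seg_end <= seg_start) next
        prot <- substr(aa, seg_start + 1L, seg_end)
        if (require_atg) {
          m <- regexpr("M", prot, fixed = TRUE)
          if (m < 0) next
          seg_start <- seg_start + (m - 1L)
          prot <- substr(prot, m, nchar(prot))
        }
        if (nchar(prot) < min_aa) next
        has_stop <- stops[k + 1L] <= nchar(aa)
        nt_start <- shift + 3L * seg_start          # on current strand
        nt_end <- shift + 3L * (seg_end + has_stop)
        if (strand == 1L) {
          fwd <- c(nt_start, nt_end)
        } else {
          fwd <- c(L - nt_end, L - nt_start)
        }
        out[[length(out) + 1L]] <- data.frame(
          parent_id = dna$id, frame = strand * (shift + 1L),
          start = fwd[1], end = fwd[2], protein = prot,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
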
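# Independent oracles used across the suite.  These deliberately do not
# share code paths with the package: brute-force scans, closed forms,
# and recursive enumeration at tiny sizes.

# --- six-frame ORF scan: direct codon-walk over every frame ----------
oracle_orfs <- function(dna_string, min_aa, require_atg = TRUE) {
  code <- Biostrings::GENETIC_CODE
  rc <- function(x) chartr("ACGTN", "TGCAN",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  L <- nchar(dna_string)
  found <- character(0)
  for (strand in c(1, -1)) {
    s <- if (strand == 1) dna_string else rc(dna_string)
    for (off in 0:2) {
      aa <- ""
      i <- off + 1
      while (i + 2 <= L) {
        codon <- substr(s, i, i + 2)
        aa <- paste0(aa, if (grepl("N", codon)) "X" else code[[codon]])
        i <- i + 3
      }
      for (seg in strsplit(aa, "*", fixed = TRUE)[[1]]) {
        if (require_atg) {
          m <- regexpr("M", seg, fixed = TRUE)
          if (m < 0) next
          seg <- substr(seg, m, nchar(seg))
        }
        if (nchar(seg) >= min_aa) found <- c(found, seg)
      }
    }
  }
  sort(found)
}

# --- Smith-Waterman by exhaustive recursion (tiny strings only) ------
# enumerates every local alignment (all start pairs, all move
# sequences) under affine gaps: gap of length L costs open + L * ext
oracle_sw <- function(a, b, mat, open = 11, ext = 1) {
  ra <- strsplit(a, "")[[1]]; rb <- strsplit(b, "")[[1]]
  best <- 0
  # state: current score, positions, last move ("m", "ga", "gb")
  rec <- function(i, j, score, last) {
    best <<- max(best, score)
    if (i <= length(ra) && j <= length(rb))
      rec(i + 1, j + 1, score + mat[ra[i], rb[j]], "m")
    if (j <= length(rb))  # gap in a
      rec(i, j + 1, score - (if (last == "ga") ext else open + ext), "ga")
    if (i <= length(ra))  # gap in b
      rec(i + 1, j, score - (if (last == "gb") ext else open + ext), "gb")
  }
  for (i in seq_along(ra))
    for (j in seq_along(rb))
      rec(i, j, 0, "start")
  best
}

# --- p-distance by explicit column loop ------------------------------
oracle_pdist <- function(s1, s2) {
  c1 <- strsplit(s1, "")[[1]]; c2 <- strsplit(s2, "")[[1]]
  ok <- c1 != "-" & c2 != "-"
  sum(c1[ok] != c2[ok]) / sum(ok)
}

# --- additive distance matrix from a random binary tree --------------
# returns list(D, tree); D is exactly additive on the tree
random_additive_matrix <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.5, 3))
  tr$tip.label <- letters[seq_len(n_taxa)]
  D <- stats::cophenetic(tr)
  D <- D[sort(rownames(D)), sort(colnames(D))]
  list(D = D, tree = tr)
}

# random peptide helper
random_peptide <- function(len) {
  paste(sample(names(residue_masses("mono")), len, replace = TRUE),
        collapse = "")
}
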
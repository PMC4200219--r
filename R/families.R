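# Peptide family assignment by motif, and similarity-network clustering
# (all-vs-all Smith-Waterman with Karlin-Altschul edge p-values),
# replacing external PSI-BLAST / CLANS runs with transparent in-package
# equivalents.

#' Compile a peptide family motif pattern
#'
#' Pattern dialect (defined here because family names like "Wx3Yamide"
#' carry no formal grammar):
#' * residue letters match themselves; `[...]` is a residue class;
#' * `x` matches any residue;
#' * `{n}` repeats the preceding element n times;
#' * a trailing `$am` requires the peptide to be C-terminally amidated;
#' * a leading `^` anchors the pattern at the N-terminus; otherwise the
#'   pattern must match a C-terminal suffix of the peptide (family
#'   motifs are C-terminal by convention, so `xPGW$am` matches both
#'   RPGW-amide and a longer ...APGW-amide).
#'
#' @param name family name.
#' @param pattern pattern string, e.g. `"F[MIL]RF$am"`.
#' @return List of class `motif_pattern` with the compiled regex.
#' @export
motif_pattern <- function(name, pattern) {
  amidation_required <- grepl("\\$am$", pattern)
  body <- sub("\\$am$", "", pattern)
  anchored <- startsWith(body, "^")
  if (anchored) body <- substring(body, 2)
  if (!nzchar(body)) stop("pattern for '", name, "' is empty")
  if (grepl("[^A-Zx0-9{}\\[\\]]", body, perl = TRUE))
    stop("pattern for '", name, "' contains unsupported characters: ",
         pattern)
  regex <- gsub("x", ".", body, fixed = TRUE)
  full <- paste0(if (anchored) "^" else "", regex, "$")
  compiled <- tryCatch(regexpr(full, ""), error = function(e)
    stop("pattern for '", name, "' does not compile: ", conditionMessage(e)))
  structure(list(name = name, pattern = pattern, regex = full,
                 amidation_required = amidation_required,
                 anchored = anchored),
            class = "motif_pattern")
}

#' Build a motif library
#'
#' Patterns are compiled at load time so malformed patterns fail early,
#' not at match time.  Names must be unique; library order is the match
#' priority.
#'
#' @param patterns named character vector or list of name = pattern.
#' @return List of class `motif_library`.
#' @export
motif_library <- function(patterns) {
  if (is.list(patterns)) patterns <- unlist(patterns)
  if (anyDuplicated(names(patterns)))
    stop("duplicate family names in motif library")
  structure(mapply(motif_pattern, names(patterns), patterns,
                   SIMPLIFY = FALSE),
            class = "motif_library")
}

#' Default molluscan neuropeptide family motifs
#'
#' Best-effort patterns for the classical families (APGWamide,
#' FMRFamide, FxRIamide, LFRFamide, myomodulin, PXVFamide,
#' sCAP/pyrokinin, luqin) and the novel pattern-named families
#' (PFGx8amide, RxIamide, Wx3Yamide).  The novel patterns follow their
#' names only and are provisional.
#'
#' @return A [motif_library()].
#' @export
default_motif_library <- function() {
  motif_library(c(
    APGWamide = "xPGW$am",
    FMRFamide = "F[MIL]RF$am",
    LFRFamide = "LFRF$am",
    FxRIamide = "xSSFxRI",
    myomodulin = "x[ML]LRL$am",
    PXVFamide = "Px[IV]F$am",
    sCAP_pyrokinin = "FxPRM$am",
    luqin = "QGRF$am",
    PFGx8amide = "PFGx{8}$am",
    RxIamide = "RxI$am",
    Wx3Yamide = "Wx{3}Y$am"
  ))
}

#' Read a motif library from YAML
#'
#' The file maps family names to pattern strings in the
#' [motif_pattern()] dialect; the packaged default is at
#' `system.file("extdata", "motif_library.yaml", package = "neuropep")`.
#'
#' @param path YAML file of `name: pattern` entries.
#' @return A [motif_library()].
#' @export
read_motif_library <- function(path) {
  motif_library(unlist(yaml::read_yaml(path)))
}

#' Assign a peptide to a motif family
#'
#' Returns the first library pattern (library order) matching the
#' mature sequence and whose amidation requirement is satisfied.
#'
#' @param sequence mature peptide string.
#' @param amidated is the peptide C-terminally amidated.
#' @param library a [motif_library()].
#' @return Family name, or `NA_character_` if none match.
#' @examples
#' assign_motif_family("RPGW", TRUE, default_motif_library())
#' @export
assign_motif_family <- function(sequence, amidated = FALSE,
                                library = default_motif_library()) {
  stopifnot(length(library) > 0)
  for (p in library) {
    if (p$amidation_required && !amidated) next
    if (grepl(p$regex, sequence)) return(p$name)
  }
  NA_character_
}

# BLOSUM62 substitution matrix (standard half-bit integer scores)
.BLOSUM62_TEXT <- "
   A  R  N  D  C  Q  E  G  H  I  L  K  M  F  P  S  T  W  Y  V
A  4 -1 -2 -2  0 -1 -1  0 -2 -1 -1 -1 -1 -2 -1  1  0 -3 -2  0
R -1  5  0 -2 -3  1  0 -2  0 -3 -2  2 -1 -3 -2 -1 -1 -3 -2 -3
N -2  0  6  1 -3  0  0  0  1 -3 -3  0 -2 -3 -2  1  0 -4 -2 -3
D -2 -2  1  6 -3  0  2 -1 -1 -3 -4 -1 -3 -3 -1  0 -1 -4 -3 -3
C  0 -3 -3 -3  9 -3 -4 -3 -3 -1 -1 -3 -1 -2 -3 -1 -1 -2 -2 -1
Q -1  1  0  0 -3  5  2 -2  0 -3 -2  1  0 -3 -1  0 -1 -2 -1 -2
E -1  0  0  2 -4  2  5 -2  0 -3 -3  1 -2 -3 -1  0 -1 -3 -2 -2
G  0 -2  0 -1 -3 -2 -2  6 -2 -4 -4 -2 -3 -3 -2  0 -2 -2 -3 -3
H -2  0  1 -1 -3  0  0 -2  8 -3 -3 -1 -2 -1 -2 -1 -2 -2  2 -3
I -1 -3 -3 -3 -1 -3 -3 -4 -3  4  2 -3  1  0 -3 -2 -1 -3 -1  3
L -1 -2 -3 -4 -1 -2 -3 -4 -3  2  4 -2  2  0 -3 -2 -1 -2 -1  1
K -1  2  0 -1 -3  1  1 -2 -1 -3 -2  5 -1 -3 -1  0 -1 -3 -2 -2
M -1 -1 -2 -3 -1  0 -2 -3 -2  1  2 -1  5  0 -2 -1 -1 -1 -1  1
F -2 -3 -3 -3 -2 -3 -3 -3 -1  0  0 -3  0  6 -4 -2 -2  1  3 -1
P -1 -2 -2 -1 -3 -1 -1 -2 -2 -3 -3 -1 -2 -4  7 -1 -1 -4 -3 -2
S  1 -1  1  0 -1  0  0  0 -1 -2 -2  0 -1 -2 -1  4  1 -3 -2 -2
T  0 -1  0 -1 -1 -1 -1 -2 -2 -1 -1 -1 -1 -2 -1  1  5 -2 -2  0
W -3 -3 -4 -4 -2 -2 -3 -2 -2 -3 -2 -3 -1  1 -4 -3 -2 11  2 -3
Y -2 -2 -2 -3 -2 -1 -2 -3  2 -1 -1 -2 -1  3 -3 -2 -2  2  7 -2
V  0 -3 -3 -3 -1 -2 -2 -3 -3  3  1 -2  1 -1 -2 -2  0 -3 -2  4"

#' BLOSUM62 substitution matrix
#' @return 20x20 integer matrix, residue letters as dimnames.
#' @export
blosum62 <- function() {
  con <- textConnection(.BLOSUM62_TEXT)
  on.exit(close(con))
  m <- as.matrix(utils::read.table(con, header = TRUE, row.names = 1,
                                   check.names = FALSE))
  colnames(m) <- rownames(m)
  storage.mode(m) <- "integer"
  m
}

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment score under affine gap penalties: a gap of
#' length L costs `gap_open + L * gap_extend` (BLAST convention for
#' "11/1").  Implemented directly (Gotoh three-matrix recursion); the
#' peptides involved are short, so no compiled code is needed.
#'
#' @param a,b protein strings.
#' @param matrix substitution matrix (default [blosum62()]).
#' @param gap_open,gap_extend affine gap parameters (11 and 1).
#' @return Optimal local score (0 if no positive-scoring alignment).
#' @examples
#' pairwise_align("FMRF", "FLRF")
#' @export
pairwise_align <- function(a, b, matrix = blosum62(), gap_open = 11,
                           gap_extend = 1) {
  stopifnot(nzchar(a), nzchar(b))
  ra <- strsplit(a, "")[[1]]
  rb <- strsplit(b, "")[[1]]
  n <- length(ra); m <- length(rb)
  sub <- matrix[ra, rb, drop = FALSE]
  gapo <- gap_open + gap_extend  # cost of opening a length-1 gap
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in a (horizontal)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in b (vertical)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gapo, E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gapo, F[i - 1, j] - gap_extend)
      h <- max(0, H[i - 1, j - 1] + sub[i - 1, j - 1], E[i, j], F[i, j])
      H[i, j] <- h
      if (h > best) best <- h
    }
  }
  best
}

#' Karlin-Altschul significance of a local alignment score
#'
#' Ungapped-statistics approximation
#' `P = 1 - exp(-K * len_a * len_b * exp(-lambda * score))`
#' with the published BLOSUM62 constants (`lambda` = 0.267, `K` =
#' 0.041, the gapped 11/1 parameter set, raw-score scale).  Monotone
#' decreasing in the score.
#'
#' @param score raw alignment score (>= 0).
#' @param len_a,len_b sequence lengths.
#' @param lambda,K Karlin-Altschul parameters.
#' @return p-value in (0, 1].
#' @export
edge_significance <- function(score, len_a, len_b, lambda = 0.267,
                              K = 0.041) {
  stopifnot(all(score >= 0))
  e_value <- K * len_a * len_b * exp(-lambda * score)
  -expm1(-e_value)
}

#' Build a peptide similarity network
#'
#' All-vs-all Smith-Waterman alignment; pairs whose Karlin-Altschul
#' p-value falls below the threshold become edges, and connected
#' components (union-find) are the peptide families.  Nodes with no
#' significant neighbour (singletons) are dropped from the component
#' report, mirroring the usual practice of removing sequences with no
#' similarity to any other before clustering.
#'
#' @param sequences named character vector of peptide sequences (names
#'   become node identifiers; defaults to seq1, seq2, ...).
#' @param p_threshold edge inclusion threshold (default 1e-5).
#' @param matrix,gap_open,gap_extend alignment parameters.
#' @param lambda,K significance parameters.
#' @return Object of class `cluster_graph`: `nodes` (all input ids),
#'   `edges` (data.frame `i`, `j`, `score`, `pvalue` with `i < j` by
#'   index), `components` (list of id vectors, size >= 2),
#'   `singletons` (ids).
#' @export
build_cluster_graph <- function(sequences, p_threshold = 1e-5,
                                matrix = blosum62(), gap_open = 11,
                                gap_extend = 1, lambda = 0.267, K = 0.041) {
  n <- length(sequences)
  stopifnot(n >= 1)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_len(n))
  ids <- names(sequences)
  edges <- list()
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        sc <- pairwise_align(sequences[[i]], sequences[[j]], matrix,
                             gap_open, gap_extend)
        pv <- edge_significance(sc, nchar(sequences[[i]]),
                                nchar(sequences[[j]]), lambda, K)
        if (pv < p_threshold) {
          edges[[length(edges) + 1]] <- data.frame(
            i = ids[i], j = ids[j], score = sc, pvalue = pv,
            stringsAsFactors = FALSE)
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(i = character(0), j = character(0), score = numeric(0),
               pvalue = numeric(0), stringsAsFactors = FALSE)
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- split(ids, roots)
  sizes <- lengths(comp)
  structure(list(nodes = ids,
                 edges = edges,
                 components = unname(comp[sizes >= 2]),
                 singletons = unlist(unname(comp[sizes == 1]))),
            class = "cluster_graph")
}

#' @export
print.cluster_graph <- function(x, ...) {
  cat("<cluster_graph> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges, ", length(x$components), " components (",
      length(x$singletons), " singletons removed)\n", sep = "")
  invisible(x)
}

#' Write cluster membership as TSV
#' @param graph a `cluster_graph`.
#' @param path output file.
#' @export
write_clusters <- function(graph, path) {
  rows <- do.call(rbind, c(
    lapply(seq_along(graph$components), function(k)
      data.frame(id = graph$components[[k]], component = k,
                 stringsAsFactors = FALSE)),
    list(if (length(graph$singletons) > 0)
      data.frame(id = graph$singletons, component = NA_integer_,
                 stringsAsFactors = FALSE))))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
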
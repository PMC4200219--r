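# Motif families, Smith-Waterman alignment, edge significance and
# similarity-network clustering.

test_that("motif patterns compile, match and enforce amidation", {
  lib <- default_motif_library()
  expect_equal(assign_motif_family("RPGW", TRUE, lib), "APGWamide")
  expect_equal(assign_motif_family("FMRF", TRUE, lib), "FMRFamide")
  expect_equal(assign_motif_family("FLRF", TRUE, lib), "FMRFamide")
  # flexible prefix: patterns anchor at the C-terminus
  expect_equal(assign_motif_family("IQQSSFIRI", FALSE, lib), "FxRIamide")
  # amidation requirement unmet
  expect_true(is.na(assign_motif_family("FMRF", FALSE, lib)))
  expect_true(is.na(assign_motif_family("WWWW", TRUE, lib)))
  # {n} repetition
  lib2 <- motif_library(c(test = "PFGx{8}$am"))
  expect_equal(assign_motif_family("PFGAAAAAAAA", TRUE, lib2), "test")
  expect_true(is.na(assign_motif_family("PFGAAAA", TRUE, lib2)))
  # malformed patterns fail at library load, not at match time
  expect_error(motif_library(c(bad = "F+RF")), "unsupported")
  expect_error(motif_library(c(a = "FMRF", a = "FLRF")), "duplicate")
})

test_that("the shipped YAML library matches the built-in default", {
  path <- system.file("extdata", "motif_library.yaml",
                      package = "neuropep")
  lib <- read_motif_library(path)
  ref <- default_motif_library()
  expect_equal(names(lib), names(ref))
  expect_equal(vapply(lib, `[[`, "", "regex"),
               vapply(ref, `[[`, "", "regex"))
})

test_that("pairwise_align equals self-scores and the brute-force DP", {
  B <- blosum62()
  # self-alignment is the diagonal sum
  expect_equal(pairwise_align("FMRF", "FMRF"),
               B["F", "F"] * 2 + B["M", "M"] + B["R", "R"])
  # exhaustive enumeration oracle on small strings
  set.seed(41)
  for (i in 1:15) {
    a <- random_peptide(sample(2:5, 1))
    b <- random_peptide(sample(2:5, 1))
    expect_equal(pairwise_align(a, b), oracle_sw(a, b, B),
                 info = paste(a, b))
  }
  # symmetry on longer random pairs
  for (i in 1:10) {
    a <- random_peptide(12); b <- random_peptide(9)
    expect_equal(pairwise_align(a, b), pairwise_align(b, a))
  }
})

test_that("pairwise_align agrees with an independent implementation", {
  skip_if_not_installed("Biostrings")
  B <- blosum62()
  set.seed(42)
  for (i in 1:10) {
    a <- random_peptide(sample(5:15, 1))
    b <- random_peptide(sample(5:15, 1))
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(pairwise_align(a, b), ref, info = paste(a, b))
  }
})

test_that("edge_significance follows the closed form and is monotone", {
  # score 0: p ~ 1 for any realistic lengths
  expect_gt(edge_significance(0, 10, 10), 0.95)
  # direct evaluation of the closed form
  for (s in c(10, 25, 40, 60)) {
    want <- 1 - exp(-0.041 * 12 * 15 * exp(-0.267 * s))
    expect_equal(edge_significance(s, 12, 15), want, tolerance = 1e-8)
  }
  # doubling the score strictly decreases the p-value
  s <- seq(5, 80, by = 5)
  p <- edge_significance(s, 10, 10)
  expect_true(all(diff(p) < 0))
  expect_true(all(edge_significance(2 * s, 10, 10) < p))
})

test_that("cluster graph groups related peptides, drops singletons", {
  # two identical peptides of realistic composition form one component
  two <- c(x = "FMRFGWYKRF", y = "FMRFGWYKRF")
  g <- build_cluster_graph(two)
  expect_equal(g$components, list(c("x", "y")))

  # constructed set: 5 related RFamide-type sequences vs 5 unrelated
  fam <- c(f1 = "ALAGDAFLRFGR", f2 = "ALAGDAFLRFGK", f3 = "ALSGDAFLRFGR",
           f4 = "ALAGDAFMRFGR", f5 = "TLAGDAFLRFGR")
  odd <- c(o1 = "GGGGGGGGGGGG", o2 = "PPPPPPPPPPPP", o3 = "NDNDNDNDNDND",
           o4 = "EQEQEQEQEQEQ", o5 = "HSHSHSHSHSHS")
  seqs <- c(fam, odd)
  g <- build_cluster_graph(seqs)
  # oracle: recompute all 45 pairs with an independent aligner
  ids <- names(seqs)
  edges_oracle <- 0
  for (i in 1:9) for (j in (i + 1):10) {
    sc <- Biostrings::pairwiseAlignment(
      seqs[[i]], seqs[[j]], type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11,
      gapExtension = 1, scoreOnly = TRUE)
    pv <- 1 - exp(-0.041 * nchar(seqs[[i]]) * nchar(seqs[[j]]) *
                    exp(-0.267 * sc))
    if (pv < 1e-5) {
      edges_oracle <- edges_oracle + 1
      expect_true(all(c(ids[i], ids[j]) %in% unlist(g$components)))
    }
  }
  expect_equal(nrow(g$edges), edges_oracle)
  expect_length(g$components, 1)
  expect_setequal(g$components[[1]], names(fam))
  expect_setequal(g$singletons, names(odd))

  # loosening the threshold never splits an existing component
  g_loose <- build_cluster_graph(seqs, p_threshold = 1e-3)
  for (comp in g$components) {
    holding <- vapply(g_loose$components, function(cl)
      all(comp %in% cl), logical(1))
    expect_true(any(holding))
  }

  # invariance under input permutation
  set.seed(43)
  g_perm <- build_cluster_graph(seqs[sample(10)])
  canon <- function(x) sort(vapply(x, function(cl)
    paste(sort(cl), collapse = ","), ""))
  expect_equal(canon(g_perm$components), canon(g$components))
})
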
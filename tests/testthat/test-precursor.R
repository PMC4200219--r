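# Signal prediction, cleavage, maturation, repeats and proteome scan.

test_that("predict_signal finds constructed signal peptides", {
  sp <- predict_signal(paste0("MKTLLVLAVLALASSSFA", strrep("Q", 60)))
  expect_true(sp$present)
  expect_gte(sp$cleavage_pos, 16)
  expect_lte(sp$cleavage_pos, 20)

  # maximally hydrophilic: never called
  expect_false(predict_signal(strrep("D", 80))$present)

  # M + 17 Leu guarantees a maximal-hydropathy window
  for (tail in c(strrep("Q", 40), "NDEQNFLDNDEQNFLDNDEQNFLD")) {
    sp <- predict_signal(paste0("M", strrep("L", 17), tail))
    expect_true(sp$present)
  }

  short <- predict_signal("MKTLLVLAVLALASSSFAQQ")
  expect_false(short$present)
  expect_match(short$reason, "30")
})

test_that("find_cleavage_sites reports maximal basic runs", {
  s <- find_cleavage_sites("AAKRAA")
  expect_equal(s$position, 2)
  expect_equal(s$motif, "KR")
  expect_equal(s$basic_run_length, 2)

  # maximal run, no overlapping double-count
  s <- find_cleavage_sites("AKRKRA")
  expect_equal(nrow(s), 1)
  expect_equal(s$basic_run_length, 4)

  expect_equal(nrow(find_cleavage_sites("AAAA")), 0)

  # exhaustive comparison against a regex run-scan on random proteins
  set.seed(31)
  for (i in 1:20) {
    p <- random_peptide(80)
    got <- find_cleavage_sites(p)
    runs <- gregexpr("[KR]{2,}", p)[[1]]
    if (runs[1] == -1) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$position, as.integer(runs) - 1L)
      expect_equal(got$basic_run_length,
                   attr(runs, "match.length"))
    }
  }
})

test_that("monobasic rule calls single Arg with upstream basic", {
  # R at position 4 (0-based), K at position 0 = 4 upstream
  s <- find_cleavage_sites("KAAARAAA", monobasic = TRUE)
  expect_true("monobasic-R" %in% s$motif)
  # no upstream basic at 2/4/6: not called
  s <- find_cleavage_sites("AAAARAAA", monobasic = TRUE)
  expect_false("monobasic-R" %in% s$motif)
  # off by default
  expect_equal(nrow(find_cleavage_sites("KAAARAAA")), 0)
})

test_that("cleave partitions the precursor and consumes dibasic pairs", {
  fr <- cleave("MKRFMRFGKRFMRFGKK")
  expect_equal(fr$sequence, c("M", "FMRFG", "FMRFG"))

  # no sites: single fragment is the whole mature region
  none <- cleave("MAAAPQWAAA")
  expect_equal(none$sequence, "MAAAPQWAAA")

  # odd runs leave the trailing basic on the downstream peptide
  fr <- cleave("AAAKRRPGWGKRA")
  expect_equal(fr$sequence, c("AAA", "RPGWG", "A"))

  # partition identity: fragments + consumed runs restore the protein
  set.seed(32)
  for (i in 1:20) {
    p <- random_peptide(60)
    sites <- find_cleavage_sites(p)
    fr <- cleave(p, NULL, sites)
    consumed <- 2 * (sites$basic_run_length %/% 2)
    pieces <- data.frame(start = fr$start, text = fr$sequence)
    if (nrow(sites) > 0)
      pieces <- rbind(pieces, data.frame(
        start = sites$position,
        text = substring(p, sites$position + 1,
                         sites$position + consumed)))
    rebuilt <- paste(pieces$text[order(pieces$start)], collapse = "")
    expect_equal(rebuilt, p)
  }
})

test_that("infer_ptms applies amidation and pyroglutamate rules", {
  m <- infer_ptms("FMRFG")
  expect_equal(m$sequence, "FMRF")
  expect_true(m$c_amidated)
  expect_equal(round(m$mono_mass, 3), 598.305)

  m <- infer_ptms("QGVWDFDYGLGGGRFG")
  expect_equal(m$sequence, "QGVWDFDYGLGGGRF")
  expect_true(m$c_amidated && m$n_pyroglu)
  expect_equal(round(m$avg_mass, 2), 1655.79)

  m <- infer_ptms("APQW")
  expect_false(m$c_amidated)
  expect_false(m$n_pyroglu)

  # E -> pyroGlu only behind the flag
  expect_false(infer_ptms("EGRF")$n_pyroglu)
  expect_true(infer_ptms("EGRF", pyroglu_from_E = TRUE)$n_pyroglu)

  expect_error(infer_ptms("G"), "empty")
})

test_that("detect_repeats counts copies with deterministic tie-breaks", {
  expect_equal(detect_repeats(c(rep("RPGW", 6), rep("KPGW", 3))),
               list(peptide = "RPGW", count = 6L))
  expect_equal(detect_repeats(c("AA", "BB", "CC"))$count, 1L)
  # tie 2 vs 2: lexicographically smaller of equal lengths
  expect_equal(detect_repeats(c("ZZ", "AA", "ZZ", "AA"))$peptide, "AA")
  # tie with different lengths: shorter wins
  expect_equal(detect_repeats(c("LONGER", "LONGER", "AB", "AB"))$peptide,
               "AB")
})

test_that("a toy APGW-style precursor releases 6 RPGWa and 3 KPGWa", {
  toy <- bio_seq("toy", paste0(
    "MKLLLLLLLLLLLLLLASA", "NDEQNFLD", "KR",
    strrep("RPGWGKR", 6), strrep("KPGWGKR", 3), "APGWG"))
  ann <- annotate_precursor(toy, motif_library = default_motif_library())
  counts <- table(ann$peptides$sequence)
  expect_equal(unname(counts[["RPGW"]]), 6)
  expect_equal(unname(counts[["KPGW"]]), 3)
  expect_equal(ann$summary$top_repeat,
               list(peptide = "RPGW", count = 6L))
  expect_true(all(ann$peptides$c_amidated[
    ann$peptides$sequence %in% c("RPGW", "KPGW", "APGW")]))
  expect_equal(round(ann$peptides$mono_mass[
    ann$peptides$sequence == "RPGW"][1], 1), 513.3)
  fams <- ann$peptides$family[ann$peptides$sequence %in%
                                c("RPGW", "KPGW", "APGW")]
  expect_true(all(fams == "APGWamide"))
})

test_that("annotation invariants hold on synthetic precursors", {
  pr <- make_proteome(synthetic_spec(n_precursors = 5, n_decoys = 0,
                                     seed = 33))
  for (p in pr$proteins) {
    ann <- annotate_precursor(p)
    # stored masses equal recomputation through the mass module
    for (i in seq_len(nrow(ann$peptides))) {
      row <- ann$peptides[i, ]
      ptms <- ptm_set(c_amidated = row$c_amidated,
                      n_pyroglu = row$n_pyroglu)
      expect_equal(row$mono_mass, peptide_mass(row$sequence, ptms))
      expect_equal(row$avg_mass,
                   peptide_mass(row$sequence, ptms, "average"))
      # coordinates point at the peptide within the precursor
      expect_equal(substring(p$residues, row$start + 1, row$end),
                   row$sequence)
    }
    # summary counts equal recomputation from the peptide table
    expect_equal(ann$summary$n_peptides, nrow(ann$peptides))
    expect_equal(ann$summary$n_amidated, sum(ann$peptides$c_amidated))
    expect_equal(ann$summary$n_pyroglu, sum(ann$peptides$n_pyroglu))
  }
})

test_that("scan_proteome separates implants from decoys", {
  pr <- make_proteome(synthetic_spec(seed = 34))
  anns <- scan_proteome(pr$proteins)
  got <- sort(vapply(anns, function(a) a$protein$id, ""))
  want <- sort(pr$truth$proteins$id[pr$truth$proteins$is_precursor])
  expect_equal(got, want)

  # single decoy without sites scores zero
  expect_length(scan_proteome(list(bio_seq("d", strrep("MA", 40)))), 0)
  expect_length(scan_proteome(list()), 0)

  # raising the threshold never adds candidates
  lo <- scan_proteome(pr$proteins, config = scan_config(threshold = 2))
  hi <- scan_proteome(pr$proteins, config = scan_config(threshold = 8))
  expect_true(all(vapply(hi, function(a) a$protein$id, "") %in%
                  vapply(lo, function(a) a$protein$id, "")))
})
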
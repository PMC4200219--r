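# Peptide mass arithmetic, fragmentation, sieve, matching and scoring.

test_that("peptide_mass reproduces the published peptide masses", {
  am <- ptm_set(c_amidated = TRUE)
  pg_am <- ptm_set(c_amidated = TRUE, n_pyroglu = TRUE)
  # printed as 598.31 in the source data; exact computation gives
  # 598.3050, agreement at the 0.01 printed precision
  expect_lt(abs(peptide_mass("FMRF", am, "mono") - 598.31), 0.01)
  expect_equal(round(peptide_mass("G"), 2), 75.03)  # free glycine
  expect_equal(round(peptide_mass("QGVWDFDYGLGGGRF", pg_am, "average"),
                     2), 1655.79)
  expect_equal(round(peptide_mass("QGAWDYDYGLGGGRF", pg_am, "average"),
                     2), 1643.74)
  expect_equal(round(peptide_mass("FGFAPMR", am, "average"), 2), 824.01)
  expect_equal(round(peptide_mass("ALAGDAFLRF", am, "mono"), 1), 1078.6)
  expect_equal(round(peptide_mass("RPGW", am, "mono"), 1), 513.3)
  expect_equal(round(peptide_mass("KPGW", am, "mono"), 1), 485.3)
})

test_that("peptide_mass validates sequence and PTM consistency", {
  expect_error(peptide_mass("FXRF"), "position 2")
  expect_error(peptide_mass("AMRF", ptm_set(n_pyroglu = TRUE)),
               "N-terminal Q")
  expect_error(peptide_mass("AMRF", ptm_set(met_ox = 2)), "Met")
  expect_error(ptm_set(n_pyroglu = TRUE, n_acetyl = TRUE), "exclusive")
  # PTM deltas are exact by definition
  d <- peptide_mass("FMRF", ptm_set(c_amidated = TRUE)) -
    peptide_mass("FMRF")
  expect_equal(d, -0.98402)
  d <- peptide_mass("QGRF", ptm_set(n_pyroglu = TRUE)) -
    peptide_mass("QGRF")
  expect_equal(d, -17.02655)
})

test_that("average mass exceeds mono mass for random peptides", {
  set.seed(21)
  for (i in 1:50) {
    p <- random_peptide(sample(1:30, 1))
    expect_gt(peptide_mass(p, convention = "average"),
              peptide_mass(p, convention = "mono"))
  }
})

test_that("ion_mz implements proton-addition arithmetic", {
  expect_equal(round(ion_mz(598.305, 1), 2), 599.31)
  # algebraic identity between charge states
  for (M in c(598.305, 1500.1, 3999.9))
    expect_equal(ion_mz(M, 1) - 2 * ion_mz(M, 2), -1.00728)
  expect_error(ion_mz(500, 0), "charge")
  # supplementary MS/MS [M+H]+ values
  am <- ptm_set(c_amidated = TRUE)
  expect_equal(round(ion_mz(peptide_mass("GMNPNMNSLFF", am)), 1), 1270.6)
  expect_equal(round(ion_mz(peptide_mass("GLDRYSFYGGL", am)), 1), 1246.6)
  expect_equal(round(ion_mz(peptide_mass("NLGTVDSLYNLPDLLYR", am))), 1965)
})

test_that("fragment series match manual sums and conserve mass", {
  fr <- fragment_ions("FMRF")
  # b2 = F + M + proton, summed by hand
  expect_equal(round(fr$b[2], 2), round(147.06841 + 131.04049 + 1.00728, 2))
  expect_equal(fr$a, fr$b - 27.99491)
  expect_equal(length(fr$b), 3)
  expect_equal(length(fr$y), 3)
  expect_error(fragment_ions("F"), "length")
  # immonium definition
  expect_equal(unname(fr$immonium["F"]), 147.06841 - 26.00307)

  # b_i + y_{n-i} = M + 2 protons, 100 random modified peptides
  set.seed(22)
  for (rep in 1:100) {
    p <- random_peptide(sample(2:25, 1))
    ptms <- ptm_set(c_amidated = sample(c(TRUE, FALSE), 1),
                    n_pyroglu = substr(p, 1, 1) == "Q")
    fr <- fragment_ions(p, ptms)
    M <- peptide_mass(p, ptms)
    n <- nchar(p)
    for (i in seq_len(n - 1))
      expect_equal(fr$b[i] + fr$y[n - i], M + 2 * 1.00728,
                   tolerance = 1e-9)
  }
})

test_that("mass_sieve applies inclusive bounds and is idempotent", {
  pl <- peak_list(c(500, 600, 4000, 4100))
  sieved <- mass_sieve(pl)
  expect_equal(sieved$mz, c(600, 4000))           # inclusive boundaries
  expect_equal(mass_sieve(sieved)$mz, sieved$mz)  # idempotent
  expect_error(mass_sieve(pl, 4000, 600), "low < high")

  set.seed(23)
  mz <- runif(1000, 100, 5000)
  got <- mass_sieve(peak_list(mz))
  expect_equal(nrow(got), sum(mz >= 600 & mz <= 4000))  # brute force
  expect_equal(got$mz, sort(mz[mz >= 600 & mz <= 4000]))
})

test_that("match_precursor_masses respects the ppm tolerance", {
  am <- ptm_set(c_amidated = TRUE)
  cand <- data.frame(sequence = "FMRF",
                     mono_mass = peptide_mass("FMRF", am))
  hit <- match_precursor_masses(peak_list(599.31), cand, tol_ppm = 300)
  expect_equal(nrow(hit), 1)
  expect_lt(abs(hit$error_ppm), 20)
  expect_equal(nrow(match_precursor_masses(peak_list(470.0), cand)), 0)
  # degenerate tolerance: only exact equality
  exact <- ion_mz(cand$mono_mass)
  expect_equal(nrow(match_precursor_masses(peak_list(exact), cand,
                                           tol_ppm = 0)), 1)
  expect_equal(nrow(match_precursor_masses(peak_list(exact + 1e-4), cand,
                                           tol_ppm = 0)), 0)
  expect_equal(nrow(match_precursor_masses(peak_list(numeric(0)), cand)),
               0)
})

test_that("matching agrees with a brute-force filter and ignores order", {
  set.seed(24)
  cands <- data.frame(
    sequence = replicate(20, random_peptide(8)),
    stringsAsFactors = FALSE)
  cands$mono_mass <- vapply(cands$sequence, peptide_mass, numeric(1))
  mz <- runif(200, 600, 4000)
  got <- match_precursor_masses(peak_list(mz), cands, tol_ppm = 300)
  # brute force count
  n_expected <- 0
  for (m in mz) for (j in seq_len(nrow(cands))) {
    t <- cands$mono_mass[j] + 1.00728
    if (abs(m - t) / t * 1e6 <= 300) n_expected <- n_expected + 1
  }
  expect_equal(nrow(got), n_expected)
  # permutation invariance
  perm <- sample(length(mz))
  got2 <- match_precursor_masses(peak_list(mz[perm]), cands, tol_ppm = 300)
  expect_equal(got, got2)
})

test_that("spectrum score behaves like a -10log10 binomial tail", {
  p <- "ALAGDAFLRF"
  fr <- fragment_ions(p)
  full <- peak_list(c(fr$b, fr$y))
  s <- score_spectrum_match(full, p)
  expect_equal(s$n_matched, s$n_ions)
  expect_gt(s$score, 20)   # every ion present clears the filter
  # closed form check: all n trials success -> P = p_match^n
  pm <- min(1, 2 * 0.6 * nrow(full) / max(100, diff(range(full$mz))))
  expect_equal(s$score, -10 * log10(pm^s$n_ions), tolerance = 1e-6)

  noise <- peak_list(c(3901.3, 3902.7, 3950.1))
  s0 <- score_spectrum_match(noise, p)
  expect_equal(s0$n_matched, 0)
  expect_equal(s0$score, 0)
  expect_equal(score_spectrum_match(peak_list(numeric(0)), p)$score, 0)

  # adding a matched ion never lowers the score
  set.seed(25)
  spec <- peak_list(runif(30, 600, 4000))
  base <- score_spectrum_match(spec, p, mass_range = 3400)
  more <- peak_list(c(spec$mz, fr$b[3]))
  expect_gte(score_spectrum_match(more, p, mass_range = 3400)$score,
             base$score)
})

test_that("peak list I/O round-trips and accepts comments", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# a comment", "650.5,100", "1200.25\t55", "700 7"), f)
  pl <- read_peaklist(f)
  expect_equal(pl$mz, c(650.5, 700, 1200.25))  # sorted
  expect_equal(pl$intensity, c(100, 7, 55))
  write_peaklist(pl, f)
  expect_equal(read_peaklist(f)$mz, pl$mz)
})
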
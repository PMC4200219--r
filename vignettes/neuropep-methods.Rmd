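---
title: "Methods: prohormone mining, peptide mass prediction and family analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prohormone mining, peptide mass prediction and family analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuropep)
```

## The problem

Neuropeptides are short signalling peptides produced from larger
precursor proteins (prohormones). A prohormone carries an N-terminal
signal peptide, one or more — often many identical — bioactive
peptides, and basic cleavage sites (KK, KR, RK, RR) recognised by
prohormone convertases. After cleavage, carboxypeptidase removes the
exposed basic residues; a C-terminal glycine is converted into an
amide on the preceding residue; an N-terminal glutamine may cyclise
into pyroglutamate. Because precursors evolve fast while the short
active cores are conserved, prohormones are found in genome-scale
protein sets by their *architecture* — recurrent basic motifs, repeat
structure, a signal peptide — rather than by overall homology, and the
predicted products are then confirmed by MALDI mass spectrometry.

`neuropep` implements that whole chain as a reusable, testable R
pipeline: candidate discovery, in-silico maturation, mass and
fragment-ion prediction, peak-list matching, motif/similarity family
assignment, and distance phylogeny — plus a synthetic-proteome
generator with ground truth so that every stage can be validated
without any external database or binary.

## Processing model

### Signal peptides

External signal-peptide predictors are replaced by a transparent
heuristic (`predict_signal()`): for each candidate cleavage position
`pos` in 15–40, the score is the best mean Kyte–Doolittle hydropathy
over 8-residue windows in residues 3..(pos−3), plus a bonus of 0.5 for
a small residue (A/G/S/C/T) at each of the −3 and −1 positions; a
signal is called when the score reaches 2.0 hydropathy units. Two
refinements matter in practice:

* the best hydrophobic window must end within 13 residues of the
  cleavage site (the c-region is short); without this, any pair of
  small residues far downstream — notably the Gly of amidation signals
  inside repeat blocks — can mimic a site;
* score ties are resolved toward the most C-terminal position, since
  the peptidase cuts after the complete c-region.

Externally produced cleavage positions can be injected from a TSV via
`scan_config(signal_tsv = ...)`, keeping the rest of the pipeline
unchanged.

### Cleavage

`find_cleavage_sites()` reports every maximal run of ≥ 2 basic
residues (position, motif = first two residues, run length). At
cleavage (`cleave()`), each run is partitioned into dibasic pairs from
its start and the pairs are consumed; when the run length is odd, the
final basic residue is retained at the N-terminus of the downstream
fragment. The retained-residue rule is forced by biology: repeat
peptides that begin with K or R (e.g. RPGWamide, KPGWamide) sit
directly behind their separator site, so `...KR|RPGWG|KR...` contains
a KRR run of which only the KR pair is removed — consuming the whole
run would amputate the peptide's first residue and no R/K-initial
peptide could ever be produced. For even runs (KK, KR, RK, RR, RRRR)
the rule coincides with consuming the entire run, so longer runs never
cause double cleavage.

A monobasic rule (single Arg preceded 2/4/6 residues upstream by a
basic residue) is available but off by default, since no quantitative
monobasic convention is established.

### Maturation

`infer_ptms()` applies the two automatic modifications: a fragment
ending in Gly (and every fragment is followed by a site or the
C-terminus by construction) loses the Gly and is flagged C-terminally
amidated; an N-terminal Gln is flagged pyroglutamate (Glu optionally,
behind a flag, off by default). N-terminal acetylation is never
auto-asserted — it remains a search-time variable modification —
because the sequence carries no acetylation signal. The lone fragment
`"G"` is an error (amidation would empty it); the scanner drops such
fragments.

### Candidate scoring

`scan_proteome()` ranks proteins by

```
score = w1·(#cleavage sites) + w2·(max repeat count − 1)
      + w3·(#peptides matching the motif library) + w4·[has signal]
```

with defaults `w = (1, 2, 3, 1)` and threshold 4. The weights are a
package-level design choice (no quantitative definition of "recurrent"
motifs exists to copy); the defaults were fixed once against the
synthetic world and give clean separation of implanted precursors from
decoys. Raising the threshold is monotone: it can only remove
candidates.

## Masses and spectra

Residue masses are the standard monoisotopic and average (ExPASy
convention) tables; both conventions are first-class because published
MALDI peptide values mix them (a 4-residue amide at 598.3 is
monoisotopic; 15-residue values like 1655.79 are average). All stored
masses are neutral; protons (1.00728 Da) are added only when an m/z is
formed. PTM deltas: amidation −0.98402 (mono), pyroglutamate from Gln
−17.02655, from Glu −18.01056, acetylation +42.01057, Met oxidation
+15.99491, dioxidation +31.98983.

`fragment_ions()` produces singly protonated a/b/y series and immonium
masses: `b_i` = sum of the first `i` residues + N-terminal PTM delta +
proton; `a_i = b_i − 27.99491` (CO loss); `y_k` = sum of the last `k`
residues + water + amidation delta + proton; immonium = residue −
26.00307. The conservation identity `b_i + y_{n−i} = M + 2·proton`
holds exactly and is property-tested on random modified peptides.

Peak matching uses the experiment-level tolerances as defaults: an
inclusive 600–4000 Da detection sieve (`mass_sieve()`; peptides
outside it are unobservable, which the pipeline reports rather than
hides), 300 ppm for precursor masses (`match_precursor_masses()`,
signed ppm errors reported), and 0.6 Da for fragments.

`score_spectrum_match()` replaces a proprietary search-engine score
with an explicit null model on the same `−10·log10(P)` scale: with `k`
of `n` theoretical b/y ions matched within the fragment tolerance and
a per-ion chance-match probability `p = 2·frag_tol·N_peaks /
mass_range`, the score is `−10·log10 P[Binom(n, p) ≥ k]`. The
conventional "score > 20" significance filter therefore applies
directly; a complete ion series scores far above it, pure noise scores
0, and the score is monotone in the number of matched ions by
construction. `mass_range` defaults to the observed spectrum span
(floored at 100 Da to keep the null model sane on narrow spectra).

## Families

**Motifs.** Family patterns use a small dialect (`x` wildcard,
`[..]` classes, `{n}` repetition, trailing `$am` = amidation
required, leading `^` = N-terminal anchor). Patterns without `^`
match a C-terminal *suffix* of the peptide: family motifs are
C-terminal by convention, and published assignments (e.g. a 9-mer
matching an `xSSFxRI` convention) require a flexible prefix. Patterns
compile at library load, so malformed patterns fail early. The shipped
library covers the classical molluscan families; the three
pattern-named novel families (PFGx8amide, RxIamide, Wx3Yamide) are
transcribed from their names only and are flagged provisional.

**Similarity network.** An external all-vs-all BLAST + CLANS run is
replaced in-package by Smith–Waterman local alignment (Gotoh affine
gaps, BLOSUM62, 11/1, a gap of length L costing 11 + L) and the
Karlin–Altschul tail approximation `P = 1 − exp(−K·m·n·e^{−λ·S})`
with the published BLOSUM62 constants λ = 0.267, K = 0.041 (raw-score
scale; both configurable). Pairs with `P < 1e-5` become edges;
connected components are families; nodes without any significant
neighbour are dropped from the component report. Note the practical
consequence of the formula: very short peptides (4-mers) cannot reach
`P < 1e-5` even when identical — network clustering is informative for
peptides of roughly 8 residues and up, which matches how such networks
are used on full repertoires rather than on tetrapeptides.

**Phylogeny.** Multiple alignment is out of scope (pre-aligned FASTA
in; a gap-free stacker for equal-length peptides is provided).
`p_distance()` counts mismatches over gap-free sites; `nj_tree()` is a
direct Saitou–Nei implementation with the Studier–Keppler Q-criterion,
deterministic lowest-index tie-breaks, and negative branch lengths
clamped to zero with a warning. On additive matrices it is exact
(property-tested against generated trees). `bootstrap_support()`
resamples columns, rebuilds NJ per replicate, reports percentage
support per internal bipartition of the full-data tree, and collapses
bipartitions below the cutoff (default 50 at 1000 replicates) into
polytomies; everything is seeded and reruns are byte-identical.

## The synthetic world

`synthetic_spec()` states the world once: 5 implanted precursors among
95 decoys; each precursor is
`[signal][spacer·KR]([peptide]·G·[dibasic])×copies[spacer]` with
repeat peptides modelled on classical families (RPGW ×3–6, FMRF ×4–8,
FGFAPMR ×2–4, GMPMLRL ×2–5, APQWRPQGRF ×2–3); generated signal
peptides have an n/h/c architecture the heuristic is *not* tuned to
(the generator predates the thresholds and is shared by all tests);
decoys contain no dibasic runs (a `hard_decoys` mode adds runs without
repeat structure to exercise the score weights instead of clean
separability). Peak lists carry one [M+H]+ peak per distinct implanted
peptide with uniform multiplicative error of ±50 ppm — a
well-calibrated reflector instrument; uniform rather than Gaussian so
the worst case is bounded by the 300 ppm matching tolerance — plus 20
uniform noise peaks in 600–4000 Da and log-normal intensities.

Design details that keep the world honest rather than easy: the
N-terminal spacer ends in a dibasic site so the first repeat copy
matures like the others; spacers avoid small residues so they cannot
fake the −3/−1 signal-peptidase fingerprint, and never end in Gly so
they cannot fake amidation. What a green end-to-end test establishes
is therefore: precursor-level precision = recall = 1.0 and
peptide-level recall 1.0 under clean decoy separation. What it does
*not* establish: performance on real genomes, where decoys do contain
dibasic runs, signal peptides are diverse, splice variants and
non-canonical processing exist, and curator judgment enters; spacer
by-products also count against peptide-level precision (≈ 0.6–0.7
here), which is the realistic behaviour of any cleavage-rule
predictor.

`evaluate_recovery()` scores predictions at precursor and peptide
level (exact sequence + PTM flags, multiset semantics so copy numbers
matter). With no predictions, precision is 1.0 by convention — no
false positive was made.

## Numerical and design choices

* ORFs are stop-to-stop in all six frames, optionally truncated at the
  first ATG (default on); coordinates are 0-based half-open on the
  forward strand and include the terminating stop codon. The default
  `min_aa = 60` admits the shortest precursors of interest and is a
  configurable choice, not a biological constant. `N` translates to
  `X`; `X` has no mass and requesting one is an error.
* `detect_repeats()` ties break to the shorter then lexicographically
  smaller peptide; scan ranking is a stable sort — all outputs are
  deterministic.
* The binomial spectrum score uses the observed spectrum span as its
  mass range; an empty spectrum scores 0 rather than erroring.
* Bootstrap replicates whose resampled distance matrix is degenerate
  (a pair with no comparable sites) are skipped, counting against
  support — the conservative direction.
* YAML configs round-trip exactly; every run logs the thresholds used
  and a hash of the config, and reruns of the same config produce
  identical artifacts.

## Known limitations

No machine-learned signal model, no splice handling, no isotope
envelopes or charge deconvolution, no multiple alignment, no
maximum-likelihood phylogeny, no force-directed network layout.
Acetylation is only a search-time modification. The novel-family
patterns are provisional transcriptions of their names. The
Karlin–Altschul constants are ungapped-statistics approximations used
with gapped scores, as is common for quick significance screens;
absolute p-values should be read as a ranking device around the fixed
1e-5 edge threshold, not as calibrated probabilities.
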
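---
title: "foldscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{foldscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Functional RNA secondary structure leaves a thermodynamic fingerprint:
evolution arranges a sequence so that its folded state is more stable than
the nucleotide composition alone would predict. `foldscan` detects this
*ordered stability* in mRNAs. A sliding window (default 120 nt, step 1 nt)
is folded at its minimum free energy (MFE, $\Delta G$, kcal/mol); the window
sequence is then shuffled (default: 100 mononucleotide shuffles) and each
shuffle is folded, giving the thermodynamic z-score

$$ z = \frac{\Delta G_\mathrm{native} - \overline{\Delta G}_\mathrm{shuffled}}
          {\sigma(\Delta G_\mathrm{shuffled})} $$

so each negative unit is one standard deviation more stable than
composition-matched random sequence. An empirical p-value (fraction of
shuffles at or below the native energy) and the ensemble diversity (ED, the
Boltzmann-weighted mean base-pair distance of the thermodynamic ensemble)
accompany each window.

A consensus stage then turns the per-window structures into one structure
model per transcript. Every base pair occurring in any window's MFE
structure is tallied in transcript coordinates: its **Zsum** is the sum of
the z-scores of the windows containing it, and its **Znorm** is Zsum
divided by a window-exposure denominator (see below). Pairs are accepted
greedily in ascending Znorm under a *competition of one* constraint (each
nucleotide has at most one partner), giving an involution. Maximal nested
components of the accepted pairing are *motifs*; a motif is reported when
its most negative pair Znorm is at or below a threshold (−1 or −2 standard
deviations in practice).

Downstream helpers aggregate windows per transcript and per region
(5'UTR/CDS/3'UTR from GENCODE-style FASTA headers), compare structure
models with DMS/SHAPE chemical-probing reactivities via ROC analysis
(pairing calls sweep a reactivity percentile from 0% to 100% in 1% steps;
TPR = TP/(TP+FN), FPR = FP/(FP+TN), AUC by trapezoid), and bin covariation
power tables into [0, 0.1), [0.1, 0.25) and [0.25, ∞).

## The folding backend

The scanning layer treats folding as a contract (`fold_backend()`): MFE
structure + energy, batch energies, ensemble diversity, and
energy-of-structure. Two adapters ship.

The default `"nn"` backend is a self-contained reduced nearest-neighbor
engine (C++): Watson–Crick and wobble stacking free energies, tabulated
hairpin/bulge/internal-loop initiation with Jacobson–Stockmayer
extrapolation beyond 30 unpaired nucleotides, a Ninio asymmetry penalty
(0.6 kcal/mol per asymmetry unit, capped at 3.0), a linear multibranch
model (3.4 close + 0.4 per branch), and a 0.5 kcal/mol terminal AU/GU
helix-end penalty, all at 37 °C. MFE is computed by a Zuker-style dynamic
program (max two-sided loop size 30, minimum hairpin loop 3, ambiguity
codes never pair) and ED by a matching McCaskill partition function with an
outside pass. Deliberately omitted: dangles, terminal mismatches, special
tetraloops and 1×1/2×2 internal-loop tables, pseudoknots, suboptimal
enumeration. The omissions shift absolute MFE values by roughly 5–15%
relative to a full Turner 2004 implementation (on random 120-mers the two
correlate at about r = 0.96), but the z-score compares native and shuffled
windows under the *same* model, so the ordered-stability contrast — the
quantity the pipeline is built around — is preserved.

The `"rnafold"` backend shells out to an installed ViennaRNA `RNAfold`
binary and is selected explicitly when absolute Turner-parameter energies
are needed. Because absolute MFE values depend on the parameter set, every
file writer records the backend name and version in its header, and
published absolute energies (e.g. per-transcript mean windowed MFE) should
only be compared across identical backends.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `window` | 120 | nt | matches the typical extent of local regulatory elements (most known cis-regulatory structures are < 150 nt) |
| `step` | 1 | nt | every interior nucleotide is seen by `window` windows, removing window-placement artifacts |
| `n_randomizations` | 100 | shuffles | empirical null resolution of 0.01 in p; z stabilizes well below this |
| shuffle `mode` | mononucleotide | — | the null preserves base composition; dinucleotide mode additionally preserves all 16 dinucleotide counts (Altschul–Erickson Euler-path shuffle) |
| `temperature_c` | 37 | °C | physiological; the built-in parameter set is defined at 37 °C (the partition function uses the requested temperature only in kT) |
| motif thresholds | −1, −2 | sd | one/two standard deviations of ordered stability; −2 marks exceptional motifs |

## Numerical choices and edge cases

* **Standard deviation**: sample (n−1) estimator. If all shuffled energies
  are identical (sd = 0; e.g. homopolymer windows) the window is flagged
  `degenerate` and reports z = 0, p = 1 by convention — leaving z undefined
  would poison every downstream average.
* **p-value ties** count as "at or below" the native energy.
* **Znorm denominator**: the number of windows containing that exact pair
  (`denominator = "pair"`), making Znorm the mean z of the windows
  supporting the pair and symmetric in both endpoints. The alternative
  reading — windows in which the *nucleotide* is paired to any partner —
  is implemented behind `denominator = "nucleotide"` (symmetrized as the
  mean of the two endpoint counts). Both appear in the test suite on a
  three-window fixture where they disagree.
* **Competition resolution**: global greedy in ascending Znorm, ties broken
  by smaller i then smaller j; a pair is accepted iff both endpoints are
  free. This guarantees determinism and the one-partner involution.
* **Crossing pairs**: greedy selection can retain pseudoknotted pair sets.
  They stay in the arc track (annotated `crossing`), but before motif/CT/
  dot-bracket emission the higher-Znorm pair of each crossing is discarded,
  since those formats require nested structures.
* **Motif delimitation**: a motif is everything enclosed by an outermost
  accepted pair, internal unpaired stretches included; isolated pairs form
  one-pair motifs. The same delimitation is used at every threshold, so the
  −2 motif set is a subset of the −1 set by construction.
* **Unpaired-position annotation** in the final-partners track is the
  per-nucleotide windowed z-average, so every position carries a value.
* **ROC pairing calls**: "paired at threshold x%" means membership in the
  lowest-x% reactivity set among applicable positions (missing values and,
  optionally for DMS, non-A/C positions excluded), with ties broken by
  position. This is the only reading that forces TPR = FPR = 0 at 0% and
  1 at 100%. AUC is trapezoidal; structures with zero paired or zero
  unpaired positions return NA with a warning.
* **Region coordinates** are 1-based inclusive transcript-local spans
  everywhere (CT, wig, GFF3 conventions). Transcripts lacking a region
  annotation are excluded from that region's aggregate and reported with
  an NA mean and a zero covered-position count.

## The synthetic-data generator

`make_transcript()` emulates exactly the features the scanning statistics
rest on: an i.i.d. mononucleotide background (matching the mononucleotide
shuffle null, so background windows score z ≈ 0) with GC-rich perfect
hairpins (default one 12-bp stem, 4-nt loop, 150 nt total in a 30/60/60
UTR5/CDS/UTR3 layout) planted at recorded positions. Every planted pair is
recorded; recovery statistics are computed against that record, never
re-derived. `make_reactivity()` draws unpaired positions from a high-mean
and paired positions from a low-mean normal (1.2 vs 0.2, sd 0.3 by
default), truncated at zero — with sd 0 the generating structure is
perfectly separable (AUC = 1).

What the generator deliberately does **not** emulate: real transcripts'
dinucleotide and codon structure, imperfect stems (bulges/internal loops),
alternative isoform overlap, probing-reagent sequence bias, and coverage-
dependent reactivity noise. A green recovery test therefore establishes
that the machinery finds *planted, thermodynamically ideal* signals above a
composition-matched background — not that real-transcriptome motif counts
are reproduced. Conversely the quantitative transcriptome-scale figures
(global mean windowed z, motif totals, expression-class contrasts) require
cluster-scale computation on external data and are covered by
property-based tests (conservation laws, arithmetic identities, brute-force
window/coverage enumeration, involution invariants, monotonicity,
recovery/null calibration, ROC endpoint/permutation behavior,
end-to-end determinism) rather than numeric reproduction.

## Known limitations

* The built-in energy model trades absolute accuracy for independence;
  absolute MFE-based quantities are backend-relative (headers record the
  backend for this reason).
* Whole-transcript scans at 120/1/100 cost roughly 0.6 s per window on one
  CPU; transcriptome-scale runs need external parallelization (the CLI
  exposes per-transcript granularity).
* No pseudoknot prediction; crossing consensus pairs are resolved away
  before structure emission.
* Expression-class summaries average over transcripts, not genes; the
  choice is recorded in the output metadata.
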
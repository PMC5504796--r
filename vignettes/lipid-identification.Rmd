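---
title: "Rule-based lipid identification: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based lipid identification: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidrules)
library(dplyr)
```

# The problem

In untargeted LC-MS/MS lipidomics a *feature* — a peak defined by m/z and
retention time — often carries several co-eluting lipids with
indistinguishable precursor masses, typically isomers sharing a lipid class
and total carbon/double-bond counts but differing in fatty acyl
constituents. Spectral-similarity scoring handles this situation poorly:
extra fragments from co-isolated species depress the score, and annotations
are frequently reported at more structural detail than the spectra justify.
`lipidrules` takes the alternative route: identification is a boolean rule
over which theoretical fragments were actually observed, the claimed
structural resolution is tied to the rule outcome, and co-eluting candidates
are ranked by summed fragment intensity as an estimate of their relative
signal contribution to the feature.

# Mass model

All m/z values derive from a single embedded table of monoisotopic atomic
masses (`atomic_masses()`, IUPAC values: C 12, H 1.00782503207,
N 14.0030740048, O 15.9949146196, P 30.97376163, S 31.97207100,
Na 22.9897692809, K 38.96370668) plus the electron rest mass
0.00054857990946 Da. The electron mass is applied exactly once per charge in
every ion m/z — cations lose it, anions gain it. This matters at the
instrument's accuracy: the protonated phosphocholine head-group fragment is
184.0733 with the correction and 184.0739 without, and the formate adduct of
PC(16:0/22:6) is 850.5604 versus 850.5598. Display rounding is 4 decimal
places, half away from zero (`round_half_up()`); library files store 6
decimals, and all tolerance arithmetic uses the stored full-precision
values, never rounded display values.

A fatty acyl chain is `carbons:double_bonds` with the free-fatty-acid
formula CnH(2n−2d)O2. Linkage offsets relative to the acyl form are
constants: alkyl (plasmanyl, `O-` prefix) −O +2H; alkenyl (plasmenyl, `P-`)
−O. Oxidation bookkeeping is by molecular-formula delta: each `+kO` token
adds k oxygens and `-kH` removes hydrogens; terminal `CHO` replaces the
terminal methyl with a carbonyl (−2H +O) and `COOH` with a carboxyl
(−2H +2O). A lipid's neutral mass is
`backbone + sum(chain FA masses) − n_chains × H2O`, with the backbone being
the head-group alcohol (e.g. glycerophosphocholine C8H20NO6P for PC,
glycerol for MG/DG/TG, sphingosine-based backbones for SM and Cer whose
d18:1 base is part of the class definition).

## The ketone/epoxide ambiguity

An oxygen added "as a ketone or epoxy" admits two mass conventions: +O
(epoxide-like; a ketone formed at a former double bond also nets +O in the
CnH(2n−2d)O2 bookkeeping because the lost unsaturation cancels the lost
hydrogens) and the explicit carbonyl +O −2H. We default to +O, matching
common oxidized-lipid sum-formula conventions, and expose the −2H variant
through `generate_oxidized_fas(keto_variant = TRUE)`. Neither choice is
claimed to be uniquely correct; both are implemented and the default is
documented here.

# Library generation

`enumerate_chain_sets()` produces all multisets of k chains from a pool —
combinations with repetition, `choose(n + k − 1, k)` of them — so redundant
permutations like `18:0_20:0` versus `20:0_18:0` never arise. Within a set,
chains are ordered canonically: ascending carbons, then double bonds, then
oxidation count, then label. The canonical order is our convention (no
standard exists for unknown sn-positions); it exists purely so that equal
species render equal annotation strings and deduplicate.

The shipped default pool has 39 chains (even- and odd-carbon saturates
C12–C24 and common mono/polyunsaturates, `inst/extdata/fa_pool_default.csv`)
giving 780 pairs and 10,660 triples. Oxidized chains come from
`generate_oxidized_fas()`: long-chain products add 1..d oxygen-bearing
groups (O, OH, OOH) to each parent with d double bonds and are deduplicated
by formula delta — O and OH collide at +O, and +2O arises both as one OOH
and as two single additions; short-chain products cleave each parent at each
double-bond position p (positions from the editable
`inst/extdata/double_bond_positions.csv`), keeping p carbons and the double
bonds below p, capped by CHO or COOH. Saturated parents produce nothing.
Both fixture tables are conventions, not measurements: pool composition and
the resulting product counts are expected to be edited per study.

Class templates (`default_fragment_templates()`) describe fragments by mode:
fixed ion formulas (the 184.0733 head group, cholestadienyl 369.3516),
per-chain carboxylate anions RCOO−, per-chain acylium-like cations, and
neutral losses of a formula, a chain, or both (TG's ammonia + fatty acid
losses). Per-chain templates use an `{i}` placeholder expanded to the
class's chain count. Sixteen classes ship by default (PC, PE, PS, PG, PI,
PA, LPC, LPE, SM, Cer, MG, DG, TG, CE, OxPC, OxTG); new classes are a
definition row plus template and rule rows, no code. Cardiolipin-scale
four-chain enumeration is supported by the combinatorics (k ≤ 4) but not
shipped as a default build: the full oxidized-TG and CL spaces are
combinatorially heavy, and the builder accepts restricted pools instead.
Library files are plain CSV (`class, annotation, adduct, precursor_mz`, one
column per fragment label) so users can author their own in a spreadsheet.

# The identification engine

Seven steps per feature table, with the tunable parameters:

| parameter | default | units | role |
|---|---|---|---|
| `ms1_tol_da` | 0.005 | Da | precursor exact-mass match (Step 1); absolute, per convention for MS1 matching |
| `rt_window_min` | 0.3 | min | scan assignment around the feature RT (Step 2) |
| `isolation_window_mz` | 1.0 | m/z | full isolation width; scans match within half of it each side (Step 2) |
| `frag_tol_ppm` | 10 | ppm | fragment matching, relative (Step 3) |
| `min_intensity` | 1000 | counts | fragment confirmation threshold (Step 4); detector-dependent, must be reviewed per instrument |
| `min_scans` | 1 | scans | confirmation scan count (Step 4) |
| `precursor_only` | FALSE | — | whether code-4 candidates are reported |

The isolation-window choice (half-width each side) and the Da/ppm split are
documented conventions. When several peaks of one scan fall inside a
fragment's window the most intense is taken; the per-fragment profile
records scan count, maximum intensity, the unweighted mean of the chosen
peaks' m/z, and the RT of the scan holding the maximum.

Rules are groups of fragment labels with a minimum pass count, typed
`chain` or `class`. Confidence 1 requires every group; confidence 3 all
class groups but not every chain group; confidence 4 (opt-in) a precursor
match without satisfied rules; confidence 2 is reserved for
data-independent acquisition and never emitted. Structural resolution
follows the code: acyl-constituent text (`PC(16:0_22:6)`, underscore =
sn-position unknown) only at code 1, sum composition (`PC(38:6)`) at codes 3
and 4. The shipped defaults require both acyl carboxylates for
formate-adduct PCs, the 184.0733 head group plus at least one acyl neutral
loss for protonated PCs, all chain neutral losses for TGs, and analogous
requirements per class; SM and LPC positive mode are capped at class level
because the choline fragment alone cannot distinguish chains.

Ranking: a candidate's summed intensity adds the per-fragment maxima of
*all* its theoretical fragments seen in at least one scan, including
fragments not required for confirmation and fragments below the
confirmation intensity threshold. The threshold governs confirmation, not
ranking — a deliberate reading of "all their fragments ... including those
not used for confirmation"; sub-threshold but matched signal still reflects
contribution to the feature. Ties break by annotation text, then adduct,
ascending — determinism, not a chemical claim. One experimental peak may
serve multiple candidates' fragment slots; no de-sharing is attempted, so
the known inflation of weak isobars sharing a strong fragment is reproduced,
not corrected (see below).

# Cross-software combining

`align_and_append()` appends annotation columns from one feature table onto
another when features agree within a ppm window (evaluated on the base
feature's m/z) and an RT window. Best-match semantics: smallest |ppm|, then
smallest |ΔRT|, then first row. We chose best-match over all-matches because
appended columns must stay rectangular; one donor row may serve several base
rows, and base rows and cells are never modified.

# The synthetic data generator

`simulate_dda()` emulates exactly the structure the engine consumes:
co-eluting isobars grouped onto one feature (precursors within 1 mDa),
scans at configurable RT offsets around the feature apex, each planted
lipid's template fragments at intensities following a Gaussian
chromatographic profile (configurable σ, default 0.05 min) centred on the
lipid's own apex, optional uniform noise peaks (m/z 105–1100) and Gaussian
ppm jitter. The seed fixes all randomness; equal seeds give byte-identical
files. Default planted settings: 8 scans across ±0.12 min, fragment
intensity 20% of the planted precursor intensity.

What it deliberately does not emulate: isotope envelopes, chimeric
co-isolation beyond planted co-elution, detector saturation, mass-dependent
resolution, real chromatographic tailing, and in-source fragmentation.
Passing the synthetic suites therefore demonstrates the engine's logic
(matching, thresholds, rules, ranking, the documented pathologies) on clean
and mildly noisy inputs — it does not validate identification rates on real
instrument data, where fragment intensities, interferences and adduct
behaviour are instrument- and method-specific.

Two pathologies are asserted as *expected behaviour*: a weak isobar sharing
a high-intensity fragment m/z with a strong one gets an inflated sum (and
can be falsely up-ranked), and a lipid whose apex the scans miss gets a
deflated sum (and can be falsely down-ranked). Both are inherent to
summed-intensity ranking and are reproduced by the test suite via the
generator.

# Numerical and design choices

- Retention times are minutes everywhere; `read_ms2(rt_seconds = TRUE)` is
  the only conversion path — no heuristics.
- Feature-table annotation is strictly additive: input rows, order and
  columns are preserved verbatim; results are appended columns.
- Filename polarity suffixes `n`/`p` only count when set off by a separator
  or digit (`feats_n.csv`, not `fraction.csv`); `neg`/`pos` match anywhere
  at the stem end; all case-insensitive.
- Degenerate inputs: empty chain sets give empty libraries; features
  without scans yield no identification (or code 4 when enabled) with
  summed intensity 0; zero-peak scans parse fine.
- `precursor_only` defaults to off so that outputs only contain
  fragment-supported claims; turning it on recovers the
  precursor-only (code 4) reporting style.
- Problem sizes in the test suite are small by design — libraries of a few
  dozen entries, scenarios of 2–20 candidates, the full 39-chain default
  pool only where the combinatorial counts themselves are checked — which
  keeps the whole suite deterministic and fast while covering every code
  path; the engine itself is routinely used with the full default library
  (≈19,000 entries across 14 classes, built in ~2 s).

# Known limitations

- Data-independent (AIF) spectra are out of scope; code 2 is reserved.
- No dimers, multimers, in-source fragments, isotope patterns, or charge
  states beyond 1 in shipped adducts.
- No false-discovery modelling and no spectral-similarity scores; ranking
  is summed intensity only, with the documented pathologies.
- Ether-lipid hydrogen bookkeeping uses the constant offsets stated above;
  classes whose ether forms deviate from that convention need their own
  template rows.
- The default rule set encodes HCD/orbitrap-style fragmentation; other
  fragmentation modes require editing the rule CSVs, which is the intended
  workflow.
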
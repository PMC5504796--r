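# lipidrules

Rule-based lipid identification for untargeted LC-MS/MS lipidomics, in R.

Untargeted lipidomics experiments produce feature tables (peaks defined by
m/z and retention time) plus data-dependent MS/MS spectra. Because isomeric
lipids co-elute and share precursor masses, a feature is rarely one lipid:
identification must be driven by which *fragments* are actually observed,
and an annotation must never claim more structure than those fragments
support. `lipidrules` implements this workflow for analysts who process
LC-MS/MS lipidomics data with open tools (MZmine/XCMS feature tables,
MSConvert `.ms2` spectra):

1. **In silico libraries.** Fatty acyl chain sets are enumerated as
   multisets (no `18:0_20:0` / `20:0_18:0` duplicates) over an editable
   chain pool, including oxidized chains (+O, +OH, +OOH additions bounded by
   the parent's double bonds, and short-chain cleavage products with
   terminal CHO/COOH). Class templates turn each chain set × adduct into a
   library entry: theoretical precursor m/z and a labelled list of
   theoretical fragment m/z, all computed from monoisotopic atomic masses
   with electron-mass correction (0.00054858 Da per charge).
2. **Identification.** For each feature: exact-mass precursor matching
   (Da tolerance) forms feature–lipid pairs; MS/MS scans are assigned by RT
   window and half the isolation window; each theoretical fragment is
   profiled across scans (scan count, max intensity, mean observed m/z, RT
   at max, ppm tolerance); fragments pass if they reach the intensity and
   scan thresholds; per-class rules over fragment groups assign a
   confidence code — **1** identified by class and fatty acyl constituents,
   **2** reserved for data-independent analysis, **3** class only, **4**
   precursor m/z only. A code-1 lipid is written `PC(16:0_22:6)` (the `_`
   means sn-positions unknown); a code-3 lipid only `PC(38:6)`.
3. **Ranking.** Co-eluting candidates on one feature are ranked by the sum
   over all matched theoretical fragments of the per-fragment maximum
   intensity — including fragments not used for confirmation.

A combiner aligns annotation tables from different software by m/z (ppm) and
RT windows, and a seeded synthetic DDA generator produces ground-truthed
feature tables and `.ms2` files for testing, including the documented
ranking pathologies (shared fragments inflating a weak isobar's sum; scans
missing a lipid's apex).

## Worked example

The classic negative-mode case: a feature at m/z 850.5604, RT 5.92 min,
whose scans carry the acyl carboxylate anions of two co-eluting
phosphatidylcholine isomers measured as formate adducts.

```r
library(lipidrules)

# small PC library over a 5-chain pool
sets <- enumerate_chain_sets(c("16:0", "18:1", "18:2", "20:4", "22:6"), 2)
lib  <- build_library("PC", sets, "[M+HCO2]-")

# one feature and three scans carrying four carboxylate peaks
features <- tibble::tibble(feature_id = "F1", mz = 850.5604, rt = 5.92)
peaks <- tibble::tibble(
  mz = fa_carboxylate_mz(c("16:0", "22:6", "18:2", "20:4")),
  intensity = c(8e4, 6e4, 3e4, 2e4))
spectra <- tibble::tibble(scan = 1:3, precursor_mz = 850.5604,
                          rt = c(5.90, 5.92, 5.94),
                          peaks = replicate(3, peaks, simplify = FALSE))

ids <- annotate_features(features, spectra, lib)
tidy(ids)
#> # A tibble: 2 × 10
#>   feature_id    mz    rt  rank annotation    class adduct    confidence summed_intensity n_fragments_observed
#> 1 F1          851.  5.92     1 PC(16:0_22:6) PC    [M+HCO2]-          1           140000                    2
#> 2 F1          851.  5.92     2 PC(18:2_20:4) PC    [M+HCO2]-          1            50000                    2
```

Both isomers are confirmed at confidence 1 because both of their acyl
carboxylates (255.2330/327.2330 and 279.2330/303.2330) pass the default
1000-count threshold in at least one scan; PC(16:0_22:6) ranks first because
its fragments sum to 140,000 counts against 50,000. `glance(ids)` gives
per-confidence counts and `autoplot(ids)` draws the ranked candidates.

Batch processing mirrors the directory conventions (`*pos.csv`/`*neg.csv`
feature tables next to `*dd*pos.ms2`/`*dd*neg.ms2` spectra, one subfolder
per substrate):

```r
annotate_run("study_dir", "libraries/", classes = c("PC", "PE", "TG"))
```

or from a shell via the thin CLI:

```sh
Rscript inst/cli/lipidrules.R build-library --out libs --classes PC,TG
Rscript inst/cli/lipidrules.R annotate --dir study_dir --libraries libs \
    --ms1-tol-da 0.005 --frag-tol-ppm 10 --min-intensity 1000
```

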
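# The identification engine: each step on the worked scenario, then
# property-style checks (brute-force equivalence, threshold monotonicity,
# structural-resolution soundness, ranking determinism).

test_that("precursor matching respects the Da tolerance and polarity", {
  lib <- fig3_library()
  features <- tibble::tibble(feature_id = c("A", "B"),
                             mz = c(850.5604, 850.6200), rt = c(5.92, 5.92))
  pairs <- match_precursors(features, lib, ms1_tol_da = 0.005)
  # two isobaric formate PCs match the first feature, nothing the second
  expect_identical(sort(pairs$annotation[pairs$feature_id == "A"]),
                   c("PC(16:0_22:6)", "PC(18:2_20:4)"))
  expect_identical(sum(pairs$feature_id == "B"), 0L)
  # polarity restriction removes negative-mode entries
  expect_identical(
    nrow(match_precursors(features, lib, 0.005, polarity = "positive")), 0L)
})

test_that("scan assignment uses the RT window and half the isolation window", {
  sp <- make_spectra(c(850.56, 850.56, 849.9, 850.56),
                     c(5.90, 7.92, 5.92, 5.80),
                     replicate(4, peaks_tbl(numeric(0), numeric(0)),
                               simplify = FALSE))
  got <- assign_scans(sp, 850.5604, 5.92, rt_window_min = 0.3,
                      isolation_window_mz = 1.0)
  expect_identical(got$scan, c(1L, 4L)) # scan 2 off-RT, scan 3 outside 0.5 m/z
  expect_identical(nrow(assign_scans(sp, 850.5604, 2.0, 0.3, 1.0)), 0L)
})

test_that("fragment profiling counts scans, takes per-scan maxima and tracks RT at max", {
  frag <- tibble::tibble(label = "FA1_carboxylate",
                         frag_mz = fa_carboxylate_mz("16:0")) # 255.2330
  scans <- make_spectra(850.5604, c(5.90, 5.92, 5.94, 5.96), list(
    peaks_tbl(c(255.2328, 255.2333), c(1e3, 5e3)), # two in-window: take 5e3
    peaks_tbl(255.2331, 8e4),
    peaks_tbl(255.2331, 4e4),
    peaks_tbl(300.0, 1e5)                          # no in-window peak
  ))
  obs <- profile_fragments(frag, scans, frag_tol_ppm = 10)
  expect_identical(obs$n_scans, 3L)
  expect_equal(obs$max_intensity, 8e4)
  expect_equal(obs$rt_at_max, 5.92)
  expect_equal(obs$mean_observed_mz, mean(c(255.2333, 255.2331, 255.2331)))
  # outside tolerance in every scan
  far <- profile_fragments(tibble::tibble(label = "x", frag_mz = 500), scans, 10)
  expect_identical(far$n_scans, 0L)
  expect_identical(far$max_intensity, 0)
})

test_that("thresholding requires both minimum intensity and scan count", {
  obs <- tibble::tibble(label = c("a", "b", "c"),
                        theoretical_mz = 1, n_scans = c(1L, 1L, 1L),
                        max_intensity = c(1200, 900, 1200),
                        mean_observed_mz = 1, rt_at_max = 1)
  got <- apply_thresholds(obs, min_intensity = 1000, min_scans = 1)
  expect_identical(got$passes, c(TRUE, FALSE, TRUE))
  got2 <- apply_thresholds(dplyr::mutate(obs, n_scans = c(1L, 2L, 0L)),
                           min_intensity = 1000, min_scans = 2)
  expect_identical(got2$passes, c(FALSE, FALSE, FALSE))
})

test_that("rules map observed fragments to confidence codes with sound structural resolution", {
  sc <- fig3_scenario()
  # both carboxylates present -> confidence 1 at acyl level
  ids <- annotate_features(sc$features, sc$spectra, sc$library)
  expect_setequal(ids$annotation, c("PC(16:0_22:6)", "PC(18:2_20:4)"))
  expect_true(all(ids$confidence == 1L))

  # only one acyl fragment above threshold -> no acyl-level identification
  sc1 <- fig3_scenario(int_22_6 = 500, int_18_2 = 500, int_20_4 = 500)
  ids1 <- annotate_features(sc1$features, sc1$spectra, sc1$library)
  expect_identical(nrow(ids1), 0L)

  # protonated PC: head group alone -> confidence 3 at sum-composition level
  libp <- fig3_library("[M+H]+")
  prec <- unique(libp$precursor_mz[libp$annotation == "PC(16:0_22:6)"])
  feats <- tibble::tibble(feature_id = "F1", mz = prec, rt = 5.92)
  sp_head <- make_spectra(prec, 5.92,
                          list(peaks_tbl(fragment_ion_mz("C5H15NO4P", "positive"),
                                         5e4)))
  ids3 <- annotate_features(feats, sp_head, libp)
  expect_true(all(ids3$confidence == 3L))
  expect_true(all(ids3$annotation == "PC(38:6)"))
  expect_false(any(grepl("_", ids3$annotation, fixed = TRUE)))

  # head group plus one acyl neutral loss -> confidence 1
  nl_fa1 <- prec - fatty_acyl_mass("16:0")
  sp_full <- make_spectra(prec, 5.92,
                          list(peaks_tbl(c(fragment_ion_mz("C5H15NO4P", "positive"),
                                           nl_fa1), c(5e4, 2e4))))
  ids_full <- annotate_features(feats, sp_full, libp)
  expect_identical(
    ids_full$confidence[ids_full$annotation == "PC(16:0_22:6)"], 1L)

  # empty spectra: nothing without precursor_only, code 4 with it
  none <- annotate_features(sc$features, sc$spectra[0, ], sc$library)
  expect_identical(nrow(none), 0L)
  p4 <- annotate_features(sc$features, sc$spectra[0, ], sc$library,
                          precursor_only = TRUE)
  expect_true(all(p4$confidence == 4L))
  expect_true(all(p4$annotation == "PC(38:6)"))
  expect_true(all(p4$summed_intensity == 0))
})

test_that("ranking sums all matched fragments and breaks ties deterministically", {
  ids <- tibble::tibble(
    feature_id = "F1",
    annotation = c("PC(18:2_20:4)", "PC(16:0_22:6)", "PC(17:1_21:5)"),
    adduct = "[M+HCO2]-",
    summed_intensity = c(3e4, 1.4e5, 3e4))
  ranked <- rank_identifications(ids)
  expect_identical(ranked$annotation,
                   c("PC(16:0_22:6)", "PC(17:1_21:5)", "PC(18:2_20:4)"))
  expect_identical(ranked$rank, 1:3)
  # summed intensity non-increasing with rank
  expect_true(all(diff(ranked$summed_intensity) <= 0))

  # through the engine: planted intensities order the two isomers
  sc <- fig3_scenario(int_16_0 = 8e4, int_22_6 = 6e4,
                      int_18_2 = 3e4, int_20_4 = 2e4)
  ids2 <- annotate_features(sc$features, sc$spectra, sc$library)
  expect_identical(ids2$annotation[ids2$rank == 1], "PC(16:0_22:6)")
  expect_equal(ids2$summed_intensity[ids2$rank == 1], 8e4 + 6e4)
})

test_that("summation includes matched fragments not used for confirmation", {
  # plant both carboxylates plus the [M-CH3]- neutral loss, which is not in
  # any rule group: it must still contribute to the candidate's sum
  lib <- fig3_library()
  e <- lib[lib$annotation == "PC(16:0_22:6)", ]
  nl <- e$frag_mz[e$label == "NL_methyl_formate"]
  pk <- peaks_tbl(c(fa_carboxylate_mz("16:0"), fa_carboxylate_mz("22:6"), nl),
                  c(8e4, 6e4, 9e3))
  feats <- tibble::tibble(feature_id = "F1", mz = 850.5604, rt = 5.92)
  sp <- make_spectra(850.5604, 5.92, list(pk))
  ids <- annotate_features(feats, sp, lib)
  top <- ids[ids$annotation == "PC(16:0_22:6)", ]
  expect_equal(top$summed_intensity, 8e4 + 6e4 + 9e3)
  # sub-threshold fragments with >= 1 scan also count toward the sum
  pk2 <- peaks_tbl(c(fa_carboxylate_mz("16:0"), fa_carboxylate_mz("22:6"),
                     fa_carboxylate_mz("18:2"), fa_carboxylate_mz("20:4")),
                   c(8e4, 6e4, 800, 700)) # isomer 2 below threshold
  sp2 <- make_spectra(850.5604, 5.92, list(pk2))
  ids2 <- annotate_features(feats, sp2, lib)
  expect_identical(nrow(ids2), 1L) # isomer 2 not confirmed...
  expect_equal(ids2$summed_intensity, 8e4 + 6e4) # ...its peaks not in this sum
})

test_that("engine output equals the brute-force reference on small instances", {
  lib <- dplyr::bind_rows(fig3_library(), fig3_library("[M+H]+"))
  rules <- default_rules()
  set.seed(7)
  for (rep in 1:5) {
    # random features around the two isobaric precursors, random peaks
    feats <- tibble::tibble(
      feature_id = paste0("F", 1:2),
      mz = c(850.5604, 850.5604 + runif(1, -0.004, 0.004)),
      rt = runif(2, 5.8, 6.0))
    frag_pool <- unique(lib$frag_mz)
    sp <- make_spectra(
      850.5604 + runif(3, -0.3, 0.3), runif(3, 5.7, 6.1),
      replicate(3, {
        n <- sample(3:8, 1)
        peaks_tbl(sample(frag_pool, n) * (1 + runif(n, -5, 5) / 1e6),
                  runif(n, 500, 1e5))
      }, simplify = FALSE))
    got <- tidy(annotate_features(feats, sp, lib, rules))
    ref <- brute_force_annotate(feats, sp, lib, rules)
    expect_identical(nrow(got), nrow(ref))
    if (nrow(ref) > 0) {
      got <- dplyr::arrange(got, feature_id, rank)
      expect_identical(got$annotation, ref$annotation)
      expect_identical(got$confidence, ref$confidence)
      expect_equal(got$summed_intensity, ref$summed_intensity)
      expect_identical(got$rank, as.integer(ref$rank))
    }
  }
})

test_that("raising thresholds never enlarges the confidence-1 set", {
  sc <- fig3_scenario(int_16_0 = 8e4, int_22_6 = 1500,
                      int_18_2 = 1100, int_20_4 = 900)
  conf1 <- function(min_int, min_scans = 1) {
    ids <- annotate_features(sc$features, sc$spectra, sc$library,
                             min_intensity = min_int, min_scans = min_scans)
    sort(ids$annotation[ids$confidence == 1])
  }
  sets <- lapply(c(500, 1000, 1200, 2000, 1e5), conf1)
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
  # scan threshold monotonicity
  s1 <- conf1(1000, 1); s2 <- conf1(1000, 4)
  expect_true(all(s2 %in% s1))
})

test_that("acyl-level text never appears unless every chain group passed", {
  lib <- dplyr::bind_rows(fig3_library(), fig3_library("[M+H]+"))
  rules <- default_rules()
  chain_groups <- rules[rules$group_type == "chain", ]
  set.seed(11)
  for (rep in 1:10) {
    feats <- tibble::tibble(feature_id = "F1", mz = 850.5604, rt = 5.9)
    frag_pool <- unique(lib$frag_mz)
    n <- sample(2:6, 1)
    sp <- make_spectra(850.5604, runif(2, 5.7, 6.1),
                       replicate(2, peaks_tbl(sample(frag_pool, n),
                                              runif(n, 200, 1e5)),
                                 simplify = FALSE))
    ids <- annotate_features(feats, sp, lib, rules, precursor_only = TRUE)
    acyl <- grepl("_", ids$annotation, fixed = TRUE)
    expect_true(all(ids$confidence[acyl] == 1L))
    expect_true(all(ids$confidence[!acyl] %in% c(3L, 4L)))
  }
})
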
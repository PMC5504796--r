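# The identification engine: precursor matching, scan assignment, fragment
# profiling, thresholding, rule evaluation, confidence coding, and
# summed-intensity ranking of co-eluting candidates.
#
# Confidence codes: 1 = identified by class and fatty acyl constituents;
# 2 = by data-independent analysis (reserved, never emitted here);
# 3 = by class only; 4 = by precursor m/z only, without fragment matching.

#' Match features to library precursors (Step 1)
#'
#' Exact-mass matching at the MS1 level with an absolute tolerance in Da.
#' Every (feature, library entry) pair with `|feature m/z - precursor m/z|
#' <= ms1_tol_da` becomes a feature-lipid pair; adducts are restricted to
#' the requested polarity. Dimers, multimers and in-source fragments are not
#' considered.
#'
#' @param features Feature tibble (see [read_feature_table()]).
#' @param library Long-form library tibble.
#' @param ms1_tol_da Absolute precursor tolerance in Da (> 0).
#' @param polarity Optional `"positive"`/`"negative"` restriction.
#' @return A tibble of pairs: one row per (feature, entry) with the entry's
#'   fragment list nested in `fragments`.
#' @export
match_precursors <- function(features, library, ms1_tol_da = 0.005,
                             polarity = NULL) {
  stopifnot(ms1_tol_da > 0)
  if (!is.null(polarity)) {
    library <- dplyr::filter(library, .data$polarity == !!polarity)
  }
  entries <- library |>
    tidyr::nest(fragments = c("label", "frag_mz")) |>
    dplyr::arrange(.data$precursor_mz)
  if (nrow(entries) == 0 || nrow(features) == 0) {
    return(dplyr::bind_cols(
      tibble::tibble(feature_id = character(0), mz = numeric(0),
                     rt = numeric(0)),
      entries[0, ]
    ))
  }
  lo <- findInterval(features$mz - ms1_tol_da, entries$precursor_mz) + 1L
  hi <- findInterval(features$mz + ms1_tol_da, entries$precursor_mz)
  hits <- purrr::map_dfr(seq_len(nrow(features)), function(i) {
    if (lo[i] > hi[i]) return(NULL)
    dplyr::bind_cols(
      tibble::tibble(feature_id = features$feature_id[i],
                     mz = features$mz[i], rt = features$rt[i]),
      entries[lo[i]:hi[i], ]
    )
  })
  if (is.null(hits) || nrow(hits) == 0) {
    return(dplyr::bind_cols(
      tibble::tibble(feature_id = character(0), mz = numeric(0),
                     rt = numeric(0)),
      entries[0, ]
    ))
  }
  hits
}

#' Assign MS/MS scans to a feature (Step 2)
#'
#' Scans are assigned when they lie within the retention-time window of the
#' feature and their isolation target lies within half the isolation window
#' of the feature m/z (the instrument isolates `isolation_window_mz` wide
#' around the target).
#'
#' @param spectra Spectra tibble (see [read_ms2()]).
#' @param feature_mz,feature_rt Feature coordinates.
#' @param rt_window_min RT tolerance in minutes (> 0).
#' @param isolation_window_mz Full isolation window width in m/z (> 0).
#' @return The subset of `spectra` assigned to the feature.
#' @export
assign_scans <- function(spectra, feature_mz, feature_rt,
                         rt_window_min = 0.3, isolation_window_mz = 1) {
  stopifnot(rt_window_min > 0, isolation_window_mz > 0)
  dplyr::filter(
    spectra,
    abs(.data$rt - feature_rt) <= rt_window_min,
    abs(.data$precursor_mz - feature_mz) <= isolation_window_mz / 2
  )
}

#' Profile theoretical fragments across assigned scans (Step 3)
#'
#' For each theoretical fragment: the number of scans containing at least
#' one peak within the ppm tolerance, the maximum intensity over matched
#' peaks, the mean observed m/z of the matched peaks, and the retention time
#' of the scan holding the maximum. When several peaks of one scan fall in
#' the window, the most intense one is taken.
#'
#' @param fragments Tibble with `label`, `frag_mz`.
#' @param scans Assigned spectra (see [assign_scans()]).
#' @param frag_tol_ppm Fragment tolerance in ppm (> 0).
#' @return A tibble with one row per fragment: `label`, `theoretical_mz`,
#'   `n_scans`, `max_intensity`, `mean_observed_mz`, `rt_at_max`.
#' @export
profile_fragments <- function(fragments, scans, frag_tol_ppm = 10) {
  stopifnot(frag_tol_ppm > 0)
  purrr::pmap_dfr(
    list(fragments$label, fragments$frag_mz),
    function(label, fmz) {
      tol <- fmz * frag_tol_ppm / 1e6
      best_mz <- best_int <- numeric(0); best_rt <- numeric(0)
      if (nrow(scans) > 0) {
        for (s in seq_len(nrow(scans))) {
          pk <- scans$peaks[[s]]
          j <- which(abs(pk$mz - fmz) <= tol)
          if (length(j) > 0) {
            jbest <- j[which.max(pk$intensity[j])]
            best_mz <- c(best_mz, pk$mz[jbest])
            best_int <- c(best_int, pk$intensity[jbest])
            best_rt <- c(best_rt, scans$rt[s])
          }
        }
      }
      n <- length(best_int)
      tibble::tibble(
        label = label, theoretical_mz = fmz, n_scans = n,
        max_intensity = if (n > 0) max(best_int) else 0,
        mean_observed_mz = if (n > 0) mean(best_mz) else NA_real_,
        rt_at_max = if (n > 0) best_rt[which.max(best_int)] else NA_real_
      )
    }
  )
}

#' Apply intensity and scan-count thresholds (Step 4)
#'
#' A fragment passes (is "observed") when its maximum intensity reaches
#' `min_intensity` and it was found in at least `min_scans` scans. The
#' default scan requirement is 1.
#'
#' @param observations Fragment observation tibble (see
#'   [profile_fragments()]).
#' @param min_intensity Minimum maximum-intensity; depends on the mass
#'   analyser and noise level and must be chosen by the user (1000 is a
#'   sensible orbitrap starting point).
#' @param min_scans Minimum number of scans (>= 1).
#' @return `observations` with a logical `passes` column.
#' @export
apply_thresholds <- function(observations, min_intensity = 1000,
                             min_scans = 1) {
  stopifnot(min_scans >= 1)
  dplyr::mutate(observations,
                passes = .data$max_intensity >= min_intensity &
                  .data$n_scans >= min_scans)
}

#' Evaluate identification rules for one feature-lipid pair (Steps 5-6)
#'
#' @param observations Thresholded observations (see [apply_thresholds()]).
#' @param rules Rule rows for this (class, adduct) (see [default_rules()]).
#' @param had_scans Whether any MS/MS scan was assigned to the feature.
#' @param precursor_only Whether precursor-only (code 4) identifications are
#'   reported when no rule group is satisfied.
#' @return Confidence code 1 (class + acyl constituents), 3 (class only),
#'   4 (precursor only, when enabled), or `NA_integer_` for no
#'   identification.
#' @export
evaluate_rules <- function(observations, rules, had_scans = TRUE,
                           precursor_only = FALSE) {
  code4 <- if (precursor_only) 4L else NA_integer_
  if (is.null(rules) || nrow(rules) == 0 || !had_scans) return(code4)
  status <- rules |>
    dplyr::left_join(observations[, c("label", "passes")], by = "label") |>
    dplyr::mutate(passes = dplyr::coalesce(.data$passes, FALSE)) |>
    dplyr::group_by(.data$group_id, .data$group_type) |>
    dplyr::summarise(satisfied = sum(.data$passes) >= .data$min_count[1],
                     .groups = "drop")
  if (all(status$satisfied)) return(1L)
  class_groups <- status[status$group_type == "class", ]
  if (nrow(class_groups) > 0 && all(class_groups$satisfied)) return(3L)
  code4
}

#' Rank co-eluting identifications of one feature (Step 7)
#'
#' The summed intensity of a candidate is the sum, over all its theoretical
#' fragments with at least one scan match, of the per-fragment maximum
#' intensity - including fragments not used for confirmation. Candidates are
#' sorted by decreasing summed intensity; exact ties break by annotation
#' text ascending so ranking is deterministic.
#'
#' @param identifications Tibble with at least `feature_id`, `annotation` and
#'   `summed_intensity`.
#' @return The tibble with a dense `rank` column (1..n per feature), sorted.
#' @export
rank_identifications <- function(identifications) {
  identifications |>
    dplyr::arrange(.data$feature_id, dplyr::desc(.data$summed_intensity),
                   .data$annotation, .data$adduct) |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Annotate a feature table against a fragment library (Steps 1-7)
#'
#' The full engine: precursor matching, scan assignment, fragment profiling,
#' thresholding, rule evaluation, confidence coding and ranking. The
#' annotation text obeys structural resolution: acyl-constituent text (with
#' `"_"`) only at confidence 1; sum-composition text at confidence 3 and 4.
#'
#' @param features Feature tibble (see [read_feature_table()]).
#' @param spectra Spectra tibble (see [read_ms2()]); may have zero rows.
#' @param library Long-form library tibble.
#' @param rules Identification rules (default [default_rules()]); validated
#'   against the library before matching.
#' @param ms1_tol_da MS1 precursor tolerance, Da.
#' @param frag_tol_ppm Fragment tolerance, ppm.
#' @param rt_window_min Scan-assignment RT window, minutes.
#' @param isolation_window_mz Isolation window width, m/z.
#' @param min_intensity,min_scans Fragment observation thresholds.
#' @param polarity Optional polarity restriction for the library.
#' @param precursor_only Report code-4 (precursor-only) candidates for
#'   features whose pairs satisfy no rule (default `FALSE`).
#' @return A `lipid_ids` tibble: one row per retained identification with
#'   `feature_id`, `mz`, `rt`, `rank`, `annotation`, `class`, `adduct`,
#'   `confidence`, `summed_intensity`, `n_fragments_observed` and a nested
#'   `observations` tibble.
#' @export
annotate_features <- function(features, spectra, library,
                              rules = default_rules(),
                              ms1_tol_da = 0.005, frag_tol_ppm = 10,
                              rt_window_min = 0.3, isolation_window_mz = 1,
                              min_intensity = 1000, min_scans = 1,
                              polarity = NULL, precursor_only = FALSE) {
  validate_rules(rules, library)
  pairs <- match_precursors(features, library, ms1_tol_da, polarity)
  empty <- tibble::tibble(
    feature_id = character(0), mz = numeric(0), rt = numeric(0),
    rank = integer(0), annotation = character(0), class = character(0),
    adduct = character(0), confidence = integer(0),
    summed_intensity = numeric(0), n_fragments_observed = integer(0),
    observations = list()
  )
  if (nrow(pairs) == 0) return(.as_lipid_ids(empty, features))

  rule_groups <- rules |>
    dplyr::group_by(.data$class, .data$adduct) |>
    tidyr::nest() |>
    dplyr::ungroup()

  ids <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    scans <- assign_scans(spectra, p$mz, p$rt, rt_window_min,
                          isolation_window_mz)
    obs <- profile_fragments(p$fragments[[1]], scans, frag_tol_ppm) |>
      apply_thresholds(min_intensity, min_scans)
    rr <- rule_groups$data[
      rule_groups$class == p$class & rule_groups$adduct == p$adduct]
    rr <- if (length(rr) == 1) rr[[1]] else NULL
    conf <- evaluate_rules(obs, rr, had_scans = nrow(scans) > 0,
                           precursor_only = precursor_only)
    if (is.na(conf)) return(NULL)
    tibble::tibble(
      feature_id = p$feature_id, mz = p$mz, rt = p$rt,
      annotation = if (conf == 1L) p$annotation else p$sum_annotation,
      class = p$class, adduct = p$adduct, confidence = conf,
      summed_intensity = sum(obs$max_intensity[obs$n_scans >= 1]),
      n_fragments_observed = sum(obs$n_scans >= 1),
      observations = list(obs)
    )
  })
  if (is.null(ids) || nrow(ids) == 0) return(.as_lipid_ids(empty, features))
  out <- rank_identifications(ids) |>
    dplyr::relocate("rank", .after = "rt")
  .as_lipid_ids(out, features)
}

.as_lipid_ids <- function(x, features) {
  class(x) <- c("lipid_ids", class(x))
  attr(x, "n_features") <- nrow(features)
  x
}

#' @export
print.lipid_ids <- function(x, ...) {
  cat("Lipid identifications:", nrow(x), "candidate(s) across",
      length(unique(x$feature_id)), "of", attr(x, "n_features") %||% NA,
      "features\n")
  NextMethod()
}
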
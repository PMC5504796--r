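# Ground-truthed synthetic data-dependent acquisition data: co-eluting
# isobaric lipids sharing a feature, fragment peaks at theoretical m/z with
# configurable intensities and chromatographic peak shape, noise peaks, and
# scans offset from the apex. Every engine behaviour - including the known
# ranking pathologies (shared fragments, off-apex scans) - is exercisable
# without any instrument data.

#' Build a simulation configuration
#'
#' @param planted A tibble describing the planted lipids with columns
#'   `annotation` and `adduct` (must exist in the library passed to
#'   [simulate_dda()]), `apex_rt` (minutes), `precursor_intensity`, and
#'   optionally `fragment_scale` (fragment intensity as a fraction of the
#'   precursor intensity, default 0.2) and `peak_sigma` (Gaussian
#'   chromatographic peak width in minutes, default 0.05).
#' @param n_scans Scans acquired per feature.
#' @param scan_offsets RT offsets of the scans from the feature apex
#'   (minutes); default symmetric, evenly spaced over +/- 0.12 min.
#' @param noise_peaks Number of uniform random noise peaks per scan.
#' @param noise_intensity Intensity range of noise peaks.
#' @param mz_jitter_ppm Gaussian m/z jitter applied to planted peaks and
#'   feature m/z (ppm standard deviation).
#' @param seed Random seed; fixes all randomness.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(planted, n_scans = 8, scan_offsets = NULL,
                              noise_peaks = 0, noise_intensity = c(50, 500),
                              mz_jitter_ppm = 0, seed = 1L) {
  stopifnot(is.data.frame(planted),
            all(c("annotation", "adduct", "apex_rt",
                  "precursor_intensity") %in% names(planted)))
  planted <- tibble::as_tibble(planted)
  if (!"fragment_scale" %in% names(planted)) planted$fragment_scale <- 0.2
  if (!"peak_sigma" %in% names(planted)) planted$peak_sigma <- 0.05
  if (any(planted$precursor_intensity <= 0) ||
      any(planted$fragment_scale <= 0) || any(planted$peak_sigma <= 0)) {
    abort("Planted intensities, scales and widths must be > 0")
  }
  if (mz_jitter_ppm < 0) abort("mz_jitter_ppm must be >= 0")
  if (is.null(scan_offsets)) {
    scan_offsets <- seq(-0.12, 0.12, length.out = n_scans)
  }
  structure(
    list(planted = planted, scan_offsets = scan_offsets,
         noise_peaks = noise_peaks, noise_intensity = noise_intensity,
         mz_jitter_ppm = mz_jitter_ppm, seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate a DDA experiment from a library
#'
#' Planted lipids whose precursor m/z agree within 1 mDa share one feature
#' (co-eluting isobars). Each feature gets scans at the configured RT
#' offsets around its apex; each scan carries every planted lipid's
#' theoretical template fragments at intensities scaled by a Gaussian
#' chromatographic peak-shape factor centred on that lipid's own apex, plus
#' uniform noise peaks. Identical seeds give byte-identical output files.
#'
#' @param config A [simulation_config()].
#' @param library Long-form library tibble containing every planted
#'   (annotation, adduct).
#' @param out_dir Optional directory; when given, `features_pos.csv` /
#'   `features_neg.csv`, `sim_dd_pos.ms2` / `sim_dd_neg.ms2` and
#'   `manifest.csv` are written following the input naming conventions.
#' @return A list with `features` (feature tibble), `spectra` (per polarity
#'   list of spectra tibbles), and `manifest` (ground truth: feature, planted
#'   annotation, adduct, expected confidence, planted rank by fragment
#'   signal).
#' @export
simulate_dda <- function(config, library, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  planted <- config$planted
  entries <- library |>
    tidyr::nest(fragments = c("label", "frag_mz")) |>
    dplyr::select("class", "annotation", "adduct", "polarity",
                  "precursor_mz", "fragments")
  planted <- dplyr::left_join(planted, entries, by = c("annotation", "adduct"))
  if (any(is.na(planted$precursor_mz))) {
    missing <- planted[is.na(planted$precursor_mz), ]
    abort(paste0("Planted lipid(s) absent from library: ",
                 paste(paste0(missing$annotation, " ", missing$adduct),
                       collapse = ", ")))
  }

  # group isobaric planted lipids into shared features (1 mDa clusters)
  ord <- order(planted$precursor_mz)
  planted <- planted[ord, ]
  gap <- c(0, diff(planted$precursor_mz)) > 0.001
  planted$feature_group <- cumsum(c(TRUE, gap[-1])) |> as.integer()

  jitter <- function(mz) {
    if (config$mz_jitter_ppm == 0) return(mz)
    mz * (1 + stats::rnorm(length(mz), 0, config$mz_jitter_ppm) / 1e6)
  }

  feats <- planted |>
    dplyr::group_by(.data$feature_group, .data$polarity) |>
    dplyr::summarise(
      mz = jitter(mean(.data$precursor_mz)),
      rt = .data$apex_rt[which.max(.data$precursor_intensity)],
      .groups = "drop") |>
    dplyr::mutate(feature_id = paste0("SF", .data$feature_group))
  planted <- dplyr::left_join(
    planted, feats[, c("feature_group", "feature_id")], by = "feature_group")

  spectra <- purrr::map(
    split(seq_len(nrow(feats)), feats$polarity),
    function(rows) {
      scan_no <- 0L
      purrr::map_dfr(rows, function(fi) {
        f <- feats[fi, ]
        members <- planted[planted$feature_group == f$feature_group, ]
        purrr::map_dfr(config$scan_offsets, function(off) {
          scan_no <<- scan_no + 1L
          scan_rt <- f$rt + off
          pk <- purrr::map_dfr(seq_len(nrow(members)), function(m) {
            pl <- members[m, ]
            shape <- exp(-(scan_rt - pl$apex_rt)^2 / (2 * pl$peak_sigma^2))
            fr <- pl$fragments[[1]]
            tibble::tibble(
              mz = jitter(fr$frag_mz),
              intensity = pl$precursor_intensity * pl$fragment_scale * shape)
          })
          if (config$noise_peaks > 0) {
            pk <- dplyr::bind_rows(pk, tibble::tibble(
              mz = runif(config$noise_peaks, 105, 1100),
              intensity = runif(config$noise_peaks,
                                config$noise_intensity[1],
                                config$noise_intensity[2])))
          }
          pk <- dplyr::arrange(pk, .data$mz)
          tibble::tibble(scan = scan_no, precursor_mz = f$mz,
                         rt = scan_rt, peaks = list(pk))
        })
      })
    })

  manifest <- planted |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::mutate(planted_rank = rank(-(.data$precursor_intensity *
                                          .data$fragment_scale),
                                      ties.method = "first")) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$feature_id, .data$annotation, .data$adduct,
                     .data$class, .data$polarity, .data$apex_rt,
                     .data$precursor_intensity, .data$fragment_scale,
                     expected_confidence = 1L, .data$planted_rank)

  features <- feats |>
    dplyr::transmute(.data$feature_id, .data$mz, .data$rt, .data$polarity)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (pol in names(spectra)) {
      suffix <- if (pol == "positive") "pos" else "neg"
      ft <- features[features$polarity == pol,
                     c("feature_id", "mz", "rt")]
      names(ft) <- c("row ID", "row m/z", "row retention time")
      ft$`row m/z` <- round(ft$`row m/z`, 6)
      readr::write_csv(ft, file.path(out_dir, paste0("features_", suffix, ".csv")))
      write_ms2(spectra[[pol]], file.path(out_dir, paste0("sim_dd_", suffix, ".ms2")))
    }
    readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  }

  list(features = features, spectra = spectra, manifest = manifest)
}
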
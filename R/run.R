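# Batch orchestration: discover inputs under a root directory, annotate
# every feature table with its own folder's MS/MS data, and write one output
# folder per substrate. The run configuration is serialised alongside the
# outputs so a run can be reproduced exactly.

#' Annotate every feature table under a directory
#'
#' Applies [discover_inputs()], then for each job reads the feature table
#' and its matching-polarity MS2 files and runs [annotate_features()].
#' Outputs (annotated table plus per-class fragment detail tables) go to an
#' `output` folder inside each substrate folder, together with
#' `run_config.json` recording every parameter.
#'
#' @param root_dir Input directory (see [discover_inputs()] for the layout
#'   and naming conventions).
#' @param library Long-form library tibble, or a directory of library CSV
#'   files, or a single library CSV path.
#' @param classes Optional class acronyms to restrict the library to (the
#'   filter is applied at load time to cut the search space).
#' @param rules Identification rules (default [default_rules()]).
#' @inheritParams annotate_features
#' @param out_name Name of the per-substrate output folder.
#' @return Invisibly, a tibble summarising each job: features read, pairs
#'   formed, identifications per confidence code, output path.
#' @export
annotate_run <- function(root_dir, library, classes = NULL,
                         rules = default_rules(),
                         ms1_tol_da = 0.005, frag_tol_ppm = 10,
                         rt_window_min = 0.3, isolation_window_mz = 1,
                         min_intensity = 1000, min_scans = 1,
                         precursor_only = FALSE, out_name = "output") {
  library <- .load_library_arg(library)
  if (!is.null(classes)) {
    library <- dplyr::filter(library, .data$class %in% classes)
    if (nrow(library) == 0) abort("No library entries left after class filter")
  }
  plan <- discover_inputs(root_dir)
  if (nrow(plan) == 0) abort(paste0("No feature tables found under ", root_dir))
  unmatched <- attr(plan, "unmatched")
  if (length(unmatched) > 0) {
    message("Ignoring files not matching naming conventions: ",
            paste(basename(unmatched), collapse = ", "))
  }
  params <- list(ms1_tol_da = ms1_tol_da, frag_tol_ppm = frag_tol_ppm,
                 rt_window_min = rt_window_min,
                 isolation_window_mz = isolation_window_mz,
                 min_intensity = min_intensity, min_scans = min_scans,
                 precursor_only = precursor_only,
                 classes = classes %||% "all")

  summary <- purrr::map_dfr(seq_len(nrow(plan)), function(i) {
    job <- plan[i, ]
    features <- read_feature_table(job$feature_table)
    spectra <- if (length(job$ms2_files[[1]]) > 0) {
      purrr::map_dfr(job$ms2_files[[1]], read_ms2)
    } else {
      tibble::tibble(scan = integer(0), precursor_mz = numeric(0),
                     rt = numeric(0), peaks = list())
    }
    ids <- annotate_features(
      features, spectra, library, rules = rules,
      ms1_tol_da = ms1_tol_da, frag_tol_ppm = frag_tol_ppm,
      rt_window_min = rt_window_min,
      isolation_window_mz = isolation_window_mz,
      min_intensity = min_intensity, min_scans = min_scans,
      polarity = job$polarity, precursor_only = precursor_only)
    out_dir <- file.path(dirname(job$feature_table), out_name)
    stem <- tools::file_path_sans_ext(basename(job$feature_table))
    write_outputs(ids, features, out_dir, stem = paste0(stem, "_annotated"))
    jsonlite::write_json(params, file.path(out_dir, "run_config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    g <- glance(ids)
    message(sprintf(
      "%s [%s]: %d features, %d with MS2 scans available, %d identifications (conf 1: %d, conf 3: %d, conf 4: %d)",
      basename(job$feature_table), job$polarity, nrow(features),
      nrow(spectra), g$n_identifications, g$n_confidence_1,
      g$n_confidence_3, g$n_confidence_4))
    dplyr::bind_cols(
      tibble::tibble(feature_table = job$feature_table,
                     polarity = job$polarity, out_dir = out_dir), g)
  })
  invisible(summary)
}

.load_library_arg <- function(library) {
  if (is.data.frame(library)) return(library)
  if (is.character(library) && length(library) == 1 && dir.exists(library)) {
    files <- list.files(library, pattern = "\\.csv$", full.names = TRUE)
    if (length(files) == 0) abort(paste0("No library CSVs in ", library))
    return(purrr::map_dfr(sort(files), read_library))
  }
  if (is.character(library)) {
    return(purrr::map_dfr(library, read_library))
  }
  abort("library must be a tibble, a CSV path, or a directory of CSVs")
}
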
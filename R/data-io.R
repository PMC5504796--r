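# Reading feature tables and .ms2 spectra, discovering inputs by the
# directory and file-naming conventions, and writing annotated outputs.

.MZ_ALIASES <- c("row m/z", "m/z", "mz")
.RT_ALIASES <- c("row retention time", "retention time", "rt")

.detect_column <- function(headers, aliases, override, what) {
  if (!is.null(override)) {
    i <- match(tolower(override), tolower(headers))
    if (is.na(i)) {
      abort(paste0("Requested ", what, " column '", override,
                   "' not found; headers seen: ",
                   paste(headers, collapse = ", ")))
    }
    return(headers[i])
  }
  for (a in aliases) {
    i <- match(a, tolower(trimws(headers)))
    if (!is.na(i)) return(headers[i])
  }
  abort(paste0("Could not detect a ", what, " column; headers seen: ",
               paste(headers, collapse = ", ")))
}

#' Read a feature table
#'
#' Feature tables are delimited text with one row per feature. The m/z and
#' retention-time columns are auto-detected by case-insensitive header match
#' (`"row m/z"`, `"m/z"`, `"mz"`; `"row retention time"`,
#' `"retention time"`, `"rt"`) unless overridden, so exports from MZmine,
#' XCMS or MS-DIAL work unchanged. All other columns are preserved verbatim
#' and are carried through annotation untouched. Retention times are minutes.
#'
#' @param path CSV file path.
#' @param mz_column,rt_column Optional explicit column names.
#' @return A tibble with `feature_id`, `mz`, `rt` first, followed by all
#'   original columns.
#' @export
read_feature_table <- function(path, mz_column = NULL, rt_column = NULL) {
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         name_repair = "minimal")
  if (nrow(tab) == 0 && ncol(tab) == 0) {
    abort(paste0("Feature table ", path, " is empty"))
  }
  mz_col <- .detect_column(names(tab), .MZ_ALIASES, mz_column, "m/z")
  rt_col <- .detect_column(names(tab), .RT_ALIASES, rt_column,
                           "retention time")
  mz <- as.numeric(tab[[mz_col]])
  rt <- as.numeric(tab[[rt_col]])
  if (any(is.na(mz)) || any(mz <= 0)) {
    abort(paste0("Feature table ", path, ": non-positive or missing m/z"))
  }
  if (any(is.na(rt)) || any(rt < 0)) {
    abort(paste0("Feature table ", path, ": negative or missing RT"))
  }
  id_col <- names(tab)[tolower(names(tab)) %in% c("row id", "feature_id", "id")]
  feature_id <- if (length(id_col) > 0) {
    as.character(tab[[id_col[1]]])
  } else {
    paste0("F", seq_len(nrow(tab)))
  }
  if (anyDuplicated(feature_id)) {
    abort(paste0("Feature table ", path, ": duplicated feature ids"))
  }
  out <- tibble::tibble(feature_id = feature_id, mz = mz, rt = rt)
  work <- tab
  clash <- names(work) %in% names(out)
  names(work)[clash] <- paste0(names(work)[clash], ".orig")
  out <- dplyr::bind_cols(out, work, .name_repair = "unique_quiet")
  # original columns, names verbatim, for lossless append-only output
  attr(out, "source_table") <- tab
  out
}

#' Read an MS2 text file
#'
#' Parses the `.ms2` dialect written by MSConvert: optional `H` header
#' lines; one block per scan starting `S <scan> <scan> <precursor m/z>`;
#' `I RTime <minutes>` (or `RetTime`) giving the scan retention time;
#' optional `Z` charge lines; then `<mz> <intensity>` peak lines.
#'
#' @param path `.ms2` file path.
#' @param rt_seconds Set `TRUE` if the file's RTime values are seconds; they
#'   are divided by 60. There is no heuristic conversion.
#' @return A tibble with one row per scan: `scan`, `precursor_mz`, `rt`
#'   (minutes), and `peaks` (list column of tibbles with `mz`, `intensity`,
#'   sorted ascending by m/z).
#' @export
read_ms2 <- function(path, rt_seconds = FALSE) {
  lines <- readLines(path)
  scans <- list(); cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    if (is.na(cur$rt)) {
      abort(paste0(path, ": scan ", cur$scan, " has no I RTime line"))
    }
    pk <- if (length(cur$mz) > 0) {
      o <- order(cur$mz)
      tibble::tibble(mz = cur$mz[o], intensity = cur$int[o])
    } else {
      tibble::tibble(mz = numeric(0), intensity = numeric(0))
    }
    tibble::tibble(scan = cur$scan, precursor_mz = cur$prec,
                   rt = if (rt_seconds) cur$rt / 60 else cur$rt,
                   peaks = list(pk))
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    first <- substring(ln, 1, 1)
    if (first == "H") next
    if (first == "S") {
      scans[[length(scans) + 1L]] <- flush(cur)
      f <- strsplit(ln, "[ \t]+")[[1]]
      if (length(f) < 4 || is.na(suppressWarnings(as.numeric(f[4])))) {
        abort(paste0(path, ": malformed S line at line ", i))
      }
      prec <- as.numeric(f[4])
      if (is.na(prec) || prec <= 0) {
        abort(paste0(path, ": non-positive precursor m/z at line ", i))
      }
      cur <- list(scan = as.integer(f[2]), prec = prec, rt = NA_real_,
                  mz = numeric(0), int = numeric(0))
    } else if (first == "I") {
      f <- strsplit(ln, "[ \t]+")[[1]]
      if (length(f) >= 3 && f[2] %in% c("RTime", "RetTime")) {
        if (is.null(cur)) abort(paste0(path, ": I line before any S line (line ", i, ")"))
        cur$rt <- as.numeric(f[3])
      }
    } else if (first == "Z" || first == "D") {
      next
    } else {
      if (is.null(cur)) {
        abort(paste0(path, ": peak line before any S line (line ", i, ")"))
      }
      f <- strsplit(ln, "[ \t]+")[[1]]
      if (length(f) != 2) {
        abort(paste0(path, ": malformed peak line at line ", i,
                     " (expected 'm/z intensity')"))
      }
      mz <- suppressWarnings(as.numeric(f[1]))
      int <- suppressWarnings(as.numeric(f[2]))
      if (is.na(mz) || is.na(int) || int < 0) {
        abort(paste0(path, ": invalid peak (negative or non-numeric) at line ", i))
      }
      cur$mz <- c(cur$mz, mz); cur$int <- c(cur$int, int)
    }
  }
  scans[[length(scans) + 1L]] <- flush(cur)
  scans <- purrr::compact(scans)
  if (length(scans) == 0) {
    return(tibble::tibble(scan = integer(0), precursor_mz = numeric(0),
                          rt = numeric(0), peaks = list()))
  }
  dplyr::bind_rows(scans)
}

#' Write spectra to an MS2 text file
#'
#' Inverse of [read_ms2()] at 6 decimal (m/z) / 1 decimal (intensity)
#' precision; used by the synthetic data generator.
#'
#' @param spectra Spectra tibble (see [read_ms2()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ms2 <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("H\tCreationDate\t1970-01-01", con)
  writeLines("H\tExtractor\tlipidrules", con)
  for (i in seq_len(nrow(spectra))) {
    sc <- spectra$scan[i]
    writeLines(sprintf("S\t%d\t%d\t%.6f", sc, sc, spectra$precursor_mz[i]), con)
    writeLines(sprintf("I\tRTime\t%.4f", spectra$rt[i]), con)
    pk <- spectra$peaks[[i]]
    if (nrow(pk) > 0) {
      writeLines(sprintf("%.6f %.1f", pk$mz, pk$intensity), con)
    }
  }
  invisible(path)
}

# Polarity from a file name stem: a "neg"/"pos" suffix, or a final single
# "n"/"p" character when set off by a separator or digit (so "fraction" or
# "ion" never reads as negative). Case-insensitive throughout.
.stem_polarity <- function(stem) {
  s <- tolower(stem)
  if (endsWith(s, "neg")) return("negative")
  if (endsWith(s, "pos")) return("positive")
  if (grepl("(^|[^a-z])n$", s)) return("negative")
  if (grepl("(^|[^a-z])p$", s)) return("positive")
  NA_character_
}

.stem_mode <- function(stem) {
  s <- tolower(stem)
  if (grepl("aif", s)) return("aif")
  if (grepl("dd", s)) return("dd")
  NA_character_
}

#' Discover feature tables and MS2 files under a directory
#'
#' Walks the root directory and one level of substrate subfolders. Feature
#' tables are `.csv` files whose name stem ends in `n`/`neg` (negative) or
#' `p`/`pos` (positive), case-insensitively; `.ms2` files follow the same
#' polarity convention and must contain `dd` (data-dependent) or `aif`
#' (all-ion fragmentation) in the name. Files that do not match the
#' conventions are reported in the `unmatched` attribute, never silently
#' dropped. A feature table with no same-folder MS2 file of matching
#' polarity is flagged: identification then degrades to precursor-only
#' (confidence code 4).
#'
#' @param root_dir Root directory.
#' @return A tibble (the job plan) with columns `substrate`, `feature_table`,
#'   `polarity`, `ms2_files` (list), `mode`, `note`; attribute `unmatched`
#'   lists unrecognised files.
#' @export
discover_inputs <- function(root_dir) {
  if (!dir.exists(root_dir)) {
    abort(paste0("Directory does not exist: ", root_dir))
  }
  subdirs <- sort(list.dirs(root_dir, recursive = FALSE))
  folders <- c(root_dir, subdirs)
  unmatched <- character(0)
  jobs <- purrr::map_dfr(folders, function(d) {
    files <- sort(list.files(d, full.names = TRUE))
    files <- files[!dir.exists(files)]
    ext <- tolower(tools::file_ext(files))
    stems <- tools::file_path_sans_ext(basename(files))
    is_csv <- ext == "csv"; is_ms2 <- ext == "ms2"
    pol <- vapply(stems, .stem_polarity, character(1), USE.NAMES = FALSE)
    mode <- vapply(stems, .stem_mode, character(1), USE.NAMES = FALSE)
    unmatched <<- c(unmatched,
                    files[(is_csv | is_ms2) & is.na(pol)],
                    files[is_ms2 & !is.na(pol) & is.na(mode)],
                    files[!is_csv & !is_ms2])
    ft <- which(is_csv & !is.na(pol))
    ms2 <- which(is_ms2 & !is.na(pol) & !is.na(mode))
    purrr::map_dfr(ft, function(i) {
      match_ms2 <- ms2[pol[ms2] == pol[i]]
      tibble::tibble(
        substrate = basename(normalizePath(d)),
        feature_table = files[i],
        polarity = pol[i],
        ms2_files = list(files[match_ms2]),
        mode = if (length(match_ms2) > 0) {
          paste(sort(unique(mode[match_ms2])), collapse = "+")
        } else NA_character_,
        note = if (length(match_ms2) == 0) "no MS2" else ""
      )
    })
  })
  attr(jobs, "unmatched") <- unique(unmatched)
  jobs
}

#' Write annotated outputs for one feature table
#'
#' Produces (a) the annotated feature table: every input row and column
#' preserved in order, with appended columns `top_annotation`, `top_class`,
#' `top_adduct`, `top_confidence`, `top_summed_intensity` and `all_ids`
#' (rank-ordered `confidence|annotation|adduct|summed_intensity` records
#' joined by `";"`); and (b) one fragment-detail CSV per lipid class with
#' one row per (feature, candidate, fragment) carrying scan counts, maximum
#' intensity, mean observed m/z and RT at the maximum.
#'
#' @param ids Identification table from [annotate_features()].
#' @param features The feature table that was annotated (from
#'   [read_feature_table()]).
#' @param out_dir Output directory (created if missing).
#' @param stem File-name stem for the annotated table.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(ids, features, out_dir, stem = "annotated") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  id_strings <- ids |>
    dplyr::arrange(.data$feature_id, .data$rank) |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      top_annotation = .data$annotation[1],
      top_class = .data$class[1],
      top_adduct = .data$adduct[1],
      top_confidence = .data$confidence[1],
      top_summed_intensity = .data$summed_intensity[1],
      all_ids = paste(
        paste(.data$confidence, .data$annotation, .data$adduct,
              signif(.data$summed_intensity, 7), sep = "|"),
        collapse = ";"),
      .groups = "drop"
    )
  orig <- attr(features, "source_table")
  if (is.null(orig)) {
    orig <- features[, setdiff(names(features), c("feature_id", "mz", "rt")),
                     drop = FALSE]
  }
  annotated <- dplyr::bind_cols(
    tibble::tibble(feature_id = features$feature_id),
    orig,
    .name_repair = "unique_quiet"
  ) |>
    dplyr::left_join(id_strings, by = "feature_id")
  chr_cols <- c("top_annotation", "top_class", "top_adduct", "all_ids")
  annotated[chr_cols] <- lapply(annotated[chr_cols],
                                function(x) dplyr::coalesce(x, ""))
  main_path <- file.path(out_dir, paste0(stem, ".csv"))
  readr::write_csv(annotated, main_path, na = "")

  detail_paths <- character(0)
  if (nrow(ids) > 0 && "observations" %in% names(ids)) {
    details <- ids |>
      dplyr::select("feature_id", "class", "annotation", "adduct",
                    "observations") |>
      tidyr::unnest("observations")
    for (cls in sort(unique(details$class))) {
      p <- file.path(out_dir, paste0(stem, "_", cls, "_fragments.csv"))
      readr::write_csv(dplyr::filter(details, .data$class == cls), p, na = "")
      detail_paths <- c(detail_paths, p)
    }
  }
  invisible(c(main_path, detail_paths))
}
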
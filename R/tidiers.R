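# broom-style verbs and plotting for identification tables.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an identification table
#'
#' Drops the nested fragment observations, returning one flat row per
#' ranked identification.
#'
#' @param x A `lipid_ids` tibble from [annotate_features()].
#' @param ... Unused.
#' @return A plain tibble.
#' @method tidy lipid_ids
#' @export
tidy.lipid_ids <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$observations <- NULL
  out
}

#' One-row summary of an annotation run
#'
#' @param x A `lipid_ids` tibble from [annotate_features()].
#' @param ... Unused.
#' @return A tibble with feature and identification counts per confidence
#'   code.
#' @method glance lipid_ids
#' @export
glance.lipid_ids <- function(x, ...) {
  tibble::tibble(
    n_features = attr(x, "n_features") %||% NA_integer_,
    n_features_identified = length(unique(x$feature_id)),
    n_identifications = nrow(x),
    n_confidence_1 = sum(x$confidence == 1),
    n_confidence_3 = sum(x$confidence == 3),
    n_confidence_4 = sum(x$confidence == 4)
  )
}

#' Plot ranked identifications per feature
#'
#' Summed fragment intensity by rank, one panel per feature; the visual
#' counterpart of the ranking step.
#'
#' @param object A `lipid_ids` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lipid_ids
#' @export
autoplot.lipid_ids <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$rank), y = .data$summed_intensity,
    fill = factor(.data$confidence))) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$feature_id), scales = "free") +
    ggplot2::labs(x = "rank", y = "summed fragment intensity",
                  fill = "confidence") +
    ggplot2::theme_minimal()
}

#' Plot one MS/MS scan with theoretical fragment markers
#'
#' @param spectra Spectra tibble (see [read_ms2()]).
#' @param scan Scan number to plot.
#' @param fragments Optional tibble with `label`, `frag_mz` to mark.
#' @return A ggplot object.
#' @export
plot_scan <- function(spectra, scan, fragments = NULL) {
  s <- spectra[spectra$scan == scan, ]
  if (nrow(s) != 1) abort(paste0("No unique scan ", scan))
  pk <- s$peaks[[1]]
  p <- ggplot2::ggplot(pk, ggplot2::aes(x = .data$mz, ymax = .data$intensity)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = 0)) +
    ggplot2::labs(x = "m/z", y = "intensity",
                  title = sprintf("scan %d, precursor %.4f, RT %.2f",
                                  s$scan, s$precursor_mz, s$rt)) +
    ggplot2::theme_minimal()
  if (!is.null(fragments)) {
    p <- p + ggplot2::geom_vline(
      data = fragments, ggplot2::aes(xintercept = .data$frag_mz),
      linetype = "dashed", colour = "red", alpha = 0.5)
  }
  p
}
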
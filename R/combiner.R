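# Align two feature tables by m/z and retention time and append annotation
# columns from one onto the other, so identifications from different
# software can be pooled on one table.

#' Align two feature tables and append annotations
#'
#' For each row of `base`, candidate rows of `other` are those within
#' `ppm_tol` (evaluated relative to the base feature's m/z) and
#' `rt_tol_min`. The best match is the candidate with the smallest absolute
#' ppm error, ties broken by smallest RT difference, then by row order.
#' `other`'s annotation columns are appended under `prefix`; unmatched base
#' rows get empty cells. One `other` row may match several base rows - no
#' exclusivity is enforced. Base rows and existing cells are never modified.
#'
#' @param base,other Data frames with detectable m/z and RT columns (same
#'   conventions as [read_feature_table()]).
#' @param ppm_tol m/z window in ppm (> 0).
#' @param rt_tol_min RT window in minutes (> 0).
#' @param prefix Prefix for the appended columns (default `"other_"`).
#' @param annotation_cols Columns of `other` to append; default all columns
#'   except its m/z and RT columns.
#' @return `base` as a tibble with the appended columns.
#' @export
#' @examples
#' base <- tibble::tibble(mz = 744.5536, rt = 6.72)
#' other <- tibble::tibble(mz = 744.5540, rt = 6.68, id = "PE(36:2)+H")
#' align_and_append(base, other, ppm_tol = 10, rt_tol_min = 0.1)
align_and_append <- function(base, other, ppm_tol = 10, rt_tol_min = 0.2,
                             prefix = "other_", annotation_cols = NULL) {
  stopifnot(ppm_tol > 0, rt_tol_min > 0)
  base <- tibble::as_tibble(base)
  other <- tibble::as_tibble(other)
  b_mz <- .detect_column(names(base), .MZ_ALIASES, NULL, "m/z")
  b_rt <- .detect_column(names(base), .RT_ALIASES, NULL, "retention time")
  o_mz <- .detect_column(names(other), .MZ_ALIASES, NULL, "m/z")
  o_rt <- .detect_column(names(other), .RT_ALIASES, NULL, "retention time")
  if (is.null(annotation_cols)) {
    annotation_cols <- setdiff(names(other), c(o_mz, o_rt))
  }
  best <- vapply(seq_len(nrow(base)), function(i) {
    mz_i <- base[[b_mz]][i]; rt_i <- base[[b_rt]][i]
    ppm <- abs(ppm_error(other[[o_mz]], mz_i))
    drt <- abs(other[[o_rt]] - rt_i)
    cand <- which(ppm <= ppm_tol & drt <= rt_tol_min)
    if (length(cand) == 0) return(NA_integer_)
    cand[order(ppm[cand], drt[cand], cand)][1]
  }, integer(1))
  appended <- other[best, annotation_cols, drop = FALSE]
  names(appended) <- paste0(prefix, annotation_cols)
  dplyr::bind_cols(base, appended, .name_repair = "unique_quiet")
}
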
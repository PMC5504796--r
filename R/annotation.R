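# Annotation grammar: the rendered string encodes the structural resolution
# an identification is allowed to claim.
#   sum_composition   PC(38:6)          class + total carbons:double bonds
#   acyl_constituents PC(16:0_22:6)     chains known, sn-positions unknown ("_")
#   acyl_positions    PC(16:0/22:6)     chains and sn-positions known ("/")

# Canonical chain order for "_" annotations: ascending carbons, then double
# bonds, then number of oxidation marks, then label. Determinism here is what
# makes 18:0_20:0 and 20:0_18:0 collapse to one species.
fa_sort <- function(fa_labels) {
  p <- fa_parse(fa_labels)
  n_ox <- p$add_o + (p$terminal != "none")
  fa_labels[order(p$carbons, p$double_bonds, n_ox, p$fa)]
}

#' Render a lipid annotation string
#'
#' @param lipid_class Class acronym, e.g. `"PC"`.
#' @param chains Character vector of chain labels (see [fa_parse()]).
#' @param level `"sum_composition"`, `"acyl_constituents"` (default) or
#'   `"acyl_positions"`. At acyl-constituent level chains are sorted
#'   canonically before joining with `"_"`; at position level the given
#'   order is kept and chains join with `"/"`.
#' @return The annotation string.
#' @export
#' @examples
#' render_annotation("PC", c("22:6", "16:0"))                # "PC(16:0_22:6)"
#' render_annotation("PC", c("16:0", "22:6"), "sum_composition") # "PC(38:6)"
render_annotation <- function(lipid_class, chains,
                              level = c("acyl_constituents",
                                        "sum_composition",
                                        "acyl_positions")) {
  level <- match.arg(level)
  p <- fa_parse(chains)
  if (level == "sum_composition") {
    prefix <- ""
    if (any(p$linkage == "alkenyl")) prefix <- "P-"
    else if (any(p$linkage == "alkyl")) prefix <- "O-"
    body <- paste0(prefix, sum(p$carbons), ":", sum(p$double_bonds))
    extra_o <- sum(p$add_o) + sum(c(none = 0, CHO = 1, COOH = 2)[p$terminal])
    if (extra_o > 0) body <- paste0(body, "(+", if (extra_o > 1) extra_o else "", "O)")
  } else {
    sep <- if (level == "acyl_constituents") "_" else "/"
    labs <- if (level == "acyl_constituents") fa_sort(p$fa) else p$fa
    body <- paste(labs, collapse = sep)
  }
  paste0(lipid_class, "(", body, ")")
}

#' Parse an annotation string back into class and chains
#'
#' @param text Annotation string such as `"PC(16:0_22:6)"`.
#' @return A list with `lipid_class`, `level`, and `chains` (character, empty
#'   for sum-composition annotations).
#' @export
parse_annotation <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regexec("^([^()]+)\\((.+)\\)$", text)[[1]]
  if (m[1] == -1) abort(paste0("Cannot parse annotation: '", text, "'"))
  parts <- regmatches(text, list(m))[[1]]
  cls <- parts[2]; body <- parts[3]
  if (grepl("/", body, fixed = TRUE)) {
    list(lipid_class = cls, level = "acyl_positions",
         chains = strsplit(body, "/", fixed = TRUE)[[1]])
  } else if (grepl("_", body, fixed = TRUE)) {
    list(lipid_class = cls, level = "acyl_constituents",
         chains = strsplit(body, "_", fixed = TRUE)[[1]])
  } else if (grepl("^(O-|P-)?[0-9]+:[0-9]+(\\([^()]*\\))?$", body)) {
    # single chain: sum composition and constituents coincide
    list(lipid_class = cls, level = "acyl_constituents", chains = body)
  } else {
    list(lipid_class = cls, level = "sum_composition", chains = character(0))
  }
}

# Sum-composition text for an annotation at any level.
annotation_to_sum <- function(text) {
  a <- parse_annotation(text)
  if (length(a$chains) == 0) return(text)
  render_annotation(a$lipid_class, a$chains, "sum_composition")
}
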
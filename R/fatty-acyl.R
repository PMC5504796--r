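# Fatty acyl chain model.
#
# Chains are written in a compact grammar:
#   [O-|P-]<carbons>:<double_bonds>[(<mods>)]
# where "O-" marks an alkyl (plasmanyl) ether linkage, "P-" an alkenyl
# (plasmenyl) vinyl-ether linkage, and <mods> is a comma-separated list of
#   +kO   k added oxygens (hydroxyl, epoxide, or hydroperoxide additions)
#   -kH   k removed hydrogens (keto variant bookkeeping)
#   CHO   terminal aldehyde (short-chain cleavage product)
#   COOH  terminal carboxylic acid (short-chain cleavage product)
# Convenience tokens OH (+O), OOH (+2O), O (+O) and keto (+O,-2H) are
# accepted on input and normalised on output.
# Examples: "16:0", "P-18:0", "18:1(+2O)", "9:0(CHO)".

.FA_LINKAGES <- c(acyl = "", alkyl = "O-", alkenyl = "P-")

.fa_parse_one <- function(label) {
  s <- label
  linkage <- "acyl"
  if (startsWith(s, "O-")) { linkage <- "alkyl";  s <- substring(s, 3) }
  if (startsWith(s, "P-")) { linkage <- "alkenyl"; s <- substring(s, 3) }
  m <- regexec("^([0-9]+):([0-9]+)(\\(([^()]*)\\))?$", s)[[1]]
  if (m[1] == -1) abort(paste0("Cannot parse fatty acyl label: '", label, "'"))
  parts <- regmatches(s, list(regexec("^([0-9]+):([0-9]+)(\\(([^()]*)\\))?$", s)[[1]]))[[1]]
  carbons <- as.integer(parts[2])
  dbs <- as.integer(parts[3])
  add_o <- 0L; sub_h <- 0L; terminal <- "none"
  mods <- parts[5]
  if (!is.na(mods) && nzchar(mods)) {
    for (tok in strsplit(mods, ",", fixed = TRUE)[[1]]) {
      tok <- trimws(tok)
      if (tok == "CHO" || tok == "COOH") {
        terminal <- tok
      } else if (tok == "OH" || tok == "O") {
        add_o <- add_o + 1L
      } else if (tok == "OOH") {
        add_o <- add_o + 2L
      } else if (tok == "keto" || tok == "oxo") {
        add_o <- add_o + 1L; sub_h <- sub_h + 2L
      } else if (grepl("^\\+[0-9]*O$", tok)) {
        k <- sub("^\\+([0-9]*)O$", "\\1", tok)
        add_o <- add_o + if (nzchar(k)) as.integer(k) else 1L
      } else if (grepl("^-[0-9]*H$", tok)) {
        k <- sub("^-([0-9]*)H$", "\\1", tok)
        sub_h <- sub_h + if (nzchar(k)) as.integer(k) else 1L
      } else {
        abort(paste0("Unknown chain modification token '", tok,
                     "' in '", label, "'"))
      }
    }
  }
  list(carbons = carbons, double_bonds = dbs, linkage = linkage,
       add_o = add_o, sub_h = sub_h, terminal = terminal)
}

#' Parse fatty acyl chain labels
#'
#' @param fa Character vector of chain labels such as `"16:0"`, `"P-18:0"`,
#'   `"18:1(+2O)"` or `"9:0(CHO)"` (see the package vignette for the grammar),
#'   or a data frame already containing the parsed columns (returned as is
#'   after validation).
#' @return A tibble with one row per chain: `fa` (normalised label),
#'   `carbons`, `double_bonds`, `linkage` (acyl/alkyl/alkenyl), `add_o`
#'   (oxygens added by oxidation), `sub_h` (hydrogens removed, keto variant),
#'   `terminal` (none/CHO/COOH) and `oxidized`.
#' @export
#' @examples
#' fa_parse(c("16:0", "18:1(+O)", "9:0(CHO)"))
fa_parse <- function(fa) {
  if (is.data.frame(fa)) {
    need <- c("carbons", "double_bonds", "linkage", "add_o", "sub_h", "terminal")
    miss <- setdiff(need, names(fa))
    if (length(miss) > 0) {
      abort(paste0("Parsed chain table lacks column(s): ",
                   paste(miss, collapse = ", ")))
    }
    out <- tibble::as_tibble(fa)
  } else {
    stopifnot(is.character(fa))
    parsed <- purrr::map(fa, .fa_parse_one)
    out <- tibble::tibble(
      carbons = purrr::map_int(parsed, "carbons"),
      double_bonds = purrr::map_int(parsed, "double_bonds"),
      linkage = purrr::map_chr(parsed, "linkage"),
      add_o = purrr::map_int(parsed, "add_o"),
      sub_h = purrr::map_int(parsed, "sub_h"),
      terminal = purrr::map_chr(parsed, "terminal")
    )
  }
  .fa_validate(out)
  out$fa <- fa_label(out)
  out$oxidized <- out$add_o > 0L | out$sub_h > 0L | out$terminal != "none"
  dplyr::relocate(out, "fa")
}

.fa_validate <- function(fa) {
  if (any(fa$carbons < 2)) abort("Fatty acyl chains need at least 2 carbons")
  if (any(fa$double_bonds < 0)) abort("double_bonds must be >= 0")
  if (any(fa$double_bonds > fa$carbons - 1)) {
    abort("double_bonds must be <= carbons - 1")
  }
  if (any(!fa$linkage %in% names(.FA_LINKAGES))) {
    abort("linkage must be one of acyl, alkyl, alkenyl")
  }
  if (any(!fa$terminal %in% c("none", "CHO", "COOH"))) {
    abort("terminal must be one of none, CHO, COOH")
  }
  if (any(fa$add_o < 0 | fa$sub_h < 0)) abort("Oxidation counts must be >= 0")
  invisible(fa)
}

#' Render fatty acyl labels from parsed chain descriptions
#'
#' Inverse of [fa_parse()]; the rendering is canonical so that equal chains
#' always produce equal labels.
#'
#' @param fa A parsed chain tibble (see [fa_parse()]).
#' @return Character vector of labels.
#' @export
fa_label <- function(fa) {
  mods <- purrr::pmap_chr(
    list(fa$add_o, fa$sub_h, fa$terminal),
    function(o, h, term) {
      toks <- character(0)
      if (o > 0) toks <- c(toks, paste0("+", if (o > 1) o else "", "O"))
      if (h > 0) toks <- c(toks, paste0("-", if (h > 1) h else "", "H"))
      if (term != "none") toks <- c(toks, term)
      if (length(toks) == 0) "" else paste0("(", paste(toks, collapse = ","), ")")
    }
  )
  paste0(.FA_LINKAGES[fa$linkage], fa$carbons, ":", fa$double_bonds, mods)
}

#' Neutral monoisotopic mass of a fatty acyl chain
#'
#' The base is the free fatty acid CnH(2n-2d)O2. Ether linkages apply the
#' standard constant offsets relative to the acyl form (alkyl: +2H, -O;
#' alkenyl: -O). Oxidation adds `add_o` oxygens and removes `sub_h`
#' hydrogens; terminal CHO replaces the terminal methyl hydrogens with a
#' carbonyl (-2H, +O) and terminal COOH with a carboxyl (-2H, +2O).
#'
#' @param fa Chain labels or a parsed chain tibble (see [fa_parse()]).
#' @return Neutral masses in Da (free fatty acid equivalents).
#' @export
#' @examples
#' fatty_acyl_mass("16:0") # C16H32O2, 256.2402
fatty_acyl_mass <- function(fa) {
  fa <- fa_parse(fa)
  n_h <- 2L * fa$carbons - 2L * fa$double_bonds - fa$sub_h +
    ifelse(fa$linkage == "alkyl", 2L, 0L) +
    ifelse(fa$terminal == "none", 0L, -2L)
  n_o <- 2L + fa$add_o +
    ifelse(fa$linkage == "acyl", 0L, -1L) +
    c(none = 0L, CHO = 1L, COOH = 2L)[fa$terminal]
  if (any(n_h < 0) || any(n_o < 0)) abort("Chain implies negative atom counts")
  fa$carbons * .ATOMIC_MASS[["C"]] + n_h * .ATOMIC_MASS[["H"]] +
    as.numeric(n_o) * .ATOMIC_MASS[["O"]]
}

# m/z of the chain carboxylate anion [FA - H]- (R-COO-).
fa_carboxylate_mz <- function(fa) {
  fatty_acyl_mass(fa) - .ATOMIC_MASS[["H"]] + .ELECTRON_MASS
}

# m/z of the chain acylium-like cation [FA + H - H2O]+.
fa_acylium_mz <- function(fa) {
  fatty_acyl_mass(fa) - formula_mass("HO") - .ELECTRON_MASS
}
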
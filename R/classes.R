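# Lipid class templates.
#
# A class is defined by a backbone formula (the head-group alcohol before
# esterification), the number of acyl chains, and a set of fragment
# templates per adduct. The neutral species mass is
#   backbone + sum(chain free-fatty-acid masses) - n_chains * H2O
# which holds for ester, amide (SM, Cer) and - via the per-chain linkage
# offsets in fatty_acyl_mass() - ether bonds.

#' Lipid class definitions shipped with the package
#'
#' The core classes: glycerophospholipids (PC, PE, PS, PG, PI, PA and the
#' lyso forms LPC, LPE), sphingolipids on a d18:1 base (SM, Cer),
#' glycerolipids (MG, DG, TG), cholesteryl esters (CE) and the oxidized
#' classes OxPC and OxTG. Users can extend identification to further classes
#' by supplying their own definition rows together with fragment templates
#' and rules in the same shape.
#'
#' @return A tibble with columns `class`, `n_chains`, `backbone_formula`,
#'   `require_oxidized` (at least one oxidized chain per species),
#'   `chain_prefix` (fixed sphingoid base rendered before the acyl chain) and
#'   `adducts` (list column of adduct names used by the default builder).
#' @export
lipid_class_defs <- function() {
  tibble::tribble(
    ~class, ~n_chains, ~backbone_formula, ~require_oxidized, ~chain_prefix, ~adducts,
    "PC",   2L, "C8H20NO6P",  FALSE, "",       list(c("[M+H]+", "[M+HCO2]-")),
    "PE",   2L, "C5H14NO6P",  FALSE, "",       list(c("[M+H]+", "[M-H]-")),
    "PS",   2L, "C6H14NO8P",  FALSE, "",       list("[M-H]-"),
    "PG",   2L, "C6H15O8P",   FALSE, "",       list("[M-H]-"),
    "PI",   2L, "C9H19O11P",  FALSE, "",       list(c("[M-H]-", "[M+NH4]+")),
    "PA",   2L, "C3H9O6P",    FALSE, "",       list("[M-H]-"),
    "LPC",  1L, "C8H20NO6P",  FALSE, "",       list(c("[M+H]+", "[M+HCO2]-")),
    "LPE",  1L, "C5H14NO6P",  FALSE, "",       list(c("[M+H]+", "[M-H]-")),
    "SM",   1L, "C23H49N2O5P", FALSE, "d18:1/", list(c("[M+H]+", "[M+HCO2]-")),
    "Cer",  1L, "C18H37NO2",  FALSE, "d18:1/", list(c("[M+H]+", "[M-H]-")),
    "MG",   1L, "C3H8O3",     FALSE, "",       list("[M+NH4]+"),
    "DG",   2L, "C3H8O3",     FALSE, "",       list("[M+NH4]+"),
    "TG",   3L, "C3H8O3",     FALSE, "",       list("[M+NH4]+"),
    "CE",   1L, "C27H46O",    FALSE, "",       list("[M+NH4]+"),
    "OxPC", 2L, "C8H20NO6P",  TRUE,  "",       list(c("[M+H]+", "[M+HCO2]-")),
    "OxTG", 3L, "C3H8O3",     TRUE,  "",       list("[M+NH4]+")
  )
}

#' Default fragment templates
#'
#' One row per theoretical fragment of a (class, adduct) combination.
#' `mode` says how the m/z is computed:
#' \describe{
#'   \item{constant}{a fixed fragment ion with ion formula `formula`}
#'   \item{chain_carboxylate}{the RCOO- anion of chain *i*}
#'   \item{chain_acylium}{the \\[FA+H-H2O\\]+ cation of chain *i*}
#'   \item{nl_formula}{precursor minus the neutral `formula`}
#'   \item{nl_chain}{precursor minus the free fatty acid of chain *i*}
#'   \item{nl_chain_formula}{precursor minus chain *i* minus `formula`}
#' }
#' Per-chain templates carry the placeholder `{i}` in `label`, expanded to
#' one fragment per chain slot when a library is built. Templates are
#' user-editable: pass a modified tibble to [build_library()].
#'
#' @return A tibble with columns `class`, `adduct`, `label`, `mode`,
#'   `formula`.
#' @export
default_fragment_templates <- function() {
  t <- tibble::tribble(
    ~class, ~adduct,       ~label,                  ~mode,               ~formula,
    "PC",  "[M+HCO2]-",    "FA{i}_carboxylate",     "chain_carboxylate", NA,
    "PC",  "[M+HCO2]-",    "NL_methyl_formate",     "nl_formula",        "C2H4O2",
    "PC",  "[M+H]+",       "HeadGroup_184",         "constant",          "C5H15NO4P",
    "PC",  "[M+H]+",       "NL_FA{i}",              "nl_chain",          NA,
    "PC",  "[M+H]+",       "NL_HeadGroup_183",      "nl_formula",        "C5H14NO4P",
    "PE",  "[M-H]-",       "FA{i}_carboxylate",     "chain_carboxylate", NA,
    "PE",  "[M-H]-",       "GPEtn_196",             "constant",          "C5H11NO5P",
    "PE",  "[M+H]+",       "NL_HeadGroup_141",      "nl_formula",        "C2H8NO4P",
    "PE",  "[M+H]+",       "NL_FA{i}",              "nl_chain",          NA,
    "PS",  "[M-H]-",       "NL_Serine_87",          "nl_formula",        "C3H5NO2",
    "PS",  "[M-H]-",       "FA{i}_carboxylate",     "chain_carboxylate", NA,
    "PG",  "[M-H]-",       "FA{i}_carboxylate",     "chain_carboxylate", NA,
    "PG",  "[M-H]-",       "GlycerolPhosphate_153", "constant",          "C3H6O5P",
    "PI",  "[M-H]-",       "FA{i}_carboxylate",     "chain_carboxylate", NA,
    "PI",  "[M-H]-",       "InositolPhosphate_241", "constant",          "C6H10O8P",
    "PI",  "[M+NH4]+",     "NL_NH3_InsP_277",       "nl_formula",        "C6H16NO9P",
    "PA",  "[M-H]-",       "FA{i}_carboxylate",     "chain_carboxylate", NA,
    "PA",  "[M-H]-",       "GlycerolPhosphate_153", "constant",          "C3H6O5P",
    "LPC", "[M+HCO2]-",    "FA1_carboxylate",       "chain_carboxylate", NA,
    "LPC", "[M+HCO2]-",    "NL_methyl_formate",     "nl_formula",        "C2H4O2",
    "LPC", "[M+H]+",       "HeadGroup_184",         "constant",          "C5H15NO4P",
    "LPC", "[M+H]+",       "NL_H2O",                "nl_formula",        "H2O",
    "LPE", "[M-H]-",       "FA1_carboxylate",       "chain_carboxylate", NA,
    "LPE", "[M+H]+",       "NL_HeadGroup_141",      "nl_formula",        "C2H8NO4P",
    "SM",  "[M+H]+",       "HeadGroup_184",         "constant",          "C5H15NO4P",
    "SM",  "[M+HCO2]-",    "NL_methyl_formate",     "nl_formula",        "C2H4O2",
    "Cer", "[M+H]+",       "NL_H2O",                "nl_formula",        "H2O",
    "Cer", "[M+H]+",       "SphingoidBase_264",     "constant",          "C18H34N",
    "Cer", "[M-H]-",       "NL_CH2O",               "nl_formula",        "CH2O",
    "MG",  "[M+NH4]+",     "FA1_acylium",           "chain_acylium",     NA,
    "MG",  "[M+NH4]+",     "NL_NH3_H2O",            "nl_formula",        "NH5O",
    "DG",  "[M+NH4]+",     "NL_NH3_FA{i}",          "nl_chain_formula",  "NH3",
    "DG",  "[M+NH4]+",     "FA{i}_acylium",         "chain_acylium",     NA,
    "TG",  "[M+NH4]+",     "NL_NH3_FA{i}",          "nl_chain_formula",  "NH3",
    "CE",  "[M+NH4]+",     "Cholestadienyl_369",    "constant",          "C27H45"
  )
  # oxidized classes fragment like their parent classes
  ox <- dplyr::bind_rows(
    dplyr::mutate(dplyr::filter(t, .data$class == "PC"), class = "OxPC"),
    dplyr::mutate(dplyr::filter(t, .data$class == "TG"), class = "OxTG")
  )
  dplyr::bind_rows(t, ox)
}

#' Default identification rules
#'
#' A rule row states that fragment `label` belongs to rule group `group_id`
#' of a (class, adduct); a group is satisfied when at least `min_count` of
#' its labels pass the intensity and scan thresholds. `group_type` is
#' `"chain"` for groups that confer fatty acyl identity and `"class"` for
#' head-group evidence. Confidence 1 requires every group; confidence 3 is
#' assigned when all class groups pass but some chain group does not.
#'
#' The shipped defaults encode the conventional requirements: formate-adduct
#' PCs need both acyl carboxylates, protonated PCs need the 184.0733 head
#' group plus at least one acyl neutral loss, TGs need the ammonia + fatty
#' acid neutral loss for every chain, and so on.
#'
#' @return A tibble with columns `class`, `adduct`, `group_id`, `group_type`,
#'   `label`, `min_count`.
#' @export
default_rules <- function() {
  r <- tibble::tribble(
    ~class, ~adduct,     ~group_id, ~group_type, ~label,                  ~min_count,
    "PC",  "[M+HCO2]-",  "acyl",  "chain", "FA1_carboxylate",       2L,
    "PC",  "[M+HCO2]-",  "acyl",  "chain", "FA2_carboxylate",       2L,
    "PC",  "[M+H]+",     "head",  "class", "HeadGroup_184",         1L,
    "PC",  "[M+H]+",     "acyl",  "chain", "NL_FA1",                1L,
    "PC",  "[M+H]+",     "acyl",  "chain", "NL_FA2",                1L,
    "PE",  "[M-H]-",     "acyl",  "chain", "FA1_carboxylate",       2L,
    "PE",  "[M-H]-",     "acyl",  "chain", "FA2_carboxylate",       2L,
    "PE",  "[M+H]+",     "head",  "class", "NL_HeadGroup_141",      1L,
    "PE",  "[M+H]+",     "acyl",  "chain", "NL_FA1",                1L,
    "PE",  "[M+H]+",     "acyl",  "chain", "NL_FA2",                1L,
    "PS",  "[M-H]-",     "head",  "class", "NL_Serine_87",          1L,
    "PS",  "[M-H]-",     "acyl",  "chain", "FA1_carboxylate",       2L,
    "PS",  "[M-H]-",     "acyl",  "chain", "FA2_carboxylate",       2L,
    "PG",  "[M-H]-",     "acyl",  "chain", "FA1_carboxylate",       2L,
    "PG",  "[M-H]-",     "acyl",  "chain", "FA2_carboxylate",       2L,
    "PI",  "[M-H]-",     "head",  "class", "InositolPhosphate_241", 1L,
    "PI",  "[M-H]-",     "acyl",  "chain", "FA1_carboxylate",       2L,
    "PI",  "[M-H]-",     "acyl",  "chain", "FA2_carboxylate",       2L,
    "PI",  "[M+NH4]+",   "head",  "class", "NL_NH3_InsP_277",       1L,
    "PA",  "[M-H]-",     "acyl",  "chain", "FA1_carboxylate",       2L,
    "PA",  "[M-H]-",     "acyl",  "chain", "FA2_carboxylate",       2L,
    "LPC", "[M+HCO2]-",  "acyl",  "chain", "FA1_carboxylate",       1L,
    "LPC", "[M+H]+",     "head",  "class", "HeadGroup_184",         1L,
    "LPE", "[M-H]-",     "acyl",  "chain", "FA1_carboxylate",       1L,
    "LPE", "[M+H]+",     "head",  "class", "NL_HeadGroup_141",      1L,
    "SM",  "[M+H]+",     "head",  "class", "HeadGroup_184",         1L,
    "SM",  "[M+HCO2]-",  "head",  "class", "NL_methyl_formate",     1L,
    "Cer", "[M+H]+",     "head",  "class", "NL_H2O",                1L,
    "Cer", "[M+H]+",     "base",  "chain", "SphingoidBase_264",     1L,
    "Cer", "[M-H]-",     "head",  "class", "NL_CH2O",               1L,
    "MG",  "[M+NH4]+",   "acyl",  "chain", "FA1_acylium",           1L,
    "DG",  "[M+NH4]+",   "acyl",  "chain", "NL_NH3_FA1",            2L,
    "DG",  "[M+NH4]+",   "acyl",  "chain", "NL_NH3_FA2",            2L,
    "TG",  "[M+NH4]+",   "acyl",  "chain", "NL_NH3_FA1",            3L,
    "TG",  "[M+NH4]+",   "acyl",  "chain", "NL_NH3_FA2",            3L,
    "TG",  "[M+NH4]+",   "acyl",  "chain", "NL_NH3_FA3",            3L,
    "CE",  "[M+NH4]+",   "head",  "class", "Cholestadienyl_369",    1L
  )
  ox <- dplyr::bind_rows(
    dplyr::mutate(dplyr::filter(r, .data$class == "PC"), class = "OxPC"),
    dplyr::mutate(dplyr::filter(r, .data$class == "TG"), class = "OxTG")
  )
  dplyr::bind_rows(r, ox)
}

#' Read / write identification rule files
#'
#' Rule files are plain CSV with columns `class`, `adduct`, `group_id`,
#' `group_type`, `label`, `min_count`, one row per fragment label.
#'
#' @param path File path.
#' @return `read_rules()` returns the rules tibble.
#' @export
read_rules <- function(path) {
  rules <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("class", "adduct", "group_id", "group_type", "label", "min_count")
  miss <- setdiff(need, names(rules))
  if (length(miss) > 0) {
    abort(paste0("Rule file ", path, " lacks column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (any(!rules$group_type %in% c("chain", "class"))) {
    abort("group_type must be 'chain' or 'class'")
  }
  rules$min_count <- as.integer(rules$min_count)
  tibble::as_tibble(rules[need])
}

#' @rdname read_rules
#' @param rules A rules tibble (see [default_rules()]).
#' @export
write_rules <- function(rules, path) {
  readr::write_csv(rules, path)
  invisible(path)
}

#' Check rules against a library's fragment labels
#'
#' Every rule label for a (class, adduct) present in the library must exist
#' among that combination's fragment labels; an unknown label is a
#' configuration error and is rejected before any matching starts.
#'
#' @param rules Rules tibble.
#' @param library A fragment library (long form, see [build_library()]).
#' @return The rules tibble, invisibly, if valid.
#' @export
validate_rules <- function(rules, library) {
  lib_labels <- dplyr::distinct(library, .data$class, .data$adduct, .data$label)
  shared <- dplyr::semi_join(rules, lib_labels, by = c("class", "adduct"))
  bad <- dplyr::anti_join(shared, lib_labels, by = c("class", "adduct", "label"))
  if (nrow(bad) > 0) {
    abort(paste0(
      "Rule label(s) not present in library templates: ",
      paste(unique(paste0(bad$class, " ", bad$adduct, " ", bad$label)),
            collapse = "; ")
    ))
  }
  invisible(rules)
}
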
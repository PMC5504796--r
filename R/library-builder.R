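# In silico library generation: fatty acyl combinatorics, oxidized chain
# enumeration, and instantiation of class templates into precursor and
# fragment m/z lists.

#' Default fatty acyl pool
#'
#' A curated pool of 39 endogenous fatty acyl chains (even- and odd-chain
#' saturates C12-C24, common mono- and polyunsaturates up to 24:6), shipped
#' as an editable CSV in `inst/extdata/fa_pool_default.csv`. Replace or
#' extend the file (or pass any character vector of chain labels) to change
#' library coverage.
#'
#' @return Character vector of chain labels.
#' @export
default_fa_pool <- function() {
  path <- system.file("extdata", "fa_pool_default.csv", package = "lipidrules")
  readr::read_csv(path, show_col_types = FALSE)$fa
}

#' Default double-bond position table
#'
#' Positions of the double bonds (counted from the carboxyl carbon) for the
#' unsaturated chains of the default pool; used to place cleavage sites when
#' enumerating short-chain oxidized fatty acids. Editable fixture
#' (`inst/extdata/double_bond_positions.csv`, positions separated by `;`).
#'
#' @return A tibble with columns `fa` and `positions` (list of integer).
#' @export
default_double_bond_positions <- function() {
  path <- system.file("extdata", "double_bond_positions.csv",
                      package = "lipidrules")
  tab <- readr::read_csv(path, show_col_types = FALSE)
  tab$positions <- purrr::map(strsplit(tab$positions, ";", fixed = TRUE),
                              as.integer)
  tibble::as_tibble(tab)
}

#' Enumerate fatty acyl chain sets
#'
#' All multisets of size `k` drawn from the pool (combinations with
#' repetition): order is irrelevant, so redundant permutations such as
#' 18:0_20:0 versus 20:0_18:0 are never produced. The number of sets equals
#' `choose(n + k - 1, k)` for a pool of `n` chains.
#'
#' @param fa_pool Character vector of unique chain labels (or a parsed chain
#'   tibble with an `fa` column).
#' @param k Chains per lipid (1 to 4).
#' @param require_oxidized If `TRUE`, keep only sets containing at least one
#'   oxidized chain.
#' @return A tibble with columns `chain_1` ... `chain_k`, chains in canonical
#'   order within each row.
#' @export
#' @examples
#' nrow(enumerate_chain_sets(c("16:0", "18:1", "22:6"), 2)) # choose(4, 2) = 6
enumerate_chain_sets <- function(fa_pool, k, require_oxidized = FALSE) {
  if (is.data.frame(fa_pool)) fa_pool <- fa_pool$fa
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > 4) {
    abort("k must be a single integer between 1 and 4")
  }
  k <- as.integer(k)
  if (length(fa_pool) == 0) abort("fa_pool must be non-empty")
  if (anyDuplicated(fa_pool)) abort("fa_pool entries must be unique")
  pool <- fa_sort(fa_pool)
  n <- length(pool)
  if (k == 1L) {
    idx <- matrix(seq_len(n), nrow = 1)
  } else {
    # stars-and-bars: strictly increasing k-subsets of 1..(n+k-1), shifted
    idx <- utils::combn(n + k - 1L, k) - (seq_len(k) - 1L)
  }
  sets <- matrix(pool[idx], nrow = k)
  out <- tibble::as_tibble(t(sets), .name_repair = "minimal")
  names(out) <- paste0("chain_", seq_len(k))
  if (require_oxidized) {
    ox <- fa_parse(pool)$oxidized
    names(ox) <- pool
    keep <- rowSums(matrix(ox[as.vector(t(as.matrix(out)))],
                           ncol = k, byrow = TRUE)) > 0
    out <- out[keep, , drop = FALSE]
  }
  out
}

#' Enumerate oxidized fatty acids from a pool
#'
#' Long-chain products add one or more oxygens to each unsaturated parent:
#' per addition, O (ketone or epoxide), OH (hydroxyl) or OOH (hydroperoxide),
#' with the total number of additions bounded by the parent's double bonds.
#' Products are deduplicated by their molecular-formula delta, since e.g. a
#' hydroxyl and an epoxide both add one oxygen. By default ketone additions
#' are mass-treated as +O like epoxides; set `keto_variant = TRUE` to also
#' emit the +O,-2H carbonyl form.
#'
#' Short-chain products cleave each unsaturated parent at each double bond
#' (positions from `db_positions`) and cap the cut end with a terminal
#' aldehyde (CHO) or carboxylic acid (COOH).
#'
#' @param fa_pool Character vector of parent chain labels.
#' @param db_positions Double-bond position table
#'   (see [default_double_bond_positions()]).
#' @param max_additions Optional cap on oxygen-bearing additions per chain.
#' @param keto_variant Also enumerate the explicit keto (+O, -2H) forms.
#' @return A list with tibbles `long_chain` and `short_chain` (parsed chain
#'   tables, see [fa_parse()]).
#' @export
#' @examples
#' generate_oxidized_fas("18:1")$long_chain$fa # "18:1(+O)"  "18:1(+2O)"
generate_oxidized_fas <- function(fa_pool,
                                  db_positions = default_double_bond_positions(),
                                  max_additions = NULL,
                                  keto_variant = FALSE) {
  parents <- fa_parse(unique(fa_pool))
  unsat <- dplyr::filter(parents, .data$double_bonds >= 1, !.data$oxidized,
                         .data$linkage == "acyl")

  long_chain <- purrr::pmap_dfr(
    list(unsat$carbons, unsat$double_bonds),
    function(c, d) {
      tmax <- if (is.null(max_additions)) d else min(d, max_additions)
      if (tmax < 1) return(NULL)
      grid <- tidyr::expand_grid(t = seq_len(tmax), a = 0:tmax)
      grid <- dplyr::filter(grid, .data$a <= .data$t)
      out <- tibble::tibble(carbons = c, double_bonds = d,
                            add_o = grid$t + grid$a, sub_h = 0L)
      if (keto_variant) {
        kg <- tidyr::expand_grid(t = seq_len(tmax), a = 0:tmax, k = 1:tmax)
        kg <- dplyr::filter(kg, .data$a <= .data$t,
                            .data$k <= .data$t - .data$a)
        out <- dplyr::bind_rows(out, tibble::tibble(
          carbons = c, double_bonds = d,
          add_o = kg$t + kg$a, sub_h = 2L * kg$k))
      }
      out
    }
  )
  if (nrow(long_chain) > 0) {
    long_chain <- dplyr::distinct(long_chain, .data$carbons,
                                  .data$double_bonds, .data$add_o,
                                  .data$sub_h)
    long_chain$linkage <- "acyl"; long_chain$terminal <- "none"
    long_chain <- fa_parse(long_chain)
  } else {
    long_chain <- fa_parse(character(0))
  }

  pos <- dplyr::semi_join(db_positions, tibble::tibble(fa = unsat$fa), by = "fa")
  short_chain <- purrr::pmap_dfr(
    list(pos$fa, pos$positions),
    function(fa, p) {
      all_pos <- sort(p)
      purrr::map_dfr(all_pos, function(cut) {
        tibble::tibble(carbons = as.integer(cut),
                       double_bonds = sum(all_pos < cut),
                       terminal = c("CHO", "COOH"))
      })
    }
  )
  if (nrow(short_chain) > 0) {
    short_chain <- dplyr::distinct(short_chain, .data$carbons,
                                   .data$double_bonds, .data$terminal)
    short_chain$linkage <- "acyl"
    short_chain$add_o <- 0L; short_chain$sub_h <- 0L
    short_chain <- fa_parse(short_chain)
  } else {
    short_chain <- fa_parse(character(0))
  }
  list(long_chain = long_chain, short_chain = short_chain)
}

# Expand {i} templates for a class with k chains.
.expand_templates <- function(templates, k) {
  per_chain <- grepl("{i}", templates$label, fixed = TRUE)
  fixed <- templates[!per_chain, ]
  # a chain-dependent template without {i} names its slot explicitly
  # (e.g. "FA1_carboxylate") or defaults to chain 1
  fixed$chain_index <- ifelse(
    fixed$mode %in% c("chain_carboxylate", "chain_acylium", "nl_chain",
                      "nl_chain_formula"),
    {
      idx <- rep(1L, nrow(fixed))
      has <- lengths(regmatches(fixed$label, gregexpr("FA[0-9]+", fixed$label))) > 0
      idx[has] <- as.integer(sub(".*FA([0-9]+).*", "\\1", fixed$label[has]))
      idx
    },
    NA_integer_)
  if (any(fixed$chain_index > k, na.rm = TRUE)) {
    abort("Template references a chain slot beyond the class's chain count")
  }
  expanded <- tidyr::expand_grid(templates[per_chain, ], chain_index = seq_len(k))
  if (nrow(expanded) > 0) {
    expanded$label <- stringr::str_replace(expanded$label, stringr::fixed("{i}"),
                                           as.character(expanded$chain_index))
  }
  dplyr::bind_rows(fixed, expanded)
}

#' Build an in silico fragmentation library
#'
#' Instantiates class templates over chain sets: one library entry per
#' (chain set, adduct), each carrying the theoretical precursor m/z and the
#' labelled theoretical fragment m/z list.
#'
#' @param lipid_class Class acronym present in `class_defs`.
#' @param chain_sets Tibble from [enumerate_chain_sets()] (columns `chain_1`
#'   ... `chain_k`), or a list of chain label vectors. Must match the class's
#'   chain count.
#' @param adducts Adduct names; defaults to the class definition's adducts.
#' @param templates Fragment template tibble
#'   (default [default_fragment_templates()]).
#' @param class_defs Class definition tibble (default [lipid_class_defs()]).
#' @return A long-form library tibble: one row per (entry, fragment) with
#'   columns `class`, `annotation`, `sum_annotation`, `adduct`, `polarity`,
#'   `precursor_mz`, `label`, `frag_mz`.
#' @export
#' @examples
#' sets <- enumerate_chain_sets(c("16:0", "22:6"), 2)
#' lib <- build_library("PC", sets, "[M+HCO2]-")
#' dplyr::distinct(lib, annotation, precursor_mz)
build_library <- function(lipid_class, chain_sets, adducts = NULL,
                          templates = default_fragment_templates(),
                          class_defs = lipid_class_defs()) {
  def <- class_defs[class_defs$class == lipid_class, ]
  if (nrow(def) != 1) abort(paste0("Unknown lipid class: ", lipid_class))
  k <- def$n_chains
  if (is.list(chain_sets) && !is.data.frame(chain_sets)) {
    if (length(chain_sets) == 0) {
      chain_sets <- tibble::as_tibble(setNames(
        replicate(k, character(0), simplify = FALSE),
        paste0("chain_", seq_len(k))))
    } else {
      if (any(lengths(chain_sets) != k)) {
        abort(paste0(lipid_class, " requires ", k, " chains per set"))
      }
      m <- do.call(rbind, lapply(chain_sets, fa_sort))
      chain_sets <- tibble::as_tibble(m, .name_repair = "minimal")
      names(chain_sets) <- paste0("chain_", seq_len(k))
    }
  }
  chain_cols <- paste0("chain_", seq_len(k))
  if (!all(chain_cols %in% names(chain_sets)) ||
      ncol(chain_sets[grepl("^chain_", names(chain_sets))]) != k) {
    abort(paste0(lipid_class, " requires chain sets of size ", k,
                 " (columns ", paste(chain_cols, collapse = ", "), ")"))
  }
  if (is.null(adducts)) adducts <- unlist(def$adducts[[1]], use.names = FALSE)
  tmpl <- .expand_templates(
    templates[templates$class == lipid_class &
                templates$adduct %in% adducts, ], k)
  missing_ad <- setdiff(adducts, unique(tmpl$adduct))
  if (length(missing_ad) > 0) {
    abort(paste0("No fragment templates for ", lipid_class, " with adduct(s) ",
                 paste(missing_ad, collapse = ", ")))
  }
  if (nrow(chain_sets) == 0) {
    return(tibble::tibble(class = character(0), annotation = character(0),
                          sum_annotation = character(0), adduct = character(0),
                          polarity = character(0), precursor_mz = numeric(0),
                          label = character(0), frag_mz = numeric(0)))
  }

  # chain masses via a label -> mass lookup (each label parsed once)
  all_labels <- unique(unlist(chain_sets[chain_cols], use.names = FALSE))
  fam <- setNames(fatty_acyl_mass(all_labels), all_labels)
  backbone <- formula_mass(def$backbone_formula)
  water <- formula_mass("H2O")

  chain_mat <- as.matrix(chain_sets[chain_cols])
  neutral <- backbone - k * water +
    rowSums(matrix(fam[chain_mat], ncol = k))
  annotation <- apply(chain_mat, 1, function(ch) {
    paste0(lipid_class, "(", def$chain_prefix,
           paste(ch, collapse = "_"), ")")
  })
  # sum composition, including a fixed sphingoid base where the class has one
  base <- if (nzchar(def$chain_prefix)) {
    bp <- sub("/$", "", def$chain_prefix)
    bcd <- as.integer(strsplit(sub("^d", "", bp), ":", fixed = TRUE)[[1]])
    list(prefix = "d", carbons = bcd[1], dbs = bcd[2])
  } else list(prefix = "", carbons = 0L, dbs = 0L)
  pset <- fa_parse(all_labels)
  tot <- function(col) {
    v <- setNames(pset[[col]], pset$fa)
    rowSums(matrix(v[chain_mat], ncol = k))
  }
  extra_o <- tot("add_o") + {
    term <- setNames(c(none = 0, CHO = 1, COOH = 2)[pset$terminal], pset$fa)
    rowSums(matrix(term[chain_mat], ncol = k))
  }
  sum_annotation <- paste0(
    lipid_class, "(", base$prefix, base$carbons + tot("carbons"), ":",
    base$dbs + tot("double_bonds"),
    ifelse(extra_o > 0,
           paste0("(+", ifelse(extra_o > 1, extra_o, ""), "O)"), ""),
    ")")

  entries <- tibble::tibble(
    class = lipid_class, annotation = annotation,
    sum_annotation = sum_annotation, neutral_mass = neutral,
    set_id = seq_along(neutral)
  )
  entries <- dplyr::bind_cols(entries, chain_sets[chain_cols])

  adduct_tab <- .adduct_lookup(adducts)
  out <- purrr::map_dfr(seq_along(adducts), function(ai) {
    ad <- adducts[ai]
    prec <- ion_mz(entries$neutral_mass, ad)
    pol <- adduct_tab$polarity[ai]
    tm <- tmpl[tmpl$adduct == ad, ]
    frags <- purrr::pmap_dfr(
      list(tm$label, tm$mode, tm$formula, tm$chain_index),
      function(label, mode, formula, ci) {
        mz <- switch(
          mode,
          constant = rep(fragment_ion_mz(formula, pol), nrow(entries)),
          chain_carboxylate = fa_carboxylate_mz(entries[[paste0("chain_", ci)]]),
          chain_acylium = fa_acylium_mz(entries[[paste0("chain_", ci)]]),
          nl_formula = prec - formula_mass(formula),
          nl_chain = prec - fam[entries[[paste0("chain_", ci)]]],
          nl_chain_formula = prec - fam[entries[[paste0("chain_", ci)]]] -
            formula_mass(formula),
          abort(paste0("Unknown template mode '", mode, "' for ",
                       lipid_class, " ", ad, " ", label))
        )
        if (any(!is.finite(mz)) || any(mz <= 0)) {
          abort(paste0("Template ", label, " for ", lipid_class, " ", ad,
                       " yields non-positive m/z"))
        }
        tibble::tibble(set_id = entries$set_id, label = label,
                       frag_mz = unname(mz))
      }
    )
    dplyr::left_join(
      tibble::tibble(set_id = entries$set_id, class = lipid_class,
                     annotation = entries$annotation,
                     sum_annotation = entries$sum_annotation,
                     adduct = ad, polarity = pol,
                     precursor_mz = unname(prec)),
      frags, by = "set_id"
    )
  })
  out$set_id <- NULL
  # one entry per (annotation, adduct): drop duplicated chain sets
  dplyr::distinct(out, .data$annotation, .data$adduct, .data$label,
                  .keep_all = TRUE)
}

#' Build the default library across classes
#'
#' Convenience wrapper enumerating chain sets from a pool for each requested
#' class and concatenating the per-class libraries. Oxidized classes draw
#' from the pool plus the long- and short-chain oxidized chains generated
#' from it and require at least one oxidized chain per species.
#'
#' @param classes Class acronyms (default: all non-oxidized core classes).
#' @param fa_pool Chain pool (default [default_fa_pool()]).
#' @param templates,class_defs See [build_library()].
#' @return Long-form library tibble.
#' @export
build_default_library <- function(classes = c("PC", "PE", "PS", "PG", "PI",
                                              "PA", "LPC", "LPE", "SM", "Cer",
                                              "MG", "DG", "TG", "CE"),
                                  fa_pool = default_fa_pool(),
                                  templates = default_fragment_templates(),
                                  class_defs = lipid_class_defs()) {
  ox_pool <- NULL
  purrr::map_dfr(classes, function(cls) {
    def <- class_defs[class_defs$class == cls, ]
    if (nrow(def) != 1) abort(paste0("Unknown lipid class: ", cls))
    pool <- fa_pool
    if (def$require_oxidized) {
      if (is.null(ox_pool)) {
        ox <- generate_oxidized_fas(fa_pool)
        ox_pool <<- c(ox$long_chain$fa, ox$short_chain$fa)
      }
      pool <- unique(c(fa_pool, ox_pool))
    }
    sets <- enumerate_chain_sets(pool, def$n_chains,
                                 require_oxidized = def$require_oxidized)
    build_library(cls, sets, templates = templates, class_defs = class_defs)
  })
}

#' Write / read library files
#'
#' The on-disk format is UTF-8 CSV with a header: columns `class`,
#' `annotation`, `adduct`, `precursor_mz`, then one column per fragment
#' label holding the theoretical fragment m/z (empty when a label does not
#' apply to an entry). m/z values are stored at 6 decimals; round trips are
#' lossless at that precision. The format is intentionally simple so users
#' can author custom libraries in any spreadsheet tool.
#'
#' @param library Long-form library tibble (see [build_library()]).
#' @param path CSV file path.
#' @return `write_library()` returns `path` invisibly; `read_library()`
#'   returns the long-form library tibble.
#' @export
write_library <- function(library, path) {
  wide <- tidyr::pivot_wider(
    dplyr::mutate(library,
                  precursor_mz = round(.data$precursor_mz, 6),
                  frag_mz = round(.data$frag_mz, 6)),
    id_cols = c("class", "annotation", "adduct", "precursor_mz"),
    names_from = "label", values_from = "frag_mz"
  )
  readr::write_csv(wide, path, na = "")
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  need <- c("class", "annotation", "adduct", "precursor_mz")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(paste0("Library file ", path, " lacks column(s): ",
                 paste(miss, collapse = ", ")))
  }
  frag_cols <- setdiff(names(raw), need)
  if (length(frag_cols) == 0) {
    abort(paste0("Library file ", path, " has no fragment columns"))
  }
  prec <- suppressWarnings(as.numeric(raw$precursor_mz))
  bad <- which(is.na(prec) | prec <= 0)
  if (length(bad) > 0) {
    abort(paste0("Library file ", path, ": invalid precursor_mz on line ",
                 bad[1] + 1L))
  }
  for (cc in frag_cols) {
    v <- raw[[cc]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(num))
    if (length(bad) > 0) {
      abort(paste0("Library file ", path, ": non-numeric value in column '",
                   cc, "' on line ", bad[1] + 1L))
    }
    raw[[cc]] <- num
  }
  raw$precursor_mz <- prec
  long <- tidyr::pivot_longer(raw, dplyr::all_of(frag_cols),
                              names_to = "label", values_to = "frag_mz",
                              values_drop_na = TRUE)
  long$polarity <- .adduct_lookup(long$adduct)$polarity
  long$sum_annotation <- purrr::map_chr(long$annotation, annotation_to_sum)
  dplyr::select(long, "class", "annotation", "sum_annotation", "adduct",
                "polarity", "precursor_mz", "label", "frag_mz")
}
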
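# Chain-set combinatorics, oxidized chain enumeration, template
# instantiation, and the library file round trip.

test_that("chain-set enumeration matches the closed-form count", {
  for (n in 1:10) {
    pool <- paste0(11 + seq_len(n), ":0")
    for (k in 1:4) {
      expect_identical(nrow(enumerate_chain_sets(pool, k)),
                       as.integer(choose(n + k - 1, k)))
    }
  }
  expect_error(enumerate_chain_sets(c("16:0"), 0), "between 1 and 4")
  expect_error(enumerate_chain_sets(c("16:0", "16:0"), 2), "unique")
})

test_that("a 39-chain pool yields 780 pairs and 10660 triples without permutation duplicates", {
  pool <- default_fa_pool()
  expect_identical(length(pool), 39L)
  pairs <- enumerate_chain_sets(pool, 2)
  triples <- enumerate_chain_sets(pool, 3)
  expect_identical(nrow(pairs), 780L)    # choose(40, 2)
  expect_identical(nrow(triples), 10660L) # choose(41, 3)
  # no permutation duplicates: every row is canonically sorted and unique
  keys <- paste(pairs$chain_1, pairs$chain_2)
  expect_identical(anyDuplicated(keys), 0L)
  expect_identical(pairs$chain_1, purrr::map_chr(seq_len(nrow(pairs)), function(i)
    fa_sort(c(pairs$chain_1[i], pairs$chain_2[i]))[1]))
  # single-chain pool, k = 2 -> exactly the homotypic set
  one <- enumerate_chain_sets("18:0", 2)
  expect_identical(nrow(one), 1L)
  expect_identical(c(one$chain_1, one$chain_2), c("18:0", "18:0"))
})

test_that("oxidized enumeration obeys unsaturation limits and deduplicates by formula delta", {
  # saturated pool: nothing to oxidize, nothing to cleave
  none <- generate_oxidized_fas("18:0")
  expect_identical(nrow(none$long_chain), 0L)
  expect_identical(nrow(none$short_chain), 0L)
  # 18:1: one addition allowed; O/OH collapse to +O, OOH gives +2O
  ox <- generate_oxidized_fas("18:1")
  expect_setequal(ox$long_chain$fa, c("18:1(+O)", "18:1(+2O)"))
  # keto variant adds the +O -2H form
  oxk <- generate_oxidized_fas("18:1", keto_variant = TRUE)
  expect_true("18:1(+O,-2H)" %in% oxk$long_chain$fa)
  # cleavage of 18:1 (double bond at 9) gives 9-carbon CHO and COOH products
  expect_setequal(ox$short_chain$fa, c("9:0(CHO)", "9:0(COOH)"))
  # 18:2 (9,12): cleavage at 12 retains the 9-double bond
  ox2 <- generate_oxidized_fas("18:2")
  expect_true(all(c("9:0(CHO)", "9:0(COOH)", "12:1(CHO)", "12:1(COOH)") %in%
                    ox2$short_chain$fa))
  # oracle: brute-force positional cleavage for 22:6
  pos <- c(4, 7, 10, 13, 16, 19)
  expected <- unique(do.call(rbind, lapply(pos, function(p)
    data.frame(carbons = p, dbs = sum(pos < p)))))
  got <- generate_oxidized_fas("22:6")$short_chain
  got <- unique(got[got$terminal == "CHO", c("carbons", "double_bonds")])
  expect_identical(nrow(got), nrow(expected))
  expect_setequal(paste(got$carbons, got$double_bonds),
                  paste(expected$carbons, expected$dbs))
  # max additions bounded by double bonds: 18:2 allows up to 4 oxygens
  expect_identical(max(generate_oxidized_fas("18:2")$long_chain$add_o), 4L)
})

test_that("library entries carry the worked precursor and fragment m/z", {
  lib <- build_library("PC", list(c("16:0", "22:6")),
                       c("[M+HCO2]-", "[M+H]+"))
  neg <- lib[lib$adduct == "[M+HCO2]-", ]
  expect_equal(round_half_up(neg$precursor_mz[1], 4), 850.5604)
  expect_equal(round_half_up(sort(
    neg$frag_mz[grepl("carboxylate", neg$label)]), 4),
    c(255.2330, 327.2330))
  pos <- lib[lib$adduct == "[M+H]+", ]
  expect_equal(round_half_up(pos$frag_mz[pos$label == "HeadGroup_184"], 4),
               184.0733)
  expect_identical(unique(lib$annotation), "PC(16:0_22:6)")
  expect_identical(unique(lib$sum_annotation), "PC(38:6)")
  # neutral losses always sit below the precursor
  nl <- lib[grepl("^NL", lib$label), ]
  expect_true(all(nl$frag_mz < nl$precursor_mz))
})

test_that("chain-derived fragments equal the chain-mass computation for every class", {
  sets2 <- enumerate_chain_sets(c("16:0", "18:1"), 2)
  for (cls in c("PE", "PG", "PA")) {
    lib <- build_library(cls, sets2, "[M-H]-")
    carbs <- lib[lib$label == "FA1_carboxylate", ]
    chain1 <- purrr::map_chr(carbs$annotation,
                             ~ parse_annotation(.x)$chains[1])
    expect_equal(carbs$frag_mz, fa_carboxylate_mz(chain1), tolerance = 1e-9)
  }
  # TG ammonium neutral losses: precursor - NH3 - FA(i)
  tg <- build_library("TG", list(c("16:0", "18:1", "18:2")), "[M+NH4]+")
  nl1 <- tg[tg$label == "NL_NH3_FA1", ]
  expect_equal(nl1$frag_mz,
               nl1$precursor_mz - formula_mass("NH3") - fatty_acyl_mass("16:0"),
               tolerance = 1e-9)
})

test_that("entries are unique by (annotation, adduct) and empty input gives empty library", {
  lib <- build_library("PC", list(c("16:0", "18:1"), c("18:1", "16:0")),
                       "[M+HCO2]-")
  expect_identical(nrow(dplyr::distinct(lib, annotation, adduct)), 1L)
  empty <- build_library("PC", list(), "[M+HCO2]-")
  expect_identical(nrow(empty), 0L)
  expect_error(build_library("PC", list(c("16:0", "18:1", "20:0")), "[M+HCO2]-"),
               "2 chains")
  expect_error(build_library("NOPE", list(c("16:0", "18:1"))), "Unknown lipid class")
})

test_that("library files round-trip losslessly at 6 decimals", {
  lib <- dplyr::bind_rows(
    build_library("PC", list(c("16:0", "22:6"), c("18:2", "20:4")),
                  c("[M+HCO2]-", "[M+H]+")),
    build_library("TG", list(c("16:0", "18:1", "18:2")), "[M+NH4]+")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_library(lib, path)
  back <- read_library(path)
  key <- function(x) dplyr::arrange(
    x[c("class", "annotation", "sum_annotation", "adduct", "polarity",
        "precursor_mz", "label", "frag_mz")],
    annotation, adduct, label)
  expect_equal(key(back),
               key(dplyr::mutate(lib,
                                 precursor_mz = round(precursor_mz, 6),
                                 frag_mz = round(frag_mz, 6))))
  # 3-entry file preserves input order
  expect_identical(unique(back$annotation)[1:2],
                   unique(lib$annotation)[1:2])
})

test_that("malformed library files are rejected with the offending column or line", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("class,annotation,adduct,FA1_carboxylate",
               "PC,PC(16:0_22:6),[M+HCO2]-,255.233"), path)
  expect_error(read_library(path), "precursor_mz")
  writeLines(c("class,annotation,adduct,precursor_mz,FA1_carboxylate",
               "PC,PC(16:0_22:6),[M+HCO2]-,850.5604,255.233",
               "PC,PC(18:2_20:4),[M+HCO2]-,oops,279.233"), path)
  expect_error(read_library(path), "line 3")
})

test_that("rule files round-trip and unknown rule labels are rejected", {
  rules <- default_rules()
  path <- withr::local_tempfile(fileext = ".csv")
  write_rules(rules, path)
  expect_equal(read_rules(path), rules)
  lib <- fig3_library()
  bad <- rules
  bad$label[bad$class == "PC" & bad$adduct == "[M+HCO2]-"][1] <- "NOT_A_FRAGMENT"
  expect_error(validate_rules(bad, lib), "NOT_A_FRAGMENT")
  expect_silent(validate_rules(rules, lib))
})
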
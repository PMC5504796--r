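# Shared fixture builders and an independent brute-force reference engine.

# Small PC library over a 5-chain pool, formate adducts (the worked negative
# mode example lives at PC(16:0_22:6) / PC(18:2_20:4), both precursor
# 850.5604).
fig3_library <- function(adducts = "[M+HCO2]-") {
  sets <- enumerate_chain_sets(c("16:0", "18:1", "18:2", "20:4", "22:6"), 2)
  build_library("PC", sets, adducts)
}

# Spectra tibble from a list of peak tables.
make_spectra <- function(prec, rts, peak_tables) {
  tibble::tibble(
    scan = seq_along(rts),
    precursor_mz = prec,
    rt = rts,
    peaks = lapply(peak_tables, function(p) p[order(p$mz), , drop = FALSE])
  )
}

peaks_tbl <- function(mz, intensity) tibble::tibble(mz = mz, intensity = intensity)

# The Fig 3 style scenario: one feature at 850.5604 / RT 5.92 whose scans
# carry the four acyl carboxylates of PC(16:0_22:6) and PC(18:2_20:4).
fig3_scenario <- function(int_16_0 = 8e4, int_22_6 = 6e4,
                          int_18_2 = 3e4, int_20_4 = 2e4,
                          n_scans = 3) {
  pk <- peaks_tbl(
    fa_carboxylate_mz(c("16:0", "22:6", "18:2", "20:4")),
    c(int_16_0, int_22_6, int_18_2, int_20_4)
  )
  list(
    features = tibble::tibble(feature_id = "F1", mz = 850.5604, rt = 5.92),
    spectra = make_spectra(850.5604, 5.92 + seq(-0.02, 0.02, length.out = n_scans),
                           replicate(n_scans, pk, simplify = FALSE)),
    library = fig3_library()
  )
}

# Independent reference engine: enumerates every (candidate, scan, peak)
# triple with plain loops. Deliberately naive and free of the package's
# engine internals; used as the oracle on small instances.
brute_force_annotate <- function(features, spectra, library, rules,
                                 ms1_tol = 0.005, ppm = 10, rt_win = 0.3,
                                 iso = 1, min_int = 1000, min_scans = 1,
                                 precursor_only = FALSE) {
  entries <- unique(library[c("class", "annotation", "sum_annotation",
                              "adduct", "precursor_mz")])
  rows <- list()
  for (fi in seq_len(nrow(features))) {
    f_mz <- features$mz[fi]; f_rt <- features$rt[fi]
    for (ei in seq_len(nrow(entries))) {
      e <- entries[ei, ]
      if (abs(f_mz - e$precursor_mz) > ms1_tol) next
      frs <- library[library$annotation == e$annotation &
                       library$adduct == e$adduct, ]
      keep <- integer(0)
      for (si in seq_len(nrow(spectra))) {
        if (abs(spectra$rt[si] - f_rt) <= rt_win &&
            abs(spectra$precursor_mz[si] - f_mz) <= iso / 2) {
          keep <- c(keep, si)
        }
      }
      nsc <- mx <- numeric(nrow(frs))
      for (k in seq_len(nrow(frs))) {
        tol <- frs$frag_mz[k] * ppm / 1e6
        for (si in keep) {
          pk <- spectra$peaks[[si]]
          best <- -Inf
          for (j in seq_len(nrow(pk))) {
            if (abs(pk$mz[j] - frs$frag_mz[k]) <= tol &&
                pk$intensity[j] > best) {
              best <- pk$intensity[j]
            }
          }
          if (is.finite(best)) {
            nsc[k] <- nsc[k] + 1
            mx[k] <- max(mx[k], best)
          }
        }
      }
      passes <- mx >= min_int & nsc >= min_scans
      rr <- rules[rules$class == e$class & rules$adduct == e$adduct, ]
      conf <- NA_integer_
      if (nrow(rr) > 0 && length(keep) > 0) {
        sat <- vapply(unique(rr$group_id), function(g) {
          gi <- rr[rr$group_id == g, ]
          sum(passes[match(gi$label, frs$label)]) >= gi$min_count[1]
        }, logical(1))
        types <- vapply(unique(rr$group_id), function(g)
          rr$group_type[rr$group_id == g][1], character(1))
        if (all(sat)) {
          conf <- 1L
        } else if (any(types == "class") && all(sat[types == "class"])) {
          conf <- 3L
        }
      }
      if (is.na(conf) && precursor_only) conf <- 4L
      if (is.na(conf)) next
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = features$feature_id[fi],
        annotation = if (conf == 1L) e$annotation else e$sum_annotation,
        adduct = e$adduct, confidence = conf,
        summed_intensity = sum(mx[nsc >= 1]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(feature_id = character(0), annotation = character(0),
                      adduct = character(0), confidence = integer(0),
                      summed_intensity = numeric(0), rank = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$feature_id, -out$summed_intensity, out$annotation,
                   out$adduct), ]
  out$rank <- stats::ave(out$summed_intensity, out$feature_id,
                         FUN = seq_along)
  rownames(out) <- NULL
  out
}
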
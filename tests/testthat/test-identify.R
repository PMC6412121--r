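small_space <- function(max_missed = 0L, window = c(100, 2000)) {
  build_search_space(list(rna_molecule("m", "GAG")), enzymes = "RNaseT1",
                     max_missed = max_missed, window = window)
}

test_that("search space enumerates fragments, variants and charges", {
  sp <- small_space()
  base <- sp[sp$variant == "unmodified", ]
  expect_setequal(unique(paste(base$start, base$end, base$sequence)),
                  c("1 1 G", "2 3 AG"))
  # a methyl on the cleaved G blocks the cut, so the blocked full-length
  # variant is reachable even at zero missed cleavages
  expect_setequal(unique(sp$variant[sp$sequence == "GAG"]), "1:2'-O-methyl")
  # one variable methyl per fragment: both placements on AG present
  ag <- sp[sp$sequence == "AG" & sp$channel == "light", ]
  expect_setequal(unique(ag$variant),
                  c("unmodified", "2:2'-O-methyl", "3:2'-O-methyl"))
  # heavy species only for the unmodified variant
  expect_true(all(sp$variant[sp$channel == "heavy"] == "unmodified"))
  # one retained cut adds the parent-length fragment
  sp1 <- small_space(max_missed = 1L)
  expect_true("GAG" %in% sp1$sequence)
  # determinism
  expect_identical(small_space(), small_space())
})

test_that("MS1 matching respects tolerance, ambiguity and monotonicity", {
  u1 <- rna_molecule("U1",
                     paste(readLines(system.file("extdata", "snrna_like.fasta",
                                                 package = "modstoich"))[2:4],
                           collapse = ""),
                     five_prime_end = "monophosphate")
  prof <- modification_profile("U1", 70, "2'-O-methyl")
  space <- build_search_space(list(u1), enzymes = "RNaseT1", profile = prof)
  mz_mod <- space$mz[space$variant == "70:2'-O-methyl" &
                       space$channel == "light" & space$z == 2][1]
  ids <- match_ms1(data.frame(mz = mz_mod), space, tol_ppm = 5)
  # every match is a single-methyl light species (never the unmodified or
  # heavy forms), and the fixed 70-methyl placement is among them
  expect_true(all(grepl("2'-O-methyl", ids$variant)))
  expect_true(all(ids$channel == "light"))
  expect_true(any(ids$variant == "70:2'-O-methyl" & ids$start == 69))
  # a peak 10 ppm off is not matched
  off <- match_ms1(data.frame(mz = mz_mod * (1 + 10e-6)), space, tol_ppm = 5)
  expect_equal(nrow(off), 0L)
  expect_error(match_ms1(data.frame(mz = 500), space, tol_ppm = 0),
               "positive")
  # the CACUCCG / ACCCCUG isobar is flagged as one ambiguity group
  mz_iso <- space$mz[space$sequence == "CACUCCG" &
                       space$channel == "light" &
                       space$variant == "unmodified" & space$z == 2][1]
  iso <- match_ms1(data.frame(mz = mz_iso), space, tol_ppm = 5)
  expect_setequal(unique(iso$sequence), c("CACUCCG", "ACCCCUG"))
  expect_true(all(iso$ambiguous))
  expect_length(unique(iso$group), 1L)
  # shrinking the tolerance never adds matches
  wide <- match_ms1(data.frame(mz = mz_iso * (1 + 3e-6)), space, tol_ppm = 5)
  narrow <- match_ms1(data.frame(mz = mz_iso * (1 + 3e-6)), space,
                      tol_ppm = 1)
  expect_true(all(paste(narrow$sequence, narrow$z) %in%
                    paste(wide$sequence, wide$z)))
})

test_that("MS2 scoring separates a species from its isobaric partner", {
  lad_a <- ms2_ladders("CACUCCG", "hydroxyl", "linear-phosphate",
                       max_charge = 2)
  lad_b <- ms2_ladders("ACCCCUG", "hydroxyl", "linear-phosphate",
                       max_charge = 2)
  spec_a <- data.frame(mz = lad_a$mz, intensity = 100)
  self <- score_ms2(spec_a, lad_a)
  cross <- score_ms2(spec_a, lad_b)
  expect_equal(unname(self[["n_matched"]]), nrow(lad_a))
  expect_equal(unname(self[["frac_intensity"]]), 1)
  expect_lt(cross[["n_matched"]], self[["n_matched"]])
  expect_equal(unname(score_ms2(data.frame(mz = numeric(),
                                           intensity = numeric()), lad_a)),
               c(0, 0))
  # random-noise spectrum scores near zero
  set.seed(1)
  noise <- data.frame(mz = runif(50, 100, 2000), intensity = 10)
  expect_lt(score_ms2(noise, lad_a)[["n_matched"]], 5)
})

test_that("ambiguity resolution uses MS2 and keeps unresolved groups", {
  u1 <- rna_molecule("U1",
                     paste(readLines(system.file("extdata", "snrna_like.fasta",
                                                 package = "modstoich"))[2:4],
                           collapse = ""),
                     five_prime_end = "monophosphate")
  space <- build_search_space(list(u1), enzymes = "RNaseT1",
                              variable_methyl = FALSE)
  mz_iso <- space$mz[space$sequence == "CACUCCG" &
                       space$channel == "light" & space$z == 2][1]
  ids <- match_ms1(data.frame(mz = mz_iso, rt = 10), space, tol_ppm = 5)
  # discriminating spectrum generated from the CACUCCG ladders
  lad <- ms2_ladders("CACUCCG", "hydroxyl", "linear-phosphate",
                     max_charge = 2)
  spectra <- list(list(precursor_mz = mz_iso, rt = 10,
                       peaks = data.frame(mz = lad$mz, intensity = 100)))
  res <- resolve_identifications(ids, spectra, space)
  expect_equal(res$sequence[res$status == "resolved"], "CACUCCG")
  expect_true(all(res$status[res$sequence == "ACCCCUG"] == "rejected"))
  # without MS2 both candidates are retained as ambiguous
  res0 <- resolve_identifications(ids, NULL, space)
  expect_true(all(res0$status == "ambiguous"))
  expect_setequal(unique(res0$sequence), c("CACUCCG", "ACCCCUG"))
})

test_that("noise-free simulated species are all recovered with no misses", {
  sc <- make_recovery_scenario(noise = list(intensity_cv = 0,
                                            measurement_cv = 0,
                                            mass_ppm_sd = 0,
                                            rt_jitter_sd = 0),
                               mixing = 1, replicates = 1L)
  sim <- simulate_lcms(sc)
  sp <- sim$species
  prof <- modification_profile(sc$sites$molecule_id, sc$sites$position,
                               sc$sites$mod_type)
  space <- build_search_space(list(sc$molecules$M), enzymes = "RNaseT1",
                              profile = prof, max_missed = 0L)
  run <- sim$runs[[1]]
  # apex peaks only (one representative peak per species trace)
  apexes <- do.call(rbind, lapply(split(run$peaks, run$peaks$mz), function(d) {
    d[which.max(d$intensity), ]
  }))
  ids <- match_ms1(apexes, space, tol_ppm = 5)
  emitted <- sim$ledger[sim$ledger$run == names(sim$runs)[1] &
                          sim$ledger$signal_observed > 0, ]
  # every emitted species is matched at its theoretical m/z
  expect_true(all(round(emitted$mz_theoretical, 4) %in%
                    round(ids$mz, 4)))
  # no false assignments: every exact-mass match corresponds to an
  # emitted species, and anything else inside the tolerance window is
  # carried as an explicit ambiguity, never assigned alone
  exact <- abs(ids$ppm_error) < 1e-6
  key <- paste(round(ids$mz, 4), ids$channel)
  led_key <- paste(round(emitted$mz_theoretical, 4), emitted$channel)
  expect_true(all(key[exact] %in% led_key))
  expect_true(all(ids$ambiguous[!exact]))
})
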
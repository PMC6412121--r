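zero_noise <- list(intensity_cv = 0, measurement_cv = 0, mass_ppm_sd = 0,
                   rt_jitter_sd = 0)

test_that("the default scenario carries the bundled molecules and sites", {
  sc <- default_scenario(seed = 5)
  expect_length(sc$molecules, 2L)
  expect_equal(nchar(sc$molecules$U1$sequence), 164L)
  expect_equal(nchar(sc$molecules$U2$sequence), 188L)
  expect_gte(nrow(sc$sites), 9L)
  expect_setequal(sc$conditions, c("control", "knockdown"))
  # fixture truths sit on the fraction scale
  expect_true(all(sc$sites$control >= 0 & sc$sites$control <= 1))
  expect_equal(sc$sites$control[sc$sites$site == "U1-70Am"], 0.793)
  expect_equal(sc$sites$knockdown[sc$sites$site == "U1-70Am"], 0.242)
  expect_equal(sc$seed, 5L)
  # the U2-like molecule is split before residue 17 for the T1 digest
  expect_equal(sc$rnase_h$RNaseT1[["U2"]], 17L)
})

test_that("scenario species include the worked Fig-2-style fragments", {
  sp <- scenario_species(default_scenario())
  # pUUG / pUUGmG: downstream 5'-monophosphate species for 19Gm
  g19 <- sp[grepl("U2-19Gm", sp$all_sites) & sp$role == "site", ]
  expect_setequal(unique(g19$annotated[g19$channel == "light"]),
                  c("UUG", "UUGmG"))
  expect_true(all(g19$five_prime_end == "monophosphate"))
  # AAGAU / AAGmAU for 25Gm from the RNase A digest
  g25 <- sp[grepl("U2-25Gm", sp$all_sites) & sp$role == "site", ]
  expect_setequal(unique(g25$annotated[g25$channel == "light"]),
                  c("AAGAU", "AAGmAU"))
  # composite GGC cluster carries all four variant species
  ggc <- sp[grepl("U2-11Gm", sp$all_sites) & sp$channel == "light", ]
  expect_setequal(unique(ggc$annotated),
                  c("GGC", "GmGC", "GGmC", "GmGmC"))
  # pseudouridine species is mass-silent but RT-shifted
  psi <- sp[grepl("U2-34Y", sp$all_sites) & sp$channel == "light", ]
  expect_equal(sort(unique(psi$annotated)), c("UAG", "YAG"))
  expect_equal(unique(psi$mz[psi$annotated == "YAG"]),
               unique(psi$mz[psi$annotated == "UAG"]))
  expect_gt(psi$rt_shift[psi$annotated == "YAG"][1], 0)
})

test_that("simulation is deterministic given a seed", {
  sc <- default_scenario(seed = 9)
  a <- simulate_lcms(sc)
  b <- simulate_lcms(sc)
  expect_identical(a$runs[[1]]$peaks, b$runs[[1]]$peaks)
  expect_identical(a$ledger, b$ledger)
  c <- simulate_lcms(sc, seed = 10)
  expect_false(identical(a$runs[[1]]$peaks, c$runs[[1]]$peaks))
})

test_that("zero-noise simulation returns the truths exactly", {
  sc <- default_scenario(seed = 3, noise = zero_noise)
  sc$sites$bio_sd <- 0
  sim <- simulate_lcms(sc)
  est <- suppressWarnings(quantify_runs(sim))
  truth <- ifelse(est$condition == "control",
                  sc$sites$control[match(est$site, sc$sites$site)],
                  sc$sites$knockdown[match(est$site, sc$sites$site)])
  expect_equal(est$f_mod, truth, tolerance = 1e-9)
  # the two estimators agree far below 1e-6
  w <- merge(est[est$method == "silnas", c("site", "condition", "replicate",
                                           "f_mod")],
             est[est$method == "peak_area", c("site", "condition",
                                              "replicate", "f_mod")],
             by = c("site", "condition", "replicate"))
  expect_gt(nrow(w), 0L)
  expect_lt(max(abs(w$f_mod.x - w$f_mod.y)), 1e-9)
})

test_that("a 0.9 mixing factor is recovered by the correction pairs", {
  sc <- make_recovery_scenario(mixing = 0.9, seed = 31L)
  sim <- simulate_lcms(sc)
  est <- suppressWarnings(quantify_runs(sim))
  expect_equal(mean(unique(est$k)), 0.9, tolerance = 0.02)
  # and the estimates remain unbiased under the miscalibrated mixing
  agg <- stats::aggregate(f_mod ~ site, est, mean)
  truths <- sc$sites$truth[match(agg$site, sc$sites$site)]
  expect_lt(max(abs(agg$f_mod - truths)), 0.03)
})

test_that("fixtures round-trip through write and read", {
  dir <- withr::local_tempdir()
  sc <- make_recovery_scenario(replicates = 1L)
  sim <- simulate_lcms(sc)
  write_fixtures(sim, dir)
  back <- read_fixtures(dir)
  expect_setequal(names(back$runs), names(sim$runs))
  r0 <- sim$runs[[1]]; r1 <- back$runs[[names(sim$runs)[1]]]
  expect_equal(r1$peaks$mz, r0$peaks$mz, tolerance = 1e-9)
  expect_equal(r1$peaks$intensity, r0$peaks$intensity, tolerance = 1e-9)
  expect_equal(length(r1$ms2), length(r0$ms2))
  expect_equal(back$scenario$mixing, sc$mixing)
  expect_equal(back$seed, sim$seed)
  # quantification of the re-read fixtures matches the in-memory result
  expect_equal(suppressWarnings(quantify_runs(back))$f_mod,
               suppressWarnings(quantify_runs(sim))$f_mod,
               tolerance = 1e-6)
  expect_error(write_fixtures(sim, file.path(dir, "nope")), "directory")
})

test_that("ledger reconciles with pipeline estimates under default noise", {
  sc <- default_scenario(seed = 13)
  sim <- simulate_lcms(sc)
  est <- suppressWarnings(quantify_runs(sim))
  # per-replicate estimates track the ledger's realized truths
  tr <- sim$truths
  f_true <- tr$f_realized[match(paste(est$site, est$condition, est$replicate),
                                paste(tr$site, tr$condition, tr$replicate))]
  expect_lt(max(abs(est$f_mod - f_true)), 0.06)
  # and site-level means are within 2 points
  agg <- stats::aggregate(cbind(f_mod, f_true) ~ site + condition + method,
                          cbind(est, f_true), mean)
  expect_lt(max(abs(agg$f_mod - agg$f_true)), 0.02)
})
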
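test_that("correction factor averages per-pair ratios", {
  expect_equal(correction_factor(rep(1000, 10), rep(1000, 10))$k, 1)
  expect_equal(correction_factor(rep(1100, 10), rep(1000, 10))$k, 1.1)
  # median option resists an outlier pair
  k <- correction_factor(c(rep(1000, 9), 5000), rep(1000, 10),
                         stat = "median")
  expect_equal(k$k, 1)
  expect_error(correction_factor(c(1, 1), c(1, 0)), "positive")
  expect_error(correction_factor(1000, 1000), "at least")
  expect_warning(correction_factor(rep(1, 7), rep(1, 7)), "7 pairs")
  # lognormal pairs around true mixing 0.9 recover it
  set.seed(21)
  heavy <- rlnorm(10, log(1e6), 0.05)
  light <- 0.9 * heavy * rlnorm(10, 0, 0.01)
  k <- suppressWarnings(correction_factor(light, heavy))
  expect_equal(k$k, 0.9, tolerance = 0.02)
})

test_that("intensity-ratio estimates follow the depletion definition", {
  expect_equal(silnas_estimate(250, 1000, 1)$f_mod, 0.75)
  expect_equal(silnas_estimate(1000, 1000, 1)$f_mod, 0)
  expect_equal(silnas_estimate(0, 1000, 1)$f_mod, 1)
  # noise-free round trip at the 0.793 fixture truth
  f <- 0.793; heavy <- 1e6; k <- 1
  est <- silnas_estimate((1 - f) * k * heavy, heavy, k,
                         light_mod = f * k * heavy)
  expect_equal(est$f_mod, f)
  expect_equal(est$consistency, 1)
  # clamping is flagged, never silent
  over <- silnas_estimate(1500, 1000, 1)
  expect_equal(over$f_mod, 0)
  expect_true(over$clamped)
  expect_error(silnas_estimate(100, 0, 1), "positive")
  expect_error(silnas_estimate(100, 1000, -1), "positive")
  # a correction_factor object is accepted for k
  kf <- correction_factor(rep(900, 10), rep(1000, 10))
  expect_equal(silnas_estimate(450, 1000, kf)$f_mod, 0.5)
})

test_that("XIC extraction windows by ppm and warns on merged traces", {
  peaks <- data.frame(mz = c(1000.000, 1000.002, 1500),
                      rt = c(10, 11, 10), intensity = c(5, 7, 100))
  x <- extract_xic(peaks, 1000, tol_ppm = 5)
  expect_equal(x$intensity, c(5, 7))
  expect_equal(nrow(extract_xic(peaks, 800, tol_ppm = 5)), 0L)
  expect_warning(extract_xic(peaks, 1000, tol_ppm = 5,
                             other_mz = 1000 * (1 + 3e-6)), "merge")
  # a sampled Gaussian comes back unchanged
  tt <- seq(9, 11, by = 0.02)
  g <- data.frame(mz = 1200, rt = tt,
                  intensity = 1e5 * exp(-(tt - 10)^2 / (2 * 0.05^2)))
  expect_equal(extract_xic(g, 1200)$intensity, g$intensity)
})

test_that("peak integration is trapezoid-exact and finds auto boundaries", {
  # rectangular pulse: area = h x w
  rect <- data.frame(rt = seq(0, 1, by = 0.1), intensity = 50)
  expect_equal(integrate_peak(rect, boundaries = c(0, 1))$area, 50)
  # Gaussian area ~ A sigma sqrt(2 pi) within 1%
  tt <- seq(5, 15, by = 0.005)
  A <- 2e5; s <- 0.07
  g <- data.frame(rt = tt, intensity = A * exp(-(tt - 10)^2 / (2 * s^2)))
  got <- integrate_peak(g, boundaries = c(5, 15))$area
  expect_equal(got, A * s * sqrt(2 * pi), tolerance = 0.01)
  auto <- integrate_peak(g)
  expect_false(auto$no_peak)
  expect_equal(auto$area, got, tolerance = 0.01)
  # degenerate traces
  z <- integrate_peak(data.frame(rt = numeric(), intensity = numeric()))
  expect_true(z$no_peak)
  expect_equal(z$area, 0)
  expect_error(integrate_peak(g, boundaries = c(20, 30)), "outside")
})

test_that("peak-area fractions handle boundaries and composite sites", {
  expect_equal(peak_area_estimate(0, 100)$f_mod, 0)
  expect_equal(peak_area_estimate(100, 0)$f_mod, 1)
  expect_equal(peak_area_estimate(300, 100)$f_mod, 0.75)
  # composite: two modified isomers summed against one unmodified species
  expect_equal(peak_area_estimate(c(200, 100), 100)$f_mod, 0.75)
  und <- peak_area_estimate(0, 0)
  expect_true(und$undefined)
  expect_true(is.na(und$f_mod))
  expect_error(peak_area_estimate(numeric(), numeric()), "at least one")
  expect_error(peak_area_estimate(-1, 5), "non-negative")
})

test_that("both estimators are invariant to global intensity scaling", {
  for (s in c(1, 17, 1e-3)) {
    expect_equal(silnas_estimate(250 * s, 1000 * s, 1)$f_mod, 0.75)
    expect_equal(peak_area_estimate(300 * s, 100 * s)$f_mod, 0.75)
  }
})

test_that("replicate aggregation reports mean, SEM and comparisons", {
  est <- data.frame(site = "s", condition = rep(c("a", "b"), each = 3),
                    replicate = rep(1:3, 2),
                    f_mod = c(0.79, 0.75, 0.82, 0.79, 0.75, 0.82))
  rep1 <- aggregate_and_compare(est, reference = "a")
  expect_equal(rep1$mean, rep(mean(c(0.79, 0.75, 0.82)), 2))
  expect_equal(rep1$sem, rep(sd(c(0.79, 0.75, 0.82)) / sqrt(3), 2))
  expect_equal(rep1$n, c(3L, 3L))
  # identical conditions: p ~ 1, not significant
  expect_gt(rep1$p_value[rep1$condition == "b"], 0.9)
  # identical replicates: SEM 0; constant equal groups get p = 1
  cst <- data.frame(site = "s", condition = rep(c("a", "b"), each = 3),
                    replicate = rep(1:3, 2), f_mod = 0.5)
  rep2 <- aggregate_and_compare(cst, reference = "a")
  expect_equal(rep2$sem, c(0, 0))
  expect_equal(rep2$p_value[2], 1)
  # n = 1: SEM undefined, reported as NA
  one <- data.frame(site = "s", condition = c("a", "b"), replicate = 1,
                    f_mod = c(0.5, 0.6))
  rep3 <- aggregate_and_compare(one, reference = "a")
  expect_true(all(is.na(rep3$sem)))
  expect_true(is.na(rep3$p_value[rep3$condition == "b"]))
  # three conditions go through Tukey-style adjustment
  set.seed(2)
  est3 <- data.frame(site = "s",
                     condition = rep(c("a", "b", "c"), each = 3),
                     replicate = rep(1:3, 3),
                     f_mod = c(rnorm(3, 0.8, 0.02), rnorm(3, 0.3, 0.02),
                               rnorm(3, 0.78, 0.02)))
  rep4 <- aggregate_and_compare(est3, reference = "a")
  expect_true(rep4$significant[rep4$condition == "b"])
  expect_false(rep4$significant[rep4$condition == "c"])
  expect_error(aggregate_and_compare(est, reference = "zz"), "absent")
})
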
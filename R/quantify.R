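## Stoichiometry estimators.
##
## Two readouts of the modified fraction at a site:
##  * light/heavy intensity ratio against the 13C-labeled, unmodified
##    internal-standard transcript ("silnas"): f = 1 - L_unmod / (k * H),
##    with k an experimentally determined mixing correction factor from
##    unmodified fragment pairs;
##  * extracted-ion-chromatogram peak areas ("peak_area"):
##    f = sum(area_mod) / (sum(area_mod) + sum(area_unmod)), which also
##    handles mass-silent pseudouridine via RT-resolved species of
##    identical m/z.

#' Mixing correction factor from unmodified fragment pairs
#'
#' The nominal 1:1 light:heavy mixing is verified with the light/heavy
#' signal ratios of around ten fragment pairs that carry no
#' modifications; their average is the correction factor applied to every
#' heavy signal.
#'
#' @param light,heavy Parallel numeric vectors of signals for the
#'   unmodified pairs (all > 0).
#' @param stat `"mean"` (the conventional average) or `"median"` (robust
#'   to outlier pairs).
#' @param min_pairs Minimum acceptable number of pairs (default 5; a
#'   warning is issued below 10).
#' @return An object of class `correction_factor`: a list with `k`,
#'   `n_pairs`, and the per-pair `ratios`.
#' @examples
#' correction_factor(rep(1100, 10), rep(1000, 10))$k
#' @export
correction_factor <- function(light, heavy, stat = c("mean", "median"),
                              min_pairs = 5L) {
  stat <- match.arg(stat)
  stopifnot(length(light) == length(heavy))
  if (any(heavy <= 0)) stop("heavy signals must be positive", call. = FALSE)
  if (any(light <= 0)) stop("light signals must be positive", call. = FALSE)
  if (length(light) < min_pairs) {
    stop(sprintf("need at least %d unmodified pairs, got %d",
                 min_pairs, length(light)), call. = FALSE)
  }
  if (length(light) < 10L) {
    warning(sprintf("correction factor from only %d pairs (< 10)",
                    length(light)), call. = FALSE)
  }
  ratios <- light / heavy
  k <- if (stat == "mean") mean(ratios) else stats::median(ratios)
  structure(list(k = k, n_pairs = length(ratios), ratios = ratios,
                 stat = stat),
            class = "correction_factor")
}

#' @export
print.correction_factor <- function(x, ...) {
  cat(sprintf("<correction_factor> k = %.4f (%s of %d pairs)\n",
              x$k, x$stat, x$n_pairs))
  invisible(x)
}

clamp01 <- function(x) {
  list(value = min(1, max(0, x)), clamped = x < 0 || x > 1)
}

#' Light/heavy internal-standard stoichiometry estimate
#'
#' `f_mod = 1 - light_unmod / (k * heavy)`, clamped to `[0, 1]` with a
#' flag when the raw estimate falls outside.  When the modified light
#' species was also measured, a consistency diagnostic
#' `(light_unmod + light_mod) / (k * heavy)` (expected ~ 1) is attached.
#'
#' @param light_unmod Signal of the unmodified light species.
#' @param heavy Signal of the heavy (internal standard) species (> 0).
#' @param k A [correction_factor] or a plain positive number.
#' @param light_mod Optional signal of the modified light species.
#' @param site,replicate Optional labels carried into the result.
#' @return A one-row data.frame of class `stoichiometry_estimate` with
#'   columns `site`, `replicate`, `method`, `f_mod`, `clamped`,
#'   `consistency`.
#' @examples
#' silnas_estimate(250, 1000, 1)$f_mod  # 0.75
#' @export
silnas_estimate <- function(light_unmod, heavy, k, light_mod = NA_real_,
                            site = NA_character_, replicate = NA_integer_) {
  if (inherits(k, "correction_factor")) k <- k$k
  if (!is.numeric(k) || k <= 0) stop("k must be positive", call. = FALSE)
  if (heavy <= 0) stop("heavy signal must be positive", call. = FALSE)
  if (light_unmod < 0) stop("signals must be non-negative", call. = FALSE)
  raw <- 1 - light_unmod / (k * heavy)
  cl <- clamp01(raw)
  consistency <- if (is.na(light_mod)) NA_real_ else
    (light_unmod + light_mod) / (k * heavy)
  out <- data.frame(site = site, replicate = replicate, method = "silnas",
                    f_mod = cl$value, clamped = cl$clamped,
                    consistency = consistency, stringsAsFactors = FALSE)
  class(out) <- c("stoichiometry_estimate", "data.frame")
  out
}

#' Extract an ion chromatogram at a target m/z
#'
#' Sums, per retention time, the intensity of all peaks within
#' `tol_ppm` of `target_mz`.
#'
#' @param peaks data.frame with columns `mz`, `rt`, `intensity`.
#' @param target_mz Target m/z (Th).
#' @param tol_ppm Extraction tolerance in ppm (default 5).
#' @param other_mz Optional m/z values of other known species; a warning
#'   is emitted if any falls inside the extraction window (merged
#'   traces).
#' @return data.frame `rt`, `intensity`, time-ordered (possibly empty).
#' @export
extract_xic <- function(peaks, target_mz, tol_ppm = 5, other_mz = NULL) {
  if (!is.null(other_mz)) {
    d <- abs(other_mz - target_mz) / target_mz * 1e6
    near <- other_mz[d > 0 & d <= 2 * tol_ppm]
    if (length(near)) {
      warning(sprintf(
        "XIC at m/z %.4f may merge other species within tolerance: %s",
        target_mz, paste(sprintf("%.4f", near), collapse = ", ")),
        call. = FALSE)
    }
  }
  sel <- abs(peaks$mz - target_mz) / target_mz * 1e6 <= tol_ppm
  sub <- peaks[sel, c("rt", "intensity"), drop = FALSE]
  if (!nrow(sub)) {
    return(data.frame(rt = numeric(), intensity = numeric()))
  }
  agg <- stats::aggregate(intensity ~ rt, data = sub, FUN = sum)
  agg <- agg[order(agg$rt), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

## Chromatographic peaks of an XIC trace: the trace is segmented at
## scan gaps (runs of missing scans) and at the noise floor, then each
## segment is integrated over the contiguous region above
## `apex * boundary_fraction` relative to its OWN apex, so the relative
## truncation is identical for small and large peaks.  Overlapping
## peaks closer than the peak width are not deconvolved.
find_chrom_peaks <- function(chrom, boundary_fraction = 0.01,
                             noise_floor = 0) {
  empty <- data.frame(rt_apex = numeric(), apex = numeric(),
                      area = numeric(), rt_start = numeric(),
                      rt_end = numeric())
  chrom <- chrom[chrom$intensity > noise_floor, , drop = FALSE]
  if (!nrow(chrom)) return(empty)
  dt <- if (nrow(chrom) > 1L) stats::median(diff(chrom$rt)) else 0
  gap <- c(FALSE, if (nrow(chrom) > 1L) diff(chrom$rt) > 2.5 * max(dt, 1e-9))
  segment <- cumsum(gap)
  out <- list()
  for (sid in unique(segment)) {
    seg <- chrom[segment == sid, , drop = FALSE]
    a <- which.max(seg$intensity)
    thr <- seg$intensity[a] * boundary_fraction
    above <- seg$intensity >= thr
    lo <- a; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
    hi <- a; while (hi < nrow(seg) && above[hi + 1L]) hi <- hi + 1L
    reg <- seg[lo:hi, , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      rt_apex = seg$rt[a],
      apex = fit_apex(reg, seg$intensity[a]),
      area = trapezoid_area(reg$rt, reg$intensity),
      rt_start = reg$rt[1], rt_end = reg$rt[nrow(reg)]
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Apex intensity by a quadratic fit of log-intensity over the top of
## the peak — exact for Gaussian elution profiles and robust to single
## dropped scans; falls back to the raw maximum for sparse regions.
fit_apex <- function(reg, raw_max) {
  top <- reg[reg$intensity >= 0.2 * raw_max, , drop = FALSE]
  if (nrow(top) < 3L) return(raw_max)
  t0 <- top$rt - mean(top$rt)
  co <- tryCatch(stats::lm.fit(cbind(1, t0, t0^2), log(top$intensity))$coefficients,
                 error = function(e) NULL)
  if (is.null(co) || anyNA(co) || co[3] >= 0) return(raw_max)
  fitted <- exp(co[1] - co[2]^2 / (4 * co[3]))
  ## sanity: the fit must not wander away from the observed maximum
  if (!is.finite(fitted) || fitted < raw_max * 0.8 || fitted > raw_max * 1.5) {
    return(raw_max)
  }
  unname(fitted)
}

trapezoid_area <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Integrate a chromatographic peak
#'
#' Trapezoidal integration either over explicit retention-time
#' boundaries or, in `"auto"` mode, over the contiguous region around
#' the apex above `max(apex * boundary_fraction, noise_floor)` —
#' an automated stand-in for manually selected peak start/end.
#'
#' @param chrom data.frame `rt`, `intensity` from [extract_xic].
#' @param boundaries `"auto"` or a numeric `c(rt_start, rt_end)`.
#' @param boundary_fraction Apex-relative threshold for auto boundaries.
#' @param noise_floor Absolute intensity floor.
#' @return A list with `area`, `rt_start`, `rt_end`, `no_peak` flag.
#' @export
integrate_peak <- function(chrom, boundaries = "auto",
                           boundary_fraction = 0.01, noise_floor = 0) {
  if (identical(boundaries, "auto")) {
    if (!nrow(chrom) || all(chrom$intensity <= noise_floor)) {
      return(list(area = 0, rt_start = NA_real_, rt_end = NA_real_,
                  no_peak = TRUE))
    }
    pk <- find_chrom_peaks(chrom, boundary_fraction, noise_floor)
    best <- which.max(pk$area)
    sel <- chrom$rt >= pk$rt_start[best] & chrom$rt <= pk$rt_end[best]
  } else {
    stopifnot(is.numeric(boundaries), length(boundaries) == 2L)
    if (!nrow(chrom) || boundaries[1] > max(chrom$rt) ||
        boundaries[2] < min(chrom$rt)) {
      stop("explicit boundaries fall outside the trace", call. = FALSE)
    }
    sel <- chrom$rt >= boundaries[1] & chrom$rt <= boundaries[2]
  }
  seg <- chrom[sel, , drop = FALSE]
  list(area = trapezoid_area(seg$rt, seg$intensity),
       rt_start = if (nrow(seg)) seg$rt[1] else NA_real_,
       rt_end = if (nrow(seg)) seg$rt[nrow(seg)] else NA_real_,
       no_peak = !nrow(seg) || all(seg$intensity == 0))
}

#' Peak-area stoichiometry estimate
#'
#' `f_mod = sum(mod areas) / (sum(mod areas) + sum(unmod areas))`.
#' Composite sites (isomeric modified species that quantify one
#' position, e.g. the doubly and singly methylated forms of a fragment
#' with two adjacent sites) are handled by passing all their areas.
#'
#' @param mod_areas Numeric vector of modified-species areas.
#' @param unmod_areas Numeric vector of unmodified-species areas.
#' @param site,replicate Optional labels carried into the result.
#' @return A one-row `stoichiometry_estimate` data.frame; `f_mod` is `NA`
#'   with `undefined = TRUE` when both sums are zero.
#' @examples
#' peak_area_estimate(300, 100)$f_mod  # 0.75
#' @export
peak_area_estimate <- function(mod_areas, unmod_areas,
                               site = NA_character_,
                               replicate = NA_integer_) {
  if (!length(mod_areas) && !length(unmod_areas)) {
    stop("at least one species per side must be measured", call. = FALSE)
  }
  if (any(c(mod_areas, unmod_areas) < 0)) {
    stop("areas must be non-negative", call. = FALSE)
  }
  sm <- sum(mod_areas); su <- sum(unmod_areas)
  undefined <- (sm + su) == 0
  f <- if (undefined) NA_real_ else sm / (sm + su)
  out <- data.frame(site = site, replicate = replicate,
                    method = "peak_area", f_mod = f, clamped = FALSE,
                    undefined = undefined, stringsAsFactors = FALSE)
  class(out) <- c("stoichiometry_estimate", "data.frame")
  out
}

#' Aggregate replicate estimates and compare conditions
#'
#' Per site and condition: mean, SEM (`sd/sqrt(n)`) and n.  Each
#' non-reference condition is compared with the reference: Welch
#' two-sample t-test for two conditions, one-way ANOVA with Tukey HSD
#' adjustment for more.  Degenerate inputs (n = 1, or zero variance in
#' both groups) are reported rather than erroring: SEM is `NA` at n = 1,
#' and the p-value is 1 for identical constant groups.
#'
#' @param estimates data.frame with columns `site`, `condition`,
#'   `replicate`, `f_mod` (and optionally `method`).
#' @param reference Name of the reference condition.
#' @return A data.frame of class `site_report`: one row per
#'   (site, condition) with `mean`, `sem`, `n`, `p_value` (vs reference;
#'   `NA` on the reference rows) and `significant` at 0.05.
#' @export
aggregate_and_compare <- function(estimates, reference) {
  stopifnot(all(c("site", "condition", "f_mod") %in% names(estimates)))
  if (!reference %in% estimates$condition) {
    stop("reference condition '", reference, "' absent from estimates",
         call. = FALSE)
  }
  conditions <- unique(estimates$condition)
  rows <- list()
  for (s in unique(estimates$site)) {
    es <- estimates[estimates$site == s, , drop = FALSE]
    pvals <- compare_to_reference(es, reference, conditions)
    for (cond in conditions) {
      x <- es$f_mod[es$condition == cond]
      rows[[length(rows) + 1L]] <- data.frame(
        site = s, condition = cond,
        mean = mean(x),
        sem = if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_,
        n = length(x),
        p_value = if (cond == reference) NA_real_ else pvals[[cond]],
        stringsAsFactors = FALSE
      )
    }
  }
  rep <- do.call(rbind, rows)
  rep$significant <- !is.na(rep$p_value) & rep$p_value < 0.05
  rownames(rep) <- NULL
  class(rep) <- c("site_report", "data.frame")
  rep
}

compare_to_reference <- function(es, reference, conditions) {
  others <- setdiff(conditions, reference)
  pvals <- stats::setNames(rep(NA_real_, length(others)), others)
  ref_x <- es$f_mod[es$condition == reference]
  if (length(others) == 1L) {
    x <- es$f_mod[es$condition == others]
    if (length(x) < 2L || length(ref_x) < 2L) return(pvals)
    if (stats::sd(x) == 0 && stats::sd(ref_x) == 0) {
      pvals[others] <- if (mean(x) == mean(ref_x)) 1 else 0
    } else {
      ## pooled-variance t, consistent with the homoscedastic Tukey
      ## comparison used for > 2 conditions
      pvals[others] <- stats::t.test(x, ref_x, var.equal = TRUE)$p.value
    }
    return(pvals)
  }
  ## > 2 conditions: Tukey-style all-pair adjustment, reported vs reference
  if (stats::sd(es$f_mod) == 0) {
    pvals[] <- 1
    return(pvals)
  }
  es$condition <- factor(es$condition)
  fit <- stats::aov(f_mod ~ condition, data = es)
  tk <- stats::TukeyHSD(fit)$condition
  for (cond in others) {
    key <- c(paste0(cond, "-", reference), paste0(reference, "-", cond))
    hit <- rownames(tk) %in% key
    if (any(hit)) pvals[cond] <- tk[hit, "p adj"][1]
  }
  pvals
}
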
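## MS1/MS2 identification of digest species against a theoretical search
## space, in the style of RNA-MS search engines: fixed (known)
## modification sites plus at most one variable methylation per fragment,
## ppm-windowed precursor matching, and MS2 ladder scoring to resolve
## isobaric collisions.

species_key <- function(df) {
  paste(df$molecule_id, df$start, df$end, df$variant, df$channel, sep = "|")
}

variant_label <- function(mods) {
  if (is.null(mods) || !nrow(mods)) return("unmodified")
  ord <- order(mods$position)
  paste(sprintf("%d:%s", mods$position[ord], mods$mod_type[ord]),
        collapse = ";")
}

#' Build the theoretical ion index for a set of molecules
#'
#' For every enzyme, the molecules are digested with up to `max_missed`
#' retained cuts under three modification regimes: unmodified, the full
#' fixed profile, and (optionally) every single-methyl placement — which
#' together realize the "one variable methylation per fragment" search
#' policy while letting fixed known sites stack beyond the cap.
#' Blocking methyls re-shape fragment boundaries, so each variant is
#' obtained from its own modification-aware digest.  Heavy-channel
#' species (the unmodified internal-standard transcript) are indexed with
#' the enzyme's label scheme.
#'
#' @param molecules Named list of [rna_molecule].
#' @param enzymes Character vector from `c("RNaseT1", "RNaseA")`.
#' @param profile Optional `modification_profile` of fixed known sites.
#' @param max_missed Missed-cleavage cap (default 1).
#' @param window Instrument m/z window.
#' @param variable_methyl Allow one variable 2'-O-methyl per fragment.
#' @param schemes Named list mapping enzyme to [label_scheme] for the
#'   heavy channel; `NULL` entries skip heavy species.
#' @param cap_composition Cap composition for capped 5' ends.
#' @return A data.frame of class `search_space`: one row per
#'   (species, charge), deterministic and deduplicated, with columns
#'   including `sequence`, `variant`, `channel`, `z`, `mz`.
#' @export
build_search_space <- function(molecules,
                               enzymes = c("RNaseT1", "RNaseA"),
                               profile = NULL,
                               max_missed = 1L,
                               window = c(480, 1980),
                               variable_methyl = TRUE,
                               schemes = list(RNaseT1 = label_scheme("T1"),
                                              RNaseA = label_scheme("A")),
                               cap_composition = DEFAULT_TMG_CAP) {
  if (!length(molecules)) stop("at least one molecule required", call. = FALSE)
  if (inherits(molecules, "rna_molecule")) molecules <- list(molecules)
  rows <- list()
  add_variants <- function(frag, enzyme) {
    for (i in seq_len(nrow(frag))) {
      fr <- frag[i, , drop = FALSE]
      mods <- fr$mods[[1]]
      scheme <- schemes[[enzyme]]
      channels <- "light"
      if (!is.null(scheme) && variant_label(mods) == "unmodified") {
        channels <- c("light", "heavy")
      }
      for (ch in channels) {
        sp <- species_mz(fr, mods = mods, channel = ch, scheme = scheme,
                         window = window, cap_composition = cap_composition)
        if (!length(sp$charges)) next
        rows[[length(rows) + 1L]] <<- data.frame(
          molecule_id = fr$molecule_id, start = fr$start, end = fr$end,
          sequence = fr$sequence,
          annotated = annotate_sequence(fr$sequence, mods, fr$start),
          variant = variant_label(mods),
          missed_cleavages = fr$missed_cleavages,
          five_prime_end = fr$five_prime_end,
          three_prime_end = fr$three_prime_end,
          enzyme = enzyme, channel = ch,
          mass = sp$mass, z = sp$charges, mz = sp$mz,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  for (mol in molecules) {
    n <- nchar(mol$sequence)
    for (enzyme in enzymes) {
      rule <- cleavage_rule(enzyme)
      add_variants(digest(mol, rule, max_missed, profile = NULL), enzyme)
      if (!is.null(profile) &&
          any(profile$molecule_id == mol$id)) {
        frag <- digest(mol, rule, max_missed, profile = profile)
        keep <- vapply(frag$mods, nrow, 0L) > 0L
        add_variants(frag[keep, , drop = FALSE], enzyme)
      }
      if (variable_methyl) {
        for (p in seq_len(n)) {
          prof_p <- modification_profile(mol$id, p, "2'-O-methyl")
          frag <- digest(mol, rule, max_missed, profile = prof_p)
          keep <- frag$start <= p & frag$end >= p
          add_variants(frag[keep, , drop = FALSE], enzyme)
        }
      }
    }
  }
  space <- do.call(rbind, rows)
  key <- paste(species_key(space), space$enzyme, space$z)
  space <- space[!duplicated(key), , drop = FALSE]
  space <- space[order(space$mz, species_key(space), space$z), , drop = FALSE]
  rownames(space) <- NULL
  attr(space, "schemes") <- schemes
  attr(space, "window") <- window
  attr(space, "cap_composition") <- cap_composition
  class(space) <- c("search_space", "data.frame")
  space
}

#' Match an MS1 peak list against a search space
#'
#' Every peak within `tol_ppm` of a theoretical m/z is matched; peaks
#' matching several distinct species are retained with an ambiguity flag
#' and a shared isobaric group id, never silently dropped.
#'
#' @param peaks data.frame with column `mz` (and optionally `rt`,
#'   `intensity`).
#' @param space A `search_space` from [build_search_space].
#' @param tol_ppm MS1 mass tolerance in ppm (default 5).
#' @return A data.frame of identifications: peak columns, matched species
#'   columns, `ppm_error`, `ambiguous`, `group`.
#' @export
match_ms1 <- function(peaks, space, tol_ppm = 5) {
  if (tol_ppm <= 0) stop("tol_ppm must be positive", call. = FALSE)
  if (is.null(peaks$rt)) peaks$rt <- NA_real_
  if (is.null(peaks$intensity)) peaks$intensity <- NA_real_
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    ppm <- (peaks$mz[i] - space$mz) / space$mz * 1e6
    hit <- which(abs(ppm) <= tol_ppm)
    if (!length(hit)) next
    sub <- space[hit, , drop = FALSE]
    keys <- species_key(sub)
    n_species <- length(unique(keys))
    out[[length(out) + 1L]] <- cbind(
      data.frame(peak = i, peak_mz = peaks$mz[i], rt = peaks$rt[i],
                 intensity = peaks$intensity[i],
                 ppm_error = ppm[hit],
                 ambiguous = n_species > 1L,
                 group = paste(sort(unique(keys)), collapse = " / "),
                 stringsAsFactors = FALSE),
      as.data.frame(sub)
    )
  }
  if (!length(out)) {
    return(data.frame(peak = integer(), peak_mz = numeric(), rt = numeric(),
                      intensity = numeric(), ppm_error = numeric(),
                      ambiguous = logical(), group = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

ladder_for_species <- function(row, schemes, cap_composition = DEFAULT_TMG_CAP,
                               max_charge = 2L) {
  mods <- NULL
  if (row$variant != "unmodified") {
    parts <- strsplit(strsplit(row$variant, ";", fixed = TRUE)[[1]], ":",
                      fixed = TRUE)
    mods <- data.frame(position = as.integer(vapply(parts, `[`, "", 1)),
                       mod_type = vapply(parts, `[`, "", 2),
                       stringsAsFactors = FALSE)
  }
  ms2_ladders(row$sequence, row$five_prime_end, row$three_prime_end,
              mods = mods, start = row$start, channel = row$channel,
              scheme = schemes[[row$enzyme]], max_charge = max_charge,
              cap_composition = cap_composition)
}

#' Score an MS2 spectrum against a candidate species
#'
#' @param spectrum data.frame with columns `mz`, `intensity` (an empty
#'   spectrum scores zero rather than erroring).
#' @param ladders Theoretical ladders from [ms2_ladders].
#' @param tol_ppm MS/MS tolerance in ppm (default 20).
#' @return Named numeric vector `c(n_matched, frac_intensity)`: the count
#'   of matched theoretical ions and the fraction of spectrum intensity
#'   explained.
#' @export
score_ms2 <- function(spectrum, ladders, tol_ppm = 20) {
  if (is.null(spectrum) || !nrow(spectrum)) {
    return(c(n_matched = 0, frac_intensity = 0))
  }
  matched_theo <- 0L
  peak_hit <- rep(FALSE, nrow(spectrum))
  for (j in seq_len(nrow(ladders))) {
    d <- abs(spectrum$mz - ladders$mz[j]) / ladders$mz[j] * 1e6
    hit <- d <= tol_ppm
    if (any(hit)) {
      matched_theo <- matched_theo + 1L
      peak_hit <- peak_hit | hit
    }
  }
  total <- sum(spectrum$intensity)
  frac <- if (total > 0) sum(spectrum$intensity[peak_hit]) / total else 0
  c(n_matched = matched_theo, frac_intensity = frac)
}

#' Resolve ambiguous identifications with MS2 evidence
#'
#' Isobaric groups are resolved by (1) highest MS2 matched-ion count,
#' (2) intensity fraction, (3) smallest absolute precursor ppm error;
#' unresolved groups are reported as ambiguous, never dropped.
#'
#' @param identifications Output of [match_ms1].
#' @param spectra Optional list of MS2 spectra, each a list with
#'   `precursor_mz`, `rt` and `peaks` (data.frame `mz`, `intensity`).
#' @param space The `search_space` the identifications came from.
#' @param tol_ppm MS/MS tolerance in ppm.
#' @param precursor_tol_ppm Tolerance for pairing a spectrum with a peak.
#' @param rt_tol Maximum |rt difference| for spectrum/peak pairing.
#' @return The identifications with a `status` column
#'   (`"unique"`, `"resolved"`, `"rejected"`, `"ambiguous"`) and MS2
#'   scores where available.
#' @export
resolve_identifications <- function(identifications, spectra = NULL,
                                    space, tol_ppm = 20,
                                    precursor_tol_ppm = 10, rt_tol = 0.5) {
  ids <- identifications
  if (!nrow(ids)) {
    ids$status <- character()
    return(ids)
  }
  ids$ms2_n <- NA_real_
  ids$ms2_frac <- NA_real_
  ids$status <- ifelse(ids$ambiguous, "ambiguous", "unique")
  schemes <- attr(space, "schemes")
  capc <- attr(space, "cap_composition")
  if (is.null(capc)) capc <- DEFAULT_TMG_CAP
  for (pk in unique(ids$peak[ids$ambiguous])) {
    sel <- which(ids$peak == pk)
    spec <- NULL
    if (!is.null(spectra) && length(spectra)) {
      pmz <- vapply(spectra, `[[`, 0, "precursor_mz")
      prt <- vapply(spectra, function(s) {
        if (is.null(s$rt)) NA_real_ else s$rt
      }, 0)
      dppm <- abs(pmz - ids$peak_mz[sel[1]]) / ids$peak_mz[sel[1]] * 1e6
      cand <- which(dppm <= precursor_tol_ppm &
                      (is.na(prt) | is.na(ids$rt[sel[1]]) |
                         abs(prt - ids$rt[sel[1]]) <= rt_tol))
      if (length(cand)) spec <- spectra[[cand[which.min(dppm[cand])]]]
    }
    if (is.null(spec)) next
    scores <- t(vapply(sel, function(k) {
      lad <- ladder_for_species(ids[k, , drop = FALSE], schemes,
                                cap_composition = capc)
      score_ms2(spec$peaks, lad, tol_ppm = tol_ppm)
    }, c(n_matched = 0, frac_intensity = 0)))
    ids$ms2_n[sel] <- scores[, "n_matched"]
    ids$ms2_frac[sel] <- scores[, "frac_intensity"]
    ord <- order(-scores[, "n_matched"], -scores[, "frac_intensity"],
                 abs(ids$ppm_error[sel]))
    best <- ord[1]
    tie <- scores[ord[1], "n_matched"] == scores[ord, "n_matched"] &
      scores[ord[1], "frac_intensity"] == scores[ord, "frac_intensity"] &
      abs(ids$ppm_error[sel[ord[1]]]) == abs(ids$ppm_error[sel[ord]])
    if (sum(tie) == 1L) {
      ids$status[sel] <- "rejected"
      ids$status[sel[best]] <- "resolved"
    }
  }
  ids
}
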
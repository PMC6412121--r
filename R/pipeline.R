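## End-to-end pipeline: quantification driver over simulated or fixture
## runs, condition reports, and a configuration-driven entry point.

xic_for <- function(peaks, mz, tol_ppm) {
  extract_xic(peaks, mz, tol_ppm = tol_ppm)
}

## Pick the chromatographic peak of `species_row` among candidates,
## using MS2 spectra when several peaks share the XIC (isobaric
## collisions); falls back to the largest peak.
pick_peak_ms2 <- function(cand, species_row, run, schemes, tol_ppm = 20,
                          precursor_tol_ppm = 10, rt_tol = 0.1) {
  if (nrow(cand) <= 1L) return(cand)
  scores <- rep(NA_real_, nrow(cand))
  if (length(run$ms2)) {
    lad <- ms2_ladders(species_row$sequence, species_row$five_prime_end,
                       species_row$three_prime_end,
                       mods = parse_variant(species_row$variant),
                       start = species_row$start,
                       channel = species_row$channel,
                       scheme = schemes[[species_row$enzyme]],
                       max_charge = 2L)
    for (i in seq_len(nrow(cand))) {
      best <- 0
      for (s in run$ms2) {
        if (abs(s$precursor_mz - species_row$mz) / species_row$mz * 1e6 >
            precursor_tol_ppm) next
        if (abs(s$rt - cand$rt_apex[i]) > rt_tol) next
        sc <- score_ms2(s$peaks, lad, tol_ppm = tol_ppm)
        best <- max(best, sc[["n_matched"]] + sc[["frac_intensity"]])
      }
      scores[i] <- best
    }
  }
  if (all(is.na(scores)) || all(scores == 0)) {
    return(cand[which.max(cand$area), , drop = FALSE])
  }
  cand[which.max(scores), , drop = FALSE]
}

peak_near <- function(cand, rt, tol = 0.3) {
  if (!nrow(cand)) return(NULL)
  d <- abs(cand$rt_apex - rt)
  if (min(d) > tol) return(NULL)
  cand[which.min(d), , drop = FALSE]
}

zero_signal <- data.frame(rt_apex = NA_real_, apex = 0, area = 0,
                          rt_start = NA_real_, rt_end = NA_real_)

#' Quantify every site of a scenario from simulated or fixture runs
#'
#' For each run, the per-run mixing correction factor is estimated from
#' the unmodified correction pairs; each site cluster is then read out:
#' the heavy (internal standard) species anchors the retention time,
#' the unmodified light species is the co-eluting peak at its m/z,
#' mass-shifted modified species are located at their own m/z (with MS2
#' disambiguation of isobaric collisions), and mass-silent species are
#' the RT-shifted peaks at the unmodified m/z.  Both estimators are
#' computed where they apply: the intensity-ratio estimate for
#' single-site clusters and the peak-area fraction for every site
#' (composite clusters sum their isomeric species per side).
#'
#' @param sim A `sim_result` from [simulate_lcms] or [read_fixtures].
#' @param tol_ppm XIC extraction / MS1 tolerance in ppm.
#' @param co_elution_tol Maximum |RT difference| (min) for pairing light
#'   and heavy peaks of one species.
#' @return data.frame of per-replicate estimates: `site`, `condition`,
#'   `replicate`, `method`, `f_mod`, `clamped`, `k`.
#' @export
quantify_runs <- function(sim, tol_ppm = 5, co_elution_tol = 0.3) {
  species <- sim$species
  schemes <- sim$scenario$schemes
  out <- list()
  for (run in sim$runs) {
    sp <- species[species$run_group == run$run_group &
                    species$enzyme == run$enzyme, , drop = FALSE]
    ## mixing correction factor from the unmodified pairs
    pair_keys <- unique(sp$cluster[sp$role == "pair"])
    ratios <- vapply(pair_keys, function(kk) {
      l <- sp[sp$cluster == kk & sp$channel == "light", , drop = FALSE]
      h <- sp[sp$cluster == kk & sp$channel == "heavy", , drop = FALSE]
      lc <- find_chrom_peaks(xic_for(run$peaks, l$mz[1], tol_ppm))
      hc <- find_chrom_peaks(xic_for(run$peaks, h$mz[1], tol_ppm))
      if (!nrow(lc) || !nrow(hc)) return(NA_real_)
      lc$apex[which.max(lc$area)] / hc$apex[which.max(hc$area)]
    }, 0)
    ratios <- ratios[!is.na(ratios)]
    k <- correction_factor(ratios, rep(1, length(ratios)),
                           min_pairs = min(5L, length(ratios)))
    for (ckey in unique(sp$cluster[sp$role == "site"])) {
      cl <- sp[sp$cluster == ckey, , drop = FALSE]
      all_sites <- strsplit(cl$all_sites[1], ";", fixed = TRUE)[[1]]
      heavy <- cl[cl$channel == "heavy", , drop = FALSE]
      lights <- cl[cl$channel == "light", , drop = FALSE]
      ## anchor RT from the heavy reference
      hc <- find_chrom_peaks(xic_for(run$peaks, heavy$mz[1], tol_ppm))
      hpk <- pick_peak_ms2(hc, heavy[1, , drop = FALSE], run, schemes)
      if (is.null(hpk) || !nrow(hpk)) next
      anchor <- hpk$rt_apex[1]
      ## measure each light species
      meas <- vector("list", nrow(lights))
      unmod_i <- which(lights$variant == "unmodified")
      ## species sharing one m/z must divide the XIC's peaks among them
      mz_grp <- match(round(lights$mz, 4), unique(round(lights$mz, 4)))
      claimed <- list()
      for (i in order(lights$variant != "unmodified",
                      lights$mass_silent_variant)) {
        li <- lights[i, , drop = FALSE]
        cand <- find_chrom_peaks(xic_for(run$peaks, li$mz, tol_ppm))
        ## drop peaks already claimed by co-m/z species of this cluster
        for (cl_rt in claimed[[as.character(mz_grp[i])]]) {
          cand <- cand[abs(cand$rt_apex - cl_rt) > 1e-9, , drop = FALSE]
        }
        pk <- NULL
        if (li$variant == "unmodified") {
          pk <- peak_near(cand, anchor, co_elution_tol)
        } else if (li$mass_silent_variant) {
          ## mass-silent: RT-shifted peak at the unmodified m/z; the
          ## modified species elutes apart from the heavy anchor
          cand2 <- cand[is.na(anchor) |
                          abs(cand$rt_apex - anchor) > co_elution_tol, ,
                        drop = FALSE]
          if (nrow(cand2)) pk <- cand2[which.max(cand2$area), , drop = FALSE]
        } else {
          pk <- pick_peak_ms2(cand, li, run, schemes)
          ## guard against claiming an unrelated collision peak when the
          ## species is actually absent: require MS2 support or a unique peak
          if (!is.null(pk) && nrow(cand) > 1L && !length(run$ms2)) pk <- NULL
        }
        if (is.null(pk) || !nrow(pk)) pk <- zero_signal
        meas[[i]] <- pk
        key <- as.character(mz_grp[i])
        if (!is.na(pk$rt_apex[1])) {
          claimed[[key]] <- c(claimed[[key]], pk$rt_apex[1])
        }
      }
      apex <- vapply(meas, function(m) m$apex[1], 0)
      area <- vapply(meas, function(m) m$area[1], 0)
      has_site <- function(i, s) {
        s %in% strsplit(lights$sites_contained[i], ";", fixed = TRUE)[[1]]
      }
      for (s in all_sites) {
        sel_mod <- vapply(seq_len(nrow(lights)), has_site, TRUE, s = s)
        est_pa <- peak_area_estimate(area[sel_mod], area[!sel_mod],
                                     site = s, replicate = run$replicate)
        out[[length(out) + 1L]] <- data.frame(
          site = s, condition = run$condition, replicate = run$replicate,
          method = "peak_area", f_mod = est_pa$f_mod,
          clamped = est_pa$clamped, k = k$k, stringsAsFactors = FALSE)
        if (length(all_sites) == 1L && length(unmod_i) == 1L) {
          lm <- if (any(sel_mod)) sum(apex[sel_mod]) else NA_real_
          est_si <- silnas_estimate(apex[unmod_i], hpk$apex[1], k,
                                    light_mod = lm, site = s,
                                    replicate = run$replicate)
          out[[length(out) + 1L]] <- data.frame(
            site = s, condition = run$condition, replicate = run$replicate,
            method = "silnas", f_mod = est_si$f_mod,
            clamped = est_si$clamped, k = k$k, stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Site report across conditions
#'
#' Aggregates per-replicate estimates (mean, SEM, n per condition),
#' compares each condition with the reference, and annotates each site
#' with its designated quantification method and guide RNA if provided.
#'
#' @param estimates Output of [quantify_runs].
#' @param scenario The `sim_scenario` (for site metadata and reference
#'   condition).
#' @param method_filter Keep only each site's designated method
#'   (`TRUE`, default) or report all computed methods.
#' @return A `site_report` data.frame.
#' @export
site_report <- function(estimates, scenario, method_filter = TRUE) {
  sites <- scenario$sites
  if (method_filter) {
    keep <- vapply(seq_len(nrow(estimates)), function(i) {
      m <- sites$method[match(estimates$site[i], sites$site)]
      is.na(m) || estimates$method[i] == m
    }, TRUE)
    estimates <- estimates[keep, , drop = FALSE]
  }
  rep <- aggregate_and_compare(estimates, scenario$reference_condition)
  rep$method <- sites$method[match(rep$site, sites$site)]
  if ("guide" %in% names(sites)) {
    rep$guide <- sites$guide[match(rep$site, sites$site)]
  }
  ord <- order(match(rep$site, sites$site), rep$condition)
  rep <- rep[ord, , drop = FALSE]
  rownames(rep) <- NULL
  class(rep) <- c("site_report", "data.frame")
  rep
}

provenance_header <- function(config_path = NULL, seed = NA) {
  c(sprintf("# modstoich %s",
            as.character(utils::packageVersion("modstoich"))),
    sprintf("# config_md5=%s",
            if (!is.null(config_path) && file.exists(config_path))
              unname(tools::md5sum(config_path)) else "none"),
    sprintf("# seed=%s", seed))
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run a pipeline stage from a configuration file
#'
#' Stages: `"digest"` (fragment tables per enzyme), `"simulate"`
#' (synthetic runs written as fixtures), `"identify"` (MS1 matching of
#' every peak list against the theoretical search space), `"quantify"`
#' (per-replicate stoichiometry estimates) and `"report"` (per-site,
#' per-condition summary with comparisons).  All outputs carry a
#' provenance header (package version, config checksum, seed).
#'
#' @param config Path to a YAML configuration file, or an equivalent
#'   named list.  Recognized keys: `fasta`, `sites`, `enzymes`,
#'   `max_missed`, `tol_ppm`, `conditions`, `reference_condition`,
#'   `rnase_h`, `replicates`, `mixing`, `seed`, `outdir`.
#' @param command One of `digest`, `simulate`, `identify`, `quantify`,
#'   `report`.
#' @return Invisibly, the path(s) of the artifacts written.
#' @export
run_pipeline <- function(config,
                         command = c("digest", "simulate", "identify",
                                     "quantify", "report")) {
  command <- match.arg(command)
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    if (!file.exists(config)) stop("no such config file: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  outdir <- config$outdir %||% "."
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  seed <- config$seed %||% 101L
  header <- provenance_header(config_path, seed)
  scenario_from_config <- function() {
    if (is.null(config$fasta)) return(default_scenario(seed = seed))
    molecules <- read_fasta(config$fasta)
    sites <- utils::read.delim(config$sites, stringsAsFactors = FALSE,
                               comment.char = "#")
    simulation_scenario(
      molecules, sites,
      conditions = config$conditions %||% c("control", "knockdown"),
      reference_condition = config$reference_condition %||% "control",
      rnase_h = lapply(config$rnase_h %||% list(), unlist),
      replicates = config$replicates %||% 3L,
      mixing = config$mixing %||% 1.0,
      seed = seed)
  }
  paths <- character()
  if (command == "digest") {
    molecules <- read_fasta(config$fasta)
    profile <- if (!is.null(config$sites)) {
      tab <- utils::read.delim(config$sites, stringsAsFactors = FALSE,
                               comment.char = "#")
      modification_profile(tab$molecule_id, tab$position, tab$mod_type,
                           molecules = molecules)
    } else NULL
    for (enzyme in (config$enzymes %||% c("RNaseT1", "RNaseA"))) {
      frs <- lapply(molecules, digest, rule = cleavage_rule(enzyme),
                    max_missed = config$max_missed %||% 1L,
                    profile = profile)
      fr <- do.call(rbind, lapply(frs, as.data.frame))
      fr$annotated <- vapply(seq_len(nrow(fr)), function(i) {
        annotate_sequence(fr$sequence[i], fr$mods[[i]], fr$start[i])
      }, "")
      fr$mods <- NULL
      p <- file.path(outdir, paste0("fragments_", enzyme, ".tsv"))
      write_tsv_with_header(fr, p, header)
      message(sprintf("[digest] %s: %d fragments -> %s", enzyme, nrow(fr), p))
      paths <- c(paths, p)
    }
  } else if (command == "simulate") {
    sim <- simulate_lcms(scenario_from_config(), seed = seed)
    write_fixtures(sim, outdir)
    message(sprintf("[simulate] %d runs, %d species -> %s",
                    length(sim$runs), nrow(sim$species), outdir))
    paths <- outdir
  } else if (command == "identify") {
    sim <- read_fixtures(config$fixtures %||% outdir)
    sc <- sim$scenario
    profile <- scenario_mods_profile(sc$sites)
    ids_all <- list()
    for (nm in names(sim$runs)) {
      run <- sim$runs[[nm]]
      dg <- digestion_molecules(sc, run$run_group, run$enzyme,
                                profile = profile)
      space <- build_search_space(dg$mols, enzymes = run$enzyme,
                                  profile = dg$profile,
                                  max_missed = config$max_missed %||% 1L,
                                  window = sc$window, schemes = sc$schemes)
      ## one representative peak per chromatographic species: apex rows
      ids <- match_ms1(run$peaks, space, tol_ppm = config$tol_ppm %||% 5)
      ids <- resolve_identifications(ids, run$ms2, space)
      if (nrow(ids)) ids$run <- nm
      ids_all[[nm]] <- ids
    }
    ids <- do.call(rbind, ids_all)
    p <- file.path(outdir, "identifications.tsv")
    write_tsv_with_header(ids, p, header)
    message(sprintf("[identify] %d peak matches -> %s", nrow(ids), p))
    paths <- p
  } else if (command == "quantify") {
    sim <- read_fixtures(config$fixtures %||% outdir)
    est <- quantify_runs(sim, tol_ppm = config$tol_ppm %||% 5)
    p <- file.path(outdir, "estimates.tsv")
    write_tsv_with_header(est, p, header)
    message(sprintf("[quantify] %d estimates (%d sites) -> %s",
                    nrow(est), length(unique(est$site)), p))
    paths <- p
  } else if (command == "report") {
    sim <- read_fixtures(config$fixtures %||% outdir)
    est_path <- file.path(config$fixtures %||% outdir, "estimates.tsv")
    est <- if (file.exists(est_path)) {
      utils::read.delim(est_path, stringsAsFactors = FALSE,
                        comment.char = "#")
    } else {
      quantify_runs(sim, tol_ppm = config$tol_ppm %||% 5)
    }
    rep <- site_report(est, sim$scenario)
    p <- file.path(outdir, "site_report.tsv")
    write_tsv_with_header(as.data.frame(rep), p, header)
    message(sprintf("[report] %d site x condition rows -> %s", nrow(rep), p))
    paths <- p
  }
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
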
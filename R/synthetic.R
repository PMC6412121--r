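## Synthetic LC-MS data generator.
##
## Emulates the paired-channel design: cellular (light, partially
## modified) RNA mixed ~1:1 with a 13C-labeled, fully unmodified
## in-vitro transcript (heavy), digested per enzyme and measured as MS1
## peak lists over retention time.  Intensity noise is lognormal
## (multiplicative), mass error Gaussian on the ppm scale, RT jitter
## Gaussian — the standard LC-MS error structure.  Methylated and
## pseudouridylated species elute later than their unmodified
## counterparts; heavy species co-elute with their light counterparts.

#' Construct a simulation scenario
#'
#' @param molecules Named list of [rna_molecule].
#' @param sites data.frame with columns `site`, `molecule_id`,
#'   `position`, `mod_type`, `enzyme`, `method`, optionally `guide`,
#'   optionally `bio_sd` (between-replicate biological SD of the true
#'   stoichiometry, on the fraction scale; 0 if absent), and one numeric
#'   truth column per condition (values in `[0, 1]`).
#' @param conditions Names of the truth columns in `sites`.
#' @param reference_condition Reference (control) condition.
#' @param rnase_h Named list: enzyme -> named integer vector of guided
#'   RNase H cut positions per molecule (`cut_before` semantics), applied
#'   before that enzyme's digestion.
#' @param replicates Replicates per condition.
#' @param mixing True light:heavy mixing factor (nominal 1.0).
#' @param n_correction_pairs Unmodified fragment pairs emitted per run
#'   for the mixing correction factor.
#' @param base_intensity Heavy-channel base signal.
#' @param noise List: `intensity_cv` (lognormal CV of species signals;
#'   shared within a fragment's species, because light and heavy
#'   channels of one fragment are chemically identical co-digested
#'   isotopologues and preparation/ionization variability hits them
#'   together), `measurement_cv` (per-species residual lognormal CV),
#'   `mass_ppm_sd` (per-scan centroid jitter), `rt_jitter_sd` (min).
#' @param rt List: `start`, `spacing` (min between fragments), `sigma`
#'   (chromatographic peak width, min), `dt` (scan interval, min),
#'   `methyl_shift`, `psi_shift`, `isomer_step` (extra shift separating
#'   positional isomers).
#' @param window Instrument m/z window.
#' @param schemes Per-enzyme label schemes for the heavy channel.
#' @param seed Default RNG seed, recorded in every output.
#' @return A list of class `sim_scenario`.
#' @export
simulation_scenario <- function(molecules, sites,
                                conditions,
                                reference_condition = conditions[1],
                                rnase_h = list(),
                                replicates = 3L,
                                mixing = 1.0,
                                n_correction_pairs = 10L,
                                base_intensity = 1e6,
                                noise = list(intensity_cv = 0.05,
                                             measurement_cv = 0.01,
                                             mass_ppm_sd = 2,
                                             rt_jitter_sd = 0.02),
                                rt = list(start = 8, spacing = 2.4,
                                          sigma = 0.05, dt = 0.02,
                                          methyl_shift = 0.5,
                                          psi_shift = 0.5,
                                          isomer_step = 0.6),
                                window = c(480, 1980),
                                schemes = list(RNaseT1 = label_scheme("T1"),
                                               RNaseA = label_scheme("A")),
                                seed = 101L) {
  stopifnot(all(conditions %in% names(sites)))
  stopifnot(all(c("site", "molecule_id", "position", "mod_type",
                  "enzyme", "method") %in% names(sites)))
  for (cond in conditions) {
    stopifnot(all(sites[[cond]] >= 0 & sites[[cond]] <= 1))
  }
  if (is.null(noise$measurement_cv)) noise$measurement_cv <- 0.01
  stopifnot(noise$intensity_cv >= 0, noise$measurement_cv >= 0,
            noise$mass_ppm_sd >= 0, noise$rt_jitter_sd >= 0, mixing > 0)
  ## validate sites against molecules
  modification_profile(sites$molecule_id, sites$position, sites$mod_type,
                       molecules = molecules)
  structure(
    list(molecules = molecules, sites = sites, conditions = conditions,
         reference_condition = reference_condition, rnase_h = rnase_h,
         replicates = as.integer(replicates), mixing = mixing,
         n_correction_pairs = as.integer(n_correction_pairs),
         base_intensity = base_intensity, noise = noise, rt = rt,
         window = window, schemes = schemes, seed = as.integer(seed)),
    class = "sim_scenario"
  )
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "<sim_scenario> %d molecule(s), %d site(s), conditions: %s; %d replicates, mixing %.2f, seed %d\n",
    length(x$molecules), nrow(x$sites), paste(x$conditions, collapse = "/"),
    x$replicates, x$mixing, x$seed))
  invisible(x)
}

scenario_mods_profile <- function(sites) {
  modification_profile(sites$molecule_id, sites$position, sites$mod_type)
}

## Digestion molecules for one parent molecule under one enzyme,
## applying any configured RNase H split; returns list(mols, profile).
digestion_molecules <- function(scenario, parent_id, enzyme,
                                profile = scenario_mods_profile(scenario$sites)) {
  mol <- scenario$molecules[[parent_id]]
  cuts <- scenario$rnase_h[[enzyme]]
  if (!is.null(cuts) && parent_id %in% names(cuts)) {
    sp <- rnase_h_split(mol, cuts[[parent_id]], profile = profile)
    list(mols = list(sp$upstream, sp$downstream),
         profile = if (is.null(sp$profile)) profile else sp$profile)
  } else {
    list(mols = list(mol), profile = profile)
  }
}

subset_label <- function(sites_sub) {
  if (!nrow(sites_sub)) return("unmodified")
  variant_label(data.frame(position = sites_sub$position,
                           mod_type = sites_sub$mod_type))
}

first_observable <- function(mass, window) {
  z <- observable_charges(mass, window)
  if (!length(z)) NA_integer_ else z[1]
}

## Enumerate every species the scenario emits (no intensities):
## site-cluster variants (light) and unmodified references (heavy),
## correction-pair fragments, and unmodified fragments whose m/z
## collides with a site species (kept as background so realistic isobaric
## interference is present in the data).
#' Theoretical species table of a scenario
#'
#' @param scenario A `sim_scenario`.
#' @return data.frame with one row per emitted species (per run group,
#'   enzyme, cluster/fragment, variant, channel), including theoretical
#'   `mz`, charge `z` and RT model fields.
#' @export
scenario_species <- function(scenario) {
  sites <- scenario$sites
  rows <- list()
  emit <- function(...) rows[[length(rows) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  for (parent_id in names(scenario$molecules)) {
    for (enzyme in unique(sites$enzyme)) {
      rule <- cleavage_rule(enzyme)
      scheme <- scenario$schemes[[enzyme]]
      dg <- digestion_molecules(scenario, parent_id, enzyme)
      psites <- sites[sites$molecule_id == parent_id &
                        sites$enzyme == enzyme, , drop = FALSE]
      ## map parent site positions onto digestion molecules
      site_map <- NULL
      if (nrow(psites)) {
        site_map <- do.call(rbind, lapply(seq_len(nrow(psites)), function(i) {
          ## the (possibly split) digestion molecules partition the parent
          ## coordinates; locate the piece covering this site
          for (m in dg$mols) {
            off <- attr(m, "source_offset"); if (is.null(off)) off <- 0L
            pos <- psites$position[i] - off
            if (pos >= 1L && pos <= nchar(m$sequence)) {
              return(data.frame(site = psites$site[i],
                                digest_id = m$id, position = pos,
                                mod_type = psites$mod_type[i],
                                stringsAsFactors = FALSE))
            }
          }
          stop("site ", psites$site[i], " not locatable after splitting")
        }))
      }
      ## clusters: fragments of the fully modified digest containing sites
      clusters <- list()
      for (m in dg$mols) {
        full_prof <- dg$profile
        frag_full <- digest(m, rule, 0L, profile = full_prof)
        if (is.null(site_map)) next
        sm <- site_map[site_map$digest_id == m$id, , drop = FALSE]
        if (!nrow(sm)) next
        for (i in seq_len(nrow(frag_full))) {
          inside <- sm[sm$position >= frag_full$start[i] &
                         sm$position <= frag_full$end[i], , drop = FALSE]
          if (nrow(inside)) {
            clusters[[length(clusters) + 1L]] <- list(mol = m, sites = inside)
          }
        }
      }
      ## species for each cluster subset
      for (ci in seq_along(clusters)) {
        cl <- clusters[[ci]]
        m <- cl$mol
        s <- cl$sites[order(cl$sites$position), , drop = FALSE]
        ckey <- sprintf("%s|%s|cluster:%s", m$id, enzyme,
                        paste(s$site, collapse = "+"))
        nsub <- nrow(s)
        for (mask in 0:(2^nsub - 1)) {
          inT <- as.logical(bitwAnd(mask, 2^(seq_len(nsub) - 1L)))
          sub <- s[inT, , drop = FALSE]
          prof <- if (nrow(sub)) {
            modification_profile(rep(m$id, nrow(sub)), sub$position,
                                 sub$mod_type)
          } else NULL
          fr <- digest(m, rule, 0L, profile = prof)
          hit <- fr[fr$start <= min(s$position) & fr$end >= min(s$position), ,
                    drop = FALSE][1, , drop = FALSE]
          mods <- if (nrow(sub)) data.frame(position = sub$position,
                                            mod_type = sub$mod_type,
                                            stringsAsFactors = FALSE) else NULL
          reg <- modification_types()
          silent <- if (nrow(sub))
            all(reg$mass_silent[match(sub$mod_type, reg$name)]) else FALSE
          shift <- 0
          if (nrow(sub)) {
            for (i in seq_len(nrow(sub))) {
              base_shift <- if (reg$mass_silent[match(sub$mod_type[i], reg$name)])
                scenario$rt$psi_shift else scenario$rt$methyl_shift
              shift <- shift + base_shift +
                scenario$rt$isomer_step * (match(sub$site[i], s$site) - 1L)
            }
          }
          channels <- if (nrow(sub)) "light" else c("light", "heavy")
          for (ch in channels) {
            sp <- species_mz(hit, mods = mods, channel = ch, scheme = scheme,
                             window = scenario$window)
            if (!length(sp$charges)) next
            emit(run_group = parent_id, enzyme = enzyme, role = "site",
                 cluster = ckey, digest_id = m$id,
                 start = hit$start, end = hit$end, sequence = hit$sequence,
                 five_prime_end = hit$five_prime_end,
                 three_prime_end = hit$three_prime_end,
                 variant = subset_label(sub),
                 annotated = annotate_sequence(hit$sequence, mods, hit$start),
                 sites_contained = paste(sub$site, collapse = ";"),
                 all_sites = paste(s$site, collapse = ";"),
                 channel = ch, z = sp$charges[1], mz = sp$mz[1],
                 mass = sp$mass, mass_silent_variant = silent,
                 rt_shift = shift)
          }
        }
      }
      ## correction-pair candidates: site-free fragments of the full digest
      cand <- list()
      for (m in dg$mols) {
        fr <- digest(m, rule, 0L, profile = dg$profile)
        has_site <- vapply(fr$mods, nrow, 0L) > 0L
        fr <- fr[!has_site & nchar(fr$sequence) >= 2L, , drop = FALSE]
        for (i in seq_len(nrow(fr))) cand[[length(cand) + 1L]] <- fr[i, ,
                                                                     drop = FALSE]
      }
      site_mz <- if (length(rows)) {
        sub <- do.call(rbind, rows)
        sub$mz[sub$run_group == parent_id & sub$enzyme == enzyme]
      } else numeric()
      taken <- 0L
      seen_seq <- character()
      for (fr in cand) {
        key <- paste(fr$sequence, fr$five_prime_end, fr$three_prime_end)
        if (key %in% seen_seq) next
        seen_seq <- c(seen_seq, key)
        spl <- species_mz(fr, mods = NULL, channel = "light",
                          window = scenario$window)
        sph <- species_mz(fr, mods = NULL, channel = "heavy", scheme = scheme,
                          window = scenario$window)
        if (!length(spl$charges) || !length(sph$charges)) next
        mzl <- spl$mz[1]; mzh <- sph$mz[1]
        near_site <- function(mz) any(abs(mz - site_mz) / mz * 1e6 <= 25)
        collides <- near_site(mzl) || near_site(mzh)
        role <- if (collides) "background" else
          if (taken < scenario$n_correction_pairs) "pair" else NA
        if (is.na(role)) next
        if (role == "pair") taken <- taken + 1L
        fkey <- sprintf("%s|%s|frag:%d-%d", fr$molecule_id, enzyme,
                        fr$start, fr$end)
        emit(run_group = parent_id, enzyme = enzyme, role = role,
             cluster = fkey, digest_id = fr$molecule_id,
             start = fr$start, end = fr$end, sequence = fr$sequence,
             five_prime_end = fr$five_prime_end,
             three_prime_end = fr$three_prime_end,
             variant = "unmodified", annotated = fr$sequence,
             sites_contained = "", all_sites = "",
             channel = c("light", "heavy"),
             z = c(spl$charges[1], sph$charges[1]),
             mz = c(mzl, mzh), mass = c(spl$mass, sph$mass),
             mass_silent_variant = FALSE, rt_shift = 0)
      }
    }
  }
  sp <- do.call(rbind, rows)
  ## deterministic RT base per cluster/fragment within each run group
  sp$rt_base <- NA_real_
  for (g in unique(paste(sp$run_group, sp$enzyme))) {
    sel <- paste(sp$run_group, sp$enzyme) == g
    keys <- unique(sp$cluster[sel][order(sp$digest_id[sel], sp$start[sel],
                                         sp$end[sel])])
    rt0 <- scenario$rt$start
    spacing <- round(scenario$rt$spacing / scenario$rt$dt) * scenario$rt$dt
    sp$rt_base[sel] <- rt0 + (match(sp$cluster[sel], keys) - 1L) * spacing
  }
  sp$rt_apex_nominal <- sp$rt_base + sp$rt_shift
  rownames(sp) <- NULL
  sp
}

## weight of a light variant under one condition's truths
variant_weight <- function(sites_contained, all_sites, sites, cond) {
  all_s <- strsplit(all_sites, ";", fixed = TRUE)[[1]]
  in_s <- strsplit(sites_contained, ";", fixed = TRUE)[[1]]
  if (!length(all_s)) return(1)
  f <- sites[[cond]][match(all_s, sites$site)]
  w <- ifelse(all_s %in% in_s, f, 1 - f)
  prod(w)
}

#' Simulate paired light/heavy LC-MS runs for a scenario
#'
#' One run is generated per (parent molecule, enzyme, condition,
#' replicate): an MS1 peak list over retention time, and MS2 spectra for
#' every species whose m/z collides with another species of the run
#' (isobaric groups, which are what MS2 is needed for).  A ground-truth
#' ledger records each species' theoretical m/z, nominal and realized
#' retention time, and noiseless and realized signals — sufficient to
#' recompute every expected estimate.
#'
#' @param scenario A `sim_scenario`.
#' @param seed RNG seed; defaults to the scenario's.
#' @return A list of class `sim_result`: `runs` (named list with
#'   `condition`, `replicate`, `run_group`, `enzyme`, `peaks`, `ms2`),
#'   `species` (theoretical table), `ledger`, `scenario`, `seed`.
#' @export
simulate_lcms <- function(scenario, seed = scenario$seed) {
  set.seed(seed)
  species <- scenario_species(scenario)
  bio_sd <- if (is.null(scenario$sites$bio_sd)) rep(0, nrow(scenario$sites))
    else scenario$sites$bio_sd
  cv_ln <- function(cv) sqrt(log(1 + cv^2))
  sigma_shared <- cv_ln(scenario$noise$intensity_cv)
  meas_cv <- scenario$noise$measurement_cv
  if (is.null(meas_cv)) meas_cv <- 0.01
  sigma_meas <- cv_ln(meas_cv)
  runs <- list()
  ledger <- list()
  truth_rows <- list()
  grid_dt <- scenario$rt$dt
  for (cond in scenario$conditions) {
    for (rep_i in seq_len(scenario$replicates)) {
      ## biological replicate: the true stoichiometry itself varies
      ## between replicates on the fraction scale
      sites_r <- scenario$sites
      jit <- stats::rnorm(nrow(sites_r), 0, bio_sd)
      sites_r[[cond]] <- pmin(1, pmax(0, sites_r[[cond]] + jit))
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        condition = cond, replicate = rep_i, site = sites_r$site,
        f_nominal = scenario$sites[[cond]], f_realized = sites_r[[cond]],
        stringsAsFactors = FALSE)
      for (g in unique(paste(species$run_group, species$enzyme, sep = "|"))) {
        parts <- strsplit(g, "|", fixed = TRUE)[[1]]
        sel <- species$run_group == parts[1] & species$enzyme == parts[2]
        sp <- species[sel, , drop = FALSE]
        n <- nrow(sp)
        ## true (noiseless) signals
        w <- vapply(seq_len(n), function(i) {
          if (sp$channel[i] == "heavy") return(1)
          scenario$mixing * variant_weight(sp$sites_contained[i],
                                           sp$all_sites[i],
                                           sites_r, cond)
        }, 0)
        signal_true <- scenario$base_intensity * w
        ## shared per-fragment factor (prep/ionization; cancels in the
        ## light/heavy ratio) plus per-species measurement residual
        cl_keys <- unique(sp$cluster)
        shared <- exp(stats::rnorm(length(cl_keys), 0, sigma_shared))
        signal <- signal_true * shared[match(sp$cluster, cl_keys)] *
          exp(stats::rnorm(n, 0, sigma_meas))
        signal[signal_true == 0] <- 0
        ## mass error is per-scan centroid jitter (ppm scale)
        mz_obs <- sp$mz * (1 + stats::rnorm(n, 0, scenario$noise$mass_ppm_sd) * 1e-6)
        rt_obs <- sp$rt_apex_nominal +
          stats::rnorm(n, 0, scenario$noise$rt_jitter_sd)
        ## chromatographic sampling on the global scan grid
        peak_rows <- list()
        for (i in seq_len(n)) {
          if (signal[i] <= 0) next
          t0 <- floor((rt_obs[i] - 3.5 * scenario$rt$sigma) / grid_dt) * grid_dt
          t1 <- ceiling((rt_obs[i] + 3.5 * scenario$rt$sigma) / grid_dt) * grid_dt
          tt <- seq(t0, t1, by = grid_dt)
          keep <- abs(tt - rt_obs[i]) <= 3.5 * scenario$rt$sigma
          tt <- tt[keep]
          inten <- signal[i] * exp(-(tt - rt_obs[i])^2 / (2 * scenario$rt$sigma^2))
          mz_scan <- sp$mz[i] *
            (1 + stats::rnorm(length(tt), 0, scenario$noise$mass_ppm_sd) * 1e-6)
          peak_rows[[length(peak_rows) + 1L]] <- data.frame(
            mz = mz_scan, rt = tt, intensity = inten)
        }
        peaks <- if (length(peak_rows)) do.call(rbind, peak_rows) else
          data.frame(mz = numeric(), rt = numeric(), intensity = numeric())
        peaks <- peaks[order(peaks$rt, peaks$mz), , drop = FALSE]
        rownames(peaks) <- NULL
        ## MS2 for isobaric groups within the run
        ms2 <- list()
        for (i in seq_len(n)) {
          if (signal[i] <= 0) next
          others <- setdiff(seq_len(n), i)
          shared <- any(abs(sp$mz[others] - sp$mz[i]) / sp$mz[i] * 1e6 <= 10 &
                          signal[others] > 0)
          if (!shared) next
          lad <- ms2_ladders(sp$sequence[i], sp$five_prime_end[i],
                             sp$three_prime_end[i],
                             mods = parse_variant(sp$variant[i]),
                             start = sp$start[i], channel = sp$channel[i],
                             scheme = scenario$schemes[[sp$enzyme[i]]],
                             max_charge = 2L)
          ms2[[length(ms2) + 1L]] <- list(
            precursor_mz = mz_obs[i], rt = rt_obs[i],
            peaks = data.frame(mz = lad$mz, intensity = 100))
        }
        run_name <- sprintf("%s_rep%d_%s_%s", cond, rep_i, parts[1], parts[2])
        runs[[run_name]] <- list(condition = cond, replicate = rep_i,
                                 run_group = parts[1], enzyme = parts[2],
                                 peaks = peaks, ms2 = ms2)
        ledger[[length(ledger) + 1L]] <- data.frame(
          run = run_name, condition = cond, replicate = rep_i,
          run_group = parts[1], enzyme = parts[2],
          role = sp$role, cluster = sp$cluster, variant = sp$variant,
          annotated = sp$annotated, channel = sp$channel,
          sites_contained = sp$sites_contained,
          mz_theoretical = sp$mz, mz_observed = mz_obs,
          rt_nominal = sp$rt_apex_nominal, rt_observed = rt_obs,
          signal_true = signal_true, signal_observed = signal,
          seed = seed, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(runs = runs, species = species,
                 ledger = do.call(rbind, ledger),
                 truths = do.call(rbind, truth_rows),
                 scenario = scenario, seed = seed),
            class = "sim_result")
}

parse_variant <- function(variant) {
  if (identical(variant, "unmodified")) return(NULL)
  parts <- strsplit(strsplit(variant, ";", fixed = TRUE)[[1]], ":",
                    fixed = TRUE)
  data.frame(position = as.integer(vapply(parts, `[`, "", 1)),
             mod_type = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Write simulated outputs as plain-text fixtures
#'
#' Writes one MS1 peak-list TSV and one MS2 TSV per run, the
#' ground-truth ledger, and the scenario (molecules as FASTA, sites as
#' TSV, parameters as YAML).  Everything round-trips through
#' [read_fixtures].
#'
#' @param sim A `sim_result` from [simulate_lcms].
#' @param directory Output directory (must exist).
#' @return The directory, invisibly.
#' @export
write_fixtures <- function(sim, directory) {
  if (!dir.exists(directory)) stop("no such directory: ", directory,
                                   call. = FALSE)
  for (nm in names(sim$runs)) {
    run <- sim$runs[[nm]]
    utils::write.table(run$peaks, file.path(directory,
                                            paste0("peaks_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ms2 <- do.call(rbind, lapply(seq_along(run$ms2), function(i) {
      s <- run$ms2[[i]]
      data.frame(spectrum = i, precursor_mz = s$precursor_mz, rt = s$rt,
                 mz = s$peaks$mz, intensity = s$peaks$intensity)
    }))
    if (is.null(ms2)) ms2 <- data.frame(spectrum = integer(),
                                        precursor_mz = numeric(),
                                        rt = numeric(), mz = numeric(),
                                        intensity = numeric())
    utils::write.table(ms2, file.path(directory, paste0("ms2_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(sim$ledger, file.path(directory, "ledger.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truths, file.path(directory, "truths.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sc <- sim$scenario
  fasta <- file.path(directory, "molecules.fasta")
  writeLines(unlist(lapply(sc$molecules, function(m) {
    c(sprintf(">%s five_prime=%s three_prime=%s", m$id, m$five_prime_end,
              m$three_prime_end),
      m$sequence)
  })), fasta)
  utils::write.table(sc$sites, file.path(directory, "sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(
    conditions = sc$conditions, reference_condition = sc$reference_condition,
    rnase_h = lapply(sc$rnase_h, as.list),
    replicates = sc$replicates, mixing = sc$mixing,
    n_correction_pairs = sc$n_correction_pairs,
    base_intensity = sc$base_intensity, noise = sc$noise, rt = sc$rt,
    window = sc$window,
    schemes = lapply(sc$schemes, function(s) as.list(unclass(s))),
    seed = sim$seed
  ), file.path(directory, "scenario.yaml"))
  invisible(directory)
}

#' Read fixtures written by [write_fixtures]
#'
#' @param directory Directory containing the fixture files.
#' @return A `sim_result`-shaped list (`runs`, `species`, `ledger`,
#'   `scenario`, `seed`), reconstructed from the plain-text files.
#' @export
read_fixtures <- function(directory) {
  cfg <- yaml::read_yaml(file.path(directory, "scenario.yaml"))
  molecules <- read_fasta(file.path(directory, "molecules.fasta"))
  sites <- utils::read.delim(file.path(directory, "sites.tsv"),
                             stringsAsFactors = FALSE)
  scenario <- simulation_scenario(
    molecules, sites, conditions = cfg$conditions,
    reference_condition = cfg$reference_condition,
    rnase_h = lapply(cfg$rnase_h, unlist),
    replicates = cfg$replicates, mixing = cfg$mixing,
    n_correction_pairs = cfg$n_correction_pairs,
    base_intensity = cfg$base_intensity, noise = cfg$noise, rt = cfg$rt,
    window = unlist(cfg$window),
    schemes = lapply(cfg$schemes, function(s) label_scheme(counts = unlist(s))),
    seed = cfg$seed
  )
  files <- list.files(directory, pattern = "^peaks_.*\\.tsv$")
  runs <- list()
  for (f in files) {
    nm <- sub("^peaks_(.*)\\.tsv$", "\\1", f)
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    np <- length(parts)
    peaks <- utils::read.delim(file.path(directory, f),
                               stringsAsFactors = FALSE)
    ms2tab <- utils::read.delim(file.path(directory, paste0("ms2_", nm, ".tsv")),
                                stringsAsFactors = FALSE)
    ms2 <- lapply(split(ms2tab, ms2tab$spectrum), function(s) {
      list(precursor_mz = s$precursor_mz[1], rt = s$rt[1],
           peaks = data.frame(mz = s$mz, intensity = s$intensity))
    })
    names(ms2) <- NULL
    runs[[nm]] <- list(condition = paste(parts[1:(np - 3)], collapse = "_"),
                       replicate = as.integer(sub("rep", "", parts[np - 2])),
                       run_group = parts[np - 1], enzyme = parts[np],
                       peaks = peaks, ms2 = ms2)
  }
  ledger <- utils::read.delim(file.path(directory, "ledger.tsv"),
                              stringsAsFactors = FALSE)
  truths_path <- file.path(directory, "truths.tsv")
  truths <- if (file.exists(truths_path))
    utils::read.delim(truths_path, stringsAsFactors = FALSE) else NULL
  structure(list(runs = runs, species = scenario_species(scenario),
                 ledger = ledger, truths = truths,
                 scenario = scenario, seed = cfg$seed),
            class = "sim_result")
}

#' Default two-condition snRNA scenario
#'
#' A U1-like molecule (164 nt) and a U2-like molecule (188 nt) with the
#' bundled site set: ribose methylations at U1 70A and U2 11G, 12G, 19G,
#' 25G, 30A, 40C, 47U, 61C, pseudouridine at U2 34, and the cap-proximal
#' U2 1A methylation; control and knockdown stoichiometries follow the
#' bundled site table.  RNase T1 digestion of the U2-like molecule is
#' preceded by a guided RNase H split before residue 17, so the
#' 5'-monophosphate species of the 19G fragment appear.  Three
#' replicates per condition.
#'
#' @param seed RNG seed recorded in the scenario.
#' @param ... Overrides passed to [simulation_scenario] (e.g. `mixing`,
#'   `noise`, `replicates`).
#' @return A `sim_scenario`.
#' @export
default_scenario <- function(seed = 101L, ...) {
  fasta <- system.file("extdata", "snrna_like.fasta", package = "modstoich",
                       mustWork = TRUE)
  sites_path <- system.file("extdata", "snrna_sites.tsv",
                            package = "modstoich", mustWork = TRUE)
  molecules <- read_fasta(fasta)
  sites <- utils::read.delim(sites_path, stringsAsFactors = FALSE,
                             comment.char = "#")
  simulation_scenario(
    molecules, sites, conditions = c("control", "knockdown"),
    reference_condition = "control",
    rnase_h = list(RNaseT1 = c(U2 = 17L)),
    seed = seed, ...
  )
}
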
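# Independent oracles used to verify digestion and mass computation.
# They deliberately avoid the package's internals.

# Brute-force digestion: scan for cut positions, then enumerate every
# (start, end) whose boundaries sit on cuts/termini and whose interior
# retains at most `max_missed` cuts.
oracle_digest <- function(sequence, cut_after, blocked = integer(),
                          max_missed = 0L) {
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(bases)
  cuts <- setdiff(which(bases %in% cut_after), n)
  cuts <- sort(setdiff(cuts, blocked))
  bounds_l <- c(1L, cuts + 1L)     # legal fragment starts
  bounds_r <- c(cuts, n)           # legal fragment ends
  out <- list()
  for (a in bounds_l) {
    for (b in bounds_r[bounds_r >= a]) {
      interior <- sum(cuts >= a & cuts < b)
      if (interior <= max_missed) {
        out[[length(out) + 1L]] <- c(a, b, interior)
      }
    }
  }
  m <- do.call(rbind, out)
  df <- data.frame(start = m[, 1], end = m[, 2], missed = m[, 3])
  df[order(df$start, df$end), ]
}

# Per-atom mass summation from an independent constants table.
oracle_atom_masses <- c(H = 1.00782503, C = 12.0, C13 = 13.00335484,
                        N = 14.00307401, O = 15.99491462, P = 30.97376151)
oracle_nucleoside_atoms <- list(
  A = c(C = 10, H = 13, N = 5, O = 4),
  C = c(C = 9, H = 13, N = 3, O = 5),
  G = c(C = 10, H = 13, N = 5, O = 5),
  U = c(C = 9, H = 12, N = 2, O = 6))

# neutral mass of an oligo with given end phosphates (counts of HPO3
# beyond the bare 5'-OH/3'-OH form) and number of methyl groups
oracle_oligo_mass <- function(sequence, extra_phosphates = 0L,
                              n_methyl = 0L, n_13c = 0L) {
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  atoms <- c(C = 0, H = 0, N = 0, O = 0)
  for (b in bases) {
    a <- oracle_nucleoside_atoms[[b]]
    atoms[names(a)] <- atoms[names(a)] + a
  }
  n <- length(bases)
  # (n-1) internal linkages: +HPO3 -H2O; extra phosphates: +HPO3 each
  mass <- sum(atoms * oracle_atom_masses[names(atoms)]) +
    (n - 1 + extra_phosphates) *
      (oracle_atom_masses["H"] + oracle_atom_masses["P"] +
         3 * oracle_atom_masses["O"]) -
    (n - 1) * (2 * oracle_atom_masses["H"] + oracle_atom_masses["O"]) +
    n_methyl * (oracle_atom_masses["C"] + 2 * oracle_atom_masses["H"]) +
    n_13c * (oracle_atom_masses["C13"] - oracle_atom_masses["C"])
  unname(mass)
}

random_rna <- function(n, letters = c("A", "C", "G", "U")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

frag_key <- function(df) {
  paste(df$start, df$end, df$missed_cleavages %||% df$missed, sep = ":")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# small scenario used by the estimator-recovery checks: one molecule,
# five single-methyl sites in separate RNase T1 fragments plus enough
# site-free fragments for the correction pairs
make_recovery_scenario <- function(truths = c(0.05, 0.25, 0.50, 0.75, 0.95),
                                   mixing = 0.9,
                                   noise = list(intensity_cv = 0.05,
                                                measurement_cv = 0.01,
                                                mass_ppm_sd = 2,
                                                rt_jitter_sd = 0.02),
                                   replicates = 3L, seed = 7L) {
  site_frags <- c("CACUCCG", "AAUCCAG", "ACUCAUCG", "AUCCAAUG", "CAAUACCG")
  # distinct base multisets so no two pair fragments are isobaric
  pair_frags <- c("CCAUUG", "AACCUG", "UUUCAG", "AAACUG", "AUAUCG",
                  "CCCAUG", "UUCCUG", "AACACG", "ACCACG", "CUCUCG",
                  "AAACAG", "CCCCUG")
  seqs <- c(site_frags, pair_frags)
  mol <- rna_molecule("M", paste(seqs, collapse = ""))
  offs <- cumsum(c(0, nchar(seqs)))[seq_along(site_frags)]
  # methylate the first A of each site fragment (non-blocking position)
  pos <- vapply(seq_along(site_frags), function(i) {
    as.integer(offs[i] + regexpr("A", site_frags[i], fixed = TRUE))
  }, 0L)
  sites <- data.frame(
    site = paste0("site", seq_along(truths)),
    molecule_id = "M", position = pos, mod_type = "2'-O-methyl",
    enzyme = "RNaseT1", method = "silnas",
    truth = truths, stringsAsFactors = FALSE)
  simulation_scenario(list(M = mol), sites, conditions = "truth",
                      replicates = replicates, mixing = mixing,
                      n_correction_pairs = 10L, noise = noise, seed = seed)
}
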
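## Elemental composition, monoisotopic mass, negative-mode m/z and MS2
## product-ion ladders for oligonucleotide species.

#' Elemental composition of an oligonucleotide species
#'
#' Sums residue compositions, phosphodiester backbone, end groups and
#' modification deltas.  For the heavy channel, the per-nucleoside 13C
#' substitution counts of the label scheme move carbons from the 12C to
#' the 13C pool according to the base content of the sequence;
#' modification and end-group carbons are unaffected (the label enters
#' through the NTPs of the in-vitro transcript only).
#'
#' @param sequence Oligonucleotide sequence (string over A, C, G, U).
#' @param five_prime_end,three_prime_end End-group tags.
#' @param mods Optional data.frame of `position` (absolute), `mod_type`.
#' @param start Absolute coordinate of the first residue (for `mods`).
#' @param channel `"light"` or `"heavy"`.
#' @param scheme A [label_scheme] (required for the heavy channel).
#' @param cap_composition Elemental composition of the 5' cap, used when
#'   `five_prime_end == "TMG-cap"`.
#' @return Named numeric vector of element counts
#'   (`C12`, `C13`, `H`, `N`, `O`, `P`).
#' @examples
#' oligo_composition("CACUCCG", three_prime_end = "linear-phosphate")
#' @export
oligo_composition <- function(sequence,
                              five_prime_end = "hydroxyl",
                              three_prime_end = "hydroxyl",
                              mods = NULL, start = 1L,
                              channel = c("light", "heavy"),
                              scheme = NULL,
                              cap_composition = DEFAULT_TMG_CAP) {
  channel <- match.arg(channel)
  bases <- strsplit(chartr("T", "U", toupper(sequence)), "", fixed = TRUE)[[1]]
  n <- length(bases)
  if (n == 0L) return(element_zero())
  if (any(!bases %in% RNA_ALPHABET)) {
    stop("sequence contains non-RNA characters", call. = FALSE)
  }
  counts <- element_zero()
  tab <- table(factor(bases, levels = RNA_ALPHABET))
  for (b in RNA_ALPHABET) {
    if (tab[[b]] > 0) {
      counts <- counts + tab[[b]] * as_element_counts(NUCLEOSIDE_COMPOSITION[[b]])
    }
  }
  ## (n - 1) internal phosphodiester linkages: +HPO3 -H2O each
  counts <- counts + (n - 1) * (as_element_counts(HPO3) - as_element_counts(WATER))
  counts <- counts + end_group_delta(five_prime_end, "five_prime", cap_composition)
  counts <- counts + end_group_delta(three_prime_end, "three_prime")
  if (!is.null(mods) && nrow(mods)) {
    rel <- mods$position - start + 1L
    if (any(rel < 1L | rel > n)) {
      stop("modification site outside fragment", call. = FALSE)
    }
    for (m in mods$mod_type) counts <- counts + mod_delta(m)
  }
  if (channel == "heavy") {
    if (is.null(scheme)) stop("heavy channel requires a label scheme",
                              call. = FALSE)
    n13 <- sum(scheme[bases])
    counts[["C12"]] <- counts[["C12"]] - n13
    counts[["C13"]] <- counts[["C13"]] + n13
  }
  if (any(counts < 0)) stop("negative element count; invalid species",
                            call. = FALSE)
  counts
}

#' Monoisotopic mass of an elemental composition
#'
#' @param counts Named numeric vector of element counts as returned by
#'   [oligo_composition] (13C at its own mass).
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(counts) {
  counts <- as_element_counts(counts)
  sum(counts * ELEMENT_MASS[names(counts)])
}

#' Negative-mode m/z of a deprotonated species
#'
#' `[M - zH]^z-`: `mz = (M - z * 1.00727646) / z`.
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param z Charge (>= 1).
#' @return m/z in Th.
#' @export
mz_negative <- function(mass, z) {
  if (any(z < 1)) stop("charge must be >= 1", call. = FALSE)
  (mass - z * PROTON_MASS) / z
}

#' Charges whose m/z falls inside the instrument window
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param window Survey-scan m/z window, default `c(480, 1980)`.
#' @param max_charge Highest charge considered.
#' @return Integer vector of observable charges (possibly empty).
#' @export
observable_charges <- function(mass, window = c(480, 1980), max_charge = 8L) {
  z <- seq_len(max_charge)
  mz <- mz_negative(mass, z)
  z[mz >= window[1] & mz <= window[2]]
}

neutral_base_composition <- function(base, mods_at = NULL) {
  comp <- as_element_counts(NUCLEOBASE_COMPOSITION[[base]])
  ## base-level methylations leave with the base
  if (!is.null(mods_at) && length(mods_at)) {
    for (m in mods_at) {
      if (m %in% c("base-methyl", "N6-methyl")) comp <- comp + mod_delta(m)
    }
  }
  comp
}

#' Theoretical MS2 product-ion ladders (c / y / w / a-B series)
#'
#' Generates the dominant CID series of RNA for every backbone position
#' and charges `1..max_charge`.  Neutral fragment masses obey the closure
#' `mass(c_i) + mass(y_(n-i)) = precursor mass + water`; `w = y + HPO3`,
#' `a = (c - HPO3) - H2O`, and a-B additionally loses the neutral
#' nucleobase of its 3'-terminal residue (with any base-level methyl).
#'
#' @param sequence,five_prime_end,three_prime_end,mods,start,channel,scheme
#'   Species description as for [oligo_composition].
#' @param max_charge Highest product-ion charge.
#' @param cap_composition Cap composition for capped 5' ends.
#' @return A data.frame with columns `series`, `index`, `charge`, `mass`,
#'   `mz`, sorted by series, index, charge.
#' @export
ms2_ladders <- function(sequence,
                        five_prime_end = "hydroxyl",
                        three_prime_end = "hydroxyl",
                        mods = NULL, start = 1L,
                        channel = "light", scheme = NULL,
                        max_charge = 2L,
                        cap_composition = DEFAULT_TMG_CAP) {
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(bases)
  if (n < 2L) stop("fragment length must be >= 2 for MS2 ladders",
                   call. = FALSE)
  sub_mods <- function(from, to) {
    if (is.null(mods) || !nrow(mods)) return(NULL)
    sel <- mods$position - start + 1L >= from & mods$position - start + 1L <= to
    mods[sel, , drop = FALSE]
  }
  hpo3_mass <- monoisotopic_mass(as_element_counts(HPO3))
  water_mass <- monoisotopic_mass(as_element_counts(WATER))
  rows <- list()
  for (i in seq_len(n - 1L)) {
    prefix <- monoisotopic_mass(oligo_composition(
      substr(sequence, 1L, i), five_prime_end, "hydroxyl",
      mods = sub_mods(1L, i), start = start, channel = channel,
      scheme = scheme, cap_composition = cap_composition))
    j <- n - i
    suffix <- monoisotopic_mass(oligo_composition(
      substr(sequence, i + 1L, n), "hydroxyl", three_prime_end,
      mods = sub_mods(i + 1L, n), start = start + i, channel = channel,
      scheme = scheme, cap_composition = cap_composition))
    mods_at_i <- if (is.null(mods) || !nrow(mods)) NULL else
      mods$mod_type[mods$position - start + 1L == i]
    base_i <- monoisotopic_mass(neutral_base_composition(bases[i], mods_at_i))
    ## heavy channel: the leaving base carries its labeled carbons
    if (channel == "heavy" && !is.null(scheme) && scheme[[bases[i]]] > 0) {
      ## base carbons labeled proportionally is not resolvable from the
      ## scheme alone; assume full substitution of base carbons when the
      ## nucleoside is fully labeled (the shipped schemes label all
      ## nucleoside carbons)
      nb <- NUCLEOBASE_COMPOSITION[[bases[i]]][["C12"]]
      if (scheme[[bases[i]]] >= NUCLEOSIDE_CARBONS[[bases[i]]]) {
        base_i <- base_i + nb * C13_C12_DELTA
      }
    }
    masses <- c(
      c = prefix + hpo3_mass,
      y = suffix,
      w = suffix + hpo3_mass,
      `a-B` = prefix - water_mass - base_i
    )
    idx <- c(i, j, j, i)
    for (k in seq_along(masses)) {
      rows[[length(rows) + 1L]] <- data.frame(
        series = names(masses)[k], index = idx[k],
        charge = seq_len(max_charge), mass = masses[[k]],
        mz = mz_negative(masses[[k]], seq_len(max_charge)),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$series, out$index, out$charge), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mass and m/z of a fragment-set row as a charged species
#'
#' Convenience wrapper mapping one row of a `fragment_set` (plus a
#' modification variant and channel) to its neutral mass and the m/z of
#' its observable charges.
#'
#' @param frag_row One-row slice of a `fragment_set`.
#' @param mods Modification variant (data.frame of absolute `position`,
#'   `mod_type`); defaults to the fragment's carried sites.
#' @param channel `"light"` or `"heavy"`.
#' @param scheme A [label_scheme] for the heavy channel.
#' @param window Instrument m/z window.
#' @param cap_composition Cap composition.
#' @return A list with `mass`, `charges`, `mz` (parallel to `charges`).
#' @export
species_mz <- function(frag_row, mods = NULL, channel = "light",
                       scheme = NULL, window = c(480, 1980),
                       cap_composition = DEFAULT_TMG_CAP) {
  if (is.null(mods)) mods <- frag_row$mods[[1]]
  comp <- oligo_composition(frag_row$sequence,
                            frag_row$five_prime_end, frag_row$three_prime_end,
                            mods = mods, start = frag_row$start,
                            channel = channel, scheme = scheme,
                            cap_composition = cap_composition)
  mass <- monoisotopic_mass(comp)
  z <- observable_charges(mass, window)
  list(mass = mass, charges = z,
       mz = if (length(z)) mz_negative(mass, z) else numeric())
}
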
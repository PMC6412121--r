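## Modification-aware in-silico digestion.
##
## RNase T1 cleaves 3' of guanosine and RNase A 3' of pyrimidines; both
## need the free 2'-OH of the residue they cut after, so ribose
## 2'-O-methylation at that residue blocks the cut (pseudouridine, a
## pyrimidine with a free 2'-OH, is still cleaved by RNase A).  T1/A
## products carry 5'-hydroxyl / 3'-phosphate ends; RNase H products carry
## 5'-phosphate / 3'-hydroxyl ends.

#' Define a cleavage rule for an endoribonuclease
#'
#' @param enzyme `"RNaseT1"` or `"RNaseA"` (RNase H splitting is handled
#'   by [rnase_h_split], which is guided rather than base-specific).
#' @param three_prime_product 3' end chemistry of internal products:
#'   `"linear-phosphate"` (default; digests are commonly read out as the
#'   hydrolyzed, opened form) or `"cyclic-phosphate"` (the 2',3'-cyclic
#'   intermediate, one water lighter).
#' @return An object of class `cleavage_rule`.
#' @examples
#' cleavage_rule("RNaseT1")
#' @export
cleavage_rule <- function(enzyme = c("RNaseT1", "RNaseA"),
                          three_prime_product = c("linear-phosphate",
                                                  "cyclic-phosphate")) {
  enzyme <- match.arg(enzyme)
  structure(
    list(
      enzyme = enzyme,
      cut_after = switch(enzyme, RNaseT1 = "G", RNaseA = c("C", "U")),
      product_5prime = "hydroxyl",
      product_3prime = match.arg(three_prime_product)
    ),
    class = "cleavage_rule"
  )
}

#' Cleavable positions of a molecule under a rule
#'
#' Position `i` is cleavable iff the base at `i` belongs to the enzyme's
#' target set, `i` is not the last residue, and no modification with
#' `blocks_3prime_cleavage` sits at `i`.
#'
#' @param molecule An [rna_molecule].
#' @param rule A [cleavage_rule].
#' @param profile Optional `modification_profile` (the modification
#'   variant being digested); blocking modifications suppress cuts.
#' @return Sorted integer vector of cut positions (cut is 3' of each).
#' @export
cleavage_sites <- function(molecule, rule, profile = NULL) {
  if (!inherits(rule, "cleavage_rule")) {
    stop("'rule' must be a cleavage_rule (RNase H uses rnase_h_split())",
         call. = FALSE)
  }
  bases <- mol_bases(molecule)
  n <- length(bases)
  pos <- which(bases %in% rule$cut_after)
  pos <- pos[pos < n]
  blocked <- blocking_positions(profile, molecule$id)
  sort(setdiff(pos, blocked))
}

empty_fragments <- function() {
  out <- data.frame(
    molecule_id = character(), start = integer(), end = integer(),
    sequence = character(), missed_cleavages = integer(),
    five_prime_end = character(), three_prime_end = character(),
    enzyme = character(), stringsAsFactors = FALSE
  )
  out$mods <- list()
  class(out) <- c("fragment_set", "data.frame")
  out
}

#' Digest a molecule in silico
#'
#' Produces all fragments between consecutive cut points plus all merges
#' spanning up to `max_missed` retained internal cuts.  Blocked positions
#' are not cleavable at all and therefore do not count as missed
#' cleavages.  Terminal fragments keep the molecule's original end
#' chemistry on the uncut side.  Fragments carry the profile sites that
#' fall inside them.
#'
#' @param molecule An [rna_molecule].
#' @param rule A [cleavage_rule].
#' @param max_missed Maximum number of retained internal cuts (>= 0).
#' @param profile Optional `modification_profile` giving the modification
#'   variant being digested.
#' @return A `fragment_set` data.frame with columns `molecule_id`,
#'   `start`, `end`, `sequence`, `missed_cleavages`, `five_prime_end`,
#'   `three_prime_end`, `enzyme` and a list-column `mods` (data.frame of
#'   absolute `position`, `mod_type` per fragment).
#' @examples
#' u1 <- rna_molecule("frag", "CACUCCGGAUG")
#' digest(u1, cleavage_rule("RNaseT1"))
#' @export
digest <- function(molecule, rule, max_missed = 0L, profile = NULL) {
  stopifnot(max_missed >= 0)
  cuts <- cleavage_sites(molecule, rule, profile)
  n <- nchar(molecule$sequence)
  starts0 <- c(1L, cuts + 1L)
  ends0 <- c(cuts, n)
  keep <- starts0 <= ends0            # drops empty tail when last cut == n-? (cuts < n so never)
  starts0 <- starts0[keep]; ends0 <- ends0[keep]
  k <- length(starts0)
  rows <- list()
  for (m in 0:max_missed) {
    if (m + 1L > k) break
    idx <- seq_len(k - m)
    rows[[m + 1L]] <- data.frame(start = starts0[idx], end = ends0[idx + m],
                                 missed_cleavages = m)
  }
  rows <- do.call(rbind, rows)
  frag <- data.frame(
    molecule_id = molecule$id,
    start = rows$start,
    end = rows$end,
    sequence = substring(molecule$sequence, rows$start, rows$end),
    missed_cleavages = as.integer(rows$missed_cleavages),
    five_prime_end = ifelse(rows$start == 1L, molecule$five_prime_end,
                            rule$product_5prime),
    three_prime_end = ifelse(rows$end == n, molecule$three_prime_end,
                             rule$product_3prime),
    enzyme = rule$enzyme,
    stringsAsFactors = FALSE
  )
  frag$mods <- lapply(seq_len(nrow(frag)), function(i) {
    profile_sites_in(profile, molecule$id, frag$start[i], frag$end[i])
  })
  frag <- frag[order(frag$start, frag$end), , drop = FALSE]
  rownames(frag) <- NULL
  class(frag) <- c("fragment_set", "data.frame")
  frag
}

#' Sequence of a fragment with modification letters
#'
#' Renders e.g. `CAmCUCCG` for a 2'-O-methyl at the second residue, `Y`
#' for pseudouridine and `m6A` style prefixes for base methylations.
#'
#' @param sequence Fragment sequence.
#' @param mods data.frame of absolute `position`, `mod_type`.
#' @param start Absolute coordinate of the first residue.
#' @return A character string.
#' @export
annotate_sequence <- function(sequence, mods, start = 1L) {
  letters <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!is.null(mods) && nrow(mods)) {
    for (i in seq_len(nrow(mods))) {
      j <- mods$position[i] - start + 1L
      letters[j] <- switch(mods$mod_type[i],
        "2'-O-methyl" = paste0(letters[j], "m"),
        "pseudouridine" = "Y",
        "N6-methyl" = paste0("m6", letters[j]),
        "base-methyl" = paste0("m", letters[j]),
        letters[j]
      )
    }
  }
  paste(letters, collapse = "")
}

#' Export a fragment set as TSV
#'
#' @param fragments A `fragment_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  out <- as.data.frame(fragments)
  out$annotated <- vapply(seq_len(nrow(out)), function(i) {
    annotate_sequence(out$sequence[i], out$mods[[i]], out$start[i])
  }, "")
  out$mods <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split a molecule at a guided RNase H site
#'
#' RNase H cleaves the RNA strand of an RNA:DNA hybrid; with a guide DNA
#' it splits the molecule immediately 5' of `cut_before`, leaving a
#' 3'-hydroxyl on the upstream product and a 5'-monophosphate on the
#' downstream product (which is why downstream 5'-terminal T1 fragments
#' are observed with a 5'-p).
#'
#' @param molecule An [rna_molecule].
#' @param cut_before 1-based position; the split happens between
#'   `cut_before - 1` and `cut_before`.  Must satisfy
#'   `1 < cut_before <= length`.
#' @param profile Optional `modification_profile`; sites are partitioned
#'   between the products with re-indexed coordinates.
#' @return A list with elements `upstream`, `downstream` (both
#'   [rna_molecule], ids suffixed with their source range), `offset` (the
#'   coordinate offset of the downstream product, i.e. `cut_before - 1`)
#'   and `profile` (re-indexed, or `NULL`).
#' @export
rnase_h_split <- function(molecule, cut_before, profile = NULL) {
  n <- nchar(molecule$sequence)
  if (cut_before <= 1L || cut_before > n) {
    stop(sprintf("cut_before must be in (1, %d]; got %s", n, cut_before),
         call. = FALSE)
  }
  up_id <- sprintf("%s:1-%d", molecule$id, cut_before - 1L)
  dn_id <- sprintf("%s:%d-%d", molecule$id, cut_before, n)
  upstream <- rna_molecule(up_id, substr(molecule$sequence, 1L, cut_before - 1L),
                           five_prime_end = molecule$five_prime_end,
                           three_prime_end = "hydroxyl")
  downstream <- rna_molecule(dn_id, substr(molecule$sequence, cut_before, n),
                             five_prime_end = "monophosphate",
                             three_prime_end = molecule$three_prime_end)
  attr(upstream, "source_offset") <- 0L
  attr(downstream, "source_offset") <- cut_before - 1L
  new_profile <- NULL
  if (!is.null(profile) && nrow(profile)) {
    sel <- profile$molecule_id == molecule$id
    moved <- profile[sel, , drop = FALSE]
    if (nrow(moved)) {
      up <- moved$position < cut_before
      moved$molecule_id <- ifelse(up, up_id, dn_id)
      moved$position <- ifelse(up, moved$position,
                               moved$position - (cut_before - 1L))
      rest <- profile[!sel, , drop = FALSE]
      new_profile <- modification_profile(
        c(rest$molecule_id, moved$molecule_id),
        c(rest$position, moved$position),
        c(rest$mod_type, moved$mod_type),
        c(rest$stoichiometry, moved$stoichiometry)
      )
    } else {
      new_profile <- profile
    }
  }
  list(upstream = upstream, downstream = downstream,
       offset = cut_before - 1L, profile = new_profile)
}
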
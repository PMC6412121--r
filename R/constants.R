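## Physical constants and composition tables.
## All masses are monoisotopic, in Da, from the CODATA/AME atomic mass
## tables; a single shared table keeps theoretical m/z self-consistent,
## which matters when matching at a few ppm.

#' Monoisotopic masses of the elements used for oligonucleotides
#'
#' Carbon is split into explicit `C12` and `C13` pools so that
#' stable-isotope-labeled (heavy) species can be described by moving
#' carbons between pools rather than by an ad hoc mass offset.
#'
#' @format Named numeric vector (Da) with elements
#'   `C12`, `C13`, `H`, `N`, `O`, `P`.
#' @export
ELEMENT_MASS <- c(
  C12 = 12.0,
  C13 = 13.0033548378,
  H   = 1.0078250319,
  N   = 14.0030740052,
  O   = 15.9949146221,
  P   = 30.97376151
)

#' @rdname ELEMENT_MASS
#' @export
PROTON_MASS <- 1.00727646

#' @rdname ELEMENT_MASS
#' @export
C13_C12_DELTA <- ELEMENT_MASS[["C13"]] - ELEMENT_MASS[["C12"]]

WATER <- c(C12 = 0, C13 = 0, H = 2, N = 0, O = 1, P = 0)
## HPO3: net addition when a phosphate mono-ester is formed
HPO3 <- c(C12 = 0, C13 = 0, H = 1, N = 0, O = 3, P = 1)

element_zero <- function() c(C12 = 0, C13 = 0, H = 0, N = 0, O = 0, P = 0)

as_element_counts <- function(x) {
  out <- element_zero()
  out[names(x)] <- out[names(x)] + x
  out
}

## Ribonucleoside compositions (free nucleoside, neutral).
NUCLEOSIDE_COMPOSITION <- list(
  A = c(C12 = 10, H = 13, N = 5, O = 4),
  C = c(C12 = 9,  H = 13, N = 3, O = 5),
  G = c(C12 = 10, H = 13, N = 5, O = 5),
  U = c(C12 = 9,  H = 12, N = 2, O = 6)
)

## Neutral nucleobase compositions (used by a-B product ions).
NUCLEOBASE_COMPOSITION <- list(
  A = c(C12 = 5, H = 5, N = 5),
  C = c(C12 = 4, H = 5, N = 3, O = 1),
  G = c(C12 = 5, H = 5, N = 5, O = 1),
  U = c(C12 = 4, H = 4, N = 2, O = 2)
)

## Carbons per nucleoside (ribose + base); upper bound for label counts.
NUCLEOSIDE_CARBONS <- c(A = 10, C = 9, G = 10, U = 9)

RNA_ALPHABET <- c("A", "C", "G", "U")

FIVE_PRIME_ENDS  <- c("hydroxyl", "monophosphate", "triphosphate", "TMG-cap")
THREE_PRIME_ENDS <- c("hydroxyl", "linear-phosphate", "cyclic-phosphate")

## Default elemental composition of the 2,2,7-trimethylguanosine cap:
## TMG nucleoside (guanosine + 3 CH2) joined to the 5' terminus through a
## 5'-5' triphosphate bridge.  Relative to a 5'-hydroxyl molecule this adds
## TMG nucleoside + 3 HPO3 - H2O.  The composition is user-configurable
## because capped species can be defined with other cap chemistries.
DEFAULT_TMG_CAP <- c(C12 = 13, H = 20, N = 5, O = 13, P = 3)

## Additions relative to the bare 5'-OH / 3'-OH oligonucleotide.
end_group_delta <- function(end, side, cap_composition = DEFAULT_TMG_CAP) {
  side <- match.arg(side, c("five_prime", "three_prime"))
  vocab <- if (side == "five_prime") FIVE_PRIME_ENDS else THREE_PRIME_ENDS
  if (!end %in% vocab) {
    stop(sprintf("unknown %s end group '%s' (expected one of: %s)",
                 side, end, paste(vocab, collapse = ", ")), call. = FALSE)
  }
  switch(end,
    "hydroxyl"         = element_zero(),
    "monophosphate"    = as_element_counts(HPO3),
    "triphosphate"     = as_element_counts(3 * HPO3),
    "TMG-cap"          = as_element_counts(cap_composition),
    "linear-phosphate" = as_element_counts(HPO3),
    ## 2',3'-cyclic phosphate: linear phosphate minus one water
    "cyclic-phosphate" = as_element_counts(HPO3) - as_element_counts(WATER)
  )
}

#' Registry of supported modification types
#'
#' Each modification type records its elemental delta relative to the
#' unmodified residue, whether it blocks 2'-OH-dependent ribonuclease
#' cleavage immediately 3' of the residue (ribose 2'-O-methylation does;
#' base methylations do not), whether it is mass-silent (pseudouridine),
#' and which bases it may sit on.
#'
#' @return A data.frame with one row per modification type.
#' @examples
#' modification_types()
#' @export
modification_types <- function() {
  data.frame(
    name = c("2'-O-methyl", "pseudouridine", "base-methyl", "N6-methyl"),
    delta_C = c(1, 0, 1, 1),
    delta_H = c(2, 0, 2, 2),
    blocks_3prime_cleavage = c(TRUE, FALSE, FALSE, FALSE),
    mass_silent = c(FALSE, TRUE, FALSE, FALSE),
    allowed_bases = c("ACGU", "U", "ACGU", "A"),
    stringsAsFactors = FALSE
  )
}

mod_type_info <- function(name) {
  reg <- modification_types()
  i <- match(name, reg$name)
  if (is.na(i)) {
    stop(sprintf("unknown modification type '%s' (known: %s)",
                 name, paste(reg$name, collapse = ", ")), call. = FALSE)
  }
  reg[i, , drop = FALSE]
}

mod_delta <- function(name) {
  info <- mod_type_info(name)
  as_element_counts(c(C12 = info$delta_C, H = info$delta_H))
}

#' Stable-isotope label schemes for in-vitro transcribed standards
#'
#' The internal-standard transcript is synthesized with 13C-substituted
#' NTPs.  The scheme used alongside RNase T1 digestion replaces all ten
#' carbons of guanosine (`G = 10`); the scheme for RNase A digestion
#' replaces the nine carbons each of cytidine and uridine
#' (`C = 9, U = 9`), so every digestion product containing at least one
#' target residue resolves from its light counterpart.
#'
#' @param name `"T1"`, `"A"`, or `"none"`; alternatively pass a named
#'   numeric vector of per-nucleoside 13C counts via `counts`.
#' @param counts Optional custom per-nucleoside 13C substitution counts,
#'   named by base; overrides `name`.
#' @return An object of class `label_scheme`: a named numeric vector with
#'   entries for A, C, G, U.
#' @examples
#' label_scheme("T1")
#' label_scheme(counts = c(G = 10, A = 10))
#' @export
label_scheme <- function(name = c("T1", "A", "none"), counts = NULL) {
  if (is.null(counts)) {
    name <- match.arg(name)
    counts <- switch(name,
      "T1"   = c(G = 10),
      "A"    = c(C = 9, U = 9),
      "none" = c()
    )
  } else {
    name <- "custom"
  }
  full <- c(A = 0, C = 0, G = 0, U = 0)
  if (length(counts)) {
    bad <- setdiff(names(counts), names(full))
    if (length(bad)) stop("unknown nucleoside(s) in label scheme: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    full[names(counts)] <- counts
  }
  if (any(full < 0) || any(full > NUCLEOSIDE_CARBONS[names(full)])) {
    stop("label counts must be between 0 and the carbon count of the nucleoside",
         call. = FALSE)
  }
  structure(full, name = name, class = "label_scheme")
}

#' @export
print.label_scheme <- function(x, ...) {
  cat(sprintf("<label_scheme '%s'> 13C per nucleoside: %s\n",
              attr(x, "name"),
              paste(sprintf("%s=%d", names(x), as.integer(x)), collapse = " ")))
  invisible(x)
}
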
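## RNA molecules, modification sites and their file readers.
## Coordinates are 1-based and inclusive throughout; conversion (if any)
## happens only at I/O boundaries.

#' Construct an RNA molecule
#'
#' @param id Molecule identifier.
#' @param sequence RNA sequence (string over A, C, G, U; `T` is accepted
#'   and mapped to `U` since sequences are commonly distributed as DNA).
#' @param five_prime_end One of `"hydroxyl"`, `"monophosphate"`,
#'   `"triphosphate"`, `"TMG-cap"`.
#' @param three_prime_end One of `"hydroxyl"`, `"linear-phosphate"`,
#'   `"cyclic-phosphate"`.
#' @return An object of class `rna_molecule`.
#' @examples
#' rna_molecule("U1-frag", "CACUCCG")
#' @export
rna_molecule <- function(id, sequence,
                         five_prime_end = "hydroxyl",
                         three_prime_end = "linear-phosphate") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(gsub("\\s", "", sequence))
  sequence <- chartr("T", "U", sequence)
  if (!nzchar(sequence)) stop("sequence must be non-empty", call. = FALSE)
  bad <- regexpr("[^ACGU]", sequence)
  if (bad > 0) {
    stop(sprintf("molecule '%s': illegal character '%s' at position %d",
                 id, substr(sequence, bad, bad), bad), call. = FALSE)
  }
  if (!five_prime_end %in% FIVE_PRIME_ENDS) {
    stop(sprintf("molecule '%s': unknown 5' end '%s'", id, five_prime_end),
         call. = FALSE)
  }
  if (!three_prime_end %in% THREE_PRIME_ENDS) {
    stop(sprintf("molecule '%s': unknown 3' end '%s'", id, three_prime_end),
         call. = FALSE)
  }
  structure(
    list(id = id, sequence = sequence,
         five_prime_end = five_prime_end,
         three_prime_end = three_prime_end),
    class = "rna_molecule"
  )
}

#' @export
print.rna_molecule <- function(x, ...) {
  cat(sprintf("<rna_molecule '%s'> %d nt, 5'-%s / 3'-%s\n",
              x$id, nchar(x$sequence), x$five_prime_end, x$three_prime_end))
  invisible(x)
}

#' @export
length.rna_molecule <- function(x) nchar(x$sequence)

mol_bases <- function(mol, start = 1L, end = nchar(mol$sequence)) {
  strsplit(substr(mol$sequence, start, end), "", fixed = TRUE)[[1]]
}

#' Read RNA molecules from a FASTA file
#'
#' DNA alphabet is accepted (`T` mapped to `U`).  End-group chemistry
#' defaults to 5'-hydroxyl / 3'-linear-phosphate and can be overridden per
#' record with `key=value` tags in the header, e.g.
#' `>U2 five_prime=triphosphate three_prime=hydroxyl`.
#'
#' @param path Path to a FASTA file.
#' @return A named list of [rna_molecule] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  mols <- lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    toks <- strsplit(trimws(header), "\\s+")[[1]]
    id <- toks[1]
    ends <- list(five_prime = "hydroxyl", three_prime = "linear-phosphate")
    for (tok in toks[-1]) {
      kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
      if (length(kv) == 2 && kv[1] %in% names(ends)) ends[[kv[1]]] <- kv[2]
    }
    rna_molecule(id, as.character(set[[i]]),
                 five_prime_end = ends$five_prime,
                 three_prime_end = ends$three_prime)
  })
  names(mols) <- vapply(mols, `[[`, "", "id")
  mols
}

#' Construct a modification profile
#'
#' A modification profile maps sites `(molecule, position, mod_type)` to a
#' stoichiometry fraction in `[0, 1]` (the fraction of molecules carrying
#' the modification at that position).
#'
#' @param molecule_id,position,mod_type,stoichiometry Parallel vectors
#'   describing one site per element.  `stoichiometry` defaults to 1
#'   (fully modified), the natural value for qualitative digests.
#' @param molecules Optional named list of [rna_molecule] used to validate
#'   positions and base compatibility.
#' @return A data.frame of class `modification_profile`.
#' @export
modification_profile <- function(molecule_id = character(),
                                 position = integer(),
                                 mod_type = character(),
                                 stoichiometry = rep(1, length(position)),
                                 molecules = NULL) {
  prof <- data.frame(
    molecule_id = as.character(molecule_id),
    position = as.integer(position),
    mod_type = as.character(mod_type),
    stoichiometry = as.numeric(stoichiometry),
    stringsAsFactors = FALSE
  )
  if (anyNA(prof)) stop("modification profile contains missing values",
                        call. = FALSE)
  if (any(prof$stoichiometry < 0 | prof$stoichiometry > 1)) {
    bad <- which(prof$stoichiometry < 0 | prof$stoichiometry > 1)[1]
    stop(sprintf("stoichiometry out of [0,1] for %s position %d",
                 prof$molecule_id[bad], prof$position[bad]), call. = FALSE)
  }
  key <- paste(prof$molecule_id, prof$position)
  if (anyDuplicated(key)) {
    stop("duplicate (molecule, position) entries: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  reg <- modification_types()
  unknown <- setdiff(prof$mod_type, reg$name)
  if (length(unknown)) {
    stop("unknown modification type(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(molecules)) {
    for (i in seq_len(nrow(prof))) {
      mol <- molecules[[prof$molecule_id[i]]]
      if (is.null(mol)) {
        stop("profile references unknown molecule '", prof$molecule_id[i],
             "'", call. = FALSE)
      }
      if (prof$position[i] < 1L || prof$position[i] > nchar(mol$sequence)) {
        stop(sprintf("position %d out of range for molecule '%s' (%d nt)",
                     prof$position[i], mol$id, nchar(mol$sequence)),
             call. = FALSE)
      }
      base <- substr(mol$sequence, prof$position[i], prof$position[i])
      allowed <- mod_type_info(prof$mod_type[i])$allowed_bases
      if (!grepl(base, allowed, fixed = TRUE)) {
        stop(sprintf("%s is not chemically compatible with %s at %s:%d",
                     prof$mod_type[i], base, mol$id, prof$position[i]),
             call. = FALSE)
      }
    }
  }
  prof <- prof[order(prof$molecule_id, prof$position), , drop = FALSE]
  rownames(prof) <- NULL
  class(prof) <- c("modification_profile", "data.frame")
  prof
}

#' Read a modification-site table
#'
#' Expects a TSV with columns `molecule_id`, `position`, `mod_type`,
#' `stoichiometry`.  Rows are validated against the supplied molecules.
#'
#' @param path Path to the TSV file.
#' @param molecules Named list of [rna_molecule].
#' @return A `modification_profile`.
#' @export
read_modification_table <- function(path, molecules) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("molecule_id", "position", "mod_type", "stoichiometry")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("modification table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  modification_profile(tab$molecule_id, tab$position, tab$mod_type,
                       tab$stoichiometry, molecules = molecules)
}

#' Write a modification profile as TSV
#'
#' @param profile A `modification_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_modification_table <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Sites of a profile falling inside [start, end] of one molecule.
profile_sites_in <- function(profile, molecule_id, start, end) {
  if (is.null(profile) || nrow(profile) == 0L) {
    return(data.frame(position = integer(), mod_type = character(),
                      stringsAsFactors = FALSE))
  }
  sel <- profile$molecule_id == molecule_id &
    profile$position >= start & profile$position <= end
  data.frame(position = profile$position[sel],
             mod_type = profile$mod_type[sel],
             stringsAsFactors = FALSE)
}

## Positions (within molecule) whose modification blocks 3' cleavage.
blocking_positions <- function(profile, molecule_id) {
  if (is.null(profile) || nrow(profile) == 0L) return(integer())
  reg <- modification_types()
  blockers <- reg$name[reg$blocks_3prime_cleavage]
  profile$position[profile$molecule_id == molecule_id &
                     profile$mod_type %in% blockers]
}
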
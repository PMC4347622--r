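#' Atom sets
#'
#' The descriptor extractor works on *atom sets*: tibbles with columns
#' `element` (symbol, e.g. `"C"`, `"Cl"`), `x`, `y`, `z` (Angstrom) and a
#' `source_id` attribute naming the structure they came from. They feed
#' [pair_counts()], which produces the element-pair contact block of a
#' feature table (the `R.` columns).
#'
#' @name atom-set
NULL

default_protein_elements <- c("C", "N", "O", "S")
default_ligand_elements <- c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I")

new_atom_set <- function(element, x, y, z, source_id) {
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z))) {
    stop_data("Atom coordinates must be finite.")
  }
  out <- tibble::tibble(element = as.character(element), x = x, y = y, z = z)
  attr(out, "source_id") <- source_id
  out
}

# Derive an element symbol from a PDB atom name when the element column
# (cols 77-78) is blank: strip digits/primes, then match against known
# two-letter elements before falling back to the first letter.
element_from_atom_name <- function(name) {
  two_letter <- c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "CA", "SE", "CU")
  nm <- toupper(gsub("[0-9' ]", "", name))
  vapply(nm, function(s) {
    if (nchar(s) >= 2 && substr(s, 1, 2) %in% two_letter) {
      first <- substr(s, 1, 2)
      paste0(substr(first, 1, 1), tolower(substr(first, 2, 2)))
    } else {
      substr(s, 1, 1)
    }
  }, character(1), USE.NAMES = FALSE)
}

#' Read protein atoms from a PDB file
#'
#' Parses `ATOM`/`HETATM` records (fixed-column PDB v3.3 layout, via the
#' bio3d reader). Water residues (`HOH`) are excluded; alternate locations
#' other than `'A'` or blank are dropped; all chains are kept. The element
#' symbol is taken from columns 77-78 with a fallback heuristic on the atom
#' name. Hydrogens are kept (elements outside the counting alphabets simply
#' never match).
#'
#' @param path Path to a PDB file.
#' @return An atom-set tibble (see [atom-set]).
#' @export
read_pdb_atoms <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop_usage("Package `bio3d` is required to read PDB files.")
  }
  if (!file.exists(path)) stop_usage(paste0("File not found: ", path))
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
                  error = function(e) {
                    stop_data(paste0("Failed to parse PDB file ", path, ": ",
                                     conditionMessage(e)))
                  })
  at <- pdb$atom
  at <- at[at$resid != "HOH", , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  if (nrow(at) == 0) stop_data(paste0("No usable atoms in ", path))
  ele <- trimws(at$elesy)
  blank <- is.na(ele) | ele == ""
  ele[blank] <- element_from_atom_name(at$elety[blank])
  ele <- paste0(toupper(substr(ele, 1, 1)),
                tolower(substring(ele, 2)))
  new_atom_set(ele, at$x, at$y, at$z,
               source_id = tools::file_path_sans_ext(basename(path)))
}

#' Read ligand atoms from an SDF/MOL file
#'
#' Parses the atom block of a V2000 SDF/MOL record from its fixed-width
#' counts line (atom count in columns 1-3) and atom lines (x, y, z in
#' columns 1-30, element symbol starting at column 32). Molecules without
#' bonds — which some cheminformatics readers reject — are accepted.
#' Multi-record files default to the first record; hydrogens are kept
#' unless `keep_hydrogens = FALSE`.
#'
#' @param path Path to an SDF or MOL V2000 file.
#' @param index Which record of a multi-record SDF to read (default 1).
#' @param keep_hydrogens Keep H atoms? Default `TRUE`.
#' @return An atom-set tibble (see [atom-set]).
#' @export
read_sdf_atoms <- function(path, index = 1, keep_hydrogens = TRUE) {
  if (!file.exists(path)) stop_usage(paste0("File not found: ", path))
  lines <- readr::read_lines(path, progress = FALSE)
  ends <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1L, head(ends, -1) + 1L)
  if (length(ends) == 0) { # bare MOL file
    starts <- 1L
    ends <- length(lines) + 1L
  }
  if (index < 1 || index > length(starts)) {
    stop_usage(paste0("Record index ", index, " out of range; file has ",
                      length(starts), " record(s)."))
  }
  rec <- lines[starts[index]:(ends[index] - 1)]
  if (length(rec) < 4) stop_data(paste0("Truncated SDF record in ", path))
  counts <- rec[4]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  if (is.na(n_atoms) || n_atoms < 1) {
    stop_data(paste0("Unreadable V2000 counts line in ", path, ": \"",
                     counts, "\""))
  }
  if (length(rec) < 4 + n_atoms) {
    stop_data(paste0("Atom count ", n_atoms, " exceeds the ",
                     length(rec) - 4, " atom line(s) present in ", path))
  }
  atom_lines <- rec[5:(4 + n_atoms)]
  num <- function(a, b) {
    v <- suppressWarnings(as.numeric(substr(atom_lines, a, b)))
    if (anyNA(v)) {
      stop_data(paste0("Unreadable coordinate in atom line ",
                       which(is.na(v))[1], " of ", path))
    }
    v
  }
  ele <- trimws(substr(atom_lines, 32, 34))
  out <- new_atom_set(ele, num(1, 10), num(11, 20), num(21, 30),
                      source_id = tools::file_path_sans_ext(basename(path)))
  if (!keep_hydrogens) out <- out[out$element != "H", , drop = FALSE]
  out
}

#' Intermolecular element-pair contact counts
#'
#' Counts, for every (protein element, ligand element) pair in the
#' configured alphabets, the number of intermolecular atom pairs within
#' `cutoff` Angstrom (boundary inclusive: distance exactly equal to the
#' cutoff counts). With the default alphabets (protein C, N, O, S; ligand
#' C, N, O, F, P, S, Cl, Br, I) this yields the familiar 36-count geometric
#' descriptor block; column names follow the `R.<ep>_<el>` convention so
#' the result drops straight into a feature table. The cutoff and alphabets
#' are configurable because published contact-count descriptor sets differ
#' in these choices; the defaults (12 Angstrom, inclusive) are stamped into
#' the attributes of the result.
#'
#' @param protein,ligand Atom-set tibbles (see [atom-set]).
#' @param protein_elements,ligand_elements Ordered element alphabets.
#' @param cutoff Distance cutoff in Angstrom (> 0), boundary inclusive.
#' @param strict If `TRUE`, an atom whose element is outside its alphabet
#'   raises an error; by default such atoms are skipped with a message.
#' @return A named integer vector of `length(protein_elements) *
#'   length(ligand_elements)` counts, ordered protein-element-major, with
#'   attributes `cutoff` and `source_ids`.
#' @export
#' @examples
#' prot <- tibble::tibble(element = "C", x = 0, y = 0, z = 0)
#' lig <- tibble::tibble(element = "C", x = 0, y = 0, z = 6)
#' pair_counts(prot, lig)[["R.C_C"]]
pair_counts <- function(protein, ligand,
                        protein_elements = default_protein_elements,
                        ligand_elements = default_ligand_elements,
                        cutoff = 12, strict = FALSE) {
  if (cutoff <= 0) stop_usage("`cutoff` must be > 0.")
  for (d in list(protein, ligand)) {
    if (!all(c("element", "x", "y", "z") %in% names(d))) {
      stop_usage("Atom sets need `element`, `x`, `y`, `z` columns.")
    }
  }
  unknown_p <- setdiff(unique(protein$element), c(protein_elements, "H"))
  unknown_l <- setdiff(unique(ligand$element), c(ligand_elements, "H"))
  if (strict && (length(unknown_p) > 0 || length(unknown_l) > 0)) {
    stop_data(paste0("Element(s) outside the counting alphabet: ",
                     paste(c(unknown_p, unknown_l), collapse = ", ")))
  }
  if (length(unknown_p) > 0 || length(unknown_l) > 0) {
    inform(paste0("pair_counts: ignoring elements outside the alphabet: ",
                  paste(unique(c(unknown_p, unknown_l)), collapse = ", ")))
  }

  labels <- as.vector(t(outer(protein_elements, ligand_elements,
                              function(p, l) paste0("R.", p, "_", l))))
  counts <- setNames(integer(length(labels)), labels)
  if (nrow(protein) > 0 && nrow(ligand) > 0) {
    cut2 <- cutoff^2
    for (ep in protein_elements) {
      pi <- protein$element == ep
      if (!any(pi)) next
      px <- protein$x[pi]; py <- protein$y[pi]; pz <- protein$z[pi]
      for (el in ligand_elements) {
        li <- ligand$element == el
        if (!any(li)) next
        # squared distances from coordinate differences (same arithmetic as
        # an all-pairs loop, so the inclusive cutoff boundary is exact)
        d2 <- outer(px, ligand$x[li], "-")^2 +
          outer(py, ligand$y[li], "-")^2 +
          outer(pz, ligand$z[li], "-")^2
        counts[paste0("R.", ep, "_", el)] <- sum(d2 <= cut2)
      }
    }
  }
  attr(counts, "cutoff") <- cutoff
  attr(counts, "source_ids") <- c(protein = attr(protein, "source_id") %||% NA,
                                  ligand = attr(ligand, "source_id") %||% NA)
  counts
}

#' Compute the contact-descriptor block for one complex
#'
#' Convenience wrapper: reads a protein PDB file and a ligand SDF file and
#' returns their element-pair contact counts as a one-row tibble ready to
#' bind into a feature table.
#'
#' @param protein_path Path to the protein PDB file.
#' @param ligand_path Path to the ligand SDF/MOL file.
#' @param complex_id ID for the row; defaults to the PDB file stem.
#' @param ... Passed to [pair_counts()].
#' @return A one-row tibble: `complex_id` plus the 36 `R.` count columns.
#' @export
featurize_complex <- function(protein_path, ligand_path, complex_id = NULL,
                              ...) {
  prot <- read_pdb_atoms(protein_path)
  lig <- read_sdf_atoms(ligand_path)
  counts <- pair_counts(prot, lig, ...)
  dplyr::bind_cols(
    tibble::tibble(complex_id = complex_id %||% attr(prot, "source_id")),
    tibble::as_tibble(as.list(counts)))
}
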
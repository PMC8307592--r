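# Classed condition helper: every user-facing failure carries a
# "detbelt_<kind>" class so the CLI can map it to a distinct exit code.
detbelt_stop <- function(kind, msg, ...) {
  stop(structure(
    class = c(paste0("detbelt_", kind), "detbelt_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

detbelt_warn <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}

#' Parse a membrane-oriented PDB file
#'
#' Reads ATOM/HETATM records from fixed-column PDB text, flags membrane
#' dummy atoms and hydrogens, and recovers the membrane half-thickness
#' (from a REMARK line or, failing that, from the dummy-atom boundary
#' layers). Structures are expected to be pre-oriented in the membrane
#' frame used by the OPM/PPM convention: z axis normal to the membrane
#' plane, origin at the membrane centre. No re-orientation is attempted.
#'
#' Only the first MODEL of a multi-model file is read (with a warning).
#' Records whose coordinate fields do not parse are skipped, and the
#' number of skipped records is reported in a warning.
#'
#' @param text PDB-format text: a character vector of lines, or a single
#'   string containing newlines.
#' @param dummy_residues residue names marking membrane boundary
#'   pseudo-atoms (OPM writes `DUM`).
#' @param solvent_residues residue names treated as solvent by
#'   [protein_heavy_atoms()].
#' @param source_label free-text label carried through to reports.
#' @return An object of class `oriented_structure`: a list with
#'   `atoms` (a data frame of atom records), `half_thickness` (Angstrom,
#'   `NA` if unrecoverable), `source_label` and `n_skipped`.
#' @examples
#' txt <- c(
#'   "REMARK      1/2 of bilayer thickness:   15.2",
#'   "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C"
#' )
#' s <- parse_pdb(txt)
#' s$half_thickness
#' @export
parse_pdb <- function(text,
                      dummy_residues = c("DUM"),
                      solvent_residues = c("HOH", "WAT"),
                      source_label = "") {
  lines <- split_pdb_lines(text)

  # Multi-model: keep everything up to the first ENDMDL (i.e. MODEL 1).
  model_idx <- grep("^MODEL ", lines)
  if (length(model_idx) > 1L) {
    endmdl <- grep("^ENDMDL", lines)
    first_end <- if (length(endmdl)) endmdl[1L] else length(lines)
    lines <- lines[seq_len(first_end)]
    detbelt_warn("multi-model file: only MODEL 1 was read")
  }

  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) {
    detbelt_stop("empty_structure", "empty structure: no ATOM or HETATM records found")
  }
  rec <- lines[is_atom]
  # Pad short lines so fixed-column extraction is safe.
  rec <- formatC(rec, width = max(80L, max(nchar(rec))), flag = "-")

  x <- suppressWarnings(as.numeric(substr(rec, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(rec, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(rec, 47, 54)))
  bad <- !is.finite(x) | !is.finite(y) | !is.finite(z)
  if (any(bad)) {
    detbelt_warn("skipped %d record(s) with malformed coordinate fields", sum(bad))
    rec <- rec[!bad]; x <- x[!bad]; y <- y[!bad]; z <- z[!bad]
  }
  if (!length(rec)) {
    detbelt_stop("empty_structure", "empty structure: all atom records were malformed")
  }

  atom_name <- trimws(substr(rec, 13, 16))
  element <- trimws(substr(rec, 77, 78))
  no_el <- !nzchar(element)
  if (any(no_el)) {
    element[no_el] <- infer_element(substr(rec[no_el], 13, 16))
  }
  element <- toupper(element)
  # Normalise two-letter symbols to title case (FE -> Fe) for table lookups.
  two <- nchar(element) == 2L
  element[two] <- paste0(substr(element[two], 1, 1), tolower(substr(element[two], 2, 2)))

  residue_name <- trimws(substr(rec, 18, 20))
  atoms <- data.frame(
    serial = suppressWarnings(as.integer(substr(rec, 7, 11))),
    atom_name = atom_name,
    element = element,
    residue_name = residue_name,
    chain_id = substr(rec, 22, 22),
    residue_number = suppressWarnings(as.integer(substr(rec, 23, 26))),
    x = x, y = y, z = z,
    record_kind = ifelse(substr(rec, 1, 4) == "ATOM", "ATOM", "HETATM"),
    is_dummy = residue_name %in% dummy_residues,
    is_hydrogen = element %in% c("H", "D"),
    stringsAsFactors = FALSE
  )

  half <- extract_half_thickness(lines, atoms)
  structure(
    list(atoms = atoms,
         half_thickness = half,
         source_label = source_label,
         solvent_residues = solvent_residues,
         n_skipped = sum(bad)),
    class = "oriented_structure"
  )
}

#' Read a membrane-oriented PDB file from disk
#'
#' @param path path to a PDB file.
#' @inheritParams parse_pdb
#' @return An `oriented_structure`; see [parse_pdb()].
#' @export
read_oriented_pdb <- function(path, dummy_residues = c("DUM"),
                              solvent_residues = c("HOH", "WAT")) {
  if (!file.exists(path)) {
    detbelt_stop("unreadable_file", "cannot read structure file '%s'", path)
  }
  parse_pdb(readLines(path, warn = FALSE),
            dummy_residues = dummy_residues,
            solvent_residues = solvent_residues,
            source_label = basename(path))
}

split_pdb_lines <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  text
}

# Element from the atom-name field (columns 13-16) when columns 77-78 are
# blank. Column 13 is blank for one-letter elements of standard residues;
# a leading digit (e.g. "1HB1") marks a hydrogen naming variant.
infer_element <- function(name_field) {
  vapply(name_field, function(f) {
    first <- substr(f, 1, 1)
    nm <- gsub("[^A-Za-z]", "", f)
    if (!nzchar(nm)) return("X")
    if (first != " " && nchar(trimws(substr(f, 1, 2))) == 2 &&
        grepl("^[0-9]", trimws(f)) == FALSE && substr(f, 1, 1) != " ") {
      two <- toupper(substr(nm, 1, 2))
      if (two %in% TWO_LETTER_ELEMENTS) return(two)
    }
    toupper(substr(nm, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}

TWO_LETTER_ELEMENTS <- c("FE", "ZN", "MG", "MN", "CU", "CO", "NI", "CD",
                         "HG", "CL", "BR", "NA", "SE", "CA")

#' Recover the membrane half-thickness from PDB text
#'
#' PPM/OPM-processed files carry the half-thickness of the bilayer as a
#' REMARK ("1/2 of bilayer thickness: <value>"); a generic
#' "HALF-THICKNESS" keyword is also accepted, case-insensitively, first
#' match wins. When no such REMARK exists the two layers of membrane
#' dummy atoms (which sit at z = +/- half-thickness) are used instead.
#'
#' @param text PDB text (lines or a single string).
#' @param atoms atom records as produced by [parse_pdb()] (used for the
#'   dummy-atom fallback); may be `NULL`.
#' @return Half-thickness in Angstrom, or `NA_real_` when neither source
#'   is present. A matching REMARK with a non-numeric or non-positive
#'   value is an error, not a silent fallback.
#' @export
extract_half_thickness <- function(text, atoms = NULL) {
  lines <- split_pdb_lines(text)
  remarks <- lines[grepl("^REMARK", lines)]
  pats <- c("1/2\\s+of\\s+(the\\s+)?bilayer\\s+thickness\\s*:?\\s*(\\S+)",
            "half[-_ ]?thickness\\s*:?\\s*(\\S+)")
  for (line in remarks) {
    for (p in pats) {
      m <- regexec(p, line, ignore.case = TRUE)[[1L]]
      if (m[1L] != -1L) {
        parts <- regmatches(line, regexec(p, line, ignore.case = TRUE))[[1L]]
        val_str <- parts[length(parts)]
        val <- suppressWarnings(as.numeric(val_str))
        if (!is.finite(val) || val <= 0) {
          detbelt_stop("invalid_thickness",
                       "invalid thickness remark: '%s' (value '%s')",
                       trimws(line), val_str)
        }
        return(val)
      }
    }
  }
  if (!is.null(atoms) && any(atoms$is_dummy)) {
    return(max(abs(atoms$z[atoms$is_dummy])))
  }
  NA_real_
}

#' Protein heavy atoms of an oriented structure
#'
#' Drops membrane dummy atoms, hydrogens (and deuteriums), and solvent
#' residues; everything else counts as a heavy atom of the structure and
#' enters the accessible-surface-area computation. Order is preserved.
#'
#' @param structure an `oriented_structure`.
#' @param solvent_residues residue names excluded as solvent; defaults to
#'   the set recorded when the structure was parsed.
#' @return A data frame of atom records (subset of `structure$atoms`).
#' @export
protein_heavy_atoms <- function(structure,
                                solvent_residues = structure$solvent_residues) {
  stopifnot(inherits(structure, "oriented_structure"))
  if (is.null(solvent_residues)) solvent_residues <- c("HOH", "WAT")
  a <- structure$atoms
  keep <- !a$is_dummy & !a$is_hydrogen & !(a$residue_name %in% solvent_residues)
  if (!any(keep)) {
    detbelt_stop("no_heavy_atoms",
                 "no heavy atoms: structure contains only dummy/hydrogen/solvent atoms")
  }
  a[keep, , drop = FALSE]
}

#' Serialize an oriented structure back to PDB text
#'
#' Writes a half-thickness REMARK (when known) followed by fixed-column
#' ATOM/HETATM records at the PDB format's 3-decimal coordinate
#' precision, so that parse -> write -> parse round-trips.
#'
#' @param structure an `oriented_structure`.
#' @param path optional file to write to.
#' @return The PDB text as a character vector of lines (invisibly when
#'   `path` is given).
#' @export
write_oriented_pdb <- function(structure, path = NULL) {
  stopifnot(inherits(structure, "oriented_structure"))
  a <- structure$atoms
  header <- character(0)
  if (is.finite(structure$half_thickness)) {
    header <- sprintf("REMARK      1/2 of bilayer thickness:  %8.3f",
                      structure$half_thickness)
  }
  lines <- c(header, format_pdb_atoms(a), "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

format_pdb_atoms <- function(a) {
  # Atom names shorter than 4 characters start in column 14.
  nm <- ifelse(nchar(a$atom_name) < 4L,
               sprintf(" %-3s", a$atom_name),
               sprintf("%-4s", a$atom_name))
  el <- toupper(a$element)
  sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$record_kind, a$serial %% 100000L, nm, a$residue_name,
          a$chain_id, a$residue_number %% 10000L, a$x, a$y, a$z,
          1.0, 0.0, el)
}

#' @export
print.oriented_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("Oriented structure%s: %d atoms (%d dummy, %d hydrogen)\n",
              if (nzchar(x$source_label)) paste0(" [", x$source_label, "]") else "",
              nrow(a), sum(a$is_dummy), sum(a$is_hydrogen)))
  cat(sprintf("  membrane half-thickness: %s\n",
              if (is.finite(x$half_thickness))
                sprintf("%.2f Angstrom", x$half_thickness) else "unknown"))
  invisible(x)
}
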
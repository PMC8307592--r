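DB_FAMILIES <- c("maltoside", "glucoside", "neopentyl glycol",
                 "cholesterol derivative", "fos-choline", "amine oxide",
                 "thio-derivative", "lipid", "amphipol", "bile salt")

DB_COLUMNS <- c("id", "full_name", "family", "formula", "mw", "cmc_mM",
                "smiles", "monomer_volume_A3", "volume_source",
                "reference", "aliases", "color")

#' Load the detergent / lipid / amphipol database
#'
#' Reads a tab-separated database of amphiphile monomers (one row per
#' compound: identity, chemistry, critical micellar concentration,
#' monomer volume) and validates it. Monomer volumes in the built-in
#' database are additive van der Waals estimates (see
#' [estimate_monomer_volume()]) except where `volume_source` says
#' `curated`; each can be overridden per run (see [total_volume()]).
#'
#' @param path path to a TSV file; `NULL` loads the built-in database.
#' @return A `detergent_db` data frame.
#' @examples
#' db <- load_detergent_db()
#' detergent_lookup(db, "ddm")$full_name
#' @export
load_detergent_db <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "detergents.tsv", package = "detbelt",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) {
    detbelt_stop("unreadable_file", "detergent database '%s' not found", path)
  }
  db <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  missing_cols <- setdiff(DB_COLUMNS, names(db))
  if (length(missing_cols)) {
    detbelt_stop("db_invalid", "database is missing required column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  validate_detergent_db(db)
  structure(db, class = c("detergent_db", "data.frame"))
}

validate_detergent_db <- function(db) {
  dup_id <- unique(db$id[duplicated(toupper(db$id))])
  if (length(dup_id)) {
    detbelt_stop("db_invalid", "duplicate detergent id(s): %s",
                 paste(dup_id, collapse = ", "))
  }
  aliases <- db_alias_list(db)
  all_alias <- toupper(unlist(aliases))
  dup_alias <- unique(all_alias[duplicated(all_alias)])
  dup_alias <- union(dup_alias, intersect(all_alias, toupper(db$id)))
  if (length(dup_alias)) {
    detbelt_stop("db_invalid", "duplicate alias(es) across the database: %s",
                 paste(dup_alias, collapse = ", "))
  }
  required_ok <- nzchar(db$id) & nzchar(db$full_name) & nzchar(db$family) &
    is.finite(db$mw) & is.finite(db$monomer_volume_A3)
  if (!all(required_ok)) {
    detbelt_stop("db_invalid", "entries with missing required fields: %s",
                 paste(db$id[!required_ok], collapse = ", "))
  }
  if (any(db$mw <= 0) || any(db$monomer_volume_A3 <= 0)) {
    detbelt_stop("db_invalid", "molecular weight and monomer volume must be > 0")
  }
  bad_family <- setdiff(unique(db$family), DB_FAMILIES)
  if (length(bad_family)) {
    detbelt_stop("db_invalid", "unknown family/families: %s",
                 paste(bad_family, collapse = ", "))
  }
  invisible(db)
}

db_alias_list <- function(db) {
  lapply(db$aliases, function(a) {
    if (is.na(a) || !nzchar(a)) character(0)
    else trimws(strsplit(a, "|", fixed = TRUE)[[1L]])
  })
}

#' Write a detergent database back to TSV
#'
#' @param db a `detergent_db`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_detergent_db <- function(db, path) {
  utils::write.table(as.data.frame(db)[, DB_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Look up a detergent by id, alias or full name
#'
#' Case-insensitive exact matching, tried in order: id, then aliases,
#' then full name. Unknown queries raise an error listing near-miss ids
#' (edit distance <= 2) as suggestions.
#'
#' @param db a `detergent_db`.
#' @param query id (e.g. `"DDM"`), alias, or full compound name.
#' @return The matching database row (one-row data frame).
#' @export
detergent_lookup <- function(db, query) {
  stopifnot(inherits(db, "detergent_db"), is.character(query), length(query) == 1L)
  q <- toupper(trimws(query))
  hit <- match(q, toupper(db$id))
  if (is.na(hit)) {
    aliases <- db_alias_list(db)
    hit_alias <- which(vapply(aliases, function(a) q %in% toupper(a), logical(1)))
    hit <- if (length(hit_alias)) hit_alias[1L] else NA_integer_
  }
  if (is.na(hit)) {
    hit <- match(q, toupper(db$full_name))
  }
  if (is.na(hit)) {
    d <- utils::adist(q, toupper(db$id))
    sugg <- db$id[d <= 2]
    detbelt_stop("unknown_detergent", "unknown detergent '%s'%s", query,
                 if (length(sugg)) paste0("; did you mean: ",
                                          paste(sugg, collapse = ", "), "?")
                 else "")
  }
  db[hit, , drop = FALSE]
}

#' Belt composition specification
#'
#' An ordered list of (detergent, monomer count) pairs — the user's
#' hypothesis about what the belt is made of. Counts are positive whole
#' monomer numbers; order defines the stacking order of mixtures.
#'
#' @param ids character vector of detergent ids/aliases/names.
#' @param counts integer vector of monomer counts, same length.
#' @return A `belt_spec` data frame with columns `detergent_id`,
#'   `n_monomers`.
#' @export
belt_spec <- function(ids, counts) {
  if (length(ids) == 0L) {
    detbelt_stop("bad_spec", "belt specification is empty")
  }
  if (length(ids) != length(counts)) {
    detbelt_stop("bad_spec", "ids and counts differ in length")
  }
  counts <- suppressWarnings(as.numeric(counts))
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != round(counts))) {
    detbelt_stop("bad_spec", "monomer count must be a positive integer")
  }
  structure(
    data.frame(detergent_id = as.character(ids), n_monomers = as.integer(counts),
               stringsAsFactors = FALSE),
    class = c("belt_spec", "data.frame")
  )
}

#' Total detergent volume of a belt specification
#'
#' Per entry, the number of monomers times the monomer volume from the
#' database (or a per-run override); the total is their sum. Linear in
#' the counts and equivariant under permutation of the entries.
#'
#' @param spec a `belt_spec`.
#' @param db a `detergent_db`.
#' @param volume_overrides optional named vector, id -> monomer volume
#'   (Angstrom^3).
#' @return List with `per_entry` (data frame: `detergent_id`,
#'   `n_monomers`, `monomer_volume`, `volume`, `color`) and `V_total`
#'   (Angstrom^3).
#' @export
total_volume <- function(spec, db, volume_overrides = NULL) {
  stopifnot(inherits(spec, "belt_spec"))
  if (nrow(spec) == 0L) detbelt_stop("bad_spec", "belt specification is empty")
  rows <- lapply(spec$detergent_id, function(id) detergent_lookup(db, id))
  canon <- vapply(rows, function(r) r$id, character(1))
  mono <- vapply(rows, function(r) r$monomer_volume_A3, numeric(1))
  color <- vapply(rows, function(r) r$color, character(1))
  if (!is.null(volume_overrides)) {
    ov <- match(toupper(canon), toupper(names(volume_overrides)))
    has <- !is.na(ov)
    if (any(volume_overrides <= 0)) {
      detbelt_stop("bad_spec", "monomer volume override must be > 0")
    }
    mono[has] <- unname(volume_overrides[ov[has]])
  }
  per <- data.frame(detergent_id = canon,
                    n_monomers = spec$n_monomers,
                    monomer_volume = mono,
                    volume = spec$n_monomers * mono,
                    color = color,
                    stringsAsFactors = FALSE)
  list(per_entry = per, V_total = sum(per$volume))
}

# Atomic van der Waals volume increments (Angstrom^3) for the additive
# estimator, with bond and ring corrections.
VOLUME_INCREMENTS <- c(C = 20.58, H = 7.24, N = 15.6, O = 14.71,
                       S = 24.43, P = 24.87)
BOND_CORRECTION <- 5.92
AROMATIC_RING_CORRECTION <- 14.7
NONAROMATIC_RING_CORRECTION <- 3.8

#' Additive van der Waals monomer volume estimate
#'
#' Estimates the volume of one amphiphile monomer from its composition:
#' the sum of atomic van der Waals increments (C 20.58, H 7.24, N 15.6,
#' O 14.71, S 24.43, P 24.87 Angstrom^3) minus 5.92 per bond, 14.7 per
#' aromatic ring and 3.8 per non-aromatic ring. For a connected
#' molecule the bond count equals atoms - 1 + rings regardless of bond
#' order.
#'
#' @param composition named vector of atom counts by element symbol,
#'   e.g. `c(C = 24, H = 46, O = 11)`.
#' @param n_bonds total number of bonds (edges between bonded atoms).
#' @param n_aromatic_rings number of aromatic rings.
#' @param n_nonaromatic_rings number of non-aromatic rings.
#' @return Estimated monomer volume (Angstrom^3).
#' @examples
#' estimate_monomer_volume(c(C = 1, H = 4), n_bonds = 4)  # methane: 25.86
#' @export
estimate_monomer_volume <- function(composition, n_bonds,
                                    n_aromatic_rings = 0,
                                    n_nonaromatic_rings = 0) {
  stopifnot(length(composition) >= 1, all(composition >= 0), sum(composition) >= 1,
            n_bonds >= 0, n_aromatic_rings >= 0, n_nonaromatic_rings >= 0)
  el <- toupper(names(composition))
  inc <- VOLUME_INCREMENTS[el]
  if (any(is.na(inc))) {
    detbelt_stop("bad_composition", "no volume increment for element(s): %s",
                 paste(el[is.na(inc)], collapse = ", "))
  }
  v <- sum(composition * inc) - BOND_CORRECTION * n_bonds -
    AROMATIC_RING_CORRECTION * n_aromatic_rings -
    NONAROMATIC_RING_CORRECTION * n_nonaromatic_rings
  if (v <= 0) {
    detbelt_stop("bad_composition",
                 "volume estimate is not positive (%.2f); check the composition", v)
  }
  v
}

#' Parse a molecular formula into element counts
#'
#' @param formula Hill-style formula such as `"C24H46O11"`.
#' @return Named integer vector of atom counts.
#' @export
parse_molecular_formula <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1L]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1L]]
  if (!length(toks) || paste(toks, collapse = "") != gsub("[^A-Za-z0-9]", "", formula)) {
    detbelt_stop("bad_composition", "cannot parse molecular formula '%s'", formula)
  }
  el <- gsub("[0-9]", "", toks)
  n <- suppressWarnings(as.integer(gsub("[A-Za-z]", "", toks)))
  n[is.na(n)] <- 1L
  out <- tapply(n, el, sum)
  stats::setNames(as.integer(out), names(out))
}

#' @export
print.detergent_db <- function(x, ...) {
  cat(sprintf("Detergent database: %d entries, %d families\n",
              nrow(x), length(unique(x$family))))
  print.data.frame(x[, c("id", "family", "mw", "cmc_mM", "monomer_volume_A3")],
                   row.names = FALSE)
  invisible(x)
}

#' One-entry information card (text form)
#'
#' @param entry a one-row database slice from [detergent_lookup()].
#' @return Character vector of display lines.
#' @export
format_detergent_info <- function(entry) {
  c(sprintf("%s — %s", entry$id, entry$full_name),
    sprintf("  family         : %s", entry$family),
    sprintf("  formula        : %s", entry$formula),
    sprintf("  MW             : %.2f g/mol", entry$mw),
    sprintf("  CMC            : %s", if (is.finite(entry$cmc_mM))
      sprintf("%.3g mM", entry$cmc_mM) else "n/a"),
    sprintf("  monomer volume : %.2f Angstrom^3 (%s)",
            entry$monomer_volume_A3, entry$volume_source),
    sprintf("  SMILES         : %s", if (is.na(entry$smiles)) "n/a" else entry$smiles),
    sprintf("  aliases        : %s", if (is.na(entry$aliases)) "none" else entry$aliases),
    sprintf("  reference      : %s", entry$reference))
}
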
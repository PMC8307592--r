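#' Bundle a belt geometry with its provenance
#'
#' @param geometry a `belt_geometry` from [build_belt()].
#' @param structure_label label of the input structure.
#' @param spec the `belt_spec` used (echoed into reports).
#' @param options the `belt_options` used.
#' @param warnings character vector of warnings collected along the way.
#' @return A `belt_report`.
#' @export
belt_report <- function(geometry, structure_label = "", spec = NULL,
                        options = NULL, warnings = character(0)) {
  stopifnot(inherits(geometry, "belt_geometry"))
  structure(
    list(geometry = geometry, structure_label = structure_label,
         spec = spec, options = options, warnings = warnings),
    class = "belt_report"
  )
}

#' Serialize belt metrics
#'
#' `json` writes a machine-readable report (keys `h_A`,
#' `inner_radius_A`, `outer_radius_A`, `total_volume_A3`, `stacks`,
#' `r_source`, `peak_radius_A`) at full numeric precision; `text` writes
#' an aligned human-readable table with 2-decimal numbers, one line per
#' stack with its z-range.
#'
#' @param report a `belt_report`.
#' @param format `"json"` or `"text"`.
#' @param path optional output file.
#' @return Character vector of output lines (invisibly when written to
#'   `path`).
#' @export
write_metrics <- function(report, format = c("json", "text"), path = NULL) {
  stopifnot(inherits(report, "belt_report"))
  format <- match.arg(format)
  g <- report$geometry
  out <- if (format == "json") {
    payload <- list(
      structure_label = report$structure_label,
      h_A = g$h,
      inner_radius_A = g$r,
      outer_radius_A = g$R,
      total_volume_A3 = g$V_total,
      r_source = g$r_source,
      peak_radius_A = if (is.null(g$peak_radius)) NULL else g$peak_radius,
      stacks = data.frame(detergent_id = g$stacks$detergent_id,
                          n_monomers = g$stacks$n_monomers,
                          volume_A3 = g$stacks$volume,
                          z_lo_A = g$stacks$z_lo,
                          z_hi_A = g$stacks$z_hi,
                          stringsAsFactors = FALSE),
      warnings = report$warnings
    )
    # I(17) significant digits: doubles survive the round trip exactly
    jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17), null = "null")
  } else {
    c(sprintf("Detergent belt metrics%s",
              if (nzchar(report$structure_label))
                paste0(" for ", report$structure_label) else ""),
      sprintf("  belt height h        : %10.2f Angstrom", g$h),
      sprintf("  inner radius r       : %10.2f Angstrom (%s)", g$r, g$r_source),
      sprintf("  outer radius R       : %10.2f Angstrom", g$R),
      sprintf("  total volume V       : %14.2f Angstrom^3", g$V_total),
      if (!is.null(g$peak_radius))
        sprintf("  density peak radius  : %10.2f Angstrom", g$peak_radius),
      sprintf("  stacks               : %d", nrow(g$stacks)),
      sprintf("    %-10s %8s %14s   z-range [%s]", "detergent", "monomers",
              "volume (A^3)", "Angstrom"),
      sprintf("    %-10s %8d %14.2f   [%8.2f, %8.2f]",
              g$stacks$detergent_id, g$stacks$n_monomers, g$stacks$volume,
              g$stacks$z_lo, g$stacks$z_hi))
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Parse belt metrics JSON back into numbers
#'
#' Inverse of `write_metrics(format = "json")`; numeric fields
#' round-trip at full precision.
#'
#' @param text JSON text (or a file path to it).
#' @return Named list mirroring the JSON structure.
#' @export
read_metrics <- function(text) {
  if (length(text) == 1L && file.exists(text)) text <- readLines(text, warn = FALSE)
  out <- jsonlite::fromJSON(paste(text, collapse = "\n"))
  # JSON has no integer/double distinction: belt lengths are doubles
  for (f in c("h_A", "inner_radius_A", "outer_radius_A", "total_volume_A3",
              "peak_radius_A")) {
    if (!is.null(out[[f]])) out[[f]] <- as.numeric(out[[f]])
  }
  if (!is.null(out$stacks)) {
    for (f in c("volume_A3", "z_lo_A", "z_hi_A")) {
      out$stacks[[f]] <- as.numeric(out$stacks[[f]])
    }
  }
  out
}

hex_to_rgb <- function(hex) {
  hex <- ifelse(is.na(hex) | !nzchar(hex), "#999999", hex)
  m <- grepl("^#[0-9A-Fa-f]{6}$", hex)
  hex[!m] <- "#999999"
  cbind(r = strtoi(substr(hex, 2, 3), 16L) / 255,
        g = strtoi(substr(hex, 4, 5), 16L) / 255,
        b = strtoi(substr(hex, 6, 7), 16L) / 255)
}

#' Write a PyMOL script drawing the belt
#'
#' Emits a PyMOL `.pml`/python command script that loads the structure
#' and draws every mixture stack as a pair of coaxial CGO cylinders:
#' an opaque neutral inner cylinder of radius r (the protein shell) and
#' a semi-transparent outer cylinder of radius R coloured by the
#' detergent. PyMOL has no hollow-cylinder primitive, so the belt
#' annulus is shown by the visual difference of the two solids (noted
#' in the script header). All radii and z-coordinates equal the
#' geometry's values to 3 decimals.
#'
#' @param report a `belt_report`.
#' @param structure_path path PyMOL should load the structure from.
#' @param path optional output file.
#' @return Character vector of script lines (invisibly when written).
#' @export
write_viewer_script <- function(report, structure_path = "structure.pdb",
                                path = NULL) {
  stopifnot(inherits(report, "belt_report"))
  g <- report$geometry
  s <- g$stacks
  col <- hex_to_rgb(if (is.null(s$color)) rep(NA_character_, nrow(s)) else s$color)
  lines <- c(
    "# Detergent belt rendering script (PyMOL)",
    "# The hollow belt cylinder is drawn as two coaxial solid CGO cylinders:",
    "# an opaque neutral inner cylinder (protein shell, radius r) and a",
    "# semi-transparent coloured outer cylinder (belt boundary, radius R).",
    "from pymol import cmd",
    "from pymol.cgo import CYLINDER",
    sprintf('cmd.load("%s", "protein")', structure_path),
    'cmd.hide("everything", "resn DUM")'
  )
  for (i in seq_len(nrow(s))) {
    inner <- sprintf(
      "belt_stack%d_inner = [CYLINDER, 0.0, 0.0, %.3f, 0.0, 0.0, %.3f, %.3f, 0.75, 0.75, 0.75, 0.75, 0.75, 0.75]",
      i, s$z_lo[i], s$z_hi[i], g$r)
    outer <- sprintf(
      "belt_stack%d_outer = [CYLINDER, 0.0, 0.0, %.3f, 0.0, 0.0, %.3f, %.3f, %.3f, %.3f, %.3f, %.3f, %.3f, %.3f]",
      i, s$z_lo[i], s$z_hi[i], g$R,
      col[i, 1], col[i, 2], col[i, 3], col[i, 1], col[i, 2], col[i, 3])
    lines <- c(lines, inner, outer,
               sprintf('cmd.load_cgo(belt_stack%d_inner, "belt_stack%d_inner")', i, i),
               sprintf('cmd.load_cgo(belt_stack%d_outer, "belt_stack%d_outer")', i, i),
               sprintf('cmd.set("cgo_transparency", 0.5, "belt_stack%d_outer")', i))
  }
  lines <- c(lines, 'cmd.zoom("all", buffer=5)')
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

# Largest-remainder apportionment of n points over weights.
apportion_points <- function(n, weights) {
  share <- n * weights / sum(weights)
  base <- floor(share)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(share - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Sample the belt annulus as pseudo-atoms
#'
#' Writes a PDB stream of HETATM dummy atoms (residue `BLT`, element
#' Ne so viewers draw unbonded spheres) sampled uniformly inside each
#' stack's annulus: radius^2 uniform in [r^2, R^2], angle uniform, z
#' uniform over the stack's range. Points are apportioned to stacks
#' proportionally to stack volume (largest-remainder rounding) and the
#' stream is byte-identical for a given seed.
#'
#' @param report a `belt_report`.
#' @param n_points total number of pseudo-atoms (>= 1).
#' @param seed RNG seed.
#' @param path optional output file.
#' @return Character vector of PDB lines (invisibly when written).
#' @export
write_belt_pseudoatoms <- function(report, n_points = 1000L, seed = 1L,
                                   path = NULL) {
  stopifnot(inherits(report, "belt_report"), n_points >= 1)
  g <- report$geometry
  s <- g$stacks
  counts <- apportion_points(n_points, s$volume)
  lines <- with_seed(seed, {
    out <- character(0)
    serial <- 0L
    for (i in seq_len(nrow(s))) {
      n <- counts[i]
      if (n == 0L) next
      rad <- sqrt(stats::runif(n, g$r^2, g$R^2))
      ang <- stats::runif(n, 0, 2 * pi)
      z <- stats::runif(n, s$z_lo[i], s$z_hi[i])
      out <- c(out, sprintf(
        "HETATM%5d NE   BLT B%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          NE",
        (serial + seq_len(n)) %% 100000L, i %% 10000L,
        rad * cos(ang), rad * sin(ang), z, 1.0, 0.0))
      serial <- serial + n
    }
    out
  })
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
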
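## Material library I/O: tabulated bead-surface potentials (PMFs), Hamaker
## files, and synthetic fixture generators.

#' Construct a tabulated bead-surface potential
#'
#' A `pmf_table` holds the solvent-averaged free-energy profile of one bead
#' type against a surface: strictly increasing distances (nm, surface to bead
#' center) and energies (kJ/mol), together with the geometry the table was
#' produced for and the vdW cutoff `r_c` used in that production run.
#'
#' @param bead_code Short bead code, e.g. a three-letter residue code.
#' @param distances Strictly increasing distances in nm.
#' @param energies Energies in kJ/mol, same length as `distances`.
#' @param source_geometry Either `"plane"`, `"none"`, or
#'   `list(type = "cylinder", radius = <nm>)`.
#' @param cutoff_rc vdW cutoff used when the table was produced, nm.
#' @param decay_tol Far-field tolerance in kJ/mol: a warning is recorded if the
#'   last tabulated energy exceeds it in magnitude (default 0.25 kJ/mol,
#'   about 0.1 kBT at 300 K).
#' @return An object of class `pmf_table`.
#' @export
pmf_table <- function(bead_code, distances, energies,
                      source_geometry = "plane", cutoff_rc = 1.0,
                      decay_tol = 0.25) {
  bead_code <- normalize_bead_code(bead_code)
  distances <- as.numeric(distances)
  energies <- as.numeric(energies)
  if (length(distances) == 0L)
    stop("PMF table is empty")
  if (length(distances) != length(energies))
    stop("distances and energies differ in length")
  if (any(!is.finite(distances)) || any(!is.finite(energies)))
    stop("PMF table contains non-finite values")
  if (any(diff(distances) <= 0))
    stop("PMF distances must be strictly increasing")
  if (is.character(source_geometry))
    source_geometry <- list(type = source_geometry)
  if (!source_geometry$type %in% c("plane", "cylinder", "none"))
    stop("source_geometry must be plane, cylinder or none")
  if (abs(energies[length(energies)]) > decay_tol)
    warning(sprintf("PMF for %s does not decay to 0 at its last point (%.3g kJ/mol)",
                    bead_code, energies[length(energies)]))
  structure(list(bead_code = bead_code, distances = distances,
                 energies = energies, source_geometry = source_geometry,
                 cutoff_rc = cutoff_rc),
            class = "pmf_table")
}

#' Read a comma-separated surface-potential table
#'
#' One file per bead code, rows `distance_nm,energy_kJmol`, `#` comments.
#' The historical fixed-width dialect is deprecated upstream and rejected here
#' with a clear message.
#'
#' @param path File path.
#' @param bead_code Bead code; defaults to the file name stem.
#' @inheritParams pmf_table
#' @return A [pmf_table].
#' @export
read_pmf_table <- function(path, bead_code = NULL, source_geometry = "plane",
                           cutoff_rc = 1.0) {
  if (!file.exists(path)) stop("PMF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  if (is.null(bead_code)) {
    hdr <- grep("^# *bead +", lines, value = TRUE)
    if (length(hdr))
      bead_code <- sub("^# *bead +(\\S+).*$", "\\1", hdr[1])
  }
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("PMF file is empty: ", path)
  if (!all(grepl(",", lines, fixed = TRUE))) {
    if (any(grepl("^[-0-9.eE+]+\\s+[-0-9.eE+]+", lines)))
      stop("fixed-width PMF dialect is deprecated and not supported; ",
           "use comma-separated 'distance,energy' rows: ", path)
    stop("malformed PMF file (expected 'distance,energy' rows): ", path)
  }
  parts <- strsplit(lines, ",", fixed = TRUE)
  if (any(lengths(parts) < 2L)) stop("malformed PMF row in ", path)
  d <- as.numeric(vapply(parts, `[[`, "", 1L))
  u <- as.numeric(vapply(parts, `[[`, "", 2L))
  if (is.null(bead_code))
    bead_code <- toupper(tools::file_path_sans_ext(basename(path)))
  pmf_table(bead_code, d, u, source_geometry = source_geometry,
            cutoff_rc = cutoff_rc)
}

#' Write a surface-potential table
#'
#' @param table A [pmf_table].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pmf_table <- function(table, path) {
  stopifnot(inherits(table, "pmf_table"))
  if (any(!is.finite(table$energies)))
    stop("refusing to write non-finite PMF energies")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# bead %s", table$bead_code),
    "# distance_nm,energy_kJmol",
    sprintf("%.6g,%.8g", table$distances, table$energies)
  ), con)
  invisible(path)
}

#' Linear interpolation of a surface potential
#'
#' Exact at tabulated points, 0 beyond the last point, and held at the first
#' tabulated value below the first point (the short-range stability wall of
#' the potentials module dominates there).
#'
#' @param table A [pmf_table].
#' @param d Distances in nm.
#' @return Energies in kJ/mol.
#' @export
pmf_interpolate <- function(table, d) {
  n <- length(table$distances)
  out <- stats::approx(table$distances, table$energies, xout = d,
                       rule = 2)$y
  out[d > table$distances[n]] <- 0
  out
}

#' Hamaker-constant set for one material
#'
#' One entry per bead code: the Hamaker constant `A_H` for that bead against
#' the material across water (kJ/mol) and the bead radius (nm).
#'
#' @param material_name Material name.
#' @param codes Character vector of bead codes (unique).
#' @param A_kJmol Hamaker constants in kJ/mol.
#' @param radius_nm Bead radii in nm (> 0).
#' @return Object of class `hamaker_set`.
#' @export
hamaker_set <- function(material_name, codes, A_kJmol, radius_nm) {
  codes <- normalize_bead_code(codes)
  if (anyDuplicated(codes)) stop("duplicate bead code in Hamaker set")
  if (any(radius_nm <= 0)) stop("bead radii must be positive")
  structure(list(material_name = material_name,
                 entries = data.frame(code = codes, A_kJmol = A_kJmol,
                                      radius_nm = radius_nm,
                                      stringsAsFactors = FALSE)),
            class = "hamaker_set")
}

#' Read / write a Hamaker file
#'
#' Text dialect: one record per bead, `CODE,A_kJmol,radius_nm`, `#` comments.
#'
#' @param path File path.
#' @param material_name Material name (defaults to the file stem).
#' @return A [hamaker_set].
#' @export
read_hamaker_file <- function(path, material_name = NULL) {
  if (!file.exists(path)) stop("Hamaker file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("Hamaker file is empty: ", path)
  parts <- strsplit(lines, ",", fixed = TRUE)
  if (any(lengths(parts) < 3L)) stop("malformed Hamaker record in ", path)
  if (is.null(material_name))
    material_name <- tools::file_path_sans_ext(basename(path))
  hamaker_set(material_name,
              vapply(parts, `[[`, "", 1L),
              as.numeric(vapply(parts, `[[`, "", 2L)),
              as.numeric(vapply(parts, `[[`, "", 3L)))
}

#' @param set A [hamaker_set].
#' @rdname read_hamaker_file
#' @export
write_hamaker_file <- function(set, path) {
  stopifnot(inherits(set, "hamaker_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# material %s", set$material_name),
    "# code,A_kJmol,radius_nm",
    sprintf("%s,%.8g,%.6g", set$entries$code, set$entries$A_kJmol,
            set$entries$radius_nm)
  ), con)
  invisible(path)
}

#' Material definition
#'
#' Binds a PMF directory and Hamaker file into one material with its source
#' geometry, production cutoff and default surface potential.
#'
#' @param name Material name.
#' @param pmf_directory Directory containing `<CODE>.dat` PMF tables.
#' @param hamaker_file Path to the Hamaker file.
#' @param source_geometry As for [pmf_table].
#' @param cutoff_rc Production vdW cutoff, nm.
#' @param default_psi0_mV Default surface potential, mV.
#' @return Object of class `material_definition`.
#' @export
material_definition <- function(name, pmf_directory, hamaker_file,
                                source_geometry = "plane", cutoff_rc = 1.0,
                                default_psi0_mV = 0) {
  structure(list(name = name, pmf_directory = pmf_directory,
                 hamaker_file = hamaker_file,
                 source_geometry = if (is.character(source_geometry))
                   list(type = source_geometry) else source_geometry,
                 cutoff_rc = cutoff_rc, default_psi0_mV = default_psi0_mV),
            class = "material_definition")
}

#' Load a material into memory
#'
#' Reads every PMF table in the material's directory plus its Hamaker file and
#' checks that each requested bead code resolves to both.
#'
#' @param definition A [material_definition].
#' @param bead_codes Codes that must resolve; default: all tables present.
#' @return Object of class `material` with elements `pmf` (named list of
#'   [pmf_table]) and `hamaker` ([hamaker_set]).
#' @export
load_material <- function(definition, bead_codes = NULL) {
  stopifnot(inherits(definition, "material_definition"))
  files <- list.files(definition$pmf_directory, pattern = "\\.dat$",
                      full.names = TRUE)
  pmfs <- lapply(files, read_pmf_table,
                 source_geometry = definition$source_geometry,
                 cutoff_rc = definition$cutoff_rc)
  names(pmfs) <- vapply(pmfs, `[[`, "", "bead_code")
  ham <- read_hamaker_file(definition$hamaker_file, definition$name)
  if (!is.null(bead_codes)) {
    bead_codes <- normalize_bead_code(bead_codes)
    missing_pmf <- setdiff(bead_codes, names(pmfs))
    missing_ham <- setdiff(bead_codes, ham$entries$code)
    if (length(missing_pmf) || length(missing_ham))
      stop("bead codes unresolved for material ", definition$name, ": ",
           paste(unique(c(missing_pmf, missing_ham)), collapse = ", "))
  }
  structure(list(definition = definition, pmf = pmfs, hamaker = ham),
            class = "material")
}

#' Generate a synthetic material library
#'
#' Writes, for each synthetic bead code, a 9-3 surface potential
#' `U(d) = eps * ((2/15) (sigma/d)^9 - (sigma/d)^3)` truncated and shifted to
#' zero at the cutoff, plus a Hamaker file with constants drawn uniformly in
#' `[0.05, 1]` kJ/mol and bead radius `sigma/2`. Deterministic per seed. The
#' analytic minimum of the untruncated form sits at `sigma * (2/5)^(1/6)`.
#'
#' @param directory Output directory (created).
#' @param n_beads Number of bead types (>= 1).
#' @param well_depth_range Range of `eps` in kJ/mol.
#' @param sigma_range Range of `sigma` in nm.
#' @param cutoff_rc Cutoff in nm.
#' @param seed Integer seed.
#' @param bead_codes Optional codes; defaults to standard residue codes.
#' @param psi0_mV Default surface potential for the material, mV.
#' @return A [material_definition] for the written library.
#' @export
generate_synthetic_material <- function(directory, n_beads = 5,
                                        well_depth_range = c(2, 10),
                                        sigma_range = c(0.25, 0.45),
                                        cutoff_rc = 1.0, seed = 1,
                                        bead_codes = NULL, psi0_mV = -20) {
  if (n_beads < 1) stop("n_beads must be >= 1")
  if (any(well_depth_range <= 0) || any(sigma_range <= 0) || cutoff_rc <= 0)
    stop("ranges and cutoff must be positive")
  if (is.null(bead_codes)) {
    if (n_beads > length(.standard_residues))
      stop("supply bead_codes for more than ", length(.standard_residues),
           " bead types")
    bead_codes <- .standard_residues[seq_len(n_beads)]
  }
  bead_codes <- normalize_bead_code(bead_codes)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  pmf_dir <- file.path(directory, "surface")
  dir.create(pmf_dir, showWarnings = FALSE)
  rng <- local({ set.seed(seed); NULL })
  set.seed(seed)
  eps <- runif(n_beads, well_depth_range[1], well_depth_range[2])
  sigma <- runif(n_beads, sigma_range[1], sigma_range[2])
  A_H <- runif(n_beads, 0.05, 1)
  u93 <- function(d, e, s) e * ((2 / 15) * (s / d)^9 - (s / d)^3)
  for (i in seq_len(n_beads)) {
    d <- seq(0.05, cutoff_rc, by = 0.01)
    u <- u93(d, eps[i], sigma[i]) - u93(cutoff_rc, eps[i], sigma[i])
    tab <- suppressWarnings(
      pmf_table(bead_codes[i], d, u, source_geometry = "plane",
                cutoff_rc = cutoff_rc))
    write_pmf_table(tab, file.path(pmf_dir, paste0(bead_codes[i], ".dat")))
  }
  ham_path <- file.path(directory, "hamaker.dat")
  write_hamaker_file(hamaker_set("synthetic", bead_codes, A_H, sigma / 2),
                     ham_path)
  material_definition("synthetic", pmf_dir, ham_path,
                      source_geometry = "plane", cutoff_rc = cutoff_rc,
                      default_psi0_mV = psi0_mV)
}

#' Generate a toy CA-bead biomolecule as a PDB file
#'
#' Writes a valid fixed-width PDB containing only CA atoms with occupancy 1.00
#' and coordinates in Angstroms. Geometries: `"helix"` (alpha-helix CA trace:
#' radius 2.3 A, rise 1.5 A per residue, 100 degrees per turn), `"line"`
#' (3.8 A spacing along x) and `"ring"` (circle with 3.8 A arc spacing).
#'
#' @param path Output path.
#' @param n_beads Number of residues (>= 1).
#' @param geometry One of `"helix"`, `"line"`, `"ring"`.
#' @param bead_codes Residue codes, recycled to `n_beads`.
#' @param seed Seed used to draw codes when `bead_codes` is `NULL`.
#' @return Invisibly, `path`.
#' @export
generate_toy_biomolecule <- function(path, n_beads = 10, geometry = "helix",
                                     bead_codes = NULL, seed = 1) {
  if (n_beads < 1) stop("n_beads must be >= 1")
  if (!geometry %in% c("helix", "line", "ring"))
    stop("unknown geometry: ", geometry)
  if (is.null(bead_codes)) {
    set.seed(seed)
    bead_codes <- sample(.standard_residues[1:5], n_beads, replace = TRUE)
  }
  bead_codes <- rep_len(normalize_bead_code(bead_codes), n_beads)
  i <- seq_len(n_beads) - 1
  xyz <- switch(geometry,
    line = cbind(3.8 * i, 0, 0),
    helix = cbind(2.3 * cos(i * 100 * pi / 180),
                  2.3 * sin(i * 100 * pi / 180),
                  1.5 * i),
    ring = {
      r <- n_beads * 3.8 / (2 * pi)
      th <- 2 * pi * i / n_beads
      cbind(r * cos(th), r * sin(th), 0)
    })
  if (n_beads == 1L) xyz <- matrix(0, 1, 3)
  lines <- sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(n_beads), bead_codes, seq_len(n_beads),
    xyz[, 1], xyz[, 2], xyz[, 3], 1.00, 0.00)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
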
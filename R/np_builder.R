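## Nanoparticle construction: beads, bounding radii, the .np CSV dialect and
## isotropic rotations.

.np_shapes <- c("sphere", "cylinder", "cube", "tube")
.np_corrections <- c("plane-sphere", "plane-cylinder", "cylinder-tube",
                     "cylinder-cylinder", "none")

#' Construct one NP bead
#'
#' A geometric building block of a composite nanoparticle: a sphere, cylinder,
#' cube or tube of one material with its own surface potential. Cylinders and
#' tubes have their axis along x by convention; cubes are treated through
#' their bounding sphere for closest-approach and electrostatic purposes.
#'
#' @param shape One of `"sphere"`, `"cylinder"`, `"cube"`, `"tube"`.
#' @param center Numeric length-3 center, nm.
#' @param radius Bead radius, nm (> 0).
#' @param material A [material_definition] or loaded [load_material] object.
#' @param psi0_mV Surface potential, mV.
#' @param correction PMF geometry-correction mode, one of
#'   `"plane-sphere"`, `"plane-cylinder"`, `"cylinder-tube"`,
#'   `"cylinder-cylinder"`, `"none"`.
#' @return Object of class `np_bead`.
#' @export
np_bead <- function(shape, center, radius, material, psi0_mV = 0,
                    correction = "plane-sphere") {
  shape <- match.arg(shape, .np_shapes)
  correction <- match.arg(correction, .np_corrections)
  if (radius <= 0) stop("NP bead radius must be positive")
  src <- if (inherits(material, "material")) material$definition else material
  if (inherits(src, "material_definition") && correction != "none") {
    src_type <- strsplit(correction, "-", fixed = TRUE)[[1]][1]
    if (!identical(src$source_geometry$type, src_type))
      stop("correction mode ", correction,
           " inconsistent with material source geometry ",
           src$source_geometry$type)
  }
  structure(list(shape = shape, center = as.numeric(center), radius = radius,
                 material = material, psi0_mV = psi0_mV,
                 correction = correction),
            class = "np_bead")
}

#' Assemble a nanoparticle from beads
#'
#' @param beads List of [np_bead].
#' @param shape_code Global coordinate-system code, 1..5 (1 sphere, 2 solid
#'   cylinder with plane-to-cylinder mapping, 3 cube with planar mapping,
#'   4 tube, 5 solid cylinder with cylinder-to-cylinder mapping).
#' @param R0b,R1b Optional manual core / outer bounding radii, nm.
#' @return Object of class `nanoparticle` with computed bounding radii.
#' @export
nanoparticle <- function(beads, shape_code = 1, R0b = NULL, R1b = NULL) {
  if (length(beads) == 0L) stop("nanoparticle needs at least one bead")
  np <- structure(list(beads = beads, shape_code = shape_code,
                       R0b = NULL, R1b = NULL),
                  class = "nanoparticle")
  br <- bounding_radii(np)
  np$R0b <- R0b %||% br[["R0b"]]
  np$R1b <- R1b %||% br[["R1b"]]
  if (np$R1b < np$R0b && is.null(R0b) && is.null(R1b))
    stop("inconsistent bounding radii")
  np
}

#' Bounding radii of a nanoparticle
#'
#' The outer bounding radius is `max_n(|r_n| + R_n)`; the core bounding radius
#' is `|r_m| + R_m` for the largest bead (ties broken by first index). Manual
#' overrides stored on the nanoparticle win.
#'
#' @param np A [nanoparticle].
#' @return Named numeric vector `c(R0b=, R1b=)`.
#' @export
bounding_radii <- function(np) {
  if (length(np$beads) == 0L) stop("empty bead list")
  if (!is.null(np$R0b) && !is.null(np$R1b))
    return(c(R0b = np$R0b, R1b = np$R1b))
  rn <- vapply(np$beads, function(b) sqrt(sum(b$center^2)), 0)
  Rn <- vapply(np$beads, `[[`, 0, "radius")
  m <- which.max(Rn)
  c(R0b = np$R0b %||% (rn[m] + Rn[m]), R1b = np$R1b %||% max(rn + Rn))
}

#' Build a simple one-bead nanoparticle
#'
#' @param shape_code 1 sphere, 2 solid cylinder (plane-to-cylinder mapping),
#'   3 cube (planar potentials used directly), 4 tube (cylinder-to-tube
#'   mapping), 5 solid cylinder (cylinder-to-cylinder mapping).
#' @param radius Radius, nm.
#' @param material Material for the bead.
#' @param psi0_mV Surface potential, mV.
#' @param length Optional cylinder length, nm (used by the KMC geometry).
#' @return A [nanoparticle].
#' @export
build_simple_np <- function(shape_code, radius, material, psi0_mV = 0,
                            length = NULL) {
  spec <- switch(as.character(shape_code),
    "1" = list(shape = "sphere", corr = "plane-sphere"),
    "2" = list(shape = "cylinder", corr = "plane-cylinder"),
    "3" = list(shape = "cube", corr = "none"),
    "4" = list(shape = "tube", corr = "cylinder-tube"),
    "5" = list(shape = "cylinder", corr = "cylinder-cylinder"),
    stop("unknown shape_code: ", shape_code))
  bead <- np_bead(spec$shape, c(0, 0, 0), radius, material, psi0_mV,
                  spec$corr)
  np <- nanoparticle(list(bead), shape_code = shape_code)
  np$length <- length
  np
}

#' Decorate a spherical core with a bead brush
#'
#' Brush beads are placed tangent to the core (center distance
#' `core_radius + brush_bead_radius`) on a Fibonacci lattice over the shell,
#' with a small seeded angular jitter, giving quasi-uniform coverage.
#'
#' @param core_radius Core radius, nm.
#' @param core_material,brush_material Materials.
#' @param n_brush Number of brush beads (>= 0).
#' @param brush_bead_radius Brush bead radius, nm.
#' @param seed Integer seed for the jitter.
#' @param psi0_mV Surface potential applied to all beads, mV.
#' @return A [nanoparticle].
#' @export
build_core_brush <- function(core_radius, core_material, brush_material,
                             n_brush, brush_bead_radius, seed = 1,
                             psi0_mV = 0) {
  if (n_brush < 0) stop("n_brush must be >= 0")
  core <- np_bead("sphere", c(0, 0, 0), core_radius, core_material, psi0_mV,
                  "plane-sphere")
  if (n_brush == 0L) return(nanoparticle(list(core)))
  shell_r <- core_radius + brush_bead_radius
  ## density cap: brush disks may not exceed ~90% of the shell area
  if (n_brush * pi * brush_bead_radius^2 > 0.9 * 4 * pi * shell_r^2)
    stop("brush density too high: beads would overlap strongly")
  set.seed(seed)
  i <- seq_len(n_brush) - 0.5
  golden <- pi * (3 - sqrt(5))
  theta <- acos(1 - 2 * i / n_brush)
  phi <- golden * (i - 0.5) + runif(1, 0, 2 * pi)
  jitter <- 0.05 * sqrt(4 / n_brush)
  theta <- pmin(pi, pmax(0, theta + rnorm(n_brush, 0, jitter)))
  phi <- phi + rnorm(n_brush, 0, jitter)
  beads <- c(list(core), lapply(seq_len(n_brush), function(k) {
    ctr <- shell_r * c(sin(theta[k]) * cos(phi[k]),
                       sin(theta[k]) * sin(phi[k]), cos(theta[k]))
    np_bead("sphere", ctr, brush_bead_radius, brush_material, psi0_mV,
            "plane-sphere")
  }))
  nanoparticle(beads)
}

#' Read / write the .np multicomponent nanoparticle format
#'
#' CSV dialect with `#` comments, one bead per row:
#' `shape,x,y,z,radius,material,psi0_mV,correction_mode` (nm and mV).
#'
#' @param path File path.
#' @param materials Named list of materials resolving the material column.
#' @param shape_code Global coordinate-system code for the loaded particle.
#' @return A [nanoparticle].
#' @export
read_np_file <- function(path, materials, shape_code = 1) {
  if (!file.exists(path)) stop(".np file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop(".np file is empty: ", path)
  beads <- lapply(lines, function(ln) {
    f <- trimws(strsplit(ln, ",", fixed = TRUE)[[1]])
    if (length(f) != 8L) stop("malformed .np row: ", ln)
    radius <- as.numeric(f[5])
    if (!is.finite(radius) || radius <= 0)
      stop("non-positive radius in .np row: ", ln)
    mat <- materials[[f[6]]]
    if (is.null(mat)) stop("unknown material in .np file: ", f[6])
    np_bead(f[1], as.numeric(f[2:4]), radius, mat, as.numeric(f[7]), f[8])
  })
  nanoparticle(beads, shape_code = shape_code)
}

#' @param np A [nanoparticle].
#' @rdname read_np_file
#' @export
write_np_file <- function(np, path) {
  stopifnot(inherits(np, "nanoparticle"))
  rows <- vapply(np$beads, function(b) {
    def <- if (inherits(b$material, "material")) b$material$definition
           else b$material
    nm <- if (is.character(def)) def else def$name
    sprintf("%s,%.9g,%.9g,%.9g,%.9g,%s,%.9g,%s", b$shape,
            b$center[1], b$center[2], b$center[3], b$radius, nm,
            b$psi0_mV, b$correction)
  }, "")
  writeLines(c("# shape,x,y,z,radius,material,psi0_mV,correction_mode", rows),
             path)
  invisible(path)
}

#' Apply one uniformly random rotation to all bead centers
#'
#' Samples a uniform unit quaternion (equivalent in distribution to Arvo's
#' method) and rotates every bead center by it; radii and attributes are
#' preserved, so the operation is an isometry of the bead arrangement.
#'
#' @param np A [nanoparticle].
#' @param seed Integer seed.
#' @return The rotated [nanoparticle].
#' @export
random_isotropic_rotation <- function(np, seed = 1) {
  set.seed(seed)
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  R <- quaternion_matrix(q)
  np$beads <- lapply(np$beads, function(b) {
    b$center <- as.numeric(R %*% b$center)
    b
  })
  np
}

quaternion_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
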
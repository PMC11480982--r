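## Orientation scanning: load CA bead models, rotate, sum bead potentials
## over the NP complex, integrate to adsorption free energies and write
## orientation maps (.uam).

#' Read a CA-only coarse-grained bead model from a PDB file
#'
#' Keeps ATOM records with atom name CA; the three-letter residue code
#' selects the bead type (protonation variants are aliased), the occupancy
#' column becomes the per-bead weight `alpha`, coordinates are converted from
#' Angstroms to nm, and the model is shifted so its center of mass is the
#' origin. Per-bead charges are assigned from the default residue table.
#'
#' @param path PDB file path.
#' @return Object of class `bead_model`: data.frame `beads` with columns
#'   `code, x, y, z, alpha, q` (nm, e) and a `name`.
#' @export
read_bead_model <- function(path) {
  pdb <- bio3d::read.pdb(path)
  sel <- bio3d::atom.select(pdb, "calpha", verbose = FALSE)
  at <- pdb$atom[sel$atom, ]
  if (nrow(at) == 0L) stop("no CA atoms found in ", path)
  alpha <- at$o
  alpha[is.na(alpha)] <- 1
  if (any(alpha == 0))
    warning("bead(s) with zero occupancy in ", basename(path),
            "; they will not contribute to the binding energy")
  codes <- normalize_bead_code(at$resid)
  beads <- data.frame(code = codes,
                      x = at$x / 10, y = at$y / 10, z = at$z / 10,
                      alpha = alpha, q = bead_charge(codes),
                      stringsAsFactors = FALSE)
  bead_model(beads, name = tools::file_path_sans_ext(basename(path)))
}

#' Construct a bead model
#'
#' @param beads data.frame with columns `code, x, y, z` and optionally
#'   `alpha` (default 1) and `q` (default from [bead_charge]); nm and e.
#' @param name Model name.
#' @return Object of class `bead_model`, COM-centered.
#' @export
bead_model <- function(beads, name = "model") {
  if (nrow(beads) == 0L) stop("bead model needs at least one bead")
  if (is.null(beads$alpha)) beads$alpha <- 1
  if (is.null(beads$q)) beads$q <- bead_charge(beads$code)
  beads$code <- normalize_bead_code(beads$code)
  com <- c(mean(beads$x), mean(beads$y), mean(beads$z))
  beads$x <- beads$x - com[1]
  beads$y <- beads$y - com[2]
  beads$z <- beads$z - com[3]
  structure(list(beads = beads, name = name), class = "bead_model")
}

#' Rotate a bead model into a scan orientation
#'
#' Applies `R_z(-phi)` then `R_y(180 - theta)` then optionally `R_z(omega)`,
#' all in degrees, so that the body direction
#' `(cos phi sin theta, sin phi sin theta, cos theta)` maps to `(0, 0, -1)`,
#' the surface normal pointing at the NP.
#'
#' @param model A [bead_model].
#' @param phi,theta,omega Angles in degrees.
#' @return The rotated [bead_model].
#' @export
rotate_model <- function(model, phi, theta, omega = 0) {
  xyz <- t(as.matrix(model$beads[, c("x", "y", "z")]))
  R <- rot_z(omega * pi / 180) %*% rot_y((180 - theta) * pi / 180) %*%
    rot_z(-phi * pi / 180)
  out <- t(R %*% xyz)
  model$beads$x <- out[, 1]
  model$beads$y <- out[, 2]
  model$beads$z <- out[, 3]
  model
}

rot_z <- function(a) matrix(c(cos(a), -sin(a), 0,
                              sin(a), cos(a), 0,
                              0, 0, 1), 3, 3, byrow = TRUE)
rot_y <- function(a) matrix(c(cos(a), 0, sin(a),
                              0, 1, 0,
                              -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)

## Presum tables for every bead type present in a model, keyed by code.
## Zero-weight beads never contribute and need no table.
presum_tables <- function(np, model, debye_length = 1, temperature = 300,
                          z_grid = NULL) {
  codes <- unique(model$beads$code[model$beads$alpha != 0])
  tabs <- lapply(codes, function(cd)
    presum_potential(np, cd, z_grid = z_grid, debye_length = debye_length,
                     temperature = temperature))
  names(tabs) <- codes
  tabs
}

#' Total biomolecule-NP potential at one COM offset
#'
#' The model must already be rotated; its center of mass is placed on the
#' z-axis at `h`. In `"presum"` mode each bead contributes the cached axial
#' table value read at the coordinate matching the global symmetry (radial
#' distance for spheres, axis distance for cylinders, height for planar
#' systems), plus a small overlap penalty (default 5 kBT per bead) if the
#' bead would sit inside an NP bead; in `"full"` mode every
#' bead-NP-bead pair is evaluated at its true three-dimensional closest
#' approach.
#'
#' @param np A [nanoparticle].
#' @param model A rotated [bead_model].
#' @param h COM offset(s) along z, nm.
#' @param mode `"presum"` or `"full"`.
#' @param tables Presum tables from an earlier call (presum mode); built on
#'   the fly when `NULL`.
#' @param debye_length,temperature Electrolyte screening length (nm) and
#'   temperature (K).
#' @param overlap_penalty_kT Penalty per overlapping bead, kBT.
#' @return Potential in kBT at each `h`.
#' @export
total_potential <- function(np, model, h, mode = c("presum", "full"),
                            tables = NULL, debye_length = 1,
                            temperature = 300, overlap_penalty_kT = 5) {
  mode <- match.arg(mode)
  kT <- kBT_kJmol(temperature)
  bd <- model$beads[model$beads$alpha != 0, , drop = FALSE]
  nb <- nrow(bd)
  nh <- length(h)
  if (nb == 0L) return(numeric(nh))
  if (mode == "presum") {
    if (is.null(tables))
      tables <- presum_tables(np, model, debye_length, temperature)
    zz <- outer(bd$z, h, "+")               # beads x offsets
    ## the axial table is read at the coordinate matching the global
    ## symmetry: radial distance for spheres, axis distance for cylinders,
    ## height for planar systems
    xx <- matrix(bd$x, nb, nh); yy <- matrix(bd$y, nb, nh)
    coord <- switch(as.character(np$shape_code),
      "1" = sqrt(xx^2 + yy^2 + zz^2),
      "2" = , "4" = , "5" = sqrt(yy^2 + zz^2),
      "3" = zz,
      sqrt(xx^2 + yy^2 + zz^2))
    u <- numeric(nh)
    for (cd in unique(bd$code)) {
      i <- bd$code == cd
      ui <- matrix(tables[[cd]]$fun(coord[i, , drop = FALSE]), sum(i), nh)
      u <- u + colSums(bd$alpha[i] * ui)
    }
    pen <- numeric(nh)
    for (b in np$beads) {
      dstar <- npb_dist_matrix(b, rep(bd$x, nh), rep(bd$y, nh), as.vector(zz))
      pen <- pen + overlap_penalty_kT *
        colSums(matrix(bd$alpha * (dstar < 0), nb, nh))
    }
    u / kT + pen
  } else {
    inters <- list()
    for (b_i in seq_along(np$beads)) {
      b <- np$beads[[b_i]]
      for (cd in unique(bd$code))
        inters[[paste(b_i, cd)]] <-
          build_bead_interaction(b, cd, debye_length, temperature)
    }
    zz <- outer(bd$z, h, "+")
    u <- numeric(nh)
    for (b_i in seq_along(np$beads)) {
      b <- np$beads[[b_i]]
      dstar <- matrix(npb_dist_matrix(b, rep(bd$x, nh), rep(bd$y, nh),
                                      as.vector(zz)), nb, nh)
      for (cd in unique(bd$code)) {
        i <- bd$code == cd
        di <- dstar[i, , drop = FALSE]
        ui <- di * 0
        pos <- di > 0
        if (any(pos))
          ui[pos] <- bead_np_potential(inters[[paste(b_i, cd)]], di[pos])
        if (any(!pos))
          ui[!pos] <- core_overlap_wall(di[!pos]) * kT
        u <- u + colSums(bd$alpha[i] * ui)
      }
    }
    u / kT
  }
}

## Vectorized closest approach of bead centers to one NP bead surface.
npb_dist_matrix <- function(b, x, y, z) {
  rx <- x - b$center[1]; ry <- y - b$center[2]; rz <- z - b$center[3]
  switch(b$shape,
    sphere = ,
    cube = sqrt(rx^2 + ry^2 + rz^2) - b$radius,
    cylinder = ,
    tube = sqrt(ry^2 + rz^2) - b$radius)
}

#' Integration bounds for the free-energy integral
#'
#' The inner bound is the COM distance at which the biomolecule, approaching
#' from infinity along the z-axis, first brings a bead center into contact
#' with an NP bead surface (clamped at zero); in full-scan mode it is instead
#' the smallest COM distance at which no bead center lies inside the core
#' bounding radius. The outer bound places the lowermost bead 2 nm above the
#' plane through `(0, 0, R1b)`.
#'
#' @param np A [nanoparticle].
#' @param model A rotated [bead_model].
#' @param full_scan Use the deep-scan inner bound.
#' @return `c(R_min, R_max)` in nm.
#' @export
integration_bounds <- function(np, model, full_scan = FALSE) {
  bd <- model$beads
  zmin <- min(bd$z)
  R_max <- np$R1b + 2 - zmin
  if (!full_scan) {
    ## first contact: largest xi with min_n,i d*(i, n) = 0
    cand <- 0
    for (b in np$beads) {
      ## bead i touches NP bead surface when |p_i(xi) - c| = R (spheres) etc.
      ## solve per bead for the largest xi
      rx <- bd$x - b$center[1]
      ry <- bd$y - b$center[2]
      R <- b$radius
      if (b$shape %in% c("sphere", "cube")) {
        lat2 <- rx^2 + ry^2
        ok <- lat2 <= R^2
        if (any(ok))
          cand <- max(cand, max(b$center[3] + sqrt(R^2 - lat2[ok]) -
                                  bd$z[ok]))
      } else {
        ok <- ry^2 <= R^2
        if (any(ok))
          cand <- max(cand, max(b$center[3] + sqrt(R^2 - ry[ok]^2) -
                                  bd$z[ok]))
      }
    }
    R_min <- max(0, cand)
  } else {
    ## smallest xi >= 0 with all |p_i| >= R0b
    R0 <- np$R0b
    lat2 <- bd$x^2 + bd$y^2
    ok <- lat2 < R0^2
    if (!any(ok)) {
      R_min <- 0
    } else {
      ## bead i sits inside the core for xi in (-z_i - s_i, -z_i + s_i);
      ## take the smallest non-negative xi outside every such interval
      s <- sqrt(R0^2 - lat2[ok])
      lo <- -bd$z[ok] - s
      hi <- -bd$z[ok] + s
      ord <- order(lo)
      xi <- 0
      for (j in ord)
        if (xi > lo[j] && xi < hi[j]) xi <- hi[j]
      R_min <- xi
    }
  }
  if (R_max <= R_min) R_max <- R_min + 2
  c(R_min = R_min, R_max = R_max)
}

#' Free-energy integral over a potential profile
#'
#' `E = -kBT ln[ \int xi^a exp(-U/kBT) dxi / \int xi^a dxi ]` with `a = 2`
#' for spherical, 1 for cylindrical and 0 for planar coordinate systems,
#' evaluated by trapezoidal quadrature. With `U == 0` the normalization makes
#' the result exactly zero.
#'
#' @param U Function of xi returning kBT, or a numeric vector on the grid.
#' @param bounds `c(R_min, R_max)`, nm.
#' @param alpha Coordinate exponent (2 sphere, 1 cylinder, 0 plane).
#' @param step Quadrature step, nm.
#' @return Energy in kBT.
#' @export
free_energy_integral <- function(U, bounds, alpha = 2, step = 0.05) {
  if (bounds[2] <= bounds[1]) stop("R_max must exceed R_min")
  xi <- seq(bounds[1], bounds[2], by = step)
  if (xi[length(xi)] < bounds[2]) xi <- c(xi, bounds[2])
  u <- if (is.function(U)) U(xi) else U
  if (length(u) != length(xi)) stop("potential grid mismatch")
  w <- xi^alpha
  num <- trapz(xi, w * exp(-pmin(u, .wall_cap_kT)))
  den <- trapz(xi, w)
  -log(num / den)
}

.alpha_for_shape_code <- function(shape_code) {
  switch(as.character(shape_code), "1" = 2, "2" = 1, "4" = 1, "5" = 1,
         "3" = 0, 2)
}

#' Orientation-specific adsorption energy
#'
#' Integrates the Boltzmann factor of the summed potential over the COM
#' offset between the automatically chosen bounds, returning the adsorption
#' free energy together with the minimum bead-surface distance and the number
#' of beads in close contact (surface distance under 0.5 nm) at the potential
#' minimum.
#'
#' @inheritParams total_potential
#' @param orientation `c(phi, theta)` or `c(phi, theta, omega)` in degrees.
#' @param full_scan Passed to [integration_bounds].
#' @param step Quadrature step, nm.
#' @return List with `E_kT`, `E_kJmol`, `min_dist`, `contact_count`,
#'   `bounds`.
#' @export
adsorption_energy <- function(np, model, orientation = c(0, 180, 0),
                              mode = "presum", tables = NULL,
                              debye_length = 1, temperature = 300,
                              full_scan = FALSE, step = 0.05) {
  rot <- rotate_model(model, orientation[1], orientation[2],
                      if (length(orientation) > 2) orientation[3] else 0)
  bounds <- integration_bounds(np, rot, full_scan)
  xi <- seq(bounds[1], bounds[2], by = step)
  if (xi[length(xi)] < bounds[2]) xi <- c(xi, bounds[2])
  u <- total_potential(np, rot, xi, mode = mode, tables = tables,
                       debye_length = debye_length,
                       temperature = temperature)
  alpha <- .alpha_for_shape_code(np$shape_code)
  w <- xi^alpha
  num <- trapz(xi, w * exp(-pmin(u, .wall_cap_kT)))
  den <- trapz(xi, w)
  E <- -log(num / den)
  ## contact metadata at the potential minimum
  hmin <- xi[which.min(u)]
  dmin <- Inf
  for (b in np$beads)
    dmin <- pmin(dmin, npb_dist_matrix(b, rot$beads$x, rot$beads$y,
                                       rot$beads$z + hmin))
  list(E_kT = E, E_kJmol = E * kBT_kJmol(temperature),
       min_dist = min(dmin), contact_count = sum(dmin < 0.5),
       bounds = bounds)
}

#' Scan biomolecule orientations against a nanoparticle
#'
#' Divides the `(phi, theta)` sphere into cells of `grid_deg` degrees
#' (default 5), draws `n_subsamples` (default 64) uniform orientations per
#' cell from a per-cell seeded stream, computes the adsorption energy of
#' each, and records per cell the (optionally Boltzmann-weighted) mean and
#' standard deviation at the cell's left-hand edge.
#'
#' @inheritParams adsorption_energy
#' @param seed Master seed; per-cell streams are derived by counter so cell
#'   results are order-independent.
#' @param averaging `"simple"` or `"boltzmann_local"`.
#' @param omega_list Values of the third angle to scan (default 0).
#' @param grid_deg Cell size in degrees (must divide 360 and 180).
#' @param n_subsamples Subsamples per cell.
#' @return Object of class `adsorption_map`: data.frame `rows` with columns
#'   `phi, theta, omega, E_kT, E_kJmol, sd_kT, mfpt, min_dist, contacts`,
#'   plus scan metadata.
#' @export
scan_orientations <- function(np, model, seed = 1,
                              averaging = c("simple", "boltzmann_local"),
                              omega_list = 0, grid_deg = 5,
                              n_subsamples = 64, mode = "presum",
                              debye_length = 1, temperature = 300,
                              full_scan = FALSE, step = 0.05) {
  averaging <- match.arg(averaging)
  stopifnot(360 %% grid_deg == 0, 180 %% grid_deg == 0)
  tables <- if (mode == "presum")
    presum_tables(np, model, debye_length, temperature) else NULL
  phis <- seq(0, 360 - grid_deg, by = grid_deg)
  thetas <- seq(0, 180 - grid_deg, by = grid_deg)
  grid <- expand.grid(omega = omega_list, theta = thetas, phi = phis)
  grid <- grid[, c("phi", "theta", "omega")]
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    set.seed((seed + 7919L * k) %% .Machine$integer.max)
    ph <- grid$phi[k] + runif(n_subsamples, 0, grid_deg)
    th <- grid$theta[k] + runif(n_subsamples, 0, grid_deg)
    res <- lapply(seq_len(n_subsamples), function(j)
      adsorption_energy(np, model, c(ph[j], th[j], grid$omega[k]),
                        mode = mode, tables = tables,
                        debye_length = debye_length,
                        temperature = temperature, full_scan = full_scan,
                        step = step))
    E <- vapply(res, `[[`, 0, "E_kT")
    Ebar <- if (averaging == "simple") mean(E)
            else sum(E * exp(-(E - min(E)))) / sum(exp(-(E - min(E))))
    data.frame(phi = grid$phi[k], theta = grid$theta[k],
               omega = grid$omega[k], E_kT = Ebar,
               E_kJmol = Ebar * kBT_kJmol(temperature),
               sd_kT = if (n_subsamples > 1) stats::sd(E) else 0,
               mfpt = -1,
               min_dist = mean(vapply(res, `[[`, 0, "min_dist")),
               contacts = mean(vapply(res, `[[`, 0, "contact_count")))
  })
  structure(list(rows = do.call(rbind, rows), grid_deg = grid_deg,
                 n_subsamples = n_subsamples, name = model$name,
                 radius = np$beads[[1]]$radius,
                 zeta = np$beads[[1]]$psi0_mV,
                 temperature = temperature),
            class = "adsorption_map")
}

#' Orientation averages of an adsorption map
#'
#' `simple_average` is the sin(theta)-weighted mean over cells, with theta
#' taken at the cell center (left edge + half a cell, in radians);
#' `boltzmann_average` additionally weights each cell by its Boltzmann
#' factor, and so is bounded above by the simple average.
#'
#' @param map An `adsorption_map`.
#' @return Mean adsorption energy in kBT.
#' @export
simple_average <- function(map) {
  r <- map$rows
  w <- sin((r$theta + map$grid_deg / 2) * pi / 180)
  sum(w * r$E_kT) / sum(w)
}

#' @param temperature Temperature in K (energies are already in kBT at the
#'   map's scan temperature; a different value rescales the weights only).
#' @rdname simple_average
#' @export
boltzmann_average <- function(map, temperature = NULL) {
  r <- map$rows
  scale <- if (is.null(temperature)) 1
           else map$temperature / temperature
  w <- sin((r$theta + map$grid_deg / 2) * pi / 180) *
    exp(-(r$E_kT - min(r$E_kT)) * scale)
  sum(w * r$E_kT) / sum(w)
}

#' Abundance-weighted average over multiple surface maps
#'
#' Generalizes the orientation averages with a per-surface weight reflecting
#' the abundance of each surface type (facets, Janus faces, omega slices).
#'
#' @param maps List of `adsorption_map`s.
#' @param weights Numeric surface weights.
#' @param boltzmann Use the Boltzmann-weighted local form.
#' @return Mean adsorption energy in kBT.
#' @export
multi_surface_average <- function(maps, weights, boltzmann = FALSE) {
  stopifnot(length(maps) == length(weights))
  num <- 0; den <- 0
  Emin <- min(vapply(maps, function(m) min(m$rows$E_kT), 0))
  for (j in seq_along(maps)) {
    r <- maps[[j]]$rows
    w <- sin((r$theta + maps[[j]]$grid_deg / 2) * pi / 180)
    if (boltzmann) w <- w * exp(-(r$E_kT - Emin))
    num <- num + weights[j] * sum(w * r$E_kT)
    den <- den + weights[j] * sum(w)
  }
  num / den
}

#' Write / read orientation maps (.uam)
#'
#' Whitespace-delimited columns `phi theta omega E_kT E_kJmol sd mfpt
#' min_dist contacts`, with the file named `<name>_<radius>_<zeta>.uam`. The
#' mean-first-passage-time column always contains -1.
#'
#' @param map An `adsorption_map`.
#' @param outdir Output directory.
#' @param name,radius,zeta Override the map's metadata in the filename.
#' @return The path written.
#' @export
write_uam <- function(map, outdir, name = NULL, radius = NULL, zeta = NULL) {
  name <- name %||% map$name
  radius <- radius %||% map$radius
  zeta <- zeta %||% map$zeta
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(outdir, sprintf("%s_%s_%s.uam", name,
                                    format(radius, trim = TRUE),
                                    format(zeta, trim = TRUE)))
  hdr <- sprintf("# %s radius %s zeta %s grid %g subsamples %d",
                 name, format(radius), format(zeta), map$grid_deg,
                 map$n_subsamples)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr,
               "# phi theta omega E_kT E_kJmol sd_kT mfpt min_dist contacts"),
             con)
  utils::write.table(format(map$rows, digits = 8, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  path
}

#' @param path A .uam file path.
#' @rdname write_uam
#' @export
read_uam <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- regmatches(first, regexec(
    "^# (\\S+) radius (\\S+) zeta (\\S+) grid (\\S+) subsamples (\\S+)",
    first))[[1]]
  rows <- utils::read.table(path, comment.char = "#",
                            col.names = c("phi", "theta", "omega", "E_kT",
                                          "E_kJmol", "sd_kT", "mfpt",
                                          "min_dist", "contacts"))
  structure(list(rows = rows,
                 grid_deg = if (length(meta)) as.numeric(meta[5]) else 5,
                 n_subsamples = if (length(meta)) as.integer(meta[6]) else 64,
                 name = if (length(meta)) meta[2] else
                   tools::file_path_sans_ext(basename(path)),
                 radius = if (length(meta)) as.numeric(meta[3]) else NA,
                 zeta = if (length(meta)) as.numeric(meta[4]) else NA,
                 temperature = 300),
            class = "adsorption_map")
}
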
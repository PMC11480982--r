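## Bead-nanoparticle interaction potentials: tabulated surface term with
## geometry remapping, Hamaker-like dispersion with a cutoff exclusion
## region, screened electrostatics, and the short-range stability wall.
##
## Distance convention throughout: d is measured from the nominal surface of
## the NP bead to the center of the adsorbate bead, matching the tabulated
## surface potentials and the point-charge electrostatic forms.

.pot_cache <- new.env(parent = emptyenv())

#' Clear cached geometry-correction and Hamaker grids
#' @export
clear_potential_cache <- function() {
  rm(list = ls(.pot_cache), envir = .pot_cache)
  invisible(NULL)
}

## ---- truncated r^-6 volume integrals -------------------------------------
## Each returns int over {NP-side volume within r_c of the bead center} of
## |r|^-6 dV for a bead center at distance d from the NP surface.

## Half-space: analytic. Shells of radius s in [d, rc] intersect the
## half-space in caps of area 2 pi s (s - d).
r6_halfspace <- function(d, rc) {
  out <- numeric(length(d))
  ok <- d > 0 & d < rc
  dd <- d[ok]
  out[ok] <- 2 * pi * (dd^-3 / 12 - rc^-3 / 3 + dd * rc^-4 / 4)
  out
}

## Sphere of radius R: 1-D quadrature over shell radius s; the cap of the
## shell inside the NP ball has area 2 pi s^2 (1 - cos(theta)).
r6_sphere_vol <- function(d, R, rc, n = 400) {
  vapply(d, function(di) {
    if (di <= 0 || di >= rc) return(0)
    z <- R + di
    s <- seq(di, min(rc, z + R), length.out = n)
    ct <- (z^2 + s^2 - R^2) / (2 * z * s)
    area <- 2 * pi * s^2 * pmin(2, pmax(0, 1 - ct))
    trapz(s, s^-6 * area)
  }, 0)
}

## Fraction of the surface of a sphere (radius s, center at perpendicular
## distance z from the axis) lying inside an infinite cylinder of radius R.
## Vectorized over z for a single s: integrates the allowed azimuth fraction
## over the axis-parallel component u of the surface normal.
cyl_sphere_fraction <- function(z, s, R, nu = 64) {
  u <- seq(0, 1, length.out = nu)       # component along the cylinder axis
  su2 <- 1 - u^2
  su <- sqrt(pmax(0, su2))
  Z <- matrix(z, length(z), nu)
  SU <- matrix(su, length(z), nu, byrow = TRUE)
  SU2 <- matrix(su2, length(z), nu, byrow = TRUE)
  g <- (R^2 - Z^2 - s^2 * SU2) / (2 * Z * s * SU)
  bad <- !is.finite(g)
  if (any(bad))
    g[bad] <- ifelse((R^2 - Z^2 - s^2 * SU2)[bad] >= 0, Inf, -Inf)
  g <- pmax(pmin(g, 1), -1)    # order keeps the matrix dim on g
  frac <- 1 - acos(g) / pi
  ## trapezoid over u (uniform grid)
  du <- u[2] - u[1]
  rowSums(frac) * du - (frac[, 1] + frac[, nu]) * du / 2
}

r6_cylinder_vol <- function(d, R, rc, n = 200) {
  vapply(d, function(di) {
    if (di <= 0 || di >= rc) return(0)
    z <- R + di
    s <- seq(di, rc, length.out = n)
    frac <- vapply(s, function(sk) cyl_sphere_fraction(z, sk, R), 0)
    trapz(s, s^-6 * 4 * pi * s^2 * frac)
  }, 0)
}

r6_tube_vol <- function(d, R, rc, wall = 0.34) {
  outer_i <- r6_cylinder_vol(d, R, rc)
  if (R - wall <= 0) return(outer_i)
  outer_i - r6_cylinder_vol(d + wall, R - wall, rc)
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

## ---- geometry correction (tabulated-potential remapping) ------------------

#' Geometry-correction factor for tabulated surface potentials
#'
#' Ratio of the r^-6 vdW integral over the target NP volume (truncated at the
#' production cutoff `r_c` around the bead center) to the same integral over
#' the source geometry the table was produced for, so that
#' `U_target(d) = f(d) * U_source(d)`. Supported mappings: plane to sphere,
#' plane to cylinder, cylinder to tube, and cylinder to cylinder. For
#' `d >= r_c` both truncated volumes vanish and the factor is 1 by
#' continuity.
#'
#' @param d Distance(s) from NP surface to bead center, nm.
#' @param source_geom `"plane"` or `list(type="cylinder", radius=)`.
#' @param target_geom One of `"sphere"`, `"cylinder"`, `"tube"`.
#' @param R_target Target NP radius, nm.
#' @param r_c Production cutoff, nm.
#' @param tube_wall Tube wall thickness, nm.
#' @return Dimensionless factor(s), same length as `d`.
#' @export
geometry_correction_factor <- function(d, source_geom, target_geom, R_target,
                                       r_c, tube_wall = 0.34) {
  if (is.character(source_geom)) source_geom <- list(type = source_geom)
  pair <- paste(source_geom$type, target_geom, sep = "-")
  if (identical(source_geom$type, target_geom) &&
      source_geom$type == "plane")
    return(rep(1, length(d)))
  ok_pairs <- c("plane-sphere", "plane-cylinder", "cylinder-tube",
                "cylinder-cylinder")
  if (!pair %in% ok_pairs)
    stop("unsupported geometry mapping: ", pair)
  key <- sprintf("gc|%s|%.5g|%.5g|%.5g", pair, R_target, r_c,
                 source_geom$radius %||% 0)
  tab <- .pot_cache[[key]]
  if (is.null(tab)) {
    dg <- seq(0.005, r_c, by = 0.005)
    num <- switch(target_geom,
      sphere = r6_sphere_vol(dg, R_target, r_c),
      cylinder = r6_cylinder_vol(dg, R_target, r_c),
      tube = r6_tube_vol(dg, R_target, r_c, tube_wall),
      stop("unsupported target geometry: ", target_geom))
    den <- switch(source_geom$type,
      plane = r6_halfspace(dg, r_c),
      cylinder = r6_cylinder_vol(dg, source_geom$radius, r_c),
      stop("unsupported source geometry: ", source_geom$type))
    f <- ifelse(den > 0, num / den, 1)
    tab <- list(d = dg, f = f)
    .pot_cache[[key]] <- tab
  }
  out <- rep(1, length(d))
  inside <- d > 0 & d < r_c
  if (any(inside))
    out[inside] <- stats::approx(tab$d, tab$f, xout = d[inside],
                                 rule = 2)$y
  out
}

## ---- interaction container ------------------------------------------------

#' Bead-nanoparticle-bead interaction parameters
#'
#' Bundles everything needed to evaluate the three interaction components of
#' one adsorbate bead type against one NP bead: the tabulated surface
#' potential, the Hamaker constant and bead radius, the bead charge, the NP
#' surface potential and screening length, the production cutoff, and the
#' target geometry.
#'
#' @param pmf A [pmf_table] (or `NULL` to disable the surface term).
#' @param A_H Hamaker constant, kJ/mol.
#' @param bead_radius Adsorbate bead radius, nm.
#' @param q Bead charge, elementary charges.
#' @param psi0_mV NP surface potential, mV.
#' @param debye_length Debye screening length, nm (> 0).
#' @param cutoff_rc Production cutoff, nm.
#' @param geometry `list(type = "sphere"|"cylinder"|"cube"|"tube"|"plane",
#'   R = <nm>)` of the target NP bead.
#' @param correction Geometry-correction mode as in [np_bead], or `"none"`.
#' @param temperature Temperature, K.
#' @return Object of class `bead_np_interaction`.
#' @export
bead_np_interaction <- function(pmf = NULL, A_H = 0, bead_radius = 0.3,
                                q = 0, psi0_mV = 0, debye_length = 1,
                                cutoff_rc = 1, geometry = list(type = "sphere", R = 5),
                                correction = "plane-sphere",
                                temperature = 300) {
  if (debye_length <= 0) stop("debye_length must be positive")
  if (cutoff_rc <= 0) stop("cutoff_rc must be positive")
  structure(list(pmf = pmf, A_H = A_H, bead_radius = bead_radius, q = q,
                 psi0_mV = psi0_mV, debye_length = debye_length,
                 cutoff_rc = cutoff_rc, geometry = geometry,
                 correction = correction, temperature = temperature),
            class = "bead_np_interaction")
}

#' Tabulated surface potential with geometry remapping
#'
#' Linear interpolation of the stored table times the geometry-correction
#' factor; zero beyond the last tabulated distance; correction `"none"`
#' returns the table value unchanged.
#'
#' @param interaction A [bead_np_interaction].
#' @param d Distances, nm (> 0).
#' @return Energies in kJ/mol.
#' @export
surface_potential <- function(interaction, d) {
  if (is.null(interaction$pmf)) return(numeric(length(d)))
  u <- pmf_interpolate(interaction$pmf, d)
  if (identical(interaction$correction, "none")) return(u)
  target <- strsplit(interaction$correction, "-", fixed = TRUE)[[1]][2]
  f <- geometry_correction_factor(d, interaction$pmf$source_geometry, target,
                                  interaction$geometry$R,
                                  interaction$cutoff_rc)
  u * f
}

## ---- Hamaker-like dispersion ----------------------------------------------

## Closed-form r^-6 double-volume integral for two balls, center distance C.
## The classic two-sphere dispersion energy is -(A/pi^2) times this.
r6_two_balls <- function(C, R1, R2) {
  num <- C^2 - (R1 + R2)^2
  den <- C^2 - (R1 - R2)^2
  (pi^2 / 6) * (2 * R1 * R2 / num + 2 * R1 * R2 / den + log(num / den))
}

## Pair-distance reduction for ball-ball: m(s) ds is the measure of point
## pairs (one in each ball) at separation in [s, s+ds]; centers distance C.
pair_density_ball_ball <- function(s, C, R_np, r_b, nu = 1024) {
  u <- seq(max(C - r_b, 1e-9), C + r_b, length.out = nu)
  ca <- (u^2 + C^2 - r_b^2) / (2 * u * C)
  w <- 2 * pi * u^2 * pmin(2, pmax(0, 1 - ca))   # shell area inside AB ball
  vapply(s, function(sk) {
    ct <- (u^2 + sk^2 - R_np^2) / (2 * u * sk)
    cap <- 2 * pi * sk^2 * pmin(2, pmax(0, 1 - ct))
    trapz(u, w * cap)
  }, 0)
}

## Pair-distance reduction for ball vs infinite cylinder (radius R, axis
## distance of the ball center Z).
pair_density_ball_cylinder <- function(s, Z, R, r_b, nrho = 48, nphi = 96) {
  rho <- seq(max(Z - r_b, 1e-9), Z + r_b, length.out = nrho)
  phi <- seq(0, 2 * pi, length.out = nphi)
  ## p(rho): measure of AB-ball points at axis distance rho
  p <- vapply(rho, function(rk) {
    delta2 <- rk^2 + Z^2 - 2 * rk * Z * cos(phi)
    chord <- 2 * sqrt(pmax(0, r_b^2 - delta2))
    rk * trapz(phi, chord)
  }, 0)
  vapply(s, function(sk) {
    a <- 4 * pi * sk^2 * cyl_sphere_fraction(rho, sk, R)
    trapz(rho, p * a)
  }, 0)
}

#' Hamaker-like dispersion potential with cutoff exclusion
#'
#' Integrated vdW attraction `-(A_H/pi^2) \iint |r1 - r2|^-6` over the NP
#' volume and the adsorbate-bead sphere, restricted to point pairs separated
#' by more than the production cutoff `r_c` (those closer are already covered
#' by the tabulated surface potential). For a spherical NP the unrestricted
#' part is the classic two-sphere closed form and the excluded near-pair part
#' is integrated numerically; cylinders and tubes are evaluated numerically
#' throughout; cubes use their bounding sphere. The result is smooth across
#' the separation where the exclusion region empties and reduces to the
#' standard two-sphere expression in the far field.
#'
#' @inheritParams surface_potential
#' @return Energies in kJ/mol.
#' @export
hamaker_potential <- function(interaction, d) {
  if (any(d <= 0)) stop("hamaker_potential requires positive distances")
  if (interaction$A_H == 0) return(numeric(length(d)))
  geom <- interaction$geometry
  key <- sprintf("ham|%s|%.5g|%.5g|%.5g|%s", geom$type, geom$R,
                 interaction$bead_radius, interaction$cutoff_rc,
                 format(interaction$A_H, digits = 8))
  tab <- .pot_cache[[key]]
  if (is.null(tab)) {
    r_b <- interaction$bead_radius
    rc <- interaction$cutoff_rc
    dmax <- max(10 * max(rc, 1), 4 * geom$R)
    dg <- sort(unique(c(seq(r_b + 0.02, r_b + 2 * rc, by = 0.02),
                        seq(r_b + 2 * rc, dmax, length.out = 60))))
    vals <- switch(geom$type,
      sphere = ,
      cube = hamaker_sphere_grid(dg, geom$R, r_b, rc),
      cylinder = hamaker_cylinder_grid(dg, geom$R, r_b, rc),
      tube = {
        outer_v <- hamaker_cylinder_grid(dg, geom$R, r_b, rc)
        wall <- 0.34
        if (geom$R - wall > 0)
          outer_v - hamaker_cylinder_grid(dg + wall, geom$R - wall, r_b, rc)
        else outer_v
      },
      plane = hamaker_sphere_grid(dg, 2000, r_b, rc),
      stop("unsupported NP geometry for Hamaker term: ", geom$type))
    tab <- list(d = dg, I = vals)
    .pot_cache[[key]] <- tab
  }
  dc <- pmax(d, tab$d[1])                 # held at contact; wall dominates
  I <- stats::approx(tab$d, tab$I, xout = pmin(dc, max(tab$d)), rule = 2)$y
  if (geom$type %in% c("sphere", "cube", "plane")) {
    ## once the exclusion region is empty the closed form is exact
    Rs <- if (geom$type == "plane") 2000 else geom$R
    far <- dc - interaction$bead_radius >= interaction$cutoff_rc
    if (any(far))
      I[far] <- r6_two_balls(Rs + dc[far], Rs, interaction$bead_radius)
  }
  -(interaction$A_H / pi^2) * I
}

hamaker_sphere_grid <- function(d, R, r_b, rc) {
  vapply(d, function(di) {
    C <- R + di
    gap <- di - r_b
    if (gap <= 0) gap <- 1e-6
    I_full <- r6_two_balls(C, R, r_b)
    if (gap >= rc) return(I_full)
    s <- gap + (rc - gap) * seq(0, 1, length.out = 300)^2
    m <- pair_density_ball_ball(s, C, R, r_b)
    I_full - trapz(s, s^-6 * m)
  }, 0)
}

hamaker_cylinder_grid <- function(d, R, r_b, rc) {
  vapply(d, function(di) {
    Z <- R + di
    gap <- max(di - r_b, 1e-6)
    smax <- max(3 * (R + di), rc + 20)
    s <- exp(seq(log(max(rc, gap)), log(smax), length.out = 120))
    m <- pair_density_ball_cylinder(s, Z, R, r_b)
    trapz(s, s^-6 * m)
  }, 0)
}

## ---- electrostatics --------------------------------------------------------

#' Screened electrostatic potential (linearized Debye-Hueckel)
#'
#' Point-charge bead against a uniformly charged NP surface held at
#' `psi0`: sphere `q psi0 (R/(R+d)) exp(-kappa d)`, plane
#' `q psi0 exp(-kappa d)`, cylinder `q psi0 K0(kappa (R+d)) / K0(kappa R)`.
#' Cube beads use the planar form; tubes the cylindrical one. Converted from
#' e.mV to kJ/mol (1 e.mV = 0.09649 kJ/mol).
#'
#' @inheritParams surface_potential
#' @param geometry Optional override of the interaction's geometry type.
#' @return Energies in kJ/mol.
#' @export
electrostatic_potential <- function(interaction, d, geometry = NULL) {
  g <- geometry %||% interaction$geometry$type
  if (interaction$q == 0) return(numeric(length(d)))
  kappa <- 1 / interaction$debye_length
  R <- interaction$geometry$R
  pref <- interaction$q * interaction$psi0_mV * .emV_kJmol
  shape <- switch(g,
    sphere = (R / (R + d)) * exp(-kappa * d),
    plane = ,
    cube = exp(-kappa * d),
    cylinder = ,
    tube = besselK(kappa * (R + d), 0) / besselK(kappa * R, 0),
    stop("unsupported geometry for electrostatics: ", g))
  pref * shape
}

## ---- stability wall --------------------------------------------------------

#' Extreme-short-range stability wall
#'
#' `U_x(h) = (0.1/h)^12 - 1` in units of kBT for `h <= 0.1` nm and 0 above,
#' continuous at 0.1 nm; capped at 1e6 kBT (non-positive `h` returns the
#' cap) so that free-energy integrands underflow to zero rather than
#' diverging.
#'
#' @param h Distance from the NP surface to the bead center, nm.
#' @return Energies in kBT.
#' @export
core_overlap_wall <- function(h) {
  out <- numeric(length(h))
  low <- h <= 0.1
  hh <- pmax(h[low], 0)
  out[low] <- pmin((0.1 / hh)^12 - 1, .wall_cap_kT)
  out[h <= 0] <- .wall_cap_kT
  out
}

## ---- total bead-NP potential ----------------------------------------------

#' Total bead-NP-bead potential
#'
#' Sum of the remapped surface term, the Hamaker-like term, the screened
#' electrostatic term and the stability wall, in kJ/mol. With
#' `components = TRUE` returns a data.frame resolving the individual terms
#' for diagnostics.
#'
#' @inheritParams surface_potential
#' @param components Return the component-resolved table instead of the sum.
#' @return Energies in kJ/mol, or a data.frame of components.
#' @export
bead_np_potential <- function(interaction, d, components = FALSE) {
  us <- surface_potential(interaction, d)
  uh <- if (interaction$A_H != 0) hamaker_potential(interaction, d)
        else numeric(length(d))
  ue <- electrostatic_potential(interaction, d)
  uw <- core_overlap_wall(d) * kBT_kJmol(interaction$temperature)
  if (components)
    return(data.frame(d = d, surface = us, hamaker = uh,
                      electrostatic = ue, wall = uw,
                      total = us + uh + ue + uw))
  us + uh + ue + uw
}

#' Dump component-resolved potentials to CSV
#'
#' @inheritParams surface_potential
#' @param path Output CSV path.
#' @return Invisibly, the component data.frame.
#' @export
dump_potential_csv <- function(interaction, d, path) {
  df <- bead_np_potential(interaction, d, components = TRUE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(df)
}

## ---- presummed NP-complex potential ---------------------------------------

## Geometry-specific closest approach of a point p to an NP bead surface.
## Cylinders and tubes have their axis along x through the bead center;
## cubes use their bounding sphere.
npb_closest_approach <- function(bead, p) {
  rel <- p - bead$center
  switch(bead$shape,
    sphere = ,
    cube = sqrt(sum(rel^2)) - bead$radius,
    cylinder = ,
    tube = sqrt(rel[2]^2 + rel[3]^2) - bead$radius)
}

build_bead_interaction <- function(npb, bead_code, debye_length = 1,
                                   temperature = 300, charge = NULL) {
  mat <- npb$material
  if (inherits(mat, "material_definition")) mat <- load_material(mat)
  code <- normalize_bead_code(bead_code)
  pmf <- mat$pmf[[code]]
  if (is.null(pmf)) stop("no surface potential for bead ", code)
  hrow <- mat$hamaker$entries[mat$hamaker$entries$code == code, ]
  if (nrow(hrow) == 0L) stop("no Hamaker entry for bead ", code)
  bead_np_interaction(
    pmf = pmf, A_H = hrow$A_kJmol, bead_radius = hrow$radius_nm,
    q = charge %||% bead_charge(code), psi0_mV = npb$psi0_mV,
    debye_length = debye_length, cutoff_rc = pmf$cutoff_rc,
    geometry = list(type = npb$shape, R = npb$radius),
    correction = npb$correction, temperature = temperature)
}

#' Presummed axial potential for one bead type
#'
#' Tabulates the total interaction of a bead of the given type placed on the
#' z-axis at `(0, 0, z)` with the whole NP complex, summed over NP beads at
#' their geometry-specific closest approach. Placing the bead inside an NP
#' bead core yields the (finite, capped) wall value.
#'
#' @param np A [nanoparticle].
#' @param bead_code Bead code.
#' @param z_grid Axial positions, nm; default `seq(0.02, R1b + 15, 0.01)`.
#' @param debye_length Debye length, nm.
#' @param temperature Temperature, K.
#' @param charge Optional charge override, e.
#' @return Object of class `presum_table` with `z`, `U` (kJ/mol) and a
#'   linear-interpolation closure `fun(z)` (held at ends).
#' @export
presum_potential <- function(np, bead_code, z_grid = NULL, debye_length = 1,
                             temperature = 300, charge = NULL) {
  if (is.null(z_grid))
    z_grid <- seq(0.02, np$R1b + 15, by = 0.01)
  U <- numeric(length(z_grid))
  for (b in np$beads) {
    inter <- build_bead_interaction(b, bead_code, debye_length, temperature,
                                    charge)
    dstar <- vapply(z_grid, function(z)
      npb_closest_approach(b, c(0, 0, z)), 0)
    ub <- numeric(length(dstar))
    pos <- dstar > 0
    if (any(pos)) ub[pos] <- bead_np_potential(inter, dstar[pos])
    ub <- ub + ifelse(pos, 0,
                      core_overlap_wall(dstar) * kBT_kJmol(temperature))
    U <- U + ub
  }
  fun <- function(z) stats::approx(z_grid, U, xout = z, rule = 2)$y
  structure(list(z = z_grid, U = U, fun = fun, bead_code = bead_code),
            class = "presum_table")
}
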
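## Long-range interaction parameters: bead radii from atomistic sites,
## Hamaker constants by force-field summation and by Lifshitz theory, and
## the metal/dielectric classification used to parametrize materials.

#' Atom sites for a molecule or surface structure
#'
#' @param sigma_nm LJ sigma per atom, nm.
#' @param eps_kJmol LJ epsilon per atom, kJ/mol.
#' @param q_e Partial charge, e.
#' @param xyz Coordinates, matrix with 3 columns, nm.
#' @param element Optional element labels.
#' @return data.frame of class `atom_sites`.
#' @export
atom_sites <- function(sigma_nm, eps_kJmol, q_e, xyz, element = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  df <- data.frame(element = element %||% rep("X", length(sigma_nm)),
                   sigma_nm = sigma_nm, eps_kJmol = eps_kJmol, q_e = q_e,
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   stringsAsFactors = FALSE)
  class(df) <- c("atom_sites", class(df))
  df
}

#' Read atom sites from CSV
#'
#' Columns `element,sigma_nm,eps_kJmol,q_e,x,y,z` with `#` comments.
#'
#' @param path CSV path.
#' @return An [atom_sites] data.frame.
#' @export
read_atom_sites <- function(path) {
  df <- utils::read.table(path, sep = ",", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  atom_sites(df$sigma_nm, df$eps_kJmol, df$q_e,
             cbind(df$x, df$y, df$z), df$element)
}

#' Bead radius and volume by the convex-hull method
#'
#' Each atom is modelled as a sphere of radius `sigma/2`; points are sampled
#' on every atom sphere, the convex hull of the merged cloud is taken as the
#' outer surface, and the radius of the equal-volume sphere is returned
#' together with the hull volume (used as the per-molecule volume in the
#' force-field Hamaker formula). All-coincident sites fall back to the
#' single-atom radius `sigma/2`.
#'
#' @param sites An [atom_sites] data.frame.
#' @param n_samples Surface samples per atom sphere.
#' @return List with `radius` (nm) and `volume` (nm^3).
#' @export
bead_radius_convex_hull <- function(sites, n_samples = 512) {
  if (nrow(sites) == 0L) stop("no atom sites")
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  spread <- if (nrow(sites) > 1L) max(dist(xyz)) else 0
  if (nrow(sites) == 1L || spread < 1e-9) {
    r <- max(sites$sigma_nm) / 2
    return(list(radius = r, volume = 4 / 3 * pi * r^3))
  }
  base <- fibonacci_sphere(n_samples)
  pts <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i)
    sweep(base * sites$sigma_nm[i] / 2, 2, xyz[i, ], "+")))
  hull <- convex_hull_volume(pts)
  list(radius = (3 * hull$volume / (4 * pi))^(1 / 3),
       volume = hull$volume)
}

## Deterministic quasi-uniform rotation set: Fibonacci axes crossed with a
## uniform set of angles (a small spherical design over SO(3)).
rotation_design <- function(n_axes = 58, n_angles = 4) {
  axes <- fibonacci_sphere(n_axes)
  angles <- (seq_len(n_angles) - 0.5) * 2 * pi / n_angles
  out <- vector("list", n_axes * n_angles)
  k <- 1L
  for (i in seq_len(n_axes)) for (a in angles) {
    u <- axes[i, ]
    q <- c(cos(a / 2), sin(a / 2) * u)
    out[[k]] <- quaternion_matrix(q)
    k <- k + 1L
  }
  out
}

lj_pair_energy <- function(sa, sb, off) {
  ## LJ interaction between two site sets, Lorentz-Berthelot combination,
  ## molecule b displaced by off
  xa <- as.matrix(sa[, c("x", "y", "z")])
  xb <- sweep(as.matrix(sb[, c("x", "y", "z")]), 2, off, "+")
  e <- 0
  for (i in seq_len(nrow(xa))) {
    dx <- sweep(xb, 2, xa[i, ], "-")
    d <- sqrt(rowSums(dx^2))
    sig <- (sa$sigma_nm[i] + sb$sigma_nm) / 2
    epsl <- sqrt(sa$eps_kJmol[i] * sb$eps_kJmol)
    sr6 <- (sig / d)^6
    e <- e + sum(4 * epsl * (sr6^2 - sr6))
  }
  e
}

#' Bead radius from the orientation-averaged LJ self-interaction
#'
#' The molecule's LJ interaction with a rotated copy of itself is averaged
#' over a deterministic set of relative rotations as a function of the
#' COM-COM separation; the effective radius is half the distance of the
#' first zero crossing from repulsive to attractive, by analogy with the
#' zero of the standard LJ potential at `sigma`.
#'
#' @param sites An [atom_sites] data.frame.
#' @param rotations Number of rotations in the averaging design.
#' @param tol Bisection tolerance, nm.
#' @return Radius in nm.
#' @export
bead_radius_lj_crossing <- function(sites, rotations = 232, tol = 1e-4) {
  if (nrow(sites) == 0L) stop("no atom sites")
  com <- colMeans(as.matrix(sites[, c("x", "y", "z")]))
  s0 <- sites
  s0$x <- s0$x - com[1]; s0$y <- s0$y - com[2]; s0$z <- s0$z - com[3]
  n_axes <- max(1L, round(rotations / 4))
  rots <- rotation_design(n_axes, 4)
  rot_sites <- lapply(rots, function(R) {
    xr <- as.matrix(s0[, c("x", "y", "z")]) %*% t(R)
    s <- s0; s$x <- xr[, 1]; s$y <- xr[, 2]; s$z <- xr[, 3]
    s
  })
  uavg <- function(r) mean(vapply(rot_sites, function(s)
    lj_pair_energy(s0, s, c(r, 0, 0)), 0))
  extent <- max(sqrt(rowSums(as.matrix(s0[, c("x", "y", "z")])^2)))
  lo <- 0.3 * min(sites$sigma_nm)
  hi <- 4 * (max(sites$sigma_nm) + 2 * extent)
  rg <- seq(lo, hi, length.out = 200)
  ug <- vapply(rg, uavg, 0)
  cross <- which(ug[-length(ug)] > 0 & ug[-1] <= 0)
  if (length(cross) == 0L) stop("no repulsive-to-attractive crossing found")
  k <- cross[1]
  root <- stats::uniroot(uavg, c(rg[k], rg[k + 1]), tol = tol)$root
  root / 2
}

#' Force-field (vacuum) Hamaker constant
#'
#' Summation over all LJ site pairs with Lorentz-Berthelot combination
#' rules: `A = pi^2 rho^2 sum_lm 4 eps_lm sigma_lm^6` with number density
#' `rho = eta / V_b`, where `eta` is the packing fraction (0.64 for a
#' random close-packed molecular condensed phase, 1 for structures already
#' in the solid phase) and `V_b` the per-molecule volume. Organics typically
#' land in 0.1-1.0 x 10^-20 J.
#'
#' @param sites An [atom_sites] data.frame.
#' @param V_b Volume per molecule, nm^3 (> 0), e.g. the convex-hull volume.
#' @param eta Packing density.
#' @return Hamaker constant in J.
#' @export
hamaker_ff <- function(sites, V_b, eta = 0.64) {
  if (nrow(sites) == 0L) stop("no atom sites")
  if (V_b <= 0) stop("V_b must be positive")
  sig <- outer(sites$sigma_nm, sites$sigma_nm, function(a, b) (a + b) / 2)
  epsl <- sqrt(outer(sites$eps_kJmol, sites$eps_kJmol))
  C6 <- sum(4 * epsl * sig^6)               # kJ/mol nm^6
  rho <- eta / V_b                          # nm^-3
  kJmol_to_J(pi^2 * rho^2 * C6)
}

#' Optical constants of one medium
#'
#' @param eps0 Static relative permittivity (metals: effectively infinite).
#' @param n Visible refractive index (dielectrics; >= 1).
#' @param nu_e Electronic absorption frequency, Hz (dielectrics).
#' @param metallic Metal flag.
#' @param nu_plasma Free-electron plasma frequency, Hz (metals).
#' @return Object of class `optical_constants`.
#' @export
optical_constants <- function(eps0, n = NULL, nu_e = 3e15, metallic = FALSE,
                              nu_plasma = NULL) {
  if (!metallic && (is.null(n) || n < 1))
    stop("dielectrics need a refractive index >= 1")
  if (metallic && is.null(nu_plasma))
    stop("metals need a plasma frequency")
  structure(list(eps0 = eps0, n = n, nu_e = nu_e, metallic = metallic,
                 nu_plasma = nu_plasma),
            class = "optical_constants")
}

## permittivity at imaginary frequency i*nu
eps_inu <- function(oc, nu) {
  if (oc$metallic) 1 + (oc$nu_plasma / nu)^2
  else 1 + (oc$n^2 - 1) / (1 + (nu / oc$nu_e)^2)
}

#' Lifshitz Hamaker constant A_132
#'
#' Sum of the zero-frequency (entropic) term
#' `A(0) = (3/4) kB T D(eps1, eps3) D(eps2, eps3)` with
#' `D(a, b) = (a - b)/(a + b)`, and a high-frequency term
#' `A(nu>0) = (3 h / 4 pi) \int_0^inf D13(i nu) D23(i nu) dnu` using the
#' single-oscillator dielectric model or the free-electron-gas metallic
#' model per component. For all-dielectric media sharing one absorption
#' frequency the integral collapses to the standard visible-refractive-index
#' closed form (see [hamaker_equal_freq]).
#'
#' @param c1,c2,c3 [optical_constants] of the two bodies and the medium.
#' @param T Temperature, K.
#' @param include_zero_frequency Include the entropic term.
#' @return Hamaker constant in J.
#' @export
lifshitz_hamaker <- function(c1, c2, c3, T = 300,
                             include_zero_frequency = TRUE) {
  D0 <- function(a, b) {
    ea <- if (a$metallic) Inf else a$eps0
    eb <- if (b$metallic) Inf else b$eps0
    if (is.infinite(ea) && is.infinite(eb)) 1
    else if (is.infinite(ea)) 1
    else if (is.infinite(eb)) -1
    else (ea - eb) / (ea + eb)
  }
  A0 <- if (include_zero_frequency)
    0.75 * .kB_J * T * D0(c1, c3) * D0(c2, c3) else 0
  ## integrate in units of the dominant electronic frequency
  nu_ref <- max(vapply(list(c1, c2, c3), function(oc)
    if (oc$metallic) oc$nu_plasma else oc$nu_e, 0))
  integrand <- function(x) {
    nu <- nu_ref * x
    e1 <- eps_inu(c1, nu); e2 <- eps_inu(c2, nu); e3 <- eps_inu(c3, nu)
    ((e1 - e3) / (e1 + e3)) * ((e2 - e3) / (e2 + e3))
  }
  Anu <- (3 * .h_planck / (4 * pi)) * nu_ref *
    stats::integrate(integrand, 0, Inf, rel.tol = 1e-8,
                     subdivisions = 500L)$value
  A0 + Anu
}

#' Closed-form high-frequency Hamaker constant (equal absorption frequency)
#'
#' All-dielectric case with a shared electronic absorption frequency
#' `nu_e`:
#' `A = (3 h nu_e / 8 sqrt(2)) (n1^2-n3^2)(n2^2-n3^2) /
#'  [sqrt(n1^2+n3^2) sqrt(n2^2+n3^2) (sqrt(n1^2+n3^2)+sqrt(n2^2+n3^2))]`.
#'
#' @param n1,n2,n3 Visible refractive indices.
#' @param nu_e Shared absorption frequency, Hz.
#' @return Hamaker constant in J.
#' @export
hamaker_equal_freq <- function(n1, n2, n3 = 1, nu_e = 3e15) {
  a <- sqrt(n1^2 + n3^2)
  b <- sqrt(n2^2 + n3^2)
  (3 * .h_planck * nu_e / (8 * sqrt(2))) *
    (n1^2 - n3^2) * (n2^2 - n3^2) / (a * b * (a + b))
}

#' Metal/dielectric classification from force-field parameters
#'
#' A structure is treated as metallic when a strict majority of its atoms
#' are highly polarizable (`eps > 12` kJ/mol) and quasi-neutral
#' (`|q| < 0.5` e).
#'
#' @param sites An [atom_sites] data.frame.
#' @return Logical flag.
#' @export
classify_metallic <- function(sites) {
  mean(sites$eps_kJmol > 12 & abs(sites$q_e) < 0.5) > 0.5
}

#' Invert the closed-form Hamaker expression for the refractive index
#'
#' Finds `n1 = n2` with `n3 = 1` such that [hamaker_equal_freq] reproduces the
#' vacuum self-interaction constant `A_cc`, by bisection.
#'
#' @param A_cc Vacuum self-interaction Hamaker constant, J (> 0).
#' @param nu_e Absorption frequency, Hz.
#' @return Refractive index.
#' @export
refractive_index_from_A <- function(A_cc, nu_e = 3e15) {
  if (A_cc <= 0) stop("A_cc must be positive")
  f <- function(n) hamaker_equal_freq(n, n, 1, nu_e) - A_cc
  hi <- 2
  while (f(hi) < 0 && hi < 100) hi <- hi * 2
  stats::uniroot(f, c(1 + 1e-12, hi), tol = 1e-12)$root
}

#' Combining relation for Hamaker constants across a medium
#'
#' `A_cmw = (sqrt(A_cc) - sqrt(A_ww)) (sqrt(A_mm) - sqrt(A_ww))`; known to
#' be unreliable when the medium is water, which motivates the Lifshitz
#' route of [material_hamaker_pipeline].
#'
#' @param A_cc,A_mm,A_ww Self-interaction constants of the two bodies and
#'   the medium, J.
#' @return Combined constant, J.
#' @export
combine_hamaker <- function(A_cc, A_mm, A_ww) {
  (sqrt(A_cc) - sqrt(A_ww)) * (sqrt(A_mm) - sqrt(A_ww))
}

#' Bead-surface Hamaker constant through approximate optical constants
#'
#' Full recipe used to parametrize materials: vacuum self-interaction
#' constants from force-field summation (bead at packing 0.64 with its
#' convex-hull volume; surface at packing 1, already solid), inversion to an
#' effective refractive index (dielectrics, `eps0 = 1.3`, `nu_e = 3e15` Hz);
#' metallic surfaces (strict-majority rule) get a nominal plasma frequency
#' of 5e15 Hz instead; the medium is water (`n = 1.33`, `eps0 = 82`); the
#' zero-frequency term is neglected (always below 1 kBT); the Lifshitz
#' combination gives the bead-surface constant across water.
#'
#' @param bead_sites,surface_sites [atom_sites] for the bead molecule and a
#'   representative chunk of the surface material.
#' @param T Temperature, K.
#' @param surface_volume Per-chunk volume for the surface, nm^3; defaults to
#'   the convex-hull volume of the surface sites.
#' @return List: `A_J`, `A_kJmol`, plus the intermediate constants
#'   (`A_bead_vac`, `A_surf_vac`, `n_bead`, `surface_metallic`,
#'   `n_surface`).
#' @export
material_hamaker_pipeline <- function(bead_sites, surface_sites, T = 300,
                                      surface_volume = NULL) {
  hull_b <- bead_radius_convex_hull(bead_sites)
  A_bb <- hamaker_ff(bead_sites, hull_b$volume, eta = 0.64)
  V_s <- surface_volume %||% bead_radius_convex_hull(surface_sites)$volume
  A_ss <- hamaker_ff(surface_sites, V_s, eta = 1)
  n_bead <- refractive_index_from_A(A_bb)
  c_bead <- optical_constants(1.3, n_bead, 3e15)
  metal <- classify_metallic(surface_sites)
  c_surf <- if (metal)
    optical_constants(Inf, metallic = TRUE, nu_plasma = 5e15)
  else optical_constants(1.3, refractive_index_from_A(A_ss), 3e15)
  c_water <- optical_constants(82, 1.33, 3e15)
  A <- lifshitz_hamaker(c_bead, c_surf, c_water, T,
                        include_zero_frequency = FALSE)
  list(A_J = A, A_kJmol = J_to_kJmol(A), A_bead_vac = A_bb,
       A_surf_vac = A_ss, n_bead = n_bead, surface_metallic = metal,
       n_surface = if (metal) NA_real_ else c_surf$n,
       bead_radius = hull_b$radius)
}

#' Three-site water model parameters
#'
#' CHARMM-style TIP3P sites (O: sigma 0.31507 nm, eps 0.6364 kJ/mol; H:
#' sigma 0.04 nm, eps 0.1924 kJ/mol; r(OH) 0.09572 nm, angle 104.52
#' degrees), used for the force-field Hamaker constant of water.
#'
#' @return An [atom_sites] data.frame with three rows.
#' @export
water_three_site <- function() {
  ang <- 104.52 * pi / 180
  r <- 0.09572
  atom_sites(sigma_nm = c(0.31507, 0.04, 0.04),
             eps_kJmol = c(0.6364, 0.1924, 0.1924),
             q_e = c(-0.834, 0.417, 0.417),
             xyz = rbind(c(0, 0, 0),
                         c(r, 0, 0),
                         c(r * cos(ang), r * sin(ang), 0)),
             element = c("O", "H", "H"))
}
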
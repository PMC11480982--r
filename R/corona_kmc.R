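## Corona prediction by kinetic Monte Carlo: conversion of orientation maps
## into per-orientation adsorbate species with rate constants, the hard-disk
## KMC driver (standard / displacement / steady-state modes) and the
## mean-field competitive-Langmuir baseline.

.v_ref_nm3 <- 1                       # reference volume pinning the rates
.c0_molar <- 1 / (.v_ref_nm3 * .N_A * 1e-24)  # reference concentration, M

#' Surface area of a KMC geometry
#'
#' Sphere `4 pi R^2`; cylinder lateral surface `2 pi R L` (end caps
#' excluded, consistent with the periodic cylinder KMC surface); periodic
#' plane `Lx Ly`.
#'
#' @param geometry `list(type = "sphere", R =)`,
#'   `list(type = "cylinder", R =, L =)` or
#'   `list(type = "plane", Lx =, Ly =)`; nm.
#' @return Area in nm^2.
#' @export
kmc_surface_area <- function(geometry) {
  switch(geometry$type,
    sphere = 4 * pi * geometry$R^2,
    cylinder = 2 * pi * geometry$R * geometry$L,
    plane = geometry$Lx * geometry$Ly,
    stop("unknown KMC geometry: ", geometry$type))
}

#' Build per-orientation adsorbate species from orientation maps
#'
#' Each orientation cell of each biomolecule becomes one adsorbate species
#' with a projected hard-disk radius (maximum in-plane bead distance from
#' the COM axis in that orientation), a sin(theta)-normalized orientation
#' weight `f_i`, an adsorption rate `k_a = f_i k_coll` from the Smoluchowski
#' collision rate with a Stokes-Einstein diffusivity, and a desorption rate
#' fixed by detailed balance against the competitive-Langmuir stationary
#' state: `k_a / k_d = n_i (c_i / c0) exp(-E_i)` with `n_i` the number of
#' disk-sized sites on the surface and `c0 = 1/(v_ref N_A)`, `v_ref = 1
#' nm^3`.
#'
#' @param maps Named list of `adsorption_map`s (one per molecule).
#' @param structures Named list of [bead_model]s, names matching `maps`.
#' @param concentrations Named numeric, mol/L.
#' @param geometry KMC geometry (see [kmc_surface_area]).
#' @param temperature Temperature, K.
#' @param masses_kDa Optional named molecular masses; defaults to 0.11 kDa
#'   per bead.
#' @param min_rp Floor on the projected radius, nm.
#' @return data.frame of class `adsorbate_species` with columns
#'   `id, molecule, r_p, conc_M, k_a, k_d, E_kT, f, mass_kDa, charge_e`.
#' @export
build_corona_params <- function(maps, structures, concentrations, geometry,
                                temperature = 300, masses_kDa = NULL,
                                min_rp = 0.1) {
  mols <- names(concentrations)
  missing_map <- setdiff(mols, names(maps))
  if (length(missing_map))
    stop("no orientation map for: ", paste(missing_map, collapse = ", "))
  missing_str <- setdiff(mols, names(structures))
  if (length(missing_str))
    stop("no structure for: ", paste(missing_str, collapse = ", "))
  area <- kmc_surface_area(geometry)
  R_np <- if (geometry$type == "plane") Inf else geometry$R
  out <- lapply(mols, function(nm) {
    map <- maps[[nm]]
    mod <- structures[[nm]]
    conc <- concentrations[[nm]]
    r <- map$rows
    th_c <- r$theta + map$grid_deg / 2
    ph_c <- r$phi + map$grid_deg / 2
    f <- sin(th_c * pi / 180)
    f <- f / sum(f)
    rp <- vapply(seq_len(nrow(r)), function(k) {
      rot <- rotate_model(mod, ph_c[k], th_c[k], r$omega[k])
      max(sqrt(rot$beads$x^2 + rot$beads$y^2))
    }, 0)
    rp <- pmax(rp, min_rp)
    ## Smoluchowski collision rate with Stokes-Einstein diffusivity
    D <- .kB_J * temperature / (6 * pi * .water_viscosity * rp * 1e-9)
    k_coll <- if (is.finite(R_np))
      4 * pi * (R_np + rp) * 1e-9 * D * .N_A * conc * 1e3
    else
      ## plane: flux onto the patch, D c / sqrt(pi D t) has no stationary
      ## limit; use the collision rate onto a disk-sized patch as the scale
      4 * (area * 1e-18 / pi)^0.5 * D * .N_A * conc * 1e3
    k_a <- f * k_coll
    n_i <- area / (pi * rp^2)
    K <- n_i * (conc / .c0_molar) * exp(-r$E_kT)
    data.frame(id = sprintf("%s_p%g_t%g_o%g", nm, r$phi, r$theta, r$omega),
               molecule = nm, r_p = rp, conc_M = conc, k_a = k_a,
               k_d = k_a / K, E_kT = r$E_kT, f = f,
               mass_kDa = if (!is.null(masses_kDa)) masses_kDa[[nm]]
                          else 0.11 * nrow(mod$beads),
               charge_e = sum(mod$beads$q),
               stringsAsFactors = FALSE)
  })
  sp <- do.call(rbind, out)
  class(sp) <- c("adsorbate_species", class(sp))
  attr(sp, "geometry") <- geometry
  attr(sp, "temperature") <- temperature
  sp
}

#' Construct adsorbate species directly
#'
#' Low-level constructor for hand-built species sets (tests, simple cases).
#'
#' @param id Species identifiers.
#' @param r_p Hard-disk radii, nm.
#' @param conc_M Bulk concentrations, mol/L.
#' @param k_a Adsorption rates, 1/s per NP.
#' @param k_d Desorption rates, 1/s.
#' @param E_kT Binding energies, kBT (negative favours binding).
#' @param molecule Molecule labels (default `id`).
#' @param mass_kDa,charge_e Optional descriptors.
#' @return An `adsorbate_species` data.frame.
#' @export
adsorbate_species <- function(id, r_p, conc_M, k_a, k_d, E_kT,
                              molecule = id, mass_kDa = 0, charge_e = 0) {
  if (any(k_a < 0) || any(k_d < 0)) stop("rates must be non-negative")
  if (any(r_p <= 0)) stop("hard-disk radii must be positive")
  sp <- data.frame(id = id, molecule = molecule, r_p = r_p, conc_M = conc_M,
                   k_a = k_a, k_d = k_d, E_kT = E_kT,
                   f = 1, mass_kDa = mass_kDa, charge_e = charge_e,
                   stringsAsFactors = FALSE)
  class(sp) <- c("adsorbate_species", class(sp))
  sp
}

#' Read / write a species CSV
#'
#' Columns `id,r_p_nm,conc_molar,k_a,k_d,E_kT,mass_kDa,charge_e` plus a
#' `molecule` column; `#` comments.
#'
#' @param species An `adsorbate_species` data.frame.
#' @param path File path.
#' @export
write_species_csv <- function(species, path) {
  utils::write.table(as.data.frame(species), path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_species_csv
#' @export
read_species_csv <- function(path) {
  df <- utils::read.table(path, sep = ",", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  sp <- adsorbate_species(df$id, df$r_p, df$conc_M, df$k_a, df$k_d,
                          df$E_kT, df$molecule, df$mass_kDa, df$charge_e)
  sp$f <- df$f %||% 1
  sp
}

#' Displacement-mode acceptance probability
#'
#' `p = exp(-dE) / (1 + exp(-dE))` where `dE` (kBT) is the binding energy of
#' the incoming adsorbate minus the summed binding energies of the adsorbates
#' it would displace; energy-neutral displacement is accepted half the time.
#'
#' @param dE Energy difference(s), kBT.
#' @return Probability in (0, 1).
#' @export
displacement_accept <- function(dE) 1 / (1 + exp(dE))

#' Rescale rates to reach the steady state faster
#'
#' Sets every adsorption rate to a common reference rate (default the
#' largest `k_a` in the set) and scales each desorption rate by the same
#' per-species factor, so every `k_a/k_d` ratio -- and hence the stationary
#' distribution of the reversible system -- is unchanged.
#'
#' @param species An `adsorbate_species` data.frame.
#' @param k_ref Common adsorption rate; default `max(k_a)`.
#' @return Rescaled species.
#' @export
steady_state_rescale <- function(species, k_ref = NULL) {
  k_ref <- k_ref %||% max(species$k_a)
  fac <- k_ref / species$k_a
  species$k_a <- species$k_a * fac
  species$k_d <- species$k_d * fac
  species
}

#' Run the hard-disk corona KMC
#'
#' Rejection-free event selection: adsorption candidates are drawn with
#' probability proportional to `k_a`, given a uniform random surface
#' position, and accepted in standard mode only if the new disk overlaps no
#' adsorbed disk (great-circle metric on spheres, periodic Euclidean metric
#' on planes, unrolled-surface metric on cylinders); in displacement mode
#' overlapping disks are evicted with probability
#' [displacement_accept] (`k_d` is scaled by the same no-overlap acceptance
#' factor to keep `k_a/k_d` fixed). Each adsorbed disk contributes `k_d` to
#' the desorption rate; time advances exponentially with the total rate.
#'
#' @param species An `adsorbate_species` data.frame.
#' @param geometry KMC geometry (see [kmc_surface_area]).
#' @param t_end Simulated time, s.
#' @param seed Integer seed (replicate `r` uses `seed + r - 1`).
#' @param mode `"standard"` or `"displacement"`.
#' @param report_interval Time between recorded snapshots, s.
#' @param replicates Number of independent replicates.
#' @param steady_state Apply [steady_state_rescale] first.
#' @param max_events Safety cap on events per replicate.
#' @return Object of class `corona_result`: `times`, `counts` (mean over
#'   replicates, species in columns), `counts_rep` (list of matrices),
#'   `final` (state of the first replicate), `species`, `geometry`.
#' @export
run_kmc <- function(species, geometry, t_end, seed = 1,
                    mode = c("standard", "displacement"),
                    report_interval = t_end / 50, replicates = 1,
                    steady_state = FALSE, max_events = 1e7) {
  mode <- match.arg(mode)
  if (t_end <= 0) stop("t_end must be positive")
  if (nrow(species) == 0L) stop("species list is empty")
  if (steady_state) species <- steady_state_rescale(species)
  kd_eff <- species$k_d
  if (mode == "displacement")
    kd_eff <- kd_eff * displacement_accept(species$E_kT)
  gcode <- match(geometry$type, c("sphere", "cylinder", "plane")) - 1L
  p1 <- switch(geometry$type, sphere = geometry$R, cylinder = geometry$R,
               plane = geometry$Lx)
  p2 <- switch(geometry$type, sphere = 0, cylinder = geometry$L,
               plane = geometry$Ly)
  reps <- lapply(seq_len(replicates), function(r) {
    set.seed((seed + r - 1) %% .Machine$integer.max)
    .kmc_run_cpp(species$k_a, kd_eff, species$r_p, species$E_kT,
                 gcode, p1, p2, t_end, if (mode == "standard") 0L else 1L,
                 report_interval, max_events)
  })
  counts_rep <- lapply(reps, function(x) {
    m <- x$counts
    colnames(m) <- species$id
    m
  })
  counts <- Reduce(`+`, counts_rep) / replicates
  structure(list(times = reps[[1]]$times, counts = counts,
                 counts_rep = counts_rep,
                 final = list(species_idx = reps[[1]]$final_species,
                              pos = reps[[1]]$final_pos,
                              t = reps[[1]]$t, events = reps[[1]]$events),
                 species = species, geometry = geometry, mode = mode),
            class = "corona_result")
}

#' Final per-species counts of a corona run
#'
#' @param result A `corona_result`.
#' @param by_molecule Sum orientation cells of the same molecule.
#' @return Named numeric vector of counts.
#' @export
corona_counts <- function(result, by_molecule = TRUE) {
  n <- tabulate(result$final$species_idx, nbins = nrow(result$species))
  names(n) <- result$species$id
  if (by_molecule)
    n <- tapply(n, result$species$molecule, sum)
  n
}

#' Mean-field (competitive-Langmuir) corona baseline
#'
#' `N_i = n_i (c_i/c0) exp(-E_i) / (1 + sum_j (c_j/c0) exp(-E_j))` with
#' `n_i = A / (pi r_p,i^2)` sites and `c0 = 1/(v_ref N_A)`; the stationary
#' solution of the blocking-rate equation the KMC reduces to at low
#' coverage.
#'
#' @param species An `adsorbate_species` data.frame.
#' @param geometry KMC geometry.
#' @param by_molecule Sum orientation cells of the same molecule.
#' @return Named numeric vector of mean occupancies.
#' @export
mean_field_corona <- function(species, geometry, by_molecule = TRUE) {
  if (nrow(species) == 0L) return(numeric(0))
  area <- kmc_surface_area(geometry)
  x <- (species$conc_M / .c0_molar) * exp(-species$E_kT)
  n_i <- area / (pi * species$r_p^2)
  N <- n_i * x / (1 + sum(x))
  names(N) <- species$id
  if (by_molecule) N <- tapply(N, species$molecule, sum)
  N
}

#' Write the KMC time series
#'
#' Per-interval counts summed over orientations of the same molecule,
#' whitespace-delimited with a `time_s` first column.
#'
#' @param result A `corona_result`.
#' @param path Output path.
#' @export
write_timeseries <- function(result, path) {
  mols <- unique(result$species$molecule)
  agg <- sapply(mols, function(m)
    rowSums(result$counts[, result$species$molecule == m, drop = FALSE]))
  if (is.null(dim(agg))) agg <- matrix(agg, nrow = 1, dimnames = list(NULL, mols))
  df <- data.frame(time_s = result$times, agg, check.names = FALSE)
  utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the final corona state
#'
#' `.kmc` file: internal surface coordinates with species ids and rate
#' constants; `finalcoords` text file: species name plus Cartesian
#' coordinates (nm).
#'
#' @param result A `corona_result`.
#' @param kmc_path Path for the `.kmc` file.
#' @param coords_path Path for the `finalcoords` file.
#' @export
write_final_state <- function(result, kmc_path, coords_path) {
  sp <- result$species
  idx <- result$final$species_idx
  pos <- result$final$pos
  kmc <- data.frame(id = sp$id[idx], c1 = pos[, 1], c2 = pos[, 2],
                    c3 = pos[, 3], r_p = sp$r_p[idx], k_a = sp$k_a[idx],
                    k_d = sp$k_d[idx], E_kT = sp$E_kT[idx])
  utils::write.table(kmc, kmc_path, row.names = FALSE, quote = FALSE)
  g <- result$geometry
  xyz <- switch(g$type,
    sphere = pos * g$R,
    cylinder = cbind(g$R * cos(pos[, 2] / g$R), g$R * sin(pos[, 2] / g$R),
                     pos[, 1]),
    plane = cbind(pos[, 1], pos[, 2], 0))
  fc <- data.frame(name = sp$molecule[idx],
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  utils::write.table(fc, coords_path, row.names = FALSE, quote = FALSE)
  invisible(list(kmc = kmc_path, coords = coords_path))
}

#' Read back a .kmc final-state file
#'
#' @param path A `.kmc` path written by [write_final_state].
#' @return data.frame of adsorbed disks.
#' @export
read_kmc_state <- function(path)
  utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)

#' Surface coverage of a corona state
#'
#' Total projected disk area over the surface area.
#'
#' @param result A `corona_result`.
#' @return Dimensionless coverage.
#' @export
corona_coverage <- function(result) {
  idx <- result$final$species_idx
  sum(pi * result$species$r_p[idx]^2) / kmc_surface_area(result$geometry)
}
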
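## End-to-end driver: orientation scan -> corona parameters -> KMC, plus
## corona postprocessing statistics and presentation-ready summaries.

#' Assemble a pipeline configuration
#'
#' @param material A [material_definition] (or loaded material).
#' @param biomolecules Named character vector of structure (PDB) paths.
#' @param concentrations Named numeric, mol/L, names matching
#'   `biomolecules`.
#' @param shape_code NP shape code (see [build_simple_np]).
#' @param radius_nm NP radius.
#' @param zeta_mV Surface potential.
#' @param temperature_K,debye_length_nm Conditions.
#' @param mode `"presum"` or `"full"`.
#' @param full_scan Deep-scan inner integration bound.
#' @param averaging Orientation-cell averaging mode.
#' @param omega_list Third-angle values.
#' @param grid_deg,n_subsamples Scan resolution.
#' @param t_end,report_interval,replicates KMC controls (s).
#' @param kmc_mode `"standard"` or `"displacement"`.
#' @param steady_state Rescale rates to reach the steady state.
#' @param cylinder_length_nm Cylinder length for the KMC surface.
#' @param seed Master seed.
#' @param outdir Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(material, biomolecules, concentrations,
                            shape_code = 1, radius_nm = 5, zeta_mV = 0,
                            temperature_K = 300, debye_length_nm = 1,
                            mode = "presum", full_scan = FALSE,
                            averaging = "simple", omega_list = 0,
                            grid_deg = 5, n_subsamples = 64,
                            t_end = 1e-3, report_interval = NULL,
                            replicates = 5, kmc_mode = "standard",
                            steady_state = FALSE,
                            cylinder_length_nm = 100,
                            seed = 1, outdir = "corona_out") {
  if (is.null(names(biomolecules)) || is.null(names(concentrations)))
    stop("biomolecules and concentrations must be named")
  missing_str <- setdiff(names(concentrations), names(biomolecules))
  if (length(missing_str))
    stop("no structure file for: ", paste(missing_str, collapse = ", "))
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  ok <- file.exists(unlist(biomolecules))
  if (!all(ok))
    stop("structure file not found: ",
         paste(unlist(biomolecules)[!ok], collapse = ", "))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config]; the material is given as
#' `material: {name, pmf_directory, hamaker_file, source_geometry,
#' cutoff_rc, default_psi0_mV}` and biomolecules as a `name: path` map with
#' a parallel `concentrations` map (mol/L).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  mat <- material_definition(
    y$material$name, y$material$pmf_directory, y$material$hamaker_file,
    y$material$source_geometry %||% "plane",
    y$material$cutoff_rc %||% 1.0, y$material$default_psi0_mV %||% 0)
  args <- y[setdiff(names(y), c("material", "biomolecules",
                                "concentrations"))]
  do.call(pipeline_config,
          c(list(material = mat,
                 biomolecules = unlist(y$biomolecules),
                 concentrations = unlist(y$concentrations)),
            args))
}

#' Run the full corona-prediction pipeline
#'
#' Orientation scan for every biomolecule, conversion to per-orientation
#' adsorbate species, and the hard-disk KMC, with consistent units and
#' seeds; all intermediates (.uam maps, species CSV, time series, final
#' state) are persisted in the output directory along with a run manifest.
#'
#' @param config A `pipeline_config`.
#' @return List with `maps`, `species`, `result` (a `corona_result`),
#'   `counts`, `summary` data.frame and the output paths.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE))
  }
  material <- stage("material", {
    m <- cfg$material
    if (inherits(m, "material_definition")) load_material(m) else m
  })
  np <- stage("np", build_simple_np(cfg$shape_code, cfg$radius_nm, material,
                                    cfg$zeta_mV,
                                    length = cfg$cylinder_length_nm))
  mols <- names(cfg$concentrations)
  structures <- stage("structures", {
    s <- lapply(mols, function(nm) {
      mod <- read_bead_model(cfg$biomolecules[[nm]])
      mod$name <- nm
      mod
    })
    names(s) <- mols
    s
  })
  maps <- stage("scan", {
    m <- lapply(seq_along(mols), function(i)
      scan_orientations(np, structures[[i]],
                        seed = cfg$seed + 1000L * i,
                        averaging = cfg$averaging,
                        omega_list = cfg$omega_list,
                        grid_deg = cfg$grid_deg,
                        n_subsamples = cfg$n_subsamples, mode = cfg$mode,
                        debye_length = cfg$debye_length_nm,
                        temperature = cfg$temperature_K,
                        full_scan = cfg$full_scan))
    names(m) <- mols
    m
  })
  uam_paths <- vapply(mols, function(nm)
    write_uam(maps[[nm]], cfg$outdir), "")
  geometry <- if (cfg$shape_code %in% c(2, 4, 5))
    list(type = "cylinder", R = cfg$radius_nm, L = cfg$cylinder_length_nm)
  else list(type = "sphere", R = cfg$radius_nm)
  species <- stage("corona_params",
    build_corona_params(maps, structures, cfg$concentrations, geometry,
                        temperature = cfg$temperature_K))
  species_path <- file.path(cfg$outdir, "species.csv")
  write_species_csv(species, species_path)
  result <- stage("kmc",
    run_kmc(species, geometry, t_end = cfg$t_end, seed = cfg$seed,
            mode = cfg$kmc_mode,
            report_interval = cfg$report_interval %||% (cfg$t_end / 50),
            replicates = cfg$replicates,
            steady_state = cfg$steady_state))
  ts_path <- file.path(cfg$outdir, "timeseries.txt")
  write_timeseries(result, ts_path)
  fin <- write_final_state(result, file.path(cfg$outdir, "final.kmc"),
                           file.path(cfg$outdir, "finalcoords.txt"))
  counts <- corona_counts(result)
  summary <- data.frame(
    molecule = mols,
    E_simple_kT = vapply(maps, simple_average, 0),
    E_boltzmann_kT = vapply(maps, boltzmann_average, 0),
    N_adsorbed = as.numeric(counts[mols]),
    relative_abundance = as.numeric(relative_abundance(counts)[mols]),
    row.names = NULL)
  manifest <- list(
    seed = cfg$seed, temperature_K = cfg$temperature_K,
    radius_nm = cfg$radius_nm, zeta_mV = cfg$zeta_mV,
    shape_code = cfg$shape_code, mode = cfg$mode,
    kmc_mode = cfg$kmc_mode, t_end = cfg$t_end,
    replicates = cfg$replicates,
    grid_deg = cfg$grid_deg, n_subsamples = cfg$n_subsamples,
    biomolecules = as.list(cfg$biomolecules),
    concentrations = as.list(cfg$concentrations),
    version = as.character(utils::packageVersion("coronaforge")))
  yaml::write_yaml(manifest, file.path(cfg$outdir, "manifest.yaml"))
  list(maps = maps, species = species, result = result, counts = counts,
       summary = summary,
       paths = list(uam = uam_paths, species = species_path,
                    timeseries = ts_path, kmc = fin$kmc,
                    finalcoords = fin$coords,
                    manifest = file.path(cfg$outdir, "manifest.yaml")))
}

#' Corona-averaged descriptor
#'
#' `<X> = sum_i x_i N_i / sum_i N_i` over adsorbates.
#'
#' @param counts Adsorbate counts `N_i`.
#' @param descriptor Per-adsorbate descriptor values `x_i`.
#' @return The corona-weighted mean.
#' @export
corona_descriptor_average <- function(counts, descriptor) {
  stopifnot(length(counts) == length(descriptor))
  if (sum(counts) == 0) return(NA_real_)
  sum(descriptor * counts) / sum(counts)
}

#' Relative abundances in the corona
#'
#' Simulation route: `N_i / sum N_i`.
#'
#' @param counts Adsorbate counts.
#' @return Abundances summing to 1.
#' @export
relative_abundance <- function(counts) {
  if (sum(counts) == 0) return(counts * 0)
  counts / sum(counts)
}

#' Relative abundances from gel band ratios
#'
#' Experimental route: each species' bound/control band-intensity ratio
#' `r_i` is scaled by its bulk number concentration and normalized,
#' `Ntilde_i = r_i [C_i] / sum_j r_j [C_j]`, removing unknown per-lane
#' dilution factors.
#'
#' @param band_ratios Bound/control intensity ratios `r_i`.
#' @param concentrations Number concentrations `[C_i]` (any common unit).
#' @return Abundances summing to 1.
#' @export
experimental_relative_abundance <- function(band_ratios, concentrations) {
  stopifnot(length(band_ratios) == length(concentrations))
  w <- band_ratios * concentrations
  w / sum(w)
}

#' SDS-PAGE-style band profile
#'
#' Bins adsorbates by `log10` molecular weight; each bin's intensity is the
#' total adsorbed mass in it, normalized to a maximum of 1 within the
#' channel.
#'
#' @param counts Adsorbate counts.
#' @param masses_kDa Molecular masses, kDa.
#' @param n_bins Number of bins.
#' @param range_log10 Optional `c(lo, hi)` in log10(kDa).
#' @return data.frame with `log10_kDa_lo`, `log10_kDa_hi`, `intensity`.
#' @export
band_profile <- function(counts, masses_kDa, n_bins = 20,
                         range_log10 = NULL) {
  stopifnot(length(counts) == length(masses_kDa))
  lm <- log10(masses_kDa)
  rg <- range_log10 %||% range(lm)
  if (diff(rg) == 0) rg <- rg + c(-0.05, 0.05)
  edges <- seq(rg[1], rg[2], length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(lm, edges, rightmost.closed = TRUE), 1),
              n_bins)
  mass <- vapply(seq_len(n_bins), function(b)
    sum(counts[bin == b] * masses_kDa[bin == b]), 0)
  inten <- if (max(mass) > 0) mass / max(mass) else mass
  data.frame(log10_kDa_lo = edges[-length(edges)],
             log10_kDa_hi = edges[-1], intensity = inten)
}

#' Normalize a corona quantity to the NP surface area
#'
#' @param quantity Extensive quantity (mass, charge, count).
#' @param geometry KMC geometry (see [kmc_surface_area]).
#' @return Quantity per nm^2.
#' @export
surface_area_normalize <- function(quantity, geometry)
  quantity / kmc_surface_area(geometry)

#' Exponential smoothing of a corona time series
#'
#' First-order exponential filter with time constant `tau` applied to each
#' species column; an optional postprocessing step for noisy counts.
#'
#' @param times Sample times, s.
#' @param counts Matrix of counts (rows = times).
#' @param tau Time constant, s.
#' @return Smoothed matrix.
#' @export
smooth_timeseries <- function(times, counts, tau = 1e-4) {
  counts <- as.matrix(counts)
  out <- counts
  for (k in 2:nrow(counts)) {
    a <- 1 - exp(-(times[k] - times[k - 1]) / tau)
    out[k, ] <- out[k - 1, ] + a * (counts[k, ] - out[k - 1, ])
  }
  out
}
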
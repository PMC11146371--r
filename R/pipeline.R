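#' Read a run configuration from YAML
#'
#' The schema mirrors [run_case()]'s `config` argument: `geometry` (either
#' a named list of [aneurysm_config()] fields or `stl:` path), `fluid`,
#' `waveform` (`psv`, `edv`, `tav`, `heart_rate`), `edge_length`,
#' `dependency_edge_lengths`, `site` (`center`, `radius`), solver settings
#' (`dt_divisor`, `n_cycles`, `bdf_order`), `flux_ml_min`, `seed`.
#'
#' @param path YAML file.
#' @return a validated config list.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

validate_run_config <- function(config) {
  defaults <- list(
    geometry = list(), fluid = list(), waveform = list(),
    edge_length = 0.6, dependency_edge_lengths = NULL, site = NULL,
    dt_divisor = 100, n_cycles = 2, bdf_order = 2, seed = 1)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  num_fields <- c("edge_length", "dt_divisor", "n_cycles", "bdf_order", "seed")
  for (nm in num_fields)
    if (!is.numeric(config[[nm]]) || length(config[[nm]]) != 1)
      stop("run config field '", nm, "' must be a single number")
  if (!is.null(config$dependency_edge_lengths) &&
      length(config$dependency_edge_lengths) != 3)
    stop("dependency_edge_lengths must give exactly three edge lengths")
  if (!is.null(config$site) &&
      (is.null(config$site$center) || length(config$site$center) != 3))
    stop("site spec needs a length-3 center")
  config
}

config_geometry <- function(config) {
  g <- config$geometry
  if (!is.null(g$stl)) {
    read_stl(g$stl)
  } else {
    do.call(aneurysm_config, g[intersect(names(g), names(formals(aneurysm_config)))]) |>
      build_idealized_aneurysm()
  }
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full hemodynamic analysis for one case
#'
#' Orchestrates geometry, morphometry, the inlet table, the optional mesh
#' dependency test, the pulsatile solve, the dome index panel and the
#' rupture-site comparison, writing each table as CSV into `output_dir`
#' together with a JSON manifest (config hash, package version, seed).
#' With `resume = TRUE`, stages whose output file already exists under a
#' matching config hash are skipped.
#'
#' @param config a config list (see [read_run_config()]) or a YAML path.
#' @param output_dir output directory, created if needed.
#' @param resume skip stages with existing outputs from the same config.
#' @return list with the computed tables and file paths.
#' @export
run_case <- function(config, output_dir = tempfile("hemoflow_run_"),
                     resume = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  manifest_path <- file.path(output_dir, "manifest.json")
  if (resume && file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path)
    done <- file.path(output_dir, c("morphometry.csv", "inlet.csv",
                                    "dome_panel.csv"))
    if (identical(old$config_hash, hash) && all(file.exists(done))) {
      # completed run with the same config: return the stored tables
      rd <- function(f) {
        p <- file.path(output_dir, f)
        if (file.exists(p)) utils::read.csv(p) else NULL
      }
      return(list(morphometry = rd("morphometry.csv"), inlet = rd("inlet.csv"),
                  dependency = rd("mesh_dependency.csv"),
                  panel = rd("dome_panel.csv"),
                  site_comparison = rd("site_comparison.csv"),
                  manifest = old, output_dir = output_dir, resumed = TRUE))
    }
  }
  emit <- function(df, name) {
    p <- file.path(output_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }

  surface <- config_geometry(config)
  fluid <- do.call(fluid_properties, config$fluid)
  wf_args <- utils::modifyList(list(psv = 0.45, edv = 0.2, tav = 0.3,
                                    heart_rate = 60), config$waveform)
  waveform <- do.call(make_waveform, wf_args)

  morpho <- compute_morphometry(surface)
  morpho_df <- data.frame(quantity = names(unclass(morpho)),
                          value = unlist(unclass(morpho)))
  emit(morpho_df, "morphometry.csv")

  vm <- tetrahedralize(surface, config$edge_length)
  inlet <- inlet_geometry(vm)
  inlet_df <- data.frame(radius_mm = inlet$radius, TAV = waveform$tav,
                         PSV = waveform$psv, EDV = waveform$edv,
                         flux_ml_min = compute_inlet_flux(inlet$radius,
                                                          waveform$tav))
  emit(inlet_df, "inlet.csv")

  dep <- NULL
  if (!is.null(config$dependency_edge_lengths)) {
    dep <- mesh_dependency_test(surface, config$dependency_edge_lengths,
                                fluid = fluid)
    emit(cbind(dep, converged = attr(dep, "converged")), "mesh_dependency.csv")
  }

  case <- flow_case(vm, fluid = fluid, waveform = waveform,
                    dt = waveform$period / config$dt_divisor,
                    n_cycles = config$n_cycles, bdf_order = config$bdf_order)
  sol <- solve_pulsatile(case)
  record <- extract_wss(sol)
  panel <- hemodynamic_report(record)
  emit(panel, "dome_panel.csv")

  site_cmp <- NULL
  if (!is.null(config$site)) {
    bsurf <- extract_boundary(vm)
    spec <- rupture_site_spec(config$site$center,
                              config$site$radius %||% 0.5)
    region <- select_rupture_region(bsurf, spec)
    wall_map <- which(!grepl("^(inlet|outlet)", bsurf$region_tags))
    site_mask <- match(region$facets, wall_map)
    site_mask <- site_mask[!is.na(site_mask)]
    site_cmp <- compare_site_to_dome(
      list(TAWSS = compute_tawss(record), OSI = compute_osi(record)),
      record$areas, which(record$tags == "dome"), site_mask)
    site_cmp$regime <- classify_site_regime(site_cmp)
    emit(site_cmp, "site_comparison.csv")
  }

  manifest <- list(package = "hemoflow",
                   version = as.character(utils::packageVersion("hemoflow")),
                   config_hash = hash, seed = config$seed,
                   mesh = list(h = vm$h, vertices = nrow(vm$vertices),
                               tets = nrow(vm$tets)))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  list(surface = surface, mesh = vm, morphometry = morpho,
       inlet = inlet_df, dependency = dep, solution = sol,
       record = record, panel = panel, site_comparison = site_cmp,
       manifest = manifest, output_dir = output_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the computational side of a PIV validation
#'
#' Steady solve at the prescribed flux, massless pathlines seeded in the
#' dome over the camera exposure, and velocity profiles along each probe
#' with its two focal-band copies; profile CSVs are written per probe. The
#' manifest records the mean inlet velocity implied by the flux.
#'
#' @param config as in [run_case()]; `flux_ml_min` defaults to 169.
#' @param probes list of [line_probe()]s (may be empty: pathlines only).
#' @param n_seeds particles for the pathline set.
#' @param exposure camera exposure (s).
#' @param output_dir output directory.
#' @return list with the solution, pathlines, profiles and manifest.
#' @export
run_piv_validation <- function(config, probes = list(), n_seeds = 200,
                               exposure = 0.010,
                               output_dir = tempfile("hemoflow_piv_")) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  flux <- config$flux_ml_min %||% 169
  surface <- config_geometry(config)
  fluid <- do.call(fluid_properties, config$fluid)
  vm <- tetrahedralize(surface, config$edge_length)
  case <- flow_case(vm, fluid = fluid)
  sol <- solve_steady(case, flux)
  paths <- trace_pathlines(sol, n_seeds = n_seeds, exposure = exposure,
                           seed = config$seed)
  profiles <- lapply(seq_along(probes), function(i) {
    pr <- sample_velocity_line(sol, probes[[i]])
    utils::write.csv(pr, file.path(output_dir, sprintf("profile_%d.csv", i)),
                     row.names = FALSE)
    pr
  })
  write_pathlines_vtp(paths, file.path(output_dir, "pathlines.vtp"))
  manifest <- list(flux_ml_min = flux,
                   inlet_radius_mm = case$inlet_radius,
                   tav_m_s = tav_from_flux(case$inlet_radius, flux),
                   seed = config$seed, config_hash = config_hash(config))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(solution = sol, pathlines = paths, profiles = profiles,
       manifest = manifest, output_dir = output_dir)
}
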
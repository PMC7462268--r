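# End-to-end orchestration: one scenario run and the shared-network
# multi-scenario sweep, with optional artifact output.

#' Pipeline configuration
#'
#' Bundles every knob of a full run. Scenario sweeps built from one config
#' share the same generated network and tumor phantom, so treatment
#' comparisons see identical initial conditions.
#'
#' @param host_species `"mouse"` or `"human"`.
#' @param seed Integer seed controlling network generation and phantom
#'   pruning/sprouting.
#' @param domain_size,lattice_pitch,n_roots,target_mvd,root_preset Network
#'   generation controls (see [generate_av_network()]).
#' @param tumor_radius,necrotic_radius,dilation_factor,prune_fraction,sprout_fraction
#'   Tumor phantom controls (see [apply_tumor_phantom()]).
#' @param grid_spacing Tissue voxel spacing, um.
#' @param scenario Scenario name (see [infusion_scenarios()]).
#' @param adapt_iter Radius-adaptation iterations per scenario.
#' @param pressures Root pressures, [root_pressures()].
#' @param root_conductance Feed conductance at each boundary root
#'   (um^3/(s mm Hg)) standing in for the truncated upstream vasculature;
#'   see [solve_flow()]. Calibrated so baseline regional blood flow lands in
#'   the physiologic 0.1-0.3 mL/(g min) range on the default fixture.
#' @param ... Overrides passed to [transport_params()].
#' @return A `run_config` list.
#' @export
run_config <- function(host_species = "mouse", seed = 1,
                       domain_size = 480, lattice_pitch = 60, n_roots = 4,
                       target_mvd = 250, root_preset = "corners",
                       tumor_radius = 150, necrotic_radius = 60,
                       dilation_factor = 1.3, prune_fraction = 0.3,
                       sprout_fraction = 0.25, grid_spacing = 30,
                       scenario = "baseline", adapt_iter = 12,
                       pressures = root_pressures(),
                       root_conductance = 12000, ...) {
  structure(list(host_species = host_species, seed = seed,
                 domain_size = domain_size, lattice_pitch = lattice_pitch,
                 n_roots = n_roots, target_mvd = target_mvd,
                 root_preset = root_preset, tumor_radius = tumor_radius,
                 necrotic_radius = necrotic_radius,
                 dilation_factor = dilation_factor,
                 prune_fraction = prune_fraction,
                 sprout_fraction = sprout_fraction,
                 grid_spacing = grid_spacing, scenario = scenario,
                 adapt_iter = adapt_iter, pressures = pressures,
                 root_conductance = root_conductance,
                 params_args = list(...)),
            class = "run_config")
}

build_fixture <- function(config) {
  params <- do.call(transport_params,
                    c(list(species = config$host_species),
                      config$params_args))
  net <- generate_av_network(
    domain_size = config$domain_size, lattice_pitch = config$lattice_pitch,
    n_roots = config$n_roots, target_mvd = config$target_mvd,
    seed = config$seed, root_preset = config$root_preset)
  ph <- apply_tumor_phantom(
    net, radius = config$tumor_radius,
    necrotic_radius = config$necrotic_radius,
    dilation_factor = config$dilation_factor,
    prune_fraction = config$prune_fraction,
    sprout_fraction = config$sprout_fraction,
    seed = config$seed + 1L, grid_spacing = config$grid_spacing,
    params = params)
  list(network = ph$network, grid = ph$grid, params = params)
}

run_one_scenario <- function(fixture, config, scenario_name) {
  params <- fixture$params
  row <- scenario_row(scenario_name)
  base_comp <- host_blood(config$host_species)
  comp <- apply_scenario(base_comp, row)
  bc0 <- boundary_model()
  bc <- if (scenario_name == "baseline") bc0 else {
    recalibrate_boundary(base_comp, comp, bc0)$bc
  }
  flow <- solve_flow(fixture$network, comp, config$pressures,
                     root_conductance = config$root_conductance)
  net <- adapt_radii(fixture$network, flow,
                     adaptation_params(k_s = row$k_s,
                                       n_iter = config$adapt_iter),
                     comp, config$pressures,
                     root_conductance = config$root_conductance)
  flow <- solve_flow(net, comp, config$pressures,
                     root_conductance = config$root_conductance)
  ox <- solve_coupled(net, fixture$grid, flow, comp, bc, params)
  regions <- c("whole", "tumor", "host", "boundary")
  bulk <- purrr::map_dfr(regions, function(rg) {
    vascular_bulk_metrics(net, flow, ox, ox$grid, rg)
  })
  oef <- oef_breakdown(net, flow, ox, comp)
  hyp <- hypoxic_fractions(ox$grid)
  bulk <- dplyr::mutate(
    bulk, scenario = scenario_name,
    oef_total = oef$oef_total, oef_plas = oef$oef_plas,
    oef_hb = oef$oef_hb, oef_hboc = oef$oef_hboc,
    mro2 = purrr::map_dbl(regions, ~ mro2(ox$grid, .x)),
    hypoxic_fraction = hyp$total_fraction,
    boundary_hypoxic_fraction = hyp$boundary_fraction,
    converged = ox$converged,
    .before = 1)
  list(metrics = dplyr::relocate(bulk, "scenario", "region"),
       network = net, flow = flow, oxygen = ox, comp = comp, bc = bc)
}

#' Run the full pipeline for one configuration
#'
#' Network generation, tumor phantom, scenario application (hemodilution,
#' HBOC loading, boundary recalibration), shear adaptation, flow solve,
#' coupled oxygen solve, and bulk metrics. When `output_dir` is given, all
#' artifacts (network CSVs, tissue grid JSON, metrics CSV, manifest JSON)
#' are written there; runs with identical config and seed produce
#' byte-identical metrics CSVs.
#'
#' @param config A [run_config()].
#' @param output_dir Optional artifact directory.
#' @return Invisible list: `metrics` (tidy tibble, one row per region),
#'   `network`, `flow`, `oxygen`, `comp`, `bc`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), output_dir = NULL) {
  fixture <- build_fixture(config)
  res <- run_one_scenario(fixture, config, config$scenario)
  manifest <- list(
    package = "hbocsim",
    version = as.character(utils::packageVersion("hbocsim")),
    seed = config$seed,
    scenario = config$scenario,
    host_species = config$host_species,
    config_hash = config_hash(unclass(config)))
  res$manifest <- manifest
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    write_network_csv(res$network, file.path(output_dir, "network"))
    write_tissue_grid(res$oxygen$grid, file.path(output_dir, "tissue.json"))
    utils::write.csv(res$metrics, file.path(output_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}

#' Run several infusion scenarios on one shared network
#'
#' Generates the network and tumor phantom once, then applies each scenario
#' (composition, boundary recalibration, k_s-scaled adaptation, coupled
#' oxygen solve) from those identical initial conditions.
#'
#' @param config A [run_config()] (its `scenario` field is ignored).
#' @param scenarios Character vector of scenario names.
#' @param output_dir Optional artifact directory (metrics CSV + manifest).
#' @return List: `metrics` (tibble, one row per scenario x region),
#'   `runs` (named list of per-scenario results), `fixture`.
#' @export
run_scenario_sweep <- function(config = run_config(),
                               scenarios = infusion_scenarios()$name,
                               output_dir = NULL) {
  fixture <- build_fixture(config)
  runs <- purrr::map(scenarios, function(sc) {
    run_one_scenario(fixture, config, sc)
  })
  names(runs) <- scenarios
  metrics <- purrr::map_dfr(runs, "metrics")
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    utils::write.csv(metrics, file.path(output_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, scenarios = scenarios,
           config_hash = config_hash(unclass(config))),
      file.path(output_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  list(metrics = metrics, runs = runs, fixture = fixture)
}
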
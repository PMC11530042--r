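# End-to-end runners for the four study scenarios, driven by plain-list
# configs (YAML-serializable). All quantities in canonical units: mm, h,
# ug, ug/mL; diffusivities in configs carry explicit unit tags.

.scenario_names <- c("in_vitro_release", "agar", "rat_tibia",
                     "human_bone_plate")

#' Default scenario configuration
#'
#' Returns the packaged configuration for one of the four scenarios as a
#' plain nested list (class `scenario_config`). Geometry, transport,
#' clearance, source and run blocks can be overridden field-by-field with
#' `overrides` (a nested list merged over the defaults).
#'
#' Defaults follow the study conditions: MIC 2 ug/mL, toxicity 1000 ug/mL,
#' human half-life 4 h, free-water diffusivity 2.83e-6 cm^2/s, tissue
#' diffusivity 2.08e-6 cm^2/s, agar diffusivity 0.72 mm^2/h, human bone
#' stack 3.5 + 14 + 3.5 mm with 1 x 1 mm^2 cross-section, 3 mm tissue
#' domain, and a synthetic three-week Fickian release profile.
#'
#' @param scenario one of `"in_vitro_release"`, `"agar"`, `"rat_tibia"`,
#'   `"human_bone_plate"`.
#' @param overrides nested list of fields to replace.
#' @return a `scenario_config`.
#' @export
default_config <- function(scenario = .scenario_names, overrides = list()) {
  scenario <- match.arg(scenario)
  base <- switch(scenario,
    in_vitro_release = list(
      scenario = "in_vitro_release",
      geometry = list(slab_length_mm = 20.8, dx_mm = 0.4,
                      cross_section_mm2 = 1),
      transport = list(D_water = list(value = 2.83e-6, unit = "cm2/s")),
      clearance = list(half_life = "disabled"),
      source = list(initial_concentration = 1000),
      thresholds = list(MIC = 2, toxicity = 1000),
      run = list(t_end = 480, record_every = 12, seed = 1)
    ),
    agar = list(
      scenario = "agar",
      geometry = list(domain_mm = 90, dx_mm = 1, square_mm = 30,
                      thickness_mm = 4),
      transport = list(D_agar = list(value = 0.72, unit = "mm2/h")),
      clearance = list(half_life = "disabled"),
      source = list(type = "peppas", k = 0.95 / sqrt(504), n = 0.5,
                    t_end = 504, n_points = 211,
                    areal_load_ug_mm2 = 100),
      thresholds = list(MIC = 2, toxicity = 1000),
      run = list(t_end = 24, record_every = 6, seed = 1)
    ),
    rat_tibia = list(
      scenario = "rat_tibia",
      geometry = list(cortical_mm = 0.7, cancellous_mm = 1.6, dx_mm = 0.1,
                      cross_section_mm2 = 1),
      transport = list(bone = .default_bone_transport()),
      clearance = list(half_life = 4, mode = "increment"),
      source = list(dose_ug = 1),
      thresholds = list(MIC = 2, toxicity = 1000),
      run = list(t_end = 24, record_every = 0.25, seed = 1)
    ),
    human_bone_plate = list(
      scenario = "human_bone_plate",
      geometry = list(tissue_mm = 3, tissue_dx_mm = 0.1,
                      cortical_mm = 3.5, cancellous_mm = 14,
                      bone_dx_mm = 0.5, cross_section_mm2 = 1,
                      height_mm = 10),
      transport = list(tissue_D = list(value = 2.08e-6, unit = "cm2/s"),
                       bone = .default_bone_transport()),
      clearance = list(half_life = 4, mode = "increment"),
      source = list(type = "peppas", k = 0.95 / sqrt(504), n = 0.5,
                    t_end = 504, n_points = 211,
                    total_load = 100, coating_area = 1,
                    tissue_split = 0.5),
      thresholds = list(MIC = 2, toxicity = 1000),
      run = list(t_end = 24, record_every = 0.5, seed = 1)
    )
  )
  cfg <- .merge_lists(base, overrides)
  validate_config(cfg)
}

.default_bone_transport <- function() {
  tp <- bone_transport_defaults()
  list(
    cortical = list(D0 = tp$cortical$D0, delta = tp$cortical$delta,
                    phi = tp$cortical$phi, tau = tp$cortical$tau,
                    D_scale = 1),
    cancellous = list(D0 = tp$cancellous$D0, delta = tp$cancellous$delta,
                      phi = tp$cancellous$phi, tau = tp$cancellous$tau,
                      D_scale = 1)
  )
}

.merge_lists <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- .merge_lists(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Validate a scenario configuration
#'
#' Checks the scenario name, threshold ordering (MIC < toxicity) and, when
#' an explicit `run$dt` is present, the stability rule for every layer.
#'
#' @param config nested list.
#' @return the config, classed `scenario_config`.
#' @export
validate_config <- function(config) {
  if (!config$scenario %in% .scenario_names) {
    stop("unknown scenario '", config$scenario, "'")
  }
  th <- config$thresholds
  if (!is.null(th) && th$MIC >= th$toxicity) {
    stop("thresholds: MIC must be below the toxicity threshold")
  }
  if (!is.null(config$run$dt)) {
    for (D in .config_diffusivities(config)) {
      dx <- .config_dx_for_D(config)
      # conservative check against the finest dx in the config
      if (config$run$dt > min(dx)^2 / (6 * D) * (1 + 1e-9)) {
        .stability_error(config$run$dt, min(dx)^2 / (6 * D))
      }
    }
  }
  structure(config, class = c("scenario_config", "list"))
}

.config_diffusivities <- function(config) {
  tr <- config$transport
  out <- numeric(0)
  for (nm in c("D_water", "D_agar", "tissue_D")) {
    if (!is.null(tr[[nm]])) {
      out <- c(out, convert_diffusivity(tr[[nm]]$value, tr[[nm]]$unit, "mm2/h"))
    }
  }
  if (!is.null(tr$bone)) {
    for (ly in tr$bone) out <- c(out, .bone_layer_D(ly))
  }
  out
}

.config_dx_for_D <- function(config) {
  g <- config$geometry
  unlist(g[grepl("dx", names(g))])
}

# effective diffusivity of a bone layer config block, mm^2/h
.bone_layer_D <- function(ly) {
  if (!is.null(ly$D_mm2_h)) return(ly$D_mm2_h * (ly$D_scale %||% 1))
  tp <- transport_params(ly$D0, ly$delta, min(ly$phi, 1), ly$tau)
  convert_diffusivity(effective_diffusivity(tp), "cm2/s", "mm2/h") *
    (ly$D_scale %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write scenario configurations as YAML
#'
#' @param path YAML file path.
#' @param config a `scenario_config`.
#' @return `read_scenario_config` returns a validated `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_scenario_config
#' @export
write_scenario_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Resolve the source block to a release_profile (with optional seeded noise).
.resolve_profile <- function(src, seed = 1) {
  if (!is.null(src$path)) return(read_release_profile(src$path))
  type <- src$type %||% "peppas"
  total <- src$total_load %||%
    ((src$areal_load_ug_mm2 %||% 100) * (src$coating_area_mm2 %||% 900))
  area <- src$coating_area %||% src$coating_area_mm2 %||% 900
  prof <- switch(type,
    peppas = peppas_profile(src$k %||% (0.95 / sqrt(504)), src$n %||% 0.5,
                            src$t_end %||% 504, src$n_points %||% 211,
                            total_load = total, coating_area = area),
    default = default_release_profile(total_load = total,
                                      coating_area = area),
    stop("unknown source type '", type, "'"))
  if (!is.null(src$noise) && (src$noise$magnitude %||% 0) > 0) {
    prof <- gen_release_measurements(
      prof, noise_spec(src$noise$kind %||% "gaussian_relative",
                       src$noise$magnitude, seed = seed))
  }
  prof
}

#' Simulate the in vitro release experiment
#'
#' One-dimensional slab of coating, initially at uniform concentration,
#' sealed at the substrate face and releasing into a perfect sink (the
#' receiving medium) over 20 days; clearance disabled and the free-water
#' diffusivity of vancomycin used throughout, matching the experiment's
#' assumptions. The slab length is an effective diffusion length (the
#' coating geometry itself is a documented assumption).
#'
#' @param config a `scenario_config` for `"in_vitro_release"`.
#' @return list of class `in_vitro_result`: `series` (data.frame time,
#'   fraction_released), `result` (the `sim_result`), `L_eff` (mm, the
#'   continuous-domain length implied by the discrete sink), `D` (mm^2/h).
#' @export
run_in_vitro_release <- function(config = default_config("in_vitro_release")) {
  stopifnot(config$scenario == "in_vitro_release")
  if (!identical(config$clearance$half_life, "disabled")) {
    warning("in vitro release assumes no degradation; clearance enabled ",
            "in config deviates from the experiment")
  }
  D <- convert_diffusivity(config$transport$D_water$value,
                           config$transport$D_water$unit, "mm2/h")
  g <- config$geometry
  grid <- grid_1d(layer_spec("coating", g$slab_length_mm, D), g$dx_mm,
                  g$cross_section_mm2)
  C0 <- rep(config$source$initial_concentration, grid$n)
  # The sink pin sits at the last cell center, so the continuous slab ends
  # there: the sink cell holds only the half of its volume inside the slab.
  C0[grid$n] <- C0[grid$n] / 2
  res <- simulate_1d(grid, left = bc_no_flux(), right = bc_sink(),
                     clearance = .config_clearance(config),
                     t_end = config$run$t_end, dt = config$run$dt %||% NULL,
                     record_every = config$run$record_every, C0 = C0)
  m0 <- res$ledger$stored_initial
  stored <- rowSums(res$states) * grid$cell_volume_mL
  series <- data.frame(time = res$times, fraction_released = 1 - stored / m0)
  structure(list(series = series, result = res,
                 L_eff = (grid$n - 0.5) * grid$dx, D = D),
            class = "in_vitro_result")
}

.config_clearance <- function(config) {
  cl <- config$clearance
  if (identical(cl$half_life, "disabled") || is.null(cl$half_life)) {
    clearance_disabled()
  } else {
    clearance_spec(cl$half_life, mode = cl$mode %||% "increment")
  }
}

#' Simulate the agar inhibition-zone assay
#'
#' A coated square substrate (default 3 x 3 cm) releases into a thin agar
#' layer discretized in 2-D; after 24 h the inhibition area is the region
#' where the concentration meets the MIC. Clearance is disabled (agar does
#' not eliminate drug). Errors if the MIC front reaches the domain edge.
#'
#' @param config a `scenario_config` for `"agar"`.
#' @return list of class `agar_result`: `result`, `area_cm2`, `zone_map`,
#'   `field` (24-h concentration matrix), `grid`.
#' @export
run_agar <- function(config = default_config("agar")) {
  stopifnot(config$scenario == "agar")
  g <- config$geometry
  D <- convert_diffusivity(config$transport$D_agar$value,
                           config$transport$D_agar$unit, "mm2/h")
  n <- round(g$domain_mm / g$dx_mm)
  side <- round(g$square_mm / g$dx_mm)
  mask <- centered_square_mask(n, n, side)
  grid <- grid_2d(n, n, g$dx_mm, D, thickness = g$thickness_mm,
                  source_mask = mask)
  src <- config$source
  src$coating_area_mm2 <- src$coating_area_mm2 %||% (g$square_mm^2)
  prof <- .resolve_profile(src, seed = config$run$seed %||% 1)
  res <- simulate_2d(grid, source_flux_fn = profile_flux_fn(prof),
                     clearance = .config_clearance(config),
                     t_end = config$run$t_end, dt = config$run$dt %||% NULL,
                     record_every = config$run$record_every)
  field <- res$states[[length(res$states)]]
  edge <- c(field[1, ], field[n, ], field[, 1], field[, n])
  if (max(edge) >= config$thresholds$MIC) {
    stop("MIC front reached the domain edge; enlarge geometry$domain_mm")
  }
  area <- inhibition_area(field, grid, MIC = config$thresholds$MIC,
                          include_source = TRUE)
  zm <- classify_zones(field, config$thresholds$MIC,
                       config$thresholds$toxicity, dx = grid$dx)
  structure(list(result = res, area_cm2 = area, zone_map = zm,
                 field = field, grid = grid),
            class = "agar_result")
}

#' Simulate the rat-tibia bolus validation scenario
#'
#' One-dimensional cortical-cancellous-cortical stack at rat scale; the
#' injected dose is deposited uniformly in the cancellous compartment at
#' t = 0 and eliminated with a 4-h half-life while diffusing into the
#' cortical shells. Output is the cortical-region average concentration
#' over time (rise to a peak within hours, then decay), the quantity
#' compared against published in vivo measurements.
#'
#' @param config a `scenario_config` for `"rat_tibia"`.
#' @return list of class `rat_tibia_result`: `series` (time, cortical
#'   average, ug/mL), `result`.
#' @export
run_rat_tibia <- function(config = default_config("rat_tibia")) {
  stopifnot(config$scenario == "rat_tibia")
  if (is.null(config$source$dose_ug)) stop("source$dose_ug is required")
  g <- config$geometry
  b <- config$transport$bone
  Dcort <- .bone_layer_D(b$cortical)
  Dcanc <- .bone_layer_D(b$cancellous)
  grid <- grid_1d(list(
    layer_spec("cortical", g$cortical_mm, Dcort, b$cortical$phi),
    layer_spec("cancellous", g$cancellous_mm, Dcanc, b$cancellous$phi),
    layer_spec("cortical", g$cortical_mm, Dcort, b$cortical$phi)
  ), g$dx_mm, g$cross_section_mm2)
  canc <- grid$cell_layer == "cancellous"
  C0 <- numeric(grid$n)
  C0[canc] <- config$source$dose_ug / (sum(canc) * grid$cell_volume_mL)
  res <- simulate_1d(grid, clearance = .config_clearance(config),
                     t_end = config$run$t_end, dt = config$run$dt %||% NULL,
                     record_every = config$run$record_every, C0 = C0)
  series <- average_concentration(res, "cortical")
  structure(list(series = series, result = res),
            class = "rat_tibia_result")
}

#' Simulate vancomycin delivery from a coated human bone plate
#'
#' The plate sits between muscle tissue and bone and releases in both
#' directions; the two sides are modeled as independent 1-D domains sharing
#' the release flux (`source$tissue_split` to tissue, remainder to bone).
#' Tissue: 3 mm domain at the agar-like tissue diffusivity. Bone: a
#' cortical (3.5 mm) - cancellous (14 mm) - cortical (3.5 mm) stack using
#' effective diffusivities from the porous-media relation. First-order
#' clearance (default half-life 4 h) acts as a volumetric negative source.
#'
#' @param config a `scenario_config` for `"human_bone_plate"`.
#' @return list of class `bone_plate_result`: `tissue`, `bone`
#'   (`sim_result`s), `tissue_series`, `bone_series` (near-plate averages),
#'   `zones` (zone maps of the bone domain at recorded times 1, 12, 24 h
#'   when available), `summary` (peak value/time of the tissue average).
#' @export
run_human_bone_plate <- function(config = default_config("human_bone_plate")) {
  stopifnot(config$scenario == "human_bone_plate")
  g <- config$geometry
  Dt <- convert_diffusivity(config$transport$tissue_D$value,
                            config$transport$tissue_D$unit, "mm2/h")
  b <- config$transport$bone
  Dcort <- .bone_layer_D(b$cortical)
  Dcanc <- .bone_layer_D(b$cancellous)
  tissue_grid <- grid_1d(layer_spec("tissue", g$tissue_mm, Dt),
                         g$tissue_dx_mm, g$cross_section_mm2)
  bone_grid <- grid_1d(list(
    layer_spec("cortical", g$cortical_mm, Dcort, b$cortical$phi),
    layer_spec("cancellous", g$cancellous_mm, Dcanc, b$cancellous$phi),
    layer_spec("cortical", g$cortical_mm, Dcort, b$cortical$phi)
  ), g$bone_dx_mm, g$cross_section_mm2)
  prof <- .resolve_profile(config$source, seed = config$run$seed %||% 1)
  split <- config$source$tissue_split %||% 0.5
  clr <- .config_clearance(config)
  run <- config$run
  tissue <- simulate_1d(tissue_grid,
                        left = bc_flux_in(profile_flux_fn(prof, split)),
                        clearance = clr, t_end = run$t_end,
                        dt = run$dt %||% NULL,
                        record_every = run$record_every)
  bone <- simulate_1d(bone_grid,
                      left = bc_flux_in(profile_flux_fn(prof, 1 - split)),
                      clearance = clr, t_end = run$t_end,
                      dt = run$dt %||% NULL,
                      record_every = run$record_every)
  tissue_series <- average_concentration(tissue)
  bone_near <- average_concentration(
    bone, seq_len(max(1L, round(1 / bone_grid$dx))))
  zones <- lapply(intersect(c(1, 12, 24), bone$times), function(tt) {
    classify_zones(bone$states[match(tt, bone$times), ],
                   config$thresholds$MIC, config$thresholds$toxicity,
                   dx = bone_grid$dx)
  })
  peak_idx <- which.max(tissue_series$concentration)
  structure(list(
    tissue = tissue, bone = bone,
    tissue_series = tissue_series, bone_series = bone_near,
    zones = zones,
    summary = list(peak_concentration = tissue_series$concentration[peak_idx],
                   peak_time = tissue_series$time[peak_idx])),
    class = "bone_plate_result")
}

#' Run any scenario from its configuration
#'
#' Dispatches on `config$scenario` and optionally writes the standard output
#' set (snapshot matrices and series as tab-separated text, ledger and
#' summary as JSON) into `out_dir`.
#'
#' @param config a `scenario_config`.
#' @param out_dir optional output directory.
#' @return the scenario result object.
#' @export
run_scenario <- function(config, out_dir = NULL) {
  config <- validate_config(config)
  res <- switch(config$scenario,
                in_vitro_release = run_in_vitro_release(config),
                agar = run_agar(config),
                rat_tibia = run_rat_tibia(config),
                human_bone_plate = run_human_bone_plate(config))
  if (!is.null(out_dir)) write_scenario_outputs(res, out_dir)
  res
}
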
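test_that("packaged configs load, validate, and reject bad thresholds", {
  cfg_dir <- system.file("extdata", "configs", package = "vancoelute")
  for (sc in c("in_vitro_release", "agar", "rat_tibia", "human_bone_plate")) {
    cfg <- read_scenario_config(file.path(cfg_dir, paste0(sc, ".yaml")))
    expect_s3_class(cfg, "scenario_config")
    expect_equal(cfg$scenario, sc)
  }
  expect_error(default_config("agar", list(thresholds = list(MIC = 2000))),
               "MIC")
  expect_error(validate_config(list(scenario = "femur")), "unknown")
  expect_error(default_config("rat_tibia", list(run = list(dt = 10))),
               class = "vanco_stability_error")
})

test_that("in vitro release reproduces the analytic slab curve", {
  cfg <- default_config("in_vitro_release",
                        list(geometry = list(dx_mm = 0.8),
                             run = list(t_end = 480, record_every = 48)))
  iv <- run_in_vitro_release(cfg)
  expect_equal(iv$series$fraction_released[1], 0)
  expect_true(all(diff(iv$series$fraction_released) >= 0))
  an <- slab_release_analytic(iv$D, iv$L_eff, iv$series$time[-1])
  fd <- iv$series$fraction_released[-1]
  expect_lt(max(abs(fd - an) / an), 0.02)
  expect_gt(max(fd), 0.9) # three-week design: most of the load released
  expect_lt(mass_balance(iv$result)$closure_error, 1e-6)
  expect_warning(
    run_in_vitro_release(default_config(
      "in_vitro_release",
      list(clearance = list(half_life = 4),
           geometry = list(dx_mm = 0.8),
           run = list(t_end = 24, record_every = 24)))),
    "deviates")
})

test_that("doubling the slab thickness quadruples the half-release time", {
  t50 <- function(L) {
    cfg <- default_config("in_vitro_release",
                          list(geometry = list(slab_length_mm = L,
                                               dx_mm = L / 26),
                               run = list(t_end = 480, record_every = 2)))
    s <- run_in_vitro_release(cfg)$series
    i <- which(s$fraction_released >= 0.5)[1]
    # linear interpolation between the bracketing snapshots
    stats::approx(s$fraction_released[(i - 1):i], s$time[(i - 1):i],
                  xout = 0.5)$y
  }
  r <- t50(20.8) / t50(10.4)
  expect_equal(r, 4, tolerance = 0.05)
})

test_that("agar assay yields an inhibition area beyond the footprint", {
  cfg <- default_config("agar", list(geometry = list(dx_mm = 2)))
  ag <- run_agar(cfg)
  expect_gt(ag$area_cm2, 9) # any positive release pushes the front outward
  expect_lt(mass_balance(ag$result)$closure_error, 1e-6)
  # area is non-decreasing in the total drug released
  cfg_lo <- default_config("agar", list(
    geometry = list(dx_mm = 2),
    source = list(areal_load_ug_mm2 = 10)))
  expect_lte(run_agar(cfg_lo)$area_cm2, ag$area_cm2)
  # zero source: only the footprint counts
  cfg0 <- default_config("agar", list(
    geometry = list(dx_mm = 2),
    source = list(areal_load_ug_mm2 = 1e-9)))
  expect_equal(run_agar(cfg0)$area_cm2, 9)
})

test_that("agar run fails loudly when the MIC front hits the edge", {
  cfg <- default_config("agar", list(
    geometry = list(domain_mm = 34, dx_mm = 2),
    run = list(t_end = 24, record_every = 12)))
  expect_error(run_agar(cfg), "enlarge")
})

test_that("rat tibia bolus rises to a cortical peak then decays away", {
  cfg <- default_config("rat_tibia", list(run = list(t_end = 40,
                                                     record_every = 0.5)))
  rt <- run_rat_tibia(cfg)
  conc <- rt$series$concentration
  pk <- which.max(conc)
  expect_gt(pk, 1)                       # rises from zero
  expect_lt(rt$series$time[pk], 12)      # peak within hours
  expect_lt(conc[length(conc)], 0.01 * conc[pk]) # < 1% of peak at 10 t_half
  expect_lt(mass_balance(rt$result)$closure_error, 1e-6)
  # dose = 0: identically zero; doubling the dose doubles the series
  expect_true(all(run_rat_tibia(default_config(
    "rat_tibia", list(source = list(dose_ug = 0),
                      run = list(t_end = 6, record_every = 1)))
  )$series$concentration == 0))
  short <- list(run = list(t_end = 6, record_every = 1))
  s1 <- run_rat_tibia(default_config("rat_tibia", short))$series
  s2 <- run_rat_tibia(default_config(
    "rat_tibia", c(short, list(source = list(dose_ug = 2)))))$series
  expect_equal(s2$concentration, 2 * s1$concentration, tolerance = 1e-9)
  expect_error(run_rat_tibia(default_config(
    "rat_tibia", list(source = list(dose_ug = NULL)))), "dose")
})

test_that("bone-plate tissue series shows the half-life phenomenology", {
  base <- coarse_plate_config()
  bp <- run_human_bone_plate(base)
  conc <- bp$tissue_series$concentration
  pk <- which.max(conc)
  # single global maximum: strictly rising before, non-increasing after
  expect_true(all(diff(conc[seq_len(pk)]) > 0))
  expect_true(all(diff(conc[pk:length(conc)]) <= 1e-9))
  expect_gt(pk, 1); expect_lt(pk, length(conc))
  # clearance disabled: non-decreasing while flux > 0
  bp0 <- run_human_bone_plate(coarse_plate_config(
    list(clearance = list(half_life = "disabled"))))
  expect_true(all(diff(bp0$tissue_series$concentration) >= 0))
  # 6-h half-life curve dominates the 4-h curve pointwise after t = 0
  bp6 <- run_human_bone_plate(coarse_plate_config(
    list(clearance = list(half_life = 6))))
  expect_true(all(bp6$tissue_series$concentration[-1] >=
                    bp$tissue_series$concentration[-1]))
  # ledgers close
  expect_lt(mass_balance(bp$tissue)$closure_error, 1e-6)
  expect_lt(mass_balance(bp$bone)$closure_error, 1e-6)
})

test_that("cortical bone next to the plate outconcentrates the cancellous core", {
  bp <- run_human_bone_plate(coarse_plate_config())
  grid <- bp$bone$grid
  near <- which(grid$cell_layer == "cortical" &
                  grid$positions < 3.5)
  canc <- which(grid$cell_layer == "cancellous")
  for (k in seq_along(bp$bone$times)[-1]) {
    expect_gte(mean(bp$bone$states[k, near]),
               mean(bp$bone$states[k, canc]))
  }
})

test_that("run_scenario dispatches and writes the standard outputs", {
  out <- tempfile()
  cfg <- default_config("rat_tibia", list(run = list(t_end = 4,
                                                     record_every = 1)))
  res <- run_scenario(cfg, out_dir = out)
  expect_s3_class(res, "rat_tibia_result")
  expect_true(all(file.exists(file.path(
    out, c("cortical_series.tsv", "snapshots.tsv", "ledger.json",
           "summary.json")))))
  led <- jsonlite::fromJSON(file.path(out, "ledger.json"))
  expect_lt(led$closure_error, 1e-6)
})
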
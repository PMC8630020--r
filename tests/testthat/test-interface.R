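test_that("profile tables are read with unit normalisation and censoring", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,depth_m,species,value,unit,sd",
               "A,0.1,O2,150,uM,5",
               "A,0.5,DIC,2.4,mmol/L,",
               "A,1.0,TOC,0.35,percent_dw,"), f)
  d <- read_profile_table(f)
  expect_equal(nrow(d), 3)
  expect_equal(d$value, c(0.15, 2.4, 0.35))
  expect_equal(d$sd[1], 5e-3)
  expect_false(any(d$censored))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,depth_m,species,value,unit,sd",
               "A,0.2,NH4,<0.1,uM,"), f2)
  d2 <- read_profile_table(f2)
  expect_true(d2$censored)
  expect_equal(d2$value, 1e-4)
})

test_that("malformed profile tables fail with row-level messages", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,species,value,unit", "A,O2,1,uM"), f)
  expect_error(read_profile_table(f), "depth_m")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,depth_m,species,value,unit",
               "A,0.1,O2,150,uM", "A,0.2,CH4,1,uM"), f2)
  expect_error(read_profile_table(f2), "row 2: unknown species")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,depth_m,species,value,unit",
               "A,0.1,O2,150,furlongs"), f3)
  expect_error(read_profile_table(f3), "row 1: unknown unit")
})

test_that("writing and re-reading a profile table is lossless", {
  sol <- preset_solution("NPG-like")$solution
  obs <- generate_observations(sol, n_depths = 12, noise_cv = 0.1, seed = 8)
  f <- withr::local_tempfile(fileext = ".csv")
  write_profile_table(obs, f)
  back <- read_profile_table(f)
  expect_equal(back$depth, obs$depth, tolerance = 1e-12)
  expect_equal(back$value, obs$value, tolerance = 1e-12)
  expect_identical(back$censored, obs$censored)
})

test_that("run configurations reject unknown keys", {
  f <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("preset: AMOR-like", "run:", "  seed: 3", "  n_e: 8"), f)
  cfg <- read_run_config(f)
  expect_equal(cfg$preset, "AMOR-like")
  expect_equal(cfg$run$seed, 3)

  f2 <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("preset: AMOR-like", "run:", "  turbo: yes"), f2)
  expect_error(read_run_config(f2), "unknown run key")

  f3 <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("site:", "  name: x", "  warp_factor: 9"), f3)
  expect_error(read_run_config(f3), "unknown site key")
})

test_that("the pipeline runs end to end and masks energetics to the oxic zone", {
  pl <- run_pipeline("AMOR-like", seed = 7)
  expect_s3_class(pl, "sed_pipeline")
  expect_true(is.finite(pl$opd))
  expect_true(all(pl$thermo$depth < pl$opd))
  expect_true(all(pl$cell_power$x <= 1))
  expect_equal(pl$aoa_fit$n, 40)
  # same seed, same bundle
  pl2 <- run_pipeline("AMOR-like", seed = 7)
  expect_identical(pl$cell_power, pl2$cell_power)
  # bundle serialises to JSON
  f <- withr::local_tempfile(fileext = ".json")
  write_bundle_json(pl, f)
  doc <- jsonlite::read_json(f)
  expect_equal(doc$aoa_fit$n, 40)
  expect_equal(length(doc$power$Ps_W_m3), nrow(pl$power))
})

test_that("pipeline configs built from YAML resolve with defaults", {
  f <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("preset: NPG-like", "run:", "  n_samples: 20",
               "  seed: 11"), f)
  pl <- run_pipeline(read_run_config(f))
  expect_equal(pl$resolved_config$run$n_samples, 20)
  expect_equal(pl$aoa_fit$n, 20)
  expect_identical(pl$opd, Inf)
  # the whole 8 m stays oxic, so the oxic extent falls back to the domain
  expect_equal(pl$oxic_extent, 8)
})

test_that("the packaged site table lists the eight cores", {
  tab <- site_properties()
  expect_equal(nrow(tab), 8)
  expect_true("SPG_U1370" %in% tab$core)
  expect_equal(tab$water_depth_m[tab$core == "SAST"], 4424)
})
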
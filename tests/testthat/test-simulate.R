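test_that("the default design has the two-block 34-treatment structure", {
  d <- design_experiments()
  expect_equal(nrow(d), 34)
  expect_equal(sum(d$block == "factorial"), 9)
  expect_equal(sum(d$block == "panel"), 25)
  expect_equal(nrow(design_experiments(panel = FALSE)), 9)
  expect_equal(nrow(design_experiments(factorial = FALSE)), 25)
  expect_setequal(unique(d$nitrogen), c(270, 135, 0))
  d3 <- design_experiments(stages = c("heading", "flowering", "grain-filling"))
  expect_equal(nrow(d3), 102)
  expect_false(anyDuplicated(d3$treatment_id) > 0)
})

test_that("noise-free plants have exactly affine vertical gradients", {
  g <- default_gradients()
  for (tr in c("M_dry", "C_w", "C_N", "C_ch")) {
    g[[tr]]$plant_sd <- 0
    g[[tr]]$segment_sd <- 0
  }
  pl <- generate_plant(mini_design(1), g, seed = 51, quantize = FALSE,
                       residue_model = "none")
  seg <- pl$segments
  prof <- relative_height_profile(seg, c("C_w", "C_N", "C_ch"))
  for (tr in c("C_w", "C_N", "C_ch")) {
    d2 <- diff(diff(prof[[tr]]) / diff(prof$rel_height))
    expect_equal(d2, rep(0, length(d2)), tolerance = 1e-9)
  }
  # gradient directions: M_dry and C_w rise toward the base, C_N/C_ch fall
  expect_true(all(diff(seg$M_dry) < 0))
  expect_true(all(diff(seg$C_w) < 0))
  expect_true(all(diff(seg$C_N) > 0))
  expect_true(all(diff(seg$C_ch) > 0))
})

test_that("every generated segment obeys the fresh-weight mass balance", {
  des <- mini_design(4)
  for (i in 1:4) {
    pl <- generate_plant(des[i, ], seed = 60 + i, plant_id = paste0("Q", i))
    seg <- pl$segments
    expect_equal(seg$M_dry, (1 - seg$C_w / 100) * seg$fresh_weight,
                 tolerance = 1e-12)
    expect_equal(seg$fresh_weight, round(seg$fresh_weight, 2))
    expect_lte(pl$plant$cum_fresh_weight, pl$plant$total_fresh_weight * 1.05)
  }
  p1 <- generate_plant(des[1, ], seed = 9, plant_id = "A")
  p2 <- generate_plant(des[1, ], seed = 9, plant_id = "A")
  expect_identical(p1, p2)
})

test_that("the forward model is the baseline at zero traits and monotone in each trait", {
  cfg <- default_forward_config(scatter_sd = 0, noise_sd = 0)
  wl <- canonical_grid()
  zero <- traits_to_reflectance(c(M_dry = 0, C_w = 0, C_N = 0, C_ch = 0),
                                cfg, seed = 1)
  base <- spectraits:::forward_baseline(cfg, wl)
  expect_equal(zero$reflectance, pmin(pmax(base, 0), 1.5), tolerance = 1e-12)
  # increasing any trait strictly lowers reflectance at its feature centers
  centers <- c(M_dry = 2100, C_w = 1450, C_N = 2180, C_ch = 662)
  for (tr in names(centers)) {
    lo <- hi <- c(M_dry = 1, C_w = 50, C_N = 10, C_ch = 1)
    hi[tr] <- hi[tr] * 2
    rlo <- traits_to_reflectance(lo, cfg, seed = 1)
    rhi <- traits_to_reflectance(hi, cfg, seed = 1)
    i <- which(wl == centers[tr])
    expect_lt(rhi$reflectance[i], rlo$reflectance[i])
  }
  r1 <- traits_to_reflectance(c(M_dry = 1, C_w = 70, C_N = 20, C_ch = 2),
                              seed = 77)
  r2 <- traits_to_reflectance(c(M_dry = 1, C_w = 70, C_N = 20, C_ch = 2),
                              seed = 77)
  expect_identical(r1, r2)
})

test_that("residue draws are right-skewed, bounded and calibrated", {
  off <- simulate_residue(100, "none", seed = 1)
  expect_equal(off$cfw, 100)
  expect_equal(off$rr, 0)
  draws <- simulate_residue(rep(100, 2000), seed = 2)
  expect_true(all(draws$cfw <= 100))
  expect_true(all(draws$rr >= 0))
  expect_gte(mean(draws$rr < 4), 0.75)
  expect_error(simulate_residue(0), "> 0")
})

test_that("datasets assemble at the configured scale with partial labels", {
  ds <- mini_dataset(6, plants = 2, seed = 70, band_step = 100)
  expect_equal(nrow(ds$plants), 12)
  n <- nrow(ds$segments)
  expect_gt(n, 12 * 7)            # plants are ~8-12 segments tall
  expect_equal(nrow(ds$spectra), n)
  expect_true(all(ds$segments$segment_id %in% rownames(ds$spectra)))
  expect_false(anyNA(ds$segments$M_dry))
  expect_false(anyNA(ds$segments$C_w))
  expect_equal(sum(!is.na(ds$segments$C_N)), round(n * 250 / 1806))
  expect_equal(sum(!is.na(ds$segments$C_ch)), round(n * 200 / 1806))
  expect_false(anyNA(ds$segments$true_C_N))
})

test_that("dataset generation and its file layout are bit-reproducible", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  mini_dataset(3, plants = 1, seed = 71, band_step = 100, out_dir = d1)
  mini_dataset(3, plants = 1, seed = 71, band_step = 100, out_dir = d2)
  for (f in c("treatments.csv", "plants.csv", "segments.csv", "spectra.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  back <- read_dataset(d1)
  fresh <- mini_dataset(3, plants = 1, seed = 71, band_step = 100)
  expect_equal(back$spectra, fresh$spectra, tolerance = 0)
  expect_equal(back$segments$M_dry, fresh$segments$M_dry, tolerance = 0)
})
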
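test_that("R2 and RMSE follow their definitions", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 4)), sqrt(1 / 3))
  expect_error(r_squared(c(2, 2), c(1, 3)), "zero variance")
  # R2 <= 1 always, = 1 iff exact
  set.seed(41)
  for (i in 1:20) {
    t <- rnorm(10); p <- rnorm(10)
    expect_lte(r_squared(t, p), 1)
  }
})

test_that("leave-one-treatment-out folds partition the treatments", {
  trs <- design_experiments()$treatment_id
  folds <- loto_folds(trs)
  expect_length(folds, 34)
  held <- vapply(folds, `[[`, "", "test")
  expect_setequal(held, trs)
  expect_false(anyDuplicated(held) > 0)
  for (f in folds) {
    expect_false(f$test %in% f$train)
    expect_setequal(c(f$train, f$test), trs)
  }
  expect_length(loto_folds(c("a", "b")), 2)
  expect_error(loto_folds("a"), ">= 2")
})

test_that("validation reports are structurally sound and deterministic", {
  ds <- mini_dataset(5, plants = 1, seed = 44)
  rep1 <- run_validation(ds, "C_w", seed = 9, n_restarts = 1, maxit = 25)
  rep2 <- run_validation(ds, "C_w", seed = 9, n_restarts = 1, maxit = 25)
  expect_identical(rep1$predictions, rep2$predictions)
  expect_identical(rep1$r2, rep2$r2)
  expect_length(rep1$folds, 5)
  # every segment appears in exactly one fold, predicted without its treatment
  expect_setequal(rep1$predictions$segment_id, ds$segments$segment_id)
  for (tid in unique(ds$segments$treatment_id)) {
    fold <- rep1$folds[[tid]]
    expect_true(all(fold$treatment_id == tid))
  }
})

test_that("near-noise-free synthetic data validates almost perfectly", {
  ds <- build_dataset(mini_design(5), plants_per_treatment = 1, seed = 45,
                      band_step = 50,
                      forward = default_forward_config(scatter_sd = 0,
                                                       noise_sd = 0),
                      residue_model = "none")
  rep <- run_validation(ds, "M_dry", "direct", seed = 3, n_restarts = 2,
                        maxit = 60)
  expect_gt(rep$r2, 0.99)
})

test_that("relative heights sit at stacked segment midpoints", {
  seg2 <- data.frame(position_index = 1:2, segment_length = 5,
                     M_dry = c(2, 1))
  prof <- relative_height_profile(seg2)
  expect_equal(prof$rel_height, c(0.25, 0.75))
  seg10 <- data.frame(position_index = 1:10, segment_length = 5,
                      M_dry = 10:1)
  expect_equal(relative_height_profile(seg10)$rel_height,
               seq(0.05, 0.95, by = 0.1))
  segu <- data.frame(position_index = 1:2, segment_length = c(2, 8),
                     M_dry = c(1, 2))
  expect_equal(relative_height_profile(segu)$rel_height, c(0.1, 0.6))
  seg1 <- data.frame(position_index = 1, segment_length = 5, M_dry = 1)
  expect_warning(p1 <- relative_height_profile(seg1), "degenerate")
  expect_true(attr(p1, "degenerate"))
})

test_that("profile interpolation reproduces affine relations exactly", {
  h <- c(0.05, 0.25, 0.45, 0.65, 0.85)
  v <- 2 + 3 * h
  g <- interpolate_profile(h, v)
  inside <- g$rel_height >= min(h) & g$rel_height <= max(h)
  expect_equal(g$value[inside], 2 + 3 * g$rel_height[inside])
  # beyond the midpoint span the end values are held
  expect_equal(g$value[g$rel_height > max(h)], rep(2 + 3 * max(h), 2))
  expect_equal(interpolate_profile(c(0.2, 0.8), c(5, 5))$value, rep(5, 10))
  expect_equal(interpolate_profile(c(0.25, 0.75), c(1, 2))$value[5], 1.5)
  expect_error(interpolate_profile(0.5, 1), ">= 2")
})

test_that("treatment profiles summarise per-height means and sds", {
  ds <- mini_dataset(3, plants = 2, seed = 46)
  prof <- profile_summary(ds$segments, c("M_dry", "C_w"))
  expect_setequal(unique(prof$trait), c("M_dry", "C_w"))
  expect_equal(sort(unique(prof$rel_height)), seq(0.1, 1, by = 0.1))
  expect_true(all(prof$sd >= 0 | is.na(prof$sd)))
  expect_equal(unique(prof$n_plants), 2)
})

test_that("trait correlations carry two-sided significance flags", {
  x <- seq(0, 1, length.out = 20)
  seg <- data.frame(M_dry = x, C_w = 1 - x,
                    C_N = x + 0.001 * sin(20 * x), C_ch = 2 * x)
  cm <- correlation_matrix(seg)
  expect_equal(diag(cm$r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cm$r["M_dry", "C_w"], -1)
  expect_equal(cm$r, t(cm$r))
  expect_true(cm$sig["M_dry", "C_N"])
  expect_error(correlation_matrix(seg[1:2, ]), ">= 3")
  segz <- seg; segz$C_ch <- 1
  w <- capture_warnings(cmz <- correlation_matrix(segz))
  expect_true(any(grepl("zero-variance", w)))
  expect_true(is.na(cmz$r["M_dry", "C_ch"]))
})

test_that("nitrogen and chlorophyll stay tightly coupled in generated data", {
  ds <- build_dataset(design_experiments()[c(1:9, 12, 18, 25), ],
                      plants_per_treatment = 1, seed = 47, band_step = 100)
  cm <- correlation_matrix(ds$segments,
                           c("M_dry", "C_w", "true_C_N", "true_C_ch"))
  expect_gt(cm$r["true_C_N", "true_C_ch"], 0.8)
  expect_true(cm$sig["true_C_N", "true_C_ch"])
})

test_that("correlation ANOVA is calm under the null and alert under signal", {
  # null: cultivars share identical generator settings
  des <- design_experiments(stages = "heading")[1:9, ]  # 3 cultivars x 3 N
  ps <- c()
  for (s in 1:8) {
    ds <- lapply(seq_len(nrow(des)), function(i)
      generate_plant(des[i, ], seed = 1000 * s + i,
                     plant_id = sprintf("s%d_p%d", s, i))$segments)
    seg <- do.call(rbind, ds)
    seg <- merge(seg, des[, c("treatment_id", "cultivar", "nitrogen", "stage")],
                 by = "treatment_id")
    a <- correlation_anova(seg, "cultivar")
    ps <- c(ps, a$p_value)
  }
  expect_gte(mean(ps > 0.05, na.rm = TRUE), 0.9)

  # alternative: two nitrogen levels with opposite-sign C_N/C_ch coupling
  set.seed(48)
  mk <- function(level, sign, g) {
    n <- 30
    z <- rnorm(n)
    data.frame(cultivar = g, nitrogen = level, stage = "heading",
               M_dry = rnorm(n), C_w = rnorm(n),
               C_N = z + rnorm(n, 0, 0.2),
               C_ch = sign * z + rnorm(n, 0, 0.2))
  }
  seg <- rbind(mk(0, 1, "a"), mk(0, 1, "b"), mk(0, 1, "c"),
               mk(270, -1, "a"), mk(270, -1, "b"), mk(270, -1, "c"))
  a <- correlation_anova(seg, "nitrogen")
  expect_lt(a$p_value[a$pair == "C_N:C_ch"], 0.01)

  seg1 <- seg[seg$nitrogen == 0, ]
  expect_error(correlation_anova(seg1, "nitrogen"), "single level")
})
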
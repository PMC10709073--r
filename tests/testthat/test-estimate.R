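# Helper: a C_w model that interpolates its training targets exactly, so a
# prediction at a training spectrum is that segment's true water content.
oracle_cw_model <- function(spectra, c_w) {
  m <- gpr_fit_fixed(spectra, c_w, gpr_params(1, 2, 0), jitter = 1e-12)
  m$trait <- "C_w"
  m
}

test_that("indirect estimation applies the water-content mass balance", {
  set.seed(21)
  X <- matrix(runif(40, 0.2, 0.6), 4, 10)
  m80 <- oracle_cw_model(X, c(80, 70, 60, 50))
  expect_equal(estimate_indirect(m80, X[1, ], 5), 1.0, tolerance = 1e-6)
  m100 <- gpr_fit_fixed(X, rep(100, 4), gpr_params(1, 2, 0))
  m100$trait <- "C_w"
  expect_equal(estimate_indirect(m100, X[1, ], 7.3), 0)
  m0 <- gpr_fit_fixed(X, rep(0, 4), gpr_params(1, 2, 0))
  m0$trait <- "C_w"
  expect_equal(estimate_indirect(m0, X[1, ], 2.5), 2.5)
  expect_error(estimate_indirect(m80, X[1, ], -1), ">= 0")
  mx <- m80; mx$trait <- "M_dry"
  expect_error(estimate_indirect(mx, X[1, ], 1), "need 'C_w'")
})

test_that("mass balance makes an oracle C_w predictor reproduce M_dry exactly", {
  des <- mini_design(3)
  for (i in 1:3) {
    pl <- generate_plant(des[i, ], seed = 30 + i, plant_id = paste0("P", i))
    seg <- pl$segments
    expect_equal((1 - seg$C_w / 100) * seg$fresh_weight, seg$M_dry,
                 tolerance = 1e-12)
  }
})

test_that("direct estimation floors negative means and checks the trait tag", {
  X <- matrix(seq(0, 1, length.out = 5), 5, 1)
  y <- c(2, 1.5, 1, 0.5, 0.01)
  m <- gpr_fit_fixed(X, y, gpr_params(4, 1.5, 1e-4), standardize = FALSE)
  m$trait <- "M_dry"
  # extrapolating the downward trend dips below zero before mean reversion
  raw <- predict_gpr(m, matrix(1.6, 1, 1))$mean
  expect_lt(raw, 0)
  expect_warning(out <- estimate_direct(m, matrix(1.6, 1, 1)), "clamped")
  expect_equal(out, 0)
  expect_equal(suppressWarnings(estimate_direct(m, X)), pmax(y, 0),
               tolerance = 0.02)
  m$trait <- "C_w"
  expect_error(estimate_direct(m, X), "need 'M_dry'")
})

test_that("ensemble weights follow inverse-RMSE cross-assignment", {
  w <- ensemble_weights(0.330, 0.270)
  expect_equal(w$w_on_indirect, 0.55)
  expect_equal(w$w_on_direct, 0.45)
  expect_equal(estimate_ensemble(3.0, 2.0, w), 2.45)
  weq <- ensemble_weights(0.4, 0.4)
  expect_equal(weq$w_on_indirect, 0.5)
  expect_equal(estimate_ensemble(1, 3, weq), 2)
  w0 <- ensemble_weights(0.5, 0)
  expect_equal(w0$w_on_indirect, 1)   # zero-RMSE indirect takes all weight
  expect_equal(estimate_ensemble(9, 2, w0), 2)
  expect_equal(ensemble_weights(0, 0)$w_on_indirect, 0.5)
  expect_error(ensemble_weights(-0.1, 0.2), "nonnegative")
})

test_that("ensemble estimates are convex and weights scale-invariant", {
  set.seed(22)
  for (i in 1:50) {
    rd <- runif(1, 0, 2); ri <- runif(1, 0, 2)
    if (rd + ri == 0) next
    w <- ensemble_weights(rd, ri)
    m_dir <- runif(1, 0, 5); m_in <- runif(1, 0, 5)
    en <- estimate_ensemble(m_dir, m_in, w)
    expect_gte(en, min(m_dir, m_in) - 1e-12)
    expect_lte(en, max(m_dir, m_in) + 1e-12)
    k <- runif(1, 0.1, 10)
    wk <- ensemble_weights(k * rd, k * ri)
    expect_equal(wk$w_on_indirect, w$w_on_indirect)
    expect_equal(estimate_ensemble(5, 5, w), 5)
  }
})

test_that("inner CV groups by treatment, clamps k, and is deterministic", {
  ds <- mini_dataset(4, plants = 1, seed = 12)
  r1 <- suppressWarnings(inner_cv_rmse(ds$segments, ds$spectra, "direct",
                                       k_folds = 3, seed = 5))
  r2 <- suppressWarnings(inner_cv_rmse(ds$segments, ds$spectra, "direct",
                                       k_folds = 3, seed = 5))
  expect_identical(r1, r2)
  expect_gt(r1, 0)
  expect_warning(
    suppressMessages(inner_cv_rmse(ds$segments, ds$spectra, "direct",
                                   k_folds = 10, seed = 5)),
    "reduced")
  one <- ds$segments[ds$segments$treatment_id == ds$segments$treatment_id[1], ]
  expect_error(inner_cv_rmse(one, ds$spectra, "direct"), ">= 2 treatment")
})

test_that("a perfect predictor drives the inner-CV RMSE to zero", {
  ds <- mini_dataset(4, plants = 1, seed = 13)
  oracle <- function(method, train, Xtr) {
    function(test, Xte) test$M_dry
  }
  r <- inner_cv_rmse(ds$segments, ds$spectra, "direct", seed = 1,
                     predictor = oracle, k_folds = 4)
  expect_lt(r, 1e-3)
})

test_that("one model is trained per sufficiently labelled trait", {
  ds <- mini_dataset(6, plants = 2, seed = 14)
  seg <- ds$segments
  # relabel generously so all four traits clear the threshold
  seg$C_N <- seg$true_C_N
  seg$C_ch <- seg$true_C_ch
  models <- train_trait_models(seg, ds$spectra, seed = 2, n_restarts = 1,
                               maxit = 25)
  expect_named(models, c("M_dry", "C_w", "C_N", "C_ch"))
  for (tr in names(models)) expect_identical(models[[tr]]$trait, tr)

  seg2 <- seg
  seg2$C_N <- NA_real_
  seg2$C_ch[-(1:5)] <- NA_real_   # 5 labels: below the 10-segment threshold
  w <- capture_warnings(
    m2 <- train_trait_models(seg2, ds$spectra, seed = 2, n_restarts = 1,
                             maxit = 25))
  expect_true(any(grepl("skipped", w)))
  expect_named(m2, c("M_dry", "C_w"))
  seg3 <- seg[1:4, ]
  expect_error(suppressWarnings(
    train_trait_models(seg3, ds$spectra, seed = 2)), "no trait")
})

test_that("model bundles round-trip through disk", {
  ds <- mini_dataset(3, plants = 1, seed = 15)
  models <- suppressWarnings(
    train_trait_models(ds$segments, ds$spectra, traits = c("M_dry", "C_w"),
                       seed = 2, n_restarts = 1, maxit = 25))
  dir <- withr::local_tempdir()
  save_model_bundle(models, dir, rmses = c(direct = 0.33, indirect = 0.27),
                    seed = 2, wavelengths = ds$wavelengths)
  back <- load_model_bundle(dir)
  expect_setequal(names(back$models), c("M_dry", "C_w"))
  expect_equal(back$manifest$rmse_direct, 0.33)
  Xq <- ds$spectra[1:3, ]
  expect_equal(predict_gpr(back$models$M_dry, Xq)$mean,
               predict_gpr(models$M_dry, Xq)$mean, tolerance = 1e-12)
})
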
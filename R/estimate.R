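# The four trait estimators and the Direct / In-Direct / Ensemble dry-matter
# scheme.
#
# Traits and units (fixed by the measurement protocol):
#   M_dry  segment dry matter, g
#   C_w    water content, % of fresh weight
#   C_N    nitrogen content, g/kg dry mass
#   C_ch   chlorophyll content, mg/g dry mass

TRAITS <- c("M_dry", "C_w", "C_N", "C_ch")

trait_units <- c(M_dry = "g", C_w = "%", C_N = "g/kg", C_ch = "mg/g")

check_trait <- function(trait) {
  stop_if(!trait %in% TRAITS, "unknown trait '%s' (expected one of %s)",
          trait, paste(TRAITS, collapse = ", "))
  trait
}

# Clamp predicted concentrations to physical ranges, warning when any value
# was moved.  C_w lives in [0, 100] %, the others are nonnegative.
clamp_trait <- function(values, trait, warn = TRUE) {
  lo <- 0
  hi <- if (trait == "C_w") 100 else Inf
  out <- pmin(pmax(values, lo), hi)
  n_moved <- sum(out != values)
  if (warn && n_moved > 0)
    warn_f("clamped %d %s prediction(s) to [%g, %g] %s",
           n_moved, trait, lo, hi, trait_units[[trait]])
  out
}

#' Train one GP model per biochemical trait
#'
#' Fits a GP regression of each measured trait on the reflectance spectra of
#' the segments that carry a measurement for it.  Traits with fewer than
#' `min_n` labelled segments are skipped with a warning (nitrogen and
#' chlorophyll are typically assayed only on a labelled subset).
#'
#' @param segments data.frame with column `segment_id` and one column per
#'   trait (`M_dry`, `C_w`, `C_N`, `C_ch`); `NA` marks an unlabelled segment.
#' @param spectra reflectance matrix, rownames = segment ids.
#' @param traits traits to attempt, default all four.
#' @param min_n minimum labelled segments per trait.
#' @param seed seed for the hyperparameter starts.
#' @param ... passed to [fit_gpr()] (`n_restarts`, `maxit`, `init`, ...).
#' @return Named list of `gpr_model`s, each tagged with its trait.
#' @export
train_trait_models <- function(segments, spectra, traits = TRAITS,
                               min_n = 10, seed = 1L, ...) {
  stop_if(!"segment_id" %in% names(segments),
          "train_trait_models: segments need a 'segment_id' column")
  stop_if(is.null(rownames(spectra)),
          "train_trait_models: spectra need segment-id rownames")
  models <- list()
  for (tr in traits) {
    check_trait(tr)
    if (!tr %in% names(segments)) {
      warn_f("trait %s has no measurement column; skipped", tr)
      next
    }
    lab <- segments[!is.na(segments[[tr]]), , drop = FALSE]
    if (nrow(lab) < min_n) {
      warn_f("trait %s has %d labelled segments (< %d); skipped",
             tr, nrow(lab), min_n)
      next
    }
    missing_sp <- setdiff(lab$segment_id, rownames(spectra))
    stop_if(length(missing_sp) > 0,
            "train_trait_models: no spectrum for segment(s) %s",
            paste(utils::head(missing_sp, 3), collapse = ", "))
    X <- spectra[lab$segment_id, , drop = FALSE]
    m <- fit_gpr(X, lab[[tr]], seed = derive_seed(seed, tr), ...)
    m$trait <- tr
    models[[tr]] <- m
  }
  stop_if(length(models) == 0,
          "train_trait_models: no trait had at least %d labelled segments", min_n)
  models
}

#' Direct dry-matter estimate from reflectance
#'
#' Predictive mean of the dry-matter GP model; physically impossible
#' negative means are floored at zero with a warning.
#'
#' @param model_mdry `gpr_model` trained on trait `M_dry`.
#' @param spectra reflectance matrix (or single spectrum vector).
#' @return Numeric vector of dry-matter estimates in g.
#' @export
estimate_direct <- function(model_mdry, spectra) {
  stopifnot(inherits(model_mdry, "gpr_model"))
  stop_if(!identical(model_mdry$trait, "M_dry"),
          "estimate_direct: model was trained on trait '%s', need 'M_dry'",
          model_mdry$trait)
  clamp_trait(predict_gpr(model_mdry, spectra)$mean, "M_dry")
}

#' Indirect dry-matter estimate via water-content mass balance
#'
#' Predicts water content from reflectance, clamps it to \[0, 100\] %, and
#' converts the measured fresh weight to dry matter:
#' `M_dry = (1 - C_w/100) * FW`.
#'
#' @param model_cw `gpr_model` trained on trait `C_w`.
#' @param spectra reflectance matrix (or single spectrum vector).
#' @param fresh_weight fresh weights in g (recycled scalar or one per row).
#' @return Numeric vector of dry-matter estimates in g.
#' @export
estimate_indirect <- function(model_cw, spectra, fresh_weight) {
  stopifnot(inherits(model_cw, "gpr_model"))
  stop_if(!identical(model_cw$trait, "C_w"),
          "estimate_indirect: model was trained on trait '%s', need 'C_w'",
          model_cw$trait)
  stop_if(any(!is.finite(fresh_weight)) || any(fresh_weight < 0),
          "estimate_indirect: fresh weights must be finite and >= 0")
  cw <- clamp_trait(predict_gpr(model_cw, spectra)$mean, "C_w")
  (1 - cw / 100) * fresh_weight
}

#' Inverse-RMSE ensemble weights
#'
#' Each method's weight is proportional to the *other* method's RMSE, so the
#' method with the lower error receives the larger weight:
#' `w_indirect = RMSE_dir / (RMSE_dir + RMSE_in)` and
#' `w_direct = RMSE_in / (RMSE_dir + RMSE_in)`.
#' With two zero RMSEs the weights default to 0.5/0.5.
#'
#' @param rmse_dir RMSE of the direct method, g.
#' @param rmse_in RMSE of the indirect method, g.
#' @return List with `rmse_dir`, `rmse_in`, `w_on_indirect`, `w_on_direct`.
#' @export
#' @examples
#' ensemble_weights(0.330, 0.270)  # w_on_indirect = 0.55
ensemble_weights <- function(rmse_dir, rmse_in) {
  stop_if(!is_scalar_num(rmse_dir) || rmse_dir < 0,
          "ensemble_weights: rmse_dir must be a nonnegative scalar")
  stop_if(!is_scalar_num(rmse_in) || rmse_in < 0,
          "ensemble_weights: rmse_in must be a nonnegative scalar")
  s <- rmse_dir + rmse_in
  if (s == 0) {
    w_in <- 0.5; w_dir <- 0.5
  } else {
    w_in <- rmse_dir / s
    w_dir <- rmse_in / s
  }
  structure(list(rmse_dir = rmse_dir, rmse_in = rmse_in,
                 w_on_indirect = w_in, w_on_direct = w_dir),
            class = "ensemble_weights")
}

#' Ensemble dry-matter estimate
#'
#' Convex combination of the direct and indirect estimates under
#' [ensemble_weights()].
#'
#' @param m_dir direct estimate(s), g.
#' @param m_in indirect estimate(s), g.
#' @param weights an `ensemble_weights` object.
#' @return Numeric vector of ensemble estimates in g.
#' @export
estimate_ensemble <- function(m_dir, m_in, weights) {
  stopifnot(inherits(weights, "ensemble_weights"))
  weights$w_on_indirect * m_in + weights$w_on_direct * m_dir
}

#' Treatment-grouped k-fold RMSE inside a training set
#'
#' Estimates the RMSE of the direct or indirect dry-matter method by k-fold
#' cross-validation *within the training partition*, with whole treatments
#' assigned to folds so that no treatment straddles a fold boundary.  This is
#' the RMSE fed to [ensemble_weights()]; held-out validation data are never
#' touched.
#'
#' By default fold models reuse the hyperparameters of `models` (or of a
#' single fit on the full training set) and refit only the kernel weights,
#' which keeps the inner loop cheap; set `refit_hyperparams = TRUE` to
#' re-optimise per fold.
#'
#' @param segments training segments: columns `segment_id`, `treatment_id`,
#'   `fresh_weight`, `M_dry` and (for the indirect method) `C_w`.
#' @param spectra reflectance matrix.
#' @param method `"direct"` or `"indirect"`.
#' @param k_folds number of folds; clamped to the number of treatments with
#'   a warning when larger.
#' @param seed seed controlling the treatment-to-fold assignment.
#' @param models optional named list with elements `M_dry` / `C_w` whose
#'   hyperparameters seed the fold refits.
#' @param refit_hyperparams re-optimise hyperparameters in every fold.
#' @param predictor optional override of the estimation backend, a
#'   `function(method, train_segments, train_spectra)` returning a
#'   `function(test_segments, test_spectra)` that yields dry-matter
#'   predictions; used for protocol diagnostics.
#' @param ... passed to [fit_gpr()] when hyperparameters are refitted.
#' @return RMSE in g.
#' @export
inner_cv_rmse <- function(segments, spectra, method = c("direct", "indirect"),
                          k_folds = 5, seed = 1L, models = NULL,
                          refit_hyperparams = FALSE, predictor = NULL, ...) {
  method <- match.arg(method)
  need <- c("segment_id", "treatment_id", "fresh_weight", "M_dry",
            if (method == "indirect") "C_w")
  miss <- setdiff(need, names(segments))
  stop_if(length(miss) > 0, "inner_cv_rmse: segments lack column(s) %s",
          paste(miss, collapse = ", "))
  trs <- unique(segments$treatment_id)
  stop_if(length(trs) < 2,
          "inner_cv_rmse: need >= 2 treatment groups, got %d", length(trs))
  if (k_folds > length(trs)) {
    warn_f("inner_cv_rmse: k reduced from %d to %d treatments",
           k_folds, length(trs))
    k_folds <- length(trs)
  }
  fold_of <- with_seed(derive_seed(seed, "inner_cv"), {
    stats::setNames(rep_len(1:k_folds, length(trs))[sample(length(trs))], trs)
  })

  trait <- if (method == "direct") "M_dry" else "C_w"
  lab <- segments[!is.na(segments[[trait]]) & !is.na(segments$M_dry), ,
                  drop = FALSE]
  base_params <- NULL
  if (!refit_hyperparams && is.null(predictor)) {
    base_params <- if (!is.null(models[[trait]])) models[[trait]]$params else
      fit_gpr(spectra[lab$segment_id, , drop = FALSE], lab[[trait]],
              seed = derive_seed(seed, paste0("inner_base_", trait)), ...)$params
  }

  preds <- truths <- numeric(0)
  for (f in sort(unique(fold_of))) {
    test <- lab[fold_of[lab$treatment_id] == f, , drop = FALSE]
    train <- lab[fold_of[lab$treatment_id] != f, , drop = FALSE]
    if (nrow(test) == 0 || nrow(train) < 3) next
    Xtr <- spectra[train$segment_id, , drop = FALSE]
    Xte <- spectra[test$segment_id, , drop = FALSE]
    if (!is.null(predictor)) {
      p <- predictor(method, train, Xtr)(test, Xte)
    } else {
      m <- if (refit_hyperparams)
        fit_gpr(Xtr, train[[trait]],
                seed = derive_seed(seed, paste0("inner_fold_", f)), ...)
      else gpr_fit_fixed(Xtr, train[[trait]], base_params)
      m$trait <- trait
      p <- if (method == "direct") suppressWarnings(estimate_direct(m, Xte))
      else suppressWarnings(estimate_indirect(m, Xte, test$fresh_weight))
    }
    preds <- c(preds, p)
    truths <- c(truths, test$M_dry)
  }
  rmse(truths, preds)
}

#' Apply trained models to a set of segments
#'
#' Produces estimated trait columns (`est_M_dry`, `est_C_w`, `est_C_N`,
#' `est_C_ch`) for every segment with a spectrum.  The dry-matter column uses
#' the requested method; for `"ensemble"` the weights must be supplied (or
#' are computed by [inner_cv_rmse()] on the segments themselves when they
#' carry measurements).
#'
#' @param segments segment table with `segment_id` and `fresh_weight`.
#' @param spectra reflectance matrix.
#' @param models named list from [train_trait_models()].
#' @param mdry_method `"direct"`, `"indirect"` or `"ensemble"`.
#' @param weights `ensemble_weights`, required for the ensemble method
#'   unless the segments carry measured `M_dry`/`C_w` and `treatment_id`.
#' @param seed seed for the fallback inner CV.
#' @return `segments` with estimated-trait columns appended.
#' @export
estimate_traits <- function(segments, spectra, models,
                            mdry_method = c("ensemble", "direct", "indirect"),
                            weights = NULL, seed = 1L) {
  mdry_method <- match.arg(mdry_method)
  X <- spectra[segments$segment_id, , drop = FALSE]
  out <- segments
  if (!is.null(models$C_w))
    out$est_C_w <- clamp_trait(predict_gpr(models$C_w, X)$mean, "C_w",
                               warn = FALSE)
  if (!is.null(models$C_N))
    out$est_C_N <- clamp_trait(predict_gpr(models$C_N, X)$mean, "C_N",
                               warn = FALSE)
  if (!is.null(models$C_ch))
    out$est_C_ch <- clamp_trait(predict_gpr(models$C_ch, X)$mean, "C_ch",
                                warn = FALSE)
  if (mdry_method %in% c("direct", "ensemble")) {
    stop_if(is.null(models$M_dry), "estimate_traits: no M_dry model")
    m_dir <- suppressWarnings(estimate_direct(models$M_dry, X))
  }
  if (mdry_method %in% c("indirect", "ensemble")) {
    stop_if(is.null(models$C_w), "estimate_traits: no C_w model")
    m_in <- (1 - out$est_C_w / 100) * segments$fresh_weight
  }
  out$est_M_dry <- switch(mdry_method,
    direct = m_dir,
    indirect = m_in,
    ensemble = {
      if (is.null(weights)) {
        weights <- ensemble_weights(
          inner_cv_rmse(segments, spectra, "direct", seed = seed,
                        models = models),
          inner_cv_rmse(segments, spectra, "indirect", seed = seed,
                        models = models))
      }
      estimate_ensemble(m_dir, m_in, weights)
    })
  attr(out, "ensemble_weights") <- weights
  out
}

#' Save / load a trained model bundle
#'
#' A bundle is a directory holding one serialized GP model per trait plus a
#' JSON manifest recording the training-set fingerprint, the seed, the
#' wavelength grid and the two ensemble-weighting RMSEs.
#'
#' @param models named list of `gpr_model`s.
#' @param dir bundle directory (created if absent).
#' @param rmses optional named numeric `c(direct = , indirect = )`, g.
#' @param seed training seed recorded for provenance.
#' @param wavelengths wavelength grid the models expect.
#' @param train_hash fingerprint of the training table (any string).
#' @return `save_model_bundle` returns `dir` invisibly; `load_model_bundle`
#'   returns `list(models, manifest)`.
#' @export
save_model_bundle <- function(models, dir, rmses = NULL, seed = NA,
                              wavelengths = NULL, train_hash = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tr in names(models)) {
    save_gpr(models[[tr]], file.path(dir, paste0("model_", tr, ".json")))
  }
  manifest <- list(format = "spectraits-bundle-1",
                   traits = names(models),
                   seed = seed,
                   train_hash = train_hash,
                   wavelengths = wavelengths,
                   rmse_direct = rmses[["direct"]] %||% NA,
                   rmse_indirect = rmses[["indirect"]] %||% NA)
  jsonlite::write_json(manifest, file.path(dir, "bundle.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(dir) {
  mpath <- file.path(dir, "bundle.json")
  stop_if(!file.exists(mpath), "load_model_bundle: no bundle.json in %s", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  models <- list()
  for (tr in manifest$traits) {
    models[[tr]] <- load_gpr(file.path(dir, paste0("model_", tr, ".json")))
  }
  list(models = models, manifest = manifest)
}
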
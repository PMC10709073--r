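# Leave-one-treatment-out validation, vertical-profile interpolation,
# trait correlations and factor ANOVA.

#' Coefficient of determination and root-mean-square error
#'
#' `r_squared` is 1 - SSres/SStot (not the squared Pearson correlation), so
#' a biased predictor is penalised even when it correlates well with truth.
#'
#' @param truth,prediction numeric vectors of equal nonzero length.
#' @return Scalar metric; `rmse` is in the units of the inputs.
#' @export
r_squared <- function(truth, prediction) {
  stop_if(length(truth) == 0 || length(truth) != length(prediction),
          "r_squared: lengths %d and %d", length(truth), length(prediction))
  sst <- sum((truth - mean(truth))^2)
  stop_if(sst == 0, "r_squared: truth has zero variance")
  1 - sum((truth - prediction)^2) / sst
}

#' @rdname r_squared
#' @export
rmse <- function(truth, prediction) {
  stop_if(length(truth) == 0 || length(truth) != length(prediction),
          "rmse: lengths %d and %d", length(truth), length(prediction))
  sqrt(mean((truth - prediction)^2))
}

#' Leave-one-treatment-out folds
#'
#' One fold per treatment: the fold's model trains on every other treatment
#' and is scored on all segments of the held-out one.
#'
#' @param treatment_ids vector of treatment ids (duplicates allowed; the
#'   unique set defines the folds).
#' @return List of `list(train = ids, test = id)`, one per treatment.
#' @export
loto_folds <- function(treatment_ids) {
  trs <- unique(treatment_ids)
  stop_if(length(trs) < 2, "loto_folds: need >= 2 treatments, got %d",
          length(trs))
  lapply(trs, function(t) list(train = setdiff(trs, t), test = t))
}

#' Leave-one-treatment-out validation of a trait model
#'
#' For every treatment, fits the trait's GP model on the remaining
#' treatments' labelled segments and predicts the held-out segments; pooled
#' R-squared and RMSE are computed once over the concatenated held-out
#' predictions.  For dry matter the `method` selects the direct, indirect or
#' ensemble estimator; the ensemble's weighting RMSEs come from
#' treatment-grouped inner CV within each fold's training share, never from
#' held-out data.  Dry-matter and ensemble runs also report plant-scale
#' aggregates (CM_dry, and CC_w for the ensemble).
#'
#' Fold fits are warm-started from a fit on the full training table (pass
#' `warm_models` to reuse models you already have), which the optimiser then
#' refines per fold.
#'
#' @param dataset a dataset list as returned by [build_dataset()] (elements
#'   `segments`, `spectra`, `plants`).
#' @param trait one of `"M_dry"`, `"C_w"`, `"C_N"`, `"C_ch"`.
#' @param method dry-matter estimator (ignored for the other traits).
#' @param seed root seed for fold fits and inner CV.
#' @param n_restarts,maxit optimiser effort per fold fit.
#' @param warm_models optional named list of full-data `gpr_model`s whose
#'   hyperparameters warm-start the fold fits.
#' @param inner_k folds of the inner weighting CV (ensemble only).
#' @return A `validation_report`: per-fold predictions, pooled `r2`/`rmse`,
#'   and plant-scale tables where applicable.
#' @export
run_validation <- function(dataset, trait, method = c("direct", "indirect",
                                                      "ensemble"),
                           seed = 1L, n_restarts = 1, maxit = 60,
                           warm_models = NULL, inner_k = 5) {
  trait <- check_trait(trait)
  method <- match.arg(method)
  if (trait != "M_dry") method <- "direct"
  seg <- dataset$segments
  spectra <- dataset$spectra
  stop_if(is.null(seg) || is.null(spectra), "run_validation: malformed dataset")
  need_traits <- if (method == "direct" && trait != "M_dry") trait
    else switch(method, direct = "M_dry", indirect = "C_w",
                ensemble = c("M_dry", "C_w"))
  folds <- loto_folds(seg$treatment_id)
  for (f in folds) {
    for (tr in need_traits) {
      n_lab <- sum(!is.na(seg[[tr]][seg$treatment_id %in% f$train]))
      stop_if(n_lab < 3,
              "run_validation: trait %s has only %d labelled segments when holding out %s",
              tr, n_lab, f$test)
    }
  }

  warm <- list()
  for (tr in need_traits) {
    warm[[tr]] <- if (!is.null(warm_models[[tr]])) warm_models[[tr]] else {
      lab <- seg[!is.na(seg[[tr]]), ]
      m <- fit_gpr(spectra[lab$segment_id, , drop = FALSE], lab[[tr]],
                   n_restarts = max(n_restarts, 3), maxit = maxit,
                   seed = derive_seed(seed, paste0("warm_", tr)))
      m$trait <- tr
      m
    }
  }

  fold_rows <- list()
  for (f in folds) {
    train <- seg[seg$treatment_id %in% f$train, , drop = FALSE]
    test <- seg[seg$treatment_id == f$test, , drop = FALSE]
    fm <- list()
    for (tr in need_traits) {
      lab <- train[!is.na(train[[tr]]), , drop = FALSE]
      m <- fit_gpr(spectra[lab$segment_id, , drop = FALSE], lab[[tr]],
                   n_restarts = n_restarts, maxit = maxit,
                   init = warm[[tr]]$params,
                   seed = derive_seed(seed, paste0("fold_", f$test, "_", tr)))
      m$trait <- tr
      fm[[tr]] <- m
    }
    Xte <- spectra[test$segment_id, , drop = FALSE]
    row <- data.frame(segment_id = test$segment_id,
                      plant_id = test$plant_id,
                      treatment_id = f$test,
                      truth = test[[trait]],
                      fresh_weight = test$fresh_weight,
                      stringsAsFactors = FALSE)
    if (trait != "M_dry") {
      row$pred <- suppressWarnings(
        clamp_trait(predict_gpr(fm[[trait]], Xte)$mean, trait))
    } else {
      if (!is.null(fm$M_dry))
        row$m_dir <- suppressWarnings(estimate_direct(fm$M_dry, Xte))
      if (!is.null(fm$C_w)) {
        row$cw_pred <- suppressWarnings(
          clamp_trait(predict_gpr(fm$C_w, Xte)$mean, "C_w"))
        row$m_in <- (1 - row$cw_pred / 100) * test$fresh_weight
        row$cw_truth <- test$C_w
      }
      if (method == "ensemble") {
        w <- ensemble_weights(
          suppressWarnings(inner_cv_rmse(train, spectra, "direct",
                                         k_folds = inner_k, seed = seed,
                                         models = fm)),
          suppressWarnings(inner_cv_rmse(train, spectra, "indirect",
                                         k_folds = inner_k, seed = seed,
                                         models = fm)))
        row$m_en <- estimate_ensemble(row$m_dir, row$m_in, w)
        row$w_on_indirect <- w$w_on_indirect
      }
      row$pred <- switch(method, direct = row$m_dir, indirect = row$m_in,
                         ensemble = row$m_en)
    }
    fold_rows[[f$test]] <- row
  }
  all_rows <- data.table::setDF(data.table::rbindlist(fold_rows))
  scored <- all_rows[!is.na(all_rows$truth), , drop = FALSE]

  report <- list(trait = trait, method = method,
                 folds = fold_rows,
                 predictions = all_rows,
                 n = nrow(scored),
                 r2 = r_squared(scored$truth, scored$pred),
                 rmse = rmse(scored$truth, scored$pred),
                 units = trait_units[[trait]])

  # plant-scale aggregates from the held-out predictions
  if (trait == "M_dry" && !anyNA(seg$M_dry)) {
    ag <- function(v, by) tapply(v, by, sum)
    cm_true <- ag(all_rows$truth, all_rows$plant_id)
    cm_pred <- ag(all_rows$pred, all_rows$plant_id)
    report$plant_cm_dry <- data.frame(plant_id = names(cm_true),
                                      truth = as.numeric(cm_true),
                                      pred = as.numeric(cm_pred))
    report$plant_cm_dry_r2 <- r_squared(report$plant_cm_dry$truth,
                                        report$plant_cm_dry$pred)
    report$plant_cm_dry_rmse <- rmse(report$plant_cm_dry$truth,
                                     report$plant_cm_dry$pred)
    if (method == "ensemble") {
      sp <- split(all_rows, all_rows$plant_id)
      ccw <- vapply(sp, function(d) {
        cw <- pmin(d$cw_pred, 99.9)
        fw_est <- d$pred / (1 - cw / 100)
        aggregate_cc_w(cw, fw_est)
      }, numeric(1))
      ccw_true <- vapply(sp, function(d)
        aggregate_cc_w(d$cw_truth, d$fresh_weight), numeric(1))
      report$plant_cc_w <- data.frame(plant_id = names(ccw),
                                      truth = as.numeric(ccw_true),
                                      pred = as.numeric(ccw))
      report$plant_cc_w_r2 <- r_squared(report$plant_cc_w$truth,
                                        report$plant_cc_w$pred)
      report$plant_cc_w_rmse <- rmse(report$plant_cc_w$truth,
                                     report$plant_cc_w$pred)
    }
  }
  structure(report, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s (%s), %d folds, n = %d\n  R2 = %.3f, RMSE = %.3f %s\n",
              x$trait, x$method, length(x$folds), x$n, x$r2, x$rmse, x$units))
  if (!is.null(x$plant_cm_dry_r2))
    cat(sprintf("  plant CM_dry: R2 = %.3f, RMSE = %.3f g\n",
                x$plant_cm_dry_r2, x$plant_cm_dry_rmse))
  if (!is.null(x$plant_cc_w_r2))
    cat(sprintf("  plant CC_w:  R2 = %.3f, RMSE = %.3f %%\n",
                x$plant_cc_w_r2, x$plant_cc_w_rmse))
  invisible(x)
}

#' Relative-height profile of a plant
#'
#' Converts stacked segment positions to relative height (0 = plant base,
#' 1 = top) using segment midpoints, and returns the trait columns at those
#' heights for interpolation.
#'
#' @param segments one plant's segments, ordered or orderable by
#'   `position_index`, with `segment_length` (cm) and trait columns.
#' @param traits trait columns to carry along (defaults to any of the
#'   measured/estimated trait columns present).
#' @return data.frame with `rel_height` plus the trait columns, base first.
#'   A single-segment plant is returned with attribute `degenerate = TRUE`
#'   and a warning, and is not suitable for interpolation.
#' @export
relative_height_profile <- function(segments, traits = NULL) {
  stop_if(!all(c("position_index", "segment_length") %in% names(segments)),
          "relative_height_profile: need position_index and segment_length")
  seg <- segments[order(segments$position_index), , drop = FALSE]
  if (is.null(traits)) {
    traits <- intersect(c(TRAITS, paste0("est_", TRAITS),
                          paste0("true_", TRAITS)), names(seg))
  }
  len <- seg$segment_length
  stop_if(any(len <= 0), "relative_height_profile: nonpositive segment length")
  total <- sum(len)
  mid <- (cumsum(len) - len / 2) / total
  out <- data.frame(rel_height = mid, seg[, traits, drop = FALSE],
                    row.names = NULL)
  if (nrow(seg) < 2) {
    warn_f("relative_height_profile: single-segment plant, degenerate profile")
    attr(out, "degenerate") <- TRUE
  }
  out
}

#' Interpolate a profile onto the standard 10-point relative-height grid
#'
#' Linear interpolation at `n_points` uniformly spaced heights in (0, 1]
#' (0.1, 0.2, ..., 1 by default); outside the span of the segment midpoints
#' the nearest end value is held constant.
#'
#' @param heights relative heights of the profile points (>= 2).
#' @param values trait values at those heights.
#' @param n_points number of grid points.
#' @return data.frame with `rel_height` and `value`.
#' @export
interpolate_profile <- function(heights, values, n_points = 10) {
  stop_if(length(heights) < 2, "interpolate_profile: need >= 2 profile points")
  stop_if(length(heights) != length(values),
          "interpolate_profile: %d heights for %d values",
          length(heights), length(values))
  grid <- seq_len(n_points) / n_points
  o <- order(heights)
  v <- stats::approx(heights[o], values[o], xout = grid, method = "linear",
                     rule = 2, ties = "ordered")$y
  data.frame(rel_height = grid, value = v)
}

#' Per-treatment mean and sd profiles on the standard height grid
#'
#' Interpolates every plant's profile onto the `n_points` grid and summarises
#' mean and standard deviation per treatment, trait and height.
#'
#' @param segments segment table (`plant_id`, `treatment_id`,
#'   `position_index`, `segment_length`, trait columns).
#' @param traits trait columns to profile.
#' @param n_points height grid size.
#' @return data.frame with `treatment_id`, `trait`, `rel_height`, `mean`,
#'   `sd`, `n_plants`.
#' @export
profile_summary <- function(segments, traits, n_points = 10) {
  miss <- setdiff(traits, names(segments))
  stop_if(length(miss) > 0, "profile_summary: no column(s) %s",
          paste(miss, collapse = ", "))
  per_plant <- list()
  for (pid in unique(segments$plant_id)) {
    seg <- segments[segments$plant_id == pid, , drop = FALSE]
    if (nrow(seg) < 2) next
    prof <- relative_height_profile(seg, traits)
    for (tr in traits) {
      g <- interpolate_profile(prof$rel_height, prof[[tr]], n_points)
      per_plant[[paste(pid, tr)]] <- data.frame(
        treatment_id = seg$treatment_id[1], plant_id = pid, trait = tr,
        rel_height = g$rel_height, value = g$value, stringsAsFactors = FALSE)
    }
  }
  stop_if(length(per_plant) == 0, "profile_summary: no plant with >= 2 segments")
  dt <- data.table::rbindlist(per_plant)
  out <- dt[, list(mean = mean(value), sd = stats::sd(value),
                   n_plants = .N),
            by = c("treatment_id", "trait", "rel_height")]
  data.table::setDF(out)
}

#' Pearson correlation matrix among the four traits
#'
#' Pairwise Pearson correlations over segments with complete values,
#' two-sided significance from the t statistic with n - 2 degrees of
#' freedom, flagged at P < 0.01.  A zero-variance trait yields an `NA`
#' row/column and a warning.
#'
#' @param segments segment table carrying the trait columns.
#' @param traits trait columns to correlate (default the four measured
#'   traits).
#' @return List with matrices `r`, `p`, logical `sig` (P < 0.01), and `n`.
#' @export
correlation_matrix <- function(segments, traits = TRAITS) {
  miss <- setdiff(traits, names(segments))
  stop_if(length(miss) > 0, "correlation_matrix: no column(s) %s",
          paste(miss, collapse = ", "))
  dat <- segments[, traits, drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  stop_if(nrow(dat) < 3,
          "correlation_matrix: need >= 3 complete segments, got %d", nrow(dat))
  k <- length(traits)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    x <- dat[[i]]; y <- dat[[j]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warn_f("correlation_matrix: zero-variance trait %s or %s",
             traits[i], traits[j])
      next
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p, sig = p < 0.01, n = nrow(dat))
}

#' ANOVA of trait-pair correlations across a design factor
#'
#' Within each replicate group (segments sharing cultivar, nitrogen level
#' and stage), the Pearson correlation of every trait pair is computed and
#' Fisher-z transformed; a one-way ANOVA then tests whether the factor's
#' levels differ in mean z.  Groups with fewer than 3 complete segments are
#' dropped with a warning.
#'
#' @param segments segment table with the trait columns plus `cultivar`,
#'   `nitrogen` and `stage` labels.
#' @param factor one of `"cultivar"`, `"nitrogen"`, `"stage"`.
#' @param traits trait columns to correlate.
#' @return data.frame with one row per trait pair: `pair`, `f_value`,
#'   `p_value`, `n_groups`.
#' @export
correlation_anova <- function(segments, factor = c("cultivar", "nitrogen",
                                                   "stage"),
                              traits = TRAITS) {
  factor <- match.arg(factor)
  labels <- c("cultivar", "nitrogen", "stage")
  miss <- setdiff(c(labels, traits), names(segments))
  stop_if(length(miss) > 0, "correlation_anova: no column(s) %s",
          paste(miss, collapse = ", "))
  stop_if(length(unique(segments[[factor]])) < 2,
          "correlation_anova: factor %s has a single level", factor)
  grp <- interaction(segments$cultivar, segments$nitrogen, segments$stage,
                     drop = TRUE)
  rows <- list()
  dropped <- 0L
  for (g in levels(grp)) {
    seg <- segments[grp == g, , drop = FALSE]
    dat <- seg[, traits, drop = FALSE]
    ok <- stats::complete.cases(dat)
    if (sum(ok) < 3) { dropped <- dropped + 1L; next }
    dat <- dat[ok, , drop = FALSE]
    for (i in seq_along(traits)[-length(traits)])
      for (j in (i + 1):length(traits)) {
        if (stats::sd(dat[[i]]) == 0 || stats::sd(dat[[j]]) == 0) next
        r <- stats::cor(dat[[i]], dat[[j]])
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, level = as.character(seg[[factor]][1]),
          pair = paste(traits[i], traits[j], sep = ":"),
          z = atanh(pmin(pmax(r, -0.9999), 0.9999)),
          stringsAsFactors = FALSE)
      }
  }
  if (dropped > 0)
    warn_f("correlation_anova: dropped %d group(s) with < 3 complete segments",
           dropped)
  stop_if(length(rows) == 0, "correlation_anova: no usable replicate groups")
  z <- data.table::setDF(data.table::rbindlist(rows))
  out <- lapply(unique(z$pair), function(pp) {
    d <- z[z$pair == pp, ]
    lv <- table(d$level)
    if (length(lv) < 2 || any(lv < 2)) {
      return(data.frame(pair = pp, f_value = NA_real_, p_value = NA_real_,
                        n_groups = nrow(d)))
    }
    a <- stats::anova(stats::lm(z ~ level, data = d))
    data.frame(pair = pp, f_value = a$`F value`[1], p_value = a$`Pr(>F)`[1],
               n_groups = nrow(d))
  })
  data.table::setDF(data.table::rbindlist(out))
}
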
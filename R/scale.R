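# Residue quality control and segment-to-plant aggregation.

#' Residual rate of chopping losses
#'
#' Percentage of fresh mass lost between the pre-chop weighing of the whole
#' plant (TFW) and the sum of per-segment balance readings (CFW):
#' `RR = (1 - CFW/TFW) * 100`.  A CFW more than 5 % above TFW exceeds what
#' balance noise can explain and is rejected.
#'
#' @param tfw total fresh weight(s) before chopping, g; must be > 0.
#' @param cfw cumulative segment fresh weight(s), g.
#' @return Residual rate(s) in percent.
#' @export
#' @examples
#' residual_rate(100, 96)  # 4
residual_rate <- function(tfw, cfw) {
  stop_if(any(!is.finite(tfw)) || any(tfw <= 0),
          "residual_rate: TFW must be finite and > 0")
  stop_if(any(!is.finite(cfw)) || any(cfw < 0),
          "residual_rate: CFW must be finite and >= 0")
  bad <- which(cfw > tfw * 1.05)
  stop_if(length(bad) > 0,
          "residual_rate: CFW %.4g g exceeds TFW %.4g g by more than 5%% (plant rejected)",
          cfw[bad[1]], tfw[bad[1]])
  (1 - cfw / tfw) * 100
}

#' Plant-scale dry matter: sum of segment estimates
#'
#' @param m_dry segment dry-matter values in g; `NA` marks a missing
#'   estimate and is an error.
#' @param segment_id optional ids used in the error message.
#' @return Total dry matter, g.
#' @export
aggregate_cm_dry <- function(m_dry, segment_id = seq_along(m_dry)) {
  bad <- which(is.na(m_dry))
  stop_if(length(bad) > 0,
          "aggregate_cm_dry: missing M_dry estimate for segment(s) %s",
          paste(segment_id[bad], collapse = ", "))
  sum(m_dry)
}

#' Plant-scale water content: fresh-mass-weighted mean
#'
#' Total segment water weight over total segment fresh weight:
#' `CC_w = sum(C_w_i/100 * FW_i) / sum(FW_i) * 100`.
#'
#' @param c_w segment water contents, %.
#' @param fresh_weight segment fresh weights, g; total must be > 0.
#' @return Plant water content, %.
#' @export
aggregate_cc_w <- function(c_w, fresh_weight) {
  stop_if(length(c_w) != length(fresh_weight),
          "aggregate_cc_w: %d water contents for %d fresh weights",
          length(c_w), length(fresh_weight))
  stop_if(any(is.na(c_w)) || any(is.na(fresh_weight)),
          "aggregate_cc_w: missing values")
  tot <- sum(fresh_weight)
  stop_if(tot <= 0, "aggregate_cc_w: total fresh weight is not positive")
  sum(c_w / 100 * fresh_weight) / tot * 100
}

#' Plant-scale concentration: dry-mass-weighted mean
#'
#' Nitrogen (g/kg) and chlorophyll (mg/g) are expressed per unit dry mass,
#' so the plant-scale value weights each segment by its dry matter:
#' `sum(c_i * M_dry_i) / sum(M_dry_i)`.  Fresh-mass weighting is available
#' as a sensitivity switch.
#'
#' @param values segment concentrations (C_N in g/kg or C_ch in mg/g).
#' @param m_dry segment dry-matter weights, g (or fresh weights when
#'   `weighting = "fresh"`).
#' @param weighting `"dry"` (default) or `"fresh"`.
#' @return Plant-scale concentration in the trait's units.
#' @export
aggregate_concentration <- function(values, m_dry,
                                    weighting = c("dry", "fresh")) {
  weighting <- match.arg(weighting)
  stop_if(length(values) != length(m_dry),
          "aggregate_concentration: %d values for %d weights",
          length(values), length(m_dry))
  stop_if(any(is.na(values)) || any(is.na(m_dry)),
          "aggregate_concentration: missing values")
  tot <- sum(m_dry)
  stop_if(tot <= 0, "aggregate_concentration: total %s mass is not positive",
          weighting)
  sum(values * m_dry) / tot
}

#' Per-plant results table
#'
#' Builds one row per plant from estimated (and, where present, measured)
#' segment traits: ids, TFW, CFW, residual rate, CM_dry, CC_w, CC_N, CC_ch.
#' Estimated CC_w follows the deduced-weight convention: segment fresh
#' weight is reconstructed from the estimated dry matter and water content
#' (`FW = M_dry / (1 - C_w/100)`), so the plant aggregate depends only on
#' the estimates.
#'
#' @param segments segment table with `plant_id`, `fresh_weight`, estimated
#'   columns `est_M_dry`, `est_C_w` (optionally `est_C_N`, `est_C_ch`) and
#'   optional measured columns `M_dry`, `C_w`, `C_N`, `C_ch`.
#' @param plants plant table with `plant_id`, `treatment_id`,
#'   `total_fresh_weight` and optionally `cum_fresh_weight`.
#' @param weighting concentration weighting, see [aggregate_concentration()].
#' @return data.frame, one row per plant.
#' @export
plant_table <- function(segments, plants, weighting = "dry") {
  out <- lapply(seq_len(nrow(plants)), function(i) {
    pl <- plants[i, ]
    seg <- segments[segments$plant_id == pl$plant_id, , drop = FALSE]
    stop_if(nrow(seg) == 0, "plant_table: plant %s has no segments", pl$plant_id)
    cfw <- pl$cum_fresh_weight %||% sum(seg$fresh_weight)
    if (is.na(cfw)) cfw <- sum(seg$fresh_weight)
    row <- data.frame(
      plant_id = pl$plant_id,
      treatment_id = pl$treatment_id,
      tfw = pl$total_fresh_weight,
      cfw = cfw,
      rr = residual_rate(pl$total_fresh_weight, cfw),
      stringsAsFactors = FALSE)
    if (!is.null(seg$est_M_dry))
      row$est_cm_dry <- aggregate_cm_dry(seg$est_M_dry, seg$segment_id)
    if (!is.null(seg$est_C_w) && !is.null(seg$est_M_dry)) {
      cw <- pmin(seg$est_C_w, 99.9)
      fw_est <- seg$est_M_dry / (1 - cw / 100)
      row$est_cc_w <- aggregate_cc_w(cw, fw_est)
    }
    if (!is.null(seg$est_C_N) && !is.null(seg$est_M_dry))
      row$est_cc_n <- aggregate_concentration(seg$est_C_N, seg$est_M_dry,
                                              weighting)
    if (!is.null(seg$est_C_ch) && !is.null(seg$est_M_dry))
      row$est_cc_ch <- aggregate_concentration(seg$est_C_ch, seg$est_M_dry,
                                               weighting)
    if (!is.null(seg$M_dry) && !anyNA(seg$M_dry)) {
      row$meas_cm_dry <- aggregate_cm_dry(seg$M_dry)
      if (!is.null(seg$C_w) && !anyNA(seg$C_w))
        row$meas_cc_w <- aggregate_cc_w(seg$C_w, seg$fresh_weight)
      if (!is.null(seg$C_N) && !anyNA(seg$C_N))
        row$meas_cc_n <- aggregate_concentration(seg$C_N, seg$M_dry, weighting)
      if (!is.null(seg$C_ch) && !anyNA(seg$C_ch))
        row$meas_cc_ch <- aggregate_concentration(seg$C_ch, seg$M_dry, weighting)
    }
    row
  })
  data.table::setDF(data.table::rbindlist(out, fill = TRUE))
}
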
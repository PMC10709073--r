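# Virtual instrument: experimental designs, plants with vertical trait
# gradients, a simple exponential-absorption forward model from traits to
# reflectance, balance readings with chopping-residue loss, and full dataset
# assembly.  All randomness flows from one root seed through named
# substreams (design, plants, spectra, residue, labelling), so any part of a
# dataset can be regenerated bit-exactly.
#
# The forward model is a deliberately simple test harness, not a
# radiative-transfer code: absorption features sit at the wavelengths of the
# known absorbers (chlorophyll ~430/662 nm; water ~970/1200/1450/1940 nm;
# dry matter ~1720/2100/2300 nm; protein-bound nitrogen ~2180/2350 nm) and
# reflectance decreases monotonically in each trait at its feature centers,
# which is what makes trait recovery well-posed.

#' Default experimental design
#'
#' Mirrors a two-part rice trial: a factorial block of 3 cultivars x 3
#' nitrogen levels (270, 135, 0 kg/hm2) plus a panel of 25 cultivars all at
#' 270 kg/hm2, i.e. 34 treatments in total.  When several growth stages are
#' requested the design is crossed with a stage label.
#'
#' @param stages growth-stage labels; subset of
#'   `c("heading", "flowering", "grain-filling")`.
#' @param factorial include the 3 x 3 factorial block.
#' @param panel include the 25-cultivar panel block.
#' @return data.frame with `treatment_id`, `cultivar`, `nitrogen` (kg/hm2),
#'   `stage`, `block`.
#' @export
#' @examples
#' nrow(design_experiments())  # 34
design_experiments <- function(stages = "heading", factorial = TRUE,
                               panel = TRUE) {
  ok_stages <- c("heading", "flowering", "grain-filling")
  stop_if(!all(stages %in% ok_stages), "design_experiments: stages must be in %s",
          paste(ok_stages, collapse = ", "))
  rows <- list()
  if (factorial) {
    fac <- expand.grid(cultivar = paste0("cv", 1:3),
                       nitrogen = c(270, 135, 0),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    fac$block <- "factorial"
    rows <- c(rows, list(fac))
  }
  if (panel) {
    pan <- data.frame(cultivar = sprintf("pcv%02d", 1:25), nitrogen = 270,
                      block = "panel", stringsAsFactors = FALSE)
    rows <- c(rows, list(pan))
  }
  stop_if(length(rows) == 0, "design_experiments: empty design")
  base <- data.table::setDF(data.table::rbindlist(rows, fill = TRUE))
  out <- do.call(rbind, lapply(stages, function(s) {
    d <- base
    d$stage <- s
    d
  }))
  out$treatment_id <- sprintf("T%02d_%s_N%03d_%s",
                              seq_len(nrow(out)), out$cultivar,
                              out$nitrogen, out$stage)
  out[, c("treatment_id", "cultivar", "nitrogen", "stage", "block")]
}

#' Default vertical trait-gradient configuration
#'
#' Linear base-to-top gradients per trait: dry matter and water content
#' increase toward the plant base while nitrogen and chlorophyll increase
#' toward the top.  `n_slope` is the relative response per unit of
#' `(N - 135)/135`; `stage_mult` rescales each stage.  Noise terms are a
#' per-plant offset (`plant_sd`) and per-segment scatter (`segment_sd`) in
#' trait units, sized like assay repeatability at desk scale.
#'
#' @return Nested list, one entry per trait.
#' @export
default_gradients <- function() {
  list(
    M_dry = list(top = 0.8, base = 2.6, plant_sd = 0.12, segment_sd = 0.04,
                 n_slope = 0.25,
                 stage_mult = c(heading = 1, flowering = 1.1,
                                `grain-filling` = 1.2)),
    C_w = list(top = 68, base = 84, plant_sd = 1.2, segment_sd = 0.4,
               n_slope = -0.03,
               stage_mult = c(heading = 1, flowering = 0.97,
                              `grain-filling` = 0.94)),
    C_N = list(top = 32, base = 14, plant_sd = 1.2, segment_sd = 0.5,
               n_slope = 0.30,
               stage_mult = c(heading = 1, flowering = 0.9,
                              `grain-filling` = 0.75)),
    C_ch = list(top = 3.2, base = 1.2, plant_sd = 0.15, segment_sd = 0.06,
                n_slope = 0.30,
                stage_mult = c(heading = 1, flowering = 0.9,
                               `grain-filling` = 0.75)),
    height = list(mean = 50, cultivar_sd = 4, plant_sd = 2.5,
                  n_slope = 0.08)
  )
}

#' Default forward-model configuration
#'
#' Smooth bright baseline over the canonical grid with Gaussian absorption
#' features per trait (center nm, width nm, strength per trait unit),
#' multiplicative scatter and additive band noise.  Default strengths put
#' trait effects roughly an order of magnitude above the band noise at the
#' feature centers.
#'
#' @param scatter_sd s.d. of the per-spectrum multiplicative scatter.
#' @param noise_sd s.d. of the additive per-band noise.
#' @return List with `baseline_knots`, `features`, `scatter_sd`, `noise_sd`.
#' @export
default_forward_config <- function(scatter_sd = 0.01, noise_sd = 0.002) {
  list(
    baseline_knots = data.frame(
      wavelength = c(350, 400, 500, 600, 700, 750, 1000, 1300, 1400, 1900,
                     2000, 2200, 2500),
      reflectance = c(0.35, 0.38, 0.42, 0.45, 0.47, 0.50, 0.52, 0.50, 0.48,
                      0.45, 0.44, 0.42, 0.38)),
    features = list(
      M_dry = data.frame(center = c(1720, 2100, 2300),
                         width = c(40, 60, 50),
                         strength = c(0.06, 0.05, 0.06)),
      C_w = data.frame(center = c(970, 1200, 1450, 1940),
                       width = c(50, 60, 70, 80),
                       strength = c(0.002, 0.003, 0.008, 0.010)),
      C_N = data.frame(center = c(2180, 2350),
                       width = c(30, 35),
                       strength = c(0.004, 0.004)),
      C_ch = data.frame(center = c(430, 662),
                        width = c(25, 30),
                        strength = c(0.15, 0.20))),
    scatter_sd = scatter_sd,
    noise_sd = noise_sd
  )
}

forward_baseline <- function(config, wavelengths) {
  stats::spline(config$baseline_knots$wavelength,
                config$baseline_knots$reflectance,
                xout = wavelengths, method = "natural")$y
}

#' Forward-model a reflectance spectrum from trait values
#'
#' `R(l) = baseline(l) * exp(-sum_t strength * value_t * g(l; center, width))
#'  * (1 + scatter) + noise`, clipped to \[0, 1.5\].  With all trait values
#' and noise at zero the baseline is returned exactly.
#'
#' @param traits named numeric vector with `M_dry`, `C_w`, `C_N`, `C_ch`
#'   (missing traits contribute nothing); values must be nonnegative and
#'   `C_w <= 100`.
#' @param config forward-model configuration, see [default_forward_config()].
#' @param seed seed for scatter and noise draws.
#' @param wavelengths wavelength grid, default the canonical 2,151-band grid.
#' @return A `reflectance_spectrum`.
#' @export
traits_to_reflectance <- function(traits, config = default_forward_config(),
                                  seed = 1L, wavelengths = canonical_grid()) {
  stop_if(any(traits < 0, na.rm = TRUE),
          "traits_to_reflectance: trait values must be nonnegative")
  stop_if(!is.na(traits["C_w"]) && !is.null(traits["C_w"]) &&
            isTRUE(traits[["C_w"]] > 100),
          "traits_to_reflectance: C_w above 100%%")
  base <- forward_baseline(config, wavelengths)
  absorb <- rep(0, length(wavelengths))
  for (tr in names(config$features)) {
    v <- traits[[tr]] %||% NA_real_
    if (is.na(v)) next
    f <- config$features[[tr]]
    for (k in seq_len(nrow(f))) {
      absorb <- absorb + f$strength[k] * v *
        exp(-(wavelengths - f$center[k])^2 / (2 * f$width[k]^2))
    }
  }
  r <- with_seed(seed, {
    scatter <- stats::rnorm(1, 0, config$scatter_sd)
    noise <- stats::rnorm(length(wavelengths), 0, config$noise_sd)
    base * exp(-absorb) * (1 + scatter) + noise
  })
  reflectance_spectrum(wavelengths, pmin(pmax(r, 0), 1.5))
}

#' Simulate chopping-residue loss
#'
#' Draws a residual rate from a right-skewed gamma distribution (shape 2,
#' scale 1.25 %, capped at 50 %) calibrated so that at least 75 % of draws
#' fall below 4 %, and converts the pre-chop weight to the cumulative segment
#' weight `CFW = TFW * (1 - RR/100)`.
#'
#' @param tfw total fresh weight before chopping, g.
#' @param residue_model `"gamma"` (default) or `"none"` (no loss, RR = 0).
#' @param seed seed for the draw.
#' @param shape,scale gamma parameters of the RR distribution (percent).
#' @return List with `cfw` (g) and `rr` (%).
#' @export
simulate_residue <- function(tfw, residue_model = c("gamma", "none"),
                             seed = 1L, shape = 2, scale = 1.25) {
  residue_model <- match.arg(residue_model)
  stop_if(any(tfw <= 0), "simulate_residue: TFW must be > 0")
  n <- length(tfw)
  rr <- if (residue_model == "none") rep(0, n) else
    with_seed(seed, pmin(stats::rgamma(n, shape = shape, scale = scale), 50))
  list(cfw = tfw * (1 - rr / 100), rr = rr)
}

# Linear gradient value at relative height h (0 = base, 1 = top) under a
# treatment's nitrogen level and stage.
gradient_value <- function(gcfg, h, nitrogen, stage) {
  v <- gcfg$base + (gcfg$top - gcfg$base) * h
  v * (1 + gcfg$n_slope * (nitrogen - 135) / 135) *
    unname(gcfg$stage_mult[stage])
}

#' Generate one plant with measured traits
#'
#' Builds a plant of 5-cm segments whose trait values follow the configured
#' linear base-to-top gradients plus seeded per-plant offsets and per-segment
#' scatter.  Segment fresh weight is derived from the mass balance
#' `FW = M_dry / (1 - C_w/100)`, balance readings are quantized to 0.01 g,
#' and the segment's dry matter is the dry fraction of the *weighed* sample,
#' so `M_dry = (1 - C_w/100) * FW` holds exactly for every recorded segment.
#' The pre-chop plant weight includes the mass later lost as chopping
#' residue.
#'
#' @param treatment one row of [design_experiments()].
#' @param gradients gradient configuration, see [default_gradients()].
#' @param segment_length segment length in cm.
#' @param seed seed for this plant's draws.
#' @param plant_id id string.
#' @param residue_model passed to [simulate_residue()].
#' @param quantize quantize balance readings to 0.01 g.
#' @return List with `plant` (one-row data.frame: ids, `total_fresh_weight`,
#'   `cum_fresh_weight`, `residual_rate`, `height`) and `segments`
#'   (data.frame with positions, fresh weights and the four measured traits).
#' @export
generate_plant <- function(treatment, gradients = default_gradients(),
                           segment_length = 5, seed = 1L,
                           plant_id = "P001", residue_model = "gamma",
                           quantize = TRUE) {
  stopifnot(is.data.frame(treatment), nrow(treatment) == 1)
  g <- gradients
  with_seed(seed, {
    hcfg <- g$height
    # cultivar height offset: fixed per cultivar label, spread ~ cultivar_sd
    cv_shift <- (sum(utf8ToInt(treatment$cultivar)) %% 5 - 2) *
      hcfg$cultivar_sd / 2
    height <- hcfg$mean * (1 + hcfg$n_slope * (treatment$nitrogen - 135) / 135) +
      cv_shift + stats::rnorm(1, 0, hcfg$plant_sd)
    height <- max(height, 2 * segment_length)
    n_seg <- max(2L, as.integer(round(height / segment_length)))
    mid <- (seq_len(n_seg) - 0.5) / n_seg

    plant_off <- vapply(TRAITS, function(tr) stats::rnorm(1, 0, g[[tr]]$plant_sd),
                        numeric(1))
    vals <- sapply(TRAITS, function(tr) {
      v <- gradient_value(g[[tr]], mid, treatment$nitrogen, treatment$stage) +
        plant_off[[tr]] + stats::rnorm(n_seg, 0, g[[tr]]$segment_sd)
      pmax(v, 0.01)
    })
    vals <- as.data.frame(vals)
    stop_if(any(vals$C_w >= 100),
            "generate_plant: gradient configuration produced C_w >= 100%%")

    fw <- vals$M_dry / (1 - vals$C_w / 100)
    if (quantize) fw <- round(fw, 2)
    # dry matter of the weighed sample: mass balance exact post-quantization
    m_dry <- (1 - vals$C_w / 100) * fw

    res <- simulate_residue(sum(fw), residue_model,
                            seed = derive_seed(seed, "residue"))
    tfw <- sum(fw) / (1 - res$rr / 100)
    if (quantize) tfw <- round(tfw, 2)

    segments <- data.frame(
      segment_id = sprintf("%s_S%02d", plant_id, seq_len(n_seg)),
      plant_id = plant_id,
      treatment_id = treatment$treatment_id,
      position_index = seq_len(n_seg),
      segment_length = segment_length,
      fresh_weight = fw,
      M_dry = m_dry,
      C_w = vals$C_w,
      C_N = vals$C_N,
      C_ch = vals$C_ch,
      stringsAsFactors = FALSE)
    plant <- data.frame(
      plant_id = plant_id,
      treatment_id = treatment$treatment_id,
      total_fresh_weight = tfw,
      cum_fresh_weight = sum(fw),
      residual_rate = residual_rate(tfw, sum(fw)),
      height = n_seg * segment_length,
      stringsAsFactors = FALSE)
    list(plant = plant, segments = segments)
  })
}

#' Build a complete synthetic dataset
#'
#' Generates plants for every treatment, forward-models their spectra,
#' applies the partial-labelling pattern (all segments carry dry-matter and
#' water truth; random subsets sized by `label_fractions` carry nitrogen and
#' chlorophyll truth), and optionally writes the full set of pipeline files.
#' Everything derives from `seed`, so the same call reproduces the dataset
#' bit-exactly.
#'
#' @param design treatment table from [design_experiments()].
#' @param gradients gradient configuration.
#' @param forward forward-model configuration.
#' @param plants_per_treatment plants generated per treatment.
#' @param seed root seed.
#' @param band_step spectral subsampling factor (1 = full 2,151-band grid;
#'   10 keeps every 10th band for fast desk-scale runs).
#' @param label_fractions named fractions of segments carrying `C_N` and
#'   `C_ch` measurements (defaults mirror assaying 250 and 200 of 1,806
#'   segments).
#' @param residue_model passed to [generate_plant()].
#' @param out_dir optional directory; when given, writes `treatments.csv`,
#'   `plants.csv`, `segments.csv`, `spectra.csv` and `provenance.json`.
#' @return A `trait_dataset` list: `treatments`, `plants`, `segments` (with
#'   measured-trait columns where labelled and `true_*` columns always),
#'   `spectra` matrix, `wavelengths`, `seed`.
#' @export
build_dataset <- function(design = design_experiments(),
                          gradients = default_gradients(),
                          forward = default_forward_config(),
                          plants_per_treatment = 3, seed = 1L,
                          band_step = 1,
                          label_fractions = c(C_N = 250 / 1806,
                                              C_ch = 200 / 1806),
                          residue_model = "gamma", out_dir = NULL) {
  stop_if(plants_per_treatment < 1, "build_dataset: plants_per_treatment >= 1")
  wl <- canonical_grid()
  if (band_step > 1) wl <- wl[seq(1, length(wl), by = band_step)]

  plants <- list(); segments <- list()
  for (i in seq_len(nrow(design))) {
    tr <- design[i, , drop = FALSE]
    for (p in seq_len(plants_per_treatment)) {
      pid <- sprintf("%s_P%d", tr$treatment_id, p)
      pl <- generate_plant(tr, gradients, seed = derive_seed(seed, pid),
                           plant_id = pid, residue_model = residue_model)
      plants[[pid]] <- pl$plant
      segments[[pid]] <- pl$segments
    }
  }
  plants <- data.table::setDF(data.table::rbindlist(plants))
  segments <- data.table::setDF(data.table::rbindlist(segments))
  segments <- merge(segments,
                    design[, c("treatment_id", "cultivar", "nitrogen", "stage")],
                    by = "treatment_id", sort = FALSE)

  spectra <- matrix(NA_real_, nrow(segments), length(wl),
                    dimnames = list(segments$segment_id, as.character(wl)))
  for (i in seq_len(nrow(segments))) {
    tv <- c(M_dry = segments$M_dry[i], C_w = segments$C_w[i],
            C_N = segments$C_N[i], C_ch = segments$C_ch[i])
    spectra[i, ] <- traits_to_reflectance(
      tv, forward, seed = derive_seed(seed, paste0("spec_", segments$segment_id[i])),
      wavelengths = wl)$reflectance
  }

  # partial labelling: keep full truth in true_* columns, blank the measured
  # columns outside the labelled subsets
  n <- nrow(segments)
  segments$true_C_N <- segments$C_N
  segments$true_C_ch <- segments$C_ch
  for (tr in c("C_N", "C_ch")) {
    n_lab <- round(label_fractions[[tr]] * n)
    keep <- with_seed(derive_seed(seed, paste0("label_", tr)),
                      sample(n, min(n_lab, n)))
    v <- rep(NA_real_, n)
    v[keep] <- segments[[tr]][keep]
    segments[[tr]] <- v
  }

  ds <- structure(list(treatments = design, plants = plants,
                       segments = segments, spectra = spectra,
                       wavelengths = wl, seed = as.integer(seed),
                       band_step = band_step),
                  class = "trait_dataset")
  if (!is.null(out_dir)) write_dataset(ds, out_dir)
  ds
}

#' @export
print.trait_dataset <- function(x, ...) {
  cat(sprintf("<trait_dataset> %d treatments, %d plants, %d segments, %d bands (seed %d)\n",
              nrow(x$treatments), nrow(x$plants), nrow(x$segments),
              length(x$wavelengths), x$seed))
  invisible(x)
}

#' Write / read a dataset directory
#'
#' The on-disk layout is exactly what the pipeline consumes: a manifest
#' split into `treatments.csv`, `plants.csv` and `segments.csv`, the wide
#' `spectra.csv`, and `provenance.json` recording the seed and scale.
#'
#' @param dataset a `trait_dataset`.
#' @param dir dataset directory.
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` the
#'   dataset list.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # doubles are written with 17 significant digits so a written dataset
  # reads back bit-for-bit
  full <- function(df) {
    for (cn in names(df)) if (is.double(df[[cn]]))
      df[[cn]] <- sprintf("%.17g", df[[cn]])
    df
  }
  data.table::fwrite(full(dataset$treatments), file.path(dir, "treatments.csv"))
  data.table::fwrite(full(dataset$plants), file.path(dir, "plants.csv"))
  data.table::fwrite(full(dataset$segments), file.path(dir, "segments.csv"))
  write_spectra_csv(dataset$spectra, file.path(dir, "spectra.csv"))
  jsonlite::write_json(list(format = "spectraits-dataset-1",
                            seed = dataset$seed,
                            band_step = dataset$band_step,
                            n_segments = nrow(dataset$segments)),
                       file.path(dir, "provenance.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  need <- c("treatments.csv", "plants.csv", "segments.csv", "spectra.csv")
  miss <- need[!file.exists(file.path(dir, need))]
  stop_if(length(miss) > 0, "read_dataset: %s missing file(s): %s",
          dir, paste(miss, collapse = ", "))
  fr <- function(f) data.table::setDF(
    data.table::fread(file.path(dir, f), header = TRUE))
  spectra <- read_spectra_csv(file.path(dir, "spectra.csv"))
  prov_path <- file.path(dir, "provenance.json")
  prov <- if (file.exists(prov_path))
    jsonlite::read_json(prov_path, simplifyVector = TRUE) else list()
  structure(list(treatments = fr("treatments.csv"),
                 plants = fr("plants.csv"),
                 segments = fr("segments.csv"),
                 spectra = spectra,
                 wavelengths = as.numeric(colnames(spectra)),
                 seed = prov$seed %||% NA_integer_,
                 band_step = prov$band_step %||% NA_integer_),
            class = "trait_dataset")
}
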
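# DSC thermoporosimetry: Gibbs-Thomson inversion of stepwise-isothermal
# melting thermograms into pore-size distributions.

#' Gibbs-Thomson constants
#'
#' Physical constants of the Gibbs-Thomson relation for water/ice confined
#' in cylindrical pores. The defaults are the conventional values for water
#' in lignocellulosic substrates: bulk melting point 273.15 K, ice/pore-wall
#' surface energy 12.1 mJ m^-2, contact angle 180 deg, water density
#' 1000 kg m^-3, fusion enthalpy 334 J g^-1.
#'
#' @param T0 Bulk melting temperature, K.
#' @param gamma Surface energy, mJ m^-2.
#' @param theta Contact angle, degrees.
#' @param rho Density, kg m^-3.
#' @param Hf Fusion enthalpy, J g^-1.
#' @return A `gt_constants` list.
#' @export
gt_constants <- function(T0 = 273.15, gamma = 12.1, theta = 180,
                         rho = 1000, Hf = 334) {
  if (T0 <= 0 || gamma <= 0 || rho <= 0 || Hf <= 0) {
    stop("T0, gamma, rho and Hf must be positive", call. = FALSE)
  }
  structure(list(T0 = T0, gamma = gamma, theta = theta, rho = rho, Hf = Hf),
            class = "gt_constants")
}

#' Pore diameter from melting-point depression (Gibbs-Thomson)
#'
#' \deqn{D = \frac{4 T_0 \gamma \cos\theta}{(T_m - T_0)\,\rho\,H_f}}
#' For water-wet pores (\eqn{\theta = 180^\circ}, \eqn{\cos\theta = -1}) the
#' negative depression cancels the negative cosine, giving a positive
#' diameter that shrinks as the depression grows. `gamma` is converted from
#' mJ m^-2 to J m^-2 and `Hf` from J g^-1 to J kg^-1 internally; the result
#' is in metres.
#'
#' @param Tm Depressed melting temperature, K; must be strictly below `T0`.
#'   Vectorized.
#' @param constants A [gt_constants()] object.
#' @return Pore diameter D, metres.
#' @export
#' @examples
#' gibbs_thomson_diameter(272.15)  # ~3.96e-8 m (39.6 nm)
gibbs_thomson_diameter <- function(Tm, constants = gt_constants()) {
  stopifnot(inherits(constants, "gt_constants"))
  if (any(Tm >= constants$T0)) {
    stop("melting temperature must be strictly below T0", call. = FALSE)
  }
  gamma_si <- constants$gamma * 1e-3         # mJ m^-2 -> J m^-2
  Hf_si <- constants$Hf * 1e3                # J g^-1 -> J kg^-1
  4 * constants$T0 * gamma_si * cos(constants$theta * pi / 180) /
    ((Tm - constants$T0) * constants$rho * Hf_si)
}

#' Melting temperature of water confined in pores of a given diameter
#'
#' Algebraic inverse of [gibbs_thomson_diameter()]; used to design
#' isothermal-step programs and by the thermogram simulator.
#'
#' @param D Pore diameter, metres (> 0). Vectorized.
#' @param constants A [gt_constants()] object.
#' @return Melting temperature Tm, K (below `T0`).
#' @export
melting_temperature_for_diameter <- function(D, constants = gt_constants()) {
  stopifnot(inherits(constants, "gt_constants"))
  if (any(D <= 0)) stop("pore diameter must be positive", call. = FALSE)
  gamma_si <- constants$gamma * 1e-3
  Hf_si <- constants$Hf * 1e3
  constants$T0 + 4 * constants$T0 * gamma_si *
    cos(constants$theta * pi / 180) / (D * constants$rho * Hf_si)
}

#' Isothermal step program
#'
#' The hold schedule of a stepwise-isothermal DSC melting experiment:
#' temperatures strictly increasing, ending at or near the bulk melting
#' point so that free water melts in the final hold. The default schedule
#' holds at -30, -10, -5, -3, -2, -1.2, -0.6, -0.2 and +2 degrees C for
#' 600 s each; any schedule can be supplied.
#'
#' @param temp_C Hold temperatures, degrees C, strictly increasing.
#' @param duration_s Hold durations, s (recycled).
#' @return A `step_program` data frame with columns `temp_C`, `temp_K`,
#'   `duration_s`.
#' @export
step_program <- function(temp_C = c(-30, -10, -5, -3, -2, -1.2, -0.6, -0.2, 2),
                         duration_s = 600) {
  if (length(temp_C) < 1L) stop("at least one hold is required", call. = FALSE)
  if (any(diff(temp_C) <= 0)) {
    stop("hold temperatures must be strictly increasing", call. = FALSE)
  }
  structure(data.frame(temp_C = temp_C, temp_K = temp_C + 273.15,
                       duration_s = rep_len(duration_s, length(temp_C))),
            class = c("step_program", "data.frame"))
}

#' Read a step program from JSON
#'
#' JSON array of objects `{"temp_C": ..., "duration_s": ...}`.
#' @param path JSON file.
#' @return A [step_program()].
#' @export
read_step_program <- function(path) {
  df <- jsonlite::fromJSON(path)
  step_program(df$temp_C, df$duration_s)
}

#' Construct a DSC thermogram
#'
#' @param time_s Time, s, strictly increasing.
#' @param temperature_K Sample temperature, K.
#' @param heat_flow_mW Heat flow, mW, endotherm-positive ("exo down").
#' @param sample_mass_mg Wet sample mass in the pan, mg (> 0).
#' @param metadata Optional named list (instrument tag etc.); the sign
#'   convention is always recorded.
#' @return A `dsc_thermogram` data frame with attributes `sample_mass_mg`
#'   and `metadata`.
#' @export
dsc_thermogram <- function(time_s, temperature_K, heat_flow_mW,
                           sample_mass_mg, metadata = list()) {
  if (any(diff(time_s) <= 0)) {
    stop("time must be strictly increasing", call. = FALSE)
  }
  if (sample_mass_mg <= 0) stop("sample mass must be positive", call. = FALSE)
  metadata$sign_convention <- "endotherm_positive"
  structure(data.frame(time_s = time_s, temperature_K = temperature_K,
                       heat_flow_mW = heat_flow_mW),
            sample_mass_mg = sample_mass_mg, metadata = metadata,
            class = c("dsc_thermogram", "data.frame"))
}

#' Segment a thermogram into isothermal-hold windows
#'
#' Finds, for each programmed hold, the longest contiguous run of samples
#' whose temperature lies within `temperature_tolerance` of the hold
#' temperature. Windows are returned in program order and must not overlap.
#'
#' @param thermogram A [dsc_thermogram()].
#' @param program A [step_program()].
#' @param temperature_tolerance Band half-width, K (default 0.05).
#' @return Data frame: `temp_K`, `i_start`, `i_end`, `t_start`, `t_end`.
#' @export
segment_steps <- function(thermogram, program, temperature_tolerance = 0.05) {
  stopifnot(inherits(thermogram, "dsc_thermogram"),
            inherits(program, "step_program"))
  out <- lapply(seq_len(nrow(program)), function(k) {
    Tk <- program$temp_K[k]
    inband <- abs(thermogram$temperature_K - Tk) <= temperature_tolerance
    if (!any(inband)) {
      stop(sprintf("thermogram never reaches programmed hold at %.2f K (%.2f C)",
                   Tk, Tk - 273.15), call. = FALSE)
    }
    r <- rle(inband)
    ends <- cumsum(r$lengths); starts <- c(1L, utils::head(ends, -1L) + 1L)
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    data.frame(temp_K = Tk, i_start = starts[best], i_end = ends[best],
               t_start = thermogram$time_s[starts[best]],
               t_end = thermogram$time_s[ends[best]])
  })
  out <- do.call(rbind, out)
  if (any(diff(out$i_start) <= 0) || any(out$i_start[-1] <= out$i_end[-nrow(out)])) {
    stop("segmented hold windows overlap or are out of order", call. = FALSE)
  }
  out
}

#' Integrate the endotherm within one hold window
#'
#' Trapezoidal area between the heat-flow trace and a baseline over the
#' window, normalized per gram of sample. The `linear` baseline is anchored
#' at the window endpoints (mean over a short margin at each end); the
#' `flat` baseline is the mean of the pre-peak margin, suitable for
#' drift-free traces. Negative net areas are clipped to zero with a
#' warning (noise artifact policy).
#'
#' @param window One row of the [segment_steps()] output (or any list with
#'   `i_start`, `i_end`).
#' @param thermogram The [dsc_thermogram()].
#' @param baseline `"linear"` (default) or `"flat"`.
#' @param margin Number of samples averaged at window ends to anchor the
#'   baseline (default 5).
#' @return Specific melting enthalpy, J per g of sample.
#' @export
integrate_endotherm <- function(window, thermogram, baseline = c("linear", "flat"),
                                margin = 5L) {
  baseline <- match.arg(baseline)
  i0 <- window$i_start; i1 <- window$i_end
  if (i1 <= i0) stop("zero-length window", call. = FALSE)
  tt <- thermogram$time_s[i0:i1]
  hf <- thermogram$heat_flow_mW[i0:i1]
  n <- length(hf)
  m <- min(margin, max(1L, n %/% 10L))
  a <- mean(hf[seq_len(m)]); b <- mean(hf[seq.int(n - m + 1L, n)])
  bl <- switch(baseline,
    linear = a + (b - a) * (tt - mean(tt[seq_len(m)])) /
      (mean(tt[seq.int(n - m + 1L, n)]) - mean(tt[seq_len(m)])),
    flat = rep(a, n))
  area_mJ <- sum(diff(tt) * (utils::head(hf - bl, -1) + utils::tail(hf - bl, -1)) / 2)
  if (area_mJ < 0) {
    warning("negative endotherm area clipped to zero", call. = FALSE)
    area_mJ <- 0
  }
  area_mJ / attr(thermogram, "sample_mass_mg")    # mJ / mg == J / g
}

#' Pore-size distribution container
#'
#' @param bins Data frame with columns `d_low_m`, `d_high_m`,
#'   `water_fraction_pct` (% of total freezing water).
#' @param free_water_fraction_pct Bulk (unconfined) freezing water, % of
#'   total freezing water.
#' @param total_freezing_water_mg Total freezing-water mass, mg.
#' @return A `pore_size_distribution` object.
#' @export
pore_size_distribution <- function(bins, free_water_fraction_pct,
                                   total_freezing_water_mg) {
  stopifnot(all(c("d_low_m", "d_high_m", "water_fraction_pct") %in% names(bins)))
  if (any(bins$d_low_m <= 0) || any(bins$d_high_m <= bins$d_low_m)) {
    stop("bin edges must be positive with d_low < d_high", call. = FALSE)
  }
  if (any(bins$water_fraction_pct < 0) || free_water_fraction_pct < 0) {
    stop("water fractions must be non-negative", call. = FALSE)
  }
  tot <- sum(bins$water_fraction_pct) + free_water_fraction_pct
  if (abs(tot - 100) > 0.5) {
    stop(sprintf("fractions sum to %.2f%%, expected 100 +- 0.5", tot),
         call. = FALSE)
  }
  structure(list(bins = bins,
                 free_water_fraction_pct = free_water_fraction_pct,
                 total_freezing_water_mg = total_freezing_water_mg),
            class = "pore_size_distribution")
}

#' @export
print.pore_size_distribution <- function(x, ...) {
  cat("Pore-size distribution (freezing water)\n")
  b <- x$bins
  for (i in seq_len(nrow(b))) {
    cat(sprintf("  %6.2f - %6.2f nm : %5.1f %%\n",
                b$d_low_m[i] * 1e9, b$d_high_m[i] * 1e9,
                b$water_fraction_pct[i]))
  }
  cat(sprintf("  free (bulk) water  : %5.1f %%\n", x$free_water_fraction_pct))
  cat(sprintf("  total freezing water: %.3f mg\n", x$total_freezing_water_mg))
  invisible(x)
}

#' Pore-size distribution from per-step melting enthalpies
#'
#' Converts the specific melting enthalpy of each isothermal hold into the
#' water mass melting there (`dH * sample_mass / Hf`) and assigns it to a
#' diameter bin via the Gibbs-Thomson relation: water melting during the
#' hold at `T_k` occupies pores with melting points between the previous
#' hold and `T_k`, i.e. diameters in `(D(T_{k-1}), D(T_k)]`. The first bin's
#' lower edge comes from the thermogram's starting temperature. Holds within
#' `free_water_cutoff` of `T0` (where the relation diverges) are pooled as
#' bulk free water. Fractions are normalized so that confined + free water
#' equals 100% of total freezing water.
#'
#' @param step_enthalpies Data frame: `temp_K` (strictly increasing hold
#'   temperatures) and `enthalpy_J_per_g` (>= 0).
#' @param constants A [gt_constants()].
#' @param free_water_cutoff Holds with `T >= T0 - cutoff` count as bulk
#'   water; K, default 0.2.
#' @param sample_mass_mg Sample mass, mg.
#' @param start_temperature_K Temperature from which the first hold was
#'   approached (lower edge of the first bin); defaults to 5 K below the
#'   first hold.
#' @return A [pore_size_distribution()].
#' @export
pore_distribution <- function(step_enthalpies, constants = gt_constants(),
                              free_water_cutoff = 0.2, sample_mass_mg,
                              start_temperature_K = NULL) {
  stopifnot(all(c("temp_K", "enthalpy_J_per_g") %in% names(step_enthalpies)))
  Tk <- step_enthalpies$temp_K
  dH <- step_enthalpies$enthalpy_J_per_g
  if (any(diff(Tk) <= 0)) {
    stop("hold temperatures must be strictly increasing", call. = FALSE)
  }
  if (any(dH < 0)) stop("enthalpies must be non-negative", call. = FALSE)
  if (all(dH == 0)) {
    stop("degenerate distribution: all step enthalpies are zero", call. = FALSE)
  }
  water_mg <- dH * sample_mass_mg / constants$Hf
  total_mg <- sum(water_mg)

  is_free <- Tk >= constants$T0 - free_water_cutoff
  conf <- which(!is_free)
  start_T <- start_temperature_K %||% (Tk[1] - 5)
  # the first bin needs a lower edge strictly colder than the first hold
  if (start_T >= Tk[1]) start_T <- Tk[1] - 5

  bins <- NULL
  if (length(conf)) {
    prev_T <- c(start_T, utils::head(Tk[conf], -1L))
    bins <- data.frame(
      d_low_m  = gibbs_thomson_diameter(prev_T, constants),
      d_high_m = gibbs_thomson_diameter(Tk[conf], constants),
      water_fraction_pct = water_mg[conf] / total_mg * 100)
  }
  pore_size_distribution(
    bins = bins %||% data.frame(d_low_m = numeric(0), d_high_m = numeric(0),
                                water_fraction_pct = numeric(0)),
    free_water_fraction_pct = sum(water_mg[is_free]) / total_mg * 100,
    total_freezing_water_mg = total_mg)
}

#' Total water content by oven drying
#'
#' `(saturated - dry) / saturated * 100`, percent of the saturated mass —
#' the gravimetric reference obtained by puncturing the DSC pan and oven
#' drying at 103 degrees C.
#'
#' @param saturated_mass_mg Fully saturated sample mass, mg.
#' @param oven_dry_mass_mg Oven-dry mass, mg.
#' @return Total water content, % of saturated mass.
#' @export
total_water_content <- function(saturated_mass_mg, oven_dry_mass_mg) {
  if (saturated_mass_mg <= 0 || oven_dry_mass_mg <= 0) {
    stop("masses must be positive", call. = FALSE)
  }
  if (oven_dry_mass_mg > saturated_mass_mg) {
    stop("dry mass exceeds saturated mass", call. = FALSE)
  }
  (saturated_mass_mg - oven_dry_mass_mg) / saturated_mass_mg * 100
}

#' Run the full thermoporosimetry pipeline on a thermogram
#'
#' Convenience wrapper: [segment_steps()], [integrate_endotherm()] per hold,
#' then [pore_distribution()].
#'
#' @inheritParams segment_steps
#' @inheritParams integrate_endotherm
#' @inheritParams pore_distribution
#' @return A [pore_size_distribution()].
#' @export
thermogram_to_pores <- function(thermogram, program,
                                constants = gt_constants(),
                                temperature_tolerance = 0.05,
                                baseline = "linear",
                                free_water_cutoff = 0.2) {
  win <- segment_steps(thermogram, program, temperature_tolerance)
  dH <- vapply(seq_len(nrow(win)), function(k)
    integrate_endotherm(win[k, ], thermogram, baseline), numeric(1))
  pore_distribution(
    data.frame(temp_K = win$temp_K, enthalpy_J_per_g = dH),
    constants = constants, free_water_cutoff = free_water_cutoff,
    sample_mass_mg = attr(thermogram, "sample_mass_mg"),
    start_temperature_K = min(thermogram$temperature_K))
}

#' Read a DSC thermogram from CSV (+ JSON sidecar)
#'
#' CSV columns `time_s, temperature_C, heat_flow_mW`; the sidecar JSON must
#' provide `sample_mass_mg` (and may carry metadata).
#'
#' @param path CSV file.
#' @param sidecar JSON sidecar path; defaults to `path` with a `.json`
#'   extension.
#' @return A [dsc_thermogram()].
#' @export
read_thermogram <- function(path, sidecar = NULL) {
  df <- utils::read.csv(path)
  need <- c("time_s", "temperature_C", "heat_flow_mW")
  if (!all(need %in% names(df))) {
    stop("thermogram CSV must have columns time_s, temperature_C, heat_flow_mW",
         call. = FALSE)
  }
  sidecar <- sidecar %||% sub("\\.csv$", ".json", path)
  meta <- jsonlite::fromJSON(sidecar)
  dsc_thermogram(df$time_s, df$temperature_C + 273.15, df$heat_flow_mW,
                 sample_mass_mg = meta$sample_mass_mg,
                 metadata = meta[setdiff(names(meta), "sample_mass_mg")])
}

#' Write a DSC thermogram to CSV (+ JSON sidecar)
#' @param thermogram A [dsc_thermogram()].
#' @param path Output CSV path; sidecar JSON written alongside.
#' @export
write_thermogram <- function(thermogram, path) {
  utils::write.csv(
    data.frame(time_s = thermogram$time_s,
               temperature_C = thermogram$temperature_K - 273.15,
               heat_flow_mW = thermogram$heat_flow_mW),
    path, row.names = FALSE)
  meta <- attr(thermogram, "metadata")
  meta$sample_mass_mg <- attr(thermogram, "sample_mass_mg")
  meta$ground_truth <- NULL
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}

#' Write a pore-size distribution to CSV (+ JSON summary)
#'
#' CSV columns `d_low_nm, d_high_nm, freezing_water_pct`; the JSON summary
#' records the free-water fraction, total freezing water and the constants
#' used.
#'
#' @param dist A [pore_size_distribution()].
#' @param path Output CSV path.
#' @param constants The [gt_constants()] used, recorded in the summary.
#' @export
write_pore_distribution <- function(dist, path, constants = gt_constants()) {
  stopifnot(inherits(dist, "pore_size_distribution"))
  utils::write.csv(
    data.frame(d_low_nm = dist$bins$d_low_m * 1e9,
               d_high_nm = dist$bins$d_high_m * 1e9,
               freezing_water_pct = dist$bins$water_fraction_pct),
    path, row.names = FALSE)
  jsonlite::write_json(
    list(free_water_fraction_pct = dist$free_water_fraction_pct,
         total_freezing_water_mg = dist$total_freezing_water_mg,
         constants = unclass(constants)),
    sub("\\.csv$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
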
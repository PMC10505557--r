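# Synthetic instrument-trace simulators with known ground truth.
#
# Every generator takes an explicit seed and is byte-deterministic given
# identical arguments. Noise is additive Gaussian unless stated otherwise.

#' Simulate an equilibrium sorption isotherm from the Park model
#'
#' Evaluates the Park model on an activity grid and applies multiplicative
#' relative Gaussian noise: `M = M_true * (1 + e)`, `e ~ N(0, noise_sd)`.
#' `noise_sd = 0` reproduces the model exactly.
#'
#' @param params A [park_params()] ground truth.
#' @param activity_grid Strictly increasing water activities in `[0, 1)`.
#' @param noise_sd Relative noise standard deviation (>= 0; 0.01 = 1%).
#' @param seed RNG seed.
#' @return Data frame `aw`, `M` with attribute `ground_truth` (the params).
#' @export
gen_park_isotherm <- function(params, activity_grid, noise_sd = 0, seed = 1) {
  stopifnot(inherits(params, "park_params"))
  if (any(activity_grid < 0) || any(activity_grid >= 1)) {
    stop("activities must lie in [0, 1)", call. = FALSE)
  }
  if (length(activity_grid) > 1L && any(diff(activity_grid) <= 0)) {
    stop("activity grid must be strictly increasing", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  set.seed(seed)
  M0 <- park_model(params, activity_grid)
  M <- M0 * (1 + stats::rnorm(length(M0), 0, noise_sd))
  structure(data.frame(aw = activity_grid, M = M),
            ground_truth = params, class = c("sorption_isotherm", "data.frame"))
}

#' Default DVS activity schedule
#'
#' Dry-reference hold at `a_w = 0`, sorption steps 0.1 to 0.9 in steps of
#' 0.1, then desorption back down to 0 — the standard full-cycle program.
#'
#' @param hold_s Hold duration per step, s (default 4800 = 8 time constants
#'   at the default tau of 600 s, so the residual relaxation
#'   `exp(-duration/tau)` is below 1e-3).
#' @return Data frame `aw`, `duration_s`.
#' @export
dvs_schedule <- function(hold_s = 4800) {
  data.frame(aw = c(0, seq(0.1, 0.9, 0.1), seq(0.8, 0, -0.1)),
             duration_s = hold_s)
}

#' Simulate a DVS kinetic trace
#'
#' Within each activity hold the mass relaxes exponentially towards the
#' Park-model equilibrium for that activity:
#' `m(t) = m_eq - (m_eq - m_start) * exp(-t / tau)`, starting from the mass
#' at the end of the previous hold. The first schedule entry should be the
#' `a_w = 0` dry-reference hold.
#'
#' @param params [park_params()] ground truth.
#' @param schedule Data frame `aw`, `duration_s` (default [dvs_schedule()]).
#' @param tau Relaxation time constant, s (default 600).
#' @param dry_mass_mg Dry mass m_d, mg (default 20).
#' @param dt Sampling interval, s (default 10).
#' @param noise_sd Additive mass noise, mg (default 0).
#' @param seed RNG seed.
#' @return A [dvs_trace()] with attribute `ground_truth` (params, tau,
#'   schedule).
#' @export
gen_dvs_kinetics <- function(params, schedule = dvs_schedule(), tau = 600,
                             dry_mass_mg = 20, dt = 10, noise_sd = 0,
                             seed = 1) {
  stopifnot(inherits(params, "park_params"))
  if (is.null(schedule) || nrow(schedule) == 0L) {
    stop("schedule must contain at least one hold", call. = FALSE)
  }
  set.seed(seed)
  t_all <- numeric(0); m_all <- numeric(0); aw_all <- numeric(0)
  t0 <- 0; m_prev <- dry_mass_mg
  for (k in seq_len(nrow(schedule))) {
    aw <- schedule$aw[k]
    m_eq <- dry_mass_mg * (1 + park_model(params, aw) / 100)
    tt <- seq(dt, schedule$duration_s[k], by = dt)
    mm <- m_eq - (m_eq - m_prev) * exp(-tt / tau)
    t_all <- c(t_all, t0 + tt); m_all <- c(m_all, mm)
    aw_all <- c(aw_all, rep(aw, length(tt)))
    t0 <- t0 + schedule$duration_s[k]
    m_prev <- mm[length(mm)]
  }
  if (noise_sd > 0) m_all <- m_all + stats::rnorm(length(m_all), 0, noise_sd)
  tr <- dvs_trace(t_all, pmax(m_all, 0), aw_all, dry_mass_mg)
  attr(tr, "ground_truth") <- list(params = params, tau = tau,
                                   schedule = schedule)
  tr
}

#' Simulate a stepwise-isothermal DSC melting thermogram
#'
#' Forward model of the thermoporosimetry experiment: the temperature ramps
#' between programmed holds and, during each hold, the water assigned to
#' that hold melts as a Gaussian-shaped endotherm centred mid-hold whose
#' integrated area equals (melting water mass) x Hf. Confined-water bins
#' are mapped to the first hold warm enough to melt them (via the
#' Gibbs-Thomson relation); bulk free water melts in the final hold. Heat
#' flow is endotherm-positive ("exo down"), declared in the metadata.
#'
#' @param pore_dist A [pore_size_distribution()] ground truth (its
#'   `free_water_fraction_pct` and `total_freezing_water_mg` drive the bulk
#'   melt and scaling).
#' @param program A [step_program()]; bin edges should be consistent with
#'   the hold temperatures.
#' @param sample_mass_mg Sample mass, mg (default 8).
#' @param peak_width Gaussian sigma of each endotherm, s (default 20).
#' @param baseline_slope Linear baseline drift, mW per s (default 0).
#' @param ramp_rate Ramp between holds, K per s (default 0.05).
#' @param dt Sampling interval, s (default 1).
#' @param noise_sd Additive heat-flow noise, mW (default 0).
#' @param seed RNG seed.
#' @param constants [gt_constants()].
#' @return A [dsc_thermogram()] whose metadata carries the ground-truth
#'   per-hold water masses.
#' @export
gen_dsc_thermogram <- function(pore_dist, program, sample_mass_mg = 8,
                               peak_width = 20, baseline_slope = 0,
                               ramp_rate = 0.05, dt = 1, noise_sd = 0,
                               seed = 1, constants = gt_constants()) {
  stopifnot(inherits(pore_dist, "pore_size_distribution"),
            inherits(program, "step_program"))
  set.seed(seed)
  Tk <- program$temp_K
  if (any(diff(Tk) <= 0)) {
    stop("program temperatures must be strictly increasing", call. = FALSE)
  }
  total <- pore_dist$total_freezing_water_mg
  bins <- pore_dist$bins

  # map each bin to the first hold that melts its largest pores
  hold_mass <- numeric(length(Tk))
  if (nrow(bins)) {
    Tm_high <- melting_temperature_for_diameter(bins$d_high_m, constants)
    for (i in seq_len(nrow(bins))) {
      k <- which(Tk >= Tm_high[i] - 1e-9)[1]
      if (is.na(k)) {
        stop("no programmed hold warm enough to melt a pore bin", call. = FALSE)
      }
      hold_mass[k] <- hold_mass[k] +
        bins$water_fraction_pct[i] / 100 * total
    }
  }
  hold_mass[length(Tk)] <- hold_mass[length(Tk)] +
    pore_dist$free_water_fraction_pct / 100 * total

  # build time/temperature profile: ramp to each hold, then hold
  t_all <- numeric(0); T_all <- numeric(0)
  seg <- data.frame(k = seq_along(Tk), t_hold_start = NA_real_,
                    t_hold_end = NA_real_)
  t0 <- 0; T_prev <- Tk[1]
  for (k in seq_along(Tk)) {
    if (k > 1L) {
      ramp_dur <- (Tk[k] - T_prev) / ramp_rate
      tt <- seq(dt, ramp_dur, by = dt)
      t_all <- c(t_all, t0 + tt)
      T_all <- c(T_all, T_prev + ramp_rate * tt)
      t0 <- t0 + ramp_dur
    }
    tt <- seq(dt, program$duration_s[k], by = dt)
    t_all <- c(t_all, t0 + tt)
    T_all <- c(T_all, rep(Tk[k], length(tt)))
    seg$t_hold_start[k] <- t0
    seg$t_hold_end[k] <- t0 + program$duration_s[k]
    t0 <- t0 + program$duration_s[k]
    T_prev <- Tk[k]
  }

  hf <- baseline_slope * t_all
  for (k in seq_along(Tk)) {
    if (hold_mass[k] <= 0) next
    area_mJ <- hold_mass[k] * constants$Hf      # mg x J/g = mJ
    centre <- (seg$t_hold_start[k] + seg$t_hold_end[k]) / 2
    hf <- hf + area_mJ / (peak_width * sqrt(2 * pi)) *
      exp(-((t_all - centre)^2) / (2 * peak_width^2))
  }
  if (noise_sd > 0) hf <- hf + stats::rnorm(length(hf), 0, noise_sd)

  dsc_thermogram(t_all, T_all, hf, sample_mass_mg,
                 metadata = list(instrument = "synthetic",
                                 ground_truth = list(
                                   hold_temp_K = Tk,
                                   hold_water_mg = hold_mass,
                                   distribution = pore_dist)))
}

#' Simulate a two-channel wall/lumen image stack
#'
#' Procedural cell-wall lattice (offset rectangular "honeycomb-like"
#' pattern of wall pixels around lumina) imaged in two channels: the
#' counterstain channel carries `counterstain_level` on wall pixels and 0
#' elsewhere; the target channel carries the programmed wall intensity on
#' wall pixels and the background intensity elsewhere. A focal-attenuation
#' profile dims slices away from the mid-stack focal plane (the middle
#' slice carries the full programmed intensity), so that a maximum
#' projection recovers the in-focus signal. Independent Gaussian noise is
#' added per voxel and intensities are clipped to the bit depth. The
#' ground-truth wall mask is returned alongside.
#'
#' @param shape Integer `(z, y, x)` dimensions.
#' @param wall_geometry List with `pitch` (cell period, px) and `thickness`
#'   (wall thickness, px).
#' @param counterstain_level Counterstain wall intensity.
#' @param target_levels Numeric `c(wall, background)` target intensities;
#'   wall must exceed background.
#' @param noise_sd Additive intensity noise (default 5).
#' @param seed RNG seed.
#' @param bit_depth Bits per sample (default 8).
#' @param focus_falloff Fractional intensity loss at the outermost slices
#'   relative to the mid-stack focal plane (default 0.2).
#' @return A [two_channel_stack()] with extra element `truth_mask`
#'   (logical y-by-x matrix).
#' @export
gen_image_stack <- function(shape = c(3, 64, 64),
                            wall_geometry = list(pitch = 16, thickness = 3),
                            counterstain_level = 200,
                            target_levels = c(wall = 100, background = 0),
                            noise_sd = 5, seed = 1, bit_depth = 8,
                            focus_falloff = 0.2) {
  set.seed(seed)
  z <- shape[1]; ny <- shape[2]; nx <- shape[3]
  maxval <- 2^bit_depth - 1
  wall <- target_levels[[1]]; bg <- target_levels[[2]]
  if (wall <= bg) stop("wall intensity must exceed background", call. = FALSE)
  if (wall > maxval || counterstain_level > maxval) {
    stop("levels exceed the declared bit depth", call. = FALSE)
  }

  p <- wall_geometry$pitch; w <- wall_geometry$thickness
  yy <- matrix(seq_len(ny) - 1L, ny, nx)
  xx <- matrix(seq_len(nx) - 1L, ny, nx, byrow = TRUE)
  band <- (yy %/% p) %% 2L                       # offset alternate rows
  mask <- (yy %% p < w) | (((xx + band * (p %/% 2L)) %% p) < w)
  if (!any(mask) || all(mask)) {
    stop("degenerate wall geometry: mask empty or full-frame", call. = FALSE)
  }

  mid <- (z + 1) / 2
  focus <- if (z > 1L) {
    1 - focus_falloff * abs(seq_len(z) - mid) / (z - mid)
  } else 1
  mk <- function(level_wall, level_bg) {
    a <- array(0, dim = c(z, ny, nx))
    for (s in seq_len(z)) {
      base <- ifelse(mask, level_wall, level_bg) * focus[s]
      slab <- base + stats::rnorm(ny * nx, 0, noise_sd)
      a[s, , ] <- pmin(pmax(slab, 0), maxval)
    }
    a
  }
  st <- two_channel_stack(mk(counterstain_level, 0), mk(wall, bg),
                          bit_depth = bit_depth)
  st$truth_mask <- mask
  st
}

#' Simulate grouped scalar measurements
#'
#' Draws labelled i.i.d. samples per group from a stated distribution
#' family. Supported families: `"normal"` (mean, sd), `"lognormal"`
#' (meanlog, sdlog), `"uniform"` (mean +- sd*sqrt(3)), `"constant"`.
#'
#' @param group_specs List of lists with fields `label`, `dist`, `mean`,
#'   `sd`, `n` (n >= 3).
#' @param seed RNG seed.
#' @return A [grouped_measurements()] data frame.
#' @export
gen_grouped_measurements <- function(group_specs, seed = 1) {
  set.seed(seed)
  draws <- lapply(group_specs, function(s) {
    if (s$n < 3L) stop("each group needs n >= 3", call. = FALSE)
    v <- switch(s$dist,
      normal    = stats::rnorm(s$n, s$mean, s$sd),
      lognormal = stats::rlnorm(s$n, s$mean, s$sd),
      uniform   = stats::runif(s$n, s$mean - s$sd * sqrt(3),
                               s$mean + s$sd * sqrt(3)),
      constant  = rep(s$mean, s$n),
      stop(sprintf("unsupported distribution '%s'", s$dist), call. = FALSE))
    data.frame(group = s$label, value = v)
  })
  d <- do.call(rbind, draws)
  grouped_measurements(d$group, d$value)
}

#' Write a simulation's ground truth as a JSON sidecar
#'
#' Serializes the `ground_truth` attribute (or `truth_mask` summary for
#' image stacks) next to the data file so test harnesses can recover the
#' programmed parameters without re-running the generator.
#'
#' @param object A generator output.
#' @param path JSON output path.
#' @export
write_ground_truth <- function(object, path) {
  gt <- attr(object, "ground_truth")
  if (is.null(gt) && !is.null(object$truth_mask)) {
    gt <- list(wall_pixel_count = sum(object$truth_mask),
               shape = dim(object$counterstain))
  }
  if (is.null(gt)) {
    gt <- attr(object, "metadata")$ground_truth
    if (!is.null(gt)) gt$distribution <- unclass(gt$distribution)
  }
  if (is.null(gt)) stop("object carries no ground truth", call. = FALSE)
  if (inherits(gt, "park_params")) gt <- unclass(gt)
  if (!is.null(gt$params)) gt$params <- unclass(gt$params)
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
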
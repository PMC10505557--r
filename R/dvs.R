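# Dynamic vapour sorption (DVS): kinetic traces -> equilibrium isotherms.

#' Construct a DVS kinetic trace
#'
#' A gravimetric sorption record: sample mass versus time under a
#' piecewise-constant water-activity program. The dry mass `m_d` (mass after
#' equilibration under dry nitrogen) is the reference for all mass gains; it
#' may be supplied explicitly or recovered later from the leading
#' `a_w = 0` segment.
#'
#' @param time_s Time, seconds, strictly increasing.
#' @param mass_mg Sample mass, mg, non-negative.
#' @param aw_setpoint Water-activity setpoint per time point, in `[0, 1]`.
#' @param dry_mass_mg Optional known dry mass, mg (> 0).
#' @return A `dvs_trace`: data frame with the three columns and a
#'   `dry_mass_mg` attribute (possibly `NA`).
#' @export
dvs_trace <- function(time_s, mass_mg, aw_setpoint, dry_mass_mg = NA_real_) {
  if (length(time_s) < 2L || any(diff(time_s) <= 0)) {
    stop("time must be strictly increasing with >= 2 samples", call. = FALSE)
  }
  if (any(mass_mg < 0)) stop("mass must be non-negative", call. = FALSE)
  if (any(aw_setpoint < 0 | aw_setpoint > 1)) {
    stop("activity setpoints must lie in [0, 1]", call. = FALSE)
  }
  if (!is.na(dry_mass_mg) && dry_mass_mg <= 0) {
    stop("dry mass must be positive", call. = FALSE)
  }
  structure(
    data.frame(time_s = time_s, mass_mg = mass_mg, aw_setpoint = aw_setpoint),
    dry_mass_mg = dry_mass_mg,
    class = c("dvs_trace", "data.frame"))
}

# Contiguous runs of constant activity setpoint.
trace_holds <- function(trace) {
  r <- rle(trace$aw_setpoint)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  data.frame(aw = r$values, i_start = starts, i_end = ends)
}

#' Detect equilibrium masses in a DVS trace
#'
#' For each activity hold, equilibrium is declared once the drift rate
#' `|dm/dt|` over a trailing window falls below a threshold expressed in
#' percent of dry mass per minute; the equilibrium mass is the mean mass
#' over that final window. Holds that never meet the criterion are reported
#' with the terminal mass and flagged `equilibrated = FALSE`.
#'
#' The drift rate is the slope of an ordinary least-squares line through the
#' window, which is robust to uncorrelated balance noise.
#'
#' @param trace A [dvs_trace()].
#' @param dmdt_threshold Drift threshold, % of dry mass per minute
#'   (default 0.002).
#' @param window Trailing window length, minutes (default 10).
#' @param dry_mass_mg Dry-mass override, mg; defaults to the trace attribute
#'   or, failing that, the mean mass over the final window of the leading
#'   `a_w = 0` hold.
#' @return Data frame with one row per hold: `aw`, `m_eq_mg`,
#'   `dmdt_pct_per_min`, `equilibrated`.
#' @export
detect_equilibria <- function(trace, dmdt_threshold = 0.002, window = 10,
                              dry_mass_mg = NULL) {
  stopifnot(inherits(trace, "dvs_trace"))
  holds <- trace_holds(trace)
  win_s <- window * 60

  durations <- trace$time_s[holds$i_end] - trace$time_s[holds$i_start]
  if (any(durations < win_s)) {
    stop(sprintf(
      "window (%g min) longer than the shortest hold (%.1f min)",
      window, min(durations) / 60), call. = FALSE)
  }

  m_d <- dry_mass_mg %||% attr(trace, "dry_mass_mg")
  if (is.null(m_d) || is.na(m_d)) {
    if (holds$aw[1] != 0) {
      stop("dry mass unknown: no leading a_w = 0 segment and no override",
           call. = FALSE)
    }
    m_d <- tail_window_mean(trace, holds$i_start[1], holds$i_end[1], win_s)
  }

  out <- holds
  out$m_eq_mg <- NA_real_
  out$dmdt_pct_per_min <- NA_real_
  out$equilibrated <- FALSE
  for (k in seq_len(nrow(holds))) {
    i0 <- holds$i_start[k]; i1 <- holds$i_end[k]
    t_end <- trace$time_s[i1]
    sel <- which(trace$time_s >= t_end - win_s & seq_along(trace$time_s) >= i0 &
                   seq_along(trace$time_s) <= i1)
    tt <- trace$time_s[sel]; mm <- trace$mass_mg[sel]
    slope <- if (length(sel) >= 2L) stats::cov(tt, mm) / stats::var(tt) else 0
    dmdt <- abs(slope) * 60 / m_d * 100      # mg/s -> % dry mass / min
    out$m_eq_mg[k] <- mean(mm)
    out$dmdt_pct_per_min[k] <- dmdt
    out$equilibrated[k] <- dmdt < dmdt_threshold
  }
  out <- out[, c("aw", "m_eq_mg", "dmdt_pct_per_min", "equilibrated")]
  attr(out, "dry_mass_mg") <- m_d
  out
}

tail_window_mean <- function(trace, i0, i1, win_s) {
  t_end <- trace$time_s[i1]
  sel <- which(trace$time_s >= t_end - win_s)
  sel <- sel[sel >= i0 & sel <= i1]
  mean(trace$mass_mg[sel])
}

#' Build sorption and desorption isotherms from a kinetic trace
#'
#' Extracts the equilibrium mass of every activity hold
#' ([detect_equilibria()]), converts to mass gain relative to the dry mass
#' ([mass_gain()]), and partitions the holds into a sorption and a
#' desorption branch at the maximum-activity hold. Holds tied at the maximum
#' activity are assigned to the sorption branch. The leading `a_w = 0`
#' (dry-reference) segment belongs to neither branch.
#'
#' @inheritParams detect_equilibria
#' @return List of class `dvs_isotherms` with elements `sorption` and
#'   `desorption`, each a `sorption_isotherm` data frame
#'   (`aw`, `M`, `equilibrated`), plus `dry_mass_mg`.
#' @export
build_isotherm <- function(trace, dmdt_threshold = 0.002, window = 10,
                           dry_mass_mg = NULL) {
  eq <- detect_equilibria(trace, dmdt_threshold, window, dry_mass_mg)
  m_d <- attr(eq, "dry_mass_mg")

  rows <- seq_len(nrow(eq))
  drop_lead <- if (eq$aw[1] == 0) 1L else integer(0)
  rows <- setdiff(rows, drop_lead)
  if (length(rows) == 0L) stop("trace contains no sorption steps", call. = FALSE)

  peak <- max(eq$aw[rows])
  last_peak <- max(rows[eq$aw[rows] == peak])   # ties -> sorption
  sor_rows <- rows[rows <= last_peak]
  des_rows <- rows[rows > last_peak]

  mk <- function(idx, branch) {
    structure(data.frame(
      aw = eq$aw[idx],
      M = if (length(idx)) suppressWarnings(mass_gain(eq$m_eq_mg[idx], m_d))
          else numeric(0),
      equilibrated = eq$equilibrated[idx]),
      branch = branch,
      class = c("sorption_isotherm", "data.frame"))
  }
  structure(list(sorption = mk(sor_rows, "sorption"),
                 desorption = mk(des_rows, "desorption"),
                 dry_mass_mg = m_d),
            class = "dvs_isotherms")
}

#' Sorption-desorption hysteresis
#'
#' Difference `M_desorption - M_sorption` at each shared water activity,
#' interpolating the desorption branch linearly onto the sorption grid.
#' Points of the sorption grid outside the desorption activity range are
#' dropped.
#'
#' @param sorption,desorption `sorption_isotherm` data frames (columns `aw`,
#'   `M`) or plain data frames with those columns.
#' @return Data frame `aw`, `delta_M` (percentage points).
#' @export
hysteresis <- function(sorption, desorption) {
  s <- as_isotherm_df(sorption); d <- as_isotherm_df(desorption)
  if (nrow(s) == 0L || nrow(d) == 0L) {
    stop("both branches must be non-empty", call. = FALSE)
  }
  lo <- max(min(s$aw), min(d$aw)); hi <- min(max(s$aw), max(d$aw))
  if (lo > hi) stop("activity ranges do not overlap", call. = FALSE)
  keep <- s$aw >= lo & s$aw <= hi
  aw <- s$aw[keep]
  d_interp <- if (nrow(d) == 1L) rep(d$M, length(aw)) else
    stats::approx(d$aw, d$M, xout = aw)$y
  data.frame(aw = aw, delta_M = d_interp - s$M[keep])
}

#' Read a DVS kinetic trace from CSV
#'
#' Expects columns `time_s, mass_mg, aw_setpoint` (header required).
#'
#' @param path CSV file.
#' @param dry_mass_mg Optional dry-mass override, mg.
#' @return A [dvs_trace()].
#' @export
read_dvs_trace <- function(path, dry_mass_mg = NA_real_) {
  df <- utils::read.csv(path)
  need <- c("time_s", "mass_mg", "aw_setpoint")
  if (!all(need %in% names(df))) {
    stop("trace CSV must have columns time_s, mass_mg, aw_setpoint",
         call. = FALSE)
  }
  dvs_trace(df$time_s, df$mass_mg, df$aw_setpoint, dry_mass_mg)
}

#' Write a DVS kinetic trace to CSV
#' @param trace A [dvs_trace()].
#' @param path Output CSV path.
#' @export
write_dvs_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Write isotherm branches to CSV
#'
#' Long format `branch, aw, mass_gain_pct`.
#' @param isotherms A `dvs_isotherms` object from [build_isotherm()].
#' @param path Output CSV path.
#' @export
write_isotherm_csv <- function(isotherms, path) {
  stopifnot(inherits(isotherms, "dvs_isotherms"))
  rows <- do.call(rbind, lapply(c("sorption", "desorption"), function(b) {
    br <- isotherms[[b]]
    if (nrow(br) == 0L) return(NULL)
    data.frame(branch = b, aw = br$aw, mass_gain_pct = br$M)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
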
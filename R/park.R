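# Park sorption-isotherm model and goodness-of-fit utilities.

#' Park model parameter set
#'
#' Bundles the five parameters of the Park sorption model: a Langmuir
#' adsorption term (specific sites), a Henry dissolution term and a
#' water-clustering term.
#'
#' @param A_L Langmuir capacity constant (% mass gain).
#' @param b_L Langmuir affinity constant (dimensionless).
#' @param k_H Henry's solubility coefficient (% mass gain per unit water
#'   activity).
#' @param k_a Equilibrium constant of the water clustering reaction.
#' @param n Mean number of water molecules per cluster (>= 1; treated as a
#'   continuous parameter).
#'
#' @return An object of class `park_params` (a named list).
#' @export
#' @examples
#' park_params(A_L = 1, b_L = 10, k_H = 0.2, k_a = 0.5, n = 4)
park_params <- function(A_L, b_L, k_H, k_a, n) {
  vals <- c(A_L = A_L, b_L = b_L, k_H = k_H, k_a = k_a, n = n)
  if (any(!is.finite(vals))) {
    stop("Park parameters must be finite numbers", call. = FALSE)
  }
  if (any(vals < 0)) {
    stop("Park parameters must be non-negative", call. = FALSE)
  }
  if (n < 1) {
    stop("cluster size 'n' must be >= 1", call. = FALSE)
  }
  structure(as.list(vals), class = "park_params")
}

#' @export
print.park_params <- function(x, ...) {
  cat("Park model parameters:\n")
  cat(sprintf("  A_L = %.4g  b_L = %.4g  k_H = %.4g  k_a = %.4g  n = %.4g\n",
              x$A_L, x$b_L, x$k_H, x$k_a, x$n))
  invisible(x)
}

#' Evaluate the Park sorption model
#'
#' Equilibrium water mass gain at water activity `a_w`:
#' \deqn{M = \frac{A_L b_L a_w}{1 + b_L a_w} + k_H a_w + n k_H^n k_a a_w^n}
#' i.e. Langmuir adsorption on specific sites, Henry-law dissolution, and
#' clustering of water molecules at high activity.
#'
#' @param params A [park_params()] object.
#' @param a_w Water activity (relative humidity / 100), values in `[0, 1)`.
#'   Vectorized.
#' @return Mass gain M, in g water per 100 g dry sample (%).
#' @export
#' @examples
#' p <- park_params(1, 10, 0.2, 0.5, 4)
#' park_model(p, 0.5)   # 0.9335
park_model <- function(params, a_w) {
  stopifnot(inherits(params, "park_params"))
  if (any(!is.finite(a_w)) || any(a_w < 0) || any(a_w >= 1)) {
    stop("water activity must lie in [0, 1)", call. = FALSE)
  }
  with(params,
       A_L * b_L * a_w / (1 + b_L * a_w) +
         k_H * a_w +
         n * k_H^n * k_a * a_w^n)
}

#' Water mass gain at equilibrium
#'
#' `M = (m_eq - m_d) / m_d * 100`, expressed in percent of dry mass
#' (equivalently g water per 100 g dry sample).
#'
#' @param m_eq Equilibrium mass, mg.
#' @param m_d Dry mass, mg (> 0).
#' @return Mass gain in %. Negative values (mass below the dry reference,
#'   possible on desorption) are allowed but raise a warning.
#' @export
mass_gain <- function(m_eq, m_d) {
  if (!is.finite(m_d) || m_d <= 0) {
    stop("dry mass must be a positive number", call. = FALSE)
  }
  M <- (m_eq - m_d) / m_d * 100
  if (any(M < 0)) {
    warning("mass gain below dry reference (negative M)", call. = FALSE)
  }
  M
}

#' Mean relative percentage deviation modulus (MRD)
#'
#' \deqn{MRD = \frac{100}{N} \sum_{i=1}^N \frac{|m_i - m_{pi}|}{m_i}}
#' where \eqn{m_i} are observed and \eqn{m_{pi}} predicted values. A value
#' below 10% is conventionally read as a good isotherm fit. Observed values
#' equal to zero are excluded (with a warning) and N reduced accordingly,
#' since the relative deviation is undefined there.
#'
#' @param observed Observed values.
#' @param predicted Predicted values, same length.
#' @return MRD in percent (non-negative scalar).
#' @export
#' @examples
#' mrd(c(10, 20), c(9, 22))  # 10
mrd <- function(observed, predicted) {
  if (length(observed) == 0L) stop("empty input", call. = FALSE)
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  keep <- observed != 0
  if (!all(keep)) {
    warning(sprintf("%d zero-valued observed point(s) excluded from MRD",
                    sum(!keep)), call. = FALSE)
  }
  if (!any(keep)) stop("no nonzero observed values", call. = FALSE)
  100 / sum(keep) * sum(abs(observed[keep] - predicted[keep]) / observed[keep])
}

#' Fit the Park model to a sorption isotherm
#'
#' Relative (1/M^2-weighted) nonlinear least squares (Levenberg-Marquardt
#' via \pkg{minpack.lm}) with multi-start: each fit is launched from every
#' point of a lattice of initial `(b_L, k_a, n)` values, with `A_L` and
#' `k_H` initialized from the data. Relative weighting is the
#' maximum-likelihood objective when measurement error scales with the
#' signal — the usual situation for sorption balances, whose accuracy is
#' quoted in percent — and keeps the low-activity points informative when
#' the clustering term makes high-activity mass gains orders of magnitude
#' larger. The best converged solution by weighted residual sum of squares
#' is returned; MRD is reported as a diagnostic, not optimized. All
#' parameters are bounded below at zero (`n >= 1`); `n` is continuous.
#'
#' @param isotherm A data frame with columns `aw` and `M` (mass gain, %), or
#'   a `sorption_isotherm` object from [build_isotherm()]. At least 5 points
#'   (the model has 5 free parameters).
#' @param init Optional [park_params()] used as an additional start.
#' @param lower,upper Optional bound overrides (length-5 numeric, order
#'   `A_L, b_L, k_H, k_a, n`).
#' @return An object of class `park_fit`: list with elements `params`
#'   ([park_params()]), `mrd` (%), `residuals` (observed - predicted),
#'   `sse` (the relative-weighted residual sum of squares), `converged`,
#'   `n_points`, and `fitted`.
#' @export
fit_park <- function(isotherm, init = NULL, lower = NULL, upper = NULL) {
  df <- as_isotherm_df(isotherm)
  if (nrow(df) < 5L) {
    stop("at least 5 isotherm points are required to fit 5 parameters",
         call. = FALSE)
  }
  if (all(df$M == 0)) {
    stop("degenerate fit: all mass gains are zero", call. = FALSE)
  }

  lower <- if (is.null(lower)) c(0, 0, 0, 0, 1) else lower
  upper <- if (is.null(upper)) rep(Inf, 5) else upper

  # data-driven starts for the linear-ish parameters
  kH0 <- max(stats::median(df$M / pmax(df$aw, 1e-6)), 1e-3)
  AL0 <- max(min(df$M[df$M > 0]), 1e-3)

  lattice <- expand.grid(b_L = c(1, 10, 50),
                         k_a = c(0.05, 0.5, 5),
                         n   = c(2, 4, 6))
  starts <- lapply(seq_len(nrow(lattice)), function(i) {
    c(A_L = AL0, b_L = lattice$b_L[i], k_H = kH0,
      k_a = lattice$k_a[i], n = lattice$n[i])
  })
  if (!is.null(init)) {
    stopifnot(inherits(init, "park_params"))
    starts <- c(starts, list(unlist(init)))
  }

  w <- 1 / pmax(abs(df$M), 1e-6)^2
  best <- NULL
  for (st in starts) {
    st <- pmax(st, lower + c(rep(1e-8, 4), 0))
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        M ~ A_L * b_L * aw / (1 + b_L * aw) + k_H * aw +
          n * k_H^n * k_a * aw^n,
        data = df,
        start = as.list(st),
        weights = w,
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 300))),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(w * (df$M - stats::fitted(fit))^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best)) {
    stop("Park fit failed to converge from any start", call. = FALSE)
  }

  cf <- stats::coef(best$fit)
  pars <- park_params(cf[["A_L"]], cf[["b_L"]], cf[["k_H"]],
                      cf[["k_a"]], max(cf[["n"]], 1))
  pred <- park_model(pars, df$aw)
  structure(list(
    params    = pars,
    mrd       = suppressWarnings(mrd(df$M, pred)),
    residuals = df$M - pred,
    fitted    = pred,
    sse       = best$sse,
    converged = best$fit$convInfo$isConv %||% TRUE,
    n_points  = nrow(df),
    data      = df
  ), class = "park_fit")
}

#' @export
print.park_fit <- function(x, ...) {
  cat(sprintf("Park model fit (%d points)\n", x$n_points))
  print(x$params)
  cat(sprintf("  MRD = %.3f%%  (below 10%% indicates a good fit)\n", x$mrd))
  cat(sprintf("  weighted SSE = %.4g  converged: %s\n", x$sse, x$converged))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Accept either a raw data frame or a sorption_isotherm.
as_isotherm_df <- function(x) {
  if (inherits(x, "sorption_isotherm")) {
    df <- data.frame(aw = x$aw, M = x$M)
  } else if (is.data.frame(x)) {
    if (!all(c("aw", "M") %in% names(x))) {
      stop("isotherm data frame needs columns 'aw' and 'M'", call. = FALSE)
    }
    df <- x[, c("aw", "M")]
  } else {
    stop("unsupported isotherm input", call. = FALSE)
  }
  df <- df[is.finite(df$aw) & is.finite(df$M), , drop = FALSE]
  df[order(df$aw), , drop = FALSE]
}
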
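# Assumption-gated one-way group comparisons with compact letter display.
#
# Decision tree: Shapiro-Wilk per group + Bartlett at alpha -> one-way
# ANOVA + Tukey HSD, otherwise Kruskal-Wallis + Tukey-type all-pairs rank
# comparisons (Nemenyi); letters from the adjusted pairwise matrix.

#' Grouped one-way measurements
#'
#' @param group Group labels (character or factor).
#' @param value Finite numeric measurements.
#' @return A `grouped_measurements` data frame.
#' @export
grouped_measurements <- function(group, value) {
  if (length(group) != length(value)) stop("length mismatch", call. = FALSE)
  if (any(!is.finite(value))) stop("values must be finite", call. = FALSE)
  g <- factor(group)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  structure(data.frame(group = g, value = value),
            class = c("grouped_measurements", "data.frame"))
}

#' Normality / homoscedasticity gate for the parametric path
#'
#' The parametric path (ANOVA + Tukey) is licensed only when every group
#' passes Shapiro-Wilk normality and the groups jointly pass Bartlett's
#' homogeneity-of-variance test, all at `alpha_gate`. Alternatively the
#' Shapiro test can be run once on pooled ANOVA residuals
#' (`shapiro = "residuals"`). A zero-variance group defeats both tests and
#' forces the nonparametric path with a warning.
#'
#' @param data A [grouped_measurements()] (or data frame with `group`,
#'   `value`), >= 3 observations per group.
#' @param alpha_gate Gate level (default 0.05).
#' @param shapiro `"per_group"` (default) or `"residuals"`.
#' @return List: `path` (`"parametric"` or `"nonparametric"`),
#'   `shapiro_p` (named vector, or scalar for residual mode), `bartlett_p`.
#' @export
assumption_gate <- function(data, alpha_gate = 0.05,
                            shapiro = c("per_group", "residuals")) {
  shapiro <- match.arg(shapiro)
  data <- as_grouped(data)
  sizes <- table(data$group)
  if (any(sizes < 3L)) {
    stop("each group needs >= 3 observations for the gate tests",
         call. = FALSE)
  }
  vars <- tapply(data$value, data$group, stats::var)
  if (any(vars == 0)) {
    warning("zero-variance group: forcing nonparametric path", call. = FALSE)
    return(list(path = "nonparametric",
                shapiro_p = NA_real_, bartlett_p = NA_real_))
  }
  sh_p <- if (shapiro == "per_group") {
    vapply(split(data$value, data$group),
           function(v) stats::shapiro.test(v)$p.value, numeric(1))
  } else {
    res <- stats::residuals(stats::aov(value ~ group, data = data))
    stats::shapiro.test(res)$p.value
  }
  ba_p <- stats::bartlett.test(value ~ group, data = data)$p.value
  path <- if (all(sh_p >= alpha_gate) && ba_p >= alpha_gate)
    "parametric" else "nonparametric"
  list(path = path, shapiro_p = sh_p, bartlett_p = ba_p)
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb algorithm: groups sharing at least one letter are not
#' significantly different (`p >= alpha`); groups sharing no letter differ
#' (`p < alpha`). Letter columns are processed in alphabetical group order
#' for determinism; absorption removes redundant columns. Minimal letter
#' count is not guaranteed, but consistency with the matrix is, and is
#' verified on every call.
#'
#' @param pairwise_p Symmetric numeric matrix of adjusted p-values with
#'   group names as dimnames; the diagonal is ignored.
#' @param alpha Significance level (default 0.05).
#' @return Named character vector of letter strings, one per group.
#' @export
letter_groups <- function(pairwise_p, alpha = 0.05) {
  p <- as.matrix(pairwise_p)
  if (nrow(p) != ncol(p) ||
      !isTRUE(all.equal(p, t(p), check.attributes = FALSE, tolerance = 1e-12))) {
    stop("pairwise p-value matrix must be symmetric", call. = FALSE)
  }
  g <- rownames(p) %||% paste0("G", seq_len(nrow(p)))
  ord <- order(g); p <- p[ord, ord, drop = FALSE]; g <- g[ord]
  k <- length(g)

  # columns = candidate letters, as logical membership vectors
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    if (is.na(p[i, j]) || p[i, j] >= alpha) next
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[i] && col[j]) {
        a <- col; a[i] <- FALSE
        b <- col; b[j] <- FALSE
        cols[[ci]] <- a
        cols[[length(cols) + 1L]] <- b
      }
    }
    # absorb: drop columns that are subsets of another
    keep <- rep(TRUE, length(cols))
    for (x in seq_along(cols)) for (y in seq_along(cols)) {
      if (x != y && keep[x] && keep[y] &&
          all(cols[[x]] <= cols[[y]]) && any(cols[[x]] < cols[[y]])) {
        keep[x] <- FALSE
      }
    }
    # drop exact duplicates
    sig <- vapply(cols, function(c) paste(as.integer(c), collapse = ""), "")
    keep <- keep & !duplicated(sig)
    cols <- cols[keep]
  }

  # order columns by first member, assign letters
  first <- vapply(cols, function(c) which(c)[1], integer(1))
  cols <- cols[order(first)]
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  lab <- vapply(seq_len(k), function(i) {
    paste(letters_pool[which(vapply(cols, `[`, logical(1), i))], collapse = "")
  }, "")
  names(lab) <- g
  verify_letters(lab, p, alpha)
  lab
}

# Exhaustive consistency check: share a letter <=> not significant.
verify_letters <- function(lab, p, alpha) {
  g <- names(lab)
  for (i in seq_along(g)[-length(g)]) for (j in seq.int(i + 1L, length(g))) {
    share <- length(intersect(strsplit(lab[i], "")[[1]],
                              strsplit(lab[j], "")[[1]])) > 0
    if (is.na(p[i, j])) next
    sig <- p[i, j] < alpha
    if (share == sig) {
      stop(sprintf("letter display inconsistent for %s vs %s (p = %.3g)",
                   g[i], g[j], p[i, j]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' One-way group comparison with automatic path selection
#'
#' Runs [assumption_gate()] (unless a path is forced), then either one-way
#' ANOVA with Tukey honestly-significant-difference pairwise comparisons,
#' or Kruskal-Wallis with Tukey-type all-pairs rank comparisons (Nemenyi
#' test: mean-rank differences from the joint ranking referred to the
#' studentized range, with tie correction) — a single-step procedure whose
#' family-wise error sits at the nominal level, mirroring the Tukey-type
#' relative-effect contrasts used for nonparametric multiple comparisons in
#' this field. Group letters are derived from the adjusted pairwise matrix
#' with [letter_groups()].
#'
#' @param data A [grouped_measurements()] or data frame with `group`,
#'   `value`.
#' @param alpha Significance level for letters (default 0.05).
#' @param path `"auto"` (gate decides), `"parametric"` or
#'   `"nonparametric"`.
#' @param alpha_gate Level of the gate tests (default 0.05).
#' @return A `comparison_result`: list with `path`, `omnibus_p`,
#'   `pairwise_p` (symmetric matrix), `letters`, `alpha`, `diagnostics`.
#' @export
compare_groups <- function(data, alpha = 0.05,
                           path = c("auto", "parametric", "nonparametric"),
                           alpha_gate = 0.05) {
  path <- match.arg(path)
  data <- as_grouped(data)
  diag <- NULL
  if (path == "auto") {
    diag <- assumption_gate(data, alpha_gate)
    path <- diag$path
  }
  lev <- levels(data$group)
  k <- length(lev)
  pmat <- matrix(NA_real_, k, k, dimnames = list(lev, lev))

  if (path == "parametric") {
    fit <- stats::aov(value ~ group, data = data)
    omnibus <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
    for (nm in rownames(tk)) {
      gg <- strsplit(nm, "-", fixed = TRUE)[[1]]
      pmat[gg[1], gg[2]] <- pmat[gg[2], gg[1]] <- tk[nm, "p adj"]
    }
  } else {
    omnibus <- stats::kruskal.test(value ~ group, data = data)$p.value
    pmat[] <- nemenyi_pairwise(data$value, data$group)
  }
  diag(pmat) <- 1
  structure(list(path = path, omnibus_p = omnibus, pairwise_p = pmat,
                 letters = letter_groups(pmat, alpha), alpha = alpha,
                 diagnostics = diag),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("One-way comparison (%s path), omnibus p = %.4g\n",
              x$path, x$omnibus_p))
  cat("Letters (alpha =", x$alpha, "):\n")
  print(x$letters)
  invisible(x)
}

# Tukey-type all-pairs rank comparison (Nemenyi): mean ranks of the joint
# ranking, studentized-range reference distribution, tie-corrected variance.
nemenyi_pairwise <- function(value, group) {
  g <- factor(group)
  k <- nlevels(g); N <- length(value)
  r <- rank(value)
  Rbar <- tapply(r, g, mean)
  n <- as.numeric(table(g))
  ties <- table(value)
  C <- sum(ties^3 - ties) / (N^3 - N)     # tie correction
  pmat <- matrix(NA_real_, k, k, dimnames = list(levels(g), levels(g)))
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    se <- sqrt(N * (N + 1) / 12 * (1 - C) * (1 / n[i] + 1 / n[j]))
    p <- if (se == 0) 1 else
      1 - stats::ptukey(abs(Rbar[i] - Rbar[j]) / se * sqrt(2), k, Inf)
    pmat[i, j] <- pmat[j, i] <- p
  }
  diag(pmat) <- 1
  pmat
}

#' Empirical family-wise error rate of a comparison path
#'
#' Draws `n_reps` null data sets (all groups standard normal), runs the
#' requested path, and reports the fraction of replicates in which any pair
#' is declared significant at `alpha` — an estimate of the family-wise
#' type-I error of the pairwise procedure.
#'
#' @param k Number of groups.
#' @param n Observations per group.
#' @param n_reps Replicates (>= 200).
#' @param seed RNG seed.
#' @param path `"parametric"` or `"nonparametric"`.
#' @param alpha Significance level (default 0.05).
#' @return List: `fwer`, `n_reps`, `se` (binomial standard error).
#' @export
type1_error_sim <- function(k, n, n_reps, seed,
                            path = c("parametric", "nonparametric"),
                            alpha = 0.05) {
  path <- match.arg(path)
  if (n_reps < 200L) stop("n_reps must be >= 200", call. = FALSE)
  set.seed(seed)
  lev <- LETTERS[seq_len(k)]
  hits <- 0L
  for (r in seq_len(n_reps)) {
    d <- grouped_measurements(rep(lev, each = n), stats::rnorm(k * n))
    res <- compare_groups(d, alpha = alpha, path = path)
    off <- res$pairwise_p[upper.tri(res$pairwise_p)]
    if (any(off < alpha, na.rm = TRUE)) hits <- hits + 1L
  }
  fwer <- hits / n_reps
  list(fwer = fwer, n_reps = n_reps,
       se = sqrt(alpha * (1 - alpha) / n_reps))
}

as_grouped <- function(data) {
  if (inherits(data, "grouped_measurements")) return(data)
  if (is.data.frame(data) && all(c("group", "value") %in% names(data))) {
    return(grouped_measurements(data$group, data$value))
  }
  stop("expected grouped measurements with columns 'group' and 'value'",
       call. = FALSE)
}
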
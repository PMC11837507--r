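# Passing-Bablok method-comparison regression: classical shifted-median and
# angle-median (equivariant) estimators, quantile-bootstrap CIs, and the
# CI-based constant/proportional difference interpretation.

# internal: point estimate (slope, intercept); x, y clean numeric, n >= 3
pb_estimate <- function(x, y, method) {
  n <- length(x)
  ij <- utils::combn(n, 2L)
  dx <- x[ij[2L, ]] - x[ij[1L, ]]
  dy <- y[ij[2L, ]] - y[ij[1L, ]]
  keep <- !(dx == 0 & dy == 0)           # identical points carry no information
  dx <- dx[keep]; dy <- dy[keep]
  if (length(dx) == 0L || all(dx == 0)) {
    stop("slope undefined: all x values identical")
  }
  if (method == "classical") {
    s <- dy[dx != 0] / dx[dx != 0]       # vertical pairs excluded (classical)
    s <- s[s != -1]                       # Passing-Bablok exclusion
    if (length(s) == 0L) stop("no admissible pairwise slopes")
    s <- sort(s)
    n_s <- length(s)
    k <- sum(s < -1)
    # shifted median; offset clamped (estimator assumes a predominantly
    # positive association, as in method comparison)
    slope <- if (n_s %% 2L == 1L) {
      s[min((n_s + 1L) %/% 2L + k, n_s)]
    } else {
      mean(s[c(min(n_s %/% 2L + k, n_s), min(n_s %/% 2L + 1L + k, n_s))])
    }
  } else {
    theta <- atan2(dy, dx) %% pi          # vertical pairs map to pi/2
    theta[theta > pi / 2] <- theta[theta > pi / 2] - pi
    slope <- tan(stats::median(theta))
  }
  intercept <- stats::median(y - slope * x)
  c(slope = slope, intercept = intercept)
}

#' Passing-Bablok method-comparison regression
#'
#' Nonparametric regression for comparing two measurement methods expected to
#' agree. Two estimators are available: the classical shifted-median of all
#' pairwise slopes, and an angle-median variant (the default) that is exactly
#' equivariant under exchange of the axes. Confidence intervals come from a
#' quantile bootstrap over paired observations; the CI-based interpretation
#' flags a proportional difference when the slope CI excludes 1 and a
#' constant difference when the intercept CI excludes 0 (closed intervals).
#'
#' @param x,y Paired measurements (e.g. lab and field values per genus);
#'   pairs with missing values are dropped.
#' @param method \code{"equivariant"} (angle median, default) or
#'   \code{"classical"} (Bablok shifted median; pairs with equal x excluded).
#' @param boot Number of bootstrap resamples for the CIs (default 1999);
#'   0 skips the bootstrap.
#' @param conf.level Confidence level (default 0.95).
#' @param seed Integer seed making the bootstrap reproducible.
#' @return An object of class \code{pb_fit}: slope, intercept, their CIs,
#'   \code{n}, Pearson's r, interpretation flags, and the data.
#' @examples
#' fit <- passing_bablok(c(1, 2, 3), c(2, 3, 5), boot = 0)
#' coef(fit)
#' @export
passing_bablok <- function(x, y, method = c("equivariant", "classical"),
                           boot = 1999, conf.level = 0.95, seed = NULL) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  est <- pb_estimate(x, y, method)
  fit <- list(
    slope = unname(est["slope"]),
    intercept = unname(est["intercept"]),
    slope_ci = c(NA_real_, NA_real_),
    intercept_ci = c(NA_real_, NA_real_),
    n = n,
    pearson_r = if (stats::sd(x) > 0 && stats::sd(y) > 0)
      stats::cor(x, y) else NA_real_,
    method = method,
    boot = boot,
    conf.level = conf.level,
    seed = seed,
    x = x, y = y,
    call = match.call()
  )
  if (boot > 0L) {
    if (n < 10L) warning("bootstrap CIs with n < 10 pairs are unreliable")
    if (!is.null(seed)) set.seed(seed)
    bs <- matrix(NA_real_, boot, 2L)
    attempts <- 0L
    b <- 1L
    while (b <= boot) {
      attempts <- attempts + 1L
      if (attempts > 10L * boot) {
        stop("too many degenerate bootstrap resamples (all x identical)")
      }
      idx <- sample.int(n, n, replace = TRUE)
      e <- tryCatch(pb_estimate(x[idx], y[idx], method),
                    error = function(e) NULL)
      if (is.null(e)) next                # degenerate resample: redraw
      bs[b, ] <- e
      b <- b + 1L
    }
    a <- (1 - conf.level) / 2
    fit$slope_ci <- unname(stats::quantile(bs[, 1L], c(a, 1 - a)))
    fit$intercept_ci <- unname(stats::quantile(bs[, 2L], c(a, 1 - a)))
    fit$boot_redraws <- attempts - boot
  }
  class(fit) <- "pb_fit"
  flags <- interpret_comparison(fit)
  fit$proportional_difference <- flags$proportional_difference
  fit$constant_difference <- flags$constant_difference
  fit
}

#' Interpret a Passing-Bablok fit
#'
#' @param fit A \code{pb_fit}, or a list with \code{slope_ci} and
#'   \code{intercept_ci} (each length-2, treated as closed intervals).
#' @return List of logical flags \code{proportional_difference} (slope CI
#'   excludes 1) and \code{constant_difference} (intercept CI excludes 0);
#'   \code{NA} when the CI is missing.
#' @export
interpret_comparison <- function(fit) {
  outside <- function(ci, v) {
    if (any(is.na(ci))) return(NA)
    !(ci[1L] <= v && v <= ci[2L])
  }
  list(proportional_difference = outside(fit$slope_ci, 1),
       constant_difference = outside(fit$intercept_ci, 0))
}

#' @export
print.pb_fit <- function(x, digits = 4, ...) {
  cat("Passing-Bablok regression (", x$method, " estimator), n = ", x$n,
      "\n", sep = "")
  fmt <- function(v) format(v, digits = digits)
  cat("  slope:     ", fmt(x$slope))
  if (!any(is.na(x$slope_ci))) {
    cat("  ", 100 * x$conf.level, "% CI [", fmt(x$slope_ci[1]), ", ",
        fmt(x$slope_ci[2]), "]", sep = "")
  }
  cat("\n  intercept: ", fmt(x$intercept))
  if (!any(is.na(x$intercept_ci))) {
    cat("  ", 100 * x$conf.level, "% CI [", fmt(x$intercept_ci[1]), ", ",
        fmt(x$intercept_ci[2]), "]", sep = "")
  }
  cat("\n  Pearson r: ", fmt(x$pearson_r), "\n")
  if (!is.na(x$proportional_difference)) {
    cat("  proportional difference (slope CI excludes 1): ",
        x$proportional_difference, "\n")
    cat("  constant difference (intercept CI excludes 0): ",
        x$constant_difference, "\n")
  }
  invisible(x)
}

#' @export
summary.pb_fit <- function(object, ...) {
  print(object, ...)
  invisible(object)
}

#' @export
coef.pb_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.pb_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else as.numeric(newdata)
  object$intercept + object$slope * x
}

#' @export
residuals.pb_fit <- function(object, ...) {
  object$y - predict(object)
}

#' @export
plot.pb_fit <- function(x, xlab = "method 1", ylab = "method 2", ...) {
  graphics::plot(x$x, x$y, xlab = xlab, ylab = ylab, ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  graphics::abline(x$intercept, x$slope, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Two-group test of replicate values (field vs lab)
#'
#' One-way fixed-effects ANOVA of two groups of replicate plot-level values
#' (equivalent to a pooled-variance t test squared). Significance tiers
#' follow the conventional ridgeline annotation: \code{"•"} at 0.10,
#' \code{"*"} at 0.05, \code{"**"} at 0.01, \code{"***"} at 0.001.
#'
#' @param values_a,values_b Replicate values per group; NAs dropped.
#' @return List with \code{statistic} (F), \code{p.value}, \code{tier}.
#' @export
genus_group_test <- function(values_a, values_b) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("need at least 2 non-missing values per group")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      f <- 0; p <- 1
    } else {
      f <- .Machine$double.xmax / 1e100   # complete separation, guarded
      p <- 0
    }
  } else {
    ft <- stats::oneway.test(v ~ g,
                             data = data.frame(v = c(a, b),
                                               g = rep(c("a", "b"),
                                                       c(length(a), length(b)))),
                             var.equal = TRUE)
    f <- unname(ft$statistic)
    p <- unname(ft$p.value)
  }
  list(statistic = f, p.value = p, tier = significance_tier(p))
}

#' Significance tier symbol for a p-value
#'
#' @param p Numeric p-value(s).
#' @return Character vector: \code{"***"} (p <= 0.001), \code{"**"} (0.01),
#'   \code{"*"} (0.05), \code{"•"} (0.10), otherwise \code{""}.
#' @export
significance_tier <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi <= 0.001) "***"
    else if (pi <= 0.01) "**"
    else if (pi <= 0.05) "*"
    else if (pi <= 0.10) "•"
    else ""
  }, character(1L))
}
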
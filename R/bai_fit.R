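# Candidate age-trajectory models, fitted per segment by least squares.
# Each entry returns list(fitted, par) or signals an error (excluded).
bai_models <- function() {
  gauss <- function(x, a, xo, s) a * exp(-(x - xo)^2 / (2 * s^2))
  list(
    linear = function(x, y) {
      f <- stats::lm(y ~ x)
      list(fitted = stats::fitted(f), par = stats::coef(f))
    },
    quadratic = function(x, y) {
      f <- stats::lm(y ~ x + I(x^2))
      list(fitted = stats::fitted(f), par = stats::coef(f))
    },
    quadratic_origin = function(x, y) {
      f <- stats::lm(y ~ 0 + x + I(x^2))
      list(fitted = stats::fitted(f), par = stats::coef(f))
    },
    log = function(x, y) {
      f <- stats::lm(y ~ log(x))
      list(fitted = stats::fitted(f), par = stats::coef(f))
    },
    exponential = function(x, y) {
      f <- minpack.lm::nlsLM(y ~ a * exp(b * x),
                             start = list(a = max(abs(y)), b = -0.01),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
      list(fitted = stats::fitted(f), par = stats::coef(f))
    },
    gaussian = function(x, y) {
      st <- list(a = max(y), xo = x[which.max(y)], s = diff(range(x)) / 2 + 1)
      f <- minpack.lm::nlsLM(y ~ a * exp(-(x - xo)^2 / (2 * s^2)), start = st,
                             lower = c(-Inf, -Inf, 1e-6),
                             control = minpack.lm::nls.lm.control(maxiter = 500))
      list(fitted = stats::fitted(f), par = stats::coef(f))
    },
    gaussian_centered = function(x, y) {
      f <- minpack.lm::nlsLM(y ~ a * exp(-x^2 / (2 * s^2)),
                             start = list(a = max(y), s = diff(range(x)) + 1),
                             lower = c(-Inf, 1e-6),
                             control = minpack.lm::nls.lm.control(maxiter = 500))
      list(fitted = stats::fitted(f), par = stats::coef(f))
    },
    gaussian_normalized = function(x, y) {
      st <- list(xo = x[which.max(y)], s = diff(range(x)) / 2 + 1)
      f <- minpack.lm::nlsLM(
        y ~ exp(-(x - xo)^2 / (2 * s^2)) / (s * sqrt(2 * pi)), start = st,
        lower = c(-Inf, 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 500))
      list(fitted = stats::fitted(f), par = stats::coef(f))
    },
    von_bertalanffy = function(x, y) {
      st <- list(a = max(y), b = 0.05, x0 = min(x) - 1)
      f <- minpack.lm::nlsLM(y ~ a * (1 - exp(-b * (x - x0))), start = st,
                             control = minpack.lm::nls.lm.control(maxiter = 500))
      list(fitted = stats::fitted(f), par = stats::coef(f))
    },
    von_bertalanffy_intercept = function(x, y) {
      st <- list(c0 = min(y), a = diff(range(y)), b = 0.05)
      f <- minpack.lm::nlsLM(y ~ c0 + a * (1 - exp(-b * x)), start = st,
                             control = minpack.lm::nls.lm.control(maxiter = 500))
      list(fitted = stats::fitted(f), par = stats::coef(f))
    }
  )
}

fit_segment <- function(x, y) {
  models <- bai_models()
  ss_tot <- sum((y - mean(y))^2)
  rows <- lapply(names(models), function(nm) {
    res <- tryCatch(models[[nm]](x, y), error = function(e) NULL)
    if (is.null(res)) return(NULL)
    r2 <- if (ss_tot > 0) 1 - sum((y - res$fitted)^2) / ss_tot else NA_real_
    list(model = nm, r2 = r2, par = res$par)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) stop("no candidate model converged on this segment")
  r2s <- vapply(rows, `[[`, 0, "r2")
  best <- rows[[which.max(r2s)]]
  gi <- which(vapply(rows, `[[`, "", "model") == "gaussian")
  gaussian <- if (length(gi)) rows[[gi]] else NULL
  list(best_model = best$model,
       r = sqrt(max(best$r2, 0)), r2 = best$r2,
       gaussian = if (!is.null(gaussian))
         list(a = unname(gaussian$par["a"]), sigma = unname(gaussian$par["s"]),
              xo = unname(gaussian$par["xo"]),
              r = sqrt(max(gaussian$r2, 0)), r2 = gaussian$r2) else NULL,
       candidates = data.frame(model = vapply(rows, `[[`, "", "model"),
                               r2 = r2s))
}

#' Two-segment age-trajectory fit of a brain age index
#'
#' Fits the candidate model family (linear, quadratic, quadratic through the
#' origin, log, exponential, Gaussian centered/non-centered and
#' area-normalized, von Bertalanffy with and without y-intercept) separately
#' to the ages at or below `split_age` and above it, selecting per segment by
#' the coefficient of determination. The three-parameter Gaussian
#' `y = a exp(-(x - xo)^2 / (2 sigma^2))` is always reported per segment and
#' is the curve used by `predict`.
#'
#' @param ages Ages in years.
#' @param values Index values (same length).
#' @param split_age Segment boundary in years (default 30).
#' @return A `bai_fit` object with per-segment model selection, Gaussian
#'   parameters and goodness of fit; supports `print`, `summary`, `coef`,
#'   `predict`, `plot` and `residuals`.
#' @export
fit_bai_curve <- function(ages, values, split_age = 30) {
  ok <- is.finite(ages) & is.finite(values)
  ages <- ages[ok]; values <- values[ok]
  lo <- ages <= split_age
  if (sum(lo) < 4 || sum(!lo) < 4)
    stop("need at least 4 points per segment")
  segs <- list(
    below = fit_segment(ages[lo], values[lo]),
    above = fit_segment(ages[!lo], values[!lo])
  )
  structure(list(segments = segs, split_age = split_age,
                 ages = ages, values = values),
            class = "bai_fit")
}

#' @export
print.bai_fit <- function(x, ...) {
  cat("Two-segment brain-age-index fit (split at", x$split_age, "years)\n")
  for (nm in names(x$segments)) {
    s <- x$segments[[nm]]
    g <- s$gaussian
    cat(sprintf("  %s %2.0f: best %-24s R = %.3f", nm, x$split_age, s$best_model, s$r))
    if (!is.null(g))
      cat(sprintf(" | Gaussian a = %.3g, sigma = %.3g, xo = %.3g (R = %.3f)",
                  g$a, g$sigma, g$xo, g$r))
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.bai_fit <- function(object, ...) {
  cat("Data:", length(object$ages), "subjects, ages",
      paste(round(range(object$ages), 1), collapse = "-"), "years\n")
  print(object)
  for (nm in names(object$segments)) {
    cat("\nCandidate models (", nm, " segment):\n", sep = "")
    cc <- object$segments[[nm]]$candidates
    print(cc[order(-cc$r2), ], row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.bai_fit <- function(object, ...) {
  do.call(rbind, lapply(object$segments, function(s) {
    g <- s$gaussian
    c(a = g$a %||% NA_real_, sigma = g$sigma %||% NA_real_, xo = g$xo %||% NA_real_)
  }))
}

#' @export
predict.bai_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$ages else
    if (is.list(newdata)) newdata$age else as.numeric(newdata)
  seg <- ifelse(x <= object$split_age, "below", "above")
  vapply(seq_along(x), function(i) {
    g <- object$segments[[seg[i]]]$gaussian
    if (is.null(g)) return(NA_real_)
    g$a * exp(-(x[i] - g$xo)^2 / (2 * g$sigma^2))
  }, numeric(1))
}

#' @export
residuals.bai_fit <- function(object, ...) {
  object$values - predict(object)
}

#' @export
plot.bai_fit <- function(x, ...) {
  graphics::plot(x$ages, x$values, xlab = "age (years)",
                 ylab = "brain age index", ...)
  xs <- seq(min(x$ages), max(x$ages), length.out = 200)
  graphics::lines(xs, predict(x, xs), col = 2, lwd = 2)
  graphics::abline(v = x$split_age, lty = 3)
  invisible(x)
}
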
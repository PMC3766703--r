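#' Construct a densitometry time course
#'
#' A quantified gel time course: per time point, the signal of the band of
#' interest and the total signal of its lane (both arbitrary units).
#'
#' @param times minutes, strictly increasing
#' @param band_signal band signal per time point, >= 0
#' @param lane_total total lane signal per time point, > 0; `band_signal`
#'   must not exceed it
#' @param label series label (e.g. `"wt"`, `"mutant+CPT"`)
#' @return a `TimeCourse`: data.frame with columns `time_min`, `band`,
#'   `lane_total` and attribute `"label"`
#' @export
time_course <- function(times, band_signal, lane_total, label = "") {
  if (length(times) != length(band_signal) ||
      length(times) != length(lane_total))
    stop("times, band_signal, lane_total must have equal length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(band_signal < 0)) stop("band_signal must be non-negative")
  if (any(lane_total <= 0)) stop("lane_total must be positive")
  if (any(band_signal > lane_total + 1e-9 * lane_total))
    stop("band_signal cannot exceed lane_total")
  structure(data.frame(time_min = as.numeric(times),
                       band = as.numeric(band_signal),
                       lane_total = as.numeric(lane_total)),
            class = c("TimeCourse", "data.frame"), label = label)
}

#' Read a time course from TSV
#'
#' Expects columns `time_min`, `band`, `lane_total` and optionally `label`
#' (constant per file).
#'
#' @param path TSV path
#' @return a [time_course()]
#' @export
read_timecourse_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("time_min", "band", "lane_total")
  if (!all(need %in% names(df)))
    stop("TSV must contain columns: ", paste(need, collapse = ", "))
  label <- if ("label" %in% names(df)) as.character(df$label[1]) else ""
  time_course(df$time_min, df$band, df$lane_total, label = label)
}

#' Write a time course to TSV
#' @param tc a [time_course()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_timecourse_tsv <- function(tc, path) {
  stopifnot(inherits(tc, "TimeCourse"))
  df <- as.data.frame(tc)
  df$label <- attr(tc, "label")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Percentage of lane signal in the band of interest
#'
#' The primary gel normalisation: each time point's band signal divided by
#' the total signal of its lane, as percent.
#'
#' @param tc a [time_course()]
#' @return numeric vector of percentages in `[0, 100]`
#' @export
lane_fraction <- function(tc) {
  stopifnot(inherits(tc, "TimeCourse"))
  zero <- which(tc$lane_total == 0)
  if (length(zero) > 0)
    stop("zero lane total at time point index ", zero[1])
  100 * tc$band / tc$lane_total
}

#' Normalise a series to the maximum of a reference series
#'
#' The cross-condition normalisation used when comparing a variant to the
#' wild type: both series are expressed as percent of the wild-type maximum,
#' so a variant reaching half the reference plateau plateaus at 50.
#'
#' @param series numeric vector
#' @param reference_series numeric vector whose maximum defines 100
#' @return numeric vector, percent of the reference maximum
#' @export
normalize_to_reference_max <- function(series, reference_series) {
  m <- max(reference_series)
  if (!is.finite(m) || m <= 0)
    stop("reference series maximum must be positive")
  100 * series / m
}

#' Normalise a series to its value at the first time point
#'
#' Percent-remaining normalisation for decay experiments: the first element
#' becomes exactly 100.
#'
#' @param series numeric vector; first element must be positive
#' @return numeric vector, percent of the t = 0 value
#' @export
normalize_to_t0 <- function(series) {
  if (!is.finite(series[1]) || series[1] <= 0)
    stop("value at the first time point must be positive")
  100 * series / series[1]
}

#' Fit first-order kinetics to a normalised percentage series
#'
#' Least-squares fit of a single-exponential model:
#' \describe{
#'   \item{`cleavage_rise`}{`y = plateau * (1 - exp(-k t))`, for cleaved
#'     product accumulating towards a plateau.}
#'   \item{`religation_decay`}{`y = offset + A * exp(-k t)`, for a
#'     percent-remaining series (normalised to t = 0, see
#'     [normalize_to_t0()]); the floating offset, bounded in \[0, 50\],
#'     absorbs a non-religatable fraction, and the free amplitude `A` absorbs
#'     the common scale error introduced by dividing by the noisy t = 0
#'     observation (pinning the amplitude at `100 - offset` transmits that
#'     error straight into the rate).}
#' }
#' Both models are scale-equivariant: multiplying the signal by a positive
#' constant leaves `k` unchanged. Because densitometry noise is
#' multiplicative (constant coefficient of variation), fitting is weighted
#' least squares with weights inversely proportional to the squared signal:
#' an unweighted Levenberg-Marquardt pass (restarted from a grid of initial
#' rates) provides fitted values, and one reweighted pass with
#' `w = 1/max(fitted, 1)^2` gives the final estimate. The rate confidence
#' interval comes from proportional (relative) residual resampling, matching
#' the same error structure.
#'
#' @param times minutes, strictly increasing
#' @param percent normalised percentage series, same length, >= 4 points
#' @param model `"cleavage_rise"` or `"religation_decay"`
#' @param n_boot bootstrap draws for the rate CI (default 1000)
#' @param seed RNG seed for the bootstrap
#' @param conf_level CI level (default 0.95)
#' @return a `RateFit`: list with `model`, `k` (per minute), `plateau`
#'   (fitted plateau for the rise model, fitted offset for decay),
#'   `amplitude` (the exponential amplitude), `rss`, `k_ci` (two-sided
#'   percentile interval), `k_boot` (the bootstrap draws) and `fitted`
#' @export
fit_first_order <- function(times, percent,
                            model = c("cleavage_rise", "religation_decay"),
                            n_boot = 1000L, seed = 1L, conf_level = 0.95) {
  model <- match.arg(model)
  times <- as.numeric(times); percent <- as.numeric(percent)
  if (length(times) != length(percent))
    stop("times and percent must have equal length")
  if (length(times) < 4) stop("at least 4 time points are required")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")

  fit1 <- function(y) fit_exp_once(times, y, model)
  base <- fit1(percent)
  if (is.null(base))
    stop("first-order fit failed to converge from all ",
         "initial-rate restarts (model ", model, "); check that the series ",
         "is a ", ifelse(model == "cleavage_rise", "rising", "decaying"),
         " percentage course")

  k_boot <- numeric(0)
  if (n_boot > 0) {
    set.seed(seed)
    rel_resid <- (percent - base$fitted) / pmax(abs(base$fitted), 1e-6)
    k_boot <- vapply(seq_len(n_boot), function(b) {
      yb <- base$fitted * (1 + sample(rel_resid, replace = TRUE))
      fb <- fit_exp_once(times, yb, model, init = base$coefficients)
      if (is.null(fb)) fb <- fit1(yb)  # fall back to the full restart grid
      if (is.null(fb)) NA_real_ else fb$k
    }, numeric(1))
    k_boot <- k_boot[is.finite(k_boot)]
  }
  alpha <- 1 - conf_level
  k_ci <- if (length(k_boot) > 0) {
    as.numeric(stats::quantile(k_boot, c(alpha / 2, 1 - alpha / 2)))
  } else c(NA_real_, NA_real_)
  structure(list(model = model, k = base$k, plateau = base$plateau,
                 amplitude = base$amplitude,
                 rss = base$rss, k_ci = k_ci, k_boot = k_boot,
                 fitted = base$fitted, times = times, percent = percent,
                 conf_level = conf_level),
            class = "RateFit")
}

# Weighted Levenberg-Marquardt fit: an unweighted pass provides fitted
# values, one reweighted pass with w = 1/max(fitted, 1)^2 (the multiplicative
# error model) gives the estimate. Starts either from `init` (warm start, for
# bootstrap refits) or from a grid of initial rates; returns NULL when no
# start converges.
fit_exp_once <- function(times, y, model, init = NULL) {
  one_fit <- function(start, weights = NULL) {
    args <- if (model == "cleavage_rise") {
      list(y ~ plateau * (1 - exp(-k * t)),
           data = list(y = y, t = times), start = start,
           lower = c(plateau = 1e-9, k = 1e-9),
           control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      list(y ~ offset + A * exp(-k * t),
           data = list(y = y, t = times), start = start,
           lower = c(offset = 0, A = 1e-9, k = 1e-9),
           upper = c(offset = 50, A = Inf, k = Inf),
           control = minpack.lm::nls.lm.control(maxiter = 200))
    }
    if (!is.null(weights)) args$weights <- weights
    fit <- try(do.call(minpack.lm::nlsLM, args), silent = TRUE)
    if (inherits(fit, "try-error")) NULL else fit
  }
  starts <- if (!is.null(init)) {
    list(as.list(init))
  } else {
    lapply(c(0.02, 0.05, 0.15, 0.4, 1, 3), function(k0) {
      if (model == "cleavage_rise") {
        list(plateau = max(max(y), 1e-3), k = k0)
      } else {
        list(offset = max(min(y), 0), A = max(y[1] - min(y), 1e-3), k = k0)
      }
    })
  }
  best <- NULL
  for (start in starts) {
    pass1 <- one_fit(start)
    if (is.null(pass1)) next
    w <- 1 / pmax(as.numeric(stats::fitted(pass1)), 1)^2
    fit <- one_fit(as.list(stats::coef(pass1)), weights = w)
    if (is.null(fit)) fit <- pass1
    fitted_y <- as.numeric(stats::fitted(fit))
    wrss <- sum((y - fitted_y)^2 / pmax(fitted_y, 1)^2)
    if (is.null(best) || wrss < best$wrss - 1e-12) {
      cf <- stats::coef(fit)
      best <- list(k = unname(cf[["k"]]),
                   plateau = unname(cf[[if (model == "cleavage_rise")
                     "plateau" else "offset"]]),
                   amplitude = if (model == "cleavage_rise")
                     unname(cf[["plateau"]]) else unname(cf[["A"]]),
                   coefficients = cf,
                   rss = sum((y - fitted_y)^2), wrss = wrss,
                   fitted = fitted_y)
    }
  }
  best
}

#' @export
print.RateFit <- function(x, ...) {
  cat(sprintf("First-order %s fit: k = %.4g /min (%.0f%% CI %.4g-%.4g), %s = %.3g, RSS = %.3g\n",
              x$model, x$k, 100 * x$conf_level, x$k_ci[1], x$k_ci[2],
              ifelse(x$model == "cleavage_rise", "plateau", "offset"),
              x$plateau, x$rss))
  invisible(x)
}

#' Crude initial-rate estimate from the early time points
#'
#' Slope-based alternative to the exponential fit: a straight line through
#' the first `n_points` observations estimates `dy/dt` at t = 0, which equals
#' `k * plateau` for the rise model and `-k * (100 - offset)` (about
#' `-100 k`) for a percent-remaining decay. Reported alongside the full-curve
#' fit when the two could disagree (e.g. multiphasic data).
#'
#' @param times minutes
#' @param percent normalised percentage series
#' @param model `"cleavage_rise"` or `"religation_decay"`
#' @param n_points number of early points for the slope (default 4)
#' @return list with `slope` (percent/min) and `k_approx` (per minute)
#' @export
initial_rate <- function(times, percent,
                         model = c("cleavage_rise", "religation_decay"),
                         n_points = 4L) {
  model <- match.arg(model)
  n_points <- min(max(n_points, 2L), length(times))
  i <- seq_len(n_points)
  sl <- unname(stats::coef(stats::lm(percent[i] ~ times[i]))[2])
  k_approx <- if (model == "cleavage_rise") {
    sl / max(percent)
  } else {
    -sl / percent[1]
  }
  list(slope = sl, k_approx = k_approx)
}

#' Ratio of two fitted rates with a paired bootstrap interval
#'
#' Compares two [fit_first_order()] results of the same model: the point
#' estimate is `k_a / k_b`; the interval pairs the two fits' bootstrap draws
#' index-by-index and takes percentile bounds of the ratio.
#'
#' @param fit_a,fit_b `RateFit` objects with the same `model`
#' @param conf_level CI level (default 0.95)
#' @return list with `ratio`, `ci` (two-sided percentile interval) and
#'   `n_pairs` (bootstrap pairs used)
#' @export
rate_ratio <- function(fit_a, fit_b, conf_level = 0.95) {
  stopifnot(inherits(fit_a, "RateFit"), inherits(fit_b, "RateFit"))
  if (fit_a$model != fit_b$model)
    stop("cannot compare fits of different models (",
         fit_a$model, " vs ", fit_b$model, ")")
  n <- min(length(fit_a$k_boot), length(fit_b$k_boot))
  alpha <- 1 - conf_level
  ci <- if (n > 0) {
    r <- fit_a$k_boot[seq_len(n)] / fit_b$k_boot[seq_len(n)]
    as.numeric(stats::quantile(r, c(alpha / 2, 1 - alpha / 2)))
  } else c(NA_real_, NA_real_)
  list(ratio = fit_a$k / fit_b$k, ci = ci, n_pairs = n)
}
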
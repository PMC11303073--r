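#' @importFrom stats lm pt coef
NULL

#' Mean and standard deviation under an explicit divisor convention
#'
#' "mean +/- std" aggregates in study tables conventionally use the
#' population (N) divisor; t-tests from summary rows use the sample (N-1)
#' divisor. The convention is always an explicit flag here.
#'
#' @param values Non-empty numeric vector.
#' @param convention `"population"` (divide by N) or `"sample"` (N-1).
#' @return A `summary_stat`: list with `mean`, `std`, `n`,
#'   `divisor_convention`.
#' @export
summarize_values <- function(values,
                             convention = c("population", "sample")) {
  convention <- match.arg(convention)
  if (length(values) == 0) stop("empty value list")
  n <- length(values)
  m <- mean(values)
  std <- if (convention == "population") {
    sqrt(sum((values - m)^2) / n)
  } else {
    if (n < 2) stop("sample convention needs n >= 2")
    sd(values)
  }
  structure(list(mean = m, std = std, n = n,
                 divisor_convention = convention),
            class = "summary_stat")
}

#' @export
print.summary_stat <- function(x, digits = 1, ...) {
  cat(sprintf("%s +/- %s (n = %d, %s divisor)\n",
              format(round(x$mean, digits)), format(round(x$std, digits)),
              x$n, x$divisor_convention))
  invisible(x)
}

#' Simple linear regression with R-squared and p-value
#'
#' Ordinary least squares of `y` on `x`; `r_squared = 1 - SS_res / SS_tot`;
#' the p-value is the two-sided F-test on the slope (equal to the slope
#' t-test for simple regression).
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`.
#' @return A `regression_result`: list with `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`.
#' @export
linreg <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need n >= 3")
  if (sd(x) == 0) stop("zero variance in x")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  p <- if (sm$sigma == 0) 0 else {
    fs <- sm$fstatistic
    unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
  }
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared, p_value = p,
                 n = length(x)),
            class = "regression_result")
}

#' Paired t-test from printed summary statistics
#'
#' Recomputes `t = mean_diff / (std_diff / sqrt(n))` with `df = n - 1` and a
#' two-sided p-value, as used for table rows reporting "mean +/- std" of
#' paired differences under the sample (N-1) convention.
#'
#' @param mean_diff Mean of the paired differences.
#' @param std_diff Sample standard deviation of the differences (> 0).
#' @param n Number of pairs (>= 2).
#' @return List with `t`, `p` (two-sided), `df`.
#' @export
paired_t_from_summary <- function(mean_diff, std_diff, n) {
  if (n < 2) stop("need n >= 2")
  if (std_diff <= 0) stop("std_diff must be > 0")
  t <- mean_diff / (std_diff / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1), df = n - 1)
}

#' Subject-motion metrics from a tracked focus trace
#'
#' MAD is the mean Euclidean distance of the tracked positions from their
#' centroid; the maximum excursion is the largest Euclidean distance from
#' the initial position.
#'
#' @param trace Matrix (n x 3) of focus positions over time, world mm.
#' @return A `motion_trace`: list with `mad`, `max_excursion` (mm), `n`.
#' @export
motion_metrics <- function(trace) {
  trace <- rbind(trace)
  stopifnot(ncol(trace) == 3)
  n <- nrow(trace)
  if (n < 1) stop("empty trace")
  if (n == 1)
    return(structure(list(mad = 0, max_excursion = 0, n = 1L),
                     class = "motion_trace"))
  cen <- colMeans(trace)
  mad_mm <- mean(sqrt(rowSums(sweep(trace, 2, cen)^2)))
  max_mm <- max(sqrt(rowSums(sweep(trace, 2, trace[1, ])^2)))
  structure(list(mad = mad_mm, max_excursion = max_mm, n = n),
            class = "motion_trace")
}

#' Distance and angle error between planned and treated trajectories
#'
#' @param planned,treated [trajectory()]s; directions are normalized with a
#'   warning if needed.
#' @return A `positioning_error`: list with `distance_error` (mm, Euclidean
#'   distance between target points) and `angle_error` (degrees, in
#'   `[0, 180]`).
#' @export
trajectory_error <- function(planned, treated) {
  stopifnot(inherits(planned, "trajectory"), inherits(treated, "trajectory"))
  unitize <- function(v) {
    nv <- sqrt(sum(v^2))
    if (abs(nv - 1) > 1e-8) {
      warning("non-unit trajectory direction; normalizing")
      v <- v / nv
    }
    v
  }
  d1 <- unitize(planned$direction)
  d2 <- unitize(treated$direction)
  ang <- acos(pmin(pmax(sum(d1 * d2), -1), 1)) * 180 / pi
  structure(list(
    distance_error = sqrt(sum((planned$focus_point - treated$focus_point)^2)),
    angle_error = ang
  ), class = "positioning_error")
}
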
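#' Total variation of a steady-state history
#'
#' CV_T = 100 * sd / mean, the coefficient of variation of an individual's
#' steady-state results. It combines the person's within-person biological
#' variation (CV_P) with the analytical variation (CV_A).
#'
#' @param mean Mean of the steady-state results; must be positive.
#' @param sd Standard deviation of the steady-state results.
#' @return Total variation in percent.
#' @examples
#' cv_total(0.420, 0.020)  # 4.76
#' @export
cv_total <- function(mean, sd) {
  if (any(!is.finite(mean)) || any(mean <= 0))
    stop("CV is undefined for non-positive mean", call. = FALSE)
  if (any(!is.finite(sd)) || any(sd < 0))
    stop("sd must be >= 0", call. = FALSE)
  100 * sd / mean
}

#' Within-person biological variation from total and analytical variation
#'
#' Removes the analytical component from the total variation of a
#' steady-state history: CV_P = sqrt(CV_T^2 - CV_A^2). When the analytical
#' variation exceeds the observed total variation the difference is
#' negative by sampling noise; CV_P is then reported as 0 with a warning.
#'
#' @param cv_t Total variation, percent.
#' @param cv_a Analytical variation, percent.
#' @return Within-person variation CV_P in percent.
#' @examples
#' cv_within_person(5, 3)  # 4
#' @export
cv_within_person <- function(cv_t, cv_a) {
  stopifnot(cv_t >= 0, cv_a >= 0)
  d <- cv_t^2 - cv_a^2
  if (any(d < 0)) {
    warning("cv_a exceeds cv_t; CV_P set to 0", call. = FALSE)
    d <- pmax(d, 0)
  }
  sqrt(d)
}

#' Two-sided standard-normal quantile for a coverage probability
#'
#' Full-precision z used in all population-route computations; the familiar
#' 1.96 is its 95% value rounded to two decimals.
#'
#' @param coverage Two-sided coverage probability in (0, 1).
#' @return The quantile z such that the central normal probability mass
#'   between -z and z equals `coverage`.
#' @examples
#' quantile_z(0.95)  # 1.959964
#' @export
quantile_z <- function(coverage = 0.95) {
  if (any(coverage <= 0) || any(coverage >= 1))
    stop("coverage must be in (0, 1)", call. = FALSE)
  stats::qnorm((1 + coverage) / 2)
}

#' Two-sided Student-t quantile for a coverage probability
#'
#' @param coverage Two-sided coverage probability in (0, 1).
#' @param df Degrees of freedom (n - 1 for an n-point history); must be
#'   at least 1.
#' @return The t-table value at the given coverage and df.
#' @examples
#' quantile_t(0.95, 2)  # 4.302653
#' @export
quantile_t <- function(coverage = 0.95, df) {
  if (any(coverage <= 0) || any(coverage >= 1))
    stop("coverage must be in (0, 1)", call. = FALSE)
  if (any(df < 1)) stop("df must be >= 1", call. = FALSE)
  stats::qt((1 + coverage) / 2, df = df)
}

# Internal constructor for reference_interval objects. Unrounded limits are
# always kept; round_interval() adds a display-rounded copy.
new_reference_interval <- function(lower, upper, method, quantile,
                                   small_n_factor, hsp = NA_real_,
                                   clamped = FALSE, degenerate = FALSE) {
  structure(
    list(lower = lower, upper = upper, method = method,
         coverage_z_or_t = quantile, small_n_factor = small_n_factor,
         hsp = hsp, clamped = clamped, degenerate = degenerate),
    class = "reference_interval")
}

#' @export
print.reference_interval <- function(x, ...) {
  cat(sprintf("%s: %.6g ~ %.6g", x$method, x$lower, x$upper))
  if (!is.null(x$rounded))
    cat(sprintf("  (display: %s ~ %s)", format(x$rounded[1]),
                format(x$rounded[2])))
  cat("\n")
  if (isTRUE(x$clamped)) cat("  note: lower limit clamped at 0\n")
  if (isTRUE(x$degenerate)) cat("  note: degenerate (zero-width) interval\n")
  invisible(x)
}

#' Personalized reference interval from population biological variation
#'
#' The prRI_pop route: the interval around the patient's homeostatic set
#' point expected to contain steady-state results at the stated coverage,
#' using the population within-subject variation CV_I together with the
#' laboratory's analytical variation CV_A, a normal quantile, and the
#' small-sample factor sqrt(1 + 1/n) that accounts for the uncertainty of
#' an HSP estimated from n results:
#'
#' limits = HSP +/- z * HSP * sqrt(CV_I^2 + CV_A^2)/100 * sqrt(1 + 1/n)
#'
#' @param hsp An [hsp_estimate()].
#' @param profile A [bv_profile()] providing CV_I and CV_A.
#' @param coverage Two-sided coverage probability; default 0.95.
#' @param clamp If `TRUE`, a negative lower limit is clamped at 0 and the
#'   result is marked as clamped. Default `FALSE`: limits are reported as
#'   computed.
#' @return A `reference_interval` with method `"prRI_pop"`.
#' @examples
#' ery <- bv_profile("erythrocytes", "x 10^12/L", cv_i = 2.80, cv_a = 0.67)
#' prri_pop(hsp_estimate(4.45, 0.17, 3), ery)  # 4.16 ~ 4.74 at 2 dp
#' @export
prri_pop <- function(hsp, profile, coverage = 0.95, clamp = FALSE) {
  stopifnot(inherits(hsp, "hsp_estimate"), inherits(profile, "bv_profile"))
  if (hsp$mean <= 0) stop("HSP mean must be > 0", call. = FALSE)
  z <- quantile_z(coverage)
  f <- sqrt(1 + 1 / hsp$n)
  tv <- z * hsp$mean * sqrt(profile$cv_i^2 + profile$cv_a^2) / 100 * f
  finalize_interval(hsp$mean - tv, hsp$mean + tv, "prRI_pop", z, f,
                    hsp$mean, clamp)
}

#' Personalized reference interval from the individual's own variation
#'
#' The prRI_ind route: uses the total variation CV_T estimated from the
#' patient's own steady-state history, with a Student-t quantile at n - 1
#' degrees of freedom and the same small-sample factor:
#'
#' limits = HSP +/- t(coverage, n-1) * HSP * CV_T/100 * sqrt(1 + 1/n)
#'
#' With short histories (n = 3, df = 2) the t quantile is large and the
#' interval can be much wider than the population reference interval.
#' A negative computed lower limit is reported as-is by default even though
#' concentrations cannot be negative, so that the arithmetic stays
#' transparent; use `clamp = TRUE` to truncate at 0.
#'
#' @inheritParams prri_pop
#' @return A `reference_interval` with method `"prRI_ind"`. A zero CV_T
#'   collapses the interval to a point and marks it degenerate with a
#'   warning.
#' @examples
#' hgb <- hsp_estimate(141, 5, 3, cv_t = 3.36)
#' prri_ind(hgb, bv_profile("hemoglobin", "g/L", cv_i = 2.70, cv_a = 0.25))
#' @export
prri_ind <- function(hsp, profile = NULL, coverage = 0.95, clamp = FALSE) {
  stopifnot(inherits(hsp, "hsp_estimate"))
  if (hsp$n < 2L) stop("prRI_ind requires n >= 2 (df = n - 1)", call. = FALSE)
  if (hsp$mean <= 0) stop("HSP mean must be > 0", call. = FALSE)
  tq <- quantile_t(coverage, df = hsp$n - 1L)
  f <- sqrt(1 + 1 / hsp$n)
  tv <- tq * hsp$mean * hsp$cv_t / 100 * f
  out <- finalize_interval(hsp$mean - tv, hsp$mean + tv, "prRI_ind", tq, f,
                           hsp$mean, clamp)
  if (hsp$cv_t == 0) {
    out$degenerate <- TRUE
    warning("CV_T is 0: degenerate prRI_ind; method not applicable",
            call. = FALSE)
  }
  out
}

finalize_interval <- function(lower, upper, method, q, f, hsp, clamp) {
  clamped <- FALSE
  if (clamp && lower < 0) {
    lower <- 0
    clamped <- TRUE
  }
  new_reference_interval(lower, upper, method, q, f, hsp, clamped,
                         degenerate = (lower == upper))
}

#' Population reference interval as a reference_interval object
#'
#' Wraps the popRI limits of a profile so they can be used interchangeably
#' with computed prRIs in flagging.
#'
#' @param profile A [bv_profile()] with popRI limits.
#' @return A `reference_interval` with method `"popRI"`.
#' @export
pop_ri <- function(profile) {
  stopifnot(inherits(profile, "bv_profile"))
  if (is.na(profile$pop_ri_lower) || is.na(profile$pop_ri_upper))
    stop("profile has no popRI limits", call. = FALSE)
  new_reference_interval(profile$pop_ri_lower, profile$pop_ri_upper,
                         "popRI", NA_real_, NA_real_)
}

#' Reference change value from population biological variation
#'
#' RCV_pop = z * sqrt(2) * sqrt(CV_I^2 + CV_A^2): the smallest percent
#' difference between two consecutive results that exceeds combined
#' analytical and within-subject biological noise at the stated coverage.
#'
#' @param profile A [bv_profile()] providing CV_I and CV_A.
#' @param coverage Two-sided coverage probability; default 0.95.
#' @return An `rcv_estimate` with basis `"pop"`.
#' @examples
#' rcv_pop(bv_profile("leukocytes", "x 10^9/L", cv_i = 11.10, cv_a = 1.26))
#' @export
rcv_pop <- function(profile, coverage = 0.95) {
  stopifnot(inherits(profile, "bv_profile"))
  z <- quantile_z(coverage)
  new_rcv(z * sqrt(2) * sqrt(profile$cv_i^2 + profile$cv_a^2), "pop", z)
}

#' Reference change value from the individual's total variation
#'
#' RCV_ind = z * sqrt(2) * CV_T. CV_T already contains the analytical
#' component, so no further CV_A term is added.
#'
#' @param hsp An [hsp_estimate()] carrying CV_T.
#' @param coverage Two-sided coverage probability; default 0.95.
#' @return An `rcv_estimate` with basis `"ind"`. A zero CV_T yields a 0%
#'   threshold flagged not-applicable with a warning.
#' @examples
#' rcv_ind(hsp_estimate(4.8, 0.5, 3, cv_t = 9.45))
#' @export
rcv_ind <- function(hsp, coverage = 0.95) {
  stopifnot(inherits(hsp, "hsp_estimate"))
  z <- quantile_z(coverage)
  out <- new_rcv(z * sqrt(2) * hsp$cv_t, "ind", z)
  if (hsp$cv_t == 0) {
    out$not_applicable <- TRUE
    warning("CV_T is 0: RCV_ind is 0% and not applicable", call. = FALSE)
  }
  out
}

new_rcv <- function(threshold, basis, z) {
  structure(list(threshold = threshold, basis = basis, quantile = z,
                 not_applicable = FALSE),
            class = "rcv_estimate")
}

#' @export
print.rcv_estimate <- function(x, ...) {
  cat(sprintf("RCV_%s: %.2f%%%s\n", x$basis, x$threshold,
              if (isTRUE(x$not_applicable)) " (not applicable)" else ""))
  invisible(x)
}

#' Index of individuality
#'
#' II = CV_I / CV_G. Measurands with low II (below about 0.6) have
#' individual set points tightly clustered relative to the population
#' spread, so population reference intervals are insensitive for monitoring
#' an individual. The `noise_adjusted` variant folds the analytical
#' variation into the numerator: sqrt(CV_I^2 + CV_A^2) / CV_G.
#'
#' @param profile A [bv_profile()] with a positive CV_G.
#' @param variant `"simple"` (default, CV_I / CV_G) or `"noise_adjusted"`.
#' @return The index of individuality (unitless).
#' @examples
#' index_of_individuality(bv_profile("x", cv_i = 10, cv_g = 20, cv_a = 1))
#' @export
index_of_individuality <- function(profile,
                                   variant = c("simple", "noise_adjusted")) {
  stopifnot(inherits(profile, "bv_profile"))
  variant <- match.arg(variant)
  if (is.na(profile$cv_g) || profile$cv_g <= 0)
    stop("index of individuality requires CV_G > 0", call. = FALSE)
  switch(variant,
         simple = profile$cv_i / profile$cv_g,
         noise_adjusted = sqrt(profile$cv_i^2 + profile$cv_a^2) / profile$cv_g)
}

#' Applicability checks for personalized reference intervals
#'
#' Applies the accepted suitability rules before recommending a prRI route:
#' the analytical variation should not exceed half the within-subject
#' variation (CV_A <= 0.5 CV_I), measurands with CV_I > 30% are considered
#' unsuitable for prRI calculation, and the individual route needs at least
#' 5 steady-state results. With fewer results the population route is
#' recommended; when the analytical noise rule fails, RCV-based delta
#' checking is the more suitable alternative.
#'
#' @param profile A [bv_profile()].
#' @param hsp An [hsp_estimate()].
#' @return An `applicability_verdict` with fields `ratio_cv_a_cv_i`,
#'   `cv_i_ok`, `cv_a_ok`, `n_ok`, `recommended_route` (one of
#'   `"individual"`, `"population"`, `"rcv_only"`, `"none"`) and `messages`.
#' @examples
#' p <- bv_profile("leukocytes", cv_i = 11.10, cv_a = 1.26, cv_g = 17.1)
#' check_applicability(p, hsp_estimate(4.8, 0.5, 3))
#' @export
check_applicability <- function(profile, hsp) {
  stopifnot(inherits(profile, "bv_profile"), inherits(hsp, "hsp_estimate"))
  ratio <- if (profile$cv_i > 0) profile$cv_a / profile$cv_i else Inf
  cv_a_ok <- profile$cv_a <= 0.5 * profile$cv_i
  cv_i_ok <- profile$cv_i <= 30
  n_ok <- hsp$n >= 5L
  msgs <- character()
  if (!cv_i_ok)
    msgs <- c(msgs, sprintf(
      "CV_I = %.2f%% exceeds 30%%: measurand unsuitable for prRIs",
      profile$cv_i))
  if (!cv_a_ok)
    msgs <- c(msgs, sprintf(
      "CV_A = %.2f%% exceeds half of CV_I = %.2f%%: RCVs are a more suitable alternative",
      profile$cv_a, profile$cv_i))
  if (!n_ok)
    msgs <- c(msgs, sprintf(
      "only %d steady-state results (at least 5 recommended): population route preferred over individual",
      hsp$n))
  route <- if (!cv_i_ok) "none"
  else if (!cv_a_ok) "rcv_only"
  else if (!n_ok) "population"
  else "individual"
  if (length(msgs) == 0L)
    msgs <- "all applicability checks passed; individual route usable"
  structure(list(ratio_cv_a_cv_i = ratio, cv_i_ok = cv_i_ok,
                 cv_a_ok = cv_a_ok, n_ok = n_ok,
                 recommended_route = route, messages = msgs),
            class = "applicability_verdict")
}

#' @export
print.applicability_verdict <- function(x, ...) {
  cat(sprintf("Recommended route: %s\n", x$recommended_route))
  for (m in x$messages) cat("  - ", m, "\n", sep = "")
  invisible(x)
}

#' Round interval limits for display
#'
#' Applies half-up (half away from zero) rounding at the measurand's display
#' decimals, the convention used on printed laboratory reports. `round()`'s
#' round-half-to-even rule is deliberately not used. The unrounded limits
#' are preserved in the returned object.
#'
#' @param interval A `reference_interval`.
#' @param decimals Non-negative number of decimals.
#' @return The interval with a `rounded` field of length 2 (lower, upper).
#' @examples
#' iv <- prri_pop(hsp_estimate(4.45, 0.17, 3),
#'                bv_profile("erythrocytes", cv_i = 2.80, cv_a = 0.67))
#' round_interval(iv, 2)$rounded  # c(4.16, 4.74)
#' @export
round_interval <- function(interval, decimals) {
  stopifnot(inherits(interval, "reference_interval"), decimals >= 0)
  interval$rounded <- c(round_half_up(interval$lower, decimals),
                        round_half_up(interval$upper, decimals))
  interval$display_decimals <- as.integer(decimals)
  interval
}

#' Half-up rounding
#'
#' Rounds halves away from zero, matching hand calculation and clinical
#' reporting, unlike base `round()`'s round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
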
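#' Biological-variation profile of a measurand
#'
#' Bundles the population and analytical variation parameters of one
#' measurand: within-subject biological variation (CV_I), between-subject
#' biological variation (CV_G), analytical imprecision (CV_A) and the
#' conventional population-based reference interval (popRI).
#'
#' @param measurand Name of the measurand (e.g. `"leukocytes"`).
#' @param units Reporting units (e.g. `"x 10^9/L"`).
#' @param cv_i Within-subject biological variation, percent.
#' @param cv_g Between-subject biological variation, percent. May be `NA`
#'   when only the index of individuality is known.
#' @param cv_a Analytical variation of the measuring system, percent.
#' @param pop_ri_lower,pop_ri_upper Limits of the population reference
#'   interval, in measurand units.
#' @param display_decimals Number of decimals used when reporting limits.
#'
#' @return An object of class `bv_profile`.
#' @examples
#' bv_profile("leukocytes", "x 10^9/L", cv_i = 11.10, cv_g = 17.08,
#'            cv_a = 1.26, pop_ri_lower = 3.5, pop_ri_upper = 9.5,
#'            display_decimals = 1)
#' @export
bv_profile <- function(measurand, units = "", cv_i, cv_g = NA_real_, cv_a,
                       pop_ri_lower = NA_real_, pop_ri_upper = NA_real_,
                       display_decimals = 2L) {
  stopifnot(is.character(measurand), length(measurand) == 1L)
  cv_i <- as.numeric(cv_i); cv_g <- as.numeric(cv_g); cv_a <- as.numeric(cv_a)
  if (is.na(cv_i) || cv_i < 0) stop("cv_i must be >= 0", call. = FALSE)
  if (!is.na(cv_g) && cv_g <= 0) stop("cv_g must be > 0", call. = FALSE)
  if (is.na(cv_a) || cv_a < 0) stop("cv_a must be >= 0", call. = FALSE)
  if (!is.na(pop_ri_lower) && !is.na(pop_ri_upper) &&
      pop_ri_lower >= pop_ri_upper)
    stop("pop_ri_lower must be < pop_ri_upper", call. = FALSE)
  display_decimals <- as.integer(display_decimals)
  if (is.na(display_decimals) || display_decimals < 0L)
    stop("display_decimals must be a non-negative integer", call. = FALSE)
  structure(
    list(measurand = measurand, units = units,
         cv_i = cv_i, cv_g = cv_g, cv_a = cv_a,
         pop_ri_lower = as.numeric(pop_ri_lower),
         pop_ri_upper = as.numeric(pop_ri_upper),
         display_decimals = display_decimals),
    class = "bv_profile")
}

#' @export
print.bv_profile <- function(x, ...) {
  cat(sprintf("BV profile: %s [%s]\n", x$measurand, x$units))
  cat(sprintf("  CV_I %.2f%%  CV_G %s%%  CV_A %.2f%%\n",
              x$cv_i, ifelse(is.na(x$cv_g), "NA", sprintf("%.2f", x$cv_g)),
              x$cv_a))
  if (!is.na(x$pop_ri_lower))
    cat(sprintf("  popRI %s ~ %s\n",
                format(x$pop_ri_lower), format(x$pop_ri_upper)))
  invisible(x)
}

#' Homeostatic set point summary
#'
#' Summarizes a patient's steady-state result history: the homeostatic set
#' point (HSP, the mean), its standard deviation, the number of results and
#' the derived total variation CV_T = 100 * sd / mean. CV_T combines the
#' individual's within-person biological variation (CV_P) with the
#' analytical variation (CV_A).
#'
#' @param mean Mean of the steady-state results (the HSP estimate).
#' @param sd Standard deviation of the steady-state results (sample SD).
#' @param n Number of steady-state results.
#' @param cv_t Optional total variation, percent. Defaults to
#'   `100 * sd / mean`; may be supplied directly when the underlying
#'   results are not available at full precision.
#' @return An object of class `hsp_estimate`.
#' @seealso [estimate_hsp()] to compute the summary from raw results.
#' @examples
#' hsp_estimate(mean = 4.45, sd = 0.17, n = 3)
#' @export
hsp_estimate <- function(mean, sd, n, cv_t = NULL) {
  mean <- as.numeric(mean); sd <- as.numeric(sd); n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be >= 2", call. = FALSE)
  if (is.na(sd) || sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (is.null(cv_t)) {
    if (is.na(mean) || mean <= 0)
      stop("mean must be > 0 to derive CV_T", call. = FALSE)
    cv_t <- 100 * sd / mean
  } else {
    cv_t <- as.numeric(cv_t)
    if (is.na(cv_t) || cv_t < 0) stop("cv_t must be >= 0", call. = FALSE)
  }
  structure(list(mean = mean, sd = sd, n = n, cv_t = cv_t),
            class = "hsp_estimate")
}

#' @export
print.hsp_estimate <- function(x, ...) {
  cat(sprintf("HSP %.4g +/- %.4g (n = %d), CV_T = %.2f%%\n",
              x$mean, x$sd, x$n, x$cv_t))
  invisible(x)
}

#' Estimate the homeostatic set point from a steady-state history
#'
#' Computes mean, sample standard deviation (n - 1 denominator) and total
#' variation CV_T from raw steady-state results.
#'
#' @param values Numeric vector of at least two positive steady-state
#'   results of one measurand.
#' @return An [hsp_estimate()] object.
#' @examples
#' estimate_hsp(c(4.3, 4.5, 4.6))
#' @export
estimate_hsp <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("at least 2 steady-state results are required", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("steady-state results must be finite and positive", call. = FALSE)
  hsp_estimate(mean = mean(values), sd = stats::sd(values),
               n = length(values))
}
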
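#' Longitudinal result series for one measurand
#'
#' @param day Integer days relative to symptom onset (Day 0); strictly
#'   increasing.
#' @param value Results in measurand units; finite and non-negative.
#' @param measurand Measurand name.
#' @return A `result_series` data frame with columns `measurand`, `day`,
#'   `value`.
#' @export
result_series <- function(day, value, measurand = "measurand") {
  day <- as.integer(day); value <- as.numeric(value)
  if (length(day) != length(value))
    stop("day and value must have equal length", call. = FALSE)
  if (length(day) > 1L && any(diff(day) <= 0))
    stop("day indices must be strictly increasing", call. = FALSE)
  if (any(!is.finite(value)) || any(value < 0))
    stop("values must be finite and >= 0", call. = FALSE)
  structure(data.frame(measurand = rep(measurand, length(day)), day = day,
                       value = value, stringsAsFactors = FALSE),
            class = c("result_series", "data.frame"))
}

#' Flag results outside a reference interval
#'
#' A point is flagged iff its value is strictly below the lower limit or
#' strictly above the upper limit; boundary values are in range.
#'
#' @param series A [result_series()].
#' @param interval A `reference_interval` (from [prri_pop()], [prri_ind()]
#'   or [pop_ri()]).
#' @param strict If `TRUE` (default) boundary values are not flagged;
#'   `FALSE` flags values at the limits too.
#' @return A data frame with columns `day`, `value`, `flag` (logical) and
#'   `direction` (`"above"`, `"below"` or `"in_range"`).
#' @export
flag_interval <- function(series, interval, strict = TRUE) {
  stopifnot(inherits(interval, "reference_interval"))
  if (nrow(series) == 0L)
    return(data.frame(day = integer(), value = numeric(),
                      flag = logical(), direction = character()))
  below <- if (strict) series$value < interval$lower else
    series$value <= interval$lower
  above <- if (strict) series$value > interval$upper else
    series$value >= interval$upper
  data.frame(day = series$day, value = series$value,
             flag = below | above,
             direction = ifelse(below, "below",
                                ifelse(above, "above", "in_range")),
             stringsAsFactors = FALSE)
}

#' Flag consecutive results exceeding a reference change value
#'
#' For each consecutive pair the percent change is computed relative to the
#' earlier value (`reference = "previous"`, the delta-check convention) or
#' to the pair mean. The later point of a pair is flagged iff the absolute
#' percent change strictly exceeds the RCV threshold; the first point of a
#' series is never RCV-flagged. A zero earlier value makes the relative
#' change undefined: the pair is skipped with a warning and `NA` direction.
#'
#' @param series A [result_series()] with at least 2 points.
#' @param rcv An `rcv_estimate`.
#' @param reference Denominator of the percent change: `"previous"`
#'   (default) or `"mean"`.
#' @param strict If `TRUE` (default) a change exactly at the threshold is
#'   not flagged.
#' @return A data frame with columns `day`, `value`, `pct_change`, `flag`,
#'   `direction` (`"rise"`, `"fall"`, `"stable"`, or `NA` for the first
#'   point / skipped pairs).
#' @export
flag_rcv <- function(series, rcv, reference = c("previous", "mean"),
                     strict = TRUE) {
  stopifnot(inherits(rcv, "rcv_estimate"))
  reference <- match.arg(reference)
  n <- nrow(series)
  if (n < 2L) stop("RCV flagging needs at least 2 points", call. = FALSE)
  v <- series$value
  prev <- v[-n]; curr <- v[-1]
  denom <- if (reference == "previous") prev else (prev + curr) / 2
  pct <- rep(NA_real_, n)
  ok <- denom > 0
  if (any(!ok))
    warning("zero reference value: pair(s) skipped for RCV flagging",
            call. = FALSE)
  pct[-1][ok] <- 100 * abs(curr[ok] - prev[ok]) / denom[ok]
  flag <- !is.na(pct) &
    (if (strict) pct > rcv$threshold else pct >= rcv$threshold)
  direction <- rep(NA_character_, n)
  delta <- c(NA_real_, curr - prev)
  direction[!is.na(pct)] <- ifelse(delta[!is.na(pct)] > 0, "rise",
                                   ifelse(delta[!is.na(pct)] < 0, "fall",
                                          "stable"))
  data.frame(day = series$day, value = v, pct_change = pct,
             flag = flag, direction = direction, stringsAsFactors = FALSE)
}

#' Flag one measurand's series under all five criteria
#'
#' Evaluates a series against popRI, prRI_pop, prRI_ind, RCV_pop and
#' RCV_ind. Criteria whose inputs are unavailable (e.g. no popRI limits)
#' are omitted.
#'
#' @param series A [result_series()].
#' @param profile A [bv_profile()].
#' @param hsp An [hsp_estimate()].
#' @param coverage Coverage probability for all criteria; default 0.95.
#' @param criteria Character vector choosing among `"popRI"`, `"prRI_pop"`,
#'   `"prRI_ind"`, `"RCV_pop"`, `"RCV_ind"`.
#' @param rcv_reference Passed to [flag_rcv()].
#' @param strict Passed to [flag_interval()] and [flag_rcv()].
#' @return A `flag_report`: long data frame with columns `measurand`,
#'   `criterion`, `day`, `value`, `flag`, `direction`.
#' @export
flag_series <- function(series, profile, hsp, coverage = 0.95,
                        criteria = c("popRI", "prRI_pop", "prRI_ind",
                                     "RCV_pop", "RCV_ind"),
                        rcv_reference = "previous", strict = TRUE) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  out <- list()
  add <- function(criterion, df) {
    out[[criterion]] <<- cbind(measurand = series$measurand[1],
                               criterion = criterion,
                               df[, c("day", "value", "flag", "direction")],
                               stringsAsFactors = FALSE)
  }
  if ("popRI" %in% criteria && !is.na(profile$pop_ri_lower))
    add("popRI", flag_interval(series, pop_ri(profile), strict))
  if ("prRI_pop" %in% criteria)
    add("prRI_pop",
        flag_interval(series, prri_pop(hsp, profile, coverage), strict))
  if ("prRI_ind" %in% criteria)
    add("prRI_ind",
        flag_interval(series,
                      suppressWarnings(prri_ind(hsp, profile, coverage)),
                      strict))
  if ("RCV_pop" %in% criteria)
    add("RCV_pop",
        flag_rcv(series, rcv_pop(profile, coverage), rcv_reference, strict))
  if ("RCV_ind" %in% criteria)
    add("RCV_ind",
        flag_rcv(series, suppressWarnings(rcv_ind(hsp, coverage)),
                 rcv_reference, strict))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("flag_report", "data.frame"))
}

#' Pool flag counts across measurands
#'
#' Tabulates flagged / total per criterion over a set of flag reports, the
#' "k/N" ratios used to compare criterion sensitivity. All measurands must
#' share the same day grid. By the delta-check attribution convention, RCV
#' flags belong to the later point of each pair but are reported against
#' the full point count (the same denominator as the interval criteria),
#' so a 10-measurand, 11-day panel has N = 110 for every criterion.
#' Points with missing values are excluded from numerator and denominator.
#'
#' @param reports A `flag_report` or list of them (one per measurand).
#' @return A data frame with columns `criterion`, `flagged`, `total`,
#'   `ratio` (text "k/N") and `fraction`.
#' @export
summarize_flags <- function(reports) {
  if (inherits(reports, "data.frame")) reports <- list(reports)
  all <- do.call(rbind, lapply(reports, as.data.frame))
  grids <- lapply(split(all$day, all$measurand), unique)
  if (length(unique(lapply(grids, sort))) > 1L)
    stop("measurands are not on the same day grid", call. = FALSE)
  keep <- !is.na(all$value)
  dropped <- sum(!keep)
  if (dropped > 0L)
    message(dropped, " point(s) with missing values excluded from totals")
  all <- all[keep, , drop = FALSE]
  agg <- lapply(split(all, all$criterion), function(d)
    data.frame(criterion = d$criterion[1],
               flagged = sum(d$flag, na.rm = TRUE),
               total = nrow(d), stringsAsFactors = FALSE))
  res <- do.call(rbind, agg)
  res$ratio <- sprintf("%d/%d", res$flagged, res$total)
  res$fraction <- res$flagged / res$total
  ord <- match(c("popRI", "prRI_pop", "prRI_ind", "RCV_pop", "RCV_ind"),
               res$criterion)
  res <- res[ord[!is.na(ord)], , drop = FALSE]
  rownames(res) <- NULL
  res
}
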
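#' Read a biological-variation parameter table
#'
#' Expects a CSV/TSV with columns `measurand`, `units`, `cv_i`, `cv_g`,
#' `cv_a`, `pop_ri_lower`, `pop_ri_upper`, `display_decimals`, one row per
#' measurand. `units`, `cv_g`, popRI limits and `display_decimals` are
#' optional.
#'
#' @param path File path.
#' @param sep Field separator; `","` (default) or `"\t"`.
#' @return A named list of [bv_profile()] objects.
#' @export
read_bv_table <- function(path, sep = ",") {
  df <- read_table_checked(path, sep, required = c("measurand", "cv_i",
                                                   "cv_a"))
  df <- fill_optional(df, list(units = "", cv_g = NA_real_,
                               pop_ri_lower = NA_real_,
                               pop_ri_upper = NA_real_,
                               display_decimals = 2L))
  out <- lapply(seq_len(nrow(df)), function(i)
    bv_profile(df$measurand[i], df$units[i], cv_i = df$cv_i[i],
               cv_g = df$cv_g[i], cv_a = df$cv_a[i],
               pop_ri_lower = df$pop_ri_lower[i],
               pop_ri_upper = df$pop_ri_upper[i],
               display_decimals = df$display_decimals[i]))
  stats::setNames(out, df$measurand)
}

#' Read a steady-state (HSP) history file
#'
#' Accepts either raw results (columns `measurand`, `value`; several rows
#' per measurand) or pre-summarized histories (columns `measurand`, `mean`,
#' `sd`, `n`, optionally `cv_t`).
#'
#' @param path File path.
#' @param sep Field separator.
#' @return A named list of [hsp_estimate()] objects.
#' @export
read_hsp_history <- function(path, sep = ",") {
  df <- read_table_checked(path, sep, required = "measurand")
  if ("value" %in% names(df)) {
    sp <- split(df$value, df$measurand)
    out <- lapply(sp, estimate_hsp)
  } else if (all(c("mean", "sd", "n") %in% names(df))) {
    out <- lapply(seq_len(nrow(df)), function(i)
      hsp_estimate(df$mean[i], df$sd[i], df$n[i],
                   cv_t = if ("cv_t" %in% names(df)) df$cv_t[i] else NULL))
    names(out) <- df$measurand
  } else {
    stop("HSP file needs either a 'value' column or 'mean','sd','n' columns",
         call. = FALSE)
  }
  out
}

#' Read a long-format longitudinal results file
#'
#' Columns `measurand`, `day`, `value`; rows with missing values are
#' dropped with a message.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return A named list of [result_series()] objects.
#' @export
read_result_series <- function(path, sep = ",") {
  df <- read_table_checked(path, sep,
                           required = c("measurand", "day", "value"))
  miss <- is.na(df$value) | is.na(df$day)
  if (any(miss)) {
    message(sum(miss), " row(s) with missing values dropped")
    df <- df[!miss, , drop = FALSE]
  }
  sp <- split(df, df$measurand)
  lapply(sp, function(d) {
    d <- d[order(d$day), , drop = FALSE]
    result_series(d$day, d$value, d$measurand[1])
  })
}

read_table_checked <- function(path, sep = ",", required = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop(path, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) stop(path, ": no data rows", call. = FALSE)
  df
}

fill_optional <- function(df, defaults) {
  for (nm in names(defaults))
    if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  df
}

#' Compute the full parameter table for a panel
#'
#' The tabular pipeline behind the `compute` subcommand: for every
#' measurand, the HSP summary, CV_T, the index of individuality, both prRI
#' routes (unrounded and display-rounded), both RCVs and the applicability
#' verdict.
#'
#' @param profiles Named list of [bv_profile()] objects.
#' @param hsps Named list of [hsp_estimate()] objects covering the same
#'   measurands.
#' @param coverage Coverage probability; default 0.95.
#' @param clamp Clamp negative lower prRI limits at zero; default `FALSE`.
#' @return A data frame with one row per measurand.
#' @export
compute_parameters <- function(profiles, hsps, coverage = 0.95,
                               clamp = FALSE) {
  missing_h <- setdiff(names(profiles), names(hsps))
  if (length(missing_h) > 0L)
    stop("no HSP history for measurand(s): ",
         paste(missing_h, collapse = ", "), call. = FALSE)
  rows <- lapply(names(profiles), function(nm) {
    p <- profiles[[nm]]; h <- hsps[[nm]]
    ivp <- round_interval(prri_pop(h, p, coverage, clamp),
                          p$display_decimals)
    ivi <- round_interval(suppressWarnings(
      prri_ind(h, p, coverage, clamp)), p$display_decimals)
    rp <- rcv_pop(p, coverage)
    ri <- suppressWarnings(rcv_ind(h, coverage))
    verdict <- check_applicability(p, h)
    data.frame(
      measurand = nm, units = p$units,
      hsp = h$mean, hsp_sd = h$sd, n = h$n, cv_t = h$cv_t,
      cv_i = p$cv_i, cv_a = p$cv_a,
      ii = if (!is.na(p$cv_g)) index_of_individuality(p) else NA_real_,
      pop_ri_lower = p$pop_ri_lower, pop_ri_upper = p$pop_ri_upper,
      prri_pop_lower = ivp$rounded[1], prri_pop_upper = ivp$rounded[2],
      prri_pop_lower_raw = ivp$lower, prri_pop_upper_raw = ivp$upper,
      rcv_pop = rp$threshold,
      prri_ind_lower = ivi$rounded[1], prri_ind_upper = ivi$rounded[2],
      prri_ind_lower_raw = ivi$lower, prri_ind_upper_raw = ivi$upper,
      rcv_ind = ri$threshold,
      recommended_route = verdict$recommended_route,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag a panel of result series under all criteria
#'
#' @param series_list Named list of [result_series()] objects.
#' @param profiles,hsps Named lists as in [compute_parameters()].
#' @param coverage Coverage probability.
#' @param ... Passed to [flag_series()] (criteria, rcv_reference, strict).
#' @return A list with `flags` (pooled long `flag_report`) and `summary`
#'   (output of [summarize_flags()]).
#' @export
flag_panel <- function(series_list, profiles, hsps, coverage = 0.95, ...) {
  unknown <- setdiff(names(series_list), names(profiles))
  if (length(unknown) > 0L)
    stop("measurand(s) absent from parameter table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  reports <- lapply(names(series_list), function(nm)
    flag_series(series_list[[nm]], profiles[[nm]], hsps[[nm]],
                coverage = coverage, ...))
  flags <- do.call(rbind, reports)
  rownames(flags) <- NULL
  list(flags = structure(flags, class = c("flag_report", "data.frame")),
       summary = summarize_flags(reports))
}

#' Write a flag report to CSV plus a JSON ratio summary
#'
#' @param panel_flags Output of [flag_panel()].
#' @param csv_path Destination for the per-point long CSV.
#' @param json_path Destination for the JSON summary of "k/N" ratios.
#' @return Invisibly, the summary data frame.
#' @export
write_flag_report <- function(panel_flags, csv_path, json_path = NULL) {
  utils::write.csv(as.data.frame(panel_flags$flags), csv_path,
                   row.names = FALSE)
  if (!is.null(json_path)) {
    s <- panel_flags$summary
    jsonlite::write_json(
      list(ratios = stats::setNames(as.list(s$ratio), s$criterion),
           flagged = stats::setNames(as.list(s$flagged), s$criterion),
           total = stats::setNames(as.list(s$total), s$criterion)),
      json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(panel_flags$summary)
}

#' Read a simulation configuration from YAML
#'
#' Top-level keys: `measurands` (list of records with `measurand`,
#' `true_hsp`, `cv_p`, `cv_a`), `days`, optional `excursions` (records
#' with `measurand`, `start`, `end`, `fold`), `n_hsp_history`, `seed`,
#' `noise`, `ramp`.
#'
#' @param path YAML file path.
#' @return A [simulation_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("measurands", "days", "excursions", "n_hsp_history", "seed",
             "noise", "ramp")
  bad <- setdiff(names(y), known)
  if (length(bad) > 0L)
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  to_df <- function(x) do.call(rbind, lapply(x, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  simulation_config(
    measurands = to_df(y$measurands),
    days = unlist(y$days),
    excursions = if (!is.null(y$excursions)) to_df(y$excursions),
    n_hsp_history = y$n_hsp_history %||% 3L,
    seed = y$seed %||% 1L,
    noise = y$noise %||% "gaussian",
    ramp = y$ramp %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulated panel to long-format CSV files
#'
#' @param panel A `simulated_panel` from [simulate_panel()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written: `results.csv`,
#'   `hsp_history.csv`, `truth_labels.csv`.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "simulated_panel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("results.csv", "hsp_history.csv",
                            "truth_labels.csv"))
  utils::write.csv(panel$results, paths[1], row.names = FALSE)
  utils::write.csv(panel$hsp_history, paths[2], row.names = FALSE)
  utils::write.csv(panel$truth, paths[3], row.names = FALSE)
  invisible(paths)
}
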
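#' Natural-log transform used for MEC phenotypes
#'
#' Analyses are run on `ln(1 + MEC)` with MEC in ng/mL, which tames the right
#' skew of concentration phenotypes while keeping zero at zero.
#'
#' @param mec MEC value(s) in ng/mL, >= 0; `NA` passes through.
#' @return `log(1 + mec)`.
#' @examples
#' mec_log_transform(c(0, 1, exp(1) - 1))
#' @export
mec_log_transform <- function(mec) {
  if (any(mec < 0, na.rm = TRUE)) stop("mec_log_transform: MEC must be >= 0")
  log1p(mec)
}

#' Extract minimum effective concentrations from a dosing history
#'
#' The MEC reading of a PCA demand is the modeled concentration immediately
#' before the demand (left limit): the level at which analgesia had become
#' insufficient. One (plasma, effect-site) pair is recorded per `pca_demand`
#' event — `initial_bolus` events shape the concentration field but generate
#' no MEC point — and the pairs are averaged over postoperative windows
#' `(0, h]` hours (default 6, 12 and 24 h; a demand at exactly the window
#' bound belongs to the window). A window with no demands yields a missing
#' mean, never zero. Log phenotypes are `ln(1 + window mean)`.
#'
#' @param history A [dosing_history()].
#' @param params A [pk_params()] object.
#' @param windows Window upper bounds in hours.
#' @return An object of class `mec_record`: list with `subject_id`,
#'   `demand_points` (data frame `time_min`, `cp_pre`, `ce_pre`),
#'   `window_means` and `log_values` (data frames with one row per window and
#'   columns `window_h`, `plasma`, `effect`).
#' @export
extract_mec <- function(history, params, windows = c(6, 12, 24)) {
  stopifnot(inherits(history, "dosing_history"))
  h <- hybrid_constants(params)
  ev <- history$events
  dem <- ev$time_min[ev$kind == "pca_demand"]
  dem <- sort(dem)
  if (length(dem)) {
    dp <- data.frame(
      time_min = dem,
      cp_pre = concentration_at(history, h, dem, "plasma", "pre"),
      ce_pre = concentration_at(history, h, dem, "effect", "pre"))
  } else {
    dp <- data.frame(time_min = numeric(), cp_pre = numeric(),
                     ce_pre = numeric())
  }
  wm <- data.frame(window_h = windows, n_demands = NA_integer_,
                   plasma = NA_real_, effect = NA_real_)
  for (i in seq_along(windows)) {
    inw <- dp$time_min > 0 & dp$time_min <= windows[i] * 60
    wm$n_demands[i] <- sum(inw)
    if (any(inw)) {
      wm$plasma[i] <- mean(dp$cp_pre[inw])
      wm$effect[i] <- mean(dp$ce_pre[inw])
    }
  }
  lv <- wm
  lv$plasma <- mec_log_transform(wm$plasma)
  lv$effect <- mec_log_transform(wm$effect)
  structure(list(subject_id = history$subject_id, demand_points = dp,
                 window_means = wm, log_values = lv),
            class = "mec_record")
}

#' @export
print.mec_record <- function(x, ...) {
  cat(sprintf("MEC record for subject %s: %d demand points\n",
              x$subject_id, nrow(x$demand_points)))
  print(x$window_means, row.names = FALSE)
  invisible(x)
}

#' Tabulate MEC phenotypes for a list of subjects
#'
#' Runs [extract_mec()] for each dosing history and assembles the wide
#' phenotype table used by the association stage. Missing window means are
#' `NA` (serialized as empty fields).
#'
#' @param histories List of [dosing_history()] objects.
#' @param params A [pk_params()] object.
#' @param windows Window upper bounds in hours.
#' @return A data frame with one row per subject: `subject_id`,
#'   `n_demands_<h>h`, `mec_plasma_0_<h>h`, `mec_effect_0_<h>h`,
#'   `log_mec_plasma_0_<h>h`, `log_mec_effect_0_<h>h` for each window.
#' @export
mec_phenotype_table <- function(histories, params, windows = c(6, 12, 24)) {
  rows <- lapply(histories, function(hist) {
    rec <- extract_mec(hist, params, windows)
    out <- list(subject_id = hist$subject_id)
    for (i in seq_along(windows)) {
      w <- windows[i]
      out[[sprintf("n_demands_%dh", w)]] <- rec$window_means$n_demands[i]
      out[[sprintf("mec_plasma_0_%dh", w)]] <- rec$window_means$plasma[i]
      out[[sprintf("mec_effect_0_%dh", w)]] <- rec$window_means$effect[i]
      out[[sprintf("log_mec_plasma_0_%dh", w)]] <- rec$log_values$plasma[i]
      out[[sprintf("log_mec_effect_0_%dh", w)]] <- rec$log_values$effect[i]
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
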
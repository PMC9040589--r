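# Dynamic calling of consumed and secreted metabolites.
#
# An annotated ion in a culture is called directional when a statistical
# trend criterion passes AND the maximum fold change relative to the first
# time point exceeds a calibrated threshold:
#
#   trend:  |Pearson r(intensity, OD)| > 0.7 with p < 0.05, OR a linear or
#           exponential (log-linear) fit of intensity against time with
#           R^2 > 0.7 and p < 0.05 (the fit branch catches metabolites that
#           are exhausted before the end of the experiment, or produced at a
#           constant rate, where the OD correlation degrades);
#   size:   maximum fold change vs the first time point >= 1.20 for
#           increases (secreted) or a decrease magnitude >= 1.37 (consumed).
#
# The fold-change thresholds ship at the values calibrated on a rich-medium
# dilution series (see calibrate_thresholds); both the statistics and the
# thresholds are configurable.

#' Dynamic-caller configuration
#'
#' @param r_od_threshold Minimum absolute Pearson correlation between ion
#'   intensity and OD.
#' @param p_threshold Maximum p-value for correlation/fit criteria.
#' @param r2_fit_threshold Minimum R^2 for the linear or exponential fit
#'   branch.
#' @param fc_secreted Minimum increase fold change (> 1) for a secretion
#'   call; default 1.20 (dilution-series calibration, 20- to 40-fold
#'   window).
#' @param fc_consumed Minimum decrease fold-change magnitude (> 1) for a
#'   consumption call; default 1.37 (40- to 80-fold window).
#' @param dilution_corr_threshold Calibration filter: ions are retained only
#'   if their Pearson correlation with the dilution factor is below this
#'   (default -0.75).
#' @param per_replicate If `FALSE` (default) replicates of the same
#'   (species, medium) are averaged per time point before testing.
#' @return A `caller_config` list.
#' @export
caller_config <- function(r_od_threshold = 0.7, p_threshold = 0.05,
                          r2_fit_threshold = 0.7, fc_secreted = 1.20,
                          fc_consumed = 1.37,
                          dilution_corr_threshold = -0.75,
                          per_replicate = FALSE) {
  stopifnot(r_od_threshold >= 0, r_od_threshold <= 1,
            p_threshold > 0, p_threshold < 1,
            r2_fit_threshold >= 0, r2_fit_threshold <= 1,
            fc_secreted > 1, fc_consumed > 1,
            dilution_corr_threshold <= 0, dilution_corr_threshold >= -1)
  structure(list(r_od_threshold = r_od_threshold, p_threshold = p_threshold,
                 r2_fit_threshold = r2_fit_threshold,
                 fc_secreted = fc_secreted, fc_consumed = fc_consumed,
                 dilution_corr_threshold = dilution_corr_threshold,
                 per_replicate = per_replicate),
            class = "caller_config")
}

# Pearson correlation with the exact t-distribution p-value under r = 0.
# Returns c(r, p); NA for degenerate input (constant series, n < 3).
cor_with_p <- function(x, y) {
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(c(r = NA_real_, p = NA_real_))
  }
  r <- stats::cor(x, y)
  n <- length(x)
  if (abs(r) >= 1) return(c(r = r, p = 0))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  c(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

# Simple linear regression y ~ x: R^2, slope, and the slope t-test p-value
# (identical to the correlation p for simple regression).
lm_fit_stats <- function(x, y) {
  cp <- cor_with_p(x, y)
  if (is.na(cp[["r"]])) {
    return(c(r2 = NA_real_, slope = NA_real_, p = NA_real_))
  }
  slope <- cp[["r"]] * stats::sd(y) / stats::sd(x)
  c(r2 = cp[["r"]]^2, slope = slope, p = cp[["p"]])
}

# Signed maximum fold change of a series vs its first value:
# +max(x/x1) if the largest change is an increase, -max(x1/x) if a decrease.
# Zero values are floored at half the smallest positive value (flagged).
signed_max_fold_change <- function(x) {
  floored <- FALSE
  if (any(x <= 0)) {
    pos <- x[x > 0]
    if (length(pos) == 0L) {
      return(list(fc = NA_real_, up = NA_real_, down = NA_real_,
                  floored = TRUE))
    }
    x[x <= 0] <- min(pos) / 2
    floored <- TRUE
  }
  up <- max(x / x[1])
  down <- max(x[1] / x)
  fc <- if (up >= down) up else -down
  list(fc = fc, up = up, down = down, floored = floored)
}

# Evaluate all caller criteria for one intensity series. Internal; exposed
# for cross-checking.
evaluate_ion <- function(intensity, od, time, config) {
  degenerate <- stats::sd(intensity) == 0 || all(intensity <= 0)
  fcs <- signed_max_fold_change(intensity)
  if (degenerate) {
    return(list(direction = "unchanged", r_od = NA_real_, p_r = NA_real_,
                r2_lin = NA_real_, p_lin = NA_real_, r2_exp = NA_real_,
                p_exp = NA_real_, max_fc = fcs$fc, degenerate = TRUE,
                floored = fcs$floored))
  }
  corr <- cor_with_p(od, intensity)
  lin <- lm_fit_stats(time, intensity)
  logx <- intensity
  exp_floored <- FALSE
  if (any(logx <= 0)) {
    logx[logx <= 0] <- min(logx[logx > 0]) / 2
    exp_floored <- TRUE
  }
  expf <- lm_fit_stats(time, log(logx))

  corr_pass <- !is.na(corr[["r"]]) &&
    abs(corr[["r"]]) > config$r_od_threshold &&
    corr[["p"]] < config$p_threshold
  lin_pass <- !is.na(lin[["r2"]]) && lin[["r2"]] > config$r2_fit_threshold &&
    lin[["p"]] < config$p_threshold
  exp_pass <- !is.na(expf[["r2"]]) &&
    expf[["r2"]] > config$r2_fit_threshold &&
    expf[["p"]] < config$p_threshold

  up_ok <- !is.na(fcs$up) && fcs$up >= config$fc_secreted
  down_ok <- !is.na(fcs$down) && fcs$down >= config$fc_consumed

  # direction support: a criterion passing with the matching trend sign
  pos_support <- (corr_pass && corr[["r"]] > 0) ||
    (lin_pass && lin[["slope"]] > 0) || (exp_pass && expf[["slope"]] > 0)
  neg_support <- (corr_pass && corr[["r"]] < 0) ||
    (lin_pass && lin[["slope"]] < 0) || (exp_pass && expf[["slope"]] < 0)

  secreted <- pos_support && up_ok
  consumed <- neg_support && down_ok
  direction <- if (secreted && consumed) {
    # conflicting support (non-monotone series): take the larger excursion
    if (fcs$up >= fcs$down) "secreted" else "consumed"
  } else if (secreted) "secreted" else if (consumed) "consumed"
  else "unchanged"

  max_fc <- switch(direction,
    secreted = fcs$up,
    consumed = -fcs$down,
    unchanged = fcs$fc
  )
  list(direction = direction, r_od = corr[["r"]], p_r = corr[["p"]],
       r2_lin = lin[["r2"]], p_lin = lin[["p"]], r2_exp = expf[["r2"]],
       p_exp = expf[["p"]], max_fc = max_fc, degenerate = FALSE,
       floored = fcs$floored || exp_floored)
}

#' Call consumed/secreted/unchanged metabolites from a time-course table
#'
#' Applies the trend + fold-change criteria to every metabolite column of an
#' ion time-course table, per (species, medium) culture. Replicates are
#' averaged per time point before testing unless
#' `config$per_replicate = TRUE`, in which case each replicate is called
#' separately.
#'
#' @param table data.frame with columns `species`, `medium`, `replicate`,
#'   `time_h`, `od`, plus one numeric column per metabolite/ion.
#' @param config A [caller_config()].
#' @return data.frame of calls: `metabolite`, `species`, `medium`,
#'   `direction`, and the full statistical evidence (`r_od`, `p_r`,
#'   `r2_lin`, `p_lin`, `r2_exp`, `p_exp`, `max_fc`, `degenerate`,
#'   `floored`).
#' @export
call_dynamics <- function(table, config = caller_config()) {
  meta_cols <- c("species", "medium", "replicate", "time_h", "od")
  check_columns(table, meta_cols, "ion time-course table")
  ion_cols <- setdiff(names(table), meta_cols)
  if (length(ion_cols) == 0L) stop("table has no ion columns")
  if (any(vapply(table[ion_cols], function(x) any(x < 0, na.rm = TRUE),
                 logical(1)))) {
    stop("negative ion intensities")
  }
  group_cols <- if (isTRUE(config$per_replicate)) {
    c("species", "medium", "replicate")
  } else c("species", "medium")
  key <- interaction(table[group_cols], drop = TRUE, sep = "\r")
  out <- lapply(split(table, key), function(d) {
    if (isTRUE(config$per_replicate)) {
      prof <- d[order(d$time_h), ]
    } else {
      # average replicates per time point
      agg <- stats::aggregate(d[c("od", ion_cols)],
                              by = list(time_h = d$time_h), FUN = mean)
      prof <- agg[order(agg$time_h), ]
    }
    if (nrow(prof) < 4L) {
      stop("fewer than 4 time points for ", d$species[1], " in ",
           d$medium[1])
    }
    calls <- lapply(ion_cols, function(ion) {
      ev <- evaluate_ion(prof[[ion]], prof$od, prof$time_h, config)
      cbind(data.frame(metabolite = ion, species = d$species[1],
                       medium = d$medium[1], stringsAsFactors = FALSE),
            as.data.frame(ev, stringsAsFactors = FALSE))
    })
    do.call(rbind, calls)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$species, out$medium, out$metabolite), ]
}

#' Calibrate fold-change thresholds from a medium dilution series
#'
#' Rich complex media contain most detectable ions, so an ion's response to
#' controlled dilution measures the fold change an actual concentration
#' change produces in flow-injection intensities (matrix effects compress
#' it). Background ions not derived from the medium are removed by keeping
#' only ions whose Pearson correlation with the dilution factor is below
#' `config$dilution_corr_threshold` (default -0.75). The consumption
#' threshold is the mean intensity fold change across kept ions between the
#' `consumed_window` dilutions (default 40x vs 80x, a 2-fold concentration
#' decrease) and the secretion threshold between the `secreted_window`
#' dilutions (default 20x vs 40x).
#'
#' @param dilution_table data.frame from [simulate_dilution_series()] or
#'   measured equivalent: columns `dilution`, `replicate`, one per ion.
#' @param config A [caller_config()] (supplies the correlation filter).
#' @param consumed_window,secreted_window Length-2 numeric: the (less
#'   diluted, more diluted) pair over which the fold change is averaged.
#' @return list with `fc_consumed`, `fc_secreted`, `n_ions_kept`,
#'   `kept_ions`.
#' @export
calibrate_thresholds <- function(dilution_table, config = caller_config(),
                                 consumed_window = c(40, 80),
                                 secreted_window = c(20, 40)) {
  check_columns(dilution_table, c("dilution", "replicate"), "dilution table")
  ion_cols <- setdiff(names(dilution_table), c("dilution", "replicate"))
  if (length(ion_cols) == 0L) stop("dilution table has no ion columns")
  dils <- sort(unique(dilution_table$dilution))
  if (length(dils) < 3L) stop("need at least 3 dilution levels")
  needed <- unique(c(consumed_window, secreted_window))
  if (!all(needed %in% dils)) {
    stop("dilution series lacks level(s): ",
         paste(setdiff(needed, dils), collapse = ", "))
  }
  # mean intensity per (dilution, ion)
  agg <- stats::aggregate(dilution_table[ion_cols],
                          by = list(dilution = dilution_table$dilution),
                          FUN = mean)
  agg <- agg[order(agg$dilution), ]
  keep <- vapply(ion_cols, function(ion) {
    r <- cor_with_p(agg$dilution, agg[[ion]])[["r"]]
    !is.na(r) && r < config$dilution_corr_threshold
  }, logical(1))
  kept <- ion_cols[keep]
  if (length(kept) == 0L) {
    stop("no ion passes the dilution-correlation filter (< ",
         config$dilution_corr_threshold, ")")
  }
  fc_at <- function(window) {
    lo <- agg[agg$dilution == window[1], kept, drop = FALSE]  # less diluted
    hi <- agg[agg$dilution == window[2], kept, drop = FALSE]  # more diluted
    mean(as.numeric(lo) / as.numeric(hi))
  }
  list(fc_consumed = fc_at(consumed_window),
       fc_secreted = fc_at(secreted_window),
       n_ions_kept = length(kept), kept_ions = kept)
}
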
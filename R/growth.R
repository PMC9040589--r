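# Growth physiology: four-parameter logistic fits of OD time series and the
# derived quantities used throughout the analysis (specific growth rate,
# maximum OD, relative maximum OD in spent media, normalized AUC,
# supplementation effect statistics).

# OD range below which a culture is treated as non-growing (OD units).
NO_GROWTH_SPAN <- 0.05

#' Fit a four-parameter logistic growth curve
#'
#' Least-squares fit of `OD(t) = A + (K - A) / (1 + exp(-r (t - t0)))` by
#' Levenberg-Marquardt. The specific growth rate `mu` is the maximum of
#' `d log(OD)/dt` evaluated on the fitted curve over the observed time
#' range, i.e. the steepest per-capita rate, not the raw shape parameter
#' `r`. Fits with an OD span (`K - A`) below 0.05 OD units are flagged
#' non-growing and get `mu = 0`.
#'
#' Initialization: `A = min(OD)`, `K = max(OD)`, `t0` at the steepest
#' log-slope, `r` from a log-linear fit of the middle of the rise; bounded
#' so that `K >= A >= 0` and `r > 0`.
#'
#' @param times Sampling times (h), at least 5 distinct values.
#' @param od Optical densities (> 0), same length as `times`.
#' @return A `growth_fit` object: list with `A`, `K`, `r`, `t0`, `mu`,
#'   `max_od` (= `K`), `r_squared`, `converged`, `no_growth`.
#' @export
fit_logistic4 <- function(times, od) {
  if (length(times) != length(od)) stop("times and od differ in length")
  keep <- is.finite(times) & is.finite(od)
  if (!all(keep)) stop("non-finite values in times or od")
  if (length(unique(times)) < 5L) stop("need at least 5 distinct time points")
  if (any(od <= 0)) stop("all OD values must be > 0")
  ord <- order(times)
  times <- times[ord]; od <- od[ord]

  if (max(od) - min(od) < NO_GROWTH_SPAN) {
    return(new_growth_fit(A = mean(od), K = mean(od), r = 0,
                          t0 = mean(times), mu = 0, r_squared = NA_real_,
                          converged = TRUE, no_growth = TRUE))
  }

  start <- logistic4_start(times, od)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      od ~ A + (K - A) / (1 + exp(-r * (t - t0))),
      data = list(od = od, t = times),
      start = start,
      lower = c(A = 0, K = 0, r = 1e-6, t0 = min(times) - diff(range(times))),
      upper = c(A = max(od), K = 2 * max(od), r = 100,
                t0 = max(times) + diff(range(times))),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(new_growth_fit(A = start[["A"]], K = start[["K"]], r = start[["r"]],
                          t0 = start[["t0"]], mu = NA_real_,
                          r_squared = NA_real_, converged = FALSE,
                          no_growth = FALSE))
  }
  p <- as.list(stats::coef(fit))
  if (p$K < p$A) { tmp <- p$A; p$A <- p$K; p$K <- tmp; p$r <- -p$r }
  fitted_od <- logistic4(times, p$A, p$K, p$r, p$t0)
  r2 <- 1 - sum((od - fitted_od)^2) / sum((od - mean(od))^2)
  no_growth <- (p$K - p$A) < NO_GROWTH_SPAN
  mu <- if (no_growth) 0 else max_specific_rate(p, range(times))
  new_growth_fit(A = p$A, K = p$K, r = p$r, t0 = p$t0, mu = mu,
                 r_squared = max(0, min(1, r2)), converged = TRUE,
                 no_growth = no_growth)
}

new_growth_fit <- function(A, K, r, t0, mu, r_squared, converged, no_growth) {
  structure(list(A = A, K = K, r = r, t0 = t0, mu = mu, max_od = K,
                 r_squared = r_squared, converged = converged,
                 no_growth = no_growth),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("4PL growth fit:",
      if (x$no_growth) "(no growth)" else "", "\n")
  cat(sprintf("  A = %.4g  K = %.4g  r = %.4g /h  t0 = %.4g h\n",
              x$A, x$K, x$r, x$t0))
  cat(sprintf("  mu = %.4g /h  max OD = %.4g  R^2 = %.4g\n",
              x$mu, x$max_od, x$r_squared))
  invisible(x)
}

logistic4_start <- function(times, od) {
  logod <- log(od)
  slopes <- diff(logod) / diff(times)
  i <- which.max(slopes)
  t0 <- mean(times[c(i, i + 1L)])
  # log-linear slope over the middle of the rise as the rate guess
  lo <- min(od) + 0.25 * (max(od) - min(od))
  hi <- min(od) + 0.75 * (max(od) - min(od))
  mid <- od >= lo & od <= hi
  r0 <- if (sum(mid) >= 2) {
    abs(stats::coef(stats::lm(logod[mid] ~ times[mid]))[[2]]) * 4
  } else {
    max(slopes) * 4
  }
  c(A = max(min(od), 1e-6), K = max(od), r = max(r0, 0.1), t0 = t0)
}

# Maximum of d log OD / dt of a fitted 4PL curve over the time window,
# by dense grid plus local refinement.
max_specific_rate <- function(p, window) {
  dlog <- function(t) {
    e <- exp(-p$r * (t - p$t0))
    odv <- p$A + (p$K - p$A) / (1 + e)
    dod <- (p$K - p$A) * p$r * e / (1 + e)^2
    dod / odv
  }
  grid <- seq(window[1], window[2], length.out = 512)
  i <- which.max(dlog(grid))
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  if (lo == hi) return(dlog(lo))
  opt <- stats::optimize(dlog, c(lo, hi), maximum = TRUE)
  max(opt$objective, dlog(grid[i]))
}

#' Maximum OD relative to fresh medium
#'
#' Ratio of the maximum OD reached in a spent-medium culture to that reached
#' in fresh medium. A value near 0.5 is the expectation under pure 1:1
#' nutrient dilution with no cross-feeding; values above it indicate that
#' the producer's supernatant supports extra growth. Non-growing spent
#' cultures return 0.
#'
#' @param spent_fit,fresh_fit `growth_fit` objects.
#' @return Dimensionless ratio.
#' @export
relative_max_od <- function(spent_fit, fresh_fit) {
  if (fresh_fit$max_od <= 0) stop("fresh-medium max OD must be > 0")
  if (isTRUE(spent_fit$no_growth)) return(0)
  spent_fit$max_od / fresh_fit$max_od
}

# Trapezoid-rule area under an OD curve.
auc_trapezoid <- function(times, od) {
  ord <- order(times)
  times <- times[ord]; od <- od[ord]
  sum(diff(times) * (utils::head(od, -1) + utils::tail(od, -1)) / 2)
}

#' Supplementation effect on growth
#'
#' Compares replicate growth curves with and without a supplemented
#' metabolite. Each replicate is fitted with [fit_logistic4()]; reported are
#' ratios of arm means for the specific growth rate, maximum OD and the
#' trapezoid-rule area under the raw OD curve (normalized to the control
#' mean), plus two-sided Welch t tests on the per-replicate `mu` and
#' `max_od`.
#'
#' @param control,treated data.frames with columns `replicate`, `time_h`,
#'   `od` (one growth curve per replicate).
#' @return list with `relative_mu`, `relative_max_od`, `relative_auc`,
#'   `p_mu`, `p_max_od`, and per-arm per-replicate fit summaries. With a
#'   single replicate in either arm the p-values are `NA` (ratios are still
#'   returned).
#' @export
supplementation_effect <- function(control, treated) {
  per_arm <- function(df) {
    reps <- split(df, df$replicate)
    data.frame(
      replicate = names(reps),
      mu = vapply(reps, function(r) fit_logistic4(r$time_h, r$od)$mu,
                  numeric(1)),
      max_od = vapply(reps, function(r) fit_logistic4(r$time_h, r$od)$max_od,
                      numeric(1)),
      auc = vapply(reps, function(r) auc_trapezoid(r$time_h, r$od),
                   numeric(1)),
      row.names = NULL
    )
  }
  ctl <- per_arm(control)
  trt <- per_arm(treated)
  welch_p <- function(x, y) {
    if (length(x) < 2L || length(y) < 2L) return(NA_real_)
    if (stats::sd(c(x, y)) == 0) return(1)
    stats::t.test(x, y, var.equal = FALSE)$p.value
  }
  list(
    relative_mu = mean(trt$mu) / mean(ctl$mu),
    relative_max_od = mean(trt$max_od) / mean(ctl$max_od),
    relative_auc = mean(trt$auc) / mean(ctl$auc),
    p_mu = welch_p(trt$mu, ctl$mu),
    p_max_od = welch_p(trt$max_od, ctl$max_od),
    control = ctl, treated = trt
  )
}

#' Fit growth curves for every culture in an ion time-course table
#'
#' @param table data.frame with at least `species`, `medium`, `replicate`,
#'   `time_h`, `od`.
#' @return data.frame with one row per (species, medium, replicate) and the
#'   fitted parameters.
#' @export
fit_growth_table <- function(table) {
  need <- c("species", "medium", "replicate", "time_h", "od")
  check_columns(table, need, "growth table")
  key <- interaction(table$species, table$medium, table$replicate, drop = TRUE)
  rows <- lapply(split(table, key), function(d) {
    f <- fit_logistic4(d$time_h, d$od)
    data.frame(species = d$species[1], medium = d$medium[1],
               replicate = d$replicate[1], A = f$A, K = f$K, r = f$r,
               t0 = f$t0, mu = f$mu, max_od = f$max_od,
               r_squared = f$r_squared, converged = f$converged,
               no_growth = f$no_growth, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$species, out$medium, out$replicate), ]
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(what, " lacks column(s): ", paste(missing, collapse = ", "))
  }
  invisible(df)
}
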
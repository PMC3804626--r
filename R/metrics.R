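#' @title Movement-pattern metrics
#'
#' @description
#' Statistics computed on group-centre trajectories, on the observation
#' schedule of the field data they are compared against: 5 observation days
#' per 30-day period, 7 consecutive hours (14 half-hour steps starting
#' 08:00) per day. Daily step length is the summed centre displacement over
#' the window; tortuosity is `ln(D_total / D_net^2)` (natural log, metres —
#' the statistic is unit-dependent because the net displacement is squared,
#' so data units must match); spatio-temporal aggregation is the
#' beta-binomial intraclass correlation over 30 x 30 m quadrats of nine
#' 10 x 10 m subcells scored visited/not per period.
#' @name metrics
NULL

#' Subsample a trajectory to the field observation schedule
#'
#' Per 30-day period, draws `days_per_month` days without replacement
#' (seeded) and keeps, within each selected day, the `2 * hours_per_day`
#' consecutive half-hour steps starting at 08:00 (step-in-day 2, 0-based,
#' for the 07:00-20:00 activity day). Months with fewer days available keep
#' them all. Only complete 30-day periods are used.
#'
#' @param trajectory data.frame with at least `day`, `step_in_day`, `x`, `y`
#' @param days_per_month observation days per period (default 5)
#' @param hours_per_day hours per observation day (default 7)
#' @param seed seed for the day draw
#' @return the subsampled trajectory with a `period` column
#' @export
subsample_observation <- function(trajectory, days_per_month = 5L,
                                  hours_per_day = 7L, seed = 1L) {
  n_periods <- floor(max(trajectory$day) / 30)
  if (n_periods < 1) stop("trajectory must cover at least one 30-day period")
  set.seed(seed)
  keep_days <- integer(0)
  for (p in seq_len(n_periods)) {
    days <- sort(unique(trajectory$day[trajectory$day > (p - 1) * 30 &
                                       trajectory$day <= p * 30]))
    k <- min(days_per_month, length(days))
    keep_days <- c(keep_days, sort(sample(days, k)))
  }
  steps <- 2L:(2L + 2L * hours_per_day - 1L)
  out <- trajectory[trajectory$day %in% keep_days &
                    trajectory$step_in_day %in% steps, , drop = FALSE]
  out$period <- (out$day - 1L) %/% 30L + 1L
  rownames(out) <- NULL
  out
}

#' Daily movement summaries
#'
#' For each observation day: `d_total`, the summed displacement between
#' consecutive centre fixes; `d_net`, the straight-line displacement from
#' first to last fix; `tortuosity = ln(d_total / d_net^2)` (`NA`, and
#' excluded from mean tortuosity, when `d_net = 0`); and the day's mean
#' group spread if a `spread` column is present. Days with fewer than two
#' fixes are dropped with a warning.
#'
#' @param trajectory a (typically subsampled) trajectory data.frame with
#'   `day`, `step`, `x`, `y` and optionally `spread`
#' @return data.frame with one row per retained day: `day`, `d_total`,
#'   `d_net`, `tortuosity`, `spread_mean`
#' @export
daily_metrics <- function(trajectory) {
  split_days <- split(trajectory, trajectory$day)
  short <- vapply(split_days, nrow, 0L) < 2L
  if (any(short)) {
    warning(sprintf("%d day(s) with a single fix dropped", sum(short)))
    split_days <- split_days[!short]
  }
  if (length(split_days) == 0)
    return(data.frame(day = integer(0), d_total = numeric(0),
                      d_net = numeric(0), tortuosity = numeric(0),
                      spread_mean = numeric(0)))
  rows <- lapply(split_days, function(d) {
    d <- d[order(d$step), ]
    dx <- diff(d$x); dy <- diff(d$y)
    d_total <- sum(sqrt(dx^2 + dy^2))
    d_net <- sqrt((d$x[nrow(d)] - d$x[1])^2 + (d$y[nrow(d)] - d$y[1])^2)
    tort <- if (d_net > 0 && d_total > 0) log(d_total / d_net^2) else NA_real_
    data.frame(day = d$day[1], d_total = d_total, d_net = d_net,
               tortuosity = tort,
               spread_mean = if ("spread" %in% names(d)) mean(d$spread)
                             else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Adjusted Fisher-Pearson sample skewness
#'
#' `G1 = g1 * sqrt(n (n - 1)) / (n - 2)` with `g1 = m3 / m2^(3/2)` on the
#' biased central moments.
#'
#' @param x numeric sample, `n >= 3` with nonzero variance
#' @return skewness
#' @export
skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) stop("skewness needs at least 3 observations")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("skewness undefined for zero-variance sample")
  g1 <- mean((x - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Grid-cell home range
#'
#' Number of distinct 30 x 30 m cells visited by the group centre within
#' each 30-day period, converted to hectares (x 0.09), consistent with the
#' model's own grid resolution.
#'
#' @param trajectory a (typically subsampled) trajectory data.frame; a
#'   `period` column is added if absent
#' @param cell_size metres (default 30)
#' @return data.frame: `period`, `cells`, `hectares`
#' @export
home_range <- function(trajectory, cell_size = 30) {
  if (!"period" %in% names(trajectory))
    trajectory$period <- (trajectory$day - 1L) %/% 30L + 1L
  res <- lapply(split(trajectory, trajectory$period), function(d) {
    cells <- unique(paste(floor(d$x / cell_size), floor(d$y / cell_size)))
    data.frame(period = d$period[1], cells = length(cells),
               hectares = length(cells) * cell_size^2 / 1e4)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Beta-binomial log-likelihood for counts k out of size n, up to the
# k-independent binomial coefficient (constant in alpha, beta).
bb_negll <- function(logab, k, n) {
  a <- exp(logab[1]); b <- exp(logab[2])
  -sum(lbeta(k + a, n - k + b) - lbeta(a, b))
}

#' Spatio-temporal beta-binomial aggregation index
#'
#' For each 30-day period, every 30 x 30 m quadrat inside the landscape
#' extent is scored `k` out of `n = 9`: how many of its nine 10 x 10 m
#' subcells received at least one centre fix during the period (a point
#' visit, matching point-sampled field data). A beta-binomial is fitted to
#' the quadrat counts by maximum likelihood, and the aggregation index is
#' the intraclass correlation `theta = 1 / (alpha + beta + 1)`: near 0 when
#' visits spread binomially over the range, large when few sites are
#' revisited often. Reported as the per-period estimates plus the mean over
#' periods with its t-based 95% confidence interval.
#'
#' @param trajectory a (typically subsampled) trajectory data.frame covering
#'   at least one full 30-day period
#' @param extent `c(width, height)` of the landscape in metres (default the
#'   108-ha world, 1200 x 900); quadrats are restricted to this extent
#' @param quadrat_size,subcell_size metres
#' @return list: `per_period` (data.frame `period`, `theta`, `alpha`,
#'   `beta`, `n_quadrats`), `mean_theta`, `ci` (95% CI of the mean),
#'   `n_periods`
#' @export
stbbd_theta <- function(trajectory, extent = c(1200, 900),
                        quadrat_size = 30, subcell_size = 10) {
  if (!"period" %in% names(trajectory))
    trajectory$period <- (trajectory$day - 1L) %/% 30L + 1L
  nq_x <- floor(extent[1] / quadrat_size)
  nq_y <- floor(extent[2] / quadrat_size)
  n_sub <- (quadrat_size / subcell_size)^2
  rows <- list()
  for (p in sort(unique(trajectory$period))) {
    d <- trajectory[trajectory$period == p, ]
    inside <- d$x >= 0 & d$x < extent[1] & d$y >= 0 & d$y < extent[2]
    d <- d[inside, ]
    sub_id <- paste(floor(d$x / subcell_size), floor(d$y / subcell_size))
    quad_of_sub <- paste(floor(d$x / quadrat_size),
                         floor(d$y / quadrat_size))
    visited <- !duplicated(sub_id)
    k_visited <- table(quad_of_sub[visited])
    k <- integer(nq_x * nq_y)  # all in-extent quadrats, zeros included
    qx <- as.integer(sub(" .*", "", names(k_visited)))
    qy <- as.integer(sub(".* ", "", names(k_visited)))
    k[qx * nq_y + qy + 1L] <- as.integer(k_visited)
    if (all(k == 0)) {
      warning(sprintf("period %d has no visits; theta undefined, skipped", p))
      next
    }
    fit <- stats::optim(c(0, 0), bb_negll, k = k, n = n_sub,
                        method = "L-BFGS-B", lower = -25, upper = 25)
    a <- exp(fit$par[1]); b <- exp(fit$par[2])
    rows[[length(rows) + 1L]] <- data.frame(
      period = p, theta = 1 / (a + b + 1), alpha = a, beta = b,
      n_quadrats = length(k))
  }
  per_period <- if (length(rows)) do.call(rbind, rows) else
    data.frame(period = integer(0), theta = numeric(0), alpha = numeric(0),
               beta = numeric(0), n_quadrats = integer(0))
  m <- nrow(per_period)
  mean_theta <- if (m) mean(per_period$theta) else NA_real_
  ci <- if (m >= 2) {
    se <- stats::sd(per_period$theta) / sqrt(m)
    mean_theta + c(-1, 1) * stats::qt(0.975, m - 1) * se
  } else c(NA_real_, NA_real_)
  list(per_period = per_period, mean_theta = mean_theta, ci = ci,
       n_periods = m)
}

#' Compare a simulated and an observed sample
#'
#' Two-sample Kolmogorov-Smirnov test (asymptotic p) and Welch's two-sample
#' t-test with Satterthwaite degrees of freedom. Daily step-length samples
#' are mean-centred first (`center = TRUE`), since the mean was consumed by
#' model calibration; tortuosity samples are compared as-is.
#'
#' @param simulated,observed numeric samples
#' @param center subtract each sample's mean before comparing?
#' @return list: `ks_d`, `ks_p`, `welch_t`, `welch_df`, `welch_p`
#' @export
compare_distributions <- function(simulated, observed, center = FALSE) {
  simulated <- simulated[is.finite(simulated)]
  observed <- observed[is.finite(observed)]
  if (!length(simulated) || !length(observed))
    stop("both samples must be nonempty")
  if (center) {
    simulated <- simulated - mean(simulated)
    observed <- observed - mean(observed)
  }
  ks <- suppressWarnings(stats::ks.test(simulated, observed, exact = FALSE))
  tt <- stats::t.test(simulated, observed, var.equal = FALSE)
  list(ks_d = unname(ks$statistic), ks_p = ks$p.value,
       welch_t = unname(tt$statistic), welch_df = unname(tt$parameter),
       welch_p = tt$p.value)
}

#' One-row feature summary of a trial
#'
#' The per-run export feeding any external regression-tree analysis: agent
#' type fields plus mean daily step length, step-length skew, mean
#' tortuosity, mean group spread, mean monthly home range, and the
#' aggregation index with its CI — all on the subsampled observation
#' schedule.
#'
#' @param trial a `foraging_trial`
#' @param obs_seed seed for the observation-day draw (defaults to the trial
#'   seed)
#' @return one-row data.frame
#' @export
trial_features <- function(trial, obs_seed = trial$config$seed) {
  obs <- subsample_observation(trial$trajectory, seed = obs_seed)
  dm <- daily_metrics(obs)
  hr <- home_range(trial$trajectory)  # full trajectory: range use, not fixes
  ext <- c(trial$landscape$n_cols, trial$landscape$n_rows) *
    trial$landscape$cell_size
  th <- stbbd_theta(obs, extent = ext)
  data.frame(
    social_rule = trial$config$social_rule,
    memory_mode = trial$config$memory_mode,
    retention = trial$config$retention,
    seed = trial$config$seed,
    mean_step = mean(dm$d_total),
    step_skew = tryCatch(skewness(dm$d_total), error = function(e) NA_real_),
    mean_tortuosity = mean(dm$tortuosity, na.rm = TRUE),
    mean_spread = mean(obs$spread),
    mean_home_range_ha = mean(hr$hectares),
    theta = th$mean_theta,
    theta_lo = th$ci[1], theta_hi = th$ci[2])
}
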
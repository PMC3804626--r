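# synthetic trajectory helper: a data.frame shaped like a trial trajectory
fake_traj <- function(days, fn, steps_per_day = 26) {
  steps <- days * steps_per_day
  df <- data.frame(step = 1:steps,
                   day = rep(1:days, each = steps_per_day),
                   step_in_day = rep(0:(steps_per_day - 1), times = days))
  xy <- fn(df)
  df$x <- xy[, 1]; df$y <- xy[, 2]
  df
}

test_that("subsample_observation draws 5 days x 14 steps per period", {
  tr <- fake_traj(180, function(d) cbind(d$step, 0))
  obs <- subsample_observation(tr, seed = 4)
  expect_equal(nrow(obs), 6 * 5 * 14)  # 420 points over 6 months
  expect_equal(length(unique(obs$day)), 30)
  expect_true(all(obs$step_in_day >= 2 & obs$step_in_day <= 15))
  expect_equal(sort(unique(obs$period)), 1:6)
  expect_true(all(tapply(obs$day, obs$period, function(d)
    length(unique(d))) == 5))

  # identity on days when the quota exceeds availability
  obs_all <- subsample_observation(tr[tr$day <= 30, ], days_per_month = 40,
                                   seed = 1)
  expect_equal(length(unique(obs_all$day)), 30)

  # seeded determinism
  expect_identical(subsample_observation(tr, seed = 9),
                   subsample_observation(tr, seed = 9))
  expect_error(subsample_observation(tr[tr$day <= 10, ]), "period")
})

test_that("daily_metrics: straight day, closed loop, printed-value check", {
  # straight-line day of 14 fixes 10 m apart: D_total = D_net = 130
  tr <- fake_traj(30, function(d) cbind(10 * d$step_in_day, 0))
  obs <- subsample_observation(tr, seed = 2)
  dm <- daily_metrics(obs)
  expect_true(all(abs(dm$d_total - 130) < 1e-9))
  expect_true(all(abs(dm$d_net - 130) < 1e-9))
  expect_equal(dm$tortuosity, rep(log(1 / 130), nrow(dm)))

  # closed loop: the 14 observation fixes (steps 2..15) walk a rectangle
  # back to the exact start, so d_net = 0 and tortuosity is excluded
  square <- rbind(c(0, 0), c(10, 0), c(20, 0), c(30, 0), c(30, 10),
                  c(30, 20), c(30, 30), c(20, 30), c(10, 30), c(0, 30),
                  c(0, 20), c(0, 10), c(0, 5), c(0, 0))
  loop <- fake_traj(30, function(d) {
    i <- pmin(pmax(d$step_in_day - 2, 0), 13) + 1
    square[i, , drop = FALSE]
  })
  obs_l <- subsample_observation(loop, seed = 2)
  dm_l <- daily_metrics(obs_l)
  expect_true(all(is.na(dm_l$tortuosity)))

  # the tortuosity functional form at the observed scale:
  # D_total 213, D_net 35 -> ln(213/35^2) ~ -1.749, near the field mean -1.69
  expect_equal(log(213 / 35^2), -1.749, tolerance = 5e-4)

  # single-fix days are dropped with a warning
  tr1 <- tr[tr$step_in_day == 2 | (tr$day > 1 & tr$step_in_day <= 5), ]
  tr1 <- tr1[tr1$day <= 3, ]
  expect_warning(daily_metrics(tr1), "single fix")
})

test_that("skewness matches the brute-force moment computation", {
  expect_equal(skewness(c(1, 2, 3)), 0)
  expect_gt(skewness(c(1, 1, 1, 10)), 0)
  set.seed(31)
  for (i in 1:30) {
    x <- rgamma(sample(10:200, 1), shape = runif(1, 0.5, 5))
    expect_equal(skewness(x), bf_skewness(x), tolerance = 1e-12)
  }
  expect_error(skewness(c(1, 2)), "at least 3")
  expect_error(skewness(rep(4, 10)), "zero-variance")
})

test_that("group_spread is the convex hull area", {
  expect_equal(group_spread(rbind(c(0, 0), c(1, 0), c(0, 1))), 0.5)
  expect_equal(group_spread(rbind(c(0, 0), c(30, 0), c(30, 30), c(0, 30))),
               900)
  expect_equal(group_spread(rbind(c(0, 0), c(10, 10), c(20, 20))), 0)
  expect_equal(group_spread(rbind(c(0, 0), c(5, 5))), 0)
  set.seed(17)
  for (i in 1:120) {
    n <- sample(3:40, 1)
    pts <- cbind(runif(n, 0, 200), runif(n, 0, 200))
    expect_equal(group_spread(pts), bf_hull_area(pts), tolerance = 1e-9)
    expect_equal(groupforage:::.hull_area_cpp(pts), bf_hull_area(pts),
                 tolerance = 1e-9)
  }
})

test_that("home_range counts distinct cells at 0.09 ha each", {
  tr <- fake_traj(30, function(d) cbind(45, 45))  # never leaves one cell
  expect_equal(home_range(tr)$hectares, 0.09)

  # a sweep crossing a known number of cells
  tr2 <- fake_traj(30, function(d) cbind((d$step %% 228) * 30 + 15, 15))
  expect_equal(home_range(tr2)$cells, 228)
  expect_equal(home_range(tr2)$hectares, 20.52)

  # monotone nondecreasing in observation duration
  tr3 <- fake_traj(60, function(d) cbind(d$step * 2 %% 1200, d$step %% 900))
  hr3 <- home_range(tr3)
  expect_equal(nrow(hr3), 2)
  h_first_half <- home_range(tr3[tr3$day <= 15, ])$hectares
  expect_gte(hr3$hectares[1], h_first_half)
})

test_that("stbbd_theta recovers binomial and beta-binomial regimes", {
  # build synthetic visit panels directly on the quadrat counts by placing
  # centre fixes: quadrat q gets k visited subcells
  panel_traj <- function(k_by_quadrat, period = 1) {
    rows <- list()
    step0 <- (period - 1) * 30 * 26
    nq_y <- 30
    for (q in seq_along(k_by_quadrat)) {
      k <- k_by_quadrat[q]
      if (k == 0) next
      qx <- (q - 1) %/% nq_y; qy <- (q - 1) %% nq_y
      for (s in seq_len(k)) {  # subcells 0..8 within the quadrat
        sx <- (s - 1) %/% 3; sy <- (s - 1) %% 3
        rows[[length(rows) + 1]] <- data.frame(
          step = step0 + length(rows) + 1, day = (period - 1) * 30 + 1,
          step_in_day = 2,
          x = qx * 30 + sx * 10 + 5, y = qy * 30 + sy * 10 + 5)
      }
    }
    do.call(rbind, rows)
  }

  set.seed(23)
  # binomial visits: theta ~ 0
  k_bin <- rbinom(1200, 9, 0.4)
  th_bin <- stbbd_theta(panel_traj(k_bin))
  expect_lt(th_bin$per_period$theta, 0.02)

  # beta-binomial alpha=1, beta=4: theta = 1/6
  k_bb <- rbinom(1200, 9, rbeta(1200, 1, 4))
  th_bb <- stbbd_theta(panel_traj(k_bb))
  expect_equal(th_bb$per_period$theta, 1 / 6, tolerance = 0.05)

  # maximal aggregation: a few quadrats fully visited, rest empty
  k_max <- integer(1200); k_max[sample(1200, 25)] <- 9
  th_max <- stbbd_theta(panel_traj(k_max))
  expect_gt(th_max$per_period$theta, 0.8)

  # several periods give a CI of the mean
  tr6 <- do.call(rbind, lapply(1:3, function(p)
    panel_traj(rbinom(1200, 9, rbeta(1200, 1, 4)), period = p)))
  th6 <- stbbd_theta(tr6)
  expect_equal(th6$n_periods, 3)
  expect_true(th6$ci[1] < th6$mean_theta && th6$mean_theta < th6$ci[2])
})

test_that("compare_distributions: KS edge cases, oracle, centring", {
  x <- rnorm(50)
  expect_equal(compare_distributions(x, x)$ks_d, 0)
  expect_equal(compare_distributions(1:20, 101:120)$ks_d, 1)
  set.seed(41)
  for (i in 1:40) {
    a <- rnorm(sample(10:80, 1)); b <- rnorm(sample(10:80, 1), mean = 0.5)
    expect_equal(compare_distributions(a, b)$ks_d, bf_ks_d(a, b),
                 tolerance = 1e-12)
  }
  # centring removes a pure location shift entirely (exact dyadic values so
  # the shifted means cancel without floating-point residue)
  xd <- (1:50) / 4
  cmp <- compare_distributions(xd + 100, xd, center = TRUE)
  expect_equal(cmp$ks_d, 0)
  expect_error(compare_distributions(numeric(0), x), "nonempty")
})
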
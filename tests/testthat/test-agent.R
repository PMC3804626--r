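p <- default_params

test_that("derived energetic constants balance the day", {
  expect_equal(p$steps_per_day, 26L)        # 13 h at half-hour steps
  expect_equal(p$feeding_steps, 11)         # floor(0.43 * 26)
  expect_equal(p$energy_decay, 100 / 26)
  expect_equal(p$gain_per_feed, 100 / 11)
  expect_equal(11 * p$gain_per_feed - 26 * p$energy_decay, 0)
})

test_that("food_site_index is distance over resources with exclusions", {
  # d = 30 at r = 10 -> 3.0; d = 20 at r = 10 -> 2.0, preferred
  pos <- c(15, 15)
  cells <- rbind(c(1, 0), c(0, 0))  # centres (45,15) d=30; (15,15) d=0
  expect_equal(food_site_index(c(15, 45), rbind(c(0, 0)), 10), 3.0)
  expect_equal(food_site_index(c(15, 35), rbind(c(0, 0)), 10), 2.0)
  expect_equal(food_site_index(pos, rbind(c(0, 0)), 10), 0)  # on site: best
  expect_equal(food_site_index(pos, cells, c(0, 5)), c(Inf, 0))
})

test_that("is_safe counts the radius and honors the leader rule", {
  ag <- primate_agent(1, c(0, 0), desired_neighbors = 3)
  mates <- rbind(c(10, 0), c(20, 0), c(60, 0))
  expect_false(is_safe(ag, mates, p))          # only 2 of 3 within 50 m
  ag$desired_neighbors <- 2L
  expect_true(is_safe(ag, mates, p))
  ag$desired_neighbors <- 0L
  expect_true(is_safe(ag, mates[0, , drop = FALSE], p))  # 0 needed: safe

  # leader rule: leader at 40 m -> safe regardless of desired count
  ag$desired_neighbors <- 60L
  expect_true(is_safe(ag, mates, p, leader_position = c(40, 0)))
  expect_false(is_safe(ag, mates, p, leader_position = c(80, 0)))
  # leader beyond sensing range: independent fallback applies
  ag$desired_neighbors <- 2L
  expect_true(is_safe(ag, mates, p, leader_position = c(500, 0)))
  # the leader itself uses the independent rule
  ldr <- primate_agent(0, c(0, 0), desired_neighbors = 2, is_leader = TRUE)
  expect_true(is_safe(ldr, mates, p, leader_position = c(0, 0)))
})

test_that("adapt_safety moves the desired count by one with clamps", {
  ag <- primate_agent(1, c(0, 0), desired_neighbors = 5)
  expect_equal(adapt_safety(ag, TRUE, TRUE, 70)$desired_neighbors, 6L)
  expect_equal(adapt_safety(ag, FALSE, FALSE, 70)$desired_neighbors, 4L)
  expect_equal(adapt_safety(ag, TRUE, FALSE, 70)$desired_neighbors, 5L)
  ag$desired_neighbors <- 0L
  expect_equal(adapt_safety(ag, FALSE, FALSE, 70)$desired_neighbors, 0L)
  ag$desired_neighbors <- 69L
  expect_equal(adapt_safety(ag, TRUE, TRUE, 70)$desired_neighbors, 69L)
})

test_that("movement_choice: rest, social cohesion with cap, forage", {
  l <- make_uniform_landscape()
  ag <- primate_agent(1, c(200, 50), energy = 100, desired_neighbors = 0)
  expect_equal(movement_choice(ag, l, rbind(c(0, 0)), p)$action, "rest")

  # unsafe: head to the mean of the nearest two mates, clipped to 100 m
  ag2 <- primate_agent(1, c(150, 50), energy = 100, desired_neighbors = 2)
  mv <- movement_choice(ag2, l, rbind(c(0, 0), c(0, 100)), p)
  expect_equal(mv$action, "move")
  expect_equal(mv$target, c(50, 50))  # toward the mean (0,50), capped 100 m
  expect_equal(sqrt(sum((mv$target - ag2$position)^2)), 100)

  # unsafe with nobody sensed: rest
  mv2 <- movement_choice(ag2, l, rbind(c(900, 900)), p)
  expect_equal(mv2$action, "rest")

  # safe and hungry with a single visible food cell: enters that cell
  l3 <- make_uniform_landscape(10, 8)
  l3$current[] <- 0
  l3$current[2, 2] <- 50   # cell (1,1), centre (45,45)
  ag3 <- primate_agent(1, c(50, 50), energy = 50, desired_neighbors = 0)
  mv3 <- movement_choice(ag3, l3, rbind(c(10, 10)), p)
  expect_equal(mv3$detail$kind, "direct")
  expect_equal(mv3$detail$cell, c(1, 1))
})

test_that("choose_destination branches: direct, stepping stone, toward", {
  l <- make_uniform_landscape(10, 8)
  ag <- primate_agent(1, c(75, 75), energy = 50, desired_neighbors = 0)

  # everything visible and safe: direct to the best-index cell
  d1 <- choose_destination(ag, l, rbind(c(75, 75)), p)
  expect_equal(d1$kind, "direct")

  # remembered goal far away: one capped hop per step in its direction
  l2 <- make_uniform_landscape(20, 8)
  l2$current[] <- 0
  mem <- initialize_memory(l2, 3)
  mem$sites <- data.frame(col = 17, row = 2, x = 525, y = 75,
                          max_level = 2000, believed = 2000,
                          last_seen = NA_integer_)
  mem$retention <- 1
  mem$adjacency <- list(1L)
  ag2 <- primate_agent(1, c(75, 75), energy = 50, desired_neighbors = 0,
                       memory = mem)
  d2 <- choose_destination(ag2, l2, rbind(c(75, 75)), p)
  expect_equal(d2$kind, "toward")
  expect_equal(d2$goal, c(17, 2))
  expect_equal(sqrt(sum((d2$target - ag2$position)^2)), 100)  # capped hop
  expect_equal(d2$target[2], 75)  # straight toward the goal

  # visible stepping stone chosen when the goal is remembered but far
  l3 <- l2
  l3$current[3, 4] <- 40   # cell (3,2), centre (105,75): visible, en route
  d3 <- choose_destination(ag2, l3, rbind(c(75, 75)), p)
  expect_equal(d3$kind, "step")
  expect_equal(d3$cell, c(3, 2))

  # nothing visible, nothing recallable: exploration
  ag3 <- primate_agent(1, c(75, 75), energy = 50, desired_neighbors = 0)
  d4 <- choose_destination(ag3, l2, rbind(c(75, 75)), p)
  expect_equal(d4$kind, "explore")
})

test_that("destination choice matches brute force and the compiled core", {
  for (seed in 1:60) {
    for (mode in c("euclidean", "landmark")) {
      sc <- random_scene(seed * 2 + (mode == "landmark"), mode)
      ag <- primate_agent(1, sc$pos, energy = 50,
                          desired_neighbors = sample(0:3, 1),
                          memory = sc$memory)
      got <- choose_destination(ag, sc$landscape, sc$mates, p)
      want <- bf_choose_goal(sc$pos, sc$landscape, sc$memory, p)
      if (is.null(want)) {
        expect_equal(got$kind, "explore")
      } else {
        expect_equal(got$goal, c(want$col, want$row))
      }
      # compiled core agrees branch-for-branch with the R reference
      rc <- recall_candidates(sc$memory, sc$pos)
      s <- sc$memory$sites[rc, , drop = FALSE]
      cpp <- groupforage:::.choose_destination_cpp(
        sc$pos, sc$landscape$current, sc$landscape$cell_size,
        as.integer(s$col), as.integer(s$row), s$believed,
        sc$mates, ag$desired_neighbors, numeric(0), p)
      expect_equal(cpp$kind, got$kind)
      if (got$kind %in% c("direct", "step"))
        expect_equal(cpp$cell, got$cell)
      if (got$kind != "explore")
        expect_equal(cpp$goal, got$goal)
    }
  }
})

test_that("energetics: decay, floor, feeding and the daily balance", {
  l <- make_uniform_landscape(5, 4, total = 2800)
  ag <- primate_agent(1, c(45, 45), energy = 50)
  st <- energetics_step(ag, l, p)
  expect_true(st$fed)
  expect_equal(st$agent$energy, 50 - 100 / 26 + 100 / 11)
  expect_equal(st$landscape$current[2, 2], 140 - 100 / 11)

  # 11 full feeds + 26 decays net to zero over a day
  ag2 <- primate_agent(1, c(45, 45), energy = 90)
  e <- ag2$energy
  e <- e - 26 * p$energy_decay + 11 * p$gain_per_feed
  expect_equal(e, 90)

  # floor at zero on an empty cell
  l0 <- l; l0$current[] <- 0
  ag3 <- primate_agent(1, c(45, 45), energy = 1)
  st3 <- energetics_step(ag3, l0, p)
  expect_equal(st3$agent$energy, 0)
  expect_false(st3$fed)

  # at target: no feeding attempt, landscape untouched
  ag4 <- primate_agent(1, c(45, 45), energy = 100 + p$energy_decay)
  st4 <- energetics_step(ag4, l, p)
  expect_false(st4$fed)
  expect_identical(st4$landscape$current, l$current)
})

test_that("engine invariants: step cap, desired bounds, self-sufficiency", {
  # two-day full-group run with snapshots: no agent displacement > 100 m,
  # desired_neighbors within [0, n-1]
  cfg <- simulation_config("independent:euclidean:20", group_size = 25,
                           days = 2, seed = 5, n_cols = 20, n_rows = 15,
                           n_hotspots = 20, total_resources = 84000)
  tr <- run_trial(cfg, record_agents = TRUE)
  sn <- tr$snapshots
  for (id in unique(sn$id)) {
    s <- sn[sn$id == id, ]
    d <- sqrt(diff(s$x)^2 + diff(s$y)^2)
    expect_true(all(d <= 100 + 1e-6))
    expect_true(all(s$desired_neighbors >= 0 &
                    s$desired_neighbors <= cfg$group_size - 1))
  }
  expect_true(all(sn$energy >= 0))

  # lone agent, whole-landscape memory, abundant food: long-run mean energy
  # stays within one decay quantum of target
  cfg1 <- simulation_config("independent:euclidean:100", group_size = 1,
                            days = 10, seed = 3, n_cols = 10, n_rows = 10,
                            n_hotspots = 10, total_resources = 140000)
  cfg1$retention <- 100L
  tr1 <- run_trial(cfg1, record_agents = TRUE)
  tail_e <- tr1$snapshots$energy[tr1$snapshots$step > 130]
  expect_gte(mean(tail_e), 100 - 100 / 26)
})
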
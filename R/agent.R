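#' @title Per-agent behavior: energetics, safety, and food-site choice
#'
#' @description
#' Each agent is a point in continuous space balancing two needs: staying
#' safe (keeping a desired number of group mates — or the leader — within a
#' safe radius) and staying fed (maintaining a target energy level). The
#' desired-neighbor count adapts: a sated agent raises it by one (prioritizing
#' safety), an agent below target that failed to feed lowers it by one
#' (prioritizing foraging). Movement follows a fixed decision tree: unsafe
#' agents move toward group mates; safe, sated agents rest; safe, hungry
#' agents head for the food site minimizing the food-site index
#' `I = d / r` (distance over expected resources).
#'
#' These R functions are the reference semantics for the compiled trial
#' engine and the surface the unit tests exercise.
#' @name agent
NULL

#' Behavioral parameter set
#'
#' Defaults are the calibrated model values: vision 50 m, social sensing
#' 200 m, safe radius 50 m, max 100 m per half-hour step, target energy 100
#' units over a 26-step (13 h) day with 43% of steps spent feeding. Derived
#' quantities: energy decay per step `target_energy / steps_per_day`
#' (~3.846), feeding steps per day `floor(feed_fraction * steps_per_day)`
#' (= 11), and gain per feeding event `target_energy / feeding_steps`
#' (~9.091) — so a full day of feeding exactly balances a full day of decay.
#'
#' @param visual_range,social_range,safe_radius,max_step metres
#' @param target_energy energy units
#' @param steps_per_day half-hour steps in the 13-h active day
#' @param feed_fraction fraction of the day spent feeding
#' @return a `behavior_params` list including the derived `energy_decay`,
#'   `feeding_steps` and `gain_per_feed`
#' @export
behavior_params <- function(visual_range = 50, social_range = 200,
                            safe_radius = 50, max_step = 100,
                            target_energy = 100, steps_per_day = 26L,
                            feed_fraction = 0.43) {
  stopifnot(visual_range > 0, social_range > 0, safe_radius > 0,
            max_step > 0, target_energy > 0, steps_per_day > 0,
            feed_fraction > 0, feed_fraction < 1)
  feeding_steps <- floor(feed_fraction * steps_per_day)
  structure(list(
    visual_range = visual_range, social_range = social_range,
    safe_radius = safe_radius, max_step = max_step,
    target_energy = target_energy, steps_per_day = as.integer(steps_per_day),
    feed_fraction = feed_fraction,
    energy_decay = target_energy / steps_per_day,
    feeding_steps = feeding_steps,
    gain_per_feed = target_energy / feeding_steps
  ), class = "behavior_params")
}

#' Construct an agent
#'
#' @param id integer id (the leader, where present, is id 0)
#' @param position numeric `c(x, y)` metres
#' @param energy starting energy (default: at target)
#' @param desired_neighbors starting desired nearby group mates (default 5)
#' @param memory a `spatial_memory` or `NULL`
#' @param is_leader logical
#' @return a `primate_agent` list
#' @export
primate_agent <- function(id, position, energy = 100, desired_neighbors = 5L,
                          memory = NULL, is_leader = FALSE) {
  stopifnot(length(position) == 2, energy >= 0, desired_neighbors >= 0)
  structure(list(id = as.integer(id), position = as.numeric(position),
                 energy = energy,
                 desired_neighbors = as.integer(desired_neighbors),
                 memory = memory, is_leader = isTRUE(is_leader)),
            class = "primate_agent")
}

#' Food-site index
#'
#' `I(x', y') = d((x, y), (x', y')) / r(x', y')`: Euclidean distance from the
#' agent to the site's cell centre divided by the expected (seen or believed)
#' resources there. Lower is better. Sites with non-positive expected
#' resources are excluded from ranking (index `Inf`), not an error.
#'
#' @param agent_position numeric `c(x, y)`
#' @param site_cells matrix/data.frame with 0-based columns `col`, `row`
#' @param resources expected resources per site (recycled if length 1)
#' @param cell_size metres
#' @return numeric index per site
#' @export
food_site_index <- function(agent_position, site_cells, resources,
                            cell_size = 30) {
  site_cells <- as.matrix(site_cells)
  ctr <- cell_center(site_cells[, 1], site_cells[, 2], cell_size)
  d <- sqrt((ctr[, "x"] - agent_position[1])^2 +
            (ctr[, "y"] - agent_position[2])^2)
  idx <- ifelse(resources > 0, d / resources, Inf)
  unname(idx)
}

# Deterministic argmin over the food-site index. Ties: smaller distance,
# then (row, col) lexical order. Returns 0 if no site is rankable.
choose_goal <- function(agent_position, site_cells, resources,
                        cell_size = 30) {
  site_cells <- as.matrix(site_cells)
  if (nrow(site_cells) == 0) return(0L)
  ctr <- cell_center(site_cells[, 1], site_cells[, 2], cell_size)
  d <- sqrt((ctr[, "x"] - agent_position[1])^2 +
            (ctr[, "y"] - agent_position[2])^2)
  idx <- ifelse(resources > 0, d / resources, Inf)
  if (all(is.infinite(idx))) return(0L)
  ord <- order(idx, d, site_cells[, 2], site_cells[, 1])
  ord[1]
}

#' Safety check
#'
#' Independent rule: at least `desired_neighbors` group mates within
#' `safe_radius` of `position`. Leader rule (non-leaders in a leader-led
#' group): safe iff the leader is within `safe_radius`; if the leader is
#' beyond `social_range` (not sensed) the agent falls back to the independent
#' rule. The leader itself always uses the independent rule.
#'
#' @param agent a `primate_agent`
#' @param mate_positions matrix of mate `(x, y)` rows, excluding the agent
#' @param params a `behavior_params`
#' @param leader_position the leader's `c(x, y)` for leader-led groups, or
#'   `NULL` for independently led groups
#' @param position evaluate safety as if the agent stood here (defaults to
#'   its current position; used for safety-at-destination tests)
#' @return logical
#' @export
is_safe <- function(agent, mate_positions, params,
                    leader_position = NULL, position = agent$position) {
  mate_positions <- matrix(as.numeric(mate_positions), ncol = 2)
  if (!is.null(leader_position) && !agent$is_leader) {
    sensed <- sqrt(sum((agent$position - leader_position)^2)) <=
      params$social_range
    if (sensed) {
      return(sqrt(sum((position - leader_position)^2)) <= params$safe_radius)
    } # leader out of sensing range: fall through to independent rule
  }
  if (agent$desired_neighbors == 0L) return(TRUE)
  if (nrow(mate_positions) == 0) return(FALSE)
  d <- sqrt((mate_positions[, 1] - position[1])^2 +
            (mate_positions[, 2] - position[2])^2)
  sum(d <= params$safe_radius) >= agent$desired_neighbors
}

#' Adapt the desired-neighbor count
#'
#' Applied once at the start of each agent step: at target energy the agent
#' wants one more neighbor (clamped at `group_size - 1`); below target and
#' having failed to feed last step it wants one fewer (clamped at 0); below
#' target but fed, it stays put.
#'
#' @param agent a `primate_agent`
#' @param fed_last_step did the agent obtain food during its previous step?
#' @param at_target_energy is energy at/above target now?
#' @param group_size total group size (upper clamp is `group_size - 1`)
#' @return the updated agent
#' @export
adapt_safety <- function(agent, fed_last_step, at_target_energy, group_size) {
  if (at_target_energy) {
    agent$desired_neighbors <- min(agent$desired_neighbors + 1L,
                                   group_size - 1L)
  } else if (!fed_last_step) {
    agent$desired_neighbors <- max(agent$desired_neighbors - 1L, 0L)
  }
  agent
}

# Cells whose centre lies within `range` of `position`, with current levels.
visible_cells <- function(landscape, position, range) {
  cs <- landscape$cell_size
  span <- ceiling(range / cs)
  c0 <- max(0L, floor(position[1] / cs) - span)
  c1 <- min(landscape$n_cols - 1L, floor(position[1] / cs) + span)
  r0 <- max(0L, floor(position[2] / cs) - span)
  r1 <- min(landscape$n_rows - 1L, floor(position[2] / cs) + span)
  if (c1 < c0 || r1 < r0)
    return(data.frame(col = integer(0), row = integer(0),
                      x = numeric(0), y = numeric(0), current = numeric(0)))
  g <- expand.grid(col = c0:c1, row = r0:r1)
  ctr <- cell_center(g$col, g$row, cs)
  d <- sqrt((ctr[, "x"] - position[1])^2 + (ctr[, "y"] - position[2])^2)
  keep <- d <= range
  data.frame(col = g$col[keep], row = g$row[keep],
             x = ctr[keep, "x"], y = ctr[keep, "y"],
             current = landscape$current[cbind(g$row[keep] + 1L,
                                               g$col[keep] + 1L)])
}

#' Choose a foraging destination (deterministic part)
#'
#' Candidates are the visible food-bearing cells (true levels) plus the
#' recallable remembered sites with positive believed resources (believed
#' levels; a remembered site inside visual range is judged by eye, not by
#' memory). The goal is the candidate minimizing the food-site index. If the
#' goal is visible, reachable in one step, and the move is safe (the safety
#' rule evaluated at the goal with mates at their current positions), the
#' agent goes directly. Otherwise it picks a stepping stone: among visible
#' food cells within one step that are safe, the one minimizing
#' `d(cell, goal) / r(cell)` (the food-site index with distance-to-goal as
#' the distance factor); if no stepping stone qualifies the agent simply
#' heads toward the goal, capped at `max_step`. With no candidates at all the
#' agent explores: a uniform-random heading with step length uniform in
#' `(0, max_step]`.
#'
#' The randomized parts (landing point inside the chosen cell, exploration
#' draw) are left to the caller so this decision is deterministic and
#' testable; the returned `kind` says which branch fired.
#'
#' @param agent a `primate_agent` (its `memory` supplies recall)
#' @param landscape a `resource_landscape`
#' @param mate_positions matrix of mate positions (for the safety test)
#' @param params a `behavior_params`
#' @param leader_position leader `c(x, y)` or `NULL`
#' @return list: `kind` in `"direct"`, `"step"`, `"toward"`, `"explore"`;
#'   `cell` = 0-based `c(col, row)` of the cell to enter (`NULL` for
#'   `"toward"`/`"explore"`); `goal` = goal cell or `NULL`; `target` = the
#'   deterministic target point (`NULL` for `"explore"`)
#' @export
choose_destination <- function(agent, landscape, mate_positions, params,
                               leader_position = NULL) {
  pos <- agent$position
  vis <- visible_cells(landscape, pos, params$visual_range)
  vis <- vis[vis$current > 0, , drop = FALSE]
  cand <- data.frame(col = vis$col, row = vis$row, r = vis$current)
  if (!is.null(agent$memory)) {
    rc <- recall_candidates(agent$memory, pos)
    if (length(rc)) {
      s <- agent$memory$sites[rc, , drop = FALSE]
      d <- sqrt((s$x - pos[1])^2 + (s$y - pos[2])^2)
      s <- s[d > params$visual_range & s$believed > 0, , drop = FALSE]
      if (nrow(s))
        cand <- rbind(cand,
                      data.frame(col = s$col, row = s$row, r = s$believed))
    }
  }
  if (nrow(cand) == 0) return(list(kind = "explore", cell = NULL,
                                   goal = NULL, target = NULL))
  gi <- choose_goal(pos, cand[, c("col", "row")], cand$r,
                    landscape$cell_size)
  if (gi == 0L) return(list(kind = "explore", cell = NULL,
                            goal = NULL, target = NULL))
  goal <- c(cand$col[gi], cand$row[gi])
  gctr <- as.numeric(cell_center(goal[1], goal[2], landscape$cell_size))
  dgoal <- sqrt(sum((gctr - pos)^2))
  if (dgoal <= params$visual_range && dgoal <= params$max_step &&
      is_safe(agent, mate_positions, params, leader_position,
              position = gctr)) {
    return(list(kind = "direct", cell = goal, goal = goal, target = gctr))
  }
  # stepping stone: visible food cells within one step, safe, best index
  # toward the goal
  if (nrow(vis)) {
    dstep <- sqrt((vis$x - pos[1])^2 + (vis$y - pos[2])^2)
    ok <- dstep <= params$max_step
    if (any(ok)) {
      v <- vis[ok, , drop = FALSE]
      dv <- dstep[ok]
      safe <- vapply(seq_len(nrow(v)), function(i)
        is_safe(agent, mate_positions, params, leader_position,
                position = c(v$x[i], v$y[i])), logical(1))
      if (any(safe)) {
        v <- v[safe, , drop = FALSE]; dv <- dv[safe]
        dg <- sqrt((v$x - gctr[1])^2 + (v$y - gctr[2])^2)
        idx <- dg / v$current
        ord <- order(idx, dv, v$row, v$col)
        b <- ord[1]
        return(list(kind = "step", cell = c(v$col[b], v$row[b]), goal = goal,
                    target = c(v$x[b], v$y[b])))
      }
    }
  }
  # no safe stepping stone: head for the goal, capped at max_step
  delta <- gctr - pos
  dd <- sqrt(sum(delta^2))
  tgt <- if (dd > params$max_step) pos + delta * params$max_step / dd else gctr
  list(kind = "toward", cell = NULL, goal = goal, target = tgt)
}

#' Top-level movement decision
#'
#' Unsafe agents move toward group mates: under the independent rule toward
#' the mean position of the nearest `desired_neighbors` mates within
#' `social_range` (all sensed mates if fewer; rest if none sensed); under the
#' leader rule toward the leader. Safe agents rest if at target energy,
#' otherwise forage via [choose_destination()]. Displacement is always capped
#' at `max_step`.
#'
#' @inheritParams choose_destination
#' @return list: `action` `"rest"` or `"move"`; for moves, `target` point and
#'   `detail` (the [choose_destination()] result for foraging moves,
#'   `"social"` for cohesion moves)
#' @export
movement_choice <- function(agent, landscape, mate_positions, params,
                            leader_position = NULL) {
  pos <- agent$position
  mate_positions <- matrix(as.numeric(mate_positions), ncol = 2)
  if (!is_safe(agent, mate_positions, params, leader_position)) {
    if (!is.null(leader_position) && !agent$is_leader &&
        sqrt(sum((pos - leader_position)^2)) <= params$social_range) {
      tgt <- leader_position
    } else {
      d <- sqrt((mate_positions[, 1] - pos[1])^2 +
                (mate_positions[, 2] - pos[2])^2)
      sensed <- which(d <= params$social_range)
      if (length(sensed) == 0) return(list(action = "rest"))
      take <- sensed[order(d[sensed])]
      take <- take[seq_len(min(max(agent$desired_neighbors, 1L),
                               length(take)))]
      tgt <- c(mean(mate_positions[take, 1]), mean(mate_positions[take, 2]))
    }
    delta <- tgt - pos
    dd <- sqrt(sum(delta^2))
    if (dd > params$max_step) tgt <- pos + delta * params$max_step / dd
    return(list(action = "move", target = tgt, detail = "social"))
  }
  if (agent$energy >= params$target_energy) return(list(action = "rest"))
  dest <- choose_destination(agent, landscape, mate_positions, params,
                             leader_position)
  list(action = "move", target = dest$target, detail = dest)
}

#' Energetics bookkeeping for one step
#'
#' Applied after movement: energy drops by the constant per-step decay
#' (`target_energy / steps_per_day`), floored at zero; then, if hungry
#' (below target) and standing on a cell with resources, the agent feeds,
#' harvesting up to `gain_per_feed` (`target_energy / feeding_steps`).
#'
#' @param agent a `primate_agent`
#' @param landscape a `resource_landscape`
#' @param params a `behavior_params`
#' @return list: updated `agent` and `landscape`, and `fed` (logical)
#' @export
energetics_step <- function(agent, landscape, params) {
  agent$energy <- max(agent$energy - params$energy_decay, 0)
  fed <- FALSE
  if (agent$energy < params$target_energy) {
    cell <- position_to_cell(agent$position[1], agent$position[2],
                             landscape$cell_size)
    if (cell[1] >= 0 && cell[1] < landscape$n_cols &&
        cell[2] >= 0 && cell[2] < landscape$n_rows) {
      h <- harvest(landscape, cell[1], cell[2], params$gain_per_feed)
      if (h$removed > 0) {
        agent$energy <- agent$energy + h$removed
        landscape <- h$landscape
        fed <- TRUE
      }
    }
  }
  list(agent = agent, landscape = landscape, fed = fed)
}

#' Write agent snapshots as CSV
#'
#' Columns: `step,id,x,y,energy,desired_neighbors`.
#'
#' @param snapshots data.frame of agent states over time
#' @param path file path
#' @export
write_agents_csv <- function(snapshots, path) {
  cols <- c("step", "id", "x", "y", "energy", "desired_neighbors")
  stopifnot(all(cols %in% names(snapshots)))
  utils::write.csv(snapshots[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
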
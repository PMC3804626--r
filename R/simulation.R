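#' @title Trial runner, scheduler, and group-centre estimation
#'
#' @description
#' A foraging trial runs a group of identical agents over a resource
#' landscape for a number of 26-step (13 h) days. Within each half-hour step
#' every agent — processed in a freshly randomized order — adapts its safety
#' demand, makes its movement choice, pays its energetic cost and feeds if it
#' can, and updates its spatial memory; then the landscape regrows one step
#' and the group centre is recorded. The centre estimator is recursive to be
#' robust to fission: the centroid must hold 80% of the whole group within a
#' 100-m buffer, otherwise the farthest member is dropped and the centroid
#' recomputed.
#' @name simulation
NULL

#' The twelve agent types
#'
#' Every combination of social rule (independent/leader), memory mode
#' (euclidean/landmark) and retention (20/60/100).
#'
#' @return data.frame with columns `social_rule`, `memory_mode`, `retention`,
#'   `label`
#' @export
all_agent_types <- function() {
  g <- expand.grid(retention = c(20L, 60L, 100L),
                   memory_mode = c("euclidean", "landmark"),
                   social_rule = c("independent", "leader"),
                   stringsAsFactors = FALSE)
  g <- g[, c("social_rule", "memory_mode", "retention")]
  g$label <- sprintf("%s:%s:%d", g$social_rule, g$memory_mode, g$retention)
  g
}

#' Parse an agent-type label
#'
#' @param label string `"<social>:<memory>:<retention>"`, e.g.
#'   `"leader:landmark:20"`
#' @return list with `social_rule`, `memory_mode`, `retention`
#' @export
parse_agent_type <- function(label) {
  parts <- strsplit(label, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3) stop("agent type must be social:memory:retention")
  social <- match.arg(parts[1], c("independent", "leader"))
  memory <- match.arg(parts[2], c("euclidean", "landmark"))
  retention <- as.integer(parts[3])
  if (is.na(retention) || retention <= 0) stop("bad retention in agent type")
  list(social_rule = social, memory_mode = memory, retention = retention)
}

#' Simulation configuration
#'
#' Bundles an agent type with group size, trial length, seed, landscape
#' parameters and behavioral parameters. Defaults are the calibrated model
#' values: 70 agents for 180 days (6 months) on a 40 x 30 grid of 30-m cells
#' (108 ha, 1,200 cells) holding 168,000 energy units regrowing at 8
#' units/step.
#'
#' @param agent_type an `"social:memory:retention"` label or the list from
#'   [parse_agent_type()]
#' @param group_size number of agents
#' @param days trial length in days
#' @param seed integer seed driving every random draw of the trial
#' @param n_cols,n_rows,n_hotspots,hotspot_intensity synthetic-landscape
#'   parameters (see [synthesize_weights()])
#' @param total_resources,grow_back_rate landscape calibration parameters
#' @param landscape_seed seed for the synthetic weight grid (defaults to
#'   `seed`, so matched-seed trials of different agent types share a world)
#' @param params a [behavior_params()] list
#' @return a `simulation_config` list
#' @export
simulation_config <- function(agent_type = "independent:euclidean:20",
                              group_size = 70L, days = 180L, seed = 1L,
                              n_cols = 40L, n_rows = 30L, n_hotspots = 100L,
                              hotspot_intensity = 8,
                              total_resources = 168000, grow_back_rate = 8,
                              landscape_seed = NULL,
                              params = behavior_params()) {
  at <- if (is.character(agent_type)) parse_agent_type(agent_type)
        else agent_type
  stopifnot(group_size >= 1, days >= 1, is.finite(seed))
  structure(c(at, list(
    group_size = as.integer(group_size), days = as.integer(days),
    seed = as.integer(seed),
    n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
    n_hotspots = as.integer(n_hotspots),
    hotspot_intensity = hotspot_intensity,
    total_resources = total_resources, grow_back_rate = grow_back_rate,
    landscape_seed = as.integer(if (is.null(landscape_seed)) seed
                                else landscape_seed),
    params = params)), class = "simulation_config")
}

#' Run one foraging trial
#'
#' Builds (or accepts) the landscape, initializes the agents and their
#' memory, and hands the step loop to the compiled engine. All agents share
#' the same memory-site roster (the landscape's top cells by ceiling) but
#' hold individual beliefs. Agents start at the target energy with a
#' desired-neighbor count of 5, placed uniformly within 100 m of a randomly
#' chosen hotspot cell's centre — a cohesive start that avoids a spurious
#' initial aggregation phase. The trial is fully reproducible from
#' `config$seed`.
#'
#' @param config a [simulation_config()]
#' @param landscape optionally a prebuilt `resource_landscape`; by default a
#'   synthetic one is generated from the config
#' @param record_agents keep per-step agent snapshots (memory-hungry; used by
#'   tests and debugging)
#' @return a `foraging_trial` list: `config`, `trajectory` (data.frame with
#'   `step`, `day`, `step_in_day` (0-based), `x`, `y`, `spread` (m^2),
#'   `n_in_center`, `center_ok`), `agents` (final states), `landscape`
#'   (final), and `snapshots` if requested
#' @export
run_trial <- function(config, landscape = NULL, record_agents = FALSE) {
  if (is.null(landscape)) {
    w <- synthesize_weights(config$n_cols, config$n_rows, config$n_hotspots,
                            config$hotspot_intensity,
                            seed = config$landscape_seed)
    landscape <- build_landscape(w, config$total_resources,
                                 config$grow_back_rate)
    hotspots <- attr(w, "hotspots")
  } else {
    hotspots <- NULL
  }
  mem <- initialize_memory(landscape, config$retention, config$memory_mode)
  p <- config$params

  set.seed(config$seed)
  # start the group within 100 m of one high-value cell
  if (!is.null(hotspots) && nrow(hotspots) > 0) {
    h <- hotspots[sample.int(nrow(hotspots), 1L), ]
  } else {
    best <- which(landscape$max_level == max(landscape$max_level),
                  arr.ind = TRUE)[1, ]
    h <- c(col = unname(best["col"]) - 1L, row = unname(best["row"]) - 1L)
  }
  ctr <- cell_center(h[1], h[2], landscape$cell_size)
  n <- config$group_size
  rad <- 100 * sqrt(stats::runif(n))
  th <- 2 * pi * stats::runif(n)
  W <- landscape$n_cols * landscape$cell_size
  H <- landscape$n_rows * landscape$cell_size
  x0 <- pmin(pmax(ctr[, "x"] + rad * cos(th), 0), W - 1e-9)
  y0 <- pmin(pmax(ctr[, "y"] + rad * sin(th), 0), H - 1e-9)

  res <- .run_trial_cpp(
    landscape$max_level, landscape$current, landscape$cell_size,
    landscape$grow_back_rate,
    mem$sites$col, mem$sites$row, mem$sites$max_level,
    lapply(mem$adjacency, function(a) a - 1L),
    landmark_mode = config$memory_mode == "landmark",
    leader_mode = config$social_rule == "leader",
    x0, y0,
    energy0 = rep(p$target_energy, n),
    desired0 = rep(5L, n),
    par = p, days = config$days, record_agents = record_agents)

  traj <- as.data.frame(res$trajectory)
  names(traj) <- c("step", "day", "step_in_day", "x", "y", "spread",
                   "n_in_center", "center_ok")
  traj$center_ok <- traj$center_ok == 1
  agents <- data.frame(id = seq_len(n) - 1L, x = res$x, y = res$y,
                       energy = res$energy, desired_neighbors = res$desired)
  landscape$current <- res$final_current
  out <- list(config = config, trajectory = traj, agents = agents,
              landscape = landscape)
  if (record_agents) {
    sn <- as.data.frame(res$snapshots)
    names(sn) <- c("step", "id", "x", "y", "energy", "desired_neighbors")
    out$snapshots <- sn
  }
  structure(out, class = "foraging_trial")
}

#' @export
print.foraging_trial <- function(x, ...) {
  cat(sprintf(
    "<foraging_trial> %s:%s:%d | %d agents, %d days (%d steps), seed %d\n",
    x$config$social_rule, x$config$memory_mode, x$config$retention,
    x$config$group_size, x$config$days, nrow(x$trajectory), x$config$seed))
  invisible(x)
}

#' Recursive group-centre estimator
#'
#' The centroid of the current member subset must contain at least
#' `quorum` (80%) of the *original* group within `buffer` (100 m); while it
#' does not, the subset member farthest from the centroid is removed and the
#' centroid recomputed. The subset shrinks every round, so the recursion
#' always terminates in at most `n` iterations. If the subset empties before
#' the quorum is met (e.g. an even fission into distant halves), the last
#' computed centre is returned flagged `ok = FALSE`.
#'
#' @param positions matrix of `(x, y)` rows, one per group member
#' @param buffer metres (default 100)
#' @param quorum fraction of the original group (default 0.8)
#' @return list: `center` (`c(x, y)`), `members` (indices of the final
#'   subset), `ok` (quorum met?)
#' @export
group_center <- function(positions, buffer = 100, quorum = 0.8) {
  positions <- matrix(as.numeric(positions), ncol = 2)
  n <- nrow(positions)
  if (n == 0) stop("need at least one position")
  subset <- seq_len(n)
  center <- c(NA_real_, NA_real_)
  members <- subset
  while (length(subset) > 0) {
    center <- colMeans(positions[subset, , drop = FALSE])
    members <- subset
    d_all <- sqrt((positions[, 1] - center[1])^2 +
                  (positions[, 2] - center[2])^2)
    if (sum(d_all <= buffer) >= quorum * n - 1e-9) {
      return(list(center = unname(center), members = members, ok = TRUE))
    }
    d_sub <- d_all[subset]
    subset <- subset[-which.max(d_sub)]
  }
  list(center = unname(center), members = members, ok = FALSE)
}

#' Convex-hull group spread (m^2)
#'
#' Area of the convex hull of member positions; degenerate sets (fewer than
#' three distinct non-collinear points) have zero spread.
#'
#' @param positions matrix of `(x, y)` rows
#' @return area in m^2
#' @export
group_spread <- function(positions) {
  positions <- matrix(as.numeric(positions), ncol = 2)
  if (nrow(positions) < 3) return(0)
  h <- grDevices::chull(positions)
  if (length(h) < 3) return(0)
  xs <- positions[h, 1]; ys <- positions[h, 2]
  abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
}

#' Calibration sweep over landscape parameters
#'
#' Systematically varies total resources and the grow-back rate, running one
#' (possibly shortened) trial per grid point per replicate, and reports the
#' three calibration summaries: mean daily step length (m per observation
#' day), mean monthly home range (ha) and mean group spread (m^2), computed
#' on the subsampled observation schedule.
#'
#' @param total_resources,grow_back_rates numeric vectors spanning the grid
#' @param config a template [simulation_config()] (its `total_resources` and
#'   `grow_back_rate` are overridden)
#' @param replicates trials per grid point (seeds `config$seed + 0:(r-1)`)
#' @return data.frame, one row per (total, rate, replicate)
#' @export
calibration_sweep <- function(total_resources, grow_back_rates, config,
                              replicates = 1L) {
  out <- list()
  for (tot in total_resources) for (rate in grow_back_rates)
    for (rep in seq_len(replicates)) {
      cfg <- config
      cfg$total_resources <- tot
      cfg$grow_back_rate <- rate
      cfg$seed <- config$seed + rep - 1L
      cfg$landscape_seed <- cfg$seed
      trial <- run_trial(cfg)
      obs <- subsample_observation(trial$trajectory, seed = cfg$seed)
      dm <- daily_metrics(obs)
      hr <- home_range(trial$trajectory)
      out[[length(out) + 1L]] <- data.frame(
        total_resources = tot, grow_back_rate = rate, replicate = rep,
        seed = cfg$seed,
        mean_daily_step = mean(dm$d_total),
        mean_home_range_ha = mean(hr$hectares),
        mean_spread = mean(obs$spread))
    }
  do.call(rbind, out)
}

# ---- flat config files and trajectory CSV ----------------------------------

#' Read/write a flat `key: value` config file and trajectory CSVs
#'
#' @param config a `simulation_config`
#' @param path file path
#' @param trajectory a trial trajectory data.frame
#' @name simulation-io
NULL

#' @rdname simulation-io
#' @export
write_config <- function(config, path) {
  flat <- config[setdiff(names(config), "params")]
  lines <- c(
    sprintf("%s: %s", names(flat), vapply(flat, as.character, "")),
    sprintf("param_%s: %s", names(config$params),
            vapply(config$params, as.character, "")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname simulation-io
#' @export
read_config <- function(path) {
  lines <- grep(":", readLines(path), fixed = TRUE, value = TRUE)
  keys <- trimws(sub(":.*", "", lines))
  vals <- trimws(sub("^[^:]*:", "", lines))
  kv <- stats::setNames(as.list(vals), keys)
  num <- suppressWarnings(lapply(kv, function(v) {
    nv <- as.numeric(v)
    if (is.na(nv)) v else nv
  }))
  pk <- grepl("^param_", names(num))
  pargs <- stats::setNames(num[pk], sub("^param_", "", names(num)[pk]))
  pargs <- pargs[names(pargs) %in% names(formals(behavior_params))]
  params <- do.call(behavior_params, pargs)
  args <- num[!pk]
  simulation_config(
    agent_type = list(social_rule = args$social_rule,
                      memory_mode = args$memory_mode,
                      retention = as.integer(args$retention)),
    group_size = args$group_size, days = args$days, seed = args$seed,
    n_cols = args$n_cols, n_rows = args$n_rows,
    n_hotspots = args$n_hotspots,
    hotspot_intensity = args$hotspot_intensity,
    total_resources = args$total_resources,
    grow_back_rate = args$grow_back_rate,
    landscape_seed = args$landscape_seed,
    params = params)
}

#' @rdname simulation-io
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(trajectory, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname simulation-io
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path)
}
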
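#' @title Spatial memory: Euclidean and landmark-based recall
#'
#' @description
#' Agents carry a fixed roster of remembered resource sites (20, 60 or 100 of
#' the landscape's top cells by resource ceiling) with a believed resource
#' level per site. Nothing is forgotten over a trial; beliefs are dynamic.
#' Out of sight, the agent assumes each remembered site regrows at the global
#' grow-back rate; when a site re-enters visual range the belief snaps back to
#' the true level. Two recall modes are modelled: a Euclidean cognitive map
#' (every remembered site is recallable from anywhere) and landmark-based
#' recall (only sites associated with the last-seen landmark are recallable,
#' where every remembered site is a landmark associated with all remembered
#' sites within 100 m of it, itself included).
#' @name memory
NULL

#' Initialize spatial memory from a landscape
#'
#' Memory is seeded with the `retention` cells of highest `max_level`
#' (ties broken by (row, col) lexical order, so membership is deterministic),
#' and beliefs start equal to the true levels at step 0. The landmark
#' association graph (sites within `landmark_radius` of each other,
#' centre-to-centre, self included) is precomputed.
#'
#' @param landscape a `resource_landscape`
#' @param retention number of remembered sites (spec values 20/60/100; any
#'   positive count up to the number of cells is accepted)
#' @param mode `"euclidean"` or `"landmark"`
#' @param landmark_radius association radius in metres (default 100)
#' @return a `spatial_memory`: list with `mode`, `retention`,
#'   `landmark_radius`, `current_landmark` (site index or `NA`), `adjacency`
#'   (list of site-index vectors) and `sites`, a data.frame with 0-based
#'   `col`, `row`, centre `x`, `y`, `max_level`, `believed`, `last_seen`
#'   (`NA` = never seen)
#' @export
initialize_memory <- function(landscape, retention,
                              mode = c("euclidean", "landmark"),
                              landmark_radius = 100) {
  mode <- match.arg(mode)
  n <- landscape$n_cols * landscape$n_rows
  if (retention <= 0) stop("retention must be positive")
  if (retention > n) stop("retention exceeds the number of cells")
  col <- rep(0:(landscape$n_cols - 1L), each = landscape$n_rows)
  row <- rep(0:(landscape$n_rows - 1L), times = landscape$n_cols)
  ord <- order(-as.vector(landscape$max_level), row, col)
  pick <- ord[seq_len(retention)]
  ctr <- cell_center(col[pick], row[pick], landscape$cell_size)
  sites <- data.frame(
    col = col[pick], row = row[pick],
    x = ctr[, "x"], y = ctr[, "y"],
    max_level = as.vector(landscape$max_level)[pick],
    believed = as.vector(landscape$current)[pick],
    last_seen = NA_integer_)
  d <- as.matrix(stats::dist(sites[, c("x", "y")]))
  adjacency <- lapply(seq_len(retention),
                      function(i) which(d[i, ] <= landmark_radius))
  structure(list(mode = mode, retention = retention,
                 landmark_radius = landmark_radius,
                 current_landmark = NA_integer_,
                 adjacency = adjacency, sites = sites),
            class = "spatial_memory")
}

#' Recallable sites from the current position
#'
#' Euclidean mode returns every remembered site. Landmark mode returns the
#' sites associated with the current landmark (those within the landmark
#' radius of it, including the landmark itself); with no landmark seen yet
#' nothing is recallable and the agent must rely on vision.
#'
#' @param memory a `spatial_memory`
#' @param agent_position unused in either mode (kept for interface symmetry:
#'   recall depends on the remembered landmark, not on where the agent stands)
#' @return integer vector of site indices into `memory$sites`
#' @export
recall_candidates <- function(memory, agent_position = NULL) {
  if (memory$mode == "euclidean") return(seq_len(memory$retention))
  if (is.na(memory$current_landmark)) return(integer(0))
  memory$adjacency[[memory$current_landmark]]
}

#' Update beliefs for sites in visual range
#'
#' Every remembered site within `visual_range` of the agent has its belief
#' replaced by the true current level and its `last_seen` stamped. In
#' landmark mode the nearest visible remembered site becomes the current
#' landmark ("the last landmark seen"); if none is visible the landmark
#' persists unchanged.
#'
#' @param memory a `spatial_memory`
#' @param landscape a `resource_landscape`
#' @param agent_position numeric `c(x, y)` in metres
#' @param visual_range metres (default 50)
#' @param step current step index stamped on seen sites
#' @return the updated memory
#' @export
update_memory <- function(memory, landscape, agent_position,
                          visual_range = 50, step = 0L) {
  d <- sqrt((memory$sites$x - agent_position[1])^2 +
            (memory$sites$y - agent_position[2])^2)
  vis <- which(d <= visual_range)
  if (length(vis)) {
    truth <- landscape$current[cbind(memory$sites$row[vis] + 1L,
                                     memory$sites$col[vis] + 1L)]
    memory$sites$believed[vis] <- truth
    memory$sites$last_seen[vis] <- step
    if (memory$mode == "landmark")
      memory$current_landmark <- vis[which.min(d[vis])]
  }
  memory
}

#' Advance beliefs for out-of-sight sites by one mental regrowth step
#'
#' Sites not currently within visual range are assumed to regrow at the
#' global grow-back rate, capped at each site's own ceiling. Sites in view
#' are left alone (vision overrides the mental model).
#'
#' @param memory a `spatial_memory`
#' @param grow_back_rate energy units per step
#' @param agent_position numeric `c(x, y)`; needed to know which sites are in
#'   view
#' @param visual_range metres (default 50)
#' @return the updated memory
#' @export
mental_regrow <- function(memory, grow_back_rate, agent_position,
                          visual_range = 50) {
  d <- sqrt((memory$sites$x - agent_position[1])^2 +
            (memory$sites$y - agent_position[2])^2)
  out <- d > visual_range
  memory$sites$believed[out] <- pmin(
    memory$sites$believed[out] + grow_back_rate,
    memory$sites$max_level[out])
  memory
}

#' Dump/restore a memory state as CSV
#'
#' Columns: `agent_id,col,row,believed,last_seen` (0-based cells).
#'
#' @param memory a `spatial_memory`
#' @param path file path
#' @param agent_id id written on every line
#' @name memory-io
#' @export
write_memory_csv <- function(memory, path, agent_id = 0L) {
  df <- data.frame(agent_id = agent_id,
                   col = memory$sites$col, row = memory$sites$row,
                   believed = memory$sites$believed,
                   last_seen = memory$sites$last_seen)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname memory-io
#' @param template a `spatial_memory` whose roster matches the file
#' @export
read_memory_csv <- function(path, template) {
  df <- utils::read.csv(path)
  key_file <- paste(df$col, df$row)
  key_mem <- paste(template$sites$col, template$sites$row)
  idx <- match(key_mem, key_file)
  if (any(is.na(idx))) stop("memory CSV does not match the site roster")
  template$sites$believed <- df$believed[idx]
  template$sites$last_seen <- df$last_seen[idx]
  template
}
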
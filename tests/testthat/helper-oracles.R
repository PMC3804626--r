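# Fixtures built in code and independent brute-force oracles.
# The oracles deliberately avoid the code paths they check.

# small uniform landscape: every cell max_level = total / n
make_uniform_landscape <- function(n_cols = 10, n_rows = 8, total = 11200,
                                   rate = 8) {
  w <- matrix(1, n_rows, n_cols)
  build_landscape(w, total_resources = total, grow_back_rate = rate)
}

# landscape with hand-placed high cells on a flat low background
make_spiked_landscape <- function(n_cols = 10, n_rows = 8,
                                  spikes = cbind(col = c(2, 7),
                                                 row = c(3, 5)),
                                  low = 1, high = 100, rate = 8) {
  w <- matrix(low, n_rows, n_cols)
  w[cbind(spikes[, "row"] + 1, spikes[, "col"] + 1)] <- high
  build_landscape(w, total_resources = sum(w) * 10, grow_back_rate = rate)
}

default_params <- behavior_params()

# brute-force convex hull area: O(n^3) hull-vertex test, then angular sort
# and the shoelace formula. Independent of chull() and of the C++ hull.
bf_hull_area <- function(pts) {
  pts <- unique(matrix(as.numeric(pts), ncol = 2))
  n <- nrow(pts)
  if (n < 3) return(0)
  on_hull <- logical(n)
  for (i in seq_len(n)) {
    # i is a hull vertex iff some line through it keeps all points one side
    for (j in seq_len(n)) {
      if (i == j) next
      v <- pts[j, ] - pts[i, ]
      crossp <- (pts[, 1] - pts[i, 1]) * v[2] - (pts[, 2] - pts[i, 2]) * v[1]
      if (all(crossp <= 1e-9) || all(crossp >= -1e-9)) {
        on_hull[i] <- TRUE
        break
      }
    }
  }
  h <- pts[on_hull, , drop = FALSE]
  if (nrow(h) < 3) return(0)
  ctr <- colMeans(h)
  h <- h[order(atan2(h[, 2] - ctr[2], h[, 1] - ctr[1])), , drop = FALSE]
  xs <- h[, 1]; ys <- h[, 2]
  abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
}

# brute-force two-sample KS D: ECDF gap scanned at every pooled point
bf_ks_d <- function(a, b) {
  pool <- sort(unique(c(a, b)))
  Fa <- vapply(pool, function(t) mean(a <= t), 0)
  Fb <- vapply(pool, function(t) mean(b <= t), 0)
  max(abs(Fa - Fb))
}

# brute-force skewness from raw moment sums
bf_skewness <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  (m3 / m2^(3 / 2)) * sqrt(n * (n - 1)) / (n - 2)
}

# literal transcription of the recursive group-centre procedure
bf_group_center <- function(pos, buffer = 100, quorum = 0.8) {
  pos <- matrix(as.numeric(pos), ncol = 2)
  n <- nrow(pos)
  sub <- seq_len(n)
  last <- c(NA, NA)
  repeat {
    if (length(sub) == 0) return(list(center = last, ok = FALSE))
    ctr <- c(mean(pos[sub, 1]), mean(pos[sub, 2]))
    last <- ctr
    within <- sqrt((pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2) <= buffer
    if (sum(within) >= quorum * n - 1e-9)
      return(list(center = ctr, ok = TRUE, members = sub))
    dsub <- sqrt((pos[sub, 1] - ctr[1])^2 + (pos[sub, 2] - ctr[2])^2)
    sub <- sub[-which.max(dsub)]
  }
}

# brute-force goal choice: enumerate the full candidate set (every visible
# food cell by truth, every recallable out-of-sight site by belief), compute
# I = d / r for each, and apply the tie rules by explicit sort
bf_choose_goal <- function(pos, landscape, memory, params) {
  cs <- landscape$cell_size
  rows <- list()
  for (c in 0:(landscape$n_cols - 1)) for (r in 0:(landscape$n_rows - 1)) {
    ctr <- c((c + 0.5) * cs, (r + 0.5) * cs)
    d <- sqrt(sum((ctr - pos)^2))
    cur <- landscape$current[r + 1, c + 1]
    if (d <= params$visual_range && cur > 0)
      rows[[length(rows) + 1]] <- data.frame(col = c, row = r, d = d,
                                             r_exp = cur)
  }
  if (!is.null(memory)) {
    for (i in recall_candidates(memory, pos)) {
      s <- memory$sites[i, ]
      d <- sqrt((s$x - pos[1])^2 + (s$y - pos[2])^2)
      if (d > params$visual_range && s$believed > 0)
        rows[[length(rows) + 1]] <- data.frame(col = s$col, row = s$row,
                                               d = d, r_exp = s$believed)
    }
  }
  if (length(rows) == 0) return(NULL)
  df <- do.call(rbind, rows)
  df$I <- df$d / df$r_exp
  df[order(df$I, df$d, df$row, df$col), ][1, c("col", "row")]
}

# random small scene: landscape with scattered food, an agent, mates, and an
# initialized memory
random_scene <- function(seed, mode = "euclidean") {
  set.seed(seed)
  nc <- sample(6:12, 1); nr <- sample(6:12, 1)
  w <- matrix(runif(nc * nr, 0.01, 0.25), nr, nc)
  k <- sample(3:8, 1)
  w[sample(nc * nr, k)] <- runif(k, 1, 10)
  l <- build_landscape(w, total_resources = 5000 * nc * nr,
                       grow_back_rate = 8)
  # deplete a random subset so zero-resource exclusions get exercised
  zero <- sample(nc * nr, floor(nc * nr / 4))
  l$current[zero] <- 0
  mem <- initialize_memory(l, retention = sample(5:15, 1), mode = mode)
  if (mode == "landmark")
    mem$current_landmark <- sample(mem$retention, 1)
  pos <- c(runif(1, 0, nc * 30), runif(1, 0, nr * 30))
  n_mates <- sample(3:10, 1)
  mates <- cbind(pos[1] + runif(n_mates, -150, 150),
                 pos[2] + runif(n_mates, -150, 150))
  list(landscape = l, memory = mem, pos = pos, mates = mates)
}
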
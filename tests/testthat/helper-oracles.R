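# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately naive (explicit loops, brute force) so it
# shares no code path with the package implementation it checks.

# --- histogram smoothing oracle -------------------------------------------
# Step-by-step Minimum-method oracle: literal loops, replicate-padded
# 3-point moving average, strict maxima, lowest valley between the peaks.
oracle_minimum_threshold <- function(hist, max_iter = 10000) {
  y <- as.numeric(hist)
  n <- length(y)
  nmax <- function(y) {
    cnt <- 0
    for (j in 1:n) {
      left <- if (j == 1) -Inf else y[j - 1]
      right <- if (j == n) -Inf else y[j + 1]
      if (y[j] > left && y[j] > right) cnt <- cnt + 1
    }
    cnt
  }
  iter <- 0
  while (nmax(y) != 2 && iter < max_iter) {
    y2 <- numeric(n)
    for (j in 1:n) {
      a <- if (j == 1) y[1] else y[j - 1]
      b <- if (j == n) y[n] else y[j + 1]
      y2[j] <- (a + y[j] + b) / 3
    }
    y <- y2
    iter <- iter + 1
  }
  if (nmax(y) != 2) {
    return(NULL)
  }
  peaks <- c()
  for (j in 1:n) {
    left <- if (j == 1) -Inf else y[j - 1]
    right <- if (j == n) -Inf else y[j + 1]
    if (y[j] > left && y[j] > right) peaks <- c(peaks, j)
  }
  best_t <- NA_integer_
  best_count <- Inf
  if (peaks[2] - peaks[1] >= 2) {
    for (j in (peaks[1] + 1):(peaks[2] - 1)) {
      if (y[j - 1] > y[j] && y[j] <= y[j + 1] && y[j] < best_count) {
        best_count <- y[j]
        best_t <- j - 1L
      }
    }
  }
  if (is.na(best_t)) {
    return(NULL)
  }
  list(threshold = best_t, smoothing_iterations = iter)
}

random_bimodal_hist <- function() {
  m1 <- sample(20:80, 1)
  m2 <- sample(150:230, 1)
  s1 <- runif(1, 4, 15)
  s2 <- runif(1, 4, 15)
  n1 <- sample(2000:20000, 1)
  n2 <- sample(2000:20000, 1)
  counts <- tabulate(
    c(
      pmin(pmax(round(rnorm(n1, m1, s1)), 0), 255),
      pmin(pmax(round(rnorm(n2, m2, s2)), 0), 255)
    ) + 1L,
    nbins = 256L
  )
  counts
}

# --- skeleton path oracle --------------------------------------------------
# Same minimal-adjacency rule as the package states (diagonal edge only when
# neither shared orthogonal neighbor is present), built with naive loops,
# then exhaustive DFS over all simple paths between all endpoint pairs.
oracle_adjacency <- function(coords) {
  n <- nrow(coords)
  adj <- vector("list", n)
  wts <- vector("list", n)
  has <- function(r, c) any(coords[, 1] == r & coords[, 2] == c)
  idx <- function(r, c) which(coords[, 1] == r & coords[, 2] == c)[1]
  for (i in 1:n) {
    r <- coords[i, 1]
    c <- coords[i, 2]
    for (dr in -1:1) {
      for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        if (!has(r + dr, c + dc)) next
        if (dr != 0 && dc != 0) {
          if (has(r + dr, c) || has(r, c + dc)) next
          w <- sqrt(2)
        } else {
          w <- 1
        }
        adj[[i]] <- c(adj[[i]], idx(r + dr, c + dc))
        wts[[i]] <- c(wts[[i]], w)
      }
    }
  }
  list(adj = adj, wts = wts)
}

# Connected and acyclic under the minimal-adjacency rule, by naive flood
# fill and edge counting.
oracle_is_tree <- function(coords) {
  g <- oracle_adjacency(coords)
  n <- nrow(coords)
  seen <- rep(FALSE, n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    for (u in g$adj[[v]]) {
      if (!seen[u]) {
        seen[u] <- TRUE
        queue <- c(queue, u)
      }
    }
  }
  n_edges <- sum(vapply(g$adj, length, integer(1))) / 2
  all(seen) && n_edges == n - 1
}

oracle_longest_path_weight <- function(coords) {
  n <- nrow(coords)
  g <- oracle_adjacency(coords)
  adj <- g$adj
  wts <- g$wts
  deg <- vapply(adj, length, integer(1))
  endpoints <- which(deg == 1)
  if (length(endpoints) == 0) {
    return(NULL)
  }
  best <- 0
  dfs <- function(v, target, visited, acc) {
    if (v == target) {
      if (acc > best) best <<- acc
      return()
    }
    for (k in seq_along(adj[[v]])) {
      u <- adj[[v]][k]
      if (!visited[u]) {
        visited[u] <- TRUE
        dfs(u, target, visited, acc + wts[[v]][k])
        visited[u] <- FALSE
      }
    }
  }
  for (a in endpoints) {
    for (b in endpoints) {
      if (a >= b) next
      visited <- rep(FALSE, n)
      visited[a] <- TRUE
      dfs(a, b, visited, 0)
    }
  }
  total <- sum(unlist(wts)) / 2
  list(weight = best, total = total)
}

# Random pixel tree: grown by random accretion, kept only when the
# independent oracle certifies it connected and acyclic.
random_pixel_tree <- function(max_pixels = 18) {
  repeat {
    coords <- matrix(c(10L, 10L), 1, 2)
    for (i in seq_len(sample(4:max_pixels, 1))) {
      base <- coords[sample(nrow(coords), 1), ]
      step <- sample(list(
        c(0L, 1L), c(1L, 0L), c(0L, -1L), c(-1L, 0L),
        c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)
      ), 1)[[1]]
      cand <- base + step
      if (!any(coords[, 1] == cand[1] & coords[, 2] == cand[2])) {
        coords <- rbind(coords, cand)
      }
    }
    if (nrow(coords) >= 3 && oracle_is_tree(coords)) {
      m <- matrix(FALSE, 30, 30)
      m[coords] <- TRUE
      return(m)
    }
  }
}

# --- noncentral t oracle ---------------------------------------------------
# CDF of the noncentral t by integrating over the chi-square mixing
# variable: T = (Z + ncp) / sqrt(W / df), so
# P(T <= t) = E_W[ Phi(t * sqrt(W / df) - ncp) ].
oracle_pt_ncp <- function(t, df, ncp) {
  stats::integrate(
    function(w) stats::pnorm(t * sqrt(w / df) - ncp) * stats::dchisq(w, df),
    0, Inf,
    rel.tol = 1e-10
  )$value
}

oracle_power_n <- function(effect, alpha, beta) {
  f <- function(n) {
    df <- 2 * (n - 1)
    tcrit <- stats::qt(1 - alpha / 2, df)
    (1 - oracle_pt_ncp(tcrit, df, effect * sqrt(n / 2))) - (1 - beta)
  }
  lo <- 2
  hi <- 1e5
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-8) break
  }
  (lo + hi) / 2
}

# --- misc fixtures ---------------------------------------------------------
rect_mask <- function(h, w, pad = 0) {
  m <- matrix(FALSE, h + 2 * pad, w + 2 * pad)
  m[pad + seq_len(h), pad + seq_len(w)] <- TRUE
  m
}

# Ring-shaped mask (a self-touching "worm"), for cycle rejection tests.
ring_mask <- function(size = 101, radius = 35, width = 8) {
  ctr <- (size + 1) / 2
  z <- matrix(0, size, size)
  d <- sqrt((row(z) - ctr)^2 + (col(z) - ctr)^2)
  d >= radius - width / 2 & d <= radius + width / 2
}

disk_mask <- function(size, radius) {
  ctr <- (size + 1) / 2
  z <- matrix(0, size, size)
  sqrt((row(z) - ctr)^2 + (col(z) - ctr)^2) <= radius
}
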
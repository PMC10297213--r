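# Independent oracles used across the suite. These deliberately avoid the
# package's own internals: connectivity is checked by a queue-based flood
# fill, boundary pixels by direct neighbor scans, window means by brute-force
# loops.

# flood fill from one seed over TRUE cells, 4-connectivity
flood_fill4 <- function(m, seed) {
  nr <- nrow(m); nc <- ncol(m)
  visited <- matrix(FALSE, nr, nc)
  queue <- list(seed)
  visited[seed[1], seed[2]] <- TRUE
  while (length(queue)) {
    p <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r <- p[1] + d[1]; c <- p[2] + d[2]
      if (r >= 1 && r <= nr && c >= 1 && c <= nc && m[r, c] &&
          !visited[r, c]) {
        visited[r, c] <- TRUE
        queue[[length(queue) + 1L]] <- c(r, c)
      }
    }
  }
  visited
}

n_components4 <- function(m) {
  todo <- m
  n <- 0L
  while (any(todo)) {
    seed <- which(todo, arr.ind = TRUE)[1, ]
    todo <- todo & !flood_fill4(todo, seed)
    n <- n + 1L
  }
  n
}

# a mask is a valid cell: one 4-connected foreground piece, one 4-connected
# background piece (no holes), no corner-only contacts, 1-px border margin
expect_valid_mask <- function(m) {
  m <- m != 0
  expect_false(any(m[1, ]) || any(m[nrow(m), ]) || any(m[, 1]) ||
                 any(m[, ncol(m)]))
  expect_identical(n_components4(m), 1L)
  expect_identical(n_components4(!m), 1L)
  nr <- nrow(m); nc <- ncol(m)
  a <- m[-nr, -nc]; b <- m[-nr, -1]; cc <- m[-1, -nc]; d <- m[-1, -1]
  expect_false(any(a & d & !b & !cc))
  expect_false(any(b & cc & !a & !d))
}

# boundary pixels of a mask by direct neighbor scan
boundary_pixels <- function(m) {
  m <- m != 0
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!m[r, c]) next
    nb <- c(if (r > 1) m[r - 1, c] else FALSE,
            if (r < nr) m[r + 1, c] else FALSE,
            if (c > 1) m[r, c - 1] else FALSE,
            if (c < nc) m[r, c + 1] else FALSE)
    out[r, c] <- !all(nb)
  }
  out
}

# brute-force masked 3x3 window mean around (r, c), center excluded
window_mean_oracle <- function(v, m, r, c) {
  s <- 0; n <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- r + dr; cc <- c + dc
    if (rr < 1 || rr > nrow(m) || cc < 1 || cc > ncol(m)) next
    if (m[rr, cc] != 0) { s <- s + v[rr, cc]; n <- n + 1L }
  }
  if (n == 0L) NA_real_ else s / n
}

# brute-force in-mask disc mean around fractional point (x, y)
disc_mean_oracle <- function(img, m, x, y, radius) {
  s <- 0; n <- 0L
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    if (m[r, c] == 0) next
    if ((r - x)^2 + (c - y)^2 <= radius^2) { s <- s + img[r, c]; n <- n + 1L }
  }
  if (n == 0L) NA_real_ else s / n
}

# analytic circle contour (points at `spacing` arc length)
circle_contour <- function(radius, center = c(32, 32), spacing = 1) {
  n <- max(8L, round(2 * pi * radius / spacing))
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

# small coupled model on a coarse grid for quick 2D tests
quick_cfg <- function(seed = 1L, noiseAmp = 5) {
  solverConfig(seed = seed, noiseAmp = noiseAmp)
}
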
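# Independent brute-force oracles. These deliberately share no code with
# the package: box counting scans every box, morphology applies literal
# set-theoretic min/max filters, convolution is a dense spatial sum, and
# component counting is a BFS flood fill.

oracleBoxCount <- function(m, sizes) {
  h <- nrow(m); w <- ncol(m)
  vapply(sizes, function(s) {
    cnt <- 0L
    for (r0 in seq(1L, h, by = s)) {
      for (c0 in seq(1L, w, by = s)) {
        if (any(m[r0:min(r0 + s - 1L, h), c0:min(c0 + s - 1L, w)]))
          cnt <- cnt + 1L
      }
    }
    cnt
  }, integer(1))
}

# literal min-filter (erosion) / max-filter (dilation); outside = background
oracleFilter <- function(m, r, f) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      rs <- max(1L, i - r):min(h, i + r)
      cs <- max(1L, j - r):min(w, j + r)
      win <- m[rs, cs]
      full <- length(rs) == 2L * r + 1L && length(cs) == 2L * r + 1L
      out[i, j] <- if (identical(f, all)) all(win) && full else any(win)
    }
  }
  out
}

oracleOpening <- function(m, r) oracleFilter(oracleFilter(m, r, all), r, any)

# dense 1D Gaussian convolution, kernel truncated at 4 sigma, symmetric
# reflection at the borders
oracleConvolve1D <- function(x, sigma) {
  n <- length(x)
  r <- ceiling(4 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  refl <- function(i) {
    while (i < 1L || i > n) {
      if (i < 1L) i <- 1L - i
      if (i > n) i <- 2L * n + 1L - i
    }
    i
  }
  vapply(seq_len(n), function(i) {
    sum(k * vapply(i + (-r:r), function(j) x[refl(j)], numeric(1)))
  }, numeric(1))
}

# number of 8-connected foreground components, BFS flood fill
countComponents8 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  seen <- matrix(FALSE, h, w)
  ncomp <- 0L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (start in which(m & !seen)) {
    if (seen[start]) next
    ncomp <- ncomp + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      i <- (cur - 1L) %% h + 1L
      j <- (cur - 1L) %/% h + 1L
      for (o in seq_len(nrow(offs))) {
        ni <- i + offs$dr[o]; nj <- j + offs$dc[o]
        if (ni >= 1L && ni <= h && nj >= 1L && nj <= w &&
            m[ni, nj] && !seen[ni, nj]) {
          seen[ni, nj] <- TRUE
          queue <- c(queue, (nj - 1L) * h + ni)
        }
      }
    }
  }
  ncomp
}

# rotate (row, col) points rigidly about a centre, degrees
rotatePoints <- function(p, deg, centre = c(0, 0)) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(sweep(p, 2, centre) %*% t(R), 2, centre, `+`)
}

# printed group summaries used throughout the two-group comparisons
# (fractal dimension per ROI and cortical width per side; n = 15 vs 45)
summaryFixtures <- list(
  fd_roi1 = list(g1 = c(15, 1.193, 0.067), g2 = c(45, 1.233, 0.082), t = 1.716),
  fd_roi2 = list(g1 = c(15, 1.162, 0.076), g2 = c(45, 1.253, 0.067), t = 4.403),
  fd_roi3 = list(g1 = c(15, 1.184, 0.101), g2 = c(45, 1.253, 0.075), t = 2.824),
  fd_roi4 = list(g1 = c(15, 1.137, 0.089), g2 = c(45, 1.206, 0.112), t = 2.151),
  mcw_r   = list(g1 = c(15, 3.399, 0.506), g2 = c(45, 3.638, 0.732), t = 1.170),
  mcw_l   = list(g1 = c(15, 3.382, 0.678), g2 = c(45, 3.718, 0.589), t = 1.846)
)

mciCounts <- rbind(FAP = c(12, 3, 0), control = c(34, 9, 2))
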
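# Shared fixtures and independent oracles for the test suite.

# rasterized shapes -------------------------------------------------------

raster_disk <- function(n, r, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  X <- matrix(rep(seq_len(n), each = n), n)
  Y <- t(X)
  (X - cx)^2 + (Y - cy)^2 <= r^2
}

raster_ellipse <- function(n, a, b, cx = (n + 1) / 2, cy = (n + 1) / 2, theta = 0) {
  X <- matrix(rep(seq_len(n), each = n), n)
  Y <- t(X)
  u <- (X - cx) * cos(theta) + (Y - cy) * sin(theta)
  v <- -(X - cx) * sin(theta) + (Y - cy) * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

raster_polygon <- function(n, px, py) {
  m <- matrix(FALSE, n, n)
  for (r in seq_len(n)) {
    xs <- numeric(0)
    np <- length(px)
    for (i in seq_len(np)) {
      j <- if (i == np) 1L else i + 1L
      y1 <- py[i]; y2 <- py[j]
      if ((y1 <= r && y2 > r) || (y2 <= r && y1 > r)) {
        t <- (r - y1) / (y2 - y1)
        xs <- c(xs, px[i] + t * (px[j] - px[i]))
      }
    }
    xs <- sort(xs)
    if (length(xs) >= 2)
      for (k in seq(1, length(xs) - 1, by = 2))
        m[r, seq(max(1, ceiling(xs[k])), min(n, floor(xs[k + 1])))] <- TRUE
  }
  m
}

star_polygon <- function(cx, cy, r_outer, r_inner, points = 5) {
  ang <- pi / 2 + seq(0, 2 * pi, length.out = 2 * points + 1)[-(2 * points + 1)]
  r <- rep(c(r_outer, r_inner), points)
  list(x = cx + r * cos(ang), y = cy - r * sin(ang))
}

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# independent distribution oracles ----------------------------------------

# Regularized incomplete beta I_x(a, b) by Lentz's continued fraction
# (independent of R's pbeta/pt/pf).
ibeta_reg <- function(x, a, b) {
  if (x <= 0) return(0)
  if (x >= 1) return(1)
  lnfront <- lgamma(a + b) - lgamma(a) - lgamma(b) + a * log(x) + b * log1p(-x)
  betacf <- function(x, a, b) {
    tiny <- 1e-300
    qab <- a + b; qap <- a + 1; qam <- a - 1
    c_ <- 1; d <- 1 - qab * x / qap
    if (abs(d) < tiny) d <- tiny
    d <- 1 / d; h <- d
    for (m in 1:300) {
      m2 <- 2 * m
      aa <- m * (b - m) * x / ((qam + m2) * (a + m2))
      d <- 1 + aa * d; if (abs(d) < tiny) d <- tiny
      c_ <- 1 + aa / c_; if (abs(c_) < tiny) c_ <- tiny
      d <- 1 / d; h <- h * d * c_
      aa <- -(a + m) * (qab + m) * x / ((a + m2) * (qap + m2))
      d <- 1 + aa * d; if (abs(d) < tiny) d <- tiny
      c_ <- 1 + aa / c_; if (abs(c_) < tiny) c_ <- tiny
      d <- 1 / d
      del <- d * c_
      h <- h * del
      if (abs(del - 1) < 1e-14) break
    }
    h
  }
  if (x < (a + 1) / (a + b + 2)) exp(lnfront) * betacf(x, a, b) / a
  else 1 - ibeta_reg(1 - x, b, a)
}

# two-tailed p of the variance F test from the incomplete beta oracle
oracle_f_p <- function(f, d1, d2) {
  x <- d1 * f / (d1 * f + d2)
  cdf <- ibeta_reg(x, d1 / 2, d2 / 2)
  min(1, 2 * min(cdf, 1 - cdf))
}

# two-tailed Welch p from the incomplete beta oracle (t-distribution tail
# P(|T| > t) = I_{df/(df+t^2)}(df/2, 1/2))
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- ibeta_reg(df / (df + t^2), df / 2, 1 / 2)
  list(statistic = t, df = df, p = p)
}

# binomial-sum identity for I_p(a, b) with integer a, b:
# I_p(a, b) = P(Bin(a + b - 1, p) >= a), evaluated by direct summation
binom_sum_ibeta <- function(p, a, b) {
  n <- a + b - 1
  k <- a:n
  sum(choose(n, k) * p^k * (1 - p)^(n - k))
}

# small phantom spec used across tests
small_phantom_spec <- function(...) {
  args <- list(image_size = 192, pixel_size = 1, organoid_axes = c(75, 60),
               rosette_count = 2, rosette_radius_range = c(12, 18),
               fissure_count = 1, droplet_area_fraction = 0.03)
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_spec, args)
}
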
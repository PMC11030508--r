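# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG stream; the caller's RNG state is
# untouched.  All generators route their randomness through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# FFT frequency coordinates (cycles per pixel), fftfreq convention.
fft_freq <- function(n) {
  k <- c(0:(ceiling(n / 2) - 1L), -(floor(n / 2)):-1L)
  k / n
}

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Connected-component labelling with selectable connectivity.  EBImage's
# bwlabel() is 4-connected; for 8-connectivity, 4-connected labels that
# touch diagonally are merged by union-find.
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  lab <- EBImage::bwlabel(mask > 0)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (connectivity == 4 || nlab <= 1) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  nr <- nrow(lab); nc <- ncol(lab)
  for (sh in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(nr - 1), , drop = FALSE]
    b <- lab[-1L, , drop = FALSE]
    if (sh[2] == 1L) { a <- a[, seq_len(nc - 1), drop = FALSE]; b <- b[, -1L, drop = FALSE] }
    else             { a <- a[, -1L, drop = FALSE];             b <- b[, seq_len(nc - 1), drop = FALSE] }
    sel <- which(a > 0 & b > 0 & a != b)
    if (length(sel)) for (i in sel) union_(a[i], b[i])
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# Paint an ellipse (semi-axes a,b in pixels, orientation theta) with value
# `code` into integer matrix `labels`, restricted to pixels where the current
# label is in `over` (NULL = anywhere).  Returns the updated matrix.
draw_ellipse <- function(labels, code, cx, cy, a, b, theta = 0, over = NULL) {
  nr <- nrow(labels); nc <- ncol(labels)
  r <- max(a, b)
  rows <- max(1L, floor(cy - r)):min(nr, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(nc, ceiling(cx + r))
  if (!length(rows) || !length(cols)) return(labels)
  X <- matrix(rep(cols, each = length(rows)), length(rows))
  Y <- matrix(rep(rows, length(cols)), length(rows))
  dx <- X - cx; dy <- Y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  sub <- labels[rows, cols, drop = FALSE]
  sel <- inside & (if (is.null(over)) TRUE else matrix(sub %in% over, nrow(sub)))
  sub[sel] <- code
  labels[rows, cols] <- sub
  labels
}

# Otsu threshold on an arbitrary-range numeric matrix (EBImage::otsu wants
# [0,1]).  Returns NA for (near-)constant input.
otsu_threshold <- function(x, levels = 256) {
  rng <- range(x, finite = TRUE)
  if (!is.finite(rng[1]) || diff(rng) < .Machine$double.eps * 100) return(NA_real_)
  xs <- (x - rng[1]) / diff(rng)
  if (is.null(dim(xs))) xs <- matrix(xs)
  t01 <- EBImage::otsu(EBImage::Image(xs), range = c(0, 1), levels = levels)
  rng[1] + t01 * diff(rng)
}

# Azimuthally averaged profile of a matrix around a center, at integer radii.
radial_profile <- function(img, cx, cy, rmax) {
  nr <- nrow(img); nc <- ncol(img)
  X <- matrix(rep(seq_len(nc), each = nr), nr)
  Y <- matrix(rep(seq_len(nr), nc), nr)
  r <- round(sqrt((X - cx)^2 + (Y - cy)^2))
  keep <- r <= rmax
  means <- tapply(img[keep], r[keep], mean)
  out <- rep(NA_real_, rmax + 1)
  out[as.integer(names(means)) + 1L] <- as.numeric(means)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
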
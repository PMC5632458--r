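# Independent brute-force oracles used across the suite. Each one takes the
# slow, literal route so it stays independent of the package's vectorized
# or compiled implementations.

# Unit-step geodesic reconstruction by dilation (8-connected), pure R.
oracle_reconstruct <- function(marker, mask) {
  shift <- function(m, di, dj) {
    M <- nrow(m); N <- ncol(m)
    out <- matrix(-Inf, M, N)
    out[max(1, 1 + di):min(M, M + di), max(1, 1 + dj):min(N, N + dj)] <-
      m[max(1, 1 - di):min(M, M - di), max(1, 1 - dj):min(N, N - dj)]
    out
  }
  cur <- pmin(marker, mask)
  repeat {
    d <- cur
    for (di in -1:1) for (dj in -1:1) d <- pmax(d, shift(cur, di, dj))
    nxt <- pmin(d, mask)
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
}

# Exhaustive-scan Otsu threshold over `levels` histogram bins on [0, 1].
oracle_otsu <- function(px, levels = 256) {
  breaks <- seq(0, 1, length.out = levels + 1)
  h <- hist(px, breaks = breaks, plot = FALSE)$counts
  mids <- (breaks[-1] + breaks[-(levels + 1)]) / 2
  best <- -Inf; best_t <- NA_real_
  for (k in 1:(levels - 1)) {
    w0 <- sum(h[1:k]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:k] * mids[1:k]) / w0
    m1 <- sum(h[(k + 1):levels] * mids[(k + 1):levels]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; best_t <- breaks[k + 1] }
  }
  best_t
}

# Binary dilation by a Euclidean disk of radius r, via distances.
oracle_disk_dilate <- function(mask, r) {
  idx <- which(mask == 1L, arr.ind = TRUE)
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (any((idx[, 1] - i)^2 + (idx[, 2] - j)^2 <= r^2)) out[i, j] <- 1L
    }
  }
  out
}

# Pixel-wise membership by direct accumulation over every patch window.
oracle_pixel_membership <- function(centers, mu, R, dims) {
  h <- (R - 1) %/% 2
  num <- matrix(0, dims[1], dims[2])
  den <- matrix(0, dims[1], dims[2])
  for (k in seq_len(nrow(centers))) {
    ri <- (centers[k, 1] - h):(centers[k, 1] + h)
    cj <- (centers[k, 2] - h):(centers[k, 2] + h)
    num[ri, cj] <- num[ri, cj] + mu[k]
    den[ri, cj] <- den[ri, cj] + 1
  }
  ifelse(den > 0, num / den, 0)
}

# Weighted moment by naive double loop.
oracle_moment <- function(px, field, p, q) {
  s <- 0
  for (i in seq_len(nrow(px))) {
    for (j in seq_len(ncol(px))) {
      s <- s + i^p * j^q * px[i, j] * field[i, j]
    }
  }
  s
}

# Radial ring distance by dense parametric sampling of the polar angle.
oracle_ring_distance <- function(xt, yt, a, b, n = 1e5) {
  phis <- seq(0, 2 * pi, length.out = n)
  rre_tab <- a * b / sqrt((b * cos(phis))^2 + (a * sin(phis))^2)
  vapply(seq_along(xt), function(k) {
    phi <- atan2(yt[k], xt[k]) %% (2 * pi)
    rre <- rre_tab[which.min(abs(phis - phi))]
    abs(sqrt(xt[k]^2 + yt[k]^2) - rre)
  }, numeric(1))
}

# A small soft elliptical ring field with noisy weights, for ellipse
# recovery tests: weights ~ N(0.9, wsd) clipped to [0, 1] on the ring
# |s - s_mid| < half_rel, zero elsewhere.
make_ring_field <- function(dims, center, phi0, a, b, half = 4, wsd = 0.05,
                            seed = 1) {
  set.seed(seed)
  pts <- cbind(rep(seq_len(dims[1]), times = dims[2]),
               rep(seq_len(dims[2]), each = dims[1]))
  tp <- transform_coords(pts, phi0, center)
  s <- sqrt((tp[, 1] / a)^2 + (tp[, 2] / b)^2)
  on_ring <- abs(s - 1) < half / b
  w <- numeric(length(s))
  w[on_ring] <- pmin(pmax(rnorm(sum(on_ring), 0.9, wsd), 0), 1)
  matrix(w, dims[1], dims[2])
}

# Shared phantom fixtures (generated once per test run).
default_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_slice(phantom_spec(), 1)
    cache
  }
})
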
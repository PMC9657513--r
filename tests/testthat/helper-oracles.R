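# Independent oracles, written deliberately in a different style from the
# package implementations they check.

# Exhaustive Otsu: for every candidate bin-edge split, recompute both class
# means from scratch and take the edge with the highest between-class
# variance (first/lowest edge on ties).
naive_otsu <- function(edges, counts) {
  centers <- (edges[-length(edges)] + edges[-1]) / 2
  cand <- numeric(0)
  bcvs <- numeric(0)
  for (k in 2:length(counts)) {
    lo <- 1:(k - 1)
    hi <- k:length(counts)
    w0 <- sum(counts[lo]); w1 <- sum(counts[hi])
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[lo] * centers[lo]) / w0
    mu1 <- sum(counts[hi] * centers[hi]) / w1
    cand <- c(cand, edges[k])
    bcvs <- c(bcvs, w0 * w1 * (mu0 - mu1)^2)
  }
  # lowest edge among (tolerance) ties for the maximum
  cand[bcvs >= max(bcvs) - 1e-10 * abs(max(bcvs))][1]
}

random_histogram <- function() {
  nbins <- sample(2:80, 1)
  lo <- runif(1, 20, 35)
  width <- runif(1, 0.02, 0.5)
  counts <- rpois(nbins, lambda = sample(c(1, 5, 50), 1))
  # ensure at least two non-empty bins
  if (sum(counts > 0) < 2) {
    idx <- sample(nbins, 2)
    counts[idx] <- counts[idx] + 1
  }
  structure(list(bin_edges = lo + width * (0:nbins), counts = counts,
                 bin_width = width),
            class = "temperature_histogram")
}

# Fan triangulation from the first vertex: polygon area as the absolute
# sum of signed triangle areas (P1, Pi, Pi+1).
fan_area <- function(verts) {
  v <- verts
  if (all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  p1 <- v[1, ]
  s <- 0
  for (i in 2:(nrow(v) - 1)) {
    a <- v[i, ] - p1
    b <- v[i + 1, ] - p1
    s <- s + (a[1] * b[2] - a[2] * b[1]) / 2
  }
  abs(s)
}

# Random simple polygon: star-shaped around the origin (sorted angles,
# positive radii guarantee simplicity).
random_simple_polygon <- function() {
  n <- sample(3:40, 1)
  theta <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, 0.5, 20)
  v <- cbind(r * cos(theta), r * sin(theta)) +
    matrix(runif(2, -50, 50), n, 2, byrow = TRUE)
  rbind(v, v[1, ])
}

# Radial numeric integration oracles for the Gaussian lesion profile
# T(r) = T_skin + A exp(-r^2 / (2 s^2)).
disk_mean_numeric <- function(T_skin, A, s, rho) {
  T_skin + stats::integrate(function(r) A * exp(-r^2 / (2 * s^2)) * 2 * pi * r,
                            0, rho)$value / (pi * rho^2)
}

annulus_mean_numeric <- function(T_skin, A, s, rho, width) {
  ro <- rho + width
  T_skin + stats::integrate(function(r) A * exp(-r^2 / (2 * s^2)) * 2 * pi * r,
                            rho, ro)$value / (pi * (ro^2 - rho^2))
}

# Regular closed polygon approximating a circle, for synthetic boundaries.
circle_polygon <- function(cx, cy, radius, n = 128) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  cbind(cx + radius * cos(th), cy + radius * sin(th))
}
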
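# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check.

# Brute-force dependent multivariate DTW by plain recursion with memoisation.
dtw_brute <- function(a, b) {
  n <- nrow(a); m <- nrow(b)
  memo <- matrix(NA_real_, n, m)
  cost <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
  rec <- function(i, j) {
    if (i < 1 || j < 1) return(Inf)
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- if (i == 1 && j == 1) 0 else min(rec(i - 1, j), rec(i, j - 1), rec(i - 1, j - 1))
    memo[i, j] <<- cost(i, j) + best
    memo[i, j]
  }
  rec(n, m)
}

# All-pairs shortest paths by Floyd-Warshall on a dense weight matrix
# (Inf = no edge).
floyd_warshall <- function(w) {
  n <- nrow(w)
  diag(w) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (w[i, k] + w[k, j] < w[i, j]) w[i, j] <- w[i, k] + w[k, j]
  w
}

# Adjusted Rand index between two labelings (Hubert & Arabie form).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  s_ij <- sum_comb(tab)
  s_a <- sum_comb(rowSums(tab))
  s_b <- sum_comb(colSums(tab))
  expected <- s_a * s_b / choose(n, 2)
  max_index <- (s_a + s_b) / 2
  if (max_index == expected) return(1)
  (s_ij - expected) / (max_index - expected)
}

# Mean silhouette width for a labeling over a coordinate matrix.
mean_silhouette <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  sil <- vapply(seq_len(nrow(coords)), function(i) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a_i <- mean(d[i, own])
    b_i <- min(vapply(setdiff(unique(labels), labels[i]),
                      function(l) mean(d[i, labels == l]), numeric(1)))
    (b_i - a_i) / max(a_i, b_i)
  }, numeric(1))
  mean(sil)
}

# 3x3 median filter oracle: reflected borders, straightforward loops.
median3x3_oracle <- function(img) {
  ny <- nrow(img); nx <- ncol(img)
  refl <- function(i, n) ifelse(i < 1, 2 - i, ifelse(i > n, 2 * n - i, i))
  out <- img
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    w <- numeric(9); k <- 1
    for (dy in -1:1) for (dx in -1:1) {
      w[k] <- img[refl(y + dy, ny), refl(x + dx, nx)]
      k <- k + 1
    }
    out[y, x] <- median(w)
  }
  out
}

# Straight constant-velocity track along +x.
straight_track <- function(n = 11, dt = 10, v_um_min = 6, id = "straight") {
  step <- v_um_min * dt / 60
  track(t = seq(0, by = dt, length.out = n),
        x = seq(0, by = step, length.out = n), y = rep(0, n), track_id = id)
}

# Fixed-modulus isotropic random-walk track (2D).
random_walk_track <- function(n_steps = 30, step = 1, dt = 10, id = "rw") {
  theta <- runif(n_steps, 0, 2 * pi)
  track(t = seq(0, by = dt, length.out = n_steps + 1),
        x = c(0, cumsum(step * cos(theta))), y = c(0, cumsum(step * sin(theta))),
        track_id = id)
}
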
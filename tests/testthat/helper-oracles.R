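# Independent brute-force oracles used to pin down the package's geometry,
# estimators and statistics. Everything here recomputes quantities from first
# principles, by enumeration or dense sampling, never by calling the code
# path under test.

# --- alpha-complex edge oracle -----------------------------------------------
# Samples the edge condition directly: a point shared by two Voronoi cells is
# equidistant from both sites, hence lies on their perpendicular bisector, so
# the candidate set is sampled densely along the bisector; a sample is a
# witness when the pair's sites are nearest there (no tolerance tricks) and
# within delta. Near-empty faces and distances close to delta are resolved by
# recursive local refinement.
oracle_alpha_edge <- function(coords, i, j, delta, n_samples = 20001L) {
  pi_ <- coords[i, ]; pj <- coords[j, ]
  d <- sqrt(sum((pi_ - pj)^2))
  if (d > 2 * delta) return(FALSE)
  if (d == 0) return(TRUE)
  m <- (pi_ + pj) / 2
  u <- c(-(pj - pi_)[2], (pj - pi_)[1]) / d
  Tmax <- sqrt(max(0, delta^2 - (d / 2)^2))
  eps <- 1e-9 * max(1, max(abs(coords)))
  others <- setdiff(seq_len(nrow(coords)), c(i, j))
  K <- coords[others, , drop = FALSE]
  probe <- function(ts) {
    P1 <- m[1] + ts * u[1]; P2 <- m[2] + ts * u[2]
    di <- sqrt((P1 - pi_[1])^2 + (P2 - pi_[2])^2)
    gap <- rep(Inf, length(ts))       # min_k d_k - d_i, >= 0 on the face
    for (r in seq_len(nrow(K)))
      gap <- pmin(gap, sqrt((P1 - K[r, 1])^2 + (P2 - K[r, 2])^2) - di)
    list(di = di, gap = gap)
  }
  decide <- function(lo, hi, n, depth) {
    ts <- seq(lo, hi, length.out = n)
    pr <- probe(ts)
    on_face <- pr$gap >= -eps
    pitch <- (hi - lo) / (n - 1)
    if (any(on_face)) {
      m1 <- min(pr$di[on_face])
      if (m1 <= delta - 2 * pitch) return(TRUE)
      if (depth >= 4) return(m1 <= delta * (1 + 1e-9) + 1e-12)
      tbest <- ts[on_face][which.min(pr$di[on_face])]
      return(decide(max(lo, tbest - 2 * pitch), min(hi, tbest + 2 * pitch),
                    n, depth + 1L))
    }
    if (depth >= 4) return(FALSE)
    amax <- which.max(pr$gap)
    if (pr$gap[amax] < -4 * pitch) return(FALSE)
    decide(max(lo, ts[amax] - 2 * pitch), min(hi, ts[amax] + 2 * pitch),
           n, depth + 1L)
  }
  decide(-Tmax - 1e-12, Tmax + 1e-12, n_samples, 0L)
}

oracle_alpha_graph <- function(coords, delta) {
  n <- nrow(coords)
  A <- matrix(0, n, n)
  D <- as.matrix(dist(coords))
  cand <- which(upper.tri(D) & D <= 2 * delta, arr.ind = TRUE)
  for (p in seq_len(nrow(cand))) {
    i <- cand[p, 1]; j <- cand[p, 2]
    if (oracle_alpha_edge(coords, i, j, delta)) A[i, j] <- A[j, i] <- 1
  }
  A
}

# --- estimator oracles (double loops, no vectorized shortcuts) ---------------
oracle_knn_edges <- function(coords, k) {
  n <- nrow(coords)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- sqrt(rowSums((coords - matrix(coords[i, ], n, ncol(coords),
                                       byrow = TRUE))^2))
    d[i] <- Inf
    nn <- order(d, seq_len(n))[seq_len(k)]
    A[i, nn] <- 1
  }
  pmax(A, t(A))
}

oracle_delta <- function(coords, k) {
  n <- nrow(coords)
  acc <- 0
  for (i in seq_len(n)) {
    d <- numeric(0)
    for (j in seq_len(n)) if (j != i)
      d <- c(d, sqrt(sum((coords[i, ] - coords[j, ])^2)))
    acc <- acc + mean(sort(d)[seq_len(k)])
  }
  acc / n
}

oracle_root <- function(H) {
  n <- nrow(H)
  best <- -Inf; at <- 0L
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) s <- s + sqrt(sum((H[i, ] - H[j, ])^2))
    if (s > best) { best <- s; at <- i }
  }
  at
}

# pair-counting ARI: classify every unordered pair as together/apart in each
# labeling and apply the chance-corrected agreement formula
oracle_ari <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa) n10 <- n10 + 1
    else if (sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  2 * (n11 * n00 - n10 * n01) /
    ((n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00))
}

# exact two-sided rank-sum p by enumeration of all group assignments
oracle_wilcoxon_exact_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  W_obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(length(pooled), nx)
  Ws <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- mean(Ws)
  min(1, 2 * min(mean(Ws <= W_obs), mean(Ws >= W_obs)))
}

# regularizer recomputed as the literal normalized double sum
oracle_reg_all_pairs <- function(coords, H) {
  n <- nrow(coords)
  Ds <- matrix(0, n, n); Dz <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    Ds[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    Dz[i, j] <- sqrt(sum((H[i, ] - H[j, ])^2))
  }
  if (max(Ds) > 0) Ds <- Ds / max(Ds) else Ds[] <- 0
  if (max(Dz) > 0) Dz <- Dz / max(Dz) else Dz[] <- 0
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    acc <- acc + Ds[i, j] * (1 - Dz[i, j])
  acc / n^2
}

# --- small fixtures ----------------------------------------------------------
tiny_layered <- function(seed = 1, cells_per_layer = 60L) {
  simulate_layered_tissue(cells_per_layer = cells_per_layer, seed = seed)
}
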
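# Independent brute-force oracles used to validate the fast implementations.
# These deliberately use naive loops / literal formulas, never the package's
# own code paths.

# All-pairs shortest paths by Floyd-Warshall on a matrix of edge lengths
# (0 = no edge off-diagonal).
fw_distances <- function(lengths) {
  n <- nrow(lengths)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && lengths[i, j] > 0) d[i, j] <- lengths[i, j]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

oracle_spl <- function(w) {
  lens <- ifelse(w > 0, 1 / w, 0)
  diag(lens) <- 0
  fw_distances(lens)
}

oracle_global_eff <- function(w) {
  n <- nrow(w)
  d <- oracle_spl(w)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(d[i, j])) tot <- tot + 1 / d[i, j]
  }
  tot / (n * (n - 1))
}

# Weighted clustering: triple enumeration with max-weight normalization.
oracle_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(numeric(n))
  u <- w / mx
  k <- rowSums(w > 0)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h) {
        s <- s + (u[i, j] * u[i, h] * u[j, h])^(1 / 3)
      }
    }
    out[i] <- s / (k[i] * (k[i] - 1))
  }
  out
}

# Weighted local efficiency: literal neighborhood formula with cube-root
# lengths, exhaustive loops.
oracle_local_eff <- function(w) {
  n <- nrow(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    v <- which(w[i, ] > 0)
    k <- length(v)
    if (k < 2) next
    sub <- w[v, v, drop = FALSE]
    lens <- ifelse(sub > 0, (1 / sub)^(1 / 3), 0)
    d <- fw_distances(lens)
    s <- 0
    for (a in seq_len(k)) for (b in seq_len(k)) {
      if (a != b && is.finite(d[a, b]) && d[a, b] > 0) {
        s <- s + (w[i, v[a]] * w[i, v[b]])^(1 / 3) / d[a, b]
      }
    }
    out[i] <- s / (k * (k - 1))
  }
  out
}

# Random symmetric weighted graph with weights in (0, 1].
rand_graph <- function(n, density = 0.5) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  m <- sum(ut)
  vals <- ifelse(runif(m) < density, runif(m, 0.05, 1), 0)
  w[ut] <- vals
  w + t(w)
}

# Independent Benjamini-Hochberg step-up implementation.
step_up_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- (m / seq_len(m)) * p[o]
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Exact two-sided Wilcoxon signed-rank p by full 2^n sign enumeration
# (midranks of |d|; returns min-sum statistic and p).
enum_wilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  m_tot <- n * (n + 1) / 2
  w_obs <- min(v_obs, m_tot - v_obs)
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(mask))[1:n]
    v <- sum(r[signs == 1])
    if (min(v, m_tot - v) <= w_obs) count <- count + 1L
  }
  list(w = w_obs, p = count / 2^n)
}

# Closed-form simple OLS with hat values and Cook's distances.
oracle_ols <- function(x, y) {
  n <- length(x)
  X <- cbind(1, x)
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  fitted <- X %*% beta
  e <- y - fitted
  h <- diag(X %*% xtx_inv %*% t(X))
  s2 <- sum(e^2) / (n - 2)
  cooks <- e^2 * h / (2 * s2 * (1 - h)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - sum(e^2) / ss_tot
  f <- r2 * (n - 2) / (1 - r2)
  list(beta = beta[2], intercept = beta[1], r2 = r2, f = f,
       resid = as.numeric(e), h = h, cooks = as.numeric(cooks))
}

# Small parcellation with all four edge classes, for fast property tests.
small_parcellation <- function(n_cortical = 6) {
  generate_parcellation(n_cortical,
                        c("Brain-stem", "Left-Caudate", "Right-Caudate"))
}

# Hand-assembled cohort from explicit per-subject matrices.
manual_cohort <- function(parc, case_counts, case_fa, ctrl_counts, ctrl_fa) {
  stopifnot(length(case_counts) == length(ctrl_counts))
  pairs <- lapply(seq_along(case_counts), function(p) {
    list(case = list(id = sprintf("p%d_case", p), group = "case", pair = p,
                     age = 20, counts = case_counts[[p]], fa = case_fa[[p]]),
         control = list(id = sprintf("p%d_control", p), group = "control",
                        pair = p, age = 21, counts = ctrl_counts[[p]],
                        fa = ctrl_fa[[p]]))
  })
  structure(list(pairs = pairs, parcellation = parc, spec = NULL),
            class = "cohort")
}
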
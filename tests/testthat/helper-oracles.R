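# Independent brute-force oracles used to validate the package's metric
# implementations on small graphs. These deliberately use naive loops and
# different algorithms (triangle enumeration, Floyd-Warshall, joint-entropy
# NMI, exhaustive partition search) from the package code paths.

rand_graph <- function(n, density = 0.5, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  m <- max(2, round(density * length(ut)))
  picks <- sample(ut, min(m, length(ut)))
  w[picks] <- runif(length(picks), 0.05, 1)
  w <- w + t(w)
  weighted_graph(w)
}

# Onnela weighted clustering by explicit triangle enumeration
bf_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(rep(0, n))
  wh <- w / mx
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    acc <- 0
    for (j in nb) for (h in nb) {
      if (j != h) acc <- acc + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
    }
    ci[i] <- acc / (k * (k - 1))
  }
  ci
}

# all-pairs shortest paths on 1/w lengths, Floyd-Warshall
bf_efficiency <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  d[w > 0] <- 1 / w[w > 0]
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# Newman modularity by the direct double sum over node pairs
bf_modularity <- function(w, a) {
  dimnames(w) <- NULL
  w2 <- sum(w)
  s <- rowSums(w)
  q <- 0
  n <- nrow(w)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (a[i] == a[j]) q <- q + w[i, j] - s[i] * s[j] / w2
  }
  q / w2
}

# NMI via joint entropy: 2*(H(a) + H(b) - H(a,b)) / (H(a) + H(b)), log2
bf_nmi <- function(a, b) {
  n <- length(a)
  ent <- function(x) {
    p <- as.numeric(table(x)) / n
    -sum(p * log2(p))
  }
  ha <- ent(a); hb <- ent(b)
  hj <- ent(paste(a, b, sep = "/"))
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  2 * (ha + hb - hj) / (ha + hb)
}

# participation coefficient by per-node, per-module loops
bf_pc <- function(w, a, weighted = TRUE) {
  if (!weighted) w <- (w > 0) + 0
  n <- nrow(w)
  pc <- numeric(n)
  for (i in seq_len(n)) {
    s <- sum(w[i, ])
    if (s == 0) next
    acc <- 0
    for (m in unique(a)) acc <- acc + (sum(w[i, a == m]) / s)^2
    pc[i] <- 1 - acc
  }
  pc
}

# all set partitions of n elements (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, mx) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(mx + 1)) rec(c(prefix, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

# exhaustive maximum-modularity score
bf_best_q <- function(w) {
  parts <- all_partitions(nrow(w))
  max(vapply(parts, function(a) bf_modularity(w, a), 0))
}

# Watts-Strogatz-style small-world fixture: ring lattice plus a few
# shortcuts, unit weights
lattice_shortcut_graph <- function(n = 30, k = 2, shortcuts = 6, seed = 5) {
  set.seed(seed)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) for (d in seq_len(k)) {
    j <- ((i + d - 1) %% n) + 1
    w[i, j] <- w[j, i] <- 1
  }
  added <- 0
  while (added < shortcuts) {
    ij <- sample(n, 2)
    if (w[ij[1], ij[2]] == 0) {
      w[ij[1], ij[2]] <- w[ij[2], ij[1]] <- 1
      added <- added + 1
    }
  }
  weighted_graph(w)
}
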
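#' Newman weighted modularity
#'
#' `Q = sum_m [ W_m / W - (S_m / 2W)^2 ]` with `W` the total edge weight,
#' `W_m` the intra-module weight and `S_m` the summed strength of module
#' `m`. A single-module partition scores exactly 0.
#'
#' @param graph a `weighted_graph`.
#' @param partition a `node_partition` (or assignment vector) covering all
#'   nodes.
#' @return scalar `Q` in `[-1, 1]`.
#' @export
modularity_score <- function(graph, partition) {
  stopifnot_graph(graph)
  p <- as_partition(partition, n_nodes(graph))
  w2 <- sum(graph$weights)  # = 2W
  if (w2 == 0) return(0)
  a <- p$assignment
  s <- rowSums(graph$weights)
  intra <- vapply(seq_len(p$m), function(m) {
    idx <- a == m
    sum(graph$weights[idx, idx])
  }, 0)
  sm <- vapply(seq_len(p$m), function(m) sum(s[a == m]), 0)
  sum(intra / w2 - (sm / w2)^2)
}

# Incremental Q machinery shared by kl_refine: module strength sums and the
# per-node weight into each module.
kappa_of <- function(w_row, a, m) {
  out <- numeric(m)
  agg <- rowsum(w_row, a)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Kernighan-Lin-style modularity refinement
#'
#' Iterative refinement in the Kernighan-Lin scheme: in each pass every
#' node, visited in seeded-random order, is moved exactly once to the
#' module (existing or a fresh singleton) with the largest modularity
#' change, even when that change is negative; the pass then reverts to the
#' best intermediate state it visited. Accepting temporarily unprofitable
#' moves lets the search tunnel out of configurations where no single
#' positive-gain move exists (e.g. the all-singleton start on a regular
#' graph). Passes repeat, followed by a best-pairwise-module-merge check,
#' until neither yields an improvement. The returned partition is
#' canonical (node #1 in module 1) and its modularity is never below that
#' of the initial partition.
#'
#' @param graph a `weighted_graph`.
#' @param initial starting `node_partition` (or assignment vector); the
#'   all-singleton partition `1..N` is the conventional cold start.
#' @param seed optional integer seed; `NULL` continues the current RNG
#'   stream (used by [consensus_partition()]).
#' @param restarts number of independent seeded restarts; the partition
#'   with the highest modularity is returned. The default single restart
#'   is what [consensus_partition()] chains; a handful of restarts
#'   substantially raises the chance of reaching the global optimum on
#'   rugged modularity landscapes.
#' @return a canonical `node_partition`.
#' @export
kl_refine <- function(graph, initial = seq_len(n_nodes(graph)),
                      seed = NULL, restarts = 1) {
  stopifnot_graph(graph)
  if (!is.null(seed)) set.seed(seed)
  if (restarts > 1) {
    cands <- lapply(seq_len(restarts), function(r)
      kl_refine(graph, initial, seed = NULL))
    qs <- vapply(cands, function(p) modularity_score(graph, p), 0)
    return(cands[[which.max(qs)]])
  }
  n <- n_nodes(graph)
  p <- as_partition(initial, n)
  a <- p$assignment
  w <- unname(graph$weights)
  s <- rowSums(w)
  w2 <- sum(s)
  if (w2 == 0) return(node_partition(rep(1L, n)))
  eps <- 1e-12
  repeat {
    res <- greedy_passes(w, s, w2, a, eps)
    a <- res$a
    # greedy moves converged: try the best pairwise module merge
    mg <- best_merge(w, s, a, w2)
    if (!is.null(mg)) {
      a[a == mg[2]] <- mg[1]
      next
    }
    # then Kernighan-Lin tunneling passes over forced moves: one steepest
    # pass, and a few random-order passes that explore different escape
    # paths; only positive-gain prefixes are ever accepted
    kl <- kl_pass(w, s, w2, a, eps)
    if (kl$gain <= eps) {
      for (try in 1:4) {
        kl <- kl_pass(w, s, w2, a, eps, order = sample.int(n))
        if (kl$gain > eps) break
      }
    }
    if (kl$gain <= eps) break
    a <- kl$a
  }
  node_partition(a)
}

# Repeated positive-gain sweeps: nodes in seeded-random order, each moved
# to the module (or fresh singleton) with the largest strictly positive
# modularity gain; stops when a full sweep makes no move.
greedy_passes <- function(w, s, w2, a, eps) {
  n <- length(a)
  a <- match(a, unique(a))
  n_mod <- max(a)
  smod <- as.numeric(tabulate_weighted(a, s, n_mod))
  repeat {
    improved <- FALSE
    for (i in sample.int(n)) {
      ai <- a[i]
      kap <- kappa_of(w[i, ], a, n_mod)
      cand <- which(kap > 0)
      empty <- which(smod[seq_len(n_mod)] == 0)
      new_mod <- if (length(empty)) empty[1] else n_mod + 1L
      cand <- unique(c(cand, new_mod))
      cand <- cand[cand != ai]
      if (!length(cand)) next
      kap_cand <- ifelse(cand <= length(kap), kap[pmin(cand, length(kap))], 0)
      kap_cand[cand > length(kap)] <- 0
      s_cand <- ifelse(cand <= n_mod, smod[pmin(cand, n_mod)], 0)
      s_cand[cand > n_mod] <- 0
      dq <- 2 * (kap_cand - kap[ai]) / w2 -
        2 * s[i] * (s_cand - (smod[ai] - s[i])) / w2^2
      best <- which.max(dq)
      if (dq[best] > eps) {
        b <- cand[best]
        if (b > n_mod) {
          n_mod <- b
          smod <- c(smod, numeric(b - length(smod)))
        }
        smod[ai] <- smod[ai] - s[i]
        smod[b] <- smod[b] + s[i]
        a[i] <- b
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(a = a)
}

# One Kernighan-Lin pass: every node is moved exactly once, each step
# taking the single best (node, module) move among not-yet-moved nodes even
# when its gain is negative; the pass then reverts to the best intermediate
# partition. This tunnels out of states where no positive single move
# exists. When `order` is supplied, nodes are instead forced to move in
# that order (each to its own best target), which randomizes the escape
# path. Returns the improved assignment and its gain (0 if none).
kl_pass <- function(w, s, w2, a, eps, order = NULL) {
  n <- length(a)
  a <- match(a, unique(a))
  n_mod <- max(a) + 1L  # one trailing empty slot
  ind <- matrix(0, n, n_mod)
  ind[cbind(seq_len(n), a)] <- 1
  kap <- w %*% ind
  smod <- as.numeric(crossprod(ind, s))
  cur <- a
  unmoved <- rep(TRUE, n)
  total <- 0
  cumdq <- numeric(n)
  moves <- matrix(0L, n, 2)
  for (step in seq_len(n)) {
    idx <- if (is.null(order)) which(unmoved) else order[step]
    own <- cbind(seq_along(idx), cur[idx])
    dq <- 2 * sweep(kap[idx, , drop = FALSE], 1,
                    kap[idx, , drop = FALSE][own], `-`) / w2 -
      2 * outer(s[idx], smod, function(si, sc) si * sc) / w2^2 +
      2 * s[idx] * (smod[cur[idx]] - s[idx]) / w2^2
    dq[own] <- -Inf
    pick <- arrayInd(which.max(dq), dim(dq))
    i <- idx[pick[1]]; b <- pick[2]
    ai <- cur[i]
    total <- total + dq[pick[1], pick[2]]
    cur[i] <- b
    kap[, ai] <- kap[, ai] - w[, i]
    kap[, b] <- kap[, b] + w[, i]
    smod[ai] <- smod[ai] - s[i]
    smod[b] <- smod[b] + s[i]
    unmoved[i] <- FALSE
    if (b == n_mod) {
      n_mod <- n_mod + 1L
      kap <- cbind(kap, 0)
      smod <- c(smod, 0)
    }
    cumdq[step] <- total
    moves[step, ] <- c(i, b)
  }
  best <- which.max(cumdq)
  if (cumdq[best] <= eps) return(list(a = a, gain = 0))
  out <- a
  for (k in seq_len(best)) out[moves[k, 1]] <- moves[k, 2]
  list(a = out, gain = cumdq[best])
}

# Largest-gain merge of two modules, or NULL when no merge increases Q.
# Merging modules u, v changes Q by 2*B_uv/W2 - 2*S_u*S_v/W2^2 with B_uv
# the total weight between them.
best_merge <- function(w, s, a, w2) {
  mods <- sort(unique(a))
  if (length(mods) < 2) return(NULL)
  ind <- outer(a, mods, `==`) + 0
  between <- t(ind) %*% w %*% ind
  smod <- as.numeric(t(ind) %*% s)
  gain <- 2 * between / w2 - 2 * outer(smod, smod) / w2^2
  diag(gain) <- -Inf
  best <- which(gain == max(gain), arr.ind = TRUE)[1, ]
  if (gain[best[1], best[2]] <= 1e-12) return(NULL)
  c(mods[min(best)], mods[max(best)])
}

tabulate_weighted <- function(a, s, m) {
  out <- numeric(m)
  agg <- rowsum(s, a)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Consensus community structure over repeated refinements
#'
#' Runs a chain of refinements `M^0 = (1, ..., N) -> M^1 -> ... -> M^T`
#' where each step seeds [kl_refine()] with the previous partition
#' (`T = iterations`, conventionally 100), canonicalizing every step so
#' that node #1 anchors module 1 and module ids are numbered consecutively
#' by first appearance. The final affiliation assigns each node the module
#' id it received most often across the chain (ties resolved in favor of
#' the earliest iteration), canonicalized once more.
#'
#' @param graph a `weighted_graph`.
#' @param iterations chain length (default 100).
#' @param seed integer seed; the whole chain is reproducible from it.
#' @return a canonical `node_partition` with attributes `chain`
#'   (iterations x N matrix of canonical assignments), `Q` (modularity of
#'   the consensus) and `seed`.
#' @export
consensus_partition <- function(graph, iterations = 100, seed = 1L) {
  stopifnot_graph(graph)
  if (iterations < 1) stop("`iterations` must be >= 1", call. = FALSE)
  set.seed(seed)
  n <- n_nodes(graph)
  chain <- matrix(0L, nrow = iterations, ncol = n)
  cur <- seq_len(n)
  for (t in seq_len(iterations)) {
    cur <- kl_refine(graph, cur, seed = NULL)$assignment
    chain[t, ] <- cur
  }
  final <- vapply(seq_len(n), function(i) {
    ids <- chain[, i]
    tab <- table(ids)
    top <- as.integer(names(tab)[tab == max(tab)])
    if (length(top) == 1L) return(top)
    # tie: earliest iteration whose value is among the tied ids
    ids[min(which(ids %in% top))]
  }, integer(1))
  out <- node_partition(final)
  attr(out, "chain") <- chain
  attr(out, "Q") <- modularity_score(graph, out)
  attr(out, "seed") <- seed
  out
}

#' Partition similarity by normalized mutual information
#'
#' `p_d = 2 I(p1; p2) / (H(p1) + H(p2))` with natural-log entropies
#' (the base cancels in the ratio). Identical partitions score 1; despite
#' the historical name "partition distance", larger values mean more
#' similar. Conventions for degenerate cases: 1 when both partitions are
#' single-module, 0 when exactly one has zero entropy.
#'
#' @param p1,p2 `node_partition`s (or assignment vectors) over the same
#'   nodes.
#' @return `p_d` in `[0, 1]`; symmetric in its arguments.
#' @export
partition_similarity <- function(p1, p2) {
  p1 <- as_partition(p1); p2 <- as_partition(p2)
  a <- p1$assignment; b <- p2$assignment
  if (length(a) != length(b))
    stop("partitions cover different node counts", call. = FALSE)
  n <- length(a)
  tab <- table(a, b) / n
  pa <- rowSums(tab); pb <- colSums(tab)
  ha <- -sum(pa * log(pa))
  hb <- -sum(pb * log(pb))
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
  max(0, min(1, 2 * mi / (ha + hb)))
}
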
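#' Paired permutation test with max-statistic FWE correction
#'
#' Computes a paired t statistic per node on the subject-wise differences
#' `d = a - b` and corrects for family-wise error with the distribution of
#' the maximal statistic: under the null, each subject's difference vector
#' is sign-flipped as a whole (jointly across nodes, preserving the spatial
#' correlation the correction relies on), and the corrected p value of node
#' `i` is the fraction of permutations whose maximum absolute t across
#' nodes reaches `|t_i|`.
#'
#' With `n` subjects, when `2^n <= n_perm` the full sign-flip distribution
#' is enumerated exactly (the observed labeling included); otherwise
#' `n_perm` random flips are drawn and the add-one estimator
#' `p = (1 + #exceedances) / (n_perm + 1)` is used, so p values are never
#' zero.
#'
#' @param values_a,values_b subjects x nodes matrices of matched
#'   observations (e.g. nodal strength per subject under two conditions).
#' @param n_perm permutation budget (default 10000).
#' @param seed integer seed (used only when sampling).
#' @return object of class `permutation_result`: list with `t` (per-node
#'   observed statistic), `p` (FWE-corrected, in `(0, 1]`), `n_perm`
#'   (permutations actually used), `exact` flag and `seed`.
#' @export
paired_permutation_tmax <- function(values_a, values_b, n_perm = 10000,
                                    seed = 1L) {
  a <- as.matrix(values_a); b <- as.matrix(values_b)
  if (!all(dim(a) == dim(b)))
    stop("`values_a` and `values_b` must have matching dimensions",
         call. = FALSE)
  n <- nrow(a)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  d <- a - b
  t_obs <- t_paired(d)
  if (any(attr(t_obs, "zero_var")))
    warning("zero-variance differences at ",
            sum(attr(t_obs, "zero_var")), " node(s); t set to 0",
            call. = FALSE)
  exact <- 2^n <= n_perm
  if (exact) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    n_used <- nrow(signs)
  } else {
    set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                    nrow = n_perm)
    n_used <- n_perm
  }
  tmax <- tmax_distribution(d, signs)
  t_abs <- abs(t_obs)
  exceed <- vapply(t_abs, function(x) sum(tmax >= x - 1e-12), 0)
  p <- if (exact) exceed / n_used else (1 + exceed) / (n_used + 1)
  structure(list(t = as.numeric(t_obs), p = p, n_perm = n_used,
                 exact = exact, seed = if (exact) NA_integer_ else seed,
                 nodes = colnames(a)),
            class = "permutation_result")
}

# Paired t per column of a difference matrix; zero-variance columns get 0.
t_paired <- function(d) {
  n <- nrow(d)
  m <- colMeans(d)
  v <- (colSums(d^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  tt <- ifelse(v > 0, m / sqrt(v / n), 0)
  attr(tt, "zero_var") <- v <= 0
  tt
}

# Max |t| across nodes for each row of a sign matrix. The squared
# differences are sign-invariant, so only the permuted means need the
# matrix product.
tmax_distribution <- function(d, signs) {
  n <- nrow(d)
  ssq <- colSums(d^2)
  m_perm <- (signs %*% d) / n
  v_perm <- sweep(-n * m_perm^2, 2, ssq, `+`) / (n - 1)
  v_perm[v_perm < 1e-15] <- Inf  # zero-variance permutations contribute t=0
  t_perm <- abs(m_perm) / sqrt(v_perm / n)
  apply(t_perm, 1, max)
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %d nodes, %d permutations%s; min p = %.4g\n",
              length(x$t), x$n_perm, if (x$exact) " (exact)" else "",
              min(x$p)))
  invisible(x)
}

#' Between-group consistency check on time-series features
#'
#' Unpaired max-statistic permutation test comparing two groups of subjects
#' on per-node summary features of their time series (the temporal mean and
#' SD of each node's signal). Used to verify that data pooled from two
#' cohorts are not biased by inter-subject differences.
#'
#' @param series_a,series_b lists of [roi_panel()]s (or subjects x T x
#'   nodes arrays), one element/slice per subject; node sets must align.
#' @param n_perm number of random group-label permutations (default 10000).
#' @param seed integer seed.
#' @return data.frame with one row per node x feature: `node`, `feature`
#'   (`"mean"` or `"sd"`), `t` and FWE-corrected `p` (max statistic taken
#'   over all nodes and both features).
#' @export
group_consistency_check <- function(series_a, series_b, n_perm = 10000,
                                    seed = 1L) {
  fa <- series_features(series_a)
  fb <- series_features(series_b)
  if (!identical(colnames(fa$mean), colnames(fb$mean)))
    stop("node sets of the two groups do not align", call. = FALSE)
  x <- cbind(rbind(fa$mean, fb$mean), rbind(fa$sd, fb$sd))
  n_a <- nrow(fa$mean); n_b <- nrow(fb$mean)
  if (n_a < 2 || n_b < 2)
    stop("need at least 2 subjects per group", call. = FALSE)
  grp <- c(rep(1L, n_a), rep(2L, n_b))
  t_obs <- t_unpaired(x, grp == 1L)
  set.seed(seed)
  tmax <- replicate(n_perm, {
    g <- sample(grp) == 1L
    max(abs(t_unpaired(x, g)))
  })
  p <- vapply(abs(t_obs),
              function(tt) (1 + sum(tmax >= tt - 1e-12)) / (n_perm + 1), 0)
  n_nodes <- ncol(fa$mean)
  data.frame(node = rep(colnames(fa$mean), 2),
             feature = rep(c("mean", "sd"), each = n_nodes),
             t = as.numeric(t_obs), p = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

series_features <- function(series) {
  if (is.array(series) && length(dim(series)) == 3) {
    mats <- lapply(seq_len(dim(series)[1]), function(s) series[s, , ])
  } else if (is.list(series)) {
    mats <- lapply(series, function(p) {
      if (inherits(p, "roi_panel")) p$data else as.matrix(p)
    })
  } else stop("unsupported series container", call. = FALSE)
  list(mean = do.call(rbind, lapply(mats, colMeans)),
       sd = do.call(rbind, lapply(mats, function(m) apply(m, 2, stats::sd))))
}

# Two-sample pooled-variance t per column; zero pooled variance gives 0.
t_unpaired <- function(x, in_a) {
  xa <- x[in_a, , drop = FALSE]; xb <- x[!in_a, , drop = FALSE]
  na <- nrow(xa); nb <- nrow(xb)
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- (colSums(xa^2) - na * ma^2) / (na - 1)
  vb <- (colSums(xb^2) - nb * mb^2) / (nb - 1)
  sp <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp * (1 / na + 1 / nb))
  ifelse(se > 0, (ma - mb) / se, 0)
}
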
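#' Cluster-based sign-flip permutation test for peri-event firing rates
#'
#' Tests, per unit and pattern, whether binned peri-event firing rates differ
#' from the pre-event baseline. Each trial's mean baseline rate is subtracted
#' from that trial's bin vector; a one-sample t-statistic per bin across
#' trials forms the first level, bins with two-tailed `p < alpha_first` are
#' merged into contiguous same-sign clusters, and each cluster's mass (sum of
#' t-values) is referred to a permutation null built by flipping the sign of
#' every trial's difference vector with probability 1/2 and recording the
#' maximum absolute cluster mass per permutation. Cluster
#' `p = (1 + #(null >= observed)) / (1 + n_perm)`; clusters in either
#' direction are read off this common max-|mass| null one-sided at
#' `alpha_cluster`, which controls the familywise any-cluster error at about
#' `alpha_cluster` overall. With `exact = TRUE` (feasible up to ~20 trials)
#' all `2^n` sign assignments are enumerated instead, giving a deterministic,
#' trial-order-invariant p-value.
#'
#' Bins with zero variance across trials are excluded from cluster formation
#' (they break contiguity) with a warning.
#'
#' @param binned trials x bins matrix ([bin_rates]).
#' @param baseline trials x baseline-bins matrix, or a per-trial numeric
#'   vector of baseline rates.
#' @param alpha_first first-level two-tailed threshold (default 0.01).
#' @param alpha_cluster cluster-level threshold (default 0.05, one-sided per
#'   direction on the max-|mass| null).
#' @param n_perm Monte-Carlo permutations (default 10000).
#' @param seed seed for the flip draws; fixed seed makes the test
#'   reproducible.
#' @param exact enumerate all `2^n_trials` sign flips (requires
#'   `n_trials <= 20`).
#' @return list of class `cluster_result`: `clusters` (data.frame:
#'   `start_bin`, `end_bin`, `direction`, `mass`, `p`, `significant`),
#'   `t_obs`, `null_max`, and the parameters.
#' @export
cluster_permutation_test <- function(binned, baseline, alpha_first = 0.01,
                                     alpha_cluster = 0.05, n_perm = 10000,
                                     seed = NULL, exact = FALSE) {
  binned <- as.matrix(binned)
  n <- nrow(binned); B <- ncol(binned)
  if (n < 5 && !exact) stop("at least 5 trials required")
  base_mean <- if (is.matrix(baseline)) rowMeans(baseline)
  else as.numeric(baseline)
  if (length(base_mean) != n)
    stop("baseline must have one value (or row) per trial")
  D <- binned - base_mean
  mu <- colMeans(D)
  ss <- colSums(D^2)
  varD <- (ss - n * mu^2) / (n - 1)
  bad <- varD <= 0
  if (any(bad))
    warning(sum(bad), " zero-variance bin(s) excluded from cluster formation")
  t_obs <- rep(NA_real_, B)
  t_obs[!bad] <- mu[!bad] / sqrt(varD[!bad] / n)
  tcrit <- stats::qt(1 - alpha_first / 2, df = n - 1)

  find_clusters <- function(tv) {
    supra <- !is.na(tv) & abs(tv) > tcrit
    sgn <- sign(tv); sgn[!supra] <- 0
    out <- list()
    j <- 1L
    while (j <= B) {
      if (sgn[j] != 0) {
        k <- j
        while (k < B && sgn[k + 1L] == sgn[j]) k <- k + 1L
        out[[length(out) + 1L]] <- data.frame(
          start_bin = j, end_bin = k,
          direction = if (sgn[j] > 0) "up" else "down",
          mass = sum(tv[j:k]))
        j <- k + 1L
      } else j <- j + 1L
    }
    if (length(out)) do.call(rbind, out)
    else data.frame(start_bin = integer(), end_bin = integer(),
                    direction = character(), mass = numeric())
  }
  obs <- find_clusters(t_obs)

  # max |cluster mass| per sign assignment, vectorized across assignments
  max_mass <- function(S) {
    M <- (S %*% D) / n                       # nperm x B flipped means
    tv <- M / sqrt(sweep(-M^2, 2, ss / n, `+`) * (n / (n - 1)) / n)
    tv[, bad] <- 0
    tv[!is.finite(tv)] <- 0
    pos <- tv > tcrit; neg <- tv < -tcrit
    run_p <- run_n <- mx <- numeric(nrow(S))
    for (j in seq_len(B)) {
      run_p <- (run_p + tv[, j]) * pos[, j]
      run_n <- (run_n + tv[, j]) * neg[, j]
      mx <- pmax(mx, run_p, -run_n)
    }
    mx
  }

  if (exact) {
    if (n > 20) stop("exact enumeration limited to 20 trials")
    grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null_max <- max_mass(grid)
    pfun <- function(m) mean(null_max >= abs(m))
    n_used <- nrow(grid)
  } else {
    S <- with_seed(seed,
                   matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                          n_perm, n))
    null_max <- max_mass(S)
    pfun <- function(m) (1 + sum(null_max >= abs(m))) / (1 + n_perm)
    n_used <- n_perm
  }
  obs$p <- if (nrow(obs)) vapply(obs$mass, pfun, 0) else numeric()
  obs$significant <- obs$p < alpha_cluster
  structure(list(clusters = obs, t_obs = t_obs, null_max = null_max,
                 alpha_first = alpha_first, alpha_cluster = alpha_cluster,
                 n_perm = n_used, exact = exact, seed = seed,
                 excluded_bins = which(bad)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), %s null of size %d\n",
              nrow(x$clusters),
              if (x$exact) "exact sign-flip" else "Monte-Carlo", x$n_perm))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Convert significant clusters to time windows
#'
#' @param result a `cluster_result`.
#' @param bin_centers_s bin-center times (s) of the tested matrix.
#' @return data.frame with `direction`, `from_s`, `to_s`, `mass`, `p` for
#'   significant clusters only.
#' @export
cluster_windows <- function(result, bin_centers_s) {
  cl <- result$clusters[result$clusters$significant, , drop = FALSE]
  bw <- if (length(bin_centers_s) > 1) diff(bin_centers_s[1:2]) else 0
  data.frame(direction = cl$direction,
             from_s = bin_centers_s[cl$start_bin] - bw / 2,
             to_s = bin_centers_s[cl$end_bin] + bw / 2,
             mass = cl$mass, p = cl$p)
}
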
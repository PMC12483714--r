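# Post-hoc normalisation, rank-clustering summaries, point estimates, and
# the posterior predictive goodness-of-fit check.

retained <- function(chain, burnin = NULL) {
  if (is.null(burnin)) burnin <- chain$burnin
  if (burnin >= chain$n_iters) stop("burn-in leaves no retained iterations")
  seq.int(burnin + 1L, chain$n_iters)
}

#' Normalise worth samples to sum to one
#'
#' Rescales each iteration's worth vector to the unit simplex. The BTL
#' likelihood depends on worths only through ratios, so any fixed scale is
#' valid; sum-to-one makes each worth interpretable as the probability of
#' being the first choice among all objects. Rescaling preserves cluster
#' equalities and all pairwise preference probabilities.
#'
#' @param x A matrix of worth samples (iterations in rows) or an
#'   `rcbtl_chain`.
#' @return The same type with each row summing to 1.
#' @export
normalize_worths <- function(x) {
  if (inherits(x, "rcbtl_chain")) {
    x$worths <- x$worths / rowSums(x$worths)
    return(x)
  }
  if (is.null(dim(x))) return(x / sum(x))
  x / rowSums(x)
}

#' Posterior co-clustering matrix
#'
#' Entry `(i, j)` is the fraction of retained iterations in which objects
#' `i` and `j` occupy the same rank-cluster: the posterior probability that
#' they are equal in population-level rank. Symmetric with unit diagonal.
#'
#' @param chain An `rcbtl_chain`.
#' @param burnin Iterations to discard (default: the chain's stored burn-in,
#'   half the run).
#' @return A `J x J` numeric matrix with object labels as dimnames.
#' @export
cocluster_matrix <- function(chain, burnin = NULL) {
  keep <- retained(chain, burnin)
  A <- chain$assignments[keep, , drop = FALSE]
  J <- ncol(A)
  M <- diag(1, J)
  for (i in seq_len(J - 1L)) {
    for (j in seq.int(i + 1L, J)) {
      M[i, j] <- M[j, i] <- mean(A[, i] == A[, j])
    }
  }
  dimnames(M) <- list(chain$labels, chain$labels)
  M
}

#' Maximum a posteriori rank-clustering
#'
#' The modal canonical partition among retained iterations. Ties in the
#' posterior mode are broken in favour of the partition seen earliest in the
#' chain, with a warning.
#'
#' @inheritParams cocluster_matrix
#' @return An [partition()].
#' @export
map_clustering <- function(chain, burnin = NULL) {
  keep <- retained(chain, burnin)
  A <- chain$assignments[keep, , drop = FALSE]
  keys <- apply(A, 1L, paste, collapse = ",")
  counts <- table(keys)
  best <- names(counts)[counts == max(counts)]
  if (length(best) > 1L) {
    first_seen <- vapply(best, function(k) match(k, keys), integer(1))
    best <- best[which.min(first_seen)]
    warning("posterior mode is tied; returning the partition seen earliest")
  }
  partition(A[match(best, keys), ])
}

#' Credible interval for the number of rank-clusters
#'
#' Equal-tailed order-statistic interval of the posterior `K` trace.
#'
#' @inheritParams cocluster_matrix
#' @param level Credibility level in (0, 1).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
k_credible_interval <- function(chain, level = 0.8, burnin = NULL) {
  stopifnot(level > 0, level < 1)
  k <- chain$K[retained(chain, burnin)]
  alpha <- (1 - level) / 2
  q <- quantile(k, probs = c(alpha, 1 - alpha), type = 1, names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Point estimates of the overall ranking with rank-cluster tiers
#'
#' Objects are ordered by posterior median normalised worth (best first);
#' tiers come from the maximum a posteriori rank-clustering, numbered from
#' the best tier down.
#'
#' @inheritParams cocluster_matrix
#' @return A data frame with columns `object`, `label`, `median_worth`
#'   (posterior median of the normalised worth), `rank` (1 = best), and
#'   `tier` (MAP rank-cluster, 1 = best), ordered best first.
#' @export
rank_point_estimates <- function(chain, burnin = NULL) {
  keep <- retained(chain, burnin)
  W <- chain$worths[keep, , drop = FALSE]
  W <- W / rowSums(W)
  med <- apply(W, 2L, median)
  map <- map_clustering(chain, burnin)
  # order MAP tiers by their best member's median worth
  tier_rank <- rank(-vapply(seq_len(map$K), function(k) {
    max(med[map$assignment == k])
  }, numeric(1)))
  out <- data.frame(
    object = seq_along(med),
    label = chain$labels,
    median_worth = med,
    rank = as.integer(rank(-med, ties.method = "min")),
    tier = as.integer(tier_rank)[map$assignment]
  )
  out[order(out$rank), , drop = FALSE]
}

#' Mean absolute error between two normalised worth vectors
#'
#' @param estimate,truth Numeric vectors of equal length, each normalised to
#'   sum to one.
#' @return Mean of absolute coordinate differences.
#' @export
mae <- function(estimate, truth) {
  if (length(estimate) != length(truth)) {
    stop("estimate and truth must have equal length")
  }
  mean(abs(estimate - truth))
}

# J x J matrix of observed pairwise win counts: entry (j, jp) counts ranking
# stages in which j was selected while jp was still remaining
count_pairwise_wins <- function(data, idx = NULL) {
  if (is.null(idx)) idx <- stage_index(data)
  J <- idx$J
  # tabulate (selected, remaining) pairs across all stages at once
  sel_rep <- idx$sel[idx$mem_stage]
  keep <- sel_rep != idx$mem_obj
  pair_id <- (sel_rep[keep] - 1L) * J + idx$mem_obj[keep]
  cnt <- tabulate(pair_id, nbins = J * J)
  matrix(cnt, J, J, byrow = TRUE)
}

# expected win counts under worths lambda for the design of `data`.
# Exact when every ranking orders its whole considered set (R >= S - 1),
# which includes complete rankings and pairwise comparisons: then
# P(j beats jp) = lambda_j / (lambda_j + lambda_jp) per co-consideration.
# Otherwise estimated by Monte Carlo over n_sim replicates of the design.
expected_pairwise_wins <- function(data, lambda, n_sim = 25L) {
  obs <- data$observations
  J <- data$n_objects
  complete <- all(vapply(obs, function(o) {
    length(o$ranked) >= length(o$considered) - 1L
  }, logical(1)))
  if (complete) {
    E <- matrix(0, J, J)
    P <- outer(lambda, lambda, function(x, y) x / (x + y))
    for (o in obs) {
      cc <- o$considered
      E[cc, cc] <- E[cc, cc] + P[cc, cc]
    }
    diag(E) <- 0
    return(E)
  }
  E <- matrix(0, J, J)
  for (r in seq_len(n_sim)) {
    E <- E + count_pairwise_wins(simulate_replicate(data, lambda))
  }
  E / n_sim
}

# replicate dataset with the same design (considered sets and ranked lengths)
simulate_replicate <- function(data, lambda) {
  obs <- lapply(data$observations, function(o) {
    sample_ranking(o$considered, length(o$ranked), lambda)
  })
  ranking_dataset(obs, data$n_objects, data$labels)
}

#' Posterior predictive p-value for model fit
#'
#' Goodness-of-fit check based on pairwise win counts. For each of `n_rep`
#' retained posterior draws, a replicate dataset with the observed design
#' (same considered sets and ranked lengths) is simulated and the chi-square
#' style discrepancy
#' `D = sum_{j < jp} (n_jjp - e_jjp)^2 / max(e_jjp, eps)`
#' is computed for both the observed and the replicate data, where `n_jjp`
#' counts stages in which `j` beats `jp` and `e_jjp` is its expectation under
#' the drawn worths. The p-value is the fraction of replicates whose
#' discrepancy is at least the observed one; values near 0.5 indicate
#' adequate fit and small values misfit.
#'
#' @param chain An `rcbtl_chain` fitted to `data`.
#' @param data The observed [ranking_dataset()].
#' @param n_rep Number of posterior draws / replicates (>= 100 recommended).
#' @param burnin Iterations to discard (default: the chain's burn-in).
#' @param n_sim_expected Monte Carlo replicates per draw used for expected
#'   counts when the design contains genuinely partial rankings (ignored
#'   when expectations are available in closed form).
#' @param eps Lower guard on the discrepancy denominator.
#' @return The posterior predictive p-value in `[0, 1]`.
#' @export
posterior_predictive_pvalue <- function(chain, data, n_rep = 200L,
                                        burnin = NULL, n_sim_expected = 25L,
                                        eps = 1e-8) {
  if (n_rep < 1L) stop("n_rep must be positive")
  keep <- retained(chain, burnin)
  take <- keep[unique(round(seq(1L, length(keep), length.out = n_rep)))]
  idx <- stage_index(data)
  J <- data$n_objects
  upper <- upper.tri(matrix(0, J, J))
  n_obs <- count_pairwise_wins(data, idx)[upper]
  exceed <- 0L
  for (t in take) {
    lambda <- chain$worths[t, ]
    e <- expected_pairwise_wins(data, lambda, n_sim = n_sim_expected)[upper]
    denom <- pmax(e, eps)
    d_obs <- sum((n_obs - e)^2 / denom)
    n_rep_w <- count_pairwise_wins(simulate_replicate(data, lambda))[upper]
    d_rep <- sum((n_rep_w - e)^2 / denom)
    if (d_rep >= d_obs) exceed <- exceed + 1L
  }
  exceed / length(take)
}

#' Summarise a fitted chain
#'
#' Collects the headline posterior summaries in a plain list suitable for
#' JSON export: point estimates with tiers, the MAP rank-clustering, the
#' credible interval for the number of rank-clusters, acceptance rates, and
#' the configuration that produced the chain.
#'
#' @inheritParams cocluster_matrix
#' @param level Credibility level for the `K` interval.
#' @return A named list.
#' @export
chain_summary <- function(chain, level = 0.8, burnin = NULL) {
  est <- rank_point_estimates(chain, burnin)
  map <- map_clustering(chain, burnin)
  ki <- k_credible_interval(chain, level = level, burnin = burnin)
  att <- pmax(chain$attempted, 1L)
  list(
    n_objects = chain$J,
    n_iters = chain$n_iters,
    burnin = if (is.null(burnin)) chain$burnin else burnin,
    seed = chain$seed,
    hyper = list(nu = chain$hyper$nu, a = chain$hyper$a, b = chain$hyper$b),
    n_aug = chain$n_aug,
    acceptance_rates = list(
      birth = unname(chain$accepted[["birth"]] / att[["birth"]]),
      death = unname(chain$accepted[["death"]] / att[["death"]])
    ),
    point_estimates = est,
    map_partition = map$assignment,
    k_interval = list(level = level, lower = unname(ki[1]), upper = unname(ki[2]))
  )
}

#' Write a chain summary to JSON
#'
#' @param summary A list from [chain_summary()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_summary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' Heatmap of posterior co-clustering probabilities
#'
#' Minimal base-graphics display of a [cocluster_matrix()], with objects
#' ordered by posterior median worth when a chain is supplied.
#'
#' @param M A co-clustering matrix.
#' @param order Optional object ordering (e.g. from [rank_point_estimates()]).
#' @return Invisibly, the plotted matrix.
#' @export
plot_cocluster <- function(M, order = NULL) {
  if (!is.null(order)) M <- M[order, order, drop = FALSE]
  J <- ncol(M)
  graphics::image(seq_len(J), seq_len(J), t(M[J:1, , drop = FALSE]),
                  zlim = c(0, 1), axes = FALSE, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE))
  graphics::axis(1, at = seq_len(J), labels = colnames(M), las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_len(J), labels = rev(rownames(M)), las = 2, cex.axis = 0.7)
  invisible(M)
}
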
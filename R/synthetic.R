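# Synthetic-data generator mirroring the model's own generative process:
# equal-sized true rank-clusters whose worths form a geometric sequence with
# fourfold separation, judges with uniformly chosen considered sets, and
# rankings drawn sequentially from the BTL model. A grid runner fits the
# model repeatedly and records worth-recovery and co-clustering metrics.

#' True worth vector with equal-sized rank-clusters
#'
#' Builds `n_clusters` equal-sized clusters of `J / n_clusters` objects whose
#' worths form the geometric sequence `ratio^0, ratio^1, ...` (best cluster
#' last). Consecutive clusters are separated by a factor of `ratio` (default
#' 4), so that in a head-to-head comparison across one separation step the
#' better object wins with probability `ratio / (1 + ratio)` = 0.8.
#'
#' The `K = 1` label is ambiguous in common usage: here it follows the
#' reading that "one cluster per object", i.e. all-singleton clusters with
#' geometrically increasing worths (`k1_means_singletons = TRUE`, the
#' default). Set the flag to `FALSE` for the literal single-cluster reading
#' in which all objects share one worth.
#'
#' @param J Number of objects.
#' @param n_clusters Number of true rank-clusters; must divide `J`.
#' @param ratio Worth separation factor between consecutive clusters.
#' @param k1_means_singletons Interpretation of `n_clusters = 1` (see above).
#' @return A list with `worths` (length `J`) and `partition` (the true
#'   [partition()]).
#' @export
make_true_worths <- function(J, n_clusters, ratio = 4,
                             k1_means_singletons = TRUE) {
  J <- as.integer(J)
  n_clusters <- as.integer(n_clusters)
  if (n_clusters < 1L || J %% n_clusters != 0L) {
    stop("n_clusters must be a positive divisor of J")
  }
  if (n_clusters == 1L && k1_means_singletons) n_clusters <- J
  size <- J %/% n_clusters
  assignment <- rep(seq_len(n_clusters), each = size)
  worths <- ratio^(assignment - 1L)
  list(worths = worths, partition = partition(assignment))
}

#' Generate a synthetic ranking dataset
#'
#' Each of `I` judges considers a size-`S` subset of the objects drawn
#' uniformly at random (all objects when `S = J`) and ranks their `R` most
#' preferred by sequential BTL sampling. `R < S` gives partial rankings,
#' `S < J` incomplete rankings, and `(R, S) = (1, 2)` pairwise comparisons.
#'
#' @param I Number of judges.
#' @param R Number of objects each judge ranks, `1 <= R <= S`.
#' @param S Number of objects each judge considers, `2 <= S <= J`.
#' @param worths True worth vector (length `J`).
#' @param labels Optional object names.
#' @return An [ranking_dataset()].
#' @export
generate_dataset <- function(I, R, S, worths, labels = NULL) {
  J <- length(worths)
  if (S < 2L || S > J) stop("S must satisfy 2 <= S <= J")
  if (R < 1L || R > S) stop("R must satisfy 1 <= R <= S")
  obs <- lapply(seq_len(I), function(i) {
    considered <- if (S == J) seq_len(J) else sort(sample.int(J, S))
    sample_ranking(considered, R, worths)
  })
  ranking_dataset(obs, J, labels = labels)
}

#' Simulation-grid runner for recovery metrics
#'
#' For every grid cell and replicate: generate true worths and a dataset,
#' fit the rank-clustered BTL model, and record (i) the mean absolute error
#' of the posterior-mean normalised worths against the normalised truth and
#' (ii) the mean posterior co-clustering probability over truly clustered
#' and over truly independent object pairs. Replicate seeds are derived from
#' `seed` by a counter and recorded in the output.
#'
#' @param grid Data frame with columns `J`, `K`, `I`, `R`, `S`, `nu`; by
#'   default the full crossing of `J = 16`, `K` in \{1, 2, 4, 8\},
#'   `I` in \{100, 400, 1600\}, `(R, S)` in \{(16,16), (8,16), (1,2)\} and
#'   `nu` in \{1, K, 2K\}.
#' @param n_reps Independent datasets per cell.
#' @param n_iters MCMC iterations per fit (half discarded as burn-in).
#' @param a,b Gamma slab hyperparameters.
#' @param seed Master seed; cell/replicate seeds are `seed + counter`.
#' @param k1_means_singletons Passed to [make_true_worths()].
#' @param out Optional CSV path for the metrics table.
#' @return A data frame with one row per (cell, replicate).
#' @export
run_experiment <- function(grid = NULL, n_reps = 20L, n_iters = 10000L,
                           a = 1, b = 1, seed = 1L,
                           k1_means_singletons = TRUE, out = NULL) {
  if (is.null(grid)) {
    base <- expand.grid(J = 16L, K = c(1L, 2L, 4L, 8L),
                        I = c(100L, 400L, 1600L),
                        design = c("complete", "partial", "pairwise"),
                        nu_mult = c("one", "K", "2K"),
                        stringsAsFactors = FALSE)
    base$R <- ifelse(base$design == "complete", base$J,
                     ifelse(base$design == "partial", base$J %/% 2L, 1L))
    base$S <- ifelse(base$design == "pairwise", 2L, base$J)
    base$nu <- ifelse(base$nu_mult == "one", 1L,
                      ifelse(base$nu_mult == "K", base$K, 2L * base$K))
    grid <- base[, c("J", "K", "I", "R", "S", "nu")]
  }
  stopifnot(all(c("J", "K", "I", "R", "S", "nu") %in% names(grid)))

  rows <- vector("list", nrow(grid) * n_reps)
  counter <- 0L
  for (cell in seq_len(nrow(grid))) {
    J <- grid$J[cell]; K <- grid$K[cell]
    truth <- make_true_worths(J, K, k1_means_singletons = k1_means_singletons)
    truth_norm <- truth$worths / sum(truth$worths)
    same <- outer(truth$partition$assignment, truth$partition$assignment, "==")
    up <- upper.tri(same)
    for (rep in seq_len(n_reps)) {
      counter <- counter + 1L
      rep_seed <- as.integer(seed) + counter
      set.seed(rep_seed)
      data <- generate_dataset(grid$I[cell], grid$R[cell], grid$S[cell],
                               truth$worths)
      chain <- run_chain(data, rc_hyper(nu = grid$nu[cell], a = a, b = b),
                         n_iters = n_iters)
      keep <- seq.int(chain$burnin + 1L, chain$n_iters)
      W <- chain$worths[keep, , drop = FALSE]
      est <- colMeans(W / rowSums(W))
      M <- cocluster_matrix(chain)
      rows[[counter]] <- data.frame(
        J = J, K = K, I = grid$I[cell], R = grid$R[cell], S = grid$S[cell],
        nu = grid$nu[cell], rep = rep, seed = rep_seed,
        mae = mae(est, truth_norm),
        cocluster_clustered = if (any(same[up])) mean(M[up][same[up]]) else NA_real_,
        cocluster_independent = if (any(!same[up])) mean(M[up][!same[up]]) else NA_real_,
        k_map = map_clustering(chain)$K
      )
    }
  }
  res <- do.call(rbind, rows)
  if (!is.null(out)) write.csv(res, out, row.names = FALSE)
  res
}
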
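# The partition-based spike-and-slab fusion (PSSF) prior: a partition of the
# objects is drawn with probability depending only on its number of clusters
# K (truncated Poisson mass, equal across partitions sharing K), then one
# Gamma(a, b) slab worth is drawn per cluster and expanded to the objects.
# The "spike" is the event that two objects share a cluster, which places
# prior mass on exactly equal worths.

# log pmf of Poisson(nu) truncated to {1..J}; vectorised in K
log_f_K <- function(K, nu, J) {
  dpois(K, nu, log = TRUE) - log(sum(dpois(seq_len(J), nu)))
}

# memoised table of log Stirling numbers of the second kind:
# entry [n + 1, k + 1] = log S(n, k), built by the standard recurrence
# S(n, k) = k S(n-1, k) + S(n-1, k-1) in log space
log_stirling2_table <- function(n) {
  key <- paste0("lS", n)
  cached <- .rcbtl_env[[key]]
  if (!is.null(cached)) return(cached)
  ls <- matrix(-Inf, n + 1L, n + 1L)
  ls[1L, 1L] <- 0
  for (nn in seq_len(n)) {
    for (k in seq_len(nn)) {
      ls[nn + 1L, k + 1L] <- logsumexp2(log(k) + ls[nn, k + 1L], ls[nn, k])
    }
  }
  .rcbtl_env[[key]] <- ls
  ls
}

# log S(J, K) for K = 1..J
log_stirling2_row <- function(J) log_stirling2_table(J)[J + 1L, seq_len(J) + 1L]

#' Log prior mass of a partition
#'
#' Under the PSSF prior every partition with the same number of clusters `K`
#' has equal mass, proportional to the Poisson(`nu`) pmf at `K` truncated to
#' `{1..J}`. The value returned is normalised over `K` but not over the
#' (Bell-number-sized) set of partitions; the partition-level constant cancels
#' in all Metropolis-Hastings ratios, and exact normalisation for small `J`
#' is available by enumeration (see [enumerate_partitions()]). Because equal
#' mass is assigned to each partition with a given `K`, the induced marginal
#' on `K` is proportional to `f(K) * S(J, K)` with `S` a Stirling number of
#' the second kind, not to `f(K)` itself.
#'
#' @param p An [partition()].
#' @param nu Positive Poisson rate on the number of clusters.
#' @return The (unnormalised) log prior mass.
#' @export
partition_log_prior <- function(p, nu) {
  log_f_K(p$K, nu, length(p$assignment))
}

#' Log prior density of cluster worths
#'
#' Cluster worths are i.i.d. Gamma(`a`, rate `b`) under the slab.
#'
#' @param cluster_worths Strictly positive numeric vector.
#' @param a,b Gamma shape and rate.
#' @return Sum of Gamma log densities.
#' @export
worth_log_prior <- function(cluster_worths, a, b) {
  if (any(cluster_worths <= 0)) stop("worths must be strictly positive")
  sum(dgamma(cluster_worths, shape = a, rate = b, log = TRUE))
}

# draw a partition from the PSSF partition prior: K from the Stirling-weighted
# truncated Poisson, then a uniform partition among those with exactly K blocks
sample_partition_prior <- function(J, nu) {
  if (J == 1L) return(partition(1L))
  lw <- log_f_K(seq_len(J), nu, J) + log_stirling2_row(J)
  K <- sample.int(J, 1L, prob = exp(lw - max(lw)))
  partition(sample_uniform_partition(J, K))
}

# uniform draw among partitions of {1..J} with exactly K blocks, via backward
# decisions on the Stirling recurrence then a forward labelling pass
sample_uniform_partition <- function(J, K) {
  ls <- log_stirling2_table(J)
  joins <- logical(J)  # joins[j]: object j joins an existing block
  n <- J
  k <- K
  while (n > 0L && k < n) {
    p_join <- exp(log(k) + ls[n, k + 1L] - ls[n + 1L, k + 1L])
    if (runif(1) < p_join) {
      joins[n] <- TRUE
    } else {
      k <- k - 1L
    }
    n <- n - 1L
  }
  g <- integer(J)
  nb <- 0L
  for (j in seq_len(J)) {
    if (joins[j]) {
      g[j] <- sample.int(nb, 1L)
    } else {
      nb <- nb + 1L
      g[j] <- nb
    }
  }
  match(g, unique(g))
}

#' Draw a worth state from the PSSF prior
#'
#' Generative sampling of the hierarchical prior: a partition is drawn with
#' mass proportional to the truncated Poisson pmf at its cluster count, then
#' each cluster receives an independent Gamma(`a`, `b`) worth, expanded to a
#' length-`J` worth vector. Regardless of the partition prior, the marginal
#' prior of every expanded coordinate is Gamma(`a`, `b`).
#'
#' @param J Number of objects.
#' @param hyper An [rc_hyper()].
#' @return An [worth_state()].
#' @export
sample_prior <- function(J, hyper) {
  g <- sample_partition_prior(J, hyper$nu)
  repeat {
    lam <- rgamma(g$K, shape = hyper$a, rate = hyper$b)
    if (all(lam > 0) && !anyDuplicated(lam)) break
  }
  worth_state(g, lam)
}

#' Prior probability that two objects share a rank-cluster
#'
#' The "spike" mass of the PSSF prior for a pair of objects: the prior
#' probability that objects `j` and `jp` fall in the same cluster. Computed
#' exactly for any `J` by Stirling-number counting: partitions of `J` objects
#' with `K` clusters in which two fixed objects are fused correspond to
#' partitions of `J - 1` objects with `K` clusters.
#'
#' @param j,jp Distinct object indices.
#' @param hyper An [rc_hyper()] (only `nu` is used).
#' @param J Number of objects.
#' @return A probability.
#' @export
prior_spike_mass <- function(j, jp, hyper, J) {
  if (j == jp) stop("j and jp must be distinct objects")
  if (J < 2L) stop("J must be >= 2")
  lf <- log_f_K(seq_len(J), hyper$nu, J)
  num <- logsumexp(lf[seq_len(J - 1L)] + log_stirling2_row(J - 1L))
  den <- logsumexp(lf + log_stirling2_row(J))
  exp(num - den)
}
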
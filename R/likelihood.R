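# Bradley-Terry-Luce likelihood for arbitrary mixes of complete, partial,
# incomplete, pairwise and groupwise comparisons, plus forward sampling.
#
# A ranking is scored stage by stage: at stage s the judge selects object
# pi(s) from the objects still remaining in the considered set, with
# probability lambda_{pi(s)} / sum(lambda_remaining). The final stage of a
# ranking that orders its whole considered set has a single remaining object
# and contributes probability 1; it is never iterated.

# Flattened per-stage index of a dataset, built once and reused in the hot
# loops. Fields:
#   n_stages   total number of non-trivial stages T
#   sel        length-T selected object index per stage
#   mem_obj    object indices remaining at each stage (concatenated)
#   mem_stage  parallel stage id (1..T, nondecreasing) for mem_obj
#   n_wins     per-object count of stages in which it was selected
#   obs_id     judge index per stage
stage_index <- function(data) {
  obs <- data$observations
  J <- data$n_objects
  n_tot <- sum(vapply(obs, function(o) {
    min(length(o$ranked), length(o$considered) - 1L)
  }, integer(1)))
  sel <- integer(n_tot)
  obs_id <- integer(n_tot)
  mem <- vector("list", n_tot)
  t <- 0L
  for (i in seq_along(obs)) {
    r <- obs[[i]]$ranked
    rem <- obs[[i]]$considered
    ns <- min(length(r), length(rem) - 1L)
    for (s in seq_len(ns)) {
      t <- t + 1L
      sel[t] <- r[s]
      obs_id[t] <- i
      mem[[t]] <- rem
      rem <- rem[rem != r[s]]
    }
  }
  mem_obj <- unlist(mem, use.names = FALSE)
  if (is.null(mem_obj)) mem_obj <- integer(0)
  # precomputed reductions for the sampler hot path: stage boundaries for
  # denominator sums, and an object-sorted permutation for latent totals
  obj_order <- order(mem_obj)
  list(
    n_stages = n_tot, sel = sel, obs_id = obs_id,
    mem_obj = mem_obj,
    mem_stage = rep.int(seq_len(n_tot), lengths(mem)),
    stage_ends = cumsum(lengths(mem)),
    obj_perm = rep.int(seq_len(n_tot), lengths(mem))[obj_order],
    obj_ends = cumsum(tabulate(mem_obj, nbins = J)),
    n_wins = tabulate(sel, nbins = J), J = J
  )
}

# stage denominators sum(lambda_remaining), in stage order 1..T, via a
# single cumulative sum cut at the precomputed stage boundaries
stage_denominators <- function(idx, lambda) {
  if (idx$n_stages == 0L) return(numeric(0))
  cs <- cumsum(lambda[idx$mem_obj])
  diff(c(0, cs[idx$stage_ends]))
}

# per-object totals of a per-stage vector over the stages in which each
# object remains (same boundary trick on the object-sorted layout)
object_totals <- function(idx, y) {
  cs <- cumsum(y[idx$obj_perm])
  diff(c(0, cs[idx$obj_ends]))
}

# fast dataset log-likelihood on a prebuilt index; the selection term
# collapses to per-object win counts
ll_index <- function(idx, lambda) {
  if (idx$n_stages == 0L) return(0)
  sum(idx$n_wins * log(lambda)) - sum(log(stage_denominators(idx, lambda)))
}

#' Log-likelihood of one ranking observation
#'
#' Sum over ranking stages of `log lambda_selected - log sum(lambda_remaining)`,
#' with stage denominators evaluated by log-sum-exp so that extreme worth
#' ratios do not overflow. The likelihood is invariant to rescaling all worths
#' by a positive constant.
#'
#' @param obs An [ranking_observation()].
#' @param worths Strictly positive numeric vector of length `J`.
#' @return The log-likelihood (a nonpositive number).
#' @export
observation_loglik <- function(obs, worths) {
  if (any(!is.finite(worths)) || any(worths <= 0)) {
    stop("worths must be strictly positive and finite")
  }
  lw <- log(worths)
  rem <- obs$considered
  ns <- min(length(obs$ranked), length(rem) - 1L)
  ll <- 0
  for (s in seq_len(ns)) {
    j <- obs$ranked[s]
    ll <- ll + lw[j] - logsumexp(lw[rem])
    rem <- rem[rem != j]
  }
  ll
}

#' Log-likelihood of a ranking dataset
#'
#' Judges are exchangeable, so the dataset log-likelihood is the sum of
#' [observation_loglik()] over observations.
#'
#' @param data An [ranking_dataset()].
#' @param worths Strictly positive numeric vector of length `data$n_objects`.
#' @return The log-likelihood.
#' @export
dataset_loglik <- function(data, worths) {
  if (length(worths) != data$n_objects) {
    stop("worths must have length n_objects")
  }
  if (any(!is.finite(worths)) || any(worths <= 0)) {
    stop("worths must be strictly positive and finite")
  }
  ll_index(stage_index(data), worths)
}

#' Bradley-Terry pairwise preference probability
#'
#' Probability that object `i` is ranked above object `j` in a head-to-head
#' comparison: `lambda_i / (lambda_i + lambda_j)`.
#'
#' @param i,j Distinct object indices.
#' @param worths Strictly positive numeric worth vector.
#' @return A probability.
#' @export
pairwise_prob <- function(i, j, worths) {
  if (i == j) stop("i and j must be distinct objects")
  if (any(worths[c(i, j)] <= 0)) stop("worths must be strictly positive")
  worths[i] / (worths[i] + worths[j])
}

#' Sample a (possibly partial) ranking from the BTL model
#'
#' Sequential sampling without replacement: at each stage an object is drawn
#' from those remaining with probability proportional to its worth, until
#' `n_ranked` objects have been selected.
#'
#' @param considered Integer vector of considered object indices.
#' @param n_ranked Number of objects to rank, `1 <= n_ranked <= length(considered)`.
#' @param worths Strictly positive numeric vector indexed by object.
#' @return An [ranking_observation()].
#' @export
sample_ranking <- function(considered, n_ranked, worths) {
  considered <- as.integer(considered)
  if (n_ranked < 1L || n_ranked > length(considered)) {
    stop("n_ranked must be between 1 and the number of considered objects")
  }
  if (any(worths[considered] <= 0)) stop("worths must be strictly positive")
  rem <- considered
  ranked <- integer(n_ranked)
  for (s in seq_len(n_ranked)) {
    if (length(rem) == 1L) {
      ranked[s] <- rem
    } else {
      ranked[s] <- rem[sample.int(length(rem), 1L, prob = worths[rem])]
    }
    rem <- rem[rem != ranked[s]]
  }
  ranking_observation(ranked, considered)
}
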
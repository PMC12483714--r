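# Reversible-jump moves on (partition, cluster worths): births split one
# cluster into two children adjacent in worth order, deaths merge two
# adjacent clusters. The worth-space bijection is the arithmetic-mean-
# preserving split driven by u ~ Uniform(0,1):
#     split:  (lambda, u) -> (2*lambda*u, 2*lambda*(1-u))
#     merge:  (l1, l2)    -> lambda = (l1+l2)/2, u = l1/(l1+l2)
# with |Jacobian| = 4*lambda. The three pieces (map, inverse, Jacobian, and
# the density of u) are kept together below so an alternative bijection is a
# local swap.

#' Split one cluster worth into two child worths
#'
#' @param lambda Parent cluster worth (positive scalar).
#' @param u Auxiliary variable in (0, 1).
#' @return Numeric vector `c(lambda1, lambda2) = c(2*lambda*u, 2*lambda*(1-u))`,
#'   which preserves the arithmetic mean of the pair at `lambda`.
#' @export
split_worth <- function(lambda, u) {
  c(2 * lambda * u, 2 * lambda * (1 - u))
}

#' Merge two child worths back into a parent worth
#'
#' Exact inverse of [split_worth()]: solves the split equations for the
#' parent worth and the auxiliary variable.
#'
#' @param l1,l2 Child cluster worths.
#' @return List with elements `lambda = (l1 + l2) / 2` and `u = l1 / (l1 + l2)`.
#' @export
merge_worth <- function(l1, l2) {
  list(lambda = 0.5 * (l1 + l2), u = l1 / (l1 + l2))
}

# log |d(lambda1, lambda2) / d(lambda, u)| of the split map
split_log_jacobian <- function(lambda) log(4 * lambda)

# log density of the auxiliary u ~ Uniform(0, 1)
log_q_u <- function(u) 0

# birth/death attempt probabilities (b_K, d_K); 1/2 each in the interior,
# forced moves at the boundaries K = 1 and K = J
bd_probs <- function(K, J) {
  if (J == 1L) return(c(b = 0, d = 0))
  if (K == 1L) return(c(b = 1, d = 0))
  if (K == J) return(c(b = 0, d = 1))
  c(b = 0.5, d = 0.5)
}

# log(2^(N-1) - 1), the number of unordered two-way nonempty splits of an
# N-object cluster, robust to large N
log_n_splits <- function(N) {
  (N - 1) * log(2) + log1p(-2^(-(N - 1)))
}

# relabel a raw (assignment, worth-per-label) pair into a canonical state
canonical_state <- function(raw_assign, raw_worths) {
  ord <- unique(raw_assign)
  worth_state(partition(match(raw_assign, ord)), raw_worths[ord])
}

#' Propose a birth move (split one cluster into two)
#'
#' A cluster with at least two members is chosen uniformly; its members are
#' assigned independently to two children conditional on both being nonempty,
#' and its worth is split by [split_worth()] driven by `u ~ Uniform(0,1)`.
#' Births whose children are not adjacent in the worth ordering of the
#' proposed state are automatically rejected (returned as `NULL`) to preserve
#' reversibility with the adjacent-merge death move.
#'
#' @param state An [worth_state()].
#' @param cluster,u,sides Optional overrides (cluster label to split,
#'   auxiliary variable, and a +-1/2 vector of child sides per member) used
#'   for deterministic testing; by default all are drawn randomly.
#' @return A proposal list (`kind`, `new_state`, `log_jacobian`,
#'   `log_proposal_ratio`, bookkeeping fields), or `NULL` when the move is
#'   unavailable or auto-rejected.
#' @export
propose_birth <- function(state, cluster = NULL, u = NULL, sides = NULL) {
  g <- state$partition
  J <- length(g$assignment)
  K <- g$K
  eligible <- which(g$sizes >= 2L)
  if (length(eligible) == 0L) return(NULL)
  k <- if (!is.null(cluster)) cluster else
    eligible[sample.int(length(eligible), 1L)]
  members <- which(g$assignment == k)
  Nk <- length(members)
  if (is.null(sides)) {
    repeat {
      sides <- sample.int(2L, Nk, replace = TRUE)
      if (length(unique(sides)) == 2L) break
    }
  }
  if (is.null(u)) u <- runif(1)
  children <- split_worth(state$cluster_worths[k], u)
  if (any(children <= 0) || children[1] == children[2]) return(NULL)

  # adjacency: no other cluster worth may lie between the children
  others <- state$cluster_worths[-k]
  if (any(others >= min(children) & others <= max(children))) return(NULL)

  raw_assign <- g$assignment
  raw_assign[members[sides == 2L]] <- K + 1L
  raw_worths <- c(state$cluster_worths, children[2])
  raw_worths[k] <- children[1]
  new_state <- canonical_state(raw_assign, raw_worths)

  bd_cur <- bd_probs(K, J)
  bd_new <- bd_probs(K + 1L, J)
  # death reversing this birth picks among K adjacent pairs of K+1 clusters
  log_pr <- log(bd_new[["d"]]) - log(K) -
    (log(bd_cur[["b"]]) - log(length(eligible)) - log_n_splits(Nk) + log_q_u(u))

  list(kind = "birth", new_state = new_state,
       log_jacobian = split_log_jacobian(state$cluster_worths[k]),
       log_proposal_ratio = log_pr, u = u, parent = k,
       children = new_state$partition$assignment[members[match(c(1L, 2L), sides)]],
       n_eligible = length(eligible), N_split = Nk)
}

#' Propose a death move (merge two adjacent clusters)
#'
#' One of the `K - 1` pairs of clusters adjacent in the sorted order of
#' cluster worths is chosen uniformly; the pair is merged with worth given by
#' [merge_worth()] (the inverse of the birth split).
#'
#' @param state An [worth_state()] with `K >= 2`.
#' @param pair Optional index in `1..(K-1)` selecting the adjacent pair in
#'   ascending worth order, for deterministic testing.
#' @return A proposal list as in [propose_birth()], or `NULL` when `K = 1`.
#' @export
propose_death <- function(state, pair = NULL) {
  g <- state$partition
  J <- length(g$assignment)
  K <- g$K
  if (K < 2L) return(NULL)
  ord <- order(state$cluster_worths)
  if (is.null(pair)) pair <- sample.int(K - 1L, 1L)
  k1 <- ord[pair]
  k2 <- ord[pair + 1L]
  m <- merge_worth(state$cluster_worths[k1], state$cluster_worths[k2])

  raw_assign <- g$assignment
  raw_assign[raw_assign == k2] <- k1
  raw_worths <- state$cluster_worths
  raw_worths[k1] <- m$lambda
  new_state <- canonical_state(raw_assign, raw_worths)

  N_merged <- g$sizes[k1] + g$sizes[k2]
  n_eligible_after <- sum(new_state$partition$sizes >= 2L)
  bd_cur <- bd_probs(K, J)
  bd_new <- bd_probs(K - 1L, J)
  # reciprocal of the ratio of the birth that this death reverses
  log_pr <- -(log(bd_cur[["d"]]) - log(K - 1L) -
                (log(bd_new[["b"]]) - log(n_eligible_after) -
                   log_n_splits(N_merged) + log_q_u(m$u)))

  list(kind = "death", new_state = new_state,
       log_jacobian = -split_log_jacobian(m$lambda),
       log_proposal_ratio = log_pr, u = m$u,
       merged = c(k1, k2), N_merged = N_merged)
}

# core acceptance computation on a prebuilt stage index (NULL for no data);
# ll_cur may be supplied to avoid recomputation
accept_log_ratio_idx <- function(current, proposal, idx, hyper, ll_cur = NULL) {
  J <- length(current$partition$assignment)
  if (is.null(idx)) {
    dll <- 0
  } else {
    if (is.null(ll_cur)) ll_cur <- ll_index(idx, current$expanded)
    dll <- ll_index(idx, proposal$new_state$expanded) - ll_cur
  }
  dll +
    (log_f_K(proposal$new_state$partition$K, hyper$nu, J) -
       log_f_K(current$partition$K, hyper$nu, J)) +
    (worth_log_prior(proposal$new_state$cluster_worths, hyper$a, hyper$b) -
       worth_log_prior(current$cluster_worths, hyper$a, hyper$b)) +
    proposal$log_proposal_ratio + proposal$log_jacobian
}

#' Metropolis-Hastings log acceptance ratio of a birth/death proposal
#'
#' `log A` is the sum of the data log-likelihood difference, the partition
#' prior difference, the worth (slab) prior difference, the proposal-ratio
#' term, and the log Jacobian of the worth-space bijection. The move is
#' accepted with probability `min(1, exp(log A))`; by construction the ratio
#' of a death reversing a birth is the exact reciprocal.
#'
#' @param current The current [worth_state()].
#' @param proposal A proposal from [propose_birth()] or [propose_death()].
#' @param data An [ranking_dataset()], or `NULL` for prior-only sampling.
#' @param hyper An [rc_hyper()].
#' @return The log acceptance ratio `log A`.
#' @export
acceptance_log_ratio <- function(current, proposal, data, hyper) {
  idx <- if (is.null(data)) NULL else stage_index(data)
  accept_log_ratio_idx(current, proposal, idx, hyper)
}

# one birth/death attempt on a prebuilt index; returns updated state, its
# cached log-likelihood, and bookkeeping
partition_step_idx <- function(state, idx, ll_cur, hyper) {
  J <- length(state$partition$assignment)
  bd <- bd_probs(state$partition$K, J)
  kind <- if (runif(1) < bd[["b"]]) "birth" else "death"
  prop <- if (kind == "birth") propose_birth(state) else propose_death(state)
  out <- list(state = state, ll = ll_cur, accepted = FALSE, kind = kind)
  if (is.null(prop)) return(out)
  ll_new <- if (is.null(idx)) 0 else ll_index(idx, prop$new_state$expanded)
  la <- (ll_new - ll_cur) +
    (log_f_K(prop$new_state$partition$K, hyper$nu, J) -
       log_f_K(state$partition$K, hyper$nu, J)) +
    (worth_log_prior(prop$new_state$cluster_worths, hyper$a, hyper$b) -
       worth_log_prior(state$cluster_worths, hyper$a, hyper$b)) +
    prop$log_proposal_ratio + prop$log_jacobian
  if (is.finite(la) && log(runif(1)) < la) {
    out$state <- prop$new_state
    out$ll <- ll_new
    out$accepted <- TRUE
  }
  out
}

#' One reversible-jump update of the partition
#'
#' Attempts a birth with probability `b_K` (1 at `K = 1`, 0 at `K = J`, 1/2
#' otherwise) and a death with the complementary probability. Unavailable or
#' auto-rejected moves leave the state unchanged and count as rejections.
#'
#' @inheritParams acceptance_log_ratio
#' @param state The current [worth_state()].
#' @return The new (or unchanged) [worth_state()].
#' @export
partition_step <- function(state, data, hyper) {
  idx <- if (is.null(data)) NULL else stage_index(data)
  ll_cur <- if (is.null(idx)) 0 else ll_index(idx, state$expanded)
  partition_step_idx(state, idx, ll_cur, hyper)$state
}

#' Run the reversible-jump Gibbs sampler
#'
#' Each iteration performs one reversible-jump birth/death update of the
#' partition (with the worth vector transformed accordingly), followed by
#' `n_aug` augmented-Gibbs sweeps of the cluster worths at fixed partition.
#' The default initialisation places every object in its own cluster with
#' worths drawn from the Gamma slab, so rank-clusters are formed during
#' estimation rather than imposed at the start.
#'
#' @param data An [ranking_dataset()], or `NULL` to sample the prior (then
#'   `J` must be given).
#' @param hyper An [rc_hyper()].
#' @param n_iters Number of iterations to record.
#' @param n_aug Number of augmented-Gibbs worth sweeps per iteration.
#' @param init `"singletons"` (default), `"one_cluster"`, or an explicit
#'   [worth_state()].
#' @param seed Optional integer seed; when supplied the sample path is fully
#'   reproducible.
#' @param J Number of objects, required only when `data` is `NULL`.
#' @return An object of class `"rcbtl_chain"`: per-iteration canonical
#'   cluster assignments (`assignments`, `n_iters x J`), expanded worths
#'   (`worths`), cluster counts (`K`), acceptance counts, and metadata
#'   including the default burn-in (half the chain).
#' @export
run_chain <- function(data, hyper = rc_hyper(), n_iters = 2000L, n_aug = 1L,
                      init = c("singletons", "one_cluster"), seed = NULL,
                      J = NULL) {
  stopifnot(n_iters >= 1L, n_aug >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(data)) {
    if (is.null(J)) stop("J is required when data is NULL")
    idx <- NULL
    labels <- paste0("object_", seq_len(J))
  } else {
    J <- data$n_objects
    idx <- stage_index(data)
    labels <- data$labels
  }

  if (inherits(init, "rcbtl_state")) {
    state <- init
  } else {
    init <- match.arg(init)
    state <- if (init == "singletons") {
      repeat {
        lam <- rgamma(J, shape = hyper$a, rate = hyper$b)
        if (all(lam > 0) && !anyDuplicated(lam)) break
      }
      worth_state(partition(seq_len(J)), lam)
    } else {
      worth_state(partition(rep(1L, J)), rgamma(1L, hyper$a, rate = hyper$b))
    }
  }

  assignments <- matrix(NA_integer_, n_iters, J)
  worths <- matrix(NA_real_, n_iters, J)
  K_trace <- integer(n_iters)
  attempted <- c(birth = 0L, death = 0L)
  accepted <- c(birth = 0L, death = 0L)

  ll_cur <- if (is.null(idx)) 0 else ll_index(idx, state$expanded)
  for (t in seq_len(n_iters)) {
    st <- partition_step_idx(state, idx, ll_cur, hyper)
    attempted[st$kind] <- attempted[st$kind] + 1L
    if (st$accepted) accepted[st$kind] <- accepted[st$kind] + 1L
    state <- st$state
    for (r in seq_len(n_aug)) state <- gibbs_once(idx, state, hyper)
    ll_cur <- if (is.null(idx)) 0 else ll_index(idx, state$expanded)
    assignments[t, ] <- state$partition$assignment
    worths[t, ] <- state$expanded
    K_trace[t] <- state$partition$K
  }

  structure(
    list(assignments = assignments, worths = worths, K = K_trace,
         n_iters = n_iters, burnin = n_iters %/% 2L,
         attempted = attempted, accepted = accepted,
         hyper = hyper, n_aug = n_aug, seed = seed,
         J = J, labels = labels),
    class = "rcbtl_chain"
  )
}

#' @export
print.rcbtl_chain <- function(x, ...) {
  cat("Rank-clustered BTL chain:", x$n_iters, "iterations,", x$J, "objects\n")
  cat("  K range:", paste(range(x$K), collapse = "-"),
      "| default burn-in:", x$burnin, "\n")
  att <- pmax(x$attempted, 1L)
  cat(sprintf("  acceptance: birth %.2f (%d att.), death %.2f (%d att.)\n",
              x$accepted[["birth"]] / att[["birth"]], x$attempted[["birth"]],
              x$accepted[["death"]] / att[["death"]], x$attempted[["death"]]))
  invisible(x)
}

#' Concatenate several chains into one sample set
#'
#' Drops each chain's burn-in and stacks the retained iterations; summary
#' functions treat the result as a single chain with zero burn-in.
#'
#' @param ... `rcbtl_chain` objects fitted to the same data.
#' @return An `rcbtl_chain` with `burnin = 0`.
#' @export
bind_chains <- function(...) {
  chains <- list(...)
  if (length(chains) == 1L && is.list(chains[[1]]) &&
      !inherits(chains[[1]], "rcbtl_chain")) {
    chains <- chains[[1]]
  }
  stopifnot(length(chains) >= 1L)
  keep <- lapply(chains, function(ch) seq.int(ch$burnin + 1L, ch$n_iters))
  out <- chains[[1]]
  out$assignments <- do.call(rbind, Map(function(ch, k) ch$assignments[k, , drop = FALSE], chains, keep))
  out$worths <- do.call(rbind, Map(function(ch, k) ch$worths[k, , drop = FALSE], chains, keep))
  out$K <- unlist(Map(function(ch, k) ch$K[k], chains, keep))
  out$n_iters <- nrow(out$assignments)
  out$burnin <- 0L
  out$attempted <- Reduce(`+`, lapply(chains, `[[`, "attempted"))
  out$accepted <- Reduce(`+`, lapply(chains, `[[`, "accepted"))
  out$seed <- vapply(chains, function(ch) ch$seed %||% NA_integer_, numeric(1))
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
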
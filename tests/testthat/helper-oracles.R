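# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: Stirling/Bell numbers come from the textbook
# recurrences, ranking probabilities from direct product enumeration, and
# small posteriors from quadrature over the (scale-reduced) Dirichlet prior.

# Stirling numbers of the second kind by S(n,k) = k S(n-1,k) + S(n-1,k-1)
oracle_stirling2 <- function(n, k) {
  if (k < 0 || k > n) return(0)
  S <- matrix(0, n + 1, n + 1)
  S[1, 1] <- 1
  for (nn in seq_len(n)) {
    for (kk in seq_len(nn)) {
      S[nn + 1, kk + 1] <- kk * S[nn, kk + 1] + S[nn, kk]
    }
  }
  S[n + 1, k + 1]
}

oracle_bell <- function(n) sum(vapply(1:n, oracle_stirling2, numeric(1), n = n))

# all permutations of a vector, as a list
all_perms <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# probability of a complete ordering under the sequential-choice model,
# computed by the direct product (independent of the package's log-space path)
oracle_ranking_prob <- function(ordering, lambda) {
  rem <- lambda[ordering]
  p <- 1
  while (length(rem) > 1L) {
    p <- p * rem[1] / sum(rem)
    rem <- rem[-1]
  }
  p
}

part_key <- function(assignment) paste(assignment, collapse = ",")

tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# truncated Poisson pmf on {1..J}, straight from the definition
oracle_trunc_pois <- function(K, nu, J) {
  w <- nu^(1:J) / factorial(1:J)
  (nu^K / factorial(K)) / sum(w)
}

# the five partitions of three objects, hard-coded (independent of
# enumerate_partitions)
partitions_of_3 <- list(c(1, 1, 1), c(1, 1, 2), c(1, 2, 1), c(1, 2, 2),
                        c(1, 2, 3))

# Per-partition marginal likelihood of complete rankings of J = 3 objects
# under i.i.d. Gamma(a, b) cluster worths. Because the likelihood is
# invariant to rescaling the worth vector, the Gamma scale integrates out
# and the marginal equals the expectation over normalised cluster worths
# w ~ Dirichlet(a, ..., a) (b drops). K = 1 is exact; K = 2 is a Beta(a, a)
# integral; K = 3 a nested simplex quadrature.
oracle_marglik_j3 <- function(rank_rows, g, a) {
  lik <- function(w) {
    lambda <- w[g]
    prod(vapply(rank_rows, oracle_ranking_prob, numeric(1), lambda = lambda))
  }
  K <- max(g)
  if (K == 1L) return(lik(1))
  if (K == 2L) {
    return(integrate(function(w) {
      vapply(w, function(wi) lik(c(wi, 1 - wi)), numeric(1)) * dbeta(w, a, a)
    }, 0, 1, rel.tol = 1e-10)$value)
  }
  f_outer <- function(w1v) {
    vapply(w1v, function(w1) {
      integrate(function(w2v) {
        vapply(w2v, function(w2) {
          w3 <- 1 - w1 - w2
          if (w3 <= 0) return(0)
          lik(c(w1, w2, w3)) * w1^(a - 1) * w2^(a - 1) * w3^(a - 1)
        }, numeric(1))
      }, 0, 1 - w1, rel.tol = 1e-8)$value
    }, numeric(1))
  }
  gamma(3 * a) / gamma(a)^3 * integrate(f_outer, 0, 1, rel.tol = 1e-8)$value
}

# exact posterior over the five partitions of three objects given complete
# rankings, prior mass per partition proportional to Poisson(nu) pmf at K
oracle_posterior_j3 <- function(data, nu, a) {
  rank_rows <- lapply(data$observations, function(o) o$ranked)
  post <- vapply(partitions_of_3, function(g) {
    oracle_trunc_pois(max(g), nu, 3) * oracle_marglik_j3(rank_rows, g, a)
  }, numeric(1))
  post / sum(post)
}

# empirical distribution of a chain's partitions over given canonical keys
empirical_partition_freq <- function(chain, keys, burnin = NULL) {
  if (is.null(burnin)) burnin <- chain$burnin
  A <- chain$assignments[seq.int(burnin + 1L, chain$n_iters), , drop = FALSE]
  seen <- apply(A, 1L, paste, collapse = ",")
  as.numeric(table(factor(seen, levels = keys))) / length(seen)
}

# a chain object concentrated at a single worth state, for calibration tests
point_mass_chain <- function(worths, n = 200L) {
  J <- length(worths)
  structure(
    list(assignments = matrix(rep(seq_len(J), each = n), nrow = n),
         worths = matrix(rep(worths, each = n), nrow = n),
         K = rep(J, n), n_iters = n, burnin = 0L,
         attempted = c(birth = 0L, death = 0L),
         accepted = c(birth = 0L, death = 0L),
         hyper = rc_hyper(), n_aug = 1L, seed = NA_integer_,
         J = J, labels = paste0("object_", seq_len(J))),
    class = "rcbtl_chain"
  )
}

# tiny rankings CSV fixture written on the fly
write_demo_rankings_csv <- function(path) {
  writeLines(c(
    "judge,rank_1,rank_2,rank_3,considered",
    "1,A,B,,",
    "2,B,C,A,",
    "3,A,,,A;C",
    "4,C,A,,A;B;C"
  ), path)
  path
}
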
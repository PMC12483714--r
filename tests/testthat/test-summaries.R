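# a tiny handmade chain used by several summary tests
make_toy_chain <- function(assignments, worths, burnin = 0L) {
  J <- ncol(assignments)
  structure(
    list(assignments = assignments, worths = worths,
         K = apply(assignments, 1, max), n_iters = nrow(assignments),
         burnin = burnin, attempted = c(birth = 1L, death = 1L),
         accepted = c(birth = 0L, death = 0L), hyper = rc_hyper(),
         n_aug = 1L, seed = 99L, J = J,
         labels = paste0("object_", seq_len(J))),
    class = "rcbtl_chain"
  )
}

test_that("normalisation is scale-only: sums, clusters and pairwise probs", {
  set.seed(50)
  W <- matrix(rgamma(40, 2), 10, 4)
  Wn <- normalize_worths(W)
  expect_equal(rowSums(Wn), rep(1, 10))
  # ratio-preserving: pairwise preference probabilities are unchanged
  for (t in 1:10) {
    expect_equal(pairwise_prob(1, 3, Wn[t, ]), pairwise_prob(1, 3, W[t, ]))
  }
  expect_equal(normalize_worths(c(2, 2)), c(0.5, 0.5))
})

test_that("co-clustering matrix counts exact fractions", {
  A <- rbind(c(1L, 1L, 2L), c(1L, 2L, 2L), c(1L, 1L, 1L), c(1L, 2L, 3L))
  ch <- make_toy_chain(A, matrix(1:12 * 1.0, 4, 3))
  M <- cocluster_matrix(ch)
  expect_equal(unname(M[1, 2]), 2 / 4)
  expect_equal(unname(M[2, 3]), 2 / 4)
  expect_equal(unname(M[1, 3]), 1 / 4)
  expect_true(isSymmetric(M))
  expect_equal(unname(diag(M)), rep(1, 3))
  expect_true(all(M >= 0 & M <= 1))

  # degenerate chains
  sing <- make_toy_chain(matrix(rep(1:3, each = 5), 5, 3),
                         matrix(rgamma(15, 1), 5, 3))
  expect_equal(unname(cocluster_matrix(sing)), diag(3))
  ones <- make_toy_chain(matrix(1L, 5, 3), matrix(rep(rgamma(5, 1), 3), 5, 3))
  expect_equal(unname(cocluster_matrix(ones)), matrix(1, 3, 3))

  expect_error(cocluster_matrix(ch, burnin = 4L), "retained")
})

test_that("MAP clustering is the posterior mode with earliest-tie-break", {
  A <- rbind(c(1L, 1L, 2L), c(1L, 2L, 3L), c(1L, 1L, 2L), c(1L, 2L, 3L),
             c(1L, 1L, 2L))
  ch <- make_toy_chain(A, matrix(rgamma(15, 1), 5, 3))
  expect_identical(map_clustering(ch)$assignment, c(1L, 1L, 2L))

  tied <- make_toy_chain(A[1:4, ], matrix(rgamma(12, 1), 4, 3))
  expect_warning(m <- map_clustering(tied), "tied")
  expect_identical(m$assignment, c(1L, 1L, 2L))  # seen first at iteration 1

  single <- make_toy_chain(A[c(1, 1, 1), ], matrix(rgamma(9, 1), 3, 3))
  expect_identical(map_clustering(single)$assignment, c(1L, 1L, 2L))
})

test_that("K credible intervals match order-statistic quantiles", {
  ch <- make_toy_chain(matrix(1L, 6, 2), matrix(rep(rgamma(6, 1), 2), 6, 2))
  ch$K <- rep(3L, 6)
  expect_equal(k_credible_interval(ch, 0.8), c(lower = 3, upper = 3))

  ktrace <- c(1, 2, 2, 2, 3, 3, 4, 4, 5, 7)
  ch$K <- ktrace
  ch$n_iters <- 10L
  ch$assignments <- matrix(1L, 10, 2)
  ch$worths <- matrix(1, 10, 2)
  expect_equal(k_credible_interval(ch, 0.999), c(lower = 1, upper = 7))
  # sort-based oracle for type-1 (order statistic) equal-tailed quantiles
  srt <- sort(ktrace)
  for (level in c(0.5, 0.8, 0.9)) {
    alpha <- (1 - level) / 2
    lo <- srt[ceiling(10 * alpha)]
    hi <- srt[ceiling(10 * (1 - alpha))]
    expect_equal(k_credible_interval(ch, level),
                 c(lower = lo, upper = hi))
  }
  expect_error(k_credible_interval(ch, 1.2), "level")
})

test_that("point estimates order objects by posterior median worth with tiers", {
  A <- matrix(rep(c(1L, 1L, 2L), each = 4), 4, 3)
  W <- rbind(c(4, 4, 1), c(5, 5, 1), c(3, 3, 1), c(4.5, 4.5, 1)) * 1.0
  ch <- make_toy_chain(A, W)
  est <- rank_point_estimates(ch)
  expect_identical(est$object[1:2], c(1L, 2L))
  expect_identical(est$rank, c(1L, 1L, 3L))
  expect_identical(est$tier, c(1L, 1L, 2L))
  expect_equal(est$median_worth[3], median(1 / rowSums(W)))

  # reversing the worths reverses the ordering (former pair now leads,
  # former singleton is last)
  ch_rev <- make_toy_chain(A, W[, 3:1])
  est_rev <- rank_point_estimates(ch_rev)
  expect_setequal(est_rev$object[1:2], 2:3)
  expect_identical(est_rev$object[3], 1L)
})

test_that("mae is the mean absolute coordinate difference", {
  expect_equal(mae(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(mae(c(0.5, 0.5), c(0.6, 0.4)), 0.1)
  x <- c(0.1, 0.3, 0.6)
  y <- c(0.2, 0.5, 0.3)
  perm <- c(3, 1, 2)
  expect_equal(mae(x[perm], y[perm]), mae(x, y))
  expect_error(mae(1:3 / 6, 1:2 / 3), "equal length")
})

test_that("pairwise win counting matches hand tallies", {
  d <- ranking_dataset(list(
    ranking_observation(c(1, 2, 3), 1:3),  # 1>2, 1>3, 2>3
    ranking_observation(2, c(2, 3))        # 2>3
  ), 3)
  W <- rcbtl:::count_pairwise_wins(d)
  expect_equal(W, rbind(c(0, 1, 1), c(0, 0, 2), c(0, 0, 0)))

  # a partial ranking credits wins only over objects still remaining
  dp <- ranking_dataset(list(ranking_observation(2, 1:3)), 3)
  expect_equal(rcbtl:::count_pairwise_wins(dp),
               rbind(c(0, 0, 0), c(1, 0, 1), c(0, 0, 0)))
})

test_that("posterior predictive p-values stay in [0, 1] and flag gross misfit", {
  set.seed(51)
  lambda <- c(16, 8, 4, 2, 1) / 31
  d <- generate_dataset(40, 5, 5, lambda)
  ch <- point_mass_chain(lambda, n = 100)
  p_ok <- posterior_predictive_pvalue(ch, d, n_rep = 60)
  expect_gte(p_ok, 0)
  expect_lte(p_ok, 1)

  # deterministic reversed rankings against a point mass at the truth
  rev_obs <- replicate(40, ranking_observation(5:1, 1:5), simplify = FALSE)
  d_rev <- ranking_dataset(rev_obs, 5)
  expect_lt(posterior_predictive_pvalue(ch, d_rev, n_rep = 60), 0.05)
})

test_that("chain summaries serialise to JSON round-trippably", {
  set.seed(52)
  d <- generate_dataset(20, 4, 4, c(1, 1, 4, 4))
  ch <- run_chain(d, rc_hyper(), n_iters = 400, seed = 53)
  s <- chain_summary(ch)
  expect_named(s, c("n_objects", "n_iters", "burnin", "seed", "hyper",
                    "n_aug", "acceptance_rates", "point_estimates",
                    "map_partition", "k_interval"))
  f <- withr::local_tempfile(fileext = ".json")
  write_fit_summary(s, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$n_objects, 4)
  expect_equal(nrow(back$point_estimates), 4)
})

test_that("summaries are invariant to thinning by a divisor", {
  set.seed(54)
  A <- matrix(sample(1:2, 40, replace = TRUE), 20, 2)
  A <- t(apply(A, 1, function(g) match(g, unique(g))))
  ch <- make_toy_chain(A, matrix(rgamma(40, 2), 20, 2))
  thin <- seq(1, 20, by = 5)
  ch_thin <- make_toy_chain(A[rep(thin, each = 5), ],
                            ch$worths[rep(thin, each = 5), ])
  expect_equal(cocluster_matrix(ch_thin),
               cocluster_matrix(make_toy_chain(A[thin, ], ch$worths[thin, ])))
})
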
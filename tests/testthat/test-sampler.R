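test_that("split/merge is a bijection with the stated Jacobian", {
  set.seed(30)
  for (r in 1:200) {
    lam <- rgamma(1, 2)
    u <- runif(1)
    ch <- split_worth(lam, u)
    expect_equal(mean(ch), lam, tolerance = 1e-13)  # mean-preserving split
    m <- merge_worth(ch[1], ch[2])
    expect_lt(abs(m$lambda - lam) / lam, 1e-13)
    expect_lt(abs(m$u - u), 1e-13)
    # merge-then-split round trip
    ch2 <- split_worth(m$lambda, m$u)
    expect_lt(max(abs(ch2 - ch) / ch), 1e-13)
  }

  # |d(children)/d(lambda, u)| = 4 lambda, checked by central differences
  num_jac <- function(lam, u, h = 1e-6) {
    abs(det(cbind(
      (split_worth(lam + h, u) - split_worth(lam - h, u)) / (2 * h),
      (split_worth(lam, u + h) - split_worth(lam, u - h)) / (2 * h)
    )))
  }
  for (r in 1:50) {
    lam <- rgamma(1, 2)
    u <- runif(1, 0.01, 0.99)
    expect_equal(log(num_jac(lam, u)), log(4 * lam), tolerance = 1e-6)
  }
})

test_that("birth proposals split a chosen cluster into adjacent children", {
  # cluster {1,2} at worth 2 flanked by worths 1 and 9
  st <- worth_state(partition(c(1L, 1L, 2L, 3L)), c(2, 1, 9))

  # u = 0.45: children (1.8, 2.2) leave the flankers outside -> proposed
  pb <- propose_birth(st, cluster = 1L, u = 0.45, sides = c(1L, 2L))
  expect_false(is.null(pb))
  expect_identical(pb$new_state$partition$K, 4L)
  expect_setequal(round(pb$new_state$cluster_worths, 10),
                  round(c(1.8, 2.2, 1, 9), 10))

  # u = 0.1: children (0.4, 3.6) straddle the worth-1 cluster -> auto-reject
  expect_null(propose_birth(st, cluster = 1L, u = 0.1, sides = c(1L, 2L)))

  # splitting a 2-object cluster always yields two singletons
  expect_identical(sort(pb$new_state$partition$sizes), c(1L, 1L, 1L, 1L))

  # all-singleton states have no eligible cluster
  expect_null(propose_birth(worth_state(partition(1:3), c(1, 2, 3))))
})

test_that("death proposals merge only worth-adjacent cluster pairs", {
  st <- worth_state(partition(c(1L, 2L, 3L)), c(1, 2, 9))
  # K - 1 = 2 adjacent pairs: (1,2) and (2,9); never (1,9)
  merged <- lapply(1:2, function(i) propose_death(st, pair = i))
  expect_equal(sort(merged[[1]]$new_state$cluster_worths), c(1.5, 9))
  expect_equal(sort(merged[[2]]$new_state$cluster_worths), c(1, 5.5))
  expect_null(propose_death(worth_state(partition(rep(1L, 3)), 2)))

  # K = 2: single pair, merging gives the all-in-one partition
  st2 <- worth_state(partition(c(1L, 2L, 1L)), c(1, 4))
  pd <- propose_death(st2, pair = 1)
  expect_identical(pd$new_state$partition$assignment, rep(1L, 3))
  expect_equal(pd$new_state$cluster_worths, 2.5)
})

test_that("proposal ratio counts splits, pairs and eligible clusters", {
  # from all-in-one on 3 objects: 2^(3-1) - 1 = 3 unordered two-way splits,
  # b_1 = 1, one eligible cluster; reverse death picks among K = 1 pair
  # with d_2 = 1/2; u has unit density
  st <- worth_state(partition(rep(1L, 3)), 2)
  pb <- propose_birth(st, cluster = 1L, u = 0.3, sides = c(1L, 1L, 2L))
  expect_equal(pb$log_proposal_ratio, log(0.5) - log(1) + log(3))
  expect_equal(pb$log_jacobian, log(4 * 2))
})

test_that("every birth is exactly reversed by its corresponding death", {
  set.seed(31)
  hy <- rc_hyper(2, 1, 1)
  d <- generate_dataset(10, 4, 4, c(1, 2, 3, 4))
  n_checked <- 0
  for (r in 1:150) {
    st <- sample_prior(4, hy)
    pb <- propose_birth(st)
    if (is.null(pb)) next
    ordw <- order(pb$new_state$cluster_worths)
    pos <- sort(match(pb$children, ordw))
    expect_identical(diff(pos), 1L)  # children adjacent in worth order
    pd <- propose_death(pb$new_state, pair = pos[1])
    laB <- acceptance_log_ratio(st, pb, d, hy)
    laD <- acceptance_log_ratio(pb$new_state, pd, d, hy)
    expect_lt(abs(laB + laD), 1e-10)
    # the death restores the original state
    expect_identical(pd$new_state$partition$assignment, st$partition$assignment)
    expect_lt(max(abs(pd$new_state$cluster_worths - st$cluster_worths) /
                    st$cluster_worths), 1e-13)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 50)
})

test_that("partition_step respects boundary states and reaches all partitions", {
  hy <- rc_hyper(1, 1, 1)
  # J = 1: no move is ever possible
  st1 <- worth_state(partition(1L), 2)
  expect_identical(partition_step(st1, NULL, hy)$partition$assignment, 1L)

  # a short prior-only chain on J = 3 visits every partition
  ch <- run_chain(NULL, hy, n_iters = 4000, J = 3, seed = 32)
  keys <- unique(apply(ch$assignments, 1, paste, collapse = ","))
  expect_setequal(keys, vapply(partitions_of_3, part_key, character(1)))
  expect_identical(ch$K, apply(ch$assignments, 1, max))
})

test_that("chains are reproducible given a seed", {
  d <- generate_dataset(15, 3, 5, c(1, 1, 2, 4, 4))
  ch1 <- run_chain(d, rc_hyper(), n_iters = 300, seed = 33)
  ch2 <- run_chain(d, rc_hyper(), n_iters = 300, seed = 33)
  expect_identical(ch1$assignments, ch2$assignments)
  expect_identical(ch1$worths, ch2$worths)
  ch3 <- run_chain(d, rc_hyper(), n_iters = 300, seed = 34)
  expect_false(identical(ch3$worths, ch1$worths))
})

test_that("with no data the chain samples the partition prior", {
  nu <- 1
  ch <- run_chain(NULL, rc_hyper(nu = nu), n_iters = 15000, J = 3, seed = 35)
  keys <- vapply(partitions_of_3, part_key, character(1))
  emp <- empirical_partition_freq(ch, keys)
  w <- vapply(partitions_of_3, function(g) oracle_trunc_pois(max(g), nu, 3),
              numeric(1))
  expect_lt(tv_dist(emp, w / sum(w)), 0.05)
})

test_that("posteriors agree from opposite initialisations", {
  set.seed(36)
  d <- generate_dataset(60, 4, 4, c(1, 1, 4, 4))
  hy <- rc_hyper(2)
  ch_a <- run_chain(d, hy, n_iters = 4000, init = "singletons", seed = 37)
  ch_b <- run_chain(d, hy, n_iters = 4000, init = "one_cluster", seed = 38)
  keep <- 2001:4000
  ka <- table(factor(ch_a$K[keep], levels = 1:4)) / length(keep)
  kb <- table(factor(ch_b$K[keep], levels = 1:4)) / length(keep)
  expect_lt(tv_dist(as.numeric(ka), as.numeric(kb)), 0.1)
  wa <- ch_a$worths[keep, 1] / rowSums(ch_a$worths[keep, ])
  wb <- ch_b$worths[keep, 1] / rowSums(ch_b$worths[keep, ])
  expect_lt(abs(median(wa) - median(wb)), 0.02)
})
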
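test_that("learning-rule increments match hand evaluation on a contact", {
  con <- build_diluted_connectivity(4, 3, allow_multiple = TRUE, seed = 1)
  con$mask[] <- 1L; diag(con$mask) <- 0L  # full mask for hand evaluation
  net <- ca3_network(con, a_target = 0.5)
  a <- 0.25
  pat <- c(1, 1, 0, 0)
  W <- store_patterns(net, pat, rule = "covariance", alpha = 2,
                      a_pre = a, a_post = a)
  # both units active: dw = alpha (1-a)^2
  expect_equal(W[1, 2], 2 * (1 - a)^2)
  # active pre, silent post: dw = -alpha a (1-a)  (the LTD component)
  expect_equal(W[3, 1], -2 * a * (1 - a))
  # both silent: dw = alpha a^2
  expect_equal(W[3, 4], 2 * a^2)
  # hebb rule has no LTD
  Wh <- store_patterns(net, pat, rule = "hebb", alpha = 1)
  expect_equal(Wh[1, 2], 1)
  expect_equal(Wh[3, 1], 0)
  # no patterns stored: weights unchanged
  expect_equal(store_patterns(net, matrix(numeric(0), 0, 4)),
               matrix(0, 4, 4))
})

test_that("weights vanish off the contact mask and storage commutes", {
  net <- small_ca3(100, 20, 0.1, seed = 5)
  pats <- generate_patterns(100, 6, 0.1, seed = 6)
  W <- store_patterns(net, pats, a_pre = 0.1, a_post = 0.1)
  expect_true(all(W[net$connectivity$mask == 0] == 0))
  # permuted presentation order gives identical weights
  Wp <- store_patterns(net, pats[c(4, 1, 6, 2, 5, 3), ],
                       a_pre = 0.1, a_post = 0.1)
  expect_equal(W, Wp)
  expect_error(store_patterns(net, generate_patterns(50, 1, 0.1, seed = 1)),
               "does not match")
})

test_that("a single stored pattern is recalled perfectly from itself", {
  net <- small_ca3(200, 50, 0.05, seed = 3)
  pat <- generate_patterns(200, 1, 0.05, seed = 4)
  W <- store_patterns(net, pat)
  res <- recall(net, W, pat[1, ], target = pat[1, ])
  expect_true(res$converged)
  expect_equal(pattern_overlap(res$pattern, pat[1, ]), 1.0)
})

test_that("half cues complete stored patterns well below capacity", {
  net <- small_ca3(1000, 200, 0.05, seed = 1)
  fix <- store_binary(net, 5, seed = 2)
  for (i in 1:5) {
    cue <- with_seed(100 + i, make_partial_cue(fix$patterns[i, ], 0.5))
    res <- recall(net, W = fix$W, cue = cue, target = fix$patterns[i, ])
    expect_gte(completion_score(res$pattern, fix$patterns[i, ],
                                which(cue > 0)), 0.95)
    # k-WTA holds the recalled active fraction at a_target
    expect_equal(sum(res$pattern > 0), 50)
  }
})

test_that("a cue unrelated to any stored pattern retrieves none of them", {
  net <- small_ca3(1000, 200, 0.05, seed = 1)
  fix <- store_binary(net, 5, seed = 2)
  alien <- generate_patterns(1000, 1, 0.05, seed = 77)[1, ]
  res <- recall(net, fix$W, alien)
  best <- max(apply(fix$patterns, 1L, pattern_overlap, q = res$pattern))
  expect_lt(best, 0.5)
})

test_that("non-convergence is flagged, not thrown", {
  net <- small_ca3(100, 30, 0.1, seed = 2, max_steps = 1)
  fix <- store_binary(net, 3, seed = 3)
  cue <- with_seed(9, make_partial_cue(fix$patterns[1, ], 0.4))
  res <- recall(net, fix$W, cue)
  expect_false(res$converged)
  expect_equal(res$steps, 1L)
})

test_that("synchronous recall matches brute-force enumeration on a tiny net", {
  # N = 10, full connectivity (C = N-1), k = 2 active: every state the
  # package dynamics converge to must be a fixed point of the independent
  # loop-based one-step map, and one package step from any state must equal
  # the oracle step.
  N <- 10; k <- 2
  con <- build_diluted_connectivity(N, N - 1, seed = 8)
  net <- ca3_network(con, a_target = k / N, max_steps = 1, cue_gain = 0)
  pats <- generate_patterns(N, 2, k / N, seed = 9)
  W <- store_patterns(net, pats, a_pre = k / N, a_post = k / N)
  states <- enumerate_states(N, k)
  for (i in seq_len(nrow(states))) {
    s <- states[i, ]
    pkg_step <- recall(net, W, s)$pattern
    expect_equal(pkg_step, brute_step(W, s, k, N - 1))
  }
  # full package dynamics land on oracle-verified fixed points
  net_full <- ca3_network(con, a_target = k / N, max_steps = 30,
                          cue_gain = 0)
  finals <- t(apply(states, 1L, function(s) recall(net_full, W, s)$pattern))
  conv <- apply(states, 1L, function(s) recall(net_full, W, s)$converged)
  fp <- brute_fixed_points(W, finals[conv, , drop = FALSE], k, N - 1)
  expect_true(all(fp))
})

test_that("measured capacity grows linearly with synapses per neuron", {
  a <- 0.05; denom <- a * log(1 / a)
  k_grid <- seq(0.05, 0.35, by = 0.05)
  C_grid <- c(100, 200, 400)
  pm <- vapply(C_grid, function(C) {
    res <- measure_capacity(1000, C, a,
                            p_grid = unique(round(k_grid * C / denom)),
                            seeds = 1L, n_test = 25L)
    res$p_max
  }, numeric(1))
  expect_true(all(diff(pm) > 0))
  fit <- stats::lm(pm ~ C_grid)
  expect_gte(summary(fit)$r.squared, 0.9)
  # recovered proportionality factors sit below the theoretical ceiling
  expect_true(all(pm * denom / C_grid <= 0.3))
})

test_that("duplicated contacts cut capacity; more duplication cuts it more", {
  grid <- seq(20, 120, by = 20)
  half <- duplicate_contact_experiment(1000, 100, 0.05, 0.5, p_grid = grid,
                                       seeds = 1L, n_test = 25L)
  expect_lt(mean(half$p_max_duplicated), mean(half$p_max_baseline))
  full <- duplicate_contact_experiment(1000, 100, 0.05, 1.0, p_grid = grid,
                                       seeds = 1L, n_test = 25L)
  expect_lte(mean(full$p_max_duplicated), mean(half$p_max_duplicated))
  # zero duplication is the baseline network
  none <- duplicate_contact_experiment(1000, 100, 0.05, 0, p_grid = c(20, 40),
                                       seeds = 1L, n_test = 10L)
  expect_equal(none$p_max_baseline, none$p_max_duplicated)
})
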
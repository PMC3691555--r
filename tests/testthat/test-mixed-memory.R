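fig_specs <- function(sigma = 50) {
  list(
    mixed_memory_spec(300, sigma, c(1, 1000), discrete_indices = 1001:1025),
    mixed_memory_spec(500, sigma, c(1, 1000), discrete_indices = 1101:1125)
  )
}

test_that("mixed-memory encoding produces the specified bump and event code", {
  spec <- mixed_memory_spec(300, 50, c(1, 1000), discrete_indices = 1001:1025)
  r <- encode_mixed_memory(spec, 1500)
  expect_equal(r[300], 1)
  expect_equal(r[250], exp(-50^2 / (2 * 50^2)))
  expect_true(all(r[1001:1025] == 1))
  expect_true(all(r[1026:1500] == 0))
  # sigma -> 0 limit: single active spatial unit
  s0 <- mixed_memory_spec(300, 0, c(1, 1000))
  r0 <- encode_mixed_memory(s0, 1000)
  expect_equal(which(r0 > 0), 300)
  # purely continuous pattern when no discrete indices
  expect_equal(sum(encode_mixed_memory(s0, 1500)[1001:1500]), 0)
  expect_error(mixed_memory_spec(2000, 50, c(1, 1000)), "inside")
  expect_error(mixed_memory_spec(300, 50, c(1, 1000),
                                 discrete_indices = 500), "disjoint")
})

test_that("well-separated bumps are nearly uncorrelated for narrow sigma", {
  # closed-form Gaussian overlap: correlation of two bumps at distance d
  # falls like exp(-d^2 / (4 sigma^2)) for sigma << range
  for (sigma in c(20, 50)) {
    b1 <- encode_mixed_memory(mixed_memory_spec(300, sigma, c(1, 1000)), 1000)
    b2 <- encode_mixed_memory(mixed_memory_spec(500, sigma, c(1, 1000)), 1000)
    expect_equal(sum(b1 * b2) / sqrt(sum(b1^2) * sum(b2^2)),
                 exp(-200^2 / (4 * sigma^2)), tolerance = 0.01)
  }
})

test_that("bump-center decoding is exact for symmetric patterns", {
  r <- numeric(1000); r[300] <- 1
  expect_equal(decode_bump_center(r, c(1, 1000)), 300)
  bump <- encode_mixed_memory(mixed_memory_spec(500, 40, c(1, 1000)), 1000)
  expect_equal(decode_bump_center(bump, c(1, 1000)), 500, tolerance = 1e-6)
  expect_error(decode_bump_center(numeric(1000), c(1, 1000)), "decode")
})

test_that("noisy bumps decode to the true center on average", {
  bump <- encode_mixed_memory(mixed_memory_spec(300, 50, c(1, 1000)), 1000)
  centers <- with_seed(21, {
    vapply(1:100, function(i) {
      noisy <- pmax(bump + rnorm(1000, sd = 0.05), 0)
      decode_bump_center(noisy, c(1, 1000), threshold = 0.2)
    }, numeric(1))
  })
  expect_lt(abs(mean(centers) - 300), 2)
})

test_that("object cue retrieves its place; place cue retrieves its object", {
  specs <- fig_specs()
  con <- build_diluted_connectivity(1500, 300, seed = 11)
  net <- ca3_network(con, a_target = 0.1, max_steps = 30)
  r1 <- recall_mixed(net, specs, 1, "discrete")
  r2 <- recall_mixed(net, specs, 2, "discrete")
  expect_equal(r1$decoded_center, 300, tolerance = 5)
  expect_equal(r2$decoded_center, 500, tolerance = 5)
  expect_true(r1$result$converged && r2$result$converged)
  # symmetric retrieval: continuous cue completes the discrete component
  r3 <- recall_mixed(net, specs, 1, "continuous")
  expect_equal(sort(r3$recalled_discrete), 1001:1025)
  r4 <- recall_mixed(net, specs, 2, "continuous")
  expect_equal(sort(r4$recalled_discrete), 1101:1125)
})
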
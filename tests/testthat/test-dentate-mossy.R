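test_that("grid maps peak at lattice vertices and are lattice-periodic", {
  expect_equal(grid_firing_map(cbind(0, 0), spacing = 30, peak_rate = 7), 7)
  # primitive translations of the triangular lattice at orientation 0
  lam <- 30
  T1 <- lam * c(sqrt(3) / 2, 1 / 2)
  T2 <- lam * c(0, 1)
  x <- with_seed(5, matrix(runif(20, 0, 120), ncol = 2))
  r0 <- grid_firing_map(x, lam)
  expect_equal(grid_firing_map(sweep(x, 2, -T1), lam), r0, tolerance = 1e-9)
  expect_equal(grid_firing_map(sweep(x, 2, -T2), lam), r0, tolerance = 1e-9)
  expect_true(all(r0 >= 0))
})

test_that("spatial mean rate matches dense quadrature over one lattice cell", {
  # frozen oracle: dense (600 x 600) quadrature of the rectified
  # three-cosine interference pattern over one primitive cell gives a mean
  # rate of 0.172085 x peak; the map is periodic so this is the global mean
  lam <- 30
  gx <- seq(0, lam * sqrt(3), length.out = 301)[-301]
  gy <- seq(0, lam, length.out = 301)[-301]
  pts <- as.matrix(expand.grid(gx, gy))
  expect_equal(mean(grid_firing_map(pts, lam)), 0.172085, tolerance = 1e-3)
  expect_equal(mean(grid_firing_map(pts, lam, peak_rate = 10)),
               1.72085, tolerance = 1e-2)
})

test_that("competitive learning keeps unit-norm rows and exact sparseness", {
  pos <- seq(0, 100, length.out = 50)
  G <- grid_population(60, pos, seed = 2)
  cn <- train_competitive(G, n_out = 100, a_out = 0.05, epochs = 3, seed = 3)
  expect_equal(sqrt(rowSums(cn$weights^2)), rep(1, 100), tolerance = 1e-9)
  for (i in seq_len(nrow(cn$outputs))) {
    expect_equal(population_sparseness(cn$outputs[i, ]), 0.05)
  }
  expect_warning(train_competitive(rbind(G[1, ], 0), n_out = 50, epochs = 1,
                                   seed = 1),
                 "all-zero")
})

test_that("competitive output separates nearby positions better than input", {
  # grid -> place transformation: across seeds, positions 50 cm apart are
  # less correlated in the trained granule code than in the grid code
  pos <- seq(0, 100, length.out = 50)
  cors <- t(vapply(1:5, function(s) {
    G <- grid_population(100, pos, seed = s)
    cn <- train_competitive(G, n_out = 200, a_out = 0.05, seed = s + 100)
    i1 <- which.min(abs(pos - 25)); i2 <- which.min(abs(pos - 75))
    c(input = pattern_overlap(G[i1, ], G[i2, ]),
      output = pattern_overlap(cn$outputs[i1, ], cn$outputs[i2, ]))
  }, numeric(2)))
  expect_gt(separation_index(mean(cors[, 1]), mean(cors[, 2])), 0)
})

test_that("place-field statistics count above-half-max response regions", {
  pos <- seq(0, 100, length.out = 101)
  gauss <- exp(-(pos - 40)^2 / (2 * 8^2))
  st <- place_field_stats(cbind(gauss), position_step = 1)
  expect_equal(st$n_fields, 1L)
  # half-max width of a Gaussian ~ 2.355 sigma
  expect_lt(abs(st$mean_width - 2.355 * 8), 2)
  # a grid cell sliced along its dense axis has multiple fields on a track
  # two lattice periods long
  g <- grid_firing_map(cbind(pos, 0), spacing = 30)
  expect_gte(place_field_stats(cbind(g), 1)$n_fields, 2L)
  expect_equal(place_field_stats(cbind(numeric(10)))$n_fields, 0L)
  # trained granule units are mostly single-field
  G <- grid_population(100, pos, seed = 7)
  cn <- train_competitive(G, n_out = 200, a_out = 0.05, seed = 8)
  st_dg <- place_field_stats(cn$outputs, position_step = 1)
  responsive <- st_dg$n_fields >= 1
  expect_gt(mean(st_dg$n_fields[responsive] == 1), 0.5)
})

test_that("mossy projection is sparse, deterministic, and decorrelating", {
  proj <- mossy_projection(600, 500, seed = 4)
  expect_equal(ncol(proj$contacts), 46)
  expect_true(all(proj$contacts >= 1 & proj$contacts <= 600))
  dg <- generate_patterns(600, 1, 0.05, seed = 5)[1, ]
  expect_identical(apply_mossy(dg, proj), apply_mossy(dg, proj))
  expect_error(mossy_projection(30, 10, n_contacts = 46), "exceed")
  # randomization: correlated granule pairs map to less correlated CA3 pairs
  for (cc in c(0.4, 0.6, 0.8)) {
    pairs <- t(vapply(1:20, function(s) {
      pats <- generate_patterns(600, 2, 0.05, pairwise_target_corr = cc,
                                seed = s)
      pr <- mossy_projection(600, 500, seed = s + 500)
      c(pattern_overlap(pats[1, ], pats[2, ]),
        pattern_overlap(apply_mossy(pats[1, ], pr),
                        apply_mossy(pats[2, ], pr)))
    }, numeric(2)))
    expect_lt(mean(pairs[, 2]), mean(pairs[, 1]))
  }
})

test_that("perforant-path cue initiates attractor recall end to end", {
  n_ec <- 400; n_ca3 <- 500
  ec <- generate_patterns(n_ec, 5, 0.1, seed = 1)
  ca3 <- generate_patterns(n_ca3, 5, 0.05, seed = 2)
  W_pp <- train_pp_cue(ec, ca3)
  con <- build_diluted_connectivity(n_ca3, 150, seed = 3)
  net <- ca3_network(con, 0.05)
  W_rc <- store_patterns(net, ca3, a_pre = 0.05, a_post = 0.05)
  # full EC pattern at p = 1-of-5: pp cue equals the stored CA3 pattern
  cue_full <- apply_pp_cue(W_pp, ec[1, ], 0.05)
  expect_equal(pattern_overlap(cue_full, ca3[1, ]), 1.0)
  # half EC cues recall the right CA3 attractor
  for (i in 1:5) {
    half <- with_seed(i, make_partial_cue(ec[i, ], 0.5))
    cue <- apply_pp_cue(W_pp, half, 0.05)
    res <- recall(net, W_rc, cue)
    expect_gte(pattern_overlap(res$pattern, ca3[i, ]), 0.9)
  }
  # untrained pp weights give a chance-level cue (~ -a/(1-a) for k-WTA)
  cue0 <- apply_pp_cue(matrix(0, n_ca3, n_ec), ec[1, ], 0.05)
  expect_lt(abs(pattern_overlap(cue0, ca3[1, ])), 0.15)
  expect_error(train_pp_cue(ec, ca3[1:3, ]), "differ")
})
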
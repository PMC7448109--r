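# Sigmoid perceptron: activation, forward pass, loss, backprop against
# finite differences, initialiser support, training, serialisation.

test_that("sigmoid closed forms and symmetry", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(log(3)), 0.75)
  expect_equal(sigmoid(700), 1)
  expect_equal(sigmoid(-700), 0, tolerance = 1e-300)
  x <- seq(-5, 5, by = 0.5)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, length(x)))
  expect_true(all(diff(sigmoid(x)) > 0))
})

test_that("network_config enforces the documented parameter ranges", {
  cfg <- network_config(c(6, 4, 1))
  expect_equal(cfg$momentum, 0.7)
  expect_equal(cfg$tolerance, 1e-4)
  expect_error(network_config(c(6, 4, 2)), "output layer")
  expect_error(network_config(c(6, 4, 1), momentum = 0.5), "momentum")
  expect_error(network_config(c(6, 4, 1), tolerance = 0.1), "tolerance")
  expect_error(network_config(c(6, 4, 1), init_high = 0.9), "initialiser")
  expect_error(network_config(c(6, 4, 1), init_low = -0.1), "initialiser")
})

test_that("init_weights: deterministic, support in [0, 0.5)", {
  cfg <- network_config(c(4, 3, 1), seed = 11)
  n1 <- init_network(cfg); n2 <- init_network(cfg)
  expect_identical(n1$weights, n2$weights)
  expect_identical(n1$biases, n2$biases)
  # 1e6 draws all inside [0, 0.5), mean near 0.25
  big <- network_config(c(999, 1000, 1), seed = 5)
  nb <- init_network(big)
  draws <- c(unlist(nb$weights), unlist(nb$biases))
  expect_gte(length(draws), 1e6)
  expect_gte(min(draws), 0)
  expect_lt(max(draws), 0.5)
  # uniform(0, 0.5): sd = 0.5/sqrt(12); 3-sigma band for the mean
  expect_lt(abs(mean(draws) - 0.25), 3 * (0.5 / sqrt(12)) / sqrt(length(draws)))
})

test_that("forward pass: shapes, ranges, hand-computed values", {
  cfg <- network_config(c(2, 2, 1), seed = 1)
  net <- init_network(cfg)
  # all-zero weights -> every activation 0.5
  z <- net
  z$weights <- lapply(z$weights, function(w) w * 0)
  z$biases <- lapply(z$biases, function(b) b * 0)
  fw <- net_forward(z, c(0.3, 0.8))
  expect_equal(fw$output, 0.5)
  expect_true(all(unlist(fw$activations[-1]) == 0.5))
  # 1-1 net, w = 1, b = 0, input 0: sigmoid(sigmoid(0) * 1) = sigmoid(0.5)
  one <- init_network(network_config(c(1, 1), seed = 1))
  one$weights[[1]][1] <- 1; one$biases[[1]][1] <- 0
  expect_equal(net_forward(one, 0)$output, sigmoid(0))
  two <- init_network(network_config(c(1, 1, 1), seed = 1))
  two$weights <- list(matrix(1), matrix(1)); two$biases <- list(0, 0)
  expect_equal(net_forward(two, 0)$output, sigmoid(0.5))
  # output strictly in (0,1) for random nets, and shape errors caught
  set.seed(3)
  for (i in 1:5) {
    out <- net_forward(net, matrix(runif(10), ncol = 2))$output
    expect_true(all(out > 0 & out < 1))
  }
  expect_error(net_forward(net, c(1, 2, 3)), "does not match")
})

test_that("net_loss is half the squared error", {
  expect_equal(net_loss(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(net_loss(0.5, 1), 0.125)
  expect_equal(net_loss(c(0, 1), c(1, 0)), 1)
  expect_error(net_loss(1, c(1, 2)), "length mismatch")
})

test_that("backprop matches central finite differences (25 random triples)", {
  set.seed(42)
  for (trial in 1:25) {
    sizes <- c(sample(2:6, 1), sample(2:5, 1), 1)
    if (trial %% 3 == 0) sizes <- append(sizes, sample(2:4, 1), after = 1)
    cfg <- network_config(sizes, seed = trial)
    net <- init_network(cfg)
    nsamp <- sample(1:4, 1)
    x <- matrix(runif(nsamp * sizes[1]), nrow = nsamp)
    d <- runif(nsamp, 0.05, 0.95)
    got <- net_gradients(net, x, d)
    want <- finite_diff_grads(net, x, d)
    for (m in seq_along(net$weights)) {
      expect_lt(max_rel_err(got$dW[[m]], want$dW[[m]]), 1e-5)
      expect_lt(max_rel_err(got$db[[m]], want$db[[m]]), 1e-5)
    }
  }
})

test_that("gradients vanish when the output already matches the target", {
  cfg <- network_config(c(2, 2, 1), seed = 9)
  net <- init_network(cfg)
  x <- c(0.4, 0.6)
  d <- net_forward(net, x)$output
  g <- net_gradients(net, x, d)
  expect_true(all(abs(unlist(g$dW)) < 1e-14))
  expect_true(all(abs(unlist(g$db)) < 1e-14))
})

test_that("training fits the AND fixture and never increases accepted error", {
  fx <- and_fixture()
  cfg <- network_config(c(2, 2, 1), tolerance = 1e-3, seed = 3)
  tr <- train_network(init_network(cfg), fx$x, fx$d)
  expect_lte(tr$result$final_error, 1e-3)
  expect_lte(tr$result$epochs_run, 20000)
  expect_true(all(diff(tr$result$error_trajectory) <= 0))
  expect_equal(tr$result$final_error,
               tail(tr$result$error_trajectory, 1))
  # already-fit data returns immediately
  tr2 <- train_network(tr$net, fx$x, fx$d, cfg)
  expect_equal(tr2$result$epochs_run, 0L)
  # random labels: error still never increases over accepted steps
  set.seed(4)
  cfg3 <- network_config(c(3, 3, 1), seed = 5, max_epochs = 300)
  x <- matrix(runif(30), ncol = 3)
  d <- runif(10, 0.05, 0.95)
  tr3 <- train_network(init_network(cfg3), x, d, cfg3)
  expect_true(all(diff(tr3$result$error_trajectory) <= 0))
  expect_error(train_network(init_network(cfg3), x[0, , drop = FALSE],
                             numeric(0), cfg3), "empty")
  expect_error(train_network(init_network(cfg3), x, rep(1.5, 10), cfg3),
               "inside")
})

test_that("predict_score is deterministic and monotone for positive weights", {
  cfg <- network_config(c(6, 1), seed = 6)
  net <- init_network(cfg)   # all weights in [0, 0.5) hence positive
  x <- runif(6)
  expect_identical(predict_score(net, x), predict_score(net, x))
  for (j in 1:6) {
    x2 <- x; x2[j] <- x2[j] + 0.2
    expect_gt(predict_score(net, x2), predict_score(net, x))
  }
})

test_that("JSON serialisation round-trips bit-exactly", {
  cfg <- network_config(c(6, 4, 1), seed = 77)
  net <- init_network(cfg)
  fx <- and_fixture()
  tf <- tempfile(fileext = ".json")
  save_network(net, tf)
  back <- load_network(tf)
  expect_identical(back$weights, net$weights)
  expect_identical(back$biases, net$biases)
  expect_identical(unclass(back$config), unclass(net$config))
  # trained networks round-trip too
  cfg2 <- network_config(c(2, 2, 1), seed = 3)
  tr <- train_network(init_network(cfg2), fx$x, fx$d, cfg2)
  save_network(tr$net, tf)
  expect_identical(load_network(tf)$weights, tr$net$weights)
})

test_that("marker-channel stage recovery on a synthetic cohort", {
  # train on 400, hold out 100; >= 90% of held-out marker scores must fall
  # in the band of their true stage
  cfg <- prostadss:::.config_net(default_run_config(seed = 7)$marker_net)
  tr_c <- generate_cohort(cohort_spec(400, seed = 401))$cohort
  te_c <- generate_cohort(cohort_spec(100, seed = 402))$cohort
  rg <- default_ranges()
  xtr <- prostadss:::.scale_cohort(tr_c, rg)[, 1:6]
  xte <- prostadss:::.scale_cohort(te_c, rg)[, 1:6]
  tr <- train_network(init_network(cfg), xtr, stage_target(tr_c$stage), cfg)
  scores <- predict_score(tr$net, xte)
  in_band <- mean(stage_of_score(scores) == te_c$stage)
  expect_gte(in_band, 0.90)
})
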
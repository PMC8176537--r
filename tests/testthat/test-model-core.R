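test_that("Nguyen-Widrow initialization: row norms, bias bounds, determinism", {
  net <- init_nguyen_widrow(c(20, 80, 80, 2), seed = 42)
  beta1 <- 0.7 * 80^(1 / 20)
  expect_true(all(abs(sqrt(rowSums(net$layer1$weights^2)) - beta1) < 1e-4))
  expect_true(all(abs(net$layer1$biases) <= beta1))
  beta2 <- 0.7 * 80^(1 / 80)
  expect_true(all(abs(sqrt(rowSums(net$layer2$weights^2)) - beta2) < 1e-4))
  expect_true(all(abs(net$layer2$biases) <= beta2))
  expect_identical(net, init_nguyen_widrow(c(20, 80, 80, 2), seed = 42))
  expect_false(identical(net, init_nguyen_widrow(c(20, 80, 80, 2), seed = 43)))
  # mass/perimeter head starts positive at order 1
  expect_true(all(net$layer3$biases >= 1 & net$layer3$biases <= 2))
  expect_error(init_nguyen_widrow(c(0, 80, 80, 2)),
               class = "pstnn_error_invalid_architecture")
  expect_error(init_nguyen_widrow(c(20, 80, 80, 3)),
               class = "pstnn_error_invalid_architecture")
})

test_that("tanh transfer equals the hyperbolic tangent and saturates", {
  grid <- seq(-10, 10, length.out = 1000)
  expect_lt(max(abs(tanh_transfer(grid) - tanh(grid))), 1e-12)
  expect_identical(tanh_transfer(0), 0)
  expect_lt(1 - tanh_transfer(50), 1e-15)
  expect_equal(tanh_transfer(1), 0.761594, tolerance = 1e-6)
  expect_true(all(tanh_transfer(grid) > -1 & tanh_transfer(grid) < 1))
})

test_that("dense preactivation matches explicit dot products", {
  expect_equal(dense_preactivation(dense_layer(matrix(0, 3, 2), c(1, 2, 3)),
                                   c(5, -5)), c(1, 2, 3))
  expect_equal(dense_preactivation(dense_layer(matrix(2, 1, 1), 1), 3), 7)
  set.seed(7)
  layer <- dense_layer(matrix(rnorm(6), 3, 2), rnorm(3))
  x <- rnorm(2)
  manual <- vapply(1:3, function(k) sum(layer$weights[k, ] * x) + layer$biases[k],
                   numeric(1))
  expect_equal(dense_preactivation(layer, x), manual, tolerance = 1e-12)
  expect_error(dense_preactivation(layer, rnorm(3)), class = "pstnn_error_shape")
})

test_that("surface-tension activation: values, limits, order, errors", {
  expect_equal(surface_tension_activation(0, 1), rep(0, 4))
  expect_true(all(abs(surface_tension_activation(1e6, 1) - 1) < 1e-9))
  expect_equal(surface_tension_activation(1, 1)[1], 1 - exp(-9.8 / 22.1),
               tolerance = 1e-12)
  expect_error(surface_tension_activation(1, 0),
               class = "pstnn_error_degenerate_geometry")
  # monotone in mass (up) and perimeter (down), per tension neuron
  ms <- seq(0.1, 20, length.out = 25)
  for (k in 1:4) {
    expect_true(all(diff(vapply(ms, function(m)
      surface_tension_activation(m, 2)[k], numeric(1))) > 0))
    expect_true(all(diff(vapply(ms, function(p)
      surface_tension_activation(3, p)[k], numeric(1))) < 0))
  }
  # increasing tensions give decreasing activations, all in (0, 1)
  O <- surface_tension_activation(3, 2)
  expect_true(all(diff(O) < 0))
  expect_true(all(O > 0 & O < 1))
  # negative perimeter is legal (activation may leave (0, 1))
  expect_no_error(surface_tension_activation(1, -0.5))
})

test_that("forward pass equals an explicit-loop oracle on toy networks", {
  for (s in 1:10) {
    net <- make_toy_net(c(3, 5, 4, 2), seed = s)
    set.seed(1000 + s)
    x <- runif(3)
    tr <- forward_pass(net, x)
    orc <- oracle_forward(net, x)
    expect_equal(unname(tr$O), orc$O, tolerance = 1e-10)
    expect_equal(unname(tr$Y3), c(orc$m, orc$Per), tolerance = 1e-10)
    expect_equal(tr$Y1, orc$Y1, tolerance = 1e-10)
    expect_true(all(abs(tr$Y1) < 1) && all(abs(tr$Y2) < 1))
    if (tr$Y3[["m"]] > 0 && tr$Y3[["Per"]] > 0) {
      expect_true(all(diff(tr$O) <= 0))
      expect_true(all(tr$O > 0 & tr$O < 1))
    }
  }
  zero <- pst_network(dense_layer(matrix(0, 5, 3), rep(0, 5)),
                      dense_layer(matrix(0, 4, 5), rep(0, 4)),
                      dense_layer(matrix(0, 2, 4), rep(0, 2)),
                      n_inputs = 3)
  expect_error(forward_pass(zero, rep(0.5, 3)),
               class = "pstnn_error_degenerate_geometry")
})

test_that("risk encoding is cumulative and decoding inverts it", {
  expect_equal(encode_risk(1)$pattern, c(1, 0, 0, 0))
  expect_equal(encode_risk(2)$pattern, c(1, 1, 0, 0))
  expect_equal(encode_risk(3)$pattern, c(1, 1, 1, 0))
  expect_equal(encode_risk(4)$pattern, c(1, 1, 1, 1))
  expect_error(encode_risk(0), class = "pstnn_error_invalid_label")
  expect_error(encode_risk(5), class = "pstnn_error_invalid_label")
  for (r in 1:4) expect_equal(decode_risk(encode_risk(r)$pattern), r)
  expect_equal(decode_risk(c(0.9, 0.7, 0.4, 0.1)), 2)
  # nearest-pattern by brute force on random outputs
  P <- rbind(c(1, 0, 0, 0), c(1, 1, 0, 0), c(1, 1, 1, 0), c(1, 1, 1, 1))
  set.seed(3)
  for (i in 1:50) {
    O <- runif(4)
    expect_equal(decode_risk(O), which.min(colSums((t(P) - O)^2)))
  }
  # ties break toward the lower risk level
  expect_equal(decode_risk(c(0.5, 0.5, 0.5, 0.5)), 1)
  expect_error(decode_risk(c(1, NA, 0, 0)), class = "pstnn_error_invalid_output")
})

test_that("class scores agree with decoding and exact patterns", {
  s <- as.numeric(class_scores(c(1, 0, 0, 0)))
  expect_equal(s[1], 0)
  expect_true(all(s[-1] < 0))
  expect_equal(as.numeric(class_scores(c(1, 1, 1, 1)))[4], 0)
  s <- as.numeric(class_scores(c(0.5, 0.5, 0.5, 0.5)))
  expect_equal(s[1], -1)
  expect_equal(s[1], s[4])
  set.seed(4)
  for (i in 1:20) {
    O <- runif(4)
    expect_equal(which.max(class_scores(O)), decode_risk(O),
                 ignore_attr = TRUE)
  }
})

test_that("model JSON serialization round-trips exactly", {
  net <- init_nguyen_widrow(c(6, 8, 8, 2), seed = 5)
  path <- tempfile(fileext = ".json")
  write_pst_model(net, path, selected = paste0("psy_", 1:6),
                  training = list(seed = 5, iterations = 0))
  back <- read_pst_model(path)
  expect_equal(back$layer1$weights, net$layer1$weights)
  expect_equal(back$layer3$biases, net$layer3$biases)
  expect_equal(back$tension$tensions, net$tension$tensions)
  expect_equal(attr(back, "selected_columns"), paste0("psy_", 1:6))
  set.seed(6)
  x <- runif(6)
  expect_equal(forward_pass(back, x)$O, forward_pass(net, x)$O,
               tolerance = 1e-15)
  expect_error(suppressWarnings(read_pst_model(tempfile())),
               class = "pstnn_error")
})
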
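# Architecture: donut mask, receptive-field recurrence, network building.

test_that("donut mask has a single structural zero at the center", {
  m3 <- donut_mask(3)
  expect_equal(sum(m3), 8)
  expect_equal(m3[2, 2], 0)
  m5 <- donut_mask(5)
  expect_equal(sum(m5), 24)
  expect_equal(m5[3, ], c(1, 1, 0, 1, 1))
  expect_error(donut_mask(4), "odd")
  expect_error(donut_mask(1), "odd")
})

test_that("receptive-field recurrence reproduces the hand-enumerated 1-D slices", {
  # K=3, one 2-dilated layer: row dy = 0 of the 2-D field is {-3,-1,+1,+3}
  rf2 <- receptive_field(net_spec(paths = list(c(2, 1)), channels = 4))
  slice2 <- sort(rf2[rf2[, "dy"] == 0L, "dx"])
  expect_equal(slice2, c(-3L, -1L, 1L, 3L))
  expect_false(offset_set_contains_zero(rf2))
  # K=3, one 1-dilated layer: {-2,...,+2} with the ZERO offset present
  rf1 <- receptive_field(net_spec(paths = list(c(1, 1)), channels = 4))
  slice1 <- sort(rf1[rf1[, "dy"] == 0L, "dx"])
  expect_equal(slice1, -2:2)
  expect_true(offset_set_contains_zero(rf1))
})

test_that("zero offset stays excluded at every depth of the (2,m)+(3,m) stacks", {
  for (m in 1:3) {
    per_path <- receptive_field(
      net_spec(paths = list(c(2, m), c(3, m)), channels = 4), by_path = TRUE)
    for (p in per_path) expect_false(offset_set_contains_zero(p))
    rf <- receptive_field(net_spec(paths = list(c(2, m), c(3, m)), channels = 4))
    expect_false(offset_set_contains_zero(rf))
  }
})

test_that("the strict dilation condition is the invariance boundary", {
  # compliant: d > floor(K/2)
  expect_true(is_j_invariant_spec(net_spec(donut_K = 3, paths = list(c(2, 2)))))
  expect_true(is_j_invariant_spec(net_spec(donut_K = 5, paths = list(c(3, 1)))))
  # boundary violations: d == floor(K/2)
  expect_false(is_j_invariant_spec(net_spec(donut_K = 3, paths = list(c(1, 1)))))
  expect_false(is_j_invariant_spec(net_spec(donut_K = 5, paths = list(c(2, 1)))))
  expect_true(offset_set_contains_zero(
    receptive_field(net_spec(donut_K = 5, paths = list(c(2, 1))))))
  # any single non-compliant path poisons the union
  expect_false(is_j_invariant_spec(net_spec(paths = list(c(2, 1), c(1, 1)))))
})

test_that("the two paths supplement each other's missing regions", {
  per_path <- receptive_field(small_spec(), by_path = TRUE)
  union_rf <- receptive_field(small_spec())
  for (p in per_path) {
    expect_gt(nrow(union_rf), nrow(p))
    # every path offset appears in the union
    expect_true(all(paste(p[, 1], p[, 2]) %in%
                      paste(union_rf[, 1], union_rf[, 2])))
  }
})

test_that("build_network is deterministic and rejects invariance violations", {
  n1 <- small_net(seed = 7)
  n2 <- small_net(seed = 7)
  expect_identical(n1, n2)
  n3 <- small_net(seed = 8)
  expect_false(identical(n1$layers$front$W, n3$layers$front$W))
  expect_error(build_network(net_spec(paths = list(c(1, 2)), channels = 4)),
               "J-invariance violation")
  # the same spec is buildable as the supervised baseline or via enforce=FALSE
  expect_s3_class(build_network(net_spec(paths = list(c(1, 2)), channels = 4),
                                enforce = FALSE), "denoiser")
})

test_that("network output preserves input shape, including non-square images", {
  net <- small_net(channels = 4L)
  y <- net_apply(net, make_synthetic_clean("texture", 64, 64))
  expect_equal(dim(y), c(64L, 64L))
  y2 <- net_apply(net, make_synthetic_clean("gradient", 24, 40))
  expect_equal(dim(y2), c(24L, 40L))
})

test_that("backpropagated gradients match finite differences", {
  net <- build_network(net_spec(paths = list(c(2, 1), c(3, 1)), channels = 3,
                                head_depth = 1), seed = 2)
  set.seed(1)
  x <- array(runif(16 * 16 * 2), c(16, 16, 2, 1))
  noisy <- array(runif(16 * 16 * 2), c(16, 16, 2, 1))
  fw <- blindspot:::net_forward(net, x, cache = TRUE)
  gy <- blindspot:::loss_grad(fw$y, noisy, loss_spec("l2"))
  bk <- blindspot:::net_backward(net, fw, gy)
  eps <- 1e-6
  for (nm in names(net$layers)) {
    idx <- sample(length(net$layers[[nm]]$W), 2)
    for (i in idx) {
      np <- net; np$layers[[nm]]$W[i] <- np$layers[[nm]]$W[i] + eps
      nm_ <- net; nm_$layers[[nm]]$W[i] <- nm_$layers[[nm]]$W[i] - eps
      fd <- (loss_l2(blindspot:::net_forward(np, x), noisy) -
               loss_l2(blindspot:::net_forward(nm_, x), noisy)) / (2 * eps)
      expect_equal(bk$grads[[nm]]$dW[i], fd, tolerance = 1e-5,
                   info = sprintf("layer %s weight %d", nm, i))
    }
  }
})

test_that("all-zero-weight network has an empty dependency map", {
  net <- small_net(channels = 4L)
  for (nm in names(net$layers)) {
    net$layers[[nm]]$W[] <- 0
    net$layers[[nm]]$b[] <- 0
  }
  dm <- dependency_map_bruteforce(net, extent = 5L, seed = 1)
  expect_equal(nrow(dm), 0L)
})
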
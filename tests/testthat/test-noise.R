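# Noise simulators: determinism, zero-noise identities, closed-form moments,
# composition of the fusion model, and the salt-and-pepper mean shift.

test_that("zero-noise settings are exact identities and inputs are unmodified", {
  x <- make_synthetic_clean("texture", 32, 32, seed = 3)
  x_orig <- x
  expect_identical(add_awgn(x, 0, 1), x)
  expect_identical(add_speckle(x, 0, 1), x)
  expect_identical(add_salt_pepper(x, 0, 1), x)
  sp <- noise_spec("fusion", 0, 0, 0, seed = 5)
  expect_identical(add_fusion(x, sp), x)
  y <- add_awgn(x, 25, 1)
  expect_identical(x, x_orig)
  expect_false(identical(y, x))
})

test_that("same (image, spec) pair reproduces the identical noisy image", {
  x <- make_synthetic_clean("shapes", 32, 32, seed = 2)
  for (fam in c("awgn", "speckle", "salt_pepper", "fusion")) {
    sp <- noise_spec(fam, sigma_g = 25, sigma_s = 10, d = 0.2, seed = 42)
    expect_identical(add_noise(x, sp), add_noise(x, sp), info = fam)
  }
})

test_that("speckle vanishes on zero signal and salt-pepper at d=1 is binary", {
  z <- matrix(0, 32, 32)
  expect_identical(add_speckle(z, 30, 1), z)
  x <- make_synthetic_clean("texture", 32, 32, seed = 1)
  y <- add_salt_pepper(x, 1, 7)
  expect_true(all(y %in% c(0, 1)))
})

test_that("empirical moments match the closed forms on a large constant image", {
  n <- 512L
  x1 <- matrix(1, n, n)
  # AWGN: std sigma_g/255, mean 0
  d_awgn <- add_awgn(x1 * 0.5, 50, seed = 11) - 0.5
  sig <- 50 / 255
  expect_lt(abs(sd(d_awgn) - sig) / sig, 0.01)
  expect_lt(abs(mean(d_awgn)), 3 * sig / n)
  # speckle on constant 1: std sigma_s/255, mean 0
  d_sp <- add_speckle(x1, 25, seed = 12) - 1
  sig_s <- 25 / 255
  expect_lt(abs(sd(d_sp) - sig_s) / sig_s, 0.01)
  expect_lt(abs(mean(d_sp)), 3 * sig_s / n)
  # salt-and-pepper replacement fraction at d = 0.25 on constant 0.5
  y <- add_salt_pepper(matrix(0.5, n, n), 0.25, seed = 13)
  frac <- mean(y != 0.5)
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / n^2) + 1e-12)
})

test_that("salt-and-pepper mean shift equals d * (0.5 - mean(x))", {
  n <- 512L
  x <- matrix(0.2, n, n)
  d <- 0.4
  y <- add_salt_pepper(x, d, seed = 21)
  shift <- mean(y) - mean(x)
  theory <- d * (0.5 - mean(x))
  # replaced pixels contribute (v - 0.2), v ~ Bernoulli(0.5); bound via 3 SE
  se <- sqrt(d * (0.25 + (0.5 - 0.2)^2) / n^2)
  expect_lt(abs(shift - theory), 3 * se)
})

test_that("fusion degenerates to the single-noise operations component-wise", {
  x <- make_synthetic_clean("gradient", 32, 32, seed = 1)
  expect_identical(add_fusion(x, noise_spec("fusion", sigma_g = 25, seed = 9)),
                   add_awgn(x, 25, seed = 9))
  expect_identical(add_fusion(x, noise_spec("fusion", sigma_s = 25, seed = 9)),
                   add_speckle(x, 25, seed = 9))
  expect_identical(add_fusion(x, noise_spec("fusion", d = 0.3, seed = 9)),
                   add_salt_pepper(x, 0.3, seed = 9))
})

test_that("toggling one fusion component never shifts another's draws", {
  x <- make_synthetic_clean("shapes", 32, 32, seed = 4)
  full <- add_fusion(x, noise_spec("fusion", 25, 10, 0.2, seed = 3))
  no_sp <- add_fusion(x, noise_spec("fusion", 25, 10, 0, seed = 3))
  # pixels not replaced by the impulse mask agree exactly
  mask_changed <- full != no_sp
  expect_true(all(full[!mask_changed] == no_sp[!mask_changed]))
  expect_gt(mean(mask_changed), 0.1)  # impulse actually fired
})

test_that("invalid noise parameters error", {
  x <- matrix(0.5, 16, 16)
  expect_error(add_awgn(x, -1), "nonnegative")
  expect_error(add_speckle(x, -0.1), "nonnegative")
  expect_error(add_salt_pepper(x, 1.5), "\\[0,1\\]")
  expect_error(noise_spec("awgn", sigma_g = -2), "nonnegative")
  expect_error(add_fusion(x, noise_spec("awgn", sigma_g = 5)), "fusion")
})

test_that("synthetic clean generator honors its contracts", {
  expect_error(make_synthetic_clean("flat", 8, 64), "at least 16")
  expect_error(make_synthetic_clean("voronoi", 64, 64), "'arg'")
  flat <- make_synthetic_clean("flat", 64, 64)
  expect_equal(loss_tv(flat), 0)
  grad <- make_synthetic_clean("gradient", 64, 48)
  expect_equal(grad[1, 1], 0)
  expect_equal(grad[64, 1], 1)
  expect_true(all(diff(grad[, 10]) > 0))
  for (kind in c("shapes", "texture", "checker")) {
    a <- make_synthetic_clean(kind, 128, 128, seed = 6)
    b <- make_synthetic_clean(kind, 128, 128, seed = 6)
    expect_identical(a, b, info = kind)
    expect_true(all(a >= 0 & a <= 1), info = kind)
  }
  # different seeds give different random-kind images
  expect_false(identical(make_synthetic_clean("shapes", 64, 64, seed = 1),
                         make_synthetic_clean("shapes", 64, 64, seed = 2)))
})
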
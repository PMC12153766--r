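test_that("global average pooling is the spatial mean per channel", {
  F <- array(3, dim = c(4, 2, 5))
  expect_equal(global_avg_pool(F), rep(3, 4))
  F1 <- array(c(1, 2, 3, 4), dim = c(1, 2, 2))
  expect_equal(global_avg_pool(F1), 2.5)
  set.seed(51)
  F2 <- array(rnorm(3 * 4 * 5), dim = c(3, 4, 5))
  loop <- sapply(1:3, function(c) {
    s <- 0
    for (i in 1:4) for (j in 1:5) s <- s + F2[c, i, j]
    s / 20
  })
  expect_equal(global_avg_pool(F2), loop)
})

test_that("an ESE branch is an affine map of the pooled vector", {
  set.seed(52)
  F <- array(rnorm(4 * 3 * 3), dim = c(4, 3, 3))
  expect_equal(ese_branch(F, diag(4)), global_avg_pool(F))
  expect_equal(ese_branch(array(0, dim = c(4, 2, 2)), matrix(rnorm(16), 4),
                          bias = 1:4), as.numeric(1:4))
  fc <- matrix(rnorm(16), 4); b <- rnorm(4)
  pooled <- global_avg_pool(F)
  loop <- sapply(1:4, function(r) sum(fc[r, ] * pooled) + b[r])
  expect_equal(ese_branch(F, fc, b), loop)
  expect_error(ese_branch(F, matrix(0, 3, 3)), "must be 4 x 4")
})

test_that("domain weights live on the simplex and resist overflow", {
  set.seed(53)
  p <- random_daa_params(4)
  zero <- array(0, dim = c(4, 2, 2))
  expect_equal(domain_weights(zero, p), rep(1 / 3, 3))
  # extreme logits: a map driving one branch's logit huge must not overflow
  p2 <- daa_params(rbind(rep(1000, 4), rep(0, 4), rep(0, 4)),
                   p$ese_fcs, p$ese_biases)
  ones <- array(1, dim = c(4, 2, 2))
  w <- domain_weights(ones, p2)
  expect_true(all(is.finite(w)))
  expect_equal(w, c(1, 0, 0), tolerance = 1e-12)
  for (k in 1:10) {
    F <- array(rnorm(4 * 8), dim = c(4, 2, 4))
    w <- domain_weights(F, p)
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-9)
  }
})

test_that("forward pass scales channels and never amplifies", {
  set.seed(54)
  p <- random_daa_params(5)
  F <- array(rnorm(5 * 3 * 4), dim = c(5, 3, 4))
  out <- daa_forward(F, p)
  expect_equal(dim(out), dim(F))
  expect_true(all(abs(out) <= abs(F)))
  expect_true(all(abs(out)[F != 0] < abs(F)[F != 0]))   # sigmoid < 1 strictly
  # each channel is one scalar multiple of the input channel
  for (c in 1:5) {
    ratio <- out[c, , ] / F[c, , ]
    expect_lt(diff(range(ratio)), 1e-12)
    expect_gt(ratio[1, 1], 0)
  }
  expect_equal(daa_forward(array(0, dim = c(5, 2, 2)), p),
               array(0, dim = c(5, 2, 2)))
})

test_that("forward pass agrees with the naive loop oracle", {
  set.seed(55)
  for (k in 1:12) {
    C <- sample(1:8, 1); H <- sample(1:5, 1); W <- sample(1:5, 1)
    p <- random_daa_params(C)
    F <- array(rnorm(C * H * W), dim = c(C, H, W))
    expect_equal(daa_forward(F, p), daa_forward_loop(F, p), tolerance = 1e-9)
  }
})

test_that("identical branches make the output independent of domain weights", {
  set.seed(56)
  C <- 6
  fc <- matrix(rnorm(C * C), C); b <- rnorm(C)
  F <- array(rnorm(C * 9), dim = c(C, 3, 3))
  p1 <- daa_params(matrix(rnorm(3 * C), 3), list(fc, fc, fc), list(b, b, b))
  p2 <- daa_params(matrix(rnorm(3 * C), 3), list(fc, fc, fc), list(b, b, b))
  expect_equal(daa_forward(F, p1), daa_forward(F, p2), tolerance = 1e-9)
})

test_that("permuting branches together with domain rows leaves output unchanged", {
  set.seed(57)
  C <- 4
  p <- random_daa_params(C)
  F <- array(rnorm(C * 6), dim = c(C, 2, 3))
  perm <- c(3, 1, 2)
  pp <- daa_params(p$domain_fc[perm, ], p$ese_fcs[perm], p$ese_biases[perm])
  expect_equal(daa_forward(F, p), daa_forward(F, pp), tolerance = 1e-12)
})

test_that("parameters round-trip through the array container file", {
  set.seed(58)
  p <- random_daa_params(5)
  path <- tempfile(fileext = ".json")
  write_daa_params(p, path)
  q <- read_daa_params(path)
  expect_equal(q$domain_fc, unname(p$domain_fc), tolerance = 1e-12)
  for (b in 1:3) {
    expect_equal(q$ese_fcs[[b]], unname(p$ese_fcs[[b]]), tolerance = 1e-12)
    expect_equal(q$ese_biases[[b]], p$ese_biases[[b]], tolerance = 1e-12)
  }
  # shape validation on load
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(domain_fc = matrix(0, 2, 5)), bad)
  expect_error(read_daa_params(bad))
  unlink(c(path, bad))
})
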
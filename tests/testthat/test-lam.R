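# Mask-guided self-attention module: algebraic identities, oracle
# equivalence, insertion into the backbone.

test_that("attention rows sum to one and a single position gives A_L = 2 * X_C", {
  set.seed(20)
  C <- 3L
  par <- octlan:::lam_init_params(C)
  # row-normalization at a realistic size
  X <- matrix(rnorm(24 * C), 24, C)
  r <- octlan:::lam_fwd(octlan:::fmap(X, c(4, 3, 2)), rep(1, 24), par)
  expect_true(all(abs(rowSums(r$cache$P) - 1) < 1e-5))
  # single spatial position: softmax of a scalar is 1, so A_L = X_C + X_C
  x1 <- matrix(rnorm(C), 1, C)
  out <- lam_forward(array(x1, c(1, 1, 1, C)), array(1, c(1, 1, 1)), par)
  XC <- x1 %*% par$Wv + matrix(par$bv, 1)
  expect_equal(matrix(out, 1), 2 * XC, tolerance = 1e-12)
})

test_that("an all-ones mask reduces the module to plain self-attention over X", {
  set.seed(21)
  C <- 4L; N <- 12L
  par <- octlan:::lam_init_params(C)
  X <- matrix(rnorm(N * C), N, C)
  masked <- lam_forward(array(X, c(3, 2, 2, C)), array(1, c(3, 2, 2)), par)
  # plain self-attention computed directly (X_L = X)
  plain <- brute_lam(X, rep(1, N), par)
  expect_equal(matrix(masked, N, C), plain, tolerance = 1e-10)
})

test_that("module output matches the brute-force N x N oracle and permutes with the positions", {
  set.seed(22)
  C <- 3L
  par <- octlan:::lam_init_params(C)
  X <- matrix(rnorm(4 * C), 4, C)       # 2 x 2 x 1 grid
  xb <- c(1, 0, 1, 1)
  out <- lam_forward(array(X, c(2, 2, 1, C)), array(xb, c(2, 2, 1)), par)
  om <- matrix(out, 4, C)
  expect_equal(om, brute_lam(X, xb, par), tolerance = 1e-10)
  # permutation equivariance
  pm <- c(3, 1, 4, 2)
  out_p <- lam_forward(array(X[pm, ], c(2, 2, 1, C)),
                       array(xb[pm], c(2, 2, 1)), par)
  expect_equal(matrix(out_p, 4, C), om[pm, ], tolerance = 1e-10)
})

test_that("masking gates the lesion features exactly and changes the output", {
  set.seed(23)
  C <- 3L; N <- 8L
  par <- octlan:::lam_init_params(C)
  X <- matrix(rnorm(N * C), N, C)
  xb <- c(1, 1, 0, 0, 1, 0, 1, 1)
  r <- octlan:::lam_fwd(octlan:::fmap(X, c(2, 2, 2)), xb, par)
  expect_equal(r$cache$XL[xb == 1, ], X[xb == 1, ])
  expect_true(all(r$cache$XL[xb == 0, ] == 0))
  expect_equal(dim(r$out$v), dim(X))     # output shape preserved
  r2 <- octlan:::lam_fwd(octlan:::fmap(X, c(2, 2, 2)), rep(1, N), par)
  expect_gt(max(abs(r$out$v - r2$out$v)), 1e-8)
  expect_error(octlan:::lam_fwd(octlan:::fmap(X, c(2, 2, 2)), c(1, 0), par),
               "mask")
})

test_that("insertion counts: 4 per stage and 8 per block on the 18-layer backbone", {
  cfg <- backbone_config(18, base_channels = 4)
  expect_length(build_lam_network(cfg, lam_config("per_stage"))$lam$params, 4)
  expect_length(build_lam_network(cfg, lam_config("per_block"))$lam$params, 8)
  m <- build_lam_network(cfg, lam_config("per_stage", sites = "s2"))
  expect_named(m$lam$params, "s2")
})

test_that("zeroed attention parameters leave the forward pass finite and defined", {
  set.seed(24)
  m <- build_lam_network(micro_backbone(), lam_config())
  for (nm in grep("^lam\\.", names(m$params), value = TRUE)) {
    m$params[[nm]] <- m$params[[nm]] * 0
  }
  fw <- net_forward(m, array(runif(10 * 10 * 6), c(10, 10, 6)),
                    mask = array(1, c(10, 10, 6)))
  expect_true(all(is.finite(fw$scores)))
})

test_that("attention parameters receive nonzero gradients and respond to the mask", {
  set.seed(25)
  m <- build_lam_network(micro_backbone(), lam_config())
  x <- array(runif(10 * 10 * 6), c(10, 10, 6))
  msk <- array(rbinom(600, 1, 0.5), c(10, 10, 6))
  fw <- net_forward(m, x, mask = msk, keep_cache = TRUE)
  xe <- octlan:::xent_fwd(fw$scores, 1L)
  bw <- net_backward(m, fw$cache, octlan:::xent_bwd(xe$p, 1L))
  for (nm in c("lam.s1.Wq", "lam.s1.Wv", "lam.s2.Wq", "lam.s2.Wv")) {
    expect_gt(max(abs(bw$grads[[nm]])), 0)
  }
  # mask sensitivity of the full network
  fw2 <- net_forward(m, x, mask = array(1, c(10, 10, 6)))
  expect_gt(max(abs(fw$scores - fw2$scores)), 1e-9)
  expect_error(net_forward(m, x), "mask is required")
})

test_that("the literal composition variant is available and agrees on N = 1", {
  set.seed(26)
  C <- 3L
  par <- octlan:::lam_init_params(C)
  x1 <- matrix(rnorm(C), 1, C)
  std <- lam_forward(array(x1, c(1, 1, 1, C)), array(1, c(1, 1, 1)), par,
                     variant = "standard")
  # for N = 1 the literal reading softmax(Q Q^T V) + V gives softmax over the
  # C channels instead of 2*X_C; it must still be finite and shaped like X
  lit <- lam_forward(array(x1, c(1, 1, 1, C)), array(1, c(1, 1, 1)), par,
                     variant = "literal")
  expect_equal(dim(lit), dim(std))
  expect_true(all(is.finite(lit)))
})

test_that("nearest-neighbor mask resampling stays binary and tracks blocks", {
  m <- array(0, c(8, 8, 4)); m[1:4, , ] <- 1
  r <- octlan:::resample_mask_nearest(m, c(4, 4, 2))
  expect_true(all(r %in% c(0, 1)))
  expect_true(all(r[1:2, , ] == 1))
  expect_true(all(r[3:4, , ] == 0))
})
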
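# 3D residual backbone: layout, shape contracts, residual identity, feature
# taps, checkpointing, end-to-end gradients.

test_that("canonical depths produce the expected block layout", {
  expect_equal(backbone_config(18)$blocks, c(2L, 2L, 2L, 2L))
  expect_equal(backbone_config(34)$blocks, c(3L, 4L, 6L, 3L))
  expect_equal(backbone_config(50)$block, "bottleneck")
  expect_equal(backbone_config(101)$blocks[3], 23L)
  expect_error(backbone_config(20), "unsupported depth")
  expect_error(backbone_config(18, n_classes = 1), "n_classes")
  m18 <- build_backbone(backbone_config(18, base_channels = 4))
  expect_equal(sum(vapply(m18$plan$stages, length, 0L)), 8L)  # 8 basic blocks
})

test_that("a standard-geometry volume yields a finite score vector of length n_classes", {
  set.seed(1)
  cfg <- backbone_config(18, base_channels = 4)
  m <- build_backbone(cfg)
  vol <- array(runif(100 * 100 * 70), c(100, 100, 70))
  fw <- net_forward(m, vol)
  expect_length(fw$scores, 2)
  expect_true(all(is.finite(fw$scores)))
  z <- net_forward(m, array(0, c(100, 100, 70)))
  expect_true(all(is.finite(z$scores)))
})

test_that("feature spatial size halves per stage from the stem resolution", {
  set.seed(2)
  cfg <- backbone_config(18, base_channels = 4,
                         blocks_per_stage = c(1, 1, 1),
                         stem_kernel = 3, stem_pool = FALSE,
                         stage_taps = c("stage1", "stage2", "stage3"))
  m <- build_backbone(cfg)
  x <- array(runif(32 * 32 * 16), c(32, 32, 16))
  fw <- forward_with_features(m, x, taps = c("stage1", "stage2", "stage3"))
  # stride bookkeeping oracle: stem stride 2, then stride 2 per stage s >= 2
  stem_dim <- ceiling(c(32, 32, 16) / 2)
  for (s in 1:3) {
    expected <- ceiling(stem_dim / 2^(s - 1))
    got <- dim(fw$features[[paste0("stage", s)]])[1:3]
    expect_equal(got, as.integer(expected))
  }
  expect_error(forward_with_features(m, x, taps = "stage9"), "unknown tap")
})

test_that("blocks with zeroed residual-branch weights act as the identity on nonnegative input", {
  set.seed(3)
  cfg <- micro_backbone()
  m <- build_backbone(cfg)
  # zero stage-1 block (identity shortcut): conv weights and norm gammas
  for (nm in c("s1.b1.W1", "s1.b1.W2", "s1.b1.g1", "s1.b1.g2")) {
    m$params[[nm]] <- m$params[[nm]] * 0
  }
  x <- octlan:::fmap(matrix(abs(rnorm(6 * 6 * 4 * 4)), 6 * 6 * 4, 4), c(6, 6, 4))
  bf <- octlan:::block_fwd(m$params, "s1.b1", "basic", x, 1L)
  expect_equal(bf$out$v, x$v)
})

test_that("evaluation is deterministic and checkpoints round-trip", {
  set.seed(4)
  m <- build_backbone(micro_backbone())
  x <- array(runif(12 * 12 * 8), c(12, 12, 8))
  s1 <- net_forward(m, x)$scores
  s2 <- net_forward(m, x)$scores
  expect_identical(s1, s2)
  ck <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, ck)
  m2 <- load_checkpoint(ck)
  expect_identical(net_forward(m2, x)$scores, s1)
  expect_error(load_checkpoint("/nonexistent/ck.rds"), "not found")
})

test_that("whole-network parameter gradients match central differences", {
  set.seed(5)
  m <- build_backbone(micro_backbone())
  x <- array(runif(10 * 10 * 6), c(10, 10, 6))
  fw <- net_forward(m, x, keep_cache = TRUE)
  xe <- octlan:::xent_fwd(fw$scores, 2L)
  bw <- net_backward(m, fw$cache, octlan:::xent_bwd(xe$p, 2L))
  loss_of <- function(params) {
    m2 <- m; m2$params <- params
    octlan:::xent_fwd(net_forward(m2, x)$scores, 2L)$loss
  }
  for (nm in c("stem.W", "s1.b1.W1", "s2.b1.down.W", "head.W", "s1.b1.g2")) {
    p <- m$params
    i <- sample(length(p[[nm]]), 1)
    eps <- 1e-5
    p[[nm]][i] <- p[[nm]][i] + eps; lp <- loss_of(p)
    p[[nm]][i] <- p[[nm]][i] - 2 * eps; lm <- loss_of(p)
    expect_lt(abs((lp - lm) / (2 * eps) - bw$grads[[nm]][i]), 1e-6)
  }
})

test_that("bottleneck blocks forward and backprop on a small input", {
  set.seed(6)
  cfg <- backbone_config(50, base_channels = 4, blocks_per_stage = c(1, 1),
                         stem_kernel = 3, stem_pool = FALSE)
  m <- build_backbone(cfg)
  x <- array(runif(10 * 10 * 6), c(10, 10, 6))
  fw <- net_forward(m, x, keep_cache = TRUE)
  expect_length(fw$scores, 2)
  bw <- net_backward(m, fw$cache, c(1, -1))
  expect_true(all(vapply(bw$grads, function(g) all(is.finite(g)), TRUE)))
  loss_of <- function(params) {
    m2 <- m; m2$params <- params
    sum(net_forward(m2, x)$scores * c(1, -1))
  }
  p <- m$params; i <- sample(length(p[["s1.b1.W3"]]), 1); eps <- 1e-5
  p[["s1.b1.W3"]][i] <- p[["s1.b1.W3"]][i] + eps; lp <- loss_of(p)
  p[["s1.b1.W3"]][i] <- p[["s1.b1.W3"]][i] - 2 * eps; lm <- loss_of(p)
  expect_lt(abs((lp - lm) / (2 * eps) - bw$grads[["s1.b1.W3"]][i]), 1e-6)
})
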
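# Diffusion mechanics: schedule, forward noising, UNet shape symmetry,
# attention gating, checkpoint cadence, seeded sampling, and reverse-chain
# consistency with the exact-noise oracle denoiser.

tiny_unet <- function(img = 8L, base = 4L, mult = c(1, 2), d_ctx = 6L,
                      seed = 1L, attn_max = 16L) {
  build_unet(unet_config(img, base = base, mult = mult, d_ctx = d_ctx,
                         time_dim = 8L, attn_max = attn_max), seed = seed)
}

test_that("the linear schedule retains signal monotonically from ~1 to ~0", {
  s <- noise_schedule(1000L)
  expect_identical(s$T, 1000L)
  expect_true(all(diff(s$alphabar) < 0))
  expect_gt(s$alphabar[1], 0.999)
  expect_lt(s$alphabar[1000], 1e-4)
})

test_that("forward noising follows the closed form and preserves variance", {
  set.seed(21)
  x0 <- array(rnorm(3 * 6 * 6), c(3, 6, 6))
  noise <- array(rnorm(length(x0)), dim(x0))
  # retention 0.25: x_t = 0.5 x0 + sqrt(0.75) noise
  s25 <- list(T = 1L, betas = 0.75, alphas = 0.25, alphabar = 0.25)
  expect_equal(forward_noise(x0, 1L, s25, noise),
               0.5 * x0 + 0.8660254 * noise, tolerance = 1e-7)
  s <- noise_schedule(100L)
  expect_equal(forward_noise(x0, 1L, s, noise), x0,
               tolerance = 2 * sqrt(1 - s$alphabar[1]))
  big0 <- rnorm(20000); bign <- rnorm(20000)
  for (t in c(1L, 50L, 100L))
    expect_equal(stats::var(forward_noise(big0, t, s, bign)), 1,
                 tolerance = 0.05)
  expect_error(forward_noise(x0, 0L, s, noise), "out of range")
  expect_error(forward_noise(x0, 101L, s, noise), "out of range")
})

test_that("UNet restores the input shape and gates attention at <= 16 px", {
  u <- tiny_unet(img = 32L, base = 4L, mult = c(1, 1, 2), attn_max = 16L)
  # levels enter at 32, 16, 8 px; attention everywhere but the first
  expect_identical(u$config$attn_at, c(FALSE, TRUE, TRUE))
  expect_true(u$config$attn_mid)   # bottleneck at 4 px
  x <- array(rnorm(3 * 32 * 32), c(3, 32, 32))
  cond <- matrix(rnorm(4 * 6), 4, 6)
  trace <- new.env(); trace$log <- NULL
  ctx <- rs$ad_ctx(u$params, frozen = "")
  out <- rs$unet_fwd(ctx, u$config, x, 3L, cond, trace = trace)
  expect_identical(dim(out$value), dim(x))
  expect_true(all(trace$log$extent <= 16))
  expect_setequal(trace$log$stage,
                  c("down2", "down3", "mid", "up2", "up3"))
})

test_that("training history, checkpoint cadence and epochs = 0 behave", {
  sched <- noise_schedule(10L)
  tg <- array(rnorm(2 * 2 * 6), c(2, 2, 6))
  u <- tiny_unet()
  x <- array(0.1, c(3, 8, 8))
  u0 <- train_diffusion(u, list(x), 1L, tg, sched, epochs = 0L)
  expect_identical(u0$params, u$params)
  expect_length(u0$loss_history, 0L)
  expect_false(u0$trained)
  ck <- withr::local_tempdir()
  u1 <- train_diffusion(u, list(x), 1L, tg, sched, epochs = 100L, lr = 1e-3,
                        ckpt_every = 25L, ckpt_dir = ck, seed = 2L)
  expect_length(u1$loss_history, 100L)
  expect_identical(u1$checkpoints, c(25L, 50L, 75L, 100L))
  expect_identical(sort(list.files(ck)),
                   sprintf("unet_ep%04d.rds", c(25L, 50L, 75L, 100L)))
  expect_error(train_diffusion(u, list(x), 1L, NULL, sched, epochs = 1L),
               "missing")
})

test_that("sampling is seed-deterministic and seed-sensitive", {
  sched <- noise_schedule(5L)
  tg <- array(rnorm(2 * 2 * 6), c(2, 2, 6))
  u <- tiny_unet(seed = 3L)
  expect_error(sample_diffusion(u, sched, conditioning_for_training(1, tg)),
               "untrained")
  u <- train_diffusion(u, list(array(0.1, c(3, 8, 8))), 1L, tg, sched,
                       epochs = 2L, lr = 1e-3, seed = 1L)
  cond <- conditioning_for_training(1, tg)
  s1 <- sample_diffusion(u, sched, cond, seed = 7L)
  s2 <- sample_diffusion(u, sched, cond, seed = 7L)
  s3 <- sample_diffusion(u, sched, cond, seed = 8L)
  expect_identical(s1, s2)
  expect_gt(mean(abs(s1 - s3)), 0)
  expect_identical(dim(s1), c(3L, 8L, 8L))
  expect_true(all(abs(s1) <= 1))
  expect_error(sample_diffusion(u, sched, cond, steps = 6L), "exceeds")
})

test_that("the reverse chain recovers the clean image with the oracle denoiser", {
  # With the data distribution a point mass at x0, the optimal noise
  # predictor is (x_t - sqrt(ab) x0) / sqrt(1 - ab); ancestral sampling with
  # that oracle must reproduce x0.
  set.seed(22)
  x0 <- array(c(0.6, -0.4, 0.2), c(3, 4, 4))
  sched <- noise_schedule(50L)
  x <- array(rnorm(length(x0)), dim(x0))
  ts <- 50:1
  for (j in seq_along(ts)) {
    t <- ts[j]
    ab_t <- sched$alphabar[t]
    ab_prev <- if (j < length(ts)) sched$alphabar[ts[j + 1]] else 1
    ratio <- ab_t / ab_prev
    eps <- (x - sqrt(ab_t) * x0) / sqrt(1 - ab_t)
    m <- (x - (1 - ratio) / sqrt(1 - ab_t) * eps) / sqrt(ratio)
    x <- if (j < length(ts)) {
      m + sqrt(1 - ratio) * array(rnorm(length(x)), dim(x))
    } else m
  }
  expect_equal(x, x0, tolerance = 1e-6)
})

test_that("the full inference composition keeps shape and determinism", {
  items <- toy_align_items(1L, seed0 = 61L)
  aln <- toy_alignnet(items, epochs = 0L, ae_steps = 2L)
  sched <- noise_schedule(5L)
  u <- tiny_unet(img = 8L, d_ctx = aln$config$d_proj, seed = 4L)
  u <- train_diffusion(u, list(array(0, c(3, 8, 8))), 1L,
                       generate_targets(aln, "HE"), sched, epochs = 1L,
                       lr = 1e-3, seed = 1L)
  cube <- items[[2]]$x
  # untrained alignment model: keep the whole class/target axis so every
  # target index is guaranteed a surviving conditioning entry
  kc <- aln$config$n_classes * aln$config$K
  g1 <- generate_from_raman(cube, aln, u, sched, k_clstarget = kc, seed = 5L)
  g2 <- generate_from_raman(cube, aln, u, sched, k_clstarget = kc, seed = 5L)
  expect_identical(dim(g1), c(3L, 8L, 8L))
  expect_identical(g1, g2)
  shapes <- attr(g1, "stage_shapes")
  expect_identical(shapes$cube, dim(cube))
  expect_identical(shapes$cond, c(aln$config$K, aln$config$d_proj))
  expect_identical(shapes$image, c(3L, 8L, 8L))
})
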
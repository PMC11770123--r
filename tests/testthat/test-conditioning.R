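# Two-step top-K masking and conditioning synthesis.

test_that("trivial and minimal top-K masks behave by definition", {
  set.seed(1)
  dist <- array(runif(2 * 3 * 2, -1, 1), c(2, 3, 2))
  full <- compute_mask(dist, 3L, 4L)
  expect_true(all(full == 1))
  d <- array(c(0.9, 0.1), c(1, 2, 1))
  m <- compute_mask(d, 1L, 1L)
  expect_identical(m[1, 1, 1], 1)
  expect_identical(m[1, 2, 1], -Inf)
  expect_error(compute_mask(d, 0L, 1L), "out of range")
  expect_error(compute_mask(d, 1L, 5L), "out of range")
})

test_that("ties at the kth value resolve to the lowest index", {
  d <- array(c(0.5, 0.5, 0.5), c(1, 3, 1))
  m <- compute_mask(d, 2L, 1L)
  expect_identical(as.vector(m[1, , 1]), c(1, 1, -Inf))
  # step 2 tie across (cls, k): class 1 (lower combined index) wins
  d2 <- array(0.4, c(2, 1, 1))
  m2 <- compute_mask(d2, 1L, 1L)
  expect_identical(as.vector(m2), c(1, -Inf))
})

test_that("mask + conditioning pipeline matches the brute-force oracle", {
  set.seed(42)
  for (trial in 1:25) {
    n_classes <- sample(2:3, 1); n_patches <- sample(2:6, 1)
    K <- sample(2:4, 1); d <- sample(3:6, 1)
    dist <- array(runif(n_classes * n_patches * K, -1, 1),
                  c(n_classes, n_patches, K))
    kp <- sample(seq_len(n_patches), 1)
    kc <- sample(seq_len(n_classes * K), 1)
    mask <- compute_mask(dist, kp, kc)
    expect_identical(mask, oracle_mask(dist, kp, kc),
                     info = paste("trial", trial))
    tg <- array(rnorm(n_classes * K * d), c(n_classes, K, d))
    ok <- tryCatch({
      got <- synthesize_conditioning(dist, mask, tg)
      expect_equal(got$cond, oracle_conditioning(dist, mask, tg),
                   tolerance = 1e-6)
      # weights are a distribution per k, zero exactly on masked entries
      for (k in seq_len(K)) {
        expect_equal(sum(got$weights[, , k]), 1, tolerance = 1e-12)
        expect_true(all(got$weights[, , k][mask[, , k] == -Inf] == 0))
      }
      TRUE
    }, error = function(e) grepl("no surviving entries", conditionMessage(e)))
    expect_true(ok)
  }
})

test_that("singleton and symmetric survivors give exact conditioning", {
  tg <- array(rnorm(2 * 2 * 4), c(2, 2, 4))
  dist <- array(0, c(2, 2, 2))
  dist[1, 1, 1] <- 0.9
  mask <- array(-Inf, dim(dist))
  mask[1, 1, 1] <- 1
  mask[, , 2] <- 1
  out <- synthesize_conditioning(dist, mask, tg)
  # single survivor: cond_1 is exactly that H&E target
  expect_equal(out$cond[1, ], tg[1, 1, ])
  # equal-distance survivors: unweighted mean across survivors
  dist2 <- array(0.3, c(2, 1, 1))
  mask2 <- array(1, dim(dist2))
  tg2 <- array(rnorm(2 * 1 * 3), c(2, 1, 3))
  out2 <- synthesize_conditioning(dist2, mask2, tg2)
  expect_equal(out2$cond[1, ], (tg2[1, 1, ] + tg2[2, 1, ]) / 2)
})

test_that("softmax weights for survivors (0.9, 0.5) are 0.59869 / 0.40131", {
  dist <- array(c(0.9, 0.5), c(2, 1, 1))
  mask <- array(1, dim(dist))
  tg <- array(rnorm(2 * 1 * 2), c(2, 1, 2))
  out <- synthesize_conditioning(dist, mask, tg)
  expect_equal(as.vector(out$weights), c(0.59869, 0.40131), tolerance = 1e-5)
})

test_that("every conditioning vector is convex in the per-class targets", {
  set.seed(9)
  dist <- array(runif(3 * 5 * 4, -1, 1), c(3, 5, 4))
  mask <- compute_mask(dist, 3L, 6L)
  tg <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  out <- synthesize_conditioning(dist, mask, tg)
  for (k in 1:4) {
    w_cls <- apply(out$weights[, , k], 1, sum)
    expect_true(all(w_cls >= 0))
    expect_equal(sum(w_cls), 1, tolerance = 1e-12)
    expect_equal(out$cond[k, ], colSums(tg[, k, ] * w_cls), tolerance = 1e-12)
  }
})

test_that("a target index with no survivors is reported by k", {
  dist <- array(0.5, c(1, 2, 2))
  mask <- array(1, dim(dist))
  mask[, , 2] <- -Inf
  tg <- array(rnorm(1 * 2 * 3), c(1, 2, 3))
  expect_error(synthesize_conditioning(dist, mask, tg), "k = 2")
})

test_that("training conditioning returns the labeled class's targets", {
  tg <- array(seq_len(2 * 3 * 4), c(2, 3, 4))
  condA <- conditioning_for_training("TSCC", tg)
  expect_identical(dim(condA), c(3L, 4L))
  for (k in 1:3) expect_equal(condA[k, ], tg[1, k, ])
  condB <- conditioning_for_training("normal", tg)
  for (k in 1:3) expect_equal(condB[k, ], tg[2, k, ])
  expect_false(isTRUE(all.equal(condA, condB)))
  expect_identical(conditioning_for_training(2L, tg), condB)
  expect_error(conditioning_for_training("stroma", tg), "unknown class")
})
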
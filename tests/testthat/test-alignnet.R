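# Alignment-network mathematics: patchification, targets, distances,
# logits, loss — each checked against independent scalar oracles.

test_that("patchify counts and flattened dimension follow the geometry", {
  set.seed(1)
  f1 <- array(rnorm(64 * 64 * 64), c(64, 64, 64))
  p1 <- patchify(f1, 4L)
  expect_identical(dim(p1), c(256L, 1024L))
  f2 <- array(rnorm(64 * 100 * 12), c(64, 100, 12))
  expect_identical(nrow(patchify(f2, 4L)), 75L)
  f3 <- array(rnorm(2 * 8 * 8), c(2, 8, 8))
  p3 <- patchify(f3, 4L)
  expect_identical(dim(p3), c(4L, 32L))
  # row-major order and exact content: first patch is the top-left block
  expect_equal(p3[1, ], as.vector(f3[, 1:4, 1:4]))
  expect_equal(p3[2, ], as.vector(f3[, 1:4, 5:8]))
  expect_equal(p3[3, ], as.vector(f3[, 5:8, 1:4]))
  expect_error(patchify(array(0, c(2, 9, 8)), 4L), "divisible")
})

test_that("cosine distances match hand values and the scalar oracle", {
  tg <- array(0, c(1, 2, 2))
  tg[1, 1, ] <- c(1, 1)
  tg[1, 2, ] <- c(0, 3)
  patches <- rbind(c(1, 0), c(2, 2))
  d <- compute_distances(patches, tg)
  expect_equal(d[1, 1, 1], 0.70711, tolerance = 1e-5)
  expect_equal(d[1, 2, 1], 1.0, tolerance = 1e-12)   # equal up to + scale
  expect_equal(d[1, 1, 2], 0.0, tolerance = 1e-12)   # orthogonal
  set.seed(2)
  for (trial in 1:10) {
    n <- sample(2:8, 1); K <- sample(2:4, 1); dd <- sample(3:6, 1)
    pts <- matrix(rnorm(n * dd), n, dd)
    tgs <- array(rnorm(2 * K * dd), c(2, K, dd))
    expect_equal(compute_distances(pts, tgs), oracle_distances(pts, tgs),
                 tolerance = 1e-6)
  }
  # all entries in [-1, 1]
  expect_true(all(abs(compute_distances(matrix(rnorm(40), 8, 5),
                                        array(rnorm(30), c(2, 3, 5)))) <= 1 + 1e-12))
})

test_that("logits collapse at lambda = 0 and match hand evaluation", {
  set.seed(3)
  dist <- array(runif(2 * 5 * 3, -1, 1), c(2, 5, 3))
  w <- matrix(runif(6), 2, 3)
  expect_equal(compute_logits(dist, w, 0), rowSums(w) * 5)
  # single patch, single target, dist 1, w 1, lambda ln 2 -> exp(2 ln 2) = 4
  expect_equal(compute_logits(array(1, c(1, 1, 1)), matrix(1, 1, 1), log(2)),
               4.0)
  # doubling one w entry raises exactly that class's logit
  l0 <- compute_logits(dist, w, 0.5)
  w2 <- w; w2[2, 1] <- 2 * w2[2, 1]
  l1 <- compute_logits(dist, w2, 0.5)
  expect_equal(l1[1], l0[1])
  expect_gt(l1[2], l0[2])
  expect_error(compute_logits(dist, w, -1), "nonnegative")
  # monotone in any single distance entry when w, lambda > 0
  dist2 <- dist; dist2[1, 3, 2] <- dist2[1, 3, 2] + 0.05
  expect_gt(compute_logits(dist2, w, 0.5)[1], l0[1] * 0 + compute_logits(dist, w, 0.5)[1])
})

test_that("label-smoothed loss matches the direct formula", {
  expect_equal(classification_loss(c(1, 1), 1, smoothing = 0), log(2))
  expect_equal(classification_loss(c(1, 1), 2, smoothing = 0.15), log(2))
  expect_equal(classification_loss(c(10, 0), 1, smoothing = 0.15),
               oracle_ce(c(10, 0), 1, 0.15))
  expect_equal(classification_loss(c(10, 0), 1, smoothing = 0.15), 0.75,
               tolerance = 1e-3)
  # smoothing penalizes confident correct predictions
  expect_lte(classification_loss(c(10, 0), 1, smoothing = 0),
             classification_loss(c(10, 0), 1, smoothing = 0.15))
  expect_error(classification_loss(c(1, 2), 3), "outside")
  expect_error(classification_loss(c(1, 2), "stroma"), "outside")
})

test_that("vectorized distance/logit/loss chain equals the triple loop", {
  set.seed(4)
  for (trial in 1:10) {
    n <- sample(2:8, 1); K <- sample(2:4, 1); dd <- sample(4:8, 1)
    pts <- matrix(rnorm(n * dd), n, dd)
    tgs <- array(rnorm(2 * K * dd), c(2, K, dd))
    w <- matrix(runif(2 * K), 2, K)
    lam <- runif(1, 0, 1.5)
    dist <- compute_distances(pts, tgs)
    lg <- compute_logits(dist, w, lam)
    expect_equal(lg, oracle_logits(oracle_distances(pts, tgs), w, lam),
                 tolerance = 1e-6)
    expect_equal(classification_loss(lg, 1, 0.15), oracle_ce(lg, 1, 0.15),
                 tolerance = 1e-9)
  }
})

test_that("positive rescaling of patches leaves the whole chain invariant", {
  set.seed(5)
  pts <- matrix(rnorm(4 * 6), 4, 6)
  tgs <- array(rnorm(2 * 3 * 6), c(2, 3, 6))
  w <- matrix(runif(6), 2, 3)
  pts2 <- pts
  pts2[2, ] <- 3.7 * pts2[2, ]
  d1 <- compute_distances(pts, tgs); d2 <- compute_distances(pts2, tgs)
  expect_equal(d1, d2, tolerance = 1e-12)
  expect_equal(compute_logits(d1, w, 0.7), compute_logits(d2, w, 0.7))
  tgs2 <- tgs; tgs2[1, 2, ] <- 0.01 * tgs2[1, 2, ]
  expect_equal(d1, compute_distances(pts, tgs2), tolerance = 1e-12)
})

test_that("target generation is deterministic and seed-local", {
  items <- toy_align_items(1L, seed0 = 21L)
  m <- toy_alignnet(items, epochs = 0L, ae_steps = 2L)
  t1 <- generate_targets(m, "HE")
  t2 <- generate_targets(m, "HE")
  expect_identical(t1, t2)
  expect_identical(dim(t1), c(2L, 4L, 128L))
  # perturbing seed (cls 1, k 1) changes only that target row
  m2 <- m
  m2$params$seeds[1, 1, ] <- m2$params$seeds[1, 1, ] + 0.1
  t3 <- generate_targets(m2, "HE")
  expect_false(isTRUE(all.equal(t1[1, 1, ], t3[1, 1, ])))
  expect_equal(t1[2, , ], t3[2, , ])
  expect_equal(t1[1, 2, ], t3[1, 2, ])
  # modality stacks differ: same seeds, different targets
  expect_false(isTRUE(all.equal(generate_targets(m, "HE"),
                                generate_targets(m, "RA"))))
})

test_that("training honors accumulation count, modality check and epochs=0", {
  items <- toy_align_items(2L, seed0 = 31L)
  m <- toy_alignnet(items, epochs = 0L, ae_steps = 2L)
  m0 <- train_alignnet(m, list(train = items), epochs = 0L)
  expect_identical(m0$updates, 0L)
  expect_identical(nrow(m0$metrics), 0L)
  expect_identical(m0$params, m$params)
  # 8 items in 2 epochs = 16 samples, accum 8 -> ceil(16/8) = 2 updates
  m$config$accum <- 8L
  m2 <- train_alignnet(m, list(train = items), epochs = 2L, seed = 1L)
  expect_identical(m2$updates, 2L)
  # partial accumulation flushes: accum 5 -> ceil(16/5) = 4
  m$config$accum <- 5L
  m3 <- train_alignnet(m, list(train = items), epochs = 2L, seed = 1L)
  expect_identical(m3$updates, 4L)
  he_only <- Filter(function(it) it$modality == "HE", items)
  expect_error(train_alignnet(m, list(train = he_only), epochs = 1L),
               "both modalities")
})

test_that("highlight overlay ranks pairs by similarity and marks windows", {
  items <- toy_align_items(1L, seed0 = 41L)
  m <- toy_alignnet(items, epochs = 0L, ae_steps = 2L)
  img <- items[[1]]$x  # 16x16 H&E phantom -> 1 patch, 2*4 = 8 pairs
  out <- highlight_regions(m, img, 8L)
  expect_true(all(out$mask))
  expect_identical(nrow(out$pairs), 8L)
  expect_true(all(diff(out$pairs$similarity) <= 0))
  out2 <- highlight_regions(m, img, 2L)
  expect_identical(out2$pairs$similarity, out$pairs$similarity[1:2])
  expect_error(highlight_regions(m, img, 9L), "exceeds")
})
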
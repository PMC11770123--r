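# Synthetic co-registered phantom generation.

test_that("phantom generation is deterministic and validates its spec", {
  sp <- phantom_spec("TSCC", canvas_um = c(16, 16), bands = 8L,
                     noise_sd = 0.05, rng_seed = 7L)
  a <- generate_sample(sp)
  b <- generate_sample(sp)
  expect_identical(a$rgb, b$rgb)
  expect_identical(a$cube, b$cube)
  expect_error(phantom_spec("TSCC", canvas_um = c(4, 16)), "at least 8")
  expect_error(phantom_spec("TSCC", noise_sd = -1), "nonnegative")
  expect_error(phantom_spec("TSCC", bands = 8L,
                            spectral_signature = rep(0.1, 5)), "length")
})

test_that("degenerate phantom is pure background and pure signature", {
  sig <- class_signature("normal", 8L)
  sp <- phantom_spec("normal", canvas_um = c(12, 10), bands = 8L,
                     n_texture_elements = 0L, noise_sd = 0, rng_seed = 1L)
  s <- generate_sample(sp)
  expect_identical(dim(s$rgb), c(3L, 10L, 12L))
  for (ch in 1:3) expect_length(unique(as.vector(s$rgb[ch, , ])), 1L)
  for (px in seq_len(prod(dim(s$cube)[2:3]))) {
    ij <- arrayInd(px, dim(s$cube)[2:3])
    expect_equal(s$cube[, ij[1], ij[2]], sig)
  }
})

test_that("both modalities deviate from background exactly on the planted mask", {
  sp <- phantom_spec("TSCC", canvas_um = c(20, 20), bands = 6L,
                     n_texture_elements = 5L, noise_sd = 0, rng_seed = 3L)
  s <- generate_sample(sp)
  bg <- generate_sample(phantom_spec("TSCC", canvas_um = c(20, 20), bands = 6L,
                                     n_texture_elements = 0L, noise_sd = 0,
                                     rng_seed = 3L))
  rgb_dev <- apply(abs(s$rgb - bg$rgb), c(2, 3), max) > 0
  cube_dev <- apply(abs(s$cube - bg$cube), c(2, 3), max) > 0
  expect_true(any(s$element_mask))
  expect_identical(rgb_dev, s$element_mask)
  expect_identical(cube_dev, s$element_mask)
})

test_that("orthogonal class spectra give perfect nearest-centroid separation", {
  bands <- 8L
  sigA <- c(rep(0.6, 4), rep(0.0, 4))
  sigB <- c(rep(0.0, 4), rep(0.6, 4))
  mean_spec <- function(cube) rowMeans(matrix(cube, dim(cube)[1]))
  centroid_acc <- function(noise) {
    specs <- list(); labs <- integer(0)
    for (ci in 1:2) for (i in 1:10) {
      sp <- phantom_spec(c("TSCC", "normal")[ci], canvas_um = c(12, 12),
                         bands = bands,
                         spectral_signature = if (ci == 1) sigA else sigB,
                         noise_sd = noise, rng_seed = 100L * ci + i)
      specs <- c(specs, list(mean_spec(generate_sample(sp)$cube)))
      labs <- c(labs, ci)
    }
    pred <- vapply(specs, function(v)
      which.min(c(sum((v - sigA)^2), sum((v - sigB)^2))), 0L)
    mean(pred == labs)
  }
  expect_equal(centroid_acc(0.02), 1.0)
  # separability degrades (weakly) as noise grows, by the same oracle
  expect_gte(centroid_acc(0.02), centroid_acc(3))
})

test_that("dataset generation writes a reproducible patient-level manifest", {
  d1 <- withr::local_tempdir()
  m1 <- generate_dataset(2L, c(1, 0, 0), out_dir = d1, rng_seed = 5L,
                         bands = 6L, canvas_um = c(12, 12))
  expect_identical(nrow(m1$records), 4L)
  expect_true(all(m1$records$split == "train"))
  expect_true(all(file.exists(m1$records$rgb_path)))
  expect_true(all(file.exists(m1$records$cube_path)))
  expect_false(any(duplicated(m1$records$sample_id)))
  # re-run with the same seed: identical manifest
  m2 <- generate_dataset(2L, c(1, 0, 0), out_dir = d1, rng_seed = 5L,
                         bands = 6L, canvas_um = c(12, 12))
  expect_identical(m1$records, m2$records)
  # cube round-trips through the TIFF + sidecar container
  cube <- read_cube(m1$records$cube_path[1])
  sp <- phantom_spec("TSCC", canvas_um = c(12, 12), bands = 6L,
                     rng_seed = (5L %% 100000L) * 10000L + 1L)
  expect_equal(cube, generate_sample(sp)$cube, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_length(attr(cube, "wavenumbers"), 6L)
})

test_that("split emulating the 12 + 3 patient cohorts yields 24/6 records", {
  d <- withr::local_tempdir()
  m <- generate_dataset(15L, c(0.8, 0, 0.2), out_dir = d, rng_seed = 2L,
                        bands = 6L, canvas_um = c(12, 12))
  expect_identical(sum(m$records$split %in% c("train", "val")), 24L)
  expect_identical(sum(m$records$split == "test"), 6L)
  # splits disjoint by sample id
  by_split <- split(m$records$sample_id, m$records$split)
  expect_length(Reduce(intersect, by_split), 0L)
  expect_error(generate_dataset(2L, c(0.5, 0.3, 0.2), out_dir = d), "too small")
})
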
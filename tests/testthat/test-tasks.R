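test_that("synthetic generator is deterministic and prototype-structured", {
  spec <- synthetic_spec(n_prototypes = 3, image_shape = c(6, 6),
                         flip_noise = 0, n_per_class = 4, seed = 13)
  ds <- generate_synthetic_dataset(spec)
  expect_equal(dim(ds$images), c(12, 36))
  expect_equal(ds$labels, rep(0:2, 4))
  # zero noise: every sample equals its prototype
  expect_equal(ds$images, ds$prototypes[ds$labels + 1, ])
  # determinism
  expect_identical(generate_synthetic_dataset(spec)$images, ds$images)
  # prototype separation constraint
  d <- as.matrix(dist(ds$prototypes, method = "manhattan")) / 36
  expect_gte(min(d[upper.tri(d)]), 0.25)
})

test_that("flip noise produces the binomial Hamming distance", {
  spec <- synthetic_spec(n_prototypes = 2, image_shape = c(28, 28),
                         flip_noise = 0.1, n_per_class = 150, seed = 19)
  ds <- generate_synthetic_dataset(spec)
  ham <- rowSums(abs(ds$images - ds$prototypes[ds$labels + 1, ]))
  # mean 784 * 0.1 = 78.4, sd of the mean of 300 binomials
  se <- sqrt(784 * 0.1 * 0.9 / nrow(ds$images))
  expect_lt(abs(mean(ham) - 78.4), 3 * se)
  # within-class similarity beats between-class
  sim <- cosine_similarity_matrix(ds$images)$matrix
  same <- outer(ds$labels, ds$labels, "==") & !diag(TRUE, nrow(sim))
  expect_gt(mean(sim[same]), mean(sim[!same & !diag(TRUE, nrow(sim))]))
})

test_that("completion bars have the stated width, value and locality", {
  ds <- tiny_dataset(hw = c(28, 28), n_per_class = 4, flip_noise = 0)
  for (case in list(list(d = 1.0, w = 14), list(d = 0.2, w = 3),
                    list(d = 0.6, w = 8))) {
    out <- make_completion_set(ds, case$d)
    expect_equal(unique(out$geometry$width), case$w)
    img <- matrix(out$images[1, ], 28, 28)       # position cycle starts "up"
    expect_true(all(img[seq_len(case$w), ] == 0.5))
    # rest untouched
    orig <- matrix(ds$images[1, ], 28, 28)
    expect_identical(img[(case$w + 1):28, ], orig[(case$w + 1):28, ])
  }
  # positions cycle over quarters
  out <- make_completion_set(ds, 0.4)
  expect_equal(out$geometry$position[1:4], c("up", "down", "left", "right"))
  expect_error(make_completion_set(tiny_dataset(hw = c(8, 2)), 1.0), "width")
})

test_that("rivalry pairing is reverse-order within blocks", {
  expect_equal(rival_index(8), 242)
  expect_equal(rival_index(242), 8)
  expect_equal(rival_index(125), 125)      # documented self-pairing midpoint
  expect_equal(rival_index(250), 250)      # wrapped end case
  expect_equal(rival_index(3, block_size = 10), 7)

  ds <- tiny_dataset(hw = c(8, 8), n_per_class = 5, flip_noise = 0)
  out <- suppressWarnings(make_rivalry_set(ds, 1.0, block_size = 10))
  expect_equal(out$geometry$rival[3], 7)
  # bar region equals the rival's pixels, rest untouched
  img <- matrix(out$images[3, ], 8, 8)
  orig <- matrix(ds$images[3, ], 8, 8)
  riv <- matrix(ds$images[7, ], 8, 8)
  expect_identical(img[, 1:4], riv[, 1:4])     # position cycle: index 3 -> left
  expect_identical(img[, 5:8], orig[, 5:8])
  expect_warning(make_rivalry_set(ds, 0.4, block_size = 10), "self-rivalry")
})

test_that("distortion kinds split the set and scale with difficulty", {
  ds <- tiny_dataset(hw = c(28, 28), n_per_class = 10, flip_noise = 0)
  out <- make_distortion_set(ds, 1.0, seed = 99)
  expect_equal(as.vector(table(out$geometry$kind)[c("noise", "grid",
                                                    "clutter", "deletion",
                                                    "occlusion")]),
               rep(4, 5))
  # determinism per seed
  out2 <- make_distortion_set(ds, 1.0, seed = 99)
  expect_identical(out$images, out2$images)

  # occlusion at D = 1: one 14x14 gray square
  occ_idx <- which(out$geometry$kind == "occlusion")[1]
  img <- matrix(out$images[occ_idx, ], 28, 28)
  expect_equal(sum(img == 0.5), 14 * 14)

  # noise at D = 1: ~ 78.4 expected flips per image
  noise_idx <- which(out$geometry$kind == "noise")
  flips <- rowSums(out$images[noise_idx, , drop = FALSE] !=
                   ds$images[noise_idx, , drop = FALSE])
  expect_lt(abs(mean(flips) - 78.4), 3 * sqrt(784 * 0.1 * 0.9 / length(flips)))

  # labels and untouched kinds preserved
  expect_identical(out$labels, ds$labels)
})

test_that("IDX files round-trip and reject malformed input precisely", {
  ds <- tiny_dataset(hw = c(5, 5), n_per_class = 1, flip_noise = 0)
  img_path <- tempfile(fileext = ".idx")
  lab_path <- tempfile(fileext = ".idx")
  write_idx(ds, img_path, lab_path)
  back <- load_idx(img_path, lab_path)
  expect_equal(back$shape, c(5, 5))
  expect_equal(back$images, ds$images)         # 0/1 survives quantization
  expect_equal(back$labels, ds$labels)

  # bad magic
  bad <- tempfile()
  writeBin(c(123L, 1L, 2L, 2L), bad, size = 4, endian = "big")
  expect_error(load_idx(bad), "magic")

  # truncated payload names expected vs actual byte counts
  trunc <- tempfile()
  con <- file(trunc, "wb")
  writeBin(c(2051L, 2L, 2L, 2L), con, size = 4, endian = "big")
  writeBin(as.raw(1:5), con)                    # should be 8 bytes
  close(con)
  expect_error(load_idx(trunc), "expected 8 bytes.*got 5")
})

test_that("task manifests carry id, task, difficulty and geometry", {
  ds <- tiny_dataset(hw = c(8, 8), n_per_class = 4, flip_noise = 0)
  out <- make_completion_set(ds, 0.6)
  man <- task_manifest(out)
  expect_equal(nrow(man), 8)
  expect_true(all(c("id", "task", "difficulty", "label",
                    "position", "width") %in% names(man)))
  expect_equal(unique(man$task), "completion")
})

test_that("split_dataset keeps prototypes shared and classes balanced", {
  ds <- tiny_dataset(n_prototypes = 4, n_per_class = 10)
  sp <- split_dataset(ds, 32)
  expect_equal(nrow(sp$train$images), 32)
  expect_equal(nrow(sp$test$images), 8)
  expect_equal(as.vector(table(sp$train$labels)), rep(8, 4))
  expect_equal(as.vector(table(sp$test$labels)), rep(2, 4))
})
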
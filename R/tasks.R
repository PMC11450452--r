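# Synthetic prototype datasets, the three associative-memory test-set
# corruptions (completion / rivalry / distortion), and IDX file IO.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

round_half_up <- function(x) floor(x + 0.5)

#' Specification for a synthetic prototype dataset
#'
#' The generator emulates a categorized binary image dataset: `K` random
#' binary prototypes plus independent pixel-flip noise per sample.  It is
#' the package's download-free stand-in for a real image benchmark.
#'
#' @param n_prototypes Number of prototype classes.
#' @param image_shape `c(H, W)` image size in pixels.
#' @param flip_noise Per-pixel flip probability for the samples.
#' @param n_per_class Samples generated per class.
#' @param min_separation Minimum pairwise prototype Hamming distance, as
#'   a fraction of the pixel count (prototypes are redrawn until met).
#' @param seed Optional RNG seed; the generator is deterministic per seed.
#' @export
synthetic_spec <- function(n_prototypes = 8, image_shape = c(28, 28),
                           flip_noise = 0.1, n_per_class = 100,
                           min_separation = 0.25, seed = NULL) {
  stopifnot(n_prototypes >= 1, length(image_shape) == 2,
            flip_noise >= 0, flip_noise < 0.5, n_per_class >= 1)
  structure(list(n_prototypes = n_prototypes, image_shape = image_shape,
                 flip_noise = flip_noise, n_per_class = n_per_class,
                 min_separation = min_separation, seed = seed),
            class = "bcpnn_synthetic_spec")
}

#' Generate a synthetic prototype-structured dataset
#'
#' Draws binary prototypes uniformly at random (redrawing until all
#' pairs differ in at least `min_separation` of the pixels), then emits
#' each sample as its prototype XOR independent Bernoulli pixel flips.
#' Class labels are 0-based.  Samples are interleaved across classes
#' (pattern `i` has label `(i-1) mod K`), so any prefix of the dataset
#' is class-balanced.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `bcpnn_dataset`: `images` (`N x H*W` matrix,
#'   column-major pixel order, values 0/1), `labels` (0-based integers),
#'   `prototypes` (`K x H*W`), `shape`.
#' @export
generate_synthetic_dataset <- function(spec) {
  with_seed(spec$seed, {
    p <- prod(spec$image_shape)
    k <- spec$n_prototypes
    for (attempt in 1:100) {
      proto <- matrix(as.numeric(runif(k * p) < 0.5), k, p)
      if (k == 1) break
      d <- as.matrix(stats::dist(proto, method = "manhattan")) / p
      if (min(d[upper.tri(d)]) >= spec$min_separation) break
      if (attempt == 100)
        stop("could not satisfy the prototype separation constraint")
    }
    n <- k * spec$n_per_class
    labels <- rep(seq_len(k) - 1L, length.out = n)
    flips <- matrix(as.numeric(runif(n * p) < spec$flip_noise), n, p)
    images <- abs(proto[labels + 1L, , drop = FALSE] - flips)  # XOR
    structure(list(images = images, labels = labels, prototypes = proto,
                   shape = spec$image_shape), class = "bcpnn_dataset")
  })
}

bar_mask <- function(h, w, width, position) {
  m <- matrix(FALSE, h, w)
  switch(position,
         up    = m[seq_len(width), ] <- TRUE,
         down  = m[h - seq_len(width) + 1L, ] <- TRUE,
         left  = m[, seq_len(width)] <- TRUE,
         right = m[, w - seq_len(width) + 1L] <- TRUE,
         stop("unknown bar position: ", position))
  m
}

task_result <- function(images, labels, shape, task, difficulty, geometry) {
  structure(list(images = images, labels = labels, shape = shape,
                 task = task, difficulty = difficulty, geometry = geometry),
            class = "bcpnn_dataset")
}

#' Pattern-completion test set
#'
#' Places a gray occluding bar (intensity exactly 0.5, i.e. chance-level
#' pixel drive) of width `round(D * H/2)` pixels flush against one image
#' edge; the four edges are cycled so each covers a quarter of the set.
#' At difficulty `D = 1` on 28x28 images the bar is 14 pixels wide (half
#' the image).
#'
#' @param dataset A `bcpnn_dataset` (clean images).
#' @param difficulty Difficulty level `D`, normally in
#'   `{0.2, 0.4, 0.6, 0.8, 1}`.
#' @param positions Edge cycle (default `up, down, left, right`).
#' @return A `bcpnn_dataset` whose `geometry` records per-pattern bar
#'   position and width.
#' @export
make_completion_set <- function(dataset, difficulty,
                                positions = c("up", "down", "left", "right")) {
  stopifnot(difficulty > 0, difficulty <= 1)
  h <- dataset$shape[1]; w <- dataset$shape[2]
  width <- round_half_up(difficulty * h / 2)
  if (width >= min(h, w)) stop("bar width exceeds image size")
  n <- nrow(dataset$images)
  pos <- positions[(seq_len(n) - 1L) %% length(positions) + 1L]
  images <- dataset$images
  for (i in seq_len(n)) {
    img <- matrix(images[i, ], h, w)
    img[bar_mask(h, w, width, pos[i])] <- 0.5
    images[i, ] <- as.vector(img)
  }
  task_result(images, dataset$labels, dataset$shape, "completion",
              difficulty, data.frame(position = pos, width = width))
}

#' Perceptual-rivalry test set
#'
#' Replaces a bar of width `round(D * H/2)` at one edge with the
#' corresponding pixels of a rival image.  The rival of the `i`-th image
#' (1-based within a block of `block_size` patterns) is image
#' `block_size - i` of the same block — a deterministic reverse-order
#' pairing (image 8 gets image 242 for 250-blocks).  The midpoint
#' `i = block_size/2` and the last image pair with themselves; both are
#' emitted with a warning.
#'
#' @inheritParams make_completion_set
#' @param block_size Pairing block length (default 250).
#' @return A `bcpnn_dataset`; `geometry` records position, width and
#'   rival index.
#' @export
make_rivalry_set <- function(dataset, difficulty,
                             positions = c("up", "down", "left", "right"),
                             block_size = 250) {
  stopifnot(difficulty > 0, difficulty <= 1)
  n <- nrow(dataset$images)
  if (n < 2) stop("rivalry needs at least 2 images per block")
  block_size <- min(block_size, n)
  h <- dataset$shape[1]; w <- dataset$shape[2]
  width <- round_half_up(difficulty * h / 2)
  if (width >= min(h, w)) stop("bar width exceeds image size")
  pos <- positions[(seq_len(n) - 1L) %% length(positions) + 1L]
  block <- (seq_len(n) - 1L) %/% block_size
  within <- (seq_len(n) - 1L) %% block_size + 1L
  rival_within <- rival_index(within, block_size)
  rival <- pmin(block * block_size + rival_within, n)
  if (any(rival == seq_len(n)))
    warning("self-rivalry at block midpoint/end: images ",
            paste(which(rival == seq_len(n)), collapse = ", "))
  images <- dataset$images
  for (i in seq_len(n)) {
    img <- matrix(dataset$images[i, ], h, w)
    riv <- matrix(dataset$images[rival[i], ], h, w)
    m <- bar_mask(h, w, width, pos[i])
    img[m] <- riv[m]
    images[i, ] <- as.vector(img)
  }
  task_result(images, dataset$labels, dataset$shape, "rivalry", difficulty,
              data.frame(position = pos, width = width, rival = rival))
}

#' Reverse-order rival pairing
#'
#' `rival(i) = block_size - i` with 1-based indices within a block; the
#' zero that arises at `i = block_size` is mapped back to `block_size`
#' (self-pairing, like the midpoint).
#'
#' @param i 1-based index (vectorized) within a block.
#' @param block_size Block length (default 250).
#' @export
rival_index <- function(i, block_size = 250) {
  r <- block_size - i
  r[r < 1] <- block_size
  r
}

random_lines <- function(h, w, n_lines, value, img) {
  for (k in seq_len(n_lines)) {
    if (runif(1) < 0.5) img[sample.int(h, 1), ] <- value
    else img[, sample.int(w, 1)] <- value
  }
  img
}

#' Distortion-resistance test set
#'
#' Splits the set into five equal parts (cycled by pattern index), one
#' per distortion kind:
#' * `noise` — independent pixel flips with probability `0.1 * D`;
#' * `grid` — gray (0.5) grid lines every `ceil(7 / D)` pixels;
#' * `clutter` — `ceil(10 * D)` random full-length black (intensity 1)
#'   lines;
#' * `deletion` — `ceil(10 * D)` random white (intensity 0) lines;
#' * `occlusion` — a gray square of side `round(D * H/2)` at a random
#'   position.
#'
#' The magnitude constants are package choices scaled so `D = 1` is a
#' severe corruption; all are overridable.
#'
#' @inheritParams make_completion_set
#' @param seed RNG seed making the random geometry reproducible.
#' @param flip_prob,grid_spacing,n_lines,occluder_side Overrides for the
#'   per-kind magnitudes (each a function of `D` by default).
#' @return A `bcpnn_dataset`; `geometry` records the kind per pattern.
#' @export
make_distortion_set <- function(dataset, difficulty, seed = NULL,
                                flip_prob = 0.1 * difficulty,
                                grid_spacing = ceiling(7 / difficulty),
                                n_lines = ceiling(10 * difficulty),
                                occluder_side = NULL) {
  stopifnot(difficulty > 0, difficulty <= 1)
  h <- dataset$shape[1]; w <- dataset$shape[2]
  if (is.null(occluder_side)) occluder_side <- round_half_up(difficulty * h / 2)
  kinds <- c("noise", "grid", "clutter", "deletion", "occlusion")
  n <- nrow(dataset$images)
  kind <- kinds[(seq_len(n) - 1L) %% 5L + 1L]
  with_seed(seed, {
    images <- dataset$images
    for (i in seq_len(n)) {
      img <- matrix(images[i, ], h, w)
      img <- switch(kind[i],
        noise = {
          f <- matrix(runif(h * w) < flip_prob, h, w)
          img[f] <- 1 - img[f]
          img
        },
        grid = {
          idx_r <- seq(grid_spacing, h, by = grid_spacing)
          idx_c <- seq(grid_spacing, w, by = grid_spacing)
          img[idx_r, ] <- 0.5; img[, idx_c] <- 0.5
          img
        },
        clutter = random_lines(h, w, n_lines, 1, img),
        deletion = random_lines(h, w, n_lines, 0, img),
        occlusion = {
          side <- min(occluder_side, h, w)
          r0 <- sample.int(h - side + 1L, 1); c0 <- sample.int(w - side + 1L, 1)
          img[r0:(r0 + side - 1L), c0:(c0 + side - 1L)] <- 0.5
          img
        })
      images[i, ] <- as.vector(img)
    }
    task_result(images, dataset$labels, dataset$shape, "distortion",
                difficulty, data.frame(kind = kind))
  })
}

#' Split a dataset into train and test parts
#'
#' Takes the first `n_train` patterns as the training set and the rest
#' as the test set.  Because [generate_synthetic_dataset()] interleaves
#' classes, both parts are class-balanced (when the sizes divide the
#' class count) and share the same prototypes.
#'
#' @param dataset A `bcpnn_dataset`.
#' @param n_train Number of leading patterns for the training part.
#' @return List with `train` and `test` datasets.
#' @export
split_dataset <- function(dataset, n_train) {
  n <- nrow(dataset$images)
  stopifnot(n_train >= 1, n_train < n)
  list(train = subset_dataset(dataset, seq_len(n_train)),
       test = subset_dataset(dataset, (n_train + 1):n))
}

# ---------------------------------------------------------------------------
# IDX (MNIST-style) binary format

IDX_MAGIC_IMAGES <- 2051L  # 0x00000803
IDX_MAGIC_LABELS <- 2049L  # 0x00000801

#' Read an IDX image/label file pair
#'
#' IDX is the big-endian binary format of the MNIST distribution: a magic
#' number (0x803 for ubyte images with 3 dims, 0x801 for ubyte labels),
#' big-endian dimension sizes, then the raw bytes.  Intensities are
#' rescaled to `[0, 1]`.
#'
#' @param images_path Path to an images IDX file.
#' @param labels_path Optional path to the matching labels file; counts
#'   are cross-validated.
#' @return A `bcpnn_dataset` (`images` as `N x H*W` in `[0,1]`, `labels`
#'   or NULL, `shape`).
#' @export
load_idx <- function(images_path, labels_path = NULL) {
  con <- file(images_path, "rb"); on.exit(close(con), add = TRUE)
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (!identical(magic, IDX_MAGIC_IMAGES))
    stop(sprintf("bad image magic 0x%08x at offset 0 (expected 0x%08x)",
                 magic, IDX_MAGIC_IMAGES))
  dims <- readBin(con, "integer", 3, size = 4, endian = "big")
  n <- dims[1]; h <- dims[2]; w <- dims[3]
  raw <- readBin(con, "raw", n * h * w)
  if (length(raw) != n * h * w)
    stop(sprintf("truncated image payload: expected %d bytes after offset 16, got %d",
                 n * h * w, length(raw)))
  px <- as.integer(raw) / 255
  # stored row-major per image; convert to the package's column-major order
  images <- matrix(0, n, h * w)
  for (i in seq_len(n)) {
    img <- matrix(px[((i - 1) * h * w + 1):(i * h * w)], h, w, byrow = TRUE)
    images[i, ] <- as.vector(img)
  }
  labels <- NULL
  if (!is.null(labels_path)) {
    lcon <- file(labels_path, "rb"); on.exit(close(lcon), add = TRUE)
    lmagic <- readBin(lcon, "integer", 1, size = 4, endian = "big")
    if (!identical(lmagic, IDX_MAGIC_LABELS))
      stop(sprintf("bad label magic 0x%08x at offset 0 (expected 0x%08x)",
                   lmagic, IDX_MAGIC_LABELS))
    ln <- readBin(lcon, "integer", 1, size = 4, endian = "big")
    if (ln != n)
      stop(sprintf("label count %d does not match image count %d", ln, n))
    lraw <- readBin(lcon, "raw", ln)
    if (length(lraw) != ln)
      stop(sprintf("truncated label payload: expected %d bytes after offset 8, got %d",
                   ln, length(lraw)))
    labels <- as.integer(lraw)
  }
  structure(list(images = images, labels = labels, shape = c(h, w)),
            class = "bcpnn_dataset")
}

#' Write a dataset to IDX files
#'
#' Intensities are quantized to bytes (`round(u * 255)`); the inverse of
#' [load_idx()] up to that quantization.
#'
#' @param dataset A `bcpnn_dataset`.
#' @param images_path,labels_path Output paths (`labels_path` optional).
#' @export
write_idx <- function(dataset, images_path, labels_path = NULL) {
  h <- dataset$shape[1]; w <- dataset$shape[2]
  n <- nrow(dataset$images)
  con <- file(images_path, "wb"); on.exit(close(con), add = TRUE)
  writeBin(as.integer(c(IDX_MAGIC_IMAGES, n, h, w)), con, size = 4,
           endian = "big")
  for (i in seq_len(n)) {
    img <- matrix(dataset$images[i, ], h, w)
    writeBin(as.raw(round(t(img) * 255)), con)  # row-major on disk
  }
  if (!is.null(labels_path)) {
    lcon <- file(labels_path, "wb"); on.exit(close(lcon), add = TRUE)
    writeBin(as.integer(c(IDX_MAGIC_LABELS, n)), lcon, size = 4,
             endian = "big")
    writeBin(as.raw(dataset$labels), lcon)
  }
  invisible(c(images_path, labels_path))
}

#' Task-set manifest table
#'
#' One row per pattern: id, task, difficulty, label and the geometry
#' columns of the generator, suitable for writing as CSV alongside
#' exported IDX files.
#'
#' @param dataset A corrupted `bcpnn_dataset`.
#' @return A `data.frame`.
#' @export
task_manifest <- function(dataset) {
  n <- nrow(dataset$images)
  out <- data.frame(id = seq_len(n),
                    task = dataset$task %||% "clean",
                    difficulty = dataset$difficulty %||% NA_real_,
                    label = if (is.null(dataset$labels)) NA else dataset$labels)
  if (!is.null(dataset$geometry)) out <- cbind(out, dataset$geometry)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
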
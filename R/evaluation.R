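# Evaluation: Gaussian-kernel rate estimation, cosine similarity and the
# orthogonality ratio, prototype extraction, and the linear readout.

#' Gaussian-kernel firing-rate estimate
#'
#' Convolves a 0/1 spike train (spikes treated as `1/dt` impulses) with
#' a unit-integral Gaussian kernel of width `sigma`; the result is an
#' instantaneous rate in Hz whose time-integral equals the spike count.
#'
#' @param spikes Binary 0/1 vector, one entry per timestep.
#' @param sigma Kernel standard deviation (s), default 20 ms.
#' @param dt Timestep (s).
#' @return Numeric vector of rates (Hz), same length as `spikes`.
#' @export
firing_rate_estimate <- function(spikes, sigma = 0.020, dt = 0.001) {
  stopifnot(sigma > 0, dt > 0, all(spikes %in% c(0, 1)))
  half <- ceiling(4 * sigma / dt)
  t <- (-half:half) * dt
  kernel <- exp(-t^2 / (2 * sigma^2))
  kernel <- kernel / (sum(kernel) * dt)          # integrates to 1
  n <- length(spikes)
  padded <- c(numeric(half), spikes / dt, numeric(half))
  out <- numeric(n)
  for (i in seq_len(n))
    out[i] <- sum(padded[i:(i + 2 * half)] * kernel) * dt
  out
}

#' Pairwise cosine-similarity matrix
#'
#' Rows are patterns, columns features.  Zero rows have similarity 0
#' against everything (including themselves, except the unit diagonal is
#' kept at 1 only for nonzero rows).
#'
#' @param x Numeric `patterns x features` matrix (>= 2 rows).
#' @param labels Optional category labels carried into the result.
#' @return A list of class `bcpnn_similarity`: `matrix`, `labels`.
#' @export
cosine_similarity_matrix <- function(x, labels = NULL) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  nrm <- sqrt(rowSums(x^2))
  safe <- ifelse(nrm > 0, nrm, 1)
  sim <- tcrossprod(x / safe)
  sim[nrm == 0, ] <- 0
  sim[, nrm == 0] <- 0
  structure(list(matrix = sim, labels = labels), class = "bcpnn_similarity")
}

#' Orthogonality ratio
#'
#' Mean within-class off-diagonal similarity divided by the mean
#' off-diagonal similarity over all pairs.  A value of 1 means class
#' identity carries no similarity structure; larger values mean more
#' orthogonalized (class-separated) representations.
#'
#' @param sim A `bcpnn_similarity` (or plain symmetric matrix) with
#'   `labels` covering at least 2 classes.
#' @param labels Labels, if `sim` is a plain matrix.
#' @return A single number, or `NA` with a warning when the overall mean
#'   similarity is zero.
#' @export
orthogonality_ratio <- function(sim, labels = NULL) {
  if (inherits(sim, "bcpnn_similarity")) {
    labels <- labels %||% sim$labels
    sim <- sim$matrix
  }
  stopifnot(!is.null(labels), length(labels) == nrow(sim))
  if (length(unique(labels)) < 2) stop("need at least 2 classes")
  off <- !diag(TRUE, nrow(sim))
  same <- outer(labels, labels, "==") & off
  denom <- mean(sim[off])
  if (denom == 0) {
    warning("overall mean similarity is zero; ratio undefined")
    return(NA_real_)
  }
  mean(sim[same]) / denom
}

#' Extract prototypes from attractor representations
#'
#' Thresholds the pairwise cosine similarities at `s_min` (strictly
#' above) and groups patterns into prototypes as the connected components
#' of the resulting graph — equivalently, single-linkage clusters.  The
#' attraction index of a prototype is its component size.
#'
#' @param x `patterns x features` matrix of attractor representations
#'   (e.g. hidden z-traces at pattern end).
#' @param s_min Similarity threshold in `[0, 1]`.
#' @param reconstructions Optional `patterns x pixels` matrix (e.g.
#'   reconstruction z-traces); per-prototype means are returned.
#' @return A list of class `bcpnn_prototypes`: `s_min`, `n_prototypes`,
#'   `assignment` (component id per pattern), `attraction` (sizes), and
#'   `reconstruction` (`n_prototypes x pixels` or NULL).
#' @export
extract_prototypes <- function(x, s_min, reconstructions = NULL) {
  stopifnot(s_min >= 0, s_min <= 1)
  sim <- cosine_similarity_matrix(x)$matrix
  n <- nrow(sim)
  adj <- sim > s_min
  diag(adj) <- FALSE
  # connected components by repeated BFS
  comp <- integer(n)
  k <- 0L
  for (v in seq_len(n)) {
    if (comp[v] != 0L) next
    k <- k + 1L
    frontier <- v
    comp[v] <- k
    while (length(frontier)) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- k
      frontier <- nb
    }
  }
  attraction <- tabulate(comp, k)
  recon <- NULL
  if (!is.null(reconstructions)) {
    stopifnot(nrow(reconstructions) == n)
    recon <- rowsum(reconstructions, comp) / attraction
  }
  structure(list(s_min = s_min, n_prototypes = k, assignment = comp,
                 attraction = attraction, reconstruction = recon),
            class = "bcpnn_prototypes")
}

#' Multinomial logistic readout trained with Adam
#'
#' A linear softmax classifier over K classes trained by minibatch Adam
#' on the cross-entropy loss; the standard probe for class separability
#' of learned representations.  Defaults: `alpha = 1e-3`,
#' `beta1 = 0.9`, `beta2 = 0.999`, `epsilon = 1e-7`, minibatch 64,
#' 10 epochs.
#'
#' @param x `patterns x features` training matrix.
#' @param y 0-based integer class labels.
#' @param n_classes Number of classes (default `max(y) + 1`).
#' @param alpha,beta1,beta2,epsilon Adam hyperparameters.
#' @param batch_size,n_epochs Minibatch size and passes over the data.
#' @param seed RNG seed for shuffling (deterministic per seed).
#' @return A `bcpnn_readout` with weight matrix `W`
#'   (`features+1 x K`, last row the intercept).
#' @export
train_linear_readout <- function(x, y, n_classes = max(y) + 1L,
                                 alpha = 1e-3, beta1 = 0.9, beta2 = 0.999,
                                 epsilon = 1e-7, batch_size = 64,
                                 n_epochs = 10, seed = NULL) {
  stopifnot(is.matrix(x), length(y) == nrow(x), all(y >= 0))
  if (length(unique(y)) < 2) stop("need at least 2 classes to train a readout")
  k <- as.integer(n_classes)
  n <- nrow(x); p <- ncol(x)
  with_seed(seed, {
    w <- matrix(0, p + 1, k)
    m <- v <- matrix(0, p + 1, k)
    t_step <- 0
    xb_all <- cbind(x, 1)
    yk <- diag(k)[y + 1L, , drop = FALSE]
    for (ep in seq_len(n_epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        xb <- xb_all[idx, , drop = FALSE]
        logits <- xb %*% w
        logits <- logits - apply(logits, 1, max)
        prob <- exp(logits); prob <- prob / rowSums(prob)
        grad <- crossprod(xb, prob - yk[idx, , drop = FALSE]) / length(idx)
        t_step <- t_step + 1
        m <- beta1 * m + (1 - beta1) * grad
        v <- beta2 * v + (1 - beta2) * grad^2
        mh <- m / (1 - beta1^t_step)
        vh <- v / (1 - beta2^t_step)
        w <- w - alpha * mh / (sqrt(vh) + epsilon)
      }
    }
    structure(list(W = w, n_classes = k), class = "bcpnn_readout")
  })
}

#' Predict classes with a trained readout
#'
#' @param object A `bcpnn_readout`.
#' @param newdata `patterns x features` matrix.
#' @param ... Unused.
#' @return 0-based predicted labels.
#' @export
predict.bcpnn_readout <- function(object, newdata, ...) {
  logits <- cbind(newdata, 1) %*% object$W
  max.col(logits, ties.method = "first") - 1L
}

#' Readout accuracy helper
#'
#' @param readout A `bcpnn_readout`.
#' @param x,y Held-out features and 0-based labels.
#' @return Fraction correctly classified.
#' @export
readout_accuracy <- function(readout, x, y) {
  mean(predict(readout, x) == y)
}
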
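# Experiment drivers: hidden-representation capture, the
# f_max x tau_m x tau_z sweep, and the associative-memory task battery.

#' Hidden representations for a dataset
#'
#' Evaluates the network and returns the HID z-traces at one record time
#' as a `patterns x units` matrix — the standard feature matrix for the
#' linear readout and for similarity analyses.
#'
#' @param net A trained `bcpnn_network`.
#' @param dataset A `bcpnn_dataset` or image matrix.
#' @param time Record time (s from ffwd onset); default pattern end.
#' @param seed RNG seed for spiking evaluation.
#' @export
hid_representations <- function(net, dataset, time = NULL, seed = NULL) {
  cfg <- net$config
  time <- time %||% (cfg$t_ffwd + cfg$t_overlap + cfg$t_recr)
  ev <- evaluate_network(net, dataset, record_times = time, seed = seed)
  ev$hid_z[, , 1]
}

#' Train-and-readout convenience wrapper
#'
#' Trains a network on `train_set`, fits the linear readout on its
#' hidden representations, and scores held-out accuracy on `test_set`.
#'
#' @param config A [network_config()].
#' @param train_set,test_set `bcpnn_dataset`s with labels.
#' @param seed Seed for training, evaluation and the readout.
#' @return List: `net`, `readout`, `accuracy`.
#' @export
fit_and_score <- function(config, train_set, test_set, seed = 1) {
  net <- build_network(config)
  net <- train_network(net, train_set, seed = seed)
  x_train <- hid_representations(net, train_set, seed = seed + 1)
  x_test <- hid_representations(net, test_set, seed = seed + 2)
  readout <- train_linear_readout(x_train, train_set$labels,
                                  n_classes = max(train_set$labels) + 1L,
                                  seed = seed + 3)
  list(net = net,
       readout = readout,
       accuracy = readout_accuracy(readout, x_test, test_set$labels))
}

#' Sweep maximum firing rate and filtering time constants
#'
#' Trains and evaluates one model per grid cell of
#' `f_max x tau_m x tau_z` (everything else taken from `config`) on
#' reduced-size training/test sets and reports linear-readout accuracy
#' per cell.  This probes the compensation between low firing rates and
#' long z-filtering: with sparse Poisson spiking, pre/post spikes must
#' fall within the z-trace window for Hebbian association, so small
#' `tau_z` plus small `f_max` cripples learning.
#'
#' @param config Base [network_config()].
#' @param f_max_values,tau_m_values,tau_z_values Grid values (Hz, s, s).
#' @param train_set,test_set Labeled `bcpnn_dataset`s.
#' @param n_train,n_test Reduced sizes (prefix of each set).
#' @param seed Base seed; each cell derives its own.
#' @return `data.frame(f_max, tau_m, tau_z, accuracy)`.
#' @export
sweep_fmax_tau <- function(config, f_max_values, tau_m_values, tau_z_values,
                           train_set, test_set,
                           n_train = nrow(train_set$images),
                           n_test = nrow(test_set$images), seed = 1) {
  grid <- expand.grid(f_max = f_max_values, tau_m = tau_m_values,
                      tau_z = tau_z_values)
  if (nrow(grid) == 0) stop("empty parameter grid")
  tr <- subset_dataset(train_set, seq_len(min(n_train, nrow(train_set$images))))
  te <- subset_dataset(test_set, seq_len(min(n_test, nrow(test_set$images))))
  grid$accuracy <- NA_real_
  for (g in seq_len(nrow(grid))) {
    cfg <- config
    cfg$f_max <- grid$f_max[g]
    cfg$tau_m <- max(grid$tau_m[g], cfg$dt)
    cfg$tau_z <- max(grid$tau_z[g], cfg$dt)
    grid$accuracy[g] <- fit_and_score(cfg, tr, te, seed = seed + g)$accuracy
  }
  grid
}

#' Subset a dataset by pattern index
#'
#' @param dataset A `bcpnn_dataset`.
#' @param idx Pattern indices.
#' @export
subset_dataset <- function(dataset, idx) {
  out <- dataset
  out$images <- dataset$images[idx, , drop = FALSE]
  if (!is.null(dataset$labels)) out$labels <- dataset$labels[idx]
  if (!is.null(dataset$geometry))
    out$geometry <- dataset$geometry[idx, , drop = FALSE]
  out
}

#' Run the associative-memory task battery
#'
#' For each trained variant, fits a linear readout on the clean training
#' representations, then scores accuracy on corrupted test sets per
#' (task, difficulty) cell.
#'
#' @param nets Named list of trained `bcpnn_network`s (names = variant
#'   labels).
#' @param train_set Labeled clean training `bcpnn_dataset` (readout fit).
#' @param test_set Labeled clean test `bcpnn_dataset` (corruption source).
#' @param tasks Subset of `c("completion", "rivalry", "distortion")`.
#' @param difficulties Difficulty levels.
#' @param seed Base seed.
#' @return `data.frame(variant, task, difficulty, accuracy)`.
#' @export
run_task_battery <- function(nets, train_set, test_set,
                             tasks = c("completion", "rivalry", "distortion"),
                             difficulties = c(0.2, 0.4, 0.6, 0.8, 1.0),
                             seed = 1) {
  stopifnot(length(nets) >= 1, !is.null(names(nets)))
  rows <- list()
  for (v in names(nets)) {
    net <- nets[[v]]
    if (!inherits(net, "bcpnn_network"))
      stop("missing or invalid network for variant: ", v)
    x_train <- hid_representations(net, train_set, seed = seed)
    readout <- train_linear_readout(x_train, train_set$labels,
                                    n_classes = max(train_set$labels) + 1L,
                                    seed = seed + 1)
    for (task in tasks) {
      for (d in difficulties) {
        corrupted <- switch(task,
          completion = make_completion_set(test_set, d),
          rivalry = suppressWarnings(make_rivalry_set(test_set, d)),
          distortion = make_distortion_set(test_set, d, seed = seed + 2),
          stop("unknown task: ", task))
        x <- hid_representations(net, corrupted, seed = seed + 3)
        rows[[length(rows) + 1L]] <- data.frame(
          variant = v, task = task, difficulty = d,
          accuracy = readout_accuracy(readout, x, corrupted$labels))
      }
    }
  }
  do.call(rbind, rows)
}
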
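# Full network: INP -> HID feedforward, HID -> HID recurrent,
# HID -> INPRC feedback, the training / evaluation phase protocol, and
# the six model variants.

VARIANTS <- c("rate_ff", "rate_full", "spk_ff", "spk_full",
              "spspk_ff", "spspk_full")

#' Parameter bindings of the six model variants
#'
#' The variants differ only in the communicated activity (posterior vs
#' Bernoulli spikes), the maximum firing rate, the trace/membrane time
#' constants, and the phase durations:
#'
#' | variant | activity | f_max | tau_z | tau_m | phases (no/ff/ov/rec, s) |
#' |---|---|---|---|---|---|
#' | rate_ff    | pi | -    | 0.001 | 0.001 | 0 / 0.005 / 0 / 0 |
#' | rate_full  | pi | -    | 0.001 | 0.001 | 0 / 0.005 / 0 / 0.020 |
#' | spk_ff     | s  | 1000 | 0.005 | 0.001 | 0.025 / 0.025 / 0 / 0 |
#' | spk_full   | s  | 1000 | 0.005 | 0.001 | 0.025 / 0.025 / 0.025 / 0.050 |
#' | spspk_ff   | s  | 100  | 0.020 | 0.005 | 0.100 / 0.100 / 0 / 0 |
#' | spspk_full | s  | 100  | 0.020 | 0.005 | 0.100 / 0.100 / 0.050 / 0.150 |
#'
#' @param variant One of `r paste(VARIANTS, collapse = ", ")`.
#' @param dt Timestep (s).
#' @return A list of parameter bindings.
#' @export
variant_params <- function(variant = VARIANTS, dt = 0.001) {
  variant <- match.arg(variant)
  full <- grepl("full$", variant)
  fam <- sub("_(ff|full)$", "", variant)
  p <- switch(fam,
    rate  = list(mode = "rate", f_max = 1 / dt, tau_z = dt, tau_m = dt,
                 t_no_input = 0, t_ffwd = 0.005,
                 t_overlap = 0, t_recr = if (full) 0.020 else 0),
    spk   = list(mode = "spiking", f_max = 1000, tau_z = 0.005, tau_m = dt,
                 t_no_input = 0.025, t_ffwd = 0.025,
                 t_overlap = if (full) 0.025 else 0,
                 t_recr = if (full) 0.050 else 0),
    spspk = list(mode = "spiking", f_max = 100, tau_z = 0.020, tau_m = 0.005,
                 t_no_input = 0.100, t_ffwd = 0.100,
                 t_overlap = if (full) 0.050 else 0,
                 t_recr = if (full) 0.150 else 0))
  c(list(variant = variant, has_recurrent = full, dt = dt), p)
}

#' Phase schedule
#'
#' Durations of the four protocol phases.  Training presents each
#' pattern as no-input + ffwd; evaluation runs all four.  Gating per
#' phase: no-input clears activity (everything off); ffwd drives `INP`
#' (and, in training, clamps `INPRC`) and propagates the feedforward
#' projection; overlap adds the recurrent projection; recr cuts the
#' input and leaves only the recurrent drive.  The feedback projection
#' propagates throughout evaluation to reconstruct `INPRC`.
#'
#' @param t_no_input,t_ffwd,t_overlap,t_recr Durations in seconds.
#' @param dt Timestep (s); durations are converted with `round(t/dt)`.
#' @export
phase_schedule <- function(t_no_input, t_ffwd, t_overlap = 0, t_recr = 0,
                           dt = 0.001) {
  steps <- as.integer(round(c(t_no_input, t_ffwd, t_overlap, t_recr) / dt))
  stopifnot(all(steps >= 0), steps[2] > 0)
  structure(list(t_no_input = t_no_input, t_ffwd = t_ffwd,
                 t_overlap = t_overlap, t_recr = t_recr, steps = steps),
            class = "bcpnn_phase_schedule")
}

#' Network configuration
#'
#' Shapes, connectivity and learning parameters for the full model.  The
#' defaults are a desk-scale configuration (hidden population 20 x 20);
#' the published full-scale setting is `h_hid = 100, m_hid = 100` with
#' `n_conn = c(ff = 78, rec = 100, fb = 10)`.
#'
#' @param variant Model variant; see [variant_params()].
#' @param h_inp Number of input hypercolumns (= number of pixels).
#' @param m_inp Minicolumns per input hypercolumn (2: pixel ON/OFF).
#' @param h_hid,m_hid Hidden population shape.
#' @param n_conn_ff,n_conn_rec,n_conn_fb Active incoming patches per
#'   receiving hypercolumn for the three projections.  Defaults: 10% of
#'   the input hypercolumns (feedforward), all hidden hypercolumns
#'   (recurrent, making rewiring a no-op there), 10 (feedback).
#' @param tau_p P-trace time constant (s).
#' @param eps Probability floor for the log transforms.
#' @param init_jitter Relative amplitude of the seeded multiplicative
#'   jitter applied to the initial joint p-traces.  The uniform prior
#'   makes every minicolumn of a hypercolumn exactly interchangeable;
#'   spiking variants break this symmetry through sampling noise, but
#'   deterministic rate variants never would, so a small tie-breaking
#'   perturbation (symmetrized for the recurrent projection, which must
#'   stay exactly symmetric) is applied at build time.  Set to 0 for the
#'   strictly uniform prior.
#' @param n_flip Maximum rewiring flips per structural-plasticity step.
#' @param n_intv Training patterns between structural-plasticity steps.
#' @param n_epochs Training epochs.
#' @param clip Input-current clipping constant.
#' @param seed Seed used by [build_network()] for the initial masks.
#' @param ... Overrides for any [variant_params()] binding
#'   (e.g. `tau_z`, `f_max`, `t_recr`).
#' @export
network_config <- function(variant = "spspk_full", h_inp = 784, m_inp = 2,
                           h_hid = 20, m_hid = 20,
                           n_conn_ff = max(1L, round(0.1 * h_inp)),
                           n_conn_rec = h_hid,
                           n_conn_fb = min(10L, h_hid),
                           tau_p = 5, eps = 1e-4, n_flip = 100, n_intv = 200,
                           n_epochs = 1, clip = 1e-10, init_jitter = 0.01,
                           seed = 1, ...) {
  vp <- variant_params(variant)
  dots <- list(...)
  stopifnot(all(names(dots) %in% names(vp)))
  vp[names(dots)] <- dots
  stopifnot(n_conn_ff <= h_inp, n_conn_rec <= h_hid, n_conn_fb <= h_hid)
  structure(c(vp, list(h_inp = h_inp, m_inp = m_inp, h_hid = h_hid,
                       m_hid = m_hid, n_conn_ff = n_conn_ff,
                       n_conn_rec = n_conn_rec, n_conn_fb = n_conn_fb,
                       tau_p = tau_p, eps = eps, n_flip = n_flip,
                       n_intv = n_intv, n_epochs = n_epochs, clip = clip,
                       init_jitter = init_jitter, seed = seed)),
            class = "bcpnn_network_config")
}

state_keys <- function() {
  c("W_ff", "W_rec", "W_fb", "b_ff", "b_rec", "b_fb",
    "mask_ff", "mask_rec", "mask_fb", "patch_ff", "patch_rec", "patch_fb",
    "z_ff_pre", "z_ff_post", "z_rec_pre", "z_rec_post",
    "z_fb_pre", "z_fb_post",
    "p_ff_pre", "p_ff_post", "p_rec_pre", "p_rec_post",
    "p_fb_pre", "p_fb_post", "P_ff", "P_rec", "P_fb",
    "v_inp", "v_hid", "v_inprc")
}

init_projection <- function(e, name, h_pre, m_pre, h_post, m_post, n_conn) {
  n_pre <- h_pre * m_pre; n_post <- h_post * m_post
  patch <- init_random_connectivity(h_pre, h_post, n_conn)
  e[[paste0("patch_", name)]] <- patch
  e[[paste0("mask_", name)]] <-
    matrix(as.integer(expand_patch_mask(unclass(patch), m_pre, m_post)),
           n_pre, n_post)
  e[[paste0("W_", name)]] <- matrix(0, n_pre, n_post)
  e[[paste0("b_", name)]] <- rep(log(1 / m_post), n_post)
  e[[paste0("z_", name, "_pre")]] <- numeric(n_pre)
  e[[paste0("z_", name, "_post")]] <- numeric(n_post)
  e[[paste0("p_", name, "_pre")]] <- rep(1 / m_pre, n_pre)
  e[[paste0("p_", name, "_post")]] <- rep(1 / m_post, n_post)
  e[[paste0("P_", name)]] <- matrix(1 / (m_pre * m_post), n_pre, n_post)
  invisible(e)
}

#' Build a network from a configuration
#'
#' Creates the three populations with zero voltages, the three
#' projections with uniform-prior traces (hence zero initial weights and
#' `log(1/M)` biases), and seed-deterministic random patchy
#' connectivity.
#'
#' @param config A [network_config()].
#' @return A `bcpnn_network`.  State lives in an internal environment;
#'   [train_network()], [evaluate_network()] and [run_pattern()] deep-copy
#'   it before mutating, so networks behave as ordinary R values.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "bcpnn_network_config"))
  e <- new.env(parent = emptyenv())
  e$H_inp <- as.integer(config$h_inp); e$M_inp <- as.integer(config$m_inp)
  e$H_hid <- as.integer(config$h_hid); e$M_hid <- as.integer(config$m_hid)
  e$dt <- config$dt; e$tau_p <- config$tau_p; e$eps <- config$eps
  e$tau_m <- config$tau_m
  e$tau_zi <- config$tau_z; e$tau_zj <- config$tau_z
  e$mu_spk <- if (config$mode == "rate") 1 else config$f_max * config$dt
  stopifnot(e$mu_spk > 0, e$mu_spk <= 1)
  with_seed(config$seed, {
    init_projection(e, "ff", config$h_inp, config$m_inp,
                    config$h_hid, config$m_hid, config$n_conn_ff)
    init_projection(e, "rec", config$h_hid, config$m_hid,
                    config$h_hid, config$m_hid, config$n_conn_rec)
    init_projection(e, "fb", config$h_hid, config$m_hid,
                    config$h_inp, config$m_inp, config$n_conn_fb)
    if (config$init_jitter > 0) {
      jit <- function(P, symmetric = FALSE) {
        J <- matrix(runif(length(P), -1, 1), nrow(P), ncol(P))
        if (symmetric) J <- (J + t(J)) / 2
        P * (1 + config$init_jitter * J)
      }
      e$P_ff <- jit(e$P_ff)
      e$P_rec <- jit(e$P_rec, symmetric = TRUE)
      e$P_fb <- jit(e$P_fb)
    }
  })
  e$v_inp <- numeric(e$H_inp * e$M_inp)
  e$v_hid <- numeric(e$H_hid * e$M_hid)
  e$v_inprc <- numeric(e$H_inp * e$M_inp)
  structure(list(config = config, state = e,
                 n_patterns_seen = 0L,
                 rewire_log = data.frame()),
            class = "bcpnn_network")
}

clone_network <- function(net) {
  e2 <- new.env(parent = emptyenv())
  for (k in ls(net$state)) {
    v <- net$state[[k]]
    # force a fresh allocation for arrays so C++ in-place writes cannot
    # alias the original
    if (is.atomic(v) && length(v) > 1) {
      out <- v + if (is.integer(v)) 0L else 0
      attributes(out) <- attributes(v)
      e2[[k]] <- out
    } else e2[[k]] <- v
  }
  net$state <- e2
  net
}

train_schedule <- function(config) {
  phase_schedule(config$t_no_input, config$t_ffwd, 0, 0, config$dt)
}

eval_schedule <- function(config) {
  phase_schedule(config$t_no_input, config$t_ffwd, config$t_overlap,
                 config$t_recr, config$dt)
}

#' Run a single pattern through the network
#'
#' Executes the phase protocol timestep by timestep.  In training mode
#' the pattern is presented for the no-input + ffwd phases, p-traces of
#' all projections update during ffwd (`INPRC` clamped to the image),
#' and bias/weight are recomputed at the last step.  In evaluation mode
#' all four phases run with learning off.
#'
#' @param net A `bcpnn_network`.
#' @param image Pixel-intensity vector in `[0,1]`, length `h_inp`.
#' @param mode `"train"` or `"eval"`.
#' @param record_times Times (s, from the start of the ffwd phase) at
#'   which to capture HID and INPRC z-traces and HID posteriors.
#' @param record_spikes Also capture full spike rasters (all steps).
#' @return List with the updated `net` and `record` (fields `hid_z`,
#'   `inprc_z`, `hid_pi`, one row per record time; plus spike rasters if
#'   requested).
#' @export
run_pattern <- function(net, image, mode = c("train", "eval"),
                        record_times = numeric(), record_spikes = FALSE) {
  mode <- match.arg(mode)
  net <- clone_network(net)
  record <- run_pattern_inplace(net, image, mode, record_times, record_spikes)
  net$n_patterns_seen <- net$n_patterns_seen +
    as.integer(mode == "train")
  list(net = net, record = record)
}

run_pattern_inplace <- function(net, image, mode, record_times = numeric(),
                                record_spikes = FALSE) {
  cfg <- net$config
  if (length(image) != cfg$h_inp)
    stop("image length must equal the number of input hypercolumns")
  sched <- if (mode == "train") train_schedule(cfg) else eval_schedule(cfg)
  steps <- sched$steps
  rec_steps <- as.integer(round(record_times / cfg$dt))
  if (length(rec_steps) && max(rec_steps) > sum(steps[2:4]))
    stop("record time beyond pattern duration")
  I <- encode_input_current(image, cfg$clip)
  cpp_run_pattern(net$state, I, I, as.integer(mode == "eval"), steps,
                  cfg$mode == "spiking", cfg$has_recurrent,
                  rec_steps, record_spikes,
                  update_weights = (mode == "train"))
}

apply_structural_plasticity <- function(net) {
  cfg <- net$config
  e <- net$state
  log_rows <- list()
  for (name in c("ff", "fb")) {
    patch <- e[[paste0("patch_", name)]]
    if (attr(patch, "n_conn") >= nrow(patch)) next   # fully connected
    dims <- if (name == "ff") c(cfg$m_inp, cfg$m_hid) else c(cfg$m_hid, cfg$m_inp)
    sc <- patch_scores(e[[paste0("P_", name)]], e[[paste0("W_", name)]],
                       unclass(patch), dims[1], dims[2])
    res <- rewire_step(unclass(patch), sc, cfg$n_flip)
    e[[paste0("patch_", name)]] <- structure(res$mask,
                                             n_conn = attr(patch, "n_conn"),
                                             class = "bcpnn_conn_mask")
    e[[paste0("mask_", name)]] <-
      matrix(as.integer(expand_patch_mask(res$mask, dims[1], dims[2])),
             nrow(e[[paste0("W_", name)]]), ncol(e[[paste0("W_", name)]]))
    active <- res$mask == 1
    log_rows[[name]] <- data.frame(
      pattern = net$n_patterns_seen, projection = name,
      n_flips = res$n_flipped,
      score_mean = mean(sc[active]), score_sd = stats::sd(sc[active]))
  }
  net$rewire_log <- rbind(net$rewire_log, do.call(rbind, log_rows))
  net
}

#' Train a network on a dataset
#'
#' Iterates [run_pattern()] in training mode over the dataset for
#' `n_epochs` epochs (fixed order unless `shuffle`), invoking the
#' structural-plasticity step every `n_intv` patterns.  Deterministic
#' given `seed` (spiking draws and shuffling both use R's RNG).
#'
#' @param net A `bcpnn_network`.
#' @param dataset A `bcpnn_dataset` (or plain `N x h_inp` matrix).
#' @param n_epochs Override of the configured epoch count.
#' @param shuffle Shuffle pattern order each epoch (default FALSE).
#' @param seed RNG seed for the run.
#' @param progress Print a line per rewiring step.
#' @return The trained network (input object untouched), with a
#'   `rewire_log` data frame of per-step flip counts and score summaries.
#' @export
train_network <- function(net, dataset, n_epochs = NULL, shuffle = FALSE,
                          seed = NULL, progress = FALSE) {
  images <- if (inherits(dataset, "bcpnn_dataset")) dataset$images else dataset
  if (!is.matrix(images) || nrow(images) == 0) stop("empty dataset")
  n_epochs <- n_epochs %||% net$config$n_epochs
  net <- clone_network(net)
  with_seed(seed, {
    for (ep in seq_len(n_epochs)) {
      ord <- if (shuffle) sample.int(nrow(images)) else seq_len(nrow(images))
      for (i in ord) {
        run_pattern_inplace(net, images[i, ], "train")
        net$n_patterns_seen <- net$n_patterns_seen + 1L
        if (net$n_patterns_seen %% net$config$n_intv == 0) {
          net <- apply_structural_plasticity(net)
          if (progress) {
            tl <- tail(net$rewire_log, 2)
            message(sprintf("pattern %d: flips %s", net$n_patterns_seen,
                            paste(tl$projection, tl$n_flips, collapse = ", ")))
          }
        }
      }
    }
  })
  net
}

#' Evaluate a network on a dataset
#'
#' Runs each pattern through the four-phase evaluation protocol with
#' learning off and captures HID and INPRC z-traces at the requested
#' times.  The input network is not modified (weights, traces and masks
#' are bit-identical before and after).
#'
#' @param net A trained `bcpnn_network`.
#' @param dataset A `bcpnn_dataset` or `N x h_inp` matrix.
#' @param record_times Times (s from ffwd onset); default captures the
#'   feedforward-driven snapshot (end of ffwd) and the attractor-driven
#'   snapshot (end of pattern).
#' @param seed RNG seed (spiking variants).
#' @return List of class `bcpnn_eval`: `hid_z`, `inprc_z`, `hid_pi` —
#'   arrays `patterns x units x record_times` — plus `record_times` and
#'   `labels` if present.
#' @export
evaluate_network <- function(net, dataset, record_times = NULL, seed = NULL) {
  images <- if (inherits(dataset, "bcpnn_dataset")) dataset$images else dataset
  labels <- if (inherits(dataset, "bcpnn_dataset")) dataset$labels else NULL
  cfg <- net$config
  record_times <- record_times %||%
    c(cfg$t_ffwd, cfg$t_ffwd + cfg$t_overlap + cfg$t_recr)
  record_times <- unique(record_times)
  net <- clone_network(net)    # scratch copy; caller's net untouched
  n <- nrow(images); nr <- length(record_times)
  hid_z <- array(0, c(n, cfg$h_hid * cfg$m_hid, nr))
  hid_pi <- array(0, c(n, cfg$h_hid * cfg$m_hid, nr))
  inprc_z <- array(0, c(n, cfg$h_inp * cfg$m_inp, nr))
  with_seed(seed, {
    for (i in seq_len(n)) {
      rec <- run_pattern_inplace(net, images[i, ], "eval", record_times)
      for (r in seq_len(nr)) {
        hid_z[i, , r] <- rec$hid_z[r, ]
        hid_pi[i, , r] <- rec$hid_pi[r, ]
        inprc_z[i, , r] <- rec$inprc_z[r, ]
      }
    }
  })
  structure(list(hid_z = hid_z, hid_pi = hid_pi, inprc_z = inprc_z,
                 record_times = record_times, labels = labels),
            class = "bcpnn_eval")
}

#' Reconstructed pixel intensities from INPRC traces
#'
#' Each input hypercolumn has an ON and an OFF unit; the reconstructed
#' intensity is the normalized ON share `z_on / (z_on + z_off)` (0.5
#' where both traces are zero).
#'
#' @param inprc_z `patterns x (2*h_inp)` matrix of INPRC z-traces.
#' @return `patterns x h_inp` matrix of intensities in `[0, 1]`.
#' @export
reconstruction_image <- function(inprc_z) {
  on <- inprc_z[, seq(1, ncol(inprc_z), by = 2), drop = FALSE]
  off <- inprc_z[, seq(2, ncol(inprc_z), by = 2), drop = FALSE]
  tot <- on + off
  out <- on / ifelse(tot > 0, tot, 1)
  out[tot == 0] <- 0.5
  out
}

#' @export
print.bcpnn_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("bcpnn network [%s]\n", cfg$variant))
  cat(sprintf("  INP %d x %d | HID %d x %d | INPRC %d x %d\n",
              cfg$h_inp, cfg$m_inp, cfg$h_hid, cfg$m_hid, cfg$h_inp, cfg$m_inp))
  cat(sprintf("  n_conn ff/rec/fb: %d/%d/%d | trained on %d patterns\n",
              cfg$n_conn_ff, cfg$n_conn_rec, cfg$n_conn_fb, x$n_patterns_seen))
  invisible(x)
}
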
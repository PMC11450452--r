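# Checkpointing: the full network state as a single hierarchical
# key -> array container.  An HDF5-style path convention
# ("projection/field", "population/field") is used over an RDS file,
# which is the portable single-file container available in base R.

checkpoint_map <- function() {
  # state key -> checkpoint path
  keys <- state_keys()
  path <- character(length(keys))
  for (i in seq_along(keys)) {
    k <- keys[i]
    path[i] <- if (grepl("^(W|b|P)_", k)) {
      parts <- strsplit(k, "_")[[1]]
      field <- c(W = "weight", b = "bias", P = "p_joint")[parts[1]]
      paste0(parts[2], "/", field)
    } else if (grepl("^mask_", k)) {
      paste0(sub("mask_", "", k), "/conn")
    } else if (grepl("^patch_", k)) {
      paste0(sub("patch_", "", k), "/patch_mask")
    } else if (grepl("^z_", k)) {
      sub("^z_([a-z]+)_(pre|post)$", "\\1/z_\\2", k)
    } else if (grepl("^p_", k)) {
      sub("^p_([a-z]+)_(pre|post)$", "\\1/p_\\2", k)
    } else if (grepl("^v_", k)) {
      paste0(sub("v_", "", k), "/v")
    } else k
  }
  setNames(path, keys)
}

#' Save a network checkpoint
#'
#' Writes a single file holding the configuration and every state array
#' under hierarchical keys (`ff/weight`, `ff/conn`, `hid/v`, ...).
#'
#' @param net A `bcpnn_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(net, path) {
  map <- checkpoint_map()
  arrays <- list()
  for (k in names(map)) arrays[[map[[k]]]] <- net$state[[k]]
  saveRDS(list(format = "bcpnn-checkpoint-1",
               config = net$config,
               n_patterns_seen = net$n_patterns_seen,
               rewire_log = net$rewire_log,
               arrays = arrays), path)
  invisible(path)
}

#' Load a network checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return A `bcpnn_network`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint file not found: ", path)
  x <- readRDS(path)
  if (!identical(x$format, "bcpnn-checkpoint-1"))
    stop("not a bcpnn checkpoint: ", path)
  net <- build_network(x$config)
  map <- checkpoint_map()
  for (k in names(map)) net$state[[k]] <- x$arrays[[map[[k]]]]
  net$n_patterns_seen <- x$n_patterns_seen
  net$rewire_log <- x$rewire_log
  net
}

#' Snapshot the network state as a flat named list
#'
#' Useful for bitwise before/after comparisons (e.g. evaluation purity).
#'
#' @param net A `bcpnn_network`.
#' @return Named list of all state arrays keyed by checkpoint path.
#' @export
network_state_snapshot <- function(net) {
  map <- checkpoint_map()
  out <- list()
  for (k in names(map)) out[[map[[k]]]] <- net$state[[k]]
  out[order(names(out))]
}
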
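# Activity-dependent structural plasticity: per-patch normalized mutual
# information scores and greedy silent/active flip operations on the
# hypercolumn-level connectivity mask.

#' Random patchy connectivity
#'
#' Every receiving hypercolumn draws `n_conn` distinct active incoming
#' patches uniformly without replacement from the sending hypercolumns.
#'
#' @param h_pre Number of sending hypercolumns.
#' @param h_post Number of receiving hypercolumns.
#' @param n_conn Active incoming patches per receiver (`<= h_pre`).
#' @return Binary `h_pre x h_post` patch mask of class `bcpnn_conn_mask`
#'   with attribute `n_conn`.
#' @export
init_random_connectivity <- function(h_pre, h_post, n_conn) {
  stopifnot(h_pre >= 1, h_post >= 1, n_conn >= 1)
  if (n_conn > h_pre) stop("n_conn exceeds the number of sending hypercolumns")
  mask <- matrix(0, h_pre, h_post)
  for (j in seq_len(h_post))
    mask[sample.int(h_pre, n_conn), j] <- 1
  structure(mask, n_conn = as.integer(n_conn), class = "bcpnn_conn_mask")
}

#' Expand a patch mask to minicolumn level
#'
#' Connections are inherited by all minicolumn units within a
#' hypercolumn: each patch entry is replicated over the
#' `m_pre x m_post` minicolumn pairs it spans.
#'
#' @param mask Patch-level binary `h_pre x h_post` matrix.
#' @param m_pre,m_post Minicolumns per hypercolumn on each side.
#' @return Binary `(h_pre*m_pre) x (h_post*m_post)` matrix.
#' @export
expand_patch_mask <- function(mask, m_pre, m_post) {
  mask[rep(seq_len(nrow(mask)), each = m_pre),
       rep(seq_len(ncol(mask)), each = m_post), drop = FALSE]
}

#' Normalized mutual-information patch scores
#'
#' For every (sending, receiving) hypercolumn pair — silent patches
#' included, since they are rewiring candidates — the score is
#' `M = sum_ij p_ij w_ij / N_out`, where the sum runs over the
#' minicolumn pairs of the patch and `N_out` is the sender's number of
#' active outgoing patches at scoring time (1 if the sender has none).
#' The numerator is the mutual information locally available at the
#' patch, since the weights are point-wise mutual informations.
#'
#' @param p_joint Minicolumn-level joint p-trace matrix (`n_pre x n_post`).
#' @param weight  Minicolumn-level weight matrix (same shape).
#' @param mask    Patch-level binary mask (`h_pre x h_post`).
#' @param m_pre,m_post Minicolumns per hypercolumn on each side.
#' @return `h_pre x h_post` matrix of scores (nats).
#' @export
patch_scores <- function(p_joint, weight, mask, m_pre, m_post) {
  h_pre <- nrow(mask); h_post <- ncol(mask)
  stopifnot(nrow(p_joint) == h_pre * m_pre, ncol(p_joint) == h_post * m_post,
            all(dim(weight) == dim(p_joint)))
  mi <- p_joint * weight
  # patch-wise sums: collapse minicolumn blocks on both axes
  g_pre <- rep(seq_len(h_pre), each = m_pre)
  g_post <- rep(seq_len(h_post), each = m_post)
  num <- rowsum(t(rowsum(mi, g_pre)), g_post)  # h_post x h_pre
  n_out <- pmax(rowSums(mask), 1)
  out <- t(num) / n_out
  dimnames(out) <- NULL
  out
}

#' One structural-plasticity step (greedy flips)
#'
#' A flip converts, within one receiving hypercolumn, its silent incoming
#' patch with the highest score into an active one and its active
#' incoming patch with the lowest score into a silent one; it is applied
#' only when the silent candidate strictly outranks the active one.
#' Scores are frozen for the whole step; at most `n_flips` flips are
#' executed globally, largest score-gain first across receivers.  The
#' active-count-per-receiver invariant is preserved exactly.
#'
#' @param mask Patch-level binary mask (as from
#'   [init_random_connectivity()]).
#' @param scores Score matrix from [patch_scores()].
#' @param n_flips Global flip budget for this step (default 100).
#' @return List with the updated `mask` and `n_flipped`.
#' @export
rewire_step <- function(mask, scores, n_flips = 100) {
  stopifnot(all(dim(scores) == dim(mask)))
  h_pre <- nrow(mask)
  n_flipped <- 0L
  best <- function(j) {
    act <- which(mask[, j] == 1)
    sil <- which(mask[, j] == 0)
    if (!length(act) || !length(sil)) return(NULL)
    # ties broken by lowest sender index (which.max/min take the first)
    i_sil <- sil[which.max(scores[sil, j])]
    i_act <- act[which.min(scores[act, j])]
    gain <- scores[i_sil, j] - scores[i_act, j]
    if (gain <= 0) return(NULL)
    list(i_sil = i_sil, i_act = i_act, gain = gain)
  }
  cand <- lapply(seq_len(ncol(mask)), best)
  while (n_flipped < n_flips) {
    gains <- vapply(cand, function(x) if (is.null(x)) -Inf else x$gain, 0)
    j <- which.max(gains)
    if (!is.finite(gains[j])) break
    mask[cand[[j]]$i_sil, j] <- 1
    mask[cand[[j]]$i_act, j] <- 0
    n_flipped <- n_flipped + 1L
    cand[j] <- list(best(j))   # NB: [[<- NULL would drop the element
  }
  list(mask = mask, n_flipped = n_flipped)
}
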
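# Training objectives: cross-view InfoNCE, supervised contrastive loss over
# drug-pair embeddings, multi-class prediction loss, and their combination
# L = L_s + alpha * (L_uc + L_sc). Similarity is cosine with temperature tau.
# All functions accept plain numerics or adnodes (see autodiff.R).

#' Loss configuration
#'
#' @param tau temperature (> 0), default 0.05.
#' @param alpha balance coefficient between prediction and contrastive
#'   losses (>= 0), default 0.1.
#' @return list of class `loss_config`.
#' @export
loss_config <- function(tau = 0.05, alpha = 0.1) {
  stopifnot(tau > 0, alpha >= 0)
  structure(list(tau = tau, alpha = alpha, similarity = "cosine"),
            class = "loss_config")
}

#' Cross-view InfoNCE loss
#'
#' Symmetric InfoNCE between the average-view and augmented-view embeddings:
#' the positive for drug i in one view is drug i in the other view; each
#' anchor's denominator sums the cosine-similarity exponentials over all |D|
#' candidates of the other view (positive included). The two directional sums
#' are averaged with the 1/(2|D|) normalization.
#'
#' @param Z_C,Z_F |D| x d embedding matrices (numeric or adnode).
#' @param tau temperature > 0.
#' @return scalar loss (adnode if any input is one).
#' @export
info_nce_views <- function(Z_C, Z_F, tau) {
  stopifnot(tau > 0)
  An <- nd_rownorm(Z_C)
  Bn <- nd_rownorm(Z_F)
  S <- nd_scale(nd_tmm(An, Bn), 1 / tau)
  pos <- nd_scale(nd_rowsums(nd_mul(An, Bn)), 1 / tau)
  l1 <- nd_mean(nd_sub(nd_rowlogsumexp(S), pos))
  l2 <- nd_mean(nd_sub(nd_rowlogsumexp(nd_t(S)), pos))
  nd_scale(nd_add(l1, l2), 0.5)
}

#' Supervised contrastive loss over a batch of pair embeddings
#'
#' Per anchor, positives are the other batch members with the same event
#' label and the denominator runs over all other batch members (the anchor is
#' excluded from both). The log-ratio terms are averaged over each anchor's
#' positives, then over the anchors that have at least one positive; anchors
#' without positives contribute nothing. A batch of size < 2 returns 0 with a
#' warning.
#'
#' @param emb n x p matrix of pair embeddings (numeric or adnode).
#' @param labels length-n event labels.
#' @param tau temperature > 0.
#' @return scalar loss.
#' @export
supervised_contrastive <- function(emb, labels, tau) {
  stopifnot(tau > 0)
  n <- nrow(ad_value(emb))
  if (n < 2L) {
    warning("supervised_contrastive: batch of size < 2, returning 0")
    return(0)
  }
  same <- outer(labels, labels, `==`) * 1
  diag(same) <- 0
  npos <- rowSums(same)
  anchors <- npos > 0
  if (!any(anchors)) return(0)
  Wp <- same / pmax(npos, 1)
  Wp[!anchors, ] <- 0
  Wp <- Wp / sum(anchors)
  P <- nd_rownorm(emb)
  S <- nd_scale(nd_tmm(P, P), 1 / tau)
  offdiag <- 1 - diag(n)
  lse <- nd_rowlogsumexp(S, offdiag)
  # sum_ij Wp_ij * (lse_i - S_ij)
  nd_sum(nd_mul(Wp, nd_add_colvec(nd_scale(S, -1), lse)))
}

#' Multi-class prediction loss (mean cross-entropy)
#'
#' @param probs n x |E| matrix of predicted probabilities (rows sum to 1).
#' @param labels length-n integer class labels (1-based).
#' @return scalar mean cross-entropy; probabilities are clipped at 1e-12
#'   before the log.
#' @export
prediction_loss <- function(probs, labels) {
  stopifnot(nrow(probs) == length(labels))
  -mean(log(pmax(probs[cbind(seq_len(nrow(probs)), labels)], 1e-12)))
}

#' Combined training loss L = L_s + alpha (L_uc + L_sc)
#'
#' @param L_s prediction loss.
#' @param L_uc cross-view InfoNCE loss.
#' @param L_sc supervised contrastive loss.
#' @param alpha balance coefficient.
#' @return scalar total loss.
#' @export
total_loss <- function(L_s, L_uc, L_sc, alpha) {
  nd_add(L_s, nd_scale(nd_add(L_uc, L_sc), alpha))
}
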
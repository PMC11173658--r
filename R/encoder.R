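# Drug encoder: feature transformation, per-graph multi-head node attention,
# and semantic (meta-path-level) attention.
#
# All functions are written over the nd_* operations from autodiff.R, so the
# same code produces plain numeric embeddings for inference/tests and a
# differentiable computation graph during training (pass parameters wrapped
# with ad_param()).

#' Initialize encoder, semantic-attention and MLP parameters
#'
#' Glorot-uniform initialization throughout (the documented default). One
#' independent attention parameter set is created per graph: the average view
#' plus each meta-path sub-graph.
#'
#' @param n_features input feature dimension F.
#' @param d embedding dimension (divisible by `H`).
#' @param H number of attention heads.
#' @param n_events number of DDI event classes.
#' @param graph_names meta-path names of the sub-graphs.
#' @param hidden integer vector of MLP hidden-layer widths.
#' @param seed RNG seed.
#' @return nested list of numeric parameter arrays.
#' @export
init_params <- function(n_features, d, H, n_events, graph_names,
                        hidden = 2L * d, seed = 1L) {
  stopifnot(d %% H == 0)
  dh <- d %/% H
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  gat_set <- function() {
    list(a = lapply(seq_len(H), function(k) glorot(2L * d, 1L)),
         W = lapply(seq_len(H), function(k) glorot(d, dh)),
         b = numeric(dh),
         ps = 0.25)
  }
  with_seed(seed, {
    p <- list(
      W = glorot(n_features, d),
      b = numeric(d),
      avg = gat_set(),
      mp = stats::setNames(lapply(graph_names, function(g) gat_set()),
                           graph_names),
      sem = list(W1 = glorot(d, d), b1 = numeric(d), q1 = glorot(d, 1L)[, 1]),
      mlp = local({
        widths <- c(4L * d, hidden, n_events)
        lapply(seq_len(length(widths) - 1L), function(i) {
          list(W = glorot(widths[i], widths[i + 1L]),
               b = numeric(widths[i + 1L]))
        })
      })
    )
    p$hyper <- list(d = d, H = H, dh = dh, n_events = n_events,
                    graph_names = graph_names)
    p
  })
}

# Recursively wrap numeric parameter arrays as autodiff leaves.
wrap_params <- function(p) {
  if (is.list(p)) return(lapply(p, wrap_params))
  if (is.numeric(p)) return(ad_param(p))
  p
}

# Recursively read values back out of wrapped parameters.
unwrap_params <- function(p) {
  if (is_adnode(p)) return(p$value)
  if (is.list(p)) return(lapply(p, unwrap_params))
  p
}

#' Transform drug features into the embedding space
#'
#' h_i = ELU(W x_i + b), applied row-wise to the feature matrix.
#'
#' @param X |D| x F feature matrix (numeric or adnode).
#' @param W F x d mapping matrix.
#' @param b length-d bias.
#' @return |D| x d matrix of transformed features.
#' @export
transform_features <- function(X, W, b) {
  if (any(!is.finite(ad_value(X)))) stop("non-finite feature input")
  nd_elu(nd_add(nd_mm(X, W), b))
}

#' Multi-head graph attention encoding of one drug graph
#'
#' For each head k, attention logits e_ij = LeakyReLU(a_k^T [h_i || h_j]) over
#' the neighborhood of i (self-loops are added so every node has at least one
#' neighbor), normalized with a softmax; the head output is
#' PReLU(sum_j alpha_ij W_k h_j + b), and the H head outputs (dimension d/H
#' each) are concatenated to dimension d.
#'
#' @param adj binary symmetric |D| x |D| adjacency (plain numeric).
#' @param h |D| x d transformed features.
#' @param gp per-graph parameter set (`a`, `W`, `b`, `ps`).
#' @param return_attention also return the per-head attention matrices
#'   (numeric path only).
#' @param edge_logit_offset optional numeric matrix added to the attention
#'   logits (used to fold fractional average-view edge weights into the
#'   softmax).
#' @return |D| x d embedding matrix; with `return_attention = TRUE`, a list
#'   `list(Z, attention)`.
#' @export
gat_encode <- function(adj, h, gp, return_attention = FALSE,
                       edge_logit_offset = NULL) {
  A <- adj
  diag(A) <- 1
  mask <- (A > 0) * 1
  H <- length(gp$a)
  heads <- vector("list", H)
  alphas <- if (return_attention) vector("list", H) else NULL
  for (k in seq_len(H)) {
    hd <- nd_gat_head(h, gp$a[[k]], gp$W[[k]], gp$b, gp$ps, mask,
                      slope = 0.2, offset = edge_logit_offset,
                      keep_alpha = return_attention)
    if (return_attention) {
      alphas[[k]] <- attr(hd, "alpha")
      attr(hd, "alpha") <- NULL
    }
    heads[[k]] <- hd
  }
  Z <- nd_cbind(heads)
  if (return_attention) list(Z = Z, attention = alphas) else Z
}

#' Encode the average graph view
#'
#' Neighborhoods are the nonzero support of the averaged adjacency M_C. With
#' `use_edge_weights = TRUE` the fractional weights are folded into the
#' attention logits (softmax(e + log w) is proportional to w exp(e)); by
#' default attention re-learns edge weights from the binary support.
#'
#' @param M_C averaged adjacency from [average_view()].
#' @param h transformed features.
#' @param gp average-view attention parameter set.
#' @param use_edge_weights fold M_C weights into the attention softmax?
#' @param ... passed to [gat_encode()].
#' @return |D| x d embedding matrix Z_C.
#' @export
encode_average_view <- function(M_C, h, gp, use_edge_weights = FALSE, ...) {
  support <- (M_C > 0) * 1
  offset <- NULL
  if (use_edge_weights) {
    offset <- matrix(0, nrow(M_C), ncol(M_C))
    offset[M_C > 0] <- log(M_C[M_C > 0])
  }
  gat_encode(support, h, gp, edge_logit_offset = offset, ...)
}

#' Semantic attention fusion across meta-path sub-graphs
#'
#' Each sub-graph embedding matrix is summarized as
#' s_P = mean_i tanh(W1 z_i^P + b1); importance e_P = q1^T s_P; weights
#' beta = softmax over the sub-graphs; fused embedding
#' z_i^F = sum_P beta_P z_i^P. Dropping a sub-graph re-normalizes beta over
#' the survivors.
#'
#' @param Z_list list of |D| x d per-sub-graph embeddings (>= 1).
#' @param sp semantic parameter set (`W1` d x d, `b1` length d, `q1` length d).
#' @return list with `beta` (weights, sum 1) and `Z_F` (|D| x d).
#' @export
semantic_fuse <- function(Z_list, sp) {
  if (!length(Z_list)) stop("semantic_fuse: empty sub-graph embedding list")
  es <- lapply(Z_list, function(Z) {
    s <- nd_colmeans(nd_tanh(nd_add(nd_mm(Z, sp$W1), sp$b1)))
    nd_sum(nd_mul(sp$q1, s))
  })
  beta <- nd_softmaxv(nd_c(es))
  Z_F <- NULL
  for (j in seq_along(Z_list)) {
    term <- nd_mul(nd_el(beta, j), Z_list[[j]])
    Z_F <- if (is.null(Z_F)) term else nd_add(Z_F, term)
  }
  list(beta = beta, Z_F = Z_F)
}

#' Encode both contrastive views
#'
#' Computes transformed features, the average-view embedding Z_C from the
#' clean sub-graph set, and the augmented-view embedding Z_F by semantic
#' fusion of the per-sub-graph attention encodings.
#'
#' @param X feature matrix.
#' @param sgs_clean clean `subgraph_set` (defines the average view).
#' @param sgs_aug sub-graph set for the augmented view (clean at inference,
#'   corrupted during training).
#' @param params parameter list from [init_params()] (numeric or wrapped).
#' @param use_edge_weights see [encode_average_view()].
#' @return list with `Z_C`, `Z_F`, `beta`, `h`.
#' @export
encode_views <- function(X, sgs_clean, sgs_aug, params,
                         use_edge_weights = FALSE) {
  h <- transform_features(X, params$W, params$b)
  M_C <- average_view(sgs_clean)
  Z_C <- encode_average_view(M_C, h, params$avg,
                             use_edge_weights = use_edge_weights)
  Z_list <- lapply(sgs_aug$names, function(nm) {
    gat_encode(sgs_aug$graphs[[nm]], h, params$mp[[nm]])
  })
  fused <- semantic_fuse(Z_list, params$sem)
  list(Z_C = Z_C, Z_F = fused$Z_F, beta = fused$beta, h = h)
}
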
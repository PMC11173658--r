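# End-to-end DDI event prediction pipeline: drug-pair representation and MLP
# head, Task1/2/3 data splitting, the training loop (Adam on the combined
# loss), the evaluation metric suite, frequency-grouped reporting and novel
# pair ranking.

#' Training configuration
#'
#' Defaults follow the documented settings: 8 attention heads, temperature
#' 0.05, balance coefficient 0.1, masking ratios (af, ae, ag) =
#' (0.2, 0.3, 0.2), Adam with learning rate 1e-3, 7:1:2 hold-out.
#'
#' @param d embedding dimension (divisible by `H`).
#' @param H number of attention heads.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size mini-batch size for the pair losses (the graphs are
#'   encoded in full at every step).
#' @param batches_per_epoch Adam steps taken per epoch: that many mini-batches
#'   are drawn from the epoch's shuffle (all batches when NULL or when the
#'   training set is small). Bounds the number of full-graph encodings per
#'   epoch; successive epochs reshuffle, so all pairs are visited across
#'   epochs.
#' @param hidden MLP hidden widths; default `2 * d`.
#' @param dropout MLP dropout rate during training.
#' @param seed controls all randomness (initialization, shuffling, masking).
#' @param aug an [aug_config()]; its mode is overridden by `ablation`.
#' @param loss a [loss_config()].
#' @param ablation one of "full", "noMask", "fMask", "eMask", "gMask",
#'   "noPPI".
#' @param K_overrides optional named per-meta-path K values.
#' @param use_edge_weights see [encode_average_view()].
#' @param verbose print per-epoch losses?
#' @return list of class `train_config`.
#' @export
train_config <- function(d = 64L, H = 8L, lr = 1e-3, epochs = 200L,
                         batch_size = 512L, batches_per_epoch = 2L,
                         hidden = NULL, dropout = 0,
                         seed = 1L, aug = NULL, loss = loss_config(),
                         ablation = "full", K_overrides = NULL,
                         use_edge_weights = FALSE, verbose = FALSE) {
  ablation <- match.arg(ablation,
                        c("full", "noMask", "fMask", "eMask", "gMask", "noPPI"))
  if (is.null(aug)) aug <- aug_config(seed = seed)
  aug$mode <- switch(ablation, noMask = "none", fMask = "f", eMask = "e",
                     gMask = "g", aug$mode)
  structure(list(d = as.integer(d), H = as.integer(H), lr = lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 batches_per_epoch = if (is.null(batches_per_epoch)) NULL
                                     else as.integer(batches_per_epoch),
                 hidden = hidden %||% (2L * as.integer(d)),
                 dropout = dropout, seed = as.integer(seed), aug = aug,
                 loss = loss, ablation = ablation,
                 K_overrides = K_overrides,
                 use_edge_weights = use_edge_weights, verbose = verbose),
            class = "train_config")
}

#' Drug-pair representation
#'
#' z_(i,j) = z_i^C || z_i^F || z_j^C || z_j^F (length 4d). The concatenation
#' is order-dependent; during training each labeled pair is presented in both
#' orders, and at evaluation the two orders' probability vectors are averaged.
#'
#' @param Z_C,Z_F view embedding matrices.
#' @param i,j drug index vectors (equal length).
#' @return n x 4d matrix of pair representations.
#' @export
pair_embed <- function(Z_C, Z_F, i, j) {
  nd_cbind(list(nd_rows(Z_C, i), nd_rows(Z_F, i),
                nd_rows(Z_C, j), nd_rows(Z_F, j)))
}

softmax_rows <- function(L) {
  m <- apply(L, 1L, max)
  ex <- exp(L - m)
  ex / rowSums(ex)
}

# MLP forward pass: ReLU hidden layers (optional inverted dropout during
# training), linear output layer. Returns logits.
mlp_forward <- function(x, mlp, dropout = 0, training = FALSE) {
  nl <- length(mlp)
  for (i in seq_len(nl - 1L)) {
    x <- nd_relu(nd_add(nd_mm(x, mlp[[i]]$W), mlp[[i]]$b))
    if (training && dropout > 0) {
      xv <- ad_value(x)
      keep <- (matrix(stats::runif(length(xv)), nrow(xv)) >= dropout) / (1 - dropout)
      x <- nd_mul(x, keep)
    }
  }
  nd_add(nd_mm(x, mlp[[nl]]$W), mlp[[nl]]$b)
}

#' Predict event probabilities for pair representations
#'
#' Softmax(MLP(z_(i,j))): each row of the result sums to 1 and its argmax is
#' the predicted event. Rows are independent (no batch coupling).
#'
#' @param pair_vecs n x 4d matrix of pair representations.
#' @param head MLP parameter list (`$mlp` of [init_params()] output).
#' @return n x |E| probability matrix.
#' @export
predict_pairs <- function(pair_vecs, head) {
  softmax_rows(ad_value(mlp_forward(pair_vecs, head)))
}

## ---- splits ----------------------------------------------------------------

#' Task1 split: stratified instance hold-out
#'
#' For every event type, instances are split at the given ratios so all three
#' sets contain DDIs from all types. Events with fewer than 3 instances are
#' placed wholly in the training set with a warning.
#'
#' @param pairs data.frame with columns drug_a, drug_b, event.
#' @param ratios train/valid/test proportions (default 7:1:2).
#' @param seed RNG seed.
#' @return factor of levels train/valid/test, one per pair.
#' @export
split_task1 <- function(pairs, ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  if (!nrow(pairs)) stop("split_task1: empty dataset")
  stopifnot(abs(sum(ratios) - 1) < 1e-8)
  tags <- character(nrow(pairs))
  with_seed(derive_seed(seed, 101L), {
    for (ev in unique(pairs$event)) {
      idx <- which(pairs$event == ev)
      n <- length(idx)
      if (n < 3L) {
        warning(sprintf("event %s has %d instance(s): placed wholly in train",
                        as.character(ev), n))
        tags[idx] <- "train"
        next
      }
      n_test <- round(ratios[3] * n)
      n_val <- round(ratios[2] * n)
      if (n - n_test - n_val < 1L) n_test <- max(0L, n - n_val - 1L)
      idx <- sample(idx)
      tags[idx] <- c(rep("test", n_test), rep("valid", n_val),
                     rep("train", n - n_test - n_val))
    }
  })
  factor(tags, levels = c("train", "valid", "test"))
}

#' Task2/Task3 split: cold-start drug hold-out
#'
#' Drugs (not instances) are partitioned at the given ratios. Training pairs
#' have both drugs in the train set. Task2 test pairs have exactly one test
#' drug (the other in train); Task3 test pairs have both drugs in test;
#' validation is analogous with validation drugs. Pairs mixing validation and
#' test drugs (and pairs not matching the task's pattern) are discarded with a
#' logged count and tagged NA.
#'
#' @param pairs data.frame with columns drug_a, drug_b, event.
#' @param drug_ids all drug identifiers.
#' @param task 2 or 3.
#' @param ratios train/valid/test proportions.
#' @param seed RNG seed.
#' @return list with `split` (factor, NA = discarded), `drug_split` (named
#'   factor over drugs), `n_discarded`.
#' @export
split_task23 <- function(pairs, drug_ids, task = 2L,
                         ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  if (!nrow(pairs)) stop("split_task23: empty dataset")
  stopifnot(task %in% c(2L, 3L))
  nd <- length(drug_ids)
  n_test <- round(ratios[3] * nd)
  n_val <- round(ratios[2] * nd)
  if (nd - n_test - n_val < 1L || n_test < 1L || n_val < 1L) {
    stop("split_task23: a drug split would be empty")
  }
  dtag <- with_seed(derive_seed(seed, 102L), {
    perm <- sample(drug_ids)
    stats::setNames(factor(c(rep("test", n_test), rep("valid", n_val),
                             rep("train", nd - n_test - n_val)),
                           levels = c("train", "valid", "test")), perm)
  })
  ta <- dtag[as.character(pairs$drug_a)]
  tb <- dtag[as.character(pairs$drug_b)]
  tags <- rep(NA_character_, nrow(pairs))
  tags[ta == "train" & tb == "train"] <- "train"
  if (task == 2L) {
    one_test <- (ta == "test" & tb == "train") | (ta == "train" & tb == "test")
    one_val <- (ta == "valid" & tb == "train") | (ta == "train" & tb == "valid")
    tags[one_test] <- "test"
    tags[one_val] <- "valid"
  } else {
    tags[ta == "test" & tb == "test"] <- "test"
    tags[ta == "valid" & tb == "valid"] <- "valid"
  }
  n_disc <- sum(is.na(tags))
  vlog(sprintf("split_task23: discarded %d pair(s) not matching the task pattern",
               n_disc))
  list(split = factor(tags, levels = c("train", "valid", "test")),
       drug_split = dtag, n_discarded = n_disc)
}

## ---- optimizer -------------------------------------------------------------

adam_init <- function(theta) {
  list(m = rapply(theta, function(x) x * 0, how = "replace"),
       v = rapply(theta, function(x) x * 0, how = "replace"),
       t = 0L)
}

adam_rec <- function(p, w, m, v, lr, b1, b2, eps, t) {
  if (is.list(p)) {
    for (k in seq_along(p)) {
      r <- adam_rec(p[[k]], w[[k]], m[[k]], v[[k]], lr, b1, b2, eps, t)
      p[[k]] <- r$p; m[[k]] <- r$m; v[[k]] <- r$v
    }
    return(list(p = p, m = m, v = v))
  }
  g <- if (is_adnode(w) && !is.null(w$grad)) w$grad else p * 0
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mh <- m / (1 - b1^t)
  vh <- v / (1 - b2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

## ---- training --------------------------------------------------------------

#' Train the DDI event prediction model
#'
#' Per epoch: the clean sub-graph set is fixed, the corrupted set is rebuilt
#' by [build_augmented_set()], and mini-batches of training pairs (each
#' labeled pair in both orders) drive Adam steps on the combined loss
#' L = L_s + alpha (L_uc + L_sc). The average view is always encoded from the
#' clean set; the augmented view from the corrupted set. Deterministic given
#' `cfg$seed`.
#'
#' @param hg a `drug_hg`.
#' @param pairs data.frame with columns drug_a, drug_b, event.
#' @param split factor from [split_task1()]/[split_task23()] (`$split`);
#'   only "train" pairs are used.
#' @param cfg a [train_config()].
#' @return an object of class `mphgcl_model` with trained parameters, the
#'   clean sub-graph set, the event vocabulary and a per-epoch loss log.
#' @export
train_model <- function(hg, pairs, split, cfg = train_config()) {
  stopifnot(inherits(cfg, "train_config"))
  event_levels <- sort(unique(as.character(pairs$event)))
  y_all <- match(as.character(pairs$event), event_levels)
  ia_all <- match(as.character(pairs$drug_a), hg$drug_ids)
  ib_all <- match(as.character(pairs$drug_b), hg$drug_ids)
  if (anyNA(ia_all) || anyNA(ib_all)) stop("pair refers to unknown drug id")

  use_ppi <- cfg$ablation != "noPPI"
  sgs_clean <- build_subgraphs(hg, K_overrides = cfg$K_overrides,
                               use_ppi = use_ppi)
  aug <- cfg$aug
  aug$seed <- derive_seed(cfg$seed, 7L)

  tr <- which(split == "train")
  if (!length(tr)) stop("no training pairs")
  # both orderings of every labeled pair
  bi <- c(ia_all[tr], ib_all[tr])
  bj <- c(ib_all[tr], ia_all[tr])
  by <- c(y_all[tr], y_all[tr])

  params <- init_params(ncol(hg$X), cfg$d, cfg$H, length(event_levels),
                        sgs_clean$names, hidden = cfg$hidden,
                        seed = derive_seed(cfg$seed, 11L))
  hyper <- params$hyper
  theta <- params[setdiff(names(params), "hyper")]
  st <- adam_init(theta)
  Xc <- hg$X * 1

  log <- data.frame(epoch = integer(0), L_s = numeric(0), L_uc = numeric(0),
                    L_sc = numeric(0), L = numeric(0))
  for (epoch in seq_len(cfg$epochs)) {
    sgs_aug <- build_augmented_set(hg, sgs_clean, aug, epoch)
    ep <- with_seed(derive_seed(cfg$seed, 13L, epoch), {
      perm <- sample(length(by))
      nb <- ceiling(length(perm) / cfg$batch_size)
      batches <- base::split(perm, ceiling(seq_along(perm) / cfg$batch_size))
      if (nb > 1L && length(batches[[nb]]) < 2L) {
        batches[[nb - 1L]] <- c(batches[[nb - 1L]], batches[[nb]])
        batches[[nb]] <- NULL
      }
      bpe <- cfg$batches_per_epoch
      if (!is.null(bpe) && length(batches) > bpe) {
        batches <- batches[seq_len(bpe)]
      }
      acc <- c(L_s = 0, L_uc = 0, L_sc = 0, L = 0)
      for (b in batches) {
        wp <- wrap_params(theta)
        enc <- encode_views(Xc, sgs_clean, sgs_aug, wp,
                            use_edge_weights = cfg$use_edge_weights)
        emb <- pair_embed(enc$Z_C, enc$Z_F, bi[b], bj[b])
        logits <- mlp_forward(emb, wp$mlp, dropout = cfg$dropout,
                              training = TRUE)
        L_s <- nd_ce(logits, by[b])
        L_uc <- info_nce_views(enc$Z_C, enc$Z_F, cfg$loss$tau)
        L_sc <- if (length(b) >= 2L) {
          supervised_contrastive(emb, by[b], cfg$loss$tau)
        } else 0
        L <- total_loss(L_s, L_uc, L_sc, cfg$loss$alpha)
        if (!is.finite(ad_value(L))) {
          stop(sprintf("training diverged at epoch %d (L_s=%.4g, L_uc=%.4g, L_sc=%.4g)",
                       epoch, ad_value(L_s), ad_value(L_uc), ad_value(L_sc)))
        }
        ad_backward(L)
        st$t <- st$t + 1L
        r <- adam_rec(theta, wp, st$m, st$v, cfg$lr, 0.9, 0.999, 1e-8, st$t)
        theta <- r$p; st$m <- r$m; st$v <- r$v
        acc <- acc + c(ad_value(L_s), ad_value(L_uc), ad_value(L_sc),
                       ad_value(L)) / length(batches)
      }
      acc
    })
    log <- rbind(log, data.frame(epoch = epoch, L_s = ep[["L_s"]],
                                 L_uc = ep[["L_uc"]], L_sc = ep[["L_sc"]],
                                 L = ep[["L"]]))
    if (cfg$verbose && (epoch %% 10L == 0L || epoch == 1L)) {
      message(sprintf("epoch %d: L=%.4f (L_s=%.4f L_uc=%.4f L_sc=%.4f)",
                      epoch, ep[["L"]], ep[["L_s"]], ep[["L_uc"]], ep[["L_sc"]]))
    }
  }

  params <- c(theta, list(hyper = hyper))
  structure(list(params = params, cfg = cfg, sgs_clean = sgs_clean,
                 event_levels = event_levels, drug_ids = hg$drug_ids,
                 log = log),
            class = "mphgcl_model")
}

#' @export
print.mphgcl_model <- function(x, ...) {
  cat(sprintf("trained DDI event model: %d drugs, %d events, %d meta-paths, d=%d H=%d\n",
              length(x$drug_ids), length(x$event_levels),
              length(x$sgs_clean$names), x$params$hyper$d, x$params$hyper$H))
  cat(sprintf("  final loss: %.4f after %d epochs\n",
              utils::tail(x$log$L, 1L), nrow(x$log)))
  invisible(x)
}

#' Predict event probabilities for drug pairs
#'
#' Inference uses the clean (un-augmented) sub-graph set for both views;
#' augmentation is a training-time regularizer. The probability vectors of
#' the two pair orderings are averaged, so scores are symmetric in the pair.
#'
#' @param model an `mphgcl_model`.
#' @param hg the `drug_hg` the model was trained on.
#' @param pairs data.frame with columns drug_a, drug_b.
#' @return n x |E| probability matrix (columns named by event).
#' @export
predict_model <- function(model, hg, pairs) {
  i <- match(as.character(pairs$drug_a), hg$drug_ids)
  j <- match(as.character(pairs$drug_b), hg$drug_ids)
  if (anyNA(i) || anyNA(j)) stop("pair refers to unknown drug id")
  enc <- encode_views(hg$X * 1, model$sgs_clean, model$sgs_clean, model$params,
                      use_edge_weights = model$cfg$use_edge_weights)
  p1 <- predict_pairs(pair_embed(enc$Z_C, enc$Z_F, i, j), model$params$mlp)
  p2 <- predict_pairs(pair_embed(enc$Z_C, enc$Z_F, j, i), model$params$mlp)
  probs <- (p1 + p2) / 2
  colnames(probs) <- model$event_levels
  probs
}

## ---- metrics ---------------------------------------------------------------

# Micro-averaged area under the precision-recall curve over the one-vs-rest
# binarization, using the step-wise average-precision convention
# AP = sum_k (R_k - R_{k-1}) P_k.
micro_aupr <- function(scores, labels01) {
  ord <- order(-scores)
  l <- labels01[ord]
  pos <- sum(l)
  if (pos == 0) return(NA_real_)
  tp <- cumsum(l)
  prec <- tp / seq_along(l)
  rec <- tp / pos
  sum(diff(c(0, rec)) * prec)
}

#' Evaluate multi-class DDI event predictions
#'
#' Computes accuracy, micro-averaged AUPR over the one-vs-rest binarization,
#' and macro-averaged F1 / recall / precision over the event classes present
#' in the test labels (absent classes are excluded from the macro averages).
#' With `event_counts` and `bin_edges`, also reports macro-F1 per event
#' frequency group (see [group_events()]).
#'
#' @param probs n x |E| probability matrix.
#' @param labels length-n integer labels (1-based, matching columns).
#' @param event_counts optional named/positional per-event instance counts.
#' @param bin_edges optional frequency bin edges for grouped reporting.
#' @return list of class `ddi_metrics` with fields acc, aupr, macro_f1,
#'   macro_rec, macro_pre, per_event and (optionally) per_group.
#' @export
evaluate <- function(probs, labels, event_counts = NULL, bin_edges = NULL) {
  stopifnot(nrow(probs) == length(labels))
  nE <- ncol(probs)
  if (any(labels < 1L | labels > nE)) stop("label outside event vocabulary")
  pred <- max.col(probs, ties.method = "first")
  present <- sort(unique(labels))
  per <- data.frame(event = present, n = 0L, precision = 0, recall = 0, f1 = 0)
  for (r in seq_along(present)) {
    e <- present[r]
    tp <- sum(pred == e & labels == e)
    fp <- sum(pred == e & labels != e)
    fn <- sum(pred != e & labels == e)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    per$n[r] <- sum(labels == e)
    per$precision[r] <- prec
    per$recall[r] <- rec
    per$f1[r] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  onehot <- matrix(0, length(labels), nE)
  onehot[cbind(seq_along(labels), labels)] <- 1
  out <- list(acc = mean(pred == labels),
              aupr = micro_aupr(as.vector(probs), as.vector(onehot)),
              macro_f1 = mean(per$f1),
              macro_rec = mean(per$recall),
              macro_pre = mean(per$precision),
              per_event = per)
  if (!is.null(event_counts) && !is.null(bin_edges)) {
    grp <- group_events(event_counts, bin_edges)
    gids <- sort(unique(grp[present]))
    out$per_group <- data.frame(
      group = gids,
      macro_f1 = vapply(gids, function(g) {
        mean(per$f1[grp[present] == g])
      }, numeric(1)))
  }
  class(out) <- "ddi_metrics"
  out
}

#' @export
print.ddi_metrics <- function(x, ...) {
  cat(sprintf("acc=%.4f aupr=%.4f macro_f1=%.4f macro_rec=%.4f macro_pre=%.4f\n",
              x$acc, x$aupr, x$macro_f1, x$macro_rec, x$macro_pre))
  invisible(x)
}

#' Assign events to frequency groups
#'
#' Events are grouped by occurrence count into half-open bins defined by
#' `bin_edges = c(e1, ..., ek)`: the first bin is the closed interval
#' `[e1, e2]`, subsequent bins are `(e_i, e_i+1]`. Edges must be strictly
#' increasing (overlapping bins are an error) and cover all counts.
#'
#' @param event_counts per-event instance counts.
#' @param bin_edges strictly increasing numeric vector (last may be Inf).
#' @return integer group index per event (same names/order as
#'   `event_counts`).
#' @export
group_events <- function(event_counts, bin_edges) {
  if (any(diff(bin_edges) <= 0)) stop("overlapping or non-increasing bins")
  if (any(event_counts < bin_edges[1]) ||
      any(event_counts > bin_edges[length(bin_edges)])) {
    stop("bins do not cover all event counts")
  }
  inner <- bin_edges[-c(1L, length(bin_edges))]
  g <- 1L + vapply(event_counts, function(cnt) sum(cnt > inner), integer(1))
  stats::setNames(g, names(event_counts))
}

#' Metrics of the majority-class baseline
#'
#' Predicts the most frequent training event for every test pair; the
#' reference point for the planted-structure learning checks.
#'
#' @param train_labels,test_labels integer labels.
#' @param n_events vocabulary size.
#' @return a `ddi_metrics` list.
#' @export
majority_class_metrics <- function(train_labels, test_labels, n_events) {
  maj <- as.integer(names(which.max(table(train_labels))))
  probs <- matrix(0, length(test_labels), n_events)
  probs[, maj] <- 1
  evaluate(probs, test_labels)
}

#' Rank unobserved drug pairs per event
#'
#' Scores all unordered drug pairs absent from the labeled set (both
#' orderings averaged by [predict_model()]) and returns the top-n pairs per
#' event of interest, sorted by descending predicted probability.
#'
#' @param model an `mphgcl_model`.
#' @param hg the `drug_hg`.
#' @param known_pairs data.frame of labeled pairs to exclude.
#' @param top_n pairs to keep per event.
#' @param events events of interest (default: all).
#' @return data.frame with columns event, drug_a, drug_b, prob.
#' @export
rank_novel_pairs <- function(model, hg, known_pairs, top_n = 10L,
                             events = NULL) {
  n <- length(hg$drug_ids)
  all_pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ka <- match(as.character(known_pairs$drug_a), hg$drug_ids)
  kb <- match(as.character(known_pairs$drug_b), hg$drug_ids)
  known <- key(ka, kb)
  keep <- !(key(all_pairs[, 1], all_pairs[, 2]) %in% known)
  cand <- all_pairs[keep, , drop = FALSE]
  if (!nrow(cand)) return(data.frame(event = character(0), drug_a = character(0),
                                     drug_b = character(0), prob = numeric(0)))
  probs <- predict_model(model, hg,
                         data.frame(drug_a = hg$drug_ids[cand[, 1]],
                                    drug_b = hg$drug_ids[cand[, 2]]))
  if (is.null(events)) events <- model$event_levels
  out <- do.call(rbind, lapply(events, function(ev) {
    sc <- probs[, as.character(ev)]
    ord <- order(-sc)[seq_len(min(top_n, length(sc)))]
    data.frame(event = as.character(ev),
               drug_a = hg$drug_ids[cand[ord, 1]],
               drug_b = hg$drug_ids[cand[ord, 2]],
               prob = sc[ord])
  }))
  rownames(out) <- NULL
  out
}

#' Write a per-epoch loss log as JSON lines
#'
#' @param log the `$log` data.frame of a trained model.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_loss_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in seq_len(nrow(log))) {
    writeLines(jsonlite::toJSON(as.list(log[r, ]), auto_unbox = TRUE,
                                digits = NA), con)
  }
  invisible(path)
}
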
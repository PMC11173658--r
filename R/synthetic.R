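# Synthetic drug-interaction data with planted cluster structure.
#
# Drugs belong to latent clusters; every attribute node (substructure,
# target, enzyme, pathway) is owned by one cluster, and a drug carries an
# attribute with probability p_in (own cluster) or p_out (other clusters).
# PPI edges are denser within a cluster's target set. The event label of a
# drug pair is a deterministic function of its cluster pair, flipped with
# probability label_noise, and the cluster-pair-to-event map is drawn from a
# power-law so event frequencies are long-tailed. SMILES are random token
# strings (no chemical validity): the featurization path treats them as
# plain sequences.

#' Synthetic data configuration
#'
#' Defaults define the desk-scale study conditions used throughout the test
#' suite: 200 drugs in 4 clusters, 4 events, p_in = 0.6, p_out = 0.05,
#' label_noise = 0.05, and a pair sampling density of 0.2 (the interaction
#' density of the real reference data).
#'
#' @param n_drugs number of drugs.
#' @param n_clusters number of latent drug clusters (<= n_drugs).
#' @param n_attrs named list/vector of attribute-node counts per type
#'   (subset of C, P, E, T).
#' @param p_in within-cluster drug-attribute edge probability.
#' @param p_out background drug-attribute edge probability (< p_in).
#' @param ppi_density PPI edge probability within a cluster's target set.
#' @param ppi_background PPI edge probability across clusters.
#' @param n_events number of DDI event types (>= 2).
#' @param pair_density probability that an unordered drug pair is labeled.
#' @param label_noise probability that a pair's label is flipped to a
#'   different uniformly chosen event.
#' @param tail_exponent skew of the cluster-pair-to-event map: event e gets
#'   weight e^(-tail_exponent), producing a long-tailed frequency histogram.
#' @param seed RNG seed; output is a pure function of the configuration.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_drugs = 200L, n_clusters = 4L,
                         n_attrs = c(C = 40L, P = 30L, E = 20L, T = 15L),
                         p_in = 0.6, p_out = 0.05,
                         ppi_density = 0.3, ppi_background = 0.02,
                         n_events = 4L, pair_density = 0.2,
                         label_noise = 0.05, tail_exponent = 1.5,
                         seed = 7L) {
  stopifnot(p_in > p_out, p_in <= 1, p_out >= 0, n_events >= 2,
            pair_density > 0, pair_density <= 1,
            label_noise >= 0, label_noise < 1)
  if (n_clusters > n_drugs) stop("more clusters than drugs")
  n_cp <- n_clusters * (n_clusters + 1) / 2
  if (n_cp < n_events) {
    stop("fewer cluster pairs than events: labels could not cover the vocabulary")
  }
  structure(as.list(environment())[c("n_drugs", "n_clusters", "n_attrs",
                                     "p_in", "p_out", "ppi_density",
                                     "ppi_background", "n_events",
                                     "pair_density", "label_noise",
                                     "tail_exponent", "seed")],
            class = "synth_config")
}

random_smiles <- function(n) {
  alphabet <- c("C", "N", "O", "S", "c", "n", "o", "(", ")", "=", "1", "2")
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, sample(8:20, 1L), replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate a synthetic drug HG and labeled pair set
#'
#' @param cfg a [synth_config()].
#' @return list with `hg` (a `drug_hg`), `pairs` (data.frame drug_a, drug_b,
#'   event), and `truth` (cluster assignment, clean labels, cluster-pair
#'   event map) for recovery tests.
#' @export
generate_synthetic <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_drugs
    k <- cfg$n_clusters
    drug_ids <- sprintf("d%03d", seq_len(n))
    # guarantee nonempty clusters, then assign the rest uniformly
    cl <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))

    M <- list()
    attr_ids <- list()
    type_key <- c(C = "DC", P = "DP", E = "DE", T = "DT")
    for (ty in names(cfg$n_attrs)) {
      na <- cfg$n_attrs[[ty]]
      if (na <= 0) next
      owner <- rep_len(seq_len(k), na)
      pm <- matrix(cfg$p_out, n, na)
      pm[outer(cl, owner, `==`)] <- cfg$p_in
      m <- (matrix(stats::runif(n * na), n, na) < pm) * 1
      dimnames(m) <- list(drug_ids, sprintf("%s%03d", tolower(ty), seq_len(na)))
      # attribute nodes with no incident drug are unobservable in the TSV
      # representation; drop them so fixtures round-trip exactly
      m <- m[, colSums(m) > 0, drop = FALSE]
      M[[type_key[[ty]]]] <- m
      attr_ids[[type_key[[ty]]]] <- colnames(m)
    }
    if (is.null(M$DC) || is.null(M$DP)) {
      stop("synthetic config must include C and P attribute types")
    }

    np <- ncol(M$DP)
    p_owner <- rep_len(seq_len(k), cfg$n_attrs[["P"]])
    p_owner <- p_owner[match(colnames(M$DP),
                             sprintf("p%03d", seq_len(cfg$n_attrs[["P"]])))]
    PP <- matrix(0, np, np, dimnames = list(colnames(M$DP), colnames(M$DP)))
    for (p in seq_len(np - 1L)) {
      for (q in (p + 1L):np) {
        pr <- if (p_owner[p] == p_owner[q]) cfg$ppi_density else cfg$ppi_background
        if (stats::runif(1) < pr) PP[p, q] <- PP[q, p] <- 1
      }
    }

    smiles <- random_smiles(n)

    # cluster-pair -> event map: each event covered at least once, the rest
    # drawn from a power-law so frequencies are long-tailed
    cps <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
    w <- seq_len(cfg$n_events)^(-cfg$tail_exponent)
    ev_map <- integer(nrow(cps))
    first <- sample(nrow(cps), cfg$n_events)
    ev_map[first] <- seq_len(cfg$n_events)
    rest <- setdiff(seq_len(nrow(cps)), first)
    if (length(rest)) {
      ev_map[rest] <- sample.int(cfg$n_events, length(rest), replace = TRUE,
                                 prob = w)
    }
    cp_index <- matrix(0L, k, k)
    cp_index[cps] <- seq_len(nrow(cps))
    cp_index[cps[, c(2, 1), drop = FALSE]] <- seq_len(nrow(cps))

    ap <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(ap)) < cfg$pair_density
    ap <- ap[keep, , drop = FALSE]
    clean <- ev_map[cp_index[cbind(cl[ap[, 1]], cl[ap[, 2]])]]
    ev <- clean
    flip <- stats::runif(length(ev)) < cfg$label_noise
    if (any(flip) && cfg$n_events > 1L) {
      ev[flip] <- vapply(ev[flip], function(e) {
        sample(setdiff(seq_len(cfg$n_events), e), 1L)
      }, integer(1))
    }

    vocab <- espf_fit(smiles, min_freq = 2L, max_size = 512L)
    X <- t(vapply(smiles, espf_encode, integer(length(vocab$tokens)),
                  vocab = vocab))
    rownames(X) <- drug_ids

    hg <- structure(list(drug_ids = drug_ids,
                         smiles = stats::setNames(smiles, drug_ids),
                         attr_ids = attr_ids, M = M, M_PP = PP, X = X,
                         vocab = vocab),
                    class = "drug_hg")
    validate_drug_hg(hg)
    pairs <- data.frame(drug_a = drug_ids[ap[, 1]], drug_b = drug_ids[ap[, 2]],
                        event = sprintf("e%02d", ev),
                        stringsAsFactors = FALSE)
    list(hg = hg, pairs = pairs,
         truth = list(cluster = stats::setNames(cl, drug_ids),
                      clean_event = sprintf("e%02d", clean),
                      event_map = ev_map))
  })
}

#' Write a synthetic dataset as the TSV fixture consumed by the builder
#'
#' Emits drugs.tsv, drug_attr_*.tsv, ppi.tsv (via [write_drug_hg()]) plus
#' ddis.tsv (drug_a, drug_b, event_id), so the full build path can be
#' exercised from files.
#'
#' @param synth output of [generate_synthetic()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(synth, dir) {
  write_drug_hg(synth$hg, dir)
  utils::write.table(synth$pairs, file.path(dir, "ddis.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(dir)
}
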
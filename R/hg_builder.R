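# Drug heterogeneous graph construction.
#
# The drug HG has five node types — drug (D), chemical substructure (C),
# target protein (P), enzyme (E), transport pathway (T) — and edge types
# {D-C, D-P, D-E, D-T, P-P}. It is represented as binary incidence matrices
# (rows in drug order, columns in first-appearance order of the attribute
# ids), a symmetric zero-diagonal protein-protein interaction matrix over the
# drug-target protein universe, and a binary drug feature matrix X from
# substructure featurization of SMILES.

read_two_col_tsv <- function(path, what = "table", header = FALSE) {
  lines <- readLines(path, warn = FALSE)
  if (header && length(lines)) lines <- lines[-1L]
  lines_keep <- which(nzchar(trimws(lines)))
  parts <- strsplit(lines[lines_keep], "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad)) {
    stop(sprintf("%s: malformed line %d in %s (expected 2 tab-separated fields)",
                 what, lines_keep[bad[1]] + if (header) 1L else 0L, path))
  }
  data.frame(a = vapply(parts, `[[`, character(1), 1L),
             b = vapply(parts, `[[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

as_two_col <- function(x, what, header = FALSE) {
  if (is.character(x) && length(x) == 1L) {
    read_two_col_tsv(x, what = what, header = header)
  } else {
    stopifnot(is.data.frame(x), ncol(x) >= 2L)
    data.frame(a = as.character(x[[1]]), b = as.character(x[[2]]),
               stringsAsFactors = FALSE)
  }
}

#' Load a drug-attribute incidence table
#'
#' Reads a two-column TSV (drug_id, attribute_id) into a binary incidence
#' matrix. Rows follow `drug_ids` order; columns follow first appearance of
#' each attribute id in the file, so the matrix is a pure function of file
#' content. Duplicate (drug, attribute) rows collapse to a single 1; a drug id
#' absent from `drug_ids` is an error naming the id.
#'
#' @param path file path or two-column data.frame.
#' @param drug_ids ordered character vector of known drug identifiers.
#' @param header does the file carry a header line to skip?
#' @return binary matrix `length(drug_ids)` x n_attributes, with dimnames.
#' @export
load_attribute_table <- function(path, drug_ids, header = FALSE) {
  df <- as_two_col(path, what = "attribute table", header = header)
  if (!nrow(df)) {
    warning("attribute table is empty: 0-column incidence matrix")
    return(matrix(0, length(drug_ids), 0, dimnames = list(drug_ids, NULL)))
  }
  unknown <- setdiff(unique(df$a), drug_ids)
  if (length(unknown)) {
    stop(sprintf("attribute table refers to unknown drug id(s): %s",
                 paste(utils::head(unknown, 5L), collapse = ", ")))
  }
  attr_ids <- unique(df$b)
  M <- matrix(0, length(drug_ids), length(attr_ids),
              dimnames = list(drug_ids, attr_ids))
  M[cbind(match(df$a, drug_ids), match(df$b, attr_ids))] <- 1
  M
}

#' Load a protein-protein interaction edge list
#'
#' Two-column TSV of protein id pairs. Pairs involving a protein outside
#' `protein_ids` and self-pairs are dropped (counts logged via message). The
#' result is symmetric with zero diagonal.
#'
#' @param path file path or two-column data.frame.
#' @param protein_ids ordered protein identifier universe.
#' @param header skip a header line?
#' @return binary symmetric matrix with zero diagonal.
#' @export
load_ppi <- function(path, protein_ids, header = FALSE) {
  df <- as_two_col(path, what = "PPI table", header = header)
  M <- matrix(0, length(protein_ids), length(protein_ids),
              dimnames = list(protein_ids, protein_ids))
  if (!nrow(df)) return(M)
  known <- df$a %in% protein_ids & df$b %in% protein_ids
  if (any(!known)) {
    vlog(sprintf("load_ppi: dropped %d pair(s) with unknown protein", sum(!known)))
  }
  df <- df[known, , drop = FALSE]
  self <- df$a == df$b
  if (any(self)) {
    vlog(sprintf("load_ppi: dropped %d self-interaction pair(s)", sum(self)))
  }
  df <- df[!self, , drop = FALSE]
  if (nrow(df)) {
    i <- match(df$a, protein_ids)
    j <- match(df$b, protein_ids)
    M[cbind(i, j)] <- 1
    M[cbind(j, i)] <- 1
  }
  M
}

#' Assemble the drug heterogeneous graph
#'
#' Builds a `drug_hg` from a drug list with SMILES, per-type attribute tables
#' (chemical substructure and target protein required; enzyme and pathway
#' optional), and an optional PPI edge list. The protein universe is the set
#' of drug-target proteins; PPI pairs among never-targeted proteins are
#' dropped. Drug features are substructure-presence vectors from
#' [espf_fit()]/[espf_encode()], or a caller-supplied |D| x F matrix.
#'
#' @param drugs path or data.frame with columns drug_id, smiles.
#' @param chem,target,enzyme,pathway attribute tables (path or data.frame);
#'   `enzyme`/`pathway` may be NULL (the corresponding meta-paths then become
#'   unavailable).
#' @param ppi PPI edge list (path or data.frame) or NULL.
#' @param espf list with `min_freq` and `max_size` for vocabulary fitting.
#' @param features optional precomputed binary feature matrix (|D| x F),
#'   bypassing SMILES featurization.
#' @param header do the TSV files carry header lines?
#' @return an object of class `drug_hg`.
#' @export
build_drug_hg <- function(drugs, chem, target, enzyme = NULL, pathway = NULL,
                          ppi = NULL, espf = list(min_freq = 2L, max_size = 2048L),
                          features = NULL, header = FALSE) {
  ddf <- as_two_col(drugs, what = "drug table", header = header)
  drug_ids <- ddf$a
  if (anyDuplicated(drug_ids)) stop("duplicate drug ids in drug table")
  smiles <- ddf$b
  names(smiles) <- drug_ids

  M <- list()
  M$DC <- load_attribute_table(chem, drug_ids, header = header)
  M$DP <- load_attribute_table(target, drug_ids, header = header)
  if (!is.null(enzyme)) M$DE <- load_attribute_table(enzyme, drug_ids, header = header)
  if (!is.null(pathway)) M$DT <- load_attribute_table(pathway, drug_ids, header = header)

  protein_ids <- colnames(M$DP)
  M_PP <- if (is.null(ppi)) {
    matrix(0, length(protein_ids), length(protein_ids),
           dimnames = list(protein_ids, protein_ids))
  } else {
    load_ppi(ppi, protein_ids, header = header)
  }

  if (is.null(features)) {
    vocab <- espf_fit(smiles, min_freq = espf$min_freq %||% 2L,
                      max_size = espf$max_size %||% 2048L)
    X <- t(vapply(smiles, function(s) {
      if (is.na(s) || !nzchar(s)) integer(length(vocab$tokens)) else espf_encode(s, vocab)
    }, integer(length(vocab$tokens))))
    if (ncol(X) == 0L) stop("empty feature vocabulary")
    rownames(X) <- drug_ids
  } else {
    X <- as.matrix(features)
    stopifnot(nrow(X) == length(drug_ids))
    rownames(X) <- drug_ids
    vocab <- NULL
  }

  deg <- Reduce(`+`, lapply(M, rowSums))
  if (any(deg == 0)) {
    vlog(sprintf("build_drug_hg: %d drug(s) with no attributes (isolated in all sub-graphs)",
                 sum(deg == 0)))
  }

  hg <- structure(list(
    drug_ids = drug_ids,
    smiles = smiles,
    attr_ids = lapply(M, colnames),
    M = M,
    M_PP = M_PP,
    X = X,
    vocab = vocab
  ), class = "drug_hg")
  validate_drug_hg(hg)
  hg
}

#' Validate drug_hg invariants
#'
#' Checks that all incidence matrices are 0/1, that the PPI matrix is
#' symmetric with zero diagonal, and that shapes are consistent.
#' @param hg a `drug_hg`.
#' @return `hg`, invisibly.
#' @export
validate_drug_hg <- function(hg) {
  stopifnot(inherits(hg, "drug_hg"))
  for (nm in names(hg$M)) {
    m <- hg$M[[nm]]
    if (!all(m %in% c(0, 1))) stop(sprintf("incidence matrix %s is not binary", nm))
    if (nrow(m) != length(hg$drug_ids)) stop(sprintf("matrix %s row mismatch", nm))
  }
  if (!isTRUE(all.equal(hg$M_PP, t(hg$M_PP)))) stop("M_PP is not symmetric")
  if (any(diag(hg$M_PP) != 0)) stop("M_PP has nonzero diagonal")
  if (!all(hg$M_PP %in% c(0, 1))) stop("M_PP is not binary")
  if (nrow(hg$X) != length(hg$drug_ids)) stop("feature matrix row mismatch")
  invisible(hg)
}

#' @export
print.drug_hg <- function(x, ...) {
  cat(sprintf("drug heterogeneous graph: %d drugs\n", length(x$drug_ids)))
  for (nm in names(x$M)) {
    cat(sprintf("  %s: %d attributes, %d incidences\n", nm, ncol(x$M[[nm]]),
                sum(x$M[[nm]])))
  }
  cat(sprintf("  PPI: %d proteins, %d interactions\n", nrow(x$M_PP),
              sum(x$M_PP) / 2))
  cat(sprintf("  features: %d dimensions\n", ncol(x$X)))
  invisible(x)
}

#' Write a drug_hg back to its TSV table representation
#'
#' Emits drugs.tsv, drug_attr_C/P/E/T.tsv (present types only) and ppi.tsv in
#' the exact formats accepted by [build_drug_hg()], so that a write/reload
#' round trip reproduces the matrices.
#'
#' @param hg a `drug_hg`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_drug_hg <- function(hg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(data.frame(hg$drug_ids, unname(hg$smiles)),
                     file.path(dir, "drugs.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  type_file <- c(DC = "drug_attr_C.tsv", DP = "drug_attr_P.tsv",
                 DE = "drug_attr_E.tsv", DT = "drug_attr_T.tsv")
  for (nm in names(hg$M)) {
    m <- hg$M[[nm]]
    idx <- which(m > 0, arr.ind = TRUE)
    # column-major order: each attribute id first appears in file in the same
    # order as the matrix columns, so reload preserves column order
    idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
    utils::write.table(data.frame(d = rownames(m)[idx[, 1]],
                                  a = colnames(m)[idx[, 2]]),
                       file.path(dir, type_file[[nm]]), sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  ed <- adj_to_edges(hg$M_PP)
  utils::write.table(data.frame(p = rownames(hg$M_PP)[ed[, 1]],
                                q = colnames(hg$M_PP)[ed[, 2]]),
                     file.path(dir, "ppi.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(dir)
}
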
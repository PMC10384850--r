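#' Tanimoto coefficient between two binary fingerprints
#'
#' The set-overlap similarity |A intersect B| / |A union B| of the on-bit
#' sets of two equal-length bit vectors. By convention two all-zero
#' fingerprints are treated as identical molecules and return 1.0 (this
#' keeps the similarity-matrix diagonal at unity); an all-zero vector
#' against a non-empty one returns 0.
#'
#' @param a,b Equal-length 0/1 vectors.
#' @return A similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop("fingerprints differ in length", call. = FALSE)
  }
  a <- as.logical(a); b <- as.logical(b)
  uni <- sum(a | b)
  if (uni == 0) return(1.0)
  sum(a & b) / uni
}

#' All-against-all Tanimoto similarity matrix as a feature space
#'
#' Builds the N x N matrix of Tanimoto coefficients between every pair of
#' molecules, including the trivial self-similarities of 1.0 on the
#' diagonal so that row i is a consistent N-dimensional feature vector for
#' molecule i. At full scale (N = 11,268) this matrix holds 11,268^2 =
#' 126,967,824 coefficients.
#'
#' @param fingerprints Integer 0/1 matrix (one fingerprint per row) or a
#'   list of equal-length 0/1 vectors.
#' @param ids Optional molecule identifiers (defaults to row names, then
#'   `mol1..molN`).
#' @return A `"feature_space"` object: a list with `matrix` (N x N,
#'   symmetric, unit diagonal) and `ids`.
#' @export
tanimoto_matrix <- function(fingerprints, ids = NULL) {
  if (is.list(fingerprints)) {
    lens <- unique(lengths(fingerprints))
    if (length(fingerprints) == 0L) stop("empty fingerprint set", call. = FALSE)
    if (length(lens) != 1L) stop("fingerprints differ in length", call. = FALSE)
    fingerprints <- do.call(rbind, fingerprints)
  }
  stopifnot(is.matrix(fingerprints))
  if (nrow(fingerprints) == 0L) stop("empty fingerprint set", call. = FALSE)
  if (is.null(ids)) {
    ids <- rownames(fingerprints)
    if (is.null(ids)) ids <- paste0("mol", seq_len(nrow(fingerprints)))
  }
  X <- fingerprints
  storage.mode(X) <- "double"
  inter <- tcrossprod(X)            # |A & B| via bit counts
  on <- rowSums(X)
  uni <- outer(on, on, "+") - inter # inclusion-exclusion
  tc <- ifelse(uni > 0, inter / uni, 0)
  # all-zero fingerprints: self-similarity 1 (degenerate convention)
  diag(tc) <- 1
  zero <- which(on == 0)
  if (length(zero) > 1L) tc[zero, zero] <- 1
  dimnames(tc) <- list(ids, ids)
  structure(list(matrix = tc, ids = ids), class = "feature_space")
}

#' Row-select train/test feature matrices from a feature space
#'
#' Selects the feature-vector rows for training and testing molecules
#' from the full N x N similarity matrix. Columns are deliberately NOT
#' subset: every feature vector keeps the full dimensionality N, exactly
#' as the similarity-matrix feature space defines it (the feature axes
#' are the molecules of the whole collection). This transductive design
#' means test molecules contribute feature *columns* to training vectors;
#' see the methods vignette for the information-leakage implication.
#'
#' @param space A [tanimoto_matrix()] result.
#' @param train_ids,test_ids Disjoint subsets of `space$ids`.
#' @return List with `train` and `test` matrices (rows in the order of
#'   the requested ids, N columns each).
#' @export
split_feature_rows <- function(space, train_ids, test_ids) {
  stopifnot(inherits(space, "feature_space"))
  unknown <- setdiff(c(train_ids, test_ids), space$ids)
  if (length(unknown) > 0) {
    stop("unknown molecule ids: ", paste(head(unknown, 5), collapse = ", "),
         call. = FALSE)
  }
  if (length(intersect(train_ids, test_ids)) > 0) {
    stop("train and test ids overlap", call. = FALSE)
  }
  list(train = space$matrix[train_ids, , drop = FALSE],
       test = space$matrix[test_ids, , drop = FALSE])
}
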
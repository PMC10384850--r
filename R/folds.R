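#' Stratify an imbalanced dataset into balanced folds plus a permanent pool
#'
#' Constructs `k` disjoint folds, each holding exactly
#' `floor(n_minority / k)` molecules of *each* class, by seeded sampling
#' without replacement. Every unassigned majority-class (non-mutagenic)
#' molecule goes to a pool of permanent testing data that is appended to
#' the test set of every cross-validation iteration and never trains a
#' model. With the full-scale class counts (1,080 mutagenic, 10,188
#' non-mutagenic, k = 5) each fold holds 216 + 216 = 432 molecules and
#' the pool holds 9,108.
#'
#' If the minority count is not divisible by `k`, the at most `k - 1`
#' leftover molecules are dropped from fold assignment: leftover
#' majority-class molecules join the pool, leftover minority-class
#' molecules are excluded entirely (with a warning), preserving perfect
#' class balance in every training set.
#'
#' @param labels Named integer vector (or 0/1 vector with names) mapping
#'   molecule id to binary label, 1 = mutagenic (minority).
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the stratified shuffle.
#' @return A `"fold_plan"`: list with `k`, `fold_members` (list of k id
#'   vectors), `pool` (id vector), `excluded` (id vector, normally
#'   empty), `labels`, `seed`.
#' @export
build_folds <- function(labels, k = 5L, seed = 1L) {
  k <- assert_count(k, "k", min = 2L)
  if (is.null(names(labels))) stop("`labels` must be named by molecule id",
                                   call. = FALSE)
  stopifnot(all(labels %in% c(0L, 1L)))
  ids1 <- names(labels)[labels == 1]
  ids0 <- names(labels)[labels == 0]
  n_min <- min(length(ids1), length(ids0))
  if (n_min < k) {
    stop("minority class has fewer molecules than folds", call. = FALSE)
  }
  per_fold <- n_min %/% k
  with_seed(seed, {
    ids1 <- sample(ids1)
    ids0 <- sample(ids0)
  })
  take <- function(ids, f) ids[((f - 1L) * per_fold + 1L):(f * per_fold)]
  fold_members <- lapply(seq_len(k), function(f) c(take(ids1, f),
                                                   take(ids0, f)))
  used1 <- k * per_fold
  leftover1 <- if (length(ids1) > used1) ids1[(used1 + 1L):length(ids1)]
               else character(0)
  pool <- ids0[-seq_len(used1)]
  excluded <- character(0)
  if (length(leftover1) > 0) {
    warning(sprintf(
      "minority count %d not divisible by k = %d: excluding %d mutagenic molecule(s) to keep training folds balanced",
      length(ids1), k, length(leftover1)), call. = FALSE)
    excluded <- leftover1
  }
  structure(list(k = k, fold_members = fold_members, pool = pool,
                 excluded = excluded, labels = labels,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' Train/test molecule ids for one cross-validation iteration
#'
#' Iteration `i` tests on fold `i` plus the permanent pool and trains on
#' the remaining `k - 1` folds, so every training set is exactly
#' class-balanced while the test set keeps the natural imbalance. At full
#' scale this makes the training set 1,728 of 11,268 molecules (15% of
#' the data) and the test set 9,540 (85%).
#'
#' @param plan A [build_folds()] plan.
#' @param i Fold index in `1..k` used as the held-out test fold.
#' @return List with `train` and `test` id vectors (disjoint).
#' @export
iteration_split <- function(plan, i) {
  stopifnot(inherits(plan, "fold_plan"))
  i <- assert_count(i, "i")
  if (i > plan$k) stop("fold index out of range", call. = FALSE)
  train <- unlist(plan$fold_members[-i], use.names = FALSE)
  test <- c(plan$fold_members[[i]], plan$pool)
  list(train = train, test = test)
}

#' Serialise / restore a fold plan as JSON
#'
#' @param plan A [build_folds()] plan.
#' @param path JSON file path.
#' @return `read_fold_plan()` returns the restored `"fold_plan"`.
#' @export
write_fold_plan <- function(plan, path) {
  stopifnot(inherits(plan, "fold_plan"))
  jsonlite::write_json(
    list(k = plan$k, fold_members = plan$fold_members, pool = plan$pool,
         excluded = plan$excluded,
         labels = as.list(plan$labels), seed = plan$seed),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  labels <- vapply(x$labels, function(v) as.integer(v), integer(1))
  structure(list(k = as.integer(x$k),
                 fold_members = lapply(x$fold_members, function(f)
                   as.character(unlist(f))),
                 pool = as.character(unlist(x$pool)),
                 excluded = as.character(unlist(x$excluded)),
                 labels = labels, seed = as.integer(x$seed)),
            class = "fold_plan")
}
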
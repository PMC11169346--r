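#' Preallocated repeated nested stratified cross-validation plan
#'
#' Builds the fold assignments shared by every model so that paired
#' comparisons across repeats are equitable: the identical plan object is
#' consumed by the CNN, the SVMs and the fusion stages. Stratification uses
#' the four granular severity categories; within each stratum members are
#' shuffled and dealt so that per-stratum counts across folds differ by at
#' most one, and remainders go to the currently smallest folds so overall
#' fold sizes also differ by at most one (231 subjects over 6 outer folds
#' gives test folds of 38-39; outer training sets of 192-193 over 8 inner
#' folds give held-out inner folds of 24-25).
#'
#' @param category4_labels Character/factor vector of granular severity
#'   categories, one per subject.
#' @param n_repeats Number of cross-validation repeats (default 20).
#' @param n_outer Outer (test) folds (default 6).
#' @param n_inner Inner (tuning) folds (default 8).
#' @param val_frac Validation fraction of the outer training set used when
#'   retraining the CNN (default 0.3).
#' @param seed Integer seed; repeat `r` draws from seed `seed + r`.
#' @return A `partition_plan` with elements `outer` (subjects x repeats fold
#'   matrix), `inner` (nested lists of inner-fold ids over the outer training
#'   set) and `val` (train/validation flags for the 70/30 resplit).
#' @export
build_nested_partitions <- function(category4_labels, n_repeats = 20,
                                    n_outer = 6, n_inner = 8,
                                    val_frac = 0.3, seed = 1L) {
  n <- length(category4_labels)
  if (n_outer > n) stop("build_nested_partitions: more outer folds than subjects")
  strata <- as.character(category4_labels)
  outer <- matrix(NA_integer_, n, n_repeats)
  inner <- vector("list", n_repeats)
  val <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    set.seed(seed + r)
    outer[, r] <- stratified_fold_ids(strata, n_outer)
    inner[[r]] <- vector("list", n_outer)
    val[[r]] <- vector("list", n_outer)
    for (f in seq_len(n_outer)) {
      train_ids <- which(outer[, r] != f)
      inn <- rep(NA_integer_, n)
      inn[train_ids] <- stratified_fold_ids(strata[train_ids], n_inner)
      inner[[r]][[f]] <- inn
      # singleton strata cannot be split; pool them into the modal stratum
      lab <- strata[train_ids]
      tt <- table(lab)
      if (any(tt < 2))
        lab[lab %in% names(tt)[tt < 2]] <- names(tt)[which.max(tt)]
      sp <- resplit_for_validation(train_ids, lab, val_frac)
      flag <- rep(NA_character_, n)
      flag[sp$train_ids] <- "train"
      flag[sp$val_ids] <- "val"
      val[[r]][[f]] <- flag
    }
  }
  structure(list(n_subjects = n, n_repeats = n_repeats, n_outer = n_outer,
                 n_inner = n_inner, val_frac = val_frac, seed = seed,
                 strata = strata, outer = outer, inner = inner, val = val),
            class = "partition_plan")
}

# Stratified fold assignment: within each stratum shuffle then fill equal
# quotas; per-stratum remainders go to the folds with the smallest running
# totals, which keeps overall fold sizes within one of each other.
stratified_fold_ids <- function(strata, n_folds) {
  n <- length(strata)
  fold <- integer(n)
  totals <- integer(n_folds)
  for (s in sort(unique(strata))) {
    ids <- which(strata == s)
    ids <- ids[sample.int(length(ids))]
    ns <- length(ids)
    quota <- rep(ns %/% n_folds, n_folds)
    rem <- ns %% n_folds
    if (rem > 0) {
      take <- order(totals, runif(n_folds))[seq_len(rem)]
      quota[take] <- quota[take] + 1L
    }
    assign_fold <- rep(seq_len(n_folds), times = quota)
    fold[ids] <- assign_fold
    totals <- totals + quota
  }
  fold
}

#' Stratified train/validation resplit
#'
#' Single stratified split of an outer training set, used to hold out
#' validation data for CNN early stopping. The validation size is
#' `round(frac * n)`, with per-stratum quotas by largest remainder.
#'
#' @param outer_train_ids Subject indices of the outer training set.
#' @param labels Stratification labels aligned with `outer_train_ids`.
#' @param frac Validation fraction in (0, 1).
#' @param seed Optional seed (omit to use the current RNG state).
#' @return List with `train_ids` and `val_ids`.
#' @export
resplit_for_validation <- function(outer_train_ids, labels, frac, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(frac > 0, frac < 1)
  n <- length(outer_train_ids)
  target <- round(frac * n)
  strata <- as.character(labels)
  lev <- sort(unique(strata))
  ns <- vapply(lev, function(s) sum(strata == s), 0L)
  if (any(ns < 2)) stop("resplit_for_validation: stratum smaller than 2")
  ideal <- frac * ns
  quota <- floor(ideal)
  rem <- target - sum(quota)
  if (rem > 0) {
    take <- order(ideal - quota, decreasing = TRUE)[seq_len(rem)]
    quota[take] <- quota[take] + 1L
  } else if (rem < 0) {
    give <- order(ideal - quota)[seq_len(-rem)]
    quota[give] <- quota[give] - 1L
  }
  val <- integer(0)
  for (i in seq_along(lev)) {
    ids <- outer_train_ids[strata == lev[i]]
    ids <- ids[sample.int(length(ids))]
    val <- c(val, ids[seq_len(quota[i])])
  }
  list(train_ids = sort(setdiff(outer_train_ids, val)), val_ids = sort(val))
}

#' Look up one outer fold of a partition plan
#'
#' @param plan A `partition_plan`.
#' @param repeat_ix Repeat index (1-based).
#' @param fold Outer fold index.
#' @return List with `train_ids`, `test_ids`, `inner_fold` (inner fold id per
#'   training subject), `retrain_train_ids`, `retrain_val_ids`.
#' @export
plan_fold <- function(plan, repeat_ix, fold) {
  test_ids <- which(plan$outer[, repeat_ix] == fold)
  train_ids <- which(plan$outer[, repeat_ix] != fold)
  inn <- plan$inner[[repeat_ix]][[fold]][train_ids]
  flag <- plan$val[[repeat_ix]][[fold]]
  list(train_ids = train_ids, test_ids = test_ids,
       inner_fold = inn,
       retrain_train_ids = which(!is.na(flag) & flag == "train"),
       retrain_val_ids = which(!is.na(flag) & flag == "val"))
}

#' Serialize / deserialize a partition plan as JSON
#'
#' @param plan A `partition_plan`.
#' @param path Output path.
#' @return `write_plan` returns `path` invisibly; `read_plan` a
#'   `partition_plan` whose [object_hash()] equals the original's.
#' @export
write_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  to_int <- function(l) vapply(l, function(e)
    if (is.null(e)) NA_integer_ else as.integer(e), integer(1))
  to_chr <- function(l) vapply(l, function(e)
    if (is.null(e)) NA_character_ else as.character(e), character(1))
  structure(list(
    n_subjects = as.integer(x$n_subjects),
    n_repeats = as.integer(x$n_repeats),
    n_outer = as.integer(x$n_outer),
    n_inner = as.integer(x$n_inner),
    val_frac = as.numeric(x$val_frac),
    seed = as.integer(x$seed),
    strata = to_chr(x$strata),
    outer = do.call(rbind, lapply(x$outer, to_int)),
    inner = lapply(x$inner, function(rep_l) lapply(rep_l, to_int)),
    val = lapply(x$val, function(rep_l) lapply(rep_l, to_chr))),
    class = "partition_plan")
}
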
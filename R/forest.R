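# Bagged decision-tree ensemble producing the miR-CERVIX score: the mean,
# over trees, of the leaf HSIL-probability reached by a sample's nine
# predictors. Tree growing lives in src/forest.cpp; this file owns seed
# derivation, class bookkeeping, cross-validation and serialization.

CLASS_ORDER <- c("NILM", "HSIL")

# diagnosis labels -> 0 (NILM) / 1 (HSIL) integer vector
encode_labels <- function(y) {
  y <- as.character(y)
  if (!all(y %in% CLASS_ORDER)) {
    stop("labels must be NILM or HSIL; got: ",
         paste(setdiff(unique(y), CLASS_ORDER), collapse = ", "))
  }
  as.integer(y == "HSIL")
}

#' Fit a single decision tree
#'
#' Greedy recursive binary partitioning on the training rows as given (no
#' bootstrap): at each node `features_per_split` predictor indices are
#' drawn without replacement and the (feature, threshold) pair minimising
#' the Gini impurity of the split is taken; growing stops at pure nodes,
#' nodes smaller than `2 * min_leaf`, or `max_depth`. Leaves store the HSIL
#' class frequency.
#'
#' @param X numeric n x 9 predictor matrix.
#' @param y labels (`NILM`/`HSIL`).
#' @param features_per_split predictors drawn per node (1..9).
#' @param max_depth maximum depth (`Inf` = unlimited).
#' @param min_leaf minimum samples per leaf.
#' @param seed integer seed for the per-node feature draws.
#' @return object of class `mc_tree`: parallel vectors `feature`,
#'   `threshold`, `left`, `right`, `prob` (node table, `NA` feature =
#'   leaf).
#' @export
fit_tree <- function(X, y, features_per_split = 9L, max_depth = Inf,
                     min_leaf = 1L, seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) < 1) stop("empty predictor matrix")
  yi <- encode_labels(y)
  res <- .grow_forest_cpp(
    X, yi, as.integer(features_per_split),
    if (is.infinite(max_depth)) -1L else as.integer(max_depth),
    as.integer(min_leaf), FALSE, as.numeric(seed)
  )
  structure(res$trees[[1]], class = "mc_tree")
}

#' Fit the bagged tree ensemble
#'
#' Grows `n_trees` trees, each on a bootstrap resample of the n training
#' rows (drawn with replacement), with per-node random feature subsets.
#' Per-predictor importances are the normalised total Gini impurity
#' decrease attributed to each predictor across all trees.
#'
#' @param X numeric n x 9 predictor matrix (as from [predictor_matrix()]).
#' @param y labels (`NILM`/`HSIL`); both classes must be present.
#' @param forest the `forest` sub-list of an [mc_config()].
#' @param seed integer seed; per-tree streams are derived from it.
#' @return object of class `mc_forest` with elements `trees`, `n_trees`,
#'   `features_per_split`, `seed`, `importances` (9-vector summing to 1),
#'   `class_order`.
#' @export
fit_forest <- function(X, y, forest = mc_config()$forest, seed = 1L) {
  X <- as.matrix(X)
  yi <- encode_labels(y)
  if (nrow(X) < 2) stop("need at least two samples")
  if (length(unique(yi)) < 2) {
    stop("both classes (NILM and HSIL) must be present in the training set")
  }
  tree_seeds <- derive_seeds(seed, forest$n_trees)
  res <- .grow_forest_cpp(
    X, yi, as.integer(forest$features_per_split),
    if (is.infinite(forest$max_depth)) -1L else as.integer(forest$max_depth),
    as.integer(forest$min_leaf), TRUE, as.numeric(tree_seeds)
  )
  raw <- res$importance_raw
  importances <- if (sum(raw) > 0) raw / sum(raw) else rep(1 / 9, 9)
  names(importances) <- paste0("chi", 1:9)
  structure(
    list(
      trees = res$trees, n_trees = as.integer(forest$n_trees),
      features_per_split = as.integer(forest$features_per_split),
      seed = as.integer(seed), importances = importances,
      class_order = CLASS_ORDER
    ),
    class = "mc_forest"
  )
}

#' Score samples with a fitted ensemble
#'
#' The miR-CERVIX value: the mean over trees of the leaf HSIL-probability
#' each sample reaches — in \[0, 1\] by construction (0 = confidently
#' normal, 1 = high-grade lesion).
#'
#' @param model an `mc_forest` (or a single `mc_tree`).
#' @param chi predictor 9-vector or n x 9 matrix.
#' @return numeric vector of scores in \[0, 1\].
#' @export
predict_score <- function(model, chi) {
  if (is.null(dim(chi))) chi <- matrix(chi, nrow = 1)
  chi <- as.matrix(chi)
  trees <- if (inherits(model, "mc_tree")) list(unclass(model)) else model$trees
  out <- .predict_forest_cpp(trees, chi)
  names(out) <- rownames(chi)
  out
}

# Balanced fold assignment: deal samples round-robin into k folds along a
# randomised order (class-blocked when stratified), continuing the deal
# across class blocks so overall fold sizes differ by at most one and,
# under stratification, per-class counts differ by at most one as well.
make_folds <- function(y, k, stratified = TRUE) {
  n <- length(y)
  ord <- if (stratified) {
    unlist(lapply(split(seq_len(n), y), sample_vec), use.names = FALSE)
  } else {
    sample_vec(seq_len(n))
  }
  offset <- sample.int(k, 1) - 1L
  fold <- integer(n)
  fold[ord] <- ((seq_len(n) - 1L + offset) %% k) + 1L
  fold
}

#' Cross-validated out-of-fold scores
#'
#' Randomly partitions the cohort into k folds (stratified by class by
#' default), trains the ensemble on each set of k-1 folds, and scores each
#' sample exactly once with the model that never saw its fold.
#'
#' @param X numeric n x 9 predictor matrix with sample ids as rownames.
#' @param y labels (`NILM`/`HSIL`).
#' @param config an [mc_config()]; uses its `forest` and `cv` entries.
#' @param seed integer seed for fold assignment and per-fold model fits.
#' @param keep_models keep the k fitted fold models (for
#'   [score_external()]).
#' @return data.frame `sample_id`, `mir_cervix`, `fold` (input row order);
#'   with `keep_models`, the models are attached as attribute `models`.
#' @export
crossval_scores <- function(X, y, config = mc_config(), seed = config$seed,
                            keep_models = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- config$cv$k
  if (k > n) stop("k = ", k, " exceeds the ", n, " available samples")
  yi <- encode_labels(y)
  if (length(unique(yi)) < 2) stop("both classes required for training")
  seeds <- derive_seeds(seed, k + 1L)
  fold <- with_seed(seeds[1], make_folds(y, k, config$cv$stratified))
  scores <- numeric(n)
  models <- if (keep_models) vector("list", k) else NULL
  for (j in seq_len(k)) {
    test <- fold == j
    if (length(unique(yi[!test])) < 2) {
      stop(
        "training split for fold ", j, " lost a class; ",
        "enable stratification or reduce k"
      )
    }
    model <- fit_forest(X[!test, , drop = FALSE], y[!test],
      forest = config$forest, seed = seeds[j + 1L]
    )
    scores[test] <- predict_score(model, X[test, , drop = FALSE])
    if (keep_models) models[[j]] <- model
  }
  out <- data.frame(
    sample_id = rownames(X) %||% as.character(seq_len(n)),
    mir_cervix = scores, fold = fold,
    stringsAsFactors = FALSE
  )
  if (keep_models) attr(out, "models") <- models
  out
}

#' Score samples outside the training cohort
#'
#' Averages the predictions of all k fold models over the new samples.
#'
#' @param models list of `mc_forest` fold models (attribute `models` of
#'   [crossval_scores()] with `keep_models = TRUE`).
#' @param chi predictor 9-vector or n x 9 matrix.
#' @return numeric vector of scores in \[0, 1\].
#' @export
score_external <- function(models, chi) {
  stopifnot(length(models) >= 1)
  preds <- vapply(
    models, function(m) predict_score(m, chi),
    numeric(if (is.null(dim(chi))) 1L else nrow(chi))
  )
  if (is.null(dim(preds))) mean(preds) else rowMeans(preds)
}

#' Serialize a fitted ensemble to JSON
#'
#' Trees are written as parallel node arrays (`feature`, `threshold`,
#' `left`, `right`, `prob`; nulls mark leaves) so scores can be recomputed
#' by any implementation.
#'
#' @param model an `mc_forest`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "mc_forest"))
  jsonlite::write_json(
    list(
      n_trees = model$n_trees,
      features_per_split = model$features_per_split,
      seed = model$seed,
      class_order = model$class_order,
      importances = model$importances,
      trees = model$trees
    ),
    path,
    auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}

#' Read a serialized ensemble back
#'
#' @param path JSON path written by [write_model()].
#' @return an `mc_forest`.
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path,
    simplifyVector = TRUE,
    simplifyDataFrame = FALSE, simplifyMatrix = FALSE
  )
  trees <- lapply(j$trees, function(t) {
    list(
      feature = as.integer(t$feature), threshold = as.numeric(t$threshold),
      left = as.integer(t$left), right = as.integer(t$right),
      prob = as.numeric(t$prob)
    )
  })
  imp <- as.numeric(j$importances)
  names(imp) <- paste0("chi", 1:9)
  structure(
    list(
      trees = trees, n_trees = as.integer(j$n_trees),
      features_per_split = as.integer(j$features_per_split),
      seed = as.integer(j$seed), importances = imp,
      class_order = as.character(j$class_order)
    ),
    class = "mc_forest"
  )
}
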
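test_that("a single-class training set yields a pure one-leaf tree", {
  X <- matrix(runif(45), 5, 9)
  tr_h <- fit_tree(X, rep("HSIL", 5))
  expect_true(is.na(tr_h$feature[1]))
  expect_equal(tr_h$prob[1], 1.0)
  tr_n <- fit_tree(X, rep("NILM", 5))
  expect_equal(tr_n$prob[1], 0.0)
})

test_that("a separable toy is solved by one split on chi1", {
  toy <- separable_toy()
  tree <- fit_tree(toy$X, toy$y, features_per_split = 9, seed = 3)
  expect_equal(tree$feature[1], 1L)
  expect_equal(tree$threshold[1], (0.1 + 10) / 2)
  expect_true(all(is.na(tree$feature[-1])))
  preds <- predict_score(structure(tree, class = "mc_tree"), toy$X)
  expect_equal(unname(preds), as.numeric(toy$y == "HSIL"))
})

test_that("tree and forest fits are deterministic in the seed", {
  d <- chi1_informative(n_per_class = 15, seed = 2)
  t1 <- fit_tree(d$X, d$y, features_per_split = 3, seed = 9)
  t2 <- fit_tree(d$X, d$y, features_per_split = 3, seed = 9)
  expect_identical(t1, t2)
  f1 <- fit_forest(d$X, d$y, mc_config(forest = list(n_trees = 20))$forest,
    seed = 4
  )
  f2 <- fit_forest(d$X, d$y, mc_config(forest = list(n_trees = 20))$forest,
    seed = 4
  )
  expect_identical(f1$trees, f2$trees)
  expect_identical(f1$importances, f2$importances)
})

test_that("on the separable toy every tree splits chi1 and owns all importance", {
  toy <- separable_toy()
  model <- fit_forest(toy$X, toy$y,
    mc_config(forest = list(n_trees = 50))$forest,
    seed = 1
  )
  split_feats <- unlist(lapply(model$trees, function(t) {
    t$feature[!is.na(t$feature)]
  }))
  expect_true(all(split_feats == 1L))
  expect_equal(unname(model$importances), c(1, rep(0, 8)))
  expect_equal(sum(model$importances), 1, tolerance = 1e-9)
  expect_error(fit_forest(toy$X, rep("HSIL", nrow(toy$X))), "both classes")
})

test_that("an ensemble of one tree is a single bootstrap tree", {
  d <- chi1_informative(n_per_class = 10, seed = 3)
  model <- fit_forest(d$X, d$y, mc_config(forest = list(n_trees = 1))$forest,
    seed = 5
  )
  expect_length(model$trees, 1)
  expect_equal(
    unname(predict_score(model, d$X)),
    unname(walk_forest(model, d$X))
  )
})

test_that("scores are the mean leaf probability over trees", {
  leaf <- function(p) {
    list(
      feature = NA_integer_, threshold = NA_real_,
      left = NA_integer_, right = NA_integer_, prob = p
    )
  }
  model <- structure(
    list(trees = list(leaf(1.0), leaf(0.5)), class_order = c("NILM", "HSIL")),
    class = "mc_forest"
  )
  x <- matrix(1, 1, 9)
  expect_equal(unname(predict_score(model, x)), 0.75)
  model$trees <- list(leaf(1), leaf(1))
  expect_equal(unname(predict_score(model, x)), 1.0)
  model$trees <- list(leaf(0), leaf(0))
  expect_equal(unname(predict_score(model, x)), 0.0)
})

test_that("batch prediction equals the tree-walking oracle on small cohorts", {
  for (seed in 1:6) {
    d <- chi1_informative(
      n_per_class = sample(5:15, 1),
      delta = 1.5, seed = seed
    )
    model <- fit_forest(d$X, d$y,
      mc_config(forest = list(n_trees = 1 + seed %% 5))$forest,
      seed = seed
    )
    batch <- predict_score(model, d$X)
    expect_equal(unname(batch), unname(walk_forest(model, d$X)),
      tolerance = 1e-12
    )
    expect_true(all(batch >= 0 & batch <= 1))
  }
})

test_that("cross-validation partitions evenly and scores out of fold", {
  d <- chi1_informative(n_per_class = 26, seed = 4)
  cfg <- mc_config(cv = list(k = 7L), forest = list(n_trees = 10L))
  sc <- crossval_scores(d$X, d$y, cfg, seed = 2)
  expect_equal(sort(sc$sample_id), sort(rownames(d$X)))
  sizes <- table(sc$fold)
  expect_length(sizes, 7)
  expect_lte(diff(range(sizes)), 1)
  # stratification keeps both classes in every fold complement
  for (j in 1:7) {
    expect_length(unique(d$y[sc$fold != j]), 2)
  }
  expect_true(all(sc$mir_cervix >= 0 & sc$mir_cervix <= 1))
})

test_that("leave-one-out (k = n) runs and scores every sample", {
  d <- chi1_informative(n_per_class = 6, seed = 8)
  cfg <- mc_config(cv = list(k = 12L), forest = list(n_trees = 5L))
  sc <- crossval_scores(d$X, d$y, cfg, seed = 3)
  expect_equal(nrow(sc), 12)
  expect_equal(sort(unique(sc$fold)), 1:12)
})

test_that("a training split losing a class is a hard error advising smaller k", {
  X <- matrix(runif(90), 10, 9)
  y <- c("HSIL", rep("NILM", 9))
  cfg <- mc_config(cv = list(k = 10L), forest = list(n_trees = 3L))
  expect_error(crossval_scores(X, y, cfg, seed = 1), "lost a class")
  expect_error(
    crossval_scores(X[1:5, ], y[1:5], mc_config(cv = list(k = 9L)), seed = 1),
    "exceeds"
  )
})

test_that("external scoring averages the fold models", {
  d <- chi1_informative(n_per_class = 15, seed = 6)
  cfg <- mc_config(cv = list(k = 5L), forest = list(n_trees = 8L))
  sc <- crossval_scores(d$X, d$y, cfg, seed = 7, keep_models = TRUE)
  models <- attr(sc, "models")
  expect_length(models, 5)
  new_x <- d$X[1:3, ]
  manual <- rowMeans(vapply(
    models, function(m) predict_score(m, new_x),
    numeric(3)
  ))
  expect_equal(unname(score_external(models, new_x)), unname(manual))
})

test_that("models survive JSON serialization", {
  d <- chi1_informative(n_per_class = 12, seed = 9)
  model <- fit_forest(d$X, d$y, mc_config(forest = list(n_trees = 6L))$forest,
    seed = 11
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(
    unname(predict_score(back, d$X)),
    unname(predict_score(model, d$X)),
    tolerance = 1e-12
  )
  expect_equal(back$importances, model$importances, tolerance = 1e-12)
})
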
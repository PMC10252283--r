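# Test helpers: independent oracles and fixture builders. Everything is
# generated in code; no stored data.

# Ensemble-prediction oracle: walk every tree of a fitted model with a
# plain R loop, independently of the package's batch predictor.
walk_tree <- function(tree, x) {
  node <- 1L
  while (!is.na(tree$feature[node])) {
    f <- tree$feature[node]
    node <- if (x[f] <= tree$threshold[node]) {
      tree$left[node]
    } else {
      tree$right[node]
    }
  }
  tree$prob[node]
}

walk_forest <- function(model, X) {
  apply(X, 1, function(x) {
    mean(vapply(model$trees, walk_tree, numeric(1), x = x))
  })
}

# AUC oracle: fraction of concordant (HSIL, NILM) pairs, ties counted half.
auc_pairs <- function(score, diagnosis) {
  h <- score[diagnosis == "HSIL"]
  n <- score[diagnosis == "NILM"]
  tot <- 0
  for (a in h) tot <- tot + sum(a > n) + 0.5 * sum(a == n)
  tot / (length(h) * length(n))
}

# A complete one-row sample with the given marker/control Ct values.
make_sample <- function(ct = 25, actb = 28, spike = 16, id = "S1",
                        diagnosis = "UNKNOWN", hpv = "UNKNOWN") {
  df <- data.frame(sample_id = id, diagnosis = diagnosis, hpv_status = hpv)
  cols <- c(
    "ct_mir21", "ct_mir29b", "ct_mir145", "ct_mir451a",
    "ct_mir1246", "ct_mir1290"
  )
  ct <- rep_len(ct, 6)
  for (i in seq_along(cols)) df[[cols[i]]] <- ct[i]
  df$ct_actb <- actb
  df$ct_celmir39 <- spike
  df
}

make_cohort <- function(n = 6, seed = 1, diagnosis = NULL) {
  withr::with_seed(seed, {
    base <- do.call(rbind, lapply(seq_len(n), function(i) {
      make_sample(
        ct = runif(6, 20, 30), id = sprintf("S%02d", i),
        diagnosis = if (is.null(diagnosis)) {
          sample(c("NILM", "HSIL"), 1)
        } else {
          diagnosis[i]
        }
      )
    }))
    mc_cohort(base)
  })
}

# Linearly separable toy predictor set: chi1 carries all the signal.
separable_toy <- function(n_per_class = 10) {
  X <- matrix(1, 2 * n_per_class, 9,
    dimnames = list(NULL, paste0("chi", 1:9))
  )
  X[, 1] <- rep(c(0.1, 10), each = n_per_class)
  y <- rep(c("NILM", "HSIL"), each = n_per_class)
  list(X = X, y = y)
}

# Predictor-level two-class set where only chi1 is informative.
chi1_informative <- function(n_per_class = 30, delta = 2, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    X <- matrix(2^stats::rnorm(n * 9), n, 9,
      dimnames = list(sprintf("S%03d", 1:n), paste0("chi", 1:9))
    )
    y <- rep(c("NILM", "HSIL"), each = n_per_class)
    X[y == "HSIL", 1] <- X[y == "HSIL", 1] * 2^delta
    list(X = X, y = y)
  })
}
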
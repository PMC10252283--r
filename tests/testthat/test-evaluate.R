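test_that("classification at a cut-off is inclusive by default", {
  expect_equal(classify(0.49, 0.49), "POSITIVE")
  expect_equal(classify(0.48, 0.49), "NEGATIVE")
  expect_equal(classify(0.49, 0.49, inclusive = FALSE), "NEGATIVE")
  expect_equal(
    as.character(score_category(c(0.1, 0.5, 0.8))),
    c("NORMAL_LEANING", "ELEVATED", "HSIL_CONFIRMING")
  )
  expect_equal(as.character(score_category(0.77)), "HSIL_CONFIRMING")
})

test_that("confusion counts follow HSIL-positive convention", {
  toy <- data.frame(
    diagnosis = c("HSIL", "HSIL", "HSIL", "NILM", "NILM", "NILM"),
    mir_cervix = c(0.9, 0.6, 0.3, 0.7, 0.2, 0.1)
  )
  cts <- confusion(toy, 0.49)
  expect_equal(cts[c("tp", "fp", "tn", "fn")],
               list(tp = 2L, fp = 1L, tn = 2L, fn = 1L),
               ignore_attr = TRUE)
  expect_equal(cts$total, 6L)
  perfect <- data.frame(
    diagnosis = rep(c("HSIL", "NILM"), each = 4),
    mir_cervix = rep(c(1, 0), each = 4)
  )
  p <- confusion(perfect, 0.5)
  expect_equal(p$fp + p$fn, 0L)
  toy$diagnosis[1] <- "UNKNOWN"
  expect_error(confusion(toy, 0.49), "UNKNOWN")
})

test_that("rates are percentages with undefined (not zero) empty denominators", {
  perfect <- metrics(list(tp = 10, fp = 0, tn = 10, fn = 0))
  expect_true(all(unlist(perfect) == 100))
  m <- metrics(list(tp = 0, fp = 0, tn = 5, fn = 0))
  expect_true(is.na(m$ppv))
  expect_true(is.na(m$sensitivity))
  expect_equal(m$specificity, 100)
  any_m <- metrics(list(tp = 3, fp = 2, tn = 4, fn = 1))
  expect_identical(any_m$precision, any_m$ppv)
})

test_that("ROC endpoints and degenerate cases behave", {
  sep <- data.frame(
    score = c(0.9, 0.8, 0.2, 0.1),
    diagnosis = c("HSIL", "HSIL", "NILM", "NILM")
  )
  expect_equal(roc_auc(sep$score, sep$diagnosis)$auc, 1.0)
  ties <- roc_auc(rep(0.5, 6), rep(c("HSIL", "NILM"), 3))
  expect_equal(ties$auc, 0.5)
  expect_error(roc_auc(1:3, rep("HSIL", 3)), "both classes")
})

test_that("trapezoid AUC equals the concordant-pair oracle and pROC", {
  for (seed in 1:8) {
    withr::with_seed(seed, {
      n <- sample(10:50, 1)
      diagnosis <- sample(c("HSIL", "NILM"), n,
        replace = TRUE,
        prob = c(0.5, 0.5)
      )
      if (length(unique(diagnosis)) < 2) diagnosis[1:2] <- c("HSIL", "NILM")
      score <- round(runif(n), 1) # coarse grid forces ties
      r <- roc_auc(score, diagnosis)
      expect_equal(r$auc, auc_pairs(score, diagnosis), tolerance = 1e-12)
      expect_true(all(diff(r$roc$tpr) >= 0))
      expect_true(all(diff(r$roc$fpr) >= 0))
    })
  }
  withr::with_seed(99, {
    score <- runif(40)
    diagnosis <- rep(c("HSIL", "NILM"), 20)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = diagnosis, predictor = score,
      levels = c("NILM", "HSIL"), direction = "<", quiet = TRUE
    )))
    expect_equal(roc_auc(score, diagnosis)$auc, ref, tolerance = 1e-12)
  })
})

test_that("metrics over the threshold sweep reproduce the ROC points", {
  withr::with_seed(21, {
    df <- data.frame(
      mir_cervix = round(runif(40), 2),
      diagnosis = rep(c("HSIL", "NILM"), 20)
    )
    r <- roc_auc(df$mir_cervix, df$diagnosis)
    for (i in seq_len(nrow(r$roc))) {
      t <- r$roc$threshold[i]
      if (!is.finite(t)) next
      m <- metrics(confusion(df, t))
      expect_equal(m$sensitivity / 100, r$roc$tpr[i], tolerance = 1e-12)
      expect_equal(1 - m$specificity / 100, r$roc$fpr[i], tolerance = 1e-12)
    }
    # weak monotonicity along increasing cut-offs
    cuts <- sort(unique(df$mir_cervix))
    ms <- lapply(cuts, function(ct) metrics(confusion(df, ct)))
    expect_true(all(diff(vapply(ms, `[[`, 1, "sensitivity")) <= 0))
    expect_true(all(diff(vapply(ms, `[[`, 1, "specificity")) >= 0))
  })
})

test_that("Mann-Whitney U follows rank-sum symmetry and invariances", {
  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$U, 8)
  expect_gt(same$p, 0.9)
  sep <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  expect_equal(sep$p, 0.1) # exact: 2 * 1/choose(6,3)
  a <- c(0.1, 0.4, 0.35, 0.8, 0.2)
  b <- c(0.5, 0.9, 0.7, 0.3)
  expect_equal(mann_whitney(a, b), mann_whitney(2 * a, 2 * b))
})

test_that("the exact Mann-Whitney p matches a large permutation test", {
  withr::with_seed(17, {
    a <- rnorm(7)
    b <- rnorm(8) + 1.2
    got <- mann_whitney(a, b)
    pooled <- c(a, b)
    n_a <- length(a)
    center <- n_a * length(b) / 2
    pooled_ranks <- rank(pooled)
    u_stat <- function(lab) {
      sum(pooled_ranks[lab]) - n_a * (n_a + 1) / 2
    }
    obs <- abs(u_stat(seq_len(n_a)) - center)
    n_perm <- 100000
    hits <- sum(vapply(seq_len(n_perm), function(i) {
      abs(u_stat(sample(length(pooled), n_a)) - center) >= obs
    }, logical(1)))
    p_perm <- hits / n_perm
    se <- sqrt(p_perm * (1 - p_perm) / n_perm)
    expect_lt(abs(got$p - p_perm), 3 * max(se, 1e-4))
  })
})

test_that("Kruskal-Wallis handles identity, two-group, and separated cases", {
  ident <- kruskal_wallis(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(ident$H, 0, tolerance = 1e-12)
  expect_equal(unname(ident$group_means), c(2, 2))

  # with two groups H is the (uncorrected) normal-approximation Mann-Whitney
  withr::with_seed(13, {
    a <- round(rnorm(12), 1)
    b <- round(rnorm(10) + 0.8, 1)
    kw <- kruskal_wallis(list(a = a, b = b))
    w <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
    expect_equal(kw$p, w$p.value, tolerance = 1e-10)
  })

  withr::with_seed(29, {
    g <- list(
      lo = rnorm(10, 0), mid = rnorm(10, 2), hi = rnorm(10, 4)
    )
    kw <- kruskal_wallis(g)
    expect_lt(kw$p, 0.05)
    # permutation oracle on H
    pooled <- unlist(g)
    sizes <- lengths(g)
    h_of <- function(vals) {
      kruskal_wallis(split(vals, rep(seq_along(sizes), sizes)))$H
    }
    n_perm <- 10000
    hs <- vapply(seq_len(n_perm), function(i) h_of(sample(pooled)),
      numeric(1)
    )
    p_perm <- mean(hs >= kw$H)
    expect_lt(p_perm, 0.05)
  })
})
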
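# Grouped-window averaging, metrics, and the comparison statistics.

test_that("grouped predictions average probabilities per trial with first-appearance order", {
  probs <- rbind(c(0.6, 0.4, 0, 0), c(0.2, 0.8, 0, 0))
  g <- group_predictions(probs, c("t1", "t1"))
  expect_equal(nrow(g), 1L)
  expect_equal(unlist(g[1, paste0("p_", activity_labels())]),
               c(p_LD = 0.4, p_S2S = 0.6, p_TN = 0, p_W = 0))
  expect_equal(as.character(g$label), "S2S")
  expect_equal(g$n_subwindows, 2L)

  # single-sub-window trial: grouped equals the sub-window prediction
  g1 <- group_predictions(probs[1, , drop = FALSE], "solo")
  expect_equal(as.character(g1$label), "LD")
  expect_equal(g1$n_subwindows, 1L)

  # tie broken towards the lowest class index
  gt <- group_predictions(matrix(0.25, 1, 4), "t")
  expect_equal(as.character(gt$label), "LD")

  # partition counting: trials of sizes 1, 2, 3 over 6 rows
  set.seed(1)
  p6 <- matrix(runif(24), 6, 4); p6 <- p6 / rowSums(p6)
  g6 <- group_predictions(p6, c("a", "b", "b", "c", "c", "c"))
  expect_equal(g6$trial_id, c("a", "b", "c"))
  expect_equal(g6$n_subwindows, 1:3)

  expect_equal(nrow(group_predictions(matrix(numeric(0), 0, 4),
                                      character(0))), 0L)
})

test_that("grouped labels match a brute-force mean-and-argmax oracle", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(3:40, 1)
    probs <- matrix(runif(4 * n), n, 4)
    probs <- probs / rowSums(probs)
    ids <- sample(paste0("tr", 1:5), n, replace = TRUE)
    g <- group_predictions(probs, ids)
    for (tr in unique(ids)) {
      mp <- colMeans(probs[ids == tr, , drop = FALSE])
      expect_equal(as.character(g$label[g$trial_id == tr]),
                   activity_labels()[which.max(mp)])
      expect_equal(sum(g[g$trial_id == tr, paste0("p_", activity_labels())]),
                   1, tolerance = 1e-9)
    }
  }
})

test_that("accuracy is the percentage of correct units", {
  expect_equal(accuracy(c("W", "TN"), c("W", "TN")), 100)
  truth <- rep(activity_labels(), each = 10)
  pred <- truth; pred[c(1, 12, 23)] <- c("W", "W", "LD")
  expect_equal(accuracy(truth, pred), 92.5) # 37 of 40
  expect_error(accuracy(truth, pred[-1]), "equal length")
})

test_that("confusion matrices tally truth x prediction and agree with accuracy", {
  truth <- c(rep("LD", 10), rep("S2S", 10), rep("TN", 9), rep("W", 8), "TN",
             "W", "W")
  pred <- c(rep("LD", 10), rep("S2S", 10), rep("TN", 9), rep("W", 8), "LD",
            "S2S", "TN")
  cm <- confusion(truth, pred)
  expect_equal(unname(diag(cm)), c(10, 10, 9, 8))
  expect_equal(sum(cm) - sum(diag(cm)), 3)
  expect_equal(100 * sum(diag(cm)) / sum(cm), accuracy(truth, pred))

  perfect <- confusion(truth, truth)
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))
  expect_equal(unname(diag(perfect)),
               as.vector(table(factor(truth, activity_labels()))))
  all_ld <- confusion(truth, rep("LD", length(truth)))
  expect_true(all(all_ld[, -1] == 0))

  # trace identity on many random fixtures
  set.seed(5)
  for (i in 1:50) {
    tt <- sample(activity_labels(), 40, replace = TRUE)
    pp <- sample(activity_labels(), 40, replace = TRUE)
    cm <- confusion(tt, pp)
    expect_equal(100 * sum(diag(cm)) / sum(cm), accuracy(tt, pp))
  }
})

test_that("friedman statistic matches the rank formula, known fixture and stats::friedman.test", {
  # identical ordering in every block: chi2 = 8, df = 2, p = exp(-4)
  m <- matrix(c(1, 2, 3), nrow = 4, ncol = 3, byrow = TRUE)
  fr <- friedman_test(m)
  expect_equal(fr$statistic, 8)
  expect_equal(fr$df, 2L)
  expect_equal(fr$p_value, pchisq(8, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(fr$p_value, 0.01831564, tolerance = 1e-6)

  # all-tie degenerate case
  expect_equal(friedman_test(matrix(5, 3, 4))$statistic, 0)
  expect_equal(friedman_test(matrix(5, 3, 4))$p_value, 1)

  # column permutation invariance
  set.seed(3)
  x <- matrix(rnorm(20), 5, 4)
  expect_equal(friedman_test(x)$statistic,
               friedman_test(x[, c(3, 1, 4, 2)])$statistic)

  # established-implementation cross-check on random, tie-free matrices
  for (i in 1:10) {
    x <- matrix(rnorm(5 * 3), 5, 3)
    fr <- friedman_test(x)
    ref <- stats::friedman.test(x)
    expect_equal(fr$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(fr$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("friedman agrees with an exhaustive permutation oracle (k=3, n=4)", {
  ## oracle: independent statistic via explicit rank sums
  oracle_stat <- function(mm) {
    k <- ncol(mm); n <- nrow(mm)
    R <- matrix(0, n, k)
    for (i in 1:n) R[i, ] <- rank(mm[i, ])
    12 * n / (k * (k + 1)) * sum((colMeans(R) - (k + 1) / 2)^2)
  }
  base <- matrix(c(10, 20, 30), 4, 3, byrow = TRUE)
  perms <- as.matrix(expand.grid(1:6, 1:6, 1:6, 1:6))
  ords <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  stats_all <- apply(perms, 1, function(pp) {
    mm <- t(vapply(1:4, function(i) base[i, ords[pp[i], ]], numeric(3)))
    s_impl <- friedman_test(mm)$statistic
    s_oracle <- oracle_stat(mm)
    expect_equal(s_impl, s_oracle, tolerance = 1e-12)
    s_impl
  })
  # the maximal statistic (8) is attained exactly by the 6 concordant
  # assignments, i.e. the exact permutation tail P(T >= 8) = 6/1296
  expect_equal(max(stats_all), 8)
  expect_equal(sum(stats_all >= 8 - 1e-9), 6L)
})

test_that("post-hoc pairwise tests apply the Bonferroni correction", {
  set.seed(11)
  m <- matrix(rnorm(10 * 11), 10, 11,
              dimnames = list(NULL, paste0("c", 1:11)))
  ph <- posthoc_pairwise(m)
  expect_equal(ph$n_comparisons, choose(11, 2)) # 55
  expected_adj <- ph$raw_p * 55
  expected_adj[expected_adj > 1] <- 1
  expect_equal(ph$adjusted_p, expected_adj, tolerance = 1e-12)
  expect_true(all(ph$adjusted_p >= ph$raw_p - 1e-12)) # monotone
  expect_true(all(ph$adjusted_p <= 1))
  expect_identical(ph$adjusted_p, t(ph$adjusted_p))
  expect_equal(unname(diag(ph$adjusted_p)), rep(1, 11))

  # agreement with the standard adjustment routine
  up <- upper.tri(ph$raw_p)
  expect_equal(ph$adjusted_p[up],
               stats::p.adjust(ph$raw_p[up], method = "bonferroni"),
               tolerance = 1e-12)

  # identical columns can never be significant
  m2 <- cbind(a = m[, 1], b = m[, 1], c = m[, 2])
  ph2 <- posthoc_pairwise(m2)
  expect_equal(ph2$adjusted_p["a", "b"], 1)
  expect_false(ph2$significant["a", "b"])
  # arithmetic of the correction: raw 0.0005 with multiplier 55
  expect_equal(min(1, 0.0005 * 55), 0.0275)
})

test_that("inference timing reports non-negative means and zero sd for one repetition", {
  wt <- toy_tensor(nw = 6, nc = 3)
  wt$trial_ids <- c("t1", "t1", "t1", "t2", "t2", "t3")
  m <- build_model(Nc = 3, seed = 1)
  t_sub <- time_inference(m, wt, "sub", repetitions = 2)
  expect_true(all(t_sub$times >= 0))
  expect_equal(t_sub$window_type, "sub")
  t_one <- time_inference(m, wt, "grouped", repetitions = 1)
  expect_equal(t_one$sd, 0)
  expect_gte(t_one$mean, 0)
})
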
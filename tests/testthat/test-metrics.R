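test_that("tolerance accuracy counts hand-checkable cases correctly", {
  expect_equal(tolerance_accuracy(c(3, 7, 9), c(3, 7, 9), 0, K = 10), 1)
  # Monk: one-off counts at 10%, three-off fails even at 20%
  expect_equal(tolerance_accuracy(c(5, 5), c(6, 8), 0.10, K = 10), 0.5)
  expect_equal(tolerance_accuracy(c(5, 5), c(6, 8), 0.20, K = 10), 0.5)
  # Fitzpatrick: 10% margin is exact match, 20% is one class
  expect_equal(tolerance_accuracy(c(3, 3), c(4, 4), 0.10, K = 6), 0)
  expect_equal(tolerance_accuracy(c(3, 3), c(4, 4), 0.20, K = 6), 1)
  expect_error(tolerance_accuracy(integer(0), integer(0), 0.1, K = 10), "empty")
})

test_that("tolerance metrics agree with brute-force counting on random pairs", {
  set.seed(101)
  for (K in c(6, 10)) {
    gold <- sample(K, 200, replace = TRUE)
    pred <- pmin(pmax(gold + sample(-3:3, 200, replace = TRUE), 1), K)
    for (margin in c(0, 0.1, 0.2)) {
      expect_identical(
        tolerance_accuracy(gold, pred, margin, K),
        brute_accuracy(gold, pred, margin, K)
      )
      expect_equal(
        balanced_accuracy(gold, pred, margin, K),
        brute_balanced(gold, pred, margin, K),
        tolerance = 1e-12
      )
    }
  }
})

test_that("accuracy is non-decreasing in the margin", {
  set.seed(33)
  gold <- sample(10, 300, replace = TRUE)
  pred <- sample(10, 300, replace = TRUE)
  accs <- vapply(c(0, 0.1, 0.2, 0.5), tolerance_accuracy,
    numeric(1), gold = gold, pred = pred, K = 10)
  expect_true(all(diff(accs) >= 0))
})

test_that("the ITA-axis margin semantics compare angles, not classes", {
  gold_ita <- c(40, 40)
  pred_ita <- c(55, 70) # deviations 15 and 30 degrees
  expect_equal(
    tolerance_accuracy(gold_ita, pred_ita, 0.10, K = 10, semantics = "ita_fraction"),
    0.5 # 10% of the 200-degree axis tolerates 20 degrees
  )
  expect_equal(
    tolerance_accuracy(gold_ita, pred_ita, 0.20, K = 10, semantics = "ita_fraction"),
    1
  )
})

test_that("balanced accuracy is the mean of supported per-class recalls", {
  expect_equal(balanced_accuracy(rep(4, 5), rep(4, 5), 0, K = 10), 1)
  # two classes with recalls 1 and 0: balanced is 0.5 whatever the sizes
  gold <- c(rep(1, 9), rep(10, 1))
  pred <- c(rep(1, 9), rep(5, 1))
  expect_equal(balanced_accuracy(gold, pred, 0.1, K = 10), 0.5)
  expect_lt(
    balanced_accuracy(gold, pred, 0.1, K = 10),
    tolerance_accuracy(gold, pred, 0.1, K = 10)
  )
  rec <- per_class_recall(gold, pred, 0.1, K = 10)
  expect_equal(rec[1], 1)
  expect_equal(rec[10], 0)
  expect_true(all(is.na(rec[2:9])))
})

test_that("balanced accuracy equals plain accuracy when recalls are equal", {
  gold <- rep(c(2, 5, 8), times = c(4, 8, 12))
  pred <- gold
  pred[c(1, 5, 6, 13, 14, 15)] <- pmin(gold[c(1, 5, 6, 13, 14, 15)] + 3, 10)
  # constructed so each class has recall 3/4, 6/8, 9/12 = 0.75
  expect_equal(per_class_recall(gold, pred, 0.1, 10)[c(2, 5, 8)], rep(0.75, 3))
  expect_equal(
    balanced_accuracy(gold, pred, 0.1, 10),
    tolerance_accuracy(gold, pred, 0.1, 10)
  )
})

test_that("eval reports satisfy their structural invariants", {
  set.seed(55)
  gold <- sample(10, 120, replace = TRUE)
  pred <- pmin(pmax(gold + sample(-2:2, 120, TRUE), 1), 10)
  rep_ <- eval_report(gold, pred, K = 10)
  expect_lte(rep_$accuracy, rep_$sufficient_accuracy)
  expect_equal(rep_$balanced_accuracy, mean(rep_$per_class_recall, na.rm = TRUE))
  expect_equal(unname(rowSums(rep_$confusion_matrix)),
    unname(table(factor(gold, levels = 1:10))), ignore_attr = TRUE)
  expect_equal(rep_$n, 120)
})

test_that("Fleiss' kappa is 1 under unanimity and 0 at chance agreement", {
  unanimous <- matrix(0, 10, 4)
  unanimous[cbind(1:10, rep(1:4, length.out = 10))] <- 3
  expect_equal(fleiss_kappa(unanimous), 1)
  # observed pairwise agreement engineered to equal chance agreement
  chance <- rbind(c(2, 0), c(0, 2), c(1, 1), c(1, 1))
  expect_equal(fleiss_kappa(chance), 0)
  expect_error(fleiss_kappa(rbind(c(2, 1), c(1, 1))), "same number")
})

test_that("Fleiss' kappa matches the frozen independent reference value", {
  # 20 subjects x 3 raters x 4 categories; reference computed once with an
  # independent implementation and frozen
  ratings <- rbind(
    c(3, 3, 1), c(3, 4, 4), c(4, 2, 2), c(1, 4, 2), c(2, 2, 3),
    c(4, 2, 1), c(3, 2, 1), c(1, 3, 3), c(1, 2, 1), c(3, 4, 4),
    c(4, 3, 4), c(4, 4, 3), c(1, 2, 1), c(2, 2, 3), c(1, 3, 2),
    c(4, 4, 3), c(1, 2, 2), c(4, 4, 3), c(3, 1, 2), c(2, 4, 4)
  )
  counts <- t(apply(ratings, 1, tabulate, nbins = 4))
  expect_equal(fleiss_kappa(counts), -0.005212211466865298, tolerance = 1e-9)
  # invariant under relabelling of categories
  expect_equal(fleiss_kappa(counts[, c(3, 1, 4, 2)]), fleiss_kappa(counts))
})

test_that("Mann-Whitney matches exhaustive enumeration on small samples", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  mw <- mann_whitney(a, b)
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1) # 2 / choose(6, 3)
  expect_equal(mw$method, "exact")
  expect_equal(mw$p, enumerate_mw_p(a, b))
  set.seed(14)
  x <- rnorm(6); y <- rnorm(7) + 0.8
  expect_equal(mann_whitney(x, y)$p, enumerate_mw_p(x, y), tolerance = 1e-12)
})

test_that("Mann-Whitney symmetry and degenerate behaviour hold", {
  a <- c(1.5, 2.5, 9); b <- c(3, 4, 8, 10)
  m1 <- mann_whitney(a, b); m2 <- mann_whitney(b, a)
  expect_equal(m1$p, m2$p)
  expect_equal(m1$U + m2$U, length(a) * length(b))
  same <- mann_whitney(1:5 + 0.1, 1:5 + 0.1)
  expect_gt(same$p, 0.99)
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("the normal approximation tracks the exact test at n = 8 + 8", {
  set.seed(77)
  for (i in 1:5) {
    a <- rnorm(8); b <- rnorm(8) + runif(1, 0, 1)
    exact <- mann_whitney(a, b)$p
    approx <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    )
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("subgroup comparison separates extreme groups and not identical ones", {
  mk_tables <- function(dev_arm, dev_face, n = 30) {
    gold <- data.frame(
      image_id = rep(sprintf("im%02d", 1:n), each = 2),
      region = rep(c("arm", "face"), n),
      class = rep(5L, 2 * n)
    )
    results <- gold
    names(results)[3] <- "monk"
    results$monk <- results$monk +
      ifelse(results$region == "arm", dev_arm, dev_face)
    list(results = results, gold = gold)
  }
  same <- mk_tables(0L, 0L)
  cmp <- subgroup_compare(same$results, same$gold, "monk", "body_site", K = 10)
  expect_true(cmp$computable)
  expect_gt(cmp$p, 0.9)
  expect_equal(cmp$accuracy, c(1, 1))
  apart <- mk_tables(0L, 3L)
  cmp2 <- subgroup_compare(apart$results, apart$gold, "monk", "body_site", K = 10)
  expect_lt(cmp2$p, 0.001)
  expect_equal(cmp2$accuracy, c(1, 0))
})

test_that("light/dark stratification partitions every gold class once", {
  coh <- make_cohort(synthetic_spec(n_images = 30, sigma = 0, seed = 8))
  res <- run_batch(coh$records)
  gold <- coh$gold[coh$gold$scale == "monk", ]
  light <- gold$class <= 5
  expect_equal(sum(light) + sum(!light), nrow(gold))
  cmp <- subgroup_compare(res, gold, "monk", "light_vs_dark", K = 10)
  if (cmp$computable) {
    expect_equal(sum(cmp$n), nrow(merge(res, gold, by = c("image_id", "region"))))
  }
})

test_that("a one-sided grouping is reported as not computable", {
  gold <- data.frame(image_id = c("a", "b"), region = "arm", class = c(2L, 3L))
  results <- data.frame(image_id = c("a", "b"), region = "arm", monk = c(2L, 3L))
  cmp <- subgroup_compare(results, gold, "monk", "body_site", K = 10)
  expect_false(cmp$computable)
})
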
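# Evaluation suite: tolerance-margin accuracy and balanced accuracy for
# ordinal skin tone classes, Fleiss' kappa for interrater agreement, and
# Mann-Whitney subgroup comparisons.

check_pairs <- function(gold, pred, K, check_range = TRUE) {
  if (length(gold) == 0L || length(pred) == 0L) {
    stop("metric undefined on empty input", call. = FALSE)
  }
  if (length(gold) != length(pred)) {
    stop("gold and predicted classes must have equal length", call. = FALSE)
  }
  ok <- stats::complete.cases(gold, pred)
  if (check_range &&
    any(gold[ok] < 1 | gold[ok] > K | pred[ok] < 1 | pred[ok] > K)) {
    stop(sprintf("classes must lie in [1, %d]", K), call. = FALSE)
  }
  ok
}

margin_to_classes <- function(margin, K) floor(margin * K)

#' Tolerance-margin correctness of class pairs
#'
#' Under the default class-fraction semantics a prediction counts as correct
#' when it deviates from the gold class by at most `floor(margin * K)`
#' classes: a 10% margin is a one-class tolerance on the 10-tone Monk scale
#' and an exact-match requirement on the 6-type Fitzpatrick scale, while 20%
#' allows two Monk tones or one Fitzpatrick type. Under the ITA-fraction
#' semantics the margin is a band of `margin * 200` degrees on the ITA axis
#' (whose physical range spans 180 degrees, padded to the conventional
#' +/-100 sentinels) and correctness compares ITA values directly.
#'
#' @param gold,pred Integer class vectors in \[1, K\] (class semantics) or
#'   numeric ITA vectors in degrees (ITA semantics).
#' @param margin Deviation margin as a fraction; 0.10 for accuracy, 0.20 for
#'   sufficient accuracy.
#' @param K Number of classes on the scale.
#' @param semantics Margin referent; `"class_fraction"` (default) or
#'   `"ita_fraction"`.
#' @return Logical vector: which pairs are within tolerance.
#' @keywords internal
within_margin <- function(gold, pred, margin, K,
                          semantics = c("class_fraction", "ita_fraction")) {
  semantics <- match.arg(semantics)
  if (semantics == "class_fraction") {
    abs(pred - gold) <= margin_to_classes(margin, K)
  } else {
    abs(pred - gold) <= margin * 200
  }
}

#' Tolerance accuracy
#'
#' Proportion of images classified correctly under a deviation margin:
#' correct classifications over the total number of images, where "correct"
#' tolerates `floor(margin * K)` classes of deviation (see [within_margin()]).
#' `margin = 0.10` gives the headline accuracy; `margin = 0.20` the
#' "sufficient accuracy" variant.
#'
#' @inheritParams within_margin
#' @return A proportion in \[0, 1\].
#' @examples
#' tolerance_accuracy(gold = c(5, 5), pred = c(6, 8), margin = 0.10, K = 10) # 0.5
#' @export
tolerance_accuracy <- function(gold, pred, margin = 0.10, K,
                               semantics = c("class_fraction", "ita_fraction")) {
  semantics <- match.arg(semantics)
  ok <- check_pairs(gold, pred, K, check_range = semantics == "class_fraction")
  mean(within_margin(gold[ok], pred[ok], margin, K, semantics))
}

#' Balanced accuracy under a tolerance margin
#'
#' Mean of the per-class recalls, where a class's recall is the
#' within-tolerance proportion among pairs with that gold class. Classes with
#' no gold support are excluded from the mean (their recall is undefined).
#' Robust to class imbalance: a majority class cannot mask poor minority
#' recall.
#'
#' @inheritParams within_margin
#' @return A proportion in \[0, 1\].
#' @export
balanced_accuracy <- function(gold, pred, margin = 0.10, K) {
  mean(per_class_recall(gold, pred, margin, K), na.rm = TRUE)
}

#' Per-class recall under a tolerance margin
#'
#' Recall is always computed per gold class, so the class-fraction margin
#' semantics apply.
#'
#' @inheritParams within_margin
#' @return Numeric vector of length K; NA for classes with no gold support.
#' @export
per_class_recall <- function(gold, pred, margin = 0.10, K) {
  ok <- check_pairs(gold, pred, K)
  gold <- gold[ok]; pred <- pred[ok]
  hit <- within_margin(gold, pred, margin, K)
  vapply(seq_len(K), function(k) {
    in_k <- gold == k
    if (!any(in_k)) NA_real_ else mean(hit[in_k])
  }, numeric(1))
}

#' Full evaluation report for one scale
#'
#' Bundles n, accuracy (10% margin), sufficient accuracy (20% margin),
#' balanced accuracy, per-class recalls and the K x K confusion matrix
#' (gold in rows, predicted in columns).
#'
#' @inheritParams within_margin
#' @param accuracy_margin Margin for accuracy and balanced accuracy.
#' @param sufficient_margin Margin for sufficient accuracy.
#' @return An `eval_report` list.
#' @export
eval_report <- function(gold, pred, K,
                        accuracy_margin = 0.10, sufficient_margin = 0.20) {
  ok <- check_pairs(gold, pred, K)
  cm <- table(
    factor(gold[ok], levels = seq_len(K)),
    factor(pred[ok], levels = seq_len(K))
  )
  structure(
    list(
      n = sum(ok),
      accuracy = tolerance_accuracy(gold, pred, accuracy_margin, K),
      sufficient_accuracy = tolerance_accuracy(gold, pred, sufficient_margin, K),
      balanced_accuracy = balanced_accuracy(gold, pred, accuracy_margin, K),
      per_class_recall = per_class_recall(gold, pred, accuracy_margin, K),
      confusion_matrix = unclass(cm)
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> n = %d | accuracy %.2f%% | sufficient %.2f%% | balanced %.2f%%\n",
    x$n, 100 * x$accuracy, 100 * x$sufficient_accuracy, 100 * x$balanced_accuracy
  ))
  invisible(x)
}

#' Fleiss' kappa for interrater agreement
#'
#' Chance-corrected agreement among m raters assigning N subjects to
#' categorical classes: kappa = (Pbar - Pe) / (1 - Pe), with Pbar the mean
#' within-subject pairwise agreement and Pe the agreement expected from the
#' marginal category frequencies. Used here to quantify how consistently
#' human annotators assign Monk tones or Fitzpatrick types.
#'
#' @param counts N x K matrix: `counts[i, k]` is how many raters put subject
#'   i in category k. Every row must sum to the same m >= 2.
#' @return The kappa statistic (1 = perfect agreement, 0 = chance level).
#' @export
fleiss_kappa <- function(counts) {
  counts <- as.matrix(counts)
  m <- rowSums(counts)
  if (length(unique(m)) != 1L || m[1L] < 2) {
    stop("every subject must be rated by the same number (>= 2) of raters",
      call. = FALSE
    )
  }
  m <- m[1L]
  n <- nrow(counts)
  p_j <- colSums(counts) / (n * m)
  P_i <- (rowSums(counts^2) - m) / (m * (m - 1))
  P_bar <- mean(P_i)
  P_e <- sum(p_j^2)
  if (P_e == 1) return(1) # all mass in one category: trivially unanimous
  (P_bar - P_e) / (1 - P_e)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples with midrank ties. The
#' two-sided p-value comes from exact enumeration when both groups have at
#' most `exact_max` observations and there are no ties, and otherwise from
#' the tie-corrected normal approximation with continuity correction
#' (delegated to [stats::wilcox.test()]).
#'
#' @param a,b Numeric vectors (nonempty).
#' @param exact_max Largest per-group size for the exact path; default 8.
#' @return List with `U` (the U statistic for group `a`), `p` (two-sided),
#'   `n_a`, `n_b`, and `method`.
#' @export
mann_whitney <- function(a, b, exact_max = 8L) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  if (length(unique(c(a, b))) == 1L) { # constant data: no shift detectable
    return(list(
      U = length(a) * length(b) / 2, p = 1,
      n_a = length(a), n_b = length(b), method = "degenerate"
    ))
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && length(a) <= exact_max && length(b) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  list(
    U = unname(wt$statistic), p = wt$p.value,
    n_a = length(a), n_b = length(b),
    method = if (exact) "exact" else "normal_approx"
  )
}

#' Compare classification quality between two subgroups
#'
#' Joins a pipeline results table with a gold annotation table and applies
#' [mann_whitney()] to a per-image statistic between two groups: per-image
#' tolerance-correctness indicators (default) or absolute class deviations.
#' Groupings: `"body_site"` (arm vs face rows), `"image_type"` (a
#' `group` column in the gold table, e.g. clinical vs generated), or
#' `"light_vs_dark"` (gold classes in the lighter vs darker half of the
#' scale: Monk 1-5 vs 6-10, Fitzpatrick I-III vs IV-VI).
#'
#' @param results Pipeline results data.frame (see [run_batch()]).
#' @param gold Gold table: columns `image_id`, `region`, `class`, optional
#'   `group`.
#' @param scale_name Which class column of `results` to evaluate.
#' @param grouping One of `"body_site"`, `"image_type"`, `"light_vs_dark"`.
#' @param K Number of classes on the scale.
#' @param margin Tolerance margin for the correctness indicator.
#' @param statistic `"correct"` (0/1 indicators) or `"abs_dev"` (absolute
#'   class deviations).
#' @return List with the two group names and sizes, per-group accuracy,
#'   `U`, `p`, and `computable` (FALSE when a group is empty, in which case
#'   no test is attempted).
#' @export
subgroup_compare <- function(results, gold, scale_name = "monk",
                             grouping = c("body_site", "image_type", "light_vs_dark"),
                             K = 10L, margin = 0.10,
                             statistic = c("correct", "abs_dev")) {
  grouping <- match.arg(grouping)
  statistic <- match.arg(statistic)
  merged <- merge(results, gold, by = c("image_id", "region"),
    suffixes = c("", ".gold")
  )
  merged <- merged[!is.na(merged[[scale_name]]) & !is.na(merged$class), , drop = FALSE]
  grp <- switch(grouping,
    body_site = merged$region,
    image_type = merged$group,
    light_vs_dark = ifelse(merged$class <= ceiling(K / 2), "light", "dark")
  )
  lv <- sort(unique(grp))
  if (length(lv) != 2L) {
    return(list(groups = lv, computable = FALSE,
      reason = "need exactly two nonempty groups"))
  }
  dev <- abs(merged[[scale_name]] - merged$class)
  stat <- if (statistic == "correct") {
    as.numeric(within_margin(merged$class, merged[[scale_name]], margin, K))
  } else {
    dev
  }
  a <- stat[grp == lv[1L]]; b <- stat[grp == lv[2L]]
  mw <- mann_whitney(a, b)
  hit <- within_margin(merged$class, merged[[scale_name]], margin, K)
  list(
    groups = lv, n = c(length(a), length(b)),
    accuracy = c(mean(hit[grp == lv[1L]]), mean(hit[grp == lv[2L]])),
    U = mw$U, p = mw$p, method = mw$method, statistic = statistic,
    computable = TRUE
  )
}
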
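# Evaluation: AUROC/AUPR, thresholding, balanced resampling, comparisons,
# BH correction, prediction cutoffs and sets.

test_that("auroc matches hand examples including the tie convention", {
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_equal(auroc(c(0.9, 0.5, 0.7, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(auroc(c(0.5, 0.5), c(TRUE, FALSE)), 0.5)
  expect_error(auroc(c(1, 2), c(TRUE, TRUE)),
               class = "proxtalk_single_class_error")
})

test_that("auroc equals the brute-force all-pairs statistic on random inputs", {
  for (seed in 1:15) {
    n <- withr::with_seed(seed, sample(10:200, 1))
    dat <- withr::with_seed(seed + 1000, {
      list(s = round(runif(n), 2), # rounding forces ties
           y = runif(n) < 0.4)
    })
    if (sum(dat$y) == 0 || sum(dat$y) == n) next
    expect_equal(auroc(dat$s, dat$y), bf_auroc(dat$s, dat$y))
  }
})

test_that("label permutation drives auroc to 0.5 on average", {
  dat <- withr::with_seed(7, list(s = rnorm(80), y = rep(c(TRUE, FALSE), 40)))
  perms <- withr::with_seed(8, {
    replicate(200, auroc(dat$s, sample(dat$y)))
  })
  expect_equal(mean(perms), 0.5, tolerance = 0.02)
})

test_that("aupr matches closed forms and the brute-force step curve", {
  expect_equal(aupr(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  # all scores tied: area equals prevalence
  expect_equal(aupr(rep(1, 10), c(rep(TRUE, 3), rep(FALSE, 7))), 0.3)
  for (seed in 1:10) {
    dat <- withr::with_seed(seed + 2000, {
      n <- sample(10:100, 1)
      list(s = round(runif(n), 1), y = runif(n) < 0.3)
    })
    if (sum(dat$y) == 0 || sum(dat$y) == length(dat$y)) next
    expect_equal(aupr(dat$s, dat$y), bf_aupr(dat$s, dat$y))
  }
})

test_that("roc_curve runs monotonically from (0,0) to (1,1)", {
  dat <- withr::with_seed(3, list(s = rnorm(50), y = runif(50) < 0.5))
  rc <- roc_curve(dat$s, dat$y)
  expect_equal(rc$tpr[1], 0); expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[nrow(rc)], 1); expect_equal(rc$fpr[nrow(rc)], 1)
  expect_true(all(diff(rc$tpr) >= 0))
  expect_true(all(diff(rc$fpr) >= 0))
})

test_that("sens_spec_threshold finds the intersection of the two curves", {
  expect_equal(sens_spec_threshold(c(3, 2, 1, 0),
                                   c(TRUE, TRUE, FALSE, FALSE)), 1.5)
  # interleaved scores: sens ~ spec ~ 0.5 at the midpoint
  s <- c(4, 3, 2, 1); y <- c(TRUE, FALSE, TRUE, FALSE)
  t0 <- sens_spec_threshold(s, y)
  expect_equal(mean(s[y] >= t0), 0.5)
  expect_equal(mean(s[!y] < t0), 0.5)
  # positive scaling scales the threshold
  expect_equal(sens_spec_threshold(10 * c(3, 2, 1, 0),
                                   c(TRUE, TRUE, FALSE, FALSE)), 15)
  # achieved |sens - spec| is the grid minimum
  dat <- withr::with_seed(11, list(s = rnorm(60), y = runif(60) < 0.4))
  t1 <- sens_spec_threshold(dat$s, dat$y)
  gap <- function(t) abs(mean(dat$s[dat$y] >= t) - mean(dat$s[!dat$y] < t))
  grid <- sort(unique(dat$s))
  cands <- c(-Inf, (grid[-1] + grid[-length(grid)]) / 2, Inf)
  expect_lte(gap(t1), min(vapply(cands, gap, numeric(1))) + 1e-12)
})

test_that("recall_at counts positives above the threshold", {
  expect_equal(recall_at(c(3, 1, 0), c(TRUE, TRUE, FALSE), -10), 1.0)
  expect_equal(recall_at(c(3, 1, 0), c(TRUE, TRUE, FALSE), 10), 0.0)
  expect_equal(recall_at(c(3, 1), c(TRUE, TRUE), 2), 0.5)
  expect_error(recall_at(c(1, 2), c(FALSE, FALSE), 0))
})

test_that("balanced_auroc resamples reproducibly with paired negative draws", {
  dat <- withr::with_seed(5, list(s = rnorm(200) + rep(c(1, 0), c(40, 160)),
                                  y = rep(c(TRUE, FALSE), c(40, 160))))
  b1 <- balanced_auroc(dat$s, dat$y, n_resamples = 50, seed = 10)
  expect_length(b1, 50)
  b2 <- balanced_auroc(dat$s, dat$y, n_resamples = 50, seed = 10)
  expect_identical(as.numeric(b1), as.numeric(b2))
  expect_identical(attr(b1, "draw_indices"), attr(b2, "draw_indices"))
  # the same draws pair across methods: scores differ, indices identical
  b3 <- balanced_auroc(-dat$s, dat$y, n_resamples = 50, seed = 10)
  expect_identical(attr(b1, "draw_indices"), attr(b3, "draw_indices"))
  # perfect separation -> every balanced AUROC is 1
  sp <- c(rep(1, 5), rep(0, 50)); yp <- rep(c(TRUE, FALSE), c(5, 50))
  expect_true(all(balanced_auroc(sp, yp, 20, seed = 2) == 1))
  # balanced mean approximates the full AUROC for exchangeable negatives
  expect_equal(mean(b1), auroc(dat$s, dat$y), tolerance = 0.05)
  expect_error(balanced_auroc(dat$s, rep(c(TRUE, FALSE), c(160, 40)),
                              10, seed = 1), "fewer negatives")
})

test_that("compare_methods runs paired and unpaired Wilcoxon tests", {
  a <- withr::with_seed(20, runif(100, 0.6, 0.9))
  expect_warning(p_eq <- compare_methods(a, a), "zero")
  expect_equal(p_eq, 1.0)
  b <- a - 0.02
  p1 <- compare_methods(a, b)
  expect_lt(p1, 0.01)
  expect_equal(compare_methods(b, a), p1) # two-sided symmetry
  p2 <- compare_methods(a, b, paired = FALSE)
  expect_true(p2 >= 0 && p2 <= 1)
})

test_that("bh_correct reproduces the step-up rule exactly", {
  expect_equal(bh_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_correct(0.37), 0.37)
  for (seed in 1:10) {
    p <- withr::with_seed(seed + 3000, runif(sample(3:50, 1)))
    q <- bh_correct(p)
    expect_equal(q, bf_bh(p))
    expect_true(all(q >= p))
  }
  expect_error(bh_correct(c(0.5, 1.2)))
})

test_that("prediction_cutoff is mean plus two population sds", {
  expect_equal(prediction_cutoff(c(0, 0, 0, 4)), 1 + 2 * sqrt(3))
  expect_warning(c0 <- prediction_cutoff(c(2, 2, 2)), "zero variance")
  expect_equal(c0, 2)
  z <- withr::with_seed(4, rnorm(50))
  expect_equal(prediction_cutoff(z + 10), prediction_cutoff(z) + 10)
})

test_that("prediction_sets partitions above-cutoff pairs", {
  ta <- data.frame(drug_id = c("d1", "d2", "d3"), disease_id = "s1",
                   z = c(3, 1, 2.5), direction = "higher_is_stronger")
  tb <- ta; tb$z <- c(3, 2.6, 0.5)
  ps <- prediction_sets(ta, tb, 2, 2)
  expect_setequal(ps$agreed, "d1|s1")
  expect_setequal(ps$unique_a, "d3|s1")
  expect_setequal(ps$unique_b, "d2|s1")
  expect_equal(sum(ps$counts), length(union(c(ps$agreed, ps$unique_a),
                                            c(ps$agreed, ps$unique_b))))
  # identical tables and cutoffs: no unique predictions
  ps2 <- prediction_sets(ta, ta, 2, 2)
  expect_length(ps2$unique_a, 0)
  expect_length(ps2$unique_b, 0)
  tb2 <- tb; tb2$drug_id[1] <- "dX"
  expect_error(prediction_sets(ta, tb2, 2, 2), "different pair universes")
})

test_that("evaluate_scores assembles a consistent summary", {
  dat <- withr::with_seed(6, list(s = rnorm(300) + rep(c(1.5, 0), c(60, 240)),
                                  y = rep(c(TRUE, FALSE), c(60, 240))))
  ev <- evaluate_scores(dat$s, dat$y, n_resamples = 30, seed = 3)
  expect_equal(ev$recall, ev$sensitivity_at_threshold)
  expect_equal(ev$recall, recall_at(dat$s, dat$y, ev$threshold))
  expect_length(ev$balanced_aurocs, 30)
  expect_true(all(ev$balanced_aurocs >= 0 & ev$balanced_aurocs <= 1))
  expect_gt(ev$auroc, 0.8)
  # new-positive recall restricted to the flagged subset
  np <- dat$y & withr::with_seed(9, runif(300) < 0.3)
  ev2 <- evaluate_scores(dat$s, dat$y, new_positive = np, n_resamples = 0)
  expect_equal(ev2$recall_new_positives,
               mean(dat$s[np] >= ev2$threshold))
})

test_that("write_eval_report produces the JSON/TSV report set", {
  dat <- withr::with_seed(8, list(s = rnorm(100) + rep(c(1, 0), c(20, 80)),
                                  y = rep(c(TRUE, FALSE), c(20, 80))))
  ev1 <- evaluate_scores(dat$s, dat$y, n_resamples = 20, seed = 4)
  ev2 <- evaluate_scores(-dat$s, dat$y, n_resamples = 20, seed = 4)
  dir <- file.path(tempdir(), "evalreport")
  write_eval_report(list(good = ev1, bad = ev2), dir)
  expect_true(file.exists(file.path(dir, "evaluation.json")))
  tsv <- read.delim(file.path(dir, "evaluation_summary.tsv"))
  expect_setequal(tsv$method, c("good", "bad"))
  cmp <- read.delim(file.path(dir, "method_comparison.tsv"))
  expect_lt(cmp$p[1], 0.05)
})
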
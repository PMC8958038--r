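# Classifier-style evaluation of oriented association scores: ROC/AUROC,
# PR/AUPR, threshold selection, recall, balanced resampling, method
# comparison, multiple-testing correction, and prediction-set bookkeeping.

# Normalize labels to logical (TRUE = positive). Accepts logical, 0/1, or
# "positive"/"negative" strings.
.as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(labels == 1)
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    if (all(labels %in% c("positive", "negative"))) {
      return(labels == "positive")
    }
  }
  stop("labels must be logical, 0/1, or 'positive'/'negative'")
}

.check_two_classes <- function(pos, n) {
  npos <- sum(pos)
  if (npos == 0 || npos == n) {
    stop(proxtalk_error("both classes must be present",
                        "proxtalk_single_class_error"))
  }
  npos
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann--Whitney statistic: the mean over all
#' (positive, negative) score pairs of 1 if the positive ranks higher, 0.5
#' on ties, 0 otherwise.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels class labels (logical, 0/1 or positive/negative).
#' @return AUROC in \[0,1\].
#' @export
auroc <- function(scores, labels) {
  pos <- .as_binary_labels(labels)
  stopifnot(length(scores) == length(pos), !anyNA(scores), !anyNA(pos))
  npos <- .check_two_classes(pos, length(pos))
  nneg <- length(pos) - npos
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision--recall curve
#'
#' Step-wise (interpolation-free) area: precision is treated as a step
#' function of recall over the distinct score thresholds, and the area is
#' the sum of precision times the recall increment at each step. With all
#' scores tied this reduces to the class prevalence.
#'
#' @inheritParams auroc
#' @return AUPR in \[0,1\].
#' @export
aupr <- function(scores, labels) {
  pos <- .as_binary_labels(labels)
  stopifnot(length(scores) == length(pos), !anyNA(scores), !anyNA(pos))
  npos <- .check_two_classes(pos, length(pos))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- pos[ord]
  # Group tied scores into single threshold steps.
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_group]
  n_seen <- seq_along(s)[last_of_group]
  precision <- tp / n_seen
  recall <- tp / npos
  sum(diff(c(0, recall)) * precision)
}

#' ROC curve points
#'
#' @inheritParams auroc
#' @return data.frame with columns `threshold` (descending; classification
#'   is score >= threshold), `tpr`, `fpr`, starting at (0,0) and ending at
#'   (1,1).
#' @export
roc_curve <- function(scores, labels) {
  pos <- .as_binary_labels(labels)
  npos <- .check_two_classes(pos, length(pos))
  nneg <- length(pos) - npos
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- pos[ord]
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_group]
  fp <- cumsum(!y)[last_of_group]
  data.frame(threshold = c(Inf, s[last_of_group]),
             tpr = c(0, tp / npos),
             fpr = c(0, fp / nneg))
}

#' Threshold at the sensitivity--specificity intersection
#'
#' Scans candidate thresholds (midpoints between consecutive distinct
#' scores, plus one beyond each extreme) and returns the one minimizing
#' `|sensitivity - specificity|` for the classification rule
#' score >= threshold. Ties are broken toward higher sensitivity (the lower
#' threshold).
#'
#' @inheritParams auroc
#' @return the selected score threshold.
#' @export
sens_spec_threshold <- function(scores, labels) {
  pos <- .as_binary_labels(labels)
  .check_two_classes(pos, length(pos))
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  sens <- vapply(cand, function(t) mean(scores[pos] >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(scores[!pos] < t), numeric(1))
  gap <- abs(sens - spec)
  best <- which(gap == min(gap))
  best <- best[sens[best] == max(sens[best])]
  cand[best[1]]
}

#' Recall (sensitivity) at a score threshold
#'
#' @inheritParams auroc
#' @param threshold finite classification threshold (score >= threshold is
#'   called positive).
#' @return fraction of positives at or above the threshold.
#' @export
recall_at <- function(scores, labels, threshold) {
  stopifnot(is.finite(threshold))
  pos <- .as_binary_labels(labels)
  if (sum(pos) == 0) stop("no positive labels; recall undefined")
  mean(scores[pos] >= threshold)
}

#' AUROC distribution over balanced resamples
#'
#' Draws `n_resamples` class-balanced subsets, each keeping all positives
#' and an equal number of negatives sampled uniformly without replacement,
#' and computes the AUROC of each. The negative index draws depend only on
#' the seed and the label vector, so evaluating several methods on tables
#' with identical pair ordering and the same seed yields paired resamples.
#'
#' @inheritParams auroc
#' @param n_resamples number of balanced subsets (default 100).
#' @param seed integer seed (mandatory).
#' @return numeric vector of `n_resamples` AUROCs; the drawn negative
#'   indices are attached as attribute `draw_indices`.
#' @export
balanced_auroc <- function(scores, labels, n_resamples = 100, seed) {
  pos <- .as_binary_labels(labels)
  stopifnot(length(scores) == length(pos))
  npos <- .check_two_classes(pos, length(pos))
  neg_idx <- which(!pos)
  if (length(neg_idx) < npos) {
    stop("fewer negatives than positives; balanced resampling impossible")
  }
  seed <- .require_seed(seed)
  draws <- withr::with_seed(seed, {
    lapply(seq_len(n_resamples), function(i) sample(neg_idx, npos))
  })
  pos_scores <- scores[pos]
  out <- vapply(draws, function(ix) {
    auroc(c(pos_scores, scores[ix]),
          c(rep(TRUE, npos), rep(FALSE, npos)))
  }, numeric(1))
  attr(out, "draw_indices") <- draws
  out
}

#' Compare two methods' AUROC distributions
#'
#' Two-sided Wilcoxon test between per-resample AUROC vectors: signed-rank
#' on paired resamples (the default, matching a shared-negative-draw
#' design) or rank-sum when `paired = FALSE`.
#'
#' @param aurocs_a,aurocs_b numeric vectors (equal length when paired).
#' @param paired use the signed-rank test on paired differences.
#' @return two-sided p-value.
#' @export
compare_methods <- function(aurocs_a, aurocs_b, paired = TRUE) {
  if (paired) {
    stopifnot(length(aurocs_a) == length(aurocs_b))
    if (all(aurocs_a == aurocs_b)) {
      warning("all paired differences are zero; p = 1")
      return(1)
    }
    suppressWarnings(
      wilcox.test(aurocs_a, aurocs_b, paired = TRUE, exact = FALSE)$p.value)
  } else {
    suppressWarnings(
      wilcox.test(aurocs_a, aurocs_b, exact = FALSE)$p.value)
  }
}

#' Benjamini--Hochberg adjusted p-values
#'
#' Step-up false discovery rate control; monotone in the input p-values and
#' clipped at 1.
#'
#' @param pvalues numeric vector of p-values in \[0,1\].
#' @return vector of q-values, same order as the input.
#' @export
bh_correct <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE) || anyNA(pvalues)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Prediction z-score cutoff (mean + 2 sd)
#'
#' Method-specific cutoff for calling novel predictions: the mean plus two
#' population (divide-by-n) standard deviations of the oriented z-scores
#' over all scored pairs. A descriptive cutoff, not an inferential one.
#'
#' @param zscores numeric vector of oriented z-scores (length >= 2).
#' @return the cutoff value.
#' @export
prediction_cutoff <- function(zscores) {
  stopifnot(length(zscores) >= 2, !anyNA(zscores))
  m <- mean(zscores)
  s <- sqrt(mean((zscores - m)^2))
  if (s == 0) {
    warning("zero variance in z-scores; cutoff equals the mean")
    return(m)
  }
  m + 2 * s
}

#' Partition above-cutoff predictions of two methods
#'
#' Given two score tables over the same pair universe and their respective
#' cutoffs, returns the pairs called by both methods and those called
#' uniquely by each.
#'
#' @param table_a,table_b data.frames with columns `drug_id`, `disease_id`,
#'   `z`, `direction` (association score tables).
#' @param cutoff_a,cutoff_b oriented-score cutoffs (e.g. from
#'   [prediction_cutoff()]).
#' @return list with character-vector elements `agreed`, `unique_a`,
#'   `unique_b` (pair keys "drug|disease") and integer `counts`.
#' @export
prediction_sets <- function(table_a, table_b, cutoff_a, cutoff_b) {
  key_a <- paste(table_a$drug_id, table_a$disease_id, sep = "|")
  key_b <- paste(table_b$drug_id, table_b$disease_id, sep = "|")
  if (!setequal(key_a, key_b)) {
    diff <- c(setdiff(key_a, key_b), setdiff(key_b, key_a))
    stop(sprintf("score tables cover different pair universes; %d mismatched pair(s), e.g. %s",
                 length(diff), paste(head(diff, 3), collapse = ", ")))
  }
  above_a <- key_a[!is.na(table_a$z) & oriented_score(table_a) >= cutoff_a]
  above_b <- key_b[!is.na(table_b$z) & oriented_score(table_b) >= cutoff_b]
  agreed <- intersect(above_a, above_b)
  unique_a <- setdiff(above_a, above_b)
  unique_b <- setdiff(above_b, above_a)
  list(agreed = agreed, unique_a = unique_a, unique_b = unique_b,
       counts = c(agreed = length(agreed), unique_a = length(unique_a),
                  unique_b = length(unique_b)))
}

#' Full evaluation summary for one method's oriented scores
#'
#' Computes AUROC, AUPR, the sensitivity--specificity intersection
#' threshold, sensitivity/specificity/recall at that threshold (recall at
#' the threshold equals sensitivity by definition), MCC and F1 at the
#' threshold, optionally recall restricted to time-stamped new positives,
#' and the balanced-resample AUROC distribution.
#'
#' @inheritParams auroc
#' @param new_positive optional logical vector flagging time-stamped new
#'   positives (subset of the positives).
#' @param n_resamples balanced resamples (default 100; 0 disables).
#' @param seed integer seed for the resampling (mandatory when
#'   `n_resamples > 0`).
#' @return object of class `eval_summary`.
#' @export
evaluate_scores <- function(scores, labels, new_positive = NULL,
                            n_resamples = 100, seed = NULL) {
  pos <- .as_binary_labels(labels)
  stopifnot(length(scores) == length(pos))
  thr <- sens_spec_threshold(scores, pos)
  thr_finite <- if (is.finite(thr)) thr else min(scores) - 1
  pred <- scores >= thr_finite
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  fn <- sum(!pred & pos); tn <- sum(!pred & !pos)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  recall_new <- if (!is.null(new_positive) && any(new_positive)) {
    mean(scores[new_positive] >= thr_finite)
  } else {
    NA_real_
  }
  bal <- if (n_resamples > 0) {
    balanced_auroc(scores, pos, n_resamples = n_resamples, seed = seed)
  } else {
    numeric(0)
  }
  structure(
    list(auroc = auroc(scores, pos),
         aupr = aupr(scores, pos),
         threshold = thr,
         sensitivity_at_threshold = sens,
         specificity_at_threshold = spec,
         recall = sens,
         recall_new_positives = recall_new,
         mcc = mcc, f1 = f1,
         balanced_aurocs = as.numeric(bal),
         n_positive = sum(pos), n_negative = sum(!pos)),
    class = "eval_summary"
  )
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("evaluation over %d positives / %d negatives\n",
              x$n_positive, x$n_negative))
  cat(sprintf("  AUROC %.3f  AUPR %.3f  threshold %.3g  recall %.3f  specificity %.3f\n",
              x$auroc, x$aupr, x$threshold, x$recall,
              x$specificity_at_threshold))
  if (length(x$balanced_aurocs) > 0) {
    cat(sprintf("  balanced AUROC: median %.3f over %d resamples\n",
                median(x$balanced_aurocs), length(x$balanced_aurocs)))
  }
  invisible(x)
}

#' Write an evaluation report (JSON + TSV)
#'
#' For a named list of `eval_summary` objects writes `evaluation.json` (all
#' summaries), `evaluation_summary.tsv` (scalar metrics per method),
#' `balanced_aurocs.tsv`, and when two or more methods are present a
#' pairwise Wilcoxon comparison matrix `method_comparison.tsv` with
#' BH-adjusted q-values.
#'
#' @param summaries named list of `eval_summary` objects.
#' @param dir output directory (created if absent).
#' @param paired use the paired signed-rank test for method comparison.
#' @return the output directory, invisibly.
#' @export
write_eval_report <- function(summaries, dir, paired = TRUE) {
  stopifnot(is.list(summaries), !is.null(names(summaries)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scalars <- do.call(rbind, lapply(names(summaries), function(m) {
    s <- summaries[[m]]
    data.frame(method = m, auroc = s$auroc, aupr = s$aupr,
               threshold = s$threshold,
               sensitivity = s$sensitivity_at_threshold,
               specificity = s$specificity_at_threshold,
               recall = s$recall,
               recall_new_positives = s$recall_new_positives,
               mcc = s$mcc, f1 = s$f1,
               balanced_auroc_median = if (length(s$balanced_aurocs)) {
                 median(s$balanced_aurocs)
               } else NA_real_,
               stringsAsFactors = FALSE)
  }))
  write.table(scalars, file.path(dir, "evaluation_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  bal <- lapply(summaries, `[[`, "balanced_aurocs")
  if (all(lengths(bal) > 0)) {
    write.table(as.data.frame(bal), file.path(dir, "balanced_aurocs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(summaries) >= 2 && all(lengths(bal) > 0)) {
    methods <- names(summaries)
    cmp <- expand.grid(method_a = methods, method_b = methods,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    cmp <- cmp[cmp$method_a < cmp$method_b, ]
    cmp$p <- mapply(function(a, b) {
      suppressWarnings(compare_methods(bal[[a]], bal[[b]], paired = paired))
    }, cmp$method_a, cmp$method_b)
    cmp$q <- bh_correct(cmp$p)
    write.table(cmp, file.path(dir, "method_comparison.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(summaries, file.path(dir, "evaluation.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(dir)
}
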
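# Mention-level exact-match evaluation: a predicted mention counts only if an
# identical (sentence, start, end, type) span is in the gold standard, so a
# boundary or type error on a multi-word entity is a full error. Precision and
# recall are pooled over all entity types (a single P and R computed from the
# joint counts), with per-type tallies alongside.

prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

mention_keys <- function(mentions) {
  paste(mentions$sentence, mentions$start, mentions$end, mentions$type,
        sep = "\r")
}

#' Score predicted mentions against gold mentions
#'
#' @param gold,predicted Mention data frames (columns `sentence`, `start`,
#'   `end`, `type`), e.g. from [split_mentions()] or [tags_to_mentions()].
#'   Duplicates within either list are an error.
#' @return An `evaluation_report`: pooled `tp`/`fp`/`fn`, `precision`,
#'   `recall`, `f1`, and a `per_type` data frame.
#' @export
score_mentions <- function(gold, predicted) {
  gk <- mention_keys(gold)
  pk <- mention_keys(predicted)
  if (anyDuplicated(gk)) stopf("duplicate mention in gold list")
  if (anyDuplicated(pk)) stopf("duplicate mention in predicted list")
  hit <- pk %in% gk
  tp <- sum(hit)
  fp <- sum(!hit)
  fn <- sum(!gk %in% pk)
  types <- sort_c(unique(c(gold$type, predicted$type)))
  per_type <- do.call(rbind, lapply(types, function(ty) {
    g <- gk[gold$type == ty]
    p <- pk[predicted$type == ty]
    tpt <- sum(p %in% g)
    s <- prf(tpt, length(p) - tpt, length(g) - tpt)
    data.frame(type = ty, tp = tpt, fp = length(p) - tpt,
               fn = length(g) - tpt, precision = s[["precision"]],
               recall = s[["recall"]], f1 = s[["f1"]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_type)) {
    per_type <- data.frame(type = character(), tp = integer(), fp = integer(),
                           fn = integer(), precision = numeric(),
                           recall = numeric(), f1 = numeric(),
                           stringsAsFactors = FALSE)
  }
  s <- prf(tp, fp, fn)
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = s[["precision"]], recall = s[["recall"]],
                 f1 = s[["f1"]], per_type = per_type),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 4, ...) {
  cat(sprintf("Mention-level exact match: P = %.*f  R = %.*f  F1 = %.*f (tp %d, fp %d, fn %d)\n",
              digits, x$precision, digits, x$recall, digits, x$f1,
              x$tp, x$fp, x$fn))
  if (nrow(x$per_type)) {
    for (i in seq_len(nrow(x$per_type))) {
      r <- x$per_type[i, ]
      cat(sprintf("  %-12s P = %.*f  R = %.*f  F1 = %.*f\n",
                  r$type, digits, r$precision, digits, r$recall, digits, r$f1))
    }
  }
  invisible(x)
}

#' Write an evaluation report as a conlleval-style tab-separated table
#'
#' One overall row plus one row per entity type.
#'
#' @param report An `evaluation_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  overall <- data.frame(type = "OVERALL", tp = report$tp, fp = report$fp,
                        fn = report$fn, precision = report$precision,
                        recall = report$recall, f1 = report$f1,
                        stringsAsFactors = FALSE)
  utils::write.table(rbind(overall, report$per_type), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Score two tagged splits at the mention level
#'
#' Convenience wrapper: decodes mentions from gold tags and predicted tags and
#' calls [score_mentions()].
#'
#' @param gold_split A [conll_split()] with gold tags.
#' @param predicted_tags List of predicted tag vectors, parallel to the split.
#' @return An `evaluation_report`.
#' @export
score_tagged_split <- function(gold_split, predicted_tags) {
  stopifnot(length(gold_split) == length(predicted_tags))
  gold <- split_mentions(gold_split)
  pred <- do.call(rbind, c(lapply(seq_along(predicted_tags), function(i) {
    tags_to_mentions(predicted_tags[[i]], i - 1L)
  }), list(empty_mentions())))
  score_mentions(gold, pred)
}

#' Token-level tagging accuracy
#'
#' @param gold_tags,predicted_tags Lists of tag vectors (or single character
#'   vectors) of matching lengths.
#' @return Fraction of positions with equal labels.
#' @export
score_token_accuracy <- function(gold_tags, predicted_tags) {
  if (is.character(gold_tags)) gold_tags <- list(gold_tags)
  if (is.character(predicted_tags)) predicted_tags <- list(predicted_tags)
  if (length(gold_tags) != length(predicted_tags)) {
    stopf("sequence count mismatch: %d vs %d",
          length(gold_tags), length(predicted_tags))
  }
  g <- unlist(gold_tags)
  p <- unlist(predicted_tags)
  if (length(g) != length(p)) {
    stopf("token count mismatch: %d vs %d", length(g), length(p))
  }
  mean(g == p)
}

#' Compare two sets of run scores with a two-tailed t-test
#'
#' Welch's unequal-variance two-sample test by default (a paired test is
#' available); significance is declared at alpha = 0.05. When both samples
#' have zero variance the convention is p = 1 for equal means and p = 0
#' otherwise.
#'
#' @param scores_a,scores_b Numeric vectors of per-run scores (length >= 2).
#' @param paired Use a paired test (samples must have equal length).
#' @param alpha Significance level (default 0.05).
#' @return A `significance_result` with `t_statistic`, `p_value` and
#'   `significant`.
#' @export
compare_runs <- function(scores_a, scores_b, paired = FALSE, alpha = 0.05) {
  if (length(scores_a) < 2L || length(scores_b) < 2L) {
    stopf("each sample needs at least 2 scores")
  }
  degenerate <- stats::sd(scores_a) == 0 && stats::sd(scores_b) == 0 &&
    (!paired || stats::sd(scores_a - scores_b) == 0)
  if (degenerate) {
    equal <- isTRUE(all.equal(mean(scores_a), mean(scores_b)))
    t_stat <- if (equal) 0 else sign(mean(scores_a) - mean(scores_b)) * Inf
    p <- if (equal) 1 else 0
  } else {
    tt <- stats::t.test(scores_a, scores_b, paired = paired,
                        var.equal = FALSE, alternative = "two.sided")
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(list(t_statistic = t_stat, p_value = p,
                 significant = p < alpha, alpha = alpha, paired = paired),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf("Two-tailed t-test%s: t = %.4g, p = %.4g (%ssignificant at alpha = %g)\n",
              if (x$paired) " (paired)" else "", x$t_statistic, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}
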
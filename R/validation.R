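# Scoring annotations against gold labels: exact/lenient matching,
# confusion-matrix metrics, paired and unpaired statistics.

#' Exact and lenient biome matching
#'
#' Exact: the normalised prediction equals the gold label verbatim.
#' Lenient: exactly one of the five allowed biome labels occurs as a
#' complete word in the prediction (possibly followed by clarifying text,
#' e.g. "animal (human)") and that label equals the gold label. A
#' prediction containing two or more distinct biome words (ambiguity) never
#' matches leniently. "animals" does not match "animal": the label must
#' appear as a complete word. Exact implies lenient.
#'
#' @param prediction Free-text predicted biome (vectorised); `NA` never
#'   matches.
#' @param gold Gold biome label(s) from [biome_levels()].
#' @return data.frame with logical columns `exact` and `lenient`.
#' @export
match_biome <- function(prediction, gold) {
  stopifnot(all(gold %in% biome_levels()))
  pred <- normalize_label(prediction)
  exact <- !is.na(pred) & pred == gold
  extracted <- extract_biome_word(pred)
  lenient <- !is.na(extracted) & extracted == gold
  lenient <- lenient | exact
  data.frame(exact = exact, lenient = lenient)
}

# the single biome label occurring as a whole word, or NA if zero or >= 2
extract_biome_word <- function(pred_normalized) {
  vapply(pred_normalized, function(p) {
    if (is.na(p)) return(NA_character_)
    hits <- biome_levels()[vapply(biome_levels(), function(b) {
      grepl(paste0("\\b", b, "\\b"), p)
    }, logical(1))]
    if (length(hits) == 1L) hits else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Score annotations sample-by-sample against gold labels
#'
#' @param annotations Annotation data.frame (`sample_id`, `biome_raw`, and
#'   optionally `sub_biome`, `status`).
#' @param gold data.frame with `sample_id`, `biome`, and optionally
#'   `sub_biome`.
#' @return data.frame: sample_id, gold_biome, pred_biome, exact, lenient
#'   (unresolved predictions are non-matches; they stay in the table).
#' @export
score_annotations <- function(annotations, gold) {
  ids <- intersect(annotations$sample_id, gold$sample_id)
  if (!length(ids)) stop("no sample_id overlap between annotations and gold")
  a <- annotations[match(ids, annotations$sample_id), ]
  g <- gold[match(ids, gold$sample_id), ]
  m <- match_biome(a$biome_raw, g$biome)
  data.frame(sample_id = ids, gold_biome = g$biome, pred_biome = a$biome_raw,
             exact = m$exact, lenient = m$lenient, stringsAsFactors = FALSE)
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement computed from the full (possibly
#' non-square) contingency table of gold rows by predicted columns.
#'
#' @param mat Numeric matrix of counts; row/column names are matched where
#'   present (unnamed square matrices assume aligned classes).
#' @return Kappa in `[-1, 1]`.
#' @export
kappa_from_matrix <- function(mat) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("c", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("c", seq_len(ncol(mat)))[seq_len(ncol(mat))]
  classes <- union(rownames(mat), colnames(mat))
  full <- matrix(0, length(classes), length(classes),
                 dimnames = list(classes, classes))
  full[rownames(mat), colnames(mat)] <- mat
  n <- sum(full)
  if (n == 0) stop("empty confusion matrix")
  po <- sum(diag(full)) / n
  pe <- sum(rowSums(full) * colSums(full)) / n^2
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

#' Metrics from a gold-by-predicted confusion matrix
#'
#' Accuracy plus macro-averaged precision, recall and F1 over the gold
#' classes, and Cohen's kappa. Precision for a class never predicted is 0
#' by convention.
#'
#' @param mat Counts, rows = gold classes, columns = predicted classes
#'   (columns may include extra classes such as `"none"`).
#' @return List: accuracy, precision, recall, f1 (all proportions in
#'   `[0, 1]`), kappa, confusion (counts), confusion_prop (row-normalised).
#' @export
metrics_from_confusion <- function(mat) {
  mat <- as.matrix(mat)
  gold_classes <- rownames(mat)
  n <- sum(mat)
  if (n == 0) stop("empty confusion matrix")
  tp <- vapply(gold_classes, function(cl) {
    if (cl %in% colnames(mat)) mat[cl, cl] else 0
  }, numeric(1))
  row_tot <- rowSums(mat)
  col_tot <- vapply(gold_classes, function(cl) {
    if (cl %in% colnames(mat)) sum(mat[, cl]) else 0
  }, numeric(1))
  prec <- ifelse(col_tot > 0, tp / col_tot, 0)
  rec <- ifelse(row_tot > 0, tp / row_tot, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  prop <- sweep(mat, 1, pmax(row_tot, 1), "/")
  list(accuracy = sum(tp) / n,
       precision = mean(prec), recall = mean(rec), f1 = mean(f1),
       per_class = data.frame(class = gold_classes, precision = prec,
                              recall = rec, f1 = f1,
                              accuracy = rec, stringsAsFactors = FALSE),
       kappa = kappa_from_matrix(mat),
       confusion = mat, confusion_prop = prop)
}

#' Compute the validation metrics report for a prediction run
#'
#' Builds the gold-by-predicted confusion matrix (five biome rows; predicted
#' columns are the five biomes plus a sixth `"none"` column for unresolved
#' or unmatchable predictions, which therefore count as wrong) and derives
#' overall and per-biome accuracy, macro precision/recall/F1 and Cohen's
#' kappa. In `exact` mode the predicted class is the normalised prediction
#' when it is one of the five labels; in `lenient` mode it is the single
#' biome word extracted from the prediction text.
#'
#' @param annotations Annotation data.frame (`sample_id`, `biome_raw`).
#' @param gold Gold data.frame (`sample_id`, `biome`).
#' @param match_mode `"lenient"` (default) or `"exact"`.
#' @return A `metrics_report`: list as [metrics_from_confusion()] plus
#'   `match_mode` and `n`.
#' @export
compute_metrics <- function(annotations, gold, match_mode = c("lenient", "exact")) {
  match_mode <- match.arg(match_mode)
  ids <- intersect(annotations$sample_id, gold$sample_id)
  if (!length(ids)) stop("no sample_id overlap between annotations and gold")
  a <- annotations[match(ids, annotations$sample_id), ]
  g <- gold[match(ids, gold$sample_id), ]
  pred_norm <- normalize_label(a$biome_raw)
  pred_class <- if (match_mode == "exact") {
    ifelse(!is.na(pred_norm) & pred_norm %in% biome_levels(), pred_norm, "none")
  } else {
    ex <- extract_biome_word(pred_norm)
    ifelse(!is.na(ex), ex, "none")
  }
  mat <- table(factor(g$biome, levels = biome_levels()),
               factor(pred_class, levels = c(biome_levels(), "none")))
  mat <- unclass(mat)
  out <- metrics_from_confusion(mat)
  out$match_mode <- match_mode
  out$n <- length(ids)
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d mode=%s acc=%.1f%% prec=%.1f%% F1=%.1f%% kappa=%.3f\n",
              x$n, x$match_mode, 100 * x$accuracy, 100 * x$precision,
              100 * x$f1, x$kappa))
  invisible(x)
}

#' McNemar's test for paired binary outcomes
#'
#' Uses the discordant-pair counts `b` (A correct, B wrong) and `c`
#' (B correct, A wrong). For `b + c >= 25` the chi-square approximation
#' `(b - c)^2 / (b + c)` on 1 df is used (no continuity correction); for
#' smaller discordant counts the exact two-sided binomial test
#' `min(1, 2 * P(X <= min(b, c)))` with `n = b + c`, `p = 1/2`. With no
#' discordant pairs the statistic is 0 and `p = 1` by convention.
#'
#' @param outcomeA,outcomeB Logical vectors over the same samples, in the
#'   same order.
#' @return List of class `stat_test_result`: test_name, statistic, p,
#'   p_adjusted (`NA` until a family correction is applied), b, c, n.
#' @export
mcnemar_test <- function(outcomeA, outcomeB) {
  stopifnot(length(outcomeA) == length(outcomeB))
  b <- sum(outcomeA & !outcomeB)
  c_ <- sum(!outcomeA & outcomeB)
  n_disc <- b + c_
  if (n_disc == 0) {
    stat <- 0; p <- 1
  } else if (n_disc >= 25) {
    stat <- (b - c_)^2 / n_disc
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    stat <- (b - c_)^2 / n_disc
    p <- min(1, 2 * stats::pbinom(min(b, c_), n_disc, 0.5))
  }
  structure(list(test_name = "mcnemar", statistic = stat, p = p,
                 p_adjusted = NA_real_, b = b, c = c_, n = length(outcomeA)),
            class = "stat_test_result")
}

#' Paired or independent t test on similarity scores
#'
#' Two-sided. Paired mode requires equal lengths over shared samples; the
#' independent mode uses the Welch form. Degenerate-input conventions: if
#' all paired differences are exactly zero, `p = 1` and the statistic is 0
#' (no evidence of a difference); if the differences are all identical but
#' non-zero the t statistic is undefined and an error is raised.
#'
#' @param simsA,simsB Numeric vectors (cosine similarities or 0/1
#'   correctness indicators).
#' @param paired Logical.
#' @return A `stat_test_result` (test_name `paired_t` or `independent_t`).
#' @export
t_tests <- function(simsA, simsB, paired = FALSE) {
  if (paired) {
    stopifnot(length(simsA) == length(simsB))
    if (length(simsA) < 2) stop("need n >= 2 for a t test")
    d <- simsA - simsB
    if (max(abs(d)) == 0) {
      return(structure(list(test_name = "paired_t", statistic = 0, p = 1,
                            p_adjusted = NA_real_, n = length(d)),
                       class = "stat_test_result"))
    }
    if (stats::sd(d) < 1e-12 * max(abs(d))) {
      stop("constant non-zero paired differences: t statistic undefined")
    }
    tt <- stats::t.test(simsA, simsB, paired = TRUE)
    nm <- "paired_t"
  } else {
    if (length(simsA) < 2 || length(simsB) < 2) stop("need n >= 2 per group")
    tt <- stats::t.test(simsA, simsB, var.equal = FALSE)
    nm <- "independent_t"
  }
  structure(list(test_name = nm, statistic = unname(tt$statistic),
                 p = tt$p.value, p_adjusted = NA_real_,
                 n = length(simsA)),
            class = "stat_test_result")
}

#' Bonferroni correction
#'
#' `p_adj = min(1, p * m)` with `m` the number of comparisons in the
#' family (defaults to the length of the vector, in which case
#' [stats::p.adjust()] is used).
#'
#' @param p_values Numeric vector of p values in `[0, 1]`.
#' @param m Family size.
#' @return Adjusted p values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  if (m == length(p_values)) {
    stats::p.adjust(p_values, method = "bonferroni")
  } else {
    pmin(1, p_values * m)
  }
}

#' Compare two scored runs
#'
#' Selects the paired tests (McNemar for biome correctness, paired t for
#' cosine similarity) when the two runs cover the identical sample-ID set,
#' and independent Welch t tests otherwise; partially overlapping ID sets
#' are an explicit error unless `allow_unpaired = TRUE` restricts nothing
#' and treats the runs as independent samples. Bonferroni correction is
#' applied across the family of comparisons in the returned report.
#'
#' @param runA,runB Scored results from [score_annotations()], optionally
#'   with a `cosine_sim` column.
#' @param match_mode Which correctness column to test (`"lenient"` or
#'   `"exact"`).
#' @param allow_unpaired Accept partially overlapping ID sets as unpaired.
#' @return data.frame: comparison, test_name, statistic, p, p_adjusted.
#' @export
compare_runs <- function(runA, runB, match_mode = c("lenient", "exact"),
                         allow_unpaired = FALSE) {
  match_mode <- match.arg(match_mode)
  idsA <- runA$sample_id; idsB <- runB$sample_id
  same <- setequal(idsA, idsB)
  overlap <- length(intersect(idsA, idsB))
  if (!same && overlap > 0 && !allow_unpaired) {
    stop("sample-ID sets overlap partially (", overlap,
         " shared); restrict to the common set or set allow_unpaired = TRUE")
  }
  rows <- list()
  if (same) {
    ord <- match(sort(idsA), idsA); ordB <- match(sort(idsA), idsB)
    mc <- mcnemar_test(runA[[match_mode]][ord], runB[[match_mode]][ordB])
    rows[["biome"]] <- data.frame(comparison = paste0("biome_", match_mode),
                                  test_name = mc$test_name,
                                  statistic = mc$statistic, p = mc$p)
    if (!is.null(runA$cosine_sim) && !is.null(runB$cosine_sim)) {
      tt <- t_tests(runA$cosine_sim[ord], runB$cosine_sim[ordB], paired = TRUE)
      rows[["sub"]] <- data.frame(comparison = "subbiome_cosine",
                                  test_name = tt$test_name,
                                  statistic = tt$statistic, p = tt$p)
    }
  } else {
    tt <- t_tests(as.numeric(runA[[match_mode]]), as.numeric(runB[[match_mode]]),
                  paired = FALSE)
    rows[["biome"]] <- data.frame(comparison = paste0("biome_", match_mode),
                                  test_name = tt$test_name,
                                  statistic = tt$statistic, p = tt$p)
    if (!is.null(runA$cosine_sim) && !is.null(runB$cosine_sim)) {
      ts <- t_tests(runA$cosine_sim, runB$cosine_sim, paired = FALSE)
      rows[["sub"]] <- data.frame(comparison = "subbiome_cosine",
                                  test_name = ts$test_name,
                                  statistic = ts$statistic, p = ts$p)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni(out$p)
  rownames(out) <- NULL
  out
}
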
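# Matching, metrics, McNemar, t tests, Bonferroni, embeddings, run comparison.

test_that("exact and lenient biome matching follow the complete-word rule", {
  m <- match_biome(c("animal", "animal (human)", "animals", "Animal ",
                     "animal or soil", NA),
                   c("animal", "animal", "animal", "animal", "animal", "animal"))
  expect_equal(m$exact, c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(m$lenient, c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  # exact always implies lenient
  expect_true(all(!m$exact | m$lenient))
})

test_that("a hand-computed 2-class confusion yields accuracy 80% and kappa 0.60", {
  mat <- matrix(c(45, 5, 15, 35), 2, 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("a", "b")))
  met <- metrics_from_confusion(mat)
  expect_equal(met$accuracy, 0.8)
  expect_equal(met$kappa, 0.6)      # p_o = 0.8, p_e = 0.5
  expect_equal(kappa_from_matrix(mat), 0.6)
})

test_that("perfect predictions score 100% accuracy, F1 and kappa 1", {
  bm <- tiny_benchmark(4, seed = 67)
  ann <- data.frame(sample_id = bm$gold$sample_id, biome_raw = bm$gold$biome)
  met <- compute_metrics(ann, bm$gold, "exact")
  expect_equal(met$accuracy, 1)
  expect_equal(met$f1, 1)
  expect_equal(met$kappa, 1)
  expect_equal(sum(met$confusion), nrow(bm$gold))
  expect_true(all(abs(rowSums(met$confusion_prop) - 1) < 1e-12))
})

test_that("metrics agree with the from-definitions oracle on random instances", {
  set.seed(1234)
  classes <- biome_levels()
  for (rep in 1:1000) {
    n <- sample(10:60, 1)
    gold <- sample(classes, n, replace = TRUE)
    pred <- ifelse(stats::runif(n) < 0.6, gold, sample(classes, n, replace = TRUE))
    # guarantee every gold class appears so per-class recall is defined
    gold[1:5] <- classes
    mat <- table(factor(gold, classes), factor(pred, classes))
    met <- metrics_from_confusion(unclass(mat))
    ora <- oracle_metrics(gold, pred, classes)
    expect_equal(met$accuracy, ora$accuracy, tolerance = 1e-12)
    expect_equal(met$precision, ora$precision, tolerance = 1e-12)
    expect_equal(met$recall, ora$recall, tolerance = 1e-12)
    expect_equal(met$f1, ora$f1, tolerance = 1e-12)
    expect_equal(met$kappa, ora$kappa, tolerance = 1e-12)
  }
})

test_that("unresolved predictions land in the none column and count as wrong", {
  gold <- data.frame(sample_id = paste0("SRS", 1:10),
                     biome = rep(biome_levels(), 2))
  ann <- data.frame(sample_id = gold$sample_id, biome_raw = gold$biome)
  ann$biome_raw[c(3, 8)] <- NA  # unresolved
  met <- compute_metrics(ann, gold, "lenient")
  expect_equal(met$accuracy, 0.8)
  expect_equal(sum(met$confusion[, "none"]), 2)
  expect_equal(sum(met$confusion), 10)
  expect_error(compute_metrics(data.frame(sample_id = "X1", biome_raw = "soil"),
                               gold), "overlap")
})

test_that("lenient accuracy is never below exact accuracy", {
  bm <- generate_benchmark(10, seed = 71)
  ma <- mock_annotate(bm$records, bm$gold, confusion = confusion_spec(0.7), seed = 5)
  res <- parse_inline(paste(ma$responses, collapse = "\n"), bm$gold$sample_id)
  # decorate some predictions with clarifying text (exact fails, lenient holds)
  res$annotations$biome_raw[1:20] <- paste0(res$annotations$biome_raw[1:20],
                                            " (incl. detail)")
  lenient <- compute_metrics(res$annotations, bm$gold, "lenient")$accuracy
  exact <- compute_metrics(res$annotations, bm$gold, "exact")$accuracy
  expect_gte(lenient, exact)
})

test_that("McNemar uses the exact binomial branch below 25 discordant pairs", {
  r <- mcnemar_test(c(rep(TRUE, 10), rep(FALSE, 10), TRUE),
                    c(rep(FALSE, 10), rep(TRUE, 10), TRUE))
  expect_equal(r$statistic, 0)      # b = c = 10: no asymmetry
  expect_equal(r$p, 1)
  # b = 1, c = 9 -> 2 * P(X <= 1 | n = 10) = 22/1024
  outA <- c(TRUE, rep(FALSE, 9)); outB <- c(FALSE, rep(TRUE, 9))
  r2 <- mcnemar_test(outA, outB)
  expect_equal(r2$p, 22 / 1024, tolerance = 1e-12)
  # zero discordance convention
  r0 <- mcnemar_test(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(r0$p, 1); expect_equal(r0$statistic, 0)
})

test_that("McNemar chi-square branch matches an independent CDF oracle", {
  outA <- c(rep(TRUE, 40), rep(FALSE, 20), rep(TRUE, 5))
  outB <- c(rep(FALSE, 40), rep(TRUE, 20), rep(TRUE, 5))
  r <- mcnemar_test(outA, outB)
  expect_equal(r$b, 40); expect_equal(r$c, 20)
  expect_equal(r$statistic, 400 / 60, tolerance = 1e-12)
  expect_equal(r$p, oracle_chisq1_upper(400 / 60), tolerance = 1e-10)
})

test_that("exact-branch p agrees with full binomial enumeration for b+c <= 24", {
  for (n_disc in 1:24) {
    for (b in 0:n_disc) {
      c_ <- n_disc - b
      outA <- c(rep(TRUE, b), rep(FALSE, c_))
      outB <- c(rep(FALSE, b), rep(TRUE, c_))
      r <- mcnemar_test(outA, outB)
      expect_equal(r$p, oracle_exact_binom_p(b, c_), tolerance = 1e-12,
                   info = sprintf("b=%d c=%d", b, c_))
    }
  }
})

test_that("t tests honour degenerate conventions and detect clear shifts", {
  expect_equal(t_tests(c(.5, .6, .7), c(.5, .6, .7), paired = TRUE)$p, 1)
  expect_error(t_tests(c(.5, .6, .7), c(.4, .5, .6), paired = TRUE),
               "constant non-zero")
  expect_error(t_tests(1, 2, paired = TRUE), "n >= 2")
  set.seed(8)
  base <- stats::rnorm(50, 0.5, 0.01)
  shifted <- base + 0.1 + stats::rnorm(50, 0, 0.01)  # delta 0.1, sigma 0.01
  expect_lt(t_tests(shifted, base, paired = TRUE)$p, 1e-6)
})

test_that("independent t test rejects at about the nominal 5% rate", {
  set.seed(2026)
  rejections <- vapply(1:2000, function(i) {
    a <- stats::rnorm(20); b <- stats::rnorm(20)
    t_tests(a, b, paired = FALSE)$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.015)
})

test_that("Bonferroni multiplies and caps", {
  expect_equal(bonferroni(0.01, m = 5), 0.05)
  expect_equal(bonferroni(0.4, m = 5), 1)
  expect_equal(bonferroni(c(0.2)), 0.2)
  expect_equal(bonferroni(c(0.01, 0.04)), c(0.02, 0.08))
})

test_that("cosine similarity matches hand computations and rejects zeros", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2, 2), c(2, 1, 2)), 8 / 9)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero")
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "dimension")
})

test_that("the mock embedder is deterministic and token-overlap monotone", {
  prov <- mock_embedding_provider(dim = 256, seed = 3)
  e <- embed_texts(c("human gut", "human gut", "human intestine overlap gut",
                     "desert soil"), prov)
  expect_equal(nrow(e$errors), 0)
  expect_equal(cosine_similarity(e$vectors[[1]], e$vectors[[2]]), 1)
  sim_close <- cosine_similarity(e$vectors[[1]], e$vectors[[3]])
  sim_far <- cosine_similarity(e$vectors[[1]], e$vectors[[4]])
  expect_gt(sim_close, sim_far)
  # empty text becomes an error record, not a silent loss
  e2 <- embed_texts(c("human gut", ""), prov)
  expect_equal(e2$errors$index, 2)
  expect_null(e2$vectors[[2]])
  # provider mixing is refused
  other <- mock_embedding_provider(dim = 256, seed = 4)
  expect_error(cosine_similarity(e$vectors[[1]],
                                 other$embed_one("human gut")), "provider")
})

test_that("run comparison picks paired tests for identical ID sets", {
  bm <- tiny_benchmark(6, seed = 73)
  ma <- mock_annotate(bm$records, bm$gold, confusion = confusion_spec(0.8),
                      seed = 12, noise = noise_profile(paraphrase_rate = 0.4))
  ann <- parse_inline(paste(ma$responses, collapse = "\n"),
                      bm$gold$sample_id)$annotations
  runA <- score_annotations(ann, bm$gold)
  runA$cosine_sim <- subbiome_similarity(ann, bm$gold)$cosine_sim
  # identical runs: no discordance anywhere, all p = 1
  rep_same <- compare_runs(runA, runA)
  expect_true(all(rep_same$p == 1))
  expect_equal(rep_same$test_name[rep_same$comparison == "biome_lenient"],
               "mcnemar")
  expect_equal(rep_same$test_name[rep_same$comparison == "subbiome_cosine"],
               "paired_t")
  expect_true(all(rep_same$p_adjusted >= rep_same$p))

  # disjoint ID sets: independent t tests
  runB <- runA
  runB$sample_id <- paste0("SRX", seq_len(nrow(runB)))
  runB$cosine_sim <- runB$cosine_sim + stats::rnorm(nrow(runB), 0, 1e-4)
  rep_ind <- compare_runs(runA, runB)
  expect_true(all(rep_ind$test_name == "independent_t"))

  # partial overlap is an explicit error
  runC <- runA
  runC$sample_id[1] <- "SRX999"
  expect_error(compare_runs(runA, runC), "overlap")
})
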
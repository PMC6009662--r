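# Accuracy-filtered voting ensemble: CV retention, voting, tie-breaks,
# determinism and importance ranking.

separable_data <- function(n = 80L, p = 10L, seed = 1L) {
  set.seed(seed)
  y <- rep(c("non-NMD", "NMD"), each = n / 2L)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("e%03d", seq_len(n)),
                              paste0("f", seq_len(p))))
  x[, 1L] <- ifelse(y == "NMD", 6, -6) + rnorm(n, sd = 0.3)
  x[, 2L] <- ifelse(y == "NMD", -4, 4) + rnorm(n, sd = 0.3)
  list(x = x, y = stats::setNames(y, rownames(x)))
}

test_that("a linearly separable problem retains the whole roster", {
  d <- separable_data()
  ens <- train_ensemble(d$x, d$y, ensemble_config("EXP", seed = 3L))
  expect_equal(sort(ens$retained), sort(names(default_learner_roster())))
  expect_true(all(ens$cv_report$cv_accuracy >= 0.95))
})

test_that("default accuracy thresholds are 0.95 (EXP) and 0.75 (NOEXP)", {
  expect_equal(ensemble_config("EXP")$accuracy_threshold, 0.95)
  expect_equal(ensemble_config("NOEXP")$accuracy_threshold, 0.75)
  expect_equal(ensemble_config("EXP")$repeats, 3L)
  expect_equal(ensemble_config("EXP")$folds, 5L)
  expect_error(ensemble_config("EXP", accuracy_threshold = 0.4))
})

test_that("training fails loudly when no model clears the threshold", {
  set.seed(5)
  x <- matrix(rnorm(60L * 5L), 60L,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- rep(c("NMD", "non-NMD"), 30L)
  expect_error(train_ensemble(x, y, ensemble_config("EXP", seed = 2L)),
               "best was")
})

test_that("raising the threshold never enlarges the retained set", {
  d <- separable_data(n = 60L, seed = 7L)
  d$x[, 1L] <- d$x[, 1L] + rnorm(60L, sd = 4)  # make it imperfect
  lo <- train_ensemble(d$x, d$y,
                       ensemble_config("NOEXP", accuracy_threshold = 0.6,
                                       seed = 11L))
  hi <- tryCatch(
    train_ensemble(d$x, d$y,
                   ensemble_config("NOEXP", accuracy_threshold = 0.9,
                                   seed = 11L)),
    error = function(e) NULL)
  hi_set <- if (is.null(hi)) character(0) else hi$retained
  expect_true(all(hi_set %in% lo$retained))
})

test_that("a fixed seed reproduces retained models, votes and report", {
  d <- separable_data(n = 60L, seed = 9L)
  e1 <- train_ensemble(d$x, d$y, ensemble_config("EXP", seed = 42L))
  e2 <- train_ensemble(d$x, d$y, ensemble_config("EXP", seed = 42L))
  expect_identical(e1$retained, e2$retained)
  expect_identical(e1$cv_report, e2$cv_report)
  expect_identical(attr(predict_ensemble(e1, d$x), "votes"),
                   attr(predict_ensemble(e2, d$x), "votes"))
})

test_that("majority voting breaks exact ties toward non-NMD", {
  fake <- function(vote) {
    list(fit = function(x, y) list(),
         predict = function(m, x) {
           factor(rep(if (vote) "NMD" else "non-NMD", nrow(x)),
                  levels = c("non-NMD", "NMD"))
         },
         importance = function(m, x, y)
           stats::setNames(rep(1, ncol(x)), colnames(x)))
  }
  mk_ens <- function(votes) {
    ids <- paste0("m", seq_along(votes))
    structure(list(
      models = stats::setNames(rep(list(list()), length(votes)), ids),
      retained = ids,
      roster = stats::setNames(lapply(votes, fake), ids),
      features = c("f1", "f2"),
      train_x = matrix(0, 2L, 2L, dimnames = list(NULL, c("f1", "f2"))),
      train_y = factor(c("NMD", "non-NMD"),
                       levels = c("non-NMD", "NMD"))),
      class = "nmd_ensemble")
  }
  x <- matrix(0, 3L, 2L, dimnames = list(paste0("e", 1:3), c("f1", "f2")))
  maj <- predict_ensemble(mk_ens(c(TRUE, TRUE, FALSE)), x)
  expect_true(all(maj$is_nmd))
  expect_equal(maj$vote_fraction, rep(2 / 3, 3L))
  tie <- predict_ensemble(mk_ens(c(TRUE, FALSE)), x)
  expect_false(any(tie$is_nmd))
  expect_equal(tie$vote_fraction, rep(0.5, 3L))
})

test_that("schema mismatches are rejected with the offending columns", {
  d <- separable_data(n = 40L, seed = 13L)
  ens <- train_ensemble(d$x, d$y, ensemble_config("NOEXP", seed = 1L))
  bad <- d$x[, -1L]
  expect_error(predict_ensemble(ens, bad), "f1")
})

test_that("a planted 3'UTR-junction signal tops the importance ranking", {
  set.seed(19)
  n <- 90L
  y <- rep(c("non-NMD", "NMD"), length.out = n)
  x <- matrix(rnorm(n * 12L), n, 12L)
  colnames(x) <- c("n_3utr_spliced_introns", paste0("noise_", 1:11))
  x[, 1L] <- ifelse(y == "NMD", 2, 0) + rnorm(n, sd = 0.25)
  rownames(x) <- sprintf("e%03d", seq_len(n))
  ens <- train_ensemble(x, stats::setNames(y, rownames(x)),
                        ensemble_config("EXP", seed = 23L))
  imp <- rank_importance(ens)
  expect_equal(imp$feature[1L], "n_3utr_spliced_introns")
  expect_equal(imp$sign[1L], "positive")
  expect_gt(imp$median_importance[1L], max(imp$median_importance[-1L]))
  # an uninformative feature carries (near) zero importance
  expect_lt(imp$median_importance[imp$feature == "noise_1"], 0.2)
})

test_that("single retained model medians equal that model's importances", {
  d <- separable_data(n = 40L, seed = 29L)
  cfg <- ensemble_config("EXP", seed = 31L,
                         roster = default_learner_roster()["glmnet_lasso"])
  ens <- train_ensemble(d$x, d$y, cfg)
  imp <- rank_importance(ens)
  raw <- abs(as.numeric(stats::coef(ens$models$glmnet_lasso$fit))[-1L])
  want <- raw / max(raw)
  expect_equal(imp$median_importance[match(colnames(d$x), imp$feature)],
               unname(want), tolerance = 1e-10)
})

test_that("fold preprocessing does not leak labels into evaluation", {
  # pure-noise features: CV accuracy must hover at chance for the
  # scaled learners (leakage would inflate it)
  set.seed(37)
  x <- matrix(rnorm(80L * 6L), 80L, dimnames = list(NULL, paste0("f", 1:6)))
  y <- rep(c("NMD", "non-NMD"), 40L)
  got <- tryCatch(
    train_ensemble(x, y, ensemble_config("NOEXP", accuracy_threshold = 0.74,
                                         seed = 41L)),
    error = function(e) e)
  acc <- if (inherits(got, "error")) {
    as.numeric(sub(".*at ([0-9.]+)$", "\\1", conditionMessage(got)))
  } else max(got$cv_report$cv_accuracy)
  expect_lt(acc, 0.74)
})
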
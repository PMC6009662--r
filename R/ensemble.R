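# Accuracy-filtered voting ensemble: many base classifiers are evaluated by
# repeated stratified cross-validation, those at or above an accuracy
# threshold are retained and refit, and events are labelled is.NMD by strict
# majority vote; feature importances are medians of per-model normalized
# importances.

NMD_LEVELS <- c("non-NMD", "NMD")

#' Ensemble configuration
#'
#' Defaults follow the published procedure: three-times-repeated stratified
#' 5-fold cross-validation, with models retained at accuracy >= 0.95 in EXP
#' mode and >= 0.75 in NOEXP mode.
#'
#' @param mode `"EXP"` or `"NOEXP"` (sets the default accuracy threshold).
#' @param repeats,folds cross-validation design.
#' @param accuracy_threshold retention threshold in (0.5, 1]; default 0.95
#'   for EXP, 0.75 for NOEXP.
#' @param roster base-learner roster, as from [default_learner_roster()].
#' @param seed integer seed governing folds and stochastic learners.
#' @return list of class `ensemble_config`.
#' @export
ensemble_config <- function(mode = c("EXP", "NOEXP"), repeats = 3L,
                            folds = 5L, accuracy_threshold = NULL,
                            roster = default_learner_roster(),
                            seed = 1L) {
  mode <- match.arg(mode)
  accuracy_threshold <- accuracy_threshold %||%
    if (mode == "EXP") 0.95 else 0.75
  stopifnot(accuracy_threshold > 0.5, accuracy_threshold <= 1, folds >= 2L)
  structure(list(mode = mode, repeats = repeats, folds = folds,
                 accuracy_threshold = accuracy_threshold, roster = roster,
                 seed = as.integer(seed)),
            class = "ensemble_config")
}

# standardize a matrix with training-fold statistics only (no leakage)
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  sd[sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}
apply_scaler <- function(scaler, x) {
  sweep(sweep(x, 2L, scaler$mu, `-`), 2L, scaler$sd, `/`)
}

# permutation importance on the training data (fallback for learners with
# no native importance measure)
perm_importance <- function(predict_fun, fit, x, y, nrep = 3L) {
  base_acc <- mean(predict_fun(fit, x) == y)
  imp <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    drop <- 0
    for (r in seq_len(nrep)) {
      xp <- x
      xp[, j] <- sample(xp[, j])
      drop <- drop + (base_acc - mean(predict_fun(fit, xp) == y))
    }
    imp[j] <- max(drop / nrep, 0)
  }
  stats::setNames(imp, colnames(x))
}

make_learner <- function(id, fit, predict, importance = NULL) {
  list(id = id, fit = fit, predict = predict,
       importance = importance %||% function(m, x, y)
         perm_importance(predict, m, x, y))
}

#' Default base-learner roster
#'
#' A configurable roster of twelve model-family/hyperparameter variants
#' (regularized linear models, trees, random forests, boosted trees, naive
#' Bayes, nearest neighbours, margin-based models, a shallow network),
#' emulating a large heterogeneous classifier collection. Every learner
#' exposes `fit`, `predict` and a normalized `importance`.
#'
#' @return named list of learner definitions.
#' @export
default_learner_roster <- function() {
  glmnet_learner <- function(id, alpha) {
    make_learner(id,
      fit = function(x, y) {
        f <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                            lambda = 0.01, standardize = TRUE)
        list(fit = f)
      },
      predict = function(m, x) {
        pr <- stats::predict(m$fit, x, type = "class")
        factor(as.character(pr), levels = NMD_LEVELS)
      },
      importance = function(m, x, y) {
        co <- abs(as.numeric(stats::coef(m$fit))[-1L])
        stats::setNames(co, colnames(x))
      })
  }
  svm_learner <- function(id, kernel) {
    make_learner(id,
      fit = function(x, y) {
        sc <- fit_scaler(x)
        f <- e1071::svm(apply_scaler(sc, x), y, kernel = kernel,
                        scale = FALSE)
        list(fit = f, sc = sc)
      },
      predict = function(m, x) {
        factor(as.character(stats::predict(m$fit, apply_scaler(m$sc, x))),
               levels = NMD_LEVELS)
      },
      importance = function(m, x, y) {
        if (m$fit$kernel == 0L) {  # linear: |w|
          w <- abs(as.numeric(t(m$fit$coefs) %*% m$fit$SV))
          stats::setNames(w, colnames(x))
        } else {
          perm_importance(function(mm, xx)
            factor(as.character(stats::predict(mm$fit,
                                               apply_scaler(mm$sc, xx))),
                   levels = NMD_LEVELS), m, x, y)
        }
      })
  }
  list(
    glmnet_ridge = glmnet_learner("glmnet_ridge", 0),
    glmnet_elnet = glmnet_learner("glmnet_elnet", 0.5),
    glmnet_lasso = glmnet_learner("glmnet_lasso", 1),
    rf_classic = make_learner("rf_classic",
      fit = function(x, y) {
        list(fit = randomForest::randomForest(x, y, ntree = 300L))
      },
      predict = function(m, x)
        factor(as.character(stats::predict(m$fit, x)), levels = NMD_LEVELS),
      importance = function(m, x, y) {
        imp <- randomForest::importance(m$fit)[, "MeanDecreaseGini"]
        stats::setNames(as.numeric(imp), rownames(
          randomForest::importance(m$fit)))[colnames(x)]
      }),
    rf_ranger = make_learner("rf_ranger",
      fit = function(x, y) {
        d <- data.frame(x, check.names = FALSE)
        d$.y <- y
        list(fit = ranger::ranger(
          dependent.variable.name = ".y", data = d, num.trees = 300L,
          importance = "impurity", num.threads = 1L,
          seed = sample.int(1e6, 1L)))
      },
      predict = function(m, x) {
        pr <- stats::predict(m$fit, data.frame(x, check.names = FALSE),
                             num.threads = 1L)$predictions
        factor(as.character(pr), levels = NMD_LEVELS)
      },
      importance = function(m, x, y) {
        imp <- ranger::importance(m$fit)
        stats::setNames(as.numeric(imp), names(imp))[colnames(x)]
      }),
    xgb_trees = make_learner("xgb_trees",
      fit = function(x, y) {
        f <- xgboost::xgboost(
          x, factor(y == "NMD", levels = c(FALSE, TRUE)), nrounds = 60L,
          objective = "binary:logistic", max_depth = 3L,
          learning_rate = 0.3, nthreads = 1L, seed = sample.int(1e6, 1L))
        list(fit = f)
      },
      predict = function(m, x) {
        pr <- stats::predict(m$fit, x, type = "response")
        factor(NMD_LEVELS[(pr > 0.5) + 1L], levels = NMD_LEVELS)
      },
      importance = function(m, x, y) {
        imp <- xgboost::xgb.importance(model = m$fit)
        out <- stats::setNames(numeric(ncol(x)), colnames(x))
        out[imp$Feature] <- imp$Gain
        out
      }),
    cart = make_learner("cart",
      fit = function(x, y) {
        d <- data.frame(x, check.names = FALSE)
        d$.y <- y
        list(fit = rpart::rpart(.y ~ ., data = d, method = "class"))
      },
      predict = function(m, x) {
        pr <- stats::predict(m$fit, data.frame(x, check.names = FALSE),
                             type = "class")
        factor(as.character(pr), levels = NMD_LEVELS)
      },
      importance = function(m, x, y) {
        out <- stats::setNames(numeric(ncol(x)), colnames(x))
        imp <- m$fit$variable.importance
        if (!is.null(imp)) out[names(imp)] <- imp
        out
      }),
    svm_linear = svm_learner("svm_linear", "linear"),
    svm_radial = svm_learner("svm_radial", "radial"),
    naive_bayes = make_learner("naive_bayes",
      fit = function(x, y) {
        sc <- fit_scaler(x)
        list(fit = e1071::naiveBayes(apply_scaler(sc, x), y), sc = sc)
      },
      predict = function(m, x) {
        factor(as.character(stats::predict(m$fit, apply_scaler(m$sc, x))),
               levels = NMD_LEVELS)
      }),
    knn5 = make_learner("knn5",
      fit = function(x, y) {
        sc <- fit_scaler(x)
        list(train = apply_scaler(sc, x), y = y, sc = sc)
      },
      predict = function(m, x) {
        pr <- class::knn(m$train, apply_scaler(m$sc, x), m$y, k = 5L)
        factor(as.character(pr), levels = NMD_LEVELS)
      }),
    mlp = make_learner("mlp",
      fit = function(x, y) {
        sc <- fit_scaler(x)
        f <- nnet::nnet(apply_scaler(sc, x), class.ind(y), size = 4L,
                        decay = 0.5, maxit = 300L, trace = FALSE,
                        softmax = TRUE, MaxNWts = 100000L)
        list(fit = f, sc = sc)
      },
      predict = function(m, x) {
        pr <- stats::predict(m$fit, apply_scaler(m$sc, x), type = "class")
        factor(pr, levels = NMD_LEVELS)
      })
  )
}

class.ind <- function(y) {
  m <- stats::model.matrix(~ y - 1)
  colnames(m) <- levels(y)
  m
}

# stratified fold assignment: repeats x n matrix of fold ids
make_cv_folds <- function(y, folds, repeats, seed) {
  n <- length(y)
  out <- matrix(0L, nrow = repeats, ncol = n)
  set.seed(seed)
  for (r in seq_len(repeats)) {
    fold <- integer(n)
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    out[r, ] <- fold
  }
  out
}

as_nmd_factor <- function(labels) {
  if (is.logical(labels)) {
    labels <- ifelse(labels, "NMD", "non-NMD")
  }
  y <- factor(as.character(labels), levels = NMD_LEVELS)
  if (any(is.na(y))) stop("labels must be 'NMD'/'non-NMD' (or logical)")
  if (any(table(y) < 2L)) stop("need at least 2 examples per class")
  y
}

#' Train the accuracy-filtered ensemble
#'
#' Evaluates every roster learner by mean accuracy over
#' `repeats x folds` stratified cross-validation resamples, retains learners
#' with accuracy at or above the threshold, and refits the retained
#' learners on the full training set. All preprocessing (standardization)
#' happens inside each training fold.
#'
#' @param matrix numeric feature matrix with `event_id` rownames (typically
#'   [filter_features()] output).
#' @param labels named vector (`event_id` -> `"NMD"`/`"non-NMD"`, or
#'   logical is-NMD) covering the matrix rows, or an unnamed vector in row
#'   order.
#' @param cfg an [ensemble_config()].
#' @return object of class `nmd_ensemble`: retained fitted models, the full
#'   CV accuracy report (`$cv_report`), feature names, config.
#' @export
train_ensemble <- function(matrix, labels, cfg = ensemble_config()) {
  x <- as.matrix(matrix)
  if (!is.null(names(labels)) && !is.null(rownames(x))) {
    missing <- setdiff(rownames(x), names(labels))
    if (length(missing)) {
      stop("labels missing for ", length(missing), " matrix rows")
    }
    labels <- labels[rownames(x)]
  }
  y <- as_nmd_factor(labels)
  stopifnot(length(y) == nrow(x))
  roster <- cfg$roster
  fold_mat <- make_cv_folds(y, cfg$folds, cfg$repeats, cfg$seed)
  acc <- matrix(NA_real_, nrow = length(roster),
                ncol = cfg$repeats * cfg$folds,
                dimnames = list(names(roster), NULL))
  for (mi in seq_along(roster)) {
    lrn <- roster[[mi]]
    col <- 0L
    for (r in seq_len(cfg$repeats)) {
      for (f in seq_len(cfg$folds)) {
        col <- col + 1L
        test_idx <- which(fold_mat[r, ] == f)
        if (!length(test_idx)) next
        set.seed(cfg$seed + 7919L * mi + 101L * r + f)
        fit <- suppressWarnings(
          lrn$fit(x[-test_idx, , drop = FALSE], y[-test_idx]))
        pred <- suppressWarnings(
          lrn$predict(fit, x[test_idx, , drop = FALSE]))
        acc[mi, col] <- mean(pred == y[test_idx], na.rm = TRUE)
      }
    }
  }
  mean_acc <- rowMeans(acc, na.rm = TRUE)
  retained_ids <- names(roster)[mean_acc >= cfg$accuracy_threshold]
  if (!length(retained_ids)) {
    stop(sprintf(paste0("no model reached the accuracy threshold %.2f; ",
                        "best was %s at %.3f"),
                 cfg$accuracy_threshold, names(which.max(mean_acc)),
                 max(mean_acc)))
  }
  models <- list()
  for (id in retained_ids) {
    set.seed(cfg$seed + 7919L * match(id, names(roster)))
    models[[id]] <- suppressWarnings(roster[[id]]$fit(x, y))
  }
  structure(list(models = models, retained = retained_ids,
                 roster = roster[retained_ids],
                 cv_report = data.frame(model = names(roster),
                                        cv_accuracy = unname(mean_acc),
                                        retained = names(roster) %in%
                                          retained_ids,
                                        stringsAsFactors = FALSE),
                 features = colnames(x), config = cfg,
                 train_x = x, train_y = y),
            class = "nmd_ensemble")
}

#' @export
print.nmd_ensemble <- function(x, ...) {
  cat(sprintf("nmd_ensemble (%s mode): %d/%d models retained at accuracy >= %.2f\n",
              x$config$mode, length(x$retained), nrow(x$cv_report),
              x$config$accuracy_threshold))
  invisible(x)
}

#' Predict is.NMD calls with the ensemble
#'
#' Each retained model votes; an event is called NMD on a strict majority,
#' with exact ties resolved to non-NMD (conservative).
#'
#' @param ensemble an [train_ensemble()] result.
#' @param matrix feature matrix with the training schema (identical column
#'   set and order).
#' @return data.frame `event_id`, `is_nmd`, `vote_fraction`; the full vote
#'   matrix is attached as `attr(x, "votes")`.
#' @export
predict_ensemble <- function(ensemble, matrix) {
  x <- as.matrix(matrix)
  if (!identical(colnames(x), ensemble$features)) {
    missing <- setdiff(ensemble$features, colnames(x))
    extra <- setdiff(colnames(x), ensemble$features)
    if (length(missing) || length(extra)) {
      stop("feature schema mismatch; missing: [",
           paste(missing, collapse = ", "), "], unexpected: [",
           paste(extra, collapse = ", "), "]")
    }
    x <- x[, ensemble$features, drop = FALSE]
  }
  votes <- vapply(ensemble$retained, function(id) {
    suppressWarnings(
      ensemble$roster[[id]]$predict(ensemble$models[[id]], x)) == "NMD"
  }, logical(nrow(x)))
  votes <- matrix(votes, nrow = nrow(x),
                  dimnames = list(rownames(x), ensemble$retained))
  frac <- rowMeans(votes)
  out <- data.frame(event_id = rownames(x) %||%
                      as.character(seq_len(nrow(x))),
                    is_nmd = frac > 0.5, vote_fraction = frac,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "votes") <- votes
  out
}

#' Median feature importance across the retained models
#'
#' Importances are normalized to \[0, 1\] within each model (division by the
#' model's maximum) before taking per-feature medians; each feature's sign
#' marks it as a positive or negative predictor of NMD, from the direction
#' of its marginal association among predicted-NMD vs predicted-non-NMD
#' events.
#'
#' @param ensemble a trained [train_ensemble()] object.
#' @param matrix matrix used for the sign assessment; defaults to the
#'   training matrix.
#' @return data.frame `feature`, `median_importance`, `sign`
#'   (`"positive"`/`"negative"`), sorted by decreasing importance.
#' @export
rank_importance <- function(ensemble, matrix = NULL) {
  x <- if (is.null(matrix)) ensemble$train_x else as.matrix(matrix)
  imp <- vapply(ensemble$retained, function(id) {
    raw <- ensemble$roster[[id]]$importance(
      ensemble$models[[id]], ensemble$train_x, ensemble$train_y)
    nm <- names(raw) %||% ensemble$features
    v <- as.numeric(raw)[match(ensemble$features, nm)]
    v[is.na(v)] <- 0
    mx <- max(v)
    if (mx > 0) v / mx else v
  }, numeric(length(ensemble$features)))
  imp <- matrix(imp, nrow = length(ensemble$features),
                dimnames = list(ensemble$features, ensemble$retained))
  med <- apply(imp, 1L, stats::median)
  pred <- predict_ensemble(ensemble, x)
  sign <- vapply(seq_along(ensemble$features), function(j) {
    a <- mean(x[pred$is_nmd, j]); b <- mean(x[!pred$is_nmd, j])
    if (is.na(a) || is.na(b) || a >= b) "positive" else "negative"
  }, character(1L))
  out <- data.frame(feature = ensemble$features, median_importance = med,
                    sign = sign, row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$median_importance), , drop = FALSE]
}
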
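#' Base learner roster and tuned defaults
#'
#' Nine tuned base learners are available. The shipped hyperparameters are
#' frozen fine-tuned values (tuning itself is out of scope) and every value
#' can be overridden through [stack_config()]:
#'
#' * `svm` — RBF support-vector machine, `cost = 800` (via e1071).
#' * `knn` — k-nearest neighbours, `k = 4`.
#' * `random_forest` — 211 trees, depth 13 (via ranger).
#' * `extra_trees` — extremely randomised trees, 63 trees, depth 12
#'   (ranger, `splitrule = "extratrees"`, no bootstrap).
#' * `mlp` — single-hidden-layer perceptron, 20 logistic units, weight decay
#'   1e-4, 300 iterations (via nnet).
#' * `gbt_shallow` — gradient-boosted trees: 100 rounds, depth 3, learning
#'   rate 0.2, subsample 0.9, column subsample 0.85 (via xgboost).
#' * `gbt_depth5` — gradient-boosted trees: 100 rounds, depth 5, learning
#'   rate 0.1.
#' * `gbt_deep` — gradient-boosted trees: 1000 rounds, depth 10, learning
#'   rate 0.1.
#' * `voting` — hard-majority vote over the tuned `svm`, `knn` and
#'   `random_forest` members (membership configurable); its "probabilities"
#'   are the vote fractions.
#'
#' @return Named list of default hyperparameter lists.
#' @export
base_learner_specs <- function() {
  list(
    svm = list(kernel = "radial", cost = 800),
    knn = list(k = 4),
    random_forest = list(num_trees = 211, max_depth = 13),
    extra_trees = list(num_trees = 63, max_depth = 12),
    mlp = list(hidden = 20, decay = 1e-4, max_iter = 300),
    gbt_shallow = list(nrounds = 100, max_depth = 3, eta = 0.2,
                       subsample = 0.9, colsample_bytree = 0.85),
    gbt_depth5 = list(nrounds = 100, max_depth = 5, eta = 0.1),
    gbt_deep = list(nrounds = 1000, max_depth = 10, eta = 0.1),
    voting = list(members = c("svm", "knn", "random_forest"))
  )
}

.default_base_roster <- c("extra_trees", "mlp", "gbt_shallow", "gbt_depth5",
                          "gbt_deep", "voting")

.stack_features <- c("C3", "C4", "SumC3C4", "C3C4")

#' Configure a stacking classifier
#'
#' The stack trains its base learners with k-fold cross-validation and feeds
#' their out-of-fold class probabilities to a multinomial logistic-regression
#' meta-model (default hyperparameters). Only the four dimensionless ratio
#' features enter the model; age and gender are never model inputs, and no
#' normalisation is applied (all features share the same dimension-ratio
#' nature).
#'
#' @param base_learners Character vector of base learner names (see
#'   [base_learner_specs()] for the valid names and defaults).
#' @param params Named list of per-learner hyperparameter overrides, e.g.
#'   `list(knn = list(k = 7))`.
#' @param cv_folds Number of cross-validation folds used to produce the
#'   out-of-fold meta-features (>= 2).
#' @param features Feature columns used as model inputs.
#' @return A `cvd_stack_config` list.
#' @export
stack_config <- function(base_learners = .default_base_roster,
                         params = list(), cv_folds = 5,
                         features = .stack_features) {
  valid <- names(base_learner_specs())
  unknown <- setdiff(base_learners, valid)
  if (length(unknown) > 0) {
    abort(paste0("Unknown base learner(s): ", paste(unknown, collapse = ", "),
                 ". Valid names: ", paste(valid, collapse = ", "), "."))
  }
  if (length(base_learners) < 1) {
    abort("At least one base learner is required.")
  }
  if (cv_folds < 2) {
    abort("`cv_folds` must be at least 2.")
  }
  if (any(c("age", "gender") %in% features)) {
    abort("`age` and `gender` are never model inputs.")
  }
  specs <- base_learner_specs()
  for (nm in names(params)) {
    if (!nm %in% valid) {
      abort(paste0("Hyperparameter override for unknown learner: ", nm))
    }
    specs[[nm]] <- modifyList(specs[[nm]], params[[nm]])
  }
  structure(
    list(base_learners = base_learners, specs = specs,
         cv_folds = as.integer(cv_folds), features = features),
    class = "cvd_stack_config"
  )
}

#' Assemble an untrained stacking classifier
#'
#' @param config A [stack_config()].
#' @return An untrained `cvd_stack` object; fit it with [train_stack()].
#' @export
build_stack <- function(config = stack_config()) {
  if (!inherits(config, "cvd_stack_config")) {
    abort("`config` must be created with stack_config().")
  }
  structure(list(config = config, fitted = FALSE), class = "cvd_stack")
}

# ---- base learner fit / predict dispatch -----------------------------------

.fit_base <- function(name, spec, X, y, seed) {
  switch(name,
    svm = with_seed(seed, {
      list(kind = "svm",
           model = e1071::svm(x = X, y = y, kernel = spec$kernel,
                              cost = spec$cost, probability = TRUE))
    }),
    knn = list(kind = "knn", X = X, y = y, k = spec$k),
    random_forest = list(kind = "ranger", model = ranger::ranger(
      x = X, y = y, num.trees = spec$num_trees, max.depth = spec$max_depth,
      probability = TRUE, seed = seed, num.threads = 1)),
    extra_trees = list(kind = "ranger", model = ranger::ranger(
      x = X, y = y, num.trees = spec$num_trees, max.depth = spec$max_depth,
      splitrule = "extratrees", num.random.splits = 1, replace = FALSE,
      sample.fraction = 1, probability = TRUE, seed = seed,
      num.threads = 1)),
    mlp = with_seed(seed, {
      list(kind = "mlp", levels = levels(y),
           model = nnet::nnet(x = X, y = nnet::class.ind(y),
                              size = spec$hidden, decay = spec$decay,
                              maxit = spec$max_iter, softmax = TRUE,
                              trace = FALSE, MaxNWts = 5000))
    }),
    gbt_shallow = ,
    gbt_depth5 = ,
    gbt_deep = .fit_gbt(spec, X, y, seed),
    voting = .fit_voting(spec, X, y, seed),
    abort(paste0("Unknown base learner: ", name))
  )
}

.fit_gbt <- function(spec, X, y, seed) {
  params <- list(
    objective = "multi:softprob",
    num_class = length(levels(y)),
    max_depth = spec$max_depth,
    eta = spec$eta,
    subsample = spec$subsample %||% 1,
    colsample_bytree = spec$colsample_bytree %||% 1,
    nthread = 1,
    seed = seed
  )
  dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L, nthread = 1)
  model <- with_seed(seed, {
    xgboost::xgb.train(params = params, data = dtrain,
                       nrounds = spec$nrounds, verbose = 0)
  })
  list(kind = "gbt", model = model, levels = levels(y))
}

.fit_voting <- function(spec, X, y, seed) {
  specs <- base_learner_specs()
  seeds <- fan_out_seeds(seed, length(spec$members))
  members <- purrr::map2(spec$members, seeds, function(m, s) {
    .fit_base(m, specs[[m]], X, y, s)
  })
  names(members) <- spec$members
  list(kind = "voting", members = members, levels = levels(y))
}

.predict_base <- function(fit, X) {
  lev <- c("1", "2", "3")
  prob <- switch(fit$kind,
    svm = {
      p <- attr(predict(fit$model, X, probability = TRUE), "probabilities")
      p[, order(colnames(p)), drop = FALSE]
    },
    knn = {
      p <- .knn_prob(fit$X, fit$y, X, fit$k)
      colnames(p) <- levels(fit$y)
      p
    },
    ranger = predict(fit$model, data = X, num.threads = 1)$predictions,
    mlp = {
      p <- predict(fit$model, X)
      colnames(p) <- fit$levels
      p
    },
    gbt = {
      p <- predict(fit$model, xgboost::xgb.DMatrix(X, nthread = 1))
      if (is.null(dim(p))) {
        p <- matrix(p, ncol = length(fit$levels), byrow = TRUE)
      }
      colnames(p) <- fit$levels
      p
    },
    voting = {
      votes <- vapply(fit$members, function(m) {
        max.col(.predict_base(m, X), ties.method = "first")
      }, integer(nrow(X)))
      votes <- matrix(votes, nrow = nrow(X))
      p <- t(apply(votes, 1, function(v) {
        tabulate(v, nbins = length(lev)) / length(v)
      }))
      colnames(p) <- lev
      p
    },
    abort("Unknown fitted base learner kind.")
  )
  prob <- as.matrix(prob)
  # Expand to the full class set so fits seen on a class subset still line up.
  fit_lev <- colnames(prob)
  if (is.null(fit_lev)) fit_lev <- lev[seq_len(ncol(prob))]
  full <- matrix(0, nrow = nrow(prob), ncol = length(lev),
                 dimnames = list(NULL, lev))
  full[, fit_lev] <- prob
  full
}

# k-NN class proportions among the k nearest training points (squared
# Euclidean metric; class::knn reports only the winning class, but the stack
# needs the full per-class vote shares).
.knn_prob <- function(train_X, train_y, test_X, k) {
  k <- min(k, nrow(train_X))
  d2 <- outer(rowSums(test_X^2), rep(1, nrow(train_X))) +
    outer(rep(1, nrow(test_X)), rowSums(train_X^2)) -
    2 * test_X %*% t(train_X)
  lev <- levels(train_y)
  t(apply(d2, 1, function(row) {
    nn <- order(row)[seq_len(k)]
    tabulate(as.integer(train_y[nn]), nbins = length(lev)) / k
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stratified fold assignment: within each class, indices are shuffled and
# dealt round-robin across folds.
.stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in levels(y)) {
      ix <- which(y == cls)
      ix <- sample(ix)
      folds[ix] <- rep_len(seq_len(k), length(ix))
    }
  })
  folds
}

.meta_feature_frame <- function(prob_list) {
  cols <- purrr::imap(prob_list, function(p, nm) {
    out <- as.data.frame(p)
    names(out) <- paste0(nm, "_p", seq_len(ncol(p)))
    out
  })
  dplyr::bind_cols(cols)
}

#' Train the stacking classifier
#'
#' Each base learner is fitted on `cv_folds` training folds and predicts the
#' held-out fold, producing out-of-fold class probabilities for every
#' training row; the meta-model (multinomial logistic regression, default
#' settings) is fitted on those probabilities, and the base learners are then
#' refitted on the full training data for prediction time. One master seed is
#' fanned out deterministically into per-learner and per-stage seeds, so the
#' whole fit is reproducible.
#'
#' @param data Training dataset table containing the feature columns and a
#'   `Maturation` column with all three classes present.
#' @param stack An untrained stack from [build_stack()], or a
#'   [stack_config()].
#' @param seed Master integer seed.
#' @return A fitted `cvd_stack`.
#' @export
#' @examples
#' cohort <- simulate_cohort(seed = 7)
#' parts <- split_dataset(cohort, seed = 7)
#' fit <- train_stack(parts$train, build_stack(stack_config("knn")), seed = 7)
#' predict(fit, parts$test)[1:5]
train_stack <- function(data, stack = build_stack(), seed = 1) {
  if (inherits(stack, "cvd_stack_config")) {
    stack <- build_stack(stack)
  }
  if (!inherits(stack, "cvd_stack")) {
    abort("`stack` must be a cvd_stack or cvd_stack_config object.")
  }
  cfg <- stack$config
  missing <- setdiff(c(cfg$features, "Maturation"), names(data))
  if (length(missing) > 0) {
    abort(paste0("Training data is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  X <- as.matrix(data[cfg$features])
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) {
    abort("Feature values must be finite.")
  }
  y <- factor(data$Maturation, levels = 1:3)
  if (anyNA(y) || nlevels(droplevels(y)) < 3) {
    abort("Insufficient data: training data must contain classes 1, 2 and 3.")
  }

  n_learners <- length(cfg$base_learners)
  seeds <- fan_out_seeds(seed, n_learners + 2L)
  fold_seed <- seeds[n_learners + 1L]
  meta_seed <- seeds[n_learners + 2L]
  folds <- .stratified_folds(y, cfg$cv_folds, fold_seed)

  oof <- vector("list", n_learners)
  names(oof) <- cfg$base_learners
  for (b in seq_len(n_learners)) {
    name <- cfg$base_learners[b]
    spec <- cfg$specs[[name]]
    fold_seeds <- fan_out_seeds(seeds[b], cfg$cv_folds)
    p <- matrix(NA_real_, nrow = nrow(X), ncol = 3)
    for (f in seq_len(cfg$cv_folds)) {
      in_f <- folds != f
      fit_f <- .fit_base(name, spec, X[in_f, , drop = FALSE],
                         droplevels(y[in_f]), fold_seeds[f])
      p[!in_f, ] <- .predict_base(fit_f, X[!in_f, , drop = FALSE])
    }
    oof[[name]] <- p
  }

  meta_df <- .meta_feature_frame(oof)
  meta_df$.y <- y
  meta <- with_seed(meta_seed, {
    nnet::multinom(.y ~ ., data = meta_df, trace = FALSE, maxit = 500)
  })

  base_fits <- purrr::map2(cfg$base_learners, seeds[seq_len(n_learners)],
                           function(name, s) {
                             .fit_base(name, cfg$specs[[name]], X, y, s)
                           })
  names(base_fits) <- cfg$base_learners

  structure(
    list(config = cfg, fitted = TRUE, base_fits = base_fits, meta = meta,
         classes = levels(y), seed = seed, n_train = nrow(X)),
    class = "cvd_stack"
  )
}

#' Predict maturation classes or probabilities from a fitted stack
#'
#' @param object A fitted `cvd_stack`.
#' @param newdata Data frame carrying the model's feature columns; any other
#'   columns (including `age` and `gender`) are ignored.
#' @param type `"class"` for integer labels in 1..3, `"prob"` for the
#'   row-normalised class probability matrix.
#' @param ... Unused.
#' @return Integer vector or numeric matrix with one row per input row.
#' @export
predict.cvd_stack <- function(object, newdata,
                              type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (!isTRUE(object$fitted)) {
    abort("The stack has not been trained; call train_stack() first.")
  }
  missing <- setdiff(object$config$features, names(newdata))
  if (length(missing) > 0) {
    abort(paste0("`newdata` is missing feature column(s): ",
                 paste(missing, collapse = ", ")))
  }
  X <- as.matrix(newdata[object$config$features])
  storage.mode(X) <- "double"
  prob_list <- purrr::map(object$base_fits, function(f) .predict_base(f, X))
  meta_df <- .meta_feature_frame(prob_list)
  p <- predict(object$meta, newdata = meta_df, type = "probs")
  if (is.null(dim(p))) {
    p <- matrix(p, nrow = nrow(meta_df),
                ncol = length(object$classes), byrow = nrow(meta_df) > 1)
  }
  p <- as.matrix(p)
  colnames(p) <- object$classes
  p <- p / rowSums(p)
  if (type == "prob") {
    return(p)
  }
  as.integer(object$classes[max.col(p, ties.method = "first")])
}

#' @export
print.cvd_stack <- function(x, ...) {
  state <- if (isTRUE(x$fitted)) sprintf("fitted on %d rows", x$n_train)
           else "untrained"
  cat(sprintf(
    "<cvd_stack> %s\n  base learners: %s\n  meta: multinomial logistic (%d-fold CV features)\n",
    state, paste(x$config$base_learners, collapse = ", "), x$config$cv_folds))
  invisible(x)
}

#' @export
tidy.cvd_stack <- function(x, ...) {
  if (!isTRUE(x$fitted)) {
    abort("Cannot tidy an untrained stack.")
  }
  coefs <- stats::coef(x$meta)
  if (is.null(dim(coefs))) {
    coefs <- matrix(coefs, nrow = 1,
                    dimnames = list(x$classes[2], names(coefs)))
  }
  tibble::as_tibble(as.data.frame.table(coefs, stringsAsFactors = FALSE)) |>
    setNames(c("class", "term", "estimate"))
}

#' @export
glance.cvd_stack <- function(x, ...) {
  tibble::tibble(
    fitted = isTRUE(x$fitted),
    n_train = if (isTRUE(x$fitted)) x$n_train else NA_integer_,
    n_base_learners = length(x$config$base_learners),
    cv_folds = x$config$cv_folds,
    features = paste(x$config$features, collapse = ","),
    seed = if (isTRUE(x$fitted)) x$seed else NA_integer_
  )
}

#' Permutation feature importance
#'
#' Importance of each model feature measured as the mean drop in accuracy on
#' `data` when that feature column is randomly shuffled, averaged over
#' `n_repeats` shuffles. A feature the model never uses (or that carries no
#' information) scores ~0.
#'
#' @param object Fitted `cvd_stack`.
#' @param data Evaluation dataset table with features and `Maturation`.
#' @param seed Integer seed for the shuffles.
#' @param n_repeats Number of shuffles per feature (>= 1; 10 by default).
#' @return A `cvd_importance` tibble with columns `feature`, `importance`
#'   (mean accuracy drop) and `sd`, sorted by decreasing importance.
#' @export
feature_importance <- function(object, data, seed = 1, n_repeats = 10) {
  if (!isTRUE(object$fitted)) {
    abort("The stack has not been trained; call train_stack() first.")
  }
  if (nrow(data) == 0) {
    abort("`data` must be non-empty.")
  }
  truth <- as.integer(data$Maturation)
  base_acc <- mean(predict(object, data) == truth)
  feats <- object$config$features
  seeds <- fan_out_seeds(seed, length(feats))
  rows <- purrr::map2(feats, seeds, function(f, s) {
    drops <- with_seed(s, {
      vapply(seq_len(n_repeats), function(r) {
        shuffled <- data
        shuffled[[f]] <- sample(shuffled[[f]])
        base_acc - mean(predict(object, shuffled) == truth)
      }, numeric(1))
    })
    tibble::tibble(feature = f, importance = mean(drops),
                   sd = stats::sd(drops))
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$importance))
  class(out) <- c("cvd_importance", class(out))
  out
}
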
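#' Stratified train/test split
#'
#' Splits a cohort into a training set of round(2n/3) patients and a test set
#' of the remainder, stratified by the dichotomized outcome so the unfavorable
#' fraction is preserved within one patient.
#'
#' @param cohort Cohort data.frame with an `unfavorable` column.
#' @param seed Integer seed.
#' @return List with `train` and `test` data.frames (disjoint, exhaustive).
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 351, seed = 2))
#' sp <- split_train_test(coh, seed = 9)
#' nrow(sp$train); nrow(sp$test) # 234, 117
#' @export
split_train_test <- function(cohort, seed = 1L) {
  n <- nrow(cohort)
  if (n < 3L) stop("cohort must have at least 3 patients", call. = FALSE)
  n_train <- round(2 * n / 3)
  y <- as.logical(cohort$unfavorable)
  with_seed(seed, {
    idx1 <- which(y); idx0 <- which(!y)
    k1 <- round(length(idx1) * n_train / n)
    k1 <- min(max(k1, n_train - length(idx0)), length(idx1), n_train)
    k0 <- n_train - k1
    tr <- c(sample(idx1, k1), sample(idx0, k0))
    list(train = cohort[sort(tr), , drop = FALSE],
         test = cohort[sort(setdiff(seq_len(n), tr)), , drop = FALSE])
  })
}

#' Desirability of a candidate feature subset
#'
#' Composite objective for feature selection: the geometric mean of a
#' discrimination desirability, `d_auc = max(0, (auc - 0.5) / 0.5)`, and a
#' parsimony desirability, `d_size = exp(-lambda * n_features)`. It rewards
#' discrimination above chance and penalizes model complexity, bounding the
#' objective in `[0, 1]`.
#'
#' @param auc Cross-validated AUC of the candidate model.
#' @param n_features Number of selected features.
#' @param lambda_complexity Per-feature complexity penalty (>= 0).
#' @return Desirability in `[0, 1]`.
#' @examples
#' desirability(0.75, 5, 0.1) # sqrt(0.5 * exp(-0.5)) = 0.5507
#' @export
desirability <- function(auc, n_features, lambda_complexity = 0.1) {
  if (!is.finite(auc) || auc < 0 || auc > 1) stop("auc must be in [0, 1]",
                                                  call. = FALSE)
  d_auc <- max(0, (auc - 0.5) / 0.5)
  d_size <- exp(-lambda_complexity * n_features)
  sqrt(d_auc * d_size)
}

#' Genetic-algorithm configuration
#'
#' @param population_size,generations GA scale.
#' @param crossover_rate Probability a selected pair undergoes uniform
#'   crossover.
#' @param mutation_rate Per-bit flip probability; `NULL` = 1/L.
#' @param tournament_size Tournament selection size.
#' @param elitism Number of top chromosomes copied unchanged each generation.
#' @param lambda_complexity Complexity penalty passed to [desirability()].
#' @param cv_folds Stratified cross-validation folds for the fitness AUC.
#' @param seed Integer seed.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 50L, generations = 40L,
                      crossover_rate = 0.8, mutation_rate = NULL,
                      tournament_size = 3L, elitism = 2L,
                      lambda_complexity = 0.1, cv_folds = 5L, seed = 1L) {
  cfg <- list(population_size = as.integer(population_size),
              generations = as.integer(generations),
              crossover_rate = crossover_rate, mutation_rate = mutation_rate,
              tournament_size = as.integer(tournament_size),
              elitism = as.integer(elitism),
              lambda_complexity = lambda_complexity,
              cv_folds = as.integer(cv_folds), seed = as.integer(seed))
  stopifnot(cfg$population_size >= 2L, cfg$generations >= 1L,
            cfg$crossover_rate >= 0, cfg$crossover_rate <= 1,
            is.null(cfg$mutation_rate) ||
              (cfg$mutation_rate >= 0 && cfg$mutation_rate <= 1),
            cfg$elitism >= 0L, cfg$elitism < cfg$population_size,
            cfg$lambda_complexity >= 0, cfg$cv_folds >= 2L)
  class(cfg) <- "ga_config"
  cfg
}

# Stratified fold assignment (balanced outcome per fold).
make_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Fast logistic fit on a model matrix via glm.fit (no formula machinery).
logit_fit_probs <- function(X_train, y_train, X_test) {
  fit <- suppressWarnings(
    glm.fit(cbind(1, X_train), y_train, family = binomial())
  )
  eta <- cbind(1, X_test) %*% ifelse(is.na(fit$coefficients), 0,
                                     fit$coefficients)
  plogis(as.numeric(eta))
}

# Pooled cross-validated AUC of a logistic model on the given feature columns.
cv_logistic_auc <- function(X, y, fold) {
  if (ncol(X) == 0L) return(0.5)
  pred <- numeric(length(y))
  for (f in unique(fold)) {
    te <- fold == f
    pred[te] <- logit_fit_probs(X[!te, , drop = FALSE], y[!te],
                                X[te, , drop = FALSE])
  }
  auc_roc(pred, y)
}

#' Genetic-algorithm feature selection
#'
#' Searches binary feature-inclusion vectors over the candidate TAI features
#' with a generational GA: tournament selection, uniform crossover, per-bit
#' mutation, and elitism. The fitness of a chromosome is the [desirability()]
#' of its cross-validated logistic-regression AUC on the training data and its
#' feature count. The population is seeded with the empty and all-features
#' chromosomes, so the returned best-ever chromosome never scores below
#' either. Deterministic given the config seed.
#'
#' @param train Training cohort data.frame (`unfavorable` plus feature
#'   columns); both outcome classes must be present.
#' @param candidate_features Character vector of candidate feature columns.
#' @param config A [ga_config()].
#' @return A `ga_result`: list with `selected_features`, `bits`, `fitness`,
#'   `cv_auc`, and `history` (best fitness per generation, non-decreasing).
#' @export
ga_select <- function(train, candidate_features, config = ga_config()) {
  y <- as.integer(train$unfavorable)
  if (length(unique(y)) < 2L) {
    stop("training outcome has a single class", call. = FALSE)
  }
  missing_cols <- setdiff(candidate_features, names(train))
  if (length(missing_cols) > 0L) {
    stop("candidate feature(s) not in training data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  L <- length(candidate_features)
  X_all <- as.matrix(train[, candidate_features, drop = FALSE])
  storage.mode(X_all) <- "double"
  mut <- config$mutation_rate %||% (1 / L)
  pop_n <- config$population_size

  with_seed(config$seed, {
    fold <- make_folds(y, config$cv_folds)
    cache <- new.env(parent = emptyenv())
    evaluate <- function(bits) {
      key <- paste(bits, collapse = "")
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      a <- cv_logistic_auc(X_all[, bits == 1L, drop = FALSE], y, fold)
      val <- list(fitness = desirability(a, sum(bits),
                                         config$lambda_complexity),
                  cv_auc = a)
      cache[[key]] <- val
      val
    }

    pop <- lapply(seq_len(pop_n), function(i) {
      if (i == 1L) rep(0L, L)
      else if (i == 2L) rep(1L, L)
      else rbinom(L, 1L, 0.5)
    })
    fit <- vapply(pop, function(b) evaluate(b)$fitness, numeric(1))
    best_bits <- pop[[which.max(fit)]]
    best_fit <- max(fit)
    history <- numeric(config$generations)

    for (gen in seq_len(config$generations)) {
      ord <- order(fit, decreasing = TRUE)
      nxt <- pop[ord[seq_len(config$elitism)]]
      while (length(nxt) < pop_n) {
        pick <- function() {
          cand <- sample.int(pop_n, config$tournament_size, replace = TRUE)
          pop[[cand[which.max(fit[cand])]]]
        }
        p1 <- pick(); p2 <- pick()
        if (runif(1) < config$crossover_rate) {
          mask <- rbinom(L, 1L, 0.5) == 1L
          c1 <- ifelse(mask, p1, p2)
          c2 <- ifelse(mask, p2, p1)
        } else {
          c1 <- p1; c2 <- p2
        }
        for (child in list(c1, c2)) {
          flip <- runif(L) < mut
          child[flip] <- 1L - child[flip]
          if (length(nxt) < pop_n) nxt[[length(nxt) + 1L]] <- as.integer(child)
        }
      }
      pop <- nxt
      fit <- vapply(pop, function(b) evaluate(b)$fitness, numeric(1))
      if (max(fit) > best_fit) {
        best_fit <- max(fit)
        best_bits <- pop[[which.max(fit)]]
      }
      history[gen] <- best_fit
    }
    best_eval <- evaluate(best_bits)
    structure(list(selected_features = candidate_features[best_bits == 1L],
                   bits = best_bits, fitness = best_fit,
                   cv_auc = best_eval$cv_auc, history = history,
                   candidate_features = candidate_features),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<GA feature selection> %d/%d features, fitness %.4f (CV-AUC %.3f)\n",
              length(x$selected_features), length(x$candidate_features),
              x$fitness, x$cv_auc))
  if (length(x$selected_features)) {
    cat("selected:", paste(x$selected_features, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Exhaustive feature-subset search
#'
#' Brute-force evaluation of every feature subset under the same
#' cross-validated desirability objective as [ga_select()]. Feasible for small
#' candidate dictionaries (about 12 features or fewer); used to benchmark the
#' GA.
#'
#' @inheritParams ga_select
#' @return List with `selected_features`, `fitness`, and `all_fitness` (one
#'   value per subset, in binary-counter order).
#' @export
exhaustive_select <- function(train, candidate_features, config = ga_config()) {
  L <- length(candidate_features)
  if (L > 20L) stop("exhaustive search limited to 20 features", call. = FALSE)
  y <- as.integer(train$unfavorable)
  X_all <- as.matrix(train[, candidate_features, drop = FALSE])
  storage.mode(X_all) <- "double"
  with_seed(config$seed, {
    fold <- make_folds(y, config$cv_folds)
    fits <- numeric(2^L)
    best <- -Inf; best_bits <- rep(0L, L)
    for (s in 0:(2^L - 1)) {
      bits <- as.integer(intToBits(s)[seq_len(L)])
      a <- cv_logistic_auc(X_all[, bits == 1L, drop = FALSE], y, fold)
      f <- desirability(a, sum(bits), config$lambda_complexity)
      fits[s + 1L] <- f
      if (f > best) { best <- f; best_bits <- bits }
    }
    list(selected_features = candidate_features[best_bits == 1L],
         fitness = best, all_fitness = fits)
  })
}

#' Random-forest internal validation of selected TAI features
#'
#' Trains two random forests on the training partition — one on the core
#' clinical predictors (age, GCS, pupillary response) plus the selected TAI
#' features, one on the core predictors only — and evaluates both on the held
#' out test partition by AUC. Gini importances (mean decrease in node
#' impurity) are reported for the core + TAI forest.
#'
#' @param train,test Cohort partitions from [split_train_test()].
#' @param selected_features TAI feature columns chosen by [ga_select()].
#' @param core_variables Core predictor columns.
#' @param seed Integer seed (controls both forests).
#' @param ntree Trees per forest.
#' @return A `derivation_report`: list with `selected_features`,
#'   `test_auc_with_tai`, `test_auc_core_only`, and `gini_importances`
#'   (named, non-negative).
#' @export
rf_validate <- function(train, test, selected_features,
                        core_variables = c("age", "gcs", "pupils"),
                        seed = 1L, ntree = 500L) {
  need <- c(core_variables, selected_features, "unfavorable")
  for (d in list(train = train, test = test)) {
    miss <- setdiff(need, names(d))
    if (length(miss) > 0L) {
      stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  prep <- function(d, vars) {
    X <- d[, vars, drop = FALSE]
    for (v in vars) if (is.character(X[[v]])) X[[v]] <- factor(X[[v]])
    X
  }
  y_train <- factor(as.integer(train$unfavorable), levels = c(0, 1))
  y_test <- as.integer(test$unfavorable)
  run_forest <- function(vars, sub_seed) {
    X_tr <- prep(train, vars); X_te <- prep(test, vars)
    for (v in vars) {
      if (is.factor(X_tr[[v]])) {
        X_te[[v]] <- factor(X_te[[v]], levels = levels(X_tr[[v]]))
      }
    }
    with_seed(sub_seed, {
      rf <- randomForest::randomForest(x = X_tr, y = y_train, ntree = ntree,
                                       importance = FALSE)
      list(rf = rf,
           auc = auc_roc(predict(rf, X_te, type = "prob")[, "1"], y_test))
    })
  }
  full <- run_forest(c(core_variables, selected_features),
                     derive_seed(seed, "rf_full"))
  core <- run_forest(core_variables, derive_seed(seed, "rf_core"))
  imp <- randomForest::importance(full$rf, type = 2)[, 1]
  structure(list(selected_features = selected_features,
                 core_variables = core_variables,
                 test_auc_with_tai = full$auc,
                 test_auc_core_only = core$auc,
                 gini_importances = imp),
            class = "derivation_report")
}

#' @export
print.derivation_report <- function(x, ...) {
  cat(sprintf("<random-forest validation> test AUC core+TAI %.3f vs core-only %.3f\n",
              x$test_auc_with_tai, x$test_auc_core_only))
  top <- sort(x$gini_importances, decreasing = TRUE)
  cat("top importances:\n")
  print(round(head(top, 8), 2))
  invisible(x)
}
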
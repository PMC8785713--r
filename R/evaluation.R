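#' Fit a logistic outcome model
#'
#' Maximum-likelihood logistic regression of the dichotomized Glasgow Outcome
#' Scale (unfavorable = GOS 1-3) on a set of predictors. Grading-system
#' predictors enter as ordinal integer scores, pupillary response as a 3-level
#' categorical, age and GCS as continuous — matching how the grading systems
#' are compared in prognostic modelling.
#'
#' @param cohort Cohort data.frame containing an `unfavorable` logical column
#'   and the predictors.
#' @param predictors Character vector of column names; `character(0)` fits the
#'   intercept-only model.
#' @param outcome Name of the logical/0-1 outcome column.
#' @return A `tai_logit` object: list with `predictors`, `coefficients`,
#'   `log_likelihood`, `aic`, `n`, `n_params`, `fitted_probs`, `separation`
#'   flag, and the underlying `glm` fit.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 300, seed = 5))
#' m <- fit_logistic(grade_cohort(coh), c("age", "gcs", "grade_stockholm"))
#' m$aic
#' @export
fit_logistic <- function(cohort, predictors = character(),
                         outcome = "unfavorable") {
  y <- cohort[[outcome]]
  if (is.null(y)) stop("outcome column '", outcome, "' not found", call. = FALSE)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  missing_cols <- setdiff(predictors, names(cohort))
  if (length(missing_cols) > 0L) {
    stop("predictor column(s) not found: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dat <- cohort[, predictors, drop = FALSE]
  for (v in predictors) if (is.character(dat[[v]])) dat[[v]] <- factor(dat[[v]])
  dat$.y <- y
  form <- if (length(predictors) == 0L) .y ~ 1 else
    as.formula(paste(".y ~", paste(sprintf("`%s`", predictors), collapse = " + ")))
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = dat),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg)) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      } else if (grepl("did not converge", msg)) {
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separated) {
    warning("possible complete separation; coefficients may be unstable",
            call. = FALSE)
  }
  ll <- as.numeric(logLik(fit))
  k <- length(coef(fit))
  structure(list(predictors = predictors, coefficients = coef(fit),
                 log_likelihood = ll, aic = 2 * k - 2 * ll, n = length(y),
                 n_params = k, fitted_probs = as.numeric(fit$fitted.values),
                 separation = separated, outcome = y, glm = fit),
            class = "tai_logit")
}

#' @export
print.tai_logit <- function(x, ...) {
  cat(sprintf("<logistic outcome model> n=%d, k=%d, logLik=%.2f, AIC=%.1f\n",
              x$n, x$n_params, x$log_likelihood, x$aic))
  cat("predictors:", if (length(x$predictors)) paste(x$predictors, collapse = ", ")
      else "(intercept only)", "\n")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Mann-Whitney estimator of the AUC with half-credit for ties, identical to
#' the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric risk scores (higher = more likely case).
#' @param labels Logical or 0/1 case indicators.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_roc(c(1, 2, 2, 3), c(0, 0, 1, 1)) # 0.875
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("missing values not allowed",
                                           call. = FALSE)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Nagelkerke pseudo-R-squared
#'
#' Rescaled Cox-Snell R2 for a likelihood-based binary-outcome model:
#' `CS = 1 - exp(2 (ll0 - ll1) / n)`, `R2 = CS / (1 - exp(2 ll0 / n))`.
#'
#' @param model A `tai_logit` (or a list with `log_likelihood` and `n`).
#' @param null_loglik Log-likelihood of the intercept-only model on the same
#'   patients.
#' @return Pseudo-R2 in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(model, null_loglik) {
  ll1 <- model$log_likelihood
  n <- model$n
  if (ll1 < null_loglik - 1e-8) {
    stop("model log-likelihood below null log-likelihood: not a nested MLE",
         call. = FALSE)
  }
  cs <- 1 - exp(2 * (null_loglik - ll1) / n)
  cs / (1 - exp(2 * null_loglik / n))
}

# DeLong placements: for each case, the fraction of controls it beats (ties
# half-credit), and symmetrically for controls.
delong_placements <- function(scores, labels) {
  x <- scores[labels]   # cases
  y <- scores[!labels]  # controls
  m <- length(x); n <- length(y)
  all_r <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (all_r[seq_len(m)] - rx) / n          # per-case placements
  v01 <- 1 - (all_r[m + seq_len(n)] - ry) / m  # per-control placements
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two risk scores evaluated on the same patients, using
#' the DeLong midrank-placement covariance estimator and a two-sided normal
#' reference.
#'
#' @param scores_a,scores_b Paired numeric score vectors.
#' @param labels Logical or 0/1 case indicators (shared by both scores).
#' @return List with `z`, `p`, `auc_a`, `auc_b`, and `var_diff`.
#' @examples
#' set.seed(1)
#' y <- rep(c(TRUE, FALSE), each = 30)
#' a <- rnorm(60, y); b <- rnorm(60, 0.5 * y)
#' delong_test(a, b, y)$p
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels)) {
    stop("scores and labels must be paired on the same patients", call. = FALSE)
  }
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- sum(labels); n <- sum(!labels)
  s10 <- var(cbind(pa$v10, pb$v10))  # 2x2 covariance of case placements
  s01 <- var(cbind(pa$v01, pb$v01))
  s <- s10 / m + s01 / n
  var_diff <- s[1, 1] + s[2, 2] - 2 * s[1, 2]
  d <- pa$auc - pb$auc
  if (var_diff <= 1e-14) {
    if (abs(d) > 1e-12) {
      warning("degenerate DeLong variance with unequal AUCs", call. = FALSE)
    } else {
      warning("identical ROC curves; DeLong variance degenerate", call. = FALSE)
    }
    return(list(z = 0, p = 1, auc_a = pa$auc, auc_b = pb$auc,
                var_diff = var_diff))
  }
  z <- d / sqrt(var_diff)
  list(z = z, p = 2 * pnorm(-abs(z)), auc_a = pa$auc, auc_b = pb$auc,
       var_diff = var_diff)
}

#' Likelihood-ratio test for nested logistic models
#'
#' @param nested,full `tai_logit` fits on the same patients, with the nested
#'   model's predictors a subset of the full model's.
#' @return List with `stat`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(nested, full) {
  if (!all(nested$predictors %in% full$predictors)) {
    stop("models are not nested (predictor sets)", call. = FALSE)
  }
  if (nested$n != full$n) stop("models fit on different patient sets",
                               call. = FALSE)
  stat <- max(0, 2 * (full$log_likelihood - nested$log_likelihood))
  df <- full$n_params - nested$n_params
  p <- if (df == 0L) 1 else pchisq(stat, df, lower.tail = FALSE)
  list(stat = stat, df = df, p = p)
}

#' Per-site lesion severity table
#'
#' For each sequence family and lesion type (the published row set: laterality
#' rows for most regions, named subregions for the corpus callosum, midbrain
#' and pons), the number of patients carrying that lesion and the percentage of
#' them with unfavorable outcome, plus a "no detected TAI" row per sequence.
#' Zero-count cells render their percentage as `NA`.
#'
#' @param cohort Cohort data.frame with lesion columns and `unfavorable`.
#' @return Data.frame with columns `sequence`, `region`, `lesion_type`, `n`,
#'   `pct_unfavorable`.
#' @export
severity_table <- function(cohort) {
  sites <- lesion_site_table()
  rows <- list(
    c("basal_ganglia", "unilateral"), c("basal_ganglia", "bilateral"),
    c("corpus_callosum", "trunk"), c("corpus_callosum", "splenium"),
    c("corpus_callosum", "genu_rostrum"),
    c("internal_capsule_plic", "unilateral"),
    c("internal_capsule_plic", "bilateral"),
    c("midbrain", "unilateral"), c("midbrain", "tegmentum"),
    c("midbrain", "tectum"), c("midbrain", "cerebral_peduncles"),
    c("midbrain", "bilateral"),
    c("pons", "ventral"), c("pons", "unilateral"), c("pons", "dorsal"),
    c("pons", "bilateral"),
    c("subcortical", "unilateral"), c("subcortical", "bilateral"),
    c("thalamus", "unilateral"), c("thalamus", "bilateral")
  )
  row_cols <- function(region, type, sq) {
    if (type %in% c("unilateral", "bilateral")) {
      # laterality rows count sites without a named subregion
      site_cols(sites, region = region, laterality = type,
                subregion = "unspecified", sequence = sq)
    } else {
      site_cols(sites, region = region, subregion = type, sequence = sq)
    }
  }
  out <- list()
  for (sq in c("dwi", "flair", "susceptibility")) {
    for (r in rows) {
      cols <- row_cols(r[1], r[2], sq)
      hit <- any_site(cohort, cols)
      n <- sum(hit)
      out[[length(out) + 1L]] <- data.frame(
        sequence = sq, region = r[1], lesion_type = r[2], n = n,
        pct_unfavorable = if (n > 0) 100 * mean(cohort$unfavorable[hit]) else NA_real_,
        stringsAsFactors = FALSE)
    }
    none <- !any_site(cohort, site_cols(sites, sequence = sq))
    out[[length(out) + 1L]] <- data.frame(
      sequence = sq, region = "none", lesion_type = "no_detected_tai",
      n = sum(none),
      pct_unfavorable = if (sum(none) > 0) 100 * mean(cohort$unfavorable[none])
                        else NA_real_,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cochran-Armitage trend test
#'
#' Tests for a linear trend in a binomial proportion across ordered categories.
#'
#' @param events Integer vector of event counts per category.
#' @param totals Integer vector of category sizes.
#' @param scores Numeric category scores (default `seq_along(events)`).
#' @return List with `z` (signed trend statistic) and two-sided `p`.
#' @examples
#' cochran_armitage_trend(c(2, 5, 9), c(10, 10, 10))
#' @export
cochran_armitage_trend <- function(events, totals,
                                   scores = seq_along(events)) {
  if (length(events) < 2L || length(events) != length(totals) ||
      length(scores) != length(events)) {
    stop("need k >= 2 categories with matching events/totals/scores",
         call. = FALSE)
  }
  if (any(events < 0) || any(totals <= 0) || any(events > totals)) {
    stop("invalid 2 x k table", call. = FALSE)
  }
  N <- sum(totals)
  pbar <- sum(events) / N
  if (pbar <= 0 || pbar >= 1) {
    stop("zero-margin table: all or no events", call. = FALSE)
  }
  num <- sum(scores * (events - totals * pbar))
  den <- pbar * (1 - pbar) * (sum(totals * scores^2) -
                                sum(totals * scores)^2 / N)
  z <- num / sqrt(den)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Compare the four TAI grading systems in a model battery
#'
#' Fits the fifteen logistic outcome models of the grading-system comparison:
#' each grading system alone, the core clinical predictors (age, GCS,
#' pupillary response), the Rotterdam CT score, core + each system, core +
#' Rotterdam, and core + Rotterdam + each system. Reports Nagelkerke pseudo-R2,
#' AIC, and AUC for every model; the likelihood-ratio test of each system's
#' addition to core + Rotterdam; and pairwise DeLong tests among the four
#' single-system models.
#'
#' Grades enter as a single ordinal integer per system (set
#' `grade_coding = "factor"` for dummy coding).
#'
#' @param cohort Cohort data.frame already graded by all four systems (see
#'   [grade_cohort()]).
#' @param grade_coding `"ordinal"` (default) or `"factor"`.
#' @return A `grading_comparison`: list with `models` (15-row data.frame),
#'   `lrt` (one row per system), and `delong` (one row per system pair).
#' @examples
#' coh <- grade_cohort(generate_cohort(cohort_config(n_patients = 400, seed = 8)))
#' cmp <- compare_grading_systems(coh)
#' cmp$models[, c("model", "pseudo_r2", "aic", "auc")]
#' @export
compare_grading_systems <- function(cohort, grade_coding = c("ordinal", "factor")) {
  grade_coding <- match.arg(grade_coding)
  systems <- c("adams", "firsching", "abu_hamdeh", "stockholm")
  gcols <- paste0("grade_", systems)
  if (!all(gcols %in% names(cohort))) {
    stop("cohort must be graded by all four systems first (grade_cohort)",
         call. = FALSE)
  }
  if (grade_coding == "factor") {
    for (g in gcols) cohort[[g]] <- factor(cohort[[g]])
  }
  core <- c("age", "gcs", "pupils")
  specs <- c(
    setNames(as.list(gcols), systems),
    list(core = core, rotterdam = "rotterdam"),
    setNames(lapply(gcols, function(g) c(core, g)), paste0("core+", systems)),
    list(`core+rotterdam` = c(core, "rotterdam")),
    setNames(lapply(gcols, function(g) c(core, "rotterdam", g)),
             paste0("core+rotterdam+", systems))
  )
  null_fit <- fit_logistic(cohort, character())
  fits <- lapply(specs, function(p) fit_logistic(cohort, p))
  models <- data.frame(
    model = names(specs),
    pseudo_r2 = vapply(fits, nagelkerke_r2, numeric(1),
                       null_loglik = null_fit$log_likelihood),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    auc = vapply(fits, function(f) auc_roc(f$fitted_probs, f$outcome),
                 numeric(1)),
    stringsAsFactors = FALSE)
  rownames(models) <- NULL

  base_fit <- fits[["core+rotterdam"]]
  lrt <- do.call(rbind, lapply(systems, function(s) {
    t <- likelihood_ratio_test(base_fit, fits[[paste0("core+rotterdam+", s)]])
    data.frame(system = s, stat = t$stat, df = t$df, p = t$p,
               stringsAsFactors = FALSE)
  }))

  pairs <- combn(systems, 2)
  delong <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    d <- delong_test(fits[[a]]$fitted_probs, fits[[b]]$fitted_probs,
                     fits[[a]]$outcome)
    data.frame(system_a = a, system_b = b, auc_a = d$auc_a, auc_b = d$auc_b,
               z = d$z, p = d$p, stringsAsFactors = FALSE)
  }))
  structure(list(models = models, lrt = lrt, delong = delong,
                 grade_coding = grade_coding),
            class = "grading_comparison")
}

#' @export
print.grading_comparison <- function(x, digits = 3, ...) {
  cat("<grading-system comparison> 15 logistic outcome models\n\n")
  m <- x$models
  m$pseudo_r2 <- round(m$pseudo_r2, digits)
  m$aic <- round(m$aic, 1)
  m$auc <- round(m$auc, digits)
  print(m, row.names = FALSE)
  cat("\nLikelihood-ratio test of each system added to core + Rotterdam:\n")
  l <- x$lrt; l$stat <- round(l$stat, 2)
  l$p <- signif(l$p, 3)
  print(l, row.names = FALSE)
  invisible(x)
}
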
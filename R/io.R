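cohort_mandatory_columns <- function() {
  c("patient_id", "age", "gcs", "pupils", "rotterdam", "gos")
}

#' Write a cohort to CSV with a JSON configuration sidecar
#'
#' One row per patient; lesion columns are named
#' `<region>_<subregion>_<laterality>_<sequence>` with 0/1 values. If the
#' cohort carries a generator configuration (attribute `"config"`), it is
#' stored alongside as `<path>.json`, including the seed.
#'
#' @param cohort Cohort data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, quote = FALSE, na = "")
  cfg <- attr(cohort, "config")
  if (!is.null(cfg)) {
    side <- unclass(cfg)
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
  }
  invisible(path)
}

#' Read a cohort CSV
#'
#' Validates the schema (mandatory columns `patient_id`, `age`, `gcs`,
#' `pupils`, `rotterdam`, `gos`) and row-level ranges (GCS 3-15, GOS 1-5,
#' Rotterdam 1-6, age >= 15; `NA` cells are allowed pre-imputation). Unknown
#' columns are preserved. `unfavorable` is recomputed as GOS <= 3 when a GOS
#' value is present.
#'
#' @param path CSV path written by [write_cohort_csv()] (or matching schema).
#' @return Cohort data.frame (empty, with a warning, for an empty file).
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    warning("empty cohort file: ", path, call. = FALSE)
    return(data.frame())
  }
  cohort <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(cohort) == 0L) {
    warning("cohort file has a header but no rows: ", path, call. = FALSE)
    return(cohort)
  }
  miss <- setdiff(cohort_mandatory_columns(), names(cohort))
  if (length(miss) > 0L) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  check_range <- function(col, lo, hi) {
    v <- cohort[[col]]
    bad <- which(!is.na(v) & (v < lo | v > hi))
    if (length(bad) > 0L) {
      stop(sprintf("column '%s' out of range [%s, %s] in row(s) %s", col, lo,
                   hi, paste(head(bad, 5), collapse = ", ")), call. = FALSE)
    }
  }
  check_range("gcs", 3, 15)
  check_range("gos", 1, 5)
  check_range("rotterdam", 1, 6)
  check_range("age", 15, Inf)
  lcols <- intersect(lesion_site_table()$column, names(cohort))
  for (col in lcols) {
    if (any(!cohort[[col]] %in% c(0L, 1L, NA))) {
      stop("lesion column '", col, "' must be 0/1", call. = FALSE)
    }
  }
  cohort$unfavorable <- cohort$gos <= 3
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    attr(cohort, "config") <- jsonlite::read_json(side, simplifyVector = TRUE)
  }
  cohort
}

# One-vs-rest logistic classifier for a categorical covariate; returns the
# argmax category at the prediction rows.
impute_categorical <- function(obs_X, obs_y, mis_X) {
  levels_y <- sort(unique(obs_y))
  if (length(levels_y) == 1L) return(rep(levels_y, nrow(mis_X)))
  scores <- vapply(levels_y, function(lv) {
    logit_fit_probs(obs_X, as.integer(obs_y == lv), mis_X)
  }, numeric(nrow(mis_X)))
  if (nrow(mis_X) == 1L) scores <- matrix(scores, nrow = 1L)
  levels_y[max.col(scores)]
}

#' Chained-equation imputation of clinical covariates
#'
#' A lightweight multivariate imputation by chained equations: starting from
#' random draws of observed values, each incomplete covariate is regressed on
#' the other covariates plus the dichotomized outcome (linear regression for
#' continuous/ordinal covariates, one-vs-rest logistic for categorical ones),
#' and the missing cells are replaced by the model prediction; the cycle
#' repeats `n_iterations` times. Predictive-mean updates make the completed
#' data deterministic given the seed; no originally observed cell is changed.
#' Ordinal covariates (GCS, Rotterdam) are rounded and clipped to their valid
#' ranges.
#'
#' @param cohort Cohort data.frame; missingness must be confined to `age`,
#'   `gcs`, `pupils`, `rotterdam`.
#' @param n_iterations Chained-equation cycles (default 10).
#' @param seed Integer seed for the initialization draws.
#' @return Completed cohort.
#' @export
impute_chained <- function(cohort, n_iterations = 10L, seed = 1L) {
  covs <- c("age", "gcs", "pupils", "rotterdam")
  covs <- intersect(covs, names(cohort))
  na_idx <- lapply(cohort[covs], function(v) which(is.na(v)))
  names(na_idx) <- covs
  if (all(lengths(na_idx) == 0L)) return(cohort)
  for (v in covs) {
    if (length(na_idx[[v]]) == nrow(cohort)) {
      stop("covariate '", v, "' is entirely missing", call. = FALSE)
    }
    if (length(na_idx[[v]]) > nrow(cohort) / 2) {
      stop("covariate '", v, "' is more than 50% missing", call. = FALSE)
    }
  }
  work <- cohort
  with_seed(seed, {
    for (v in covs) {
      idx <- na_idx[[v]]
      if (length(idx) > 0L) {
        obs <- work[[v]][!is.na(work[[v]])]
        work[[v]][idx] <- sample(obs, length(idx), replace = TRUE)
      }
    }
    design <- function(exclude) {
      others <- setdiff(covs, exclude)
      X <- matrix(0, nrow(work), 0)
      for (o in others) {
        if (is.character(work[[o]])) {
          lv <- sort(unique(work[[o]]))
          for (l in lv[-1]) X <- cbind(X, as.integer(work[[o]] == l))
        } else {
          X <- cbind(X, work[[o]])
        }
      }
      if (!is.null(work$unfavorable)) X <- cbind(X, as.integer(work$unfavorable))
      X
    }
    bounds <- list(gcs = c(3, 15), rotterdam = c(1, 6), age = c(15, 82))
    for (it in seq_len(n_iterations)) {
      for (v in covs) {
        idx <- na_idx[[v]]
        if (length(idx) == 0L) next
        X <- design(v)
        if (is.character(work[[v]])) {
          work[[v]][idx] <- impute_categorical(X[-idx, , drop = FALSE],
                                               work[[v]][-idx],
                                               X[idx, , drop = FALSE])
        } else {
          fit <- lm.fit(cbind(1, X[-idx, , drop = FALSE]), work[[v]][-idx])
          beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
          pred <- as.numeric(cbind(1, X[idx, , drop = FALSE]) %*% beta)
          b <- bounds[[v]]
          if (!is.null(b)) pred <- pmin(pmax(pred, b[1]), b[2])
          if (v %in% c("gcs", "rotterdam")) pred <- as.integer(round(pred))
          work[[v]][idx] <- pred
        }
      }
    }
  })
  work
}

#' Pipeline configuration
#'
#' @param cohort A [cohort_config()].
#' @param ga A [ga_config()] for the derivation stage.
#' @param candidate_features Candidate TAI feature columns for the GA; default
#'   is the susceptibility-family site columns (the family the published
#'   selection found most informative).
#' @param grade_coding Passed to [compare_grading_systems()].
#' @param alpha Significance level recorded in reports.
#' @param impute_iterations Chained-imputation cycles.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            ga = ga_config(population_size = 30L,
                                           generations = 15L),
                            candidate_features = NULL,
                            grade_coding = "ordinal", alpha = 0.05,
                            impute_iterations = 10L) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  if (is.null(candidate_features)) {
    sites <- lesion_site_table()
    candidate_features <- sites$column[sites$sequence == "susceptibility"]
  }
  structure(list(cohort = cohort, ga = ga,
                 candidate_features = candidate_features,
                 grade_coding = grade_coding, alpha = alpha,
                 impute_iterations = as.integer(impute_iterations)),
            class = "pipeline_config")
}

# FNV-1a hash of an R object's serialized bytes (stable fingerprint for
# manifests; not cryptographic).
fnv1a <- function(obj) {
  bytes <- as.integer(serialize(obj, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> inject/impute missingness -> grade -> derive ->
#' evaluate on a synthetic cohort, writing all artifacts plus a manifest (seed,
#' configuration hash, package version, per-file hashes) to `out_dir`.
#' Identical configuration and seed produce identical artifacts and manifest
#' hash. A stage failure halts with an error naming the stage; files already
#' written keep a `.partial` suffix.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("taigrade_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$cohort$seed
  manifest <- list(seed = seed, config_hash = fnv1a(unclass(config)),
                   package_version = as.character(utils::packageVersion("taigrade")),
                   stages = character(), files = list())
  partial <- character()
  emit <- function(name, writer) {
    tmp <- file.path(out_dir, paste0(name, ".partial"))
    writer(tmp)
    partial <<- c(partial, tmp)
    tmp
  }
  finalize_stage <- function(stage) {
    for (tmp in partial) {
      # writers may add sidecars next to the temporary path
      sidecars <- Sys.glob(paste0(tmp, ".*"))
      for (f in c(tmp, sidecars)) {
        final <- sub("\\.partial", "", f)
        file.rename(f, final)
        manifest$files[[basename(final)]] <<- fnv1a(readBin(final, "raw",
                                                            file.size(final)))
      }
    }
    partial <<- character()
    manifest$stages <<- c(manifest$stages, stage)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  cohort <- stage("simulate", {
    coh <- generate_cohort(config$cohort)
    emit("cohort.csv", function(p) write_cohort_csv(coh, p))
    finalize_stage("simulate")
    coh
  })

  cohort <- stage("impute", {
    masked <- inject_missingness(cohort, config$cohort$missingness_rate,
                                 seed = derive_seed(seed, "missingness"))
    done <- impute_chained(masked, config$impute_iterations,
                           seed = derive_seed(seed, "impute"))
    finalize_stage("impute")
    done
  })

  graded <- stage("grade", {
    g <- grade_cohort(cohort)
    emit("graded.csv", function(p) write.csv(g, p, row.names = FALSE))
    finalize_stage("grade")
    g
  })

  derivation <- stage("derive", {
    sp <- split_train_test(graded, seed = derive_seed(seed, "split"))
    ga_cfg <- config$ga
    ga_cfg$seed <- derive_seed(seed, "ga")
    sel <- ga_select(sp$train, config$candidate_features, ga_cfg)
    rep <- rf_validate(sp$train, sp$test, sel$selected_features,
                       seed = derive_seed(seed, "rf"))
    out <- list(selected_features = sel$selected_features,
                ga_fitness = sel$fitness, ga_cv_auc = sel$cv_auc,
                test_auc_with_tai = rep$test_auc_with_tai,
                test_auc_core_only = rep$test_auc_core_only,
                gini_importances = as.list(rep$gini_importances))
    emit("derivation.json", function(p) {
      jsonlite::write_json(out, p, auto_unbox = TRUE, digits = NA)
    })
    finalize_stage("derive")
    out
  })

  comparison <- stage("evaluate", {
    cmp <- compare_grading_systems(graded, config$grade_coding)
    emit("model_comparison.csv", function(p) {
      write.csv(cmp$models, p, row.names = FALSE)
    })
    emit("tests.json", function(p) {
      jsonlite::write_json(list(alpha = config$alpha, lrt = cmp$lrt,
                                delong = cmp$delong),
                           p, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
    })
    emit("severity_table.csv", function(p) {
      write.csv(severity_table(graded), p, row.names = FALSE)
    })
    finalize_stage("evaluate")
    cmp
  })

  manifest$manifest_hash <- fnv1a(manifest[c("seed", "config_hash", "files")])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, cohort = graded,
                 derivation = derivation, comparison = comparison,
                 out_dir = out_dir))
}
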
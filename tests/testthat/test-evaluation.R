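test_that("logistic fitting reproduces closed-form and nesting properties", {
  coh <- grade_cohort(generate_cohort(cohort_config(n_patients = 351,
                                                    seed = 3)))
  # intercept-only MLE is the marginal unfavorable fraction
  m0 <- fit_logistic(coh, character())
  expect_equal(unique(round(m0$fitted_probs, 12)),
               round(mean(coh$unfavorable), 12))
  expect_equal(m0$aic, 2 - 2 * m0$log_likelihood)

  m1 <- fit_logistic(coh, "grade_stockholm")
  expect_gte(m1$log_likelihood, m0$log_likelihood)
  m2 <- fit_logistic(coh, c("grade_stockholm", "age", "gcs", "pupils"))
  expect_gte(m2$log_likelihood, m1$log_likelihood)
  expect_equal(m2$aic, 2 * m2$n_params - 2 * m2$log_likelihood)
  # pupils enters as a 3-level categorical: 2 dummies + intercept + 3 others
  expect_equal(m2$n_params, 6L)

  expect_error(fit_logistic(coh, "nonexistent_column"), "not found")
  one_class <- coh
  one_class$unfavorable <- TRUE
  expect_error(fit_logistic(one_class, "age"), "classes")
})

test_that("perfect separation is flagged", {
  d <- data.frame(x = c(-(10:1), 1:10), unfavorable = rep(c(FALSE, TRUE),
                                                          each = 10))
  expect_warning(m <- fit_logistic(d, "x"), "separation")
  expect_true(m$separation)
})

test_that("AUC equals the pairwise Mann-Whitney count with tie half-credit", {
  expect_equal(auc_roc(c(1, 2, 2, 3), c(0, 0, 1, 1)), 0.875)
  expect_equal(auc_roc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  set.seed(14)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- sample(1:6, n, replace = TRUE) # heavy ties
    expect_equal(auc_roc(scores, labels), brute_force_auc(scores, labels))
  }
  set.seed(15)
  null_auc <- auc_roc(rnorm(10000), sample(c(TRUE, FALSE), 10000,
                                           replace = TRUE))
  expect_lt(abs(null_auc - 0.5), 0.02)
  expect_error(auc_roc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("Nagelkerke pseudo-R2 matches hand-worked values and bounds", {
  expect_equal(nagelkerke_r2(list(log_likelihood = -2, n = 4), 4 * log(0.5)),
               0.4272, tolerance = 1e-4)
  expect_equal(nagelkerke_r2(list(log_likelihood = -7, n = 10), -7), 0)
  # near-saturated fit approaches 1
  expect_gt(nagelkerke_r2(list(log_likelihood = -1e-9, n = 50),
                          50 * log(0.5)), 0.999)
  expect_error(nagelkerke_r2(list(log_likelihood = -5, n = 4), -2), "nested")
  coh <- grade_cohort(generate_cohort(cohort_config(n_patients = 400,
                                                    seed = 21)))
  m0 <- fit_logistic(coh, character())
  m <- fit_logistic(coh, c("age", "gcs", "grade_stockholm"))
  r2 <- nagelkerke_r2(m, m0$log_likelihood)
  expect_gte(r2, 0)
  expect_lte(r2, 1)
})

test_that("DeLong test agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  for (i in 1:50) {
    n <- sample(40:120, 1)
    y <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    a <- rnorm(n) + y * runif(1, 0, 1.5)
    b <- rnorm(n) + y * runif(1, 0, 1.5)
    if (i %% 2 == 0) { # ties
      a <- round(a); b <- round(b)
    }
    mine <- delong_test(a, b, y)
    ref <- suppressMessages(pROC::roc.test(
      pROC::roc(y, a, quiet = TRUE, direction = "<"),
      pROC::roc(y, b, quiet = TRUE, direction = "<"),
      method = "delong", paired = TRUE))
    expect_equal(abs(mine$z), abs(unname(ref$statistic)), tolerance = 1e-8)
    expect_equal(mine$p, unname(ref$p.value), tolerance = 1e-8)
    expect_equal(mine$auc_a, auc_roc(a, y), tolerance = 1e-12)
    expect_equal(mine$auc_b, auc_roc(b, y), tolerance = 1e-12)
  }
})

test_that("DeLong single-curve variance matches the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(34)
  for (i in 1:100) {
    n <- sample(30:80, 1)
    y <- c(TRUE, FALSE, runif(n - 2) < 0.4)
    a <- rnorm(n) + y # continuous scores: no ties
    pl <- taigrade:::delong_placements(a, y)
    v <- var(pl$v10) / sum(y) + var(pl$v01) / sum(!y)
    expect_equal(v, unname(pROC::var(pROC::roc(y, a, quiet = TRUE,
                                               direction = "<"),
                                     method = "delong")), tolerance = 1e-9)
  }
})

test_that("identical score vectors give z = 0, p = 1 with a warning", {
  y <- rep(c(TRUE, FALSE), each = 10)
  s <- rnorm(20)
  expect_warning(res <- delong_test(s, s, y), "degenerate")
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)
  expect_error(delong_test(1:5, 1:6, rep(c(TRUE, FALSE), 3)), "paired")
})

test_that("likelihood-ratio test handles nesting and trivial cases", {
  coh <- grade_cohort(generate_cohort(cohort_config(n_patients = 500,
                                                    seed = 41)))
  m0 <- fit_logistic(coh, c("age", "gcs"))
  m1 <- fit_logistic(coh, c("age", "gcs", "grade_stockholm"))
  res <- likelihood_ratio_test(m0, m1)
  expect_gte(res$stat, 0)
  expect_equal(res$df, 1L)
  expect_equal(res$stat, 2 * (m1$log_likelihood - m0$log_likelihood))

  same <- likelihood_ratio_test(m0, m0)
  expect_equal(same$stat, 0)
  expect_equal(same$p, 1)

  m2 <- fit_logistic(coh, c("rotterdam"))
  expect_error(likelihood_ratio_test(m2, m1), "nested")
})

test_that("severity table equals a hand tally on a fixture cohort", {
  coh <- hand_cohort(
    list("pons_unspecified_bilateral_dwi",
         "pons_unspecified_bilateral_dwi",
         "pons_unspecified_unilateral_dwi",
         c("corpus_callosum_splenium_not_applicable_flair",
           "thalamus_unspecified_bilateral_flair"),
         "corpus_callosum_splenium_not_applicable_flair",
         "midbrain_tegmentum_unilateral_susceptibility",
         "subcortical_unspecified_unilateral_susceptibility",
         character(), character(), character()),
    unfavorable = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
                    FALSE, FALSE, TRUE))
  tab <- severity_table(coh)
  pick <- function(sq, type) {
    tab[tab$sequence == sq & tab$lesion_type == type, ]
  }
  expect_equal(pick("dwi", "bilateral")[pick("dwi", "bilateral")$region ==
                                          "pons", ]$n, 2L)
  expect_equal(pick("dwi", "bilateral")[pick("dwi", "bilateral")$region ==
                                          "pons", ]$pct_unfavorable, 100)
  expect_equal(pick("flair", "splenium")$n, 2L)
  expect_equal(pick("flair", "splenium")$pct_unfavorable, 50)
  expect_equal(pick("susceptibility", "tegmentum")$n, 1L)
  # zero-count cells have a missing percentage
  expect_equal(pick("dwi", "tegmentum")$n, 0L)
  expect_true(is.na(pick("dwi", "tegmentum")$pct_unfavorable))
  # per-sequence "no detected TAI" rows
  none_dwi <- pick("dwi", "no_detected_tai")
  expect_equal(none_dwi$n, 7L) # 10 - 3 with DWI lesions
  expect_equal(none_dwi$pct_unfavorable, 100 * 3 / 7)
})

test_that("bilateral pontine TAI is more severe than unilateral on every sequence", {
  coh <- generate_cohort(cohort_config(n_patients = 6000, seed = 51))
  tab <- severity_table(coh)
  for (sq in c("dwi", "flair", "susceptibility")) {
    bi <- tab[tab$sequence == sq & tab$region == "pons" &
                tab$lesion_type == "bilateral", ]
    uni <- tab[tab$sequence == sq & tab$region == "pons" &
                 tab$lesion_type == "unilateral", ]
    expect_gt(bi$pct_unfavorable, uni$pct_unfavorable)
  }
})

test_that("Cochran-Armitage trend test matches the base-R chi-square and flips sign", {
  events <- c(2, 5, 9); totals <- c(12, 11, 13)
  mine <- cochran_armitage_trend(events, totals)
  ref <- suppressWarnings(prop.trend.test(events, totals))
  expect_equal(mine$z^2, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)

  rev_res <- cochran_armitage_trend(rev(events), rev(totals))
  expect_equal(rev_res$z, -mine$z, tolerance = 1e-12)
  expect_equal(rev_res$p, mine$p, tolerance = 1e-12)

  flat <- cochran_armitage_trend(c(5, 5, 5), c(10, 10, 10))
  expect_equal(flat$z, 0)
  expect_equal(flat$p, 1)

  expect_error(cochran_armitage_trend(c(0, 0), c(5, 5)), "zero-margin")
  expect_error(cochran_armitage_trend(c(5), c(5)), "categories")
})

test_that("the grading-system battery fits 15 models with valid metrics", {
  coh <- grade_cohort(generate_cohort(cohort_config(n_patients = 800,
                                                    seed = 61)))
  cmp <- compare_grading_systems(coh)
  expect_equal(nrow(cmp$models), 15L)
  expect_true(all(cmp$models$pseudo_r2 >= 0 & cmp$models$pseudo_r2 <= 1))
  expect_true(all(is.finite(cmp$models$aic)))
  expect_true(all(cmp$models$auc >= 0.5 & cmp$models$auc <= 1))
  expect_equal(nrow(cmp$lrt), 4L)
  expect_equal(nrow(cmp$delong), 6L)
  # core + system discriminates at least as well as core alone (in-sample)
  auc_of <- function(m) cmp$models$auc[cmp$models$model == m]
  for (s in c("adams", "firsching", "abu_hamdeh", "stockholm")) {
    expect_gte(auc_of(paste0("core+", s)), auc_of("core"))
  }
  # row-order invariance
  cmp_perm <- compare_grading_systems(coh[sample(nrow(coh)), ])
  expect_equal(cmp_perm$models, cmp$models, tolerance = 1e-9)
  expect_equal(cmp_perm$lrt$p, cmp$lrt$p, tolerance = 1e-9)

  expect_error(compare_grading_systems(generate_cohort(
    cohort_config(n_patients = 50, seed = 1))), "graded")
})

test_that("dummy-coded grades are available behind the coding flag", {
  coh <- grade_cohort(generate_cohort(cohort_config(n_patients = 600,
                                                    seed = 71)))
  cmp <- compare_grading_systems(coh, grade_coding = "factor")
  expect_equal(nrow(cmp$models), 15L)
  # factor coding spends more parameters, so in-sample fit cannot be worse
  ord <- compare_grading_systems(coh)
  expect_gte(cmp$models$pseudo_r2[cmp$models$model == "stockholm"],
             ord$models$pseudo_r2[ord$models$model == "stockholm"])
})
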
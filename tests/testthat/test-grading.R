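test_that("published worked examples grade correctly under all four systems", {
  bilat_pons <- lesion_map("pons", laterality = "bilateral", sequence = "flair")
  expect_equal(grade_stockholm(bilat_pons)$grade, 4L)
  expect_equal(grade_firsching(bilat_pons)$grade, 4L)

  expect_equal(grade_stockholm(lesion_map())$grade, 1L)
  expect_equal(grade_stockholm(lesion_map())$label, "I")

  teg_cc <- lesion_map(c("midbrain", "corpus_callosum"),
                       c("tegmentum", "splenium"),
                       c("unilateral", "not_applicable"),
                       c("susceptibility", "flair"))
  expect_equal(grade_stockholm(teg_cc)$grade, 3L)

  tectum <- lesion_map("midbrain", "tectum", "unilateral", "dwi")
  expect_equal(grade_stockholm(tectum)$grade, 2L)

  expect_equal(grade_adams(lesion_map("subcortical", laterality = "unilateral",
                                      sequence = "flair"))$grade, 1L)
  cc_plus_subcort <- lesion_map(c("corpus_callosum", "subcortical"),
                                c("splenium", "unspecified"),
                                c("not_applicable", "bilateral"),
                                c("dwi", "flair"))
  expect_equal(grade_adams(cc_plus_subcort)$grade, 2L)
  expect_equal(grade_adams(lesion_map("pons", "dorsal", "unilateral",
                                      "susceptibility"))$grade, 3L)
  expect_equal(grade_adams(lesion_map())$grade, 0L)

  expect_equal(grade_firsching(lesion_map("thalamus", laterality = "unilateral",
                                          sequence = "flair"))$grade, 1L)
  expect_equal(grade_firsching(lesion_map("midbrain", laterality = "bilateral",
                                          sequence = "susceptibility"))$grade, 3L)
  mb_pons_bilat <- lesion_map(c("midbrain", "pons"),
                              laterality = "bilateral", sequence = "flair")
  expect_equal(grade_firsching(mb_pons_bilat)$grade, 4L)
  expect_equal(grade_firsching(lesion_map())$grade, 0L)

  iva <- grade_abu_hamdeh(lesion_map("midbrain", "tegmentum", "unilateral",
                                     "susceptibility"), age = 25)
  expect_equal(iva$label, "IVa")
  iib <- grade_abu_hamdeh(lesion_map("corpus_callosum", "trunk",
                                     sequence = "flair"), age = 45)
  expect_equal(iib$label, "IIb")
  # age exactly 30 falls in stratum b
  expect_equal(grade_abu_hamdeh(lesion_map("subcortical",
                                           laterality = "unilateral",
                                           sequence = "dwi"),
                                age = 30)$age_stratum, "b")
  # tegmentum seen only on FLAIR is brainstem grade III, not IV
  expect_equal(grade_abu_hamdeh(lesion_map("midbrain", "tegmentum",
                                           "unilateral", "flair"),
                                age = 40)$grade, 3L)
  # the pooled susceptibility family stands in for SWI when unavailable
  expect_equal(grade_abu_hamdeh(lesion_map("midbrain", "tegmentum",
                                           "unilateral", "susceptibility"),
                                age = 40, swi_available = FALSE)$grade, 4L)
})

test_that("Stockholm grade I is the exhaustive fallback", {
  # basal ganglia is not named by grades II-IV: grade I despite a lesion
  bg_only <- lesion_map("basal_ganglia", laterality = "bilateral",
                        sequence = "susceptibility")
  expect_equal(grade_stockholm(bg_only)$grade, 1L)
  expect_equal(grade_adams(bg_only)$grade, 1L) # but hemispheric for Adams
})

test_that("triggering sites are a subset of the input and match the rule", {
  map <- lesion_map(c("pons", "pons", "corpus_callosum"),
                    c("unspecified", "ventral", "splenium"),
                    c("bilateral", "unilateral", "not_applicable"),
                    c("flair", "dwi", "flair"))
  res <- grade_stockholm(map)
  expect_equal(res$grade, 4L)
  expect_true(all(res$triggering_sites$column %in% map$column))
  expect_true(all(res$triggering_sites$region == "pons" &
                    res$triggering_sites$laterality == "bilateral"))
})

test_that("malformed sites are rejected", {
  expect_error(lesion_map("cerebellum", sequence = "flair"), "invalid lesion")
  bad <- lesion_map("pons", laterality = "bilateral", sequence = "flair")
  bad$sequence <- "t1"
  expect_error(grade_stockholm(bad), "malformed")
  expect_error(grade_abu_hamdeh(lesion_map(), age = 10), "age")
})

test_that("grades are monotone in the lesion map on all 1- and 2-site maps", {
  n_sites <- nrow(lesion_site_table())
  singles <- engine_grades_many(as.list(seq_len(n_sites)))
  pairs <- combn(n_sites, 2)
  pair_grades <- engine_grades_many(
    lapply(seq_len(ncol(pairs)), function(j) pairs[, j]))
  expect_true(all(pair_grades >= pmax(singles[, pairs[1, ]],
                                      singles[, pairs[2, ]])))
  # every system assigns exactly one grade to every map (range check)
  expect_true(all(singles["stockholm", ] %in% 1:4))
  expect_true(all(singles["adams", ] %in% 0:3))
  expect_true(all(singles["firsching", ] %in% 0:4))
  expect_true(all(singles["abu_hamdeh", ] %in% 0:4))
})

test_that("hand-coded engines match the declarative rule-table oracle", {
  idx_small <- small_map_indices()
  hand <- engine_grades_many(idx_small)
  oracle <- vapply(idx_small,
                   function(idx) oracle_grades(site_rows_to_map(idx)),
                   integer(4))
  expect_identical(unname(hand), unname(oracle))

  set.seed(42)
  idx_rand <- lapply(seq_len(2000), function(i) {
    k <- sample.int(7L, 1L) - 1L
    sample.int(nrow(lesion_site_table()), k)
  })
  hand_r <- engine_grades_many(idx_rand)
  oracle_r <- vapply(idx_rand,
                     function(idx) oracle_grades(site_rows_to_map(idx)),
                     integer(4))
  expect_identical(unname(hand_r), unname(oracle_r))
})

test_that("grade_cohort is vectorized, order-invariant, and validated", {
  coh <- hand_cohort(
    list("pons_unspecified_bilateral_flair",
         c("midbrain_tegmentum_unilateral_susceptibility",
           "corpus_callosum_splenium_not_applicable_flair"),
         character()),
    unfavorable = c(TRUE, TRUE, FALSE), age = c(25, 45, 70))
  g <- grade_cohort(coh, systems = "all")
  expect_equal(g$grade_stockholm, c(4L, 3L, 1L))
  expect_equal(g$grade_adams, c(3L, 3L, 0L))
  expect_equal(g$grade_firsching, c(4L, 2L, 0L))
  expect_equal(g$grade_abu_hamdeh, c(3L, 4L, 0L))
  expect_equal(g$abu_hamdeh_stratum, c("a", "b", "b"))
  # 4 systems x 3 patients = 12 grades
  expect_equal(sum(lengths(g[paste0("grade_",
                                    c("adams", "firsching", "abu_hamdeh",
                                      "stockholm"))])), 12L)

  perm <- c(3, 1, 2)
  g_perm <- grade_cohort(coh[perm, ], systems = "all")
  expect_equal(g_perm$grade_stockholm[order(g_perm$patient_id)],
               g$grade_stockholm[order(g$patient_id)])

  expect_error(grade_cohort(coh, systems = "mannion"), "unknown grading")
})

test_that("vectorized cohort grading agrees with per-patient engines", {
  coh <- generate_cohort(cohort_config(n_patients = 150, seed = 77))
  g <- grade_cohort(coh)
  for (i in seq(1, 150, by = 7)) {
    map <- lesion_site_table()[
      as.numeric(coh[i, lesion_site_table()$column]) == 1, ]
    expect_equal(g$grade_stockholm[i], grade_stockholm(map)$grade)
    expect_equal(g$grade_adams[i], grade_adams(map)$grade)
    expect_equal(g$grade_firsching[i], grade_firsching(map)$grade)
    expect_equal(g$grade_abu_hamdeh[i],
                 grade_abu_hamdeh(map, age = coh$age[i])$grade)
  }
})
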
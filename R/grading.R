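#' @title TAI grading systems
#' @description
#' Deterministic rule engines mapping a patient's lesion map (and age, for the
#' Abu Hamdeh system) to a grade under four MRI-based TAI grading systems:
#'
#' * **Stockholm** (grades I-IV, grade I is the exhaustive fallback):
#'   IV = bilateral pontine TAI; III = midbrain-tegmentum TAI (any laterality),
#'   bilateral thalamic TAI, or TAI in the posterior limb of the internal
#'   capsule; II = corpus callosum TAI, unilateral thalamic TAI, unilateral
#'   pontine TAI, or midbrain TAI outside the tegmentum; I = everything else
#'   (including no detected TAI).
#' * **Adams** (0-III): III = brainstem; II = corpus callosum; I = hemispheric
#'   (lobar white matter / deep grey); 0 = no qualifying lesion.
#' * **Firsching** (0-IV): IV = bilateral pons; III = bilateral midbrain;
#'   II = unilateral brainstem at any level; I = supratentorial lesions only;
#'   0 = no lesion.
#' * **Abu Hamdeh** (0-IV with age strata a/b): IV = substantia nigra /
#'   mesencephalic tegmentum on the susceptibility-sensitive family; III =
#'   other brainstem; II = corpus callosum; I = hemispheric; stratum a for age
#'   under 30, b otherwise.
#'
#' All systems are applied across FLAIR, DWI and the susceptibility-sensitive
#' sequences; when sequences disagree the most severe grade wins, so multiple
#' qualifying sites within a grade never change the grade.
#'
#' @param lesions A lesion map ([lesion_map()]), possibly empty.
#' @param age Patient age in years (Abu Hamdeh only).
#' @param swi_available Whether SWI was acquired; when `FALSE`, T2*GRE stands
#'   in for SWI. Both belong to the pooled susceptibility family used here, so
#'   the flag is interface-compatible but does not alter the result.
#' @return A `grade_result`: list with `system`, `grade` (integer),
#'   `age_stratum` (`"a"`, `"b"` or `"none"`), `label` (e.g. `"IVa"`), and
#'   `triggering_sites` (the subset of input sites matching the awarded
#'   grade's rule).
#' @examples
#' grade_stockholm(lesion_map("pons", laterality = "bilateral",
#'                            sequence = "flair"))$grade # 4
#' grade_adams(lesion_map())$grade # 0
#' @name grading
NULL

roman_label <- function(grade, stratum = "none") {
  r <- c("0", "I", "II", "III", "IV")[grade + 1L]
  if (stratum %in% c("a", "b") && grade > 0L) paste0(r, stratum) else r
}

new_grade_result <- function(system, grade, triggering, stratum = "none") {
  structure(list(system = system, grade = as.integer(grade),
                 age_stratum = stratum,
                 label = roman_label(as.integer(grade), stratum),
                 triggering_sites = triggering),
            class = "grade_result")
}

#' @export
print.grade_result <- function(x, ...) {
  cat(sprintf("<%s grading> grade %s (%d triggering site%s)\n", x$system,
              x$label, nrow(x$triggering_sites),
              if (nrow(x$triggering_sites) == 1L) "" else "s"))
  invisible(x)
}

check_lesion_map <- function(lesions) {
  need <- c("region", "subregion", "laterality", "sequence")
  if (!is.data.frame(lesions) || !all(need %in% names(lesions))) {
    stop("lesions must be a lesion_map() data.frame", call. = FALSE)
  }
  key <- paste(lesions$region, lesions$subregion, lesions$laterality,
               lesions$sequence, sep = "_")
  bad <- setdiff(key, lesion_site_table()$column)
  if (length(bad) > 0L) {
    stop("malformed lesion site(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  lesions
}

# --- Stockholm ---------------------------------------------------------------

stockholm_rule_sets <- function(l) {
  list(
    `4` = l$region == "pons" & l$laterality == "bilateral",
    `3` = (l$region == "midbrain" & l$subregion == "tegmentum") |
          (l$region == "thalamus" & l$laterality == "bilateral") |
          (l$region == "internal_capsule_plic"),
    `2` = (l$region == "corpus_callosum") |
          (l$region == "thalamus" & l$laterality == "unilateral") |
          (l$region == "pons" & l$laterality == "unilateral") |
          (l$region == "midbrain" & l$subregion != "tegmentum")
  )
}

#' @rdname grading
#' @export
grade_stockholm <- function(lesions) {
  l <- check_lesion_map(lesions)
  rules <- stockholm_rule_sets(l)
  for (g in c(4L, 3L, 2L)) {
    hit <- rules[[as.character(g)]]
    if (any(hit)) {
      return(new_grade_result("stockholm", g, l[hit, , drop = FALSE]))
    }
  }
  new_grade_result("stockholm", 1L, l[0L, , drop = FALSE])
}

# --- Adams -------------------------------------------------------------------

#' @rdname grading
#' @export
grade_adams <- function(lesions) {
  l <- check_lesion_map(lesions)
  rules <- list(
    `3` = l$region %in% brainstem_regions(),
    `2` = l$region == "corpus_callosum",
    `1` = l$region %in% hemispheric_regions()
  )
  for (g in c(3L, 2L, 1L)) {
    hit <- rules[[as.character(g)]]
    if (any(hit)) return(new_grade_result("adams", g, l[hit, , drop = FALSE]))
  }
  new_grade_result("adams", 0L, l[0L, , drop = FALSE])
}

# --- Firsching ---------------------------------------------------------------

#' @rdname grading
#' @export
grade_firsching <- function(lesions) {
  l <- check_lesion_map(lesions)
  rules <- list(
    `4` = l$region == "pons" & l$laterality == "bilateral",
    `3` = l$region == "midbrain" & l$laterality == "bilateral",
    `2` = l$region %in% brainstem_regions() & l$laterality == "unilateral",
    `1` = l$region %in% supratentorial_regions()
  )
  for (g in c(4L, 3L, 2L, 1L)) {
    hit <- rules[[as.character(g)]]
    if (any(hit)) {
      return(new_grade_result("firsching", g, l[hit, , drop = FALSE]))
    }
  }
  new_grade_result("firsching", 0L, l[0L, , drop = FALSE])
}

# --- Abu Hamdeh --------------------------------------------------------------

#' @rdname grading
#' @export
grade_abu_hamdeh <- function(lesions, age, swi_available = TRUE) {
  l <- check_lesion_map(lesions)
  if (!is.finite(age) || age < 15) stop("age must be >= 15", call. = FALSE)
  stratum <- if (age < 30) "a" else "b"
  # The susceptibility family already pools SWI and T2*GRE, so grade IV is
  # assessed on that family whether or not SWI itself was acquired.
  rules <- list(
    `4` = l$region == "midbrain" & l$subregion == "tegmentum" &
          l$sequence == "susceptibility",
    `3` = l$region %in% brainstem_regions(),
    `2` = l$region == "corpus_callosum",
    `1` = l$region %in% hemispheric_regions()
  )
  rules[["3"]] <- rules[["3"]] & !rules[["4"]]
  for (g in c(4L, 3L, 2L, 1L)) {
    hit <- rules[[as.character(g)]]
    if (any(hit)) {
      return(new_grade_result("abu_hamdeh", g, l[hit, , drop = FALSE], stratum))
    }
  }
  new_grade_result("abu_hamdeh", 0L, l[0L, , drop = FALSE], stratum)
}

# --- Vectorized cohort grading ----------------------------------------------

# Any-hit indicator over a set of lesion columns, for a wide cohort.
any_site <- function(cohort, cols) {
  cols <- intersect(cols, names(cohort))
  if (length(cols) == 0L) return(rep(FALSE, nrow(cohort)))
  rowSums(as.matrix(cohort[, cols, drop = FALSE])) > 0
}

site_cols <- function(sites, ...) {
  f <- list(...)
  keep <- rep(TRUE, nrow(sites))
  for (nm in names(f)) keep <- keep & sites[[nm]] %in% f[[nm]]
  sites$column[keep]
}

# Vectorized Stockholm grades for a wide cohort data.frame.
stockholm_grades <- function(cohort, sites = lesion_site_table()) {
  g4 <- any_site(cohort, site_cols(sites, region = "pons",
                                   laterality = "bilateral"))
  g3 <- any_site(cohort, c(
    site_cols(sites, region = "midbrain", subregion = "tegmentum"),
    site_cols(sites, region = "thalamus", laterality = "bilateral"),
    site_cols(sites, region = "internal_capsule_plic")
  ))
  g2 <- any_site(cohort, c(
    site_cols(sites, region = "corpus_callosum"),
    site_cols(sites, region = "thalamus", laterality = "unilateral"),
    site_cols(sites, region = "pons", laterality = "unilateral"),
    site_cols(sites, region = "midbrain",
              subregion = c("tectum", "cerebral_peduncles", "unspecified"))
  ))
  ifelse(g4, 4L, ifelse(g3, 3L, ifelse(g2, 2L, 1L)))
}

adams_grades <- function(cohort, sites = lesion_site_table()) {
  g3 <- any_site(cohort, site_cols(sites, region = brainstem_regions()))
  g2 <- any_site(cohort, site_cols(sites, region = "corpus_callosum"))
  g1 <- any_site(cohort, site_cols(sites, region = hemispheric_regions()))
  ifelse(g3, 3L, ifelse(g2, 2L, ifelse(g1, 1L, 0L)))
}

firsching_grades <- function(cohort, sites = lesion_site_table()) {
  g4 <- any_site(cohort, site_cols(sites, region = "pons",
                                   laterality = "bilateral"))
  g3 <- any_site(cohort, site_cols(sites, region = "midbrain",
                                   laterality = "bilateral"))
  g2 <- any_site(cohort, site_cols(sites, region = brainstem_regions(),
                                   laterality = "unilateral"))
  g1 <- any_site(cohort, site_cols(sites, region = supratentorial_regions()))
  ifelse(g4, 4L, ifelse(g3, 3L, ifelse(g2, 2L, ifelse(g1, 1L, 0L))))
}

abu_hamdeh_grades <- function(cohort, sites = lesion_site_table()) {
  g4 <- any_site(cohort, site_cols(sites, region = "midbrain",
                                   subregion = "tegmentum",
                                   sequence = "susceptibility"))
  g3 <- any_site(cohort, site_cols(sites, region = brainstem_regions()))
  g2 <- any_site(cohort, site_cols(sites, region = "corpus_callosum"))
  g1 <- any_site(cohort, site_cols(sites, region = hemispheric_regions()))
  ifelse(g4, 4L, ifelse(g3, 3L, ifelse(g2, 2L, ifelse(g1, 1L, 0L))))
}

#' Grade a cohort under one or more TAI grading systems
#'
#' Vectorized application of the rule engines in [grading] to a wide cohort
#' data.frame (0/1 lesion columns named as in [lesion_site_table()]).
#'
#' @param cohort Cohort data.frame; must contain `age` if `abu_hamdeh` is
#'   requested.
#' @param systems Character vector among `"adams"`, `"firsching"`,
#'   `"abu_hamdeh"`, `"stockholm"`, or `"all"`.
#' @return The cohort with one integer grade column per requested system
#'   (`grade_adams`, `grade_firsching`, `grade_abu_hamdeh` plus
#'   `abu_hamdeh_stratum`, `grade_stockholm`).
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 50, seed = 3))
#' graded <- grade_cohort(coh)
#' table(graded$grade_stockholm)
#' @export
grade_cohort <- function(cohort, systems = "all") {
  all_sys <- c("adams", "firsching", "abu_hamdeh", "stockholm")
  if (identical(systems, "all")) systems <- all_sys
  unknown <- setdiff(systems, all_sys)
  if (length(unknown) > 0L) {
    stop("unknown grading system(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sites <- lesion_site_table()
  for (s in systems) {
    cohort[[paste0("grade_", s)]] <- switch(
      s,
      adams = adams_grades(cohort, sites),
      firsching = firsching_grades(cohort, sites),
      abu_hamdeh = abu_hamdeh_grades(cohort, sites),
      stockholm = stockholm_grades(cohort, sites)
    )
  }
  if ("abu_hamdeh" %in% systems) {
    if (is.null(cohort$age)) stop("abu_hamdeh grading requires an age column",
                                  call. = FALSE)
    cohort$abu_hamdeh_stratum <- ifelse(cohort$age < 30, "a", "b")
  }
  cohort
}
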
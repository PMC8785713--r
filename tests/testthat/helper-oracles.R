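# Independent oracles and fixture builders shared across the test files.

# --- Declarative grading-rule oracle -----------------------------------------
# A brute-force interpreter over a rule table, independent of the hand-coded
# engines: a lesion map's grade is the maximum grade over all matching rules
# (most-severe-grade precedence); the floor applies when nothing matches.

supra <- c("basal_ganglia", "corpus_callosum", "internal_capsule_plic",
           "subcortical", "thalamus")
hemis <- c("subcortical", "basal_ganglia", "internal_capsule_plic", "thalamus")

rule_row <- function(system, grade, regions, subregions = "*",
                     lateralities = "*", sequences = "*") {
  data.frame(system = system, grade = grade,
             regions = paste(regions, collapse = ","),
             subregions = paste(subregions, collapse = ","),
             lateralities = paste(lateralities, collapse = ","),
             sequences = paste(sequences, collapse = ","),
             stringsAsFactors = FALSE)
}

grading_rule_table <- rbind(
  rule_row("stockholm", 4, "pons", "*", "bilateral"),
  rule_row("stockholm", 3, "midbrain", "tegmentum"),
  rule_row("stockholm", 3, "thalamus", "*", "bilateral"),
  rule_row("stockholm", 3, "internal_capsule_plic"),
  rule_row("stockholm", 2, "corpus_callosum"),
  rule_row("stockholm", 2, "thalamus", "*", "unilateral"),
  rule_row("stockholm", 2, "pons", "*", "unilateral"),
  rule_row("stockholm", 2, "midbrain",
           c("tectum", "cerebral_peduncles", "unspecified")),
  rule_row("adams", 3, c("midbrain", "pons")),
  rule_row("adams", 2, "corpus_callosum"),
  rule_row("adams", 1, hemis),
  rule_row("firsching", 4, "pons", "*", "bilateral"),
  rule_row("firsching", 3, "midbrain", "*", "bilateral"),
  rule_row("firsching", 2, c("midbrain", "pons"), "*", "unilateral"),
  rule_row("firsching", 1, supra),
  rule_row("abu_hamdeh", 4, "midbrain", "tegmentum", "*", "susceptibility"),
  rule_row("abu_hamdeh", 3, c("midbrain", "pons")),
  rule_row("abu_hamdeh", 2, "corpus_callosum"),
  rule_row("abu_hamdeh", 1, hemis)
)

grade_floor <- c(stockholm = 1L, adams = 0L, firsching = 0L, abu_hamdeh = 0L)

oracle_grade <- function(map, system) {
  rules <- grading_rule_table[grading_rule_table$system == system, ]
  best <- grade_floor[[system]]
  if (nrow(map) == 0L) return(best)
  matches_field <- function(vals, spec) {
    spec == "*" | vals %in% strsplit(spec, ",")[[1]]
  }
  for (r in seq_len(nrow(rules))) {
    hit <- matches_field(map$region, rules$regions[r]) &
      matches_field(map$subregion, rules$subregions[r]) &
      matches_field(map$laterality, rules$lateralities[r]) &
      matches_field(map$sequence, rules$sequences[r])
    if (any(hit)) best <- max(best, rules$grade[r])
  }
  as.integer(best)
}

# Hand-coded engine grades for a single lesion map, as a named vector.
engine_grades <- function(map, age = 40) {
  c(stockholm = grade_stockholm(map)$grade,
    adams = grade_adams(map)$grade,
    firsching = grade_firsching(map)$grade,
    abu_hamdeh = grade_abu_hamdeh(map, age = age)$grade)
}

# Engine grades for many maps at once, through the package's vectorized
# cohort path (one wide 0/1 row per map). Returns a 4 x n_maps matrix.
engine_grades_many <- function(map_indices) {
  sites <- lesion_site_table()
  wide <- matrix(0L, length(map_indices), nrow(sites),
                 dimnames = list(NULL, sites$column))
  for (i in seq_along(map_indices)) wide[i, map_indices[[i]]] <- 1L
  coh <- cbind(data.frame(age = 40), as.data.frame(wide))
  g <- grade_cohort(coh, systems = "all")
  rbind(stockholm = g$grade_stockholm, adams = g$grade_adams,
        firsching = g$grade_firsching, abu_hamdeh = g$grade_abu_hamdeh)
}

oracle_grades <- function(map) {
  vapply(c("stockholm", "adams", "firsching", "abu_hamdeh"),
         function(s) oracle_grade(map, s), integer(1))
}

# All single-site and two-site lesion maps, as row-index sets into the table.
small_map_indices <- function() {
  n <- nrow(lesion_site_table())
  c(lapply(seq_len(n), identity),
    combn(n, 2, simplify = FALSE))
}

site_rows_to_map <- function(idx) {
  lesion_site_table()[idx, , drop = FALSE]
}

random_lesion_map <- function(max_sites = 6L) {
  sites <- lesion_site_table()
  k <- sample.int(max_sites + 1L, 1L) - 1L
  site_rows_to_map(sample.int(nrow(sites), k))
}

# --- Brute-force AUC ----------------------------------------------------------
brute_force_auc <- function(scores, labels) {
  x <- scores[as.logical(labels)]
  y <- scores[!as.logical(labels)]
  total <- 0
  for (xi in x) total <- total + sum(xi > y) + 0.5 * sum(xi == y)
  total / (length(x) * length(y))
}

# --- Fixture cohorts ----------------------------------------------------------
# A minimal wide cohort with the given lesion columns set per patient.
hand_cohort <- function(lesion_lists, unfavorable, age = 40, gcs = 7,
                        pupils = "responsive", rotterdam = 3) {
  n <- length(lesion_lists)
  sites <- lesion_site_table()
  lesions <- matrix(0L, n, nrow(sites), dimnames = list(NULL, sites$column))
  for (i in seq_len(n)) lesions[i, lesion_lists[[i]]] <- 1L
  gos <- ifelse(unfavorable, 3L, 4L)
  cbind(data.frame(patient_id = sprintf("H%02d", seq_len(n)),
                   age = rep_len(age, n), gcs = rep_len(gcs, n),
                   pupils = rep_len(pupils, n),
                   rotterdam = rep_len(rotterdam, n), scan_delay = 7,
                   stringsAsFactors = FALSE),
        as.data.frame(lesions),
        data.frame(gos = gos, unfavorable = unfavorable))
}

# Planted-signal cohort for feature-selection tests: binary features, exactly
# `informative` of them carrying (decreasing) log-odds signal for the outcome.
planted_cohort <- function(n, n_features, informative = 1L, beta_max = 2,
                           seed = 1L) {
  set.seed(seed)
  X <- matrix(rbinom(n * n_features, 1L, 0.3), n, n_features,
              dimnames = list(NULL, paste0("feat", seq_len(n_features))))
  beta <- rep(0, n_features)
  if (informative > 0L) {
    beta[seq_len(informative)] <- beta_max * rev(seq_len(informative)) / informative
  }
  p <- plogis(-0.6 + X %*% beta)
  data.frame(X, unfavorable = runif(n) < p)
}

# Susceptibility-family columns for high-grade sites (used as a fixed,
# clinically sensible TAI feature set in random-forest checks).
susceptibility_features <- function() {
  sites <- lesion_site_table()
  sites$column[sites$sequence == "susceptibility"]
}
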
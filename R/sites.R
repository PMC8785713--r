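#' Lesion-site dictionary for MRI-detected traumatic axonal injury
#'
#' Every TAI observation is a binary indicator at a *site*: the combination of
#' an anatomical region, a subregion (where the region is subdivided), a
#' laterality, and the MRI sequence family on which the lesion was seen.
#' Sequence families are diffusion-weighted imaging (`dwi`), fluid-attenuated
#' inversion recovery (`flair`), and the susceptibility-sensitive family
#' (`susceptibility`, pooling SWI and T2*-weighted gradient echo).
#'
#' The corpus callosum is a midline structure, so its sites carry laterality
#' `not_applicable`. Regions without named subdivisions use subregion
#' `unspecified`.
#'
#' @return A data.frame with one row per valid site and columns `region`,
#'   `subregion`, `laterality`, `sequence`, and `column` (the canonical cohort
#'   CSV column name, `<region>_<subregion>_<laterality>_<sequence>`).
#' @examples
#' sites <- lesion_site_table()
#' nrow(sites)           # 75 valid sites
#' head(sites$column, 3)
#' @export
lesion_site_table <- function() {
  seqs <- c("dwi", "flair", "susceptibility")
  base <- rbind(
    expand.grid(region = "basal_ganglia", subregion = "unspecified",
                laterality = c("unilateral", "bilateral"),
                stringsAsFactors = FALSE),
    expand.grid(region = "corpus_callosum",
                subregion = c("trunk", "splenium", "genu_rostrum"),
                laterality = "not_applicable", stringsAsFactors = FALSE),
    expand.grid(region = "internal_capsule_plic", subregion = "unspecified",
                laterality = c("unilateral", "bilateral"),
                stringsAsFactors = FALSE),
    expand.grid(region = "midbrain",
                subregion = c("tegmentum", "tectum", "cerebral_peduncles",
                              "unspecified"),
                laterality = c("unilateral", "bilateral"),
                stringsAsFactors = FALSE),
    expand.grid(region = "pons", subregion = c("ventral", "dorsal", "unspecified"),
                laterality = c("unilateral", "bilateral"),
                stringsAsFactors = FALSE),
    expand.grid(region = "subcortical", subregion = "unspecified",
                laterality = c("unilateral", "bilateral"),
                stringsAsFactors = FALSE),
    expand.grid(region = "thalamus", subregion = "unspecified",
                laterality = c("unilateral", "bilateral"),
                stringsAsFactors = FALSE)
  )
  out <- merge(base, data.frame(sequence = seqs, stringsAsFactors = FALSE))
  out <- out[order(match(out$region, unique(base$region)), out$subregion,
                   out$laterality, out$sequence), , drop = FALSE]
  out$column <- paste(out$region, out$subregion, out$laterality, out$sequence,
                      sep = "_")
  rownames(out) <- NULL
  out
}

#' Regions counted as supratentorial / hemispheric / brainstem by the graders
#'
#' @name region_groups
#' @keywords internal
supratentorial_regions <- function() {
  c("basal_ganglia", "corpus_callosum", "internal_capsule_plic",
    "subcortical", "thalamus")
}

#' @rdname region_groups
#' @keywords internal
brainstem_regions <- function() c("midbrain", "pons")

#' @rdname region_groups
#' @keywords internal
hemispheric_regions <- function() {
  c("subcortical", "basal_ganglia", "internal_capsule_plic", "thalamus")
}

#' Construct a lesion map
#'
#' A lesion map is the set of TAI sites observed in one patient, represented
#' as a data.frame of site rows. Sites are validated against
#' [lesion_site_table()] and de-duplicated.
#'
#' @param region,subregion,laterality,sequence Character vectors, recycled to
#'   common length, one element per site. `subregion` defaults to
#'   `"unspecified"` and `laterality` to `"not_applicable"` for the corpus
#'   callosum (its only valid value).
#' @return A data.frame of validated unique sites (zero rows for an empty map).
#' @examples
#' lesion_map(region = "pons", laterality = "bilateral", sequence = "flair")
#' lesion_map() # empty map
#' @export
lesion_map <- function(region = character(), subregion = NULL,
                       laterality = NULL, sequence = character()) {
  if (length(region) == 0L) {
    return(lesion_site_table()[0L, , drop = FALSE])
  }
  n <- max(length(region), length(sequence),
           length(subregion %||% character()), length(laterality %||% character()))
  region <- rep_len(region, n)
  sequence <- rep_len(sequence, n)
  subregion <- rep_len(subregion %||% "unspecified", n)
  laterality <- if (is.null(laterality)) {
    ifelse(region == "corpus_callosum", "not_applicable", "unilateral")
  } else {
    rep_len(laterality, n)
  }
  laterality[region == "corpus_callosum"] <- "not_applicable"
  map <- data.frame(region = region, subregion = subregion,
                    laterality = laterality, sequence = sequence,
                    stringsAsFactors = FALSE)
  map$column <- paste(map$region, map$subregion, map$laterality, map$sequence,
                      sep = "_")
  valid <- lesion_site_table()$column
  bad <- setdiff(map$column, valid)
  if (length(bad) > 0L) {
    stop("invalid lesion site(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  map <- map[!duplicated(map$column), , drop = FALSE]
  rownames(map) <- NULL
  map
}

# Extract patient i's lesion map from a wide cohort data.frame.
cohort_lesion_map <- function(cohort, i, sites = lesion_site_table()) {
  cols <- intersect(sites$column, names(cohort))
  present <- cols[as.numeric(cohort[i, cols]) == 1]
  sites[sites$column %in% present, , drop = FALSE]
}
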
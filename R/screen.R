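# Validity screening of smart pump records.
#
# A pump record is usable for linkage only when its hand-keyed patient ID
# maps to a registered patient and a medication was selected from the pump
# drug library (a "basic" infusion leaves the name blank). Screening places
# every record in one of four quadrants (ID +/- x name +/-) and categorizes
# invalid IDs into the nine failure modes.

#' Screen smart pump records for valid patient IDs and medication names
#'
#' @param sprs tibble of pump records with columns `spr_id`, `patient_id`
#'   (the raw string as keyed into the pump) and `medication`.
#' @param registry a [patient_registry()].
#' @param drug_library character vector of medication names available in
#'   the pump drug library.
#' @return A tibble with one row per record: `spr_id`, `id_valid`,
#'   `name_present`, and `invalid_category` (NA when the ID is valid).
#' @export
screen_sprs <- function(sprs, registry, drug_library) {
  stopifnot(inherits(registry, "patient_registry"))
  id_valid <- sprs$patient_id %in% registry$valid_ids
  name_present <- !is.na(sprs$medication) & nzchar(sprs$medication) &
    sprs$medication %in% drug_library
  invalid_category <- rep(NA_character_, nrow(sprs))
  if (any(!id_valid)) {
    invalid_category[!id_valid] <-
      classify_invalid_id(sprs$patient_id[!id_valid], registry)
  }
  tibble::tibble(
    spr_id = sprs$spr_id,
    id_valid = id_valid,
    name_present = name_present,
    invalid_category = invalid_category
  )
}

#' Two-by-two validity quadrant table
#'
#' Tabulates screened pump records by patient-ID validity and medication
#' name presence, with percentages of the grand total.
#'
#' @param results output of [screen_sprs()].
#' @return A tibble with rows `id+name+`, `id-name+`, `id+name-`,
#'   `id-name-`: counts `n` and percentages `pct` (half-up, 2 decimals).
#' @export
quadrant_table <- function(results) {
  if (nrow(results) == 0) {
    stop("`results` must be nonempty", call. = FALSE)
  }
  n <- c(
    sum(results$id_valid & results$name_present),
    sum(!results$id_valid & results$name_present),
    sum(results$id_valid & !results$name_present),
    sum(!results$id_valid & !results$name_present)
  )
  total <- sum(n)
  out <- tibble::tibble(
    quadrant = c("id+name+", "id-name+", "id+name-", "id-name-"),
    n = n,
    pct = round_half_up(100 * n / total, 2)
  )
  attr(out, "total") <- total
  out
}
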
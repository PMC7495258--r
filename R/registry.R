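# Patient registry and the nine-way taxonomy of invalid pump patient IDs.
#
# Clinical staff key patient IDs into infusion pumps by hand, so the raw ID
# strings on pump records fail in recognizable ways: dates of birth typed in
# place of IDs, patient names, encounter numbers, dropped or doubled digits,
# stray letters, IDs retired after chart merges, one-keystroke typos, or
# plain random numbers. The registry carries the reference sets needed to
# tell these apart.

#' Patient registry
#'
#' Reference sets used to validate and categorize raw patient-ID strings
#' found on smart pump records.
#'
#' @param valid_ids character vector of current patient IDs (all the same
#'   width, digits only).
#' @param encounter_ids character vector of encounter (visit) identifiers.
#' @param patient_names character vector of patient name strings as they
#'   could be keyed into a pump.
#' @param expired_ids character vector of retired patient IDs (e.g. after a
#'   chart merge); must be disjoint from `valid_ids`.
#' @return A `patient_registry` object (a list).
#' @export
patient_registry <- function(valid_ids,
                             encounter_ids = character(),
                             patient_names = character(),
                             expired_ids = character()) {
  valid_ids <- as.character(valid_ids)
  if (length(valid_ids) == 0) {
    stop("`valid_ids` must be nonempty", call. = FALSE)
  }
  if (anyDuplicated(valid_ids)) {
    stop("`valid_ids` must be unique", call. = FALSE)
  }
  if (length(intersect(valid_ids, expired_ids)) > 0) {
    stop("`expired_ids` must be disjoint from `valid_ids`", call. = FALSE)
  }
  widths <- unique(nchar(valid_ids))
  if (length(widths) != 1 || !all(grepl("^[0-9]+$", valid_ids))) {
    stop("`valid_ids` must be digit strings of a single common width",
         call. = FALSE)
  }
  structure(
    list(
      valid_ids = valid_ids,
      encounter_ids = as.character(encounter_ids),
      patient_names = as.character(patient_names),
      expired_ids = as.character(expired_ids),
      id_width = widths
    ),
    class = "patient_registry"
  )
}

#' The nine invalid patient-ID categories
#'
#' Failure modes observed when patient IDs are entered into pumps by hand,
#' in classification precedence order (most specific first).
#'
#' @return Character vector of category labels.
#' @export
id_categories <- function() {
  c("patient_name", "encounter_id", "expired_id", "dob_out_of_range",
    "invalid_letters", "missing_digits", "random_number", "extra_digits",
    "typographical")
}

# An 8-digit string parseable as YYYYMMDD or MMDDYYYY whose year falls
# outside the plausible date-of-birth range for the unit's patients.
# Registry IDs are narrower than 8 digits, so the 8-digit restriction keeps
# this category disjoint from the length-based ones.
is_dob_out_of_range <- function(raw, year_range = c(1965, 2014)) {
  if (!grepl("^[0-9]{8}$", raw)) {
    return(FALSE)
  }
  parse_ok <- function(y, m, d) {
    if (m < 1 || m > 12 || d < 1 || d > 31) {
      return(NA_integer_)
    }
    dt <- as.Date(sprintf("%04d-%02d-%02d", y, m, d), format = "%Y-%m-%d")
    if (is.na(dt)) NA_integer_ else y
  }
  y1 <- parse_ok(as.integer(substr(raw, 1, 4)), as.integer(substr(raw, 5, 6)),
                 as.integer(substr(raw, 7, 8)))
  y2 <- parse_ok(as.integer(substr(raw, 5, 8)), as.integer(substr(raw, 1, 2)),
                 as.integer(substr(raw, 3, 4)))
  out_of_range <- function(y) {
    !is.na(y) && (y < year_range[1] || y > year_range[2])
  }
  out_of_range(y1) || out_of_range(y2)
}

# Same-width substitution distance 1 from any valid ID (one wrong keystroke).
is_one_substitution_away <- function(raw, valid_ids, width) {
  if (nchar(raw) != width || !grepl("^[0-9]+$", raw)) {
    return(FALSE)
  }
  cand <- valid_ids[nchar(valid_ids) == width]
  if (length(cand) == 0) {
    return(FALSE)
  }
  raw_chars <- strsplit(raw, "")[[1]]
  for (v in cand) {
    if (sum(raw_chars != strsplit(v, "")[[1]]) == 1) {
      return(TRUE)
    }
  }
  FALSE
}

#' Categorize an invalid patient-ID string
#'
#' Assigns a raw ID string that failed registry validation to exactly one of
#' the nine failure-mode categories (see [id_categories()]). Patterns can
#' overlap, so classification follows a fixed specific-before-generic
#' precedence: empty/missing, patient name, encounter ID, expired ID,
#' out-of-range date of birth, invalid letters, missing digits, extra
#' digits, one-substitution typo, and finally random number.
#'
#' @param raw character vector of raw ID strings not present in the
#'   registry's valid set.
#' @param registry a [patient_registry()].
#' @param dob_year_range plausible birth-year range; dates outside it are
#'   classed as out-of-range dates of birth.
#' @return Character vector of category labels (`"missing"` for empty
#'   strings, otherwise one of [id_categories()]).
#' @export
classify_invalid_id <- function(raw, registry,
                                dob_year_range = c(1965, 2014)) {
  stopifnot(inherits(registry, "patient_registry"))
  vapply(as.character(raw), function(x) {
    if (!is.na(x) && x %in% registry$valid_ids) {
      stop("`raw` contains a valid patient ID: ", x, call. = FALSE)
    }
    if (is.na(x) || !nzchar(x)) {
      return("missing")
    }
    if (x %in% registry$patient_names) {
      return("patient_name")
    }
    if (x %in% registry$encounter_ids) {
      return("encounter_id")
    }
    if (x %in% registry$expired_ids) {
      return("expired_id")
    }
    if (is_dob_out_of_range(x, dob_year_range)) {
      return("dob_out_of_range")
    }
    if (grepl("[^0-9]", x)) {
      return("invalid_letters")
    }
    if (nchar(x) < registry$id_width) {
      return("missing_digits")
    }
    if (nchar(x) > registry$id_width) {
      return("extra_digits")
    }
    if (is_one_substitution_away(x, registry$valid_ids, registry$id_width)) {
      return("typographical")
    }
    "random_number"
  }, character(1), USE.NAMES = FALSE)
}

#' Corrupt a valid patient ID into a given invalid category
#'
#' Produces a corrupted ID string that (a) is not in the registry's valid
#' set and (b) classifies back to the requested category under
#' [classify_invalid_id()]'s precedence. Draws are rejection-sampled so rare
#' pattern collisions (e.g. a digit insertion that happens to form a
#' calendar date) cannot leak across categories.
#'
#' @param valid_id a single valid patient-ID string.
#' @param category one of [id_categories()].
#' @param registry a [patient_registry()].
#' @param max_tries rejection-sampling cap before erroring.
#' @return A single corrupted ID string.
#' @export
corrupt_patient_id <- function(valid_id, category, registry,
                               max_tries = 1000L) {
  stopifnot(inherits(registry, "patient_registry"))
  if (!category %in% id_categories()) {
    stop("unknown invalid-ID category: ", category, call. = FALSE)
  }
  draw <- switch(
    category,
    patient_name = function() {
      if (length(registry$patient_names) == 0) {
        stop("registry has no patient names to draw from", call. = FALSE)
      }
      sample(registry$patient_names, 1)
    },
    encounter_id = function() {
      if (length(registry$encounter_ids) == 0) {
        stop("registry has no encounter IDs to draw from", call. = FALSE)
      }
      sample(registry$encounter_ids, 1)
    },
    expired_id = function() {
      if (length(registry$expired_ids) == 0) {
        stop("registry has no expired IDs to draw from", call. = FALSE)
      }
      sample(registry$expired_ids, 1)
    },
    dob_out_of_range = function() {
      year <- sample(c(1900:1964, 2015:2030), 1)
      month <- sample(1:12, 1)
      day <- sample(1:28, 1)
      if (stats::runif(1) < 0.5) {
        sprintf("%04d%02d%02d", year, month, day)
      } else {
        sprintf("%02d%02d%04d", month, day, year)
      }
    },
    invalid_letters = function() {
      chars <- strsplit(valid_id, "")[[1]]
      k <- sample(1:2, 1)
      pos <- sample(seq_along(chars), k)
      chars[pos] <- sample(LETTERS, k, replace = TRUE)
      paste(chars, collapse = "")
    },
    missing_digits = function() {
      chars <- strsplit(valid_id, "")[[1]]
      k <- sample(1:2, 1)
      keep <- sort(sample(seq_along(chars), length(chars) - k))
      paste(chars[keep], collapse = "")
    },
    random_number = function() {
      paste(sample(0:9, nchar(valid_id), replace = TRUE), collapse = "")
    },
    extra_digits = function() {
      chars <- strsplit(valid_id, "")[[1]]
      k <- sample(1:2, 1)
      for (i in seq_len(k)) {
        pos <- sample(0:length(chars), 1)
        chars <- append(chars, as.character(sample(0:9, 1)), after = pos)
      }
      paste(chars, collapse = "")
    },
    typographical = function() {
      chars <- strsplit(valid_id, "")[[1]]
      pos <- sample(seq_along(chars), 1)
      chars[pos] <- as.character(sample(setdiff(0:9, as.integer(chars[pos])), 1))
      paste(chars, collapse = "")
    }
  )
  for (i in seq_len(max_tries)) {
    out <- draw()
    if (!out %in% registry$valid_ids &&
        identical(classify_invalid_id(out, registry), category)) {
      return(out)
    }
  }
  stop("could not produce a '", category, "' corruption of '", valid_id,
       "' in ", max_tries, " tries", call. = FALSE)
}
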
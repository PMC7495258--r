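# Synthetic paired EHR / smart-pump event streams with a ground-truth
# error ledger.
#
# Institutional pump logs and EHR extracts cannot be shared, so the
# generator emulates their shape: per patient-medication order sequences
# with dose titrations (order events), nurse-documented MAR entries at a
# documentation cadence, pump start/restart records at a faster cadence,
# and injected corruption with a ledger recording every planted error.
# Everything downstream is validated against that ledger.

#' Default study medications
#'
#' The nine high-risk continuous infusions the pipeline targets:
#' vasopressors, narcotics, TPN and lipids.
#'
#' @return Character vector of medication names.
#' @export
default_medications <- function() {
  c("dopamine", "dobutamine", "epinephrine", "milrinone", "vasopressin",
    "fentanyl", "morphine", "TPN", "lipid")
}

# Typical continuous-infusion starting doses/rates, one fixed unit per
# medication (mcg/kg/min for vasopressors, mcg/kg/h for narcotics,
# milliunits/kg/min for vasopressin, mL/h for TPN and lipid). A single
# consistent unit per medication keeps the arithmetic unit-free.
default_dose_baselines <- function() {
  c(dopamine = 5, dobutamine = 5, epinephrine = 0.05, milrinone = 0.5,
    vasopressin = 0.3, fentanyl = 1, morphine = 10, TPN = 10, lipid = 1)
}

# Order mix across medications, shaped like a NICU cohort where lipid, TPN
# and morphine dominate order volume and dobutamine is rare.
default_medication_weights <- function() {
  c(dopamine = 0.008, dobutamine = 0.002, epinephrine = 0.141,
    milrinone = 0.031, vasopressin = 0.021, fentanyl = 0.058,
    morphine = 0.188, TPN = 0.290, lipid = 0.261)
}

# Invalid-ID category mix used when corrupting pump patient IDs, shaped
# like the observed failure-mode distribution (dates of birth and patient
# names most common, typos rare).
default_id_category_weights <- function() {
  c(dob_out_of_range = 42, patient_name = 33, missing_digits = 30,
    random_number = 23, encounter_id = 20, invalid_letters = 13,
    expired_id = 4, extra_digits = 4, typographical = 4)
}

#' Cohort generator configuration
#'
#' Parameters controlling the synthetic cohort's shape: how many patients,
#' which medications with what order mix, how often orders are modified,
#' and the MAR/SPR documentation cadences.
#'
#' @param n_patients number of patients.
#' @param medications medication names (the drug library).
#' @param medication_weights sampling weights over `medications` for order
#'   assignment; defaults to a NICU-like order mix.
#' @param orders_per_patient list with `lambda`: Poisson mean of orders per
#'   patient (floored at one order).
#' @param modifications_per_order list with `lambda`: Poisson mean of dose
#'   modifications per order.
#' @param mar_interval_minutes cadence of MAR documentation within a block.
#' @param spr_interval_minutes cadence of pump start/restart records.
#' @param block_hours length-2 range (hours) of the interval between
#'   consecutive order events.
#' @param study_start,study_end study window bounds (parsed as UTC).
#' @param dose_baselines named per-medication starting dose/rate.
#' @param titration_factors multiplicative dose steps used at
#'   modifications (never 1, so every modification changes the dose).
#' @param seed integer RNG seed; identical seed and settings reproduce the
#'   streams byte for byte.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 60,
                          medications = default_medications(),
                          medication_weights = NULL,
                          orders_per_patient = list(lambda = 2.6),
                          modifications_per_order = list(lambda = 1.5),
                          mar_interval_minutes = 240,
                          spr_interval_minutes = 120,
                          block_hours = c(4, 16),
                          study_start = "2014-01-01 00:00",
                          study_end = "2014-12-31 23:59",
                          dose_baselines = default_dose_baselines(),
                          titration_factors = c(0.8, 1.25, 1.5),
                          seed = 1L) {
  if (length(medications) == 0) {
    stop("`medications` must be nonempty", call. = FALSE)
  }
  if (n_patients < 1) {
    stop("`n_patients` must be positive", call. = FALSE)
  }
  if (mar_interval_minutes <= 0 || spr_interval_minutes <= 0) {
    stop("documentation intervals must be positive", call. = FALSE)
  }
  start <- as_utc_minute(study_start)
  end <- as_utc_minute(study_end)
  if (!(start < end)) {
    stop("study window start must precede end", call. = FALSE)
  }
  if (orders_per_patient$lambda < 0 || modifications_per_order$lambda < 0) {
    stop("distribution means must be nonnegative", call. = FALSE)
  }
  weights <- medication_weights %||%
    default_medication_weights()[medications]
  weights[is.na(weights)] <- mean(weights, na.rm = TRUE)
  baselines <- dose_baselines[medications]
  baselines[is.na(baselines)] <- 1
  names(baselines) <- medications
  structure(
    list(
      n_patients = as.integer(n_patients),
      medications = medications,
      medication_weights = unname(weights / sum(weights)),
      orders_per_patient = orders_per_patient,
      modifications_per_order = modifications_per_order,
      mar_interval_minutes = mar_interval_minutes,
      spr_interval_minutes = spr_interval_minutes,
      block_hours = block_hours,
      study_start = start,
      study_end = end,
      dose_baselines = baselines,
      titration_factors = titration_factors,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Error-injection mixture
#'
#' Probabilities and distributions for every corruption channel the
#' generator can plant: invalid pump patient IDs (nine categories), missing
#' medication names ("basic" infusions), per-block MAR/SPR dose
#' discrepancies (independent or joint), and late order placement (> 30
#' minutes after administration, producing 0% documentation discrepancies).
#'
#' @param p_invalid_id per-SPR probability of corrupting the patient ID.
#' @param invalid_id_category_weights nonnegative weights over
#'   [id_categories()].
#' @param p_missing_med_name per-SPR probability of blanking the
#'   medication name.
#' @param p_mar_discrepancy,p_spr_discrepancy,p_joint_discrepancy per
#'   event-block probabilities of corrupting the block's MAR values, SPR
#'   values, or both with a shared error.
#' @param mod_distribution signed relative-error distribution for injected
#'   discrepancies, as `list(kind = ...)`: `"reporting_bins"` (default; a mixture
#'   over the ten reporting bins excluding 0%), `"degenerate"` (`value`),
#'   `"uniform"` (`min`, `max`) or `"normal"` (`mean`, `sd`), in percent.
#' @param p_late_order per event-block probability of delaying the block's
#'   opening order event past its first administration.
#' @param late_order_delay_minutes length-2 range of the delay; support
#'   must lie strictly above 30 minutes.
#' @return An `error_mixture` list.
#' @export
error_mixture <- function(p_invalid_id = 0,
                          invalid_id_category_weights =
                            default_id_category_weights(),
                          p_missing_med_name = 0,
                          p_mar_discrepancy = 0,
                          p_spr_discrepancy = 0,
                          p_joint_discrepancy = 0,
                          mod_distribution = list(kind = "reporting_bins"),
                          p_late_order = 0,
                          late_order_delay_minutes = c(31, 120)) {
  probs <- c(p_invalid_id, p_missing_med_name, p_mar_discrepancy,
             p_spr_discrepancy, p_joint_discrepancy, p_late_order)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  w <- invalid_id_category_weights[id_categories()]
  if (anyNA(w) || any(w < 0) || sum(w) <= 0) {
    stop("`invalid_id_category_weights` must be nonnegative weights over ",
         "the nine categories", call. = FALSE)
  }
  if (late_order_delay_minutes[1] <= 30) {
    stop("`late_order_delay_minutes` support must exceed 30 minutes",
         call. = FALSE)
  }
  structure(
    list(
      p_invalid_id = p_invalid_id,
      invalid_id_category_weights = w / sum(w),
      p_missing_med_name = p_missing_med_name,
      p_mar_discrepancy = p_mar_discrepancy,
      p_spr_discrepancy = p_spr_discrepancy,
      p_joint_discrepancy = p_joint_discrepancy,
      mod_distribution = mod_distribution,
      p_late_order = p_late_order,
      late_order_delay_minutes = late_order_delay_minutes
    ),
    class = "error_mixture"
  )
}

# Draw a signed magnitude-of-discrepancy (percent) for an injected dose
# error. The "reporting_bins" mixture reproduces the reporting-bin structure of
# observed discrepancies (minor under-/overdoses common, substantial
# overdoses a thick tail); the 0% bin is excluded because exact-dose
# documentation discrepancies arise from the late-order channel instead.
draw_mod <- function(dist) {
  kind <- dist$kind %||% "reporting_bins"
  if (kind == "degenerate") {
    return(dist$value)
  }
  if (kind == "uniform") {
    return(stats::runif(1, dist$min, dist$max))
  }
  if (kind == "normal") {
    for (i in 1:100) {
      m <- stats::rnorm(1, dist$mean, dist$sd)
      if (m > -99) return(m)
    }
    stop("normal mod distribution keeps drawing <= -99%", call. = FALSE)
  }
  if (kind == "reporting_bins") {
    lo <- c(-95, -50, -20, -10, 0, 10, 20, 50, 100)
    hi <- c(-50, -20, -10, 0, 10, 20, 50, 100, 300)
    w <- c(62, 165, 104, 24, 35, 124, 142, 175, 167)
    b <- sample(length(w), 1, prob = w)
    return(stats::runif(1, lo[b], hi[b]))
  }
  stop("unknown mod_distribution kind: ", kind, call. = FALSE)
}

# Registry to accompany a synthetic cohort: one valid 7-digit ID per
# patient, 10-digit encounter IDs, name strings as they might be keyed
# into a pump, and a handful of retired (merged-chart) IDs.
build_registry <- function(n_patients) {
  pool_first <- c("AVERY", "BLAKE", "CAMERON", "DEVON", "ELLIOT", "FINLEY",
                  "HARPER", "JORDAN", "KENDALL", "LOGAN", "MORGAN", "PARKER",
                  "QUINN", "RILEY", "SKYLER", "TAYLOR")
  pool_last <- c("ANDERSON", "BROOKS", "CARTER", "DELGADO", "ELLISON",
                 "FOSTER", "GRIFFIN", "HAYES", "IBARRA", "JENSEN", "KELLER",
                 "LAWSON", "MERCER", "NOLAN", "OKAFOR", "PRESTON")
  n_expired <- max(3L, ceiling(n_patients / 10))
  ids <- as.character(sample(1000000:9999999, n_patients + n_expired))
  patient_registry(
    valid_ids = ids[seq_len(n_patients)],
    encounter_ids = sprintf("5%09.0f", sample(1e9, n_patients) - 1),
    patient_names = paste(sample(pool_last, n_patients, replace = TRUE),
                          sample(pool_first, n_patients, replace = TRUE),
                          sep = ", "),
    expired_ids = ids[n_patients + seq_len(n_expired)]
  )
}

#' Generate a synthetic cohort with a ground-truth error ledger
#'
#' Builds paired EHR and smart-pump event streams: medication orders and
#' their dose-modification events, MAR documentation entries, and pump
#' records (start/restart per programming, one terminal "completed" record
#' per order), then plants errors per `errors` and records every planted
#' error in a ledger. Orders for the same patient and medication are
#' separated by more than 48 hours so timestamp linkage is unambiguous.
#'
#' @param config a [cohort_config()].
#' @param errors an [error_mixture()].
#' @return A `pump_cohort` list with tibbles `orders`, `order_events`,
#'   `mars`, `sprs`, `ledger`, plus the `registry`, `drug_library`, and the
#'   `config`/`errors` used. SPRs carry `true_patient_id` and
#'   `true_order_id` ground-truth columns that the pipeline must not use.
#' @export
generate_cohort <- function(config, errors = error_mixture()) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(errors, "error_mixture"))
  set.seed(config$seed)
  registry <- build_registry(config$n_patients)
  patient_ids <- registry$valid_ids

  window_mins <- mins_between(config$study_start, config$study_end)
  ord_rows <- list(); ev_rows <- list(); mar_rows <- list()
  spr_rows <- list(); led_rows <- list()
  n_ord <- 0L; n_ev <- 0L; n_mar <- 0L; n_spr <- 0L

  for (pid in patient_ids) {
    k_orders <- max(1L, stats::rpois(1, config$orders_per_patient$lambda))
    meds <- sample(config$medications, k_orders, replace = TRUE,
                   prob = config$medication_weights)
    for (med in unique(meds)) {
      k <- sum(meds == med)
      slot <- window_mins / k
      for (j in seq_len(k)) {
        n_mods <- stats::rpois(1, config$modifications_per_order$lambda)
        durs <- round(stats::runif(n_mods + 1, config$block_hours[1],
                                   config$block_hours[2]) * 60)
        # keep the order (plus a 48 h separation) inside its slot
        while (length(durs) > 1 && sum(durs) + 48 * 60 >= slot) {
          durs <- durs[-length(durs)]
        }
        if (sum(durs) + 48 * 60 >= slot) next
        start_off <- (j - 1) * slot +
          stats::runif(1, 0, slot - sum(durs) - 48 * 60)
        t0 <- as_utc_minute(config$study_start + start_off * 60)

        n_blocks <- length(durs)
        bounds <- t0 + c(0, cumsum(durs)) * 60  # n_blocks + 1 boundaries
        factors <- sample(config$titration_factors, n_blocks - 1,
                          replace = TRUE)
        d0 <- config$dose_baselines[[med]] * stats::runif(1, 0.75, 1.5)
        values <- d0 * cumprod(c(1, factors))

        n_ord <- n_ord + 1L
        order_id <- sprintf("O%05d", n_ord)
        ord_rows[[order_id]] <- tibble::tibble(
          order_id = order_id, patient_id = pid, medication = med,
          timestamp = t0, value = d0)

        ev_t <- bounds[seq_len(n_blocks)]
        ev <- tibble::tibble(
          event_id = sprintf("E%06d", n_ev + seq_len(n_blocks)),
          order_id = order_id, patient_id = pid, medication = med,
          timestamp = ev_t,
          kind = c("initiation", rep("modification", n_blocks - 1)),
          value = values)
        n_ev <- n_ev + n_blocks

        # administrations per block, at the configured cadences, stopping
        # 45 min before the block ends so grace windows cannot straddle
        # block boundaries
        first_spr <- TRUE
        for (b in seq_len(n_blocks)) {
          s <- bounds[b]; e <- bounds[b + 1]
          admin_times <- function(first_off, interval) {
            t1 <- s + round(first_off) * 60
            last <- e - 45 * 60
            if (t1 >= last) return(as.POSIXct(character(), tz = "UTC"))
            seq(t1, last, by = interval * 60)
          }
          m_t <- admin_times(stats::runif(1, 5, 25),
                             config$mar_interval_minutes)
          s_t <- admin_times(stats::runif(1, 1, 4),
                             config$spr_interval_minutes)
          mar_rows[[length(mar_rows) + 1L]] <- tibble::tibble(
            mar_id = sprintf("M%06d", n_mar + seq_along(m_t)),
            patient_id = pid, medication = med, timestamp = m_t,
            value = rep(values[b], length(m_t)),
            true_order_id = order_id, true_block_index = b)
          n_mar <- n_mar + length(m_t)
          states <- rep("restarted", length(s_t))
          if (first_spr && length(s_t) > 0) {
            states[1] <- "started"; first_spr <- FALSE
          }
          spr_rows[[length(spr_rows) + 1L]] <- tibble::tibble(
            spr_id = sprintf("S%06d", n_spr + seq_along(s_t)),
            patient_id = pid, medication = med, timestamp = s_t,
            state = states, value = rep(values[b], length(s_t)),
            true_patient_id = pid, true_order_id = order_id,
            true_block_index = b)
          n_spr <- n_spr + length(s_t)
        }
        # terminal pump record when the infusion completes
        n_spr <- n_spr + 1L
        spr_rows[[length(spr_rows) + 1L]] <- tibble::tibble(
          spr_id = sprintf("S%06d", n_spr), patient_id = pid,
          medication = med, timestamp = bounds[n_blocks + 1],
          state = "completed", value = values[n_blocks],
          true_patient_id = pid, true_order_id = order_id,
          true_block_index = NA_integer_)
        ev_rows[[order_id]] <- ev
      }
    }
  }

  orders <- dplyr::bind_rows(ord_rows)
  order_events <- dplyr::bind_rows(ev_rows)
  mars <- dplyr::bind_rows(mar_rows)
  sprs <- dplyr::bind_rows(spr_rows)
  ledger <- empty_ledger()

  # ---- error-injection phase -------------------------------------------
  # All stream-structure randomness is consumed above, so regenerating with
  # an all-zero mixture at the same seed reproduces the base streams
  # exactly; corruption can then be audited by diffing.
  led_rows <- list()
  for (oid in orders$order_id) {
    ev_idx <- which(order_events$order_id == oid)
    for (b in seq_along(ev_idx)) {
      m_idx <- which(mars$true_order_id == oid &
                       mars$true_block_index == b)
      s_idx <- which(sprs$true_order_id == oid &
                       !is.na(sprs$true_block_index) &
                       sprs$true_block_index == b)
      inj <- inject_block_errors(
        mars[m_idx, , drop = FALSE], sprs[s_idx, , drop = FALSE],
        order_events[ev_idx, , drop = FALSE], b,
        order_events$value[ev_idx[b]], oid, errors)
      mars$value[m_idx] <- inj$mars$value
      sprs$value[s_idx] <- inj$sprs$value
      order_events$timestamp[ev_idx] <- inj$events$timestamp
      if (nrow(inj$ledger) > 0) {
        led_rows[[length(led_rows) + 1L]] <- inj$ledger
      }
    }
  }
  if (length(led_rows) > 0) {
    ledger <- dplyr::bind_rows(led_rows)
  }

  orders <- dplyr::arrange(orders, timestamp, order_id)
  order_events <- dplyr::arrange(order_events, timestamp, event_id)
  mars <- dplyr::arrange(mars, timestamp, mar_id)
  sprs <- dplyr::arrange(sprs, timestamp, spr_id)

  # record-level identity corruption on the pump side
  id_led <- list()
  if (nrow(sprs) > 0 && errors$p_invalid_id > 0) {
    hit <- stats::runif(nrow(sprs)) < errors$p_invalid_id
    for (i in which(hit)) {
      cat_i <- sample(id_categories(), 1,
                      prob = errors$invalid_id_category_weights)
      bad <- corrupt_patient_id(sprs$true_patient_id[i], cat_i, registry)
      id_led[[length(id_led) + 1L]] <- ledger_row(
        record_id = sprs$spr_id[i], source = "ID", order_id =
          sprs$true_order_id[i], block_index = NA_integer_,
        category = cat_i, true_value = NA_real_, corrupted_value = NA_real_,
        mod_percent = NA_real_, timestamp = sprs$timestamp[i])
      sprs$patient_id[i] <- bad
    }
  }
  if (nrow(sprs) > 0 && errors$p_missing_med_name > 0) {
    hit <- stats::runif(nrow(sprs)) < errors$p_missing_med_name
    for (i in which(hit)) {
      id_led[[length(id_led) + 1L]] <- ledger_row(
        record_id = sprs$spr_id[i], source = "NAME", order_id =
          sprs$true_order_id[i], block_index = NA_integer_,
        category = NA_character_, true_value = NA_real_,
        corrupted_value = NA_real_, mod_percent = NA_real_,
        timestamp = sprs$timestamp[i])
      sprs$medication[i] <- ""
    }
  }
  if (length(id_led) > 0) {
    ledger <- dplyr::bind_rows(ledger, dplyr::bind_rows(id_led))
  }

  structure(
    list(orders = orders, order_events = order_events, mars = mars,
         sprs = sprs, ledger = ledger, registry = registry,
         drug_library = config$medications, config = config,
         errors = errors),
    class = "pump_cohort"
  )
}

empty_ledger <- function() {
  tibble::tibble(
    record_id = character(), source = character(), order_id = character(),
    block_index = integer(), category = character(), true_value = double(),
    corrupted_value = double(), mod_percent = double(),
    timestamp = as.POSIXct(character(), tz = "UTC"))
}

ledger_row <- function(record_id, source, order_id, block_index, category,
                       true_value, corrupted_value, mod_percent, timestamp) {
  tibble::tibble(record_id = record_id, source = source,
                 order_id = order_id, block_index = as.integer(block_index),
                 category = category, true_value = true_value,
                 corrupted_value = corrupted_value,
                 mod_percent = mod_percent, timestamp = timestamp)
}

# Per-block error injection. Channels are exclusive within a block: a block
# either has its opening order event delayed (late-order channel) or has
# dose values corrupted (MAR / SPR / joint channels). The ledger stores the
# magnitude exactly as the detector computes it, (corrupted - prescribed) /
# prescribed * 100, so recovery can be asserted to machine precision.
inject_block_errors <- function(mar_b, spr_b, ev, block_index, prescribed,
                                order_id, errors) {
  led <- list()
  started <- spr_b$state %in% c("started", "restarted")
  n_admin <- nrow(mar_b) + sum(started)

  u_late <- stats::runif(1)
  if (u_late < errors$p_late_order && n_admin > 0) {
    admin_t <- sort(c(mar_b$timestamp, spr_b$timestamp[started]))
    delay <- round(stats::runif(1, errors$late_order_delay_minutes[1],
                                errors$late_order_delay_minutes[2]))
    delay <- max(delay, 31)
    new_t <- admin_t[1] + delay * 60
    block_end <- if (block_index < nrow(ev)) {
      ev$timestamp[block_index + 1]
    } else {
      admin_t[length(admin_t)] + 3600
    }
    if (new_t < block_end - 60) {
      ev$timestamp[block_index] <- new_t
      late_entry <- function(id, src, t, v) {
        ledger_row(record_id = id, source = "LATE_ORDER",
                   order_id = order_id, block_index = block_index,
                   category = src, true_value = v, corrupted_value = v,
                   mod_percent = 0, timestamp = t)
      }
      for (i in seq_len(nrow(mar_b))) {
        if (mins_between(mar_b$timestamp[i], new_t) > 30) {
          led[[length(led) + 1L]] <- late_entry(
            mar_b$mar_id[i], "MAR", mar_b$timestamp[i], mar_b$value[i])
        }
      }
      for (i in which(started)) {
        if (mins_between(spr_b$timestamp[i], new_t) > 30) {
          led[[length(led) + 1L]] <- late_entry(
            spr_b$spr_id[i], "SPR", spr_b$timestamp[i], spr_b$value[i])
        }
      }
      return(list(mars = mar_b, sprs = spr_b, events = ev,
                  ledger = bind_ledger(led)))
    }
  }

  u_joint <- stats::runif(1)
  u_mar <- stats::runif(1)
  u_spr <- stats::runif(1)
  corrupt_stream <- function(df, ids, src, mod) {
    bad <- prescribed * (1 + mod / 100)
    rows <- lapply(seq_along(ids), function(i) {
      ledger_row(record_id = ids[i], source = src, order_id = order_id,
                 block_index = block_index, category = NA_character_,
                 true_value = prescribed, corrupted_value = bad,
                 mod_percent = (bad - prescribed) / prescribed * 100,
                 timestamp = df$timestamp[i])
    })
    list(value = bad, rows = rows)
  }
  if (u_joint < errors$p_joint_discrepancy &&
      (nrow(mar_b) > 0 || any(started))) {
    mod <- draw_mod(errors$mod_distribution)
    if (nrow(mar_b) > 0) {
      cm <- corrupt_stream(mar_b, mar_b$mar_id, "MAR", mod)
      mar_b$value <- cm$value; led <- c(led, cm$rows)
    }
    if (any(started)) {
      cs <- corrupt_stream(spr_b[started, ], spr_b$spr_id[started],
                           "SPR", mod)
      spr_b$value[started] <- cs$value; led <- c(led, cs$rows)
    }
  } else {
    if (u_mar < errors$p_mar_discrepancy && nrow(mar_b) > 0) {
      cm <- corrupt_stream(mar_b, mar_b$mar_id, "MAR",
                           draw_mod(errors$mod_distribution))
      mar_b$value <- cm$value; led <- c(led, cm$rows)
    }
    if (u_spr < errors$p_spr_discrepancy && any(started)) {
      cs <- corrupt_stream(spr_b[started, ], spr_b$spr_id[started], "SPR",
                           draw_mod(errors$mod_distribution))
      spr_b$value[started] <- cs$value; led <- c(led, cs$rows)
    }
  }
  list(mars = mar_b, sprs = spr_b, events = ev, ledger = bind_ledger(led))
}

bind_ledger <- function(led) {
  if (length(led) == 0) empty_ledger() else dplyr::bind_rows(led)
}
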
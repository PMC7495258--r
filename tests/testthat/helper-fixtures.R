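# Shared fixture builders: tiny registries, hand-laid timelines and groups.

ts <- function(x) as.POSIXct(x, tz = "UTC")

tiny_registry <- function() {
  patient_registry(
    valid_ids = c("1234567", "7654321", "1111111"),
    encounter_ids = c("5000000001", "5000000002"),
    patient_names = c("CARTER, QUINN", "HAYES, MORGAN"),
    expired_ids = c("9999999", "8888888")
  )
}

# A timeline tibble in build_timeline() layout, from compact event /
# administration shorthand tables. `events`: data.frame(t, value[, order_id, kind]);
# `mars` / `sprs`: data.frame(t, value[, state, linked]).
fixture_timeline <- function(events, mars = NULL, sprs = NULL,
                             patient = "1234567", med = "TPN") {
  n_ev <- nrow(events)
  rows <- tibble::tibble(
    record_id = paste0("E", seq_len(n_ev)),
    kind = "order_event",
    timestamp = ts(events$t),
    value = events$value,
    order_id = if ("order_id" %in% names(events)) events$order_id else "O1",
    event_kind = if ("kind" %in% names(events)) events$kind else
      c("initiation", rep("modification", n_ev - 1)),
    state = NA_character_,
    linked_order_id = NA_character_
  )
  if (!is.null(mars)) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      record_id = paste0("M", seq_len(nrow(mars))),
      kind = "mar", timestamp = ts(mars$t), value = mars$value,
      order_id = NA_character_, event_kind = NA_character_,
      state = NA_character_, linked_order_id = NA_character_))
  }
  if (!is.null(sprs)) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      record_id = paste0("S", seq_len(nrow(sprs))),
      kind = "spr", timestamp = ts(sprs$t), value = sprs$value,
      order_id = NA_character_, event_kind = NA_character_,
      state = if ("state" %in% names(sprs)) sprs$state else "started",
      linked_order_id = if ("linked" %in% names(sprs)) sprs$linked else "O1"))
  }
  rank <- match(rows$kind, c("order_event", "mar", "spr"))
  rows <- rows[order(rows$timestamp, rank), , drop = FALSE]
  rows$patient_id <- patient
  rows$medication <- med
  rows
}

# One row of group_records() output from explicit component tables.
fixture_group <- function(orders, order_events, mars = NULL, sprs = NULL) {
  empty_mar <- tibble::tibble(
    mar_id = character(), patient_id = character(), medication = character(),
    timestamp = ts(character()), value = double())
  empty_spr <- tibble::tibble(
    spr_id = character(), patient_id = character(), medication = character(),
    timestamp = ts(character()), state = character(), value = double())
  any_orders <- nrow(orders) > 0
  tibble::tibble(
    patient_id = orders$patient_id[1],
    medication = orders$medication[1],
    orders = list(orders),
    order_events = list(order_events),
    mars = list(mars %||% empty_mar),
    sprs = list(sprs %||% empty_spr),
    has_orders = any_orders
  )
}

fixture_orders <- function(order_id, t, value,
                           patient = "1234567", med = "TPN") {
  tibble::tibble(order_id = order_id, patient_id = patient,
                 medication = med, timestamp = ts(t), value = value)
}

fixture_events <- function(order_id, t, value, kind = NULL,
                           patient = "1234567", med = "TPN") {
  tibble::tibble(
    event_id = paste0("E", seq_along(t)), order_id = order_id,
    patient_id = patient, medication = med, timestamp = ts(t),
    kind = kind %||% rep("modification", length(t)), value = value)
}

fixture_mars <- function(t, value, patient = "1234567", med = "TPN") {
  tibble::tibble(mar_id = paste0("M", seq_along(t)), patient_id = patient,
                 medication = med, timestamp = ts(t), value = value)
}

fixture_sprs <- function(t, value, state = "started",
                         patient = "1234567", med = "TPN") {
  tibble::tibble(spr_id = paste0("S", seq_along(t)), patient_id = patient,
                 medication = med, timestamp = ts(t),
                 state = rep_len(state, length(t)), value = value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Expansion-based Cohen-kappa oracle: materialize the per-block MAR/SPR
# discrepancy labels and compute observed and chance agreement from the
# expanded vectors. Independent of the package's closed-form path.
kappa_oracle <- function(a, b, c, d) {
  m <- rep(c(1L, 1L, 0L, 0L), c(a, b, c, d))
  s <- rep(c(1L, 0L, 1L, 0L), c(a, b, c, d))
  po <- mean(m == s)
  pm <- mean(m); ps <- mean(s)
  pe <- pm * ps + (1 - pm) * (1 - ps)
  if (1 - pe < 8 * .Machine$double.eps) return(NA_real_)
  (po - pe) / (1 - pe)
}
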
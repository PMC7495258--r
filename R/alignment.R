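# Timestamp-based alignment of pump records to medication orders.
#
# Pump records are not keyed to orders, so linkage goes: keep only
# start/restart records (the moment of programmed delivery), group all
# streams by (patient, medication), then link each pump record to the
# closest order showing activity (order placement, modification, or MAR
# documentation) within 24 hours. The merged per-group sequence is the
# timeline that downstream detection and segmentation operate on.

#' Pump states
#'
#' @return Character vector of recognized pump-record states. The
#'   `started` / `restarted` pair marks initiation of medication delivery.
#' @export
spr_states <- function() {
  c("started", "restarted", "stopped", "completed", "paused", "canceled",
    "delayed")
}

#' Keep only infusion started/restarted pump records
#'
#' Delivery-initiation records are the point at which an erroneous infusion
#' could be intercepted; all other pump states are dropped. Input order is
#' preserved.
#'
#' @param sprs tibble of pump records with a `state` column.
#' @return The subset with `state` in `started`/`restarted`.
#' @export
filter_started <- function(sprs) {
  bad <- setdiff(unique(sprs$state), spr_states())
  if (length(bad) > 0) {
    stop("unrecognized pump state(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sprs[sprs$state %in% c("started", "restarted"), , drop = FALSE]
}

#' Group the four streams by patient and medication
#'
#' Every record lands in exactly one (patient, medication) group; order
#' events travel with their orders. Groups holding pump records but no
#' orders are flagged (`has_orders = FALSE`): their records cannot be
#' linked and are reported separately.
#'
#' @param orders,order_events,mars,sprs the four streams; `sprs` should
#'   already be validity-screened (invalid records excluded).
#' @return A tibble with one row per group: `patient_id`, `medication`,
#'   list-columns `orders`, `order_events`, `mars`, `sprs`, and
#'   `has_orders`.
#' @export
group_records <- function(orders, order_events, mars, sprs) {
  keys <- dplyr::distinct(dplyr::bind_rows(
    orders[c("patient_id", "medication")],
    mars[c("patient_id", "medication")],
    sprs[c("patient_id", "medication")]
  ))
  keys <- dplyr::arrange(keys, patient_id, medication)
  ev <- dplyr::left_join(order_events,
                         orders[c("order_id", "patient_id", "medication")],
                         by = c("order_id", "patient_id", "medication"))
  pick <- function(df, pid, med) {
    df[df$patient_id == pid & df$medication == med, , drop = FALSE]
  }
  keys$orders <- purrr::map2(keys$patient_id, keys$medication,
                             function(p, m) pick(orders, p, m))
  keys$order_events <- purrr::map2(keys$patient_id, keys$medication,
                                   function(p, m) pick(ev, p, m))
  keys$mars <- purrr::map2(keys$patient_id, keys$medication,
                           function(p, m) pick(mars, p, m))
  keys$sprs <- purrr::map2(keys$patient_id, keys$medication,
                           function(p, m) pick(sprs, p, m))
  keys$has_orders <- purrr::map_int(keys$orders, nrow) > 0
  keys
}

# Attribute MARs to the order active at documentation time (latest order
# initiated at or before the MAR). MARs carry no order key of their own;
# under the generator's >48 h same-patient-medication order separation this
# attribution is exact.
attribute_mars <- function(orders, mars) {
  if (nrow(mars) == 0 || nrow(orders) == 0) {
    return(rep(NA_character_, nrow(mars)))
  }
  o <- dplyr::arrange(orders, timestamp, order_id)
  idx <- findInterval(as.numeric(mars$timestamp), as.numeric(o$timestamp))
  out <- rep(NA_character_, nrow(mars))
  out[idx > 0] <- o$order_id[idx[idx > 0]]
  out
}

#' Link one pump record to its most plausible order
#'
#' Candidate orders are those in the record's (patient, medication) group
#' with at least one activity event -- order placement, modification,
#' free-text communication, or MAR documentation -- within
#' `window_hours` of the pump record's timestamp (symmetric window). Among
#' candidates the order with the smallest activity gap wins; ties break to
#' the earlier-initiated order, then lexicographic `order_id`.
#'
#' @param spr_time POSIXct timestamp of the pump record.
#' @param orders,order_events,mars the group's streams.
#' @param window_hours linkage window (default 24).
#' @return An `order_id`, or `NA` if no order qualifies.
#' @export
align_spr_to_order <- function(spr_time, orders, order_events, mars,
                               window_hours = 24) {
  if (nrow(orders) == 0) {
    return(NA_character_)
  }
  mar_order <- attribute_mars(orders, mars)
  gap <- vapply(seq_len(nrow(orders)), function(i) {
    oid <- orders$order_id[i]
    act <- c(order_events$timestamp[order_events$order_id == oid],
             mars$timestamp[!is.na(mar_order) & mar_order == oid])
    if (length(act) == 0) {
      return(Inf)
    }
    min(abs(mins_between(act, spr_time)))
  }, numeric(1))
  ok <- gap <= window_hours * 60
  if (!any(ok)) {
    return(NA_character_)
  }
  cand <- which(ok)
  cand <- cand[order(gap[cand], orders$timestamp[cand],
                     orders$order_id[cand])]
  orders$order_id[cand[1]]
}

#' Link all of a group's pump records
#'
#' @param group one row of [group_records()] output (a list or one-row
#'   tibble with `orders`, `order_events`, `mars`, `sprs`).
#' @param window_hours linkage window (default 24).
#' @return A tibble `spr_id`, `order_id` (`NA` where unlinkable).
#' @export
align_sprs <- function(group, window_hours = 24) {
  sprs <- group$sprs[[1]]
  if (nrow(sprs) == 0) {
    return(tibble::tibble(spr_id = character(), order_id = character()))
  }
  tibble::tibble(
    spr_id = sprs$spr_id,
    order_id = vapply(seq_len(nrow(sprs)), function(i) {
      align_spr_to_order(sprs$timestamp[i], group$orders[[1]],
                         group$order_events[[1]], group$mars[[1]],
                         window_hours)
    }, character(1))
  )
}

#' Build the merged chronological timeline of a group
#'
#' Merges order events, MARs, and linked pump records into one sequence
#' sorted by timestamp. At equal timestamps order events sort before MARs,
#' which sort before pump records, so a simultaneous order modification
#' legitimizes the administrations documented at the same minute.
#'
#' @param group one row of [group_records()] output.
#' @param links tibble from [align_sprs()].
#' @return A tibble timeline: `record_id`, `kind` (`order_event` / `mar` /
#'   `spr`), `timestamp`, `value`, `order_id` (owning order for events),
#'   `event_kind`, `state`, `linked_order_id`, plus `patient_id` and
#'   `medication`.
#' @export
build_timeline <- function(group, links) {
  ev <- group$order_events[[1]]
  mars <- group$mars[[1]]
  sprs <- group$sprs[[1]]
  rows <- dplyr::bind_rows(
    tibble::tibble(
      record_id = ev$event_id, kind = "order_event", timestamp = ev$timestamp,
      value = ev$value, order_id = ev$order_id, event_kind = ev$kind,
      state = NA_character_, linked_order_id = NA_character_),
    tibble::tibble(
      record_id = mars$mar_id, kind = "mar", timestamp = mars$timestamp,
      value = mars$value, order_id = NA_character_,
      event_kind = NA_character_, state = NA_character_,
      linked_order_id = NA_character_),
    tibble::tibble(
      record_id = sprs$spr_id, kind = "spr", timestamp = sprs$timestamp,
      value = sprs$value, order_id = NA_character_,
      event_kind = NA_character_, state = sprs$state,
      linked_order_id = links$order_id[match(sprs$spr_id, links$spr_id)])
  )
  rank <- match(rows$kind, c("order_event", "mar", "spr"))
  rows <- rows[order(rows$timestamp, rank), , drop = FALSE]
  rows$patient_id <- group$patient_id[[1]]
  rows$medication <- group$medication[[1]]
  rows
}
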
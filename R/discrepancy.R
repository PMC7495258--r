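# Rule-based discrepancy detection with a 30-minute verbal-order grace
# window, and magnitude-of-discrepancy (MoD) arithmetic.
#
# A discrepancy is a mismatch between the prescribed dose/rate in force at
# administration time and the dose/rate documented (MAR) or programmed
# (pump). A matching order arriving within 30 minutes after the
# administration legitimizes it (verbal order being transcribed); a
# matching order arriving later than that leaves a documentation
# discrepancy with MoD = 0%.

#' Prescribed dose/rate in force at a time point
#'
#' Returns the value of the latest dose-bearing order event at or before
#' `t`. If no order event precedes `t`, the earliest order event within the
#' grace window after `t` is returned with `via_grace = TRUE`.
#'
#' @param timeline a [build_timeline()] tibble.
#' @param t POSIXct time point.
#' @param grace_minutes grace window (default 30).
#' @return `list(value, via_grace)`, or `NULL` if no order event is in
#'   force at or within grace of `t`.
#' @export
prescribed_value_at <- function(timeline, t, grace_minutes = 30) {
  ev <- timeline[timeline$kind == "order_event" & !is.na(timeline$value), ,
                 drop = FALSE]
  if (nrow(ev) == 0) {
    return(NULL)
  }
  idx <- findInterval(as.numeric(t), as.numeric(ev$timestamp))
  if (idx >= 1) {
    return(list(value = ev$value[idx], via_grace = FALSE))
  }
  lead <- mins_between(t, ev$timestamp)
  ahead <- which(lead > 0 & lead <= grace_minutes)
  if (length(ahead) > 0) {
    return(list(value = ev$value[ahead[1]], via_grace = TRUE))
  }
  NULL
}

#' Magnitude of discrepancy
#'
#' Signed percentage of the administered-minus-prescribed difference over
#' the prescribed dose or rate; positive values are overdoses.
#'
#' @param administered,prescribed numeric dose/rate values;
#'   `prescribed` must be positive.
#' @return `(administered - prescribed) / prescribed * 100`.
#' @export
magnitude_of_discrepancy <- function(administered, prescribed) {
  if (any(prescribed <= 0)) {
    stop("`prescribed` must be positive", call. = FALSE)
  }
  (administered - prescribed) / prescribed * 100
}

#' Magnitude-of-discrepancy bin labels
#'
#' @return The ten bin labels, in increasing order. The intervals partition
#'   the real line: four negative bins, the exact-0% bin (documentation
#'   discrepancies), and five positive bins whose top bin (> 100%) holds
#'   substantial overdoses.
#' @export
mod_bin_levels <- function() {
  c("<-50%", "[-50%,-20%)", "[-20%,-10%)", "[-10%,0%)", "0%",
    "(0%,10%]", "(10%,20%]", "(20%,50%]", "(50%,100%]", ">100%")
}

#' Bin a magnitude of discrepancy
#'
#' @param mod numeric vector of MoD percentages (finite).
#' @return Factor over [mod_bin_levels()]; each value lands in exactly one
#'   bin (note -50 falls in `[-50%,-20%)` and +10 in `(0%,10%]`).
#' @export
bin_mod <- function(mod) {
  if (any(!is.finite(mod))) {
    stop("`mod` must be finite", call. = FALSE)
  }
  lab <- ifelse(mod < -50, "<-50%",
         ifelse(mod < -20, "[-50%,-20%)",
         ifelse(mod < -10, "[-20%,-10%)",
         ifelse(mod < 0, "[-10%,0%)",
         ifelse(mod == 0, "0%",
         ifelse(mod <= 10, "(0%,10%]",
         ifelse(mod <= 20, "(10%,20%]",
         ifelse(mod <= 50, "(20%,50%]",
         ifelse(mod <= 100, "(50%,100%]", ">100%")))))))))
  factor(lab, levels = mod_bin_levels())
}

#' Discrepancy rate
#'
#' @param n_discrepant,n_records counts; `n_records` must be positive.
#' @return `100 * n_discrepant / n_records`, half-up to one decimal.
#' @export
discrepancy_rate <- function(n_discrepant, n_records) {
  if (any(n_records <= 0)) {
    stop("`n_records` must be positive", call. = FALSE)
  }
  round_half_up(100 * n_discrepant / n_records, 1)
}

#' Overdose summary from binned discrepancies
#'
#' @param bin_counts numeric vector of counts named by
#'   [mod_bin_levels()] (one source).
#' @return A one-row tibble: `total`, `n_overdose`, `overdose_pct`,
#'   `n_substantial`, `substantial_pct`. Overdoses are the five positive
#'   bins; substantial overdoses exceed +100%. Shares are `NA` (undefined),
#'   not 0, when their denominator is zero.
#' @export
overdose_summary <- function(bin_counts) {
  stopifnot(all(mod_bin_levels() %in% names(bin_counts)))
  total <- sum(bin_counts[mod_bin_levels()])
  pos <- c("(0%,10%]", "(10%,20%]", "(20%,50%]", "(50%,100%]", ">100%")
  n_over <- sum(bin_counts[pos])
  n_sub <- unname(bin_counts[">100%"])
  tibble::tibble(
    total = total,
    n_overdose = n_over,
    overdose_pct = if (total > 0) 100 * n_over / total else NA_real_,
    n_substantial = n_sub,
    substantial_pct = if (n_over > 0) 100 * n_sub / n_over else NA_real_
  )
}

#' Detect MAR and SPR discrepancies on a timeline
#'
#' Evaluates every MAR and every linked started/restarted pump record
#' against the prescribed dose/rate in force at its timestamp. A record is
#' discrepant when its value differs from the active prescription (relative
#' tolerance `tol`) and no value-matching order event arrives within the
#' grace window. A record whose value is matched only by an order event
#' arriving later than the grace window (but within `horizon_hours`) is a
#' documentation discrepancy: MoD = 0 against that late order. Records
#' preceding every order event with no grace match are flagged
#' (`preceded_orders`) and referenced against the first order value.
#'
#' Pump records never linked to an order are excluded from evaluation and
#' counted in the `n_unlinked_sprs` attribute.
#'
#' @param timeline a [build_timeline()] tibble.
#' @param grace_minutes verbal-order grace window (default 30).
#' @param tol relative dose-equality tolerance (default 1e-6;
#'   machine-entered values, not measurements).
#' @param horizon_hours how far ahead a late matching order is sought
#'   (default 24, the linkage window).
#' @return Tibble of discrepancies: `record_id`, `source` (`MAR`/`SPR`),
#'   `timestamp`, `administered`, `reference`, `mod_percent`, `mod_bin`,
#'   `documentation_only`, `preceded_orders`. Attributes `n_evaluated` and
#'   `n_unlinked_sprs` carry the denominators.
#' @export
detect_discrepancies <- function(timeline, grace_minutes = 30, tol = 1e-6,
                                 horizon_hours = 24) {
  ev <- timeline[timeline$kind == "order_event" & !is.na(timeline$value), ,
                 drop = FALSE]
  is_mar <- timeline$kind == "mar"
  is_spr_started <- timeline$kind == "spr" &
    timeline$state %in% c("started", "restarted")
  is_linked <- is_spr_started & !is.na(timeline$linked_order_id)
  adm <- timeline[is_mar | is_linked, , drop = FALSE]
  n_unlinked <- sum(is_spr_started & is.na(timeline$linked_order_id))

  out <- list()
  if (nrow(adm) > 0 && nrow(ev) > 0) {
    ev_num <- as.numeric(ev$timestamp)
    active_idx <- findInterval(as.numeric(adm$timestamp), ev_num)
    for (i in seq_len(nrow(adm))) {
      v <- adm$value[i]
      t <- adm$timestamp[i]
      active <- if (active_idx[i] >= 1) ev$value[active_idx[i]] else NA_real_
      if (!is.na(active) && rel_eq(v, active, tol)) {
        next
      }
      # first value-matching order event after t, within the horizon
      ahead <- which(ev_num > as.numeric(t) &
                       ev_num <= as.numeric(t) + horizon_hours * 3600)
      match_i <- ahead[rel_eq(ev$value[ahead], v, tol)]
      if (length(match_i) > 0) {
        lead <- mins_between(t, ev$timestamp[match_i[1]])
        if (lead <= grace_minutes) {
          next  # legitimized: verbal order transcribed within grace
        }
        out[[length(out) + 1L]] <- tibble::tibble(
          record_id = adm$record_id[i],
          source = if (adm$kind[i] == "mar") "MAR" else "SPR",
          timestamp = t, administered = v, reference = v, mod_percent = 0,
          documentation_only = TRUE, preceded_orders = is.na(active))
      } else {
        ref <- if (!is.na(active)) active else ev$value[1]
        out[[length(out) + 1L]] <- tibble::tibble(
          record_id = adm$record_id[i],
          source = if (adm$kind[i] == "mar") "MAR" else "SPR",
          timestamp = t, administered = v, reference = ref,
          mod_percent = magnitude_of_discrepancy(v, ref),
          documentation_only = FALSE, preceded_orders = is.na(active))
      }
    }
  }
  res <- if (length(out) > 0) {
    dplyr::bind_rows(out)
  } else {
    tibble::tibble(
      record_id = character(), source = character(),
      timestamp = as.POSIXct(character(), tz = "UTC"),
      administered = double(), reference = double(), mod_percent = double(),
      documentation_only = logical(), preceded_orders = logical())
  }
  res$mod_bin <- if (nrow(res) > 0) bin_mod(res$mod_percent) else
    factor(character(), levels = mod_bin_levels())
  attr(res, "n_evaluated") <- nrow(adm)
  attr(res, "n_evaluated_mar") <- sum(adm$kind == "mar")
  attr(res, "n_evaluated_spr") <- sum(adm$kind == "spr")
  attr(res, "n_unlinked_sprs") <- n_unlinked
  res
}
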
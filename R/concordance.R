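# Event-block segmentation and MAR/SPR concordance assessment.
#
# Each order sequence is cut into event blocks at order initiations,
# modifications, and audits. A block is classified by which sources show
# discrepancies among its member administrations (none / MAR-only /
# SPR-only / both), and Cohen's kappa over the block-level 2x2 agreement
# table measures how far EHR documentation and pump logs flag the same
# problems.

#' Segment a timeline into event blocks
#'
#' Block boundaries are the timeline's dose-bearing order events
#' (initiations, modifications, audits; free-text communications set no
#' boundary). Each block spans one inter-event interval -- the tail block
#' runs to the end of the sequence -- and is attributed to the order owning
#' its opening event. Intervals with no member administration emit no
#' block, because block categories are defined by member discrepancies.
#' Administrations preceding every boundary belong to no block.
#'
#' @param timeline a [build_timeline()] tibble.
#' @return A tibble of blocks: `order_id`, `block_index` (per order, over
#'   emitted blocks), `patient_id`, `medication`, `start`, `end`, counts
#'   `n_mar` / `n_spr`, and list-columns `mar_ids`, `spr_ids`.
#' @export
segment_event_blocks <- function(timeline) {
  bnd <- timeline[timeline$kind == "order_event" &
                    !timeline$event_kind %in% "communication", ,
                  drop = FALSE]
  empty <- tibble::tibble(
    order_id = character(), block_index = integer(),
    patient_id = character(), medication = character(),
    start = as.POSIXct(character(), tz = "UTC"),
    end = as.POSIXct(character(), tz = "UTC"),
    n_mar = integer(), n_spr = integer(),
    mar_ids = list(), spr_ids = list())
  if (nrow(bnd) == 0) {
    return(empty)
  }
  is_adm <- timeline$kind == "mar" |
    (timeline$kind == "spr" &
       timeline$state %in% c("started", "restarted") &
       !is.na(timeline$linked_order_id))
  adm <- timeline[is_adm, , drop = FALSE]
  if (nrow(adm) == 0) {
    return(empty)
  }
  blk <- findInterval(as.numeric(adm$timestamp), as.numeric(bnd$timestamp))
  rows <- lapply(sort(unique(blk[blk > 0])), function(b) {
    members <- adm[blk == b, , drop = FALSE]
    tibble::tibble(
      order_id = bnd$order_id[b],
      block_index = NA_integer_,
      patient_id = members$patient_id[1],
      medication = members$medication[1],
      start = bnd$timestamp[b],
      end = if (b < nrow(bnd)) bnd$timestamp[b + 1] else
        as.POSIXct(NA, tz = "UTC"),
      n_mar = sum(members$kind == "mar"),
      n_spr = sum(members$kind == "spr"),
      mar_ids = list(members$record_id[members$kind == "mar"]),
      spr_ids = list(members$record_id[members$kind == "spr"]))
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, order_id, start)
  out$block_index <- stats::ave(seq_len(nrow(out)), out$order_id,
                                FUN = seq_along)
  out
}

#' Classify event blocks by discrepancy sources
#'
#' @param blocks output of [segment_event_blocks()] (possibly several
#'   timelines row-bound).
#' @param discrepancies output of [detect_discrepancies()] (row-bound).
#' @return `blocks` with a `category` factor (`none`, `MAR_only`,
#'   `SPR_only`, `both`) and discrepancy counts `n_mar_disc`, `n_spr_disc`.
#' @export
classify_blocks <- function(blocks, discrepancies) {
  mar_disc <- discrepancies$record_id[discrepancies$source == "MAR"]
  spr_disc <- discrepancies$record_id[discrepancies$source == "SPR"]
  blocks$n_mar_disc <- purrr::map_int(blocks$mar_ids,
                                      function(x) sum(x %in% mar_disc))
  blocks$n_spr_disc <- purrr::map_int(blocks$spr_ids,
                                      function(x) sum(x %in% spr_disc))
  has_m <- blocks$n_mar_disc > 0
  has_s <- blocks$n_spr_disc > 0
  blocks$category <- factor(
    ifelse(has_m & has_s, "both",
    ifelse(has_m, "MAR_only",
    ifelse(has_s, "SPR_only", "none"))),
    levels = c("none", "MAR_only", "SPR_only", "both"))
  blocks
}

#' Orders eligible for the concordance analysis
#'
#' An order enters the concordance analysis only if both sources document
#' it: at least one MAR and at least one linked pump record among its
#' blocks.
#'
#' @param blocks output of [segment_event_blocks()].
#' @return Tibble `order_id`, `included`.
#' @export
include_order <- function(blocks) {
  dplyr::summarise(dplyr::group_by(blocks, order_id),
                   included = sum(n_mar) > 0 && sum(n_spr) > 0,
                   .groups = "drop")
}

#' Cohen's kappa from block-level 2x2 agreement counts
#'
#' Treats the MAR and SPR discrepancy indicators as two raters of each
#' block and computes chance-corrected agreement,
#' kappa = (po - pe) / (1 - pe), with observed agreement
#' po = (both + none) / N and expected agreement pe from the 2x2 marginal
#' products.
#'
#' @param counts numeric length-4 vector `(both, MAR_only, SPR_only,
#'   none)`; names `both` / `mar_only` / `spr_only` / `none` are honored if
#'   present.
#' @return Kappa (full precision). Degenerate marginals (pe = 1) yield
#'   `NA` with a `"degenerate"` attribute, signalling that agreement is
#'   undefined rather than perfect.
#' @export
cohen_kappa <- function(counts) {
  if (!is.null(names(counts)) &&
      all(c("both", "mar_only", "spr_only", "none") %in% names(counts))) {
    counts <- counts[c("both", "mar_only", "spr_only", "none")]
  }
  stopifnot(length(counts) == 4, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) {
    stop("`counts` must sum to a positive total", call. = FALSE)
  }
  a <- counts[[1]]; b <- counts[[2]]; c <- counts[[3]]; d <- counts[[4]]
  po <- (a + d) / n
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  if (1 - pe < .Machine$double.eps * 8) {
    out <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (po - pe) / (1 - pe)
}

#' Concordance summary table
#'
#' Per-medication and overall block-level concordance: order counts (all
#' vs included), analysis blocks, raw MAR/SPR discrepancy counts inside
#' the analysis blocks, the four category counts, overall Cohen's kappa,
#' and the shares of discrepancy-bearing blocks by category.
#'
#' @param blocks classified blocks ([classify_blocks()] output).
#' @param orders the orders table (for the "all orders" column).
#' @return A `concordance_result` list: `table` (per-medication rows plus
#'   an `Overall` row), `kappa` (full precision, on the overall counts),
#'   and `shares` (percent of discrepancy blocks that are SPR-only,
#'   MAR-only, both, and the SPR-capture share; `NA` when no block has a
#'   discrepancy).
#' @export
concordance_summary <- function(blocks, orders) {
  inc <- include_order(blocks)
  blocks <- dplyr::left_join(blocks, inc, by = "order_id")
  ana <- blocks[blocks$included, , drop = FALSE]
  per_med <- function(med, blk) {
    ord_all <- if (is.null(med)) {
      length(unique(orders$order_id))
    } else {
      length(unique(orders$order_id[orders$medication == med]))
    }
    tibble::tibble(
      medication = med %||% "Overall",
      orders_all = ord_all,
      orders_included = length(unique(blk$order_id)),
      n_blocks = nrow(blk),
      mar_disc = sum(blk$n_mar_disc),
      spr_disc = sum(blk$n_spr_disc),
      none = sum(blk$category == "none"),
      MAR_only = sum(blk$category == "MAR_only"),
      SPR_only = sum(blk$category == "SPR_only"),
      both = sum(blk$category == "both"))
  }
  meds <- sort(unique(c(orders$medication, ana$medication)))
  tab <- dplyr::bind_rows(
    lapply(meds, function(m) per_med(m, ana[ana$medication == m, ])),
    per_med(NULL, ana))
  ov <- tab[tab$medication == "Overall", ]
  counts <- c(both = ov$both, mar_only = ov$MAR_only,
              spr_only = ov$SPR_only, none = ov$none)
  kappa <- if (ov$n_blocks > 0) cohen_kappa(counts) else NA_real_
  n_disc <- ov$both + ov$MAR_only + ov$SPR_only
  shares <- if (n_disc > 0) {
    c(spr_only_pct = 100 * ov$SPR_only / n_disc,
      mar_only_pct = 100 * ov$MAR_only / n_disc,
      both_pct = 100 * ov$both / n_disc,
      spr_capture_pct = 100 * (ov$SPR_only + ov$both) / n_disc)
  } else {
    c(spr_only_pct = NA_real_, mar_only_pct = NA_real_,
      both_pct = NA_real_, spr_capture_pct = NA_real_)
  }
  structure(list(table = tab, kappa = kappa, shares = shares),
            class = "concordance_result")
}
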
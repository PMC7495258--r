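# Plain-text persistence for cohorts: four CSV streams, a long-format
# registry CSV, and a JSON-lines ground-truth ledger.

fmt_ts <- function(x) format(x, "%Y-%m-%d %H:%M:%S", tz = "UTC")

write_stream_csv <- function(df, path) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    if (inherits(df[[col]], "POSIXct")) {
      df[[col]] <- fmt_ts(df[[col]])
    } else if (is.double(df[[col]])) {
      df[[col]] <- sprintf("%.17g", df[[col]])  # round-trip exact doubles
    }
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
}

#' Write a cohort to a directory of plain-text files
#'
#' Emits `orders.csv`, `order_events.csv`, `mar.csv`, `spr.csv`, a
#' long-format `registry.csv` (component/value pairs, including the drug
#' library), and `ledger.jsonl` (one ground-truth entry per line).
#'
#' @param cohort a `pump_cohort` (see [generate_cohort()]).
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stream_csv(cohort$orders, file.path(dir, "orders.csv"))
  write_stream_csv(cohort$order_events, file.path(dir, "order_events.csv"))
  write_stream_csv(cohort$mars, file.path(dir, "mar.csv"))
  write_stream_csv(cohort$sprs, file.path(dir, "spr.csv"))
  reg <- cohort$registry
  reg_df <- rbind(
    data.frame(component = "valid_id", value = reg$valid_ids),
    data.frame(component = "encounter_id", value = reg$encounter_ids),
    data.frame(component = "patient_name", value = reg$patient_names),
    data.frame(component = "expired_id", value = reg$expired_ids),
    data.frame(component = "drug_library", value = cohort$drug_library))
  utils::write.csv(reg_df, file.path(dir, "registry.csv"),
                   row.names = FALSE)
  led <- cohort$ledger
  led$timestamp <- fmt_ts(led$timestamp)
  writeLines(
    vapply(seq_len(nrow(led)), function(i) {
      jsonlite::toJSON(as.list(led[i, ]), auto_unbox = TRUE, na = "null",
                       digits = NA)
    }, character(1)),
    file.path(dir, "ledger.jsonl"))
  invisible(dir)
}

#' Read a cohort back from a directory written by [write_cohort()]
#'
#' @param dir directory holding the CSV/JSONL files.
#' @return A `pump_cohort`-shaped list (without generator settings).
#' @export
read_cohort <- function(dir) {
  rd <- function(name) {
    df <- utils::read.csv(file.path(dir, name), colClasses = "character",
                          na.strings = character())
    df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC")
    if ("value" %in% names(df)) df$value <- as.numeric(df$value)
    if ("true_block_index" %in% names(df)) {
      df$true_block_index <- suppressWarnings(as.integer(df$true_block_index))
    }
    tibble::as_tibble(df)
  }
  reg_df <- utils::read.csv(file.path(dir, "registry.csv"),
                            colClasses = "character")
  registry <- patient_registry(
    valid_ids = reg_df$value[reg_df$component == "valid_id"],
    encounter_ids = reg_df$value[reg_df$component == "encounter_id"],
    patient_names = reg_df$value[reg_df$component == "patient_name"],
    expired_ids = reg_df$value[reg_df$component == "expired_id"])
  ledger_path <- file.path(dir, "ledger.jsonl")
  lines <- readLines(ledger_path)
  ledger <- if (length(lines) == 0) {
    empty_ledger()
  } else {
    rows <- lapply(lines, function(l) {
      x <- jsonlite::fromJSON(l)
      x[vapply(x, is.null, logical(1))] <- NA
      tibble::as_tibble(x)
    })
    led <- dplyr::bind_rows(rows)
    led$timestamp <- as.POSIXct(led$timestamp, tz = "UTC")
    led$block_index <- as.integer(led$block_index)
    led
  }
  list(
    orders = rd("orders.csv"),
    order_events = rd("order_events.csv"),
    mars = rd("mar.csv"),
    sprs = rd("spr.csv"),
    ledger = ledger,
    registry = registry,
    drug_library = reg_df$value[reg_df$component == "drug_library"])
}
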
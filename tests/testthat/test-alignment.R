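test_that("only started and restarted pump records survive the state filter", {
  sprs <- fixture_sprs(
    t = paste0("2014-03-01 0", 1:4, ":00"),
    value = 1,
    state = c("started", "paused", "restarted", "completed"))
  kept <- filter_started(sprs)
  expect_equal(kept$state, c("started", "restarted"))
  expect_equal(kept$spr_id, c("S1", "S3"))
  expect_equal(nrow(filter_started(sprs[0, ])), 0)
  expect_equal(nrow(filter_started(
    fixture_sprs("2014-03-01 01:00", 1, state = "paused"))), 0)
  expect_error(filter_started(
    fixture_sprs("2014-03-01 01:00", 1, state = "exploded")),
    "unrecognized pump state")
})

test_that("grouping partitions records by patient and medication", {
  orders <- dplyr::bind_rows(
    fixture_orders("O1", "2014-01-01 08:00", 1, patient = "1234567", med = "TPN"),
    fixture_orders("O2", "2014-01-01 08:00", 2, patient = "1234567", med = "morphine"),
    fixture_orders("O3", "2014-01-01 08:00", 3, patient = "7654321", med = "TPN"),
    fixture_orders("O4", "2014-01-01 08:00", 4, patient = "7654321", med = "morphine"))
  events <- dplyr::bind_rows(lapply(1:4, function(i) {
    fixture_events(paste0("O", i), "2014-01-01 08:00", i,
                   kind = "initiation",
                   patient = orders$patient_id[i], med = orders$medication[i])
  }))
  mars <- dplyr::bind_rows(
    fixture_mars("2014-01-01 09:00", 1, patient = "1234567", med = "TPN"),
    fixture_mars("2014-01-01 09:00", 3, patient = "7654321", med = "TPN"))
  sprs <- dplyr::bind_rows(
    fixture_sprs("2014-01-01 09:10", 2, patient = "1234567", med = "morphine"),
    fixture_sprs("2014-01-01 09:10", 9, patient = "1111111", med = "fentanyl"))
  g <- group_records(orders, events, mars, sprs)
  expect_equal(nrow(g), 5)  # 4 ordered groups + 1 order-less pump group
  expect_equal(sum(purrr::map_int(g$orders, nrow)), nrow(orders))
  expect_equal(sum(purrr::map_int(g$order_events, nrow)), nrow(events))
  expect_equal(sum(purrr::map_int(g$mars, nrow)), nrow(mars))
  expect_equal(sum(purrr::map_int(g$sprs, nrow)), nrow(sprs))
  orphan <- g[g$patient_id == "1111111", ]
  expect_false(orphan$has_orders)
  expect_equal(nrow(orphan$sprs[[1]]), 1)
})

test_that("pump records link to the closest active order within 24 hours", {
  orders <- fixture_orders("O1", "2014-03-01 08:00", 5)
  events <- fixture_events("O1", "2014-03-01 08:00", 5, kind = "initiation")
  mars <- fixture_mars(character(0), double(0))
  # activity one hour before the record
  expect_equal(align_spr_to_order(ts("2014-03-01 09:00"), orders, events,
                                  mars), "O1")
  # nearest activity 25 h away exceeds the window
  expect_true(is.na(align_spr_to_order(ts("2014-03-02 09:00"), orders,
                                       events, mars)))
  # MAR documentation alone keeps an order in candidacy
  expect_equal(align_spr_to_order(
    ts("2014-03-02 09:00"), orders, events,
    fixture_mars("2014-03-02 06:00", 5)), "O1")
})

test_that("linkage picks the order minimizing the activity gap (brute force)", {
  orders <- dplyr::bind_rows(
    fixture_orders("O1", "2014-03-01 00:00", 5),
    fixture_orders("O2", "2014-03-05 00:00", 8))
  events <- dplyr::bind_rows(
    fixture_events("O1", c("2014-03-01 00:00", "2014-03-03 10:00"), c(5, 6),
                   kind = c("initiation", "modification")),
    fixture_events("O2", c("2014-03-05 00:00", "2014-03-03 17:00"), c(8, 8),
                   kind = c("initiation", "modification")))
  mars <- fixture_mars(c("2014-03-02 20:00", "2014-03-04 23:00"), c(5, 8))
  # brute force over every activity gap for a grid of query times
  for (q in seq(ts("2014-03-02 00:00"), ts("2014-03-06 00:00"),
                by = 3 * 3600)) {
    q <- as.POSIXct(q, tz = "UTC", origin = "1970-01-01")
    gaps <- sapply(c("O1", "O2"), function(oid) {
      act <- c(events$timestamp[events$order_id == oid],
               mars$timestamp[c("O1", "O2")[findInterval(
                 as.numeric(mars$timestamp),
                 as.numeric(orders$timestamp))] == oid])
      min(abs(as.numeric(difftime(act, q, units = "hours"))))
    })
    expected <- if (min(gaps) > 24) NA_character_ else
      names(gaps)[which.min(gaps)]
    expect_identical(align_spr_to_order(q, orders, events, mars),
                     expected)
  }
})

test_that("timelines sort chronologically with order events first at ties", {
  group <- fixture_group(
    fixture_orders("O1", "2014-03-01 08:00", 5),
    fixture_events("O1", c("2014-03-01 08:00", "2014-03-01 12:00"), c(5, 6),
                   kind = c("initiation", "modification")),
    mars = fixture_mars(c("2014-03-01 12:00", "2014-03-01 09:00"), c(6, 5)),
    sprs = fixture_sprs("2014-03-01 12:00", 6))
  links <- tibble::tibble(spr_id = "S1", order_id = "O1")
  tl <- build_timeline(group, links)
  expect_equal(nrow(tl), 5)  # nothing lost
  expect_true(!is.unsorted(tl$timestamp))
  noon <- tl[tl$timestamp == ts("2014-03-01 12:00"), ]
  expect_equal(noon$kind, c("order_event", "mar", "spr"))
  expect_equal(tl$linked_order_id[tl$kind == "spr"], "O1")
  # rebuilding from its own sorted components is stable
  expect_identical(tl, tl[order(tl$timestamp,
                                match(tl$kind,
                                      c("order_event", "mar", "spr"))), ])
})

test_that("on synthetic data every pump record links to its source order", {
  co <- generate_cohort(cohort_config(n_patients = 20, seed = 55),
                        error_mixture())
  started <- filter_started(co$sprs)
  groups <- group_records(co$orders, co$order_events, co$mars, started)
  for (g in seq_len(nrow(groups))) {
    links <- align_sprs(groups[g, ])
    truth <- groups$sprs[[g]]$true_order_id
    expect_equal(links$order_id, truth)
  }
})
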
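test_that("the active prescription is the latest order event at or before t", {
  tl <- fixture_timeline(data.frame(
    t = c("2014-03-01 09:00", "2014-03-01 10:10"), value = c(0.5, 1.0)))
  at <- function(t) prescribed_value_at(tl, ts(t))
  expect_equal(at("2014-03-01 10:00"),
               list(value = 0.5, via_grace = FALSE))
  expect_equal(at("2014-03-01 10:10"),
               list(value = 1.0, via_grace = FALSE))
  # before any order: the upcoming order inside grace stands in
  expect_equal(at("2014-03-01 08:45"),
               list(value = 0.5, via_grace = TRUE))
  expect_null(at("2014-03-01 08:00"))
})

test_that("magnitude of discrepancy is signed percent over the prescription", {
  expect_equal(magnitude_of_discrepancy(2.0, 1.0), 100)
  expect_equal(magnitude_of_discrepancy(0.5, 1.0), -50)
  expect_equal(magnitude_of_discrepancy(1.0, 1.0), 0)
  expect_error(magnitude_of_discrepancy(1.0, 0), "positive")
  # sign symmetry: mod(p + d, p) = -mod(p - d, p)
  set.seed(1)
  for (i in 1:200) {
    p <- runif(1, 0.1, 20)
    d <- runif(1, 0, p * 0.99)
    expect_equal(magnitude_of_discrepancy(p + d, p),
                 -magnitude_of_discrepancy(p - d, p))
  }
})

test_that("binning respects the printed bracket conventions and partitions", {
  expect_equal(as.character(bin_mod(-50)), "[-50%,-20%)")
  expect_equal(as.character(bin_mod(10)), "(0%,10%]")
  expect_equal(as.character(bin_mod(0)), "0%")
  expect_equal(as.character(bin_mod(c(-51, -20, -10.0001, -0.5, 1e-9,
                                      10.5, 20, 50.0001, 100, 101))),
               c("<-50%", "[-20%,-10%)", "[-20%,-10%)", "[-10%,0%)",
                 "(0%,10%]", "(10%,20%]", "(10%,20%]", "(50%,100%]",
                 "(50%,100%]", ">100%"))
  expect_error(bin_mod(Inf), "finite")
  # exactly one bin per value over a fine grid
  grid <- seq(-200, 200, by = 0.25)
  bins <- bin_mod(grid)
  expect_false(anyNA(bins))
  expect_equal(length(levels(bins)), 10)
  expect_true(all(table(bins) > 0))
})

test_that("discrepancy rates round half-up to one decimal", {
  expect_equal(discrepancy_rate(321, 10575), 3.0)
  expect_equal(discrepancy_rate(682, 23397), 2.9)
  expect_equal(discrepancy_rate(0, 100), 0.0)
  expect_equal(discrepancy_rate(1, 400), 0.3)  # 0.25 rounds up
  expect_error(discrepancy_rate(1, 0), "positive")
})

test_that("overdose shares come from the five positive bins", {
  counts <- setNames(c(19, 61, 38, 12, 4, 20, 36, 44, 46, 41),
                     mod_bin_levels())
  s <- overdose_summary(counts)
  expect_equal(s$total, 321)
  expect_equal(s$n_overdose, 187)
  expect_equal(s$n_substantial, 41)
  zero <- overdose_summary(setNames(rep(0, 10), mod_bin_levels()))
  expect_true(is.na(zero$overdose_pct))
  expect_true(is.na(zero$substantial_pct))
})

test_that("matching administrations raise no discrepancy; mismatches do", {
  tl <- fixture_timeline(
    data.frame(t = "2014-03-01 08:00", value = 0.1),
    mars = data.frame(t = "2014-03-01 10:00", value = 0.1),
    sprs = data.frame(t = "2014-03-01 10:05", value = 0.2))
  d <- detect_discrepancies(tl)
  expect_equal(nrow(d), 1)
  expect_equal(d$source, "SPR")
  expect_equal(d$mod_percent, 100)
  expect_equal(as.character(d$mod_bin), "(50%,100%]")
  expect_false(d$documentation_only)
  expect_equal(attr(d, "n_evaluated"), 2)
})

test_that("a matching order within the grace window legitimizes the dose", {
  # administration of 1.0 at 10:00; modification to 1.0 placed 10:10
  tl <- fixture_timeline(
    data.frame(t = c("2014-03-01 09:00", "2014-03-01 10:10"),
               value = c(0.5, 1.0)),
    mars = data.frame(t = "2014-03-01 10:00", value = 1.0))
  expect_equal(nrow(detect_discrepancies(tl)), 0)
})

test_that("an order placed beyond the grace window is a 0% documentation discrepancy", {
  tl <- fixture_timeline(
    data.frame(t = c("2014-03-01 09:00", "2014-03-01 10:45"),
               value = c(0.5, 1.0)),
    sprs = data.frame(t = "2014-03-01 10:00", value = 1.0))
  d <- detect_discrepancies(tl)
  expect_equal(nrow(d), 1)
  expect_true(d$documentation_only)
  expect_equal(d$mod_percent, 0)
  expect_equal(d$reference, 1.0)
  expect_equal(as.character(d$mod_bin), "0%")
})

test_that("records preceding every order are referenced to the first order", {
  tl <- fixture_timeline(
    data.frame(t = "2014-03-01 12:00", value = 2.0),
    mars = data.frame(t = "2014-03-01 08:00", value = 1.0))
  d <- detect_discrepancies(tl)
  expect_equal(nrow(d), 1)
  expect_true(d$preceded_orders)
  expect_equal(d$reference, 2.0)
  expect_equal(d$mod_percent, -50)
})

test_that("unlinked pump records are excluded and counted separately", {
  tl <- fixture_timeline(
    data.frame(t = "2014-03-01 08:00", value = 1.0),
    sprs = data.frame(t = c("2014-03-01 09:00", "2014-03-01 10:00"),
                      value = c(5, 5),
                      linked = c(NA_character_, "O1")))
  d <- detect_discrepancies(tl)
  expect_equal(nrow(d), 1)
  expect_equal(attr(d, "n_unlinked_sprs"), 1)
  expect_equal(attr(d, "n_evaluated"), 1)
})

test_that("widening the grace window never adds discrepancies", {
  co <- generate_cohort(cohort_config(n_patients = 15, seed = 91),
                        error_mixture(p_mar_discrepancy = 0.1,
                                      p_spr_discrepancy = 0.1,
                                      p_late_order = 0.15))
  started <- filter_started(co$sprs)
  groups <- group_records(co$orders, co$order_events, co$mars, started)
  counts <- sapply(c(0, 10, 30, 60, 120), function(gr) {
    n <- 0
    for (g in seq_len(nrow(groups))) {
      tl <- build_timeline(groups[g, ], align_sprs(groups[g, ]))
      n <- n + nrow(detect_discrepancies(tl, grace_minutes = gr))
    }
    n
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("injected discrepancies are recovered exactly from the ledger", {
  co <- generate_cohort(cohort_config(n_patients = 25, seed = 47),
                        error_mixture(p_mar_discrepancy = 0.08,
                                      p_spr_discrepancy = 0.08))
  rep <- run_pipeline(co)
  ev <- evaluate_against_ledger(rep, co$ledger)
  expect_gt(ev$n_injected, 0)
  expect_equal(ev$sensitivity, 1.0)
  expect_equal(ev$precision, 1.0)
  expect_lt(ev$max_mod_error, 1e-9)
  # bin totals conserve the discrepancy totals
  bins <- rep$mod_bins$bins
  expect_equal(sum(bins$n[bins$source == "MAR"]),
               sum(rep$discrepancies$source == "MAR"))
  expect_equal(sum(bins$n[bins$source == "SPR"]),
               sum(rep$discrepancies$source == "SPR"))
})
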
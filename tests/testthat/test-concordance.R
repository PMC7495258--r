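test_that("segmentation emits one block per populated inter-event interval", {
  # initiation + 2 modifications, administrations in every interval
  tl3 <- fixture_timeline(
    data.frame(t = c("2014-03-01 08:00", "2014-03-01 16:00",
                     "2014-03-02 00:00"), value = c(1, 2, 3)),
    mars = data.frame(t = c("2014-03-01 10:00", "2014-03-01 18:00",
                            "2014-03-02 02:00"), value = c(1, 2, 3)))
  b3 <- segment_event_blocks(tl3)
  expect_equal(nrow(b3), 3)
  expect_equal(b3$block_index, 1:3)
  expect_equal(b3$n_mar, rep(1L, 3))
  # no modifications -> a single block
  tl1 <- fixture_timeline(
    data.frame(t = "2014-03-01 08:00", value = 1),
    mars = data.frame(t = "2014-03-01 10:00", value = 1))
  expect_equal(nrow(segment_event_blocks(tl1)), 1)
  # an interval without administrations emits no block
  tl_sparse <- fixture_timeline(
    data.frame(t = c("2014-03-01 08:00", "2014-03-01 16:00",
                     "2014-03-02 00:00"), value = c(1, 2, 3)),
    mars = data.frame(t = c("2014-03-01 10:00", "2014-03-02 02:00"),
                      value = c(1, 3)))
  b_sparse <- segment_event_blocks(tl_sparse)
  expect_equal(nrow(b_sparse), 2)
  expect_equal(b_sparse$start, ts(c("2014-03-01 08:00", "2014-03-02 00:00")))
  # an administration at the boundary minute opens the new block
  tl_tie <- fixture_timeline(
    data.frame(t = c("2014-03-01 08:00", "2014-03-01 16:00"), value = c(1, 2)),
    mars = data.frame(t = "2014-03-01 16:00", value = 2))
  expect_equal(segment_event_blocks(tl_tie)$start, ts("2014-03-01 16:00"))
})

test_that("blocks are classified by the sources of their member discrepancies", {
  tl <- fixture_timeline(
    data.frame(t = c("2014-03-01 08:00", "2014-03-01 16:00",
                     "2014-03-02 00:00"), value = c(1, 2, 3)),
    mars = data.frame(t = c("2014-03-01 10:00", "2014-03-01 18:00",
                            "2014-03-02 02:00"), value = c(1, 5, 5)),
    sprs = data.frame(t = c("2014-03-01 11:00", "2014-03-01 19:00",
                            "2014-03-02 03:00"), value = c(9, 9, 3)))
  disc <- detect_discrepancies(tl)
  blocks <- classify_blocks(segment_event_blocks(tl), disc)
  expect_equal(as.character(blocks$category),
               c("SPR_only", "both", "MAR_only"))
  # a block with no discrepant member is 'none'
  clean <- classify_blocks(segment_event_blocks(tl), disc[0, ])
  expect_equal(as.character(clean$category), rep("none", 3))
})

test_that("orders need both MARs and pump records to enter the analysis", {
  tl_mar_only <- fixture_timeline(
    data.frame(t = "2014-03-01 08:00", value = 1),
    mars = data.frame(t = "2014-03-01 10:00", value = 1))
  expect_false(include_order(segment_event_blocks(tl_mar_only))$included)
  tl_both <- fixture_timeline(
    data.frame(t = "2014-03-01 08:00", value = 1),
    mars = data.frame(t = "2014-03-01 10:00", value = 1),
    sprs = data.frame(t = "2014-03-01 10:30", value = 1))
  expect_true(include_order(segment_event_blocks(tl_both))$included)
})

test_that("Cohen kappa matches its closed-form cases", {
  expect_equal(round_half_up(cohen_kappa(c(67, 44, 197, 2330)), 2), 0.32)
  expect_equal(cohen_kappa(c(5, 0, 0, 5)), 1.0)
  expect_equal(cohen_kappa(c(25, 25, 25, 25)), 0.0)
  expect_equal(cohen_kappa(c(both = 67, none = 2330, spr_only = 197,
                             mar_only = 44)),
               cohen_kappa(c(67, 44, 197, 2330)))
  # degenerate marginals: agreement undefined, not perfect
  k <- cohen_kappa(c(10, 0, 0, 0))
  expect_true(is.na(k))
  expect_true(isTRUE(attr(k, "degenerate")))
  expect_error(cohen_kappa(c(0, 0, 0, 0)), "positive")
})

test_that("kappa agrees with an expansion-based agreement oracle", {
  check_tables <- function(tabs) {
    tabs <- as.matrix(tabs)
    max_diff <- 0
    na_mismatch <- 0L
    for (r in seq_len(nrow(tabs))) {
      cc <- as.numeric(tabs[r, ])
      k_pkg <- cohen_kappa(cc)
      k_orc <- kappa_oracle(cc[1], cc[2], cc[3], cc[4])
      if (is.na(k_orc) || is.na(k_pkg)) {
        na_mismatch <- na_mismatch + (is.na(k_orc) != is.na(k_pkg))
      } else {
        max_diff <- max(max_diff, abs(k_pkg - k_orc))
      }
    }
    list(max_diff = max_diff, na_mismatch = na_mismatch)
  }
  # exhaustive over all 2x2 tables with N <= 30
  parts <- expand.grid(a = 0:30, b = 0:30, c = 0:30)
  parts <- parts[parts$a + parts$b + parts$c <= 30, ]
  exhaustive <- do.call(rbind, lapply(1:30, function(n) {
    p <- parts[parts$a + parts$b + parts$c <= n, ]
    cbind(p, d = n - p$a - p$b - p$c)
  }))
  res <- check_tables(exhaustive)
  expect_lt(res$max_diff, 1e-12)
  expect_equal(res$na_mismatch, 0L)
  # seeded random tables up to N = 200
  set.seed(2024)
  n <- sample(1:200, 20000, replace = TRUE)
  cuts <- t(vapply(n, function(ni) sort(sample(0:ni, 3, replace = TRUE)),
                   integer(3)))
  rand <- data.frame(a = cuts[, 1], b = cuts[, 2] - cuts[, 1],
                     c = cuts[, 3] - cuts[, 2], d = n - cuts[, 3])
  res2 <- check_tables(rand)
  expect_lt(res2$max_diff, 1e-12)
  expect_equal(res2$na_mismatch, 0L)
})

test_that("the concordance summary reproduces printed-table arithmetic", {
  # overall concordance categories: 2330 none, 44 MAR-only, 197 SPR-only,
  # 67 both -> 308 discrepancy blocks
  shares <- c(spr_only = 100 * 197 / 308, mar_only = 100 * 44 / 308,
              both = 100 * 67 / 308)
  expect_equal(round_half_up(shares[["spr_only"]], 1), 64.0)
  expect_equal(round_half_up(shares[["mar_only"]], 1), 14.3)
  expect_lt(abs(shares[["both"]] - 21.7), 0.1)
  expect_gte(100 * (197 + 67) / 308, 85)
})

test_that("summary rows conserve block counts, overall equals column sums", {
  co <- generate_cohort(cohort_config(n_patients = 25, seed = 8),
                        error_mixture(p_mar_discrepancy = 0.1,
                                      p_spr_discrepancy = 0.1))
  rep <- run_pipeline(co)
  tab <- rep$concordance$table
  per_med <- tab[tab$medication != "Overall", ]
  ov <- tab[tab$medication == "Overall", ]
  for (col in c("orders_included", "n_blocks", "mar_disc", "spr_disc",
                "none", "MAR_only", "SPR_only", "both")) {
    expect_equal(sum(per_med[[col]]), ov[[col]])
  }
  expect_equal(ov$none + ov$MAR_only + ov$SPR_only + ov$both, ov$n_blocks)
})

test_that("independent errors give near-zero kappa; joint errors give one", {
  co_ind <- generate_cohort(
    cohort_config(n_patients = 450, seed = 1234),
    error_mixture(p_mar_discrepancy = 0.1, p_spr_discrepancy = 0.1))
  rep_ind <- run_pipeline(co_ind)
  n_blocks <- rep_ind$concordance$table$n_blocks[
    rep_ind$concordance$table$medication == "Overall"]
  expect_gt(n_blocks, 2000)
  expect_lt(abs(rep_ind$concordance$kappa), 3 / sqrt(n_blocks))

  co_joint <- generate_cohort(
    cohort_config(n_patients = 20, seed = 5),
    error_mixture(p_joint_discrepancy = 0.2))
  rep_joint <- run_pipeline(co_joint)
  expect_equal(rep_joint$concordance$kappa, 1.0)
})
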
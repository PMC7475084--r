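# Coverage arithmetic, episode merging, exposure and average daily dose.

test_that("coverage length and dose follow the recorded-field hierarchy", {
  # 30 capsules x 50 mg, instruction 50 mg/day -> 30 days at 50 mg/day
  rx <- data.frame(patient_id = "A", drug = "LDX", issue_date = D0,
                   strength_mg = 50, quantity = 30,
                   daily_dose_instruction_mg = 50, supply_days = NA_real_)
  cov <- build_coverage(rx)
  expect_equal(cov$days, 30)
  expect_equal(cov$dose_mg_per_day, 50)
  expect_equal(cov$end, D0 + 30)

  # recorded supply wins: 28 days at 70 mg/day
  rx2 <- data.frame(patient_id = "A", drug = "LDX", issue_date = D0,
                    strength_mg = 70, quantity = 28,
                    daily_dose_instruction_mg = NA_real_, supply_days = 28)
  cov2 <- build_coverage(rx2)
  expect_equal(cov2$days, 28)
  expect_equal(cov2$dose_mg_per_day, 70)

  # nothing recorded: configured default, dose from quantity x strength
  rx3 <- data.frame(patient_id = "A", drug = "LDX", issue_date = D0,
                    strength_mg = 50, quantity = 30,
                    daily_dose_instruction_mg = NA_real_, supply_days = NA_real_)
  expect_equal(build_coverage(rx3, default_supply_days = 30)$dose_mg_per_day, 50)
  no_basis <- build_coverage(rx3[, setdiff(names(rx3), "quantity")] |>
                               transform(quantity = NA_real_),
                             default_supply_days = NA)
  expect_equal(nrow(no_basis), 0L)
  expect_equal(nrow(attr(no_basis, "rejected")), 1L)
})

test_that("total covered days equals the per-record sum before merging", {
  set.seed(21)
  n <- 100
  rx <- mk_rx(sample(LETTERS[1:5], n, replace = TRUE), "LDX",
              sample(0:900, n, replace = TRUE),
              supply = sample(c(14, 28, 30, 90), n, replace = TRUE))
  cov <- build_coverage(rx)
  expect_equal(sum(cov$days), sum(rx$supply_days))
})

test_that("intervals within the grace period merge; beyond it they split", {
  # 10-day gap: one episode, covered 60, span 70
  cov <- build_coverage(mk_rx("A", "LDX", c(0, 40)))
  ep <- build_episodes(cov, gap_days = 30)
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$covered_days, 60)
  expect_equal(ep$span_days, 70)

  # 31-day gap exceeds "within 30 days": two episodes
  ep2 <- build_episodes(build_coverage(mk_rx("A", "LDX", c(0, 61))), gap_days = 30)
  expect_equal(nrow(ep2), 2L)
  # 30-day gap is still within the window: one episode
  ep3 <- build_episodes(build_coverage(mk_rx("A", "LDX", c(0, 60))), gap_days = 30)
  expect_equal(nrow(ep3), 1L)

  expect_error(build_episodes(cov, gap_days = -1), "non-negative")
})

test_that("overlapping refills stockpile: supply is appended, not discarded", {
  # second prescription 10 days early: coverage shifts, nothing lost
  cov <- build_coverage(mk_rx("A", "LDX", c(0, 20)))
  ep <- build_episodes(cov, gap_days = 30)
  expect_equal(ep$covered_days, 60)
  expect_equal(ep$span_days, 60)
  expect_equal(ep$end, D0 + 60)
  # truncation model clips instead
  ept <- build_episodes(cov, gap_days = 30, overlap = "truncate")
  expect_equal(ept$covered_days, 50)
})

test_that("episode partition matches the brute-force oracle on enumerated gap patterns", {
  gaps <- c(0, 10, 29, 30, 31, 45, 60, 75, 90)
  grid <- expand.grid(g1 = gaps, g2 = gaps)
  for (k in seq_len(nrow(grid))) {
    days <- cumsum(c(0, 30 + grid$g1[k], 30 + grid$g2[k]))  # end-to-issue gaps
    got <- build_episodes(build_coverage(mk_rx("A", "LDX", days)), gap_days = 30)
    want <- oracle_episodes_one(days, rep(30, 3), 30)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$covered_days, want$covered)
    expect_equal(as.numeric(got$n_prescriptions), as.numeric(want$n))
    expect_equal(as.numeric(unclass(got$start - D0)), want$start)
    expect_equal(as.numeric(unclass(got$end - D0)), want$end)
  }
  # random small interval sets, including overlaps
  set.seed(31)
  for (k in 1:200) {
    n <- sample(1:6, 1)
    days <- cumsum(c(0, sample(0:60, n - 1, replace = TRUE)))
    lens <- sample(c(14, 30, 45), n, replace = TRUE)
    rx <- mk_rx("A", "LDX", days, supply = lens)
    got <- build_episodes(build_coverage(rx), gap_days = 30)
    want <- oracle_episodes_one(days, lens, 30)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$covered_days, want$covered)
  }
})

test_that("episode building is idempotent and conserves mg and days", {
  set.seed(41)
  for (k in 1:50) {
    n <- sample(1:8, 1)
    days <- cumsum(c(0, sample(0:70, n - 1, replace = TRUE)))
    rx <- mk_rx("A", "LDX", days, dose = sample(c(30, 50, 70), n, replace = TRUE))
    cov <- build_coverage(rx)
    ep <- build_episodes(cov, gap_days = 30)
    expect_equal(sum(ep$covered_days), sum(cov$days))
    expect_equal(sum(ep$total_mg), sum(cov$total_mg))
    # re-express episodes as intervals and rebuild: same partition
    recov <- data.frame(patient_id = "A", drug = "LDX", issue_date = ep$start,
                        start = ep$start, end = ep$end, days = ep$covered_days,
                        dose_mg_per_day = ep$total_mg / ep$covered_days,
                        total_mg = ep$total_mg, rx_id = seq_len(nrow(ep)))
    ep2 <- build_episodes(recov, gap_days = 30)
    expect_equal(nrow(ep2), nrow(ep))
    expect_equal(ep2$start, ep$start)
    expect_equal(sum(ep2$covered_days), sum(ep$covered_days))
  }
})

test_that("raising the grace period never increases the episode count", {
  set.seed(51)
  for (k in 1:30) {
    n <- sample(2:8, 1)
    days <- cumsum(c(0, sample(0:100, n - 1, replace = TRUE)))
    cov <- build_coverage(mk_rx("A", "LDX", days))
    counts <- vapply(c(7, 14, 30, 60, 90),
                     function(g) nrow(build_episodes(cov, gap_days = g)), 0L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("repeat-user status and exposure durations follow the definitions", {
  # single prescription: not a repeat user, duration = one supply period
  ep1 <- build_episodes(build_coverage(mk_rx("A", "LDX", 0)))
  ex1 <- patient_exposure(ep1)
  expect_false(ex1$repeat_user)
  expect_equal(ex1$duration_days, 30)

  # two prescriptions in one episode: repeat user ("more than one prescription")
  ex2 <- patient_exposure(build_episodes(build_coverage(mk_rx("A", "LDX", c(0, 20)))))
  expect_true(ex2$repeat_user)

  # two episodes: headline duration sums spans; follow-up span crosses the gap
  ex3 <- patient_exposure(build_episodes(build_coverage(mk_rx("A", "LDX", c(0, 100)))))
  expect_equal(ex3$n_episodes, 2L)
  expect_equal(ex3$duration_days, 60)
  expect_equal(ex3$followup_span_days, 130)
})

test_that("average daily dose is the covered-days-weighted mean and caps at 70", {
  add1 <- average_daily_dose(build_coverage(mk_rx("A", "LDX", 0, dose = 50)))
  expect_equal(add1$add_mg_per_day, 50)
  expect_false(add1$exceeds_cap)

  add2 <- average_daily_dose(build_coverage(mk_rx("A", "LDX", 0, dose = 100)))
  expect_true(add2$exceeds_cap)

  # 30 d @ 30 mg + 30 d @ 70 mg -> 50 mg/day (weighted-mean oracle)
  rx <- rbind(mk_rx("A", "LDX", 0, dose = 30), mk_rx("A", "LDX", 30, dose = 70))
  add3 <- average_daily_dose(build_coverage(rx))
  expect_equal(add3$add_mg_per_day, (30 * 30 + 70 * 30) / 60)
  expect_equal(add3$add_mg_per_day, 50)

  # exactly 70 mg/day does not exceed the cap (criterion is "exceeding")
  add4 <- average_daily_dose(build_coverage(mk_rx("A", "LDX", 0, dose = 70)))
  expect_false(add4$exceeds_cap)
})

test_that("splitting a prescription into two half-quantity halves leaves ADD unchanged", {
  whole <- data.frame(patient_id = "A", drug = "LDX", issue_date = D0,
                      strength_mg = 50, quantity = 30,
                      daily_dose_instruction_mg = 50, supply_days = NA_real_)
  halves <- rbind(transform(whole, quantity = 15),
                  transform(whole, quantity = 15, issue_date = D0 + 15))
  a1 <- average_daily_dose(build_coverage(whole))
  a2 <- average_daily_dose(build_coverage(halves))
  expect_equal(a1$add_mg_per_day, a2$add_mg_per_day)
})
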
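# Discontinuation and switching classification under the 30-day definitions.

pat_one <- function(rx, wend_day, gap = 30, boundary = "inclusive") {
  classify_patterns(build_coverage(rx), window_end = D0 + wend_day,
                    gap_days = gap, boundary = boundary)
}

test_that("discontinuation requires a silent grace window and enough follow-up", {
  # last LDX coverage ends day 30, nothing after, window ends day 200
  p <- pat_one(mk_rx("A", "LDX", 0), 200)
  expect_true(p$discontinued)
  expect_false(p$censored)
  expect_equal(p$discontinuation_date, D0 + 30)

  # an MPH prescription 20 days after the end is switch evidence
  p2 <- pat_one(rbind(mk_rx("A", "LDX", 0), mk_rx("A", "MPH", 50)), 200)
  expect_false(p2$discontinued)
  expect_true(p2$switched_from_ldx)

  # coverage ends 10 days before the window end: censored, not discontinued
  p3 <- pat_one(mk_rx("A", "LDX", 0), 40)
  expect_false(p3$discontinued)
  expect_true(p3$censored)
  expect_true(p3$discontinued_naive)
})

test_that("switching to LDX is anchored at the other drug's period end", {
  # MPH covers [0, 30); LDX issued day 40 -> gap 10, switch
  p <- pat_one(rbind(mk_rx("A", "MPH", 0), mk_rx("A", "LDX", 40)), 300)
  expect_true(p$switched_to_ldx)
  expect_equal(p$switch_to_date, D0 + 40)

  # LDX issued day 65 -> gap 35 > 30, no switch
  p2 <- pat_one(rbind(mk_rx("A", "MPH", 0), mk_rx("A", "LDX", 65)), 300)
  expect_false(p2$switched_to_ldx)

  # LDX issued during ongoing MPH coverage counts only via the period end
  p3 <- pat_one(rbind(mk_rx("A", "MPH", 0, supply = 90), mk_rx("A", "LDX", 10)), 300)
  expect_false(p3$switched_to_ldx)  # issue 80 days before the MPH end
  p4 <- pat_one(rbind(mk_rx("A", "MPH", 0, supply = 90), mk_rx("A", "MPH", 10),
                      mk_rx("A", "LDX", 125)), 300)
  expect_true(p4$switched_to_ldx)   # stockpiled MPH end is day 120, gap 5
})

test_that("switching from LDX mirrors the definition with roles reversed", {
  p <- pat_one(rbind(mk_rx("A", "LDX", 0, supply = 50), mk_rx("A", "ATX", 70)), 300)
  expect_true(p$switched_from_ldx)   # LDX ends day 50, ATX at 70
  p2 <- pat_one(mk_rx("A", "LDX", 0), 300)
  expect_false(p2$switched_from_ldx) # no other prescriptions at all
  # non-ADHD drugs are never switch evidence
  p3 <- pat_one(rbind(mk_rx("A", "LDX", 0), mk_rx("A", "non_ADHD", 40)), 300)
  expect_false(p3$switched_from_ldx)
  expect_true(p3$discontinued)
})

test_that("the 30/31-day boundary is exact under the inclusive convention", {
  # switch at exactly 30 days: detected; at 31: not
  p30 <- pat_one(rbind(mk_rx("A", "LDX", 0), mk_rx("A", "MPH", 60)), 300)
  expect_true(p30$switched_from_ldx)
  p31 <- pat_one(rbind(mk_rx("A", "LDX", 0), mk_rx("A", "MPH", 61)), 300)
  expect_false(p31$switched_from_ldx)
  # exclusive convention flips the 30-day case
  p30x <- pat_one(rbind(mk_rx("A", "LDX", 0), mk_rx("A", "MPH", 60)), 300,
                  boundary = "exclusive")
  expect_false(p30x$switched_from_ldx)
})

test_that("a patient can switch to LDX and later from it; same-end flags exclude", {
  rx <- rbind(mk_rx("A", "MPH", 0), mk_rx("A", "LDX", 35), mk_rx("A", "ATX", 80))
  p <- pat_one(rx, 300)
  expect_true(p$switched_to_ldx)
  expect_true(p$switched_from_ldx)
  expect_false(p$discontinued)  # the only LDX episode end has switch evidence
})

test_that("an unbounded grace period leaves no discontinuation when therapy continues", {
  set.seed(61)
  for (k in 1:20) {
    n <- sample(2:6, 1)
    ldx_days <- cumsum(c(0, sample(0:90, n - 1, replace = TRUE)))
    other_day <- max(ldx_days) + 30 * n + 10  # safely after every LDX period end
    rx <- rbind(mk_rx("A", rep("LDX", n), ldx_days),
                mk_rx("A", sample(c("MPH", "ATX"), 1), other_day))
    p <- pat_one(rx, other_day + 2000, gap = 1e6)
    expect_false(p$discontinued)        # switch evidence inside the open window
    expect_false(p$discontinued_naive)
  }
})

test_that("raising the grace period never increases the discontinued count", {
  set.seed(71)
  seqs <- replicate(120, random_sequence(), simplify = FALSE)
  counts <- vapply(c(7, 14, 30, 60, 90), function(g) {
    b <- classify_batch(seqs, gap = g, wend_offset = 400)
    sum(b$got$discontinued)
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("classifier agrees with the quadratic-scan oracle on random sequences", {
  set.seed(81)
  seqs <- replicate(400, random_sequence(), simplify = FALSE)
  offs <- sample(c(10, 31, 45, 120), length(seqs), replace = TRUE)
  b <- classify_batch(seqs, wend_offset = offs)
  for (i in seq_along(seqs)) {
    events <- data.frame(drug = seqs[[i]]$drug, day = seqs[[i]]$day, len = 30)
    want <- oracle_patterns_one(events, 30, b$wend[i] - as.numeric(unclass(D0)))
    row <- b$got[b$got$patient_id == b$ids[i], ]
    expect_equal(row$switched_to_ldx, want$switched_to_ldx)
    expect_equal(row$switched_from_ldx, want$switched_from_ldx)
    expect_equal(row$discontinued, want$discontinued)
    expect_equal(row$censored, want$censored)
  }
})
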
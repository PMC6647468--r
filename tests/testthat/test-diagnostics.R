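test_that("item mean checks: percentile mechanics and degenerate cases", {
  d <- simulate_trial(make_presets(n_early = 25)$study168_baseline,
                      fix_pop, fix_bank, fix_map, seed = 91)
  # replicates = 2: band is the min/max of the two replicate means
  chk2 <- item_mean_check(d, fix_pop, fix_bank, fix_map, replicates = 2,
                          seed = 3)
  sims <- attr(chk2, "simulated")$early
  expect_equal(chk2$pi_low, unname(apply(sims, 1, min)), tolerance = 1e-10)
  expect_equal(chk2$pi_high, unname(apply(sims, 1, max)), tolerance = 1e-10)
  # bit-identical reruns under the same seed
  chk2b <- item_mean_check(d, fix_pop, fix_bank, fix_map, replicates = 2,
                           seed = 3)
  expect_identical(as.data.frame(chk2), as.data.frame(chk2b))
  # a forced-degenerate item: all responses 3 in truth and model
  bank_deg <- fix_bank
  i <- match("03.single", bank_deg$key)
  # thresholds far out so category 3 has essentially all the mass
  bank_deg[i, c("b1", "b2", "b3", "b4")] <- c(-60, -40, -20, 60)
  d_deg <- simulate_trial(list(name = "deg", n_subjects = 10,
                               population = "early", visit_weeks = 0,
                               arms = c(all = 1)),
                          fix_pop, bank_deg, fix_map, seed = 5,
                          items = c("03.single", "05.single"))
  # items absent from the data are omitted with a warning
  expect_warning(
    chk_deg <- item_mean_check(d_deg, fix_pop, bank_deg, fix_map,
                               replicates = 10, seed = 5),
    "absent")
  row <- chk_deg[chk_deg$key == "03.single", ]
  expect_equal(row$observed_mean, 3)
  expect_equal(row$pi_low, 3)
  expect_equal(row$pi_high, 3)
  expect_true(row$covered)
})

test_that("residual correlation matrix is symmetric with unit diagonal", {
  d <- simulate_trial(make_presets(n_early = 60)$study168_baseline,
                      fix_pop, fix_bank, fix_map, seed = 95)
  rc <- residual_correlation(d, fix_pop, fix_bank, fix_map)
  expect_equal(dim(rc), c(44, 44))
  expect_equal(rc, t(rc), tolerance = 1e-12)
  ok <- !is.na(diag(rc))
  expect_true(all(diag(rc)[ok] == 1))
  # self-consistency: off-diagonals small when the model generated the data
  off <- rc[upper.tri(rc)]
  expect_lt(mean(abs(off), na.rm = TRUE), 0.2)
  # constant residuals yield NA, not zero
  d2 <- d
  key2 <- sprintf("%02d.%s", d2$ITEM, d2$SUB)
  d2$DV[key2 == "05.single"] <- 4L
  rc2 <- residual_correlation(d2, fix_pop, fix_bank, fix_map)
  expect_true(all(is.na(rc2["05.single", setdiff(colnames(rc2), "05.single")]) |
                    abs(rc2["05.single", setdiff(colnames(rc2), "05.single")]) < 1))
})

test_that("VPC summarises subscores with ordered, reproducible bands", {
  des <- make_presets(n_placebo = 30)$study169_placebo_longitudinal
  des$visit_weeks <- c(0, 4, 12, 24)
  d <- simulate_trial(des, fix_pop, fix_bank, fix_map, seed = 97)
  v <- vpc_check(d, fix_pop, fix_bank, fix_map, replicates = 40, seed = 8)
  expect_setequal(unique(v$stratum),
                  c("PR_Score", "NSR_Score", "SR_Score", "Total"))
  expect_setequal(unique(v$time), c(0, 4, 12, 24))
  expect_true(all(v$pi_low <= v$pi_high))
  # intervals contain their own replicate medians
  expect_true(all(v$sim_median >= v$pi_low & v$sim_median <= v$pi_high))
  # percentile curves ordered within stratum x time
  for (st in unique(v$stratum)) for (tb in unique(v$time)) {
    s <- v[v$stratum == st & v$time == tb, ]
    expect_lte(s$observed[s$statistic == "q2.5"],
               s$observed[s$statistic == "median"])
    expect_lte(s$observed[s$statistic == "median"],
               s$observed[s$statistic == "q97.5"])
  }
  # subscore ranges and record-wise additivity
  sv <- paste(d$ID, d$TIME)
  pr_keys <- build_item_table()$key[build_item_table()$latent == "PR"]
  key <- sprintf("%02d.%s", d$ITEM, d$SUB)
  pr <- tapply(d$DV[key %in% pr_keys], sv[key %in% pr_keys], sum)
  expect_true(all(pr >= 0 & pr <= 68))
  tot <- tapply(d$DV, sv, sum)
  nsr_keys <- build_item_table()$key[build_item_table()$latent == "NSR"]
  nsr <- tapply(d$DV[key %in% nsr_keys], sv[key %in% nsr_keys], sum)
  sr <- tot - pr[names(tot)] - nsr[names(tot)]
  expect_true(all(sr >= 0 & sr <= 72))
  # identical rerun
  v2 <- vpc_check(d, fix_pop, fix_bank, fix_map, replicates = 40, seed = 8)
  expect_identical(as.data.frame(v), as.data.frame(v2))
})
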
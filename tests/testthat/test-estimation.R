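test_that("degenerate integral: vanishing variance gives the plug-in probability", {
  pop <- default_population(variance = c(PR = 1e-10, NSR = 1e-10, SR = 1e-10),
                            S1_variance = 1e-10,
                            correlation_early = diag(3))
  d <- data.frame(ID = 1, STUDY = "early", ARM = "all", TIME = 0,
                  ITEM = 3, SUB = "single", DV = 2, MDV = 0)
  ll <- subject_marginal_loglik(d, pop, fix_bank, fix_map)
  i <- match("03.single", fix_bank$key)
  p <- category_probabilities(fix_bank$a[i],
                              as.numeric(fix_bank[i, c("b1", "b2", "b3", "b4")]),
                              pop$mean[["PR"]])
  expect_equal(ll, log(p[[3]]), tolerance = 1e-6)
})

test_that("marginal likelihood agrees with dense-grid integration oracles", {
  # 1-D toy (two patient-reported items): 10,001-point trapezoid oracle
  d1 <- data.frame(ID = 1, STUDY = "early", ARM = "all", TIME = 0,
                   ITEM = c(3, 5), SUB = "single", DV = c(1, 2), MDV = 0)
  gr <- seq(-8, 8, length.out = 10001)
  w <- gr[2] - gr[1]
  lik <- rep(1, length(gr))
  for (r in 1:2) {
    i <- match(sprintf("%02d.single", d1$ITEM[r]), fix_bank$key)
    p <- category_probabilities(fix_bank$a[i],
                                as.numeric(fix_bank[i, c("b1", "b2", "b3", "b4")]),
                                fix_pop$mean[["PR"]] + gr)
    lik <- lik * p[, d1$DV[r] + 1]
  }
  oracle1 <- log(sum(lik * stats::dnorm(gr, 0, sqrt(fix_pop$variance[["PR"]]))) * w)
  agh1 <- subject_marginal_loglik(d1, fix_pop, fix_bank, fix_map,
                                  control = irm_control(nodes = 15))
  lap1 <- subject_marginal_loglik(d1, fix_pop, fix_bank, fix_map)
  expect_equal(agh1, oracle1, tolerance = 1e-3)
  expect_lt(abs(lap1 - oracle1), 0.02)

  # 2-D toy (PR + NSR items, 5 items, 2 subjects): dense 2-D grid oracle
  des <- list(name = "toy", n_subjects = 2, population = "early",
              visit_weeks = 0, arms = c(all = 1))
  d2 <- simulate_trial(des, fix_pop, fix_bank, fix_map, seed = 3,
                       items = pr_nsr_keys)
  oracle2 <- oracle_loglik_2d(d2, fix_pop, fix_bank, fix_map)
  agh2 <- as.numeric(irm_loglik(d2, fix_pop, fix_bank, fix_map,
                                control = irm_control(nodes = 9)))
  lap2 <- as.numeric(irm_loglik(d2, fix_pop, fix_bank, fix_map))
  expect_equal(agh2, oracle2, tolerance = 1e-3)
  # pure Laplace is the fast mode; with only five ordinal items per subject
  # its error is visibly larger than the quadrature mode's (it shrinks as
  # items accumulate), so it only gets a coarse sanity bound here
  expect_lt(abs(lap2 - oracle2), 0.1)
})

test_that("likelihood is invariant to relabelling body sides with pi <-> 1-pi", {
  des <- list(name = "toy", n_subjects = 6, population = "advanced",
              visit_weeks = 0, arms = c(all = 1))
  d <- simulate_trial(des, fix_pop, fix_bank, fix_map, seed = 9)
  swap <- function(s) {
    out <- s
    out[grepl("right", s)] <- sub("right", "left", s[grepl("right", s)])
    out[grepl("left", s) & !grepl("right", s)] <-
      sub("left", "right", s[grepl("left", s) & !grepl("right", s)])
    out
  }
  d_sw <- d
  d_sw$SUB <- swap(d$SUB)
  pop_sw <- default_population(mixture_pi = 1 - fix_pop$mixture_pi)
  ll <- as.numeric(irm_loglik(d, fix_pop, fix_bank, fix_map))
  ll_sw <- as.numeric(irm_loglik(d_sw, pop_sw, fix_bank, fix_map))
  expect_equal(ll, ll_sw, tolerance = 1e-8)
})

test_that("total log-likelihood sums per-subject contributions; no-data subjects error", {
  des <- list(name = "toy", n_subjects = 4, population = "early",
              visit_weeks = 0, arms = c(all = 1))
  d <- simulate_trial(des, fix_pop, fix_bank, fix_map, seed = 12)
  ll <- irm_loglik(d, fix_pop, fix_bank, fix_map)
  per <- vapply(split(d, d$ID), subject_marginal_loglik, 0,
                pop = fix_pop, bank = fix_bank, mapping = fix_map)
  expect_equal(as.numeric(ll), sum(per), tolerance = 1e-8)
  expect_equal(unname(attr(ll, "by_subject")), unname(per), tolerance = 1e-8)
  empty <- d[d$ID == 1, ]
  empty$MDV <- 1
  expect_error(subject_marginal_loglik(empty, fix_pop, fix_bank, fix_map),
               class = "irm_no_data")
})

test_that("frozen fit evaluates without iterating; nesting never hurts", {
  d <- sim_baseline(25, 25, seed = 51)
  frozen <- irm_fit(d, fix_bank, fix_map, start = fix_pop,
                    free = character(0))
  expect_equal(frozen$iterations, 0L)
  expect_true(frozen$converged)
  expect_equal(frozen$loglik,
               as.numeric(irm_loglik(d, fix_pop, fix_bank, fix_map)),
               tolerance = 1e-10)
  reduced <- irm_fit(d, fix_bank, fix_map, start = fix_pop, free = "pi",
                     control = irm_control(se = FALSE))
  full <- irm_fit(d, fix_bank, fix_map, start = fix_pop,
                  free = c("pi", "S1"), control = irm_control(se = FALSE))
  expect_lte(full$ofv, reduced$ofv + 1e-6)
  cmp <- compare_models(reduced, full)
  expect_equal(cmp$df, 1)
  expect_gte(cmp$delta_ofv, -1e-6)
  expect_true(cmp$p_value >= 0 && cmp$p_value <= 1)
  # identical fits
  cmp0 <- compare_models(reduced, reduced)
  expect_equal(cmp0$delta_ofv, 0)
  expect_equal(cmp0$p_value, 1)
  # chi-square reference point: delta OFV 3.84 on 1 df sits at p ~ 0.05
  fake_full <- full
  fake_full$ofv <- reduced$ofv - 3.84
  expect_equal(compare_models(reduced, fake_full)$p_value, 0.05,
               tolerance = 2e-3)
  # non-nested: AIC only
  expect_null(compare_models(reduced, full, nested = FALSE)$p_value)
  expect_named(compare_models(reduced, full, nested = FALSE)$aic,
               c("reduced", "full"))
})

test_that("latent means are recovered from simulated early-PD data", {
  des <- make_presets(n_early = 120)$study168_baseline
  d <- simulate_trial(des, fix_pop, fix_bank, fix_map, seed = 61)
  fit <- irm_fit(d, fix_bank, fix_map, start = fix_pop,
                 free = c("mu_PR", "mu_NSR", "mu_SR"))
  expect_true(fit$converged)
  truth <- fix_pop$mean
  for (nm in c("mu_PR", "mu_NSR", "mu_SR")) {
    lat <- sub("mu_", "", nm)
    expect_lt(abs(fit$estimates[[nm]] - truth[[lat]]), 3 * fit$se[[nm]])
  }
})

test_that("stage-1 style fit recovers reassignment fractions on focused data", {
  # concentrate information: many subjects, leg-agility evaluations only,
  # fractions moved off their defaults in the generating truth
  map_truth <- fix_map
  map_truth$fr2[map_truth$item_id == 26] <- 0.6
  map_truth$fr3[map_truth$item_id == 26] <- 0.15
  des <- list(name = "frtoy", n_subjects = 250, population = "early",
              visit_weeks = 0, arms = c(all = 1))
  d <- simulate_trial(des, fix_pop, fix_bank, map_truth, seed = 71,
                      items = c("26.right", "26.left", "03.single",
                                "18.single"))
  fit <- irm_fit(d, fix_bank, fix_map, start = fix_pop,
                 free = c("fr2_26", "fr3_26"))
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["fr2_26"]] - 0.6),
            3 * max(fit$se[["fr2_26"]], 0.02))
  expect_lt(abs(fit$estimates[["fr3_26"]] - 0.15),
            3 * max(fit$se[["fr3_26"]], 0.02))
})

test_that("empirical Bayes estimates behave like posterior summaries", {
  des <- list(name = "toy", n_subjects = 8, population = "early",
              visit_weeks = 0, arms = c(all = 1))
  d <- simulate_trial(des, fix_pop, fix_bank, fix_map, seed = 81)
  eb <- empirical_bayes(d, fix_pop, fix_bank, fix_map)
  expect_equal(nrow(eb), 8)
  expect_true(all(eb$p_right >= 0 & eb$p_right <= 1))
  # subject with all patient-reported records missing: PR mode shrinks to
  # the population mean (eta ~ 0 up to cross-latent correlation pull)
  d2 <- d[d$ID == 1, ]
  d2$MDV[d2$ITEM <= 17] <- 1L
  pop_uncor <- default_population(correlation_early = diag(3))
  eb2 <- empirical_bayes(d2, pop_uncor, fix_bank, fix_map)
  expect_lt(abs(eb2$eta_PR), 1e-6)
  expect_equal(eb2$D0_PR, pop_uncor$mean[["PR"]], tolerance = 1e-6)
  # exaggerated right-side disability drives the responsibility right
  tab <- build_item_table()
  sr_right <- tab$key[tab$sidedness == "right"]
  sr_left <- tab$key[tab$sidedness == "left"]
  d3 <- d[d$ID == 2, ]
  key3 <- sprintf("%02d.%s", d3$ITEM, d3$SUB)
  d3$DV[key3 %in% sr_right] <- 4L
  d3$DV[key3 %in% sr_left] <- 0L
  eb3 <- empirical_bayes(d3, fix_pop, fix_bank, fix_map)
  expect_gt(eb3$p_right, 0.5)
  expect_equal(eb3$dominant_side, "right")
})
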
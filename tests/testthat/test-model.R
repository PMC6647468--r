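test_that("graded-response curves evaluate the logistic formula", {
  # logistic at its location: P(Y >= k) = 0.5 when D = b_k
  b <- c(-1, 0, 1, 2)
  for (k in 1:4) {
    p <- category_probabilities(1.7, b, b[k])
    expect_equal(sum(p[(k + 1):5]), 0.5, tolerance = 1e-12)
  }
  # hand-evaluated example
  expect_equal(unname(category_probabilities(1, c(-1, 0, 1, 2), 0)),
               c(0.269, 0.231, 0.231, 0.150, 0.119), tolerance = 2e-3)
  # limits
  expect_equal(unname(category_probabilities(2, b, -40))[1], 1,
               tolerance = 1e-10)
  expect_equal(unname(category_probabilities(2, b, 40))[5], 1,
               tolerance = 1e-10)
  expect_error(category_probabilities(-1, b, 0), "positive")
  expect_error(category_probabilities(1, c(0, -1, 1, 2), 0), "increasing")
})

test_that("probabilities sum to one and expected score is monotone in D", {
  set.seed(99)
  for (r in 1:100) {
    a <- stats::runif(1, 0.3, 3)
    b <- sort(stats::rnorm(4, 0.5, 1.5))
    if (any(diff(b) <= 0)) next
    D <- sort(stats::rnorm(7, 0, 2))
    p <- category_probabilities(a, b, D)
    expect_equal(rowSums(p), rep(1, 7), tolerance = 1e-12)
    es <- expected_score(p)
    expect_true(all(diff(es) >= -1e-12))
    # every exceedance curve increasing in D
    cum <- t(apply(p, 1, function(x) rev(cumsum(rev(x)))))
    expect_true(all(apply(cum[, 2:5], 2, diff) >= -1e-12))
  }
})

test_that("effective disability composes baseline, shifts and slope", {
  pop <- fix_pop
  subj <- list(eta_baseline = c(PR = 0.4, NSR = -0.2, SR = 0.1),
               eta_s1 = 0.05, eta_slope = c(PR = 0, NSR = 0, SR = 0.001),
               dominant_side = "right")
  # reference case: early study, PR, t = 0 -> mean + eta only
  expect_equal(effective_disability(subj, pop,
                                    list(latent = "PR", evaluated_side = "none",
                                         study = "early", time = 0)),
               pop$mean[["PR"]] + 0.4)
  # SR same side, advanced: + S4
  expect_equal(effective_disability(subj, pop,
                                    list(latent = "SR", evaluated_side = "right",
                                         study = "advanced", time = 0)),
               pop$mean[["SR"]] + 0.1 + pop$S4)
  # SR different side, advanced: + S1 + eta_s1 + S5
  expect_equal(effective_disability(subj, pop,
                                    list(latent = "SR", evaluated_side = "left",
                                         study = "advanced", time = 0)),
               pop$mean[["SR"]] + 0.1 + pop$S1 + 0.05 + pop$S5)
  # same-side disability exceeds different-side (S1 < 0 dominates)
  same <- effective_disability(subj, pop,
                               list(latent = "SR", evaluated_side = "right",
                                    study = "early", time = 0))
  diff <- effective_disability(subj, pop,
                               list(latent = "SR", evaluated_side = "left",
                                    study = "early", time = 0))
  expect_gt(same, diff)
  # progression contribution: slope x time
  d24 <- effective_disability(subj, pop,
                              list(latent = "SR", evaluated_side = "right",
                                   study = "advanced", time = 24))
  expect_equal(d24 - (pop$mean[["SR"]] + 0.1 + pop$S4),
               (pop$slope_mean[["SR_same"]] + 0.001) * 24)
  expect_equal(unname(pop$slope_mean[["SR_same"]] * 24), -0.2256)
  # inconsistent context
  expect_error(effective_disability(subj, pop,
                                    list(latent = "PR", evaluated_side = "right",
                                         study = "early", time = 0)),
               "evaluated_side")
})

test_that("response distribution routes through the mapping pathways", {
  bank <- fix_bank
  map <- fix_map
  # indirect item with zero fractions reduces to the direct pathway
  map0 <- map
  map0$fr2[] <- 0
  map0$fr3[] <- 0
  i <- match("26.left", bank$key)
  direct <- category_probabilities(bank$a[i],
                                   as.numeric(bank[i, c("b1", "b2", "b3", "b4")]),
                                   0.7)
  expect_equal(response_distribution("26.left", 0.7, bank, map0),
               direct, tolerance = 1e-12)
  # with fractions the result is the reassigned vector
  expect_equal(response_distribution("26.left", 0.7, bank, map),
               reassign_probabilities(direct, 0.3, 0.3), tolerance = 1e-12)
  # exclusive item uses its own (estimated) curve
  expect_equal(bank$provenance[match("13.single", bank$key)], "estimated")
  p13 <- response_distribution("13.single", 0.2, bank, map)
  expect_equal(sum(p13), 1, tolerance = 1e-12)
  expect_error(response_distribution("99.single", 0, bank, map), "not found")
})

test_that("mixture marginal is the pi-weighted side average", {
  pop1 <- default_population(mixture_pi = 0.9999)
  f <- function(s) if (s == "right") 0.2 else 0.1
  expect_equal(mixture_marginal(f, pop1), 0.2, tolerance = 1e-3)
  expect_equal(mixture_marginal(function(s) 0.37, fix_pop), 0.37)
  expect_equal(mixture_marginal(f, default_population(mixture_pi = 0.58)),
               0.158, tolerance = 1e-12)
})
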
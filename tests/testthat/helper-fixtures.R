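# Shared fixtures: a fixed synthetic item bank, default mapping and truth
# population, plus small helpers used across test files.

fix_bank <- generate_fixture_bank(seed = 7)
fix_map <- default_mapping()
fix_pop <- default_population()

# Small two-population baseline dataset
sim_baseline <- function(n_early, n_advanced, seed, pop = fix_pop,
                         bank = fix_bank, map = fix_map) {
  pres <- make_presets(n_early = n_early, n_advanced = n_advanced)
  d <- rbind(
    simulate_trial(pres$study168_baseline, pop, bank, map, seed = seed),
    simulate_trial(pres$study169_baseline, pop, bank, map, seed = seed + 1))
  d$ID <- paste0(d$STUDY, "_", d$ID)
  d
}

# Dense-grid marginal likelihood over the two non-sided latents, for toy
# subjects whose records involve only PR and NSR items at baseline.
# Independent of the package's Laplace/quadrature machinery: it evaluates
# the logistic curves directly and integrates by trapezoid summation.
oracle_loglik_2d <- function(data, pop, bank, map, grid_n = 301, lim = 6) {
  gr <- seq(-lim, lim, length.out = grid_n)
  w <- gr[2] - gr[1]
  V <- pop$variance[1:2]
  C <- pop$correlation_early[1:2, 1:2]
  Sig <- C * tcrossprod(sqrt(V))
  Si <- solve(Sig)
  E <- expand.grid(e1 = gr, e2 = gr)
  dens <- exp(-0.5 * (Si[1, 1] * E$e1^2 + 2 * Si[1, 2] * E$e1 * E$e2 +
                        Si[2, 2] * E$e2^2)) / (2 * pi * sqrt(det(Sig)))
  per_subject <- function(sd1) {
    lik <- rep(1, nrow(E))
    for (r in seq_len(nrow(sd1))) {
      key <- sprintf("%02d.%s", sd1$ITEM[r], sd1$SUB[r])
      i <- match(key, bank$key)
      stopifnot(bank$latent[i] %in% c("PR", "NSR"))
      D <- pop$mean[[bank$latent[i]]] +
        (if (bank$latent[i] == "PR") E$e1 else E$e2)
      cum <- stats::plogis(bank$a[i] *
                             outer(D, as.numeric(bank[i, c("b1", "b2", "b3", "b4")]), "-"))
      p5 <- cbind(1 - cum[, 1], cum[, 1] - cum[, 2], cum[, 2] - cum[, 3],
                  cum[, 3] - cum[, 4], cum[, 4])
      if (bank$mapping[i] == "indirect") {
        j <- match(bank$item_id[i], map$item_id)
        p5 <- cbind(p5[, 1], p5[, 2] + p5[, 3] * map$fr2[j],
                    p5[, 3] * (1 - map$fr2[j]) + p5[, 4] * map$fr3[j],
                    p5[, 4] * (1 - map$fr3[j]), p5[, 5])
      }
      lik <- lik * p5[, sd1$DV[r] + 1]
    }
    log(sum(lik * dens) * w^2)
  }
  sum(vapply(split(data, data$ID), per_subject, 0))
}

pr_nsr_keys <- c("01.single", "03.single", "06.single", "18.single",
                 "19.single")
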
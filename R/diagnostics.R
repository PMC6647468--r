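# Simulation-based model diagnostics: per-item mean-score checks, residual
# correlation matrices, and visual predictive checks on latent-variable
# subscores. All diagnostics condition on the observed covariate structure
# (subjects, studies, visit layout, missingness pattern) and are pure
# functions of (data, parameters, seed).

# Precomputed layout of the usable records of a dataset.
.layout <- function(data, bank, mapping) {
  d <- .coerce_dataset(data)
  use <- which(d$MDV == 0)
  du <- d[use, , drop = FALSE]
  key <- sprintf("%02d.%s", du$ITEM, du$SUB)
  bi <- match(key, bank$key)
  if (anyNA(bi)) stop("records reference evaluations absent from the bank")
  subjects <- unique(du$ID)
  list(d = d, use = use, du = du, key = key, bi = bi,
       subjects = subjects, si = match(du$ID, subjects),
       lat = match(bank$latent[bi], .LATENTS),
       sided = match(bank$sidedness[bi], c("none", "right", "left")) - 1L,
       ind = bank$mapping[bi] == "indirect",
       fr_row = match(bank$item_id[bi], mapping$item_id),
       a = bank$a[bi],
       bmat = as.matrix(bank[bi, c("b1", "b2", "b3", "b4")]),
       adv = du$STUDY == "advanced", time = du$TIME)
}

# Simulate R replicate response vectors for the usable records of one
# subject, drawing fresh latents per replicate. Returns an nrec x R matrix.
.sim_subject_reps <- function(rows, lay, pop, mapping, R, seed_i) {
  nrec <- length(rows)
  adv <- lay$adv[rows[1]]
  lat <- lay$lat[rows]
  sided <- lay$sided[rows]
  time <- lay$time[rows]
  set.seed(seed_i)
  side <- ifelse(stats::runif(R) < pop$mixture_pi, 1L, 2L)
  v <- if (adv) pop$adv_variance else pop$variance
  C <- if (adv) pop$correlation_advanced else pop$correlation_early
  Lb <- t(chol(C * tcrossprod(sqrt(v))))
  etaB <- Lb %*% matrix(stats::rnorm(3 * R), 3, R)
  eta_s1 <- if (pop$S1_variance > 0)
    stats::rnorm(R, 0, sqrt(pop$S1_variance)) else numeric(R)
  etaS <- matrix(stats::rnorm(3 * R, 0, sqrt(pop$slope_variance)), 3, R)
  latR <- rep(lat, R)
  timeR <- rep(time, R)
  repidx <- rep(seq_len(R), each = nrec)
  sideR <- side[repidx]
  sidedR <- rep(sided, R)
  comboR <- ifelse(sidedR == 0L, 0L, ifelse(sidedR == sideR, 1L, 2L))
  D <- .fixed_offset(latR, comboR, timeR, adv, pop) +
    etaB[cbind(latR, repidx)] + ifelse(comboR == 2L, eta_s1[repidx], 0) +
    etaS[cbind(latR, repidx)] * timeR
  indR <- rep(lay$ind[rows], R)
  frr <- lay$fr_row[rows][lay$ind[rows]]
  p5 <- .rec_probs(rep(lay$a[rows], R),
                   lay$bmat[rows, , drop = FALSE][rep(seq_len(nrec), R), ,
                                                  drop = FALSE],
                   indR, rep(mapping$fr2[frr], R), rep(mapping$fr3[frr], R),
                   D, order = 0L)$p5
  matrix(.sample_cat(p5, stats::runif(length(D))), nrec, R)
}

# One replicate dataset on the observed layout (used by simulate.irm_fit).
.resimulate_layout <- function(data, pop, bank, mapping, seed) {
  lay <- .layout(data, bank, mapping)
  d <- lay$d
  ynew <- rep(NA_integer_, nrow(d))
  for (i in seq_along(lay$subjects)) {
    rows <- which(lay$si == i)
    ynew[lay$use[rows]] <-
      .sim_subject_reps(rows, lay, pop, mapping, 1L, .subject_seed(seed, i))
  }
  d$DV <- ynew
  d
}

# Expected scores at the empirical-Bayes mode (MAP side class), aligned to
# the rows of `data` (NA for missing records).
.expected_scores_eb <- function(data, pop, bank, mapping,
                                control = irm_control()) {
  data <- validate_dataset(data)
  ctx <- .build_context(data, bank, mapping, pop)
  res <- .eval_loglik(ctx, pop, bank, mapping, control, want_eb = TRUE)
  dims <- ctx$dims
  use <- which(data$MDV == 0)
  expd <- rep(NA_real_, nrow(data))
  it_all <- NULL
  for (e in res$eb) {
    g <- e$group
    map_side <- ifelse(e$p_right >= 0.5, 1L, 2L)
    it <- .group_items(g, bank, mapping)
    for (side in 1:2) {
      subj_side <- which(map_side == side)
      if (length(subj_side) == 0) next
      cls <- g$classes[[side]]
      attr(cls, "dims") <- dims
      off <- .fixed_offset(g$lat, cls$combo, g$time, g$adv, pop)
      D <- .rec_D(g, cls, off, e$modes[[side]], dims)
      rows <- which(g$si %in% subj_side)
      p5 <- .rec_probs(it$a[rows], it$bmat[rows, , drop = FALSE],
                       it$ind[rows], it$fr2[.ind_sub(it$ind, rows)],
                       it$fr3[.ind_sub(it$ind, rows)], D[rows], order = 0L)$p5
      expd[use[g$rec[rows]]] <- drop(p5 %*% (0:4))
    }
  }
  expd
}

#' Per-item simulated-mean diagnostic
#'
#' For each of the 44 evaluations and each population stratum, compares the
#' observed mean score with the distribution of mean scores across
#' simulation replicates of the fitted (or supplied) model, conditioning on
#' the observed record layout. The default 200 replicates give a 95%
#' simulation band per item.
#'
#' @param data Long-format dataset.
#' @param pop Population parameters (e.g. \code{fit$population}).
#' @param bank Item parameter bank.
#' @param mapping Reassignment specification.
#' @param replicates Number of simulation replicates (>= 2).
#' @param seed Integer seed; results are bit-reproducible given the seed.
#' @return A data frame of class \code{irm_item_check} with one row per
#'   evaluation x stratum: \code{key}, \code{stratum}, \code{observed_mean},
#'   \code{pi_low}, \code{pi_high} (2.5th/97.5th percentiles of the
#'   replicate means), \code{covered}, and the replicate means as attribute
#'   \code{simulated}.
#' @export
item_mean_check <- function(data, pop = default_population(),
                            bank = generate_fixture_bank(),
                            mapping = default_mapping(),
                            replicates = 200L, seed = 1L) {
  stopifnot(replicates >= 2)
  data <- validate_dataset(data)
  lay <- .layout(data, bank, mapping)
  keys <- bank$key[lay$bi]
  strata <- unique(lay$du$STUDY)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  out <- list()
  sims <- list()
  for (st in strata) {
    in_st <- lay$du$STUDY == st
    item_f <- factor(keys[in_st], levels = bank$key)
    obs_mean <- tapply(lay$du$DV[in_st], item_f, mean)
    n_item <- table(item_f)
    sums <- matrix(0, nlevels(item_f), replicates,
                   dimnames = list(levels(item_f), NULL))
    for (i in which(lay$subjects %in% unique(lay$du$ID[in_st]))) {
      rows <- which(lay$si == i)
      y <- .sim_subject_reps(rows, lay, pop, mapping, replicates,
                             .subject_seed(seed, i))
      contrib <- rowsum(y, keys[rows])
      sums[rownames(contrib), ] <- sums[rownames(contrib), ] + contrib
    }
    means <- sums / as.numeric(n_item)
    present <- as.numeric(n_item) > 0
    if (any(!present))
      warning("evaluation(s) absent from stratum ", st, ": ",
              paste(levels(item_f)[!present], collapse = ", "))
    # type = 1 (inverse ECDF): at 2 replicates the band is exactly min/max
    qs <- apply(means[present, , drop = FALSE], 1, stats::quantile,
                probs = c(0.025, 0.975), names = FALSE, type = 1)
    df <- data.frame(key = levels(item_f)[present], stratum = st,
                     observed_mean = as.numeric(obs_mean[present]),
                     pi_low = qs[1, ], pi_high = qs[2, ])
    df$covered <- df$observed_mean >= df$pi_low & df$observed_mean <= df$pi_high
    out[[st]] <- df
    sims[[st]] <- means[present, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "simulated") <- sims
  attr(res, "replicates") <- as.integer(replicates)
  class(res) <- c("irm_item_check", "data.frame")
  res
}

#' @export
plot.irm_item_check <- function(x, ...) {
  strata <- unique(x$stratum)
  op <- graphics::par(mfrow = c(length(strata), 1),
                      mar = c(7, 4, 2, 1))
  on.exit(graphics::par(op))
  for (st in strata) {
    d <- x[x$stratum == st, ]
    n <- nrow(d)
    graphics::plot(seq_len(n), d$observed_mean, ylim = c(0, 4), pch = 19,
                   col = ifelse(d$covered, "black", "red"), xaxt = "n",
                   xlab = "", ylab = "mean score", main = st, ...)
    graphics::segments(seq_len(n), d$pi_low, seq_len(n), d$pi_high,
                       col = "purple", lwd = 3)
    graphics::points(seq_len(n), d$observed_mean, pch = 19,
                     col = ifelse(d$covered, "black", "red"))
    graphics::axis(1, at = seq_len(n), labels = d$key, las = 2,
                   cex.axis = 0.6)
  }
  invisible(x)
}

#' Residual correlation matrix across items
#'
#' Per-record residuals (observed minus expected score at the
#' empirical-Bayes latent mode) are arranged subject-visit by evaluation
#' and their pairwise correlation matrix is returned. Under a
#' well-specified model the off-diagonal correlations are near zero.
#' Evaluations with constant residuals yield \code{NA} rows/columns (the
#' correlation is undefined, not zero).
#'
#' @inheritParams item_mean_check
#' @param control Likelihood control settings.
#' @return A 44 x 44 symmetric matrix (unit diagonal where defined) with
#'   evaluation keys as dimnames.
#' @export
residual_correlation <- function(data, pop = default_population(),
                                 bank = generate_fixture_bank(),
                                 mapping = default_mapping(),
                                 control = irm_control()) {
  data <- validate_dataset(data)
  expd <- .expected_scores_eb(data, pop, bank, mapping, control)
  use <- data$MDV == 0
  res <- data$DV - expd
  key <- sprintf("%02d.%s", data$ITEM, data$SUB)
  sv <- paste(data$ID, data$TIME)
  wide <- stats::reshape(
    data.frame(sv = sv[use], key = key[use], res = res[use]),
    idvar = "sv", timevar = "key", direction = "wide")
  m <- as.matrix(wide[, -1, drop = FALSE])
  colnames(m) <- sub("^res\\.", "", colnames(m))
  keep <- intersect(bank$key, colnames(m))
  m <- m[, keep, drop = FALSE]
  cc <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  cc[sds == 0 | is.na(sds), ] <- NA_real_
  cc[, sds == 0 | is.na(sds)] <- NA_real_
  diag(cc)[sds > 0 & !is.na(sds)] <- 1
  cc
}

#' Visual predictive check on latent-variable subscores
#'
#' Sums observed scores into the three latent-variable subscores
#' (\code{PR_Score}, 17 items, range 0-68; \code{NSR_Score}, 9 evaluations,
#' range 0-36; \code{SR_Score}, 18 evaluations, range 0-72) and the total
#' score, then compares, per visit week, the observed median and 2.5th and
#' 97.5th percentiles across subjects with 95% prediction intervals
#' obtained from simulation replicates of the model on the observed
#' layout. The default 500 replicates match routine practice; fewer are
#' adequate for quick checks.
#'
#' @inheritParams item_mean_check
#' @return A data frame of class \code{irm_vpc}, one row per stratum x
#'   time x statistic: \code{observed}, \code{sim_median}, \code{pi_low},
#'   \code{pi_high}, \code{covered}.
#' @export
vpc_check <- function(data, pop = default_population(),
                      bank = generate_fixture_bank(),
                      mapping = default_mapping(),
                      replicates = 500L, seed = 1L) {
  stopifnot(replicates >= 2)
  data <- validate_dataset(data)
  lay <- .layout(data, bank, mapping)
  sv <- paste(lay$du$ID, lay$du$TIME)
  svi <- match(sv, unique(sv))
  n_sv <- max(svi)
  sv_time <- lay$du$TIME[match(unique(sv), sv)]
  strat_names <- c("PR_Score", "NSR_Score", "SR_Score", "Total")
  masks <- cbind(lay$lat == 1, lay$lat == 2, lay$lat == 3, TRUE)

  score_sv <- function(y) {
    vapply(1:4, function(s) {
      as.numeric(rowsum(y * masks[, s], svi))
    }, numeric(n_sv))
  }
  obs_scores <- score_sv(lay$du$DV)

  # replicate subscores: array [subject-visit, stratum, replicate]
  simsc <- array(0, dim = c(n_sv, 4, replicates))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  for (i in seq_along(lay$subjects)) {
    rows <- which(lay$si == i)
    y <- .sim_subject_reps(rows, lay, pop, mapping, replicates,
                           .subject_seed(seed, i))
    svr <- svi[rows]
    for (s in 1:4) {
      contrib <- rowsum(y * masks[rows, s], svr)
      simsc[sort(unique(svr)), s, ] <-
        simsc[sort(unique(svr)), s, ] + contrib
    }
  }

  stats_of <- function(x) c(median = stats::median(x),
                            q2.5 = unname(stats::quantile(x, 0.025)),
                            q97.5 = unname(stats::quantile(x, 0.975)))
  bins <- sort(unique(sv_time))
  out <- list()
  for (s in 1:4) {
    for (tb in bins) {
      rows <- which(sv_time == tb)
      if (length(rows) == 0) {
        warning("empty time bin dropped: week ", tb)
        next
      }
      obs <- stats_of(obs_scores[rows, s])
      sim <- apply(simsc[rows, s, , drop = FALSE], 3,
                   function(x) stats_of(x))      # 3 x R
      for (k in seq_along(obs)) {
        pi_k <- stats::quantile(sim[k, ], c(0.025, 0.975), names = FALSE)
        out[[length(out) + 1]] <- data.frame(
          stratum = strat_names[s], time = tb, statistic = names(obs)[k],
          observed = obs[k], sim_median = stats::median(sim[k, ]),
          pi_low = pi_k[1], pi_high = pi_k[2],
          covered = obs[k] >= pi_k[1] & obs[k] <= pi_k[2])
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "replicates") <- as.integer(replicates)
  class(res) <- c("irm_vpc", "data.frame")
  res
}

#' @export
plot.irm_vpc <- function(x, statistic = "median", ...) {
  d <- x[x$statistic == statistic, ]
  strata <- unique(d$stratum)
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (st in strata) {
    ds <- d[d$stratum == st, ]
    ylim <- range(c(ds$observed, ds$pi_low, ds$pi_high))
    graphics::plot(ds$time, ds$observed, type = "b", pch = 19, ylim = ylim,
                   xlab = "week", ylab = statistic, main = st, ...)
    graphics::polygon(c(ds$time, rev(ds$time)),
                      c(ds$pi_low, rev(ds$pi_high)),
                      col = grDevices::adjustcolor("skyblue", 0.4),
                      border = NA)
    graphics::lines(ds$time, ds$observed, type = "b", pch = 19)
  }
  invisible(x)
}
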
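#' Control settings for model fitting and likelihood evaluation
#'
#' @param nodes Gauss-Hermite nodes per random-effect dimension; 1 (the
#'   default) is the pure Laplace approximation, larger values refine the
#'   integral by adaptive quadrature centered at the per-subject mode
#'   (practical only for low-dimensional problems: the grid is a tensor
#'   product).
#' @param tol Relative convergence tolerance of the outer optimizer.
#' @param max_iter Outer iteration cap.
#' @param newton_tol,newton_max Convergence tolerance and iteration cap of
#'   the inner (per-subject mode) Newton search.
#' @param se Compute standard errors from the numeric Hessian of the
#'   marginal log-likelihood at the optimum.
#' @param include_correlations Free the latent correlation matrices in the
#'   stage-2 preset (off by default).
#' @param verbose Print objective values during optimization.
#' @return A list of class \code{irm_control}.
#' @export
irm_control <- function(nodes = 1L, tol = 1e-6, max_iter = 300L,
                        newton_tol = 1e-7, newton_max = 50L, se = TRUE,
                        include_correlations = FALSE, verbose = FALSE) {
  stopifnot(nodes >= 1, tol > 0)
  structure(list(nodes = as.integer(nodes), tol = tol,
                 max_iter = as.integer(max_iter), newton_tol = newton_tol,
                 newton_max = as.integer(newton_max), se = se,
                 include_correlations = include_correlations,
                 verbose = verbose),
            class = "irm_control")
}

# ---- parameter vector <-> model objects --------------------------------

.param_template <- function(pop, bank, mapping) {
  v <- c(mu_PR = unname(pop$mean["PR"]), mu_NSR = unname(pop$mean["NSR"]),
         mu_SR = unname(pop$mean["SR"]),
         var_PR = unname(pop$variance["PR"]),
         var_NSR = unname(pop$variance["NSR"]),
         var_SR = unname(pop$variance["SR"]),
         advvar_PR = unname(pop$adv_variance["PR"]),
         advvar_NSR = unname(pop$adv_variance["NSR"]),
         advvar_SR = unname(pop$adv_variance["SR"]),
         S1 = pop$S1, S1_var = pop$S1_variance,
         S2 = pop$S2, S3 = pop$S3, S4 = pop$S4, S5 = pop$S5,
         pi = pop$mixture_pi,
         slope_PR = unname(pop$slope_mean["PR"]),
         slope_NSR = unname(pop$slope_mean["NSR"]),
         slope_SR_same = unname(pop$slope_mean["SR_same"]),
         slope_SR_diff = unname(pop$slope_mean["SR_diff"]),
         slopevar_PR = unname(pop$slope_variance["PR"]),
         slopevar_NSR = unname(pop$slope_variance["NSR"]),
         slopevar_SR = unname(pop$slope_variance["SR"]))
  rho <- c()
  for (st in c("early", "advanced")) {
    cm <- if (st == "early") pop$correlation_early else pop$correlation_advanced
    rho <- c(rho, stats::setNames(
      c(cm[1, 2], cm[1, 3], cm[2, 3]),
      paste0("rho_", c("PR_NSR", "PR_SR", "NSR_SR"), "_", st)))
  }
  fr <- c(stats::setNames(mapping$fr2, paste0("fr2_", mapping$item_id)),
          stats::setNames(mapping$fr3, paste0("fr3_", mapping$item_id)))
  icc <- c()
  bm <- as.matrix(bank[, c("b1", "b2", "b3", "b4")])
  icc <- c(stats::setNames(bank$a, paste0("a_", bank$key)),
           stats::setNames(bm[, 1], paste0("b1_", bank$key)),
           stats::setNames(bm[, 2] - bm[, 1], paste0("d2_", bank$key)),
           stats::setNames(bm[, 3] - bm[, 2], paste0("d3_", bank$key)),
           stats::setNames(bm[, 4] - bm[, 3], paste0("d4_", bank$key)))
  c(v, rho, fr, icc)
}

.apply_params <- function(v, pop, bank, mapping) {
  pop$mean <- c(PR = v[["mu_PR"]], NSR = v[["mu_NSR"]], SR = v[["mu_SR"]])
  pop$variance <- c(PR = v[["var_PR"]], NSR = v[["var_NSR"]],
                    SR = v[["var_SR"]])
  pop$adv_variance <- c(PR = v[["advvar_PR"]], NSR = v[["advvar_NSR"]],
                        SR = v[["advvar_SR"]])
  pop$S1 <- v[["S1"]]; pop$S1_variance <- v[["S1_var"]]
  pop$S2 <- v[["S2"]]; pop$S3 <- v[["S3"]]
  pop$S4 <- v[["S4"]]; pop$S5 <- v[["S5"]]
  pop$mixture_pi <- v[["pi"]]
  pop$slope_mean <- c(PR = v[["slope_PR"]], NSR = v[["slope_NSR"]],
                      SR_same = v[["slope_SR_same"]],
                      SR_diff = v[["slope_SR_diff"]])
  pop$slope_variance <- c(PR = v[["slopevar_PR"]], NSR = v[["slopevar_NSR"]],
                          SR = v[["slopevar_SR"]])
  for (st in c("early", "advanced")) {
    cm <- diag(3)
    cm[1, 2] <- cm[2, 1] <- v[[paste0("rho_PR_NSR_", st)]]
    cm[1, 3] <- cm[3, 1] <- v[[paste0("rho_PR_SR_", st)]]
    cm[2, 3] <- cm[3, 2] <- v[[paste0("rho_NSR_SR_", st)]]
    dimnames(cm) <- dimnames(pop$correlation_early)
    if (st == "early") pop$correlation_early <- cm
    else pop$correlation_advanced <- cm
  }
  mapping$fr2 <- unname(v[paste0("fr2_", mapping$item_id)])
  mapping$fr3 <- unname(v[paste0("fr3_", mapping$item_id)])
  bank$a <- unname(v[paste0("a_", bank$key)])
  b1 <- unname(v[paste0("b1_", bank$key)])
  b2 <- b1 + unname(v[paste0("d2_", bank$key)])
  b3 <- b2 + unname(v[paste0("d3_", bank$key)])
  b4 <- b3 + unname(v[paste0("d4_", bank$key)])
  bank$b1 <- b1; bank$b2 <- b2; bank$b3 <- b3; bank$b4 <- b4
  list(pop = pop, bank = bank, mapping = mapping)
}

# Transform classes keeping natural constraints on an unconstrained scale:
# log for positives (variances, S2-S5, discriminations, threshold gaps),
# negated log for S1 <= 0, logit for probabilities and fractions, atanh for
# correlations, identity otherwise.
.par_class <- function(name) {
  if (name == "S1") return("neglog")
  if (grepl("^(S[2-5]$|var_|advvar_|slopevar_|S1_var$|a_|d[234]_)", name))
    return("log")
  if (name == "pi" || grepl("^fr[23]_", name)) return("logit")
  if (grepl("^rho_", name)) return("atanh")
  "identity"
}

.to_unc <- function(name, value) {
  switch(.par_class(name),
    log = {
      if (value <= 0) stop("parameter '", name,
                           "' must be positive to be estimated")
      log(value)
    },
    neglog = {
      if (value >= 0) stop("parameter '", name,
                           "' must be negative to be estimated")
      log(-value)
    },
    logit = stats::qlogis(min(max(value, 1e-8), 1 - 1e-8)),
    atanh = atanh(min(max(value, -1 + 1e-8), 1 - 1e-8)),
    value)
}

.from_unc <- function(name, x) {
  switch(.par_class(name),
    log = exp(x), neglog = -exp(x), logit = stats::plogis(x),
    atanh = tanh(x), x)
}

# |d natural / d unconstrained| for delta-method standard errors
.dnat_dunc <- function(name, value) {
  switch(.par_class(name),
    log = abs(value), neglog = abs(value),
    logit = value * (1 - value), atanh = 1 - value^2, 1)
}

.stage_free <- function(stage, bank, mapping, control) {
  switch(stage,
    stage1_mapping_and_exclusive = {
      excl <- bank$key[bank$mapping == "exclusive"]
      c(paste0("fr2_", mapping$item_id), paste0("fr3_", mapping$item_id),
        paste0("a_", excl), paste0("b1_", excl), paste0("d2_", excl),
        paste0("d3_", excl), paste0("d4_", excl),
        "mu_PR", "mu_NSR", "mu_SR", "var_PR", "var_NSR", "var_SR", "S1")
    },
    stage2_population_shifts = {
      base <- c("S1", "S2", "S3", "S4", "S5",
                "advvar_PR", "advvar_NSR", "advvar_SR")
      if (isTRUE(control$include_correlations))
        base <- c(base, paste0("rho_", c("PR_NSR", "PR_SR", "NSR_SR"),
                               "_early"),
                  paste0("rho_", c("PR_NSR", "PR_SR", "NSR_SR"), "_advanced"))
      base
    },
    longitudinal = "slope_SR_same",
    stop("unknown stage: ", stage))
}

# ---- fitting -----------------------------------------------------------

#' Fit the bridged item response model by marginal maximum likelihood
#'
#' Maximizes the Laplace (or adaptive-quadrature) marginal likelihood of a
#' long-format item-level dataset over a chosen set of free parameters,
#' holding all others fixed. Constraints are enforced by transparent
#' reparameterization: \code{S1 <= 0} via a negated log, \code{S2}-\code{S5},
#' variances, discriminations and threshold gaps via logs, the mixture
#' proportion and reassignment fractions via logits, correlations via
#' atanh (with a positive-definiteness barrier).
#'
#' Stage presets mirror the staged bridging workflow:
#' \describe{
#'   \item{\code{stage1_mapping_and_exclusive}}{reassignment fractions,
#'     ICC parameters of UPDRS-exclusive items, baseline latent means and
#'     variances, and S1;}
#'   \item{\code{stage2_population_shifts}}{S1 and the advanced-population
#'     shifts S2-S5 with the advanced variances (optionally the latent
#'     correlations, see \code{\link{irm_control}});}
#'   \item{\code{longitudinal}}{the progression slope of the sided latent
#'     for the same-side combination.}
#' }
#' An explicit \code{free} vector overrides the preset; \code{free =
#' character(0)} evaluates the likelihood at \code{start} without
#' optimizing. Subjects with no usable records are skipped with a warning.
#'
#' @param data Long-format dataset (see \code{\link{read_dataset}}).
#' @param bank Item parameter bank.
#' @param mapping Reassignment specification.
#' @param start Population parameters used as starting values and for all
#'   frozen parameters.
#' @param stage Stage preset name (see above), ignored when \code{free}
#'   is given.
#' @param free Character vector of parameter names to estimate.
#' @param control An \code{\link{irm_control}} list.
#' @return An object of class \code{irm_fit} with components
#'   \code{estimates}, \code{se}, \code{population} (updated),
#'   \code{bank}, \code{mapping}, \code{loglik}, \code{ofv}
#'   (\eqn{-2 \log L}), \code{converged}, \code{iterations},
#'   \code{n_subjects}, \code{n_observations} and \code{free}.
#' @seealso \code{\link{compare_models}}, \code{\link{empirical_bayes}},
#'   \code{\link{irm_loglik}}
#' @export
irm_fit <- function(data, bank = generate_fixture_bank(),
                    mapping = default_mapping(),
                    start = default_population(),
                    stage = c("stage2_population_shifts",
                              "stage1_mapping_and_exclusive",
                              "longitudinal"),
                    free = NULL, control = irm_control()) {
  cl <- match.call()
  data <- validate_dataset(data)
  validate_item_bank(bank)
  validate_mapping(mapping)
  validate_population(start)
  usable <- tapply(data$MDV == 0, data$ID, any)
  skipped <- names(usable)[!usable]
  if (length(skipped) > 0) {
    warning("skipping subject(s) with no usable records: ",
            paste(skipped, collapse = ", "))
    data <- data[!data$ID %in% skipped, , drop = FALSE]
  }
  if (is.null(free)) {
    stage <- match.arg(stage)
    free <- .stage_free(stage, bank, mapping, control)
  } else {
    stage <- "custom"
  }
  template <- .param_template(start, bank, mapping)
  unknown <- setdiff(free, names(template))
  if (length(unknown) > 0)
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))

  ctx <- .build_context(data, bank, mapping, start)
  vfull <- template
  rho_free <- any(grepl("^rho_", free))

  negll <- function(phi) {
    v <- vfull
    v[free] <- vapply(seq_along(free),
                      function(j) .from_unc(free[j], phi[j]), 0)
    if (rho_free) {
      for (st in c("early", "advanced")) {
        cm <- diag(3)
        cm[1, 2] <- cm[2, 1] <- v[[paste0("rho_PR_NSR_", st)]]
        cm[1, 3] <- cm[3, 1] <- v[[paste0("rho_PR_SR_", st)]]
        cm[2, 3] <- cm[3, 2] <- v[[paste0("rho_NSR_SR_", st)]]
        if (min(eigen(cm, symmetric = TRUE,
                      only.values = TRUE)$values) < 1e-6)
          return(1e10)
      }
    }
    upd <- .apply_params(v, start, bank, mapping)
    ll <- .eval_loglik(ctx, upd$pop, upd$bank, upd$mapping, control)$total
    if (!is.finite(ll)) return(1e10)
    if (control$verbose) cat(sprintf("  -2LL = %.4f\n", -2 * ll))
    -ll
  }

  n_subj <- length(ctx$subjects)
  if (length(free) == 0) {
    ll <- -negll(numeric(0))
    est <- numeric(0)
    se <- numeric(0)
    conv <- TRUE
    iters <- 0L
    evals <- 1L
  } else {
    phi0 <- vapply(free, function(nm) .to_unc(nm, template[[nm]]), 0)
    opt <- stats::nlminb(phi0, negll,
                         control = list(rel.tol = control$tol,
                                        iter.max = control$max_iter,
                                        eval.max = 10 * control$max_iter))
    ll <- -opt$objective
    est <- stats::setNames(
      vapply(seq_along(free), function(j) .from_unc(free[j], opt$par[j]), 0),
      free)
    conv <- opt$convergence == 0
    iters <- opt$iterations
    evals <- sum(opt$evaluations)
    se <- rep(NA_real_, length(free))
    names(se) <- free
    if (isTRUE(control$se)) {
      H <- tryCatch(stats::optimHess(opt$par, negll), error = function(e) NULL)
      if (!is.null(H)) {
        cov_unc <- tryCatch(solve(H), error = function(e) NULL)
        if (!is.null(cov_unc)) {
          dv <- diag(cov_unc)
          dv[dv < 0] <- NA_real_
          se_unc <- sqrt(dv)
          se <- se_unc * vapply(seq_along(free), function(j)
            .dnat_dunc(free[j], est[j]), 0)
          names(se) <- free
        }
      }
    }
    vfull[free] <- est
  }
  upd <- .apply_params(vfull, start, bank, mapping)

  structure(list(
    estimates = est, se = se, all_params = vfull,
    population = upd$pop, bank = upd$bank, mapping = upd$mapping,
    loglik = ll, ofv = -2 * ll, converged = conv,
    iterations = iters, evaluations = evals,
    n_subjects = n_subj, n_observations = ctx$n_obs,
    n_missing = ctx$n_missing, free = free, stage = stage,
    control = control, data = data, call = cl), class = "irm_fit")
}

#' Marginal log-likelihood of a dataset
#'
#' Evaluates the mixture-weighted marginal log-likelihood of a long-format
#' dataset under given population parameters, item bank and mapping, using
#' the same Laplace/adaptive-quadrature machinery as \code{\link{irm_fit}}.
#'
#' @inheritParams irm_fit
#' @param pop Population parameters.
#' @return Total log-likelihood (numeric scalar) with attribute
#'   \code{by_subject}.
#' @export
irm_loglik <- function(data, pop = default_population(),
                       bank = generate_fixture_bank(),
                       mapping = default_mapping(),
                       control = irm_control()) {
  data <- validate_dataset(data)
  ctx <- .build_context(data, bank, mapping, pop)
  res <- .eval_loglik(ctx, pop, bank, mapping, control)
  structure(res$total,
            by_subject = stats::setNames(res$by_subject, ctx$subjects))
}

#' Marginal log-likelihood of a single subject
#'
#' The per-subject building block of the total likelihood: the log of the
#' mixture-weighted integral, over the subject's random effects, of the
#' product of category probabilities for all usable records. A subject
#' with no usable (non-missing) records raises an error of class
#' \code{irm_no_data} rather than silently contributing zero.
#'
#' @param subject_data Long-format records of one subject.
#' @inheritParams irm_loglik
#' @return Log-likelihood (numeric scalar).
#' @export
subject_marginal_loglik <- function(subject_data, pop = default_population(),
                                    bank = generate_fixture_bank(),
                                    mapping = default_mapping(),
                                    control = irm_control()) {
  if (length(unique(subject_data$ID)) != 1)
    stop("subject_data must contain records of exactly one subject")
  if (nrow(subject_data) == 0 || all(subject_data$MDV == 1))
    stop(structure(class = c("irm_no_data", "error", "condition"),
                   list(message = "subject has no usable records",
                        call = sys.call())))
  as.numeric(irm_loglik(subject_data, pop, bank, mapping, control))
}

#' Likelihood-ratio and information-criterion model comparison
#'
#' For nested fits on the same data, reports the objective-function-value
#' difference \eqn{\Delta OFV = OFV_{reduced} - OFV_{full}}, its degrees of
#' freedom (difference in free-parameter count) and the chi-square p-value;
#' for non-nested fits, reports AIC values only.
#'
#' @param fit_reduced,fit_full Two \code{irm_fit} objects on identical
#'   data, the first with the smaller free-parameter set when
#'   \code{nested = TRUE}.
#' @param nested Are the models nested?
#' @return A list with \code{delta_ofv}, \code{df}, \code{p_value} (nested
#'   only) and \code{aic} (both models).
#' @export
compare_models <- function(fit_reduced, fit_full, nested = TRUE) {
  stopifnot(inherits(fit_reduced, "irm_fit"), inherits(fit_full, "irm_fit"))
  if (fit_reduced$n_observations != fit_full$n_observations ||
      fit_reduced$n_subjects != fit_full$n_subjects)
    stop("fits are not on identical data")
  k1 <- length(fit_reduced$free)
  k2 <- length(fit_full$free)
  aic <- c(reduced = fit_reduced$ofv + 2 * k1, full = fit_full$ofv + 2 * k2)
  if (!nested) return(list(aic = aic))
  if (k2 < k1) stop("fit_full must have at least as many free parameters")
  delta <- fit_reduced$ofv - fit_full$ofv
  df <- k2 - k1
  p <- if (df == 0) {
    if (abs(delta) < 1e-8) 1 else NA_real_
  } else stats::pchisq(delta, df, lower.tail = FALSE)
  list(delta_ofv = delta, df = df, p_value = p, aic = aic)
}

#' Empirical Bayes latent estimates and mixture responsibilities
#'
#' Posterior-mode random effects per subject (under the maximum a
#' posteriori side class) and the posterior probability that the subject's
#' more disabled side is the right side.
#'
#' @inheritParams irm_loglik
#' @return A data frame with one row per subject: \code{ID}, \code{study},
#'   \code{p_right}, \code{dominant_side} (MAP class), the baseline random
#'   effects \code{eta_PR}, \code{eta_NSR}, \code{eta_SR}, \code{eta_S1}
#'   (0 when the side-shift effect is disabled), slope effects when
#'   present, and the realized baseline disabilities \code{D0_PR},
#'   \code{D0_NSR}, \code{D0_SR} (sided latent under the same-side
#'   combination, study shifts included).
#' @export
empirical_bayes <- function(data, pop = default_population(),
                            bank = generate_fixture_bank(),
                            mapping = default_mapping(),
                            control = irm_control()) {
  data <- validate_dataset(data)
  ctx <- .build_context(data, bank, mapping, pop)
  res <- .eval_loglik(ctx, pop, bank, mapping, control, want_eb = TRUE)
  dims <- ctx$dims
  rows <- lapply(res$eb, function(e) {
    g <- e$group
    map_side <- ifelse(e$p_right >= 0.5, 1L, 2L)
    eta <- t(vapply(seq_len(g$n), function(i) e$modes[[map_side[i]]][i, ],
                    numeric(dims$d)))
    adv <- g$adv
    D0 <- cbind(
      pop$mean[["PR"]] + (if (adv) pop$S2 else 0) + eta[, 1],
      pop$mean[["NSR"]] + (if (adv) pop$S3 else 0) + eta[, 2],
      pop$mean[["SR"]] + (if (adv) pop$S4 else 0) + eta[, 3])
    out <- data.frame(ID = ctx$subjects[g$subj], study = g$study,
                      p_right = e$p_right,
                      dominant_side = c("right", "left")[map_side],
                      eta_PR = eta[, 1], eta_NSR = eta[, 2],
                      eta_SR = eta[, 3],
                      eta_S1 = if (dims$s1col > 0) eta[, dims$s1col] else 0,
                      D0_PR = D0[, 1], D0_NSR = D0[, 2], D0_SR = D0[, 3])
    for (m in dims$slope_latents)
      out[[paste0("eta_slope_", .LATENTS[m])]] <-
        eta[, dims$slopecols[[as.character(m)]]]
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$ID, ctx$subjects)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
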
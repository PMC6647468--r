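#' @export
print.irm_fit <- function(x, ...) {
  cat("Bridged item response model fit (", x$stage, ")\n", sep = "")
  cat(sprintf("  %d subjects, %d observations (%d missing records excluded)\n",
              x$n_subjects, x$n_observations, x$n_missing))
  cat(sprintf("  log-likelihood %.3f (OFV %.3f), %s after %d iterations\n",
              x$loglik, x$ofv,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  if (length(x$estimates) > 0) {
    cat("  estimates:\n")
    tab <- cbind(estimate = x$estimates, se = x$se)
    print(round(utils::head(tab, 20), 5))
    if (length(x$estimates) > 20)
      cat("  ... and", length(x$estimates) - 20, "more\n")
  } else cat("  (no free parameters: likelihood evaluation only)\n")
  invisible(x)
}

#' @export
summary.irm_fit <- function(object, ...) {
  z <- object$estimates / object$se
  coefs <- data.frame(estimate = object$estimates, se = object$se,
                      z = z, row.names = names(object$estimates))
  structure(list(fit = object, coefficients = coefs),
            class = "summary.irm_fit")
}

#' @export
print.summary.irm_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPopulation parameters after update:\n")
  print(x$fit$population)
  invisible(x)
}

#' @export
coef.irm_fit <- function(object, complete = FALSE, ...) {
  if (complete) object$all_params else object$estimates
}

#' @export
logLik.irm_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$free),
            nobs = object$n_observations, class = "logLik")
}

#' @export
vcov.irm_fit <- function(object, ...) {
  v <- diag(object$se^2, length(object$se))
  dimnames(v) <- list(names(object$estimates), names(object$estimates))
  v
}

#' Simulate replicate datasets from a fitted model
#'
#' Draws new subjects (sides, random effects and responses) for the same
#' record layout as the fitted data, at the fitted parameter values.
#'
#' @param object An \code{irm_fit}.
#' @param nsim Number of replicate datasets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of \code{nsim} long-format datasets.
#' @export
simulate.irm_fit <- function(object, nsim = 1, seed = 1L, ...) {
  lapply(seq_len(nsim), function(r)
    .resimulate_layout(object$data, object$population, object$bank,
                       object$mapping, seed = .subject_seed(seed, r)))
}

#' @export
fitted.irm_fit <- function(object, ...) {
  .expected_scores_eb(object$data, object$population, object$bank,
                      object$mapping, object$control)
}

#' Residuals of a fitted bridged item response model
#'
#' Per-record residual: observed score minus the model-expected score
#' \eqn{\sum_k k P(Y=k)} evaluated at the subject's empirical-Bayes latent
#' mode (records with missing responses give \code{NA}).
#'
#' @param object An \code{irm_fit}.
#' @param ... Unused.
#' @return Numeric vector aligned with the rows of the fitted data.
#' @export
residuals.irm_fit <- function(object, ...) {
  obs <- ifelse(object$data$MDV == 0, object$data$DV, NA_real_)
  obs - fitted(object)
}

#' Expected item scores at given latent disabilities
#'
#' @param object An \code{irm_fit}.
#' @param newdata Data frame with columns \code{key} (evaluation key) and
#'   \code{D} (latent disability); defaults to all 44 evaluations at
#'   \code{D}.
#' @param D Latent disability used when \code{newdata} is missing.
#' @param ... Unused.
#' @return \code{newdata} with columns \code{p0}..\code{p4} and
#'   \code{expected}.
#' @export
predict.irm_fit <- function(object, newdata = NULL, D = 0, ...) {
  if (is.null(newdata))
    newdata <- data.frame(key = object$bank$key, D = D)
  p <- t(vapply(seq_len(nrow(newdata)), function(i)
    response_distribution(newdata$key[i], newdata$D[i], object$bank,
                          object$mapping), numeric(5)))
  colnames(p) <- paste0("p", 0:4)
  cbind(newdata, p, expected = expected_score(p))
}

#' Diagnostic plot for a fitted model
#'
#' Item-mean diagnostic: observed per-item mean scores against the 95%
#' simulation band (see \code{\link{item_mean_check}}).
#'
#' @param x An \code{irm_fit}.
#' @param replicates Simulation replicates for the band.
#' @param seed Seed for the replicates.
#' @param ... Passed to \code{\link{plot.irm_item_check}}.
#' @return Invisibly, the \code{\link{item_mean_check}} table.
#' @export
plot.irm_fit <- function(x, replicates = 200L, seed = 1L, ...) {
  chk <- item_mean_check(x$data, x$population, x$bank, x$mapping,
                         replicates = replicates, seed = seed)
  plot(chk, ...)
  invisible(chk)
}
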
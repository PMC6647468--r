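#' Graded-response category probabilities
#'
#' Item characteristic curves of the graded response model. For an item with
#' discrimination \eqn{a} and ordered difficulties \eqn{b_k},
#' \deqn{P(Y \ge k \mid D) = \frac{e^{a (D - b_k)}}{1 + e^{a (D - b_k)}},}
#' and category probabilities follow by differencing,
#' \eqn{P(Y = k) = P(Y \ge k) - P(Y \ge k+1)} with \eqn{P(Y \ge 0) = 1}.
#' Higher latent disability \eqn{D} shifts mass towards more severe
#' categories; each exceedance probability is strictly increasing in D.
#'
#' @param a Discrimination, a positive scalar.
#' @param b Numeric vector of strictly increasing difficulty thresholds
#'   (one per response boundary; length K for K+1 categories).
#' @param D Latent disability value(s).
#' @return A matrix with \code{length(D)} rows and \code{length(b) + 1}
#'   columns of category probabilities (a plain vector if \code{D} is a
#'   scalar).
#' @examples
#' category_probabilities(a = 1, b = c(-1, 0, 1, 2), D = 0)
#' @export
category_probabilities <- function(a, b, D) {
  if (length(a) != 1 || !is.finite(a) || a <= 0)
    stop("discrimination 'a' must be a positive scalar")
  if (any(diff(b) <= 0)) stop("difficulties 'b' must be strictly increasing")
  cum <- stats::plogis(a * outer(D, b, "-"))        # |D| x K
  p <- cbind(1 - cum[, 1], -t(apply(cbind(cum, 0), 1, diff)))
  colnames(p) <- paste0("P", 0:length(b))
  if (length(D) == 1) p[1, ] else p
}

#' Expected item score
#'
#' The model-expected score \eqn{\sum_k k \, P(Y = k)} for one or more
#' category-probability vectors.
#'
#' @param p Category probabilities: a vector, or a matrix with categories in
#'   columns.
#' @return Numeric scalar or vector of expected scores.
#' @export
expected_score <- function(p) {
  if (is.null(dim(p))) {
    sum((seq_along(p) - 1) * p)
  } else {
    drop(p %*% (seq_len(ncol(p)) - 1))
  }
}

#' Effective latent disability for one evaluation
#'
#' Assembles the latent disability that drives one item evaluation,
#' \deqn{D_i(t) = D_{i,0} + \mathrm{Shift} + \mathrm{Slope}_i \, t,}
#' where \eqn{D_{i,0}} is the subject's baseline disability on the latent
#' variable (population mean plus subject random effect), the shift
#' collects the applicable population offsets, and the slope term adds
#' linear progression over time (weeks).
#'
#' Shifts by context: evaluations of the sided latent on the side opposite
#' the subject's more disabled side (the "different" combination) receive
#' S1 plus the subject's S1 random effect; subjects in the advanced study
#' additionally receive S2 (PR), S3 (NSR), or S4/S5 (SR, same/different
#' combination).
#'
#' @param subject List describing the subject: \code{eta_baseline} (named
#'   numeric, PR/NSR/SR), \code{dominant_side} ("right" or "left"), and
#'   optionally \code{eta_s1} (default 0) and \code{eta_slope} (named
#'   PR/NSR/SR, default 0).
#' @param pop An \code{\link{default_population}} object.
#' @param ctx Evaluation context: list with \code{latent} ("PR", "NSR" or
#'   "SR"), \code{evaluated_side} ("none", "right" or "left"),
#'   \code{study} ("early" or "advanced") and \code{time} (weeks, >= 0).
#' @return The latent disability value (numeric scalar).
#' @examples
#' pop <- default_population()
#' subj <- list(eta_baseline = c(PR = 0, NSR = 0, SR = 0.5),
#'              dominant_side = "right")
#' ctx <- list(latent = "SR", evaluated_side = "right",
#'             study = "advanced", time = 0)
#' effective_disability(subj, pop, ctx)  # 0.353 + 0.5 + S4
#' @export
effective_disability <- function(subject, pop, ctx) {
  latent <- match.arg(ctx$latent, c("PR", "NSR", "SR"))
  side <- match.arg(ctx$evaluated_side %||% "none", c("none", "right", "left"))
  study <- match.arg(ctx$study %||% "early", c("early", "advanced"))
  time <- ctx$time %||% 0
  if (time < 0) stop("time must be non-negative (weeks since baseline)")
  if ((latent == "SR") != (side != "none"))
    stop("evaluated_side must be set for SR evaluations and 'none' otherwise")
  dom <- match.arg(subject$dominant_side, c("right", "left"))
  combo <- if (latent != "SR") "none" else if (side == dom) "same" else "different"

  D <- pop$mean[[latent]] + subject$eta_baseline[[latent]]
  if (combo == "different")
    D <- D + pop$S1 + (subject$eta_s1 %||% 0)
  if (study == "advanced")
    D <- D + switch(latent, PR = pop$S2, NSR = pop$S3,
                    SR = if (combo == "same") pop$S4 else pop$S5)
  slope_mu <- switch(latent, PR = pop$slope_mean[["PR"]],
                     NSR = pop$slope_mean[["NSR"]],
                     SR = if (combo == "same") pop$slope_mean[["SR_same"]]
                          else pop$slope_mean[["SR_diff"]])
  eta_sl <- (subject$eta_slope %||% c(PR = 0, NSR = 0, SR = 0))[[latent]]
  D + (slope_mu + eta_sl) * time
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Response distribution for one evaluation
#'
#' Category probabilities for an observed UPDRS response, composing the
#' graded-response curves with the bridging pathway of the evaluation:
#' direct and UPDRS-exclusive items use their bank parameters as-is, while
#' indirect items pass the probabilities through the reassignment scheme
#' (see \code{\link{reassign_probabilities}}). With all fractions 0 the
#' indirect pathway equals the direct one.
#'
#' @param key Evaluation key, e.g. \code{"26.left"} (see
#'   \code{\link{build_item_table}}).
#' @param D Latent disability value(s).
#' @param bank Item parameter bank.
#' @param mapping Reassignment specification (see
#'   \code{\link{default_mapping}}).
#' @return Category probabilities (vector, or matrix over \code{D}).
#' @export
response_distribution <- function(key, D, bank, mapping = default_mapping()) {
  i <- match(key, bank$key)
  if (is.na(i)) stop("evaluation not found in item bank: ", key)
  p <- category_probabilities(bank$a[i],
                              as.numeric(bank[i, c("b1", "b2", "b3", "b4")]), D)
  if (bank$mapping[i] == "indirect") {
    j <- match(bank$item_id[i], mapping$item_id)
    if (is.na(j)) stop("indirect item missing from mapping specification: ",
                       bank$item_id[i])
    p <- reassign_probabilities(p, mapping$fr2[j], mapping$fr3[j])
  }
  p
}

#' Marginalize a quantity over the side-dominance mixture
#'
#' Weights a side-dependent quantity by the mixture proportion:
#' \eqn{\pi f(\mathrm{right}) + (1 - \pi) f(\mathrm{left})}, where
#' \eqn{\pi} is the probability that the right side is the more disabled
#' side at baseline.
#'
#' @param prob_fn Function of one argument (\code{"right"} or
#'   \code{"left"}) returning a numeric value.
#' @param pop Population parameters (uses \code{mixture_pi}).
#' @return The mixture-weighted value.
#' @examples
#' pop <- default_population()
#' mixture_marginal(function(s) if (s == "right") 0.2 else 0.1, pop) # 0.158
#' @export
mixture_marginal <- function(prob_fn, pop) {
  pop$mixture_pi * prob_fn("right") + (1 - pop$mixture_pi) * prob_fn("left")
}
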
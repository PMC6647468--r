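#' Trial design presets
#'
#' Designs emulating the two source trials: an early-PD study (N = 161,
#' baseline assessment only), an advanced-PD study at baseline (N = 393)
#' and the advanced-PD placebo arm followed longitudinally at weeks
#' 0, 1, 2, 3, 4, 6, 8, 10, 12, 16, 20 and 24. All sizes and schedules can
#' be overridden for scaled-down work.
#'
#' @param n_early,n_advanced,n_placebo Subject counts overriding the
#'   preset defaults.
#' @return A named list of three design lists
#'   (\code{study168_baseline}, \code{study169_baseline},
#'   \code{study169_placebo_longitudinal}), each with components
#'   \code{name}, \code{n_subjects}, \code{population}, \code{visit_weeks}
#'   and \code{arms}.
#' @examples
#' make_presets()$study169_placebo_longitudinal$visit_weeks
#' @export
make_presets <- function(n_early = 161L, n_advanced = 393L,
                         n_placebo = 197L) {
  list(
    study168_baseline = list(
      name = "study168_baseline", n_subjects = as.integer(n_early),
      population = "early", visit_weeks = 0, arms = c(all = 1)),
    study169_baseline = list(
      name = "study169_baseline", n_subjects = as.integer(n_advanced),
      population = "advanced", visit_weeks = 0, arms = c(all = 1)),
    study169_placebo_longitudinal = list(
      name = "study169_placebo_longitudinal",
      n_subjects = as.integer(n_placebo), population = "advanced",
      visit_weeks = c(0, 1, 2, 3, 4, 6, 8, 10, 12, 16, 20, 24),
      arms = c(placebo = 1)))
}

.validate_design <- function(design) {
  stopifnot(is.list(design), design$n_subjects >= 1)
  if (!design$population %in% c("early", "advanced"))
    stop("unknown population in design: ", design$population)
  vw <- design$visit_weeks
  if (any(vw < 0) || vw[1] != 0 || any(diff(vw) <= 0))
    stop("visit_weeks must be non-negative, strictly increasing, starting at 0")
  invisible(design)
}

#' Simulate an item-level trial dataset
#'
#' Runs the bridged item response model forward: each subject draws a
#' dominant (more disabled) side from the mixture, correlated baseline
#' latent effects, a side-shift random effect and slope random effects
#' (for longitudinal designs); each visit then scores all 44 evaluations by
#' sampling from the graded-response category probabilities, routed
#' through the reassignment scheme for indirectly mapped items.
#'
#' Reproducibility is per subject: a subject-level seed stream is derived
#' deterministically from \code{seed} and the subject index, so enlarging
#' or shrinking \code{n_subjects} leaves the records of the retained
#' subjects unchanged.
#'
#' @param design A design list (see \code{\link{make_presets}}).
#' @param pop Population parameters (\code{\link{default_population}}).
#' @param bank Item parameter bank (\code{\link{generate_fixture_bank}}).
#' @param mapping Reassignment specification (\code{\link{default_mapping}}).
#' @param seed Integer master seed.
#' @param dropout Per-record probability that a response is missing
#'   (recorded with \code{MDV = 1}); default 0.
#' @param items Optional subset of evaluation keys to score (default: all
#'   44).
#' @return A long-format dataset (see \code{\link{read_dataset}}) with
#'   attributes \code{truth} (the generating \code{pop}) and \code{sides}
#'   (each subject's simulated dominant side).
#' @export
simulate_trial <- function(design, pop = default_population(),
                           bank = generate_fixture_bank(),
                           mapping = default_mapping(), seed = 1L,
                           dropout = 0, items = NULL) {
  .validate_design(design)
  validate_population(pop)
  validate_item_bank(bank)
  validate_mapping(mapping)
  tab <- bank
  if (!is.null(items)) {
    bad <- setdiff(items, bank$key)
    if (length(bad) > 0) stop("unknown evaluation keys: ",
                              paste(bad, collapse = ", "))
    tab <- bank[bank$key %in% items, , drop = FALSE]
  }
  adv <- design$population == "advanced"
  vw <- design$visit_weeks
  arm <- names(design$arms)[1]
  n <- design$n_subjects
  nrec_v <- nrow(tab)
  lat <- match(tab$latent, .LATENTS)
  sided <- match(tab$sidedness, c("none", "right", "left")) - 1L
  ind <- tab$mapping == "indirect"
  fr_row <- match(tab$item_id, mapping$item_id)
  fr2 <- mapping$fr2[fr_row[ind]]
  fr3 <- mapping$fr3[fr_row[ind]]
  a <- tab$a
  bmat <- as.matrix(tab[, c("b1", "b2", "b3", "b4")])

  v <- if (adv) pop$adv_variance else pop$variance
  C <- if (adv) pop$correlation_advanced else pop$correlation_early
  Lb <- t(chol(C * tcrossprod(sqrt(v))))

  lat_v <- rep(lat, times = length(vw))
  sided_v <- rep(sided, times = length(vw))
  time_v <- rep(vw, each = nrec_v)
  a_v <- rep(a, times = length(vw))
  bmat_v <- bmat[rep(seq_len(nrec_v), times = length(vw)), , drop = FALSE]
  ind_v <- rep(ind, times = length(vw))
  fr2_v <- rep(fr2, times = length(vw))
  fr3_v <- rep(fr3, times = length(vw))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  out <- vector("list", n)
  sides <- integer(n)
  for (i in seq_len(n)) {
    set.seed(.subject_seed(seed, i))
    side <- if (stats::runif(1) < pop$mixture_pi) 1L else 2L
    sides[i] <- side
    eta_b <- as.numeric(Lb %*% stats::rnorm(3))
    eta_s1 <- if (pop$S1_variance > 0)
      stats::rnorm(1, 0, sqrt(pop$S1_variance)) else 0
    eta_sl <- stats::rnorm(3, 0, sqrt(pop$slope_variance))
    combo <- ifelse(sided_v == 0L, 0L, ifelse(sided_v == side, 1L, 2L))
    D <- .fixed_offset(lat_v, combo, time_v, adv, pop) +
      eta_b[lat_v] + ifelse(combo == 2L, eta_s1, 0) + eta_sl[lat_v] * time_v
    p5 <- .rec_probs(a_v, bmat_v, ind_v, fr2_v, fr3_v, D, order = 0L)$p5
    u <- stats::runif(length(D))
    y <- .sample_cat(p5, u)
    mdv <- if (dropout > 0)
      as.integer(stats::runif(length(D)) < dropout) else 0L
    out[[i]] <- data.frame(
      ID = i, STUDY = design$population, ARM = arm, TIME = time_v,
      ITEM = rep(tab$item_id, times = length(vw)),
      SUB = rep(tab$sub_id, times = length(vw)),
      DV = as.integer(y), MDV = mdv)
  }
  d <- do.call(rbind, out)
  d$DV[d$MDV == 1] <- NA_integer_
  attr(d, "truth") <- pop
  attr(d, "sides") <- c("right", "left")[sides]
  d
}

# Inverse-CDF draw of ordinal scores from rows of category probabilities.
.sample_cat <- function(p5, u) {
  c1 <- p5[, 1]
  c2 <- c1 + p5[, 2]
  c3 <- c2 + p5[, 3]
  c4 <- c3 + p5[, 4]
  (u > c1) + (u > c2) + (u > c3) + (u > c4)
}

# Deterministic per-subject seed stream (kept below 2^31).
.subject_seed <- function(master, i) {
  as.integer((as.double(master) %% 65011 * 48271 + i * 1299709 + 17) %%
               2147483629)
}
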
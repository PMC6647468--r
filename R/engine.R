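# Internal marginal-likelihood engine.
#
# The marginal likelihood integrates, per subject, the product of
# graded-response category probabilities over the joint normal random
# effects (three correlated baseline latents, the side-shift effect, and
# slope effects when longitudinal data are present), then mixes over the
# two side-dominance classes. The integral is approximated by a Laplace
# approximation at the per-subject posterior mode (found by a damped Newton
# iteration with analytic first and second derivatives), optionally refined
# by adaptive Gauss-Hermite quadrature centered and scaled at that mode.
#
# All subjects of one (study, side-class) group are iterated simultaneously:
# record-level quantities are vectors over the stacked records and
# per-subject reductions go through rowsum().

.LATENTS <- c("PR", "NSR", "SR")

# Random-effect dimension layout, fixed at context-build time.
.dims_layout <- function(pop, has_time) {
  s1col <- if (pop$S1_variance > 0) 4L else 0L
  nb <- if (s1col > 0) 4L else 3L
  slope_latents <- if (has_time) which(pop$slope_variance > 0) else integer(0)
  slopecols <- if (length(slope_latents) > 0)
    stats::setNames(nb + seq_along(slope_latents), slope_latents) else integer(0)
  list(d = nb + length(slope_latents), s1col = s1col,
       slope_latents = as.integer(slope_latents), slopecols = slopecols)
}

# Build the evaluation context for a long-format dataset.
.build_context <- function(data, bank, mapping, pop) {
  data <- .coerce_dataset(data)
  use <- data$MDV == 0
  n_missing <- sum(!use)
  d <- data[use, , drop = FALSE]
  if (nrow(d) == 0) stop("dataset has no usable (non-missing) records")
  key <- sprintf("%02d.%s", d$ITEM, d$SUB)
  bi <- match(key, bank$key)
  if (anyNA(bi))
    stop("records reference evaluations absent from the item bank: ",
         paste(unique(key[is.na(bi)]), collapse = ", "))
  subjects <- unique(d$ID)
  si_all <- match(d$ID, subjects)
  study_subj <- tapply(d$STUDY, si_all, function(s) {
    u <- unique(s)
    if (length(u) > 1) stop("subject assigned to more than one study")
    u
  })
  study_subj <- as.character(study_subj[order(as.integer(names(study_subj)))])
  has_time <- any(d$TIME > 0)
  dims <- .dims_layout(pop, has_time)

  lat <- match(bank$latent[bi], .LATENTS)
  sided <- match(bank$sidedness[bi], c("none", "right", "left")) - 1L
  indirect <- bank$mapping[bi] == "indirect"
  fr_row <- ifelse(indirect, match(bank$item_id[bi], mapping$item_id), NA_integer_)
  if (any(indirect & is.na(fr_row)))
    stop("indirect item(s) missing from mapping specification: ",
         paste(unique(bank$item_id[bi][indirect & is.na(fr_row)]), collapse = ", "))

  groups <- lapply(unique(study_subj), function(st) {
    subj_g <- which(study_subj == st)
    rec <- which(si_all %in% subj_g)
    si <- match(si_all[rec], subj_g)
    g <- list(study = st, subj = subj_g, rec = rec, si = si,
              n = length(subj_g), lat = lat[rec], sided = sided[rec],
              time = d$TIME[rec], y = d$DV[rec], bank_idx = bi[rec],
              fr_row = fr_row[rec], indirect = indirect[rec],
              adv = st == "advanced")
    g$classes <- lapply(1:2, function(side) .class_design(g, side, dims))
    g
  })
  names(groups) <- vapply(groups, `[[`, "", "study")

  list(subjects = subjects, study_subj = study_subj, dims = dims,
       groups = groups, n_obs = nrow(d), n_missing = n_missing,
       has_time = has_time, warm = new.env(parent = emptyenv()))
}

# Fixed per-class design: side-combination flags and random-effect loading
# matrices (these depend on data layout only, never on parameter values).
.class_design <- function(g, side, dims) {
  combo <- ifelse(g$sided == 0L, 0L, ifelse(g$sided == side, 1L, 2L))
  nrec <- length(g$lat)
  X <- matrix(0, nrec, dims$d)
  X[cbind(seq_len(nrec), g$lat)] <- 1
  if (dims$s1col > 0) X[, dims$s1col] <- as.numeric(combo == 2L)
  slopecol <- rep(0L, nrec)
  for (m in dims$slope_latents) {
    rows <- which(g$lat == m)
    cc <- dims$slopecols[[as.character(m)]]
    X[rows, cc] <- g$time[rows]
    slopecol[rows] <- cc
  }
  pr <- which(upper.tri(diag(dims$d), diag = TRUE), arr.ind = TRUE)
  keep <- logical(nrow(pr))
  P <- matrix(0, nrec, nrow(pr))
  for (m in seq_len(nrow(pr))) {
    v <- X[, pr[m, 1]] * X[, pr[m, 2]]
    if (any(v != 0)) {
      keep[m] <- TRUE
      P[, m] <- v
    }
  }
  list(combo = combo, X = X, P = P[, keep, drop = FALSE],
       pairs = pr[keep, , drop = FALSE], slopecol = slopecol)
}

# Fixed-effect offset for records, given latent, side combination, study and
# time. Shared by the likelihood and the trial simulator so that the
# generative and fitted models are literally the same map.
.fixed_offset <- function(lat, combo, time, adv, pop) {
  off <- pop$mean[lat]
  if (adv) {
    sh <- c(pop$S2, pop$S3, 0)[lat]
    i3 <- lat == 3L
    sh[i3] <- ifelse(combo[i3] == 1L, pop$S4, pop$S5)
    off <- off + sh
  }
  off <- off + ifelse(combo == 2L, pop$S1, 0)
  sm <- pop$slope_mean[c("PR", "NSR", "SR_same")][lat]
  i3 <- lat == 3L
  sm[i3] <- ifelse(combo[i3] == 1L, pop$slope_mean[["SR_same"]],
                   pop$slope_mean[["SR_diff"]])
  off + sm * time
}

# Category probabilities (and optionally first/second derivatives in D) for
# stacked records, including the indirect-mapping reassignment.
.rec_probs <- function(a, bmat, ind, fr2, fr3, D, order = 0L) {
  cm <- stats::plogis(a * (D - bmat))                       # nrec x 4
  p5 <- cbind(1 - cm[, 1], cm[, 1] - cm[, 2], cm[, 2] - cm[, 3],
              cm[, 3] - cm[, 4], cm[, 4])
  reassign <- function(M) {
    Ms <- M[ind, , drop = FALSE]
    M[ind, ] <- cbind(Ms[, 1], Ms[, 2] + Ms[, 3] * fr2,
                      Ms[, 3] * (1 - fr2) + Ms[, 4] * fr3,
                      Ms[, 4] * (1 - fr3), Ms[, 5])
    M
  }
  any_ind <- any(ind)
  if (any_ind) p5 <- reassign(p5)
  if (order == 0L) return(list(p5 = p5))
  dc <- a * cm * (1 - cm)
  dp5 <- cbind(-dc[, 1], dc[, 1] - dc[, 2], dc[, 2] - dc[, 3],
               dc[, 3] - dc[, 4], dc[, 4])
  d2c <- a * dc * (1 - 2 * cm)
  d2p5 <- cbind(-d2c[, 1], d2c[, 1] - d2c[, 2], d2c[, 2] - d2c[, 3],
                d2c[, 3] - d2c[, 4], d2c[, 4])
  if (any_ind) {
    dp5 <- reassign(dp5)
    d2p5 <- reassign(d2p5)
  }
  list(p5 = p5, dp5 = dp5, d2p5 = d2p5)
}

# Current item-parameter slices for a group.
.group_items <- function(g, bank, mapping) {
  ind <- g$indirect
  list(a = bank$a[g$bank_idx],
       bmat = as.matrix(bank[g$bank_idx, c("b1", "b2", "b3", "b4")]),
       ind = ind,
       fr2 = mapping$fr2[g$fr_row[ind]],
       fr3 = mapping$fr3[g$fr_row[ind]])
}

.rec_D <- function(g, cls, off, eta, dims) {
  D <- off + eta[cbind(g$si, g$lat)]
  if (dims$s1col > 0) D <- D + cls$X[, dims$s1col] * eta[g$si, dims$s1col]
  sc <- cls$slopecol
  has <- sc > 0L
  if (any(has))
    D[has] <- D[has] + g$time[has] * eta[cbind(g$si[has], sc[has])]
  D
}

.obs_loglik <- function(g, it, D) {
  p5 <- .rec_probs(it$a, it$bmat, it$ind, it$fr2, it$fr3, D, order = 0L)$p5
  log(pmax(p5[cbind(seq_along(g$y), g$y + 1L)], 1e-300))
}

.sigma_for <- function(pop, study, dims) {
  v <- if (study == "advanced") pop$adv_variance else pop$variance
  C <- if (study == "advanced") pop$correlation_advanced else pop$correlation_early
  if (any(v <= 0)) stop("baseline latent variances must be positive")
  s <- sqrt(v)
  Sig3 <- C * tcrossprod(s)
  extra <- c(if (dims$s1col > 0) pop$S1_variance,
             pop$slope_variance[dims$slope_latents])
  d <- dims$d
  Sig <- matrix(0, d, d)
  Sig[1:3, 1:3] <- Sig3
  if (length(extra) > 0) diag(Sig)[4:d] <- extra
  Sig
}

# Damped Newton mode search + Laplace marginal log-likelihood for all
# subjects of one (study, side) class. Returns per-subject log-likelihood,
# posterior modes and the negative-Hessian Cholesky factors.
.class_laplace <- function(g, cls, it, off, Sigma, eta0, control) {
  n <- g$n
  dd <- ncol(Sigma)
  R_sig <- chol(Sigma)
  SigInv <- chol2inv(R_sig)
  ldSig <- 2 * sum(log(diag(R_sig)))
  eta <- if (is.null(eta0) || !all(dim(eta0) == c(n, dd)))
    matrix(0, n, dd) else eta0
  dims <- attr(cls, "dims")

  obj <- function(eta) {
    D <- .rec_D(g, cls, off, eta, dims)
    lp <- .obs_loglik(g, it, D)
    as.numeric(rowsum(lp, g$si)) -
      0.5 * rowSums((eta %*% SigInv) * eta)
  }
  cur <- obj(eta)

  for (iter in seq_len(control$newton_max)) {
    D <- .rec_D(g, cls, off, eta, dims)
    der <- .rec_probs(it$a, it$bmat, it$ind, it$fr2, it$fr3, D, order = 2L)
    ii <- cbind(seq_along(g$y), g$y + 1L)
    p <- pmax(der$p5[ii], 1e-300)
    dl <- der$dp5[ii] / p
    d2l <- der$d2p5[ii] / p - dl^2
    G <- rowsum(cls$X * dl, g$si) - eta %*% SigInv
    Hp <- rowsum(cls$P * d2l, g$si)
    step <- matrix(0, n, dd)
    for (i in seq_len(n)) {
      A <- SigInv
      for (m in seq_len(nrow(cls$pairs))) {
        j <- cls$pairs[m, 1]; k <- cls$pairs[m, 2]
        A[j, k] <- A[j, k] - Hp[i, m]
        if (j != k) A[k, j] <- A[j, k]
      }
      R <- .safe_chol(A)
      step[i, ] <- backsolve(R, backsolve(R, G[i, ], transpose = TRUE))
    }
    # damped update: halve steps for subjects whose objective would drop
    for (h in 0:12) {
      eta_new <- eta + step
      new <- obj(eta_new)
      bad <- new < cur - 1e-10
      if (!any(bad)) break
      step[bad, ] <- step[bad, , drop = FALSE] / 2
    }
    moved <- max(abs(step))
    eta <- eta_new
    cur <- new
    if (moved < control$newton_tol) break
  }

  # Laplace assembly at the mode
  D <- .rec_D(g, cls, off, eta, dims)
  der <- .rec_probs(it$a, it$bmat, it$ind, it$fr2, it$fr3, D, order = 2L)
  ii <- cbind(seq_along(g$y), g$y + 1L)
  p <- pmax(der$p5[ii], 1e-300)
  dl <- der$dp5[ii] / p
  d2l <- der$d2p5[ii] / p - dl^2
  Hp <- rowsum(cls$P * d2l, g$si)
  lp_sum <- as.numeric(rowsum(log(p), g$si))
  qf <- rowSums((eta %*% SigInv) * eta)
  ll <- numeric(n)
  Rlist <- vector("list", n)
  for (i in seq_len(n)) {
    A <- SigInv
    for (m in seq_len(nrow(cls$pairs))) {
      j <- cls$pairs[m, 1]; k <- cls$pairs[m, 2]
      A[j, k] <- A[j, k] - Hp[i, m]
      if (j != k) A[k, j] <- A[j, k]
    }
    R <- .safe_chol(A)
    Rlist[[i]] <- R
    ll[i] <- lp_sum[i] - 0.5 * ldSig - 0.5 * qf[i] - sum(log(diag(R)))
  }
  list(ll = ll, eta = eta, R = Rlist, SigInv = SigInv, ldSig = ldSig)
}

.safe_chol <- function(A) {
  R <- tryCatch(chol(A), error = function(e) NULL)
  ridge <- 1e-8 * max(1, max(abs(diag(A))))
  while (is.null(R)) {
    A <- A + diag(ridge, nrow(A))
    R <- tryCatch(chol(A), error = function(e) NULL)
    ridge <- ridge * 10
    if (ridge > 1e6) stop("posterior curvature matrix could not be stabilized")
  }
  R
}

# Adaptive Gauss-Hermite refinement for one subject, centered at the
# posterior mode with scaling from the Laplace curvature. nodes = 1 is the
# Laplace approximation itself.
.subject_agh <- function(g, cls, it, off, SigInv, ldSig, eta_i, R_i, i,
                         nodes, dims) {
  dd <- ncol(SigInv)
  gh <- pracma::gaussHermite(nodes)
  grid <- as.matrix(expand.grid(rep(list(seq_len(nodes)), dd)))
  if (nrow(grid) > 2e5)
    stop("quadrature grid too large; reduce nodes or use Laplace (nodes = 1)")
  Z <- matrix(gh$x[grid], nrow(grid), dd)
  logw <- rowSums(matrix(log(gh$w[grid]), nrow(grid), dd))
  L <- backsolve(R_i, diag(dd))            # L L' = A^{-1}
  Etas <- sweep(sqrt(2) * Z %*% t(L), 2, eta_i, "+")

  rec <- which(g$si == i)
  lat_r <- g$lat[rec]
  time_r <- g$time[rec]
  sc_r <- cls$slopecol[rec]
  x_s1 <- if (dims$s1col > 0) cls$X[rec, dims$s1col] else numeric(length(rec))
  lj <- vapply(seq_len(nrow(Etas)), function(q) {
    e <- Etas[q, ]
    D <- off[rec] + e[lat_r]
    if (dims$s1col > 0) D <- D + x_s1 * e[dims$s1col]
    has <- sc_r > 0L
    if (any(has)) D[has] <- D[has] + time_r[has] * e[sc_r[has]]
    p5 <- .rec_probs(it$a[rec], it$bmat[rec, , drop = FALSE], it$ind[rec],
                     it$fr2[.ind_sub(it$ind, rec)], it$fr3[.ind_sub(it$ind, rec)],
                     D, order = 0L)$p5
    sum(log(pmax(p5[cbind(seq_along(rec), g$y[rec] + 1L)], 1e-300))) -
      0.5 * ldSig - 0.5 * dd * log(2 * pi) - 0.5 * sum((e %*% SigInv) * e)
  }, 0)
  (dd / 2) * log(2) + sum(log(abs(diag(L)))) +
    .logsumexp(lj + rowSums(Z^2) + logw)
}

# position of rec rows within the indirect-only fraction vectors
.ind_sub <- function(ind, rec) {
  pos <- cumsum(ind)
  pos[rec][ind[rec]]
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Full-data marginal log-likelihood (and optionally empirical-Bayes output).
.eval_loglik <- function(ctx, pop, bank, mapping, control, want_eb = FALSE) {
  n_all <- length(ctx$subjects)
  ll_subj <- numeric(n_all)
  eb <- if (want_eb) vector("list", length(ctx$groups)) else NULL
  lpi <- c(log(pop$mixture_pi), log1p(-pop$mixture_pi))
  dims <- ctx$dims
  for (gi in seq_along(ctx$groups)) {
    g <- ctx$groups[[gi]]
    Sigma <- .sigma_for(pop, g$study, dims)
    it <- .group_items(g, bank, mapping)
    llm <- matrix(0, g$n, 2)
    modes <- vector("list", 2)
    for (side in 1:2) {
      cls <- g$classes[[side]]
      attr(cls, "dims") <- dims
      combo <- cls$combo
      off <- .fixed_offset(g$lat, combo, g$time, g$adv, pop)
      warm_key <- paste(g$study, side)
      res <- .class_laplace(g, cls, it, off, Sigma,
                            ctx$warm[[warm_key]], control)
      ctx$warm[[warm_key]] <- res$eta
      ll_side <- res$ll
      if (control$nodes > 1) {
        ll_side <- vapply(seq_len(g$n), function(i)
          .subject_agh(g, cls, it, off, res$SigInv, res$ldSig,
                       res$eta[i, ], res$R[[i]], i, control$nodes, dims), 0)
      }
      llm[, side] <- ll_side
      modes[[side]] <- res$eta
    }
    comb <- cbind(lpi[1] + llm[, 1], lpi[2] + llm[, 2])
    mx <- pmax(comb[, 1], comb[, 2])
    ll_g <- mx + log(exp(comb[, 1] - mx) + exp(comb[, 2] - mx))
    ll_subj[g$subj] <- ll_g
    if (want_eb) {
      p_right <- exp(comb[, 1] - ll_g)
      eb[[gi]] <- list(group = g, p_right = p_right, modes = modes)
    }
  }
  out <- list(total = sum(ll_subj), by_subject = ll_subj)
  if (want_eb) out$eb <- eb
  out
}
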
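#' Generate a synthetic item parameter bank
#'
#' Produces one set of item characteristic curve (ICC) parameters per UPDRS
#' evaluation: a discrimination \code{a > 0} and four ordered difficulty
#' thresholds \code{b1 < b2 < b3 < b4} on the latent disability scale. The
#' bank is a synthetic stand-in for a previously fitted reference ICC set
#' (such values are not shipped with this package); it is the fixed "prior
#' knowledge" against which bridging parameters are estimated, and the truth
#' used by the synthetic trial generator.
#'
#' Discriminations are drawn uniformly on (1, 2.5); the first threshold on
#' (-2, -0.5) with threshold gaps on (0.8, 1.6), so thresholds span roughly
#' (-2, +4) latent-scale units and item information covers both early and
#' advanced disease severities. Items listed in \code{extra_severe} receive
#' a fifth threshold \code{b5 = b4 + gap}, flagged \code{estimated}: it
#' extends the MDS-side curve into a more severe response category. Because
#' UPDRS responses are capped at 4 (so that P(Y = 4) = P(Y >= 4)), b5 does
#' not enter the UPDRS likelihood.
#'
#' Provenance is \code{prior_fixed} for direct and indirect items (their
#' curves are carried over from the reference model) and \code{estimated}
#' for UPDRS-exclusive items, whose curves are fitted from UPDRS data.
#'
#' @param seed Integer seed; the same seed always yields the same bank.
#' @param extra_severe Character vector of evaluation keys (see
#'   \code{\link{build_item_table}}) that receive the extra severe-category
#'   threshold. Default none.
#' @return A 44-row data frame with the item table columns plus
#'   \code{provenance}, \code{a}, \code{b1}..\code{b4} and \code{b5}
#'   (\code{NA} unless configured).
#' @examples
#' bank <- generate_fixture_bank(seed = 42)
#' all(bank$b1 < bank$b2)
#' @export
generate_fixture_bank <- function(seed = 20190717L, extra_severe = character()) {
  tab <- build_item_table()
  bad <- setdiff(extra_severe, tab$key)
  if (length(bad) > 0)
    stop("unknown evaluation keys in extra_severe: ", paste(bad, collapse = ", "))
  # Mirrored left/right evaluations of one item share ICC parameters: the
  # question asked is the same on either side, and side differences are
  # carried by the latent structure (side mixture and S1 shift), which also
  # keeps the likelihood exactly invariant under a global left/right
  # relabelling.
  unit <- paste(tab$item_id, gsub("right|left", "side", tab$sub_id))
  units <- unique(unit)
  ui <- match(unit, units)
  nu <- length(units)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  a_u <- stats::runif(nu, 1.0, 2.5)
  b1_u <- stats::runif(nu, -2, -0.5)
  gaps_u <- matrix(stats::runif(4 * nu, 0.8, 1.6), nu, 4)
  a <- a_u[ui]
  b1 <- b1_u[ui]
  gaps <- gaps_u[ui, , drop = FALSE]
  b <- b1 + cbind(0, gaps[, 1], gaps[, 1] + gaps[, 2],
                  gaps[, 1] + gaps[, 2] + gaps[, 3])
  b5 <- ifelse(tab$key %in% extra_severe, b[, 4] + gaps[, 4], NA_real_)
  bank <- cbind(tab[, c("item_id", "sub_id", "key", "latent", "sidedness",
                        "mapping")],
                data.frame(
                  provenance = ifelse(tab$mapping == "exclusive",
                                      "estimated", "prior_fixed"),
                  a = a, b1 = b[, 1], b2 = b[, 2], b3 = b[, 3], b4 = b[, 4],
                  b5 = b5))
  rownames(bank) <- NULL
  validate_item_bank(bank)
  bank
}

# Preserve the caller's RNG state around internally seeded draws.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Validate an item parameter bank
#'
#' Checks that the bank covers every one of the 44 evaluations exactly once,
#' that all discriminations are positive and that each row's difficulty
#' thresholds are strictly increasing.
#'
#' @param bank A bank data frame as returned by
#'   \code{\link{generate_fixture_bank}} or \code{\link{load_item_bank}}.
#' @return The bank, invisibly, if valid; otherwise an error naming the
#'   offending items.
#' @export
validate_item_bank <- function(bank) {
  tab <- build_item_table()
  need <- c("item_id", "sub_id", "key", "a", "b1", "b2", "b3", "b4")
  miss_col <- setdiff(need, names(bank))
  if (length(miss_col) > 0)
    stop("item bank is missing columns: ", paste(miss_col, collapse = ", "))
  missing <- setdiff(tab$key, bank$key)
  if (length(missing) > 0)
    stop("item bank is incomplete; absent evaluations: ",
         paste(missing, collapse = ", "))
  dup <- bank$key[duplicated(bank$key)]
  if (length(dup) > 0)
    stop("item bank has duplicated evaluations: ", paste(dup, collapse = ", "))
  if (any(!is.finite(bank$a)) || any(bank$a <= 0))
    stop("non-positive discrimination for item(s): ",
         paste(bank$key[!is.finite(bank$a) | bank$a <= 0], collapse = ", "))
  bmat <- as.matrix(bank[, c("b1", "b2", "b3", "b4")])
  if ("b5" %in% names(bank)) {
    b5 <- ifelse(is.na(bank$b5), Inf, bank$b5)
    bmat <- cbind(bmat, b5)
  }
  ok <- apply(bmat, 1, function(b) all(diff(b[is.finite(b)]) > 0)) &
    apply(bmat[, 1:4], 1, function(b) all(is.finite(b)))
  if (any(!ok))
    stop("difficulty thresholds not strictly increasing for item(s): ",
         paste(bank$key[!ok], collapse = ", "))
  invisible(bank)
}

#' Read and write item parameter banks
#'
#' The on-disk format is UTF-8 tab-separated text with a header row and
#' columns \code{item_id}, \code{sub_id}, \code{key}, \code{latent},
#' \code{sidedness}, \code{mapping}, \code{provenance}, \code{a},
#' \code{b1}..\code{b5}. \code{load_item_bank} validates the parsed bank
#' (see \code{\link{validate_item_bank}}) and fails with the offending line
#' on malformed numeric fields.
#'
#' @param bank A bank data frame.
#' @param path File path.
#' @return \code{load_item_bank} returns the validated bank data frame;
#'   \code{write_item_bank} returns \code{path} invisibly.
#' @export
write_item_bank <- function(bank, path) {
  validate_item_bank(bank)
  utils::write.table(bank, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_item_bank
#' @export
load_item_bank <- function(path) {
  if (!file.exists(path)) stop("item bank file not found: ", path)
  bank <- utils::read.delim(path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  num_cols <- intersect(c("a", "b1", "b2", "b3", "b4", "b5"), names(bank))
  for (cc in num_cols) {
    v <- bank[[cc]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(vn))
      if (length(bad) > 0)
        stop("could not parse column '", cc, "' at line(s) ",
             paste(bad + 1, collapse = ", "), " of ", path)
      bank[[cc]] <- vn
    }
  }
  validate_item_bank(bank)
  bank
}

#' Reference prior constants from the source item response model
#'
#' Constants carried over from the previously developed MDS-UPDRS item
#' response model: the mixture proportion (probability that the right side
#' is the more disabled side at baseline) and the prior side-shift (the
#' lower disability of the initially better side, mean and SD). The shift is
#' retained as a reference value only; the bridging workflow re-estimates
#' its own side shift (\code{S1}).
#'
#' @return A list with components \code{mixture_prior} (0.58),
#'   \code{shift_prior_mean} (2.11) and \code{shift_prior_sd} (0.60).
#' @export
prior_constants <- function() {
  list(mixture_prior = 0.58, shift_prior_mean = 2.11, shift_prior_sd = 0.60)
}
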
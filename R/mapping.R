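#' Default probability-reassignment specification
#'
#' For indirectly mapped items the MDS-UPDRS item characteristic curves are
#' reused but the response categories of the two instruments differ in
#' perceived severity, so part of the probability mass of the MDS categories
#' is reassigned to adjacent UPDRS categories. Every indirect item follows
#' the adjacent-split template exemplified by leg agility
#' (MDS 1 -> UPDRS 1 or 2, MDS 2 -> UPDRS 2 or 3), governed by two free
#' fractions per item:
#' \deqn{P(Y=1) = P1 + P2 \cdot FR2, \quad
#'       P(Y=2) = P2 (1 - FR2) + P3 \cdot FR3, \quad
#'       P(Y=3) = P3 (1 - FR3),}
#' with \eqn{P(Y=0) = P0} and \eqn{P(Y=4) = P4} unchanged. One scheme is
#' shared by all evaluations of a multi-evaluation item (e.g. left and right
#' leg agility share FR2, FR3).
#'
#' The shipped default sets FR2 = FR3 = 0.3 for each of the 16 indirect
#' UPDRS items (24 evaluations): a moderate reassignment that keeps most
#' mass on the matching category. These defaults serve as simulation truth;
#' fitting re-estimates the fractions on a logit scale.
#'
#' @param path Optional path to a mapping specification file (tab-separated,
#'   columns \code{item_id}, \code{fr2}, \code{fr3}).
#' @return A data frame with columns \code{item_id}, \code{fr2}, \code{fr3},
#'   one row per indirect UPDRS item.
#' @examples
#' m <- default_mapping()
#' nrow(m)   # 16 indirect items
#' @export
default_mapping <- function() {
  tab <- build_item_table()
  items <- sort(unique(tab$item_id[tab$mapping == "indirect"]))
  data.frame(item_id = items, fr2 = 0.3, fr3 = 0.3)
}

#' @rdname default_mapping
#' @export
load_mapping <- function(path) {
  if (!file.exists(path)) stop("mapping specification file not found: ", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_mapping(m)
  m
}

#' @rdname default_mapping
#' @param mapping A mapping data frame.
#' @export
write_mapping <- function(mapping, path) {
  validate_mapping(mapping)
  utils::write.table(mapping, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname default_mapping
#' @export
validate_mapping <- function(mapping) {
  need <- c("item_id", "fr2", "fr3")
  miss <- setdiff(need, names(mapping))
  if (length(miss) > 0)
    stop("mapping specification missing columns: ", paste(miss, collapse = ", "))
  tab <- build_item_table()
  indirect <- sort(unique(tab$item_id[tab$mapping == "indirect"]))
  extra <- setdiff(mapping$item_id, indirect)
  if (length(extra) > 0)
    stop("mapping rows for items that are not indirectly mapped: ",
         paste(extra, collapse = ", "))
  absent <- setdiff(indirect, mapping$item_id)
  if (length(absent) > 0)
    stop("mapping specification incomplete; absent indirect items: ",
         paste(absent, collapse = ", "))
  fr <- c(mapping$fr2, mapping$fr3)
  if (any(!is.finite(fr)) || any(fr < 0 | fr > 1))
    stop("reassignment fractions must lie in [0, 1]")
  invisible(mapping)
}

#' Reassign category probabilities between instrument versions
#'
#' Applies the adjacent-split reassignment that maps MDS-UPDRS category
#' probabilities onto UPDRS categories (see \code{\link{default_mapping}}
#' for the scheme). The operation is linear and mass-preserving: the output
#' sums to 1 whenever the input does, and FR2 = FR3 = 0 is the identity.
#'
#' @param p Numeric vector of 5 category probabilities (P0..P4), or a matrix
#'   with 5 columns (one row per evaluation point).
#' @param fr2,fr3 Reassignment fractions in [0, 1]; scalars, or vectors
#'   recycled along the rows of \code{p}.
#' @return Reassigned probabilities, same shape as \code{p}.
#' @examples
#' reassign_probabilities(rep(0.2, 5), fr2 = 0.5, fr3 = 0.5)
#' # 0.2 0.3 0.2 0.1 0.2
#' @export
reassign_probabilities <- function(p, fr2, fr3) {
  if (any(!is.finite(c(fr2, fr3))) || any(c(fr2, fr3) < 0 | c(fr2, fr3) > 1))
    stop("reassignment fractions must lie in [0, 1]")
  vec <- is.null(dim(p))
  if (vec) p <- matrix(p, nrow = 1)
  if (ncol(p) != 5) stop("expected 5 category probabilities (P0..P4)")
  out <- cbind(p[, 1],
               p[, 2] + p[, 3] * fr2,
               p[, 3] * (1 - fr2) + p[, 4] * fr3,
               p[, 4] * (1 - fr3),
               p[, 5])
  colnames(out) <- paste0("P", 0:4)
  if (vec) out[1, ] else out
}

#' Convert between category and cumulative (exceedance) probabilities
#'
#' \code{cumulative_from_categories} turns category probabilities
#' \eqn{P(Y=k)} into the exceedance probabilities \eqn{P(Y \ge k)},
#' \eqn{k = 0, \ldots, K}: a non-increasing vector starting at 1.
#' \code{categories_from_cumulative} is its inverse,
#' \eqn{P(Y=k) = P(Y \ge k) - P(Y \ge k+1)}.
#'
#' @param p Category probabilities (vector, or matrix with categories in
#'   columns).
#' @param cum Exceedance probabilities in the same layout.
#' @return Vector or matrix matching the input layout.
#' @examples
#' cumulative_from_categories(rep(0.2, 5))  # 1 0.8 0.6 0.4 0.2
#' @export
cumulative_from_categories <- function(p) {
  f <- function(x) rev(cumsum(rev(x)))
  if (is.null(dim(p))) f(p) else t(apply(p, 1, f))
}

#' @rdname cumulative_from_categories
#' @export
categories_from_cumulative <- function(cum) {
  f <- function(x) -diff(c(x, 0))
  if (is.null(dim(cum))) f(cum) else t(apply(cum, 1, f))
}
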
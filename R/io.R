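# Canonical long-format dataset exchange: one row per subject x visit x
# evaluation, columns ID, STUDY, ARM, TIME (weeks), ITEM, SUB, DV (ordinal
# score 0-4), MDV (1 = missing response). UTF-8 tab-separated on disk.

.coerce_dataset <- function(data) {
  need <- c("ID", "STUDY", "ARM", "TIME", "ITEM", "SUB", "DV", "MDV")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop("dataset missing columns: ", paste(miss, collapse = ", "))
  data$ITEM <- as.integer(data$ITEM)
  data$MDV <- as.integer(data$MDV)
  data$TIME <- as.numeric(data$TIME)
  data
}

#' Read and write item-level trial datasets
#'
#' The canonical exchange format is long: columns \code{ID}, \code{STUDY}
#' (\code{"early"} or \code{"advanced"}), \code{ARM}, \code{TIME} (weeks
#' since baseline), \code{ITEM} (UPDRS item number), \code{SUB} (evaluation
#' label), \code{DV} (ordinal score) and \code{MDV} (1 marks a missing
#' response; such rows are retained but contribute nothing to the
#' likelihood). \code{read_dataset} validates on load: unknown evaluations,
#' duplicated (subject, time, item, sub) rows, scores outside the category
#' range and negative times are errors naming the offending rows.
#'
#' @param path File path.
#' @param data A dataset data frame.
#' @return \code{read_dataset}: the validated data frame.
#'   \code{write_dataset}: \code{path}, invisibly.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_dataset(d)
}

#' @rdname read_dataset
#' @export
write_dataset <- function(data, path) {
  validate_dataset(data)
  utils::write.table(data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_dataset
#' @export
validate_dataset <- function(data) {
  d <- .coerce_dataset(data)
  tab <- build_item_table()
  key <- sprintf("%02d.%s", d$ITEM, d$SUB)
  unknown <- setdiff(unique(key), tab$key)
  if (length(unknown) > 0)
    stop("unknown item evaluations: ", paste(unknown, collapse = ", "))
  if (any(d$TIME < 0)) stop("negative TIME at row(s): ",
                            paste(utils::head(which(d$TIME < 0), 5), collapse = ", "))
  obs <- d$MDV == 0
  bad <- obs & (!is.finite(d$DV) | d$DV < 0 | d$DV > 4 | d$DV != round(d$DV))
  if (any(bad))
    stop("DV outside the 0-4 category range at row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  id <- paste(d$ID, d$TIME, key)
  if (anyDuplicated(id) > 0)
    stop("duplicated (subject, time, item, sub) records at row(s): ",
         paste(utils::head(which(duplicated(id)), 5), collapse = ", "))
  d
}
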
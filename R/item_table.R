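#' Canonical UPDRS item table
#'
#' Expands UPDRS items 1-31 (parts I-III) into the 44 evaluations scored at
#' each assessment. Seven items are rated for several body parts and/or
#' sides: tremor at rest (face/lips/chin plus hands and feet on both sides),
#' action/postural tremor (both hands), rigidity (neck plus upper and lower
#' extremities on both sides), and finger taps, hand movements,
#' pronation/supination and leg agility (both sides). Each evaluation is
#' assigned to one of the three latent disability variables:
#' \describe{
#'   \item{PR}{patient-reported items 1-17,}
#'   \item{NSR}{non-sided clinician-rated items 18, 19, 27-31 plus the
#'     non-sided evaluations of items 20 and 22,}
#'   \item{SR}{side-specific clinician-rated evaluations (items 21, 23-26
#'     and the sided evaluations of items 20 and 22).}
#' }
#' The \code{mapping} column carries the bridging taxonomy onto the
#' MDS-UPDRS instrument: \code{direct} (MDS item characteristic curves
#' reused as-is), \code{indirect} (reused with probability reassignment) or
#' \code{exclusive} (items absent from MDS-UPDRS, with their own curves).
#'
#' @return A 44-row data frame with columns \code{item_id}, \code{item_name},
#'   \code{sub_id}, \code{key} (\code{"<item>.<sub>"}), \code{latent},
#'   \code{sidedness} (\code{"none"}, \code{"right"} or \code{"left"}),
#'   \code{n_categories} and \code{mapping}. Deterministic and order-stable.
#' @examples
#' tab <- build_item_table()
#' nrow(tab)                     # 44
#' table(tab$latent)             # PR 17, NSR 9, SR 18
#' @export
build_item_table <- function() {
  item_names <- c(
    "Intellectual impairment", "Thought disorder", "Depression",
    "Motivation/initiative", "Speech (ADL)", "Salivation", "Swallowing",
    "Handwriting", "Cutting food", "Dressing", "Hygiene", "Turning in bed",
    "Falling", "Freezing when walking", "Walking", "Tremor (ADL)",
    "Sensory complaints", "Speech (motor)", "Facial expression",
    "Tremor at rest", "Action/postural tremor", "Rigidity", "Finger taps",
    "Hand movements", "Pronation/supination", "Leg agility",
    "Arising from chair", "Posture", "Gait", "Postural stability",
    "Body bradykinesia/hypokinesia")

  indirect  <- c(1, 2, 6, 7, 8, 12, 15, 18, 22, 23, 24, 25, 26, 28, 29, 30)
  exclusive <- c(13, 14, 20, 21)

  subs <- function(item) {
    switch(as.character(item),
      "20" = data.frame(
        sub_id = c("face-lips-chin", "right-hand", "left-hand",
                   "right-foot", "left-foot"),
        sidedness = c("none", "right", "left", "right", "left")),
      "21" = data.frame(
        sub_id = c("right-hand", "left-hand"),
        sidedness = c("right", "left")),
      "22" = data.frame(
        sub_id = c("neck", "right-upper", "left-upper",
                   "right-lower", "left-lower"),
        sidedness = c("none", "right", "left", "right", "left")),
      "23" = , "24" = , "25" = , "26" = data.frame(
        sub_id = c("right", "left"), sidedness = c("right", "left")),
      data.frame(sub_id = "single", sidedness = "none"))
  }

  rows <- lapply(1:31, function(item) {
    s <- subs(item)
    latent <- if (item <= 17) "PR"
      else ifelse(s$sidedness == "none", "NSR", "SR")
    mapping <- if (item %in% indirect) "indirect"
      else if (item %in% exclusive) "exclusive" else "direct"
    data.frame(item_id = item, item_name = item_names[item],
               sub_id = s$sub_id, latent = latent, sidedness = s$sidedness,
               n_categories = 5L, mapping = mapping)
  })
  tab <- do.call(rbind, rows)
  tab$key <- sprintf("%02d.%s", tab$item_id, tab$sub_id)
  rownames(tab) <- NULL
  tab[, c("item_id", "item_name", "sub_id", "key", "latent", "sidedness",
          "n_categories", "mapping")]
}

#' @rdname mapping_summary
#' @export
classify_items <- function() {
  build_item_table()[, c("item_id", "item_name", "sub_id", "key", "mapping")]
}

#' Bridging taxonomy between UPDRS and MDS-UPDRS
#'
#' \code{classify_items()} returns the per-evaluation classification of the
#' 44 UPDRS evaluations into direct, indirect and UPDRS-exclusive bridging
#' categories. \code{mapping_summary()} tallies the classification using the
#' counting convention in which every evaluation of a multi-evaluation item
#' counts once: 24 indirect, 11 direct, 9 exclusive.
#'
#' @return For \code{mapping_summary}, a data frame with columns
#'   \code{mapping}, \code{n} and \code{percent}.
#' @examples
#' mapping_summary()
#' @export
mapping_summary <- function() {
  tab <- build_item_table()
  n <- table(factor(tab$mapping, levels = c("indirect", "direct", "exclusive")))
  data.frame(mapping = names(n), n = as.integer(n),
             percent = round(100 * as.integer(n) / sum(n)))
}
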
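#' The 13 DRS-R-98 severity items
#'
#' Canonical machine-readable names for the thirteen severity items of the
#' Delirium Rating Scale-Revised-98, each scored on an ordinal 0--3 scale.
#' The scale itself never fixes a single authoritative ordering of the
#' items for matrix indexing, so the order used here is a package
#' convention: the sleep--wake item first, then perceptual/thought-content
#' accessory symptoms, affective lability, higher-order thinking, the two
#' motor items, and the cognitive domain items.
#'
#' @return Character vector of length 13.
#' @seealso [item_catalog()]
#' @export
#' @examples
#' drs_r98_items()
drs_r98_items <- function() {
  c("sleep_wake_cycle", "perceptual_disturbance", "delusion",
    "affective_lability", "language", "thought_process",
    "motor_agitation", "motor_retardation", "orientation",
    "attention", "short_term_memory", "long_term_memory",
    "visuospatial_ability")
}

#' Item catalogue for ordinal severity scores
#'
#' A catalogue fixes the set of questionnaire items and the shared ordinal
#' score range. It is carried by every [longitudinal_scores] object and
#' defines the column layout of the wide feature matrix.
#'
#' @param items character vector of unique, non-empty item names. Defaults
#'   to the 13 DRS-R-98 severity items ([drs_r98_items()]).
#' @param score_min,score_max integer bounds of the ordinal score range
#'   (default 0 and 3).
#' @return An object of class `item_catalog`: a list with elements
#'   `items`, `score_min`, `score_max`.
#' @export
#' @examples
#' item_catalog()
#' item_catalog(c("pain", "nausea"), 0, 10)
item_catalog <- function(items = drs_r98_items(), score_min = 0L,
                         score_max = 3L) {
  items <- as.character(items)
  if (length(items) == 0L || anyNA(items) || any(!nzchar(items)))
    stop("item names must be non-empty strings", call. = FALSE)
  if (anyDuplicated(items))
    stop("item names must be unique", call. = FALSE)
  if (!is_count(score_min, min = -Inf) || !is_count(score_max, min = -Inf))
    stop("`score_min` and `score_max` must be single integers",
         call. = FALSE)
  if (score_min >= score_max)
    stop("`score_min` must be strictly less than `score_max`",
         call. = FALSE)
  structure(list(items = items,
                 score_min = as.integer(score_min),
                 score_max = as.integer(score_max)),
            class = "item_catalog")
}

#' @export
print.item_catalog <- function(x, ...) {
  cat(sprintf("Item catalogue: %d items scored %d-%d\n",
              length(x$items), x$score_min, x$score_max))
  cat(" ", paste(x$items, collapse = ", "), "\n")
  invisible(x)
}

#' Feature (column) labels of the wide matrix
#'
#' Labels are `"<item>@d<day>"`, ordered day-major: all items of day 1 in
#' catalogue order, then all items of day 2, and so on. This fixed order
#' makes every wide matrix reproducible.
#'
#' @param catalog an [item_catalog].
#' @param n_days number of assessment days (default 5).
#' @return Character vector of length `length(catalog$items) * n_days`.
#' @export
feature_labels <- function(catalog = item_catalog(), n_days = 5L) {
  stopifnot(inherits(catalog, "item_catalog"), is_count(n_days))
  as.vector(vapply(seq_len(n_days),
                   function(d) paste0(catalog$items, "@d", d),
                   character(length(catalog$items))))
}

#' Parse feature labels back to (item, day)
#'
#' @param labels character vector of `"<item>@d<day>"` labels.
#' @param catalog an [item_catalog]; items must belong to it.
#' @return A data frame with columns `item` and `day`.
#' @export
parse_feature_labels <- function(labels, catalog = item_catalog()) {
  m <- regmatches(labels, regexec("^(.*)@d([0-9]+)$", labels))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("malformed feature label(s): ",
         abbreviate_list(labels[bad]), call. = FALSE)
  item <- vapply(m, `[`, "", 2L)
  day <- as.integer(vapply(m, `[`, "", 3L))
  unknown <- setdiff(item, catalog$items)
  if (length(unknown))
    stop("unknown item(s) in feature labels: ",
         abbreviate_list(unknown), call. = FALSE)
  data.frame(item = item, day = day, stringsAsFactors = FALSE)
}
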
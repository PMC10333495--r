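#' Longitudinal ordinal severity scores
#'
#' Tidy container for per-participant, per-day, per-item ordinal scores:
#' the raw input of the phenotyping pipeline. Each record is one cell
#' `(participant, day, item, score)`; at most one record may exist per
#' cell, days are integers `1..n_days`, items must belong to the
#' catalogue, and scores must lie within the catalogue's ordinal range.
#'
#' @param records data frame with columns `participant`, `day`, `item`,
#'   `score`.
#' @param catalog an [item_catalog] (default: the 13 DRS-R-98 items,
#'   scored 0--3).
#' @param n_days number of assessment days (default 5).
#' @return An object of class `longitudinal_scores`: a list with elements
#'   `records` (validated, row-sorted data frame), `catalog`, `n_days`.
#' @seealso [read_long()], [to_wide()], [max_total_severity()]
#' @export
#' @examples
#' rec <- expand.grid(participant = "P1", day = 1:5,
#'                    item = drs_r98_items(), stringsAsFactors = FALSE)
#' rec$score <- 0L
#' longitudinal_scores(rec)
longitudinal_scores <- function(records, catalog = item_catalog(),
                                n_days = 5L) {
  stopifnot(inherits(catalog, "item_catalog"), is_count(n_days))
  records <- validate_records(records, catalog, n_days)
  structure(list(records = records, catalog = catalog,
                 n_days = as.integer(n_days)),
            class = "longitudinal_scores")
}

validate_records <- function(records, catalog, n_days, lines = NULL) {
  if (!is.data.frame(records))
    stop("`records` must be a data frame", call. = FALSE)
  need <- c("participant", "day", "item", "score")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  records <- records[need]
  if (is.null(lines)) lines <- seq_len(nrow(records))
  where <- function(i) {
    paste0(if (is.null(lines)) "row " else "line ",
           abbreviate_list(lines[i]))
  }

  records$participant <- as.character(records$participant)
  day <- suppressWarnings(as.numeric(records$day))
  score <- suppressWarnings(as.numeric(records$score))
  records$item <- as.character(records$item)

  bad <- is.na(records$participant) | !nzchar(records$participant) |
    is.na(records$item) | !nzchar(records$item) |
    is.na(day) | day != round(day) | is.na(score) | score != round(score)
  if (any(bad))
    stop("malformed record(s) at ", where(which(bad)), call. = FALSE)
  records$day <- as.integer(day)
  records$score <- as.integer(score)

  bad <- records$day < 1L | records$day > n_days
  if (any(bad))
    stop(sprintf("day out of range [1,%d] at %s", n_days,
                 where(which(bad))), call. = FALSE)
  bad <- !(records$item %in% catalog$items)
  if (any(bad))
    stop("unknown item(s) ",
         abbreviate_list(unique(records$item[bad])),
         " at ", where(which(bad)), call. = FALSE)
  bad <- records$score < catalog$score_min | records$score > catalog$score_max
  if (any(bad))
    stop(sprintf("score out of range [%d,%d] at %s", catalog$score_min,
                 catalog$score_max, where(which(bad))), call. = FALSE)

  key <- paste(records$participant, records$day, records$item, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (participant, day, item) record(s) at ",
         where(which(duplicated(key))), call. = FALSE)

  ord <- order(records$participant, records$day,
               match(records$item, catalog$items))
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  records
}

#' @export
print.longitudinal_scores <- function(x, ...) {
  ids <- unique(x$records$participant)
  cat(sprintf(
    "Longitudinal scores: %d records, %d participants, %d items x %d days\n",
    nrow(x$records), length(ids), length(x$catalog$items), x$n_days))
  comp <- complete_participants(x)
  cat(sprintf("  complete participants: %d of %d\n", sum(comp), length(comp)))
  invisible(x)
}

#' Which participants have every cell observed?
#'
#' A participant is complete when all `n_days * length(items)` cells are
#' present. Only complete participants can enter the wide matrix.
#'
#' @param scores a [longitudinal_scores] object.
#' @return Named logical vector, one element per participant.
#' @export
complete_participants <- function(scores) {
  stopifnot(inherits(scores, "longitudinal_scores"))
  full <- scores$n_days * length(scores$catalog$items)
  cnt <- table(scores$records$participant)
  out <- as.vector(cnt) == full
  names(out) <- names(cnt)
  out
}

#' Peak daily total severity per participant
#'
#' For each requested participant, the daily total is the sum of all item
#' scores on one day; the statistic returned is the maximum daily total
#' over the observation window (for the default catalogue, a value in
#' 0--39). This is the severity measure used to order participant
#' clusters.
#'
#' @param scores a [longitudinal_scores] object.
#' @param participant_id character vector of participants (default: all
#'   complete participants). Unknown or incomplete participants are an
#'   error.
#' @return Named numeric vector of peak daily totals.
#' @export
#' @examples
#' coh <- simulate_cohort(default_design(), seed = 1)
#' head(max_total_severity(coh$scores))
max_total_severity <- function(scores, participant_id = NULL) {
  stopifnot(inherits(scores, "longitudinal_scores"))
  comp <- complete_participants(scores)
  if (is.null(participant_id)) {
    participant_id <- names(comp)[comp]
  } else {
    participant_id <- as.character(participant_id)
    unknown <- setdiff(participant_id, names(comp))
    if (length(unknown))
      stop("unknown participant(s): ", abbreviate_list(unknown),
           call. = FALSE)
    incomplete <- participant_id[!comp[participant_id]]
    if (length(incomplete))
      stop("incomplete participant(s): ", abbreviate_list(incomplete),
           call. = FALSE)
  }
  rec <- scores$records[scores$records$participant %in% participant_id, ]
  daily <- rowsum(rec$score, paste(rec$participant, rec$day, sep = "\r"))
  pid <- sub("\r.*$", "", rownames(daily))
  peak <- vapply(split(daily[, 1L], pid), max, numeric(1))
  peak[participant_id]
}
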
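#' Meal-slot schema for the 24-hour diary
#'
#' The diary records eleven predefined eating occasions ("food contacts"):
#' the three main meals, four planned snack slots and four nibbling slots
#' (unplanned, constant between-meal eating). Each slot covers a fixed
#' clock window; a window `[start, end]` marks every integer hour
#' `start..end` inclusive on the grid `t = 1..24`.
#'
#' Snack windows sit inside the corresponding nibbling windows (e.g. the
#' morning snack 10-11 inside morning nibbling 9-12), so a patient flagging
#' both contributes a single 1 per hour: windows combine by union.
#'
#' @return A tibble with columns `slot`, `window_start`, `window_end`
#'   (hour-of-day integers in 1..24), one row per slot.
#' @examples
#' meal_slot_schema()
#' @export
meal_slot_schema <- function() {
  tibble::tibble(
    slot = c(
      "breakfast", "morning_nibbling", "morning_snack", "lunch",
      "afternoon_nibbling", "afternoon_snack", "dinner",
      "evening_nibbling", "evening_snack", "night_nibbling", "night_snack"
    ),
    window_start = c(7L, 9L, 10L, 12L, 14L, 16L, 19L, 21L, 21L, 1L, 3L),
    window_end   = c(8L, 12L, 11L, 13L, 18L, 17L, 20L, 24L, 22L, 6L, 4L)
  )
}

#' Names of the eleven meal-slot flag columns
#' @return Character vector of length 11.
#' @export
slot_names <- function() meal_slot_schema()$slot

validate_schema <- function(schema) {
  stopifnot(is.data.frame(schema))
  req <- c("slot", "window_start", "window_end")
  if (!all(req %in% names(schema))) {
    abort("schema must have columns slot, window_start, window_end")
  }
  if (nrow(schema) != 11L || anyDuplicated(schema$slot)) {
    abort("schema must contain exactly 11 uniquely named slots")
  }
  with(schema, {
    if (any(window_start < 1 | window_end > 24 | window_end < window_start)) {
      abort("slot windows must satisfy 1 <= start <= end <= 24")
    }
  })
  invisible(schema)
}

validate_contacts <- function(contacts) {
  miss <- setdiff(slot_names(), names(contacts))
  if (length(miss)) {
    abort(paste0("missing contact flag column(s): ", paste(miss, collapse = ", ")))
  }
  for (s in slot_names()) {
    v <- contacts[[s]]
    bad <- which(!(v %in% c(0, 1)) | is.na(v))
    if (length(bad)) {
      abort(paste0("non-binary value in flag '", s, "' at row ", bad[1]))
    }
  }
  invisible(contacts)
}

#' Expand contact flags into hourly step functions
#'
#' Turns the eleven binary meal-contact flags of each patient into a binary
#' step function y(t) on the hourly grid t = 1..24: y(t) = 1 exactly when
#' hour t falls inside the window of at least one flagged slot (union over
#' overlapping windows, so co-flagged nested slots are not double counted).
#'
#' @param contacts Data frame with a `patient_id` column and the eleven
#'   flag columns named as in [slot_names()].
#' @param schema Slot schema, by default [meal_slot_schema()].
#' @return A tibble in long format with columns `patient_id`, `hour`
#'   (1..24) and `y` (0/1), 24 rows per patient.
#' @examples
#' df <- tibble::tibble(patient_id = "p1", breakfast = 1, morning_nibbling = 0,
#'   morning_snack = 0, lunch = 1, afternoon_nibbling = 0, afternoon_snack = 0,
#'   dinner = 1, evening_nibbling = 0, evening_snack = 0, night_nibbling = 0,
#'   night_snack = 0)
#' sum(contacts_to_series(df)$y)  # 6 hours: 7,8,12,13,19,20
#' @export
contacts_to_series <- function(contacts, schema = meal_slot_schema()) {
  validate_schema(schema)
  validate_contacts(contacts)
  if (!"patient_id" %in% names(contacts)) {
    contacts$patient_id <- as.character(seq_len(nrow(contacts)))
  }
  Y <- series_matrix(contacts, schema)
  tibble::tibble(
    patient_id = rep(rownames(Y), each = 24L),
    hour = rep(1:24, times = nrow(Y)),
    y = as.vector(t(Y))
  )
}

# N x 24 binary matrix of hourly step functions, rownames = patient_id
series_matrix <- function(contacts, schema = meal_slot_schema()) {
  # 11 x 24 window indicator
  win <- vapply(seq_len(nrow(schema)), function(i) {
    as.numeric(1:24 >= schema$window_start[i] & 1:24 <= schema$window_end[i])
  }, numeric(24))
  colnames(win) <- schema$slot
  flags <- as.matrix(contacts[, schema$slot, drop = FALSE])
  storage.mode(flags) <- "double"
  Y <- (flags %*% t(win)) > 0
  storage.mode(Y) <- "double"
  rownames(Y) <- as.character(contacts$patient_id %||% seq_len(nrow(flags)))
  Y
}
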
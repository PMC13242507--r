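#' The five emotion labels
#'
#' The admissible rating-scale labels, in their canonical (alphabetical)
#' order: anger < disgust < fear < happiness < sadness. All combination keys,
#' table orderings and confusion-kernel dimensions follow this order.
#'
#' @return A character vector of length 5.
#' @export
#' @examples
#' emotion_labels()
emotion_labels <- function() {
  c("anger", "disgust", "fear", "happiness", "sadness")
}

#' The three prominence-proportion conditions
#'
#' Proportion labels are interpreted relative to the stored
#' (`emotion_first`, `emotion_second`) order of a stimulus: under `"30:70"`
#' the second emotion is the more prominent, under `"70:30"` the first is,
#' and under `"50:50"` neither. The labels denote intended relative salience,
#' not exact percentages.
#'
#' @return A character vector of length 3, in display order.
#' @export
proportion_levels <- function() {
  c("30:70", "50:50", "70:30")
}

assert_emotion <- function(x, arg = deparse(substitute(x))) {
  bad <- !x %in% emotion_labels()
  if (any(bad)) {
    stop(sprintf("`%s` contains invalid emotion label(s): %s", arg,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Canonical combination key for an emotion pair
#'
#' Orders the two emotions of a blend alphabetically and joins them with
#' `"-"`, giving one of the 10 possible combination keys. Symmetric in its
#' arguments; identical labels are a degenerate pair and raise an error.
#'
#' @param a,b Character vectors of emotion labels (recycled to a common
#'   length).
#' @return A character vector of combination keys, e.g. `"anger-sadness"`.
#' @export
#' @examples
#' canonical_pair("sadness", "anger") # "anger-sadness"
canonical_pair <- function(a, b) {
  assert_emotion(a, "a")
  assert_emotion(b, "b")
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  if (any(a == b)) {
    stop("degenerate pair: the two emotions of a blend must differ",
         call. = FALSE)
  }
  paste(pmin(a, b), pmax(a, b), sep = "-")
}

#' All 10 pairwise combination keys
#'
#' @return Character vector of the 10 canonical combination keys, in
#'   alphabetical order.
#' @export
all_combinations <- function() {
  e <- emotion_labels()
  idx <- utils::combn(5L, 2L)
  paste(e[idx[1L, ]], e[idx[2L, ]], sep = "-")
}

#' Split combination keys back into their two emotions
#'
#' @param key Character vector of combination keys.
#' @return A tibble with columns `low` and `high` (alphabetical order).
#' @export
split_combination <- function(key) {
  parts <- stringr::str_split_fixed(key, "-", 2L)
  tibble::tibble(low = parts[, 1L], high = parts[, 2L])
}

#' More- and less-prominent emotion of an unequal-proportion stimulus
#'
#' For `"30:70"` the second stored emotion is the more prominent; for
#' `"70:30"` the first. `"50:50"` has no prominence ordering and yields `NA`.
#'
#' @param emotion_first,emotion_second Stored emotion order of the stimulus.
#' @param proportion Proportion condition labels.
#' @return A tibble with columns `prominent` and `subtle`.
#' @export
prominence <- function(emotion_first, emotion_second, proportion) {
  stopifnot(all(proportion %in% proportion_levels()))
  prominent <- dplyr::case_when(
    proportion == "70:30" ~ emotion_first,
    proportion == "30:70" ~ emotion_second,
    TRUE ~ NA_character_
  )
  subtle <- dplyr::case_when(
    proportion == "70:30" ~ emotion_second,
    proportion == "30:70" ~ emotion_first,
    TRUE ~ NA_character_
  )
  tibble::tibble(prominent = prominent, subtle = subtle)
}

rating_cols <- function() paste0("rating_", emotion_labels())
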
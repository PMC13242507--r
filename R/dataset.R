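#' Construct a blended-emotion judgment dataset
#'
#' A dataset is a tibble with one row per (participant, stimulus) judgment
#' and columns `participant_id`, `stimulus_id`, `actor_id`, `emotion_first`,
#' `emotion_second`, `proportion`, and five rating columns `rating_anger` ...
#' `rating_sadness`. A rating is an integer 0-10 on a scale the participant
#' selected, and `NA` on a scale they did not select: "not selected" and
#' "rated 0" are distinct states throughout.
#'
#' @param x A data frame with the columns above.
#' @param mode `"forced2"` (exactly two scales per judgment) or `"free"`
#'   (one to five scales).
#' @param check Validate invariants and fail on violations (default `TRUE`).
#' @return A `blend_dataset` tibble with a `mode` attribute.
#' @export
blend_dataset <- function(x, mode = c("forced2", "free"), check = TRUE) {
  mode <- match.arg(mode)
  required <- c("participant_id", "stimulus_id", "actor_id",
                "emotion_first", "emotion_second", "proportion",
                rating_cols())
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- tibble::as_tibble(x)[required]
  x <- dplyr::mutate(
    x,
    dplyr::across(dplyr::all_of(c("participant_id", "stimulus_id", "actor_id",
                                  "emotion_first", "emotion_second",
                                  "proportion")), as.character),
    dplyr::across(dplyr::all_of(rating_cols()), as.integer)
  )
  ds <- structure(x, mode = mode,
                  class = c("blend_dataset", class(tibble::tibble())))
  if (check) {
    problems <- validate_dataset(ds)
    errors <- problems$message[problems$severity == "error"]
    if (length(errors) > 0L) {
      stop("invalid dataset:\n  ", paste(errors, collapse = "\n  "),
           call. = FALSE)
    }
  }
  ds
}

#' @export
print.blend_dataset <- function(x, ...) {
  cat(sprintf("# blend_dataset (%s mode): %d judgments, %d participants, %d stimuli\n",
              dataset_mode(x), nrow(x),
              dplyr::n_distinct(x$participant_id),
              dplyr::n_distinct(x$stimulus_id)))
  NextMethod()
}

#' Response mode of a dataset
#' @param ds A `blend_dataset`.
#' @return `"forced2"` or `"free"`.
#' @export
dataset_mode <- function(ds) {
  mode <- attr(ds, "mode", exact = TRUE)
  if (is.null(mode)) "free" else mode
}

#' Number of scales selected per judgment
#' @param ds A `blend_dataset` (or any tibble with the rating columns).
#' @return Integer vector, one entry per row, in 1..5.
#' @export
k_selected <- function(ds) {
  rowSums(!is.na(as.matrix(ds[rating_cols()])))
}

#' Read a judgment dataset from CSV
#'
#' Reads the long-format trial CSV dialect: UTF-8, header required, one row
#' per (participant, stimulus), empty rating cells meaning "scale not
#' selected" (never rating 0). Structural problems (out-of-range ratings,
#' duplicate judgments, wrong selection count under `forced2`) are reported
#' with row numbers.
#'
#' @param path Path to the CSV file.
#' @param mode Response mode the file must conform to.
#' @return A validated [blend_dataset()].
#' @export
load_dataset <- function(path, mode = c("forced2", "free")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  required <- c("participant_id", "stimulus_id", "actor_id", "emotion_first",
                "emotion_second", "proportion", rating_cols())
  absent <- setdiff(required, trimws(header))
  if (length(absent) > 0L) {
    stop("CSV header is missing column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      stimulus_id = readr::col_character(),
      actor_id = readr::col_character(),
      emotion_first = readr::col_character(),
      emotion_second = readr::col_character(),
      proportion = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  ds <- blend_dataset(raw, mode = mode, check = FALSE)
  problems <- validate_dataset(ds)
  errors <- problems[problems$severity == "error", ]
  if (nrow(errors) > 0L) {
    stop("malformed dataset in ", path, ":\n  ",
         paste(errors$message, collapse = "\n  "), call. = FALSE)
  }
  ds
}

#' Write a judgment dataset to CSV
#'
#' Inverse of [load_dataset()]: unselected scales are written as empty cells,
#' so a read/write cycle preserves the selection pattern and ratings exactly.
#'
#' @param ds A `blend_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  readr::write_csv(tibble::as_tibble(ds), path, na = "")
  invisible(path)
}

#' Validate a judgment dataset
#'
#' Checks every structural invariant — admissible emotion labels and
#' proportions, non-degenerate pairs, integer ratings in 0-10, at least one
#' and at most five selected scales (exactly two under `forced2`), unique
#' (participant, stimulus) pairs — and, as a warning rather than an error,
#' design completeness (every participant judged every stimulus).
#'
#' @param ds A `blend_dataset`.
#' @return A tibble of findings with columns `severity` (`"error"` or
#'   `"warning"`), `row` (first offending row, `NA` for dataset-level
#'   findings) and `message`. Zero rows when the dataset is clean.
#' @export
validate_dataset <- function(ds) {
  findings <- list()
  add <- function(severity, row, message) {
    findings[[length(findings) + 1L]] <<-
      tibble::tibble(severity = severity, row = row, message = message)
  }
  rownum <- seq_len(nrow(ds))

  bad <- rownum[!ds$emotion_first %in% emotion_labels() |
                  !ds$emotion_second %in% emotion_labels()]
  for (r in bad) add("error", r, sprintf("row %d: invalid emotion label", r))

  bad <- rownum[ds$emotion_first == ds$emotion_second]
  for (r in bad) add("error", r, sprintf("row %d: degenerate emotion pair", r))

  bad <- rownum[!ds$proportion %in% proportion_levels()]
  for (r in bad) add("error", r, sprintf("row %d: invalid proportion '%s'",
                                         r, ds$proportion[r]))

  rat <- as.matrix(ds[rating_cols()])
  out_of_range <- which(!is.na(rat) & (rat < 0 | rat > 10), arr.ind = TRUE)
  for (r in unique(out_of_range[, 1L])) {
    add("error", r, sprintf("row %d: rating outside 0-10", r))
  }

  k <- rowSums(!is.na(rat))
  bad <- rownum[k < 1L]
  for (r in bad) add("error", r, sprintf("row %d: no scale selected", r))
  if (dataset_mode(ds) == "forced2") {
    bad <- rownum[k >= 1L & k != 2L]
    for (r in bad) {
      add("error", r,
          sprintf("row %d: %d scales selected; forced2 mode requires exactly 2",
                  r, k[r]))
    }
  }

  dup <- duplicated(ds[c("participant_id", "stimulus_id")])
  for (r in rownum[dup]) {
    add("error", r,
        sprintf("row %d: duplicate (participant '%s', stimulus '%s') judgment",
                r, ds$participant_id[r], ds$stimulus_id[r]))
  }

  # referential integrity of the stimulus table implied by the rows: a
  # stimulus_id must map to a single (actor, pair, proportion) description
  stim <- dplyr::distinct(
    tibble::as_tibble(ds),
    .data$stimulus_id, .data$actor_id, .data$emotion_first,
    .data$emotion_second, .data$proportion
  )
  clash <- stim$stimulus_id[duplicated(stim$stimulus_id)]
  for (s in unique(clash)) {
    add("error", NA_integer_,
        sprintf("stimulus '%s' has conflicting descriptions across rows", s))
  }

  # completeness: every participant saw every stimulus (warning only)
  n_stim <- dplyr::n_distinct(ds$stimulus_id)
  seen <- dplyr::count(tibble::as_tibble(ds), .data$participant_id)
  incomplete <- seen[seen$n < n_stim, ]
  if (nrow(incomplete) > 0L) {
    all_stim <- unique(ds$stimulus_id)
    for (i in seq_len(nrow(incomplete))) {
      p <- incomplete$participant_id[i]
      missing <- setdiff(all_stim, ds$stimulus_id[ds$participant_id == p])
      add("warning", NA_integer_,
          sprintf("participant '%s' is missing %d stimuli: %s", p,
                  length(missing), paste(missing, collapse = ", ")))
    }
  }

  if (length(findings) == 0L) {
    return(tibble::tibble(severity = character(), row = integer(),
                          message = character()))
  }
  dplyr::bind_rows(findings)
}

#' Extract the stimulus table of a dataset
#'
#' @param ds A `blend_dataset`.
#' @return A tibble with one row per stimulus: `stimulus_id`, `actor_id`,
#'   `emotion_first`, `emotion_second`, `proportion`, and the canonical
#'   `combination` key.
#' @export
stimuli <- function(ds) {
  dplyr::mutate(
    dplyr::distinct(
      tibble::as_tibble(ds),
      .data$stimulus_id, .data$actor_id, .data$emotion_first,
      .data$emotion_second, .data$proportion
    ),
    combination = canonical_pair(.data$emotion_first, .data$emotion_second)
  )
}
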
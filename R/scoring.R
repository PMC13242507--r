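#' Score every judgment under the three accuracy indices
#'
#' Per-trial 0/1 correctness under the three indices used for blended-emotion
#' recognition:
#' \describe{
#'   \item{generous}{1 iff at least one selected scale matches one of the two
#'     intended emotions.}
#'   \item{strict}{1 iff the selected scales cover both intended emotions.
#'     Under the default `"superset"` policy extra selections are allowed
#'     (relevant in free mode); under `"exact"` the selected set must equal
#'     the intended pair.}
#'   \item{very_strict}{Defined only for the unequal 30:70 / 70:30
#'     conditions (`NA` for 50:50): 1 iff strict is 1 and the more prominent
#'     intended emotion received a strictly higher rating than the less
#'     prominent one. Ties score 0.}
#' }
#' On every trial `generous >= strict` and, where defined,
#' `strict >= very_strict`.
#'
#' @param ds A [blend_dataset()].
#' @param strict_policy `"superset"` (default) or `"exact"`.
#' @return A tibble with one row per judgment: identifiers, `combination`,
#'   `proportion`, `k_selected`, and integer columns `generous`, `strict`,
#'   `very_strict`.
#' @export
score_trials <- function(ds, strict_policy = c("superset", "exact")) {
  strict_policy <- match.arg(strict_policy)
  rat <- as.matrix(ds[rating_cols()])
  labels <- emotion_labels()
  n <- nrow(ds)
  i_first <- match(ds$emotion_first, labels)
  i_second <- match(ds$emotion_second, labels)
  sel <- !is.na(rat)
  k <- rowSums(sel)
  first_sel <- sel[cbind(seq_len(n), i_first)]
  second_sel <- sel[cbind(seq_len(n), i_second)]

  generous <- as.integer(first_sel | second_sel)
  strict <- as.integer(first_sel & second_sel)
  if (strict_policy == "exact") {
    strict <- as.integer(strict == 1L & k == 2L)
  }

  prom <- prominence(ds$emotion_first, ds$emotion_second, ds$proportion)
  i_prom <- match(prom$prominent, labels)
  i_sub <- match(prom$subtle, labels)
  unequal <- ds$proportion != "50:50"
  very_strict <- rep(NA_integer_, n)
  idx <- which(unequal)
  if (length(idx) > 0L) {
    r_prom <- rat[cbind(idx, i_prom[idx])]
    r_sub <- rat[cbind(idx, i_sub[idx])]
    ordered_ok <- !is.na(r_prom) & !is.na(r_sub) & r_prom > r_sub
    very_strict[idx] <- as.integer(strict[idx] == 1L & ordered_ok)
  }

  tibble::tibble(
    participant_id = ds$participant_id,
    stimulus_id = ds$stimulus_id,
    actor_id = ds$actor_id,
    combination = canonical_pair(ds$emotion_first, ds$emotion_second),
    proportion = ds$proportion,
    k_selected = as.integer(k),
    generous = generous,
    strict = strict,
    very_strict = very_strict
  )
}

wald_ci <- function(p, n, level) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(max(0, p - half), min(1, p + half))
}

wilson_ci <- function(p, n, level) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

#' Aggregate trial scores into accuracy estimates per cell
#'
#' Pools the 0/1 trial scores of one index within each grouping cell and
#' reports the proportion correct, its sample SD, a 95\% (by default)
#' confidence interval, the chance level, and whether the cell is above
#' chance (lower CI bound strictly exceeds chance). Default aggregation pools
#' trials across participants and actors; `unit = "participant"` instead
#' averages per-participant accuracies.
#'
#' @param scores Output of [score_trials()].
#' @param index `"generous"`, `"strict"` or `"very_strict"`.
#' @param by Character vector of grouping columns (any of `"combination"`,
#'   `"proportion"`, `"actor_id"`, `"participant_id"`); empty (default) for a
#'   single overall cell.
#' @param chance Chance probability to compare against. Defaults to the
#'   analytic fixed two-selection value for the index (see
#'   [analytic_chance()]).
#' @param ci_method `"wald"` (normal approximation, default) or `"wilson"`.
#' @param level Confidence level, default 0.95.
#' @param unit `"trial"` (pool trials, default) or `"participant"`.
#' @return A `blend_accuracy` tibble: grouping columns, `index`, `n`,
#'   `mean`, `sd`, `ci_low`, `ci_high`, `chance`, `above_chance`. For
#'   `very_strict`, 50:50 trials are excluded before aggregation.
#' @export
aggregate_accuracy <- function(scores, index = c("generous", "strict", "very_strict"),
                               by = character(), chance = NULL,
                               ci_method = c("wald", "wilson"), level = 0.95,
                               unit = c("trial", "participant")) {
  index <- match.arg(index)
  ci_method <- match.arg(ci_method)
  unit <- match.arg(unit)
  if (is.null(chance)) chance <- analytic_chance(index, k = 2L)
  ci_fun <- if (ci_method == "wald") wald_ci else wilson_ci

  x <- scores[!is.na(scores[[index]]), ]
  if (nrow(x) == 0L) stop("no scorable trials for index '", index, "'",
                          call. = FALSE)
  if (unit == "participant") {
    x <- dplyr::summarise(
      dplyr::group_by(x, dplyr::across(dplyr::all_of(unique(c(by, "participant_id"))))),
      .value = mean(.data[[index]]), .groups = "drop"
    )
    names(x)[names(x) == ".value"] <- index
  }

  grouped <- dplyr::group_by(x, dplyr::across(dplyr::all_of(by)))
  out <- dplyr::summarise(
    grouped,
    n = dplyr::n(),
    mean = mean(.data[[index]]),
    sd = stats::sd(.data[[index]]),
    .groups = "drop"
  )
  if (any(out$n < 1L)) stop("empty cell in accuracy aggregation", call. = FALSE)
  ci <- purrr::map2(out$mean, out$n, ci_fun, level = level)
  out <- dplyr::mutate(
    out,
    index = index,
    sd = dplyr::coalesce(.data$sd, 0),
    ci_low = purrr::map_dbl(ci, 1L),
    ci_high = purrr::map_dbl(ci, 2L),
    chance = chance,
    above_chance = .data$ci_low > chance
  )
  out <- dplyr::relocate(out, "index", .before = "n")
  structure(out, class = c("blend_accuracy", class(out)))
}

#' Distribution of the number of scales used per judgment
#'
#' Describes how many of the five rating scales raters chose to use,
#' primarily of interest for free-selection data. Percentages are over all
#' judgments; the SD of the per-judgment count uses the sample (n-1)
#' formula.
#'
#' @param ds A [blend_dataset()].
#' @return A `blend_scale_usage` tibble with columns `k`, `n`, `pct`, and
#'   attributes `mean_k` and `sd_k` (see [glance.blend_scale_usage()]).
#' @export
scale_usage_summary <- function(ds) {
  if (nrow(ds) == 0L) stop("empty dataset", call. = FALSE)
  k <- k_selected(ds)
  tab <- dplyr::count(tibble::tibble(k = as.integer(k)), .data$k, name = "n")
  tab <- dplyr::mutate(tab, pct = 100 * .data$n / sum(.data$n))
  structure(tab,
            mean_k = mean(k),
            sd_k = stats::sd(k),
            n_judgments = length(k),
            class = c("blend_scale_usage", class(tab)))
}

#' @rdname scale_usage_summary
#' @param x A `blend_scale_usage` object.
#' @param ... Unused.
#' @export
glance.blend_scale_usage <- function(x, ...) {
  tibble::tibble(
    mean_k = attr(x, "mean_k"),
    sd_k = attr(x, "sd_k"),
    n = attr(x, "n_judgments")
  )
}

#' Mean (and SD) rating per combination, proportion and scale
#'
#' The cell table of mean intensity ratings, one cell per
#' 10 combinations x 3 proportions x 5 scales. Unselected scales contribute 0
#' to the mean: the cell mean is the average endorsed intensity over all
#' judgments in the cell, with non-use counted as zero intensity.
#'
#' @param ds A [blend_dataset()].
#' @return A tibble with columns `combination`, `proportion`, `scale`,
#'   `n`, `mean`, `sd`.
#' @export
cell_mean_ratings <- function(ds) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(ds),
                  combination = canonical_pair(.data$emotion_first,
                                               .data$emotion_second)),
    cols = dplyr::all_of(rating_cols()),
    names_to = "scale", names_prefix = "rating_",
    values_to = "rating"
  )
  long$rating[is.na(long$rating)] <- 0L
  dplyr::summarise(
    dplyr::group_by(long, .data$combination, .data$proportion, .data$scale),
    n = dplyr::n(),
    mean = mean(.data$rating),
    sd = stats::sd(.data$rating),
    .groups = "drop"
  )
}
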
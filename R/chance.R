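#' Exact chance level of an accuracy index under random responding
#'
#' Probability of a correct response when a rater selects `k` of the `m`
#' scales uniformly at random, for a stimulus with `t` intended target
#' emotions. Computed by exact enumeration of all `choose(m, k)` unordered
#' selections:
#' \describe{
#'   \item{generous}{probability the selection intersects the targets.}
#'   \item{strict}{probability the selection contains all targets.}
#'   \item{very_strict}{strict probability times 1/2: under the null the
#'     ratings on the two target scales are exchangeable continuous
#'     variables, so given both targets are selected the more prominent one
#'     outranks the other with probability 1/2 (ties have measure zero).
#'     With integer ratings ties are possible and score 0, so an
#'     integer-rating null lies below this value; see
#'     [simulate_random_responder()].}
#' }
#' With five scales and two targets the fixed two-selection values are 0.70
#' (generous), 0.10 (strict) and 0.05 (very strict).
#'
#' @param index `"generous"`, `"strict"` or `"very_strict"`.
#' @param k Number of scales selected (1..m).
#' @param m Number of available scales (default 5).
#' @param t Number of intended target emotions (default 2).
#' @return A probability in \[0, 1\].
#' @export
#' @examples
#' analytic_chance("generous", k = 2)    # 0.70
#' analytic_chance("strict", k = 2)      # 0.10
#' analytic_chance("very_strict", k = 2) # 0.05
analytic_chance <- function(index = c("generous", "strict", "very_strict"),
                            k, m = 5L, t = 2L) {
  index <- match.arg(index)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > m) {
    stop("`k` must be a single integer in 1..", m, call. = FALSE)
  }
  if (t > m) stop("`t` cannot exceed `m`", call. = FALSE)
  selections <- utils::combn(m, k, simplify = FALSE)
  targets <- seq_len(t)
  hit_any <- vapply(selections, function(s) any(targets %in% s), logical(1))
  hit_all <- vapply(selections, function(s) all(targets %in% s), logical(1))
  switch(index,
         generous = mean(hit_any),
         strict = mean(hit_all),
         very_strict = mean(hit_all) / 2)
}

#' Chance level under a distribution over the number of selections
#'
#' When raters are free to select any number of scales, the chance level of
#' an index is the mixture of the fixed-`k` values weighted by the selection
#' count distribution: `sum_k d(k) * analytic_chance(index, k)`.
#'
#' @inheritParams analytic_chance
#' @param d Named numeric vector of weights over selection counts; names are
#'   the counts (e.g. `c("1" = .5, "3" = .5)`). Must be nonnegative and sum
#'   to 1 (tolerance 1e-8).
#' @return A probability in \[0, 1\].
#' @export
#' @examples
#' mixture_chance("generous", c("1" = 0.5, "3" = 0.5)) # 0.65
mixture_chance <- function(index = c("generous", "strict", "very_strict"),
                           d, m = 5L, t = 2L) {
  index <- match.arg(index)
  if (is.null(names(d))) stop("`d` must be a named vector (names = counts)",
                              call. = FALSE)
  ks <- as.integer(names(d))
  if (anyNA(ks) || any(ks < 1L) || any(ks > m)) {
    stop("selection counts in `d` must be integers in 1..", m, call. = FALSE)
  }
  if (any(d < 0) || abs(sum(d) - 1) > 1e-8) {
    stop("`d` must be nonnegative and sum to 1", call. = FALSE)
  }
  sum(d * vapply(ks, function(k) analytic_chance(index, k, m = m, t = t),
                 numeric(1)))
}

#' Empirical selection-count distribution of a dataset
#'
#' @param ds A [blend_dataset()].
#' @return A named numeric vector of proportions over observed selection
#'   counts, suitable for [mixture_chance()].
#' @export
empirical_k_distribution <- function(ds) {
  k <- k_selected(ds)
  tab <- table(factor(k, levels = 1:5))
  d <- as.numeric(tab) / sum(tab)
  names(d) <- names(tab)
  d[d > 0]
}

#' Table of chance levels for every index and selection count
#'
#' @inheritParams analytic_chance
#' @return A tibble with columns `index`, `k`, `chance`.
#' @export
chance_table <- function(m = 5L, t = 2L) {
  tidyr::expand_grid(index = c("generous", "strict", "very_strict"),
                     k = seq_len(m)) |>
    dplyr::mutate(chance = purrr::map2_dbl(.data$index, .data$k,
                                           analytic_chance, m = m, t = t))
}

#' Monte-Carlo random-responder estimate of a chance level
#'
#' Independent oracle for [analytic_chance()]: simulates raters who select
#' scales uniformly at random (a uniform 2-subset in `forced2` mode, or a
#' count drawn from `d` followed by a uniform subset of that size in `free`
#' mode) and give independent continuous uniform ratings on the selected
#' scales, then scores each trial with [score_trials()] against a fixed
#' target pair with 70:30 prominence. Continuous ratings make rating ties
#' measure-zero, matching the analytic very-strict null; set
#' `integer_ratings = TRUE` for the conservative discrete variant, whose
#' very-strict estimate falls below the analytic value because ties score 0.
#'
#' @param index `"generous"`, `"strict"` or `"very_strict"`.
#' @param mode `"forced2"` or `"free"`.
#' @param d Selection-count distribution (required for `mode = "free"`).
#' @param n_trials Number of simulated trials.
#' @param seed Integer seed; the estimate is reproducible given the seed.
#' @param integer_ratings Round ratings to the 0-10 integer grid (default
#'   `FALSE`).
#' @return A tibble with columns `index`, `estimate`, `se` (binomial
#'   Monte-Carlo standard error) and `n`.
#' @export
simulate_random_responder <- function(index = c("generous", "strict", "very_strict"),
                                      mode = c("forced2", "free"), d = NULL,
                                      n_trials = 1e5, seed = 1L,
                                      integer_ratings = FALSE) {
  index <- match.arg(index)
  mode <- match.arg(mode)
  stopifnot(n_trials >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  labels <- emotion_labels()
  n <- as.integer(n_trials)
  if (mode == "forced2") {
    k <- rep(2L, n)
  } else {
    if (is.null(d)) stop("free mode requires a selection-count distribution `d`",
                         call. = FALSE)
    ks <- as.integer(names(d))
    k <- sample(ks, n, replace = TRUE, prob = d)
  }
  # uniform unordered k-subset per trial: rank iid uniforms
  u <- matrix(stats::runif(n * 5L), nrow = n)
  ranks <- row_rank_desc(u)
  sel <- ranks <= matrix(k, nrow = n, ncol = 5L)
  ratings <- matrix(stats::runif(n * 5L, 0, 10), nrow = n)
  if (integer_ratings) ratings <- round(ratings)
  ratings[!sel] <- NA_real_

  ds <- tibble::tibble(
    participant_id = "mc",
    stimulus_id = as.character(seq_len(n)),
    actor_id = "mc",
    emotion_first = labels[1L],
    emotion_second = labels[2L],
    proportion = "70:30"
  )
  ds[rating_cols()] <- as.data.frame(ratings)
  # bypass integer coercion: scoring only compares ratings, so keep doubles
  ds <- structure(ds, mode = mode,
                  class = c("blend_dataset", class(tibble::tibble())))
  scores <- score_trials(ds)
  x <- scores[[index]]
  est <- mean(x)
  tibble::tibble(index = index, estimate = est,
                 se = sqrt(est * (1 - est) / n), n = n)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
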
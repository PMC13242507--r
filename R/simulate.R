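#' Build a fully crossed stimulus design
#'
#' Each actor portrays every pairwise combination of the five emotions at
#' every proportion condition: `n_actors` x 10 x 3 stimuli with unique IDs.
#' The stored (first, second) emotion order is the alphabetical order, so
#' prominence is carried entirely by the proportion label.
#'
#' @param n_actors Number of actors (>= 1).
#' @param combinations Combination keys to include (default all 10).
#' @param proportions Proportion conditions to include (default all 3).
#' @return A tibble of stimuli: `stimulus_id`, `actor_id`, `emotion_first`,
#'   `emotion_second`, `proportion`.
#' @export
#' @examples
#' nrow(build_design(6)) # 180
build_design <- function(n_actors, combinations = all_combinations(),
                         proportions = proportion_levels()) {
  if (n_actors < 1L) stop("`n_actors` must be >= 1", call. = FALSE)
  stopifnot(all(combinations %in% all_combinations()),
            all(proportions %in% proportion_levels()))
  grid <- tidyr::expand_grid(
    actor_id = sprintf("actor%02d", seq_len(n_actors)),
    combination = combinations,
    proportion = proportions
  )
  pair <- split_combination(grid$combination)
  grid |>
    dplyr::mutate(emotion_first = pair$low,
                  emotion_second = pair$high,
                  stimulus_id = sprintf("%s_%s_%s", .data$actor_id,
                                        .data$combination,
                                        gsub(":", "", .data$proportion))) |>
    dplyr::select("stimulus_id", "actor_id", "emotion_first",
                  "emotion_second", "proportion")
}

#' Default confusion kernel
#'
#' A 5x5 nonnegative leakage matrix `C` with unit diagonal: `C[i, j]` is the
#' fraction of intended emotion i's signal that raters perceive on scale j.
#' Rows need not sum to 1 (leakage, not a probability distribution). The
#' default encodes the qualitative difficulty structure typical of
#' within-valence blends: mutual anger/disgust leakage, stronger
#' fear/sadness leakage, a little fear perceived in anger and disgust
#' displays, and essentially no cross-valence leakage with happiness. The
#' values are simulator conventions, not empirical estimates.
#'
#' @return A 5x5 matrix with `emotion_labels()` dimnames.
#' @export
default_confusion_kernel <- function() {
  e <- emotion_labels()
  C <- diag(5)
  dimnames(C) <- list(intended = e, perceived = e)
  C["anger", "disgust"] <- 0.15
  C["disgust", "anger"] <- 0.15
  C["fear", "sadness"] <- 0.20
  C["sadness", "fear"] <- 0.20
  C["anger", "fear"] <- 0.05
  C["disgust", "fear"] <- 0.05
  C
}

#' Generative parameters of the synthetic rater model
#'
#' A rater perceives latent intensity
#' `mu_j = A * sum_i w_i * C[i, j]` over the two intended emotions `i` with
#' prominence weights `w`, adds independent Gaussian rating noise, clips to
#' the 0-10 response range, rounds to the integer grid, and then selects
#' which scales to report (the two highest under `top2`, or all scales at or
#' above `tau` under `threshold`, with a single-argmax fallback so at least
#' one rating is always given).
#'
#' @param gain Maximum expected intensity `A` of a fully expressed emotion,
#'   in rating units (default 8).
#' @param weights Named list mapping each proportion condition to the
#'   (first, second) prominence weights; each pair sums to 1. The default
#'   0.3/0.7 split is a simulator convention for "less/more prominent".
#' @param kernel Confusion kernel (default [default_confusion_kernel()]).
#' @param sigma Rating noise SD in rating units (default 1).
#' @param policy Selection policy: `"top2"` or `"threshold"`.
#' @param tau Selection threshold in rating units (used by `"threshold"`,
#'   default 2).
#' @param actor_gain Optional named per-actor gain multiplier (default 1 for
#'   every actor).
#' @param seed Integer seed controlling all randomness in
#'   [simulate_study()].
#' @return A `rater_params` list.
#' @export
rater_params <- function(gain = 8,
                         weights = list("30:70" = c(0.3, 0.7),
                                        "50:50" = c(0.5, 0.5),
                                        "70:30" = c(0.7, 0.3)),
                         kernel = default_confusion_kernel(),
                         sigma = 1,
                         policy = c("top2", "threshold"),
                         tau = 2,
                         actor_gain = NULL,
                         seed = 1L) {
  policy <- match.arg(policy)
  stopifnot(gain >= 0, sigma >= 0,
            is.matrix(kernel), all(dim(kernel) == c(5L, 5L)),
            all(diag(kernel) == 1), all(kernel >= 0),
            all(kernel[row(kernel) != col(kernel)] < 1))
  stopifnot(setequal(names(weights), proportion_levels()))
  for (w in weights) stopifnot(length(w) == 2L, abs(sum(w) - 1) < 1e-8)
  structure(list(gain = gain, weights = weights, kernel = kernel,
                 sigma = sigma, policy = policy, tau = tau,
                 actor_gain = actor_gain, seed = as.integer(seed)),
            class = "rater_params")
}

#' Read rater-model parameters from a YAML or JSON config file
#'
#' Accepts the fields of [rater_params()] plus `n_participants`, `n_actors`
#' and `mode`; unknown fields are rejected. The kernel may be given as a
#' list of `from`/`to`/`value` entries overriding the default kernel.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `params` (a `rater_params`),
#'   `n_participants`, `n_actors` and `mode`.
#' @export
read_sim_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- c("gain", "sigma", "tau", "policy", "seed", "kernel",
             "n_participants", "n_actors", "mode")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  kernel <- default_confusion_kernel()
  if (!is.null(cfg$kernel)) {
    entries <- if (is.data.frame(cfg$kernel)) {
      split(cfg$kernel, seq_len(nrow(cfg$kernel)))
    } else cfg$kernel
    for (e in entries) kernel[e$from, e$to] <- e$value
  }
  args <- cfg[intersect(names(cfg), c("gain", "sigma", "tau", "policy", "seed"))]
  params <- do.call(rater_params, c(args, list(kernel = kernel)))
  list(params = params,
       n_participants = cfg$n_participants %||% 40L,
       n_actors = cfg$n_actors %||% 6L,
       mode = cfg$mode %||% "forced2")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

latent_means <- function(design, params) {
  e <- emotion_labels()
  mu <- matrix(0, nrow(design), 5L, dimnames = list(NULL, e))
  w_first <- vapply(params$weights, `[`, numeric(1), 1L)[design$proportion]
  w_second <- vapply(params$weights, `[`, numeric(1), 2L)[design$proportion]
  gain <- rep(params$gain, nrow(design))
  if (!is.null(params$actor_gain)) {
    mult <- params$actor_gain[design$actor_id]
    mult[is.na(mult)] <- 1
    gain <- gain * mult
  }
  C <- params$kernel
  i_first <- match(design$emotion_first, e)
  i_second <- match(design$emotion_second, e)
  for (j in seq_len(5L)) {
    mu[, j] <- gain * (w_first * C[cbind(i_first, j)] +
                         w_second * C[cbind(i_second, j)])
  }
  pmin(pmax(mu, 0), 10)
}

#' Latent perception of one stimulus
#'
#' The pre-selection rating vector a simulated rater forms for a stimulus:
#' the kernel-mixed latent mean plus independent Gaussian noise, clipped to
#' 0-10 and rounded to the integer grid. Uses the current RNG state.
#'
#' @param stimulus One-row tibble (or list) with `actor_id`,
#'   `emotion_first`, `emotion_second`, `proportion`.
#' @param params A [rater_params()] object.
#' @return Named integer vector of 5 ratings.
#' @export
perceive <- function(stimulus, params) {
  stimulus <- tibble::as_tibble(stimulus[c("actor_id", "emotion_first",
                                           "emotion_second", "proportion")])
  mu <- latent_means(stimulus, params)[1L, ]
  noisy <- mu + stats::rnorm(5L, 0, params$sigma)
  r <- as.integer(round(pmin(pmax(noisy, 0), 10)))
  names(r) <- emotion_labels()
  r
}

#' Apply a selection policy to a full rating vector
#'
#' `top2` keeps the two highest ratings (ties broken uniformly at random);
#' `threshold` keeps every scale rated at or above `tau`, falling back to a
#' single argmax (ties again broken at random) when none qualifies, so a
#' response always has at least one rating.
#'
#' @param ratings Named numeric vector of 5 ratings.
#' @param params A [rater_params()] object.
#' @return Named vector with unselected scales set to `NA`.
#' @export
select_scales <- function(ratings, params) {
  stopifnot(length(ratings) == 5L)
  jitter <- stats::runif(5L)
  keep <- if (params$policy == "top2") {
    order(ratings + jitter * 1e-9, decreasing = TRUE)[1:2]
  } else {
    q <- which(ratings >= params$tau)
    if (length(q) > 0L) q else which.max(ratings + jitter * 1e-9)
  }
  out <- ratings
  out[-keep] <- NA
  out
}

#' Simulate a complete judgment study
#'
#' Generates a fully crossed dataset (every participant judges every
#' stimulus) under the synthetic rater model, reproducible bit-for-bit from
#' the seed carried in `params`. The generating latent mean matrix is
#' attached for oracle checks in noise-free settings.
#'
#' @param design Stimulus table from [build_design()].
#' @param n_participants Number of simulated raters.
#' @param params A [rater_params()] object; `params$policy` must match
#'   `mode` (`top2` for `forced2`, `threshold` for `free`).
#' @param mode `"forced2"` or `"free"`.
#' @return A [blend_dataset()] with attribute `latent_means` (stimulus-level
#'   matrix of generative means).
#' @export
simulate_study <- function(design, n_participants,
                           params = rater_params(),
                           mode = c("forced2", "free")) {
  mode <- match.arg(mode)
  expected_policy <- if (mode == "forced2") "top2" else "threshold"
  if (params$policy != expected_policy) {
    stop(sprintf("mode '%s' requires selection policy '%s'", mode,
                 expected_policy), call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(params$seed)

  n_stim <- nrow(design)
  n <- n_participants * n_stim
  rows <- tidyr::expand_grid(
    participant_id = sprintf("p%03d", seq_len(n_participants)),
    stimulus_row = seq_len(n_stim)
  )
  mu_stim <- latent_means(design, params)
  mu <- mu_stim[rows$stimulus_row, , drop = FALSE]
  noisy <- mu + matrix(stats::rnorm(n * 5L, 0, params$sigma), nrow = n)
  ratings <- round(pmin(pmax(noisy, 0), 10))

  jitter <- matrix(stats::runif(n * 5L), nrow = n) * 1e-9
  if (params$policy == "top2") {
    ranks <- row_rank_desc(ratings + jitter)
    sel <- ranks <= 2L
  } else {
    sel <- ratings >= params$tau
    none <- rowSums(sel) == 0L
    if (any(none)) {
      amax <- max.col(ratings[none, , drop = FALSE] + jitter[none, , drop = FALSE])
      sel[cbind(which(none), amax)] <- TRUE
    }
  }
  ratings[!sel] <- NA

  out <- dplyr::bind_cols(
    tibble::tibble(participant_id = rows$participant_id),
    design[rows$stimulus_row,
           c("stimulus_id", "actor_id", "emotion_first", "emotion_second",
             "proportion")]
  )
  out[rating_cols()] <- as.data.frame(ratings)
  ds <- blend_dataset(out, mode = mode, check = FALSE)
  rownames(mu_stim) <- design$stimulus_id
  attr(ds, "latent_means") <- mu_stim
  ds
}
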
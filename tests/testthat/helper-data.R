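# In-code fixtures: tiny judgment tables built row by row.

ratings_row <- function(participant, stimulus, actor, first, second,
                        proportion, ...) {
  ratings <- list(...)
  row <- tibble::tibble(
    participant_id = participant, stimulus_id = stimulus, actor_id = actor,
    emotion_first = first, emotion_second = second, proportion = proportion,
    rating_anger = NA_integer_, rating_disgust = NA_integer_,
    rating_fear = NA_integer_, rating_happiness = NA_integer_,
    rating_sadness = NA_integer_
  )
  for (nm in names(ratings)) {
    row[[paste0("rating_", nm)]] <- as.integer(ratings[[nm]])
  }
  row
}

# 2 participants x one stimulus per combination/proportion subset; forced2
tiny_forced2 <- function() {
  rows <- dplyr::bind_rows(
    ratings_row("p1", "s1", "a1", "anger", "disgust", "30:70",
                anger = 3, disgust = 7),
    ratings_row("p1", "s2", "a1", "fear", "sadness", "50:50",
                fear = 5, sadness = 5),
    ratings_row("p2", "s1", "a1", "anger", "disgust", "30:70",
                anger = 6, disgust = 4),
    ratings_row("p2", "s2", "a1", "fear", "sadness", "50:50",
                fear = 2, happiness = 1)
  )
  blend_dataset(rows, mode = "forced2")
}

# a quick small simulated study for structural tests
small_sim <- function(n_participants = 6, n_actors = 2, sigma = 1,
                      gain = 8, seed = 11, mode = "forced2", ...) {
  policy <- if (mode == "forced2") "top2" else "threshold"
  simulate_study(build_design(n_actors), n_participants,
                 rater_params(gain = gain, sigma = sigma, policy = policy,
                              seed = seed, ...),
                 mode = mode)
}

identity_kernel <- function() {
  k <- diag(5)
  dimnames(k) <- list(intended = emotion_labels(),
                      perceived = emotion_labels())
  k
}
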
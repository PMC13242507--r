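score_one <- function(first, second, proportion, ..., policy = "superset") {
  ds <- blend_dataset(
    ratings_row("p1", "s1", "a1", first, second, proportion, ...),
    mode = "free"
  )
  score_trials(ds, strict_policy = policy)
}

test_that("generous scoring: any selected scale matching either target", {
  expect_equal(score_one("anger", "disgust", "50:50",
                         anger = 6, fear = 2)$generous, 1L)
  expect_equal(score_one("anger", "disgust", "50:50",
                         fear = 3, sadness = 5)$generous, 0L)
  expect_equal(score_one("anger", "happiness", "50:50",
                         anger = 1)$generous, 1L)
})

test_that("strict scoring covers both targets; superset vs exact policy", {
  expect_equal(score_one("anger", "disgust", "50:50",
                         anger = 6, disgust = 4)$strict, 1L)
  expect_equal(score_one("anger", "disgust", "50:50",
                         anger = 6, fear = 4)$strict, 0L)
  sup <- score_one("anger", "disgust", "50:50",
                   anger = 6, disgust = 4, fear = 1)
  expect_equal(sup$strict, 1L)
  exa <- score_one("anger", "disgust", "50:50",
                   anger = 6, disgust = 4, fear = 1, policy = "exact")
  expect_equal(exa$strict, 0L)
})

test_that("very strict requires the prominence ordering, ties fail, 50:50 undefined", {
  expect_equal(score_one("anger", "disgust", "30:70",
                         anger = 3, disgust = 7)$very_strict, 1L)
  expect_equal(score_one("anger", "disgust", "30:70",
                         anger = 5, disgust = 5)$very_strict, 0L)
  expect_equal(score_one("anger", "disgust", "70:30",
                         anger = 3, disgust = 7)$very_strict, 0L)
  expect_true(is.na(score_one("fear", "sadness", "50:50",
                              fear = 5, sadness = 5)$very_strict))
})

test_that("per-trial index ordering generous >= strict >= very_strict holds on generated data", {
  for (seed in c(2, 3)) {
    ds <- small_sim(n_participants = 4, n_actors = 2, sigma = 2,
                    mode = "free", seed = seed)
    s <- score_trials(ds)
    expect_true(all(s$generous >= s$strict))
    ok <- !is.na(s$very_strict)
    expect_true(all(s$strict[ok] >= s$very_strict[ok]))
    expect_true(is.na(s$very_strict[s$proportion == "50:50"]) |> all())
  }
  # forced2 always selects exactly two scales
  s2 <- score_trials(small_sim(n_participants = 3, n_actors = 2, seed = 5))
  expect_true(all(s2$k_selected == 2L))
})

test_that("aggregation matches the closed-form Wald interval and chance comparison", {
  scores <- tibble::tibble(
    participant_id = "p", stimulus_id = as.character(1:100), actor_id = "a",
    combination = "anger-disgust", proportion = "50:50",
    k_selected = 2L, generous = rep(c(0L, 1L), 50),
    strict = rep(c(0L, 1L), 50), very_strict = NA_integer_
  )
  res <- aggregate_accuracy(scores, "strict")
  expect_equal(res$mean, 0.5)
  expect_equal(res$ci_low, 0.5 - stats::qnorm(0.975) * sqrt(0.25 / 100),
               tolerance = 1e-10)
  expect_equal(res$ci_high, 0.5 + stats::qnorm(0.975) * sqrt(0.25 / 100),
               tolerance = 1e-10)
  expect_equal(round(c(res$ci_low, res$ci_high), 3), c(0.402, 0.598))
  expect_true(res$above_chance) # chance 0.10 for strict

  res_high <- aggregate_accuracy(scores, "strict", chance = 0.70)
  expect_false(res_high$above_chance)

  perfect <- dplyr::mutate(scores, strict = 1L)
  res1 <- aggregate_accuracy(perfect, "strict")
  expect_equal(res1$mean, 1)
  expect_equal(res1$sd, 0)
  expect_equal(c(res1$ci_low, res1$ci_high), c(1, 1))

  # Wilson interval stays inside [0, 1] and contains the estimate
  w <- aggregate_accuracy(perfect, "strict", ci_method = "wilson")
  expect_true(w$ci_low <= w$mean && w$mean <= w$ci_high && w$ci_high <= 1)
})

test_that("pooled aggregation over two disjoint cells equals trial-weighted pooling", {
  ds <- small_sim(n_participants = 5, n_actors = 2, seed = 9)
  s <- score_trials(ds)
  by_cell <- aggregate_accuracy(s, "strict", by = "proportion")
  overall <- aggregate_accuracy(s, "strict")
  expect_equal(sum(by_cell$mean * by_cell$n) / sum(by_cell$n), overall$mean)

  # participant-level aggregation is available and averages participant means
  per_part <- aggregate_accuracy(s, "strict", unit = "participant")
  manual <- s |>
    dplyr::summarise(m = mean(strict), .by = "participant_id") |>
    dplyr::pull(m) |> mean()
  expect_equal(per_part$mean, manual)
  expect_equal(per_part$n, 5L)
})

test_that("scale usage distribution: counts, percentages, mean and sample SD", {
  all2 <- small_sim(n_participants = 3, n_actors = 1, seed = 4)
  u <- scale_usage_summary(all2)
  expect_equal(u$k, 2L)
  expect_equal(u$pct, 100)
  g <- glance(u)
  expect_equal(g$mean_k, 2)
  expect_equal(g$sd_k, 0)

  rows <- dplyr::bind_rows(
    ratings_row("p1", "s1", "a1", "anger", "disgust", "50:50", anger = 5),
    ratings_row("p2", "s1", "a1", "anger", "disgust", "50:50",
                anger = 5, disgust = 4),
    ratings_row("p3", "s1", "a1", "anger", "disgust", "50:50",
                anger = 5, disgust = 4, fear = 1)
  )
  u3 <- scale_usage_summary(blend_dataset(rows, mode = "free"))
  g3 <- glance(u3)
  expect_equal(g3$mean_k, 2)
  expect_equal(g3$sd_k, stats::sd(c(1, 2, 3)))
  expect_equal(sum(u3$pct), 100)

  empty <- blend_dataset(ratings_row("p", "s", "a", "anger", "disgust",
                                     "50:50", anger = 1)[0, ],
                         mode = "free", check = FALSE)
  expect_error(scale_usage_summary(empty), "empty")
})

test_that("cell mean ratings impute zero for unselected scales", {
  one <- blend_dataset(
    ratings_row("p1", "s1", "a1", "anger", "disgust", "50:50",
                anger = 6, disgust = 4),
    mode = "forced2"
  )
  cm <- cell_mean_ratings(one)
  expect_equal(nrow(cm), 5L) # one combination x one proportion x 5 scales
  get <- function(sc) cm$mean[cm$scale == sc]
  expect_equal(get("anger"), 6)
  expect_equal(get("disgust"), 4)
  expect_equal(get("fear"), 0)
  expect_equal(get("happiness"), 0)

  two <- blend_dataset(dplyr::bind_rows(
    ratings_row("p1", "s1", "a1", "anger", "disgust", "50:50",
                anger = 6, disgust = 4),
    ratings_row("p2", "s1", "a1", "anger", "disgust", "50:50",
                anger = 4, disgust = 4)
  ), mode = "forced2")
  cm2 <- cell_mean_ratings(two)
  expect_equal(cm2$mean[cm2$scale == "anger"], 5)
})

test_that("noise-free simulated cell means equal the generative means", {
  ds <- small_sim(n_participants = 2, n_actors = 2, sigma = 0, seed = 21,
                  kernel = identity_kernel())
  mu <- attr(ds, "latent_means")
  cm <- cell_mean_ratings(ds)
  stim <- stimuli(ds)
  # with sigma = 0, identity kernel and top2, recorded target ratings are
  # round(mu) and all other scales are unselected hence 0
  for (i in seq_len(3)) {
    st <- stim[i, ]
    expected <- round(mu[st$stimulus_id, ])
    expected[setdiff(emotion_labels(),
                     c(st$emotion_first, st$emotion_second))] <- 0
    got <- cm[cm$combination == canonical_pair(st$emotion_first,
                                               st$emotion_second) &
                cm$proportion == st$proportion, ]
    expect_equal(got$mean[match(names(expected), got$scale)],
                 unname(expected))
  }
})
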
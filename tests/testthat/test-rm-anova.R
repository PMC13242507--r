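# independent brute-force sum-of-squares decomposition for small tables
brute_ss <- function(m) {
  grand <- mean(m)
  ss_subject <- 0
  for (i in seq_len(nrow(m))) ss_subject <- ss_subject + ncol(m) * (mean(m[i, ]) - grand)^2
  ss_cond <- 0
  for (j in seq_len(ncol(m))) ss_cond <- ss_cond + nrow(m) * (mean(m[, j]) - grand)^2
  ss_total <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    ss_total <- ss_total + (m[i, j] - grand)^2
  }
  c(condition = ss_cond, subject = ss_subject,
    error = ss_total - ss_subject - ss_cond, total = ss_total)
}

test_that("degrees of freedom follow the within-subject layout", {
  set.seed(101)
  for (p in c(43, 39)) {
    m <- matrix(rnorm(p * 10), nrow = p)
    fit <- rm_anova_oneway(m)
    expect_equal(fit$df_num, 9L)
    expect_equal(fit$df_den, 9L * (p - 1L))
  }
  expect_equal(rm_anova_oneway(matrix(rnorm(430), 43))$df_den, 378L)
  expect_equal(rm_anova_oneway(matrix(rnorm(390), 39))$df_den, 342L)
})

test_that("a hand-checked 3x3 table reproduces the brute-force decomposition", {
  m <- matrix(c(2, 4, 6,
                3, 6, 9,
                1, 5, 6), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("p", 1:3), paste0("c", 1:3)))
  fit <- rm_anova_oneway(m)
  ss <- brute_ss(m)
  expect_equal(fit$ss[["condition"]], ss[["condition"]])
  expect_equal(fit$ss[["subject"]], ss[["subject"]])
  expect_equal(fit$ss[["error"]], ss[["error"]], tolerance = 1e-12)
  f_hand <- (ss[["condition"]] / 2) / (ss[["error"]] / 4)
  expect_equal(fit$F, f_hand)
  expect_equal(fit$p, stats::pf(f_hand, 2, 4, lower.tail = FALSE))
})

test_that("pure subject offsets give a null, degenerate-flagged result", {
  m <- outer(c(1, 5, 9, 2), rep(1, 6)) # identical condition means per subject
  fit <- rm_anova_oneway(m)
  expect_true(fit$degenerate)
  expect_equal(fit$F, 0)
  expect_equal(fit$eta2_partial, 0)
  expect_equal(fit$eta2_generalized, 0)
})

test_that("SS conservation and effect-size ordering hold on random layouts", {
  set.seed(77)
  for (rep in 1:5) {
    p <- sample(8:30, 1)
    k <- sample(3:8, 1)
    m <- matrix(rnorm(p * k, sd = runif(1, 0.5, 3)), nrow = p) +
      rnorm(p) # subject offsets
    fit <- rm_anova_oneway(m)
    rel_err <- abs(sum(fit$ss[c("condition", "subject", "error")]) -
                     fit$ss[["total"]]) / fit$ss[["total"]]
    expect_lt(rel_err, 1e-8)
    expect_lte(fit$eta2_generalized, fit$eta2_partial)
    expect_gte(fit$gg_epsilon, 1 / (k - 1))
    expect_lte(fit$gg_epsilon, 1)
  }
})

test_that("epsilon concentrates near 1 under compound symmetry", {
  set.seed(5150)
  eps <- replicate(20, {
    m <- matrix(rnorm(60 * 4), nrow = 60) + rnorm(60)
    rm_anova_oneway(m)$gg_epsilon
  })
  expect_gt(mean(eps), 0.9)
})

test_that("F, GG correction and Mauchly agree with an independent multivariate fit", {
  skip_if_not_installed("car")
  set.seed(404)
  m <- matrix(rnorm(18 * 4), nrow = 18)
  m[, 1] <- m[, 1] * 2 + 1 # break sphericity a little
  fit <- rm_anova_oneway(m)

  idata <- data.frame(cond = factor(paste0("c", 1:4)))
  mlm <- stats::lm(m ~ 1)
  av <- car::Anova(mlm, idata = idata, idesign = ~cond, type = 3)
  s <- summary(av, multivariate = FALSE)
  uni <- s$univariate.tests
  expect_equal(fit$F, uni["cond", "F value"], tolerance = 1e-8)
  expect_equal(fit$p, uni["cond", "Pr(>F)"], tolerance = 1e-8)
  expect_equal(fit$mauchly_p, s$sphericity.tests["cond", "p-value"],
               tolerance = 1e-8)
  expect_equal(fit$gg_epsilon, s$pval.adjustments["cond", "GG eps"],
               tolerance = 1e-8)
  expect_equal(fit$p_gg, s$pval.adjustments["cond", "Pr(>F[GG])"],
               tolerance = 1e-8)
})

test_that("participant cell means average trials with zero imputation", {
  rows <- dplyr::bind_rows(
    ratings_row("p1", "s1", "a1", "anger", "disgust", "30:70",
                anger = 2, disgust = 7),
    ratings_row("p1", "s2", "a2", "anger", "disgust", "30:70",
                anger = 4, disgust = 7),
    ratings_row("p1", "s3", "a1", "anger", "fear", "30:70",
                fear = 6, sadness = 1)
  )
  ds <- blend_dataset(rows, mode = "forced2", check = FALSE)
  cells <- participant_cell_means(ds, "anger", "30:70")
  expect_equal(cells$value[cells$condition == "anger-disgust"], 3)
  expect_equal(cells$value[cells$condition == "anger-fear"], 0) # unselected
})

test_that("noise-free simulated cell means equal the generative means", {
  ds <- small_sim(n_participants = 2, n_actors = 2, sigma = 0, seed = 3,
                  kernel = identity_kernel())
  mu <- attr(ds, "latent_means")
  cells <- participant_cell_means(ds, "anger", "70:30")
  # 70:30 anger-first blends: anger latent mean = 0.7 * 8 = 5.6, recorded 6
  expect_equal(unique(cells$value[cells$condition == "anger-disgust"]), 6)
  # anger not in the blend: never selected, imputed 0
  expect_equal(unique(cells$value[cells$condition == "fear-sadness"]), 0)
})

test_that("paired t statistics match the textbook formula", {
  # x - y differences (1, 2, 3): t = mean/ (sd/sqrt(n)) = 2 / (1/sqrt(3))
  fit <- stats::t.test(c(1, 2, 3), c(0, 0, 0), paired = TRUE)
  expect_equal(unname(fit$statistic), 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(unname(fit$parameter), 2)

  set.seed(88)
  x <- rnorm(15); y <- rnorm(15)
  d <- x - y
  t_hand <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  expect_equal(unname(stats::t.test(x, y, paired = TRUE)$statistic), t_hand)
})

test_that("target/non-target family has 24 contrasts at corrected alpha 0.0021", {
  ds <- small_sim(n_participants = 6, n_actors = 2, seed = 15)
  ph <- target_vs_nontarget_contrasts(ds, "anger", "50:50")
  expect_equal(nrow(ph), 24L)
  expect_equal(unique(ph$alpha_corrected), 0.0021)
  expect_equal(dplyr::n_distinct(ph$target), 4L)
  expect_equal(dplyr::n_distinct(ph$nontarget), 6L)
  expect_identical(ph$significant, ph$p < 0.0021)
})

test_that("proportion-order family has 20 tests at alpha 0.0025 and recovers direction", {
  ds <- small_sim(n_participants = 20, n_actors = 2, sigma = 0.5, seed = 16,
                  kernel = identity_kernel())
  po <- proportion_order_tests(ds)
  expect_equal(nrow(po), 20L)
  expect_equal(unique(po$alpha_corrected), 0.0025)
  # strong, low-noise signal: every contrast significant, prominent higher
  expect_true(all(po$significant))
  expect_true(all(po$direction_correct))
  # prominence bookkeeping: 30:70 prominence lies with the second emotion
  row <- po[po$combination == "anger-disgust" & po$proportion == "30:70", ]
  expect_equal(row$prominent, "disgust")
})
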
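#' Participant-level cell means for one scale within one proportion
#'
#' Averages each participant's ratings on one scale over all trials of each
#' of the 10 combination conditions within a proportion condition, with
#' unselected scales counted as 0 (consistent with [cell_mean_ratings()]).
#' These per-participant condition means are the unit of analysis for the
#' repeated-measures inference.
#'
#' @param ds A [blend_dataset()].
#' @param scale One emotion label (the rating scale analysed).
#' @param proportion One proportion condition.
#' @return A tibble with columns `participant_id`, `condition` (combination
#'   key) and `value` (mean rating in 0-10).
#' @export
participant_cell_means <- function(ds, scale, proportion) {
  assert_emotion(scale, "scale")
  stopifnot(proportion %in% proportion_levels())
  col <- paste0("rating_", scale)
  x <- dplyr::filter(tibble::as_tibble(ds), .data$proportion == !!proportion)
  if (nrow(x) == 0L) stop("no trials in proportion condition ", proportion,
                          call. = FALSE)
  x <- dplyr::mutate(
    x,
    condition = canonical_pair(.data$emotion_first, .data$emotion_second),
    rating = dplyr::coalesce(as.numeric(.data[[col]]), 0)
  )
  out <- dplyr::summarise(
    dplyr::group_by(x, .data$participant_id, .data$condition),
    value = mean(.data$rating), .groups = "drop"
  )
  n_cond <- dplyr::n_distinct(out$condition)
  per_part <- dplyr::count(out, .data$participant_id)
  if (any(per_part$n < n_cond)) {
    stop("participant(s) with empty condition cells: ",
         paste(per_part$participant_id[per_part$n < n_cond], collapse = ", "),
         call. = FALSE)
  }
  out
}

cells_to_matrix <- function(cells) {
  wide <- tidyr::pivot_wider(cells, id_cols = "participant_id",
                             names_from = "condition", values_from = "value")
  m <- as.matrix(wide[setdiff(names(wide), "participant_id")])
  rownames(m) <- wide$participant_id
  m <- m[, sort(colnames(m)), drop = FALSE]
  if (anyNA(m)) stop("incomplete participant x condition layout", call. = FALSE)
  m
}

#' One-way repeated-measures ANOVA with sphericity handling
#'
#' Classical within-subject decomposition for a single within factor:
#' `SS_total = SS_subject + SS_condition + SS_error`, with
#' `F = MS_condition / MS_error` on `(c-1, (c-1)(p-1))` degrees of freedom
#' for `p` participants and `c` conditions. Sphericity of the condition
#' covariance is assessed with Mauchly's test, and the primary p-value is
#' Greenhouse-Geisser corrected (`F` referred to epsilon-scaled degrees of
#' freedom). Effect sizes are partial eta squared
#' `SS_cond / (SS_cond + SS_err)` and generalized eta squared
#' `SS_cond / (SS_cond + SS_subject + SS_err)`, which additionally accounts
#' for individual differences and so never exceeds the partial form.
#'
#' Zero error variance (e.g. noise-free simulated data) yields a flagged
#' `degenerate` result rather than a division failure.
#'
#' @param cells Output of [participant_cell_means()] (long tibble with
#'   `participant_id`, `condition`, `value`), or a participants x conditions
#'   numeric matrix.
#' @return A `blend_rm_anova` object; see [tidy.blend_rm_anova()] and
#'   [glance.blend_rm_anova()].
#' @export
rm_anova_oneway <- function(cells) {
  m <- if (is.matrix(cells)) cells else cells_to_matrix(cells)
  p <- nrow(m)
  c_ <- ncol(m)
  if (p < 2L || c_ < 2L) stop("need at least 2 participants and 2 conditions",
                              call. = FALSE)
  grand <- mean(m)
  ss_subject <- c_ * sum((rowMeans(m) - grand)^2)
  ss_cond <- p * sum((colMeans(m) - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_subject - ss_cond
  ss_err <- max(ss_err, 0) # guard tiny negative rounding
  df1 <- c_ - 1L
  df2 <- (c_ - 1L) * (p - 1L)
  tol <- 1e-12 * max(ss_total, 1)
  degenerate <- ss_err <= tol

  if (degenerate) {
    f_stat <- if (ss_cond <= tol) 0 else Inf
    p_val <- if (ss_cond <= tol) 1 else 0
  } else {
    f_stat <- (ss_cond / df1) / (ss_err / df2)
    p_val <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  }
  eta2_p <- if (ss_cond + ss_err <= tol) 0 else ss_cond / (ss_cond + ss_err)
  eta2_g <- if (ss_cond + ss_subject + ss_err <= tol) 0 else
    ss_cond / (ss_cond + ss_subject + ss_err)

  # Mauchly's W and Greenhouse-Geisser epsilon on the contrast covariance
  mauchly_W <- mauchly_p <- NA_real_
  eps <- NA_real_
  p_gg <- NA_real_
  if (!degenerate && p > c_ - 1L) {
    S <- stats::cov(m)
    M <- contrast_basis(c_)
    S1 <- t(M) %*% S %*% M
    lam <- eigen(S1, symmetric = TRUE, only.values = TRUE)$values
    lam <- pmax(lam, 0)
    eps <- sum(lam)^2 / (df1 * sum(lam^2))
    eps <- min(max(eps, 1 / df1), 1)
    if (all(lam > 0)) {
      # Mauchly's W with Box's chi-square approximation including the
      # second-order series term (as in the standard MLM implementations)
      W <- prod(lam) / (mean(lam))^df1
      n_res <- p - 1L
      rho <- 1 - (2 * df1^2 + df1 + 2) / (6 * df1 * n_res)
      z <- -n_res * rho * log(W)
      df_w <- df1 * (df1 + 1) / 2 - 1
      w2 <- (df1 + 2) * (df1 - 1) * (df1 - 2) *
        (2 * df1^3 + 6 * df1^2 + 3 * c_ + 2) / (288 * (n_res * df1 * rho)^2)
      pr1 <- stats::pchisq(z, df_w, lower.tail = FALSE)
      pr2 <- stats::pchisq(z, df_w + 4, lower.tail = FALSE)
      mauchly_W <- W
      mauchly_p <- pr1 + w2 * (pr2 - pr1)
    }
    p_gg <- stats::pf(f_stat, eps * df1, eps * df2, lower.tail = FALSE)
  } else if (!degenerate) {
    # too few participants to estimate the full contrast covariance
    eps <- NA_real_
    p_gg <- p_val
  }

  structure(
    list(F = f_stat, df_num = df1, df_den = df2, p = p_val,
         mauchly_W = mauchly_W, mauchly_p = mauchly_p,
         gg_epsilon = eps, p_gg = p_gg,
         eta2_partial = eta2_p, eta2_generalized = eta2_g,
         ss = c(condition = ss_cond, subject = ss_subject, error = ss_err,
                total = ss_total),
         n_participants = p, n_conditions = c_, degenerate = degenerate),
    class = "blend_rm_anova"
  )
}

contrast_basis <- function(k) {
  m <- stats::contr.helmert(k)
  sweep(m, 2L, sqrt(colSums(m^2)), "/")
}

#' @export
print.blend_rm_anova <- function(x, ...) {
  cat(sprintf("One-way repeated-measures ANOVA: %d participants x %d conditions\n",
              x$n_participants, x$n_conditions))
  cat(sprintf("F(%d, %d) = %.2f, p = %.3g (GG-corrected p = %.3g, eps = %.3f)\n",
              x$df_num, x$df_den, x$F, x$p, x$p_gg, x$gg_epsilon))
  cat(sprintf("eta2_partial = %.3f, eta2_generalized = %.3f\n",
              x$eta2_partial, x$eta2_generalized))
  if (x$degenerate) cat("NOTE: degenerate fit (zero error variance)\n")
  invisible(x)
}

#' Tidy a repeated-measures ANOVA fit
#'
#' @param x A `blend_rm_anova` object.
#' @param ... Unused.
#' @return One-row tibble with the test statistic, degrees of freedom,
#'   uncorrected and Greenhouse-Geisser p-values, Mauchly statistics, and
#'   both eta-squared effect sizes.
#' @export
tidy.blend_rm_anova <- function(x, ...) {
  tibble::tibble(
    F = x$F, df_num = x$df_num, df_den = x$df_den, p = x$p,
    mauchly_W = x$mauchly_W, mauchly_p = x$mauchly_p,
    gg_epsilon = x$gg_epsilon, p_gg = x$p_gg,
    eta2_partial = x$eta2_partial, eta2_generalized = x$eta2_generalized,
    degenerate = x$degenerate
  )
}

#' @rdname tidy.blend_rm_anova
#' @export
glance.blend_rm_anova <- function(x, ...) {
  tibble::tibble(n_participants = x$n_participants,
                 n_conditions = x$n_conditions,
                 ss_condition = unname(x$ss["condition"]),
                 ss_subject = unname(x$ss["subject"]),
                 ss_error = unname(x$ss["error"]))
}

#' All 15 scale-by-proportion repeated-measures ANOVAs
#'
#' Runs [rm_anova_oneway()] on the participant cell means of every
#' (scale, proportion) pair, mirroring the standard reporting layout.
#'
#' @param ds A [blend_dataset()].
#' @return A tibble with one row per scale x proportion and the tidied
#'   ANOVA columns.
#' @export
anova_table <- function(ds) {
  grid <- tidyr::expand_grid(scale = emotion_labels(),
                             proportion = proportion_levels())
  res <- purrr::pmap(grid, function(scale, proportion) {
    fit <- rm_anova_oneway(participant_cell_means(ds, scale, proportion))
    tidy.blend_rm_anova(fit)
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(res))
}

# Zero-variance difference vectors (e.g. a scale never selected in either
# condition) yield a flagged NA row instead of an error; cells are never
# silently dropped.
paired_t <- function(x, y) {
  d <- x - y
  if (stats::sd(d) < .Machine$double.eps^0.5) {
    return(tibble::tibble(estimate = mean(d), t = NA_real_,
                          df = length(d) - 1, p = NA_real_))
  }
  fit <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(estimate = unname(fit$estimate),
                 t = unname(fit$statistic),
                 df = unname(fit$parameter),
                 p = fit$p.value)
}

#' Target versus non-target post-hoc contrasts for one ANOVA
#'
#' For one rating scale within one proportion condition, the 4 target
#' combinations (those containing the scale's emotion) are each compared
#' against the 6 non-target combinations by paired t-tests on participant
#' cell means: 24 two-sided comparisons, Bonferroni-corrected alpha
#' 0.05/24 reported to four decimals as 0.0021.
#'
#' @param ds A [blend_dataset()].
#' @param scale Emotion label of the rating scale.
#' @param proportion Proportion condition.
#' @return A tibble with one row per contrast: `family`, `scale`,
#'   `proportion`, `target`, `nontarget`, `estimate` (target minus
#'   non-target mean difference), `t`, `df`, `p`, `alpha_corrected`,
#'   `significant`.
#' @export
target_vs_nontarget_contrasts <- function(ds, scale, proportion) {
  cells <- participant_cell_means(ds, scale, proportion)
  m <- cells_to_matrix(cells)
  combos <- colnames(m)
  is_target <- purrr::map_lgl(combos, function(k) {
    scale %in% unlist(split_combination(k))
  })
  targets <- combos[is_target]
  nontargets <- combos[!is_target]
  if (length(targets) != 4L) {
    stop("expected 4 target combinations for scale '", scale, "', found ",
         length(targets), call. = FALSE)
  }
  grid <- tidyr::expand_grid(target = targets, nontarget = nontargets)
  alpha <- round(0.05 / nrow(grid), 4)
  res <- purrr::pmap(grid, function(target, nontarget) {
    paired_t(m[, target], m[, nontarget])
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  dplyr::mutate(out,
                family = "target_vs_nontarget",
                scale = scale, proportion = proportion,
                alpha_corrected = alpha,
                significant = .data$p < alpha,
                .before = "target")
}

#' Prominence-order tests for the unequal-proportion conditions
#'
#' For each of the 10 combinations in each of the 30:70 and 70:30
#' conditions, a paired t-test compares each participant's mean rating on
#' the more prominent target scale against their mean rating on the less
#' prominent target scale: 20 two-sided tests at Bonferroni-corrected alpha
#' 0.05/20 = 0.0025. A positive estimate means the more prominent emotion
#' was rated higher, i.e. the intended ordering was perceived.
#'
#' @param ds A [blend_dataset()].
#' @return A tibble with one row per test: `family`, `combination`,
#'   `proportion`, `prominent`, `subtle`, `estimate`, `t`, `df`, `p`,
#'   `alpha_corrected`, `significant`, `direction_correct`.
#' @export
proportion_order_tests <- function(ds) {
  grid <- tidyr::expand_grid(combination = all_combinations(),
                             proportion = c("30:70", "70:30"))
  alpha <- round(0.05 / nrow(grid), 4)
  x <- dplyr::mutate(tibble::as_tibble(ds),
                     combination = canonical_pair(.data$emotion_first,
                                                  .data$emotion_second))
  res <- purrr::pmap(grid, function(combination, proportion) {
    trials <- x[x$combination == combination & x$proportion == proportion, ]
    if (nrow(trials) == 0L) {
      stop("no trials for ", combination, " at ", proportion, call. = FALSE)
    }
    prom <- prominence(trials$emotion_first, trials$emotion_second,
                       trials$proportion)
    rat <- as.matrix(trials[rating_cols()])
    rat[is.na(rat)] <- 0
    idx <- seq_len(nrow(trials))
    v_prom <- rat[cbind(idx, match(prom$prominent, emotion_labels()))]
    v_sub <- rat[cbind(idx, match(prom$subtle, emotion_labels()))]
    per_part <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(participant_id = trials$participant_id,
                                     v_prom = v_prom, v_sub = v_sub),
                      .data$participant_id),
      v_prom = mean(.data$v_prom), v_sub = mean(.data$v_sub),
      .groups = "drop"
    )
    cbind(tibble::tibble(prominent = prom$prominent[1L],
                         subtle = prom$subtle[1L]),
          paired_t(per_part$v_prom, per_part$v_sub))
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  dplyr::mutate(out,
                family = "proportion_order",
                alpha_corrected = alpha,
                significant = .data$p < alpha,
                direction_correct = .data$estimate > 0,
                .before = "combination")
}
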
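#' Configuration for the end-to-end reporting pipeline
#'
#' Exactly one of `input` (path to a judgment CSV) or `sim` (a simulation
#' request, see below) must be given.
#'
#' @param input Path to a CSV in the [load_dataset()] dialect, or `NULL`.
#' @param sim `NULL`, or a list with `n_participants`, `n_actors` and
#'   optionally `params` (a [rater_params()]).
#' @param mode `"forced2"` or `"free"`.
#' @param ci_method `"wald"` or `"wilson"` (see [aggregate_accuracy()]).
#' @param strict_policy `"superset"` or `"exact"` (see [score_trials()]).
#' @param chance_reference `"fixed2"` (the fixed two-selection anchors,
#'   default) or `"empirical"` (mixture over the dataset's observed
#'   selection-count distribution).
#' @param out_dir Output directory for the report bundle.
#' @param seed Integer seed (used when simulating).
#' @param verbose Print one structured log line per stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, sim = NULL,
                            mode = c("forced2", "free"),
                            ci_method = c("wald", "wilson"),
                            strict_policy = c("superset", "exact"),
                            chance_reference = c("fixed2", "empirical"),
                            out_dir = "emoblend-report", seed = 1L,
                            verbose = FALSE) {
  if (is.null(input) == is.null(sim)) {
    stop("exactly one of `input` and `sim` must be set", call. = FALSE)
  }
  structure(list(input = input, sim = sim, mode = match.arg(mode),
                 ci_method = match.arg(ci_method),
                 strict_policy = match.arg(strict_policy),
                 chance_reference = match.arg(chance_reference),
                 out_dir = out_dir, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

pipeline_log <- function(cfg, stage, rows_in, rows_out) {
  if (cfg$verbose) {
    message(sprintf("[%s] rows_in=%d rows_out=%d", stage, rows_in, rows_out))
  }
}

#' Run the full analysis pipeline
#'
#' Loads or simulates a dataset, validates it, and writes the report bundle
#' to `cfg$out_dir`: cell-mean ratings, the 15 repeated-measures ANOVA
#' summaries, accuracy per combination x proportion with CIs and
#' above-chance flags (plus a rendered wide table), both post-hoc contrast
#' families, the chance-level table, a selection-count distribution (free
#' mode only), and a machine-readable `manifest.json` recording config,
#' seed and package version. On failure, partially written outputs are
#' removed and the error is re-raised with its stage name.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a named list of the output tibbles plus
#'   `files` (paths written).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  stage <- "setup"
  emit <- function(x, name) {
    path <- file.path(cfg$out_dir, paste0(name, ".csv"))
    readr::write_csv(x, path, na = "NA")
    written <<- c(written, path)
    path
  }
  result <- tryCatch({
    stage <- "data"
    if (!is.null(cfg$input)) {
      ds <- load_dataset(cfg$input, mode = cfg$mode)
    } else {
      sim <- cfg$sim
      params <- sim$params %||% rater_params(
        policy = if (cfg$mode == "forced2") "top2" else "threshold",
        seed = cfg$seed
      )
      params$seed <- cfg$seed
      design <- build_design(sim$n_actors %||% 6L)
      ds <- simulate_study(design, sim$n_participants %||% 40L, params,
                           mode = cfg$mode)
    }
    pipeline_log(cfg, "data", 0L, nrow(ds))

    stage <- "validate"
    findings <- validate_dataset(ds)
    if (any(findings$severity == "error")) {
      stop("dataset failed validation: ", findings$message[1L], call. = FALSE)
    }

    stage <- "cell_means"
    cm <- cell_mean_ratings(ds)
    emit(cm, "cell_means")
    pipeline_log(cfg, stage, nrow(ds), nrow(cm))

    stage <- "anova"
    av <- anova_table(ds)
    emit(av, "anova")
    pipeline_log(cfg, stage, nrow(ds), nrow(av))

    stage <- "accuracy"
    scores <- score_trials(ds, strict_policy = cfg$strict_policy)
    chance_for <- function(index) {
      if (cfg$chance_reference == "empirical") {
        mixture_chance(index, empirical_k_distribution(ds))
      } else {
        analytic_chance(index, k = 2L)
      }
    }
    acc <- dplyr::bind_rows(lapply(
      c("generous", "strict", "very_strict"),
      function(ix) aggregate_accuracy(scores, ix,
                                      by = c("combination", "proportion"),
                                      chance = chance_for(ix),
                                      ci_method = cfg$ci_method)
    ))
    emit(acc, "accuracy")
    rendered <- render_accuracy_table(acc)
    emit(rendered, "accuracy_table")
    pipeline_log(cfg, stage, nrow(scores), nrow(acc))

    stage <- "posthoc_target"
    grid <- tidyr::expand_grid(scale = emotion_labels(),
                               proportion = proportion_levels())
    ph <- dplyr::bind_rows(purrr::pmap(grid, function(scale, proportion) {
      target_vs_nontarget_contrasts(ds, scale, proportion)
    }))
    emit(ph, "posthoc_target")
    pipeline_log(cfg, stage, nrow(ds), nrow(ph))

    stage <- "posthoc_order"
    po <- proportion_order_tests(ds)
    emit(po, "posthoc_order")
    pipeline_log(cfg, stage, nrow(ds), nrow(po))

    stage <- "chance"
    ch <- chance_table()
    emit(ch, "chance")

    usage <- NULL
    if (cfg$mode == "free") {
      stage <- "scale_usage"
      usage <- scale_usage_summary(ds)
      emit(dplyr::bind_cols(tibble::as_tibble(usage),
                            glance.blend_scale_usage(usage)),
           "scale_usage")
      pipeline_log(cfg, stage, nrow(ds), nrow(usage))
    }

    stage <- "manifest"
    manifest <- list(
      package = "emoblend",
      version = as.character(utils::packageVersion("emoblend")),
      mode = cfg$mode, seed = cfg$seed,
      input = cfg$input %||% NA,
      simulated = is.null(cfg$input),
      sim = if (is.null(cfg$sim)) NULL else
        cfg$sim[intersect(names(cfg$sim), c("n_participants", "n_actors"))],
      ci_method = cfg$ci_method,
      strict_policy = cfg$strict_policy,
      chance_reference = cfg$chance_reference,
      n_judgments = nrow(ds)
    )
    manifest_path <- file.path(cfg$out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    written <- c(written, manifest_path)

    list(dataset = ds, cell_means = cm, anova = av, accuracy = acc,
         accuracy_table = rendered, posthoc_target = ph, posthoc_order = po,
         chance = ch, scale_usage = usage, files = written)
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

#' Render the accuracy results in the standard wide layout
#'
#' One row per combination x proportion (combinations alphabetical,
#' proportions ordered 30:70, 50:50, 70:30), with the very-strict, strict
#' and generous means and 95\% CIs side by side. Very-strict cells are `NA`
#' for the 50:50 condition, where the index is undefined. Point estimates
#' and CI bounds are rounded to 2 decimals for display; the long-format
#' accuracy output retains full precision.
#'
#' @param results Long accuracy tibble from [aggregate_accuracy()] covering
#'   the three indices by `combination` and `proportion`.
#' @return A wide tibble with 30 rows (for a full design).
#' @export
render_accuracy_table <- function(results) {
  if (nrow(results) == 0L) stop("empty accuracy results", call. = FALSE)
  stopifnot(all(c("combination", "proportion", "index") %in% names(results)))
  x <- dplyr::mutate(results,
                     value = round(.data$mean, 2),
                     ci = sprintf("[%.2f, %.2f]", .data$ci_low, .data$ci_high))
  wide <- tidyr::pivot_wider(
    x[c("combination", "proportion", "index", "value", "ci")],
    names_from = "index", values_from = c("value", "ci"),
    names_glue = "{index}_{.value}"
  )
  cols <- c("combination", "proportion",
            "very_strict_value", "very_strict_ci",
            "strict_value", "strict_ci",
            "generous_value", "generous_ci")
  for (col in setdiff(cols, names(wide))) wide[[col]] <- NA
  wide <- wide[cols]
  wide$very_strict_ci[is.na(wide$very_strict_value)] <- NA_character_
  dplyr::arrange(wide, .data$combination,
                 factor(.data$proportion, levels = proportion_levels()))
}
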
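# Experiment harness: sample-task calibration sweep, corrupted-input test
# batteries, CA3 size sweep and the training-error comparison across
# variants. Replicates are independent seeds covering network
# initialisation, presentation order and corruption draws; the association
# world is fixed per experiment (one stimulus set, many subjects).

# train one replicate inside an experiment, returning the frozen state
train_one_ <- function(spec, assoc, epochs, seed, settle, learn) {
  fit <- train_network(spec, assoc, epochs = epochs, seeds = seed,
                       settle = settle, learn = learn, eval_epochs = FALSE)
  fit$states[[1]]
}

#' Sample-task errors for one crossconnection multiplier
#'
#' Trains the variant and scores each output stream on its calibration
#' sample tests: the object and context outputs on matched trials with 15%
#' mixed noise in both inputs and on 40%-complete trials in both inputs; the
#' object-based context guess on mismatch, 30% mixed context-noise and
#' 40%-complete-context trials; the context-based object guess on mismatch,
#' 30% mixed object-noise and 40%-complete-object trials.
#'
#' @param variant Variant name or [default_config()].
#' @param multiplier Optional crossconnection multiplier override applied to
#'   the swept `side`.
#' @param side Which crossconnections the override applies to
#'   (`"posterior"` = MEC into the object-dominated side, `"anterior"` =
#'   LEC into the context-dominated side).
#' @param seeds Replicate seeds.
#' @param epochs Training epochs.
#' @param assoc Optional prebuilt `assoc_set`; by default the standard world
#'   is generated from `world_seed`.
#' @param world_seed Seed for the association world.
#' @param settle,learn Engine configurations.
#' @return A tibble with one row per (seed, output, test tag): the mean
#'   error of that output over that sample test.
#' @export
run_sample_tasks <- function(variant = "Baseline", multiplier = NULL,
                             side = c("posterior", "anterior"),
                             seeds = 1:10, epochs = 20L, assoc = NULL,
                             world_seed = 1L, settle = settle_config(),
                             learn = learning_config()) {
  side <- match.arg(side)
  cfg <- if (inherits(variant, "architecture_config")) {
    variant
  } else if (is.null(multiplier)) {
    default_config(variant)
  } else if (side == "posterior") {
    default_config(variant, posterior_multiplier = multiplier)
  } else {
    default_config(variant, anterior_multiplier = multiplier)
  }
  spec <- build_network(cfg)
  if (is.null(assoc)) assoc <- build_association_set(seed = world_seed)
  relevant <- list(O = "sample_O_C", C = "sample_O_C",
                   OBCG = "sample_OBCG", CBOG = "sample_CBOG")
  res <- lapply(seeds, function(sd) {
    st <- train_one_(spec, assoc, epochs, sd, settle, learn)
    batt_seed <- as.integer(sd) + 100000L
    out <- lapply(unique(unlist(relevant)), function(bn) {
      trials <- build_test_battery(assoc, bn, seed = batt_seed)
      outs <- names(relevant)[vapply(relevant, identical, logical(1), bn)]
      evaluate(st, trials, settle, outputs = outs)
    })
    dplyr::bind_rows(out) |>
      dplyr::group_by(.data$output, .data$tag) |>
      dplyr::summarise(error = mean(.data$error), .groups = "drop") |>
      dplyr::mutate(seed = as.integer(sd), .before = 1)
  })
  dplyr::bind_rows(res) |>
    dplyr::mutate(variant = cfg$variant, side = side,
                  multiplier = multiplier %||% NA_real_, .before = 1)
}

#' Sweep the crossconnection multiplier
#'
#' Repeats the sample-task evaluation over a grid of crossconnection
#' multipliers, producing per-output error curves (one per sample test, plus
#' their average) with SEM error bars across replicate seeds.
#'
#' @param variant Variant name.
#' @param grid Numeric vector of multiplier values.
#' @param seeds Replicate seeds.
#' @inheritParams run_sample_tasks
#' @return A `hippo_sweep` object with `$detail` (seed x output x tag),
#'   `$per_output` (per-seed average over each output's tests) and
#'   `$summary` (mean and SEM per multiplier and output).
#' @export
sweep_crossconnections <- function(variant = "Baseline", grid = c(0, 1.5, 3),
                                   seeds = 1:10,
                                   side = c("posterior", "anterior"),
                                   epochs = 20L, world_seed = 1L,
                                   settle = settle_config(),
                                   learn = learning_config()) {
  side <- match.arg(side)
  stopifnot(length(grid) >= 1)
  assoc <- build_association_set(seed = world_seed)
  detail <- dplyr::bind_rows(lapply(grid, function(m) {
    dplyr::mutate(
      run_sample_tasks(variant, multiplier = m, side = side, seeds = seeds,
                       epochs = epochs, assoc = assoc,
                       world_seed = world_seed, settle = settle,
                       learn = learn),
      multiplier = m
    )
  }))
  per_output <- detail |>
    dplyr::group_by(.data$multiplier, .data$seed, .data$output) |>
    dplyr::summarise(error = mean(.data$error), .groups = "drop")
  summary <- per_output |>
    dplyr::group_by(.data$multiplier, .data$output) |>
    dplyr::summarise(
      mean = mean(.data$error),
      sem = if (dplyr::n() >= 2) stats::sd(.data$error) / sqrt(dplyr::n())
            else NA_real_,
      n_seeds = dplyr::n(), .groups = "drop"
    )
  structure(list(variant = variant, side = side, grid = grid,
                 seeds = as.integer(seeds), detail = detail,
                 per_output = per_output, summary = summary),
            class = "hippo_sweep")
}

#' @export
print.hippo_sweep <- function(x, ...) {
  cat("<hippo_sweep> ", x$variant, ", ", x$side,
      " multiplier grid {", paste(x$grid, collapse = ", "), "}, ",
      length(x$seeds), " seeds\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Run corrupted-input test batteries across variants
#'
#' Trains each variant with its default multipliers on the standard world,
#' freezes the weights, and evaluates the named batteries over the given
#' corruption levels. Reports per-output errors and the combined score (mean
#' of the object error and the better context output).
#'
#' @param variants Character vector of variant names.
#' @param battery One or more battery names (trained networks are reused
#'   across batteries).
#' @param levels Corruption levels passed to [build_test_battery()]. The
#'   default grids are noise levels `c(0, .1, .2, .3, .4, .5)` for the noise
#'   batteries and completeness `c(1, .8, .6, .4, .2)` for the partial-cue
#'   batteries.
#' @param seeds Replicate seeds.
#' @inheritParams run_sample_tasks
#' @return A `hippo_battery` object with `$errors` (per seed/level/output
#'   means), `$combined`, `$summary` and `$combined_summary`.
#' @export
run_battery <- function(variants = "Baseline", battery = "partial_object",
                        levels = NULL, seeds = 1:10, epochs = 20L,
                        world_seed = 1L, settle = settle_config(),
                        learn = learning_config()) {
  stopifnot(all(variants %in% variant_names()),
            all(battery %in% battery_names()))
  default_levels <- function(bn) {
    if (grepl("^partial", bn)) c(1, 0.8, 0.6, 0.4, 0.2)
    else if (grepl("^(additive|nonadditive)", bn)) c(0, 0.1, 0.2, 0.3, 0.4, 0.5)
    else NULL
  }
  assoc <- build_association_set(seed = world_seed)
  rows <- list()
  for (v in variants) {
    spec <- build_network(default_config(v))
    for (sd in seeds) {
      st <- train_one_(spec, assoc, epochs, sd, settle, learn)
      for (bn in battery) {
        lv <- levels %||% default_levels(bn)
        trials <- build_test_battery(assoc, bn, levels = lv,
                                     seed = as.integer(sd) + 100000L)
        err <- evaluate(st, trials, settle)
        rows[[length(rows) + 1L]] <- err |>
          dplyr::group_by(.data$battery, .data$level, .data$output) |>
          dplyr::summarise(error = mean(.data$error), .groups = "drop") |>
          dplyr::mutate(variant = v, seed = as.integer(sd), .before = 1)
      }
    }
  }
  errors <- dplyr::bind_rows(rows)
  combined <- errors |>
    tidyr::pivot_wider(names_from = "output", values_from = "error") |>
    dplyr::mutate(combined = (.data$O + pmin(.data$C, .data$OBCG)) / 2)
  sem_ <- function(x) if (length(x) >= 2) stats::sd(x) / sqrt(length(x))
                      else NA_real_
  summary <- errors |>
    dplyr::group_by(.data$variant, .data$battery, .data$level,
                    .data$output) |>
    dplyr::summarise(mean = mean(.data$error), sem = sem_(.data$error),
                     n_seeds = dplyr::n(), .groups = "drop")
  combined_summary <- combined |>
    dplyr::group_by(.data$variant, .data$battery, .data$level) |>
    dplyr::summarise(mean = mean(.data$combined), sem = sem_(.data$combined),
                     n_seeds = dplyr::n(), .groups = "drop")
  structure(list(variants = variants, battery = battery,
                 seeds = as.integer(seeds), errors = errors,
                 combined = combined, summary = summary,
                 combined_summary = combined_summary),
            class = "hippo_battery")
}

#' @export
print.hippo_battery <- function(x, ...) {
  cat("<hippo_battery> ", paste(x$battery, collapse = ", "), " over ",
      paste(x$variants, collapse = ", "), " (", length(x$seeds),
      " seeds)\n", sep = "")
  print(x$combined_summary)
  invisible(x)
}

#' Posterior CA3 size sweep
#'
#' Trains the Baseline variant with the posterior CA3 resized to each grid
#' value and scores the object output on the partial-object task at the
#' given completeness level.
#'
#' @param sizes Integer vector of posterior CA3 sizes.
#' @param level Completeness fraction of the partial-object test.
#' @param seeds Replicate seeds.
#' @inheritParams run_sample_tasks
#' @return A `hippo_ca3_sweep` with `$detail` (size, seed, error) and
#'   `$summary`.
#' @export
sweep_ca3_size <- function(sizes = c(32, 128, 256, 512), level = 0.4,
                           seeds = 1:10, epochs = 20L, world_seed = 1L,
                           settle = settle_config(),
                           learn = learning_config()) {
  stopifnot(all(sizes >= 1))
  assoc <- build_association_set(seed = world_seed)
  detail <- dplyr::bind_rows(lapply(sizes, function(n) {
    spec <- build_network(default_config("Baseline", posterior_ca3 = n))
    dplyr::bind_rows(lapply(seeds, function(sd) {
      st <- train_one_(spec, assoc, epochs, sd, settle, learn)
      trials <- build_test_battery(assoc, "partial_object", levels = level,
                                   seed = as.integer(sd) + 100000L)
      err <- evaluate(st, trials, settle, outputs = "O")
      tibble::tibble(size = as.integer(n), seed = as.integer(sd),
                     error = mean(err$error))
    }))
  }))
  summary <- detail |>
    dplyr::group_by(.data$size) |>
    dplyr::summarise(
      mean = mean(.data$error),
      sem = if (dplyr::n() >= 2) stats::sd(.data$error) / sqrt(dplyr::n())
            else NA_real_,
      n_seeds = dplyr::n(), .groups = "drop"
    )
  structure(list(sizes = as.integer(sizes), level = level,
                 seeds = as.integer(seeds), detail = detail,
                 summary = summary),
            class = "hippo_ca3_sweep")
}

#' @export
print.hippo_ca3_sweep <- function(x, ...) {
  cat("<hippo_ca3_sweep> partial-object completeness ", x$level, ", ",
      length(x$seeds), " seeds\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Training-set error comparison across variants
#'
#' Trains each variant for the full schedule and reports the final-epoch
#' training error per output with SEM across seeds, flagging the two
#' comparison groups: equal unit count (Baseline, SplitDG, AllSplit) and
#' equal training error (Baseline, SplitDGplus, AllSplitplus).
#'
#' @param variants Character vector of variant names.
#' @param seeds Replicate seeds.
#' @inheritParams run_sample_tasks
#' @return A summary tibble (variant, output, mean, sem, group flags) with
#'   the per-seed detail in `attr(, "detail")`.
#' @export
training_error_comparison <- function(variants = variant_names(),
                                      seeds = 1:10, epochs = 20L,
                                      world_seed = 1L,
                                      settle = settle_config(),
                                      learn = learning_config()) {
  stopifnot(all(variants %in% variant_names()))
  assoc <- build_association_set(seed = world_seed)
  detail <- dplyr::bind_rows(lapply(variants, function(v) {
    fit <- train_network(build_network(default_config(v)), assoc,
                         epochs = epochs, seeds = seeds, settle = settle,
                         learn = learn, eval_epochs = FALSE)
    dplyr::mutate(fit$log[fit$log$epoch == epochs, ], variant = v,
                  .before = 1)
  }))
  summary <- detail |>
    dplyr::group_by(.data$variant, .data$output) |>
    dplyr::summarise(
      mean = mean(.data$error),
      sem = if (dplyr::n() >= 2) stats::sd(.data$error) / sqrt(dplyr::n())
            else NA_real_,
      n_seeds = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(
      equal_units = .data$variant %in% c("Baseline", "SplitDG", "AllSplit"),
      equal_error = .data$variant %in% c("Baseline", "SplitDGplus",
                                         "AllSplitplus")
    )
  attr(summary, "detail") <- detail
  summary
}
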
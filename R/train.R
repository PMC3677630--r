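# Two-phase training on the object/context world and frozen-weight
# evaluation of trial sets.

#' Train networks on the association world
#'
#' For each replicate seed: initialises the network, then for each epoch
#' presents all matched object-context pairs in a fresh random order,
#' running a minus phase (inputs clamped), a plus phase (inputs and all four
#' output targets clamped) and one contrastive Hebbian weight update per
#' presentation. The end-of-epoch training error is the pure minus-phase
#' recall error over all training trials. Weights are frozen afterward
#' (evaluation never updates them).
#'
#' @param spec A [network_spec()], [default_config()] or variant name.
#' @param assoc An `assoc_set` world.
#' @param epochs Number of training epochs.
#' @param seeds Integer vector of replicate seeds (one trained network per
#'   seed).
#' @param settle A [settle_config()].
#' @param learn A [learning_config()].
#' @param eval_epochs Record the training error at the end of every epoch
#'   (`TRUE`, the default) or only after the final epoch.
#' @return A `hippo_fit` object: trained `states` (one per seed) and the
#'   tidy training `log` (seed, epoch, output, error).
#' @export
train_network <- function(spec, assoc, epochs = 20L, seeds = 1L,
                          settle = settle_config(),
                          learn = learning_config(),
                          eval_epochs = TRUE) {
  if (is.character(spec) || inherits(spec, "architecture_config")) {
    spec <- build_network(spec)
  }
  stopifnot(inherits(spec, "network_spec"), inherits(assoc, "assoc_set"),
            epochs >= 1)
  trials <- training_trials(assoc)
  n <- nrow(trials)
  states <- list()
  logs <- list()
  for (sd in seeds) {
    with_seed_(sd, {
      st <- init_network(spec)
      for (ep in seq_len(epochs)) {
        for (i in sample.int(n)) {
          ph <- run_trial(st, trials[i, ], settle)
          chl_update(st, ph, learn)
        }
        if (eval_epochs || ep == epochs) {
          err <- evaluate(st, trials, settle)
          logs[[length(logs) + 1L]] <- dplyr::summarise(
            dplyr::group_by(err, .data$output),
            error = mean(.data$error), .groups = "drop"
          ) |>
            dplyr::mutate(seed = sd, epoch = ep, .before = 1)
        }
      }
      states[[as.character(sd)]] <- st
    })
  }
  structure(
    list(variant = spec$variant, spec = spec, assoc = assoc,
         seeds = as.integer(seeds), epochs = as.integer(epochs),
         states = states, log = dplyr::bind_rows(logs),
         settle = settle, learn = learn),
    class = "hippo_fit"
  )
}

#' @export
print.hippo_fit <- function(x, ...) {
  cat("<hippo_fit> ", x$variant, ", ", x$epochs, " epochs, ",
      length(x$states), " seed(s)\n", sep = "")
  fin <- x$log[x$log$epoch == x$epochs, ]
  if (nrow(fin) > 0) {
    m <- tapply(fin$error, fin$output, mean)
    cat("final training error: ",
        paste(names(m), round(m, 3), sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}

#' Evaluate a trained network on a trial set
#'
#' Runs a minus phase (inputs clamped, everything else free) per trial on
#' frozen weights and scores each requested output with the normalized miss
#' rate of [output_error()]. The context-based object guess is scored per
#' canonical 64-unit slot and averaged over slots.
#'
#' @param state A trained `network_state` (or a `hippo_fit`, in which case
#'   every replicate is evaluated and a `seed` column added).
#' @param trials A trial tibble from [training_trials()] or
#'   [build_test_battery()].
#' @param cfg A [settle_config()].
#' @param outputs Output layers to score.
#' @return A tibble with one row per trial and output: trial descriptors
#'   plus `output` and `error`.
#' @export
evaluate <- function(state, trials, cfg = settle_config(),
                     outputs = c("O", "OBCG", "CBOG", "C")) {
  if (inherits(state, "hippo_fit")) {
    res <- lapply(seq_along(state$states), function(i) {
      dplyr::mutate(
        evaluate(state$states[[i]], trials, cfg, outputs),
        seed = state$seeds[i], .before = 1
      )
    })
    return(dplyr::bind_rows(res))
  }
  stopifnot(inherits(state, "network_state"))
  if (!all(c("lec", "mec") %in% names(trials))) {
    stop("`trials` is not a trial tibble", call. = FALSE)
  }
  if (length(trials$lec[[1]]) != state$sizes[["LEC"]] ||
      length(trials$target_CBOG[[1]]) != state$sizes[["CBOG"]]) {
    stop("trial pattern sizes do not match the network", call. = FALSE)
  }
  n_units <- state$sizes[["O"]]
  rows <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    reset_activations(state)
    settle(state, list(LEC = trials$lec[[i]], MEC = trials$mec[[i]]), cfg)
    errs <- vapply(outputs, function(out) {
      act <- layer_activations(state, out)
      tgt <- trials[[paste0("target_", out)]][[i]]
      if (out == "CBOG") {
        slots <- length(tgt) / n_units
        mean(vapply(seq_len(slots), function(s) {
          idx <- ((s - 1) * n_units + 1):(s * n_units)
          output_error(act[idx], tgt[idx])
        }, numeric(1)))
      } else {
        output_error(act, tgt)
      }
    }, numeric(1))
    rows[[i]] <- tibble::tibble(
      battery = trials$battery[i], level = trials$level[i],
      tag = trials$tag[i], object_id = trials$object_id[i],
      context_id = trials$context_id[i], output = outputs,
      error = unname(errs)
    )
  }
  dplyr::bind_rows(rows)
}

#' Summarise per-trial errors into per-output means
#'
#' @param errors A per-trial error tibble from [evaluate()].
#' @param ... Additional grouping columns (e.g. `level`, `seed`, `tag`).
#' @return A tibble of mean errors by output (and any extra groups), with
#'   SEM across seeds when a `seed` column is present in `errors` and not
#'   used as a grouping variable.
#' @export
summarise_errors <- function(errors, ...) {
  by_seed <- "seed" %in% names(errors)
  grp <- if (by_seed) {
    dplyr::group_by(errors, .data$seed, .data$output, ...)
  } else {
    dplyr::group_by(errors, .data$output, ...)
  }
  per_seed <- dplyr::summarise(grp, error = mean(.data$error),
                               .groups = "drop")
  if (!by_seed) return(per_seed)
  dplyr::summarise(
    dplyr::group_by(per_seed, .data$output, ...),
    mean = mean(.data$error),
    sem = if (dplyr::n() >= 2) stats::sd(.data$error) / sqrt(dplyr::n())
          else NA_real_,
    n_seeds = dplyr::n(),
    .groups = "drop"
  )
}

#' Combined recognition score
#'
#' The figure-of-merit used for whole-network comparisons: the mean of the
#' object-output error and the better (lower) of the two context outputs
#' (context guess or object-based context guess).
#'
#' @param errors A per-trial error tibble from [evaluate()] containing the
#'   `O`, `C` and `OBCG` outputs.
#' @param ... Grouping columns (e.g. `seed`, `level`).
#' @return A tibble with one `combined` error per group.
#' @export
combined_score <- function(errors, ...) {
  means <- dplyr::summarise(
    dplyr::group_by(errors, .data$output, ...),
    error = mean(.data$error), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(means, names_from = "output",
                             values_from = "error")
  if (!all(c("O", "C", "OBCG") %in% names(wide))) {
    stop("combined score needs the O, C and OBCG outputs", call. = FALSE)
  }
  dplyr::mutate(wide,
                combined = (.data$O + pmin(.data$C, .data$OBCG)) / 2)
}

#' Tidy summary of a trained network
#'
#' One row per output stream: mean and SEM of the final-epoch training
#' error across replicate seeds.
#'
#' @param x A `hippo_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hippo_fit <- function(x, ...) {
  fin <- x$log[x$log$epoch == x$epochs, ]
  dplyr::summarise(
    dplyr::group_by(fin, .data$output),
    mean = mean(.data$error),
    sem = if (dplyr::n() >= 2) stats::sd(.data$error) / sqrt(dplyr::n())
          else NA_real_,
    n_seeds = dplyr::n(),
    .groups = "drop"
  ) |>
    dplyr::mutate(variant = x$variant, epochs = x$epochs, .before = 1)
}

#' One-row summary of a trained network
#'
#' @param x A `hippo_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.hippo_fit <- function(x, ...) {
  fin <- x$log[x$log$epoch == x$epochs, ]
  tibble::tibble(
    variant = x$variant,
    epochs = x$epochs,
    n_seeds = length(x$states),
    n_trials = nrow(x$assoc$objects),
    mean_training_error = mean(fin$error)
  )
}
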
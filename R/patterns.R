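# Synthetic training world: sparse binary object/context patterns, the
# object -> context association map, and the corrupted test batteries.

#' Generate a random sparse binary pattern
#'
#' Draws a binary activity vector with exactly `n_active` ones placed
#' uniformly at random. The defaults produce the 8 x 8 input patterns used
#' throughout the package: 64 units of which 16 are active, matching the 25%
#' activity of the entorhinal input layers.
#'
#' @param n_units Pattern length (number of units).
#' @param n_active Number of active (1) units; must not exceed `n_units`.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return An integer vector of 0/1 of length `n_units` with exactly
#'   `n_active` ones.
#' @examples
#' p <- generate_pattern(64, 16, seed = 1)
#' sum(p)
#' @export
generate_pattern <- function(n_units = 64L, n_active = 16L, seed = NULL) {
  stopifnot(length(n_units) == 1, length(n_active) == 1)
  n_units <- as.integer(n_units)
  n_active <- as.integer(n_active)
  if (is.na(n_units) || n_units < 1) {
    stop("`n_units` must be a positive integer", call. = FALSE)
  }
  if (is.na(n_active) || n_active < 0 || n_active > n_units) {
    stop("`n_active` must lie in [0, n_units]", call. = FALSE)
  }
  with_seed_(seed, {
    p <- integer(n_units)
    if (n_active > 0) p[sample.int(n_units, n_active)] <- 1L
    p
  })
}

#' Build the object/context association world
#'
#' Generates the full training world: `n_contexts * objects_per_context`
#' unique object patterns, `n_contexts` unique context patterns, and the map
#' assigning each object to exactly one context. All patterns are pairwise
#' distinct (duplicates are redrawn). Defaults give the standard world of
#' 120 objects and 40 contexts, 3 objects per context.
#'
#' @param n_contexts Number of context patterns.
#' @param objects_per_context Number of objects associated with each context.
#' @param n_units,n_active Pattern geometry, see [generate_pattern()].
#' @param seed Optional integer seed.
#' @return An object of class `assoc_set`: a list with integer matrices
#'   `objects` (one pattern per row) and `contexts`, the integer vector
#'   `context_of` (trained context id of each object), and the generation
#'   parameters.
#' @examples
#' world <- build_association_set(seed = 1)
#' nrow(world$objects)
#' @export
build_association_set <- function(n_contexts = 40L, objects_per_context = 3L,
                                  n_units = 64L, n_active = 16L,
                                  seed = NULL) {
  n_contexts <- as.integer(n_contexts)
  objects_per_context <- as.integer(objects_per_context)
  if (n_contexts < 1 || objects_per_context < 1) {
    stop("counts must be positive", call. = FALSE)
  }
  n_objects <- n_contexts * objects_per_context
  n_total <- n_objects + n_contexts
  if (lchoose(n_units, n_active) < log(n_total)) {
    stop("cannot draw ", n_total, " distinct patterns with ", n_active,
         " of ", n_units, " units active", call. = FALSE)
  }
  with_seed_(seed, {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    draw <- function() {
      repeat {
        p <- generate_pattern(n_units, n_active)
        key <- paste(p, collapse = "")
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          return(p)
        }
      }
    }
    objects <- matrix(0L, n_objects, n_units)
    for (i in seq_len(n_objects)) objects[i, ] <- draw()
    contexts <- matrix(0L, n_contexts, n_units)
    for (i in seq_len(n_contexts)) contexts[i, ] <- draw()
    structure(
      list(
        objects = objects,
        contexts = contexts,
        context_of = rep(seq_len(n_contexts), each = objects_per_context),
        objects_per_context = objects_per_context,
        n_units = n_units,
        n_active = n_active
      ),
      class = "assoc_set"
    )
  })
}

#' @export
print.assoc_set <- function(x, ...) {
  cat("<assoc_set> ", nrow(x$objects), " objects, ", nrow(x$contexts),
      " contexts (", x$objects_per_context, " objects/context), patterns ",
      x$n_active, "/", x$n_units, " active\n", sep = "")
  invisible(x)
}

#' Tidy view of an association world
#'
#' @param x An `assoc_set`.
#' @param ... Unused.
#' @return A tibble with one row per pattern: `id`, `role` ("object" or
#'   "context"), `context_id` (trained context for objects, own id for
#'   contexts) and the list-column `pattern`.
#' @export
as_tibble.assoc_set <- function(x, ...) {
  tibble::tibble(
    id = c(seq_len(nrow(x$objects)), seq_len(nrow(x$contexts))),
    role = rep(c("object", "context"),
               c(nrow(x$objects), nrow(x$contexts))),
    context_id = c(x$context_of, seq_len(nrow(x$contexts))),
    pattern = c(
      lapply(seq_len(nrow(x$objects)), function(i) x$objects[i, ]),
      lapply(seq_len(nrow(x$contexts)), function(i) x$contexts[i, ])
    )
  )
}

#' Ground-truth output targets for one trial
#'
#' Assembles the four output-layer targets for an object presented in a
#' context. The object guess `O` and object-based context guess `OBCG` are
#' keyed to the object's *trained* context; the context guess `C` and the
#' context-based object guess `CBOG` are keyed to the *presented* context.
#' `CBOG` is the concatenation of the presented context's objects in
#' ascending object-id order.
#'
#' @param object_id,context_id Object and presented-context ids.
#' @param assoc An `assoc_set`.
#' @return A list with integer vectors `O`, `OBCG`, `C` (length `n_units`)
#'   and `CBOG` (length `objects_per_context * n_units`).
#' @export
make_targets <- function(object_id, context_id, assoc) {
  stopifnot(inherits(assoc, "assoc_set"))
  if (length(object_id) != 1 || object_id < 1 ||
      object_id > nrow(assoc$objects)) {
    stop("unknown object id: ", object_id, call. = FALSE)
  }
  if (length(context_id) != 1 || context_id < 1 ||
      context_id > nrow(assoc$contexts)) {
    stop("unknown context id: ", context_id, call. = FALSE)
  }
  members <- which(assoc$context_of == context_id)
  list(
    O = assoc$objects[object_id, ],
    OBCG = assoc$contexts[assoc$context_of[object_id], ],
    C = assoc$contexts[context_id, ],
    CBOG = as.integer(t(assoc$objects[members, , drop = FALSE]))
  )
}

#' Describe a pattern corruption
#'
#' @param mode One of `"additive"` (extra active units), `"nonadditive"`
#'   (paired 0->1 / 1->0 swaps, activity preserved), `"partial"` (the level
#'   is the *completeness*: the fraction of original ones retained), or
#'   `"mixed"` (half additive, half non-additive; an odd change count puts
#'   the extra unit on the additive half).
#' @param level Fraction in \[0, 1\]. For the noise modes it is the fraction
#'   of units changed; for `partial` it is the fraction retained.
#' @param basis Reference count the level is taken against:
#'   `"active_units"` (the pattern's original active count, the default) or
#'   `"total_units"`.
#' @return A `corruption_spec` list.
#' @export
corruption_spec <- function(mode = c("additive", "nonadditive", "partial",
                                     "mixed"),
                            level, basis = c("active_units", "total_units")) {
  mode <- match.arg(mode)
  basis <- match.arg(basis)
  if (!is.numeric(level) || length(level) != 1 || is.na(level) ||
      level < 0 || level > 1) {
    stop("`level` must be a single fraction in [0, 1]", call. = FALSE)
  }
  structure(list(mode = mode, level = level, basis = basis),
            class = "corruption_spec")
}

#' Corrupt a binary pattern
#'
#' Applies one of the four degradation modes to a binary pattern. The number
#' of changed units is `round(level * basis_count)` (half away from zero),
#' where the basis count is the pattern's original active count or its total
#' length, per `spec$basis`.
#'
#' @param pattern Integer 0/1 vector.
#' @param spec A [corruption_spec()].
#' @param seed Optional integer seed.
#' @return The corrupted pattern (integer 0/1 vector, same length).
#' @examples
#' p <- generate_pattern(seed = 1)
#' sum(corrupt(p, corruption_spec("additive", 0.3), seed = 2))  # 16 + 5
#' @export
corrupt <- function(pattern, spec, seed = NULL) {
  stopifnot(inherits(spec, "corruption_spec"))
  pattern <- as.integer(pattern)
  ones <- which(pattern == 1L)
  zeros <- which(pattern == 0L)
  basis_count <- if (spec$basis == "active_units") length(ones)
                 else length(pattern)
  if (spec$mode != "additive" && length(ones) == 0) {
    stop("pattern has no active units", call. = FALSE)
  }
  with_seed_(seed, {
    out <- pattern
    if (spec$mode == "partial") {
      retain <- as.integer(round_half_up(spec$level * basis_count))
      if (retain > length(ones)) {
        stop("cannot retain ", retain, " ones: pattern has only ",
             length(ones), call. = FALSE)
      }
      keep <- ones[sample.int(length(ones), retain)]
      out[] <- 0L
      out[keep] <- 1L
      return(out)
    }
    n_change <- as.integer(round_half_up(spec$level * basis_count))
    if (n_change == 0) return(out)
    n_add <- switch(spec$mode, additive = n_change, nonadditive = 0L,
                    mixed = as.integer(ceiling(n_change / 2)))
    n_swap <- n_change - n_add
    if (n_add + n_swap > length(zeros)) {
      stop("not enough inactive units to corrupt", call. = FALSE)
    }
    if (n_swap > length(ones)) {
      stop("not enough active units to swap out", call. = FALSE)
    }
    turn_on <- zeros[sample.int(length(zeros), n_add + n_swap)]
    out[turn_on] <- 1L
    if (n_swap > 0) {
      turn_off <- ones[sample.int(length(ones), n_swap)]
      out[turn_off] <- 0L
    }
    out
  })
}

#' Names of the recognised test batteries
#' @return Character vector.
#' @export
battery_names <- function() {
  c("cbog_context_only", "partial_context", "partial_object",
    "additive_object", "additive_context", "nonadditive_object",
    "nonadditive_context", "mismatch", "sample_O_C", "sample_OBCG",
    "sample_CBOG")
}

# random derangement of 1..n (no fixed points)
derangement_ <- function(n) {
  if (n < 2) stop("a derangement needs at least 2 elements", call. = FALSE)
  repeat {
    s <- sample.int(n)
    if (all(s != seq_len(n))) return(s)
  }
}

# one trial row; lec/mec are integer vectors (an absent input is all zeros)
trial_row_ <- function(assoc, object_id, context_id, lec, mec, battery,
                       level, tag) {
  tg <- make_targets(object_id, context_id, assoc)
  tibble::tibble(
    battery = battery, level = level, tag = tag,
    object_id = as.integer(object_id), context_id = as.integer(context_id),
    mismatch = assoc$context_of[object_id] != context_id,
    lec = list(as.integer(lec)), mec = list(as.integer(mec)),
    target_O = list(tg$O), target_OBCG = list(tg$OBCG),
    target_C = list(tg$C), target_CBOG = list(tg$CBOG)
  )
}

#' Clean matched training trials
#'
#' One trial per object: the clean object pattern on LEC, its trained
#' context on MEC, all four targets populated.
#'
#' @param assoc An `assoc_set`.
#' @return A trial tibble (one row per trial, list-columns `lec`, `mec`,
#'   `target_*`).
#' @export
training_trials <- function(assoc) {
  stopifnot(inherits(assoc, "assoc_set"))
  rows <- lapply(seq_len(nrow(assoc$objects)), function(o) {
    ctx <- assoc$context_of[o]
    trial_row_(assoc, o, ctx, assoc$objects[o, ], assoc$contexts[ctx, ],
               "training", 0, "clean")
  })
  dplyr::bind_rows(rows)
}

# matched trials with one input corrupted (or both, for the sample sets)
corrupted_trials_ <- function(assoc, battery, level, tag,
                              lec_spec = NULL, mec_spec = NULL) {
  rows <- lapply(seq_len(nrow(assoc$objects)), function(o) {
    ctx <- assoc$context_of[o]
    lec <- assoc$objects[o, ]
    mec <- assoc$contexts[ctx, ]
    if (!is.null(lec_spec)) lec <- corrupt(lec, lec_spec)
    if (!is.null(mec_spec)) mec <- corrupt(mec, mec_spec)
    trial_row_(assoc, o, ctx, lec, mec, battery, level, tag)
  })
  dplyr::bind_rows(rows)
}

mismatch_trials_ <- function(assoc, battery = "mismatch", tag = "mismatch",
                             lec_spec = NULL, mec_spec = NULL) {
  sigma <- derangement_(nrow(assoc$contexts))
  rows <- lapply(seq_len(nrow(assoc$objects)), function(o) {
    ctx <- sigma[assoc$context_of[o]]
    lec <- assoc$objects[o, ]
    mec <- assoc$contexts[ctx, ]
    if (!is.null(lec_spec)) lec <- corrupt(lec, lec_spec)
    if (!is.null(mec_spec)) mec <- corrupt(mec, mec_spec)
    trial_row_(assoc, o, ctx, lec, mec, battery, 0, tag)
  })
  dplyr::bind_rows(rows)
}

#' Build a corrupted test battery
#'
#' Constructs the trial set for one of the standard degraded-input tests:
#' one trial per object association and level, with the named input degraded
#' and the other input clean.
#'
#' Batteries: `partial_object` / `partial_context` (levels are completeness
#' fractions), `additive_*` and `nonadditive_*` (levels are noise
#' fractions), `mismatch` (every object presented with a deranged context,
#' never its trained one), `cbog_context_only` (LEC clamped to all zeros,
#' clean context on MEC), and the three calibration sample sets:
#' `sample_O_C` (15% mixed noise in both inputs, plus 40%-complete in both),
#' `sample_OBCG` (mismatch; 30% mixed context noise; 40%-complete context)
#' and `sample_CBOG` (mismatch; 30% mixed object noise; 40%-complete
#' object).
#'
#' @param assoc An `assoc_set`.
#' @param battery Battery name, one of [battery_names()].
#' @param levels Numeric vector of corruption levels; ignored by the
#'   mismatch, context-only and sample batteries which have fixed designs.
#' @param seed Optional integer seed for the corruption draws.
#' @return A trial tibble (see [training_trials()]) with `battery`, `level`
#'   and `tag` columns.
#' @export
build_test_battery <- function(assoc, battery, levels = NULL, seed = NULL) {
  stopifnot(inherits(assoc, "assoc_set"))
  if (!battery %in% battery_names()) {
    stop("unknown battery: ", battery, call. = FALSE)
  }
  with_seed_(seed, {
    switch(battery,
      cbog_context_only = {
        rows <- lapply(seq_len(nrow(assoc$objects)), function(o) {
          ctx <- assoc$context_of[o]
          trial_row_(assoc, o, ctx, integer(assoc$n_units),
                     assoc$contexts[ctx, ], battery, 0, "context_only")
        })
        dplyr::bind_rows(rows)
      },
      mismatch = mismatch_trials_(assoc),
      partial_context = dplyr::bind_rows(lapply(levels, function(lv) {
        corrupted_trials_(assoc, battery, lv, "partial_context",
                          mec_spec = corruption_spec("partial", lv))
      })),
      partial_object = dplyr::bind_rows(lapply(levels, function(lv) {
        corrupted_trials_(assoc, battery, lv, "partial_object",
                          lec_spec = corruption_spec("partial", lv))
      })),
      additive_object = dplyr::bind_rows(lapply(levels, function(lv) {
        corrupted_trials_(assoc, battery, lv, "additive_object",
                          lec_spec = corruption_spec("additive", lv))
      })),
      additive_context = dplyr::bind_rows(lapply(levels, function(lv) {
        corrupted_trials_(assoc, battery, lv, "additive_context",
                          mec_spec = corruption_spec("additive", lv))
      })),
      nonadditive_object = dplyr::bind_rows(lapply(levels, function(lv) {
        corrupted_trials_(assoc, battery, lv, "nonadditive_object",
                          lec_spec = corruption_spec("nonadditive", lv))
      })),
      nonadditive_context = dplyr::bind_rows(lapply(levels, function(lv) {
        corrupted_trials_(assoc, battery, lv, "nonadditive_context",
                          mec_spec = corruption_spec("nonadditive", lv))
      })),
      sample_O_C = dplyr::bind_rows(
        corrupted_trials_(assoc, battery, 0.15, "mixed_noise_15",
                          lec_spec = corruption_spec("mixed", 0.15),
                          mec_spec = corruption_spec("mixed", 0.15)),
        corrupted_trials_(assoc, battery, 0.40, "partial_40",
                          lec_spec = corruption_spec("partial", 0.40),
                          mec_spec = corruption_spec("partial", 0.40))
      ),
      sample_OBCG = dplyr::bind_rows(
        mismatch_trials_(assoc, battery, "mismatch"),
        corrupted_trials_(assoc, battery, 0.30, "context_noise_30",
                          mec_spec = corruption_spec("mixed", 0.30)),
        corrupted_trials_(assoc, battery, 0.40, "partial_context_40",
                          mec_spec = corruption_spec("partial", 0.40))
      ),
      sample_CBOG = dplyr::bind_rows(
        mismatch_trials_(assoc, battery, "mismatch"),
        corrupted_trials_(assoc, battery, 0.30, "object_noise_30",
                          lec_spec = corruption_spec("mixed", 0.30)),
        corrupted_trials_(assoc, battery, 0.40, "partial_object_40",
                          lec_spec = corruption_spec("partial", 0.40))
      )
    )
  })
}
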
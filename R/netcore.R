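# Rate-coded network engine: layer/projection specs, weight state,
# net-input accumulation with relative projection scaling, kWTA inhibition,
# two-phase settling and the contrastive Hebbian weight update.
#
# Weight matrices are stored receiver x sender, so `W %*% acts(source)` is a
# drive contribution; columns index senders.

#' Declare a layer
#'
#' @param name Unique layer name.
#' @param size Number of units.
#' @param activity_fraction Fraction of units left active by the layer's
#'   k-winners-take-all inhibition; the winner count is
#'   `max(1, round(activity_fraction * size))`.
#' @param clampable Whether the layer can be clamped to an external pattern
#'   (input and output layers).
#' @return A one-row tibble.
#' @export
layer_spec <- function(name, size, activity_fraction, clampable = FALSE) {
  size <- as.integer(size)
  stopifnot(size >= 1, activity_fraction >= 0, activity_fraction <= 1)
  k <- max(1L, as.integer(round_half_up(activity_fraction * size)))
  if (k > size) stop("k_active exceeds layer size", call. = FALSE)
  tibble::tibble(name = as.character(name), size = size,
                 activity_fraction = activity_fraction, k = k,
                 clampable = isTRUE(clampable))
}

#' Declare a projection
#'
#' @param source,target Layer names.
#' @param rel_weight Nonnegative relative strength multiplier. Net input to
#'   a layer is the sum over incoming projections of
#'   `rel_weight * (W %*% acts) / k_active(source)`; dividing by the
#'   expected active sender count makes multipliers comparable across source
#'   layers of different sizes.
#' @param learnable Whether the projection's weights are updated by the
#'   learning rule.
#' @param bidirectional When `TRUE`, an independent return projection
#'   (target -> source) with the same settings is created as well.
#' @return A one-row tibble.
#' @export
projection_spec <- function(source, target, rel_weight = 1,
                            learnable = TRUE, bidirectional = FALSE) {
  stopifnot(rel_weight >= 0)
  tibble::tibble(source = as.character(source),
                 target = as.character(target),
                 rel_weight = as.numeric(rel_weight),
                 learnable = isTRUE(learnable),
                 bidirectional = isTRUE(bidirectional))
}

#' Assemble a network specification
#'
#' Validates layer and projection tables and expands bidirectional
#' projections into two independent directed projections.
#'
#' @param variant Variant label.
#' @param layers Tibble of [layer_spec()] rows.
#' @param projections Tibble of [projection_spec()] rows.
#' @return A `network_spec` object.
#' @export
network_spec <- function(variant, layers, projections) {
  layers <- dplyr::bind_rows(layers)
  projections <- dplyr::bind_rows(projections)
  if (anyDuplicated(layers$name)) {
    stop("layer names must be unique", call. = FALSE)
  }
  missing <- setdiff(unique(c(projections$source, projections$target)),
                     layers$name)
  if (length(missing) > 0) {
    stop("projection references missing layer(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  back <- projections[projections$bidirectional, ]
  if (nrow(back) > 0) {
    back <- tibble::tibble(source = back$target, target = back$source,
                           rel_weight = back$rel_weight,
                           learnable = back$learnable,
                           bidirectional = FALSE)
  }
  projections$bidirectional <- NULL
  projections <- dplyr::bind_rows(projections, back)
  projections$id <- paste0(projections$source, "->", projections$target)
  if (anyDuplicated(projections$id)) {
    stop("duplicate projection: ",
         projections$id[duplicated(projections$id)][1], call. = FALSE)
  }
  structure(list(variant = variant, layers = layers,
                 projections = projections),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec> variant ", x$variant, ": ", nrow(x$layers),
      " layers (", sum(x$layers$size), " units), ", nrow(x$projections),
      " projections\n", sep = "")
  invisible(x)
}

#' Settling configuration
#'
#' @param max_cycles Maximum synchronous update cycles per phase.
#' @param tol Convergence tolerance on the maximum activation change.
#' @param gain Logistic activation gain applied to the suprathreshold drive.
#' @param clamp_value Activation assigned to active units of a clamped
#'   pattern.
#' @param step_size Under-relaxation step for the synchronous update;
#'   damping below 1 keeps recurrent and bidirectional loops from
#'   oscillating.
#' @return A `settle_config` list.
#' @export
settle_config <- function(max_cycles = 60L, tol = 1e-4, gain = 2,
                          clamp_value = 1, step_size = 0.7) {
  stopifnot(max_cycles >= 1, tol > 0, gain > 0, step_size > 0,
            step_size <= 1)
  structure(list(max_cycles = as.integer(max_cycles), tol = tol, gain = gain,
                 clamp_value = clamp_value, step_size = step_size),
            class = "settle_config")
}

#' Learning configuration
#'
#' @param rate Learning rate.
#' @param hebb Hebbian mixing fraction in \[0, 1\] blended with the
#'   contrastive (error-driven) term.
#' @param soft_bound Scale positive raw changes by `1 - w` and negative by
#'   `w`, keeping weights in \[0, 1\].
#' @return A `learning_config` list.
#' @export
learning_config <- function(rate = 0.05, hebb = 0.125, soft_bound = TRUE) {
  stopifnot(rate > 0, hebb >= 0, hebb <= 1)
  structure(list(rate = rate, hebb = hebb, soft_bound = isTRUE(soft_bound)),
            class = "learning_config")
}

#' Initialise network weights and activations
#'
#' Weights are drawn uniformly from \[0.25, 0.75\] (each direction of a
#' bidirectional pair independently); activations start at zero.
#'
#' @param spec A [network_spec()].
#' @param seed Optional integer seed.
#' @return A `network_state` environment holding the weight matrices
#'   (receiver x sender, named `"source->target"`), the concatenated
#'   activation vector and cached index tables. The state has reference
#'   semantics: settling and learning update it in place.
#' @export
init_network <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  ly <- spec$layers
  pr <- spec$projections
  offsets <- c(0L, cumsum(ly$size))[seq_len(nrow(ly))]
  names(offsets) <- ly$name
  sizes <- stats::setNames(ly$size, ly$name)
  src_i <- match(pr$source, ly$name)
  tgt_i <- match(pr$target, ly$name)
  st <- new.env(parent = emptyenv())
  st$spec <- spec
  st$offsets <- offsets
  st$sizes <- sizes
  st$kvec <- stats::setNames(ly$k, ly$name)
  st$psrc0 <- src_i - 1L
  st$ptgt0 <- tgt_i - 1L
  st$pscale <- pr$rel_weight / ly$k[src_i]
  st$acts <- numeric(sum(ly$size))
  st$last_converged <- NA
  with_seed_(seed, {
    st$W <- stats::setNames(lapply(seq_len(nrow(pr)), function(p) {
      nt <- ly$size[tgt_i[p]]
      ns <- ly$size[src_i[p]]
      matrix(runif(nt * ns, 0.25, 0.75), nt, ns)
    }), pr$id)
  })
  class(st) <- "network_state"
  st
}

#' @export
print.network_state <- function(x, ...) {
  cat("<network_state> variant ", x$spec$variant, ": ",
      length(x$W), " weight tables, ", length(x$acts), " units\n", sep = "")
  invisible(x)
}

# index range of a layer in the concatenated activation vector
layer_index_ <- function(state, layer) {
  off <- state$offsets[[layer]]
  seq.int(off + 1L, off + state$sizes[[layer]])
}

#' Current activations of one layer
#' @param state A `network_state`.
#' @param layer Layer name.
#' @return Numeric activation vector.
#' @export
layer_activations <- function(state, layer) {
  if (!layer %in% names(state$sizes)) {
    stop("unknown layer: ", layer, call. = FALSE)
  }
  state$acts[layer_index_(state, layer)]
}

#' Reset all activations to zero
#' @param state A `network_state`.
#' @export
reset_activations <- function(state) {
  state$acts[] <- 0
  invisible(state)
}

#' Net input drive to a layer
#'
#' Reference implementation of the drive accumulation used during settling:
#' each incoming projection contributes
#' `rel_weight * (W %*% acts(source)) / k_active(source)`.
#'
#' @param state A `network_state`.
#' @param layer Target layer name.
#' @return Numeric drive vector of the layer's size.
#' @export
net_input <- function(state, layer) {
  if (!layer %in% names(state$sizes)) {
    stop("unknown layer: ", layer, call. = FALSE)
  }
  pr <- state$spec$projections
  drive <- numeric(state$sizes[[layer]])
  for (p in which(pr$target == layer)) {
    a <- state$acts[layer_index_(state, pr$source[p])]
    drive <- drive + state$pscale[p] * as.numeric(state$W[[p]] %*% a)
  }
  drive
}

#' k-winners-take-all threshold
#'
#' Returns the inhibition threshold placed midway between the k-th and
#' (k+1)-th largest drives, after a deterministic index-order tie
#' perturbation so that exactly `k` units strictly exceed it (ties resolve
#' to the lowest index). `k = 0` yields a threshold above the maximum,
#' `k = length(drives)` one below the minimum.
#'
#' @param drives Numeric drive vector.
#' @param k Number of winners.
#' @return Threshold scalar.
#' @examples
#' kwta_threshold(c(0.9, 0.5, 0.1, 0), 2)
#' @export
kwta_threshold <- function(drives, k) {
  cpp_kwta_threshold(as.numeric(drives), as.integer(k))
}

#' Settle the network to an activation fixed point
#'
#' Clamped layers are fixed at their patterns (scaled by
#' `cfg$clamp_value`); free layers are updated synchronously from the
#' current state until the maximum activation change falls below `cfg$tol`
#' or `cfg$max_cycles` is reached. Each cycle a layer's inhibition threshold
#' is the kWTA threshold of its drives; winners take a logistic of their
#' suprathreshold drive and sub-threshold units transmit zero.
#'
#' @param state A `network_state` (updated in place).
#' @param clamps Named list mapping layer names to 0/1 patterns.
#' @param cfg A [settle_config()].
#' @return Invisibly, a named list of per-layer activation vectors with
#'   attributes `cycles` and `converged`.
#' @export
settle <- function(state, clamps = list(), cfg = settle_config()) {
  ly <- state$spec$layers
  clamped <- ly$name %in% names(clamps)
  for (nm in names(clamps)) {
    if (!nm %in% ly$name) stop("unknown layer: ", nm, call. = FALSE)
    if (!ly$clampable[ly$name == nm]) {
      stop("layer ", nm, " is not clampable", call. = FALSE)
    }
    pat <- as.numeric(clamps[[nm]])
    if (length(pat) != state$sizes[[nm]]) {
      stop("clamp for ", nm, " has wrong length", call. = FALSE)
    }
    state$acts[layer_index_(state, nm)] <- pat * cfg$clamp_value
  }
  res <- cpp_settle(state$W, state$psrc0, state$ptgt0, state$pscale,
                    unname(state$offsets), unname(state$sizes),
                    unname(state$kvec), clamped, state$acts, cfg$gain,
                    cfg$max_cycles, cfg$tol, cfg$step_size)
  state$acts <- res$acts
  state$last_converged <- res$converged
  out <- lapply(stats::setNames(ly$name, ly$name),
                function(nm) layer_activations(state, nm))
  attr(out, "cycles") <- res$cycles
  attr(out, "converged") <- res$converged
  invisible(out)
}

# coerce a one-row trial tibble (or a compatible list) to plain list form
as_trial_ <- function(trial) {
  if (is.data.frame(trial)) {
    stopifnot(nrow(trial) == 1)
    trial <- lapply(trial, function(col) {
      if (is.list(col)) col[[1]] else col
    })
  }
  if (is.null(trial$lec) && is.null(trial$mec)) {
    stop("a trial needs at least one of lec/mec inputs", call. = FALSE)
  }
  trial
}

#' Run one two-phase trial
#'
#' Minus phase: entorhinal inputs clamped, all other layers free, settled
#' from rest. Plus phase: inputs and all four output targets clamped,
#' settled from the minus-phase state.
#'
#' @param state A `network_state` (activations updated in place).
#' @param trial A one-row trial tibble (see [training_trials()]) or a list
#'   with elements `lec`, `mec`, `target_O`, `target_OBCG`, `target_C`,
#'   `target_CBOG`. A `NULL` input is clamped to all zeros.
#' @param cfg A [settle_config()].
#' @return A `phase_pair`: list with concatenated activation snapshots
#'   `minus` and `plus` plus convergence flags.
#' @export
run_trial <- function(state, trial, cfg = settle_config()) {
  trial <- as_trial_(trial)
  lec <- trial$lec %||% integer(state$sizes[["LEC"]])
  mec <- trial$mec %||% integer(state$sizes[["MEC"]])
  reset_activations(state)
  settle(state, list(LEC = lec, MEC = mec), cfg)
  minus <- state$acts
  conv_minus <- state$last_converged
  settle(state, list(LEC = lec, MEC = mec, O = trial$target_O,
                     OBCG = trial$target_OBCG, C = trial$target_C,
                     CBOG = trial$target_CBOG), cfg)
  plus <- state$acts
  structure(list(minus = minus, plus = plus,
                 converged = c(minus = conv_minus,
                               plus = state$last_converged)),
            class = "phase_pair")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Contrastive Hebbian weight update
#'
#' For every learnable projection applies
#' `dw = rate * ((1 - hebb) * (x+ y+ - x- y-) + hebb * y+ (x+ - w))`,
#' with soft bounding scaling positive raw changes by `1 - w` and negative
#' ones by `w`. Weights stay in \[0, 1\].
#'
#' @param state A `network_state` (weights updated in place).
#' @param phases A `phase_pair` from [run_trial()].
#' @param cfg A [learning_config()].
#' @return Invisibly, the state.
#' @export
chl_update <- function(state, phases, cfg = learning_config()) {
  stopifnot(inherits(phases, "phase_pair"))
  pr <- state$spec$projections
  for (p in which(pr$learnable)) {
    si <- layer_index_(state, pr$source[p])
    ti <- layer_index_(state, pr$target[p])
    cpp_chl_update(state$W[[p]], phases$minus[si], phases$plus[si],
                   phases$minus[ti], phases$plus[ti], cfg$rate, cfg$hebb,
                   cfg$soft_bound)
  }
  invisible(state)
}

#' Binarize an activation vector
#'
#' Sets the `m` most active units to 1 (ties to the lowest index) and the
#' rest to 0.
#'
#' @param activations Numeric vector.
#' @param m Number of units to activate.
#' @return Integer 0/1 vector.
#' @export
binarize <- function(activations, m) {
  m <- as.integer(m)
  stopifnot(m >= 0, m <= length(activations))
  out <- integer(length(activations))
  if (m > 0) {
    ord <- order(-activations, seq_along(activations))
    out[ord[seq_len(m)]] <- 1L
  }
  out
}

#' Normalized recall error of an output layer
#'
#' Binarizes the activations at the target's active count `m` and reports
#' the fraction of target-active units missed (0 = perfect recall, 1 =
#' disjoint support).
#'
#' @param activations Numeric activation vector.
#' @param target Integer 0/1 target pattern of the same length.
#' @return Error fraction in \[0, 1\].
#' @export
output_error <- function(activations, target) {
  if (length(activations) != length(target)) {
    stop("activation/target length mismatch", call. = FALSE)
  }
  m <- sum(target > 0)
  if (m == 0) stop("target has no active units", call. = FALSE)
  b <- binarize(activations, m)
  sum(target > 0 & b == 0L) / m
}
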
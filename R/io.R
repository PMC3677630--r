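# Plain-text serialization: pattern tables (TSV), trial batteries (TSV),
# weight snapshots (CSV per projection + JSON sidecar) and JSON run
# manifests.

pattern_string_ <- function(p) paste(p, collapse = "")

pattern_from_string_ <- function(s) {
  as.integer(strsplit(s, "", fixed = TRUE)[[1]])
}

#' Write / read an association world as a pattern table
#'
#' One row per pattern: `id`, `role` ("object"/"context"), `context_id` (the
#' trained context of an object; a context's own id) and the binary digits
#' of the pattern as a string.
#'
#' @param assoc An `assoc_set`.
#' @param path File path (tab-separated text).
#' @return `write_patterns()` returns `path` invisibly; `read_patterns()`
#'   returns the reconstructed `assoc_set`.
#' @export
write_patterns <- function(assoc, path) {
  stopifnot(inherits(assoc, "assoc_set"))
  tb <- as_tibble.assoc_set(assoc)
  tb$values <- vapply(tb$pattern, pattern_string_, character(1))
  tb$pattern <- NULL
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("integer", "character", "integer",
                                         "character"))
  obj <- tb[tb$role == "object", ]
  ctx <- tb[tb$role == "context", ]
  obj <- obj[order(obj$id), ]
  ctx <- ctx[order(ctx$id), ]
  objects <- do.call(rbind, lapply(obj$values, pattern_from_string_))
  contexts <- do.call(rbind, lapply(ctx$values, pattern_from_string_))
  opc <- nrow(obj) / nrow(ctx)
  if (opc != round(opc)) {
    stop("object count is not a multiple of context count", call. = FALSE)
  }
  structure(
    list(objects = objects, contexts = contexts,
         context_of = obj$context_id, objects_per_context = as.integer(opc),
         n_units = ncol(objects), n_active = sum(objects[1, ])),
    class = "assoc_set"
  )
}

#' Write a trial battery as a flat table
#'
#' Stores the trial descriptors and input patterns (targets are
#' reconstructable from the association world via [make_targets()]).
#'
#' @param trials A trial tibble.
#' @param path File path (tab-separated text).
#' @return `path`, invisibly.
#' @export
write_battery <- function(trials, path) {
  flat <- tibble::tibble(
    battery = trials$battery, level = trials$level, tag = trials$tag,
    object_id = trials$object_id, context_id = trials$context_id,
    lec = vapply(trials$lec, pattern_string_, character(1)),
    mec = vapply(trials$mec, pattern_string_, character(1))
  )
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_battery
#' @param assoc The `assoc_set` the battery was built from (supplies the
#'   targets).
#' @export
read_battery <- function(path, assoc) {
  stopifnot(inherits(assoc, "assoc_set"))
  flat <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = c("character", "numeric",
                                           "character", "integer", "integer",
                                           "character", "character"))
  rows <- lapply(seq_len(nrow(flat)), function(i) {
    trial_row_(assoc, flat$object_id[i], flat$context_id[i],
               pattern_from_string_(flat$lec[i]),
               pattern_from_string_(flat$mec[i]),
               flat$battery[i], flat$level[i], flat$tag[i])
  })
  dplyr::bind_rows(rows)
}

#' Save / restore network weights
#'
#' Writes one CSV per projection (receiver x sender matrix) plus a JSON
#' sidecar recording the variant, layer table and projection table, so a
#' snapshot is self-describing.
#'
#' @param state A `network_state`.
#' @param dir Snapshot directory (created if needed).
#' @param ... Extra metadata fields stored in the sidecar (e.g. seed,
#'   epoch).
#' @return `write_weights()` returns `dir` invisibly; `read_weights()`
#'   returns a `network_state` with the stored weights and zeroed
#'   activations.
#' @export
write_weights <- function(state, dir, ...) {
  stopifnot(inherits(state, "network_state"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pr <- state$spec$projections
  files <- paste0("w", seq_len(nrow(pr)), ".csv")
  for (p in seq_len(nrow(pr))) {
    utils::write.table(state$W[[p]], file.path(dir, files[p]), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  sidecar <- list(
    package = "hippsplit", version = as.character(packageVersion("hippsplit")),
    variant = state$spec$variant,
    layers = state$spec$layers,
    projections = cbind(pr, file = files),
    ...
  )
  jsonlite::write_json(sidecar, file.path(dir, "snapshot.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' @rdname write_weights
#' @export
read_weights <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "snapshot.json"),
                                 simplifyVector = TRUE)
  ly <- tibble::as_tibble(sidecar$layers)
  pr <- tibble::as_tibble(sidecar$projections)
  spec <- structure(
    list(variant = sidecar$variant, layers = ly,
         projections = pr[, c("source", "target", "rel_weight", "learnable",
                              "id")]),
    class = "network_spec"
  )
  st <- init_network(spec, seed = 0L)
  for (p in seq_len(nrow(pr))) {
    w <- as.matrix(utils::read.table(file.path(dir, pr$file[p]), sep = ","))
    dimnames(w) <- NULL
    stopifnot(all(dim(w) == dim(st$W[[p]])))
    st$W[[p]] <- w
  }
  reset_activations(st)
  st
}

#' Write a JSON run manifest
#'
#' Records everything needed to rerun a result: command, resolved
#' configuration, seeds, package version and timestamps.
#'
#' @param path Output file.
#' @param command Short command/experiment name.
#' @param ... Configuration fields to record.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, ...) {
  manifest <- list(
    package = "hippsplit",
    version = as.character(packageVersion("hippsplit")),
    command = command,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = list(...)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
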
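# Builders for the five hippocampal architecture variants. Every network has
# a posterior (object-dominated) and an anterior (context-dominated) side;
# "crossconnections" are MEC input to the posterior side and LEC input to
# the anterior side, carried as relative weight multipliers.

#' Names of the five architecture variants
#' @return Character vector.
#' @export
variant_names <- function() {
  c("Baseline", "SplitDG", "AllSplit", "SplitDGplus", "AllSplitplus")
}

#' Default architecture configuration for a variant
#'
#' Encodes the standard layer sizes, activity fractions and crossconnection
#' multiplier tables: entorhinal input layers of 64 units at 25% activity;
#' per side a dentate gyrus of 800 units at 1.5% (split variants: two
#' 400-unit blades), CA3 of 256 units at 2.3% (AllSplit: two 128-unit
#' regions), and two 400-unit CA1 subregions at 2.5%; output layers at 25%
#' activity. The "+" variants double the split DG blades (SplitDGplus) and
#' additionally the split CA3 regions (AllSplitplus). Mossy-fiber
#' projections are 10 times stronger than the entorhinal perforant-path
#' input. Posterior crossconnections: uniform 1.5 for Baseline; for split
#' variants 3.0 into the object-stream DG blade (and object-stream CA3
#' region in AllSplit) and 0.05 into the context-guess stream's blade / CA3
#' region / proximal CA1, with SplitDG's single shared CA3 keeping 1.5. The
#' anterior side uses one shared LEC multiplier for all variants.
#'
#' @param variant One of `"Baseline"`, `"SplitDG"`, `"AllSplit"`,
#'   `"SplitDGplus"`, `"AllSplitplus"`.
#' @param posterior_multiplier Optional single value overriding every
#'   posterior (MEC-side) crossconnection multiplier; used by the
#'   calibration sweep.
#' @param anterior_multiplier Shared LEC multiplier into the anterior side.
#'   The default 0.05 is the argmin of the context-stream sample-task sweep
#'   (see the methods vignette).
#' @param posterior_ca3 Optional posterior CA3 size override (layer-size
#'   sweep); only meaningful for unsplit-CA3 variants.
#' @param mossy_multiplier,primary_multiplier,recurrent_multiplier Relative
#'   strengths of the mossy-fiber, primary entorhinal and CA3 recurrent
#'   projections.
#' @param output_feedback Relative strength of the output-to-CA1 return
#'   projections that carry target information into the hidden layers
#'   during the plus phase. Kept below the feedforward strength so the
#'   CA1/output attractor loops settle rather than oscillate.
#' @param objects_per_context Slot count of the context-based object-guess
#'   output layer.
#' @return An `architecture_config` list.
#' @export
default_config <- function(variant = variant_names(),
                           posterior_multiplier = NULL,
                           anterior_multiplier = 0.05,
                           posterior_ca3 = NULL,
                           mossy_multiplier = 10,
                           primary_multiplier = 1,
                           recurrent_multiplier = 1,
                           output_feedback = 0.25,
                           objects_per_context = 3L) {
  variant <- match.arg(variant)
  split_dg <- variant != "Baseline"
  split_ca3 <- variant %in% c("AllSplit", "AllSplitplus")
  plus <- variant %in% c("SplitDGplus", "AllSplitplus")
  blade <- if (plus) 800L else 400L
  ca3 <- if (!split_ca3) 256L else if (plus) 256L else 128L
  sizes <- list(
    ec = 64L,
    dg = 800L,           # unsplit DG (Baseline)
    dg_blade = blade,    # per blade when split
    ca3 = ca3,           # per CA3 region
    ca1 = 400L,          # per CA1 subregion
    out = 64L,
    cbog = 64L * as.integer(objects_per_context)
  )
  if (!is.null(posterior_ca3)) {
    if (split_ca3) {
      stop("posterior CA3 size override applies to unsplit-CA3 variants",
           call. = FALSE)
    }
    sizes$ca3_post <- as.integer(posterior_ca3)
  }
  activity <- list(ec = 0.25, dg = 0.015, ca3 = 0.023, ca1 = 0.025,
                   out = 0.25)
  posterior <- if (!split_dg) {
    c(dg = 1.5, ca3 = 1.5, ca1p = 1.5)
  } else if (!split_ca3) {
    c(dg_inferior = 3, dg_superior = 0.05, ca3 = 1.5, ca1p = 0.05)
  } else {
    c(dg_inferior = 3, dg_superior = 0.05, ca3_proximal = 3,
      ca3_distal = 0.05, ca1p = 0.05)
  }
  if (!is.null(posterior_multiplier)) {
    stopifnot(posterior_multiplier >= 0)
    posterior[] <- posterior_multiplier
  }
  stopifnot(anterior_multiplier >= 0, mossy_multiplier >= 0,
            primary_multiplier >= 0, recurrent_multiplier >= 0,
            output_feedback >= 0)
  structure(
    list(variant = variant, split_dg = split_dg, split_ca3 = split_ca3,
         plus = plus, sizes = sizes, activity = activity,
         cross = list(posterior = posterior,
                      anterior = anterior_multiplier),
         mossy = mossy_multiplier, primary = primary_multiplier,
         recurrent = recurrent_multiplier, output_feedback = output_feedback,
         objects_per_context = as.integer(objects_per_context)),
    class = "architecture_config"
  )
}

#' Output-stream wiring map
#'
#' The canonical assignment of each output to its CA1 subregion, upstream
#' CA3 region and DG blade: the object guess leaves by posterior distal CA1
#' fed by proximal CA3 and the inferior blade; the object-based context
#' guess by posterior proximal CA1 fed by distal CA3 and the superior blade;
#' the anterior side mirrors this for the context-based object guess (distal
#' CA1) and the context guess (proximal CA1).
#'
#' @return A tibble with one row per output stream.
#' @export
stream_map <- function() {
  tibble::tibble(
    output = c("O", "OBCG", "CBOG", "C"),
    side = c("post", "post", "ant", "ant"),
    ca1 = c("CA1d_post", "CA1p_post", "CA1d_ant", "CA1p_ant"),
    ca3 = c("CA3prox_post", "CA3dist_post", "CA3prox_ant", "CA3dist_ant"),
    blade = c("DGinf_post", "DGsup_post", "DGinf_ant", "DGsup_ant")
  )
}

# layer names on one side under a config
side_layers_ <- function(cfg, side) {
  dg <- if (cfg$split_dg) paste0(c("DGsup_", "DGinf_"), side)
        else paste0("DG_", side)
  ca3 <- if (cfg$split_ca3) paste0(c("CA3prox_", "CA3dist_"), side)
         else paste0("CA3_", side)
  list(dg = dg, ca3 = ca3,
       ca1d = paste0("CA1d_", side), ca1p = paste0("CA1p_", side))
}

#' Build the network specification for an architecture
#'
#' Emits the layers and projections realising a configured variant: both
#' entorhinal layers project to DG, CA3 and CA1 on both sides (with the
#' configured crossconnection multipliers on the non-dominant side);
#' mossy-fiber DG to CA3 projections at the mossy multiplier (in AllSplit
#' the inferior blade reaches only proximal CA3 and the superior blade only
#' distal CA3); recurrent CA3 collaterals; proximal CA3 to distal CA1 and
#' distal CA3 to proximal CA1; distal CA1 receives LEC and proximal CA1
#' receives MEC; and each CA1 subregion is bidirectionally coupled to its
#' output layer per [stream_map()].
#'
#' @param cfg An [default_config()] object (or a variant name).
#' @return A [network_spec()].
#' @export
build_network <- function(cfg) {
  if (is.character(cfg)) cfg <- default_config(cfg)
  stopifnot(inherits(cfg, "architecture_config"))
  sz <- cfg$sizes
  ac <- cfg$activity

  ca3_size <- function(side) {
    if (side == "post" && !is.null(sz$ca3_post)) sz$ca3_post else sz$ca3
  }
  layers <- list(
    layer_spec("LEC", sz$ec, ac$ec, clampable = TRUE),
    layer_spec("MEC", sz$ec, ac$ec, clampable = TRUE)
  )
  projections <- list()
  add_proj <- function(...) {
    projections[[length(projections) + 1L]] <<- projection_spec(...)
  }

  for (side in c("post", "ant")) {
    L <- side_layers_(cfg, side)
    primary <- if (side == "post") "LEC" else "MEC"
    crossec <- if (side == "post") "MEC" else "LEC"
    cross_of <- function(region) {
      if (side == "ant") return(cfg$cross$anterior)
      unname(cfg$cross$posterior[[region]])
    }
    dg_size <- if (cfg$split_dg) sz$dg_blade else sz$dg
    for (dg in L$dg) {
      layers[[length(layers) + 1L]] <- layer_spec(dg, dg_size, ac$dg)
      region <- if (!cfg$split_dg) "dg"
                else if (grepl("^DGinf", dg)) "dg_inferior" else "dg_superior"
      add_proj(primary, dg, cfg$primary)
      add_proj(crossec, dg, cross_of(region))
    }
    for (ca3 in L$ca3) {
      layers[[length(layers) + 1L]] <- layer_spec(ca3, ca3_size(side), ac$ca3)
      region <- if (!cfg$split_ca3) "ca3"
                else if (grepl("^CA3prox", ca3)) "ca3_proximal"
                else "ca3_distal"
      add_proj(primary, ca3, cfg$primary)
      add_proj(crossec, ca3, cross_of(region))
      add_proj(ca3, ca3, cfg$recurrent)
    }
    # mossy fibers: blade-specific in split-CA3 variants
    if (cfg$split_ca3) {
      add_proj(paste0("DGinf_", side), paste0("CA3prox_", side), cfg$mossy)
      add_proj(paste0("DGsup_", side), paste0("CA3dist_", side), cfg$mossy)
    } else {
      for (dg in L$dg) add_proj(dg, L$ca3, cfg$mossy)
    }
    # CA3 -> CA1 (proximal CA3 to distal CA1 and vice versa)
    layers[[length(layers) + 1L]] <- layer_spec(L$ca1d, sz$ca1, ac$ca1)
    layers[[length(layers) + 1L]] <- layer_spec(L$ca1p, sz$ca1, ac$ca1)
    if (cfg$split_ca3) {
      add_proj(paste0("CA3prox_", side), L$ca1d, 1)
      add_proj(paste0("CA3dist_", side), L$ca1p, 1)
    } else {
      add_proj(L$ca3, L$ca1d, 1)
      add_proj(L$ca3, L$ca1p, 1)
    }
    # entorhinal input to CA1: LEC to distal, MEC to proximal
    lec_rel <- if (side == "post") cfg$primary else cross_of("ca1d")
    mec_rel <- if (side == "post") cross_of("ca1p") else cfg$primary
    add_proj("LEC", L$ca1d, lec_rel)
    add_proj("MEC", L$ca1p, mec_rel)
  }
  # output layers, bidirectionally coupled to their CA1 subregion
  layers <- c(layers, list(
    layer_spec("O", sz$out, ac$out, clampable = TRUE),
    layer_spec("OBCG", sz$out, ac$out, clampable = TRUE),
    layer_spec("CBOG", sz$cbog, ac$out, clampable = TRUE),
    layer_spec("C", sz$out, ac$out, clampable = TRUE)
  ))
  for (i in seq_len(nrow(stream_map()))) {
    sm <- stream_map()[i, ]
    add_proj(sm$ca1, sm$output, 1)
    add_proj(sm$output, sm$ca1, cfg$output_feedback)
  }

  network_spec(cfg$variant, dplyr::bind_rows(layers),
               dplyr::bind_rows(projections))
}

#' Audit a network specification against the canonical wiring rules
#'
#' Report-based check of the output-stream wiring (each output coupled to
#' exactly its designated CA1 subregion), the blade-to-CA3 routing of
#' split-CA3 variants, the entorhinal CA1 rule (distal CA1 receives LEC,
#' proximal receives MEC), the presence of mossy and recurrent projections,
#' and the expected layer set for the variant.
#'
#' @param spec A [network_spec()].
#' @return A tibble of violations (zero rows when the spec is clean).
#' @export
validate_spec <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  pr <- spec$projections
  ly <- spec$layers
  bad <- list()
  note <- function(check, detail) {
    bad[[length(bad) + 1L]] <<- tibble::tibble(check = check,
                                               detail = detail)
  }
  sm <- stream_map()
  ca1 <- unique(sm$ca1)
  for (i in seq_len(nrow(sm))) {
    out <- sm$output[i]
    senders <- pr$source[pr$target == out]
    wrong <- setdiff(intersect(senders, ca1), sm$ca1[i])
    if (length(wrong) > 0) {
      note("stream_map", paste0(out, " receives CA1 input from ",
                                paste(wrong, collapse = ", ")))
    }
    if (!sm$ca1[i] %in% senders) {
      note("stream_map", paste0(out, " not driven by ", sm$ca1[i]))
    }
  }
  # split-CA3 blade routing
  for (side in c("post", "ant")) {
    prox <- paste0("CA3prox_", side)
    if (prox %in% ly$name) {
      if (any(pr$source == paste0("DGsup_", side) & pr$target == prox)) {
        note("blade_routing",
             paste0("superior blade projects to ", prox))
      }
      if (any(pr$source == paste0("DGinf_", side) &
              pr$target == paste0("CA3dist_", side))) {
        note("blade_routing",
             paste0("inferior blade projects to CA3dist_", side))
      }
    }
    # entorhinal CA1 rule
    if (any(pr$source == "MEC" & pr$target == paste0("CA1d_", side))) {
      note("ec_ca1", paste0("MEC projects to distal CA1 (", side, ")"))
    }
    if (any(pr$source == "LEC" & pr$target == paste0("CA1p_", side))) {
      note("ec_ca1", paste0("LEC projects to proximal CA1 (", side, ")"))
    }
    # mossy + recurrent presence
    dg <- ly$name[grepl(paste0("^DG.*_", side, "$"), ly$name)]
    ca3s <- ly$name[grepl(paste0("^CA3.*_", side, "$"), ly$name)]
    for (r in ca3s) {
      if (!any(pr$source == r & pr$target == r)) {
        note("recurrent", paste0(r, " has no recurrent projection"))
      }
      if (!any(pr$source %in% dg & pr$target == r)) {
        note("mossy", paste0(r, " receives no mossy-fiber input"))
      }
    }
  }
  # expected layer roster for the named variant
  if (spec$variant %in% variant_names()) {
    cfg <- default_config(spec$variant)
    expected <- unlist(lapply(c("post", "ant"), function(s) {
      L <- side_layers_(cfg, s)
      c(L$dg, L$ca3, L$ca1d, L$ca1p)
    }))
    expected <- c("LEC", "MEC", expected, "O", "OBCG", "CBOG", "C")
    extra <- setdiff(ly$name, expected)
    miss <- setdiff(expected, ly$name)
    if (length(extra) > 0) {
      note("layers", paste0("unexpected layer(s): ",
                            paste(extra, collapse = ", ")))
    }
    if (length(miss) > 0) {
      note("layers", paste0("missing layer(s): ",
                            paste(miss, collapse = ", ")))
    }
  }
  if (length(bad) == 0) {
    tibble::tibble(check = character(), detail = character())
  } else {
    dplyr::bind_rows(bad)
  }
}

#' Layer and projection tables of a variant
#'
#' @param x A variant name, [default_config()] or [network_spec()].
#' @param path Optional directory; when given, writes `layers.csv` and
#'   `projections.csv` there.
#' @return A list with tibbles `layers` and `projections`.
#' @export
describe_network <- function(x, path = NULL) {
  spec <- if (inherits(x, "network_spec")) x else build_network(x)
  out <- list(layers = spec$layers, projections = spec$projections)
  if (!is.null(path)) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$layers, file.path(path, "layers.csv"),
                     row.names = FALSE)
    utils::write.csv(out$projections, file.path(path, "projections.csv"),
                     row.names = FALSE)
  }
  out
}
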
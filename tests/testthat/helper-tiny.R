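# Small association world and a down-scaled two-sided network with the
# canonical layer names, for fast engine tests.

tiny_world <- function(seed = 42) {
  build_association_set(n_contexts = 4, objects_per_context = 3,
                        n_units = 16, n_active = 4, seed = seed)
}

tiny_spec <- function(mossy = 10, feedback = 0.25) {
  layers <- dplyr::bind_rows(
    layer_spec("LEC", 16, 0.25, clampable = TRUE),
    layer_spec("MEC", 16, 0.25, clampable = TRUE),
    layer_spec("DG_post", 40, 0.05),
    layer_spec("CA3_post", 20, 0.1),
    layer_spec("CA1d_post", 20, 0.1),
    layer_spec("CA1p_post", 20, 0.1),
    layer_spec("DG_ant", 40, 0.05),
    layer_spec("CA3_ant", 20, 0.1),
    layer_spec("CA1d_ant", 20, 0.1),
    layer_spec("CA1p_ant", 20, 0.1),
    layer_spec("O", 16, 0.25, clampable = TRUE),
    layer_spec("OBCG", 16, 0.25, clampable = TRUE),
    layer_spec("CBOG", 48, 0.25, clampable = TRUE),
    layer_spec("C", 16, 0.25, clampable = TRUE)
  )
  pr <- list()
  for (side in c("post", "ant")) {
    dg <- paste0("DG_", side)
    ca3 <- paste0("CA3_", side)
    ca1d <- paste0("CA1d_", side)
    ca1p <- paste0("CA1p_", side)
    pr <- c(pr, list(
      projection_spec("LEC", dg), projection_spec("MEC", dg),
      projection_spec("LEC", ca3), projection_spec("MEC", ca3),
      projection_spec(dg, ca3, mossy), projection_spec(ca3, ca3),
      projection_spec(ca3, ca1d), projection_spec(ca3, ca1p),
      projection_spec("LEC", ca1d), projection_spec("MEC", ca1p)
    ))
  }
  pr <- c(pr, list(
    projection_spec("CA1d_post", "O"), projection_spec("O", "CA1d_post", feedback),
    projection_spec("CA1p_post", "OBCG"), projection_spec("OBCG", "CA1p_post", feedback),
    projection_spec("CA1d_ant", "CBOG"), projection_spec("CBOG", "CA1d_ant", feedback),
    projection_spec("CA1p_ant", "C"), projection_spec("C", "CA1p_ant", feedback)
  ))
  network_spec("tiny", layers, dplyr::bind_rows(pr))
}

# fast settle configuration for tiny networks
tiny_settle <- function() settle_config(max_cycles = 60)

layer_index_tst <- function(state, layer) {
  off <- state$offsets[[layer]]
  seq.int(off + 1L, off + state$sizes[[layer]])
}

hash_weights <- function(state) {
  sum(vapply(state$W, function(w) sum(w * seq_along(w)), numeric(1)))
}
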
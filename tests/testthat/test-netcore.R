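# Engine: kWTA, settling, phases, learning rule, readout.

test_that("kWTA threshold sits between the k-th and (k+1)-th drives", {
  expect_equal(kwta_threshold(c(0.9, 0.5, 0.1, 0), 2), 0.3, tolerance = 1e-6)
  d <- c(0.9, 0.5, 0.1, 0)
  expect_gt(kwta_threshold(d, 0), max(d))
  expect_lt(kwta_threshold(d, 4), min(d))
  expect_error(kwta_threshold(d, 5), "k must be")
})

test_that("kWTA ties resolve to the lowest indices, exactly k winners", {
  d <- rep(1, 6)
  for (k in 0:6) {
    thr <- kwta_threshold(d, k)
    winners <- which(d - seq_along(d) * 1e-9 > thr)
    expect_identical(winners, seq_len(k) + 0L)
  }
  # random drives: always exactly k strictly above threshold
  set.seed(1)
  for (rep in 1:20) {
    d <- sample(round(runif(50), 2))  # coarse values force ties
    k <- sample(0:50, 1)
    thr <- kwta_threshold(d, k)
    expect_equal(sum(d - seq_along(d) * 1e-9 > thr), k)
  }
})

test_that("weights initialise uniformly in [0.25, 0.75] and deterministically", {
  spec <- tiny_spec()
  st <- init_network(spec, seed = 1)
  expect_setequal(names(st$W), spec$projections$id)
  rng <- range(unlist(lapply(st$W, range)))
  expect_gte(rng[1], 0.25)
  expect_lte(rng[2], 0.75)
  st2 <- init_network(spec, seed = 1)
  expect_identical(st$W, st2$W)
  st3 <- init_network(spec, seed = 2)
  expect_false(identical(st$W, st3$W))
})

test_that("a projection to a missing layer is rejected", {
  expect_error(
    network_spec("bad", layer_spec("A", 4, 0.5),
                 projection_spec("A", "nowhere")),
    "missing layer"
  )
})

test_that("net input is linear in the relative weight and normalized by sender count", {
  spec <- network_spec(
    "probe",
    dplyr::bind_rows(layer_spec("IN", 8, 0.5, clampable = TRUE),
                     layer_spec("IN2", 8, 0.5, clampable = TRUE),
                     layer_spec("HID", 6, 0.5)),
    dplyr::bind_rows(projection_spec("IN", "HID", rel_weight = 10),
                     projection_spec("IN2", "HID", rel_weight = 1))
  )
  st <- init_network(spec, seed = 1)
  expect_equal(net_input(st, "HID"), numeric(6))  # all senders silent
  # fixed weights isolate the scaling: equal sender statistics, rel 10 vs 1
  st$W[["IN->HID"]][] <- 0.5
  st$W[["IN2->HID"]][] <- 0.5
  st$acts[layer_index_tst(st, "IN")] <- rep(c(1, 0), each = 4)
  d1 <- net_input(st, "HID")
  st$acts[] <- 0
  st$acts[layer_index_tst(st, "IN2")] <- rep(c(1, 0), each = 4)
  d2 <- net_input(st, "HID")
  # identical sender statistics, rel_weights 10 vs 1
  expect_equal(d1 / d2, rep(10, 6))
  # doubling rel_weight doubles the drive
  st$pscale <- st$pscale * 2
  expect_equal(net_input(st, "HID"), 2 * d2)
})

test_that("settling respects clamps and realizes the layer activity levels", {
  spec <- tiny_spec()
  st <- init_network(spec, seed = 1)
  w <- tiny_world()
  tr <- training_trials(w)
  out <- settle(st, list(LEC = tr$lec[[1]], MEC = tr$mec[[1]]), tiny_settle())
  expect_true(attr(out, "converged"))
  expect_equal(out$LEC, as.numeric(tr$lec[[1]]))  # clamp overrides drive
  # exactly k units strictly above the kWTA threshold of the settled drive
  for (layer in c("DG_post", "CA3_ant", "CA1d_post")) {
    k <- st$kvec[[layer]]
    d <- net_input(st, layer)
    thr <- kwta_threshold(d, k)
    expect_equal(sum(d - seq_along(d) * 1e-9 > thr), k)
    expect_lte(sum(out[[layer]] > 1e-3), k)
  }
  expect_error(settle(st, list(DG_post = rep(1, 40))), "not clampable")
})

test_that("full-size dentate gyrus realizes 12 winners of 800 at 1.5% activity", {
  spec <- build_network(default_config("Baseline"))
  expect_equal(spec$layers$k[spec$layers$name == "DG_post"], 12L)
  st <- init_network(spec, seed = 2)
  w <- build_association_set(seed = 2)
  tr <- training_trials(w)
  settle(st, list(LEC = tr$lec[[1]], MEC = tr$mec[[1]]))
  d <- net_input(st, "DG_post")
  thr <- kwta_threshold(d, 12)
  expect_equal(sum(d - seq_along(d) * 1e-9 > thr), 12)
})

test_that("two-phase trials clamp targets in the plus phase only", {
  spec <- tiny_spec()
  st <- init_network(spec, seed = 3)
  w <- tiny_world()
  tr <- training_trials(w)
  ph <- run_trial(st, tr[1, ], tiny_settle())
  oi <- layer_index_tst(st, "O")
  expect_equal(ph$plus[oi], as.numeric(tr$target_O[[1]]))
  ci <- layer_index_tst(st, "CBOG")
  expect_equal(ph$plus[ci], as.numeric(tr$target_CBOG[[1]]))
  # minus phase leaves outputs free: untrained recall differs from target
  expect_false(isTRUE(all.equal(ph$minus[oi], as.numeric(tr$target_O[[1]]))))
  # determinism: identical state and trial give identical phases
  st2 <- init_network(spec, seed = 3)
  ph2 <- run_trial(st2, tr[1, ], tiny_settle())
  expect_identical(ph, ph2)
})

test_that("contrastive Hebbian update follows the formula with soft bounding", {
  spec <- network_spec(
    "pair",
    dplyr::bind_rows(layer_spec("A", 1, 1, clampable = TRUE),
                     layer_spec("B", 1, 1, clampable = TRUE)),
    projection_spec("A", "B")
  )
  mkphase <- function(xm, xp, ym, yp) {
    structure(list(minus = c(xm, ym), plus = c(xp, yp)),
              class = "phase_pair")
  }
  cfg <- learning_config(rate = 0.1, hebb = 0)
  st <- init_network(spec, seed = 1)
  # x-y- = 0, x+ = y+ = 1, w = 0: dw = +rate * (1 - w) = +0.1
  st$W[[1]][] <- 0
  chl_update(st, mkphase(0, 1, 0, 1), cfg)
  expect_equal(st$W[[1]][1, 1], 0.1)
  # x+y+ = 0, x- = y- = 1, w = 1: dw = -rate * w = -0.1
  st$W[[1]][] <- 1
  chl_update(st, mkphase(1, 0, 1, 0), cfg)
  expect_equal(st$W[[1]][1, 1], 0.9)
  # minus == plus is a fixed point at hebb = 0
  st$W[[1]][] <- 0.37
  chl_update(st, mkphase(0.6, 0.6, 0.8, 0.8), cfg)
  expect_equal(st$W[[1]][1, 1], 0.37)
  # without soft bounding the raw formula applies
  st$W[[1]][] <- 0.5
  chl_update(st, mkphase(0, 1, 0, 1),
             learning_config(rate = 0.1, hebb = 0, soft_bound = FALSE))
  expect_equal(st$W[[1]][1, 1], 0.6)
})

test_that("weights stay in [0, 1] over many random updates", {
  spec <- network_spec(
    "pair",
    dplyr::bind_rows(layer_spec("A", 8, 0.5, clampable = TRUE),
                     layer_spec("B", 8, 0.5, clampable = TRUE)),
    projection_spec("A", "B")
  )
  st <- init_network(spec, seed = 1)
  cfg <- learning_config(rate = 0.5, hebb = 0.2)
  set.seed(99)
  for (i in 1:10000) {
    ph <- structure(list(minus = runif(16), plus = runif(16)),
                    class = "phase_pair")
    chl_update(st, ph, cfg)
  }
  expect_gte(min(st$W[[1]]), 0)
  expect_lte(max(st$W[[1]]), 1)
})

test_that("binarize keeps the top-m units with index tie-breaking", {
  expect_equal(binarize(c(0.2, 0.9, 0.9, 0.1), 2), c(0L, 1L, 1L, 0L))
  expect_equal(binarize(c(0.5, 0.5, 0.5), 2), c(1L, 1L, 0L))
  expect_equal(binarize(c(0.3, 0.1), 0), c(0L, 0L))
  tgt <- c(1L, 0L, 1L, 0L)
  expect_equal(binarize(c(5, 1, 4, 0), sum(tgt)), tgt)
})

test_that("output error is the normalized miss rate", {
  tgt <- rep(c(1L, 0L), c(16, 48))
  expect_equal(output_error(as.numeric(tgt), tgt), 0)
  expect_equal(output_error(rev(as.numeric(tgt)), tgt), 1)
  act <- as.numeric(tgt)
  act[1:4] <- 0            # demote 4 of 16 target units
  act[17:20] <- 0.5        # and promote 4 others
  expect_equal(output_error(act, tgt), 0.25)
  expect_error(output_error(act, integer(64)), "no active units")
  expect_error(output_error(act, tgt[1:10]), "length mismatch")
})

test_that("doubling every relative weight leaves winner sets unchanged", {
  spec <- tiny_spec()
  st <- init_network(spec, seed = 5)
  w <- tiny_world()
  tr <- training_trials(w)
  out1 <- settle(st, list(LEC = tr$lec[[2]], MEC = tr$mec[[2]]), tiny_settle())
  st2 <- init_network(spec, seed = 5)
  st2$pscale <- st2$pscale * 2
  out2 <- settle(st2, list(LEC = tr$lec[[2]], MEC = tr$mec[[2]]), tiny_settle())
  for (layer in c("DG_post", "CA3_post", "CA1d_ant", "O")) {
    expect_identical(which(out1[[layer]] > 1e-3), which(out2[[layer]] > 1e-3))
  }
})
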
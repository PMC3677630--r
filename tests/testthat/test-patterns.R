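# Synthetic world generator and corruption operators.

test_that("generated patterns have exactly the requested number of active units", {
  p <- generate_pattern(64, 16, seed = 1)
  expect_length(p, 64)
  expect_equal(sum(p), 16)
  expect_true(all(p %in% c(0L, 1L)))
  expect_equal(sum(generate_pattern(64, 0, seed = 1)), 0)
  expect_equal(sum(generate_pattern(64, 64, seed = 1)), 64)
  expect_error(generate_pattern(64, 65), "n_active")
})

test_that("association world has the standard composition and all patterns distinct", {
  w <- build_association_set(seed = 3)
  expect_equal(nrow(w$objects), 120)
  expect_equal(nrow(w$contexts), 40)
  expect_equal(w$objects_per_context, 3)
  expect_true(all(table(w$context_of) == 3))
  expect_true(all(rowSums(w$objects) == 16))
  expect_true(all(rowSums(w$contexts) == 16))
  # brute-force pairwise distinctness over all 160 patterns
  keys <- apply(rbind(w$objects, w$contexts), 1, paste, collapse = "")
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("world generation is deterministic, handles degenerate and infeasible inputs", {
  w1 <- build_association_set(seed = 11)
  w2 <- build_association_set(seed = 11)
  expect_identical(w1, w2)
  one <- build_association_set(n_contexts = 1, objects_per_context = 3,
                               seed = 2)
  expect_equal(one$context_of, c(1L, 1L, 1L))
  # choose(4, 2) = 6 distinct patterns < 9 requested
  expect_error(
    build_association_set(n_contexts = 3, objects_per_context = 2,
                          n_units = 4, n_active = 2, seed = 1),
    "distinct"
  )
})

test_that("targets are keyed to trained vs presented context as appropriate", {
  w <- build_association_set(seed = 5)
  o <- 7L
  trained <- w$context_of[o]
  tg <- make_targets(o, trained, w)
  expect_equal(tg$O, w$objects[o, ])
  expect_identical(tg$OBCG, tg$C)  # matched trial
  # mismatch: OBCG follows the trained context, C and CBOG the presented one
  other <- if (trained == 1) 2L else 1L
  tg2 <- make_targets(o, other, w)
  expect_equal(tg2$OBCG, w$contexts[trained, ])
  expect_equal(tg2$C, w$contexts[other, ])
  members <- which(w$context_of == other)  # ascending id order
  expect_equal(tg2$CBOG, as.integer(t(w$objects[members, ])))
  expect_length(tg2$CBOG, 192)
  expect_equal(sum(tg2$CBOG), 48)
  expect_error(make_targets(500, 1, w), "unknown object")
  expect_error(make_targets(1, 500, w), "unknown context")
})

test_that("corruption modes change exactly the contracted number of units", {
  p <- generate_pattern(seed = 9)
  add <- corrupt(p, corruption_spec("additive", 0.3), seed = 1)
  expect_equal(sum(add), 21)            # round(0.3 * 16) = 5 added
  expect_true(all(add[p == 1L] == 1L))  # originals kept
  non <- corrupt(p, corruption_spec("nonadditive", 0.3), seed = 1)
  expect_equal(sum(non), 16)
  expect_equal(sum(non != p), 10)       # 5 swaps each direction
  part <- corrupt(p, corruption_spec("partial", 0.4), seed = 1)
  expect_equal(sum(part), 6)            # 40% complete
  expect_true(all(p[part == 1L] == 1L))
  mix <- corrupt(p, corruption_spec("mixed", 0.15), seed = 1)
  expect_equal(sum(mix), 17)            # n=2: 1 additive + 1 swap
  expect_equal(sum(mix != p), 3)
})

test_that("identity levels and error paths of corruption", {
  p <- generate_pattern(seed = 2)
  for (m in c("additive", "nonadditive", "mixed")) {
    expect_identical(corrupt(p, corruption_spec(m, 0), seed = 1), p)
  }
  expect_identical(corrupt(p, corruption_spec("partial", 1), seed = 1), p)
  expect_error(corruption_spec("additive", 1.2), "level")
  expect_error(corruption_spec("bogus", 0.1))
  full <- rep(1L, 8)
  expect_error(corrupt(full, corruption_spec("additive", 0.5)), "inactive")
  empty <- rep(0L, 8)
  expect_error(corrupt(empty, corruption_spec("partial", 0.5)), "active")
})

test_that("corruption count contracts hold across modes, levels and bases", {
  set.seed(7)
  for (rep in 1:5) {
    p <- generate_pattern(64, 16)
    for (lv in c(0, 0.1, 0.25, 0.5, 0.75, 1)) {
      n <- round(lv * 16)  # .5 cases in this grid are exact either way
      expect_equal(sum(corrupt(p, corruption_spec("additive", lv))), 16 + n)
      expect_equal(sum(corrupt(p, corruption_spec("nonadditive", lv))), 16)
      expect_equal(sum(corrupt(p, corruption_spec("partial", lv))), n)
      expect_equal(sum(corrupt(p, corruption_spec("mixed", lv))),
                   16 + ceiling(n / 2))
    }
    tot <- corrupt(p, corruption_spec("additive", 0.25, basis = "total_units"))
    expect_equal(sum(tot), 16 + 16)  # round(0.25 * 64)
  }
})

test_that("mismatch battery is a derangement of trained contexts", {
  w <- build_association_set(seed = 4)
  tr <- build_test_battery(w, "mismatch", seed = 8)
  expect_equal(nrow(tr), 120)
  expect_true(all(tr$context_id != w$context_of[tr$object_id]))
  expect_true(all(tr$mismatch))
})

test_that("level-1 partial battery reproduces the clean training trials", {
  w <- build_association_set(seed = 4)
  tr <- build_test_battery(w, "partial_context", levels = 1, seed = 8)
  clean <- training_trials(w)
  expect_equal(tr$lec, clean$lec)
  expect_equal(tr$mec, clean$mec)
  expect_equal(tr$target_O, clean$target_O)
})

test_that("context-only battery clamps the object input to zero", {
  w <- build_association_set(seed = 4)
  tr <- build_test_battery(w, "cbog_context_only", seed = 8)
  expect_true(all(vapply(tr$lec, sum, numeric(1)) == 0))
  expect_true(all(vapply(tr$mec, sum, numeric(1)) == 16))
  expect_false(any(tr$mismatch))
})

test_that("sample batteries implement the calibration designs", {
  w <- build_association_set(seed = 4)
  oc <- build_test_battery(w, "sample_O_C", seed = 8)
  expect_equal(nrow(oc), 240)
  expect_setequal(unique(oc$tag), c("mixed_noise_15", "partial_40"))
  mixed <- oc[oc$tag == "mixed_noise_15", ]
  expect_true(all(vapply(mixed$lec, sum, numeric(1)) == 17))  # 16 + ceil(2/2)
  expect_true(all(vapply(mixed$mec, sum, numeric(1)) == 17))
  part <- oc[oc$tag == "partial_40", ]
  expect_true(all(vapply(part$lec, sum, numeric(1)) == 6))
  expect_true(all(vapply(part$mec, sum, numeric(1)) == 6))

  ob <- build_test_battery(w, "sample_OBCG", seed = 8)
  expect_equal(nrow(ob), 360)
  expect_setequal(unique(ob$tag),
                  c("mismatch", "context_noise_30", "partial_context_40"))
  # degradation in the context input only
  noisy <- ob[ob$tag != "mismatch", ]
  expect_true(all(mapply(function(l, o) identical(l, w$objects[o, ]),
                         noisy$lec, noisy$object_id)))

  cb <- build_test_battery(w, "sample_CBOG", seed = 8)
  expect_setequal(unique(cb$tag),
                  c("mismatch", "object_noise_30", "partial_object_40"))
  noisy <- cb[cb$tag != "mismatch", ]
  expect_true(all(mapply(function(m, cx) identical(m, w$contexts[cx, ]),
                         noisy$mec, noisy$context_id)))

  expect_error(build_test_battery(w, "nope"), "unknown battery")
})

test_that("batteries are reproducible from their seed", {
  w <- build_association_set(seed = 4)
  a <- build_test_battery(w, "additive_object", levels = c(0.1, 0.3), seed = 5)
  b <- build_test_battery(w, "additive_object", levels = c(0.1, 0.3), seed = 5)
  expect_identical(a, b)
  expect_equal(nrow(a), 240)
})
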
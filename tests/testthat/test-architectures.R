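# Variant builders, multiplier tables and wiring audits.

test_that("Baseline defaults match the standard configuration", {
  cfg <- default_config("Baseline")
  expect_equal(cfg$sizes$ec, 64L)
  expect_equal(cfg$sizes$dg, 800L)
  expect_equal(cfg$sizes$ca3, 256L)
  expect_equal(cfg$sizes$ca1, 400L)
  expect_equal(cfg$sizes$cbog, 192L)
  expect_equal(unname(cfg$cross$posterior), rep(1.5, 3))
  expect_equal(cfg$mossy, 10)
  spec <- build_network(cfg)
  ly <- spec$layers
  # one DG, one CA3, two CA1 subregions per side
  expect_setequal(
    ly$name,
    c("LEC", "MEC", "DG_post", "CA3_post", "CA1d_post", "CA1p_post",
      "DG_ant", "CA3_ant", "CA1d_ant", "CA1p_ant", "O", "OBCG", "CBOG", "C")
  )
  # activity fractions realized as winner counts
  k <- stats::setNames(ly$k, ly$name)
  expect_equal(unname(k[c("LEC", "DG_post", "CA3_post", "CA1d_post",
                          "O", "CBOG")]),
               c(16L, 12L, 6L, 10L, 16L, 48L))
  pr <- spec$projections
  rel <- function(id) pr$rel_weight[pr$id == id]
  expect_equal(rel("MEC->DG_post"), 1.5)
  expect_equal(rel("MEC->CA3_post"), 1.5)
  expect_equal(rel("MEC->CA1p_post"), 1.5)
  expect_equal(rel("DG_post->CA3_post"), 10)
  expect_equal(rel("CA3_post->CA3_post"), 1)
  expect_equal(rel("LEC->DG_ant"), 0.05)
})

test_that("split variants route blades and CA3 subregions per the wiring rules", {
  spec <- build_network(default_config("AllSplit"))
  pr <- spec$projections
  has <- function(id) id %in% pr$id
  expect_true(has("DGinf_post->CA3prox_post"))
  expect_true(has("DGsup_post->CA3dist_post"))
  expect_false(has("DGinf_post->CA3dist_post"))
  expect_false(has("DGsup_post->CA3prox_post"))
  rel <- function(id) pr$rel_weight[pr$id == id]
  expect_equal(rel("MEC->DGinf_post"), 3)
  expect_equal(rel("MEC->DGsup_post"), 0.05)
  expect_equal(rel("MEC->CA3prox_post"), 3)
  expect_equal(rel("MEC->CA3dist_post"), 0.05)
  expect_equal(rel("MEC->CA1p_post"), 0.05)
  expect_equal(rel("DGinf_post->CA3prox_post"), 10)
  # O output is coupled to posterior distal CA1 only
  expect_identical(pr$source[pr$target == "O"], "CA1d_post")
  expect_identical(pr$target[pr$source == "O"], "CA1d_post")

  sdg <- build_network(default_config("SplitDG"))
  prs <- sdg$projections
  expect_equal(prs$rel_weight[prs$id == "MEC->CA3_post"], 1.5)  # shared CA3
  expect_equal(prs$rel_weight[prs$id == "MEC->DGinf_post"], 3)
  # both blades feed the single CA3
  expect_true(all(c("DGinf_post->CA3_post", "DGsup_post->CA3_post") %in%
                  prs$id))
})

test_that("the + variants only change layer sizes", {
  sdg <- default_config("SplitDG")
  sdgp <- default_config("SplitDGplus")
  expect_equal(sdgp$sizes$dg_blade, 800L)
  expect_equal(sdg$sizes$dg_blade, 400L)
  expect_equal(sdgp$sizes$ca3, sdg$sizes$ca3)
  expect_identical(sdgp$cross, sdg$cross)
  asp <- default_config("AllSplitplus")
  expect_equal(asp$sizes$ca3, 256L)
  expect_equal(default_config("AllSplit")$sizes$ca3, 128L)
  expect_error(default_config("Bogus"))
})

test_that("unit counts: equal-size group and the + increments check out", {
  total <- function(v) sum(build_network(default_config(v))$layers$size)
  expect_equal(total("Baseline"), total("SplitDG"))
  expect_equal(total("Baseline"), total("AllSplit"))
  # SplitDG+ doubles four 400-unit blades
  expect_equal(total("SplitDGplus") - total("SplitDG"), 4L * 400L)
  # AllSplit+ additionally doubles four 128-unit CA3 regions
  expect_equal(total("AllSplitplus") - total("AllSplit"),
               4L * 400L + 4L * 128L)
})

test_that("builders are pure and validate cleanly", {
  for (v in variant_names()) {
    s1 <- build_network(default_config(v))
    s2 <- build_network(default_config(v))
    expect_identical(s1, s2)
    expect_equal(nrow(validate_spec(s1)), 0)
  }
})

test_that("wiring audit reports violations", {
  spec <- build_network(default_config("Baseline"))
  spec$layers <- dplyr::bind_rows(spec$layers, layer_spec("DGsup_post", 400, 0.015))
  rep1 <- validate_spec(spec)
  expect_true(any(rep1$check == "layers" & grepl("DGsup_post", rep1$detail)))

  spec2 <- build_network(default_config("AllSplit"))
  spec2$projections <- dplyr::bind_rows(
    spec2$projections,
    dplyr::mutate(projection_spec("DGsup_post", "CA3prox_post", 10),
                  bidirectional = NULL, id = "DGsup_post->CA3prox_post")
  )
  rep2 <- validate_spec(spec2)
  expect_true(any(rep2$check == "blade_routing"))
})

test_that("posterior CA3 can be resized for the layer-size sweep", {
  spec <- build_network(default_config("Baseline", posterior_ca3 = 32))
  ly <- spec$layers
  expect_equal(ly$size[ly$name == "CA3_post"], 32L)
  expect_equal(ly$size[ly$name == "CA3_ant"], 256L)
  expect_equal(ly$k[ly$name == "CA3_post"], 1L)
  expect_error(default_config("AllSplit", posterior_ca3 = 32), "unsplit")
})

test_that("network description tables can be exported", {
  d <- describe_network("Baseline", path = file.path(tempdir(), "desc"))
  expect_true(file.exists(file.path(tempdir(), "desc", "layers.csv")))
  expect_true(file.exists(file.path(tempdir(), "desc", "projections.csv")))
  expect_setequal(names(d), c("layers", "projections"))
})
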
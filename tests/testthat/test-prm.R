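test_that("voxel classification reproduces the four-category threshold rule", {
  # emphysema: both low; fSAD: air trapping only; normal: both high;
  # uncategorized: low inspiration but normal expiration
  expect_identical(classify_prm(-960, -900), 1L)
  expect_identical(classify_prm(-940, -860), 2L)
  expect_identical(classify_prm(-940, -800), 3L)
  expect_identical(classify_prm(-960, -860), 1L)
  expect_identical(classify_prm(-960, -800), 4L)
  # threshold values themselves fall on the <= side of each half-plane
  expect_identical(classify_prm(-950, -856), 1L)
  expect_identical(classify_prm(-950, -855.999), 4L)
  expect_identical(classify_prm(-949.999, -856), 2L)
})

test_that("the four classes partition the HU plane", {
  g <- expand.grid(insp = seq(-1100, -500, by = 7), exp = seq(-1100, -500, by = 7))
  lab <- classify_prm(g$insp, g$exp)
  expect_true(all(lab %in% 1:4))
  # half-plane membership determines the class uniquely
  expected <- ifelse(g$exp <= -856, ifelse(g$insp <= -950, 1L, 2L),
                     ifelse(g$insp <= -950, 4L, 3L))
  expect_identical(lab, expected)
})

test_that("non-finite HU values are rejected", {
  expect_error(classify_prm(NA_real_, -900), "non-finite")
  expect_error(classify_prm(-900, Inf), "non-finite")
  expect_error(classify_prm(c(-900, -900), -900), "equal length")
})

test_that("zero-noise unwarped phantom is classified back exactly", {
  ph <- fixture_clean_phantom()
  m <- measure_prm(ph$study)
  expect_identical(as.integer(m$label_map), as.integer(ph$truth$label_map))
  # measured per-class voxel counts equal the generator's assignment counts
  measured <- table(factor(as.integer(m$label_map)[ph$study$lung_mask], levels = 1:4))
  expect_equal(as.numeric(measured), as.numeric(colSums(ph$truth$class_counts)))
})

test_that("lung volume converts voxel counts by the voxel volume", {
  d <- c(32, 32, 32)
  mask <- array(FALSE, d); mask[seq_len(1000)] <- TRUE
  insp <- array(-900, d); expv <- array(-700, d)
  map <- compute_prm_map(insp, expv, mask)
  lobe <- array(0L, d); lobe[mask] <- 1L
  p <- aggregate_prm_regions(map, lobe, spacing = c(1, 1, 1))
  expect_identical(unname(p["prm_whole_lv_ml"]), 1.0)
  # empty mask: all-zero map and zero lung volume
  map0 <- compute_prm_map(insp, expv, array(FALSE, d))
  expect_true(all(map0 == 0L))
  p0 <- aggregate_prm_regions(map0, lobe, spacing = c(1, 1, 1))
  expect_identical(unname(p0["prm_whole_lv_ml"]), 0)
})

test_that("aggregation conserves volumes and normalizes percentages", {
  ph <- generate_phantom_pair(phantom_config(dim = c(40, 40, 40), seed = 3,
                                             class_fractions = c(0.1, 0.2, 0.7, 0),
                                             spacing = c(1.2, 1.2, 1.8)))
  p <- measure_prm(ph$study)$parameters
  vox_ml <- prod(c(1.2, 1.2, 1.8)) / 1000
  for (r in prm_regions()) {
    vols <- p[paste0("prm_", r, "_", c("emph", "fsad", "normal", "uncat"), "_ml")]
    pcts <- p[paste0("prm_", r, "_", c("emph", "fsad", "normal", "uncat"), "_pct")]
    expect_lt(abs(sum(vols) - p[paste0("prm_", r, "_lv_ml")]), vox_ml + 1e-9)
    expect_lt(abs(sum(pcts) - 100), 1e-6)
  }
  expect_true(all(p >= 0))
  # whole = left + right = sum of lobes, to within one voxel volume
  expect_lt(abs(p["prm_whole_lv_ml"] - p["prm_left_lv_ml"] - p["prm_right_lv_ml"]), vox_ml)
  lobes_lv <- sum(p[paste0("prm_", c("rul", "rml", "rll", "lul", "lll"), "_lv_ml")])
  expect_lt(abs(p["prm_whole_lv_ml"] - lobes_lv), vox_ml)
  # measured per-lobe percentages equal the generator's assignment exactly
  counts <- ph$truth$class_counts
  for (l in 1:5) {
    r <- c("rul", "rml", "rll", "lul", "lll")[l]
    expect_equal(unname(p[paste0("prm_", r, "_fsad_pct")]),
                 100 * counts[l, "fsad"] / sum(counts[l, ]))
  }
})

test_that("raising the fSAD target fraction raises measured whole-lung fSAD%", {
  fr <- function(f) {
    rest <- (1 - f) * c(0.1, 0.8, 0.1) / 1
    c(rest[1], f, rest[2], rest[3])
  }
  vals <- vapply(c(0.1, 0.3, 0.5), function(f) {
    ph <- generate_phantom_pair(phantom_config(dim = c(40, 40, 40), seed = 5,
                                               class_fractions = fr(f)))
    measure_prm(ph$study)$parameters[["prm_whole_fsad_pct"]]
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("lung voxels without a lobe label count toward whole lung only", {
  d <- c(32, 32, 32)
  mask <- array(FALSE, d); mask[1:200] <- TRUE
  lobe <- array(0L, d); lobe[1:150] <- 1L   # 50 lung voxels uncovered
  insp <- array(-900, d); expv <- array(-700, d)
  map <- compute_prm_map(insp, expv, mask)
  expect_warning(p <- aggregate_prm_regions(map, lobe, c(1, 1, 1)), "no lobe label")
  expect_equal(unname(p["prm_whole_lv_ml"]), 200 / 1000)
  expect_equal(unname(p["prm_rul_lv_ml"]), 150 / 1000)
  # single populated lobe, all-normal: 100% normal there, others empty-flagged
  expect_equal(unname(p["prm_rul_normal_pct"]), 100)
  expect_setequal(attr(p, "empty_regions"), c("left", "rml", "rll", "lul", "lll"))
  expect_equal(unname(p["prm_lul_normal_pct"]), 0)
})

test_that("grid mismatches are input errors", {
  insp <- array(-900, c(32, 32, 32))
  expect_error(compute_prm_map(insp, array(-700, c(32, 32, 33)),
                               array(TRUE, c(32, 32, 32))), "grid")
  map <- compute_prm_map(insp, array(-700, c(32, 32, 32)), array(TRUE, c(32, 32, 32)))
  expect_error(aggregate_prm_regions(map, array(1L, c(32, 32, 33))), "grid")
})
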
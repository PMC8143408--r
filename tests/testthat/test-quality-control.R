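test_that("ILM indicator measures minimum edge strength", {
  # uniform volume: nothing to segment, indicator 0
  flat <- new_oct_volume(array(50, c(4, 4, 64)))
  seg_flat <- segment_volume(flat)
  expect_equal(ilm_indicator(flat, seg_flat), 0)

  # clean volume: indicator within a factor of 2 of contrast / 2
  map <- small_map(32)
  r <- render_oct_volume(map, seed = 1)
  seg <- segment_volume(r$volume)
  ind <- ilm_indicator(r$volume, seg)
  contrast <- 200 - 10
  expect_gt(ind, contrast / 4)
  expect_lt(ind, contrast)

  # blink: interpolated boundary crosses suppressed bands, indicator ~ 0
  rb <- render_oct_volume(map, blink_bscans = 6:8, seed = 1)
  segb <- segment_volume(rb$volume)
  expect_lt(ilm_indicator(rb$volume, segb), 1e-9)
})

test_that("valid count measures the unclipped fraction", {
  ok <- matrix(TRUE, 10, 10)
  surf <- new_boundary_surfaces(matrix(120, 10, 10), matrix(40, 10, 10),
                                ok, 256)
  expect_equal(valid_count(surf), 1.0)
  # clip 10% of A-scan columns via the renderer
  map <- small_map(20)
  rc <- render_oct_volume(map, clip_ascans = 1:2, seed = 1)
  expect_equal(valid_count(rc$truth), 0.9)
  # everything invalid
  none <- new_boundary_surfaces(matrix(NA_real_, 4, 4), matrix(NA_real_, 4, 4),
                                matrix(FALSE, 4, 4), 256)
  expect_equal(valid_count(none), 0.0)
})

test_that("motion indicators match closed-form Pearson results", {
  base <- matrix(rep(c(250, 255, 265, 280, 300, 330), 4), 4, 6, byrow = TRUE)
  # identical consecutive B-scans
  m <- motion_indicators(base)
  expect_equal(m$min_motion_correlation, 1.0)
  expect_equal(m$max_motion_delta, 0.0)
  expect_equal(m$max_motion_factor, 0.0)

  # constant +10 um shift: correlation stays 1, delta is exactly 10
  shifted <- base
  shifted[2, ] <- shifted[2, ] + 10
  m2 <- motion_indicators(shifted)
  expect_equal(m2$min_motion_correlation, 1.0)
  expect_equal(m2$max_motion_delta, 10.0)
  expect_equal(m2$max_motion_factor,
               10 / mean(c(base[1, ], base[1, ] + 10)))

  # reversed non-palindromic profile correlates negatively (brute force)
  rev2 <- base
  rev2[2, ] <- rev(base[2, ])
  m3 <- motion_indicators(rev2)
  x <- base[1, ]; y <- rev(base[1, ])
  brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_lt(m3$min_motion_correlation, 0)
  expect_equal(m3$min_motion_correlation, brute)

  # zero-variance pair flagged with correlation treated as 0
  zv <- matrix(100, 2, 6)
  m4 <- motion_indicators(zv)
  expect_equal(m4$min_motion_correlation, 0)
  expect_true(m4$zero_variance)
})

test_that("image QC removes by score and by strict percentiles", {
  ind <- indicator_table(100, seed = 2)
  dec <- apply_image_qc(ind)
  reasons <- unlist(dec$reasons)
  # quality rule: exactly the scans with score < 45
  expect_equal(sum(grepl("^image_quality$", reasons)),
               sum(ind$image_quality < 45))
  expect_setequal(dec$scan_id[vapply(dec$reasons, function(r)
    "image_quality" %in% r, logical(1))],
    ind$scan_id[ind$image_quality < 45])
  # each percentile rule marks exactly floor(0.2 * N), verified by sorting
  for (col in c("ilm_indicator", "valid_count", "min_motion_correlation")) {
    marked <- dec$scan_id[vapply(dec$reasons, function(r)
      paste0("poorest_", col) %in% r, logical(1))]
    expect_setequal(marked, ind$scan_id[order(ind[[col]])][1:20])
  }
  for (col in c("max_motion_delta", "max_motion_factor")) {
    marked <- dec$scan_id[vapply(dec$reasons, function(r)
      paste0("poorest_", col) %in% r, logical(1))]
    expect_setequal(marked,
                    ind$scan_id[order(ind[[col]], decreasing = TRUE)][1:20])
  }
  # kept <=> no reasons
  expect_identical(dec$kept, lengths(dec$reasons) == 0)

  # ties at the cut are retained: identical above-threshold scans keep all
  tied <- ind
  tied$image_quality <- 60
  tied$ilm_indicator <- 50
  tied$valid_count <- 1
  tied$min_motion_correlation <- 0.99
  tied$max_motion_delta <- 1
  tied$max_motion_factor <- 0.01
  expect_true(all(apply_image_qc(tied)$kept))

  # threshold strictness: 44.9 with perfect indicators removed for quality only
  one <- indicator_table(50, seed = 3)
  one$image_quality[1] <- 44.9
  one$ilm_indicator[1] <- max(one$ilm_indicator) + 1
  one$valid_count[1] <- 1.5
  one$min_motion_correlation[1] <- 1
  one$max_motion_delta[1] <- -1
  one$max_motion_factor[1] <- -1
  dec1 <- apply_image_qc(one)
  expect_identical(dec1$reasons[[1]], "image_quality")

  # monotonicity: raising the threshold never retains a removed scan
  dec_lo <- apply_image_qc(ind, quality_threshold = 40)
  dec_hi <- apply_image_qc(ind, quality_threshold = 50)
  expect_true(all(dec_hi$kept <= dec_lo$kept))

  # empty table
  expect_equal(nrow(apply_image_qc(ind[0, ])), 0)
})

test_that("refractive error and outlier rules follow their formulas", {
  expect_equal(refractive_error(0, 0), 0)
  expect_equal(refractive_error(-2.0, -1.0), -2.5)
  expect_equal(refractive_error(1.25, 0.5), 1.5)

  expect_true(all(!refractive_outlier_mask(rep(1.5, 20))))
  v <- c(1:100, 10000)
  mask <- refractive_outlier_mask(v)
  med <- median(v); iqr <- unname(diff(quantile(v, c(.25, .75))))
  expect_identical(mask, abs(v - med) > 1.5 * iqr)
  expect_identical(which(mask), 101L)
  # symmetry under sign flip
  sym <- c(-10, -5, 0, 5, 10, 60, -60)
  expect_identical(refractive_outlier_mask(sym), refractive_outlier_mask(-sym))
})

test_that("PC-distance filter keeps points within the radius (inclusive)", {
  expect_true(all(pc_distance_filter(rnorm(20), rnorm(20), Inf)))
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  expect_true(all(pc_distance_filter(cos(th), sin(th), 1)))
  # two clusters: brute-force distances decide
  pc1 <- c(rnorm(50, 0, 0.1), rnorm(10, 20, 0.1))
  pc2 <- c(rnorm(50, 0, 0.1), rnorm(10, 20, 0.1))
  keep <- pc_distance_filter(pc1, pc2, radius = 10)
  d <- sqrt((pc1 - mean(pc1))^2 + (pc2 - mean(pc2))^2)
  expect_identical(keep, d <= 10)
  expect_true(all(!keep[51:60]))
})

test_that("kinship filter removes a minimal deterministic vertex set", {
  expect_identical(kinship_filter(tibble::tibble(id1 = character(),
                                                 id2 = character(),
                                                 degree = numeric()),
                                  ids = c("A", "B")), c("A", "B"))
  # single pair: lexicographic tie-break removes A, retains B
  expect_identical(kinship_filter(tibble::tibble(id1 = "A", id2 = "B",
                                                 degree = 2)), "B")
  # star: hub removed, leaves retained — matches the unique minimum cover,
  # verified by exhaustive search over all vertex subsets of the 6 nodes
  pairs <- tibble::tibble(id1 = "HUB", id2 = paste0("X", 1:5), degree = 1)
  got <- kinship_filter(pairs)
  nodes <- c("HUB", paste0("X", 1:5))
  covers <- Filter(function(rm) {
    all(pairs$id1 %in% rm | pairs$id2 %in% rm)
  }, lapply(seq_len(2^6) - 1, function(m) nodes[bitwAnd(m, 2^(0:5)) > 0]))
  best <- covers[[which.min(lengths(covers))]]
  expect_identical(sort(got), sort(setdiff(nodes, best)))
  # retained set induces no edges
  expect_true(all(!(pairs$id1 %in% got & pairs$id2 %in% got)))
  # pairs beyond max_degree are ignored
  far <- tibble::tibble(id1 = "A", id2 = "B", degree = 4)
  expect_identical(kinship_filter(far), c("A", "B"))
})
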
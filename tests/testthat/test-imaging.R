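wt <- genotype_preset("wild-type")
tr <- build_intestine_lineage()
demo_cells <- function(seed = 5) {
  st <- simulate_silencing(tr, wt, seed = seed)
  simulate_animal(tr, st, wt, seed = seed + 100)
}

test_that("empty and blank stacks are handled without error", {
  stk <- render_animal_stack(demo_cells()[0, ])
  expect_true(all(stk$green == 0) && all(stk$red == 0))
  expect_length(segment_nuclei(stk), 0)
  q <- quantify_nuclei(stk, list())
  expect_equal(nrow(q), 0)
  # saturated/constant stack
  lim <- 2^16 - 1
  sat <- image_stack(array(lim, c(3, 8, 8)), array(lim, c(3, 8, 8)))
  expect_length(segment_nuclei(sat), 0)
})

test_that("rendering is calibrated: equatorial disk mean equals the raw value", {
  cells <- demo_cells()[1, , drop = FALSE]
  stk <- render_animal_stack(cells)
  ctr <- attr(stk, "centers")
  m <- equatorial_disk_mean(stk, ctr[1, ], radius = 4)
  expect_lt(abs(m[["green"]] - cells$raw_green) / cells$raw_green, 0.01)
  expect_lt(abs(m[["red"]] - cells$raw_red) / cells$raw_red, 0.01)
})

test_that("rendering is seed-deterministic and bounds-checked", {
  cells <- demo_cells()
  s1 <- render_animal_stack(cells, noise = list(read_sd = 3, shot = TRUE), seed = 9)
  s2 <- render_animal_stack(cells, noise = list(read_sd = 3, shot = TRUE), seed = 9)
  expect_identical(s1$green, s2$green)
  expect_identical(s1$red, s2$red)
  expect_error(render_animal_stack(cells, layout = cbind(8, 24, c(2, 30:35))),
               "layout overflow")
})

test_that("noiseless rendering segments to the true nuclei", {
  cells <- demo_cells()
  stk <- render_animal_stack(cells)
  rois <- segment_nuclei(stk)
  expect_length(rois, 7)
  ctr <- attr(stk, "centers")
  got <- t(vapply(rois, `[[`, numeric(3), "centroid"))
  expect_true(all(abs(got - ctr) <= 1))
})

test_that("moderate noise does not break detection", {
  cells <- demo_cells(seed = 6)
  # read noise well below signal (SNR >= 10 at typical intensities)
  stk <- render_animal_stack(cells, noise = list(read_sd = 25, shot = TRUE),
                             seed = 77)
  rois <- segment_nuclei(stk)
  expect_length(rois, 7)
})

test_that("simulate -> render -> segment -> quantify closes within 5%", {
  for (seed in c(5, 7)) {
    cells <- demo_cells(seed)
    stk <- render_animal_stack(cells)
    rois <- segment_nuclei(stk)
    expect_length(rois, nrow(cells))  # 100% detection
    q <- quantify_nuclei(stk, rois)
    # rois are ordered along x = cell order of the default layout
    expect_true(all(abs(q$raw_green - cells$raw_green) / cells$raw_green <= 0.05))
    expect_true(all(abs(q$raw_red - cells$raw_red) / cells$raw_red <= 0.05))
  }
})

test_that("swapping channel arrays swaps recovered values exactly", {
  cells <- demo_cells()
  stk <- render_animal_stack(cells)
  swapped <- image_stack(stk$red, stk$green, bit_depth = stk$bit_depth,
                         gain = stk$gain)
  r1 <- segment_nuclei(stk)
  r2 <- segment_nuclei(swapped)
  q1 <- quantify_nuclei(stk, r1)
  q2 <- quantify_nuclei(swapped, r2)
  expect_equal(q1$raw_green, q2$raw_red, tolerance = 1e-12)
  expect_equal(q1$raw_red, q2$raw_green, tolerance = 1e-12)
})

test_that("bit depth does not affect analysis downstream of normalization", {
  set.seed(20)
  mut <- genotype_preset("met-2-null-like")
  res <- list()
  for (bd in c(8, 16)) {
    rows <- list()
    for (a in 1:4) {
      cells <- simulate_animal(tr, simulate_silencing(tr, mut, seed = 40 + a),
                               mut, seed = 140 + a)
      stk <- render_animal_stack(cells, bit_depth = bd)
      q <- quantify_nuclei(stk, segment_nuclei(stk))
      rows[[a]] <- data.frame(animal = paste0("w", a), experiment = 1L,
                              group = "g", cell = paste0("w", a, "_", seq_len(nrow(q))),
                              raw_green = q$raw_green, raw_red = q$raw_red)
    }
    tab <- group_noise(normalize_per_experiment(do.call(rbind, rows)))
    res[[as.character(bd)]] <- median(tab$eta)
  }
  expect_lt(abs(res[["8"]] - res[["16"]]) / max(res[["16"]], 1e-9), 0.01)
})

test_that("background estimators agree on a constant background", {
  cells <- demo_cells()
  stk <- render_animal_stack(cells, background = 50)
  rois <- segment_nuclei(stk)
  qg <- quantify_nuclei(stk, rois, background = "global")
  qa <- quantify_nuclei(stk, rois, background = "annulus")
  expect_equal(qg$bg_green, rep(50, 7))
  expect_true(all(abs(qa$raw_green - qg$raw_green) /
                    pmax(qg$raw_green, 1) <= 0.01))
  expect_true(all(abs(qa$raw_red - qg$raw_red) /
                    pmax(qg$raw_red, 1) <= 0.01))
})

test_that("a uniform nucleus over zero background quantifies to its value", {
  g <- array(0, c(5, 20, 20))
  g[3, 8:12, 8:12] <- 400
  stk <- image_stack(g, g)
  mask <- matrix(FALSE, 20, 20); mask[8:12, 8:12] <- TRUE
  roi <- list(centroid = c(3, 10, 10), z_eq = 3, mask = mask,
              area = 25, voxels = which(g > 0))
  q <- quantify_nuclei(stk, list(roi), background = "global")
  expect_equal(q$raw_green, 400)
  bad <- roi; bad$mask <- matrix(FALSE, 20, 20)
  expect_error(quantify_nuclei(stk, list(bad)), "empty equatorial mask")
})

test_that("TIFF round trip preserves voxels and metadata", {
  cells <- demo_cells()
  stk <- render_animal_stack(cells, noise = list(read_sd = 10, shot = FALSE),
                             seed = 3)
  path <- tempfile(fileext = ".tif")
  write_stack_tiff(stk, path)
  back <- read_stack_tiff(path)
  expect_equal(back$green, stk$green)
  expect_equal(back$red, stk$red)
  expect_equal(back$bit_depth, stk$bit_depth)
  expect_equal(back$gain, stk$gain)
  expect_equal(back$z_step, stk$z_step)
  unlink(c(path, paste0(path, ".json")))
})
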
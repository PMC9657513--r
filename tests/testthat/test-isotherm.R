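test_that("shoelace area matches hand values and is orientation-invariant", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  expect_identical(shoelace_area(sq), 1)
  expect_identical(shoelace_area(sq[5:1, ]), 1)        # clockwise
  rot <- rbind(sq[2:4, ], sq[1, ], sq[2, ])            # different start vertex
  expect_identical(shoelace_area(rot), 1)
  tri <- rbind(c(0, 0), c(4, 0), c(0, 3), c(0, 0))
  expect_equal(shoelace_area(tri), 6)
})

test_that("shoelace rejects unclosed or degenerate polygons", {
  expect_error(shoelace_area(rbind(c(0, 0), c(1, 0), c(1, 1))), "closed")
  expect_error(shoelace_area(rbind(c(0, 0), c(1, 1), c(0, 0))), "3 distinct")
  # collinear vertices are distinct but enclose nothing
  collinear <- rbind(c(0, 0), c(1, 1), c(2, 2), c(0, 0))
  expect_equal(shoelace_area(collinear), 0)
})

test_that("shoelace agrees with fan triangulation on random simple polygons", {
  set.seed(303)
  for (i in 1:200) {
    v <- random_simple_polygon()
    a1 <- shoelace_area(v)
    a2 <- fan_area(v)
    expect_lt(abs(a1 - a2), 1e-9 * max(1, a2))
  }
})

test_that("marching squares recovers circular isotherms of a Gaussian bump", {
  spec <- single_lesion_spec(sigma = 12, amplitude = 1.0, size = 120L)
  ph <- generate_phantom(spec)
  for (lv in c(36.5, 36.8, 37.0)) {
    cs <- extract_contours(ph$frame, lv)
    expect_length(cs$contours, 1L)
    ct <- cs$contours[[1L]]
    expect_false(ct$touches_border)
    # closed by construction
    expect_equal(ct$vertices[1L, ], ct$vertices[nrow(ct$vertices), ])
    # centroid within 1 px of the lesion center
    cen <- polygon_centroid(ct$vertices)
    expect_lt(sqrt(sum((cen - c(59.5, 59.5))^2)), 1)
    # approximately circular: radial spread below 5%
    r <- sqrt((ct$vertices[, 1] - cen[1])^2 + (ct$vertices[, 2] - cen[2])^2)
    expect_lt((max(r) - min(r)) / mean(r), 0.05)
  }
})

test_that("levels above the maximum yield no contours, not an error", {
  spec <- single_lesion_spec(sigma = 12, amplitude = 1.0, size = 100L)
  ph <- generate_phantom(spec)
  cs <- extract_contours(ph$frame, c(36.5, 39.0))
  expect_true(all(vapply(cs$contours, function(ct) ct$level, numeric(1)) == 36.5))
  expect_error(extract_contours(thermal_frame(matrix(36, 1, 3))), "too small")
})

test_that("contour area matches the above-level pixel count to the perimeter bound", {
  spec <- single_lesion_spec(sigma = 15, amplitude = 1.2, size = 140L)
  ph <- generate_phantom(spec)
  for (lv in c(36.6, 36.9)) {
    ct <- lesion_boundary(extract_contours(ph$frame, lv), lv)
    a <- shoelace_area(ct)
    npx <- sum(ph$frame$grid >= lv, na.rm = TRUE)      # pixel-set oracle
    perim <- sum(sqrt(rowSums(diff(ct$vertices)^2)))
    expect_lt(abs(a - npx), perim / 2)
  }
})

test_that("contour area matches the analytic Gaussian iso-area within 5%", {
  for (sigma in c(10, 12, 15)) {
    spec <- single_lesion_spec(sigma = sigma, amplitude = 1.0, size = 140L)
    ph <- generate_phantom(spec)
    for (lv in c(36.45, 36.7, 36.95)) {
      ct <- lesion_boundary(extract_contours(ph$frame, lv), lv)
      expect_lt(abs(shoelace_area(ct) - phantom_iso_area(ph$truth, lv)),
                0.05 * phantom_iso_area(ph$truth, lv))
    }
  }
})

test_that("marching squares agrees with grDevices::contourLines", {
  spec <- single_lesion_spec(sigma = 12, amplitude = 1.0, size = 100L)
  ph <- generate_phantom(spec)
  lv <- 36.7
  ours <- lesion_boundary(extract_contours(ph$frame, lv), lv)
  g <- ph$frame$grid
  # contourLines indexes z[i, j] at (x[i], y[j]); i = row = our y + 1
  cl <- grDevices::contourLines(x = 0:(nrow(g) - 1), y = 0:(ncol(g) - 1),
                                z = g, levels = lv)
  expect_length(cl, 1L)
  ref <- cbind(cl[[1L]]$y, cl[[1L]]$x)   # back to (x, y) = (col-1, row-1)
  if (any(ref[1L, ] != ref[nrow(ref), ])) ref <- rbind(ref, ref[1L, ])
  expect_lt(abs(shoelace_area(ours) - shoelace_area(ref)),
            0.01 * shoelace_area(ref))
  cen_ref <- polygon_centroid(ref)
  cen_our <- polygon_centroid(ours$vertices)
  expect_lt(sqrt(sum((cen_ref - cen_our)^2)), 0.1)
})

test_that("nested isotherms have non-increasing areas (monotone in level)", {
  spec <- single_lesion_spec(sigma = 13, amplitude = 1.5, size = 120L)
  ph <- generate_phantom(spec)
  lvls <- seq(36.4, 37.5, by = 0.1)
  cs <- extract_contours(ph$frame, lvls)
  areas <- vapply(lvls, function(lv)
    shoelace_area(lesion_boundary(cs, lv)), numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("border-crossing isotherms are closed along the border and flagged", {
  spec <- phantom_spec(height = 80L, width = 80L, skin_margin = 0L,
                       lesions = list(list(x = 8, y = 40, sigma = 12,
                                           amplitude = 1.0)),
                       noise_sd = 0, seed = 2L)
  ph <- generate_phantom(spec)
  # the iso-disk radius (~16 px) exceeds the 8 px distance to the image edge
  ct <- lesion_boundary(extract_contours(ph$frame, 36.6), 36.6)
  expect_true(ct$touches_border)
  expect_equal(ct$vertices[1L, ], ct$vertices[nrow(ct$vertices), ])
  expect_gt(shoelace_area(ct), 0)
  expect_lt(shoelace_area(ct), phantom_iso_area(ph$truth, 36.6))
})

test_that("absolute area follows the pinhole scaling laws exactly", {
  expect_identical(absolute_area(0, distance_d = 30, focal_f = 1,
                                 pixel_width_W = 0.0017,
                                 pixel_length_L = 0.0017), 0)
  # d = f: both conventions reduce to area * W * L
  for (conv in c("pinhole", "printed"))
    expect_equal(absolute_area(100, distance_d = 2, focal_f = 2,
                               pixel_width_W = 0.1, pixel_length_L = 0.2,
                               convention = conv), 100 * 0.1 * 0.2)
  a1 <- absolute_area(50, distance_d = 30, focal_f = 1,
                      pixel_width_W = 0.0017, pixel_length_L = 0.0017)
  a2 <- absolute_area(50, distance_d = 60, focal_f = 1,
                      pixel_width_W = 0.0017, pixel_length_L = 0.0017)
  expect_equal(a2, 4 * a1)
  p1 <- absolute_area(50, distance_d = 30, focal_f = 1, pixel_width_W = 0.0017,
                      pixel_length_L = 0.0017, convention = "printed")
  p2 <- absolute_area(50, distance_d = 60, focal_f = 1, pixel_width_W = 0.0017,
                      pixel_length_L = 0.0017, convention = "printed")
  expect_equal(p2, p1 / 4)
  # linear in pixel area
  expect_equal(absolute_area(150, distance_d = 30, focal_f = 1,
                             pixel_width_W = 0.0017, pixel_length_L = 0.0017),
               3 * a1)
  expect_error(absolute_area(10, distance_d = 30), "needs")
})

test_that("lesion_boundary picks the largest closed contour deterministically", {
  spec <- phantom_spec(height = 120L, width = 160L, skin_margin = 5L,
                       lesions = list(list(x = 40, y = 60, sigma = 14, amplitude = 1.0),
                                      list(x = 115, y = 60, sigma = 8, amplitude = 1.0)),
                       noise_sd = 0, seed = 4L)
  ph <- generate_phantom(spec)
  cs <- extract_contours(ph$frame, 36.7)
  expect_length(cs$contours, 2L)
  b <- lesion_boundary(cs, 36.7)
  cen <- polygon_centroid(b$vertices)
  expect_lt(abs(cen[1] - 40), 1)    # the sigma = 14 lesion is the larger one
  # oracle: shoelace areas of both contours
  areas <- vapply(cs$contours, shoelace_area, numeric(1))
  expect_equal(shoelace_area(b), max(areas))
  expect_error(lesion_boundary(cs, 37.9), "not among")
  cs2 <- extract_contours(ph$frame, 37.9)
  expect_error(lesion_boundary(cs2, 37.9), "no closed contour")
})
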
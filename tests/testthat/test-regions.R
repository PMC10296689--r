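test_that("compartment calls honour containment and the closed-boundary convention", {
  disc <- make_disc_polygon(0, 0, 100)
  g <- region_geometry("r", list(disc), c(-500, -500, 500, 500))
  expect_identical(assign_compartment(0, 0, g), "tumour")
  expect_identical(assign_compartment(200, 0, g), "stroma")
  # (100, 0) is a polygon vertex: exactly on the boundary -> tumour
  expect_identical(assign_compartment(100, 0, g), "tumour")
  expect_error(assign_compartment(600, 0, g), "outside ROI bounds",
               class = "tme_bounds_error")
})

test_that("point-in-polygon agrees with an independent ray-casting oracle", {
  skip_if_not_installed("mgcv")
  set.seed(11)
  for (rep in 1:3) {
    # two disjoint nests (the generator guarantees disjointness; mgcv's
    # even-odd rule over concatenated loops only matches a union then)
    cx <- c(runif(1, -300, -120), runif(1, 120, 300))
    cy <- runif(2, -200, 200)
    g <- region_geometry("r",
                         list(make_disc_polygon(cx[1], cy[1], runif(1, 50, 110), 17),
                              make_disc_polygon(cx[2], cy[2], runif(1, 30, 90), 23)),
                         c(-500, -500, 500, 500))
    x <- runif(3000, -499, 499); y <- runif(3000, -499, 499)
    # exclude near-boundary points where the conventions legitimately differ
    dmin <- pmin(sapply(seq_along(x), function(i) oracle_dist_ring(x[i], y[i], g$tumour_polygons[[1]])),
                 sapply(seq_along(x), function(i) oracle_dist_ring(x[i], y[i], g$tumour_polygons[[2]])))
    keep <- dmin > 1e-3
    inside_pkg <- assign_compartment(x[keep], y[keep], g) == "tumour"
    bnd <- do.call(rbind, lapply(g$tumour_polygons, function(p) {
      rbind(p, p[1, ], c(NA, NA))
    }))
    io <- mgcv::in.out(bnd, cbind(x[keep], y[keep]))
    expect_identical(inside_pkg, as.vector(io))
  }
})

test_that("border distance is signed, matches half-plane geometry and the segment oracle", {
  g <- half_plane_geometry()
  expect_equal(border_distance(-100, 5, g), -100)
  expect_equal(border_distance(200, 0, g), 200)
  # random points vs independent scalar segment-distance oracle
  set.seed(7)
  disc <- make_disc_polygon(10, -20, 140, 31)
  gd <- region_geometry("r", list(disc), c(-500, -500, 500, 500))
  x <- runif(200, -499, 499); y <- runif(200, -499, 499)
  d_pkg <- abs(border_distance(x, y, gd))
  d_or <- vapply(seq_along(x), function(i) oracle_dist_ring(x[i], y[i], disc), numeric(1))
  expect_equal(d_pkg, d_or, tolerance = 1e-12)
  empty <- region_geometry("e", list(), c(0, 0, 10, 10))
  expect_error(border_distance(1, 1, empty), "empty tumour border",
               class = "tme_undefined_region_error")
})

test_that("invasive-margin labels respect the 250 um band and its sides", {
  g <- half_plane_geometry()
  expect_identical(assign_invasive_margin(-100, 0, g), "IM_T")
  expect_identical(assign_invasive_margin(200, 0, g), "IM_S")
  expect_identical(assign_invasive_margin(300, 0, g), "NONE")
  # inclusive band edge
  expect_identical(assign_invasive_margin(250, 0, g), "IM_S")
})

test_that("IM labels are consistent with compartments and monotone in the half-width", {
  set.seed(3)
  g <- region_geometry("r", list(make_disc_polygon(-100, 50, 150),
                                 make_disc_polygon(250, -200, 90)),
                       c(-500, -500, 500, 500))
  x <- runif(2000, -500, 500); y <- runif(2000, -500, 500)
  comp <- assign_compartment(x, y, g)
  widths <- c(100, 250, 400)
  labels <- lapply(widths, function(w) {
    assign_invasive_margin(x, y, g, region_config(im_half_width = w))
  })
  for (lab in labels) {
    expect_true(all(comp[lab == "IM_T"] == "tumour"))
    expect_true(all(comp[lab == "IM_S"] == "stroma"))
  }
  # growing the band never removes a cell from the margin
  for (k in 1:2) {
    expect_true(all(labels[[k + 1]][labels[[k]] != "NONE"] != "NONE"))
  }
})

test_that("region areas match closed-form disc geometry", {
  r_1mm2 <- 564.18958
  g <- region_geometry("r", list(make_disc_polygon(0, 0, r_1mm2, 256)),
                       c(-1500, -1500, 1500, 1500))
  expect_equal(region_area(g, "TUMOUR"), 1.0, tolerance = 5e-4)
  expect_equal(region_area(g, "ALL"), 9.0)
  expect_equal(region_area(g, "STROMA"), 8.0, tolerance = 5e-4)
  # disc radius 300: IM_T is the annulus 50 < r <= 300 plus boundary
  g2 <- region_geometry("r2", list(make_disc_polygon(0, 0, 300, 256)),
                        c(-1000, -1000, 1000, 1000))
  expect_equal(region_area(g2, "IM_T", grid_n = 300),
               pi * (300^2 - 50^2) * 1e-6, tolerance = 0.02)
  expect_equal(region_area(g2, "IM_S", grid_n = 300),
               pi * (550^2 - 300^2) * 1e-6, tolerance = 0.02)
})
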
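test_that("grid construction validates and exposes spacings", {
  g <- fv_grid(100, 50, 200, 100)
  expect_equal(g$dx, 2)
  expect_equal(g$dy, 2)
  expect_error(fv_grid(1, 10, 100, 100), "at least 2")
  expect_error(fv_grid(10, 10, -5, 100), "positive")
  cc <- cell_centers(fv_grid(2, 2, 200, 200))
  expect_equal(cc$x, c(50, 150, 50, 150))
  expect_equal(cc$y, c(50, 50, 150, 150))
})

test_that("rasterize_blocks paints by cell centre with background fill", {
  g <- fv_grid(4, 4, 200, 200)
  rm0 <- rasterize_blocks(g)
  expect_true(all(rm0$labels == "street"))

  g2 <- fv_grid(2, 2, 200, 200)
  rm1 <- rasterize_blocks(
    g2, tibble::tibble(label = "block", x0 = 0, y0 = 0, x1 = 100, y1 = 100))
  expect_equal(rm1$labels[1, 1], "block")
  expect_equal(sum(rm1$labels == "block"), 1L)

  # later rectangles overpaint earlier ones
  rm2 <- rasterize_blocks(
    g2, tibble::tibble(label = c("block", "park"),
                       x0 = c(0, 0), y0 = c(0, 0),
                       x1 = c(100, 100), y1 = c(100, 100)))
  expect_equal(rm2$labels[1, 1], "park")
})

test_that("rasterize_blocks rejects bad rectangles and labels", {
  g <- fv_grid(4, 4, 200, 200)
  expect_error(rasterize_blocks(
    g, tibble::tibble(label = "block", x0 = 0, y0 = 0, x1 = 300, y1 = 100)),
    "outside the domain")
  expect_error(rasterize_blocks(
    g, tibble::tibble(label = "block", x0 = 50, y0 = 0, x1 = 50, y1 = 100)),
    "empty rectangle")
  expect_error(rasterize_blocks(
    g, tibble::tibble(label = "lake", x0 = 0, y0 = 0, x1 = 100, y1 = 100)),
    "unknown region label")
  expect_error(rasterize_blocks(g, background = "lake"), "unknown background")
  expect_error(region_map(matrix("lake", 4, 4), g), "unknown region label")
})

test_that("Juiz de Fora preset has 17 blocks, one contiguous park and streets", {
  cfg <- scenario_example2(dx = 10)
  expect_equal(sum(cfg$layout$rectangles$label == "block"), 17L)
  regions <- scenario_regions(cfg)
  expect_setequal(unique(as.vector(regions$labels)), c("block", "street", "park"))
  # park occupies exactly one full index rectangle
  park <- which(regions$labels == "park", arr.ind = TRUE)
  expect_equal(nrow(park),
               length(unique(park[, 1])) * length(unique(park[, 2])))
  expect_true(all(diff(sort(unique(park[, 1]))) == 1))
  expect_true(all(diff(sort(unique(park[, 2]))) == 1))
})

test_that("rasterized region areas match rectangle areas to one cell layer per edge", {
  g <- fv_grid(50, 50, 200, 200)
  rects <- tibble::tibble(
    label = c("block", "park", "beach"),
    x0 = c(8, 120, 0), y0 = c(8, 30, 150),
    x1 = c(72, 190, 60), y1 = c(100, 110, 200))
  rm <- rasterize_blocks(g, rects)
  areas <- region_areas(rm)
  for (k in seq_len(nrow(rects))) {
    r <- rects[k, ]
    true_area <- (r$x1 - r$x0) * (r$y1 - r$y0)
    tol <- 2 * (r$x1 - r$x0 + r$y1 - r$y0) * max(g$dx, g$dy)  # one layer/edge
    got <- areas$area_m2[areas$label == r$label]
    expect_lt(abs(got - true_area), tol)
  }
})

test_that("build_parameter_fields expands region tables piecewise-constantly", {
  cfg1 <- scenario_example1(dx = 10)
  regions <- scenario_regions(cfg1)
  p <- build_parameter_fields(regions, cfg1$region_table)
  street <- regions$labels == "street"
  expect_true(all(p$psi[street] == 0.3))
  expect_true(all(p$vx[street] == 5.0e-2))
  expect_true(all(p$vy[street] == 1.5e-1))
  expect_true(all(p$Dx[street] == 1.25e-2))
  expect_true(all(p$Dx[!street] == 3.75e-3))

  # park row of the Juiz de Fora table
  cfg2 <- scenario_example2(dx = 10)
  r2 <- scenario_regions(cfg2)
  p2 <- build_parameter_fields(r2, cfg2$region_table)
  park <- r2$labels == "park"
  expect_true(all(p2$psi[park] == 0.8))
  expect_true(all(p2$vx[park] == -5.0e-2))
  expect_true(all(p2$vy[park] == 2.5e-2))

  # all-streets insecticide: h1 on streets only, h2 identically zero
  cfg3 <- scenario_example3("all_streets", dx = 10)
  p3 <- build_parameter_fields(scenario_regions(cfg3), cfg3$region_table)
  street3 <- scenario_regions(cfg3)$labels == "street"
  expect_true(all(p3$h1[street3] == 0.928))
  expect_true(all(p3$h1[!street3] == 0))
  expect_true(all(p3$h2 == 0))
})

test_that("build_parameter_fields validates coverage and invariants", {
  g <- fv_grid(4, 4, 40, 40)
  rm <- rasterize_blocks(
    g, tibble::tibble(label = "block", x0 = 0, y0 = 0, x1 = 20, y1 = 20))
  tab <- tibble::tibble(label = "street", psi = 0.3, vx = 0, vy = 0,
                        Dx = 0.01, Dy = 0.01)
  expect_error(build_parameter_fields(rm, tab), "block")
  tab2 <- dplyr::bind_rows(tab, tibble::tibble(
    label = "block", psi = 1.5, vx = 0, vy = 0, Dx = 0.01, Dy = 0.01))
  expect_error(build_parameter_fields(rm, tab2), "psi")
  tab2$psi[2] <- 1e-9
  expect_error(build_parameter_fields(rm, tab2), "psi")
  tab2$psi[2] <- 1
  tab2$Dx[2] <- -1
  expect_error(build_parameter_fields(rm, tab2), "non-negative")
})

test_that("field expansion is idempotent and row-order independent", {
  cfg <- scenario_example2(dx = 10)
  regions <- scenario_regions(cfg)
  p1 <- build_parameter_fields(regions, cfg$region_table)
  p2 <- build_parameter_fields(regions, cfg$region_table[c(3, 1, 2), ])
  for (f in c("psi", "vx", "vy", "Dx", "Dy", "h1", "h2")) {
    expect_identical(p1[[f]], p2[[f]])
  }
  p3 <- build_parameter_fields(regions, cfg$region_table)
  expect_identical(p1[c("psi", "vx", "vy")], p3[c("psi", "vx", "vy")])
})

test_that("region rasters round-trip through the CSV label-grid format", {
  cfg <- scenario_example4(dx = 20)
  regions <- scenario_regions(cfg)
  path <- tempfile(fileext = ".csv")
  write_region_csv(regions, path)
  back <- read_region_csv(path, regions$grid)
  expect_identical(back$labels, regions$labels)
  expect_error(read_region_csv(path, fv_grid(5, 5, 100, 100)),
               "dimensions")
  unlink(c(path, paste0(path, ".legend")))
})
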
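test_that("point lookup matches hand lookup on the 3x3 fixture", {
  st <- tiny_stack()
  # cells are 1 degree, origin upper-left (0, 3): cell (row r, col c)
  # covers lon [c-1, c), lat (3-r, 3-r+1]
  rec <- data.frame(
    species = "s",
    longitude = c(0.5, 2.5, 1.5, 0.5, 2.999),
    latitude = c(2.5, 2.5, 1.5, 0.001, 0.001),
    record_id = sprintf("p%d", 1:5))
  vals <- extract_values(st, rec)
  # p1 -> cell (1,1): AI is nodata there -> dropped
  expect_equal(vals$record_id, c("p2", "p3", "p4", "p5"))
  expect_equal(vals$MAP, c(300, 500, 700, 900))
  expect_equal(vals$P_dry, c(3, 5, 7, 9))
  expect_equal(vals$AET_PET, c(70 / 140, 90 / 180, 110 / 220, 130 / 260))
  expect_equal(attr(vals, "drop_log")$n_nodata, 1)
})

test_that("half-open cell convention assigns edge points to the eastern cell", {
  st <- tiny_stack()
  rec <- data.frame(species = "s",
                    longitude = c(1, 1 + 1e-9, 1 - 1e-9),
                    latitude = c(1.5, 1.5, 1.5),
                    record_id = c("edge", "inside", "west"))
  vals <- extract_values(st, rec)
  expect_equal(vals$MAP, c(500, 500, 400))
})

test_that("points outside the grid are dropped and counted", {
  st <- tiny_stack()
  rec <- data.frame(species = "s",
                    longitude = c(0.5, -0.5, 3.5),
                    latitude = c(2.5, 2.5, 2.5),
                    record_id = c("in", "west_out", "east_out"))
  vals <- extract_values(st, rec)
  expect_equal(attr(vals, "drop_log")$n_outside, 2)
})

test_that("species summaries match a brute-force per-point oracle", {
  st <- quick_landscape(seed = 17L)
  set.seed(17)
  n <- 100
  rec <- data.frame(
    species = sample(c("u", "v", "w"), n, replace = TRUE),
    longitude = runif(n, st$origin_lon, st$origin_lon + st$n_cols * st$cell_size),
    latitude = runif(n, st$origin_lat - st$n_rows * st$cell_size, st$origin_lat),
    record_id = sprintf("r%03d", 1:n))
  vals <- extract_values(st, rec)
  summ <- summarize_species(vals)
  for (sp in summ$species) {
    d <- vals[vals$species == sp, ]
    for (v in hydro_indicators()) {
      x <- numeric(0)
      for (i in seq_len(nrow(d))) x <- c(x, d[[v]][i])
      expect_equal(summ[[paste0(v, "_mean")]][summ$species == sp], mean(x))
      expect_equal(summ[[paste0(v, "_range")]][summ$species == sp],
                   max(x) - min(x))
    }
  }
})

test_that("summary simple arithmetic and degenerate cases", {
  vals <- data.frame(species = "s", MAP = c(1000, 1500, 2000),
                     AI = c(5000, 5000, 5000), AET_PET = c(0.5, 0.6, 0.7),
                     P_dry = c(0, 10, 20), P_seas = c(30, 40, 50))
  s <- summarize_species(vals)
  expect_equal(s$MAP_mean, 1500)
  expect_equal(s$MAP_range, 1000)
  expect_equal(s$AI_range, 0)
  # species with < 3 points is excluded with a warning
  vals2 <- rbind(vals, data.frame(species = "t", MAP = 1, AI = 1,
                                  AET_PET = 1, P_dry = 1, P_seas = 1))
  expect_warning(s2 <- summarize_species(vals2), "t")
  expect_equal(s2$species, "s")
  expect_equal(attr(s2, "excluded_species"), "t")
})

test_that("dropping a point never widens a species range", {
  st <- quick_landscape(seed = 23L)
  set.seed(23)
  rec <- data.frame(
    species = "s",
    longitude = runif(40, st$origin_lon, st$origin_lon + st$n_cols * st$cell_size),
    latitude = runif(40, st$origin_lat - st$n_rows * st$cell_size, st$origin_lat),
    record_id = sprintf("r%02d", 1:40))
  vals <- extract_values(st, rec)
  full <- summarize_species(vals)
  for (k in 1:10) {
    sub <- summarize_species(vals[-sample.int(nrow(vals), 5), ])
    for (v in hydro_indicators()) {
      expect_lte(sub[[paste0(v, "_range")]], full[[paste0(v, "_range")]])
    }
  }
  # order invariance
  shuffled <- summarize_species(vals[sample.int(nrow(vals)), ])
  expect_equal(shuffled, full, ignore_attr = TRUE)
})

test_that("collinearity screen flags exact and quadratic relationships", {
  set.seed(5)
  n <- 200
  base <- lapply(hydro_indicators(), function(v) {
    ctr <- runif(n, 50, 150)
    cbind(ctr - 1, ctr, ctr + 1)
  })
  names(base) <- hydro_indicators()
  s <- summaries_from_values(base)

  # independent random summaries: no pair strongly correlated
  scr <- variable_collinearity_screen(s)
  off <- scr$r2[upper.tri(scr$r2)]
  expect_true(all(off < 0.2))
  expect_equal(nrow(scr$flagged), 0)

  # AI an exact multiple of MAP: r2 = 1, flagged
  s2 <- s
  s2$AI_mean <- 3 * s2$MAP_mean
  scr2 <- suppressWarnings(variable_collinearity_screen(s2))  # exact fit
  expect_equal(scr2$r2["MAP", "AI"], 1)
  expect_true(any(scr2$flagged$var1 == "MAP" & scr2$flagged$var2 == "AI"))

  # quadratic relationship: quadratic fit near 1, linear below it
  s3 <- s
  x <- seq(-3, 3, length.out = n)
  s3$MAP_mean <- x
  s3$AI_mean <- x^2
  scr3 <- suppressWarnings(variable_collinearity_screen(s3))
  expect_gt(scr3$r2["MAP", "AI"], 0.999)
  expect_lt(summary(lm(s3$AI_mean ~ s3$MAP_mean))$r.squared, 0.5)

  # zero-variance variable: undefined (NA), not an error
  s4 <- s
  s4$P_dry_mean <- 7
  scr4 <- variable_collinearity_screen(s4)
  expect_true(all(is.na(scr4$r2["P_dry", setdiff(hydro_indicators(), "P_dry")])))
})
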
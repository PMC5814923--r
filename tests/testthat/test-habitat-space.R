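test_that("habitat space satisfies its algebraic invariants", {
  s <- random_summaries(60, seed = 8)
  for (kind in c("position", "range")) {
    sp <- fit_habitat_space(s, kind)
    expect_equal(sum(sp$variance_explained), 1, tolerance = 1e-9)
    expect_true(all(sp$variance_explained >= 0))
    # loadings orthonormal
    expect_equal(t(sp$loadings) %*% sp$loadings, diag(5),
                 ignore_attr = TRUE, tolerance = 1e-8)
    # scores centered
    expect_true(all(abs(colMeans(sp$scores)) < 1e-8))
    # sign convention: largest-|loading| entry positive
    for (k in 1:5) {
      expect_gt(sp$loadings[which.max(abs(sp$loadings[, k])), k], 0)
    }
  }
})

test_that("scores equal the projection of the transformed data", {
  s <- random_summaries(40, seed = 12)
  sp <- fit_habitat_space(s, "position")
  x <- as.matrix(s[, paste0(hydro_indicators(), "_mean")])
  xt <- scale(log10(x + sp$log_offset), center = sp$center, scale = sp$scale)
  expect_equal(unname(xt %*% sp$loadings), unname(sp$scores), tolerance = 1e-8)
})

test_that("a zero-variance variable is an error naming the variable", {
  s <- random_summaries(20, seed = 3)
  s$P_seas_mean <- 33
  expect_error(fit_habitat_space(s, "position"), "P_seas")
})

test_that("PCA on uncorrelated data spreads variance near 1/5 per component", {
  s <- random_summaries(2000, seed = 101)
  sp <- fit_habitat_space(s, "position")
  expect_true(all(abs(sp$variance_explained - 0.2) < 0.05))
})

test_that("two latent blocks concentrate variance on the first two components", {
  set.seed(77)
  n <- 500
  f_moist <- rnorm(n)
  f_seas <- rnorm(n)
  lat <- list(MAP = f_moist, AI = f_moist, AET_PET = f_moist,
              P_seas = f_seas, P_dry = f_seas)
  s <- data.frame(species = sprintf("sp%03d", 1:n), n_points_used = 3L)
  for (v in hydro_indicators()) {
    z <- 0.9 * lat[[v]] + sqrt(1 - 0.81) * rnorm(n)
    s[[paste0(v, "_mean")]] <- 10^(0.3 * z + 3)
  }
  sp <- fit_habitat_space(s, "position")
  expect_gte(sum(sp$variance_explained[1:2]), 0.85)
  comp <- apply(abs(sp$loadings[, 1:2]), 1, which.max)
  expect_equal(length(unique(comp[c("MAP", "AI", "AET_PET")])), 1)
  expect_equal(length(unique(comp[c("P_seas", "P_dry")])), 1)
  expect_false(comp[["MAP"]] == comp[["P_seas"]])
})

test_that("group hull areas match simple geometry and the brute-force oracle", {
  # unit square with species at its corners
  sc <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1, 0.5, 0.5), ncol = 2, byrow = TRUE)
  space <- structure(list(kind = "position",
                          scores = cbind(PC1 = sc[, 1], PC2 = sc[, 2],
                                         PC3 = 0, PC4 = 0, PC5 = 0)),
                     class = "habitat_space")
  rownames(space$scores) <- sprintf("s%d", 1:5)
  groups <- data.frame(species = sprintf("s%d", 1:5), group = "g")
  res <- group_hull_area(space, groups)
  expect_equal(res$hull_area, 1)

  # collinear scores: zero area
  space$scores[, "PC2"] <- space$scores[, "PC1"]
  expect_equal(group_hull_area(space, groups)$hull_area, 0)

  # random instances against the O(n^3) hull oracle
  set.seed(9)
  for (k in 1:25) {
    n <- sample(3:10, 1)
    xy <- cbind(runif(n), runif(n))
    sp2 <- structure(list(kind = "position",
                          scores = cbind(PC1 = xy[, 1], PC2 = xy[, 2])),
                     class = "habitat_space")
    rownames(sp2$scores) <- sprintf("s%d", 1:n)
    g2 <- data.frame(species = sprintf("s%d", 1:n), group = "g")
    expect_equal(group_hull_area(sp2, g2)$hull_area, bf_hull_area(xy),
                 tolerance = 1e-12)
  }
})

test_that("hull area is order- and rotation-invariant and monotone", {
  set.seed(31)
  xy <- cbind(runif(8), runif(8))
  a0 <- bf_hull_area(xy)
  area_of <- function(m) {
    sp <- structure(list(kind = "position",
                         scores = cbind(PC1 = m[, 1], PC2 = m[, 2])),
                    class = "habitat_space")
    rownames(sp$scores) <- sprintf("s%d", seq_len(nrow(m)))
    group_hull_area(sp, data.frame(species = rownames(sp$scores),
                                   group = "g"))$hull_area
  }
  expect_equal(area_of(xy), a0, tolerance = 1e-12)
  expect_equal(area_of(xy[sample.int(8), ]), a0, tolerance = 1e-12)
  th <- 0.83
  rot <- xy %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(area_of(rot), a0, tolerance = 1e-10)
  # interior point changes nothing; exterior point cannot shrink the hull
  expect_equal(area_of(rbind(xy, colMeans(xy[grDevices::chull(xy), ]))), a0,
               tolerance = 1e-12)
  expect_gte(area_of(rbind(xy, c(2, 2))), a0)
  # groups below the species minimum are omitted, not errored
  sp <- structure(list(kind = "position",
                       scores = cbind(PC1 = xy[, 1], PC2 = xy[, 2])),
                  class = "habitat_space")
  rownames(sp$scores) <- sprintf("s%d", 1:8)
  g <- data.frame(species = rownames(sp$scores),
                  group = rep(c("big", "small"), c(6, 2)))
  res <- group_hull_area(sp, g)
  expect_equal(res$group, "big")
  expect_equal(attr(res, "omitted_groups"), "small")
})
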
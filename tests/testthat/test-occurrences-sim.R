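test_that("occurrence sampling is seeded and insertion-order independent", {
  st <- quick_landscape(seed = 4L)
  rng <- range(st$layers$MAP)
  ns <- lapply(c("a", "b"), function(id) {
    niche_spec(id, c(MAP = mean(rng)), c(MAP = 0.2 * diff(rng)), n_points = 15)
  })
  g1 <- generate_species_occurrences(st, ns, seed = 9L)
  g2 <- generate_species_occurrences(st, ns, seed = 9L)
  expect_identical(g1$occurrences, g2$occurrences)
  # reversing the niche list must not change any species' points
  g3 <- generate_species_occurrences(st, rev(ns), seed = 9L)
  for (sp in c("a", "b")) {
    a <- g1$occurrences[g1$occurrences$species == sp, ]
    b <- g3$occurrences[g3$occurrences$species == sp, ]
    rownames(a) <- rownames(b) <- NULL
    expect_identical(a, b)
  }
  expect_false(identical(
    g1$occurrences,
    generate_species_occurrences(st, ns, seed = 10L)$occurrences))
})

test_that("a vanishing niche breadth concentrates sampling at the optimal cells", {
  st <- quick_landscape(seed = 4L)
  rng <- range(st$layers$MAP)
  opt <- unname(quantile(st$layers$MAP, 0.5))
  sigma <- 1e-3 * diff(rng)
  ns <- niche_spec("narrow", c(MAP = opt), c(MAP = sigma), n_points = 50)
  g <- generate_species_occurrences(st, ns, seed = 2L)
  vals <- extract_values(st, g$occurrences)
  best <- min(abs(st$layers$MAP - opt))
  # sampled cells sit within a few kernel widths of the closest cell value
  expect_true(all(abs(vals$MAP - opt) <= best + 5 * sigma))
})

test_that("sampled cell values center on the niche optimum", {
  # a landscape whose MAP values are uniformly dense, so availability is
  # symmetric about the optimum and the sampled mean is unbiased
  n <- 100
  m <- function(v) matrix(v, n, n)
  layers <- list(MAP = matrix(seq(0, 2000, length.out = n * n), n, n),
                 P_dry = m(50), P_seas = m(60), AET = m(1000), PET = m(1500))
  layers$AI <- round(10000 * layers$MAP / layers$PET)
  st <- climate_stack(layers, origin_lon = -75, origin_lat = 0, cell_size = 0.05)
  ns <- niche_spec("sp", c(MAP = 1000), c(MAP = 150), n_points = 1000)
  g <- generate_species_occurrences(st, ns, seed = 31L)
  vals <- extract_values(st, g$occurrences)
  se <- sd(vals$MAP) / sqrt(nrow(vals))
  expect_lt(abs(mean(vals$MAP) - 1000), 2 * se)
})

test_that("a niche with zero kernel mass over the landscape errors by name", {
  st <- quick_landscape(seed = 4L)
  ns <- niche_spec("ghost", c(MAP = 1e6), c(MAP = 1), n_points = 5)
  expect_error(generate_species_occurrences(st, ns), "ghost")
})

test_that("contamination counts and labels partition the record set", {
  ch <- contaminated_cohort(seed = 11L)
  cont <- ch$contaminated
  expect_setequal(unique(cont$label),
                  c("clean", "duplicate", "institution", "out_of_range"))
  for (sp in unique(cont$species)) {
    d <- cont[cont$species == sp, ]
    expect_equal(sum(d$label == "duplicate"), ch$spec$n_duplicates)
    expect_equal(sum(d$label == "institution"), ch$spec$n_institution)
    expect_equal(sum(d$label == "out_of_range"), ch$spec$n_out_of_range)
    expect_equal(sum(d$label == "clean"), 12)
  }
  # duplicates really duplicate a clean record's coordinates
  for (i in which(cont$label == "duplicate")) {
    d <- cont[cont$species == cont$species[i] & cont$label == "clean", ]
    expect_true(any(d$longitude == cont$longitude[i] &
                      d$latitude == cont$latitude[i]))
  }
  # out-of-range records lie outside the native box
  oor <- cont[cont$label == "out_of_range", ]
  for (i in seq_len(nrow(oor))) {
    box <- ch$boxes[ch$boxes$species == oor$species[i], ]
    expect_true(oor$longitude[i] > box$lon_max)
  }
})

test_that("all-zero contamination is the identity with clean labels", {
  ch <- contaminated_cohort(seed = 11L)
  clean <- ch$contaminated[ch$contaminated$label == "clean",
                           c("species", "longitude", "latitude", "record_id")]
  out <- inject_contaminants(clean, ch$boxes, contamination_spec())
  expect_true(all(out$label == "clean"))
  expect_equal(nrow(out), nrow(clean))
})

test_that("contaminating a species without a native box errors", {
  ch <- contaminated_cohort(seed = 11L)
  clean <- ch$contaminated[ch$contaminated$label == "clean",
                           c("species", "longitude", "latitude", "record_id")]
  boxes <- ch$boxes[-1, ]
  expect_error(
    inject_contaminants(clean, boxes,
                        contamination_spec(n_out_of_range = 1, seed = 1L)),
    "native box")
})

test_that("fixed-extent sampler bounds every species to its window", {
  st <- quick_landscape(seed = 4L)
  occ <- sample_fixed_extent_occurrences(st, sprintf("s%d", 1:5), 30, 1.0,
                                         seed = 6L)
  for (sp in unique(occ$species)) {
    d <- occ[occ$species == sp, ]
    expect_lte(diff(range(d$longitude)), 1.0)
    expect_lte(diff(range(d$latitude)), 1.0)
  }
  expect_identical(occ, sample_fixed_extent_occurrences(
    st, sprintf("s%d", 1:5), 30, 1.0, seed = 6L))
})
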
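test_that("CSV loading validates coordinates and reports rejected rows", {
  d <- withr::local_tempdir()
  p <- file.path(d, "occ.csv")
  df <- data.frame(
    species = c("a", "a", "a", "b", "b", "b", "b", "", "c", "c"),
    longitude = c(-70, -70.5, -71, 10, 11, 12, 200, 5, -60, -60.1),
    latitude = c(-15, -15.5, 95, 45, 46, 47, 45, 5, 0, 0.1),
    record_id = sprintf("r%02d", 1:10))
  write.csv(df, p, row.names = FALSE)
  res <- load_occurrences(p)
  expect_equal(nrow(res$records), 7)  # rows 3 (lat 95), 7 (lon 200), 8 (no species)
  expect_equal(res$rejected$row, c(3, 7, 8))
  expect_true(any(grepl("latitude", res$rejected$reason)))

  # missing required column is a format error
  p2 <- file.path(d, "bad.csv")
  write.csv(df[, -4], p2, row.names = FALSE)
  expect_error(load_occurrences(p2), "record_id")

  # empty file yields an empty set with a warning
  p3 <- file.path(d, "empty.csv")
  write.csv(df[0, ], p3, row.names = FALSE)
  expect_warning(res3 <- load_occurrences(p3), "empty")
  expect_equal(nrow(res3$records), 0)
})

test_that("the three removal rules and the minimum-points rule work together", {
  # one species: a duplicated point, one good point, one on another
  # continent, one at an institution -> 2 retained -> excluded (< 3)
  rec <- data.frame(
    species = "x",
    longitude = c(-70.1, -70.1, -70.3, 10.0, -70.5),
    latitude = c(-15.2, -15.2, -15.1, 45.0, -15.5),
    record_id = sprintf("r%d", 1:5))
  box <- data.frame(species = "x", lon_min = -75, lon_max = -65,
                    lat_min = -20, lat_max = -10)
  inst <- data.frame(longitude = -70.5, latitude = -15.5)
  res <- clean_occurrences(rec, box, inst, min_points = 3,
                           institution_tolerance_deg = 0)
  rep <- res$report
  expect_equal(rep$n_input, 5)
  expect_equal(rep$n_removed_duplicate, 1)
  expect_equal(rep$n_removed_institution, 1)
  expect_equal(rep$n_removed_outside, 1)
  expect_equal(rep$n_retained, 2)
  expect_equal(res$excluded_species, "x")
  expect_equal(nrow(res$records), 0)
})

test_that("a clean set passes through with an all-zero report", {
  rec <- data.frame(species = "y", longitude = -70 - (1:5) / 10,
                    latitude = -15 + (1:5) / 10, record_id = sprintf("r%d", 1:5))
  box <- data.frame(species = "y", lon_min = -75, lon_max = -65,
                    lat_min = -20, lat_max = -10)
  res <- clean_occurrences(rec, box, NULL)
  expect_equal(nrow(res$records), 5)
  expect_equal(res$report$n_removed_duplicate +
                 res$report$n_removed_institution +
                 res$report$n_removed_outside, 0)
})

test_that("cleaning recovers exactly the truth-labelled clean records", {
  ch <- contaminated_cohort(seed = 11L)
  cont <- ch$contaminated
  res <- clean_occurrences(cont[, c("species", "longitude", "latitude", "record_id")],
                           ch$boxes, ch$institutions,
                           institution_tolerance_deg = 0)
  truth_clean <- cont[cont$label == "clean", ]
  got <- res$records[order(res$records$species, res$records$record_id), ]
  want <- truth_clean[order(truth_clean$species, truth_clean$record_id),
                      c("species", "longitude", "latitude", "record_id")]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("report counts conserve records per species", {
  ch <- contaminated_cohort(seed = 13L)
  cont <- ch$contaminated
  res <- clean_occurrences(cont[, c("species", "longitude", "latitude", "record_id")],
                           ch$boxes, ch$institutions,
                           institution_tolerance_deg = 0)
  rep <- res$report
  expect_equal(rep$n_input,
               rep$n_retained + rep$n_removed_duplicate +
                 rep$n_removed_institution + rep$n_removed_outside)
})

test_that("cleaning is idempotent and invariant to record order", {
  ch <- contaminated_cohort(seed = 11L)
  cont <- ch$contaminated[, c("species", "longitude", "latitude", "record_id")]
  res1 <- clean_occurrences(cont, ch$boxes, ch$institutions,
                            institution_tolerance_deg = 0)
  res2 <- clean_occurrences(res1$records, ch$boxes, ch$institutions,
                            institution_tolerance_deg = 0)
  expect_equal(res2$records, res1$records)
  expect_true(all(res2$report$n_removed_duplicate == 0))
  set.seed(1)
  shuffled <- cont[sample.int(nrow(cont)), ]
  res3 <- clean_occurrences(shuffled, ch$boxes, ch$institutions,
                            institution_tolerance_deg = 0)
  rownames(res3$records) <- rownames(res1$records) <- NULL
  expect_equal(res3$records, res1$records)
})

test_that("species without a native box skip the range rule with a warning", {
  rec <- data.frame(species = "z", longitude = c(-70, 10, -71),
                    latitude = c(-15, 45, -16), record_id = c("a", "b", "c"))
  box <- data.frame(species = "other", lon_min = 0, lon_max = 1,
                    lat_min = 0, lat_max = 1)
  expect_warning(res <- clean_occurrences(rec, box, NULL), "native region")
  expect_equal(nrow(res$records), 3)  # outlier kept: no box to judge it by
  expect_error(clean_occurrences(rec, box, NULL, min_points = 0), "min_points")
})
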
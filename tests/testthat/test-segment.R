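test_that("green cut-off classification partitions exactly and is idempotent", {
  pc <- point_cloud(1:4, 1:4, 0, r = 0, g = c(200, 50, 115, 114), b = 0)
  cl <- classify_vegetation(pc)
  expect_identical(as.character(cl$class),
                   c("vegetation", "soil", "vegetation", "soil"))
  counts <- attr(cl, "class_counts")
  expect_identical(sum(counts), 4L)

  again <- classify_vegetation(cl)
  expect_identical(again$class, cl$class)

  flipped <- classify_vegetation(pc, direction = "veg_lt_cutoff")
  expect_identical(as.character(flipped$class),
                   c("soil", "vegetation", "soil", "vegetation"))
  expect_error(classify_vegetation(pc, green_cutoff = 300), "\\[0, 255\\]")
})

test_that("classification recovers generator labels exactly on disjoint ranges", {
  field <- generate_field(n_plots = 2, row_length = 1, base_density = 200,
                          seed = 51)
  cl <- classify_vegetation(field$cloud)
  expect_identical(as.character(cl$class), field$truth_points$label)
})

test_that("classification audit computes accuracy and kappa from the table", {
  pc <- point_cloud(1:100, 1, 0, r = 0,
                    g = c(rep(200, 50), rep(50, 50)), b = 0)
  cl <- classify_vegetation(pc)
  truth <- as.character(cl$class)
  perfect <- audit_classification(cl, truth, seed = 1)
  expect_identical(perfect$accuracy, 1)
  expect_identical(perfect$kappa, 1)
  expect_identical(perfect$n_audited, 100L)

  # all-one-class prediction against balanced truth: kappa 0
  allveg <- classify_vegetation(pc, green_cutoff = 0)
  aud <- audit_classification(allveg, truth, seed = 1)
  expect_identical(aud$accuracy, 0.5)
  expect_equal(aud$kappa, 0)
})

test_that("audited subsample matches hand-computed confusion arithmetic", {
  n <- 4000
  pc <- withr::with_seed(61, point_cloud(
    seq_len(n), 1, 0, r = 0, g = sample(c(60, 200), n, TRUE), b = 0))
  truth <- ifelse(pc$g >= 115, "vegetation", "soil")
  # flip 5% of the truth labels to emulate symmetric classifier error
  flip <- withr::with_seed(62, sample.int(n, n * 0.05))
  truth[flip] <- ifelse(truth[flip] == "vegetation", "soil", "vegetation")
  cl <- classify_vegetation(pc)
  aud <- audit_classification(cl, truth, n_sample = 1000, seed = 63)
  expect_identical(aud$n_audited, 1000L)
  expect_gt(aud$accuracy, 0.93)
  expect_lt(aud$accuracy, 0.97)
  tab <- aud$confusion
  po <- sum(diag(tab)) / 1000
  pe <- sum(rowSums(tab) * colSums(tab)) / 1000^2
  expect_equal(aud$kappa, (po - pe) / (1 - pe))
  if (requireNamespace("e1071", quietly = TRUE))
    expect_equal(aud$kappa, e1071::classAgreement(tab)$kappa)
})

ridge_cloud <- function(x_centers, n_per = 400, length = 2, width = 0.05,
                        seed = 1) {
  withr::with_seed(seed, {
    parts <- lapply(x_centers, function(cx) {
      tibble::tibble(x = runif(n_per, cx - width / 2, cx + width / 2),
                     y = runif(n_per, 0, length),
                     z = runif(n_per, 0.5, 0.6),
                     r = 80L, g = 180L, b = 40L)
    })
    as_point_cloud(dplyr::bind_rows(parts))
  })
}

test_that("two ridges 0.76 m apart form exactly two clusters", {
  pc <- ridge_cloud(c(0, 0.76))
  rows <- extract_rows(pc)
  summ <- attr(rows, "row_summary")
  expect_identical(nrow(summ), 2L)
  expect_identical(sort(unique(rows$row_id)), c(1L, 2L))
  expect_lt(summ$mean_across[1], summ$mean_across[2])

  single <- extract_rows(ridge_cloud(0))
  expect_identical(nrow(attr(single, "row_summary")), 1L)
  expect_identical(nrow(single), 400L)
})

test_that("the 50-point cluster threshold keeps 50 and drops 49", {
  blob <- function(cx, n) withr::with_seed(71, tibble::tibble(
    x = runif(n, cx, cx + 0.1), y = runif(n, 0, 0.1), z = 0.5,
    r = 1L, g = 180L, b = 1L))
  pc <- as_point_cloud(dplyr::bind_rows(blob(0, 49), blob(5, 50),
                                        blob(10, 400)))
  rows <- extract_rows(pc)
  summ <- attr(rows, "row_summary")
  expect_identical(summ$n_points, c(50L, 400L))
  expect_identical(attr(rows, "n_dropped_points"), 49L)
})

test_that("voxel component labels agree with brute-force flood fill", {
  pc <- random_cloud(300, seed = 73, xr = c(0, 3), yr = c(0, 1),
                     zr = c(0, 0.6))
  for (conn in c(26, 6)) {
    xyz <- pc_mat(pc)
    iv <- canopyr:::voxelize(xyz, 0.15)
    uv <- unique(iv)
    got <- canopyr:::voxel_components(uv, connectivity = conn)
    want <- oracle_components(uv, connectivity = conn)
    # same partition: label vectors agree up to renaming
    expect_identical(table(table(got)), table(table(want)))
    cross <- table(got, want)
    expect_true(all(rowSums(cross > 0) == 1) && all(colSums(cross > 0) == 1))
  }
})

test_that("row extraction is invariant under grid-aligned translation", {
  pc <- ridge_cloud(c(0, 0.76, 1.52), seed = 5)
  base <- extract_rows(pc)
  shifted <- pc
  shifted$x <- shifted$x + 3 * 0.15
  shifted$z <- shifted$z + 2 * 0.15
  out <- extract_rows(shifted)
  expect_identical(out$row_id, base$row_id)
  expect_identical(nrow(attr(out, "row_summary")),
                   nrow(attr(base, "row_summary")))
})

test_that("border-row removal keeps the interior in cross-row order", {
  pc <- ridge_cloud(seq(0, by = 0.76, length.out = 8), n_per = 120, seed = 9)
  rows <- extract_rows(pc)
  expect_identical(nrow(attr(rows, "row_summary")), 8L)
  inner <- drop_border_rows(rows)
  expect_identical(sort(unique(inner$row_id)), 2:7)
  expect_gt(min(inner$x), min(rows$x))
  expect_lt(max(inner$x), max(rows$x))

  three <- extract_rows(ridge_cloud(c(0, 0.76, 1.52), seed = 2))
  one <- drop_border_rows(three)
  expect_identical(unique(one$row_id), 2L)

  two <- extract_rows(ridge_cloud(c(0, 0.76), seed = 3))
  expect_error(drop_border_rows(two), "at least 3 rows")
})

test_that("degenerate row-extraction inputs error cleanly", {
  pc <- ridge_cloud(0)
  expect_error(extract_rows(pc, grid_step = 0), "positive")
  expect_error(extract_rows(pc[0, ]), "empty")
})
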
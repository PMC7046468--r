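## Plate analytics: normalisation, Z', hit calling, exclusions, heatmaps.

test_that("percent of control follows the ratio definition", {
  expect_equal(percent_of_control(42.5, 85), 50)
  expect_equal(percent_of_control(85, c(80, 85, 90)), 100)
  expect_equal(percent_of_control(c(17, 85), 85), c(20, 100))
  expect_error(percent_of_control(50, numeric(0)), "normalization")
  expect_error(percent_of_control(50, c(0, 0)), "normalization")
})

test_that("Z' matches its closed form and limit cases", {
  set.seed(10)
  neg <- rnorm(16, 100, 5)
  pos <- rnorm(16, 20, 2)
  ## closed form on exact moments
  neg_e <- c(95, 100, 105, 100)   # mean 100, sd sqrt(50/3)
  expect_equal(zprime(c(100, 100), c(20, 20)), 1)           # zero variance
  expect_true(is.na(zprime(c(99, 101), c(99, 101))))        # equal means
  expect_error(zprime(100, c(1, 2)))
  z <- zprime(neg, pos)
  expect_equal(z, 1 - 3 * (sd(pos) + sd(neg)) / abs(mean(pos) - mean(neg)))
  ## affine invariance: same positive scale and shift on both groups
  expect_equal(zprime(2 * neg + 7, 2 * pos + 7), z, tolerance = 1e-12)
})

test_that("Z' closed-form worked example", {
  ## controls with sample mean 100, sd 5 (negative) and 20, sd 2 (positive)
  neg <- c(95, 105, 100 + 5 / sqrt(2), 100 - 5 / sqrt(2))
  pos <- c(18, 22, 20 + 2 / sqrt(2), 20 - 2 / sqrt(2))
  expect_equal(mean(neg), 100)
  expect_equal(sd(neg), 5, tolerance = 1e-12)
  expect_equal(sd(pos), 2, tolerance = 1e-12)
  expect_equal(zprime(neg, pos), 0.7375, tolerance = 1e-12)
})

test_that("hit calling applies the strict 85/115 cut-offs", {
  res <- data.table::data.table(
    well = sprintf("A%02d", 1:6),
    role = c(rep("compound", 5), "dmso"),
    pct_control = c(84, 86, 20, 130, 85, 50))
  out <- call_motility_hits(res)
  expect_equal(out$call[1:5],
               c("inhibitor_hit", "none", "inhibitor_hit",
                 "upregulator_flag", "none"))
  expect_true(is.na(out$call[6]))  # controls are never called
})

test_that("flagged wells are excluded from analysis and from the reference", {
  wells <- data.table::data.table(well = sprintf("A%02d", 1:6),
                                  median_vcl = c(80, 80, 80, 80, 10, 80))
  out <- exclude_wells(wells, data.frame(well = c("A02", "A05"),
                                         flag = c("autofocus_error",
                                                  "sticky_compound")))
  expect_equal(sum(out$excluded), 2)
  expect_equal(out$reason[out$well == "A05"], "sticky_compound")
  ## identity with no flags
  out2 <- exclude_wells(wells)
  expect_equal(sum(out2$excluded), 0)
})

test_that("plate analysis normalises DMSO to 100 and is idempotent", {
  layout <- plate_layout()
  set.seed(6)
  wells <- data.table::data.table(
    well = layout$well,
    n_tracks = 400,
    median_vcl = rnorm(384, 130, 5),
    flags = "")
  res <- analyze_plate_motility(wells, layout)
  dmso_pct <- res$results[role == "dmso", pct_control]
  expect_equal(median(dmso_pct), 100, tolerance = 1e-9)
  ## normalising already-normalised values changes nothing
  renorm <- percent_of_control(res$results$pct_control, dmso_pct)
  expect_equal(renorm, res$results$pct_control, tolerance = 1e-9)
  ## an excluded DMSO well drops out of the reference pool
  res2 <- analyze_plate_motility(wells, layout,
                                 flags = data.frame(well = "A24",
                                                    flag = "autofocus_error"))
  expect_true(res2$results[well == "A24", is.na(pct_control)])
  expect_equal(median(res2$results[role == "dmso" & !excluded, pct_control]),
               100, tolerance = 1e-9)
  expect_equal(nrow(res2$results) - sum(res2$results$excluded), 383)
})

test_that("hit calling is monotone in percent of control", {
  layout <- plate_layout()
  base <- data.table::data.table(well = layout$well, role = layout$role,
                                 pct_control = 90, excluded = FALSE)
  for (p in c(86, 85, 84.9, 50, 10, 0)) {
    base2 <- data.table::copy(base)
    base2[well == "A01", pct_control := p]
    call <- call_motility_hits(base2)[well == "A01", call]
    if (p < 85) expect_equal(call, "inhibitor_hit") else expect_equal(call, "none")
  }
})

test_that("heatmap grids expose plate geometry and edge effects", {
  layout <- plate_layout()
  uniform <- data.table::data.table(well = layout$well,
                                    row_idx = layout$row_idx,
                                    col_idx = layout$col_idx,
                                    pct_control = 100)
  hm <- plate_heatmap(uniform, "pct_control")
  expect_equal(length(hm$grid), 384)
  expect_equal(unname(diff(range(hm$row_means))), 0)
  expect_equal(unname(diff(range(hm$col_means))), 0)
  ## simulated edge effect: border wells at 80% of interior
  edged <- data.table::copy(uniform)
  edged[row_idx %in% c(1, 16) | col_idx %in% c(1, 24), pct_control := 80]
  hm2 <- plate_heatmap(edged, "pct_control")
  expect_lt(hm2$row_means[["A"]], mean(hm2$row_means[8:9]))
  csv <- tempfile(fileext = ".csv")
  png <- tempfile(fileext = ".png")
  plate_heatmap(edged, "pct_control", csv_path = csv, png_path = png)
  expect_true(file.exists(csv) && file.exists(png))
  grid_csv <- data.table::fread(csv)
  expect_equal(nrow(grid_csv), 17)  # 16 rows + column means
})
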
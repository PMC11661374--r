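test_that("feature extraction sums channel signal under each label", {
  mask <- matrix(0L, 4, 4)
  mask[1:2, 1:2] <- 1L
  ch <- array(3, c(4, 4, 1))
  tab <- extract_cell_features(mask, ch, "M1")
  expect_equal(tab$M1, 12)
  expect_equal(tab$area, 4)
  expect_equal(tab$x, 0.5)  # mean of 0-based columns 0,1
  expect_equal(tab$y, 0.5)

  mask2 <- matrix(0L, 5, 5)
  mask2[1:2, 1:2] <- 1L
  mask2[4:5, 4:5] <- 2L
  ch2 <- array(0, c(5, 5, 1))
  ch2[, , 1][mask2 == 1L] <- 1
  tab2 <- extract_cell_features(mask2, ch2, "M1")
  expect_equal(tab2$M1, c(4, 0))
  expect_equal(tab2$M1[1], tab2$area[1])
})

test_that("feature extraction equals a per-pixel brute-force accumulator", {
  set.seed(31)
  for (rep in 1:3) {
    mask <- matrix(sample(0:6, 64 * 64, replace = TRUE), 64, 64)
    stack <- array(runif(64 * 64 * 3), c(64, 64, 3))
    nm <- c("A", "B", "C")
    got <- extract_cell_features(mask, stack, nm)
    want <- oracle_cell_features(mask, stack, nm)
    expect_equal(got$area, unname(want[, "area"]))
    expect_equal(got$x, unname(want[, "x"]))
    expect_equal(got$y, unname(want[, "y"]))
    for (ch in nm) expect_equal(got[[ch]], unname(want[, ch]), tolerance = 1e-12)
  }
})

test_that("feature extraction validates inputs", {
  mask <- matrix(0L, 4, 4)
  expect_error(extract_cell_features(mask, array(1, c(3, 4, 1)), "M"),
               "4x4.*3x4")
  expect_warning(tab <- extract_cell_features(mask, array(1, c(4, 4, 1)), "M"),
                 "no cells")
  expect_equal(nrow(tab), 0)
})

test_that("size and nuclear filters match the brute-force quantile oracle", {
  cells <- as_cell_table(data.frame(cell_id = as.character(1:100),
                                    x = 0, y = 0, area = 1:100,
                                    DAPI = rep(5, 100), M = runif(100)),
                         markers = c("DAPI", "M"))
  # areas 1..100: type-7 bounds [5.95, 95.05] -> cells 6..95 pass on size
  got <- filter_cells(cells, dapi_channel = "M", dapi_quantile = 0)
  qa <- oracle_quantile(1:100, c(0.05, 0.95))
  expect_equal(qa, c(5.95, 95.05))
  kept_area <- cells$area >= qa[1] & cells$area <= qa[2]
  expect_equal(sum(kept_area), 90)

  # DAPI 0..99: q0.1 = 9.9, strict inequality -> 90 pass
  cells2 <- as_cell_table(data.frame(cell_id = as.character(1:100),
                                     x = 0, y = 0, area = 50, DAPI = 0:99),
                          markers = "DAPI")
  got2 <- filter_cells(cells2, size_quantile_range = c(0, 1))
  expect_equal(oracle_quantile(0:99, 0.1), 9.9)
  expect_equal(nrow(got2), 90)
  expect_true(all(got2$DAPI > 9.9))

  # combined filter equals independent re-application of recorded thresholds
  set.seed(32)
  cells3 <- as_cell_table(data.frame(cell_id = as.character(1:200), x = 0, y = 0,
                                     area = rlnorm(200, 4), DAPI = rlnorm(200)),
                          markers = "DAPI")
  kept <- filter_cells(cells3)
  th <- attr(kept, "filter_thresholds")
  manual <- cells3$area >= th$area_low & cells3$area <= th$area_high &
    cells3$DAPI > th$dapi
  expect_identical(kept$cell_id, cells3$cell_id[manual])
  expect_lte(nrow(kept), nrow(cells3))
})

test_that("a single cell passes the inclusive size bound but fails strict nuclear rule", {
  one <- as_cell_table(data.frame(cell_id = "c", x = 0, y = 0, area = 10,
                                  DAPI = 7), markers = "DAPI")
  out <- filter_cells(one)
  expect_equal(nrow(out), 0)
})

test_that("quantile scaling matches hand arithmetic and clips to [0, 1]", {
  cells <- as_cell_table(data.frame(cell_id = as.character(0:100), x = 0, y = 0,
                                    area = 1, M = 0:100), markers = "M")
  res <- normalize_features(cells, area_normalize = TRUE)
  expect_equal(res$record$q_low[["M"]], 5)
  expect_equal(res$record$q_high[["M"]], 95)
  expect_equal(res$cells$M[cells$M == 50], (50 - 5) / 90)
  expect_true(all(res$cells$M[cells$M >= 95] == 1))
  expect_true(all(res$cells$M[cells$M <= 5] == 0))
})

test_that("constant markers scale to zero with a warning", {
  cells <- as_cell_table(data.frame(cell_id = as.character(1:10), x = 0, y = 0,
                                    area = 1, K = rep(4, 10), M = 1:10),
                         markers = c("K", "M"))
  expect_warning(res <- normalize_features(cells), "constant")
  expect_true(all(res$cells$K == 0))
  expect_true(all(res$cells$M >= 0 & res$cells$M <= 1))
})

test_that("normalization equals the brute-force oracle and is monotone", {
  set.seed(33)
  for (rep in 1:5) {
    n <- 80
    cells <- as_cell_table(
      data.frame(cell_id = as.character(seq_len(n)), x = 0, y = 0,
                 area = runif(n, 1, 50),
                 A = rlnorm(n), B = runif(n, 0, 100), C = rpois(n, 3) * 1.0),
      markers = c("A", "B", "C"))
    res <- normalize_features(cells, area_normalize = TRUE)
    for (m in c("A", "B", "C")) {
      v <- cells[[m]] / cells$area
      qq <- oracle_quantile(v, c(0.05, 0.95))
      want <- if (qq[2] == qq[1]) rep(0, n) else
        pmin(pmax((v - qq[1]) / (qq[2] - qq[1]), 0), 1)
      expect_equal(res$cells[[m]], want, tolerance = 1e-12)
      ord <- order(v)
      expect_true(all(diff(res$cells[[m]][ord]) >= -1e-12))
      expect_true(all(res$cells[[m]][v >= qq[2]] == 1))
    }
  }
})
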
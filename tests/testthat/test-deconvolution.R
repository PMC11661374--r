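make_toy_spots <- function(counts, pitch = 50, width = 50) {
  n <- nrow(counts)
  spots <- data.frame(spot_id = sprintf("s%d", seq_len(n)),
                      a = seq_len(n), b = 1,
                      x = 50 + (seq_len(n) - 1) * pitch, y = 50,
                      stringsAsFactors = FALSE)
  new_spot_matrix(counts, spots, colnames(counts), pixel_size = width,
                  pitch = pitch, origin = c(50, 50))
}

test_that("cell-to-spot assignment follows the half-open footprint rule", {
  counts <- matrix(1, 2, 2, dimnames = list(NULL, c("g1", "g2")))
  sm <- make_toy_spots(counts, pitch = 100, width = 50)  # centers x=50,150; gaps
  cells <- as_cell_table(data.frame(
    cell_id = c("center", "gap", "right_edge", "left_edge", "outside"),
    x = c(50, 100, 75, 25, 400), y = c(50, 50, 50, 50, 50),
    area = 1), markers = character())
  asg <- assign_cells_to_spots(cells, sm)
  expect_equal(asg$spot_id[asg$cell_id == "center"], "s1")
  expect_true(is.na(asg$spot_id[asg$cell_id == "gap"]))        # midway in gap
  expect_true(is.na(asg$spot_id[asg$cell_id == "right_edge"])) # x = cx + w/2
  expect_equal(asg$spot_id[asg$cell_id == "left_edge"], "s1")  # x = cx - w/2
  expect_true(is.na(asg$spot_id[asg$cell_id == "outside"]))
})

test_that("assignment agrees with simulator truth and rejects overlapping footprints", {
  d <- make_small_dataset(seed = 61)
  asg <- assign_cells_to_spots(d$tissue$cells, d$spots)
  expect_identical(asg$spot_id, d$spots$truth$assignment$spot_id)
  bad <- d$spots
  bad$pixel_size <- bad$pitch + 1
  expect_error(assign_cells_to_spots(d$tissue$cells, bad), "overlap")
})

test_that("proportions are exact count fractions with empty spots flagged", {
  counts <- matrix(0, 3, 1, dimnames = list(NULL, "g"))
  sm <- make_toy_spots(counts)
  asg <- data.frame(cell_id = c("c1", "c2", "c3", "c4"),
                    spot_id = c("s1", "s2", "s2", "s2"))
  labels <- c(c1 = "A", c2 = "A", c3 = "A", c4 = "B")
  pr <- compute_proportions(asg, labels, type_universe = c("A", "B"),
                            spot_ids = sm$spots$spot_id)
  expect_equal(pr$beta[, "s1"], c(A = 1, B = 0))
  expect_equal(pr$beta[, "s2"], c(A = 2 / 3, B = 1 / 3))
  expect_equal(pr$beta[, "s3"], c(A = 0, B = 0))
  expect_true(pr$empty[["s3"]])
  expect_equal(unname(colSums(pr$beta[, !pr$empty])), c(1, 1))

  expect_error(compute_proportions(asg, labels[-2], type_universe = c("A", "B")),
               "c2")
})

test_that("signature aggregation is the arithmetic mean per type", {
  expr <- rbind(c(1, 3), c(3, 5), c(10, 2))
  colnames(expr) <- c("g1", "g2")
  mu <- aggregate_signatures(expr, c("A", "A", "B"))
  expect_equal(mu["A", ], c(g1 = 2, g2 = 4))
  expect_equal(mu["B", ], c(g1 = 10, g2 = 2))
  # duplicating every profile leaves the mean unchanged
  mu2 <- aggregate_signatures(rbind(expr, expr), rep(c("A", "A", "B"), 2))
  expect_equal(mu2, mu)
  # one profile per type: the signature row is that profile
  mu3 <- aggregate_signatures(expr[c(1, 3), ], c("A", "B"))
  expect_equal(mu3["A", ], expr[1, ])
  expect_error(aggregate_signatures(expr, c("A", "A", "B"), types = c("A", "C")),
               "C")
})

test_that("spot splitting reproduces the allocation formula on hand cases", {
  # two types, one gene each case checked by hand
  counts <- matrix(c(7, 10, 4), 3, 1, dimnames = list(NULL, "g1"))
  sm <- make_toy_spots(counts)
  beta <- matrix(c(1, 0, 0.5, 0.5, 0.5, 0.5), 2, 3,
                 dimnames = list(c("A", "B"), sm$spots$spot_id))
  pr <- structure(list(beta = beta, n_cells = setNames(c(1, 2, 2), sm$spots$spot_id),
                       empty = setNames(rep(FALSE, 3), sm$spots$spot_id)),
                  class = "spot_proportions")
  mu <- matrix(c(2, 6), 2, 1, dimnames = list(c("A", "B"), "g1"))

  ss <- split_spots(sm, pr, mu)
  get <- function(spot, type) ss$counts[paste(spot, type, sep = "|"), "g1"]
  expect_equal(get("s1", "A"), 7)                  # single-type spot
  expect_false("s1|B" %in% rownames(ss$counts))    # beta 0 -> no sub-spot
  expect_equal(get("s2", "A"), 10 * 0.5 * 2 / 4)   # 2.5
  expect_equal(get("s2", "B"), 10 * 0.5 * 6 / 4)   # 7.5

  # degenerate gene: mu column all zero (types still have signal elsewhere)
  counts2 <- cbind(counts, g2 = c(3, 6, 9))
  sm2 <- make_toy_spots(counts2)
  mu0 <- matrix(c(0, 0, 1, 2), 2, 2, dimnames = list(c("A", "B"), c("g1", "g2")))
  ss_beta <- split_spots(sm2, pr, mu0, zero_denominator_policy = "beta")
  expect_equal(ss_beta$counts["s3|A", "g1"], 2)  # x = 4 split by beta alone
  expect_equal(ss_beta$counts["s3|B", "g1"], 2)
  ss_drop <- split_spots(sm2, pr, mu0, zero_denominator_policy = "drop")
  expect_equal(unname(ss_drop$unassigned["s3", "g1"]), 4)
  expect_equal(unname(ss_drop$counts[c("s3|A", "s3|B"), "g1"]), c(0, 0))
})

test_that("splitting mu with an all-zero row is rejected, as is a type mismatch", {
  counts <- matrix(1, 1, 1, dimnames = list(NULL, "g1"))
  sm <- make_toy_spots(counts)
  pr <- structure(list(beta = matrix(c(0.5, 0.5), 2, 1,
                                     dimnames = list(c("A", "B"), "s1")),
                       n_cells = c(s1 = 2), empty = c(s1 = FALSE)),
                  class = "spot_proportions")
  expect_error(split_spots(sm, pr, matrix(c(1, 0), 2, 1,
                                          dimnames = list(c("A", "C"), "g1"))),
               "type names")
  expect_error(split_spots(sm, pr, matrix(c(1, 0), 2, 1,
                                          dimnames = list(c("A", "B"), "g1"))),
               "all-zero")
})

test_that("splitting conserves counts and respects support on random instances", {
  set.seed(62)
  for (rep in 1:10) {
    S <- sample(3:20, 1); G <- sample(5:40, 1); K <- sample(2:5, 1)
    counts <- matrix(rpois(S * G, 8), S, G,
                     dimnames = list(NULL, sprintf("g%d", seq_len(G))))
    sm <- make_toy_spots(counts)
    ncell <- sample(1:6, S, replace = TRUE)
    raw <- matrix(rmultinom(1, sum(ncell) * 3, rep(1, S * K)), K, S) * 1.0
    beta <- sweep(raw, 2, pmax(colSums(raw), 1), "/")
    dimnames(beta) <- list(sprintf("T%d", 1:K), sm$spots$spot_id)
    pr <- structure(list(beta = beta,
                         n_cells = setNames(pmax(ncell, 1), sm$spots$spot_id),
                         empty = setNames(rep(FALSE, S), sm$spots$spot_id)),
                    class = "spot_proportions")
    mu <- matrix(rgamma(K * G, 0.5), K, G,
                 dimnames = list(rownames(beta), colnames(counts)))
    mu[sample(length(mu), round(length(mu) / 4))] <- 0
    mu <- mu + (rowSums(mu) == 0)   # avoid all-zero rows
    ss <- split_spots(sm, pr, mu)
    recon <- rowsum(ss$counts, ss$keys$spot_id)
    x <- counts[match(rownames(recon), sm$spots$spot_id), , drop = FALSE]
    expect_lt(max(abs(recon - x) / pmax(x, 1)), 1e-9)
    expect_true(all(ss$counts >= 0))
    # support: positive mass only where beta > 0
    expect_true(all(ss$keys$beta > 0))
  }
})

test_that("splitting is invariant to per-gene scaling of mu and maps per-type scaling to beta", {
  set.seed(63)
  counts <- matrix(rpois(40, 10), 4, 10,
                   dimnames = list(NULL, sprintf("g%d", 1:10)))
  sm <- make_toy_spots(counts)
  beta <- matrix(runif(8), 2, 4); beta <- sweep(beta, 2, colSums(beta), "/")
  dimnames(beta) <- list(c("A", "B"), sm$spots$spot_id)
  pr <- structure(list(beta = beta, n_cells = setNames(rep(2, 4), sm$spots$spot_id),
                       empty = setNames(rep(FALSE, 4), sm$spots$spot_id)),
                  class = "spot_proportions")
  mu <- matrix(rgamma(20, 1) + 0.05, 2, 10,
               dimnames = list(c("A", "B"), colnames(counts)))
  base <- split_spots(sm, pr, mu)

  gene_scale <- runif(10, 0.2, 5)
  scaled <- split_spots(sm, pr, sweep(mu, 2, gene_scale, "*"))
  expect_equal(scaled$counts, base$counts, tolerance = 1e-12)

  ck <- c(A = 2.5, B = 0.4)
  beta2 <- beta * ck
  beta2 <- sweep(beta2, 2, colSums(beta2), "/")
  pr2 <- pr; pr2$beta <- beta2
  via_beta <- split_spots(sm, pr2, mu)
  via_mu <- split_spots(sm, pr, mu * ck)
  expect_equal(via_beta$counts, via_mu$counts, tolerance = 1e-12)
})

test_that("protein sub-spots mirror the RNA sub-spot keys and average cells", {
  cells <- as_cell_table(data.frame(
    cell_id = c("c1", "c2", "c3"), x = 0, y = 0, area = 1,
    type = c("A", "A", "B"), M1 = c(0.2, 0.6, 1.0), M2 = c(0, 0.4, 0.8)),
    markers = c("M1", "M2"))
  asg <- data.frame(cell_id = c("c1", "c2", "c3"),
                    spot_id = c("s1", "s1", "s1"))
  agg <- aggregate_codex_subspots(cells, asg)
  expect_equal(agg$protein["s1|A", "M1"], 0.4)
  expect_equal(agg$protein["s1|A", "M2"], 0.2)
  expect_equal(agg$protein["s1|B", "M1"], 1.0)
  expect_equal(agg$keys$n_cells, c(2, 1))

  # keys coincide with RNA sub-spots built from the same assignment
  counts <- matrix(5, 1, 2, dimnames = list(NULL, c("g1", "g2")))
  sm <- make_toy_spots(counts)
  pr <- compute_proportions(asg, setNames(cells$type, cells$cell_id),
                            type_universe = c("A", "B"),
                            spot_ids = sm$spots$spot_id)
  mu <- matrix(1, 2, 2, dimnames = list(c("A", "B"), c("g1", "g2")))
  ss <- split_spots(sm, pr, mu)
  expect_setequal(rownames(ss$counts), rownames(agg$protein))
})
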
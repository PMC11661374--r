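make_linked_dataset <- function(seed = 71, n = 300, sep = 6) {
  # two modalities measuring the same two features for two well-separated types
  withr::with_seed(seed, {
    lab <- rep(c("A", "B"), each = n / 2)
    centers <- rbind(A = c(1, 5), B = c(5, 1))
    ref <- centers[lab, ] + matrix(rnorm(n * 2, 0, 0.2), n, 2)
    colnames(ref) <- c("f1", "f2")
    rownames(ref) <- sprintf("r%03d", seq_len(n))
    cdx <- centers[lab, ] + matrix(rnorm(n * 2, 0, 0.2), n, 2)
    colnames(cdx) <- c("f1", "f2")
    cells <- as_cell_table(data.frame(cell_id = sprintf("c%03d", seq_len(n)),
                                      x = 0, y = 0, area = 1,
                                      f1 = cdx[, 1], f2 = cdx[, 2]),
                           markers = c("f1", "f2"))
    list(ref = ref, ref_labels = setNames(lab, rownames(ref)),
         cells = cells, true_labels = setNames(lab, cells$cell_id))
  })
}

test_that("feature linkage resolves names, aliases and the deviation screen", {
  set.seed(72)
  ref <- matrix(rnorm(600), 100, 6,
                dimnames = list(NULL, c("MS4A1", "CD3E", "g3", "g4", "g5", "g6")))
  cdx <- cbind(CD20 = rnorm(100), CD3E = rnorm(100), FLAT = rep(1, 100),
               UNMATCHED = rnorm(100))
  lk <- link_features(ref, cdx, alias_map = list(CD20 = "MS4A1"))
  expect_setequal(lk$protein[lk$retained], c("CD20", "CD3E"))
  expect_equal(lk$gene[lk$protein == "CD20"], "MS4A1")
  expect_false("UNMATCHED" %in% lk$protein)

  # constant protein feature fails the screen with a reason
  ref2 <- cbind(ref, FLAT = rnorm(100))
  lk2 <- link_features(ref2, cdx, alias_map = list(CD20 = "MS4A1"))
  expect_false(lk2$retained[lk2$protein == "FLAT"])
  expect_match(lk2$reason[lk2$protein == "FLAT"], "protein_sd")

  # screen matches a brute-force sd scan
  set.seed(73)
  g <- sprintf("g%02d", 1:30)
  refm <- matrix(rnorm(3000), 100, 30, dimnames = list(NULL, g))
  cdxm <- matrix(rnorm(3000), 100, 30, dimnames = list(NULL, g))
  flat <- sample(30, 5)
  cdxm[, flat] <- matrix(rep(cdxm[1, flat], each = 100), 100)  # constant columns
  lk3 <- link_features(refm, cdxm)
  expect_equal(sum(lk3$retained), 25)
  expect_setequal(lk3$protein[!lk3$retained], g[flat])

  expect_error(link_features(refm[, 1, drop = FALSE] * 0 + 1,
                             cdxm[, 1, drop = FALSE]),
               "screen|linkable")
})

test_that("pivot matching is pure on separable data and deterministic", {
  d <- make_linked_dataset()
  lk <- link_features(d$ref, d$cells)
  pv <- match_pivots(d$ref, d$cells, lk, seed = 1)
  expect_true(all(d$ref_labels[pv$ref_id] == d$true_labels[pv$cell_id]))
  expect_equal(nrow(pv), ceiling(0.10 * nrow(d$cells)))
  expect_false(anyDuplicated(pv$cell_id) > 0)

  pv2 <- match_pivots(d$ref, d$cells, lk, seed = 1)
  expect_identical(pv, pv2)

  # pivot_fraction = 1 returns every mutual-nearest candidate
  pv_all <- match_pivots(d$ref, d$cells, lk, pivot_fraction = 1, seed = 1)
  expect_gte(nrow(pv_all), nrow(pv))

  expect_error(match_pivots(d$ref, d$cells, lk, n_components = 50),
               "n_components")
})

test_that("zero smoothing weight is the identity on linked features", {
  set.seed(74)
  target <- matrix(rnorm(40), 10, 4)
  space <- matrix(rnorm(80), 10, 8)
  expect_identical(spotsplit:::knn_smooth(target, space, k = 3, w = 0), target)
  smoothed <- spotsplit:::knn_smooth(target, space, k = 3, w = 0.3)
  expect_false(identical(smoothed, target))
})

test_that("label transfer is exact and permutation-equivariant", {
  d <- make_linked_dataset()
  lk <- link_features(d$ref, d$cells)
  pv <- match_pivots(d$ref, d$cells, lk, seed = 1)
  lab <- transfer_labels(pv, d$ref_labels)
  expect_equal(unname(lab$label), unname(d$ref_labels[lab$ref_id]))
  expect_setequal(unique(lab$label), c("A", "B"))

  perm <- c(A = "typeB", B = "typeA")
  lab2 <- transfer_labels(pv, setNames(perm[d$ref_labels], names(d$ref_labels)))
  expect_equal(unname(lab2$label), unname(perm[lab$label]))

  incomplete <- d$ref_labels[setdiff(names(d$ref_labels), pv$ref_id[1])]
  expect_error(transfer_labels(pv, incomplete), "without labels")
})

test_that("label propagation is perfect on separable pivots and consistent", {
  d <- make_linked_dataset()
  lk <- link_features(d$ref, d$cells)
  pv <- transfer_labels(match_pivots(d$ref, d$cells, lk, seed = 1), d$ref_labels)
  out <- propagate_labels(pv, d$cells, seed = 2)
  expect_equal(unname(out$f1), rep(1, 2))
  expect_equal(out$macro_f1, 1)
  expect_equal(mean(out$labels$label == d$true_labels[out$labels$cell_id]), 1)

  # a non-pivot cell identical to a pivot receives that pivot's class
  pivot1 <- pv$cell_id[1]
  clone <- d$cells[d$cells$cell_id == pivot1, ]
  clone$cell_id <- "clone"
  cells2 <- as_cell_table(rbind(as.data.frame(d$cells), clone),
                          markers = marker_names(d$cells))
  out2 <- propagate_labels(pv, cells2, seed = 2)
  expect_equal(out2$labels$label[out2$labels$cell_id == "clone"],
               pv$label[pv$cell_id == pivot1])

  single <- pv[pv$label == "A", ]
  expect_error(propagate_labels(single, d$cells), "2 pivot classes")
})

test_that("pivot quality degrades monotonically with imaging noise", {
  purities <- vapply(c(0.1, 0.6, 1.5), function(cv) {
    ts <- generate_tissue(n_cells = 600, n_types = 3, n_genes = 60,
                          n_markers = 9, seed = 75)
    cd <- render_codex(ts, noise_config(protein_cv = cv), seed = 76)
    cells <- normalize_features(cd)$cells
    ref <- render_reference(ts, 600, seed = 77)
    refn <- lognormalize_counts(ref$counts)
    lk <- link_features(refn, cells, alias_map = ts$marker_genes)
    pv <- match_pivots(refn, cells, lk, seed = 78)
    truth <- setNames(ts$cells$type, ts$cells$cell_id)
    mean(ref$labels[pv$ref_id] == truth[pv$cell_id])
  }, numeric(1))
  expect_true(all(diff(purities) <= 0.02))  # non-increasing up to MC slack
  expect_gt(purities[1], 0.95)
})
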
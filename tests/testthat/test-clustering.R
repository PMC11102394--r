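test_that("unity normalization rescales, fixes points, flags degeneracy", {
  expect_equal(as.numeric(normalize_unity(c(2, 4, 6))), c(0, 0.5, 1))
  expect_equal(as.numeric(normalize_unity(c(0, 0.5, 1))), c(0, 0.5, 1))
  expect_warning(out <- normalize_unity(c(3, 3, 3)), "degenerate")
  expect_equal(as.numeric(out), c(0, 0, 0))
  expect_error(normalize_unity(1:3, mask = c(FALSE, FALSE, FALSE)), "empty")
})

test_that("normalization restricts to the mask", {
  v <- c(100, 2, 4, 6)
  out <- normalize_unity(v, mask = c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(as.numeric(out), c(0, 0, 0.5, 1))
})

test_that("complete linkage merges the hand-computed pair first", {
  m <- rbind(a = c(0, 0), b = c(0, 1), c = c(5, 5))
  hc <- hcluster(m, method = "complete")
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))
  expect_equal(hc$height[1], 1)
  expect_true(all(diff(hc$height) >= 0))
})

test_that("duplicated rows merge at height zero", {
  m <- rbind(a = c(1, 2), b = c(1, 2), c = c(9, 9))
  hc <- hcluster(m)
  expect_equal(hc$height[1], 0)
})

test_that("tree cuts behave at the extremes and recover planted groups", {
  set.seed(14)
  m <- rbind(matrix(rnorm(20, 0, 0.1), 4), matrix(rnorm(20, 10, 0.1), 4))
  rownames(m) <- paste0("t", 1:8)
  hc <- hcluster(m)
  expect_equal(cut_model(hc, 8)$k, 8)
  expect_equal(unname(cut_model(hc, 1)$assignment), rep(1L, 8))
  expect_error(cut_model(hc, 0), "out of range")
  planted <- rep(1:2, each = 4)
  got <- cut_model(hc, 2)$assignment
  expect_equal(rand_index(got, planted)$adjusted_rand, 1)
})

test_that("ward and complete agree on well-separated planted groups", {
  set.seed(15)
  m <- rbind(matrix(rnorm(30, 0, 0.2), 5), matrix(rnorm(30, 8, 0.2), 5))
  rownames(m) <- paste0("t", 1:10)
  a <- cut_model(hcluster(m, "complete"), 2)$assignment
  b <- cut_model(hcluster(m, "ward"), 2)$assignment
  expect_equal(rand_index(a, b)$adjusted_rand, 1)
})

test_that("clustering is invariant to positive affine rescaling of a topic", {
  grid <- voxel_grid(c(4, 4, 1), spacing = 2)
  mask <- array(TRUE, dim = grid$shape)
  set.seed(16)
  mk <- function(v) volume(grid, array(v, dim = grid$shape), mask = mask)
  raw <- replicate(4, rnorm(16), simplify = FALSE)
  zs1 <- lapply(raw, mk); names(zs1) <- paste0("t", 1:4)
  zs2 <- lapply(raw, function(v) mk(3.7 * v + 11)); names(zs2) <- names(zs1)
  tm1 <- topic_matrix(zs1, mask); tm2 <- topic_matrix(zs2, mask)
  expect_equal(tm1$values, tm2$values)
  expect_equal(hcluster(tm1)$merge, hcluster(tm2)$merge)
})

test_that("row permutation permutes but never changes cluster composition", {
  set.seed(17)
  m <- rbind(matrix(rnorm(12, 0, 0.1), 3), matrix(rnorm(12, 6, 0.1), 3))
  rownames(m) <- paste0("t", 1:6)
  perm <- c(4, 1, 6, 2, 5, 3)
  a <- cut_model(hcluster(m), 2)$assignment
  b <- cut_model(hcluster(m[perm, ]), 2)$assignment[rownames(m)]
  expect_equal(rand_index(a, b)$adjusted_rand, 1)
})

test_that("reconciliation keeps close whole-brain splits, breaks far ones", {
  # cerebellar solution: {A,B} {C,D}; whole-brain tree splits both pairs,
  # A/B joining low, C/D joining at the maximum height
  m_cb <- rbind(A = c(0, 0), B = c(0.1, 0), C = c(8, 0), D = c(8.1, 0))
  cb <- cut_model(hcluster(m_cb), 2)
  m_wb <- rbind(A = c(0, 0), B = c(3, 0), C = c(20, 0), D = c(45, 0))
  wb <- hcluster(m_wb)
  rec <- reconcile(cb, wb, k_wb = 4, split_ratio_threshold = 0.5)
  a <- rec$assignment
  expect_equal(a[["A"]], a[["B"]])   # kept: joined at 3 of max 45
  expect_false(a[["C"]] == a[["D"]]) # split: joined at 25 > 0.5 * max
  expect_equal(rec$k, 3)
  expect_setequal(rec$decisions$action, c("kept", "split"))
})

test_that("identical solutions reconcile to themselves with no decisions", {
  m <- rbind(A = c(0, 0), B = c(0.1, 0), C = c(8, 0), D = c(8.1, 0))
  cb <- cut_model(hcluster(m), 2)
  rec <- reconcile(cb, hcluster(m), k_wb = 2)
  expect_equal(rand_index(rec$assignment, cb$assignment)$adjusted_rand, 1)
  expect_equal(nrow(rec$decisions), 0)
})
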
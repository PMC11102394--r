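test_that("world/voxel conversion is exact on identity-scaled affines", {
  grid <- voxel_grid(c(10, 10, 10), spacing = 2, origin = c(0, 0, 0))
  expect_equal(world_to_voxel(c(4, 6, 8), grid),
               matrix(c(2L, 3L, 4L), 1))
  expect_equal(voxel_to_world(c(0, 0, 0), grid), matrix(c(0, 0, 0), 1))
})

test_that("roundtrip error is below half a voxel on random in-grid points", {
  grid <- cerebellar_grid(2)
  set.seed(42)
  lo <- grid$affine[1:3, 4]
  hi <- lo + (grid$shape - 1) * grid$spacing
  pts <- cbind(runif(1000, lo[1], hi[1]), runif(1000, lo[2], hi[2]),
               runif(1000, lo[3], hi[3]))
  back <- voxel_to_world(world_to_voxel(pts, grid), grid)
  expect_lt(max(abs(back - pts)), grid$spacing / 2 + 1e-12)
})

test_that("out-of-grid coordinates raise an error naming the axis", {
  grid <- cerebellar_grid(2)
  expect_error(world_to_voxel(c(1e3, -50, -30), grid), "axis x")
  expect_error(world_to_voxel(c(0, 50, -30), grid), "axis y")
})

test_that("label volumes roundtrip exactly through NIfTI", {
  grid <- voxel_grid(c(10, 10, 10), spacing = 2, origin = c(-10, -20, -30))
  set.seed(1)
  vol <- volume(grid, array(sample(0:7, 1000, TRUE), dim = c(10, 10, 10)))
  path <- tempfile(fileext = ".nii.gz")
  write_label_volume(vol, path)
  back <- read_volume(path)
  expect_identical(as.integer(back$values), as.integer(vol$values))
  expect_equal(back$grid$affine, grid$affine)
  expect_equal(back$grid$spacing, grid$spacing)
})

test_that("float volumes roundtrip within float32 precision", {
  grid <- voxel_grid(c(6, 6, 6), spacing = 4, origin = c(0, 0, 0))
  set.seed(2)
  vol <- volume(grid, array(rnorm(216), dim = c(6, 6, 6)))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_lt(max(abs(back$values - vol$values)), 1e-6)
})

test_that("negative labels are rejected by the label writer", {
  grid <- voxel_grid(c(3, 3, 3), spacing = 1)
  vol <- volume(grid, array(-1, dim = c(3, 3, 3)))
  expect_error(write_label_volume(vol, tempfile(fileext = ".nii")),
               "negative label")
})

test_that("foci tables read with studies grouped and malformed rows named", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("study_id,x,y,z,n,topic,flags",
               "a,-10,-60,-20,12,t1,",
               "a,-12,-62,-22,12,t1,",
               "b,20,-70,-30,20,t2,patients"), path)
  db <- read_foci_table(path)
  expect_s3_class(db, "topic_database")
  expect_equal(nrow(db$studies), 2)
  expect_equal(as.integer(table(db$foci$study_id)[c("a", "b")]), c(2L, 1L))
  expect_equal(db$studies$screening_flags[[2]], "patients")

  bad <- tempfile(fileext = ".csv")
  writeLines(c("study_id,x,y,z,n,topic", "a,NA,-60,-20,12,t1"), bad)
  expect_error(read_foci_table(bad), "row 1")

  noz <- tempfile(fileext = ".csv")
  writeLines(c("study_id,x,y,n,topic", "a,1,2,12,t1"), noz)
  expect_error(read_foci_table(noz), "missing mandatory column")

  empty <- tempfile(fileext = ".csv")
  writeLines("study_id,x,y,z,n,topic", empty)
  expect_warning(db0 <- read_foci_table(empty), "empty")
  expect_equal(nrow(db0$studies), 0)
})

test_that("foci tables roundtrip through the TSV writer", {
  sc <- reference_scenario(n_groups = 2, topics_per_group = 1)
  db <- generate_database(sim_config(studies_per_topic = 5, seed = 3),
                          sc$truth)
  path <- tempfile(fileext = ".tsv")
  write_foci_table(db, path)
  back <- read_foci_table(path)
  expect_equal(back$studies$study_id, db$studies$study_id)
  expect_equal(back$foci$x, db$foci$x, tolerance = 1e-9)
  expect_equal(studies_per_topic(back), studies_per_topic(db))
})
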
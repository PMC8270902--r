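# Cohort data model, NIfTI round trips, manifest reading, configuration.

test_that("volumes round-trip through NIfTI with data and affine intact", {
  g <- voxel_grid(c(2, 2, 2), c(8L, 6L, 4L))
  vol <- array(rnorm(prod(g$dim)), g$dim)
  path <- file.path(withr::local_tempdir(), "vol.nii.gz")
  write_map(vol, g, path)
  back <- read_map(path)
  expect_equal(array(as.numeric(back), g$dim), vol, tolerance = 1e-7)
  expect_equal(attr(back, "grid")$affine, g$affine, tolerance = 1e-6)

  mask <- array(vol > 0, g$dim)
  write_map(mask, g, path)
  expect_identical(array(read_map(path) > 0.5, g$dim), mask)

  expect_error(write_map(vol, g, file.path(tempdir(), "no_such_dir", "x.nii")),
               "directory does not exist")
})

test_that("a written cohort reads back with counts, grids and zones preserved", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  manifest <- write_cohort(co, dir)
  back <- read_cohort(manifest, dir)
  expect_length(back$controls, length(co$controls))
  expect_length(back$patients, 1L)
  expect_identical(back$grid$dim, co$grid$dim)
  expect_identical(back$brain_mask, co$brain_mask)
  expect_identical(names(back$resection_zones), "pat001")
  expect_equal(back$patients[[1]]$md, co$patients[[1]]$md, tolerance = 1e-6)
  expect_identical(back$atlas$legend$lobe, co$atlas$legend$lobe)
})

test_that("manifest errors name the subject and metric, and reject bad tokens", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  manifest <- write_cohort(co, dir)

  file.remove(file.path(dir, "ctrl002_mk.nii.gz"))
  expect_error(read_cohort(manifest, dir), "mk.*ctrl002|ctrl002.*mk")

  # restore, then corrupt one subject's grid: mismatch must error, not resample
  co2 <- small_cohort()
  dir2 <- withr::local_tempdir()
  manifest2 <- write_cohort(co2, dir2)
  g_odd <- voxel_grid(c(3, 3, 3), co2$grid$dim)
  write_map(co2$controls[[1]]$md, g_odd, file.path(dir2, "ctrl001_md.nii.gz"))
  expect_error(read_cohort(manifest2, dir2), "mismatch.*ctrl001")

  man <- read.csv(manifest2, stringsAsFactors = FALSE)
  man$group[1] <- "healthy"
  write.csv(man, manifest2, row.names = FALSE)
  expect_error(read_cohort(manifest2, dir2), "unknown group token")
})

test_that("map-set and cohort constructors enforce the type invariants", {
  g <- voxel_grid(2, c(6L, 6L, 6L))
  ok <- array(0.5, g$dim)
  expect_s3_class(parametric_map_set("s1", "control", "F", 30,
                                     ok, ok, ok, g), "parametric_map_set")
  bad_fa <- ok; bad_fa[1] <- 1.5
  expect_error(parametric_map_set("s1", "control", "F", 30, ok, bad_fa, ok, g),
               "FA outside")
  bad_md <- ok; bad_md[1] <- -1
  expect_error(parametric_map_set("s1", "control", "F", 30, bad_md, ok, ok, g),
               "negative MD or MK")
  expect_error(parametric_map_set("s1", "control", "F", -5, ok, ok, ok, g),
               "age")
  expect_error(parametric_map_set("s1", "control", "F", 30,
                                  array(0.5, c(4, 4, 4)), ok, ok, g),
               "dimensions")

  s <- parametric_map_set("s1", "control", "F", 30, ok, ok, ok, g)
  p <- parametric_map_set("p1", "patient", "M", 28, ok, ok, ok, g)
  lab <- array(0L, g$dim); lab[4:6, , ] <- 1L; lab[1:3, , ] <- 2L
  atlas <- lobe_atlas(lab, data.frame(label = 1:2, lobe = "lobeA",
                                      hemisphere = c("right", "left")))
  mask <- array(TRUE, g$dim)
  expect_s3_class(make_cohort(list(s), list(p), mask, atlas, grid = g),
                  "idrark_cohort")
  expect_error(make_cohort(list(s), list(p), mask, atlas,
                           list(zz = mask), g), "unknown patients")
  s2 <- s; s2$grid <- voxel_grid(3, g$dim)
  expect_error(make_cohort(list(s2), list(p), mask, atlas, grid = g),
               "mismatch")
})

test_that("atlas symmetry validation catches asymmetric parcellations", {
  d <- c(4L, 2L, 2L)
  labels <- array(0L, d)
  labels[3:4, , ] <- 1L; labels[1:2, , ] <- 2L
  legend <- data.frame(label = 1:2, lobe = "lobeA",
                       hemisphere = c("right", "left"))
  expect_s3_class(lobe_atlas(labels, legend), "lobe_atlas")
  labels[1, 1, 1] <- 0L  # break mirror symmetry
  expect_error(lobe_atlas(labels, legend), "symmetric")
  legend_bad <- data.frame(label = 1L, lobe = "lobeA", hemisphere = "right")
  expect_error(lobe_atlas(array(1:2, d), legend_bad), "missing from legend")
})

test_that("configuration defaults match the protocol and files override them", {
  cfg <- idrark_config()
  expect_equal(cfg$fa_skeleton_threshold, 0.2)
  expect_equal(cfg$voxelwise_p, 0.001)
  expect_equal(cfg$fwe_alpha, 0.05)
  expect_equal(cfg$min_cluster_voxels, 20L)
  expect_equal(cfg$erz_dilation_mm, 10)
  expect_equal(cfg$ppv_success_threshold, 0.5)

  yml <- file.path(withr::local_tempdir(), "cfg.yaml")
  writeLines(c("fa_skeleton_threshold: 0.3", "n_permutations: 15"), yml)
  cfg2 <- read_config(yml)
  expect_equal(cfg2$fa_skeleton_threshold, 0.3)
  expect_equal(cfg2$n_permutations, 15L)
  expect_equal(cfg2$min_cluster_voxels, 20L)

  writeLines("not_a_key: 1", yml)
  expect_error(read_config(yml), "unknown config keys")
  expect_error(idrark_config(ppv_success_threshold = 1.2), "\\(0, 1\\]")
  expect_error(idrark_config(cluster_connectivity = 5), "connectivity")
})
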
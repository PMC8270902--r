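# Resection-zone dilation, cluster-level PPV, SD/UD/NS classification and
# the cohort accuracy / detection-rate arithmetic.

test_that("eRZ dilation matches brute-force offset enumeration", {
  d <- c(20L, 20L, 20L)
  rz <- array(FALSE, d); rz[10, 10, 10] <- TRUE
  erz <- extend_resection_zone(rz, voxel_mm = 2, dilation_mm = 10)
  # oracle: all integer offsets with Euclidean norm <= 5 voxels
  off <- expand.grid(dx = -5:5, dy = -5:5, dz = -5:5)
  n_ball <- sum(off$dx^2 + off$dy^2 + off$dz^2 <= 25)
  expect_equal(sum(erz), n_ball)
  expect_identical(erz, dilate_ball_for_test(rz, 2, 10))

  expect_identical(extend_resection_zone(rz, 2, 0), rz)
  expect_true(all(erz[rz]))

  # anisotropic voxels scale per axis
  erz_a <- extend_resection_zone(rz, voxel_mm = c(1, 2, 4), dilation_mm = 4)
  expect_identical(erz_a, dilate_ball_for_test(rz, c(1, 2, 4), 4))

  expect_error(extend_resection_zone(array(FALSE, d), 2, 10), "empty")
})

# four well-separated 27-voxel cube clusters in a 40^3 volume
four_cluster_map <- function() {
  d <- c(40L, 40L, 40L)
  m <- array(FALSE, d)
  at <- list(c(4, 4, 4), c(4, 4, 24), c(4, 24, 4), c(24, 4, 4))
  for (p in at) m[p[1] + 0:2, p[2] + 0:2, p[3] + 0:2] <- TRUE
  list(map = intersect_and_filter(list(iDrArK = m), subject_id = "p"),
       at = at, d = d)
}

test_that("PPV counts majority-inside clusters and classifies SD/UD/NS", {
  f <- four_cluster_map()
  expect_equal(nrow(f$map$clusters), 4L)
  cover <- function(which_clusters, n_vox = 27L) {
    erz <- array(FALSE, f$d)
    for (i in which_clusters) {
      p <- f$at[[i]]
      erz[p[1] + 0:2, p[2] + 0:2, p[3] + 0:2] <- TRUE
    }
    erz
  }
  # 2 of 4 inside: PPV exactly 0.5 -> successful detection (boundary included)
  r2 <- positive_predictive_value(f$map, cover(1:2))
  expect_equal(r2$nc, 4L); expect_equal(r2$nc_erz, 2L)
  expect_equal(r2$ppv, 0.5)
  expect_identical(r2$status, "SD")

  # 1 of 3... here 1 of 4 covered differently: below threshold -> UD
  r1 <- positive_predictive_value(f$map, cover(1))
  expect_equal(r1$ppv, 0.25)
  expect_identical(r1$status, "UD")

  # no clusters -> NS with undefined PPV
  d <- c(20L, 16L, 16L)
  empty_map <- intersect_and_filter(list(iDrArK = array(FALSE, d)))
  r0 <- positive_predictive_value(empty_map, array(TRUE, d))
  expect_identical(r0$status, "NS")
  expect_true(is.na(r0$ppv))
  expect_equal(r0$nc, 0L)

  # majority rule: 14/27 voxels inside counts, 13/27 does not
  partial <- array(FALSE, f$d)
  p1 <- f$at[[1]]
  partial[p1[1] + 0:2, p1[2] + 0:2, p1[3] + 0:1] <- TRUE   # 18 of 27 voxels
  expect_equal(positive_predictive_value(f$map, partial)$nc_erz, 1L)
  partial2 <- array(FALSE, f$d)
  partial2[p1[1] + 0:2, p1[2] + 0:2, p1[3]] <- TRUE        # 9 of 27
  expect_equal(positive_predictive_value(f$map, partial2)$nc_erz, 0L)
})

test_that("cohort accuracy and detection rate follow their definitions", {
  ev <- evaluate_cohort(list(sd = 8, ud = 1, ns = 16), "iDrArK")
  expect_equal(ev$accuracy, 8 / 9)
  expect_equal(ev$detection_rate, 9 / 25)
  expect_equal(round(100 * ev$accuracy), 89)
  expect_equal(100 * ev$detection_rate, 36)

  ev2 <- evaluate_cohort(list(sd = 9, ud = 5, ns = 11))
  expect_equal(round(100 * ev2$accuracy, 1), 64.3)
  expect_equal(100 * ev2$detection_rate, 56)

  ev0 <- evaluate_cohort(list(sd = 0, ud = 0, ns = 7))
  expect_true(is.na(ev0$accuracy))
  expect_equal(ev0$detection_rate, 0)

  # from detection_result objects, via brute-force recount
  mk_status <- c("SD", "SD", "UD", "NS", "NS")
  results <- lapply(seq_along(mk_status), function(i)
    structure(list(subject_id = paste0("p", i), method = "MK",
                   nc = if (mk_status[i] == "NS") 0L else 4L,
                   nc_erz = switch(mk_status[i], SD = 3L, UD = 1L, NS = 0L),
                   ppv = switch(mk_status[i], SD = 0.75, UD = 0.25,
                                NS = NA_real_),
                   status = mk_status[i]),
              class = "detection_result"))
  ev3 <- evaluate_cohort(results)
  expect_equal(c(ev3$sd, ev3$ud, ev3$ns), c(2, 1, 2))
  expect_equal(ev3$accuracy, sum(mk_status == "SD") /
                 sum(mk_status %in% c("SD", "UD")))
  expect_identical(ev3$method, "MK")
})

test_that("the one-step vs two-step comparison evaluates the subgroup only", {
  mk_result <- function(id, status, restricted) {
    structure(list(subject_id = id, method = "iDrArK",
                   nc = if (status == "NS") 0L else 2L,
                   nc_erz = if (status == "SD") 2L else 0L,
                   ppv = switch(status, SD = 1, UD = 0, NS = NA_real_),
                   status = status), class = "detection_result")
  }
  ids <- paste0("p", 1:12)
  one_status <- c("SD", "SD", "SD", "UD", "UD", "UD", "UD", "UD", "NS", "NS",
                  "SD", "UD")  # p11, p12 are outside the subgroup
  two_status <- c("SD", "SD", "SD", "SD", "SD", "NS", "NS", "NS", "NS", "NS",
                  "UD", "UD")
  one <- Map(mk_result, ids, one_status, FALSE)
  two <- Map(mk_result, ids, two_status, TRUE)
  tab <- two_step_utility(one, two, subgroup = ids[1:10])
  one_row <- tab[tab$method == "one_step", ]
  two_row <- tab[tab$method == "two_step", ]
  expect_equal(c(one_row$sd, one_row$ud, one_row$ns), c(3, 5, 2))
  expect_equal(one_row$accuracy, 0.375)
  expect_equal(one_row$detection_rate, 0.8)
  expect_equal(c(two_row$sd, two_row$ud, two_row$ns), c(5, 0, 5))
  expect_equal(two_row$accuracy, 1.0)
  expect_equal(two_row$detection_rate, 0.5)

  expect_error(two_step_utility(one[1:5], two, subgroup = ids[1:10]),
               "missing from the one-step")
})
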
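# GLM t-maps, TFCE, parametric thresholding and permutation FWE correction.

# closed-form unequal-n two-sample t with a single patient (n1 = 1)
two_sample_t_n1 <- function(patient, controls) {
  n0 <- length(controls)
  s2 <- sum((controls - mean(controls))^2) / (n0 - 1)  # pooled; patient SS = 0
  (patient - mean(controls)) / sqrt(s2 * (1 + 1 / n0))
}

test_that("one-vs-group GLM t matches the closed-form two-sample t", {
  y <- matrix(c(1, 2, 3, 4, 5, 10), nrow = 1)
  des <- glm_design(y, group = c(0, 0, 0, 0, 0, 1))
  fit <- fit_glm_t(des)
  expect_equal(fit$df, 4)
  expect_equal(fit$t, 7 / sqrt(3))            # = 4.041452...
  expect_equal(fit$t, two_sample_t_n1(10, 1:5))

  # random small instances
  set.seed(7)
  for (rep in 1:25) {
    n0 <- sample(5:15, 1)
    ctl <- rnorm(n0)
    pat <- rnorm(1, 0.5)
    des <- glm_design(matrix(c(ctl, pat), nrow = 1), c(rep(0, n0), 1))
    expect_equal(fit_glm_t(des)$t, two_sample_t_n1(pat, ctl))
  }
})

test_that("GLM t is zero at the null and invariant to location shifts", {
  y <- matrix(c(1, 2, 3, 2), nrow = 1)  # patient equals the control mean
  des <- glm_design(y, c(0, 0, 0, 1))
  expect_equal(fit_glm_t(des)$t, 0)

  set.seed(3)
  y2 <- matrix(rnorm(12), nrow = 2)
  g <- c(rep(0, 5), 1)
  t1 <- fit_glm_t(glm_design(y2, g))$t
  t2 <- fit_glm_t(glm_design(y2 + 100, g))$t
  expect_equal(t1, t2)
})

test_that("GLM with covariates matches lm() per feature", {
  set.seed(11)
  n <- 14
  y <- matrix(rnorm(3 * n), nrow = 3)
  g <- c(rep(0, n - 1), 1)
  sex <- rbinom(n, 1, 0.5)
  age <- runif(n, 20, 40)
  des <- glm_design(y, g, sex = sex, age = age)
  fit <- fit_glm_t(des)
  expect_equal(fit$df, n - 4)
  for (v in 1:3) {
    lmfit <- summary(lm(y[v, ] ~ g + sex + I(age - mean(age))))
    expect_equal(fit$t[v], lmfit$coefficients["g", "t value"])
  }
  expect_error(glm_design(y, g, sex = rep(1, n)), "rank deficient")
  expect_error(glm_design(y, rep(0, n)), "exactly one")
})

test_that("TFCE matches the closed form on a constant blob and is monotone", {
  d <- c(10L, 10L, 10L)
  stat <- array(0, d)
  stat[3:6, 3:6, 3:6] <- 2.5         # one connected blob, n = 64, h0 = 2.5
  n <- 64; h0 <- 2.5; E <- 0.5; H <- 2
  enh <- tfce(stat, E = E, H = H, dh = h0 / 100)
  closed <- n^E * h0^(H + 1) / (H + 1)
  expect_equal(max(enh), closed, tolerance = 0.02)
  expect_equal(min(enh[stat > 0]), closed, tolerance = 0.02)
  expect_true(all(enh[stat == 0] == 0))

  # halving dh tightens the Riemann sum by less than the O(dh) bound
  e1 <- max(tfce(stat, dh = h0 / 100))
  e2 <- max(tfce(stat, dh = h0 / 200))
  bound <- n^E * h0^H * (h0 / 100)   # max integrand * dh
  expect_lt(abs(e1 - e2), bound)

  expect_identical(tfce(array(0, d)), array(0, d))
  bigger <- stat; bigger[3:6, 3:6, 3:6] <- 3.0; bigger[7, 3, 3] <- 1
  expect_true(all(tfce(bigger, dh = 0.01) >= tfce(stat, dh = 0.01) - 1e-9))
  expect_error(tfce(stat, dh = -1), "positive")
})

test_that("parametric one-tailed thresholding behaves at its boundaries", {
  # t = 0 gives one-tailed p = 0.5
  des0 <- glm_design(matrix(c(1, 2, 3, 2), nrow = 1), c(0, 0, 0, 1))
  res0 <- parametric_t_threshold(des0, 0.001)
  expect_equal(res0$p_map, 0.5)
  expect_false(any(res0$sig_mask))

  # engineer an exact t: with a group dummy the patient is fitted exactly,
  # so s^2 depends only on the controls and t is linear in the patient value
  ctl <- rnorm(101); ctl <- (ctl - mean(ctl)) / sd(ctl)  # n0 = 101, df = 100
  s <- sqrt(sum((ctl - mean(ctl))^2) / 100)
  tstar <- qt(0.999, 100)
  make_p <- function(tval) {
    pat <- mean(ctl) + tval * s * sqrt(1 + 1 / 101)
    des <- glm_design(matrix(c(ctl, pat), nrow = 1), c(rep(0, 101), 1))
    parametric_t_threshold(des, 0.001)
  }
  expect_equal(make_p(tstar)$p_map, 0.001, tolerance = 1e-9)
  expect_false(any(make_p(tstar * 0.999)$sig_mask))  # below the quantile
  expect_true(any(make_p(tstar * 1.01)$sig_mask))    # above it

  # flipping the tail mirrors the significant set for the mirrored effect
  set.seed(21)
  y <- matrix(rnorm(30), nrow = 5); y[, 6] <- y[, 6] + 3
  g <- c(rep(0, 5), 1)
  up <- parametric_t_threshold(glm_design(y, g, tail = "greater"), 0.05)
  dn <- parametric_t_threshold(glm_design(-y, g, tail = "less"), 0.05)
  expect_identical(up$sig_mask, dn$sig_mask)
})

test_that("permutation FWE p-values respect the combinatorial floor and cap", {
  an <- small_anatomy()
  co <- small_cohort()
  skel <- build_symmetric_skeleton(lapply(co$controls, `[[`, "fa"),
                                  an$brain_mask, an$atlas)
  subjects <- c(co$controls, co$patients)
  n <- length(subjects)
  ai <- vapply(subjects, function(s) {
    pr <- project_to_skeleton(s, skel, "MK")
    asymmetry_index(pr$right, pr$left)
  }, numeric(nrow(skel$pairs)))
  des <- glm_design(ai, c(rep(0, n - 1), 1), tail = "greater")
  geom <- list(dim = skel$dim, index = skel$pairs[, "right"])
  res <- permutation_fwe(des, geom)
  expect_gte(min(res$p_map), 1 / n)
  expect_lte(max(res$p_map), 1)
  expect_identical(res$sig_mask, res$p_map < idrark_config()$fwe_alpha)

  cfg_bad <- idrark_config(n_permutations = n)
  expect_error(permutation_fwe(des, geom, cfg_bad), "combinatorial cap")
})

test_that("a strong planted lobar MK decrease is detected within its lobe", {
  an <- small_anatomy()
  les <- lesion_spec(center = c(17, 18, 13), radius_mm = 4,
                     delta_md = 0, delta_fa = 0, delta_mk = 0,
                     lobar_mk_decrease = list(lobe = "lobe02",
                                              hemisphere = "left",
                                              delta = 0.3))
  controls <- lapply(1:20, function(i)
    simulate_control(an, sprintf("c%02d", i), derive_seed(314, i)))
  pat <- simulate_patient(an, les, "p", derive_seed(314, 99))$maps
  subjects <- c(controls, list(pat))
  skel <- build_symmetric_skeleton(lapply(subjects, `[[`, "fa"),
                                  an$brain_mask, an$atlas)
  ai <- vapply(subjects, function(s) {
    pr <- project_to_skeleton(s, skel, "MK")
    asymmetry_index(pr$right, pr$left)
  }, numeric(nrow(skel$pairs)))
  # left MK decrease raises right-minus-left asymmetry: tail = greater
  des <- glm_design(ai, c(rep(0, 20), 1), tail = "greater")
  res <- permutation_fwe(des, list(dim = skel$dim,
                                   index = skel$pairs[, "right"]))
  expect_gt(sum(res$sig_mask & skel$lobe == "lobe02"), 0)
})
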
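# Single-patient vs control-group inference: vectorised GLM t-maps with sex
# and age as nuisance covariates, TFCE, and max-statistic permutation FWE
# correction over label reassignments (Freedman-Lane residual scheme).

#' One-patient-vs-controls GLM design
#'
#' @param response numeric matrix, features (voxels or skeleton pairs) x
#'   subjects
#' @param group 0/1 indicator over subjects; exactly one subject (the tested
#'   patient) carries 1
#' @param sex optional 0/1 vector over subjects
#' @param age optional numeric vector (years); mean-centred internally
#' @param tail `"greater"` (patient above controls) or `"less"`
#' @return a `glm_design`
#' @export
glm_design <- function(response, group, sex = NULL, age = NULL,
                       tail = c("greater", "less")) {
  tail <- match.arg(tail)
  response <- as.matrix(response)
  n <- ncol(response)
  group <- as.numeric(group)
  if (length(group) != n || sum(group == 1) != 1 || !all(group %in% c(0, 1)))
    stop("group must be a 0/1 vector over subjects with exactly one 1")
  X <- cbind(intercept = 1, group = group)
  if (!is.null(sex)) X <- cbind(X, sex = as.numeric(sex))
  if (!is.null(age)) X <- cbind(X, age = as.numeric(age) - mean(as.numeric(age)))
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  if (n - ncol(X) < 1) stop("no residual degrees of freedom: need more controls")
  structure(list(response = response, X = X, group = group, tail = tail),
            class = "glm_design")
}

# t statistic of the group column for every feature, given a design matrix.
ols_t <- function(Y, X) {
  # Y: features x subjects
  XtXi <- chol2inv(chol(crossprod(X)))
  B <- XtXi %*% crossprod(X, t(Y))          # p x V
  R <- t(Y) - X %*% B                        # n x V residuals
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(R^2) / df
  se <- sqrt(pmax(sigma2 * XtXi[2, 2], .Machine$double.eps))
  list(t = as.numeric(B[2, ] / se), df = df)
}

#' Voxel-wise GLM t-map for one patient against controls
#'
#' Ordinary least squares of the response on intercept, patient indicator and
#' the nuisance covariates; t is the patient coefficient over its standard
#' error with `n - p` degrees of freedom (p = 4 with sex and age, 2 without).
#' With no covariates this equals the unequal-n two-sample t with n1 = 1.
#'
#' @param design a [glm_design()]
#' @return list with `t` (per feature) and `df`
#' @export
fit_glm_t <- function(design) {
  stopifnot(inherits(design, "glm_design"))
  ols_t(design$response, design$X)
}

#' Threshold-free cluster enhancement
#'
#' `TFCE(v) = sum_h extent(v, h)^E * h^H * dh` over thresholds
#' `h = dh, 2dh, ...`; negative input values are clamped to zero before
#' enhancement.
#'
#' @param stat_map numeric 3-D array (e.g. a t-map embedded in a volume)
#' @param E,H extent and height exponents (published defaults 0.5 and 2)
#' @param dh integration step; `NULL` uses `max(stat_map)/100`
#' @param connectivity 6, 18 or 26
#' @return enhanced array of the same shape
#' @export
tfce <- function(stat_map, E = 0.5, H = 2, dh = NULL, connectivity = 26) {
  d <- dim(stat_map)
  stopifnot(length(d) == 3L)
  s <- pmax(as.numeric(stat_map), 0)
  if (is.null(dh)) {
    m <- max(s)
    if (m == 0) return(array(0, d))
    dh <- m / 100
  }
  if (dh <= 0) stop("dh must be positive")
  array(.tfce_cpp(s, as.integer(d), E, H, dh, as.integer(connectivity)), d)
}

# Embed per-feature values into a volume at the given linear indices.
embed_volume <- function(values, index, d) {
  v <- array(0, d)
  v[index] <- values
  v
}

#' Permutation test with TFCE and max-statistic FWE correction
#'
#' The observed one-tailed t-map is TFCE-enhanced; the null distribution of
#' its spatial maximum is obtained by reassigning the patient label to other
#' subjects (Freedman-Lane: residuals from the nuisance-only model are
#' permuted by swapping the patient's row with each reassigned subject's row,
#' the nuisance fit is added back, and the full model is refitted). Corrected
#' p-values use the add-one estimator
#' `p(v) = (1 + #\{perm max >= observed(v)\}) / (1 + n_permutations)`, so with
#' exhaustive reassignment over N subjects the smallest attainable p is 1/N.
#'
#' @param design a [glm_design()]
#' @param geometry list with `dim` (volume dimensions) and `index` (linear
#'   voxel index of each feature row), giving features their spatial layout
#' @param cfg an [idrark_config()]; uses `n_permutations` (NULL = exhaustive,
#'   capped at N - 1 distinct reassignments), `tfce_*`,
#'   `cluster_connectivity`, `fwe_alpha`, `rng_seed`
#' @return a `stat_result`: `t_map`, `tfce_map`, `p_map` (FWE-corrected),
#'   `sig_mask`, `alpha`, `df`, `method = "permutation_tfce_fwe"`,
#'   `null_max` (permutation distribution of the maximum)
#' @export
permutation_fwe <- function(design, geometry, cfg = idrark_config()) {
  stopifnot(inherits(design, "glm_design"))
  Y <- design$response
  X <- design$X
  n <- ncol(Y)
  sign <- if (design$tail == "greater") 1 else -1
  pat <- which(design$group == 1)
  max_perm <- n - 1L  # distinct non-identity label reassignments
  n_perm <- cfg$n_permutations
  if (is.null(n_perm)) n_perm <- max_perm
  if (n_perm < 1 || n_perm > max_perm)
    stop("n_permutations must be between 1 and the combinatorial cap of ",
         max_perm, " distinct label reassignments for ", n, " subjects")

  run_tfce <- function(tvals) {
    vol <- embed_volume(pmax(sign * tvals, 0), geometry$index, geometry$dim)
    enh <- tfce(vol, cfg$tfce_E, cfg$tfce_H, cfg$tfce_dh,
                cfg$cluster_connectivity)
    enh[geometry$index]
  }

  obs <- ols_t(Y, X)
  obs_tfce <- run_tfce(obs$t)

  # Freedman-Lane: residualise on the nuisance-only model once.
  Z <- X[, -2, drop = FALSE]
  Yt <- t(Y)                                  # n x V
  fitZ <- Z %*% (chol2inv(chol(crossprod(Z))) %*% crossprod(Z, Yt))
  RZ <- Yt - fitZ
  others <- setdiff(seq_len(n), pat)
  if (n_perm < max_perm) {
    set.seed(derive_seed(cfg$rng_seed, 777L))
    others <- sample(others, n_perm)
  }
  null_max <- vapply(others, function(j) {
    P <- seq_len(n); P[c(pat, j)] <- c(j, pat)
    Ystar <- t(fitZ + RZ[P, , drop = FALSE])  # V x n
    max(run_tfce(ols_t(Ystar, X)$t))
  }, 0)

  p_map <- (1 + vapply(obs_tfce, function(o) sum(null_max >= o), 0L)) /
    (1 + n_perm)
  structure(list(t_map = obs$t, tfce_map = obs_tfce, p_map = p_map,
                 sig_mask = p_map < cfg$fwe_alpha, alpha = cfg$fwe_alpha,
                 df = obs$df, tail = design$tail, null_max = null_max,
                 method = "permutation_tfce_fwe"),
            class = "stat_result")
}

#' Parametric one-tailed t-map thresholded at an uncorrected p
#'
#' @param design a [glm_design()]
#' @param p_threshold uncorrected one-tailed p threshold (strict inequality)
#' @return a `stat_result` with uncorrected parametric `p_map` and `sig_mask`
#' @export
parametric_t_threshold <- function(design, p_threshold = 0.001) {
  stopifnot(inherits(design, "glm_design"))
  fit <- fit_glm_t(design)
  stat <- if (design$tail == "greater") fit$t else -fit$t
  p <- pt(stat, df = fit$df, lower.tail = FALSE)
  structure(list(t_map = fit$t, p_map = p, sig_mask = p < p_threshold,
                 alpha = p_threshold, df = fit$df, tail = design$tail,
                 method = "parametric_uncorrected"),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("stat_result (%s, tail=%s): %d features, %d significant at %g\n",
              x$method, x$tail, length(x$t_map), sum(x$sig_mask), x$alpha))
  invisible(x)
}
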
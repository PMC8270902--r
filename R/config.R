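#' Analysis configuration
#'
#' Bundles every tunable constant of the two-step detection protocol. Defaults
#' reproduce the published protocol: FA >= 0.2 defines the deep white-matter
#' skeleton, skeleton inference is permutation-based with TFCE and FWE control
#' at alpha = 0.05, volume t-maps are thresholded at uncorrected p < 0.001,
#' clusters under 20 voxels are discarded, resection zones are dilated by
#' 10 mm, and a subject counts as a successful detection when at least half of
#' its clusters fall inside the extended resection zone.
#'
#' @param fa_skeleton_threshold mean-FA cutoff defining WM/GM borders
#' @param voxelwise_p uncorrected one-tailed p threshold for volume t-maps
#' @param fwe_alpha family-wise error level for skeleton permutation tests
#' @param min_cluster_voxels clusters smaller than this are removed
#' @param erz_dilation_mm dilation radius (mm) applied to resection zones
#' @param ppv_success_threshold PPV at or above which detection counts as
#'   successful
#' @param n_permutations number of label reassignments; `NULL` means exhaustive
#'   (all subjects other than the tested one)
#' @param tfce_E,tfce_H TFCE extent and height exponents
#' @param tfce_dh TFCE integration step; `NULL` means max(statistic)/100 per map
#' @param cluster_connectivity 6, 18 or 26
#' @param rng_seed root seed for all randomised stages
#' @return an `idrark_config` list
#' @export
idrark_config <- function(fa_skeleton_threshold = 0.2,
                          voxelwise_p = 0.001,
                          fwe_alpha = 0.05,
                          min_cluster_voxels = 20L,
                          erz_dilation_mm = 10,
                          ppv_success_threshold = 0.5,
                          n_permutations = NULL,
                          tfce_E = 0.5,
                          tfce_H = 2,
                          tfce_dh = NULL,
                          cluster_connectivity = 26L,
                          rng_seed = 1L) {
  cfg <- list(fa_skeleton_threshold = fa_skeleton_threshold,
              voxelwise_p = voxelwise_p,
              fwe_alpha = fwe_alpha,
              min_cluster_voxels = as.integer(min_cluster_voxels),
              erz_dilation_mm = erz_dilation_mm,
              ppv_success_threshold = ppv_success_threshold,
              n_permutations = if (is.null(n_permutations)) NULL
                               else as.integer(n_permutations),
              tfce_E = tfce_E, tfce_H = tfce_H, tfce_dh = tfce_dh,
              cluster_connectivity = as.integer(cluster_connectivity),
              rng_seed = as.integer(rng_seed))
  validate_config(cfg)
  structure(cfg, class = "idrark_config")
}

validate_config <- function(cfg) {
  pos <- c("fa_skeleton_threshold", "voxelwise_p", "fwe_alpha",
           "min_cluster_voxels", "ppv_success_threshold")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop("config field '", f, "' must be a positive scalar")
  if (cfg$erz_dilation_mm < 0) stop("erz_dilation_mm must be >= 0")
  if (cfg$ppv_success_threshold > 1)
    stop("ppv_success_threshold must lie in (0, 1]")
  if (!cfg$cluster_connectivity %in% c(6L, 18L, 26L))
    stop("cluster_connectivity must be 6, 18 or 26")
  if (!is.null(cfg$tfce_dh) && cfg$tfce_dh <= 0)
    stop("tfce_dh must be positive")
  invisible(cfg)
}

#' Read an analysis configuration from YAML or JSON
#'
#' Keys missing from the file keep their protocol defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file
#' @return an `idrark_config`
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- names(formals(idrark_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(idrark_config, vals)
}

#' @export
print.idrark_config <- function(x, ...) {
  cat("idrark analysis configuration\n")
  for (f in names(x)) {
    v <- x[[f]]
    cat(sprintf("  %-22s %s\n", f,
                if (is.null(v)) "(auto)" else format(v)))
  }
  invisible(x)
}
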
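#' Configuration of a synthetic tractography cohort
#'
#' Describes a multi-subject cohort of seed-voxel x target streamline-count
#' matrices with `k_true` planted, spatially contiguous clusters.  The
#' defaults define the reference desk-scale cohort used throughout the test
#' suite: 12 subjects on a 10 x 10 x 3 seed grid, two planted clusters,
#' 19 target regions, 2,000 streamlines seeded per voxel, medium profile
#' separation with mild per-subject jitter and a small uniform noise floor.
#'
#' @param n_subjects number of subjects.
#' @param seed_shape 3 integers, the seed-ROI grid.
#' @param k_true number of planted clusters (>= 1, <= number of seed voxels).
#' @param n_targets number of target regions (default 19, the homologous ROI
#'   count).
#' @param n_streamlines streamlines seeded per voxel; every count row sums to
#'   this exactly.
#' @param separation real in \[0,1\]: distance between cluster connection
#'   profiles.  0 makes all clusters share one profile; 1 gives disjoint
#'   high-mass target sets.
#' @param subject_jitter scale of per-subject log-normal perturbation of the
#'   cluster profiles (>= 0).
#' @param noise_floor real in \[0,1): fraction of probability mass spread
#'   uniformly over targets, emulating spurious streamlines.
#' @param rng_seed integer seed; regeneration with the same config is
#'   bit-identical.
#' @param target_names optional character vector of target names; defaults to
#'   [default_target_rois()] when `n_targets` is 19, else `target_01`, ...
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 12L, seed_shape = c(10L, 10L, 3L),
                          k_true = 2L, n_targets = 19L,
                          n_streamlines = 2000L, separation = 0.5,
                          subject_jitter = 0.1, noise_floor = 0.05,
                          rng_seed = 42L, target_names = NULL) {
  n_subjects <- as.integer(n_subjects)
  seed_shape <- as.integer(seed_shape)
  k_true <- as.integer(k_true)
  n_targets <- as.integer(n_targets)
  n_streamlines <- as.integer(n_streamlines)
  stopifnot(n_subjects >= 1L, length(seed_shape) == 3L, all(seed_shape >= 1L),
            k_true >= 1L, n_targets >= 2L, n_streamlines >= 1L,
            separation >= 0, separation <= 1,
            subject_jitter >= 0, noise_floor >= 0, noise_floor < 1)
  if (k_true > prod(seed_shape))
    stop("infeasible config: k_true exceeds the number of seed voxels")
  if (separation + noise_floor > 1)
    stop("infeasible config: separation + noise_floor must be <= 1")
  if (is.null(target_names)) {
    target_names <- if (n_targets == 19L) default_target_rois()
                    else sprintf("target_%02d", seq_len(n_targets))
  }
  if (length(target_names) != n_targets) stop("target_names length mismatch")
  structure(list(n_subjects = n_subjects, seed_shape = seed_shape,
                 k_true = k_true, n_targets = n_targets,
                 n_streamlines = n_streamlines, separation = separation,
                 subject_jitter = subject_jitter, noise_floor = noise_floor,
                 rng_seed = as.integer(rng_seed),
                 target_names = target_names),
            class = "cohort_config")
}

# Partition the seed grid into k contiguous slabs along its longest axis.
planted_labels <- function(seed_shape, k) {
  axis <- which.max(seed_shape)
  breaks <- round(seq(0, seed_shape[axis], length.out = k + 1L))
  slab <- rep(seq_len(k), times = diff(breaks))
  idx <- slice.index(array(0L, dim = seed_shape), axis)
  array(slab[idx], dim = seed_shape)
}

#' Generate a synthetic tractography cohort with known ground truth
#'
#' The seed grid is split into `k_true` contiguous slabs along its longest
#' axis.  Cluster `c` receives the propensity vector
#' `theta_c = (1 - separation) * base + separation * delta_c`, where `base`
#' is a shared positive simplex vector and the `delta_c` are cluster-specific
#' simplex vectors with disjoint support.  For subject `s`, `theta_c` is
#' perturbed by log-normal jitter (`exp(subject_jitter * z)`, renormalized)
#' and mixed with a uniform noise floor; each voxel then draws its target
#' counts from `Multinomial(n_streamlines, p)`.
#'
#' @param config a [cohort_config()].
#' @return An object of class `synthetic_cohort`: list with `subjects` (one
#'   [connectivity_matrix()] each), `ground_truth` ([label_volume()] with
#'   labels 1..k_true), `theta` (k_true x n_targets propensity matrix) and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cf <- config
  grid <- volume_grid(cf$seed_shape)
  truth <- label_volume(planted_labels(cf$seed_shape, cf$k_true), grid)
  vox_cluster <- as.vector(truth$labels)
  n_vox <- length(vox_cluster)

  withr::with_seed(cf$rng_seed, {
    base <- stats::rexp(cf$n_targets)
    base <- base / sum(base)
    # disjoint-support simplex vectors, one target block per cluster
    blk <- round(seq(0, cf$n_targets, length.out = cf$k_true + 1L))
    if (any(diff(blk) < 1L)) stop("n_targets too small for k_true")
    delta <- matrix(0, cf$k_true, cf$n_targets)
    for (c in seq_len(cf$k_true)) {
      j <- (blk[c] + 1L):blk[c + 1L]
      delta[c, j] <- 1 / length(j)
    }
    theta <- (1 - cf$separation) * rep(base, each = cf$k_true) +
      cf$separation * delta
    dim(theta) <- c(cf$k_true, cf$n_targets)

    vox_ids <- sprintf("v%06d", seq_len(n_vox))
    subjects <- vector("list", cf$n_subjects)
    for (s in seq_len(cf$n_subjects)) {
      z <- matrix(stats::rnorm(cf$k_true * cf$n_targets),
                  cf$k_true, cf$n_targets)
      th_s <- theta * exp(cf$subject_jitter * z)
      th_s <- th_s / rowSums(th_s)
      prob <- (1 - cf$noise_floor) * th_s + cf$noise_floor / cf$n_targets
      counts <- matrix(0L, n_vox, cf$n_targets,
                       dimnames = list(vox_ids, cf$target_names))
      for (c in seq_len(cf$k_true)) {
        v <- which(vox_cluster == c)
        counts[v, ] <- t(stats::rmultinom(length(v), cf$n_streamlines,
                                          prob[c, ]))
      }
      subjects[[s]] <- connectivity_matrix(counts,
                                           seed_voxel_ids = seq_len(n_vox),
                                           subject_id = sprintf("sub-%02d", s))
    }
  })
  dimnames(theta) <- list(sprintf("cluster_%d", seq_len(cf$k_true)),
                          cf$target_names)
  structure(list(subjects = subjects, ground_truth = truth, theta = theta,
                 config = cf),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cf <- x$config
  cat("<synthetic_cohort> ", cf$n_subjects, " subjects, ",
      paste(cf$seed_shape, collapse = "x"), " seed grid, k_true = ",
      cf$k_true, ", ", cf$n_targets, " targets\n", sep = "")
  invisible(x)
}

#' Generate region time series with prescribed pairwise correlations
#'
#' Draws zero-mean Gaussian series whose population correlation matrix equals
#' `target_corr` (latent-factor construction through the eigendecomposition,
#' so exactly singular targets such as r = 1 pairs are allowed).  Sample
#' correlations converge to the target at rate ~ 1/sqrt(length).
#'
#' @param region_names character vector naming the rows.
#' @param target_corr symmetric positive semi-definite matrix with unit
#'   diagonal, the desired pairwise Pearson correlations.
#' @param length number of time points (>= 2).
#' @param rng_seed integer seed.
#' @return Numeric matrix, regions x time, with `rownames = region_names`.
#' @export
generate_timeseries <- function(region_names, target_corr, length,
                                rng_seed = 42L) {
  p <- base::length(region_names)
  target_corr <- as.matrix(target_corr)
  stopifnot(identical(dim(target_corr), c(p, p)), length >= 2L)
  if (max(abs(target_corr - t(target_corr))) > 1e-8)
    stop("target correlation matrix must be symmetric")
  if (max(abs(diag(target_corr) - 1)) > 1e-8)
    stop("target correlation matrix must have unit diagonal")
  e <- eigen((target_corr + t(target_corr)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    stop("target correlation matrix is not positive semi-definite")
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), p)
  x <- withr::with_seed(rng_seed,
                        L %*% matrix(stats::rnorm(p * length), p, length))
  rownames(x) <- region_names
  x
}

#' Generate two fingerprint sets with planted homolog pairs
#'
#' Builds one fingerprint set per species over a shared ordered target list.
#' Each planted pair `(a, b)` shares a base connection profile, observed on
#' both sides with independent additive Gaussian noise; non-planted regions
#' receive independent profiles.  The returned truth pairing is the test bed
#' for homolog matching.
#'
#' @param n_regions_a,n_regions_b number of regions per set.
#' @param n_targets number of shared targets (default 19).
#' @param planted_pairs 2-column matrix (or list of length-2 vectors) of
#'   region indices `(a, b)` planted as homologs.
#' @param noise standard deviation of the additive noise.
#' @param rng_seed integer seed.
#' @param target_names optional target names (defaults as in
#'   [cohort_config()]).
#' @return List with `set_a`, `set_b` ([fingerprint_set()]s tagged
#'   `"human"`/`"macaque"`) and `pairs` (the planted 2-column index matrix).
#' @export
generate_fingerprint_sets <- function(n_regions_a, n_regions_b,
                                      n_targets = 19L, planted_pairs,
                                      noise = 0, rng_seed = 42L,
                                      target_names = NULL) {
  if (is.list(planted_pairs))
    planted_pairs <- do.call(rbind, lapply(planted_pairs, as.integer))
  planted_pairs <- matrix(as.integer(planted_pairs), ncol = 2L)
  stopifnot(all(planted_pairs[, 1L] >= 1L), all(planted_pairs[, 1L] <= n_regions_a),
            all(planted_pairs[, 2L] >= 1L), all(planted_pairs[, 2L] <= n_regions_b),
            !anyDuplicated(planted_pairs[, 1L]), !anyDuplicated(planted_pairs[, 2L]),
            noise >= 0)
  if (is.null(target_names)) {
    target_names <- if (n_targets == 19L) default_target_rois()
                    else sprintf("target_%02d", seq_len(n_targets))
  }
  withr::with_seed(rng_seed, {
    prof_a <- matrix(stats::runif(n_regions_a * n_targets), n_regions_a)
    prof_b <- matrix(stats::runif(n_regions_b * n_targets), n_regions_b)
    for (i in seq_len(nrow(planted_pairs))) {
      shared <- stats::runif(n_targets)
      prof_a[planted_pairs[i, 1L], ] <- shared + noise * stats::rnorm(n_targets)
      prof_b[planted_pairs[i, 2L], ] <- shared + noise * stats::rnorm(n_targets)
    }
  })
  mk <- function(prof, species, prefix) {
    fps <- lapply(seq_len(nrow(prof)), function(i)
      fingerprint(prof[i, ], target_names,
                  region_id = sprintf("%s_%02d", prefix, i),
                  kind = "structural"))
    fingerprint_set(fps, species = species)
  }
  list(set_a = mk(prof_a, "human", "A"),
       set_b = mk(prof_b, "macaque", "B"),
       pairs = planted_pairs)
}
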
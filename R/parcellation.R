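#' Single-subject parcellation of a seed mask
#'
#' @param labels a [label_volume()] with labels 1..k inside the seed mask and
#'   0 outside.
#' @param k number of clusters.
#' @param subject_id optional subject tag.
#' @return An object of class `subject_parcellation`.
#' @export
subject_parcellation <- function(labels, k, subject_id = NULL) {
  stopifnot(inherits(labels, "label_volume"))
  k <- as.integer(k)
  if (max(labels$labels) > k) stop("labels exceed k")
  structure(list(labels = labels, k = k, subject_id = subject_id),
            class = "subject_parcellation")
}

#' @export
print.subject_parcellation <- function(x, ...) {
  cat("<subject_parcellation> k = ", x$k, ", ",
      length(mask_indices(x$labels)), " in-mask voxels",
      if (!is.null(x$subject_id)) paste0(" (", x$subject_id, ")"), "\n",
      sep = "")
  invisible(x)
}

# connected components of the thresholded affinity graph (A > 0 off-diagonal)
affinity_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(A[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Spectral clustering of a voxel similarity matrix
#'
#' Clips negative similarities to zero (unit diagonal kept) to form the
#' affinity, embeds via the symmetric normalized graph Laplacian (top-k
#' eigenvectors of `D^-1/2 A D^-1/2`, rows normalized to unit length) and
#' partitions the embedding with k-means (10 restarts, fixed seed).  If the
#' affinity graph is disconnected a warning is raised; with more components
#' than clusters, the k largest components become cluster cores and each
#' smaller component is merged into the core with maximal mean raw
#' similarity.
#'
#' @param sim square symmetric similarity matrix over the in-mask seed
#'   voxels, in scan order (as from [build_similarity()]).
#' @param k number of clusters, `2 <= k <= nrow(sim)`.
#' @param seed_mask [label_volume()] whose nonzero voxels, in scan order,
#'   correspond to the rows of `sim`.
#' @param rng_seed integer seed for the k-means restarts.
#' @param subject_id optional subject tag.
#' @return A [subject_parcellation()] with labels 1..k in-mask.
#' @export
spectral_cluster <- function(sim, k, seed_mask, rng_seed = 42L,
                             subject_id = NULL) {
  sim <- as.matrix(sim)
  n <- nrow(sim)
  stopifnot(n == ncol(sim), inherits(seed_mask, "label_volume"))
  k <- as.integer(k)
  if (k < 2L || k > n) stop("k out of range [2, ", n, "]")
  idx <- mask_indices(seed_mask)
  if (length(idx) != n)
    stop("similarity matrix size does not match the seed mask (",
         length(idx), " in-mask voxels vs ", n, " rows)")

  A <- pmax(sim, 0)
  diag(A) <- 1
  comp <- affinity_components(A)
  ncomp <- max(comp)
  if (ncomp > 1L)
    warning("affinity graph has ", ncomp, " connected components")

  if (ncomp > k) {
    # more components than clusters: k largest components are cores, the
    # rest merge into the core with the highest mean raw similarity
    sizes <- tabulate(comp, ncomp)
    cores <- order(sizes, decreasing = TRUE)[seq_len(k)]
    assign <- integer(ncomp)
    assign[cores] <- seq_len(k)
    for (c in setdiff(seq_len(ncomp), cores)) {
      m <- vapply(cores, function(cc)
        mean(sim[comp == c, comp == cc, drop = FALSE]), numeric(1))
      assign[c] <- which.max(m)
    }
    cl <- assign[comp]
  } else {
    d <- rowSums(A)
    s <- 1 / sqrt(d)
    M <- A * tcrossprod(s)
    e <- eigen(M, symmetric = TRUE)
    U <- e$vectors[, seq_len(k), drop = FALSE]
    nrm <- sqrt(rowSums(U^2))
    nrm[nrm == 0] <- 1
    U <- U / nrm
    km <- withr::with_seed(as.integer(rng_seed),
                           stats::kmeans(U, centers = k, nstart = 10L,
                                         iter.max = 100L))
    cl <- km$cluster
  }

  lab <- integer(prod(seed_mask$grid$shape))
  lab[idx] <- cl
  subject_parcellation(label_volume(lab, seed_mask$grid), k,
                       subject_id = subject_id)
}

# all permutations of 1..n (n small)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L))
    for (i in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
  out
}

#' Align cluster labels to a reference parcellation
#'
#' Cluster labels from independent clustering runs are arbitrary; this
#' permutes the labels of `parc` by the bijection that maximizes the total
#' voxel overlap with `reference` (exhaustive search over permutations for
#' k <= 7, greedy otherwise).  The partition itself is unchanged.
#'
#' @param parc,reference [subject_parcellation()]s on the same grid with the
#'   same k.
#' @return `parc` with permuted labels.
#' @export
align_labels <- function(parc, reference) {
  stopifnot(inherits(parc, "subject_parcellation"),
            inherits(reference, "subject_parcellation"))
  check_same_grid(parc$labels$grid, reference$labels$grid, "parcellations")
  if (parc$k != reference$k) stop("k mismatch: ", parc$k, " vs ", reference$k)
  k <- parc$k
  a <- as.vector(parc$labels$labels)
  b <- as.vector(reference$labels$labels)
  joint <- a > 0L & b > 0L
  C <- matrix(0, k, k)   # C[i, j] = voxels with parc label i, ref label j
  tab <- table(factor(a[joint], levels = seq_len(k)),
               factor(b[joint], levels = seq_len(k)))
  C[] <- as.numeric(tab)
  if (k <= 7L) {
    perms <- all_permutations(k)
    scores <- vapply(perms, function(p)
      sum(C[cbind(seq_len(k), p)]), numeric(1))
    sigma <- perms[[which.max(scores)]]
  } else {
    sigma <- integer(k)
    Cw <- C
    for (step in seq_len(k)) {
      best <- arrayInd(which.max(Cw), dim(Cw))
      sigma[best[1L]] <- best[2L]
      Cw[best[1L], ] <- -Inf
      Cw[, best[2L]] <- -Inf
    }
  }
  new_lab <- a
  new_lab[a > 0L] <- sigma[a[a > 0L]]
  subject_parcellation(label_volume(new_lab, parc$labels$grid), k,
                       subject_id = parc$subject_id)
}

# per-voxel label counts over the 26-neighbourhood, restricted to in-mask
# voxels; returns an n_vox x k matrix of neighbour votes
neighbour_label_counts <- function(lab_arr, k) {
  shp <- dim(lab_arr)
  off <- neighbourhood26()
  n <- prod(shp)
  counts <- matrix(0L, n, k)
  coords <- arrayInd(seq_len(n), shp)
  for (r in seq_len(nrow(off))) {
    nb <- coords + matrix(off[r, ], n, 3L, byrow = TRUE)
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= shp[1L] &
          nb[, 2L] >= 1L & nb[, 2L] <= shp[2L] &
          nb[, 3L] >= 1L & nb[, 3L] <= shp[3L]
    lin <- nb[ok, 1L] + (nb[ok, 2L] - 1L) * shp[1L] +
      (nb[ok, 3L] - 1L) * shp[1L] * shp[2L]
    nb_lab <- lab_arr[lin]
    has <- nb_lab > 0L
    i <- which(ok)[has]
    j <- nb_lab[has]
    counts[cbind(i, j)] <- counts[cbind(i, j)] + 1L
  }
  counts
}

#' Modal (majority) filtering of cluster labels
#'
#' A single pass in which every in-mask voxel takes the most frequent label
#' among its 26-neighbourhood restricted to in-mask voxels; ties keep the
#' voxel's original label.  This is the order-free analogue of median
#' filtering for categorical labels, used to smooth clustering results.
#'
#' @param parc a [subject_parcellation()], [mpm_volume()] or
#'   [label_volume()].
#' @return An object of the same class with filtered labels.
#' @export
median_filter_labels <- function(parc) {
  vol <- if (inherits(parc, "label_volume")) parc else parc$labels
  lab <- vol$labels
  k <- max(1L, max(lab))
  counts <- neighbour_label_counts(lab, k)
  v <- which(as.vector(lab) > 0L)
  best <- max.col(counts[v, , drop = FALSE], ties.method = "first")
  maxn <- counts[cbind(v, best)]
  n_at_max <- rowSums(counts[v, , drop = FALSE] == maxn)
  tie <- n_at_max > 1L | maxn == 0L
  new_lab <- as.vector(lab)
  new_lab[v[!tie]] <- best[!tie]
  out <- label_volume(array(new_lab, dim = dim(lab)), vol$grid)
  if (inherits(parc, "label_volume")) return(out)
  if (inherits(parc, "mpm_volume")) return(mpm_volume(out, parc$k))
  subject_parcellation(out, parc$k, subject_id = parc$subject_id)
}

#' Group probability maps from aligned subject parcellations
#'
#' For each cluster c, `map_c(v)` is the fraction of subjects labelling voxel
#' v with c.  Subjects must already share a grid, k, and label semantics (see
#' [align_labels()]).
#'
#' @param parcs list of aligned [subject_parcellation()]s.
#' @return An object of class `group_probability_maps`: list with `maps`
#'   (4-D array, shape x k), `k`, `n_subjects`, `grid`.
#' @export
group_probability_maps <- function(parcs) {
  stopifnot(length(parcs) >= 1L,
            all(vapply(parcs, inherits, logical(1), "subject_parcellation")))
  k <- parcs[[1L]]$k
  grid <- parcs[[1L]]$labels$grid
  for (p in parcs) {
    if (p$k != k) stop("all parcellations must share k")
    check_same_grid(p$labels$grid, grid, "parcellations")
  }
  n <- length(parcs)
  shp <- grid$shape
  maps <- array(0, dim = c(shp, k))
  nv <- prod(shp)
  for (p in parcs) {
    lab <- as.vector(p$labels$labels)
    v <- which(lab > 0L)
    maps[v + (lab[v] - 1L) * nv] <- maps[v + (lab[v] - 1L) * nv] + 1
  }
  probability_maps(maps / n, grid, n_subjects = n)
}

#' Construct group probability maps from a probability array
#'
#' Low-level constructor, useful for hand-built fixtures.  Probabilities must
#' lie in \[0, 1\] and sum to at most 1 per voxel.
#'
#' @param maps 4-D numeric array (shape x k) of per-cluster probabilities.
#' @param grid the common [volume_grid()].
#' @param n_subjects number of subjects behind the probabilities.
#' @return An object of class `group_probability_maps`.
#' @export
probability_maps <- function(maps, grid, n_subjects) {
  stopifnot(inherits(grid, "volume_grid"), length(dim(maps)) == 4L,
            identical(as.integer(dim(maps)[1:3]), grid$shape))
  if (min(maps) < 0 || max(maps) > 1 + 1e-9)
    stop("probabilities must lie in [0, 1]")
  tot <- apply(maps, 1:3, sum)
  if (max(tot) > 1 + 1e-9)
    stop("per-voxel probabilities must sum to at most 1")
  structure(list(maps = maps, k = dim(maps)[4L], grid = grid,
                 n_subjects = as.integer(n_subjects)),
            class = "group_probability_maps")
}

#' Maximum probability map
#'
#' @param labels a [label_volume()].
#' @param k number of clusters.
#' @return An object of class `mpm_volume`.
#' @export
mpm_volume <- function(labels, k) {
  stopifnot(inherits(labels, "label_volume"))
  structure(list(labels = labels, k = as.integer(k)), class = "mpm_volume")
}

#' Build the maximum probability map from group probability maps
#'
#' Assigns every voxel with any group support to the cluster with the highest
#' probability.  Exact ties are broken in favour of the cluster with the
#' higher mean probability over the voxel's 26-neighbourhood (in-grid
#' neighbours only); residual exact ties fall back to the lower cluster
#' index, with a warning.  Voxels where all probabilities are 0 stay
#' background.
#'
#' @param gpm a [group_probability_maps()] object.
#' @return An [mpm_volume()].
#' @export
build_mpm <- function(gpm) {
  stopifnot(inherits(gpm, "group_probability_maps"))
  shp <- gpm$grid$shape
  k <- gpm$k
  nv <- prod(shp)
  P <- matrix(gpm$maps, nv, k)
  pmaxv <- do.call(pmax, lapply(seq_len(k), function(c) P[, c]))
  lab <- integer(nv)
  active <- pmaxv > 0
  at_max <- P == pmaxv            # exact comparison: ties are exact ties
  n_max <- rowSums(at_max)
  uniq <- active & n_max == 1L
  lab[uniq] <- max.col(at_max[uniq, , drop = FALSE], ties.method = "first")

  tied <- which(active & n_max > 1L)
  if (length(tied) > 0L) {
    nb_mean <- neighbourhood_means(gpm$maps)   # nv x k
    residual <- FALSE
    for (v in tied) {
      cand <- which(at_max[v, ])
      m <- nb_mean[v, cand]
      best <- cand[m >= max(m) - 1e-12]
      if (length(best) > 1L) residual <- TRUE
      lab[v] <- min(best)
    }
    if (residual)
      warning("argmax and neighbourhood-mean ties remained for some voxels; ",
              "assigned the lower cluster index")
  }
  mpm_volume(label_volume(array(lab, dim = shp), gpm$grid), k)
}

# mean probability per cluster over the 26-neighbourhood (in-grid neighbours
# only); returns an n_vox x k matrix
neighbourhood_means <- function(maps) {
  shp <- dim(maps)[1:3]
  k <- dim(maps)[4L]
  nv <- prod(shp)
  off <- neighbourhood26()
  sums <- matrix(0, nv, k)
  cnt <- numeric(nv)
  coords <- arrayInd(seq_len(nv), shp)
  P <- matrix(maps, nv, k)
  for (r in seq_len(nrow(off))) {
    nb <- coords + matrix(off[r, ], nv, 3L, byrow = TRUE)
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= shp[1L] &
          nb[, 2L] >= 1L & nb[, 2L] <= shp[2L] &
          nb[, 3L] >= 1L & nb[, 3L] <= shp[3L]
    lin <- nb[ok, 1L] + (nb[ok, 2L] - 1L) * shp[1L] +
      (nb[ok, 3L] - 1L) * shp[1L] * shp[2L]
    sums[ok, ] <- sums[ok, ] + P[lin, , drop = FALSE]
    cnt[ok] <- cnt[ok] + 1
  }
  sums / cnt
}
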
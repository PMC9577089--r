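# Fixture builders and independent brute-force oracles.  The oracles compute
# every metric straight from its definition, separately from the package's
# code paths, so that agreement is a real cross-check.

make_grid <- function(shape = c(4, 4, 2)) volume_grid(shape)

make_labels <- function(values, shape = c(4, 4, 2)) {
  label_volume(array(as.integer(values), dim = shape), volume_grid(shape))
}

random_label_pair <- function(n_max = 200L, k_max = 5L) {
  shape <- c(sample(2:6, 1), sample(2:6, 1), sample(2:6, 1))
  n <- prod(shape)
  k <- sample(2:k_max, 1)
  a <- sample(0:k, n, replace = TRUE)
  b <- sample(0:k, n, replace = TRUE)
  list(a = make_labels(a, shape), b = make_labels(b, shape))
}

# --- definitional metric oracles (natural logs throughout) ---------------

oracle_contingency <- function(a, b) {
  la <- as.vector(a$labels); lb <- as.vector(b$labels)
  j <- la > 0 & lb > 0
  la <- la[j]; lb <- lb[j]
  ra <- sort(unique(la)); rb <- sort(unique(lb))
  m <- matrix(0L, length(ra), length(rb))
  for (i in seq_along(ra)) for (jj in seq_along(rb))
    m[i, jj] <- sum(la == ra[i] & lb == rb[jj])
  m
}

oracle_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

oracle_mi <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  s
}

oracle_nmi <- function(tab) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  hx <- oracle_entropy(rowSums(tab) / sum(tab))
  hy <- oracle_entropy(colSums(tab) / sum(tab))
  if (hx == 0 || hy == 0) return(0)
  2 * oracle_mi(tab) / (hx + hy)
}

oracle_vi <- function(tab) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  hx <- oracle_entropy(rowSums(tab) / sum(tab))
  hy <- oracle_entropy(colSums(tab) / sum(tab))
  hx + hy - 2 * oracle_mi(tab)
}

oracle_cramers_v <- function(tab) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) return(0)
  n <- sum(tab)
  chi2 <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / n
    chi2 <- chi2 + (tab[i, j] - e)^2 / e
  }
  sqrt(chi2 / (n * (min(dim(tab)) - 1)))
}

oracle_dice_multilabel <- function(a, b) {
  la <- as.vector(a$labels); lb <- as.vector(b$labels)
  labs <- sort(unique(c(la[la > 0], lb[lb > 0])))
  per <- sapply(labs, function(c)
    2 * sum(la == c & lb == c) / (sum(la == c) + sum(lb == c)))
  mean(per)
}

oracle_overlap <- function(a, b, label) {
  A <- as.vector(a$labels) == label
  B <- as.vector(b$labels) == label
  list(dice = 2 * sum(A & B) / (sum(A) + sum(B)),
       sensitivity = sum(A & B) / sum(A),
       specificity = sum(!A & !B) / sum(!A),
       iou = sum(A & B) / sum(A | B))
}

# per-voxel 26-neighbour modal vote, written as a plain triple loop
oracle_mode_filter <- function(vol) {
  lab <- vol$labels
  shp <- dim(lab)
  out <- lab
  for (x in seq_len(shp[1])) for (y in seq_len(shp[2])) for (z in seq_len(shp[3])) {
    if (lab[x, y, z] == 0) next
    votes <- integer(0)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      xx <- x + dx; yy <- y + dy; zz <- z + dz
      if (xx < 1 || xx > shp[1] || yy < 1 || yy > shp[2] ||
          zz < 1 || zz > shp[3]) next
      if (lab[xx, yy, zz] > 0) votes <- c(votes, lab[xx, yy, zz])
    }
    if (length(votes) == 0) next
    tab <- table(votes)
    winners <- as.integer(names(tab)[tab == max(tab)])
    if (length(winners) == 1) out[x, y, z] <- winners
  }
  label_volume(out, vol$grid)
}

# default desk-scale cohort with per-subject similarity matrices
default_cohort_with_sims <- function(rng_seed = 42L) {
  cohort <- generate_cohort(cohort_config(rng_seed = rng_seed))
  sims <- lapply(cohort$subjects, function(s) suppressWarnings(build_similarity(s)))
  list(cohort = cohort, sims = sims)
}

cluster_and_align <- function(sims, mask, k, rng_seed = 7L,
                              reference = NULL) {
  parcs <- lapply(sims, function(s)
    suppressWarnings(spectral_cluster(s, k, mask, rng_seed = rng_seed)))
  ref <- if (is.null(reference)) parcs[[1L]] else reference
  lapply(parcs, align_labels, reference = ref)
}
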
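as_labels <- function(x) {
  if (inherits(x, "subject_parcellation") || inherits(x, "mpm_volume"))
    x <- x$labels
  stopifnot(inherits(x, "label_volume"))
  x
}

#' Contingency table of two label volumes
#'
#' Cross-tabulates labels over the voxels labelled > 0 in *both* volumes
#' (background is excluded: group maps need not share support exactly).
#'
#' @param a,b [label_volume()]s (or parcellations/MPMs) on the same grid.
#' @return An object of class `contingency_table`: integer matrix of counts
#'   with row labels from `a` and column labels from `b`.
#' @export
contingency_table <- function(a, b) {
  a <- as_labels(a); b <- as_labels(b)
  check_same_grid(a$grid, b$grid)
  la <- as.vector(a$labels); lb <- as.vector(b$labels)
  joint <- la > 0L & lb > 0L
  if (!any(joint)) stop("empty joint support: no voxel is labelled in both volumes")
  tab <- table(la[joint], lb[joint])
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  structure(m, class = c("contingency_table", "matrix"))
}

drop_empty_margins <- function(tab) {
  tab <- unclass(tab)
  tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
}

#' Cramer's V association between two labelings
#'
#' `V = sqrt(chi2 / (N * (min(r, c) - 1)))` with the standard Pearson
#' chi-square statistic, computed after dropping empty rows/columns.  A
#' degenerate table (fewer than 2 nonzero rows or columns) returns 0 with a
#' warning.
#'
#' @param tab a [contingency_table()] (or plain count matrix) with r, c >= 2.
#' @return Real in \[0, 1\].
#' @export
cramers_v <- function(tab) {
  tab <- unclass(as.matrix(tab))
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("Cramer's V is undefined for tables with fewer than 2 rows or columns")
  tab <- drop_empty_margins(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    warning("degenerate contingency table (single nonzero row or column); ",
            "Cramer's V set to 0")
    return(0)
  }
  n <- sum(tab)
  expd <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - expd)^2 / expd)
  sqrt(chi2 / (n * (min(dim(tab)) - 1)))
}

table_entropies <- function(tab) {
  tab <- drop_empty_margins(as.matrix(tab))
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  hx <- -sum(px * log(px))
  hy <- -sum(py * log(py))
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
  list(hx = hx, hy = hy, mi = max(mi, 0))
}

#' Normalized mutual information of two labelings
#'
#' `NMI = 2 I(X; Y) / (H(X) + H(Y))` with natural-log entropies from the
#' table's empirical joint distribution.  Identical partitions (up to
#' relabelling) score 1; independent partitions score 0.  If either
#' partition has a single cluster the score is 0 with a warning (the
#' normalization is degenerate).
#'
#' @param tab a [contingency_table()] (or plain count matrix) with total >= 1.
#' @return Real in \[0, 1\].
#' @export
nmi <- function(tab) {
  tab <- as.matrix(tab)
  if (sum(tab) < 1) stop("empty contingency table")
  e <- table_entropies(tab)
  if (e$hx + e$hy == 0) {
    warning("both partitions have a single cluster; NMI set to 0")
    return(0)
  }
  if (e$hx == 0 || e$hy == 0) {
    warning("one partition has a single cluster; NMI set to 0")
    return(0)
  }
  min(2 * e$mi / (e$hx + e$hy), 1)
}

#' Variation of information between two labelings
#'
#' `VI = H(X) + H(Y) - 2 I(X; Y)` in nats; a metric on partitions (0 iff the
#' partitions coincide up to relabelling).
#'
#' @param tab a [contingency_table()] (or plain count matrix) with total >= 1.
#' @return Real >= 0.
#' @export
variation_of_information <- function(tab) {
  tab <- as.matrix(tab)
  if (sum(tab) < 1) stop("empty contingency table")
  e <- table_entropies(tab)
  max(e$hx + e$hy - 2 * e$mi, 0)
}

#' Multi-label Dice overlap between two parcellations
#'
#' Per label c present in either volume: `2 |A_c & B_c| / (|A_c| + |B_c|)`.
#' Labels must already be aligned ([align_labels()]).  Labels absent from
#' both volumes contribute nothing.
#'
#' @param a,b [label_volume()]s (or parcellations/MPMs) on the same grid.
#' @return List with `mean` and named vector `per_label`.
#' @export
dice_multilabel <- function(a, b) {
  a <- as_labels(a); b <- as_labels(b)
  check_same_grid(a$grid, b$grid)
  la <- as.vector(a$labels); lb <- as.vector(b$labels)
  labs <- sort(unique(c(la[la > 0L], lb[lb > 0L])))
  if (length(labs) == 0L) stop("both volumes are all background")
  per <- vapply(labs, function(c) {
    A <- la == c; B <- lb == c
    2 * sum(A & B) / (sum(A) + sum(B))
  }, numeric(1))
  names(per) <- labs
  list(mean = mean(per), per_label = per)
}

#' Binary overlap report for one label: Dice, sensitivity, specificity, IoU
#'
#' Compares the binary masks `A = (a == label)` (reference) and
#' `B = (b == label)` (test) over the full common grid.
#'
#' @param a reference [label_volume()] (or parcellation/MPM); must contain
#'   `label`.
#' @param b test volume on the same grid.
#' @param label the cluster/region label to compare.
#' @return Named list with `dice`, `sensitivity`, `specificity`, `iou`.
#' @export
overlap_report <- function(a, b, label) {
  a <- as_labels(a); b <- as_labels(b)
  check_same_grid(a$grid, b$grid)
  A <- as.vector(a$labels) == label
  B <- as.vector(b$labels) == label
  if (!any(A)) stop("label ", label, " absent from the reference volume")
  tp <- sum(A & B); fn <- sum(A & !B); fp <- sum(!A & B); tn <- sum(!A & !B)
  list(dice = 2 * tp / (2 * tp + fp + fn),
       sensitivity = tp / (tp + fn),
       specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
       iou = tp / (tp + fp + fn))
}

half_metric <- function(m1, m2, metric) {
  switch(metric,
         dice = dice_multilabel(m1, m2)$mean,
         cv   = cramers_v(contingency_table(m1, m2)),
         nmi  = nmi(contingency_table(m1, m2)),
         vi   = variation_of_information(contingency_table(m1, m2)),
         stop("unknown metric: ", metric))
}

#' Split-half consistency of a group parcellation
#'
#' Repeatedly splits the subjects at random into two equal halves (sizes
#' differ by one for odd counts), builds a maximum probability map per half,
#' and scores the agreement of the two MPMs with the chosen metric.  The
#' mean over repetitions is the reproducibility index used to pick the
#' number of clusters.
#'
#' @param parcs list of aligned [subject_parcellation()]s (>= 4 subjects).
#' @param metric one of `"cv"`, `"dice"`, `"nmi"`, `"vi"`.
#' @param n_reps number of random splits (the reference protocol uses 1,000).
#' @param rng_seed integer seed; results are deterministic given the seed.
#' @return List with `mean`, `sd`, `values` (per-rep), `metric`, `n_reps`.
#' @export
split_half_consistency <- function(parcs, metric = c("cv", "dice", "nmi", "vi"),
                                   n_reps = 1000L, rng_seed = 42L) {
  metric <- match.arg(metric)
  n <- length(parcs)
  if (n < 4L) stop("split-half consistency needs at least 4 subjects")
  n_reps <- as.integer(n_reps)
  stopifnot(n_reps >= 1L)
  h <- n %/% 2L
  vals <- withr::with_seed(as.integer(rng_seed), {
    vapply(seq_len(n_reps), function(r) {
      perm <- sample.int(n)
      # tie and degeneracy warnings are routine in resampled half-cohorts
      suppressWarnings({
        m1 <- build_mpm(group_probability_maps(parcs[perm[seq_len(h)]]))
        m2 <- build_mpm(group_probability_maps(parcs[perm[(h + 1L):n]]))
        half_metric(m1, m2, metric)
      })
    }, numeric(1))
  })
  list(mean = mean(vals), sd = stats::sd(vals), values = vals,
       metric = metric, n_reps = n_reps)
}

#' Split-half evaluation report over a range of cluster numbers
#'
#' Computes the split-half mean of every index (CV, Dice, NMI, VI) for each
#' candidate K, the table consumed by [select_optimal_k()].
#'
#' @param parcs_by_k named list: one entry per K, each a list of aligned
#'   [subject_parcellation()]s at that K.
#' @param n_reps random splits per index and K.
#' @param rng_seed integer seed.
#' @return Data frame with columns `k`, `cv`, `dice`, `nmi`, `vi` and their
#'   `*_sd` companions; one row per K.
#' @export
evaluation_report <- function(parcs_by_k, n_reps = 1000L, rng_seed = 42L) {
  ks <- as.integer(names(parcs_by_k))
  if (anyNA(ks)) ks <- vapply(parcs_by_k, function(p) p[[1L]]$k, integer(1))
  rows <- lapply(seq_along(parcs_by_k), function(i) {
    res <- lapply(c("cv", "dice", "nmi", "vi"), function(m)
      split_half_consistency(parcs_by_k[[i]], metric = m, n_reps = n_reps,
                             rng_seed = rng_seed))
    names(res) <- c("cv", "dice", "nmi", "vi")
    data.frame(k = ks[i],
               cv = res$cv$mean, dice = res$dice$mean,
               nmi = res$nmi$mean, vi = res$vi$mean,
               cv_sd = res$cv$sd, dice_sd = res$dice$sd,
               nmi_sd = res$nmi$sd, vi_sd = res$vi$sd)
  })
  do.call(rbind, rows)
}

#' Select the optimal number of clusters from an evaluation report
#'
#' Ranks the candidate K values on each index (CV, Dice, NMI: higher is
#' better; VI: lower is better) and returns the K with the best (lowest)
#' total rank.  Exact ties go to the smaller K, with a message.
#'
#' @param report data frame with columns `k`, `cv`, `dice`, `nmi`, `vi`
#'   covering >= 2 values of K (as from [evaluation_report()]).
#' @return The selected K (integer).
#' @export
select_optimal_k <- function(report) {
  need <- c("k", "cv", "dice", "nmi", "vi")
  if (!all(need %in% names(report)))
    stop("report must have columns ", paste(need, collapse = ", "))
  if (nrow(report) < 2L) stop("report must cover at least 2 values of K")
  if (anyNA(report[need]) || !all(vapply(report[need], is.numeric, logical(1))))
    stop("report contains missing or non-numeric values")
  total <- rank(-report$cv, ties.method = "average") +
    rank(-report$dice, ties.method = "average") +
    rank(-report$nmi, ties.method = "average") +
    rank(report$vi, ties.method = "average")
  best <- which(total == min(total))
  if (length(best) > 1L) {
    message("tied total ranks for K = ",
            paste(report$k[best], collapse = ", "),
            "; selecting the smallest")
    best <- best[which.min(report$k[best])]
  }
  as.integer(report$k[best])
}
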
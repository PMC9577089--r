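#' Connectivity fingerprint of one seed region
#'
#' A fingerprint is one region's vector of connection values over a fixed,
#' ordered set of named target regions — either structural connection
#' probabilities (streamline fractions) or functional Pearson correlations.
#'
#' @param values numeric vector of connection values, one per target.
#' @param target_names character vector of target names, same length and
#'   fixed order.
#' @param region_id identifier of the seed region.
#' @param kind `"structural"` or `"functional"`.
#' @param normalized logical; `TRUE` after [normalize_fingerprint()].
#' @return An object of class `fingerprint`.
#' @export
fingerprint <- function(values, target_names, region_id,
                        kind = c("structural", "functional"),
                        normalized = FALSE) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  target_names <- as.character(target_names)
  if (length(values) != length(target_names))
    stop("one value per target is required")
  if (anyDuplicated(target_names)) stop("target names must be unique")
  if (anyNA(values)) stop("fingerprint values contain NA")
  if (kind == "functional" && (min(values) < -1 - 1e-9 || max(values) > 1 + 1e-9))
    stop("functional fingerprint values must lie in [-1, 1]")
  if (normalized &&
      (abs(min(values)) > 1e-12 || abs(max(values) - 1) > 1e-12))
    stop("a normalized fingerprint must have min 0 and max 1")
  structure(list(region_id = region_id, target_names = target_names,
                 values = stats::setNames(values, target_names),
                 kind = kind, normalized = isTRUE(normalized)),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat("<fingerprint> ", x$region_id, " (", x$kind,
      if (x$normalized) ", normalized", "): ",
      length(x$values), " targets\n", sep = "")
  print(round(x$values, 3))
  invisible(x)
}

#' A set of fingerprints sharing one target order
#'
#' @param fingerprints list of [fingerprint()]s with identical
#'   `target_names` in identical order.
#' @param species species tag (e.g. `"human"`, `"macaque"`).
#' @return An object of class `fingerprint_set`.
#' @export
fingerprint_set <- function(fingerprints, species = "unspecified") {
  stopifnot(length(fingerprints) >= 1L,
            all(vapply(fingerprints, inherits, logical(1), "fingerprint")))
  tn <- fingerprints[[1L]]$target_names
  for (fp in fingerprints)
    if (!identical(fp$target_names, tn))
      stop("all fingerprints in a set must share the same target order")
  ids <- vapply(fingerprints, function(fp) as.character(fp$region_id),
                character(1))
  if (anyDuplicated(ids)) stop("duplicate region ids in fingerprint set")
  names(fingerprints) <- ids
  structure(list(species = species, fingerprints = fingerprints,
                 target_names = tn),
            class = "fingerprint_set")
}

check_same_targets <- function(p, q) {
  if (!identical(p$target_names, q$target_names))
    stop("fingerprints are defined over different target orders")
  invisible(TRUE)
}

#' Structural fingerprint of a seed region from streamline counts
#'
#' The connection probability to target j is the fraction of seeded
#' streamlines from the region that reached the target:
#' `sum(counts[region, j]) / (|region| * samples_per_voxel)`.
#'
#' @param conn a [connectivity_matrix()] whose columns include all targets.
#' @param seed_region seed voxel ids (subset of `conn$seed_voxel_ids`)
#'   forming the region, or a logical row selector.
#' @param targets a [region_set()] or character vector of target names.
#' @param samples_per_voxel streamlines seeded per voxel (the tractography
#'   sampling count, e.g. 20,000).
#' @param region_id identifier for the resulting fingerprint.
#' @return An unnormalized structural [fingerprint()].
#' @export
extract_structural_fingerprint <- function(conn, seed_region, targets,
                                           samples_per_voxel,
                                           region_id = "region") {
  stopifnot(inherits(conn, "connectivity_matrix"), samples_per_voxel > 0)
  target_names <- if (inherits(targets, "region_set")) targets$names
                  else as.character(targets)
  missing <- setdiff(target_names, conn$target_ids)
  if (length(missing) > 0L)
    stop("unknown target(s): ", paste(missing, collapse = ", "))
  if (is.logical(seed_region)) {
    rows <- which(seed_region)
  } else {
    rows <- match(as.integer(seed_region), conn$seed_voxel_ids)
    if (anyNA(rows)) stop("seed_region contains voxels outside the matrix")
  }
  if (length(rows) == 0L) stop("empty seed region")
  tot <- colSums(conn$counts[rows, target_names, drop = FALSE])
  fingerprint(tot / (length(rows) * samples_per_voxel), target_names,
              region_id = region_id, kind = "structural")
}

#' Min-max normalization of a fingerprint
#'
#' Rescales the connection values so that the strongest target maps to 1 and
#' the weakest to 0: `v' = (v - min) / (max - min)`.  Idempotent and
#' rank-preserving.  A constant fingerprint cannot be normalized.
#'
#' @param fp a [fingerprint()].
#' @return The normalized [fingerprint()] (`normalized = TRUE`).
#' @export
normalize_fingerprint <- function(fp) {
  stopifnot(inherits(fp, "fingerprint"))
  lo <- min(fp$values); hi <- max(fp$values)
  if (hi == lo) stop("degenerate fingerprint: all connection values equal")
  v <- (fp$values - lo) / (hi - lo)
  fingerprint(v, fp$target_names, region_id = fp$region_id, kind = fp$kind,
              normalized = TRUE)
}

#' Cosine similarity between two fingerprints
#'
#' `CS = sum(p_i q_i) / (sqrt(sum(p_i^2)) * sqrt(sum(q_i^2)))`, in \[-1, 1\];
#' values near 1 indicate near-identical connection patterns (candidate
#' homologs), near 0 unrelated patterns.
#'
#' @param p,q [fingerprint()]s over the same target order; neither all-zero.
#' @return Real in \[-1, 1\].
#' @export
cosine_similarity <- function(p, q) {
  stopifnot(inherits(p, "fingerprint"), inherits(q, "fingerprint"))
  check_same_targets(p, q)
  np <- sqrt(sum(p$values^2)); nq <- sqrt(sum(q$values^2))
  if (np == 0 || nq == 0)
    stop("cosine similarity is undefined for an all-zero fingerprint")
  max(min(sum(p$values * q$values) / (np * nq), 1), -1)
}

#' Manhattan distance between two fingerprints
#'
#' `MD = sum(|p_i - q_i|)`; smaller distances indicate more similar
#' connection patterns.
#'
#' @param p,q [fingerprint()]s over the same target order.
#' @return Real >= 0.
#' @export
manhattan_distance <- function(p, q) {
  stopifnot(inherits(p, "fingerprint"), inherits(q, "fingerprint"))
  check_same_targets(p, q)
  sum(abs(p$values - q$values))
}

#' Functional connectivity fingerprint from region time series
#'
#' The value for target j is the Pearson correlation between the seed
#' region's time series and target j's series.
#'
#' @param timeseries numeric matrix, regions x time, with region names as
#'   `rownames` (>= 3 time points).
#' @param seed_region name of the seed region's row.
#' @param targets a [region_set()] or character vector of target names
#'   present in `timeseries`.
#' @return A functional [fingerprint()].
#' @export
fc_fingerprint <- function(timeseries, seed_region, targets) {
  stopifnot(is.matrix(timeseries), !is.null(rownames(timeseries)),
            ncol(timeseries) >= 3L)
  target_names <- if (inherits(targets, "region_set")) targets$names
                  else as.character(targets)
  need <- c(seed_region, target_names)
  missing <- setdiff(need, rownames(timeseries))
  if (length(missing) > 0L)
    stop("region(s) absent from the time series: ",
         paste(missing, collapse = ", "))
  sds <- apply(timeseries[need, , drop = FALSE], 1L, stats::sd)
  if (any(sds == 0))
    stop("constant time series for region(s): ",
         paste(need[sds == 0], collapse = ", "))
  r <- as.vector(stats::cor(timeseries[seed_region, ],
                            t(timeseries[target_names, , drop = FALSE])))
  fingerprint(pmin(pmax(r, -1), 1), target_names, region_id = seed_region,
              kind = "functional")
}

#' Select targets above a correlation threshold
#'
#' Keeps the targets whose functional connection value strictly exceeds
#' `r_min` (the reference analysis uses 0.4 and 0.5 cutoffs) and orders them
#' by descending connection strength.
#'
#' @param fp a functional [fingerprint()].
#' @param r_min correlation cutoff (strict: values equal to `r_min` are
#'   excluded).
#' @return A [fingerprint()] restricted to the selected targets, sorted
#'   descending; may be empty (zero targets).
#' @export
threshold_targets <- function(fp, r_min) {
  stopifnot(inherits(fp, "fingerprint"))
  if (fp$kind != "functional")
    stop("threshold_targets applies to functional fingerprints")
  keep <- which(fp$values > r_min)
  keep <- keep[order(fp$values[keep], decreasing = TRUE)]
  structure(list(region_id = fp$region_id,
                 target_names = fp$target_names[keep],
                 values = fp$values[keep],
                 kind = fp$kind, normalized = fp$normalized),
            class = "fingerprint")
}

#' Average fingerprints across subjects
#'
#' Structural fingerprints are averaged elementwise (typically after Eq.-1
#' style min-max normalization); functional fingerprints are averaged on the
#' Fisher-z scale and transformed back, the variance-stabilizing default for
#' correlations.
#'
#' @param fps list of [fingerprint()]s with identical kind and target order.
#' @param region_id identifier for the pooled fingerprint.
#' @return A [fingerprint()].
#' @export
pool_fingerprints <- function(fps, region_id = fps[[1L]]$region_id) {
  stopifnot(length(fps) >= 1L,
            all(vapply(fps, inherits, logical(1), "fingerprint")))
  kind <- fps[[1L]]$kind
  for (fp in fps) {
    check_same_targets(fp, fps[[1L]])
    if (fp$kind != kind) stop("cannot pool structural with functional")
  }
  vals <- do.call(rbind, lapply(fps, function(fp) fp$values))
  if (kind == "functional") {
    z <- atanh(pmin(pmax(vals, -1 + 1e-12), 1 - 1e-12))
    v <- tanh(colMeans(z))
  } else {
    v <- colMeans(vals)
  }
  fingerprint(v, fps[[1L]]$target_names, region_id = region_id, kind = kind)
}

#' Match candidate homolog regions across two fingerprint sets
#'
#' Computes the full cosine-similarity and Manhattan-distance matrices over
#' all cross pairs and proposes, for every region in `set_a`, the region of
#' `set_b` with maximal cosine similarity.  The Manhattan-distance best match
#' is reported alongside; disagreement between the two criteria, and exact
#' CS ties, are flagged rather than resolved.
#'
#' @param set_a,set_b [fingerprint_set()]s over the same target order, both
#'   raw or both normalized consistently.
#' @return An object of class `homolog_match`: list with matrices `cs`, `md`
#'   (rows = `set_a` regions, columns = `set_b` regions) and a data frame
#'   `matches` with columns `region_a`, `match_cs`, `cs`, `match_md`, `md`,
#'   `agree`, `cs_tie`.
#' @export
match_homologs <- function(set_a, set_b) {
  stopifnot(inherits(set_a, "fingerprint_set"),
            inherits(set_b, "fingerprint_set"))
  if (!identical(set_a$target_names, set_b$target_names))
    stop("fingerprint sets are defined over different target orders")
  norm_a <- vapply(set_a$fingerprints, function(f) f$normalized, logical(1))
  norm_b <- vapply(set_b$fingerprints, function(f) f$normalized, logical(1))
  if (length(unique(c(norm_a, norm_b))) > 1L)
    stop("sets mix normalized and unnormalized fingerprints")
  na <- length(set_a$fingerprints); nb <- length(set_b$fingerprints)
  cs <- matrix(NA_real_, na, nb,
               dimnames = list(names(set_a$fingerprints),
                               names(set_b$fingerprints)))
  md <- cs
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    cs[i, j] <- cosine_similarity(set_a$fingerprints[[i]],
                                  set_b$fingerprints[[j]])
    md[i, j] <- manhattan_distance(set_a$fingerprints[[i]],
                                   set_b$fingerprints[[j]])
  }
  best_cs <- apply(cs, 1L, which.max)
  cs_tie <- apply(cs, 1L, function(r) sum(r == max(r)) > 1L)
  best_md <- apply(md, 1L, which.min)
  matches <- data.frame(
    region_a = names(set_a$fingerprints),
    match_cs = colnames(cs)[best_cs],
    cs = cs[cbind(seq_len(na), best_cs)],
    match_md = colnames(md)[best_md],
    md = md[cbind(seq_len(na), best_md)],
    agree = best_cs == best_md,
    cs_tie = cs_tie,
    row.names = NULL)
  if (any(cs_tie))
    warning("exact cosine-similarity ties for region(s): ",
            paste(matches$region_a[cs_tie], collapse = ", "))
  structure(list(cs = cs, md = md, matches = matches),
            class = "homolog_match")
}

#' @export
print.homolog_match <- function(x, ...) {
  cat("<homolog_match> ", nrow(x$cs), " x ", ncol(x$cs), " regions\n", sep = "")
  print(x$matches)
  invisible(x)
}
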
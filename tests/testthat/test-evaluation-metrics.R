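flat_pair <- function(a, b) {
  n <- length(a)
  list(a = make_labels(a, c(n, 1, 1)), b = make_labels(b, c(n, 1, 1)))
}

test_that("contingency tables count jointly labelled voxels", {
  p <- flat_pair(c(1, 1, 2, 2), c(1, 2, 1, 2))
  tab <- contingency_table(p$a, p$b)
  expect_equal(as.vector(unclass(tab)), rep(1L, 4))

  q <- flat_pair(c(1, 1, 2, 2), c(1, 1, 2, 2))
  tab2 <- unclass(contingency_table(q$a, q$b))
  expect_equal(diag(tab2), c(2L, 2L), ignore_attr = TRUE)
  expect_equal(sum(tab2) - sum(diag(tab2)), 0L)

  # background in either volume is excluded from the total
  r <- flat_pair(c(0, 1, 2, 2, 1), c(1, 1, 0, 2, 2))
  expect_equal(sum(contingency_table(r$a, r$b)),
               sum(c(0, 1, 2, 2, 1) > 0 & c(1, 1, 0, 2, 2) > 0))
  z <- flat_pair(c(1, 0), c(0, 1))
  expect_error(contingency_table(z$a, z$b), "empty joint support")
})

test_that("Cramer's V matches its chi-square definition", {
  expect_equal(cramers_v(matrix(c(2, 0, 0, 2), 2)), 1)
  expect_equal(cramers_v(matrix(c(1, 1, 1, 1), 2)), 0)
  tab <- matrix(c(10, 3, 2, 9), 2)
  expect_equal(cramers_v(tab), oracle_cramers_v(tab), tolerance = 1e-12)
  expect_error(cramers_v(matrix(c(1, 2), 1)), "fewer than 2")
  expect_warning(v <- cramers_v(matrix(c(3, 0, 4, 0), 2)), "degenerate")
  expect_equal(v, 0)
})

test_that("NMI and VI match their entropy definitions", {
  ident <- matrix(c(3, 0, 0, 5), 2)
  expect_equal(nmi(ident), 1)
  expect_equal(variation_of_information(ident), 0)

  indep <- matrix(c(2, 2, 2, 2), 2)
  expect_equal(nmi(indep), 0)
  expect_equal(variation_of_information(indep), 2 * log(2))

  tab <- matrix(c(3, 1, 1, 3), 2)
  expect_equal(nmi(tab), oracle_nmi(tab), tolerance = 1e-12)
  expect_equal(variation_of_information(tab), oracle_vi(tab),
               tolerance = 1e-12)

  # VI equals H(X|Y) + H(Y|X)
  n <- sum(tab); p <- tab / n
  hxy <- -sum(p[p > 0] * log(p[p > 0]))
  hx <- oracle_entropy(rowSums(p)); hy <- oracle_entropy(colSums(p))
  expect_equal(variation_of_information(tab), (hxy - hy) + (hxy - hx),
               tolerance = 1e-12)

  expect_warning(nmi(matrix(c(4, 3), 1, 2)), "single cluster")
})

test_that("multi-label Dice matches explicit set counting", {
  p <- flat_pair(rep(1:2, each = 4), c(1, 1, 1, 2, 2, 2, 2, 2))
  d <- dice_multilabel(p$a, p$b)
  expect_equal(d$per_label[["1"]], 2 * 3 / (4 + 3))
  expect_equal(d$per_label[["2"]], 2 * 4 / (4 + 5))
  expect_equal(d$mean, mean(c(6 / 7, 8 / 9)))

  same <- flat_pair(rep(1:2, 4), rep(1:2, 4))
  expect_equal(dice_multilabel(same$a, same$b)$mean, 1)

  disj <- flat_pair(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(dice_multilabel(disj$a, disj$b)$mean, 0)
})

test_that("the binary overlap report matches direct set arithmetic", {
  # |A| = 100, |B| = 90, |A & B| = 80 in a 1000-voxel domain
  a <- c(rep(1, 100), rep(0, 900))
  b <- c(rep(1, 80), rep(0, 20), rep(1, 10), rep(0, 890))
  p <- flat_pair(a, b)
  rep_ <- overlap_report(p$a, p$b, 1)
  expect_equal(rep_$dice, 2 * 80 / (100 + 90))
  expect_equal(rep_$sensitivity, 80 / 100)
  expect_equal(rep_$specificity, (1000 - 110) / 900)
  expect_equal(rep_$iou, 80 / 110)

  same <- overlap_report(p$a, p$a, 1)
  expect_equal(unlist(same), c(dice = 1, sensitivity = 1, specificity = 1,
                               iou = 1))

  compl <- flat_pair(c(1, 1, 0, 0), c(0, 0, 1, 1))
  r2 <- overlap_report(compl$a, compl$b, 1)
  expect_equal(r2$dice, 0)
  expect_equal(r2$sensitivity, 0)
  expect_equal(r2$iou, 0)
  expect_error(overlap_report(p$a, p$b, 7), "absent")
})

test_that("all contingency metrics agree with brute force on random volumes", {
  set.seed(71)
  for (rep in 1:100) {
    pair <- random_label_pair()
    tab <- tryCatch(contingency_table(pair$a, pair$b), error = function(e) NULL)
    if (is.null(tab)) next
    oracle_tab <- oracle_contingency(pair$a, pair$b)
    expect_equal(as.vector(unclass(tab)), as.vector(oracle_tab))
    if (nrow(tab) >= 2 && ncol(tab) >= 2)
      expect_equal(suppressWarnings(cramers_v(tab)), oracle_cramers_v(tab),
                   tolerance = 1e-10)
    expect_equal(suppressWarnings(nmi(tab)), min(oracle_nmi(tab), 1),
                 tolerance = 1e-10)
    expect_equal(variation_of_information(tab), max(oracle_vi(tab), 0),
                 tolerance = 1e-10)
    expect_equal(dice_multilabel(pair$a, pair$b)$mean,
                 oracle_dice_multilabel(pair$a, pair$b), tolerance = 1e-10)
    lab1 <- as.vector(pair$a$labels)
    lab1 <- lab1[lab1 > 0][1]
    o <- oracle_overlap(pair$a, pair$b, lab1)
    expect_equal(unlist(overlap_report(pair$a, pair$b, lab1)), unlist(o),
                 tolerance = 1e-10)
  }
})

test_that("metrics are invariant to consistent label permutation", {
  set.seed(81)
  pair <- random_label_pair(k_max = 4L)
  tab <- contingency_table(pair$a, pair$b)
  v0 <- suppressWarnings(cramers_v(tab))
  n0 <- suppressWarnings(nmi(tab))
  vi0 <- variation_of_information(tab)
  # permute the labels of b
  lb <- as.vector(pair$b$labels)
  k <- max(lb)
  perm <- sample(k)
  lb2 <- ifelse(lb > 0, perm[pmax(lb, 1)], 0L)
  b2 <- make_labels(lb2, pair$b$grid$shape)
  tab2 <- contingency_table(pair$a, b2)
  expect_equal(suppressWarnings(cramers_v(tab2)), v0, tolerance = 1e-12)
  expect_equal(suppressWarnings(nmi(tab2)), n0, tolerance = 1e-12)
  expect_equal(variation_of_information(tab2), vi0, tolerance = 1e-12)
})

test_that("VI satisfies the metric axioms on sampled partition triples", {
  set.seed(91)
  for (rep in 1:100) {
    shape <- c(5, 4, 2)
    n <- prod(shape)
    labs <- replicate(3, sample(1:3, n, replace = TRUE), simplify = FALSE)
    vols <- lapply(labs, make_labels, shape = shape)
    vi <- function(x, y) variation_of_information(contingency_table(x, y))
    d12 <- vi(vols[[1]], vols[[2]])
    d13 <- vi(vols[[1]], vols[[3]])
    d23 <- vi(vols[[2]], vols[[3]])
    expect_gte(d12, 0)
    expect_equal(d12, vi(vols[[2]], vols[[1]]), tolerance = 1e-12)
    expect_equal(vi(vols[[1]], vols[[1]]), 0, tolerance = 1e-12)
    expect_lte(d13, d12 + d23 + 1e-10)
  }
})

test_that("split-half consistency is 1 for identical subjects and reproducible", {
  shape <- c(4, 3, 2)
  lab <- rep(c(1, 2), 12)
  parcs <- replicate(6, subject_parcellation(make_labels(lab, shape), 2),
                     simplify = FALSE)
  r <- split_half_consistency(parcs, "dice", n_reps = 20, rng_seed = 5L)
  expect_equal(r$mean, 1)
  expect_equal(r$sd, 0)

  cs <- default_cohort_with_sims()
  parcs2 <- cluster_and_align(cs$sims, cs$cohort$ground_truth, 3)
  a <- split_half_consistency(parcs2, "cv", n_reps = 10, rng_seed = 9L)
  b <- split_half_consistency(parcs2, "cv", n_reps = 10, rng_seed = 9L)
  expect_identical(a$values, b$values)
  expect_error(split_half_consistency(parcs2[1:3], "cv"), "at least 4")
})

test_that("the optimal-K rule ranks all four indexes jointly", {
  # K = 3 dominating every index wins
  rep3 <- data.frame(k = 2:5,
                     cv = c(0.3, 0.6, 0.2, 0.1),
                     dice = c(0.3, 0.6, 0.2, 0.1),
                     nmi = c(0.3, 0.6, 0.2, 0.1),
                     vi = c(0.5, 0.1, 0.6, 0.7))
  expect_equal(select_optimal_k(rep3), 3L)

  # exact tie between K = 2 and K = 3 goes to the smaller K
  tied <- data.frame(k = 2:3, cv = c(0.5, 0.5), dice = c(0.4, 0.4),
                     nmi = c(0.5, 0.5), vi = c(0.1, 0.1))
  expect_message(kk <- select_optimal_k(tied), "smallest")
  expect_equal(kk, 2L)

  expect_error(select_optimal_k(data.frame(k = 2, cv = 1, dice = 1,
                                           nmi = 1, vi = 0)),
               "at least 2")
})
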
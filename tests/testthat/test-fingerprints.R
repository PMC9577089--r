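fp <- function(v, kind = "structural", normalized = FALSE,
               targets = sprintf("t%d", seq_along(v)), id = "r") {
  fingerprint(v, targets, region_id = id, kind = kind,
              normalized = normalized)
}

test_that("structural fingerprints are streamline fractions per target", {
  m <- rbind(v1 = c(10, 40, 0))
  colnames(m) <- c("t1", "t2", "t3")
  conn <- connectivity_matrix(m)
  f <- extract_structural_fingerprint(conn, 1L, c("t1", "t2", "t3"), 1000)
  expect_equal(unname(f$values), c(0.01, 0.04, 0))

  # doubling counts and samples per voxel changes nothing
  conn2 <- connectivity_matrix(2 * m)
  f2 <- extract_structural_fingerprint(conn2, 1L, c("t1", "t2", "t3"), 2000)
  expect_equal(f2$values, f$values)

  # 2-voxel region: sums divided by |region| * samples
  m3 <- rbind(v1 = c(5, 5, 0), v2 = c(15, 35, 0))
  colnames(m3) <- c("t1", "t2", "t3")
  f3 <- extract_structural_fingerprint(connectivity_matrix(m3), 1:2,
                                       c("t1", "t2", "t3"), 1000)
  expect_equal(unname(f3$values), c(0.01, 0.02, 0))

  expect_error(extract_structural_fingerprint(conn, 1L, "nope", 1000),
               "unknown target")
  expect_error(extract_structural_fingerprint(conn, integer(0), "t1", 1000),
               "empty seed region")
})

test_that("min-max normalization maps min to 0, max to 1 and is idempotent", {
  expect_equal(unname(normalize_fingerprint(fp(c(2, 5, 8)))$values),
               c(0, 0.5, 1))
  expect_equal(unname(normalize_fingerprint(fp(c(0.01, 0.04, 0)))$values),
               c(0.25, 1, 0))
  once <- normalize_fingerprint(fp(c(3, 9, 4, 7)))
  twice <- normalize_fingerprint(once)
  expect_equal(twice$values, once$values)
  expect_true(twice$normalized)
  # order-preserving
  expect_equal(order(once$values), order(c(3, 9, 4, 7)))
  expect_error(normalize_fingerprint(fp(c(2, 2, 2))), "degenerate")
})

test_that("cosine similarity and Manhattan distance match their formulas", {
  p <- fp(c(1, 2, 2)); q <- fp(c(2, 1, 2))
  expect_equal(cosine_similarity(p, q), 8 / 9, tolerance = 1e-12)
  expect_equal(cosine_similarity(p, p), 1)
  expect_equal(cosine_similarity(fp(c(1, 0)), fp(c(0, 1))), 0)
  expect_equal(manhattan_distance(p, p), 0)
  expect_equal(manhattan_distance(fp(c(1, 0, 1)), fp(c(0, 1, 1))), 2)

  expect_error(cosine_similarity(fp(c(0, 0)), fp(c(1, 1))), "all-zero")
  mismatch <- fp(c(1, 2), targets = c("x", "y"))
  expect_error(cosine_similarity(p, mismatch), "different target orders")
  expect_error(manhattan_distance(p, mismatch), "different target orders")
})

test_that("CS is scale-invariant and bounded; MD satisfies the metric axioms", {
  set.seed(13)
  for (rep in 1:200) {
    n <- sample(3:19, 1)
    a <- fp(rnorm(n)); b <- fp(rnorm(n)); c <- fp(rnorm(n))
    cs <- cosine_similarity(a, b)
    expect_gte(cs, -1); expect_lte(cs, 1)
    expect_equal(cosine_similarity(fp(3.7 * a$values), b), cs,
                 tolerance = 1e-12)
    d_ab <- manhattan_distance(a, b)
    expect_equal(d_ab, sum(abs(a$values - b$values)), tolerance = 1e-12)
    expect_equal(d_ab, manhattan_distance(b, a))
    expect_lte(manhattan_distance(a, c),
               d_ab + manhattan_distance(b, c) + 1e-12)
  }
  # non-negative fingerprints give CS in [0, 1]
  for (rep in 1:50) {
    a <- fp(runif(10)); b <- fp(runif(10))
    cs <- cosine_similarity(a, b)
    expect_gte(cs, 0); expect_lte(cs, 1)
  }
})

test_that("functional fingerprints are Pearson correlations with the seed", {
  set.seed(17)
  ts <- matrix(rnorm(4 * 50), 4, dimnames = list(c("seed", "a", "b", "c")))
  ts["a", ] <- ts["seed", ]
  ts["b", ] <- -ts["seed", ]
  f <- fc_fingerprint(ts, "seed", c("a", "b", "c"))
  expect_equal(f$kind, "functional")
  expect_equal(unname(f$values["a"]), 1)
  expect_equal(unname(f$values["b"]), -1)
  expect_equal(unname(f$values["c"]), cor(ts["seed", ], ts["c", ]),
               tolerance = 1e-12)

  ts2 <- ts; ts2["c", ] <- 5
  expect_error(fc_fingerprint(ts2, "seed", c("a", "c")), "constant.*c")
  expect_error(fc_fingerprint(ts, "seed", "zz"), "absent")
})

test_that("planted functional correlation is recovered through the full path", {
  tc <- diag(3)
  tc[1, 2] <- tc[2, 1] <- 0.6
  ts <- generate_timeseries(c("seed", "hit", "miss"), tc, length = 1000,
                            rng_seed = 19L)
  f <- fc_fingerprint(ts, "seed", c("hit", "miss"))
  expect_lt(abs(f$values[["hit"]] - 0.6), 0.05)
  expect_lt(abs(f$values["miss"]), 0.15)
})

test_that("threshold_targets applies a strict cutoff and sorts descending", {
  f <- fp(c(0.45, 0.39, 0.62), kind = "functional",
          targets = c("A", "B", "C"))
  sel <- threshold_targets(f, 0.4)
  expect_identical(sel$target_names, c("C", "A"))
  expect_identical(unname(sel$values), c(0.62, 0.45))

  expect_length(threshold_targets(f, 0.9)$values, 0)

  g <- fp(c(0.4, 0.5), kind = "functional", targets = c("A", "B"))
  expect_identical(threshold_targets(g, 0.4)$target_names, "B")
  expect_error(threshold_targets(fp(c(1, 2)), 0.4), "functional")
})

test_that("homolog matching recovers identity and flags ties", {
  sets <- generate_fingerprint_sets(4, 4, n_targets = 19,
                                    planted_pairs = cbind(1:4, 1:4),
                                    noise = 0.1, rng_seed = 23L)
  norm_set <- function(s)
    fingerprint_set(lapply(s$fingerprints, normalize_fingerprint), s$species)
  a <- norm_set(sets$set_a)

  # set_b = copy of set_a: identity pairing, CS diagonal 1, MD diagonal 0
  self <- match_homologs(a, a)
  expect_equal(unname(diag(self$cs)), rep(1, 4))
  expect_equal(unname(diag(self$md)), rep(0, 4))
  expect_identical(self$matches$match_cs, self$matches$region_a)
  expect_true(all(self$matches$agree))

  # two identical regions in set_b produce a flagged CS tie
  dup <- fingerprint_set(list(a$fingerprints[[1]],
                              fp(a$fingerprints[[1]]$values, id = "copy",
                                 targets = a$target_names,
                                 normalized = TRUE)),
                         species = "dup")
  expect_warning(tied <- match_homologs(a, dup), "ties")
  expect_true(tied$matches$cs_tie[1])
})

test_that("pooling averages structural values and Fisher-z for functional", {
  s1 <- fp(c(0, 0.5, 1), normalized = TRUE)
  s2 <- fp(c(0, 0.7, 1), normalized = TRUE)
  pooled <- pool_fingerprints(list(s1, s2))
  expect_equal(unname(pooled$values), c(0, 0.6, 1))

  f1 <- fp(c(0.2, 0.8), kind = "functional")
  f2 <- fp(c(0.4, 0.6), kind = "functional")
  pf <- pool_fingerprints(list(f1, f2))
  expect_equal(unname(pf$values),
               tanh(colMeans(rbind(atanh(c(0.2, 0.8)), atanh(c(0.4, 0.6))))),
               tolerance = 1e-12)
})
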
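# Frozen oracle values for the methods worked example (X = ABCC, Y = DBBCE,
# S(A,D) = 0.8): dot = 0.8 + 1 + 1 + 0.8 + 0 = 3.6, |x| = sqrt(3.64),
# |y| = sqrt(4.64), cosine = 3.6 / sqrt(3.64 * 4.64).
COS_WORKED <- 3.6 / sqrt(3.64 * 4.64)

test_that("worked-example universe and vectors reproduce exactly", {
  ex <- worked_example()
  sx <- domain_set(ex$dax); sy <- domain_set(ex$day)
  u <- domain_universe(sx, sy)
  expect_length(u, 5L)
  expect_equal(u, c("A", "B", "C", "D", "E"))
  vx <- universe_vector(u, sx, ex$m)
  vy <- universe_vector(u, sy, ex$m)
  expect_equal(vx, c(1.0, 1.0, 1.0, 0.8, 0.0))
  expect_equal(vy, c(0.8, 1.0, 1.0, 1.0, 1.0))
  expect_equal(cosine(vx, vy), COS_WORKED)
  expect_equal(da_similarity(ex$dax, ex$day, ex$m, measure_config("cos", 1)),
               COS_WORKED)
})

test_that("worked-example MWM selects {(A,D),(B,B),(C,C)} and scores 0.7", {
  ex <- worked_example()
  s <- mwm_score(domain_set(ex$dax), domain_set(ex$day), ex$m)
  expect_equal(as.numeric(s), 0.7)   # (0.8 + 1 + 1) / max(3, 4)
  matching <- attr(s, "matching")
  expect_setequal(paste(matching[, 1], matching[, 2]),
                  c("A D", "B B", "C C"))
  # independent check: exhaustive enumeration over the 3 x 4 bipartite graph
  w <- outer(c("A", "B", "C"), c("B", "C", "D", "E"),
             function(a, b) similarity(ex$m, a, b))
  expect_equal(brute_mwm(w) / 4, 0.7)
  expect_equal(da_similarity(ex$dax, ex$day, ex$m, measure_config("mwm", 1)),
               0.7)
})

test_that("order-2 items and pair similarities follow the pair formula", {
  ex <- worked_example()
  # universe of pair sets, first-seen order: X pairs then new Y pairs
  u2 <- domain_universe(unique(consecutive_pairs(ex$dax)),
                        unique(consecutive_pairs(ex$day)))
  expect_equal(u2, c("A>B", "B>C", "C>C", "D>B", "B>B", "C>E"))
  expect_equal(pair_similarity(ex$m, "A>B", "A>C"), 0.5)  # S(B,C) = 0
  expect_equal(pair_similarity(ex$m, "A>B", "D>B"), 0.9)  # 0.5*(0.8 + 1)
  expect_equal(pair_similarity(ex$m, "A>B", "A>B"), 1)
})

test_that("cosine limit cases: disjoint -> 0, same content reordered -> 1", {
  id <- domain_simmatrix()   # identity-only matrix
  expect_equal(da_similarity(c("A", "B"), c("C", "D"), id,
                             measure_config("cos", 1)), 0)
  m <- random_matrix()
  expect_equal(da_similarity(c("A", "B", "C"), c("C", "B", "A"), m,
                             measure_config("cos", 1)), 1)
  expect_equal(da_similarity(c("A", "B", "C"), c("C", "B", "A"),
                             worked_example_matrix(),
                             measure_config("cos", 1)), 1)
  expect_error(cosine(c(0, 0), c(1, 1)), "zero-norm")
})

test_that("with the identity matrix COS_O1 reduces to the set cosine", {
  id <- domain_simmatrix()
  withr::with_seed(7, {
    for (i in 1:50) {
      dax <- random_arrangement(); day <- random_arrangement()
      sx <- domain_set(dax); sy <- domain_set(day)
      expected <- length(intersect(sx, sy)) /
        sqrt(length(sx) * length(sy))
      expect_equal(da_similarity(dax, day, id, measure_config("cos", 1)),
                   expected)
    }
  })
})

test_that("COS_O1 is invariant under reordering and tandem repetition", {
  withr::with_seed(8, {
    cfg <- measure_config("cos", 1)
    for (i in 1:25) {
      m <- random_matrix()
      dax <- random_arrangement(); day <- random_arrangement()
      base <- da_similarity(dax, day, m, cfg)
      expect_equal(da_similarity(sample(dax), sample(day), m, cfg), base)
      rep_x <- rep(dax, each = 3)   # tandem repetition leaves the set alone
      expect_equal(da_similarity(rep_x, day, m, cfg), base)
    }
  })
})

test_that("mwm_score equals exhaustive enumeration on random instances", {
  withr::with_seed(9, {
    for (i in 1:100) {
      m <- random_matrix()
      items_x <- unique(random_arrangement())
      items_y <- unique(random_arrangement())
      w <- outer(items_x, items_y, function(a, b) similarity(m, a, b))
      expected <- brute_mwm(matrix(w, nrow = length(items_x))) /
        max(length(items_x), length(items_y))
      expect_equal(as.numeric(mwm_score(items_x, items_y, m)), expected,
                   tolerance = 1e-9)
    }
  })
})

test_that("weighting squares sub-unit components and never raises a score", {
  expect_equal(apply_weighting(c(0, 0.5, 1)), c(0, 0.25, 1))
  expect_equal(apply_weighting(0.5, exponent = 3), 0.125)
  s <- seq(0, 1, by = 0.05)
  expect_true(all(diff(apply_weighting(s)) >= 0))   # monotone
  withr::with_seed(10, {
    for (cfgmeasure in c("cos", "mwm")) for (ord in 1:2) {
      for (i in 1:15) {
        m <- random_matrix()
        dax <- random_arrangement(); day <- random_arrangement()
        u <- da_similarity(dax, day, m, measure_config(cfgmeasure, ord))
        w <- da_similarity(dax, day, m,
                           measure_config(cfgmeasure, ord, weighted = TRUE))
        expect_lte(w, u + 1e-12)
      }
    }
  })
})

test_that("every configuration is symmetric with self-similarity 1", {
  withr::with_seed(11, {
    configs <- all_measure_configs()
    for (i in 1:10) {
      m <- random_matrix()
      dax <- random_arrangement(); day <- random_arrangement()
      for (config in configs) {
        expect_equal(da_similarity(dax, day, m, config),
                     da_similarity(day, dax, m, config))
        expect_equal(da_similarity(dax, dax, m, config), 1)
        val <- da_similarity(dax, day, m, config)
        expect_true(val >= 0 && val <= 1)
      }
    }
  })
})

test_that("order-2 comparisons fall back to order 1 for single-domain DAs", {
  m <- worked_example_matrix()
  cfg2 <- measure_config("cos", 2)
  cfg1 <- measure_config("cos", 1)
  expect_equal(da_similarity("A", c("D", "B"), m, cfg2),
               da_similarity("A", c("D", "B"), m, cfg1))
  expect_equal(da_similarity("A", "D", m, measure_config("mwm", 2)),
               0.8)
  expect_error(domain_universe(c("A", "B"), c("A>B")), "mix")
})

test_that("repeat collapsing changes O2 items but not O1 sets", {
  m <- worked_example_matrix()
  da_rep <- c("A", "B", "B", "C")
  da_flat <- c("A", "B", "C")
  cfg <- measure_config("cos", 2, collapse_repeats = TRUE)
  expect_equal(da_similarity(da_rep, da_flat, m, cfg), 1)
  cfg_raw <- measure_config("cos", 2)
  expect_lt(da_similarity(da_rep, da_flat, m, cfg_raw), 1)
})
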
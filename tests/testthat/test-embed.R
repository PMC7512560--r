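test_that("embedding produces the N - m + 1 overlapping templates", {
  t1 <- embed_templates(c(1, 2, 3, 4), m = 2)
  expect_equal(nrow(t1), 3)
  expect_equal(t1[1, ], c(1, 2))
  expect_equal(t1[2, ], c(2, 3))
  expect_equal(t1[3, ], c(3, 4))

  x <- rnorm(10)
  t2 <- embed_templates(x, m = 1)
  expect_equal(nrow(t2), 10)
  expect_equal(as.vector(t2), x)

  t3 <- embed_templates(rep(5, 5), m = 3)
  expect_equal(nrow(t3), 3)
  expect_true(all(t3 == 5))

  # consecutive templates overlap in m - 1 samples
  t4 <- embed_templates(seq_len(20), m = 4)
  expect_equal(t4[2, 1:3], t4[1, 2:4])
})

test_that("embedding errors name N and m for too-short signals", {
  expect_error(embed_templates(c(1, 2), m = 2), "N = 2.*m = 2")
  expect_error(embed_templates(c(1, NA, 3), m = 1), "non-finite")
})

test_that("chebyshev distance matches hand values and grows with window length", {
  expect_equal(chebyshev_distance(c(0, 0), c(1, 3)), 3)
  expect_equal(chebyshev_distance(c(1.5, -2), c(1.5, -2)), 0)
  expect_error(chebyshev_distance(1:2, 1:3), "length mismatch")

  set.seed(11)
  for (i in 1:200) {
    m <- sample(1:6, 1)
    a <- rnorm(m + 1)
    b <- rnorm(m + 1)
    expect_gte(chebyshev_distance(a, b), chebyshev_distance(a[1:m], b[1:m]))
    expect_equal(chebyshev_distance(a, b), chebyshev_distance(b, a))
  }
})

test_that("range distance matches hand values and is undefined on identical templates", {
  expect_equal(range_distance(c(0, 0), c(1, 3)), 0.5)
  expect_equal(range_distance(c(0, 0), c(2, 2)), 0)
  expect_true(is.na(range_distance(c(1, 2), c(1, 2))))
  expect_error(range_distance(1:2, 1:3), "length mismatch")

  # m = 2 closed form (A - B)/(A + B) on the two absolute differences
  set.seed(12)
  for (i in 1:100) {
    a <- rnorm(2); b <- rnorm(2)
    d <- abs(a - b)
    expect_equal(range_distance(a, b), (max(d) - min(d)) / (max(d) + min(d)))
  }
})

test_that("range distance is bounded, symmetric, offset- and scale-invariant, and monotone in m", {
  set.seed(13)
  # bounded in [0, 1] over >= 1e5 random template pairs (vectorised check)
  tm <- matrix(rnorm(350 * 3), ncol = 3)
  D <- rangeen:::pairwise_distance_matrix(tm, "range")
  off <- D[upper.tri(D)]
  expect_gt(length(off), 6e4) # 61075 ordered pairs each way -> >1.2e5 pairs
  expect_true(all(is.na(off) | (off >= 0 & off <= 1)))

  for (i in 1:300) {
    m <- sample(2:6, 1)
    a <- rnorm(m + 1); b <- rnorm(m + 1)
    c0 <- rnorm(1); lam <- rnorm(1)
    if (lam == 0) lam <- 1
    d_m <- range_distance(a[1:m], b[1:m])
    d_m1 <- range_distance(a, b)
    expect_identical(range_distance(a, b), range_distance(b, a))
    # offset invariance is exact in real arithmetic; floating-point rounding
    # of (a + c) - (b + c) perturbs it at the last bit
    d_off <- range_distance(a + c0, b + c0)
    if (!is.na(d_m1)) expect_equal(d_off, d_m1, tolerance = 1e-12)
    expect_equal(range_distance(lam * a, lam * b), d_m1, tolerance = 1e-14)
    # dimension monotonicity (max non-decreasing, min non-increasing in m)
    if (!is.na(d_m) && !is.na(d_m1)) expect_gte(d_m1, d_m)
  }
})

test_that("match counting honours mode, undefined pairs, and r-monotonicity", {
  # constant signal: all chebyshev distances zero
  tm <- embed_templates(rep(2, 9), m = 3)
  cc <- match_counts(tm, r = 0, distance = "chebyshev", mode = "include_self")
  expect_equal(as.integer(cc), rep(7L, 7))

  # duplicate-free set under range distance, r >= 1: every count is N - m
  set.seed(14)
  x <- rnorm(30)
  tr <- embed_templates(x, m = 2)
  rc <- match_counts(tr, r = 1, distance = "range", mode = "exclude_self")
  expect_equal(as.integer(rc), rep(length(x) - 2L, nrow(tr)))
  # include_self gives the same result: the self-pair is undefined, not a match
  rc2 <- match_counts(tr, r = 1, distance = "range", mode = "include_self")
  expect_equal(as.integer(rc2), as.integer(rc))

  # duplicate non-self templates are tallied as excluded pairs
  td <- embed_templates(c(1, 2, 3, 1, 2, 3), m = 3)
  rd <- match_counts(td, r = 1, distance = "range", mode = "include_self")
  expect_gt(attr(rd, "n_excluded_pairs"), 0)

  # toy set vs exhaustive enumeration with the scalar oracle distance
  tt <- embed_templates(c(0.3, -1.2, 0.8, 0.1, -0.5, 1.4), m = 3)
  for (r in c(0.1, 0.4, 0.8)) {
    got <- match_counts(tt, r = r, distance = "range", mode = "exclude_self")
    want <- vapply(seq_len(nrow(tt)), function(i) {
      sum(vapply(seq_len(nrow(tt)), function(j) {
        if (j == i) return(FALSE)
        d <- oracle_range(tt[i, ], tt[j, ])
        !is.na(d) && d <= r
      }, TRUE))
    }, 0L)
    expect_equal(as.integer(got), want)
  }

  # counts are non-decreasing step functions of r
  counts_by_r <- sapply(seq(0, 1.2, 0.05), function(r) {
    as.integer(match_counts(tr, r = r, distance = "range", mode = "exclude_self"))
  })
  expect_true(all(apply(counts_by_r, 1, function(v) all(diff(v) >= 0))))
})
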
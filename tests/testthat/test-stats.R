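test_that("binomial_tail matches enumeration and handles edge cases", {
  expect_equal(binomial_tail(1, 3, 0.01), 1 - 0.99^3)
  expect_equal(binomial_tail(5, 5, 1.0), 1.0)
  expect_equal(binomial_tail(1, 1, 0.5), 0.5)

  withr::with_seed(42, {
    for (i in 1:50) {
      m <- sample(1:12, 1)
      k <- sample(1:m, 1)
      p <- runif(1)
      expect_equal(binomial_tail(k, m, p), naive_binomial_tail(k, m, p),
                   tolerance = 1e-12)
    }
  })

  expect_error(binomial_tail(0, 3, 0.5), "1 <= k <= m")
  expect_error(binomial_tail(4, 3, 0.5), "1 <= k <= m")
  expect_error(binomial_tail(1, 3, 1.5), "0, 1")
})

test_that("enrichment_score minimizes the binomial tail over prefixes", {
  es <- enrichment_score(c(0.01, 0.2, 0.9))
  oracle <- naive_enrichment(c(0.01, 0.2, 0.9))
  expect_equal(es$k_star, 1)
  expect_equal(es$p_tilde_min, 0.029701)
  expect_equal(es$es, oracle$es, tolerance = 1e-12)
  expect_equal(naive_binomial_tail(2, 3, 0.2), 0.104) # interior prefix

  flat <- enrichment_score(c(1, 1, 1))
  expect_equal(flat$es, 0)
  expect_equal(flat$k_star, 1)

  single <- enrichment_score(0.5)
  expect_equal(single$es, -log10(0.5))
  expect_equal(single$k_star, 1)
  expect_equal(single$m, 1)

  expect_error(enrichment_score(numeric(0)), "empty")
  expect_error(enrichment_score(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(enrichment_score(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("enrichment_score is order-invariant and tie-breaks to smallest k", {
  withr::with_seed(7, {
    for (i in 1:25) {
      p <- 1 - runif(sample(1:10, 1))
      a <- enrichment_score(p)
      b <- enrichment_score(rev(sort(p)))
      expect_equal(a$es, b$es)
      expect_equal(a$k_star, b$k_star)
      o <- naive_enrichment(p)
      expect_equal(a$es, o$es, tolerance = 1e-12)
      expect_equal(a$k_star, o$k_star)
      expect_equal(a$p_k_star, o$p_k_star)
    }
  })
  # duplicated values give tied tails; the smallest qualifying k wins
  tied <- enrichment_score(c(0.2, 0.2))
  expect_equal(tied$k_star, which.min(c(naive_binomial_tail(1, 2, 0.2),
                                        naive_binomial_tail(2, 2, 0.2))))
})

test_that("lowering any subnetwork P-value never decreases the score", {
  withr::with_seed(21, {
    for (i in 1:30) {
      p <- 1 - runif(sample(2:12, 1))
      j <- sample(seq_along(p), 1)
      q <- p
      q[j] <- p[j] * runif(1)
      expect_gte(enrichment_score(q)$es, enrichment_score(p)$es - 1e-12)
    }
  })
})

test_that("sample_background honors count, sign, determinism, degeneracy", {
  pool <- 1 - stats::runif(100)
  withr::with_seed(1, bg <- sample_background(pool, 5, n_samples = 500))
  expect_length(bg$samples, 500)
  expect_true(all(bg$samples >= 0))
  expect_equal(bg$size, 5)

  withr::with_seed(1, bg2 <- sample_background(pool, 5, n_samples = 500))
  expect_identical(bg$samples, bg2$samples)

  flat <- sample_background(rep(1, 50), 4, n_samples = 100)
  expect_true(all(flat$samples == 0))

  expect_error(sample_background(pool, 101, n_samples = 10), "exceeds")
  withr::with_seed(2, {
    wr <- sample_background(pool[1:5], 5, n_samples = 50, replace = TRUE)
    expect_length(wr$samples, 50)
  })
})

test_that("vectorized background scoring equals per-sample enrichment_score", {
  pool <- 1 - stats::runif(60)
  for (m in c(1, 2, 7, 25)) {
    withr::with_seed(100 + m, bg <- sample_background(pool, m, n_samples = 40))
    withr::with_seed(100 + m, {
      idx <- vapply(1:40, function(i) sample.int(60, m), integer(m))
      manual <- apply(matrix(pool[idx], nrow = 40, byrow = TRUE), 1,
                      function(row) enrichment_score(row)$es)
    })
    expect_equal(bg$samples, manual, tolerance = 1e-12)
  }
})

test_that("empirical_pvalue uses the add-one convention with inclusive ties", {
  expect_equal(empirical_pvalue(5, rep(0, 9999)), 1e-4)
  expect_equal(empirical_pvalue(0, c(0.5, 1, 2)), 1.0)
  expect_equal(empirical_pvalue(2.0, c(1.0, 1.5, 2.5, 3.0)), 0.6)
  expect_equal(empirical_pvalue(2.0, c(2.0, 1.5, 2.5, 3.0)), 0.8) # tie counts
  expect_error(empirical_pvalue(1, numeric(0)), "empty")
})

test_that("bh_adjust matches the textbook step-up recursion", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.002)),
               c(0.02, 0.04, 0.04, 0.008))
  expect_equal(bh_adjust(1.0), 1.0)
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))

  withr::with_seed(13, {
    for (i in 1:1000) {
      p <- 1 - runif(sample(1:20, 1))
      expect_equal(bh_adjust(p), bh_recursion(p), tolerance = 1e-12)
    }
  })

  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(numeric(0)), "empty")
})
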
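test_that("the additive model matches closed-form regression", {
  d <- data.frame(g = rep(0:2, each = 10))
  d$y <- 3 * d$g
  fit <- suppressWarnings(additive_linear_assoc(d, "y", "g"))  # perfect fit
  expect_equal(fit$beta, 3)
  expect_lt(fit$p_value, 1e-12)

  # oracle equivalence with the simple-regression slope on small cases
  withr::with_seed(1, {
    for (i in 1:10) {
      n <- sample(8:20, 1)
      g <- rbinom(n, 2, 0.4)
      if (var(g) == 0) next
      y <- rnorm(n)
      slope <- sum((g - mean(g)) * (y - mean(y))) / sum((g - mean(g))^2)
      got <- additive_linear_assoc(data.frame(g = g, y = y), "y", "g")
      expect_equal(got$beta, slope)
    }
  })

  # monomorphic dosage: NA result with warning, not an error
  dm <- data.frame(y = rnorm(30), g = rep(1, 30))
  expect_warning(res <- additive_linear_assoc(dm, "y", "g"), "Monomorphic")
  expect_true(is.na(res$beta))

  # permuting the outcome destroys a strong simulated association
  withr::with_seed(2, {
    g <- rbinom(300, 2, 0.3)
    y <- 5 * g + rnorm(300)
    expect_lt(additive_linear_assoc(data.frame(g, y), "y", "g")$p_value,
              1e-10)
    perm_p <- replicate(100, {
      additive_linear_assoc(data.frame(g = g, y = sample(y)), "y", "g")$p_value
    })
    # permutation p-values behave uniformly
    expect_gt(min(perm_p), 0)
    expect_gt(mean(perm_p > 0.05), 0.8)
    expect_gt(stats::ks.test(perm_p, "punif")$p.value, 0.01)
  })
})

test_that("the residualised scan equals per-variant full fits", {
  withr::with_seed(3, {
    n <- 300
    dat <- data.frame(y = rnorm(n), age = rnorm(n, 57, 8),
                      sex = rbinom(n, 1, 0.5),
                      machine_id = sample(c("A", "B"), n, TRUE))
    G <- cbind(v1 = rbinom(n, 2, 0.3), v2 = rbinom(n, 2, 0.1),
               v3 = rbinom(n, 2, 0.5))
    scan <- assoc_scan(dat, "y", G, c("age", "sex", "machine_id"))
    for (j in 1:3) {
      d2 <- cbind(dat, g = G[, j])
      ref <- additive_linear_assoc(d2, "y", "g", c("age", "sex", "machine_id"))
      expect_equal(scan$beta[j], ref$beta)
      expect_equal(scan$se[j], ref$se)
      expect_equal(scan$p_value[j], ref$p_value)
    }
  })
})

test_that("sex-interaction models recover differential effects", {
  withr::with_seed(4, {
    n <- 2000
    g <- rbinom(n, 2, 0.3)
    sex <- rbinom(n, 1, 0.5)
    # identical effect in both sexes: interaction t statistic small
    y_eq <- 5 * g + 2 * sex + rnorm(n)
    eq <- sex_interaction_assoc(data.frame(y = y_eq, g = g, sex = sex),
                                "y", "g")
    expect_lt(abs(eq$statistic), 3)
    # male-only 10 um effect: interaction recovers +-10
    y_m <- 10 * g * sex + rnorm(n)
    mo <- sex_interaction_assoc(data.frame(y = y_m, g = g, sex = sex),
                                "y", "g")
    expect_lt(abs(abs(mo$beta) - 10), 3 * mo$se)
  })
  expect_error(sex_interaction_assoc(
    data.frame(y = rnorm(10), g = rbinom(10, 2, 0.5), sex = rep(1, 10)),
    "y", "g"), "constant")
})

test_that("min-p meta, loci, and threshold utilities are exact", {
  expect_equal(min_p_meta(0.01, 0.5), 0.01)
  expect_equal(min_p_meta(0.3, 0.3), 0.3)
  withr::with_seed(5, {
    pa <- runif(200); pb <- runif(200)
    m <- min_p_meta(pa, pb)
    expect_true(all(m <= pa & m <= pb))
    # monotone: improving one input never worsens the meta p
    expect_true(all(min_p_meta(pa / 2, pb) <= m))
  })

  v <- tibble::tibble(id = c("a", "b", "c"), chrom = "1",
                      bp = c(1.0e6, 2.4e6, 5.0e6))
  cl <- cluster_loci(v)
  expect_equal(cl$locus[cl$id %in% c("a", "b")][1],
               cl$locus[cl$id %in% c("a", "b")][2])
  expect_false(cl$locus[cl$id == "c"] %in% cl$locus[cl$id != "c"])
  # single variant, and cross-chromosome separation
  expect_equal(nrow(attr(cluster_loci(v[1, ]), "loci")), 1)
  v2 <- tibble::tibble(id = c("a", "b"), chrom = c("1", "2"), bp = c(1e6, 1e6))
  expect_equal(nrow(attr(cluster_loci(v2), "loci")), 2)
  # order invariance
  cl_shuf <- cluster_loci(v[c(3, 1, 2), ])
  expect_identical(cl_shuf, cl)

  expect_identical(bonferroni_mask(c(0.04, 0.06), m = 1), c(TRUE, FALSE))
  expect_true(bonferroni_mask(0.001, m = 46))
  expect_false(bonferroni_mask(0.0011, m = 46))
  expect_true(all(!bonferroni_mask(rep(1, 10))))
  expect_identical(genomewide_significant(c(4e-8, 6e-8)), c(TRUE, FALSE))
})

test_that("ordinal trait association recovers the pigment effect sign", {
  withr::with_seed(6, {
    signs <- replicate(200, {
      n <- 400
      g <- rbinom(n, 2, 0.3)
      latent <- 0.5 * g + rnorm(n)
      hair <- as.integer(cut(latent, quantile(latent, c(0, .25, .5, .75, 1)),
                             include.lowest = TRUE, labels = FALSE))
      red <- runif(n) < 0.04
      fit <- ordinal_trait_assoc(data.frame(hair = hair, g = g, red = red),
                                 "hair", "g", exclude = "red")
      sign(fit$beta)
    })
    expect_gte(mean(signs == 1), 0.95)
  })
  # empty exclusion filter leaves the fit unchanged
  d <- data.frame(hair = rep(1:4, 10), g = rbinom(40, 2, 0.5),
                  red = rep(FALSE, 40))
  expect_equal(ordinal_trait_assoc(d, "hair", "g", exclude = "red"),
               ordinal_trait_assoc(d, "hair", "g"))
  # all one colour: zero-variance outcome
  d$hair <- 2
  expect_error(ordinal_trait_assoc(d, "hair", "g"), "Zero-variance")
})

test_that("acuity association uses the better-seeing eye", {
  expect_equal(better_eye_logmar(0.2, 0.0), 0.0)
  expect_equal(better_eye_logmar(c(0.2, NA, NA), c(0.3, 0.1, NA)),
               c(0.2, 0.1, NA))
  withr::with_seed(7, {
    n <- 2000
    g <- rbinom(n, 2, 0.3)
    d <- data.frame(
      g = g, age = rnorm(n, 57, 8), sex = rbinom(n, 1, 0.5),
      logmar_left = 0.02 * g + rnorm(n, 0, 0.1),
      logmar_right = 0.02 * g + rnorm(n, 0, 0.1))
    fit <- acuity_assoc(d, "g")
    expect_lt(abs(fit$beta - 0.02), 3 * fit$se)
    # null dosage: p-values uniform across replicates
    pnull <- replicate(100, {
      d$g2 <- rbinom(n, 2, 0.3)
      acuity_assoc(d[sample(n, 300), ], "g2")$p_value
    })
    expect_gt(stats::ks.test(pnull, "punif")$p.value, 0.01)
  })
})

test_that("the GCC group contrast is a calibrated rank-sum test", {
  # disjoint supports: statistic equals the extreme rank sum (brute force)
  d <- data.frame(gcc = c(1:5, 101:108),
                  glaucoma = c(rep(TRUE, 5), rep(FALSE, 8)))
  res <- gcc_group_contrast(d, "gcc", "glaucoma")
  ranks <- rank(d$gcc)
  w_brute <- sum(ranks[d$glaucoma]) - 5 * 6 / 2  # Mann-Whitney U of cases
  expect_equal(res$statistic, w_brute)
  expect_equal(res$statistic, 0)  # cases all below controls
  expect_equal(res$n_case, 5)
  expect_lt(res$p_value, 0.01)

  # null calibration: ~5% rejections under identical distributions
  withr::with_seed(8, {
    rej <- replicate(500, {
      gcc_group_contrast(
        data.frame(gcc = rnorm(100), glaucoma = rep(c(TRUE, FALSE), 50)),
        "gcc", "glaucoma")$p_value < 0.05
    })
    expect_lt(abs(mean(rej) - 0.05),
              2.58 * sqrt(0.05 * 0.95 / 500) + 0.01)
  })
  expect_error(gcc_group_contrast(
    data.frame(gcc = 1:5, glaucoma = rep(FALSE, 5)), "gcc", "glaucoma"),
    "non-empty")
})
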
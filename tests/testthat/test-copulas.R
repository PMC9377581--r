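# fixed moderate-dependence parameters used throughout
.test_specs <- function() list(
  copula_spec("normal", 0.6), copula_spec("gumbel", 1.7),
  copula_spec("frank", 4), copula_spec("frank", -3),
  copula_spec("clayton", 2), copula_spec("clayton", -0.3))

test_that("copula distribution functions satisfy their identities", {
  # closed-form spot value: clayton theta = 2 at (0.5, 0.5) is 7^(-1/2)
  expect_equal(copula_cdf(copula_spec("clayton", 2), 0.5, 0.5),
               7^(-0.5), tolerance = 1e-12)
  # gumbel theta = 1 is the independence copula
  g1 <- copula_spec("gumbel", 1)
  u <- seq(0.1, 0.9, by = 0.2); v <- rev(u)
  expect_equal(copula_cdf(g1, u, v), u * v, tolerance = 1e-12)

  for (s in .test_specs()) {
    # uniform margins and groundedness
    expect_equal(copula_cdf(s, 0.7, 1), 0.7, tolerance = 1e-9)
    expect_equal(copula_cdf(s, 1, 0.37), 0.37, tolerance = 1e-9)
    expect_equal(copula_cdf(s, 0.7, 0), 0)
    expect_equal(copula_cdf(s, 0, 0.7), 0)
    # 2-increasing on random rectangles
    set.seed(31)
    u1 <- runif(40); u2 <- u1 + runif(40) * (1 - u1)
    v1 <- runif(40); v2 <- v1 + runif(40) * (1 - v1)
    vol <- copula_cdf(s, u2, v2) - copula_cdf(s, u2, v1) -
           copula_cdf(s, u1, v2) + copula_cdf(s, u1, v1)
    expect_true(all(vol >= -1e-12))
  }
  expect_error(copula_spec("gumbel", 0.8), "domain")
  expect_error(copula_spec("normal", 1.2), "domain")
  expect_error(copula_cdf(copula_spec("frank", 2), 1.4, 0.5), "\\[0, 1\\]")
})

test_that("copula densities are the mixed partials of the CDF", {
  set.seed(32)
  for (s in .test_specs()) {
    u <- runif(50, 0.08, 0.92); v <- runif(50, 0.08, 0.92)
    expect_equal(copula_pdf(s, u, v), copula_pdf_fd_oracle(s, u, v),
                 tolerance = 1e-4)
    expect_true(all(copula_pdf(s, u, v) >= 0))
  }
  # independence limits give unit density
  expect_equal(copula_pdf(copula_spec("gumbel", 1), 0.3, 0.8), 1)
  expect_equal(copula_pdf(copula_spec("frank", 1e-8), 0.3, 0.8), 1)
  expect_equal(copula_pdf(copula_spec("clayton", 1e-8), 0.3, 0.8), 1)
  expect_error(copula_pdf(copula_spec("frank", 2), 0, 0.5), "open unit")

  # normalization at moderate dependence: double quadrature of the density
  # over an inner square, plus the exact boundary mass from the separately
  # verified CDF (the archimedean densities are integrable but unbounded
  # at the corners, so the corner strips are handled through the CDF)
  d <- 0.01
  for (fam in copula_families) {
    s <- copula_spec(fam, theta_moderate(fam))
    inner <- integrate(function(vv) {
      vapply(vv, function(v1) {
        integrate(function(uu) copula_pdf(s, uu, v1), d, 1 - d,
                  rel.tol = 1e-8, subdivisions = 400L)$value
      }, numeric(1))
    }, d, 1 - d, rel.tol = 1e-7, subdivisions = 400L)$value
    rect <- copula_cdf(s, 1 - d, 1 - d) - copula_cdf(s, 1 - d, d) -
            copula_cdf(s, d, 1 - d) + copula_cdf(s, d, d)
    boundary <- 1 - rect
    expect_equal(inner + boundary, 1, tolerance = 1e-4)
  }
})

test_that("Kendall tau maps reproduce the published parameter pairs", {
  # every published (family, theta, tau) pair consistent with the analytic
  # maps, checked to the printed 3 decimal places
  pairs <- list(
    list("clayton", 0.453, 0.185), list("clayton", 0.185, 0.085),
    list("clayton", 0.222, 0.100), list("clayton", 0.456, 0.186),
    list("frank", -2.512, -0.263), list("frank", 1.305, 0.143),
    list("clayton", 0.099, 0.047), list("frank", 0.201, 0.022),
    list("frank", 0.892, 0.098), list("normal", 0.130, 0.083),
    list("normal", 0.263, 0.169), list("frank", 0.034, 0.004),
    list("clayton", 0.795, 0.284), list("gumbel", 1.181, 0.153),
    list("clayton", 0.210, 0.095), list("clayton", 0.628, 0.239),
    list("frank", 0.809, 0.089), list("normal", -0.034, -0.022),
    list("clayton", 0.437, 0.179), list("clayton", 0.295, 0.129),
    list("normal", 0.155, 0.099), list("clayton", 0.823, 0.292),
    list("frank", -1.016, -0.112), list("frank", 0.638, 0.071),
    list("gumbel", 1.075, 0.070), list("frank", -0.221, -0.025),
    list("frank", -0.822, -0.091), list("clayton", 0.112, 0.053),
    list("frank", -1.973, -0.211), list("clayton", 0.468, 0.190),
    list("normal", -0.179, -0.115), list("frank", -0.890, -0.098),
    list("frank", 0.368, 0.041), list("frank", 0.450, 0.050),
    list("clayton", 0.098, 0.047), list("clayton", 0.194, 0.088),
    list("normal", 0.012, 0.008), list("normal", -0.235, -0.151),
    list("clayton", 0.047, 0.023), list("gumbel", 1.000, 0.000))
  for (p in pairs)
    expect_equal(round(kendall_tau_of(copula_spec(p[[1]], p[[2]])), 3),
                 p[[3]], tolerance = 1e-9,
                 label = sprintf("%s theta=%g", p[[1]], p[[2]]))

  # oddness of the frank map and exact gumbel independence
  expect_equal(kendall_tau_of(copula_spec("frank", -4)),
               -kendall_tau_of(copula_spec("frank", 4)))
  expect_identical(kendall_tau_of(copula_spec("gumbel", 1)), 0)

  # theta_from_tau inverts the maps
  for (fam in copula_families) {
    th <- theta_moderate(fam)
    expect_equal(kendall_tau_of(copula_spec(fam, th)), 1 / 3,
                 tolerance = 1e-8)
  }
})

test_that("empirical copula counts pairs below the corner", {
  p <- pseudo_obs(c(0.2, 0.5, 0.8), c(0.3, 0.9, 0.1))
  expect_equal(empirical_copula(p, 0.6, 0.95), 2 / 3)
  expect_equal(empirical_copula(p, 1, 1), 1)
  expect_equal(empirical_copula(p, 0, 0), 0)
  expect_error(pseudo_obs(c(0, 0.5), c(0.5, 0.5)), "strictly inside")
})

test_that("squared distance from the empirical copula behaves", {
  # near-perfect match construction at a single upper-corner point
  p1 <- pseudo_obs(0.999, 0.999)
  d <- sq_euclid_distance(copula_spec("gumbel", 1), p1)
  expect_lt(d, 1e-5)

  # order invariance of the sum
  set.seed(33)
  u <- runif(30, 0.05, 0.95); v <- runif(30, 0.05, 0.95)
  s <- copula_spec("clayton", 1)
  perm <- sample(30)
  expect_equal(sq_euclid_distance(s, pseudo_obs(u, v)),
               sq_euclid_distance(s, pseudo_obs(u[perm], v[perm])),
               tolerance = 1e-12)

  # five-point toy set against a term-by-term hand sum
  u5 <- c(0.1, 0.3, 0.5, 0.7, 0.9); v5 <- c(0.2, 0.6, 0.4, 0.8, 0.5)
  p5 <- pseudo_obs(u5, v5)
  hand <- sum(vapply(1:5, function(i) {
    cth <- (u5[i]^(-1) + v5[i]^(-1) - 1)^(-1)
    cem <- mean(u5 <= u5[i] & v5 <= v5[i])
    (cth - cem)^2
  }, numeric(1)))
  expect_equal(sq_euclid_distance(s, p5), hand, tolerance = 1e-12)
})

test_that("selection picks the minimal distance with the fixed tie order", {
  set.seed(34)
  p <- copula_sample(copula_spec("clayton", 1.5), 200, seed = 44)
  fits <- lapply(copula_families, fit_copula_mle, pobs = p)
  best <- select_best(fits)
  d <- vapply(fits, function(f) f$sq_euclid_dist, numeric(1))
  expect_equal(best$sq_euclid_dist, min(d))
  expect_identical(select_best(fits[2])$spec$family, "gumbel")

  # exact tie: normal preferred over clayton by the fixed order
  f_norm <- fits[[1]]; f_clay <- fits[[4]]
  f_norm$sq_euclid_dist <- 0.01; f_clay$sq_euclid_dist <- 0.01
  expect_identical(select_best(list(f_clay, f_norm))$spec$family, "normal")
  expect_error(select_best(list()), "no fitted")
})

test_that("maximum likelihood recovers generating parameters", {
  # parameter recovery within 3 likelihood-theory standard errors
  for (fam in copula_families) {
    th0 <- theta_moderate(fam)
    p <- copula_sample(copula_spec(fam, th0), 2000, seed = 55)
    f <- fit_copula_mle(fam, p)
    expect_false(is.na(f$se))
    expect_lt(abs(f$spec$theta - th0), 3 * f$se)
  }
  # independence inputs: implied |tau| <= 0.05 for every family
  set.seed(56)
  pu <- pseudo_obs(runif(2000), runif(2000))
  for (fam in copula_families) {
    f <- fit_copula_mle(fam, pu)
    expect_lte(abs(f$kendall_tau), 0.05)
  }
  # gumbel cannot express negative dependence: boundary solution
  pneg <- copula_sample(copula_spec("frank", -5), 500, seed = 57)
  expect_identical(fit_copula_mle("gumbel", pneg)$spec$theta, 1)
})

test_that("sampling reproduces the family's dependence and margins", {
  # clayton theta = 2: population tau is 0.5
  p <- copula_sample(copula_spec("clayton", 2), 20000, seed = 61)
  expect_equal(cor(p$u, p$v, method = "kendall"), 0.5, tolerance = 0.02)

  # uniform margins via Kolmogorov-Smirnov at alpha = 0.01
  for (s in list(copula_spec("gumbel", 1.7), copula_spec("frank", -3))) {
    ps <- copula_sample(s, 20000, seed = 62)
    expect_gt(suppressWarnings(ks.test(ps$u, "punif"))$p.value, 0.01)
    expect_gt(suppressWarnings(ks.test(ps$v, "punif"))$p.value, 0.01)
  }

  # independence at the gumbel boundary
  pi0 <- copula_sample(copula_spec("gumbel", 1), 20000, seed = 63)
  expect_lte(abs(cor(pi0$u, pi0$v)), 0.02)

  # determinism given seed
  a <- copula_sample(copula_spec("frank", 4), 100, seed = 64)
  b <- copula_sample(copula_spec("frank", 4), 100, seed = 64)
  expect_identical(a, b)
})

test_that("fit-sample-fit closure recovers theta for every family", {
  for (fam in copula_families) {
    th0 <- theta_moderate(fam)
    p0 <- copula_sample(copula_spec(fam, th0), 800, seed = 71)
    f1 <- fit_copula_mle(fam, p0)
    p1 <- copula_sample(f1$spec, 5000, seed = 72)
    f2 <- fit_copula_mle(fam, p1)
    expect_lt(abs(f2$spec$theta - f1$spec$theta), 3 * f2$se)
  }
})
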
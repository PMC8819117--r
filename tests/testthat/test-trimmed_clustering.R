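test_that("alpha = 0 reduces to the (regularized) Gaussian MLE", {
  withr::with_seed(10L, {
    X <- matrix(rnorm(40), ncol = 2)
  })
  fit <- trimmed_fit(X, alpha = 0, n_starts = 1L)
  expect_length(fit$trimmed, 0L)
  expect_equal(fit$mu, colMeans(X), ignore_attr = TRUE)
  n <- nrow(X)
  C <- crossprod(sweep(X, 2, colMeans(X))) / n
  expect_equal(fit$sigma, C, tolerance = 1e-5, ignore_attr = TRUE)
  expect_monotone_trace(fit)
})

test_that("a single planted outlier is the trimmed point", {
  withr::with_seed(11L, {
    X <- rbind(matrix(rnorm(22, sd = 0.5), ncol = 2),
               c(100, 100))
  })
  # oracle: best single-point removal by exhaustive enumeration
  oracle <- enum_trim_oracle(X, alpha = 1 / 12)
  expect_equal(oracle$retained, 1:11)
  fit <- trimmed_fit(X, alpha = 1 / 12, n_starts = 20L, seed = 1L)
  expect_equal(fit$trimmed, 12L)
  expect_equal(fit$objective, oracle$objective, tolerance = 1e-9)
  expect_monotone_trace(fit)
})

test_that("small instances match exhaustive subset enumeration", {
  for (s in 1:4) {
    withr::with_seed(100L + s, {
      n <- sample(8:10, 1L)
      X <- rbind(matrix(rnorm(2 * (n - 2), sd = 0.7), ncol = 2),
                 matrix(rnorm(4, mean = 6), ncol = 2))
    })
    alpha <- 0.2
    oracle <- enum_trim_oracle(X, alpha)
    fit <- trimmed_fit(X, alpha, n_starts = 50L, seed = s)
    expect_equal(sort(fit$retained), oracle$retained)
    expect_equal(fit$objective, oracle$objective, tolerance = 1e-9)
    expect_monotone_trace(fit)
  }
})

test_that("the trimmed set always has the lowest log-densities", {
  withr::with_seed(12L, {
    X <- matrix(rnorm(400), ncol = 10)
  })
  fit <- trimmed_fit(X, alpha = 0.15, n_starts = 5L, seed = 2L)
  expect_length(fit$trimmed, floor(40 * 0.15))
  ll <- covskew:::mvn_logdensity(X, fit$mu, fit$sigma)
  expect_lte(max(ll[fit$trimmed]), min(ll[fit$retained]))
  expect_gte(min(eigen(fit$sigma, symmetric = TRUE)$values), 1e-12)
})

test_that("row permutation permutes the partition identically", {
  withr::with_seed(13L, {
    X <- rbind(matrix(rnorm(180, sd = 0.4), ncol = 2),
               matrix(rnorm(20, mean = 5), ncol = 2))
    perm <- sample(nrow(X))
  })
  f1 <- trimmed_fit(X, 0.1, n_starts = 10L, seed = 3L)
  f2 <- trimmed_fit(X[perm, ], 0.1, n_starts = 10L, seed = 3L)
  expect_setequal(perm[f2$trimmed], f1$trimmed)
})

test_that("preconditions are enforced", {
  X <- matrix(rnorm(40), ncol = 10)
  expect_error(trimmed_fit(X, alpha = 0.8), "alpha")
  expect_error(trimmed_fit(X, alpha = 0.5), "retained size")
  expect_error(ctl_curve(X, alpha_grid = c(0.1, 0.2)), "at least 5")
  expect_error(ctl_curve(X, alpha_grid = seq(0.5, 0.1, -0.1)), "ascending")
})

test_that("the log-density agrees with a reference implementation", {
  skip_if_not_installed("mvtnorm")
  withr::with_seed(14L, {
    X <- matrix(rnorm(50), ncol = 5)
    A <- matrix(rnorm(25), 5)
    S <- crossprod(A) + diag(5)
    mu <- rnorm(5)
  })
  expect_equal(covskew:::mvn_logdensity(X, mu, S),
               mvtnorm::dmvnorm(X, mu, S, log = TRUE))
})

test_that("CTL curve is monotone and flags planted contamination at 0.2", {
  sim <- generate_profiles(n_cells = 150L, skew_fraction = 0.2, seed = 77L)
  X <- clustering_input(reduce_bins(sim$matrix))$X
  curve <- ctl_curve(X, seq(0.05, 0.45, by = 0.05), n_starts = 10L, seed = 4L)
  expect_monotone_curve(curve)
  for (f in curve$fits) expect_monotone_trace(f)
  gains <- diff(curve$mean_objectives)
  # the largest discrete gain ends at the grid point nearest 0.2
  expect_equal(curve$alphas[which.max(gains) + 1L], 0.2)
  sel <- select_alpha_auto(curve)
  expect_lte(abs(sel$selected_alpha - 0.2), 0.05 + 1e-9)
})

test_that("alpha selection handles flat and constructed-elbow curves", {
  flat <- structure(list(alphas = seq(0.05, 0.5, by = 0.05),
                         mean_objectives = rep(1, 10),
                         objectives = rep(10, 10),
                         n_trimmed = 1:10, fits = NULL,
                         selected_alpha = NA_real_,
                         selection_mode = NA_character_,
                         low_confidence = NA),
                    class = "ctl_curve")
  expect_equal(select_alpha_auto(flat)$selected_alpha, 0.05)
  expect_false(select_alpha_auto(flat)$low_confidence)

  # piecewise-linear elbow at index 4 (0-based) of 10
  elbow <- flat
  elbow$mean_objectives <- c(1, 1.2, 1.4, 1.6, 9, 9.001, 9.002, 9.003,
                             9.004, 9.005)
  sel <- select_alpha_auto(elbow)
  expect_equal(sel$selected_alpha, elbow$alphas[5L])
  expect_false(sel$low_confidence)

  # a curve that never flattens is low-confidence at the grid minimum
  steep <- flat
  steep$mean_objectives <- exp(seq(0, 9))
  sel2 <- select_alpha_auto(steep)
  expect_equal(sel2$selected_alpha, steep$alphas[1L])
  expect_true(sel2$low_confidence)
})

test_that("CTL curve export writes the four-column TSV", {
  sim <- generate_profiles(n_cells = 60L, skew_fraction = 0.1, seed = 5L)
  X <- clustering_input(reduce_bins(sim$matrix))$X
  curve <- ctl_curve(X, seq(0.05, 0.25, by = 0.05), n_starts = 5L, seed = 6L)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ctl.tsv")
  save_ctl_curve(curve, path)
  back <- data.table::fread(path)
  expect_equal(names(back), c("alpha", "objective", "mean_objective",
                              "n_trimmed"))
  expect_equal(back$alpha, curve$alphas)
  expect_equal(back$n_trimmed, curve$n_trimmed)
})
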
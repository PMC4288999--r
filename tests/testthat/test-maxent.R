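# Independent oracle: grid/derivative-free optimization of the same penalized
# objective, kept separate from the FISTA path under test.
oracle_1d <- function(X, presence, beta, lo = -10, hi = 10) {
  obj <- function(l) traitshift:::maxent_objective(l, X[presence, , drop = FALSE],
                                                  X, beta)
  grid <- seq(lo, hi, by = 1e-3)
  vals <- vapply(grid, obj, numeric(1))
  g0 <- grid[which.max(vals)]
  stats::optimize(obj, c(g0 - 2e-3, g0 + 2e-3), maximum = TRUE,
                  tol = 1e-10)$maximum
}

test_that("feature building standardizes on background and expands categories", {
  env <- small_env()
  fb <- build_features(env)
  # temp linear+quadratic plus soil codes 1 and 2
  expect_setequal(colnames(fb$X), c("temp:lin", "temp:quad", "soil:1", "soil:2"))
  expect_all_equal(colMeans(fb$X), 0, tol = 1e-12)
  expect_all_equal(apply(fb$X, 2, sd), 1, tol = 1e-12)
  # constant layer features are dropped with a warning
  env2 <- env_stack(list(temp = small_env()$layers$temp, flat = matrix(1, 4, 4)),
                    kind = c(temp = "continuous", flat = "continuous"))
  expect_warning(fb2 <- build_features(env2), "zero-variance")
  expect_false(any(grepl("flat", colnames(fb2$X))))
})

test_that("degenerate fits reduce to the uniform distribution", {
  env <- small_env()
  fb <- build_features(env)
  # huge penalty forces all weights to zero
  m <- maxent_fit(fb$X, presence = c(1, 5, 9), beta = 1e6)
  expect_all_equal(m$lambda, 0)
  p <- maxent_project(m, env, fb$constants, scale = "raw")
  expect_all_equal(p, 1 / 16, tol = 1e-12)
})

test_that("fitted weights match the brute-force oracle on a 1-D binary feature", {
  # presences only where the feature is 1
  set.seed(42)
  f <- rep(c(0, 1), each = 50)
  X <- matrix((f - mean(f)) / sd(f), ncol = 1, dimnames = list(NULL, "x"))
  presence <- sample(which(f == 1), 20)
  for (beta in c(0.1, 0.01)) {
    fit <- maxent_fit(X, presence, beta = beta, tol = 1e-9)
    expect_true(fit$converged)
    expect_equal(unname(fit$lambda), oracle_1d(X, presence, beta),
                 tolerance = 1e-4)
  }
})

test_that("fitted weights match coordinate-wise oracle refinement in 2-D", {
  # linear + quadratic features of one gradient; oracle = cyclic 1-D line
  # searches of the same objective from zero, far from the FISTA path
  set.seed(7)
  x <- seq(-2, 2, length.out = 120)
  X <- cbind(lin = x, quad = x^2)
  X <- sweep(sweep(X, 2, colMeans(X)), 2, apply(X, 2, sd), "/")
  presence <- sample(seq_along(x), 40, prob = exp(-(x - 0.5)^2 / 0.5))
  beta <- 0.05
  fit <- maxent_fit(X, presence, beta = beta, tol = 1e-10)
  obj <- function(l) traitshift:::maxent_objective(l, X[presence, , drop = FALSE], X, beta)
  l <- c(0, 0)
  for (sweep_i in 1:200) {
    for (j in 1:2) {
      l[j] <- stats::optimize(function(v) obj(replace(l, j, v)),
                              c(-20, 20), maximum = TRUE, tol = 1e-12)$maximum
    }
  }
  expect_equal(unname(fit$lambda), l, tolerance = 1e-3)
  expect_gte(obj(unname(fit$lambda)), obj(c(0, 0)))  # concavity sanity
})

test_that("raw projections normalize to 1 and logistic is a monotone map of raw", {
  env <- generate_landscape(10, 10, 2, 1, correlation_length = 3, seed = 11)
  fb <- build_features(env)
  set.seed(1)
  fit <- maxent_fit(fb$X, presence = sample(100, 15), beta = 0.1)
  raw <- maxent_project(fit, env, fb$constants, scale = "raw")
  expect_equal(sum(raw), 1, tolerance = 1e-9)
  logi <- maxent_project(fit, env, fb$constants, scale = "logistic")
  expect_true(all(logi > 0 & logi < 1))
  o <- order(raw)
  expect_true(all(diff(logi[o]) >= 0))
})

test_that("a scenario shifted toward the optimum raises mean suitability", {
  env <- generate_landscape(16, 16, 2, 0, correlation_length = 4, seed = 21)
  # species prefers temp one degree above today's mean
  sp <- structure(
    list(id = "s", optimum = c(temp = 1), breadth = c(temp = 0.8),
         cat_pref = list(), max_abundance = 5, pfg = "graminoid",
         wetland = "fen"),
    class = "species_truth"
  )
  occ <- sample_occurrences(list(sp), env, 256, detection = "proportional",
                            seed = 2)
  fb <- build_features(env)
  pres <- match((occ$col - 1L) * 16L + occ$row, fb$cells)
  fit <- maxent_fit(fb$X, pres, beta = 0.1)
  fut <- apply_scenario(env, c(temp = 0.75))
  cur_s <- maxent_project(fit, env, fb$constants, scale = "logistic")
  fut_s <- maxent_project(fit, fut, fb$constants, scale = "logistic")
  expect_gt(mean(fut_s), mean(cur_s))
})

test_that("fit_all_sdms fits per class, skips sparse classes, and is deterministic", {
  env <- generate_landscape(12, 12, 2, 1, correlation_length = 3, seed = 31)
  sp <- generate_species(env, 3, seed = 31)
  occ <- sample_occurrences(sp, env, 144, detection = "always", seed = 31)
  res <- fit_all_sdms(occ, env, apply_scenario(env, c(temp = 1)), beta = 0.1)
  expect_setequal(names(res), unique(occ$species_id))
  for (s in names(res)) {
    counts <- table(factor(occ$abundance_class[occ$species_id == s], 1:3))
    expect_identical(unname(res[[s]]$fitted), as.vector(counts >= 5))
    for (k in which(res[[s]]$fitted)) {
      expect_equal(sum(res[[s]]$current[[k]]), 1, tolerance = 1e-9)
      expect_false(is.null(res[[s]]$future[[k]]))
    }
    for (k in which(!res[[s]]$fitted)) expect_null(res[[s]]$models[[k]])
  }
  res2 <- fit_all_sdms(occ, env, apply_scenario(env, c(temp = 1)), beta = 0.1)
  expect_identical(res[seq_along(res)], res2[seq_along(res2)])
})

test_that("a 1-D Gaussian niche is recovered with a negative quadratic weight", {
  env <- generate_landscape(24, 24, 1, 0, correlation_length = 5, seed = 41)
  sp <- niche_species(opt = 0.4, breadth = 0.7, max_abundance = 8)
  occ <- sample_occurrences(list(sp), env, 576, detection = "proportional",
                            seed = 41)
  expect_gt(nrow(occ), 200)
  fb <- build_features(env)
  pres <- match((occ$col - 1L) * 24L + occ$row, fb$cells)
  fit <- maxent_fit(fb$X, pres, beta = 0.1)
  # response in raw units: eta = a*temp + b*temp^2 (up to standardization)
  b_std <- fit$lambda[["temp:quad"]] / fb$constants$scale[["temp:quad"]]
  a_std <- fit$lambda[["temp:lin"]] / fb$constants$scale[["temp:lin"]]
  expect_lt(b_std, 0)
  opt_hat <- -a_std / (2 * b_std)
  expect_lt(abs(opt_hat - 0.4), 0.5 * 0.7)
})
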
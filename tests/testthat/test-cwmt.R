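test_that("CWMT is the share-weighted trait mean with its closure properties", {
  sh <- const_shares(c(a = 0.25, b = 0.75))
  expect_all_equal(cwmt(sh, c(a = 10, b = 20)), 17.5)
  # all species sharing a trait value pin the CWMT to it
  sh3 <- const_shares(c(a = 0.2, b = 0.3, c = 0.5))
  expect_all_equal(cwmt(sh3, c(a = 7, b = 7, c = 7)), 7)
  # single-species pool returns its trait
  expect_all_equal(cwmt(const_shares(c(a = 1)), c(a = 3.2)), 3.2)
  expect_error(cwmt(sh, c(a = 1)), "no trait value.*b")
  # linearity in trait values and order invariance
  t1 <- c(a = 1, b = 5); t2 <- c(a = 2, b = -1)
  expect_all_equal(cwmt(sh, t1 + 2 * t2), cwmt(sh, t1) + 2 * cwmt(sh, t2))
  expect_all_equal(cwmt(rev(sh), t1), cwmt(sh, t1))
})

test_that("CWMT stays within pool trait extrema over random pools", {
  set.seed(31)
  for (i in 1:1000) {
    n <- sample(2:8, 1)
    raw <- matrix(runif(n), n, 1)
    shares <- lapply(seq_len(n), function(k) matrix(raw[k] / sum(raw), 1, 1))
    names(shares) <- paste0("s", seq_len(n))
    tv <- stats::setNames(rnorm(n, sd = 10), names(shares))
    v <- cwmt(shares, tv)[1, 1]
    expect_gte(v, min(tv) - 1e-12)
    expect_lte(v, max(tv) + 1e-12)
    tot <- Reduce(`+`, shares)[1, 1]
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("categorical profiles partition unity and handle unknown levels", {
  sh <- const_shares(c(a = 0.2, b = 0.3, c = 0.5))
  prof <- categorical_profile(sh, c(a = "tussock", b = "tussock",
                                    c = "rhizomatous"))
  expect_all_equal(prof$tussock, 0.5)
  expect_all_equal(prof$rhizomatous, 0.5)
  # all one level
  p1 <- categorical_profile(sh, c(a = "evergreen", b = "evergreen",
                                  c = "evergreen"))
  expect_all_equal(p1$evergreen, 1)
  # unknown species excluded and shares renormalized
  p2 <- categorical_profile(sh, c(a = "x", b = NA, c = "y"))
  expect_all_equal(p2$x, 0.2 / 0.7, tol = 1e-12)
  expect_all_equal(p2$y, 0.5 / 0.7, tol = 1e-12)
  expect_identical(attr(p2, "n_unknown"), 1L)
  expect_error(categorical_profile(sh, c(a = NA, b = NA, c = NA)[names(sh)]),
               "known level")
  expect_error(categorical_profile(sh, c(a = "x", b = "x", c = "x"),
                                   levels = "z"), "levels")
})

test_that("delta surfaces subtract cell-wise and categorical deltas sum to zero", {
  cur <- matrix(1:4, 2, 2); fut <- matrix(c(2, 1, 6, 0), 2, 2)
  expect_equal(delta_surface(cur, fut), fut - cur)
  expect_all_equal(delta_surface(cur, cur), 0)
  expect_error(delta_surface(cur, matrix(0, 3, 3)), "dimensions")
  set.seed(4)
  shc <- const_shares(c(a = 0.5, b = 0.3, c = 0.2))
  raw <- runif(3); raw <- raw / sum(raw)
  shf <- const_shares(stats::setNames(raw, c("a", "b", "c")))
  lv <- c(a = "p", b = "q", c = "p")
  d <- delta_surface(categorical_profile(shc, lv), categorical_profile(shf, lv))
  expect_all_equal(Reduce(`+`, d), 0, tol = 1e-12)
})

test_that("regional summaries average cells within labels", {
  surf <- matrix(c(1, 3, 2, 4), 2, 2)  # values (1,2 | 3,4) row-wise
  regions <- matrix(c(1, 2, 1, 2), 2, 2)
  s <- regional_summary(surf, regions)
  expect_equal(s$mean, c(1.5, 3.5))
  expect_equal(s$n_cells, c(2L, 2L))
  # single region: global mean; constant surface: zero sd
  s1 <- regional_summary(surf, matrix(1, 2, 2))
  expect_equal(s1$mean, mean(surf))
  s0 <- regional_summary(matrix(5, 2, 2), regions)
  expect_equal(s0$sd, c(0, 0))
})

test_that("species contributions match hand arithmetic on a 2-species, 3-cell toy", {
  sc <- list(a = matrix(c(0.2, 0.5, 0.8), 1), b = matrix(c(0.8, 0.5, 0.2), 1))
  sf <- list(a = matrix(c(0.6, 0.1, 0.9), 1), b = matrix(c(0.4, 0.9, 0.1), 1))
  tv <- c(a = 10, b = 20)
  # full delta per cell: (t_a - t_b) * (a_fut - a_cur) + 0 ... hand values:
  full <- (10 * c(0.6, 0.1, 0.9) + 20 * c(0.4, 0.9, 0.1)) -
    (10 * c(0.2, 0.5, 0.8) + 20 * c(0.8, 0.5, 0.2))
  # removing either species leaves a single-species pool: delta == 0
  exp_score <- mean((0 - full)^2) / var(full)
  res <- species_contribution(sc, sf, tv)
  expect_equal(sort(res$score), rep(exp_score, 2), tolerance = 1e-12)
})

test_that("zero-share and trait-at-the-mean species contribute exactly zero", {
  set.seed(8)
  # dyadic shares: 1 - x and the pool sum are exact, so removing the
  # zero-share species is a bit-level no-op
  base <- matrix(sample(1:63, 9) / 64, 3, 3)
  sc <- list(a = base, b = 1 - base, z = matrix(0, 3, 3))
  fut <- matrix(sample(1:63, 9) / 64, 3, 3)
  sf <- list(a = fut, b = 1 - fut, z = matrix(0, 3, 3))
  res <- species_contribution(sc, sf, c(a = 4, b = 9, z = 100))
  expect_identical(res$score[res$species_id == "z"], 0)
  # a species whose trait equals the two-species CWMT everywhere: take all
  # traits equal, then any removal leaves the CWMT unchanged
  res_eq <- suppressWarnings(
    species_contribution(sc[1:2], sf[1:2], c(a = 5, b = 5))
  )
  expect_true(all(is.na(res_eq$score)))  # zero-variance full delta flagged
  expect_error(species_contribution(sc["a"], sf["a"], c(a = 1)), "2 species")
})

test_that("layer pools follow the functional-group scheme", {
  tr <- data.frame(
    species_id = paste0("s", 1:6),
    pfg = c("moss", "pteridophyte", "graminoid", "herbaceous", "shrub", "tree")
  )
  expect_setequal(layer_pool(tr, "field"), c("s2", "s3", "s4"))
  expect_identical(layer_pool(tr, "shrub"), "s5")
  expect_identical(layer_pool(tr, "tree"), "s6")
  expect_false("s1" %in% unlist(lapply(c("field", "shrub", "tree"),
                                       function(l) layer_pool(tr, l))))
})
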
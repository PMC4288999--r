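#' Build a standardized feature matrix from an environmental stack
#'
#' Continuous layers contribute linear and (optionally) quadratic features;
#' categorical layers contribute one 0/1 indicator per code. Every feature is
#' standardized using its mean and sd over the background cells (here: all
#' valid cells); zero-variance features are dropped with a warning. The
#' standardization constants are stored so scenario environments can be
#' projected in the training feature space.
#'
#' @param env an [env_stack()].
#' @param layers layers to use; default all.
#' @param quadratic add quadratic features for continuous layers?
#' @param constants optional list of training constants (from a previous call)
#'   to reuse instead of recomputing — required when projecting onto a
#'   scenario environment.
#' @return list with `X` (cells x features matrix over valid cells), `cells`
#'   (linear indices matching rows of `X`), `constants` (feature definitions +
#'   center/scale), `dropped` (names of zero-variance features).
#' @export
build_features <- function(env, layers = names(env$layers), quadratic = TRUE,
                           constants = NULL) {
  stopifnot(inherits(env, "env_stack"))
  bad <- setdiff(layers, names(env$layers))
  if (length(bad)) stop("unknown layer(s): ", paste(bad, collapse = ", "))
  vc <- valid_cells(env)
  if (!length(vc)) stop("environment has no valid cells")

  if (is.null(constants)) {
    defs <- list()
    for (nm in layers) {
      if (env$kind[[nm]] == "continuous") {
        defs[[paste0(nm, ":lin")]] <- list(layer = nm, type = "lin")
        if (quadratic) defs[[paste0(nm, ":quad")]] <- list(layer = nm, type = "quad")
      } else {
        for (code in sort(unique(env$layers[[nm]][vc]))) {
          defs[[paste0(nm, ":", code)]] <- list(layer = nm, type = "ind", code = code)
        }
      }
    }
  } else defs <- constants$defs

  raw <- sapply(defs, function(d) {
    v <- env$layers[[d$layer]][vc]
    switch(d$type, lin = v, quad = v^2, ind = as.numeric(v == d$code))
  })
  raw <- matrix(raw, nrow = length(vc), dimnames = list(NULL, names(defs)))

  if (is.null(constants)) {
    center <- colMeans(raw)
    scale <- apply(raw, 2L, stats::sd)
    dropped <- names(defs)[scale <= 0 | !is.finite(scale)]
    if (length(dropped)) {
      warning("dropping zero-variance feature(s): ", paste(dropped, collapse = ", "))
      keep <- setdiff(names(defs), dropped)
      defs <- defs[keep]; raw <- raw[, keep, drop = FALSE]
      center <- center[keep]; scale <- scale[keep]
    }
    if (!length(defs)) stop("no informative features remain")
    constants <- list(defs = defs, center = center, scale = scale)
  } else dropped <- character(0)

  X <- sweep(sweep(raw, 2L, constants$center), 2L, constants$scale, "/")
  list(X = X, cells = vc, constants = constants, dropped = dropped)
}

# Penalized maxent objective (to be maximized):
#   mean_presence(eta) - logsumexp_background(eta) - beta * sum(|lambda|)
maxent_objective <- function(lambda, Xp, Xb, beta) {
  etab <- as.vector(Xb %*% lambda)
  m <- max(etab)
  mean(Xp %*% lambda) - (m + log(sum(exp(etab - m)))) - beta * sum(abs(lambda))
}

#' Fit a presence-background maximum-entropy model
#'
#' Maximizes the L1-penalized log-likelihood
#' `mean_presence(lambda . f) - log sum_background exp(lambda . f) -
#' beta * sum(|lambda|)` by proximal Newton: each outer step builds the local
#' quadratic model of the log-partition term (gradient and Hessian under the
#' current background distribution), solves the L1-penalized quadratic by
#' cyclic coordinate descent, and backtracks on the true objective. The
#' objective is concave, so the optimum is global. Convergence is declared
#' when the largest component of the generalized gradient falls below `tol`.
#'
#' @param X feature matrix over valid cells (from [build_features()]).
#' @param presence rows of `X` holding presence cells (>= 1).
#' @param background rows of `X` forming the background; default all rows.
#'   Presence cells are also background (standard maxent convention).
#' @param beta L1 penalty per standardized feature (>= 0).
#' @param tol convergence tolerance on the generalized gradient.
#' @param max_iter iteration cap; hitting it flags `converged = FALSE`.
#' @return a `maxent_model`: `lambda`, `beta`, `calibration_r` (mean linear
#'   predictor over presences), `n_background`, `converged`, `iterations`,
#'   `grad_norm`, `objective`.
#' @export
maxent_fit <- function(X, presence, background = seq_len(nrow(X)),
                       beta = 0.1, tol = 1e-8, max_iter = 200L) {
  if (!length(presence)) stop("at least one presence cell is required")
  if (beta < 0) stop("beta must be >= 0")
  Xp <- X[presence, , drop = FALSE]
  Xb <- X[background, , drop = FALSE]
  p <- ncol(X)
  fbar <- colMeans(Xp)

  smooth_val <- function(lambda) {
    eta <- as.vector(Xb %*% lambda)
    m <- max(eta)
    (m + log(sum(exp(eta - m)))) - sum(fbar * lambda)
  }
  penalty <- function(lambda) beta * sum(abs(lambda))
  soft <- function(z, a) sign(z) * pmax(abs(z) - a, 0)

  lambda <- numeric(p)
  fcur <- smooth_val(lambda)
  it <- 0L
  gn <- Inf
  repeat {
    it <- it + 1L
    eta <- as.vector(Xb %*% lambda)
    q <- exp(eta - max(eta)); q <- q / sum(q)
    mq <- as.vector(crossprod(Xb, q))
    g <- mq - fbar                                   # gradient of smooth part
    H <- crossprod(Xb * sqrt(q)) - tcrossprod(mq)    # Fisher information
    diag(H) <- diag(H) + 1e-10

    gg <- ifelse(lambda != 0, abs(g + beta * sign(lambda)),
                 pmax(abs(g) - beta, 0))
    gn <- max(gg)
    if (gn <= tol || it > max_iter) break

    # inner problem: minimize c'u + u'Hu/2 + beta|u|_1 by coordinate descent
    cvec <- g - as.vector(H %*% lambda)
    u <- lambda
    Hu <- as.vector(H %*% u)
    for (sweep_i in 1:1000) {
      delta_max <- 0
      for (j in seq_len(p)) {
        uj_new <- soft(H[j, j] * u[j] - (cvec[j] + Hu[j]), beta) / H[j, j]
        dj <- uj_new - u[j]
        if (dj != 0) {
          Hu <- Hu + H[, j] * dj
          u[j] <- uj_new
          delta_max <- max(delta_max, abs(dj))
        }
      }
      if (delta_max < 1e-12) break
    }
    d <- u - lambda
    # backtracking on the true penalized objective
    t_step <- 1
    repeat {
      cand <- lambda + t_step * d
      fnew <- smooth_val(cand)
      if (fnew + penalty(cand) <= fcur + penalty(lambda) + 1e-12) break
      t_step <- t_step / 2
      if (t_step < 1e-10) { cand <- lambda; fnew <- fcur; break }
    }
    if (max(abs(cand - lambda)) == 0) break  # no progress possible
    lambda <- cand
    fcur <- fnew
  }
  if (gn > tol) warning("maxent_fit did not converge (grad norm ", signif(gn, 3), ")")

  structure(
    list(lambda = stats::setNames(lambda, colnames(X)), beta = beta,
         calibration_r = mean(Xp %*% lambda), n_background = nrow(Xb),
         converged = gn <= tol, iterations = it, grad_norm = gn,
         objective = maxent_objective(lambda, Xp, Xb, beta)),
    class = "maxent_model"
  )
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("maxent_model: %d features, beta %g, %s in %d iters (grad %.2e)\n",
              length(x$lambda), x$beta,
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$grad_norm))
  invisible(x)
}

#' Project a fitted maxent model onto an environment
#'
#' `scale = "raw"` returns the maxent probability distribution
#' `exp(lambda . f(x)) / Z` normalized over the projection environment's valid
#' cells (sums to 1). `scale = "logistic"` applies the entropy-calibrated
#' transform `1 - exp(-exp(r) * p_raw(x) * N_bg)` with `r` the mean linear
#' predictor over the training presences — a monotone map of raw into (0, 1).
#'
#' @param model a `maxent_model`.
#' @param env an [env_stack()] providing the training layers. Features are
#'   rebuilt with the training standardization constants.
#' @param constants the training feature constants (from [build_features()]).
#' @param scale `"raw"` or `"logistic"`.
#' @return numeric matrix of suitabilities (NA on masked cells).
#' @export
maxent_project <- function(model, env, constants, scale = c("raw", "logistic")) {
  scale <- match.arg(scale)
  fb <- build_features(env, constants = constants)
  eta <- as.vector(fb$X %*% model$lambda[colnames(fb$X)])
  m <- max(eta)
  praw <- exp(eta - m) / sum(exp(eta - m))
  val <- switch(scale,
    raw = praw,
    logistic = 1 - exp(-exp(model$calibration_r) * praw * length(eta))
  )
  out <- matrix(NA_real_, nrow(env$mask), ncol(env$mask))
  out[fb$cells] <- val
  out
}

#' Fit per-species, per-abundance-class suitability models and project them
#'
#' Occurrence records are split by abundance class; each (species, class) with
#' at least `min_presences` records is fitted against the full valid-cell
#' background and projected onto the current and (if given) scenario
#' environments. Classes below the threshold are returned as `NULL` markers
#' that downstream weighting handles by dropping the class weight.
#'
#' @param occurrences an occurrence data.frame (`species_id`, `row`, `col`,
#'   `abundance_class`).
#' @param env training [env_stack()].
#' @param env_future optional scenario [env_stack()].
#' @param beta,min_presences,quadratic,scale see [maxent_fit()],
#'   [maxent_project()].
#' @return list keyed by species; each element has `models`, `current`,
#'   `future` (lists of length 3 indexed by class; `NULL` where skipped) and a
#'   `fitted` logical vector. Attribute `log` records fitted/skipped counts.
#' @export
fit_all_sdms <- function(occurrences, env, env_future = NULL, beta = 0.1,
                         min_presences = 5L, quadratic = TRUE,
                         scale = "raw") {
  stopifnot(inherits(env, "env_stack"))
  fb <- build_features(env, quadratic = quadratic)
  cell_row <- match(
    (occurrences$col - 1L) * nrow(env$mask) + occurrences$row,
    fb$cells
  )
  if (anyNA(cell_row)) stop("occurrence records fall on masked cells")

  species <- unique(occurrences$species_id)
  log_lines <- character(0)
  out <- lapply(species, function(sp) {
    res <- list(models = vector("list", 3L), current = vector("list", 3L),
                future = vector("list", 3L), fitted = logical(3L))
    for (cls in 1:3) {
      idx <- cell_row[occurrences$species_id == sp &
                        occurrences$abundance_class == cls]
      idx <- unique(idx)
      if (length(idx) < min_presences) {
        log_lines <<- c(log_lines, sprintf("%s class %d: skipped (%d < %d presences)",
                                           sp, cls, length(idx), min_presences))
        next
      }
      mod <- maxent_fit(fb$X, presence = idx, beta = beta)
      res$models[[cls]] <- mod
      res$current[[cls]] <- maxent_project(mod, env, fb$constants, scale = scale)
      if (!is.null(env_future)) {
        res$future[[cls]] <- maxent_project(mod, env_future, fb$constants,
                                            scale = scale)
      }
      res$fitted[cls] <- TRUE
      log_lines <<- c(log_lines, sprintf("%s class %d: fitted on %d presences",
                                         sp, cls, length(idx)))
    }
    if (!any(res$fitted)) {
      warning("species ", sp, " has no class with >= ", min_presences,
              " presences; skipped entirely")
    }
    res
  })
  names(out) <- species
  attr(out, "log") <- log_lines
  attr(out, "constants") <- fb$constants
  out
}
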
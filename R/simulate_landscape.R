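#' @keywords internal
#' Run code with a temporary RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Smooth a matrix with a separable Gaussian kernel (reflective padding).
# sigma is the kernel sd in cells; this is the low-pass filter that turns
# white noise into a spatially autocorrelated field.
gaussian_smooth <- function(m, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  pad_reflect <- function(v, h) {
    n <- length(v)
    i <- c(rev(seq_len(min(h, n))), seq_len(n), n + 1 - rev(seq_len(min(h, n))))
    # for h > n, recycle the reflection (tiny grids with long kernels)
    while (length(i) < n + 2 * h) i <- c(i[1L], i, i[length(i)])
    v[i]
  }
  smooth_vec <- function(v) {
    p <- pad_reflect(v, half)
    stats::convolve(p, rev(k), type = "filter")
  }
  m <- apply(m, 2L, smooth_vec)
  t(apply(t(m), 2L, smooth_vec))
}

#' Generate a synthetic environmental landscape
#'
#' Builds a stack of spatially autocorrelated layers emulating gridded climate,
#' terrain and substrate predictors. Continuous layers are smooth Gaussian
#' random fields: white noise low-pass filtered with a separable Gaussian
#' kernel of standard deviation `correlation_length` cells, then (by default)
#' standardized to zero mean and unit variance over valid cells. Categorical
#' layers are contiguous patches obtained by cutting an auxiliary smooth field
#' at its quantiles into `n_codes` integer-coded classes.
#'
#' The first two continuous layers are named `temp` and `precip` and flagged
#' climatic (a scenario delta may shift them); further continuous layers are
#' `cont3`, `cont4`, ...; categorical layers are `soil`, `bedrock`, `cat3`, ...
#'
#' @param nrows,ncols grid dimensions (each at least 2).
#' @param n_continuous,n_categorical number of layers of each kind.
#' @param correlation_length smoothing kernel sd in cells (> 0); larger values
#'   give smoother fields.
#' @param n_codes integer codes per categorical layer (recycled).
#' @param standardize standardize continuous layers to mean 0, sd 1? Without
#'   standardization, heavier smoothing shrinks the field's variance.
#' @param cellsize,origin grid geometry, as in [env_stack()].
#' @param seed integer seed; output is deterministic given the seed.
#' @return an [env_stack()].
#' @export
generate_landscape <- function(nrows, ncols, n_continuous = 4, n_categorical = 2,
                               correlation_length = 5, n_codes = 4,
                               standardize = TRUE, cellsize = 500,
                               origin = c(0, 0), seed = 1) {
  if (nrows < 2 || ncols < 2) stop("grid must be at least 2 x 2")
  if (correlation_length <= 0) stop("correlation_length must be > 0")
  if (n_continuous < 1) stop("need at least one continuous layer")
  n_codes <- rep_len(as.integer(n_codes), max(1L, n_categorical))

  cont_names <- c("temp", "precip", paste0("cont", seq_len(max(0, n_continuous - 2)) + 2))
  cont_names <- cont_names[seq_len(n_continuous)]
  cat_names <- c("soil", "bedrock", paste0("cat", seq_len(max(0, n_categorical - 2)) + 2))
  cat_names <- cat_names[seq_len(n_categorical)]

  with_seed(seed, {
    layers <- list()
    for (nm in cont_names) {
      f <- gaussian_smooth(matrix(stats::rnorm(nrows * ncols), nrows, ncols),
                           correlation_length)
      if (standardize) {
        s <- stats::sd(f)
        f <- if (s > 0) (f - mean(f)) / s else f - mean(f)
      }
      layers[[nm]] <- f
    }
    for (j in seq_along(cat_names)) {
      f <- gaussian_smooth(matrix(stats::rnorm(nrows * ncols), nrows, ncols),
                           correlation_length)
      br <- stats::quantile(f, probs = seq(0, 1, length.out = n_codes[j] + 1L))
      br[1L] <- -Inf; br[length(br)] <- Inf
      layers[[cat_names[j]]] <- matrix(as.numeric(cut(f, breaks = unique(br))),
                                       nrows, ncols)
    }
    kind <- stats::setNames(
      c(rep("continuous", n_continuous), rep("categorical", n_categorical)),
      c(cont_names, cat_names)
    )
    climatic <- stats::setNames(rep(FALSE, length(kind)), names(kind))
    climatic[intersect(c("temp", "precip"), names(kind))] <- TRUE
    env_stack(layers, kind, climatic, cellsize = cellsize, origin = origin)
  })
}
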
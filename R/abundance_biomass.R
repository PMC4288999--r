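#' Class weights for the abundance-class weighted average
#'
#' Field abundance classes are single individuals (1), frequent (2) and
#' dominant (3); the relative-abundance approximation weights their modeled
#' occurrence probabilities 0.01, 0.1 and 1 respectively.
#' @export
DEFAULT_CLASS_WEIGHTS <- c(single = 0.01, frequent = 0.1, dominant = 1)

#' Weighted-average relative abundance from per-class occurrence probabilities
#'
#' Combines the three abundance-class suitability surfaces into one
#' relative-abundance estimate. Under the `"normalized"` convention the result
#' is `(w1 p1 + w2 p2 + w3 p3) / (w1 + w2 + w3)`; under `"sum"` the normalizer
#' is dropped. A class whose surface is `NULL` (no model fitted) contributes
#' nothing to the numerator and, under the normalized convention, its weight is
#' removed from the denominator.
#'
#' @param p1,p2,p3 per-cell probability matrices in `[0, 1]`, or `NULL` for an
#'   absent class.
#' @param weights positive class weights `(single, frequent, dominant)`.
#' @param convention `"normalized"` (default) or `"sum"`.
#' @return matrix of relative-abundance estimates.
#' @export
weighted_abundance <- function(p1, p2, p3, weights = DEFAULT_CLASS_WEIGHTS,
                               convention = c("normalized", "sum")) {
  convention <- match.arg(convention)
  if (any(weights <= 0)) stop("class weights must be > 0")
  ps <- list(p1, p2, p3)
  present <- !vapply(ps, is.null, logical(1))
  if (!any(present)) stop("all three abundance classes are absent")
  dims <- unique(lapply(ps[present], dim))
  if (length(dims) != 1L) stop("class surfaces must share dimensions")
  num <- matrix(0, dims[[1L]][1L], dims[[1L]][2L])
  for (k in which(present)) {
    pk <- ps[[k]]
    rng <- range(pk, na.rm = TRUE)
    if (rng[1L] < 0 || rng[2L] > 1) stop("class probabilities must lie in [0, 1]")
    num <- num + weights[k] * pk
  }
  if (convention == "normalized") num / sum(weights[present]) else num
}

#' Allometric parameter sets
#'
#' The height-to-biomass conversion rests on two interspecific scaling laws:
#' plant height is proportional to individual mass `M^a` and maximum stand
#' density to `M^d` with `d = -0.757`. The published combination is
#' `B_max = c * (H / b)^(d / a)` with `c = 1.769e5` kg dry weight per square
#' metre, `a = 0.264`, `b = 2.58` for non-trees and `a = 0.345`, `b = 3.71`
#' for trees.
#' @export
ALLOMETRIC_PARAMS <- list(
  `non-tree` = list(a = 0.264, b = 2.58, c = 1.769e5, d = -0.757),
  tree       = list(a = 0.345, b = 3.71, c = 1.769e5, d = -0.757)
)

#' Maximum potential biomass from canopy height
#'
#' Default mode `"printed"` evaluates the published formula
#' `B_max = c * (H / b)^(d / a)` exactly as stated: a strict power law,
#' decreasing in height since `d / a < 0`, equal to the prefactor `c` at
#' `H = b`. Mode `"derived"` instead uses exponent `(1 + d) / a`, the exponent
#' obtained by multiplying per-individual mass (`M ~ (H/b)^(1/a)`) by maximum
#' density (`N ~ M^d`), i.e. `B = M * N ~ M^(1+d)` — provided for sensitivity
#' analysis of the published form; relative-biomass shares, not absolute
#' values, are what propagates downstream.
#'
#' @param H canopy height in metres (> 0); vectorized.
#' @param form `"non-tree"` or `"tree"`.
#' @param mode `"printed"` (default) or `"derived"`.
#' @return maximum potential biomass, kg dry weight per square metre.
#' @export
b_max <- function(H, form = c("non-tree", "tree"), mode = c("printed", "derived")) {
  form <- match.arg(form); mode <- match.arg(mode)
  if (any(!is.finite(H)) || any(H <= 0)) stop("height must be finite and > 0")
  p <- ALLOMETRIC_PARAMS[[form]]
  expo <- if (mode == "printed") p$d / p$a else (1 + p$d) / p$a
  p$c * (H / p$b)^expo
}

#' Per-cell relative biomass shares for a species pool
#'
#' Each species' relative abundance surface is scaled by its maximum potential
#' biomass (from canopy height via [b_max()]); shares are the per-cell
#' proportions of that product over the pool, summing to 1 on every cell with
#' a positive denominator. Cells where no species has positive abundance (or
#' masked in any input) are masked rather than set to a uniform community.
#'
#' @param abundances named list (species -> relative-abundance matrix).
#' @param heights named numeric, canopy height (m) per species.
#' @param forms named character, `"non-tree"` or `"tree"` per species.
#' @param mode allometric mode, see [b_max()].
#' @return named list of share matrices (same order as `abundances`), with an
#'   attribute `mask` marking cells carrying a community.
#' @export
relative_biomass <- function(abundances, heights, forms, mode = "printed") {
  if (!length(abundances)) stop("species pool is empty")
  sp <- names(abundances)
  if (is.null(sp) || anyDuplicated(sp)) stop("abundances must be uniquely named by species")
  missing_h <- setdiff(sp, names(heights))
  if (length(missing_h)) stop("no height for species: ", paste(missing_h, collapse = ", "))
  d <- dim(abundances[[1L]])
  bm <- vapply(sp, function(s) b_max(heights[[s]], forms[[s]], mode), numeric(1))
  weighted <- lapply(sp, function(s) abundances[[s]] * bm[[s]])
  denom <- Reduce(`+`, weighted)
  ok <- is.finite(denom) & denom > 0
  shares <- lapply(weighted, function(w) {
    s <- w / denom
    s[!ok] <- NA_real_
    s
  })
  names(shares) <- sp
  attr(shares, "mask") <- ok
  shares
}
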
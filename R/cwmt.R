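#' Community-weighted mean trait surface
#'
#' Per cell, the trait value averaged over the species pool weighted by
#' relative biomass share: `CWMT(x) = sum_s share_s(x) * t_s`. By the
#' mass-ratio hypothesis this is the community property that drives ecosystem
#' processes. Because shares sum to 1, the CWMT is bounded by the pool's trait
#' extrema and is linear in the trait values.
#'
#' @param shares named list of share matrices (from [relative_biomass()]),
#'   summing to 1 cell-wise on unmasked cells.
#' @param trait named numeric vector of trait values covering every pooled
#'   species.
#' @return matrix of CWMT values (NA where the community is masked).
#' @export
cwmt <- function(shares, trait) {
  sp <- names(shares)
  missing_t <- sp[!(sp %in% names(trait)) | is.na(trait[sp])]
  if (length(missing_t)) {
    stop("no trait value for species: ", paste(missing_t, collapse = ", "))
  }
  Reduce(`+`, Map(function(s, t) s * t, shares, as.list(trait[sp])))
}

#' Biomass-proportion profile of a categorical trait
#'
#' The proportion of community biomass carried by each level of a categorical
#' trait: `prop(level) = sum over species at that level of share_s(x)`.
#' Species with unknown level are excluded and the remaining shares
#' renormalized per cell (the excluded count is recorded in attribute
#' `n_unknown`); cells where every species is unknown are masked.
#'
#' @param shares named list of share matrices.
#' @param trait named character vector, level per species (NA = unknown).
#' @param levels level set; defaults to the sorted observed levels.
#' @return named list of proportion matrices, one per level, summing to 1
#'   cell-wise on unmasked cells.
#' @export
categorical_profile <- function(shares, trait, levels = NULL) {
  sp <- names(shares)
  lev_by_sp <- trait[sp]
  known <- !is.na(lev_by_sp)
  if (!any(known)) stop("no pooled species has a known level")
  if (is.null(levels)) levels <- sort(unique(lev_by_sp[known]))
  if (!length(intersect(lev_by_sp[known], levels))) {
    stop("no pooled species carries any of the requested levels")
  }
  known_total <- Reduce(`+`, shares[sp[known]])
  ok <- is.finite(known_total) & known_total > 0
  out <- lapply(levels, function(lv) {
    members <- sp[known & lev_by_sp == lv]
    m <- if (length(members)) Reduce(`+`, shares[members]) else
      matrix(0, nrow(known_total), ncol(known_total))
    m <- m / known_total
    m[!ok] <- NA_real_
    m
  })
  names(out) <- levels
  attr(out, "n_unknown") <- sum(!known)
  out
}

#' Change surface between scenarios
#'
#' Cell-wise `future - current`. For categorical profiles (lists of level
#' matrices) the difference is taken level by level; level deltas sum to zero
#' cell-wise since each profile partitions unity.
#'
#' @param current,future matrices, or named lists of matrices with identical
#'   level sets.
#' @return same shape as the inputs.
#' @export
delta_surface <- function(current, future) {
  if (is.list(current) != is.list(future)) stop("inputs must have the same form")
  if (is.list(current)) {
    if (!identical(names(current), names(future))) stop("level sets differ")
    return(stats::setNames(Map(delta_surface, current, future), names(current)))
  }
  if (!identical(dim(current), dim(future))) stop("grid dimensions differ")
  future - current
}

#' Regional summary of a change surface
#'
#' Arithmetic mean and sd of cell values within each region (cells weighted
#' equally), with cell counts. Regions with no unmasked cells are reported
#' with `n_cells = 0` and NA statistics.
#'
#' @param surface numeric matrix.
#' @param regions integer matrix of region labels (same dimensions; NA =
#'   unlabelled).
#' @return data.frame with `region`, `mean`, `sd`, `n_cells`.
#' @export
regional_summary <- function(surface, regions) {
  if (!identical(dim(surface), dim(regions))) stop("grid dimensions differ")
  labs <- sort(unique(regions[!is.na(regions)]))
  do.call(rbind, lapply(labs, function(r) {
    v <- surface[!is.na(regions) & regions == r]
    v <- v[is.finite(v)]
    data.frame(region = r,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else if (length(v)) 0 else NA_real_,
               n_cells = length(v))
  }))
}

#' Per-species contribution to CWMT change
#'
#' Leave-one-out importance: for each species the scenario-change surface
#' `dCWMT = CWMT_future - CWMT_current` is recomputed with that species
#' removed and the remaining shares renormalized per cell, and the score is
#' the standardized mean squared error
#' `mean_cells((dCWMT_-s - dCWMT_full)^2) / var_cells(dCWMT_full)` —
#' scale-free, hence comparable across traits. A species with zero share
#' everywhere, or whose trait equals the community mean everywhere, scores 0.
#'
#' @param shares_current,shares_future named lists of share matrices over the
#'   same pool (>= 2 species).
#' @param trait named numeric trait vector.
#' @return data.frame `species_id`, `score`, sorted descending by score.
#' @export
species_contribution <- function(shares_current, shares_future, trait) {
  sp <- names(shares_current)
  if (!identical(sp, names(shares_future))) stop("pools differ between scenarios")
  if (length(sp) < 2) stop("need at least 2 species in the pool")
  full <- delta_surface(cwmt(shares_current, trait), cwmt(shares_future, trait))
  ok <- is.finite(full)
  v_full <- stats::var(full[ok])
  if (!isTRUE(v_full > 0)) {
    warning("full-model change surface has zero spatial variance; scores undefined, returning NA")
  }
  drop_renorm <- function(shares, s) {
    rest <- shares[setdiff(names(shares), s)]
    tot <- Reduce(`+`, rest)
    lapply(rest, function(m) {
      r <- m / tot
      r[!is.finite(tot) | tot <= 0] <- NA_real_
      r
    })
  }
  scores <- vapply(sp, function(s) {
    cur <- drop_renorm(shares_current, s)
    fut <- drop_renorm(shares_future, s)
    red <- delta_surface(cwmt(cur, trait), cwmt(fut, trait))
    use <- ok & is.finite(red)
    if (!any(use) || !isTRUE(v_full > 0)) return(NA_real_)
    mean((red[use] - full[use])^2) / v_full
  }, numeric(1))
  out <- data.frame(species_id = sp, score = unname(scores))
  out[order(-out$score), , drop = FALSE]
}

#' Assemble layer pools from a trait/functional-group table
#'
#' Field layer pools pteridophytes, graminoids and herbs; the shrub layer is
#' shrubs; trees are treated separately and mosses are excluded from trait
#' weighting entirely.
#'
#' @param traits data.frame with `species_id` and `pfg`.
#' @param layer `"field"`, `"shrub"` or `"tree"`.
#' @return character vector of species ids.
#' @export
layer_pool <- function(traits, layer = c("field", "shrub", "tree")) {
  layer <- match.arg(layer)
  groups <- switch(layer,
    field = c("pteridophyte", "graminoid", "herbaceous"),
    shrub = "shrub",
    tree = "tree"
  )
  traits$species_id[traits$pfg %in% groups]
}
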
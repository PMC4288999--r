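#' Multi-layer environmental raster stack
#'
#' An `env_stack` bundles named gridded layers on a common grid: continuous
#' layers (climate, terrain, pH) and categorical layers (soil, bedrock classes
#' coded as integers). All layers share dimensions and a validity mask.
#'
#' Grid convention: layers are `nrows x ncols` numeric matrices; cells are
#' addressed by 1-based `(row, col)` pairs or 1-based linear matrix indices
#' (column-major, as R matrices are indexed). The origin `(x0, y0)` is the
#' lower-left corner of the grid, matching the ESRI ASCII header convention.
#'
#' @param layers named list of numeric matrices, all the same dimension.
#' @param kind named character vector, `"continuous"` or `"categorical"` per
#'   layer.
#' @param climatic named logical vector flagging layers a climate scenario may
#'   shift; only continuous layers may be climatic.
#' @param cellsize cell edge length in metres.
#' @param origin numeric length-2, x/y of the lower-left corner.
#' @param mask logical matrix, `TRUE` where cells hold valid data; defaults to
#'   all cells valid.
#' @return an object of class `env_stack`.
#' @export
env_stack <- function(layers, kind, climatic = NULL, cellsize = 500,
                      origin = c(0, 0), mask = NULL) {
  if (!length(layers) || is.null(names(layers)) || anyDuplicated(names(layers))) {
    stop("`layers` must be a non-empty uniquely named list")
  }
  dims <- lapply(layers, dim)
  if (any(vapply(dims, is.null, logical(1)))) stop("every layer must be a matrix")
  d0 <- dims[[1L]]
  if (!all(vapply(dims, function(d) identical(d, d0), logical(1)))) {
    stop("all layers must share dimensions")
  }
  kind <- kind[names(layers)]
  if (anyNA(kind) || !all(kind %in% c("continuous", "categorical"))) {
    stop("`kind` must name every layer as 'continuous' or 'categorical'")
  }
  if (is.null(climatic)) {
    climatic <- stats::setNames(rep(FALSE, length(layers)), names(layers))
  }
  climatic <- climatic[names(layers)]
  climatic[is.na(climatic)] <- FALSE
  if (any(climatic & kind == "categorical")) {
    stop("categorical layers cannot be flagged climatic")
  }
  if (is.null(mask)) mask <- matrix(TRUE, d0[1L], d0[2L])
  if (!identical(dim(mask), d0)) stop("mask must share layer dimensions")
  for (nm in names(layers)) {
    v <- layers[[nm]][mask]
    if (any(!is.finite(v))) stop("layer '", nm, "' has non-finite values on valid cells")
    if (kind[[nm]] == "categorical" && any(v != round(v))) {
      stop("categorical layer '", nm, "' must hold integer codes")
    }
  }
  structure(
    list(layers = layers, kind = kind, climatic = climatic,
         cellsize = cellsize, origin = origin, mask = mask),
    class = "env_stack"
  )
}

#' @export
print.env_stack <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("env_stack: %d layers, %d x %d cells (%d valid), cellsize %g m\n",
              length(x$layers), d[1L], d[2L], sum(x$mask), x$cellsize))
  for (nm in names(x$layers)) {
    cat(sprintf("  %-12s %s%s\n", nm, x$kind[[nm]],
                if (isTRUE(x$climatic[[nm]])) " [climatic]" else ""))
  }
  invisible(x)
}

#' @export
dim.env_stack <- function(x) dim(x$mask)

#' Linear indices of valid (non-nodata) cells
#' @param env an `env_stack`.
#' @return integer vector of 1-based linear matrix indices.
#' @export
valid_cells <- function(env) which(env$mask)

n_layers <- function(env) length(env$layers)

#' Additive climate-scenario delta
#'
#' A scenario is a named numeric vector of per-layer additive offsets, in the
#' layer's own units (e.g. `c(temp = +2.85)` for degrees Celsius). Layers not
#' named are left unchanged; only continuous layers flagged climatic may be
#' shifted.
#'
#' @param deltas named numeric vector of offsets.
#' @return object of class `scenario_delta`.
#' @export
scenario_delta <- function(deltas) {
  if (length(deltas) && (is.null(names(deltas)) || any(!nzchar(names(deltas))))) {
    stop("scenario offsets must be named by layer")
  }
  if (any(!is.finite(deltas))) stop("scenario offsets must be finite")
  structure(as.list(deltas), class = "scenario_delta")
}

#' Apply a climate-scenario delta to an environmental stack
#'
#' Returns a copy of `env` with each named offset added to the corresponding
#' layer on valid cells. All other layers and the mask are returned unchanged.
#'
#' @param env an `env_stack`.
#' @param delta a `scenario_delta` (or a named numeric vector of offsets).
#' @return a new `env_stack`.
#' @export
apply_scenario <- function(env, delta) {
  stopifnot(inherits(env, "env_stack"))
  if (!inherits(delta, "scenario_delta")) delta <- scenario_delta(unlist(delta))
  for (nm in names(delta)) {
    if (!nm %in% names(env$layers)) {
      stop("scenario names unknown layer '", nm, "'")
    }
    if (env$kind[[nm]] != "continuous" || !isTRUE(env$climatic[[nm]])) {
      stop("layer '", nm, "' is not a continuous climatic layer; cannot apply offset")
    }
    env$layers[[nm]] <- env$layers[[nm]] + delta[[nm]]
  }
  env
}
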
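#' Write a grid layer as an ESRI ASCII raster
#'
#' Plain-text single-band raster: a 6-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by one line
#' of values per grid row, top row first. `NA` cells are written as the nodata
#' value. Values are written with full double precision so that
#' `read_grid(write_grid(x))` round-trips exactly.
#'
#' @param m numeric matrix (row 1 = top of the map).
#' @param path output path.
#' @param cellsize,origin grid geometry; `origin` is the lower-left corner.
#' @param nodata nodata sentinel written for `NA` cells.
#' @export
write_grid <- function(m, path, cellsize = 500, origin = c(0, 0),
                       nodata = -9999) {
  stopifnot(is.matrix(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", format(origin[1L], digits = 17)),
    paste("yllcorner", format(origin[2L], digits = 17)),
    paste("cellsize", format(cellsize, digits = 17)),
    paste("NODATA_value", nodata)
  ), con)
  v <- m
  v[is.na(v)] <- nodata
  for (i in seq_len(nrow(v))) {
    writeLines(paste(format(v[i, ], digits = 17, trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path file path.
#' @return numeric matrix with `NA` at nodata cells; attributes `cellsize` and
#'   `origin` carry the geometry.
#' @export
read_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  expected <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                "NODATA_value")
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(parts) != 2L || tolower(parts[1L]) != tolower(expected[i])) {
      stop("malformed ESRI ASCII header at line ", i, " of ", path,
           ": expected '", expected[i], "'")
    }
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
  }
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != hdr$nrows) {
    stop("expected ", hdr$nrows, " data rows, found ", length(body), " in ", path)
  }
  vals <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
  if (any(lengths(vals) != hdr$ncols)) stop("row length mismatch in ", path)
  m <- do.call(rbind, vals)
  m[m == hdr$nodata_value] <- NA_real_
  attr(m, "cellsize") <- hdr$cellsize
  attr(m, "origin") <- c(hdr$xllcorner, hdr$yllcorner)
  m
}

#' Write / read an environmental stack (one .asc per layer + YAML manifest)
#'
#' The manifest records, per layer, the grid file, kind and climatic flag, so
#' a stack round-trips with its metadata.
#'
#' @param env an [env_stack()].
#' @param dir output directory (created if needed).
#' @return `write_env_stack`: the manifest path; `read_env_stack`: an
#'   [env_stack()].
#' @export
write_env_stack <- function(env, dir) {
  stopifnot(inherits(env, "env_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  layers <- lapply(names(env$layers), function(nm) {
    f <- paste0(nm, ".asc")
    m <- env$layers[[nm]]
    m[!env$mask] <- NA_real_
    write_grid(m, file.path(dir, f), cellsize = env$cellsize,
               origin = env$origin)
    list(name = nm, file = f, kind = unname(env$kind[[nm]]),
         climatic = isTRUE(env$climatic[[nm]]))
  })
  manifest <- file.path(dir, "stack.yml")
  yaml::write_yaml(list(cellsize = env$cellsize,
                        origin = as.list(env$origin), layers = layers),
                   manifest)
  invisible(manifest)
}

#' @rdname write_env_stack
#' @param manifest path to a `stack.yml` manifest.
#' @export
read_env_stack <- function(manifest) {
  spec <- yaml::read_yaml(manifest)
  dir <- dirname(manifest)
  mats <- lapply(spec$layers, function(l) read_grid(file.path(dir, l$file)))
  names(mats) <- vapply(spec$layers, `[[`, character(1), "name")
  mask <- Reduce(`&`, lapply(mats, function(m) !is.na(m)))
  mats <- lapply(mats, function(m) { m[is.na(m)] <- 0; m })
  env_stack(
    mats,
    kind = stats::setNames(vapply(spec$layers, `[[`, character(1), "kind"),
                           names(mats)),
    climatic = stats::setNames(vapply(spec$layers, function(l)
      isTRUE(l$climatic), logical(1)), names(mats)),
    cellsize = spec$cellsize, origin = unlist(spec$origin), mask = mask
  )
}

#' Read and validate an occurrence table
#'
#' CSV with columns `species_id`, `row`, `col`, `abundance_class`; class codes
#' must be 1 (single), 2 (frequent) or 3 (dominant).
#'
#' @param path CSV path.
#' @return validated occurrence data.frame.
#' @export
read_occurrences <- function(path) {
  occ <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "row", "col", "abundance_class")
  miss <- setdiff(need, names(occ))
  if (length(miss)) stop("occurrence table lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad <- which(!(occ$abundance_class %in% 1:3))
  if (length(bad)) {
    stop("abundance_class outside {1,2,3} at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  class(occ) <- c("occurrence_set", "data.frame")
  occ
}

#' Read a trait table
#'
#' CSV with a `species_id` column; empty cells are missing values. Duplicate
#' species ids are rejected.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_traits <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (!"species_id" %in% names(tr)) stop("trait table lacks species_id column")
  if (anyDuplicated(tr$species_id)) {
    stop("duplicate species ids in trait table: ",
         paste(unique(tr$species_id[duplicated(tr$species_id)]), collapse = ", "))
  }
  tr
}

#' Read a phylogeny (Newick), checking tip coverage
#'
#' @param path Newick file.
#' @param species optional species ids that must be covered; tips absent from
#'   `species` are retained with a warning.
#' @return an \pkg{ape} `phylo`.
#' @export
read_tree <- function(path, species = NULL) {
  tr <- ape::read.tree(path)
  if (!is.null(species)) {
    missing_sp <- setdiff(species, tr$tip.label)
    if (length(missing_sp)) {
      stop("tree lacks tip(s): ", paste(missing_sp, collapse = ", "))
    }
    extra <- setdiff(tr$tip.label, species)
    if (length(extra)) {
      warning(length(extra), " tree tip(s) absent from the trait table; retained")
    }
  }
  tr
}

#' Read / write a climate-scenario delta as YAML
#'
#' A mapping from layer name to additive offset in layer units.
#'
#' @param path YAML file.
#' @return a [scenario_delta()].
#' @export
read_scenario <- function(path) {
  scenario_delta(unlist(yaml::read_yaml(path)))
}

#' @rdname read_scenario
#' @param delta a [scenario_delta()] or named numeric vector.
#' @export
write_scenario <- function(delta, path) {
  yaml::write_yaml(as.list(unclass(delta)), path)
  invisible(path)
}
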
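#' Plant functional groups recognised by the pipeline
#'
#' Mosses are excluded from trait weighting (no trait or size data);
#' pteridophytes, graminoids and herbs form the field layer; shrubs form the
#' shrub layer; trees are treated separately.
#' @export
PFG_LEVELS <- c("moss", "pteridophyte", "graminoid", "herbaceous", "shrub", "tree")

#' Wetland types
#' @export
WETLAND_TYPES <- c("bog", "fen", "riparian")

#' Generate synthetic species with known niches
#'
#' Each species gets a unimodal (Gaussian) response to every continuous layer
#' — an optimum drawn uniformly within the layer's observed range and a niche
#' breadth proportional to the layer's spread — plus per-code multipliers for
#' every categorical layer (one preferred code at 1, others below 1), a maximum
#' local abundance, a plant functional group, and membership in one or more
#' wetland types. These truths are the ground truth for recovery tests.
#'
#' @param env an [env_stack()].
#' @param n_species number of species (>= 1).
#' @param pfg_scheme character vector of functional groups to cycle through;
#'   every group is represented when `n_species >=` number of groups.
#' @param breadth_range niche breadth as multiples of the layer sd (min, max).
#' @param niche_dims number of continuous layers each species responds to
#'   (sampled per species; capped at the number available). Real species
#'   respond strongly to a few predictors, and a low-dimensional niche keeps
#'   synthetic species widespread enough to be recorded, as the common
#'   dominant wetland plants the analysis targets are.
#' @param n_cat_pref number of categorical layers each species has code
#'   preferences for (others are neutral).
#' @param seed integer seed.
#' @return a list of `species_truth` objects with fields `id`, `optimum`,
#'   `breadth`, `cat_pref` (per-layer named multiplier vectors),
#'   `max_abundance`, `pfg`, `wetland`.
#' @export
generate_species <- function(env, n_species, pfg_scheme = PFG_LEVELS,
                             breadth_range = c(0.75, 1.75), niche_dims = 2L,
                             n_cat_pref = 1L, seed = 1) {
  stopifnot(inherits(env, "env_stack"))
  if (n_species < 1) stop("n_species must be >= 1")
  vc <- valid_cells(env)
  if (!length(vc)) stop("environment has no valid cells")
  cont <- names(env$layers)[env$kind == "continuous"]
  catl <- names(env$layers)[env$kind == "categorical"]

  with_seed(seed, {
    pfgs <- rep_len(pfg_scheme, n_species)
    lapply(seq_len(n_species), function(i) {
      use_cont <- if (length(cont) > niche_dims) {
        sort(sample(cont, niche_dims))
      } else cont
      use_cat <- if (length(catl) > n_cat_pref) {
        sort(sample(catl, n_cat_pref))
      } else catl
      opt <- br <- numeric(0)
      for (nm in use_cont) {
        v <- env$layers[[nm]][vc]
        opt[nm] <- stats::runif(1, min(v), max(v))
        s <- max(stats::sd(v), 1e-8)
        br[nm] <- stats::runif(1, breadth_range[1L], breadth_range[2L]) * s
      }
      cat_pref <- lapply(use_cat, function(nm) {
        codes <- sort(unique(env$layers[[nm]][vc]))
        mult <- stats::setNames(stats::runif(length(codes), 0.4, 0.9), codes)
        mult[sample(length(codes), 1L)] <- 1
        mult
      })
      names(cat_pref) <- use_cat
      structure(
        list(id = sprintf("sp%02d", i), optimum = opt, breadth = br,
             cat_pref = cat_pref,
             max_abundance = stats::runif(1, 1, 10),
             pfg = pfgs[i],
             wetland = sort(sample(WETLAND_TYPES,
                                   size = sample(1:2, 1L),
                                   replace = FALSE))),
        class = "species_truth"
      )
    })
  })
}

#' True abundance surface of a synthetic species
#'
#' Per-cell abundance is the species' maximum abundance times the product of
#' Gaussian responses `exp(-(x - opt)^2 / (2 * breadth^2))` over continuous
#' layers and the categorical preference multipliers; it lies in
#' `[0, max_abundance]` and equals `max_abundance` where every layer sits at
#' the optimum with all multipliers 1.
#'
#' @param species a `species_truth`.
#' @param env an [env_stack()] providing every layer named in the niche.
#' @return numeric matrix of abundances; `NA` on masked cells.
#' @export
true_abundance <- function(species, env) {
  stopifnot(inherits(env, "env_stack"))
  for (nm in c(names(species$optimum), names(species$cat_pref))) {
    if (!nm %in% names(env$layers)) {
      stop("environment lacks layer '", nm, "' required by species ", species$id)
    }
  }
  d <- dim(env$mask)
  a <- matrix(species$max_abundance, d[1L], d[2L])
  for (nm in names(species$optimum)) {
    x <- env$layers[[nm]]
    a <- a * exp(-(x - species$optimum[[nm]])^2 / (2 * species$breadth[[nm]]^2))
  }
  for (nm in names(species$cat_pref)) {
    mult <- species$cat_pref[[nm]]
    code <- as.character(env$layers[[nm]])
    m <- mult[code]
    m[is.na(m)] <- 0  # codes unseen at generation get zero preference
    a <- a * matrix(m, d[1L], d[2L])
  }
  a[!env$mask] <- NA_real_
  a
}

#' Sample occurrence records with abundance classes
#'
#' Sites are drawn without replacement from valid cells. At each sampled site a
#' species is recorded with probability equal to its normalized abundance
#' (abundance / its own maximum; `detection = "always"` records every species
#' with positive abundance). A recorded species gets an abundance class by
#' thresholding normalized abundance: `(0, t1]` = 1 (single), `(t1, t2]` = 2
#' (frequent), `(t2, 1]` = 3 (dominant).
#'
#' @param truths list of `species_truth`.
#' @param env an [env_stack()].
#' @param n_sites number of sites (<= number of valid cells).
#' @param class_thresholds numeric `(t1, t2)` with `0 < t1 < t2 < 1`.
#' @param detection `"proportional"` (default) or `"always"`.
#' @param seed integer seed.
#' @return a data.frame with columns `species_id`, `row`, `col`,
#'   `abundance_class`; class `occurrence_set`.
#' @export
sample_occurrences <- function(truths, env, n_sites,
                               class_thresholds = c(0.1, 0.5),
                               detection = c("proportional", "always"),
                               seed = 1) {
  stopifnot(inherits(env, "env_stack"))
  detection <- match.arg(detection)
  t1 <- class_thresholds[1L]; t2 <- class_thresholds[2L]
  if (!(t1 < t2)) stop("class thresholds must satisfy t1 < t2")
  vc <- valid_cells(env)
  if (n_sites > length(vc)) stop("n_sites exceeds number of valid cells")
  d <- dim(env$mask)

  with_seed(seed, {
    sites <- sort(sample(vc, n_sites))
    rows <- ((sites - 1L) %% d[1L]) + 1L
    cols <- ((sites - 1L) %/% d[1L]) + 1L
    recs <- lapply(truths, function(sp) {
      a <- true_abundance(sp, env)[sites] / sp$max_abundance
      det <- if (detection == "always") a > 0 else stats::runif(length(a)) < a
      det[is.na(det)] <- FALSE
      keep <- which(det & a > 0)
      if (!length(keep)) return(NULL)
      cls <- ifelse(a[keep] <= t1, 1L, ifelse(a[keep] <= t2, 2L, 3L))
      data.frame(species_id = sp$id, row = rows[keep], col = cols[keep],
                 abundance_class = cls, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, recs)
    if (is.null(out)) {
      out <- data.frame(species_id = character(0), row = integer(0),
                        col = integer(0), abundance_class = integer(0))
    }
    rownames(out) <- NULL
    class(out) <- c("occurrence_set", "data.frame")
    out
  })
}
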
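#' Default categorical trait assignment per plant functional group
#'
#' Categorical traits are assigned deterministically by functional group so the
#' expected categorical-profile behaviour has a known truth. Mosses carry no
#' trait values (excluded from community weighting). Hydrophyte traits (body
#' flexibility, space occupancy) are carried by herbaceous species here, the
#' group that contains the aquatic plants in the synthetic pools.
#'
#' @return data.frame keyed by `pfg` with columns `leaf_persistence`
#'   (evergreen/summergreen), `clonality` (nonclonal/tussock/rhizomatous) and
#'   `mycorrhiza` (none/facultative/obligatory).
#' @export
default_categorical_scheme <- function() {
  data.frame(
    pfg = c("moss", "pteridophyte", "graminoid", "herbaceous", "shrub", "tree"),
    leaf_persistence = c(NA, "summergreen", "summergreen", "summergreen",
                         "evergreen", "summergreen"),
    clonality = c(NA, "rhizomatous", "tussock", "nonclonal",
                  "nonclonal", "nonclonal"),
    mycorrhiza = c(NA, "none", "facultative", "obligatory",
                   "obligatory", "obligatory"),
    stringsAsFactors = FALSE
  )
}

#' Simulate a phylogeny over a species pool
#'
#' A random coalescent tree (via \pkg{ape}) with tips labelled by species id;
#' branch lengths rescaled so the mean root-to-tip depth is `depth`.
#'
#' @param species_ids character vector of tip labels (>= 2).
#' @param depth target mean root-to-tip path length.
#' @param seed integer seed.
#' @return an \pkg{ape} `phylo` object.
#' @export
simulate_phylogeny <- function(species_ids, depth = 1, seed = 1) {
  n <- length(species_ids)
  if (n < 2) stop("need at least 2 species")
  with_seed(seed, {
    tr <- ape::rcoal(n, tip.label = species_ids)
    dt <- mean(diag(ape::vcv.phylo(tr)))
    tr$edge.length <- tr$edge.length * depth / dt
    tr
  })
}

#' Simulate continuous traits under Brownian motion, with a missing mask
#'
#' Continuous traits evolve by Brownian motion on the tree: tip values are
#' multivariate normal with mean `root_state` and covariance `sigma2 * C`,
#' where `C[i, j]` is the shared root-to-MRCA path length. With
#' `log_scale = TRUE` the simulated values are exponentiated, giving
#' log-normal-ish size traits (specific leaf area, canopy height, root depth
#' are right-skewed in real floras). A fraction of entries, chosen uniformly at
#' random, is masked as missing. Categorical traits are attached per
#' functional group from `cat_scheme`.
#'
#' @param tree `phylo` with >= 2 tips.
#' @param traits character vector of continuous trait names.
#' @param sigma2 Brownian rate(s), recycled over traits (> 0).
#' @param root_state root value(s) on the simulation scale, recycled.
#' @param missing_fraction fraction of continuous entries masked, in `[0, 1)`.
#' @param log_scale exponentiate simulated values? (default TRUE)
#' @param pfg optional named character vector (species -> functional group)
#'   used to attach categorical traits.
#' @param cat_scheme categorical assignment table, see
#'   [default_categorical_scheme()].
#' @param seed integer seed.
#' @return data.frame with `species_id`, one column per continuous trait (NA =
#'   missing), and, when `pfg` is given, `pfg` plus categorical trait columns.
#' @export
simulate_traits <- function(tree, traits = c("SLA", "CH", "RD"),
                            sigma2 = 0.25, root_state = 0,
                            missing_fraction = 0.2, log_scale = TRUE,
                            pfg = NULL, cat_scheme = default_categorical_scheme(),
                            seed = 1) {
  if (length(tree$tip.label) < 2) stop("tree must have >= 2 tips")
  if (missing_fraction < 0 || missing_fraction >= 1) {
    stop("missing_fraction must be in [0, 1)")
  }
  sigma2 <- rep_len(sigma2, length(traits))
  if (any(sigma2 <= 0)) stop("sigma2 must be > 0")
  root_state <- rep_len(root_state, length(traits))

  C <- ape::vcv.phylo(tree)
  n <- nrow(C)
  L <- t(chol(C + diag(1e-10, n)))
  with_seed(seed, {
    X <- sapply(seq_along(traits), function(j) {
      x <- root_state[j] + sqrt(sigma2[j]) * as.vector(L %*% stats::rnorm(n))
      if (log_scale) exp(x) else x
    })
    X <- matrix(X, nrow = n, dimnames = list(rownames(C), traits))
    n_missing <- floor(missing_fraction * length(X))
    if (n_missing > 0) X[sample(length(X), n_missing)] <- NA_real_
    out <- data.frame(species_id = rownames(C), X, row.names = NULL,
                      stringsAsFactors = FALSE)
    if (!is.null(pfg)) {
      out$pfg <- unname(pfg[out$species_id])
      out <- merge(out, cat_scheme, by = "pfg", all.x = TRUE, sort = FALSE)
      out <- out[match(rownames(C), out$species_id),
                 c("species_id", traits, "pfg",
                   setdiff(names(cat_scheme), "pfg"))]
      rownames(out) <- NULL
    }
    out
  })
}
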
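#' Phylogenetic covariance matrix of a tree
#'
#' Under Brownian motion, the covariance of two tips is proportional to the
#' shared path length from the root to their most recent common ancestor;
#' `C[i, i]` is the root-to-tip distance. Computed with \pkg{ape}.
#'
#' @param tree an \pkg{ape} `phylo` with branch lengths.
#' @return symmetric positive semidefinite matrix, tips x tips.
#' @export
phylo_covariance <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths are not allowed")
  ape::vcv.phylo(tree)
}

#' Fit a univariate Brownian-motion model by maximum likelihood
#'
#' Closed-form GLS estimates on the observed tips: root state
#' `mu = (1' C^-1 x) / (1' C^-1 1)` and rate
#' `sigma2 = (x - mu)' C^-1 (x - mu) / n` (ML, not REML).
#'
#' @param x named numeric vector of trait values on observed tips (>= 2),
#'   names matching tip labels.
#' @param tree `phylo` containing all observed tips.
#' @return list `mu`, `sigma2`, `loglik`, `n`.
#' @export
fit_bm <- function(x, tree) {
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("need at least 2 observed tips")
  C <- phylo_covariance(tree)
  miss <- setdiff(names(x), rownames(C))
  if (length(miss)) stop("tips not in tree: ", paste(miss, collapse = ", "))
  Co <- C[names(x), names(x)]
  Ci <- solve(Co)
  one <- rep(1, length(x))
  mu <- as.numeric((one %*% Ci %*% x) / (one %*% Ci %*% one))
  r <- x - mu
  n <- length(x)
  sigma2 <- as.numeric(r %*% Ci %*% r) / n
  ll <- -0.5 * (n * log(2 * pi) + n * log(max(sigma2, .Machine$double.xmin)) +
                  determinant(Co)$modulus + n)
  list(mu = mu, sigma2 = sigma2, loglik = as.numeric(ll), n = n)
}

# Conditional BM expectation and variance for missing tips of one trait.
impute_one_trait <- function(x, C) {
  obs <- which(!is.na(x)); mis <- which(is.na(x))
  Co <- C[obs, obs, drop = FALSE]
  Ci <- solve(Co)
  one <- rep(1, length(obs))
  mu <- as.numeric((one %*% Ci %*% x[obs]) / (one %*% Ci %*% one))
  sigma2 <- as.numeric((x[obs] - mu) %*% Ci %*% (x[obs] - mu)) / length(obs)
  if (!length(mis)) {
    return(list(values = x, sd = rep(0, length(x)), mu = mu, sigma2 = sigma2))
  }
  Cmo <- C[mis, obs, drop = FALSE]
  Cmm <- C[mis, mis, drop = FALSE]
  mean_m <- mu + as.vector(Cmo %*% Ci %*% (x[obs] - mu))
  var_m <- sigma2 * pmax(diag(Cmm - Cmo %*% Ci %*% t(Cmo)), 0)
  out <- x
  out[mis] <- mean_m
  sdv <- rep(0, length(x))
  sdv[mis] <- sqrt(var_m)
  list(values = out, sd = sdv, mu = mu, sigma2 = sigma2)
}

#' Fill missing continuous trait values by Brownian-motion conditioning
#'
#' For each trait independently, a univariate Brownian-motion model is fitted
#' by ML on the observed tips ([fit_bm()]); missing tips are set to the
#' conditional expectation of the multivariate normal given the observed tips,
#' `E[x_m | x_o] = mu + C_mo C_oo^-1 (x_o - mu)`, with the conditional
#' standard deviation reported per imputed value. Observed values are returned
#' bit-identical. Traits named in `log_transform` are fitted on the log scale
#' and back-transformed (size traits are right-skewed). Categorical traits are
#' never imputed.
#'
#' @param traits data.frame with `species_id` and continuous trait columns
#'   (NA = missing).
#' @param tree `phylo` containing every species as a tip (extra tips allowed).
#' @param trait_cols columns to impute; default all numeric columns.
#' @param log_transform trait names fitted on the log scale; default
#'   `c("SLA", "CH", "RD")` intersected with `trait_cols`.
#' @return list: `traits` (completed data.frame), `report` (data.frame of
#'   species, trait, imputed value, conditional sd), `fits` (per-trait mu,
#'   sigma2 on the fitting scale).
#' @export
impute_traits <- function(traits, tree, trait_cols = NULL,
                          log_transform = c("SLA", "CH", "RD")) {
  if (is.null(trait_cols)) {
    trait_cols <- names(traits)[vapply(traits, is.numeric, logical(1))]
  }
  if (!"species_id" %in% names(traits)) stop("traits must have a species_id column")
  if (anyDuplicated(traits$species_id)) stop("duplicate species ids in trait table")
  C <- phylo_covariance(tree)
  absent <- setdiff(traits$species_id, rownames(C))
  if (length(absent)) stop("species missing from tree: ", paste(absent, collapse = ", "))
  C <- C[traits$species_id, traits$species_id]
  log_transform <- intersect(log_transform, trait_cols)

  report <- list(); fits <- list()
  out <- traits
  for (tc in trait_cols) {
    x <- traits[[tc]]
    n_obs <- sum(!is.na(x))
    if (n_obs == 0) stop("trait '", tc, "' has no observed values")
    if (n_obs < 2) stop("trait '", tc, "' needs >= 2 observed species")
    uselog <- tc %in% log_transform
    if (uselog && any(x <= 0, na.rm = TRUE)) {
      stop("trait '", tc, "' has non-positive values; cannot log-transform")
    }
    xf <- if (uselog) log(x) else x
    res <- impute_one_trait(xf, C)
    mis <- which(is.na(x))
    filled <- x
    if (length(mis)) {
      filled[mis] <- if (uselog) exp(res$values[mis]) else res$values[mis]
      report[[tc]] <- data.frame(
        species_id = traits$species_id[mis], trait = tc,
        value = filled[mis],
        conditional_sd = res$sd[mis],  # on the fitting (possibly log) scale
        stringsAsFactors = FALSE
      )
    }
    out[[tc]] <- filled
    fits[[tc]] <- list(mu = res$mu, sigma2 = res$sigma2, log_scale = uselog)
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(species_id = character(0), trait = character(0),
               value = numeric(0), conditional_sd = numeric(0))
  rownames(report) <- NULL
  list(traits = out, report = report, fits = fits)
}
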
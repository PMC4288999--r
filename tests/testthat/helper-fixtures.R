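# Shared fixtures: tiny deterministic grids and species built in code.

# 1-layer continuous stack from an explicit matrix
env_from_matrix <- function(m, name = "temp", climatic = TRUE) {
  env_stack(
    stats::setNames(list(m), name),
    kind = stats::setNames("continuous", name),
    climatic = stats::setNames(climatic, name)
  )
}

# two-layer (continuous + categorical) 4x4 stack with hand-set values
small_env <- function() {
  temp <- matrix(seq(0, 3, length.out = 16), 4, 4)
  soil <- matrix(rep(c(1, 1, 2, 2), each = 4), 4, 4)
  env_stack(
    list(temp = temp, soil = soil),
    kind = c(temp = "continuous", soil = "categorical"),
    climatic = c(temp = TRUE, soil = FALSE)
  )
}

# a species with a known Gaussian niche on the 'temp' layer only
niche_species <- function(opt = 0, breadth = 1, max_abundance = 10,
                          id = "spX", pfg = "graminoid") {
  structure(
    list(id = id,
         optimum = c(temp = opt), breadth = c(temp = breadth),
         cat_pref = list(), max_abundance = max_abundance,
         pfg = pfg, wetland = "fen"),
    class = "species_truth"
  )
}

# constant share matrices over a small grid
const_shares <- function(values, nr = 2, nc = 2) {
  lapply(values, function(v) matrix(v, nr, nc))
}

expect_all_equal <- function(x, y, tol = 1e-12) {
  expect_true(all(abs(x - y) < tol, na.rm = TRUE))
}
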
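# shared fixtures: all synthetic, built at test time

# noiseless deterministic generator for exactness checks
noiseless_preset <- function(taxon = "Olea") {
  taxon_preset(taxon, noise_sd = 0, scatter_sd = 0)
}

# a small uniform grid whose nodes include round wavenumbers, so band
# centres can sit exactly on grid points
coarse_grid <- function() grid_spec(1800, 400, 8)  # nodes 1800, 1600, ..., 400

# random centered regression problem
random_problem <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  list(Xc = scale(X, scale = FALSE), yc = y - mean(y), X = X, y = y)
}

# write a temporary CSV and return its path
tmp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
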
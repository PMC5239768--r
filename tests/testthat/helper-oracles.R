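# Independent brute-force oracles used to cross-check package statistics.
# These deliberately share no code with the implementation under test.

# all permutations of a vector (recursive; for tiny n only)
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# exact RTEI p-value by enumerating every edge/interior split of the pool
rtei_exact_p <- function(edge, interior) {
  pool <- c(edge, interior)
  n_e <- length(edge)
  obs <- (mean(edge) - mean(interior)) / (mean(edge) + mean(interior))
  splits <- utils::combn(length(pool), n_e)
  vals <- apply(splits, 2, function(ix) {
    e <- mean(pool[ix]); i <- mean(pool[-ix])
    (e - i) / (e + i)
  })
  mean(abs(vals) >= abs(obs) - 1e-12)
}

# direct double-loop Moran's I with inverse-distance row-standardized weights
moran_brute <- function(x, coords) {
  n <- length(x)
  z <- x - mean(x)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) W[i, j] <- 1 / sqrt(sum((coords[i, ] - coords[j, ])^2))
  }
  for (i in seq_len(n)) W[i, ] <- W[i, ] / sum(W[i, ])
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# exact two-sided Moran permutation p-value by enumerating all orderings
moran_exact_p <- function(x, coords) {
  n <- length(x)
  e_i <- -1 / (n - 1)
  obs <- moran_brute(x, coords)
  vals <- vapply(all_perms(seq_len(n)), function(p) moran_brute(x[p], coords), 0.0)
  mean(abs(vals - e_i) >= abs(obs - e_i) - 1e-12)
}

# default traits table for the default community model
default_traits <- function(model = community_model()) {
  extrapolate_mass(model$species[, c("species", "guild", "diel", "size_class",
                                     "length_mm", "width_mm", "mean_mass_g")])
}
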
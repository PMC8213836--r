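# Brute-force reference implementation of the saturation-binding rule,
# deliberately literal: explicit pairwise distance matrix, linear scans,
# one runif(1) draw per molecule. Consumes the RNG exactly like the
# package's optimized simulator, so under the same seed both must make
# identical decisions.
oracle_saturate <- function(anchors, reach, seed) {
  n <- nrow(anchors)
  d <- as.matrix(dist(anchors))
  free <- rep(2L, n)
  mols <- list()
  set.seed(seed)
  while (sum(free) > 0) {
    elig <- which(free > 0)
    k <- floor(runif(1) * length(elig))
    if (k >= length(elig)) k <- length(elig) - 1
    a <- elig[k + 1]
    free[a] <- free[a] - 1L
    cand <- setdiff(which(free > 0 & d[a, ] <= reach), a)
    if (length(cand) > 0) {
      b <- cand[which.min(d[a, cand])] # ties: first = lowest index
      free[b] <- free[b] - 1L
      mols[[length(mols) + 1]] <- c(a, b)
    } else {
      mols[[length(mols) + 1]] <- c(a, NA_integer_)
    }
  }
  do.call(rbind, mols)
}

# Canonical sorted bridge set (two-column matrix, a < b) for comparison.
bridge_set <- function(lever_a, lever_b) {
  keep <- !is.na(lever_b)
  m <- cbind(pmin(lever_a[keep], lever_b[keep]),
             pmax(lever_a[keep], lever_b[keep]))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# Build a lever_field directly from anchor coordinates (test fixture).
make_field <- function(anchors, in_radius_nm = 2.5) {
  structure(
    list(anchors = anchors, mean_distance_nm = NA_real_,
         occupancy_p = NA_real_, seed = NA_integer_,
         in_radius_nm = in_radius_nm, side_length_nm = NA_real_),
    class = "lever_field")
}

# Build a binding_state directly from a molecule table (test fixture).
make_state <- function(lever_a, lever_b, n_levers) {
  keep <- !is.na(lever_b)
  bridges <- cbind(lever_a = pmin(lever_a[keep], lever_b[keep]),
                   lever_b = pmax(lever_a[keep], lever_b[keep]))
  structure(
    list(molecules = data.frame(molecule_id = seq_along(lever_a),
                                lever_a = lever_a, lever_b = lever_b),
         bridges = bridges, free_sites = integer(n_levers),
         n_levers = n_levers, spec = NULL, seed = NA_integer_),
    class = "binding_state")
}
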
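# Shared fixtures, all built in code.

# Tiny 6x6x6 atlas with two 2x2x2 regions.
tiny_atlas <- function() {
  labels <- array(0L, dim = c(6, 6, 6))
  labels[2:3, 2:3, 2:3] <- 1L
  labels[4:5, 4:5, 4:5] <- 2L
  atlas_parcellation(labels, voxel_size_mm = 1.5)
}

const_image <- function(value = 0.5, shape = c(6, 6, 6), subject_id = "s1",
                        label = "NC") {
  tissue_image(array(value, dim = shape), subject_id = subject_id,
               label = label)
}

# Ground-truth 3-node network: chain z1 -> z2 given the class, z3 independent.
chain3_model <- function(q = 0.85, hi = 0.9, lo = 0.1) {
  st <- bn_structure(1:3, edges = data.frame(from = 1L, to = 2L))
  # node 2 has parent z1: configs (y,z1) = (-,-), (-,+), (+,-), (+,+)
  bn_model(st, prior_pos = 0.5, p1 = list(
    c(1 - q, q),
    c(lo, hi, lo, hi),
    c(1 - q, q)
  ))
}

# Random class-rooted model on m nodes with a random acyclic augmenting set.
random_model <- function(m, max_parents = 3L, p_edge = 0.4) {
  perm <- sample(m)
  adj <- matrix(FALSE, m, m)
  for (a in seq_len(m - 1)) for (b in (a + 1):m) {
    if (runif(1) < p_edge) adj[perm[a], perm[b]] <- TRUE
  }
  # enforce the parent cap by dropping surplus parents
  for (j in seq_len(m)) {
    pa <- which(adj[, j])
    if (length(pa) > max_parents) adj[sample(pa, length(pa) - max_parents), j] <- FALSE
  }
  st <- bn_structure(seq_len(m), edges = adj, max_parents = max_parents)
  p1 <- lapply(seq_len(m), function(j) {
    runif(2^(1 + sum(adj[, j])), min = 0.05, max = 0.95)
  })
  bn_model(st, prior_pos = runif(1, 0.2, 0.8), p1 = p1)
}

# All +/-1 configurations of length m, as a matrix with 2^m rows.
all_configs <- function(m) {
  as.matrix(expand.grid(rep(list(c(-1L, 1L)), m)))
}

# Small phantom configuration keeping unit tests fast; study-scale defaults
# stay in phantom_config().
small_phantom <- function(n = 80, seed = 1L, dependent = TRUE, n_mci = 0L,
                          shape = c(10L, 10L, 10L)) {
  if (dependent) {
    phantom_config(shape = shape, n_regions = 8L, n = n, n_mci = n_mci,
                   seed = seed)
  } else {
    phantom_config(shape = shape, n_regions = 8L, n = n, n_mci = n_mci,
                   affected = 1:8, dependency = NULL, p_root = 0.8,
                   seed = seed)
  }
}
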
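# Independent oracles and small fixture builders shared across the suite.

# Brute-force circular-environment enumerator, independent of the hashed
# implementation: for each atom and radius (while the ball still grows),
# extract the rooted ball subgraph and canonicalise it by exhaustive
# permutation with the root pinned first; count distinct canonical forms.
oracle_environment_count <- function(graph, radius = 2L) {
  A <- imrcat:::adjacency_matrix(graph)
  at <- graph$atoms
  n <- nrow(at)
  neighbours <- lapply(seq_len(n), function(a) which(A[a, ] > 0L))

  canon_ball <- function(root, members) {
    members <- setdiff(members, root)
    m <- length(members)
    perms <- if (m == 0L) list(integer(0)) else imrcat:::all_permutations(m)
    best <- NULL
    for (p in perms) {
      ord <- c(root, members[p])
      lab <- paste(at$hydrogen_count[ord], at$free_valence[ord],
                   collapse = ";")
      adj <- paste(A[ord, ord, drop = FALSE], collapse = ",")
      s <- paste(lab, adj, sep = "#")
      if (is.null(best) || s < best) best <- s
    }
    best
  }

  forms <- character(0)
  for (a in seq_len(n)) {
    ball <- a
    forms <- c(forms, canon_ball(a, ball))
    if (radius > 0L) for (r in seq_len(radius)) {
      nxt <- sort(unique(c(ball, unlist(neighbours[ball]))))
      if (length(nxt) == length(ball)) break
      ball <- nxt
      forms <- c(forms, canon_ball(a, ball))
    }
  }
  length(unique(forms))
}

# small deterministic multi-functional dataset for fast model tests
tiny_dataset <- function(n_species = 12L, seed = 7L, ensemble = 0L,
                         distortion = 0.1, noise = 0.05) {
  generate_synthetic_dataset(synthetic_config(
    n_species = n_species, ensemble_members = ensemble,
    distortion_scale = distortion, noise_sd = noise, seed = seed))
}

# quick training settings for tests that need a fitted Siamese model
fast_control <- function(epochs = 150L, seed = 1L)
  siamese_control(epochs = epochs, patience = 50L, seed = seed)
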
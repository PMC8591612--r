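# Independent oracles used by the test suite.  These deliberately avoid
# the package's own geometry helpers: distances are minimized over the 27
# explicit periodic image translations, and searches are plain loops.

# Minimum-image distance by enumeration over the 27 image translations.
oracle_pbc_distance <- function(p1, p2, box) {
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- p2 + c(i, j, k) * box - p1
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}

oracle_pbc_vector <- function(p1, p2, box) {
  best <- NULL; bd <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- p2 + c(i, j, k) * box - p1
    nd <- sqrt(sum(d^2))
    if (nd < bd) { bd <- nd; best <- d }
  }
  best
}

# O(N^2) hydrogen-bond search written independently of the package:
# donors is a matrix (heavy, h), acceptors an index vector.
oracle_hbonds <- function(coords, box, donors, acceptors,
                          molecule_id, max_dist = 0.35, max_ang = 30,
                          exclude_intra = TRUE) {
  found <- NULL
  for (di in seq_len(nrow(donors))) {
    d <- donors[di, 1]; h <- donors[di, 2]
    for (a in acceptors) {
      if (a == d) next
      if (exclude_intra && molecule_id[a] == molecule_id[d]) next
      dist <- oracle_pbc_distance(coords[d, ], coords[a, ], box)
      if (dist >= max_dist) next
      vh <- oracle_pbc_vector(coords[d, ], coords[h, ], box)
      va <- oracle_pbc_vector(coords[d, ], coords[a, ], box)
      ang <- acos(max(min(sum(vh * va) /
                            sqrt(sum(vh^2) * sum(va^2)), 1), -1)) * 180 / pi
      if (ang < max_ang) found <- rbind(found, c(d, h, a))
    }
  }
  found
}

# Random mixed box of water-like OH donors and lone-O acceptors for
# neighbor-search equivalence tests.
random_hbond_box <- function(n_donors, n_acceptors, box_edge, seed) {
  set.seed(seed)
  box <- rep(box_edge, 3)
  coords <- NULL; element <- character(0); mid <- integer(0)
  for (i in seq_len(n_donors)) {
    o <- runif(3) * box
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    coords <- rbind(coords, o, o + 0.096 * u)
    element <- c(element, "O", "H")
    mid <- c(mid, i, i)
  }
  for (j in seq_len(n_acceptors)) {
    coords <- rbind(coords, runif(3) * box)
    element <- c(element, "O")
    mid <- c(mid, n_donors + j)
  }
  molecular_configuration(coords, element, element, mid,
                          rep("x", length(mid)), box)
}
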
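# Independent oracles and fixture builders shared across the suite.

# Count the double-insertion space by exhaustive nested loops.
brute_force_insertion_count <- function(n, n_alphabet = 20) {
  cnt <- 0
  for (p1 in 1:(n + 1)) for (p2 in (p1 + 1):(n + 2)) cnt <- cnt + n_alphabet^2
  cnt
}

# Shannon entropy of a cluster-size partition, written independently of cce().
entropy_oracle <- function(sizes) {
  N <- sum(sizes)
  if (N <= 1 || length(sizes) == 1) return(0)
  p <- sizes / N
  -sum(p * log(p)) / log(N)
}

# Random partition of N atoms into 1..N positive parts.
random_partition <- function(N) {
  k <- sample.int(N, 1)
  if (k == 1) return(N)
  cuts <- sort(sample.int(N - 1, k - 1))
  diff(c(0, cuts, N))
}

# Apply a random rigid-body rotation + translation to a structure.
rigid_transform <- function(structure) {
  M <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  shift <- rnorm(3, sd = 10)
  xyz <- as.matrix(structure$atom[, c("x", "y", "z")]) %*% t(Q)
  structure$atom$x <- xyz[, 1] + shift[1]
  structure$atom$y <- xyz[, 2] + shift[2]
  structure$atom$z <- xyz[, 3] + shift[3]
  structure
}

# Rigid-cluster partition oracle for small frameworks, via the randomized
# rigidity-matrix rank: bodies u, v are mutually rigid iff a probe bar
# between them is dependent (rank unchanged); clusters are the transitive
# closure. Independent of the pebble-game implementation.
oracle_cluster_partition <- function(graph, seed = 1) {
  B <- graph$n_bodies
  base <- rigidity_matrix_rank(graph, n_placements = 3, seed = seed)
  same <- diag(TRUE, B)
  if (B > 1) {
    for (u in 1:(B - 1)) for (v in (u + 1):B) {
      probe <- rbind(graph$edges[, c("u", "v", "bars", "kind")],
                     data.frame(u = u, v = v, bars = 1L, kind = "probe"))
      r2 <- rigidity_matrix_rank(bbh_framework(B, probe),
                                 n_placements = 3, seed = seed + 37 * u + v)
      if (r2 == base) same[u, v] <- same[v, u] <- TRUE
    }
  }
  comp <- seq_len(B)
  repeat {
    changed <- FALSE
    for (u in seq_len(B)) for (v in seq_len(B)) {
      if (same[u, v] && comp[u] != comp[v]) {
        m <- min(comp[u], comp[v])
        comp[comp == comp[u] | comp == comp[v]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# Canonical labelling of a partition vector for comparisons.
canon_partition <- function(p) match(p, unique(p))

# Minimal hand-built structure: residues of selected atoms at given coords.
# `residues` is a list; each residue a named list of atom coordinate
# 3-vectors, with an optional ".resid" element (default "ALA").
toy_structure <- function(residues, helix = NULL, source = "toy") {
  rows <- list()
  serial <- 0L
  for (r in seq_along(residues)) {
    res <- residues[[r]]
    resid <- if (!is.null(res$.resid)) res$.resid else "ALA"
    res$.resid <- NULL
    for (nm in names(res)) {
      serial <- serial + 1L
      rows[[serial]] <- data.frame(
        serial = serial, name = nm,
        elem = if (grepl("^H", nm)) "H" else substr(nm, 1, 1),
        resno = r, resid = resid, chain = "A",
        x = res[[nm]][1], y = res[[nm]][2], z = res[[nm]][3])
    }
  }
  protein_structure(do.call(rbind, rows), helix = helix, source = source)
}
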
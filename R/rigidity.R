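# Body-bar-hinge mechanical model and (6,6) pebble game.
#
# Atoms joined by locked bonds (peptide, double/partial-double, rings,
# terminal atoms, hydrogens) merge into rigid bodies; rotatable covalent
# bonds become 5-bar hinges; hydrogen bonds contribute 5 bars and
# hydrophobic tethers 2 bars. Generic rigidity of such a 3D framework is
# combinatorial (Tay-Whiteley): a set of bars is independent iff every
# sub-multigraph on n' bodies uses at most 6 n' - 6 bars, which the (6,6)
# pebble game decides exactly. Rigid clusters are the maximal body sets
# spanned by (6,6)-tight subgraphs; for l = k = 6 two tight subgraphs that
# share a body merge into a tight one, so the clusters partition the bodies.

#' Construct a body-bar-hinge framework directly
#'
#' Low-level constructor used by the synthetic framework generator and by
#' tests; protein models are built with [build_mechanical_model()]. Each body
#' doubles as one "atom" so that cluster-size accounting works uniformly.
#'
#' @param n_bodies Number of rigid bodies (>= 1).
#' @param edges Data frame with columns `u`, `v` (body ids), `bars` (1..6)
#'   and optionally `kind`; parallel records are allowed and are processed
#'   separately (their bars are not pooled), so multigraphs with more than 6
#'   bars between one pair can be expressed.
#' @return A `bbh_graph` object.
#' @export
bbh_framework <- function(n_bodies, edges = NULL) {
  n_bodies <- as.integer(n_bodies)
  stopifnot(n_bodies >= 1)
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- data.frame(u = integer(0), v = integer(0), bars = integer(0),
                        kind = character(0))
  } else {
    edges <- as.data.frame(edges)
    if (!"kind" %in% names(edges)) edges$kind <- "bar"
    edges <- edges[, c("u", "v", "bars", "kind")]
    edges$u <- as.integer(edges$u)
    edges$v <- as.integer(edges$v)
    edges$bars <- as.integer(edges$bars)
    if (any(edges$u == edges$v)) stop("self-edges are not allowed")
    if (any(edges$u < 1 | edges$v < 1 | edges$u > n_bodies | edges$v > n_bodies))
      stop("edge endpoints out of range")
    if (any(edges$bars < 1 | edges$bars > 6))
      stop("bars per edge record must be in 1..6")
    swap <- edges$u > edges$v
    tmp <- edges$u[swap]; edges$u[swap] <- edges$v[swap]; edges$v[swap] <- tmp
  }
  structure(list(n_bodies = n_bodies, edges = edges,
                 body_of = seq_len(n_bodies),
                 n_atoms = n_bodies,
                 atom_label = as.character(seq_len(n_bodies))),
            class = "bbh_graph")
}

#' @export
print.bbh_graph <- function(x, ...) {
  cat("bbh_graph:", x$n_bodies, "bodies,", nrow(x$edges), "edge records,",
      sum(x$edges$bars), "bars,", x$n_atoms, "atoms\n")
  invisible(x)
}

#' Build the body-bar-hinge mechanical model of a structure
#'
#' Infers the covalent topology from residue templates ([covalent_bonds()]),
#' merges atoms joined by locked bonds into rigid bodies, adds rotatable
#' bonds as 5-bar hinge edges, and adds the supplied non-covalent
#' interactions with their bar multiplicities (hydrogen bond 5, hydrophobic
#' tether 2). Parallel edges between one body pair are summed and capped at
#' 6 bars; edges internal to a body are dropped. Atoms without any covalent
#' bond become isolated singleton bodies.
#'
#' @param structure A `protein_structure`.
#' @param interactions Data frame from [detect_interactions()] (columns `i`,
#'   `j`, `bars`, `kind`); computed from the structure when `NULL`.
#' @return A `bbh_graph`: fields `n_bodies`, `edges` (u, v, bars, kind),
#'   `body_of` (atom row -> body id), `n_atoms`.
#' @export
build_mechanical_model <- function(structure, interactions = NULL) {
  at <- structure$atom
  na <- nrow(at)
  bonds <- covalent_bonds(structure)
  if (is.null(interactions)) interactions <- detect_interactions(structure)
  if (NROW(interactions) > 0 &&
      (any(interactions$i < 1 | interactions$i > na) ||
       any(interactions$j < 1 | interactions$j > na)))
    stop("interaction references an unknown atom")

  # terminal heavy atoms and hydrogens carry no spin DOF: lock their bond
  deg <- tabulate(c(bonds$i, bonds$j), nbins = na)
  locked <- bonds$locked | deg[bonds$i] == 1 | deg[bonds$j] == 1 |
    at$elem[bonds$i] == "H" | at$elem[bonds$j] == "H"

  parent <- seq_len(na)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in which(locked)) {
    a <- find(bonds$i[k]); b <- find(bonds$j[k])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(na), find, integer(1))
  body_of <- match(root, unique(root))
  if (any(deg == 0) && na > 1)
    message(sum(deg == 0), " atom(s) without covalent bonds kept as isolated bodies")
  nb <- max(body_of)

  eu <- c(body_of[bonds$i[!locked]], if (NROW(interactions)) body_of[interactions$i])
  ev <- c(body_of[bonds$j[!locked]], if (NROW(interactions)) body_of[interactions$j])
  ebars <- c(rep.int(5L, sum(!locked)),
             if (NROW(interactions)) as.integer(interactions$bars))
  ekind <- c(rep.int("hinge", sum(!locked)),
             if (NROW(interactions)) as.character(interactions$kind))
  keep <- eu != ev
  eu <- eu[keep]; ev <- ev[keep]; ebars <- ebars[keep]; ekind <- ekind[keep]
  swap <- eu > ev
  tmp <- eu[swap]; eu[swap] <- ev[swap]; ev[swap] <- tmp
  edges <- if (length(eu)) {
    key <- paste(eu, ev)
    agg_bars <- tapply(ebars, key, function(b) min(6L, sum(b)))
    agg_kind <- tapply(ekind, key, function(k) paste(sort(unique(k)), collapse = "+"))
    uv <- do.call(rbind, strsplit(names(agg_bars), " "))
    e <- data.frame(u = as.integer(uv[, 1]), v = as.integer(uv[, 2]),
                    bars = as.integer(agg_bars), kind = as.character(agg_kind))
    e[order(e$u, e$v), , drop = FALSE]
  } else {
    data.frame(u = integer(0), v = integer(0), bars = integer(0),
               kind = character(0))
  }
  rownames(edges) <- NULL
  structure(list(n_bodies = nb, edges = edges, body_of = body_of,
                 n_atoms = na,
                 atom_label = paste0(at$resid, at$resno, ":", at$name)),
            class = "bbh_graph")
}

# --------------------------------------------------------------------------
# (6,6) pebble game.
#
# State: 6 pebbles per body; accepted bars are oriented edges. A bar (u,v)
# is independent iff >= 7 free pebbles can be gathered on {u,v} by pebble
# moves (reversing a directed path from u or v to a body holding a free
# pebble); accepting consumes one pebble from u. Rejected bars are redundant.
# --------------------------------------------------------------------------

#' Run the (6,6) pebble game on a body-bar-hinge graph
#'
#' Decides independence of every bar, counts redundant bars, and extracts
#' the rigid cluster decomposition (maximal body sets with no internal
#' relative degrees of freedom). Edge records are processed in a fixed
#' lexicographic order (u, v, kind), making the run deterministic; the
#' decomposition itself is a matroid invariant of the multigraph and does
#' not depend on processing order.
#'
#' @param graph A `bbh_graph`.
#' @return A `rigid_decomp` object: `cluster_of` (body -> cluster id),
#'   `clusters` (list of body-id vectors, decreasing size),
#'   `independent_edges`, `redundant_edges` (bar counts), `internal_dof`
#'   (`6 * n_bodies - independent_edges`; includes the 6 trivial rigid-body
#'   motions of each connected component), and `n_bodies`.
#' @export
#' @examples
#' g <- bbh_framework(2, data.frame(u = 1, v = 2, bars = 6))
#' pebble_game(g)$clusters
pebble_game <- function(graph) {
  stopifnot(inherits(graph, "bbh_graph"))
  B <- graph$n_bodies
  ed <- graph$edges
  if (nrow(ed)) ed <- ed[order(ed$u, ed$v, ed$kind), , drop = FALSE]

  pebbles <- rep.int(6L, B)
  adj <- vector("list", B)  # adj[[u]]: one entry per oriented accepted bar
  for (k in seq_len(B)) adj[[k]] <- integer(0)

  # Find a free pebble reachable from {u, v} along oriented bars; move it
  # back to u or v by reversing the path. Returns TRUE if a pebble moved.
  pull_pebble <- function(u, v) {
    visited <- logical(B)
    visited[c(u, v)] <- TRUE
    pred <- integer(B)
    stack <- c(v, u)  # explore from u first (deterministic)
    while (length(stack)) {
      x <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      for (y in sort(unique(adj[[x]]))) {
        if (visited[[y]]) next
        visited[[y]] <- TRUE
        pred[[y]] <- x
        if (pebbles[[y]] > 0L) {
          # reverse path y <- ... <- source
          node <- y
          while (pred[[node]] != 0L) {
            p <- pred[[node]]
            hit <- match(node, adj[[p]])
            adj[[p]] <<- adj[[p]][-hit]
            adj[[node]] <<- c(adj[[node]], p)
            node <- p
          }
          pebbles[[y]] <<- pebbles[[y]] - 1L
          pebbles[[node]] <<- pebbles[[node]] + 1L
          return(TRUE)
        }
        stack <- c(stack, y)
      }
    }
    FALSE
  }

  can_collect <- function(u, v, need = 7L) {
    while (pebbles[[u]] + pebbles[[v]] < need) {
      if (!pull_pebble(u, v)) return(FALSE)
    }
    TRUE
  }

  indep <- 0L; redund <- 0L
  for (k in seq_len(nrow(ed))) {
    u <- ed$u[k]; v <- ed$v[k]
    for (b in seq_len(ed$bars[k])) {
      if (can_collect(u, v, 7L)) {
        pebbles[[u]] <- pebbles[[u]] - 1L
        adj[[u]] <- c(adj[[u]], v)
        indep <- indep + 1L
      } else {
        redund <- redund + 1L
      }
    }
  }

  # Rigid clusters: adjacent bodies from which 7 free pebbles cannot be
  # gathered lie in a common (6,6)-tight subgraph; tight subgraphs are
  # connected, so unioning over adjacent pairs recovers every cluster.
  parent <- seq_len(B)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(ed)) {
    pairs <- unique(ed[, c("u", "v")])
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs$u[k]); b <- find(pairs$v[k])
      if (a == b) next
      if (!can_collect(pairs$u[k], pairs$v[k], 7L))
        parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(B), find, integer(1))
  cluster_of <- match(root, unique(root))
  clusters <- split(seq_len(B), cluster_of)
  clusters <- clusters[order(-lengths(clusters),
                             vapply(clusters, min, integer(1)))]
  names(clusters) <- NULL

  structure(list(cluster_of = cluster_of, clusters = clusters,
                 independent_edges = indep, redundant_edges = redund,
                 internal_dof = 6L * B - indep, n_bodies = B),
            class = "rigid_decomp")
}

#' @export
print.rigid_decomp <- function(x, ...) {
  cat("rigid_decomp:", x$n_bodies, "bodies in", length(x$clusters),
      "rigid clusters\n")
  cat("  independent bars:", x$independent_edges,
      " redundant:", x$redundant_edges,
      " DOF:", x$internal_dof, "\n")
  invisible(x)
}

#' Atom-level rigid clusters
#'
#' Expands a body-level decomposition to atom sets via the graph's atom-to-
#' body map, ordered by decreasing size. Cluster sizes always sum to the
#' total atom count.
#'
#' @param decomp A `rigid_decomp` produced from `graph`.
#' @param graph The `bbh_graph` the decomposition was computed on.
#' @return List of integer vectors of atom row indices.
#' @export
rigid_clusters_atoms <- function(decomp, graph) {
  stopifnot(inherits(decomp, "rigid_decomp"), inherits(graph, "bbh_graph"))
  if (decomp$n_bodies != graph$n_bodies)
    stop("decomposition does not match graph (body counts differ)")
  cl <- split(seq_len(graph$n_atoms), decomp$cluster_of[graph$body_of])
  cl <- cl[order(-lengths(cl), vapply(cl, min, integer(1)))]
  names(cl) <- NULL
  cl
}

#' Randomized rigidity-matrix rank of a framework
#'
#' Independent cross-check for the pebble game: instantiates the framework
#' generically (random body placements, each bar attached at its own random
#' points) and computes the rank of the 3D body-bar rigidity matrix, taking
#' the maximum over several placements to avoid accidental degeneracies.
#' For a generic framework this rank equals the pebble game's independent
#' bar count (Tay's theorem).
#'
#' @param graph A `bbh_graph`.
#' @param n_placements Number of random placements (default 3).
#' @param seed Optional integer seed for the placements.
#' @return Integer rank.
#' @export
rigidity_matrix_rank <- function(graph, n_placements = 3, seed = NULL) {
  stopifnot(inherits(graph, "bbh_graph"))
  if (!is.null(seed)) set.seed(seed)
  ed <- graph$edges
  total_bars <- sum(ed$bars)
  if (total_bars == 0) return(0L)
  B <- graph$n_bodies
  best <- 0L
  for (p in seq_len(n_placements)) {
    M <- matrix(0, nrow = total_bars, ncol = 6L * B)
    row <- 0L
    for (k in seq_len(nrow(ed))) {
      u <- ed$u[k]; v <- ed$v[k]
      for (b in seq_len(ed$bars[k])) {
        row <- row + 1L
        pu <- stats::rnorm(3); pv <- stats::rnorm(3)
        d <- pu - pv
        M[row, (6 * (u - 1) + 1):(6 * (u - 1) + 3)] <- d
        M[row, (6 * (u - 1) + 4):(6 * u)] <- cross3(pu, d)
        M[row, (6 * (v - 1) + 1):(6 * (v - 1) + 3)] <- -d
        M[row, (6 * (v - 1) + 4):(6 * v)] <- -cross3(pv, d)
      }
    }
    best <- max(best, qr(M)$rank)
  }
  as.integer(best)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
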
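# Synthetic polypeptide structures with ideal geometry.
#
# Backbones are grown atom by atom with the natural-extension reference
# frame (NeRF) construction from standard bond lengths (N-CA 1.458, CA-C
# 1.525, C-N 1.329, C=O 1.231, CA-CB 1.521, N-H 1.01 A) and angles; only the
# (phi, psi) dihedrals differ between the helix and the extended chain. The
# amide hydrogen is placed analytically in the peptide plane, anti to the
# carbonyl oxygen.

IDEAL_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.521, b_n_h = 1.01,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.8, a_c_n_h = 119.0, a_n_ca_cb = 110.5,
  t_n_c_ca_cb = 122.6   # improper fixing L-chirality
)

unit3 <- function(v) v / sqrt(sum(v^2))

# Place atom D bonded to C given reference atoms A-B-C, bond length r,
# bond angle theta = angle(B, C, D) and IUPAC torsion phi = torsion(A,B,C,D),
# both in degrees.
nerf_place <- function(A, B, C, r, theta, phi) {
  th <- theta * pi / 180
  ph <- -phi * pi / 180  # sign such that the realized IUPAC torsion is `phi`
  bc <- unit3(C - B)
  n <- unit3(cross3(B - A, bc))
  M <- cbind(bc, cross3(n, bc), n)
  as.numeric(C + M %*% (r * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))))
}

build_polyala <- function(n, phi, psi, omega = 180, helix = NULL,
                          source = "polyala") {
  g <- IDEAL_GEOM
  res <- vector("list", n)
  N <- c(0, 0, 0)
  CA <- c(g$b_n_ca, 0, 0)
  a <- g$a_n_ca_c * pi / 180
  C <- CA + g$b_ca_c * c(-cos(a), sin(a), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      prev <- res[[i - 1]]
      N <- nerf_place(prev$N, prev$CA, prev$C, g$b_c_n, g$a_ca_c_n, psi)
      CA <- nerf_place(prev$CA, prev$C, N, g$b_n_ca, g$a_c_n_ca, omega)
      C <- nerf_place(prev$C, N, CA, g$b_ca_c, g$a_n_ca_c, phi)
    }
    O <- nerf_place(N, CA, C, g$b_c_o, g$a_ca_c_o, psi + 180)
    CB <- nerf_place(N, C, CA, g$b_ca_cb, g$a_n_ca_cb, g$t_n_c_ca_cb)
    H <- if (i > 1)
      nerf_place(res[[i - 1]]$O, res[[i - 1]]$C, N, g$b_n_h, g$a_c_n_h, 180)
    else NULL
    res[[i]] <- list(N = N, CA = CA, C = C, O = O, CB = CB, H = H)
  }
  rows <- list()
  serial <- 0L
  for (i in seq_len(n)) {
    for (nm in c("N", "CA", "C", "O", "CB", "H")) {
      p <- res[[i]][[nm]]
      if (is.null(p)) next
      serial <- serial + 1L
      rows[[serial]] <- data.frame(
        serial = serial, name = nm,
        elem = if (nm == "H") "H" else substr(nm, 1, 1),
        resno = i, resid = "ALA", chain = "A",
        x = round(p[1], 3), y = round(p[2], 3), z = round(p[3], 3))
    }
  }
  protein_structure(do.call(rbind, rows), helix = helix, source = source)
}

#' Ideal alpha-helical poly-alanine structure
#'
#' Poly-alanine backbone with ideal helix dihedrals (phi = -57, psi = -47
#' degrees), explicit amide hydrogens, and a HELIX annotation spanning the
#' whole chain. The canonical i -> i-4 backbone hydrogen bond ladder emerges
#' from the geometry: for n residues, [detect_hbonds()] finds max(n - 4, 0)
#' backbone bonds.
#'
#' @param n Residue count (>= 1).
#' @return A `protein_structure`.
#' @export
#' @examples
#' hbond_count(ideal_helix_structure(12))  # 8
ideal_helix_structure <- function(n) {
  stopifnot(length(n) == 1, n >= 1)
  build_polyala(n, phi = -57, psi = -47,
                helix = data.frame(start = 1L, end = as.integer(n)),
                source = sprintf("ideal_helix_%d", n))
}

#' Extended-chain poly-alanine structure
#'
#' Poly-alanine with extended dihedrals (phi = -120, psi = 120 degrees) and
#' no helix annotation; its geometry supports no backbone hydrogen bonds.
#'
#' @param n Residue count (>= 1).
#' @return A `protein_structure`.
#' @export
#' @examples
#' hbond_count(extended_chain_structure(12))  # 0
extended_chain_structure <- function(n) {
  stopifnot(length(n) == 1, n >= 1)
  build_polyala(n, phi = -120, psi = 120, helix = NULL,
                source = sprintf("extended_chain_%d", n))
}

#' Random body-bar framework
#'
#' Reproducible random multigraph over `n_bodies` bodies with bar counts in
#' 1..6 per edge record, used as pebble-game oracle fixtures.
#'
#' @param n_bodies Number of bodies (>= 1).
#' @param n_edges Number of edge records to draw (default `2 * n_bodies`);
#'   parallel records may repeat a body pair, so more than 6 bars can join
#'   one pair.
#' @param seed Optional integer seed; fixing it fixes the graph.
#' @return A `bbh_graph`.
#' @export
#' @examples
#' g <- random_framework(5, 8, seed = 1)
random_framework <- function(n_bodies, n_edges = 2 * n_bodies, seed = NULL) {
  stopifnot(n_bodies >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (n_bodies < 2 || n_edges == 0) return(bbh_framework(n_bodies))
  u <- sample.int(n_bodies, n_edges, replace = TRUE)
  v <- sample.int(n_bodies - 1L, n_edges, replace = TRUE)
  v <- ifelse(v >= u, v + 1L, v)
  bbh_framework(n_bodies, data.frame(u = u, v = v,
                                     bars = sample.int(6L, n_edges,
                                                       replace = TRUE)))
}
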
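# Stabilizing-interaction detection: hydrogen bonds and hydrophobic tethers.
#
# Criteria are geometric (distance + angle), with implicit-hydrogen donor
# typing from residue templates so unprotonated PDB files work. Bar
# multiplicities attached here parameterize the body-bar-hinge model:
# hydrogen bond -> 5 bars, hydrophobic tether -> 2 bars.

HBOND_BARS <- 5L
HYDROPHOBIC_BARS <- 2L
VDW_RADII <- c(C = 1.7, S = 1.8)

#' Covalent bond list of a structure
#'
#' Infers the covalent topology from residue templates: shared backbone bonds
#' (N-CA and CA-C rotatable; C-O, C-OXT locked), side-chain bonds with
#' ring/partial-double bonds locked, inter-residue peptide bonds (locked),
#' disulfide bridges (SG-SG within 2.3 A, rotatable), and hydrogens attached
#' to their nearest heavy atom in the same residue (locked). Bonds whose atoms
#' are absent from the file are skipped; peptide bonds across chain breaks
#' (C-N beyond 2.5 A) are skipped with a message.
#'
#' @param structure A `protein_structure`.
#' @return Data frame with columns `i`, `j` (row indices into
#'   `structure$atom`) and `locked` (logical: TRUE merges the two atoms into
#'   one rigid body, FALSE is a rotatable 5-bar hinge).
#' @export
covalent_bonds <- function(structure) {
  at <- structure$atom
  idx_of <- function(resno, name) {
    which(at$resno == resno & at$name == name)[1]
  }
  ii <- integer(0); jj <- integer(0); ll <- logical(0)
  add <- function(i, j, locked) {
    if (!is.na(i) && !is.na(j)) {
      ii[[length(ii) + 1L]] <<- i
      jj[[length(jj) + 1L]] <<- j
      ll[[length(ll) + 1L]] <<- locked
    }
  }
  for (r in seq_len(structure$n)) {
    rows <- which(at$resno == r)
    resid <- at$resid[rows[1]]
    tpl <- RESIDUE_TEMPLATES[[resid]]
    pro <- identical(resid, "PRO")
    # backbone (proline's N-CA and CA-CB are in its locked ring template)
    if (!pro) {
      add(idx_of(r, "N"), idx_of(r, "CA"), FALSE)
      add(idx_of(r, "CA"), idx_of(r, "CB"), FALSE)
    }
    add(idx_of(r, "CA"), idx_of(r, "C"), FALSE)
    add(idx_of(r, "C"), idx_of(r, "O"), TRUE)
    add(idx_of(r, "C"), idx_of(r, "OXT"), TRUE)
    if (!is.null(tpl)) {
      for (b in tpl$bonds) add(idx_of(r, b$a), idx_of(r, b$b), b$locked)
    }
    # hydrogens: attach to the nearest heavy atom of the same residue
    hrows <- rows[at$elem[rows] == "H"]
    heavy <- rows[at$elem[rows] != "H"]
    for (h in hrows) {
      d2 <- (at$x[heavy] - at$x[h])^2 + (at$y[heavy] - at$y[h])^2 +
            (at$z[heavy] - at$z[h])^2
      k <- heavy[which.min(d2)]
      if (min(d2) <= 1.5^2) add(k, h, TRUE)
    }
    # peptide bond to the next residue
    if (r < structure$n) {
      ci <- idx_of(r, "C"); ni <- idx_of(r + 1, "N")
      if (!is.na(ci) && !is.na(ni)) {
        d <- sqrt((at$x[ci] - at$x[ni])^2 + (at$y[ci] - at$y[ni])^2 +
                  (at$z[ci] - at$z[ni])^2)
        if (d <= 2.5) add(ci, ni, TRUE)
        else message("chain break between residues ", r, " and ", r + 1)
      }
    }
  }
  # disulfides
  sg <- which(at$name == "SG")
  if (length(sg) > 1) {
    for (a in seq_along(sg)[-length(sg)]) for (b in (a + 1):length(sg)) {
      i <- sg[a]; j <- sg[b]
      d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                (at$z[i] - at$z[j])^2)
      if (d <= 2.3) add(i, j, FALSE)
    }
  }
  data.frame(i = ii, j = jj, locked = ll)
}

# Adjacency list (atom index -> integer vector of covalent neighbours).
covalent_adjacency <- function(n_atoms, bonds) {
  adj <- vector("list", n_atoms)
  for (k in seq_len(n_atoms)) adj[[k]] <- integer(0)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# Covalent separation between atoms i and j, counted in bonds, capped at
# `cap` (returns cap + 1 when farther or disconnected).
bond_separation <- function(adj, i, j, cap = 4L) {
  if (i == j) return(0L)
  frontier <- i
  seen <- i
  for (d in seq_len(cap)) {
    frontier <- unique(unlist(adj[frontier], use.names = FALSE))
    frontier <- setdiff(frontier, seen)
    if (j %in% frontier) return(d)
    if (length(frontier) == 0) break
    seen <- c(seen, frontier)
  }
  cap + 1L
}

donor_acceptor_typing <- function(structure) {
  at <- structure$atom
  donor <- logical(nrow(at)); acceptor <- logical(nrow(at))
  for (k in seq_len(nrow(at))) {
    tpl <- RESIDUE_TEMPLATES[[at$resid[k]]]
    nm <- at$name[k]
    if (nm == "N" && !identical(at$resid[k], "PRO")) donor[k] <- TRUE
    if (nm %in% c("O", "OXT")) acceptor[k] <- TRUE
    if (!is.null(tpl)) {
      if (nm %in% tpl$donors) donor[k] <- TRUE
      if (nm %in% tpl$acceptors) acceptor[k] <- TRUE
    }
  }
  list(donor = donor, acceptor = acceptor)
}

vec_angle <- function(xyz, a, b, c) {
  # angle at b (degrees) between a and c
  v1 <- xyz[a, ] - xyz[b, ]
  v2 <- xyz[c, ] - xyz[b, ]
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Detect hydrogen bonds geometrically
#'
#' A donor-acceptor pair (D, A) is a hydrogen bond when: D is an N/O/S atom
#' typed as a donor by the residue templates (backbone amide N of every
#' non-proline residue plus side-chain donors); A is an N/O/S template
#' acceptor; the heavy-atom distance |D-A| does not exceed `dist_cutoff`;
#' and the geometry is hydrogen-compatible - if D carries an explicit
#' hydrogen, some D-H...A angle is at least `h_angle` degrees, otherwise
#' every covalent heavy neighbour B of D must satisfy angle(B-D...A) of at
#' least `antecedent_angle` degrees. Covalently bonded and 1-3 pairs are
#' excluded; each (D, A) pair is reported once.
#'
#' @param structure A `protein_structure`.
#' @param dist_cutoff Donor-acceptor heavy-atom distance cutoff in Angstroms
#'   (default 3.5).
#' @param h_angle Minimum D-H...A angle in degrees when an explicit hydrogen
#'   is present (default 120).
#' @param antecedent_angle Minimum antecedent-D...A angle in degrees for the
#'   implicit-hydrogen route (default 90).
#' @return Data frame of interactions: `kind` (`"hbond"`), `i` (donor row),
#'   `j` (acceptor row), `dist`, `bars`.
#' @export
#' @examples
#' hb <- detect_hbonds(ideal_helix_structure(12))
#' nrow(hb)  # 8: backbone N(i) -> O(i-4) for i = 5..12
detect_hbonds <- function(structure, dist_cutoff = 3.5, h_angle = 120,
                          antecedent_angle = 90) {
  at <- structure$atom
  xyz <- as.matrix(at[, c("x", "y", "z")])
  typ <- donor_acceptor_typing(structure)
  don <- which(typ$donor & at$elem %in% c("N", "O", "S"))
  acc <- which(typ$acceptor & at$elem %in% c("N", "O", "S"))
  empty <- data.frame(kind = character(0), i = integer(0), j = integer(0),
                      dist = numeric(0), bars = integer(0))
  if (length(don) == 0 || length(acc) == 0) return(empty)

  bonds <- covalent_bonds(structure)
  adj <- covalent_adjacency(nrow(at), bonds)

  out_i <- integer(0); out_j <- integer(0); out_d <- numeric(0)
  for (d in don) {
    dd <- sqrt(colSums((t(xyz[acc, , drop = FALSE]) - xyz[d, ])^2))
    cand <- acc[dd <= dist_cutoff]
    cdist <- dd[dd <= dist_cutoff]
    if (length(cand) == 0) next
    hyd <- adj[[d]][at$elem[adj[[d]]] == "H"]
    heavy_nb <- adj[[d]][at$elem[adj[[d]]] != "H"]
    for (t in seq_along(cand)) {
      a <- cand[t]
      if (a == d) next
      if (bond_separation(adj, d, a, cap = 2L) <= 2L) next
      ok <- if (length(hyd) > 0) {
        any(vapply(hyd, function(h) vec_angle(xyz, d, h, a) >= h_angle,
                   logical(1)))
      } else if (length(heavy_nb) > 0) {
        all(vapply(heavy_nb, function(b) vec_angle(xyz, b, d, a) >=
                     antecedent_angle, logical(1)))
      } else TRUE
      if (ok) {
        out_i <- c(out_i, d); out_j <- c(out_j, a); out_d <- c(out_d, cdist[t])
      }
    }
  }
  if (length(out_i) == 0) return(empty)
  data.frame(kind = "hbond", i = out_i, j = out_j, dist = out_d,
             bars = HBOND_BARS)
}

#' Hydrogen bond count (HBC)
#'
#' Number of hydrogen bonds detected in a structure; used as an indirect
#' stability measure (more hydrogen bonds, more stable).
#'
#' @inheritParams detect_hbonds
#' @return Non-negative integer.
#' @export
hbond_count <- function(structure, dist_cutoff = 3.5, h_angle = 120,
                        antecedent_angle = 90) {
  nrow(detect_hbonds(structure, dist_cutoff, h_angle, antecedent_angle))
}

#' Detect hydrophobic tethers
#'
#' Pairs of carbon or sulfur atoms from different residues whose distance is
#' at most the sum of their van der Waals radii (C 1.7 A, S 1.8 A) plus
#' `slack`. Pairs closer than 4 covalent bonds are excluded: near-covalent
#' carbon pairs (e.g. backbone 1-3 and 1-4 neighbours at 2.4-3.0 A) reflect
#' bonded geometry, not hydrophobic contact.
#'
#' @param structure A `protein_structure`.
#' @param slack Distance slack added to the radii sum, in Angstroms
#'   (default 0.25).
#' @return Data frame of interactions: `kind` (`"hydrophobic"`), `i`, `j`,
#'   `dist`, `bars`.
#' @export
detect_hydrophobics <- function(structure, slack = 0.25) {
  at <- structure$atom
  xyz <- as.matrix(at[, c("x", "y", "z")])
  hp <- which(at$elem %in% names(VDW_RADII))
  empty <- data.frame(kind = character(0), i = integer(0), j = integer(0),
                      dist = numeric(0), bars = integer(0))
  if (length(hp) < 2) return(empty)
  bonds <- covalent_bonds(structure)
  adj <- covalent_adjacency(nrow(at), bonds)
  rad <- VDW_RADII[at$elem[hp]]
  out_i <- integer(0); out_j <- integer(0); out_d <- numeric(0)
  for (a in seq_along(hp)[-length(hp)]) {
    i <- hp[a]
    rest <- hp[(a + 1):length(hp)]
    dd <- sqrt(colSums((t(xyz[rest, , drop = FALSE]) - xyz[i, ])^2))
    cut <- rad[a] + rad[(a + 1):length(hp)] + slack
    sel <- which(dd <= cut & at$resno[rest] != at$resno[i])
    for (s in sel) {
      j <- rest[s]
      if (bond_separation(adj, i, j, cap = 3L) <= 3L) next
      out_i <- c(out_i, i); out_j <- c(out_j, j); out_d <- c(out_d, dd[s])
    }
  }
  if (length(out_i) == 0) return(empty)
  data.frame(kind = "hydrophobic", i = out_i, j = out_j, dist = out_d,
             bars = HYDROPHOBIC_BARS)
}

#' All stabilizing interactions of a structure
#'
#' Convenience wrapper returning hydrogen bonds and hydrophobic tethers in
#' one table, the non-covalent input to [build_mechanical_model()].
#'
#' @inheritParams detect_hbonds
#' @param slack Hydrophobic distance slack (see [detect_hydrophobics()]).
#' @return Data frame with columns `kind`, `i`, `j`, `dist`, `bars`.
#' @export
detect_interactions <- function(structure, dist_cutoff = 3.5, h_angle = 120,
                                antecedent_angle = 90, slack = 0.25) {
  rbind(detect_hbonds(structure, dist_cutoff, h_angle, antecedent_angle),
        detect_hydrophobics(structure, slack))
}
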
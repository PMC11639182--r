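# Per-mutant stability/flexibility metrics: HBC, CCE, ROP.

#' Cluster configuration entropy (CCE)
#'
#' Shannon entropy of the rigid-cluster size distribution, normalized to
#' [0, 1]: `H = -sum((s/N) * log(s/N)) / log(N)` where `s` are cluster sizes
#' and `N` their total. 0 means one rigid cluster (maximally stable); 1 means
#' all singletons (maximally fragmented/flexible). Defined as 0 when `N = 1`.
#'
#' @param cluster_sizes Vector of positive integers.
#' @return Value in [0, 1].
#' @export
#' @examples
#' cce(c(2, 2))   # 0.5
#' cce(10)        # 0
#' cce(rep(1, 8)) # 1
cce <- function(cluster_sizes) {
  s <- as.numeric(cluster_sizes)
  if (length(s) == 0 || any(!is.finite(s)) || any(s <= 0))
    stop("cluster sizes must be positive")
  N <- sum(s)
  if (N <= 1 || length(s) == 1) return(0)
  p <- s / N
  h <- -sum(p * log(p)) / log(N)
  min(1, max(0, h))
}

#' Rigidity order parameter (ROP)
#'
#' Fraction of atoms in the largest rigid cluster, in (0, 1]. Higher values
#' mean a larger dominant rigid cluster, correlated with greater stability.
#'
#' @param cluster_sizes Vector of positive integers.
#' @return Value in (0, 1].
#' @export
#' @examples
#' rop(c(6, 4))  # 0.6
rop <- function(cluster_sizes) {
  s <- as.numeric(cluster_sizes)
  if (length(s) == 0 || any(!is.finite(s)) || any(s <= 0))
    stop("cluster sizes must be positive")
  max(s) / sum(s)
}

#' Compute the full metric record of a structure
#'
#' Runs the pipeline interactions -> mechanical model -> pebble game ->
#' atom-level clusters and reports the three per-mutant metrics.
#'
#' @param structure A `protein_structure`.
#' @param ... Cutoff arguments forwarded to [detect_interactions()].
#' @return One-row data frame: `mutant_id` (the structure's source id),
#'   `hbc`, `cce`, `rop`, `n_atoms`.
#' @export
#' @examples
#' metric_record(ideal_helix_structure(8))
metric_record <- function(structure, ...) {
  ints <- detect_interactions(structure, ...)
  g <- build_mechanical_model(structure, ints)
  d <- pebble_game(g)
  sizes <- lengths(rigid_clusters_atoms(d, g))
  data.frame(mutant_id = structure$source,
             hbc = sum(ints$kind == "hbond"),
             cce = cce(sizes),
             rop = rop(sizes),
             n_atoms = nrow(structure$atom))
}
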
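# Exhaustive double-insertion mutant space: counting, enumeration, annotation.
#
# Coordinates: the two inserted residues are located by their positions in the
# elongated (n+2)-residue sequence, 1-based, pos1 < pos2. Mapping back to
# wildtype insertion gaps: gap1 = pos1 - 1, gap2 = pos2 - 2. Adjacent
# positions (pos2 = pos1 + 1) are two insertions at the same wildtype gap.

#' Count the exhaustive double-insertion mutant space
#'
#' For a protein of `n` residues there are `choose(n + 2, 2)` ways to place
#' two inserted residues in the elongated (n+2)-long sequence and `20^2`
#' ordered residue-type choices, giving `choose(n + 2, 2) * 400` distinct
#' mutants.
#'
#' @param n_residues Wildtype residue count (>= 1); vectorized.
#' @return Number of distinct double-insertion mutants.
#' @export
#' @examples
#' count_double_insertions(46)   # 451200
#' count_double_insertions(99)   # 2020000
count_double_insertions <- function(n_residues) {
  n_residues <- as.numeric(n_residues)
  if (any(!is.finite(n_residues)) || any(n_residues < 1) ||
      any(n_residues != floor(n_residues)))
    stop("n_residues must be an integer >= 1")
  choose(n_residues + 2, 2) * 400
}

#' Enumerate the double-insertion mutant space
#'
#' Produces every double-insertion mutant exactly once in deterministic
#' lexicographic order over (pos1, pos2, aa1, aa2). The first mutant for the
#' full alphabet is always (1, 2, "A", "A").
#'
#' @param n_residues Wildtype residue count.
#' @param alphabet Inserted residue alphabet (1-letter codes); defaults to the
#'   20 standard amino acids.
#' @param limit Optional cap on the number of rows returned (head of the
#'   stream), for piloting on large spaces.
#' @return Data frame with columns `mutant_id`, `pos1`, `pos2`, `aa1`, `aa2`,
#'   `gap1`, `gap2`.
#' @export
#' @examples
#' enumerate_double_insertions(1, alphabet = "A")
enumerate_double_insertions <- function(n_residues, alphabet = standard_aa(),
                                        limit = NULL) {
  if (length(n_residues) != 1 || n_residues < 1)
    stop("n_residues must be a single integer >= 1")
  alphabet <- sort(unique(as.character(alphabet)))
  if (length(alphabet) == 0) stop("alphabet must be non-empty")
  bad <- setdiff(alphabet, standard_aa())
  if (length(bad)) stop("non-standard residue code(s): ", paste(bad, collapse = ","))
  np <- as.integer(n_residues) + 2L
  pr <- t(utils::combn(np, 2L))  # lexicographic (pos1, pos2)
  k <- length(alphabet)
  pos1 <- rep(pr[, 1], each = k * k)
  pos2 <- rep(pr[, 2], each = k * k)
  aa1 <- rep(rep(alphabet, each = k), times = nrow(pr))
  aa2 <- rep(alphabet, times = nrow(pr) * k)
  df <- data.frame(pos1 = pos1, pos2 = pos2, aa1 = aa1, aa2 = aa2)
  if (!is.null(limit)) df <- utils::head(df, limit)
  df$gap1 <- df$pos1 - 1L
  df$gap2 <- df$pos2 - 2L
  df <- df[, c("pos1", "pos2", "aa1", "aa2", "gap1", "gap2")]
  df <- cbind(mutant_id = mutant_id(df$pos1, df$aa1, df$pos2, df$aa2), df)
  df
}

#' Mutant identifier string
#'
#' Join key used across all tables: `"{pos1}{aa1}_{pos2}{aa2}"`, e.g.
#' `"12P_40W"`.
#'
#' @param pos1,aa1,pos2,aa2 Vectors describing the two insertions.
#' @return Character vector.
#' @export
mutant_id <- function(pos1, aa1, pos2, aa2) {
  paste0(pos1, aa1, "_", pos2, aa2)
}

#' Volume size class of an amino acid
#'
#' @param aa Vector of 1-letter codes.
#' @return Character vector of class labels in VS/S/M/L/VL.
#' @export
#' @examples
#' size_class_of(c("G", "W"))
size_class_of <- function(aa) {
  aa <- as.character(aa)
  out <- AA_SIZE_CLASS[aa]
  if (anyNA(out)) stop("non-standard residue code(s): ",
                       paste(unique(aa[is.na(out)]), collapse = ","))
  unname(out)
}

#' Size group of an inserted residue pair
#'
#' The unordered pair of volume classes of the two inserted residues.
#' Homogeneous pairs carry the compact labels `VSVS`, `SS`, `MM`, `LL`,
#' `VLVL`; mixed pairs are labelled `"<smaller>-<larger>"` (e.g. `"VS-VL"`).
#'
#' @param aa1,aa2 Vectors of inserted 1-letter codes.
#' @return Character vector of pair labels.
#' @export
#' @examples
#' pair_size_group("G", "A")  # "VSVS"
#' pair_size_group("G", "W")  # "VS-VL"
pair_size_group <- function(aa1, aa2) {
  c1 <- size_class_of(aa1)
  c2 <- size_class_of(aa2)
  i1 <- match(c1, SIZE_ORDER)
  i2 <- match(c2, SIZE_ORDER)
  lo <- SIZE_ORDER[pmin(i1, i2)]
  hi <- SIZE_ORDER[pmax(i1, i2)]
  ifelse(lo == hi, paste0(lo, hi), paste(lo, hi, sep = "-"))
}

#' Alpha-helix group of a double insertion
#'
#' Maps the elongated-sequence positions back to wildtype gaps
#' (`gap1 = pos1 - 1`, `gap2 = pos2 - 2`, each independent of the other
#' insertion), tests each gap with [gap_in_helix()], and classifies by the
#' number of helix hits: `I_XX` (none), `I_XH` (one), `I_HH` (both).
#'
#' @param pos1,pos2 Elongated-sequence positions, `1 <= pos1 < pos2 <= n + 2`;
#'   vectorized.
#' @param structure A `protein_structure` providing `n` and helix ranges.
#' @return Character vector in `{"I_XX", "I_XH", "I_HH"}`.
#' @export
helix_group_of <- function(pos1, pos2, structure) {
  n <- structure$n
  if (any(pos1 < 1 | pos2 > n + 2 | pos1 >= pos2))
    stop("positions must satisfy 1 <= pos1 < pos2 <= n + 2")
  hits <- gap_in_helix(structure, pos1 - 1L) + gap_in_helix(structure, pos2 - 2L)
  c("I_XX", "I_XH", "I_HH")[hits + 1L]
}

#' Annotate enumerated mutants with size and helix groups
#'
#' @param mutants Data frame from [enumerate_double_insertions()].
#' @param structure A `protein_structure` supplying helix annotations (its
#'   residue count must equal the `n` the mutants were enumerated for).
#' @return The input with `size_group` and `helix_group` columns appended.
#' @export
annotate_mutants <- function(mutants, structure) {
  stopifnot(all(c("pos1", "pos2", "aa1", "aa2") %in% names(mutants)))
  if (max(mutants$pos2) > structure$n + 2)
    stop("mutant positions exceed structure length + 2")
  mutants$size_group <- pair_size_group(mutants$aa1, mutants$aa2)
  mutants$helix_group <- helix_group_of(mutants$pos1, mutants$pos2, structure)
  mutants
}
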
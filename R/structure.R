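# Protein structure representation and PDB input/output.
#
# A protein_structure holds one chain of one model: an atom table (one row per
# atom), alpha-helix ranges in 1..n residue numbering, and a source id. All
# downstream stages (interactions, rigidity, metrics) consume this object.

#' Construct a protein structure object
#'
#' Low-level constructor. Most users will obtain structures from [read_pdb()],
#' [ideal_helix_structure()] or [extended_chain_structure()].
#'
#' @param atom Data frame with columns `serial`, `name`, `elem`, `resno`
#'   (1-based residue index), `resid` (3-letter residue code), `chain`,
#'   `x`, `y`, `z`.
#' @param helix Data frame (or 2-column matrix) of inclusive residue ranges
#'   `start`, `end` annotated as alpha helices; may have zero rows.
#' @param source Character identifier for the structure.
#' @return An object of class `protein_structure` with fields `atom`, `helix`,
#'   `source` and `n` (residue count).
#' @export
protein_structure <- function(atom, helix = NULL, source = "structure") {
  stopifnot(is.data.frame(atom), nrow(atom) >= 1)
  need <- c("serial", "name", "elem", "resno", "resid", "chain", "x", "y", "z")
  miss <- setdiff(need, names(atom))
  if (length(miss)) stop("atom table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(atom$serial)) stop("atom serial numbers must be unique")
  if (!all(is.finite(atom$x)) || !all(is.finite(atom$y)) || !all(is.finite(atom$z)))
    stop("atom coordinates must be finite")
  if (any(!nzchar(atom$elem))) stop("every atom needs a non-empty element symbol")
  if (is.unsorted(atom$resno)) stop("residue indices must be non-decreasing in atom order")
  n <- length(unique(atom$resno))
  if (!identical(sort(unique(atom$resno)), seq_len(n)))
    stop("residues must be numbered 1..n")
  helix <- normalize_helix_ranges(helix, n)
  structure(list(atom = atom, helix = helix, source = source, n = n),
            class = "protein_structure")
}

normalize_helix_ranges <- function(helix, n) {
  if (is.null(helix) || NROW(helix) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  helix <- as.data.frame(helix)
  if (ncol(helix) < 2) stop("helix ranges need start and end columns")
  names(helix)[1:2] <- c("start", "end")
  helix <- helix[, c("start", "end")]
  helix$start <- as.integer(helix$start)
  helix$end <- as.integer(helix$end)
  if (any(helix$start < 1 | helix$end > n | helix$start > helix$end))
    stop("helix ranges must satisfy 1 <= start <= end <= n")
  helix <- helix[order(helix$start), , drop = FALSE]
  if (nrow(helix) > 1 && any(helix$start[-1] <= helix$end[-nrow(helix)]))
    stop("helix ranges must not overlap")
  rownames(helix) <- NULL
  helix
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("protein_structure:", x$source, "\n")
  cat("  residues:", x$n, "  atoms:", nrow(x$atom), "\n")
  if (nrow(x$helix)) {
    cat("  helices: ", paste(sprintf("%d-%d", x$helix$start, x$helix$end),
                             collapse = ", "), "\n")
  } else cat("  helices: none\n")
  invisible(x)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM and HELIX records of a PDB file (first model, one chain) into a
#' [protein_structure()]. Residues are renumbered 1..n preserving file order
#' (insertion-code residues keep their position); HELIX ranges are remapped to
#' that numbering. Waters and non-standard (HETATM / unknown residue name)
#' records are excluded. Alternate locations keep the first variant.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier; default takes the first chain (with a
#'   warning if the file has several).
#' @param keep_hydrogens Keep hydrogen atoms if present (default `TRUE`).
#' @return A `protein_structure`.
#' @export
#' @examples
#' pdb <- system.file("examples", "1hel.pdb", package = "bio3d")
#' s <- read_pdb(pdb)
#' s$n
read_pdb <- function(path, chain = NULL, keep_hydrogens = TRUE) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB file '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]

  chains <- unique(at$chain)
  if (is.null(chain)) {
    chain <- chains[[1]]
    if (length(chains) > 1)
      warning("multiple chains (", paste(chains, collapse = ","),
              "); using first chain '", chain, "'")
  }
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records for chain '", chain, "' in ", path)

  nonstd <- !(at$resid %in% AA_THREE)
  if (any(nonstd)) {
    message("excluding ", sum(nonstd), " atoms in non-standard residues: ",
            paste(unique(at$resid[nonstd]), collapse = ","))
    at <- at[!nonstd, , drop = FALSE]
    if (nrow(at) == 0) stop("no standard-residue ATOM records in ", path)
  }
  # alternate locations: keep first conformer of each (residue, atom name)
  if (any(!is.na(at$alt))) {
    key <- paste(at$resno, at$insert, at$elety)
    at <- at[!duplicated(key), , drop = FALSE]
  }

  rkey <- paste(at$resno, ifelse(is.na(at$insert), "", at$insert))
  ukey <- unique(rkey)
  resno_new <- match(rkey, ukey)

  elem <- at$elesy
  bad <- is.na(elem) | !nzchar(trimws(elem))
  if (any(bad)) elem[bad] <- element_from_name(at$elety[bad])
  elem <- trimws(elem)

  atom <- data.frame(serial = at$eleno, name = at$elety, elem = elem,
                     resno = resno_new, resid = at$resid, chain = at$chain,
                     x = at$x, y = at$y, z = at$z, row.names = NULL)
  if (!keep_hydrogens) atom <- atom[atom$elem != "H", , drop = FALSE]
  if (anyNA(atom$x) || anyNA(atom$y) || anyNA(atom$z))
    stop("malformed coordinate fields in ", path)

  helix <- NULL
  hx <- pdb$helix
  if (!is.null(hx) && length(hx$start)) {
    keep <- hx$chain %in% chain
    if (any(keep)) {
      # HELIX records are in author numbering; remap via the ATOM residue keys
      # (insertion codes in HELIX records are rare and ignored here).
      author_res <- as.integer(sub(" .*$", "", ukey))
      s <- match(as.integer(hx$start[keep]), author_res)
      e <- match(as.integer(hx$end[keep]), author_res)
      ok <- !is.na(s) & !is.na(e) & s <= e
      if (any(ok)) helix <- data.frame(start = s[ok], end = e[ok])
    }
  }
  protein_structure(atom, helix, source = sub("\\.pdb$", "", basename(path),
                                              ignore.case = TRUE))
}

element_from_name <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(nm, 1, 2)
  out <- substr(nm, 1, 1)
  # distinguish e.g. "SE"/"FE"/"CL" from single-letter C/N/O/S/H/P
  known2 <- c("SE", "FE", "CL", "BR", "MG", "ZN", "MN", "NA")
  out[two %in% known2] <- two[two %in% known2]
  # PDB convention: leading digit means hydrogen (e.g. 1HB)
  out[grepl("^[0-9]", name)] <- "H"
  out
}

#' Write a protein structure to a PDB file
#'
#' Emits HELIX and ATOM records in wwPDB v3.3 fixed-column format, readable by
#' [read_pdb()] and standard tools. Coordinates are written with three
#' decimals (the PDB precision).
#'
#' @param structure A `protein_structure`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "protein_structure"))
  at <- structure$atom
  lines <- character(0)
  hx <- structure$helix
  if (nrow(hx)) {
    for (i in seq_len(nrow(hx))) {
      res_s <- at$resid[match(hx$start[i], at$resno)]
      res_e <- at$resid[match(hx$end[i], at$resno)]
      ch <- at$chain[1]
      lines <- c(lines, sprintf(
        "HELIX  %3d %3s %3s %s %4d  %3s %s %4d %2d%-30s %5d",
        i, sprintf("%d", i), res_s, ch, hx$start[i], res_e, ch, hx$end[i],
        1L, "", hx$end[i] - hx$start[i] + 1L))
    }
  }
  name_fmt <- ifelse(nchar(at$name) < 4, sprintf(" %-3s", at$name),
                     sprintf("%-4s", at$name))
  lines <- c(lines, sprintf(
    "ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    at$serial, name_fmt, at$resid, at$chain, at$resno,
    at$x, at$y, at$z, 1, 0, at$elem))
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Is an insertion gap inside an alpha helix?
#'
#' Insertion gaps use 0-based coordinates: gap `g` lies between residue `g`
#' and residue `g + 1`, with gap 0 before the first residue and gap `n` after
#' the last. A gap is "in" a helix only when both flanking residues belong to
#' the same annotated helix range, i.e. when inserting there interrupts that
#' helix; terminal gaps are therefore never in a helix.
#'
#' @param structure A `protein_structure` (only its `n` and `helix` fields are
#'   used).
#' @param gap Integer vector of gaps in `0..n`.
#' @return Logical vector.
#' @export
#' @examples
#' s <- ideal_helix_structure(12)
#' gap_in_helix(s, c(0, 5, 12))
gap_in_helix <- function(structure, gap) {
  n <- structure$n
  gap <- as.integer(gap)
  if (any(gap < 0 | gap > n)) stop("gap out of range 0..", n)
  hx <- structure$helix
  if (is.null(hx) || nrow(hx) == 0) return(rep(FALSE, length(gap)))
  out <- rep(FALSE, length(gap))
  inner <- gap >= 1 & gap + 1 <= n
  for (i in seq_len(nrow(hx))) {
    out <- out | (inner & gap >= hx$start[i] & gap + 1 <= hx$end[i])
  }
  out
}

#' Summarize a structure as JSON
#'
#' @param structure A `protein_structure`.
#' @param path Optional file to write the JSON to.
#' @return JSON string (invisibly if `path` given).
#' @export
structure_summary <- function(structure, path = NULL) {
  stopifnot(inherits(structure, "protein_structure"))
  hx <- structure$helix
  js <- jsonlite::toJSON(list(
    source = structure$source,
    n_residues = structure$n,
    n_atoms = nrow(structure$atom),
    helix_ranges = if (nrow(hx)) unname(apply(hx, 1, as.integer, simplify = FALSE))
                   else list()
  ), auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
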
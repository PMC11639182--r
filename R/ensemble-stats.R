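# Statistical layer over mutant metric ensembles: outlier sets, frequency
# tallies, effect sizes, helix-group and size-group comparisons.
#
# A mutant ensemble is a data frame keyed by mutant_id with metric columns
# (hbc, cce, rop) and annotation columns (pos1, pos2, aa1, aa2, gap1, gap2,
# helix_group, size_group), as produced by simulate_metric_ensemble() or by
# joining enumerate_double_insertions() annotations with computed metrics.

#' Standard-deviation outlier set of a metric
#'
#' Mutants whose metric deviates from the ensemble mean by at least
#' `k` standard deviations. Two-sided by default (`|x - mean| >= k * sd`);
#' set `side` for one-sided variants. Mean and sd are taken over all records;
#' the sd is the sample (n - 1 denominator) standard deviation.
#'
#' @param ensemble Mutant ensemble data frame with a `mutant_id` column.
#' @param metric Metric column name (e.g. `"rop"`).
#' @param k Threshold in standard deviations (default 2).
#' @param side `"both"` (default), `"upper"` or `"lower"`.
#' @return An `outlier_set`: list with `metric`, `k`, `side`, `mean`, `sd`,
#'   `member_ids` (character vector of mutant ids).
#' @export
outliers <- function(ensemble, metric, k = 2, side = c("both", "upper", "lower")) {
  side <- match.arg(side)
  if (!metric %in% names(ensemble)) stop("no metric column '", metric, "'")
  x <- ensemble[[metric]]
  if (length(x) < 2) stop("need at least 2 records")
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    warning("metric '", metric, "' has zero variance; empty outlier set")
    ids <- character(0)
  } else {
    dev <- switch(side, both = abs(x - m), upper = x - m, lower = m - x)
    ids <- as.character(ensemble$mutant_id[dev >= k * s])
  }
  structure(list(metric = metric, k = k, side = side, mean = m, sd = s,
                 member_ids = ids),
            class = "outlier_set")
}

#' @export
print.outlier_set <- function(x, ...) {
  cat(sprintf("outlier_set: %d mutants with |%s - %.4g| >= %g * %.4g (%s)\n",
              length(x$member_ids), x$metric, x$mean, x$k, x$sd, x$side))
  invisible(x)
}

outlier_rows <- function(ensemble, outlier_set) {
  if (inherits(outlier_set, "outlier_set")) outlier_set <- outlier_set$member_ids
  rows <- ensemble[ensemble$mutant_id %in% outlier_set, , drop = FALSE]
  if (nrow(rows) < length(unique(outlier_set)))
    stop("outlier ids not all present in ensemble")
  rows
}

#' Inserted-residue frequencies in an outlier set
#'
#' Each outlier mutant contributes one count per inserted residue occurrence
#' (both `aa1` and `aa2`; a homotypic pair contributes 2 to its residue), so
#' counts sum to twice the outlier set size.
#'
#' @param ensemble Mutant ensemble.
#' @param outlier_set An `outlier_set` (or character vector of mutant ids).
#' @return Named integer vector over the 20 residues.
#' @export
residue_frequency <- function(ensemble, outlier_set) {
  rows <- outlier_rows(ensemble, outlier_set)
  tab <- table(factor(c(rows$aa1, rows$aa2), levels = standard_aa()))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Inserted-pair frequency matrix of an outlier set
#'
#' 20 x 20 symmetric count matrix: an outlier with inserted pair (a, b)
#' increments cells (a, b) and (b, a); homotypic pairs increment the diagonal
#' once per mutant.
#'
#' @inheritParams residue_frequency
#' @return 20 x 20 integer matrix with residue dimnames.
#' @export
pair_frequency_matrix <- function(ensemble, outlier_set) {
  rows <- outlier_rows(ensemble, outlier_set)
  aa <- standard_aa()
  m <- matrix(0L, 20, 20, dimnames = list(aa, aa))
  for (k in seq_len(nrow(rows))) {
    a <- rows$aa1[k]; b <- rows$aa2[k]
    m[a, b] <- m[a, b] + 1L
    if (a != b) m[b, a] <- m[b, a] + 1L
  }
  m
}

#' Insertion-gap frequencies of an outlier set
#'
#' Counts, for every wildtype insertion gap 0..n, how often it hosts an
#' insertion of an outlier mutant (each outlier contributes its `gap1` and
#' `gap2`), annotated with alpha-helix membership of the gap.
#'
#' @inheritParams residue_frequency
#' @param structure A `protein_structure` for helix annotation.
#' @return Data frame with columns `gap`, `count`, `in_helix`.
#' @export
position_frequency <- function(ensemble, outlier_set, structure) {
  rows <- outlier_rows(ensemble, outlier_set)
  gaps <- 0:structure$n
  cnt <- tabulate(c(rows$gap1, rows$gap2) + 1L, nbins = structure$n + 1L)
  data.frame(gap = gaps, count = cnt, in_helix = gap_in_helix(structure, gaps))
}

#' Tally outlier mutants by unordered pair
#'
#' Builds the pair tallies consumed by [top_pairs()]: unordered inserted
#' residue pairs (`by = "aa"`) or unordered insertion gap pairs
#' (`by = "gap"`), one count per outlier mutant.
#'
#' @inheritParams residue_frequency
#' @param by `"aa"` or `"gap"`.
#' @return Data frame with columns `item1`, `item2`, `count`, sorted by
#'   decreasing count.
#' @export
outlier_pair_tally <- function(ensemble, outlier_set, by = c("aa", "gap")) {
  by <- match.arg(by)
  rows <- outlier_rows(ensemble, outlier_set)
  if (by == "aa") {
    a <- pmin(rows$aa1, rows$aa2); b <- pmax(rows$aa1, rows$aa2)
  } else {
    a <- as.character(pmin(rows$gap1, rows$gap2))
    b <- as.character(pmax(rows$gap1, rows$gap2))
  }
  key <- paste(a, b, sep = "|")
  tab <- sort(table(key), decreasing = TRUE)
  parts <- do.call(rbind, strsplit(names(tab), "|", fixed = TRUE))
  out <- data.frame(item1 = parts[, 1], item2 = parts[, 2],
                    count = as.integer(tab))
  rownames(out) <- NULL
  out
}

#' Top-k pairs of a tally with element breakdown
#'
#' Ranks pair tallies by count (ties broken lexicographically by pair label)
#' and reports, over the selected top-k pairs, the 5 most frequent individual
#' elements; each element of a pair accrues that pair's full count, so a
#' homotypic pair contributes its count twice to its element.
#'
#' @param tally Data frame with columns `item1`, `item2`, `count` (from
#'   [outlier_pair_tally()]) or a symmetric count matrix (from
#'   [pair_frequency_matrix()]).
#' @param k Number of pairs to keep (default 30). If `k` exceeds the number
#'   of distinct pairs, all are returned with a warning.
#' @param n_elements Number of top elements to report (default 5).
#' @return List with `pairs` (ranked data frame: `item1`, `item2`, `pair`,
#'   `count`) and `elements` (data frame: `element`, `count`).
#' @export
top_pairs <- function(tally, k = 30, n_elements = 5) {
  if (is.matrix(tally)) {
    stopifnot(nrow(tally) == ncol(tally))
    nm <- rownames(tally)
    idx <- which(upper.tri(tally, diag = TRUE) & tally > 0, arr.ind = TRUE)
    tally <- data.frame(item1 = nm[idx[, 1]], item2 = nm[idx[, 2]],
                        count = tally[idx])
  }
  stopifnot(all(c("item1", "item2", "count") %in% names(tally)))
  tally <- tally[tally$count > 0, , drop = FALSE]
  if (nrow(tally) == 0) stop("tally is empty")
  pair <- paste0(tally$item1, tally$item2)
  ord <- order(-tally$count, pair)
  if (k > nrow(tally)) {
    warning("k = ", k, " exceeds ", nrow(tally), " distinct pairs; returning all")
    k <- nrow(tally)
  }
  top <- tally[ord[seq_len(k)], , drop = FALSE]
  top$pair <- paste0(top$item1, top$item2)
  rownames(top) <- NULL
  el <- tapply(rep(top$count, 2), c(top$item1, top$item2), sum)
  el <- sort(el, decreasing = TRUE)
  el <- el[seq_len(min(n_elements, length(el)))]
  list(pairs = top[, c("item1", "item2", "pair", "count")],
       elements = data.frame(element = names(el), count = as.integer(el),
                             row.names = NULL))
}

#' Cohen's d effect size between two samples
#'
#' Standardized mean difference `d = (M1 - M2) / d_pooled` with the
#' unweighted pooled standard deviation `d_pooled = sqrt((s1^2 + s2^2) / 2)`
#' of the two sample (n - 1 denominator) standard deviations. Benchmarks:
#' 0.2 small, 0.5 medium, 0.8 large. Also carries the pooled-variance
#' two-sample t-test of the same comparison.
#'
#' @param group1,group2 Numeric samples, each of length >= 2.
#' @return An `effect_size` object: `M1`, `M2`, `sd1`, `sd2`, `sd_pooled`,
#'   `d`, `t`, `p`, `df`, `n1`, `n2`.
#' @export
#' @examples
#' cohens_d(rnorm(100, 1), rnorm(100, 0))
cohens_d <- function(group1, group2) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 observations")
  s1 <- stats::sd(group1); s2 <- stats::sd(group2)
  if (s1 == 0 && s2 == 0) stop("both groups have zero variance")
  sp <- sqrt((s1^2 + s2^2) / 2)
  tt <- two_sample_t(group1, group2)
  structure(list(M1 = mean(group1), M2 = mean(group2), sd1 = s1, sd2 = s2,
                 sd_pooled = sp, d = (mean(group1) - mean(group2)) / sp,
                 t = tt$t, p = tt$p, df = tt$df, n1 = n1, n2 = n2),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's d = %.4f  (M1 = %.4g, M2 = %.4g, pooled sd = %.4g)\n",
              x$d, x$M1, x$M2, x$sd_pooled))
  cat(sprintf("t(%d) = %.4f, p = %.4g  (n1 = %d, n2 = %d)\n",
              x$df, x$t, x$p, x$n1, x$n2))
  invisible(x)
}

#' Pooled-variance two-sample t-test
#'
#' Classical Student two-sample t-test (equal variances pooled over
#' `n1 + n2 - 2` degrees of freedom), two-sided. Set `welch = TRUE` for the
#' Welch variant.
#'
#' @param group1,group2 Numeric samples, each of length >= 2.
#' @param welch Use the Welch unequal-variance test instead (default FALSE).
#' @return List with `t`, `p`, `df`.
#' @export
two_sample_t <- function(group1, group2, welch = FALSE) {
  if (length(group1) < 2 || length(group2) < 2)
    stop("each group needs at least 2 observations")
  if (stats::sd(group1) == 0 && stats::sd(group2) == 0) {
    if (mean(group1) == mean(group2)) return(list(t = 0, p = 1,
      df = length(group1) + length(group2) - 2L))
    stop("zero pooled variance with unequal means")
  }
  ht <- stats::t.test(group1, group2, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Compare alpha-helix insertion groups on a metric
#'
#' Pairwise effect sizes and t-tests between the helix groups I_XX, I_XH,
#' I_HH for one metric, plus per-group normal-curve summaries (mean,
#' mean +/- sd) for plotting. Comparisons involving a group with fewer than
#' 2 mutants are skipped with a warning (proteins without enough helix
#' content have no I_HH group).
#'
#' @param ensemble Mutant ensemble with a `helix_group` column.
#' @param metric Metric column name.
#' @return List with `comparisons` (data frame: `group1`, `group2`, `n1`,
#'   `n2`, `M1`, `M2`, `sd1`, `sd2`, `d`, `t`, `p`) and `groups` (data
#'   frame: `group`, `n`, `mean`, `sd`, `lower`, `upper`).
#' @export
helix_group_comparison <- function(ensemble, metric) {
  if (!"helix_group" %in% names(ensemble)) stop("no helix_group column")
  if (!metric %in% names(ensemble)) stop("no metric column '", metric, "'")
  lv <- c("I_XX", "I_XH", "I_HH")
  gr <- split(ensemble[[metric]], factor(ensemble$helix_group, levels = lv))
  summ <- data.frame(group = lv, n = lengths(gr),
                     mean = vapply(gr, function(x) if (length(x)) mean(x) else NA_real_, 0),
                     sd = vapply(gr, function(x) if (length(x) > 1) stats::sd(x) else NA_real_, 0))
  summ$lower <- summ$mean - summ$sd
  summ$upper <- summ$mean + summ$sd
  rownames(summ) <- NULL
  combos <- list(c("I_XX", "I_XH"), c("I_XX", "I_HH"), c("I_XH", "I_HH"))
  rows <- list()
  for (cb in combos) {
    g1 <- gr[[cb[1]]]; g2 <- gr[[cb[2]]]
    if (length(g1) < 2 || length(g2) < 2) {
      warning("skipping ", cb[1], " vs ", cb[2], ": group with n < 2")
      next
    }
    es <- cohens_d(g1, g2)
    rows[[length(rows) + 1L]] <- data.frame(
      group1 = cb[1], group2 = cb[2], n1 = es$n1, n2 = es$n2,
      M1 = es$M1, M2 = es$M2, sd1 = es$sd1, sd2 = es$sd2,
      d = es$d, t = es$t, p = es$p)
  }
  comparisons <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group1 = character(0), group2 = character(0))
  list(comparisons = comparisons, groups = summ[summ$n > 0, , drop = FALSE])
}

#' Size-group normalized outlier rates
#'
#' For the single-residue classes VS, S, M, L, VL (a mutant belongs when
#' either inserted residue is in the class) and the homogeneous pair groups
#' VSVS, SS, MM, LL, VLVL (both residues in the class), reports the
#' within-group outlier fraction for a metric:
#' `rate = outliers in group / ensemble members in group`. Per block
#' (singles, pairs) the maximum- and minimum-rate groups are flagged. With
#' `denominator = "wildtype"` the single-class counts are instead divided by
#' the number of wildtype residues of that class (requires `structure`;
#' pair groups are undefined there and get `NA`).
#'
#' @param ensemble Mutant ensemble with `aa1`, `aa2` columns.
#' @param metric Metric column name.
#' @param k Outlier threshold in standard deviations (default 2).
#' @param denominator `"group"` (default) or `"wildtype"`.
#' @param structure Wildtype `protein_structure`, needed for
#'   `denominator = "wildtype"`.
#' @return Data frame with columns `group`, `block`, `n_group`, `n_outlier`,
#'   `rate`, `flag` (`"max"`, `"min"` or `""`).
#' @export
normalized_size_outlier_rates <- function(ensemble, metric, k = 2,
                                          denominator = c("group", "wildtype"),
                                          structure = NULL) {
  denominator <- match.arg(denominator)
  os <- outliers(ensemble, metric, k = k)
  is_out <- ensemble$mutant_id %in% os$member_ids
  c1 <- size_class_of(ensemble$aa1)
  c2 <- size_class_of(ensemble$aa2)
  rows <- list()
  for (cls in SIZE_ORDER) {
    member <- c1 == cls | c2 == cls
    denom <- if (denominator == "group") sum(member) else {
      if (is.null(structure)) stop("denominator = 'wildtype' needs a structure")
      res1 <- structure$atom$resid[!duplicated(structure$atom$resno)]
      sum(size_class_of(unname(AA_ONE[res1])) == cls)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      group = cls, block = "single", n_group = sum(member),
      n_outlier = sum(member & is_out),
      rate = if (denom > 0) sum(member & is_out) / denom else NA_real_)
  }
  for (cls in SIZE_ORDER) {
    member <- c1 == cls & c2 == cls
    rows[[length(rows) + 1L]] <- data.frame(
      group = paste0(cls, cls), block = "pair", n_group = sum(member),
      n_outlier = sum(member & is_out),
      rate = if (denominator == "group" && sum(member) > 0)
        sum(member & is_out) / sum(member) else NA_real_)
  }
  out <- do.call(rbind, rows)
  out$flag <- ""
  for (blk in c("single", "pair")) {
    sel <- which(out$block == blk & !is.na(out$rate))
    if (length(sel) >= 2) {
      out$flag[sel[which.max(out$rate[sel])]] <- "max"
      out$flag[sel[which.min(out$rate[sel])]] <- "min"
    }
  }
  rownames(out) <- NULL
  out
}

#' Hydrogen-bond-count grid over residue pairs and position pairs
#'
#' Matrix of HBC values with one row per unordered inserted residue pair,
#' ordered from the smallest pair (GG) to the largest (WW) by summed residue
#' volume (ties broken lexicographically), and one column per insertion
#' position pair `(pos1, pos2)` in lexicographic order. A cell is the mean
#' HBC of the mutants mapping to it (the two orientations of a heterotypic
#' pair share a cell); cells with no mutant are `NA` (absent).
#'
#' @param ensemble Mutant ensemble with `hbc`, `pos1`, `pos2`, `aa1`, `aa2`.
#' @return Numeric matrix with pair-label rownames (first `"GG"`, last
#'   `"WW"` when all pairs are present) and `"pos1_pos2"` colnames.
#' @export
hbc_by_pair_grid <- function(ensemble) {
  if (!"hbc" %in% names(ensemble)) stop("no hbc column")
  aa <- standard_aa()
  cmb <- t(utils::combn(aa, 2))
  pairs <- rbind(cmb, cbind(aa, aa))
  vol <- AA_VOLUME[pairs[, 1]] + AA_VOLUME[pairs[, 2]]
  lab <- paste0(pairs[, 1], pairs[, 2])
  ord <- order(vol, lab)
  lab <- lab[ord]
  rowlab <- paste0(pmin(ensemble$aa1, ensemble$aa2),
                   pmax(ensemble$aa1, ensemble$aa2))
  pp <- unique(ensemble[order(ensemble$pos1, ensemble$pos2),
                        c("pos1", "pos2")])
  collab <- paste0(pp$pos1, "_", pp$pos2)
  m <- matrix(NA_real_, nrow = length(lab), ncol = length(collab),
              dimnames = list(lab, collab))
  cell <- paste0(rowlab, "|", ensemble$pos1, "_", ensemble$pos2)
  agg <- tapply(ensemble$hbc, cell, mean)
  parts <- do.call(rbind, strsplit(names(agg), "|", fixed = TRUE))
  m[cbind(match(parts[, 1], lab), match(parts[, 2], collab))] <- agg
  m
}
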
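# Outlier sets, frequency tallies, effect sizes and group comparisons.

# small deterministic ensemble fixture
make_ensemble <- function(n = 8,
                          helix = if (n >= 6) data.frame(start = 2, end = 6),
                          seed = 5, planted = list()) {
  cfg <- synthetic_ensemble_config(n_residues = n, seed = seed,
                                   planted_effects = planted)
  simulate_metric_ensemble(cfg, helix_ranges = helix)
}

test_that("outlier sets contain exactly the >= k-sigma deviants", {
  ens <- data.frame(mutant_id = sprintf("m%03d", 1:100),
                    rop = c(rep(0, 99), 100))
  os <- outliers(ens, "rop")
  expect_s3_class(os, "outlier_set")
  expect_equal(os$member_ids, "m100")
  expect_equal(os$mean, 1)
  # every member satisfies the defining inequality
  x <- ens$rop[ens$mutant_id %in% os$member_ids]
  expect_true(all(abs(x - os$mean) >= os$k * os$sd))

  const <- data.frame(mutant_id = c("a", "b", "c"), rop = c(1, 1, 1))
  expect_warning(os0 <- outliers(const, "rop"), "zero variance")
  expect_length(os0$member_ids, 0)
  expect_error(outliers(ens, "nope"), "metric")
})

test_that("outlier membership is invariant under affine metric transforms", {
  set.seed(21)
  ens <- data.frame(mutant_id = as.character(1:500), m = rnorm(500))
  base <- outliers(ens, "m")$member_ids
  for (ab in list(c(3, 0), c(-2, 5), c(0.01, -7))) {
    tr <- ens
    tr$m <- ab[1] * tr$m + ab[2]
    expect_setequal(outliers(tr, "m")$member_ids, base)
  }
})

test_that("one-sided outlier variants split the two-sided set", {
  set.seed(22)
  ens <- data.frame(mutant_id = as.character(1:2000), m = rnorm(2000))
  both <- outliers(ens, "m", side = "both")$member_ids
  up <- outliers(ens, "m", side = "upper")$member_ids
  lo <- outliers(ens, "m", side = "lower")$member_ids
  expect_setequal(c(up, lo), both)
  expect_length(intersect(up, lo), 0)
})

test_that("residue, pair and position tallies obey their conservation sums", {
  ens <- make_ensemble(n = 6)
  os <- outliers(ens, "rop")
  expect_gt(length(os$member_ids), 0)

  rf <- residue_frequency(ens, os)
  expect_equal(sum(rf), 2 * length(os$member_ids))

  pm <- pair_frequency_matrix(ens, os)
  expect_true(isSymmetric(pm))
  expect_equal(sum(diag(pm)) + sum(pm[upper.tri(pm)]), length(os$member_ids))
  off <- sum(pm) - sum(diag(pm))
  expect_equal(off %% 2, 0)

  ctx <- toy_structure(rep(list(list(CA = c(0, 0, 0))), 6),
                       helix = data.frame(start = 2, end = 6))
  pf <- position_frequency(ens, os, ctx)
  expect_equal(sum(pf$count), 2 * length(os$member_ids))
  expect_equal(pf$gap, 0:6)
  expect_equal(pf$in_helix, gap_in_helix(ctx, 0:6))

  # hand-checked single outliers
  tiny <- ens[1:3, ]
  tiny$aa1 <- c("P", "C", "H"); tiny$aa2 <- c("W", "C", "W")
  rf1 <- residue_frequency(tiny, tiny$mutant_id[1])
  expect_equal(rf1[["P"]], 1); expect_equal(rf1[["W"]], 1)
  rf2 <- residue_frequency(tiny, tiny$mutant_id[2])
  expect_equal(rf2[["C"]], 2)  # homotypic pair counts twice
  pm3 <- pair_frequency_matrix(tiny, tiny$mutant_id[3])
  expect_equal(pm3["H", "W"], 1); expect_equal(pm3["W", "H"], 1)
  expect_equal(sum(pm3), 2)
  pm2 <- pair_frequency_matrix(tiny, tiny$mutant_id[2])
  expect_equal(pm2["C", "C"], 1); expect_equal(sum(pm2), 1)

  expect_error(residue_frequency(ens, "not_a_mutant"), "not all present")
})

test_that("empty outlier set yields an all-zero position map", {
  ens <- make_ensemble(n = 4)
  ctx <- toy_structure(rep(list(list(CA = c(0, 0, 0))), 4))
  pf <- position_frequency(ens, character(0), ctx)
  expect_true(all(pf$count == 0))
})

test_that("top_pairs ranks by count with lexicographic tie-break", {
  tally <- data.frame(item1 = c("P", "M", "F"), item2 = c("W", "P", "P"),
                      count = c(19, 7, 7))
  tp <- top_pairs(tally, k = 2)
  expect_equal(tp$pairs$pair, c("PW", "FP"))  # FP < MP breaks the 7-7 tie
  # identity when k exceeds the list
  expect_warning(all3 <- top_pairs(tally, k = 10), "exceeds")
  expect_equal(nrow(all3$pairs), 3)
  # element breakdown accumulates pair counts per occurrence
  expect_equal(all3$elements$count[all3$elements$element == "P"], 19 + 7 + 7)
  expect_equal(all3$elements$count[all3$elements$element == "W"], 19)
  # matrix input is accepted
  m <- matrix(0L, 2, 2, dimnames = list(c("A", "G"), c("A", "G")))
  m["A", "G"] <- m["G", "A"] <- 4L; m["A", "A"] <- 2L
  tpm <- top_pairs(m, k = 2)
  expect_equal(tpm$pairs$pair, c("AG", "AA"))
})

test_that("cohens_d reproduces the closed-form arithmetic", {
  g1 <- c(1, 2, 3); g2 <- g1
  expect_equal(cohens_d(g1, g2)$d, 0)
  t0 <- two_sample_t(g1, g2)
  expect_equal(t0$t, 0)
  expect_equal(t0$p, 1)

  # delta = 2 with sds 3 and 4: pooled sd sqrt(12.5)
  set.seed(31)
  a <- rnorm(2000); a <- (a - mean(a)) / sd(a) * 3 + 2
  b <- rnorm(2000); b <- (b - mean(b)) / sd(b) * 4
  es <- cohens_d(a, b)
  expect_equal(es$sd_pooled, sqrt(12.5))
  expect_equal(es$d, 2 / sqrt(12.5))
  expect_equal(es$M1 - es$M2, 2)
  expect_equal(sign(es$d), sign(es$M1 - es$M2))
})

test_that("cohens_d is antisymmetric and scale invariant", {
  set.seed(32)
  for (i in 1:20) {
    a <- rnorm(sample(5:50, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(5:50, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    expect_equal(cohens_d(a, b)$d, -cohens_d(b, a)$d)
    c0 <- runif(1, 0.1, 10)
    expect_equal(cohens_d(c0 * a, c0 * b)$d, cohens_d(a, b)$d)
  }
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
  expect_error(cohens_d(c(1, 1), c(2, 2)), "zero variance")
})

test_that("two_sample_t matches the pooled-variance formula and offers Welch", {
  set.seed(33)
  a <- rnorm(30); b <- rnorm(25, 0.5)
  tt <- two_sample_t(a, b)
  n1 <- 30; n2 <- 25
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  expect_equal(tt$t, t_manual)
  expect_equal(tt$df, n1 + n2 - 2)
  expect_equal(tt$p, 2 * pt(-abs(t_manual), n1 + n2 - 2))
  tw <- two_sample_t(a, b, welch = TRUE)
  expect_false(identical(tt$df, tw$df))
})

test_that("helix group comparison recovers a planted shift and skips absent
           groups", {
  planted <- list(list(column = "helix_group", value = "I_HH",
                       metric = "hbc", shift = -0.4))
  ens <- make_ensemble(n = 12, helix = data.frame(start = 3, end = 9),
                       seed = 41, planted = planted)
  hg <- helix_group_comparison(ens, "hbc")
  cmp <- hg$comparisons
  d_xx_hh <- cmp$d[cmp$group1 == "I_XX" & cmp$group2 == "I_HH"]
  expect_equal(d_xx_hh, 0.4, tolerance = 0.05)
  d_xx_xh <- cmp$d[cmp$group1 == "I_XX" & cmp$group2 == "I_XH"]
  expect_lt(abs(d_xx_xh), 0.05)  # unshifted pair stays null
  expect_equal(nrow(hg$groups), 3)
  expect_true(all(hg$groups$lower < hg$groups$mean &
                  hg$groups$mean < hg$groups$upper))

  # no helices: only I_XX exists, zero comparisons
  ens0 <- make_ensemble(n = 5, helix = NULL, seed = 42)
  w <- capture_warnings(hg0 <- helix_group_comparison(ens0, "hbc"))
  expect_length(w, 3)  # every comparison is skipped
  expect_true(all(grepl("skipping", w)))
  expect_equal(nrow(hg0$comparisons), 0)
  expect_equal(hg0$groups$group, "I_XX")
})

test_that("size-group rates normalize within groups and flag extremes", {
  ens <- make_ensemble(n = 6, seed = 43)
  # k = 0 makes every mutant an outlier: every defined rate is 1
  allout <- normalized_size_outlier_rates(ens, "rop", k = 0)
  expect_true(all(allout$rate == 1, na.rm = TRUE))
  rates <- normalized_size_outlier_rates(ens, "rop")
  expect_setequal(rates$group[rates$block == "single"], c("VS", "S", "M", "L", "VL"))
  expect_setequal(rates$group[rates$block == "pair"],
                  c("VSVS", "SS", "MM", "LL", "VLVL"))
  expect_true(all(rates$rate >= 0 & rates$rate <= 1, na.rm = TRUE))
  expect_equal(sum(rates$flag == "max"), 2)  # one per block
  expect_equal(sum(rates$flag == "min"), 2)
  # membership definitions: singles by either residue, pairs by both
  vs <- rates[rates$group == "VS", ]
  expect_equal(vs$n_group, sum(size_class_of(ens$aa1) == "VS" |
                               size_class_of(ens$aa2) == "VS"))
  vsvs <- rates[rates$group == "VSVS", ]
  expect_equal(vsvs$n_group, sum(ens$size_group == "VSVS"))
})

test_that("a doubled-tail planted group is flagged max", {
  planted <- list(list(column = "size_group", value = "VLVL",
                       metric = "rop", shift = 0.75))
  ens <- make_ensemble(n = 10, seed = 44, planted = planted)
  rates <- normalized_size_outlier_rates(ens, "rop")
  expect_equal(rates$group[rates$block == "pair" & rates$flag == "max"], "VLVL")
})

test_that("hbc grid runs GG to WW with absent mutants marked NA", {
  ens <- make_ensemble(n = 3, seed = 45)
  grid <- hbc_by_pair_grid(ens)
  expect_equal(rownames(grid)[1], "GG")
  expect_equal(rownames(grid)[nrow(grid)], "WW")
  expect_equal(nrow(grid), 210)  # 190 heterotypic + 20 homotypic pairs
  expect_false(anyNA(grid))      # full space: every cell populated
  expect_equal(mean(grid[!is.na(grid)]),
               mean(tapply(ens$hbc, paste0(pmin(ens$aa1, ens$aa2),
                                           pmax(ens$aa1, ens$aa2), "|",
                                           ens$pos1, "_", ens$pos2), mean)))
  # drop one mutant: its cell (a homotypic pair has one orientation) is NA
  drop_id <- ens$mutant_id[ens$aa1 == "W" & ens$aa2 == "W"][1]
  g2 <- hbc_by_pair_grid(ens[ens$mutant_id != drop_id, ])
  expect_equal(sum(is.na(g2)), 1)
  expect_true(is.na(g2["WW", paste0(ens$pos1[ens$mutant_id == drop_id], "_",
                                    ens$pos2[ens$mutant_id == drop_id])]))
})
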
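# Geometric hydrogen-bond and hydrophobic-tether detection.

test_that("distant polar groups form no hydrogen bonds", {
  s <- toy_structure(list(
    list(.resid = "GLY", N = c(0, 0, 0), CA = c(1.46, 0, 0),
         C = c(2, 1.4, 0), O = c(3.2, 1.5, 0)),
    list(.resid = "GLY", N = c(10, 0, 0), CA = c(11.46, 0, 0),
         C = c(12, 1.4, 0), O = c(13.2, 1.5, 0))))
  expect_equal(suppressMessages(hbond_count(s)), 0)
})

test_that("a constructed collinear donor-H-acceptor pair gives one bond", {
  # acceptor carbonyl (res 1) and donor amide N with H pointing at it (res 2);
  # residues are not peptide-bonded (C..N far beyond 2.5 A)
  s <- toy_structure(list(
    list(C = c(-1.23, 0, 0), O = c(0, 0, 0)),
    list(N = c(2.9, 0, 0), H = c(1.9, 0, 0), CA = c(3.8, 1.1, 0))))
  hb <- suppressMessages(detect_hbonds(s))
  expect_equal(nrow(hb), 1)
  expect_equal(s$atom$name[hb$i], "N")
  expect_equal(s$atom$name[hb$j], "O")
  expect_equal(hb$dist, 2.9, tolerance = 1e-9)
  expect_equal(hb$bars, 5L)
  # same pair at 3.6 A exceeds the 3.5 A heavy-atom cutoff
  s2 <- toy_structure(list(
    list(C = c(-1.23, 0, 0), O = c(0, 0, 0)),
    list(N = c(3.6, 0, 0), H = c(2.6, 0, 0), CA = c(4.5, 1.1, 0))))
  expect_equal(suppressMessages(hbond_count(s2)), 0)
})

test_that("the ideal helix carries the canonical i -> i-4 bond ladder", {
  h <- ideal_helix_structure(12)
  hb <- detect_hbonds(h)
  expect_equal(nrow(hb), 8)
  don_res <- h$atom$resno[hb$i]
  acc_res <- h$atom$resno[hb$j]
  expect_setequal(don_res, 5:12)
  expect_equal(acc_res, don_res - 4L)
  expect_true(all(h$atom$name[hb$i] == "N"))
  expect_true(all(h$atom$name[hb$j] == "O"))
  expect_equal(hbond_count(extended_chain_structure(12)), 0)
})

test_that("counts are invariant under rigid-body transforms and atom order", {
  set.seed(42)
  h <- ideal_helix_structure(10)
  base_hb <- hbond_count(h)
  base_hp <- nrow(detect_hydrophobics(h))
  for (rep in 1:5) {
    t <- rigid_transform(h)
    expect_equal(hbond_count(t), base_hb)
    expect_equal(nrow(detect_hydrophobics(t)), base_hp)
  }
  # shuffle atom order within each residue (a permuted but valid file)
  at <- h$atom
  perm <- unlist(lapply(split(seq_len(nrow(at)), at$resno), sample))
  sh <- protein_structure(at[perm, ], helix = h$helix, source = "shuffled")
  expect_equal(hbond_count(sh), base_hb)
  expect_equal(nrow(detect_hydrophobics(sh)), base_hp)
})

test_that("implicit-hydrogen donors work on deprotonated structures", {
  h <- ideal_helix_structure(12)
  noH <- protein_structure(h$atom[h$atom$elem != "H", ], helix = h$helix,
                           source = "noH")
  hb <- detect_hbonds(noH)
  # the antecedent-angle route is deliberately looser than the explicit-H
  # criterion (without the hydrogen it cannot resolve near-miss contacts like
  # i -> i-3), so it must recover at least the canonical i -> i-4 ladder
  expect_gte(nrow(hb), 8)
  key <- paste(noH$atom$resno[hb$i], noH$atom$resno[hb$j])
  expect_true(all(paste(5:12, 1:8) %in% key))
  expect_false(any(duplicated(paste(hb$i, hb$j))))
})

test_that("hydrophobic tethers obey the vdW + slack cutoff", {
  two_ala <- function(gap) toy_structure(list(
    list(N = c(-1.2, 1.1, 0), CA = c(0, 0, 0), CB = c(1.52, 0, 0),
         C = c(-0.6, -1.4, 0), O = c(-1.8, -1.5, 0)),
    list(N = c(30, 1.1, 0), CA = c(31.52 + gap, 0, 0), CB = c(1.52 + gap, 0, 0),
         C = c(30.6, -1.4, 0), O = c(31.8, -1.5, 0))))
  s35 <- two_ala(3.5)
  hp35 <- suppressMessages(detect_hydrophobics(s35))
  expect_equal(nrow(hp35), 1)  # CB..CB at 3.5 <= 1.7 + 1.7 + 0.25
  expect_equal(s35$atom$name[hp35$i], "CB")
  expect_equal(s35$atom$name[hp35$j], "CB")
  expect_equal(hp35$bars, 2L)
  hp40 <- suppressMessages(detect_hydrophobics(two_ala(4.0)))
  expect_equal(nrow(hp40), 0)  # 4.0 > 3.65
  # never within one residue (residue 1 has carbon pairs well under cutoff)
  expect_false(any(s35$atom$resno[hp35$i] == s35$atom$resno[hp35$j]))
})

test_that("loosening cutoffs never decreases counts; pairs are unique", {
  h <- ideal_helix_structure(10)
  hb_tight <- detect_hbonds(h, dist_cutoff = 3.0)
  hb_std <- detect_hbonds(h, dist_cutoff = 3.5)
  hb_loose <- detect_hbonds(h, dist_cutoff = 4.0, h_angle = 100)
  expect_lte(nrow(hb_tight), nrow(hb_std))
  expect_lte(nrow(hb_std), nrow(hb_loose))
  key <- paste(pmin(hb_loose$i, hb_loose$j), pmax(hb_loose$i, hb_loose$j))
  expect_false(any(duplicated(key)))
})
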
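# Body-bar-hinge model construction and the (6,6) pebble game.

test_that("a lone glycine reduces to two bodies joined by one hinge", {
  # N and O are terminal atoms and lock into their neighbours' bodies,
  # leaving {N,CA} -- 5 bars -- {C,O} across the rotatable CA-C bond
  s <- toy_structure(list(list(.resid = "GLY",
    N = c(-1.46, 0, 0), CA = c(0, 0, 0), C = c(0.55, 1.42, 0),
    O = c(1.77, 1.53, 0))))
  g <- build_mechanical_model(s, interactions = NULL)
  expect_equal(g$n_bodies, 2)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$bars, 5L)
  expect_equal(g$edges$kind, "hinge")
  expect_equal(sort(unique(g$body_of)), 1:2)
})

test_that("locked bonds merge bodies; parallel bars sum and cap at 6", {
  # two residues bridged by two hydrogen bonds between the same body pair:
  # 5 + 5 caps at 6 bars on one edge
  s <- toy_structure(list(
    list(C = c(-1.23, 0, 0), O = c(0, 0, 0)),
    list(N = c(2.9, 0, 0), H = c(1.9, 0, 0), CA = c(3.8, 1.1, 0))))
  ints <- data.frame(kind = "hbond", i = c(2L, 2L), j = c(3L, 3L),
                     dist = 2.9, bars = 5L)
  g <- suppressMessages(build_mechanical_model(s, ints))
  expect_equal(g$edges$bars, 6L)
  expect_equal(nrow(g$edges), 1)
  d <- pebble_game(g)
  expect_length(d$clusters, 1)  # 6 bars lock the two bodies together
  expect_equal(d$redundant_edges, 0)
})

test_that("interactions referencing unknown atoms are rejected", {
  s <- ideal_helix_structure(3)
  bad <- data.frame(kind = "hbond", i = 1L, j = nrow(s$atom) + 5L,
                    dist = 3, bars = 5L)
  expect_error(build_mechanical_model(s, bad), "unknown atom")
})

test_that("pebble game handles free, rigid and overbraced body pairs", {
  free <- pebble_game(bbh_framework(1))
  expect_length(free$clusters, 1)
  expect_equal(free$internal_dof, 6)
  expect_equal(free$redundant_edges, 0)

  locked <- pebble_game(bbh_framework(2, data.frame(u = 1, v = 2, bars = 6)))
  expect_length(locked$clusters, 1)
  expect_equal(locked$independent_edges, 6)
  expect_equal(locked$internal_dof, 6)  # only the trivial motions remain

  over <- pebble_game(bbh_framework(2, data.frame(u = c(1, 1), v = c(2, 2),
                                                  bars = c(6, 1))))
  expect_length(over$clusters, 1)
  expect_equal(over$independent_edges, 6)
  expect_equal(over$redundant_edges, 1)

  under <- pebble_game(bbh_framework(2, data.frame(u = 1, v = 2, bars = 5)))
  expect_length(under$clusters, 2)  # a hinge leaves one internal DOF
})

test_that("bar accounting: independent + redundant = total bars, bounded", {
  for (seed in 1:25) {
    g <- random_framework(sample(2:8, 1), sample(1:15, 1), seed = seed)
    d <- pebble_game(g)
    expect_equal(d$independent_edges + d$redundant_edges, sum(g$edges$bars))
    expect_lte(d$independent_edges, max(0, 6 * g$n_bodies - 6))
    expect_equal(d$internal_dof, 6 * g$n_bodies - d$independent_edges)
    sizes <- lengths(rigid_clusters_atoms(d, g))
    expect_equal(sum(sizes), g$n_atoms)
  }
})

test_that("independent bar count equals the generic rigidity-matrix rank", {
  for (seed in 1:40) {
    set.seed(seed)
    g <- random_framework(sample(2:8, 1), sample(1:12, 1), seed = seed)
    d <- pebble_game(g)
    expect_equal(d$independent_edges,
                 rigidity_matrix_rank(g, n_placements = 3, seed = seed + 500))
  }
})

test_that("cluster partition matches the rank-probe oracle on small graphs", {
  for (seed in 1:12) {
    g <- random_framework(sample(2:6, 1), sample(1:10, 1), seed = seed)
    d <- pebble_game(g)
    expect_equal(canon_partition(d$cluster_of),
                 canon_partition(oracle_cluster_partition(g, seed = seed)))
  }
})

test_that("decomposition is invariant to edge processing order", {
  for (seed in 1:10) {
    g <- random_framework(sample(3:8, 1), sample(2:12, 1), seed = seed)
    d0 <- pebble_game(g)
    set.seed(seed + 99)
    for (rep in 1:3) {
      gs <- g
      gs$edges <- gs$edges[sample(nrow(gs$edges)), , drop = FALSE]
      ds <- pebble_game(gs)
      expect_equal(canon_partition(ds$cluster_of), canon_partition(d0$cluster_of))
      expect_equal(ds$independent_edges, d0$independent_edges)
    }
  }
})

test_that("adding a bar never splits a rigid cluster", {
  refines <- function(coarse, fine) {
    # every fine-partition block lies within one coarse block
    all(tapply(coarse, fine, function(x) length(unique(x))) == 1)
  }
  for (seed in 1:15) {
    g <- random_framework(sample(3:7, 1), sample(2:10, 1), seed = seed)
    d0 <- pebble_game(g)
    set.seed(seed)
    u <- sample(g$n_bodies, 1)
    v <- sample(setdiff(seq_len(g$n_bodies), u), 1)
    g2 <- bbh_framework(g$n_bodies,
                        rbind(g$edges, data.frame(u = u, v = v, bars = 1L,
                                                  kind = "extra")))
    d2 <- pebble_game(g2)
    expect_true(refines(d2$cluster_of, d0$cluster_of))
  }
})

test_that("atom clusters partition the atom set of a real model", {
  h <- ideal_helix_structure(8)
  g <- build_mechanical_model(h)
  d <- pebble_game(g)
  cl <- rigid_clusters_atoms(d, g)
  expect_equal(sum(lengths(cl)), nrow(h$atom))
  expect_false(any(duplicated(unlist(cl))))
  expect_true(all(diff(lengths(cl)) <= 0))  # decreasing sizes
  # helix H-bond ladder rigidifies most of the backbone
  expect_gt(lengths(cl)[1] / nrow(h$atom), 0.5)
  # mismatched pairing is caught
  g2 <- bbh_framework(3)
  expect_error(rigid_clusters_atoms(d, g2), "match")
})
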
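# small handmade ensembles make the proximity rules easy to verify
mk_ensemble <- function(coord_list, chroms, bin_size = 100e3) {
  n <- nrow(coord_list[[1]])
  coords <- array(NA_real_, c(length(coord_list), n, 3))
  for (m in seq_along(coord_list)) coords[m, , ] <- coord_list[[m]]
  layout <- tibble::tibble(bead = seq_len(n), chrom = chroms,
                           start = unlist(lapply(table(chroms)[unique(chroms)],
                                                 function(k) (seq_len(k) - 1) * bin_size)))
  structure_ensemble(coords, layout, bin_size)
}

test_that("proximity requires closeness in every model and good precision", {
  base <- rbind(c(0, 0, 0), c(1, 0, 0), c(10, 0, 0))
  chroms <- c("chr1", "chr2", "chr2")
  # beads 1-2 close in both models -> mutual neighbours
  ens <- mk_ensemble(list(base, base), chroms)
  prox <- proximity_sets(ens)
  expect_true(prox$neighbors[1, 2] && prox$neighbors[2, 1])
  expect_false(isTRUE(prox$neighbors[1, 3]))

  # close in one model only -> not neighbours
  moved <- base; moved[2, 1] <- 9
  ens2 <- mk_ensemble(list(base, moved), chroms)
  # bead 2 moves 8 radii between models -> fails the precision filter too
  prox2 <- proximity_sets(ens2)
  expect_false(prox2$precise[2])
  expect_true(is.na(prox2$neighbors[1, 2]))

  # wobble below the precision cut but above the proximity radius
  near <- base; near[2, 1] <- 2.5
  prox3 <- proximity_sets(mk_ensemble(list(base, near), chroms))
  expect_true(prox3$precise[2])
  expect_false(prox3$neighbors[1, 2])   # not within 2 in ALL models
})

test_that("intermingling scores are the trans fraction of the neighbour set", {
  # bead 1 (chr1) has neighbours: 3 trans + 1 cis
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                  c(-1, 0, 0), c(50, 50, 50))
  chroms <- c("chr1", "chr1", "chr2", "chr2", "chr2", "chr2")
  ens <- mk_ensemble(list(coords, coords), chroms)
  tr <- intermingling_score(proximity_sets(ens), ens$layout)
  expect_equal(tr$score[1], 3 / 4)
  expect_equal(tr$score[6], NA_real_)   # empty neighbour set

  all_cis <- mk_ensemble(list(coords[1:4, ], coords[1:4, ]),
                         rep("chr1", 4))
  tr2 <- intermingling_score(proximity_sets(all_cis), all_cis$layout)
  expect_equal(tr2$score[1], 0)
})

test_that("scores and trans densities match a naive all-pairs oracle", {
  cell <- toy_cell(toy_genome(2, 5e6), seed = 40)
  conf <- cell$conformation
  prox <- suppressMessages(proximity_sets(conf))
  tr <- intermingling_score(prox, conf$layout)

  xyz <- model_coords(conf, 1)
  chrom <- conf$layout$chrom
  n <- nrow(xyz)
  for (b in seq(1, n, by = 7)) {
    nb_cis <- 0; nb_trans <- 0
    for (k in seq_len(n)) {
      if (k == b) next
      if (sqrt(sum((xyz[b, ] - xyz[k, ])^2)) < 2 - 1e-9) {
        if (chrom[k] == chrom[b]) nb_cis <- nb_cis + 1 else nb_trans <- nb_trans + 1
      }
    }
    expected <- if (nb_cis + nb_trans == 0) NA_real_ else nb_trans / (nb_cis + nb_trans)
    expect_identical(tr$score[b], expected)
  }

  td <- trans_density(conf)
  for (b in seq(1, n, by = 13)) {
    acc <- 0
    for (k in seq_len(n)) {
      if (chrom[k] != chrom[b]) acc <- acc + 1 / sqrt(sum((xyz[b, ] - xyz[k, ])^2))
    }
    expect_equal(td$track$density[b], acc)
  }
  expect_equal(median(td$track$scaled_density), 1)

  # densities are invariant under global rotation
  theta <- 1.1
  R <- matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0,
                0, 0, 1), 3, byrow = TRUE)
  rot <- structure_ensemble(xyz %*% R, conf$layout, conf$bin_size)
  expect_equal(trans_density(rot)$track$density, td$track$density,
               tolerance = 1e-9)
})

test_that("trans density handles labels and simple arithmetic", {
  coords <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 3, 0))
  # single trans partner at distance 2 -> density 1/2; two at 1 and 2 -> 1.5
  ens <- mk_ensemble(list(coords), c("chr1", "chr2", "chr2"))
  td <- trans_density(ens, c("hub", "A", "B"))
  expect_equal(td$track$density[1], 1 / 2 + 1 / 3)
  expect_setequal(td$by_class$class, c("hub", "A", "B"))

  two <- mk_ensemble(list(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
                     c("chr1", "chr2", "chr2"))
  expect_equal(trans_density(two)$track$density[1], 1 + 1 / 2)
})

test_that("normalisation, aggregation and grouping follow the stated rules", {
  g <- toy_genome(1, 10e6)
  mk_track <- function(scores) {
    tibble::tibble(bead = seq_along(scores), chrom = "chr1",
                   start = (seq_along(scores) - 1) * 100e3,
                   n_neighbors = 4L, n_trans = NA_integer_, score = scores)
  }
  sc <- seq(0, 1, length.out = 100)
  agg <- normalize_and_aggregate(list(mk_track(sc)), n_groups = 10)
  expect_equal(rank(agg$median_score), rank(sc))       # rank preservation
  expect_true(all(table(agg$group) == 10))

  set.seed(2)
  t1 <- mk_track(runif(100)); t2 <- mk_track(runif(100)); t3 <- mk_track(runif(100))
  a123 <- normalize_and_aggregate(list(t1, t2, t3))
  a321 <- normalize_and_aggregate(list(t3, t2, t1))
  expect_equal(a123$median_score, a321$median_score)

  # all-NA loci are excluded from grouping
  t_na <- mk_track(c(NA, runif(99)))
  a_na <- normalize_and_aggregate(list(t_na), n_groups = 9)
  expect_true(is.na(a_na$group[1]))
  expect_equal(sum(!is.na(a_na$group)), 99)
})

test_that("feature enrichment matches the exact hypergeometric tail", {
  g <- toy_genome(1, 10e6)
  mk_track <- function(scores) {
    tibble::tibble(bead = seq_along(scores), chrom = "chr1",
                   start = (seq_along(scores) - 1) * 100e3,
                   n_neighbors = 4L, n_trans = NA_integer_, score = scores)
  }
  agg <- normalize_and_aggregate(list(mk_track(seq(0, 1, length.out = 200))),
                                 n_groups = 10)
  # uniform features -> logFC ~ 0
  unif <- feature_enrichment(agg, seq(2, 200, by = 2), mode = "logfc")
  expect_lt(abs(unif$log2fc), 0.2)
  # features only in the top stratum -> capped
  top_only <- feature_enrichment(agg, 181:200, mode = "logfc")
  expect_true(top_only$capped)
  expect_equal(top_only$log2fc, 10)

  fisher <- feature_enrichment(agg, c(1:15, 190:200), mode = "fisher")
  # brute-force two-sided hypergeometric for the same 2x2 table
  tab <- matrix(c(fisher$feat_high, fisher$nofeat_high,
                  fisher$feat_low, fisher$nofeat_low), 2)
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  probs <- dhyper(0:min(m, k), m, n2, k)
  p_brute <- sum(probs[probs <= dhyper(tab[1, 1], m, n2, k) * (1 + 1e-7)])
  expect_equal(fisher$p, p_brute, tolerance = 1e-9)
})
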
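test_that("build_genome does the bin arithmetic and rejects bad input", {
  g <- build_genome(2, 10e6, 100e3)
  expect_equal(nrow(g), 2)
  expect_equal(g$n_bins, c(100L, 100L))
  g1 <- build_genome(1, 100e3, 100e3)
  expect_equal(g1$n_bins, 1L)
  expect_equal(build_genome(3, 5e6, 25e3)$n_bins, rep(200L, 3))
  expect_error(build_genome(2, 10e6 + 1, 100e3), "multiple")
})

test_that("conformations are deterministic and territory level behaves", {
  g <- toy_genome(2, 20e6)
  c1 <- simulate_conformation(g, 0.3, seed = 7)
  c2 <- simulate_conformation(g, 0.3, seed = 7)
  expect_identical(c1$coords, c2$coords)

  c0 <- simulate_conformation(g, 0, seed = 7)
  rg <- radius_of_gyration(c0)
  centroid_sep <- sqrt(sum((as.numeric(rg[1, c("cx", "cy", "cz")]) -
                              as.numeric(rg[2, c("cx", "cy", "cz")]))^2))
  expect_gt(centroid_sep, max(rg$rg))

  cfull <- simulate_conformation(g, 1, seed = 7)
  expect_gt(trans_neighbor_fraction(cfull), trans_neighbor_fraction(c0))

  expect_error(simulate_conformation(g, 1.2, seed = 1), "\\[0, 1\\]")
})

test_that("sampled contacts respect the capture rule and planted hubs", {
  g <- toy_genome()
  conf <- simulate_conformation(g, 0.5, seed = 3)
  sc <- sample_contacts(conf, 300, capture_radius = 2, noise_fraction = 0,
                        seed = 4)
  d <- as.matrix(dist(model_coords(conf, 1)))
  bi <- schichubs:::global_bead(sc$contacts$chromA, sc$contacts$posA, g, 100e3)
  bj <- schichubs:::global_bead(sc$contacts$chromB, sc$contacts$posB, g, 100e3)
  expect_true(all(d[cbind(bi, bj)] < 2))

  plan <- plant_hubs("chr1", 2e6, k = 8)
  sc2 <- sample_contacts(conf, 100, planted_hubs = plan, seed = 5)
  ct <- dplyr::filter(sc2$contacts, chromA == "chr1", chromB == "chr1",
                      abs(posB - posA) > 50e3)
  end_in_anchor <- (ct$posA >= 2e6 & ct$posA < 2.04e6) |
    (ct$posB >= 2e6 & ct$posB < 2.04e6)
  expect_gte(sum(end_in_anchor), 8)

  empty <- sample_contacts(conf, 0, seed = 6)
  expect_equal(nrow(empty$contacts), 0)

  expect_error(
    sample_contacts(conf, 10, planted_hubs = plant_hubs("chr1", 99e6), seed = 1),
    "outside")
})

test_that("contact lists come out canonicalised and survive end swaps", {
  g <- toy_genome()
  sc <- toy_cell(g, n_contacts = 200, seed = 9)$contacts
  rank_a <- match(sc$chromA, g$chrom)
  rank_b <- match(sc$chromB, g$chrom)
  expect_true(all(rank_a < rank_b | (rank_a == rank_b & sc$posA <= sc$posB)))
  swapped <- tibble::tibble(chromA = sc$chromB, posA = sc$posB,
                            chromB = sc$chromA, posB = sc$posA)
  back <- canonicalize_contacts(swapped, g$chrom)
  expect_equal(dplyr::arrange(back, chromA, posA, posB),
               dplyr::arrange(sc, chromA, posA, posB))
})

test_that("Poisson-beta counts match the analytic moments", {
  kin <- tibble::tibble(gene = "g", k_on = 0.8, k_off = 2.2, s = 40)
  counts <- simulate_expression_counts(kin, 10000, seed = 11)[1, ]
  f <- kin$k_on / (kin$k_on + kin$k_off)
  mu <- kin$s * f
  # law of total variance for the mixed Poisson
  v <- mu + kin$s^2 * kin$k_on * kin$k_off /
    ((kin$k_on + kin$k_off)^2 * (kin$k_on + kin$k_off + 1))
  expect_lt(abs(mean(counts) - mu), 4 * sqrt(v / 10000))
  expect_lt(abs(var(counts) / v - 1), 0.15)

  zero <- simulate_expression_counts(
    tibble::tibble(gene = "z", k_on = 1, k_off = 1, s = 0), 100, seed = 1)
  expect_true(all(zero == 0))
  expect_error(simulate_expression_counts(
    tibble::tibble(gene = "b", k_on = -1, k_off = 1, s = 5), 10), "positive")
})

test_that("generated tracks encode the planted element classes", {
  g <- toy_genome(1)
  plan <- tibble::tibble(chrom = "chr1", bin = c(10, 30, 50),
                         class = c("emerging_enhancer", "bivalent_promoter",
                                   "weakening_enhancer"))
  tr <- generate_tracks(g, plan, seed = 2)
  k27ac <- tr$peaks[tr$peaks$mark == "H3K27ac", ]
  emerging_center <- (10 - 0.5) * 100e3
  at_emerging <- function(tp) {
    k27ac[k27ac$timepoint == tp & k27ac$start < emerging_center &
            k27ac$end > emerging_center, ]
  }
  expect_equal(nrow(at_emerging("naive")), 0)
  expect_gt(nrow(at_emerging("48h")), 0)
  pseudo_floor <- 0.01 * median(k27ac$intensity)
  expect_gt(mean(at_emerging("48h")$intensity) / pseudo_floor, 3)

  tss <- tr$tss
  expect_equal(nrow(tss), 1)
  biv <- tr$peaks[tr$peaks$start <= tss$pos & tr$peaks$end > tss$pos, ]
  expect_setequal(unique(biv$mark), c("H3K4me3", "H3K27me3"))

  empty <- generate_tracks(g, plan[0, ], seed = 1)
  expect_equal(nrow(empty$peaks), 0)
  dup <- tibble::tibble(chrom = "chr1", bin = c(5, 5),
                        class = "active_promoter")
  expect_error(generate_tracks(g, dup, seed = 1), "Duplicate TSS")
})

test_that("planted checkerboard matrices are symmetric and enriched", {
  labels <- rep(rep(c("A", "B"), each = 5), 4)
  m <- simulate_compartment_matrix(labels, enrichment = 3, depth = 8, seed = 3)
  expect_true(isSymmetric(m))
  same <- outer(labels, labels, `==`)
  far <- abs(outer(seq_along(labels), seq_along(labels), `-`)) > 5
  expect_gt(mean(m[same & far]), mean(m[!same & far]))
  expect_identical(m, simulate_compartment_matrix(labels, 3, 8, seed = 3))
})
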
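test_that("candidate anchors match the brute-force window scan", {
  g <- toy_genome(2, 10e6)
  for (seed in 1:8) {
    cell <- toy_cell(g, n_contacts = 300 + seed * 150, seed = seed,
                     hubs = plant_hubs("chr1", 2e6 + seed * 20e3, k = 8))
    got <- find_candidate_anchors(cell$contacts, g)
    want <- brute_force_anchors(cell$contacts, g)
    expect_equal(as.data.frame(got[c("chrom", "start", "long_range_count")]),
                 want, ignore_attr = TRUE)
  }
  expect_equal(nrow(find_candidate_anchors(toy_cell(g, 0, seed = 1)$contacts, g)), 0)
})

test_that("overlapping candidate windows keep the larger count", {
  g <- toy_genome(1, 10e6)
  # 6 long-range ends in [0, 20kb) and 9 in [40kb, 60kb): the 40 kb
  # windows at 0, 20k and 40k overlap with counts 6, 9, 9
  contacts <- tibble::tibble(
    chromA = "chr1",
    posA = c(seq(1e3, 19e3, length.out = 6), seq(41e3, 59e3, length.out = 9)),
    chromB = "chr1",
    posB = 5e6 + seq(0, 14) * 1e5)
  cand <- find_candidate_anchors(contacts, g)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$start, 20e3)
  expect_equal(cand$long_range_count, 9)
})

test_that("the permutation preserves the separation multiset exactly", {
  cell <- toy_cell(toy_genome(2, 10e6), n_contacts = 800, seed = 3)
  perm <- permute_long_range_contacts(cell$contacts, cell$genome, seed = 4)
  sep_of <- function(ct) {
    intra <- ct[ct$chromA == ct$chromB, ]
    sort(abs(intra$posB - intra$posA))
  }
  expect_identical(sep_of(perm), sep_of(cell$contacts))
  expect_equal(nrow(perm), nrow(cell$contacts))
  expect_identical(perm,
                   permute_long_range_contacts(cell$contacts, cell$genome,
                                               seed = 4))
  # positions actually move
  expect_false(identical(perm$posA, cell$contacts$posA))
})

test_that("empirical p uses the (1+r)/(1+n) floor and BH is monotone", {
  g <- toy_genome(1, 10e6)
  conf <- simulate_conformation(g, 0.5, seed = 6)
  sc <- sample_contacts(conf, 150, planted_hubs = plant_hubs("chr1", 2e6, k = 15),
                        seed = 7)
  hubs <- hub_significance(sc$contacts, g, n_perm = 100, seed = 8,
                           cell_id = "c1")
  null <- attr(hubs, "null_counts")
  top <- hubs[which.max(hubs$long_range_count), ]
  n_null <- sum(null$chrom == top$chrom)
  r <- sum(null$long_range_count >= top$long_range_count)
  expect_equal(top$empirical_p, (1 + r) / (1 + n_null))
  expect_true(all(hubs$fdr_q >= hubs$empirical_p))
  ord <- order(hubs$empirical_p)
  expect_true(all(diff(cummin(rev(hubs$fdr_q[ord]))) <= 0))

  expect_warning(hub_significance(sc$contacts, g, n_perm = 10, seed = 1),
                 "unstable")
})

test_that("span classification uses the 1 Mb half-open rule", {
  near <- tibble::tibble(chrom = "chr1", pos = c(2.2e6, 2.5e6), intra = TRUE)
  expect_equal(span_class(2.1e6, near), "short")
  far <- tibble::tibble(chrom = "chr1", pos = c(2.2e6, 10.1e6), intra = TRUE)
  expect_equal(span_class(2.1e6, far), "long")
  boundary <- tibble::tibble(chrom = "chr1", pos = 3.1e6, intra = TRUE)
  expect_equal(span_class(2.1e6, boundary), "long")
  trans_only <- tibble::tibble(chrom = "chr2", pos = 1e6, intra = FALSE)
  expect_true(is.na(span_class(2.1e6, trans_only)))
})

test_that("hub abundance profiles scale to mean 1 with bootstrap SDs", {
  g <- toy_genome(1, 10e6)
  track <- tibble::tibble(bead = 1:100, chrom = "chr1",
                          start = (0:99) * 100e3,
                          median_score = seq(0, 1, length.out = 100),
                          group = rep(1:10, each = 10))
  uniform <- tibble::tibble(chrom = "chr1",
                            center = (seq(5, 95, by = 10) - 0.5) * 100e3,
                            retained = TRUE)
  prof <- hub_abundance_by_intermingling(uniform, track, n_boot = 50, seed = 1)
  expect_equal(prof$scaled_abundance, rep(1, 10))
  expect_equal(mean(prof$scaled_abundance), 1)

  one_group <- tibble::tibble(chrom = "chr1", center = rep(150e3, 7),
                              retained = TRUE)
  prof2 <- hub_abundance_by_intermingling(one_group, track, n_boot = 50,
                                          seed = 2)
  expect_equal(prof2$scaled_abundance[prof2$group == 1], 10)
  expect_equal(sum(prof2$scaled_abundance), 10)
})
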
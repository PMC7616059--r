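test_that("scaling curves normalise to 1 and match the binned matrix", {
  one_sep <- tibble::tibble(chromA = "chr1", posA = seq(0, 9e5, 1e5),
                            chromB = "chr1", posB = seq(0, 9e5, 1e5) + 5e6)
  sc <- scaling_curve(one_sep)
  expect_equal(sum(sc$prob), 1)
  expect_equal(sum(sc$prob > 0), 1)

  cell <- toy_cell(toy_genome(1, 10e6), n_contacts = 3000, seed = 2)
  curve <- scaling_curve(cell$contacts)
  expect_equal(sum(curve$prob), 1)
  # contact probability decays from chain-local to chromosome scale
  near <- curve[curve$sep_mid > 1e5 & curve$sep_mid < 3e5, ]
  far <- curve[curve$sep_mid > 1e6 & curve$sep_mid < 3e6, ]
  expect_lt(mean(far$prob), mean(near$prob))

  # consistency oracle: bin-centred contacts give the same curve from
  # the contact list and from its binned matrix
  g <- toy_genome(1, 10e6)
  binned <- dplyr::mutate(
    dplyr::filter(cell$contacts, chromA == chromB),
    posA = floor(posA / 25e3) * 25e3, posB = floor(posB / 25e3) * 25e3)
  m <- contacts_to_matrix(binned, g, 25e3)
  expect_equal(scaling_curve(binned, min_separation = 25e3)$prob,
               scaling_curve(m, min_separation = 25e3, bin_size = 25e3)$prob)
  expect_error(scaling_curve(one_sep[0, ]), "No intra")
})

test_that("separation fractions follow the half-open class boundaries", {
  trans_only <- tibble::tibble(chromA = "chr1", posA = 1,
                               chromB = "chr2", posB = 1)
  f <- separation_fractions(trans_only)
  expect_equal(f$fraction[f$class == "trans"], 1)

  at_10kb <- tibble::tibble(chromA = "chr1", posA = 0,
                            chromB = "chr1", posB = 10e3)
  f2 <- separation_fractions(at_10kb)
  expect_equal(f2$fraction[f2$class == "10-100 kb"], 1)

  cell <- toy_cell(seed = 5)
  f3 <- separation_fractions(cell$contacts)
  expect_equal(sum(f3$fraction), 1)
  # brute-force tally oracle
  sep <- with(dplyr::filter(cell$contacts, chromA == chromB), abs(posB - posA))
  expect_equal(f3$count[f3$class == "1-5 Mb"], sum(sep >= 1e6 & sep < 5e6))
  expect_equal(f3$count[f3$class == "<10 kb"], sum(sep < 10e3))
  expect_error(separation_fractions(trans_only[0, ]), "Empty")
})

test_that("distance normalisation is exact, scale-free and idempotent", {
  m <- matrix(5, 20, 20)
  expect_true(all(normalize_matrix(m) == 1))
  set.seed(3)
  r <- matrix(rpois(400, 6), 20); r <- r + t(r)
  expect_equal(normalize_matrix(r), normalize_matrix(2 * r))
  nm <- normalize_matrix(r)
  for (d in 0:19) {
    idx <- cbind(seq_len(20 - d), seq_len(20 - d) + d)
    if (mean(r[idx]) > 0) expect_equal(mean(nm[idx]), 1, tolerance = 1e-9)
  }
  expect_equal(normalize_matrix(nm), nm, tolerance = 1e-9)
  expect_error(normalize_matrix(matrix(0, 3, 3)), "All-zero")
})

test_that("compartment scores recover planted blocks and obey sign rules", {
  labels <- rep(rep(c("A", "B"), each = 10), 3)
  m <- simulate_compartment_matrix(labels, enrichment = 3, depth = 12, seed = 4)
  nm <- normalize_matrix(m)
  orient <- as.numeric(labels == "A")
  cs <- compartment_scores(nm, orient)
  expect_equal(cs$label, labels)
  flipped <- compartment_scores(nm, -orient)
  expect_equal(flipped$score, -cs$score)

  perm <- sample(length(labels))
  cs_perm <- compartment_scores(nm[perm, perm], orient[perm])
  expect_equal(cs_perm$score, cs$score[perm], tolerance = 1e-9)
})

test_that("saddle analysis separates planted compartments from noise", {
  labels <- rep(rep(c("A", "B"), each = 10), 3)
  m <- simulate_compartment_matrix(labels, enrichment = 3, depth = 12, seed = 6)
  nm <- normalize_matrix(m)
  cs <- compartment_scores(nm, as.numeric(labels == "A"))
  sad <- saddle(nm, cs$score, n_groups = 10)
  corners <- sad$corners
  expect_gt(min(corners$contact[corners$corner %in% c("AA", "BB")]),
            max(corners$contact[corners$corner %in% c("AB", "BA")]))
  expect_true(isSymmetric(unname(sad$saddle)))

  # scores unrelated to the matrix flatten the saddle
  set.seed(7)
  sad_null <- saddle(nm, sample(cs$score), n_groups = 10)
  expect_lt(max(abs(sad_null$saddle - 1)), max(abs(sad$saddle - 1)))
  expect_lt(abs(sad_null$mixing_ratio - 1), 0.35)
  expect_error(saddle(nm, cs$score, n_groups = 1), ">= 2")
})

test_that("bootstrap SD behaves on constants and i.i.d. normals", {
  expect_equal(bootstrap_sd(function(x) 42, rnorm(100), 50, 0.2, seed = 1), 0)
  set.seed(8)
  x <- rnorm(2000)
  sd_hat <- bootstrap_sd(mean, x, n_samples = 200, sample_fraction = 0.2,
                         seed = 2)
  theo <- 1 / sqrt(2000 * 0.2)
  expect_lt(sd_hat, 3 * theo)
  expect_gt(sd_hat, theo / 3)
  expect_identical(sd_hat, bootstrap_sd(mean, x, 200, 0.2, seed = 2))
  expect_error(bootstrap_sd(mean, rnorm(3), 10, 0.1), "too small")
})
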
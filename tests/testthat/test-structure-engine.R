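test_that("restraint construction dedupes contacts and adds the backbone", {
  g <- build_genome(1, 10e6, 100e3)
  contacts <- tibble::tibble(
    chromA = "chr1", posA = c(110e3, 150e3, 150e3),
    chromB = "chr1", posB = c(5.05e6, 5.08e6, 5.09e6))
  res <- contacts_to_restraints(contacts, g)
  expect_equal(sum(!res$backbone), 1)        # all three hit the same bead pair
  expect_equal(sum(res$backbone), 99)        # 100-bead chromosome
  expect_true(all(res$lower <= res$target & res$target <= res$upper))

  # a contact between adjacent beads folds into the backbone restraint
  adj <- tibble::tibble(chromA = "chr1", posA = 10e3,
                        chromB = "chr1", posB = 110e3)
  res2 <- contacts_to_restraints(adj, g)
  expect_equal(nrow(res2), 99)
  expect_error(contacts_to_restraints(
    tibble::tibble(chromA = "chrX", posA = 1, chromB = "chr1", posB = 2), g),
    "Unknown")
})

test_that("annealing satisfies a satisfiable toy and is deterministic", {
  g <- build_genome(1, 200e3, 100e3)
  contacts <- tibble::tibble(chromA = "chr1", posA = 10,
                             chromB = "chr1", posB = 150e3)
  res <- contacts_to_restraints(contacts, g)
  ens <- anneal(res, n_models = 2, seed = 5)
  d <- sqrt(sum((model_coords(ens, 1)[1, ] - model_coords(ens, 1)[2, ])^2))
  expect_gte(d, res$lower[1] - 1e-6)
  expect_lte(d, res$upper[1] + 1e-6)
  expect_identical(ens$coords, anneal(res, n_models = 2, seed = 5)$coords)
})

test_that("annealed energy is far below the random start", {
  cell <- toy_cell(toy_genome(1, 5e6), n_contacts = 150, seed = 3)
  res <- contacts_to_restraints(cell$contacts, cell$genome)
  ens <- anneal(res, n_models = 1, seed = 6)
  e_final <- structure_energy(model_coords(ens, 1), res)
  set.seed(6)
  start <- matrix(rnorm(n_beads(ens) * 3, 0, 5), ncol = 3)
  e_start <- structure_energy(start, res)
  expect_lt(e_final, e_start / 2)
})

test_that("alignment is invariant to rotation, translation and reflection", {
  conf <- simulate_conformation(toy_genome(1, 5e6), 0.5, seed = 8)
  P <- model_coords(conf, 1)
  theta <- 0.8
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0, 0, 0, 1), 3, byrow = TRUE)
  rotated <- P %*% R + matrix(rep(c(3, -2, 7), each = nrow(P)), ncol = 3)
  mirrored <- P %*% diag(c(1, 1, -1))
  mk <- function(other) {
    coords <- array(NA_real_, c(2, nrow(P), 3))
    coords[1, , ] <- P
    coords[2, , ] <- other
    structure_ensemble(coords, conf$layout, conf$bin_size)
  }
  for (other in list(P, rotated, mirrored)) {
    al <- align_ensemble(mk(other))
    expect_lt(max(al$bead_rmsd), 1e-6)
    expect_lt(al$model_rmsd[2], 1e-6)
  }
})

test_that("violation reports separate folded from random coordinates", {
  cell <- toy_cell(toy_genome(1, 5e6), n_contacts = 200, seed = 12)
  res <- contacts_to_restraints(cell$contacts, cell$genome)
  ens <- anneal(res, n_models = 1, seed = 13)
  folded <- violation_report(ens, res)
  expect_lt(folded$per_model$fraction, 0.05)

  set.seed(1)
  rand <- structure_ensemble(matrix(rnorm(n_beads(ens) * 3, 0, 20), ncol = 3),
                             ens$layout, ens$bin_size)
  expect_gt(violation_report(rand, res)$per_model$fraction, 0.8)
  expect_error(violation_report(ens, res[0, ]), "Empty")
})

test_that("structural-consistency filtering removes planted noise", {
  g <- toy_genome(2, 10e6)
  conf <- simulate_conformation(g, 0, seed = 20)   # territorial
  sc <- sample_contacts(conf, 400, noise_fraction = 0.25, seed = 21)
  d <- as.matrix(dist(model_coords(conf, 1)))
  bi <- schichubs:::global_bead(sc$contacts$chromA, sc$contacts$posA, g, 100e3)
  bj <- schichubs:::global_bead(sc$contacts$chromB, sc$contacts$posB, g, 100e3)
  is_noise <- d[cbind(bi, bj)] > 2

  filt <- filter_noise_contacts(sc$contacts, conf, g, max_distance = 3)
  kept <- paste(sc$contacts$posA, sc$contacts$posB) %in%
    paste(filt$posA, filt$posB)
  expect_gt(1 - mean(kept[is_noise]), mean(kept[is_noise]) * 0 + 0.5)
  expect_gt(mean(kept[!is_noise]), 0.99)

  ident <- filter_noise_contacts(sc$contacts, conf, g, max_distance = Inf)
  expect_equal(nrow(ident), nrow(sc$contacts))
  expect_equal(attr(ident, "removed_fraction"), 0)

  iso <- filter_isolated_contacts(sc$contacts, g)
  kept_iso <- paste(sc$contacts$posA, sc$contacts$posB) %in%
    paste(iso$posA, iso$posB)
  expect_lt(mean(kept_iso[is_noise]), mean(kept_iso[!is_noise]))
})

test_that("the resolution ladder always reaches the target bin size", {
  cell <- toy_cell(toy_genome(1, 5e6), n_contacts = 150, seed = 30)
  res <- contacts_to_restraints(cell$contacts, cell$genome)
  # a ladder that omits the 1x rung still returns full-resolution models
  ens <- anneal(res, n_models = 1, schedule = list(ladder = c(8L, 4L, 2L)),
                seed = 31)
  expect_equal(n_beads(ens), 50)
  # subdivision then annealing leaves the fine-level restraints satisfied
  vr <- violation_report(ens, res)
  expect_lt(vr$per_model$fraction, 0.05)
})
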
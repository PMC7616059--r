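mk_tracks <- function() {
  g <- build_genome(1, 10e6, 100e3)
  plan <- tibble::tibble(
    chrom = "chr1",
    bin = c(10, 20, 30, 40, 50),
    class = c("active_promoter", "bivalent_promoter", "active_enhancer",
              "emerging_enhancer", "weakening_enhancer"))
  list(genome = g, tracks = generate_tracks(g, plan, seed = 3), plan = plan)
}

test_that("element classification implements the mark-combination rules", {
  w <- mk_tracks()
  el <- classify_elements(w$tracks)
  class_at <- function(bin, tp) {
    center <- (bin - 0.5) * 100e3
    sort(unique(el$class[el$timepoint == tp & el$start <= center &
                           el$end >= center - 1]))
  }
  expect_true("active_promoter" %in% class_at(10, "naive"))
  expect_true("bivalent_promoter" %in% class_at(20, "naive"))
  expect_true("active_enhancer" %in% class_at(30, "48h"))
  expect_true("emerging_enhancer" %in% class_at(40, "48h"))
  expect_true("weakening_enhancer" %in% class_at(50, "naive"))
  # K27ac overlapping a promoter mark never becomes an enhancer
  expect_false("active_enhancer" %in% class_at(10, "naive"))

  missing <- w$tracks
  missing$peaks <- dplyr::filter(missing$peaks, mark != "H3K27me3")
  expect_error(classify_elements(missing), "H3K27me3")
})

test_that("the 3x emerging-enhancer threshold is a hard boundary", {
  # intensity just below 3x the pseudo-floor is not called emerging
  base <- mk_tracks()$tracks
  pk <- base$peaks
  floor_int <- 0.01 * median(pk$intensity[pk$mark == "H3K27ac"])
  target <- pk$mark == "H3K27ac" & pk$timepoint == "48h" &
    pk$start < 40 * 100e3 & pk$end > 39 * 100e3
  pk$intensity[target] <- floor_int * 2.5
  el_low <- classify_elements(list(peaks = pk, tss = base$tss))
  expect_false("emerging_enhancer" %in% el_low$class)
  pk$intensity[target] <- floor_int * 3.5
  el_high <- classify_elements(list(peaks = pk, tss = base$tss))
  expect_true("emerging_enhancer" %in% el_high$class)
})

test_that("long H3K27ac peaks are trimmed to 1 kb around the centre", {
  g <- build_genome(1, 10e6, 100e3)
  peaks <- tidyr::crossing(mark = c("H3K4me3", "H3K27ac", "H3K27me3"),
                           timepoint = c("naive", "24h", "48h"),
                           replicate = 1:2) |>
    dplyr::mutate(chrom = "chr1",
                  start = ifelse(mark == "H3K27ac", 5e6 - 2000, 1e6),
                  end = ifelse(mark == "H3K27ac", 5e6 + 2000, 1e6 + 500),
                  intensity = 10)
  el <- classify_elements(list(peaks = peaks,
                               tss = tibble::tibble(chrom = character(),
                                                    pos = double(),
                                                    gene = character())))
  enh <- el[el$class == "active_enhancer", ]
  expect_true(all(enh$end - enh$start == 1000))
  expect_true(all(enh$start == 5e6 - 500))
})

test_that("hub contact typing respects the 20 kb and 5 kb boundaries", {
  hubs <- tibble::tibble(
    chrom = "chr1", start = 2e6, end = 2.04e6, center = 2.02e6,
    cell_id = "c1", retained = TRUE,
    sites = list(tibble::tibble(chrom = "chr1", pos = c(3e6, 4e6),
                                intra = TRUE)))
  elements <- tibble::tibble(
    chrom = "chr1",
    start = c(2.02e6 + 9.5e3, 3e6 + 14.5e3, 4e6 + 24.5e3) - 500,
    end = c(2.02e6 + 9.5e3, 3e6 + 14.5e3, 4e6 + 24.5e3) + 500,
    class = c("active_promoter", "emerging_enhancer", "emerging_enhancer"),
    timepoint = "48h", gene = c("gA", NA, NA))
  tss <- tibble::tibble(chrom = "chr1", pos = c(2.02e6 + 4.9e3, 2.02e6 + 5e3),
                        gene = c("near", "exact"))
  groups <- tibble::tibble(gene = c("near", "exact"),
                           group = c("group_near", "group_exact"))
  ep <- call_hub_ep_contacts(hubs, elements, timepoint = "48h", tss = tss,
                             gene_groups = groups)
  # promoter 9.5 kb from the anchor centre types the anchor
  expect_true("active_promoter" %in% ep$anchor_categories$category)
  # TSS at 4.9 kb is inside the (exclusive) 5 kb rule; 5.0 kb is not
  expect_true("group_near" %in% ep$anchor_categories$category)
  expect_false("group_exact" %in% ep$anchor_categories$category)
  # enhancer 14.5 kb from a site counts, 24.5 kb does not
  expect_equal(sum(ep$site_class_counts$n), 1)
})

test_that("the compartment-matched shuffle is calibrated and finds excess", {
  w <- toy_ep_world(120, excess = 1, seed = 1)
  res <- shuffle_and_test(w$ep, w$compartments, n_perm = 300, seed = 2)
  expect_true(all(res$p_enrich >= 1 / 301))
  expect_lt(mean(abs(res$log2fc)), 0.25)

  planted <- toy_ep_world(200, excess = 3, seed = 3)
  res2 <- shuffle_and_test(planted$ep, planted$compartments, n_perm = 500,
                           seed = 4)
  cell <- res2[res2$anchor_category == "active_promoter" &
                 res2$site_class == "emerging_enhancer", ]
  expect_lt(cell$fdr_q, 0.05)
  expect_gt(cell$log2fc, 0)

  # p-value floor when the observed beats every permutation
  expect_equal(min(res2$p_enrich[res2$observed >
                                   apply(array(res2$null_mean), 1, max)]) >=
                 1 / 501, TRUE)
})

test_that("inter-chromosomal contacts are structure-filtered at 3.5 radii", {
  g <- build_genome(2, 1e6, 100e3)
  # bead 1 of chr1 sits 3.0 radii from bead 1 of chr2; bead 2 pairs are 4.0
  coords <- matrix(0, 20, 3)
  coords[1:10, 1] <- seq(0, 18, by = 2)
  coords[11:20, 1] <- seq(0, 18, by = 2)
  coords[11, 2] <- 3.0
  coords[12:20, 2] <- 4.0
  layout <- tibble::tibble(bead = 1:20, chrom = rep(c("chr1", "chr2"), each = 10),
                           start = rep((0:9) * 100e3, 2))
  ens <- structure_ensemble(coords, layout, 100e3)
  contacts <- tibble::tibble(
    chromA = "chr1", posA = c(50e3, 150e3),
    chromB = "chr2", posB = c(50e3, 150e3),
    cell_id = "c1")
  promoters <- tibble::tibble(chrom = "chr1", pos = c(50e3, 150e3),
                              group = "exit", compartment = "A")
  enhancers <- tibble::tibble(chrom = "chr2", pos = c(50e3, 150e3),
                              class = "emerging", compartment = "A")
  out <- interchrom_ep_contacts(contacts, list(c1 = ens), promoters, enhancers,
                                g, n_perm = 50, seed = 5)
  expect_equal(out$n_kept, 1)       # the 3.0-radii pair passes, 4.0 fails
  expect_equal(out$n_filtered, 1)
  expect_equal(out$result$observed[1], 1)
})

test_that("hub state profiles cluster planted populations and stay aligned", {
  set.seed(6)
  mk_hub <- function(i, kind) {
    pos <- 1e6 * i
    tibble::tibble(chrom = "chr1", center = pos, cell_id = "c1",
                   retained = TRUE,
                   sites = list(tibble::tibble(chrom = "chr1",
                                               pos = pos + c(1e5, 2e5),
                                               intra = TRUE)),
                   kind = kind)
  }
  hubs <- dplyr::bind_rows(
    purrr::map(1:6, mk_hub, kind = "active"),
    purrr::map(7:12, mk_hub, kind = "polycomb"))
  marks <- purrr::list_rbind(purrr::map(seq_len(nrow(hubs)), function(i) {
    pos <- hubs$center[i] + c(0, 1e5, 2e5)
    active <- hubs$kind[i] == "active"
    tidyr::crossing(mark = c("H3K27ac", "H3K27me3"), pos = pos) |>
      dplyr::mutate(chrom = "chr1", start = pos - 500, end = pos + 500,
                    intensity = ifelse((mark == "H3K27ac") == active,
                                       10 + rnorm(dplyr::n(), 0, 0.3), 0.5))
  }))
  prof <- hub_state_profiles(hubs, marks, k = 2)
  expect_equal(nrow(prof$contact_profile), 12)
  expect_identical(rownames(prof$contact_profile),
                   rownames(prof$anchor_profile))
  kinds <- hubs$kind[prof$hub_id]
  expect_equal(length(unique(tapply(prof$cluster, kinds, function(x) x[1]))), 2)
  expect_true(all(tapply(prof$cluster, kinds, function(x) length(unique(x))) == 1))
})
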
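# Shared fixture builders.  Everything is generated in code at test
# time; sizes are desk-scale so the whole suite stays fast.

toy_genome <- function(n_chroms = 2, chrom_length = 10e6, bin_size = 100e3) {
  build_genome(n_chroms, chrom_length, bin_size)
}

# A conformation plus sampled contacts with optional planted hubs.
toy_cell <- function(genome = toy_genome(), n_contacts = 500,
                     intermingle = 0.5, noise = 0, hubs = NULL, seed = 1) {
  conf <- simulate_conformation(genome, intermingle, seed = seed)
  sc <- sample_contacts(conf, n_contacts, noise_fraction = noise,
                        planted_hubs = hubs, seed = seed + 1000)
  c(sc, list(conformation = conf, genome = genome))
}

# Alternating A/B labels in blocks of `block` bins, one per bead.
toy_compartments <- function(genome, block = 10) {
  bins <- unlist(lapply(genome$n_bins, seq_len))
  ifelse((bins - 1) %/% block %% 2 == 0, "A", "B")
}

# Independent brute-force sliding-window hub scan used as the oracle
# for find_candidate_anchors(): nested loops, no shared helpers.
brute_force_anchors <- function(contacts, genome, window = 40e3, step = 20e3,
                                min_separation = 50e3, min_count = 4) {
  out <- list()
  for (ch in genome$chrom) {
    L <- genome$length[genome$chrom == ch]
    intra <- contacts[contacts$chromA == ch & contacts$chromB == ch, ]
    intra <- intra[abs(intra$posB - intra$posA) > min_separation, ]
    ends <- c(intra$posA, intra$posB)
    starts <- seq(0, max(0, L - window), by = step)
    counts <- integer(length(starts))
    for (w in seq_along(starts)) {
      counts[w] <- sum(ends >= starts[w] & ends < starts[w] + window)
    }
    hit <- which(counts >= min_count)
    # greedy: biggest count, leftmost on ties, no overlaps
    keep <- integer(0)
    for (i in hit[order(-counts[hit], starts[hit])]) {
      if (!length(keep) || all(abs(starts[keep] - starts[i]) >= window)) {
        keep <- c(keep, i)
      }
    }
    keep <- sort(keep)
    if (length(keep)) {
      out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                              long_range_count = counts[keep])
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Hub/element world for the enrichment tests: anchors and contact-site
# class counts with an optional planted promoter->emerging excess.
toy_ep_world <- function(n_hubs, excess = 1, sites_per_hub = 5, seed = 1) {
  set.seed(seed)
  acats <- c("active_promoter", "bivalent_promoter", "gene_group_exit")
  scls <- c("active_enhancer", "emerging_enhancer", "weakening_enhancer")
  anchor <- tibble::tibble(
    hub_id = seq_len(n_hubs),
    category = sample(acats, n_hubs, replace = TRUE)
  )
  sites <- purrr::list_rbind(purrr::map(seq_len(n_hubs), function(i) {
    w <- c(1, 1, 1)
    if (excess > 1 && anchor$category[i] == "active_promoter") w[2] <- excess
    cls <- sample(scls, sites_per_hub, replace = TRUE, prob = w)
    cnt <- table(cls)
    tibble::tibble(hub_id = i, class = names(cnt), n = as.integer(cnt))
  }))
  list(
    ep = list(
      hubs = tibble::tibble(hub_id = seq_len(n_hubs), chrom = "chr1",
                            center = seq_len(n_hubs) * 1e5, cell_id = "c1"),
      anchor_categories = anchor,
      site_class_counts = sites
    ),
    compartments = sample(c("A", "B"), n_hubs, replace = TRUE,
                          prob = c(0.7, 0.3))
  )
}
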
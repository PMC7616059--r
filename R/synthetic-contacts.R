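#' Describe hubs to plant in a synthetic contact list
#'
#' @param chrom Chromosome per hub.
#' @param anchor_start 0-based start of the 40 kb anchor window.
#' @param k Number of hub contacts (anchor to distal site).
#' @param separations Optional list of numeric vectors (one per hub) of
#'   signed bp separations from the anchor centre to each contact site;
#'   when `NULL`, `k` separations are drawn log-uniformly in
#'   `[100 kb, 3 Mb]` (alternating sign) at sampling time.
#' @param anchor_width Anchor window width in bp (40 kb, the hub anchor
#'   scale used throughout the package).
#' @return A `hub_plan` tibble.
#' @export
plant_hubs <- function(chrom, anchor_start, k = 8L, separations = NULL,
                       anchor_width = 40e3) {
  n <- length(chrom)
  out <- tibble(
    chrom = chrom,
    anchor_start = as.double(anchor_start),
    anchor_width = as.double(anchor_width),
    k = rep_len(as.integer(k), n),
    separations = separations %||% rep(list(NULL), n)
  )
  class(out) <- c("hub_plan", class(out))
  out
}

#' Sample a single-cell contact list from a conformation
#'
#' Emits `n_contacts` contacts: a fraction `1 - noise_fraction` is drawn
#' uniformly from the bead pairs lying within `capture_radius` of each
#' other in the conformation (proximity ligation at desk scale), and
#' `noise_fraction` uniformly over arbitrary bead pairs.  Base-pair
#' positions are uniform within each bead.  Hubs from `planted_hubs` add
#' `k` contacts each from random positions inside the 40 kb anchor window
#' to sites at the planned separations.  Output is canonicalised so
#' `(chromA, posA) <= (chromB, posB)` in genome order.
#'
#' @param conformation A single-model `structure_ensemble` (ground truth).
#' @param n_contacts Number of background contacts.
#' @param capture_radius Capture distance in bead radii (default 2, the
#'   same proximity scale the downstream intermingling analysis uses).
#' @param noise_fraction Fraction of spatially random contacts in `[0,1]`.
#' @param planted_hubs Optional `hub_plan` from [plant_hubs()].
#' @param compartment_labels Optional per-bead `"A"`/`"B"` labels; when
#'   given, proximity contacts between same-compartment beads are
#'   sampled `compartment_enrichment` times more often, planting a
#'   checkerboard compartment pattern in the pooled contact matrix.
#' @param compartment_enrichment Same-compartment sampling weight.
#' @param seed Integer seed.
#' @return A list with `contacts` (tibble: `chromA`, `posA`, `chromB`,
#'   `posB`) and `truth` (list: `conformation`, `hubs` tibble with planted
#'   site positions, `capture_radius`).
#' @export
sample_contacts <- function(conformation, n_contacts, capture_radius = 2,
                            noise_fraction = 0, planted_hubs = NULL,
                            compartment_labels = NULL,
                            compartment_enrichment = 3, seed = 1L) {
  stopifnot_scalar_number(capture_radius, "capture_radius", min = 1e-9)
  stopifnot_scalar_number(noise_fraction, "noise_fraction", min = 0, max = 1)
  stopifnot_scalar_number(n_contacts, "n_contacts", min = 0)
  layout <- conformation$layout
  bs <- conformation$bin_size
  chrom_len <- layout |> group_by(chrom) |>
    summarise(len = max(start) + bs, .groups = "drop")

  with_seed(seed, {
    n_noise <- round(n_contacts * noise_fraction)
    n_prox <- n_contacts - n_noise

    prox <- if (n_prox > 0) {
      d <- model_dist(conformation, 1L)
      pairs <- which(upper.tri(d) & d < capture_radius, arr.ind = TRUE)
      if (nrow(pairs) == 0L) {
        abort("No bead pairs within `capture_radius`; cannot sample contacts.")
      }
      w <- if (!is.null(compartment_labels)) {
        same <- compartment_labels[pairs[, 1]] == compartment_labels[pairs[, 2]]
        ifelse(same, compartment_enrichment, 1)
      } else {
        rep(1, nrow(pairs))
      }
      idx <- sample.int(nrow(pairs), n_prox, replace = TRUE, prob = w)
      beads_to_contacts(pairs[idx, 1], pairs[idx, 2], layout, bs)
    }

    noise <- if (n_noise > 0) {
      nb <- nrow(layout)
      i <- sample.int(nb, n_noise, replace = TRUE)
      j <- sample.int(nb - 1L, n_noise, replace = TRUE)
      j <- ifelse(j >= i, j + 1L, j)  # uniform over pairs i != j
      beads_to_contacts(i, j, layout, bs)
    }

    planted <- truth_hubs <- NULL
    if (!is.null(planted_hubs) && nrow(planted_hubs) > 0) {
      planted_rows <- purrr::pmap(planted_hubs, function(chrom, anchor_start,
                                                         anchor_width, k,
                                                         separations) {
        len <- chrom_len$len[match(chrom, chrom_len$chrom)]
        if (is.na(len)) abort(sprintf("Planted hub on unknown chromosome %s.", chrom))
        if (anchor_start < 0 || anchor_start + anchor_width > len) {
          abort(sprintf("Planted anchor [%s, %s) outside %s (length %s).",
                        format(anchor_start), format(anchor_start + anchor_width),
                        chrom, format(len)))
        }
        center <- anchor_start + anchor_width / 2
        sep <- separations %||% {
          s <- exp(stats::runif(k, log(100e3), log(3e6)))
          s * rep_len(c(1, -1), k)
        }
        site <- pmin(pmax(center + sep, 0), len - 1)
        if (any(abs(site - center) <= 50e3)) {
          # keep planted contacts unambiguously long range
          site <- ifelse(abs(site - center) <= 50e3,
                         pmin(center + sign(site - center + 0.5) * 60e3, len - 1),
                         site)
        }
        tibble(
          chromA = chrom,
          posA = floor(stats::runif(length(site), anchor_start,
                                    anchor_start + anchor_width)),
          chromB = chrom,
          posB = floor(site)
        )
      })
      planted <- purrr::list_rbind(planted_rows)
      truth_hubs <- dplyr::mutate(planted_hubs,
                                  sites = purrr::map(planted_rows, "posB"))
    }

    contacts <- canonicalize_contacts(dplyr::bind_rows(prox, noise, planted),
                                      chrom_order = chrom_len$chrom)
    list(
      contacts = contacts,
      truth = list(conformation = conformation, hubs = truth_hubs,
                   capture_radius = capture_radius)
    )
  })
}

beads_to_contacts <- function(i, j, layout, bs) {
  tibble(
    chromA = layout$chrom[i],
    posA = layout$start[i] + floor(stats::runif(length(i), 0, bs)),
    chromB = layout$chrom[j],
    posB = layout$start[j] + floor(stats::runif(length(j), 0, bs))
  )
}

#' Simulate a population Hi-C matrix with planted compartments
#'
#' Expected counts combine a power-law distance decay `(|i-j|)^-alpha`
#' with a checkerboard factor: bin pairs in the same planted compartment
#' get `enrichment` times the contact weight of mixed pairs.  Counts are
#' Poisson draws around `depth` times the normalised expectation, so the
#' matrix behaves like a binned bulk Hi-C observation at desk scale.
#'
#' @param labels Character vector of planted `"A"`/`"B"` labels, one per
#'   bin of one chromosome.
#' @param enrichment Same-compartment contact weight (>= 1).
#' @param depth Mean count per bin pair.
#' @param alpha Distance-decay exponent.
#' @param seed Integer seed.
#' @return Symmetric count matrix with planted labels as attribute
#'   `labels`.
#' @export
simulate_compartment_matrix <- function(labels, enrichment = 3, depth = 10,
                                        alpha = 1, seed = 1L) {
  n <- length(labels)
  sep <- abs(outer(seq_len(n), seq_len(n), `-`))
  decay <- ifelse(sep == 0, 1, sep^(-alpha))
  same <- outer(labels, labels, `==`)
  expect <- decay * ifelse(same, enrichment, 1)
  expect <- expect / mean(expect) * depth
  with_seed(seed, {
    m <- matrix(stats::rpois(n * n, expect), n, n)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    attr(m, "labels") <- labels
    m
  })
}

#' Canonicalise a contact list
#'
#' Orders each record so that `(chromA, posA) <= (chromB, posB)` in
#' genome order (chromosome rank, then position).
#'
#' @param contacts Tibble with `chromA`, `posA`, `chromB`, `posB`.
#' @param chrom_order Chromosome ordering; defaults to order of first
#'   appearance.
#' @return The canonicalised tibble.
#' @export
canonicalize_contacts <- function(contacts, chrom_order = NULL) {
  if (nrow(contacts) == 0L) return(contacts)
  chrom_order <- chrom_order %||% unique(c(contacts$chromA, contacts$chromB))
  ra <- match(contacts$chromA, chrom_order)
  rb <- match(contacts$chromB, chrom_order)
  flip <- rb < ra | (rb == ra & contacts$posB < contacts$posA)
  out <- contacts
  out$chromA[flip] <- contacts$chromB[flip]
  out$posA[flip] <- contacts$posB[flip]
  out$chromB[flip] <- contacts$chromA[flip]
  out$posB[flip] <- contacts$posA[flip]
  out
}
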
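#' Find candidate multiway-hub anchors by sliding-window scan
#'
#' Slides a 40 kb window (step 20 kb, half the window, so any true 40 kb
#' cluster overlaps some window by at least half) along each chromosome
#' and counts, for every window, the contact ends falling inside it whose
#' intra-chromosomal partner is more than `min_separation` away (both
#' ends of a contact are tested as potential anchor members).  Windows
#' with at least `min_count` long-range contacts are candidates; where
#' candidates overlap, the one with the larger count is kept (ties:
#' leftmost).  Significance is left to [hub_significance()] — the
#' `min_count` floor only bounds compute.
#'
#' @param contacts One cell's contact tibble.
#' @param assembly A `genome_assembly`.
#' @param window Anchor window width in bp.
#' @param step Window step in bp.
#' @param min_separation Long-range separation threshold in bp (> 50 kb).
#' @param min_count Candidate count floor.
#' @return Tibble `chrom`, `start`, `end`, `center`, `long_range_count`.
#' @export
find_candidate_anchors <- function(contacts, assembly, window = 40e3,
                                   step = 20e3, min_separation = 50e3,
                                   min_count = 4L) {
  assert_assembly(assembly)
  empty <- tibble(chrom = character(), start = double(), end = double(),
                  center = double(), long_range_count = integer())
  if (nrow(contacts) == 0L) return(empty)
  ends <- long_range_ends(contacts, min_separation)
  if (nrow(ends) == 0L) return(empty)

  cands <- lapply(assembly$chrom, function(ch) {
    p <- ends$pos[ends$chrom == ch]
    if (!length(p)) return(NULL)
    L <- assembly$length[assembly$chrom == ch]
    counts <- window_counts(p, L, window, step)
    hit <- which(counts >= min_count)
    if (!length(hit)) return(NULL)
    tibble(chrom = ch, start = (hit - 1) * step, end = (hit - 1) * step + window,
           long_range_count = counts[hit])
  })
  cands <- purrr::list_rbind(purrr::compact(cands))
  if (nrow(cands) == 0L) return(empty)
  out <- cands |>
    group_by(chrom) |>
    group_modify(~ resolve_overlaps(.x, window)) |>
    ungroup() |>
    mutate(center = (start + end) / 2) |>
    select(chrom, start, end, center, long_range_count) |>
    arrange(chrom, start)
  out
}

# Ends of intra-chromosomal contacts at separation > min_separation;
# both ends qualify, each with its partner as the contact site.
long_range_ends <- function(contacts, min_separation) {
  intra <- filter(contacts, chromA == chromB,
                  abs(posB - posA) > min_separation)
  bind_rows(
    tibble(chrom = intra$chromA, pos = intra$posA, partner = intra$posB),
    tibble(chrom = intra$chromB, pos = intra$posB, partner = intra$posA)
  )
}

# Number of qualifying ends per sliding window (starts 0, step, ...).
window_counts <- function(pos, chrom_length, window, step) {
  n_win <- max(1L, floor((chrom_length - window) / step) + 1L)
  span <- as.integer(window / step)
  j_hi <- pmin(floor(pos / step), n_win - 1)
  counts <- integer(n_win)
  for (o in 0:(span - 1)) {
    j <- j_hi - o
    ok <- j >= 0 & pos < j * step + window & pos >= j * step
    counts <- counts + tabulate(j[ok] + 1L, nbins = n_win)
  }
  counts
}

# Greedy selection: larger count first, leftmost on ties.
resolve_overlaps <- function(cands, window) {
  ord <- order(-cands$long_range_count, cands$start)
  kept <- integer(0)
  for (i in ord) {
    if (!any(abs(cands$start[kept] - cands$start[i]) < window)) {
      kept <- c(kept, i)
    }
  }
  cands[sort(kept), , drop = FALSE]
}

#' Separation-preserving permutation of long-range contacts
#'
#' Every intra-chromosomal contact with separation above
#' `min_separation` is placed into a different region of its chromosome,
#' keeping the sequence separation exactly: the left end is drawn
#' uniformly on `[0, L - separation)`.  Short-range and trans contacts
#' are left in place (they do not enter the hub statistic).  A contact
#' whose separation reaches the chromosome length is kept in place with
#' a warning.
#'
#' @param contacts Contact tibble.
#' @param assembly A `genome_assembly`.
#' @param min_separation Long-range threshold in bp.
#' @param seed Integer seed.
#' @return Permuted contact tibble (same number of rows per chromosome;
#'   the multiset of separations is preserved exactly).
#' @export
permute_long_range_contacts <- function(contacts, assembly,
                                        min_separation = 50e3, seed = 1L) {
  idx <- which(contacts$chromA == contacts$chromB &
                 abs(contacts$posB - contacts$posA) > min_separation)
  if (!length(idx)) return(contacts)
  L <- assembly$length[match(contacts$chromA[idx], assembly$chrom)]
  sep <- abs(contacts$posB - contacts$posA)[idx]
  fixed <- sep >= L
  if (any(fixed)) {
    warn(sprintf("%d contact(s) with separation >= chromosome length kept in place.",
                 sum(fixed)))
  }
  out <- contacts
  with_seed(seed, {
    move <- idx[!fixed]
    newA <- floor(stats::runif(length(move), 0, (L - sep)[!fixed]))
    out$posA[move] <- newA
    out$posB[move] <- newA + sep[!fixed]
  })
  out
}

#' Test candidate anchors against a permutation null and keep hubs
#'
#' The same anchor-identification scan is run on `n_perm`
#' separation-preserving permutations of the cell's long-range contacts;
#' the pseudo-anchor long-range counts, pooled over permutations per
#' chromosome, form the null.  Each candidate's empirical p-value is
#' `(1 + #(null >= observed)) / (1 + n_null)`; Benjamini-Hochberg FDR is
#' applied across all candidates in the cell and hubs with `q < fdr` are
#' retained.  Retained hubs carry their contact sites (partners of the
#' window's qualifying ends, plus trans partners touching the window)
#' and a span class.
#'
#' @inheritParams find_candidate_anchors
#' @param n_perm Number of permutations (the reference analysis uses
#'   400; fewer than 50 triggers an unstable-p warning).
#' @param fdr FDR threshold for retention.
#' @param seed Integer seed.
#' @param cell_id Optional cell label carried into the output.
#' @return Tibble of candidates with `empirical_p`, `fdr_q`, `retained`,
#'   `span_class`, and a `sites` list-column; the pooled null counts are
#'   attached as attribute `null_counts` (tibble `chrom`, `count`).
#' @export
hub_significance <- function(contacts, assembly, window = 40e3, step = 20e3,
                             min_separation = 50e3, min_count = 4L,
                             n_perm = 400L, fdr = 0.05, seed = 1L,
                             cell_id = NA_character_) {
  if (n_perm < 50L) warn("n_perm < 50 gives an unstable empirical-p floor.")
  cands <- find_candidate_anchors(contacts, assembly, window, step,
                                  min_separation, min_count)
  null_counts <- null_anchor_counts(contacts, assembly, window, step,
                                    min_separation, min_count, n_perm, seed)

  if (nrow(cands) == 0L) {
    out <- mutate(cands, cell_id = cell_id, empirical_p = double(),
                  fdr_q = double(), retained = logical(),
                  span_class = character(), sites = list())
    attr(out, "null_counts") <- null_counts
    return(out)
  }
  p <- vapply(seq_len(nrow(cands)), function(i) {
    nc <- null_counts$long_range_count[null_counts$chrom == cands$chrom[i]]
    (1 + sum(nc >= cands$long_range_count[i])) / (1 + length(nc))
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  out <- cands |>
    mutate(cell_id = cell_id, empirical_p = p, fdr_q = q, retained = q < fdr)
  out$sites <- hub_contact_sites(out, contacts, min_separation)
  out$span_class <- vapply(seq_len(nrow(out)), function(i) {
    span_class(out$center[i], out$sites[[i]])
  }, character(1))
  attr(out, "null_counts") <- null_counts
  out
}

# Pooled pseudo-anchor counts over n_perm separation-preserving
# permutations.  Draws the same uniforms in the same order as
# permute_long_range_contacts() + find_candidate_anchors() would per
# permutation (with per-permutation seeds derived identically), but
# skips the tibble plumbing, which dominates at 400 permutations/cell.
null_anchor_counts <- function(contacts, assembly, window, step,
                               min_separation, min_count, n_perm, seed) {
  is_lr <- contacts$chromA == contacts$chromB &
    abs(contacts$posB - contacts$posA) > min_separation
  idx <- which(is_lr)
  chrom <- contacts$chromA[idx]
  sep <- abs(contacts$posB - contacts$posA)[idx]
  L <- assembly$length[match(chrom, assembly$chrom)]
  movable <- sep < L
  out_ch <- character(0)
  out_n <- integer(0)
  for (k in seq_len(n_perm)) {
    newA <- with_seed(derive_seed(seed, k), {
      floor(stats::runif(sum(movable), 0, (L - sep)[movable]))
    })
    posA <- contacts$posA[idx]
    posB <- contacts$posB[idx]
    posA[movable] <- newA
    posB[movable] <- newA + sep[movable]
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      p <- c(posA[sel], posB[sel])
      counts <- window_counts(p, assembly$length[assembly$chrom == ch],
                              window, step)
      hit <- which(counts >= min_count)
      if (!length(hit)) next
      kept <- greedy_keep(hit, counts[hit], as.integer(window / step))
      out_ch <- c(out_ch, rep(ch, length(kept)))
      out_n <- c(out_n, counts[kept])
    }
  }
  tibble(chrom = out_ch, long_range_count = out_n)
}

# Greedy overlap resolution on window indices: larger count first,
# leftmost on ties; windows within `span` indices overlap.
greedy_keep <- function(win_idx, counts, span) {
  ord <- order(-counts, win_idx)
  kept <- integer(0)
  for (i in ord) {
    if (!any(abs(win_idx[kept] - win_idx[i]) < span)) kept <- c(kept, i)
  }
  win_idx[sort(kept)]
}

# Contact sites for each anchor window: partners of intra long-range
# ends inside the window, plus trans partners of ends inside the window.
hub_contact_sites <- function(anchors, contacts, min_separation) {
  intra_ends <- long_range_ends(contacts, min_separation)
  trans <- filter(contacts, chromA != chromB)
  trans_ends <- bind_rows(
    tibble(chrom = trans$chromA, pos = trans$posA,
           site_chrom = trans$chromB, site_pos = trans$posB),
    tibble(chrom = trans$chromB, pos = trans$posB,
           site_chrom = trans$chromA, site_pos = trans$posA)
  )
  lapply(seq_len(nrow(anchors)), function(i) {
    a <- anchors[i, ]
    ii <- intra_ends$chrom == a$chrom & intra_ends$pos >= a$start &
      intra_ends$pos < a$end
    ti <- trans_ends$chrom == a$chrom & trans_ends$pos >= a$start &
      trans_ends$pos < a$end
    bind_rows(
      tibble(chrom = a$chrom, pos = intra_ends$partner[ii], intra = TRUE),
      tibble(chrom = trans_ends$site_chrom[ti], pos = trans_ends$site_pos[ti],
             intra = FALSE)
    )
  })
}

#' Classify a hub's sequence span
#'
#' `"short"` if the maximum distance from the anchor centre to any
#' intra-chromosomal contact site is below 1 Mb, `"long"` otherwise
#' (half-open: exactly 1 Mb is long).  Hubs with no intra-chromosomal
#' site return `NA` (span undefined).
#'
#' @param anchor_center Anchor centre position in bp.
#' @param sites Tibble with `pos` and `intra` columns.
#' @param threshold Span threshold in bp.
#' @return `"short"`, `"long"`, or `NA_character_`.
#' @export
span_class <- function(anchor_center, sites, threshold = 1e6) {
  intra_pos <- sites$pos[sites$intra]
  if (!length(intra_pos)) return(NA_character_)
  if (max(abs(intra_pos - anchor_center)) < threshold) "short" else "long"
}

#' Hub abundance across intermingling groups
#'
#' Counts retained hubs per intermingling group (anchors mapped to beads
#' through the group track) and scales by the mean across groups, so the
#' profile averages 1; per-group bootstrap SDs use 2,000 random samples
#' of 30% of the hubs.
#'
#' @param hubs Hub tibble (retained rows are used).
#' @param group_track Output of [normalize_and_aggregate()] (`bead`,
#'   `chrom`, `start`, `group`).
#' @param n_boot Bootstrap samples.
#' @param boot_fraction Fraction per bootstrap sample.
#' @param seed Integer seed.
#' @return Tibble `group`, `n_hubs`, `scaled_abundance`, `boot_sd`.
#' @export
hub_abundance_by_intermingling <- function(hubs, group_track, n_boot = 2000,
                                           boot_fraction = 0.3, seed = 1L) {
  groups <- sort(unique(group_track$group[!is.na(group_track$group)]))
  if (!length(groups)) abort("Group track has no groups.")
  if ("retained" %in% names(hubs)) hubs <- filter(hubs, retained)
  bs <- diff(sort(unique(group_track$start))[1:2])
  hub_grp <- hub_groups(hubs, group_track, bs)
  profile_of <- function(g) {
    n <- vapply(groups, function(k) sum(g == k, na.rm = TRUE), numeric(1))
    n / mean(n)
  }
  prof <- profile_of(hub_grp)
  sds <- with_seed(seed, {
    mat <- vapply(seq_len(n_boot), function(b) {
      profile_of(sample(hub_grp, max(1, floor(length(hub_grp) * boot_fraction))))
    }, numeric(length(groups)))
    apply(matrix(mat, nrow = length(groups)), 1, stats::sd)
  })
  tibble(group = groups,
         n_hubs = vapply(groups, function(k) sum(hub_grp == k, na.rm = TRUE),
                         numeric(1)),
         scaled_abundance = prof, boot_sd = sds)
}

hub_groups <- function(hubs, group_track, bin_size) {
  vapply(seq_len(nrow(hubs)), function(i) {
    hit <- group_track$chrom == hubs$chrom[i] &
      group_track$start <= hubs$center[i] &
      group_track$start + bin_size > hubs$center[i]
    g <- group_track$group[hit]
    if (length(g) == 1L) as.integer(g) else NA_integer_
  }, integer(1))
}
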
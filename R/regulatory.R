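#' Classify regulatory elements from mark tracks
#'
#' Applies the mark-combination rules per time point:
#' * active enhancer: H3K27ac and no H3K4me3 or H3K27me3 (H3K27ac peaks
#'   longer than 1,000 bp are trimmed to 1,000 bp around their centre);
#' * active promoter: TSS has H3K4me3, H3K27ac and no H3K27me3;
#' * bivalent promoter: TSS has H3K4me3 and H3K27me3;
#' * emerging enhancer: H3K27ac absent at naive, present at 48h, with at
#'   least a 3x intensity increase (48h vs naive);
#' * weakening enhancer: the mirror rule (present naive, absent 48h,
#'   at least 3x decrease).
#'
#' "Absent" means no called peak at that time point; the 3x ratio uses a
#' pseudo-intensity floor of 1% of the genome-wide median H3K27ac
#' intensity in place of a missing peak, so the ratio is always defined.
#' Replicate intensities are averaged per peak.
#'
#' @param tracks List with `peaks` (tibble: `mark`, `timepoint`,
#'   `replicate`, `chrom`, `start`, `end`, `intensity`) and `tss`
#'   (tibble: `chrom`, `pos`, `gene`).
#' @param ratio Fold-change threshold for emerging/weakening calls.
#' @param trim_width Trimmed H3K27ac width in bp.
#' @return Tibble `chrom`, `start`, `end`, `class`, `timepoint`, `gene`.
#' @export
classify_elements <- function(tracks, ratio = 3, trim_width = 1000) {
  peaks <- tracks$peaks
  tss <- tracks$tss
  needed <- c("H3K4me3", "H3K27ac", "H3K27me3")
  missing <- setdiff(needed, unique(peaks$mark))
  if (length(missing)) {
    abort(sprintf(
      "Missing mark track(s) %s: promoter/enhancer rules need H3K4me3, H3K27ac and H3K27me3.",
      paste(missing, collapse = ", ")))
  }
  # collapse replicates, trim long H3K27ac peaks around their centre
  pk <- peaks |>
    group_by(mark, timepoint, chrom, start, end) |>
    summarise(intensity = mean(intensity), .groups = "drop") |>
    mutate(
      mid = (start + end) / 2,
      start = ifelse(mark == "H3K27ac" & end - start > trim_width,
                     mid - trim_width / 2, start),
      end = ifelse(mark == "H3K27ac" & end - start > trim_width,
                   mid + trim_width / 2, end)
    ) |>
    select(-mid)
  tps <- unique(pk$timepoint)
  floor_int <- 0.01 * stats::median(pk$intensity[pk$mark == "H3K27ac"])

  promoters <- purrr::map(tps, function(tp) {
    marks_at_tss <- function(mark) {
      p <- filter(pk, mark == !!mark, timepoint == tp)
      vapply(seq_len(nrow(tss)), function(i) {
        any(p$chrom == tss$chrom[i] & p$start <= tss$pos[i] & p$end > tss$pos[i])
      }, logical(1))
    }
    if (nrow(tss) == 0L) return(NULL)
    k4 <- marks_at_tss("H3K4me3"); k27ac <- marks_at_tss("H3K27ac")
    k27me3 <- marks_at_tss("H3K27me3")
    cls <- dplyr::case_when(
      k4 & k27me3 ~ "bivalent_promoter",
      k4 & k27ac & !k27me3 ~ "active_promoter",
      TRUE ~ NA_character_
    )
    keep <- !is.na(cls)
    tibble(chrom = tss$chrom[keep], start = tss$pos[keep] - 500,
           end = tss$pos[keep] + 500, class = cls[keep], timepoint = tp,
           gene = tss$gene[keep])
  }) |> purrr::list_rbind()

  k27ac <- filter(pk, mark == "H3K27ac")
  excl <- filter(pk, mark %in% c("H3K4me3", "H3K27me3"))
  is_clean <- function(e) {  # no promoter-mark overlap at the same time point
    vapply(seq_len(nrow(e)), function(i) {
      !any(excl$timepoint == e$timepoint[i] & excl$chrom == e$chrom[i] &
             excl$start < e$end[i] & excl$end > e$start[i])
    }, logical(1))
  }
  active_enh <- if (nrow(k27ac)) {
    ae <- k27ac[is_clean(k27ac), , drop = FALSE]
    tibble(chrom = ae$chrom, start = ae$start, end = ae$end,
           class = "active_enhancer", timepoint = ae$timepoint,
           gene = NA_character_)
  }

  # emerging / weakening: compare K27ac presence and intensity, naive vs 48h
  dynamic_enh <- NULL
  if (all(c("naive", "48h") %in% tps)) {
    k27_clean <- k27ac[is_clean(k27ac), , drop = FALSE]
    at_tp <- function(tp) filter(k27_clean, timepoint == tp)
    pair_calls <- function(present_tp, absent_tp, label) {
      pres <- at_tp(present_tp); abs_ <- at_tp(absent_tp)
      if (nrow(pres) == 0L) return(NULL)
      other_int <- vapply(seq_len(nrow(pres)), function(i) {
        hit <- abs_$chrom == pres$chrom[i] & abs_$start < pres$end[i] &
          abs_$end > pres$start[i]
        if (any(hit)) max(abs_$intensity[hit]) else NA_real_
      }, numeric(1))
      # absence = no called peak at the reference time point; the ratio
      # uses the pseudo-intensity floor in place of the missing peak
      keep <- is.na(other_int) & pres$intensity / floor_int >= ratio
      if (!any(keep)) return(NULL)
      tibble(chrom = pres$chrom[keep], start = pres$start[keep],
             end = pres$end[keep], class = label, timepoint = present_tp,
             gene = NA_character_)
    }
    dynamic_enh <- bind_rows(
      pair_calls("48h", "naive", "emerging_enhancer"),
      pair_calls("naive", "48h", "weakening_enhancer")
    )
  }
  bind_rows(promoters, active_enh, dynamic_enh) |>
    arrange(class, timepoint, chrom, start)
}

#' Type hub anchor-contact pairs by nearby regulatory elements
#'
#' An element types the anchor if its midpoint is no more than `flank`
#' (inclusive) from the anchor centre, and types a contact site likewise
#' around the site position.  Anchors are additionally typed by the gene
#' group of any TSS strictly closer than `tss_flank`.
#'
#' @param hubs Hub tibble from [hub_significance()] (retained rows used;
#'   needs `chrom`, `center`, `sites`).
#' @param elements Element tibble from [classify_elements()].
#' @param timepoint Which time point's element calls to use.
#' @param tss Optional TSS tibble (`chrom`, `pos`, `gene`).
#' @param gene_groups Optional tibble (`gene`, `group`) of gene-group
#'   labels used as extra anchor categories.
#' @param flank Flank around anchor centre / contact site in bp
#'   (inclusive).
#' @param tss_flank Gene-group assignment radius in bp (exclusive).
#' @return List with `hubs` (tibble `hub_id`, `chrom`, `center`),
#'   `anchor_categories` (`hub_id`, `category`), and `site_class_counts`
#'   (`hub_id`, `class`, `n`), ready for [shuffle_and_test()].
#' @export
call_hub_ep_contacts <- function(hubs, elements, timepoint = "24h",
                                 tss = NULL, gene_groups = NULL,
                                 flank = 20e3, tss_flank = 5e3) {
  if ("retained" %in% names(hubs)) hubs <- filter(hubs, retained)
  hubs <- mutate(hubs, hub_id = dplyr::row_number())
  el <- elements |>
    filter(timepoint == !!timepoint | !class %in%
             c("active_promoter", "bivalent_promoter", "active_enhancer")) |>
    mutate(mid = (start + end) / 2)

  classes_near <- function(chrom, pos) {
    hit <- el$chrom == chrom & abs(el$mid - pos) <= flank
    unique(el$class[hit])
  }
  anchor_cats <- purrr::map(seq_len(nrow(hubs)), function(i) {
    cats <- classes_near(hubs$chrom[i], hubs$center[i])
    if (!is.null(tss) && !is.null(gene_groups)) {
      near <- tss$chrom == hubs$chrom[i] &
        abs(tss$pos - hubs$center[i]) < tss_flank
      g <- gene_groups$group[match(tss$gene[near], gene_groups$gene)]
      cats <- c(cats, unique(g[!is.na(g)]))
    }
    if (length(cats)) tibble(hub_id = i, category = cats) else NULL
  }) |> purrr::list_rbind()

  site_counts <- purrr::map(seq_len(nrow(hubs)), function(i) {
    s <- hubs$sites[[i]]
    if (is.null(s) || nrow(s) == 0L) return(NULL)
    cls <- unlist(lapply(seq_len(nrow(s)), function(k) {
      classes_near(s$chrom[k], s$pos[k])
    }))
    if (!length(cls)) return(NULL)
    cnt <- table(cls)
    tibble(hub_id = i, class = names(cnt), n = as.integer(cnt))
  }) |> purrr::list_rbind()

  if (is.null(anchor_cats) || ncol(anchor_cats) == 0L) {
    anchor_cats <- tibble(hub_id = integer(), category = character())
  }
  if (is.null(site_counts) || ncol(site_counts) == 0L) {
    site_counts <- tibble(hub_id = integer(), class = character(), n = integer())
  }
  list(
    hubs = hubs[intersect(c("hub_id", "chrom", "center", "cell_id"), names(hubs))],
    anchor_categories = anchor_cats,
    site_class_counts = site_counts
  )
}

#' Compartment label for each hub anchor
#'
#' Majority compartment over the anchor window's bins; ties go to A.
#'
#' @param hubs Hub tibble (`chrom`, `start`, `end`).
#' @param compartment_track Tibble `chrom`, `start` (bin start), `label`
#'   (`"A"`/`"B"`), with uniform bins.
#' @param bin_size Track bin size in bp.
#' @return Character vector of labels per hub.
#' @export
hub_compartment <- function(hubs, compartment_track, bin_size) {
  vapply(seq_len(nrow(hubs)), function(i) {
    hit <- compartment_track$chrom == hubs$chrom[i] &
      compartment_track$start < hubs$end[i] &
      compartment_track$start + bin_size > hubs$start[i]
    lab <- compartment_track$label[hit]
    if (!length(lab) || sum(lab == "A", na.rm = TRUE) >= sum(lab == "B", na.rm = TRUE))
      "A" else "B"
  }, character(1))
}

#' Permutation test of hub contact-type enrichment
#'
#' The observed total of each (anchor category, contact class) pair is
#' compared with a null in which each anchor is re-paired with the
#' contact set of another hub drawn from the same A/B compartment (the
#' contact sets themselves stay intact, so the null preserves
#' per-compartment hub counts and each set's internal composition, and
#' removes only the anchor-contact association while controlling for
#' global compartment effects).  Two one-sided empirical p-values use
#' the `(1 + r) / (1 + n)` estimator; BH-FDR is applied to the
#' two-sided `min(2p, 1)` across category pairs.
#'
#' @param ep Output of [call_hub_ep_contacts()].
#' @param compartments Character vector, one `"A"`/`"B"` per hub (in
#'   `ep$hubs` order), e.g. from [hub_compartment()].
#' @param n_perm Number of permutations (reference analysis: 5,000).
#' @param seed Integer seed.
#' @param cap Absolute cap for infinite log2 fold changes.
#' @return Tibble `anchor_category`, `site_class`, `observed`,
#'   `null_mean`, `null_sd`, `log2fc`, `capped`, `p_enrich`,
#'   `p_deplete`, `p_two`, `fdr_q`.
#' @export
shuffle_and_test <- function(ep, compartments, n_perm = 5000L, seed = 1L,
                             cap = 10) {
  hubs <- ep$hubs
  n_h <- nrow(hubs)
  if (length(compartments) != n_h) {
    abort("`compartments` must give one label per hub.")
  }
  a_cats <- sort(unique(ep$anchor_categories$category))
  s_cls <- sort(unique(ep$site_class_counts$class))
  if (!length(a_cats) || !length(s_cls)) {
    abort("No typed anchors or contact sites to test.")
  }
  A <- matrix(0L, n_h, length(a_cats), dimnames = list(NULL, a_cats))
  A[cbind(ep$anchor_categories$hub_id,
          match(ep$anchor_categories$category, a_cats))] <- 1L
  S <- matrix(0L, n_h, length(s_cls), dimnames = list(NULL, s_cls))
  S[cbind(ep$site_class_counts$hub_id,
          match(ep$site_class_counts$class, s_cls))] <-
    ep$site_class_counts$n

  observed <- crossprod(A, S)
  comp_idx <- split(seq_len(n_h), compartments)
  small <- names(comp_idx)[lengths(comp_idx) < 2]
  if (length(small)) {
    warn(sprintf("Compartment(s) %s have < 2 hubs and are not shuffled.",
                 paste(small, collapse = ", ")))
  }
  null_tot <- array(0, c(length(a_cats), length(s_cls), n_perm))
  with_seed(seed, {
    for (k in seq_len(n_perm)) {
      perm <- seq_len(n_h)
      for (idx in comp_idx) {
        if (length(idx) >= 2) perm[idx] <- idx[sample.int(length(idx))]
      }
      null_tot[, , k] <- crossprod(A, S[perm, , drop = FALSE])
    }
  })
  obs_m <- observed
  res <- tidyr::crossing(ai = seq_along(a_cats), si = seq_along(s_cls)) |>
    mutate(
      anchor_category = a_cats[ai],
      site_class = s_cls[si],
      observed = obs_m[cbind(ai, si)],
      null_mean = purrr::map2_dbl(ai, si, function(a, s) mean(null_tot[a, s, ])),
      null_sd = purrr::map2_dbl(ai, si, function(a, s) stats::sd(null_tot[a, s, ])),
      p_enrich = purrr::map2_dbl(ai, si, function(a, s) {
        (1 + sum(null_tot[a, s, ] >= obs_m[a, s])) / (1 + n_perm)
      }),
      p_deplete = purrr::map2_dbl(ai, si, function(a, s) {
        (1 + sum(null_tot[a, s, ] <= obs_m[a, s])) / (1 + n_perm)
      }),
      capped = null_mean == 0 | observed == 0,
      log2fc = dplyr::case_when(
        null_mean > 0 & observed > 0 ~ log2(observed / null_mean),
        null_mean == 0 & observed == 0 ~ 0,
        null_mean == 0 ~ cap,
        TRUE ~ -cap
      ),
      p_two = pmin(2 * pmin(p_enrich, p_deplete), 1),
      fdr_q = stats::p.adjust(p_two, method = "BH")
    ) |>
    select(-ai, -si)
  res
}

#' Structure-filtered inter-chromosomal enhancer-promoter enrichment
#'
#' Trans contacts are kept only when the contacted beads lie within
#' `max_dist` bead radii in the cell's 3D structure (minimum over
#' models); the filtered contacts are pooled across cells, each typed by
#' the promoter gene group at one end and the enhancer class at the
#' other (element within `flank` of the contact position, inclusive).
#' The null randomly re-assigns promoter and enhancer identities within
#' their A/B compartment and recounts; empirical p and BH-FDR as in
#' [shuffle_and_test()].
#'
#' @param contacts Contact tibble with a `cell_id` column.
#' @param ensembles Named list of `structure_ensemble`s, one per cell.
#' @param promoters Tibble `chrom`, `pos`, `group`, `compartment`.
#' @param enhancers Tibble `chrom`, `pos`, `class`, `compartment`.
#' @param assembly A `genome_assembly`.
#' @param max_dist Structure-support cutoff in bead radii.
#' @param flank Element-to-contact matching distance in bp (inclusive).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `result` (enrichment tibble as in
#'   [shuffle_and_test()]), `n_kept`, `n_filtered`, `n_no_structure`.
#' @export
interchrom_ep_contacts <- function(contacts, ensembles, promoters, enhancers,
                                   assembly, max_dist = 3.5, flank = 20e3,
                                   n_perm = 5000L, seed = 1L) {
  trans <- filter(contacts, chromA != chromB)
  n_no_structure <- sum(!trans$cell_id %in% names(ensembles))
  if (n_no_structure > 0) {
    inform(sprintf("%d trans contact(s) from cells without structures dropped.",
                   n_no_structure))
  }
  trans <- filter(trans, cell_id %in% names(ensembles))
  keep <- vapply(seq_len(nrow(trans)), function(i) {
    ens <- ensembles[[trans$cell_id[i]]]
    bi <- global_bead(trans$chromA[i], trans$posA[i], assembly, ens$bin_size)
    bj <- global_bead(trans$chromB[i], trans$posB[i], assembly, ens$bin_size)
    dmin <- min(vapply(seq_len(n_models(ens)), function(m) {
      sqrt(sum((ens$coords[m, bi, ] - ens$coords[m, bj, ])^2))
    }, numeric(1)))
    dmin < max_dist
  }, logical(1))
  kept <- trans[keep, , drop = FALSE]

  # match each kept contact to (promoter, enhancer) identities
  match_pairs <- purrr::map(seq_len(nrow(kept)), function(i) {
    ends <- list(c(kept$chromA[i], kept$posA[i]),
                 c(kept$chromB[i], kept$posB[i]))
    for (ord in list(c(1, 2), c(2, 1))) {
      pi <- which(promoters$chrom == ends[[ord[1]]][1] &
                    abs(promoters$pos - as.double(ends[[ord[1]]][2])) <= flank)
      ei <- which(enhancers$chrom == ends[[ord[2]]][1] &
                    abs(enhancers$pos - as.double(ends[[ord[2]]][2])) <= flank)
      if (length(pi) && length(ei)) {
        return(tibble(promoter = pi[1], enhancer = ei[1]))
      }
    }
    NULL
  }) |> purrr::list_rbind()

  if (is.null(match_pairs) || nrow(match_pairs) == 0L) {
    abort("No structure-supported trans contacts join a promoter and an enhancer.")
  }
  p_groups <- sort(unique(promoters$group))
  e_classes <- sort(unique(enhancers$class))
  count_tab <- function(p_lab, e_lab) {
    tab <- table(factor(p_lab[match_pairs$promoter], levels = p_groups),
                 factor(e_lab[match_pairs$enhancer], levels = e_classes))
    unclass(tab)
  }
  observed <- count_tab(promoters$group, enhancers$class)
  null_tot <- array(0, c(length(p_groups), length(e_classes), n_perm))
  with_seed(seed, {
    for (k in seq_len(n_perm)) {
      pg <- promoters$group
      ec <- enhancers$class
      for (cc in unique(promoters$compartment)) {
        idx <- which(promoters$compartment == cc)
        pg[idx] <- pg[idx[sample.int(length(idx))]]
      }
      for (cc in unique(enhancers$compartment)) {
        idx <- which(enhancers$compartment == cc)
        ec[idx] <- ec[idx[sample.int(length(idx))]]
      }
      null_tot[, , k] <- count_tab(pg, ec)
    }
  })
  obs_m <- observed
  res <- tidyr::crossing(gi = seq_along(p_groups), ci = seq_along(e_classes)) |>
    mutate(
      group = p_groups[gi],
      class = e_classes[ci],
      observed = obs_m[cbind(gi, ci)],
      null_mean = purrr::map2_dbl(gi, ci, function(g, c) mean(null_tot[g, c, ])),
      p_enrich = purrr::map2_dbl(gi, ci, function(g, c) {
        (1 + sum(null_tot[g, c, ] >= obs_m[g, c])) / (1 + n_perm)
      }),
      p_deplete = purrr::map2_dbl(gi, ci, function(g, c) {
        (1 + sum(null_tot[g, c, ] <= obs_m[g, c])) / (1 + n_perm)
      }),
      log2fc = ifelse(observed > 0 & null_mean > 0, log2(observed / null_mean),
                      ifelse(observed == null_mean, 0,
                             sign(observed - null_mean) * 10)),
      p_two = pmin(2 * pmin(p_enrich, p_deplete), 1),
      fdr_q = stats::p.adjust(p_two, method = "BH")
    ) |>
    select(-gi, -ci)
  list(result = res, n_kept = nrow(kept), n_filtered = sum(!keep),
       n_no_structure = n_no_structure)
}

#' Cluster hub chromatin-state profiles
#'
#' For every hub, the mean mark-abundance vector over its contact sites
#' (peak intensities within `flank` of each site, averaged) forms one
#' row of the contact-profile matrix; rows are ordered by Ward
#' hierarchical clustering.  The anchor-profile matrix (same per-mark
#' vectors at the anchor centre) keeps the identical row order so the
#' two heatmaps stay aligned hub-for-hub.
#'
#' @param hubs Hub tibble (retained rows; `chrom`, `center`, `sites`).
#' @param mark_tracks Tibble `mark`, `chrom`, `start`, `end`,
#'   `intensity` of read-abundance per mark.
#' @param flank Matching distance in bp.
#' @param k Number of clusters to cut (optional; `NULL` skips cutting).
#' @return List with `contact_profile`, `anchor_profile` (matrices in
#'   clustered row order), `order`, `hclust`, `cluster` (if `k` given),
#'   `hub_id` (row identity).
#' @export
hub_state_profiles <- function(hubs, mark_tracks, flank = 20e3, k = NULL) {
  if ("retained" %in% names(hubs)) hubs <- filter(hubs, retained)
  marks <- sort(unique(mark_tracks$mark))
  profile_at <- function(chrom, pos) {
    vapply(marks, function(mk) {
      t <- mark_tracks[mark_tracks$mark == mk & mark_tracks$chrom == chrom, ]
      hit <- abs((t$start + t$end) / 2 - pos) <= flank
      if (any(hit)) mean(t$intensity[hit]) else 0
    }, numeric(1))
  }
  rows <- purrr::map(seq_len(nrow(hubs)), function(i) {
    s <- hubs$sites[[i]]
    if (is.null(s) || nrow(s) == 0L) return(NULL)
    site_prof <- vapply(seq_len(nrow(s)), function(j) {
      profile_at(s$chrom[j], s$pos[j])
    }, numeric(length(marks)))
    list(hub = i,
         contact = rowMeans(matrix(site_prof, nrow = length(marks))),
         anchor = profile_at(hubs$chrom[i], hubs$center[i]))
  })
  rows <- purrr::compact(rows)
  if (length(rows) < 2L) abort("Need >= 2 hubs with typed sites to cluster.")
  contact <- do.call(rbind, lapply(rows, `[[`, "contact"))
  anchor <- do.call(rbind, lapply(rows, `[[`, "anchor"))
  colnames(contact) <- colnames(anchor) <- marks
  hc <- stats::hclust(stats::dist(contact), method = "ward.D2")
  ord <- hc$order
  out <- list(
    contact_profile = contact[ord, , drop = FALSE],
    anchor_profile = anchor[ord, , drop = FALSE],
    order = ord, hclust = hc,
    hub_id = vapply(rows, `[[`, numeric(1), "hub")[ord]
  )
  if (!is.null(k)) out$cluster <- stats::cutree(hc, k = k)[ord]
  out
}
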
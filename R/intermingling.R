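#' Per-bead proximal neighbour sets from a structure ensemble
#'
#' A bead's neighbour set contains every other bead that lies within
#' `proximity_radius` (centre-centre) in ALL models of the ensemble.
#' Beads whose position is not well determined — per-bead RMSD across
#' the aligned models of at least `precision_rmsd` — are excluded and
#' reported as `NA`; a neighbour relation requires both beads to pass.
#'
#' @param ensemble A `structure_ensemble` (M >= 1; precision filtering
#'   needs M >= 2 and is skipped with a message for M = 1).
#' @param proximity_radius Proximity threshold in bead radii (default 2).
#' @param precision_rmsd Precision threshold in bead radii (default 1.5).
#' @return List with `neighbors` (logical n x n matrix; `NA` rows/cols
#'   for imprecise beads), `precise` (logical per bead), and `bead_rmsd`.
#' @export
proximity_sets <- function(ensemble, proximity_radius = 2,
                           precision_rmsd = 1.5) {
  M <- n_models(ensemble)
  if (M == 0) abort("Ensemble has no models.")
  n <- n_beads(ensemble)
  if (M >= 2) {
    al <- align_ensemble(ensemble)
    bead_rmsd <- al$bead_rmsd
    precise <- bead_rmsd < precision_rmsd
  } else {
    inform("Single-model ensemble: precision filter skipped.")
    bead_rmsd <- rep(NA_real_, n)
    precise <- rep(TRUE, n)
  }
  within <- matrix(TRUE, n, n)
  for (m in seq_len(M)) {
    # the 1e-9 guard makes the strict inequality stable for pairs that
    # sit exactly at the radius (e.g. bonded beads at one diameter)
    within <- within & (model_dist(ensemble, m) < proximity_radius - 1e-9)
  }
  diag(within) <- FALSE
  within[!precise, ] <- NA
  within[, !precise] <- NA
  list(neighbors = within, precise = precise, bead_rmsd = bead_rmsd)
}

#' Raw inter-chromosomal intermingling scores
#'
#' For each bead, the fraction of its proximal neighbour set that lies on
#' other chromosomes (with uniform bins, summed genomic length reduces to
#' bead counting).  Beads with an empty or undefined neighbour set score
#' `NA`.
#'
#' @param prox Output of [proximity_sets()].
#' @param layout Bead layout tibble (`bead`, `chrom`, `start`), e.g.
#'   `ensemble$layout`.
#' @return Tibble `bead`, `chrom`, `start`, `n_neighbors`, `n_trans`,
#'   `score`.
#' @export
intermingling_score <- function(prox, layout) {
  nb <- prox$neighbors
  chrom <- layout$chrom
  res <- vapply(seq_len(nrow(nb)), function(b) {
    row <- nb[b, ]
    if (anyNA(row) && !prox$precise[b]) return(c(NA_real_, NA_real_))
    set <- which(!is.na(row) & row)
    if (!length(set)) return(c(0, NA_real_))
    c(length(set), sum(chrom[set] != chrom[b]))
  }, numeric(2))
  tibble(
    bead = layout$bead, chrom = chrom, start = layout$start,
    n_neighbors = ifelse(is.na(res[1, ]), NA_integer_, as.integer(res[1, ])),
    n_trans = as.integer(res[2, ]),
    score = ifelse(is.na(res[2, ]) | res[1, ] == 0, NA_real_,
                   res[2, ] / res[1, ])
  )
}

#' Quantile-normalise per-cell tracks, aggregate, and group loci
#'
#' Scores from individual cells are quantile-normalised to a common
#' reference (the mean of the sorted per-cell distributions), the median
#' across cells is taken per locus, and non-`NA` loci are partitioned
#' into `n_groups` equal-sized ordered groups (lowest 10%, 10-20%, ...)
#' by their median score.
#'
#' @param tracks List of per-cell score tibbles from
#'   [intermingling_score()] (same bead layout).
#' @param n_groups Number of groups (5 or 10 are the conventional
#'   choices).
#' @return Tibble `bead`, `chrom`, `start`, per-cell normalised scores in
#'   a list-column `normalized`, `median_score`, `group` (1 = least
#'   intermingled; `NA` loci excluded from grouping).
#' @export
normalize_and_aggregate <- function(tracks, n_groups = 10) {
  if (length(tracks) < 1) abort("Need at least one cell.")
  scores <- vapply(tracks, function(t) t$score, numeric(nrow(tracks[[1]])))
  scores <- matrix(scores, nrow = nrow(tracks[[1]]))
  normalized <- quantile_normalize(scores)
  med <- apply(normalized, 1, function(r) {
    if (all(is.na(r))) NA_real_ else stats::median(r, na.rm = TRUE)
  })
  out <- tracks[[1]][c("bead", "chrom", "start")]
  out$normalized <- lapply(seq_len(nrow(out)), function(i) normalized[i, ])
  out$median_score <- med
  out$group <- NA_integer_
  ok <- which(!is.na(med))
  if (length(ok)) {
    ord <- ok[order(med[ok])]
    grp <- ceiling(seq_along(ord) / (length(ord) / n_groups))
    out$group[ord] <- pmin(as.integer(grp), n_groups)
  }
  as_tibble(out)
}

# Column-wise quantile normalisation to the mean sorted distribution,
# NA-tolerant: each column's non-NA values are rank-mapped onto the
# reference quantiles.
quantile_normalize <- function(m) {
  n_ok <- colSums(!is.na(m))
  ref_n <- max(n_ok)
  sorted <- vapply(seq_len(ncol(m)), function(j) {
    v <- sort(m[, j][!is.na(m[, j])])
    if (length(v) == 0) return(rep(NA_real_, ref_n))
    stats::approx(seq_along(v) / length(v), v,
                  xout = seq_len(ref_n) / ref_n, rule = 2)$y
  }, numeric(ref_n))
  ref <- rowMeans(matrix(sorted, nrow = ref_n), na.rm = TRUE)
  out <- m
  for (j in seq_len(ncol(m))) {
    ok <- !is.na(m[, j])
    if (!any(ok)) next
    r <- rank(m[ok, j], ties.method = "average")
    out[ok, j] <- stats::approx(seq_len(ref_n) / ref_n, ref,
                                xout = r / sum(ok), rule = 2)$y
  }
  out
}

#' Feature enrichment across intermingling strata
#'
#' Two modes mirror the analyses relating genomic features to
#' intermingling level: `"logfc"` compares feature density between the
#' top 30% and bottom 30% most intermingled loci (log2 fold change);
#' `"fisher"` runs a 2x2 Fisher's exact test of feature/non-feature
#' membership in the highest vs lowest group.
#'
#' @param track Output of [normalize_and_aggregate()].
#' @param feature_bins Integer bead indices carrying the feature.
#' @param mode `"logfc"` or `"fisher"`.
#' @param cap Absolute cap for infinite log fold changes.
#' @return One-row tibble with `log2fc` (and `capped` flag) or the
#'   Fisher table counts, `p`, and `odds_ratio`.
#' @export
feature_enrichment <- function(track, feature_bins, mode = c("logfc", "fisher"),
                               cap = 10) {
  mode <- match.arg(mode)
  ok <- filter(track, !is.na(median_score))
  if (nrow(ok) == 0L) abort("No scored loci.")
  has_feat <- ok$bead %in% feature_bins
  if (mode == "logfc") {
    qs <- stats::quantile(ok$median_score, c(0.3, 0.7))
    bottom <- ok$median_score <= qs[1]
    top <- ok$median_score >= qs[2]
    if (!any(top) || !any(bottom)) abort("Empty stratum.")
    d_top <- mean(has_feat[top]); d_bot <- mean(has_feat[bottom])
    capped <- d_top == 0 || d_bot == 0
    lfc <- if (capped) sign(d_top - d_bot) * cap else log2(d_top / d_bot)
    tibble(mode = "logfc", density_top = d_top, density_bottom = d_bot,
           log2fc = lfc, capped = capped)
  } else {
    hi <- ok$group == max(ok$group, na.rm = TRUE)
    lo <- ok$group == min(ok$group, na.rm = TRUE)
    if (!any(hi) || !any(lo)) abort("Empty stratum.")
    tab <- matrix(c(sum(has_feat[hi]), sum(!has_feat[hi]),
                    sum(has_feat[lo]), sum(!has_feat[lo])), 2,
                  dimnames = list(c("feature", "no_feature"), c("high", "low")))
    ft <- stats::fisher.test(tab)
    tibble(mode = "fisher",
           feat_high = tab[1, 1], nofeat_high = tab[2, 1],
           feat_low = tab[1, 2], nofeat_low = tab[2, 2],
           odds_ratio = unname(ft$estimate), p = ft$p.value)
  }
}

#' Inverse-distance trans density for hub 3D localisation
#'
#' For each bead, the sum over beads on other chromosomes of one over the
#' centre-centre distance, averaged over the structure replicas.  The
#' track is scaled so the median of the all-bead background distribution
#' equals 1.00 exactly; per-class (A / B / hub) scaled-density
#' distributions are returned for histogramming.
#'
#' @param ensemble A `structure_ensemble`.
#' @param class_labels Character per bead (`"A"`, `"B"`, `"hub"`, or
#'   `NA`); beads keep their density regardless of label.
#' @return List with `track` (tibble: `bead`, `chrom`, `start`, `class`,
#'   `density`, `scaled_density`) and `by_class` (tibble of scaled
#'   densities with class labels, background median = 1).
#' @export
trans_density <- function(ensemble, class_labels = NULL) {
  n <- n_beads(ensemble)
  chrom <- ensemble$layout$chrom
  class_labels <- class_labels %||% rep(NA_character_, n)
  if (length(class_labels) != n) abort("`class_labels` must have one entry per bead.")
  M <- n_models(ensemble)
  acc <- numeric(n)
  trans_mask <- outer(chrom, chrom, `!=`)
  dropped <- 0L
  for (m in seq_len(M)) {
    d <- model_dist(ensemble, m)
    inv <- ifelse(trans_mask, 1 / d, 0)
    zero <- trans_mask & d == 0
    if (any(zero)) {
      dropped <- dropped + sum(zero) / 2
      inv[zero] <- 0
    }
    acc <- acc + rowSums(inv)
  }
  if (dropped > 0) {
    warn(sprintf("%d coincident trans bead pair(s) excluded from the density.",
                 dropped))
  }
  density <- acc / M
  med <- stats::median(density)
  if (med == 0) abort("Background density median is zero; cannot scale.")
  scaled <- density / med
  track <- tibble(bead = ensemble$layout$bead, chrom = chrom,
                  start = ensemble$layout$start,
                  class = class_labels, density = density,
                  scaled_density = scaled)
  list(track = track,
       by_class = filter(track, !is.na(class))[c("bead", "class", "scaled_density")])
}
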
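#' Bin a contact list into a dense symmetric matrix
#'
#' @param contacts Contact tibble.
#' @param assembly A `genome_assembly`.
#' @param bin_size Bin size in bp (default 25 kb, the compartment-analysis
#'   resolution).
#' @param chrom Optional chromosome; when given only that chromosome's
#'   intra-chromosomal block is returned.
#' @return Dense symmetric count matrix over genome (or chromosome) bins.
#' @export
contacts_to_matrix <- function(contacts, assembly, bin_size = 25e3,
                               chrom = NULL) {
  assert_assembly(assembly)
  if (!is.null(chrom)) {
    contacts <- filter(contacts, chromA == chrom, chromB == chrom)
    assembly <- assembly[assembly$chrom == chrom, ]
    class(assembly) <- c("genome_assembly", "tbl_df", "tbl", "data.frame")
  }
  n <- sum(as.integer(assembly$length / bin_size))
  m <- matrix(0, n, n)
  if (nrow(contacts) > 0) {
    bi <- global_bead(contacts$chromA, contacts$posA, assembly, bin_size)
    bj <- global_bead(contacts$chromB, contacts$posB, assembly, bin_size)
    for (k in seq_along(bi)) {
      m[bi[k], bj[k]] <- m[bi[k], bj[k]] + 1
      if (bi[k] != bj[k]) m[bj[k], bi[k]] <- m[bj[k], bi[k]] + 1
    }
  }
  m
}

#' Contact-probability scaling curve
#'
#' Log-binned contact probability against intra-chromosomal sequence
#' separation; probabilities are normalised to sum to 1 over separation
#' bins (per-bin counts divided by the total intra count), so curves from
#' cells with different depths are comparable.
#'
#' @param x Contact tibble (only intra-chromosomal pairs are used) or an
#'   intra-chromosomal count matrix.
#' @param n_bins Number of logarithmic separation bins.
#' @param min_separation Smallest separation tracked (bp).
#' @param ... Passed to methods.
#' @return Tibble `sep_lo`, `sep_hi`, `sep_mid` (geometric mid), `count`,
#'   `prob`.
#' @export
scaling_curve <- function(x, n_bins = 25, min_separation = 10e3, ...) {
  UseMethod("scaling_curve")
}

#' @rdname scaling_curve
#' @export
scaling_curve.data.frame <- function(x, n_bins = 25, min_separation = 10e3, ...) {
  sep <- with(filter(x, chromA == chromB), abs(posB - posA))
  scaling_from_separations(sep, n_bins, min_separation)
}

#' @rdname scaling_curve
#' @param bin_size Bin size in bp (matrix method; separations are taken
#'   at bin resolution).
#' @export
scaling_curve.matrix <- function(x, n_bins = 25, min_separation = 10e3,
                                 bin_size, ...) {
  n <- nrow(x)
  sep <- unlist(lapply(1:(n - 1), function(d) {
    idx <- cbind(seq_len(n - d), seq_len(n - d) + d)
    rep(d * bin_size, sum(x[idx]))
  }))
  scaling_from_separations(sep, n_bins, min_separation)
}

scaling_from_separations <- function(sep, n_bins, min_separation) {
  sep <- sep[sep >= min_separation]
  if (length(sep) == 0L) abort("No intra-chromosomal contacts above `min_separation`.")
  breaks <- exp(seq(log(min_separation), log(max(sep) + 1), length.out = n_bins + 1))
  idx <- findInterval(sep, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  tibble(
    sep_lo = breaks[-length(breaks)],
    sep_hi = breaks[-1],
    sep_mid = sqrt(sep_lo * sep_hi),
    count = counts,
    prob = counts / sum(counts)
  )
}

#' Fractions of contacts by sequence-separation class
#'
#' The six classes used for single-cell Hi-C QC profiles: intra
#' separations `<10 kb`, `10-100 kb`, `100 kb-1 Mb`, `1-5 Mb`, `>5 Mb`
#' (all half-open `[low, high)`, so a contact at exactly 10 kb falls in
#' the second class) and `trans`.
#'
#' @param contacts Contact tibble.
#' @return Tibble `class` (ordered factor), `count`, `fraction`; the
#'   fractions sum to 1.
#' @export
separation_fractions <- function(contacts) {
  if (nrow(contacts) == 0L) abort("Empty contact list.")
  intra <- contacts$chromA == contacts$chromB
  sep <- abs(contacts$posB - contacts$posA)[intra]
  breaks <- c(0, 10e3, 100e3, 1e6, 5e6, Inf)
  labels <- c("<10 kb", "10-100 kb", "100 kb-1 Mb", "1-5 Mb", ">5 Mb")
  idx <- findInterval(sep, breaks)          # [low, high) by default
  counts <- c(tabulate(idx, nbins = 5), sum(!intra))
  tibble(
    class = factor(c(labels, "trans"), levels = c(labels, "trans")),
    count = counts,
    fraction = counts / sum(counts)
  )
}

#' Distance-normalise an intra-chromosomal matrix (observed / expected)
#'
#' Divides each entry by the mean of its diagonal (the average contact
#' score between bin pairs at the same sequence separation), removing the
#' dominant distance decay.  Zeros stay zero; all-zero diagonals are left
#' untouched.
#'
#' @param m Square symmetric non-negative matrix.
#' @return The observed/expected matrix.
#' @export
normalize_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) abort("`m` must be square.")
  if (all(m == 0)) abort("All-zero matrix cannot be normalised.")
  n <- nrow(m)
  out <- m
  for (d in 0:(n - 1)) {
    idx <- cbind(seq_len(n - d), seq_len(n - d) + d)
    mu <- mean(m[idx])
    if (mu > 0) {
      out[idx] <- m[idx] / mu
      if (d > 0) out[idx[, 2:1, drop = FALSE]] <- out[idx]
    }
  }
  out
}

#' Per-bin compartment scores and A/B labels
#'
#' Leading eigenvector of the bin-bin Pearson correlation matrix of the
#' observed/expected matrix, the standard continuous compartment-strength
#' score.  The sign is oriented so that positive scores correlate with
#' `orientation_track` (e.g. a gene-density or planted-A indicator
#' track); positive = A.
#'
#' @param norm_m Observed/expected matrix for one chromosome.
#' @param orientation_track Numeric vector, one value per bin, higher in
#'   A-like bins.
#' @return Tibble `bin`, `score`, `label` (`"A"`, `"B"`, or `NA` for bins
#'   with no signal).
#' @export
compartment_scores <- function(norm_m, orientation_track) {
  n <- nrow(norm_m)
  if (length(orientation_track) != n) {
    abort("`orientation_track` must have one value per bin.")
  }
  ok <- apply(norm_m, 1, function(r) stats::sd(r) > 0)
  score <- rep(NA_real_, n)
  if (sum(ok) >= 2) {
    cm <- suppressWarnings(stats::cor(norm_m[ok, ok, drop = FALSE]))
    cm[!is.finite(cm)] <- 0
    ev <- eigen(cm, symmetric = TRUE)
    v <- ev$vectors[, 1]
    s <- suppressWarnings(stats::cor(v, orientation_track[ok]))
    if (is.finite(s) && s < 0) v <- -v
    score[ok] <- v
  }
  tibble(
    bin = seq_len(n),
    score = score,
    label = dplyr::case_when(is.na(score) ~ NA_character_,
                             score > 0 ~ "A", score < 0 ~ "B",
                             TRUE ~ NA_character_)
  )
}

#' Saddle analysis of compartmentalisation
#'
#' Bins are ordered by compartment score (most-B to most-A) and cut into
#' `n_groups` equal-sized groups; the saddle matrix holds the mean
#' observed/expected contact between every pair of groups.  Corner
#' summaries average the outer 20% x 20% of groups: `BB` (low-low),
#' `AA` (high-high), and the mixing corners `AB`/`BA`.  Corner averages
#' of both the contact enrichments and the (quantile-scale) scores are
#' reported.
#'
#' @param norm_m Observed/expected matrix.
#' @param scores Per-bin compartment scores (`NA` bins are dropped).
#' @param n_groups Number of score groups (>= 2).
#' @return List with `saddle` (`n_groups x n_groups` matrix), `corners`
#'   (tibble: corner, mean contact enrichment, mean score), and
#'   `mixing_ratio` (`(AA + BB) / (AB + BA)`).
#' @export
saddle <- function(norm_m, scores, n_groups = 10) {
  if (n_groups < 2) abort("`n_groups` must be >= 2.")
  if (length(scores) != nrow(norm_m)) abort("`scores` must cover matrix bins.")
  keep <- which(!is.na(scores))
  ord <- keep[order(scores[keep])]
  grp <- ceiling(seq_along(ord) / (length(ord) / n_groups))
  grp <- pmin(grp, n_groups)
  sad <- matrix(NA_real_, n_groups, n_groups)
  for (a in seq_len(n_groups)) {
    for (b in a:n_groups) {
      rows <- ord[grp == a]; cols <- ord[grp == b]
      block <- norm_m[rows, cols, drop = FALSE]
      if (a == b) {
        vals <- block[upper.tri(block, diag = FALSE)]
        if (!length(vals)) vals <- block
      } else {
        vals <- block
      }
      sad[a, b] <- sad[b, a] <- mean(vals)
    }
  }
  k <- max(1L, floor(0.2 * n_groups))
  lo <- seq_len(k); hi <- n_groups - k + seq_len(k)
  grp_score <- vapply(seq_len(n_groups), function(g) mean(scores[ord[grp == g]]),
                      numeric(1))
  corners <- tibble(
    corner = c("BB", "AA", "AB", "BA"),
    contact = c(mean(sad[lo, lo]), mean(sad[hi, hi]),
                mean(sad[lo, hi]), mean(sad[hi, lo])),
    score = c(mean(grp_score[lo]), mean(grp_score[hi]),
              mean(c(grp_score[lo], grp_score[hi])),
              mean(c(grp_score[hi], grp_score[lo])))
  )
  mixing <- (corners$contact[1] + corners$contact[2]) /
    (corners$contact[3] + corners$contact[4])
  list(saddle = sad, corners = corners, mixing_ratio = mixing)
}

#' Bootstrap standard deviation of a statistic
#'
#' SD of `statistic` over `n_samples` random subsamples (without
#' replacement) of `sample_fraction` of the data rows/elements — the
#' subsample-bootstrap used for saddle and hub-abundance error bars
#' (e.g. 200 samples of 20%, or 2,000 samples of 30%).
#'
#' @param statistic Function of a data subset returning one number.
#' @param data Vector or data frame; subsampling is over elements/rows.
#' @param n_samples Number of subsamples.
#' @param sample_fraction Fraction of the data per subsample.
#' @param seed Integer seed.
#' @return Scalar SD estimate.
#' @export
bootstrap_sd <- function(statistic, data, n_samples = 200,
                         sample_fraction = 0.2, seed = 1L) {
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  k <- floor(n * sample_fraction)
  if (k < 1) abort("Subsample too small for the statistic.")
  take <- if (is.data.frame(data)) {
    function(idx) data[idx, , drop = FALSE]
  } else {
    function(idx) data[idx]
  }
  with_seed(seed, {
    vals <- vapply(seq_len(n_samples), function(s) {
      statistic(take(sample.int(n, k)))
    }, numeric(1))
    stats::sd(vals)
  })
}
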
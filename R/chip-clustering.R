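#' Scaled H3K27me3 change-vector features per promoter
#'
#' For each gene, the intensity differences (24h - naive) and
#' (primed - 24h) are computed per replicate, then the whole change
#' vector is divided by the gene's maximum intensity across all time
#' points, making features invariant to per-gene intensity scale.
#' Genes with all-zero intensity are excluded.
#'
#' @param intensities Tibble `gene`, `timepoint` (naive / 24h / primed),
#'   `replicate`, `intensity` (non-negative).
#' @return Numeric matrix, genes x (2 * replicates), rownames = genes.
#' @export
trajectory_features <- function(intensities) {
  if (any(intensities$intensity < 0)) abort("Intensities must be non-negative.")
  tps <- c("naive", "24h", "primed")
  if (!all(tps %in% unique(intensities$timepoint))) {
    abort("Need intensities at naive, 24h and primed.")
  }
  wide <- intensities |>
    filter(timepoint %in% tps) |>
    tidyr::pivot_wider(id_cols = gene, names_from = c(timepoint, replicate),
                       values_from = intensity)
  reps <- sort(unique(intensities$replicate))
  genes <- wide$gene
  feat <- do.call(cbind, lapply(reps, function(r) {
    cbind(wide[[paste0("24h_", r)]] - wide[[paste0("naive_", r)]],
          wide[[paste0("primed_", r)]] - wide[[paste0("24h_", r)]])
  }))
  colnames(feat) <- as.vector(vapply(reps, function(r) {
    c(paste0("d24h_naive_r", r), paste0("dprimed_24h_r", r))
  }, character(2)))
  scale_max <- apply(do.call(cbind, lapply(tps, function(tp) {
    do.call(cbind, lapply(reps, function(r) wide[[paste0(tp, "_", r)]]))
  })), 1, max)
  keep <- scale_max > 0
  feat <- feat[keep, , drop = FALSE] / scale_max[keep]
  rownames(feat) <- genes[keep]
  feat
}

#' Cluster promoter trajectories with Ward linkage and a size-guarded cut
#'
#' Ward (ward.D2) agglomerative clustering on Euclidean distances
#' between change-vector features, cut by descending the dendrogram and
#' splitting a branch only while both children would keep at least
#' `min_cluster_size` members — a conservative analogue of a dynamic
#' hybrid cut at its shallowest split setting, which by construction
#' never produces an undersized cluster.  Ties are broken by input
#' order, so the result is deterministic.
#'
#' @param features Matrix from [trajectory_features()].
#' @param min_cluster_size Minimum cluster size (reference value 100).
#' @return Tibble `gene`, `cluster` (1-based, ordered by dendrogram).
#' @export
cluster_promoters <- function(features, min_cluster_size = 100) {
  n <- nrow(features)
  if (n < 2 * min_cluster_size) {
    warn("Too few genes to split; returning a single cluster.")
    return(tibble(gene = rownames(features), cluster = 1L))
  }
  hc <- stats::hclust(stats::dist(features), method = "ward.D2")
  labels <- size_guarded_cut(hc, n, min_cluster_size)
  tibble(gene = rownames(features), cluster = labels)
}

# Descend the merge tree from the root; a node splits into its two
# children iff both have >= min_size leaves, otherwise it becomes a
# cluster.  Returns integer labels in leaf order of the input.
size_guarded_cut <- function(hc, n, min_size) {
  merge <- hc$merge
  # leaves under each internal node
  members <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    kids <- merge[i, ]
    members[[i]] <- unlist(lapply(kids, function(k) {
      if (k < 0) -k else members[[k]]
    }))
  }
  labels <- integer(n)
  next_label <- 0L
  assign_node <- function(node) {
    # node > 0: internal; node < 0: singleton leaf
    if (node > 0) {
      kids <- merge[node, ]
      sizes <- vapply(kids, function(k) {
        if (k < 0) 1L else length(members[[k]])
      }, integer(1))
      if (all(sizes >= min_size)) {
        assign_node(kids[1])
        assign_node(kids[2])
        return(invisible())
      }
    }
    next_label <<- next_label + 1L
    leaves <- if (node > 0) members[[node]] else -node
    labels[leaves] <<- next_label
    invisible()
  }
  assign_node(nrow(merge))
  labels
}

#' Track bivalent promoter formation and resolution
#'
#' Classifies each promoter's bivalency trajectory over (naive, 24h,
#' primed) from per-time-point H3K4me3/H3K27me3 presence calls:
#' `always_bivalent`, `formed_24h_maintained` (bivalent from 24h on,
#' not at naive), `bivalent_only_naive`, `bivalent_only_primed`,
#' `never_bivalent`, and `other_transition` for the remaining patterns.
#' Monovalent states at each time point are recorded alongside.
#'
#' @param marks Tibble `gene`, `timepoint`, `k4me3`, `k27me3` (logical),
#'   covering all three time points for every gene.
#' @return Tibble `gene`, `state_naive`, `state_24h`, `state_primed`,
#'   `trajectory`.
#' @export
track_bivalency <- function(marks) {
  tps <- c("naive", "24h", "primed")
  state_of <- function(k4, k27) {
    dplyr::case_when(k4 & k27 ~ "bivalent", k4 ~ "k4_only",
                     k27 ~ "k27_only", TRUE ~ "none")
  }
  wide <- marks |>
    mutate(state = state_of(k4me3, k27me3)) |>
    tidyr::pivot_wider(id_cols = gene, names_from = timepoint,
                       values_from = state)
  if (!all(tps %in% names(wide))) abort("Need calls at naive, 24h and primed.")
  b <- function(tp) wide[[tp]] == "bivalent"
  wide |>
    transmute(
      gene,
      state_naive = naive, state_24h = `24h`, state_primed = primed,
      trajectory = dplyr::case_when(
        b("naive") & b("24h") & b("primed") ~ "always_bivalent",
        !b("naive") & b("24h") & b("primed") ~ "formed_24h_maintained",
        b("naive") & !b("24h") & !b("primed") ~ "bivalent_only_naive",
        !b("naive") & !b("24h") & b("primed") ~ "bivalent_only_primed",
        !b("naive") & !b("24h") & !b("primed") ~ "never_bivalent",
        TRUE ~ "other_transition"
      )
    )
}
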
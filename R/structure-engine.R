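#' Convert a contact list into a distance-restraint set
#'
#' One flat-bottom restraint per distinct contacted bead pair (duplicate
#' contacts collapse; self-pairs are dropped), plus backbone restraints
#' between sequence-adjacent beads of each chromosome.  Bounds follow a
#' flat-bottom harmonic with lower 0.8 and upper 1.2 bead diameters
#' around a 1-diameter target (1.6 / 2.0 / 2.4 in bead radii), the
#' standard tolerance for contact-radius ambiguity in restraint-based
#' genome structure calculation.
#'
#' @param contacts Canonicalised contact tibble.
#' @param assembly A `genome_assembly`.
#' @param bin_size Bead size in bp (defaults to the assembly's).
#' @return A `restraint_set` tibble (`i`, `j`, `target`, `lower`,
#'   `upper`, `backbone`) with the bead layout attached as attributes.
#' @export
contacts_to_restraints <- function(contacts, assembly, bin_size = NULL) {
  assert_assembly(assembly)
  bs <- bin_size %||% attr(assembly, "bin_size")
  if (any(assembly$length %% bs != 0)) {
    abort("`bin_size` must divide every chromosome length.")
  }
  layout <- bead_layout(assembly, bs)
  backbone <- layout |>
    group_by(chrom) |>
    reframe(i = bead[-dplyr::n()], j = bead[-1]) |>
    transmute(i, j, backbone = TRUE)

  data_res <- if (nrow(contacts) > 0) {
    bi <- global_bead(contacts$chromA, contacts$posA, assembly, bs)
    bj <- global_bead(contacts$chromB, contacts$posB, assembly, bs)
    tibble(i = pmin(bi, bj), j = pmax(bi, bj)) |>
      filter(i != j) |>
      distinct() |>
      mutate(backbone = FALSE)
  }
  out <- bind_rows(data_res, backbone) |>
    distinct(i, j, .keep_all = TRUE) |>      # adjacent-bead contacts fold into backbone row order
    mutate(target = 2, lower = 1.6, upper = 2.4) |>
    select(i, j, target, lower, upper, backbone) |>
    arrange(i, j)
  attr(out, "layout") <- layout
  attr(out, "n_beads") <- nrow(layout)
  attr(out, "bin_size") <- bs
  attr(out, "assembly") <- assembly
  class(out) <- c("restraint_set", class(out))
  out
}

default_schedule <- function() {
  list(
    ladder = c(8L, 4L, 2L, 1L),
    temp_high = 25, temp_factor = 0.6, n_temps = 14L,
    steps_per_temp = 800L, dt = 0.002, dt_min = 0.002, max_step = 0.4,
    minimize_steps = 3000L, level_cool = 1,
    bound_margin = 0.08,
    res_k = 60, rep_k = 50, rep_dist = 2, jitter = 0.1
  )
}

#' Anneal a restraint set into a structure ensemble
#'
#' Hierarchical simulated annealing of an initially random conformation:
#' restraints are coarse-grained onto a decreasing resolution ladder
#' (default 8x, 4x, 2x, 1x the target bin size); at each rung the polymer
#' is annealed through a geometric temperature ladder of overdamped
#' Langevin dynamics (flat-bottom restraint potential plus soft excluded
#' volume), then beads are subdivided with linear interpolation along the
#' chain and Gaussian jitter.  Each of the `n_models` models starts from
#' a different random conformation; a final zero-temperature descent
#' polishes each model.
#'
#' @param restraints A `restraint_set` from [contacts_to_restraints()].
#' @param n_models Number of replica models.
#' @param schedule Optional named list overriding the default annealing
#'   schedule (`ladder`, `temp_high`, `temp_factor`, `n_temps`,
#'   `steps_per_temp`, `dt`, `max_step`, `minimize_steps`, `res_k`,
#'   `rep_k`, `rep_dist`, `jitter`).
#' @param seed Integer seed; per-model seeds are derived from it.
#' @return A `structure_ensemble` with `n_models` models.
#' @export
anneal <- function(restraints, n_models = 10L, schedule = NULL, seed = 1L) {
  if (!inherits(restraints, "restraint_set")) {
    abort("`restraints` must come from contacts_to_restraints().")
  }
  if (nrow(restraints) == 0L) abort("Empty restraint set.")
  sch <- utils::modifyList(default_schedule(), schedule %||% list())
  layout <- attr(restraints, "layout")
  if (!any(!restraints$backbone)) {
    warn("No data restraints; annealing a backbone-only fold.")
  }
  temps <- c(sch$temp_high * sch$temp_factor^(seq_len(sch$n_temps) - 1), 0)
  steps <- c(rep(sch$steps_per_temp, sch$n_temps), sch$minimize_steps)
  # shrink the timestep as the system cools: dense coordination makes
  # large steps unstable near the minimum
  dts <- c(exp(seq(log(sch$dt), log(sch$dt_min), length.out = sch$n_temps)),
           sch$dt_min)

  models <- lapply(seq_len(n_models), function(m) {
    with_seed(derive_seed(seed, m), {
      anneal_one(restraints, layout, sch, temps, steps, dts)
    })
  })
  coords <- array(NA_real_, c(n_models, nrow(layout), 3))
  for (m in seq_len(n_models)) coords[m, , ] <- models[[m]]
  structure_ensemble(coords, layout, attr(restraints, "bin_size"))
}

anneal_one <- function(restraints, layout, sch, temps, steps, dts) {
  chrom <- layout$chrom
  n_fine <- nrow(layout)
  fine_idx <- layout |> group_by(chrom) |> mutate(within = dplyr::row_number()) |>
    ungroup()
  ladder <- sort(unique(c(pmax(sch$ladder, 1L), 1L)), decreasing = TRUE)

  coords <- NULL
  prev_group <- NULL
  level <- 0L
  for (f in ladder) {
    grp <- make_groups(fine_idx, f)              # fine bead -> coarse bead id
    n_coarse <- max(grp$coarse)
    res <- coarsen_restraints(restraints, grp$coarse, grp$chrom_of)

    if (is.null(coords)) {
      r_start <- (n_coarse / 0.1)^(1 / 3)
      coords <- matrix(rnorm(n_coarse * 3, 0, r_start / 2), ncol = 3)
    } else {
      coords <- subdivide_coords(coords, prev_group, grp, sch$jitter)
    }
    # forces drive pairs a small margin inside the flat bottom, so the
    # equilibrium against excluded-volume pressure lands within bounds
    # rather than exactly on the edge
    t_cap <- max(temps) * sch$level_cool^level
    run <- which(temps <= t_cap + 1e-12)
    for (s in run) {
      coords <- anneal_core(coords, res$i - 1L, res$j - 1L,
                            res$lower + sch$bound_margin,
                            res$upper - sch$bound_margin,
                            temps[s], as.integer(steps[s]),
                            dts[s], sch$rep_dist, sch$rep_k, sch$res_k,
                            sch$max_step)
    }
    prev_group <- grp
    level <- level + 1L
  }
  coords
}

# Coarse-grain fine beads by factor f within each chromosome; coarse ids
# are global and chain-ordered.
make_groups <- function(fine_idx, f) {
  key <- fine_idx |>
    mutate(cg = ceiling(within / f)) |>
    group_by(chrom) |>
    mutate(cg = cg) |>
    ungroup()
  lab <- paste(key$chrom, key$cg)
  coarse <- match(lab, unique(lab))
  list(coarse = coarse, chrom_of = key$chrom[!duplicated(lab)],
       fine_chrom = key$chrom)
}

coarsen_restraints <- function(restraints, coarse, chrom_of) {
  ci <- coarse[restraints$i]
  cj <- coarse[restraints$j]
  keep <- ci != cj
  res <- tibble(i = pmin(ci, cj)[keep], j = pmax(ci, cj)[keep]) |> distinct()
  # backbone between adjacent coarse beads of the same chromosome
  n_coarse <- length(chrom_of)
  bb <- tibble(i = seq_len(n_coarse - 1), j = seq_len(n_coarse - 1) + 1L) |>
    filter(chrom_of[i] == chrom_of[j])
  res <- bind_rows(res, bb) |> distinct(i, j)
  list(i = res$i, j = res$j,
       lower = rep(1.6, nrow(res)), upper = rep(2.4, nrow(res)))
}

# Place fine beads by linear interpolation of coarse-bead centres along
# the chain, rescaling coordinates for the smaller bead radius
# (radius ~ cube root of bead sequence length), plus Gaussian jitter.
subdivide_coords <- function(coords, prev_group, grp, jitter) {
  f_ratio <- length(unique(prev_group$coarse)) / length(unique(grp$coarse))
  scale <- (1 / f_ratio)^(1 / 3)  # > 1: expressed in smaller bead radii
  out <- matrix(NA_real_, max(grp$coarse), 3)
  for (ch in unique(grp$fine_chrom)) {
    sel_fine <- grp$fine_chrom == ch
    prev_ids <- unique(prev_group$coarse[sel_fine])
    new_ids <- unique(grp$coarse[sel_fine])
    # chain position of each bead: index of its first fine bead
    prev_pos <- vapply(prev_ids, function(id) mean(which(prev_group$coarse == id)),
                       numeric(1))
    new_pos <- vapply(new_ids, function(id) mean(which(grp$coarse == id)),
                      numeric(1))
    for (k in 1:3) {
      out[new_ids, k] <- if (length(prev_ids) < 2) {
        coords[prev_ids, k] * scale
      } else {
        stats::approx(prev_pos, coords[prev_ids, k] * scale,
                      xout = new_pos, rule = 2)$y
      }
    }
  }
  out + matrix(rnorm(length(out), 0, jitter), ncol = 3)
}

#' Align an ensemble and report per-bead RMSD
#'
#' Rigid-body superposition of every model onto the first, testing both
#' chiralities (global chirality is not determinable from distance data,
#' so the mirror image is allowed and the lower-RMSD alignment kept).
#' Per-bead RMSD is the root-mean-square deviation of each bead from its
#' across-model mean position, in bead radii.
#'
#' @param ensemble A `structure_ensemble`.
#' @return List with `ensemble` (aligned), `bead_rmsd` (per-bead, `NA`
#'   with a message for single-model ensembles), and `model_rmsd`
#'   (per-model RMSD to the reference).
#' @export
align_ensemble <- function(ensemble) {
  M <- n_models(ensemble)
  ref <- model_coords(ensemble, 1L)
  ref_c <- sweep(ref, 2, colMeans(ref))
  coords <- ensemble$coords
  coords[1, , ] <- ref_c
  model_rmsd <- c(0, numeric(M - 1))
  if (M >= 2) {
    for (m in 2:M) {
      fit <- superpose(model_coords(ensemble, m), ref_c, allow_reflection = TRUE)
      coords[m, , ] <- fit$coords
      model_rmsd[m] <- fit$rmsd
    }
  }
  aligned <- structure_ensemble(coords, ensemble$layout, ensemble$bin_size)
  bead_rmsd <- if (M >= 2) {
    mean_pos <- apply(coords, c(2, 3), mean)
    sqrt(vapply(seq_len(n_beads(ensemble)), function(b) {
      mean(rowSums((coords[, b, , drop = TRUE] -
                      matrix(mean_pos[b, ], M, 3, byrow = TRUE))^2))
    }, numeric(1)))
  } else {
    inform("Single-model ensemble: per-bead RMSD undefined, returning NA.")
    rep(NA_real_, n_beads(ensemble))
  }
  list(ensemble = aligned, bead_rmsd = bead_rmsd, model_rmsd = model_rmsd)
}

# Least-squares rigid superposition of P onto centred Q (Kabsch),
# optionally allowing an improper rotation.
superpose <- function(P, Q_centered, allow_reflection = TRUE) {
  Pc <- sweep(P, 2, colMeans(P))
  H <- crossprod(Pc, Q_centered)
  s <- svd(H)
  R_proper <- s$u %*% diag(c(1, 1, sign(det(s$u %*% t(s$v))))) %*% t(s$v)
  cand <- list(R_proper)
  if (allow_reflection) {
    R_any <- s$u %*% t(s$v)  # may be improper
    cand <- c(cand, list(R_any))
  }
  fits <- lapply(cand, function(R) {
    A <- Pc %*% R
    list(coords = A, rmsd = sqrt(mean(rowSums((A - Q_centered)^2))))
  })
  fits[[which.min(vapply(fits, `[[`, numeric(1), "rmsd"))]]
}

#' Report restraint violations for an ensemble
#'
#' @param ensemble A `structure_ensemble`.
#' @param restraints A `restraint_set` on the same bead layout.
#' @param include_backbone Include backbone restraints in the fractions.
#' @param tol Numerical slack on the bounds (beads settling exactly on a
#'   flat-bottom edge are satisfied).
#' @return List with `per_model` (tibble: `model`, `n_violated`,
#'   `fraction`) and `per_restraint` (tibble with the worst-case distance
#'   across models for each restraint).
#' @export
violation_report <- function(ensemble, restraints, include_backbone = TRUE,
                             tol = 1e-6) {
  if (nrow(restraints) == 0L) abort("Empty restraint set.")
  res <- if (include_backbone) restraints else filter(restraints, !backbone)
  if (nrow(res) == 0L) abort("No restraints left to check.")
  M <- n_models(ensemble)
  dists <- vapply(seq_len(M), function(m) {
    xyz <- model_coords(ensemble, m)
    sqrt(rowSums((xyz[res$i, , drop = FALSE] - xyz[res$j, , drop = FALSE])^2))
  }, numeric(nrow(res)))
  dists <- matrix(dists, nrow = nrow(res))
  viol <- dists < res$lower - tol | dists > res$upper + tol
  per_model <- tibble(
    model = seq_len(M),
    n_violated = colSums(viol),
    fraction = colSums(viol) / nrow(res)
  )
  excess <- pmax(res$lower - dists, dists - res$upper, 0)
  worst <- apply(excess, 1, max)
  per_restraint <- mutate(as_tibble(res), worst_excess = worst,
                          worst_distance = dists[cbind(seq_len(nrow(res)),
                                                       apply(excess, 1, which.max))])
  list(per_model = per_model, per_restraint = per_restraint)
}

#' Structural-consistency filter for noisy contacts
#'
#' Drops contacts whose bead pair exceeds `max_distance` in every model
#' of a preliminary (coarse) ensemble — the "likely close in space"
#' cleanup applied before final structure calculation.
#'
#' @param contacts Contact tibble.
#' @param ensemble A preliminary `structure_ensemble`.
#' @param assembly The `genome_assembly` the contacts live on.
#' @param max_distance Distance cutoff in bead radii (`Inf` keeps all).
#' @return The filtered tibble, with attribute `removed_fraction`.
#' @export
filter_noise_contacts <- function(contacts, ensemble, assembly,
                                  max_distance = 4) {
  if (nrow(contacts) == 0L) return(contacts)
  bs <- ensemble$bin_size
  bi <- global_bead(contacts$chromA, contacts$posA, assembly, bs)
  bj <- global_bead(contacts$chromB, contacts$posB, assembly, bs)
  keep <- rep(FALSE, nrow(contacts))
  for (m in seq_len(n_models(ensemble))) {
    xyz <- model_coords(ensemble, m)
    d <- sqrt(rowSums((xyz[bi, , drop = FALSE] - xyz[bj, , drop = FALSE])^2))
    keep <- keep | d <= max_distance
  }
  keep <- keep | bi == bj                     # same-bead contacts are trivially close
  out <- contacts[keep, , drop = FALSE]
  attr(out, "removed_fraction") <- 1 - mean(keep)
  out
}

#' Remove isolated (unsupported) contacts
#'
#' A spatially genuine contact is rarely alone: beads close in space
#' drag their chain neighbours along, so other contacts fall in the
#' surrounding bin neighbourhood.  A contact is kept when at least
#' `min_support` other contacts join bins within `support_bins` of both
#' of its end bins; uniform-random noise contacts almost never have
#' such support and are dropped before structure calculation.
#'
#' @param contacts Contact tibble.
#' @param assembly A `genome_assembly`.
#' @param bin_size Binning for the support test (defaults to the
#'   assembly's bin size).
#' @param support_bins Neighbourhood half-width in bins.
#' @param min_support Minimum number of supporting contacts.
#' @return Filtered tibble with attribute `removed_fraction`.
#' @export
filter_isolated_contacts <- function(contacts, assembly, bin_size = NULL,
                                     support_bins = 2L, min_support = 1L) {
  if (nrow(contacts) == 0L) return(contacts)
  bs <- bin_size %||% attr(assembly, "bin_size")
  bi <- global_bead(contacts$chromA, contacts$posA, assembly, bs)
  bj <- global_bead(contacts$chromB, contacts$posB, assembly, bs)
  lo <- pmin(bi, bj); hi <- pmax(bi, bj)
  n <- sum(as.integer(assembly$length / bs))
  support <- vapply(seq_len(nrow(contacts)), function(k) {
    near <- abs(lo - lo[k]) <= support_bins & abs(hi - hi[k]) <= support_bins
    sum(near) - 1L
  }, integer(1))
  keep <- support >= min_support
  out <- contacts[keep, , drop = FALSE]
  attr(out, "removed_fraction") <- 1 - mean(keep)
  out
}

#' Potential energy of a model under a restraint set
#'
#' Flat-bottom restraint energy plus soft excluded volume; used for the
#' annealing energy-decrease check and audit output.
#'
#' @param coords `n_beads x 3` matrix.
#' @param restraints A `restraint_set`.
#' @param schedule Optional schedule list (for force constants).
#' @return Scalar energy.
#' @export
structure_energy <- function(coords, restraints, schedule = NULL) {
  sch <- utils::modifyList(default_schedule(), schedule %||% list())
  polymer_energy(coords, restraints$i - 1L, restraints$j - 1L,
                 restraints$lower, restraints$upper,
                 sch$rep_dist, sch$rep_k, sch$res_k)
}
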
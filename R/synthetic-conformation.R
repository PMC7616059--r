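#' Simulate a ground-truth genome conformation
#'
#' Grows each chromosome as a discrete random walk with fixed bond length
#' (2 bead radii) and soft excluded volume (placements closer than 1.6
#' radii to an existing bead are rejected, with a bounded number of
#' retries), confined in a nuclear sphere.  Chromosome territories are
#' modelled as per-chromosome sub-spheres: at `intermingle_level = 0`
#' each chromosome is restricted to a distinct sub-sphere whose centre
#' sits on a shell, at `intermingle_level = 1` every chromosome may roam
#' the whole nucleus, and intermediate levels interpolate the sub-sphere
#' radius and centre displacement linearly.
#'
#' The nuclear radius is set so that beads occupy ~25% of the nuclear
#' volume and territories ~45% of their sub-sphere, melt-like densities
#' that give each bead a realistic number of spatial neighbours at this
#' coarse-graining.  Distances are in bead-radius units throughout.
#'
#' @param assembly A `genome_assembly`.
#' @param intermingle_level Territory intermingling in `[0, 1]`.
#' @param seed Integer seed; identical seeds give identical coordinates.
#' @return A single-model `structure_ensemble` (the true conformation).
#' @examples
#' g <- build_genome(2, 2e6, 100e3)
#' conf <- simulate_conformation(g, intermingle_level = 0, seed = 1)
#' @export
simulate_conformation <- function(assembly, intermingle_level = 0, seed = 1L) {
  assert_assembly(assembly)
  if (!is.numeric(intermingle_level) || length(intermingle_level) != 1L ||
      is.na(intermingle_level) || intermingle_level < 0 || intermingle_level > 1) {
    abort("`intermingle_level` must be a single number in [0, 1].")
  }
  layout <- bead_layout(assembly)
  n_tot <- nrow(layout)
  packing_nucleus <- 0.25
  packing_territory <- 0.45
  r_nuc <- (n_tot / packing_nucleus)^(1 / 3)

  with_seed(seed, {
    # Chromosome territories are denser sub-spheres with centres on a
    # shell; intermingling inflates each sub-sphere toward the shared
    # sphere that holds every chromosome at territory density, and pulls
    # the centres together, so at level 1 all chromosomes co-occupy one
    # central volume.
    r_chrom <- pmin((assembly$n_bins / packing_territory)^(1 / 3), r_nuc)
    r_shared <- min((n_tot / packing_territory)^(1 / 3), r_nuc)
    r_sub <- r_chrom + intermingle_level * (r_shared - r_chrom)
    shell <- pmax((1 - intermingle_level) * (r_nuc - r_sub), 0)
    dirs <- unit_directions(nrow(assembly))
    centers <- dirs * shell

    coords <- matrix(NA_real_, n_tot, 3)
    row0 <- 0L
    for (ci in seq_len(nrow(assembly))) {
      nb <- assembly$n_bins[ci]
      coords[row0 + seq_len(nb), ] <- grow_chain(
        n = nb, center = centers[ci, ], radius = r_sub[ci],
        prior = if (row0 > 0) coords[seq_len(row0), , drop = FALSE] else NULL
      )
      row0 <- row0 + nb
    }
    structure_ensemble(coords, layout, attr(assembly, "bin_size"))
  })
}

# Deterministic well-separated unit directions (vertices-of-polyhedron
# style): antipodal pairs first, then a Fibonacci lattice for larger n.
unit_directions <- function(n) {
  if (n == 1L) return(matrix(c(0, 0, 1), 1))
  if (n == 2L) return(rbind(c(0, 0, 1), c(0, 0, -1)))
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Random-walk chain with bond length 2, excluded volume and spherical
# confinement by candidate rejection.  Each step draws up to `max_try`
# in-sphere candidates and takes the first with clearance `min_sep` to
# every placed bead; if none clears, the candidate with the largest
# clearance is taken (soft excluded volume: residual overlaps are rare
# and shallow).  With no in-sphere candidate the chain steps back toward
# the centre.
grow_chain <- function(n, center, radius, prior = NULL, bond = 2,
                       min_sep = 1.6, max_try = 60L) {
  pts <- matrix(NA_real_, n, 3)
  pts[1, ] <- center + random_unit() * stats::runif(1, 0, max(radius - 1, 0))
  if (n == 1L) return(pts)
  for (i in 2:n) {
    best <- NULL
    best_clear <- -Inf
    for (try in seq_len(max_try)) {
      cand <- pts[i - 1, ] + random_unit() * bond
      if (sqrt(sum((cand - center)^2)) > radius) next
      others <- rbind(prior, pts[seq_len(i - 1), , drop = FALSE])
      d2 <- rowSums((others - rep(cand, each = nrow(others)))^2)
      clear <- sqrt(min(d2))
      # the bonded predecessor sits at exactly `bond`, which passes
      if (clear >= min_sep * (1 - 1e-12)) {
        best <- cand
        break
      }
      if (clear > best_clear) {
        best <- cand
        best_clear <- clear
      }
    }
    if (is.null(best)) {
      # step back toward the centre to stay confined
      dir <- center - pts[i - 1, ]
      nd <- sqrt(sum(dir^2))
      dir <- if (nd > 0) dir / nd else random_unit()
      best <- pts[i - 1, ] + dir * bond
    }
    pts[i, ] <- best
  }
  pts
}

random_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

#' Radius of gyration per chromosome
#'
#' @param ensemble A `structure_ensemble`.
#' @param model Model index.
#' @return Tibble with `chrom`, `rg`, and centroid coordinates.
#' @export
radius_of_gyration <- function(ensemble, model = 1L) {
  xyz <- model_coords(ensemble, model)
  ensemble$layout |>
    mutate(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]) |>
    group_by(chrom) |>
    summarise(
      cx = mean(x), cy = mean(y), cz = mean(z),
      rg = sqrt(mean((x - mean(x))^2 + (y - mean(y))^2 + (z - mean(z))^2)),
      .groups = "drop"
    )
}

#' Fraction of each bead's nearest neighbours on other chromosomes
#'
#' Diagnostic used to verify that the generator's `intermingle_level`
#' dial actually changes territory mixing: for each bead, the fraction of
#' beads within `radius` that belong to a different chromosome.
#'
#' @param ensemble A `structure_ensemble`.
#' @param radius Neighbourhood radius in bead radii.
#' @param model Model index.
#' @return Mean trans-neighbour fraction over beads with any neighbour.
#' @export
trans_neighbor_fraction <- function(ensemble, radius = 4, model = 1L) {
  d <- model_dist(ensemble, model)
  diag(d) <- Inf
  chrom <- ensemble$layout$chrom
  near <- d < radius
  per_bead <- vapply(seq_len(nrow(d)), function(i) {
    nb <- which(near[i, ])
    if (!length(nb)) return(NA_real_)
    mean(chrom[nb] != chrom[i])
  }, numeric(1))
  mean(per_bead, na.rm = TRUE)
}
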
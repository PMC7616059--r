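#' Generate histone-mark peak tracks and a TSS table from an element plan
#'
#' Writes BED-like peak intervals (with an intensity per replicate) for
#' marks among H3K4me3, H3K27ac, H3K27me3, H3K9me3 across the three time
#' points `naive`, `24h`, `48h` (the 48 h / primed state), constructed so
#' that the planned element classes are recoverable by
#' [classify_elements()]:
#'
#' * `active_promoter`: H3K4me3 + H3K27ac at every time point, no H3K27me3.
#' * `bivalent_promoter`: H3K4me3 + H3K27me3 at every time point.
#' * `active_enhancer`: H3K27ac only, at every time point.
#' * `emerging_enhancer`: H3K27ac absent at naive, present at 48h with a
#'   >= 3x intensity gain.
#' * `weakening_enhancer`: the mirror of emerging.
#'
#' Intensities are log-normal around class means with multiplicative
#' replicate noise (CV 0.2); two replicates are emitted.
#'
#' @param assembly A `genome_assembly`.
#' @param element_plan Tibble with columns `chrom`, `bin` (1-based bin
#'   index within the chromosome), `class`, and optionally `gene`
#'   (promoters are assigned auto-named genes when absent).
#' @param seed Integer seed.
#' @return List with `peaks` (tibble: `mark`, `timepoint`, `replicate`,
#'   `chrom`, `start`, `end`, `intensity`) and `tss` (tibble: `chrom`,
#'   `pos`, `gene`).
#' @export
generate_tracks <- function(assembly, element_plan, seed = 1L) {
  assert_assembly(assembly)
  marks_ok <- c("H3K4me3", "H3K27ac", "H3K27me3", "H3K9me3")
  tps <- c("naive", "24h", "48h")
  if (nrow(element_plan) == 0L) {
    return(list(
      peaks = tibble(mark = character(), timepoint = character(),
                     replicate = integer(), chrom = character(),
                     start = double(), end = double(), intensity = double()),
      tss = tibble(chrom = character(), pos = double(), gene = character())
    ))
  }
  classes <- c("active_promoter", "bivalent_promoter", "active_enhancer",
               "emerging_enhancer", "weakening_enhancer")
  if (!all(element_plan$class %in% classes)) {
    abort(sprintf("Unknown element class(es): %s",
                  paste(setdiff(element_plan$class, classes), collapse = ", ")))
  }
  bs <- bin_size(assembly)
  plan <- element_plan |>
    mutate(center = (bin - 0.5) * bs,
           is_promoter = class %in% c("active_promoter", "bivalent_promoter"))
  if (any(!plan$chrom %in% assembly$chrom)) {
    abort("Element plan references unknown chromosomes.")
  }
  over <- plan$center > assembly$length[match(plan$chrom, assembly$chrom)]
  if (any(over)) abort("Element plan bins fall outside their chromosome.")

  if (!"gene" %in% names(plan)) plan$gene <- NA_character_
  plan$gene[plan$is_promoter & is.na(plan$gene)] <-
    paste0("gene", which(plan$is_promoter & is.na(plan$gene)))

  tss <- plan |> filter(is_promoter) |>
    transmute(chrom, pos = center, gene)
  if (anyDuplicated(tss[c("chrom", "pos")])) {
    abort("Duplicate TSS coordinates in the element plan.")
  }

  # which (mark, timepoint) combinations each class produces, with a
  # relative intensity multiplier
  recipe <- function(class) {
    switch(class,
      active_promoter = tibble(
        mark = rep(c("H3K4me3", "H3K27ac"), each = 3),
        timepoint = rep(tps, 2), rel = 1),
      bivalent_promoter = tibble(
        mark = rep(c("H3K4me3", "H3K27me3"), each = 3),
        timepoint = rep(tps, 2), rel = 1),
      active_enhancer = tibble(
        mark = "H3K27ac", timepoint = tps, rel = 1),
      emerging_enhancer = tibble(
        mark = "H3K27ac", timepoint = c("24h", "48h"), rel = c(0.5, 1.2)),
      weakening_enhancer = tibble(
        mark = "H3K27ac", timepoint = c("naive", "24h"), rel = c(1.2, 0.5))
    )
  }
  widths <- c(H3K4me3 = 1000, H3K27ac = 1600, H3K27me3 = 5000, H3K9me3 = 5000)
  base_mean <- 10
  sdlog <- sqrt(log(1 + 0.2^2))

  with_seed(seed, {
    peaks <- purrr::pmap(plan, function(chrom, bin, class, center, gene,
                                        is_promoter, ...) {
      rec <- recipe(class)
      rec |>
        mutate(chrom = chrom,
               start = pmax(center - widths[mark] / 2, 0),
               end = center + widths[mark] / 2,
               base = base_mean * rel)
    }) |>
      purrr::list_rbind() |>
      tidyr::crossing(replicate = 1:2) |>
      mutate(intensity = base * rlnorm(dplyr::n(), -sdlog^2 / 2, sdlog)) |>
      select(mark, timepoint, replicate, chrom, start, end, intensity) |>
      arrange(mark, timepoint, replicate, chrom, start)
    list(peaks = peaks, tss = tss)
  })
}

#' Simulate H3K27me3 promoter trajectories from planted archetypes
#'
#' Produces per-gene, per-time-point, per-replicate intensities following
#' one of four trajectory archetypes over (naive, 24h, primed):
#' gain-maintained, transient gain, progressive gain, and loss —
#' the qualitative shapes seen for Polycomb-target promoter groups during
#' naive-to-primed progression.  Gaussian noise of `noise_sd` (on the
#' unit-scaled profile) is added independently per replicate.
#'
#' @param n_per_group Genes per archetype.
#' @param noise_sd Noise standard deviation on the unit-scale profile.
#' @param n_replicates ChIP replicates.
#' @param scale Peak intensity scale.
#' @param seed Integer seed.
#' @return Tibble `gene`, `group` (planted archetype), `timepoint`,
#'   `replicate`, `intensity`.
#' @export
simulate_promoter_trajectories <- function(n_per_group = 150, noise_sd = 0.05,
                                           n_replicates = 2, scale = 10,
                                           seed = 1L) {
  archetypes <- list(
    gain_maintained = c(naive = 0.15, `24h` = 1.0, primed = 1.0),
    transient_gain  = c(naive = 0.15, `24h` = 1.0, primed = 0.3),
    progressive_gain = c(naive = 0.1, `24h` = 0.45, primed = 1.0),
    loss            = c(naive = 1.0, `24h` = 0.5, primed = 0.15)
  )
  with_seed(seed, {
    purrr::imap(archetypes, function(prof, gname) {
      tidyr::crossing(idx = seq_len(n_per_group),
                      timepoint = names(prof),
                      replicate = seq_len(n_replicates)) |>
        mutate(
          gene = paste0(gname, "_", idx),
          group = gname,
          intensity = pmax(scale * (prof[timepoint] +
                                      rnorm(dplyr::n(), 0, noise_sd)), 0)
        ) |>
        select(gene, group, timepoint, replicate, intensity)
    }) |>
      purrr::list_rbind()
  })
}

#' Simulate counts from the Poisson-beta bursting model
#'
#' For each gene with parameters `(k_on, k_off, s)`, each cell draws an
#' active-state occupancy `p ~ Beta(k_on, k_off)` and a count
#' `~ Poisson(s * p)`.  `k_on` and `k_off` are the promoter activation
#' and inactivation rates (per unit mRNA-lifetime) and `s` the
#' transcription rate while active; `k_on / (k_on + k_off)` is the mean
#' fraction of time spent active.
#'
#' @param kinetics Tibble with columns `gene`, `k_on`, `k_off`, `s`
#'   (all rates strictly positive; `s = 0` is allowed and yields zeros).
#' @param n_cells Number of cells.
#' @param seed Integer seed.
#' @return Integer matrix, genes x cells, dimnames set.
#' @export
simulate_expression_counts <- function(kinetics, n_cells, seed = 1L) {
  req <- c("gene", "k_on", "k_off", "s")
  if (!all(req %in% names(kinetics))) {
    abort("`kinetics` needs columns gene, k_on, k_off, s.")
  }
  if (any(kinetics$k_on <= 0 | kinetics$k_off <= 0 | kinetics$s < 0)) {
    abort("Kinetic rates must be positive (s may be zero).")
  }
  with_seed(seed, {
    counts <- t(vapply(seq_len(nrow(kinetics)), function(g) {
      p <- rbeta(n_cells, kinetics$k_on[g], kinetics$k_off[g])
      rpois(n_cells, kinetics$s[g] * p)
    }, integer(n_cells)))
    dimnames(counts) <- list(kinetics$gene, paste0("cell", seq_len(n_cells)))
    counts
  })
}
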
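#' Default pipeline configuration
#'
#' Thresholds default to the reference analysis values: 40 kb anchor
#' window (step 20 kb), 50 kb long-range separation, 400 hub
#' permutations, FDR 0.05, 2 bead-radii proximity, 1.5 radii precision,
#' 3.5 radii trans-contact structure filter, 20 kb / 5 kb flanks, 5,000
#' enrichment permutations, minimum promoter-cluster size 100, and the
#' k_off > 10 kinetics exclusion.  Synthetic-data sizes are desk-scale.
#'
#' @return Nested named list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    genome = list(n_chroms = 3L, chrom_length = 20e6, bin_size = 100e3),
    cells = list(n_cells = 8L, intermingle_level = 0.6, n_contacts = 3000L,
                 noise_fraction = 0.05, hubs_per_cell = 2L, hub_k = 12L,
                 compartment_block = 10L, compartment_enrichment = 3),
    population = list(depth = 10, enrichment = 3),
    structure = list(n_models = 3L, enabled = TRUE),
    thresholds = list(
      window = 40e3, step = 20e3, min_separation = 50e3, min_count = 4L,
      proximity_radius = 2, precision_rmsd = 1.5, trans_max_dist = 3.5,
      flank = 20e3, tss_flank = 5e3, n_perm_hubs = 400L,
      n_perm_enrich = 5000L, fdr = 0.05, n_groups = 10L,
      min_cluster_size = 100L, k_off_max = 10
    ),
    stages = list(synthesize = TRUE, structures = TRUE, intermingling = TRUE,
                  compartments = TRUE, hubs = TRUE, regulatory = TRUE,
                  kinetics = TRUE),
    kinetics = list(n_genes = 10L, n_cells = 300L)
  )
}

#' Run the analysis pipeline end to end on synthetic data
#'
#' Orchestrates the stages in dependency order with per-stage seeds
#' derived from the master seed: synthetic genome/cells, 3D structures,
#' intermingling scores, compartment/saddle analysis, hub detection,
#' regulatory enrichment, and bursting kinetics.  Artifacts are written
#' under `out_dir` and a summary report is returned (and written as
#' YAML).  Re-running with the same seed gives byte-identical outputs.
#'
#' @param config Named list (merged over [default_run_config()]) or a
#'   path to a YAML file with the same structure.
#' @return Invisibly, the report list (`config`, per-stage summaries).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_run_config(), config)
  if (is.null(cfg$out_dir)) abort("`out_dir` must be set.")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- cfg$thresholds
  report <- list(config = cfg)
  say <- function(...) inform(sprintf(...))

  ## stage 1: synthetic cells -------------------------------------------
  if (!isTRUE(cfg$stages$synthesize)) {
    abort("Stage `synthesize` is required: downstream stages consume its output.")
  }
  say("[synthesize] generating %d cells", cfg$cells$n_cells)
  assembly <- build_genome(cfg$genome$n_chroms, cfg$genome$chrom_length,
                           cfg$genome$bin_size)
  layout <- bead_layout(assembly)
  comp_labels <- ifelse(
    (pos_to_bin(layout$start, cfg$genome$bin_size) - 1) %/%
      cfg$cells$compartment_block %% 2 == 0, "A", "B")
  cells <- lapply(seq_len(cfg$cells$n_cells), function(ci) {
    sd1 <- derive_seed(cfg$seed, 100 + ci)
    conf <- simulate_conformation(assembly, cfg$cells$intermingle_level, sd1)
    plan <- with_seed(derive_seed(cfg$seed, 200 + ci), {
      ch <- sample(assembly$chrom, cfg$cells$hubs_per_cell, replace = TRUE)
      anchor <- floor(stats::runif(cfg$cells$hubs_per_cell, 5e6,
                                   cfg$genome$chrom_length - 5e6) /
                        th$step) * th$step
      plant_hubs(ch, anchor, k = cfg$cells$hub_k)
    })
    sc <- sample_contacts(conf, cfg$cells$n_contacts,
                          noise_fraction = cfg$cells$noise_fraction,
                          planted_hubs = plan,
                          compartment_labels = comp_labels,
                          compartment_enrichment = cfg$cells$compartment_enrichment,
                          seed = derive_seed(cfg$seed, 300 + ci))
    write_contacts(sc$contacts,
                   file.path(cfg$out_dir, sprintf("cell%02d.pairs", ci)))
    list(id = sprintf("cell%02d", ci), conf = conf, contacts = sc$contacts,
         truth = sc$truth)
  })
  report$synthesize <- list(
    n_cells = length(cells),
    n_contacts = vapply(cells, function(c) nrow(c$contacts), numeric(1)),
    planted_hubs = sum(vapply(cells, function(c) nrow(c$truth$hubs), numeric(1)))
  )

  ## stage 2: structures -------------------------------------------------
  ensembles <- NULL
  if (isTRUE(cfg$stages$structures)) {
    say("[structures] annealing %d models/cell", cfg$structure$n_models)
    ensembles <- lapply(seq_along(cells), function(ci) {
      clean <- filter_isolated_contacts(cells[[ci]]$contacts, assembly)
      res <- contacts_to_restraints(clean, assembly)
      ens <- anneal(res, n_models = cfg$structure$n_models,
                    seed = derive_seed(cfg$seed, 400 + ci))
      al <- align_ensemble(ens)
      vr <- violation_report(al$ensemble, res)
      write_structure(al$ensemble,
                      file.path(cfg$out_dir, sprintf("%s.n3d", cells[[ci]]$id)))
      utils::write.table(vr$per_model,
                         file.path(cfg$out_dir,
                                   sprintf("%s_violations.tsv", cells[[ci]]$id)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(ensemble = al$ensemble, bead_rmsd = al$bead_rmsd,
           violations = vr$per_model)
    })
    names(ensembles) <- vapply(cells, `[[`, "", "id")
    report$structures <- list(
      mean_violation_fraction =
        mean(vapply(ensembles, function(e) mean(e$violations$fraction),
                    numeric(1)))
    )
  }

  ## stage 3: intermingling ---------------------------------------------
  agg <- NULL
  if (isTRUE(cfg$stages$intermingling)) {
    if (is.null(ensembles)) abort("Stage `intermingling` needs `structures`.")
    say("[intermingling] scoring %d cells", length(ensembles))
    tracks <- lapply(ensembles, function(e) {
      prox <- proximity_sets(e$ensemble, th$proximity_radius, th$precision_rmsd)
      intermingling_score(prox, e$ensemble$layout)
    })
    agg <- normalize_and_aggregate(tracks, n_groups = th$n_groups)
    write_bedgraph(
      agg |> filter(!is.na(median_score)) |>
        transmute(chrom, start, end = start + cfg$genome$bin_size,
                  value = median_score),
      file.path(cfg$out_dir, "intermingling_median.bedgraph"))
    report$intermingling <- list(
      n_scored = sum(!is.na(agg$median_score)),
      median_A = stats::median(agg$median_score[comp_labels == "A"], na.rm = TRUE),
      median_B = stats::median(agg$median_score[comp_labels == "B"], na.rm = TRUE)
    )
  }

  ## stage 4: compartments ----------------------------------------------
  if (isTRUE(cfg$stages$compartments)) {
    say("[compartments] pooled matrix + saddle")
    pooled <- purrr::list_rbind(lapply(cells, `[[`, "contacts"))
    # compartment scoring runs on a planted-checkerboard population
    # matrix (the bulk Hi-C input); profiles come from the cells
    per_chrom <- lapply(seq_along(assembly$chrom), function(k) {
      ch <- assembly$chrom[k]
      labs <- comp_labels[layout$chrom == ch]
      m <- simulate_compartment_matrix(labs,
                                       enrichment = cfg$population$enrichment,
                                       depth = cfg$population$depth,
                                       seed = derive_seed(cfg$seed, 900 + k))
      nm <- normalize_matrix(m)
      sc <- compartment_scores(nm, as.numeric(labs == "A"))
      list(chrom = ch, norm = nm, scores = sc)
    })
    scores_all <- purrr::list_rbind(purrr::map(per_chrom, function(x) {
      mutate(x$scores, chrom = x$chrom)
    }))
    sad <- saddle(per_chrom[[1]]$norm, per_chrom[[1]]$scores$score,
                  n_groups = min(th$n_groups,
                                 max(2, nrow(per_chrom[[1]]$norm) %/% 5)))
    frac <- separation_fractions(pooled)
    utils::write.table(frac, file.path(cfg$out_dir, "separation_fractions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_matrix_tsv(sad$saddle, file.path(cfg$out_dir, "saddle.tsv"))
    acc <- mean((scores_all$score > 0) ==
                  (comp_labels == "A"), na.rm = TRUE)
    report$compartments <- list(
      label_accuracy = max(acc, 1 - acc),
      mixing_ratio = sad$mixing_ratio,
      trans_fraction = frac$fraction[frac$class == "trans"]
    )
  }

  ## stage 5: hubs -------------------------------------------------------
  hubs_all <- NULL
  if (isTRUE(cfg$stages$hubs)) {
    say("[hubs] permutation testing (%d permutations/cell)", th$n_perm_hubs)
    hubs_all <- purrr::list_rbind(lapply(seq_along(cells), function(ci) {
      hub_significance(cells[[ci]]$contacts, assembly,
                       window = th$window, step = th$step,
                       min_separation = th$min_separation,
                       min_count = th$min_count, n_perm = th$n_perm_hubs,
                       fdr = th$fdr, seed = derive_seed(cfg$seed, 500 + ci),
                       cell_id = cells[[ci]]$id)
    }))
    hubs_flat <- hubs_all |>
      mutate(n_sites = vapply(sites, nrow, numeric(1))) |>
      select(-sites)
    utils::write.table(hubs_flat, file.path(cfg$out_dir, "hubs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    detected <- filter(hubs_all, retained)
    planted_found <- sum(vapply(seq_along(cells), function(ci) {
      tr <- cells[[ci]]$truth$hubs
      if (is.null(tr)) return(0L)
      det <- filter(detected, cell_id == cells[[ci]]$id)
      sum(vapply(seq_len(nrow(tr)), function(h) {
        any(det$chrom == tr$chrom[h] &
              abs(det$center - (tr$anchor_start[h] + tr$anchor_width[h] / 2)) <=
                th$window)
      }, logical(1)))
    }, integer(1)))
    abundance <- if (!is.null(agg)) {
      hub_abundance_by_intermingling(detected, agg,
                                     seed = derive_seed(cfg$seed, 600))
    }
    report$hubs <- list(
      n_candidates = nrow(hubs_all), n_retained = nrow(detected),
      planted = report$synthesize$planted_hubs,
      planted_detected = planted_found,
      abundance = abundance
    )
  }

  ## stage 6: regulatory -------------------------------------------------
  if (isTRUE(cfg$stages$regulatory)) {
    if (is.null(hubs_all)) abort("Stage `regulatory` needs `hubs`.")
    say("[regulatory] element classification + enrichment")
    detected <- filter(hubs_all, retained)
    plan <- regulatory_plan_for_hubs(detected, assembly,
                                     seed = derive_seed(cfg$seed, 700))
    tracks <- generate_tracks(assembly, plan, seed = derive_seed(cfg$seed, 701))
    elements <- classify_elements(tracks)
    ep <- call_hub_ep_contacts(detected, elements, timepoint = "48h",
                               tss = tracks$tss,
                               flank = th$flank, tss_flank = th$tss_flank)
    enr <- NULL
    if (nrow(ep$anchor_categories) && nrow(ep$site_class_counts) &&
        nrow(ep$hubs) >= 4) {
      comp <- hub_compartment(mutate(ep$hubs, start = center - th$window / 2,
                                     end = center + th$window / 2),
                              tibble(chrom = layout$chrom, start = layout$start,
                                     label = comp_labels),
                              cfg$genome$bin_size)
      enr <- shuffle_and_test(ep, comp, n_perm = th$n_perm_enrich,
                              seed = derive_seed(cfg$seed, 702))
      utils::write.table(enr, file.path(cfg$out_dir, "ep_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    report$regulatory <- list(
      n_elements = nrow(elements),
      n_typed_pairs = nrow(ep$site_class_counts),
      enrichment = enr
    )
  }

  ## stage 7: kinetics ----------------------------------------------------
  if (isTRUE(cfg$stages$kinetics)) {
    say("[kinetics] Poisson-beta fits for %d genes", cfg$kinetics$n_genes)
    kin_truth <- with_seed(derive_seed(cfg$seed, 800), {
      tibble(
        gene = paste0("gene", seq_len(cfg$kinetics$n_genes)),
        k_on = stats::rlnorm(cfg$kinetics$n_genes, log(0.7), 0.5),
        k_off = stats::rlnorm(cfg$kinetics$n_genes, log(2), 0.5),
        s = stats::rlnorm(cfg$kinetics$n_genes, log(60), 0.4)
      )
    })
    counts <- simulate_expression_counts(kin_truth, cfg$kinetics$n_cells,
                                         seed = derive_seed(cfg$seed, 801))
    fits <- fit_kinetics(counts, seed = derive_seed(cfg$seed, 802))
    kept <- filter_fits(fits, k_off_max = th$k_off_max)
    utils::write.table(select(kept, -fit),
                       file.path(cfg$out_dir, "kinetic_fits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$kinetics <- list(
      n_fit = nrow(fits), n_kept = nrow(kept),
      median_abs_rel_error_fraction = stats::median(abs(
        kept$active_fraction /
          (kin_truth$k_on / (kin_truth$k_on + kin_truth$k_off))[
            match(kept$gene, kin_truth$gene)] - 1))
    )
  }

  writeLines(yaml::as.yaml(strip_for_yaml(report)),
             file.path(cfg$out_dir, "report.yaml"))
  invisible(report)
}

# drop non-scalar members (tibbles etc.) for the YAML summary
strip_for_yaml <- function(x) {
  if (is.data.frame(x)) return(as.list(utils::head(x, 20)))
  if (is.list(x)) return(lapply(x, strip_for_yaml))
  x
}

# Plant promoter/enhancer elements near detected hub anchors and sites so
# the regulatory stage has signal to find: anchors get promoters,
# contact sites get emerging enhancers (plus background elements).
regulatory_plan_for_hubs <- function(hubs, assembly, seed = 1L,
                                     n_background = 30L) {
  bs <- attr(assembly, "bin_size")
  anchor_bins <- if (nrow(hubs)) {
    tibble(chrom = hubs$chrom, bin = pos_to_bin(hubs$center, bs),
           class = "active_promoter")
  }
  site_bins <- if (nrow(hubs)) {
    sites <- purrr::list_rbind(hubs$sites)
    tibble(chrom = sites$chrom, bin = pos_to_bin(sites$pos, bs),
           class = "emerging_enhancer")
  }
  bg <- with_seed(seed, {
    tibble(
      chrom = sample(assembly$chrom, n_background, replace = TRUE),
      bin = sample.int(min(assembly$n_bins), n_background, replace = TRUE),
      class = sample(c("active_enhancer", "bivalent_promoter",
                       "weakening_enhancer"), n_background, replace = TRUE)
    )
  })
  bind_rows(anchor_bins, site_bins, bg) |>
    distinct(chrom, bin, .keep_all = TRUE)
}
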
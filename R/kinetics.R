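#' Fit the Poisson-beta bursting model to one gene's counts
#'
#' Bayesian inference for the two-state (telegraph) bursting model in
#' its Poisson-beta form: each cell's count is Poisson(`s * p`) with
#' `p ~ Beta(k_on, k_off)` — `k_on`/`k_off` the promoter activation and
#' inactivation rates (in units of the mRNA degradation rate) and `s`
#' the transcription rate while active.  Sampling is random-walk
#' Metropolis on `(log k_on, log k_off, log s)` against the marginal
#' likelihood, which is evaluated by quantile quadrature: the Beta
#' mixing distribution is represented by the midpoint quantiles
#' `qbeta((k - 1/2) / K, k_on, k_off)` so each count's marginal
#' probability is a plain average of Poisson densities.  A joint scale
#' move on `(k_on, k_off)` improves mixing of the active fraction
#' `k_on / (k_on + k_off)`.  Priors are truncated log-normals.
#'
#' @param counts Integer vector of per-cell counts for one gene.
#' @param mcmc Named list: `n_iter` (post-burn-in iterations), `burn`,
#'   `thin`, proposal SDs `sd_rates`, `sd_s`, `sd_scale`.
#' @param priors Named list: log-normal `meanlog`/`sdlog` for the rates
#'   and for `s`.
#' @param seed Integer seed.
#' @param gene Gene label carried into summaries.
#' @return A `pb_fit` object: posterior draws, medians, central 90%
#'   intervals, the active fraction, acceptance rates and a split-half
#'   convergence diagnostic.  All-zero genes return a stub flagged
#'   `excluded_low_expression`.
#' @export
fit_poisson_beta <- function(counts, mcmc = list(), priors = list(),
                             seed = 1L, gene = NA_character_) {
  counts <- as.integer(counts)
  if (all(counts == 0L)) {
    out <- list(gene = gene, excluded_low_expression = TRUE, draws = NULL)
    class(out) <- "pb_fit"
    return(out)
  }
  mc <- utils::modifyList(list(n_iter = 2000L, burn = 500L, thin = 3L,
                               sd_rates = 0.3, sd_s = 0.12, sd_scale = 0.35,
                               sd_ridge = 0.4, quad_points = 200L),
                          mcmc)
  # s prior centred on the data scale (counts bound s from below); rate
  # priors truncated to keep the sampler off the unidentifiable
  # negative-binomial ridge (k_off -> Inf with s -> Inf)
  pr <- utils::modifyList(list(rate_meanlog = 0, rate_sdlog = 2.5,
                               rate_max = 1e3, rate_min = 1e-3,
                               s_meanlog = log(max(2 * mean(counts),
                                                   max(counts), 1)),
                               s_sdlog = 1.5, s_max = 1e6, s_min = 1e-2),
                          priors)
  n <- length(counts)
  total_iter <- mc$burn + mc$n_iter
  tab <- table(counts)
  uniq <- as.integer(names(tab))
  mult <- as.vector(tab)
  K <- mc$quad_points %||% 200L

  qg <- (seq_len(K) - 0.5) / K
  grid_of <- function(kon, koff) {
    # qbeta warns about reduced accuracy for extreme shape pairs the
    # chain passes through transiently; the clamped grid is still a
    # valid (slightly diffuse) representation there
    g <- suppressWarnings(stats::qbeta(qg, kon, koff))
    pmin(pmax(g, 1e-12), 1 - 1e-12)
  }
  loglik_grid <- function(pgrid, s) {
    pb_loglik(uniq, mult, pgrid, s)
  }
  lprior <- function(kon, koff, s) {
    if (kon < pr$rate_min || kon > pr$rate_max ||
        koff < pr$rate_min || koff > pr$rate_max ||
        s < pr$s_min || s > pr$s_max) return(-Inf)
    stats::dlnorm(kon, pr$rate_meanlog, pr$rate_sdlog, log = TRUE) +
      stats::dlnorm(koff, pr$rate_meanlog, pr$rate_sdlog, log = TRUE) +
      stats::dlnorm(s, pr$s_meanlog, pr$s_sdlog, log = TRUE)
  }

  with_seed(seed, {
    # moment-based initialisation (guarded)
    m1 <- mean(counts)
    s <- max(m1 * 2, max(counts), 1)
    f <- min(max(m1 / s, 0.05), 0.9)
    kon <- 1
    koff <- kon * (1 - f) / f
    pgrid <- grid_of(kon, koff)
    lp <- loglik_grid(pgrid, s) + lprior(kon, koff, s)

    keep <- seq(mc$burn + 1L, total_iter, by = mc$thin)
    draws <- matrix(NA_real_, length(keep), 3,
                    dimnames = list(NULL, c("k_on", "k_off", "s")))
    acc <- c(rates = 0, scale = 0, ridge = 0, s = 0)
    ki <- 0L
    # proposal: move one of (kon, koff) | joint scale | s, each iteration
    for (it in seq_len(total_iter)) {
      # (k_on, k_off) random walk on logs (log-scale proposal Jacobian
      # is absorbed by the dlnorm prior evaluated on the natural scale
      # plus the explicit log terms)
      kon2 <- kon * exp(stats::rnorm(1, 0, mc$sd_rates))
      koff2 <- koff * exp(stats::rnorm(1, 0, mc$sd_rates))
      pri2 <- lprior(kon2, koff2, s)
      if (is.finite(pri2)) {
        grid2 <- grid_of(kon2, koff2)
        lp2 <- loglik_grid(grid2, s) + pri2
        if (is.finite(lp2) &&
            log(stats::runif(1)) < lp2 - lp + log(kon2 / kon) + log(koff2 / koff)) {
          kon <- kon2; koff <- koff2; lp <- lp2; pgrid <- grid2
          acc["rates"] <- acc["rates"] + 1
        }
      } else stats::rnorm(1)  # keep the RNG stream aligned across paths

      # joint scale move: (kon, koff) <- g * (kon, koff), fraction fixed
      g <- exp(stats::rnorm(1, 0, mc$sd_scale))
      pri2 <- lprior(g * kon, g * koff, s)
      if (is.finite(pri2)) {
        grid2 <- grid_of(g * kon, g * koff)
        lp2 <- loglik_grid(grid2, s) + pri2
        if (is.finite(lp2) && log(stats::runif(1)) < lp2 - lp + 2 * log(g)) {
          kon <- g * kon; koff <- g * koff; lp <- lp2; pgrid <- grid2
          acc["scale"] <- acc["scale"] + 1
        }
      } else stats::rnorm(1)

      # ridge move: (k_off, s) <- g * (k_off, s).  In the bursty regime
      # the likelihood is nearly flat along this direction (burst size
      # s / k_off and burst frequency k_on fixed), so axis-aligned moves
      # alone mix poorly there.
      g <- exp(stats::rnorm(1, 0, mc$sd_ridge))
      pri2 <- lprior(kon, g * koff, g * s)
      if (is.finite(pri2)) {
        grid2 <- grid_of(kon, g * koff)
        lp2 <- loglik_grid(grid2, g * s) + pri2
        if (is.finite(lp2) && log(stats::runif(1)) < lp2 - lp + 2 * log(g)) {
          koff <- g * koff; s <- g * s; lp <- lp2; pgrid <- grid2
          acc["ridge"] <- acc["ridge"] + 1
        }
      } else stats::rnorm(1)

      # transcription rate
      s2 <- s * exp(stats::rnorm(1, 0, mc$sd_s))
      pri2 <- lprior(kon, koff, s2)
      if (is.finite(pri2)) {
        lp2 <- loglik_grid(pgrid, s2) + pri2
        if (is.finite(lp2) && log(stats::runif(1)) < lp2 - lp + log(s2 / s)) {
          s <- s2; lp <- lp2
          acc["s"] <- acc["s"] + 1
        }
      } else stats::rnorm(1)

      if (it > mc$burn && (it - mc$burn - 1L) %% mc$thin == 0L) {
        ki <- ki + 1L
        draws[ki, ] <- c(kon, koff, s)
      }
    }
    draws <- draws[seq_len(ki), , drop = FALSE]
    frac <- draws[, "k_on"] / (draws[, "k_on"] + draws[, "k_off"])
    qs <- function(x) stats::quantile(x, c(0.05, 0.5, 0.95), names = FALSE)
    summ <- rbind(k_on = qs(draws[, "k_on"]), k_off = qs(draws[, "k_off"]),
                  s = qs(draws[, "s"]), active_fraction = qs(frac))
    colnames(summ) <- c("q05", "median", "q95")
    # split-half ratio of medians on log(s): crude but honest stability flag
    half <- nrow(draws) %/% 2
    split_ratio <- abs(log(stats::median(draws[seq_len(half), "s"]) /
                             stats::median(draws[half + seq_len(half), "s"])))
    out <- list(
      gene = gene, excluded_low_expression = FALSE,
      draws = draws, active_fraction_draws = frac,
      summary = summ,
      acceptance = acc / total_iter,
      split_half_log_ratio = split_ratio,
      n_cells = n, mean_count = m1
    )
    class(out) <- "pb_fit"
    out
  })
}

#' @export
print.pb_fit <- function(x, ...) {
  if (isTRUE(x$excluded_low_expression)) {
    cat(sprintf("<pb_fit> %s: excluded (all-zero counts)\n", x$gene))
    return(invisible(x))
  }
  cat(sprintf("<pb_fit> %s: %d cells, mean count %.2f\n",
              x$gene, x$n_cells, x$mean_count))
  print(round(x$summary, 3))
  invisible(x)
}

#' @export
tidy.pb_fit <- function(x, ...) {
  if (isTRUE(x$excluded_low_expression)) {
    return(tibble(gene = x$gene, term = character(), estimate = double()))
  }
  tibble(
    gene = x$gene,
    term = rownames(x$summary),
    estimate = x$summary[, "median"],
    conf.low = x$summary[, "q05"],
    conf.high = x$summary[, "q95"]
  )
}

#' @export
glance.pb_fit <- function(x, ...) {
  if (isTRUE(x$excluded_low_expression)) {
    return(tibble(gene = x$gene, excluded_low_expression = TRUE))
  }
  tibble(gene = x$gene, excluded_low_expression = FALSE,
         n_cells = x$n_cells, mean_count = x$mean_count,
         split_half_log_ratio = x$split_half_log_ratio,
         accept_rates = x$acceptance[["rates"]],
         accept_s = x$acceptance[["s"]])
}

#' Fit bursting kinetics for every gene of a count matrix
#'
#' @param counts Genes x cells integer matrix.
#' @param mcmc,priors Passed to [fit_poisson_beta()].
#' @param seed Integer master seed (per-gene seeds derived).
#' @return Tibble with one row per gene: posterior medians and 90%
#'   intervals for `k_on`, `k_off`, `s` and the active fraction, plus
#'   exclusion flags; fit objects in a `fit` list-column.
#' @export
fit_kinetics <- function(counts, mcmc = list(), priors = list(), seed = 1L) {
  fits <- lapply(seq_len(nrow(counts)), function(g) {
    fit_poisson_beta(counts[g, ], mcmc = mcmc, priors = priors,
                     seed = derive_seed(seed, g),
                     gene = rownames(counts)[g] %||% paste0("gene", g))
  })
  rows <- purrr::map(fits, function(f) {
    if (isTRUE(f$excluded_low_expression)) {
      return(tibble(gene = f$gene, excluded_low_expression = TRUE,
                    k_on = NA_real_, k_off = NA_real_, s = NA_real_,
                    active_fraction = NA_real_,
                    k_on_lo = NA_real_, k_on_hi = NA_real_,
                    k_off_lo = NA_real_, k_off_hi = NA_real_,
                    s_lo = NA_real_, s_hi = NA_real_,
                    active_fraction_lo = NA_real_,
                    active_fraction_hi = NA_real_))
    }
    sm <- f$summary
    tibble(gene = f$gene, excluded_low_expression = FALSE,
           k_on = sm["k_on", "median"], k_off = sm["k_off", "median"],
           s = sm["s", "median"],
           active_fraction = sm["active_fraction", "median"],
           k_on_lo = sm["k_on", "q05"], k_on_hi = sm["k_on", "q95"],
           k_off_lo = sm["k_off", "q05"], k_off_hi = sm["k_off", "q95"],
           s_lo = sm["s", "q05"], s_hi = sm["s", "q95"],
           active_fraction_lo = sm["active_fraction", "q05"],
           active_fraction_hi = sm["active_fraction", "q95"])
  })
  out <- purrr::list_rbind(rows)
  out$fit <- fits
  out
}

#' Filter unreliable kinetic fits
#'
#' Removes genes whose posterior-median `k_off` exceeds `k_off_max`
#' (parameter estimation is poor in that regime) and genes excluded for
#' zero or extremely low expression (mean count below `min_mean`).
#'
#' @param fits Tibble from [fit_kinetics()].
#' @param k_off_max Exclusion threshold on the posterior-median `k_off`
#'   (reference value 10).
#' @param min_mean Minimum mean count per cell.
#' @return The retained rows, with a `filter_reason` attribute tibble
#'   recording what was removed and why.
#' @export
filter_fits <- function(fits, k_off_max = 10, min_mean = 0.05) {
  mean_count <- vapply(fits$fit, function(f) f$mean_count %||% 0, numeric(1))
  reason <- dplyr::case_when(
    fits$excluded_low_expression | mean_count < min_mean ~ "low_expression",
    fits$k_off > k_off_max ~ "high_k_off",
    TRUE ~ NA_character_
  )
  out <- fits[is.na(reason), , drop = FALSE]
  attr(out, "filter_reason") <- tibble(gene = fits$gene, reason = reason)
  out
}

#' Compare bursting kinetics between two conditions
#'
#' Per-gene log2 fold changes of `k_on`, `k_off`, `s` and the active
#' fraction between matched fits, with two-sided paired Wilcoxon
#' signed-rank tests across the shared genes.
#'
#' @param fits_x,fits_y Tibbles from [fit_kinetics()] (filtered).
#' @return List with `per_gene` (tibble of log2 ratios) and `tests`
#'   (tibble `parameter`, `median_log2fc`, `p`).
#' @export
compare_conditions <- function(fits_x, fits_y) {
  shared <- intersect(fits_x$gene, fits_y$gene)
  if (length(shared) < 10) warn("Fewer than 10 shared genes; tests are weak.")
  if (!length(shared)) abort("No shared genes.")
  x <- fits_x[match(shared, fits_x$gene), ]
  y <- fits_y[match(shared, fits_y$gene), ]
  per_gene <- tibble(
    gene = shared,
    log2fc_k_on = log2(y$k_on / x$k_on),
    log2fc_k_off = log2(y$k_off / x$k_off),
    log2fc_s = log2(y$s / x$s),
    log2fc_active_fraction = log2(y$active_fraction / x$active_fraction)
  )
  test_one <- function(a, b) {
    if (all(a == b)) return(1)
    stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
  }
  tests <- tibble(
    parameter = c("k_on", "k_off", "s", "active_fraction"),
    median_log2fc = c(stats::median(per_gene$log2fc_k_on),
                      stats::median(per_gene$log2fc_k_off),
                      stats::median(per_gene$log2fc_s),
                      stats::median(per_gene$log2fc_active_fraction)),
    p = c(test_one(y$k_on, x$k_on), test_one(y$k_off, x$k_off),
          test_one(y$s, x$s), test_one(y$active_fraction, x$active_fraction))
  )
  list(per_gene = per_gene, tests = tests)
}
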
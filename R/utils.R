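#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider unnest
#' @importFrom purrr map map_dbl map_int map2 pmap imap list_rbind
#' @importFrom stats median quantile rnorm runif rbeta rpois rlnorm sd
#'   setNames cor p.adjust fisher.test wilcox.test hclust dist cutree
#'   dbeta dpois dlnorm ecdf ks.test
#' @importFrom utils head tail
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched.  All stochastic operations in the
# package funnel through this so that seeds compose predictably.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Stage seeds are derived from one master seed by a fixed affine hash so
# that pipeline stages can be re-run in isolation yet stay decoupled.
derive_seed <- function(master_seed, stage_index) {
  as.integer((as.double(master_seed) * 1000003 + stage_index * 7919) %% 2147483629L)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(min), format(max)))
  }
  invisible(x)
}

#' Map base-pair positions to bead (bin) indices
#'
#' Beads tile each chromosome in half-open windows:
#' bead `i` (1-based) covers `[(i-1) * bin_size, i * bin_size)`.
#'
#' @param pos Integer-ish vector of 0-based bp positions.
#' @param bin_size Bin width in bp.
#' @return 1-based bin indices.
#' @keywords internal
pos_to_bin <- function(pos, bin_size) {
  as.integer(floor(pos / bin_size)) + 1L
}

# Interval overlap at desk scale: returns a tibble of (query, subject)
# index pairs for half-open [start, end) intervals, optionally padded.
overlap_pairs <- function(q_start, q_end, s_start, s_end, pad = 0) {
  if (length(q_start) == 0L || length(s_start) == 0L) {
    return(tibble(query = integer(), subject = integer()))
  }
  hits <- lapply(seq_along(q_start), function(i) {
    j <- which(s_start < q_end[i] + pad & s_end > q_start[i] - pad)
    if (length(j)) tibble(query = i, subject = j) else NULL
  })
  dplyr::bind_rows(hits)
}
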
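#' Structure ensembles
#'
#' A `structure_ensemble` holds M replica models of a genome conformation
#' as an `M x n_beads x 3` array of coordinates in bead-radius units,
#' together with the bead layout (chromosome and 0-based start per bead)
#' and the bin size.  One bead represents one genomic bin.
#'
#' @param coords Numeric array `M x n_beads x 3` (a single `n_beads x 3`
#'   matrix is promoted to M = 1).
#' @param layout Tibble with columns `bead`, `chrom`, `start`.
#' @param bin_size Bin size in bp.
#' @return A `structure_ensemble`.
#' @export
structure_ensemble <- function(coords, layout, bin_size) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), 3L))
  }
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    abort("`coords` must be an M x n_beads x 3 array.")
  }
  if (dim(coords)[1] < 1L) abort("An ensemble needs at least one model (M >= 1).")
  if (any(!is.finite(coords))) abort("Coordinates must be finite.")
  if (dim(coords)[2] != nrow(layout)) {
    abort("`layout` must have one row per bead.")
  }
  structure(
    list(coords = coords, layout = as_tibble(layout[c("bead", "chrom", "start")]),
         bin_size = as.double(bin_size)),
    class = "structure_ensemble",
    bin_size = as.double(bin_size)
  )
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf(
    "<structure_ensemble> %d model(s), %d beads, %d chromosome(s), bin_size = %s bp\n",
    n_models(x), n_beads(x), length(unique(x$layout$chrom)),
    format(x$bin_size, big.mark = ",")))
  invisible(x)
}

#' Number of replica models in an ensemble
#' @param ensemble A `structure_ensemble`.
#' @export
n_models <- function(ensemble) dim(ensemble$coords)[1]

#' Number of beads in an ensemble
#' @param ensemble A `structure_ensemble`.
#' @export
n_beads <- function(ensemble) dim(ensemble$coords)[2]

#' Coordinates of one model as an n_beads x 3 matrix
#' @param ensemble A `structure_ensemble`.
#' @param model Model index (1-based).
#' @export
model_coords <- function(ensemble, model = 1L) {
  m <- ensemble$coords[model, , , drop = FALSE]
  matrix(m, ncol = 3L, dimnames = list(NULL, c("x", "y", "z")))
}

#' Tidy a structure ensemble into a long tibble
#'
#' @param x A `structure_ensemble`.
#' @param ... Unused.
#' @return A tibble with columns `model`, `bead`, `chrom`, `start`,
#'   `x`, `y`, `z`.
#' @export
tidy.structure_ensemble <- function(x, ...) {
  M <- n_models(x)
  out <- purrr::map(seq_len(M), function(m) {
    xyz <- model_coords(x, m)
    dplyr::mutate(x$layout, model = m,
                  x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  })
  dplyr::relocate(purrr::list_rbind(out), model)
}

#' @export
glance.structure_ensemble <- function(x, ...) {
  tibble(
    n_models = n_models(x), n_beads = n_beads(x),
    n_chroms = length(unique(x$layout$chrom)), bin_size = x$bin_size
  )
}

# Pairwise Euclidean distances between beads of one model.
model_dist <- function(ensemble, model = 1L) {
  as.matrix(stats::dist(model_coords(ensemble, model)))
}
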
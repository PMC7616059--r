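#' Build a toy genome assembly
#'
#' An assembly is a tibble with one row per chromosome (`chrom`, `length`,
#' `n_bins`, `offset`) and a `bin_size` attribute.  `offset` is the global
#' bead index of the chromosome's first bead minus one, so bead indices are
#' comparable across chromosomes in structure ensembles.
#'
#' @param n_chroms Number of chromosomes (>= 1).
#' @param chrom_length Chromosome length in bp; a single value recycled to
#'   all chromosomes or one value per chromosome.  Must be a positive
#'   multiple of `bin_size`.
#' @param bin_size Bin (bead) size in bp.
#' @return A `genome_assembly` tibble.
#' @examples
#' build_genome(2, 10e6, 100e3)
#' @export
build_genome <- function(n_chroms, chrom_length, bin_size) {
  stopifnot_scalar_number(n_chroms, "n_chroms", min = 1)
  stopifnot_scalar_number(bin_size, "bin_size", min = 1)
  if (!is.numeric(chrom_length) || any(!is.finite(chrom_length)) ||
      any(chrom_length <= 0)) {
    abort("`chrom_length` must be positive.")
  }
  lengths <- rep_len(as.double(chrom_length), n_chroms)
  if (any(lengths %% bin_size != 0)) {
    abort("Every chromosome length must be a multiple of `bin_size`.")
  }
  n_bins <- as.integer(lengths / bin_size)
  out <- tibble(
    chrom  = paste0("chr", seq_len(n_chroms)),
    length = lengths,
    n_bins = n_bins,
    offset = cumsum(c(0L, n_bins[-length(n_bins)]))
  )
  attr(out, "bin_size") <- as.double(bin_size)
  class(out) <- c("genome_assembly", class(out))
  out
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("<genome_assembly> %d chromosome(s), bin_size = %s bp\n",
              nrow(x), format(bin_size(x), big.mark = ",")))
  NextMethod()
}

#' Bin size of an assembly or ensemble
#' @param x A `genome_assembly` or `structure_ensemble`.
#' @return Bin size in bp.
#' @export
bin_size <- function(x) {
  bs <- attr(x, "bin_size")
  if (is.null(bs)) abort("Object carries no `bin_size` attribute.")
  bs
}

assert_assembly <- function(assembly) {
  if (!inherits(assembly, "genome_assembly")) {
    abort("`assembly` must be created by `build_genome()`.")
  }
  if (anyDuplicated(assembly$chrom)) abort("Chromosome names must be unique.")
  invisible(assembly)
}

total_beads <- function(assembly) sum(assembly$n_bins)

# Per-bead chromosome labels and 0-based start coordinates, in assembly
# order.  Used to lay out structure ensembles.
bead_layout <- function(assembly, bin_size = NULL) {
  bs <- bin_size %||% attr(assembly, "bin_size")
  n_bins <- as.integer(assembly$length / bs)
  tibble(
    bead  = seq_len(sum(n_bins)),
    chrom = rep(assembly$chrom, n_bins),
    start = unlist(lapply(n_bins, function(n) (seq_len(n) - 1) * bs))
  )
}

# Global bead index for (chrom, pos) pairs under an arbitrary bin size.
global_bead <- function(chrom, pos, assembly, bin_size) {
  n_bins <- as.integer(assembly$length / bin_size)
  offset <- cumsum(c(0L, n_bins[-length(n_bins)]))
  idx <- match(chrom, assembly$chrom)
  if (anyNA(idx)) {
    bad <- unique(chrom[is.na(idx)])
    abort(sprintf("Unknown chromosome(s): %s", paste(bad, collapse = ", ")))
  }
  if (any(pos < 0 | pos >= assembly$length[idx])) {
    abort("Positions must lie within [0, chromosome length).")
  }
  offset[idx] + pos_to_bin(pos, bin_size)
}
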
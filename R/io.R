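#' Read a contact list from pairs-style text
#'
#' Expects whitespace-delimited text with one contact per line:
#' `chromA posA chromB posB` (a simplified pairs dialect; only positions
#' are consumed downstream).  Lines starting with `#` are comments.
#' Records are canonicalised so `(chromA, posA) <= (chromB, posB)` in
#' genome order.
#'
#' @param path File path.
#' @param assembly Optional `genome_assembly`; when given, chromosomes
#'   and positions are validated against it.
#' @return Tibble `chromA`, `posA`, `chromB`, `posB`.
#' @export
read_contacts <- function(path, assembly = NULL) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) {
    return(tibble(chromA = character(), posA = double(),
                  chromB = character(), posB = double()))
  }
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    bad <- keep[which(nf < 4L)[1]]
    abort(sprintf("%s:%d: expected 4 fields (chromA posA chromB posB), got %d.",
                  path, bad, nf[which(nf < 4L)[1]]))
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:4))
  posA <- suppressWarnings(as.double(m[, 2]))
  posB <- suppressWarnings(as.double(m[, 4]))
  if (anyNA(posA) || anyNA(posB)) {
    bad <- keep[which(is.na(posA) | is.na(posB))[1]]
    abort(sprintf("%s:%d: non-numeric position.", path, bad))
  }
  out <- tibble(chromA = m[, 1], posA = posA, chromB = m[, 3], posB = posB)
  if (!is.null(assembly)) {
    assert_assembly(assembly)
    chroms <- unique(c(out$chromA, out$chromB))
    unknown <- setdiff(chroms, assembly$chrom)
    if (length(unknown)) {
      abort(sprintf("%s: unknown chromosome(s): %s", path,
                    paste(unknown, collapse = ", ")))
    }
    lenA <- assembly$length[match(out$chromA, assembly$chrom)]
    lenB <- assembly$length[match(out$chromB, assembly$chrom)]
    off <- which(out$posA < 0 | out$posA >= lenA |
                   out$posB < 0 | out$posB >= lenB)
    if (length(off)) {
      abort(sprintf("%s:%d: position outside chromosome.", path, keep[off[1]]))
    }
    out <- canonicalize_contacts(out, chrom_order = assembly$chrom)
  } else {
    out <- canonicalize_contacts(out)
  }
  out
}

#' @rdname read_contacts
#' @param contacts Tibble with `chromA`, `posA`, `chromB`, `posB`.
#' @export
write_contacts <- function(contacts, path) {
  lines <- sprintf("%s\t%d\t%s\t%d", contacts$chromA, as.integer(contacts$posA),
                   contacts$chromB, as.integer(contacts$posB))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write structure ensembles in an N3D-style text format
#'
#' A simple x,y,z coordinate block format: a `#bin_size <bp>` header,
#' then per chromosome a line `>chrom <name> <n_beads> <n_models>`
#' followed by one line per bead: the bead's 0-based start coordinate and
#' `x y z` for each model (6 decimal places).
#'
#' @param path File path.
#' @return A `structure_ensemble`.
#' @export
read_structure <- function(path) {
  lines <- readLines(path)
  header <- grep("^#bin_size\\s", lines, value = TRUE)
  if (length(header) != 1L) abort(sprintf("%s: missing '#bin_size' header.", path))
  bs <- as.double(strsplit(trimws(header), "\\s+")[[1]][2])
  block_at <- grep("^>chrom\\s", lines)
  if (!length(block_at)) abort(sprintf("%s: no chromosome blocks.", path))
  ends <- c(block_at[-1] - 1L, length(lines))
  blocks <- purrr::map2(block_at, ends, function(b, e) {
    hdr <- strsplit(trimws(lines[b]), "\\s+")[[1]]
    nb <- as.integer(hdr[3]); nm <- as.integer(hdr[4])
    body <- lines[(b + 1):e]
    body <- body[!grepl("^\\s*$", body)]
    if (length(body) != nb) {
      abort(sprintf("%s:%d: block '%s' declares %d beads but has %d rows.",
                    path, b, hdr[2], nb, length(body)))
    }
    vals <- lapply(seq_along(body), function(k) {
      v <- suppressWarnings(as.double(strsplit(trimws(body[k]), "\\s+")[[1]]))
      if (anyNA(v) || length(v) != 1L + 3L * nm) {
        abort(sprintf("%s:%d: expected %d numeric fields, got %d.",
                      path, b + k, 1L + 3L * nm, length(v)))
      }
      v
    })
    m <- do.call(rbind, vals)
    list(chrom = hdr[2], n_models = nm, start = m[, 1],
         xyz = m[, -1, drop = FALSE])
  })
  nms <- vapply(blocks, function(b) b$n_models, integer(1))
  if (length(unique(nms)) != 1L) {
    abort(sprintf("%s: model count differs across chromosomes (%s).",
                  path, paste(unique(nms), collapse = ", ")))
  }
  M <- nms[1]
  layout <- purrr::list_rbind(purrr::map(blocks, function(b) {
    tibble(chrom = b$chrom, start = b$start)
  }))
  layout$bead <- seq_len(nrow(layout))
  coords <- array(NA_real_, c(M, nrow(layout), 3))
  row0 <- 0L
  for (b in blocks) {
    nb <- length(b$start)
    for (m in seq_len(M)) {
      coords[m, row0 + seq_len(nb), ] <- b$xyz[, (3 * (m - 1) + 1):(3 * m)]
    }
    row0 <- row0 + nb
  }
  structure_ensemble(coords, layout[c("bead", "chrom", "start")], bs)
}

#' @rdname read_structure
#' @param ensemble A `structure_ensemble`.
#' @export
write_structure <- function(ensemble, path) {
  if (!inherits(ensemble, "structure_ensemble")) {
    abort("`ensemble` must be a structure_ensemble.")
  }
  M <- n_models(ensemble)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#bin_size %d", as.integer(ensemble$bin_size)), con)
  for (ch in unique(ensemble$layout$chrom)) {
    rows <- which(ensemble$layout$chrom == ch)
    writeLines(sprintf(">chrom %s %d %d", ch, length(rows), M), con)
    for (k in seq_along(rows)) {
      vals <- unlist(lapply(seq_len(M), function(m) ensemble$coords[m, rows[k], ]))
      writeLines(paste(c(sprintf("%d", as.integer(ensemble$layout$start[rows[k]])),
                         sprintf("%.6f", vals)), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read/write BED intervals (0-based, half-open)
#'
#' Columns: `chrom`, `start`, `end`, and optionally `name` and a numeric
#' 5th column read as `intensity`.
#'
#' @param path File path.
#' @return Tibble of intervals.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|track|browser|$)", lines))
  if (!length(keep)) {
    return(tibble(chrom = character(), start = double(), end = double()))
  }
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort(sprintf("%s:%d: BED needs >= 3 fields.", path, keep[which(nf < 3L)[1]]))
  }
  out <- tibble(
    chrom = vapply(fields, `[`, "", 1),
    start = suppressWarnings(as.double(vapply(fields, `[`, "", 2))),
    end = suppressWarnings(as.double(vapply(fields, `[`, "", 3)))
  )
  if (anyNA(out$start) || anyNA(out$end)) {
    abort(sprintf("%s:%d: non-numeric coordinate.",
                  path, keep[which(is.na(out$start) | is.na(out$end))[1]]))
  }
  bad <- which(out$start >= out$end)
  if (length(bad)) {
    abort(sprintf("%s:%d: start >= end.", path, keep[bad[1]]))
  }
  if (all(nf >= 4L)) out$name <- vapply(fields, `[`, "", 4)
  if (all(nf >= 5L)) {
    out$intensity <- suppressWarnings(as.double(vapply(fields, `[`, "", 5)))
  }
  out
}

#' @rdname read_bed
#' @param intervals Tibble with `chrom`, `start`, `end` and optional
#'   `name`/`intensity` columns.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) && any(intervals$start >= intervals$end)) {
    abort("BED intervals must satisfy start < end.")
  }
  cols <- list(intervals$chrom, as.integer(intervals$start),
               as.integer(intervals$end))
  if ("name" %in% names(intervals)) {
    cols <- c(cols, list(intervals$name))
    if ("intensity" %in% names(intervals)) {
      cols <- c(cols, list(sprintf("%.6f", intervals$intensity)))
    }
  } else if ("intensity" %in% names(intervals)) {
    cols <- c(cols, list(".", sprintf("%.6f", intervals$intensity)))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read/write bedGraph (per-interval numeric score)
#'
#' @param path File path.
#' @return Tibble `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  out <- read_bed(path)
  if (!"name" %in% names(out)) {
    if (nrow(out)) abort(sprintf("%s: bedGraph needs a 4th value column.", path))
    return(tibble(chrom = character(), start = double(), end = double(),
                  value = double()))
  }
  value <- suppressWarnings(as.double(out$name))
  if (anyNA(value) && nrow(out)) abort(sprintf("%s: non-numeric bedGraph value.", path))
  tibble(chrom = out$chrom, start = out$start, end = out$end, value = value)
}

#' @rdname read_bedgraph
#' @param track Tibble with `chrom`, `start`, `end`, `value`.
#' @export
write_bedgraph <- function(track, path) {
  if (nrow(track) && any(track$start >= track$end)) {
    abort("bedGraph intervals must satisfy start < end.")
  }
  writeLines(sprintf("%s\t%d\t%d\t%.6f", track$chrom, as.integer(track$start),
                     as.integer(track$end), track$value), path)
  invisible(path)
}

#' Read/write a numeric matrix as TSV (row names in the first column)
#' @param path File path.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_matrix_tsv
#' @param m Matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m) %||% seq_len(nrow(m)), m,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
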
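#' Read a catalog of DNase hypersensitive sites
#'
#' One BED file per cell type (BED3 minimum; extra columns are ignored).
#' BED coordinates are 0-based half-open, and are stored as such; the
#' conversion to 1-based CpG coordinates happens in [cpgs_in_dhs()].
#'
#' @param paths Named character vector or list, `cell_type = path/to.bed`.
#' @return A named list of tibbles with columns `chrom`, `start`, `end`
#'   (class `dhs_catalog`). Empty BED files yield zero-row tibbles.
#' @export
read_dhs_catalog <- function(paths) {
  if (is.null(names(paths)) || any(names(paths) == "")) {
    abort("`paths` must be named by cell type.")
  }
  catalog <- lapply(paths, read_bed3)
  structure(catalog, class = c("dhs_catalog", "list"))
}

read_bed3 <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t| +")
  if (any(lengths(fields) < 3)) {
    abort(paste0("BED line ", which(lengths(fields) < 3)[1], " has fewer than 3 fields in ", path))
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- as.integer(vapply(fields, `[[`, character(1), 2))
  end <- as.integer(vapply(fields, `[[`, character(1), 3))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad) > 0) {
    abort(paste0("Invalid interval (start >= end) at line ", bad[1], " of ", path))
  }
  tibble::tibble(chrom = chrom, start = start, end = end)
}

#' Build a DHS catalog from in-memory interval tables
#'
#' @param intervals Named list of data frames with columns `chrom`, `start`,
#'   `end` (0-based half-open), one element per cell type.
#' @return A `dhs_catalog` (see [read_dhs_catalog()]).
#' @export
dhs_catalog <- function(intervals) {
  stopifnot(is.list(intervals), !is.null(names(intervals)))
  catalog <- lapply(intervals, function(df) {
    df <- tibble::as_tibble(df[, c("chrom", "start", "end")])
    if (nrow(df) > 0 && any(df$start >= df$end)) abort("Invalid interval (start >= end).")
    df
  })
  structure(catalog, class = c("dhs_catalog", "list"))
}

#' CpGs overlapping a DHS of any listed cell type
#'
#' A CpG at 1-based position `p` overlaps a 0-based half-open interval
#' `[start, end)` when `start <= p - 1 < end`. The union rule applies: a CpG
#' is returned if it falls in a DHS of at least one of the listed cell types.
#'
#' @param cpg_map Tibble with columns `CpG`, `chrom`, `pos` (1-based), as
#'   returned by [read_cpg_map()].
#' @param catalog A `dhs_catalog`.
#' @param cell_types Cell types to consider; must be keys of `catalog`.
#' @return Character vector of CpG identifiers (in `cpg_map` order).
#' @export
cpgs_in_dhs <- function(cpg_map, catalog, cell_types = names(catalog)) {
  unknown <- setdiff(cell_types, names(catalog))
  if (length(unknown) > 0) {
    abort(paste0("Cell type(s) not in catalog: ", paste(unknown, collapse = ", ")))
  }
  iv <- dplyr::bind_rows(catalog[cell_types])
  if (nrow(iv) == 0) return(character())
  # GRanges are 1-based closed: BED [start, end) -> [start + 1, end]
  subject <- GenomicRanges::GRanges(
    iv$chrom, IRanges::IRanges(start = iv$start + 1L, end = iv$end)
  )
  query <- GenomicRanges::GRanges(
    cpg_map$chrom, IRanges::IRanges(start = cpg_map$pos, width = 1L)
  )
  hits <- GenomicRanges::findOverlaps(query, subject)
  cpg_map$CpG[unique(S4Vectors::queryHits(hits))]
}
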
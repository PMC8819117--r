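# ---- per-cell gene-body coverage from aligned reads --------------------------

#' Alignment filter configuration
#'
#' Defaults follow common gene-body-coverage practice: primary alignments
#' only, QC-fail and duplicate-flagged records dropped, no MAPQ floor. UMI
#' deduplication is off by default and not performed by this engine.
#'
#' @param primary_only Drop secondary/supplementary alignments.
#' @param drop_qcfail Drop reads failing platform QC.
#' @param drop_duplicates Drop duplicate-flagged reads.
#' @param min_mapq Minimum mapping quality (0 keeps everything mapped).
#' @return A list of class `alignment_filters`.
#' @export
alignment_filters <- function(primary_only = TRUE, drop_qcfail = TRUE,
                              drop_duplicates = TRUE, min_mapq = 0L) {
  structure(list(primary_only = primary_only, drop_qcfail = drop_qcfail,
                 drop_duplicates = drop_duplicates,
                 min_mapq = as.integer(min_mapq)),
            class = "alignment_filters")
}

scan_param <- function(filters, tag = character(0)) {
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = if (filters$primary_only) FALSE else NA,
    isSupplementaryAlignment = if (filters$primary_only) FALSE else NA,
    isNotPassingQualityControls = if (filters$drop_qcfail) FALSE else NA,
    isDuplicate = if (filters$drop_duplicates) FALSE else NA)
  Rsamtools::ScanBamParam(flag = flag, tag = tag,
                          mapqFilter = filters$min_mapq)
}

read_alignments <- function(bam, filters = alignment_filters(),
                            tag = character(0)) {
  GenomicAlignments::readGAlignments(bam, param = scan_param(filters, tag))
}

# width-1 GRanges of every transcript's 100 percentile positions, with the
# percentile index k (0..99) in mcols; 0-based BED coordinate -> 1-based here
percentile_index <- function(gene_models) {
  stopifnot(inherits(gene_models, "gene_model_set"))
  tx <- gene_models$transcripts
  pos <- unlist(lapply(tx, `[[`, "percentile_positions"))
  chrom <- rep(vapply(tx, `[[`, character(1), "chrom"), each = 100L)
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = pos + 1L, width = 1L),
                         k = rep.int(0:99, length(tx)))
}

#' Compute one cell's gene-body-coverage vector
#'
#' For each transcript and each of its 100 gene-body percentile positions,
#' counts the alignments whose reference-aligned bases span that genomic
#' coordinate (CIGAR-aware: M/=/X consume and cover the reference, N and D
#' gaps do not cover), sums counts over transcripts per percentile, and
#' normalizes the 100-vector by its maximum, so values lie in [0, 1] with
#' maximum 1 for any cell with signal. A cell with no passing alignments
#' gets an all-zero vector and a warning flag, never NaN.
#'
#' @param alignments A BAM path or a `GAlignments` object.
#' @param gene_models A `gene_model_set`.
#' @param filters An `alignment_filters` (used only when reading a BAM path).
#' @param cell_id Cell identifier (defaults to the BAM file stem).
#' @return A `coverage_vector`: list with `cell_id`, `values` (100 doubles in
#'   [0,1]), `raw_counts` (100 integers), `total_assigned`, `zero_flag`.
#' @export
compute_cell_coverage <- function(alignments, gene_models,
                                  filters = alignment_filters(),
                                  cell_id = NULL) {
  if (is.character(alignments)) {
    if (is.null(cell_id))
      cell_id <- sub("\\.bam$", "", basename(alignments))
    alignments <- read_alignments(alignments, filters)
  }
  if (is.null(cell_id)) cell_id <- "cell"
  pos_gr <- percentile_index(gene_models)

  if (length(alignments) == 0L) {
    return(new_coverage_vector(cell_id, integer(100), 0L))
  }
  # reference-space covered ranges per read; N/D gaps drop out
  covered <- GenomicAlignments::grglist(alignments, drop.D.ranges = TRUE)
  ov <- suppressWarnings(GenomicRanges::findOverlaps(pos_gr, covered))
  counts_per_pos <- tabulate(S4Vectors::queryHits(ov), nbins = length(pos_gr))
  raw <- as.integer(rowsum(counts_per_pos,
                           group = S4Vectors::mcols(pos_gr)$k,
                           reorder = TRUE))
  total_assigned <- length(unique(S4Vectors::subjectHits(ov)))
  new_coverage_vector(cell_id, raw, total_assigned)
}

new_coverage_vector <- function(cell_id, raw_counts, total_assigned) {
  m <- max(raw_counts)
  values <- if (m > 0) raw_counts / m else rep(0, 100L)
  structure(list(cell_id = cell_id,
                 values = as.numeric(values),
                 raw_counts = as.integer(raw_counts),
                 total_assigned = as.integer(total_assigned),
                 zero_flag = m == 0L),
            class = "coverage_vector")
}

#' @export
print.coverage_vector <- function(x, ...) {
  cat(sprintf("<coverage_vector> %s: %d reads assigned%s\n", x$cell_id,
              x$total_assigned, if (x$zero_flag) " [zero coverage]" else ""))
  invisible(x)
}

# ---- 10x barcoded BAM handling ----------------------------------------------

#' Build a cell-barcode manifest
#'
#' @param barcodes Character vector of barcodes, or a path to a barcodes.tsv
#'   (one barcode per line, optionally gzip-compressed, optional "-1" suffix).
#' @param tag_name BAM tag carrying the cell barcode (10x uses "CB").
#' @param suffix_policy "strip" removes a trailing "-<digit>" GEM-well suffix
#'   from both manifest and BAM tag values before matching; "keep" matches
#'   verbatim.
#' @return A `barcode_manifest`.
#' @export
barcode_manifest <- function(barcodes, tag_name = "CB",
                             suffix_policy = c("strip", "keep")) {
  suffix_policy <- match.arg(suffix_policy)
  if (length(barcodes) == 1L && file.exists(barcodes)) {
    con <- if (grepl("\\.gz$", barcodes)) gzfile(barcodes, "rt")
           else file(barcodes, "rt")
    on.exit(close(con))
    barcodes <- readLines(con, warn = FALSE)
  }
  barcodes <- trimws(barcodes)
  barcodes <- barcodes[nzchar(barcodes)]
  if (suffix_policy == "strip") barcodes <- sub("-\\d+$", "", barcodes)
  if (anyDuplicated(barcodes))
    stop("duplicate barcodes after applying suffix policy", call. = FALSE)
  if (length(barcodes) == 0L) stop("empty barcode manifest", call. = FALSE)
  structure(list(barcodes = barcodes, tag_name = tag_name,
                 suffix_policy = suffix_policy),
            class = "barcode_manifest")
}

#' Split a barcoded BAM into per-cell alignment streams
#'
#' Routes every record whose barcode tag (after the manifest's suffix policy)
#' is listed in the manifest to that barcode's stream; records with a missing
#' or unlisted tag are counted and discarded. Streams are accumulated in
#' memory (no intermediate per-cell BAM files); record order within each
#' stream follows the input.
#'
#' @param bam Path to a coordinate-sorted barcoded BAM.
#' @param manifest A `barcode_manifest`.
#' @param filters An `alignment_filters`.
#' @return A `barcode_split`: list with `streams` (named list of
#'   `GAlignments`, one per manifest barcode, possibly empty), `routed`,
#'   `discarded`.
#' @export
split_by_barcode <- function(bam, manifest, filters = alignment_filters()) {
  stopifnot(inherits(manifest, "barcode_manifest"))
  aln <- read_alignments(bam, filters, tag = manifest$tag_name)
  tags <- S4Vectors::mcols(aln)[[manifest$tag_name]]
  if (is.null(tags)) tags <- rep(NA_character_, length(aln))
  if (manifest$suffix_policy == "strip") tags <- sub("-\\d+$", "", tags)
  hit <- !is.na(tags) & tags %in% manifest$barcodes
  if (!any(hit))
    stop("no records matched the barcode manifest; check tag_name ('",
         manifest$tag_name, "') and suffix_policy", call. = FALSE)
  idx <- split(which(hit), factor(tags[hit], levels = manifest$barcodes))
  streams <- lapply(idx, function(i) aln[i])
  structure(list(streams = streams,
                 routed = sum(hit),
                 discarded = sum(!hit)),
            class = "barcode_split")
}

#' @export
print.barcode_split <- function(x, ...) {
  cat(sprintf("<barcode_split> %d barcodes, %d routed, %d discarded\n",
              length(x$streams), x$routed, x$discarded))
  invisible(x)
}

# ---- the coverage matrix -----------------------------------------------------

#' Compute the cells x 100 coverage matrix
#'
#' Per-cell computation is independent; with `workers > 1` cells are
#' processed with [parallel::mclapply()] and merged back in input order, so
#' the result is identical for any worker count.
#'
#' @param per_cell_inputs Named list of per-cell inputs (BAM paths or
#'   `GAlignments`), a character vector of BAM paths, or a `barcode_split`.
#'   Names (or file stems) become cell ids and must be unique.
#' @param gene_models A `gene_model_set`.
#' @param filters An `alignment_filters`.
#' @param workers Number of parallel workers.
#' @return A `coverage_matrix`: list with `cell_ids`, `values` (n x 100
#'   matrix, rownames = cell ids), `zero_flags`, `total_assigned`.
#' @export
coverage_matrix <- function(per_cell_inputs, gene_models,
                            filters = alignment_filters(), workers = 1L) {
  if (inherits(per_cell_inputs, "barcode_split"))
    per_cell_inputs <- per_cell_inputs$streams
  if (is.character(per_cell_inputs)) {
    nm <- names(per_cell_inputs)
    if (is.null(nm)) nm <- sub("\\.bam$", "", basename(per_cell_inputs))
    per_cell_inputs <- as.list(per_cell_inputs)
    names(per_cell_inputs) <- nm
  }
  if (length(per_cell_inputs) == 0L) stop("no cell inputs", call. = FALSE)
  ids <- names(per_cell_inputs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("per-cell inputs must be named (cell ids)", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate cell ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)

  worker <- function(i) {
    compute_cell_coverage(per_cell_inputs[[i]], gene_models, filters,
                          cell_id = ids[i])
  }
  covs <- if (workers > 1L) {
    parallel::mclapply(seq_along(ids), worker, mc.cores = workers)
  } else {
    lapply(seq_along(ids), worker)
  }
  new_coverage_matrix(
    cell_ids = ids,
    values = do.call(rbind, lapply(covs, `[[`, "values")),
    zero_flags = vapply(covs, `[[`, logical(1), "zero_flag"),
    total_assigned = vapply(covs, `[[`, integer(1), "total_assigned"))
}

new_coverage_matrix <- function(cell_ids, values, zero_flags,
                                total_assigned = NULL) {
  stopifnot(ncol(values) == 100L, nrow(values) == length(cell_ids))
  rownames(values) <- cell_ids
  colnames(values) <- paste0("pos_", 0:99)
  structure(list(cell_ids = cell_ids, values = values,
                 zero_flags = as.logical(zero_flags),
                 total_assigned = total_assigned),
            class = "coverage_matrix")
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat(sprintf("<coverage_matrix> %d cells x 100 positions (%d zero-coverage)\n",
              length(x$cell_ids), sum(x$zero_flags)))
  invisible(x)
}
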
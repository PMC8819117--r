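# ---- BED12 gene models -------------------------------------------------------
#
# Coordinates are 0-based half-open throughout (BED standard); conversion to
# the 1-based conventions of Bioconductor containers happens only at the
# alignment boundary (see coverage_engine).

#' Parse one BED12 line into a transcript model
#'
#' A transcript model holds the exon block structure of one BED12 record plus
#' the 100 gene-body percentile positions (genomic coordinates of the spliced
#' transcript at 0, 1, ..., 99 percent of its length, walked 5' to 3' in
#' transcript orientation, i.e. in reverse genomic order on the minus strand).
#'
#' @param line A single BED12 line (>= 12 tab-separated fields).
#' @param line_number Line number used in error messages.
#' @return An object of class `transcript_model`: a list with fields
#'   `transcript_id`, `chrom`, `strand`, `tx_start`, `tx_end`, `blocks`
#'   (two-column matrix: genomic start, length), `spliced_length`,
#'   `percentile_positions` (length-100 integer vector, or NULL when the
#'   spliced length is below 100), plus the pass-through BED fields needed to
#'   rewrite the record (`score`, `thick_start`, `thick_end`, `item_rgb`).
#' @export
parse_bed12 <- function(line, line_number = NA_integer_) {
  fail <- function(msg) {
    stop(sprintf("BED12 parse error at line %s: %s",
                 ifelse(is.na(line_number), "?", line_number), msg),
         call. = FALSE)
  }
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(f) < 12L) fail(sprintf("expected >= 12 fields, got %d", length(f)))

  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) fail(sprintf("non-numeric %s: '%s'", what, x))
    v
  }
  chrom_start <- num(f[2L], "chromStart")
  chrom_end   <- num(f[3L], "chromEnd")
  strand      <- f[6L]
  if (!strand %in% c("+", "-")) fail(sprintf("invalid strand '%s'", strand))
  block_count <- num(f[10L], "blockCount")

  parse_ints <- function(x, what) {
    parts <- strsplit(x, ",", fixed = TRUE)[[1L]]
    parts <- parts[nzchar(parts)]
    vapply(parts, num, numeric(1), what = what, USE.NAMES = FALSE)
  }
  sizes  <- parse_ints(f[11L], "blockSizes")
  starts <- parse_ints(f[12L], "blockStarts")
  if (length(sizes) != block_count || length(starts) != block_count)
    fail(sprintf("blockCount %d does not match blockSizes (%d) / blockStarts (%d)",
                 block_count, length(sizes), length(starts)))
  if (any(sizes < 1)) fail("blockSizes must be positive")
  if (is.unsorted(starts, strictly = TRUE) && block_count > 1L)
    fail("blockStarts must be strictly ascending")

  block_start <- chrom_start + starts
  block_end   <- block_start + sizes
  if (any(block_end > chrom_end) || any(block_start < chrom_start))
    fail("blocks exceed [chromStart, chromEnd)")
  if (block_count > 1L && any(block_start[-1L] < block_end[-block_count]))
    fail("blocks overlap")

  model <- structure(list(
    transcript_id = f[4L],
    chrom         = f[1L],
    strand        = strand,
    tx_start      = as.integer(chrom_start),
    tx_end        = as.integer(chrom_end),
    blocks        = cbind(start = as.integer(block_start),
                          length = as.integer(sizes)),
    spliced_length = as.integer(sum(sizes)),
    score         = f[5L],
    thick_start   = f[7L],
    thick_end     = f[8L],
    item_rgb      = f[9L]
  ), class = "transcript_model")
  model$percentile_positions <-
    if (model$spliced_length >= 100L) percentile_positions(model) else NULL
  model
}

#' Gene-body percentile positions of a transcript
#'
#' Position k (k = 0..99) is the genomic coordinate of spliced-transcript
#' nucleotide `floor(k * L / 100)` where L is the spliced length, counted 5'
#' to 3'. On the minus strand the spliced walk runs in decreasing genomic
#' order, so index 0 maps to the highest-coordinate exonic base.
#'
#' @param model A `transcript_model`.
#' @return Integer vector of 100 genomic coordinates (0-based).
#' @export
percentile_positions <- function(model) {
  L <- model$spliced_length
  if (L < 100L) stop("spliced length must be >= 100 for percentile sampling")
  # spliced offsets 5'->3'; +1e-9 guards binary-float underrun of k*L/100
  k <- 0:99
  off <- as.integer(floor(k * as.numeric(L) / 100 + 1e-9))
  starts <- model$blocks[, "start"]
  lens   <- model$blocks[, "length"]
  if (model$strand == "-") off <- L - 1L - off  # walk from the high end
  # map spliced offset (genomic-ascending orientation) to genomic coordinate
  cum <- cumsum(lens)
  blk <- findInterval(off, c(0, cum[-length(cum)] ), rightmost.closed = FALSE)
  within <- off - c(0L, cum)[blk]
  as.integer(starts[blk] + within)
}

#' Read a BED12 gene model file
#'
#' Accepts plain or gzip-compressed BED12; `#` comment and `track` lines are
#' skipped. Each record becomes one `transcript_model`.
#'
#' @param path Path to a BED12 file (optionally .gz).
#' @return List of `transcript_model` objects.
#' @export
read_bed12 <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  lapply(idx, function(i) parse_bed12(sub("\r$", "", lines[i]), i))
}

#' Filter a gene model for use in coverage profiling
#'
#' Drops transcripts shorter than `min_spliced_length` (percentile sampling
#' needs at least one base per bin) and transcripts whose name matches any of
#' `exclude_patterns` (by default ribosomal and transfer RNA name patterns,
#' for gene models that were not pre-filtered). Duplicate transcript ids are
#' allowed but reported via a message.
#'
#' @param models List of `transcript_model` (from [read_bed12()]).
#' @param min_spliced_length Minimum spliced length in nucleotides (>= 100).
#' @param exclude_patterns Character vector of regular expressions matched
#'   against transcript names.
#' @param source_path Recorded provenance string.
#' @return A `gene_model_set`: list with `transcripts`, `excluded_count`,
#'   `source_path`.
#' @export
filter_gene_model <- function(models,
                              min_spliced_length = 100L,
                              exclude_patterns = c("rRNA", "tRNA",
                                                   "Mt_rRNA", "Mt_tRNA"),
                              source_path = NA_character_) {
  if (min_spliced_length < 100L)
    stop("min_spliced_length must be >= 100", call. = FALSE)
  n_total <- length(models)
  if (n_total == 0L) stop("no usable transcripts: empty gene model", call. = FALSE)
  ids <- vapply(models, `[[`, character(1), "transcript_id")
  lens <- vapply(models, `[[`, integer(1), "spliced_length")
  excluded <- lens < min_spliced_length
  for (p in exclude_patterns) excluded <- excluded | grepl(p, ids)
  kept <- models[!excluded]
  if (length(kept) == 0L)
    stop("no usable transcripts after filtering", call. = FALSE)
  dup <- duplicated(vapply(kept, `[[`, character(1), "transcript_id"))
  if (any(dup))
    message(sum(dup), " duplicate transcript id(s) retained in gene model")
  structure(list(transcripts   = kept,
                 excluded_count = sum(excluded),
                 source_path    = source_path),
            class = "gene_model_set")
}

#' Read and filter a gene model in one step
#' @inheritParams filter_gene_model
#' @param path BED12 path.
#' @return A `gene_model_set`.
#' @export
load_gene_model <- function(path, min_spliced_length = 100L,
                            exclude_patterns = c("rRNA", "tRNA",
                                                 "Mt_rRNA", "Mt_tRNA")) {
  filter_gene_model(read_bed12(path), min_spliced_length, exclude_patterns,
                    source_path = path)
}

#' Write transcript models back to BED12
#'
#' Field formatting reproduces the parsed fields exactly, so a read/write
#' round trip of retained records is lossless.
#'
#' @param models List of `transcript_model` or a `gene_model_set`.
#' @param path Output path.
#' @export
write_bed12 <- function(models, path) {
  if (inherits(models, "gene_model_set")) models <- models$transcripts
  lines <- vapply(models, function(m) {
    paste(m$chrom, m$tx_start, m$tx_end, m$transcript_id, m$score, m$strand,
          m$thick_start, m$thick_end, m$item_rgb, nrow(m$blocks),
          paste0(paste(m$blocks[, "length"], collapse = ","), ","),
          paste0(paste(m$blocks[, "start"] - m$tx_start, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s %s:%d-%d(%s) blocks=%d spliced=%dnt\n",
              x$transcript_id, x$chrom, x$tx_start, x$tx_end, x$strand,
              nrow(x$blocks), x$spliced_length))
  invisible(x)
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat(sprintf("<gene_model_set> %d transcripts (%d excluded) from %s\n",
              length(x$transcripts), x$excluded_count, x$source_path))
  invisible(x)
}
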
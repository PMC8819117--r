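# ---- synthetic inputs with known truth --------------------------------------
#
# Two levels of fixture: (1) coverage-profile matrices with a planted
# fraction of skewed cells, for the clustering/classification stages; and
# (2) miniature BAM+BED datasets with read placement drawn from a stated
# positional density, for the alignment-facing stages, with expected raw
# counts computed by an independent brute-force pileup oracle.

#' Protocol profile archetypes
#'
#' Smooth positional densities on the scaled gene body emulating the three
#' protocol families: 5' end-tagging (peak in the first fifth), 3'
#' end-tagging (peak in the last fifth), and full-length (gentle plateau).
#' Curves are scaled beta densities evaluated at position midpoints and
#' normalized to maximum 1.
#'
#' @param name One of `"five_prime_tag"`, `"three_prime_tag"`,
#'   `"full_length"`.
#' @param noise_sd Per-bin Gaussian noise scale used by
#'   [generate_profiles()].
#' @return A `profile_archetype`: list with `name`, `shape` (beta
#'   parameters), `noise_sd`, `curve` (length-100 mean profile, max 1).
#' @export
profile_archetype <- function(name = c("five_prime_tag", "three_prime_tag",
                                       "full_length"),
                              noise_sd = 0.05) {
  name <- match.arg(name)
  shape <- switch(name,
                  five_prime_tag  = c(1.5, 8),
                  three_prime_tag = c(8, 1.5),
                  full_length     = c(1.3, 1.3))
  x <- (0:99 + 0.5) / 100
  curve <- dbeta(x, shape[1L], shape[2L])
  curve <- curve / max(curve)
  structure(list(name = name, shape = shape, noise_sd = noise_sd,
                 curve = curve),
            class = "profile_archetype")
}

# skew modes are declared multiplicative distortions of the archetype curve
skew_curve <- function(archetype, mode) {
  x <- (0:99 + 0.5) / 100
  base <- archetype$curve
  v <- switch(mode,
    opposite_end_bias  = rev(base),
    mid_body_dropout   = base * (1 - 0.9 * exp(-(x - 0.5)^2 / (2 * 0.15^2))),
    degradation_3prime = base * exp(-4 * (1 - x)) +
                         0.6 * dbeta(x, 8, 1.5) / max(dbeta(x, 8, 1.5)),
    stop("unknown skew mode: ", mode, call. = FALSE))
  v / max(v)
}

#' Generate a labeled synthetic coverage matrix
#'
#' Typical cells are the archetype curve plus per-bin Gaussian noise
#' (truncated at 0, re-normalized to max 1); a planted fraction of skewed
#' cells is drawn the same way from the skew-mode curves, cycling over
#' `skew_modes`. Fully reproducible from `seed`; the global RNG state is
#' untouched.
#'
#' @param n_cells Number of cells (>= 20).
#' @param skew_fraction Planted fraction of skewed cells, in [0, 0.5).
#' @param archetype A `profile_archetype` or its name.
#' @param skew_modes Character subset of `opposite_end_bias`,
#'   `mid_body_dropout`, `degradation_3prime`.
#' @param seed Integer seed (required).
#' @return List with `matrix` (a `coverage_matrix`), `labels` (character,
#'   `"typical"`/`"skewed"`), `modes` (skew mode per cell, NA for typical),
#'   `spec` (the resolved generator settings).
#' @export
generate_profiles <- function(n_cells = 200L, skew_fraction = 0.2,
                              archetype = "five_prime_tag",
                              skew_modes = "opposite_end_bias",
                              seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (n_cells < 20L) stop("n_cells must be >= 20", call. = FALSE)
  if (skew_fraction < 0 || skew_fraction >= 0.5)
    stop("skew_fraction must be in [0, 0.5)", call. = FALSE)
  if (is.character(archetype)) archetype <- profile_archetype(archetype)
  n_skew <- as.integer(round(n_cells * skew_fraction))
  modes <- rep(NA_character_, n_cells)
  if (n_skew > 0L) {
    skew_idx <- seq_len(n_skew)  # leading rows; row order carries no signal
    modes[skew_idx] <- rep_len(skew_modes, n_skew)
  }
  curves <- lapply(seq_len(n_cells), function(i) {
    if (is.na(modes[i])) archetype$curve else skew_curve(archetype, modes[i])
  })
  values <- withr::with_seed(seed, {
    t(vapply(curves, function(cv) {
      v <- pmax(cv + rnorm(100L, 0, archetype$noise_sd), 0)
      if (max(v) > 0) v / max(v) else v
    }, numeric(100L)))
  })
  ids <- sprintf("cell_%03d", seq_len(n_cells))
  list(matrix = new_coverage_matrix(ids, values,
                                    zero_flags = rowSums(values) == 0),
       labels = ifelse(is.na(modes), "typical", "skewed"),
       modes = modes,
       spec = list(n_cells = n_cells, skew_fraction = skew_fraction,
                   archetype = archetype$name, noise_sd = archetype$noise_sd,
                   skew_modes = skew_modes, seed = seed))
}

# ---- toy BAM + BED fixtures --------------------------------------------------

# the fixed miniature gene model: one single-exon plus-strand, one spliced
# plus-strand, one spliced minus-strand transcript
toy_bed_lines <- function() {
  c("chrT1\t100\t300\ttxU\t0\t+\t100\t300\t0\t1\t200,\t0,",
    "chrT2\t100\t1000\ttxS\t0\t+\t100\t1000\t0\t2\t150,250,\t0,650,",
    "chrT3\t200\t900\ttxM\t0\t-\t200\t900\t0\t2\t120,180,\t0,520,")
}

# genomic coordinates (0-based, ascending) of spliced indices 0..L-1
spliced_index_to_genomic <- function(blocks, idx) {
  cum <- cumsum(blocks[, "length"])
  blk <- findInterval(idx, c(0, cum[-length(cum)]))
  idx - c(0L, cum)[blk] + blocks[blk, "start"]
}

# genomic start (0-based) and CIGAR of a read covering spliced offsets
# s..s+rl-1 of a transcript (gaps across introns become N operations)
spliced_read_alignment <- function(model, s, rl) {
  L <- model$spliced_length
  asc <- if (model$strand == "+") s:(s + rl - 1L) else (L - s - rl):(L - s - 1L)
  g <- sort(spliced_index_to_genomic(model$blocks, asc))
  brk <- c(0L, which(diff(g) > 1L), length(g))
  run_start <- g[brk[-length(brk)] + 1L]
  run_len <- diff(brk)
  cig <- character(0)
  for (j in seq_along(run_len)) {
    if (j > 1L)
      cig <- c(cig, sprintf("%dN", run_start[j] - (run_start[j - 1L] +
                                                   run_len[j - 1L])))
    cig <- c(cig, sprintf("%dM", run_len[j]))
  }
  list(pos = g[1L], cigar = paste(cig, collapse = ""))
}

# brute-force per-base pileup from (chrom, pos, cigar) records, independent
# of any alignment library: M/=/X advance the reference and cover it, D/N
# advance without covering, I/S/H consume no reference
#' Brute-force pileup oracle
#'
#' Computes the expected per-percentile raw counts for a set of alignment
#' records by expanding every CIGAR into per-base reference coverage and
#' reading the depth at each transcript's percentile positions. Used to
#' build toy-fixture truth tables and as the independent check of the
#' coverage engine.
#'
#' @param records Data.frame with columns `chrom`, `pos` (0-based leftmost
#'   reference position), `cigar`.
#' @param gene_models A `gene_model_set`.
#' @return Integer vector of 100 raw counts.
#' @export
pileup_oracle <- function(records, gene_models) {
  depth <- new.env(parent = emptyenv())
  add <- function(chrom, at) {
    key <- chrom
    cur <- if (!is.null(depth[[key]])) depth[[key]] else integer(0)
    need <- max(at) + 1L
    if (length(cur) < need) cur <- c(cur, integer(need - length(cur)))
    cur[at + 1L] <- cur[at + 1L] + 1L
    depth[[key]] <- cur
  }
  for (r in seq_len(nrow(records))) {
    ops <- regmatches(records$cigar[r],
                      gregexpr("[0-9]+[MIDNSHP=X]", records$cigar[r]))[[1L]]
    ref <- records$pos[r]
    for (op in ops) {
      len <- as.integer(sub("[MIDNSHP=X]$", "", op))
      type <- sub("^[0-9]+", "", op)
      if (type %in% c("M", "=", "X")) {
        add(records$chrom[r], ref:(ref + len - 1L))
        ref <- ref + len
      } else if (type %in% c("D", "N")) {
        ref <- ref + len
      }                                   # I/S/H/P: no reference advance
    }
  }
  raw <- integer(100L)
  for (m in gene_models$transcripts) {
    dv <- depth[[m$chrom]]
    if (is.null(dv)) next
    pp <- m$percentile_positions
    ok <- pp < length(dv)
    raw[which(ok)] <- raw[which(ok)] + dv[pp[ok] + 1L]
  }
  raw
}

#' Generate a toy BAM+BED dataset with a known truth table
#'
#' Writes the miniature three-transcript gene model (single-exon plus
#' strand, spliced plus strand, spliced minus strand) as BED12, and a
#' coordinate-sorted, indexed BAM whose reads are placed along each
#' transcript's spliced body according to a per-cell beta positional
#' density. In barcoded mode a single BAM carries a `CB` tag per record
#' (plus `n_untagged` untagged records) and a `barcodes.tsv` with "-1"
#' suffixes is written; otherwise one BAM per cell is written. The truth
#' table holds each cell's expected raw counts from [pileup_oracle()].
#'
#' @param out_dir Output directory.
#' @param n_cells Number of cells.
#' @param reads_per_cell Reads per transcript per cell.
#' @param read_length Read length in nt (must not exceed the shortest
#'   spliced transcript).
#' @param cell_densities List of beta parameter pairs, one per cell
#'   (recycled); the density of a read's spliced midpoint. Default: 5'
#'   biased cells with one 3'-concentrated (skewed) cell at the end.
#' @param barcoded Write one tagged BAM + barcodes.tsv instead of per-cell
#'   BAMs.
#' @param n_untagged Untagged records added in barcoded mode.
#' @param seed Integer seed (required).
#' @return List with `bed`, `bam` (path or named vector of paths),
#'   `barcodes` (path or NULL), `cell_ids`, `truth` (named list of length-
#'   100 integer vectors), `records` (the per-cell alignment tables).
#' @export
generate_toy_bam <- function(out_dir, n_cells = 3L, reads_per_cell = 30L,
                             read_length = 25L,
                             cell_densities = NULL,
                             barcoded = FALSE, n_untagged = 2L, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (n_cells < 1L || reads_per_cell < 1L)
    stop("need >= 1 cell and >= 1 read", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bed_path <- file.path(out_dir, "toy_model.bed")
  writeLines(toy_bed_lines(), bed_path)
  gm <- load_gene_model(bed_path)
  min_L <- min(vapply(gm$transcripts, `[[`, integer(1), "spliced_length"))
  if (read_length > min_L)
    stop(sprintf("read length %d exceeds shortest transcript (%d nt)",
                 read_length, min_L), call. = FALSE)
  if (is.null(cell_densities)) {
    cell_densities <- rep(list(c(1.5, 6)), n_cells)
    cell_densities[[n_cells]] <- c(8, 1.5)   # one 3'-skewed cell
  }
  cell_densities <- rep_len(cell_densities, n_cells)
  # barcodes must be unique; redraw deterministically on clash
  cell_ids <- if (barcoded) {
    withr::with_seed(seed, {
      draw <- function() vapply(seq_len(n_cells), function(i)
        paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = ""),
        character(1))
      ids <- draw()
      while (anyDuplicated(ids)) ids <- draw()
      ids
    })
  } else sprintf("toycell%d", seq_len(n_cells))

  sample_reads <- function(dens) {
    recs <- list()
    for (m in gm$transcripts) {
      L <- m$spliced_length
      starts <- 0:(L - read_length)
      w <- dbeta((starts + read_length / 2) / L, dens[1L], dens[2L]) + 1e-9
      s <- sample(starts, reads_per_cell, replace = TRUE, prob = w)
      for (si in s) {
        al <- spliced_read_alignment(m, si, read_length)
        recs[[length(recs) + 1L]] <-
          data.frame(chrom = m$chrom, pos = al$pos, cigar = al$cigar,
                     stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, recs)
  }
  per_cell <- withr::with_seed(seed + 1L,
                               lapply(cell_densities, sample_reads))
  names(per_cell) <- cell_ids
  truth <- lapply(per_cell, pileup_oracle, gene_models = gm)

  header <- c("@HD\tVN:1.6\tSO:coordinate",
              "@SQ\tSN:chrT1\tLN:400", "@SQ\tSN:chrT2\tLN:1100",
              "@SQ\tSN:chrT3\tLN:1000")
  sam_body <- function(recs, tag = NULL, prefix = "r") {
    vapply(seq_len(nrow(recs)), function(i) {
      base <- paste(sprintf("%s%04d", prefix, i), 0L, recs$chrom[i],
                    recs$pos[i] + 1L, 60L, recs$cigar[i], "*", 0L, 0L,
                    strrep("A", read_length), strrep("I", read_length),
                    sep = "\t")
      if (is.null(tag)) base else paste0(base, "\tCB:Z:", tag)
    }, character(1))
  }
  write_bam <- function(lines, stem) {
    sam <- file.path(out_dir, paste0(stem, ".sam"))
    writeLines(c(header, lines), sam)
    bam <- suppressMessages(
      Rsamtools::asBam(sam, file.path(out_dir, stem), overwrite = TRUE,
                       indexDestination = TRUE))
    unlink(sam)
    bam
  }

  if (barcoded) {
    lines <- unlist(lapply(seq_len(n_cells), function(i) {
      sam_body(per_cell[[i]], tag = paste0(cell_ids[i], "-1"),
               prefix = sprintf("c%d_r", i))
    }))
    if (n_untagged > 0L) {
      extra <- per_cell[[1L]][seq_len(min(n_untagged, nrow(per_cell[[1L]]))), ]
      lines <- c(lines, sam_body(extra, tag = NULL, prefix = "untag"))
    }
    bam <- write_bam(lines, "toy_barcoded")
    bc_path <- file.path(out_dir, "barcodes.tsv")
    writeLines(paste0(cell_ids, "-1"), bc_path)
  } else {
    bam <- vapply(seq_len(n_cells), function(i) {
      write_bam(sam_body(per_cell[[i]]), cell_ids[i])
    }, character(1))
    names(bam) <- cell_ids
    bc_path <- NULL
  }
  list(bed = bed_path, bam = bam, barcodes = bc_path, cell_ids = cell_ids,
       truth = truth, records = per_cell)
}
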
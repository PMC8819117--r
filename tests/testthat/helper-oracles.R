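# Independent oracles used across the suite.

# Exhaustive-subset trimmed-Gaussian oracle: for every retained subset of
# size h, fit moments (same regularization as the model definition) and
# score the trimmed log-likelihood with mvtnorm; return the best subset.
# Independent of the package's C-step implementation.
enum_trim_oracle <- function(X, alpha, reg_eps = 1e-6, eig_floor = 1e-12) {
  n <- nrow(X)
  d <- ncol(X)
  h <- n - floor(n * alpha + 1e-9)
  combs <- utils::combn(n, h)
  best <- -Inf
  best_s <- NULL
  for (j in seq_len(ncol(combs))) {
    S <- combs[, j]
    Xs <- X[S, , drop = FALSE]
    mu <- colMeans(Xs)
    C <- crossprod(sweep(Xs, 2L, mu)) / h
    C <- (C + t(C)) / 2 + diag(reg_eps * max(mean(diag(C)), eig_floor), d)
    ev <- eigen(C, symmetric = TRUE)
    if (min(ev$values) < eig_floor)
      C <- ev$vectors %*% (pmax(ev$values, eig_floor) * t(ev$vectors))
    obj <- sum(mvtnorm::dmvnorm(Xs, mu, C, log = TRUE))
    if (obj > best) {
      best <- obj
      best_s <- S
    }
  }
  list(objective = best, retained = sort(best_s))
}

# Brute-force spliced-coordinate list of a transcript model: all exonic
# genomic coordinates walked 5'->3' in transcript orientation.
spliced_walk <- function(model) {
  coords <- unlist(lapply(seq_len(nrow(model$blocks)), function(i) {
    s <- model$blocks[i, "start"]
    s:(s + model$blocks[i, "length"] - 1L)
  }))
  if (model$strand == "-") rev(coords) else coords
}

# assert every C-step trace and CTL curve in the suite is monotone
expect_monotone_trace <- function(fit) {
  tr <- fit$objective_trace
  expect_true(all(diff(tr) >= -1e-7 * (1 + abs(tr[-length(tr)]))))
}
expect_monotone_curve <- function(curve) {
  m <- curve$mean_objectives
  expect_true(all(diff(m) >= -1e-7 * (1 + abs(m[-length(m)]))))
}

# minimal SAM writing + BAM conversion for hand-built alignment layouts
toy_sam_header <- c("@HD\tVN:1.6\tSO:coordinate",
                    "@SQ\tSN:chr1\tLN:5000")
write_toy_bam <- function(records, dir, stem = "toy",
                          header = toy_sam_header) {
  # records: data.frame chrom, pos (0-based), cigar, optional tag
  lines <- vapply(seq_len(nrow(records)), function(i) {
    qlen <- sum(as.integer(
      regmatches(records$cigar[i],
                 gregexpr("[0-9]+(?=[MIS=X])", records$cigar[i],
                          perl = TRUE))[[1L]]))
    base <- paste(sprintf("q%04d", i), 0L, records$chrom[i],
                  records$pos[i] + 1L, 60L, records$cigar[i], "*", 0L, 0L,
                  strrep("A", qlen), strrep("I", qlen), sep = "\t")
    if (!is.null(records$tag) && !is.na(records$tag[i]))
      base <- paste0(base, "\tCB:Z:", records$tag[i])
    base
  }, character(1))
  sam <- file.path(dir, paste0(stem, ".sam"))
  writeLines(c(header, lines), sam)
  suppressMessages(Rsamtools::asBam(sam, file.path(dir, stem),
                                    overwrite = TRUE,
                                    indexDestination = TRUE))
}

# a 100 nt single-exon plus-strand model on chr1:1000-1100 as a BED line
single_exon_bed <- "chr1\t1000\t1100\ttx1\t0\t+\t1000\t1100\t0\t1\t100,\t0,"

make_gene_model <- function(bed_lines, dir = withr::local_tempdir()) {
  path <- file.path(dir, "model.bed")
  writeLines(bed_lines, path)
  load_gene_model(path)
}
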
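# ---- per-cell annotation and output artifacts -------------------------------

#' Turn a trimmed fit into per-cell Typical/Skewed annotations
#'
#' Cells retained by the fit are Typical; trimmed cells are Skewed with
#' reason `clustering`; zero-coverage cells (which never entered the fit)
#' are Skewed with reason `zero_coverage`. Every input cell appears exactly
#' once.
#'
#' @param fit A `trimmed_fit` whose indices refer to rows of `matrix` after
#'   removing zero-flagged cells (see [clustering_input()]).
#' @param matrix The `reduced_matrix` the fit was computed from.
#' @param zero_flagged Character vector of zero-coverage cell ids (default:
#'   the matrix's own flags).
#' @param mode `"auto"` or `"manual"` — how alpha was chosen.
#' @return A data.frame of class `cell_annotation` with columns `cell_id`,
#'   `label` (TYPICAL/SKEWED), `reason`, `alpha_used`, `mode`, in the
#'   matrix's cell order.
#' @export
classify <- function(fit, matrix, zero_flagged = NULL,
                     mode = c("auto", "manual")) {
  stopifnot(inherits(fit, "trimmed_fit"), inherits(matrix, "reduced_matrix"))
  mode <- match.arg(mode)
  if (is.null(zero_flagged))
    zero_flagged <- matrix$cell_ids[matrix$zero_flags]
  fit_ids <- setdiff(matrix$cell_ids, zero_flagged)
  if (fit$n != length(fit_ids))
    stop(sprintf(
      "fit covers %d observations but matrix has %d non-zero-flagged cells",
      fit$n, length(fit_ids)), call. = FALSE)
  label <- setNames(rep("TYPICAL", length(fit_ids)), fit_ids)
  reason <- setNames(rep("clustering", length(fit_ids)), fit_ids)
  label[fit_ids[fit$trimmed]] <- "SKEWED"
  if (length(zero_flagged)) {
    label[zero_flagged] <- "SKEWED"
    reason[zero_flagged] <- "zero_coverage"
  }
  ann <- data.frame(cell_id = matrix$cell_ids,
                    label = unname(label[matrix$cell_ids]),
                    reason = unname(reason[matrix$cell_ids]),
                    alpha_used = fit$alpha,
                    mode = mode,
                    stringsAsFactors = FALSE)
  class(ann) <- c("cell_annotation", "data.frame")
  ann
}

#' Write the annotation artifacts
#'
#' Writes three files to `out_dir`: `TypicalCellsID.tsv` and
#' `SkewedCellsID.tsv` (one cell id per line) and `SkewCAnnotation.tsv`
#' (header `cell_id<TAB>SkewC`, values `Typical`/`Skewed`), a two-column
#' table directly loadable as cell metadata by downstream single-cell
#' toolkits.
#'
#' @param annotations A `cell_annotation` data.frame from [classify()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_outputs <- function(annotations, out_dir) {
  stopifnot(inherits(annotations, "cell_annotation"))
  if (any(grepl("[[:space:]]", annotations$cell_id)))
    stop("cell ids must not contain whitespace (TSV safety)", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  typical <- annotations$cell_id[annotations$label == "TYPICAL"]
  skewed  <- annotations$cell_id[annotations$label == "SKEWED"]
  paths <- c(typical = file.path(out_dir, "TypicalCellsID.tsv"),
             skewed = file.path(out_dir, "SkewedCellsID.tsv"),
             annotation = file.path(out_dir, "SkewCAnnotation.tsv"))
  writeLines(typical, paths[["typical"]])
  writeLines(skewed, paths[["skewed"]])
  writeLines(c("cell_id\tSkewC",
               paste(annotations$cell_id,
                     ifelse(annotations$label == "TYPICAL",
                            "Typical", "Skewed"),
                     sep = "\t")),
             paths[["annotation"]])
  invisible(paths)
}

#' Read an annotation table back
#' @param path Path to `SkewCAnnotation.tsv`.
#' @return Data.frame with `cell_id` and `label` (TYPICAL/SKEWED).
#' @export
read_annotation <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (!identical(names(dt), c("cell_id", "SkewC")))
    stop("malformed annotation header", call. = FALSE)
  data.frame(cell_id = dt$cell_id,
             label = ifelse(dt$SkewC == "Typical", "TYPICAL", "SKEWED"),
             stringsAsFactors = FALSE)
}

#' Overlay gene-body-coverage curves by class
#'
#' Draws each cell's 100-position profile, colored Typical vs Skewed, with
#' the per-class mean curve emphasized. Requires ggplot2.
#'
#' @param matrix A `coverage_matrix`.
#' @param annotations A `cell_annotation`.
#' @return A ggplot object.
#' @export
plot_coverage_classes <- function(matrix, annotations) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  lab <- setNames(annotations$label, annotations$cell_id)
  df <- data.frame(
    cell_id = rep(matrix$cell_ids, each = 100L),
    position = rep(0:99, length(matrix$cell_ids)),
    coverage = as.vector(t(matrix$values)),
    class = rep(unname(lab[matrix$cell_ids]), each = 100L))
  ggplot2::ggplot(df, ggplot2::aes(x = position, y = coverage,
                                   group = cell_id,
                                   color = class)) +
    ggplot2::geom_line(alpha = 0.25, linewidth = 0.3) +
    ggplot2::stat_summary(ggplot2::aes(group = class), fun = mean,
                          geom = "line", linewidth = 1.1) +
    ggplot2::facet_wrap(~class) +
    ggplot2::labs(x = "gene body percentile (5' → 3')",
                  y = "normalized coverage", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a CTL curve with the selected alpha marked
#' @param curve A `ctl_curve` (ideally after [select_alpha_auto()]).
#' @return A ggplot object.
#' @export
plot_ctl_curve <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  df <- data.frame(alpha = curve$alphas, mean_objective = curve$mean_objectives)
  p <- ggplot2::ggplot(df, ggplot2::aes(alpha, mean_objective)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "trimming level α",
                  y = "mean trimmed log-likelihood") +
    ggplot2::theme_minimal()
  if (!is.na(curve$selected_alpha))
    p <- p + ggplot2::geom_vline(xintercept = curve$selected_alpha,
                                 linetype = "dashed", color = "red")
  p
}
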
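# Dot plots of enumerated statistics with jackknife error bars, plus a
# plain-text "plot spec" so the rendered content is testable without pixel
# comparison.

#' Read a population -> category file
#'
#' Two tab-separated columns: population, category.
#'
#' @param path file path.
#' @return data frame with `pop` and `category`.
#' @export
read_catfile <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop("malformed category file ", path, " at line ",
         which(keep)[bad[1L]], ": expected 2 tab-separated columns",
         call. = FALSE)
  }
  m <- do.call(rbind, parts)
  data.frame(pop = m[, 1L], category = m[, 2L], stringsAsFactors = FALSE)
}

#' Read a category -> colour/symbol legend file
#'
#' Three tab-separated columns: category, colour, plotting symbol (an R
#' `pch` code).
#'
#' @param path file path.
#' @return data frame with `category`, `color`, `symbol`.
#' @export
read_legfile <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    stop("malformed legend file ", path, " at line ",
         which(keep)[bad[1L]], ": expected 3 tab-separated columns",
         call. = FALSE)
  }
  m <- do.call(rbind, parts)
  sym <- suppressWarnings(as.integer(m[, 3L]))
  if (anyNA(sym)) {
    stop("malformed legend file ", path, " at line ",
         which(keep)[which(is.na(sym))[1L]],
         ": symbol must be an integer pch code", call. = FALSE)
  }
  data.frame(category = m[, 1L], color = m[, 2L], symbol = sym,
             stringsAsFactors = FALSE)
}

#' Plot a result table as a horizontal dot plot with error bars
#'
#' Points are sorted by estimate (unless `sort_by_estimate = FALSE`, e.g.
#' for proportion grids) with error bars `estimate +/- multiplier * se`;
#' the conventional multipliers are 1.96 for f3/distance wrappers and 3.3
#' for D/f4 wrappers.  When `out_prefix` is given, writes `<prefix>.pdf`
#' and `<prefix>.plotspec` — a tab-separated file with one row per plotted
#' point (rank, label, category, colour, symbol, estimate, bar ends,
#' Z-score) in plotted order.
#'
#' @param tab a `stat_table` (or any data frame with `estimate`, `se`, `z`
#'   columns and a label column).
#' @param catfile optional path to a population -> category file;
#'   populations missing from it get the `"default"` category.
#' @param legfile optional path to a category -> colour/symbol file.
#' @param error_bar_multiplier half-width of the error bars in units of se.
#' @param out_prefix output prefix, or `NULL` to skip writing files.
#' @param annotate_z annotate each point with its |Z|-score.
#' @param sort_by_estimate order points by estimate.
#' @param label_col column naming each point; defaults to the table's
#'   `free_col` attribute, then `"label"`.
#' @return the ggplot object, invisibly.
#' @importFrom ggplot2 .data
#' @export
emit_plot <- function(tab, catfile = NULL, legfile = NULL,
                      error_bar_multiplier = 1.96, out_prefix = NULL,
                      annotate_z = FALSE, sort_by_estimate = TRUE,
                      label_col = NULL) {
  stopifnot(is.data.frame(tab), all(c("estimate", "se") %in% names(tab)))
  if (is.null(label_col)) {
    label_col <- attr(tab, "free_col")
    if (is.null(label_col)) label_col <- "label"
  }
  if (!label_col %in% names(tab)) {
    stop("label column '", label_col, "' not found in table", call. = FALSE)
  }
  spec <- data.frame(label = as.character(tab[[label_col]]),
                     estimate = tab$estimate, se = tab$se,
                     z = if ("z" %in% names(tab)) tab$z else NA_real_,
                     stringsAsFactors = FALSE)
  spec$lo <- spec$estimate - error_bar_multiplier * spec$se
  spec$hi <- spec$estimate + error_bar_multiplier * spec$se

  cat_map <- if (!is.null(catfile)) read_catfile(catfile) else NULL
  spec$category <- if (is.null(cat_map)) "default" else {
    ifelse(is.na(match(spec$label, cat_map$pop)), "default",
           cat_map$category[match(spec$label, cat_map$pop)])
  }
  leg <- if (!is.null(legfile)) read_legfile(legfile) else NULL
  j <- if (is.null(leg)) rep(NA_integer_, nrow(spec)) else
    match(spec$category, leg$category)
  spec$color <- ifelse(is.na(j), "grey30", leg$color[j])
  spec$symbol <- ifelse(is.na(j), 16L, leg$symbol[j])

  if (sort_by_estimate) spec <- spec[order(spec$estimate), , drop = FALSE]
  spec$rank <- seq_len(nrow(spec))
  spec$label <- factor(spec$label, levels = spec$label)

  pal <- unique(spec[, c("category", "color", "symbol")])
  p <- ggplot2::ggplot(spec, ggplot2::aes(x = .data$estimate,
                                          y = .data$label,
                                          colour = .data$category,
                                          shape = .data$category)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey70") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0) +
    ggplot2::geom_point(size = 2.2) +
    ggplot2::scale_colour_manual(values = setNames(pal$color,
                                                   pal$category)) +
    ggplot2::scale_shape_manual(values = setNames(pal$symbol,
                                                  pal$category)) +
    ggplot2::labs(x = "estimate", y = NULL) +
    ggplot2::theme_bw()
  if (annotate_z && !all(is.na(spec$z))) {
    p <- p + ggplot2::geom_text(ggplot2::aes(x = .data$hi,
                                             label = sprintf("%.1f",
                                                             abs(.data$z))),
                                hjust = -0.25, size = 2.6,
                                colour = "grey20", show.legend = FALSE)
  }
  if (!is.null(out_prefix)) {
    out <- spec[, c("rank", "label", "category", "color", "symbol",
                    "estimate", "lo", "hi", "z")]
    write.table(out, paste0(out_prefix, ".plotspec"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    grDevices::pdf(paste0(out_prefix, ".pdf"), width = 6,
                   height = max(3, 0.25 * nrow(spec) + 1.5))
    print(p)
    grDevices::dev.off()
  }
  invisible(p)
}
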
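# Pearson correlation of per-segment tracks, per chromosome and averaged.

#' Pearson product-moment correlation
#'
#' Returns `NA` (an undefined value, deliberately not 0) when either series
#' has zero variance; a zero would fabricate the absence of a relation out
#' of a degenerate track.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return Pearson r in \[-1, 1\], or `NA` when undefined.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 2L) stop("need at least 2 observations")
  xc <- x - mean(x); yc <- y - mean(y)
  sx <- sqrt(sum(xc^2)); sy <- sqrt(sum(yc^2))
  if (sx == 0 || sy == 0) return(NA_real_)
  r <- sum(xc * yc) / (sx * sy)
  max(-1, min(1, r))
}

#' Correlate every SSTR track with every feature track
#'
#' Computes Pearson r over the non-excluded segments of one chromosome for
#' every (SSTR key, feature key) pair. Excluded segments are dropped
#' identically for every pair.
#'
#' @param tracks list from [segment_tracks()] (one chromosome).
#' @param sstr_keys_use row keys (default all 176 of [sstr_keys()]).
#' @param feature_keys column keys (default gc, the 11 gene categories and
#'   the 5 retrotransposon families).
#' @return Numeric matrix of r values (rows = SSTR keys, columns = feature
#'   keys); `NA` where a track has zero variance. NULL, with a warning, when
#'   fewer than 2 segments survive exclusion.
#' @export
correlate_all <- function(tracks, sstr_keys_use = sstr_keys(),
                          feature_keys = c("gc", GENE_CATEGORIES,
                                           RETRO_FAMILIES)) {
  keep <- !tracks$segments$excluded
  if (sum(keep) < 2L) {
    warning("chromosome ", tracks$segments$chrom[1],
            " skipped: fewer than 2 non-excluded segments")
    return(NULL)
  }
  v <- tracks$values[keep, , drop = FALSE]
  m <- matrix(NA_real_, length(sstr_keys_use), length(feature_keys),
              dimnames = list(sstr_keys_use, feature_keys))
  for (fk in feature_keys) {
    y <- v[, fk]
    for (sk in sstr_keys_use) m[sk, fk] <- pearson(v[, sk], y)
  }
  m
}

#' Average correlation matrices over chromosomes
#'
#' Unweighted arithmetic mean per cell over the chromosomes where the cell
#' is defined; a cell undefined everywhere stays `NA`.
#'
#' @param matrices list of matrices from [correlate_all()] (NULL entries are
#'   dropped).
#' @return Matrix of the same shape.
#' @export
average_over_chromosomes <- function(matrices) {
  matrices <- matrices[!vapply(matrices, is.null, logical(1))]
  if (!length(matrices)) stop("no chromosome matrices to average")
  a <- Reduce(`+`, lapply(matrices, function(m) replace(m, is.na(m), 0)))
  n <- Reduce(`+`, lapply(matrices, function(m) 0 + !is.na(m)))
  out <- a / n
  out[n == 0] <- NA_real_
  out
}

#' Render a correlation matrix as a PNG heatmap
#'
#' Rows are ordered by motif group (SS, WW, SW, WS), then unit, then length;
#' the colour scale is diverging and symmetric about zero; undefined cells
#' are drawn grey. Thin separators mark the four group blocks.
#'
#' @param matrix correlation matrix (rows named with SSTR keys).
#' @param path output PNG path.
#' @param main plot title.
#' @return The output path, invisibly.
#' @export
plot_heatmap <- function(matrix, path, main = "SSTR correlation") {
  if (!nrow(matrix) || !ncol(matrix)) stop("empty correlation matrix")
  ord <- order_by_group(rownames(matrix))
  m <- matrix[ord, , drop = FALSE]
  lim <- max(abs(m), na.rm = TRUE)
  if (!is.finite(lim) || lim == 0) lim <- 1
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(101)
  grDevices::png(path, width = 480 + 40 * ncol(m), height = 1200, res = 110)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(6, 6, 3, 1))
  z <- t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                  z = matrix(0, ncol(m), nrow(m)),
                  col = "grey80", axes = FALSE, xlab = "", ylab = "",
                  main = main)
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = z,
                  zlim = c(-lim, lim), col = pal, add = TRUE)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.7)
  lab_rows <- which(seq_len(nrow(m)) %% 11 == 6)
  graphics::axis(2, at = nrow(m) + 1 - lab_rows,
                 labels = sub("\\..*", "", rownames(m)[lab_rows]),
                 las = 2, cex.axis = 0.6)
  grp <- group_of_keys(rownames(m))
  breaks <- which(diff(as.integer(grp)) != 0)
  graphics::abline(h = nrow(m) - breaks + 0.5, lwd = 2, col = "black")
  invisible(path)
}

# order SSTR keys by group (SS, WW, SW, WS), unit, length
order_by_group <- function(keys) {
  units <- sub("\\..*", "", keys)
  lens <- suppressWarnings(as.integer(sub(".*\\.", "", keys)))
  lens[is.na(lens)] <- 0L
  ut <- sstr_units()
  grp <- ut$group[match(units, ut$unit)]
  order(as.integer(grp), match(units, ut$unit), lens)
}

group_of_keys <- function(keys) {
  units <- sub("\\..*", "", keys)
  ut <- sstr_units()
  ut$group[match(units, ut$unit)]
}

#' Write a correlation matrix as TSV
#' @param matrix correlation matrix.
#' @param path output path.
#' @export
write_correlation <- function(matrix, path) {
  df <- data.frame(sstr_key = rownames(matrix), matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
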
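# Nucleosome-landscape analysis of ATAC insert sizes: length spectra,
# nucleosome-class fractions, the multi-nucleosome index, and V-plot
# aggregation around peak centers.

#' Fragment-class configuration
#'
#' Length bands: NFR (sub-nucleosomal) fragments are shorter than `nfr_max`
#' bp (exclusive; "less than 140 bp"); mono-nucleosomal fragments span
#' `[mono_min, mono_max]` bp inclusive ("150-200 bp"); multi-nucleosomal
#' fragments are at least `multi_min` bp. Lengths in the gaps (140-149 and
#' 201-249 with defaults) are classed "other" rather than forced into a
#' band.
#'
#' @param nfr_max,mono_min,mono_max,multi_min band boundaries in bp.
#' @param hist_binwidth,hist_max histogram bin width and upper edge in bp
#'   (longer fragments fall into the last bin).
#' @return list of class `frag_class_config`.
#' @export
frag_class_config <- function(nfr_max = 140L, mono_min = 150L,
                              mono_max = 200L, multi_min = 250L,
                              hist_binwidth = 10L, hist_max = 1000L) {
  stopifnot(nfr_max < mono_min, mono_min < mono_max, mono_max < multi_min,
            hist_binwidth > 0, hist_max > hist_binwidth)
  structure(list(nfr_max = as.integer(nfr_max),
                 mono_min = as.integer(mono_min),
                 mono_max = as.integer(mono_max),
                 multi_min = as.integer(multi_min),
                 hist_binwidth = as.integer(hist_binwidth),
                 hist_max = as.integer(hist_max)),
            class = "frag_class_config")
}

classify_lengths <- function(len, config) {
  ifelse(len < config$nfr_max, "nfr",
         ifelse(len >= config$mono_min & len <= config$mono_max, "mono",
                ifelse(len >= config$multi_min, "multi", "other")))
}

#' Fragment-length spectrum
#'
#' Histogram of insert lengths plus nucleosome-class fractions.
#'
#' @param frags a [fragments()] table or an integer vector of lengths.
#' @param config a [frag_class_config()].
#' @return list of class `length_spectrum` with `breaks`, `counts`,
#'   `class_fractions` (`nfr`, `mono`, `multi`, `other`, summing to 1) and
#'   `n_total`.
#' @export
length_spectrum <- function(frags, config = frag_class_config()) {
  len <- if (is.data.frame(frags)) fragment_lengths(frags) else
    as.integer(frags)
  if (length(len) == 0L) stop("no fragments")
  breaks <- seq.int(0L, config$hist_max, by = config$hist_binwidth)
  bin <- pmin(pmax(ceiling(len / config$hist_binwidth), 1L),
              length(breaks) - 1L)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  cls <- classify_lengths(len, config)
  fr <- c(nfr = sum(cls == "nfr"), mono = sum(cls == "mono"),
          multi = sum(cls == "multi"), other = sum(cls == "other")) /
    length(len)
  structure(list(breaks = breaks, counts = counts, class_fractions = fr,
                 n_total = length(len)),
            class = "length_spectrum")
}

#' @export
print.length_spectrum <- function(x, ...) {
  cat("length_spectrum: n =", x$n_total, "\n")
  print(round(x$class_fractions, 4))
  invisible(x)
}

#' Multi-nucleosome index
#'
#' Scalar summary of the nucleosome landscape:
#' `multi fraction / (nfr + mono fractions)`; 0 when there are no
#' multi-nucleosomal fragments. A collapse of the multi-nucleosomal
#' component (as in the remodeled final condition) lowers the index.
#'
#' @param spectrum a [length_spectrum()].
#' @return non-negative float.
#' @export
multinucleosome_index <- function(spectrum) {
  fr <- spectrum$class_fractions
  if (fr[["multi"]] == 0) return(0)
  fr[["multi"]] / (fr[["nfr"]] + fr[["mono"]])
}

#' V-plot aggregation of fragments around peak centers
#'
#' 2-D histogram of (signed midpoint-to-center distance, insert length) over
#' all qualifying (fragment, peak) pairs: a fragment whose midpoint lies
#' within `max_dist` bp of a peak center (summit when present, else
#' midpoint) contributes one count per qualifying peak. Fragments longer
#' than `max_len` are excluded.
#'
#' @param frags a [fragments()] table.
#' @param pk a [peaks()] table (optionally cluster-labelled).
#' @param cluster_filter optional: keep only peaks whose label (in
#'   `cluster_labels`) equals this value.
#' @param cluster_labels named vector peak name -> cluster label; required
#'   with `cluster_filter`.
#' @param max_dist,max_len grid extent in bp.
#' @param w_d,w_l bin widths (distance, length) in bp.
#' @param normalization `"raw"` counts, `"per-peak-mean"` (divide by the
#'   number of contributing peaks), or `"density"` (divide by the total).
#' @return list of class `vplot_grid`: `counts` (length bins x distance
#'   bins), `dist_breaks`, `len_breaks`, `n_peaks`, `normalization`.
#' @export
vplot <- function(frags, pk, cluster_filter = NULL, cluster_labels = NULL,
                  max_dist = 500L, max_len = 600L, w_d = 10L, w_l = 10L,
                  normalization = c("raw", "per-peak-mean", "density")) {
  normalization <- match.arg(normalization)
  if (!is.null(cluster_filter)) {
    if (is.null(cluster_labels)) stop("cluster_filter needs cluster_labels")
    pk <- pk[pk$name %in% names(cluster_labels)[cluster_labels ==
                                                  cluster_filter], ,
             drop = FALSE]
  }
  if (nrow(pk) == 0L) stop("no peaks left after cluster filter")
  dist_breaks <- seq.int(-max_dist, max_dist, by = w_d)
  len_breaks <- seq.int(0L, max_len, by = w_l)
  nd <- length(dist_breaks) - 1L
  nl <- length(len_breaks) - 1L
  counts <- matrix(0, nl, nd)
  centers <- peak_anchor(pk)
  contributing <- 0L
  for (sc in unique(pk$scaffold)) {
    fi <- which(frags$scaffold == sc)
    if (length(fi) == 0L) next
    mid <- (frags$start[fi] + frags$end[fi]) %/% 2L
    len <- frags$end[fi] - frags$start[fi]
    o <- order(mid)
    mid <- mid[o]; len <- len[o]
    for (ci in which(pk$scaffold == sc)) {
      c0 <- centers[ci]
      lo <- findInterval(c0 - max_dist - 1L, mid) + 1L
      hi <- findInterval(c0 + max_dist, mid)
      if (hi < lo) next
      d <- mid[lo:hi] - c0
      l <- len[lo:hi]
      ok <- l >= 1L & l <= max_len
      if (!any(ok)) next
      contributing <- contributing + 1L
      db <- pmin(pmax(floor((d[ok] + max_dist) / w_d) + 1L, 1L), nd)
      lb <- pmin(pmax(ceiling(l[ok] / w_l), 1L), nl)
      idx <- cbind(lb, db)
      for (r in seq_len(nrow(idx)))
        counts[idx[r, 1L], idx[r, 2L]] <- counts[idx[r, 1L], idx[r, 2L]] + 1
    }
  }
  if (normalization == "per-peak-mean" && contributing > 0L)
    counts <- counts / contributing
  if (normalization == "density" && sum(counts) > 0)
    counts <- counts / sum(counts)
  structure(list(counts = counts, dist_breaks = dist_breaks,
                 len_breaks = len_breaks, n_peaks = nrow(pk),
                 n_contributing = contributing,
                 normalization = normalization),
            class = "vplot_grid")
}

#' @export
print.vplot_grid <- function(x, ...) {
  cat("vplot_grid:", nrow(x$counts), "length bins x", ncol(x$counts),
      "distance bins;", x$n_peaks, "peaks;", x$normalization,
      "normalization\n")
  invisible(x)
}

#' Write a V-plot grid as TSV
#'
#' Matrix TSV with a distance bin-edge header row and a leading length
#' bin-edge column.
#'
#' @param grid a [vplot()] result.
#' @param path output path.
#' @export
write_vplot <- function(grid, path) {
  dn <- paste0("d", grid$dist_breaks[-length(grid$dist_breaks)])
  df <- data.frame(length_bin = grid$len_breaks[-length(grid$len_breaks)],
                   grid$counts, check.names = FALSE)
  names(df)[-1L] <- dn
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
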
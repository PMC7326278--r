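# Per-base fragment coverage as run-length encoded tracks, the simplified
# Poisson sliding-window peak caller, and per-peak signal averaging.

#' Construct a coverage track
#'
#' A coverage track is a named list (one element per scaffold) of run tables
#' `data.frame(start, end, value)` with sorted, non-overlapping runs and
#' values >= 0. Zero runs may be omitted; the track is defined as 0
#' everywhere not covered by a run.
#'
#' @param runs named list of run data frames.
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(runs) {
  for (sc in names(runs)) {
    r <- runs[[sc]]
    if (nrow(r)) {
      if (is.unsorted(r$start) || any(r$start[-1L] < r$end[-nrow(r)]))
        stop("coverage runs must be sorted and non-overlapping on ", sc)
      if (any(r$value < 0)) stop("coverage values must be >= 0")
    }
    rownames(runs[[sc]]) <- NULL
  }
  structure(runs, class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(x), "scaffold(s),",
      sum(vapply(x, nrow, 0L)), "runs\n")
  invisible(x)
}

#' Compute fragment coverage
#'
#' The value at base `b` is the number of fragments overlapping `b`
#' (exact integers before any scaling).
#'
#' @param frags a [fragments()] table.
#' @return a [coverage_track()] containing only the non-zero runs.
#' @export
compute_coverage <- function(frags) {
  out <- list()
  for (sc in sort(unique(frags$scaffold))) {
    i <- frags$scaffold == sc
    pos <- c(frags$start[i], frags$end[i])
    w <- c(rep(1, sum(i)), rep(-1, sum(i)))
    delta <- rowsum(w, pos)          # rows sorted by position
    u <- as.integer(rownames(delta))
    depth <- cumsum(delta[, 1L])[-length(u)]
    runs <- data.frame(start = u[-length(u)], end = u[-1L], value = depth)
    runs <- runs[runs$value != 0, , drop = FALSE]
    # merge adjacent equal-value runs split by internal breakpoints
    if (nrow(runs) > 1L) {
      joinable <- c(FALSE, runs$start[-1L] == runs$end[-nrow(runs)] &
                      runs$value[-1L] == runs$value[-nrow(runs)])
      grp <- cumsum(!joinable)
      runs <- data.frame(start = runs$start[!joinable],
                         end = as.integer(tapply(runs$end, grp, max)),
                         value = runs$value[!joinable])
    }
    out[[sc]] <- runs
  }
  coverage_track(out)
}

# Cumulative mass function: integral of depth over [0, x), vectorized in x.
track_mass_at <- function(runs, x) {
  if (nrow(runs) == 0L) return(numeric(length(x)))
  cs <- c(0, cumsum((runs$end - runs$start) * runs$value))
  j <- findInterval(x, runs$start)
  res <- numeric(length(x))
  inside <- j >= 1L
  jj <- pmax(j, 1L)
  res[inside] <- cs[jj[inside]] +
    runs$value[jj[inside]] *
    pmax(0, pmin(x[inside], runs$end[jj[inside]]) - runs$start[jj[inside]])
  res
}

# Summed depth over [a, b) per interval (vectorized)
track_window_mass <- function(runs, a, b) {
  track_mass_at(runs, b) - track_mass_at(runs, a)
}

track_total_mass <- function(track) {
  sum(vapply(track, function(r)
    sum((r$end - r$start) * r$value), numeric(1)))
}

#' Peak-calling configuration
#'
#' @param window sliding window size in bp.
#' @param step window step in bp (must be <= `window`).
#' @param q_cutoff Benjamini-Hochberg q-value threshold (default 0.01, the
#'   initial cutoff used for peak calling).
#' @param min_peak_len minimum emitted peak length in bp.
#' @param frag_len expected fragment length in bp; window depth mass is
#'   divided by it to approximate a fragment count, the unit in which the
#'   Poisson background model holds (per-bp depth mass itself is
#'   overdispersed because each fragment paints many correlated bases).
#' @return list of class `peak_call_config`.
#' @export
peak_call_config <- function(window = 200L, step = 50L, q_cutoff = 0.01,
                             min_peak_len = 150L, frag_len = 200L) {
  stopifnot(q_cutoff > 0, q_cutoff < 1, step <= window, window > 0, step > 0,
            frag_len > 0)
  structure(list(window = as.integer(window), step = as.integer(step),
                 q_cutoff = q_cutoff, min_peak_len = as.integer(min_peak_len),
                 frag_len = as.integer(frag_len)),
            class = "peak_call_config")
}

#' Call peaks from a coverage track
#'
#' Simplified Poisson window caller: windows of `config$window` bp slide by
#' `config$step` across every scaffold; each window's summed depth mass
#' (converted to approximate fragment counts via `config$frag_len`) is
#' tested against the genome-wide background rate -- estimated as the
#' median window count so that the enriched minority of windows does not
#' inflate the null -- with a Poisson upper-tail p-value,
#' Benjamini-Hochberg corrected over all windows. Significant (q < cutoff) overlapping windows are merged
#' into peaks; the summit is the leftmost base of maximal depth; peaks
#' shorter than `min_peak_len` are dropped. A zero-signal track yields an
#' empty peak list. This is a deliberately simple stand-in for a full
#' local-background caller such as MACS2.
#'
#' @param track single-sample [coverage_track()].
#' @param config a [peak_call_config()].
#' @param scaffold_lens named integer vector of scaffold lengths; the genome
#'   length is their sum.
#' @return a [peaks()] table; `score` is the peak's best `-log10(q)`.
#' @export
call_peaks <- function(track, config = peak_call_config(), scaffold_lens) {
  total <- track_total_mass(track)
  if (total == 0) return(peaks(character(), integer(), integer()))
  wtab <- list()
  for (sc in names(scaffold_lens)) {
    L <- scaffold_lens[[sc]]
    if (L < config$window) next
    starts <- seq.int(0L, L - config$window, by = config$step)
    runs <- track[[sc]]
    cnt <- if (is.null(runs)) numeric(length(starts)) else
      track_window_mass(runs, starts, starts + config$window)
    wtab[[sc]] <- data.frame(scaffold = sc, start = starts,
                             count = round(cnt / config$frag_len),
                             stringsAsFactors = FALSE)
  }
  w <- do.call(rbind, wtab)
  # genome-wide background: the median window count is robust to the
  # enriched minority of windows (the mean would fold signal into the null)
  mu <- max(stats::median(w$count), 0.5)
  w$p <- stats::ppois(w$count - 1, mu, lower.tail = FALSE)
  w$q <- stats::p.adjust(w$p, method = "BH")
  sig <- w[w$q < config$q_cutoff, , drop = FALSE]
  if (nrow(sig) == 0L) return(peaks(character(), integer(), integer()))
  m <- merge_interval_rows(sig$scaffold, sig$start,
                           sig$start + config$window)
  score <- as.numeric(tapply(-log10(pmax(sig$q, 1e-300)), m$group, max))
  keep <- (m$end - m$start) >= config$min_peak_len
  if (!any(keep)) return(peaks(character(), integer(), integer()))
  summit <- integer(sum(keep))
  ks <- which(keep)
  for (i in seq_along(ks)) {
    k <- ks[i]
    runs <- track[[m$scaffold[k]]]
    sel <- runs$end > m$start[k] & runs$start < m$end[k]
    if (!any(sel)) { summit[i] <- 0L; next }
    rr <- runs[sel, , drop = FALSE]
    best <- which.max(rr$value)        # leftmost maximal run
    summit[i] <- max(rr$start[best], m$start[k]) - m$start[k]
  }
  peaks(m$scaffold[keep], m$start[keep], m$end[keep],
        name = paste0("peak_", seq_len(sum(keep))),
        score = score[keep], summit_offset = summit)
}

#' Merge peak sets into consensus peaks
#'
#' Applies the replicate/consensus merge rule: two peaks are joined iff the
#' distance between their proximal ends is < 1 bp in half-open coordinates,
#' i.e. they overlap or are exactly book-ended. The merged peak's score is
#' the maximum of its constituents; names are `merged_<k>` in sorted order.
#' The operation is idempotent, commutative and associative, so merging all
#' samples at once equals any iterated pairwise merge.
#'
#' @param ... peak tables, or a single list of peak tables.
#' @return consensus [peaks()] table sorted by (scaffold, start).
#' @export
merge_peak_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) &&
      !is.data.frame(sets[[1L]])) sets <- sets[[1L]]
  pooled <- do.call(rbind, lapply(sets, function(p)
    data.frame(scaffold = p$scaffold, start = p$start, end = p$end,
               score = p$score, stringsAsFactors = FALSE)))
  if (is.null(pooled) || nrow(pooled) == 0L)
    return(peaks(character(), integer(), integer()))
  m <- merge_interval_rows(pooled$scaffold, pooled$start, pooled$end)
  score <- as.numeric(tapply(pooled$score, m$group, max))
  peaks(m$scaffold, m$start, m$end,
        name = paste0("merged_", seq_along(m$start)), score = score)
}

#' Mean signal of a track over each peak
#'
#' For each peak, the mean per-base depth: the coverage mass intersecting the
#' peak divided by the peak length (the "average score across each peak").
#'
#' @param track a [coverage_track()].
#' @param pk a [peaks()] table.
#' @return numeric vector named by peak name.
#' @export
average_signal <- function(track, pk) {
  out <- numeric(nrow(pk))
  for (sc in unique(pk$scaffold)) {
    i <- pk$scaffold == sc
    runs <- track[[sc]]
    if (is.null(runs)) next
    out[i] <- track_window_mass(runs, pk$start[i], pk$end[i]) /
      (pk$end[i] - pk$start[i])
  }
  names(out) <- pk$name
  out
}

#' Build a peaks x samples signal matrix
#'
#' @param tracks named list of per-sample [coverage_track()]s.
#' @param pk consensus [peaks()] defining the rows.
#' @param groups named character vector mapping sample -> group label.
#' @return numeric matrix (peaks x samples) with a `"groups"` attribute.
#' @export
signal_matrix <- function(tracks, pk, groups = NULL) {
  m <- vapply(tracks, average_signal, numeric(nrow(pk)), pk = pk)
  if (nrow(pk) == 1L) m <- matrix(m, nrow = 1L,
                                  dimnames = list(pk$name, names(tracks)))
  rownames(m) <- pk$name
  if (!is.null(groups)) attr(m, "groups") <- groups[colnames(m)]
  m
}

#' Apply per-sample scale factors
#'
#' Multiplies every value by its sample's factor; structure is unchanged.
#' For a single-sample coverage track pass the sample name.
#'
#' @param x a signal matrix (samples in columns) or a [coverage_track()].
#' @param factors a [scale_factors()] table.
#' @param sample for a coverage track, which sample's factor to apply.
#' @return scaled object of the same shape.
#' @export
apply_scale <- function(x, factors, sample = NULL) {
  f <- stats::setNames(factors$factor, factors$sample)
  if (inherits(x, "coverage_track")) {
    stopifnot(!is.null(sample), sample %in% names(f))
    return(coverage_track(lapply(unclass(x), function(r) {
      r$value <- r$value * f[[sample]]
      r
    })))
  }
  miss <- setdiff(colnames(x), names(f))
  if (length(miss)) stop("no scale factor for sample(s): ",
                         paste(miss, collapse = ", "))
  sweep(x, 2L, f[colnames(x)], `*`)
}
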
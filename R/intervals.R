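# Shared interval arithmetic. All coordinates are 0-based half-open [start, end)
# on named scaffolds; strand is one of "+", "-", "." and never affects
# interval arithmetic.

#' Construct a peak table
#'
#' Peaks are plain data frames with one row per peak and columns
#' `scaffold`, `start`, `end`, `name`, `score`, `strand` and
#' `summit_offset` (offset of the summit from `start`, `NA` when unknown).
#' Coordinates are 0-based half-open.
#'
#' @param scaffold character vector of scaffold names.
#' @param start,end integer vectors, `0 <= start < end`.
#' @param name peak names (defaults to `peak_<i>`).
#' @param score non-negative numeric scores.
#' @param strand strand characters, `"+"`, `"-"` or `"."`.
#' @param summit_offset integer offsets of the summit from `start`
#'   (`NA` = absent); must be `< end - start`.
#' @return a `data.frame` of class `c("peaks", "data.frame")`.
#' @export
peaks <- function(scaffold, start, end, name = NULL, score = 0,
                  strand = ".", summit_offset = NA_integer_) {
  n <- length(scaffold)
  if (is.null(name)) name <- if (n) paste0("peak_", seq_len(n)) else character()
  df <- data.frame(scaffold = as.character(scaffold),
                   start = as.integer(start), end = as.integer(end),
                   name = as.character(name),
                   score = rep_len(as.numeric(score), n),
                   strand = rep_len(as.character(strand), n),
                   summit_offset = rep_len(as.integer(summit_offset), n),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  bad <- !is.na(df$summit_offset) &
    (df$summit_offset < 0L | df$summit_offset >= df$end - df$start)
  if (any(bad)) stop("summit_offset outside peak for: ",
                     paste(df$name[bad], collapse = ", "))
  class(df) <- c("peaks", "data.frame")
  df
}

#' Construct a fragment table
#'
#' Fragments are sequenced ATAC inserts: strandless intervals whose length is
#' `end - start` (at least 1 bp).
#'
#' @param scaffold,start,end as in [peaks()].
#' @return a `data.frame` of class `c("fragments", "data.frame")` with
#'   columns `scaffold`, `start`, `end`.
#' @export
fragments <- function(scaffold, start, end) {
  df <- data.frame(scaffold = as.character(scaffold),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  class(df) <- c("fragments", "data.frame")
  df
}

#' Fragment lengths
#' @param frags a fragment table.
#' @return integer vector of insert lengths (`end - start`).
#' @export
fragment_lengths <- function(frags) frags$end - frags$start

validate_intervals <- function(df, what = "interval") {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$start) | is.na(df$end)))
    stop(what, ": non-integer coordinates")
  bad <- which(df$start < 0L | df$start >= df$end | !nzchar(df$scaffold) |
                 is.na(df$scaffold))
  if (length(bad))
    stop(what, " invariant violated (need 0 <= start < end, non-empty scaffold) at row ",
         bad[1L])
  invisible(df)
}

# Union-merge intervals: two intervals join iff their gap is < 1 bp in
# half-open coordinates, i.e. they overlap or are book-ended
# (next start <= current end).  Returns scaffold/start/end sorted by
# (scaffold, start) plus $group mapping input rows to output rows.
merge_interval_rows <- function(scaffold, start, end) {
  n <- length(start)
  if (n == 0L)
    return(list(scaffold = character(), start = integer(), end = integer(),
                group = integer()))
  o <- order(scaffold, start, end)
  s <- scaffold[o]; a <- start[o]; b <- end[o]
  run_end <- cummax_by(b, s)
  # new cluster whenever start exceeds the running max end of the same scaffold
  new_clust <- c(TRUE, a[-1L] > run_end[-n] | s[-1L] != s[-n])
  cl <- cumsum(new_clust)
  out_s <- s[new_clust]
  out_a <- a[new_clust]
  out_b <- as.integer(tapply(b, cl, max))
  group <- integer(n); group[o] <- cl
  list(scaffold = out_s, start = out_a, end = out_b, group = group)
}

# cummax restarted at scaffold changes (input sorted by scaffold)
cummax_by <- function(x, by) {
  ave(x, by, FUN = cummax)
}

# Total bp covered by the (already merged) interval set
merged_bp <- function(m) sum(as.numeric(m$end - m$start))

# Per scaffold, length of the intersection of two merged interval lists
intersect_bp <- function(m1, m2) {
  total <- 0
  for (sc in intersect(unique(m1$scaffold), unique(m2$scaffold))) {
    i1 <- m1$scaffold == sc; i2 <- m2$scaffold == sc
    a1 <- m1$start[i1]; b1 <- m1$end[i1]
    a2 <- m2$start[i2]; b2 <- m2$end[i2]
    j <- 1L; k <- 1L
    while (j <= length(a1) && k <= length(a2)) {
      lo <- max(a1[j], a2[k]); hi <- min(b1[j], b2[k])
      if (hi > lo) total <- total + (hi - lo)
      if (b1[j] < b2[k]) j <- j + 1L else k <- k + 1L
    }
  }
  total
}

# For each query interval, does it intersect (>= 1 bp) any subject interval?
# Subject need not be pre-merged.
overlaps_any <- function(q_scaffold, q_start, q_end,
                         s_scaffold, s_start, s_end) {
  m <- merge_interval_rows(s_scaffold, s_start, s_end)
  out <- logical(length(q_start))
  for (sc in unique(q_scaffold)) {
    qi <- which(q_scaffold == sc)
    si <- m$scaffold == sc
    if (!any(si)) next
    a <- m$start[si]; b <- m$end[si]
    # candidate run: last run starting at or before the query start, and the next
    j <- findInterval(q_start[qi], a)
    hit <- (j >= 1L & ifelse(j >= 1L, b[pmax(j, 1L)] > q_start[qi], FALSE))
    j2 <- j + 1L
    hit2 <- j2 <= length(a) & a[pmin(j2, length(a))] < q_end[qi]
    out[qi] <- hit | hit2
  }
  out
}
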
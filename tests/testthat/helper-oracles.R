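# Independent brute-force oracles. These deliberately share no code with
# the package internals: everything is per-base enumeration or double loops
# over small instances.

# per-base coverage counter over [0, L)
oracle_coverage_vector <- function(frags, scaffold, L) {
  v <- integer(L)
  f <- frags[frags$scaffold == scaffold, , drop = FALSE]
  for (i in seq_len(nrow(f))) {
    b <- seq(f$start[i] + 1L, f$end[i])  # 1-based positions of bases
    v[b] <- v[b] + 1L
  }
  v
}

# expand a coverage track to a per-base vector
track_to_vector <- function(track, scaffold, L) {
  v <- numeric(L)
  r <- track[[scaffold]]
  if (is.null(r)) return(v)
  for (i in seq_len(nrow(r)))
    v[seq(r$start[i] + 1L, r$end[i])] <- r$value[i]
  v
}

# interval union under the "gap < 1 bp" rule by per-base painting
oracle_merge <- function(scaffold, start, end, L = 10000L) {
  out <- NULL
  for (sc in sort(unique(scaffold))) {
    covered <- logical(L + 1L)
    idx <- which(scaffold == sc)
    for (i in idx) covered[seq(start[i] + 1L, end[i])] <- TRUE
    # book-ended intervals ([a,b) + [b,c)) must fuse: runs of TRUE suffice
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep))
      out <- rbind(out, data.frame(scaffold = sc, start = starts[keep],
                                   end = ends[keep]))
  }
  out
}

oracle_average_signal <- function(track, pk, L = 10000L) {
  sapply(seq_len(nrow(pk)), function(i) {
    v <- track_to_vector(track, pk$scaffold[i], L)
    mean(v[seq(pk$start[i] + 1L, pk$end[i])])
  })
}

# exhaustive five-category classifier + nearest gene
oracle_annotate <- function(pk, genes, promoter_window = 3000L,
                            tts_window = 1000L) {
  anchor <- ifelse(is.na(pk$summit_offset),
                   (pk$start + pk$end) %/% 2L,
                   pk$start + pk$summit_offset)
  res <- data.frame(peak_id = pk$name, category = "intergenic",
                    gene_id = NA_character_,
                    distance_to_tss = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pk))) {
    a <- anchor[i]
    gi <- which(genes$scaffold == pk$scaffold[i])
    if (length(gi) == 0L) next
    d <- abs(a - genes$tss[gi])
    cand <- gi[d == min(d)]
    best <- cand[order(genes$gene_id[cand])][1L]
    res$gene_id[i] <- genes$gene_id[best]
    res$distance_to_tss[i] <-
      if (genes$strand[best] == "+") a - genes$tss[best]
      else genes$tss[best] - a
    if (any(abs(a - genes$tss[gi]) <= promoter_window)) {
      res$category[i] <- "promoter-TSS"
    } else if (any(abs(a - genes$tts[gi]) <= tts_window)) {
      res$category[i] <- "TTS"
    } else {
      cat_i <- "intergenic"
      for (g in gi) {
        if (a >= genes$start[g] && a < genes$end[g]) {
          ex <- genes$exons[[g]]
          in_ex <- any(a >= ex$start & a < ex$end)
          if (in_ex) { cat_i <- "exon"; break } else cat_i <- "intron"
        }
      }
      res$category[i] <- cat_i
    }
  }
  res
}

# per-bp set overlap statistics
oracle_overlap <- function(pa, pb, L = 10000L) {
  base_set <- function(p) {
    s <- list()
    for (sc in unique(p$scaffold)) {
      v <- logical(L)
      for (i in which(p$scaffold == sc))
        v[seq(p$start[i] + 1L, p$end[i])] <- TRUE
      s[[sc]] <- v
    }
    s
  }
  sa <- base_set(pa); sb <- base_set(pb)
  hit <- vapply(seq_len(nrow(pa)), function(i) {
    v <- sb[[pa$scaffold[i]]]
    !is.null(v) && any(v[seq(pa$start[i] + 1L, pa$end[i])])
  }, logical(1))
  scs <- union(names(sa), names(sb))
  inter <- 0L; uni <- 0L
  for (sc in scs) {
    va <- if (!is.null(sa[[sc]])) sa[[sc]] else logical(L)
    vb <- if (!is.null(sb[[sc]])) sb[[sc]] else logical(L)
    inter <- inter + sum(va & vb)
    uni <- uni + sum(va | vb)
  }
  list(n_A_overlapping_B = sum(hit),
       percent_A_in_B = 100 * mean(hit),
       jaccard_bp = if (uni > 0) inter / uni else NA_real_)
}

# V-plot counts by double loop over (fragment, peak) pairs
oracle_vplot <- function(frags, pk, max_dist = 500L, max_len = 600L,
                         w_d = 10L, w_l = 10L) {
  nd <- 2L * max_dist / w_d
  nl <- max_len / w_l
  counts <- matrix(0, nl, nd)
  centers <- ifelse(is.na(pk$summit_offset), (pk$start + pk$end) %/% 2L,
                    pk$start + pk$summit_offset)
  for (fi in seq_len(nrow(frags))) {
    mid <- (frags$start[fi] + frags$end[fi]) %/% 2L
    len <- frags$end[fi] - frags$start[fi]
    if (len < 1L || len > max_len) next
    for (pi in seq_len(nrow(pk))) {
      if (frags$scaffold[fi] != pk$scaffold[pi]) next
      d <- mid - centers[pi]
      if (abs(d) > max_dist) next
      db <- min(max(floor((d + max_dist) / w_d) + 1L, 1L), nd)
      lb <- min(max(ceiling(len / w_l), 1L), nl)
      counts[lb, db] <- counts[lb, db] + 1
    }
  }
  counts
}

# exact hypergeometric upper tail P(X >= k) by direct summation of choose()
oracle_fisher_one_sided <- function(k, n, K, N) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# classical pooled two-sample t-test on log2(x + 1)
oracle_pooled_t <- function(mat, g1, g2, pseudo = 1) {
  x <- log2(mat + pseudo)
  t(apply(x, 1L, function(r) {
    a <- r[g1]; b <- r[g2]
    sp <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
      (length(a) + length(b) - 2)
    tt <- (mean(b) - mean(a)) / sqrt(sp * (1 / length(a) + 1 / length(b)))
    c(t = tt, p = 2 * pt(-abs(tt), df = length(a) + length(b) - 2))
  }))
}
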
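# HOMER-style genomic feature annotation, nearest-gene assignment,
# interval-set overlap statistics, per-cluster signal metaprofiles, and
# Fisher/FDR GO enrichment.

#' Annotation configuration
#'
#' @param promoter_window bp around the TSS defining promoter-TSS elements
#'   (default 3000, "within 3 kb of the reference TSS").
#' @param tts_window bp around the TTS (default 1000).
#' @return list of class `annotation_config`; `$categories` is the fixed
#'   category order promoter-TSS, TTS, exon, intron, intergenic.
#' @export
annotation_config <- function(promoter_window = 3000L, tts_window = 1000L) {
  stopifnot(promoter_window > 0, tts_window > 0)
  structure(list(promoter_window = as.integer(promoter_window),
                 tts_window = as.integer(tts_window),
                 categories = c("promoter-TSS", "TTS", "exon", "intron",
                                "intergenic")),
            class = "annotation_config")
}

peak_anchor <- function(pk) {
  ifelse(is.na(pk$summit_offset),
         (pk$start + pk$end) %/% 2L,
         pk$start + pk$summit_offset)
}

#' Annotate peaks with genomic features and nearest genes
#'
#' Each peak is reduced to an anchor point (summit when present, otherwise
#' the interval midpoint) and classified by priority:
#' promoter-TSS (anchor within `promoter_window` of any TSS) > TTS (within
#' `tts_window` of any TTS) > exon (anchor inside an exon) > intron (inside
#' a gene body, not in an exon) > intergenic. The nearest gene is the gene
#' with minimal `|anchor - tss|` on the peak's scaffold (ties broken
#' lexicographically by gene_id); `distance_to_tss` is signed by gene
#' orientation (negative = upstream of the TSS). Peaks on a scaffold with no
#' genes get `NA` nearest gene and are intergenic.
#'
#' @param pk a [peaks()] table.
#' @param genes a [gene_models()] table.
#' @param config an [annotation_config()].
#' @return data.frame with `peak_id`, `category`, `gene_id`,
#'   `distance_to_tss`.
#' @export
annotate_peaks <- function(pk, genes, config = annotation_config()) {
  anchor <- peak_anchor(pk)
  n <- nrow(pk)
  category <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  dist_tss <- rep(NA_integer_, n)
  by_sc <- split(seq_len(nrow(genes)), genes$scaffold)
  for (i in seq_len(n)) {
    gi <- by_sc[[pk$scaffold[i]]]
    if (is.null(gi) || length(gi) == 0L) next
    a <- anchor[i]
    dt <- abs(a - genes$tss[gi])
    best <- gi[order(dt, genes$gene_id[gi])][1L]
    gene_id[i] <- genes$gene_id[best]
    dist_tss[i] <- if (genes$strand[best] == "+") a - genes$tss[best]
    else genes$tss[best] - a
    if (min(dt) <= config$promoter_window) {
      category[i] <- "promoter-TSS"
    } else if (min(abs(a - genes$tts[gi])) <= config$tts_window) {
      category[i] <- "TTS"
    } else {
      in_exon <- FALSE; in_body <- FALSE
      for (g in gi) {
        if (a >= genes$start[g] && a < genes$end[g]) {
          in_body <- TRUE
          ex <- genes$exons[[g]]
          if (any(a >= ex$start & a < ex$end)) { in_exon <- TRUE; break }
        }
      }
      category[i] <- if (in_exon) "exon" else if (in_body) "intron"
      else "intergenic"
    }
  }
  data.frame(peak_id = pk$name, category = category, gene_id = gene_id,
             distance_to_tss = dist_tss, stringsAsFactors = FALSE)
}

#' Genomic feature distribution
#'
#' Fractions of peaks per annotation category (all five categories reported,
#' zeros included; fractions sum to 1).
#'
#' @param records an [annotate_peaks()] result.
#' @param config an [annotation_config()] (for the category order).
#' @return named numeric vector over the five categories.
#' @export
feature_distribution <- function(records, config = annotation_config()) {
  if (nrow(records) == 0L) stop("no annotation records")
  tab <- table(factor(records$category, levels = config$categories))
  as.numeric(tab) / nrow(records) -> fr
  stats::setNames(fr, config$categories)
}

#' Overlap statistics between two peak sets
#'
#' A peak of A overlaps B iff it shares >= 1 bp with any B interval.
#' `percent_A_in_B = 100 * n_A_overlapping_B / n_A` (count-based and
#' asymmetric); `jaccard_bp` is the symmetric base-pair Jaccard index of the
#' merged base sets.
#'
#' @param peaks_a,peaks_b [peaks()] tables.
#' @return list with `n_A`, `n_B`, `n_A_overlapping_B`, `percent_A_in_B`,
#'   `jaccard_bp`.
#' @export
overlap_sets <- function(peaks_a, peaks_b) {
  hit <- if (nrow(peaks_a) && nrow(peaks_b))
    overlaps_any(peaks_a$scaffold, peaks_a$start, peaks_a$end,
                 peaks_b$scaffold, peaks_b$start, peaks_b$end)
  else logical(nrow(peaks_a))
  ma <- merge_interval_rows(peaks_a$scaffold, peaks_a$start, peaks_a$end)
  mb <- merge_interval_rows(peaks_b$scaffold, peaks_b$start, peaks_b$end)
  inter <- intersect_bp(ma, mb)
  uni <- merged_bp(ma) + merged_bp(mb) - inter
  list(n_A = nrow(peaks_a), n_B = nrow(peaks_b),
       n_A_overlapping_B = sum(hit),
       percent_A_in_B = if (nrow(peaks_a)) 100 * sum(hit) / nrow(peaks_a)
       else NA_real_,
       jaccard_bp = if (uni > 0) inter / uni else NA_real_)
}

#' Per-cluster signal metaprofiles
#'
#' For each cluster, the mean (scaled) depth in fixed-width bins across
#' peak-center-anchored windows of `+- flank` bp; when several sample tracks
#' are given, profiles are averaged across samples.
#'
#' @param tracks a [coverage_track()] or named list of them.
#' @param clusters a `cluster_result` from [kmeans_cluster()] (or any named
#'   label vector via its `labels` field).
#' @param pk the [peaks()] table the labels refer to (by name).
#' @param flank half-window in bp (default 1000).
#' @param bins number of bins across the window (default 100).
#' @return matrix cluster x bin of mean signal.
#' @export
per_cluster_signal_profile <- function(tracks, clusters, pk, flank = 1000L,
                                       bins = 100L) {
  labels <- if (inherits(clusters, "cluster_result")) clusters$labels
  else clusters
  if (inherits(tracks, "coverage_track")) tracks <- list(tracks)
  centers <- peak_anchor(pk)
  width <- 2 * flank / bins
  lev <- sort(unique(labels))
  prof <- matrix(0, length(lev), bins,
                 dimnames = list(as.character(lev), NULL))
  for (ci in seq_along(lev)) {
    idx <- which(labels[pk$name] == lev[ci])
    acc <- matrix(0, length(tracks), bins)
    for (ti in seq_along(tracks)) {
      tr <- tracks[[ti]]
      for (i in idx) {
        edges <- centers[i] - flank + width * (0:bins)
        runs <- tr[[pk$scaffold[i]]]
        if (is.null(runs)) next
        acc[ti, ] <- acc[ti, ] +
          diff(track_mass_at(runs, edges)) / width
      }
    }
    prof[ci, ] <- colMeans(acc) / max(length(idx), 1L)
  }
  prof
}

#' GO term enrichment by Fisher's exact test with FDR correction
#'
#' Per term: one-sided (enrichment) Fisher exact p from the 2x2 table of
#' study/background membership, equal to the hypergeometric upper tail
#' `P(X >= k)` with `K` term genes among `N` background genes and a study of
#' size `n`; Benjamini-Hochberg adjustment across all tested terms. Terms
#' with no study hit are skipped.
#'
#' @param study_genes character vector (must be a subset of the background).
#' @param background_genes character vector of all eligible genes.
#' @param term_map named list: term id -> character vector of member genes
#'   (restricted to the background before testing).
#' @return data.frame sorted by p with `term_id`, `k`, `n`, `K`, `N`,
#'   `odds_ratio`, `p`, `fdr`.
#' @export
go_enrichment <- function(study_genes, background_genes, term_map) {
  study <- unique(study_genes)
  bg <- unique(background_genes)
  if (!all(study %in% bg))
    stop("study genes must be a subset of the background")
  N <- length(bg); n <- length(study)
  rows <- lapply(names(term_map), function(tm) {
    members <- intersect(unique(term_map[[tm]]), bg)
    K <- length(members)
    k <- length(intersect(study, members))
    if (k == 0L) return(NULL)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    a <- k; b <- n - k; c <- K - k; d <- N - K - (n - k)
    or <- if (b > 0 && c > 0) (a * d) / (b * c) else Inf
    data.frame(term_id = tm, k = k, n = n, K = K, N = N, odds_ratio = or,
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(term_id = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), odds_ratio = numeric(),
                      p = numeric(), fdr = numeric(),
                      stringsAsFactors = FALSE))
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res[order(res$p, res$term_id), , drop = FALSE]
}

#' Read a 2-column GO map (term_id, gene_id) into a term list
#' @param path TSV path with columns term_id, gene_id (no header required;
#'   a `term_id` header line is skipped).
#' @return named list term -> gene character vector.
#' @export
read_go_map <- function(path) {
  lines <- read_tab_lines(path)
  lines <- lines[!startsWith(lines, "term_id")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) && any(lengths(fields) < 2L))
    stop("parse error in ", path, ": expected 2 tab-separated columns")
  term <- vapply(fields, `[`, "", 1L)
  gene <- vapply(fields, `[`, "", 2L)
  split(gene, term)
}
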
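# Stable-gene (housekeeping) normalization of ATAC signal and spike-in
# scaling of ChIP signal.
#
# The ATAC route mirrors the screen used in the study: pick the ~30 most
# stably expressed genes from RNA-seq, count ATAC fragments within 1 kb of
# their TSSs in every sample, and rescale samples so those counts are equal.

#' Per-sample scale factors
#'
#' @param sample sample identifiers.
#' @param factor positive finite multipliers.
#' @param method `"stable_gene"` or `"spike_in"`.
#' @param reference free-text description of the reference set.
#' @return data.frame of class `scale_factors`.
#' @export
scale_factors <- function(sample, factor,
                          method = c("stable_gene", "spike_in"),
                          reference = "") {
  method <- match.arg(method)
  if (any(!is.finite(factor) | factor <= 0))
    stop("scale factors must be finite and > 0")
  structure(data.frame(sample = as.character(sample),
                       factor = as.numeric(factor),
                       method = method, stringsAsFactors = FALSE),
            reference = reference,
            class = c("scale_factors", "data.frame"))
}

#' Reads per kilobase per million (RPKM)
#'
#' `rpkm = counts / (gene_length/1e3 * lib_size/1e6)`.
#'
#' @param counts gene x sample count matrix.
#' @param gene_lengths bp lengths, named by or aligned with rows.
#' @param lib_sizes per-sample library sizes; defaults to column sums.
#' @return gene x sample numeric matrix.
#' @export
rpkm <- function(counts, gene_lengths, lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts)))
    gene_lengths <- gene_lengths[rownames(counts)]
  stopifnot(length(gene_lengths) == nrow(counts),
            length(lib_sizes) == ncol(counts))
  counts / (outer(as.numeric(gene_lengths) / 1e3,
                  as.numeric(lib_sizes) / 1e6))
}

#' Select stably expressed genes
#'
#' Ranks genes by the coefficient of variation of RPKM across all samples
#' (ascending), after excluding genes whose mean RPKM falls below
#' `min_mean`, and returns the first `n`. Ties break deterministically by
#' gene_id. CV rather than raw variance is used so that highly expressed
#' genes do not dominate the "low variance" screen.
#'
#' @param rpkm_mat gene x sample RPKM matrix.
#' @param n number of genes to return (default 30).
#' @param min_mean expression floor on mean RPKM (default 1.0).
#' @return character vector of `n` gene ids.
#' @export
select_stable_genes <- function(rpkm_mat, n = 30L, min_mean = 1.0) {
  mu <- rowMeans(rpkm_mat)
  keep <- which(mu >= min_mean)
  if (length(keep) < n)
    stop("only ", length(keep), " genes pass the expression floor; need ", n)
  sdv <- apply(rpkm_mat[keep, , drop = FALSE], 1L, stats::sd)
  cv <- sdv / mu[keep]
  ids <- rownames(rpkm_mat)[keep]
  ids[order(cv, ids)][seq_len(n)]
}

#' Count fragments near the TSSs of selected genes
#'
#' Counts fragments whose midpoint lies within `window` bp of the TSS of any
#' listed gene (`[tss - window, tss + window]`, inclusive). A fragment in two
#' overlapping windows is counted once.
#'
#' @param frags a [fragments()] table (one sample).
#' @param genes a [gene_models()] table.
#' @param gene_ids genes whose TSS windows to use.
#' @param window half-width in bp (default 1000, i.e. "within 1 kb").
#' @return integer count.
#' @export
tss_fragment_counts <- function(frags, genes, gene_ids, window = 1000L) {
  g <- genes[genes$gene_id %in% gene_ids, , drop = FALSE]
  if (nrow(g) == 0L) return(0L)
  mid <- (frags$start + frags$end) %/% 2L
  # windows as half-open [tss - window, tss + window + 1) over midpoints
  m <- merge_interval_rows(g$scaffold, pmax(0L, g$tss - as.integer(window)),
                           g$tss + as.integer(window) + 1L)
  total <- 0L
  for (sc in unique(m$scaffold)) {
    wi <- m$scaffold == sc
    fi <- frags$scaffold == sc
    if (!any(fi)) next
    j <- findInterval(mid[fi], m$start[wi])
    inside <- j >= 1L & mid[fi] < m$end[wi][pmax(j, 1L)]
    total <- total + sum(inside)
  }
  total
}

#' Stable-gene scale factors
#'
#' `factor_s = mean(counts) / counts_s`, so that after [apply_scale()] each
#' sample's stable-gene TSS fragment count equals the cross-sample mean
#' exactly.
#'
#' @param counts named integer vector, one TSS fragment count per sample.
#' @return a [scale_factors()] table (method `"stable_gene"`).
#' @export
stable_gene_scale_factors <- function(counts) {
  if (any(counts == 0))
    stop("zero stable-gene TSS count for sample(s): ",
         paste(names(counts)[counts == 0], collapse = ", "))
  scale_factors(names(counts), mean(counts) / counts,
                method = "stable_gene",
                reference = "stable-gene TSS fragment counts")
}

#' Spike-in scale factors
#'
#' ChIP-seq scaling from exogenous spike-in chromatin: factors proportional
#' to `1 / spike_reads`, normalized so the mean factor is 1.
#'
#' @param target_reads named vector of target-genome read counts (recorded in
#'   the result; not used in the factor).
#' @param spike_reads named vector of spike-genome read counts.
#' @return a [scale_factors()] table (method `"spike_in"`).
#' @export
spike_in_scale_factors <- function(target_reads, spike_reads) {
  stopifnot(all(spike_reads > 0))
  inv <- 1 / spike_reads
  scale_factors(names(spike_reads), inv / mean(inv), method = "spike_in",
                reference = "exogenous spike-in chromatin reads")
}
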
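# Random small instances for the oracle-equivalence checks, all within a
# [0, L) toy coordinate space.

random_fragments <- function(n, scaffolds = c("s1", "s2"), L = 2000L,
                             max_len = 300L) {
  start <- sample.int(L - max_len, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  fragments(sample(scaffolds, n, replace = TRUE), start, start + len)
}

random_peaks <- function(n, scaffolds = c("s1", "s2"), L = 2000L,
                         max_w = 400L, with_summit = FALSE) {
  start <- sample.int(L - max_w, n, replace = TRUE) - 1L
  w <- sample.int(max_w - 1L, n, replace = TRUE) + 1L
  summit <- if (with_summit)
    ifelse(runif(n) < 0.5, NA_integer_, floor(runif(n) * w)) else
      NA_integer_
  peaks(sample(scaffolds, n, replace = TRUE), start, start + w,
        score = round(runif(n) * 100, 2), summit_offset = summit)
}

random_genes <- function(n, scaffolds = c("s1", "s2"), L = 20000L) {
  start <- sample.int(L - 3000L, n, replace = TRUE) - 1L
  w <- sample(500:2500, n, replace = TRUE)
  exons <- lapply(seq_len(n), function(i) {
    n_ex <- sample(1:3, 1L)
    if (n_ex == 1L) return(data.frame(start = start[i], end = start[i] + w[i]))
    cuts <- start[i] + sort(sample(seq_len(w[i] - 1L), 2L * (n_ex - 1L)))
    edges <- c(start[i], cuts, start[i] + w[i])
    data.frame(start = edges[seq(1L, by = 2L, length.out = n_ex)],
               end = edges[seq(2L, by = 2L, length.out = n_ex)])
  })
  gene_models(sprintf("g%03d", sample.int(999L, n)),
              sample(scaffolds, n, replace = TRUE),
              start, start + w, sample(c("+", "-"), n, replace = TRUE),
              exons)
}

# scaled-down simulation for fast Monte-Carlo property tests
small_sim_config <- function(seed, ...) {
  args <- list(seed = seed, n_scaffolds = 2L, scaffold_len = 100000L,
               n_genes = 60L, n_stable_genes = 10L,
               n_peaks_per_cluster = c(I = 8L, II = 8L, III = 8L, IV = 8L),
               frags_per_sample = 30000L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# restrict fragments to those that can touch the given peaks (exact for
# signal over the peaks; used only to speed up coverage in tests)
frags_near <- function(frags, pk, margin = 1500L) {
  hit <- accessdyn:::overlaps_any(frags$scaffold, frags$start, frags$end,
                                  pk$scaffold, pmax(0L, pk$start - margin),
                                  pk$end + margin)
  frags[hit, , drop = FALSE]
}

truth_peaks_table <- function(truth) {
  tp <- truth$peaks
  peaks(tp$scaffold, tp$start, tp$end, name = tp$peak_id)
}

# normalized truth-peak signal matrix for a simulated experiment
truth_signal_matrix <- function(sim, log_scale = FALSE) {
  tpk <- truth_peaks_table(sim$truth)
  tracks <- lapply(sim$atac, function(f)
    compute_coverage(frags_near(f, tpk)))
  m <- signal_matrix(tracks, tpk)
  rp <- rpkm(sim$rnaseq$counts, sim$rnaseq$gene_lengths)
  stable <- select_stable_genes(rp, sim$config$n_stable_genes)
  cnts <- vapply(names(sim$atac), function(s)
    tss_fragment_counts(sim$atac[[s]], sim$genes, stable), numeric(1))
  m <- apply_scale(m, stable_gene_scale_factors(cnts))
  if (log_scale) log2(m + 1) else m
}
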
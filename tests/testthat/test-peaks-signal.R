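# Coverage, the Poisson window caller, consensus merging, per-peak signal
# averaging, and the two normalization routes.

test_that("coverage equals the per-base brute-force counter", {
  expect_equal(compute_coverage(fragments(character(), integer(),
                                          integer())),
               coverage_track(list()))
  tr <- compute_coverage(fragments("s1", 0L, 100L))
  expect_equal(tr[["s1"]], data.frame(start = 0L, end = 100L, value = 1))
  set.seed(11)
  for (rep in 1:30) {
    fr <- random_fragments(50)
    tr <- compute_coverage(fr)
    for (sc in c("s1", "s2"))
      expect_equal(track_to_vector(tr, sc, 3000L),
                   as.numeric(oracle_coverage_vector(fr, sc, 3000L)))
  }
})

test_that("consensus merge follows the gap < 1 bp rule", {
  p <- function(s, e) peaks("s1", s, e)
  m <- merge_peak_sets(p(100L, 200L), p(150L, 250L))
  expect_equal(cbind(m$start, m$end), cbind(100L, 250L))
  # book-ended intervals (gap 0 < 1 bp) fuse
  m <- merge_peak_sets(p(100L, 200L), p(200L, 300L))
  expect_equal(cbind(m$start, m$end), cbind(100L, 300L))
  # gap of 1 bp does not
  m <- merge_peak_sets(p(100L, 200L), p(201L, 300L))
  expect_equal(m$start, c(100L, 201L))
  expect_equal(m$name, c("merged_1", "merged_2"))
})

test_that("merging is idempotent, order-invariant and equals the oracle", {
  set.seed(12)
  for (rep in 1:30) {
    sets <- lapply(1:3, function(i) random_peaks(15))
    m <- merge_peak_sets(sets)
    # idempotence
    expect_equal(merge_peak_sets(m)[c("scaffold", "start", "end")],
                 m[c("scaffold", "start", "end")])
    # iterated pairwise merge in shuffled order gives the same result
    o <- sample(3L)
    m2 <- merge_peak_sets(merge_peak_sets(sets[[o[1]]], sets[[o[2]]]),
                          sets[[o[3]]])
    expect_equal(m2[c("scaffold", "start", "end")],
                 m[c("scaffold", "start", "end")])
    # per-base painting oracle
    pooled <- do.call(rbind, lapply(sets, as.data.frame))
    orc <- oracle_merge(pooled$scaffold, pooled$start, pooled$end)
    expect_equal(m$scaffold, orc$scaffold)
    expect_equal(m$start, orc$start)
    expect_equal(m$end, orc$end)
  }
  # merged score is the max of constituents
  m <- merge_peak_sets(peaks("s1", 0L, 10L, score = 3),
                       peaks("s1", 5L, 15L, score = 7))
  expect_equal(m$score, 7)
})

test_that("average signal is the brute-force per-base mean and is linear", {
  tr <- compute_coverage(fragments(rep("s1", 2), c(0L, 0L), c(50L, 100L)))
  pk <- peaks("s1", 0L, 100L)
  expect_equal(unname(average_signal(tr, pk)), 1.5)
  set.seed(13)
  for (rep in 1:30) {
    fr <- random_fragments(40)
    tr <- compute_coverage(fr)
    pk <- random_peaks(10)
    expect_equal(unname(average_signal(tr, pk)),
                 oracle_average_signal(tr, pk, 3000L))
  }
  # linearity: scaling the track scales the averages
  sf <- scale_factors("a", 2.5, "stable_gene")
  tr2 <- apply_scale(tr, sf, sample = "a")
  expect_equal(average_signal(tr2, pk), 2.5 * average_signal(tr, pk))
})

test_that("average signal is invariant under peak subdivision", {
  set.seed(14)
  fr <- random_fragments(60, scaffolds = "s1")
  tr <- compute_coverage(fr)
  pk <- peaks("s1", 200L, 1000L)
  halves <- peaks(c("s1", "s1"), c(200L, 600L), c(600L, 1000L))
  a <- average_signal(tr, pk)
  h <- average_signal(tr, halves)
  expect_equal(unname(a), unname(h[1] + h[2]) / 2)
})

test_that("the window caller flags an enriched region and not a flat one", {
  lens <- c(s1 = 20000L)
  set.seed(15)
  # flat uniform background only
  bg_start <- sample.int(19800L, 400L) - 1L
  bg <- fragments("s1", bg_start, bg_start + 100L)
  expect_equal(nrow(call_peaks(compute_coverage(bg), peak_call_config(),
                               lens)), 0L)
  # a strong block of signal stands out
  sig_start <- as.integer(round(rnorm(300, 10000, 60)))
  fr <- fragments("s1", c(bg_start, sig_start - 50L),
                  c(bg_start + 100L, sig_start + 50L))
  called <- call_peaks(compute_coverage(fr), peak_call_config(), lens)
  expect_equal(nrow(called), 1L)
  expect_true(called$start < 10000 && called$end > 10000)
  expect_true(abs(called$start + called$summit_offset - 10000) < 300)
  # zero-signal track: empty result, not an error
  expect_equal(nrow(call_peaks(coverage_track(list()), peak_call_config(),
                               lens)), 0L)
})

test_that("window p-values are the Poisson upper tail of the background", {
  # one window with count 10 against mean 2: P(X >= 10; 2) ~ 2.6e-5
  expect_equal(ppois(9, 2, lower.tail = FALSE), 4.64980750e-05,
               tolerance = 1e-6)
  expect_equal(ppois(9, 2, lower.tail = FALSE),
               1 - sum(dpois(0:9, 2)), tolerance = 1e-12)
})

test_that("caller recovers planted truth peaks with high sensitivity", {
  cfg <- sim_config(seed = 21)
  gen <- generate_genome(cfg)
  atac <- generate_atac(cfg, gen$truth, gen$genes)
  lens <- sim_scaffold_lens(cfg)
  tp <- gen$truth$peaks
  # the 48h sample has every cluster open
  called <- call_peaks(compute_coverage(atac[["48h_r1"]]),
                       peak_call_config(), lens)
  sens <- mean(accessdyn:::overlaps_any(tp$scaffold, tp$start, tp$end,
                                        called$scaffold, called$start,
                                        called$end))
  # planted signal = truth peaks plus the stable-gene TSS windows (which
  # carry invariant but real fragment pileups)
  stab <- gen$genes[gen$genes$gene_id %in% gen$truth$stable_genes, ]
  sig_sc <- c(tp$scaffold, stab$scaffold)
  sig_start <- c(tp$start, pmax(0L, stab$tss - 1000L))
  sig_end <- c(tp$end, stab$tss + 1000L)
  fdr <- 1 - mean(accessdyn:::overlaps_any(called$scaffold, called$start,
                                           called$end, sig_sc, sig_start,
                                           sig_end))
  expect_gte(sens, 0.9)
  expect_lte(fdr, 0.1)
})

test_that("stable-gene selection, TSS counting and scaling are coherent", {
  # CV 0 gene ranks first
  m <- rbind(flat = rep(10, 4), noisy = c(5, 20, 9, 14),
             mid = c(10, 11, 10, 11))
  colnames(m) <- paste0("s", 1:4)
  expect_equal(select_stable_genes(m, 1), "flat")
  expect_equal(select_stable_genes(m, 3), c("flat", "mid", "noisy"))
  expect_error(select_stable_genes(m, 4), "floor")
  # midpoint-in-window counting against a brute-force oracle
  set.seed(22)
  genes <- random_genes(8, scaffolds = "s1", L = 20000L)
  for (rep in 1:20) {
    fr <- random_fragments(200, scaffolds = "s1", L = 19000L)
    mid <- (fr$start + fr$end) %/% 2L
    manual <- sum(vapply(seq_len(nrow(fr)), function(i)
      any(abs(mid[i] - genes$tss) <= 1000L), logical(1)))
    expect_equal(tss_fragment_counts(fr, genes, genes$gene_id), manual)
  }
  # boundary: midpoint exactly at tss counts, tss + 1001 does not
  g1 <- gene_models("g1", "s1", 5000L, 7000L, "+")
  expect_equal(tss_fragment_counts(fragments("s1", 4950L, 5050L), g1,
                                   "g1"), 1L)
  expect_equal(tss_fragment_counts(fragments("s1", 5951L, 6051L), g1,
                                   "g1"), 0L)
  # factors equalize counts exactly
  cnts <- c(A = 100, B = 200)
  sf <- stable_gene_scale_factors(cnts)
  expect_equal(sf$factor, c(1.5, 0.75))
  expect_equal(unname(cnts * sf$factor), c(150, 150))
  expect_equal(stable_gene_scale_factors(c(A = 7, B = 7))$factor, c(1, 1))
  expect_error(stable_gene_scale_factors(c(A = 0, B = 5)), "zero")
})

test_that("spike-in factors are inverse to spike reads with mean 1", {
  sf <- spike_in_scale_factors(c(A = 4e6, B = 4e6),
                               c(A = 1e6, B = 2e6))
  expect_equal(sf$factor, c(4 / 3, 2 / 3))
  expect_equal(spike_in_scale_factors(c(A = 1, B = 1),
                                      c(A = 5, B = 5))$factor, c(1, 1))
})

test_that("scale-then-average equals average-then-scale", {
  set.seed(23)
  fr <- random_fragments(50)
  tr <- compute_coverage(fr)
  pk <- random_peaks(6)
  sf <- scale_factors(c("x", "y"), c(1.7, 0.4), "stable_gene")
  m <- signal_matrix(list(x = tr, y = tr), pk)
  expect_equal(apply_scale(m, sf)[, "x"],
               average_signal(apply_scale(tr, sf, "x"), pk))
  # factor 1 is the identity
  one <- scale_factors("x", 1, "stable_gene")
  expect_equal(apply_scale(tr, one, "x"), tr)
})
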
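# The synthetic-data generator: determinism, configured structure, and the
# statistical couplings downstream stages rely on.

test_that("every generator output is a pure function of config and seed", {
  cfg <- small_sim_config(seed = 71)
  s1 <- simulate_experiment(cfg, mark_config = list(H3K4me3 = "I"))
  s2 <- simulate_experiment(cfg, mark_config = list(H3K4me3 = "I"))
  expect_identical(s1$truth$peaks, s2$truth$peaks)
  expect_identical(s1$atac, s2$atac)
  expect_identical(s1$rnaseq$counts, s2$rnaseq$counts)
  expect_identical(s1$chip, s2$chip)
  s3 <- simulate_experiment(small_sim_config(seed = 72))
  expect_false(identical(s1$atac[[1]], s3$atac[[1]]))
})

test_that("the genome echoes the configured structure", {
  cfg <- small_sim_config(seed = 73)
  gen <- generate_genome(cfg)
  expect_equal(nrow(gen$truth$peaks), 32L)
  expect_equal(length(gen$truth$stable_genes), 10L)
  expect_equal(nrow(gen$genes), 60L)
  expect_true(all(table(gen$truth$peaks$cluster) == 8L))
  # truth peaks are >= 1 kb apart
  tp <- gen$truth$peaks[order(gen$truth$peaks$scaffold,
                              gen$truth$peaks$start), ]
  same <- tp$scaffold[-1] == tp$scaffold[-nrow(tp)]
  gaps <- tp$start[-1] - tp$end[-nrow(tp)]
  expect_true(all(gaps[same] >= 1000L))
  # defaults: 160 truth peaks, 30 stable genes
  gen_d <- generate_genome(sim_config(seed = 74))
  expect_equal(nrow(gen_d$truth$peaks), 160L)
  expect_equal(length(gen_d$truth$stable_genes), 30L)
  # n_genes = 0: no genes, peaks still placed
  cfg0 <- small_sim_config(seed = 75, n_genes = 0L, n_stable_genes = 0L)
  gen0 <- generate_genome(cfg0)
  expect_equal(nrow(gen0$genes), 0L)
  expect_equal(nrow(gen0$truth$peaks), 32L)
  # an impossible genome errors out
  expect_error(generate_genome(sim_config(seed = 76, n_scaffolds = 1L,
                                          scaffold_len = 5000L)),
               "too small")
})

test_that("no multi weight means no long fragments at truth peaks", {
  cfg <- small_sim_config(seed = 77,
                          multi_weight_by_group = c(ctrl = 0, `8h` = 0.25,
                                                    `24h` = 0.25,
                                                    `48h` = 0.25))
  sim <- simulate_experiment(cfg)
  tpk <- truth_peaks_table(sim$truth)
  near <- frags_near(sim$atac[["ctrl_r1"]], tpk, margin = 0L)
  expect_lt(max(fragment_lengths(near)),
            cfg$mono_len_mean + 4 * cfg$mono_len_sd)
})

test_that("cluster III signal decreases monotonically across groups", {
  mono_frac <- sapply(1:20, function(s) {
    cfg <- small_sim_config(seed = 300 + s)
    sim <- list(truth = generate_genome(cfg)$truth)
    gen <- generate_genome(cfg)
    atac <- generate_atac(cfg, gen$truth, gen$genes)
    tp3 <- gen$truth$peaks[gen$truth$peaks$cluster == "III", ]
    tpk <- peaks(tp3$scaffold, tp3$start, tp3$end, name = tp3$peak_id)
    sf <- gen$truth$scale_factors
    per_group <- sapply(cfg$groups, function(g) {
      ss <- paste0(g, "_r", 1:2)
      mean(sapply(ss, function(s2) {
        tr <- compute_coverage(frags_near(atac[[s2]], tpk))
        mean(average_signal(tr, tpk)) / sf[[s2]]
      }))
    })
    all(diff(per_group) < 0)
  })
  expect_gte(mean(mono_frac), 0.9)
})

test_that("stable-gene TSS counts track the true depth factors", {
  rel_err <- sapply(1:5, function(s) {
    cfg <- small_sim_config(seed = 200 + s)
    gen <- generate_genome(cfg)
    atac <- generate_atac(cfg, gen$truth, gen$genes)
    cnts <- vapply(names(atac), function(sm)
      tss_fragment_counts(atac[[sm]], gen$genes, gen$truth$stable_genes),
      numeric(1))
    est <- cnts / mean(cnts)
    tr <- gen$truth$scale_factors[names(cnts)]
    tr <- tr / mean(tr)
    max(abs(est / tr - 1))
  })
  expect_lt(max(rel_err), 0.05)
})

test_that("stable genes sit in the low tail of the expression CV", {
  hits <- sapply(1:20, function(s) {
    cfg <- small_sim_config(seed = 500 + s)
    gen <- generate_genome(cfg)
    rna <- generate_rnaseq(cfg, gen$truth)
    rp <- rpkm(rna$counts, rna$gene_lengths)
    cv <- apply(rp, 1, sd) / rowMeans(rp)
    q10 <- quantile(cv, 10 / 60)   # stable share of this toy gene set
    stable_cv <- cv[gen$truth$stable_genes]
    sel <- select_stable_genes(rp, cfg$n_stable_genes)
    c(below = mean(stable_cv <= q10),
      recovered = length(intersect(sel, gen$truth$stable_genes)) /
        cfg$n_stable_genes)
  })
  expect_gte(mean(hits["recovered", ]), 27 / 30)
  expect_gt(mean(hits["below", ]), 0.8)
})

test_that("expression couples to promoter accessibility only late", {
  # with the coupling exponent zeroed the peak/gene deltas are uncorrelated
  set.seed(78)
  rs <- sapply(1:10, function(s) {
    cfg <- small_sim_config(seed = 600 + s, rna_alpha = 0)
    gen <- generate_genome(cfg)
    rna <- generate_rnaseq(cfg, gen$truth)
    rp <- rpkm(rna$counts, rna$gene_lengths)
    owned <- !is.na(gen$truth$expr$promoter_peak)
    d_expr <- log2(rowMeans(rp[, 7:8]) + 1) - log2(rowMeans(rp[, 1:2]) + 1)
    cl <- gen$truth$peaks$cluster[match(gen$truth$expr$promoter_peak,
                                        gen$truth$peaks$peak_id)][owned]
    d_acc <- log2(gen$truth$profiles[cl, "48h"] /
                    gen$truth$profiles[cl, "ctrl"])
    cor(d_acc, d_expr[owned])
  })
  expect_lt(median(abs(rs)), 0.25)
  # with the default coupling the correlation is clearly positive
  cfg <- small_sim_config(seed = 79)
  gen <- generate_genome(cfg)
  rna <- generate_rnaseq(cfg, gen$truth)
  rp <- rpkm(rna$counts, rna$gene_lengths)
  owned <- !is.na(gen$truth$expr$promoter_peak)
  d_expr <- log2(rowMeans(rp[, 7:8]) + 1) - log2(rowMeans(rp[, 1:2]) + 1)
  cl <- gen$truth$peaks$cluster[match(gen$truth$expr$promoter_peak,
                                      gen$truth$peaks$peak_id)][owned]
  d_acc <- log2(gen$truth$profiles[cl, "48h"] /
                  gen$truth$profiles[cl, "ctrl"])
  expect_gt(cor(d_acc, d_expr[owned]), 0.5)
})

test_that("ChIP sets respect mark configuration and spike arithmetic", {
  cfg <- small_sim_config(seed = 80)
  gen <- generate_genome(cfg)
  expect_error(generate_chip(cfg, gen$truth, list(H3K9me3 = "I")),
               "unknown mark")
  chip <- generate_chip(cfg, gen$truth,
                        list(H3K4me3 = c("I", "III", "IV"),
                             H3K27me3 = "II"))
  # spike reads ~ target * f/(1-f) within the +-20% noise band
  for (mark in names(chip)) for (g in cfg$groups) {
    rec <- chip[[mark]][[g]]
    ratio <- rec$spike_read_count /
      (rec$target_read_count * cfg$spike_fraction / (1 - cfg$spike_fraction))
    expect_gte(ratio, 0.8 - 1e-9)
    expect_lte(ratio, 1.2 + 1e-9)
  }
  # jittered mark peaks overlap their source clusters almost perfectly
  tp <- gen$truth$peaks
  open_pk <- truth_peaks_table(gen$truth)[tp$cluster %in%
                                            c("I", "III", "IV"), ]
  ov <- overlap_sets(chip$H3K4me3$ctrl$peaks, open_pk)
  expect_gte(ov$percent_A_in_B, 90)
  ov2 <- overlap_sets(chip$H3K27me3$ctrl$peaks, open_pk)
  expect_lte(ov2$percent_A_in_B, 20)
})

test_that("a simulation writes to disk and reads back consistently", {
  cfg <- small_sim_config(seed = 81)
  sim <- simulate_experiment(cfg, mark_config = list(H3K27ac = "I"))
  d <- withr::local_tempdir()
  write_simulation(sim, d)
  fr <- read_fragments(file.path(d, "fragments", "ctrl_r1.bed"))
  expect_equal(nrow(fr), nrow(sim$atac[["ctrl_r1"]]))
  g <- read_genes(file.path(d, "genes.gtf"), "gtf")
  expect_equal(g$tss, sim$genes$tss)
  cnt <- read_counts(file.path(d, "rnaseq_counts.tsv"))
  expect_equal(cnt, sim$rnaseq$counts + 0)
  pk <- read_peaks(file.path(d, "chip", "H3K27ac_ctrl.narrowPeak"),
                   "narrowPeak")
  expect_equal(nrow(pk), nrow(sim$chip$H3K27ac$ctrl$peaks))
})
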
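# Deterministic synthetic-data generator.
#
# Emulates the signal structure of a four-timepoint infection course with
# two replicates per group: a toy multi-scaffold genome with gene models;
# truth peaks following four accessibility archetypes (I gradual gain,
# II gain only in the final condition from a near-closed baseline,
# III gradual loss, IV late gain); a three-component nucleosomal
# fragment-length mixture (sub-nucleosomal NFR, mono-nucleosomal,
# ~period-spaced multi-nucleosomal) whose multi-nucleosomal weight
# collapses in the final condition; stably expressed genes with invariant
# TSS-proximal fragment counts used for normalization; RNA-seq counts
# coupled to promoter accessibility only in the final condition; and
# ChIP-like peak sets with spike-in read counts around a 1:4 exogenous
# chromatin mix. Every output is a pure function of (config, seed).

#' Simulation configuration
#'
#' @param seed master RNG seed; all generator outputs are deterministic
#'   functions of the config including this seed.
#' @param n_scaffolds,scaffold_len toy genome shape.
#' @param n_genes,n_stable_genes gene counts; stable genes have invariant
#'   expression and TSS-proximal ATAC counts.
#' @param groups ordered condition labels; the last label is the remodeled
#'   final condition.
#' @param replicates samples per group.
#' @param n_peaks_per_cluster named integer vector over clusters I-IV.
#' @param peak_width truth peak width in bp.
#' @param frags_per_sample approximate total fragments per sample before
#'   depth scaling.
#' @param nfr_len_mean,nfr_len_sd,mono_len_mean,mono_len_sd Normal length
#'   components (bp) for NFR and mono-nucleosomal inserts.
#' @param nucleosome_period bp per nucleosome in multi-nucleosomal inserts.
#' @param multi_max_n maximum nucleosomes spanned by a multi insert.
#' @param multi_weight_by_group named fraction of multi-nucleosomal
#'   fragments per group (default 0.25 except 0.05 in the final condition:
#'   the multi component collapses late).
#' @param cluster_signal_profiles cluster x group matrix of relative
#'   accessibility multipliers. Defaults: I = (1,2.5,5,10) monotone gradual
#'   gain; II = (0.05,0.05,0.05,6) near-closed until a final-condition
#'   jump; III = (10,5,2.5,1) monotone gradual loss; IV = (1,1,4,8) late
#'   gain starting mid-course.
#' @param background_rate background fragments per bp of genome.
#' @param peak_dispersion negative-binomial dispersion of per-peak fragment
#'   counts (replicate overdispersion).
#' @param stable_tss_frags expected fragments per stable-gene TSS window
#'   before depth scaling.
#' @param scale_factor_range per-sample true depth multipliers are drawn
#'   uniformly from this range.
#' @param rna_alpha coupling exponent between promoter accessibility fold
#'   change and expression in the final condition (0 elsewhere).
#' @param rna_dispersion_stable,rna_dispersion NB dispersions for stable and
#'   ordinary genes.
#' @param spike_fraction expected spike-in read share of total ChIP reads
#'   (default 1/5, from a 1:4 exogenous:target chromatin mix).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_scaffolds = 5L, scaffold_len = 200000L,
                       n_genes = 300L, n_stable_genes = 30L,
                       groups = c("ctrl", "8h", "24h", "48h"),
                       replicates = 2L,
                       n_peaks_per_cluster = c(I = 40L, II = 40L,
                                               III = 40L, IV = 40L),
                       peak_width = 400L,
                       frags_per_sample = 200000L,
                       nfr_len_mean = 80, nfr_len_sd = 20,
                       mono_len_mean = 180, mono_len_sd = 15,
                       nucleosome_period = 200L, multi_max_n = 5L,
                       multi_weight_by_group = NULL,
                       cluster_signal_profiles = NULL,
                       background_rate = 0.05,
                       peak_dispersion = 0.05,
                       stable_tss_frags = 200,
                       scale_factor_range = c(0.7, 1.3),
                       rna_alpha = 0.6,
                       rna_dispersion_stable = 0.01,
                       rna_dispersion = 0.1,
                       spike_fraction = 0.2) {
  if (is.null(multi_weight_by_group)) {
    multi_weight_by_group <- stats::setNames(rep(0.25, length(groups)),
                                             groups)
    multi_weight_by_group[length(groups)] <- 0.05
  }
  if (is.null(cluster_signal_profiles)) {
    cluster_signal_profiles <- rbind(I = c(1, 2.5, 5, 10),
                                     II = c(0.05, 0.05, 0.05, 6),
                                     III = c(10, 5, 2.5, 1),
                                     IV = c(1, 1, 4, 8))
    colnames(cluster_signal_profiles) <- groups
  }
  stopifnot(all(multi_weight_by_group >= 0 & multi_weight_by_group <= 1),
            length(multi_weight_by_group) == length(groups),
            ncol(cluster_signal_profiles) == length(groups),
            all(rownames(cluster_signal_profiles) ==
                  names(n_peaks_per_cluster)))
  cfg <- list(seed = as.integer(seed), n_scaffolds = as.integer(n_scaffolds),
              scaffold_len = as.integer(scaffold_len),
              n_genes = as.integer(n_genes),
              n_stable_genes = as.integer(n_stable_genes),
              groups = groups, replicates = as.integer(replicates),
              n_peaks_per_cluster = n_peaks_per_cluster,
              peak_width = as.integer(peak_width),
              frags_per_sample = as.integer(frags_per_sample),
              nfr_len_mean = nfr_len_mean, nfr_len_sd = nfr_len_sd,
              mono_len_mean = mono_len_mean, mono_len_sd = mono_len_sd,
              nucleosome_period = as.integer(nucleosome_period),
              multi_max_n = as.integer(multi_max_n),
              multi_weight_by_group = multi_weight_by_group,
              cluster_signal_profiles = cluster_signal_profiles,
              background_rate = background_rate,
              peak_dispersion = peak_dispersion,
              stable_tss_frags = stable_tss_frags,
              scale_factor_range = scale_factor_range,
              rna_alpha = rna_alpha,
              rna_dispersion_stable = rna_dispersion_stable,
              rna_dispersion = rna_dispersion,
              spike_fraction = spike_fraction)
  class(cfg) <- "sim_config"
  cfg
}

#' Scaffold lengths of a simulated genome
#' @param config a [sim_config()].
#' @return named integer vector.
#' @export
sim_scaffold_lens <- function(config) {
  stats::setNames(rep(config$scaffold_len, config$n_scaffolds),
                  paste0("scaffold_", seq_len(config$n_scaffolds)))
}

#' Sample sheet of a simulation
#' @param config a [sim_config()].
#' @return data.frame with `sample`, `group`, `replicate`.
#' @export
sim_samples <- function(config) {
  data.frame(sample = paste0(rep(config$groups, each = config$replicates),
                             "_r", seq_len(config$replicates)),
             group = rep(config$groups, each = config$replicates),
             replicate = rep(seq_len(config$replicates),
                             length(config$groups)),
             stringsAsFactors = FALSE)
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# uniform non-overlapping placement of n segments of the given lengths in
# [0, L), with at least `gap` bp between consecutive segments
place_segments <- function(n, lens, L, gap = 0L) {
  slack <- L - sum(lens) - gap * (n - 1L)
  if (n > 0L && slack < 0)
    stop("genome too small to place ", n, " segments of total ", sum(lens),
         " bp in ", L, " bp")
  if (n == 0L) return(integer())
  cuts <- sort(stats::runif(n, 0, slack))
  as.integer(floor(cuts + cumsum(c(0, lens[-n] + gap))))
}

#' Generate the toy genome and ground truth skeleton
#'
#' Places genes uniformly without overlap (1-4 exons each), draws the stable
#' gene set and per-sample true depth factors, and places truth peaks for
#' the four accessibility archetypes in non-exonic space with >= 1 kb
#' separation, avoiding stable-gene TSS neighborhoods so that differential
#' peak signal cannot contaminate the normalization windows.
#'
#' @param config a [sim_config()].
#' @return list: `genes` ([gene_models()]) and `truth` (class
#'   `truth_table`): `$peaks` (peak_id, scaffold, start, end, cluster),
#'   `$profiles`, `$stable_genes`, `$scale_factors`, `$samples`, `$expr`
#'   (per-gene base expression and owned promoter peak).
#' @export
generate_genome <- function(config) with_seed(config$seed, {
  lens <- sim_scaffold_lens(config)
  samples <- sim_samples(config)
  # genes spread evenly over scaffolds
  sc_of_gene <- rep(names(lens), length.out = config$n_genes)
  gene_rows <- list()
  for (sc in names(lens)) {
    ids <- which(sc_of_gene == sc)
    if (length(ids) == 0L) next
    glen <- sample(1000:3000, length(ids), replace = TRUE)
    starts <- place_segments(length(ids), glen, lens[[sc]], gap = 200L)
    gene_rows[[sc]] <- data.frame(gene_id = sprintf("gene_%04d", ids),
                                  scaffold = sc, start = starts,
                                  end = starts + glen,
                                  strand = sample(c("+", "-"), length(ids),
                                                  replace = TRUE),
                                  stringsAsFactors = FALSE)
  }
  gdf <- do.call(rbind, gene_rows)
  exons <- list()
  if (!is.null(gdf)) {
    gdf <- gdf[order(gdf$gene_id), , drop = FALSE]
    for (i in seq_len(nrow(gdf))) {
      n_ex <- sample(1:4, 1L)
      if (n_ex == 1L) {
        exons[[i]] <- data.frame(start = gdf$start[i], end = gdf$end[i])
      } else {
        span <- gdf$end[i] - gdf$start[i]
        cuts <- gdf$start[i] +
          sort(sample(seq_len(span - 1L), 2L * (n_ex - 1L)))
        edges <- c(gdf$start[i], cuts, gdf$end[i])
        exons[[i]] <- data.frame(start = edges[seq(1L, by = 2L,
                                                   length.out = n_ex)],
                                 end = edges[seq(2L, by = 2L,
                                                 length.out = n_ex)])
      }
    }
    genes <- gene_models(gdf$gene_id, gdf$scaffold, gdf$start, gdf$end,
                         gdf$strand, exons)
  } else {
    genes <- gene_models(character(), character(), integer(), integer(),
                         character(), list())
  }
  stable <- if (nrow(genes)) sort(sample(genes$gene_id,
                                         config$n_stable_genes)) else
    character()
  # forbidden space for truth peaks: exons and stable-gene TSS windows
  stab <- genes[genes$gene_id %in% stable, , drop = FALSE]
  forb_sc <- c(unlist(lapply(seq_len(nrow(genes)), function(i)
    rep(genes$scaffold[i], nrow(genes$exons[[i]])))), stab$scaffold)
  forb_start <- c(unlist(lapply(genes$exons, `[[`, "start")),
                  pmax(0L, stab$tss - 1500L))
  forb_end <- c(unlist(lapply(genes$exons, `[[`, "end")), stab$tss + 1500L)
  clusters <- rep(names(config$n_peaks_per_cluster),
                  config$n_peaks_per_cluster)
  n_pk <- length(clusters)
  pk_sc <- character(n_pk); pk_start <- integer(n_pk)
  placed_sc <- character(); placed_start <- integer()
  w <- config$peak_width
  for (i in seq_len(n_pk)) {
    ok <- FALSE
    for (try in 1:500) {
      sc <- sample(names(lens), 1L)
      st <- sample.int(lens[[sc]] - w, 1L) - 1L
      if (length(forb_start) &&
          any(overlaps_any(sc, st, st + w, forb_sc, forb_start, forb_end)))
        next
      near <- placed_sc == sc & abs(placed_start - st) < w + 1000L
      if (any(near)) next
      ok <- TRUE; break
    }
    if (!ok) stop("genome too small to place ", n_pk,
                  " truth peaks with 1 kb separation")
    pk_sc[i] <- sc; pk_start[i] <- st
    placed_sc <- c(placed_sc, sc); placed_start <- c(placed_start, st)
  }
  truth_peaks <- data.frame(peak_id = sprintf("truth_%03d", seq_len(n_pk)),
                            scaffold = pk_sc, start = pk_start,
                            end = pk_start + w, cluster = clusters,
                            stringsAsFactors = FALSE)
  scale_true <- stats::setNames(
    round(stats::runif(nrow(samples), config$scale_factor_range[1L],
                       config$scale_factor_range[2L]), 3),
    samples$sample)
  # promoter ownership: gene whose TSS is within 3 kb of a truth peak center
  ctr <- (truth_peaks$start + truth_peaks$end) %/% 2L
  owner <- rep(NA_character_, nrow(genes))
  owned_peak <- rep(NA_character_, nrow(genes))
  if (nrow(genes)) {
    for (i in seq_len(n_pk)) {
      gi <- which(genes$scaffold == truth_peaks$scaffold[i] &
                    abs(genes$tss - ctr[i]) <= 3000L)
      if (length(gi)) {
        g <- gi[which.min(abs(genes$tss[gi] - ctr[i]))]
        if (is.na(owned_peak[g])) owned_peak[g] <- truth_peaks$peak_id[i]
      }
    }
  }
  base_mean <- exp(stats::rnorm(nrow(genes), 4.5, 1))
  # stable (housekeeping-like) genes are highly and tightly expressed
  is_stable <- genes$gene_id %in% stable
  base_mean[is_stable] <- exp(stats::rnorm(sum(is_stable), 5.5, 0.5))
  expr <- data.frame(gene_id = genes$gene_id,
                     gene_length = genes$end - genes$start,
                     base_mean = base_mean,
                     promoter_peak = owned_peak, stringsAsFactors = FALSE)
  truth <- structure(list(peaks = truth_peaks,
                          profiles = config$cluster_signal_profiles,
                          stable_genes = stable,
                          scale_factors = scale_true,
                          samples = samples, expr = expr,
                          scaffold_lens = lens),
                     class = "truth_table")
  list(genes = genes, truth = truth)
})

# mixture component weights for a group: multi from config, remainder split
# evenly between NFR and mono
mixture_weights <- function(config, group) {
  wm <- config$multi_weight_by_group[[group]]
  c(nfr = (1 - wm) / 2, mono = (1 - wm) / 2, multi = wm)
}

# draw n insert lengths from the group's three-component mixture
draw_lengths <- function(n, config, group) {
  w <- mixture_weights(config, group)
  cls <- sample(c("nfr", "mono", "multi"), n, replace = TRUE, prob = w)
  len <- numeric(n)
  i <- cls == "nfr"
  len[i] <- stats::rnorm(sum(i), config$nfr_len_mean, config$nfr_len_sd)
  i <- cls == "mono"
  len[i] <- stats::rnorm(sum(i), config$mono_len_mean, config$mono_len_sd)
  i <- cls == "multi"
  if (any(i)) {
    k <- 2L + pmin(stats::rgeom(sum(i), 0.5), config$multi_max_n - 2L)
    len[i] <- k * config$nucleosome_period +
      stats::rnorm(sum(i), 0, config$mono_len_sd)
  }
  list(len = pmax(1L, as.integer(round(len))), class = cls)
}

#' Theoretical fragment-length bin probabilities of the simulated mixture
#'
#' Probability that a simulated insert length (integer-rounded) falls in
#' each half-open bin `[breaks[i], breaks[i+1])`, for goodness-of-fit
#' checks against [length_spectrum()] histograms.
#'
#' @param config a [sim_config()].
#' @param group group label (sets the multi-nucleosomal weight).
#' @param breaks increasing integer bin edges.
#' @return numeric vector of bin probabilities.
#' @export
fragment_length_probs <- function(config, group, breaks) {
  w <- mixture_weights(config, group)
  # bins are (a, b] over integer lengths; integer L arises from continuous
  # draws in (L - .5, L + .5], so bin (a, b] collects (a + .5, b + .5]
  pn <- function(mean, sd) diff(stats::pnorm(breaks + 0.5, mean, sd))
  p <- w[["nfr"]] * pn(config$nfr_len_mean, config$nfr_len_sd) +
    w[["mono"]] * pn(config$mono_len_mean, config$mono_len_sd)
  kmax <- config$multi_max_n
  kp <- stats::dgeom(0:(kmax - 3L), 0.5)
  kp <- c(kp, 1 - sum(kp))           # truncated at multi_max_n nucleosomes
  for (j in seq_along(kp))
    p <- p + w[["multi"]] * kp[j] *
      pn((j + 1L) * config$nucleosome_period, config$mono_len_sd)
  p
}

#' Generate per-sample ATAC fragment tables
#'
#' For each sample: uniform background fragments at `background_rate` per
#' bp; per truth peak a negative-binomial fragment count with mean
#' proportional to cluster profile x true depth factor, NFR fragments
#' centered tightly on the summit (Normal sd 30 bp) and nucleosomal
#' fragments offset +-1 nucleosome period; stable-gene TSS windows receive
#' Poisson fragment counts whose pre-scaling expectation is equal across all
#' samples. All insert lengths come from the group's mixture. Replicates
#' share expectations and differ only through the RNG stream.
#'
#' @param config a [sim_config()].
#' @param truth from [generate_genome()] (needs the matching `genes` only
#'   through the truth table's stable-gene TSS list, carried in `genes`).
#' @param genes the [gene_models()] from the same [generate_genome()] call.
#' @return named list (sample -> [fragments()] table).
#' @export
generate_atac <- function(config, truth, genes) with_seed(config$seed + 1L, {
  lens <- truth$scaffold_lens
  genome_len <- sum(as.numeric(lens))
  samples <- truth$samples
  tp <- truth$peaks
  prof <- truth$profiles
  mean_mult <- rowMeans(prof)[tp$cluster]
  n_bg_exp <- config$background_rate * genome_len
  base <- max((config$frags_per_sample - n_bg_exp), 0) / sum(mean_mult)
  stab <- genes[genes$gene_id %in% truth$stable_genes, , drop = FALSE]
  out <- list()
  for (si in seq_len(nrow(samples))) {
    g <- samples$group[si]
    sf <- truth$scale_factors[[samples$sample[si]]]
    # background
    n_bg <- stats::rpois(1L, n_bg_exp * sf)
    bg_sc <- sample(names(lens), n_bg, replace = TRUE,
                    prob = as.numeric(lens))
    bg_mid <- floor(stats::runif(n_bg, 0, lens[bg_sc]))
    bg_len <- draw_lengths(n_bg, config, g)$len
    # truth peaks
    mu <- base * prof[tp$cluster, g] * sf
    cnt <- stats::rnbinom(nrow(tp), mu = mu,
                          size = 1 / config$peak_dispersion)
    pk_idx <- rep(seq_len(nrow(tp)), cnt)
    summit <- (tp$start + tp$end) %/% 2L
    drawn <- draw_lengths(length(pk_idx), config, g)
    offset <- ifelse(drawn$class == "nfr", 0L,
                     sample(c(-1L, 1L), length(pk_idx), replace = TRUE) *
                       config$nucleosome_period)
    pk_mid <- summit[pk_idx] + offset +
      as.integer(round(stats::rnorm(length(pk_idx), 0, 30)))
    pk_sc <- tp$scaffold[pk_idx]
    # stable-gene TSS windows: equal pre-scaling expectation in all samples
    s_cnt <- stats::rpois(nrow(stab), config$stable_tss_frags * sf)
    st_idx <- rep(seq_len(nrow(stab)), s_cnt)
    st_mid <- floor(stats::runif(length(st_idx), stab$tss[st_idx] - 800,
                                 stab$tss[st_idx] + 800))
    st_len <- draw_lengths(length(st_idx), config, g)$len
    mid <- c(bg_mid, pk_mid, st_mid)
    len <- c(bg_len, drawn$len, st_len)
    sc <- c(bg_sc, pk_sc, stab$scaffold[st_idx])
    L <- lens[sc]
    start <- pmax(0L, pmin(as.integer(mid - len %/% 2L),
                           as.integer(L - len)))
    start <- pmax(start, 0L)
    end <- pmin(start + len, L)
    keep <- end > start
    out[[samples$sample[si]]] <-
      fragments(sc[keep], start[keep], end[keep])
  }
  out
})

#' Generate the RNA-seq count table
#'
#' Negative-binomial counts over the simulated genes and the ATAC sample
#' grid. Stable genes have equal means in every group (dispersion
#' `rna_dispersion_stable`); other genes get a mild per-group lognormal
#' wobble (sd 0.2 on the log scale) plus, in the final condition only, a
#' promoter-coupling term: genes owning a truth promoter peak have their
#' final-condition mean multiplied by
#' `(profile[cluster, last] / profile[cluster, first])^rna_alpha`.
#' Library sizes vary by +-30%.
#'
#' @param config a [sim_config()].
#' @param truth from [generate_genome()].
#' @return list: `counts` (gene x sample), `gene_lengths`, `lib_factors`.
#' @export
generate_rnaseq <- function(config, truth) with_seed(config$seed + 2L, {
  samples <- truth$samples
  expr <- truth$expr
  ng <- nrow(expr)
  groups <- config$groups
  last <- groups[length(groups)]
  is_stable <- expr$gene_id %in% truth$stable_genes
  cluster_of_peak <- stats::setNames(truth$peaks$cluster,
                                     truth$peaks$peak_id)
  lift <- rep(1, ng)
  owned <- !is.na(expr$promoter_peak) & !is_stable
  if (any(owned)) {
    cl <- cluster_of_peak[expr$promoter_peak[owned]]
    up <- (truth$profiles[cl, last] /
             truth$profiles[cl, groups[1L]])^config$rna_alpha
    # composition-preserving: the transcriptome redistributes toward newly
    # accessible promoters without inflating the total expression mass, so
    # library totals (and the stable genes' means) stay comparable
    lift[owned] <- up / stats::weighted.mean(up, expr$base_mean[owned])
  }
  wobble <- matrix(1, ng, length(groups), dimnames = list(NULL, groups))
  wobble[!is_stable, ] <- exp(stats::rnorm(sum(!is_stable) * length(groups),
                                           0, 0.2))
  lib <- stats::setNames(stats::runif(nrow(samples), 0.7, 1.3),
                         samples$sample)
  counts <- matrix(0L, ng, nrow(samples),
                   dimnames = list(expr$gene_id, samples$sample))
  for (si in seq_len(nrow(samples))) {
    g <- samples$group[si]
    mu <- expr$base_mean * wobble[, g] *
      (if (g == last) lift else 1) * lib[[samples$sample[si]]]
    size <- ifelse(is_stable, 1 / config$rna_dispersion_stable,
                   1 / config$rna_dispersion)
    counts[, si] <- stats::rnbinom(ng, mu = mu, size = size)
  }
  list(counts = counts,
       gene_lengths = stats::setNames(expr$gene_length, expr$gene_id),
       lib_factors = lib)
})

#' Generate ChIP-like peak sets with spike-in read counts
#'
#' For each configured histone mark and each group, the mark's peak set is
#' the truth peaks of the clusters it occupies in that group, with
#' boundaries jittered by Normal(0, 20) bp. Target read counts are ~1e6 and
#' spike-in read counts are drawn around the configured mix ratio
#' (`spike/target = f/(1-f)` for spike read share `f`; the default f = 1/5
#' corresponds to a 1:4 exogenous:target chromatin mix) with +-20%
#' multiplicative noise.
#'
#' @param config a [sim_config()].
#' @param truth from [generate_genome()].
#' @param mark_config named list: mark (one of H3K4me3, H3K27ac, H3K27me3)
#'   -> either a character vector of clusters (same in every group) or a
#'   named list group -> clusters.
#' @return nested list mark -> group -> list(peaks, target_read_count,
#'   spike_read_count).
#' @export
generate_chip <- function(config, truth, mark_config) {
  known <- c("H3K4me3", "H3K27ac", "H3K27me3")
  bad <- setdiff(names(mark_config), known)
  if (length(bad)) stop("unknown mark label(s): ", paste(bad, collapse = ", "))
  with_seed(config$seed + 3L, {
    out <- list()
    for (mark in names(mark_config)) {
      spec <- mark_config[[mark]]
      out[[mark]] <- list()
      for (g in config$groups) {
        clusters <- if (is.list(spec)) spec[[g]] else spec
        tp <- truth$peaks[truth$peaks$cluster %in% clusters, , drop = FALSE]
        jit_s <- as.integer(round(stats::rnorm(nrow(tp), 0, 20)))
        jit_e <- as.integer(round(stats::rnorm(nrow(tp), 0, 20)))
        st <- pmax(0L, tp$start + jit_s)
        en <- pmax(st + 50L, tp$end + jit_e)
        pkset <- peaks(tp$scaffold, st, en,
                       name = paste0(mark, "_", g, "_", tp$peak_id),
                       score = 100)
        target <- round(1e6 * stats::runif(1, 0.9, 1.1))
        f <- config$spike_fraction
        spike <- round(target * f / (1 - f) * stats::runif(1, 0.8, 1.2))
        out[[mark]][[g]] <- list(peaks = pkset,
                                 target_read_count = target,
                                 spike_read_count = spike)
      }
    }
    out
  })
}

#' Run the full generator
#'
#' Convenience wrapper: genome + truth, ATAC fragments, RNA-seq counts and
#' (optionally) ChIP sets in one deterministic call.
#'
#' @param config a [sim_config()].
#' @param mark_config optional [generate_chip()] mark configuration.
#' @return list with `config`, `genes`, `truth`, `atac`, `rnaseq`, `chip`.
#' @export
simulate_experiment <- function(config = sim_config(), mark_config = NULL) {
  gen <- generate_genome(config)
  atac <- generate_atac(config, gen$truth, gen$genes)
  rna <- generate_rnaseq(config, gen$truth)
  chip <- if (!is.null(mark_config))
    generate_chip(config, gen$truth, mark_config) else NULL
  list(config = config, genes = gen$genes, truth = gen$truth, atac = atac,
       rnaseq = rna, chip = chip)
}

#' Write a simulated experiment to disk
#'
#' Emits `fragments/<sample>.bed`, `genes.gtf`, `rnaseq_counts.tsv`,
#' `truth.tsv`, and for each ChIP mark/group a narrowPeak file plus a pooled
#' `chip/spike_counts.tsv`.
#'
#' @param sim a [simulate_experiment()] result.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(file.path(dir, "fragments"), recursive = TRUE,
             showWarnings = FALSE)
  for (s in names(sim$atac))
    write_fragments(sim$atac[[s]], file.path(dir, "fragments",
                                             paste0(s, ".bed")))
  write_genes(sim$genes, file.path(dir, "genes.gtf"), format = "gtf")
  write_counts(sim$rnaseq$counts, file.path(dir, "rnaseq_counts.tsv"))
  utils::write.table(sim$truth$peaks, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$chip)) {
    dir.create(file.path(dir, "chip"), showWarnings = FALSE)
    rows <- list()
    for (mark in names(sim$chip)) for (g in names(sim$chip[[mark]])) {
      rec <- sim$chip[[mark]][[g]]
      write_peaks(rec$peaks,
                  file.path(dir, "chip", paste0(mark, "_", g,
                                                ".narrowPeak")),
                  format = "narrowPeak")
      rows[[paste(mark, g)]] <- data.frame(mark = mark, group = g,
                                           target_reads =
                                             rec$target_read_count,
                                           spike_reads =
                                             rec$spike_read_count)
    }
    utils::write.table(do.call(rbind, rows),
                       file.path(dir, "chip", "spike_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
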
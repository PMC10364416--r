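# Seeded synthetic-data generator. Emulates the statistical structure the
# reconstruction pipeline assumes: state-structured CAGE activity with
# replicate samples, planted enhancer->promoter links with positive activity
# coupling, cell-type-restricted element usage, noisy validation link sets,
# and GWAS p-values inflated inside causal genes' bodies and enhancers.

#' Build a configuration for the synthetic-data generator
#'
#' Defaults describe a small, desk-scale genome: 2 chromosomes of 50 Mb,
#' enhancers of 400 bp, log-normal active-element activity with median 5 TPM
#' (so the > 1 TPM usage rule is meaningful), sub-threshold uniform activity
#' for inactive elements, and additive Gaussian noise floored at 0 on
#' promoter activity. Each element is active (in usage) in a
#' \code{usage_specificity} fraction of states, giving the strong cell-type
#' restriction seen for real CREs (Gini index of per-state mean activity
#' above 0.8 at the default 0.2).
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param n_enh,n_prom Number of enhancers / promoters (genes).
#' @param n_states Number of cell/tissue states.
#' @param replicates_per_state Replicate samples per state.
#' @param links_per_promoter Integer range \code{c(min, max)} of planted
#'   enhancer links per promoter; \code{c(0, 0)} gives a pure-noise dataset.
#' @param noise_sd SD of the additive Gaussian noise on promoter TPM.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of active
#'   element activity.
#' @param usage_specificity Fraction of states in which an element is active.
#' @param inactive_max_tpm Upper bound of the uniform sub-threshold activity
#'   of inactive elements (must be below the 1 TPM usage threshold).
#' @param beta_range Range of planted link effect sizes (all positive).
#' @param gene_body_length Gene body length in bp (body starts at the TSS).
#' @param enhancer_width Enhancer width in bp.
#' @param n_causal_genes Number of causal genes planted for GWAS simulation.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A list of class \code{synth_config}.
#' @export
synth_config <- function(n_chrom = 2L, chrom_length = 5e7, n_enh = 1000L,
                         n_prom = 200L, n_states = 10L,
                         replicates_per_state = 2L,
                         links_per_promoter = c(2L, 4L), noise_sd = 0.25,
                         baseline_meanlog = log(5), baseline_sdlog = 0.5,
                         usage_specificity = 0.2, inactive_max_tpm = 0.1,
                         beta_range = c(0.5, 1.5), gene_body_length = 2e4,
                         enhancer_width = 400L, n_causal_genes = 20L,
                         seed = 1L) {
  cfg <- list(n_chrom = as.integer(n_chrom),
              chrom_length = as.numeric(chrom_length),
              n_enh = as.integer(n_enh), n_prom = as.integer(n_prom),
              n_states = as.integer(n_states),
              replicates_per_state = as.integer(replicates_per_state),
              links_per_promoter = as.integer(links_per_promoter),
              noise_sd = as.numeric(noise_sd),
              baseline_meanlog = as.numeric(baseline_meanlog),
              baseline_sdlog = as.numeric(baseline_sdlog),
              usage_specificity = as.numeric(usage_specificity),
              inactive_max_tpm = as.numeric(inactive_max_tpm),
              beta_range = as.numeric(beta_range),
              gene_body_length = as.numeric(gene_body_length),
              enhancer_width = as.integer(enhancer_width),
              n_causal_genes = as.integer(n_causal_genes),
              seed = as.integer(seed))
  stopifnot(cfg$n_chrom >= 1L, cfg$n_enh >= 1L, cfg$n_prom >= 1L,
            cfg$n_states >= 1L, cfg$replicates_per_state >= 1L,
            cfg$usage_specificity > 0, cfg$usage_specificity <= 1,
            cfg$noise_sd >= 0, cfg$inactive_max_tpm < 1,
            all(cfg$links_per_promoter >= 0L),
            cfg$links_per_promoter[1] <= cfg$links_per_promoter[2])
  class(cfg) <- "synth_config"
  cfg
}

#' Simulate a full synthetic CAGE dataset with planted regulatory links
#'
#' Promoter activity in a promoter's active states is the beta-weighted sum
#' of its planted enhancers' activities plus Gaussian noise, floored at 0;
#' planted enhancers share their target promoter's active states so that the
#' positive activity coupling is observable across samples. Elements are
#' sub-threshold (< 1 TPM) in the states where they are inactive. All planted
#' links are intra-chromosomal and within 1 Mb of the target TSS.
#'
#' @param config A [synth_config()].
#' @return A list of class \code{epilink_dataset} with components
#'   \code{enhancers}, \code{promoters}, \code{enh_activity},
#'   \code{prom_activity}, \code{samples} and \code{truth} (planted links
#'   with true effects, causal genes, and per-element active states).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  set.seed(cfg$seed)
  chroms <- sprintf("chr%d", seq_len(cfg$n_chrom))

  # promoters: TSS uniform away from chromosome ends, one gene per promoter
  prom_chrom <- sort(rep_len(chroms, cfg$n_prom))
  tss <- unlist(lapply(chroms, function(ch) {
    n <- sum(prom_chrom == ch)
    sort(as.integer(runif(n, 1e6, cfg$chrom_length - 1e6 - cfg$gene_body_length)))
  }))
  promoters <- data.frame(
    gene_id = sprintf("G%04d", seq_len(cfg$n_prom)), chrom = prom_chrom,
    tss = tss, strand = sample(c("+", "-"), cfg$n_prom, replace = TRUE),
    gene_start = tss, gene_end = as.integer(tss + cfg$gene_body_length),
    stringsAsFactors = FALSE)
  promoters$win_start <- pmax(0L, promoters$tss - 500L)
  promoters$win_end <- promoters$tss + 500L

  # enhancers: uniform placement
  enh_chrom <- sort(rep_len(chroms, cfg$n_enh))
  enh_start <- unlist(lapply(chroms, function(ch) {
    n <- sum(enh_chrom == ch)
    sort(as.integer(runif(n, 0, cfg$chrom_length - cfg$enhancer_width)))
  }))
  enhancers <- data.frame(
    chrom = enh_chrom, start = enh_start,
    end = as.integer(enh_start + cfg$enhancer_width),
    id = sprintf("E%05d", seq_len(cfg$n_enh)), stringsAsFactors = FALSE)
  enh_mid <- (enhancers$start + enhancers$end) / 2

  # samples: n_states states x replicates
  states <- sprintf("state%02d", seq_len(cfg$n_states))
  samples <- data.frame(
    sample_id = sprintf("S_%s_r%d", rep(states, each = cfg$replicates_per_state),
                        rep(seq_len(cfg$replicates_per_state), cfg$n_states)),
    state = rep(states, each = cfg$replicates_per_state),
    group = rep(sprintf("group%s", LETTERS[(seq_len(cfg$n_states) - 1L) %% 3L + 1L]),
                each = cfg$replicates_per_state),
    life_stage = rep(sample(c("fetal", "newborn", "adult"), cfg$n_states,
                            replace = TRUE), each = cfg$replicates_per_state),
    stringsAsFactors = FALSE)

  n_active <- max(1L, round(cfg$usage_specificity * cfg$n_states))
  prom_states <- lapply(seq_len(cfg$n_prom),
                        function(i) sort(sample(states, n_active)))
  names(prom_states) <- promoters$gene_id

  # planted links: per promoter, 'k' enhancers within 1 Mb on the same chrom
  k_links <- if (cfg$links_per_promoter[2] == 0L) integer(cfg$n_prom) else
    sample(seq(cfg$links_per_promoter[1], cfg$links_per_promoter[2]),
           cfg$n_prom, replace = TRUE)
  link_list <- vector("list", cfg$n_prom)
  for (i in seq_len(cfg$n_prom)) {
    if (k_links[i] == 0L) next
    cand <- which(enhancers$chrom == promoters$chrom[i] &
                    abs(enh_mid - promoters$tss[i]) <= 1e6)
    if (length(cand) < k_links[i]) {
      stop(sprintf("infeasible geometry: %d link(s) requested for %s but only %d candidate enhancer(s) within 1 Mb",
                   k_links[i], promoters$gene_id[i], length(cand)))
    }
    chosen <- sample(cand, k_links[i])
    link_list[[i]] <- data.frame(
      enhancer_id = enhancers$id[chosen], gene_id = promoters$gene_id[i],
      beta_true = runif(k_links[i], cfg$beta_range[1], cfg$beta_range[2]),
      stringsAsFactors = FALSE)
  }
  planted <- if (all(k_links == 0L)) {
    data.frame(enhancer_id = character(), gene_id = character(),
               beta_true = numeric(), stringsAsFactors = FALSE)
  } else do.call(rbind, link_list)

  # enhancer active states: planted enhancers inherit their targets' states
  enh_states <- lapply(seq_len(cfg$n_enh),
                       function(i) sort(sample(states, n_active)))
  names(enh_states) <- enhancers$id
  if (nrow(planted)) {
    inherited <- tapply(planted$gene_id, planted$enhancer_id, function(gs) {
      sort(unique(unlist(prom_states[gs])))
    })
    enh_states[names(inherited)] <- inherited
  }

  active_mask <- function(state_sets) {
    t(vapply(state_sets, function(s) samples$state %in% s,
             logical(nrow(samples))))
  }
  enh_active <- active_mask(enh_states)
  prom_active <- active_mask(prom_states)

  n_samp <- nrow(samples)
  enh_activity <- matrix(runif(cfg$n_enh * n_samp, 0, cfg$inactive_max_tpm),
                         cfg$n_enh, n_samp,
                         dimnames = list(enhancers$id, samples$sample_id))
  n_on <- sum(enh_active)
  enh_activity[enh_active] <- stats::rlnorm(n_on, cfg$baseline_meanlog,
                                            cfg$baseline_sdlog)

  prom_activity <- matrix(runif(cfg$n_prom * n_samp, 0, cfg$inactive_max_tpm),
                          cfg$n_prom, n_samp,
                          dimnames = list(promoters$gene_id, samples$sample_id))
  base_draw <- matrix(stats::rlnorm(cfg$n_prom * n_samp, cfg$baseline_meanlog,
                                    cfg$baseline_sdlog), cfg$n_prom, n_samp)
  noise <- matrix(stats::rnorm(cfg$n_prom * n_samp, 0, cfg$noise_sd),
                  cfg$n_prom, n_samp)
  leak <- 0.2 # sub-usage (basal) transcription: damped coupling below 1 TPM
  for (i in seq_len(cfg$n_prom)) {
    on <- prom_active[i, ]
    li <- link_list[[i]]
    if (is.null(li)) {
      if (any(on)) prom_activity[i, on] <- base_draw[i, on]
    } else {
      signal <- as.vector(li$beta_true %*%
                            enh_activity[li$enhancer_id, , drop = FALSE])
      if (any(on)) prom_activity[i, on] <- pmax(0, signal[on] + noise[i, on])
      if (any(!on)) {
        # saturating (rank-preserving) squash keeps basal activity < 1 TPM
        basal <- pmax(0, leak * signal[!on] + leak * noise[i, !on])
        prom_activity[i, !on] <- cfg$inactive_max_tpm * basal / (basal + 1)
      }
    }
  }

  causal_genes <- sort(sample(promoters$gene_id,
                              min(cfg$n_causal_genes, cfg$n_prom)))

  out <- list(enhancers = enhancers, promoters = promoters,
              enh_activity = enh_activity, prom_activity = prom_activity,
              samples = samples,
              truth = list(planted_links = planted,
                           causal_genes = causal_genes,
                           enh_states = enh_states,
                           prom_states = prom_states),
              config = cfg)
  class(out) <- "epilink_dataset"
  out
}

#' Derive a noisy validation link set from the planted truth
#'
#' Stands in for pcHi-C- or eQTL-derived truth pairs: each planted link is
#' included with probability \code{sensitivity}; false links are drawn from
#' the non-linked within-1-Mb same-chromosome pairs, each included with
#' probability \code{false_link_rate}.
#'
#' @param dataset An [simulate_dataset()] result.
#' @param sensitivity Inclusion probability for true links, in \[0, 1\].
#' @param false_link_rate Inclusion probability for non-linked candidate
#'   pairs, in \[0, 1\].
#' @param seed Integer seed.
#' @return data.frame with columns \code{enhancer_id}, \code{gene_id},
#'   \code{source} (\code{"synthetic"}).
#' @export
make_validation <- function(dataset, sensitivity = 1, false_link_rate = 0,
                            seed = 1L) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            false_link_rate >= 0, false_link_rate <= 1)
  set.seed(seed)
  truth <- dataset$truth$planted_links
  keep_true <- truth[runif(nrow(truth)) < sensitivity,
                     c("enhancer_id", "gene_id"), drop = FALSE]
  false_part <- NULL
  if (false_link_rate > 0) {
    cand <- candidate_links(dataset$promoters, dataset$enhancers)
    key <- paste(cand$enhancer_id, cand$gene_id)
    truth_key <- paste(truth$enhancer_id, truth$gene_id)
    nonlinked <- cand[!(key %in% truth_key), c("enhancer_id", "gene_id")]
    false_part <- nonlinked[runif(nrow(nonlinked)) < false_link_rate, ,
                            drop = FALSE]
  }
  out <- rbind(keep_true, false_part)
  out <- out[!duplicated(paste(out$enhancer_id, out$gene_id)), , drop = FALSE]
  rownames(out) <- NULL
  out$source <- rep("synthetic", nrow(out))
  out
}

#' Simulate a GWAS variant table over the synthetic genome
#'
#' SNPs are placed uniformly along the genome. Background SNPs receive
#' Uniform(0, 1) p-values; SNPs falling in a causal gene's body +/- 2 kb or
#' in one of its planted enhancers receive Beta(1 / (1 + effect_shift), 1)
#' p-values, i.e. shifted toward 0 for \code{effect_shift > 0} and identical
#' to the background law at \code{effect_shift = 0}.
#'
#' @param dataset An [simulate_dataset()] result.
#' @param n_variants Number of SNPs.
#' @param maf_sampler Function \code{n -> MAF vector in (0, 0.5]}.
#' @param effect_shift Non-negative effect strength.
#' @param seed Integer seed.
#' @return data.frame with columns \code{snp_id}, \code{chrom}, \code{pos},
#'   \code{maf}, \code{p} and the synthetic-truth flag
#'   \code{in_causal_region}.
#' @export
make_gwas <- function(dataset, n_variants = 10000L,
                      maf_sampler = function(n) runif(n, 0.01, 0.5),
                      effect_shift = 9, seed = 1L) {
  stopifnot(effect_shift >= 0)
  set.seed(seed)
  cfg <- dataset$config
  chroms <- sprintf("chr%d", seq_len(cfg$n_chrom))
  chrom <- sample(chroms, n_variants, replace = TRUE)
  pos <- as.integer(runif(n_variants, 1, cfg$chrom_length))
  ord <- order(match(chrom, chroms), pos)
  chrom <- chrom[ord]; pos <- pos[ord]

  causal <- dataset$truth$causal_genes
  pr <- dataset$promoters
  body <- pr[pr$gene_id %in% causal, , drop = FALSE]
  in_causal <- logical(n_variants)
  for (i in seq_len(nrow(body))) {
    in_causal <- in_causal | (chrom == body$chrom[i] &
                                pos >= body$gene_start[i] - 2000L &
                                pos < body$gene_end[i] + 2000L)
  }
  links <- dataset$truth$planted_links
  causal_enh <- unique(links$enhancer_id[links$gene_id %in% causal])
  enh <- dataset$enhancers[dataset$enhancers$id %in% causal_enh, , drop = FALSE]
  for (i in seq_len(nrow(enh))) {
    in_causal <- in_causal | (chrom == enh$chrom[i] & pos >= enh$start[i] &
                                pos < enh$end[i])
  }

  p <- runif(n_variants)
  if (effect_shift > 0 && any(in_causal)) {
    p[in_causal] <- stats::rbeta(sum(in_causal), 1 / (1 + effect_shift), 1)
  }
  data.frame(snp_id = sprintf("rs%06d", seq_len(n_variants)), chrom = chrom,
             pos = pos, maf = maf_sampler(n_variants), p = p,
             in_causal_region = in_causal, stringsAsFactors = FALSE)
}

#' Gini index of a non-negative vector
#'
#' Used to quantify the cell-type restriction of element activity: the Gini
#' index of per-state mean activity is high (> 0.8) for highly specific
#' elements.
#'
#' @param x Non-negative numeric vector.
#' @return Gini index in \[0, 1\].
#' @export
gini_index <- function(x) {
  stopifnot(all(x >= 0), sum(x) > 0)
  x <- sort(x)
  n <- length(x)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}

#' Write a synthetic dataset to a directory in the pipeline's file formats
#'
#' Writes \code{enhancers.bed}, \code{promoters.tsv}, \code{enh_activity.tsv},
#' \code{prom_activity.tsv}, \code{samples.tsv} and a \code{truth.json} with
#' the planted links and causal genes.
#'
#' @param dataset An [simulate_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_enhancers(dataset$enhancers, file.path(dir, "enhancers.bed"))
  write_promoters(dataset$promoters, file.path(dir, "promoters.tsv"))
  write_activity_matrix(dataset$enh_activity, file.path(dir, "enh_activity.tsv"))
  write_activity_matrix(dataset$prom_activity, file.path(dir, "prom_activity.tsv"))
  write_sample_table(dataset$samples, file.path(dir, "samples.tsv"))
  truth <- list(planted_links = dataset$truth$planted_links,
                causal_genes = dataset$truth$causal_genes)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
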
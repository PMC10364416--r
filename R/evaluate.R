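# Evaluation of reconstructed networks against validation link sets, and
# the enrichment statistics used to validate CAGE-derived elements.

#' Area under the precision-recall curve against a validation set
#'
#' Pairs are ranked by score (descending; ties and the ordering of equal
#' scores broken by gene_id then enhancer_id for determinism) over a
#' restricted universe of candidate pairs. Universe pairs missing from the
#' predictions rank last with score 0. The AUPR is computed as average
#' precision (step-wise integration of the PR curve): the mean, over true
#' pairs, of the precision at each true pair's rank.
#'
#' @param predicted data.frame (enhancer_id, gene_id, score).
#' @param truth data.frame (enhancer_id, gene_id) of validated pairs.
#' @param universe data.frame (enhancer_id, gene_id) of candidate pairs to
#'   evaluate over (e.g. within-1-Mb pairs whose enhancer appears in the
#'   validation data at least once).
#' @return AUPR in \[0, 1\].
#' @export
aupr_against <- function(predicted, truth, universe) {
  stopifnot(nrow(universe) > 0L)
  ukey <- paste(universe$enhancer_id, universe$gene_id)
  stopifnot(!anyDuplicated(ukey))
  tkey <- paste(truth$enhancer_id, truth$gene_id)
  is_true <- ukey %in% tkey
  if (!any(is_true)) stop("undefined recall: no true pair in the universe")
  pkey <- paste(predicted$enhancer_id, predicted$gene_id)
  score <- rep(0, length(ukey))
  m <- match(ukey, pkey)
  score[!is.na(m)] <- predicted$score[m[!is.na(m)]]
  ord <- order(-score, universe$gene_id, universe$enhancer_id)
  pos <- is_true[ord]
  prec_at <- cumsum(pos) / seq_along(pos)
  mean(prec_at[pos])
}

#' Baseline enhancer-to-promoter linking strategies
#'
#' Three alternative linkers used as AUPR comparators: \code{closest} links
#' each enhancer to the nearest TSS within 1 Mb (score 1/(1 + distance)),
#' \code{max_corr} to the promoter with the maximum Spearman activity
#' correlation within 1 Mb (score = rho), and \code{random} to a uniformly
#' drawn promoter within 1 Mb (seeded; score drawn Uniform(0,1)). Enhancers
#' with no promoter within range are skipped and counted in attribute
#' \code{"n_unlinked"}.
#'
#' @param method One of \code{"closest"}, \code{"max_corr"}, \code{"random"}.
#' @param enhancers,promoters Element tables.
#' @param enh_activity,prom_activity Activity matrices (required for
#'   \code{max_corr}).
#' @param seed Integer seed (used by \code{random}).
#' @param max_dist Cis window in bp (default 1 Mb).
#' @return data.frame (enhancer_id, gene_id, score).
#' @export
baseline_links <- function(method = c("closest", "max_corr", "random"),
                           enhancers, promoters, enh_activity = NULL,
                           prom_activity = NULL, seed = 1L, max_dist = 1e6) {
  method <- match.arg(method)
  if (method == "random") set.seed(seed)
  if (method == "max_corr") {
    stopifnot(!is.null(enh_activity), !is.null(prom_activity))
    prom_ranks <- .rank_standardize(prom_activity)
    n_samp <- ncol(prom_activity)
  }
  mid <- (enhancers$start + enhancers$end) / 2
  rows <- vector("list", nrow(enhancers))
  n_unlinked <- 0L
  for (i in seq_len(nrow(enhancers))) {
    sel <- which(promoters$chrom == enhancers$chrom[i])
    d <- abs(promoters$tss[sel] - mid[i])
    sel <- sel[d <= max_dist]; d <- d[d <= max_dist]
    if (length(sel) == 0L) { n_unlinked <- n_unlinked + 1L; next }
    if (method == "closest") {
      j <- sel[order(d, promoters$gene_id[sel])[1L]]
      sc <- 1 / (1 + min(d))
    } else if (method == "max_corr") {
      yz <- .rank_standardize_vec(enh_activity[enhancers$id[i], ])
      rho <- as.numeric(prom_ranks[match(promoters$gene_id[sel],
                                         rownames(prom_activity)), ,
                                   drop = FALSE] %*% yz) / (n_samp - 1)
      k <- order(-rho, promoters$gene_id[sel])[1L]
      j <- sel[k]; sc <- rho[k]
    } else {
      j <- sel[sample.int(length(sel), 1L)]
      sc <- runif(1L)
    }
    rows[[i]] <- data.frame(enhancer_id = enhancers$id[i],
                            gene_id = promoters$gene_id[j], score = sc,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(enhancer_id = character(),
                                      gene_id = character(), score = numeric(),
                                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_unlinked") <- n_unlinked
  out
}

#' Enrichment odds ratio OR = (a/b) / (c/d)
#'
#' \code{a}: query hits in the target regions; \code{b}: control hits in the
#' target regions; \code{c}: query hits in the baseline; \code{d}: control
#' hits in the baseline.
#'
#' @param a,b,c,d Non-negative counts; \code{b} and \code{c} must be > 0.
#' @return The odds ratio.
#' @export
enrichment_or <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (b == 0) stop("enrichment OR undefined: b (controls in target regions) is 0")
  if (c == 0) stop("enrichment OR undefined: c (query hits in baseline) is 0")
  (a / b) / (c / d)
}

# logical: is each (chrom, pos) inside >= 1 half-open [start, end) region
.pos_in_regions <- function(chrom, pos, regions) {
  if (nrow(regions) == 0L) return(logical(length(pos)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
  s <- GenomicRanges::GRanges(regions$chrom,
                              IRanges::IRanges(regions$start + 1L, regions$end))
  IRanges::overlapsAny(q, s)
}

#' cis-QTL enrichment in CREs with MAF-matched control variants
#'
#' For each of \code{n_repeats} draws, a control set with the same size and
#' MAF distribution as the QTL variants (matched within 50 equal-width MAF
#' bins over (0, 0.5]) is sampled from \code{control_pool}, and
#' \code{OR = (a/b)/(c/d)} is computed with a = QTL variants in the CREs,
#' b = controls in the CREs, c = QTL variants in the baseline regions,
#' d = controls in the baseline regions. Returns the mean and SD of the OR
#' across repeats.
#'
#' @param qtl data.frame (chrom, pos, maf, optionally pp).
#' @param control_pool data.frame (chrom, pos, maf) of candidate controls.
#' @param cre_regions,baseline_regions Interval tables (chrom, start, end).
#' @param n_repeats Number of control draws (default 30).
#' @param n_maf_bins Number of equal-width MAF bins (default 50).
#' @param pp_threshold Optional fine-mapping posterior-probability cutoff;
#'   when given, only QTL rows with \code{pp > pp_threshold} are used.
#' @param seed Integer seed.
#' @return List with \code{or_mean}, \code{or_sd} and the per-repeat
#'   \code{or_values}.
#' @export
qtl_enrichment <- function(qtl, control_pool, cre_regions, baseline_regions,
                           n_repeats = 30L, n_maf_bins = 50L,
                           pp_threshold = NULL, seed = 1L) {
  stopifnot(nrow(cre_regions) > 0L, nrow(baseline_regions) > 0L,
            nrow(qtl) > 0L, nrow(control_pool) > 0L)
  if (!is.null(pp_threshold)) {
    stopifnot("pp" %in% names(qtl))
    qtl <- qtl[qtl$pp > pp_threshold, , drop = FALSE]
    if (nrow(qtl) == 0L) stop("no QTL variant passes the pp threshold")
  }
  bin_of <- function(maf) pmin(n_maf_bins,
                               pmax(1L, ceiling(maf / (0.5 / n_maf_bins))))
  qtl_bin <- bin_of(qtl$maf)
  pool_bin <- bin_of(control_pool$maf)
  need <- table(qtl_bin)
  pool_idx <- split(seq_len(nrow(control_pool)), pool_bin)
  missing_bins <- setdiff(names(need), names(pool_idx))
  if (length(missing_bins)) {
    stop("no candidate control variants in MAF bin(s): ",
         paste(missing_bins, collapse = ", "))
  }
  a <- sum(.pos_in_regions(qtl$chrom, qtl$pos, cre_regions))
  cc <- sum(.pos_in_regions(qtl$chrom, qtl$pos, baseline_regions))
  in_cre_pool <- .pos_in_regions(control_pool$chrom, control_pool$pos,
                                 cre_regions)
  in_base_pool <- .pos_in_regions(control_pool$chrom, control_pool$pos,
                                  baseline_regions)
  set.seed(seed)
  ors <- vapply(seq_len(n_repeats), function(r) {
    ctrl <- unlist(lapply(names(need), function(bn) {
      avail <- pool_idx[[bn]]
      k <- need[[bn]]
      if (length(avail) < k) {
        warning(sprintf("MAF bin %s: pool smaller than needed; sampling with replacement", bn))
        sample(avail, k, replace = TRUE)
      } else sample(avail, k)
    }), use.names = FALSE)
    b <- sum(in_cre_pool[ctrl])
    d <- sum(in_base_pool[ctrl])
    enrichment_or(a, b, cc, d)
  }, numeric(1L))
  list(or_mean = mean(ors), or_sd = stats::sd(ors), or_values = ors)
}

#' Interval-overlap enrichment with a hypergeometric test
#'
#' A query interval "hits" when it intersects (>= 1 bp) at least one active
#' interval. The p-value is the upper tail of the hypergeometric
#' distribution with population = the query background annotated by
#' active-set overlap, draws = the query set, successes = observed hits.
#' The odds ratio follows the ratio-of-ratios
#' \code{(hits / |query_background|) / (|active| / |active_background|)}.
#'
#' @param query,active Interval tables (chrom, start, end).
#' @param query_background,active_background Background interval tables
#'   (supersets of query / active respectively; non-empty).
#' @return List with \code{or}, \code{p}, and the counts used.
#' @export
overlap_enrichment <- function(query, active, query_background,
                               active_background) {
  stopifnot(nrow(query_background) > 0L, nrow(active_background) > 0L)
  hit <- function(q, s) {
    if (nrow(q) == 0L || nrow(s) == 0L) return(logical(nrow(q)))
    qr <- GenomicRanges::GRanges(q$chrom, IRanges::IRanges(q$start + 1L, q$end))
    sr <- GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$start + 1L, s$end))
    IRanges::overlapsAny(qr, sr)
  }
  k <- sum(hit(query, active))
  K <- sum(hit(query_background, active))
  N <- nrow(query_background)
  n <- nrow(query)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  or <- (k / N) / (nrow(active) / nrow(active_background))
  list(or = or, p = p, overlap = k, background_overlap = K,
       n_query = n, n_background = N)
}

#' Fisher's exact test for the overlap of two gene sets
#'
#' Builds the 2x2 table (in both, A only, B only, neither) over the supplied
#' universe and returns the sample odds ratio
#' \code{(n11 * n22) / (n12 * n21)} together with the two-sided Fisher exact
#' p-value.
#'
#' @param set_a,set_b Character vectors of gene ids (subsets of universe).
#' @param universe Character vector, the gene universe.
#' @return List with \code{or}, \code{p} and the 2x2 \code{table}.
#' @export
overlap_fisher <- function(set_a, set_b, universe) {
  stopifnot(length(universe) > 0L)
  universe <- unique(universe)
  set_a <- intersect(unique(set_a), universe)
  set_b <- intersect(unique(set_b), universe)
  n11 <- length(intersect(set_a, set_b))
  n12 <- length(setdiff(set_a, set_b))
  n21 <- length(setdiff(set_b, set_a))
  n22 <- length(universe) - n11 - n12 - n21
  tab <- matrix(c(n11, n12, n21, n22), 2L, byrow = TRUE)
  or <- if (n12 == 0L || n21 == 0L) {
    if (n11 == 0L || n22 == 0L) NaN else Inf
  } else (n11 * n22) / (n12 * n21)
  if (n11 == 0L) or <- 0
  p <- stats::fisher.test(tab)$p.value
  list(or = or, p = p, table = tab)
}
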
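# Multi-step EPI reconstruction: cis candidate enumeration, LASSO selection
# of positively contributing enhancers, empirical-FDR Spearman filtering
# against trans-chromosomal null pairs, per-sample activation from usage
# calls, ABC scoring, and replicate aggregation into per-state networks.

#' ABC model parameters
#'
#' The contact term is a power-law distance decay
#' \code{C(d) = (d + d0)^(-gamma)}; \code{background} is the promoter
#' background share added to the normalizing denominator.
#'
#' @param gamma Distance-decay exponent (>= 0), default 1.
#' @param d0 Pseudo-distance in bp (>= 0; it avoids a singularity at d = 0,
#'   so 0 is only sensible when all distances are positive), default 5000.
#' @param background Promoter background term B_p (>= 0), default 0.
#' @return List of class \code{abc_params}.
#' @export
abc_params <- function(gamma = 1, d0 = 5000, background = 0) {
  stopifnot(gamma >= 0, d0 >= 0, background >= 0)
  structure(list(gamma = gamma, d0 = d0, background = background),
            class = "abc_params")
}

#' Enumerate candidate cis enhancers for each promoter
#'
#' A candidate is any enhancer on the promoter's chromosome whose midpoint
#' is within \code{max_dist} (default 1 Mb) of the TSS. Distance is
#' |enhancer midpoint - TSS|.
#'
#' @param promoters Promoter table ([read_promoters()] layout).
#' @param enhancers Enhancer table ([read_enhancers()] layout).
#' @param max_dist Maximum midpoint-to-TSS distance in bp.
#' @return data.frame (gene_id, enhancer_id, distance), sorted by distance
#'   within each promoter.
#' @export
candidate_links <- function(promoters, enhancers, max_dist = 1e6) {
  if (nrow(enhancers) == 0L || nrow(promoters) == 0L) {
    return(data.frame(gene_id = character(), enhancer_id = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  }
  mid <- (enhancers$start + enhancers$end) / 2
  out <- lapply(seq_len(nrow(promoters)), function(i) {
    sel <- enhancers$chrom == promoters$chrom[i]
    d <- abs(mid[sel] - promoters$tss[i])
    keep <- d <= max_dist
    if (!any(keep)) return(NULL)
    df <- data.frame(gene_id = promoters$gene_id[i],
                     enhancer_id = enhancers$id[sel][keep],
                     distance = d[keep], stringsAsFactors = FALSE)
    df[order(df$distance, df$enhancer_id), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(gene_id = character(),
                                      enhancer_id = character(),
                                      distance = numeric(),
                                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Row-wise midrank standardization: each row is replaced by its ranks
# (average ties), centered and scaled so that crossprod/(n-1) gives Spearman
# correlations. Constant rows become all-zero (Spearman treated as 0).
.rank_standardize <- function(mat) {
  r <- t(apply(mat, 1L, rank))
  if (nrow(mat) == 1L) r <- matrix(r, 1L)
  mu <- rowMeans(r)
  s <- sqrt(apply(r, 1L, stats::var))
  z <- (r - mu) / ifelse(s > 0, s, Inf)
  z
}

.rank_standardize_vec <- function(y) {
  r <- rank(y)
  s <- stats::sd(r)
  if (s == 0) return(rep(0, length(y)))
  (r - mean(r)) / s
}

#' Select positively contributing enhancers by LASSO regression
#'
#' Fits an L1-penalized linear model of promoter activity on all candidate
#' enhancer activities jointly (all variables z-scored; penalty chosen by
#' seeded k-fold cross-validation) and retains the candidates with a strictly
#' positive coefficient. A single-candidate model degenerates to the sign of
#' the Pearson correlation. A zero-variance promoter yields an empty
#' retained set.
#'
#' @param y Promoter activity across samples (length >= 8).
#' @param X Matrix of candidate activities, samples x candidates, with
#'   candidate ids as colnames.
#' @param nfolds Cross-validation folds (default 5).
#' @param seed Integer seed for fold assignment.
#' @return data.frame (enhancer_id, beta) over all candidates; attribute
#'   \code{"retained"} gives the ids with beta > 0.
#' @export
lasso_select <- function(y, X, nfolds = 5L, seed = 1L) {
  stopifnot(is.matrix(X), length(y) == nrow(X), ncol(X) >= 1L)
  if (length(y) < 8L) stop("lasso_select requires >= 8 samples")
  ids <- colnames(X)
  beta <- stats::setNames(numeric(ncol(X)), ids)
  sy <- stats::sd(y)
  if (is.na(sy) || sy == 0) {
    out <- data.frame(enhancer_id = ids, beta = beta, stringsAsFactors = FALSE)
    attr(out, "retained") <- character()
    return(out)
  }
  yz <- (y - mean(y)) / sy
  sx <- apply(X, 2L, stats::sd)
  ok <- sx > 0
  if (any(ok)) {
    Xz <- scale(X[, ok, drop = FALSE])
    if (sum(ok) == 1L) {
      beta[ok] <- stats::cor(yz, Xz[, 1L])
    } else {
      n <- length(y)
      # keep >= 3 observations per CV fold (glmnet's grouped-CV requirement)
      k <- max(3L, min(nfolds, n %/% 3L))
      old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
      set.seed(seed)
      foldid <- sample(rep_len(seq_len(k), n))
      # near-degenerate promoters can leave a CV fold with constant y;
      # fall back to marginal correlation signs in that case
      fit <- tryCatch(
        glmnet::cv.glmnet(Xz, yz, nfolds = k, foldid = foldid,
                          standardize = FALSE),
        error = function(e) NULL)
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      beta[ok] <- if (is.null(fit)) {
        as.numeric(stats::cor(yz, Xz))
      } else {
        as.numeric(stats::coef(fit, s = "lambda.min"))[-1L]
      }
    }
  }
  out <- data.frame(enhancer_id = ids, beta = as.numeric(beta),
                    stringsAsFactors = FALSE)
  attr(out, "retained") <- ids[beta > 0]
  out
}

#' Empirical threshold for a null distribution
#'
#' The retained-correlation cutoff is the (1 - fdr) empirical quantile of
#' the null values, using the linear-interpolation quantile (type 7).
#'
#' @param null_values Numeric vector of null statistics.
#' @param fdr Target empirical false discovery rate in (0, 1).
#' @return The threshold value.
#' @export
empirical_threshold <- function(null_values, fdr = 0.05) {
  stopifnot(fdr > 0, fdr < 1, length(null_values) > 0)
  stats::quantile(null_values, probs = 1 - fdr, type = 7, names = FALSE)
}

#' Per-promoter null Spearman threshold from trans-chromosomal enhancers
#'
#' Draws \code{n_null} enhancers from a pool located on other chromosomes,
#' computes the Spearman correlation of each with the promoter activity, and
#' returns the (1 - fdr) empirical quantile of this null distribution. Pools
#' smaller than \code{n_null} are sampled with replacement (with a warning).
#'
#' @param y Promoter activity across samples.
#' @param trans_pool Matrix of trans enhancer activities (elements x
#'   samples).
#' @param n_null Number of null pairs (default 10000).
#' @param fdr Empirical FDR (default 0.05).
#' @param seed Integer seed.
#' @return Threshold (numeric scalar); attribute \code{"null_rho"} holds the
#'   null correlations.
#' @export
null_rho_threshold <- function(y, trans_pool, n_null = 10000L, fdr = 0.05,
                               seed = 1L) {
  stopifnot(nrow(trans_pool) > 0L, ncol(trans_pool) == length(y))
  set.seed(seed)
  if (nrow(trans_pool) < n_null) {
    warning(sprintf("trans pool (%d) smaller than n_null (%d); sampling with replacement",
                    nrow(trans_pool), n_null))
    idx <- sample.int(nrow(trans_pool), n_null, replace = TRUE)
  } else {
    idx <- sample.int(nrow(trans_pool), n_null)
  }
  z <- .rank_standardize(trans_pool[idx, , drop = FALSE])
  yz <- .rank_standardize_vec(y)
  rho <- as.numeric(z %*% yz) / (length(y) - 1)
  thr <- empirical_threshold(rho, fdr)
  attr(thr, "null_rho") <- rho
  thr
}

#' Filter candidate links by observed activity correlation
#'
#' Retains links whose Spearman rho is strictly higher than the (per-promoter
#' or global) null threshold.
#'
#' @param links data.frame with columns \code{gene_id}, \code{enhancer_id},
#'   \code{rho}.
#' @param threshold Scalar threshold, or named vector keyed by gene_id.
#' @return The retained rows.
#' @export
correlation_filter <- function(links, threshold) {
  if (nrow(links) == 0L) return(links)
  thr <- if (length(threshold) == 1L && is.null(names(threshold))) {
    rep(as.numeric(threshold), nrow(links))
  } else {
    as.numeric(threshold[links$gene_id])
  }
  out <- links[!is.na(thr) & links$rho > thr, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sample activation of candidate EPIs from usage calls
#'
#' An EPI is active in a sample iff both its enhancer and its promoter are
#' in usage in that sample.
#'
#' @param links data.frame with \code{gene_id} and \code{enhancer_id}.
#' @param enh_usage,prom_usage Logical usage matrices (elements x samples).
#' @param sample_id Sample to evaluate.
#' @return \code{links} with a logical \code{active} column and the
#'   \code{sample_id}.
#' @export
activate_per_sample <- function(links, enh_usage, prom_usage, sample_id) {
  unknown_e <- setdiff(links$enhancer_id, rownames(enh_usage))
  if (length(unknown_e)) stop("unknown enhancer id: ", unknown_e[1L])
  unknown_g <- setdiff(links$gene_id, rownames(prom_usage))
  if (length(unknown_g)) stop("unknown gene id: ", unknown_g[1L])
  if (!sample_id %in% colnames(enh_usage)) stop("unknown sample id: ", sample_id)
  links$sample_id <- rep(sample_id, nrow(links))
  links$active <- enh_usage[links$enhancer_id, sample_id] &
    prom_usage[links$gene_id, sample_id]
  rownames(links) <- NULL
  links
}

#' ABC scores for the active links of one promoter in one sample
#'
#' \code{score(e) = sqrt(A_e * A_p) * C(d_e) / (sum_e' sqrt(A_e' * A_p) *
#' C(d_e') + B_p)} with \code{C(d) = (d + d0)^(-gamma)}: the Activity term is
#' the geometric mean of enhancer and promoter TPM and Contact is a
#' power-law distance decay. Scores lie in \[0, 1\] and sum to at most 1
#' (exactly 1 - B_p share when \code{background > 0} participates).
#'
#' @param links data.frame of active links sharing one promoter and sample,
#'   with \code{enhancer_id} and \code{distance}.
#' @param enh_activity Named activity vector covering the link enhancers.
#' @param prom_activity Promoter activity (scalar, >= 0).
#' @param params An [abc_params()].
#' @return Named numeric vector of scores (empty when the denominator is 0).
#' @export
abc_quantify <- function(links, enh_activity, prom_activity,
                         params = abc_params()) {
  stopifnot(prom_activity >= 0)
  if (nrow(links) == 0L && params$background == 0) {
    return(stats::setNames(numeric(0), character(0)))
  }
  a_e <- enh_activity[links$enhancer_id]
  stopifnot(all(a_e >= 0))
  w <- sqrt(a_e * prom_activity) * (links$distance + params$d0)^(-params$gamma)
  denom <- sum(w) + params$background
  if (denom == 0) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(as.numeric(w / denom), links$enhancer_id)
}

#' Aggregate per-sample EPI records into a per-state network
#'
#' The state's edge set is the union of links active in at least one of the
#' state's samples; each edge carries the maximal ABC score across those
#' samples.
#'
#' @param records data.frame of per-sample records with columns
#'   \code{sample_id}, \code{enhancer_id}, \code{gene_id}, \code{active},
#'   \code{abc}.
#' @param sample_table Sample annotation table.
#' @param state State label (must have >= 1 sample).
#' @return data.frame (enhancer_id, gene_id, abc, n_samples_active) — the
#'   state's network edges.
#' @export
aggregate_state <- function(records, sample_table, state) {
  samp <- sample_table$sample_id[sample_table$state == state]
  if (length(samp) == 0L) stop("state has no samples: ", state)
  rec <- records[records$sample_id %in% samp & records$active, , drop = FALSE]
  if (nrow(rec) == 0L) {
    return(data.frame(enhancer_id = character(), gene_id = character(),
                      abc = numeric(), n_samples_active = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(rec$gene_id, rec$enhancer_id, sep = "\r")
  agg_abc <- tapply(rec$abc, key, max)
  agg_n <- tapply(rec$abc, key, length)
  parts <- strsplit(names(agg_abc), "\r", fixed = TRUE)
  out <- data.frame(enhancer_id = vapply(parts, `[[`, "", 2L),
                    gene_id = vapply(parts, `[[`, "", 1L),
                    abc = as.numeric(agg_abc),
                    n_samples_active = as.integer(agg_n),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$enhancer_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full EPI reconstruction pipeline
#'
#' Executes, for every promoter: candidate enumeration within the cis
#' window, LASSO selection (positive coefficients only), the per-promoter
#' empirical-FDR Spearman filter against a trans-chromosomal null, then
#' per-sample activation from usage calls, ABC scoring, and aggregation into
#' one network per state (union of active replicates, maximal ABC score).
#'
#' @param dataset Either an [simulate_dataset()] result or a list with
#'   components \code{enhancers}, \code{promoters}, \code{enh_activity},
#'   \code{prom_activity}, \code{samples}.
#' @param config Pipeline configuration from [default_config()].
#' @return List of class \code{epi_reconstruction}: \code{links} (retained
#'   links with beta, rho, distance), \code{records} (per-sample activation
#'   and ABC), \code{networks} (named list of per-state edge tables),
#'   \code{thresholds} (per-promoter null cutoffs) and \code{report}
#'   (per-step counts and parameters).
#' @export
reconstruct_all <- function(dataset, config = default_config()) {
  config <- validate_config(config)
  enh <- dataset$enhancers; prom <- dataset$promoters
  Ae <- dataset$enh_activity; Ap <- dataset$prom_activity
  samples <- dataset$samples
  stopifnot(identical(colnames(Ae), colnames(Ap)),
            all(samples$sample_id %in% colnames(Ae)))
  params <- abc_params(config$abc_gamma, config$abc_d0, config$abc_background)

  enh_usage <- usage_from_activity(Ae, config$usage_threshold)
  prom_usage <- usage_from_activity(Ap, config$usage_threshold)
  cand <- candidate_links(prom, enh, config$max_dist)

  report <- list(seed = config$seed, parameters = config,
                 n_promoters = nrow(prom), n_enhancers = nrow(enh),
                 n_candidates = nrow(cand))

  empty_links <- data.frame(gene_id = character(), enhancer_id = character(),
                            distance = numeric(), beta = numeric(),
                            rho = numeric(), stringsAsFactors = FALSE)
  if (nrow(cand) == 0L) {
    networks <- lapply(unique(samples$state), function(s) {
      data.frame(enhancer_id = character(), gene_id = character(),
                 abc = numeric(), n_samples_active = integer(),
                 stringsAsFactors = FALSE)
    })
    names(networks) <- unique(samples$state)
    report$n_lasso_retained <- 0L; report$n_correlation_retained <- 0L
    report$n_active_records <- 0L
    return(structure(list(links = empty_links,
                          records = cbind(empty_links[0, ],
                                          data.frame(sample_id = character(),
                                                     active = logical(),
                                                     abc = numeric())),
                          networks = networks, thresholds = numeric(),
                          report = report),
                     class = "epi_reconstruction"))
  }

  n_samp <- ncol(Ae)
  yz_all <- t(apply(Ap, 1L, .rank_standardize_vec))
  enh_ranks <- .rank_standardize(Ae)

  genes <- unique(cand$gene_id)
  cand_by_gene <- split(cand, cand$gene_id)
  thresholds <- stats::setNames(rep(NA_real_, length(genes)), genes)
  retained_list <- vector("list", length(genes))
  n_lasso <- 0L
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    cg <- cand_by_gene[[g]]
    y <- Ap[g, ]
    sel <- lasso_select(y, t(Ae[cg$enhancer_id, , drop = FALSE]),
                        nfolds = config$lasso_nfolds,
                        seed = config$seed + gi)
    keep <- attr(sel, "retained")
    n_lasso <- n_lasso + length(keep)
    if (length(keep) == 0L) next
    cg <- cg[cg$enhancer_id %in% keep, , drop = FALSE]
    cg$beta <- sel$beta[match(cg$enhancer_id, sel$enhancer_id)]
    # Spearman rho of each retained candidate with the promoter
    yz <- yz_all[g, ]
    cg$rho <- as.numeric(enh_ranks[match(cg$enhancer_id, rownames(Ae)), ,
                                   drop = FALSE] %*% yz) / (n_samp - 1)
    # per-promoter null from trans-chromosomal enhancers
    g_chrom <- prom$chrom[match(g, prom$gene_id)]
    trans <- which(enh$chrom != g_chrom)
    if (length(trans) == 0L) next
    set.seed(config$seed + 7919L + gi)
    idx <- if (length(trans) < config$n_null) {
      sample(trans, config$n_null, replace = TRUE)
    } else sample(trans, config$n_null)
    null_rho <- as.numeric(enh_ranks[idx, , drop = FALSE] %*% yz) / (n_samp - 1)
    thr <- empirical_threshold(null_rho, config$fdr)
    thresholds[g] <- thr
    cg <- cg[cg$rho > thr, , drop = FALSE]
    if (nrow(cg)) retained_list[[gi]] <- cg
  }
  links <- do.call(rbind, retained_list)
  if (is.null(links)) links <- empty_links
  rownames(links) <- NULL
  report$n_lasso_retained <- n_lasso
  report$n_correlation_retained <- nrow(links)

  # per-sample activation + ABC
  rec_list <- vector("list", 0L)
  if (nrow(links)) {
    e_use <- enh_usage[links$enhancer_id, samples$sample_id, drop = FALSE]
    p_use <- prom_usage[links$gene_id, samples$sample_id, drop = FALSE]
    act <- e_use & p_use
    rec <- links[rep(seq_len(nrow(links)), times = n_samp), , drop = FALSE]
    rec$sample_id <- rep(samples$sample_id, each = nrow(links))
    rec$active <- as.vector(act)
    rec$abc <- 0
    by_gene_rows <- split(seq_len(nrow(links)), links$gene_id)
    for (s in seq_len(n_samp)) {
      sid <- samples$sample_id[s]
      off <- (s - 1L) * nrow(links)
      for (g in names(by_gene_rows)) {
        rows <- by_gene_rows[[g]]
        a_rows <- rows[act[rows, s]]
        if (length(a_rows) == 0L) next
        a_ids <- links$enhancer_id[a_rows]
        sc <- abc_quantify(links[a_rows, , drop = FALSE],
                           stats::setNames(Ae[a_ids, sid], a_ids),
                           Ap[g, sid], params)
        if (length(sc)) rec$abc[off + a_rows] <- as.numeric(sc)
      }
    }
    rownames(rec) <- NULL
    rec_list <- rec
  } else {
    rec_list <- cbind(empty_links[0, ],
                      data.frame(sample_id = character(), active = logical(),
                                 abc = numeric()))
  }
  report$n_active_records <- sum(rec_list$active)

  states <- unique(samples$state)
  networks <- lapply(states, function(st) {
    net <- aggregate_state(rec_list, samples, st)
    if (nrow(net)) {
      m <- match(net$enhancer_id, enh$id)
      net$chrom <- enh$chrom[m]; net$start <- enh$start[m]; net$end <- enh$end[m]
      ml <- match(paste(net$gene_id, net$enhancer_id),
                  paste(links$gene_id, links$enhancer_id))
      net$distance <- links$distance[ml]
      net$beta <- links$beta[ml]; net$rho <- links$rho[ml]
    }
    net
  })
  names(networks) <- states
  report$n_state_edges <- sum(vapply(networks, nrow, 0L))

  structure(list(links = links, records = rec_list, networks = networks,
                 thresholds = thresholds, report = report),
            class = "epi_reconstruction")
}

#' @export
print.epi_reconstruction <- function(x, ...) {
  cat("EPI reconstruction\n")
  cat(sprintf("  candidates: %d; LASSO-retained: %d; correlation-retained: %d\n",
              x$report$n_candidates, x$report$n_lasso_retained,
              x$report$n_correlation_retained))
  cat(sprintf("  states: %d; aggregated edges: %d\n", length(x$networks),
              x$report$n_state_edges))
  invisible(x)
}
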
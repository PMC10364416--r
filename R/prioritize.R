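# EPI-informed SNP-to-gene assignment, gene-level significance per state,
# and expression-specificity filtering of associated genes.

#' Assign GWAS SNPs to genes directly and via EPIs
#'
#' A SNP is assigned to a gene when its position falls in the gene body
#' flanked by 2 kb on both sides (\code{[gene_start - flank, gene_end +
#' flank)}), and additionally when it falls inside an enhancer linked to the
#' gene in the given state network. A SNP may map to multiple genes; within
#' one gene each SNP is counted once (the proximal route wins when both
#' apply).
#'
#' @param variants Variant table (snp_id, chrom, pos).
#' @param promoters Promoter/gene table with \code{gene_start},
#'   \code{gene_end}.
#' @param enhancers Enhancer table.
#' @param network One state's edge table (enhancer_id, gene_id).
#' @param flank Flanking width in bp (default 2000).
#' @return data.frame (gene_id, snp_id, route) with route in
#'   \{"proximal", "distal"\}.
#' @export
assign_snps_to_genes <- function(variants, promoters, enhancers, network,
                                 flank = 2000L) {
  stopifnot(all(c("gene_start", "gene_end") %in% names(promoters)))
  out <- list()
  if (nrow(variants) && nrow(promoters)) {
    vq <- GenomicRanges::GRanges(variants$chrom,
                                 IRanges::IRanges(variants$pos + 1L,
                                                  variants$pos + 1L))
    gs <- GenomicRanges::GRanges(promoters$chrom,
                                 IRanges::IRanges(pmax(1L, promoters$gene_start - flank + 1L),
                                                  promoters$gene_end + flank))
    h <- GenomicRanges::findOverlaps(vq, gs)
    if (length(h)) {
      out$proximal <- data.frame(
        gene_id = promoters$gene_id[S4Vectors::subjectHits(h)],
        snp_id = variants$snp_id[S4Vectors::queryHits(h)],
        route = "proximal", stringsAsFactors = FALSE)
    }
  }
  if (nrow(variants) && nrow(network) && nrow(enhancers)) {
    enh_used <- enhancers[enhancers$id %in% network$enhancer_id, , drop = FALSE]
    if (nrow(enh_used)) {
      vq <- GenomicRanges::GRanges(variants$chrom,
                                   IRanges::IRanges(variants$pos + 1L,
                                                    variants$pos + 1L))
      er <- GenomicRanges::GRanges(enh_used$chrom,
                                   IRanges::IRanges(enh_used$start + 1L,
                                                    enh_used$end))
      h <- GenomicRanges::findOverlaps(vq, er)
      if (length(h)) {
        hit_enh <- enh_used$id[S4Vectors::subjectHits(h)]
        hit_snp <- variants$snp_id[S4Vectors::queryHits(h)]
        edge_genes <- split(network$gene_id, network$enhancer_id)
        genes_per_hit <- edge_genes[hit_enh]
        out$distal <- data.frame(
          gene_id = unlist(genes_per_hit, use.names = FALSE),
          snp_id = rep(hit_snp, lengths(genes_per_hit)),
          route = "distal", stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(gene_id = character(), snp_id = character(),
                      route = character(), stringsAsFactors = FALSE))
  }
  # proximal listed first, so duplicated() keeps the proximal route
  res <- res[!duplicated(paste(res$gene_id, res$snp_id)), , drop = FALSE]
  res <- res[order(res$gene_id, res$snp_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Combine SNP p-values into a gene-level p-value (Fisher's method)
#'
#' \code{X = -2 sum(ln p)} compared against the chi-square distribution with
#' 2k degrees of freedom. SNPs are treated as independent, which holds for
#' the synthetic generator and is a documented approximation for real,
#' LD-structured data.
#'
#' @param p Vector of SNP p-values in (0, 1\] (length >= 1).
#' @return Gene-level p-value.
#' @export
gene_pvalue <- function(p) {
  stopifnot(length(p) >= 1L, all(p > 0), all(p <= 1))
  x <- -2 * sum(log(p))
  stats::pchisq(x, df = 2 * length(p), lower.tail = FALSE)
}

#' Benjamini-Hochberg significance calls for gene-level p-values
#'
#' q-values are computed within the supplied set (one state at a time);
#' significant means q < alpha.
#'
#' @param gene_p Named numeric vector of gene-level p-values.
#' @param state State label attached to the output.
#' @param alpha FDR threshold (default 0.05).
#' @return data.frame (gene_id, state, gene_p, fdr_q, significant).
#' @export
significant_genes <- function(gene_p, state = NA_character_, alpha = 0.05) {
  stopifnot(length(gene_p) >= 1L)
  q <- stats::p.adjust(gene_p, method = "BH")
  out <- data.frame(gene_id = names(gene_p), state = state,
                    gene_p = as.numeric(gene_p), fdr_q = as.numeric(q),
                    significant = q < alpha, stringsAsFactors = FALSE)
  out <- out[order(out$gene_p, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter candidate genes by expression in a state
#'
#' Per sample of the state, a gene qualifies as relatively highly expressed
#' iff its TPM is > 1 and strictly exceeds the median TPM of all other genes
#' in that sample. Qualified sets are union-aggregated across the state's
#' replicate samples; the returned genes are the candidates intersected with
#' this set.
#'
#' @param candidates Character vector of candidate gene ids.
#' @param prom_activity Promoter activity matrix (genes x samples).
#' @param sample_table Sample annotation table.
#' @param state State label (must exist in the sample table).
#' @param tpm_threshold Absolute TPM cutoff (default 1, strict).
#' @param percentile Quantile of the other genes to exceed (default 0.5,
#'   the median).
#' @return Character vector: candidates passing the expression filter.
#' @export
expression_filter <- function(candidates, prom_activity, sample_table, state,
                              tpm_threshold = 1, percentile = 0.5) {
  samp <- sample_table$sample_id[sample_table$state == state]
  if (length(samp) == 0L) stop("state not present in sample table: ", state)
  qualified <- character()
  for (s in samp) {
    v <- prom_activity[, s]
    n <- length(v)
    med_others <- vapply(seq_len(n), function(i) {
      stats::quantile(v[-i], probs = percentile, type = 7, names = FALSE)
    }, numeric(1L))
    ok <- v > tpm_threshold & v > med_others
    qualified <- union(qualified, rownames(prom_activity)[ok])
  }
  intersect(candidates, qualified)
}

#' Full gene prioritization for one state
#'
#' Assigns SNPs to genes (gene body +/- 2 kb plus EPI-routed enhancer SNPs),
#' combines SNP p-values per gene with Fisher's method, applies
#' Benjamini-Hochberg within the state, and flags whether each candidate
#' passes the expression filter. Genes with no assigned SNP are omitted.
#'
#' @param variants Variant table (snp_id, chrom, pos, p).
#' @param promoters Promoter/gene table with gene bodies.
#' @param enhancers Enhancer table.
#' @param network One state's edge table.
#' @param prom_activity Promoter activity matrix.
#' @param sample_table Sample annotation table.
#' @param state State label.
#' @param alpha FDR threshold (default 0.05).
#' @param flank Proximal assignment flank in bp (default 2000).
#' @return data.frame (gene_id, state, n_snps_proximal, n_snps_distal,
#'   gene_p, fdr_q, significant, expressed_pass).
#' @export
prioritize_genes <- function(variants, promoters, enhancers, network,
                             prom_activity, sample_table, state,
                             alpha = 0.05, flank = 2000L) {
  assign <- assign_snps_to_genes(variants, promoters, enhancers, network,
                                 flank = flank)
  if (nrow(assign) == 0L) {
    return(data.frame(gene_id = character(), state = character(),
                      n_snps_proximal = integer(), n_snps_distal = integer(),
                      gene_p = numeric(), fdr_q = numeric(),
                      significant = logical(), expressed_pass = logical(),
                      stringsAsFactors = FALSE))
  }
  pv <- stats::setNames(variants$p, variants$snp_id)
  by_gene <- split(assign, assign$gene_id)
  gene_p <- vapply(by_gene, function(a) gene_pvalue(pv[a$snp_id]), numeric(1L))
  res <- significant_genes(gene_p, state = state, alpha = alpha)
  res$n_snps_proximal <- vapply(by_gene[res$gene_id],
                                function(a) sum(a$route == "proximal"), 0L)
  res$n_snps_distal <- vapply(by_gene[res$gene_id],
                              function(a) sum(a$route == "distal"), 0L)
  expressed <- expression_filter(res$gene_id, prom_activity, sample_table,
                                 state)
  res$expressed_pass <- res$gene_id %in% expressed
  res[, c("gene_id", "state", "n_snps_proximal", "n_snps_distal", "gene_p",
          "fdr_q", "significant", "expressed_pass")]
}

#' Shared associated genes within and between trait categories
#'
#' Counts, per category, the genes associated with at least two of the
#' category's traits, and tests every pairwise trait overlap with Fisher's
#' exact test over the supplied gene universe.
#'
#' @param gene_sets Named list of character vectors (associated genes per
#'   trait).
#' @param categories Named character vector mapping trait -> category.
#' @param universe Gene universe for the Fisher tests.
#' @return List with \code{within} (data.frame category, n_shared,
#'   shared_genes) and \code{pairwise} (data.frame trait_a, trait_b,
#'   category_a, category_b, n_shared, or, p).
#' @export
shared_genes <- function(gene_sets, categories, universe) {
  stopifnot(all(names(gene_sets) %in% names(categories)))
  cats <- unique(categories[names(gene_sets)])
  within <- do.call(rbind, lapply(cats, function(cc) {
    traits <- names(gene_sets)[categories[names(gene_sets)] == cc]
    tabs <- table(unlist(lapply(gene_sets[traits], unique)))
    sh <- sort(names(tabs)[tabs >= 2L])
    data.frame(category = cc, n_shared = length(sh),
               shared_genes = paste(sh, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  traits <- names(gene_sets)
  pw <- NULL
  if (length(traits) >= 2L) {
    combs <- utils::combn(traits, 2L)
    pw <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
      ta <- combs[1L, i]; tb <- combs[2L, i]
      ft <- overlap_fisher(gene_sets[[ta]], gene_sets[[tb]], universe)
      data.frame(trait_a = ta, trait_b = tb,
                 category_a = unname(categories[ta]),
                 category_b = unname(categories[tb]),
                 n_shared = length(intersect(gene_sets[[ta]], gene_sets[[tb]])),
                 or = ft$or, p = ft$p, stringsAsFactors = FALSE)
    }))
  }
  list(within = within, pairwise = pw)
}
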
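test_that("average precision matches hand-computed PR values", {
  universe <- data.frame(enhancer_id = c("e1", "e2"), gene_id = c("g1", "g2"),
                         stringsAsFactors = FALSE)
  truth <- data.frame(enhancer_id = "e2", gene_id = "g2",
                      stringsAsFactors = FALSE)
  # perfect ranking
  pred_good <- data.frame(enhancer_id = c("e2", "e1"), gene_id = c("g2", "g1"),
                          score = c(0.9, 0.1), stringsAsFactors = FALSE)
  expect_equal(aupr_against(pred_good, truth, universe), 1.0)
  # ranking [false, true] -> precision 1/2 at the single true pair
  pred_bad <- data.frame(enhancer_id = c("e1", "e2"), gene_id = c("g1", "g2"),
                         score = c(0.9, 0.1), stringsAsFactors = FALSE)
  expect_equal(aupr_against(pred_bad, truth, universe), 0.5)
  # unscored universe pairs rank last
  expect_equal(aupr_against(pred_good[1, ], truth, universe), 1.0)
  expect_error(aupr_against(pred_good, data.frame(enhancer_id = "ex",
                                                  gene_id = "gx"), universe),
               "undefined recall")
})

test_that("AUPR is invariant to strictly monotone score transforms", {
  set.seed(17)
  universe <- data.frame(enhancer_id = sprintf("e%d", 1:300),
                         gene_id = sprintf("g%d", 1:300),
                         stringsAsFactors = FALSE)
  truth <- universe[sample(300, 60), ]
  pred <- universe
  pred$score <- runif(300)
  a1 <- aupr_against(pred, truth, universe)
  pred2 <- pred; pred2$score <- exp(5 * pred$score)
  expect_equal(aupr_against(pred2, truth, universe), a1)
})

test_that("a random ranker's AUPR approximates the truth prevalence", {
  set.seed(23)
  n <- 2000L
  universe <- data.frame(enhancer_id = sprintf("e%d", seq_len(n)),
                         gene_id = sprintf("g%d", seq_len(n)),
                         stringsAsFactors = FALSE)
  truth <- universe[sample(n, n / 5L), ]  # prevalence 0.2
  auprs <- replicate(50, {
    pred <- universe; pred$score <- runif(n)
    aupr_against(pred, truth, universe)
  })
  expect_lt(abs(mean(auprs) - 0.2), 0.02)
})

test_that("baseline linkers follow their stated rules", {
  geo <- toy_geometry()
  # closest: E_near is 1 Mb from G1, 1.6 Mb from G2 -> G1
  bl <- baseline_links("closest", geo$enhancers[1, ], geo$promoters)
  expect_equal(bl$gene_id, "G1")
  # max_corr picks the promoter with the highest Spearman correlation
  set.seed(2)
  x <- rlnorm(12); samples <- sprintf("s%d", 1:12)
  ea <- matrix(x, 1, dimnames = list("E_near", samples))
  pa <- rbind(G1 = x + rnorm(12, 0, 0.01), G2 = rnorm(12))
  colnames(pa) <- samples
  bl2 <- baseline_links("max_corr", geo$enhancers[1, ], geo$promoters,
                        enh_activity = ea, prom_activity = pa)
  expect_equal(bl2$gene_id, "G1")
  # random: seeded determinism; unlinked enhancers are skipped and counted
  r1 <- baseline_links("random", geo$enhancers, geo$promoters, seed = 6L)
  r2 <- baseline_links("random", geo$enhancers, geo$promoters, seed = 6L)
  expect_identical(r1, r2)
  expect_equal(attr(r1, "n_unlinked"), 1L)  # E_trans has no cis promoter
})

test_that("the enrichment odds ratio follows (a/b)/(c/d)", {
  expect_equal(enrichment_or(10, 5, 100, 100), 2.0)
  expect_equal(enrichment_or(7, 14, 30, 60), 1.0)
  expect_equal(enrichment_or(0, 5, 100, 100), 0.0)
  expect_error(enrichment_or(1, 0, 10, 10), "b")
  expect_error(enrichment_or(1, 5, 0, 10), "c")
})

test_that("QTL enrichment is ~1 for exchangeable variants and reproducible", {
  set.seed(41)
  cre <- data.frame(chrom = "chr1", start = seq(0, 9e5, by = 1e5),
                    end = seq(0, 9e5, by = 1e5) + 2e4)
  baseline <- data.frame(chrom = "chr1", start = 0L, end = 1e6)
  pool <- data.frame(chrom = "chr1", pos = as.integer(runif(20000, 0, 1e6)),
                     maf = runif(20000, 0.01, 0.5))
  qtl <- pool[sample(20000, 500), ]
  res <- qtl_enrichment(qtl, pool, cre, baseline, n_repeats = 30L, seed = 3L)
  expect_lt(abs(res$or_mean - 1), 2 * res$or_sd + 1e-9)
  res2 <- qtl_enrichment(qtl, pool, cre, baseline, n_repeats = 30L, seed = 3L)
  expect_identical(res, res2)
  # planted placement: nearly all QTL inside CREs -> OR >> 1
  inside <- qtl
  inside$pos <- as.integer(runif(500, 1, 19999))
  res3 <- qtl_enrichment(inside, pool, cre, baseline, n_repeats = 10L, seed = 3L)
  expect_gt(res3$or_mean, 5)
  # an occupied MAF bin with no candidate controls is an error naming the bin
  qtl_hi <- qtl; qtl_hi$maf <- 0.499
  pool_lo <- pool; pool_lo$maf <- 0.1
  expect_error(qtl_enrichment(qtl_hi, pool_lo, cre, baseline, seed = 1L),
               "MAF bin")
})

test_that("overlap enrichment matches the closed-form hypergeometric tail", {
  # universe of 10 query-background intervals, 5 hitting the active set,
  # query of 4 with all 4 overlapping: p = C(5,4) C(5,0) / C(10,4) = 5/210
  qbg <- data.frame(chrom = "chr1", start = (0:9) * 1000L,
                    end = (0:9) * 1000L + 100L)
  active <- qbg[1:5, ]
  query <- qbg[1:4, ]
  abg <- active
  res <- overlap_enrichment(query, active, qbg, abg)
  expect_equal(res$p, 5 / 210)
  expect_equal(res$overlap, 4L)
  # identical sets and equal backgrounds give OR 1
  res_id <- overlap_enrichment(active, active, qbg, qbg)
  expect_equal(res_id$or, 1.0)
  # zero overlap: upper-tail p at k = 0 is 1
  far <- data.frame(chrom = "chr2", start = 0L, end = 10L)
  expect_equal(overlap_enrichment(far, active, rbind(qbg, far), abg)$p, 1.0)
  expect_error(overlap_enrichment(query, active, qbg[0, ], abg), "")
})

test_that("overlap enrichment p equals brute-force enumeration on tiny universes", {
  # enumeration oracle: all C(N, n) query choices of a 12-interval universe
  set.seed(55)
  N <- 12L
  qbg <- data.frame(chrom = "chr1", start = (0:(N - 1)) * 1000L,
                    end = (0:(N - 1)) * 1000L + 100L)
  hits_active <- c(1, 3, 4, 7, 9)
  active <- qbg[hits_active, ]
  n <- 5L
  query_rows <- c(1, 3, 5, 7, 11)
  k_obs <- sum(query_rows %in% hits_active)
  combs <- combn(N, n)
  k_all <- apply(combs, 2L, function(rows) sum(rows %in% hits_active))
  p_brute <- mean(k_all >= k_obs)
  res <- overlap_enrichment(qbg[query_rows, ], active, qbg, active)
  expect_equal(res$p, p_brute)
})

test_that("gene-set overlap uses the sample odds ratio and exact p", {
  universe <- sprintf("g%d", 1:100)
  A <- universe[1:10]; B <- universe[6:15]
  # table [[5,5],[5,85]] -> OR (5*85)/(5*5) = 17
  res <- overlap_fisher(A, B, universe)
  expect_equal(res$or, 17.0)
  expect_equal(res$p, fisher.test(matrix(c(5, 5, 5, 85), 2))$p.value)
  # disjoint non-empty sets
  expect_equal(overlap_fisher(universe[1:5], universe[6:10], universe)$or, 0)
  # exact-test oracle on a small universe: enumerate all 6-subsets of the
  # universe and accumulate the probability of tables as or less likely
  uni <- sprintf("x%d", 1:16)
  sa <- uni[1:6]; sb <- uni[c(2, 4, 9, 12)]
  res2 <- overlap_fisher(sa, sb, uni)
  cc <- combn(16, 6)
  ov <- apply(cc, 2L, function(rows) length(intersect(uni[rows], sb)))
  obs <- length(intersect(sa, sb))
  d_obs <- dhyper(obs, 4, 12, 6)
  p_brute <- mean(dhyper(ov, 4, 12, 6) <= d_obs + 1e-12)
  expect_equal(res2$p, p_brute)
})
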
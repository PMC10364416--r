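# Cross-state network similarity and clustering, expression specificity,
# and state-specific element calls.

#' Extended Jaccard (Tanimoto) similarity of two edge-weight vectors
#'
#' \code{f(a, b) = <a, b> / (||a||^2 + ||b||^2 - <a, b>)}, in \[0, 1\] for
#' non-negative vectors; reduces to the binary Jaccard index on 0/1 weights.
#'
#' @param a,b Non-negative numeric vectors of equal length (over a common
#'   edge universe).
#' @return Similarity in \[0, 1\].
#' @export
extended_jaccard <- function(a, b) {
  stopifnot(length(a) == length(b), all(a >= 0), all(b >= 0))
  ab <- sum(a * b)
  denom <- sum(a^2) + sum(b^2) - ab
  if (denom == 0) stop("undefined similarity: both vectors are all-zero")
  ab / denom
}

#' ABC edge-weight vectors of state networks over the global EPI universe
#'
#' The universe is the union of edges over all states, lexicographically
#' ordered by (gene_id, enhancer_id); absent edges weigh 0.
#'
#' @param networks Named list of per-state edge tables (columns
#'   \code{enhancer_id}, \code{gene_id}, \code{abc}).
#' @return Numeric matrix, states x edges, with edge keys as colnames.
#' @export
edge_weight_matrix <- function(networks) {
  stopifnot(length(networks) >= 1L, !is.null(names(networks)))
  keys <- sort(unique(unlist(lapply(networks, function(n) {
    if (nrow(n) == 0L) character() else paste(n$gene_id, n$enhancer_id, sep = "|")
  }))))
  w <- matrix(0, length(networks), length(keys),
              dimnames = list(names(networks), keys))
  for (s in names(networks)) {
    n <- networks[[s]]
    if (nrow(n) == 0L) next
    w[s, paste(n$gene_id, n$enhancer_id, sep = "|")] <- n$abc
  }
  w
}

#' Hierarchical clustering of states by EPI network similarity
#'
#' Computes the pairwise extended-Jaccard similarity of the per-state ABC
#' edge-weight vectors, turns it into the distance 1 - f, and performs
#' agglomerative clustering. Similarities involving an all-zero network are
#' undefined and treated as distance 1 with a warning.
#'
#' @param networks Named list of per-state edge tables (>= 2 states).
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default \code{"average"}).
#' @return List with \code{distance} (symmetric matrix 1 - f), \code{hclust}
#'   (the merge tree) and \code{newick} (the tree serialized as a Newick
#'   string).
#' @export
cluster_states <- function(networks, linkage = "average") {
  stopifnot(length(networks) >= 2L)
  w <- edge_weight_matrix(networks)
  ns <- nrow(w)
  d <- matrix(0, ns, ns, dimnames = list(rownames(w), rownames(w)))
  empty <- rowSums(w^2) == 0
  if (any(empty)) warning("all-zero network(s): ",
                          paste(rownames(w)[empty], collapse = ", "),
                          "; undefined similarities treated as distance 1")
  for (i in seq_len(ns - 1L)) {
    for (j in seq(i + 1L, ns)) {
      d[i, j] <- d[j, i] <- if (empty[i] || empty[j]) 1 else
        1 - extended_jaccard(w[i, ], w[j, ])
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(distance = d, hclust = hc, newick = newick)
}

#' Shannon-entropy expression specificity score
#'
#' \code{S(i) = log2(m) + sum_j p_ij log2 p_ij} with
#' \code{p_ij = y_ij / sum_l y_il} over the m samples; zero entries
#' contribute 0. S ranges from 0 (uniform expression) to log2(m)
#' (single-sample expression); higher means more specific. An all-zero row
#' is undefined and returns NA.
#'
#' @param y Non-negative activity vector over samples.
#' @return Specificity score in \[0, log2(m)\], or NA for an all-zero row.
#' @export
entropy_specificity <- function(y) {
  stopifnot(all(y >= 0))
  tot <- sum(y)
  if (tot == 0) return(NA_real_)
  p <- y / tot
  terms <- ifelse(p > 0, p * log2(p), 0)
  log2(length(y)) + sum(terms)
}

#' Specificity scores for every row of an activity matrix
#' @param mat Activity matrix (elements x samples).
#' @return Named numeric vector of scores (NA for all-zero rows).
#' @export
entropy_specificity_matrix <- function(mat) {
  apply(mat, 1L, entropy_specificity)
}

#' State-specific elements from per-sample activity flags
#'
#' An element (or EPI) is specific to state s iff it is active in more than
#' 50% of s's samples and in fewer than 50% of the samples of every other
#' state (both inequalities strict). An element is therefore specific to at
#' most one state.
#'
#' @param active Logical matrix, elements x samples (usage calls or
#'   per-sample EPI activity flags).
#' @param sample_table Sample annotation mapping every sample to one state.
#' @return data.frame (element_id, state) of specific calls; attribute
#'   \code{"fraction"} carries the elements x states active-fraction matrix.
#' @export
state_specific <- function(active, sample_table) {
  stopifnot(all(colnames(active) %in% sample_table$sample_id))
  states <- unique(sample_table$state)
  frac <- sapply(states, function(s) {
    cols <- sample_table$sample_id[sample_table$state == s]
    cols <- intersect(cols, colnames(active))
    rowMeans(active[, cols, drop = FALSE])
  })
  if (is.null(dim(frac))) frac <- matrix(frac, ncol = length(states),
                                         dimnames = list(rownames(active), states))
  calls <- lapply(states, function(s) {
    others <- setdiff(states, s)
    ok <- frac[, s] > 0.5 &
      apply(frac[, others, drop = FALSE] < 0.5, 1L, all)
    if (!any(ok)) return(NULL)
    data.frame(element_id = rownames(active)[ok], state = s,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  if (is.null(out)) out <- data.frame(element_id = character(),
                                      state = character(),
                                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fraction") <- frac
  out
}
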
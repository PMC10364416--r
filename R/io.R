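# Readers/writers for the external representations the pipeline touches.
# Coordinates are BED-style throughout: 0-based, half-open [start, end).

#' Read CAGE-derived enhancer regions from a BED file
#'
#' Parses a 3+ column BED file into an enhancer table. The 4th column, when
#' present, is used as the element id; otherwise ids default to
#' \code{"chrom:start-end"}. Lines starting with \code{#}, \code{track} or
#' \code{browser} are skipped.
#'
#' @param path Path to a tab-delimited BED file.
#' @return A data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{id}. Coordinates are 0-based half-open.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t600\tE1", "chr2\t5\t15"), bed)
#' read_enhancers(bed)
#' @export
read_enhancers <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      id = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- idx[which(nf < 3L)[1L]]
    stop(sprintf("malformed BED line %d: fewer than 3 fields", bad))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    bad <- idx[which(is.na(start) | is.na(end))[1L]]
    stop(sprintf("malformed BED line %d: non-numeric coordinates", bad))
  }
  if (any(start >= end)) {
    bad <- idx[which(start >= end)[1L]]
    stop(sprintf("invalid interval at line %d: start >= end", bad))
  }
  id <- ifelse(nf >= 4L, vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else "", ""),
               sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end)))
  if (anyDuplicated(id)) {
    stop(sprintf("duplicate enhancer id: %s", id[anyDuplicated(id)]))
  }
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             id = id, stringsAsFactors = FALSE)
}

#' Write enhancer regions to a BED file
#'
#' @param enhancers Enhancer table as returned by [read_enhancers()].
#' @param path Output path.
#' @export
write_enhancers <- function(enhancers, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", enhancers$chrom, enhancers$start,
                     enhancers$end, enhancers$id), path)
  invisible(path)
}

#' Read promoter annotation from a TSS table
#'
#' Expects a tab-delimited file with a header containing at least
#' \code{gene_id}, \code{chrom}, \code{tss}, \code{strand} (optionally
#' \code{gene_start}, \code{gene_end} for gene bodies). One promoter per gene.
#' A symmetric 1 kb window \code{[tss - 500, tss + 500)} is attached; genes
#' on chrY and chrM are removed (the count is available as attribute
#' \code{"n_dropped"}). Windows extending past the chromosome start are
#' clipped at 0 with a warning.
#'
#' @param path Path to the TSV file.
#' @param window_halfwidth Half-width of the promoter window in bp (default
#'   500, giving a 1 kb window).
#' @return A data.frame with columns \code{gene_id}, \code{chrom}, \code{tss},
#'   \code{strand}, \code{win_start}, \code{win_end} and, if present in the
#'   input, \code{gene_start}, \code{gene_end}.
#' @export
read_promoters <- function(path, window_halfwidth = 500L) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("promoter table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$gene_id)) {
    stop("duplicate gene_id in promoter table: ",
         tab$gene_id[anyDuplicated(tab$gene_id)])
  }
  drop <- tab$chrom %in% c("chrY", "chrM", "Y", "M", "MT", "chrMT")
  n_dropped <- sum(drop)
  tab <- tab[!drop, , drop = FALSE]
  tab$win_start <- tab$tss - as.integer(window_halfwidth)
  tab$win_end <- tab$tss + as.integer(window_halfwidth)
  if (any(tab$win_start < 0L)) {
    warning(sprintf("%d promoter window(s) clipped at chromosome start",
                    sum(tab$win_start < 0L)))
    tab$win_start[tab$win_start < 0L] <- 0L
  }
  rownames(tab) <- NULL
  attr(tab, "n_dropped") <- n_dropped
  tab
}

#' Write a promoter annotation table
#' @param promoters Promoter table as returned by [read_promoters()].
#' @param path Output path.
#' @export
write_promoters <- function(promoters, path) {
  keep <- intersect(c("gene_id", "chrom", "tss", "strand", "gene_start", "gene_end"),
                    names(promoters))
  utils::write.table(promoters[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dense activity matrix (elements x samples, TPM)
#'
#' The format is tab-delimited with a header row of sample ids and a first
#' column of element ids, matching FANTOM-style dense activity tables.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix with element ids as rownames and sample ids as
#'   colnames. All values must be finite and non-negative.
#' @export
read_activity_matrix <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) stop("duplicate element id in activity matrix: ",
                               ids[anyDuplicated(ids)])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) stop("duplicate sample id in activity matrix")
  if (any(!is.finite(m)) || any(m < 0)) stop("activity values must be finite and >= 0")
  m
}

#' Write a dense activity matrix
#' @param mat Numeric matrix, elements x samples.
#' @param path Output path.
#' @export
write_activity_matrix <- function(mat, path) {
  df <- data.frame(element_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the sample annotation table
#'
#' Tab-delimited with header \code{sample_id}, \code{state}, \code{group},
#' \code{life_stage}. Every sample maps to exactly one state (cell/tissue
#' type); replicates share a state.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the four columns above.
#' @export
read_sample_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample_id", "state", "group", "life_stage")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("sample table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id in sample table")
  tab
}

#' Write a sample annotation table
#' @param samples Sample table.
#' @param path Output path.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' @param path Path to a bedGraph file (chrom, start, end, value).
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{value}.
#' @export
read_bedgraph <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  tab <- tab[!grepl("^(track|browser)", tab[[1L]]), , drop = FALSE]
  if (ncol(tab) < 4L) stop("bedGraph requires 4 columns")
  out <- data.frame(chrom = as.character(tab[[1L]]), start = as.integer(tab[[2L]]),
                    end = as.integer(tab[[3L]]), value = as.numeric(tab[[4L]]),
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("invalid bedGraph interval: start >= end")
  out
}

#' Quantify promoter activity (TPM) from a coverage track
#'
#' Computes, for each promoter window, the CAGE TPM value: summed read
#' coverage overlapping the window divided by millions of mapped reads.
#' Coverage is summed as value x overlapped width over all track intervals
#' intersecting the window (for single-bp 5'-end tracks this equals the read
#' count in the window); any overlap counts.
#'
#' @param track bedGraph data.frame from [read_bedgraph()].
#' @param promoters Promoter table from [read_promoters()].
#' @param total_mapped_reads Total mapped reads in the library (> 0).
#' @return Named numeric vector of TPM, one entry per promoter gene_id.
#' @export
promoter_tpm_from_coverage <- function(track, promoters, total_mapped_reads) {
  if (!is.numeric(total_mapped_reads) || total_mapped_reads <= 0) {
    stop("total_mapped_reads must be > 0")
  }
  tpm <- stats::setNames(numeric(nrow(promoters)), promoters$gene_id)
  if (nrow(track) > 0L) {
    missing_chrom <- setdiff(promoters$chrom, track$chrom)
    if (length(missing_chrom)) {
      warning("chromosome(s) absent from coverage track: ",
              paste(missing_chrom, collapse = ", "))
    }
    tr <- GenomicRanges::GRanges(track$chrom,
                                 IRanges::IRanges(track$start + 1L, track$end))
    pr <- GenomicRanges::GRanges(promoters$chrom,
                                 IRanges::IRanges(promoters$win_start + 1L,
                                                  promoters$win_end))
    hits <- GenomicRanges::findOverlaps(pr, tr)
    if (length(hits)) {
      ov <- IRanges::pintersect(pr[S4Vectors::queryHits(hits)],
                                tr[S4Vectors::subjectHits(hits)])
      contrib <- track$value[S4Vectors::subjectHits(hits)] * IRanges::width(ov)
      sums <- tapply(contrib, S4Vectors::queryHits(hits), sum)
      tpm[as.integer(names(sums))] <- as.numeric(sums)
    }
  }
  tpm / (total_mapped_reads / 1e6)
}

#' Derive usage calls from an activity matrix
#'
#' An element is "in usage" in a sample iff its TPM is strictly larger than
#' the threshold (default 1 TPM).
#'
#' @param mat Activity matrix (elements x samples).
#' @param threshold TPM threshold (default 1); the inequality is strict.
#' @return Logical matrix with the same dimnames.
#' @export
usage_from_activity <- function(mat, threshold = 1) {
  stopifnot(threshold >= 0)
  mat > threshold
}
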
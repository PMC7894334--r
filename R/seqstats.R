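#' Trim alignment columns by non-gap fraction
#'
#' Retains exactly the columns whose fraction of non-gap characters is at
#' least `gap_threshold` (trimAl `-gt` semantics).
#'
#' @param alignment A character matrix (rows = sequences), a named
#'   character vector of equal-length aligned strings, or a
#'   [Biostrings::XStringSet].
#' @param gap_threshold Minimum non-gap fraction for a column to be kept.
#' @param gap_chars Characters treated as gaps.
#' @return An `alignment_block`: list with `seqs` (character matrix of
#'   retained columns), `kept_columns` (strictly increasing map to the
#'   original column indices) and `n_sites`.
#' @export
trim_columns <- function(alignment, gap_threshold = 0.3,
                         gap_chars = c("-", ".")) {
  m <- .as_aln_matrix(alignment)
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty alignment")
  nongap <- colMeans(!matrix(m %in% gap_chars, nrow(m), ncol(m)))
  keep <- which(nongap >= gap_threshold)
  structure(list(seqs = m[, keep, drop = FALSE],
                 kept_columns = keep,
                 n_sites = length(keep)),
            class = "alignment_block")
}

.as_aln_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  if (inherits(alignment, "XStringSet")) {
    alignment <- stats::setNames(as.character(alignment), names(alignment))
  }
  if (is.character(alignment)) {
    if (length(unique(nchar(alignment))) > 1L) {
      stop("alignment rows must have equal length")
    }
    m <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
    rownames(m) <- names(alignment)
    return(m)
  }
  stop("unsupported alignment representation")
}

#' Percent identity over mutually ungapped columns
#'
#' @param row_a,row_b Equal-length aligned sequences (strings or
#'   character vectors).
#' @param gap_chars Characters treated as gaps.
#' @return Percent identity in `[0, 100]`, or `NA` when no column has a
#'   residue in both rows.
#' @export
pairwise_similarity <- function(row_a, row_b, gap_chars = c("-", ".")) {
  a <- if (length(row_a) == 1L) strsplit(row_a, "")[[1]] else row_a
  b <- if (length(row_b) == 1L) strsplit(row_b, "")[[1]] else row_b
  if (length(a) != length(b)) stop("rows differ in length")
  use <- !(a %in% gap_chars) & !(b %in% gap_chars)
  if (!any(use)) return(NA_real_)
  100 * sum(a[use] == b[use]) / sum(use)
}

#' Per-lineage conserved-region length and similarity
#'
#' For each lineage: the conserved-region length is the column count of
#' the gap-threshold-trimmed member alignment; the similarity is the
#' median percent identity over all unordered member pairs, computed on
#' the trimmed columns.
#'
#' @param partition A `lineage_partition`.
#' @param alignment Protein alignment covering the partition's genes
#'   (names = gene ids); per-lineage sub-alignments are extracted and
#'   trimmed independently.
#' @param gap_threshold Passed to [trim_columns()].
#' @return data.frame `lineage_id`, `n`, `conserved_len`,
#'   `median_similarity` (`NA` for single-member lineages).
#' @export
lineage_conservation_stats <- function(partition, alignment,
                                       gap_threshold = 0.3) {
  m <- .as_aln_matrix(alignment)
  ids <- partition$lineages$lineage_id
  out <- lapply(ids, function(lid) {
    genes <- partition$assignment$gene_id[
      partition$assignment$lineage_id == lid]
    genes <- intersect(genes, rownames(m))
    if (length(genes) == 0L) {
      return(data.frame(lineage_id = lid, n = 0L,
                        conserved_len = NA_integer_,
                        median_similarity = NA_real_))
    }
    sub <- m[genes, , drop = FALSE]
    tb <- trim_columns(sub, gap_threshold)
    sim <- NA_real_
    if (length(genes) >= 2L) {
      prs <- utils::combn(length(genes), 2)
      sims <- vapply(seq_len(ncol(prs)), function(k) {
        pairwise_similarity(tb$seqs[prs[1, k], ], tb$seqs[prs[2, k], ])
      }, numeric(1))
      sim <- stats::median(sims, na.rm = TRUE)
    }
    data.frame(lineage_id = lid, n = length(genes),
               conserved_len = tb$n_sites, median_similarity = sim)
  })
  do.call(rbind, out)
}

#' Protein length summary
#'
#' @param x Path to a protein FASTA file, a [Biostrings::AAStringSet], or
#'   a numeric vector of lengths.
#' @param short_threshold Count of sequences strictly shorter than this.
#' @return List `n`, `min`, `max`, `median` (mean-of-central-pair for
#'   even n) and `n_short`.
#' @export
length_summary <- function(x, short_threshold = 100) {
  len <- if (is.numeric(x)) {
    x
  } else if (inherits(x, "XStringSet")) {
    Biostrings::width(x)
  } else {
    aa <- Biostrings::readAAStringSet(x)
    if (length(aa) == 0L) stop("empty FASTA: ", x)
    Biostrings::width(aa)
  }
  if (length(len) == 0L) stop("no sequences")
  list(n = length(len), min = min(len), max = max(len),
       median = stats::median(len),
       n_short = sum(len < short_threshold))
}
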
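#' Read a species-to-clade map
#'
#' Tab-separated file with a header line and columns `species_id`,
#' `clade`.  Clade labels are free-form but a declared alphabet can be
#' enforced.
#'
#' @param file Path to a TSV file.
#' @param alphabet Allowed clade labels, or `NULL` for no check.
#' @return Named character vector: `clade_map[species] -> clade`.
#' @export
read_clade_map <- function(file, alphabet = NULL) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("species_id", "clade")
  if (!all(need %in% names(df))) {
    stop("clade map must have columns: ", paste(need, collapse = ", "))
  }
  as_clade_map(stats::setNames(df$clade, df$species_id), alphabet)
}

#' Validate a clade map
#'
#' @param x Named character vector species -> clade.
#' @param alphabet Allowed clade labels, or `NULL`.
#' @return The validated map.
#' @export
as_clade_map <- function(x, alphabet = NULL) {
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("clade map must be a named vector (names = species ids)")
  }
  if (anyDuplicated(names(x))) {
    stop("duplicated species in clade map: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  }
  if (!is.null(alphabet) && !all(x %in% alphabet)) {
    stop("clade labels outside the declared alphabet: ",
         paste(setdiff(unique(x), alphabet), collapse = ", "))
  }
  x
}

#' Read gene loci from BED or GFF3
#'
#' Coordinates are stored 0-based half-open internally; GFF3's 1-based
#' inclusive coordinates are converted at the boundary.  Gene order ranks
#' are assigned per chromosome by start coordinate.
#'
#' @param file Path to a 6-column BED file or a GFF3 file (`.gff`,
#'   `.gff3`); gene ids are taken from the BED name column or the GFF3
#'   `ID` attribute of `gene` features.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `rank` (1-based order along each chromosome).
#' @export
read_gene_loci <- function(file, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", file, ignore.case = TRUE)) "gff3" else "bed"
  }
  if (format == "bed") {
    df <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE,
                            comment.char = "#")
    if (ncol(df) < 6L) stop("BED input needs 6 columns (chrom..strand)")
    loci <- data.frame(gene_id = df[[4]], chrom = df[[1]],
                       start = df[[2]], end = df[[3]], strand = df[[6]],
                       stringsAsFactors = FALSE)
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GFF3 requires the rtracklayer package")
    }
    gr <- rtracklayer::import(file, format = "gff3")
    gr <- gr[gr$type == "gene"]
    loci <- data.frame(
      gene_id = as.character(gr$ID),
      chrom   = as.character(GenomicRanges::seqnames(gr)),
      start   = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
      end     = GenomicRanges::end(gr),
      strand  = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE
    )
  }
  as_gene_loci(loci)
}

#' Validate a gene locus table and (re)assign ranks
#'
#' @param loci data.frame with columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand` (`rank` is recomputed).
#' @return Validated data.frame with a `rank` column, unique per
#'   chromosome.
#' @export
as_gene_loci <- function(loci) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(loci))) {
    stop("locus table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(loci$start >= loci$end)) {
    bad <- loci$gene_id[loci$start >= loci$end]
    stop("start must be < end (0-based half-open); offending genes: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (anyDuplicated(loci$gene_id)) {
    stop("duplicated gene ids in locus table")
  }
  loci <- loci[order(loci$chrom, loci$start), , drop = FALSE]
  loci$rank <- stats::ave(loci$start, loci$chrom,
                          FUN = function(x) seq_along(x))
  rownames(loci) <- NULL
  loci
}

#' Read homolog pairs from BLAST tabular output
#'
#' Uses columns 1 (query), 2 (subject) and 11 (E-value) of the standard
#' 12-column `-outfmt 6` layout; a two- or three-column TSV (optionally
#' with a header `gene_a  gene_b  evalue`) is also accepted.
#'
#' @param file Path.
#' @param e_value_max Pairs with a larger E-value are dropped.
#' @return data.frame `gene_a`, `gene_b`, `evalue`, unordered unique
#'   pairs, self-hits removed.
#' @export
read_homolog_pairs <- function(file, e_value_max = Inf) {
  first <- readLines(file, n = 1L)
  header <- grepl("gene_a", first, fixed = TRUE)
  df <- utils::read.delim(file, header = header, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) >= 11L) {
    pairs <- data.frame(gene_a = df[[1]], gene_b = df[[2]],
                        evalue = as.numeric(df[[11]]),
                        stringsAsFactors = FALSE)
  } else if (ncol(df) >= 2L) {
    pairs <- data.frame(gene_a = df[[1]], gene_b = df[[2]],
                        evalue = if (ncol(df) >= 3L) as.numeric(df[[3]]) else 0,
                        stringsAsFactors = FALSE)
  } else {
    stop("homolog pair table needs at least 2 columns")
  }
  as_homolog_pairs(pairs, e_value_max)
}

#' Validate homolog pairs
#'
#' @param pairs data.frame `gene_a`, `gene_b` and optional `evalue`.
#' @param e_value_max Admission threshold.
#' @return Canonicalised (sorted within pair), de-duplicated data.frame.
#' @export
as_homolog_pairs <- function(pairs, e_value_max = Inf) {
  if (is.null(pairs$evalue)) pairs$evalue <- 0
  if (any(pairs$evalue < 0)) stop("E-values must be >= 0")
  pairs <- pairs[pairs$gene_a != pairs$gene_b, , drop = FALSE]
  pairs <- pairs[pairs$evalue <= e_value_max, , drop = FALSE]
  a <- pmin(pairs$gene_a, pairs$gene_b)
  b <- pmax(pairs$gene_a, pairs$gene_b)
  pairs$gene_a <- a
  pairs$gene_b <- b
  key <- paste(a, b, sep = "\r")
  pairs <- pairs[order(key, pairs$evalue), , drop = FALSE]
  pairs <- pairs[!duplicated(paste(pairs$gene_a, pairs$gene_b, sep = "\r")), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}
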
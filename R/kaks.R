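# Nei-Gojobori (1986) synonymous / nonsynonymous substitution counting
# with Jukes-Cantor multiple-hit correction.

.kaks_env <- new.env(parent = emptyenv())

.gencode <- function() {
  if (is.null(.kaks_env$gc)) .kaks_env$gc <- Biostrings::GENETIC_CODE
  .kaks_env$gc
}

.NUC <- c("A", "C", "G", "T")

# synonymous site count of one codon: per position, the fraction of the
# three possible changes that preserve the amino acid; changes creating a
# stop codon count as nonsynonymous
.codon_syn_sites <- function(codon) {
  if (is.null(.kaks_env$syn_sites)) {
    gc <- .gencode()
    tab <- vapply(names(gc), function(cod) {
      aa <- gc[[cod]]
      split <- strsplit(cod, "")[[1]]
      s <- 0
      for (p in 1:3) {
        for (nt in setdiff(.NUC, split[p])) {
          alt <- split
          alt[p] <- nt
          alt_aa <- gc[[paste(alt, collapse = "")]]
          if (alt_aa == aa && alt_aa != "*") s <- s + 1 / 3
        }
      }
      s
    }, numeric(1))
    .kaks_env$syn_sites <- tab
  }
  .kaks_env$syn_sites[[codon]]
}

# pathway-averaged (syn, nonsyn) differences between two codons;
# pathways passing through stop codons are excluded (all pathways used
# if every one is blocked)
.codon_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(0, 0))
  gc <- .gencode()
  s1 <- strsplit(c1, "")[[1]]
  s2 <- strsplit(c2, "")[[1]]
  pos <- which(s1 != s2)
  paths <- .perms(pos)
  tally <- matrix(NA_real_, length(paths), 2)
  for (k in seq_along(paths)) {
    cur <- s1
    sd <- nd <- 0
    ok <- TRUE
    for (p in paths[[k]]) {
      nxt <- cur
      nxt[p] <- s2[p]
      from <- paste(cur, collapse = "")
      to <- paste(nxt, collapse = "")
      if (gc[[to]] == "*" && to != paste(s2, collapse = "")) {
        ok <- FALSE
        break
      }
      if (gc[[from]] == gc[[to]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) tally[k, ] <- c(sd, nd)
  }
  if (all(is.na(tally[, 1]))) {  # every pathway blocked by a stop
    tally <- matrix(NA_real_, length(paths), 2)
    for (k in seq_along(paths)) {
      cur <- s1
      sd <- nd <- 0
      for (p in paths[[k]]) {
        nxt <- cur
        nxt[p] <- s2[p]
        if (gc[[paste(cur, collapse = "")]] == gc[[paste(nxt, collapse = "")]]) {
          sd <- sd + 1
        } else {
          nd <- nd + 1
        }
        cur <- nxt
      }
      tally[k, ] <- c(sd, nd)
    }
  }
  colMeans(tally, na.rm = TRUE)
}

.perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

.split_codons <- function(x, label) {
  s <- toupper(if (inherits(x, "DNAString") || inherits(x, "DNAStringSet")) {
    as.character(x)
  } else {
    x
  })
  if (nchar(s) %% 3 != 0) {
    stop(label, ": length ", nchar(s), " not divisible by 3")
  }
  substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
}

#' Raw Nei-Gojobori substitution counts for a CDS pair
#'
#' Per-codon synonymous/nonsynonymous site fractions and
#' pathway-averaged substitution counts (multi-hit codons average over
#' all substitution orders, excluding pathways through stop codons).
#' Codons containing a gap or ambiguity character in either sequence are
#' skipped.
#'
#' @param cds_a,cds_b In-frame CDS of equal length (strings or
#'   [Biostrings::DNAString]).
#' @return List `S`, `N` (site counts, averaged between the sequences),
#'   `Sd`, `Nd` (substitution counts), `n_codons` (codons used).
#' @export
ng86_counts <- function(cds_a, cds_b) {
  ca <- .split_codons(cds_a, "cds_a")
  cb <- .split_codons(cds_b, "cds_b")
  if (length(ca) != length(cb)) stop("CDS lengths differ")
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  gc <- .gencode()
  # terminal stop codons are dropped; internal stops are an error
  last <- length(ca)
  if (clean[last] && (gc[[ca[last]]] == "*" || gc[[cb[last]]] == "*")) {
    clean[last] <- FALSE
  }
  idx <- which(clean)
  stops <- idx[vapply(idx, function(i) {
    gc[[ca[i]]] == "*" || gc[[cb[i]]] == "*"
  }, logical(1))]
  if (length(stops) > 0L) {
    stop("internal stop codon at codon index ", stops[1L])
  }
  # memoized per-codon sites and per-codon-pair pathway-averaged diffs
  .codon_syn_sites("AAA")
  if (is.null(.kaks_env$diff_sd)) {
    cods <- names(gc)
    sd_m <- matrix(0, 64, 64, dimnames = list(cods, cods))
    nd_m <- sd_m
    for (i1 in 1:64) {
      for (i2 in 1:64) {
        if (i1 != i2) {
          d <- .codon_diffs(cods[i1], cods[i2])
          sd_m[i1, i2] <- d[1]
          nd_m[i1, i2] <- d[2]
        }
      }
    }
    .kaks_env$diff_sd <- sd_m
    .kaks_env$diff_nd <- nd_m
  }
  sa <- .kaks_env$syn_sites[ca[idx]]
  sb <- .kaks_env$syn_sites[cb[idx]]
  S <- sum((sa + sb) / 2)
  N <- 3 * length(idx) - S
  pk <- cbind(ca[idx], cb[idx])
  Sd <- sum(.kaks_env$diff_sd[pk])
  Nd <- sum(.kaks_env$diff_nd[pk])
  list(S = S, N = N, Sd = Sd, Nd = Nd, n_codons = length(idx))
}

#' Ka/Ks for a pair of coding sequences (NG86 + Jukes-Cantor)
#'
#' Substitutions are counted by the Nei-Gojobori (1986) pathway method
#' ([ng86_counts()]) and corrected for multiple hits with the
#' Jukes-Cantor transform `d = -(3/4) log(1 - 4p/3)`.
#'
#' @inheritParams ng86_counts
#' @return A `kaks_result`: list `ka`, `ks`, `ratio`, `pn`, `ps`,
#'   `saturated` (`TRUE` when a proportion reached the JC ceiling
#'   p >= 3/4; the corresponding distance is `NA`), plus the raw counts.
#'   `ratio` is `NA` when `ks` is 0 or undefined.
#' @export
ka_ks <- function(cds_a, cds_b) {
  cnt <- ng86_counts(cds_a, cds_b)
  if (cnt$n_codons == 0L) stop("no usable codons")
  pn <- cnt$Nd / cnt$N
  ps <- cnt$Sd / cnt$S
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  ka <- jc(pn)
  ks <- jc(ps)
  ratio <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  structure(list(ka = ka, ks = ks, ratio = ratio, pn = pn, ps = ps,
                 saturated = is.na(ka) || is.na(ks),
                 S = cnt$S, N = cnt$N, Sd = cnt$Sd, Nd = cnt$Nd,
                 n_codons = cnt$n_codons),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("Ka = %.4f  Ks = %.4f  Ka/Ks = %s  (%d codons)\n",
              x$ka, x$ks,
              if (is.na(x$ratio)) "undefined" else sprintf("%.3f", x$ratio),
              x$n_codons))
  invisible(x)
}

#' Ka/Ks for within-lineage homolog pairs of two species
#'
#' For every lineage containing genes from both species, all interspecies
#' gene pairs are scored.
#'
#' @param partition A `lineage_partition`.
#' @param cds Named CDS collection (list/character vector/
#'   [Biostrings::DNAStringSet]; names = gene ids).  Sequences must form
#'   a codon alignment (equal length, in frame).
#' @param species_a,species_b The two species compared.
#' @return data.frame `lineage_id`, `gene_a`, `gene_b`, `ka`, `ks`,
#'   `ratio`, `saturated`.
#' @export
lineage_kaks <- function(partition, cds, species_a, species_b) {
  if (inherits(cds, "DNAStringSet")) {
    cds <- stats::setNames(as.character(cds), names(cds))
  }
  asg <- partition$assignment
  rows <- list()
  for (lid in partition$lineages$lineage_id) {
    ga <- asg$gene_id[asg$lineage_id == lid & asg$species_id == species_a]
    gb <- asg$gene_id[asg$lineage_id == lid & asg$species_id == species_b]
    ga <- intersect(ga, names(cds))
    gb <- intersect(gb, names(cds))
    for (a in ga) {
      for (b in gb) {
        r <- ka_ks(cds[[a]], cds[[b]])
        rows[[length(rows) + 1L]] <- data.frame(
          lineage_id = lid, gene_a = a, gene_b = b,
          ka = r$ka, ks = r$ks, ratio = r$ratio, saturated = r$saturated,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(lineage_id = character(0), gene_a = character(0),
                      gene_b = character(0), ka = numeric(0),
                      ks = numeric(0), ratio = numeric(0),
                      saturated = logical(0)))
  }
  do.call(rbind, rows)
}
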
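# Binding-cluster calling from aligned PAR-CLIP reads, preferred crosslink
# sites, cross-replicate consensus pairing, and boundary density profiles.

#' Call binding clusters from aligned PAR-CLIP reads
#'
#' Maximal sets of transitively overlapping same-strand reads are merged into
#' one cluster each; per-position T-to-C conversion counts are tallied and
#' the preferred crosslink site (the position with the highest conversion
#' count, leftmost on ties) is computed. Clusters with fewer than `min_reads`
#' reads or fewer than `min_conversions` converted positions-worth of
#' evidence are dropped. PCR duplicates (identical chrom/start/end/strand and
#' conversion set) are collapsed first by default.
#'
#' @param reads data.frame with `chrom`, `start`, `end`, `strand` (0-based
#'   half-open) and list-column `conv` of 0-based conversion positions; all
#'   reads are assumed uniquely mapped.
#' @param min_reads minimum reads per cluster (default 2).
#' @param min_converted minimum converted reads per cluster (default 1).
#' @param collapse_duplicates drop PCR-duplicate reads first.
#' @return data.frame of clusters: `cluster_id`, `chrom`, `start`, `end`,
#'   `strand`, `n_reads`, `n_converted_reads`, `crosslink`, `score`, plus
#'   list-column `conv` (named per-position conversion counts) and an
#'   attribute `read_cluster` mapping retained read row -> cluster_id.
#' @export
call_clusters <- function(reads, min_reads = 2L, min_converted = 1L,
                          collapse_duplicates = TRUE) {
  stopifnot(all(c("chrom", "start", "end", "strand", "conv") %in% names(reads)))
  conv <- reads$conv
  bad <- mapply(function(cv, s, e) length(cv) > 0L && (min(cv) < s || max(cv) >= e),
                conv, reads$start, reads$end)
  if (any(bad)) {
    stop(sum(bad), " read(s) carry conversions outside their interval")
  }
  if (collapse_duplicates) {
    key <- paste(reads$chrom, reads$start, reads$end, reads$strand,
                 vapply(conv, paste, character(1), collapse = ","), sep = "|")
    keep <- !duplicated(key)
    reads <- reads[keep, , drop = FALSE]
    conv <- conv[keep]
  }
  n <- nrow(reads)
  empty <- data.frame(
    cluster_id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), n_reads = integer(),
    n_converted_reads = integer(), crosslink = integer(), score = numeric(),
    stringsAsFactors = FALSE
  )
  if (n == 0L) { empty$conv <- list(); return(empty) }

  gr <- as_granges0(reads$chrom, reads$start, reads$end, reads$strand)
  # min.gapwidth = 0: abutting reads do not overlap under half-open coords
  cl <- GenomicRanges::reduce(gr, ignore.strand = FALSE, min.gapwidth = 0L)
  h <- GenomicRanges::findOverlaps(gr, cl, ignore.strand = FALSE)
  member <- S4Vectors::subjectHits(h)[order(S4Vectors::queryHits(h))]

  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(cl)),
    start = GenomicRanges::start(cl) - 1L,
    end = GenomicRanges::end(cl),
    strand = as.character(GenomicRanges::strand(cl)),
    stringsAsFactors = FALSE
  )
  out$n_reads <- as.integer(tabulate(member, nbins = nrow(out)))
  converted <- vapply(conv, function(cv) length(cv) > 0L, logical(1))
  out$n_converted_reads <- as.integer(
    tabulate(member[converted], nbins = nrow(out)))

  conv_tab <- vector("list", nrow(out))
  cpos <- unlist(conv, use.names = FALSE)
  ccl <- rep(member, lengths(conv))
  if (length(cpos) > 0L) {
    agg <- split(cpos, ccl)
    for (nm in names(agg)) {
      tb <- table(agg[[nm]])
      v <- as.integer(tb)
      names(v) <- names(tb)
      conv_tab[[as.integer(nm)]] <- v
    }
  }
  out$crosslink <- vapply(conv_tab, function(v) {
    if (is.null(v) || length(v) == 0L) return(NA_integer_)
    preferred_crosslink_site(v)
  }, integer(1))
  out$score <- cluster_score(out$n_converted_reads)
  out$conv <- conv_tab

  keep <- out$n_reads >= min_reads & out$n_converted_reads >= min_converted
  out <- out[keep, , drop = FALSE]
  if (nrow(out) == 0L) { empty$conv <- list(); return(empty) }
  # deterministic order, stable ids
  o <- order(out$chrom, out$start, out$strand)
  out <- out[o, , drop = FALSE]
  out$cluster_id <- sprintf("c%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  old2new <- stats::setNames(out$cluster_id, which(keep)[o])
  out <- out[, c("cluster_id", "chrom", "start", "end", "strand", "n_reads",
                 "n_converted_reads", "crosslink", "score", "conv")]
  attr(out, "read_cluster") <- unname(old2new[as.character(member)])
  out
}

#' Preferred crosslink site of a conversion-count map
#'
#' The position with the highest T-to-C conversion count; ties are broken by
#' the smallest genomic coordinate.
#'
#' @param conv named integer vector (names = 0-based positions, values =
#'   conversion counts); must be non-empty.
#' @return Integer position.
#' @export
preferred_crosslink_site <- function(conv) {
  if (length(conv) == 0L) stop("empty conversion map (cluster should have been filtered)")
  pos <- as.integer(names(conv))
  o <- order(pos)
  pos <- pos[o]; cnt <- as.integer(conv)[o]
  pos[which.max(cnt)]
}

#' Cluster binding score
#'
#' Default score: `log2(1 + n_converted_reads)`, monotone in the converted
#' read count. The score definition is a stated stand-in - the quantity it
#' proxies is not standardised.
#'
#' @param n_converted_reads integer vector.
#' @return Numeric scores.
#' @export
cluster_score <- function(n_converted_reads) {
  log2(1 + n_converted_reads)
}

#' Pair replicate clusters into consensus clusters
#'
#' A consensus cluster is a reciprocal pair: replicate 1's preferred
#' crosslink lies inside the replicate 2 cluster and vice versa (same chrom
#' and strand). A cluster participating in several reciprocal pairs is
#' resolved greedily to the pair with the smallest crosslink distance. The
#' consensus crosslink is adopted from replicate 1; the consensus score is
#' the mean of the two cluster scores.
#'
#' @param rep1,rep2 cluster tables from [call_clusters()] run with identical
#'   parameters.
#' @return data.frame: `chrom`, `strand`, `crosslink`, `start`, `end` (the
#'   replicate-1 interval), `rep1_id`, `rep2_id`, `crosslink2`, `score`.
#' @export
consensus_clusters <- function(rep1, rep2) {
  empty <- data.frame(
    chrom = character(), strand = character(), crosslink = integer(),
    start = integer(), end = integer(), rep1_id = character(),
    rep2_id = character(), crosslink2 = integer(), score = numeric(),
    stringsAsFactors = FALSE
  )
  if (nrow(rep1) == 0L || nrow(rep2) == 0L) return(empty)
  x1 <- points_granges0(rep1$chrom, rep1$crosslink, rep1$strand)
  g2 <- as_granges0(rep2$chrom, rep2$start, rep2$end, rep2$strand)
  h12 <- GenomicRanges::findOverlaps(x1, g2, ignore.strand = FALSE)
  i1 <- S4Vectors::queryHits(h12)
  i2 <- S4Vectors::subjectHits(h12)
  # reciprocal test: rep2 crosslink inside rep1 interval
  ok <- rep2$crosslink[i2] >= rep1$start[i1] &
        rep2$crosslink[i2] < rep1$end[i1]
  i1 <- i1[ok]; i2 <- i2[ok]
  if (length(i1) == 0L) return(empty)
  d <- abs(rep1$crosslink[i1] - rep2$crosslink[i2])
  o <- order(d, rep1$cluster_id[i1], rep2$cluster_id[i2])
  i1 <- i1[o]; i2 <- i2[o]
  used1 <- logical(nrow(rep1)); used2 <- logical(nrow(rep2))
  keep <- logical(length(i1))
  for (k in seq_along(i1)) {
    if (!used1[i1[k]] && !used2[i2[k]]) {
      keep[k] <- TRUE
      used1[i1[k]] <- TRUE
      used2[i2[k]] <- TRUE
    }
  }
  i1 <- i1[keep]; i2 <- i2[keep]
  out <- data.frame(
    chrom = rep1$chrom[i1], strand = rep1$strand[i1],
    crosslink = rep1$crosslink[i1],
    start = rep1$start[i1], end = rep1$end[i1],
    rep1_id = rep1$cluster_id[i1], rep2_id = rep2$cluster_id[i2],
    crosslink2 = rep2$crosslink[i2],
    score = (rep1$score[i1] + rep2$score[i2]) / 2,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Positional density profile around exon/intron boundaries
#'
#' Accumulates transcript-oriented offsets of item positions (cluster
#' crosslinks, read positions, ...) around every annotated boundary of the
#' requested kind and normalises to density per boundary. For
#' `which = "exon_intron"` the anchor (offset 0) is the first intronic base
#' of each intron (5' splice site); negative offsets are exonic. For
#' `which = "intron_exon"` the anchor is the first exonic base after each
#' intron; negative offsets are intronic, so a binding site 70 nt upstream
#' of a 3' splice site appears at offset -70.
#'
#' @param positions data.frame with `chrom`, `pos` (0-based), `strand`.
#' @param genes a [gene_set()].
#' @param window nt flank on each side (>= 1).
#' @param which boundary kind.
#' @return data.frame with `offset` (-window..window), `count` and `density`
#'   (= count / number of boundaries).
#' @export
boundary_density_profile <- function(positions, genes, window = 300L,
                                     which = c("intron_exon", "exon_intron")) {
  which <- match.arg(which)
  stopifnot(window >= 1L, inherits(genes, "gene_set"))
  intr <- genes$introns
  offs <- seq.int(-window, window)
  out <- data.frame(offset = offs, count = 0L, density = 0)
  if (nrow(intr) == 0L) {
    warning("no boundaries in annotation; empty profile")
    return(out)
  }
  plus <- intr$strand == "+"
  anchor <- if (which == "exon_intron") {
    ifelse(plus, intr$start, intr$end - 1L)        # first intronic base
  } else {
    ifelse(plus, intr$end, intr$start - 1L)        # first exonic base after
  }
  n_bound <- nrow(intr)
  if (nrow(positions) == 0L) return(out)
  pts <- points_granges0(positions$chrom, positions$pos, positions$strand)
  wins <- as_granges0(intr$chrom, anchor - window, anchor + window + 1L,
                      intr$strand)
  h <- GenomicRanges::findOverlaps(pts, wins, ignore.strand = FALSE)
  if (length(h) == 0L) return(out)
  qi <- S4Vectors::queryHits(h)
  si <- S4Vectors::subjectHits(h)
  off <- ifelse(plus[si],
                positions$pos[qi] - anchor[si],
                anchor[si] - positions$pos[qi])
  cnt <- tabulate(off + window + 1L, nbins = 2L * window + 1L)
  out$count <- as.integer(cnt)
  out$density <- cnt / n_bound
  out
}
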
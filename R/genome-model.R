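# Gene/exon/intron models, annotation I/O and region classification.
#
# Coordinates are 0-based half-open on the genomic (+) axis throughout the
# package; BED is native, GTF is converted on read. Exons of a model are kept
# in transcription order (ascending genomic start on '+', descending on '-'),
# and intron i is the gap between transcript exons i and i+1.

#' Construct a gene-model set from an exon table
#'
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (one row per exon, 0-based half-open coordinates). Any row order
#'   is accepted; exons of one model must share chrom and strand and must not
#'   overlap.
#' @return An object of class `gene_set`: a list with data.frames `genes`
#'   (gene_id, chrom, strand, start, end, n_exons), `exons` (plus
#'   `exon_index`, transcription order, 1-based) and `introns` (plus
#'   `intron_index`; intron i lies between transcript exons i and i+1).
#' @export
gene_set <- function(exons) {
  req <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(req %in% names(exons))) {
    stop("exon table must have columns: ", paste(req, collapse = ", "))
  }
  exons <- as.data.frame(exons)[, req]
  exons$gene_id <- as.character(exons$gene_id)
  exons$chrom <- as.character(exons$chrom)
  exons$strand <- as.character(exons$strand)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(!exons$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(exons$start < 0L) || any(exons$start >= exons$end)) {
    stop("exons must satisfy 0 <= start < end")
  }

  parts <- split(exons, exons$gene_id)
  ex_list <- vector("list", length(parts))
  in_list <- vector("list", length(parts))
  gn_list <- vector("list", length(parts))
  for (k in seq_along(parts)) {
    ex <- parts[[k]]
    if (length(unique(ex$chrom)) != 1L || length(unique(ex$strand)) != 1L) {
      stop("gene ", ex$gene_id[1], ": exons span multiple chrom/strand")
    }
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)])) {
      stop("gene ", ex$gene_id[1], ": overlapping exons")
    }
    minus <- ex$strand[1] == "-"
    if (minus) ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    ex$exon_index <- seq_len(nrow(ex))
    ex_list[[k]] <- ex
    n <- nrow(ex)
    if (n > 1L) {
      i <- seq_len(n - 1L)
      if (minus) {
        istart <- ex$end[i + 1L]
        iend <- ex$start[i]
      } else {
        istart <- ex$end[i]
        iend <- ex$start[i + 1L]
      }
      in_list[[k]] <- data.frame(
        gene_id = ex$gene_id[1], chrom = ex$chrom[1],
        start = istart, end = iend, strand = ex$strand[1],
        intron_index = i, stringsAsFactors = FALSE
      )
    }
    gn_list[[k]] <- data.frame(
      gene_id = ex$gene_id[1], chrom = ex$chrom[1], strand = ex$strand[1],
      start = min(ex$start), end = max(ex$end), n_exons = n,
      stringsAsFactors = FALSE
    )
  }
  genes <- do.call(rbind, gn_list)
  ord <- order(genes$chrom, genes$start, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  exons <- do.call(rbind, ex_list[ord])
  introns <- do.call(rbind, in_list[ord][!vapply(in_list[ord], is.null, TRUE)])
  rownames(genes) <- rownames(exons) <- NULL
  if (!is.null(introns)) rownames(introns) <- NULL
  exons$exon_id <- paste0(exons$gene_id, ":E", exons$exon_index)
  if (!is.null(introns)) {
    introns$intron_id <- paste0(introns$gene_id, ":I", introns$intron_index)
  } else {
    introns <- data.frame(
      gene_id = character(), chrom = character(), start = integer(),
      end = integer(), strand = character(), intron_index = integer(),
      intron_id = character(), stringsAsFactors = FALSE
    )
  }
  structure(list(genes = genes, exons = exons, introns = introns),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set:", nrow(x$genes), "gene models,", nrow(x$exons), "exons,",
      nrow(x$introns), "introns\n")
  invisible(x)
}

#' Load gene models from GTF or BED12
#'
#' Builds one gene model per transcript. GTF exon records are grouped by
#' `transcript_id` (falling back to `gene_id`); BED12 blocks become exons.
#' Zero-length exon blocks are rejected with a warning. Models come back in a
#' deterministic (chrom, start, gene_id) order.
#'
#' @param path file path.
#' @param format "auto" (by extension), "gtf" or "bed12".
#' @return A [gene_set()].
#' @export
load_annotation <- function(path, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "bed12"
  }
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[!is.na(gr$type) & gr$type == "exon"]
    if (length(gr) == 0L) stop("no exon records in GTF: ", path)
    id <- as.character(gr$transcript_id %||% gr$gene_id)
    if (all(is.na(id))) id <- as.character(gr$gene_id)
    ex <- data.frame(
      gene_id = id,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE
    )
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    nm <- gr$name %||% paste0("feature_", seq_along(gr))
    if (!is.null(gr$blocks)) {
      bl <- gr$blocks
      nblock <- S4Vectors::elementNROWS(bl)
      off <- rep(GenomicRanges::start(gr) - 1L, nblock)
      rel <- unlist(bl, use.names = FALSE)
      ex <- data.frame(
        gene_id = rep(as.character(nm), nblock),
        chrom = rep(as.character(GenomicRanges::seqnames(gr)), nblock),
        start = off + IRanges::start(rel) - 1L,
        end = off + IRanges::end(rel),
        strand = rep(as.character(GenomicRanges::strand(gr)), nblock),
        stringsAsFactors = FALSE
      )
    } else {
      ex <- data.frame(
        gene_id = as.character(nm),
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L,
        end = GenomicRanges::end(gr),
        strand = as.character(GenomicRanges::strand(gr)),
        stringsAsFactors = FALSE
      )
    }
  }
  bad <- ex$end <= ex$start
  if (any(bad)) {
    warning(sum(bad), " zero-length exon record(s) rejected")
    ex <- ex[!bad, , drop = FALSE]
  }
  gene_set(ex)
}

#' Write gene models as BED12
#'
#' @param genes a [gene_set()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(genes, path) {
  stopifnot(inherits(genes, "gene_set"))
  g <- genes$genes
  lines <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    ex <- genes$exons[genes$exons$gene_id == g$gene_id[i], , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    lines[i] <- paste(
      g$chrom[i], g$start[i], g$end[i], g$gene_id[i], 0L, g$strand[i],
      g$start[i], g$end[i], "0", nrow(ex),
      paste0(paste(ex$end - ex$start, collapse = ","), ","),
      paste0(paste(ex$start - g$start[i], collapse = ","), ","),
      sep = "\t"
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write intervals as BED6
#'
#' @param df data.frame with `chrom`, `start`, `end`, `strand` and optionally
#'   `name` and `score` columns (0-based half-open).
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_bed6 <- function(df, path) {
  name <- df$name %||% paste0("iv_", seq_len(nrow(df)))
  score <- df$score %||% rep(0, nrow(df))
  writeLines(paste(df$chrom, df$start, df$end, name, score, df$strand,
                   sep = "\t"), path)
  invisible(path)
}

# 5'/3' splice-site base positions (first/last intronic base, 0-based) for an
# intron table; vectorised.
intron_splice_bases <- function(introns) {
  plus <- introns$strand == "+"
  data.frame(
    intron_id = introns$intron_id,
    five = ifelse(plus, introns$start, introns$end - 1L),
    three = ifelse(plus, introns$end - 1L, introns$start),
    stringsAsFactors = FALSE
  )
}

#' Classify positions as exonic, intronic or intergenic
#'
#' Each position gets exactly one label. Priority is exonic > intronic >
#' intergenic across all models; within a category same-strand models are
#' preferred over opposite-strand ones, remaining ties broken by smallest
#' model span, then gene_id.
#'
#' @param positions data.frame with `chrom`, `pos` (0-based base position)
#'   and optionally `strand` (NA allowed).
#' @param genes a [gene_set()].
#' @return data.frame with added `region` ("exonic"/"intronic"/"intergenic")
#'   and `gene_id` (NA for intergenic).
#' @export
classify_region <- function(positions, genes) {
  stopifnot(inherits(genes, "gene_set"))
  positions <- as.data.frame(positions)
  n <- nrow(positions)
  strand <- if ("strand" %in% names(positions)) as.character(positions$strand)
            else rep(NA_character_, n)
  out_region <- rep("intergenic", n)
  out_gene <- rep(NA_character_, n)
  if (n == 0L) {
    positions$region <- character(0)
    positions$gene_id <- character(0)
    return(positions)
  }
  pts <- points_granges0(positions$chrom, positions$pos)
  span_width <- genes$genes$end - genes$genes$start
  names(span_width) <- genes$genes$gene_id

  pick <- function(hit_q, hit_gene, hit_strand) {
    # resolve one winner per query: same strand first, then smallest span
    same <- !is.na(strand[hit_q]) & strand[hit_q] == hit_strand
    o <- order(hit_q, !same, span_width[hit_gene], hit_gene)
    keep <- !duplicated(hit_q[o])
    list(q = hit_q[o][keep], gene = hit_gene[o][keep])
  }

  exg <- as_granges0(genes$exons$chrom, genes$exons$start, genes$exons$end)
  h <- GenomicRanges::findOverlaps(pts, exg, ignore.strand = TRUE)
  if (length(h) > 0L) {
    qi <- S4Vectors::queryHits(h)
    si <- S4Vectors::subjectHits(h)
    res <- pick(qi, genes$exons$gene_id[si], genes$exons$strand[si])
    out_region[res$q] <- "exonic"
    out_gene[res$q] <- res$gene
  }
  todo <- out_region == "intergenic"
  if (any(todo)) {
    spg <- as_granges0(genes$genes$chrom, genes$genes$start, genes$genes$end)
    h <- GenomicRanges::findOverlaps(pts[todo], spg, ignore.strand = TRUE)
    if (length(h) > 0L) {
      qi <- which(todo)[S4Vectors::queryHits(h)]
      si <- S4Vectors::subjectHits(h)
      res <- pick(qi, genes$genes$gene_id[si], genes$genes$strand[si])
      out_region[res$q] <- "intronic"
      out_gene[res$q] <- res$gene
    }
  }
  positions$region <- out_region
  positions$gene_id <- out_gene
  positions
}

#' Four splice sites flanking an internal exon
#'
#' Returns the 5' and 3' splice-site base positions (first/last intronic
#' bases, 0-based) of the two introns flanking an internal exon, labelled in
#' transcript orientation: `up5ss`/`up3ss` belong to the upstream intron,
#' `down5ss`/`down3ss` to the downstream intron.
#'
#' @param genes a [gene_set()].
#' @param gene_id model identifier.
#' @param exon_index 1-based transcript-order exon index; must be internal.
#' @return Named list with `up5ss`, `up3ss`, `down5ss`, `down3ss`,
#'   `up_intron_id`, `down_intron_id`.
#' @export
flanking_splice_sites <- function(genes, gene_id, exon_index) {
  stopifnot(inherits(genes, "gene_set"))
  g <- genes$genes[genes$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) != 1L) stop("unknown gene_id: ", gene_id)
  if (exon_index <= 1L || exon_index >= g$n_exons) {
    stop("not an internal exon: ", gene_id, " exon ", exon_index)
  }
  intr <- genes$introns[genes$introns$gene_id == gene_id, , drop = FALSE]
  up <- intr[intr$intron_index == exon_index - 1L, , drop = FALSE]
  dn <- intr[intr$intron_index == exon_index, , drop = FALSE]
  ub <- intron_splice_bases(up)
  db <- intron_splice_bases(dn)
  list(up5ss = ub$five, up3ss = ub$three,
       down5ss = db$five, down3ss = db$three,
       up_intron_id = up$intron_id, down_intron_id = dn$intron_id)
}

#' Cassette-exon contexts for all internal exons
#'
#' Vectorised companion to [flanking_splice_sites()]: one row per internal
#' exon, carrying the exon interval, the two flanking introns and the four
#' splice-site base positions in transcript orientation.
#'
#' @param genes a [gene_set()].
#' @return data.frame with columns exon_id, gene_id, exon_index, chrom,
#'   strand, exon_start, exon_end, up_intron_id, down_intron_id,
#'   up_start/up_end, down_start/down_end, up5ss, up3ss, down5ss, down3ss.
#' @export
cassette_contexts <- function(genes) {
  stopifnot(inherits(genes, "gene_set"))
  ex <- genes$exons
  ngene <- genes$genes$n_exons
  names(ngene) <- genes$genes$gene_id
  internal <- ex$exon_index > 1L & ex$exon_index < ngene[ex$gene_id]
  ex <- ex[internal, , drop = FALSE]
  if (nrow(ex) == 0L) {
    stop("no internal exons in gene set")
  }
  intr <- genes$introns
  key <- paste0(intr$gene_id, ":", intr$intron_index)
  upk <- paste0(ex$gene_id, ":", ex$exon_index - 1L)
  dnk <- paste0(ex$gene_id, ":", ex$exon_index)
  up <- intr[match(upk, key), , drop = FALSE]
  dn <- intr[match(dnk, key), , drop = FALSE]
  ub <- intron_splice_bases(up)
  db <- intron_splice_bases(dn)
  data.frame(
    exon_id = ex$exon_id, gene_id = ex$gene_id, exon_index = ex$exon_index,
    chrom = ex$chrom, strand = ex$strand,
    exon_start = ex$start, exon_end = ex$end,
    up_intron_id = up$intron_id, down_intron_id = dn$intron_id,
    up_start = up$start, up_end = up$end,
    down_start = dn$start, down_end = dn$end,
    up5ss = ub$five, up3ss = ub$three,
    down5ss = db$five, down3ss = db$three,
    stringsAsFactors = FALSE
  )
}
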
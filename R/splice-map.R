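# Integration of consensus binding sites with differential splicing:
# four-site binding proximity, splicing-map density profiles by exon group,
# group CDF comparisons, intron-retention association, and PWM-based
# splice-site strength.

#' Binding proximity of consensus crosslinks to the four splice sites
#'
#' For every internal-exon context, a splice-site flag is set when at least
#' one consensus crosslink lies on the intronic side of that site and within
#' `max_dist` nt of it. Crosslinks in the exon body never set a flag unless
#' `include_exonic_side = TRUE` relaxes the rule to a plain distance test.
#'
#' @param consensus consensus-cluster table from [consensus_clusters()] (or
#'   any data.frame with `chrom`, `strand`, `crosslink`).
#' @param contexts contexts from [cassette_contexts()].
#' @param max_dist nt (default 150).
#' @param include_exonic_side drop the intronic-side requirement.
#' @return data.frame: `exon_id`, logical `up5ss`, `up3ss`, `down5ss`,
#'   `down3ss`, and `n_sites_bound` (0-4).
#' @export
binding_proximity <- function(consensus, contexts, max_dist = 150L,
                              include_exonic_side = FALSE) {
  n <- nrow(contexts)
  out <- data.frame(exon_id = contexts$exon_id, up5ss = FALSE, up3ss = FALSE,
                    down5ss = FALSE, down3ss = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(consensus) > 0L) {
    pts <- points_granges0(consensus$chrom, consensus$crosslink,
                           consensus$strand)
    for (a in c("up5ss", "up3ss", "down5ss", "down3ss")) {
      sp <- contexts[[a]]
      lo <- sp - max_dist
      hi <- sp + max_dist + 1L
      if (!include_exonic_side) {
        if (a %in% c("up5ss", "up3ss")) {
          lo <- pmax(lo, contexts$up_start)
          hi <- pmin(hi, contexts$up_end)
        } else {
          lo <- pmax(lo, contexts$down_start)
          hi <- pmin(hi, contexts$down_end)
        }
      }
      win <- as_granges0(contexts$chrom, lo, pmax(hi, lo + 1L),
                         contexts$strand)
      h <- GenomicRanges::findOverlaps(pts, win, ignore.strand = FALSE)
      out[[a]][unique(S4Vectors::subjectHits(h))] <- TRUE
    }
  }
  out$n_sites_bound <- rowSums(out[, c("up5ss", "up3ss", "down5ss", "down3ss")])
  out
}

# transcript-oriented offset of positions around one anchor column of the
# context table; positive offsets point downstream in transcript direction
.anchor_offsets <- function(positions, contexts, anchor_col, window) {
  sp <- contexts[[anchor_col]]
  win <- as_granges0(contexts$chrom, sp - window, sp + window + 1L,
                     contexts$strand)
  pts <- points_granges0(positions$chrom, positions$pos, positions$strand)
  h <- GenomicRanges::findOverlaps(pts, win, ignore.strand = FALSE)
  qi <- S4Vectors::queryHits(h)
  si <- S4Vectors::subjectHits(h)
  plus <- contexts$strand[si] == "+"
  data.frame(
    exon_id = contexts$exon_id[si],
    offset = ifelse(plus, positions$pos[qi] - sp[si],
                    sp[si] - positions$pos[qi])
  )
}

#' RNA splicing map: binding density around the four splice sites by group
#'
#' For each exon group and each of the four splice-site anchors, consensus
#' crosslink offsets within the window are binned and normalised per exon:
#' the density in a bin is crosslink hits divided by group size, so the sum
#' over bins equals hits per exon at that anchor.
#'
#' @param consensus consensus table (`chrom`, `strand`, `crosslink`).
#' @param groups named list of exon_id vectors.
#' @param contexts contexts from [cassette_contexts()].
#' @param window nt each side of the anchor (default 300, >= 50).
#' @param bin bin width in nt (default 5).
#' @return data.frame: `group`, `anchor`, `offset` (bin left edge), `count`,
#'   `density`, `n_exons`.
#' @export
splicing_map <- function(consensus, groups, contexts, window = 300L,
                         bin = 5L) {
  stopifnot(window >= 50L, bin >= 1L)
  anchors <- c("up5ss", "up3ss", "down5ss", "down3ss")
  edges <- seq.int(-window, window, by = bin)
  nb <- length(edges) - 1L
  pos <- data.frame(chrom = consensus$chrom, pos = consensus$crosslink,
                    strand = consensus$strand, stringsAsFactors = FALSE)
  rows <- list()
  for (gname in names(groups)) {
    ids <- groups[[gname]]
    ctx <- contexts[contexts$exon_id %in% ids, , drop = FALSE]
    ng <- nrow(ctx)
    if (ng == 0L) warning("empty exon group: ", gname)
    for (a in anchors) {
      cnt <- integer(nb)
      if (ng > 0L && nrow(pos) > 0L) {
        od <- .anchor_offsets(pos, ctx, a, window)
        if (nrow(od) > 0L) {
          idx <- findInterval(od$offset, edges, rightmost.closed = TRUE)
          idx <- idx[idx >= 1L & idx <= nb]
          cnt <- tabulate(idx, nbins = nb)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = gname, anchor = a, offset = edges[-length(edges)],
        count = as.integer(cnt),
        density = if (ng > 0L) cnt / ng else 0,
        n_exons = ng, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Group-wise empirical CDFs with a background comparison
#'
#' Splits a per-exon statistic (Z or delta PSI) into groups and compares each
#' group against the background group with a two-sided Mann-Whitney U test
#' (the CDF-shift test of choice here; groups smaller than `min_n` are
#' returned without a comparison, with a warning).
#'
#' @param values named numeric vector (names = exon ids).
#' @param groups named list of exon_id vectors; must include `background`.
#' @param background name of the reference group.
#' @param min_n minimum group size for testing (default 5).
#' @return List with `values` (data.frame group/exon_id/value) and `tests`
#'   (data.frame group/n/median/shift/statistic/p_value vs background).
#' @export
group_effect_cdf <- function(values, groups, background = "background",
                             min_n = 5L) {
  stopifnot(background %in% names(groups))
  val_rows <- list()
  for (gname in names(groups)) {
    ids <- intersect(groups[[gname]], names(values))
    if (length(ids) == 0L) {
      warning("group ", gname, " has no exons with values")
      next
    }
    val_rows[[gname]] <- data.frame(
      group = gname, exon_id = ids, value = unname(values[ids]),
      stringsAsFactors = FALSE
    )
  }
  vals <- do.call(rbind, val_rows)
  rownames(vals) <- NULL
  bg <- vals$value[vals$group == background]
  tests <- lapply(setdiff(unique(vals$group), background), function(gname) {
    v <- vals$value[vals$group == gname]
    if (length(v) < min_n) {
      warning("group ", gname, " smaller than ", min_n, "; comparison skipped")
      return(data.frame(group = gname, n = length(v), median = stats::median(v),
                        shift = stats::median(v) - stats::median(bg),
                        statistic = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    }
    wt <- stats::wilcox.test(v, bg, alternative = "two.sided", exact = FALSE)
    data.frame(group = gname, n = length(v), median = stats::median(v),
               shift = stats::median(v) - stats::median(bg),
               statistic = unname(wt$statistic), p_value = wt$p.value,
               stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, tests)
  list(values = vals, tests = tests)
}

#' Intron-retention change stratified by exon splicing response
#'
#' Maps each grouped exon to its upstream and downstream flanking introns and
#' compares the introns' Z(PIR) distributions across exon groups with the
#' same CDF machinery as [group_effect_cdf()]. Introns without a PIR value
#' are excluded and counted.
#'
#' @param z_pir named numeric vector of intron Z(PIR) values (names =
#'   intron ids).
#' @param groups named list of exon_id vectors (incl. `background`).
#' @param contexts contexts from [cassette_contexts()].
#' @param background reference group name.
#' @return List with one [group_effect_cdf()] result per side (`upstream`,
#'   `downstream`) and `n_missing` introns lacking values.
#' @export
intron_retention_association <- function(z_pir, groups, contexts,
                                         background = "background") {
  n_missing <- 0L
  res <- list()
  for (side in c("upstream", "downstream")) {
    col <- if (side == "upstream") "up_intron_id" else "down_intron_id"
    intron_of <- stats::setNames(contexts[[col]], contexts$exon_id)
    side_groups <- lapply(groups, function(ids) {
      iids <- unname(intron_of[intersect(ids, names(intron_of))])
      iids[iids %in% names(z_pir)]
    })
    n_missing <- n_missing +
      sum(lengths(lapply(groups, function(ids)
        setdiff(unname(intron_of[intersect(ids, names(intron_of))]),
                names(z_pir)))))
    iv <- z_pir
    res[[side]] <- group_effect_cdf(iv, side_groups, background)
    # relabel exon_id column for clarity
    names(res[[side]]$values)[names(res[[side]]$values) == "exon_id"] <- "intron_id"
  }
  res$n_missing <- n_missing
  res
}

#' Train splice-site position weight matrices from annotation
#'
#' Builds donor (3 exonic + 6 intronic nt) and acceptor (20 intronic + 3
#' exonic nt) position frequency matrices over all annotated introns, with
#' pseudocount 1, and converts them to log2-odds against the genome-wide
#' base composition.
#'
#' @param genes a [gene_set()].
#' @param sequence named `Biostrings::DNAStringSet` (one entry per chrom).
#' @param min_sites minimum introns required (default 50).
#' @return Object of class `splice_site_model`: list with `donor` and
#'   `acceptor` (each `prob` and `logodds` 4 x L matrices) and `background`.
#' @export
train_splice_site_model <- function(genes, sequence, min_sites = 50L) {
  stopifnot(inherits(genes, "gene_set"))
  if (nrow(genes$introns) < min_sites) {
    stop("fewer than ", min_sites,
         " introns; supply a pre-trained model instead")
  }
  w <- splice_site_windows(genes, sequence)
  af <- Biostrings::alphabetFrequency(sequence, collapse = TRUE)
  bg <- af[c("A", "C", "G", "T")] / sum(af[c("A", "C", "G", "T")])
  make <- function(seqs) {
    cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs))
    cm <- cm[c("A", "C", "G", "T"), , drop = FALSE]
    prob <- sweep(cm + 1, 2, colSums(cm) + 4, "/")
    list(prob = prob, logodds = log2(sweep(prob, 1, bg, "/")))
  }
  structure(list(donor = make(w$donor), acceptor = make(w$acceptor),
                 background = bg),
            class = "splice_site_model")
}

# Sense-strand donor and acceptor windows for every annotated intron.
# Windows crossing a contig edge are dropped.
splice_site_windows <- function(genes, sequence) {
  intr <- genes$introns
  seqlen <- stats::setNames(Biostrings::width(sequence), names(sequence))
  plus <- intr$strand == "+"
  dstart <- ifelse(plus, intr$start - 3L, intr$end - 6L)
  dend <- dstart + 9L
  astart <- ifelse(plus, intr$end - 20L, intr$start - 3L)
  aend <- astart + 23L
  ok <- dstart >= 0L & astart >= 0L &
        dend <= seqlen[intr$chrom] & aend <= seqlen[intr$chrom]
  intr <- intr[ok, , drop = FALSE]
  dstart <- dstart[ok]; dend <- dend[ok]
  astart <- astart[ok]; aend <- aend[ok]
  plus <- plus[ok]
  grab <- function(s, e, chrom, rc) {
    out <- character(length(s))
    for (i in seq_along(s)) {
      x <- Biostrings::subseq(sequence[[chrom[i]]], s[i] + 1L, e[i])
      if (rc[i]) x <- Biostrings::reverseComplement(x)
      out[i] <- as.character(x)
    }
    out
  }
  list(donor = grab(dstart, dend, intr$chrom, !plus),
       acceptor = grab(astart, aend, intr$chrom, !plus),
       intron_id = intr$intron_id)
}

#' Score a splice-site window with a trained model
#'
#' `score = sum over positions of log2(P_model(base) / P_background(base))`.
#'
#' @param model a `splice_site_model`.
#' @param window character sense-strand window (9 nt for "5ss", 23 nt for
#'   "3ss").
#' @param kind "5ss" (donor) or "3ss" (acceptor).
#' @return Numeric log2-odds score (NA for windows with non-ACGT bases).
#' @export
splice_site_strength <- function(model, window, kind = c("5ss", "3ss")) {
  kind <- match.arg(kind)
  lo <- if (kind == "5ss") model$donor$logodds else model$acceptor$logodds
  vapply(window, function(wd) {
    b <- strsplit(wd, "")[[1]]
    if (length(b) != ncol(lo) || !all(b %in% rownames(lo))) return(NA_real_)
    sum(lo[cbind(match(b, rownames(lo)), seq_along(b))])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Score the splice sites of all annotated introns
#'
#' @param model a `splice_site_model`.
#' @param genes a [gene_set()].
#' @param sequence named `Biostrings::DNAStringSet`.
#' @return data.frame: `intron_id`, `five_score`, `three_score`.
#' @export
score_annotated_sites <- function(model, genes, sequence) {
  w <- splice_site_windows(genes, sequence)
  data.frame(
    intron_id = w$intron_id,
    five_score = splice_site_strength(model, w$donor, "5ss"),
    three_score = splice_site_strength(model, w$acceptor, "3ss"),
    stringsAsFactors = FALSE
  )
}
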
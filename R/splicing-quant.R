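# PSI / PIR / RPKM quantification from junction-aware read counts, the
# 6 bp junction-overlap rule, and the cassette-exon universe.

#' Percent spliced in
#'
#' `PSI = e_in / (e_in + e_out)`: the fraction of junction-informative reads
#' supporting inclusion of an exon. Undefined (NA) when both counts are zero.
#'
#' @param e_in,e_out non-negative integer vectors.
#' @return Numeric vector in [0, 1] with NA where 0/0.
#' @export
psi <- function(e_in, e_out) {
  if (any(e_in < 0) || any(e_out < 0)) stop("counts must be non-negative")
  tot <- e_in + e_out
  ifelse(tot > 0, e_in / tot, NA_real_)
}

#' Percent intron retention
#'
#' `PIR = i_in / (i_in + i_out)`: the fraction of junction-informative reads
#' supporting retention of an intron. Undefined (NA) when both counts are
#' zero.
#'
#' @param i_in,i_out non-negative integer vectors.
#' @return Numeric vector in [0, 1] with NA where 0/0.
#' @export
pir <- function(i_in, i_out) {
  if (any(i_in < 0) || any(i_out < 0)) stop("counts must be non-negative")
  tot <- i_in + i_out
  ifelse(tot > 0, i_in / tot, NA_real_)
}

#' Reads per kilobase of exon per million mapped reads
#'
#' @param mapped_reads reads mapped to the gene's exons/junctions.
#' @param exon_kb cumulative exon length in kb (> 0).
#' @param total_mapped_millions library size in millions (> 0).
#' @return Numeric RPKM values.
#' @export
rpkm <- function(mapped_reads, exon_kb, total_mapped_millions) {
  if (any(exon_kb <= 0) || any(total_mapped_millions <= 0)) {
    stop("exon_kb and total_mapped_millions must be positive")
  }
  mapped_reads / (exon_kb * total_mapped_millions)
}

#' Count junction-aware reads into exon and intron tables
#'
#' Applies the junction-overlap rules to labelled read records (see
#' [simulate_junction_reads()] for the record format): an exon-body read or
#' an adjacent exon-exon junction read with at least `min_overlap` bp on the
#' relevant exon(s) is inclusion evidence (`e_in`) for the internal exon(s)
#' it contains, and splicing-out evidence (`i_out`) for the spliced intron;
#' a skipping junction read with at least `min_overlap` bp on both flanking
#' exons is exclusion evidence (`e_out`) for every skipped internal exon and
#' `i_out` for every spanned intron; an intron-boundary read with at least
#' `min_overlap` bp of intronic overlap is retention evidence (`i_in`).
#' Reads failing the overlap rule count nowhere. Each read receives exactly
#' one primary assignment label, returned for bookkeeping.
#'
#' @param reads data.frame with `read_id`, `gene_id`, `kind`
#'   ("exon"/"junction"/"intron_junction"), `a`, `b`, `ov1`, `ov2`.
#' @param genes a [gene_set()].
#' @param min_overlap minimum junction overlap in bp (default 6).
#' @return List with `exons` (gene_id, exon_index, exon_id, e_in, e_out),
#'   `introns` (gene_id, intron_index, intron_id, i_in, i_out) and
#'   `assignment` (per-read label: inclusion / skipping / intron_retention /
#'   unassigned).
#' @export
count_junction_reads <- function(reads, genes, min_overlap = 6L) {
  stopifnot(inherits(genes, "gene_set"))
  n_ex <- genes$genes$n_exons
  names(n_ex) <- genes$genes$gene_id
  unknown <- !reads$gene_id %in% names(n_ex)
  if (any(unknown)) {
    stop("reads reference unknown gene(s): ",
         paste(unique(reads$gene_id[unknown]), collapse = ", "))
  }

  ex <- genes$exons[, c("gene_id", "exon_index", "exon_id")]
  ex$e_in <- 0L
  ex$e_out <- 0L
  ex$internal <- ex$exon_index > 1L & ex$exon_index < n_ex[ex$gene_id]
  ekey <- paste0(ex$gene_id, ":", ex$exon_index)
  intr <- genes$introns[, c("gene_id", "intron_index", "intron_id")]
  intr$i_in <- 0L
  intr$i_out <- 0L
  ikey <- paste0(intr$gene_id, ":", intr$intron_index)

  add_ex <- function(col, g, idx, w = 1L) {
    m <- match(paste0(g, ":", idx), ekey)
    m <- m[!is.na(m)]
    if (length(m)) {
      t <- tabulate(m, nbins = nrow(ex)) * w
      ex[[col]] <<- ex[[col]] + as.integer(t)
    }
  }
  add_in <- function(col, g, idx) {
    m <- match(paste0(g, ":", idx), ikey)
    m <- m[!is.na(m)]
    if (length(m)) {
      t <- tabulate(m, nbins = nrow(intr))
      intr[[col]] <<- intr[[col]] + as.integer(t)
    }
  }

  label <- rep("unassigned", nrow(reads))
  kind <- reads$kind

  # exon-body reads: inclusion evidence for internal exons
  i <- which(kind == "exon" & reads$ov1 >= min_overlap)
  if (length(i)) {
    intl <- ex$internal[match(paste0(reads$gene_id[i], ":", reads$a[i]), ekey)]
    intl[is.na(intl)] <- FALSE
    i <- i[intl]
    add_ex("e_in", reads$gene_id[i], reads$a[i])
    label[i] <- "inclusion"
  }

  j <- which(kind == "junction" & reads$ov1 >= min_overlap &
             reads$ov2 >= min_overlap)
  if (length(j)) {
    adj <- reads$b[j] == reads$a[j] + 1L
    ja <- j[adj]
    if (length(ja)) {
      # inclusion for both junction exons (internal ones only)
      for (side in c("a", "b")) {
        idx <- reads[[side]][ja]
        intl <- ex$internal[match(paste0(reads$gene_id[ja], ":", idx), ekey)]
        intl[is.na(intl)] <- FALSE
        add_ex("e_in", reads$gene_id[ja][intl], idx[intl])
      }
      add_in("i_out", reads$gene_id[ja], reads$a[ja])
      label[ja] <- "inclusion"
    }
    js <- j[!adj]
    if (length(js)) {
      for (k in js) {
        skipped <- (reads$a[k] + 1L):(reads$b[k] - 1L)
        add_ex("e_out", rep(reads$gene_id[k], length(skipped)), skipped)
        spanned <- reads$a[k]:(reads$b[k] - 1L)
        add_in("i_out", rep(reads$gene_id[k], length(spanned)), spanned)
      }
      label[js] <- "skipping"
    }
  }

  i <- which(kind == "intron_junction" & reads$ov1 >= min_overlap)
  if (length(i)) {
    add_in("i_in", reads$gene_id[i], reads$a[i])
    label[i] <- "intron_retention"
  }

  ex$internal <- NULL
  list(exons = ex, introns = intr, assignment = label)
}

#' Define the cassette-exon universe
#'
#' Internal exons whose PSI is defined and falls inside the closed interval
#' `[lo, hi]` in at least one sample are cassette exons.
#'
#' @param psi_tables list of per-sample data.frames with `exon_id` and `psi`.
#' @param lo,hi interval bounds (defaults 0.02 and 0.98, both inclusive).
#' @return Character vector of exon_ids.
#' @export
define_cassette_exons <- function(psi_tables, lo = 0.02, hi = 0.98) {
  stopifnot(length(psi_tables) >= 1L)
  hits <- lapply(psi_tables, function(tb) {
    tb$exon_id[!is.na(tb$psi) & tb$psi >= lo & tb$psi <= hi]
  })
  sort(unique(unlist(hits)))
}

#' Add PSI/PIR and coverage to count tables
#'
#' @param counts list with `exons` (e_in, e_out) and `introns` (i_in, i_out)
#'   as produced by [count_junction_reads()] or the generator.
#' @return Same list with `psi`/`pir` and `coverage` columns added.
#' @export
quantify_splicing <- function(counts) {
  ex <- counts$exons
  ex$psi <- psi(ex$e_in, ex$e_out)
  ex$coverage <- ex$e_in + ex$e_out
  out <- list(exons = ex)
  if (!is.null(counts$introns)) {
    it <- counts$introns
    it$pir <- pir(it$i_in, it$i_out)
    it$coverage <- it$i_in + it$i_out
    out$introns <- it
  }
  out
}
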
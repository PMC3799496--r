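# End-to-end orchestration: simulate -> clusters -> quant -> diff -> map,
# with seed fan-out, plain-text outputs, a digest manifest for
# reproducibility, and evaluation against recorded ground truth.

write_tsv <- function(df, path) {
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# reads table with a conversions column serialised as comma strings
write_clip_tsv <- function(reads, path) {
  df <- reads
  df$conv <- vapply(reads$conv, paste, character(1), collapse = ",")
  write_tsv(df, path)
}

#' Read a simplified CLIP alignment TSV
#'
#' @param path TSV with columns read_id, chrom, start, end, strand, conv
#'   (comma-separated 0-based conversion positions, empty allowed).
#' @return data.frame with a `conv` list-column.
#' @export
read_clip_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(conv = "character"),
                          stringsAsFactors = FALSE)
  df$conv <- lapply(strsplit(ifelse(is.na(df$conv), "", df$conv), ","),
                    function(x) as.integer(x[nzchar(x)]))
  df
}

#' Run the full synthetic-study pipeline
#'
#' Executes, in dependency order: genome/truth simulation, PAR-CLIP read
#' simulation, cluster calling and consensus pairing, boundary profiling,
#' junction-count simulation, PSI/PIR quantification, differential testing,
#' and splicing-map integration. Every output file is written as plain text
#' under `outdir` and recorded with an md5 digest in `manifest.json`;
#' rerunning with the same configuration reproduces identical digests.
#'
#' @param config a [sim_config()] describing the simulated study.
#' @param outdir output directory (created if missing).
#' @param diff_config a [differential_config()]; its seed is re-derived from
#'   the simulation seed for reproducibility.
#' @param stages character subset of
#'   c("simulate", "clusters", "quant", "diff", "map"); later stages require
#'   earlier ones in-memory, so this mainly trims the tail of the run.
#' @return Invisible list with all in-memory stage results plus `manifest`.
#' @export
run_pipeline <- function(config, outdir,
                         diff_config = differential_config(),
                         stages = c("simulate", "clusters", "quant", "diff",
                                    "map")) {
  stopifnot(inherits(config, "sim_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  diff_config$seed <- stage_seed(config$seed, "differential")
  files <- character(0)
  res <- list()
  t0 <- Sys.time()
  log <- function(...) message(sprintf("[%5.1fs] ", as.numeric(Sys.time() - t0)), ...)

  log("simulate: generating genome and truth (seed ", config$seed, ")")
  sim <- simulate_genome(config)
  res$sim <- sim
  files <- c(files, write_annotation(sim$genes, file.path(outdir, "genes.bed")))
  if (!is.null(sim$sequence)) {
    fa <- file.path(outdir, "genome.fa")
    Biostrings::writeXStringSet(sim$sequence, fa)
    files <- c(files, fa)
  }
  files <- c(files,
             write_tsv(sim$truth$exons, file.path(outdir, "truth_exons.tsv")),
             write_tsv(sim$truth$introns, file.path(outdir, "truth_introns.tsv")),
             write_tsv(sim$truth$sites, file.path(outdir, "truth_sites.tsv")))
  ctx <- cassette_contexts(sim$genes)

  if ("clusters" %in% stages) {
    log("clusters: simulating PAR-CLIP reads and calling clusters")
    clip <- simulate_parclip_reads(sim)
    res$clip <- clip
    cl <- vector("list", length(clip))
    for (r in seq_along(clip)) {
      files <- c(files, write_clip_tsv(
        clip[[r]], file.path(outdir, sprintf("clip_rep%d.tsv", r))))
      cl[[r]] <- call_clusters(clip[[r]])
      files <- c(files, write_tsv(
        cl[[r]], file.path(outdir, sprintf("clusters_rep%d.tsv", r))))
    }
    res$clusters <- cl
    cons <- consensus_clusters(cl[[1]], cl[[2]])
    res$consensus <- cons
    files <- c(files, write_tsv(cons, file.path(outdir, "consensus.tsv")))
    log("clusters: ", nrow(cl[[1]]), " / ", nrow(cl[[2]]),
        " clusters; ", nrow(cons), " consensus")
    prof <- boundary_density_profile(
      data.frame(chrom = cons$chrom, pos = cons$crosslink,
                 strand = cons$strand),
      sim$genes, window = 300L, which = "intron_exon")
    res$profile_3ss <- prof
    files <- c(files, write_tsv(prof, file.path(outdir, "profile_3ss.tsv")))
  }

  if ("quant" %in% stages) {
    log("quant: simulating junction counts (",
        config$n_case_replicates, " replicate pairs)")
    counts <- simulate_splicing_counts(sim)
    res$counts <- counts
    for (arm in c("case", "control")) {
      for (r in seq_along(counts$exons[[arm]])) {
        q <- quantify_splicing(list(exons = counts$exons[[arm]][[r]],
                                    introns = counts$introns[[arm]][[r]]))
        files <- c(files,
                   write_tsv(q$exons, file.path(
                     outdir, sprintf("psi_%s_rep%d.tsv", arm, r))),
                   write_tsv(q$introns, file.path(
                     outdir, sprintf("pir_%s_rep%d.tsv", arm, r))))
      }
    }
    psi_tabs <- lapply(c(counts$exons$case, counts$exons$control),
                       function(tb) quantify_splicing(list(exons = tb))$exons)
    res$cassette <- define_cassette_exons(psi_tabs)
    log("quant: ", length(res$cassette), " cassette exons")
  }

  if ("diff" %in% stages) {
    log("diff: rank-product differential testing")
    dpsi <- differential_test(res$counts$exons$case, res$counts$exons$control,
                              "psi", diff_config)
    dpir <- differential_test(res$counts$introns$case,
                              res$counts$introns$control, "pir", diff_config)
    res$diff_psi <- dpsi
    res$diff_pir <- dpir
    files <- c(files,
               write_tsv(dpsi, file.path(outdir, "differential_psi.tsv")),
               write_tsv(dpir, file.path(outdir, "differential_pir.tsv")))
    log("diff: ", sum(dpsi$call != "none"), " exon calls, ",
        sum(dpir$call != "none"), " intron calls")
  }

  if ("map" %in% stages) {
    log("map: binding proximity and splicing map")
    prox <- binding_proximity(res$consensus, ctx)
    res$proximity <- prox
    files <- c(files, write_tsv(prox, file.path(outdir, "proximity.tsv")))
    dpsi <- res$diff_psi
    called_down <- dpsi$feature_id[dpsi$call == "down"]
    groups <- list(background = intersect(res$cassette, dpsi$feature_id),
                   called_down = called_down)
    smap <- splicing_map(res$consensus, groups, ctx)
    res$splicing_map <- smap
    files <- c(files, write_tsv(smap, file.path(outdir, "splicing_map.tsv")))
  }

  manifest <- list(
    package = "clipsplice",
    version = as.character(utils::packageVersion("clipsplice")),
    seed = config$seed,
    stages = stages,
    n_genes = config$n_genes,
    files = lapply(
      stats::setNames(files, basename(files)),
      function(f) unname(tools::md5sum(f))
    )
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  log("done: ", length(files), " files in ", outdir)
  invisible(res)
}

#' Evaluate pipeline output against recorded ground truth
#'
#' @param diff data.frame from [differential_test()] (PSI metric).
#' @param truth truth-exon table from the simulation.
#' @param consensus optional consensus table; enables crosslink positional
#'   error against true sites.
#' @param sites optional truth-site table (needed with `consensus`).
#' @param proximity optional table from [binding_proximity()]; enables the
#'   binding-enrichment ratio of called vs uncalled exons.
#' @param direction direction of the planted effect ("down" when planted
#'   deltas are negative).
#' @return One-row data.frame: sensitivity, false-discovery proportion (NA
#'   when nothing is called), mean delta bias and RMSE on true positives,
#'   median |crosslink error| nt, and proximity enrichment ratio.
#' @export
evaluate_against_truth <- function(diff, truth, consensus = NULL,
                                   sites = NULL, proximity = NULL,
                                   direction = "down") {
  m <- match(diff$feature_id, truth$exon_id)
  if (anyNA(m)) {
    stop("feature ids absent from truth: ",
         paste(utils::head(diff$feature_id[is.na(m)]), collapse = ", "))
  }
  tr <- truth[m, ]
  planted <- tr$planted & (if (direction == "down") tr$delta_psi < 0
                           else tr$delta_psi > 0)
  called <- diff$call == direction
  tp <- called & planted
  sens <- if (sum(planted) > 0L) sum(tp) / sum(planted) else NA_real_
  fdp <- if (sum(called) > 0L) sum(called & !planted) / sum(called) else NA_real_
  bias <- if (sum(tp) > 0L) {
    mean(diff$delta_mean[tp] - tr$delta_psi[tp])
  } else NA_real_
  rmse <- if (sum(tp) > 0L) {
    sqrt(mean((diff$delta_mean[tp] - tr$delta_psi[tp])^2))
  } else NA_real_

  xl_err <- NA_real_
  if (!is.null(consensus) && !is.null(sites) && nrow(consensus) > 0L &&
      nrow(sites) > 0L) {
    err <- vapply(seq_len(nrow(consensus)), function(i) {
      same <- sites$strand == consensus$strand[i] &
              sites$chrom == consensus$chrom[i]
      if (!any(same)) return(NA_real_)
      min(abs(sites$pos[same] - consensus$crosslink[i]))
    }, numeric(1))
    xl_err <- stats::median(err, na.rm = TRUE)
  }

  enrich <- NA_real_
  if (!is.null(proximity)) {
    pm <- match(diff$feature_id, proximity$exon_id)
    bound <- proximity$n_sites_bound[pm] >= 1L
    p_called <- mean(bound[called], na.rm = TRUE)
    p_other <- mean(bound[!called], na.rm = TRUE)
    enrich <- p_called / max(p_other, 1e-12)
  }

  data.frame(
    n_tested = nrow(diff), n_planted = sum(planted), n_called = sum(called),
    sensitivity = sens, fdp = fdp, delta_bias = bias, delta_rmse = rmse,
    crosslink_error_nt = xl_err, proximity_enrichment = enrich
  )
}
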
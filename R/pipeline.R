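## end-to-end orchestration: segments -> alignment -> variant catalog ->
## repeat analysis -> distances -> divergence, with persisted intermediates
## and a report object mirroring the package's summary tables.

#' Run the full comparative pipeline
#'
#' Executes segment detection (when absent), IGS annotation, whole-genome
#' anchored alignment, indel/SNP calling with outgroup polarization and
#' context/synonymy classification, tandem-array and hairpin analysis of
#' the hotspot spacer, p-distances, and (when an outgroup is present) a
#' calibration-ratio divergence estimate. With `outdir` set, all
#' intermediates (FASTA, aligned FASTA, VCF, BED, TSV tables, JSON
#' manifest) are persisted.
#'
#' @param genomeA,genomeB `AnnotatedPlastome`s (or paths handled by
#'   [read_plastome()]). Alternatively pass a [simulation_config()] as
#'   `config` to simulate-then-analyze.
#' @param outgroup optional `AnnotatedPlastome`; without it all indel
#'   polarities stay `"unknown"` (carriers are still assigned).
#' @param config optional `SimulationConfig` for the simulate-then-analyze
#'   round trip (ignores `genomeA`/`genomeB`).
#' @param hotspot_igs name of the hypervariable spacer analyzed for tandem
#'   repeats (default `"trnY-trnE"`).
#' @param calibration `c(point, half_width)` calibration age in mya used
#'   for divergence scaling when an outgroup is present.
#' @param scoring a [scheme_params()].
#' @param outdir optional output directory for persisted intermediates.
#' @param verbose log stage progress to standard error.
#' @return object of class `RunReport`.
#' @export
run_pipeline <- function(genomeA = NULL, genomeB = NULL, outgroup = NULL,
                         config = NULL, hotspot_igs = "trnY-trnE",
                         calibration = c(28.5, 5.5),
                         scoring = scheme_params(), outdir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message("[plastdiff] ", ...)
  t0 <- Sys.time()
  truth <- NULL
  if (!is.null(config)) {
    say("simulating ancestor and pair (seed ", config$seed, ")")
    anc <- generate_ancestor(config)
    sim <- evolve_pair(anc, config)
    genomeA <- sim$genomeA; genomeB <- sim$genomeB
    outgroup <- sim$outgroup; truth <- sim$truth
  }
  if (is.character(genomeA)) genomeA <- read_plastome(genomeA)
  if (is.character(genomeB)) genomeB <- read_plastome(genomeB)
  if (is.null(genomeA) || is.null(genomeB))
    stop("stage 'input': need genomeA and genomeB (or a config)")

  for (nm in c("genomeA", "genomeB")) {
    g <- get(nm)
    if (is.null(g$segments)) {
      say("detecting segments for ", g$id)
      g$segments <- tryCatch(detect_segments(g),
        error = function(e) stop("stage 'segments' failed for ", g$id,
                                 ": ", conditionMessage(e)))
    }
    if (!any(g$features$kind == "IGS") && nrow(g$features))
      g <- annotate_igs(g)
    assign(nm, g)
  }

  say("aligning genomes (", plastome_length(genomeA), " vs ",
      plastome_length(genomeB), " bp)")
  aln <- align_auto(genomeA$sequence, genomeB$sequence, scoring = scoring,
                    labelA = genomeA$id, labelB = genomeB$id)

  say("calling variants")
  indels <- call_indels(aln, genomeA)
  snps <- call_snps(aln, genomeA)
  indels <- classify_indel_context(indels, genomeA, genomeB)
  snps <- classify_synonymy(snps, genomeA, aln, genomeB)
  if (!is.null(outgroup)) {
    say("polarizing indels against outgroup")
    trip <- align_triplet(genomeA$sequence, genomeB$sequence,
                          outgroup$sequence, scoring = scoring)
    indels <- polarize_indels(indels, trip)
  }
  summary <- summarize_variants(indels, snps, genomeA, aln)

  say("analyzing hotspot spacer '", hotspot_igs, "'")
  repeats <- analyze_hotspot(genomeA, genomeB, outgroup, hotspot_igs)

  say("computing distances")
  region_seqs <- repeats$region_seqs %||%
    stats::setNames(list(genomeA$sequence, genomeB$sequence),
                    c(genomeA$id, genomeB$id))
  dm <- distance_matrix(region_seqs, scoring = scoring)

  divergence <- NULL
  if (nrow(snps) + nrow(indels) == 0L) {
    say("genomes identical: divergence stage skipped")
  } else if (!is.null(outgroup) && outgroup$id %in% dm$labels) {
    ingroup <- setdiff(dm$labels, outgroup$id)
    p_ref <- group_mean_distance(dm, ingroup, outgroup$id)
    p_focal <- dm$pdist[ingroup[1], ingroup[2]]
    if (p_focal > 0) {
      fold <- fold_difference(p_ref, p_focal)
      divergence <- scale_divergence(calibration, fold,
                                     basis = hotspot_igs)
    } else say("focal divergence zero in '", hotspot_igs,
               "': divergence stage skipped")
  }

  recovery <- if (!is.null(truth))
    recovery_stats(truth, indels, snps) else NULL

  report <- structure(list(
    manifest = list(
      genomeA = genomeA$id, genomeB = genomeB$id,
      outgroup = if (!is.null(outgroup)) outgroup$id,
      lengthA = plastome_length(genomeA),
      lengthB = plastome_length(genomeB),
      seed = if (!is.null(config)) config$seed,
      scoring = unclass(scoring),
      version = as.character(utils::packageVersion("plastdiff")),
      timestamp = format(t0, "%Y-%m-%dT%H:%M:%S")),
    aln = aln, indels = indels, snps = snps, summary = summary,
    repeats = repeats, distances = dm, divergence = divergence,
    truth = truth, recovery = recovery,
    genomeA = genomeA, genomeB = genomeB, outgroup = outgroup),
    class = "RunReport")

  if (!is.null(outdir)) persist_report(report, outdir, say)
  say("done in ", round(as.numeric(Sys.time() - t0, units = "secs"), 1),
      " s")
  report
}

## tandem/hairpin analysis of the named spacer in each genome
analyze_hotspot <- function(genomeA, genomeB, outgroup, hotspot_igs) {
  region_of <- function(g) {
    f <- g$features[g$features$kind == "IGS" &
                      g$features$name == hotspot_igs, , drop = FALSE]
    if (!nrow(f)) return(NULL)
    substr(g$sequence, min(f$start) + 1L, max(f$end))
  }
  genomes <- list(genomeA, genomeB)
  if (!is.null(outgroup) &&
      any(outgroup$features$name == hotspot_igs)) genomes <-
    c(genomes, list(outgroup))
  seqs <- lapply(genomes, region_of)
  names(seqs) <- vapply(genomes, `[[`, "", "id")
  seqs <- seqs[!vapply(seqs, is.null, TRUE)]
  if (!length(seqs)) return(NULL)
  per_genome <- lapply(seqs, function(s) {
    arrs <- find_tandem_arrays(s)
    if (!length(arrs)) return(NULL)
    arr <- arrs[[1]]
    fold <- fold_hairpin(arr$consensus)
    forms <- vapply(arr$copies$seq, classify_form, character(1))
    profile <- tryCatch(consensus_profile(arr$copies$seq),
                        error = function(e) NULL)
    list(array = arr, fold = fold,
         form_counts = table(factor(forms, c("A", "B", "other"))),
         profile = profile)
  })
  list(region_seqs = seqs, per_genome = per_genome)
}

persist_report <- function(report, outdir, say = message) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(outdir, ...)
  say("writing intermediates to ", outdir)
  write_plastome_fasta(report$genomeA, fp("genomeA.fasta"))
  write_plastome_fasta(report$genomeB, fp("genomeB.fasta"))
  if (!is.null(report$outgroup))
    write_plastome_fasta(report$outgroup, fp("outgroup.fasta"))
  write_aligned_fasta(report$aln, fp("alignment.fasta"))
  write_vcf(report$snps, report$indels, report$genomeA, fp("variants.vcf"))
  write_bed(report$genomeA, fp("segments.bed"), "segments")
  if (nrow(report$genomeA$features))
    write_bed(report$genomeA, fp("features.bed"), "features")
  utils::write.table(as.data.frame(report$summary$indel_table),
                     fp("indel_table.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(report$summary$snp_table),
                     fp("snp_table.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(report$summary$gene_table))
    utils::write.table(report$summary$gene_table, fp("gene_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  write_distance_matrix(report$distances, fp("distances.tsv"), "tsv")
  write_distance_matrix(report$distances, fp("distances.phy"), "phylip")
  if (!is.null(report$repeats)) {
    pg <- report$repeats$per_genome
    for (nm in names(pg)) if (!is.null(pg[[nm]])) {
      write_repeat_tsv(pg[[nm]]$array, fp(paste0("repeats_", nm, ".tsv")))
      if (!is.null(pg[[nm]]$profile))
        write_profile_tsv(pg[[nm]]$profile,
                          fp(paste0("profile_", nm, ".tsv")))
    }
  }
  manifest <- report$manifest
  manifest$summary <- list(
    n_indels = report$summary$n_indels, n_snps = report$summary$n_snps,
    snp_divergence_pct = report$summary$snp_divergence_pct,
    ts_tv = as.list(report$summary$ts_tv))
  if (!is.null(report$divergence))
    manifest$divergence <- list(
      point = report$divergence$point_reported,
      half_width = report$divergence$half_width_reported,
      fold = report$divergence$fold, basis = report$divergence$basis)
  if (!is.null(report$recovery)) manifest$recovery <- report$recovery
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(outdir)
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport:", x$manifest$genomeA, "vs", x$manifest$genomeB,
      if (!is.null(x$manifest$outgroup))
        paste("(outgroup", x$manifest$outgroup, ")"), "\n")
  print(x$summary)
  if (!is.null(x$divergence)) print(x$divergence)
  if (!is.null(x$recovery))
    cat("  truth recovery:", sprintf("%.1f%%", 100 * x$recovery$recovery),
        "of", x$recovery$n_planted, "planted events\n")
  invisible(x)
}
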
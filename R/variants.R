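## variant catalog: indel and SNP calling from an AlignedPair, outgroup
## polarization, context and synonymy classification, and the summary
## statistics (per-region densities, Ts/Tv, per-gene K2P).

#' Call indel events from a pairwise alignment
#'
#' Each maximal single-row gap run becomes one event. The carrier is the
#' genome holding the extra bases (the row without the gap); `posA` is the
#' 0-based coordinate of the first A-row base at or after the run (the run
#' itself for carrier A events), `posB` the analogous B coordinate. Gap runs
#' are left-normalized by the aligners, so coordinates are stable.
#'
#' When `genomeA` has segments, events falling in IRb are dropped (variants
#' in the inverted repeat are counted once, on IRa; densities later use
#' twice the IR length).
#'
#' @param aln an `AlignedPair` (A-row mapped to `genomeA` when given).
#' @param genomeA optional `AnnotatedPlastome` supplying segments.
#' @return data.frame of class `IndelEvents`: `segment`, `posA`, `posB`,
#'   `length`, `carrier`, `polarity` (`"unknown"` until
#'   [polarize_indels()]), `context` (`NA` until
#'   [classify_indel_context()]), `inserted_seq`, plus internal column
#'   bounds `col_start`/`col_end`.
#' @export
call_indels <- function(aln, genomeA = NULL) {
  ca <- str2chars(aln$gappedA); cb <- str2chars(aln$gappedB)
  ev <- list()
  grab <- function(runs, carrier, bases) {
    if (!nrow(runs)) return(NULL)
    data.frame(
      col_start = runs[, "start"], col_end = runs[, "end"],
      carrier = carrier,
      length = runs[, "end"] - runs[, "start"] + 1L,
      inserted_seq = vapply(seq_len(nrow(runs)), function(i)
        chars2str(bases[runs[i, "start"]:runs[i, "end"]]), character(1)),
      stringsAsFactors = FALSE)
  }
  ev <- rbind(grab(true_runs(ca == "-"), "B", cb),
              grab(true_runs(cb == "-"), "A", ca))
  if (is.null(ev) || !nrow(ev)) {
    out <- data.frame(segment = character(), posA = integer(),
                      posB = integer(), length = integer(),
                      carrier = character(), polarity = character(),
                      context = character(), inserted_seq = character(),
                      col_start = integer(), col_end = integer())
    class(out) <- c("IndelEvents", "data.frame")
    return(out)
  }
  nA <- sum(ca != "-"); nB <- sum(cb != "-")
  # coordinate of first source base at/after a column
  next_pos <- function(colmap, n, col) {
    cm <- colmap
    # fill NA with the next non-NA value (coordinate at/after)
    filled <- rev(cummin(rev(ifelse(is.na(cm), n, cm))))
    filled[col]
  }
  ev$posA <- next_pos(aln$colmapA, nA, ev$col_start)
  ev$posB <- next_pos(aln$colmapB, nB, ev$col_start)
  ev$polarity <- "unknown"
  ev$context <- NA_character_
  ev$segment <- if (!is.null(genomeA)) segment_of(genomeA, ev$posA)
                else NA_character_
  ev <- drop_irb(ev, genomeA)
  ev <- ev[order(ev$col_start),
           c("segment", "posA", "posB", "length", "carrier", "polarity",
             "context", "inserted_seq", "col_start", "col_end")]
  rownames(ev) <- NULL
  class(ev) <- c("IndelEvents", "data.frame")
  ev
}

## drop events whose A coordinate falls in IRb (IR counted once, on IRa)
drop_irb <- function(ev, genomeA) {
  if (is.null(genomeA) || is.null(genomeA$segments) || !nrow(ev)) return(ev)
  irb <- genomeA$segments[genomeA$segments$name == "IRb", ]
  if (nrow(irb) != 1) return(ev)
  ev[!(ev$posA >= irb$start & ev$posA < irb$end), , drop = FALSE]
}

#' Polarize indel events against an outgroup
#'
#' An indel's carrier says which genome holds the extra bases; the outgroup
#' says whether those bases are ancestral. Outgroup lacks the segment:
#' the event is an insertion in the carrier lineage. Outgroup has the
#' segment: a deletion in the non-carrier lineage. Outgroup coverage absent
#' or ambiguous over the locus (under half the flanking columns covered, or
#' no clear majority over the run): polarity stays `"unknown"`. Carrier
#' assignment is never changed.
#'
#' @param events `IndelEvents` from [call_indels()] on `triplet$pair`.
#' @param triplet a `TripletAlignment` over the same pair.
#' @param flank flanking window (columns) used to check outgroup coverage.
#' @param majority fraction of run columns required to call presence or
#'   absence of the segment in the outgroup.
#' @return `events` with `polarity` filled in.
#' @export
polarize_indels <- function(events, triplet, flank = 20L, majority = 0.5) {
  if (!nrow(events)) return(events)
  oc <- str2chars(triplet$gappedO)
  ncol <- length(oc)
  # a flank column is informative when the outgroup agrees with at least
  # one genome there; mere base coverage is not homology evidence
  informative <- triplet$states %in% c("A-like", "B-like", "both")
  for (i in seq_len(nrow(events))) {
    cs <- events$col_start[i]; ce <- events$col_end[i]
    if (is.na(cs) || cs < 1L || ce > ncol) {
      warning("indel locus outside triplet alignment; polarity unknown")
      next
    }
    lf <- informative[max(1L, cs - flank):max(1L, cs - 1L)]
    rf <- informative[min(ncol, ce + 1L):min(ncol, ce + flank)]
    cover <- mean(c(lf, rf))
    if (!is.finite(cover) || cover < 0.5) next       # unknown: no homology
    has_frac <- mean(oc[cs:ce] != "-")
    events$polarity[i] <-
      if (has_frac >= majority) {
        # outgroup has the segment: deletion in the non-carrier lineage
        "deletion"
      } else if ((1 - has_frac) >= majority) {
        # outgroup lacks it: insertion in the carrier lineage
        "insertion"
      } else "unknown"
  }
  events
}

#' Classify indel context (homopolymer / tandem / other)
#'
#' `homopolymer`: the event is a run of one repeated base and the carrier
#' genome's run of that base covering the site (event bases included) is at
#' least `homopolymer_min` bp. `tandem`: the event sequence (length >= 2)
#' exactly duplicates an immediately adjacent window of the same length in
#' the carrier genome. Everything else, including dispersed-repeat context,
#' is `other`.
#'
#' @param events `IndelEvents`.
#' @param genomeA,genomeB the two plastomes (or plain sequences) the
#'   alignment was built from.
#' @param homopolymer_min minimum carrier-genome run length (default 4 bp,
#'   separating slippage-prone runs from chance).
#' @return `events` with `context` filled in.
#' @export
classify_indel_context <- function(events, genomeA, genomeB,
                                   homopolymer_min = 4L) {
  seqs <- list(A = as_sequence(genomeA), B = as_sequence(genomeB))
  if (!nrow(events)) return(events)
  for (i in seq_len(nrow(events))) {
    s <- seqs[[events$carrier[i]]]
    pos <- if (events$carrier[i] == "A") events$posA[i] else events$posB[i]
    len <- events$length[i]
    ins <- events$inserted_seq[i]
    events$context[i] <- indel_context_one(s, pos, len, ins, homopolymer_min)
  }
  events
}

as_sequence <- function(x) {
  if (inherits(x, "AnnotatedPlastome")) x$sequence else toupper(as.character(x))
}

indel_context_one <- function(seq, pos, len, ins, homopolymer_min) {
  bases <- unique(str2chars(ins))
  n <- nchar(seq)
  if (length(bases) == 1L) {
    b <- bases
    lo <- pos; hi <- pos + len - 1L              # 0-based inclusive
    while (lo > 0L && substr(seq, lo, lo) == b) lo <- lo - 1L
    while (hi + 2L <= n && substr(seq, hi + 2L, hi + 2L) == b) hi <- hi + 1L
    if (hi - lo + 1L >= homopolymer_min) return("homopolymer")
  }
  if (len >= 2L) {
    before <- if (pos - len >= 0L) substr(seq, pos - len + 1L, pos) else ""
    after <- if (pos + 2L * len <= n)
      substr(seq, pos + len + 1L, pos + 2L * len) else ""
    if (identical(before, ins) || identical(after, ins)) return("tandem")
  }
  "other"
}

#' Call SNPs from a pairwise alignment
#'
#' Every gap-free mismatch column with both bases in `{A,C,G,T}` yields one
#' event (no MNP merging; columns with N are excluded). Compartment and gene
#' come from the genome A annotation under the precedence CDS > intron >
#' tRNA > rRNA > IGS; `mut_class` is `Ts` iff the unordered base pair is
#' `{A,G}` or `{C,T}`. Events in IRb are dropped when segments are known
#' (IR variants counted once).
#'
#' @param aln `AlignedPair` with the A row mapped to `genomeA`.
#' @param genomeA optional annotated plastome.
#' @return data.frame of class `SnpEvents`: `segment`, `posA`, `posB`,
#'   `baseA`, `baseB`, `compartment`, `gene`, `mut_class`, `coding_effect`
#'   (`not_applicable` until [classify_synonymy()]).
#' @export
call_snps <- function(aln, genomeA = NULL) {
  ca <- str2chars(aln$gappedA); cb <- str2chars(aln$gappedB)
  acgt <- c("A", "C", "G", "T")
  hit <- which(ca != cb & ca %in% acgt & cb %in% acgt)
  out <- data.frame(
    segment = rep(NA_character_, length(hit)),
    posA = if (length(hit)) aln$colmapA[hit] else integer(),
    posB = if (length(hit)) aln$colmapB[hit] else integer(),
    baseA = ca[hit], baseB = cb[hit],
    compartment = rep(NA_character_, length(hit)),
    gene = rep(NA_character_, length(hit)),
    mut_class = ifelse(is_transition(ca[hit], cb[hit]), "Ts", "Tv"),
    coding_effect = rep("not_applicable", length(hit)),
    stringsAsFactors = FALSE)
  if (!is.null(genomeA) && length(hit)) {
    out$segment <- segment_of(genomeA, out$posA)
    ct <- compartment_table(genomeA, out$posA)
    out$compartment <- ct$compartment
    out$gene <- ct$gene
    out <- drop_irb(out, genomeA)
  }
  rownames(out) <- NULL
  class(out) <- c("SnpEvents", "data.frame")
  out
}

#' Classify a coding SNP as synonymous or nonsynonymous
#'
#' Reconstructs the codon containing the site on the coding strand from each
#' genome (the two companion positions taken from the same genome via the
#' alignment) and translates both with the bacterial/plastid genetic code
#' (NCBI table 11). Synonymous iff the amino acids are equal. A codon
#' interrupted by an alignment gap, or a degenerate CDS (length not a
#' multiple of 3), yields `not_applicable`.
#'
#' @param snps `SnpEvents` (only rows with `compartment == "coding"` are
#'   touched).
#' @param genomeA annotated plastome carrying the CDS features.
#' @param aln the `AlignedPair` the SNPs were called from.
#' @param genomeB genome B (or plain sequence).
#' @return `snps` with `coding_effect` filled for coding rows.
#' @export
classify_synonymy <- function(snps, genomeA, aln, genomeB) {
  idx <- which(snps$compartment == "coding")
  if (!length(idx)) return(snps)
  seqB <- as_sequence(genomeB)
  # column index of each A source position
  col_of_A <- integer(sum(!is.na(aln$colmapA)))
  col_of_A[aln$colmapA[!is.na(aln$colmapA)] + 1L] <-
    which(!is.na(aln$colmapA))
  cb <- str2chars(aln$gappedB)
  gc11 <- Biostrings::getGeneticCode("11")
  for (i in idx) {
    snps$coding_effect[i] <- synonymy_one(
      snps$posA[i], snps$gene[i], genomeA, cb, col_of_A, gc11)
  }
  snps
}

synonymy_one <- function(posA, gene, genomeA, cb, col_of_A, gc11) {
  f <- genomeA$features[genomeA$features$kind == "CDS" &
                          genomeA$features$name == gene, , drop = FALSE]
  if (!nrow(f)) return("not_applicable")
  if (any(f$degenerate)) return("not_applicable")
  strand <- f$strand[1]
  # genomic coordinates of the CDS in coding order
  ord <- order(f$start)
  coords <- unlist(lapply(ord, function(j) f$start[j]:(f$end[j] - 1L)))
  if (strand == "-") coords <- rev(coords)
  k <- match(posA, coords)
  if (is.na(k)) return("not_applicable")
  codon_idx <- ((k - 1L) %/% 3L) * 3L + 1L
  cpos <- coords[codon_idx:(codon_idx + 2L)]       # genomic, coding order
  if (any(is.na(cpos))) return("not_applicable")
  chA <- vapply(cpos, function(p) substr(genomeA$sequence, p + 1L, p + 1L),
                character(1))
  cols <- col_of_A[cpos + 1L]
  if (any(cols == 0L)) return("not_applicable")
  chB <- cb[cols]
  if (any(chB == "-")) {
    warning("codon interrupted by alignment gap at A position ", posA)
    return("not_applicable")
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  if (strand == "-") { chA <- comp[chA]; chB <- comp[chB] }
  codA <- chars2str(chA); codB <- chars2str(chB)
  if (!codA %in% names(gc11) || !codB %in% names(gc11))
    return("not_applicable")
  if (gc11[[codA]] == gc11[[codB]]) "synonymous" else "nonsynonymous"
}

#' Kimura two-parameter distance
#'
#' `K = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))` with `P` and `Q` the
#' transition and transversion proportions over comparable sites (both
#' bases in `{A,C,G,T}`; gap and N columns excluded pairwise).
#'
#' @param seqA,seqB equal-length (aligned) sequences.
#' @return K in substitutions/site; 0 iff the comparable sites are
#'   identical.
#' @export
k2p_distance <- function(seqA, seqB) {
  ca <- str2chars(toupper(seqA)); cb <- str2chars(toupper(seqB))
  if (length(ca) != length(cb)) stop("sequences must be equal length")
  acgt <- c("A", "C", "G", "T")
  ok <- ca %in% acgt & cb %in% acgt
  n <- sum(ok)
  if (n < 1L) stop("no comparable sites")
  diff <- ok & ca != cb
  P <- sum(diff & is_transition(ca, cb)) / n
  Q <- sum(diff & !is_transition(ca, cb)) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) stop("K2P undefined (saturated)")
  -0.5 * log(w1 * sqrt(w2))
}

#' Per-region variant density ratio
#'
#' Densities (count per bp) for LSC, SSC and IR, normalized so the IR
#' density equals 1. The IR length must already be doubled by the caller
#' (both repeat copies contribute length; events are counted once). When
#' the IR count is zero the densities are normalized to the smallest
#' nonzero density instead.
#'
#' @param counts numeric (LSC, SSC, IR) event counts.
#' @param lengths numeric (LSC, SSC, IR) lengths in bp, IR doubled.
#' @param digits decimals for reporting (half-away-from-zero); `NULL` for
#'   raw ratios.
#' @return named numeric triple (LSC, SSC, IR).
#' @export
density_ratio <- function(counts, lengths, digits = 1) {
  if (length(counts) != 3L || length(lengths) != 3L)
    stop("counts and lengths must be (LSC, SSC, IR) triples")
  if (any(lengths <= 0)) stop("zero-length region")
  dens <- counts / lengths
  base <- if (dens[3] > 0) dens[3] else {
    nz <- dens[dens > 0]
    if (!length(nz)) stop("all region counts are zero")
    min(nz)
  }
  r <- dens / base
  names(r) <- c("LSC", "SSC", "IR")
  if (is.null(digits)) r else round_half_up(r, digits)
}

#' Cross-tabulate and summarize classified variants
#'
#' Builds the standard report tables: indel counts by segment x context
#' x carrier, SNP counts by segment x compartment x mutation class, per-gene
#' substitution tables (with K2P when the alignment and annotation are
#' available), density ratios, per-compartment Ts/Tv ratios and the overall
#' SNP divergence percentage.
#'
#' @param indels `IndelEvents` (classified).
#' @param snps `SnpEvents` (classified).
#' @param genome annotated plastome A (segments used for densities; length
#'   for the divergence percentage).
#' @param aln optional `AlignedPair` for per-gene K2P distances.
#' @return list of class `VariantSummary`.
#' @export
summarize_variants <- function(indels, snps, genome = NULL, aln = NULL) {
  seg_lv <- c("LSC", "SSC", "IR")
  ctx_lv <- c("homopolymer", "tandem", "other")
  comp_lv <- c("coding", "IGS", "intron", "rRNA", "tRNA")
  cls_lv <- c("Ts", "Tv")

  indel_tab <- table(
    context = factor(indels$context, ctx_lv),
    segment = factor(indels$segment, seg_lv),
    carrier = factor(indels$carrier, c("A", "B")))
  snp_tab <- table(
    segment = factor(snps$segment, seg_lv),
    compartment = factor(snps$compartment, comp_lv),
    mut_class = factor(snps$mut_class, cls_lv))

  ts_by_comp <- apply(snp_tab, c(2, 3), sum)
  ratios <- c(
    whole = ts_tv_ratio(sum(snps$mut_class == "Ts"),
                        sum(snps$mut_class == "Tv")),
    vapply(comp_lv, function(cp)
      ts_tv_ratio(ts_by_comp[cp, "Ts"], ts_by_comp[cp, "Tv"]),
      numeric(1)))

  gene_table <- NULL
  coding <- snps[snps$compartment == "coding" & !is.na(snps$gene), ,
                 drop = FALSE]
  if (nrow(coding)) {
    gene_table <- do.call(rbind, lapply(split(coding, coding$gene),
      function(d) data.frame(
        gene = d$gene[1],
        Ts = sum(d$mut_class == "Ts"), Tv = sum(d$mut_class == "Tv"),
        S = sum(d$coding_effect == "synonymous"),
        N = sum(d$coding_effect == "nonsynonymous"),
        K2P = if (!is.null(aln) && !is.null(genome))
          gene_k2p(d$gene[1], genome, aln) else NA_real_)))
    rownames(gene_table) <- NULL
    gene_table <- gene_table[order(gene_table$gene), ]
  }

  densities <- NULL
  total_pct <- NULL
  if (!is.null(genome)) {
    if (!is.null(genome$segments)) {
      s <- genome$segments
      lens <- c(LSC = sum(s$end[s$name == "LSC"] - s$start[s$name == "LSC"]),
                SSC = sum(s$end[s$name == "SSC"] - s$start[s$name == "SSC"]),
                IR = sum(s$end[grepl("^IR", s$name)] -
                           s$start[grepl("^IR", s$name)]))
      cnt <- function(x) c(sum(x == "LSC", na.rm = TRUE),
                           sum(x == "SSC", na.rm = TRUE),
                           sum(x == "IR", na.rm = TRUE))
      densities <- list(
        segment_lengths = lens,
        indel = if (nrow(indels) && any(cnt(indels$segment) > 0))
          density_ratio(cnt(indels$segment), unname(lens)) else NULL,
        snp = if (nrow(snps) && any(cnt(snps$segment) > 0))
          density_ratio(cnt(snps$segment), unname(lens)) else NULL)
    }
    total_pct <- round_half_up(
      100 * nrow(snps) / plastome_length(genome), 2)
  }

  structure(list(
    n_indels = nrow(indels), n_snps = nrow(snps),
    indel_table = indel_tab, snp_table = snp_tab,
    gene_table = gene_table, ts_tv = ratios,
    densities = densities, snp_divergence_pct = total_pct),
    class = "VariantSummary")
}

## K2P over the aligned span of one annotated gene
gene_k2p <- function(gene, genome, aln) {
  f <- genome$features[genome$features$name == gene &
                         genome$features$kind != "IGS", , drop = FALSE]
  if (!nrow(f)) return(NA_real_)
  keep <- !is.na(aln$colmapA) &
    Reduce(`|`, lapply(seq_len(nrow(f)), function(j)
      aln$colmapA >= f$start[j] & aln$colmapA < f$end[j]))
  if (!any(keep)) return(NA_real_)
  ca <- str2chars(aln$gappedA)[keep]
  cb <- str2chars(aln$gappedB)[keep]
  tryCatch(k2p_distance(chars2str(ca), chars2str(cb)),
           error = function(e) NA_real_)
}

#' @export
print.VariantSummary <- function(x, ...) {
  cat("VariantSummary:", x$n_indels, "indels,", x$n_snps, "SNPs\n")
  if (!is.null(x$snp_divergence_pct))
    cat("  SNP divergence:", x$snp_divergence_pct, "%\n")
  cat("  Ts/Tv:", paste(names(x$ts_tv),
                        ifelse(is.na(x$ts_tv), "-", x$ts_tv),
                        sep = "=", collapse = " "), "\n")
  if (!is.null(x$densities)) {
    if (!is.null(x$densities$indel))
      cat("  indel density (LSC:SSC:IR):",
          paste(x$densities$indel, collapse = " : "), "\n")
    if (!is.null(x$densities$snp))
      cat("  SNP density (LSC:SSC:IR):",
          paste(x$densities$snp, collapse = " : "), "\n")
  }
  invisible(x)
}

#' Export variants as VCF v4.2 against genome A
#'
#' SNPs are written as simple substitutions; indels are left-normalized
#' with the conventional anchor base before the event (events at position 0
#' use the following base as anchor). Carrier A events (extra bases in the
#' reference genome A) appear as deletions in sample B, carrier B events as
#' insertions.
#'
#' @param snps `SnpEvents`.
#' @param indels `IndelEvents`.
#' @param genomeA annotated plastome A (the VCF reference).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(snps, indels, genomeA, path) {
  seqA <- genomeA$sequence
  rows <- character()
  fmt <- function(pos, ref, alt, info)
    paste(genomeA$id, pos, ".", ref, alt, ".", "PASS", info, sep = "\t")
  if (nrow(snps)) {
    info <- paste0("TYPE=SNP;CLASS=", snps$mut_class,
                   ifelse(is.na(snps$compartment), "",
                          paste0(";COMP=", snps$compartment)),
                   ifelse(is.na(snps$gene), "",
                          paste0(";GENE=", snps$gene)),
                   ifelse(snps$coding_effect == "not_applicable", "",
                          paste0(";EFFECT=", snps$coding_effect)))
    rows <- c(rows, fmt(snps$posA + 1L, snps$baseA, snps$baseB, info))
  }
  if (nrow(indels)) {
    for (i in seq_len(nrow(indels))) {
      p <- indels$posA[i]; ins <- indels$inserted_seq[i]
      carrier_a <- indels$carrier[i] == "A"
      if (p > 0L) {
        anchor <- substr(seqA, p, p)            # base before, 0-based p-1
        if (carrier_a) { ref <- paste0(anchor, ins); alt <- anchor }
        else { ref <- anchor; alt <- paste0(anchor, ins) }
        pos <- p                                 # 1-based anchor position
      } else {
        anchor <- if (carrier_a) substr(seqA, p + indels$length[i] + 1L,
                                        p + indels$length[i] + 1L)
                  else substr(seqA, 1L, 1L)
        if (carrier_a) { ref <- paste0(ins, anchor); alt <- anchor }
        else { ref <- anchor; alt <- paste0(ins, anchor) }
        pos <- 1L
      }
      info <- paste0("TYPE=INDEL;CARRIER=", indels$carrier[i],
                     ";POLARITY=", indels$polarity[i],
                     ifelse(is.na(indels$context[i]), "",
                            paste0(";CONTEXT=", indels$context[i])))
      rows <- c(rows, fmt(pos, ref, alt, info))
    }
  }
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", genomeA$id, ",length=",
                  plastome_length(genomeA), ">"),
           "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"SNP or INDEL\">",
           "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Ts or Tv\">",
           "##INFO=<ID=COMP,Number=1,Type=String,Description=\"Compartment\">",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene name\">",
           "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Coding effect\">",
           "##INFO=<ID=CARRIER,Number=1,Type=String,Description=\"Genome holding the extra bases\">",
           "##INFO=<ID=POLARITY,Number=1,Type=String,Description=\"insertion, deletion or unknown\">",
           "##INFO=<ID=CONTEXT,Number=1,Type=String,Description=\"homopolymer, tandem or other\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  ord <- order(as.integer(sub("^[^\t]*\t([0-9]+)\t.*$", "\\1", rows)))
  writeLines(c(hdr, rows[ord]), path)
  invisible(path)
}
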
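## synthetic plastome pairs: a quadripartite ancestor with annotated toy
## genes, homopolymer-enriched spacers and a planted tandem hairpin array,
## evolved into two lineages plus an outgroup under a seeded mutation
## process (Ts/Tv-biased substitutions, homopolymer slippage, tandem
## copy-number steps, other indels), with a machine-readable truth catalog.

PLASTID_GENE_NAMES <- c(
  "rbcL", "matK", "psbA", "psbB", "psbC", "psbD", "atpA", "atpB", "atpI",
  "rpoB", "rpoC1", "rpoC2", "rps3", "rps7", "rps8", "rps11", "rps14",
  "rpl2", "rpl20", "accD", "cemA", "clpP", "ccsA", "petA", "petB",
  "ndhA", "ndhD", "ndhF", "psaA", "psaB", "ycf2", "ycf3")

#' Simulation configuration
#'
#' Defaults describe a desk-scale plastome (~28 kb) with the structure the
#' analysis assumes: a quadripartite genome, AT-rich composition,
#' homopolymer-enriched intergenic spacers, one spacer carrying a tandem
#' array of 19 bp palindromic units, and per-lineage mutation rates whose
#' pairwise expectations match a conspecific plastome pair (~0.12% SNP
#' divergence, slippage-dominated indels with a weak genome-wide transition
#' bias).
#'
#' @param seed integer RNG seed (keep below 2^31).
#' @param segment_lengths named numeric `c(LSC=, SSC=, IR=)` in bp.
#' @param gc_fraction genomic GC fraction.
#' @param gene_count number of CDS genes placed in the single-copy regions.
#' @param mean_cds_length mean CDS length (rounded to a codon multiple).
#' @param igs_homopolymer_enrichment factor by which mean homopolymer run
#'   length in spacers exceeds the iid baseline (1 = baseline).
#' @param repeat_unit unit sequence of the planted tandem array.
#' @param repeat_copies initial copy number of the array.
#' @param repeat_copy_mut per-site mutation probability applied once per
#'   planted copy (ancestral heterogeneity among copies).
#' @param repeat_loop_b_fraction fraction of planted copies whose loop is
#'   swapped to the B form (TTTAA).
#' @param mu_sub substitutions per site per lineage.
#' @param kappa transition/transversion rate ratio (per-type; the expected
#'   Ts/Tv count ratio is `kappa/2`).
#' @param rate_homopolymer slippage indel events per site per lineage
#'   (targeted at homopolymer runs >= `homopolymer_min`).
#' @param rate_tandem_dup duplication/contraction events per site per
#'   lineage outside the planted array (tandem context).
#' @param rate_other other indel events per site per lineage.
#' @param tandem_step_rate expected copy-number steps of the planted array
#'   per lineage.
#' @param homopolymer_min minimum run length for slippage targets.
#' @param outgroup_factor divergence multiplier of the outgroup branch.
#' @return list of class `SimulationConfig`.
#' @export
simulation_config <- function(
    seed = 1L,
    segment_lengths = c(LSC = 20000L, SSC = 4000L, IR = 2000L),
    gc_fraction = 0.33,
    gene_count = 16L,
    mean_cds_length = 600L,
    igs_homopolymer_enrichment = 3,
    repeat_unit = CANONICAL_UNIT_19,
    repeat_copies = 30L,
    repeat_copy_mut = 0.03,
    repeat_loop_b_fraction = 0.4,
    mu_sub = 6e-4,
    kappa = 1.1,
    rate_homopolymer = 4e-4,
    rate_tandem_dup = 9e-5,
    rate_other = 9e-5,
    tandem_step_rate = 0.5,
    homopolymer_min = 4L,
    outgroup_factor = 12) {
  cfg <- as.list(environment())
  stopifnot(all(segment_lengths > 0),
            mu_sub >= 0, kappa > 0, rate_homopolymer >= 0,
            rate_tandem_dup >= 0, rate_other >= 0, tandem_step_rate >= 0,
            outgroup_factor > 0)
  structure(cfg, class = "SimulationConfig")
}

base_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

random_dna <- function(n, probs) {
  if (n <= 0) return("")
  chars2str(sample(names(probs), n, replace = TRUE, prob = probs))
}

## spacer sequence with homopolymer run lengths enriched by `f` over the
## iid baseline; f = 1 reproduces the iid process exactly
homopolymer_enriched_dna <- function(n, probs, f) {
  if (f <= 1) return(random_dna(n, probs))
  mean_run <- f / (1 - sum(probs^2))     # baseline iid mean run is 1/(1-sum p^2)
  out <- character(0); total <- 0L; prev <- ""
  while (total < n) {
    repeat {
      b <- sample(names(probs), 1L, prob = probs)
      if (b != prev) break
    }
    len <- 1L + stats::rgeom(1L, 1 / mean_run)
    out <- c(out, strrep(b, len))
    total <- total + len
    prev <- b
  }
  substr(paste(out, collapse = ""), 1L, n)
}

## planted tandem array: copies of `unit` with ancestral heterogeneity
planted_array <- function(unit, copies, per_copy_mut, loop_b_fraction) {
  L <- nchar(unit)
  fold <- fold_hairpin(unit)
  vapply(seq_len(copies), function(i) {
    u <- str2chars(unit)
    if (fold$stem_length == 7L && stats::runif(1) < loop_b_fraction)
      u[8:12] <- str2chars("TTTAA")
    hit <- which(stats::runif(L) < per_copy_mut)
    for (p in hit) u[p] <- sample(setdiff(c("A", "C", "G", "T"), u[p]), 1L)
    chars2str(u)
  }, character(1))
}

#' Generate a synthetic annotated ancestor plastome
#'
#' Layout: LSC - IRa - SSC - IRb with IRb the exact reverse complement of
#' IRa. CDS genes (plastid-style names, one of them intron-split) are
#' placed in the LSC and SSC separated by homopolymer-enriched spacers; the
#' tRNA pair trnY/trnE flanks a spacer carrying the planted tandem array;
#' an rRNA (rrn16) sits in IRa.
#'
#' @param config a [simulation_config()].
#' @return an [plastome()] with segments and features set.
#' @export
generate_ancestor <- function(config) {
  set.seed(config$seed)
  probs <- base_probs(config$gc_fraction)
  sl <- config$segment_lengths
  enrich <- config$igs_homopolymer_enrichment

  blocks <- list()   # each: list(seq, kind, name, strand) or spacer
  add <- function(seq, kind = NA_character_, name = NA_character_,
                  strand = "+")
    blocks[[length(blocks) + 1L]] <<- list(seq = seq, kind = kind,
                                           name = name, strand = strand)
  spacer <- function(n) if (n > 0)
    add(homopolymer_enriched_dna(n, probs, enrich))

  genes <- PLASTID_GENE_NAMES[seq_len(min(config$gene_count,
                                          length(PLASTID_GENE_NAMES)))]
  cds_len <- function() {
    n <- max(90L, stats::rpois(1L, config$mean_cds_length))
    (n %/% 3L) * 3L
  }
  array_seq <- paste(planted_array(config$repeat_unit, config$repeat_copies,
                                   config$repeat_copy_mut,
                                   config$repeat_loop_b_fraction),
                     collapse = "")

  # --- LSC: genes | trnY | [array spacer] | trnE | genes -----------------
  n_lsc_genes <- max(1L, round(0.8 * length(genes)))
  lsc_genes <- genes[seq_len(n_lsc_genes)]
  ssc_genes <- setdiff(genes, lsc_genes)
  split_gene <- lsc_genes[1]              # this one gets an intron
  # rough budget: genes + trnas + array; remainder split across spacers
  gene_seqs <- lapply(lsc_genes, function(g) random_dna(cds_len(), probs))
  names(gene_seqs) <- lsc_genes
  trna_len <- 75L
  used <- sum(nchar(unlist(gene_seqs))) + 2L * trna_len +
    nchar(array_seq) + 200L   # intron
  n_spacers <- length(lsc_genes) + 3L
  sp <- max(10L, (sl[["LSC"]] - used) %/% n_spacers)

  half <- ceiling(length(lsc_genes) / 2)
  for (i in seq_len(half)) {
    spacer(sp)
    g <- lsc_genes[i]
    strand <- if (i %% 2L) "+" else "-"
    if (g == split_gene) {
      s <- gene_seqs[[g]]
      cut <- (nchar(s) %/% 6L) * 3L
      add(substr(s, 1L, cut), "CDS", g, strand)
      add(homopolymer_enriched_dna(200L, probs, enrich), "intron", g, strand)
      add(substr(s, cut + 1L, nchar(s)), "CDS", g, strand)
    } else add(gene_seqs[[g]], "CDS", g, strand)
  }
  spacer(sp)
  add(random_dna(trna_len, probs), "tRNA", "trnY", "+")
  # hotspot spacer: plain flank + array + plain flank
  add(homopolymer_enriched_dna(max(30L, sp %/% 2L), probs, enrich))
  array_block_idx <- length(blocks) + 1L
  add(array_seq)
  add(homopolymer_enriched_dna(max(30L, sp %/% 2L), probs, enrich))
  add(random_dna(trna_len, probs), "tRNA", "trnE", "+")
  for (i in (half + 1L):length(lsc_genes)) {
    spacer(sp)
    add(gene_seqs[[lsc_genes[i]]], "CDS", lsc_genes[i],
        if (i %% 2L) "+" else "-")
  }
  # pad LSC to its configured length
  cur <- sum(vapply(blocks, function(b) nchar(b$seq), 1L))
  spacer(sl[["LSC"]] - cur)

  # --- IRa: spacer | rrn16 | spacer --------------------------------------
  rrn_len <- min(1400L, (sl[["IR"]] * 2L) %/% 3L)
  pad <- sl[["IR"]] - rrn_len
  add(random_dna(pad %/% 2L, probs))
  add(random_dna(rrn_len, probs), "rRNA", "rrn16", "+")
  add(random_dna(pad - pad %/% 2L, probs))

  # --- SSC: genes (ycf1-style) -------------------------------------------
  cur <- sum(vapply(blocks, function(b) nchar(b$seq), 1L))
  ssc_start <- cur
  if (length(ssc_genes)) {
    ssc_seqs <- lapply(ssc_genes, function(g) random_dna(cds_len(), probs))
    ssp <- max(10L, (sl[["SSC"]] - sum(nchar(unlist(ssc_seqs)))) %/%
                 (length(ssc_genes) + 1L))
    for (i in seq_along(ssc_genes)) {
      spacer(ssp)
      add(ssc_seqs[[i]], "CDS", ssc_genes[i], if (i %% 2L) "+" else "-")
    }
  }
  cur <- sum(vapply(blocks, function(b) nchar(b$seq), 1L))
  spacer(sl[["LSC"]] + sl[["IR"]] + sl[["SSC"]] - cur)

  # --- assemble, then append IRb = revcomp(IRa) --------------------------
  seqs <- vapply(blocks, `[[`, "", "seq")
  ends <- cumsum(nchar(seqs))
  starts <- ends - nchar(seqs)            # 0-based starts
  feats <- do.call(rbind, lapply(which(
    !is.na(vapply(blocks, `[[`, NA_character_, "kind"))), function(i)
      data.frame(kind = blocks[[i]]$kind, name = blocks[[i]]$name,
                 start = starts[i], end = ends[i],
                 strand = blocks[[i]]$strand, stringsAsFactors = FALSE)))
  feats$degenerate <- FALSE
  body <- paste(seqs, collapse = "")
  ira_start <- sl[["LSC"]]; ira_end <- ira_start + sl[["IR"]]
  ira <- substr(body, ira_start + 1L, ira_end)
  genome_seq <- paste0(body, revcomp(ira))
  L <- nchar(genome_seq)
  segs <- data.frame(
    name = c("LSC", "IRa", "SSC", "IRb"),
    start = c(0L, ira_start, ira_end, L - sl[["IR"]]),
    end = c(ira_start, ira_end, L - sl[["IR"]], L))
  if (any(feats$end > L)) stop("features overflow segment budget")
  anc <- plastome(id = "ancestor", sequence = genome_seq, segments = segs,
                  features = feats, ir_mismatch_tolerance = 0L)
  # exact coordinates of the planted array (0-based half-open)
  anc$array_region <- c(starts[array_block_idx], ends[array_block_idx])
  anc
}

## ---- mutation machinery ----------------------------------------------

## draw planted events for one lineage on the ancestor; `occupied` is a
## global logical footprint over ancestor positions shared across lineages
draw_lineage_events <- function(anc, cfg, lineage, occupied, factor = 1) {
  seq <- anc$sequence
  segs <- anc$segments
  irb <- segs[segs$name == "IRb", ]
  mut_len <- irb$start                    # mutate [0, IRb); IRb is mirrored
  ch <- str2chars(seq)
  ev <- list()
  bases <- c("A", "C", "G", "T")
  reserve <- function(lo, hi) {           # 0-based inclusive, +1 bp margin
    lo <- max(0L, lo - 1L); hi <- min(mut_len - 1L, hi + 1L)
    if (any(occupied[(lo:hi) + 1L])) return(FALSE)
    occupied[(lo:hi) + 1L] <<- TRUE
    TRUE
  }
  boundaries <- sort(c(segs$start, segs$end))
  crosses_boundary <- function(lo, hi)
    any(boundaries > lo & boundaries <= hi)
  # context label of a planted indel, from the carrier genome's content:
  # for a deletion the carrier is the unmutated lineage (ancestor content);
  # for an insertion, the ancestor with the event applied
  content_context <- function(kind, pos, len, sq) {
    if (kind == "substitution") return(NA_character_)
    carrier_seq <- if (kind == "deletion") seq else
      paste0(substr(seq, 1L, pos), sq,
             substr(seq, pos + 1L, nchar(seq)))
    indel_context_one(carrier_seq, pos, len, sq, cfg$homopolymer_min)
  }
  push <- function(kind, pos, len, sq, mechanism) {
    ev[[length(ev) + 1L]] <<- data.frame(
      kind = kind, lineage = lineage, pos_ancestor = pos,
      length = len, seq = sq, mechanism = mechanism,
      context = content_context(kind, pos, len, sq),
      stringsAsFactors = FALSE)
  }

  # substitutions
  n_sub <- stats::rpois(1L, cfg$mu_sub * factor * mut_len)
  drawn <- 0L; tries <- 0L
  while (drawn < n_sub && tries < 50L * n_sub + 50L) {
    tries <- tries + 1L
    p <- sample.int(mut_len, 1L) - 1L
    b <- ch[p + 1L]
    if (b == "N" || !reserve(p, p)) next
    ts_partner <- c(A = "G", G = "A", C = "T", T = "C")[[b]]
    new <- if (stats::runif(1) < cfg$kappa / (cfg$kappa + 2))
      ts_partner else sample(setdiff(bases, c(b, ts_partner)), 1L)
    push("substitution", p, 1L, new, "substitution")
    drawn <- drawn + 1L
  }

  # homopolymer slippage (+/- 1 bp in runs >= homopolymer_min)
  r <- rle(ch[seq_len(mut_len)])
  run_end <- cumsum(r$lengths); run_start <- run_end - r$lengths + 1L
  big <- which(r$lengths >= cfg$homopolymer_min & r$values %in% bases)
  if (length(big)) {
    n_hp <- stats::rpois(1L, cfg$rate_homopolymer * factor * mut_len)
    drawn <- 0L; tries <- 0L
    while (drawn < n_hp && tries < 50L * n_hp + 50L) {
      tries <- tries + 1L
      k <- big[sample.int(length(big), 1L,
                          prob = r$lengths[big])]
      lo <- run_start[k] - 1L; hi <- run_end[k] - 1L   # 0-based
      if (crosses_boundary(lo, hi) || !reserve(lo, hi)) next
      b <- r$values[k]
      if (stats::runif(1) < 0.5)
        push("insertion", lo, 1L, b, "slippage")
      else
        push("deletion", lo, 1L, b, "slippage")
      drawn <- drawn + 1L
    }
  }

  # tandem copy-number steps on the planted array
  arr <- locate_planted_array(anc, cfg)
  if (!is.null(arr)) {
    n_steps <- stats::rpois(1L, cfg$tandem_step_rate * factor)
    p <- nchar(cfg$repeat_unit)
    drawn <- 0L; tries <- 0L
    while (drawn < n_steps && tries < 50L * n_steps + 50L) {
      tries <- tries + 1L
      kmax <- (arr[2] - arr[1]) %/% p
      bnd <- arr[1] + p * sample.int(kmax - 1L, 1L)   # internal boundary
      k <- sample(1:3, 1L, prob = c(0.7, 0.2, 0.1))
      if (bnd + k * p > arr[2]) next
      unit_seq <- substr(seq, bnd + 1L, bnd + k * p)
      if (!reserve(bnd, bnd + k * p - 1L)) next
      if (stats::runif(1) < 0.5)
        push("insertion", bnd, k * p, unit_seq, "array_step")
      else
        push("deletion", bnd, k * p, unit_seq, "array_step")
      drawn <- drawn + 1L
    }
  }

  # tandem duplications elsewhere (a contraction needs a pre-existing
  # repeat, which outside the planted array the ancestor does not carry)
  n_td <- stats::rpois(1L, cfg$rate_tandem_dup * factor * mut_len)
  drawn <- 0L; tries <- 0L
  while (drawn < n_td && tries < 50L * n_td + 50L) {
    tries <- tries + 1L
    len <- sample(2:24, 1L)
    p <- sample.int(mut_len - 2L * len, 1L) - 1L
    if (!is.null(arr) && p + 2L * len >= arr[1] && p < arr[2]) next
    win <- substr(seq, p + 1L, p + len)
    if (grepl("N", win) || length(unique(str2chars(win))) < 2L ||
        crosses_boundary(p, p + 2L * len - 1L)) next
    if (!reserve(p, p + 2L * len - 1L)) next
    push("insertion", p + len, len, win, "duplication")
    drawn <- drawn + 1L
  }

  # other indels (random sequence / random span); candidates whose content
  # would read as slippage or a duplication are redrawn so the mechanism
  # stays recoverable from sequence alone
  n_ot <- stats::rpois(1L, cfg$rate_other * factor * mut_len)
  drawn <- 0L; tries <- 0L
  while (drawn < n_ot && tries < 50L * n_ot + 50L) {
    tries <- tries + 1L
    len <- 1L + stats::rpois(1L, 3L)
    p <- sample.int(mut_len - len, 1L) - 1L
    if (!is.null(arr) && p + len >= arr[1] && p < arr[2]) next
    if (crosses_boundary(p, p + len - 1L)) next
    kind <- if (stats::runif(1) < 0.5) "insertion" else "deletion"
    sq <- if (kind == "insertion") random_dna(len, base_probs(0.5))
          else substr(seq, p + 1L, p + len)
    if (grepl("N", sq)) next
    if (content_context(kind, p, len, sq) != "other") next
    if (!reserve(p, p + len - 1L)) next
    push(kind, p, len, sq, "other")
    drawn <- drawn + 1L
  }

  list(events = if (length(ev)) do.call(rbind, ev) else NULL,
       occupied = occupied)
}

## 0-based half-open interval of the planted array in the ancestor. The
## generator records the exact coordinates; for genomes lacking that record
## the array is re-located inside the trnY-trnE spacer (the spacer also
## carries non-repetitive flanks, which must not receive array steps).
locate_planted_array <- function(anc, cfg) {
  if (!is.null(anc$array_region)) return(anc$array_region)
  trny <- anc$features[anc$features$name == "trnY", ]
  trne <- anc$features[anc$features$name == "trnE", ]
  if (!nrow(trny) || !nrow(trne)) return(NULL)
  p <- nchar(cfg$repeat_unit)
  igs_start <- trny$end[1]
  region <- substr(anc$sequence, igs_start + 1L, trne$start[1])
  if (nchar(region) < 2L * p) return(NULL)
  arrs <- find_tandem_arrays(region, unit_range = c(p, p), min_copies = 2L)
  if (!length(arrs)) return(NULL)
  igs_start + arrs[[1]]$region
}

## apply planted events to a sequence; returns the mutated [0, IRb) body.
## events carry ancestor coordinates; indels are applied right to left.
apply_events <- function(body, events) {
  if (is.null(events) || !nrow(events)) return(body)
  ch <- str2chars(body)
  subs <- events[events$kind == "substitution", , drop = FALSE]
  if (nrow(subs)) ch[subs$pos_ancestor + 1L] <- subs$seq
  ind <- events[events$kind != "substitution", , drop = FALSE]
  if (nrow(ind)) {
    ind <- ind[order(-ind$pos_ancestor), , drop = FALSE]
    out <- ch
    for (i in seq_len(nrow(ind))) {
      p <- ind$pos_ancestor[i]; len <- ind$length[i]
      if (ind$kind[i] == "insertion") {
        out <- append(out, str2chars(ind$seq[i]), after = p)
      } else {
        out <- out[-((p + 1L):(p + len))]
      }
    }
    ch <- out
  }
  chars2str(ch)
}

## shift an ancestor coordinate through a lineage's indel events
lift_positions <- function(pos, events) {
  if (is.null(events)) return(pos)
  ind <- events[events$kind != "substitution", , drop = FALSE]
  if (!nrow(ind)) return(pos)
  delta <- ifelse(ind$kind == "insertion", ind$length, -ind$length)
  vapply(pos, function(p) {
    d <- sum(delta[ind$pos_ancestor < p |
                     (ind$kind == "insertion" & ind$pos_ancestor == p)])
    # positions inside a deleted span collapse to the span start
    inside <- ind$kind == "deletion" & p > ind$pos_ancestor &
      p < ind$pos_ancestor + ind$length
    if (any(inside)) {
      k <- which(inside)[1]
      d <- sum(delta[ind$pos_ancestor < ind$pos_ancestor[k]])
      return(ind$pos_ancestor[k] + d)
    }
    p + d
  }, numeric(1))
}

## rebuild a full plastome from the mutated body: IRb re-mirrored from the
## mutated IRa (copy correction), segments and features lifted
rebuild_genome <- function(anc, body, events, id) {
  segs <- anc$segments
  lift <- function(p) as.integer(lift_positions(p, events))
  lsc_end <- lift(segs$end[segs$name == "LSC"])
  ira_end <- lift(segs$end[segs$name == "IRa"])
  ssc_end <- lift(segs$end[segs$name == "SSC"])
  ira <- substr(body, lsc_end[1] + 1L, ira_end[1])
  seq <- paste0(body, revcomp(ira))
  L <- nchar(seq)
  segs2 <- data.frame(
    name = c("LSC", "IRa", "SSC", "IRb"),
    start = c(0L, lsc_end, ira_end, ssc_end),
    end = c(lsc_end, ira_end, ssc_end, L))
  f <- anc$features
  f$start <- lift(f$start)
  f$end <- lift(f$end)
  f <- f[f$end > f$start, , drop = FALSE]
  plastome(id = id, sequence = seq, segments = segs2, features = f,
           ir_mismatch_tolerance = 0L)
}

#' Evolve a plastome pair (plus outgroup) from an ancestor
#'
#' Star tree: two lineages (A, B) evolve independently from the ancestor;
#' an outgroup lineage evolves with `outgroup_factor` times the per-lineage
#' rates. Substitutions are Poisson over sites with transition bias
#' `kappa`; slippage indels target homopolymer runs; the planted tandem
#' array takes copy-number steps of 1-3 units; occasional tandem
#' duplications and random-sequence indels occur elsewhere. Planted events
#' never overlap (a shared footprint registry re-draws colliding events),
#' so every event is individually recoverable. Mutations are planted on
#' `[0, IRb)` and IRb is re-mirrored from the mutated IRa (plastome copy
#' correction), so IR events exist once and the IR invariant stays exact.
#'
#' @param ancestor an ancestor from [generate_ancestor()].
#' @param config the same [simulation_config()].
#' @return list with `genomeA`, `genomeB`, `outgroup`
#'   (`AnnotatedPlastome`s) and `truth` (class `MutationTruth`): the
#'   planted-event table with ancestor coordinates, per-event coordinates
#'   on genome A (`posA`) and on the carrier genome (`pos_carrier`), the
#'   expected carrier, realized per-lineage counts, net array steps and a
#'   config echo.
#' @export
evolve_pair <- function(ancestor, config) {
  set.seed(config$seed + 1L)
  irb_start <- ancestor$segments$start[ancestor$segments$name == "IRb"]
  body <- substr(ancestor$sequence, 1L, irb_start)
  occupied <- logical(irb_start)

  dA <- draw_lineage_events(ancestor, config, "A", occupied)
  dB <- draw_lineage_events(ancestor, config, "B", dA$occupied)
  dO <- draw_lineage_events(ancestor, config, "O", dB$occupied,
                            factor = config$outgroup_factor)

  genomeA <- rebuild_genome(ancestor, apply_events(body, dA$events),
                            dA$events, "lineageA")
  genomeB <- rebuild_genome(ancestor, apply_events(body, dB$events),
                            dB$events, "lineageB")
  outgroup <- rebuild_genome(ancestor, apply_events(body, dO$events),
                             dO$events, "outgroup")

  truth <- rbind(dA$events, dB$events, dO$events)
  if (is.null(truth)) {
    truth <- data.frame(kind = character(), lineage = character(),
                        pos_ancestor = numeric(), length = integer(),
                        seq = character(), mechanism = character(),
                        context = character())
  }
  # carrier of an indel: the genome holding the extra bases
  truth$carrier <- ifelse(
    truth$kind == "substitution", NA_character_,
    ifelse(truth$kind == "insertion",
           truth$lineage,
           ifelse(truth$lineage == "A", "B", "A")))
  # locus coordinate on genome A (ancestor position lifted through A's
  # indels); for carrier-genome context checks also the carrier coordinate
  truth$posA <- as.integer(lift_positions(truth$pos_ancestor, dA$events))
  liftB <- as.integer(lift_positions(truth$pos_ancestor, dB$events))
  truth$pos_carrier <- ifelse(!is.na(truth$carrier) & truth$carrier == "B",
                              liftB, truth$posA)
  rownames(truth) <- NULL

  net_steps <- function(ev) {
    if (is.null(ev)) return(0L)
    t <- ev[ev$mechanism %in% "array_step", , drop = FALSE]
    arr <- locate_planted_array(ancestor, config)
    if (is.null(arr) || !nrow(t)) return(0L)
    t <- t[t$pos_ancestor >= arr[1] & t$pos_ancestor < arr[2], ,
           drop = FALSE]
    p <- nchar(config$repeat_unit)
    sum(ifelse(t$kind == "insertion", t$length, -t$length)) %/% p
  }

  structure(list(
    genomeA = genomeA, genomeB = genomeB, outgroup = outgroup,
    truth = structure(list(
      events = truth,
      counts = table(lineage = truth$lineage, kind = truth$kind),
      net_array_steps = c(A = net_steps(dA$events), B = net_steps(dB$events),
                          O = net_steps(dO$events)),
      config = config), class = "MutationTruth")),
    class = "SimulatedPair")
}

#' @export
print.MutationTruth <- function(x, ...) {
  cat("MutationTruth:", nrow(x$events), "planted events\n")
  print(x$counts)
  cat("net array steps:", paste(names(x$net_array_steps),
                                x$net_array_steps, sep = "=",
                                collapse = " "), "\n")
  invisible(x)
}

#' Match recovered variants against the planted truth
#'
#' A planted ingroup substitution is recovered when a called SNP sits at
#' its genome A coordinate (within `snp_tol`); a planted ingroup indel is
#' recovered when a called event of the same length lies within
#' `indel_tol` bp (alignment normalization can slide a gap through
#' repeated sequence, so the tolerance is generous for tandem context).
#' Carrier and context correctness are evaluated over recovered indels.
#'
#' @param truth a `MutationTruth`.
#' @param indels called `IndelEvents` (classified).
#' @param snps called `SnpEvents`.
#' @param snp_tol,indel_tol matching tolerances in bp.
#' @return list with counts and the `recovery`, `carrier_acc`,
#'   `context_acc` fractions.
#' @export
recovery_stats <- function(truth, indels, snps, snp_tol = 2L,
                           indel_tol = 60L) {
  ev <- truth$events
  ev <- ev[ev$lineage %in% c("A", "B"), , drop = FALSE]
  tsub <- ev[ev$kind == "substitution", , drop = FALSE]
  tind <- ev[ev$kind != "substitution", , drop = FALSE]

  sub_hit <- vapply(seq_len(nrow(tsub)), function(i)
    any(abs(snps$posA - tsub$posA[i]) <= snp_tol), logical(1))

  used <- rep(FALSE, nrow(indels))
  ind_hit <- logical(nrow(tind)); ind_match <- rep(NA_integer_, nrow(tind))
  if (nrow(tind)) for (i in order(tind$length, decreasing = TRUE)) {
    cand <- which(!used & indels$length == tind$length[i] &
                    abs(indels$posA - tind$posA[i]) <= indel_tol)
    if (length(cand)) {
      j <- cand[which.min(abs(indels$posA[cand] - tind$posA[i]))]
      used[j] <- TRUE; ind_hit[i] <- TRUE; ind_match[i] <- j
    }
  }
  rec_ind <- which(ind_hit)
  carrier_ok <- vapply(rec_ind, function(i)
    indels$carrier[ind_match[i]] == tind$carrier[i], logical(1))
  context_ok <- vapply(rec_ind, function(i)
    indels$context[ind_match[i]] == tind$context[i], logical(1))

  n_planted <- nrow(tsub) + nrow(tind)
  n_rec <- sum(sub_hit) + sum(ind_hit)
  list(
    n_planted = n_planted, n_recovered = n_rec,
    n_sub = nrow(tsub), n_sub_recovered = sum(sub_hit),
    n_indel = nrow(tind), n_indel_recovered = sum(ind_hit),
    recovery = if (n_planted) n_rec / n_planted else NA_real_,
    carrier_acc = if (length(rec_ind)) mean(carrier_ok) else NA_real_,
    context_acc = if (length(rec_ind)) mean(context_ok) else NA_real_)
}
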
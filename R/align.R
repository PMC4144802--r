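## pairwise alignment: exact affine-gap DP for short regions, k-mer anchored
## chaining for whole plastomes, and three-row threading of an outgroup.

#' Alignment scoring scheme
#'
#' Defaults favor contiguous gap runs so that tandem and slippage indels
#' surface as single events rather than scattered single-base gaps.
#'
#' @param match,mismatch per-column scores.
#' @param gap_open penalty charged once per gap run (negative).
#' @param gap_extend penalty per gap base (negative); a run of length L
#'   scores `gap_open + L * gap_extend`.
#' @return list of class `SchemeParams`.
#' @export
scheme_params <- function(match = 1, mismatch = -2, gap_open = -5,
                          gap_extend = -1) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "SchemeParams")
}

## substitution matrix over A,C,G,T,N: N columns score 0 against anything
scheme_matrix <- function(scoring) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- scoring$match
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

#' Construct an aligned pair
#'
#' Validates the pairwise-alignment invariants: equal gapped lengths, no
#' column gapped in both rows, and exact gap-stripping round trip against
#' the supplied source sequences. The score is always recomputed from the
#' gapped rows under `scoring`, so scores are comparable across the exact
#' and anchored aligners.
#'
#' @param gappedA,gappedB equal-length gapped sequences over `A,C,G,T,N,-`.
#' @param labelA,labelB sequence labels.
#' @param scoring a [scheme_params()] object.
#' @return object of class `AlignedPair` with per-column 0-based coordinate
#'   maps `colmapA`/`colmapB` (`NA` at gap columns).
#' @export
aligned_pair <- function(gappedA, gappedB, labelA = "A", labelB = "B",
                         scoring = scheme_params()) {
  if (nchar(gappedA) != nchar(gappedB))
    stop("gapped rows differ in length")
  ca <- str2chars(gappedA); cb <- str2chars(gappedB)
  if (any(ca == "-" & cb == "-")) stop("column gapped in both rows")
  colmapA <- cumsum(ca != "-") - 1L; colmapA[ca == "-"] <- NA_integer_
  colmapB <- cumsum(cb != "-") - 1L; colmapB[cb == "-"] <- NA_integer_
  structure(
    list(labelA = labelA, labelB = labelB,
         gappedA = gappedA, gappedB = gappedB,
         colmapA = colmapA, colmapB = colmapB,
         score = score_alignment(ca, cb, scoring),
         scoring = scoring),
    class = "AlignedPair")
}

#' @export
print.AlignedPair <- function(x, ...) {
  ca <- str2chars(x$gappedA); cb <- str2chars(x$gappedB)
  both <- ca != "-" & cb != "-"
  cat("AlignedPair ", x$labelA, " vs ", x$labelB, ": ",
      length(ca), " columns, score ", x$score,
      ", identity ", sprintf("%.4f", sum(ca == cb & both) / max(1, sum(both))),
      ", ", sum(ca == "-") + sum(cb == "-"), " gap bases\n", sep = "")
  invisible(x)
}

## score from gapped rows: per-run affine gaps
score_alignment <- function(ca, cb, scoring) {
  both <- ca != "-" & cb != "-"
  n_match <- sum(both & ca == cb & ca != "N")
  n_mm <- sum(both & ca != cb & ca != "N" & cb != "N")
  runs_a <- nrow(true_runs(ca == "-")); gaps_a <- sum(ca == "-")
  runs_b <- nrow(true_runs(cb == "-")); gaps_b <- sum(cb == "-")
  n_match * scoring$match + n_mm * scoring$mismatch +
    (runs_a + runs_b) * scoring$gap_open +
    (gaps_a + gaps_b) * scoring$gap_extend
}

## strip gaps from a gapped row
degap <- function(g) gsub("-", "", g, fixed = TRUE)

#' Exact global alignment (affine gaps)
#'
#' Optimal Needleman-Wunsch alignment with affine gap penalties, for regions
#' up to `dp_limit` bp. Gap runs are subsequently left-normalized inside
#' repeated context (see [normalize_gaps()]), which makes indel coordinates
#' deterministic and stable for context classification.
#'
#' @param seqA,seqB non-empty DNA strings.
#' @param scoring a [scheme_params()].
#' @param dp_limit maximum sequence length for direct DP.
#' @param labelA,labelB labels carried into the result.
#' @return an [aligned_pair()].
#' @export
align_global <- function(seqA, seqB, scoring = scheme_params(),
                         dp_limit = 50000L, labelA = "A", labelB = "B") {
  if (!nchar(seqA) || !nchar(seqB)) stop("sequences must be non-empty")
  if (nchar(seqA) > dp_limit || nchar(seqB) > dp_limit)
    stop("sequence exceeds direct-DP limit (", dp_limit,
         " bp); use align_anchored()")
  aln <- Biostrings::pairwiseAlignment(
    seqA, seqB, type = "global",
    substitutionMatrix = scheme_matrix(scoring),
    gapOpening = abs(scoring$gap_open),
    gapExtension = abs(scoring$gap_extend))
  gA <- as.character(Biostrings::alignedPattern(aln))
  gB <- as.character(Biostrings::alignedSubject(aln))
  norm <- normalize_gaps(gA, gB)
  aligned_pair(norm$gA, norm$gB, labelA, labelB, scoring)
}

#' Left-normalize gap runs
#'
#' Shifts every gap run leftward while the shift preserves both ungapped
#' sequences and the alignment score (i.e. within homopolymer or repeated
#' context: the last base of the run's partner-row segment equals the base
#' in the preceding match column). This is the pairwise-alignment analogue
#' of VCF indel left-normalization.
#'
#' @param gA,gB gapped rows of equal length.
#' @return list with normalized `gA`, `gB`.
#' @export
normalize_gaps <- function(gA, gB) {
  ca <- str2chars(gA); cb <- str2chars(gB)
  shift_row <- function(gap_row, base_row) {
    # gap_row holds the gaps, base_row the extra bases
    runs <- true_runs(gap_row == "-")
    if (!nrow(runs)) return(list(gap_row, base_row))
    for (r in seq_len(nrow(runs))) {
      i <- runs[r, "start"]; j <- runs[r, "end"]
      while (i > 1L &&
             gap_row[i - 1L] != "-" && base_row[i - 1L] != "-" &&
             gap_row[i - 1L] == base_row[i - 1L] &&       # match column
             base_row[j] == base_row[i - 1L]) {
        # slide the gap left: the matched base moves to the run's right end;
        # the partner row keeps its characters in place
        gap_row[j] <- gap_row[i - 1L]
        gap_row[i - 1L] <- "-"
        i <- i - 1L; j <- j - 1L
      }
    }
    list(gap_row, base_row)
  }
  res <- shift_row(ca, cb); ca <- res[[1]]; cb <- res[[2]]
  res <- shift_row(cb, ca); cb <- res[[1]]; ca <- res[[2]]
  list(gA = chars2str(ca), gB = chars2str(cb))
}

## unique-in-both k-mer anchors collapsed into maximal exact diagonal blocks;
## returns data.frame(iA, iB, len) with 1-based starts, or NULL
anchor_blocks <- function(seqA, seqB, k) {
  nA <- nchar(seqA) - k + 1L; nB <- nchar(seqB) - k + 1L
  if (nA < 1L || nB < 1L) return(NULL)
  kA <- substring(seqA, 1:nA, k:nchar(seqA))
  kB <- substring(seqB, 1:nB, k:nchar(seqB))
  uA <- !(duplicated(kA) | duplicated(kA, fromLast = TRUE))
  uB <- !(duplicated(kB) | duplicated(kB, fromLast = TRUE))
  iA <- which(uA)
  pos <- match(kA[iA], kB)
  ok <- !is.na(pos) & uB[ifelse(is.na(pos), 1L, pos)]
  iA <- iA[ok]; iB <- pos[ok]
  if (!length(iA)) return(NULL)
  o <- order(iA)
  iA <- iA[o]; iB <- iB[o]
  # collapse runs advancing by +1 on both coordinates into blocks
  newblk <- c(TRUE, !(diff(iA) == 1L & diff(iB) == 1L))
  grp <- cumsum(newblk)
  starts <- !duplicated(grp)
  len <- as.integer(tapply(iA, grp, length)) + k - 1L
  data.frame(iA = iA[starts], iB = iB[starts], len = len)
}

## heaviest strictly-increasing chain of blocks (O(n^2); block counts are
## small because near-identical genomes collapse to few blocks)
chain_blocks <- function(bl) {
  n <- nrow(bl)
  o <- order(bl$iA, bl$iB)
  bl <- bl[o, ]
  dp <- as.numeric(bl$len); prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (bl$iA[j] < bl$iA[i] && bl$iB[j] < bl$iB[i] &&
          dp[j] + bl$len[i] > dp[i]) {
        dp[i] <- dp[j] + bl$len[i]; prev[i] <- j
      }
    }
  }
  best <- which.max(dp)
  chain <- integer()
  while (!is.na(best)) { chain <- c(best, chain); best <- prev[best] }
  out <- bl[chain, ]
  # trim overlaps so successive blocks are disjoint on both coordinates
  if (nrow(out) > 1) for (i in 2:nrow(out)) {
    lag <- out[i - 1L, ]
    cut <- max(lag$iA + lag$len - out$iA[i], lag$iB + lag$len - out$iB[i], 0L)
    out$iA[i] <- out$iA[i] + cut; out$iB[i] <- out$iB[i] + cut
    out$len[i] <- out$len[i] - cut
  }
  out[out$len > 0L, ]
}

#' Anchored global alignment for long sequences
#'
#' Chains k-mers that occur exactly once in each sequence into the heaviest
#' collinear block chain, closes the inter-anchor gaps with [align_global()]
#' and concatenates. Repetitive regions (e.g. tandem arrays) carry no unique
#' k-mers and are closed by exact DP between the flanking anchors.
#'
#' @param seqA,seqB DNA strings.
#' @param k anchor word size (default 21, plastome-scale unique).
#' @param scoring a [scheme_params()].
#' @param dp_limit maximum inter-anchor (or whole-sequence fallback) span
#'   for exact DP.
#' @param labelA,labelB labels.
#' @return an [aligned_pair()].
#' @export
align_anchored <- function(seqA, seqB, k = 21L, scoring = scheme_params(),
                           dp_limit = 50000L, labelA = "A", labelB = "B") {
  if (!nchar(seqA) || !nchar(seqB)) stop("sequences must be non-empty")
  bl <- anchor_blocks(seqA, seqB, k)
  if (is.null(bl) || !nrow(bl)) {
    if (nchar(seqA) <= dp_limit && nchar(seqB) <= dp_limit)
      return(align_global(seqA, seqB, scoring, dp_limit, labelA, labelB))
    stop("no collinear chain: sequences share no unique ", k,
         "-mer anchor and exceed the DP limit")
  }
  ch <- chain_blocks(bl)
  pieces_a <- character(); pieces_b <- character()
  posA <- 1L; posB <- 1L
  emit_gap <- function(a0, a1, b0, b1) {
    # align seqA[a0..a1] vs seqB[b0..b1] (1-based inclusive, may be empty)
    sa <- if (a1 >= a0) substr(seqA, a0, a1) else ""
    sb <- if (b1 >= b0) substr(seqB, b0, b1) else ""
    if (!nchar(sa) && !nchar(sb)) return(list("", ""))
    if (!nchar(sa)) return(list(strrep("-", nchar(sb)), sb))
    if (!nchar(sb)) return(list(sa, strrep("-", nchar(sa))))
    if (nchar(sa) > dp_limit || nchar(sb) > dp_limit)
      stop("inter-anchor span exceeds DP limit (", dp_limit, " bp)")
    sub <- align_global(sa, sb, scoring, dp_limit)
    list(sub$gappedA, sub$gappedB)
  }
  for (i in seq_len(nrow(ch))) {
    g <- emit_gap(posA, ch$iA[i] - 1L, posB, ch$iB[i] - 1L)
    pieces_a <- c(pieces_a, g[[1]]); pieces_b <- c(pieces_b, g[[2]])
    blk <- substr(seqA, ch$iA[i], ch$iA[i] + ch$len[i] - 1L)
    pieces_a <- c(pieces_a, blk); pieces_b <- c(pieces_b, blk)
    posA <- ch$iA[i] + ch$len[i]; posB <- ch$iB[i] + ch$len[i]
  }
  g <- emit_gap(posA, nchar(seqA), posB, nchar(seqB))
  pieces_a <- c(pieces_a, g[[1]]); pieces_b <- c(pieces_b, g[[2]])
  norm <- normalize_gaps(paste(pieces_a, collapse = ""),
                         paste(pieces_b, collapse = ""))
  out <- aligned_pair(norm$gA, norm$gB, labelA, labelB, scoring)
  if (degap(out$gappedA) != seqA || degap(out$gappedB) != seqB)
    stop("internal error: anchored alignment failed round-trip")
  out
}

#' Align two sequences, choosing exact or anchored automatically
#' @inheritParams align_anchored
#' @param small_limit direct DP is used when both inputs are at most this
#'   long.
#' @return an [aligned_pair()].
#' @export
align_auto <- function(seqA, seqB, scoring = scheme_params(),
                       small_limit = 5000L, k = 21L, dp_limit = 50000L,
                       labelA = "A", labelB = "B") {
  if (nchar(seqA) <= small_limit && nchar(seqB) <= small_limit)
    align_global(seqA, seqB, scoring, dp_limit, labelA, labelB)
  else align_anchored(seqA, seqB, k, scoring, dp_limit, labelA, labelB)
}

#' Thread an outgroup onto a pairwise alignment
#'
#' Aligns A against B, then aligns the outgroup independently against each
#' genome and threads its bases onto the A-B columns: columns where A has a
#' base take the outgroup base aligned to that A position, gap-in-A columns
#' take the outgroup base aligned to the B position carrying the extra base.
#' Each column is labeled with the outgroup state used to polarize indels:
#' `A-like`/`B-like` (outgroup matches one row), `both` (uninformative,
#' all three agree), `other` (outgroup differs from both) or `gap`.
#' At a gap column the outgroup state is `carrier-like` when the outgroup
#' also holds a base there and `noncarrier-like` when it lacks one.
#'
#' @param seqA,seqB,outgroup DNA strings covering the same homologous
#'   region.
#' @param scoring a [scheme_params()].
#' @param ... passed to [align_auto()].
#' @return object of class `TripletAlignment`: the A-B `AlignedPair`, the
#'   threaded `gappedO` row, per-column `states`, and the two
#'   outgroup alignments. When the outgroup fails to anchor, `gappedO` is
#'   all-gap and every state is `"gap"` (downstream polarity `"unknown"`).
#' @export
align_triplet <- function(seqA, seqB, outgroup, scoring = scheme_params(),
                          ...) {
  pair <- align_auto(seqA, seqB, scoring = scoring, ...)
  oa <- tryCatch(align_auto(outgroup, seqA, scoring = scoring, ...),
                 error = function(e) NULL)
  ob <- tryCatch(align_auto(outgroup, seqB, scoring = scoring, ...),
                 error = function(e) NULL)
  ncol <- nchar(pair$gappedA)
  if (is.null(oa) || is.null(ob)) {
    warning("outgroup failed anchoring; indel polarity will be 'unknown'")
    return(structure(list(pair = pair, gappedO = strrep("-", ncol),
                          states = rep("gap", ncol),
                          pairOA = NULL, pairOB = NULL),
                     class = "TripletAlignment"))
  }
  # outgroup base over each A (resp. B) source position
  o_over <- function(p) {
    co <- str2chars(p$gappedA)          # outgroup row
    ct <- str2chars(p$gappedB)          # target genome row
    out <- rep("-", sum(ct != "-"))
    out[p$colmapB[ct != "-"] + 1L] <- co[ct != "-"]
    out
  }
  oA <- o_over(oa); oB <- o_over(ob)
  ca <- str2chars(pair$gappedA); cb <- str2chars(pair$gappedB)
  oc <- ifelse(!is.na(pair$colmapA), oA[pair$colmapA + 1L],
               oB[pair$colmapB + 1L])
  states <- vapply(seq_len(ncol), function(i) {
    a <- ca[i]; b <- cb[i]; o <- oc[i]
    if (a != "-" && b != "-") {
      if (o == "-") return("gap")
      if (o == a && o == b) return("both")
      if (o == a) return("A-like")
      if (o == b) return("B-like")
      return("other")
    }
    carrier_like <- if (a == "-") "B-like" else "A-like"
    noncarrier_like <- if (a == "-") "A-like" else "B-like"
    # carrier holds the extra base at this column
    if (o != "-") carrier_like else noncarrier_like
  }, character(1))
  structure(list(pair = pair, gappedO = chars2str(oc), states = states,
                 pairOA = oa, pairOB = ob),
            class = "TripletAlignment")
}

#' @export
print.TripletAlignment <- function(x, ...) {
  cat("TripletAlignment over", nchar(x$pair$gappedA), "columns; states:\n")
  print(table(x$states))
  invisible(x)
}

#' Export a pairwise alignment as aligned FASTA
#' @param aln an `AlignedPair`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(aln, path) {
  x <- Biostrings::BStringSet(c(aln$gappedA, aln$gappedB))
  names(x) <- c(aln$labelA, aln$labelB)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
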
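## tandem repeat arrays, hairpin folding of short palindromic units,
## per-position consensus profiles, and dot-plot matrices.

#' The canonical 19 bp repeat unit
#'
#' Phase anchor used to orient 19 bp tandem-array copies: the consensus
#' hairpin-forming unit of the hypervariable trnY-trnE intergenic spacer.
#' @export
CANONICAL_UNIT_19 <- "TATGGATTTCTTGTCCATA"

#' Find tandem arrays of short repeat units
#'
#' Period detection by lagged self-comparison: for each candidate unit
#' length `p` the sequence is compared against itself shifted by `p`, and
#' maximal regions whose rolling per-period identity stays at or above
#' `min_identity` become candidate arrays. Candidates are accepted greedily,
#' highest copy count first, without overlap. Copies are chopped in phase
#' from the array start; 19 bp arrays are re-phased to the canonical unit
#' [CANONICAL_UNIT_19] when that improves the consensus match.
#'
#' @param seq DNA string.
#' @param unit_range integer `c(min, max)` unit lengths to scan.
#' @param min_copies minimum number of full copies.
#' @param min_identity minimum identity of the region to its own
#'   period-shifted self (and of retained edge copies to the consensus).
#' @return list of `RepeatArray` objects, highest copy count first. Each has
#'   `region` (0-based half-open interval), `unit_length`, `copies` (a
#'   data.frame with `start`, `end`, `seq`, `identity`), `consensus` and
#'   `mean_copy_identity`.
#' @export
find_tandem_arrays <- function(seq, unit_range = c(10L, 30L),
                               min_copies = 3L, min_identity = 0.8) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 2L * unit_range[1]) return(list())
  ch <- utf8ToInt(seq)
  cands <- list()
  for (p in unit_range[1]:unit_range[2]) {
    if (n < 2L * p) next
    eq <- as.integer(ch[1:(n - p)] == ch[(p + 1):n])
    if (length(eq) < p) next
    cs <- c(0L, cumsum(eq))
    win <- (cs[(p + 1):length(cs)] - cs[1:(length(cs) - p)]) / p
    runs <- true_runs(win >= min_identity)
    if (!nrow(runs)) next
    for (r in seq_len(nrow(runs))) {
      start <- runs[r, "start"]                  # 1-based
      span <- runs[r, "end"] - start + 2L * p    # through last partner base
      span <- min(span, n - start + 1L)
      copies <- span %/% p
      if (copies >= min_copies)
        cands[[length(cands) + 1L]] <-
          list(start = start, p = p, copies = copies, span = copies * p)
    }
  }
  if (!length(cands)) return(list())
  ord <- order(-vapply(cands, `[[`, 0L, "copies"),
               vapply(cands, `[[`, 0L, "p"),
               vapply(cands, `[[`, 0L, "start"))
  taken <- logical(n)
  out <- list()
  for (cd in cands[ord]) {
    span_idx <- cd$start:(cd$start + cd$span - 1L)
    if (any(taken[span_idx])) next
    arr <- build_array(seq, cd$start, cd$p, cd$copies, min_identity)
    if (is.null(arr) || nrow(arr$copies) < min_copies) next
    region_idx <- (arr$region[1] + 1L):arr$region[2]
    if (any(taken[region_idx])) next           # extension hit an earlier array
    taken[region_idx] <- TRUE
    out[[length(out) + 1L]] <- arr
  }
  out[order(-vapply(out, function(a) nrow(a$copies), 0L))]
}

## chop copies, compute consensus, trim low-identity edge copies, re-phase
## 19-mers to the canonical unit; start is 1-based
build_array <- function(seq, start, p, copies, min_identity) {
  chop <- function(s0) {
    k <- ((nchar(seq) - s0 + 1L) %/% p)
    k <- min(k, copies + 1L)                     # allow one extra at the end
    if (k < 2L) return(NULL)
    starts <- s0 + (0:(k - 1L)) * p
    data.frame(start = starts - 1L, end = starts - 1L + p,
               seq = substring(seq, starts, starts + p - 1L),
               stringsAsFactors = FALSE)
  }
  ident_to <- function(u, cons) mean(str2chars(u) == str2chars(cons))
  # extend copy-by-copy outward while new copies stay within min_identity
  # of the running consensus (tolerates alternating unit variants whose
  # adjacent-copy identity dips below the seeding threshold)
  extend <- function(cp, cons) {
    repeat {
      s0 <- cp$start[1] - p + 1L               # 1-based candidate start
      if (s0 < 1L) break
      u <- substr(seq, s0, s0 + p - 1L)
      if (ident_to(u, cons) < min_identity) break
      cp <- rbind(data.frame(start = s0 - 1L, end = s0 - 1L + p, seq = u,
                             stringsAsFactors = FALSE), cp)
      cons <- majority_consensus(cp$seq)
    }
    repeat {
      s0 <- cp$end[nrow(cp)] + 1L
      if (s0 + p - 1L > nchar(seq)) break
      u <- substr(seq, s0, s0 + p - 1L)
      if (ident_to(u, cons) < min_identity) break
      cp <- rbind(cp, data.frame(start = s0 - 1L, end = s0 - 1L + p,
                                 seq = u, stringsAsFactors = FALSE))
      cons <- majority_consensus(cp$seq)
    }
    list(cp = cp, cons = cons)
  }
  cp <- chop(start)
  if (is.null(cp)) return(NULL)
  cons <- majority_consensus(cp$seq)
  if (p == 19L) {
    sc <- vapply(0:18, function(r) {
      rot <- paste0(substr(cons, r + 1L, 19L), substr(cons, 1L, r))
      sum(str2chars(rot) == str2chars(CANONICAL_UNIT_19))
    }, numeric(1))
    r <- which.max(sc) - 1L
    if (r > 0L && start + r + p - 1L <= nchar(seq)) {
      cp2 <- chop(start + r)
      if (!is.null(cp2) && nrow(cp2) >= 2L) {
        cp <- cp2
        cons <- majority_consensus(cp$seq)
      }
    }
  }
  ext <- extend(cp, cons)
  cp <- ext$cp; cons <- ext$cons
  ident <- vapply(cp$seq, function(u)
    mean(str2chars(u) == str2chars(cons)), numeric(1))
  cp$identity <- unname(ident)
  # trim trailing/leading copies that have drifted below the threshold
  while (nrow(cp) > 2L && cp$identity[nrow(cp)] < min_identity)
    cp <- cp[-nrow(cp), ]
  while (nrow(cp) > 2L && cp$identity[1] < min_identity)
    cp <- cp[-1, ]
  cons <- majority_consensus(cp$seq)
  cp$identity <- vapply(cp$seq, function(u)
    mean(str2chars(u) == str2chars(cons)), numeric(1))
  rownames(cp) <- NULL
  structure(list(
    region = c(cp$start[1], cp$end[nrow(cp)]),
    unit_length = p, copies = cp, consensus = cons,
    mean_copy_identity = mean(cp$identity)),
    class = "RepeatArray")
}

majority_consensus <- function(units) {
  m <- do.call(rbind, strsplit(units, "", fixed = TRUE))
  chars2str(apply(m, 2, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    # ties broken alphabetically
    cands <- names(tb)[tb == tb[1]]
    sort(cands)[1]
  }))
}

#' @export
print.RepeatArray <- function(x, ...) {
  cat("RepeatArray: unit ", x$unit_length, " bp x ", nrow(x$copies),
      " copies at [", x$region[1], ",", x$region[2], "), consensus ",
      x$consensus, ", mean identity ",
      sprintf("%.3f", x$mean_copy_identity), "\n", sep = "")
  invisible(x)
}

#' Fold a repeat unit into a terminal-inward hairpin
#'
#' Pairs position `i` with position `L + 1 - i` from the ends inward,
#' accepting Watson-Crick pairs plus the G:T wobble by default, and stops at
#' the first disallowed pair or when the unpaired middle would drop below
#' `min_loop`. This is a complementarity scan, not a thermodynamic fold.
#'
#' @param unit DNA string of length at least `min_loop + 2`.
#' @param allowed_pairs character vector of allowed unordered pairs.
#' @param min_loop minimum loop length (default 3 nt).
#' @return object of class `HairpinFold`: `stem_length`, `loop`, `pairs`
#'   (matrix of 1-based paired positions), `wobble_count`.
#' @export
fold_hairpin <- function(unit, allowed_pairs = c("AT", "GC", "GT"),
                         min_loop = 3L) {
  unit <- toupper(unit)
  L <- nchar(unit)
  if (L < min_loop + 2L) stop("unit shorter than min_loop + 2")
  allowed <- unique(c(allowed_pairs,
                      vapply(strsplit(allowed_pairs, ""), function(x)
                        paste(rev(x), collapse = ""), character(1))))
  ch <- str2chars(unit)
  s <- 0L; wob <- 0L; pairs <- NULL
  while (L - 2L * (s + 1L) >= min_loop) {
    i <- s + 1L; j <- L - s
    pr <- paste0(ch[i], ch[j])
    if (!pr %in% allowed) break
    if (pr %in% c("GT", "TG")) wob <- wob + 1L
    pairs <- rbind(pairs, c(i, j))
    s <- s + 1L
  }
  loop <- if (s < L - s) substr(unit, s + 1L, L - s) else ""
  structure(list(stem_length = s, loop = loop,
                 pairs = pairs %||% matrix(integer(), ncol = 2),
                 wobble_count = wob),
            class = "HairpinFold")
}

#' @export
print.HairpinFold <- function(x, ...) {
  cat("HairpinFold: stem ", x$stem_length, " bp (", x$wobble_count,
      " wobble), loop ", x$loop, "\n", sep = "")
  invisible(x)
}

#' Classify a repeat unit's hairpin form
#'
#' `A` iff the loop is `TTCTT`, `B` iff `TTTAA`, else `other` — the two
#' predominant loop variants of the 19 bp unit (both share the TATGGAT
#' stem). The A/B forms are defined on the consensus structure, a 7 bp stem
#' closing a 5 nt loop, so classification folds with `min_loop = 5`: on a
#' 19-mer this caps the stem at 7 and reads positions 8-12 as the loop.
#' (Under the maximal-pairing rule with a 3 nt loop floor the B form's
#' terminal T:A contact would extend the stem to 8 and hide its loop.)
#'
#' @param unit DNA string.
#' @param fold optional precomputed [fold_hairpin()] result; when missing,
#'   the unit is folded with `min_loop = 5`.
#' @param ... passed to [fold_hairpin()] when `fold` is missing.
#' @return `"A"`, `"B"` or `"other"`.
#' @export
classify_form <- function(unit, fold = NULL, ...) {
  if (is.null(fold)) fold <- fold_hairpin(unit, min_loop = 5L, ...)
  switch(fold$loop, TTCTT = "A", TTTAA = "B", "other")
}

#' Per-position consensus profile of aligned repeat copies
#'
#' @param copies character vector of at least two equal-length units
#'   (copies bearing internal indels must be excluded or phase-aligned
#'   upstream).
#' @return object of class `ConsensusProfile`: `unit_length`, `freq`
#'   (position x A/C/G/T frequency matrix, rows summing to 1), `consensus`
#'   (majority, ties alphabetical), `invariable_positions` (1-based
#'   positions with a single observed base), `n_copies`.
#' @export
consensus_profile <- function(copies) {
  if (length(copies) < 2L) stop("need at least two copies")
  lens <- nchar(copies)
  if (length(unique(lens)) != 1L)
    stop("copies have mixed lengths; phase-align or exclude ",
         "indel-bearing copies first")
  m <- do.call(rbind, strsplit(toupper(copies), "", fixed = TRUE))
  bases <- c("A", "C", "G", "T")
  freq <- t(apply(m, 2, function(col) {
    tb <- table(factor(col, bases))
    as.numeric(tb) / length(col)
  }))
  colnames(freq) <- bases
  structure(list(
    unit_length = lens[1],
    freq = freq,
    consensus = majority_consensus(copies),
    invariable_positions = which(apply(freq, 1, function(r) any(r == 1))),
    n_copies = length(copies)),
    class = "ConsensusProfile")
}

#' @export
print.ConsensusProfile <- function(x, ...) {
  cat("ConsensusProfile over ", x$n_copies, " copies of ", x$unit_length,
      " bp: ", x$consensus, "\n  invariable positions: ",
      paste(x$invariable_positions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Dot-plot match matrix
#'
#' Sliding-window comparison: an entry at `(i, j)` (0-based window starts)
#' means the `window`-bp windows of `seqX` at `i` and `seqY` at `j` agree at
#' `min_matches` or more positions. Computed per diagonal with rolling
#' sums.
#'
#' @param seqX,seqY DNA strings.
#' @param window window size in bp (default 19, the repeat-unit scale).
#' @param min_matches match threshold within a window (default 15, ~80%).
#' @return data.frame with 0-based columns `i`, `j`.
#' @export
dotplot <- function(seqX, seqY, window = 19L, min_matches = 15L) {
  x <- utf8ToInt(toupper(seqX)); y <- utf8ToInt(toupper(seqY))
  nx <- length(x); ny <- length(y)
  if (window > nx || window > ny) stop("window exceeds a sequence length")
  res_i <- list(); res_j <- list(); idx <- 0L
  for (d in (-(nx - window)):(ny - window)) {
    xs <- max(1L, 1L - d); ys <- xs + d
    len <- min(nx - xs, ny - ys) + 1L
    if (len < window) next
    eq <- as.integer(x[xs:(xs + len - 1L)] == y[ys:(ys + len - 1L)])
    cs <- c(0L, cumsum(eq))
    wsum <- cs[(window + 1L):(len + 1L)] - cs[1:(len - window + 1L)]
    hit <- which(wsum >= min_matches)
    if (length(hit)) {
      idx <- idx + 1L
      res_i[[idx]] <- xs + hit - 2L              # 0-based window starts
      res_j[[idx]] <- ys + hit - 2L
    }
  }
  data.frame(i = as.integer(unlist(res_i)), j = as.integer(unlist(res_j)))
}

#' Dispersed repeat scan (forward and palindromic)
#'
#' Thin exhaustive window scan reporting repeated window pairs of at least
#' `min_len` bp within `hamming` mismatches, on the forward strand and
#' against the reverse complement (palindromic). Built on [dotplot()];
#' self-matches on the main diagonal are removed for the forward scan.
#'
#' @param seq DNA string.
#' @param min_len minimum repeat length (default 10).
#' @param hamming maximum mismatches (default 3).
#' @return list with data.frames `forward` and `palindromic` of 0-based
#'   window-start pairs `i < j`.
#' @export
dispersed_repeats <- function(seq, min_len = 10L, hamming = 3L) {
  fw <- dotplot(seq, seq, window = min_len,
                min_matches = min_len - hamming)
  fw <- fw[fw$i < fw$j, , drop = FALSE]
  pal <- dotplot(seq, revcomp(seq), window = min_len,
                 min_matches = min_len - hamming)
  n <- nchar(seq)
  # map the revcomp coordinate back onto the forward strand
  pal$j <- n - pal$j - min_len
  pal <- pal[pal$i < pal$j, , drop = FALSE]
  rownames(fw) <- rownames(pal) <- NULL
  list(forward = fw, palindromic = pal)
}

#' Export a repeat array as TSV (per-copy table)
#' @param array a `RepeatArray`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_repeat_tsv <- function(array, path) {
  utils::write.table(array$copies, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a consensus profile as TSV (position x base frequency)
#' @param profile a `ConsensusProfile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  tab <- data.frame(position = seq_len(profile$unit_length),
                    profile$freq,
                    consensus = str2chars(profile$consensus),
                    invariable = seq_len(profile$unit_length) %in%
                      profile$invariable_positions)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
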
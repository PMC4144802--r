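## genome model: annotated plastomes, quadripartite segments, features.
## Coordinates are 0-based half-open everywhere internally; 1-based only at
## the FASTA/GenBank/VCF boundaries.

#' Construct an annotated plastome
#'
#' An `AnnotatedPlastome` is a lightweight record holding one circular
#' chloroplast genome linearized at its conventional origin (a single-copy
#' region start), its quadripartite segments (LSC, SSC, IRa, IRb) and its
#' feature annotation (CDS, tRNA, rRNA, intron, IGS).
#'
#' @param id character label.
#' @param sequence DNA string over `A,C,G,T,N` (uppercased on input).
#' @param circular logical; plastomes are circular, stored linearized.
#' @param segments `NULL` or a data.frame with columns `name` (one of
#'   LSC/SSC/IRa/IRb), `start`, `end` (0-based half-open) that tile
#'   `[0, length)` disjointly.
#' @param features `NULL` or a data.frame with columns `kind` (CDS, tRNA,
#'   rRNA, intron, IGS), `name`, `start`, `end` (0-based half-open, one row
#'   per interval; multi-interval features share a `name`), `strand`
#'   (`+`/`-`) and logical `degenerate` (CDS whose total length is not a
#'   multiple of 3; excluded from synonymy calls).
#' @param ir_mismatch_tolerance maximum Hamming mismatches allowed between
#'   IRa and the reverse complement of IRb before validation fails.
#' @return an object of class `AnnotatedPlastome`.
#' @export
plastome <- function(id, sequence, circular = TRUE, segments = NULL,
                     features = NULL, ir_mismatch_tolerance = 10L) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGTN]*$", sequence))
    stop("sequence contains characters outside {A,C,G,T,N}")
  L <- nchar(sequence)
  if (is.null(features)) features <- empty_features()
  features <- validate_features(features, L)
  if (!is.null(segments)) validate_segments(segments, sequence,
                                            ir_mismatch_tolerance)
  structure(
    list(id = id, sequence = sequence, circular = circular,
         segments = segments, features = features),
    class = "AnnotatedPlastome")
}

empty_features <- function() {
  data.frame(kind = character(), name = character(),
             start = integer(), end = integer(),
             strand = character(), degenerate = logical(),
             stringsAsFactors = FALSE)
}

validate_features <- function(features, L) {
  req <- c("kind", "name", "start", "end", "strand")
  if (!all(req %in% names(features)))
    stop("features must have columns: ", paste(req, collapse = ", "))
  bad <- features$start < 0 | features$end > L | features$start >= features$end
  if (any(bad))
    stop("feature interval outside [0, genome length) or empty: ",
         paste(unique(features$name[bad]), collapse = ", "))
  if (is.null(features$degenerate)) features$degenerate <- FALSE
  # CDS total length (summed over a feature's intervals) must be divisible
  # by 3; otherwise the feature is flagged degenerate, not rejected
  is_cds <- features$kind == "CDS"
  if (any(is_cds)) {
    lens <- tapply(features$end[is_cds] - features$start[is_cds],
                   features$name[is_cds], sum)
    degen <- names(lens)[lens %% 3L != 0L]
    features$degenerate[is_cds & features$name %in% degen] <- TRUE
  }
  rownames(features) <- NULL
  features
}

validate_segments <- function(segments, sequence, tol = 10L) {
  L <- nchar(sequence)
  req <- c("name", "start", "end")
  if (!all(req %in% names(segments)))
    stop("segments must have columns name, start, end")
  if (!all(segments$name %in% c("LSC", "SSC", "IRa", "IRb")))
    stop("segment names must be LSC, SSC, IRa, IRb")
  if (any(segments$start >= segments$end)) stop("empty segment interval")
  o <- order(segments$start)
  s <- segments[o, ]
  if (s$start[1] != 0 || s$end[nrow(s)] != L ||
      (nrow(s) > 1 && any(s$start[-1] != s$end[-nrow(s)])))
    stop("segments must tile [0, genome length) exactly and disjointly")
  ira <- segments[segments$name == "IRa", ]
  irb <- segments[segments$name == "IRb", ]
  if (nrow(ira) == 1 && nrow(irb) == 1) {
    if ((ira$end - ira$start) != (irb$end - irb$start))
      stop("IRa and IRb lengths differ")
    a <- substr(sequence, ira$start + 1L, ira$end)
    b <- revcomp(substr(sequence, irb$start + 1L, irb$end))
    mm <- sum(str2chars(a) != str2chars(b))
    if (mm > tol)
      stop("IRa is not the reverse complement of IRb (", mm,
           " mismatches > tolerance ", tol, ")")
  }
  invisible(segments)
}

#' @export
print.AnnotatedPlastome <- function(x, ...) {
  cat("AnnotatedPlastome '", x$id, "': ", nchar(x$sequence), " bp",
      if (x$circular) " (circular, linearized)", "\n", sep = "")
  if (!is.null(x$segments)) {
    s <- x$segments[order(x$segments$start), ]
    cat("  segments: ",
        paste(sprintf("%s[%d,%d)", s$name, s$start, s$end), collapse = " "),
        "\n", sep = "")
  }
  if (nrow(x$features))
    cat("  features: ", nrow(x$features), " intervals (",
        paste(sprintf("%s=%d", names(table(x$features$kind)),
                      table(x$features$kind)), collapse = ", "),
        ")\n", sep = "")
  invisible(x)
}

#' Genome length of an annotated plastome
#' @param genome an `AnnotatedPlastome`.
#' @return integer length in bp.
#' @export
plastome_length <- function(genome) nchar(genome$sequence)

#' Read a plastome from FASTA (plus optional GenBank annotation)
#'
#' The FASTA file must contain exactly one record. When a GenBank flat file
#' is supplied its feature table is parsed for `CDS`, `tRNA`, `rRNA` and
#' `intron` features (`gene`/`product`/`locus_tag` qualifiers name the
#' feature); coordinates are converted from GenBank 1-based inclusive to the
#' package's 0-based half-open convention.
#'
#' @param fasta_path path to a single-record FASTA file.
#' @param annotation_path optional path to a GenBank flat file whose feature
#'   coordinates refer to the same sequence.
#' @param id optional label; defaults to the FASTA record name.
#' @return an [plastome()] object; `segments` is `NULL` until
#'   [detect_segments()] (or manual assignment) supplies it.
#' @export
read_plastome <- function(fasta_path, annotation_path = NULL, id = NULL) {
  set <- Biostrings::readDNAStringSet(fasta_path)
  if (length(set) != 1L)
    stop("FASTA must contain exactly one record, found ", length(set))
  seq <- as.character(set[[1]])
  id <- id %||% sub("\\s.*$", "", names(set)[1])
  feats <- if (!is.null(annotation_path)) {
    f <- read_genbank_features(annotation_path)
    over <- f$end > nchar(seq)
    if (any(over))
      stop("annotation coordinates exceed sequence length for feature(s): ",
           paste(unique(f$name[over]), collapse = ", "))
    f
  } else NULL
  plastome(id = id, sequence = toupper(gsub("[^ACGTNacgtn]", "N", seq)),
           features = feats)
}

## Minimal GenBank flat-file feature-table reader: location strings limited
## to the forms seen in organelle records — `a..b`, `complement(a..b)`,
## `join(a..b,c..d,...)` and `complement(join(...))`.
read_genbank_features <- function(path,
                                  kinds = c("CDS", "tRNA", "rRNA", "intron")) {
  lines <- readLines(path, warn = FALSE)
  fs <- grep("^FEATURES", lines)
  if (!length(fs)) stop("no FEATURES table in ", path)
  end <- grep("^(ORIGIN|//)", lines)
  end <- if (length(end)) min(end[end > fs[1]]) - 1L else length(lines)
  block <- lines[(fs[1] + 1L):end]

  recs <- list()
  key <- NULL; loc <- ""; quals <- character()
  flush <- function() {
    if (!is.null(key) && key %in% kinds)
      recs[[length(recs) + 1L]] <<- list(key = key, loc = loc, quals = quals)
  }
  for (ln in block) {
    if (grepl("^ {5}\\S", ln)) {            # new feature key line
      flush()
      key <- sub("^ {5}(\\S+).*$", "\\1", ln)
      loc <- sub("^ {5}\\S+\\s+", "", ln)
      quals <- character()
    } else if (grepl("^ {21}/", trimws(ln, "right"))) {
      quals <- c(quals, trimws(ln))
    } else if (!is.null(key) && !length(quals)) {
      loc <- paste0(loc, trimws(ln))        # continued location
    }
  }
  flush()

  if (!length(recs)) return(empty_features())
  rows <- lapply(recs, function(r) {
    strand <- if (grepl("complement", r$loc)) "-" else "+"
    inner <- gsub("complement\\(|join\\(|order\\(|\\)", "", r$loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
    m <- regmatches(parts, regexec("[<>]?(\\d+)\\.\\.[<>]?(\\d+)", parts))
    ok <- lengths(m) == 3L
    if (!any(ok)) return(NULL)
    starts <- as.integer(vapply(m[ok], `[`, "", 2L))
    ends <- as.integer(vapply(m[ok], `[`, "", 3L))
    nm <- qual_value(r$quals, "gene") %||%
      qual_value(r$quals, "locus_tag") %||%
      qual_value(r$quals, "product") %||% r$key
    data.frame(kind = r$key, name = nm, start = starts - 1L, end = ends,
               strand = strand, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  out$degenerate <- FALSE
  out
}

qual_value <- function(quals, what) {
  hit <- grep(paste0("^/", what, "="), quals, value = TRUE)
  if (!length(hit)) return(NULL)
  gsub("^/[^=]+=|\"", "", hit[1])
}

#' Detect the quadripartite LSC/SSC/IR architecture
#'
#' Finds the longest pair of reverse-complement repeats of at least `min_ir`
#' bp (the inverted repeats), labels the larger intervening single-copy
#' region LSC and the smaller SSC, and returns four segments tiling the
#' genome. The genome must be linearized so that a single-copy region starts
#' at position 0 (the conventional plastome origin); otherwise rotation is
#' suggested.
#'
#' Seeds are exact shared k-mers between the sequence and its reverse
#' complement, grouped on the anti-diagonal, then extended and trimmed under
#' the mismatch tolerance.
#'
#' @param genome an `AnnotatedPlastome`.
#' @param min_ir minimum IR length in bp.
#' @param tolerance maximum Hamming mismatches tolerated between the two IR
#'   copies.
#' @param k seed word size.
#' @return data.frame of four segments (`name`, `start`, `end`), ordered by
#'   `start`.
#' @export
detect_segments <- function(genome, min_ir = 500L, tolerance = 2L, k = 21L) {
  seq <- genome$sequence
  L <- nchar(seq)
  if (L <= 4L * min_ir)
    stop("sequence length must exceed 4 x min_ir")
  hit <- find_inverted_repeat(seq, min_ir, tolerance, k)
  if (is.null(hit)) stop("no IR detected (>= ", min_ir,
                         " bp reverse-complement pair); supply segments manually")
  s1 <- hit$s1; e1 <- hit$e1; s2 <- hit$s2; e2 <- hit$e2  # 0-based half-open
  if (s1 != 0 && e2 != L) {
    gap_mid <- s2 - e1
    gap_wrap <- (L - e2) + s1
    if (gap_wrap > 0 && gap_mid > 0 && s1 > 0)
      stop("IR copies found at [", s1, ",", e1, ") and [", s2, ",", e2,
           "), but the linearized origin falls inside a single-copy region ",
           "split across the ends; rotate the sequence so a single-copy ",
           "region starts at position 0")
  }
  segs <- if (e2 == L && s1 > 0) {
    # layout SC1 - IR - SC2 - IR
    sc1 <- c(0L, s1); sc2 <- c(e1, s2)
    sc_names <- if ((sc1[2] - sc1[1]) >= (sc2[2] - sc2[1])) c("LSC", "SSC")
                else c("SSC", "LSC")
    data.frame(
      name = c(sc_names[1], "IRa", sc_names[2], "IRb"),
      start = c(sc1[1], s1, sc2[1], s2),
      end = c(sc1[2], e1, sc2[2], e2))
  } else {
    stop("unsupported IR layout: copies at [", s1, ",", e1, ") and [",
         s2, ",", e2, ") do not leave a single-copy region at the origin")
  }
  validate_segments(segs, seq, tol = tolerance)
  segs
}

## longest reverse-complement repeat pair; returns 0-based half-open
## coordinates of both copies or NULL
find_inverted_repeat <- function(seq, min_ir, tolerance, k) {
  L <- nchar(seq)
  rc <- revcomp(seq)
  n <- L - k + 1L
  if (n < 1L) return(NULL)
  km_f <- substring(seq, 1:n, k:L)
  km_r <- substring(rc, 1:n, k:L)
  idx <- match(km_f, km_r)            # first match is enough for IR seeds
  has <- which(!is.na(idx))
  if (!length(has)) return(NULL)
  i <- has; j <- idx[has]             # 1-based starts in seq and rc
  # seq[i..i+k-1] == rc[j..j+k-1] == revcomp(seq[L-j-k+2 .. L-j+1])
  s2 <- L - j - k + 2L                # 1-based start of the partner in seq
  diagonal <- s2 - i                  # constant along one repeat pair
  best <- NULL
  for (d in unique(diagonal)) {
    ii <- sort(i[diagonal == d])
    # merge seed starts into runs (allow holes up to k from seed breakage)
    runs <- split(ii, cumsum(c(1L, diff(ii) > k)))
    for (r in runs) {
      a1 <- min(r); a2 <- max(r) + k - 1L       # copy 1, 1-based inclusive
      b1 <- a1 + d; b2 <- a2 + d                # copy 2
      if (b1 <= a2) {                           # overlapping: self-palindrome
        next
      }
      ext <- extend_ir(seq, a1, a2, b1, b2, tolerance)
      len <- ext$a2 - ext$a1 + 1L
      if (len >= min_ir && (is.null(best) || len > best$len))
        best <- list(len = len,
                     s1 = ext$a1 - 1L, e1 = ext$a2,
                     s2 = ext$b1 - 1L, e2 = ext$b2)
    }
  }
  best
}

## greedily extend copy1=[a1,a2], copy2=[b1,b2] (1-based inclusive, copy2 the
## revcomp partner: seq[a1+t] pairs with seq[b2-t]) outward while total
## mismatches <= tolerance, keeping the copies disjoint; each front is
## rolled back to its last matching pair so boundaries never end on an
## absorbed mismatch
extend_ir <- function(seq, a1, a2, b1, b2, tolerance) {
  ch <- str2chars(seq)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  mism <- 0L
  # outward on the left of copy1 / right of copy2
  steps <- logical(0)
  while (a1 > 1L && b2 < length(ch)) {
    ok <- comp[[ch[a1 - 1L]]] == ch[b2 + 1L]
    if (!ok && mism + 1L > tolerance) break
    if (!ok) mism <- mism + 1L
    steps <- c(steps, ok)
    a1 <- a1 - 1L; b2 <- b2 + 1L
  }
  while (length(steps) && !steps[length(steps)]) {
    a1 <- a1 + 1L; b2 <- b2 - 1L; mism <- mism - 1L
    steps <- steps[-length(steps)]
  }
  # inward side: right of copy1 / left of copy2
  steps <- logical(0)
  while (a2 + 1L < b1 && b1 > 1L) {
    ok <- comp[[ch[a2 + 1L]]] == ch[b1 - 1L]
    if (!ok && mism + 1L > tolerance) break
    if (!ok) mism <- mism + 1L
    steps <- c(steps, ok)
    a2 <- a2 + 1L; b1 <- b1 - 1L
  }
  while (length(steps) && !steps[length(steps)]) {
    a2 <- a2 - 1L; b1 <- b1 + 1L; mism <- mism - 1L
    steps <- steps[-length(steps)]
  }
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2)
}

#' Derive intergenic-spacer features from an annotation
#'
#' Maximal gaps between consecutive annotated (non-IGS) features become IGS
#' features named `"<left>-<right>"`; zero-length gaps are omitted. For a
#' circular genome the gap from the final feature across the origin back to
#' the first feature is included.
#'
#' @param genome an `AnnotatedPlastome` with at least one non-IGS feature.
#' @return data.frame of IGS features in the feature-table layout.
#' @export
derive_igs_features <- function(genome) {
  f <- genome$features[genome$features$kind != "IGS", , drop = FALSE]
  if (!nrow(f)) stop("genome has no annotated non-IGS features")
  L <- plastome_length(genome)
  # merge a feature's intervals to its span for gap purposes
  spans <- do.call(rbind, lapply(split(f, f$name), function(d)
    data.frame(name = d$name[1], start = min(d$start), end = max(d$end))))
  spans <- spans[order(spans$start), ]
  # drop spans nested inside an earlier span (e.g. introns inside genes)
  keep <- rep(TRUE, nrow(spans))
  hi <- spans$end[1]
  if (nrow(spans) > 1) for (i in 2:nrow(spans)) {
    if (spans$end[i] <= hi) keep[i] <- FALSE else hi <- spans$end[i]
  }
  spans <- spans[keep, ]
  n <- nrow(spans)
  out <- list()
  for (i in seq_len(n)) {
    left <- spans[i, ]
    right <- spans[if (i == n) 1L else i + 1L, ]
    gs <- left$end
    ge <- if (i == n) right$start + L else right$start
    if (ge > gs) {
      # circular closure gap may wrap; only emit when genome is circular
      if (i == n && !genome$circular) next
      if (i == n && ge > L) {
        if (gs < L)
          out[[length(out) + 1L]] <- data.frame(
            kind = "IGS", name = paste0(left$name, "-", right$name),
            start = gs, end = L, strand = "+", degenerate = FALSE)
        if (right$start > 0)
          out[[length(out) + 1L]] <- data.frame(
            kind = "IGS", name = paste0(left$name, "-", right$name),
            start = 0L, end = right$start, strand = "+", degenerate = FALSE)
      } else {
        out[[length(out) + 1L]] <- data.frame(
          kind = "IGS", name = paste0(left$name, "-", right$name),
          start = gs, end = min(ge, L), strand = "+", degenerate = FALSE)
      }
    }
  }
  if (!length(out)) return(empty_features())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Attach derived IGS features to a plastome
#' @param genome an `AnnotatedPlastome`.
#' @return the genome with IGS features appended to its feature table.
#' @export
annotate_igs <- function(genome) {
  igs <- derive_igs_features(genome)
  genome$features <- rbind(genome$features[genome$features$kind != "IGS", ],
                           igs)
  rownames(genome$features) <- NULL
  genome
}

#' Write a plastome to FASTA
#' @param genome an `AnnotatedPlastome`.
#' @param path output file.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_plastome_fasta <- function(genome, path, width = 70L) {
  x <- Biostrings::DNAStringSet(genome$sequence)
  names(x) <- genome$id
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Export segments or features as BED
#'
#' BED is 0-based half-open, matching the internal convention, so
#' coordinates pass through unchanged.
#'
#' @param genome an `AnnotatedPlastome`.
#' @param path output file.
#' @param what `"segments"` or `"features"`.
#' @return `path`, invisibly.
#' @export
write_bed <- function(genome, path, what = c("segments", "features")) {
  what <- match.arg(what)
  tab <- if (what == "segments") {
    if (is.null(genome$segments)) stop("genome has no segments")
    data.frame(chrom = genome$id, start = genome$segments$start,
               end = genome$segments$end, name = genome$segments$name)
  } else {
    data.frame(chrom = genome$id, start = genome$features$start,
               end = genome$features$end,
               name = paste(genome$features$kind, genome$features$name,
                            sep = ":"))
  }
  tab <- tab[order(tab$start), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Map a position to its segment name
#' @param genome plastome with segments.
#' @param pos 0-based positions.
#' @return character vector over LSC/SSC/IR (both IR copies report "IR").
#' @export
segment_of <- function(genome, pos) {
  if (is.null(genome$segments)) return(rep(NA_character_, length(pos)))
  s <- genome$segments
  out <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(s))) {
    inside <- pos >= s$start[i] & pos < s$end[i]
    out[inside] <- sub("^IR[ab]$", "IR", s$name[i])
  }
  out
}

#' Map a position to its compartment class
#'
#' Precedence when annotations overlap: CDS > intron > tRNA > rRNA > IGS.
#' Positions covered by no feature report `"IGS"` (unannotated spacer).
#'
#' @param genome plastome with features.
#' @param pos 0-based positions.
#' @return character vector over coding/intron/tRNA/rRNA/IGS, with the gene
#'   name as the `"gene"` attribute-free second column in the data.frame
#'   returned by [compartment_table()].
#' @export
compartment_of <- function(genome, pos) {
  compartment_table(genome, pos)$compartment
}

#' @rdname compartment_of
#' @export
compartment_table <- function(genome, pos) {
  f <- genome$features
  prec <- c(CDS = 1L, intron = 2L, tRNA = 3L, rRNA = 4L, IGS = 5L)
  comp <- rep("IGS", length(pos))
  gene <- rep(NA_character_, length(pos))
  best <- rep(6L, length(pos))
  for (i in seq_len(nrow(f))) {
    p <- prec[[f$kind[i]]]
    inside <- pos >= f$start[i] & pos < f$end[i] & p < best
    if (any(inside)) {
      comp[inside] <- if (f$kind[i] == "CDS") "coding" else f$kind[i]
      gene[inside] <- f$name[i]
      best[inside] <- p
    }
  }
  data.frame(pos = pos, compartment = comp, gene = gene,
             stringsAsFactors = FALSE)
}
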
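# shared fixture builders: everything is generated in code at test time

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# mutate a sequence with `n_sub` random substitutions; returns the string
mutate_subs <- function(seq, n_sub) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), n_sub)
  for (p in pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1)
  paste(ch, collapse = "")
}

# quadripartite toy genome with planted coordinates; returns list with the
# sequence and the true segment table
planted_quadripartite <- function(lsc = 5000, ir = 800, ssc = 1200,
                                  seed = 11, ir_mismatches = 0) {
  set.seed(seed)
  lsc_s <- rand_dna(lsc)
  ira_s <- rand_dna(ir)
  ssc_s <- rand_dna(ssc)
  # pin the SSC edges to the same base so the IR boundary is unambiguous
  # (a chance-complementary edge pair would legitimately extend the IR)
  substr(ssc_s, 1, 1) <- "A"
  substr(ssc_s, ssc, ssc) <- "A"
  irb_s <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(ira_s)))
  if (ir_mismatches > 0) irb_s <- mutate_subs(irb_s, ir_mismatches)
  list(
    sequence = paste0(lsc_s, ira_s, ssc_s, irb_s),
    segments = data.frame(
      name = c("LSC", "IRa", "SSC", "IRb"),
      start = c(0, lsc, lsc + ir, lsc + ir + ssc),
      end = c(lsc, lsc + ir, lsc + ir + ssc, lsc + 2 * ir + ssc)))
}

# minimal GenBank flat file for a given feature table (1-based inclusive)
write_genbank <- function(path, length, features) {
  loc <- function(start, end, strand) {
    core <- paste0(start, "..", end)
    if (strand == "-") paste0("complement(", core, ")") else core
  }
  lines <- c(
    sprintf("LOCUS       test %d bp DNA circular PLN 01-JAN-2000", length),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", length))
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    lines <- c(lines,
               sprintf("     %-15s %s", f$kind, loc(f$start, f$end, f$strand)),
               sprintf("                     /gene=\"%s\"", f$name))
  }
  writeLines(c(lines, "ORIGIN", "//"), path)
  path
}

write_fasta <- function(path, seqs) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  path
}

# SnpEvents stub with the columns summarize_variants consumes
make_snps <- function(compartment, ts, tv, segment = "LSC") {
  n <- ts + tv
  if (n == 0) return(NULL)
  data.frame(
    segment = segment, posA = seq_len(n), posB = seq_len(n),
    baseA = "A", baseB = c(rep("G", ts), rep("C", tv)),
    compartment = compartment, gene = NA_character_,
    mut_class = c(rep("Ts", ts), rep("Tv", tv)),
    coding_effect = "not_applicable", stringsAsFactors = FALSE)
}

empty_snps <- function() {
  data.frame(segment = character(), posA = integer(), posB = integer(),
             baseA = character(), baseB = character(),
             compartment = character(), gene = character(),
             mut_class = character(), coding_effect = character())
}

empty_indels <- function() {
  data.frame(segment = character(), posA = integer(), posB = integer(),
             length = integer(), carrier = character(),
             polarity = character(), context = character(),
             inserted_seq = character())
}

# printed trnY-trnE p-distance matrix between the six accessions
# (lower triangle of the published table)
table5_matrix <- function() {
  labs <- c("ArvKor", "ArvChn", "ArvAme", "HyeKor", "HyeAme", "Ram")
  p <- matrix(0, 6, 6, dimnames = list(labs, labs))
  fill <- function(i, j, v) p[i, j] <<- p[j, i] <<- v
  fill(2, 1, 0.0004)
  fill(3, 1, 0.008); fill(3, 2, 0.008)
  fill(4, 1, 0.090); fill(4, 2, 0.092); fill(4, 3, 0.095)
  fill(5, 1, 0.084); fill(5, 2, 0.089); fill(5, 3, 0.084); fill(5, 4, 0.008)
  fill(6, 1, 0.095); fill(6, 2, 0.095); fill(6, 3, 0.096)
  fill(6, 4, 0.031); fill(6, 5, 0.034)
  nd <- matrix(0L, 6, 6, dimnames = list(labs, labs))
  cs <- matrix(4500L, 6, 6, dimnames = list(labs, labs))
  diag(cs) <- 0L
  new_distance_matrix(labs, nd, p, cs)
}
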
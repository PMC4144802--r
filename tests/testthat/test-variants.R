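test_that("indel calling turns each gap run into one carrier-labeled event", {
  aln <- aligned_pair("AC---GT", "ACTTAGT")
  ev <- call_indels(aln)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$length, 3)
  expect_equal(ev$carrier, "B")
  expect_equal(ev$inserted_seq, "TTA")
  expect_equal(ev$posA, 2)             # first A base at/after the run

  expect_equal(nrow(call_indels(aligned_pair("ACGT", "ACGT"))), 0)
})

test_that("calling conserves gap runs and mismatch columns exactly", {
  set.seed(53)
  for (i in 1:5) {
    sa <- rand_dna(800)
    sb <- mutate_subs(sa, 10)
    cut <- sort(sample(seq(50, 750, by = 40), 4))
    for (k in rev(seq_along(cut)))
      sb <- paste0(substr(sb, 1, cut[k]),
                   substr(sb, cut[k] + k + 1, nchar(sb)))
    aln <- align_global(sa, sb)
    ca <- strsplit(aln$gappedA, "")[[1]]; cb <- strsplit(aln$gappedB, "")[[1]]
    n_runs <- sum(rle(ca == "-")$values) + sum(rle(cb == "-")$values)
    n_mm <- sum(ca != cb & ca %in% BASES & cb %in% BASES)
    expect_equal(nrow(call_indels(aln)), n_runs)
    expect_equal(nrow(call_snps(aln)), n_mm)
  }
})

test_that("indel polarity follows the outgroup's state over the locus", {
  set.seed(59)
  s <- rand_dna(400)
  extra <- rand_dna(19)
  sa <- paste0(substr(s, 1, 200), extra, substr(s, 201, 400))

  # outgroup lacks the segment: insertion in the carrier (A) lineage
  tr <- align_triplet(sa, s, s)
  ev <- polarize_indels(call_indels(tr$pair), tr)
  expect_equal(ev$carrier, "A")
  expect_equal(ev$polarity, "insertion")

  # outgroup has the segment: deletion in the non-carrier (B) lineage
  tr2 <- align_triplet(sa, s, sa)
  ev2 <- polarize_indels(call_indels(tr2$pair), tr2)
  expect_equal(ev2$carrier, "A")
  expect_equal(ev2$polarity, "deletion")

  # outgroup unalignable over the locus: polarity stays unknown
  so <- paste0(substr(s, 1, 150), rand_dna(120), substr(s, 271, 400))
  tr3 <- align_triplet(sa, s, so)
  ev3 <- polarize_indels(call_indels(tr3$pair), tr3)
  expect_equal(ev3$polarity, "unknown")
})

test_that("indel context separates slippage, tandem and other events", {
  # 1 bp A inside a carrier AAAAA run
  gA <- "GCAAAAAGC"
  gB <- "GCAAAA-GC"
  ev <- classify_indel_context(call_indels(aligned_pair(gA, gB)),
                               gsub("-", "", gA), gsub("-", "", gB))
  expect_equal(ev$context, "homopolymer")

  # the 24 bp coding tandem duplication
  unit <- "ATCAATGCTAGATGTTTCAAAAGT"
  left <- rand_dna(40, seed = 61); right <- rand_dna(40)
  sa <- paste0(left, unit, unit, right)
  sb <- paste0(left, unit, right)
  aln <- align_global(sa, sb)
  ev2 <- classify_indel_context(call_indels(aln), sa, sb)
  expect_equal(ev2$length, 24)
  expect_equal(ev2$context, "tandem")

  # 5 bp insertion with no flanking similarity
  sa3 <- paste0(substr(sa <- rand_dna(100, seed = 67), 1, 50), "GATCC",
                substr(sa, 51, 100))
  ev3 <- classify_indel_context(call_indels(align_global(sa3, sa)),
                                sa3, sa)
  expect_equal(ev3$context, "other")
})

test_that("SNP classification assigns Ts/Tv and annotation compartments", {
  ev <- call_snps(aligned_pair("AG", "GG"))
  expect_equal(ev$mut_class, "Ts")
  ev2 <- call_snps(aligned_pair("AG", "CG"))
  expect_equal(ev2$mut_class, "Tv")

  seq <- rand_dna(300, seed = 71)
  g <- plastome("snp", seq, features = data.frame(
    kind = "CDS", name = "psbA", start = 90, end = 240, strand = "+",
    degenerate = FALSE))
  ch <- strsplit(seq, "")[[1]]
  ch[100] <- setdiff(BASES, ch[100])[1]
  aln <- align_global(seq, paste(ch, collapse = ""))
  ev3 <- call_snps(aln, g)
  expect_equal(ev3$compartment, "coding")
  expect_equal(ev3$gene, "psbA")
  expect_equal(ev3$posA, 99)
})

test_that("planted kappa bias is recovered in the Ts fraction", {
  set.seed(73)
  kappa <- 4
  s <- rand_dna(5000)
  ch <- strsplit(s, "")[[1]]
  pos <- sample(5000, 200)
  ts_of <- c(A = "G", G = "A", C = "T", T = "C")
  for (p in pos) {
    ch[p] <- if (runif(1) < kappa / (kappa + 2)) ts_of[[ch[p]]]
    else sample(setdiff(BASES, c(ch[p], ts_of[[ch[p]]])), 1)
  }
  ev <- call_snps(align_global(s, paste(ch, collapse = "")))
  n_ts <- sum(ev$mut_class == "Ts")
  expect_gte(n_ts, qbinom(0.005, 200, kappa / (kappa + 2)))
  expect_lte(n_ts, qbinom(0.995, 200, kappa / (kappa + 2)))
})

test_that("synonymy calls match the plastid genetic code on point cases", {
  # GCA -> GCG (Ala/Ala) at codon position 3; ATG -> ACG (Met/Thr)
  seq <- paste0("ATGGCAATGTAA", rand_dna(60, seed = 79))
  g <- plastome("syn", seq, features = data.frame(
    kind = "CDS", name = "tester", start = 0, end = 12, strand = "+",
    degenerate = FALSE))
  swap <- function(s, at, to) {
    ch <- strsplit(s, "")[[1]]; ch[at] <- to; paste(ch, collapse = "")
  }
  alnS <- align_global(seq, swap(seq, 6, "G"))   # GCA -> GCG
  evS <- classify_synonymy(call_snps(alnS, g), g, alnS, swap(seq, 6, "G"))
  expect_equal(evS$coding_effect, "synonymous")

  alnN <- align_global(seq, swap(seq, 8, "C"))   # ATG -> ACG
  evN <- classify_synonymy(call_snps(alnN, g), g, alnN, swap(seq, 8, "C"))
  expect_equal(evN$coding_effect, "nonsynonymous")
})

test_that("synonymy agrees with full-CDS translation on both strands", {
  set.seed(83)
  gc11 <- Biostrings::getGeneticCode("11")
  for (i in 1:50) {
    n_codons <- sample(10:30, 1)
    cds <- paste(sample(setdiff(names(gc11), c("TAA", "TAG", "TGA")),
                        n_codons, replace = TRUE), collapse = "")
    strand <- sample(c("+", "-"), 1)
    flank5 <- rand_dna(20); flank3 <- rand_dna(20)
    genomic <- if (strand == "+") cds else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    seqA <- paste0(flank5, genomic, flank3)
    at <- 20 + sample(nchar(cds), 1)
    ch <- strsplit(seqA, "")[[1]]
    ch[at] <- sample(setdiff(BASES, ch[at]), 1)
    seqB <- paste(ch, collapse = "")
    g <- plastome("orc", seqA, features = data.frame(
      kind = "CDS", name = "orf", start = 20, end = 20 + nchar(cds),
      strand = strand, degenerate = FALSE))
    aln <- align_global(seqA, seqB)
    got <- classify_synonymy(call_snps(aln, g), g, aln, seqB)
    # independent oracle: translate the whole CDS from both genomes
    extract <- function(s) {
      sub <- substr(s, 21, 20 + nchar(cds))
      if (strand == "-") sub <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(sub)))
      as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                         genetic.code = gc11))
    }
    expected <- if (extract(seqA) == extract(seqB)) "synonymous"
                else "nonsynonymous"
    expect_equal(got$coding_effect, expected)
  }
})

test_that("K2P distance matches its closed form and flags saturation", {
  expect_equal(k2p_distance("ACGTACGT", "ACGTACGT"), 0)

  # 300 sites, 3 transitions, 0 transversions
  s <- rand_dna(300, seed = 89)
  ch <- strsplit(s, "")[[1]]
  ts_of <- c(A = "G", G = "A", C = "T", T = "C")
  for (p in c(10, 150, 290)) ch[p] <- ts_of[[ch[p]]]
  expect_equal(k2p_distance(s, paste(ch, collapse = "")),
               -0.5 * log(1 - 2 * 0.01), tolerance = 1e-12)

  # Q = 0.5 drives the 1 - 2Q factor to zero: saturated
  sat_a <- strrep("A", 100)
  sat_b <- paste0(strrep("C", 50), strrep("A", 50))
  expect_error(k2p_distance(sat_a, sat_b), "saturated")
})

test_that("K2P agrees with an independent K80 implementation", {
  skip_if_not_installed("ape")
  set.seed(97)
  sa <- rand_dna(2000)
  sb <- mutate_subs(sa, 60)
  ours <- k2p_distance(sa, sb)
  m <- rbind(a = strsplit(tolower(sa), "")[[1]],
             b = strsplit(tolower(sb), "")[[1]])
  theirs <- as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "K80"))
  expect_equal(ours, theirs, tolerance = 1e-9)
})

test_that("density ratios reproduce printed per-region statistics", {
  lens <- c(92961, 19477, 2 * 10144)
  expect_equal(unname(density_ratio(c(142, 13, 4), lens)),
               c(7.7, 3.4, 1))
  expect_equal(unname(density_ratio(c(155, 8, 2), lens))[2], 4.2)
  expect_equal(unname(density_ratio(c(10, 10, 10), c(100, 100, 100))),
               c(1, 1, 1))
  # invariance under uniform length scaling
  expect_equal(density_ratio(c(142, 13, 4), lens, digits = NULL),
               density_ratio(c(142, 13, 4), lens * 7, digits = NULL))
  expect_error(density_ratio(c(1, 1, 1), c(100, 0, 100)), "zero-length")
})

test_that("variant summary margins and ratios follow the cross-tabs", {
  snps <- rbind(make_snps("coding", 23, 27), make_snps("IGS", 28, 72),
                make_snps("intron", 4, 9), make_snps("rRNA", 2, 0))
  s <- summarize_variants(empty_indels(), snps)
  expect_equal(sum(s$snp_table), nrow(snps))          # margins conserve
  expect_equal(unname(s$ts_tv["whole"]), 0.53)
  expect_equal(unname(s$ts_tv["coding"]), 0.85)
  expect_equal(unname(s$ts_tv["IGS"]), 0.39)

  s0 <- summarize_variants(empty_indels(), empty_snps())
  expect_equal(s0$n_snps, 0)
  expect_true(all(is.na(s0$ts_tv)))
})

test_that("VCF export writes well-formed, coordinate-sorted records", {
  set.seed(103)
  sa <- rand_dna(600)
  ch <- strsplit(sa, "")[[1]]
  ch[50] <- setdiff(BASES, ch[50])[1]
  sb <- paste(ch, collapse = "")
  sb <- paste0(substr(sb, 1, 300), substr(sb, 306, 600))  # 5 bp deletion
  g <- plastome("ref", sa)
  aln <- align_global(sa, sb)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(call_snps(aln, g), call_indels(aln, g), g, vcf)
  lines <- readLines(vcf)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- read.table(vcf, sep = "\t", comment.char = "#")
  expect_equal(nrow(body), 2)
  expect_false(is.unsorted(body$V2))
  # the indel record carries the anchor base convention
  indel_row <- body[grepl("INDEL", body$V8), ]
  expect_equal(nchar(indel_row$V4), nchar(indel_row$V5) + 5)
  # REF matches the reference genome at POS
  for (r in seq_len(nrow(body)))
    expect_equal(substr(sa, body$V2[r],
                        body$V2[r] + nchar(body$V4[r]) - 1), body$V4[r])
})
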
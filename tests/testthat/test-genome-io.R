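test_that("single-record FASTA reads into a plastome; multi-record errors", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(fa, c(chr = "ACGTACGTAC"))
  g <- read_plastome(fa)
  expect_s3_class(g, "AnnotatedPlastome")
  expect_equal(plastome_length(g), 10)
  expect_equal(nrow(g$features), 0)

  fa2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(fa2, c(a = "ACGT", b = "ACGT"))
  expect_error(read_plastome(fa2), "exactly one record.*2")
})

test_that("GenBank features parse with strand, naming and degeneracy", {
  seq <- rand_dna(1000, seed = 5)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(fa, c(chr = seq))
  gb <- withr::local_tempfile(fileext = ".gb")
  write_genbank(gb, 1000, data.frame(
    kind = c("CDS", "tRNA"), name = c("rbcL", "trnY"),
    start = c(1, 401), end = c(300, 475), strand = c("+", "-")))
  g <- read_plastome(fa, gb)
  cds <- g$features[g$features$kind == "CDS", ]
  expect_equal(cds$start, 0)
  expect_equal(cds$end, 300)
  expect_false(cds$degenerate)          # 300 bp: codon-multiple
  trna <- g$features[g$features$kind == "tRNA", ]
  expect_equal(trna$strand, "-")
  expect_equal(c(trna$start, trna$end), c(400, 475))

  # CDS of length 301 is flagged degenerate, not rejected
  gb2 <- withr::local_tempfile(fileext = ".gb")
  write_genbank(gb2, 1000, data.frame(
    kind = "CDS", name = "orfX", start = 1, end = 301, strand = "+"))
  g2 <- read_plastome(fa, gb2)
  expect_true(g2$features$degenerate[1])

  # coordinates past the sequence end are an error naming the feature
  gb3 <- withr::local_tempfile(fileext = ".gb")
  write_genbank(gb3, 1000, data.frame(
    kind = "CDS", name = "orfY", start = 900, end = 1200, strand = "+"))
  expect_error(read_plastome(fa, gb3), "orfY")
})

test_that("FASTA write/read round-trips the sequence exactly", {
  g <- plastome("rt", rand_dna(512, seed = 9))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_plastome_fasta(g, fa)
  g2 <- read_plastome(fa)
  expect_identical(g2$sequence, g$sequence)
  expect_identical(g2$id, "rt")
})

test_that("detect_segments recovers planted quadripartite coordinates", {
  pl <- planted_quadripartite()
  g <- plastome("q", pl$sequence)
  segs <- detect_segments(g, min_ir = 500)
  expect_equal(segs$name, pl$segments$name)
  expect_equal(segs$start, pl$segments$start)
  expect_equal(segs$end, pl$segments$end)
  # tiling invariant
  segs <- segs[order(segs$start), ]
  expect_equal(sum(segs$end - segs$start), plastome_length(g))
})

test_that("detect_segments tolerates IR mismatches within tolerance", {
  pl <- planted_quadripartite(ir_mismatches = 1, seed = 13)
  g <- plastome("q", pl$sequence, ir_mismatch_tolerance = 2)
  segs <- detect_segments(g, min_ir = 500, tolerance = 2)
  ira <- segs[segs$name == "IRa", ]
  expect_equal(ira$end - ira$start, 800)
  expect_equal(segs$start[segs$name == "LSC"], 0)
})

test_that("detect_segments errors when no inverted repeat exists", {
  g <- plastome("flat", rand_dna(5000, seed = 21))
  expect_error(detect_segments(g, min_ir = 500), "no IR detected")
})

test_that("IGS features are the maximal inter-feature gaps", {
  g <- plastome("igs", rand_dna(1000, seed = 3), features = data.frame(
    kind = c("tRNA", "tRNA"), name = c("trnY", "trnE"),
    start = c(100, 700), end = c(180, 780), strand = "+",
    degenerate = FALSE))
  igs <- derive_igs_features(g)
  mid <- igs[igs$name == "trnY-trnE", ]
  expect_equal(nrow(mid), 1)
  expect_equal(c(mid$start, mid$end), c(180, 700))
  # circular closure: the trnE-trnY gap wraps across the origin
  wrap <- igs[igs$name == "trnE-trnY", ]
  expect_setequal(wrap$start, c(780, 0))
  expect_setequal(wrap$end, c(1000, 100))

  # adjacent features emit no spacer
  g2 <- plastome("adj", rand_dna(300, seed = 4), circular = FALSE,
                 features = data.frame(
    kind = "CDS", name = c("a", "b"), start = c(0, 150),
    end = c(150, 300), strand = "+", degenerate = FALSE))
  expect_equal(nrow(derive_igs_features(g2)), 0)
})

test_that("IGS derivation matches a brute-force gap scan", {
  set.seed(77)
  for (rep in 1:5) {
    n_genes <- sample(3:7, 1)
    starts <- sort(sample(seq(10, 1900, by = 10), n_genes))
    ends <- pmin(starts + sample(30:80, n_genes, replace = TRUE), 1990)
    ok <- c(TRUE, starts[-1] > ends[-n_genes])
    starts <- starts[ok]; ends <- ends[ok]
    g <- plastome("bf", rand_dna(2000), features = data.frame(
      kind = "CDS", name = sprintf("g%02d", seq_along(starts) * 3),
      start = starts, end = ends, strand = "+", degenerate = FALSE))
    igs <- derive_igs_features(g)
    # brute force: positions covered by no feature
    covered <- logical(2000)
    for (i in seq_along(starts)) covered[(starts[i] + 1):ends[i]] <- TRUE
    igs_cov <- logical(2000)
    for (i in seq_len(nrow(igs))) igs_cov[(igs$start[i] + 1):igs$end[i]] <- TRUE
    expect_identical(igs_cov, !covered)
  }
})

test_that("compartment precedence is CDS > intron > tRNA > rRNA > IGS", {
  g <- plastome("prec", rand_dna(600, seed = 8), features = data.frame(
    kind = c("CDS", "intron", "CDS", "rRNA"),
    name = c("ndhA", "ndhA", "ndhA", "rrn16"),
    start = c(0, 100, 200, 400), end = c(100, 200, 300, 500),
    strand = "+", degenerate = FALSE))
  ct <- compartment_table(g, c(50, 150, 250, 450, 550))
  expect_equal(ct$compartment,
               c("coding", "intron", "coding", "rRNA", "IGS"))
  expect_equal(ct$gene[1:4], c("ndhA", "ndhA", "ndhA", "rrn16"))
})

test_that("segments and features export as valid BED intervals", {
  pl <- planted_quadripartite(seed = 31)
  g <- plastome("bed", pl$sequence, segments = pl$segments)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(g, bed, "segments")
  tab <- read.table(bed, sep = "\t")
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$V2 < tab$V3))
  expect_equal(sum(tab$V3 - tab$V2), plastome_length(g))
})
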
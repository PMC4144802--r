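test_that("hairpin folding reproduces the published unit structures", {
  a <- fold_hairpin("TATGGATTTCTTGTCCATA")
  expect_equal(a$stem_length, 7)
  expect_equal(a$loop, "TTCTT")
  expect_equal(a$wobble_count, 1)       # the T:G contact at 7/13

  b <- fold_hairpin("TATGGATTTTAAGTCCATA", min_loop = 5)
  expect_equal(b$stem_length, 7)
  expect_equal(b$loop, "TTTAA")

  expect_equal(fold_hairpin("AAAAAA")$stem_length, 0)
})

test_that("stem length never exceeds the loop-constrained maximum", {
  set.seed(7)
  for (i in 1:50) {
    L <- sample(6:40, 1)
    min_loop <- sample(3:5, 1)
    u <- rand_dna(L)
    f <- fold_hairpin(u, min_loop = min_loop)
    expect_lte(f$stem_length, floor((L - min_loop) / 2))
    if (f$stem_length > 0)
      expect_equal(nrow(f$pairs), f$stem_length)
  }
})

test_that("A/B form classification keys on the published loops", {
  expect_equal(classify_form("TATGGATTTCTTGTCCATA"), "A")
  expect_equal(classify_form("TATGGATTTTAAGTCCATA"), "B")
  expect_equal(classify_form("TATGGATCTTAAGTCCATA"), "other")
})

test_that("tandem arrays are found with exact unit length and copy count", {
  arr <- find_tandem_arrays(strrep("AT", 6), unit_range = c(2, 10),
                            min_copies = 3)
  expect_equal(arr[[1]]$unit_length, 2)
  expect_equal(nrow(arr[[1]]$copies), 6)
  expect_equal(arr[[1]]$mean_copy_identity, 1)

  # two copies of the 24 bp unit
  unit24 <- "ATCAATGCTAGATGTTTCAAAAGT"
  s <- paste0(rand_dna(60, seed = 11), strrep(unit24, 2), rand_dna(60))
  arr24 <- find_tandem_arrays(s, unit_range = c(10, 30), min_copies = 2)
  expect_equal(arr24[[1]]$unit_length, 24)
  expect_equal(nrow(arr24[[1]]$copies), 2)
})

test_that("mutated 19-mer arrays are recovered within one copy", {
  set.seed(13)
  for (i in 1:10) {
    n_cop <- sample(8:15, 1)
    copies <- vapply(seq_len(n_cop), function(k) {
      ch <- strsplit(CANONICAL_UNIT_19, "")[[1]]
      hit <- which(runif(19) < 0.05)
      for (p in hit) ch[p] <- sample(setdiff(BASES, ch[p]), 1)
      paste(ch, collapse = "")
    }, character(1))
    s <- paste0(rand_dna(150), paste(copies, collapse = ""), rand_dna(150))
    arrs <- find_tandem_arrays(s)
    expect_equal(length(arrs), 1)
    expect_equal(arrs[[1]]$unit_length, 19)
    expect_lte(abs(nrow(arrs[[1]]$copies) - n_cop), 1)
    # length conservation over the array region
    expect_lte(19 * nrow(arrs[[1]]$copies),
               arrs[[1]]$region[2] - arrs[[1]]$region[1] + 19)
  }
})

test_that("shuffled sequences yield no confident array (false positives)", {
  set.seed(17)
  for (i in 1:20) {
    s <- rand_dna(600)
    arrs <- find_tandem_arrays(s, unit_range = c(10, 30), min_copies = 3,
                               min_identity = 0.9)
    confident <- Filter(function(a)
      nrow(a$copies) >= 3 && a$mean_copy_identity >= 0.9, arrs)
    expect_length(confident, 0)
  }
})

test_that("consensus profiles report frequencies and invariable sites", {
  prof <- consensus_profile(rep("ACGT", 5))
  expect_equal(prof$invariable_positions, 1:4)
  expect_true(all(apply(prof$freq, 1, max) == 1))

  p2 <- consensus_profile(c("ACGT", "AGGT"))
  expect_equal(setdiff(1:4, p2$invariable_positions), 2)

  expect_error(consensus_profile(c("ACGT", "ACG")), "phase-align")
  # frequencies always sum to one per position
  expect_equal(unname(rowSums(p2$freq)), rep(1, 4))
})

test_that("planted profile frequencies are recovered at n = 200", {
  set.seed(19)
  n <- 200
  copies <- vapply(seq_len(n), function(i) {
    ch <- strsplit("TACGT", "")[[1]]
    if (runif(1) < 0.15) ch[2] <- "C"       # position 2: A 0.85 / C 0.15
    paste(ch, collapse = "")
  }, character(1))
  prof <- consensus_profile(copies)
  expect_gte(prof$freq[2, "A"] * n, qbinom(0.005, n, 0.85))
  expect_lte(prof$freq[2, "A"] * n, qbinom(0.995, n, 0.85))
  expect_false(2 %in% prof$invariable_positions)
})

test_that("dotplot shows the main diagonal and period off-diagonals", {
  s <- rand_dna(120, seed = 23)
  d <- dotplot(s, s, window = 10, min_matches = 10)
  diag_hits <- d[d$i == d$j, ]
  expect_equal(nrow(diag_hits), 120 - 10 + 1)

  arr <- strrep("ATCGATCGGTA", 8)       # period 11
  da <- dotplot(arr, arr, window = 11, min_matches = 11)
  offs <- unique(abs(da$i - da$j))
  expect_true(all(offs %% 11 == 0))
  expect_true(11 %in% offs)

  # unrelated sequences at a stringent threshold stay near-empty
  set.seed(29)
  dr <- dotplot(rand_dna(300), rand_dna(300), window = 19,
                min_matches = 17)
  n_windows <- (300 - 19 + 1)^2
  p_hit <- pbinom(16, 19, 0.25, lower.tail = FALSE)
  expect_lte(nrow(dr), qbinom(0.999, n_windows, p_hit) + 1)
})

test_that("dispersed repeat scan finds forward and palindromic pairs", {
  set.seed(31)
  core <- rand_dna(15)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(core)))
  s <- paste0(rand_dna(50), core, rand_dna(50), core, rand_dna(50), rc,
              rand_dna(50))
  rep <- dispersed_repeats(s, min_len = 15, hamming = 0)
  expect_gte(nrow(rep$forward), 1)
  expect_gte(nrow(rep$palindromic), 1)
  fwd <- rep$forward[1, ]
  expect_equal(substr(s, fwd$i + 1, fwd$i + 15),
               substr(s, fwd$j + 1, fwd$j + 15))
})
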
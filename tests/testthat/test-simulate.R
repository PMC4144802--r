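test_that("generated ancestor has the configured quadripartite anatomy", {
  cfg <- simulation_config(seed = 5)
  anc <- generate_ancestor(cfg)
  segs <- anc$segments[order(anc$segments$start), ]
  expect_equal(segs$name, c("LSC", "IRa", "SSC", "IRb"))
  expect_equal(sum(segs$end - segs$start), plastome_length(anc))
  expect_equal(unname(segs$end - segs$start),
               unname(cfg$segment_lengths[c("LSC", "IR", "SSC", "IR")]))
  # IRb is the exact reverse complement of IRa
  ira <- substr(anc$sequence, segs$start[2] + 1, segs$end[2])
  irb <- substr(anc$sequence, segs$start[4] + 1, segs$end[4])
  expect_identical(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(irb))),
    ira)
  # the planted array spans copies x unit inside the trnY-trnE spacer
  arr_iv <- plastdiff:::locate_planted_array(anc, cfg)
  expect_equal(arr_iv[2] - arr_iv[1],
               cfg$repeat_copies * nchar(cfg$repeat_unit))
  trny_end <- anc$features$end[anc$features$name == "trnY"][1]
  trne_start <- anc$features$start[anc$features$name == "trnE"][1]
  expect_true(arr_iv[1] >= trny_end && arr_iv[2] <= trne_start)
  region <- substr(anc$sequence, arr_iv[1] + 1, arr_iv[2])
  arrs <- find_tandem_arrays(region)
  expect_equal(arrs[[1]]$unit_length, 19)
})

test_that("IGS homopolymer enrichment raises mean run length", {
  set.seed(9)
  probs <- c(A = 0.335, C = 0.165, G = 0.165, T = 0.335)
  run_mean <- function(s) mean(rle(strsplit(s, "")[[1]])$lengths)
  base <- replicate(5, run_mean(
    plastdiff:::homopolymer_enriched_dna(4000, probs, 1)))
  enr <- replicate(5, run_mean(
    plastdiff:::homopolymer_enriched_dna(4000, probs, 3)))
  expect_gt(mean(enr), 1.8 * mean(base))
  # factor 1 reproduces the iid run-length distribution
  iid_runs <- unlist(replicate(5, rle(strsplit(
    plastdiff:::random_dna(4000, probs), "")[[1]])$lengths,
    simplify = FALSE))
  f1_runs <- unlist(replicate(5, rle(strsplit(
    plastdiff:::homopolymer_enriched_dna(4000, probs, 1), "")[[1]])$lengths,
    simplify = FALSE))
  expect_gt(suppressWarnings(ks.test(iid_runs, f1_runs)$p.value), 0.01)
})

test_that("zero rates leave both lineages identical to the ancestor", {
  cfg <- simulation_config(seed = 3, mu_sub = 0, rate_homopolymer = 0,
                           rate_tandem_dup = 0, rate_other = 0,
                           tandem_step_rate = 0)
  anc <- generate_ancestor(cfg)
  sim <- evolve_pair(anc, cfg)
  expect_identical(sim$genomeA$sequence, anc$sequence)
  expect_identical(sim$genomeB$sequence, anc$sequence)
  ing <- sim$truth$events[sim$truth$events$lineage %in% c("A", "B"), ]
  expect_equal(nrow(ing), 0)
})

test_that("realized substitution counts are Poisson-plausible", {
  counts <- vapply(1:8, function(s) {
    cfg <- simulation_config(seed = s)
    sim <- evolve_pair(generate_ancestor(cfg), cfg)
    ev <- sim$truth$events
    sum(ev$kind == "substitution" & ev$lineage %in% c("A", "B"))
  }, numeric(1))
  cfg <- simulation_config()
  lambda <- 2 * cfg$mu_sub * (sum(cfg$segment_lengths[c("LSC", "SSC")]) +
                                cfg$segment_lengths[["IR"]])
  # pooled count over 8 seeds against the pooled Poisson
  expect_gte(sum(counts), qpois(0.005, 8 * lambda))
  expect_lte(sum(counts), qpois(0.995, 8 * lambda))
})

test_that("array copy-number difference equals the truth net steps", {
  # homogeneous array (no form mixing, minimal heterogeneity) so that the
  # copy counter is exact and the test isolates the simulator bookkeeping
  hits <- 0
  for (s in 1:6) {
    cfg <- simulation_config(seed = s, tandem_step_rate = 2,
                             repeat_loop_b_fraction = 0,
                             repeat_copy_mut = 0.01)
    anc <- generate_ancestor(cfg)
    sim <- evolve_pair(anc, cfg)
    ns <- sim$truth$net_array_steps
    if (ns[["A"]] == ns[["B"]]) next
    hits <- hits + 1
    cnt <- function(g) {
      arrs <- find_tandem_arrays(substr(
        g$sequence,
        g$features$end[g$features$name == "trnY"][1] + 1,
        g$features$start[g$features$name == "trnE"][1]))
      nrow(arrs[[1]]$copies)
    }
    expect_equal(cnt(sim$genomeA) - cnt(sim$genomeB),
                 ns[["A"]] - ns[["B"]])
  }
  expect_gte(hits, 1)   # at least one informative seed actually compared
})

test_that("identical seeds reproduce byte-identical simulations", {
  cfg <- simulation_config(seed = 27)
  s1 <- evolve_pair(generate_ancestor(cfg), cfg)
  s2 <- evolve_pair(generate_ancestor(cfg), cfg)
  expect_identical(s1$genomeA$sequence, s2$genomeA$sequence)
  expect_identical(s1$genomeB$sequence, s2$genomeB$sequence)
  expect_identical(s1$outgroup$sequence, s2$outgroup$sequence)
  expect_identical(s1$truth$events, s2$truth$events)
})

test_that("planted events carry valid, liftable coordinates", {
  cfg <- simulation_config(seed = 15)
  anc <- generate_ancestor(cfg)
  sim <- evolve_pair(anc, cfg)
  ev <- sim$truth$events
  expect_true(all(ev$pos_ancestor >= 0 &
                    ev$pos_ancestor < plastome_length(anc)))
  expect_true(all(ev$posA >= 0 & ev$posA <= plastome_length(sim$genomeA)))
  # substitutions in lineage A are visible at their lifted coordinate
  subA <- ev[ev$kind == "substitution" & ev$lineage == "A", ]
  got <- substring(sim$genomeA$sequence, subA$posA + 1, subA$posA + 1)
  expect_true(mean(got == subA$seq) > 0.95)
})
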
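test_that("gc_fraction counts G+C over unambiguous bases", {
  expect_equal(gc_fraction("ATGC"), 0.5)
  expect_equal(gc_fraction("AAAA"), 0)
  expect_equal(gc_fraction("ATGNNC"), 2 / 4)   # N excluded on both sides
  expect_equal(gc_fraction("ATGNNCAA"), 2 / 6)
  expect_equal(gc_fraction("atgc"), 0.5)
  expect_error(gc_fraction(""), "empty")
  expect_error(gc_fraction("NNNN"), "unambiguous")
  expect_error(gc_fraction("ATXG"), "invalid")
})

test_that("window_identity is the max ungapped identity over offsets", {
  set.seed(10)
  ref <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  win <- substr(ref, 101, 300)
  expect_equal(window_identity(win, ref), 1)
  # exactly 20 mismatches over 200 bp at the source locus
  win20 <- mutate_at(win, seq(5, 195, by = 10))
  expect_equal(window_identity(win20, ref), 0.9)
  expect_equal(window_identity(strrep("A", 50), strrep("C", 100)), 0)
  expect_error(window_identity(strrep("A", 10), "ACGT"), "longer")
})

test_that("candidate enumeration equals the exhaustive scan oracle", {
  ig <- island_genome(n_islands = 6, seed = 77)
  cfg <- probe_config(length_set = 156L, step = 156L)
  cands <- enumerate_candidates(ig$genome, references = ig$reference,
                                cfg = cfg)
  oracle <- exhaustive_enumerate(ig$genome, ig$reference, cfg)
  expect_equal(cands$start, oracle$start)
  expect_equal(cands$length, oracle$length)
  # exactly the conserved islands pass
  expect_equal(sort(cands$start), sort(ig$island_starts0))
})

test_that("enumeration respects degenerate inputs and self-identity", {
  expect_error(enumerate_candidates(strrep("ACGT", 25)),
               "shorter")   # 100 bp < 156
  set.seed(3)
  g <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE,
                    prob = c(0.33, 0.17, 0.17, 0.33)), collapse = "")
  cfg <- probe_config(length_set = c(156L, 200L), step = 50L)
  self <- enumerate_candidates(g, references = g, cfg = cfg)
  expect_true(all(self$min_identity == 1))
  expect_warning(noref <- enumerate_candidates(g, cfg = cfg), "skipped")
  expect_true(all(is.na(noref$min_identity)))
  # in-band GC guaranteed by construction
  expect_true(all(self$gc >= cfg$gc_band[1] & self$gc <= cfg$gc_band[2]))
})

test_that("tightening the identity gate never adds candidates", {
  ig <- island_genome(n_islands = 4, seed = 5)
  # mutate each island lightly in the reference so identities spread
  ref <- ig$reference
  for (s in ig$island_starts0)
    ref <- mutate_at(ref, s + seq(3, 150, by = 21))
  ns <- vapply(c(0.80, 0.90, 0.95, 1.0), function(t) {
    cfg <- probe_config(length_set = 156L, step = 156L, identity_min = t)
    nrow(enumerate_candidates(ig$genome, references = ref, cfg = cfg))
  }, numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("off-target screening removes ambiguous candidates", {
  set.seed(8)
  g <- paste(sample(c("A", "C", "G", "T"), 1200, TRUE,
                    prob = c(0.33, 0.17, 0.17, 0.33)), collapse = "")
  cfg <- probe_config(length_set = 200L, step = 100L)
  cands <- enumerate_candidates(g, references = g, cfg = cfg)
  expect_gt(nrow(cands), 2)
  # candidate copied verbatim into the off-target set is removed
  kept <- screen_offtargets(cands, offtarget_db = cands$seq[1], cfg = cfg)
  expect_false(cands$start[1] %in% kept$start)
  expect_equal(nrow(attr(kept, "removed")), 1)
  # no shared sequence at all: retained
  kept2 <- screen_offtargets(cands, offtarget_db = strrep("AC", 300),
                             cfg = cfg)
  expect_equal(nrow(kept2), nrow(cands))
  # exactly at the threshold: retained (strict inequality removes)
  cand1 <- cands$seq[1]                       # 200 bp
  at_thr <- mutate_at(cand1, seq(1, 196, by = 5))   # 40 mismatches -> 0.80
  expect_equal(window_identity(cand1, at_thr), 0.80)
  kept3 <- screen_offtargets(cands[1, , drop = FALSE],
                             offtarget_db = at_thr, cfg = cfg)
  expect_equal(nrow(kept3), 1)
  # one fewer mismatch exceeds the threshold: removed
  over_thr <- mutate_at(cand1, seq(1, 191, by = 5))  # 39 mismatches
  kept4 <- screen_offtargets(cands[1, , drop = FALSE],
                             offtarget_db = over_thr, cfg = cfg)
  expect_equal(nrow(kept4), 0)
  # shared-k-mer mode: verbatim copy removed, unrelated decoy retained
  cfg_k <- probe_config(length_set = 200L, step = 100L,
                        offtarget_method = "kmer")
  kept5 <- screen_offtargets(cands, offtarget_db = cands$seq[1],
                             cfg = cfg_k)
  expect_false(cands$start[1] %in% kept5$start)
  set.seed(30)
  decoy <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  expect_equal(nrow(screen_offtargets(cands, decoy, cfg_k)), nrow(cands))
})

test_that("probe selection respects capacity, overlap and determinism", {
  # 30 synthetic disjoint candidates
  mk <- function(n, len = 200L) data.frame(
    target_id = "t", start = (0:(n - 1)) * 400L,
    end = (0:(n - 1)) * 400L + len, length = len,
    gc = 0.33, min_identity = 1, gene_class = "unannotated",
    seq = strrep("A", len))
  cfg <- probe_config()
  ps <- select_probes(mk(30), cfg, genome_gc = 0.33,
                      genome_length = 30 * 400)
  expect_equal(ps$summary$count, 13)
  p <- ps$probes
  expect_false(any(outer(p$start, p$end, `<`) &
                     outer(p$end, p$start, `>`) & !diag(nrow(p))))
  # under capacity: all 12 kept
  expect_equal(select_probes(mk(12), cfg, genome_gc = 0.33,
                             genome_length = 12 * 400)$summary$count, 12)
  # infeasible
  expect_error(select_probes(mk(9), cfg), "k_min")
  # deterministic
  ps2 <- select_probes(mk(30), cfg, genome_gc = 0.33,
                       genome_length = 30 * 400)
  expect_identical(ps$probes, ps2$probes)
})

test_that("end-to-end design on the synthetic genome passes the audit", {
  g <- synthetic_probe_genome(length_bp = 20000, seed = 2)
  cfg <- probe_config(step = 25L)
  ps <- design_probes(g, references = g,
                      annotations = attr(g, "annotations"), cfg = cfg)
  p <- ps$probes
  expect_gte(nrow(p), 10); expect_lte(nrow(p), 13)
  expect_true(all(p$length >= 156 & p$length <= 318))
  expect_true(all(p$min_identity >= 0.90))
  expect_true(all(p$gc >= cfg$gc_band[1] & p$gc <= cfg$gc_band[2]))
  expect_false(any(outer(p$start, p$end, `<`) &
                     outer(p$end, p$start, `>`) & !diag(nrow(p))))
  # writers produce the three standard outputs
  pre <- withr::local_tempfile()
  paths <- write_probe_set(ps, pre)
  expect_true(all(file.exists(paths)))
  bed <- read.delim(paths[["bed"]], header = FALSE)
  expect_equal(nrow(bed), nrow(p))
})
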
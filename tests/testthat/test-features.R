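test_that("centromere/telomere distances follow the arm rules with clamping", {
  st <- data.frame(chrom = "1", p_telomere = 0, centromere_start = 50,
                   centromere_end = 60, q_telomere = 200)
  d <- positional_distances(gintervals("1", 10, 20), st)
  expect_equal(c(d$centromere_distance, d$telomere_distance), c(30, 10))
  d <- positional_distances(gintervals("1", 150, 180), st)
  expect_equal(c(d$centromere_distance, d$telomere_distance), c(90, 20))
  d <- positional_distances(gintervals("1", 55, 58), st)  # inside centromere
  expect_equal(d$centromere_distance, 0)
  expect_equal(d$telomere_distance, min(55 - 0, 200 - 58))
  expect_error(positional_distances(gintervals("9", 1, 5), st), "missing")
})

test_that("GC content is case-insensitive and excludes ambiguous bases", {
  genome <- Biostrings::DNAStringSet(c("1" = "GGCCatatACGTNNNN"))
  iv <- function(s, e) gintervals("1", s, e)
  expect_equal(gc_content(iv(0, 4), genome), 1.0)
  expect_equal(gc_content(iv(4, 8), genome), 0.0)
  expect_equal(gc_content(iv(8, 12), genome), 0.5)
  expect_equal(gc_content(iv(0, 8), genome), 0.5)   # soft-mask ignored
  expect_warning(g <- gc_content(iv(12, 16), genome), "ambiguous")
  expect_equal(g, 0)
  expect_equal(suppressWarnings(gc_content(iv(10, 14), genome)), 0.5)
})

test_that("functional counts match the mini-bundle by hand", {
  b <- mini_bundle()
  # exon padded by 10 bp catches a CNV just past the exon end
  fc <- functional_counts(gintervals("1", 2005, 2009), b)
  expect_equal(fc$exon_count, 1)
  expect_equal(fc$gene_count, 0)
  # promoter = 1,000 bp immediately upstream of the TSS
  fc <- functional_counts(gintervals("1", 200, 500), b)
  expect_equal(fc$promoter_count, 1)
  # SNV positions are points: CNV [1498,1500) holds 1-based pos 1500
  fc <- functional_counts(gintervals("1", 1498, 1500), b)
  expect_equal(fc$pathogenic_snv_count, 1)
  fc <- functional_counts(gintervals("1", 1500, 1502), b)
  expect_equal(fc$pathogenic_snv_count, 0)
})

test_that("popmax requires type match and >= 50% reciprocal overlap", {
  sv <- data.frame(chrom = "1", start = c(0, 0), end = c(100, 100),
                   type = c("DEL", "DUP"), af_a = c(0.01, 0.3),
                   af_b = c(0.05, 0.1))
  attr(sv, "af_cols") <- c("af_a", "af_b")
  del <- function(s, e) {
    d <- gintervals("1", s, e); d$type <- "DEL"; d
  }
  expect_equal(popmax_frequency(del(0, 100), sv), 0.05)  # highest pop wins
  expect_equal(popmax_frequency(del(500, 600), sv), 0)   # no overlap
  expect_equal(popmax_frequency(del(50, 150), sv), 0.05) # RO exactly 0.5
  expect_equal(popmax_frequency(del(51, 151), sv), 0)    # RO below 0.5
  dup <- del(0, 100); dup$type <- "DUP"
  expect_equal(popmax_frequency(dup, sv), 0.3)           # type-matched record

  # order invariance and agreement with a direct max-filter
  set.seed(23)
  for (rep in 1:25) {
    n <- 40
    sv2 <- data.frame(chrom = "1", start = s <- sample(2000, n, TRUE))
    sv2$end <- sv2$start + sample(400, n, TRUE)
    sv2$type <- sample(c("DEL", "DUP"), n, TRUE)
    sv2$af_x <- round(runif(n), 4)
    attr(sv2, "af_cols") <- "af_x"
    probe <- del(q <- sample(2000, 1), q + sample(400, 1))
    ro <- reciprocal_overlap(probe[rep(1, n), ], sv2)
    ok <- sv2$type == "DEL" & ro >= 0.5
    want <- if (any(ok)) max(sv2$af_x[ok]) else 0
    expect_equal(popmax_frequency(probe, sv2), want)
    perm <- sample(n)
    sv_perm <- sv2[perm, ]
    attr(sv_perm, "af_cols") <- "af_x"
    expect_equal(popmax_frequency(probe, sv_perm), want)
  }
})

test_that("conservation smoothing matches the literal moving average", {
  # spike track: scores [0,0,10,0,0] at positions 0..4, window 3
  tr <- data.frame(chrom = "1", start = 0:4, end = 1:5,
                   score = c(0, 0, 10, 0, 0))
  got <- smoothed_conservation_max(gintervals("1", 0, 5), tr, window = 3)
  expect_equal(got, 10 / 3)
  # window 1 is the raw in-interval maximum
  expect_equal(smoothed_conservation_max(gintervals("1", 0, 5), tr, 1), 10)
  expect_equal(smoothed_conservation_max(gintervals("1", 0, 2), tr, 1), 0)
  # constant track: any window returns the constant
  ct <- data.frame(chrom = "1", start = 0, end = 1000, score = 2.5)
  expect_equal(smoothed_conservation_max(gintervals("1", 100, 300), ct, 101),
               2.5)
  # nothing in reach: sentinel with warning
  expect_warning(
    far <- smoothed_conservation_max(gintervals("2", 0, 50), tr, 3), "sentinel")
  expect_equal(far, 0)
  expect_error(smoothed_conservation_max(gintervals("1", 0, 5), tr, 4))
})

test_that("dosage features sum one-hots and aggregate metrics", {
  dr <- data.frame(chrom = "1", start = c(0, 50), end = c(100, 150),
                   hi_score = c("3", "3"), ts_score = c("0", "2"),
                   hi_index = c(20, 5), pli = c(0.10, 0.99),
                   loeuf = c(0.3, 0.5))
  f <- dosage_features(gintervals("1", 40, 120), dr)
  expect_equal(f$hi_3, 2)            # summed across overlapping regions
  expect_equal(f$ts_0, 1)
  expect_equal(f$ts_2, 1)
  expect_equal(f$hi_index_min, 5)
  expect_equal(f$pli_max, 0.99)
  expect_equal(f$loeuf_min, 0.3)
  # no overlap: all-zero one-hots, loss-tolerant sentinels
  f0 <- dosage_features(gintervals("1", 5000, 5100), dr)
  onehot_cols <- c(paste0("hi_", dosage_vocabulary()),
                   paste0("ts_", dosage_vocabulary()))
  expect_true(all(f0[onehot_cols] == 0))
  expect_equal(f0$hi_index_min, 100)
  expect_equal(f0$pli_max, 0)
  expect_equal(f0$loeuf_min, 2.0)
})

test_that("the feature matrix reproduces the hand-computed golden values", {
  feats <- extract_features(golden_cnvs(), mini_bundle(), window = 5)
  expect_equal(feats$id, paste0("c", 1:9))
  got <- as.matrix(feats[, feature_manifest()])
  rownames(got) <- feats$id
  expect_equal(got, golden_expected(), tolerance = 1e-12)
  # determinism: bit-identical on repeat
  again <- extract_features(golden_cnvs(), mini_bundle(), window = 5)
  expect_identical(feats, again)
  # empty input keeps the full header
  empty <- extract_features(golden_cnvs()[0, ], mini_bundle())
  expect_equal(colnames(empty), c("id", feature_manifest()))
  expect_equal(nrow(empty), 0)
})

test_that("counts are non-negative integers and grow under containment", {
  b <- fx_bundle()
  cnvs <- fx_cnvs(40, seed = 311)
  f <- extract_features(cnvs, b)
  cnt_cols <- c("gene_count", "disease_count", "exon_count",
                "promoter_count", "pathogenic_snv_count")
  for (cc in cnt_cols) {
    expect_true(all(f[[cc]] >= 0))
    expect_equal(f[[cc]], round(f[[cc]]))
  }
  expect_true(all(f$gc_content >= 0 & f$gc_content <= 1))
  expect_true(all(f$popmax_af >= 0 & f$popmax_af <= 1))
  # enlarge every CNV: monotone features never decrease
  big <- cnvs
  big$start <- pmax(0, big$start - 2000)
  big$end <- pmin(big$end + 2000,
                  Biostrings::width(b$genome)[match(big$chrom,
                                                    names(b$genome))])
  fb <- extract_features(big, b)
  for (cc in c(cnt_cols, "bp_length"))
    expect_true(all(fb[[cc]] >= f[[cc]]), label = cc)
})
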
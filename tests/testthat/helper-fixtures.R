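# Shared fixtures, built once per test run and cached. The synthetic
# bundle/CNV sets come from the package's own generator (which is itself
# under test in test-fixtures.R); the "mini" bundle is fully
# hand-specified so feature values can be verified by hand arithmetic.

.fx_cache <- new.env(parent = emptyenv())

.fx_memo <- function(key, builder) {
  if (!exists(key, envir = .fx_cache)) assign(key, builder(), envir = .fx_cache)
  get(key, envir = .fx_cache)
}

fx_config <- function(...) fixture_config(seed = 42, ...)

fx_bundle <- function() .fx_memo("bundle", function() {
  dir <- file.path(tempdir(), "cnvclass-fx-bundle")
  suppressWarnings(generate_bundle(fx_config(), dir))
})

fx_cnvs <- function(n_per_class = 150, seed = 1001, noise = 0) {
  key <- sprintf("cnvs_%d_%d_%g", n_per_class, seed, noise)
  .fx_memo(key, function() {
    cfg <- fx_config(cnv_counts = stats::setNames(rep(n_per_class, 3),
                                                  c("benign", "VUS",
                                                    "pathogenic")),
                     label_noise = noise)
    generate_labeled_cnvs(cfg, fx_bundle(), seed = seed)
  })
}

fx_features <- function(n_per_class = 150, seed = 1001) {
  key <- sprintf("feat_%d_%d", n_per_class, seed)
  .fx_memo(key, function()
    extract_features(fx_cnvs(n_per_class, seed), fx_bundle()))
}

# A small trained deletion model on the shared fixture (rf roster only,
# few draws): reused by the classifier, SHAP and export tests.
fx_model <- function() .fx_memo("model", function() {
  cnvs <- fx_cnvs()
  feats <- fx_features()
  del <- cnvs$type == "DEL"
  cnv_classifier(feats[del, ], cnvs$observed_label[del], cnv_type = "DEL",
                 roster = default_roster("rf"), folds = 3, n_draws = 2,
                 seed = 5)
})

# ---- hand-specified mini bundle (golden feature values) ------------------
# One 10 kb chromosome: p telomere 0, centromere [4000,4500), q telomere
# 10000. Sequence is "ACGT" repeated (GC exactly 0.5 in any window of
# length divisible by 4), with [6050,6150) replaced by 100 G's. Gene A
# [1000,2000)+ (exons [1000,1200),[1800,2000); promoter [0,1000); 2
# diseases), gene B [2500,3000)- (exon [2600,2700); promoter [3000,4000);
# 1 disease). Pathogenic SNVs at 1-based 1500, 2650, 5000. SV records:
# DEL [1000,2000) af .01, DUP [6000,7000) af .3, DEL [6000,7000) af .12.
# Dosage regions: r1 [900,2100) HI 3/TS 40 (10, .97, .2);
# r2 [2400,3100) HI 2/TS NA (NA, .5, 1.5); r3 [8000,8300) HI 3/TS 0
# (20, .8, .3); r4 [8100,8500) HI 3/TS 2 (5, .99, .5). phyloP 1.0
# everywhere except 11.0 on [1190,1210); phastCons 0.4 everywhere.
mini_bundle_dir <- function() .fx_memo("mini_dir", function() {
  dir <- file.path(tempdir(), "cnvclass-mini-bundle")
  dir.create(dir, showWarnings = FALSE)
  seq <- strsplit(strrep("ACGT", 2500), "")[[1]]
  seq[6051:6150] <- "G"                       # 0-based [6050,6150)
  writeLines(c(">1", paste(seq, collapse = "")), file.path(dir, "genome.fa"))
  writeLines(c("#chrom\tstart\tend\tstrand\tgene\texon_starts\texon_ends",
               "1\t1000\t2000\t+\tA\t1000,1800\t1200,2000",
               "1\t2500\t3000\t-\tB\t2600\t2700"),
             file.path(dir, "genes.tsv"))
  writeLines(c("#gene\tdisease", "A\tD1", "A\tD2", "B\tD1"),
             file.path(dir, "diseases.tsv"))
  writeLines(c("#chrom\tpos\tsignificance",
               "1\t1500\tPathogenic",
               "1\t2650\tLikely pathogenic",
               "1\t5000\tPathogenic"),
             file.path(dir, "pathogenic_snvs.tsv"))
  writeLines(c("#chrom\tstart\tend\ttype\taf_eas\taf_afr\taf_nfe",
               "1\t1000\t2000\tDEL\t0.01\t0\t0",
               "1\t6000\t7000\tDUP\t0\t0.3\t0",
               "1\t6000\t7000\tDEL\t0\t0\t0.12"),
             file.path(dir, "sv_frequencies.tsv"))
  writeLines(c("#chrom\tstart\tend\thi_score\tts_score\thi_index\tpli\tloeuf",
               "1\t900\t2100\t3\t40\t10\t0.97\t0.2",
               "1\t2400\t3100\t2\tNA\tNA\t0.5\t1.5",
               "1\t8000\t8300\t3\t0\t20\t0.8\t0.3",
               "1\t8100\t8500\t3\t2\t5\t0.99\t0.5"),
             file.path(dir, "dosage_regions.tsv"))
  writeLines(c("1\t0\t1190\t1.0", "1\t1190\t1210\t11.0",
               "1\t1210\t10000\t1.0"),
             file.path(dir, "phylop.bedGraph"))
  writeLines("1\t0\t10000\t0.4", file.path(dir, "phastcons.bedGraph"))
  writeLines(c(paste0("#chrom\tp_telomere\tcentromere_start\t",
                      "centromere_end\tq_telomere"),
               "1\t0\t4000\t4500\t10000"),
             file.path(dir, "chromosome_structure.tsv"))
  dir
})

mini_bundle <- function() .fx_memo("mini", function()
  load_bundle(mini_bundle_dir()))

# The nine golden CNVs and their hand-computed 17-feature rows.
golden_cnvs <- function() {
  df <- data.frame(
    chrom = "1",
    start = c(1150, 6050, 3900, 2550, 0, 850, 2005, 8050, 1500),
    end = c(1250, 6950, 4600, 3500, 60, 2150, 2060, 8450, 2700),
    type = c("DEL", "DUP", "DEL", "DUP", "DEL", "DEL", "DUP", "DUP", "DEL"),
    id = paste0("c", 1:9), labels = NA_character_,
    stringsAsFactors = FALSE)
  class(df) <- c("cnv_set", "data.frame")
  df
}

golden_expected <- function() {
  z7 <- rep(0, 7)
  onehot <- function(...) {
    v <- rep(0, 7)
    sel <- list(...)
    for (s in names(sel)) v[match(s, c("0", "1", "2", "3", "30", "40",
                                       "not_evaluated"))] <- sel[[s]]
    v
  }
  rows <- list(
    #     cen   tel    gc      len  gn ds ex pr sv popmax  pp   pc
    c1 = c(2750, 1150, 0.5,    100, 1, 2, 1, 0, 0, 0,     11, 0.4,
           onehot("3" = 1), onehot("40" = 1), 10, 0.97, 0.2),
    c2 = c(1550, 3050, 5 / 9,  900, 0, 0, 0, 0, 0, 0.3,    1, 0.4,
           z7, z7, 100, 0, 2),
    c3 = c(0,    3900, 0.5,    700, 0, 0, 0, 1, 0, 0,      1, 0.4,
           z7, z7, 100, 0, 2),
    c4 = c(500,  2550, 0.5,    950, 1, 1, 1, 1, 1, 0,      1, 0.4,
           onehot("2" = 1), onehot("not_evaluated" = 1), 100, 0.5, 1.5),
    c5 = c(3940, 0,    0.5,     60, 0, 0, 0, 1, 0, 0,      1, 0.4,
           z7, z7, 100, 0, 2),
    c6 = c(1850, 850,  0.5,   1300, 1, 2, 2, 1, 1, 0.01,  11, 0.4,
           onehot("3" = 1), onehot("40" = 1), 10, 0.97, 0.2),
    c7 = c(1940, 2005, 28 / 55, 55, 0, 0, 1, 0, 0, 0,      1, 0.4,
           onehot("3" = 1), onehot("40" = 1), 10, 0.97, 0.2),
    c8 = c(3550, 1550, 0.5,    400, 0, 0, 0, 0, 0, 0,      1, 0.4,
           onehot("3" = 2), onehot("0" = 1, "2" = 1), 5, 0.99, 0.3),
    c9 = c(1300, 1500, 0.5,   1200, 2, 3, 2, 0, 1, 0,      1, 0.4,
           onehot("2" = 1, "3" = 1),
           onehot("40" = 1, "not_evaluated" = 1), 10, 0.97, 0.2))
  m <- do.call(rbind, rows)
  colnames(m) <- feature_manifest()
  m
}

# Synthetic 3-class data with known structure for the training machinery:
# class depends nonlinearly on two features, so flexible learners beat the
# linear baseline.
.toy_xy <- function(n, seed, noise_features = 3) {
  set.seed(seed)
  x1 <- runif(n); x2 <- runif(n)
  y <- ifelse(x1 > 0.55 & x2 > 0.55, "pathogenic",
              ifelse(x1 < 0.45 & x2 < 0.45, "benign", "VUS"))
  x <- cbind(x1 = x1, x2 = x2,
             matrix(runif(n * noise_features), n,
                    dimnames = list(NULL, paste0("noise", 1:noise_features))))
  list(x = x, y = factor(y, levels = significance_classes()))
}
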
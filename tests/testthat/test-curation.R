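test_that("submitted labels collapse by the pathogenic > VUS > benign rules", {
  expect_equal(collapse_label("Pathogenic;VUS"), "pathogenic")
  expect_equal(collapse_label("Likely pathogenic;Benign"), "pathogenic")
  expect_equal(collapse_label("VUS;Likely benign"), "VUS")
  expect_equal(collapse_label("Uncertain significance"), "VUS")
  expect_equal(collapse_label("Benign;Likely benign"), "benign")
  expect_equal(collapse_label("drug response"), "AMBIGUOUS")
  expect_equal(collapse_label("Benign;risk factor"), "AMBIGUOUS")
})

.toy_records <- function() {
  df <- data.frame(
    chrom = "1",
    start = c(100, 5000, 5000, 9000, 9000, 20000, 30000, 40000),
    end = c(900, 6000, 6000, 9800, 9800, 20030, 31000, 41000),
    type = c("INV", "DEL", "DEL", "DUP", "DUP", "DEL", "DEL", "DUP"),
    id = paste0("r", 1:8),
    labels = c("Pathogenic", "Benign", "Benign", "Pathogenic", "Benign",
               "Uncertain significance", "Pathogenic", "Benign"),
    stringsAsFactors = FALSE)
  class(df) <- c("cnv_set", "data.frame")
  df
}

test_that("the constructed toy set yields the rule-forced tallies", {
  # 1 inversion, an agreeing duplicate pair, a conflicting co-located
  # pair, one 30 bp record, two clean records
  res <- curate_cnvs(.toy_records())
  expect_equal(res$report$removed$non_cnv_type, 1)
  expect_equal(res$report$removed$duplicate, 1)
  expect_equal(res$report$removed$conflict, 2)
  expect_equal(res$report$removed$too_small, 1)
  expect_equal(res$report$n_kept, 3)
  expect_setequal(res$kept$id, c("r2", "r7", "r8"))
  expect_equal(sort(unique(res$kept$collapsed_label)),
               c("benign", "pathogenic"))
})

test_that("the leakage guard drops exact coordinate+type matches", {
  res <- curate_cnvs(.toy_records(),
                     training_coordinates = data.frame(
                       chrom = "1", start = 30000, end = 31000, type = "DEL"))
  expect_equal(res$report$removed$leakage, 1)
  expect_false("r7" %in% res$kept$id)
  # same coordinates, different type: not leakage
  res2 <- curate_cnvs(.toy_records(),
                      training_coordinates = data.frame(
                        chrom = "1", start = 30000, end = 31000, type = "DUP"))
  expect_equal(res2$report$removed$leakage, 0)
})

test_that("report counts are conserved and curation is idempotent", {
  expect_equal(curate_cnvs(.toy_records()[0, ])$report$n_kept, 0)
  set.seed(99)
  for (rep in 1:15) {
    n <- sample(20:120, 1)
    df <- data.frame(
      chrom = sample(c("1", "2"), n, TRUE),
      start = s <- sample(10, n, TRUE) * 1000,
      type = sample(c("DEL", "DUP", "INV"), n, TRUE,
                    prob = c(0.45, 0.45, 0.1)),
      id = paste0("x", seq_len(n)),
      labels = sample(c("Pathogenic", "Benign", "VUS", "other",
                        "Pathogenic;VUS"), n, TRUE),
      stringsAsFactors = FALSE)
    df$end <- df$start + sample(c(10, 30, 500, 5000), n, TRUE)
    class(df) <- c("cnv_set", "data.frame")
    res <- curate_cnvs(df)
    expect_equal(res$report$n_input,
                 res$report$n_kept + sum(unlist(res$report$removed)))
    # second pass removes nothing
    res2 <- curate_cnvs(res$kept)
    expect_equal(res2$report$n_kept, res$report$n_kept)
    expect_equal(sum(unlist(res2$report$removed)), 0)
    # row order never changes the kept set
    resp <- curate_cnvs(df[sample(n), ])
    expect_setequal(resp$kept$id, res$kept$id)
  }
})
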
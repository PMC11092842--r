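# Synthetic annotation bundle and labeled CNV sets with known generative
# structure, so every stage is testable without downloads. The genome is a
# few short chromosomes with blockwise-varying GC; genes carry exons,
# strands and TSSs; conservation tracks have localized bumps over exons;
# pathogenic SNVs cluster in haploinsufficient genes; common SV-frequency
# records sit in a reserved gene desert so clearly-benign CNVs exist.
# Labels follow a deterministic rule over in-scope features (dosage HI
# category 3 overlap, exon count vs popmax, short+common+non-genic), with
# optional uniform label noise; the pre-noise rule label is kept in the
# manifest as ground truth.

#' Configuration for the synthetic fixture generator
#'
#' @param seed bundle RNG seed.
#' @param cnv_seed CNV-set RNG seed (defaults to `seed + 1`); separate so
#'   train/test sets can share annotations but not variants.
#' @param n_chromosomes,chrom_length genome shape.
#' @param n_genes total genes across the genome.
#' @param exons_per_gene inclusive range.
#' @param gene_length inclusive range in bp.
#' @param dosage_fraction fraction of genes that get a curated dosage
#'   region.
#' @param n_sv_records SV population-frequency records (a third are
#'   common variants placed in the gene desert).
#' @param cnv_counts named per-class CNV quotas (pre-noise).
#' @param label_noise probability a label is flipped to a uniformly chosen
#'   other class; must lie in \[0, 0.5).
#' @param rule_tau,rule_phi,rule_lambda parameters of the labeling rule:
#'   pathogenic iff (overlaps an HI category-3 dosage region) or
#'   (exon_count >= tau and popmax < phi); benign iff (bp_length < lambda
#'   and popmax >= phi and exon_count == 0); else VUS.
#' @return object of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1, cnv_seed = seed + 1,
                           n_chromosomes = 3, chrom_length = 300000,
                           n_genes = 45, exons_per_gene = c(2, 8),
                           gene_length = c(2000, 8000),
                           dosage_fraction = 0.35, n_sv_records = 120,
                           cnv_counts = c(benign = 100, VUS = 100,
                                          pathogenic = 100),
                           label_noise = 0, rule_tau = 3, rule_phi = 0.05,
                           rule_lambda = 2000) {
  stopifnot(label_noise >= 0, label_noise < 0.5, n_chromosomes >= 1,
            all(cnv_counts >= 0), n_genes >= 0)
  cfg <- as.list(environment())
  class(cfg) <- "fixture_config"
  cfg
}

.chrom_layout <- function(cfg) {
  L <- cfg$chrom_length
  data.frame(
    chrom = as.character(seq_len(cfg$n_chromosomes)),
    p_telomere = 0,
    centromere_start = floor(0.45 * L),
    centromere_end = floor(0.50 * L),
    q_telomere = L,
    desert_start = floor(0.80 * L),   # reserved gene-free zone on the q arm
    desert_end = L - 3000,
    stringsAsFactors = FALSE)
}

#' Generate a synthetic annotation bundle
#'
#' Writes the full resource set (genome FASTA, genes, diseases,
#' pathogenic SNVs, SV frequencies, phyloP/phastCons bedGraph tracks,
#' dosage regions, chromosome structure) plus `manifest.json` into `dir`,
#' then loads and returns it. Byte-identical output for a fixed seed.
#'
#' @param config a [fixture_config()].
#' @param dir output directory (created if missing).
#' @return the loaded `annotation_bundle`, with the manifest attached as
#'   `attr(, "manifest")`.
#' @export
generate_bundle <- function(config, dir) {
  stopifnot(inherits(config, "fixture_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  layout <- .chrom_layout(config)
  L <- config$chrom_length

  # genome with blockwise GC
  seqs <- character(config$n_chromosomes)
  block <- 1000
  for (c_i in seq_len(config$n_chromosomes)) {
    nb <- ceiling(L / block)
    gc <- stats::runif(nb, 0.3, 0.7)
    chunks <- vapply(seq_len(nb), function(b) {
      len <- min(block, L - (b - 1) * block)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                   prob = c((1 - gc[b]) / 2, gc[b] / 2, gc[b] / 2,
                            (1 - gc[b]) / 2)), collapse = "")
    }, "")
    seqs[c_i] <- paste(chunks, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- layout$chrom
  Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"), width = 70)

  # gene placement on both arms, outside centromere/telomere margins and
  # the reserved desert
  zones <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    rbind(data.frame(chrom = layout$chrom[i], lo = 3000,
                     hi = layout$centromere_start[i] - 2000),
          data.frame(chrom = layout$chrom[i],
                     lo = layout$centromere_end[i] + 2000,
                     hi = layout$desert_start[i] - 2000))
  }))
  genes <- NULL
  cursor <- zones$lo          # per-zone placement cursor; zones fill round-robin
  full <- rep(FALSE, nrow(zones))
  zi <- 0
  for (g in seq_len(config$n_genes)) {
    len <- round(stats::runif(1, config$gene_length[1], config$gene_length[2]))
    gap <- round(stats::runif(1, 1500, 4000))
    placed <- FALSE
    for (try in seq_len(nrow(zones))) {
      zi <- zi %% nrow(zones) + 1
      if (full[zi]) next
      if (cursor[zi] + gap + len > zones$hi[zi]) { full[zi] <- TRUE; next }
      start <- cursor[zi] + gap
      genes <- rbind(genes, data.frame(
        chrom = zones$chrom[zi], start = start, end = start + len,
        strand = sample(c("+", "-"), 1), gene = sprintf("GENE%03d", g),
        stringsAsFactors = FALSE))
      cursor[zi] <- start + len
      placed <- TRUE
      break
    }
    if (!placed)
      stop("impossible config: ", config$n_genes,
           " genes exceed chromosome capacity")
  }
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL

  # exons: first at the gene edge (so the TSS sits on an exon), the rest
  # spread through the body
  exon_starts <- character(nrow(genes)); exon_ends <- character(nrow(genes))
  exon_tab <- NULL
  for (i in seq_len(nrow(genes))) {
    k <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1)
    glen <- genes$end[i] - genes$start[i]
    anchors <- sort(sample(seq(0, glen - 150, by = 50), k))
    es <- genes$start[i] + anchors
    ee <- pmin(genes$end[i], es + round(stats::runif(k, 80, 200)))
    keep <- !duplicated(es) & ee > es
    es <- es[keep]; ee <- ee[keep]
    # enforce disjoint exons
    if (length(es) > 1) for (j in 2:length(es))
      es[j] <- max(es[j], ee[j - 1] + 10)
    ok <- es < ee & ee <= genes$end[i]
    es <- es[ok]; ee <- ee[ok]
    exon_starts[i] <- paste(es, collapse = ",")
    exon_ends[i] <- paste(ee, collapse = ",")
    exon_tab <- rbind(exon_tab, data.frame(chrom = genes$chrom[i],
                                           start = es, end = ee,
                                           gene = genes$gene[i]))
  }
  gene_df <- cbind(genes, exon_starts = exon_starts, exon_ends = exon_ends)
  .write_tsv(gene_df[, c("chrom", "start", "end", "strand", "gene",
                         "exon_starts", "exon_ends")],
             file.path(dir, "genes.tsv"))

  # disease-gene map
  n_dis <- stats::rpois(nrow(genes), 1.5)
  diseases <- data.frame(
    gene = rep(genes$gene, n_dis),
    disease = sprintf("D%04d", seq_len(sum(n_dis))),
    stringsAsFactors = FALSE)
  .write_tsv(diseases, file.path(dir, "diseases.tsv"))

  # dosage regions over a fraction of genes; category 3 = sufficient
  # evidence for haploinsufficiency, with concordant gene metrics
  nd <- max(1, round(config$dosage_fraction * nrow(genes)))
  dosage_genes <- sort(sample(seq_len(nrow(genes)), nd))
  hi_cat <- sample(c("0", "1", "2", "3", "30", "40"), nd, replace = TRUE,
                   prob = c(0.2, 0.1, 0.1, 0.3, 0.15, 0.15))
  ts_cat <- sample(c("0", "1", "2", "3", "30", "40"), nd, replace = TRUE,
                   prob = c(0.3, 0.15, 0.1, 0.2, 0.1, 0.15))
  is3 <- hi_cat == "3"
  dosage <- data.frame(
    chrom = genes$chrom[dosage_genes],
    start = pmax(0, genes$start[dosage_genes] - round(stats::runif(nd, 0, 400))),
    end = genes$end[dosage_genes] + round(stats::runif(nd, 0, 400)),
    hi_score = hi_cat, ts_score = ts_cat,
    hi_index = round(ifelse(is3, stats::runif(nd, 0, 15),
                            stats::runif(nd, 40, 95)), 3),
    pli = round(ifelse(is3, stats::runif(nd, 0.9, 1),
                       stats::runif(nd, 0, 0.6)), 4),
    loeuf = round(ifelse(is3, stats::runif(nd, 0.05, 0.35),
                         stats::runif(nd, 0.6, 1.9)), 4),
    stringsAsFactors = FALSE)
  na_rows <- sample(seq_len(nd), max(0, round(0.1 * nd)))
  dosage$hi_index[na_rows] <- NA
  .write_tsv(dosage, file.path(dir, "dosage_regions.tsv"))

  # pathogenic SNVs cluster in exons of HI-3 genes, sparse elsewhere
  snvs <- NULL
  hi3_genes <- genes$gene[dosage_genes[is3]]
  for (i in seq_len(nrow(exon_tab))) {
    lam <- if (exon_tab$gene[i] %in% hi3_genes) 2.5 else 0.1
    npts <- stats::rpois(1, lam)
    if (npts > 0) {
      p <- sort(sample(seq(exon_tab$start[i] + 1, exon_tab$end[i]), npts,
                       replace = FALSE))
      snvs <- rbind(snvs, data.frame(
        chrom = exon_tab$chrom[i], pos = p,   # 1-based
        significance = sample(c("Pathogenic", "Likely pathogenic"),
                              npts, replace = TRUE)))
    }
  }
  if (is.null(snvs))
    snvs <- data.frame(chrom = character(), pos = numeric(),
                       significance = character())
  .write_tsv(snvs, file.path(dir, "pathogenic_snvs.tsv"))

  # SV frequency records: common variants in the desert, rare ones anywhere
  n_common <- round(config$n_sv_records / 3)
  n_rare <- config$n_sv_records - n_common
  pops <- c("af_afr", "af_amr", "af_eas", "af_nfe", "af_sas")
  mk_af <- function(n, lo, hi) {
    m <- matrix(0, n, length(pops), dimnames = list(NULL, pops))
    top <- sample(length(pops), n, replace = TRUE)
    for (i in seq_len(n)) {
      m[i, top[i]] <- stats::runif(1, lo, hi)
      m[i, -top[i]] <- stats::runif(length(pops) - 1, 0, m[i, top[i]])
    }
    round(m, 6)
  }
  ci <- sample(nrow(layout), n_common, replace = TRUE)
  clen <- round(stats::runif(n_common, 300, 1500))
  cstart <- floor(stats::runif(n_common, layout$desert_start[ci],
                               layout$desert_end[ci] - clen))
  common <- data.frame(chrom = layout$chrom[ci], start = cstart,
                       end = cstart + clen,
                       type = sample(c("DEL", "DUP"), n_common, TRUE),
                       stringsAsFactors = FALSE)
  common <- cbind(common, mk_af(n_common, 0.06, 0.25))
  ri <- sample(nrow(layout), n_rare, replace = TRUE)
  rlen <- round(stats::runif(n_rare, 500, 20000))
  rstart <- floor(stats::runif(n_rare, 2000, layout$q_telomere[ri] - rlen - 2000))
  rare <- data.frame(chrom = layout$chrom[ri], start = rstart,
                     end = rstart + rlen,
                     type = sample(c("DEL", "DUP"), n_rare, TRUE),
                     stringsAsFactors = FALSE)
  rare <- cbind(rare, mk_af(n_rare, 1e-5, 0.01))
  svf <- rbind(common, rare)
  .write_tsv(svf, file.path(dir, "sv_frequencies.tsv"))

  # conservation: 150 bp runs; bumps over exons
  exon_idx <- build_index(exon_tab)
  run <- 150
  for (track in c("phylop", "phastcons")) {
    rows <- NULL
    for (c_i in seq_len(nrow(layout))) {
      starts <- seq(0, L - 1, by = run)
      ends <- pmin(L, starts + run)
      rdf <- data.frame(chrom = layout$chrom[c_i], start = starts, end = ends)
      hit <- unique(index_hits(exon_idx, rdf)$query)
      exonic <- seq_along(starts) %in% hit
      score <- if (track == "phylop")
        round(stats::rnorm(length(starts), 0, 0.5) +
                ifelse(exonic, stats::runif(length(starts), 2, 5), 0), 4)
      else
        round(ifelse(exonic, stats::runif(length(starts), 0.6, 0.99),
                     stats::runif(length(starts), 0.01, 0.2)), 4)
      rows <- rbind(rows, cbind(rdf, score = score))
    }
    writeLines(sprintf("%s\t%d\t%d\t%s", rows$chrom, rows$start, rows$end,
                       format(rows$score, trim = TRUE, scientific = FALSE)),
               file.path(dir, paste0(track, ".bedGraph")))
  }

  .write_tsv(layout[, c("chrom", "p_telomere", "centromere_start",
                        "centromere_end", "q_telomere")],
             file.path(dir, "chromosome_structure.tsv"))

  manifest <- list(
    seed = config$seed, n_chromosomes = config$n_chromosomes,
    chrom_length = L, n_genes = nrow(genes), n_exons = nrow(exon_tab),
    n_diseases = nrow(diseases), n_dosage_regions = nrow(dosage),
    n_hi3_regions = sum(is3), n_pathogenic_snvs = nrow(snvs),
    n_sv_records = nrow(svf),
    rule = list(tau = config$rule_tau, phi = config$rule_phi,
                lambda = config$rule_lambda))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  bundle <- load_bundle(dir)
  attr(bundle, "manifest") <- manifest
  bundle
}

.write_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(colnames(df), collapse = "\t")), con)
  if (nrow(df))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, na = "NA")
  invisible(path)
}

# Rule labels from the features the rule is defined over.
.rule_label <- function(cnvs, bundle, config) {
  fc <- functional_counts(cnvs, bundle)
  popmax <- popmax_frequency(cnvs, bundle$sv_frequencies)
  dos <- dosage_features(cnvs, bundle$dosage_regions, vocab = bundle$vocab)
  len <- cnvs$end - cnvs$start
  hi3 <- dos[["hi_3"]] > 0
  path <- hi3 | (fc$exon_count >= config$rule_tau & popmax < config$rule_phi)
  ben <- !path & len < config$rule_lambda & popmax >= config$rule_phi &
    fc$exon_count == 0
  ifelse(path, "pathogenic", ifelse(ben, "benign", "VUS"))
}

#' Generate a labeled synthetic CNV set
#'
#' Draws CNVs until the per-class quotas of `config$cnv_counts` are filled
#' under the deterministic labeling rule (see [fixture_config()]), then
#' flips each label to a uniformly chosen other class with probability
#' `label_noise`. The pre-noise rule label is retained.
#'
#' @param config a [fixture_config()].
#' @param bundle the bundle from [generate_bundle()].
#' @param dir optional; when given, writes `cnvs.tsv` (observed labels)
#'   and `cnv_manifest.json` (pre-noise class counts, rule parameters).
#' @param seed RNG seed (defaults to `config$cnv_seed`).
#' @return a `cnv_set` with `labels` (submitted-style observed label),
#'   `observed_label` and `rule_label` columns.
#' @export
generate_labeled_cnvs <- function(config, bundle, dir = NULL,
                                  seed = config$cnv_seed) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(seed)
  layout <- .chrom_layout(config)
  quotas <- config$cnv_counts[c("benign", "VUS", "pathogenic")]
  got <- list(benign = NULL, VUS = NULL, pathogenic = NULL)
  dos <- bundle$dosage_regions
  hi3 <- dos[dos$hi_score == "3", , drop = FALSE]
  commons <- bundle$sv_frequencies[
    do.call(pmax, bundle$sv_frequencies[grep("^af_",
      colnames(bundle$sv_frequencies))]) >= config$rule_phi, , drop = FALSE]
  genes <- bundle$genes

  propose <- function(n) {
    kind <- sample(c("dosage", "exonic", "common", "random"), n,
                   replace = TRUE, prob = c(0.25, 0.2, 0.3, 0.25))
    out <- NULL
    for (k in kind) {
      row <- switch(k,
        dosage = if (nrow(hi3)) {
          i <- sample(nrow(hi3), 1)
          len <- (hi3$end[i] - hi3$start[i]) + round(stats::runif(1, 0, 4000))
          s <- max(0, hi3$start[i] - round(stats::runif(1, 0, 2000)))
          data.frame(chrom = hi3$chrom[i], start = s, end = s + len,
                     type = sample(c("DEL", "DUP"), 1))
        },
        exonic = {
          i <- sample(nrow(genes), 1)
          pad <- round(stats::runif(1, 0, 1500))
          data.frame(chrom = genes$chrom[i],
                     start = max(0, genes$start[i] - pad),
                     end = genes$end[i] + round(stats::runif(1, 0, 1500)),
                     type = sample(c("DEL", "DUP"), 1))
        },
        common = if (nrow(commons)) {
          i <- sample(nrow(commons), 1)
          len <- commons$end[i] - commons$start[i]
          jit <- round(stats::runif(1, -0.1, 0.1) * len)
          data.frame(chrom = commons$chrom[i],
                     start = max(0, commons$start[i] + jit),
                     end = commons$end[i] + jit, type = commons$type[i])
        },
        random = {
          c_i <- sample(nrow(layout), 1)
          len <- round(exp(stats::runif(1, log(100), log(20000))))
          s <- floor(stats::runif(1, 500,
                                  layout$q_telomere[c_i] - len - 500))
          data.frame(chrom = layout$chrom[c_i], start = s, end = s + len,
                     type = sample(c("DEL", "DUP"), 1))
        })
      if (!is.null(row)) out <- rbind(out, row)
    }
    out
  }

  for (batch in seq_len(60)) {
    need <- vapply(names(quotas), function(cl)
      quotas[[cl]] - NROW(got[[cl]]), 0)
    if (all(need <= 0)) break
    cand <- propose(max(60, 3 * sum(pmax(0, need))))
    cand$chrom <- as.character(cand$chrom)
    cand <- .new_cnv_set(cbind(cand, id = NA_character_,
                               labels = NA_character_))
    cand$rule_label <- .rule_label(cand, bundle, config)
    for (cl in names(quotas)) {
      take <- min(max(0, need[[cl]]), sum(cand$rule_label == cl))
      if (take > 0)
        got[[cl]] <- rbind(got[[cl]],
                           cand[which(cand$rule_label == cl)[seq_len(take)], ])
    }
  }
  short <- names(quotas)[vapply(names(quotas), function(cl)
    NROW(got[[cl]]) < quotas[[cl]], TRUE)]
  if (length(short))
    stop("could not fill CNV quotas for class(es): ",
         paste(short, collapse = ", "),
         "; relax the rule parameters or enlarge the bundle")
  cnvs <- do.call(rbind, got[names(quotas)])
  cnvs$id <- sprintf("cnv_%05d", seq_len(nrow(cnvs)))

  flip <- stats::runif(nrow(cnvs)) < config$label_noise
  classes <- significance_classes()
  observed <- cnvs$rule_label
  if (any(flip))
    observed[flip] <- vapply(cnvs$rule_label[flip], function(cl)
      sample(setdiff(classes, cl), 1), "")
  cnvs$observed_label <- observed
  cnvs$labels <- c(benign = "Benign", VUS = "Uncertain significance",
                   pathogenic = "Pathogenic")[observed]
  rownames(cnvs) <- NULL
  class(cnvs) <- c("cnv_set", "data.frame")

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_cnvs(cnvs, file.path(dir, "cnvs.tsv"))
    jsonlite::write_json(list(
      seed = seed, label_noise = config$label_noise,
      rule = list(tau = config$rule_tau, phi = config$rule_phi,
                  lambda = config$rule_lambda),
      pre_noise_counts = as.list(table(factor(cnvs$rule_label,
                                              levels = classes))),
      observed_counts = as.list(table(factor(observed, levels = classes))),
      rule_labels = stats::setNames(as.list(cnvs$rule_label), cnvs$id)),
      file.path(dir, "cnv_manifest.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
  }
  cnvs
}
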
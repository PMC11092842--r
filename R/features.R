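# The 17-feature annotation engine. Six feature groups:
#   genomic position (centromere/telomere distance), CNV composition
#   (GC content, bp length), functional annotation (gene/disease/exon/
#   promoter/pathogenic-SNV counts), population frequency (popmax over
#   type-matched records at >= 50% reciprocal overlap), conservation
#   (max of a centered moving average of phyloP and phastCons), and dosage
#   sensitivity (HI/TS one-hot sums, min HI index, max pLI, min LOEUF).

#' Default sentinels for CNVs overlapping no dosage-sensitive region
#'
#' Absence of dosage evidence is encoded in the loss-tolerant direction of
#' each metric: a high HI index, zero pLI and a high LOEUF.
#' @return named list with `hi_index`, `pli`, `loeuf`.
#' @export
dosage_sentinels <- function() list(hi_index = 100, pli = 0, loeuf = 2.0)

#' Distances to centromere and telomere
#'
#' For a CNV on the P arm the centromere distance runs from the CNV end to
#' the centromere start, and the telomere distance from the P telomere to
#' the CNV start; on the Q arm the mirror definitions apply (CNV start to
#' centromere end; CNV end to Q telomere). Both are clamped at zero. Arm
#' assignment uses the CNV midpoint; a CNV centered inside the centromere
#' gets centromere distance 0 and the nearer arm's telomere distance.
#'
#' @param cnvs a `cnv_set` or interval data frame.
#' @param structure chromosome structure table
#'   (see [read_chromosome_structure()]).
#' @return data frame with `centromere_distance`, `telomere_distance` (bp).
#' @export
positional_distances <- function(cnvs, structure) {
  i <- match(cnvs$chrom, structure$chrom)
  if (any(is.na(i)))
    stop("chromosome(s) missing from structure table: ",
         paste(unique(cnvs$chrom[is.na(i)]), collapse = ", "))
  st <- structure[i, , drop = FALSE]
  mid <- (cnvs$start + cnvs$end) / 2
  p_arm <- mid < st$centromere_start
  q_arm <- mid >= st$centromere_end
  cen <- ifelse(p_arm, st$centromere_start - cnvs$end,
         ifelse(q_arm, cnvs$start - st$centromere_end, 0))
  tel <- ifelse(p_arm, cnvs$start - st$p_telomere,
         ifelse(q_arm, st$q_telomere - cnvs$end,
                pmin(cnvs$start - st$p_telomere, st$q_telomere - cnvs$end)))
  data.frame(centromere_distance = pmax(0, cen),
             telomere_distance = pmax(0, tel))
}

#' GC content of CNV intervals
#'
#' Fraction of unambiguous bases (A/C/G/T, case-insensitive) in the spanned
#' sequence that are G or C. `N` runs are excluded from the denominator; an
#' all-N interval yields 0 with a warning.
#'
#' @param cnvs interval data frame.
#' @param genome a named `DNAStringSet` keyed by normalized chromosome.
#' @return numeric vector in \[0, 1\].
#' @export
gc_content <- function(cnvs, genome) {
  out <- numeric(nrow(cnvs))
  for (r in seq_len(nrow(cnvs))) {
    chrom <- cnvs$chrom[r]
    if (!chrom %in% names(genome))
      stop("chromosome ", chrom, " not in genome")
    seq <- Biostrings::subseq(genome[[chrom]], cnvs$start[r] + 1, cnvs$end[r])
    counts <- Biostrings::letterFrequency(seq, c("A", "C", "G", "T"))
    denom <- sum(counts)
    if (denom == 0) {
      warning("all-ambiguous sequence in interval ", chrom, ":",
              cnvs$start[r], "-", cnvs$end[r], "; GC set to 0")
      out[r] <- 0
    } else out[r] <- (counts[["C"]] + counts[["G"]]) / denom
  }
  out
}

#' Functional annotation counts
#'
#' Five counts per CNV: overlapping genes (>= 1 shared bp); diseases,
#' summed over overlapping genes (a disease shared by two hit genes counts
#' twice); exons across all genes, each padded by 10 bp for canonical
#' splice regions; promoter regions (the 1,000 bp immediately upstream of
#' each TSS, strand-aware); and pathogenic/likely-pathogenic short-variant
#' positions inside the CNV.
#'
#' @param cnvs interval data frame.
#' @param bundle an `annotation_bundle`.
#' @return data frame with columns `gene_count`, `disease_count`,
#'   `exon_count`, `promoter_count`, `pathogenic_snv_count`.
#' @export
functional_counts <- function(cnvs, bundle) {
  n <- nrow(cnvs)
  cnt <- function(idx) {
    h <- index_hits(idx, cnvs)
    tabulate(h$query, nbins = n)
  }
  gh <- index_hits(bundle$idx$genes, cnvs)
  gene_count <- tabulate(gh$query, nbins = n)
  dis <- bundle$idx$genes$intervals$n_diseases[gh$subject]
  disease_count <- numeric(n)
  if (nrow(gh)) {
    agg <- tapply(dis, gh$query, sum)
    disease_count[as.integer(names(agg))] <- as.numeric(agg)
  }
  data.frame(gene_count = gene_count,
             disease_count = disease_count,
             exon_count = cnt(bundle$idx$exons),
             promoter_count = cnt(bundle$idx$promoters),
             pathogenic_snv_count = cnt(bundle$idx$snvs))
}

#' Population-maximum allele frequency
#'
#' The highest allele frequency, across all populations, among SV
#' frequency records that match the CNV's type (DEL or DUP) and share at
#' least `min_ro` reciprocal overlap with it; 0 when no record qualifies.
#'
#' @param cnvs a `cnv_set` (needs a `type` column).
#' @param sv_records SV frequency table from [read_sv_frequencies()].
#' @param min_ro reciprocal-overlap threshold (default 0.5).
#' @return numeric vector in \[0, 1\].
#' @export
popmax_frequency <- function(cnvs, sv_records, min_ro = 0.5) {
  af_cols <- attr(sv_records, "af_cols")
  if (is.null(af_cols)) af_cols <- grep("^af_", colnames(sv_records), value = TRUE)
  out <- numeric(nrow(cnvs))
  if (!nrow(sv_records) || !nrow(cnvs)) return(out)
  afmax <- do.call(pmax, c(unname(as.list(sv_records[af_cols])), na.rm = TRUE))
  afmax[is.na(afmax)] <- 0
  for (tp in c("DEL", "DUP")) {
    ci <- which(cnvs$type == tp)
    si <- which(sv_records$type == tp)
    if (!length(ci) || !length(si)) next
    idx <- build_index(cbind(sv_records[si, c("chrom", "start", "end")],
                             orig = si))
    h <- index_hits(idx, cnvs[ci, , drop = FALSE])
    if (!nrow(h)) next
    a <- cnvs[ci[h$query], , drop = FALSE]
    b <- idx$intervals[h$subject, , drop = FALSE]
    ro <- reciprocal_overlap(a, b)
    ok <- ro >= min_ro
    if (!any(ok)) next
    vals <- afmax[b$orig[ok]]
    agg <- tapply(vals, h$query[ok], max)
    out[ci[as.integer(names(agg))]] <- as.numeric(agg)
  }
  out
}

#' Maximum of a smoothed conservation curve within a CNV
#'
#' Per-base conservation scores (phyloP, phastCons) are volatile, so each
#' base position p inside the CNV gets the mean of the available raw scores
#' in the centered window `[p - (w-1)/2, p + (w-1)/2]`; the feature is the
#' maximum of this smoothed curve over the CNV. Bases with no score are
#' excluded from the means; if no score exists anywhere in the CNV plus its
#' window margin, a sentinel (default 0) is returned with a warning.
#'
#' @param cnvs interval data frame.
#' @param track run-length conservation table from [read_conservation()].
#' @param window odd window width in bp (default 1001; `window = 1` is the
#'   raw in-interval maximum).
#' @param sentinel value returned when no score is in reach.
#' @return numeric vector.
#' @export
smoothed_conservation_max <- function(cnvs, track, window = 1001,
                                      sentinel = 0) {
  stopifnot(window >= 1, window %% 2 == 1)
  h <- (window - 1) / 2
  out <- numeric(nrow(cnvs))
  by_chrom <- split(seq_len(nrow(track)), track$chrom)
  for (r in seq_len(nrow(cnvs))) {
    rows <- by_chrom[[cnvs$chrom[r]]]
    lo <- cnvs$start[r] - h
    hi <- cnvs$end[r] - 1 + h          # last base position needed
    vals <- rep(NA_real_, hi - lo + 1)
    if (!is.null(rows)) {
      tr <- track[rows, , drop = FALSE]
      tr <- tr[tr$end > lo & tr$start <= hi, , drop = FALSE]
      for (k in seq_len(nrow(tr))) {
        a <- max(tr$start[k], lo); b <- min(tr$end[k] - 1, hi)
        if (a <= b) vals[(a - lo + 1):(b - lo + 1)] <- tr$score[k]
      }
    }
    if (all(is.na(vals))) {
      warning("no conservation scores within reach of ", cnvs$chrom[r], ":",
              cnvs$start[r], "-", cnvs$end[r], "; using sentinel ", sentinel)
      out[r] <- sentinel
      next
    }
    present <- !is.na(vals)
    cs <- c(0, cumsum(ifelse(present, vals, 0)))
    cn <- c(0, cumsum(present))
    # smoothed value for base p (offset i in [h+1, h+len]) averages
    # offsets [i-h, i+h] clipped to the populated buffer
    len <- cnvs$end[r] - cnvs$start[r]
    i <- (h + 1):(h + len)
    aa <- pmax(1, i - h); bb <- pmin(length(vals), i + h)
    wsum <- cs[bb + 1] - cs[aa]
    wcnt <- cn[bb + 1] - cn[aa]
    sm <- ifelse(wcnt > 0, wsum / wcnt, NA_real_)
    out[r] <- if (all(is.na(sm))) sentinel else max(sm, na.rm = TRUE)
  }
  out
}

#' Dosage-sensitivity features
#'
#' Over all dosage-sensitive regions overlapping the CNV: per-category
#' one-hot counts for the HI and TS evidence scores (summed across
#' overlapping regions), the minimum HI index, the maximum pLI and the
#' minimum LOEUF. With no overlap the one-hot counts are all 0 and the
#' metrics take the sentinels of [dosage_sentinels()].
#'
#' @param cnvs interval data frame.
#' @param dosage_regions table from [read_dosage_regions()].
#' @param vocab category vocabulary (defaults to the table's).
#' @param sentinels see [dosage_sentinels()].
#' @return data frame with `hi_<cat>` and `ts_<cat>` count columns followed
#'   by `hi_index_min`, `pli_max`, `loeuf_min`.
#' @export
dosage_features <- function(cnvs, dosage_regions,
                            vocab = NULL, sentinels = dosage_sentinels()) {
  if (is.null(vocab)) {
    vocab <- attr(dosage_regions, "vocab")
    if (is.null(vocab)) vocab <- dosage_vocabulary()
  }
  n <- nrow(cnvs)
  hi <- matrix(0, n, length(vocab), dimnames = list(NULL, paste0("hi_", vocab)))
  ts <- matrix(0, n, length(vocab), dimnames = list(NULL, paste0("ts_", vocab)))
  hi_index_min <- rep(sentinels$hi_index, n)
  pli_max <- rep(sentinels$pli, n)
  loeuf_min <- rep(sentinels$loeuf, n)
  if (nrow(dosage_regions) && n) {
    idx <- build_index(cbind(dosage_regions[, c("chrom", "start", "end")],
                             orig = seq_len(nrow(dosage_regions))))
    h <- index_hits(idx, cnvs)
    if (nrow(h)) {
      reg <- dosage_regions[idx$intervals$orig[h$subject], , drop = FALSE]
      for (k in seq_len(nrow(h))) {
        q <- h$query[k]
        hi[q, paste0("hi_", reg$hi_score[k])] <-
          hi[q, paste0("hi_", reg$hi_score[k])] + 1
        ts[q, paste0("ts_", reg$ts_score[k])] <-
          ts[q, paste0("ts_", reg$ts_score[k])] + 1
      }
      # CNVs with hits but all-NA metrics keep the sentinels; CNVs with
      # hits and metrics take min/max over the observed values only
      hit_rows <- unique(h$query)
      for (q in hit_rows) {
        rows <- reg[h$query == q, , drop = FALSE]
        if (any(!is.na(rows$hi_index)))
          hi_index_min[q] <- min(rows$hi_index, na.rm = TRUE)
        if (any(!is.na(rows$pli)))
          pli_max[q] <- max(rows$pli, na.rm = TRUE)
        if (any(!is.na(rows$loeuf)))
          loeuf_min[q] <- min(rows$loeuf, na.rm = TRUE)
      }
    }
  }
  cbind(as.data.frame(hi), as.data.frame(ts),
        data.frame(hi_index_min = hi_index_min, pli_max = pli_max,
                   loeuf_min = loeuf_min))
}

#' Feature column manifest
#'
#' Fixed column order of the extracted feature matrix, with the HI/TS
#' one-hot groups expanded over `vocab`.
#'
#' @param vocab dosage category vocabulary.
#' @return character vector of column names.
#' @export
feature_manifest <- function(vocab = dosage_vocabulary()) {
  c("centromere_distance", "telomere_distance", "gc_content", "bp_length",
    "gene_count", "disease_count", "exon_count", "promoter_count",
    "pathogenic_snv_count", "popmax_af", "phylop_max", "phastcons_max",
    paste0("hi_", vocab), paste0("ts_", vocab),
    "hi_index_min", "pli_max", "loeuf_min")
}

#' Extract the full feature matrix for a CNV set
#'
#' Computes all 17 features (one-hot groups expanded) for each CNV, in the
#' fixed column order of [feature_manifest()]. Deterministic given inputs.
#'
#' @param cnvs a `cnv_set`.
#' @param bundle an `annotation_bundle`.
#' @param window conservation smoothing window (odd bp; default 1001).
#' @param sentinels dosage sentinels, see [dosage_sentinels()].
#' @return data frame with an `id` column followed by the feature columns;
#'   the manifest is attached as `attr(, "manifest")`.
#' @export
extract_features <- function(cnvs, bundle, window = 1001,
                             sentinels = dosage_sentinels()) {
  vocab <- bundle$vocab
  man <- feature_manifest(vocab)
  if (nrow(cnvs) == 0) {
    out <- as.data.frame(setNames(rep(list(numeric()), length(man) + 1),
                                  c("id", man)))
    attr(out, "manifest") <- man
    return(out)
  }
  pos <- positional_distances(cnvs, bundle$chromosome_structure)
  fun <- functional_counts(cnvs, bundle)
  out <- data.frame(
    id = cnvs$id,
    centromere_distance = pos$centromere_distance,
    telomere_distance = pos$telomere_distance,
    gc_content = gc_content(cnvs, bundle$genome),
    bp_length = cnvs$end - cnvs$start,
    stringsAsFactors = FALSE)
  out <- cbind(out, fun)
  out$popmax_af <- popmax_frequency(cnvs, bundle$sv_frequencies)
  out$phylop_max <- smoothed_conservation_max(cnvs, bundle$phylop, window)
  out$phastcons_max <- smoothed_conservation_max(cnvs, bundle$phastcons, window)
  out <- cbind(out, dosage_features(cnvs, bundle$dosage_regions,
                                    vocab = vocab, sentinels = sentinels))
  out <- out[, c("id", man)]
  rownames(out) <- NULL
  attr(out, "manifest") <- man
  out
}
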
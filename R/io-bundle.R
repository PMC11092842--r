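# Readers for the annotation resources backing feature extraction, and the
# load_bundle() assembler. All resources are flat text files with documented
# headers; chromosome names are normalized on read. Schemas:
#
#   genes.tsv      #chrom start end strand gene exon_starts exon_ends
#                  (exon columns: comma-separated 0-based half-open pairs)
#   diseases.tsv   #gene disease
#   pathogenic_snvs.tsv  #chrom pos significance  (pos is 1-based)
#   sv_frequencies.tsv   #chrom start end type af_<pop>...
#   dosage_regions.tsv   #chrom start end hi_score ts_score hi_index pli loeuf
#   chromosome_structure.tsv  #chrom p_telomere centromere_start
#                              centromere_end q_telomere
#   conservation     bedGraph or fixed-step wiggle (phylop, phastcons)
#   genome.fa        FASTA; soft-masked lowercase is fine (GC is
#                    case-insensitive)

#' Default dosage-sensitivity category vocabulary
#'
#' ClinGen-style categorical evidence codes: 0 (no evidence) through
#' 3 (sufficient evidence), 30 (autosomal recessive), 40 (dosage
#' insensitive), plus `not_evaluated`.
#' @return character vector of category codes.
#' @export
dosage_vocabulary <- function() c("0", "1", "2", "3", "30", "40", "not_evaluated")

.read_headed_tsv <- function(path, required) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^#", lines[1]))
    stop(path, ": expected a '#'-prefixed header line")
  header <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  miss <- setdiff(required, header)
  if (length(miss))
    stop(path, ": missing required column(s): ", paste(miss, collapse = ", "))
  body <- lines[-1]
  body <- body[nzchar(trimws(body)) & !grepl("^#", body)]
  if (!length(body)) {
    df <- as.data.frame(setNames(rep(list(character()), length(header)), header),
                        stringsAsFactors = FALSE)
    return(df)
  }
  df <- utils::read.table(text = body, sep = "\t", header = FALSE,
                          col.names = header, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), quote = "",
                          comment.char = "")
  df
}

#' @rdname load_bundle
#' @param path a resource file path.
#' @export
read_genes <- function(path) {
  df <- .read_headed_tsv(path, c("chrom", "start", "end", "strand", "gene",
                                 "exon_starts", "exon_ends"))
  df$chrom <- normalize_chrom(df$chrom)
  split_num <- function(x) lapply(strsplit(as.character(x), ","), as.numeric)
  es <- split_num(df$exon_starts)
  ee <- split_num(df$exon_ends)
  for (i in seq_len(nrow(df))) {
    if (length(es[[i]]) != length(ee[[i]]))
      stop(path, ": exon_starts/exon_ends length mismatch for gene ",
           df$gene[i])
    if (length(es[[i]]) &&
        (min(es[[i]]) < df$start[i] || max(ee[[i]]) > df$end[i]))
      stop(path, ": exon outside gene span for gene ", df$gene[i])
  }
  genes <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                      strand = df$strand, gene = df$gene,
                      stringsAsFactors = FALSE)
  exons <- data.frame(
    chrom = rep(df$chrom, lengths(es)),
    start = unlist(es, use.names = FALSE),
    end = unlist(ee, use.names = FALSE),
    gene = rep(df$gene, lengths(es)),
    stringsAsFactors = FALSE)
  if (nrow(exons) == 0)
    exons <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), gene = character())
  # TSS is strand-dependent: gene start on '+', gene end on '-'.
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  list(genes = genes, exons = exons)
}

#' @rdname load_bundle
#' @export
read_diseases <- function(path) {
  .read_headed_tsv(path, c("gene", "disease"))
}

#' @rdname load_bundle
#' @export
read_pathogenic_snvs <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "vcf") {
    vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
    rr <- SummarizedExperiment::rowRanges(vcf)
    df <- data.frame(
      chrom = normalize_chrom(as.character(GenomicRanges::seqnames(rr))),
      pos = as.numeric(GenomicRanges::start(rr)),
      significance = "Pathogenic", stringsAsFactors = FALSE)
    inf <- VariantAnnotation::info(vcf)
    if ("CLNSIG" %in% colnames(inf))
      df$significance <- as.character(inf$CLNSIG)
  } else {
    df <- .read_headed_tsv(path, c("chrom", "pos", "significance"))
    df$chrom <- normalize_chrom(df$chrom)
    df$pos <- as.numeric(df$pos)
  }
  sig <- tolower(df$significance)
  df <- df[sig %in% c("pathogenic", "likely pathogenic", "likely_pathogenic"),
           , drop = FALSE]
  # internal 0-based point interval [pos-1, pos)
  df$start <- df$pos - 1
  df$end <- df$pos
  rownames(df) <- NULL
  df
}

#' @rdname load_bundle
#' @export
read_sv_frequencies <- function(path) {
  df <- .read_headed_tsv(path, c("chrom", "start", "end", "type"))
  df$chrom <- normalize_chrom(df$chrom)
  df$type <- toupper(df$type)
  af_cols <- grep("^af_", colnames(df), value = TRUE)
  if (!length(af_cols))
    stop(path, ": needs at least one population frequency column (af_*)")
  for (col in af_cols) {
    v <- df[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop(path, ": allele frequencies must lie in [0, 1] (column ", col, ")")
  }
  attr(df, "af_cols") <- af_cols
  df
}

#' @rdname load_bundle
#' @param vocab dosage categorical vocabulary; see [dosage_vocabulary()].
#' @param strict if `TRUE`, an unknown HI/TS category is an error; otherwise
#'   it is retained into the vocabulary with a warning.
#' @export
read_dosage_regions <- function(path, vocab = dosage_vocabulary(),
                                strict = FALSE) {
  df <- .read_headed_tsv(path, c("chrom", "start", "end", "hi_score",
                                 "ts_score", "hi_index", "pli", "loeuf"))
  df$chrom <- normalize_chrom(df$chrom)
  df$hi_score <- as.character(df$hi_score)
  df$ts_score <- as.character(df$ts_score)
  df$hi_score[is.na(df$hi_score)] <- "not_evaluated"
  df$ts_score[is.na(df$ts_score)] <- "not_evaluated"
  seen <- unique(c(df$hi_score, df$ts_score))
  unknown <- setdiff(seen, vocab)
  if (length(unknown)) {
    if (strict)
      stop(path, ": unknown dosage categories: ", paste(unknown, collapse = ", "))
    warning(path, ": retaining unknown dosage categories into vocabulary: ",
            paste(unknown, collapse = ", "))
    vocab <- c(vocab, unknown)
  }
  bad <- which(!is.na(df$pli) & (df$pli < 0 | df$pli > 1))
  if (length(bad)) stop(path, ": pLI must lie in [0, 1]")
  attr(df, "vocab") <- vocab
  df
}

#' @rdname load_bundle
#' @export
read_chromosome_structure <- function(path) {
  df <- .read_headed_tsv(path, c("chrom", "p_telomere", "centromere_start",
                                 "centromere_end", "q_telomere"))
  df$chrom <- normalize_chrom(df$chrom)
  ok <- df$p_telomere < df$centromere_start &
    df$centromere_start <= df$centromere_end &
    df$centromere_end < df$q_telomere
  if (!all(ok))
    stop(path, ": require p_telomere < centromere <= q_telomere per chromosome")
  df
}

#' @rdname load_bundle
#' @export
read_conservation <- function(path) {
  ext <- tolower(tools::file_ext(path))
  fmt <- if (ext %in% c("wig", "wiggle")) "wig" else "bedGraph"
  gr <- rtracklayer::import(path, format = fmt)
  df <- data.frame(
    chrom = normalize_chrom(as.character(GenomicRanges::seqnames(gr))),
    start = as.numeric(GenomicRanges::start(gr)) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    score = as.numeric(gr$score), stringsAsFactors = FALSE)
  ord <- order(df$chrom, df$start)
  df <- df[ord, , drop = FALSE]
  # positions strictly increasing per chromosome
  by_chrom <- split(df, df$chrom)
  for (d in by_chrom)
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
      stop(path, ": overlapping conservation runs on chromosome ", d$chrom[1])
  rownames(df) <- NULL
  df
}

#' Load an annotation bundle
#'
#' Assembles every annotation resource needed by the feature extractor into
#' one object: gene models with exons and TSS, the disease-gene map,
#' pathogenic short-variant positions, SV population frequencies, phyloP and
#' phastCons conservation tracks, dosage-sensitivity regions, chromosome
#' structure (centromere/telomere anchors) and the genome sequence.
#'
#' @param config either a directory containing the conventionally named
#'   resource files (`genome.fa`, `genes.tsv`, `diseases.tsv`,
#'   `pathogenic_snvs.tsv`, `sv_frequencies.tsv`, `phylop.bedGraph`,
#'   `phastcons.bedGraph`, `dosage_regions.tsv`,
#'   `chromosome_structure.tsv`), a YAML file mapping those keys to paths,
#'   or a named list of paths.
#' @param strict passed to [read_dosage_regions()]; also promotes reader
#'   warnings to errors when `TRUE`.
#' @param vocab dosage category vocabulary.
#' @return an object of class `annotation_bundle`.
#' @export
load_bundle <- function(config, strict = FALSE, vocab = dosage_vocabulary()) {
  keys <- c(genome = "genome.fa", genes = "genes.tsv",
            diseases = "diseases.tsv", pathogenic_snvs = "pathogenic_snvs.tsv",
            sv_frequencies = "sv_frequencies.tsv",
            phylop = "phylop.bedGraph", phastcons = "phastcons.bedGraph",
            dosage_regions = "dosage_regions.tsv",
            chromosome_structure = "chromosome_structure.tsv")
  if (is.character(config) && length(config) == 1) {
    if (dir.exists(config)) {
      paths <- file.path(config, keys)
      names(paths) <- names(keys)
    } else {
      cfg <- yaml::read_yaml(config)
      paths <- unlist(cfg[names(keys)])
      paths[!is.na(paths)] <- ifelse(
        file.exists(paths[!is.na(paths)]), paths[!is.na(paths)],
        file.path(dirname(config), paths[!is.na(paths)]))
    }
  } else if (is.list(config)) {
    paths <- unlist(config[names(keys)])
  } else stop("config must be a directory, a YAML file or a named list")
  missing_keys <- names(keys)[!(names(keys) %in% names(paths)) |
                                is.na(paths[names(keys)])]
  present <- setdiff(names(keys), missing_keys)
  gone <- present[!file.exists(paths[present])]
  missing_keys <- union(missing_keys, gone)
  if (length(missing_keys))
    stop("annotation bundle is missing required resource(s): ",
         paste(missing_keys, collapse = ", "),
         if ("phylop" %in% missing_keys) " (phylop track required)" else "")

  wrap <- if (strict) function(expr) withCallingHandlers(expr,
    warning = function(w) stop(conditionMessage(w))) else identity

  gene_tab <- wrap(read_genes(paths[["genes"]]))
  dosage <- wrap(read_dosage_regions(paths[["dosage_regions"]],
                                     vocab = vocab, strict = strict))
  genome <- Biostrings::readDNAStringSet(paths[["genome"]])
  names(genome) <- normalize_chrom(sub("\\s.*$", "", names(genome)))

  bundle <- list(
    genes = gene_tab$genes,
    exons = gene_tab$exons,
    diseases = wrap(read_diseases(paths[["diseases"]])),
    pathogenic_snvs = wrap(read_pathogenic_snvs(paths[["pathogenic_snvs"]])),
    sv_frequencies = wrap(read_sv_frequencies(paths[["sv_frequencies"]])),
    phylop = wrap(read_conservation(paths[["phylop"]])),
    phastcons = wrap(read_conservation(paths[["phastcons"]])),
    dosage_regions = dosage,
    chromosome_structure = wrap(read_chromosome_structure(
      paths[["chromosome_structure"]])),
    genome = genome,
    vocab = attr(dosage, "vocab"),
    paths = as.list(paths))
  # promoters: the 1,000 bp immediately upstream of the TSS, strand-aware
  g <- bundle$genes
  prom_start <- ifelse(g$strand == "+", pmax(0, g$tss - 1000), g$tss)
  prom_end <- ifelse(g$strand == "+", g$tss, g$tss + 1000)
  bundle$promoters <- data.frame(chrom = g$chrom, start = prom_start,
                                 end = prom_end, gene = g$gene,
                                 stringsAsFactors = FALSE)
  bundle$promoters <- bundle$promoters[
    bundle$promoters$end > bundle$promoters$start, , drop = FALSE]
  # per-gene disease counts for the disease_count feature
  dc <- table(bundle$diseases$gene)
  bundle$genes$n_diseases <- as.numeric(dc[bundle$genes$gene])
  bundle$genes$n_diseases[is.na(bundle$genes$n_diseases)] <- 0
  # prebuilt overlap indexes
  bundle$idx <- list(
    genes = build_index(bundle$genes),
    exons = build_index(.pad_intervals(bundle$exons, 10)),
    promoters = build_index(bundle$promoters),
    snvs = build_index(bundle$pathogenic_snvs[, c("chrom", "start", "end"),
                                              drop = FALSE]),
    dosage = build_index(bundle$dosage_regions))
  class(bundle) <- "annotation_bundle"
  bundle
}

# Exon boundaries padded to take in canonical splice regions (10 bp).
.pad_intervals <- function(df, pad) {
  if (nrow(df)) {
    df$start <- pmax(0, df$start - pad)
    df$end <- df$end + pad
  }
  df
}

#' @export
print.annotation_bundle <- function(x, ...) {
  cat("annotation_bundle\n")
  cat(sprintf("  chromosomes: %d (%s)\n", length(x$genome),
              paste(names(x$genome), collapse = ", ")))
  cat(sprintf("  genes: %d  exons: %d  promoters: %d\n",
              nrow(x$genes), nrow(x$exons), nrow(x$promoters)))
  cat(sprintf("  disease-gene links: %d  pathogenic SNVs: %d\n",
              nrow(x$diseases), nrow(x$pathogenic_snvs)))
  cat(sprintf("  SV frequency records: %d  dosage regions: %d\n",
              nrow(x$sv_frequencies), nrow(x$dosage_regions)))
  cat(sprintf("  conservation runs: phyloP %d, phastCons %d\n",
              nrow(x$phylop), nrow(x$phastcons)))
  invisible(x)
}
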
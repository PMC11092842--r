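# CNV call-set input/output. Two dialects are supported:
#   * BED-like TSV: chrom, start, end, type [, id [, labels]] with 0-based
#     half-open coordinates and type DEL/DUP;
#   * VCF with symbolic SV alleles, SVTYPE in {DEL,DUP} and an END tag
#     (1-based inclusive; converted to 0-based half-open on read).

.default_chroms <- function() c(as.character(1:22), "X", "Y", "MT")

.new_cnv_set <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("cnv_set", "data.frame")
  df
}

#' Read a CNV call set
#'
#' Reads deletion/duplication calls from a BED-like TSV or a VCF. Records
#' with a type other than DEL/DUP (e.g. inversions) are skipped and
#' counted; records on unrecognized chromosomes are skipped with a
#' warning. Coordinates are converted to the internal 0-based half-open
#' convention.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"bed"` or `"vcf"`.
#' @param chroms recognized chromosome names after normalization.
#' @return a `cnv_set` data frame with columns `chrom`, `start`, `end`,
#'   `type`, `id`, `labels` (semicolon-joined submitted significance
#'   strings, possibly `NA`). The number of non-CNV records dropped is in
#'   `attr(, "skipped_type")`; dropped unknown-chromosome records in
#'   `attr(, "skipped_chrom")`.
#' @export
read_cnvs <- function(path, format = c("auto", "bed", "vcf"),
                      chroms = .default_chroms()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext == "vcf") "vcf" else "bed"
  }
  if (format == "vcf") .read_cnvs_vcf(path, chroms) else
    .read_cnvs_bed(path, chroms)
}

.read_cnvs_bed <- function(path, chroms) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  header <- NULL
  hl <- grep("^#", lines, value = TRUE)
  if (length(hl)) {
    cand <- strsplit(sub("^#", "", hl[length(hl)]), "\t")[[1]]
    if ("chrom" %in% cand) header <- cand
  }
  body <- lines[keep]
  lineno <- which(keep)
  if (!length(body)) {
    return(.new_cnv_set(data.frame(chrom = character(), start = numeric(),
                                   end = numeric(), type = character(),
                                   id = character(), labels = character(),
                                   stringsAsFactors = FALSE)))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 4))
    stop("malformed CNV row (need >= 4 tab-separated fields) at line ",
         lineno[which(nf < 4)[1]], " of ", path)
  get <- function(i) vapply(parts, function(p) if (length(p) >= i) p[i] else NA_character_, "")
  cols <- list(chrom = get(1), start = get(2), end = get(3), type = get(4),
               id = get(5), labels = get(6))
  if (!is.null(header)) {
    named <- lapply(seq_along(header), function(i) get(i))
    names(named) <- header
    for (k in c("chrom", "start", "end", "type", "id", "labels"))
      if (k %in% header) cols[[k]] <- named[[k]]
  }
  start <- suppressWarnings(as.numeric(cols$start))
  end <- suppressWarnings(as.numeric(cols$end))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad))
    stop("malformed CNV coordinates at line ", lineno[bad[1]], " of ", path)
  df <- data.frame(chrom = normalize_chrom(cols$chrom), start = start,
                   end = end, type = toupper(cols$type),
                   id = cols$id, labels = cols$labels,
                   stringsAsFactors = FALSE)
  .finish_cnvs(df, chroms)
}

.read_cnvs_vcf <- function(path, chroms) {
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  rr <- SummarizedExperiment::rowRanges(vcf)
  inf <- VariantAnnotation::info(vcf)
  if (!all(c("SVTYPE", "END") %in% colnames(inf)))
    stop("VCF must define SVTYPE and END INFO fields: ", path)
  df <- data.frame(
    chrom = normalize_chrom(as.character(GenomicRanges::seqnames(rr))),
    start = as.numeric(GenomicRanges::start(rr)) - 1,  # 1-based POS -> 0-based
    end = as.numeric(inf$END),
    type = toupper(as.character(inf$SVTYPE)),
    id = names(rr),
    labels = NA_character_,
    stringsAsFactors = FALSE)
  .finish_cnvs(df, chroms)
}

.finish_cnvs <- function(df, chroms) {
  is_cnv <- df$type %in% c("DEL", "DUP")
  skipped_type <- sum(!is_cnv)
  df <- df[is_cnv, , drop = FALSE]
  known <- df$chrom %in% chroms
  skipped_chrom <- sum(!known)
  if (skipped_chrom)
    warning(skipped_chrom, " record(s) on unrecognized chromosomes skipped")
  df <- df[known, , drop = FALSE]
  noid <- is.na(df$id) | !nzchar(df$id)
  if (any(noid))
    df$id[noid] <- sprintf("cnv_%05d", which(noid))
  df <- .new_cnv_set(df)
  attr(df, "skipped_type") <- skipped_type
  attr(df, "skipped_chrom") <- skipped_chrom
  df
}

#' Write a CNV call set as BED-like TSV
#'
#' Inverse of [read_cnvs()] for the TSV dialect; re-reading the written
#' file yields identical records.
#'
#' @param cnvs a `cnv_set` data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cnvs <- function(cnvs, path) {
  cols <- c("chrom", "start", "end", "type", "id", "labels")
  out <- cnvs[, intersect(cols, colnames(cnvs)), drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(colnames(out), collapse = "\t")), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, na = "NA")
  invisible(path)
}
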
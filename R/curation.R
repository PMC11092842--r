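# Dataset curation: ClinVar-style label collapsing and the ordered
# filtering rules that produce deduplicated, leakage-safe training/test
# sets. Rule order is fixed:
#   (1) drop non-DEL/DUP records;
#   (2) collapse submitted labels, drop ambiguous ones;
#   (3) among records sharing (chrom, start, end, type): identical labels
#       keep one representative, conflicting labels drop the whole group;
#   (4) drop records shorter than 50 bp;
#   (5) drop records whose (chrom, start, end, type) matches a training
#       coordinate (leakage guard).

#' Collapse submitted significance labels to three classes
#'
#' A record with at least one pathogenic or likely-pathogenic designation
#' is pathogenic; otherwise one with at least one VUS designation is VUS;
#' otherwise a record with only benign/likely-benign designations is
#' benign. Anything else ("drug response", "risk factor", ...) is
#' `AMBIGUOUS`.
#'
#' @param labels a character vector; each element holds one record's
#'   submitted labels joined by `";"`.
#' @return character vector over `{"benign", "VUS", "pathogenic",
#'   "AMBIGUOUS"}`.
#' @examples
#' collapse_label(c("Pathogenic;VUS", "VUS;Likely benign",
#'                  "Benign;Likely benign", "drug response"))
#' @export
collapse_label <- function(labels) {
  vapply(strsplit(as.character(labels), ";"), function(ls) {
    ls <- tolower(trimws(ls))
    ls <- ls[nzchar(ls)]
    if (!length(ls) || anyNA(ls)) return("AMBIGUOUS")
    path <- c("pathogenic", "likely pathogenic", "likely_pathogenic")
    vus <- c("vus", "uncertain significance", "uncertain_significance",
             "variant of uncertain significance")
    ben <- c("benign", "likely benign", "likely_benign")
    if (any(ls %in% path)) "pathogenic"
    else if (any(ls %in% vus)) "VUS"
    else if (all(ls %in% ben)) "benign"
    else "AMBIGUOUS"
  }, "")
}

#' Curate a labeled CNV set
#'
#' Applies the fixed-order curation rules (type filter, label collapse,
#' duplicate/conflict resolution, >= 50 bp size filter, optional leakage
#' guard against a training coordinate set) and reports per-rule removal
#' tallies. The report conserves counts: input = kept + sum(removed).
#'
#' @param records a `cnv_set` with a `labels` column (semicolon-joined
#'   submitted significance strings) or an already collapsed
#'   `collapsed_label` column.
#' @param training_coordinates optional data frame with `chrom`, `start`,
#'   `end`, `type`; test records matching one of these exactly are dropped.
#' @param min_size smallest retained CNV length in bp (default 50).
#' @return a list with `kept` (curated `cnv_set` carrying
#'   `collapsed_label`) and `report` (a `curation_report`).
#' @export
curate_cnvs <- function(records, training_coordinates = NULL, min_size = 50) {
  n_input <- nrow(records)
  removed <- c(non_cnv_type = 0, ambiguous_label = 0, duplicate = 0,
               conflict = 0, too_small = 0, leakage = 0)

  is_cnv <- records$type %in% c("DEL", "DUP")
  removed[["non_cnv_type"]] <- sum(!is_cnv)
  records <- records[is_cnv, , drop = FALSE]

  if (!"collapsed_label" %in% colnames(records) ||
      all(is.na(records$collapsed_label)))
    records$collapsed_label <- collapse_label(records$labels)
  amb <- records$collapsed_label == "AMBIGUOUS"
  removed[["ambiguous_label"]] <- sum(amb)
  records <- records[!amb, , drop = FALSE]

  key <- paste(records$chrom, records$start, records$end, records$type,
               sep = "|")
  if (nrow(records)) {
    grp <- split(seq_len(nrow(records)), key)
    drop_idx <- integer()
    for (g in grp) {
      if (length(g) == 1) next
      if (length(unique(records$collapsed_label[g])) == 1) {
        # representative chosen by id order, so the kept set does not
        # depend on input row order
        g <- g[order(as.character(records$id[g]), g)]
        drop_idx <- c(drop_idx, g[-1])
        removed[["duplicate"]] <- removed[["duplicate"]] + length(g) - 1
      } else {
        drop_idx <- c(drop_idx, g)                # conflicting labels: drop all
        removed[["conflict"]] <- removed[["conflict"]] + length(g)
      }
    }
    if (length(drop_idx))
      records <- records[-drop_idx, , drop = FALSE]
  }

  small <- (records$end - records$start) < min_size
  removed[["too_small"]] <- sum(small)
  records <- records[!small, , drop = FALSE]

  if (!is.null(training_coordinates) && nrow(records)) {
    tc <- training_coordinates
    tkey <- paste(normalize_chrom(tc$chrom), tc$start, tc$end,
                  toupper(tc$type), sep = "|")
    leak <- paste(records$chrom, records$start, records$end, records$type,
                  sep = "|") %in% tkey
    removed[["leakage"]] <- sum(leak)
    records <- records[!leak, , drop = FALSE]
  }

  rownames(records) <- NULL
  class(records) <- c("cnv_set", "data.frame")
  report <- list(
    n_input = n_input, n_kept = nrow(records), removed = as.list(removed),
    kept_by_class = as.list(table(factor(records$collapsed_label,
                                         levels = c("benign", "VUS",
                                                    "pathogenic")))),
    kept_by_type = as.list(table(factor(records$type,
                                        levels = c("DEL", "DUP")))))
  class(report) <- "curation_report"
  stopifnot(report$n_input == report$n_kept + sum(unlist(report$removed)))
  list(kept = records, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("curation_report:", x$n_input, "in,", x$n_kept, "kept\n")
  rm <- unlist(x$removed)
  for (nm in names(rm)) if (rm[[nm]] > 0)
    cat(sprintf("  removed %-16s %d\n", nm, rm[[nm]]))
  cat("  kept by class:",
      paste(sprintf("%s=%d", names(x$kept_by_class),
                    unlist(x$kept_by_class)), collapse = " "), "\n")
  invisible(x)
}
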
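#' Read an exon-exon junction count table
#'
#' Parses the tab-separated junction dialect
#' `sample_id<TAB>donor_id<TAB>acceptor_id<TAB>count` with `#` comment
#' lines. Each (sample, donor) pair must be unique.
#'
#' @param path path to the file.
#' @return data.frame with columns `sample_id`, `donor_id`, `acceptor_id`,
#'   `count`.
#' @export
readJunctionTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0L)
    return(data.frame(sample_id = character(), donor_id = character(),
                      acceptor_id = character(), count = integer()))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 4L)
  if (length(bad))
    stop("malformed junction line ", keep[bad[1L]],
         ": expected 4 tab-separated fields")
  cnt <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4L)))
  bad <- which(is.na(cnt) | cnt < 0 | cnt != round(cnt))
  if (length(bad))
    stop("malformed junction line ", keep[bad[1L]],
         ": count must be a non-negative integer")
  out <- data.frame(sample_id = vapply(fields, `[`, "", 1L),
                    donor_id = vapply(fields, `[`, "", 2L),
                    acceptor_id = vapply(fields, `[`, "", 3L),
                    count = as.integer(cnt))
  dup <- which(duplicated(paste(out$sample_id, out$donor_id, sep = "\r")))
  if (length(dup))
    stop("duplicate (sample, donor) pair at line ", keep[dup[1L]], ": ",
         out$sample_id[dup[1L]], "/", out$donor_id[dup[1L]])
  out
}

#' Write a junction count table
#'
#' @param counts data.frame as returned by [readJunctionTable()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeJunctionTable <- function(counts, path) {
  stopifnot(all(c("sample_id", "donor_id", "acceptor_id", "count") %in%
                  names(counts)))
  utils::write.table(
    counts[, c("sample_id", "donor_id", "acceptor_id", "count")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a splice-donor annotation table
#'
#' Dialect: `donor_id<TAB>chrom<TAB>pos<TAB>class` where class is one of
#' `ancestral_long`, `ancestral_short_skip`, `eutherian_specific`,
#' `lineage_specific`. Coordinates are 1-based.
#'
#' @param path path to the TSV.
#' @return data.frame with columns `donor_id`, `chrom`, `pos`, `class`.
#' @export
readDonorAnnotation <- function(path) {
  ann <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("donor_id", "chrom", "pos", "class"),
                           colClasses = c("character", "character",
                                          "integer", "character"))
  bad <- setdiff(unique(ann$class), DONOR_CLASSES)
  if (length(bad))
    stop("unknown donor class(es): ", paste(bad, collapse = ", "))
  if (anyDuplicated(ann$donor_id)) stop("duplicate donor_id in annotation")
  ann
}

#' Percent of junction reads per evolutionary donor class
#'
#' For each sample group, computes the percentage of exon-exon junction
#' reads reaching the shared reference acceptor that come from donors of
#' each evolutionary class (ancestral long-isoform, ancestral
#' exon-skipping, eutherian-specific, lineage-specific). Relative donor
#' usage is the read-level proxy for transcription-start-site usage.
#'
#' @param counts junction count data.frame (see [readJunctionTable()]).
#' @param annotation donor annotation data.frame (see
#'   [readDonorAnnotation()]); every counted donor must be annotated.
#' @param grouping named character vector mapping sample_id to group label;
#'   every counted sample must be mapped.
#' @param mode `"pooled"` (default): sum counts across the group's samples
#'   first, then take percentages — robust to low-coverage samples.
#'   `"mean"`: per-sample percentages averaged across the group.
#' @return data.frame with columns `group`, `class`, `percent`; classes
#'   sum to 100 within each group. Groups (or, in mean mode, groups with
#'   no covered sample) with zero total reads get `NA` percentages with a
#'   warning.
#' @export
donorClassPercent <- function(counts, annotation, grouping,
                              mode = c("pooled", "mean")) {
  mode <- match.arg(mode)
  missAnn <- setdiff(unique(counts$donor_id), annotation$donor_id)
  if (length(missAnn))
    stop("unannotated donor(s): ", paste(missAnn, collapse = ", "))
  missGrp <- setdiff(unique(counts$sample_id), names(grouping))
  if (length(missGrp))
    stop("ungrouped sample(s): ", paste(missGrp, collapse = ", "))
  cls <- annotation$class[match(counts$donor_id, annotation$donor_id)]
  grp <- unname(grouping[counts$sample_id])
  groups <- unique(unname(grouping))
  out <- expand.grid(group = groups, class = DONOR_CLASSES,
                     stringsAsFactors = FALSE)
  out$percent <- NA_real_
  for (g in groups) {
    sel <- grp == g
    if (mode == "pooled") {
      tot <- sum(counts$count[sel])
      if (tot == 0) {
        warning("group '", g, "' has zero total reads; percent set to NA")
        next
      }
      byClass <- vapply(DONOR_CLASSES, function(cl)
        sum(counts$count[sel & cls == cl]), numeric(1L))
      out$percent[out$group == g] <- 100 * byClass[out$class[out$group == g]] / tot
    } else {
      smp <- unique(counts$sample_id[sel])
      perSample <- list()
      for (s in smp) {
        ssel <- sel & counts$sample_id == s
        tot <- sum(counts$count[ssel])
        if (tot == 0) {
          warning("sample '", s, "' has zero total reads; excluded from group mean")
          next
        }
        perSample[[s]] <- vapply(DONOR_CLASSES, function(cl)
          100 * sum(counts$count[ssel & cls == cl]) / tot, numeric(1L))
      }
      if (length(perSample) == 0L) {
        warning("group '", g, "' has no covered sample; percent set to NA")
        next
      }
      m <- Reduce(`+`, perSample) / length(perSample)
      out$percent[out$group == g] <- m[out$class[out$group == g]]
    }
  }
  out
}
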
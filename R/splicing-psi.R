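.psiCols <- function(psi) {
  s <- sub("^psi\\.", "", grep("^psi\\.", names(psi), value = TRUE))
  q <- sub("^q\\.", "", grep("^q\\.", names(psi), value = TRUE))
  if (length(s) == 0L) stop("no psi.<sample> columns found")
  if (!setequal(s, q))
    stop("psi.<sample> and q.<sample> columns must cover the same samples")
  s
}

#' Read a PSI table
#'
#' Dialect: header line then
#' `event_id gene chrom span psi.<sample>... q.<sample>...`
#' (tab-separated). PSI values are percent spliced in (0-100); `q.*`
#' columns carry the ordinal coverage score (N < VLOW < LOW < OK < SOK)
#' per sample.
#'
#' @param path path to the TSV.
#' @return data.frame in the same layout.
#' @export
readPsiTable <- function(path) {
  psi <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  samples <- .psiCols(psi)
  for (s in samples) {
    v <- psi[[paste0("psi.", s)]]
    if (any(v < 0 | v > 100, na.rm = TRUE))
      stop("PSI values must lie in [0, 100]")
  }
  psi
}

#' Write a PSI table
#'
#' @param psi data.frame in the [readPsiTable()] layout.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePsiTable <- function(psi, path) {
  utils::write.table(psi, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter splicing events on per-sample coverage scores
#'
#' Keeps events whose coverage score is at least `minScore` in every
#' sample, on the ordinal scale N < VLOW < LOW < OK < SOK. The default
#' (`"LOW"`) excludes events with any VLOW or N sample. Unknown score
#' labels are a hard error.
#'
#' @param psi PSI data.frame (see [readPsiTable()]).
#' @param minScore minimum acceptable score label.
#' @return the retained rows; the number dropped is reported.
#' @export
coverageFilter <- function(psi, minScore = "LOW") {
  if (!minScore %in% COVERAGE_LEVELS)
    stop("unknown coverage score: ", minScore)
  qcols <- grep("^q\\.", names(psi), value = TRUE)
  if (length(qcols) == 0L) stop("no q.<sample> coverage columns found")
  minOrd <- match(minScore, COVERAGE_LEVELS)
  keep <- rep(TRUE, nrow(psi))
  for (qc in qcols) {
    ord <- match(psi[[qc]], COVERAGE_LEVELS)
    if (anyNA(ord))
      stop("unknown coverage score label(s) in ", qc, ": ",
           paste(unique(psi[[qc]][is.na(ord)]), collapse = ", "))
    keep <- keep & ord >= minOrd
  }
  if (any(!keep))
    message("coverage filter dropped ", sum(!keep), " of ", nrow(psi),
            " events")
  psi[keep, , drop = FALSE]
}

.pairwiseStats <- function(ko, wt, pairing) {
  if (pairing == "by_index") {
    if (length(ko) != length(wt))
      stop("by_index pairing requires equal replicate counts")
    d <- ko - wt
    c(minD = min(d), maxD = max(d))
  } else {
    # all KO x WT pairwise differences; extremes reduce to these
    c(minD = min(ko) - max(wt), maxD = max(ko) - min(wt))
  }
}

#' Call differentially spliced exons between two conditions
#'
#' An event is called `up` when the mean PSI difference (KO minus WT) is
#' at least `dpsiMin` AND every replicate-level difference is at least
#' `perRepMin` in the same direction; `down` symmetrically. With the
#' default `pairing = "all_pairs"` the replicate rule uses every KO x WT
#' combination (equivalent to `min(KO) - max(WT) >= perRepMin`), the
#' stricter reading; `"by_index"` pairs replicates positionally.
#'
#' @param psi PSI data.frame (see [readPsiTable()]).
#' @param koSamples,wtSamples sample names of the two conditions.
#' @param dpsiMin minimum absolute mean delta-PSI (default 15).
#' @param perRepMin minimum same-direction per-replicate delta-PSI
#'   (default 5).
#' @param pairing `"all_pairs"` or `"by_index"`.
#' @return data.frame with columns `event_id`, `direction`, `mean_dpsi`,
#'   `min_pairwise_dpsi` (for down calls, the pairwise difference closest
#'   to zero, which is negative).
#' @examples
#' psi <- data.frame(event_id = "e1", gene = "g", chrom = "chr1",
#'                   span = "1-2",
#'                   psi.KO_1 = 80, psi.KO_2 = 78,
#'                   psi.WT_1 = 60, psi.WT_2 = 62,
#'                   q.KO_1 = "OK", q.KO_2 = "OK",
#'                   q.WT_1 = "OK", q.WT_2 = "OK", check.names = FALSE)
#' callDifferential(psi, c("KO_1", "KO_2"), c("WT_1", "WT_2"))
#' @export
callDifferential <- function(psi, koSamples, wtSamples, dpsiMin = 15,
                             perRepMin = 5,
                             pairing = c("all_pairs", "by_index")) {
  pairing <- match.arg(pairing)
  if (length(koSamples) < 1L || length(wtSamples) < 1L)
    stop("both conditions need at least one sample")
  kc <- paste0("psi.", koSamples); wc <- paste0("psi.", wtSamples)
  missing <- setdiff(c(kc, wc), names(psi))
  if (length(missing))
    stop("missing sample column(s): ", paste(missing, collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(psi))) {
    ko <- as.numeric(psi[i, kc]); wt <- as.numeric(psi[i, wc])
    meanD <- mean(ko) - mean(wt)
    pw <- .pairwiseStats(ko, wt, pairing)
    if (meanD >= dpsiMin && pw["minD"] >= perRepMin) {
      out[[length(out) + 1L]] <- data.frame(
        event_id = psi$event_id[i], direction = "up", mean_dpsi = meanD,
        min_pairwise_dpsi = unname(pw["minD"]))
    } else if (meanD <= -dpsiMin && pw["maxD"] <= -perRepMin) {
      out[[length(out) + 1L]] <- data.frame(
        event_id = psi$event_id[i], direction = "down", mean_dpsi = meanD,
        min_pairwise_dpsi = unname(pw["maxD"]))
    }
  }
  if (length(out) == 0L)
    return(data.frame(event_id = character(), direction = character(),
                      mean_dpsi = numeric(), min_pairwise_dpsi = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call developmentally regulated exons between two stages
#'
#' Same rules as [callDifferential()] with the conditions being WT
#' samples at a late versus an early developmental stage; `up` means
#' higher inclusion at the late stage.
#'
#' @param psi PSI data.frame.
#' @param earlyWt,lateWt sample names of the early/late WT replicates.
#' @param dpsiMin,perRepMin,pairing as in [callDifferential()].
#' @return as [callDifferential()].
#' @export
callDevelopmental <- function(psi, earlyWt, lateWt, dpsiMin = 15,
                              perRepMin = 5,
                              pairing = c("all_pairs", "by_index")) {
  callDifferential(psi, koSamples = lateWt, wtSamples = earlyWt,
                   dpsiMin = dpsiMin, perRepMin = perRepMin,
                   pairing = match.arg(pairing))
}

#' Summarize KO shifts over developmentally regulated exons
#'
#' Given developmental calls and the KO-vs-WT delta-PSI of each called
#' event, reports the median KO delta-PSI among developmentally
#' up-regulated and down-regulated exons and the fraction of events
#' whose KO shift opposes the developmental direction (an
#' anti-maturation signature). Zero KO deltas count as non-opposing.
#'
#' @param devCalls data.frame from [callDevelopmental()].
#' @param koDeltas named numeric vector of KO-minus-WT delta-PSI, named
#'   by event_id; must cover every developmental call.
#' @return list with `median_dpsi_dev_up`, `median_dpsi_dev_down`
#'   (NA when a direction has no events) and `fraction_opposing`.
#' @export
maturationShiftSummary <- function(devCalls, koDeltas) {
  if (nrow(devCalls) == 0L) stop("empty developmental call set")
  missing <- setdiff(devCalls$event_id, names(koDeltas))
  if (length(missing))
    stop("KO deltas missing for event(s): ", paste(missing, collapse = ", "))
  d <- koDeltas[devCalls$event_id]
  up <- devCalls$direction == "up"
  devSign <- ifelse(up, 1, -1)
  list(
    median_dpsi_dev_up = if (any(up)) stats::median(d[up]) else NA_real_,
    median_dpsi_dev_down = if (any(!up)) stats::median(d[!up]) else NA_real_,
    fraction_opposing = mean(sign(d) == -devSign & d != 0))
}

#' Overlap counts between named call sets (Venn regions)
#'
#' @param callSets named list (>= 2) of character vectors of event ids.
#' @return data.frame with columns `region` (e.g. `"A&B"`) and `count`;
#'   one row per non-empty membership pattern, summing to the union size.
#' @export
overlapCounts <- function(callSets) {
  if (length(callSets) < 2L) stop("need at least two sets")
  if (is.null(names(callSets)) || any(!nzchar(names(callSets))))
    stop("sets must be named")
  u <- unique(unlist(callSets))
  pattern <- vapply(u, function(e)
    paste(names(callSets)[vapply(callSets, function(s) e %in% s,
                                 logical(1L))], collapse = "&"),
    character(1L))
  tab <- table(pattern)
  data.frame(region = names(tab), count = as.integer(tab),
             row.names = NULL)
}
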
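# Segmentation-accuracy metrics: kappa, volume difference, L1 error.

#' Kappa statistic of two binary masks
#'
#' Chance-corrected voxelwise agreement,
#' `kappa = (p_agree - p_random) / (1 - p_random)`, where `p_agree` is
#' the fraction of the domain on which the masks agree (both foreground
#' or both background) and `p_random = fA*fM + (1-fA)(1-fM)` is the
#' agreement expected from the foreground fractions alone. Computed over
#' the full grid by default; kappa is biased by structure size (larger
#' structures score higher) and 0.8 is the conventional "quite good"
#' threshold for brain structures.
#'
#' @param auto,manual logical vectors/arrays of equal length (automated
#'   and manual masks).
#' @param domainSize total voxel count (default `length(manual)`).
#' @return kappa in [-1, 1]; two identical constant masks give 1
#' @export
kappaStatistic <- function(auto, manual, domainSize = length(manual)) {
  auto <- as.logical(auto); manual <- as.logical(manual)
  stopifnot(length(auto) == length(manual),
            domainSize == length(manual))
  pAgree <- sum(auto == manual) / domainSize
  fA <- sum(auto) / domainSize
  fM <- sum(manual) / domainSize
  pRandom <- fA * fM + (1 - fA) * (1 - fM)
  if (pRandom >= 1 - .Machine$double.eps) {
    if (pAgree >= 1 - .Machine$double.eps) return(1)
    stop("kappa undefined: both masks constant but unequal",
         call. = FALSE)
  }
  (pAgree - pRandom) / (1 - pRandom)
}

#' Percent volume difference of two masks
#'
#' `VD = 100 |V(A) - V(M)| / V(M)` on integer voxel counts.
#'
#' @param auto,manual logical vectors/arrays.
#' @return non-negative percent; 0 for equal volumes, 100 when the
#'   automated volume is double the manual one
#' @export
volumeError <- function(auto, manual) {
  vA <- sum(as.logical(auto))
  vM <- sum(as.logical(manual))
  if (vM == 0) stop("manual mask is empty; volume error undefined",
                    call. = FALSE)
  100 * abs(vA - vM) / vM
}

#' L1 misclassification error of two masks
#'
#' `L1 = (|A u M| - |A n M|) / (|A u M| / 2)`, i.e. twice the Jaccard
#' distance: 0 for identical masks, 2 for disjoint ones. The alternative
#' normalization by the mean mask size `(|A| + |M|)/2` (twice the Dice
#' distance) is available via `denominator = "mean_size"`.
#'
#' @param auto,manual logical vectors/arrays.
#' @param denominator `"union"` (default) or `"mean_size"`.
#' @return error in [0, 2]
#' @export
l1Error <- function(auto, manual, denominator = c("union", "mean_size")) {
  denominator <- match.arg(denominator)
  auto <- as.logical(auto); manual <- as.logical(manual)
  u <- sum(auto | manual)
  i <- sum(auto & manual)
  if (u == 0) stop("both masks empty; L1 error undefined", call. = FALSE)
  den <- if (denominator == "union") u / 2
    else (sum(auto) + sum(manual)) / 2
  (u - i) / den
}

#' Per-ROI segmentation accuracy report
#'
#' Computes kappa, percent volume difference and L1 error for every
#' non-background label present in the manual segmentation, plus
#' unweighted across-ROI means (the per-subject summary used when
#' comparing parameter settings). Labels present in only one input are
#' reported in the `onlyAuto` / `onlyManual` attributes rather than
#' failing, but at least one shared label is required.
#'
#' @param auto automated [LabelImage-class].
#' @param manual manual / ground-truth [LabelImage-class] on the same
#'   grid.
#' @return a data.frame with columns `roi`, `name`, `kappa`, `vd`, `l1`,
#'   `vAuto`, `vManual`, plus attributes `means` (named numeric) and
#'   `onlyAuto`/`onlyManual` (label ids)
#' @export
evaluateROIs <- function(auto, manual) {
  stopIfGridMismatch(auto@grid, manual@grid, "auto and manual labels")
  av <- as.vector(auto@labels)
  mv <- as.vector(manual@labels)
  aIds <- setdiff(unique(av), 0L)
  mIds <- sort(setdiff(unique(mv), 0L))
  shared <- intersect(mIds, aIds)
  if (length(shared) == 0L)
    stop("no common non-background labels", call. = FALSE)
  rows <- lapply(mIds, function(id) {
    A <- av == id
    M <- mv == id
    data.frame(
      roi = id,
      name = if (as.character(id) %in% names(manual@labelNames))
        unname(manual@labelNames[as.character(id)]) else NA_character_,
      kappa = kappaStatistic(A, M),
      vd = volumeError(A, M),
      l1 = l1Error(A, M),
      vAuto = sum(A), vManual = sum(M))
  })
  out <- do.call(rbind, rows)
  attr(out, "means") <- c(kappa = mean(out$kappa), vd = mean(out$vd),
                          l1 = mean(out$l1))
  attr(out, "onlyAuto") <- setdiff(aIds, mIds)
  attr(out, "onlyManual") <- setdiff(mIds, aIds)
  out
}

#' Write a per-subject/ROI metrics table
#'
#' Appends a `subject` column and writes a tab-delimited table with
#' header columns `subject, roi, name, kappa, vd, l1, v_auto, v_manual`.
#'
#' @param metrics data.frame from [evaluateROIs()] (or a list of them).
#' @param path output file path.
#' @param subjects subject identifier(s), one per data.frame.
#' @return the combined data.frame, invisibly
#' @export
writeMetricsReport <- function(metrics, path, subjects = "subject1") {
  if (is.data.frame(metrics)) metrics <- list(metrics)
  stopifnot(length(subjects) == length(metrics))
  tabs <- mapply(function(m, s) {
    data.frame(subject = s, roi = m$roi, name = m$name,
               kappa = m$kappa, vd = m$vd, l1 = m$l1,
               v_auto = m$vAuto, v_manual = m$vManual)
  }, metrics, subjects, SIMPLIFY = FALSE)
  out <- do.call(rbind, tabs)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(out)
}
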
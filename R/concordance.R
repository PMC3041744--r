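## Concordance between the differentiation tracks and the Fmax scan:
## correlations, threshold-grouped means with one-tailed Wilcoxon
## signed-rank tests, and discovery-panel subset reanalysis.

#' Align an Fmax scan with binned and smoothed differentiation tracks
#'
#' Inner join on (chromosome, rounded position) across the scan grid and
#' the four differentiation tracks; rows missing any column are dropped
#' and counted. Chromosomes with an empty intersection are omitted with a
#' warning.
#'
#' @param scan a [ScanResult-class].
#' @param binnedDelta,binnedFst [binTrack()] data.frames.
#' @param maDelta,maFst [movingAverage()] data.frames.
#' @return data.frame: `chrom`, `pos`, `Fmax`, `delta`, `fst`, `maDelta`,
#'   `maFst`; attribute `nDropped`.
#' @export
alignTracks <- function(scan, binnedDelta, binnedFst, maDelta, maFst) {
  fm <- fmaxTrack(scan)
  key <- function(d) paste(d$chrom, d$pos, sep = ":")
  out <- data.frame(chrom = fm$chrom, pos = fm$pos, Fmax = fm$Fmax,
                    stringsAsFactors = FALSE)
  tracks <- list(delta = binnedDelta, fst = binnedFst,
                 maDelta = maDelta, maFst = maFst)
  for (nm in names(tracks))
    out[[nm]] <- tracks[[nm]]$value[match(key(out), key(tracks[[nm]]))]
  keep <- stats::complete.cases(out)
  nDropped <- sum(!keep)
  lost <- setdiff(unique(out$chrom), unique(out$chrom[keep]))
  if (length(lost))
    warning("no aligned positions on chromosome(s): ",
            paste(lost, collapse = ", "))
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nDropped") <- nDropped
  out
}

#' Correlations between Fmax and the differentiation measures
#'
#' Coefficients of Fmax against each of `delta`, `fst`, `maDelta`, `maFst`,
#' per chromosome (at least 3 rows; zero-variance columns give `NA`) and
#' genome-wide. The genome-wide value pools all rows (`chrom = "genome"`);
#' the unweighted mean of the per-chromosome coefficients is also reported
#' (`chrom = "genome_chrom_mean"`).
#'
#' @param aligned an [alignTracks()] data.frame.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame: `chrom`, `measure`, `r`, `n`.
#' @export
trackCorrelations <- function(aligned, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  measures <- c("delta", "fst", "maDelta", "maFst")
  corOne <- function(d) {
    n <- nrow(d)
    vapply(measures, function(m) {
      if (n < 3 || sd(d$Fmax) == 0 || sd(d[[m]]) == 0) return(NA_real_)
      cor(d$Fmax, d[[m]], method = method)
    }, 0)
  }
  perChrom <- lapply(split(aligned, aligned$chrom), function(d)
    data.frame(chrom = d$chrom[1], measure = measures, r = unname(corOne(d)),
               n = nrow(d), stringsAsFactors = FALSE))
  pooled <- data.frame(chrom = "genome", measure = measures,
                       r = unname(corOne(aligned)), n = nrow(aligned),
                       stringsAsFactors = FALSE)
  pc <- do.call(rbind, perChrom)
  cm <- vapply(measures, function(m)
    mean(pc$r[pc$measure == m], na.rm = TRUE), 0)
  chromMean <- data.frame(chrom = "genome_chrom_mean", measure = measures,
                          r = unname(cm), n = nrow(aligned),
                          stringsAsFactors = FALSE)
  out <- rbind(pc, pooled, chromMean)
  rownames(out) <- NULL
  out
}

#' Per-chromosome means of the differentiation measures in highF/lowF groups
#'
#' For each threshold, positions are grouped by whether `Fmax` exceeds it
#' (strictly; ties go to lowF) and each measure is averaged per group per
#' chromosome. Chromosomes whose highF group is empty are excluded for
#' that threshold; an empty lowF group yields `NA` with `nLow = 0`.
#'
#' @param aligned an [alignTracks()] data.frame.
#' @param thresholds a [thresholdSet()] or positive numeric vector.
#' @return data.frame: `threshold`, `chrom`, `measure`, `meanHigh`,
#'   `meanLow`, `nHigh`, `nLow`.
#' @export
thresholdGroupMeans <- function(aligned, thresholds = thresholdSet()) {
  stopifnot(all(thresholds > 0))
  measures <- c("delta", "fst", "maDelta", "maFst")
  rows <- list()
  for (thr in as.numeric(thresholds)) {
    for (d in split(aligned, aligned$chrom)) {
      hi <- d$Fmax > thr
      if (!any(hi)) next
      for (m in measures) {
        rows[[length(rows) + 1L]] <- data.frame(
          threshold = thr, chrom = d$chrom[1], measure = m,
          meanHigh = mean(d[[m]][hi]),
          meanLow = if (any(!hi)) mean(d[[m]][!hi]) else NA_real_,
          nHigh = sum(hi), nLow = sum(!hi), stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(threshold = numeric(), chrom = character(),
                  measure = character(), meanHigh = numeric(),
                  meanLow = numeric(), nHigh = integer(), nLow = integer())
  rownames(out) <- NULL
  out
}

#' One-tailed Wilcoxon signed-rank test (exact with midranked ties)
#'
#' Tests whether the paired differences `x - y` tend to be positive. Zero
#' differences are dropped (and counted); tied absolute differences are
#' midranked. The null distribution of the positive-rank sum V is computed
#' exactly for up to `exactMax` pairs by convolution over doubled ranks
#' (which stay integral under midranks), and by a normal approximation
#' with continuity and tie correction beyond.
#'
#' @param x numeric vector (e.g. highF group means), or differences if `y`
#'   is `NULL`.
#' @param y optional paired values (e.g. lowF group means).
#' @param exactMax maximum number of pairs for the exact null (default 25).
#' @return list of class `signedRankTest`: `statistic` (V), `p.value`
#'   (one-tailed, greater), `nPairs`, `nZeroDropped`, `exact`.
#' @examples
#' wilcoxonSignedRankOneTailed(rep(1, 6))$p.value  # 1/64
#' @export
wilcoxonSignedRankOneTailed <- function(x, y = NULL, exactMax = 25L) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  nZero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1")
    return(structure(list(statistic = 0, p.value = 1, nPairs = 0L,
                          nZeroDropped = nZero, exact = TRUE),
                     class = "signedRankTest"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exactMax) {
    r2 <- round(2 * r)
    maxw <- sum(r2)
    f <- c(1, numeric(maxw))
    for (rr in r2)
      f <- (f + c(numeric(rr), f[seq_len(maxw + 1 - rr)])) / 2
    v2 <- round(2 * v)
    p <- sum(f[(v2 + 1):(maxw + 1)])
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    p <- pnorm((v - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
    exact <- FALSE
  }
  structure(list(statistic = v, p.value = min(max(p, .Machine$double.xmin), 1),
                 nPairs = n, nZeroDropped = nZero, exact = exact),
            class = "signedRankTest")
}

#' Wilcoxon signed-rank tests on threshold-grouped chromosome means
#'
#' One test per (threshold, measure): pairs are the per-chromosome
#' (meanHigh, meanLow) values, chromosomes missing either group dropped;
#' the one-tailed alternative is that highF means exceed lowF means.
#'
#' @param groupMeans a [thresholdGroupMeans()] data.frame.
#' @return data.frame: `threshold`, `measure`, `statistic`, `p`, `nPairs`,
#'   `nZeroDropped`.
#' @export
concordanceTests <- function(groupMeans) {
  rows <- list()
  for (thr in unique(groupMeans$threshold)) {
    for (m in unique(groupMeans$measure)) {
      d <- groupMeans[groupMeans$threshold == thr &
                        groupMeans$measure == m, ]
      d <- d[!is.na(d$meanHigh) & !is.na(d$meanLow), ]
      if (!nrow(d)) next
      wt <- wilcoxonSignedRankOneTailed(d$meanHigh, d$meanLow)
      rows[[length(rows) + 1L]] <- data.frame(
        threshold = thr, measure = m, statistic = wt$statistic,
        p = wt$p.value, nPairs = wt$nPairs,
        nZeroDropped = wt$nZeroDropped, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(threshold = numeric(), measure = character(),
                  statistic = numeric(), p = numeric(), nPairs = integer(),
                  nZeroDropped = integer())
  rownames(out) <- NULL
  out
}

#' Reanalyse concordance on a subset of loci by discovery-panel label
#'
#' Rebuilds the delta/F_ST binned and smoothed tracks from the retained
#' loci only, realigns with the scan, and recomputes correlations. Also
#' compares mean delta between retained and excluded loci (two-sample
#' Wilcoxon rank-sum), a check on discovery-panel ascertainment bias.
#'
#' @param stats a [locusDiffStats()] data.frame (after
#'   [restrictDefinedFst()]).
#' @param scan a [ScanResult-class].
#' @param keep character vector of panel labels to retain.
#' @param window moving-average window.
#' @param binSize bin size in bp.
#' @param method correlation method.
#' @return list: `correlations`, `aligned`, `panelMeans` (mean delta per
#'   panel label), `panelTest` (rank-sum p for kept vs excluded delta;
#'   `NA` if nothing is excluded).
#' @export
subsetReanalysis <- function(stats, scan, keep, window = 11L,
                             binSize = 1e5, method = "pearson") {
  stopifnot("panel" %in% names(stats))
  inKeep <- stats$panel %in% keep
  if (!any(inKeep)) stop("no loci carry the requested panel label(s)")
  sub <- stats[inKeep, , drop = FALSE]
  bd <- binTrack(sub, "delta", binSize)
  bf <- binTrack(sub, "fst", binSize)
  md <- movingAverage(bd, window)
  mf <- movingAverage(bf, window)
  aligned <- alignTracks(scan, bd, bf, md, mf)
  cors <- trackCorrelations(aligned, method)
  panelMeans <- vapply(split(stats$delta, stats$panel), mean, 0)
  panelTest <- if (all(inKeep)) NA_real_ else
    suppressWarnings(wilcox.test(stats$delta[!inKeep], stats$delta[inKeep],
                                 alternative = "two.sided")$p.value)
  list(correlations = cors, aligned = aligned,
       panelMeans = panelMeans, panelTest = panelTest)
}
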
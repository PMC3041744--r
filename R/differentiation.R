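## Per-locus differentiation statistics and genome tracks.
##
## delta is the absolute between-breed allele-frequency difference. F_ST is
## the two-sample Weir-Cockerham variance-components estimator theta-hat,
## which adjusts for unequal sample sizes; negative estimates are clamped
## to 0 (the unclamped value is retained for audit). Tracks are binned to a
## 100-kb grid by rounding positions to the nearest multiple of 100,000 and
## averaging, then smoothed with an 11-position centered moving average.

#' Absolute allele-frequency difference between two breeds
#'
#' @param p1,p2 allele frequencies in `[0, 1]`.
#' @return `|p1 - p2|`.
#' @examples
#' deltaStat(0.9, 0.2)  # 0.7
#' @export
deltaStat <- function(p1, p2) {
  stopifnot(all(p1 >= 0 & p1 <= 1, na.rm = TRUE),
            all(p2 >= 0 & p2 <= 1, na.rm = TRUE))
  abs(p1 - p2)
}

#' Two-sample Weir-Cockerham F_ST estimator
#'
#' Variance-components estimator for r = 2 sampled populations with sample
#' sizes `n1`, `n2` (individuals), allele frequencies `p1`, `p2` and
#' observed heterozygote proportions `h1`, `h2`. With
#' `nbar = (n1 + n2)/2`,
#' `nc = (2 nbar - (n1^2 + n2^2)/(2 nbar))`,
#' `pbar` and `hbar` the sample-size-weighted means and `s2` the weighted
#' between-population variance, the components are
#' `a = (nbar/nc) [s2 - (pbar(1-pbar) - s2/2 - hbar/4)/(nbar-1)]`,
#' `b = (nbar/(nbar-1)) [pbar(1-pbar) - s2/2 - (2 nbar - 1)/(4 nbar) hbar]`,
#' `c = hbar/2`, and `theta-hat = a/(a+b+c)`. Loci where `a+b+c = 0` are
#' flagged undefined. `fst` is theta-hat clamped to `[0, 1]`.
#'
#' @param p1,p2 per-breed allele frequencies.
#' @param n1,n2 called sample sizes (individuals, >= `minCalled`).
#' @param h1,h2 observed heterozygote proportions.
#' @param minCalled minimum called individuals per breed (default 2).
#' @return data.frame: `a`, `b`, `c`, `thetaRaw`, `fst`, `defined`.
#' @examples
#' fstWeirCockerham(1, 49, 0, 0, 20, 0)$thetaRaw  # 1
#' @export
fstWeirCockerham <- function(p1, n1, h1, p2, n2, h2, minCalled = 2L) {
  stopifnot(all(p1 >= 0 & p1 <= 1, na.rm = TRUE),
            all(p2 >= 0 & p2 <= 1, na.rm = TRUE),
            all(h1 <= 1, na.rm = TRUE), all(h2 <= 1, na.rm = TRUE))
  if (any(c(n1, n2) < minCalled, na.rm = TRUE))
    stop("called sample sizes below minCalled = ", minCalled,
         "; filter such loci upstream")
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  theta <- ifelse(denom == 0, NA_real_, a / denom)
  data.frame(a = a, b = b, c = cc, thetaRaw = theta,
             fst = pmin(pmax(theta, 0), 1),
             defined = !is.na(theta))
}

#' Multilocus Weir-Cockerham theta (ratio of summed components)
#'
#' The standard multilocus combination: summed `a` over summed `a + b + c`
#' across loci.
#'
#' @param comps data.frame with columns `a`, `b`, `c` from
#'   [fstWeirCockerham()].
#' @return A single theta-hat estimate.
#' @export
multilocusFst <- function(comps) {
  ok <- stats::complete.cases(comps[, c("a", "b", "c")])
  sum(comps$a[ok]) / sum(comps$a[ok] + comps$b[ok] + comps$c[ok])
}

#' Per-locus differentiation statistics for a two-breed panel
#'
#' Computes per-breed allele frequencies and heterozygote proportions,
#' delta and (clamped) Weir-Cockerham F_ST for every locus. Loci with fewer
#' than `minCalled` called individuals in either breed are excluded with an
#' audit flag; the `defined` column marks loci whose mean frequency is not
#' 0 or 1 (use [restrictDefinedFst()] before track building).
#'
#' @param panel a [GenotypePanel-class] with two populations (or the two
#'   named in `pops`).
#' @param pops character vector of two population labels; defaults to the
#'   first two in order of appearance.
#' @param minCalled minimum called individuals per breed.
#' @return data.frame (one row per retained locus): `locus`, `chrom`,
#'   `pos`, `panel`, `p1`, `p2`, `n1`, `n2`, `h1`, `h2`, `delta`,
#'   `thetaRaw`, `fst`, `defined`; attribute `nExcludedLowCall` counts loci
#'   dropped for low call numbers.
#' @export
locusDiffStats <- function(panel, pops = NULL, minCalled = 2L) {
  if (is.null(pops)) pops <- head(populations(panel), 2L)
  stopifnot(length(pops) == 2L)
  f1 <- alleleFrequencies(panel, pops[1])
  f2 <- alleleFrequencies(panel, pops[2])
  gr <- loci(panel)
  panelLab <- if (!is.null(S4Vectors::mcols(gr)$panel))
    S4Vectors::mcols(gr)$panel else rep(NA_character_, length(gr))
  ok <- f1$nCalled >= minCalled & f2$nCalled >= minCalled
  nExcluded <- sum(!ok)
  f1 <- f1[ok, ]; f2 <- f2[ok, ]; panelLab <- panelLab[ok]
  wc <- fstWeirCockerham(f1$freq, f1$nCalled, f1$het,
                         f2$freq, f2$nCalled, f2$het, minCalled = minCalled)
  pbar <- (f1$freq + f2$freq) / 2
  out <- data.frame(locus = f1$locus, chrom = f1$chrom, pos = f1$pos,
                    panel = panelLab,
                    p1 = f1$freq, p2 = f2$freq,
                    n1 = f1$nCalled, n2 = f2$nCalled,
                    h1 = f1$het, h2 = f2$het,
                    delta = deltaStat(f1$freq, f2$freq),
                    a = wc$a, b = wc$b, c = wc$c,
                    thetaRaw = wc$thetaRaw, fst = wc$fst,
                    defined = pbar > 0 & pbar < 1 & wc$defined,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "nExcludedLowCall") <- nExcluded
  out
}

## round to the nearest multiple of `binSize`; ties at exactly half a bin
## round up by default ("half-up"), or to even multiples ("banker")
roundToBin <- function(pos, binSize = 1e5, ties = c("up", "banker")) {
  ties <- match.arg(ties)
  if (ties == "up") floor(pos / binSize + 0.5) * binSize
  else round(pos / binSize) * binSize
}

#' Bin per-locus statistics to a rounded-position grid
#'
#' Positions are rounded to the nearest multiple of `binSize` (default
#' 100 kb; ties at exactly half a bin round up) and the statistic is
#' averaged with equal weight over loci sharing a rounded position.
#'
#' @param stats per-locus data.frame with `chrom`, `pos` and the statistic
#'   column.
#' @param statistic which column to bin, `"delta"` or `"fst"` (any numeric
#'   column name is accepted).
#' @param binSize grid step in bp.
#' @param ties tie rule for positions exactly between bins.
#' @return data.frame: `chrom`, `pos` (bin), `value`, `nLoci`, sorted by
#'   (chrom, pos).
#' @export
binTrack <- function(stats, statistic = c("delta", "fst"), binSize = 1e5,
                     ties = c("up", "banker")) {
  if (is.character(statistic) && length(statistic) > 1)
    statistic <- match.arg(statistic)
  stopifnot(statistic %in% names(stats))
  v <- stats[[statistic]]
  keep <- !is.na(v)
  bin <- roundToBin(stats$pos[keep], binSize, ties)
  key <- paste(stats$chrom[keep], bin, sep = "\r")
  agg <- tapply(v[keep], key, mean)
  cnt <- tapply(v[keep], key, length)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                    pos = as.numeric(vapply(parts, `[`, "", 2L)),
                    value = unname(as.numeric(agg)),
                    nLoci = unname(as.integer(cnt)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Centered moving average of a binned track
#'
#' Default mode slides an 11-value window over the occupied bins of each
#' chromosome: the smoothed value at the i-th occupied bin is the mean of
#' occupied-bin values i-5 ... i+5, so the first and last 5 positions of
#' each chromosome are excluded and the output has `L - window + 1` rows.
#' `mode = "grid"` instead averages occupied bins within a fixed
#' `(window-1)/2 x binSize` bp distance of each retained bin (gaps in
#' marker coverage are skipped, not padded) - provided for sensitivity
#' analysis.
#'
#' @param track a [binTrack()] data.frame.
#' @param window odd window size (default 11).
#' @param mode `"bins"` (default) or `"grid"`.
#' @param binSize bp per grid step (used by `mode = "grid"`).
#' @return data.frame: `chrom`, `pos`, `value`, `window`. Chromosomes with
#'   fewer than `window` bins yield no rows (with a warning).
#' @export
movingAverage <- function(track, window = 11L, mode = c("bins", "grid"),
                          binSize = 1e5) {
  mode <- match.arg(mode)
  if (window %% 2L != 1L) stop("window must be odd")
  half <- (window - 1L) / 2L
  res <- lapply(split(track, track$chrom), function(tr) {
    tr <- tr[order(tr$pos), , drop = FALSE]
    L <- nrow(tr)
    if (L < window) {
      warning("chromosome ", tr$chrom[1], " has ", L, " bins < window ",
              window, "; no smoothed values")
      return(NULL)
    }
    if (mode == "bins") {
      idx <- (half + 1L):(L - half)
      ## two-pass mean per window: constant tracks stay exact fixed points
      val <- vapply(idx, function(i) mean(tr$value[(i - half):(i + half)]),
                    0)
      data.frame(chrom = tr$chrom[1], pos = tr$pos[idx], value = val,
                 window = window, stringsAsFactors = FALSE)
    } else {
      val <- vapply(tr$pos, function(p)
        mean(tr$value[abs(tr$pos - p) <= half * binSize]), 0)
      data.frame(chrom = tr$chrom[1], pos = tr$pos, value = val,
                 window = window, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(chrom = character(), pos = numeric(),
                      value = numeric(), window = integer())
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the genome-wide top fraction of a track
#'
#' Pools all values, takes the empirical `1 - q` quantile as the cut-off,
#' and reports positions with value strictly greater than it, together with
#' per-chromosome counts.
#'
#' @param track data.frame with `chrom`, `pos`, `value`.
#' @param q upper tail fraction in (0, 1), e.g. 0.01 for the top 1%.
#' @return list of class `RegionReport`: `cutoff`, `regions` (rows of
#'   `track` above the cut-off, ranked descending), `perChrom`
#'   (data.frame `chrom`, `n`), `q`.
#' @export
topFraction <- function(track, q) {
  stopifnot(q > 0, q < 1, all(c("chrom", "pos", "value") %in% names(track)))
  v <- track$value[!is.na(track$value)]
  cutoff <- unname(quantile(v, 1 - q, type = 7))
  sel <- !is.na(track$value) & track$value > cutoff
  regions <- track[sel, c("chrom", "pos", "value"), drop = FALSE]
  regions <- regions[order(-regions$value), , drop = FALSE]
  rownames(regions) <- NULL
  tab <- table(regions$chrom)
  perChrom <- data.frame(chrom = names(tab), n = as.integer(tab),
                         stringsAsFactors = FALSE)
  structure(list(cutoff = cutoff, regions = regions, perChrom = perChrom,
                 q = q), class = "RegionReport")
}

#' Write a RegionReport as BED plus a values TSV
#'
#' BED intervals are 0-based half-open windows of width `binSize` centered
#' on each reported bin position.
#'
#' @param report a [topFraction()] result.
#' @param bedPath,tsvPath output paths.
#' @param binSize bin width in bp.
#' @return Invisibly, the BED data.frame.
#' @export
writeRegionsBed <- function(report, bedPath, tsvPath, binSize = 1e5) {
  r <- report$regions
  if (nrow(r) == 0L) {
    file.create(bedPath)
    write.table(r, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(data.frame()))
  }
  bed <- data.frame(chrom = r$chrom,
                    start = pmax(0, r$pos - binSize / 2),
                    end = r$pos + binSize / 2,
                    name = sprintf("bin_%s_%d", r$chrom, as.integer(r$pos)),
                    score = round(1000 * r$value / max(r$value, 1e-12)),
                    strand = ".")
  write.table(bed, bedPath, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  write.table(r, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(bed)
}
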
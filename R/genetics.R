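#' @include AllClasses.R
NULL

#' Construct genotyping counts for one cross
#'
#' @param nHet,nWt heterozygous and wild-type progeny counts.
#' @param direction `"female"` (het parent as mother) or `"male"`.
#' @param line line label.
#' @return a [CrossCounts].
#' @export
crossCounts <- function(nHet, nWt, direction = "female", line = "") {
    new("CrossCounts", nHet = as.integer(nHet), nWt = as.integer(nWt),
        direction = direction, line = line)
}

#' Round half away from zero
#'
#' Display rounding used for transmission-efficiency tables (R's `round`
#' rounds half to even).
#'
#' @param x numeric.
#' @param digits decimal places (default 1).
#' @return rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 1L)
    sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits

#' Transmission efficiency of a mutant allele
#'
#' `TE = 100 * n_het / n_wt` from the genotyped progeny of a heterozygote x
#' wild-type cross; 100 under Mendelian transmission. The raw ratio is
#' returned; tables conventionally print it to one decimal
#' ([roundHalfUp()]).
#'
#' @param x a [CrossCounts], or the heterozygous count.
#' @param nWt wild-type count when `x` is given as a count.
#' @return TE in percent (raw, unrounded).
#' @export
#' @examples
#' roundHalfUp(transmissionEfficiency(16, 133))  # 12.0
transmissionEfficiency <- function(x, nWt = NULL) {
    if (is(x, "CrossCounts")) { nHet <- x@nHet; nWt <- x@nWt }
    else nHet <- x
    if (nWt == 0L) stop("TE undefined: no wild-type progeny")
    100 * nHet / nWt
}

#' Chi-square test against 1:1 segregation
#'
#' Goodness-of-fit of observed (het, wt) counts to the Mendelian 1:1
#' expectation, without continuity correction; the deviation is called
#' significant when the statistic exceeds 3.85 (the conventional df = 1,
#' alpha = 0.05 critical value as printed in transmission tables).
#'
#' @param x a [CrossCounts], or the heterozygous count.
#' @param nWt wild-type count when `x` is given as a count.
#' @return list with `X2`, `expected` (per class), `p` and `significant`.
#' @export
#' @examples
#' chisq1to1(16, 133)$X2  # 91.87...
chisq1to1 <- function(x, nWt = NULL) {
    if (is(x, "CrossCounts")) { nHet <- x@nHet; nWt <- x@nWt }
    else nHet <- x
    total <- nHet + nWt
    if (total < 1L) stop("at least one progeny is required")
    ct <- suppressWarnings(
        stats::chisq.test(c(nHet, nWt), p = c(0.5, 0.5), correct = FALSE))
    list(X2 = unname(ct$statistic), expected = total / 2,
         p = unname(ct$p.value),
         significant = unname(ct$statistic) > 3.85)
}

#' Abnormal-phenotype fraction with Wilson confidence interval
#'
#' @param nAbnormal,nTotal counts, `0 <= nAbnormal <= nTotal`,
#'   `nTotal > 0`.
#' @param conf confidence level (default 0.95).
#' @return list with `percent` (integer display convention), `raw`
#'   (unrounded percent) and `ci` (Wilson interval, percent).
#' @export
#' @examples
#' phenotypeFraction(50, 100)$ci  # approx (40.4, 59.6)
phenotypeFraction <- function(nAbnormal, nTotal, conf = 0.95) {
    if (nTotal <= 0L || nAbnormal < 0L || nAbnormal > nTotal)
        stop("require 0 <= nAbnormal <= nTotal, nTotal > 0")
    pt <- suppressWarnings(
        stats::prop.test(nAbnormal, nTotal, conf.level = conf,
                         correct = FALSE))
    list(percent = roundHalfUp(100 * nAbnormal / nTotal, 0L),
         raw = 100 * nAbnormal / nTotal,
         ci = 100 * as.numeric(pt$conf.int))
}

#' Relative fluorescence within one ovule
#'
#' Divides each nucleus's intensity sum by the within-ovule minimum, so the
#' dimmest nucleus maps to exactly 1; scale-invariant.
#'
#' @param intensities positive numeric vector of per-nucleus intensity
#'   sums.
#' @return relative intensities (minimum exactly 1).
#' @export
#' @examples
#' relativeFluorescence(c(100, 200))  # 1, 2
relativeFluorescence <- function(intensities) {
    if (!length(intensities)) stop("need at least one nucleus")
    if (any(!is.finite(intensities)) || any(intensities <= 0))
        stop("intensity sums must be positive")
    intensities / min(intensities)
}

#' Summarize reciprocal crosses as a transmission table
#'
#' Mirrors the conventional transmission-efficiency table: observed and
#' expected counts, totals, the 1:1 chi-square statistic, and TE, with the
#' statistic and TE rounded to one decimal for display.
#'
#' @param crosses list of [CrossCounts].
#' @return data.frame, one row per cross.
#' @export
crossSummary <- function(crosses) {
    do.call(rbind, lapply(crosses, function(cc) {
        ch <- chisq1to1(cc)
        data.frame(line = cc@line, direction = cc@direction,
                   het_obs = cc@nHet, wt_obs = cc@nWt,
                   expected = ch$expected, total = cc@nHet + cc@nWt,
                   X2 = roundHalfUp(ch$X2), significant = ch$significant,
                   TE = roundHalfUp(transmissionEfficiency(cc)))
    }))
}

#' Read a cross-count table
#'
#' @param file TSV with columns `line`, `direction`, `n_het`, `n_wt`.
#' @return list of [CrossCounts].
#' @export
readCrossCounts <- function(file) {
    df <- utils::read.delim(file)
    lapply(seq_len(nrow(df)), function(i)
        crossCounts(df$n_het[i], df$n_wt[i], direction = df$direction[i],
                    line = df$line[i]))
}
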
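## Per-combination null-distribution fitting and p-values.
##
## The Negative Binomial is fitted by the method of moments (the empirical
## mean and variance of the shuffle samples), deliberately not by maximum
## likelihood: moment fitting is more robust here and small likelihood
## differences would swing extreme p-values. Convention used throughout
## (matching stats::pnbinom): mean = r(1-p)/p and variance = mean/p, so
## p = mean/variance and r = mean^2/(variance - mean), defined when
## variance > mean.

#' Method-of-moments Negative Binomial fit
#'
#' @param samples integer vector of shuffle samples (length >= 2).
#' @return a list with \code{status} one of \code{"ok"},
#'   \code{"underdispersed"} (variance <= mean: the NB is undefined; a
#'   Poisson with the sample mean is kept as fallback) or
#'   \code{"untestable"} (all samples zero / constant at zero), plus
#'   \code{r}, \code{p} (when ok), \code{lambda} (when underdispersed) and
#'   \code{mean}, \code{var}.
#' @examples
#' fitNegbinMoments(c(8, 12, 9, 11, 10, 10))  # mean 10
#' @export
fitNegbinMoments <- function(samples) {
    if (length(samples) < 2L) stop("need at least 2 samples")
    if (any(samples < 0)) stop("samples must be non-negative")
    m <- mean(samples); v <- stats::var(samples)
    if (m == 0)
        return(list(status = "untestable", mean = m, var = v))
    if (v <= m)
        return(list(status = "underdispersed", lambda = m, mean = m, var = v))
    list(status = "ok", p = m / v, r = m^2 / (v - m), mean = m, var = v)
}

#' Upper-tail Negative Binomial p-value
#'
#' Returns \code{P(X >= sObs)} (inclusive) for the fitted null: the
#' probability of observing at least the actual overlap by chance. For an
#' underdispersed fit the Poisson fallback tail is returned; for an
#' untestable fit \code{NA} (use the empirical p-value instead).
#'
#' @param fit result of \code{\link{fitNegbinMoments}}.
#' @param sObs observed value.
#' @return p-value in [0, 1], or \code{NA} when untestable.
#' @export
negbinPvalue <- function(fit, sObs) {
    if (sObs <= 0) return(1)
    switch(fit$status,
        ok = stats::pnbinom(sObs - 1, size = fit$r, prob = fit$p,
                            lower.tail = FALSE),
        underdispersed = stats::ppois(sObs - 1, lambda = fit$lambda,
                                      lower.tail = FALSE),
        NA_real_)
}

#' Empirical p-value with add-one correction
#'
#' \code{(1 + #\{samples >= sObs\}) / (n + 1)}: the add-one rule keeps the
#' p-value strictly positive, floored at \code{1/(n+1)}.
#'
#' @param samples shuffle samples.
#' @param sObs observed value.
#' @return p-value in (0, 1].
#' @export
empiricalPvalue <- function(samples, sObs) {
    (1 + sum(samples >= sObs)) / (length(samples) + 1)
}

#' Log2 fold change of observed over expected overlap
#'
#' \code{log2(sObs / sExp)}; when either term is zero, a pseudo-count
#' \code{eps} (1 bp by default) is added to both so the fold change stays
#' finite.
#'
#' @param sObs observed S (bp).
#' @param sExp expected S under the null (mean of the shuffles).
#' @param eps pseudo-count in bp.
#' @return the log2 ratio.
#' @examples
#' foldChange(2000, 2)   # ~ 9.97: very enriched
#' @export
foldChange <- function(sObs, sExp, eps = 1) {
    if (sObs > 0 && sExp > 0) log2(sObs / sExp)
    else log2((sObs + eps) / (sExp + eps))
}

#' Cramer's V goodness-of-fit diagnostic
#'
#' Bins the shuffle samples and the fitted Negative Binomial into shared
#' quantile classes (targeting an expected count of at least 5 per bin),
#' computes the chi-square statistic and reports Cramer's V
#' \code{sqrt(chi2 / (n * (bins - 1)))}. The fit verdict is \code{"good"}
#' when V is below \code{threshold}. Poor fits arise mainly when the
#' combination is too rare in the shuffles; p-values are then conservative.
#'
#' @param samples shuffle samples (length >= 20 for a testable verdict).
#' @param fit result of \code{\link{fitNegbinMoments}}.
#' @param threshold verdict threshold on V (default 0.25; a configurable
#'   knob, reported alongside the verdict).
#' @return list with \code{cramersV}, \code{nBins} and \code{verdict}
#'   (\code{"good"}, \code{"poor"} or \code{"untestable"}).
#' @export
cramersVFit <- function(samples, fit, threshold = 0.25) {
    n <- length(samples)
    if (fit$status != "ok" || n < 20L || length(unique(samples)) < 3L)
        return(list(cramersV = NA_real_, nBins = 0L, verdict = "untestable"))
    nBins <- max(2L, min(10L, floor(n / 5)))
    qs <- stats::qnbinom(seq(0, 1, length.out = nBins + 1L),
                         size = fit$r, prob = fit$p)
    breaks <- unique(c(-0.5, qs[-c(1L, nBins + 1L)] + 0.5, Inf))
    if (length(breaks) < 3L)
        return(list(cramersV = NA_real_, nBins = 0L, verdict = "untestable"))
    obs <- table(cut(samples, breaks))
    pr <- diff(stats::pnbinom(breaks, size = fit$r, prob = fit$p))
    pr <- pr / sum(pr)
    expd <- n * pr
    keep <- expd > 0
    chi2 <- sum((as.numeric(obs[keep]) - expd[keep])^2 / expd[keep])
    v <- sqrt(chi2 / (n * (sum(keep) - 1L)))
    list(cramersV = min(v, 1), nBins = sum(keep),
         verdict = if (v < threshold) "good" else "poor")
}

#' Beta-distribution p-value for S
#'
#' Companion to the Negative Binomial model: the shuffle samples are
#' rescaled by the total bp of the analysed (sub-)genome, a Beta
#' distribution is moment-fitted to the rescaled samples, and the upper
#' tail at \code{sObs/scale} is returned. With only hundreds of shuffles
#' the Beta moments are imprecise, so the fit is flagged low-confidence
#' below 1000 shuffles; it becomes preferable only with thousands of
#' shuffles.
#'
#' @param samples shuffle samples of S (bp).
#' @param sObs observed S (bp).
#' @param scale total bp of the analysed (sub-)genome; must be positive and
#'   at least \code{max(samples)}.
#' @return list with \code{a}, \code{b}, \code{scale}, \code{p},
#'   \code{status} (\code{"ok"} or \code{"degenerate"}) and
#'   \code{lowConfidence} (TRUE when fewer than 1000 shuffles).
#' @export
fitBetaPvalue <- function(samples, sObs, scale) {
    if (scale <= 0 || scale < max(samples))
        stop("scale must be positive and >= max(samples)")
    x <- samples / scale
    m <- mean(x); v <- stats::var(x)
    low <- length(samples) < 1000L
    if (v == 0 || m <= 0 || m >= 1)
        return(list(a = NA_real_, b = NA_real_, scale = scale, p = NA_real_,
                    status = "degenerate", lowConfidence = low))
    common <- m * (1 - m) / v - 1
    a <- m * common; b <- (1 - m) * common
    if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0)
        return(list(a = NA_real_, b = NA_real_, scale = scale, p = NA_real_,
                    status = "degenerate", lowConfidence = low))
    p <- if (sObs <= 0) 1 else
        stats::pbeta(sObs / scale, a, b, lower.tail = FALSE)
    list(a = a, b = b, scale = scale, p = p, status = "ok",
         lowConfidence = low)
}

#' Assemble the full statistics for one combination
#'
#' Fits the Negative Binomial (method of moments) to the S and N shuffle
#' samples, computes NB / empirical / Beta p-values, the log2 fold change
#' and the Cramer's V fit diagnostic. Degenerate fits never raise; they
#' are flagged in the output.
#'
#' @param Ssamples,Nsamples shuffle sample vectors (equal length).
#' @param Sobs,Nobs observed values.
#' @param scale total bp of the analysed (sub-)genome (Beta scale).
#' @param cramersVThreshold verdict threshold for \code{\link{cramersVFit}}.
#' @param fitAssessed set \code{FALSE} for merged superbatches: the fit
#'   diagnostic is then reported as \code{"not assessed"}.
#' @return one-row data.frame of statistics.
#' @export
summarizeCombination <- function(Ssamples, Nsamples, Sobs, Nobs, scale,
                                 cramersVThreshold = 0.25,
                                 fitAssessed = TRUE) {
    stopifnot(length(Ssamples) == length(Nsamples))
    fitS <- fitNegbinMoments(Ssamples)
    fitN <- fitNegbinMoments(Nsamples)
    beta <- fitBetaPvalue(Ssamples, Sobs, scale)
    diag <- if (fitAssessed) cramersVFit(Ssamples, fitS, cramersVThreshold)
            else list(cramersV = NA_real_, nBins = 0L,
                      verdict = "not assessed")
    pS <- negbinPvalue(fitS, Sobs)
    data.frame(
        S_obs = Sobs,
        S_exp_mean = fitS$mean,
        S_exp_sd = sqrt(fitS$var),
        log2_fold_change = foldChange(Sobs, fitS$mean),
        p_nb_S = if (is.na(pS)) empiricalPvalue(Ssamples, Sobs) else pS,
        p_nb_S_flag = fitS$status,
        p_empirical_S = empiricalPvalue(Ssamples, Sobs),
        p_beta_S = beta$p,
        fit_cramers_v = diag$cramersV,
        fit_verdict = diag$verdict,
        N_obs = Nobs,
        N_exp_mean = fitN$mean,
        p_nb_N = {
            pN <- negbinPvalue(fitN, Nobs)
            if (is.na(pN)) empiricalPvalue(Nsamples, Nobs) else pN
        },
        nb_r = if (fitS$status == "ok") fitS$r else NA_real_,
        nb_p = if (fitS$status == "ok") fitS$p else NA_real_,
        stringsAsFactors = FALSE)
}

#' Merge Monte Carlo runs into a superbatch
#'
#' Concatenates the per-combination shuffle samples of two or more runs
#' sharing the same set list and counting mode (combinations absent from a
#' run are padded with zeros). Goodness of fit is \emph{not} assessed on
#' merged superbatches, and the merged result is flagged accordingly.
#'
#' @param ... two or more \code{\linkS4class{MonteCarloResult}} objects.
#' @return a merged \code{MonteCarloResult} with \code{fitAssessed} FALSE.
#' @export
mergeRuns <- function(...) {
    runs <- list(...)
    if (length(runs) == 1L && is.list(runs[[1L]]) &&
        !methods::is(runs[[1L]], "MonteCarloResult"))
        runs <- runs[[1L]]
    if (length(runs) < 2L) stop("need at least two runs to merge")
    for (r in runs)
        if (!methods::is(r, "MonteCarloResult"))
            stop("all arguments must be MonteCarloResult objects")
    base <- runs[[1L]]
    for (r in runs[-1L]) {
        if (!identical(r@setNames, base@setNames))
            stop("runs have different set lists; cannot merge")
        if (!identical(r@mode, base@mode))
            stop("runs have different counting modes; cannot merge")
    }
    codes <- sort(unique(unlist(lapply(runs, function(r) r@codes))))
    nshTot <- sum(vapply(runs, function(r) r@nShuffles, integer(1)))
    S <- matrix(0, length(codes), nshTot)
    N <- matrix(0, length(codes), nshTot)
    Sobs <- numeric(length(codes)); Nobs <- numeric(length(codes))
    col <- 0L
    for (r in runs) {
        idx <- match(r@codes, codes)
        S[idx, col + seq_len(r@nShuffles)] <- r@S
        N[idx, col + seq_len(r@nShuffles)] <- r@N
        Sobs[idx] <- r@Sobs
        Nobs[idx] <- r@Nobs
        col <- col + r@nShuffles
    }
    methods::new("MonteCarloResult",
                 setNames = base@setNames, mode = base@mode,
                 codes = codes, Sobs = Sobs, Nobs = Nobs, S = S, N = N,
                 nShuffles = nshTot, seed = base@seed,
                 queryIndex = base@queryIndex, genomeSize = base@genomeSize,
                 fitAssessed = FALSE)
}
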
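pcEffectLabel <- function(term, predictor) {
    pred <- if (predictor == "anxiety") "Anxiety" else "Avoidance"
    if (term == "(Intercept)") return("Intercept")
    if (grepl("^condition[^:]*$", term))
        return(sprintf("Condition: %s", sub("^condition", "", term)))
    if (term == "attachment") return(sprintf("Attachment %s", pred))
    if (grepl("^condition.*:attachment$", term))
        return(sprintf("%s × %s",
                       sub(":attachment$", "", sub("^condition", "", term)), pred))
    term
}

#' Fit the linear mixed-effects moderation model
#'
#' Maximum-likelihood fit (lme4, `REML = FALSE`) of
#' `dwpli ~ condition + attachment + condition:attachment + (1 | participant)`
#' on a long-format model table (see [buildModelTable()]).  The reference
#' condition is Negative, so the reported condition terms are
#' "Condition: Reappraise" and "Condition: Suppress"; the attachment score
#' (anxiety or avoidance) is mean-centred within the table before entering
#' the model.  Wald tests per fixed effect use the normal reference by
#' default (`dfMethod = "residual"` switches to a t reference with
#' `nObs - nFixed` degrees of freedom; at typical sample sizes the
#' difference is negligible).
#'
#' @param table model-table data.frame with columns `participant`,
#'   `condition`, `dwpli`, and the predictor column; rows with missing
#'   outcome or predictor are dropped (complete-case).
#' @param predictor `"anxiety"` or `"avoidance"`.
#' @param fixedTerms subset of
#'   `c("condition", "attachment", "condition:attachment")` defining the
#'   fixed-effect structure (used to fit nested models for likelihood-ratio
#'   tests).
#' @param center mean-centre the attachment score (default TRUE).
#' @param dfMethod `"normal"` or `"residual"`.
#' @param refCondition reference level for condition dummies.
#' @return an [LMMResult].
#' @export
fitLmm <- function(table, predictor = c("anxiety", "avoidance"),
                   fixedTerms = c("condition", "attachment",
                                  "condition:attachment"),
                   center = TRUE, dfMethod = c("normal", "residual"),
                   refCondition = "Negative") {
    predictor <- match.arg(predictor)
    dfMethod <- match.arg(dfMethod)
    if (!predictor %in% names(table))
        stop(sprintf("predictor column '%s' absent from the model table", predictor))
    bad <- setdiff(fixedTerms, c("condition", "attachment", "condition:attachment"))
    if (length(bad))
        stop(sprintf("unknown fixed terms: %s", paste(bad, collapse = ", ")))
    d <- table[!is.na(table$dwpli) & !is.na(table[[predictor]]), , drop = FALSE]
    lev <- unique(d$condition)
    if (length(lev) < 2L)
        stop("at least two conditions are required for identifiability")
    if (length(unique(d$participant)) < 2L)
        stop("at least two participants are required")
    lev <- c(intersect(refCondition, lev), sort(setdiff(lev, refCondition)))
    d$condition <- factor(d$condition, levels = lev)
    d$attachment <- d[[predictor]]
    if (center) d$attachment <- d$attachment - mean(d$attachment)

    rhs <- paste(c(fixedTerms, "(1 | participant)"), collapse = " + ")
    fit <- lme4::lmer(stats::as.formula(paste("dwpli ~", rhs)), data = d,
                      REML = FALSE,
                      control = lme4::lmerControl(check.conv.singular = "ignore",
                                                  calc.derivs = FALSE))
    conv <- fit@optinfo$conv$opt
    if (!is.null(conv) && conv != 0)
        stop(sprintf("mixed-model fit did not converge (optimizer code %d)", conv))

    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    stat <- beta / se
    nfix <- length(beta)
    nobs <- nrow(d)
    if (dfMethod == "normal") {
        p <- 2 * stats::pnorm(-abs(stat))
        crit <- stats::qnorm(0.975)
    } else {
        dfres <- nobs - nfix
        p <- 2 * stats::pt(-abs(stat), df = dfres)
        crit <- stats::qt(0.975, df = dfres)
    }
    ll <- stats::logLik(fit)
    vc <- lme4::VarCorr(fit)
    fixed <- data.frame(term = names(beta),
                        label = vapply(names(beta), pcEffectLabel, "",
                                       predictor = predictor),
                        estimate = unname(beta), se = unname(se),
                        stat = unname(stat), p = unname(p),
                        ciLow = unname(beta - crit * se),
                        ciHigh = unname(beta + crit * se),
                        stringsAsFactors = FALSE)
    new("LMMResult", fixed = fixed,
        ranVar = as.numeric(vc$participant[1, 1]),
        resVar = attr(vc, "sc")^2,
        aic = stats::AIC(fit), bic = stats::BIC(fit),
        logLik = as.numeric(ll), deviance = -2 * as.numeric(ll),
        nObs = as.integer(nobs),
        nGroups = as.integer(lme4::ngrps(fit)[["participant"]]),
        nPar = as.integer(attr(ll, "df")),
        band = if (!is.null(d$band)) as.character(d$band[1]) else NA_character_,
        roi = if (!is.null(d$roi)) as.character(d$roi[1]) else NA_character_,
        predictor = predictor, terms = fixedTerms)
}

#' @rdname accessors
#' @export
setMethod("fixedEffects", "LMMResult", function(object) object@fixed)

setMethod("show", "LMMResult", function(object) {
    cat(sprintf("LMMResult (%s / %s / %s): %d obs, %d participants\n",
                object@predictor, object@roi, object@band, object@nObs,
                object@nGroups))
    cat(sprintf("  AIC %.2f  BIC %.2f  logLik %.2f  deviance %.2f\n",
                object@aic, object@bic, object@logLik, object@deviance))
    cat(sprintf("  random-intercept var %.4g, residual var %.4g\n",
                object@ranVar, object@resVar))
    print(object@fixed[, c("label", "estimate", "se", "stat", "p")],
          row.names = FALSE, digits = 4)
})

#' Likelihood-ratio test between nested ML fits
#'
#' `statistic = deviance(nested) - deviance(full)` referenced to a
#' chi-squared distribution with df equal to the parameter-count
#' difference.  Both models must be ML fits of the same data with nested
#' fixed-effect term sets; identical models give statistic 0 and p = 1.
#'
#' @param nested,full [LMMResult] objects.
#' @return list with `statistic`, `df`, `p.value`.
#' @export
likelihoodRatioTest <- function(nested, full) {
    stopifnot(is(nested, "LMMResult"), is(full, "LMMResult"))
    if (nested@nObs != full@nObs)
        stop("models were not fitted to the same data (different n)")
    if (!all(nested@terms %in% full@terms))
        stop("models are not nested (nested terms are not a subset)")
    df <- full@nPar - nested@nPar
    if (df < 0L) stop("nested model has more parameters than the full model")
    stat <- nested@deviance - full@deviance
    if (stat < 0 && stat > -1e-6) stat <- 0
    if (stat < 0)
        stop("negative deviance difference: models are not nested ML fits")
    p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
    list(statistic = stat, df = df, p.value = p)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values `p_(i) = min_(j >= i) p_(j) * m / j`, capped at
#' 1, returned in the original order (delegates to
#' `stats::p.adjust(method = "BH")`).
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhFdr <- function(pvals) {
    if (!length(pvals)) return(numeric(0))
    if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
        stop("all p-values must lie in [0, 1]")
    stats::p.adjust(pvals, method = "BH")
}

#' Shapiro-Wilk normality gate
#'
#' Standard W statistic; flags the sample for non-parametric analysis when
#' p < .05.
#'
#' @param x numeric sample, 3 <= n <= 5000, not constant.
#' @return list with `W`, `p.value`, `useNonparametric`.
#' @export
shapiroWilkGate <- function(x) {
    n <- length(x)
    if (n < 3L || n > 5000L)
        stop("sample size must be in 3..5000")
    if (stats::sd(x) == 0)
        stop("degenerate input: all values are identical")
    sw <- stats::shapiro.test(x)
    list(W = unname(sw$statistic), p.value = sw$p.value,
         useNonparametric = sw$p.value < 0.05)
}

#' Friedman test across repeated-measures conditions
#'
#' Within-participant midrank-based Friedman chi-squared with the standard
#' tie correction, df = k - 1.
#'
#' @param ratings numeric matrix, participants x conditions, no missing
#'   cells.
#' @return list with `statistic`, `df`, `p.value`.
#' @export
friedmanTest <- function(ratings) {
    ratings <- as.matrix(ratings)
    if (anyNA(ratings))
        stop("ratings matrix has missing cells")
    if (nrow(ratings) < 2L || ncol(ratings) < 2L)
        stop("need at least 2 participants and 2 conditions")
    r <- t(apply(ratings, 1, rank))
    n <- nrow(r); k <- ncol(r)
    num <- (k - 1) * (sum(colSums(r)^2) - n^2 * k * (k + 1)^2 / 4)
    den <- sum(r^2) - n * k * (k + 1)^2 / 4
    stat <- if (den == 0) 0 else num / den
    list(statistic = stat, df = k - 1,
         p.value = stats::pchisq(stat, k - 1, lower.tail = FALSE))
}

#' Dunn's post-hoc tests after a Friedman test
#'
#' Pairwise z statistics from within-participant rank sums with a midrank
#' tie correction: the variance of a rank-sum difference is accumulated per
#' participant as `2 * s_i^2 * k / (k - 1)` with `s_i^2` the variance of
#' that participant's midranks (reducing to `n k (k + 1) / 6` without ties).
#' P-values use the normal reference and a Bonferroni-style adjustment over
#' the k(k-1)/2 comparisons, capped at 1.
#'
#' @param ratings numeric matrix, participants x conditions (column names
#'   label the conditions).
#' @return data.frame (`group1`, `group2`, `z`, `p`, `pAdj`).
#' @export
dunnPosthoc <- function(ratings) {
    ratings <- as.matrix(ratings)
    if (anyNA(ratings))
        stop("ratings matrix has missing cells")
    if (nrow(ratings) < 2L || ncol(ratings) < 2L)
        stop("need at least 2 participants and 2 conditions")
    if (is.null(colnames(ratings)))
        colnames(ratings) <- paste0("C", seq_len(ncol(ratings)))
    r <- t(apply(ratings, 1, rank))
    n <- nrow(r); k <- ncol(r)
    rs <- colSums(r)
    s2 <- apply(r, 1, function(v) mean((v - mean(v))^2))
    varDiff <- sum(2 * s2 * k / (k - 1))
    m <- k * (k - 1) / 2
    rows <- list()
    for (u in seq_len(k - 1)) for (v in (u + 1):k) {
        diff <- rs[u] - rs[v]
        z <- if (diff == 0) 0 else diff / sqrt(varDiff)
        p <- 2 * stats::pnorm(-abs(z))
        rows[[length(rows) + 1L]] <-
            data.frame(group1 = colnames(r)[u], group2 = colnames(r)[v],
                       z = z, p = p, pAdj = min(1, p * m),
                       stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
}

#' Paired Cohen's d
#'
#' `d = mean(x - y) / sd(x - y)` (difference-score convention).
#'
#' @param x,y paired numeric vectors of equal length, n >= 2.
#' @return scalar d.
#' @export
cohensDPaired <- function(x, y) {
    if (length(x) != length(y))
        stop("x and y must have equal length")
    if (length(x) < 2L)
        stop("need at least 2 pairs")
    dd <- x - y
    s <- stats::sd(dd)
    if (s <= 1e-12 * max(1, abs(mean(dd))))
        stop("degenerate input: difference scores have (near-)zero SD")
    mean(dd) / s
}
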
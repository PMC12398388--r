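#' Power of a within-factors repeated-measures ANOVA
#'
#' Noncentral-F power with `df1 = (k - 1) * eps`,
#' `df2 = (n - 1) * (k - 1) * eps` and noncentrality
#' `lambda = f^2 * n * k * eps / (1 - rho)` — the G*Power convention for a
#' within-subject factor with `k` levels, Cohen's effect size `f`, assumed
#' correlation `rho` among repeated measures and nonsphericity correction
#' `eps`.
#'
#' @param n sample size (participants).
#' @param k number of within-subject conditions.
#' @param f Cohen's effect size f (> 0).
#' @param alpha type-I error rate.
#' @param rho correlation among repeated measures (default 0.5).
#' @param eps nonsphericity correction in (0, 1\].
#' @return achieved power in (0, 1).
#' @examples
#' rmAnovaPowerValue(48, k = 3, f = 0.20)  # ~0.858
#' @export
rmAnovaPowerValue <- function(n, k, f, alpha = 0.05, rho = 0.5, eps = 1) {
    if (f <= 0) stop("f must be > 0")
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
    if (rho <= -1 || rho >= 1) stop("rho must be in (-1, 1)")
    if (eps <= 0 || eps > 1) stop("eps must be in (0, 1]")
    if (n < 2) stop("n must be >= 2")
    df1 <- (k - 1) * eps
    df2 <- (n - 1) * (k - 1) * eps
    lambda <- f^2 * n * k * eps / (1 - rho)
    1 - stats::pf(stats::qf(1 - alpha, df1, df2), df1, df2, ncp = lambda)
}

#' A priori / sensitivity power analysis for RM-ANOVA
#'
#' `solveFor = "n"` returns the smallest integer sample size achieving the
#' target power at effect size `f`; `solveFor = "f"` returns the minimal
#' detectable effect size at sample size `n` (conventionally reported to
#' two decimals).
#'
#' @param k number of within-subject conditions.
#' @param f effect size (required for `solveFor = "n"`).
#' @param n sample size (required for `solveFor = "f"`).
#' @param alpha type-I error rate.
#' @param power target power.
#' @param rho correlation among repeated measures.
#' @param eps nonsphericity correction.
#' @param solveFor `"n"` or `"f"`.
#' @return integer sample size, or numeric effect size f.
#' @examples
#' rmAnovaPower(k = 3, f = 0.20)                    # 48 participants
#' round(rmAnovaPower(k = 3, n = 60, solveFor = "f"), 2)  # 0.18
#' @export
rmAnovaPower <- function(k, f = NULL, n = NULL, alpha = 0.05, power = 0.85,
                         rho = 0.5, eps = 1, solveFor = c("n", "f")) {
    solveFor <- match.arg(solveFor)
    if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
    if (solveFor == "n") {
        if (is.null(f)) stop("solveFor = 'n' requires f")
        for (N in 2:1000000) {
            if (rmAnovaPowerValue(N, k, f, alpha, rho, eps) >= power)
                return(as.integer(N))
        }
        stop("target power unreachable within the search bound (n <= 1e6)")
    }
    if (is.null(n)) stop("solveFor = 'f' requires n")
    g <- function(ff) rmAnovaPowerValue(n, k, ff, alpha, rho, eps) - power
    if (g(10) < 0)
        stop("target power unreachable at this n for any f <= 10")
    stats::uniroot(g, c(1e-8, 10), tol = 1e-10)$root
}
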
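test_that("window selection keeps [tStart, tEnd) at the sampling grid", {
    mont <- miniMontage(2)
    coh <- sampleCohort(2, seed = 1)
    des <- designSpec(trialsPerCondition = 2, srate = 500,
                      conditions = "NatNeutral")
    eps <- simulateParticipant(coh[1, ], list(), des, mont, seed = 1)
    w <- selectWindow(eps$NatNeutral, 0.3, 4.0)
    expect_equal(dim(epochData(w))[3], 1850)    # (4.0 - 0.3) * 500
    expect_equal(startTime(w), 0.3)

    ident <- selectWindow(w, startTime(w), startTime(w) + 1850 / 500)
    expect_identical(epochData(ident), epochData(w))

    expect_error(selectWindow(eps$NatNeutral, 0.3, 5.0), "outside")
    expect_error(selectWindow(eps$NatNeutral, 2, 1), "tStart")
})

test_that("taper count follows floor(2 T W) - 1 and rejects tiny products", {
    expect_identical(dpssTaperCount(3.7, 2), 13L)
    expect_identical(dpssTaperCount(1.0, 2), 3L)
    expect_error(dpssTaperCount(1.0, 0.5), "time-bandwidth")
    # content-independent: same K regardless of data
    mont <- miniMontage(2)
    coh <- sampleCohort(2, seed = 1)
    des <- quickDesign(trials = 2, srate = 100)
    for (s in 1:2) {
        eps <- simulateParticipant(coh[s, ], list(), des, mont, seed = s)
        co <- multitaperCoeffs(selectWindow(eps$NatNeutral), 2, c(1, 30))
        expect_identical(co@nTapers, 13L)
    }
})

test_that("DPSS tapers are unit-energy and near-orthogonal", {
    tap <- dpssTapers(256, 4 / 256, 5)
    G <- crossprod(tap)
    expect_equal(diag(G), rep(1, 5), tolerance = 1e-10)
    expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
})

test_that("matrix-product DFT equals stats::fft on the selected bins", {
    mont <- miniMontage(2)
    coh <- sampleCohort(2, seed = 3)
    des <- quickDesign(trials = 3, srate = 100)
    eps <- simulateParticipant(coh[1, ], list(), des, mont, seed = 9)
    w <- selectWindow(eps$NatNeutral)
    co <- multitaperCoeffs(w, 2, c(1, 20))
    n <- dim(epochData(w))[3]
    tap <- dpssTapers(n, 2 / srate(w), co@nTapers)
    kk <- round(co@freqs * n / srate(w))
    for (tr in 1:2) for (k in c(1, 7)) for (ch in 1:2) {
        x <- epochData(w)[tr, ch, ]
        ref <- fft((x - mean(x)) * tap[, k])[kk + 1] / sqrt(n)
        expect_equal(co@coeffs[tr, k, ch, ], ref, tolerance = 1e-10)
    }
})

test_that("a pure sinusoid concentrates its multitaper power within the half-bandwidth", {
    srate <- 100; n <- 370          # 3.7 s window
    f0 <- 10                        # exactly bin 37
    tt <- (0:(n - 1)) / srate
    dat <- array(sin(2 * pi * f0 * tt), dim = c(1, 1, n))
    eeg <- new("EpochedEEG", participant = "x", condition = "y", data = dat,
               srate = srate, t0 = 0, montage = montage("Fz"))
    co <- multitaperCoeffs(eeg, 2, c(0, srate / 2))
    pw <- colSums(abs(co@coeffs[1, , 1, ])^2)   # summed over tapers
    inBand <- abs(co@freqs - f0) <= 2
    expect_gte(sum(pw[inBand]) / sum(pw), 0.95)
})

test_that("a constant signal has all-zero coefficients after demeaning", {
    dat <- array(5, dim = c(1, 1, 200))
    eeg <- new("EpochedEEG", participant = "x", condition = "y", data = dat,
               srate = 50, t0 = 0, montage = montage("Fz"))
    co <- multitaperCoeffs(eeg, 1, c(0, 25))
    expect_lt(max(abs(co@coeffs)), 1e-10)
})

test_that("identical channels give identical coefficients", {
    set.seed(8)
    x <- rnorm(200)
    dat <- array(0, dim = c(1, 2, 200))
    dat[1, 1, ] <- x; dat[1, 2, ] <- x
    eeg <- new("EpochedEEG", participant = "x", condition = "y", data = dat,
               srate = 50, t0 = 0, montage = montage(c("A", "B")))
    co <- multitaperCoeffs(eeg, 1, c(1, 20))
    expect_identical(co@coeffs[, , 1, ], co@coeffs[, , 2, ])
})

test_that("multitaper power satisfies Parseval against windowed variance (white noise)", {
    set.seed(12)
    srate <- 50; n <- 250; ntr <- 100
    dat <- array(rnorm(ntr * n), dim = c(ntr, 1, n))
    eeg <- new("EpochedEEG", participant = "x", condition = "y", data = dat,
               srate = srate, t0 = 0, montage = montage("Fz"))
    co <- multitaperCoeffs(eeg, 1, c(0, srate / 2))
    w <- ifelse(co@freqs %in% c(0, srate / 2), 1, 2)   # one-sided doubling
    totalPower <- mean(apply(abs(co@coeffs[, , 1, ])^2, 1:2,
                             function(v) sum(v * w)))
    expect_equal(totalPower, mean(apply(dat[, 1, ], 1, var)),
                 tolerance = 0.05)
    # per trial/taper the identity is exact: tapered energy = summed power
    tap <- dpssTapers(n, 1 / srate, co@nTapers)
    x1 <- dat[1, 1, ] - mean(dat[1, 1, ])
    expect_equal(sum(abs(co@coeffs[1, 1, 1, ])^2 * w), sum((x1 * tap[, 1])^2),
                 tolerance = 1e-10)
    expect_error(multitaperCoeffs(eeg, 1, c(0, srate)), "Nyquist")
})

test_that("cross-spectra are Hermitian and match the hand-computed example", {
    co <- new("SpectralCoeffs", participant = "x", condition = "y",
              coeffs = array(c(1 + 0i, 0 - 1i), dim = c(1, 1, 2, 1)),
              freqs = 5, nTapers = 1L, windowSpan = 1, srate = 10,
              labels = c("A", "B"))
    cs <- crossSpectra(co, cbind("A", "B"))
    expect_equal(cs@obs[1, 1, 1], 0 + 1i)     # (1)(conj(0 - 1i)) = i
    csSwap <- crossSpectra(co, cbind("B", "A"))
    expect_equal(csSwap@obs[1, 1, 1], Conj(cs@obs[1, 1, 1]))
    auto <- crossSpectra(co, cbind("A", "A"))
    expect_equal(Im(auto@obs), array(0, dim(auto@obs)))
    expect_error(crossSpectra(co, cbind("A", "Q")), "unknown")
})

test_that("cross-spectral Hermitian symmetry holds exactly on simulated data", {
    mont <- miniMontage(3)
    coh <- sampleCohort(2, seed = 3)
    des <- quickDesign(trials = 3, srate = 100)
    eps <- simulateParticipant(coh[1, ], list(), des, mont, seed = 2)
    co <- multitaperCoeffs(selectWindow(eps$NatNeutral), 2, c(1, 20))
    ab <- crossSpectra(co, cbind("Fz", "Cz"))
    ba <- crossSpectra(co, cbind("Cz", "Fz"))
    expect_identical(ab@obs, Conj(ba@obs))
    expect_equal(nObs(ab), 3L * 13L)
})
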
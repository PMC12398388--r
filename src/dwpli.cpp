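#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Band-averaged debiased wPLI from multitaper coefficients.
//
// coeffs: complex vector with dim (nobs, nch, nbin) — pooled (trial, taper)
// observations.  pairs: npair x 2 matrix of 1-based channel indices.
// binGroups: list of integer vectors of 1-based bin indices per band.
//
// For each pair and bin the debiased estimator of squared wPLI is
//   ((sum Im)^2 - sum Im^2) / ((sum |Im|)^2 - sum Im^2)
// with Im the imaginary part of coeff(a) * conj(coeff(b)); bins whose
// denominator is zero (pure zero-lag) are NaN and excluded from the band
// mean, with their count reported.
// [[Rcpp::export]]
List cpp_band_dwpli(ComplexVector coeffs, IntegerVector dims,
                    IntegerMatrix pairs, List binGroups) {
    const int nobs = dims[0], nch = dims[1], nbin = dims[2];
    const int npair = pairs.nrow(), nband = binGroups.size();
    if ((R_xlen_t) nobs * nch * nbin != coeffs.size())
        stop("dims do not match coefficient array length");
    NumericMatrix values(npair, nband);
    IntegerMatrix nanCounts(npair, nband);
    const Rcomplex *c = COMPLEX(coeffs);

    for (int g = 0; g < nband; ++g) {
        IntegerVector bins = binGroups[g];
        for (int p = 0; p < npair; ++p) {
            const int ia = pairs(p, 0) - 1, ib = pairs(p, 1) - 1;
            if (ia < 0 || ia >= nch || ib < 0 || ib >= nch)
                stop("pair index out of range");
            double acc = 0.0;
            int used = 0, undef = 0;
            for (int bi = 0; bi < bins.size(); ++bi) {
                const int b = bins[bi] - 1;
                if (b < 0 || b >= nbin) stop("bin index out of range");
                const Rcomplex *ca = c + (R_xlen_t) nobs * (ia + (R_xlen_t) nch * b);
                const Rcomplex *cb = c + (R_xlen_t) nobs * (ib + (R_xlen_t) nch * b);
                double sIm = 0.0, sIm2 = 0.0, sAbs = 0.0;
                for (int o = 0; o < nobs; ++o) {
                    const double im = ca[o].i * cb[o].r - ca[o].r * cb[o].i;
                    sIm += im;
                    sIm2 += im * im;
                    sAbs += std::fabs(im);
                }
                const double den = sAbs * sAbs - sIm2;
                if (den == 0.0) {
                    ++undef;
                } else {
                    acc += (sIm * sIm - sIm2) / den;
                    ++used;
                }
            }
            values(p, g) = used > 0 ? acc / used : R_NaN;
            nanCounts(p, g) = undef;
        }
    }
    return List::create(_["values"] = values, _["nanCounts"] = nanCounts);
}
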
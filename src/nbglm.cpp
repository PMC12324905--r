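// Negative-binomial GLM fitting for ASV count matrices.
//
// One IRLS (Fisher scoring) fit per ASV row, log link with offsets, fixed
// per-ASV dispersion phi (variance = mu + phi mu^2). Returns coefficients,
// log-likelihood, deviance, convergence flags and the Cox-Reid adjustment
// 0.5 * log det(X' W X) used by the adjusted profile likelihood.
// Counts may be non-integer (prior-count augmented); all likelihood terms
// use lgamma and remain valid.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double MU_MIN = 1e-10;

static double nb_loglik(const arma::vec& y, const arma::vec& mu, double phi) {
    double ll = 0.0;
    if (phi < 1e-10) {
        for (arma::uword i = 0; i < y.n_elem; ++i)
            ll += y[i] * std::log(mu[i]) - mu[i] - std::lgamma(y[i] + 1.0);
        return ll;
    }
    const double a = 1.0 / phi;
    for (arma::uword i = 0; i < y.n_elem; ++i) {
        double m = std::max(mu[i], MU_MIN);
        ll += std::lgamma(y[i] + a) - std::lgamma(a) - std::lgamma(y[i] + 1.0)
            + y[i] * std::log(phi * m / (1.0 + phi * m))
            - a * std::log1p(phi * m);
    }
    return ll;
}

static double nb_deviance(const arma::vec& y, const arma::vec& mu, double phi) {
    double dev = 0.0;
    if (phi < 1e-10) {
        for (arma::uword i = 0; i < y.n_elem; ++i) {
            double t = (y[i] > 0) ? y[i] * std::log(y[i] / mu[i]) : 0.0;
            dev += 2.0 * (t - (y[i] - mu[i]));
        }
        return dev;
    }
    const double a = 1.0 / phi;
    for (arma::uword i = 0; i < y.n_elem; ++i) {
        double m = std::max(mu[i], MU_MIN);
        double t = (y[i] > 0) ? y[i] * std::log(y[i] / m) : 0.0;
        dev += 2.0 * (t - (y[i] + a) *
                      std::log((1.0 + phi * y[i]) / (1.0 + phi * m)));
    }
    return dev;
}

// [[Rcpp::export(name = ".nbglm_fit_cpp")]]
List nbglm_fit_cpp(const arma::mat& counts, const arma::mat& X,
                   const arma::vec& offset, const arma::vec& phi,
                   int maxit = 50, double tol = 1e-8) {
    const arma::uword G = counts.n_rows, n = counts.n_cols,
                      p = X.n_cols;
    if (offset.n_elem != n) stop("offset length mismatch");
    if (phi.n_elem != G && phi.n_elem != 1) stop("phi length mismatch");

    arma::mat beta(G, p, arma::fill::zeros);
    arma::vec loglik(G), deviance(G), cr_adj(G);
    LogicalVector converged(G);

    for (arma::uword g = 0; g < G; ++g) {
        arma::vec y = counts.row(g).t();
        double ph = (phi.n_elem == 1) ? phi[0] : phi[g];

        // init: LS regression of log((y + 0.5) / exp(offset)) on X
        arma::vec z0 = arma::log(y + 0.5) - offset;
        arma::vec b = arma::solve(X.t() * X, X.t() * z0);

        arma::vec eta = X * b + offset;
        arma::vec mu = arma::clamp(arma::exp(eta), MU_MIN,
                                   arma::datum::inf);
        double dev = nb_deviance(y, mu, ph);
        bool conv = false;
        arma::mat XtWX(p, p, arma::fill::zeros);

        for (int it = 0; it < maxit; ++it) {
            arma::vec w = mu / (1.0 + ph * mu);
            arma::vec z = (eta - offset) + (y - mu) / mu;
            arma::mat Xw = X.each_col() % w;
            XtWX = X.t() * Xw;
            arma::vec bNew;
            bool ok = arma::solve(bNew, XtWX, X.t() * (w % z));
            if (!ok || !bNew.is_finite()) break;

            // step halving if the deviance fails to decrease
            double devNew = arma::datum::inf;
            arma::vec bTry = bNew;
            for (int h = 0; h < 10; ++h) {
                arma::vec etaTry = X * bTry + offset;
                arma::vec muTry = arma::clamp(arma::exp(etaTry), MU_MIN,
                                              arma::datum::inf);
                devNew = nb_deviance(y, muTry, ph);
                if (std::isfinite(devNew) && devNew <= dev + 1e-10) {
                    eta = etaTry; mu = muTry; break;
                }
                bTry = 0.5 * (bTry + b);
            }
            if (!std::isfinite(devNew)) break;
            b = bTry;
            if (std::fabs(dev - devNew) / (std::fabs(devNew) + 0.1) < tol) {
                dev = devNew; conv = true; break;
            }
            dev = devNew;
        }
        // final weights for the Cox-Reid adjustment
        arma::vec w = mu / (1.0 + ph * mu);
        XtWX = X.t() * (X.each_col() % w);
        double val, sign;
        arma::log_det(val, sign, XtWX);
        cr_adj[g] = (sign > 0) ? 0.5 * val : arma::datum::nan;

        beta.row(g) = b.t();
        loglik[g] = nb_loglik(y, mu, ph);
        deviance[g] = dev;
        converged[g] = conv;
    }
    return List::create(_["beta"] = beta, _["loglik"] = loglik,
                        _["deviance"] = deviance, _["converged"] = converged,
                        _["cr_adj"] = cr_adj);
}
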
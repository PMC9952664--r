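#include <Rcpp.h>
using namespace Rcpp;

// BayesC Gibbs sampler: spike-and-slab marker effects with a common slab
// variance and fixed prior inclusion probability (1 - pi0). The residual
// vector is updated incrementally; SNPs are visited in map order so chains
// are reproducible under R's RNG.
//
// X must be column-centred; W holds fixed-effect covariates (intercept
// included). Variances follow scaled-inverse-chi-square full conditionals.
// [[Rcpp::export]]
List bayesc_gibbs(const NumericMatrix& X, const NumericVector& y,
                  const NumericMatrix& W, double pi0,
                  int nIter, int nBurnin, int thin,
                  double nuB, double scaleB, double nuE, double scaleE,
                  double sigmaB2Start, double sigmaE2Start) {
  const int n = X.nrow(), M = X.ncol(), C = W.ncol();
  if (y.size() != n) stop("y length mismatch");
  if (W.nrow() != n) stop("W row mismatch");
  if (nBurnin >= nIter) stop("nBurnin must be below nIter");

  std::vector<double> xtx(M), wtw(C);
  for (int j = 0; j < M; ++j) {
    double s = 0; for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  for (int k = 0; k < C; ++k) {
    double s = 0; for (int i = 0; i < n; ++i) s += W(i, k) * W(i, k);
    wtw[k] = s;
    if (wtw[k] <= 0) stop("zero-variance covariate column");
  }

  std::vector<double> beta(M, 0.0), alpha(C, 0.0), e(y.begin(), y.end());
  std::vector<int> delta(M, 0);
  double sigmaB2 = sigmaB2Start, sigmaE2 = sigmaE2Start;
  const double sigmaE2Floor = 1e-10;
  const double logPriorOdds = std::log((1.0 - pi0) / pi0);

  const int nKeep = (nIter - nBurnin + thin - 1) / thin;
  NumericMatrix betaSamples(nKeep, M);
  NumericVector sigB2Trace(nKeep), sigE2Trace(nKeep), sizeTrace(nKeep);
  NumericMatrix alphaSamples(nKeep, C);
  std::vector<double> betaSum(M, 0.0);
  std::vector<double> inclSum(M, 0.0);
  int kept = 0;

  for (int it = 0; it < nIter; ++it) {
    // fixed effects, coordinate-wise Gaussian updates (flat prior)
    for (int k = 0; k < C; ++k) {
      double rhs = 0;
      for (int i = 0; i < n; ++i) rhs += W(i, k) * e[i];
      rhs += wtw[k] * alpha[k];
      double mean = rhs / wtw[k];
      double newA = R::rnorm(mean, std::sqrt(sigmaE2 / wtw[k]));
      double diff = alpha[k] - newA;
      if (diff != 0) for (int i = 0; i < n; ++i) e[i] += W(i, k) * diff;
      alpha[k] = newA;
    }

    // marker effects with inclusion indicators, map order
    int mIn = 0;
    double betaSS = 0;
    for (int j = 0; j < M; ++j) {
      double cjj = xtx[j];
      if (cjj <= 0) { delta[j] = 0; beta[j] = 0; continue; }
      double r = cjj * beta[j];
      for (int i = 0; i < n; ++i) r += X(i, j) * e[i];
      // marginal likelihood ratio of r with beta_j integrated out;
      // pi0 = 0 keeps every SNP in the model (ridge/SNP-BLUP limit)
      double pIn;
      if (pi0 <= 0.0) {
        pIn = 1.0;
      } else {
        double v0 = cjj * sigmaE2;
        double v1 = cjj * cjj * sigmaB2 + cjj * sigmaE2;
        double logOdds = logPriorOdds + 0.5 * (std::log(v0) - std::log(v1)) +
                         0.5 * r * r * (1.0 / v0 - 1.0 / v1);
        if (!std::isfinite(logOdds))
          stop("non-finite full conditional at iteration %d, SNP %d", it + 1, j + 1);
        pIn = 1.0 / (1.0 + std::exp(-logOdds));
      }
      double oldBeta = beta[j];
      if (R::runif(0.0, 1.0) < pIn) {
        double cc = cjj + sigmaE2 / sigmaB2;
        double newBeta = R::rnorm(r / cc, std::sqrt(sigmaE2 / cc));
        delta[j] = 1; beta[j] = newBeta;
        ++mIn; betaSS += newBeta * newBeta;
      } else {
        delta[j] = 0; beta[j] = 0;
      }
      double diff = oldBeta - beta[j];
      if (diff != 0) for (int i = 0; i < n; ++i) e[i] += X(i, j) * diff;
    }

    // slab variance
    sigmaB2 = (betaSS + nuB * scaleB) / R::rchisq(nuB + mIn);
    // residual variance
    double ess = 0;
    for (int i = 0; i < n; ++i) ess += e[i] * e[i];
    sigmaE2 = (ess + nuE * scaleE) / R::rchisq(nuE + n);
    if (sigmaE2 < sigmaE2Floor) sigmaE2 = sigmaE2Floor;
    if (!std::isfinite(sigmaB2) || !std::isfinite(sigmaE2))
      stop("non-finite variance component at iteration %d", it + 1);

    if (it >= nBurnin && (it - nBurnin) % thin == 0) {
      for (int j = 0; j < M; ++j) {
        betaSamples(kept, j) = beta[j];
        betaSum[j] += beta[j];
        inclSum[j] += delta[j];
      }
      for (int k = 0; k < C; ++k) alphaSamples(kept, k) = alpha[k];
      sigB2Trace[kept] = sigmaB2;
      sigE2Trace[kept] = sigmaE2;
      sizeTrace[kept] = mIn;
      ++kept;
    }
  }

  NumericVector postMean(M), pip(M);
  for (int j = 0; j < M; ++j) {
    postMean[j] = betaSum[j] / kept;
    pip[j] = inclSum[j] / kept;
  }
  return List::create(
    _["betaSamples"] = betaSamples,
    _["alphaSamples"] = alphaSamples,
    _["sigmaB2"] = sigB2Trace,
    _["sigmaE2"] = sigE2Trace,
    _["modelSize"] = sizeTrace,
    _["postMeanBeta"] = postMean,
    _["pip"] = pip,
    _["nKept"] = kept);
}
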
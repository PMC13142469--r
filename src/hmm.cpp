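#include <Rcpp.h>
using namespace Rcpp;

// Two-state (farmer / hunter-gatherer) scaled forward-backward over one
// chromosome for a batch of haplotypes. State order: F = farmer,
// H = hunter-gatherer. Inputs are sites x haplotypes so that one
// haplotype's track is contiguous in memory. stayF/stayH are the
// per-interval probabilities of NOT switching out of the state between
// adjacent sites (length S - 1). Returns the per-site posterior of the
// hunter-gatherer state (sites x haplotypes) and per-haplotype
// log-likelihoods.

static void fb_one(const double* eF, const double* eH, int S,
                   const double* stayF, const double* stayH,
                   double priorH, double* postH, double* loglik) {
  std::vector<double> aF(S), aH(S), sc(S);
  double vF = (1.0 - priorH) * eF[0];
  double vH = priorH * eH[0];
  double c = vF + vH;
  aF[0] = vF / c; aH[0] = vH / c; sc[0] = c;
  for (int s = 1; s < S; ++s) {
    double pF = aF[s - 1] * stayF[s - 1] + aH[s - 1] * (1.0 - stayH[s - 1]);
    double pH = aF[s - 1] * (1.0 - stayF[s - 1]) + aH[s - 1] * stayH[s - 1];
    vF = pF * eF[s];
    vH = pH * eH[s];
    c = vF + vH;
    aF[s] = vF / c; aH[s] = vH / c; sc[s] = c;
  }
  double bF = 1.0, bH = 1.0;
  postH[S - 1] = aH[S - 1];
  for (int s = S - 2; s >= 0; --s) {
    double bFn = bF * eF[s + 1];
    double bHn = bH * eH[s + 1];
    double nF = (stayF[s] * bFn + (1.0 - stayF[s]) * bHn) / sc[s + 1];
    double nH = ((1.0 - stayH[s]) * bFn + stayH[s] * bHn) / sc[s + 1];
    bF = nF; bH = nH;
    double num = aH[s] * bH;
    postH[s] = num / (aF[s] * bF + num);
  }
  double ll = 0.0;
  for (int s = 0; s < S; ++s) ll += std::log(sc[s]);
  *loglik = ll;
}

// [[Rcpp::export]]
List hmm_fb_genotype(IntegerMatrix allelesT, NumericVector fH, NumericVector fF,
                     NumericVector stayF, NumericVector stayH, double priorH) {
  const int S = allelesT.nrow();
  const int Hn = allelesT.ncol();
  NumericMatrix post(S, Hn);
  NumericVector loglik(Hn);
  std::vector<double> eF(S), eH(S);
  for (int h = 0; h < Hn; ++h) {
    const int* col = &allelesT(0, h);
    for (int s = 0; s < S; ++s) {
      int g = col[s];
      if (g == NA_INTEGER) { eF[s] = 1.0; eH[s] = 1.0; }
      else if (g == 1)     { eF[s] = fF[s]; eH[s] = fH[s]; }
      else                 { eF[s] = 1.0 - fF[s]; eH[s] = 1.0 - fH[s]; }
    }
    double ll;
    fb_one(eF.data(), eH.data(), S, REAL(stayF), REAL(stayH), priorH,
           &post(0, h), &ll);
    loglik[h] = ll;
  }
  return List::create(_["posterior"] = post, _["loglik"] = loglik);
}

// Emission-matrix variant (read-count or other custom emission models):
// emisF / emisH are sites x haplotypes likelihoods P(obs | state).
// [[Rcpp::export]]
List hmm_fb_emission(NumericMatrix emisF, NumericMatrix emisH,
                     NumericVector stayF, NumericVector stayH, double priorH) {
  const int S = emisF.nrow();
  const int Hn = emisF.ncol();
  NumericMatrix post(S, Hn);
  NumericVector loglik(Hn);
  for (int h = 0; h < Hn; ++h) {
    double ll;
    fb_one(&emisF(0, h), &emisH(0, h), S, REAL(stayF), REAL(stayH), priorH,
           &post(0, h), &ll);
    loglik[h] = ll;
  }
  return List::create(_["posterior"] = post, _["loglik"] = loglik);
}
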
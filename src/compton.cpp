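#include <Rcpp.h>
#include "compton.h"
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_sample_compton(double E, int n) {
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double c = kn_sample_cost(E);
    out(i, 0) = c;
    out(i, 1) = compton_eprime(E, c);
  }
  colnames(out) = CharacterVector::create("cos_theta", "energy_keV");
  return out;
}

// [[Rcpp::export]]
double cpp_kn_f(double E, double cost) { return kn_f(E, cost); }

// [[Rcpp::export]]
double cpp_kn_total(double E) { return kn_total(E); }

// [[Rcpp::export]]
double cpp_window_prob(double E, double lo, double hi, double eres140) {
  return window_prob(E, lo, hi, eres140);
}
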
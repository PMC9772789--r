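#include <Rcpp.h>
using namespace Rcpp;

// Harrell's C over comparable pairs (i,j): t_i < t_j and event_i == 1.
// Concordant when lp_i > lp_j; tied predictors receive half credit.
// [[Rcpp::export(name = ".harrellC_cpp")]]
NumericVector harrellC_cpp(NumericVector lp, NumericVector time,
                           IntegerVector event) {
  const R_xlen_t n = lp.size();
  double conc = 0.0, comparable = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (event[i] != 1) continue;
    const double ti = time[i], li = lp[i];
    for (R_xlen_t j = 0; j < n; ++j) {
      if (time[j] <= ti) continue;
      comparable += 1.0;
      if (li > lp[j]) conc += 1.0;
      else if (li == lp[j]) conc += 0.5;
    }
  }
  return NumericVector::create(conc, comparable);
}
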
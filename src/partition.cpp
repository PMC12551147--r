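#include <Rcpp.h>
using namespace Rcpp;

// McCaskill-style partition function over pseudoknot-free secondary
// structures with a per-pair energy model and an optional stacking bonus
// added when a pair sits directly inside another ((i,j) and (i+1,j-1)).
//
// Q(i,j)  = partition function of subsequence [i,j] (empty structure = 1)
// Qb(i,j) = partition function of [i,j] given that i pairs with j
//
// Qb(i,j) = B(i,j) * ( Q(i+1,j-1) + (Bs - 1) * Qb(i+1,j-1) )
// Q(i,j)  = Q(i,j-1) + sum_k Q(i,k-1) * Qb(k,j)
//
// where B(i,j) = exp(-E_pair/RT), Bs = exp(-E_stack/RT). The (Bs - 1) term
// upgrades the already-counted stacked configuration inside Q(i+1,j-1).

static inline int base_index(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'U': case 'u': case 'T': case 't': return 3;
    default: return -1;
  }
}

// [[Rcpp::export]]
NumericVector partition_function_cpp(CharacterVector seqs, double e_gc,
                                     double e_au, double e_gu, double e_stack,
                                     int min_loop, double rt, bool allow_gu) {
  if (rt <= 0) stop("RT must be positive");
  if (min_loop < 3) stop("minimum hairpin loop must be >= 3");
  double B[4][4] = {{0}};
  const double bgc = std::exp(-e_gc / rt);
  const double bau = std::exp(-e_au / rt);
  const double bgu = std::exp(-e_gu / rt);
  B[2][1] = B[1][2] = bgc;                      // G-C
  B[0][3] = B[3][0] = bau;                      // A-U
  if (allow_gu) B[2][3] = B[3][2] = bgu;        // G-U wobble
  const double bs = std::exp(-e_stack / rt);

  const int m = seqs.size();
  NumericVector z(m);
  for (int s = 0; s < m; ++s) {
    std::string seq = as<std::string>(seqs[s]);
    const int n = seq.size();
    std::vector<int> b(n);
    for (int i = 0; i < n; ++i) {
      b[i] = base_index(seq[i]);
      if (b[i] < 0) stop("invalid character '%s' in sequence %d",
                         std::string(1, seq[i]), s + 1);
    }
    if (n < min_loop + 2) { z[s] = 1.0; continue; }
    std::vector<double> Q(n * n, 1.0), Qb(n * n, 0.0);
    // Q over spans shorter than min_loop+2 is 1 (no pair fits); initialized.
    for (int span = min_loop + 1; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        const int j = i + span;
        double pb = B[b[i]][b[j]];
        if (pb > 0.0) {
          double inner = (span >= min_loop + 3) ? Q[(i + 1) * n + (j - 1)] : 1.0;
          double qbin = (span >= min_loop + 3) ? Qb[(i + 1) * n + (j - 1)] : 0.0;
          Qb[i * n + j] = pb * (inner + (bs - 1.0) * qbin);
        }
        double q = Q[i * n + (j - 1)];
        for (int k = i; k <= j - min_loop - 1; ++k) {
          double qb = Qb[k * n + j];
          if (qb > 0.0) q += (k > i ? Q[i * n + (k - 1)] : 1.0) * qb;
        }
        Q[i * n + j] = q;
      }
    }
    z[s] = Q[n - 1];  // Q(0, n-1)
  }
  return z;
}
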
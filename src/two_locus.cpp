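#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Monte-Carlo two-locus coalescent configurations (Hudson model).
//
// Simulates, backward in time, the genealogy of two linked loci separated by
// scaled recombination rate rho for a sample of n haplotypes. Lineages carry
// a set of sampled descendants per locus (bitmask); coalescence occurs at
// rate k(k-1)/2 among the k active lineages and recombination at rate rho/2
// per lineage ancestral at both loci (splitting it into one-locus pieces).
// Material that reaches its locus MRCA is dropped. One mutation is placed
// per locus, uniformly over the branch length subtending 1..n-1 samples
// (i.e. conditional on the locus segregating), via streaming weighted
// reservoir sampling over lineage lifetimes. Returns the derived-allele
// joint counts (n00, n01, n10, n11) per replicate.
//
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix cpp_two_locus_configs(int n, double rho, int reps) {
  if (n < 2 || n > 62) stop("n must be between 2 and 62");
  if (rho < 0) stop("rho must be >= 0");
  IntegerMatrix out(reps, 4);
  const uint64_t full = (1ULL << n) - 1ULL;
  std::vector<uint64_t> A(2 * n + 4), B(2 * n + 4);

  for (int r = 0; r < reps; ++r) {
    int k = n;
    if ((int)A.size() < 2 * n + 4) { A.resize(2 * n + 4); B.resize(2 * n + 4); }
    for (int i = 0; i < n; ++i) { A[i] = 1ULL << i; B[i] = 1ULL << i; }
    double WA = 0.0, WB = 0.0;
    uint64_t mA = 0, mB = 0;

    while (true) {
      int nboth = 0, nA = 0, nB = 0;
      for (int i = 0; i < k; ++i) {
        if (A[i]) ++nA;
        if (B[i]) ++nB;
        if (A[i] && B[i]) ++nboth;
      }
      if (nA == 0 && nB == 0) break;
      double cr = k * (k - 1) / 2.0;
      double rr = rho / 2.0 * nboth;
      double tot = cr + rr;
      double dt = R::exp_rand() / tot;

      // accumulate mutation-placement weights over this interval
      for (int i = 0; i < k; ++i) {
        int pa = __builtin_popcountll(A[i]);
        if (pa >= 1 && pa < n) {
          WA += dt;
          if (R::unif_rand() * WA < dt) mA = A[i];
        }
        int pb = __builtin_popcountll(B[i]);
        if (pb >= 1 && pb < n) {
          WB += dt;
          if (R::unif_rand() * WB < dt) mB = B[i];
        }
      }

      if (R::unif_rand() * tot < cr) {
        // coalescence of a random pair
        int i = (int)(R::unif_rand() * k); if (i == k) i = k - 1;
        int j = (int)(R::unif_rand() * (k - 1)); if (j == k - 1) j = k - 2;
        if (j >= i) ++j;
        uint64_t na = A[i] | A[j], nb = B[i] | B[j];
        if (na == full) na = 0;  // locus A fixed on this lineage
        if (nb == full) nb = 0;
        A[i] = na; B[i] = nb;
        --k;
        A[j] = A[k]; B[j] = B[k];
        int mi = (i == k) ? j : i;  // merged slot after the swap
        if (A[mi] == 0 && B[mi] == 0) { --k; A[mi] = A[k]; B[mi] = B[k]; }
      } else {
        // recombination on a random both-locus lineage
        int pick = (int)(R::unif_rand() * nboth); if (pick == nboth) pick = nboth - 1;
        int idx = -1;
        for (int i = 0; i < k; ++i) {
          if (A[i] && B[i] && ++idx == pick) { idx = i; break; }
        }
        if ((int)A.size() < k + 1) { A.resize(k + 8); B.resize(k + 8); }
        A[k] = 0; B[k] = B[idx];
        B[idx] = 0;
        ++k;
      }
    }

    int n11 = __builtin_popcountll(mA & mB);
    int n10 = __builtin_popcountll(mA & ~mB & full);
    int n01 = __builtin_popcountll(~mA & mB & full);
    out(r, 0) = n - n11 - n10 - n01;
    out(r, 1) = n01;
    out(r, 2) = n10;
    out(r, 3) = n11;
  }
  return out;
}
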
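#include <Rcpp.h>
using namespace Rcpp;

// uniform integer in [0, n): same construction as the R reference
// (floor(runif(1) * n) clamped), so seeded runs agree bit-for-bit
static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// total payoff of node i over all its games in both layers; summation order
// matches total_payoff() in R (pair edges in adjacency order, then
// triangles with partners in stored order)
static inline double node_payoff(int i, const int *sp, const int *st,
                                 const int *padj, const int *poff,
                                 const int *tpart, const int *toff,
                                 const double *pay) {
  // pay: [0]=R_pair [1]=S_pair [2]=T_pair [3]=P_pair
  //      [4]=R_tri  [5]=G_tri  [6]=S_tri  [7]=T_tri [8]=W_tri [9]=P_tri
  double tot = 0.0;
  const int si = sp[i];
  for (int e = poff[i]; e < poff[i + 1]; ++e) {
    const int sj = sp[padj[e]];
    tot += si ? (sj ? pay[0] : pay[1]) : (sj ? pay[2] : pay[3]);
  }
  const int ti = st[i];
  for (int e = toff[i]; e < toff[i + 1]; e += 2) {
    const int nc = st[tpart[e]] + st[tpart[e + 1]];
    tot += ti ? (nc == 2 ? pay[4] : (nc == 1 ? pay[5] : pay[6]))
              : (nc == 2 ? pay[7] : (nc == 1 ? pay[8] : pay[9]));
  }
  return tot;
}

// n_updates elementary imitation updates. vector_mode: focal/model draw,
// payoffs, Fermi probability, then target-slot, source-order and acceptance
// draws (five draws per update with the union rule, six with the layer
// rule). scalar mode: focal, model, acceptance (s_tri_in is ignored).
// Returns fresh copies of the slot vectors plus acceptance counters.
// [[Rcpp::export]]
List hc_run_updates(int n_updates,
                    IntegerVector s_pair_in, IntegerVector s_tri_in,
                    IntegerVector padj, IntegerVector poff,
                    IntegerVector tpart, IntegerVector toff,
                    IntegerVector uadj, IntegerVector uoff,
                    IntegerVector tdadj, IntegerVector tdoff,
                    NumericVector pay, double w, double pswitch,
                    int vector_mode, int layer_rule) {
  const int n = poff.size() - 1;
  IntegerVector sp_out = clone(s_pair_in);
  IntegerVector st_out = vector_mode ? clone(s_tri_in) : sp_out;
  int *sp = INTEGER(sp_out);
  int *st = vector_mode ? INTEGER(st_out) : sp;
  const int *cpadj = INTEGER(padj), *cpoff = INTEGER(poff);
  const int *ctpart = INTEGER(tpart), *ctoff = INTEGER(toff);
  const int *cuadj = INTEGER(uadj), *cuoff = INTEGER(uoff);
  const int *ctd = INTEGER(tdadj), *ctdoff = INTEGER(tdoff);
  const double *cpay = REAL(pay);

  long n_accepted = 0, n_cross = 0;
  for (int it = 0; it < n_updates; ++it) {
    const int f = runif_int(n);
    int m;
    if (layer_rule) {
      if (unif_rand() < 0.5) {
        const int deg = cpoff[f + 1] - cpoff[f];
        if (deg == 0) stop("node %d has no pairwise neighbours", f);
        m = cpadj[cpoff[f] + runif_int(deg)];
      } else {
        const int deg = ctdoff[f + 1] - ctdoff[f];
        if (deg == 0) stop("node %d has no triangle partners", f);
        m = ctd[ctdoff[f] + runif_int(deg)];
      }
    } else {
      const int deg = cuoff[f + 1] - cuoff[f];
      if (deg == 0) stop("node %d has no co-players", f);
      m = cuadj[cuoff[f] + runif_int(deg)];
    }
    const double pf = node_payoff(f, sp, st, cpadj, cpoff, ctpart, ctoff, cpay);
    const double pm = node_payoff(m, sp, st, cpadj, cpoff, ctpart, ctoff, cpay);
    const double pi_t = 1.0 / (1.0 + exp(-w * (pm - pf)));
    if (vector_mode) {
      const bool target_pair = unif_rand() < 0.5;
      const bool cross = unif_rand() < pswitch;
      const bool accepted = unif_rand() < pi_t;
      if (accepted) {
        // source is the other order iff cross
        const bool source_tri = (target_pair == cross);
        const int val = source_tri ? st[m] : sp[m];
        if (target_pair) sp[f] = val; else st[f] = val;
        ++n_accepted;
        if (cross) ++n_cross;
      }
    } else {
      const bool accepted = unif_rand() < pi_t;
      if (accepted) {
        sp[f] = sp[m];
        ++n_accepted;
      }
    }
  }
  return List::create(_["pair"] = sp_out,
                      _["tri"] = vector_mode ? st_out : sp_out,
                      _["n_accepted"] = (double)n_accepted,
                      _["n_cross_accepted"] = (double)n_cross);
}
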
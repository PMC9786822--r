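// Exact path-dependent TreeSHAP for a parsed tree ensemble.
// Implements the polynomial-time path algorithm (EXTEND / UNWIND over the
// unique-feature path) with cover-weighted conditional expectations as the
// value function. The R-level brute-force subset enumeration serves as the
// independent oracle for this kernel in the test suite.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Tree {
  const int *feature;      // 1-based feature index, NA -> leaf
  const double *threshold;
  const int *yes, *no, *miss;   // 1-based row indices
  const double *value;
  const double *cover;
};

struct Path {
  std::vector<int> d;
  std::vector<double> z, o, w;
};

void extend(Path &p, double pz, double po, int pi) {
  int l = p.d.size();
  p.d.push_back(pi); p.z.push_back(pz); p.o.push_back(po);
  p.w.push_back(l == 0 ? 1.0 : 0.0);
  for (int i = l; i >= 1; --i) {
    p.w[i] += po * p.w[i - 1] * i / (l + 1.0);
    p.w[i - 1] = pz * p.w[i - 1] * (l + 1.0 - i) / (l + 1.0);
  }
}

void unwind(Path &p, int i) {   // i is 0-based position in the path
  int l = p.d.size();
  double n = p.w[l - 1];
  double o = p.o[i], z = p.z[i];
  for (int j = l - 2; j >= 0; --j) {
    if (o != 0) {
      double t = p.w[j];
      p.w[j] = n * l / ((j + 1.0) * o);
      n = t - p.w[j] * z * (l - 1.0 - j) / l;
    } else {
      p.w[j] = p.w[j] * l / (z * (l - 1.0 - j));
    }
  }
  p.d.erase(p.d.begin() + i);
  p.z.erase(p.z.begin() + i);
  p.o.erase(p.o.begin() + i);
  p.w.pop_back();
}

double unwound_sum(const Path &p, int i) {
  int l = p.d.size();
  double n = p.w[l - 1];
  double o = p.o[i], z = p.z[i], tot = 0.0;
  for (int j = l - 2; j >= 0; --j) {
    if (o != 0) {
      double t = n * l / ((j + 1.0) * o);
      tot += t;
      n = p.w[j] - t * z * (l - 1.0 - j) / l;
    } else {
      tot += p.w[j] * l / (z * (l - 1.0 - j));
    }
  }
  return tot;
}

void recurse(const Tree &tr, const double *x, int node, Path p,
             double pz, double po, int pi, double *phi) {
  extend(p, pz, po, pi);
  if (tr.feature[node] == NA_INTEGER) {           // leaf
    int l = p.d.size();
    for (int j = 1; j < l; ++j) {
      double w = unwound_sum(p, j);
      phi[p.d[j] - 1] += w * (p.o[j] - p.z[j]) * tr.value[node];
    }
    return;
  }
  int f = tr.feature[node];
  double v = x[f - 1];
  int yes = tr.yes[node] - 1, no = tr.no[node] - 1, miss = tr.miss[node] - 1;
  int hot, cold;
  if (ISNAN(v)) hot = miss;
  else if (v < tr.threshold[node]) hot = yes;
  else hot = no;
  cold = (hot == yes) ? no : yes;
  double iz = 1.0, io = 1.0;
  int k = -1;
  for (size_t q = 0; q < p.d.size(); ++q) if (p.d[q] == f) { k = q; break; }
  if (k >= 0) { iz = p.z[k]; io = p.o[k]; unwind(p, k); }
  recurse(tr, x, hot, p, iz * tr.cover[hot] / tr.cover[node], io, f, phi);
  recurse(tr, x, cold, p, iz * tr.cover[cold] / tr.cover[node], 0.0, f, phi);
}

Tree as_tree(const List &t) {
  Tree tr;
  tr.feature = INTEGER(VECTOR_ELT(t, 0));
  tr.threshold = REAL(VECTOR_ELT(t, 1));
  tr.yes = INTEGER(VECTOR_ELT(t, 2));
  tr.no = INTEGER(VECTOR_ELT(t, 3));
  tr.miss = INTEGER(VECTOR_ELT(t, 4));
  tr.value = REAL(VECTOR_ELT(t, 5));
  tr.cover = REAL(VECTOR_ELT(t, 6));
  return tr;
}

} // namespace

// [[Rcpp::export(name = ".treeshap_ensemble_cpp")]]
NumericMatrix treeshap_ensemble_cpp(List trees, NumericMatrix X, int nfeat) {
  int nr = X.nrow();
  NumericMatrix out(nr, nfeat);
  int nt = trees.size();
  std::vector<Tree> tv;
  tv.reserve(nt);
  for (int t = 0; t < nt; ++t) tv.push_back(as_tree(trees[t]));
  std::vector<double> x(X.ncol());
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < X.ncol(); ++c) x[c] = X(r, c);
    double *phi = &out(r, 0);
    // NumericMatrix is column-major; accumulate into a row buffer instead
    std::vector<double> buf(nfeat, 0.0);
    for (int t = 0; t < nt; ++t) {
      Path p;
      recurse(tv[t], x.data(), 0, p, 1.0, 1.0, 0, buf.data());
    }
    for (int c = 0; c < nfeat; ++c) out(r, c) = buf[c];
    (void)phi;
  }
  return out;
}
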
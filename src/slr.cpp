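// Core numerics for structured logistic regression over sequences.
//
// The model is f(x) = bias + sum_j w_j * I(s_j substring of x) with
// P(y = +1 | x) = sigmoid(f(x)).  Training maximizes the log-likelihood
// sum_i log sigmoid(y_i f(x_i)) by coordinate-wise ascent: at each step the
// substring with the largest absolute likelihood gradient is located by a
// length-increasing expansion over the substring lattice with an
// anti-monotone pruning bound, and its weight is set by a bisection line
// search along that coordinate.
//
// Occurrence lists are static during training (only the per-document
// sigmoid weights change between iterations), so the first two lattice
// levels are built once per training run and reused by every search.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstring>
#include <string>
#include <unordered_map>
#include <utility>
#include <vector>

using namespace Rcpp;

static inline double sigmoid(double z) {
  if (z >= 0.0) return 1.0 / (1.0 + std::exp(-z));
  double e = std::exp(z);
  return e / (1.0 + e);
}

// log(sigmoid(z)) without overflow for any representable z
static inline double log_sigmoid(double z) {
  if (z >= 0.0) return -std::log1p(std::exp(-z));
  return z - std::log1p(std::exp(z));
}

static std::vector<std::string> as_corpus(const CharacterVector& seqs) {
  std::vector<std::string> out;
  out.reserve(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) out.push_back(as<std::string>(seqs[i]));
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_occurs(std::string subseq, CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  IntegerVector out(n);
  const char* pat = subseq.c_str();
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = (std::strstr(CHAR(STRING_ELT(seqs, i)), pat) != NULL) ? 1 : 0;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_decision_scores(CharacterVector predictors, NumericVector weights,
                                  double bias, CharacterVector seqs) {
  R_xlen_t n = seqs.size(), k = predictors.size();
  std::vector<std::string> preds(k);
  for (R_xlen_t j = 0; j < k; ++j) preds[j] = as<std::string>(predictors[j]);
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    double f = bias;
    // summation in predictor (selection) order so that persisted models
    // reproduce scores bit-exactly after a round trip
    for (R_xlen_t j = 0; j < k; ++j) {
      if (std::strstr(s, preds[j].c_str()) != NULL) f += weights[j];
    }
    out[i] = f;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_log_likelihood(NumericVector scores, IntegerVector labels) {
  double L = 0.0;
  for (R_xlen_t i = 0; i < scores.size(); ++i) {
    L += log_sigmoid((double)labels[i] * scores[i]);
  }
  return L;
}

// [[Rcpp::export]]
double cpp_coordinate_gradient(std::string subseq, CharacterVector seqs,
                               IntegerVector labels, NumericVector scores) {
  double g = 0.0;
  const char* pat = subseq.c_str();
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    if (std::strstr(CHAR(STRING_ELT(seqs, i)), pat) != NULL) {
      double y = (double)labels[i];
      g += y * sigmoid(-y * scores[i]);
    }
  }
  return g;
}

// [[Rcpp::export]]
double cpp_gradient_bound(std::string subseq, CharacterVector seqs,
                          IntegerVector labels, NumericVector scores) {
  double pos = 0.0, neg = 0.0;
  const char* pat = subseq.c_str();
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    if (std::strstr(CHAR(STRING_ELT(seqs, i)), pat) != NULL) {
      if (labels[i] > 0) pos += sigmoid(-scores[i]);
      else neg += sigmoid(scores[i]);
    }
  }
  return std::max(pos, neg);
}

// ---------------------------------------------------------------------------
// Substring-lattice search
// ---------------------------------------------------------------------------

typedef std::pair<int, int> OccEntry;  // (document, start position)

// lattice levels cached across the searches of one training run
#define CACHE_DEPTH 3

// reusable per-character buckets (single-threaded, never nested)
static std::vector<std::vector<OccEntry> >& scratch_buckets() {
  static std::vector<std::vector<OccEntry> > b(256);
  return b;
}

static std::vector<int> dedup_docs(const std::vector<OccEntry>& occ) {
  std::vector<int> docs;
  int last = -1;
  for (size_t u = 0; u < occ.size(); ++u) {
    if (occ[u].first != last) {
      last = occ[u].first;
      docs.push_back(last);
    }
  }
  return docs;
}

// Cached lattice node: a substring, its occurrence list (sorted by document
// by construction) and the distinct documents containing it.  Every
// substring of length L+1 is a one-character right-extension of a corpus
// substring of length L, so right-extension from single characters
// enumerates the whole substring universe; occurrence lists only shrink
// along extensions, which is what makes the pruning bound anti-monotone.
struct CNode {
  std::string s;
  std::vector<OccEntry> occ;
  std::vector<int> docs;
  std::vector<int> children;
  bool built;
};

struct Lattice {
  const std::vector<std::string>* seqs;
  std::vector<CNode> arena;
  std::vector<int> level1;

  void init(const std::vector<std::string>& s) {
    seqs = &s;
    std::vector<std::vector<OccEntry> > buckets(256);
    for (int d = 0; d < (int)s.size(); ++d) {
      const std::string& str = s[d];
      for (size_t p = 0; p < str.size(); ++p) {
        buckets[(unsigned char)str[p]].push_back(std::make_pair(d, (int)p));
      }
    }
    for (int c = 0; c < 256; ++c) {
      if (!buckets[c].empty()) {
        CNode nd;
        nd.s = std::string(1, (char)c);
        nd.occ = std::move(buckets[c]);
        nd.docs = dedup_docs(nd.occ);
        nd.built = false;
        level1.push_back((int)arena.size());
        arena.push_back(nd);
      }
    }
  }

  // build (once) the right-extensions of arena node `idx`
  void ensure_children(int idx) {
    if (arena[idx].built) return;
    std::string s = arena[idx].s;
    int len = (int)s.size();
    std::vector<std::vector<OccEntry> >& buckets = scratch_buckets();
    {
      const std::vector<OccEntry>& occ = arena[idx].occ;
      for (size_t u = 0; u < occ.size(); ++u) {
        int d = occ[u].first;
        size_t p = (size_t)occ[u].second;
        if (p + (size_t)len < (*seqs)[d].size()) {
          buckets[(unsigned char)(*seqs)[d][p + len]].push_back(occ[u]);
        }
      }
    }
    std::vector<int> kids;
    for (int c = 0; c < 256; ++c) {
      if (!buckets[c].empty()) {
        CNode child;
        child.s = s + (char)c;
        child.occ.swap(buckets[c]);
        child.docs = dedup_docs(child.occ);
        child.built = false;
        kids.push_back((int)arena.size());
        arena.push_back(child);  // may reallocate: no references held
      }
    }
    arena[idx].children = kids;
    arena[idx].built = true;
  }
};

struct SearchResult {
  std::string subseq;
  double gradient;
  int support;
  bool found;
  std::vector<int> docs;
};

// transient node for lattice levels beyond the cache
struct DynNode {
  std::string s;
  std::vector<OccEntry> occ;
};

static void expand_into(std::vector<DynNode>& out, const std::string& s,
                        const std::vector<OccEntry>& occ,
                        const std::vector<std::string>& seqs) {
  int len = (int)s.size();
  std::vector<std::vector<OccEntry> >& buckets = scratch_buckets();
  for (size_t u = 0; u < occ.size(); ++u) {
    int d = occ[u].first;
    size_t p = (size_t)occ[u].second;
    if (p + (size_t)len < seqs[d].size()) {
      buckets[(unsigned char)seqs[d][p + len]].push_back(occ[u]);
    }
  }
  for (int c = 0; c < 256; ++c) {
    if (!buckets[c].empty()) {
      DynNode child;
      child.s = s + (char)c;
      child.occ.swap(buckets[c]);
      out.push_back(std::move(child));
    }
  }
}

// Best-first is unnecessary: BFS by length with lexicographic node order
// makes the first maximal candidate the shortest lexicographically-smallest
// one, which is the documented deterministic tie-break.  Pruning uses
// mu <= best (with equality): an extension can at best tie, and ties go to
// the incumbent.
static SearchResult search_best(Lattice& lat, const std::vector<int>& labels,
                                const std::vector<double>& a,
                                int min_support, int min_len, int max_len) {
  SearchResult best;
  best.gradient = 0.0;
  best.support = 0;
  best.found = false;
  double best_abs = -1.0;

  std::vector<DynNode> dyn;
  std::vector<int> cur = lat.level1;
  for (int len = 1; len <= CACHE_DEPTH && !cur.empty(); ++len) {
    std::vector<int> nxt;
    for (size_t q = 0; q < cur.size(); ++q) {
      int id = cur[q];
      int support = (int)lat.arena[id].docs.size();
      if (support < min_support) continue;
      double P = 0.0, N = 0.0;
      {
        const std::vector<int>& docs = lat.arena[id].docs;
        for (size_t u = 0; u < docs.size(); ++u) {
          int d = docs[u];
          if (labels[d] > 0) P += a[d];
          else N += a[d];
        }
      }
      double g = P - N, mu = std::max(P, N);
      if (len >= min_len && std::fabs(g) > best_abs) {
        best_abs = std::fabs(g);
        best.subseq = lat.arena[id].s;
        best.gradient = g;
        best.support = support;
        best.found = true;
        best.docs = lat.arena[id].docs;
      }
      if (mu <= best_abs) continue;
      if (max_len > 0 && len >= max_len) continue;
      if (len < CACHE_DEPTH) {
        lat.ensure_children(id);
        const std::vector<int>& ch = lat.arena[id].children;
        nxt.insert(nxt.end(), ch.begin(), ch.end());
      } else {
        expand_into(dyn, lat.arena[id].s, lat.arena[id].occ, *lat.seqs);
      }
    }
    cur = nxt;
  }

  int len = CACHE_DEPTH + 1;
  std::vector<DynNode> level = std::move(dyn);
  while (!level.empty()) {
    std::vector<DynNode> next;
    for (size_t q = 0; q < level.size(); ++q) {
      DynNode& nd = level[q];
      double P = 0.0, N = 0.0;
      int support = 0, lastdoc = -1;
      for (size_t u = 0; u < nd.occ.size(); ++u) {
        int d = nd.occ[u].first;
        if (d != lastdoc) {
          lastdoc = d;
          ++support;
          if (labels[d] > 0) P += a[d];
          else N += a[d];
        }
      }
      if (support < min_support) continue;
      double g = P - N, mu = std::max(P, N);
      if (len >= min_len && std::fabs(g) > best_abs) {
        best_abs = std::fabs(g);
        best.subseq = nd.s;
        best.gradient = g;
        best.support = support;
        best.found = true;
        best.docs = dedup_docs(nd.occ);
      }
      if (mu <= best_abs) continue;
      if (max_len > 0 && len >= max_len) continue;
      expand_into(next, nd.s, nd.occ, *lat.seqs);
    }
    level = std::move(next);
    ++len;
  }
  return best;
}

static std::vector<double> contrib_weights(const std::vector<int>& labels,
                                           const std::vector<double>& scores) {
  std::vector<double> a(labels.size());
  for (size_t i = 0; i < labels.size(); ++i) {
    a[i] = sigmoid(-(double)labels[i] * scores[i]);
  }
  return a;
}

// [[Rcpp::export]]
List cpp_best_predictor(CharacterVector seqs, IntegerVector labels, NumericVector scores,
                        int min_support, int min_len, int max_len) {
  std::vector<std::string> corpus = as_corpus(seqs);
  std::vector<int> y(labels.begin(), labels.end());
  std::vector<double> f(scores.begin(), scores.end());
  Lattice lat;
  lat.init(corpus);
  SearchResult r = search_best(lat, y, contrib_weights(y, f), min_support,
                               min_len, max_len);
  return List::create(_["found"] = r.found, _["subseq"] = r.subseq,
                      _["gradient"] = r.gradient, _["support"] = r.support);
}

// ---------------------------------------------------------------------------
// Line search
// ---------------------------------------------------------------------------

struct LSResult {
  double weight;
  bool separation;
};

// derivative of the 1-D (optionally ridge-penalized) likelihood restriction
// at weight w0 + delta
static double dir_deriv(const std::vector<int>& docs, const std::vector<int>& labels,
                        const std::vector<double>& scores, double delta,
                        double w0 = 0.0, double lambda = 0.0) {
  double g = 0.0;
  for (size_t u = 0; u < docs.size(); ++u) {
    int d = docs[u];
    double y = (double)labels[d];
    g += y * sigmoid(-y * (scores[d] + delta));
  }
  return g - lambda * (w0 + delta);
}

// Concave 1-D maximization by bisection on the derivative sign over an
// expanding bracket.  The returned endpoint is the one reached from the
// current weight through a region of improving likelihood, so the ascent
// guarantee L(new) >= L(current) holds exactly, not just to tolerance.
static LSResult line_search_impl(const std::vector<int>& docs, const std::vector<int>& labels,
                                 const std::vector<double>& scores, double w0,
                                 double tol, double w_max, double lambda = 0.0) {
  LSResult r;
  r.weight = w0;
  r.separation = false;
  double g0 = dir_deriv(docs, labels, scores, 0.0, w0, lambda);
  if (g0 == 0.0) return r;
  if (g0 > 0.0) {
    double lo = w0, hi = w0, step = 1.0;
    for (;;) {
      hi = lo + step;
      if (hi >= w_max) {
        hi = w_max;
        if (dir_deriv(docs, labels, scores, hi - w0, w0, lambda) > 0.0) {
          r.weight = w_max;
          r.separation = true;
          return r;
        }
        break;
      }
      if (dir_deriv(docs, labels, scores, hi - w0, w0, lambda) <= 0.0) break;
      lo = hi;
      step *= 2.0;
    }
    while (hi - lo > tol) {
      double mid = 0.5 * (lo + hi);
      if (dir_deriv(docs, labels, scores, mid - w0, w0, lambda) > 0.0) lo = mid;
      else hi = mid;
    }
    r.weight = lo;
  } else {
    double hi = w0, lo = w0, step = 1.0;
    for (;;) {
      lo = hi - step;
      if (lo <= -w_max) {
        lo = -w_max;
        if (dir_deriv(docs, labels, scores, lo - w0, w0, lambda) < 0.0) {
          r.weight = -w_max;
          r.separation = true;
          return r;
        }
        break;
      }
      if (dir_deriv(docs, labels, scores, lo - w0, w0, lambda) >= 0.0) break;
      hi = lo;
      step *= 2.0;
    }
    while (hi - lo > tol) {
      double mid = 0.5 * (lo + hi);
      if (dir_deriv(docs, labels, scores, mid - w0, w0, lambda) < 0.0) hi = mid;
      else lo = mid;
    }
    r.weight = hi;
  }
  return r;
}

// [[Rcpp::export]]
List cpp_line_search(CharacterVector seqs, IntegerVector labels, NumericVector scores,
                     std::string subseq, double current_weight, double tol, double w_max,
                     double lambda) {
  std::vector<int> y(labels.begin(), labels.end());
  std::vector<double> f(scores.begin(), scores.end());
  std::vector<int> docs;
  const char* pat = subseq.c_str();
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    if (std::strstr(CHAR(STRING_ELT(seqs, i)), pat) != NULL) docs.push_back((int)i);
  }
  if (docs.empty()) stop("subseq occurs in no sequence");
  LSResult r = line_search_impl(docs, y, f, current_weight, tol, w_max, lambda);
  return List::create(_["weight"] = r.weight, _["separation"] = r.separation);
}

// ---------------------------------------------------------------------------
// Training loop
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_train(CharacterVector seqs_, IntegerVector labels_, int max_iters,
               double grad_tol, double loglik_rel_tol, int min_support, int min_len,
               int max_len, double line_tol, double w_max, int refresh_every,
               double lambda, bool fit_bias) {
  std::vector<std::string> seqs = as_corpus(seqs_);
  std::vector<int> labels(labels_.begin(), labels_.end());
  int n = (int)seqs.size();

  Lattice lat;
  lat.init(seqs);

  std::vector<double> scores(n, 0.0);
  double bias = 0.0;
  std::vector<int> all_docs(n);
  for (int i = 0; i < n; ++i) all_docs[i] = i;
  std::vector<std::string> preds;
  std::vector<double> weights;
  std::vector<std::vector<int> > pred_docs;  // occurrence docs per predictor
  std::unordered_map<std::string, int> index;

  std::vector<int> tr_iter;
  std::vector<std::string> tr_pred;
  std::vector<double> tr_grad, tr_weight, tr_loglik;

  double L = n * log_sigmoid(0.0);
  double obj = L;  // ridge-penalized objective; equals L when lambda = 0
  bool separation = false;
  std::string stop_reason = "max_iters";
  int iters_used = 0;

  for (int it = 1; it <= max_iters; ++it) {
    // best fresh candidate by data gradient (a new coordinate has weight 0,
    // so its penalized gradient equals its data gradient)
    SearchResult sr = search_best(lat, labels, contrib_weights(labels, scores),
                                  min_support, min_len, max_len);
    double best_g = sr.found ? sr.gradient : 0.0;
    int best_existing = -1;
    bool use_bias = false;
    if (fit_bias) {
      // the intercept is an always-on coordinate, never penalized; on equal
      // gradients it is preferred (it is the "shortest" feature)
      double g_bias = dir_deriv(all_docs, labels, scores, 0.0);
      if (std::fabs(g_bias) >= std::fabs(best_g)) {
        best_g = g_bias;
        use_bias = true;
      }
    }
    if (lambda > 0.0) {
      // under a penalty an already-selected coordinate can carry a larger
      // penalized gradient than any fresh candidate; check them explicitly
      for (size_t j = 0; j < preds.size(); ++j) {
        double g = dir_deriv(pred_docs[j], labels, scores, 0.0, weights[j],
                             lambda);
        if (std::fabs(g) > std::fabs(best_g)) {
          best_g = g;
          best_existing = (int)j;
          use_bias = false;
        }
      }
    }
    if (!sr.found && best_existing < 0 && !use_bias) {
      stop_reason = "no_candidate";
      break;
    }
    if (std::fabs(best_g) < grad_tol) { stop_reason = "gradient"; break; }

    std::string chosen;
    double w0 = 0.0;
    const std::vector<int>* docs_ptr;
    if (use_bias) {
      chosen = "<bias>";
      w0 = bias;
      docs_ptr = &all_docs;
    } else if (best_existing >= 0) {
      chosen = preds[best_existing];
      w0 = weights[best_existing];
      docs_ptr = &pred_docs[best_existing];
    } else {
      chosen = sr.subseq;
      std::unordered_map<std::string, int>::iterator itx = index.find(chosen);
      if (itx != index.end()) {
        w0 = weights[itx->second];
        best_existing = itx->second;
        docs_ptr = &pred_docs[itx->second];
      } else {
        docs_ptr = &sr.docs;
      }
    }
    LSResult ls = line_search_impl(*docs_ptr, labels, scores, w0, line_tol,
                                   w_max, use_bias ? 0.0 : lambda);
    if (ls.separation) separation = true;
    double delta = ls.weight - w0;
    if (use_bias) {
      bias = ls.weight;
    } else if (best_existing >= 0) {
      weights[best_existing] = ls.weight;  // re-selection updates in place
    } else {
      index[chosen] = (int)preds.size();
      preds.push_back(chosen);
      weights.push_back(ls.weight);
      pred_docs.push_back(sr.docs);
    }
    const std::vector<int>& docs = *docs_ptr;
    for (size_t u = 0; u < docs.size(); ++u) scores[docs[u]] += delta;
    iters_used = it;

    // periodic refresh guards against drift of the incremental score cache
    if (refresh_every > 0 && it % refresh_every == 0) {
      for (int i = 0; i < n; ++i) {
        const char* s = seqs[i].c_str();
        double f = bias;
        for (size_t j = 0; j < preds.size(); ++j) {
          if (std::strstr(s, preds[j].c_str()) != NULL) f += weights[j];
        }
        scores[i] = f;
      }
    }

    double Lnew = 0.0;
    for (int i = 0; i < n; ++i) Lnew += log_sigmoid((double)labels[i] * scores[i]);
    tr_iter.push_back(it);
    tr_pred.push_back(chosen);
    tr_grad.push_back(best_g);
    tr_weight.push_back(ls.weight);
    tr_loglik.push_back(Lnew);

    double obj_new = Lnew;
    if (lambda > 0.0) {
      double ss = 0.0;
      for (size_t j = 0; j < weights.size(); ++j) ss += weights[j] * weights[j];
      obj_new -= 0.5 * lambda * ss;
    }
    double rel = (obj_new - obj) / std::max(std::fabs(obj), 1e-12);
    obj = obj_new;
    L = Lnew;
    if (rel < loglik_rel_tol) { stop_reason = "loglik"; break; }
  }

  return List::create(
      _["predictors"] = wrap(preds), _["weights"] = wrap(weights),
      _["bias"] = bias, _["loglik"] = L, _["iterations"] = iters_used,
      _["stop_reason"] = stop_reason, _["separation"] = separation,
      _["trace"] = DataFrame::create(
          _["iteration"] = wrap(tr_iter), _["predictor"] = wrap(tr_pred),
          _["gradient"] = wrap(tr_grad), _["weight"] = wrap(tr_weight),
          _["loglik"] = wrap(tr_loglik), _["stringsAsFactors"] = false));
}
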
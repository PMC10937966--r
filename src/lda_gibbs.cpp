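#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation on a
// document-term count matrix. Documents are areas, terms are POI
// categories, tokens are individual POIs. Symmetric priors alpha (topics
// per document) and eta (terms per topic).
//
// [[Rcpp::export]]
List lda_gibbs(IntegerMatrix counts, int n_topics, double alpha, double eta,
               int n_iter, int seed) {
  int n_docs = counts.nrow();
  int n_terms = counts.ncol();

  // expand counts into token streams
  std::vector<int> doc_of, term_of;
  for (int d = 0; d < n_docs; ++d)
    for (int w = 0; w < n_terms; ++w)
      for (int c = 0; c < counts(d, w); ++c) {
        doc_of.push_back(d);
        term_of.push_back(w);
      }
  int n_tok = doc_of.size();

  IntegerMatrix ndk(n_docs, n_topics);   // topic counts per doc
  IntegerMatrix nkw(n_topics, n_terms);  // term counts per topic
  IntegerVector nk(n_topics);            // tokens per topic
  std::vector<int> z(n_tok);

  // deterministic xorshift RNG so results depend only on `seed`
  uint64_t state = (uint64_t)seed * 2654435761u + 1u;
  auto runif01 = [&]() {
    state ^= state << 13; state ^= state >> 7; state ^= state << 17;
    return (double)(state >> 11) / 9007199254740992.0;
  };

  for (int i = 0; i < n_tok; ++i) {
    int k = (int)(runif01() * n_topics);
    if (k >= n_topics) k = n_topics - 1;
    z[i] = k;
    ndk(doc_of[i], k)++; nkw(k, term_of[i])++; nk[k]++;
  }

  std::vector<double> prob(n_topics);
  for (int iter = 0; iter < n_iter; ++iter) {
    for (int i = 0; i < n_tok; ++i) {
      int d = doc_of[i], w = term_of[i], k = z[i];
      ndk(d, k)--; nkw(k, w)--; nk[k]--;
      double tot = 0.0;
      for (int t = 0; t < n_topics; ++t) {
        prob[t] = (ndk(d, t) + alpha) * (nkw(t, w) + eta) /
                  (nk[t] + n_terms * eta);
        tot += prob[t];
      }
      double u = runif01() * tot, acc = 0.0;
      int knew = n_topics - 1;
      for (int t = 0; t < n_topics; ++t) {
        acc += prob[t];
        if (u <= acc) { knew = t; break; }
      }
      z[i] = knew;
      ndk(d, knew)++; nkw(knew, w)++; nk[knew]++;
    }
  }

  NumericMatrix theta(n_docs, n_topics);   // per-doc topic proportions
  NumericMatrix phi(n_topics, n_terms);    // per-topic term proportions
  for (int d = 0; d < n_docs; ++d) {
    double tot = 0.0;
    for (int t = 0; t < n_topics; ++t) tot += ndk(d, t) + alpha;
    for (int t = 0; t < n_topics; ++t) theta(d, t) = (ndk(d, t) + alpha) / tot;
  }
  for (int t = 0; t < n_topics; ++t) {
    double tot = nk[t] + n_terms * eta;
    for (int w = 0; w < n_terms; ++w) phi(t, w) = (nkw(t, w) + eta) / tot;
  }
  return List::create(_["theta"] = theta, _["phi"] = phi);
}
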
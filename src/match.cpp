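#include <Rcpp.h>
using namespace Rcpp;

// For each query tag, return the 1-based indices of database entries at the
// minimal Hamming distance <= max_mismatch, together with that distance.
// Distances are computed with early termination once max_mismatch is
// exceeded; queries with no entry within the allowance get an empty hit set
// and distance -1. Tag lengths are assumed validated by the caller.
// [[Rcpp::export(name = ".hamming_min_hits")]]
List hamming_min_hits(CharacterVector queries, CharacterVector db_tags,
                      int max_mismatch) {
  const int nq = queries.size();
  const int nd = db_tags.size();
  std::vector<std::string> db(nd);
  for (int j = 0; j < nd; ++j) db[j] = as<std::string>(db_tags[j]);

  List hits(nq);
  IntegerVector best(nq);
  for (int i = 0; i < nq; ++i) {
    const std::string q = as<std::string>(queries[i]);
    const int L = q.size();
    int bmin = max_mismatch + 1;
    std::vector<int> idx;
    for (int j = 0; j < nd; ++j) {
      const std::string& t = db[j];
      if ((int)t.size() != L) continue;
      int d = 0;
      for (int k = 0; k < L; ++k) {
        if (q[k] != t[k] && ++d > bmin) break;
      }
      if (d < bmin) {
        bmin = d;
        idx.clear();
        idx.push_back(j + 1);
      } else if (d == bmin && bmin <= max_mismatch) {
        idx.push_back(j + 1);
      }
    }
    if (bmin > max_mismatch) {
      best[i] = -1;
      hits[i] = IntegerVector(0);
    } else {
      best[i] = bmin;
      hits[i] = wrap(idx);
    }
  }
  return List::create(_["distance"] = best, _["hits"] = hits);
}
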
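// k-mer seed-and-extend transcriptome mapper.
//
// Ungapped extension only: the simulator emits substitution-only reads,
// so every true alignment lies on a single diagonal. A candidate
// (transcript, diagonal) is any diagonal carrying >= 1 exact k-mer seed
// and on which the full read fits inside the transcript; its score is
// the exact ungapped score of the whole read at that diagonal.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>

using namespace Rcpp;

struct KIndex {
  int k;
  std::vector<std::string> tx;
  std::vector<std::string> tx_id;
  std::vector<std::string> gene;
  // k-mer -> postings of (transcript index, 0-based offset)
  std::unordered_map<std::string, std::vector<std::pair<int, int> > > post;
  long long n_postings;
};

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector tx_ids,
                     CharacterVector genes, int k) {
  KIndex* idx = new KIndex();
  idx->k = k;
  idx->n_postings = 0;
  for (int t = 0; t < seqs.size(); ++t) {
    std::string s = as<std::string>(seqs[t]);
    idx->tx.push_back(s);
    idx->tx_id.push_back(as<std::string>(tx_ids[t]));
    idx->gene.push_back(as<std::string>(genes[t]));
    int n = (int)s.size() - k + 1;
    for (int i = 0; i < n; ++i) {
      idx->post[s.substr(i, k)].push_back(std::make_pair(t, i));
      ++idx->n_postings;
    }
  }
  XPtr<KIndex> p(idx, true);
  return p;
}

// [[Rcpp::export]]
double cpp_index_n_postings(SEXP xp) {
  XPtr<KIndex> p(xp);
  return (double)p->n_postings;
}

// [[Rcpp::export]]
DataFrame cpp_index_postings(SEXP xp) {
  XPtr<KIndex> p(xp);
  std::vector<std::string> km, tid;
  std::vector<int> off;
  for (std::unordered_map<std::string,
         std::vector<std::pair<int, int> > >::const_iterator
         it = p->post.begin(); it != p->post.end(); ++it) {
    for (size_t j = 0; j < it->second.size(); ++j) {
      km.push_back(it->first);
      tid.push_back(p->tx_id[it->second[j].first]);
      off.push_back(it->second[j].second);
    }
  }
  return DataFrame::create(_["kmer"] = km, _["transcript_id"] = tid,
                           _["offset"] = off,
                           _["stringsAsFactors"] = false);
}

// best ungapped hit per transcript for every read; hits below
// min_frac * match * read_length are dropped
// [[Rcpp::export]]
DataFrame cpp_align(SEXP xp, CharacterVector reads, int match_score,
                    int mismatch_score, double min_frac) {
  XPtr<KIndex> p(xp);
  const int k = p->k;
  const int n_tx = (int)p->tx.size();

  std::vector<int> out_read, out_start, out_score, out_mm;
  std::vector<int> out_tx;

  // per-transcript best, reset between reads
  std::vector<int> best_score(n_tx), best_start(n_tx), best_mm(n_tx);
  std::vector<char> seen(n_tx);
  std::unordered_map<long long, bool> cand;  // (tx, diag) dedup

  for (int r = 0; r < reads.size(); ++r) {
    std::string rd = as<std::string>(reads[r]);
    const int L = (int)rd.size();
    if (L < k) continue;  // no seeds possible: unmapped by construction
    const int min_score = (int)std::ceil(min_frac * match_score * L) ;
    std::fill(seen.begin(), seen.end(), 0);
    cand.clear();

    for (int i = 0; i + k <= L; ++i) {
      std::unordered_map<std::string,
        std::vector<std::pair<int, int> > >::const_iterator it =
        p->post.find(rd.substr(i, k));
      if (it == p->post.end()) continue;
      const std::vector<std::pair<int, int> >& v = it->second;
      for (size_t j = 0; j < v.size(); ++j) {
        int t = v[j].first;
        int d = v[j].second - i;  // read offset 0 aligns to tx position d
        if (d < 0 || d + L > (int)p->tx[t].size()) continue;  // read must fit
        long long key = (long long)t * 1000000007LL + d;
        if (cand.count(key)) continue;
        cand[key] = true;
        // score full read on this diagonal
        const std::string& ts = p->tx[t];
        int mm = 0;
        for (int q = 0; q < L; ++q) if (ts[d + q] != rd[q]) ++mm;
        int sc = match_score * (L - mm) + mismatch_score * mm;
        if (!seen[t] || sc > best_score[t] ||
            (sc == best_score[t] && d < best_start[t])) {
          seen[t] = 1; best_score[t] = sc; best_start[t] = d; best_mm[t] = mm;
        }
      }
    }
    for (int t = 0; t < n_tx; ++t) {
      if (seen[t] && best_score[t] >= min_score) {
        out_read.push_back(r + 1);
        out_tx.push_back(t + 1);
        out_start.push_back(best_start[t]);
        out_score.push_back(best_score[t]);
        out_mm.push_back(best_mm[t]);
      }
    }
  }
  return DataFrame::create(_["read"] = out_read, _["tx"] = out_tx,
                           _["start"] = out_start, _["score"] = out_score,
                           _["n_mismatches"] = out_mm,
                           _["stringsAsFactors"] = false);
}
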
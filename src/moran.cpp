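#include <Rcpp.h>
using namespace Rcpp;

// Death-birth (Moran) update loop for a local community of individuals.
// All randomness is pre-drawn in R so the R RNG remains the single source
// of reproducibility; this loop only applies the events.
//
// community: 1-based taxon id per individual (length J)
// death_idx: 1-based index of the individual that dies at each event
// migrant:   1-based taxon id of the metacommunity migrant for each event
// local_idx: 1-based index of the local parent if no migration
// is_migrant: 1 if the replacement comes from the metacommunity
// [[Rcpp::export]]
IntegerVector moran_update(IntegerVector community, IntegerVector death_idx,
                           IntegerVector migrant, IntegerVector local_idx,
                           IntegerVector is_migrant) {
  IntegerVector comm = clone(community);
  const int n_events = death_idx.size();
  for (int e = 0; e < n_events; ++e) {
    int repl = is_migrant[e] ? migrant[e] : comm[local_idx[e] - 1];
    comm[death_idx[e] - 1] = repl;
  }
  return comm;
}
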
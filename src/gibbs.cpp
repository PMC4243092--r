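#include <Rcpp.h>
using namespace Rcpp;

// Local field T(i) = alpha_i + sum_k [(beta_k - 1) M0_k + (gamma_k - beta_k) M1_k]
// computed from the current labels; adjacency passed as CSR per network
// (offsets: length N+1, nbr: concatenated 0-based neighbor indices).
static inline double local_field(int g, const IntegerVector &labels,
                                 const NumericVector &alphaI,
                                 const NumericVector &beta,
                                 const NumericVector &gamma,
                                 const std::vector<const int *> &off,
                                 const std::vector<const int *> &nbr) {
    double T = alphaI[g];
    const int K = beta.size();
    for (int k = 0; k < K; ++k) {
        const int *o = off[k];
        const int *nb = nbr[k];
        int m1 = 0;
        const int deg = o[g + 1] - o[g];
        for (int t = o[g]; t < o[g + 1]; ++t) m1 += labels[nb[t]];
        const int m0 = deg - m1;
        T += (beta[k] - 1.0) * m0 + (gamma[k] - beta[k]) * m1;
    }
    return T;
}

static void unpack_adj(const List &offsets, const List &nbrs,
                       std::vector<const int *> &off,
                       std::vector<const int *> &nbr) {
    const int K = offsets.size();
    off.resize(K);
    nbr.resize(K);
    for (int k = 0; k < K; ++k) {
        off[k] = INTEGER(offsets[k]);
        nbr[k] = INTEGER(nbrs[k]);
    }
}

// One sequential Gibbs sweep over the free genes in the given order.
// Returns updated labels and the conditional probability sigmoid(T(i))
// recorded for each free gene at its visit (earlier updates of the same
// sweep already applied). Uses R's RNG.
// [[Rcpp::export]]
List cpp_gibbs_sweep(IntegerVector labels, IntegerVector order,
                     NumericVector alphaI, NumericVector beta,
                     NumericVector gamma, List offsets, List nbrs) {
    IntegerVector x = clone(labels);
    std::vector<const int *> off, nbr;
    unpack_adj(offsets, nbrs, off, nbr);
    const int nf = order.size();
    NumericVector probs(nf);
    for (int u = 0; u < nf; ++u) {
        const int g = order[u];
        const double T = local_field(g, x, alphaI, beta, gamma, off, nbr);
        const double p = 1.0 / (1.0 + std::exp(-T));
        probs[u] = p;
        x[g] = (unif_rand() < p) ? 1 : 0;
    }
    return List::create(_["labels"] = x, _["probs"] = probs);
}

// Fixed-parameter Gibbs run: `sweeps` sequential sweeps; after `burnin`
// sweeps every `thin`-th sweep is recorded. Accumulates the mean of the
// conditional probabilities and of the binary labels over recorded sweeps
// (aligned with the order passed in) and the chain variation Q(t) between
// consecutive sweeps.
// [[Rcpp::export]]
List cpp_gibbs_run(IntegerVector labels, IntegerVector order,
                   NumericVector alphaI, NumericVector beta,
                   NumericVector gamma, List offsets, List nbrs,
                   int sweeps, int burnin, int thin, bool shuffled) {
    IntegerVector x = clone(labels);
    IntegerVector ord = clone(order);
    std::vector<const int *> off, nbr;
    unpack_adj(offsets, nbrs, off, nbr);
    const int nf = ord.size();
    const int N = labels.size();
    // fixed slot per free gene so accumulators are stable under shuffling
    std::vector<int> slot(N, -1);
    for (int u = 0; u < nf; ++u) slot[order[u]] = u;
    std::vector<double> psum(nf, 0.0), lsum(nf, 0.0), prev(nf, 0.0), cur(nf, 0.0);
    NumericVector qtrace(sweeps);
    int nrec = 0;
    for (int t = 1; t <= sweeps; ++t) {
        if (shuffled) { // Fisher-Yates using R's RNG
            for (int u = nf - 1; u > 0; --u) {
                int v = (int)(unif_rand() * (u + 1));
                if (v > u) v = u;
                std::swap(ord[u], ord[v]);
            }
        }
        for (int u = 0; u < nf; ++u) {
            const int g = ord[u];
            const double T = local_field(g, x, alphaI, beta, gamma, off, nbr);
            const double p = 1.0 / (1.0 + std::exp(-T));
            cur[slot[g]] = p;
            x[g] = (unif_rand() < p) ? 1 : 0;
        }
        if (t > 1) {
            double q = 0.0;
            for (int u = 0; u < nf; ++u) {
                const double d = cur[u] - prev[u];
                q += d * d;
            }
            qtrace[t - 1] = q;
        } else {
            qtrace[0] = NA_REAL;
        }
        if (t > burnin && (t - burnin) % thin == 0) {
            for (int u = 0; u < nf; ++u) {
                psum[u] += cur[u];
                lsum[u] += x[order[u]];
            }
            ++nrec;
        }
        prev = cur;
    }
    NumericVector pmean(nf), lmean(nf);
    if (nrec > 0) {
        for (int u = 0; u < nf; ++u) {
            pmean[u] = psum[u] / nrec;
            lmean[u] = lsum[u] / nrec;
        }
    }
    return List::create(_["labels"] = x, _["pmean"] = pmean,
                        _["lmean"] = lmean, _["nrec"] = nrec,
                        _["qtrace"] = qtrace);
}
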
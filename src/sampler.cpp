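// Metropolis-within-Gibbs sampler for the Dirichlet-multinomial DTU model.
//
// One call runs the full MCMC for one gene cluster: latent read allocations
// X (Gibbs, multinomial within each equivalence class), sample-specific
// transcript proportions pi (Gibbs, conjugate Dirichlet), and group-level
// Dirichlet parameters delta (Metropolis on the log scale with an adaptive
// random-walk proposal). Multi-gene equivalence classes allocate reads
// across genes with probabilities weighted by each gene's read mass from
// the previous sweep.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static const double PI_CLAMP = 1e-12;

// log Dirichlet density, pi clamped away from 0 before log evaluation
static double log_dirichlet(const arma::vec& pi, const arma::vec& delta) {
    double out = lgamma(arma::accu(delta));
    for (arma::uword k = 0; k < delta.n_elem; ++k) {
        out -= lgamma(delta(k));
        out += (delta(k) - 1.0) * std::log(std::max(pi(k), PI_CLAMP));
    }
    return out;
}

// prior density of log delta; mode 0 = vague, 1 = informative (Jacobian
// transform of the (log delta_1..K-1, log delta_+) parameterisation)
static double log_prior(const arma::vec& logd, int priorMode,
                        double priorMean, double priorVar, double vagueVar) {
    const arma::uword K = logd.n_elem;
    double out = 0.0;
    if (priorMode == 0) {
        for (arma::uword k = 0; k < K; ++k)
            out += R::dnorm(logd(k), 0.0, std::sqrt(vagueVar), 1);
        return out;
    }
    double dplus = 0.0;
    for (arma::uword k = 0; k < K; ++k) dplus += std::exp(logd(k));
    for (arma::uword k = 0; k + 1 < K; ++k)
        out += R::dnorm(logd(k), priorMean - std::log((double)K),
                        std::sqrt(vagueVar), 1);
    out += R::dnorm(std::log(dplus), priorMean, std::sqrt(priorVar), 1);
    out += logd(K - 1) - std::log(dplus);
    return out;
}

// sequential-binomial multinomial draw of f reads over weights w (size m);
// returns allocations in out. Falls back to uniform when all weights are 0.
static bool rmultinom_w(int f, const arma::vec& w, arma::ivec& out) {
    const arma::uword m = w.n_elem;
    out.zeros(m);
    double wsum = arma::accu(w);
    bool fallback = false;
    arma::vec ww = w;
    if (!(wsum > 0.0) || !std::isfinite(wsum)) {
        ww.ones();
        wsum = (double)m;
        fallback = true;
    }
    int rem = f;
    for (arma::uword k = 0; k + 1 < m && rem > 0; ++k) {
        double p = ww(k) / wsum;
        if (p > 1.0) p = 1.0;
        if (p < 0.0) p = 0.0;
        int nk = (int)R::rbinom((double)rem, p);
        out(k) = nk;
        rem -= nk;
        wsum -= ww(k);
        if (wsum <= 0.0) {
            // numerical exhaustion: dump remainder on next positive weight
            break;
        }
    }
    if (rem > 0) out(m - 1) += rem;
    return fallback;
}

static arma::vec rdirichlet(const arma::vec& alpha) {
    arma::vec g(alpha.n_elem);
    for (arma::uword k = 0; k < alpha.n_elem; ++k)
        g(k) = R::rgamma(alpha(k), 1.0);
    double s = arma::accu(g);
    if (!(s > 0.0)) {
        g.ones();
        s = (double)alpha.n_elem;
    }
    return g / s;
}

// [[Rcpp::export(name = ".run_cluster_mcmc")]]
List run_cluster_mcmc(List classMembers, IntegerMatrix classCounts,
                      IntegerVector geneOf, IntegerVector groupOf,
                      NumericVector effLen, int nGenes, int nGroups,
                      int niter, int burnin, int priorMode, double priorMean,
                      double priorVar, double vagueVar, bool allocPiT) {
    const int J = classMembers.size();
    const int N = classCounts.ncol();
    const int K = geneOf.size();

    // class structure as arma vectors (0-based transcript indices)
    std::vector<arma::uvec> cls(J);
    for (int j = 0; j < J; ++j) {
        IntegerVector v = classMembers[j];
        arma::uvec u(v.size());
        for (int t = 0; t < v.size(); ++t) u(t) = (arma::uword)v[t];
        cls[j] = u;
    }

    // transcripts of each gene, local index of each transcript in its gene
    std::vector<arma::uvec> geneTx(nGenes);
    arma::uvec localIdx(K);
    {
        std::vector<std::vector<arma::uword>> tmp(nGenes);
        for (int k = 0; k < K; ++k) {
            localIdx(k) = tmp[geneOf[k]].size();
            tmp[geneOf[k]].push_back((arma::uword)k);
        }
        for (int g = 0; g < nGenes; ++g)
            geneTx[g] = arma::uvec(tmp[g]);
    }

    // uniform-split proportion estimate p-hat and initial gene masses
    arma::mat M(nGenes, N, arma::fill::zeros);  // read mass per gene/sample
    arma::vec phat(K, arma::fill::zeros);
    for (int j = 0; j < J; ++j) {
        const arma::uvec& c = cls[j];
        for (int i = 0; i < N; ++i) {
            double share = (double)classCounts(j, i) / (double)c.n_elem;
            for (arma::uword t = 0; t < c.n_elem; ++t) {
                phat(c(t)) += share;
                M(geneOf[c(t)], i) += share;
            }
        }
    }

    const double initScale = (priorMode == 1) ? std::exp(priorMean) : 1.0;
    std::vector<arma::vec> delta0(nGenes);
    for (int g = 0; g < nGenes; ++g) {
        // normalise p-hat within the gene with a 0.01 floor share
        arma::vec q = phat(geneTx[g]);
        double qs = arma::accu(q);
        if (qs > 0) q /= qs; else q.fill(1.0 / geneTx[g].n_elem);
        q += 0.01;
        q /= arma::accu(q);
        delta0[g] = initScale * q;
    }

    // state: log delta per gene per group, pi per gene (Kg x N)
    std::vector<std::vector<arma::vec>> logDelta(nGenes,
        std::vector<arma::vec>(nGroups));
    for (int g = 0; g < nGenes; ++g)
        for (int r = 0; r < nGroups; ++r)
            logDelta[g][r] = arma::log(delta0[g]);

    std::vector<arma::mat> piMat(nGenes);
    for (int g = 0; g < nGenes; ++g) {
        piMat[g].set_size(geneTx[g].n_elem, N);
        for (int i = 0; i < N; ++i)
            piMat[g].col(i) = rdirichlet(delta0[g]);
    }

    // adaptation state per (gene, group), only for Kg >= 2
    std::vector<std::vector<arma::vec>> adMean(nGenes,
        std::vector<arma::vec>(nGroups));
    std::vector<std::vector<arma::mat>> adM2(nGenes,
        std::vector<arma::mat>(nGroups));
    std::vector<std::vector<arma::mat>> propChol(nGenes,
        std::vector<arma::mat>(nGroups));
    std::vector<std::vector<bool>> useAdapt(nGenes,
        std::vector<bool>(nGroups, false));
    std::vector<std::vector<long>> accCount(nGenes,
        std::vector<long>(nGroups, 0));
    long adN = 0;  // shared adaptation counter (sweeps)

    for (int g = 0; g < nGenes; ++g) {
        const arma::uword Kg = geneTx[g].n_elem;
        for (int r = 0; r < nGroups; ++r) {
            adMean[g][r].zeros(Kg);
            adM2[g][r].zeros(Kg, Kg);
        }
    }

    // samples per group
    std::vector<arma::uvec> grpSamples(nGroups);
    {
        std::vector<std::vector<arma::uword>> tmp(nGroups);
        for (int i = 0; i < N; ++i) tmp[groupOf[i]].push_back(i);
        for (int r = 0; r < nGroups; ++r) grpSamples[r] = arma::uvec(tmp[r]);
    }

    // output storage
    std::vector<std::vector<arma::mat>> draws(nGenes,
        std::vector<arma::mat>(nGroups));
    for (int g = 0; g < nGenes; ++g)
        if (geneTx[g].n_elem >= 2)
            for (int r = 0; r < nGroups; ++r)
                draws[g][r].set_size(niter, geneTx[g].n_elem);
    arma::mat logPost(niter, nGroups, arma::fill::zeros);
    bool conserved = true;
    long fallbackCount = 0;

    arma::mat X(K, N);
    arma::ivec allocBuf;
    std::vector<arma::mat> pAlloc(nGenes);

    const int total = burnin + niter;
    for (int s = 0; s < total; ++s) {
        // --- (a) allocate reads given current pi (and gene masses) ---
        for (int g = 0; g < nGenes; ++g) {
            if (allocPiT) {
                const arma::uvec& tx = geneTx[g];
                arma::mat pt = piMat[g];
                for (int i = 0; i < N; ++i) {
                    for (arma::uword t = 0; t < tx.n_elem; ++t)
                        pt(t, i) /= effLen[tx(t)];
                    double sc = arma::accu(pt.col(i));
                    if (sc > 0) pt.col(i) /= sc;
                }
                pAlloc[g] = pt;
            } else {
                pAlloc[g] = piMat[g];
            }
        }
        X.zeros();
        for (int i = 0; i < N; ++i) {
            for (int j = 0; j < J; ++j) {
                const int f = classCounts(j, i);
                if (f == 0) continue;
                const arma::uvec& c = cls[j];
                if (c.n_elem == 1) {
                    X(c(0), i) += f;
                    continue;
                }
                arma::vec w(c.n_elem);
                for (arma::uword t = 0; t < c.n_elem; ++t) {
                    const int k = c(t);
                    const int g = geneOf[k];
                    const double mass = std::max(M(g, i), 1.0);
                    w(t) = mass * pAlloc[g](localIdx(k), i);
                }
                if (rmultinom_w(f, w, allocBuf)) ++fallbackCount;
                int chk = 0;
                for (arma::uword t = 0; t < c.n_elem; ++t) {
                    X(c(t), i) += allocBuf(t);
                    chk += allocBuf(t);
                }
                if (chk != f) conserved = false;
            }
        }
        // refresh gene masses for the next sweep
        for (int g = 0; g < nGenes; ++g)
            for (int i = 0; i < N; ++i)
                M(g, i) = arma::accu(X(geneTx[g], arma::uvec{(arma::uword)i}));

        // --- (b) pi | X, delta ~ Dirichlet(delta + X) ---
        for (int g = 0; g < nGenes; ++g) {
            const arma::uvec& tx = geneTx[g];
            if (tx.n_elem == 1) {
                piMat[g].row(0).ones();
                continue;
            }
            for (int i = 0; i < N; ++i) {
                arma::vec alpha = arma::exp(logDelta[g][groupOf[i]]) +
                    X(tx, arma::uvec{(arma::uword)i});
                piMat[g].col(i) = rdirichlet(alpha);
            }
        }

        // --- (c) delta | pi via adaptive random-walk Metropolis ---
        ++adN;
        arma::vec lpGroup(nGroups, arma::fill::zeros);
        for (int g = 0; g < nGenes; ++g) {
            const arma::uword Kg = geneTx[g].n_elem;
            if (Kg < 2) continue;
            for (int r = 0; r < nGroups; ++r) {
                arma::vec cur = logDelta[g][r];
                arma::vec curd = arma::exp(cur);
                double curT = log_prior(cur, priorMode, priorMean, priorVar,
                                        vagueVar);
                const arma::uvec& ss = grpSamples[r];
                for (arma::uword u = 0; u < ss.n_elem; ++u)
                    curT += log_dirichlet(piMat[g].col(ss(u)), curd);

                arma::vec z(Kg);
                for (arma::uword k = 0; k < Kg; ++k) z(k) = norm_rand();
                arma::vec prop;
                if (useAdapt[g][r])
                    prop = cur + propChol[g][r].t() * z;
                else
                    prop = cur + 0.1 * z;

                bool ok = prop.max() <= 700.0;
                double propT = -arma::datum::inf;
                if (ok) {
                    arma::vec propd = arma::exp(prop);
                    propT = log_prior(prop, priorMode, priorMean, priorVar,
                                      vagueVar);
                    for (arma::uword u = 0; u < ss.n_elem; ++u)
                        propT += log_dirichlet(piMat[g].col(ss(u)), propd);
                    if (!std::isfinite(propT)) ok = false;
                }
                if (ok && std::log(unif_rand()) < propT - curT) {
                    logDelta[g][r] = prop;
                    curT = propT;
                    ++accCount[g][r];
                }
                lpGroup(r) += curT;

                // running covariance of the log-delta chain
                arma::vec x = logDelta[g][r];
                arma::vec dmean = x - adMean[g][r];
                adMean[g][r] += dmean / (double)adN;
                adM2[g][r] += dmean * (x - adMean[g][r]).t();
                if (adN >= 200 && adN % 100 == 0) {
                    arma::mat S = adM2[g][r] / (double)(adN - 1);
                    arma::mat P = (2.38 * 2.38 / (double)Kg) *
                        (S + 1e-6 * arma::eye(Kg, Kg));
                    arma::mat Ch;
                    if (arma::chol(Ch, P)) {
                        propChol[g][r] = Ch;
                        useAdapt[g][r] = true;
                    }
                }

                if (s >= burnin)
                    draws[g][r].row(s - burnin) = logDelta[g][r].t();
            }
        }
        if (s >= burnin)
            logPost.row(s - burnin) = lpGroup.t();
        if (s % 512 == 0) Rcpp::checkUserInterrupt();
    }

    List deltaOut(nGenes);
    for (int g = 0; g < nGenes; ++g) {
        if (geneTx[g].n_elem < 2) {
            deltaOut[g] = R_NilValue;
            continue;
        }
        List byGroup(nGroups);
        for (int r = 0; r < nGroups; ++r)
            byGroup[r] = wrap(draws[g][r]);
        deltaOut[g] = byGroup;
    }
    NumericMatrix acc(nGenes, nGroups);
    for (int g = 0; g < nGenes; ++g)
        for (int r = 0; r < nGroups; ++r)
            acc(g, r) = (double)accCount[g][r] / (double)total;

    return List::create(
        _["delta"] = deltaOut,
        _["logPosterior"] = wrap(logPost),
        _["acceptance"] = acc,
        _["conserved"] = conserved,
        _["fallbacks"] = (double)fallbackCount);
}

// Single-sample, single-sweep read allocation; exposed for unit laws.
// [[Rcpp::export(name = ".alloc_reads_once")]]
IntegerVector alloc_reads_once(List classMembers, IntegerVector f,
                               NumericVector pi, IntegerVector geneOf,
                               NumericVector geneMass, NumericVector effLen,
                               bool allocPiT) {
    const int J = classMembers.size();
    const int K = pi.size();
    // local index of each transcript within its gene + per-gene scale
    int nGenes = 0;
    for (int k = 0; k < K; ++k) nGenes = std::max(nGenes, geneOf[k] + 1);
    std::vector<double> p(K);
    if (allocPiT) {
        std::vector<double> sc(nGenes, 0.0);
        for (int k = 0; k < K; ++k) sc[geneOf[k]] += pi[k] / effLen[k];
        for (int k = 0; k < K; ++k)
            p[k] = sc[geneOf[k]] > 0 ? (pi[k] / effLen[k]) / sc[geneOf[k]] : 0.0;
    } else {
        for (int k = 0; k < K; ++k) p[k] = pi[k];
    }
    IntegerVector X(K);
    arma::ivec buf;
    for (int j = 0; j < J; ++j) {
        IntegerVector c = classMembers[j];
        if (f[j] == 0) continue;
        if (c.size() == 1) {
            X[c[0]] += f[j];
            continue;
        }
        arma::vec w(c.size());
        for (int t = 0; t < c.size(); ++t)
            w(t) = std::max(geneMass[geneOf[c[t]]], 1.0) * p[c[t]];
        rmultinom_w(f[j], w, buf);
        for (int t = 0; t < c.size(); ++t) X[c[t]] += buf(t);
    }
    return X;
}
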
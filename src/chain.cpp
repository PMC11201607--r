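// Block Gibbs sampler for the binomial spline functional-regression model.
//
// Parameter vector layout (must match designLayout() on the R side):
//   gamma0 (p) | delta_g, g = 2..G (p each) | upsilon_i, i = 1..M (pI each)
//   | eta (q = depth flag + #covariates)
//
// Each block update draws from the Gaussian approximation to the block's
// full conditional: one Newton step from the current value using the
// penalized curvature A = X'WX + I/tau^2 (refreshed on a sweep schedule),
// then theta_new = theta_hat + chol(A)^-T z.  For an exactly quadratic
// conditional a single Newton step from any starting point lands exactly
// at the conditional mean, so the update is exact in the Gaussian limit.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct Block {
    int type;                 // 0 gamma0, 1 delta, 2 upsilon, 3 eta
    arma::uword offset;       // first index in theta
    arma::uword size;
    arma::uvec samples;       // 0-based columns of y/n this block touches
    // cached curvature factor
    arma::mat L;              // lower Cholesky of A
    bool haveL = false;
};

inline arma::vec clamp_lp(const arma::vec& x) {
    return arma::clamp(x, -35.0, 35.0);
}

inline arma::vec log1pexp_vec(const arma::vec& x) {
    arma::vec out(x.n_elem);
    for (arma::uword i = 0; i < x.n_elem; ++i) {
        double v = x[i];
        out[i] = (v <= 18.0) ? std::log1p(std::exp(v))
                             : v + std::exp(-v);
    }
    return out;
}

arma::mat chol_jitter(arma::mat A) {
    arma::mat L;
    if (arma::chol(L, A, "lower")) return L;
    double jit = 1e-8 * arma::trace(A) / A.n_rows;
    A.diag() += jit;
    if (arma::chol(L, A, "lower")) return L;
    A.diag() += 1e4 * jit;
    if (arma::chol(L, A, "lower")) return L;
    stop("singular penalized information matrix in block update");
    return L;  // unreachable
}

// Design matrix of the eta block for sample i (T x q).
arma::mat eta_design(const arma::mat& dlog, const arma::mat& Zc,
                     bool use_depth, arma::uword i, arma::uword T) {
    arma::uword q = (use_depth ? 1 : 0) + Zc.n_cols;
    arma::mat B(T, q);
    arma::uword c = 0;
    if (use_depth) B.col(c++) = dlog.col(i);
    for (arma::uword j = 0; j < Zc.n_cols; ++j)
        B.col(c++).fill(Zc(i, j));
    return B;
}

} // namespace

// [[Rcpp::export(name = ".chain_core")]]
List chain_core(const arma::mat& y, const arma::mat& n,
                const arma::mat& Xg, const arma::mat& Xi,
                const arma::ivec& grp, const arma::mat& Zc,
                bool use_depth, const arma::mat& dlog,
                arma::vec theta, const arma::vec& tau_pr, int prior_kind,
                double ig_a, double ig_b, int n_groups,
                int init_sweeps, int n_iter, int burnin, int thin,
                int refresh, bool random_scan) {
    const arma::uword T = y.n_rows, M = y.n_cols;
    const arma::uword p = Xg.n_cols, pI = Xi.n_cols;
    const arma::uword q = (use_depth ? 1 : 0) + Zc.n_cols;
    const int G = n_groups;
    if (refresh < 1) refresh = 1;

    // ---- block table -------------------------------------------------
    std::vector<Block> blocks;
    {
        arma::uword off = 0;
        Block b0; b0.type = 0; b0.offset = off; b0.size = p;
        b0.samples = arma::regspace<arma::uvec>(0, M - 1);
        blocks.push_back(b0); off += p;
        for (int g = 2; g <= G; ++g) {
            Block b; b.type = 1; b.offset = off; b.size = p;
            b.samples = arma::find(grp == g);
            blocks.push_back(b); off += p;
        }
        for (arma::uword i = 0; i < M; ++i) {
            Block b; b.type = 2; b.offset = off; b.size = pI;
            b.samples = arma::uvec({i});
            blocks.push_back(b); off += pI;
        }
        if (q > 0) {
            Block b; b.type = 3; b.offset = off; b.size = q;
            b.samples = arma::regspace<arma::uvec>(0, M - 1);
            blocks.push_back(b); off += q;
        }
        if (off != theta.n_elem)
            stop("theta length does not match the block layout");
    }
    const int nblocks = static_cast<int>(blocks.size());

    // per-block prior variances
    if (static_cast<int>(tau_pr.n_elem) != nblocks)
        stop("per-block prior vector does not match the block layout");
    arma::vec tau2 = arma::square(tau_pr);

    // ---- initial linear predictor ------------------------------------
    arma::mat lp(T, M, arma::fill::zeros);
    for (const Block& b : blocks) {
        arma::vec th = theta.subvec(b.offset, b.offset + b.size - 1);
        if (b.type == 0 || b.type == 1) {
            arma::vec v = Xg * th;
            for (arma::uword k = 0; k < b.samples.n_elem; ++k)
                lp.col(b.samples[k]) += v;
        } else if (b.type == 2) {
            lp.col(b.samples[0]) += Xi * th;
        } else {
            for (arma::uword i = 0; i < M; ++i)
                lp.col(i) += eta_design(dlog, Zc, use_depth, i, T) * th;
        }
    }

    // ---- storage ------------------------------------------------------
    const int nkeep = (n_iter - burnin) / thin;
    arma::mat draws(nkeep, theta.n_elem);
    arma::mat beta_mean(T, M, arma::fill::zeros);
    arma::cube group_curves(T, G, nkeep);
    arma::vec loglik(nkeep);

    // ---- one block update ---------------------------------------------
    auto update_block = [&](Block& b, bool sample_noise, bool do_refresh) {
        const arma::uword pb = b.size;
        arma::vec th = theta.subvec(b.offset, b.offset + pb - 1);
        arma::vec g(pb, arma::fill::zeros);
        arma::vec wsum;
        bool want_w = do_refresh || !b.haveL;
        if (b.type == 3) {
            arma::mat A;
            if (want_w) A = arma::eye(pb, pb) / tau2[&b - &blocks[0]];
            for (arma::uword i = 0; i < M; ++i) {
                arma::vec mu = 1.0 / (1.0 + arma::exp(-clamp_lp(lp.col(i))));
                arma::vec resid = y.col(i) - n.col(i) % mu;
                arma::mat B = eta_design(dlog, Zc, use_depth, i, T);
                g += B.t() * resid;
                if (want_w) {
                    arma::vec w = n.col(i) % mu % (1.0 - mu);
                    A += B.t() * (B.each_col() % w);
                }
            }
            g -= th / tau2[&b - &blocks[0]];
            if (want_w) { b.L = chol_jitter(A); b.haveL = true; }
        } else {
            const arma::mat& X = (b.type == 2) ? Xi : Xg;
            arma::vec r(T, arma::fill::zeros);
            if (want_w) wsum.zeros(T);
            for (arma::uword k = 0; k < b.samples.n_elem; ++k) {
                arma::uword i = b.samples[k];
                arma::vec mu = 1.0 / (1.0 + arma::exp(-clamp_lp(lp.col(i))));
                r += y.col(i) - n.col(i) % mu;
                if (want_w) wsum += n.col(i) % mu % (1.0 - mu);
            }
            g = X.t() * r - th / tau2[&b - &blocks[0]];
            if (want_w) {
                arma::mat A = X.t() * (X.each_col() % wsum);
                A.diag() += 1.0 / tau2[&b - &blocks[0]];
                b.L = chol_jitter(A);
                b.haveL = true;
            }
        }
        // Newton step: theta_hat = th + A^{-1} g  (A = L L')
        arma::vec u = arma::solve(arma::trimatl(b.L), g);
        arma::vec dth = arma::solve(arma::trimatu(b.L.t()), u);
        arma::vec thnew = th + dth;
        if (sample_noise) {
            arma::vec z(pb);
            for (arma::uword j = 0; j < pb; ++j) z[j] = R::norm_rand();
            thnew += arma::solve(arma::trimatu(b.L.t()), z);
        }
        arma::vec delta = thnew - th;
        if (b.type == 0 || b.type == 1) {
            arma::vec v = Xg * delta;
            for (arma::uword k = 0; k < b.samples.n_elem; ++k)
                lp.col(b.samples[k]) += v;
        } else if (b.type == 2) {
            lp.col(b.samples[0]) += Xi * delta;
        } else {
            for (arma::uword i = 0; i < M; ++i)
                lp.col(i) += eta_design(dlog, Zc, use_depth, i, T) * delta;
        }
        theta.subvec(b.offset, b.offset + pb - 1) = thnew;
    };

    // ---- recentering moves ---------------------------------------------
    // The likelihood depends on delta_g and upsilon_{g,i} only through
    // their sums, so the posterior has long ridges along c -> (delta_g + c,
    // upsilon_{g,i} - c).  These directions are Gaussian given everything
    // else (only the priors act on them), so we add exact Gibbs updates
    // along them after every sweep; they leave the linear predictor (and
    // hence the cached curvature) untouched and make the chain mix across
    // the group/individual decomposition.  Requires a common resolution
    // for group and individual blocks.
    const bool can_recenter = (p == pI);
    const int first_ups = 1 + (G - 1);
    auto recenter = [&](void) {
        if (!can_recenter) return;
        // delta_g vs its group's upsilons, g = 2..G
        for (int g = 2; g <= G; ++g) {
            Block& bd = blocks[g - 1];
            double prec = 1.0 / tau2[g - 1];
            arma::vec num = -theta.subvec(bd.offset, bd.offset + p - 1) /
                            tau2[g - 1];
            for (arma::uword k = 0; k < bd.samples.n_elem; ++k) {
                int bi = first_ups + bd.samples[k];
                const Block& bu = blocks[bi];
                num += theta.subvec(bu.offset, bu.offset + p - 1) / tau2[bi];
                prec += 1.0 / tau2[bi];
            }
            arma::vec c = num / prec;
            double sdc = 1.0 / std::sqrt(prec);
            for (arma::uword j = 0; j < p; ++j) c[j] += sdc * R::norm_rand();
            theta.subvec(bd.offset, bd.offset + p - 1) += c;
            for (arma::uword k = 0; k < bd.samples.n_elem; ++k) {
                const Block& bu = blocks[first_ups + bd.samples[k]];
                theta.subvec(bu.offset, bu.offset + p - 1) -= c;
            }
        }
        // gamma0 vs all upsilons
        {
            Block& b0 = blocks[0];
            double prec = 1.0 / tau2[0];
            arma::vec num = -theta.subvec(b0.offset, b0.offset + p - 1) /
                            tau2[0];
            for (arma::uword i = 0; i < M; ++i) {
                int bi = first_ups + i;
                const Block& bu = blocks[bi];
                num += theta.subvec(bu.offset, bu.offset + p - 1) / tau2[bi];
                prec += 1.0 / tau2[bi];
            }
            arma::vec c = num / prec;
            double sdc = 1.0 / std::sqrt(prec);
            for (arma::uword j = 0; j < p; ++j) c[j] += sdc * R::norm_rand();
            theta.subvec(b0.offset, b0.offset + p - 1) += c;
            for (arma::uword i = 0; i < M; ++i) {
                const Block& bu = blocks[first_ups + i];
                theta.subvec(bu.offset, bu.offset + p - 1) -= c;
            }
        }
    };

    // ---- quasi-IRLS initialization sweeps (no noise) -------------------
    for (int s = 0; s < init_sweeps; ++s)
        for (int bi = 0; bi < nblocks; ++bi)
            update_block(blocks[bi], false, true);

    // ---- sampling ------------------------------------------------------
    int kept = 0;
    for (int it = 1; it <= n_iter; ++it) {
        bool do_refresh = ((it - 1) % refresh == 0);
        if (!random_scan) {
            for (int bi = 0; bi < nblocks; ++bi)
                update_block(blocks[bi], true, do_refresh);
        } else {
            arma::uvec ord = arma::regspace<arma::uvec>(0, nblocks - 1);
            for (int bi = nblocks - 1; bi > 0; --bi) {
                int j = static_cast<int>(R::unif_rand() * (bi + 1));
                std::swap(ord[bi], ord[j]);
            }
            for (int bi = 0; bi < nblocks; ++bi)
                update_block(blocks[ord[bi]], true, do_refresh);
        }
        recenter();
        if (prior_kind == 1) {
            for (int bi = 0; bi < nblocks; ++bi) {
                arma::vec th = theta.subvec(blocks[bi].offset,
                                            blocks[bi].offset + blocks[bi].size - 1);
                double shape = ig_a + 0.5 * blocks[bi].size;
                double rate = ig_b + 0.5 * arma::dot(th, th);
                tau2[bi] = rate / R::rgamma(shape, 1.0);
                blocks[bi].haveL = false;  // prior precision changed
            }
        }
        if (it > burnin && (it - burnin) % thin == 0) {
            draws.row(kept) = theta.t();
            arma::vec gamma0 = theta.subvec(0, p - 1);
            arma::vec base = Xg * gamma0;
            group_curves.slice(kept).col(0) = base;
            for (int g = 2; g <= G; ++g) {
                arma::uword off = p + (g - 2) * p;
                group_curves.slice(kept).col(g - 1) =
                    base + Xg * theta.subvec(off, off + p - 1);
            }
            double ll = 0.0;
            for (arma::uword i = 0; i < M; ++i) {
                arma::vec l = clamp_lp(lp.col(i));
                ll += arma::dot(y.col(i), l) -
                      arma::dot(n.col(i), log1pexp_vec(l));
                beta_mean.col(i) += 1.0 / (1.0 + arma::exp(-l));
            }
            loglik[kept] = ll;
            ++kept;
        }
    }
    if (kept > 0) beta_mean /= kept;
    if (lp.has_nan())
        stop("NaN in linear predictor; chain aborted");

    return List::create(
        _["draws"] = draws,
        _["beta_mean"] = beta_mean,
        _["group_curves"] = group_curves,
        _["loglik"] = loglik,
        _["theta"] = theta,
        _["tau2"] = tau2);
}

// Single quasi-IRLS pass used by the initializer (exported separately so
// the R side can run deterministic mode-finding without sampling).
// [[Rcpp::export(name = ".init_core")]]
List init_core(const arma::mat& y, const arma::mat& n,
               const arma::mat& Xg, const arma::mat& Xi,
               const arma::ivec& grp, const arma::mat& Zc,
               bool use_depth, const arma::mat& dlog,
               arma::vec theta, const arma::vec& tau_pr, int n_groups,
               int sweeps) {
    return chain_core(y, n, Xg, Xi, grp, Zc, use_depth, dlog, theta, tau_pr,
                      0, 0.0, 0.0, n_groups, sweeps, 0, 0, 1, 1, false);
}
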
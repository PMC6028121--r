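// Core discriminant-taxon / risk-index engine.
//
// The leave-one-out pipeline re-selects taxa inside every fold and the
// permutation test re-runs the whole LOO scheme for each of B label
// permutations, so the screen + bootstrapped LDA sit in C++.
//
// All randomness goes through R's RNG (unif_rand), so set.seed() on the R
// side makes every run, including the bootstrap subsampling, reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Average-tie ranks of x into r; returns the tie correction term
// sum(t^3 - t) over tie groups.
static double rank_avg(const arma::vec& x, arma::vec& r) {
    const int n = x.n_elem;
    arma::uvec ord = arma::sort_index(x);
    double tie_term = 0.0;
    int i = 0;
    while (i < n) {
        int j = i;
        while (j + 1 < n && x[ord[j + 1]] == x[ord[i]]) ++j;
        const double avg = 0.5 * (i + j) + 1.0; // average of ranks i+1..j+1
        const int t = j - i + 1;
        for (int k = i; k <= j; ++k) r[ord[k]] = avg;
        if (t > 1) tie_term += (double)t * t * t - t;
        i = j + 1;
    }
    return tie_term;
}

// Two-group Kruskal-Wallis p-values for every row of X (taxa x samples),
// chi-square approximation with tie correction. Constant rows get p = 1.
static arma::vec kw_rows(const arma::mat& X, const arma::ivec& grp) {
    const int T = X.n_rows, N = X.n_cols;
    int n1 = 0;
    for (int j = 0; j < N; ++j) n1 += (grp[j] == 1);
    const int n0 = N - n1;
    arma::vec p(T), r(N);
    const double denom = (double)N * N * N - N;
    for (int t = 0; t < T; ++t) {
        arma::vec row = X.row(t).t();
        const double tie_term = rank_avg(row, r);
        const double tie_corr = 1.0 - tie_term / denom;
        if (tie_corr <= 0.0) { p[t] = 1.0; continue; } // all values equal
        double R1 = 0.0;
        for (int j = 0; j < N; ++j) if (grp[j] == 1) R1 += r[j];
        const double Rtot = 0.5 * N * (N + 1.0);
        const double R0 = Rtot - R1;
        double H = 12.0 / ((double)N * (N + 1.0)) *
            (R0 * R0 / n0 + R1 * R1 / n1) - 3.0 * (N + 1.0);
        H /= tie_corr;
        if (H < 0) H = 0;
        p[t] = R::pchisq(H, 1.0, 0, 0);
    }
    return p;
}

// Sample k indices without replacement from idx (uses R's RNG).
static arma::uvec sample_wo_repl(arma::uvec idx, int k) {
    const int n = idx.n_elem;
    for (int j = 0; j < k; ++j) {
        int u = j + (int)std::floor(unif_rand() * (n - j));
        if (u >= n) u = n - 1;
        std::swap(idx[j], idx[u]);
    }
    return idx.head(k);
}

struct FitResult {
    arma::vec kw_p;        // all taxa
    arma::uvec screened;   // 0-based taxon indices passing the KW screen
    arma::vec lda_log10;   // per screened taxon
    arma::ivec enriched;   // per screened taxon: 1 if class-1 mean larger
    arma::uvec pos;        // selected, enriched in class 1 (target)
    arma::uvec neg;        // selected, enriched in class 0
    int n_degenerate;      // bootstraps that needed the hard ridge fallback
};

// One discriminant fit: KW screen then bootstrapped one-dimensional Fisher
// LDA with ridge-regularised pooled covariance; effect size per taxon is the
// bootstrap mean of (|w_unit[t] * (projection mean difference)| +
// |raw class-mean difference|) / 2, reported as log10(1 + scaling * effect).
static FitResult fit_discriminant(const arma::mat& X, const arma::ivec& grp,
                                  double kw_alpha, double lda_threshold,
                                  int n_boot, double boot_frac,
                                  double scaling, double ridge) {
    FitResult out;
    out.n_degenerate = 0;
    const int N = X.n_cols;
    out.kw_p = kw_rows(X, grp);
    out.screened = arma::find(out.kw_p < kw_alpha);
    const int d = out.screened.n_elem;
    if (d == 0) return out;

    arma::uvec idx0 = arma::find(grp == 0), idx1 = arma::find(grp == 1);
    // Iterate the two classes in order of first sample occurrence so the
    // bootstrap RNG stream is invariant under relabelling of the classes.
    bool zero_first = idx0.min() < idx1.min();

    arma::mat Xs = X.rows(out.screened); // d x N
    arma::vec eff(d, arma::fill::zeros);
    const int k0 = std::max(2, (int)std::ceil(boot_frac * idx0.n_elem));
    const int k1 = std::max(2, (int)std::ceil(boot_frac * idx1.n_elem));

    for (int b = 0; b < n_boot; ++b) {
        arma::uvec s0, s1;
        if (zero_first) {
            s0 = sample_wo_repl(idx0, std::min((int)idx0.n_elem, k0));
            s1 = sample_wo_repl(idx1, std::min((int)idx1.n_elem, k1));
        } else {
            s1 = sample_wo_repl(idx1, std::min((int)idx1.n_elem, k1));
            s0 = sample_wo_repl(idx0, std::min((int)idx0.n_elem, k0));
        }
        arma::mat X0 = Xs.cols(s0), X1 = Xs.cols(s1);
        arma::vec mu0 = arma::mean(X0, 1), mu1 = arma::mean(X1, 1);
        X0.each_col() -= mu0;
        X1.each_col() -= mu1;
        arma::mat Sw = (X0 * X0.t() + X1 * X1.t()) /
            std::max(1, (int)(s0.n_elem + s1.n_elem) - 2);
        const double lam = ridge * arma::trace(Sw) / d + 1e-12;
        Sw.diag() += lam;
        arma::vec delta = mu1 - mu0, w;
        if (!arma::solve(w, Sw, delta, arma::solve_opts::likely_sympd +
                                       arma::solve_opts::no_approx)) {
            // degenerate covariance even after the ridge: fall back to a
            // heavily regularised (near-diagonal) solve
            out.n_degenerate++;
            Sw.diag() += arma::trace(Sw) / d + 1e-8;
            w = arma::solve(Sw, delta);
        }
        const double nw = arma::norm(w);
        if (nw <= 0) continue;
        w /= nw;
        const double dproj = arma::dot(delta, w);
        eff += 0.5 * (arma::abs(w * dproj) + arma::abs(delta));
    }
    eff /= n_boot;
    out.lda_log10 = arma::log10(1.0 + scaling * eff);

    // enrichment direction from the raw class means on the full fold data
    arma::vec m0 = arma::mean(X.submat(out.screened, idx0), 1);
    arma::vec m1 = arma::mean(X.submat(out.screened, idx1), 1);
    out.enriched = arma::conv_to<arma::ivec>::from(m1 > m0);

    arma::uvec sel = arma::find(out.lda_log10 >= lda_threshold);
    std::vector<arma::uword> pos, neg;
    for (arma::uword i = 0; i < sel.n_elem; ++i) {
        arma::uword s = sel[i];
        if (out.enriched[s] == 1) pos.push_back(out.screened[s]);
        else                      neg.push_back(out.screened[s]);
    }
    out.pos = arma::uvec(pos);
    out.neg = arma::uvec(neg);
    return out;
}

// Positive and negative sums are accumulated separately and subtracted once
// so that swapping the two taxon sets negates the index bit-exactly.
static double risk_index_col(const arma::mat& X, int col,
                             const arma::uvec& pos, const arma::uvec& neg) {
    double sp = 0.0, sn = 0.0;
    for (arma::uword i = 0; i < pos.n_elem; ++i)
        sp += std::asin(std::sqrt(X(pos[i], col)));
    for (arma::uword i = 0; i < neg.n_elem; ++i)
        sn += std::asin(std::sqrt(X(neg[i], col)));
    return sp - sn;
}

// [[Rcpp::export(name = ".cppFitDiscriminant")]]
List cppFitDiscriminant(const arma::mat& X, const arma::ivec& grp,
                        double kw_alpha, double lda_threshold,
                        int n_boot, double boot_frac,
                        double scaling, double ridge) {
    FitResult f = fit_discriminant(X, grp, kw_alpha, lda_threshold,
                                   n_boot, boot_frac, scaling, ridge);
    return List::create(
        _["kw_p"] = NumericVector(f.kw_p.begin(), f.kw_p.end()),
        _["screened"] = IntegerVector(f.screened.begin(), f.screened.end()),
        _["lda_log10"] = NumericVector(f.lda_log10.begin(), f.lda_log10.end()),
        _["enriched"] = IntegerVector(f.enriched.begin(), f.enriched.end()),
        _["pos"] = IntegerVector(f.pos.begin(), f.pos.end()),
        _["neg"] = IntegerVector(f.neg.begin(), f.neg.end()),
        _["n_degenerate"] = f.n_degenerate);
}

// Full leave-one-out run: for each sample i, refit the discriminant model on
// the other n-1 samples and score sample i. Optionally also returns, per
// fold, the training-sample risk indices (for cutoff refinement).
// [[Rcpp::export(name = ".cppLooRisk")]]
List cppLooRisk(const arma::mat& X, const arma::ivec& grp,
                double kw_alpha, double lda_threshold,
                int n_boot, double boot_frac,
                double scaling, double ridge, bool return_train) {
    const int N = X.n_cols;
    NumericVector ri(N, NA_REAL);
    IntegerVector ntaxa(N, 0);
    List train_scores(return_train ? N : 0);
    List fold_pos(N), fold_neg(N);

    for (int i = 0; i < N; ++i) {
        arma::uvec keep(N - 1);
        arma::ivec g(N - 1);
        int k = 0;
        for (int j = 0; j < N; ++j) {
            if (j == i) continue;
            keep[k] = j;
            g[k] = grp[j];
            ++k;
        }
        arma::mat Xf = X.cols(keep);
        FitResult f = fit_discriminant(Xf, g, kw_alpha, lda_threshold,
                                       n_boot, boot_frac, scaling, ridge);
        ntaxa[i] = f.pos.n_elem + f.neg.n_elem;
        fold_pos[i] = IntegerVector(f.pos.begin(), f.pos.end());
        fold_neg[i] = IntegerVector(f.neg.begin(), f.neg.end());
        if (ntaxa[i] > 0) {
            ri[i] = risk_index_col(X, i, f.pos, f.neg);
            if (return_train) {
                NumericVector ts(N - 1);
                for (int j = 0; j < N - 1; ++j)
                    ts[j] = risk_index_col(Xf, j, f.pos, f.neg);
                train_scores[i] = ts;
            }
        } else if (return_train) {
            train_scores[i] = NumericVector(0);
        }
    }
    return List::create(_["ri"] = ri, _["n_taxa"] = ntaxa,
                        _["pos"] = fold_pos, _["neg"] = fold_neg,
                        _["train_scores"] = train_scores);
}
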
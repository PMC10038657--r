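#include <Rcpp.h>
using namespace Rcpp;

// Diploid dosage-state transition matrix for the single-pulse ancestry model.
// Haploid chain: Q(d) = e^{-dT} I + (1 - e^{-dT}) Pi with stationary row
// (alpha, 1 - alpha) over (specialist, generalist); the diploid matrix is the
// product chain of two independent haploids collapsed to dosage {0, 1, 2}
// (number of specialist copies). State order: dosage 0, 1, 2.
static inline void diploid_transition(double d, double T, double alpha,
                                      double P[3][3]) {
    double e = std::exp(-d * T);
    double qss = e + (1.0 - e) * alpha;        // specialist -> specialist
    double qsg = (1.0 - e) * (1.0 - alpha);    // specialist -> generalist
    double qgs = (1.0 - e) * alpha;            // generalist -> specialist
    double qgg = e + (1.0 - e) * (1.0 - alpha);
    P[0][0] = qgg * qgg;       P[0][1] = 2.0 * qgg * qgs;           P[0][2] = qgs * qgs;
    P[1][0] = qsg * qgg;       P[1][1] = qss * qgg + qsg * qgs;     P[1][2] = qss * qgs;
    P[2][0] = qsg * qsg;       P[2][1] = 2.0 * qss * qsg;           P[2][2] = qss * qss;
}

static inline void stationary(double alpha, double pi[3]) {
    pi[0] = (1.0 - alpha) * (1.0 - alpha);
    pi[1] = 2.0 * alpha * (1.0 - alpha);
    pi[2] = alpha * alpha;
}

// [[Rcpp::export]]
NumericMatrix cpp_diploid_transition(double d, double T, double alpha) {
    double P[3][3];
    diploid_transition(d, T, alpha, P);
    NumericMatrix out(3, 3);
    for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) out(i, j) = P[i][j];
    return out;
}

// Scaled forward pass over several individuals sharing one site grid.
// E: list of n x 3 emission matrices (one per individual); d: genetic
// distance (Morgans) from the previous site (ignored where new_chrom is
// TRUE, which restarts the chain at the stationary distribution).
// [[Rcpp::export]]
double cpp_forward_loglik(List E, NumericVector d, LogicalVector new_chrom,
                          double T, double alpha) {
    int n_ind = E.size();
    if (n_ind == 0) return 0.0;
    NumericMatrix e0 = E[0];
    int n = e0.nrow();
    std::vector<NumericMatrix> em;
    em.reserve(n_ind);
    for (int k = 0; k < n_ind; ++k) em.push_back(as<NumericMatrix>(E[k]));
    double pi[3];
    stationary(alpha, pi);
    std::vector<double> F(n_ind * 3);
    double loglik = 0.0;
    double P[3][3];
    for (int i = 0; i < n; ++i) {
        bool restart = new_chrom[i];
        if (!restart) diploid_transition(d[i], T, alpha, P);
        for (int k = 0; k < n_ind; ++k) {
            double* f = &F[3 * k];
            double a0, a1, a2;
            if (restart) {
                a0 = pi[0]; a1 = pi[1]; a2 = pi[2];
            } else {
                a0 = f[0] * P[0][0] + f[1] * P[1][0] + f[2] * P[2][0];
                a1 = f[0] * P[0][1] + f[1] * P[1][1] + f[2] * P[2][1];
                a2 = f[0] * P[0][2] + f[1] * P[1][2] + f[2] * P[2][2];
            }
            a0 *= em[k](i, 0); a1 *= em[k](i, 1); a2 *= em[k](i, 2);
            double s = a0 + a1 + a2;
            if (s <= 0.0 || !std::isfinite(s))
                stop("non-finite likelihood at site %d", i + 1);
            f[0] = a0 / s; f[1] = a1 / s; f[2] = a2 / s;
            loglik += std::log(s);
        }
    }
    return loglik;
}

// Forward-backward posteriors for one individual, with per-site scaling.
// [[Rcpp::export]]
List cpp_forward_backward(NumericMatrix E, NumericVector d,
                          LogicalVector new_chrom, double T, double alpha) {
    int n = E.nrow();
    NumericMatrix F(n, 3), B(n, 3);
    NumericVector scale(n);
    double pi[3];
    stationary(alpha, pi);
    double P[3][3];
    double loglik = 0.0;
    for (int i = 0; i < n; ++i) {
        double a[3];
        if (new_chrom[i]) {
            for (int s = 0; s < 3; ++s) a[s] = pi[s];
        } else {
            diploid_transition(d[i], T, alpha, P);
            for (int s = 0; s < 3; ++s)
                a[s] = F(i - 1, 0) * P[0][s] + F(i - 1, 1) * P[1][s] + F(i - 1, 2) * P[2][s];
        }
        double tot = 0.0;
        for (int s = 0; s < 3; ++s) { a[s] *= E(i, s); tot += a[s]; }
        if (tot <= 0.0 || !std::isfinite(tot))
            stop("non-finite likelihood at site %d", i + 1);
        for (int s = 0; s < 3; ++s) F(i, s) = a[s] / tot;
        scale[i] = tot;
        loglik += std::log(tot);
    }
    for (int s = 0; s < 3; ++s) B(n - 1, s) = 1.0;
    for (int i = n - 2; i >= 0; --i) {
        if (new_chrom[i + 1]) {
            // next site starts a fresh chain: it does not constrain site i
            for (int s = 0; s < 3; ++s) B(i, s) = 1.0;
        } else {
            diploid_transition(d[i + 1], T, alpha, P);
            for (int s = 0; s < 3; ++s) {
                double b = 0.0;
                for (int t = 0; t < 3; ++t)
                    b += P[s][t] * E(i + 1, t) * B(i + 1, t);
                B(i, s) = b / scale[i + 1];
            }
        }
    }
    NumericMatrix post(n, 3);
    for (int i = 0; i < n; ++i) {
        double tot = 0.0;
        for (int s = 0; s < 3; ++s) { post(i, s) = F(i, s) * B(i, s); tot += post(i, s); }
        for (int s = 0; s < 3; ++s) post(i, s) /= tot;
    }
    return List::create(_["posteriors"] = post, _["loglik"] = loglik);
}

// Viterbi decoding for one individual; ties broken toward lower dosage.
// [[Rcpp::export]]
List cpp_viterbi(NumericMatrix E, NumericVector d, LogicalVector new_chrom,
                 double T, double alpha) {
    int n = E.nrow();
    NumericMatrix V(n, 3);
    IntegerMatrix ptr(n, 3);
    double pi[3];
    stationary(alpha, pi);
    double P[3][3];
    const double NEG_INF = -std::numeric_limits<double>::infinity();
    for (int i = 0; i < n; ++i) {
        bool restart = new_chrom[i];
        double carry = 0.0;
        if (restart && i > 0) {
            // chain restarts: carry the best score of the previous chromosome
            carry = std::max(V(i - 1, 0), std::max(V(i - 1, 1), V(i - 1, 2)));
        }
        if (!restart) diploid_transition(d[i], T, alpha, P);
        for (int s = 0; s < 3; ++s) {
            double loge = E(i, s) > 0.0 ? std::log(E(i, s)) : NEG_INF;
            if (restart) {
                double logpi = pi[s] > 0.0 ? std::log(pi[s]) : NEG_INF;
                V(i, s) = carry + logpi + loge;
                ptr(i, s) = -1;
            } else {
                double best = NEG_INF;
                int arg = 0;
                for (int t = 0; t < 3; ++t) {  // ascending: ties keep lower dosage
                    double cand = V(i - 1, t) +
                        (P[t][s] > 0.0 ? std::log(P[t][s]) : NEG_INF);
                    if (cand > best) { best = cand; arg = t; }
                }
                V(i, s) = best + loge;
                ptr(i, s) = arg;
            }
        }
    }
    IntegerVector path(n);
    // backtrack chromosome by chromosome (restart sites have ptr -1)
    int last = n - 1;
    while (last >= 0) {
        int first = last;
        while (first > 0 && ptr(first, 0) != -1) --first;
        // pick best end state of this chromosome segment, ties toward lower dosage
        int s = 0;
        for (int t = 1; t < 3; ++t) if (V(last, t) > V(last, s)) s = t;
        for (int i = last; i > first; --i) {
            path[i] = s;
            s = ptr(i, s);
        }
        path[first] = s;
        last = first - 1;
    }
    double best_end = std::max(V(n - 1, 0), std::max(V(n - 1, 1), V(n - 1, 2)));
    return List::create(_["path"] = path, _["logprob"] = best_end);
}
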
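#include <Rcpp.h>
#include <random>
#include <cmath>

// Two-step Heun (predictor/corrector) integration of the dimensionless
// rotational Langevin equation for a dipole orientation m on the unit sphere:
//
//   dm = (xi0/2Omega) m x (cos(2 pi t*) zhat x m) dt*  +  m x dW / sqrt(Omega)
//
// Heun converges to the Stratonovich solution for this multiplicative noise,
// which is what makes the static-field stationary distribution Boltzmann
// (mean m_z -> Langevin function).  The same Gaussian 3-vector is used in the
// predictor and the corrector of one step; m is renormalized to unit length
// after each accepted step (the continuous dynamics conserve |m| exactly).

namespace {

// a x (h zhat x a) = h * ( zhat*(a.a) - a*a_z )  -- valid for non-unit a
inline void field_torque(const double a[3], double h, double out[3]) {
    const double aa = a[0] * a[0] + a[1] * a[1] + a[2] * a[2];
    out[0] = -h * a[0] * a[2];
    out[1] = -h * a[1] * a[2];
    out[2] = h * (aa - a[2] * a[2]);
}

inline void cross(const double a[3], const double b[3], double out[3]) {
    out[0] = a[1] * b[2] - a[2] * b[1];
    out[1] = a[2] * b[0] - a[0] * b[2];
    out[2] = a[0] * b[1] - a[1] * b[0];
}

// One Heun step.  ratio = xi0/Omega (computed once so that scaling (xi0,
// Omega) by a common power of two leaves the arithmetic bit-identical),
// s = sqrt(dt/Omega), c_now/c_next = cos(2 pi t*) at the step endpoints.
// noise N is a standard Gaussian 3-vector (zeros for deterministic runs).
// Returns false if the corrector collapses to the origin (pathological).
inline bool heun_one(double m[3], double dt, double ratio, double s,
                     double c_now, double c_next, const double N[3]) {
    const double pref_p = 0.5 * ratio * dt;  // predictor drift prefactor
    const double pref_c = 0.25 * ratio * dt; // corrector drift prefactor

    double drift0[3], mxN[3], mbar[3];
    field_torque(m, c_now, drift0);
    cross(m, N, mxN);
    for (int k = 0; k < 3; ++k)
        mbar[k] = m[k] + pref_p * drift0[k] + s * mxN[k];

    double drift1[3], msumxN[3];
    field_torque(mbar, c_next, drift1);
    const double msum[3] = {m[0] + mbar[0], m[1] + mbar[1], m[2] + mbar[2]};
    cross(msum, N, msumxN);

    double out[3];
    for (int k = 0; k < 3; ++k)
        out[k] = m[k] + pref_c * (drift1[k] + drift0[k]) + 0.5 * s * msumxN[k];

    const double nrm = std::sqrt(out[0] * out[0] + out[1] * out[1] + out[2] * out[2]);
    if (nrm == 0.0) return false;
    m[0] = out[0] / nrm;
    m[1] = out[1] / nrm;
    m[2] = out[2] / nrm;
    return true;
}

} // namespace

//' @noRd
// [[Rcpp::export]]
Rcpp::NumericVector heun_step_cpp(Rcpp::NumericVector m, double t_star,
                                  double dt_star, double xi0, double omega,
                                  Rcpp::NumericVector noise,
                                  bool static_field = false) {
    if (m.size() != 3 || noise.size() != 3)
        Rcpp::stop("m and noise must be 3-vectors");
    if (omega <= 0) Rcpp::stop("omega must be positive");
    double mm[3] = {m[0], m[1], m[2]};
    double N[3] = {noise[0], noise[1], noise[2]};
    const double c_now = static_field ? 1.0 : std::cos(2.0 * M_PI * t_star);
    const double c_next =
        static_field ? 1.0 : std::cos(2.0 * M_PI * (t_star + dt_star));
    const double s = std::sqrt(dt_star / omega);
    if (!heun_one(mm, dt_star, xi0 / omega, s, c_now, c_next, N))
        Rcpp::stop("Heun step failure: corrector collapsed to zero vector");
    return Rcpp::NumericVector::create(mm[0], mm[1], mm[2]);
}

//' @noRd
// [[Rcpp::export]]
Rcpp::List heun_simulate_cpp(Rcpp::NumericMatrix m0, Rcpp::NumericVector xi0,
                             Rcpp::NumericVector omega, double dt_star,
                             int steps_transient, int steps_record, bool noise,
                             bool static_field, int seed) {
    const int n = m0.nrow();
    if (m0.ncol() != 3) Rcpp::stop("m0 must be an n x 3 matrix");
    if (xi0.size() != n || omega.size() != n)
        Rcpp::stop("xi0 and omega must have one entry per particle");
    if (dt_star <= 0) Rcpp::stop("dt_star must be positive");
    if (steps_record < 1) Rcpp::stop("need at least one recorded step");
    for (int i = 0; i < n; ++i)
        if (omega[i] <= 0) Rcpp::stop("all omega must be positive");

    const int total = steps_transient + steps_record;

    // cos(2 pi t*) at each step boundary, shared across particles
    std::vector<double> ctab(total + 1, 1.0);
    if (!static_field)
        for (int j = 0; j <= total; ++j)
            ctab[j] = std::cos(2.0 * M_PI * (double)j * dt_star);

    std::vector<double> sum_mz(steps_record, 0.0);
    std::vector<double> sumsq_mz(steps_record, 0.0);

    std::mt19937_64 rng((uint64_t)(uint32_t)seed);
    std::normal_distribution<double> gauss(0.0, 1.0);

    const double zeroN[3] = {0.0, 0.0, 0.0};
    for (int i = 0; i < n; ++i) {
        double m[3] = {m0(i, 0), m0(i, 1), m0(i, 2)};
        const double ratio = xi0[i] / omega[i];
        const double s = std::sqrt(dt_star / omega[i]);
        for (int j = 0; j < total; ++j) {
            if (j >= steps_transient) {
                const int r = j - steps_transient;
                sum_mz[r] += m[2];
                sumsq_mz[r] += m[2] * m[2];
            }
            double N[3];
            const double *Np = zeroN;
            if (noise) {
                N[0] = gauss(rng);
                N[1] = gauss(rng);
                N[2] = gauss(rng);
                Np = N;
            }
            if (!heun_one(m, dt_star, ratio, s, ctab[j], ctab[j + 1], Np))
                Rcpp::stop("Heun step failure at particle %d, step %d", i + 1,
                           j + 1);
        }
    }

    return Rcpp::List::create(
        Rcpp::Named("sum_mz") = Rcpp::NumericVector(sum_mz.begin(), sum_mz.end()),
        Rcpp::Named("sumsq_mz") =
            Rcpp::NumericVector(sumsq_mz.begin(), sumsq_mz.end()),
        Rcpp::Named("n") = n);
}
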
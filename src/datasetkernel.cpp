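// Whole-dataset kernels: one call evaluates the joint marginal
// log-likelihood (or its analytic score) for every subject.  The constant
// design pieces are prepared once per fit on the R side and passed as a
// nested list of no-copy views; only the current parameter values change
// between calls.
//
// Per subject: the marker marginal log-density and random-effects
// posterior via q x q Woodbury identities, the pseudo-adaptive
// Gauss-Hermite node matrix b = mu + sqrt(2) U^{-1} A', the conditional
// log-likelihood of the visiting process (optionally gamma-frailty
// marginalized) and the cause-specific blocks across all nodes, a
// log-sum-exp marginalization, and -- for the score -- the complete-data
// score averaged with the normalized posterior node weights.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat mview(SEXP s) {
  NumericMatrix m(s);
  return arma::mat(const_cast<double*>(m.begin()), m.nrow(), m.ncol(),
                   false, true);
}
static arma::vec vview(SEXP s) {
  NumericVector v(s);
  return arma::vec(const_cast<double*>(v.begin()), v.size(), false, true);
}

struct BlockPar {
  arma::vec psi, coef;
  double a1, a2;
};

struct BlockWork {
  arma::mat Hb, qSl, evSl;
  arma::vec e1, evSum, Lam, qFix, qSlFix, evFix, evSlFix;
  int dcount;
  bool isVisit;
  arma::uword G, d;
};

static void evalBlock(const List& cb, const BlockPar& bp,
                      const arma::mat& Bmat, const arma::vec& m0,
                      const arma::vec& beta, BlockWork& w) {
  const arma::uword M = Bmat.n_cols;
  w.dcount = as<int>(cb["dcount"]);
  w.isVisit = as<bool>(cb["isVisit"]);
  arma::vec qw = vview(cb["qw"]);
  w.G = qw.n_elem;
  w.d = as<int>(cb["nev"]);
  w.e1 = arma::exp(bp.a1 * m0);
  w.evSum.zeros(M);
  w.Lam.zeros(M);
  if (w.d > 0) {
    arma::mat evB = mview(cb["evB"]), evXd = mview(cb["evXd"]),
      evZd = mview(cb["evZd"]);
    w.evSlFix = evXd * beta;
    w.evFix = evB * bp.psi + bp.a2 * w.evSlFix;
    if (bp.coef.n_elem > 0) w.evFix += mview(cb["evF"]) * bp.coef;
    w.evSl = evZd * Bmat;
    w.evSum = arma::accu(w.evFix) + bp.a2 * arma::sum(w.evSl, 0).t() +
      double(w.d) * bp.a1 * m0;
  } else {
    w.evSl.set_size(0, M);
  }
  if (w.G > 0) {
    arma::mat qB = mview(cb["qB"]), qXd = mview(cb["qXd"]),
      qZd = mview(cb["qZd"]);
    w.qSlFix = qXd * beta;
    w.qFix = qB * bp.psi + bp.a2 * w.qSlFix;
    if (bp.coef.n_elem > 0) w.qFix += mview(cb["qF"]) * bp.coef;
    w.qSl = qZd * Bmat;
    arma::mat lh = bp.a2 * w.qSl;
    lh.each_col() += w.qFix;
    w.Hb = arma::exp(lh);
    w.Lam = (w.Hb.t() * qw) % w.e1;
  } else {
    w.Hb.set_size(0, M);
    w.qSl.set_size(0, M);
  }
}

struct MarkerStats {
  double llY;
  arma::vec mu, r0;
  arma::mat U;
};

static MarkerStats markerStats(const List& sub, const arma::vec& beta,
                               const arma::mat& Dinv, double logdetD,
                               double sigma2) {
  MarkerStats ms;
  arma::vec y = vview(sub["y"]);
  arma::mat X = mview(sub["X"]), Z = mview(sub["Z"]),
    ZtZ = mview(sub["ZtZ"]);
  ms.r0 = y - X * beta;
  arma::vec Zr = Z.t() * ms.r0;
  arma::mat Cinv = Dinv + ZtZ / sigma2;
  ms.U = arma::chol(Cinv);
  arma::vec w1 = arma::solve(arma::trimatl(ms.U.t()), Zr);
  double quad = (arma::dot(ms.r0, ms.r0) - arma::dot(w1, w1) / sigma2) /
    sigma2;
  double n = double(y.n_elem);
  ms.llY = -0.5 * (n * std::log(2.0 * arma::datum::pi * sigma2) + logdetD +
                   2.0 * arma::accu(arma::log(ms.U.diag())) + quad);
  ms.mu = arma::solve(arma::trimatu(ms.U), w1) / sigma2;
  return ms;
}

static std::vector<BlockPar> readPars(const List& bpars) {
  std::vector<BlockPar> out(bpars.size());
  for (R_xlen_t b = 0; b < bpars.size(); ++b) {
    List p = bpars[b];
    out[b].psi = as<arma::vec>(p["psi"]);
    out[b].coef = as<arma::vec>(p["coef"]);
    out[b].a1 = as<double>(p["a1"]);
    out[b].a2 = as<double>(p["a2"]);
  }
  return out;
}

static arma::vec condLL(const std::vector<BlockWork>& works, double eta,
                        arma::uword M) {
  arma::vec ll(M, arma::fill::zeros);
  for (size_t b = 0; b < works.size(); ++b) {
    const BlockWork& w = works[b];
    if (w.isVisit) {
      if (eta > 0) {
        double nu = 1.0 / eta;
        ll += w.evSum + std::lgamma(nu + w.dcount) - std::lgamma(nu) +
          nu * std::log(nu) - (nu + w.dcount) * arma::log(nu + w.Lam);
      } else {
        ll += w.evSum - w.Lam;
      }
    } else {
      ll += double(w.dcount) * w.evSum - w.Lam;
    }
  }
  return ll;
}

// complete-data marker + random-effects log density at fixed nodes,
// minus the (fixed) log importance density: the anchored route
static arma::vec anchoredMarkerLL(const List& sub, const arma::mat& Bmat,
                                  const arma::vec& logg,
                                  const arma::vec& beta,
                                  const arma::mat& Dinv, double logdetD,
                                  double sigma2) {
  arma::vec y = vview(sub["y"]);
  arma::mat X = mview(sub["X"]), Z = mview(sub["Z"]);
  const double n = double(y.n_elem);
  const arma::uword q = Dinv.n_rows;
  arma::vec r0 = y - X * beta;
  arma::mat ZB = Z * Bmat;                       // n x M
  arma::vec cross = ZB.t() * r0;                 // M
  arma::vec zb2 = arma::sum(ZB % ZB, 0).t();     // M
  arma::vec quad = (arma::dot(r0, r0) - 2.0 * cross + zb2) / sigma2;
  arma::mat DB = Dinv * Bmat;
  arma::vec bq = arma::sum(Bmat % DB, 0).t();
  return -0.5 * (n * std::log(2.0 * arma::datum::pi * sigma2) + quad) -
    0.5 * (double(q) * std::log(2.0 * arma::datum::pi) + logdetD + bq) -
    logg;
}

// [[Rcpp::export(name = ".datasetLLCpp")]]
NumericVector datasetLLCpp(List subs, const NumericVector& betaR,
                           const NumericMatrix& DinvR, double logdetD,
                           double sigma2, List bpars, double eta,
                           const NumericVector& logwR,
                           const NumericMatrix& tAR,
                           Nullable<List> anchorR = R_NilValue) {
  arma::vec beta = vview(betaR), logw = vview(logwR);
  arma::mat Dinv = mview(DinvR), tA = mview(tAR);
  std::vector<BlockPar> pars = readPars(bpars);
  bool anchored = anchorR.isNotNull();
  List anchor;
  if (anchored) anchor = anchorR.get();
  R_xlen_t N = subs.size();
  NumericVector out(N);
  for (R_xlen_t i = 0; i < N; ++i) {
    List sub = subs[i];
    arma::mat Bmat;
    double llY = 0.0;
    arma::vec extra;
    if (anchored) {
      List an = anchor[i];
      Bmat = mview(an["B"]);
      extra = anchoredMarkerLL(sub, Bmat, vview(an["logg"]), beta, Dinv,
                               logdetD, sigma2);
    } else {
      MarkerStats ms = markerStats(sub, beta, Dinv, logdetD, sigma2);
      Bmat = arma::solve(arma::trimatu(ms.U), tA);
      Bmat.each_col() += ms.mu;
      llY = ms.llY;
      extra = arma::vec(Bmat.n_cols, arma::fill::zeros);
    }
    arma::vec X0 = vview(sub["X0"]), Z0 = vview(sub["Z0"]);
    arma::vec m0 = (Bmat.t() * Z0) + arma::dot(X0, beta);
    List cblocks = sub["cblocks"];
    std::vector<BlockWork> works(cblocks.size());
    for (R_xlen_t b = 0; b < cblocks.size(); ++b)
      evalBlock(cblocks[b], pars[b], Bmat, m0, beta, works[b]);
    arma::vec lw = logw + extra + condLL(works, eta, Bmat.n_cols);
    double mx = lw.max();
    out[i] = std::isfinite(mx)
      ? llY + mx + std::log(arma::accu(arma::exp(lw - mx)))
      : -arma::datum::inf;
  }
  return out;
}

// [[Rcpp::export(name = ".datasetScoreCpp")]]
List datasetScoreCpp(List subs, const NumericVector& betaR,
                     const NumericMatrix& DinvR, double logdetD,
                     double sigma2, List bpars, double eta,
                     const NumericVector& logwR,
                     const NumericMatrix& tAR,
                     Nullable<List> anchorR = R_NilValue) {
  arma::vec beta = vview(betaR), logw = vview(logwR);
  arma::mat Dinv = mview(DinvR), tA = mview(tAR);
  std::vector<BlockPar> pars = readPars(bpars);
  bool anchored = anchorR.isNotNull();
  List anchor;
  if (anchored) anchor = anchorR.get();
  R_xlen_t N = subs.size();
  size_t nb = pars.size();
  const arma::uword p = beta.n_elem, q = Dinv.n_rows;
  arma::vec gBeta(p, arma::fill::zeros);
  double gLogSig = 0.0, gEta = 0.0;
  arma::mat GD(q, q, arma::fill::zeros);
  // per-block accumulators
  std::vector<arma::vec> gPsi(nb), gCoef(nb);
  arma::vec gA1(nb, arma::fill::zeros), gA2(nb, arma::fill::zeros);
  for (size_t b = 0; b < nb; ++b) {
    gPsi[b] = arma::vec(pars[b].psi.n_elem, arma::fill::zeros);
    gCoef[b] = arma::vec(pars[b].coef.n_elem, arma::fill::zeros);
  }
  for (R_xlen_t i = 0; i < N; ++i) {
    List sub = subs[i];
    arma::mat Bmat;
    arma::vec extra, r0;
    if (anchored) {
      List an = anchor[i];
      Bmat = mview(an["B"]);
      extra = anchoredMarkerLL(sub, Bmat, vview(an["logg"]), beta, Dinv,
                               logdetD, sigma2);
      arma::vec y = vview(sub["y"]);
      arma::mat X = mview(sub["X"]);
      r0 = y - X * beta;
    } else {
      MarkerStats ms = markerStats(sub, beta, Dinv, logdetD, sigma2);
      Bmat = arma::solve(arma::trimatu(ms.U), tA);
      Bmat.each_col() += ms.mu;
      extra = arma::vec(Bmat.n_cols, arma::fill::zeros);
      r0 = ms.r0;
    }
    arma::vec X0 = vview(sub["X0"]), Z0 = vview(sub["Z0"]);
    arma::vec m0 = (Bmat.t() * Z0) + arma::dot(X0, beta);
    List cblocks = sub["cblocks"];
    std::vector<BlockWork> works(nb);
    for (size_t b = 0; b < nb; ++b)
      evalBlock(cblocks[b], pars[b], Bmat, m0, beta, works[b]);
    arma::vec lw = logw + extra + condLL(works, eta, Bmat.n_cols);
    double mx = lw.max();
    if (!std::isfinite(mx))
      stop("all quadrature nodes underflowed in the score");
    double logI = mx + std::log(arma::accu(arma::exp(lw - mx)));
    arma::vec w = arma::exp(lw - logI);
    // marker block
    arma::vec bbar = Bmat * w;
    arma::mat Bw = Bmat;
    Bw.each_row() %= w.t();
    arma::mat S2 = Bw * Bmat.t();
    arma::mat X = mview(sub["X"]), Z = mview(sub["Z"]),
      ZtZ = mview(sub["ZtZ"]);
    arma::vec Zb = Z * bbar;
    gBeta += X.t() * (r0 - Zb) / sigma2;
    double Erss = arma::dot(r0, r0) - 2.0 * arma::dot(r0, Zb) +
      arma::accu(ZtZ % S2);
    gLogSig += -0.5 * double(r0.n_elem) + Erss / (2.0 * sigma2);
    GD += -0.5 * (Dinv - Dinv * S2 * Dinv);
    // hazard blocks
    for (size_t b = 0; b < nb; ++b) {
      BlockWork& bw = works[b];
      List cb = cblocks[b];
      double dcount = double(bw.dcount);
      arma::vec cvec(w.n_elem, arma::fill::ones);
      if (bw.isVisit && eta > 0) {
        double nu = 1.0 / eta;
        cvec = (nu + dcount) / (nu + bw.Lam);
        arma::vec dnu = R::digamma(nu + dcount) - R::digamma(nu) +
          std::log(nu) + 1.0 - arma::log(nu + bw.Lam) -
          (nu + dcount) / (nu + bw.Lam);
        gEta += -nu * arma::dot(w, dnu);
      }
      arma::vec wce = w % cvec % bw.e1;
      double LamW = arma::dot(w % cvec, bw.Lam);
      double evScale = (bw.d > 0 && bw.dcount > 0)
        ? dcount / double(bw.d) : 0.0;
      if (bw.G > 0) {
        arma::vec qw = vview(cb["qw"]);
        arma::mat qB = mview(cb["qB"]), qXd = mview(cb["qXd"]);
        arma::vec hbarC = bw.Hb * wce;
        arma::vec qwh = qw % hbarC;
        gPsi[b] -= qB.t() * qwh;
        if (pars[b].coef.n_elem > 0)
          gCoef[b] -= mview(cb["qF"]).t() * qwh;
        gA2[b] -= arma::dot(bw.qSlFix, qwh) +
          arma::dot(qw, (bw.Hb % bw.qSl) * wce);
        gBeta -= pars[b].a2 * (qXd.t() * qwh);
      }
      if (evScale > 0.0) {
        gPsi[b] += evScale * vview(cb["evBsum"]);
        if (pars[b].coef.n_elem > 0)
          gCoef[b] += evScale * vview(cb["evFsum"]);
        gA2[b] += evScale *
          (arma::accu(bw.evSlFix) + arma::accu(bw.evSl * w));
        gBeta += pars[b].a2 * evScale * vview(cb["evXdsum"]);
      }
      gA1[b] += dcount * arma::dot(w, m0) -
        arma::dot(w % cvec % m0, bw.Lam);
      gBeta += pars[b].a1 * (dcount - LamW) * X0;
    }
  }
  List psiOut(nb), coefOut(nb);
  for (size_t b = 0; b < nb; ++b) {
    psiOut[b] = wrap(gPsi[b]);
    coefOut[b] = wrap(gCoef[b]);
  }
  return List::create(_["gBeta"] = gBeta, _["gLogSig"] = gLogSig,
                      _["GD"] = GD, _["gPsi"] = psiOut,
                      _["gCoef"] = coefOut, _["gA1"] = gA1,
                      _["gA2"] = gA2, _["gEta"] = gEta);
}
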
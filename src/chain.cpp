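// Core numerical kernels: CTMC branch propagation, Felsenstein pruning,
// and the Metropolis-Hastings / reversible-jump chain over rate partitions.
// Rate models are passed in as a cell map (off-diagonal cells of Q, each
// tied to one free rate), so the same kernel serves 2-state Mk models,
// 4-state trait-pair models and constrained variants.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Propagator {
  // exp(Q t) applied via eigendecomposition when well-conditioned,
  // scaling-and-squaring fallback otherwise; closed form for 2 states.
  arma::mat Q;
  int k;
  bool closed2 = false, eig_ok = false, real_eig = false;
  double q01 = 0.0, q10 = 0.0;
  arma::cx_mat U, Uinv;
  arma::cx_vec lam;
  arma::mat Ur, Uinvr;  // real fast path (spectra are usually real here)
  arma::vec lamr;

  void init(const arma::mat& Qin) {
    Q = Qin;
    k = Q.n_rows;
    closed2 = (k == 2);
    eig_ok = false;
    if (closed2) {
      q01 = Q(0, 1);
      q10 = Q(1, 0);
      return;
    }
    arma::cx_vec l;
    arma::cx_mat V;
    if (arma::eig_gen(l, V, Q)) {
      arma::cx_mat Vi;
      if (arma::inv(Vi, V)) {
        arma::mat rec = arma::real(V * arma::diagmat(l) * Vi);
        double scale = std::max(1.0, arma::norm(Q, "inf"));
        if (arma::norm(rec - Q, "inf") < 1e-9 * scale) {
          U = V; Uinv = Vi; lam = l; eig_ok = true;
          if (arma::norm(arma::imag(l), "inf") < 1e-12 * scale &&
              arma::norm(arma::imag(V), "inf") < 1e-12) {
            Ur = arma::real(V); Uinvr = arma::real(Vi);
            lamr = arma::real(l); real_eig = true;
          }
        }
      }
    }
  }

  arma::mat pmat(double t) const {
    arma::mat P;
    if (closed2) {
      P.set_size(2, 2);
      double s = q01 + q10;
      if (s <= 0.0) {
        P.eye(2, 2);
      } else {
        double E = std::exp(-s * t);
        double pi1 = q01 / s;
        P(0, 0) = 1.0 - pi1 * (1.0 - E);
        P(0, 1) = pi1 * (1.0 - E);
        P(1, 0) = (1.0 - pi1) * (1.0 - E);
        P(1, 1) = 1.0 - (1.0 - pi1) * (1.0 - E);
      }
    } else if (real_eig) {
      P = Ur * arma::diagmat(arma::exp(lamr * t)) * Uinvr;
    } else if (eig_ok) {
      P = arma::real(U * arma::diagmat(arma::exp(lam * t)) * Uinv);
    } else {
      P = arma::expmat(Q * t);
    }
    P.clamp(0.0, 1.0);
    return P;
  }

  arma::vec pvec(double t, const arma::vec& v) const {
    if (real_eig) {
      arma::vec w = Uinvr * v;
      w %= arma::exp(lamr * t);
      arma::vec out = Ur * w;
      out.clamp(0.0, arma::datum::inf);
      return out;
    }
    if (closed2 || !eig_ok) {
      arma::vec w = pmat(t) * v;
      w.clamp(0.0, arma::datum::inf);
      return w;
    }
    arma::cx_vec w = Uinv * arma::cx_vec(v, arma::vec(v.n_elem, arma::fill::zeros));
    w %= arma::exp(lam * t);
    arma::vec out = arma::real(U * w);
    out.clamp(0.0, arma::datum::inf);
    return out;
  }
};

// Pruning over a postorder edge list (0-based node ids; tips 0..ntip-1).
// Partial-likelihood rows are rescaled per node; per-node scaling cancels
// in conditional node-state sampling so only the summed log-scale is kept.
double prune_loglik(const arma::umat& edge, const arma::vec& elen, int ntip,
                    int nnode_tot, int root, const arma::mat& tip_part,
                    const Propagator& pg, const arma::vec& rootp,
                    arma::mat* keep_part) {
  int k = rootp.n_elem;
  arma::mat part(nnode_tot, k);
  part.rows(0, ntip - 1) = tip_part;
  for (int i = ntip; i < nnode_tot; ++i) part.row(i).ones();
  double logscale = 0.0;
  for (arma::uword e = 0; e < edge.n_rows; ++e) {
    int par = edge(e, 0), ch = edge(e, 1);
    arma::vec v = part.row(ch).t();
    if (ch >= ntip) {  // completed internal node: rescale before use
      double s = v.max();
      if (s <= 0.0) return -arma::datum::inf;
      v /= s;
      part.row(ch) = v.t();
      logscale += std::log(s);
    }
    part.row(par) %= pg.pvec(elen(e), v).t();
  }
  double rootsum = arma::dot(rootp, part.row(root).t());
  if (keep_part) *keep_part = part;
  if (rootsum <= 0.0) return -arma::datum::inf;
  return std::log(rootsum) + logscale;
}

int sample_index(const arma::vec& w) {
  double tot = arma::accu(w);
  double u = unif_rand() * tot;
  double c = 0.0;
  for (arma::uword i = 0; i < w.n_elem; ++i) {
    c += w(i);
    if (u <= c) return i;
  }
  return w.n_elem - 1;
}

arma::mat build_q(const arma::imat& cells, const arma::vec& rates, int k) {
  arma::mat Q(k, k, arma::fill::zeros);
  for (arma::uword c = 0; c < cells.n_rows; ++c)
    Q(cells(c, 0), cells(c, 1)) = rates(cells(c, 2));
  Q.diag() = -arma::sum(Q, 1);
  return Q;
}

// Rate-class partition state. assign[i] in {0 = zero-bin, 1..ncls};
// classes stay contiguously numbered 1..ncls in order of first use.
struct Partition {
  arma::ivec assign;
  std::vector<double> val;  // val[c-1] = shared rate of class c

  int ncls() const { return val.size(); }

  arma::vec rates() const {
    arma::vec r(assign.n_elem, arma::fill::zeros);
    for (arma::uword i = 0; i < assign.n_elem; ++i)
      if (assign(i) > 0) r(i) = val[assign(i) - 1];
    return r;
  }

  std::vector<int> members(int c) const {
    std::vector<int> m;
    for (arma::uword i = 0; i < assign.n_elem; ++i)
      if (assign(i) == c) m.push_back(i);
    return m;
  }

  void canonicalize() {
    // renumber classes by first occurrence, drop empty ones
    std::vector<int> map(ncls() + 1, 0);
    std::vector<double> nv;
    arma::ivec na = assign;
    int next = 0;
    for (arma::uword i = 0; i < assign.n_elem; ++i) {
      int c = assign(i);
      if (c > 0) {
        if (map[c] == 0) {
          map[c] = ++next;
          nv.push_back(val[c - 1]);
        }
        na(i) = map[c];
      }
    }
    assign = na;
    val = nv;
  }

  std::string id() const {
    std::string s;
    for (arma::uword i = 0; i < assign.n_elem; ++i) {
      if (assign(i) == 0) s += 'Z';
      else s += ('a' + assign(i) - 1);
    }
    return s;
  }
};

// Count elementary RJ operations available from a partition:
// merges C(ncls,2); splits sum(2^(sz-1)-1); zero per singleton class;
// unzero per zero-bin rate.  Used for the proposal-count ratio.
double count_ops(const Partition& p, double* n_merge, double* n_split,
                 double* n_zero, double* n_unzero) {
  int nc = p.ncls();
  double nm = nc * (nc - 1) / 2.0, ns = 0.0, nz = 0.0, nu = 0.0;
  for (int c = 1; c <= nc; ++c) {
    int sz = p.members(c).size();
    if (sz >= 2) ns += std::pow(2.0, sz - 1) - 1.0;
    if (sz == 1) nz += 1.0;
  }
  for (arma::uword i = 0; i < p.assign.n_elem; ++i)
    if (p.assign(i) == 0) nu += 1.0;
  if (n_merge) { *n_merge = nm; *n_split = ns; *n_zero = nz; *n_unzero = nu; }
  return nm + ns + nz + nu;
}

}  // namespace

// [[Rcpp::export]]
arma::mat expm_cpp(const arma::mat& Q, double t) {
  return arma::expmat(Q * t);
}

// [[Rcpp::export]]
double ctmc_loglik_cpp(const arma::umat& edge, const arma::vec& elen, int ntip,
                       int nnode_tot, int root, const arma::mat& tip_part,
                       const arma::mat& Q, const arma::vec& rootp) {
  Propagator pg;
  pg.init(Q);
  return prune_loglik(edge, elen, ntip, nnode_tot, root, tip_part, pg, rootp,
                      nullptr);
}

// [[Rcpp::export]]
List chain_cpp(const arma::umat& edge, const arma::vec& elen, int ntip,
               int nnode_tot, int root, const arma::mat& tip_part,
               const arma::imat& cells, int k, const arma::vec& rootp,
               int nrates, double ratedev, double hyper_upper, bool hyper_on,
               bool rj_on, double iterations, double burn_in, int thin,
               const arma::vec& init_rates, const arma::ivec& init_assign,
               double init_hyper, bool fix_rates, bool sample_nodes) {
  Partition part;
  part.assign = init_assign;
  {
    int nc = init_assign.max();
    part.val.assign(std::max(nc, 0), 0.0);
    for (int i = 0; i < nrates; ++i)
      if (init_assign(i) > 0) part.val[init_assign(i) - 1] = init_rates(i);
    part.canonicalize();
  }
  double m = init_hyper;  // exponential-prior mean (hyperparameter)

  Propagator pg;
  arma::vec rates = part.rates();
  pg.init(build_q(cells, rates, k));
  double logL = prune_loglik(edge, elen, ntip, nnode_tot, root, tip_part, pg,
                             rootp, nullptr);
  if (!std::isfinite(logL) && logL != -arma::datum::inf)
    stop("non-finite initial log-likelihood");

  long nsamp = (long)std::floor((iterations - burn_in) / thin);
  arma::mat samp_rates(nsamp, nrates, arma::fill::zeros);
  arma::vec samp_logL(nsamp), samp_hyper(nsamp);
  std::vector<std::string> samp_model(nsamp);
  int n_internal = nnode_tot - ntip;
  arma::mat tally(n_internal, k, arma::fill::zeros);

  double att_rate = 0, acc_rate = 0, att_hyp = 0, acc_hyp = 0, att_rj = 0,
         acc_rj = 0;
  long rec = 0;

  for (double it = 1; it <= iterations; ++it) {
    if (((long)it) % 4096 == 0) Rcpp::checkUserInterrupt();
    if (!fix_rates) {
      double u = unif_rand();
      double p_rj = rj_on ? 0.2 : 0.0;
      double p_hyp = hyper_on ? 0.1 : 0.0;
      if (u < p_rj) {
        // --- reversible-jump move over rate-class partitions ---
        att_rj += 1;
        double nm, ns, nz, nu;
        double nops = count_ops(part, &nm, &ns, &nz, &nu);
        if (nops > 0) {
          double pick = unif_rand() * nops;
          Partition prop = part;
          if (pick < nm) {
            // merge a uniformly chosen unordered pair of classes
            int idx = (int)pick;
            int nc = part.ncls(), c1 = -1, c2 = -1, cnt = 0;
            for (int a = 1; a <= nc && c1 < 0; ++a)
              for (int b = a + 1; b <= nc; ++b)
                if (cnt++ == idx) { c1 = a; c2 = b; break; }
            for (arma::uword i = 0; i < prop.assign.n_elem; ++i)
              if (prop.assign(i) == c2) prop.assign(i) = c1;
            prop.val[c1 - 1] = exp_rand() * std::max(m, 1e-12);
            prop.canonicalize();
          } else if (pick < nm + ns) {
            // split a class along a uniformly chosen bipartition
            double target = pick - nm;
            int nc = part.ncls(), csel = -1;
            long mask = 0;
            for (int c = 1; c <= nc; ++c) {
              int sz = part.members(c).size();
              if (sz < 2) continue;
              double nb = std::pow(2.0, sz - 1) - 1.0;
              if (target < nb) { csel = c; mask = (long)target + 1; break; }
              target -= nb;
            }
            std::vector<int> mem = prop.members(csel);
            int newc = prop.ncls() + 1;
            prop.val.push_back(0.0);
            for (size_t j = 1; j < mem.size(); ++j)
              if (mask & (1L << (j - 1))) prop.assign(mem[j]) = newc;
            prop.val[csel - 1] = exp_rand() * std::max(m, 1e-12);
            prop.val[newc - 1] = exp_rand() * std::max(m, 1e-12);
            prop.canonicalize();
          } else if (pick < nm + ns + nz) {
            // send a singleton class to the zero-bin
            int idx = (int)(pick - nm - ns), cnt = 0, csel = -1;
            for (int c = 1; c <= part.ncls(); ++c)
              if (part.members(c).size() == 1 && cnt++ == idx) { csel = c; break; }
            int r = prop.members(csel)[0];
            prop.assign(r) = 0;
            prop.canonicalize();
          } else {
            // pull a zero-bin rate into a fresh singleton class
            int idx = (int)(pick - nm - ns - nz), cnt = 0, rsel = -1;
            for (int i = 0; i < nrates; ++i)
              if (part.assign(i) == 0 && cnt++ == idx) { rsel = i; break; }
            int newc = prop.ncls() + 1;
            prop.val.push_back(exp_rand() * std::max(m, 1e-12));
            prop.assign(rsel) = newc;
            prop.canonicalize();
          }
          Propagator pg2;
          arma::vec r2 = prop.rates();
          pg2.init(build_q(cells, r2, k));
          double logL2 = prune_loglik(edge, elen, ntip, nnode_tot, root,
                                      tip_part, pg2, rootp, nullptr);
          double nops2 = count_ops(prop, nullptr, nullptr, nullptr, nullptr);
          double la = logL2 - logL + std::log(nops) - std::log(nops2);
          if (std::log(unif_rand()) < la) {
            part = prop; rates = r2; pg = pg2; logL = logL2; acc_rj += 1;
          }
        }
      } else if (u < p_rj + p_hyp) {
        // --- update the exponential-prior mean (uniform hyperprior) ---
        att_hyp += 1;
        double w = hyper_upper * 0.1;
        double m2 = m + (unif_rand() * 2.0 - 1.0) * w;
        if (m2 < 0) m2 = -m2;
        if (m2 > hyper_upper) m2 = 2 * hyper_upper - m2;
        if (m2 > 1e-12) {
          double lr = 0.0;
          for (int i = 0; i < nrates; ++i)
            if (part.assign(i) > 0) {
              double r = rates(i);
              lr += -std::log(m2) - r / m2 + std::log(m) + r / m;
            }
          if (std::log(unif_rand()) < lr) { m = m2; acc_hyp += 1; }
        }
      } else if (part.ncls() > 0) {
        // --- reflected-uniform update of one rate class ---
        att_rate += 1;
        int c = (int)(unif_rand() * part.ncls()) + 1;
        if (c > part.ncls()) c = part.ncls();
        double v = part.val[c - 1];
        double v2 = std::fabs(v + (unif_rand() * 2.0 - 1.0) * ratedev);
        Partition prop = part;
        prop.val[c - 1] = v2;
        Propagator pg2;
        arma::vec r2 = prop.rates();
        pg2.init(build_q(cells, r2, k));
        double logL2 = prune_loglik(edge, elen, ntip, nnode_tot, root,
                                    tip_part, pg2, rootp, nullptr);
        int nmem = prop.members(c).size();
        double la = logL2 - logL - nmem * (v2 - v) / m;
        if (std::log(unif_rand()) < la) {
          part = prop; rates = r2; pg = pg2; logL = logL2; acc_rate += 1;
        }
      }
    }

    if (it > burn_in && ((long)(it - burn_in)) % thin == 0 && rec < nsamp) {
      samp_rates.row(rec) = rates.t();
      samp_logL(rec) = logL;
      samp_hyper(rec) = m;
      samp_model[rec] = part.id();
      if (sample_nodes) {
        arma::mat partml;
        prune_loglik(edge, elen, ntip, nnode_tot, root, tip_part, pg, rootp,
                     &partml);
        arma::ivec state(nnode_tot, arma::fill::value(-1));
        arma::vec wroot = rootp % partml.row(root).t();
        state(root) = sample_index(wroot);
        tally(root - ntip, state(root)) += 1.0;
        // preorder = reverse postorder: parent state known before child
        for (arma::sword e = (arma::sword)edge.n_rows - 1; e >= 0; --e) {
          int par = edge(e, 0), ch = edge(e, 1);
          if (ch < ntip) continue;
          arma::mat P = pg.pmat(elen(e));
          arma::vec w = P.row(state(par)).t() % partml.row(ch).t();
          state(ch) = sample_index(w);
          tally(ch - ntip, state(ch)) += 1.0;
        }
      }
      ++rec;
    }
  }

  return List::create(
      _["rates"] = samp_rates, _["logL"] = samp_logL,
      _["hyper"] = samp_hyper, _["model_id"] = wrap(samp_model),
      _["node_tally"] = tally,
      _["acceptance"] = NumericVector::create(
          _["rate_accepted"] = acc_rate, _["rate_attempted"] = att_rate,
          _["hyper_accepted"] = acc_hyp, _["hyper_attempted"] = att_hyp,
          _["rj_accepted"] = acc_rj, _["rj_attempted"] = att_rj),
      _["final_rates"] = rates, _["final_model"] = part.id(),
      _["final_hyper"] = m);
}
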
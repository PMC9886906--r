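// Recurrent triangle-network core: synchronous discrete-time forward pass,
// backpropagation through time, and the online (per-trial) training loop.
// All randomness comes from R's RNG so set.seed() governs every draw.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

static inline double logistic_scalar(double x) {
  return 1.0 / (1.0 + std::exp(-x));
}

struct NetC {
  int nl;                     // layers
  int nc;                     // connections
  std::vector<int> sizes;
  std::vector<int> src, dst;  // 0-based
  std::vector<mat> W;         // dst_size x src_size
  std::vector<vec> b;         // per layer (unused for input layers)
  std::vector<bool> input;    // layer has no incoming connections
  double init_act;
};

static NetC parse_net(const List& net) {
  NetC N;
  IntegerVector sizes = net["layer_sizes"];
  IntegerVector src = net["conn_src"];
  IntegerVector dst = net["conn_dst"];
  List W = net["weights"];
  List b = net["biases"];
  LogicalVector inp = net["is_input"];
  N.nl = sizes.size();
  N.nc = src.size();
  N.sizes.assign(sizes.begin(), sizes.end());
  N.src.resize(N.nc); N.dst.resize(N.nc);
  for (int c = 0; c < N.nc; ++c) { N.src[c] = src[c]; N.dst[c] = dst[c]; }
  N.W.resize(N.nc);
  for (int c = 0; c < N.nc; ++c) N.W[c] = as<mat>(W[c]);
  N.b.resize(N.nl);
  for (int l = 0; l < N.nl; ++l) N.b[l] = as<vec>(b[l]);
  N.input.resize(N.nl);
  for (int l = 0; l < N.nl; ++l) N.input[l] = inp[l];
  N.init_act = as<double>(net["init_act"]);
  return N;
}

struct SchedC {
  int T;
  // clamp entries aligned with externally supplied patterns
  std::vector<int> cl_layer, cl_from, cl_to;
  // target entries aligned with target patterns
  std::vector<int> tg_layer, tg_from, tg_to;
  std::vector<bool> active;   // per connection
};

static SchedC parse_sched(const List& sched, int nc) {
  SchedC S;
  S.T = as<int>(sched["steps"]);
  IntegerVector cl = sched["clamp_layer"], cf = sched["clamp_from"], ct = sched["clamp_to"];
  for (int i = 0; i < cl.size(); ++i) {
    S.cl_layer.push_back(cl[i]); S.cl_from.push_back(cf[i]); S.cl_to.push_back(ct[i]);
  }
  IntegerVector tl = sched["target_layer"], tf = sched["target_from"], tt = sched["target_to"];
  for (int i = 0; i < tl.size(); ++i) {
    S.tg_layer.push_back(tl[i]); S.tg_from.push_back(tf[i]); S.tg_to.push_back(tt[i]);
  }
  LogicalVector act = sched["active"];
  S.active.resize(nc);
  for (int c = 0; c < nc; ++c) S.active[c] = act[c];
  return S;
}

// which clamp entry (index into patterns) governs layer l at step t; -1 if none
static inline int clamp_entry(const SchedC& S, int l, int t) {
  for (size_t i = 0; i < S.cl_layer.size(); ++i)
    if (S.cl_layer[i] == l && t >= S.cl_from[i] && t <= S.cl_to[i]) return (int)i;
  return -1;
}

// Forward pass into preallocated activation store.
// acts[l]: sizes[l] x (T+1); column 0 holds initial activations.
// If contrib != nullptr, contrib->at(c): dst_size x T net-input contributions.
static void run_forward(const NetC& N, const SchedC& S,
                        const std::vector<vec>& clamp_pats,
                        std::vector<mat>& acts,
                        std::vector<vec>& netin,
                        std::vector<mat>* contrib) {
  const int T = S.T;
  for (int l = 0; l < N.nl; ++l)
    acts[l].col(0).fill(N.input[l] ? 0.0 : N.init_act);
  for (int t = 1; t <= T; ++t) {
    for (int l = 0; l < N.nl; ++l)
      if (!N.input[l]) netin[l] = N.b[l];
    for (int c = 0; c < N.nc; ++c) {
      if (!S.active[c]) continue;
      if (contrib) {
        vec z = N.W[c] * acts[N.src[c]].col(t - 1);
        netin[N.dst[c]] += z;
        (*contrib)[c].col(t - 1) = z;
      } else {
        netin[N.dst[c]] += N.W[c] * acts[N.src[c]].col(t - 1);
      }
    }
    for (int l = 0; l < N.nl; ++l) {
      int e = clamp_entry(S, l, t);
      if (e >= 0) {
        acts[l].col(t) = clamp_pats[e];
      } else if (N.input[l]) {
        acts[l].col(t).zeros();
      } else {
        vec x = netin[l];
        for (arma::uword i = 0; i < x.n_elem; ++i)
          acts[l](i, t) = logistic_scalar(x(i));
      }
    }
  }
}

// Backward pass; fills dx (dL/d netinput, per layer, cols 1..T) and returns the loss.
// loss_type: 0 cross-entropy, 1 summed squared error.
static double run_bptt(const NetC& N, const SchedC& S,
                       const std::vector<vec>& targ_pats,
                       int loss_type,
                       const std::vector<mat>& acts,
                       std::vector<mat>& dx,
                       std::vector<vec>& da) {
  const int T = S.T;
  const double eps = 1e-10;
  double loss = 0.0;
  // loss value
  for (size_t k = 0; k < S.tg_layer.size(); ++k) {
    int l = S.tg_layer[k];
    for (int t = S.tg_from[k]; t <= S.tg_to[k]; ++t) {
      const vec a = acts[l].col(t);
      const vec& tg = targ_pats[k];
      if (loss_type == 0) {
        for (arma::uword i = 0; i < a.n_elem; ++i) {
          double ai = std::min(std::max(a(i), eps), 1.0 - eps);
          loss += -(tg(i) * std::log(ai) + (1.0 - tg(i)) * std::log(1.0 - ai));
        }
      } else {
        loss += arma::accu(arma::square(a - tg));
      }
    }
  }
  for (int t = T; t >= 1; --t) {
    for (int l = 0; l < N.nl; ++l) da[l].zeros();
    if (t < T)
      for (int c = 0; c < N.nc; ++c) {
        if (!S.active[c]) continue;
        da[N.src[c]] += N.W[c].t() * dx[N.dst[c]].col(t + 1);
      }
    for (int l = 0; l < N.nl; ++l) {
      if (N.input[l]) continue;
      if (clamp_entry(S, l, t) >= 0) { dx[l].col(t).zeros(); continue; }
      vec a = acts[l].col(t);
      vec d = da[l];
      vec direct(a.n_elem, arma::fill::zeros);
      for (size_t k = 0; k < S.tg_layer.size(); ++k) {
        if (S.tg_layer[k] != l || t < S.tg_from[k] || t > S.tg_to[k]) continue;
        if (loss_type == 0) {
          direct += a - targ_pats[k];          // d CE / d netinput
        } else {
          d += 2.0 * (a - targ_pats[k]);       // d SSE / d activation
        }
      }
      dx[l].col(t) = d % (a % (1.0 - a)) + direct;
    }
  }
  return loss;
}

static List pack_weights(const NetC& N) {
  List W(N.nc), b(N.nl);
  for (int c = 0; c < N.nc; ++c) W[c] = wrap(N.W[c]);
  for (int l = 0; l < N.nl; ++l) b[l] = wrap(N.b[l]);
  return List::create(_["weights"] = W, _["biases"] = b);
}

// [[Rcpp::export]]
List cpp_forward(List net, List sched, List clamp_pats, bool contributions) {
  NetC N = parse_net(net);
  SchedC S = parse_sched(sched, N.nc);
  std::vector<vec> cp(clamp_pats.size());
  for (int i = 0; i < clamp_pats.size(); ++i) cp[i] = as<vec>(clamp_pats[i]);
  std::vector<mat> acts(N.nl);
  std::vector<vec> netin(N.nl);
  for (int l = 0; l < N.nl; ++l) {
    acts[l].set_size(N.sizes[l], S.T + 1);
    netin[l].set_size(N.sizes[l]);
  }
  std::vector<mat> contrib;
  std::vector<mat>* cptr = nullptr;
  if (contributions) {
    contrib.resize(N.nc);
    for (int c = 0; c < N.nc; ++c)
      contrib[c].zeros(N.sizes[N.dst[c]], S.T);
    cptr = &contrib;
  }
  run_forward(N, S, cp, acts, netin, cptr);
  List acts_out(N.nl);
  for (int l = 0; l < N.nl; ++l) acts_out[l] = wrap(acts[l]);
  List out = List::create(_["acts"] = acts_out);
  if (contributions) {
    List con(N.nc);
    for (int c = 0; c < N.nc; ++c) con[c] = wrap(contrib[c]);
    out["contrib"] = con;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_bptt(List net, List sched, List clamp_pats, List target_pats,
              std::string loss) {
  NetC N = parse_net(net);
  SchedC S = parse_sched(sched, N.nc);
  int loss_type = (loss == "sse") ? 1 : 0;
  std::vector<vec> cp(clamp_pats.size()), tp(target_pats.size());
  for (int i = 0; i < clamp_pats.size(); ++i) cp[i] = as<vec>(clamp_pats[i]);
  for (int i = 0; i < target_pats.size(); ++i) tp[i] = as<vec>(target_pats[i]);
  std::vector<mat> acts(N.nl), dx(N.nl);
  std::vector<vec> netin(N.nl), da(N.nl);
  for (int l = 0; l < N.nl; ++l) {
    acts[l].set_size(N.sizes[l], S.T + 1);
    dx[l].zeros(N.sizes[l], S.T + 1);
    netin[l].set_size(N.sizes[l]);
    da[l].set_size(N.sizes[l]);
  }
  run_forward(N, S, cp, acts, netin, nullptr);
  double loss_val = run_bptt(N, S, tp, loss_type, acts, dx, da);
  List gW(N.nc), gb(N.nl);
  for (int c = 0; c < N.nc; ++c) {
    mat g = dx[N.dst[c]].cols(1, S.T) * acts[N.src[c]].cols(0, S.T - 1).t();
    gW[c] = wrap(g);
  }
  for (int l = 0; l < N.nl; ++l) {
    vec g = N.input[l] ? vec(N.sizes[l], arma::fill::zeros)
                       : vec(arma::sum(dx[l].cols(1, S.T), 1));
    gb[l] = wrap(g);
  }
  return List::create(_["loss"] = loss_val, _["gw"] = gW, _["gb"] = gb);
}

// Online training loop. `tasks` holds, per trainable task, its schedule plus
// trainable-parameter masks; each trial draws a task then a word (both from
// R's RNG), runs forward + BPTT, and applies one SGD update.
// Task codes: 0 PS, 1 SP, 2 PP, 3 SS, 4 READ.
// Encoding matrices are dim x n_items (column per item).
// [[Rcpp::export]]
List cpp_train(List net, List tasks, NumericVector task_cum,
               arma::mat O, arma::mat P, arma::mat S, arma::mat C,
               IntegerVector cand, NumericVector word_cum,
               int n_trials, double lr, std::string loss, int log_every) {
  NetC N = parse_net(net);
  int loss_type = (loss == "sse") ? 1 : 0;
  const int ntask = tasks.size();
  std::vector<SchedC> sch(ntask);
  std::vector<int> code(ntask);
  std::vector<std::vector<bool>> trW(ntask);
  std::vector<std::vector<bool>> trB(ntask);
  int Tmax = 0;
  for (int k = 0; k < ntask; ++k) {
    List tk = tasks[k];
    code[k] = as<int>(tk["code"]);
    sch[k] = parse_sched(tk, N.nc);
    Tmax = std::max(Tmax, sch[k].T);
    LogicalVector tw = tk["trainable_conn"], tb = tk["trainable_bias"];
    trW[k].resize(N.nc); trB[k].resize(N.nl);
    for (int c = 0; c < N.nc; ++c) trW[k][c] = tw[c];
    for (int l = 0; l < N.nl; ++l) trB[k][l] = tb[l];
  }
  std::vector<mat> acts(N.nl), dx(N.nl);
  std::vector<vec> netin(N.nl), da(N.nl);
  for (int l = 0; l < N.nl; ++l) {
    acts[l].set_size(N.sizes[l], Tmax + 1);
    dx[l].zeros(N.sizes[l], Tmax + 1);
    netin[l].set_size(N.sizes[l]);
    da[l].set_size(N.sizes[l]);
  }
  const int nb = (n_trials + log_every - 1) / log_every;
  vec bin_loss(std::max(nb, 1), arma::fill::zeros);
  arma::ivec bin_n(std::max(nb, 1), arma::fill::zeros);
  std::vector<int> task_count(5, 0);
  std::vector<vec> cp, tp;

  for (int trial = 0; trial < n_trials; ++trial) {
    // draw task
    double u = R::unif_rand();
    int k = 0;
    while (k < ntask - 1 && u > task_cum[k]) ++k;
    // draw word
    double v = R::unif_rand();
    int lo = 0, hi = word_cum.size() - 1;
    while (lo < hi) { int mid = (lo + hi) / 2; if (v > word_cum[mid]) lo = mid + 1; else hi = mid; }
    int w = cand[lo];
    task_count[code[k]]++;

    cp.clear(); tp.clear();
    switch (code[k]) {
      case 0: cp.push_back(P.col(w)); cp.push_back(C.col(w)); tp.push_back(S.col(w)); break; // PS
      case 1: cp.push_back(S.col(w)); tp.push_back(P.col(w)); break;                         // SP
      case 2: cp.push_back(P.col(w)); tp.push_back(P.col(w)); break;                         // PP
      case 3: cp.push_back(S.col(w)); tp.push_back(S.col(w)); break;                         // SS
      default: cp.push_back(O.col(w)); tp.push_back(P.col(w)); tp.push_back(S.col(w));       // READ
    }
    const SchedC& Sc = sch[k];
    run_forward(N, Sc, cp, acts, netin, nullptr);
    double lval = run_bptt(N, Sc, tp, loss_type, acts, dx, da);
    int bi = trial / log_every;
    bin_loss(bi) += lval; bin_n(bi) += 1;
    for (int c = 0; c < N.nc; ++c) {
      if (!trW[k][c]) continue;
      N.W[c] -= lr * (dx[N.dst[c]].cols(1, Sc.T) * acts[N.src[c]].cols(0, Sc.T - 1).t());
    }
    for (int l = 0; l < N.nl; ++l) {
      if (!trB[k][l]) continue;
      N.b[l] -= lr * vec(arma::sum(dx[l].cols(1, Sc.T), 1));
    }
    if ((trial + 1) % 4096 == 0) {
      if (!N.W[0].is_finite())
        stop("non-finite weights at trial %d", trial + 1);
      Rcpp::checkUserInterrupt();
    }
  }
  List out = pack_weights(N);
  NumericMatrix log(nb, 2);
  for (int i = 0; i < nb; ++i) {
    log(i, 0) = (i + 1.0) * log_every < n_trials ? (i + 1.0) * log_every : n_trials;
    log(i, 1) = bin_n(i) > 0 ? bin_loss(i) / bin_n(i) : NA_REAL;
  }
  out["log"] = log;
  out["task_count"] = IntegerVector(task_count.begin(), task_count.end());
  return out;
}

// Batched forward over many items sharing one schedule: clamp patterns for the
// i-th clamp entry come from column j of clamp_mats[i]. Returns final-step
// activations of out_layers and mean |contribution| of contrib_conns per item.
// [[Rcpp::export]]
List cpp_forward_batch(List net, List sched, List clamp_mats,
                       IntegerVector out_layers, IntegerVector contrib_conns) {
  NetC N = parse_net(net);
  SchedC S = parse_sched(sched, N.nc);
  const int ncl = clamp_mats.size();
  std::vector<mat> cm(ncl);
  for (int i = 0; i < ncl; ++i) cm[i] = as<mat>(clamp_mats[i]);
  const int n = ncl > 0 ? (int)cm[0].n_cols : 0;
  std::vector<mat> acts(N.nl);
  std::vector<vec> netin(N.nl);
  for (int l = 0; l < N.nl; ++l) {
    acts[l].set_size(N.sizes[l], S.T + 1);
    netin[l].set_size(N.sizes[l]);
  }
  std::vector<mat> contrib(N.nc);
  bool want_contrib = contrib_conns.size() > 0;
  if (want_contrib)
    for (int c = 0; c < N.nc; ++c) contrib[c].zeros(N.sizes[N.dst[c]], S.T);
  std::vector<mat> outs(out_layers.size());
  for (int k = 0; k < out_layers.size(); ++k)
    outs[k].set_size(N.sizes[out_layers[k]], n);
  mat cmean(n, std::max((int)contrib_conns.size(), 1), arma::fill::zeros);
  std::vector<vec> cp(ncl);
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < ncl; ++i) cp[i] = cm[i].col(j);
    run_forward(N, S, cp, acts, netin, want_contrib ? &contrib : nullptr);
    for (int k = 0; k < out_layers.size(); ++k)
      outs[k].col(j) = acts[out_layers[k]].col(S.T);
    for (int k = 0; k < contrib_conns.size(); ++k)
      cmean(j, k) = arma::mean(arma::abs(contrib[contrib_conns[k]].col(S.T - 1)));
  }
  List outs_r(out_layers.size());
  for (int k = 0; k < out_layers.size(); ++k) outs_r[k] = wrap(outs[k]);
  List res = List::create(_["outputs"] = outs_r);
  if (want_contrib) res["contrib_mean_abs"] = wrap(cmean);
  return res;
}
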
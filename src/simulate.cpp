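#include <Rcpp.h>
using namespace Rcpp;

// Discrete-event fractionation simulator.
//
// Positions are 0-based on [0, N).  g and h are 0/1 occupancy vectors for the
// two homeologs; g(i) + h(i) >= 1 is maintained by construction (two-sided
// events stop at the first position that is single copy on the other
// sequence).  Per event the draw order from the single R RNG stream is:
// anchor, target sequence (two-sided only), requested length.  Anchors are
// uniform over currently eligible positions (rejection sampling with an exact
// fallback enumeration when the eligible set is sparse).
//
// truncated codes: 0 none, 1 stopped at a single-copy position, 2 hit the
// interval boundary with budget remaining.
//
// One-sided events are classified by how many pre-existing deleted runs the
// event touches or engulfs (k): k=0 -> A (new run), k=1 -> B (left) or C
// (right), k=2 -> E (left+right) or D (right + beyond), k>=3 -> other.
// Codes: 1=A 2=B 3=C 4=D 5=E 6=other; NA for two-sided events.

// [[Rcpp::export(name = ".sim_fractionation_cpp")]]
List sim_fractionation_cpp(int N, double mu, double theta_target, int model,
                           double phi) {
  std::vector<int> g(N, 1), h(N, 1);
  long eligible = N;  // one-sided: #(g==1); two-sided: #(g==1 & h==1)
  std::vector<int> ev_target, ev_anchor, ev_req, ev_real, ev_trunc, ev_type,
      ev_off;
  std::vector<double> ev_theta;
  std::vector<int> dels;
  bool early = false;
  const double p = 1.0 / mu;

  while (static_cast<double>(eligible) / N > theta_target) {
    if (eligible <= 0) {
      early = true;
      break;
    }
    int anchor = -1, tries = 0;
    while (anchor < 0) {
      int i = static_cast<int>(unif_rand() * N);
      if (i >= N) i = N - 1;
      bool ok = (model == 1) ? g[i] == 1 : (g[i] == 1 && h[i] == 1);
      if (ok) {
        anchor = i;
        break;
      }
      if (++tries >= 1000) {
        // sparse eligible set: index into it directly (still uniform)
        long k = static_cast<long>(unif_rand() * eligible);
        if (k >= eligible) k = eligible - 1;
        long seen = 0;
        for (int j = 0; j < N; ++j) {
          bool okj = (model == 1) ? g[j] == 1 : (g[j] == 1 && h[j] == 1);
          if (okj && seen++ == k) {
            anchor = j;
            break;
          }
        }
        break;
      }
    }
    int target = 0;  // 0 = G, 1 = H
    if (model == 2) target = (unif_rand() < phi) ? 0 : 1;
    int a = 1 + static_cast<int>(R::rgeom(p));
    ev_off.push_back(static_cast<int>(dels.size()));
    int realized = 0, trunc = 0, type = NA_INTEGER;

    if (model == 1) {
      bool touch_left = anchor > 0 && g[anchor - 1] == 0;
      bool pending = false;  // inside a skipped pre-existing zero run
      int k_inside = 0, last = anchor, rem = a, pos = anchor;
      while (rem > 0 && pos < N) {
        if (g[pos] == 0) {
          pending = true;
        } else {
          if (pending) {
            ++k_inside;
            pending = false;
          }
          g[pos] = 0;
          dels.push_back(pos);
          ++realized;
          --rem;
          --eligible;
          last = pos;
        }
        ++pos;
      }
      if (rem > 0) trunc = 2;
      bool touch_right = (last + 1 < N) && g[last + 1] == 0;
      int k = (touch_left ? 1 : 0) + k_inside + (touch_right ? 1 : 0);
      if (k == 0)
        type = 1;
      else if (k == 1)
        type = touch_left ? 2 : 3;
      else if (k == 2)
        type = touch_left ? 5 : 4;
      else
        type = 6;
    } else {
      std::vector<int>& tg = (target == 0) ? g : h;
      std::vector<int>& ot = (target == 0) ? h : g;
      int rem = a, pos = anchor;
      while (rem > 0 && pos < N) {
        if (tg[pos] == 0) {  // already deleted in target: skip
          ++pos;
          continue;
        }
        if (ot[pos] == 0) {  // single copy here: deletion must stop
          trunc = 1;
          break;
        }
        tg[pos] = 0;
        dels.push_back(pos);
        ++realized;
        --rem;
        --eligible;
        ++pos;
      }
      if (rem > 0 && trunc == 0) trunc = 2;
    }

    ev_target.push_back(target);
    ev_anchor.push_back(anchor);
    ev_req.push_back(a);
    ev_real.push_back(realized);
    ev_trunc.push_back(trunc);
    ev_type.push_back(type);
    ev_theta.push_back(static_cast<double>(eligible) / N);
  }

  return List::create(
      _["g"] = IntegerVector(g.begin(), g.end()),
      _["h"] = IntegerVector(h.begin(), h.end()), _["target"] = wrap(ev_target),
      _["anchor"] = wrap(ev_anchor), _["requested"] = wrap(ev_req),
      _["realized"] = wrap(ev_real), _["truncated"] = wrap(ev_trunc),
      _["type"] = wrap(ev_type), _["theta_after"] = wrap(ev_theta),
      _["del_off"] = wrap(ev_off), _["deleted"] = wrap(dels),
      _["theta_achieved"] = static_cast<double>(eligible) / N,
      _["early_stop"] = early);
}
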
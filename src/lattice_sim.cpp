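#include <Rcpp.h>
using namespace Rcpp;

// Spatial stochastic simulator for domain-mediated protein binding.
//
// Protein instances live on a grid_side x grid_side lattice of sub-volumes
// (SVs). Each instance carries the domain slots of its protein; a slot is
// either free or engaged in exactly one bond (site exclusivity). Dynamics
// follow an operator-splitting (Gillespie multiparticle) scheme: one
// diffusion sweep per interval, in which every connected bound group moves
// as a unit to a uniformly chosen option among {stay, valid 4-neighbours},
// followed by an exact SSA within each SV for the interval duration with
// association channels (one per free complementary slot pair co-located in
// the SV, propensity k_on of the licensing rule) and dissociation channels
// (one per bond, propensity k_off of its rule).

struct BondRec {
  int ia, sa;   // instance / slot index of first endpoint
  int ib, sb;   // second endpoint
  int rule;     // licensing rule index
  bool alive;
};

// [[Rcpp::export(name = ".sim_run_cpp")]]
List sim_run_cpp(IntegerVector inst_protein,  // 0-based protein index per instance
                 List prot_slots,             // per protein: 0-based domain ids of slots
                 IntegerMatrix rules,         // n_rules x 4: pa, da, pb, db (0-based)
                 NumericVector rule_kon,
                 NumericVector rule_koff,
                 int n_prot, int n_dom,
                 int grid_side, int n_steps, double diff_interval,
                 IntegerVector sample_steps,  // 1-based interval indices to snapshot
                 bool periodic) {
  const int n_inst = inst_protein.size();
  if (grid_side < 1) stop("grid_side must be >= 1");
  if (n_inst < 1) stop("model has no protein instances");
  if (n_steps < 1) stop("t_end must span at least one diffusion interval");
  const int n_sv = grid_side * grid_side;
  const int n_rules = rules.nrow();
  const double tau = diff_interval;

  // flattened slot tables
  std::vector<int> slot_off(n_inst + 1, 0);
  for (int i = 0; i < n_inst; ++i) {
    IntegerVector sl = prot_slots[inst_protein[i]];
    slot_off[i + 1] = slot_off[i] + sl.size();
  }
  const int n_slot = slot_off[n_inst];
  std::vector<int> slot_dom(n_slot), slot_bond(n_slot, -1);
  for (int i = 0; i < n_inst; ++i) {
    IntegerVector sl = prot_slots[inst_protein[i]];
    for (int k = 0; k < sl.size(); ++k) slot_dom[slot_off[i] + k] = sl[k];
  }

  // rule (protein, domain) codes
  std::vector<long long> pdA(n_rules), pdB(n_rules);
  for (int r = 0; r < n_rules; ++r) {
    pdA[r] = (long long)rules(r, 0) * n_dom + rules(r, 1);
    pdB[r] = (long long)rules(r, 2) * n_dom + rules(r, 3);
  }
  const long long n_pd = (long long)n_prot * n_dom;

  // initial placement: uniform over SVs
  std::vector<int> inst_sv(n_inst);
  for (int i = 0; i < n_inst; ++i) {
    int s = (int)(unif_rand() * n_sv);
    if (s >= n_sv) s = n_sv - 1;
    inst_sv[i] = s;
  }

  std::vector<BondRec> bonds;
  std::vector<int> spare_bond_ids;
  double bond_time = 0.0;
  long long n_assoc = 0, n_dissoc = 0;

  // per-SV SSA scratch (indexed by pd code; cleared via touched list)
  std::vector<int> cnt(n_pd, 0);
  std::vector<char> pd_used(n_pd, 0);
  std::vector<std::vector<std::pair<int, int> > > free_slots(n_pd);
  std::vector<long long> touched;
  std::vector<double> propR(n_rules, 0.0);

  std::vector<std::vector<int> > sv_insts(n_sv);
  std::vector<char> visited(n_inst);
  std::vector<int> stack_buf, comp_buf;

  std::vector<char> do_sample(n_steps + 1, 0);
  for (int k = 0; k < sample_steps.size(); ++k) {
    int s = sample_steps[k];
    if (s >= 1 && s <= n_steps) do_sample[s] = 1;
  }
  List snapshots;

  auto touch = [&](long long pd) {
    if (!pd_used[pd]) { pd_used[pd] = 1; touched.push_back(pd); }
  };

  for (int step = 1; step <= n_steps; ++step) {
    // ---- diffusion sweep: connected bound groups move as rigid units ----
    std::fill(visited.begin(), visited.end(), 0);
    for (int i0 = 0; i0 < n_inst; ++i0) {
      if (visited[i0]) continue;
      comp_buf.clear();
      stack_buf.clear();
      stack_buf.push_back(i0);
      visited[i0] = 1;
      while (!stack_buf.empty()) {
        int i = stack_buf.back();
        stack_buf.pop_back();
        comp_buf.push_back(i);
        for (int k = slot_off[i]; k < slot_off[i + 1]; ++k) {
          int b = slot_bond[k];
          if (b < 0) continue;
          int other = (bonds[b].ia == i && bonds[b].sa == k - slot_off[i])
                          ? bonds[b].ib : bonds[b].ia;
          if (!visited[other]) { visited[other] = 1; stack_buf.push_back(other); }
        }
      }
      int sv = inst_sv[i0];
      int row = sv / grid_side, col = sv % grid_side;
      int opts[5][2];
      int n_opt = 0;
      opts[n_opt][0] = row; opts[n_opt][1] = col; ++n_opt;  // stay
      const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
      for (int d = 0; d < 4; ++d) {
        int r2 = row + dr[d], c2 = col + dc[d];
        if (periodic) {
          r2 = (r2 + grid_side) % grid_side;
          c2 = (c2 + grid_side) % grid_side;
        } else if (r2 < 0 || r2 >= grid_side || c2 < 0 || c2 >= grid_side) {
          continue;  // reflecting: off-grid moves resampled among valid options
        }
        opts[n_opt][0] = r2; opts[n_opt][1] = c2; ++n_opt;
      }
      int pick = (int)(unif_rand() * n_opt);
      if (pick >= n_opt) pick = n_opt - 1;
      int new_sv = opts[pick][0] * grid_side + opts[pick][1];
      for (size_t m = 0; m < comp_buf.size(); ++m) inst_sv[comp_buf[m]] = new_sv;
    }

    // ---- SV occupancy ----
    for (int s = 0; s < n_sv; ++s) sv_insts[s].clear();
    for (int i = 0; i < n_inst; ++i) sv_insts[inst_sv[i]].push_back(i);

    // ---- exact SSA within each occupied SV for duration tau ----
    for (int sv = 0; sv < n_sv; ++sv) {
      std::vector<int>& insts = sv_insts[sv];
      if (insts.empty()) continue;

      touched.clear();
      std::vector<int> sv_bonds;
      double sum_koff = 0.0;
      for (size_t m = 0; m < insts.size(); ++m) {
        int i = insts[m];
        for (int k = slot_off[i]; k < slot_off[i + 1]; ++k) {
          int b = slot_bond[k];
          if (b < 0) {
            long long pd = (long long)inst_protein[i] * n_dom + slot_dom[k];
            touch(pd);
            cnt[pd] += 1;
            free_slots[pd].push_back(std::make_pair(i, k - slot_off[i]));
          } else if (bonds[b].ia == i && bonds[b].sa == k - slot_off[i]) {
            sv_bonds.push_back(b);
            sum_koff += rule_koff[bonds[b].rule];
          }
        }
      }

      double t = 0.0;
      while (true) {
        double asum = 0.0;
        for (int r = 0; r < n_rules; ++r) {
          long long a = pdA[r], b = pdB[r];
          double pairs;
          if (a == b) {
            double c = cnt[a];
            pairs = c * (c - 1.0) / 2.0;
          } else {
            pairs = (double)cnt[a] * (double)cnt[b];
          }
          propR[r] = rule_kon[r] * pairs;
          asum += propR[r];
        }
        double a0 = asum + sum_koff;
        int nb = (int)sv_bonds.size();
        if (a0 <= 0.0) { bond_time += nb * (tau - t); break; }
        double dt = exp_rand() / a0;
        if (t + dt >= tau) { bond_time += nb * (tau - t); break; }
        bond_time += nb * dt;
        t += dt;

        double u = unif_rand() * a0;
        if (u < asum) {
          // association: pick the rule, then a uniform free slot pair
          int r = 0;
          double acc = 0.0;
          for (; r < n_rules - 1; ++r) {
            acc += propR[r];
            if (u < acc) break;
          }
          while (r < n_rules - 1 && propR[r] <= 0.0) ++r;  // fp-roundoff guard
          long long a = pdA[r], b = pdB[r];
          int iA, iB;
          long long pdx = a, pdy = b;
          if (a == b) {
            int c = cnt[a];
            iA = (int)(unif_rand() * c);
            if (iA >= c) iA = c - 1;
            iB = (int)(unif_rand() * (c - 1));
            if (iB >= c - 1) iB = c - 2;
            if (iB >= iA) ++iB;
          } else {
            iA = (int)(unif_rand() * cnt[a]);
            if (iA >= cnt[a]) iA = cnt[a] - 1;
            iB = (int)(unif_rand() * cnt[b]);
            if (iB >= cnt[b]) iB = cnt[b] - 1;
          }
          std::pair<int, int> epA = free_slots[pdx][iA];
          std::pair<int, int> epB = free_slots[pdy][iB];
          int bid;
          BondRec rec;
          rec.ia = epA.first; rec.sa = epA.second;
          rec.ib = epB.first; rec.sb = epB.second;
          rec.rule = r; rec.alive = true;
          if (!spare_bond_ids.empty()) {
            bid = spare_bond_ids.back();
            spare_bond_ids.pop_back();
            bonds[bid] = rec;
          } else {
            bid = (int)bonds.size();
            bonds.push_back(rec);
          }
          slot_bond[slot_off[rec.ia] + rec.sa] = bid;
          slot_bond[slot_off[rec.ib] + rec.sb] = bid;
          // remove both endpoints from the free-slot pools (higher index first
          // when they share a pool, so the other index stays valid)
          if (pdx == pdy) {
            int hi = std::max(iA, iB), lo = std::min(iA, iB);
            std::vector<std::pair<int, int> >& fl = free_slots[pdx];
            fl[hi] = fl.back(); fl.pop_back();
            fl[lo] = fl.back(); fl.pop_back();
            cnt[pdx] -= 2;
          } else {
            std::vector<std::pair<int, int> >& fa = free_slots[pdx];
            fa[iA] = fa.back(); fa.pop_back(); cnt[pdx] -= 1;
            std::vector<std::pair<int, int> >& fb = free_slots[pdy];
            fb[iB] = fb.back(); fb.pop_back(); cnt[pdy] -= 1;
          }
          sv_bonds.push_back(bid);
          sum_koff += rule_koff[r];
          ++n_assoc;
        } else {
          // dissociation: pick a bond proportionally to its k_off
          double v = u - asum;
          int k = 0;
          double acc = 0.0;
          int nsb = (int)sv_bonds.size();
          for (; k < nsb - 1; ++k) {
            acc += rule_koff[bonds[sv_bonds[k]].rule];
            if (v < acc) break;
          }
          int bid = sv_bonds[k];
          BondRec& rec = bonds[bid];
          slot_bond[slot_off[rec.ia] + rec.sa] = -1;
          slot_bond[slot_off[rec.ib] + rec.sb] = -1;
          long long pd1 = (long long)inst_protein[rec.ia] * n_dom +
                          slot_dom[slot_off[rec.ia] + rec.sa];
          long long pd2 = (long long)inst_protein[rec.ib] * n_dom +
                          slot_dom[slot_off[rec.ib] + rec.sb];
          touch(pd1);
          free_slots[pd1].push_back(std::make_pair(rec.ia, rec.sa));
          cnt[pd1] += 1;
          touch(pd2);
          free_slots[pd2].push_back(std::make_pair(rec.ib, rec.sb));
          cnt[pd2] += 1;
          sum_koff -= rule_koff[rec.rule];
          if (sum_koff < 0) sum_koff = 0;
          rec.alive = false;
          spare_bond_ids.push_back(bid);
          sv_bonds[k] = sv_bonds.back();
          sv_bonds.pop_back();
          ++n_dissoc;
        }
      }

      for (size_t m = 0; m < touched.size(); ++m) {
        long long pd = touched[m];
        cnt[pd] = 0;
        pd_used[pd] = 0;
        free_slots[pd].clear();
      }
    }

    // ---- snapshot ----
    if (do_sample[step]) {
      int m = 0;
      for (int i = 0; i < n_inst; ++i)
        for (int k = slot_off[i]; k < slot_off[i + 1]; ++k) {
          int b = slot_bond[k];
          if (b >= 0 && bonds[b].ia == i && bonds[b].sa == k - slot_off[i]) ++m;
        }
      IntegerMatrix bm(m, 5);
      int row = 0;
      for (int i = 0; i < n_inst; ++i)
        for (int k = slot_off[i]; k < slot_off[i + 1]; ++k) {
          int b = slot_bond[k];
          if (b >= 0 && bonds[b].ia == i && bonds[b].sa == k - slot_off[i]) {
            bm(row, 0) = bonds[b].ia; bm(row, 1) = bonds[b].sa;
            bm(row, 2) = bonds[b].ib; bm(row, 3) = bonds[b].sb;
            bm(row, 4) = bonds[b].rule;
            ++row;
          }
        }
      snapshots.push_back(List::create(
          _["step"] = step,
          _["time"] = step * diff_interval,
          _["bonds"] = bm,
          _["inst_sv"] = IntegerVector(inst_sv.begin(), inst_sv.end())));
    }
    if (step % 64 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["snapshots"] = snapshots,
      _["n_assoc"] = (double)n_assoc,
      _["n_dissoc"] = (double)n_dissoc,
      _["bond_time"] = bond_time);
}
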
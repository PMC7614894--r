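#include <Rcpp.h>
using namespace Rcpp;

// Cylindrical crypt lattice. Rows 0..nr-1 (row 0 = crypt base), columns cyclic
// with period nc. Labels are non-negative integers; -1 marks a vacancy
// (ablation mode only). Two event types, both at per-cell rates over occupied
// sites:
//   division  (k_d): the label is duplicated; the daughter is inserted at a
//     uniformly chosen site among {left, right, above}; occupied cells in the
//     insertion column at or above the insertion row shift up one row, the
//     shift being absorbed by the first vacancy or by exit past the top row.
//     A vacant insertion site is filled with no push-up; insertion above the
//     top row means the daughter exits immediately.
//   relocation (k_r): contents of the site and of a uniformly chosen existing
//     lattice neighbour (left, right, up, down; row 0 has no down-neighbour)
//     are swapped; swapping with a vacancy moves the cell into it.
// All randomness comes from R's RNG so set.seed() governs every trajectory.

static inline int wrap(int c, int nc) { return (c % nc + nc) % nc; }

static inline int runif_int(int n) {
  int k = (int)(R::unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct Lattice {
  int nr, nc, n;
  std::vector<int> occ;
  int n_occ;

  Lattice(const IntegerMatrix &m) : nr(m.nrow()), nc(m.ncol()), n(nr * nc), occ(n), n_occ(0) {
    for (int r = 0; r < nr; ++r)
      for (int c = 0; c < nc; ++c) {
        occ[r * nc + c] = m(r, c);
        if (m(r, c) >= 0) ++n_occ;
      }
  }
  Lattice(int nr_, int nc_, int fill) : nr(nr_), nc(nc_), n(nr_ * nc_), occ(n, fill), n_occ(fill >= 0 ? n : 0) {}

  int at(int r, int c) const { return occ[r * nc + c]; }
  void set(int r, int c, int v) { occ[r * nc + c] = v; }

  // uniform over occupied sites (rejection; occupancy >= 50% in all supported modes)
  int sample_occupied() const {
    for (;;) {
      int idx = runif_int(n);
      if (occ[idx] >= 0) return idx;
    }
  }

  // Insert `lab` at (ir, ic); push occupied cells up; returns label pushed out
  // of the lattice (or -1 if the shift was absorbed by a vacancy / none exited).
  int insert_push(int ir, int ic, int lab) {
    int v = ir;
    while (v < nr && occ[v * nc + ic] >= 0) ++v;
    int expelled = -1;
    if (v == nr) { // column full above ir: topmost occupant exits
      expelled = occ[(nr - 1) * nc + ic];
      --n_occ;
      v = nr - 1;
    }
    for (int rr = v; rr > ir; --rr) occ[rr * nc + ic] = occ[(rr - 1) * nc + ic];
    occ[ir * nc + ic] = lab;
    ++n_occ;
    return expelled;
  }

  // division at occupied (r, c); choice in {0 left, 1 right, 2 above}.
  // Returns expelled label (-1 none).
  int division(int r, int c, int choice) {
    int lab = occ[r * nc + c];
    int ir, ic;
    if (choice == 0) { ir = r; ic = wrap(c - 1, nc); }
    else if (choice == 1) { ir = r; ic = wrap(c + 1, nc); }
    else { ir = r + 1; ic = c; }
    if (ir >= nr) return -1; // daughter exits immediately
    if (occ[ir * nc + ic] < 0) { occ[ir * nc + ic] = lab; ++n_occ; return -1; }
    return insert_push(ir, ic, lab);
  }

  // relocation at occupied (r, c); choice indexes the existing neighbours in
  // order {left, right, up?, down?}. Returns target flat index.
  int relocation(int r, int c, int choice) {
    int tr = r, tc = c;
    if (choice == 0) tc = wrap(c - 1, nc);
    else if (choice == 1) tc = wrap(c + 1, nc);
    else if (choice == 2) { tr = (r + 1 < nr) ? r + 1 : r - 1; }
    else tr = r - 1;
    int a = r * nc + c, b = tr * nc + tc;
    std::swap(occ[a], occ[b]);
    return b;
  }

  int n_neighbours(int r) const { return 2 + (r + 1 < nr ? 1 : 0) + (r > 0 ? 1 : 0); }

  IntegerMatrix as_matrix() const {
    IntegerMatrix m(nr, nc);
    for (int r = 0; r < nr; ++r)
      for (int c = 0; c < nc; ++c) m(r, c) = occ[r * nc + c];
    return m;
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_apply_division(IntegerMatrix state, int row, int col) {
  Lattice L(state);
  if (L.at(row, col) < 0) stop("division at a vacant site");
  L.division(row, col, runif_int(3));
  return L.as_matrix();
}

// [[Rcpp::export]]
IntegerMatrix cpp_apply_relocation(IntegerMatrix state, int row, int col) {
  Lattice L(state);
  if (L.at(row, col) < 0) stop("relocation at a vacant site");
  L.relocation(row, col, runif_int(L.n_neighbours(row)));
  return L.as_matrix();
}

// Exact event-driven simulation from an arbitrary occupancy matrix.
// Snapshots are taken at record_times (sorted, within [0, duration]).
// [[Rcpp::export]]
List cpp_simulate(IntegerMatrix state, double kd, double kr, double duration,
                  NumericVector record_times, bool log_events) {
  Lattice L(state);
  int nt = record_times.size();
  List snaps(nt);
  std::vector<double> ev_t;
  std::vector<int> ev_kind, ev_sr, ev_sc, ev_tr, ev_tc;
  double t = 0.0;
  int ti = 0;
  for (;;) {
    double total = L.n_occ * (kd + kr);
    double tn = (total > 0) ? t + R::exp_rand() / total : duration + 1.0;
    while (ti < nt && record_times[ti] <= std::min(tn, duration)) snaps[ti++] = L.as_matrix();
    if (tn > duration) break;
    t = tn;
    int idx = L.sample_occupied();
    int r = idx / L.nc, c = idx % L.nc;
    bool div = R::unif_rand() < kd / (kd + kr);
    int tr, tc;
    if (div) {
      int choice = runif_int(3);
      // record the insertion site as the event target
      tr = (choice == 2) ? r + 1 : r;
      tc = (choice == 0) ? wrap(c - 1, L.nc) : (choice == 1 ? wrap(c + 1, L.nc) : c);
      L.division(r, c, choice);
    } else {
      int b = L.relocation(r, c, runif_int(L.n_neighbours(r)));
      tr = b / L.nc; tc = b % L.nc;
    }
    if (log_events) {
      ev_t.push_back(t); ev_kind.push_back(div ? 0 : 1);
      ev_sr.push_back(r); ev_sc.push_back(c); ev_tr.push_back(tr); ev_tc.push_back(tc);
    }
  }
  List out = List::create(_["snapshots"] = snaps, _["final_time"] = duration);
  if (log_events)
    out["events"] = DataFrame::create(
      _["time"] = ev_t, _["kind"] = ev_kind, _["site_row"] = ev_sr, _["site_col"] = ev_sc,
      _["target_row"] = ev_tr, _["target_col"] = ev_tc);
  return out;
}

// Fast path for lineage tracing: one labelled cell (label 1) on a label-0
// background, full homeostatic lattice. Returns clone cell counts by row at
// each record time; trajectories are cut short once the clone is extinct
// (all-zero rows thereafter) or has fixed the whole lattice (full rows).
// [[Rcpp::export]]
IntegerMatrix cpp_trace_clone(int n_rows, int n_cols, int start_row, int start_col,
                              double kd, double kr, NumericVector record_times) {
  Lattice L(n_rows, n_cols, 0);
  L.set(start_row, start_col, 1);
  int n_clone = 1;
  int nt = record_times.size();
  IntegerMatrix out(nt, n_rows);
  double t = 0.0;
  int ti = 0;
  double total = L.n * (kd + kr);
  for (;;) {
    double tn = t + R::exp_rand() / total;
    while (ti < nt && record_times[ti] <= tn) {
      for (int r = 0; r < n_rows; ++r) {
        int cnt = 0;
        for (int c = 0; c < n_cols; ++c) if (L.at(r, c) == 1) ++cnt;
        out(ti, r) = cnt;
      }
      ++ti;
    }
    if (ti >= nt) break;
    t = tn;
    int idx = L.sample_occupied();
    int r = idx / n_cols, c = idx % n_cols;
    if (R::unif_rand() < kd / (kd + kr)) {
      int choice = runif_int(3);
      if (choice != 2 || r + 1 < n_rows) { // otherwise the daughter exits at once
        int lab = L.occ[idx];
        int expelled = L.division(r, c, choice);
        if (lab == 1) ++n_clone;
        if (expelled == 1) --n_clone;
      }
    } else {
      L.relocation(r, c, runif_int(L.n_neighbours(r)));
    }
    if (n_clone == 0) {
      while (ti < nt) { for (int r2 = 0; r2 < n_rows; ++r2) out(ti, r2) = 0; ++ti; }
      break;
    }
    if (n_clone == L.n) {
      while (ti < nt) { for (int r2 = 0; r2 < n_rows; ++r2) out(ti, r2) = n_cols; ++ti; }
      break;
    }
  }
  return out;
}

// Monoclonal drift from an all-distinct lattice. Records whether all sites of
// rows [band_lo, band_hi] share one label at each record time, and the first
// time the band becomes monoclonal (NA if not before t_max).
// [[Rcpp::export]]
List cpp_monoclonal(int n_rows, int n_cols, double kd, double kr,
                    NumericVector record_times, int band_lo, int band_hi, double t_max) {
  Lattice L(n_rows, n_cols, 0);
  for (int i = 0; i < L.n; ++i) L.occ[i] = i;
  int nt = record_times.size();
  LogicalVector mono(nt);
  double t = 0.0, t_fix = NA_REAL;
  int ti = 0;
  double total = L.n * (kd + kr);
  auto band_mono = [&]() {
    int lab = L.at(band_lo, 0);
    for (int r = band_lo; r <= band_hi; ++r)
      for (int c = 0; c < n_cols; ++c) if (L.at(r, c) != lab) return false;
    return true;
  };
  auto lattice_mono = [&]() {
    for (int i = 1; i < L.n; ++i) if (L.occ[i] != L.occ[0]) return false;
    return true;
  };
  for (;;) {
    double tn = t + R::exp_rand() / total;
    while (ti < nt && record_times[ti] <= std::min(tn, t_max)) mono[ti++] = band_mono();
    if (tn > t_max) break;
    t = tn;
    int idx = L.sample_occupied();
    int r = idx / n_cols, c = idx % n_cols;
    if (R::unif_rand() < kd / (kd + kr)) L.division(r, c, runif_int(3));
    else L.relocation(r, c, runif_int(L.n_neighbours(r)));
    if (ISNA(t_fix) && band_mono()) t_fix = t;
    if (ti >= nt) {
      if (!ISNA(t_fix)) break;         // nothing left to record; fixation time known
    } else if (lattice_mono()) {       // whole lattice one label: frozen forever
      while (ti < nt) mono[ti++] = true;
      if (ISNA(t_fix)) t_fix = t;
      break;
    }
  }
  while (ti < nt) mono[ti++] = NA_LOGICAL; // only reachable if t_max < max(record_times)
  return List::create(_["monoclonal"] = mono, _["t_fix"] = t_fix);
}
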
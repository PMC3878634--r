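#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dense two-phase tableau simplex for
//   min c'x  s.t.  Aub x <= bub,  Aeq x = beq,  x >= 0.
// Pivot rules are deterministic: Dantzig (most negative reduced cost, lowest
// index on ties) with a Bland fallback after 10*(m+n) iterations to rule out
// cycling. Problem sizes here are a few hundred rows/columns, so a dense
// tableau is the right tool.
//
// status: 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit / numeric.

static const double PIVTOL = 1e-9;
static const double DJTOL = 1e-9;

struct Tableau {
  int m, N;                  // rows, columns (excluding rhs)
  std::vector<double> T;     // (m+1) x (N+1); row m is the cost row
  std::vector<int> basis;    // basis[i] = column basic in row i
  double &at(int i, int j) { return T[(size_t)i * (N + 1) + j]; }

  void pivot(int pr, int pc) {
    double piv = at(pr, pc);
    for (int j = 0; j <= N; ++j) at(pr, j) /= piv;
    at(pr, pc) = 1.0;
    for (int i = 0; i <= m; ++i) {
      if (i == pr) continue;
      double f = at(i, pc);
      if (f == 0.0) continue;
      for (int j = 0; j <= N; ++j) at(i, j) -= f * at(pr, j);
      at(i, pc) = 0.0;
    }
    basis[pr] = pc;
  }
};

// Run simplex iterations on tab with costs already canonical in row m.
// allowed[j] = may enter. Returns 0 optimal, 2 unbounded, 3 maxiter.
static int iterate(Tableau &tab, const std::vector<bool> &allowed,
                   long maxit, long bland_after) {
  int m = tab.m, N = tab.N;
  for (long it = 0; it < maxit; ++it) {
    bool bland = it >= bland_after;
    int pc = -1;
    double best = -DJTOL;
    for (int j = 0; j < N; ++j) {
      if (!allowed[j]) continue;
      double dj = tab.at(m, j);
      if (dj < -DJTOL) {
        if (bland) { pc = j; break; }
        if (dj < best) { best = dj; pc = j; }
      }
    }
    if (pc < 0) return 0;  // optimal
    int pr = -1;
    double bestratio = 0.0;
    for (int i = 0; i < m; ++i) {
      double a = tab.at(i, pc);
      if (a > PIVTOL) {
        double r = tab.at(i, N) / a;
        if (pr < 0 || r < bestratio - 1e-12 ||
            (r < bestratio + 1e-12 && tab.basis[i] < tab.basis[pr])) {
          pr = i; bestratio = r;
        }
      }
    }
    if (pr < 0) return 2;  // unbounded direction
    tab.pivot(pr, pc);
  }
  return 3;
}

// [[Rcpp::export(name = ".simplex_cpp")]]
List simplex_cpp(NumericVector cvec, NumericMatrix Aub, NumericVector bub,
                 NumericMatrix Aeq, NumericVector beq, bool maximize) {
  int n = cvec.size();
  int mu = Aub.nrow(), me = Aeq.nrow();
  int m = mu + me;

  // columns: n structural, mu slacks, then artificials as needed
  std::vector<std::vector<double>> rows(m, std::vector<double>(n + mu, 0.0));
  std::vector<double> rhs(m);
  for (int i = 0; i < mu; ++i) {
    for (int j = 0; j < n; ++j) rows[i][j] = Aub(i, j);
    rows[i][n + i] = 1.0;
    rhs[i] = bub[i];
  }
  for (int i = 0; i < me; ++i) {
    for (int j = 0; j < n; ++j) rows[mu + i][j] = Aeq(i, j);
    rhs[mu + i] = beq[i];
  }
  double bscale = 1.0;
  for (int i = 0; i < m; ++i) bscale = std::max(bscale, std::fabs(rhs[i]));

  // flip rows with negative rhs; decide which rows need an artificial
  std::vector<int> art_of_row(m, -1);
  int na = 0;
  for (int i = 0; i < m; ++i) {
    if (rhs[i] < 0) {
      for (double &v : rows[i]) v = -v;
      rhs[i] = -rhs[i];
      art_of_row[i] = na++;           // flipped slack is -1: needs artificial
    } else if (i >= mu) {
      art_of_row[i] = na++;           // equality rows always need one
    }
  }

  int N = n + mu + na;
  Tableau tab;
  tab.m = m; tab.N = N;
  tab.T.assign((size_t)(m + 1) * (N + 1), 0.0);
  tab.basis.assign(m, -1);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n + mu; ++j) tab.at(i, j) = rows[i][j];
    tab.at(i, N) = rhs[i];
    if (art_of_row[i] >= 0) {
      int ac = n + mu + art_of_row[i];
      tab.at(i, ac) = 1.0;
      tab.basis[i] = ac;
    } else {
      tab.basis[i] = n + i;           // unflipped slack
    }
  }

  long maxit = 200L * (m + N + 1);
  long bland_after = 10L * (m + N + 1);
  std::vector<bool> allowed(N, true);

  // phase 1: minimize sum of artificials
  if (na > 0) {
    for (int j = 0; j <= N; ++j) {
      double s = 0.0;
      for (int i = 0; i < m; ++i)
        if (tab.basis[i] >= n + mu) s += tab.at(i, j);
      tab.at(m, j) = -s;              // reduced costs of min sum(artificials)
    }
    for (int a = 0; a < na; ++a) tab.at(m, n + mu + a) += 1.0;
    int rc = iterate(tab, allowed, maxit, bland_after);
    if (rc == 3) return List::create(_["status"] = 3);
    double p1 = -tab.at(m, N);
    if (p1 > 1e-7 * bscale)
      return List::create(_["status"] = 1);
    // drive remaining artificials out of the basis where possible
    for (int i = 0; i < m; ++i) {
      if (tab.basis[i] >= n + mu) {
        int pc = -1;
        for (int j = 0; j < n + mu; ++j)
          if (std::fabs(tab.at(i, j)) > PIVTOL) { pc = j; break; }
        if (pc >= 0) tab.pivot(i, pc);
        // else: redundant row, artificial stays basic at zero level
      }
    }
    for (int a = 0; a < na; ++a) allowed[n + mu + a] = false;
  }

  // phase 2 cost row: canonical reduced costs of (sign * c)
  double sgn = maximize ? -1.0 : 1.0;
  std::vector<double> cost(N, 0.0);
  for (int j = 0; j < n; ++j) cost[j] = sgn * cvec[j];
  for (int j = 0; j <= N; ++j) {
    double s = 0.0;
    for (int i = 0; i < m; ++i) {
      int b = tab.basis[i];
      if (b < n && cost[b] != 0.0) s += cost[b] * tab.at(i, j);
    }
    tab.at(m, j) = (j < N ? cost[j] : 0.0) - s;
  }
  int rc = iterate(tab, allowed, maxit, bland_after);
  if (rc == 3) return List::create(_["status"] = 3);
  if (rc == 2) return List::create(_["status"] = 2);

  NumericVector x(n);
  for (int i = 0; i < m; ++i)
    if (tab.basis[i] < n) x[tab.basis[i]] = tab.at(i, N);
  double val = 0.0;
  for (int j = 0; j < n; ++j) val += cvec[j] * x[j];
  return List::create(_["status"] = 0, _["x"] = x, _["value"] = val);
}
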
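#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Rectangular minimum-cost linear assignment by shortest augmenting paths
// with dual potentials (Jonker-Volgenant style). Requires nr <= nc; the R
// wrapper transposes when needed. Complexity O(nr^2 * nc).

static int augmenting_path(int nc, const std::vector<double> &cost, int nr_stride,
                           std::vector<double> &u, std::vector<double> &v,
                           std::vector<int> &path, std::vector<int> &row4col,
                           std::vector<double> &shortestPathCosts, int i,
                           std::vector<bool> &SR, std::vector<bool> &SC,
                           std::vector<int> &remaining, double *p_minVal) {
  double minVal = 0;
  int num_remaining = nc;
  for (int it = 0; it < nc; it++) remaining[it] = nc - it - 1;
  std::fill(SR.begin(), SR.end(), false);
  std::fill(SC.begin(), SC.end(), false);
  std::fill(shortestPathCosts.begin(), shortestPathCosts.end(),
            std::numeric_limits<double>::infinity());

  int sink = -1;
  while (sink == -1) {
    int index = -1;
    double lowest = std::numeric_limits<double>::infinity();
    SR[i] = true;
    for (int it = 0; it < num_remaining; it++) {
      int j = remaining[it];
      double r = minVal + cost[(size_t)i * nr_stride + j] - u[i] - v[j];
      if (r < shortestPathCosts[j]) {
        path[j] = i;
        shortestPathCosts[j] = r;
      }
      // prefer unassigned columns among ties so the path terminates sooner
      if (shortestPathCosts[j] < lowest ||
          (shortestPathCosts[j] == lowest && row4col[j] == -1)) {
        lowest = shortestPathCosts[j];
        index = it;
      }
    }
    minVal = lowest;
    if (!std::isfinite(minVal)) return -1;  // infeasible
    int j = remaining[index];
    if (row4col[j] == -1) {
      sink = j;
    } else {
      i = row4col[j];
    }
    SC[j] = true;
    remaining[index] = remaining[--num_remaining];
  }
  *p_minVal = minVal;
  return sink;
}

// [[Rcpp::export]]
List lap_solve_cpp(NumericMatrix D) {
  int nr = D.nrow(), nc = D.ncol();
  if (nr > nc) stop("lap_solve_cpp requires nrow <= ncol");
  // row-major copy for locality
  std::vector<double> cost((size_t)nr * nc);
  for (int i = 0; i < nr; i++)
    for (int j = 0; j < nc; j++) cost[(size_t)i * nc + j] = D(i, j);

  std::vector<double> u(nr, 0.0), v(nc, 0.0), shortestPathCosts(nc);
  std::vector<int> path(nc, -1), col4row(nr, -1), row4col(nc, -1), remaining(nc);
  std::vector<bool> SR(nr), SC(nc);

  for (int curRow = 0; curRow < nr; curRow++) {
    double minVal;
    int sink = augmenting_path(nc, cost, nc, u, v, path, row4col,
                               shortestPathCosts, curRow, SR, SC, remaining,
                               &minVal);
    if (sink < 0) stop("infeasible cost matrix (non-finite entries)");
    u[curRow] += minVal;
    for (int i = 0; i < nr; i++)
      if (SR[i] && i != curRow) u[i] += minVal - shortestPathCosts[col4row[i]];
    for (int j = 0; j < nc; j++)
      if (SC[j]) v[j] -= minVal - shortestPathCosts[j];
    // augment along the alternating path back from the sink
    int j = sink;
    while (true) {
      int i = path[j];
      row4col[j] = i;
      int tmp = col4row[i];
      col4row[i] = j;
      j = tmp;
      if (i == curRow) break;
    }
  }

  double objective = 0.0;
  IntegerVector assignment(nr);
  for (int i = 0; i < nr; i++) {
    assignment[i] = col4row[i] + 1;  // 1-based for R
    objective += cost[(size_t)i * nc + col4row[i]];
  }
  return List::create(_["assignment"] = assignment,
                      _["objective"] = objective);
}
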
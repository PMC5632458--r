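#include <Rcpp.h>
#include <queue>

using namespace Rcpp;

// Grayscale morphological reconstruction by dilation (marker under mask),
// 8-connected: hybrid raster/anti-raster scan followed by a FIFO queue
// sweep. Exact fixed point of the unit geodesic dilation.
// [[Rcpp::export(name = ".reconstruct_dilation")]]
NumericMatrix reconstruct_dilation(NumericMatrix marker, NumericMatrix mask) {
  const int M = marker.nrow(), N = marker.ncol();
  if (mask.nrow() != M || mask.ncol() != N)
    stop("marker and mask dimensions differ");
  NumericMatrix J(clone(marker));

  for (int i = 0; i < M; ++i)
    for (int j = 0; j < N; ++j)
      if (J(i, j) > mask(i, j)) stop("marker must lie below the mask");

  // raster scan: neighbours already visited (N, W, NW, NE)
  for (int j = 0; j < N; ++j) {
    for (int i = 0; i < M; ++i) {
      double v = J(i, j);
      if (i > 0 && J(i - 1, j) > v) v = J(i - 1, j);
      if (j > 0) {
        if (J(i, j - 1) > v) v = J(i, j - 1);
        if (i > 0 && J(i - 1, j - 1) > v) v = J(i - 1, j - 1);
        if (i < M - 1 && J(i + 1, j - 1) > v) v = J(i + 1, j - 1);
      }
      J(i, j) = std::min(v, mask(i, j));
    }
  }

  // anti-raster scan, enqueue boundary pixels of the propagation front
  std::queue<std::pair<int, int> > fifo;
  for (int j = N - 1; j >= 0; --j) {
    for (int i = M - 1; i >= 0; --i) {
      double v = J(i, j);
      if (i < M - 1 && J(i + 1, j) > v) v = J(i + 1, j);
      if (j < N - 1) {
        if (J(i, j + 1) > v) v = J(i, j + 1);
        if (i < M - 1 && J(i + 1, j + 1) > v) v = J(i + 1, j + 1);
        if (i > 0 && J(i - 1, j + 1) > v) v = J(i - 1, j + 1);
      }
      J(i, j) = std::min(v, mask(i, j));
      // queue condition: some later-scanned neighbour could still grow
      bool push = false;
      const int di[4] = {1, 0, 1, -1};
      const int dj[4] = {0, 1, 1, 1};
      for (int k = 0; k < 4 && !push; ++k) {
        int qi = i + di[k], qj = j + dj[k];
        if (qi < 0 || qi >= M || qj < 0 || qj >= N) continue;
        if (J(qi, qj) < J(i, j) && J(qi, qj) < mask(qi, qj)) push = true;
      }
      if (push) fifo.push(std::make_pair(i, j));
    }
  }

  const int di8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!fifo.empty()) {
    std::pair<int, int> p = fifo.front();
    fifo.pop();
    const int i = p.first, j = p.second;
    const double vp = J(i, j);
    for (int k = 0; k < 8; ++k) {
      int qi = i + di8[k], qj = j + dj8[k];
      if (qi < 0 || qi >= M || qj < 0 || qj >= N) continue;
      if (J(qi, qj) < vp && mask(qi, qj) != J(qi, qj)) {
        double nv = std::min(vp, mask(qi, qj));
        if (nv > J(qi, qj)) {
          J(qi, qj) = nv;
          fifo.push(std::make_pair(qi, qj));
        }
      }
    }
  }
  return J;
}
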
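#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// SLIC superpixel clustering on one 2D multi-channel slice.
//
// img:  numeric vector holding an H x W x C array (column-major).
// mask: logical H x W; pixels outside the mask are never assigned (label 0).
// gridSize S: initial cluster spacing in pixels; compactness m weights the
// spatial term as D^2 = d_colour^2 + m^2 * d_spatial^2 / S^2, which assumes
// channels rescaled to [0, 1].
// Deterministic: no random initialisation, fixed scan order.
// [[Rcpp::export]]
IntegerMatrix slic_slice(NumericVector img, int H, int W, int C,
                         LogicalMatrix mask, int gridSize,
                         double compactness, int maxIter) {
  const int S = gridSize;
  const double m2S2 = (compactness * compactness) / double(S * S);

  // initial centres on a regular grid, snapped to masked pixels
  std::vector<double> cy, cx;
  std::vector<std::vector<double> > ccol;
  for (int gy = S / 2; gy < H; gy += S) {
    for (int gx = S / 2; gx < W; gx += S) {
      if (!mask(gy, gx)) continue;
      cy.push_back(gy);
      cx.push_back(gx);
      std::vector<double> col(C);
      for (int c = 0; c < C; ++c) col[c] = img[gy + H * (gx + W * c)];
      ccol.push_back(col);
    }
  }
  int K = (int)cy.size();
  IntegerMatrix labels(H, W);
  if (K == 0) return labels;  // fully unmasked slice

  std::vector<int> lab(H * W, -1);
  std::vector<double> dist(H * W, R_PosInf);

  for (int iter = 0; iter < maxIter; ++iter) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    for (int k = 0; k < K; ++k) {
      int y0 = std::max(0, (int)std::floor(cy[k]) - S);
      int y1 = std::min(H - 1, (int)std::floor(cy[k]) + S);
      int x0 = std::max(0, (int)std::floor(cx[k]) - S);
      int x1 = std::min(W - 1, (int)std::floor(cx[k]) + S);
      for (int x = x0; x <= x1; ++x) {
        for (int y = y0; y <= y1; ++y) {
          if (!mask(y, x)) continue;
          double dc = 0.0;
          for (int c = 0; c < C; ++c) {
            double d = img[y + H * (x + W * c)] - ccol[k][c];
            dc += d * d;
          }
          double dy = y - cy[k], dx = x - cx[k];
          double D = dc + m2S2 * (dy * dy + dx * dx);
          int idx = y + H * x;
          if (D < dist[idx]) { dist[idx] = D; lab[idx] = k; }
        }
      }
    }
    // recompute centres
    std::vector<double> ny(K, 0.0), nx(K, 0.0), n(K, 0.0);
    std::vector<std::vector<double> > ncol(K, std::vector<double>(C, 0.0));
    for (int x = 0; x < W; ++x) {
      for (int y = 0; y < H; ++y) {
        int k = lab[y + H * x];
        if (k < 0) continue;
        ny[k] += y; nx[k] += x; n[k] += 1.0;
        for (int c = 0; c < C; ++c) ncol[k][c] += img[y + H * (x + W * c)];
      }
    }
    for (int k = 0; k < K; ++k) {
      if (n[k] == 0) continue;
      cy[k] = ny[k] / n[k];
      cx[k] = nx[k] / n[k];
      for (int c = 0; c < C; ++c) ccol[k][c] = ncol[k][c] / n[k];
    }
  }

  // Enforce 4-connectivity: flood-fill connected regions; regions smaller
  // than S^2/4 are absorbed into the previously assigned neighbour region.
  const int minSize = (S * S) / 4;
  std::vector<int> newlab(H * W, -1);
  int next = 0;
  const int dy4[4] = {-1, 1, 0, 0}, dx4[4] = {0, 0, -1, 1};
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      int idx = y + H * x;
      if (lab[idx] < 0 || newlab[idx] >= 0) continue;
      int adj = -1;  // an adjacent already-relabelled region
      std::vector<int> member;
      std::queue<std::pair<int,int> > q;
      q.push(std::make_pair(y, x));
      newlab[idx] = next;
      member.push_back(idx);
      while (!q.empty()) {
        int py = q.front().first, px = q.front().second; q.pop();
        for (int d = 0; d < 4; ++d) {
          int qy = py + dy4[d], qx = px + dx4[d];
          if (qy < 0 || qy >= H || qx < 0 || qx >= W) continue;
          int qi = qy + H * qx;
          if (lab[qi] < 0) continue;
          if (newlab[qi] >= 0) {
            if (newlab[qi] != next) adj = newlab[qi];
            continue;
          }
          if (lab[qi] == lab[idx]) {
            newlab[qi] = next;
            member.push_back(qi);
            q.push(std::make_pair(qy, qx));
          }
        }
      }
      if ((int)member.size() < minSize && adj >= 0) {
        for (size_t i = 0; i < member.size(); ++i) newlab[member[i]] = adj;
      } else {
        ++next;
      }
    }
  }
  // compact ids to 1..K' (absorbed ids leave gaps)
  std::vector<int> remap(next, 0);
  for (int i = 0; i < H * W; ++i) if (newlab[i] >= 0) remap[newlab[i]] = 1;
  int out = 0;
  for (int k = 0; k < next; ++k) if (remap[k]) remap[k] = ++out;
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      int v = newlab[y + H * x];
      labels(y, x) = v < 0 ? 0 : remap[v];
    }
  return labels;
}

// Label connected components of a 3D boolean array under 26-connectivity.
// mask: logical vector of an nx x ny x nz array (column-major).
// Returns integer vector of same length, 0 outside the mask, components
// numbered 1..K in discovery order.
// [[Rcpp::export]]
IntegerVector label_components_26(LogicalVector mask, int nx, int ny, int nz) {
  IntegerVector out(mask.size(), 0);
  std::vector<int> stack;
  int comp = 0;
  for (int z = 0; z < nz; ++z)
   for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      int idx = x + nx * (y + ny * z);
      if (!mask[idx] || out[idx] != 0) continue;
      ++comp;
      out[idx] = comp;
      stack.push_back(idx);
      while (!stack.empty()) {
        int cur = stack.back(); stack.pop_back();
        int cz = cur / (nx * ny);
        int cy = (cur / nx) % ny;
        int cx = cur % nx;
        for (int dz = -1; dz <= 1; ++dz)
         for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int qx = cx + dx, qy = cy + dy, qz = cz + dz;
            if (qx < 0 || qx >= nx || qy < 0 || qy >= ny ||
                qz < 0 || qz >= nz) continue;
            int qi = qx + nx * (qy + ny * qz);
            if (mask[qi] && out[qi] == 0) {
              out[qi] = comp;
              stack.push_back(qi);
            }
          }
      }
    }
  out.attr("ncomp") = comp;
  return out;
}

// Majority vote over f x f blocks of an integer label matrix (H*f x W*f),
// used to transfer upsampled superpixel labels back to the native grid.
// Ties break toward the smaller label id (deterministic).
// [[Rcpp::export]]
IntegerMatrix block_majority(IntegerMatrix labels, int f) {
  int H = labels.nrow() / f, W = labels.ncol() / f;
  IntegerMatrix out(H, W);
  std::vector<int> vals(f * f);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int n = 0;
      for (int bj = 0; bj < f; ++bj)
        for (int bi = 0; bi < f; ++bi)
          vals[n++] = labels(i * f + bi, j * f + bj);
      std::sort(vals.begin(), vals.end());
      int best = vals[0], bestCount = 1, run = 1;
      for (int k = 1; k < n; ++k) {
        if (vals[k] == vals[k - 1]) ++run; else run = 1;
        if (run > bestCount) { bestCount = run; best = vals[k]; }
      }
      out(i, j) = best;
    }
  }
  return out;
}
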
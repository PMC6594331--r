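#include <Rcpp.h>
using namespace Rcpp;

// Connected-component labeling of a 0/1 mask by breadth-first search.
// Labels are assigned in raster-scan order (row-major, top-left first), so
// label k is the k-th component encountered scanning rows left-to-right.
// connectivity: 4 (edge neighbours) or 8 (edge + diagonal neighbours).
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerMatrix cc_label_cpp(const IntegerMatrix &mask, int connectivity) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::vector<int> stack;
  stack.reserve(1024);
  int next = 0;

  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int nd = (connectivity == 8) ? 8 : 4;

  for (int r = 0; r < h; ++r) {
    for (int c = 0; c < w; ++c) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * h);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % h, cc = idx / h;
        for (int k = 0; k < nd; ++k) {
          int nr = cr + dr[k], nc = cc + dc[k];
          if (nr < 0 || nr >= h || nc < 0 || nc >= w) continue;
          if (mask(nr, nc) != 0 && lab(nr, nc) == 0) {
            lab(nr, nc) = next;
            stack.push_back(nr + nc * h);
          }
        }
      }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}

// CRC-32 (IEEE 802.3, as used by PNG chunks) of a raw vector.
// [[Rcpp::export(name = ".crc32_cpp")]]
double crc32_cpp(const RawVector &data) {
  static uint32_t table[256];
  static bool have_table = false;
  if (!have_table) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? (0xEDB88320u ^ (c >> 1)) : (c >> 1);
      table[i] = c;
    }
    have_table = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return static_cast<double>(crc ^ 0xFFFFFFFFu);
}
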
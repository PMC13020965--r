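#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

// Classic 3-D Perlin gradient noise with a seeded permutation table and
// fractal (octave) summation: amplitude halves and frequency doubles per
// octave.  Used to draw fibrosis archetypes on mesh element centroids.

namespace {

inline double fade(double t) { return t * t * t * (t * (t * 6 - 15) + 10); }
inline double lerp(double a, double b, double t) { return a + t * (b - a); }

// 12 edge-of-cube gradient directions
static const int GRAD[12][3] = {
  {1,1,0},{-1,1,0},{1,-1,0},{-1,-1,0},
  {1,0,1},{-1,0,1},{1,0,-1},{-1,0,-1},
  {0,1,1},{0,-1,1},{0,1,-1},{0,-1,-1}
};

struct Perm {
  int p[512];
  explicit Perm(uint32_t seed) {
    int base[256];
    for (int i = 0; i < 256; ++i) base[i] = i;
    // xorshift32 Fisher-Yates shuffle
    uint32_t s = seed ? seed : 0x9e3779b9u;
    for (int i = 255; i > 0; --i) {
      s ^= s << 13; s ^= s >> 17; s ^= s << 5;
      int j = (int)(s % (uint32_t)(i + 1));
      int tmp = base[i]; base[i] = base[j]; base[j] = tmp;
    }
    for (int i = 0; i < 512; ++i) p[i] = base[i & 255];
  }
};

inline double grad_dot(int h, double x, double y, double z) {
  const int* g = GRAD[h % 12];
  return g[0] * x + g[1] * y + g[2] * z;
}

double perlin3(const Perm& perm, double x, double y, double z) {
  int X = (int)std::floor(x), Y = (int)std::floor(y), Z = (int)std::floor(z);
  double xf = x - X, yf = y - Y, zf = z - Z;
  X &= 255; Y &= 255; Z &= 255;
  double u = fade(xf), v = fade(yf), w = fade(zf);
  const int* p = perm.p;
  int A  = p[X] + Y,     AA = p[A] + Z,     AB = p[A + 1] + Z;
  int B  = p[X + 1] + Y, BA = p[B] + Z,     BB = p[B + 1] + Z;
  double x1 = lerp(grad_dot(p[AA],     xf,     yf,     zf),
                   grad_dot(p[BA],     xf - 1, yf,     zf), u);
  double x2 = lerp(grad_dot(p[AB],     xf,     yf - 1, zf),
                   grad_dot(p[BB],     xf - 1, yf - 1, zf), u);
  double y1 = lerp(x1, x2, v);
  x1 = lerp(grad_dot(p[AA + 1], xf,     yf,     zf - 1),
            grad_dot(p[BA + 1], xf - 1, yf,     zf - 1), u);
  x2 = lerp(grad_dot(p[AB + 1], xf,     yf - 1, zf - 1),
            grad_dot(p[BB + 1], xf - 1, yf - 1, zf - 1), u);
  double y2 = lerp(x1, x2, v);
  return lerp(y1, y2, w);
}

} // namespace

// pts: N x 3 coordinates already scaled to noise space (1/feature_size and
// any fiber-frame anisotropic compression applied by the caller).
// [[Rcpp::export(name = ".perlin_fractal3d")]]
Rcpp::NumericVector perlin_fractal3d(Rcpp::NumericMatrix pts, int octaves,
                                     int seed) {
  if (octaves < 1) Rcpp::stop("octaves must be >= 1");
  const int n = pts.nrow();
  Rcpp::NumericVector out(n);
  double amp = 1.0, freq = 1.0, norm = 0.0;
  for (int o = 0; o < octaves; ++o) {
    Perm perm((uint32_t)(seed + 1315423911 * o));
    for (int i = 0; i < n; ++i)
      out[i] += amp * perlin3(perm, pts(i, 0) * freq + 0.1234,
                              pts(i, 1) * freq + 0.5678,
                              pts(i, 2) * freq + 0.9012);
    norm += amp;
    amp *= 0.5; freq *= 2.0;
  }
  for (int i = 0; i < n; ++i) out[i] /= norm;
  return out;
}
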
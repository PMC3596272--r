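#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pairwise-complete covariance (and sd's) for one SNP pair with missing data.
// Returns false if fewer than 2 complete observations or zero variance (for
// the correlation form).
static bool pair_cov(const NumericMatrix &G, int x, int y, double &cov,
                     double &sdx, double &sdy) {
  int n = G.nrow();
  double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
  int m = 0;
  for (int i = 0; i < n; i++) {
    double a = G(i, x), b = G(i, y);
    if (ISNAN(a) || ISNAN(b)) continue;
    sx += a; sy += b; sxx += a * a; syy += b * b; sxy += a * b;
    m++;
  }
  if (m < 2) return false;
  cov = (sxy - sx * sy / m) / (m - 1);
  double vx = (sxx - sx * sx / m) / (m - 1);
  double vy = (syy - sy * sy / m) / (m - 1);
  sdx = vx > 0 ? std::sqrt(vx) : 0.0;
  sdy = vy > 0 ? std::sqrt(vy) : 0.0;
  return true;
}


// Dot product with 4 accumulators (breaks the add-latency chain; the
// kernels below are bound by this loop).
static inline double dot4(const double *a, const double *b, int n) {
  double s0 = 0, s1 = 0, s2 = 0, s3 = 0;
  int i = 0;
  for (; i + 4 <= n; i += 4) {
    s0 += a[i] * b[i];
    s1 += a[i + 1] * b[i + 1];
    s2 += a[i + 2] * b[i + 2];
    s3 += a[i + 3] * b[i + 3];
  }
  for (; i < n; i++) s0 += a[i] * b[i];
  return s0 + s1 + s2 + s3;
}

// Weighted-LD decay curve accumulation. Z: centered dosage matrix
// (individuals x SNPs, complete-data column means removed); G: raw dosages
// with NA; hasmiss: per-SNP missingness flag; w: per-SNP weights; sd:
// per-SNP dosage standard deviation (complete data); pos in Morgans; chrom:
// integer chromosome codes, SNPs sorted by (chrom, pos). For every same-
// chromosome pair with 0 <= d <= d_max, accumulates into bin floor(d/bin):
//   sum_cov  += cov(x,y) * w[x] * w[y]
// and, when legacy = true, additionally
//   sum_wz += corr * w[x]*w[y];  sum_ww += (w[x]*w[y])^2;  sum_zz += corr^2.
// [[Rcpp::export]]
List cpp_pair_curve(NumericMatrix Z, NumericMatrix G, LogicalVector hasmiss,
                    NumericVector w, NumericVector sd, NumericVector pos,
                    IntegerVector chrom, double bin_width, double d_max,
                    bool legacy) {
  int p = Z.ncol(), n = Z.nrow();
  int n_bins = (int)std::ceil(d_max / bin_width - 1e-12);
  if (n_bins < 1) n_bins = 1;
  NumericVector sum_cov(n_bins), sum_wz(n_bins), sum_ww(n_bins),
      sum_zz(n_bins);
  NumericVector count(n_bins);
  double inv_nm1 = 1.0 / (n - 1);

  for (int x = 0; x < p; x++) {
    double px = pos[x];
    int cx = chrom[x];
    const double *zx = &Z(0, x);
    for (int y = x + 1; y < p; y++) {
      if (chrom[y] != cx) break;
      double d = pos[y] - px;
      if (d > d_max) break;
      int b = (int)(d / bin_width);
      if (b >= n_bins) b = n_bins - 1;
      double cov, sdx, sdy;
      if (!hasmiss[x] && !hasmiss[y]) {
        cov = dot4(zx, &Z(0, y), n) * inv_nm1;
        sdx = sd[x]; sdy = sd[y];
      } else {
        if (!pair_cov(G, x, y, cov, sdx, sdy)) continue;
      }
      double ww = w[x] * w[y];
      sum_cov[b] += cov * ww;
      count[b] += 1.0;
      if (legacy) {
        if (sdx <= 0 || sdy <= 0) continue;
        double corr = cov / (sdx * sdy);
        sum_wz[b] += corr * ww;
        sum_ww[b] += ww * ww;
        sum_zz[b] += corr * corr;
      }
    }
  }
  return List::create(_["sum_cov"] = sum_cov, _["count"] = count,
                      _["sum_wz"] = sum_wz, _["sum_ww"] = sum_ww,
                      _["sum_zz"] = sum_zz);
}

// As cpp_pair_curve (covariance form only), but returns per-chromosome bin
// sums and counts so a delete-one-chromosome jackknife can be assembled
// without recomputing pairs. chrom codes must be 0-based consecutive.
// [[Rcpp::export]]
List cpp_pair_curve_bychrom(NumericMatrix Z, NumericMatrix G,
                            LogicalVector hasmiss, NumericVector w,
                            NumericVector pos, IntegerVector chrom,
                            int n_chrom, double bin_width, double d_max) {
  int p = Z.ncol(), n = Z.nrow();
  int n_bins = (int)std::ceil(d_max / bin_width - 1e-12);
  if (n_bins < 1) n_bins = 1;
  NumericMatrix sum_cov(n_bins, n_chrom), count(n_bins, n_chrom);
  double inv_nm1 = 1.0 / (n - 1);

  for (int x = 0; x < p; x++) {
    double px = pos[x];
    int cx = chrom[x];
    const double *zx = &Z(0, x);
    for (int y = x + 1; y < p; y++) {
      if (chrom[y] != cx) break;
      double d = pos[y] - px;
      if (d > d_max) break;
      int b = (int)(d / bin_width);
      if (b >= n_bins) b = n_bins - 1;
      double cov, sdx, sdy;
      if (!hasmiss[x] && !hasmiss[y]) {
        cov = dot4(zx, &Z(0, y), n) * inv_nm1;
      } else {
        if (!pair_cov(G, x, y, cov, sdx, sdy)) continue;
      }
      sum_cov(b, cx) += cov * w[x] * w[y];
      count(b, cx) += 1.0;
    }
  }
  return List::create(_["sum_cov"] = sum_cov, _["count"] = count);
}

// Mean Pearson correlation of allele-sharing vectors per distance bin.
// S: (pair x SNP) matrix of standardized sharing columns already scaled so
// that dot(S[,x], S[,y]) is the correlation; ok: per-SNP flag (false =
// monomorphic sharing column, skipped).
// [[Rcpp::export]]
List cpp_sharing_autocorr(NumericMatrix S, LogicalVector ok,
                          NumericVector pos, IntegerVector chrom,
                          double bin_width, double d_max) {
  int p = S.ncol(), n = S.nrow();
  int n_bins = (int)std::ceil(d_max / bin_width - 1e-12);
  if (n_bins < 1) n_bins = 1;
  NumericVector sum(n_bins), count(n_bins);

  for (int x = 0; x < p; x++) {
    if (!ok[x]) continue;
    double px = pos[x];
    int cx = chrom[x];
    const double *sx = &S(0, x);
    for (int y = x + 1; y < p; y++) {
      if (chrom[y] != cx) break;
      double d = pos[y] - px;
      if (d > d_max) break;
      if (!ok[y]) continue;
      int b = (int)(d / bin_width);
      if (b >= n_bins) b = n_bins - 1;
      sum[b] += dot4(sx, &S(0, y), n);
      count[b] += 1.0;
    }
  }
  return List::create(_["sum"] = sum, _["count"] = count);
}

// One generation of random mating with recombination: children's gametes
// are parental haplotype mosaics with crossovers at Poisson rate 1 per
// Morgan per chromosome (phase alternating across crossovers, random
// starting haplotype). H: n_snps x 2N_parent matrix of 0/1 alleles; pos in
// Morgans sorted within chromosomes; chrom_start: 0-based first-SNP index
// of each chromosome plus a terminal n_snps. parents: 2 x n_children
// matrix of 0-based parent indices. Uses R's RNG.
// [[Rcpp::export]]
IntegerMatrix cpp_mate_generation(IntegerMatrix H, NumericVector pos,
                                  IntegerVector chrom_start,
                                  IntegerMatrix parents) {
  int n_snps = H.nrow();
  int n_child = parents.ncol();
  int n_chrom = chrom_start.size() - 1;
  IntegerMatrix out(n_snps, 2 * n_child);
  std::vector<double> bp;
  for (int c = 0; c < n_child; c++) {
    for (int g = 0; g < 2; g++) {
      int par = parents(g, c);
      const int *h1 = &H(0, 2 * par);
      const int *h2 = &H(0, 2 * par + 1);
      int *dst = &out(0, 2 * c + g);
      for (int k = 0; k < n_chrom; k++) {
        int lo = chrom_start[k], hi = chrom_start[k + 1];
        if (lo >= hi) continue;
        double p0 = pos[lo], p1 = pos[hi - 1];
        int n_co = (int)R::rpois(p1 - p0);
        int phase = (unif_rand() < 0.5) ? 0 : 1;
        if (n_co == 0) {
          const int *src = phase ? h2 : h1;
          for (int i = lo; i < hi; i++) dst[i] = src[i];
        } else {
          bp.resize(n_co);
          for (int b = 0; b < n_co; b++)
            bp[b] = p0 + unif_rand() * (p1 - p0);
          std::sort(bp.begin(), bp.end());
          int seg = 0;
          for (int i = lo; i < hi; i++) {
            while (seg < n_co && pos[i] >= bp[seg]) { seg++; phase ^= 1; }
            dst[i] = phase ? h2[i] : h1[i];
          }
        }
      }
    }
  }
  return out;
}
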
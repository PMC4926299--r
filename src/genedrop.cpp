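#include <Rcpp.h>
using namespace Rcpp;

// Transmit one gamete from a parent's two haplotypes over one chromosome.
// Crossover count ~ Poisson(length_morgans), positions uniform on the
// chromosome; SNP k sits at pos[k]. Start phase chosen at random.
static void meiosis_chrom(const int *hap1, const int *hap2,
                          const std::vector<double> &pos,
                          double len, int *out) {
  const int m = (int)pos.size();
  int ncx = (int)R::rpois(len);
  std::vector<double> cx(ncx);
  for (int c = 0; c < ncx; ++c) cx[c] = unif_rand() * len;
  std::sort(cx.begin(), cx.end());
  int phase = (unif_rand() < 0.5) ? 0 : 1;
  int c = 0;
  for (int k = 0; k < m; ++k) {
    while (c < ncx && cx[c] < pos[k]) {
      phase ^= 1;
      ++c;
    }
    out[k] = phase == 0 ? hap1[k] : hap2[k];
  }
}

// Gene-drop founder haplotypes through a topologically sorted pedigree.
// sire/dam: 1-based positions, 0 = unknown (treated as a base-population
// draw from the founder allele frequencies p). p has length
// n_chrom * snps_per_chrom. Returns the two haplotype matrices
// (animals x SNPs, alleles 0/1). Uses R's RNG stream.
// [[Rcpp::export]]
List genedrop_cpp(IntegerVector sire, IntegerVector dam, NumericVector p,
                  int n_chrom, int snps_per_chrom, double chrom_length) {
  const int n = sire.size();
  const int m = n_chrom * snps_per_chrom;
  if (p.size() != m) stop("allele frequency vector has wrong length");
  IntegerMatrix h1(n, m), h2(n, m);

  // SNPs evenly spaced along each chromosome
  std::vector<double> pos(snps_per_chrom);
  for (int k = 0; k < snps_per_chrom; ++k)
    pos[k] = (k + 0.5) / snps_per_chrom * chrom_length;

  std::vector<int> g1(m), g2(m), buf(snps_per_chrom);
  std::vector<int> par1(m), par2(m);

  for (int i = 0; i < n; ++i) {
    for (int which = 0; which < 2; ++which) {
      int par = which == 0 ? sire[i] : dam[i];
      std::vector<int> &gam = which == 0 ? g1 : g2;
      if (par == 0) {
        for (int j = 0; j < m; ++j) gam[j] = (unif_rand() < p[j]) ? 1 : 0;
      } else {
        for (int j = 0; j < m; ++j) {
          par1[j] = h1(par - 1, j);
          par2[j] = h2(par - 1, j);
        }
        for (int c = 0; c < n_chrom; ++c) {
          int off = c * snps_per_chrom;
          meiosis_chrom(&par1[off], &par2[off], pos, chrom_length, buf.data());
          for (int k = 0; k < snps_per_chrom; ++k) gam[off + k] = buf[k];
        }
      }
    }
    for (int j = 0; j < m; ++j) {
      h1(i, j) = g1[j];
      h2(i, j) = g2[j];
    }
  }
  return List::create(_["h1"] = h1, _["h2"] = h2);
}
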
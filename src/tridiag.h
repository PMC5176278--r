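#ifndef MIRTUMOR_TRIDIAG_H
#define MIRTUMOR_TRIDIAG_H

#include <vector>

// Thomas algorithm; rhs d is overwritten with the solution.
inline void thomas(const std::vector<double>& a,  // sub-diagonal (n-1)
                   const std::vector<double>& b,  // diagonal (n)
                   const std::vector<double>& c,  // super-diagonal (n-1)
                   std::vector<double>& d) {
  int n = (int)b.size();
  std::vector<double> cp(n - 1), dp(n);
  cp[0] = c[0] / b[0];
  dp[0] = d[0] / b[0];
  for (int i = 1; i < n; ++i) {
    double m = b[i] - a[i - 1] * cp[i - 1];
    if (i < n - 1) cp[i] = c[i] / m;
    dp[i] = (d[i] - a[i - 1] * dp[i - 1]) / m;
  }
  d[n - 1] = dp[n - 1];
  for (int i = n - 2; i >= 0; --i) d[i] = dp[i] - cp[i] * d[i + 1];
}

#endif
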
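// Exact linear algebra for the cleared fixation system.
//
// The cleared system has entries that are degree-one polynomials in the
// fitness r with integer coefficients (after scaling each row by the lcm of
// the vertex degrees).  At a rational fitness r = p/q the system
// (A0 + r A1) x = c0 + r c1 is equivalent to the integer system
// (q A0 + p A1) x = q c0 + p c1, which is solved by fraction-free
// (Bareiss) elimination followed by rational back-substitution.

#include "exact_common.h"
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_exact_solve(NumericMatrix A0, NumericMatrix A1,
                     NumericVector c0, NumericVector c1,
                     std::string p_str, std::string q_str) {
  const int n = A0.nrow();
  if (A0.ncol() != n || A1.nrow() != n || A1.ncol() != n ||
      c0.size() != n || c1.size() != n)
    stop("inconsistent system dimensions");
  mpz_class p(p_str), q(q_str);
  if (q <= 0 || p <= 0) stop("fitness must be a positive rational p/q");

  // Augmented integer matrix [M | b].
  std::vector<std::vector<mpz_class> > M(n, std::vector<mpz_class>(n + 1));
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      M[i][j] = q * mpz_class((long)A0(i, j)) + p * mpz_class((long)A1(i, j));
    }
    M[i][n] = q * mpz_class((long)c0[i]) + p * mpz_class((long)c1[i]);
  }

  // Bareiss fraction-free elimination with row pivoting.
  mpz_class prev(1);
  for (int k = 0; k < n - 1; ++k) {
    if (M[k][k] == 0) {
      int piv = -1;
      for (int i = k + 1; i < n; ++i) if (M[i][k] != 0) { piv = i; break; }
      if (piv < 0) stop("singular system in exact solve");
      std::swap(M[k], M[piv]);
      // A row swap flips the determinant sign; compensate so that the
      // Bareiss exact divisions stay exact.
      for (int j = 0; j <= n; ++j) M[k][j] = -M[k][j];
    }
    for (int i = k + 1; i < n; ++i) {
      for (int j = k + 1; j <= n; ++j) {
        mpz_class t = M[i][j] * M[k][k] - M[i][k] * M[k][j];
        mpz_divexact(M[i][j].get_mpz_t(), t.get_mpz_t(), prev.get_mpz_t());
      }
      M[i][k] = 0;
    }
    prev = M[k][k];
    if ((k & 15) == 0) checkUserInterrupt();
  }
  if (M[n - 1][n - 1] == 0) stop("singular system in exact solve");

  // Back substitution over Q.
  std::vector<mpq_class> x(n);
  for (int i = n - 1; i >= 0; --i) {
    mpq_class acc(M[i][n]);
    for (int j = i + 1; j < n; ++j) acc -= mpq_class(M[i][j]) * x[j];
    x[i] = acc / mpq_class(M[i][i]);
    x[i].canonicalize();
  }

  CharacterVector frac(n);
  NumericVector val(n);
  for (int i = 0; i < n; ++i) {
    frac[i] = rat_str(x[i]);
    val[i] = x[i].get_d();
  }
  return List::create(_["frac"] = frac, _["value"] = val);
}

// ---- modular helpers for fast rank detection ----

typedef unsigned long long u64;
typedef unsigned __int128 u128;

static inline u64 mulmod_u(u64 a, u64 b, u64 p) { return (u64)((u128)a * b % p); }

static u64 powmod_u(u64 a, u64 e, u64 p) {
  u64 r = 1;
  while (e) { if (e & 1) r = mulmod_u(r, a, p); a = mulmod_u(a, a, p); e >>= 1; }
  return r;
}

// rank of the row-echelon reduction of [A | b] mod p; also reports whether
// the system is consistent mod p
static void modular_rank(const std::vector<std::vector<mpz_class> >& M,
                         u64 p, int m, int& rankA, bool& consistent) {
  int n = (int)M.size();
  std::vector<std::vector<u64> > R(n, std::vector<u64>(m + 1));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j <= m; ++j) {
      mpz_class v = M[i][j] % (long)p;
      if (v < 0) v += (long)p;
      R[i][j] = v.get_ui();
    }
  rankA = 0;
  for (int col = 0; col < m && rankA < n; ++col) {
    int piv = -1;
    for (int i = rankA; i < n; ++i) if (R[i][col]) { piv = i; break; }
    if (piv < 0) continue;
    std::swap(R[rankA], R[piv]);
    u64 inv = powmod_u(R[rankA][col], p - 2, p);
    for (int j = col; j <= m; ++j) R[rankA][j] = mulmod_u(R[rankA][j], inv, p);
    for (int i = rankA + 1; i < n; ++i) {
      if (!R[i][col]) continue;
      u64 f = R[i][col];
      for (int j = col; j <= m; ++j) {
        u64 t = mulmod_u(f, R[rankA][j], p);
        R[i][j] = (R[i][j] + p - t) % p;
      }
    }
    ++rankA;
  }
  consistent = true;
  for (int i = rankA; i < n; ++i)
    if (R[i][m]) { consistent = false; break; }
}

// Dense exact solve with rank detection, used for the interpolation system
// of the fixation curve.  Rows are scaled to integers; rank deficiency is
// detected by row reduction modulo two large primes (a deficient report is
// an upper bound that the caller's held-out validation guards); a
// full-rank system is solved exactly by fraction-free (Bareiss)
// elimination.  Returns status "unique" with the solution, "deficient"
// with the rank so the caller can shrink the degree bound, or
// "inconsistent".
// [[Rcpp::export]]
List cpp_rat_solve(CharacterMatrix A, CharacterVector b) {
  const int n = A.nrow(), m = A.ncol();
  if (b.size() != n) stop("dimension mismatch");
  std::vector<std::vector<mpz_class> > M(n, std::vector<mpz_class>(m + 1));
  for (int i = 0; i < n; ++i) {
    std::vector<mpq_class> row(m + 1);
    mpz_class l(1);
    for (int j = 0; j <= m; ++j) {
      row[j] = parse_rat(as<std::string>(j < m ? A(i, j) : b[i]));
      if (row[j] != 0)
        mpz_lcm(l.get_mpz_t(), l.get_mpz_t(), row[j].get_den().get_mpz_t());
    }
    for (int j = 0; j <= m; ++j) {
      mpq_class t = row[j] * l;
      M[i][j] = t.get_num();
    }
  }

  // 2^61 - 1 is prime; the second prime is generated once
  static u64 primes[2] = { 2305843009213693951ULL, 0 };
  if (primes[1] == 0) {
    mpz_class q;
    mpz_nextprime(q.get_mpz_t(), mpz_class("1152921504606846976").get_mpz_t());
    primes[1] = q.get_ui();
  }
  int rank1, rank2; bool cons1, cons2;
  modular_rank(M, primes[0], m, rank1, cons1);
  if (rank1 < std::min(n, m)) {
    modular_rank(M, primes[1], m, rank2, cons2);
    int rank = std::max(rank1, rank2);
    bool cons = rank1 >= rank2 ? cons1 : cons2;
    if (rank < std::min(n, m) || n > m) {
      if (!cons)
        return List::create(_["status"] = "inconsistent", _["rank"] = rank);
      if (rank < m)
        return List::create(_["status"] = "deficient", _["rank"] = rank);
    }
  }
  if (n != m)
    return List::create(_["status"] = "deficient", _["rank"] = rank1);

  // Full rank (with overwhelming probability): solve modulo a stream of
  // 61-bit primes, combine by CRT, and recover the rational solution by
  // rational reconstruction; the candidate is verified against the system
  // modulo a fresh prime (and the caller re-validates at a held-out
  // point).  This keeps the cost polynomial in the true coefficient size.
  auto solve_mod = [&](u64 p, std::vector<u64>& x) -> bool {
    std::vector<std::vector<u64> > R(n, std::vector<u64>(n + 1));
    for (int i = 0; i < n; ++i)
      for (int j = 0; j <= n; ++j) {
        mpz_class v = M[i][j] % (long)p;
        if (v < 0) v += (long)p;
        R[i][j] = v.get_ui();
      }
    for (int k = 0; k < n; ++k) {
      int piv = -1;
      for (int i = k; i < n; ++i) if (R[i][k]) { piv = i; break; }
      if (piv < 0) return false; // p divides the determinant: skip prime
      std::swap(R[k], R[piv]);
      u64 inv = powmod_u(R[k][k], p - 2, p);
      for (int j = k; j <= n; ++j) R[k][j] = mulmod_u(R[k][j], inv, p);
      for (int i = 0; i < n; ++i) {
        if (i == k || !R[i][k]) continue;
        u64 f = R[i][k];
        for (int j = k; j <= n; ++j) {
          u64 t = mulmod_u(f, R[k][j], p);
          R[i][j] = (R[i][j] + p - t) % p;
        }
      }
    }
    x.resize(n);
    for (int i = 0; i < n; ++i) x[i] = R[i][n];
    return true;
  };

  std::vector<mpz_class> X(n, mpz_class(0)); // CRT accumulator
  mpz_class P(1);
  std::vector<mpq_class> sol_q(n);
  mpz_class prime("2305843009213693951"); // 2^61 - 1, then next primes
  bool done = false;
  for (int np = 0; np < 400 && !done; ++np) {
    u64 p = prime.get_ui();
    std::vector<u64> xp;
    if (solve_mod(p, xp)) {
      // CRT: X <- X + P * ((xp - X) * P^{-1} mod p)
      mpz_class pz((long)p);
      u64 Pinv = powmod_u(mpz_class(P % pz).get_ui() % p, p - 2, p);
      for (int i = 0; i < n; ++i) {
        mpz_class xi = X[i] % pz;
        u64 diff = (xp[i] + p - xi.get_ui() % p) % p;
        X[i] += P * mpz_class((long)mulmod_u(diff, Pinv, p));
      }
      P *= pz;
    }
    mpz_nextprime(prime.get_mpz_t(), prime.get_mpz_t());
    if (np < 3 || (np % 3) != 0) continue;
    // attempt rational reconstruction: |num|, den <= sqrt(P/2)
    mpz_class B;
    mpz_sqrt(B.get_mpz_t(), mpz_class(P / 2).get_mpz_t());
    bool ok = true;
    for (int i = 0; i < n && ok; ++i) {
      mpz_class r0 = P, s0 = 0, r1 = X[i], s1 = 1;
      while (r1 >= B) {
        mpz_class q = r0 / r1;
        mpz_class r2 = r0 - q * r1, s2 = s0 - q * s1;
        r0 = r1; s0 = s1; r1 = r2; s1 = s2;
      }
      if (s1 == 0) { ok = false; break; }
      mpz_class den = abs(s1), num = (s1 < 0) ? mpz_class(-r1) : r1;
      if (den > B) { ok = false; break; }
      mpz_class gg;
      mpz_gcd(gg.get_mpz_t(), num.get_mpz_t(), den.get_mpz_t());
      if (gg != 1) { num /= gg; den /= gg; }
      sol_q[i] = mpq_class(num, den);
      sol_q[i].canonicalize();
    }
    if (!ok) continue;
    // verify A x = b modulo a fresh prime
    mpz_class vq = prime;
    mpz_nextprime(vq.get_mpz_t(), vq.get_mpz_t());
    u64 q = vq.get_ui();
    std::vector<u64> xq(n);
    bool vok = true;
    for (int i = 0; i < n && vok; ++i) {
      mpz_class nu = sol_q[i].get_num() % (long)q; if (nu < 0) nu += (long)q;
      mpz_class de = sol_q[i].get_den() % (long)q;
      if (de == 0) { vok = false; break; }
      xq[i] = mulmod_u(nu.get_ui(), powmod_u(de.get_ui(), q - 2, q), q);
    }
    for (int i = 0; i < n && vok; ++i) {
      u64 acc = 0;
      for (int j = 0; j <= n; ++j) {
        mpz_class v = M[i][j] % (long)q;
        if (v < 0) v += (long)q;
        if (j < n) acc = (acc + mulmod_u(v.get_ui(), xq[j], q)) % q;
        else vok = acc == v.get_ui();
      }
    }
    done = vok;
    checkUserInterrupt();
  }
  if (!done)
    stop("internal: rational reconstruction of the solution failed");
  CharacterVector sol(n);
  NumericVector val(n);
  for (int k = 0; k < n; ++k) {
    sol[k] = rat_str(sol_q[k]);
    val[k] = sol_q[k].get_d();
  }
  return List::create(_["status"] = "unique", _["rank"] = n,
                      _["frac"] = sol, _["value"] = val);
}

// Scalar/vector arithmetic on fraction strings (elementwise, recycled).
// [[Rcpp::export]]
CharacterVector cpp_rat_arith(CharacterVector a, CharacterVector b, std::string op) {
  int n = std::max(a.size(), b.size());
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    mpq_class x = parse_rat(as<std::string>(a[i % a.size()]));
    mpq_class y = parse_rat(as<std::string>(b[i % b.size()]));
    mpq_class z;
    if (op == "+") z = x + y;
    else if (op == "-") z = x - y;
    else if (op == "*") z = x * y;
    else if (op == "/") {
      if (y == 0) stop("division by zero");
      z = x / y;
    } else stop("unknown op");
    z.canonicalize();
    out[i] = rat_str(z);
  }
  return out;
}

// Comparison of fraction strings: sign of a - b, elementwise.
// [[Rcpp::export]]
IntegerVector cpp_rat_cmp(CharacterVector a, CharacterVector b) {
  int n = std::max(a.size(), b.size());
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    mpq_class x = parse_rat(as<std::string>(a[i % a.size()]));
    mpq_class y = parse_rat(as<std::string>(b[i % b.size()]));
    out[i] = sgn(mpq_class(x - y));
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_rat_to_double(CharacterVector a) {
  NumericVector out(a.size());
  for (int i = 0; i < a.size(); ++i)
    out[i] = parse_rat(as<std::string>(a[i])).get_d();
  return out;
}

// Decimal rendering of a fraction with the requested number of significant
// digits, used by the high-precision display mode.
// [[Rcpp::export]]
std::string cpp_rat_to_decimal(std::string x, int digits) {
  if (digits < 1) stop("digits must be >= 1");
  mpq_class q = parse_rat(x);
  bool neg = q < 0;
  if (neg) q = -q;
  if (q == 0) return "0";
  mpz_class num = q.get_num(), den = q.get_den();
  // exponent: position of the leading digit
  mpz_class ip = num / den;
  std::string out;
  long expo = 0;
  if (ip > 0) {
    expo = (long)ip.get_str().size() - 1;
  } else {
    mpz_class t = num;
    while (t < den) { t *= 10; --expo; }
  }
  // scale so that we extract `digits` significant digits (plus one for rounding)
  long shift = digits - expo - 1;
  mpz_class sn = num, sd = den;
  mpz_class ten(10), f;
  if (shift >= 0) { mpz_pow_ui(f.get_mpz_t(), ten.get_mpz_t(), shift); sn *= f; }
  else { mpz_pow_ui(f.get_mpz_t(), ten.get_mpz_t(), -shift); sd *= f; }
  mpz_class d2, r2;
  mpz_fdiv_qr(d2.get_mpz_t(), r2.get_mpz_t(), sn.get_mpz_t(), sd.get_mpz_t());
  if (mpz_class(2 * r2) >= sd) d2 += 1; // round half up
  std::string digs = d2.get_str();
  if ((long)digs.size() > digits) { expo += (long)digs.size() - digits; digs = digs.substr(0, digits); }
  std::string mant = digs.substr(0, 1);
  if (digs.size() > 1) mant += "." + digs.substr(1);
  std::string res = (neg ? "-" : "") + mant;
  if (expo != 0) res += "e" + std::to_string(expo);
  return res;
}
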
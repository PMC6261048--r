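#ifndef EVOFIX_EXACT_COMMON_H
#define EVOFIX_EXACT_COMMON_H

#include <Rcpp.h>
#include <gmpxx.h>
#include <vector>
#include <string>

// Fraction strings use the canonical form "p" or "p/q" with q > 0.
inline mpq_class parse_rat(const std::string& s) {
  mpq_class x;
  if (x.set_str(s, 10) != 0)
    Rcpp::stop("invalid rational literal: '%s'", s.c_str());
  x.canonicalize();
  return x;
}

inline std::string rat_str(const mpq_class& x) { return x.get_str(); }

// Polynomials are coefficient vectors, constant term first.
typedef std::vector<mpq_class> QPoly;
typedef std::vector<mpz_class> ZPoly;

inline QPoly parse_poly(const Rcpp::CharacterVector& v) {
  QPoly p(v.size());
  for (int i = 0; i < v.size(); ++i) p[i] = parse_rat(Rcpp::as<std::string>(v[i]));
  while (p.size() > 1 && p.back() == 0) p.pop_back();
  return p;
}

inline Rcpp::CharacterVector poly_out(const QPoly& p) {
  Rcpp::CharacterVector v(p.size());
  for (size_t i = 0; i < p.size(); ++i) v[i] = rat_str(p[i]);
  return v;
}

inline bool poly_is_zero(const QPoly& p) {
  for (const auto& c : p) if (c != 0) return false;
  return true;
}

inline int poly_deg(const QPoly& p) {
  for (int i = (int)p.size() - 1; i >= 0; --i) if (p[i] != 0) return i;
  return -1; // zero polynomial
}

// Clear denominators and divide by integer content: primitive integer image.
inline ZPoly poly_primitive(const QPoly& p) {
  mpz_class l(1);
  for (const auto& c : p) if (c != 0) mpz_lcm(l.get_mpz_t(), l.get_mpz_t(), c.get_den().get_mpz_t());
  ZPoly z(p.size());
  for (size_t i = 0; i < p.size(); ++i) {
    mpq_class t = p[i] * l;
    z[i] = t.get_num(); // exact integer after lcm scaling
  }
  mpz_class g(0);
  for (const auto& c : z) mpz_gcd(g.get_mpz_t(), g.get_mpz_t(), c.get_mpz_t());
  if (g > 1) for (auto& c : z) c /= g;
  while (z.size() > 1 && z.back() == 0) z.pop_back();
  return z;
}

inline mpq_class poly_eval_q(const QPoly& p, const mpq_class& r) {
  mpq_class acc(0);
  for (int i = (int)p.size() - 1; i >= 0; --i) acc = acc * r + p[i];
  return acc;
}

inline int sgn_q(const mpq_class& x) { return sgn(x); }

#endif
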
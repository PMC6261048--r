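// Exact univariate polynomial arithmetic over Q and real-root isolation
// on (1, Inf), used for rational-function fixation curves and regime
// transitions.  Root isolation follows the classical Vincent-Collins-
// Akritas scheme (Descartes' rule on (0,1) via Moebius transforms) applied
// to the square-free radical of the numerator of Phi(r) - Phi0(r).

#include "exact_common.h"
using namespace Rcpp;

// ---------- basic arithmetic ----------

static QPoly q_add(const QPoly& a, const QPoly& b, int sign) {
  QPoly r(std::max(a.size(), b.size()), mpq_class(0));
  for (size_t i = 0; i < a.size(); ++i) r[i] += a[i];
  for (size_t i = 0; i < b.size(); ++i) r[i] += sign > 0 ? b[i] : mpq_class(-b[i]);
  for (auto& c : r) c.canonicalize();
  while (r.size() > 1 && r.back() == 0) r.pop_back();
  return r;
}

static QPoly q_mul(const QPoly& a, const QPoly& b) {
  if (poly_is_zero(a) || poly_is_zero(b)) return QPoly(1, mpq_class(0));
  QPoly r(a.size() + b.size() - 1, mpq_class(0));
  for (size_t i = 0; i < a.size(); ++i) {
    if (a[i] == 0) continue;
    for (size_t j = 0; j < b.size(); ++j) r[i + j] += a[i] * b[j];
  }
  for (auto& c : r) c.canonicalize();
  return r;
}

// Long division over Q; returns quotient, stores remainder in rem.
static QPoly q_divmod(const QPoly& a, const QPoly& b, QPoly& rem) {
  int db = poly_deg(b);
  if (db < 0) stop("polynomial division by zero");
  QPoly r = a, q(std::max((int)a.size() - db, 1), mpq_class(0));
  int dr = poly_deg(r);
  while (dr >= db) {
    mpq_class f = r[dr] / b[db];
    f.canonicalize();
    q[dr - db] = f;
    for (int j = 0; j <= db; ++j) {
      r[dr - db + j] -= f * b[j];
      r[dr - db + j].canonicalize();
    }
    r[dr] = 0;
    dr = poly_deg(r);
  }
  rem = r;
  while (rem.size() > 1 && rem.back() == 0) rem.pop_back();
  return q;
}

static QPoly q_deriv(const QPoly& a) {
  if (a.size() <= 1) return QPoly(1, mpq_class(0));
  QPoly r(a.size() - 1);
  for (size_t i = 1; i < a.size(); ++i) r[i - 1] = a[i] * (long)i;
  return r;
}

static int zdeg(const ZPoly& p) {
  for (int i = (int)p.size() - 1; i >= 0; --i) if (p[i] != 0) return i;
  return -1;
}

static mpz_class z_content(const ZPoly& p) {
  mpz_class g(0);
  for (const auto& c : p) mpz_gcd(g.get_mpz_t(), g.get_mpz_t(), c.get_mpz_t());
  return g;
}

// Primitive-PRS gcd of primitive integer polynomials; result is primitive
// with positive leading coefficient.
static ZPoly z_gcd(ZPoly a, ZPoly b) {
  if (zdeg(a) < zdeg(b)) std::swap(a, b);
  while (zdeg(b) >= 0) {
    int da = zdeg(a), db = zdeg(b);
    // lazy pseudo-remainder of a by b (content is stripped anyway)
    mpz_class lb = b[db];
    ZPoly r = a;
    for (int k = da; k >= db; --k) {
      mpz_class lr = r[k];
      if (lr == 0) continue;
      for (int j = 0; j < k; ++j) r[j] *= lb;
      r[k] = 0;
      for (int j = 0; j < db; ++j) r[k - db + j] -= lr * b[j];
    }
    r.resize(db > 0 ? db : 1, mpz_class(0));
    if (zdeg(r) < 0) { a = b; break; }
    mpz_class c = z_content(r);
    if (c > 1) for (auto& x : r) x /= c;
    a = b;
    b = r;
  }
  int da = zdeg(a);
  if (da >= 0 && a[da] < 0) for (auto& x : a) x = -x;
  return a;
}

static QPoly z_to_q(const ZPoly& z) {
  QPoly q(z.size());
  for (size_t i = 0; i < z.size(); ++i) q[i] = mpq_class(z[i]);
  return q;
}

// ---------- exported arithmetic ----------

// [[Rcpp::export]]
CharacterVector cpp_poly_arith(CharacterVector a, CharacterVector b, std::string op) {
  QPoly x = parse_poly(a), y = parse_poly(b);
  if (op == "+") return poly_out(q_add(x, y, +1));
  if (op == "-") return poly_out(q_add(x, y, -1));
  if (op == "*") return poly_out(q_mul(x, y));
  stop("unknown op");
}

// [[Rcpp::export]]
CharacterVector cpp_poly_deriv(CharacterVector a) {
  return poly_out(q_deriv(parse_poly(a)));
}

// [[Rcpp::export]]
List cpp_poly_eval(CharacterVector a, std::string r) {
  mpq_class v = poly_eval_q(parse_poly(a), parse_rat(r));
  return List::create(_["frac"] = rat_str(v), _["value"] = v.get_d(),
                      _["sign"] = sgn(v));
}

// [[Rcpp::export]]
CharacterVector cpp_poly_gcd(CharacterVector a, CharacterVector b) {
  QPoly x = parse_poly(a), y = parse_poly(b);
  if (poly_is_zero(x)) return poly_out(y);
  if (poly_is_zero(y)) return poly_out(x);
  return poly_out(z_to_q(z_gcd(poly_primitive(x), poly_primitive(y))));
}

// Exact division; errors if the remainder is nonzero.
// [[Rcpp::export]]
CharacterVector cpp_poly_divexact(CharacterVector a, CharacterVector b) {
  QPoly rem, q = q_divmod(parse_poly(a), parse_poly(b), rem);
  if (!poly_is_zero(rem)) stop("polynomial division is not exact");
  return poly_out(q);
}

// ---------- root isolation ----------

// Taylor shift by one: p(x) <- p(x + 1), in place (integer coefficients).
static void z_shift1(ZPoly& p) {
  int n = (int)p.size();
  for (int i = n - 2; i >= 0; --i)
    for (int j = i; j < n - 1; ++j)
      p[j] += p[j + 1];
}

static int z_variations(const ZPoly& p) {
  int v = 0, last = 0;
  for (const auto& c : p) {
    int s = sgn(c);
    if (s == 0) continue;
    if (last != 0 && s != last) ++v;
    last = s;
  }
  return v;
}

// Number of sign variations of (x+1)^n p(1/(x+1)): reverse then shift.
static int moebius_variations(const ZPoly& p) {
  ZPoly r(p.rbegin(), p.rend());
  z_shift1(r);
  return z_variations(r);
}

struct IsoResult {
  // isolating intervals (lo, hi) in u-space plus exact dyadic roots found
  // at subdivision points
  std::vector<std::pair<mpq_class, mpq_class> > intervals;
  std::vector<mpq_class> exact;
};

// p square-free with p(0) != 0, p(1) != 0; isolates the roots in (0,1).
static void vca(ZPoly p, mpq_class lo, mpq_class width, IsoResult& out, int depth) {
  if (depth > 400) stop("root isolation exceeded recursion bound");
  int v = moebius_variations(p);
  if (v == 0) return;
  if (v == 1) {
    out.intervals.push_back(std::make_pair(lo, lo + width));
    return;
  }
  int n = (int)p.size() - 1;
  // left half: 2^n p(x/2)
  ZPoly pl(p);
  mpz_class two(2), f;
  for (int i = 0; i <= n; ++i) {
    mpz_pow_ui(f.get_mpz_t(), two.get_mpz_t(), n - i);
    pl[i] *= f;
  }
  ZPoly pr(pl);
  z_shift1(pr); // right half: pl(x+1)
  mpq_class half = width / 2;
  mpq_class mid = lo + half;
  mid.canonicalize();
  if (pr[0] == 0) {
    // exact root at the midpoint; peel it off both halves
    out.exact.push_back(mid);
    pr.erase(pr.begin());
    // divide pl by (x - 1) synthetically (the midpoint maps to x = 1)
    ZPoly pl2(pl.size() - 1);
    mpz_class acc(0);
    for (int i = n; i >= 1; --i) { acc += pl[i]; pl2[i - 1] = acc; }
    pl = pl2;
  }
  vca(pl, lo, half, out, depth + 1);
  vca(pr, mid, half, out, depth + 1);
}

// Square-free radical (primitive integer image) of a rational polynomial.
static ZPoly q_radical(const QPoly& Pq) {
  ZPoly P = poly_primitive(Pq);
  ZPoly G = z_gcd(P, poly_primitive(q_deriv(z_to_q(P))));
  QPoly rem, radq = q_divmod(z_to_q(P), z_to_q(G), rem);
  if (!poly_is_zero(rem)) stop("internal: radical division not exact");
  return poly_primitive(radq);
}

// Isolate positive roots of the square-free integer polynomial Qs (with
// Qs(0) != 0) via a Cauchy bound and VCA on (0,1); returns roots in the
// variable of Qs.
static IsoResult isolate_positive(const ZPoly& Qs) {
  IsoResult iso;
  int n = zdeg(Qs);
  if (n < 1) return iso;
  mpz_class an = abs(Qs[n]), mx(0);
  for (int i = 0; i < n; ++i) if (abs(Qs[i]) > mx) mx = abs(Qs[i]);
  mpz_class bound = mx / an + 2, b2(1);
  while (b2 < bound) b2 <<= 1;
  ZPoly S(Qs.begin(), Qs.begin() + n + 1);
  mpz_class f(1);
  for (int i = 1; i <= n; ++i) { f *= b2; S[i] *= f; }
  IsoResult iso01;
  vca(S, mpq_class(0), mpq_class(1), iso01, 0);
  mpq_class B(b2);
  for (auto& it : iso01.intervals) {
    mpq_class lo = B * it.first, hi = B * it.second;
    lo.canonicalize(); hi.canonicalize();
    iso.intervals.push_back(std::make_pair(lo, hi));
  }
  for (auto& e : iso01.exact) {
    mpq_class x = B * e;
    x.canonicalize();
    iso.exact.push_back(x);
  }
  return iso;
}

// Isolate all real roots of M in the open interval (1, Inf).
//
// Returns `zero` = TRUE if M is identically zero; otherwise parallel
// vectors describing each distinct root in ascending order: exact rational
// isolating endpoints, refined double endpoints of width <= tol, the sign
// of M strictly before and after the root, and whether the sign changes
// (odd multiplicity, i.e. a regime transition when M is the numerator of
// Phi - Phi0).
// [[Rcpp::export]]
List cpp_isolate_roots_gt1(CharacterVector coef, double tol) {
  QPoly M = parse_poly(coef);
  if (poly_is_zero(M))
    return List::create(_["zero"] = true);

  ZPoly rad = q_radical(M);

  // shift to t = r - 1 and strip any root at t = 0 (the domain is open)
  ZPoly Q = rad;
  z_shift1(Q);
  size_t k0 = 0;
  while (k0 < Q.size() && Q[k0] == 0) ++k0;
  ZPoly Qs(Q.begin() + k0, Q.end());
  IsoResult iso = isolate_positive(Qs);

  // roots in r-space
  struct Root { mpq_class lo, hi; bool exact; };
  std::vector<Root> roots;
  for (auto& it : iso.intervals) {
    Root rt; rt.lo = 1 + it.first; rt.hi = 1 + it.second; rt.exact = false;
    rt.lo.canonicalize(); rt.hi.canonicalize();
    roots.push_back(rt);
  }
  for (auto& e : iso.exact) {
    Root rt; rt.lo = 1 + e; rt.lo.canonicalize(); rt.hi = rt.lo; rt.exact = true;
    roots.push_back(rt);
  }
  std::sort(roots.begin(), roots.end(),
            [](const Root& a, const Root& b) { return a.lo + a.hi < b.lo + b.hi; });
  int nr = (int)roots.size();

  // W: the radical with the root at r = 1 (if any) and all exact dyadic
  // roots divided out, so that W is nonzero at every interval endpoint.
  QPoly W = z_to_q(rad);
  if (k0 > 0) {
    QPoly lin(2); lin[0] = -1; lin[1] = 1; // (r - 1)
    QPoly rem; W = q_divmod(W, lin, rem);
    if (!poly_is_zero(rem)) stop("internal: (r-1) division not exact");
  }
  for (auto& rt : roots) {
    if (!rt.exact) continue;
    QPoly lin(2); lin[0] = -rt.lo; lin[1] = 1;
    QPoly rem; W = q_divmod(W, lin, rem);
    if (!poly_is_zero(rem)) stop("internal: exact-root division not exact");
  }

  // refine: width <= tol and strict separation between consecutive regions
  // (and from the left boundary r = 1)
  auto refine_once = [&](Root& rt) {
    mpq_class mid = (rt.lo + rt.hi) / 2;
    mid.canonicalize();
    int sl = sgn_q(poly_eval_q(W, rt.lo));
    int sm = sgn_q(poly_eval_q(W, mid));
    if (sm == 0) { rt.lo = rt.hi = mid; rt.exact = true; return; }
    if (sm == sl) rt.lo = mid; else rt.hi = mid;
  };
  for (auto& rt : roots) {
    if (rt.exact) continue;
    int sl = sgn_q(poly_eval_q(W, rt.lo)), sh = sgn_q(poly_eval_q(W, rt.hi));
    if (sl == 0 || sh == 0 || sl == sh) stop("internal: invalid isolating interval");
    int guard = 0;
    while (!rt.exact && mpq_class(rt.hi - rt.lo).get_d() > tol) {
      refine_once(rt);
      if (++guard > 5000) stop("internal: refinement did not converge");
    }
  }
  {
    int guard = 0;
    bool again = true;
    while (again) {
      again = false;
      for (int i = 0; i < nr; ++i) {
        mpq_class prev = (i == 0) ? mpq_class(1) : roots[i - 1].hi;
        if (!(prev < roots[i].lo) && !roots[i].exact) { refine_once(roots[i]); again = true; }
        else if (!(prev < roots[i].lo) && roots[i].exact && i > 0 && !roots[i - 1].exact) {
          refine_once(roots[i - 1]); again = true;
        } else if (!(prev < roots[i].lo) && roots[i].exact && (i == 0 || roots[i - 1].exact)) {
          // two exact roots (or boundary) cannot coincide; nothing to do
          if (prev == roots[i].lo && !(i > 0 && roots[i - 1].exact && roots[i - 1].hi == roots[i].lo))
            stop("internal: cannot separate root from boundary");
        }
      }
      if (++guard > 20000) stop("internal: separation did not converge");
    }
  }

  // signs of M on the gaps between consecutive root regions
  QPoly Mprim = z_to_q(poly_primitive(M)); // positive rescaling keeps signs
  std::vector<int> gap_sign(nr + 1);
  for (int g = 0; g <= nr; ++g) {
    mpq_class pt;
    if (nr == 0) pt = 2;
    else if (g == 0) pt = (1 + roots[0].lo) / 2;
    else if (g == nr) pt = roots[nr - 1].hi + 1;
    else pt = (roots[g - 1].hi + roots[g].lo) / 2;
    pt.canonicalize();
    gap_sign[g] = sgn_q(poly_eval_q(Mprim, pt));
    if (gap_sign[g] == 0) stop("internal: gap point is a root");
  }

  CharacterVector lo_s(nr), hi_s(nr);
  NumericVector lo_d(nr), hi_d(nr), mid_d(nr);
  IntegerVector s_before(nr), s_after(nr);
  LogicalVector changes(nr), exact(nr);
  for (int i = 0; i < nr; ++i) {
    lo_s[i] = rat_str(roots[i].lo); hi_s[i] = rat_str(roots[i].hi);
    lo_d[i] = roots[i].lo.get_d(); hi_d[i] = roots[i].hi.get_d();
    mid_d[i] = mpq_class((roots[i].lo + roots[i].hi) / 2).get_d();
    s_before[i] = gap_sign[i]; s_after[i] = gap_sign[i + 1];
    changes[i] = gap_sign[i] != gap_sign[i + 1];
    exact[i] = roots[i].exact;
  }
  return List::create(_["zero"] = false, _["n_roots"] = nr,
                      _["root"] = mid_d, _["lo"] = lo_d, _["hi"] = hi_d,
                      _["lo_str"] = lo_s, _["hi_str"] = hi_s,
                      _["sign_before"] = s_before, _["sign_after"] = s_after,
                      _["sign_change"] = changes, _["is_exact"] = exact,
                      _["sign_tail"] = gap_sign[nr]);
}

// Count distinct real roots in (0, Inf): used to certify that fixation-
// curve denominators have no positive poles.
// [[Rcpp::export]]
int cpp_count_roots_pos(CharacterVector coef) {
  QPoly M = parse_poly(coef);
  if (poly_is_zero(M)) stop("zero polynomial");
  ZPoly rad = q_radical(M);
  size_t k0 = 0;
  while (k0 < rad.size() && rad[k0] == 0) ++k0;
  ZPoly Qs(rad.begin() + k0, rad.end());
  IsoResult iso = isolate_positive(Qs);
  return (int)(iso.intervals.size() + iso.exact.size());
}
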
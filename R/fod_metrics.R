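## Divergence-entropy scoring: Kullback-Leibler divergence (bits), the
## relative-distance score RD, the environment-modified field M(K), and the
## optimisation of the environment-participation parameter K.

#' Kullback-Leibler divergence (bits)
#'
#' `D_KL(P|Q) = sum_i P_i log2(P_i / Q_i)`, with the convention
#' `0 * log(0/q) = 0`.  Q entries are floored at `eps` (no renormalisation)
#' so that profiles with exact zeros — which arise only in pathological
#' cases, since the Gaussian T is strictly positive — remain scorable.
#'
#' @param p,q profiles ([fod_profile] or plain numeric, same length; `p`
#'   should be normalised).
#' @param eps floor applied to `q` (default `1e-12`).
#' @return divergence in bits (non-negative for normalised inputs).
#' @examples
#' dkl(c(1, 0), c(0.5, 0.5))   # 1 bit
#' @export
dkl <- function(p, q, eps = 1e-12) {
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != length(q))
    fodm_stop(sprintf("profile length mismatch: %d vs %d",
                      length(p), length(q)), "fodm_shape_error")
  q <- pmax(q, eps)
  i <- p > 0
  sum(p[i] * log2(p[i] / q[i]))
}

#' Relative-distance score RD
#'
#' `RD = D_KL(O|T) / (D_KL(O|T) + D_KL(O|R))`: 0 when the observed
#' distribution coincides with the theoretical micelle-like field, 1 when
#' it coincides with the undifferentiated uniform reference.  Values above
#' 0.5 indicate that O is further from the micelle-like arrangement than
#' from no arrangement at all.
#'
#' @param o,t profiles of equal length (observed, theoretical).
#' @param r reference profile; uniform `1/n` by default.
#' @return RD in \[0, 1\], or `NA` with a warning when both divergences are
#'   zero (O, T and R all identical) and the ratio is undefined.
#' @export
rd_score <- function(o, t, r = NULL) {
  o <- as.numeric(o); t <- as.numeric(t)
  if (is.null(r)) r <- rep(1 / length(o), length(o))
  d_ot <- dkl(o, t)
  d_or <- dkl(o, r)
  if (d_ot + d_or <= 0) {
    fodm_warn("O, T and R coincide; RD is undefined (returning NA)")
    return(NA_real_)
  }
  d_ot / (d_ot + d_or)
}

norm_complement <- function(t) {
  t <- as.numeric(t)
  comp <- max(t) - t
  s <- sum(comp)
  if (s <= 0) return(NULL)   # constant T: complement degenerate
  comp / s
}

#' Environment-modified profile M(K)
#'
#' The modified target field blends the micelle-like Gaussian T with its
#' normalised complement (the "inverse" field `T_MAX - Ti`, normalised),
#' weighted by the environment-participation parameter K, and renormalises:
#' `Mi = [Ti + K * (T_MAX - Ti)_n]_n`.  K = 0 recovers T; as K grows, M
#' approaches the normalised complement.
#'
#' @param t a normalised T-role profile.
#' @param k participation parameter (>= 0).
#' @return an M-role [fod_profile].  For constant `t` the complement is
#'   identically zero; `t` is returned with a warning.
#' @export
m_profile <- function(t, k) {
  if (length(k) != 1L || !is.finite(k) || k < 0)
    fodm_stop("K must be a single value >= 0", "fodm_value_error")
  tv <- as.numeric(t)
  comp <- norm_complement(tv)
  if (is.null(comp)) {
    if (k > 0) fodm_warn("T is constant; M(K) equals T for every K")
    return(fod_profile(tv, role = "M", selection = attr(t, "selection"),
                       normalize = TRUE))
  }
  fod_profile(tv + k * comp, role = "M", selection = attr(t, "selection"))
}

# D_KL(o | M(t, K)) for a whole grid of K at once.  Because sum(t) = 1 and
# the normalised complement also sums to 1, the normaliser of M(K) is
# simply 1 + K.
dkl_om_grid <- function(o, t, kgrid, eps = 1e-12) {
  o <- as.numeric(o); t <- as.numeric(t)
  comp <- norm_complement(t)
  if (is.null(comp)) return(rep(dkl(o, t, eps), length(kgrid)))
  M <- (outer(t, rep(1, length(kgrid))) + outer(comp, kgrid)) /
    rep(1 + kgrid, each = length(t))
  i <- o > 0
  base <- sum(o[i] * log2(o[i]))
  base - colSums(o[i] * log2(pmax(M[i, , drop = FALSE], eps)))
}

#' Optimal environment-participation parameter K
#'
#' Finds the K >= 0 whose modified field M(T, K) is closest to the observed
#' distribution, i.e. minimises `D_KL(O | M(T,K))`.  A coarse grid scan
#' (`0` to `k_max` in steps of `step`) locates the basin; golden-section
#' refinement on the bracketing interval then polishes the minimum.
#' Reported K is also rounded to one decimal, the granularity at which
#' table-style output is conventionally printed; the raw value is kept.
#'
#' @param o,t profiles of equal length.
#' @param k_max upper search bound (default 10; membrane complexes can
#'   need K > 3).
#' @param step coarse grid step (default 0.01).
#' @param refine golden-section refinement of the grid minimum (default
#'   `TRUE`).
#' @return list with `k_opt` (raw), `k` (rounded to 0.1), `dkl_om_min`
#'   (bits), and `at_bound` (`TRUE` if the optimum sits at `k_max`).
#' @export
optimize_k <- function(o, t, k_max = 10, step = 0.01, refine = TRUE) {
  o <- as.numeric(o); t <- as.numeric(t)
  if (length(o) != length(t))
    fodm_stop("O and T must have equal length", "fodm_shape_error")
  kgrid <- seq(0, k_max, by = step)
  dk <- dkl_om_grid(o, t, kgrid)
  j <- which.min(dk)
  k_best <- kgrid[j]; d_best <- dk[j]
  if (refine && j > 1 && j < length(kgrid)) {
    opt <- optimize(function(k) dkl(o, m_profile(t, k)),
                    interval = c(kgrid[j - 1], kgrid[j + 1]),
                    tol = 1e-6)
    if (opt$objective < d_best) {
      k_best <- opt$minimum; d_best <- opt$objective
    }
  }
  list(k_opt = k_best, k = round(k_best, 1), dkl_om_min = d_best,
       at_bound = (j == length(kgrid)))
}

#' K at which the modified field becomes uniform
#'
#' The uniform reference R marks the balance point between the Gaussian
#' field and its complement: this function returns the K minimising
#' `D_KL(R | M(T,K))`, i.e. the participation level at which the modified
#' target field is closest to carrying no hydrophobicity differentiation at
#' all.  Systems whose optimal K exceeds this value are dominated by the
#' "inverse" field.
#'
#' @inheritParams optimize_k
#' @param t a non-constant T-role profile.
#' @return list as in [optimize_k()] (the `k_opt` component is the
#'   R-equivalence K).
#' @export
r_equivalence_k <- function(t, k_max = 10, step = 0.01, refine = TRUE) {
  tv <- as.numeric(t)
  if (is.null(norm_complement(tv)))
    fodm_stop("T is constant; the R-equivalence K is undefined",
              "fodm_numeric_error")
  optimize_k(rep(1 / length(tv), length(tv)), tv,
             k_max = k_max, step = step, refine = refine)
}

#' Full FOD score for one selection
#'
#' Convenience wrapper bundling the divergences, RD and the K optimisation
#' for one (O, T) pair into a single record.
#'
#' @param o,t profiles of equal length.
#' @param r reference profile (uniform by default).
#' @param selection_name label carried into reports.
#' @param conventions optional list recording scale/kernel/sigma settings.
#' @param r_equiv also compute the R-equivalence K (default `FALSE`).
#' @inheritParams optimize_k
#' @return object of class `"fod_score"`: list with `selection`, `n`, `rd`,
#'   `dkl_ot`, `dkl_or`, `dkl_om_min`, `k_opt`, `k`, `k_r_equiv` (or `NA`),
#'   `at_bound`, `conventions`.
#' @export
fod_score <- function(o, t, r = NULL, selection_name = "",
                      conventions = NULL, k_max = 10, step = 0.01,
                      r_equiv = FALSE) {
  o <- as.numeric(o); t <- as.numeric(t)
  if (is.null(r)) r <- rep(1 / length(o), length(o))
  ko <- optimize_k(o, t, k_max = k_max, step = step)
  res <- list(selection = selection_name, n = length(o),
              rd = rd_score(o, t, r),
              dkl_ot = dkl(o, t), dkl_or = dkl(o, r),
              dkl_om_min = ko$dkl_om_min,
              k_opt = ko$k_opt, k = ko$k, at_bound = ko$at_bound,
              k_r_equiv = if (r_equiv)
                r_equivalence_k(t, k_max = k_max, step = step)$k_opt
                else NA_real_,
              conventions = conventions)
  class(res) <- "fod_score"
  res
}

#' @export
print.fod_score <- function(x, ...) {
  cat(sprintf("<fod_score> %s (n = %d): RD = %.3f, K = %.1f (raw %.3f)\n",
              if (nzchar(x$selection)) x$selection else "(unnamed)",
              x$n, x$rd, x$k, x$k_opt))
  cat(sprintf("  D_KL(O|T) = %.4f, D_KL(O|R) = %.4f, min D_KL(O|M) = %.4f bits\n",
              x$dkl_ot, x$dkl_or, x$dkl_om_min))
  if (!is.na(x$k_r_equiv))
    cat(sprintf("  R-equivalence K = %.2f\n", x$k_r_equiv))
  invisible(x)
}
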
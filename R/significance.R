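#' Null CDF of the Pearson correlation of two random vectors
#'
#' The marginal null for a single fixed-placement window comparison: for two
#' independent smooth Gaussian profiles with m effective degrees of freedom
#' the correlation c has density proportional to (1 - c^2)^((m-3)/2).
#' Equivalently (c + 1) / 2 ~ Beta(a, a) with a = (m - 1) / 2, so the CDF is
#' the regularized incomplete beta function. PSF smoothing reduces m below
#' the pixel count; the calibrated effective-pixel model accounts for it.
#'
#' @param c Correlation value(s) in `[-1, 1]`.
#' @param m Effective sample size (>= 4; may be non-integer).
#' @return `P(PCC <= c)`.
#' @export
pcc_null_cdf <- function(c, m) {
  if (any(m < 4)) stop("effective sample size m must be >= 4", call. = FALSE)
  if (any(c < -1 - 1e-6 | c > 1 + 1e-6)) {
    stop("correlation outside [-1, 1]", call. = FALSE)
  }
  c <- pmin(pmax(c, -1), 1)  # absorb float round-off from exact matches
  a <- (m - 1) / 2
  stats::pbeta((c + 1) / 2, a, a)
}

pcc_null_logpdf <- function(c, m) {
  a <- (m - 1) / 2
  stats::dbeta((pmin(pmax(c, -1), 1) + 1) / 2, a, a, log = TRUE) - log(2)
}

pcc_null_logcdf <- function(c, m) {
  a <- (m - 1) / 2
  stats::pbeta((pmin(pmax(c, -1), 1) + 1) / 2, a, a, log.p = TRUE)
}

#' Number of tested placements for a barcode pair
#'
#' Counts the comparisons performed by [best_local_overlap()] for a pair
#' with the given raw lengths: window placements summed over the rescaling
#' grid times the searched orientations. Used as the trial count K of the
#' extreme-value null, so p-values are comparable across pairs of differing
#' lengths.
#'
#' @param n_ref,n_query Raw pixel lengths (reference is the rescaled side).
#' @param p An [overlap_params()].
#' @return Integer-valued count.
#' @export
placement_count <- function(n_ref, n_query, p) {
  k2 <- max(0L, n_query - p$w + 1L)
  k1 <- sum(pmax(0, round(p$r_grid * n_ref) - p$w + 1))
  k1 * k2 * length(p$orientations)
}

fit_gumbel <- function(z) {
  nll <- function(par) {
    mu <- par[1]; be <- exp(par[2])
    t <- (z - mu) / be
    -sum(-log(be) - t - exp(-t))
  }
  f <- stats::optim(c(mean(z), log(stats::sd(z))), nll,
                    control = list(reltol = 1e-12, maxit = 5000))
  list(mu = f$par[1], beta = exp(f$par[2]), convergence = f$convergence)
}

#' Calibrate the overlap null model by Monte Carlo
#'
#' Simulates `calib_n` independent pairs of PSF-smoothed random barcodes
#' (no true overlap), scores each with the full overlap search, and fits
#' three null components by maximum likelihood:
#'
#' * the local max statistic: a Gumbel law for `atanh(C_max)` at the
#'   calibration trial count `K_cal`; extreme-value max-stability transfers
#'   it to other pair lengths through `G(c)^(K / K_cal)`;
#' * a beta-power model `F(c; m_eff_factor * w)^(nu * K)` (the classical
#'   effective-trials form), retained for p-values of full-length reference
#'   alignments whose window width differs from `w`;
#' * the leftover score *conditional on the selected placement*: a shifted
#'   beta with location `shift1/n + shift2/sqrt(n)` and effective degrees
#'   of freedom `dof_a * n + dof_b`. The location term is required because
#'   conditioning on the local arg-max depresses the leftover correlation
#'   slightly below zero; an unshifted (symmetric) null is measurably
#'   non-uniform under the pipeline.
#'
#' @param p An [overlap_params()].
#' @param barcode_len_1,barcode_len_2 Lengths (px) of the simulated pairs.
#' @param psf_sigma_px PSF width of the simulated barcodes; should match the
#'   data the model will be applied to.
#' @param calib_n Number of simulated pairs (>= 200; the default 1000 keeps
#'   the fitted tail stable).
#' @param seed Integer seed; calibration is deterministic given it.
#' @return A list of class `null_model_params`.
#' @export
calibrate_null <- function(p = overlap_params(), barcode_len_1 = 850L,
                           barcode_len_2 = 850L, psf_sigma_px = 1.5,
                           calib_n = 1000L, seed = 1L) {
  calib_n <- as.integer(calib_n)
  if (calib_n < 200L) stop("calib_n must be >= 200", call. = FALSE)
  w <- p$w
  C <- numeric(calib_n)
  Cl <- rep(NA_real_, calib_n)
  nl <- integer(calib_n)
  for (i in seq_len(calib_n)) {
    b1 <- random_reference(barcode_len_1, psf_sigma_px,
                           seed = split_seed(seed, 2L * i), id = "cal1")
    b2 <- random_reference(barcode_len_2, psf_sigma_px,
                           seed = split_seed(seed, 2L * i + 1L), id = "cal2")
    cand <- best_local_overlap(b1, b2, p)
    C[i] <- cand$C
    Cl[i] <- cand$C_leftover
    nl[i] <- cand$n_leftover
  }
  K_cal <- placement_count(barcode_len_1, barcode_len_2, p)

  gum <- fit_gumbel(atanh(pmin(pmax(C, -1 + 1e-12), 1 - 1e-12)))

  # beta-power (effective trials) fit, used for full-length alignments
  nll_bp <- function(par) {
    nu <- exp(par[1]); mf <- stats::plogis(par[2])
    m <- pmax(4.5, mf * w)
    -sum(log(nu * K_cal) + (nu * K_cal - 1) * pcc_null_logcdf(C, m) +
           pcc_null_logpdf(C, m))
  }
  bp <- stats::optim(c(log(1e-3), stats::qlogis(0.25)), nll_bp,
                     control = list(reltol = 1e-12, maxit = 5000))
  nu <- exp(bp$par[1]); m_eff_factor <- stats::plogis(bp$par[2])
  if (nu < 1e-6 || nu > 1) {
    stop("degenerate null calibration: nu = ", format(nu), call. = FALSE)
  }

  ok <- !is.na(Cl) & nl >= p$min_leftover
  if (sum(ok) < 50L) stop("too few leftover samples to calibrate", call. = FALSE)
  nll_lo <- function(par) {
    s1 <- par[1]; s2 <- par[2]; a <- exp(par[3]); b <- par[4]
    m <- pmax(4.5, a * nl[ok] + b)
    cc <- Cl[ok] - s1 / nl[ok] - s2 / sqrt(nl[ok])
    if (any(abs(cc) >= 1)) return(1e10)
    -sum(pcc_null_logpdf(cc, m))
  }
  lo <- stats::optim(c(-5, -0.1, log(0.28), 0), nll_lo,
                     control = list(reltol = 1e-12, maxit = 10000))

  structure(list(w = w, K_cal = K_cal,
                 gum_mu = gum$mu, gum_beta = gum$beta,
                 nu = nu, m_eff_factor = m_eff_factor,
                 lo_shift1 = lo$par[1], lo_shift2 = lo$par[2],
                 lo_dof_a = exp(lo$par[3]), lo_dof_b = lo$par[4],
                 psf_sigma_px = psf_sigma_px, calib_n = calib_n,
                 seed = as.integer(seed), overlap_params = p),
            class = "null_model_params")
}

#' @export
print.null_model_params <- function(x, ...) {
  cat(sprintf(paste0("<null_model_params> w=%d (psf %.2g px, n=%d)\n",
                     "  local max: Gumbel(mu=%.4f, beta=%.4f) on atanh scale, K_cal=%.3g\n",
                     "  beta-power: nu=%.3g, m_eff_factor=%.3g\n",
                     "  leftover: shift %.2f/n %+.3f/sqrt(n), dof %.3g*n %+.2f\n"),
              x$w, x$psf_sigma_px, x$calib_n, x$gum_mu, x$gum_beta, x$K_cal,
              x$nu, x$m_eff_factor, x$lo_shift1, x$lo_shift2, x$lo_dof_a,
              x$lo_dof_b))
  invisible(x)
}

clamp_p <- function(p) pmin(pmax(p, 1e-15), 1 - 1e-15)

#' Local-overlap p-value
#'
#' Converts a best local overlap score to a p-value under the calibrated
#' max-statistics null: with `G` the fitted Gumbel CDF of `atanh(C_max)` at
#' the calibration trial count, `p = 1 - G(atanh(C))^(K / K_cal)`, clamped
#' to `[1e-15, 1 - 1e-15]`; strictly decreasing in C.
#'
#' @param C Local overlap score(s).
#' @param params A `null_model_params`.
#' @param K Number of tested placements for the pair (see
#'   [placement_count()]).
#' @param w Window width the score was computed with; must match the
#'   calibration.
#' @return p-value(s).
#' @export
p_local <- function(C, params, K, w = params$w) {
  if (w != params$w) {
    stop("null model calibrated for w=", params$w, ", got w=", w, call. = FALSE)
  }
  z <- atanh(pmin(pmax(C, -1 + 1e-12), 1 - 1e-12))
  gamma <- K / params$K_cal
  clamp_p(1 - exp(-gamma * exp(-(z - params$gum_mu) / params$gum_beta)))
}

#' Leftover p-value
#'
#' Single-comparison test of the leftover correlation under its calibrated
#' conditional null (the placement was fixed by the local stage, so no
#' max-statistics correction applies, but the arg-max selection shifts the
#' conditional location slightly): the score is re-centred by the fitted
#' `shift1/n + shift2/sqrt(n)` and referred to the beta null with
#' `max(4, dof_a * n + dof_b)` effective degrees of freedom.
#'
#' @param C_leftover Leftover correlation(s).
#' @param n_leftover Leftover pixel count(s).
#' @param params A `null_model_params`.
#' @param min_leftover Below this count the test is undefined (single-score
#'   mode) and NA is returned.
#' @return p-value(s), NA where single-score.
#' @export
p_leftover <- function(C_leftover, n_leftover, params, min_leftover = 20L) {
  out <- rep(NA_real_, length(C_leftover))
  ok <- !is.na(C_leftover) & n_leftover >= min_leftover
  if (any(ok)) {
    n <- n_leftover[ok]
    m <- pmax(4, params$lo_dof_a * n + params$lo_dof_b)
    cc <- C_leftover[ok] - params$lo_shift1 / n - params$lo_shift2 / sqrt(n)
    cc <- pmin(pmax(cc, -1), 1)
    out[ok] <- clamp_p(1 - pcc_null_cdf(cc, m))
  }
  out
}

# p-value for the maximum over K placements of a full-length (window m_w)
# alignment, via the transferable beta-power component of the null model.
p_max_beta <- function(C, m_w, K, params) {
  m <- pmax(4.5, params$m_eff_factor * m_w)
  clamp_p(1 - exp(params$nu * K * pcc_null_logcdf(C, m)))
}

#' Stouffer combination of the two overlap p-values
#'
#' `s = (qnorm(1 - p_local) + qnorm(1 - p_leftover)) / sqrt(2)`; in
#' single-score mode (no leftover p-value) `s = qnorm(1 - p_local)`.
#'
#' @param p_local,p_leftover p-values in (0, 1); `p_leftover` may be NA for
#'   single-score candidates.
#' @return Combined z-score(s).
#' @export
stouffer <- function(p_local, p_leftover = NA_real_) {
  if (any(p_local <= 0 | p_local >= 1, na.rm = TRUE) ||
      any(p_leftover <= 0 | p_leftover >= 1, na.rm = TRUE)) {
    stop("p-values must lie strictly in (0, 1)", call. = FALSE)
  }
  z1 <- stats::qnorm(1 - p_local)
  z2 <- stats::qnorm(1 - p_leftover)
  ifelse(is.na(p_leftover), z1, (z1 + z2) / sqrt(2))
}

#' Filter overlap candidates by dual p-value significance
#'
#' Annotates every candidate with p_local, p_leftover and the Stouffer
#' score, then keeps those with `p_local < p_local_thresh` and (in
#' single-score mode, nothing more; otherwise) `p_leftover <
#' p_leftover_thresh`. Kept candidates are sorted by Stouffer score
#' descending; the removed candidates' annotated rows are retained on the
#' `"removed"` attribute for diagnostics (score histograms of discarded
#' overlaps).
#'
#' @param cands Candidate data.frame from [all_pairs_overlaps()].
#' @param set The `barcode_set` the candidates were computed from (needed
#'   for per-pair placement counts).
#' @param params A `null_model_params`.
#' @param p_local_thresh,p_leftover_thresh Significance thresholds
#'   (defaults 0.05 / 0.05).
#' @return Data.frame of significant overlaps with added columns p_local,
#'   p_leftover, s_stouffer; attribute `removed` holds the discarded rows.
#' @export
filter_significant <- function(cands, set, params, p_local_thresh = 0.05,
                               p_leftover_thresh = 0.05) {
  if (nrow(cands) == 0L) {
    out <- cands
    attr(out, "removed") <- cands
    return(out)
  }
  p <- params$overlap_params
  nref <- vapply(cands$ref_id, function(id) n_px(set[[id]]), integer(1))
  nqry <- vapply(cands$query_id, function(id) n_px(set[[id]]), integer(1))
  K <- mapply(placement_count, nref, nqry, MoreArgs = list(p = p))
  cands$p_local <- p_local(cands$C, params, K)
  cands$p_leftover <- p_leftover(cands$C_leftover, cands$n_leftover, params,
                                 min_leftover = p$min_leftover)
  cands$s_stouffer <- stouffer(cands$p_local, cands$p_leftover)
  keep <- cands$p_local < p_local_thresh &
    (cands$single_score | (!is.na(cands$p_leftover) &
                             cands$p_leftover < p_leftover_thresh))
  out <- cands[keep, , drop = FALSE]
  out <- out[order(-out$s_stouffer, out$query_id, out$ref_id), , drop = FALSE]
  rownames(out) <- NULL
  removed <- cands[!keep, , drop = FALSE]
  rownames(removed) <- NULL
  attr(out, "removed") <- removed
  out
}
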
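## Multi-state competition model: calcium-state distribution of S100A1 and
## competitive binding of the titin PEVK segment by actin versus the three
## S100A1 calcium states.  Free calcium is clamped (buffered) at a given
## pCa; all concentrations are site concentrations in micromolar.

#' Calcium-binding parameters of the two EF hands
#'
#' Sequential two-site scheme: calcium binds the high-affinity canonical
#' hand (cEF) first, then the low-affinity pseudo hand (pEF).  Reported
#' affinities span roughly 27-50 uM (cEF) and 250-16,700 uM (pEF); the
#' defaults take the tight end of each range.
#'
#' @param kd_cef cEF dissociation constant, uM.
#' @param kd_pef pEF dissociation constant, uM (may be `Inf` to disable the
#'   second site).
#' @return object of class `ca_binding_params`.
#' @export
ca_binding_params <- function(kd_cef = 27, kd_pef = 250) {
  if (kd_cef <= 0 || kd_pef <= 0) stop("calcium Kd values must be positive")
  structure(list(kd_cef = kd_cef, kd_pef = kd_pef), class = "ca_binding_params")
}

#' PEVK affinities of the three S100A1 calcium states
#'
#' Dissociation constants for PEVK binding by apo (`kd1`), half-saturated
#' (`kd2`) and fully-saturated (`kd2p`) S100A1, in uM.  `binding_enabled`
#' distinguishes the two model variants: variant 2 (default) lets all three
#' states bind; variant 1 disables the half-saturated state.
#'
#' @param kd1,kd2,kd2p dissociation constants, uM.  Defaults are the
#'   fitted values 0.52, 0.13 and 0.03 uM.
#' @param binding_enabled logical length 3 (apo, half, full).
#' @return object of class `peptide_affinities`.
#' @export
peptide_affinities <- function(kd1 = 0.52, kd2 = 0.13, kd2p = 0.03,
                               binding_enabled = c(TRUE, TRUE, TRUE)) {
  if (any(c(kd1, kd2, kd2p) <= 0)) stop("peptide Kd values must be positive")
  structure(list(kd1 = kd1, kd2 = kd2, kd2p = kd2p,
                 binding_enabled = as.logical(binding_enabled)),
            class = "peptide_affinities")
}

#' Model variant 1: half-saturated S100A1 does not bind PEVK
#' @param kd1,kd2p dissociation constants, uM.
#' @return `peptide_affinities` with the half-saturated state disabled.
#' @export
peptide_affinities_variant1 <- function(kd1 = 0.52, kd2p = 0.03) {
  peptide_affinities(kd1 = kd1, kd2p = kd2p,
                     binding_enabled = c(TRUE, FALSE, TRUE))
}

#' Total concentrations of the competing species
#'
#' @param s_total total S100A1 (site concentration), uM.
#' @param a_total total actin, uM.
#' @param p_total total PEVK, uM.
#' @param pca clamped free calcium as pCa = -log10(\[Ca\]/M).
#' @return object of class `system_totals`.
#' @export
system_totals <- function(s_total, a_total, p_total, pca = 7) {
  if (any(c(s_total, a_total, p_total) < 0)) stop("totals must be >= 0")
  if (!is.finite(pca)) stop("pCa must be finite")
  structure(list(s_total = s_total, a_total = a_total, p_total = p_total,
                 pca = pca), class = "system_totals")
}

#' Free calcium concentration (uM) from pCa
#' @param pca pCa value.
#' @export
ca_from_pca <- function(pca) 10^(6 - pca)

#' Calcium-state fractions of S100A1
#'
#' Sequential two-site equilibrium at clamped free calcium: the apo,
#' half-saturated (cEF only) and fully-saturated (cEF + pEF) states carry
#' relative weights 1, \[Ca\]/Kd_cEF and \[Ca\]^2/(Kd_cEF Kd_pEF), normalised
#' to sum to one.
#'
#' @param ca_uM free calcium, uM (>= 0).
#' @param ca_params [ca_binding_params()].
#' @return named numeric vector `c(apo=, half=, full=)`.
#' @export
ca_state_fractions <- function(ca_uM, ca_params = ca_binding_params()) {
  if (ca_uM < 0) stop("calcium concentration must be >= 0")
  w <- c(apo = 1,
         half = ca_uM / ca_params$kd_cef,
         full = if (is.finite(ca_params$kd_pef))
           ca_uM^2 / (ca_params$kd_cef * ca_params$kd_pef) else 0)
  w / sum(w)
}

## Effective PEVK-binding strength of the free-S100A1 pool at clamped Ca:
## sum over enabled states of f_state / Kd_state (1/uM).
effective_inv_kd <- function(fractions, affinities) {
  kds <- c(affinities$kd1, affinities$kd2, affinities$kd2p)
  sum(ifelse(affinities$binding_enabled, fractions / kds, 0))
}

#' Solve the competitive binding equilibrium
#'
#' Mass-action scheme at clamped free calcium: actin and PEVK associate
#' with dissociation constant `k_ap`, while each calcium state of free
#' S100A1 competes for PEVK with its own dissociation constant (Kd1, Kd2,
#' Kd2').  Because calcium is buffered, the free S100A1 pool keeps fixed
#' state fractions and the system reduces to a single monotone conservation
#' equation in free PEVK, solved to near machine precision; conservation
#' and every reported equilibrium hold to better than 1e-9 relative.
#'
#' @param totals [system_totals()].
#' @param ca_params [ca_binding_params()].
#' @param affinities [peptide_affinities()].
#' @param k_ap actin-PEVK dissociation constant, uM.
#' @return object of class `equilibrium_state`: free-species and complex
#'   concentrations (uM: `s_apo`, `s_half`, `s_full`, `a`, `p`, `ap`,
#'   `sp_apo`, `sp_half`, `sp_full`), the observable `f_ap` = \[AP\]/P_total,
#'   and `f_ap_norm` = f_ap relative to the S100A1-free baseline.
#' @export
solve_equilibrium <- function(totals, ca_params = ca_binding_params(),
                              affinities = peptide_affinities(), k_ap = 0.5) {
  if (k_ap <= 0) stop("k_ap must be positive")
  frac <- ca_state_fractions(ca_from_pca(totals$pca), ca_params)
  kap_inv <- effective_inv_kd(frac, affinities)
  st <- totals$s_total; at <- totals$a_total; pt <- totals$p_total

  solve_pf <- function(s_tot) {
    if (pt == 0) return(0)
    g <- function(pf) pf + at * pf / (k_ap + pf) +
      s_tot * kap_inv * pf / (1 + kap_inv * pf) - pt
    if (g(pt) <= 0) return(pt)
    pf <- uniroot(g, c(0, pt), tol = .Machine$double.eps^0.75)$root
    ## Newton polish to drive the conservation residual below 1e-12 relative
    for (i in 1:5) {
      gp <- 1 + at * k_ap / (k_ap + pf)^2 +
        s_tot * kap_inv / (1 + kap_inv * pf)^2
      step <- g(pf) / gp
      pf <- min(max(pf - step, 0), pt)
      if (abs(step) < 1e-15 * max(pf, 1e-12)) break
    }
    pf
  }

  pf <- solve_pf(st)
  af <- at / (1 + pf / k_ap)
  ap <- af * pf / k_ap
  sf <- st / (1 + kap_inv * pf)
  s_free <- sf * frac
  kds <- c(affinities$kd1, affinities$kd2, affinities$kd2p)
  sp <- ifelse(affinities$binding_enabled, s_free * pf / kds, 0)
  f_ap <- if (pt > 0) ap / pt else 0

  pf0 <- solve_pf(0)
  ap0 <- (at / (1 + pf0 / k_ap)) * pf0 / k_ap
  f_ap0 <- if (pt > 0) ap0 / pt else 0

  state <- list(s_apo = s_free[["apo"]], s_half = s_free[["half"]],
                s_full = s_free[["full"]],
                a = af, p = pf, ap = ap,
                sp_apo = sp[[1]], sp_half = sp[[2]], sp_full = sp[[3]],
                f_ap = f_ap,
                f_ap_norm = if (f_ap0 > 0) f_ap / f_ap0 else NA_real_,
                ca_fractions = frac, totals = totals, k_ap = k_ap)
  ## invariant check: conservation to 1e-9 relative
  p_rec <- pf + ap + sum(sp)
  s_rec <- sf + sum(sp)
  a_rec <- af + ap
  chk <- function(rec, tot) tot == 0 || abs(rec - tot) <= 1e-9 * tot
  if (!chk(p_rec, pt) || !chk(s_rec, st) || !chk(a_rec, at))
    stop(sprintf("equilibrium solver residual too large (P %,g, S %g, A %g)",
                 p_rec - pt, s_rec - st, a_rec - at))
  structure(state, class = "equilibrium_state")
}

#' Dose-response curve of actin-bound PEVK versus total S100A1
#'
#' Solves the competition equilibrium over a grid of total S100A1
#' concentrations at fixed actin/PEVK totals and clamped calcium.  The
#' fraction of PEVK bound to actin is non-increasing in S100A1 and, when
#' the calcium-loaded states bind more tightly, lies lower at elevated
#' calcium.
#'
#' @param s_grid total S100A1 concentrations, uM.
#' @param a_total,p_total actin and PEVK totals, uM.
#' @param pca clamped pCa.
#' @param ca_params [ca_binding_params()].
#' @param affinities [peptide_affinities()].
#' @param k_ap actin-PEVK dissociation constant, uM.
#' @return data.frame with columns `s100_total_uM`, `f_ap`, `f_ap_norm`,
#'   `pca`.
#' @export
dose_response <- function(s_grid, a_total, p_total, pca = 7,
                          ca_params = ca_binding_params(),
                          affinities = peptide_affinities(), k_ap = 0.5) {
  if (!length(s_grid)) stop("empty S100A1 grid")
  rows <- lapply(s_grid, function(s) {
    eq <- solve_equilibrium(system_totals(s, a_total, p_total, pca),
                            ca_params, affinities, k_ap)
    data.frame(s100_total_uM = s, f_ap = eq$f_ap, f_ap_norm = eq$f_ap_norm,
               pca = pca)
  })
  do.call(rbind, rows)
}

#' Fit S100A1-state PEVK affinities to dose-response data
#'
#' Nonlinear least squares on log10 Kd (bounds 1e-4 to 1e3 uM), fitted
#' jointly across curves measured at different pCa.  Confidence intervals
#' come from seeded residual-resampling bootstrap.  A parameter whose
#' perturbation leaves the residual sum of squares essentially unchanged
#' (for instance Kd2' when the fully-saturated state is never populated) is
#' flagged unidentifiable.
#'
#' @param data data.frame with columns `s100_total_uM`, `f_ap`, `pca`.
#' @param a_total,p_total fixed totals, uM.
#' @param ca_params [ca_binding_params()].
#' @param k_ap actin-PEVK dissociation constant, uM.
#' @param variant 2 (default, all states bind) or 1 (half-saturated state
#'   does not bind; only Kd1 and Kd2' are fitted).
#' @param n_boot bootstrap replicates for confidence intervals (default
#'   200; 0 skips them).
#' @param seed RNG seed for the bootstrap.
#' @param start starting Kd values, uM (length 3).
#' @return object of class `fit_result`: `affinities`
#'   ([peptide_affinities()]), `rss`, `fitted` (data.frame), `ci`
#'   (2.5/97.5 percent bootstrap limits per fitted parameter, uM) and
#'   `unidentifiable` (character vector of flagged parameters).
#' @export
fit_affinities <- function(data, a_total, p_total,
                           ca_params = ca_binding_params(), k_ap = 0.5,
                           variant = 2, n_boot = 200, seed = NULL,
                           start = c(1, 1, 1)) {
  if (!all(c("s100_total_uM", "f_ap", "pca") %in% names(data)))
    stop("data needs columns s100_total_uM, f_ap, pca")
  if (any(data$s100_total_uM < 0)) stop("concentrations must be >= 0")
  enabled <- if (variant == 1) c(TRUE, FALSE, TRUE) else c(TRUE, TRUE, TRUE)
  par_names <- c("kd1", "kd2", "kd2p")[enabled]

  make_aff <- function(log10_kd) {
    kd <- setNames(rep(1, 3), c("kd1", "kd2", "kd2p"))
    kd[par_names] <- 10^log10_kd
    peptide_affinities(kd[["kd1"]], kd[["kd2"]], kd[["kd2p"]],
                       binding_enabled = enabled)
  }
  predict_fap <- function(aff, d) {
    vapply(seq_len(nrow(d)), function(i) {
      solve_equilibrium(system_totals(d$s100_total_uM[i], a_total, p_total,
                                      d$pca[i]),
                        ca_params, aff, k_ap)$f_ap
    }, numeric(1))
  }
  rss_fun <- function(log10_kd, y) sum((y - predict_fap(make_aff(log10_kd), data))^2)

  run_fit <- function(y) {
    optim(log10(start[enabled]), rss_fun, y = y, method = "L-BFGS-B",
          lower = rep(-4, sum(enabled)), upper = rep(3, sum(enabled)),
          control = list(factr = 1e4, maxit = 500))
  }
  fit <- run_fit(data$f_ap)
  aff <- make_aff(fit$par)
  pred <- predict_fap(aff, data)
  rss <- fit$value

  ## identifiability: shifting a parameter by +/- 0.3 decades must move RSS
  scale_ref <- max(rss, 1e-8 * nrow(data))
  unid <- character(0)
  for (k in seq_along(par_names)) {
    moves <- vapply(c(-0.3, 0.3), function(dlt) {
      p <- fit$par; p[k] <- p[k] + dlt
      rss_fun(p, data$f_ap) - rss
    }, numeric(1))
    if (max(moves) < 1e-3 * scale_ref) unid <- c(unid, par_names[k])
  }

  ci <- NULL
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    resid <- data$f_ap - pred
    boot <- vapply(seq_len(n_boot), function(b) {
      y <- pmin(pmax(pred + sample(resid, length(resid), replace = TRUE), 0), 1)
      run_fit(y)$par
    }, numeric(length(par_names)))
    boot <- matrix(boot, nrow = length(par_names))
    ci <- t(apply(10^boot, 1, stats::quantile, probs = c(0.025, 0.975)))
    rownames(ci) <- par_names
  }

  structure(list(affinities = aff, rss = rss,
                 fitted = cbind(data, f_ap_fit = pred),
                 ci = ci, unidentifiable = unid, variant = variant,
                 k_ap = k_ap),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  a <- x$affinities
  cat(sprintf("fit_result (variant %d): Kd1 = %.4g, Kd2 = %.4g, Kd2' = %.4g uM; RSS = %.3g\n",
              x$variant, a$kd1, a$kd2, a$kd2p, x$rss))
  if (length(x$unidentifiable))
    cat("  unidentifiable:", paste(x$unidentifiable, collapse = ", "), "\n")
  invisible(x)
}

#' Predicted dose-response curves for wild-type versus modified S100A1
#'
#' Applies a [ptm_scale_factor()] to the calcium-activated affinities (Kd2
#' and Kd2') and solves the wild-type and modified dose-response curves at
#' each requested pCa.
#'
#' @param affinities wild-type [peptide_affinities()] (or a `fit_result`).
#' @param scale_factor multiplicative factor on Kd2 and Kd2' (e.g. from
#'   [ptm_scale_factor()]; default uses the standard calibration).
#' @param pca_list pCa values to evaluate.
#' @param s_grid total S100A1 grid, uM.
#' @param a_total,p_total fixed totals, uM.
#' @param ca_params [ca_binding_params()].
#' @param k_ap actin-PEVK dissociation constant, uM.
#' @return data.frame with columns `pca`, `s100_total_uM`, `f_ap_wt`,
#'   `f_ap_mod`; attribute `scale_factor` records the factor used.
#' @export
predict_ptm_curves <- function(affinities = peptide_affinities(),
                               scale_factor = ptm_scale_factor(),
                               pca_list = c(7, 4.5),
                               s_grid = 10^seq(-2, 1.5, length.out = 15),
                               a_total = 1, p_total = 0.2,
                               ca_params = ca_binding_params(), k_ap = 0.5) {
  if (inherits(affinities, "fit_result")) affinities <- affinities$affinities
  mod <- affinities
  mod$kd2 <- mod$kd2 * scale_factor
  mod$kd2p <- mod$kd2p * scale_factor
  rows <- lapply(pca_list, function(pca) {
    wt <- dose_response(s_grid, a_total, p_total, pca, ca_params, affinities, k_ap)
    pm <- dose_response(s_grid, a_total, p_total, pca, ca_params, mod, k_ap)
    data.frame(pca = pca, s100_total_uM = s_grid,
               f_ap_wt = wt$f_ap, f_ap_mod = pm$f_ap)
  })
  out <- do.call(rbind, rows)
  attr(out, "scale_factor") <- scale_factor
  out
}
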
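#' Willmott agreement index
#'
#' d = 1 - sum((E - M)^2) / sum((|E - Mbar| + |M - Mbar|)^2), where Mbar is
#' the mean of the measurements. Ranges from 0 (complete disagreement) to 1
#' (complete agreement). Note d is scale-dependent: it is invariant under a
#' common translation of both series but not under general affine
#' relabelling.
#'
#' @param estimates Numeric vector of model estimates E.
#' @param measurements Numeric vector of measurements M, same length (>= 2).
#' @return Agreement index in [0, 1].
#' @export
agreement_index <- function(estimates, measurements) {
  if (length(estimates) != length(measurements)) {
    stop("estimates and measurements must have equal length", call. = FALSE)
  }
  if (length(estimates) < 2) stop("need at least 2 values", call. = FALSE)
  if (any(!is.finite(estimates)) || any(!is.finite(measurements))) {
    stop("inputs must be finite", call. = FALSE)
  }
  m_bar <- mean(measurements)
  denom <- sum((abs(estimates - m_bar) + abs(measurements - m_bar))^2)
  if (denom == 0) {
    stop("degenerate input: all measurements and estimates equal their mean",
      call. = FALSE
    )
  }
  d <- 1 - sum((estimates - measurements)^2) / denom
  min(1, max(0, d)) # clamp pure floating-point noise at the bounds
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Shuffled-complex-evolution (SCE-UA) maximization
#'
#' Standard shuffled complex evolution global optimizer over a box, run as a
#' maximizer. The population is partitioned into complexes which evolve
#' independently by competitive simplex steps (reflection, contraction,
#' random replacement) and are periodically shuffled. Deterministic for a
#' fixed seed.
#'
#' @param objective Function of a numeric parameter vector returning a
#'   scalar; non-finite returns are treated as -Inf.
#' @param lower,upper Numeric vectors of box bounds (finite, equal length).
#' @param seed Integer seed; the optimizer uses its own RNG state and
#'   restores the caller's.
#' @param control List overriding defaults: `n_complexes` (default 2),
#'   `pts_per_complex` (default 2n+1), `max_evals` (default 10000), `pcento`
#'   (relative objective-improvement tolerance, default 1e-6), `kstop`
#'   (shuffling loops over which improvement is measured, default 5).
#' @return List: `par`, `value`, `n_eval`, `converged`, and `trace` (data
#'   frame of best objective per shuffling loop).
#' @export
sce_ua_maximize <- function(objective, lower, upper, seed = 1, control = list()) {
  n <- length(lower)
  stopifnot(length(upper) == n, all(is.finite(lower)), all(is.finite(upper)),
    all(lower < upper))
  ctl <- list(
    n_complexes = 2, pts_per_complex = 2 * n + 1,
    max_evals = 10000, pcento = 1e-6, kstop = 5
  )
  ctl[names(control)] <- control
  p <- ctl$n_complexes
  m <- ctl$pts_per_complex
  q <- n + 1 # sub-complex size
  beta <- 2 * n + 1 # evolution steps per complex per shuffle
  npop <- p * m

  f_wrap <- function(x) {
    v <- objective(x)
    if (!is.finite(v)) -Inf else v
  }

  .with_seed(seed, {
    pop <- matrix(stats::runif(npop * n, rep(lower, each = npop),
      rep(upper, each = npop)
    ), npop, n)
    fv <- apply(pop, 1, f_wrap)
    n_eval <- npop
    if (mean(!is.finite(fv)) > 0.5) {
      stop("optimization failure: objective non-finite on >50% of initial population",
        call. = FALSE
      )
    }
    ord <- order(fv, decreasing = TRUE)
    pop <- pop[ord, , drop = FALSE]
    fv <- fv[ord]
    trace <- numeric(0)
    best_hist <- fv[1]
    converged <- FALSE

    repeat {
      for (k in seq_len(p)) {
        idx <- seq(k, npop, by = p)
        cx <- pop[idx, , drop = FALSE]
        cf <- fv[idx]
        for (step in seq_len(beta)) {
          # triangular selection probabilities favour better points
          probs <- 2 * (m + 1 - seq_len(m)) / (m * (m + 1))
          sel <- sample(m, q, prob = probs)
          sel <- sel[order(cf[sel], decreasing = TRUE)]
          worst <- sel[q]
          centroid <- colMeans(cx[sel[-q], , drop = FALSE])
          cand <- 2 * centroid - cx[worst, ]
          in_box <- all(cand >= lower & cand <= upper)
          fc <- if (in_box) f_wrap(cand) else -Inf
          if (in_box) n_eval <- n_eval + 1
          if (fc <= cf[worst]) {
            cand <- (centroid + cx[worst, ]) / 2
            fc <- f_wrap(cand)
            n_eval <- n_eval + 1
            if (fc <= cf[worst]) {
              cand <- lower + stats::runif(n) * (upper - lower)
              fc <- f_wrap(cand)
              n_eval <- n_eval + 1
            }
          }
          cx[worst, ] <- cand
          cf[worst] <- fc
          o <- order(cf, decreasing = TRUE)
          cx <- cx[o, , drop = FALSE]
          cf <- cf[o]
        }
        pop[idx, ] <- cx
        fv[idx] <- cf
      }
      ord <- order(fv, decreasing = TRUE)
      pop <- pop[ord, , drop = FALSE]
      fv <- fv[ord]
      trace <- c(trace, fv[1])
      best_hist <- c(best_hist, fv[1])
      if (length(best_hist) > ctl$kstop + 1) {
        span <- utils::tail(best_hist, ctl$kstop + 1)
        improve <- abs(span[length(span)] - span[1]) /
          max(abs(span[1]), .Machine$double.eps)
        if (improve < ctl$pcento) {
          converged <- TRUE
          break
        }
      }
      if (n_eval >= ctl$max_evals) break
    }
    list(
      par = pop[1, ], value = fv[1], n_eval = n_eval, converged = converged,
      trace = data.frame(shuffle = seq_along(trace), best = trace)
    )
  })
}

#' Calibrate maximum light-use efficiencies for one vegetation type
#'
#' Splits the sites of one vegetation type into calibration and validation
#' subsets (split by site, seeded), then finds the pair of maximum light-use
#' efficiencies (shaded, sunlit; g C MJ^-1) that maximizes the Willmott
#' agreement index between modelled and observed daily GPP pooled over all
#' calibration days. Because GPP is linear in the two efficiencies, the model
#' response is precomputed once per day as a pair of basis series (shaded and
#' sunlit APAR times the scalar product), making the objective cheap.
#' Validation reports the agreement index on pooled held-out days and the
#' mean per-site daily R^2.
#'
#' @param records Screened, gap-filled flux records (from
#'   [screen_site_years()] or [make_site()]): columns `site`, `date`,
#'   forcing fields and `gpp_obs`.
#' @param pft Vegetation-type code; its fixed parameters (T_opt, VPD bounds,
#'   albedo, clumping) come from `params_table`.
#' @param bounds Lower/upper bounds for both efficiencies, g C MJ^-1
#'   (default c(0.01, 10), covering the calibrated range 0.65--4.80).
#' @param split_fraction Fraction of sites used for calibration (default
#'   0.75).
#' @param seed Integer seed controlling the site split and the optimizer.
#' @param params_table Parameter table (default shipped table).
#' @param control Passed to [sce_ua_maximize()].
#' @return List of class `tllue_calibration`: `eps_msh_hat`, `eps_msu_hat`,
#'   `d_calibration`, `d_validation`, `r2_validation`, `n_site_years`,
#'   `sites_calibration`, `sites_validation`, `trace`.
#' @export
calibrate_pft <- function(records, pft, bounds = c(0.01, 10),
                          split_fraction = 0.75, seed = 1,
                          params_table = pft_parameters(), control = list()) {
  params <- pft_parameters(pft)
  stopifnot(bounds[1] < bounds[2])
  sites <- sort(unique(records$site))
  if (length(sites) < 2) {
    warning("fewer than 2 sites: degenerating to leave-none-out (no validation)")
    cal_sites <- sites
    val_sites <- character(0)
  } else {
    n_cal <- max(1, round(split_fraction * length(sites)))
    n_cal <- min(n_cal, length(sites) - 1)
    cal_sites <- .with_seed(seed, sort(sample(sites, n_cal)))
    val_sites <- setdiff(sites, cal_sites)
  }

  basis <- function(df) {
    out <- run_series(df, params)
    lim <- out$t_s * out$w_s * out$c_s
    data.frame(
      site = df$site,
      a_shade = out$apar_shade_MJ * lim,
      a_sun = out$apar_sun_MJ * lim,
      gpp_obs = df$gpp_obs
    )
  }
  cal_df <- records[records$site %in% cal_sites, , drop = FALSE]
  cal_df <- cal_df[order(cal_df$site, as.Date(cal_df$date)), , drop = FALSE]
  cal <- do.call(rbind, lapply(split(cal_df, cal_df$site), basis))
  cal <- cal[is.finite(cal$gpp_obs) & is.finite(cal$a_shade), , drop = FALSE]
  if (nrow(cal) < 2) stop("not enough calibration days", call. = FALSE)

  obj <- function(p) {
    agreement_index(p[1] * cal$a_shade + p[2] * cal$a_sun, cal$gpp_obs)
  }
  opt <- sce_ua_maximize(obj, rep(bounds[1], 2), rep(bounds[2], 2),
    seed = seed, control = control
  )

  d_val <- NA_real_
  r2_val <- NA_real_
  if (length(val_sites)) {
    val_df <- records[records$site %in% val_sites, , drop = FALSE]
    val_df <- val_df[order(val_df$site, as.Date(val_df$date)), , drop = FALSE]
    val <- do.call(rbind, lapply(split(val_df, val_df$site), basis))
    val <- val[is.finite(val$gpp_obs) & is.finite(val$a_shade), , drop = FALSE]
    if (nrow(val) >= 2) {
      est <- opt$par[1] * val$a_shade + opt$par[2] * val$a_sun
      d_val <- agreement_index(est, val$gpp_obs)
      r2_site <- vapply(split(seq_len(nrow(val)), val$site), function(i) {
        if (length(i) < 3 || stats::sd(val$gpp_obs[i]) == 0) {
          return(NA_real_)
        }
        stats::cor(est[i], val$gpp_obs[i])^2
      }, numeric(1))
      r2_val <- mean(r2_site, na.rm = TRUE)
    }
  }

  yrs <- unique(paste(records$site, format(as.Date(records$date), "%Y")))
  structure(list(
    pft = pft,
    eps_msh_hat = opt$par[1],
    eps_msu_hat = opt$par[2],
    d_calibration = opt$value,
    d_validation = d_val,
    r2_validation = r2_val,
    n_site_years = length(yrs),
    sites_calibration = cal_sites,
    sites_validation = val_sites,
    n_eval = opt$n_eval,
    converged = opt$converged,
    trace = opt$trace
  ), class = "tllue_calibration")
}

#' @export
print.tllue_calibration <- function(x, ...) {
  cat("Two-leaf LUE calibration:", x$pft, "\n")
  cat(sprintf(
    "  eps_msh = %.4f  eps_msu = %.4f  (g C MJ^-1)\n",
    x$eps_msh_hat, x$eps_msu_hat
  ))
  cat(sprintf(
    "  d (calibration) = %.4f   d (validation) = %.4f   R2 (validation) = %.4f\n",
    x$d_calibration, x$d_validation, x$r2_validation
  ))
  cat(sprintf(
    "  %d site-years; %d calibration / %d validation sites; %d evaluations\n",
    x$n_site_years, length(x$sites_calibration),
    length(x$sites_validation), x$n_eval
  ))
  invisible(x)
}
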
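#' @include AllClasses.R AllGenerics.R constants.R
NULL

#' Tensile stress from an applied force over the clamped aperture
#'
#' Thin-shell hoop stress of the cornea loaded over a circular aperture:
#' \deqn{\sigma = \frac{F}{2\pi R \, cct}.}
#'
#' @param F force, N (vectorised).
#' @param g a \linkS4class{LoadingGeometry} (aperture \code{radius} mm,
#'   \code{cct} um).
#' @return stress in Pa.
#' @examples
#' stressFromForce(0.4, LoadingGeometry(cct = 148, radius = 0.8)) / 1000 # kPa
#' @export
stressFromForce <- function(F, g) {
  stopifnot(is(g, "LoadingGeometry"))
  if (g@cct <= 0) stop("geometry with non-positive cct")
  F / (2 * pi * (g@radius * 1e-3) * (g@cct * 1e-6))
}

#' Tensile strain from the axial indenter travel
#'
#' The cornea clamped over an aperture of radius \eqn{R} and pushed axially
#' by \eqn{\Delta l} deforms into a spherical cap of radius
#' \eqn{r = (\Delta l^2 + R^2)/(2\Delta l)}. The default \code{"arcsin"}
#' form reports the arc-length-over-chord stretch of that cap,
#' \deqn{\epsilon = \frac{r}{R}\arcsin\!\frac{R}{r} - 1,}
#' which is zero at zero travel, non-negative, and strictly increasing up
#' to \eqn{\Delta l = R} (where it reaches \eqn{\pi/2 - 1}). Its small
#' travel expansion is \eqn{\epsilon \approx \tfrac{2}{3}(\Delta l/R)^2}.
#' The \code{"printed"} form replaces arcsin by sin; it is retained only
#' for comparison, as it goes negative for small travel and is not a
#' physical stretch.
#'
#' @param dl axial travel, um (vectorised, non-negative).
#' @param R aperture radius, mm.
#' @param form \code{"arcsin"} (default) or \code{"printed"}.
#' @return dimensionless tensile strain.
#' @examples
#' strainFromTravel(80, R = 0.8)          # ~ (2/3) * (0.1)^2
#' @export
strainFromTravel <- function(dl, R = .DEFAULT_APERTURE_RADIUS,
                             form = c("arcsin", "printed")) {
  form <- match.arg(form)
  if (any(dl < 0, na.rm = TRUE)) stop("negative travel")
  stopifnot(R > 0)
  dlMm <- dl / 1000
  out <- numeric(length(dlMm))
  nz <- which(dlMm > 0)
  d <- dlMm[nz]
  ratio <- 2 * d * R / (d^2 + R^2)       # = R/r, in (0, 1]
  out[nz] <- if (form == "arcsin") asin(pmin(1, ratio)) / ratio - 1
             else sin(ratio) / ratio - 1
  out
}

#' Indenter travel producing a given tensile strain
#'
#' Numerical inverse of [strainFromTravel()] (arcsin form) on the
#' monotone branch \eqn{0 \le \Delta l \le R}.
#'
#' @param eps strain, in \eqn{[0, \pi/2 - 1)} (vectorised).
#' @param R aperture radius, mm.
#' @return travel in mm.
#' @export
travelFromStrain <- function(eps, R = .DEFAULT_APERTURE_RADIUS) {
  stopifnot(R > 0)
  if (any(eps < 0)) stop("strain must be non-negative")
  if (any(eps >= pi / 2 - 1)) stop("strain beyond the invertible range (pi/2 - 1)")
  vapply(as.numeric(eps), function(e) {
    if (e == 0) return(0)
    stats::uniroot(function(d) strainFromTravel(d * 1000, R) - e,
                   interval = c(1e-12, R), tol = 1e-12)$root
  }, numeric(1))
}

#' Stress-strain curve of a force trace
#'
#' Converts a trace's force and travel samples to tensile stress and strain
#' using the trace geometry.
#'
#' @param trace a \linkS4class{ForceTrace}.
#' @param form strain form passed to [strainFromTravel()].
#' @return data.frame with columns \code{t}, \code{eps}, \code{sigma} (Pa).
#' @export
stressStrainCurve <- function(trace, form = c("arcsin", "printed")) {
  stopifnot(is(trace, "ForceTrace"))
  g <- traceGeometry(trace)
  data.frame(t = traceTime(trace),
             eps = strainFromTravel(traceTravel(trace), g@radius,
                                    form = match.arg(form)),
             sigma = stressFromForce(traceForce(trace), g))
}

#' Segment a three-phase extensometry protocol
#'
#' Assigns each sample of an unlabelled trace to \code{"precondition"},
#' \code{"relaxation"} or \code{"ramp"}. The relaxation plateau is found
#' as the longest run of constant indenter travel (the displacement is
#' held during stress relaxation, so the force decays while the travel is
#' flat) lasting at least \code{minPlateau} seconds; everything before it
#' is pre-conditioning and everything after it is the rupture ramp. If no
#' plateau is found the whole trace is labelled \code{"ramp"} when the
#' force is predominantly rising, otherwise \code{"precondition"};
#' relaxation analyses on such traces fail with an explicit error.
#'
#' @param tr a \linkS4class{ForceTrace}.
#' @param minPlateau minimum plateau duration to accept, s.
#' @param tol travel constancy tolerance, um.
#' @return the trace with segment labels assigned (existing non-empty
#'   labels are preserved).
#' @export
splitProtocol <- function(tr, minPlateau = 5, tol = 0.01) {
  stopifnot(is(tr, "ForceTrace"))
  if (length(tr@t) == 0L) stop("empty trace")
  if (all(nzchar(tr@segment))) return(tr)
  travel <- tr@travel
  n <- length(travel)
  flat <- c(FALSE, abs(diff(travel)) <= tol)
  ## runs of flat travel
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- NULL
  for (i in which(r$values)) {
    s <- max(1L, starts[i] - 1L)   # include the sample opening the run
    e <- ends[i]
    if (tr@t[e] - tr@t[s] >= minPlateau &&
        (is.null(best) || (e - s) > (best[2] - best[1])))
      best <- c(s, e)
  }
  seg <- rep("", n)
  if (is.null(best)) {
    rising <- stats::cor(tr@t, tr@force) > 0.8
    seg[] <- if (isTRUE(rising)) "ramp" else "precondition"
  } else {
    seg[best[1]:best[2]] <- "relaxation"
    if (best[1] > 1L) seg[1:(best[1] - 1L)] <- "precondition"
    if (best[2] < n) seg[(best[2] + 1L):n] <- "ramp"
  }
  initialize(tr, segment = seg)
}

#' Percent stress reduction over a relaxation horizon
#'
#' \deqn{100 \cdot \frac{\sigma(t_0) - \sigma(t_0 + h)}{\sigma(t_0)}}
#' where \eqn{t_0} is the first post-load sample of the relaxation segment
#' and \eqn{h} the horizon (default 100 s). The stress at the horizon is
#' linearly interpolated between samples.
#'
#' @param sigma stress samples, Pa.
#' @param t times, s (same length, increasing).
#' @param horizon relaxation horizon, s.
#' @return percent reduction (0-100 for a relaxing trace).
#' @examples
#' t <- seq(0, 120, 0.1)
#' relaxationReduction(exp(-t / 50), t)   # 100 * (1 - exp(-2))
#' @export
relaxationReduction <- function(sigma, t, horizon = 100) {
  stopifnot(length(sigma) == length(t), horizon > 0)
  t0 <- t[1]
  if (max(t) - t0 < horizon)
    stop(sprintf("trace spans %.1f s, shorter than the %.1f s horizon",
                 max(t) - t0, horizon))
  s0 <- sigma[1]
  sh <- stats::approx(t, sigma, xout = t0 + horizon)$y
  100 * (s0 - sh) / s0
}

## variable projection residual: given taus, the moduli enter linearly and
## are solved by non-negative least squares
.pronyDesign <- function(t, tau) cbind(1, exp(-outer(t, tau, "/")))

.pronyVarpro <- function(logTau, sigma, t, eps0) {
  tau <- exp(logTau)
  X <- .pronyDesign(t, tau) * eps0
  cf <- tryCatch(pracma::lsqnonneg(X, sigma)$x, error = function(e) NULL)
  if (is.null(cf)) {
    ## lsqnonneg can stall on collinear designs (near-equal taus, constant
    ## traces); fall back to one active-set pass on the LS solution
    cf <- tryCatch(stats::coef(stats::lm.fit(X, sigma)), error = function(e) NULL)
    if (!is.null(cf)) {
      cf[is.na(cf)] <- 0
      if (any(cf < 0)) {
        keep <- cf > 0
        cf <- numeric(ncol(X))
        if (any(keep)) {
          ck <- stats::coef(stats::lm.fit(X[, keep, drop = FALSE], sigma))
          ck[is.na(ck) | ck < 0] <- 0
          cf[keep] <- ck
        }
      }
    }
  }
  if (is.null(cf) || any(!is.finite(cf)))
    return(list(rss = Inf, cf = NULL, tau = tau))
  r <- sigma - as.vector(X %*% cf)
  list(rss = sum(r^2), cf = cf, tau = tau)
}

#' Fit a Prony-series relaxation model to a stress trace
#'
#' Fits \eqn{\sigma(t) = \epsilon_0 (E_\infty + \sum_i E_i e^{-t/\tau_i})}
#' by constrained least squares with all parameters positive.
#' Exponential-sum fitting is ill-conditioned, so the fit uses variable
#' projection - for fixed time constants the moduli are solved by
#' non-negative least squares, and Nelder-Mead searches over log time
#' constants from multi-start initialisations spanning log-spaced decades -
#' followed by a bounded Levenberg-Marquardt polish of all parameters.
#' Terms are returned sorted by ascending time constant.
#'
#' @param sigma stress samples, Pa.
#' @param t times, s (relaxation clock; re-zeroed internally to t[1]).
#' @param eps0 applied strain held during relaxation (> 0).
#' @param nTerms number of Prony terms (default 3).
#' @param horizon horizon for the reported reduction, s; the reduction in
#'   the result is the closed-form reduction of the fitted model.
#' @return a \linkS4class{RelaxationResult}.
#' @examples
#' wt <- mouseCorneaPronyConstants("wt")
#' tr <- simulateRelaxationTrace(wt, eps0 = 0.18)
#' fit <- fitProny(stressFromForce(traceForce(tr), traceGeometry(tr)),
#'                 traceTime(tr), eps0 = 0.18)
#' eInf(pronyFit(fit)) / 1e6    # MPa
#' @export
fitProny <- function(sigma, t, eps0, nTerms = 3L, horizon = 100) {
  stopifnot(length(sigma) == length(t), eps0 > 0, nTerms >= 1L)
  if (length(sigma) < 3L * nTerms + 1L)
    stop("too few samples for the requested number of terms")
  t <- t - t[1]
  tmax <- max(t)

  ## multi-starts: log-spaced decades scaled to the trace span
  base <- exp(seq(log(max(tmax / 120, 0.5)), log(tmax), length.out = nTerms + 1))
  starts <- list(base[seq_len(nTerms)],
                 base[seq_len(nTerms)] / 3,
                 base[seq_len(nTerms)] * 3,
                 exp(seq(log(1), log(tmax / 2), length.out = nTerms)))
  if (nTerms == 3L)
    starts <- c(starts, list(c(1, 10, 100), c(1, 50, 100), c(5, 50, 120)))

  best <- NULL
  for (s0 in starts) {
    o <- stats::optim(log(s0), function(l) .pronyVarpro(l, sigma, t, eps0)$rss,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  vp <- .pronyVarpro(best$par, sigma, t, eps0)
  if (!is.finite(vp$rss))
    stop("Prony fit failed to converge from any start")
  cf <- vp$cf; tau <- vp$tau

  ## full nonlinear polish, parameters bounded positive
  dat <- data.frame(tt = t, s = sigma)
  pn <- c("Einf", paste0("E", seq_len(nTerms)), paste0("tau", seq_len(nTerms)))
  st <- as.list(c(max(cf[1], 1e-6 * max(sigma) / eps0),
                  pmax(cf[-1], 1e-8), tau))
  names(st) <- pn
  rhs <- paste0("eps0 * (Einf + ",
                paste(sprintf("E%d * exp(-tt / tau%d)", seq_len(nTerms),
                              seq_len(nTerms)), collapse = " + "), ")")
  fit <- tryCatch(
    minpack.lm::nlsLM(stats::as.formula(paste("s ~", rhs)), data = dat,
                      start = st, lower = rep(1e-12, 2 * nTerms + 1),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)

  if (!is.null(fit) && sum(stats::residuals(fit)^2) <= vp$rss) {
    p <- stats::coef(fit)
    eInfHat <- unname(p["Einf"])
    eHat <- unname(p[paste0("E", seq_len(nTerms))])
    tauHat <- unname(p[paste0("tau", seq_len(nTerms))])
    rss <- sum(stats::residuals(fit)^2)
  } else {
    eInfHat <- cf[1]; eHat <- cf[-1]; tauHat <- tau; rss <- vp$rss
  }

  model <- PronyModel(max(eInfHat, .Machine$double.eps), e = pmax(eHat, 0),
                      tau = tauHat)
  e0 <- relaxationModulus(model, 0)
  eh <- relaxationModulus(model, horizon)
  red <- max(0, min(100, 100 * (e0 - eh) / e0))
  new("RelaxationResult", reductionPct = red, prony = model, fitRSS = rss)
}

#' Elastic modulus from the stress-strain window of a ramp
#'
#' Least-squares slope of stress versus strain restricted to the given
#' strain window (default 10-15 percent). The curve must cover the whole
#' window; a premature rupture that truncates the curve before the window
#' completes raises an error flagging the eye as ruptured.
#'
#' @param curve data.frame with columns \code{eps} and \code{sigma} (Pa),
#'   e.g. from [stressStrainCurve()].
#' @param window strain window \code{c(low, high)}, \code{low < high}.
#' @return the window slope in Pa.
#' @export
modulusFromRamp <- function(curve, window = c(0.10, 0.15)) {
  stopifnot(is.data.frame(curve), all(c("eps", "sigma") %in% names(curve)))
  if (length(window) != 2L || window[1] >= window[2])
    stop("'window' must be an increasing strain interval")
  if (max(curve$eps) < window[2])
    stop(sprintf(paste("ruptured: curve reaches strain %.3f, window",
                       "[%.2f, %.2f] not covered"),
                 max(curve$eps), window[1], window[2]))
  sel <- curve$eps >= window[1] & curve$eps <= window[2]
  if (sum(sel) < 2L)
    stop("fewer than two samples inside the strain window")
  unname(stats::coef(stats::lm(sigma ~ eps, data = curve[sel, ]))["eps"])
}

## rupture: instantaneous force drop > 50% of the running maximum
.detectRupture <- function(force) {
  if (length(force) < 2L) return(NA_integer_)
  runmax <- cummax(force)
  drop <- which(force[-1] < 0.5 * runmax[-length(force)])
  if (length(drop)) drop[1] + 1L else NA_integer_
}

#' Per-eye extensometry analysis of a protocol trace
#'
#' Splits an (optionally unlabelled) trace into protocol phases, then
#' computes the relaxation statistics (percent reduction at the horizon
#' from the data, plus the constrained Prony fit) on the relaxation
#' segment and the window modulus on the ramp segment. Rupture is detected
#' as an instantaneous force drop greater than 50 percent of the running
#' maximum within the ramp; a ruptured curve is truncated at the drop, and
#' the eye is flagged ruptured when the strain window was not completed.
#'
#' @param trace a \linkS4class{ForceTrace}.
#' @param horizon relaxation horizon, s.
#' @param window modulus strain window.
#' @param eps0 applied strain during relaxation; by default recovered from
#'   the constant travel of the relaxation plateau.
#' @return list with \code{E_ext_kPa}, \code{reduction_pct},
#'   \code{prony} (list \code{e_inf_MPa}, \code{e_i_MPa}, \code{tau_i_s}),
#'   \code{fit_rss}, \code{ruptured}, and \code{errors} (character vector
#'   of per-stage failures; analyses that could not run are \code{NA}).
#' @export
analyzeTrace <- function(trace, horizon = 100, window = c(0.10, 0.15),
                         eps0 = NULL) {
  stopifnot(is(trace, "ForceTrace"))
  tr <- splitProtocol(trace)
  g <- traceGeometry(tr)
  errors <- character()
  out <- list(E_ext_kPa = NA_real_, reduction_pct = NA_real_,
              prony = NULL, fit_rss = NA_real_, ruptured = FALSE)

  relIdx <- which(traceSegment(tr) == "relaxation")
  if (length(relIdx) >= 10L) {
    tRel <- traceTime(tr)[relIdx]
    sRel <- stressFromForce(traceForce(tr)[relIdx], g)
    if (is.null(eps0))
      eps0 <- strainFromTravel(stats::median(traceTravel(tr)[relIdx]),
                               g@radius)
    red <- tryCatch(relaxationReduction(sRel, tRel, horizon),
                    error = function(e) {
                      errors <<- c(errors, conditionMessage(e)); NA_real_
                    })
    fit <- tryCatch(fitProny(sRel, tRel, eps0 = eps0, horizon = horizon),
                    error = function(e) {
                      errors <<- c(errors, conditionMessage(e)); NULL
                    })
    out$reduction_pct <- red
    if (!is.null(fit)) {
      pm <- pronyFit(fit)
      out$prony <- list(e_inf_MPa = eInf(pm) / 1e6,
                        e_i_MPa = pronyE(pm) / 1e6,
                        tau_i_s = pronyTau(pm))
      out$fit_rss <- fit@fitRSS
    }
  } else {
    errors <- c(errors, "no relaxation plateau detected")
  }

  rampIdx <- which(traceSegment(tr) == "ramp")
  if (length(rampIdx) >= 2L) {
    f <- traceForce(tr)[rampIdx]
    rup <- .detectRupture(f)
    if (!is.na(rup)) rampIdx <- rampIdx[seq_len(rup - 1L)]
    curve <- data.frame(
      eps = strainFromTravel(traceTravel(tr)[rampIdx], g@radius),
      sigma = stressFromForce(traceForce(tr)[rampIdx], g))
    em <- tryCatch(modulusFromRamp(curve, window),
                   error = function(e) {
                     errors <<- c(errors, conditionMessage(e))
                     out$ruptured <<- TRUE
                     NA_real_
                   })
    if (!is.na(rup) && is.na(em)) out$ruptured <- TRUE
    out$E_ext_kPa <- em / 1000
  } else {
    errors <- c(errors, "no ramp segment detected")
  }
  out$errors <- errors
  out
}
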
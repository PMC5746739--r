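# Weighted least-squares flux fitting with multistart Levenberg-Marquardt,
# Monte Carlo replicate fitting and parameter-continuation confidence
# intervals.

#' Fit settings
#' @param multistart Number of optimizer starts (Latin-hypercube over the
#'   free-flux box, plus its midpoint).
#' @param ftol Optimizer tolerance.
#' @param seed RNG seed controlling the start points.
#' @param early_stop_ssr Stop the multistart once a start reaches this SSR
#'   (a practically perfect fit); NULL disables.
#' @param maxiter Per-start iteration cap.
#' @export
fit_settings <- function(multistart = 20L, ftol = 1e-9, seed = 1L,
                         early_stop_ssr = 1e-10, maxiter = 200L) {
  stopifnot(multistart >= 1)
  structure(list(multistart = as.integer(multistart), ftol = ftol,
                 seed = as.integer(seed), early_stop_ssr = early_stop_ssr,
                 maxiter = as.integer(maxiter)), class = "fit_settings")
}

#' Monte Carlo settings
#' @param replicates Number of replicate datasets (default 100).
#' @param rel,floor The noise rule sd = max(rel * value, floor); defaults
#'   1 percent with an absolute minimum of 0.001.
#' @param seed RNG seed.
#' @export
mc_settings <- function(replicates = 100L, rel = 0.01, floor = 0.001,
                        seed = 1L) {
  stopifnot(replicates >= 2, rel > 0, floor > 0)
  structure(list(replicates = as.integer(replicates), rel = rel,
                 floor = floor, seed = as.integer(seed)),
            class = "mc_settings")
}

#' Confidence-interval settings for parameter continuation
#' @param level Confidence level (default 0.95).
#' @param nominal_sd Nominal absolute measurement error used to weigh the
#'   objective during continuation (default 0.001).
#' @param step0 Initial relative continuation step.
#' @param max_steps Step cap per direction.
#' @export
ci_settings <- function(level = 0.95, nominal_sd = 0.001, step0 = 0.02,
                        max_steps = 200L) {
  stopifnot(level > 0, level < 1)
  structure(list(level = level, nominal_sd = nominal_sd, step0 = step0,
                 max_steps = as.integer(max_steps)), class = "ci_settings")
}

# Simulation plan: one EMU system covering every measured quantity, plus the
# bookkeeping to map a cascade solution onto the data rows.
build_sim_plan <- function(net, data) {
  stopifnot(inherits(data, "measurement_set"))
  targets <- character(); mid_map <- list(); iso_map <- list()
  flux_map <- list()
  frag_key <- function(sp, carb) paste0(sp, "[", carb, "]")
  for (fid in unique(data$fragment_id)) {
    rows <- which(data$fragment_id == fid)
    kind <- data$kind[rows[1]]
    sp <- data$species[rows[1]]
    carb <- data$carbons[rows[1]]
    if (kind == "mid") {
      tg <- frag_key(sp, carb)
      targets <- union(targets, tg)
      mid_map[[fid]] <- list(target = tg, rows = rows,
                             k = as.integer(sub("^M", "", data$index[rows])))
    } else if (kind == "iso") {
      nc <- nchar(data$index[rows[1]])
      subs <- lapply(seq_len(2^nc - 1L), function(m) {
        which(bitwAnd(m, 2^(0:(nc - 1))) > 0)
      })
      tgs <- vapply(subs, function(s) {
        paste0(sp, "[", paste(s, collapse = ","), "]")
      }, "")
      targets <- union(targets, tgs)
      iso_map[[fid]] <- list(species = sp, nc = nc, targets = tgs,
                             sizes = vapply(subs, length, 0L),
                             rows = rows, patterns = data$index[rows])
    } else if (kind == "flux") {
      flux_map[[fid]] <- list(reaction = sp, rows = rows)
    } else {
      stop("cannot fit measurement kind '", kind, "' (correct raw data first)")
    }
  }
  if (!length(targets)) stop("no labelling measurements in dataset")
  system <- decompose_emus(net, as.list(targets))
  list(system = system, mid_map = mid_map, iso_map = iso_map,
       flux_map = flux_map,
       target_index = stats::setNames(seq_along(system$targets), system$targets),
       n_rows = nrow(data))
}

sim_plan_values <- function(plan, net, flux, tracer) {
  rates <- directional_rates(net, flux)
  vals <- suppressWarnings(solve_emu_cascade(plan$system, rates, tracer))
  out <- rep(NA_real_, plan$n_rows)
  for (fm in plan$flux_map) out[fm$rows] <- flux$net[[fm$reaction]]
  key_of <- stats::setNames(plan$system$target_keys, plan$system$targets)
  for (mm in plan$mid_map) {
    mid <- vals[[key_of[[mm$target]]]]
    out[mm$rows] <- mid[mm$k + 1L]
  }
  for (im in plan$iso_map) {
    cumo <- c(1, vapply(seq_along(im$targets), function(i) {
      vals[[key_of[[im$targets[i]]]]][im$sizes[i] + 1L]
    }, 0))
    nc <- im$nc
    p <- numeric(2^nc)
    for (x in 0:(2^nc - 1L)) {
      comp <- bitwAnd(bitwNot(x), 2^nc - 1L)
      tot <- 0; tmask <- comp
      repeat {
        sgn <- (-1)^sum(bitwAnd(tmask, 2^(0:(nc - 1))) > 0)
        tot <- tot + sgn * cumo[bitwOr(x, tmask) + 1L]
        if (tmask == 0) break
        tmask <- bitwAnd(tmask - 1L, comp)
      }
      p[x + 1L] <- tot
    }
    pat <- vapply(0:(2^nc - 1L), function(x) {
      paste0(as.integer(bitwAnd(x, 2^(0:(nc - 1))) > 0), collapse = "")
    }, "")
    out[im$rows] <- p[match(im$patterns, pat)]
  }
  out
}

#' Variance-weighted sum of squared residuals
#'
#' @param net,param,tracer Model inputs.
#' @param free_values Free-flux vector (net then exchange, see
#'   \code{\link{free_names}}).
#' @param data A \code{\link{measurement_set}}.
#' @param plan Optional pre-built simulation plan.
#' @return sum(((sim - meas)/sd)^2).
#' @export
ssr <- function(net, param, free_values, data, tracer, plan = NULL) {
  if (any(data$sd <= 0)) stop("zero or negative measurement SD")
  if (is.null(plan)) plan <- build_sim_plan(net, data)
  flux <- complete_fluxes(param, free_values, check_bounds = FALSE)
  sim <- sim_plan_values(plan, net, flux, tracer)
  sum(((sim - data$value) / data$sd)^2)
}

fit_residual_fn <- function(net, param, data, tracer, plan) {
  force(plan)
  function(theta) {
    flux <- tryCatch(complete_fluxes(param, theta, check_bounds = FALSE,
                                     tol = 1e-6),
                     error = function(e) NULL)
    if (is.null(flux)) return(rep(1e6, nrow(data)))
    sim <- tryCatch(sim_plan_values(plan, net, flux, tracer),
                    error = function(e) rep(NA_real_, nrow(data)))
    r <- (sim - data$value) / data$sd
    r[!is.finite(r)] <- 1e6
    r
  }
}

#' Fit free fluxes to labelling data
#'
#' Multistart bounded Levenberg-Marquardt least squares: starts are the
#' midpoint of the free-flux box plus Latin-hypercube samples, each polished
#' with \code{minpack.lm::nls.lm}.  Distinct optima within an SSR margin of
#' 1e-6 of the best are retained and flagged as multimodality.
#'
#' @param net,param,data,tracer Model and data.
#' @param settings A \code{\link{fit_settings}}.
#' @return A \code{flux_fit} with elements \code{par} (best free fluxes),
#'   \code{ssr}, \code{residuals}, \code{fitted_state}, \code{optima},
#'   \code{multimodal}, \code{converged}, plus the inputs for downstream
#'   Monte Carlo / continuation analysis.
#' @export
fit_fluxes <- function(net, param, data, tracer, settings = fit_settings()) {
  nfree <- n_free(param)
  if (nrow(data) <= nfree) {
    stop("degrees of freedom: need more measurements (", nrow(data),
         ") than free fluxes (", nfree, ")")
  }
  b <- free_bounds(param)
  if (any(!is.finite(b$lo)) || any(!is.finite(b$hi))) {
    stop("fitting requires finite free-flux bounds")
  }
  plan <- build_sim_plan(net, data)
  fn <- fit_residual_fn(net, param, data, tracer, plan)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(settings$seed)
  n_lhs <- settings$multistart - 1L
  starts <- matrix((b$lo + b$hi) / 2, nrow = 1)
  if (n_lhs > 0) {
    u <- lhs::randomLHS(n_lhs, nrow(b))
    starts <- rbind(starts, sweep(sweep(u, 2, b$hi - b$lo, `*`), 2, b$lo, `+`))
  }
  results <- list()
  for (i in seq_len(nrow(starts))) {
    fitted <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = b$lo, upper = b$hi,
                         fn = fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = settings$ftol, ptol = settings$ftol,
                           maxiter = settings$maxiter)),
      error = function(e) NULL)
    if (is.null(fitted)) next
    results[[length(results) + 1L]] <- list(par = fitted$par,
                                            ssr = fitted$deviance)
    if (!is.null(settings$early_stop_ssr) &&
        fitted$deviance < settings$early_stop_ssr) break
  }
  if (!length(results)) stop("no optimizer start converged")
  ssrs <- vapply(results, `[[`, 0, "ssr")
  best <- results[[which.min(ssrs)]]
  near <- results[ssrs <= best$ssr + 1e-6]
  optima <- list(best$par)
  for (r in near) {
    if (all(vapply(optima, function(o) {
      max(abs(o - r$par)) > 1e-4
    }, logical(1)))) {
      optima[[length(optima) + 1L]] <- r$par
    }
  }
  par <- stats::setNames(best$par, b$name)
  res <- fn(par)
  structure(list(par = par, ssr = best$ssr, residuals = res,
                 fitted_state = complete_fluxes(param, par, check_bounds = FALSE),
                 optima = optima, multimodal = length(optima) > 1L,
                 converged = TRUE, n_starts = length(results),
                 net = net, param = param, data = data, tracer = tracer,
                 plan = plan, settings = settings, bounds = b),
            class = "flux_fit")
}

#' @export
print.flux_fit <- function(x, ...) {
  cat("Flux fit: SSR =", format(x$ssr, digits = 6), "over", nrow(x$data),
      "measurements\n")
  print(round(x$par, 6))
  if (!is.null(x$mc)) {
    cat("Monte Carlo (", x$mc$replicates, " replicates):\n", sep = "")
    print(round(rbind(mean = x$mc$mean, sd = x$mc$sd), 6))
  }
  if (!is.null(x$ci)) {
    cat("95% continuation confidence intervals:\n")
    print(round(x$ci, 6))
  }
  if (x$multimodal) cat("NOTE: multiple distinct optima found\n")
  invisible(x)
}

#' Monte Carlo replicate fitting
#'
#' Draws replicate datasets with independent Gaussian noise at
#' sd = max(rel * value, floor) per measurement, refits each (warm-started
#' from the point fit), and reports per-flux means and SDs.
#'
#' @param net,param,data,tracer Model and data.
#' @param mc A \code{\link{mc_settings}}.
#' @param settings A \code{\link{fit_settings}} for the base fit.
#' @return The base \code{flux_fit} with an \code{mc} element: list(mean,
#'   sd, replicates, estimates, n_failed).
#' @export
monte_carlo_fit <- function(net, param, data, tracer, mc = mc_settings(),
                            settings = fit_settings()) {
  base <- fit_fluxes(net, param, data, tracer, settings)
  fn_data <- data
  b <- base$bounds
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(mc$seed)
  sds <- pmax(mc$rel * abs(data$value), mc$floor)
  est <- matrix(NA_real_, mc$replicates, length(base$par),
                dimnames = list(NULL, names(base$par)))
  failed <- 0L
  for (r in seq_len(mc$replicates)) {
    fn_data$value <- data$value + stats::rnorm(nrow(data), 0, sds)
    fn_data$sd <- sds
    plan <- base$plan
    fn <- fit_residual_fn(net, param, fn_data, tracer, plan)
    fitted <- tryCatch(
      minpack.lm::nls.lm(par = unname(base$par), lower = b$lo, upper = b$hi,
                         fn = fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = settings$ftol, ptol = settings$ftol,
                           maxiter = settings$maxiter)),
      error = function(e) NULL)
    if (is.null(fitted)) { failed <- failed + 1L; next }
    est[r, ] <- fitted$par
  }
  if (failed > 0.1 * mc$replicates) {
    stop("more than 10% of Monte Carlo replicate fits failed (", failed, ")")
  }
  base$mc <- list(mean = colMeans(est, na.rm = TRUE),
                  sd = apply(est, 2, stats::sd, na.rm = TRUE),
                  replicates = mc$replicates, estimates = est,
                  n_failed = failed)
  base
}

# SSR with parameter i fixed at theta_i, others re-optimized (warm start).
profile_ssr <- function(fit, i, value, warm = NULL) {
  b <- fit$bounds
  free_idx <- setdiff(seq_along(fit$par), i)
  fn_full <- fit_residual_fn(fit$net, fit$param, fit$data, fit$tracer, fit$plan)
  if (!length(free_idx)) {
    theta <- fit$par; theta[i] <- value
    return(list(ssr = sum(fn_full(theta)^2), par = theta))
  }
  start <- if (is.null(warm)) fit$par[free_idx] else warm[free_idx]
  fn_sub <- function(sub) {
    theta <- numeric(length(fit$par))
    theta[free_idx] <- sub; theta[i] <- value
    fn_full(theta)
  }
  fitted <- minpack.lm::nls.lm(par = unname(start), lower = b$lo[free_idx],
                               upper = b$hi[free_idx], fn = fn_sub,
                               control = minpack.lm::nls.lm.control(
                                 ftol = 1e-10, ptol = 1e-10, maxiter = 100))
  theta <- numeric(length(fit$par))
  theta[free_idx] <- fitted$par; theta[i] <- value
  list(ssr = fitted$deviance, par = theta)
}

#' Parameter-continuation confidence intervals
#'
#' Each free flux is stepped away from its optimum while the remaining free
#' fluxes are re-optimized, until the SSR crosses the chi-square threshold
#' SSR_min + qchisq(level, 1); the crossing is refined by bisection.  A
#' parameter bound reached while still below the threshold gives an open
#' interval at that bound (flagged in the \code{open_lo}/\code{open_hi}
#' columns).
#'
#' @param fit A converged \code{\link{fit_fluxes}} result.
#' @param ci A \code{\link{ci_settings}}.
#' @param refit_sd If TRUE (default), measurement sds are replaced by the
#'   nominal absolute error \code{ci$nominal_sd} and the fit re-polished
#'   before profiling, matching the continuation protocol.
#' @return data.frame(flux, estimate, lo, hi, open_lo, open_hi); the SSR
#'   threshold used is stored in attribute "threshold".
#' @export
continuation_ci <- function(fit, ci = ci_settings(), refit_sd = TRUE) {
  stopifnot(inherits(fit, "flux_fit"))
  label_rows <- fit$data$kind != "flux"
  if (refit_sd && any(fit$data$sd[label_rows] != ci$nominal_sd)) {
    data2 <- fit$data
    data2$sd[label_rows] <- ci$nominal_sd
    fn <- fit_residual_fn(fit$net, fit$param, data2, fit$tracer, fit$plan)
    polished <- minpack.lm::nls.lm(
      par = unname(fit$par), lower = fit$bounds$lo, upper = fit$bounds$hi,
      fn = fn, control = minpack.lm::nls.lm.control(ftol = 1e-10,
                                                    ptol = 1e-10,
                                                    maxiter = 200))
    fit$par <- stats::setNames(polished$par, names(fit$par))
    fit$ssr <- polished$deviance
    fit$data <- data2
  }
  thr <- fit$ssr + stats::qchisq(ci$level, 1)
  b <- fit$bounds
  out <- data.frame(flux = names(fit$par), estimate = unname(fit$par),
                    lo = NA_real_, hi = NA_real_,
                    open_lo = FALSE, open_hi = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(fit$par)) {
    scale_i <- max(abs(fit$par[i]), 0.05 * (b$hi[i] - b$lo[i]), 1e-3)
    for (dir in c(-1, 1)) {
      h <- ci$step0 * scale_i
      inside <- fit$par[i]; warm <- NULL
      bound <- if (dir < 0) b$lo[i] else b$hi[i]
      crossing <- NA_real_; open <- FALSE
      outside <- NA_real_
      for (step in seq_len(ci$max_steps)) {
        cand <- inside + dir * h
        hit_bound <- (dir < 0 && cand <= bound) || (dir > 0 && cand >= bound)
        if (hit_bound) cand <- bound
        pr <- profile_ssr(fit, i, cand, warm)
        if (pr$ssr < thr) {
          inside <- cand; warm <- pr$par
          if (hit_bound) { crossing <- bound; open <- TRUE; break }
          h <- h * 1.6
        } else {
          outside <- cand
          if (h <= 1e-6 * scale_i) { crossing <- cand; break }
          h <- h / 2
        }
      }
      if (is.na(crossing) && !is.na(outside)) {
        # bisection refinement between last inside and first outside
        lo_x <- inside; hi_x <- outside
        for (k in seq_len(40)) {
          mid <- (lo_x + hi_x) / 2
          pr <- profile_ssr(fit, i, mid, warm)
          if (pr$ssr < thr) { lo_x <- mid; warm <- pr$par } else hi_x <- mid
          if (abs(hi_x - lo_x) < 1e-6 * scale_i) break
        }
        crossing <- (lo_x + hi_x) / 2
      }
      if (is.na(crossing)) { crossing <- inside; open <- TRUE }
      if (dir < 0) {
        out$lo[i] <- crossing; out$open_lo[i] <- open
      } else {
        out$hi[i] <- crossing; out$open_hi[i] <- open
      }
    }
  }
  attr(out, "threshold") <- thr
  attr(out, "fit_ssr") <- fit$ssr
  out
}
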
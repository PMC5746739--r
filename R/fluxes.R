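# Free-flux parameterization of the stoichiometric null space.
#
# The net flux vector v (one entry per reaction) must satisfy S v = 0 at every
# internal metabolite, the declared equality/proportionality constraints, and
# the designated free fluxes v_f = f.  When these determine v exactly, the
# solution is affine in f: v = v0 + B f.

#' Construct a flux state
#'
#' @param net Named numeric vector of net fluxes (one per reaction).
#' @param xch01 Named numeric vector of exchange fluxes for reversible
#'   reactions on the compactified [0,1) scale.  The raw exchange flux is
#'   \code{e = xch01/(1 - xch01)}; the forward rate of a reversible reaction
#'   is \code{max(net, 0) + e} and the backward rate \code{max(-net, 0) + e}.
#' @return A \code{flux_state} object.
#' @export
flux_state <- function(net, xch01 = numeric()) {
  stopifnot(is.numeric(net), !is.null(names(net)))
  if (length(xch01)) {
    stopifnot(!is.null(names(xch01)), all(xch01 >= 0), all(xch01 < 1))
  }
  structure(list(net = net, xch01 = xch01), class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat("Flux state (", length(x$net), " net fluxes)\n", sep = "")
  print(round(x$net, 6))
  if (length(x$xch01)) {
    cat("exchange (xch01):\n"); print(round(x$xch01, 6))
  }
  invisible(x)
}

#' Check stoichiometric balance of a flux state
#' @param net An \code{atn} network.
#' @param flux A \code{flux_state}.
#' @param tol Balance tolerance.
#' @return Maximum absolute residual of S v over internal metabolites.
#' @export
balance_residual <- function(net, flux, tol = 1e-9) {
  S <- stoichiometric_matrix(net)
  v <- flux$net[colnames(S)]
  max(abs(S %*% v))
}

constraint_rows <- function(net, rn) {
  cons <- net$constraints
  if (is.null(cons) || nrow(cons) == 0L) {
    return(list(C = matrix(0, 0, length(rn), dimnames = list(NULL, rn)),
                d = numeric()))
  }
  C <- matrix(0, nrow(cons), length(rn), dimnames = list(NULL, rn))
  d <- numeric(nrow(cons))
  for (i in seq_len(nrow(cons))) {
    C[i, cons$reaction[i]] <- 1
    if (is.na(cons$prop_to[i])) {
      d[i] <- cons$value[i]
    } else {
      C[i, cons$prop_to[i]] <- C[i, cons$prop_to[i]] - cons$coef[i]
      d[i] <- 0
    }
  }
  list(C = C, d = d)
}

#' Free-flux parameterization
#'
#' Builds the affine map from designated free net fluxes to the full net flux
#' vector, using the stoichiometric balances and the network's constraints.
#' The combination must determine the flux space exactly: fewer equations
#' than unknowns is rejected as underdetermined, an inconsistent excess as
#' overdetermined.
#'
#' @param net An \code{atn} network.
#' @param designated_free Character vector of free net-flux reaction names.
#'   Defaults to the network's FREE section (net entries).
#' @param constraints Optional named numeric vector of additional fixed net
#'   fluxes (\code{c(R0 = 1)}), merged with the network's CONSTRAINTS section.
#' @param bounds Optional data.frame(name, lo, hi) overriding free-flux
#'   bounds; defaults to the FREE section bounds (or [-Inf, Inf]).
#' @return A \code{free_flux_param} object with elements \code{free_names},
#'   \code{v0}, \code{basis} (matrix reactions x free), \code{bounds},
#'   \code{xch_free} (data.frame of free exchange fluxes), and \code{net}.
#' @export
free_flux_basis <- function(net, designated_free = NULL, constraints = NULL,
                            bounds = NULL) {
  rn <- reaction_names(net)
  if (is.null(designated_free)) {
    designated_free <- net$free$reaction[net$free$type == "net"]
  }
  if (length(designated_free) == 0L) stop("no free net fluxes designated")
  stopifnot(all(designated_free %in% rn))
  S <- stoichiometric_matrix(net)
  cr <- constraint_rows(net, rn)
  if (!is.null(constraints)) {
    extra <- matrix(0, length(constraints), length(rn),
                    dimnames = list(NULL, rn))
    for (i in seq_along(constraints)) {
      extra[i, names(constraints)[i]] <- 1
    }
    cr$C <- rbind(cr$C, extra)
    cr$d <- c(cr$d, unname(constraints))
  }
  FR <- matrix(0, length(designated_free), length(rn),
               dimnames = list(NULL, rn))
  for (i in seq_along(designated_free)) FR[i, designated_free[i]] <- 1
  M <- rbind(S, cr$C, FR)
  qrM <- qr(M)
  rank_deficit <- length(rn) - qrM$rank
  if (rank_deficit > 0) {
    stop(sprintf("flux space is underdetermined: %d unresolved degree(s) of freedom",
                 rank_deficit))
  }
  solve_for <- function(f) {
    rhs <- c(rep(0, nrow(S)), cr$d, f)
    sol <- qr.coef(qrM, rhs)
    sol[is.na(sol)] <- 0
    res <- max(abs(M %*% sol - rhs))
    if (res > 1e-8) {
      stop(sprintf(
        "flux space is overdetermined: constraints and free fluxes are inconsistent (residual %.3g)",
        res))
    }
    sol
  }
  v0 <- solve_for(rep(0, length(designated_free)))
  B <- matrix(0, length(rn), length(designated_free),
              dimnames = list(rn, designated_free))
  for (j in seq_along(designated_free)) {
    f <- rep(0, length(designated_free)); f[j] <- 1
    B[, j] <- solve_for(f) - v0
  }
  # bounds: explicit argument > FREE section > unbounded
  bt <- data.frame(name = designated_free,
                   lo = rep(-Inf, length(designated_free)),
                   hi = rep(Inf, length(designated_free)),
                   stringsAsFactors = FALSE)
  fsec <- net$free[net$free$type == "net", , drop = FALSE]
  hit <- match(bt$name, fsec$reaction)
  bt$lo[!is.na(hit)] <- fsec$lo[stats::na.omit(hit)]
  bt$hi[!is.na(hit)] <- fsec$hi[stats::na.omit(hit)]
  if (!is.null(bounds)) {
    for (i in seq_len(nrow(bounds))) {
      j <- match(bounds$name[i], bt$name)
      if (!is.na(j)) { bt$lo[j] <- bounds$lo[i]; bt$hi[j] <- bounds$hi[i] }
    }
  }
  xch_free <- net$free[net$free$type == "xch", , drop = FALSE]
  structure(list(free_names = designated_free, v0 = v0, basis = B,
                 bounds = bt, xch_free = xch_free, net = net),
            class = "free_flux_param")
}

#' @export
print.free_flux_param <- function(x, ...) {
  cat("Free-flux parameterization:", length(x$free_names), "net +",
      nrow(x$xch_free), "exchange degrees of freedom\n")
  cat("  net:", paste(x$free_names, collapse = ", "), "\n")
  if (nrow(x$xch_free)) cat("  xch:", paste(x$xch_free$reaction, collapse = ", "), "\n")
  invisible(x)
}

#' Number of fit parameters (net + exchange) of a parameterization
#' @param param A \code{free_flux_param}.
#' @export
n_free <- function(param) length(param$free_names) + nrow(param$xch_free)

#' Names of all fit parameters (net then exchange)
#' @param param A \code{free_flux_param}.
#' @export
free_names <- function(param) {
  c(paste0(param$free_names, ".net"),
    if (nrow(param$xch_free)) paste0(param$xch_free$reaction, ".xch"))
}

#' Bounds matrix for all fit parameters
#' @param param A \code{free_flux_param}.
#' @return data.frame(name, lo, hi) for net then exchange parameters.
#' @export
free_bounds <- function(param) {
  nb <- data.frame(name = paste0(param$bounds$name, ".net"),
                   lo = param$bounds$lo, hi = param$bounds$hi,
                   stringsAsFactors = FALSE)
  if (nrow(param$xch_free)) {
    xb <- data.frame(name = paste0(param$xch_free$reaction, ".xch"),
                     lo = param$xch_free$lo,
                     hi = pmin(param$xch_free$hi, 1 - 1e-6),
                     stringsAsFactors = FALSE)
    nb <- rbind(nb, xb)
  }
  nb
}

#' Complete a flux state from free-flux values
#'
#' @param param A \code{free_flux_param} from \code{\link{free_flux_basis}}.
#' @param values Numeric vector of free net fluxes (ordered as
#'   \code{param$free_names}), optionally followed by free exchange fluxes on
#'   the xch01 scale (ordered as \code{param$xch_free$reaction}).  Names are
#'   honoured when present.
#' @param check_bounds Reject out-of-bounds values (default TRUE).
#' @param tol Tolerance for irreversibility violations.
#' @return A \code{flux_state} with all net fluxes and the exchange fluxes of
#'   reversible reactions (0 unless freed).
#' @export
complete_fluxes <- function(param, values, check_bounds = TRUE, tol = 1e-9) {
  nn <- length(param$free_names); nx <- nrow(param$xch_free)
  if (length(values) == nn) {
    netv <- values; xchv <- rep(0, nx)
  } else if (length(values) == nn + nx) {
    netv <- values[seq_len(nn)]; xchv <- values[nn + seq_len(nx)]
  } else {
    stop(sprintf("expected %d or %d free-flux values, got %d",
                 nn, nn + nx, length(values)))
  }
  if (!is.null(names(values)) && all(nzchar(names(values)))) {
    want <- free_names(param)[seq_along(values)]
    if (setequal(names(values), want)) {
      netv <- values[want[seq_len(nn)]]
      if (length(values) > nn) xchv <- values[want[nn + seq_len(nx)]]
    }
  }
  if (check_bounds) {
    b <- free_bounds(param)
    vv <- c(netv, xchv)
    bad <- which(vv < b$lo - 1e-12 | vv > b$hi + 1e-12)
    if (length(bad)) {
      stop(sprintf("free flux %s = %.6g violates bounds [%g, %g]",
                   b$name[bad[1]], vv[bad[1]], b$lo[bad[1]], b$hi[bad[1]]))
    }
  }
  v <- drop(param$v0 + param$basis %*% netv)
  names(v) <- rownames(param$basis)
  rev_rxns <- vapply(param$net$reactions, function(r) r$reversible, logical(1))
  irrev <- names(rev_rxns)[!rev_rxns]
  viol <- irrev[v[irrev] < -tol]
  if (length(viol)) {
    stop(sprintf("negative net flux through irreversible reaction %s (%.6g)",
                 viol[1], v[viol[1]]))
  }
  v[irrev] <- pmax(v[irrev], 0)
  xch01 <- stats::setNames(rep(0, sum(rev_rxns)), names(rev_rxns)[rev_rxns])
  if (nx) xch01[param$xch_free$reaction] <- xchv
  flux_state(v, xch01)
}

#' Extract the free-flux values realised by a flux state
#' @param param A \code{free_flux_param}.
#' @param flux A \code{flux_state}.
#' @export
free_values <- function(param, flux) {
  v <- flux$net[param$free_names]
  names(v) <- paste0(param$free_names, ".net")
  if (nrow(param$xch_free)) {
    x <- flux$xch01[param$xch_free$reaction]
    names(x) <- paste0(param$xch_free$reaction, ".xch")
    v <- c(v, x)
  }
  v
}

#' Sample random feasible free-flux vectors
#'
#' Draws uniformly within the free-flux bounding box and keeps draws whose
#' completed flux state satisfies irreversibility.  Used for property checks.
#'
#' @param param A \code{free_flux_param}.
#' @param n Number of feasible states wanted.
#' @param max_tries Rejection-sampling cap.
#' @return Matrix (n x n_free) of feasible free-flux vectors.
#' @export
sample_feasible_fluxes <- function(param, n, max_tries = 1000L * n) {
  b <- free_bounds(param)
  if (any(!is.finite(b$lo)) || any(!is.finite(b$hi))) {
    stop("sampling requires finite free-flux bounds")
  }
  out <- matrix(NA_real_, 0, nrow(b), dimnames = list(NULL, b$name))
  tries <- 0L
  while (nrow(out) < n && tries < max_tries) {
    tries <- tries + 1L
    v <- stats::runif(nrow(b), b$lo, b$hi)
    ok <- tryCatch({
      complete_fluxes(param, v); TRUE
    }, error = function(e) FALSE)
    if (ok) out <- rbind(out, v)
  }
  if (nrow(out) < n) stop("could not find enough feasible flux states")
  out
}
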
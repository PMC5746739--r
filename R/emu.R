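# Elementary-metabolite-unit (EMU) steady-state label simulation.
#
# An EMU is a subset of a metabolite's carbons.  At isotopic steady state the
# mass-isotopomer distribution (MID) of every EMU of size s satisfies a linear
# balance whose source terms involve only substrate EMUs and EMUs of size < s
# (convolutions), so the system is solved as a size-ordered cascade of dense
# linear solves.

emu_key <- function(met, atoms) paste0(met, "|", paste(sort(atoms), collapse = ","))

#' Parse a fragment specification string
#'
#' Accepts \code{"Met[i-j]"} (inclusive carbon range), \code{"Met[i,j,k]"}
#' (explicit carbons, 1-based) or \code{"Met"} (all carbons).
#'
#' @param spec Fragment specification string.
#' @param net Optional network, required to resolve the \code{"Met"} form and
#'   to validate carbon indices.
#' @return list(met, atoms, id)
#' @export
parse_fragment <- function(spec, net = NULL) {
  m <- regmatches(spec, regexec("^([A-Za-z0-9_]+)(\\[([0-9,-]+)\\])?$", spec))[[1]]
  if (length(m) == 0L) stop("cannot parse fragment specification '", spec, "'")
  met <- m[2]
  if (nzchar(m[4])) {
    part <- m[4]
    if (grepl("-", part, fixed = TRUE)) {
      ij <- as.integer(strsplit(part, "-", fixed = TRUE)[[1]])
      atoms <- seq(ij[1], ij[2])
    } else {
      atoms <- as.integer(strsplit(part, ",", fixed = TRUE)[[1]])
    }
  } else {
    if (is.null(net)) stop("whole-metabolite fragment needs a network to resolve carbons")
    atoms <- seq_len(n_carbons(net, met))
  }
  if (!is.null(net)) {
    nc <- n_carbons(net, met)
    if (is.na(nc)) stop("fragment references undeclared metabolite '", met, "'")
    if (length(atoms) == 0L || any(atoms < 1L | atoms > nc)) {
      stop(sprintf("fragment %s cites carbon outside 1..%d of %s", spec, nc, met))
    }
  }
  list(met = met, atoms = sort(unique(atoms)), id = spec)
}

# Expand reactions into unidirectional atom-map variants.  Reversible
# reactions yield a forward and a backward copy; consumption of symmetric
# metabolites is scrambled over both orientations at half weight each.
directional_variants <- function(net) {
  out <- list()
  scramble <- function(reactants) {
    varlist <- list(list(w = 1, r = reactants))
    for (i in seq_along(reactants)) {
      if (reactants[[i]]$met %in% net$symmetric &&
          length(reactants[[i]]$atoms) > 1L) {
        varlist <- unlist(lapply(varlist, function(v) {
          flipped <- v$r
          flipped[[i]]$atoms <- rev(flipped[[i]]$atoms)
          list(list(w = v$w / 2, r = v$r), list(w = v$w / 2, r = flipped))
        }), recursive = FALSE)
      }
    }
    varlist
  }
  for (rx in net$reactions) {
    for (v in scramble(rx$reactants)) {
      out[[length(out) + 1L]] <- list(rid = rx$name, dir = "f", weight = v$w,
                                      reactants = v$r, products = rx$products)
    }
    if (rx$reversible) {
      for (v in scramble(rx$products)) {
        out[[length(out) + 1L]] <- list(rid = rx$name, dir = "b", weight = v$w,
                                        reactants = v$r, products = rx$reactants)
      }
    }
  }
  out
}

# Per-metabolite consumption stoichiometry by directional reaction:
# named list met -> data.frame(rid, dir, count)
consumption_index <- function(net) {
  idx <- list()
  add <- function(met, rid, dir) {
    key <- paste0(rid, "|", dir)
    if (is.null(idx[[met]])) idx[[met]] <<- list()
    idx[[met]][[key]] <<- (if (is.null(idx[[met]][[key]])) 0 else idx[[met]][[key]]) + 1
  }
  for (rx in net$reactions) {
    for (inst in rx$reactants) add(inst$met, rx$name, "f")
    if (rx$reversible) for (inst in rx$products) add(inst$met, rx$name, "b")
  }
  idx
}

#' Decompose a network into the EMU system needed for target fragments
#'
#' @param net An \code{atn} network.
#' @param targets List of fragment specification strings (see
#'   \code{\link{parse_fragment}}) or pre-parsed fragments.
#' @return An \code{emu_system}: the minimal EMU set reachable backwards from
#'   the targets, with per-EMU production terms, grouped by size.
#' @export
decompose_emus <- function(net, targets) {
  frs <- lapply(targets, function(t) {
    if (is.character(t)) parse_fragment(t, net) else t
  })
  dvs <- directional_variants(net)
  # index: product metabolite -> indices into dvs
  prod_index <- list()
  for (k in seq_along(dvs)) {
    for (p in dvs[[k]]$products) {
      prod_index[[p$met]] <- c(prod_index[[p$met]], k)
    }
  }
  emus <- list()
  work <- lapply(frs, function(f) list(met = f$met, atoms = f$atoms))
  while (length(work)) {
    cur <- work[[1]]; work[[1]] <- NULL
    key <- emu_key(cur$met, cur$atoms)
    if (!is.null(emus[[key]])) next
    role <- met_role(net, cur$met)
    rec <- list(met = cur$met, atoms = cur$atoms, size = length(cur$atoms),
                role = role, terms = list())
    if (role != "substrate") {
      for (k in unique(prod_index[[cur$met]])) {
        dv <- dvs[[k]]
        for (p in dv$products) {
          if (p$met != cur$met) next
          need <- p$atoms[cur$atoms]
          src <- list()
          for (r in dv$reactants) {
            hit <- which(r$atoms %in% need)
            if (length(hit)) {
              src[[length(src) + 1L]] <- list(met = r$met, atoms = sort(hit))
            }
          }
          if (sum(vapply(src, function(s) length(s$atoms), 0L)) != length(need)) {
            stop("internal error: atom-map lookup lost carbons in reaction ", dv$rid)
          }
          rec$terms[[length(rec$terms) + 1L]] <- list(
            rid = dv$rid, dir = dv$dir, weight = dv$weight,
            sources = vapply(src, function(s) emu_key(s$met, s$atoms), ""),
            source_sizes = vapply(src, function(s) length(s$atoms), 0L))
          for (s in src) work[[length(work) + 1L]] <- s
        }
      }
    }
    emus[[key]] <- rec
  }
  # reachability: label can reach an EMU if some term has all sources fed
  fed <- vapply(emus, function(e) e$role == "substrate", logical(1))
  repeat {
    changed <- FALSE
    for (key in names(emus)) {
      if (fed[[key]]) next
      for (tm in emus[[key]]$terms) {
        if (all(fed[tm$sources])) { fed[[key]] <- TRUE; changed <- TRUE; break }
      }
    }
    if (!changed) break
  }
  for (f in frs) {
    if (!fed[[emu_key(f$met, f$atoms)]]) {
      stop("fragment ", f$id, " is unreachable: no path from any substrate")
    }
  }
  structure(list(net = net, emus = emus,
                 sizes = sort(unique(vapply(emus, `[[`, 0L, "size"))),
                 cons = consumption_index(net),
                 targets = vapply(frs, `[[`, "", "id"),
                 target_keys = vapply(frs, function(f) emu_key(f$met, f$atoms), "")),
            class = "emu_system")
}

#' @export
print.emu_system <- function(x, ...) {
  cat("EMU system:", length(x$emus), "EMUs, sizes",
      paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

# Unidirectional reaction rates from a flux state.
# e = xch01/(1-xch01); fwd = max(net,0)+e, bwd = max(-net,0)+e.
directional_rates <- function(net, flux) {
  rates <- list()
  for (rx in net$reactions) {
    v <- flux$net[[rx$name]]
    if (is.null(v) || is.na(v)) stop("flux state lacks reaction ", rx$name)
    if (rx$reversible) {
      x <- if (rx$name %in% names(flux$xch01)) flux$xch01[[rx$name]] else 0
      e <- x / (1 - x)
      rates[[paste0(rx$name, "|f")]] <- max(v, 0) + e
      rates[[paste0(rx$name, "|b")]] <- max(-v, 0) + e
    } else {
      if (v < -1e-9) stop("negative flux through irreversible reaction ", rx$name)
      rates[[paste0(rx$name, "|f")]] <- max(v, 0)
    }
  }
  rates
}

mid_convolve <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' Simulate steady-state mass isotopomer distributions
#'
#' Solves the EMU cascade for the requested target fragments at a given flux
#' state and tracer mixture.  Deterministic: repeated calls give identical
#' results.
#'
#' @param net An \code{atn} network.
#' @param flux A \code{flux_state} (see \code{\link{complete_fluxes}}).
#' @param tracer A \code{\link{substrate_labelling}}.
#' @param targets Fragment specification strings.
#' @param system Optional pre-computed \code{\link{decompose_emus}} system
#'   (reused across flux states during fitting).
#' @return Named list of MID vectors (length size+1, entries M0..Mn summing
#'   to 1), one per target.
#' @export
simulate_mids <- function(net, flux, tracer, targets, system = NULL) {
  if (is.null(system)) system <- decompose_emus(net, targets)
  rates <- directional_rates(net, flux)
  values <- solve_emu_cascade(system, rates, tracer)
  out <- stats::setNames(vector("list", length(system$targets)), system$targets)
  for (i in seq_along(system$targets)) {
    out[[i]] <- values[[system$target_keys[i]]]
  }
  out
}

solve_emu_cascade <- function(system, rates, tracer, tol = 1e-12) {
  net <- system$net
  values <- list()
  rate_of <- function(rid, dir) {
    r <- rates[[paste0(rid, "|", dir)]]
    if (is.null(r)) 0 else r
  }
  # total consumption throughput of a metabolite
  cons_of <- function(met) {
    ci <- system$cons[[met]]
    if (is.null(ci)) return(0)
    tot <- 0
    for (key in names(ci)) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      tot <- tot + rate_of(parts[1], parts[2]) * ci[[key]]
    }
    tot
  }
  # substrate EMUs first
  for (key in names(system$emus)) {
    e <- system$emus[[key]]
    if (e$role == "substrate") {
      values[[key]] <- substrate_emu_mid(tracer, net, e$met, e$atoms)
    }
  }
  pruned <- character()
  for (s in system$sizes) {
    keys <- names(system$emus)[vapply(system$emus, function(e) {
      e$size == s && e$role != "substrate"
    }, logical(1))]
    if (!length(keys)) next
    thr <- vapply(keys, function(k) cons_of(system$emus[[k]]$met), 0)
    dead <- keys[thr <= tol]
    if (length(dead)) {
      hit <- intersect(dead, system$target_keys)
      if (length(hit)) {
        stop("singular EMU system: pool ",
             system$emus[[hit[1]]]$met, " has zero total input")
      }
      for (k in dead) {
        values[[k]] <- c(1, rep(0, system$emus[[k]]$size))
      }
      pruned <- c(pruned, dead)
      keys <- setdiff(keys, dead)
      if (!length(keys)) next
    }
    n <- length(keys)
    A <- matrix(0, n, n, dimnames = list(keys, keys))
    b <- matrix(0, n, s + 1L)
    for (i in seq_len(n)) {
      e <- system$emus[[keys[i]]]
      A[i, i] <- cons_of(e$met)
      for (tm in e$terms) {
        coef <- rate_of(tm$rid, tm$dir) * tm$weight
        if (coef == 0) next
        if (length(tm$sources) == 1L && tm$sources %in% keys) {
          A[i, tm$sources] <- A[i, tm$sources] - coef
        } else {
          val <- NULL
          for (skey in tm$sources) {
            sv <- values[[skey]]
            if (is.null(sv)) {
              stop("internal error: EMU ", skey, " needed before it was solved")
            }
            val <- if (is.null(val)) sv else mid_convolve(val, sv)
          }
          b[i, ] <- b[i, ] + coef * val
        }
      }
    }
    x <- solve(A, b)
    for (i in seq_len(n)) values[[keys[i]]] <- x[i, ]
  }
  if (length(pruned)) {
    warning("pruned zero-throughput pool(s): ",
            paste(unique(vapply(pruned, function(k) system$emus[[k]]$met, "")),
                  collapse = ", "))
  }
  values
}

#' Positional isotopomer distribution of metabolites via the EMU cascade
#'
#' Computes the full positional-isotopomer distribution by assembling the
#' cumomer fractions of every carbon subset (the top mass isotopomer of each
#' subset EMU equals the probability that all its carbons are labelled) and
#' inverting with the Moebius/inclusion-exclusion transform.
#'
#' @param net,flux,tracer As in \code{\link{simulate_mids}}.
#' @param metabolites Character vector of metabolite names.
#' @return Named list; per metabolite a named numeric vector of isotopomer
#'   abundances indexed by binary pattern strings (1 = 13C), carbon 1
#'   leftmost, summing to 1.
#' @export
simulate_isotopomers <- function(net, flux, tracer, metabolites) {
  out <- list()
  for (met in metabolites) {
    nc <- n_carbons(net, met)
    if (is.na(nc)) stop("undeclared metabolite ", met)
    if (nc > 12) stop("isotopomer reconstruction limited to 12 carbons (", met, ")")
    subsets <- lapply(seq_len(2^nc - 1L), function(m) which(bitwAnd(m, 2^(0:(nc - 1))) > 0))
    specs <- vapply(subsets, function(s) paste0(met, "[", paste(s, collapse = ","), "]"), "")
    mids <- simulate_mids(net, flux, tracer, specs)
    cumo <- c(1, vapply(seq_along(subsets), function(i) {
      mids[[i]][length(subsets[[i]]) + 1L]
    }, 0))  # cumo[mask+1] = P(all carbons in mask labelled); mask 0 -> 1
    names(cumo) <- NULL
    p <- numeric(2^nc)
    for (x in 0:(2^nc - 1L)) {
      comp <- bitwAnd(bitwNot(x), 2^nc - 1L)
      tot <- 0
      tmask <- comp
      repeat {
        tot <- tot + (-1)^(sum(bitwAnd(tmask, 2^(0:(nc - 1))) > 0)) * cumo[bitwOr(x, tmask) + 1L]
        if (tmask == 0) break
        tmask <- bitwAnd(tmask - 1L, comp)
      }
      p[x + 1L] <- tot
    }
    pat <- vapply(0:(2^nc - 1L), function(x) {
      paste0(as.integer(bitwAnd(x, 2^(0:(nc - 1))) > 0), collapse = "")
    }, "")
    out[[met]] <- stats::setNames(p, pat)
  }
  out
}

#' Per-carbon labelled fractions of an isotopomer distribution
#'
#' @param dist Named numeric vector of isotopomer abundances indexed by
#'   binary pattern strings (as returned by
#'   \code{\link{simulate_isotopomers}}).
#' @return Numeric vector of marginal 13C fractions, one per carbon.
#' @export
positional_abundances <- function(dist) {
  pat <- names(dist)
  nc <- nchar(pat[1])
  vapply(seq_len(nc), function(j) {
    sum(dist[substr(pat, j, j) == "1"])
  }, 0)
}

#' Sweep free fluxes over a grid and record isotopomer datasets
#'
#' @param net An \code{atn} network whose FREE section defines the swept
#'   fluxes.
#' @param grid data.frame; columns must match the parameterization's free
#'   parameter names (see \code{\link{free_names}}).
#' @param tracer A \code{\link{substrate_labelling}}.
#' @param metabolites Metabolites whose isotopomer distributions are recorded.
#' @param param Optional pre-built parameterization.
#' @return Long data.frame: grid columns + metabolite, pattern, abundance.
#' @export
sweep_toy_network <- function(net, grid, tracer, metabolites, param = NULL) {
  if (is.null(param)) param <- free_flux_basis(net)
  cols <- free_names(param)
  if (!all(cols %in% names(grid))) {
    stop("grid must have columns ", paste(cols, collapse = ", "))
  }
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    vals <- as.numeric(grid[i, cols]); names(vals) <- cols
    fs <- complete_fluxes(param, vals)
    iso <- simulate_isotopomers(net, fs, tracer, metabolites)
    for (met in metabolites) {
      d <- iso[[met]]
      rows[[length(rows) + 1L]] <- data.frame(
        grid[i, cols, drop = FALSE], metabolite = met,
        pattern = names(d), abundance = unname(d),
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
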
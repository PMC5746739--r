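# Brute-force positional-isotopomer oracle.
#
# Solves the full isotopomer balance equations directly by damped
# Gauss-Seidel fixed-point iteration over every internal pool's complete
# isotopomer distribution.  No EMU reduction, no cumomer transform: this is
# the independent validation oracle for the EMU cascade.  Cost is
# exponential in pool size, so use is limited to networks whose internal
# pools together hold at most 16 carbons.

#' Brute-force steady-state isotopomer distributions
#'
#' @param net An \code{atn} network whose internal metabolites carry at most
#'   16 carbons in total.
#' @param flux A \code{flux_state}.
#' @param tracer A \code{\link{substrate_labelling}}.
#' @param metabolites Metabolites to report (default: all internal).
#' @param tol Convergence tolerance on the maximum absolute update.
#' @param max_iter Iteration cap.
#' @return Named list of isotopomer distributions (named numeric vectors over
#'   binary pattern strings), as in \code{\link{simulate_isotopomers}}.
#' @export
simulate_isotopomers_oracle <- function(net, flux, tracer, metabolites = NULL,
                                        tol = 1e-13, max_iter = 200000L) {
  mets <- net$metabolites
  internal <- mets$name[mets$role == "internal" & mets$n_carbons > 0]
  if (is.null(metabolites)) metabolites <- internal
  total_c <- sum(mets$n_carbons[mets$name %in% internal])
  if (total_c > 16) {
    stop("oracle size limit exceeded: internal pools carry ", total_c,
         " carbons (max 16)")
  }
  dvs <- directional_variants(net)
  rates <- directional_rates(net, flux)
  cons_idx <- consumption_index(net)
  rate_of <- function(rid, dir) {
    r <- rates[[paste0(rid, "|", dir)]]; if (is.null(r)) 0 else r
  }
  cons_of <- function(met) {
    ci <- cons_idx[[met]]
    if (is.null(ci)) return(0)
    tot <- 0
    for (key in names(ci)) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      tot <- tot + rate_of(parts[1], parts[2]) * ci[[key]]
    }
    tot
  }
  pat_names <- function(nc) {
    vapply(0:(2^nc - 1L), function(x) {
      paste0(as.integer(bitwAnd(x, 2^(0:(nc - 1))) > 0), collapse = "")
    }, "")
  }
  # state: distributions for substrates (fixed) and internal pools (iterated)
  dist <- list()
  for (i in seq_len(nrow(mets))) {
    met <- mets$name[i]; nc <- mets$n_carbons[i]
    if (nc == 0) next
    if (mets$role[i] == "substrate") {
      dist[[met]] <- substrate_isotopomers(tracer, net, met)
    } else if (mets$role[i] == "internal") {
      d <- numeric(2^nc); d[1] <- 1
      dist[[met]] <- stats::setNames(d, pat_names(nc))
    }
  }
  # production terms: for each internal metabolite, list of
  # (coef, mapping): mapping = per product position the (reactant met,
  # reactant position, reactant instance id) it comes from
  prod_terms <- list()
  for (dv in dvs) {
    coef0 <- rate_of(dv$rid, dv$dir) * dv$weight
    for (p in dv$products) {
      if (!(p$met %in% internal)) next
      mapping <- lapply(p$atoms, function(letter) {
        for (ri in seq_along(dv$reactants)) {
          q <- match(letter, dv$reactants[[ri]]$atoms)
          if (!is.na(q)) return(c(ri, q))
        }
        stop("unmapped atom letter in reaction ", dv$rid)
      })
      prod_terms[[p$met]] <- c(prod_terms[[p$met]], list(list(
        coef = coef0,
        rmets = vapply(dv$reactants, `[[`, "", "met"),
        rsizes = vapply(dv$reactants, function(r) length(r$atoms), 0L),
        map = do.call(rbind, mapping))))
    }
  }
  # Gauss-Seidel sweeps
  for (iter in seq_len(max_iter)) {
    delta <- 0
    for (met in internal) {
      ctot <- cons_of(met)
      if (ctot <= 1e-12) next  # dead pool: leave at initialisation
      nc <- n_carbons(net, met)
      newd <- numeric(2^nc)
      for (tm in prod_terms[[met]]) {
        if (tm$coef == 0) next
        # probability of each product pattern: product over reactant
        # instances of the marginal probability of the required sub-pattern
        for (x in 0:(2^nc - 1L)) {
          bits <- bitwAnd(bitwShiftR(x, 0:(nc - 1L)), 1L)
          pr <- tm$coef
          for (ri in seq_along(tm$rmets)) {
            sel <- which(tm$map[, 1] == ri)
            if (!length(sel)) next
            rd <- dist[[tm$rmets[ri]]]
            if (is.null(rd)) { pr <- 0; break }
            # marginal over reactant patterns consistent with required bits
            need_pos <- tm$map[sel, 2]
            need_bit <- bits[sel]
            rn <- tm$rsizes[ri]
            m <- 0
            for (y in 0:(2^rn - 1L)) {
              yb <- bitwAnd(bitwShiftR(y, need_pos - 1L), 1L)
              if (all(yb == need_bit)) m <- m + rd[y + 1L]
            }
            pr <- pr * m
          }
          newd[x + 1L] <- newd[x + 1L] + pr
        }
      }
      newd <- newd / ctot
      # renormalize: the exact solution sums to 1, and projecting back onto
      # the simplex suppresses rounding drift that the quadratic
      # (condensation) terms would otherwise amplify
      s <- sum(newd)
      if (is.finite(s) && s > 0) newd <- newd / s
      delta <- max(delta, max(abs(newd - unname(dist[[met]]))))
      dist[[met]] <- stats::setNames(newd, names(dist[[met]]))
    }
    if (!is.finite(delta)) stop("isotopomer oracle diverged")
    if (delta < tol) break
  }
  if (delta >= tol) {
    stop("isotopomer oracle failed to converge (last update ", delta, ")")
  }
  dist[metabolites]
}
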
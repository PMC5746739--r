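# Substrate labelling (tracer) specifications.

#' Define substrate labelling
#'
#' @param patterns Named list, one entry per substrate metabolite; each entry
#'   a named numeric vector mapping binary isotopomer pattern strings
#'   (1 = 13C, carbon 1 leftmost) to molar fractions summing to 1.  Example:
#'   \code{list(Gluc = c("100000" = 0.8, "111111" = 0.2))} for 80 percent
#'   [1-13C]glucose + 20 percent [13C6]glucose.
#' @param natural_abundance Probability that a position left as "0" by the
#'   pattern is 13C anyway.  0 for pure in-silico simulations; 0.011 when
#'   emulating real measurements.
#' @return A \code{substrate_labelling} object.
#' @export
substrate_labelling <- function(patterns, natural_abundance = 0) {
  stopifnot(is.list(patterns), length(names(patterns)) == length(patterns))
  for (met in names(patterns)) {
    p <- patterns[[met]]
    if (is.null(names(p)) || !all(grepl("^[01]+$", names(p)))) {
      stop("patterns for ", met, " must be named by binary strings")
    }
    if (abs(sum(p) - 1) > 1e-12) {
      stop("pattern fractions for ", met, " must sum to 1 (got ", sum(p), ")")
    }
    if (length(unique(nchar(names(p)))) != 1L) {
      stop("patterns for ", met, " have inconsistent carbon counts")
    }
  }
  stopifnot(natural_abundance >= 0, natural_abundance < 1)
  structure(list(patterns = patterns, natural_abundance = natural_abundance),
            class = "substrate_labelling")
}

#' @export
print.substrate_labelling <- function(x, ...) {
  for (met in names(x$patterns)) {
    p <- x$patterns[[met]]
    cat(met, ": ", paste(sprintf("%s (%.3g)", names(p), p), collapse = ", "),
        "\n", sep = "")
  }
  if (x$natural_abundance > 0) {
    cat("natural 13C abundance on unset positions:", x$natural_abundance, "\n")
  }
  invisible(x)
}

#' Glucose tracer mixtures used throughout
#'
#' @param frac_1 Fraction of [1-13C]glucose.
#' @param frac_u Fraction of [13C6]glucose (uniformly labelled).
#' @param natural_abundance See \code{\link{substrate_labelling}}.
#' @param substrate Substrate metabolite name (default "Gluc").
#' @return A \code{substrate_labelling}; the remaining fraction is unlabelled
#'   glucose.
#' @export
glucose_tracer <- function(frac_1 = 0, frac_u = 0.2, natural_abundance = 0,
                           substrate = "Gluc") {
  stopifnot(frac_1 >= 0, frac_u >= 0, frac_1 + frac_u <= 1)
  p <- c("100000" = frac_1, "111111" = frac_u, "000000" = 1 - frac_1 - frac_u)
  p <- p[p > 0]
  if (length(p) == 0L) p <- c("000000" = 1)
  substrate_labelling(stats::setNames(list(p), substrate), natural_abundance)
}

# MID of a substrate EMU (subset of carbons) under the tracer.
substrate_emu_mid <- function(tracer, net, met, atoms) {
  spec <- tracer$patterns[[met]]
  if (is.null(spec)) {
    stop("tracer does not define labelling for substrate ", met)
  }
  nc <- n_carbons(net, met)
  if (nchar(names(spec)[1]) != nc) {
    stop("tracer pattern length for ", met, " does not match its carbon count")
  }
  na <- tracer$natural_abundance
  out <- numeric(length(atoms) + 1L)
  for (k in seq_along(spec)) {
    pat <- names(spec)[k]
    mid <- 1
    for (pos in atoms) {
      p1 <- if (substr(pat, pos, pos) == "1") 1 else na
      mid <- mid_convolve(mid, c(1 - p1, p1))
    }
    out <- out + spec[[k]] * mid
  }
  unname(out)
}

# Full positional-isotopomer distribution of a substrate under the tracer.
substrate_isotopomers <- function(tracer, net, met) {
  nc <- n_carbons(net, met)
  spec <- tracer$patterns[[met]]
  if (is.null(spec)) stop("tracer does not define labelling for substrate ", met)
  na <- tracer$natural_abundance
  p <- numeric(2^nc)
  for (k in seq_along(spec)) {
    pat <- names(spec)[k]
    for (x in 0:(2^nc - 1L)) {
      bits <- as.integer(bitwAnd(x, 2^(0:(nc - 1))) > 0)
      pr <- 1
      for (j in seq_len(nc)) {
        p1 <- if (substr(pat, j, j) == "1") 1 else na
        pr <- pr * if (bits[j] == 1L) p1 else 1 - p1
      }
      p[x + 1L] <- p[x + 1L] + spec[[k]] * pr
    }
  }
  pat_names <- vapply(0:(2^nc - 1L), function(x) {
    paste0(as.integer(bitwAnd(x, 2^(0:(nc - 1))) > 0), collapse = "")
  }, "")
  stats::setNames(p, pat_names)
}
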
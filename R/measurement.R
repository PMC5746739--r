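# MeasurementSet: the tabular currency passed between simulator, noise
# generator, QC and fitter.  A data.frame in long format, one row per
# measured abundance:
#   fragment_id - fragment or metabolite identifier
#   species     - amino acid / metabolite the backbone belongs to
#   carbons     - comma-separated backbone carbon indices ("1,2,3")
#   kind        - "mid" (mass isotopomers M0..Mn), "iso" (positional
#                 isotopomer abundances, index = binary pattern) or "raw"
#                 (uncorrected mass-shift envelope)
#   index       - "M0".."Mn" or a binary pattern string
#   value       - fractional abundance
#   sd          - standard deviation used as fit weight
#   ion_count   - total ion count of the fragment (QC)

.ms_cols <- c("fragment_id", "species", "carbons", "kind", "index",
              "value", "sd", "ion_count")

#' Construct a measurement set
#' @param df data.frame with columns fragment_id, species, carbons, kind,
#'   index, value, sd, ion_count.
#' @return The data.frame with class \code{measurement_set}.
#' @export
measurement_set <- function(df) {
  miss <- setdiff(.ms_cols, names(df))
  if (length(miss)) stop("measurement set lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$sd <= 0, na.rm = TRUE)) stop("measurement SDs must be positive")
  if (any(df$ion_count < 0, na.rm = TRUE)) stop("ion counts must be non-negative")
  rownames(df) <- NULL
  class(df) <- c("measurement_set", "data.frame")
  df
}

#' @export
print.measurement_set <- function(x, ...) {
  cat("Measurement set:", length(unique(x$fragment_id)), "fragments,",
      nrow(x), "abundances\n")
  NextMethod()
}

#' Nominal measurement standard deviation
#'
#' The Monte Carlo noise rule: sd = max(rel * |value|, floor), defaulting to
#' 1 percent of the measurement with an absolute minimum of 0.001.
#'
#' @param value Measured abundances.
#' @param rel Relative component (default 0.01).
#' @param floor Minimum absolute sd (default 0.001).
#' @export
sd_nominal <- function(value, rel = 0.01, floor = 0.001) {
  pmax(rel * abs(value), floor)
}

#' Build a measurement set from simulated fragment MIDs
#'
#' @param net,flux,tracer,panel Simulation inputs; \code{panel} is a list of
#'   \code{\link{fragment_spec}} objects.
#' @param sd Either a numeric (absolute sd for all rows) or a function of the
#'   abundance vector returning sds (default \code{\link{sd_nominal}}).
#' @param ion_count Ion count recorded per fragment (default 1e6).
#' @return A \code{\link{measurement_set}} of kind "mid".
#' @export
simulate_panel_measurements <- function(net, flux, tracer, panel,
                                        sd = sd_nominal, ion_count = 1e6) {
  targets <- vapply(panel, function(f) {
    paste0(f$amino_acid, "[", paste(f$carbons, collapse = ","), "]")
  }, "")
  mids <- simulate_mids(net, flux, tracer, targets)
  rows <- Map(function(frag, mid) {
    n <- length(frag$carbons)
    data.frame(fragment_id = frag$fragment_id, species = frag$amino_acid,
               carbons = paste(frag$carbons, collapse = ","), kind = "mid",
               index = paste0("M", 0:n), value = unname(mid),
               sd = if (is.function(sd)) sd(mid) else rep(sd, n + 1L),
               ion_count = ion_count, stringsAsFactors = FALSE)
  }, panel, mids)
  measurement_set(do.call(rbind, rows))
}

#' Build a measurement set of positional isotopomer abundances
#'
#' The measurement model of the toy-network analyses: the fractional
#' abundances of all isotopomers of each requested internal metabolite
#' (including the fully unlabelled one).
#'
#' @param net,flux,tracer Simulation inputs.
#' @param metabolites Metabolites whose isotopomers are recorded.
#' @param sd As in \code{\link{simulate_panel_measurements}}.
#' @param ion_count Recorded ion count (default 1e6).
#' @return A \code{\link{measurement_set}} of kind "iso".
#' @export
simulate_iso_measurements <- function(net, flux, tracer, metabolites,
                                      sd = sd_nominal, ion_count = 1e6) {
  iso <- simulate_isotopomers(net, flux, tracer, metabolites)
  rows <- lapply(metabolites, function(met) {
    d <- iso[[met]]
    data.frame(fragment_id = met, species = met,
               carbons = paste(seq_len(nchar(names(d)[1])), collapse = ","),
               kind = "iso", index = names(d), value = unname(d),
               sd = if (is.function(sd)) sd(unname(d)) else rep(sd, length(d)),
               ion_count = ion_count, stringsAsFactors = FALSE)
  })
  measurement_set(do.call(rbind, rows))
}

#' Direct flux-rate measurement rows
#'
#' Steady-state MIDs are invariant to a uniform scaling of all fluxes, so a
#' labelling dataset alone cannot pin the absolute flux scale.  Measured
#' external rates (e.g. glucose consumption) enter the fit as rows of kind
#' "flux".
#'
#' @param reactions Reaction names.
#' @param values Measured net fluxes.
#' @param sd Standard deviations (default: the nominal 1 percent rule).
#' @return A \code{\link{measurement_set}} of kind "flux".
#' @export
flux_measurements <- function(reactions, values, sd = sd_nominal(values)) {
  measurement_set(data.frame(
    fragment_id = reactions, species = reactions, carbons = "",
    kind = "flux", index = "net", value = values, sd = sd,
    ion_count = NA_real_, stringsAsFactors = FALSE))
}

#' Concatenate measurement sets
#' @param ... \code{\link{measurement_set}} objects.
#' @export
bind_measurements <- function(...) {
  measurement_set(do.call(rbind, lapply(list(...), as.data.frame)))
}

#' Write / read measurement sets as TSV
#' @param ms A \code{\link{measurement_set}}.
#' @param path File path.
#' @export
write_measurements <- function(ms, path) {
  utils::write.table(as.data.frame(ms), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  measurement_set(utils::read.table(path, sep = "\t", header = TRUE,
                                    colClasses = c(index = "character",
                                                   carbons = "character"),
                                    stringsAsFactors = FALSE))
}

#' Write simulated MIDs as TSV (fragment_id, n_carbons, M0..Mn columns)
#' @param mids Named list of MID vectors (see \code{\link{simulate_mids}}).
#' @param path File path.
#' @export
write_mid_table <- function(mids, path) {
  nmax <- max(vapply(mids, length, 0L)) - 1L
  rows <- lapply(names(mids), function(id) {
    m <- mids[[id]]
    pad <- c(m, rep(NA, nmax + 1L - length(m)))
    df <- data.frame(fragment_id = id, n_carbons = length(m) - 1L)
    for (k in 0:nmax) df[[paste0("M", k)]] <- sprintf("%.8f", pad[k + 1L])
    df
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
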
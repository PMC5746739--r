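# GC-MS mass-isotopomer processing: natural-abundance correction for
# tBDMS-derivatized amino acid fragments, fractional enrichment, ion-count
# quality control, and dataset averaging.

#' Natural-abundance isotope constants
#'
#' Heavy-isotope probabilities used to build correction matrices.  13C is
#' 1.109 percent; the remaining entries are standard terrestrial abundances.
#' Override entries by passing a modified copy to
#' \code{\link{build_correction_matrix}}.
#' @export
isotope_constants <- function() {
  list(
    C = c(0.98891, 0.01109),
    H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364),
    O = c(0.99757, 0.00038, 0.00205),
    Si = c(0.92223, 0.04685, 0.03092),
    S = c(0.9493, 0.0075, 0.0425))
}

#' Fragment specification
#'
#' @param fragment_id Identifier, e.g. \code{"Ala_M57"}.
#' @param amino_acid Amino acid (or metabolite) the backbone carbons belong to.
#' @param carbons Integer vector of backbone carbon indices covered by the
#'   detected ion (1-based on the amino acid).
#' @param composition Named integer vector of the elemental composition of
#'   the detected derivatized ion \emph{excluding} the backbone carbons
#'   (elements among C, H, N, O, S, Si).
#' @return A \code{fragment_spec}.
#' @export
fragment_spec <- function(fragment_id, amino_acid, carbons, composition) {
  stopifnot(length(carbons) >= 1, all(carbons >= 1))
  comp <- composition[composition != 0]
  if (any(comp < 0)) {
    stop("negative element count in composition of ", fragment_id, ": ",
         paste(names(comp)[comp < 0], collapse = ", "))
  }
  bad <- setdiff(names(comp), c("C", "H", "N", "O", "S", "Si"))
  if (length(bad)) stop("unknown element(s): ", paste(bad, collapse = ", "))
  structure(list(fragment_id = fragment_id, amino_acid = amino_acid,
                 carbons = sort(unique(carbons)), composition = comp),
            class = "fragment_spec")
}

# Mass-shift distribution of the non-backbone atom envelope, by direct
# polynomial expansion (repeated convolution) of per-atom distributions.
natural_envelope <- function(frag, constants = isotope_constants(),
                             drop_below = 1e-9) {
  env <- 1
  for (el in names(frag$composition)) {
    d <- constants[[el]]
    if (is.null(d)) stop("no isotope constants for element ", el)
    for (k in seq_len(frag$composition[[el]])) env <- mid_convolve(env, d)
  }
  keep <- max(which(env > drop_below), 1L)
  env[seq_len(keep)]
}

#' Build the natural-abundance correction matrix of a fragment
#'
#' The matrix maps a backbone MID (length n+1) to the observed mass-shift
#' envelope by convolution with the natural-abundance mass distribution of
#' all non-backbone atoms (derivatization carbons, H, N, O, S, Si).
#'
#' @param frag A \code{\link{fragment_spec}}.
#' @param constants Isotope table, see \code{\link{isotope_constants}}.
#' @return Matrix with n+1 columns and n+k+1 rows (k = truncated envelope
#'   width); each column holds the envelope shifted down by the backbone
#'   mass, and sums to the retained envelope mass (>= 0.99).
#' @export
build_correction_matrix <- function(frag, constants = isotope_constants()) {
  env <- natural_envelope(frag, constants)
  n <- length(frag$carbons)
  k <- length(env) - 1L
  M <- matrix(0, n + k + 1L, n + 1L)
  for (j in 0:n) M[j + seq_along(env), j + 1L] <- env
  structure(M, fragment_id = frag$fragment_id, envelope = env)
}

#' Forward-convolve a backbone MID into an observed mass envelope
#'
#' The synthetic-measurement counterpart of
#' \code{\link{correct_natural_abundance}}: what a GC-MS instrument would see
#' for a fragment whose backbone carries the given MID.
#'
#' @param mid Backbone MID (length n+1).
#' @param frag A \code{\link{fragment_spec}}.
#' @param constants Isotope table.
#' @return Observed mass-shift abundances (length n+k+1, sums to ~1).
#' @export
convolve_fragment <- function(mid, frag, constants = isotope_constants()) {
  M <- build_correction_matrix(frag, constants)
  drop(M %*% mid)
}

#' Correct measured mass envelopes for natural isotope abundance
#'
#' Solves the least-squares deconvolution of each fragment's measured
#' mass-shift abundances against its correction matrix and renormalizes the
#' backbone MID to sum 1.  Negative corrected entries are retained by default
#' (they carry the statistical signature of baseline-corrected low-count
#' signals); \code{clamp = TRUE} truncates them at zero before
#' renormalization.
#'
#' @param raw A \code{\link{measurement_set}} whose rows hold raw mass-shift
#'   abundances (kind "raw", index "M0", "M1", ...).
#' @param panel List of \code{\link{fragment_spec}} objects covering the
#'   fragments present.
#' @param constants Isotope table.
#' @param clamp Truncate negative corrected abundances at zero.
#' @param cond_limit Condition-number threshold above which a fragment is
#'   flagged (attribute "flagged") with a warning.
#' @return A \code{measurement_set} of backbone MIDs (kind "mid").
#' @export
correct_natural_abundance <- function(raw, panel, constants = isotope_constants(),
                                      clamp = FALSE, cond_limit = 1e8) {
  stopifnot(inherits(raw, "measurement_set"))
  panel_ids <- vapply(panel, `[[`, "", "fragment_id")
  out <- list(); flagged <- character()
  for (fid in unique(raw$fragment_id)) {
    rows <- raw[raw$fragment_id == fid, , drop = FALSE]
    frag <- panel[[match(fid, panel_ids)]]
    if (is.na(match(fid, panel_ids))) stop("fragment ", fid, " not in panel")
    shift <- as.integer(sub("^M", "", rows$index))
    y <- rows$value[order(shift)]
    if (all(y == 0)) stop("empty spectrum for fragment ", fid)
    n <- length(frag$carbons)
    if (length(y) < n + 1L) {
      stop("fragment ", fid, ": need at least ", n + 1L, " mass-shift abundances")
    }
    M <- build_correction_matrix(frag, constants)
    m <- min(length(y), nrow(M))
    Mm <- M[seq_len(m), , drop = FALSE]
    cond <- kappa(Mm, exact = TRUE)
    if (cond > cond_limit) {
      warning("ill-conditioned correction matrix for ", fid,
              " (condition number ", format(cond, digits = 3), ")")
      flagged <- c(flagged, fid)
    }
    x <- qr.coef(qr(Mm), y[seq_len(m)])
    if (clamp) x <- pmax(x, 0)
    x <- x / sum(x)
    out[[fid]] <- data.frame(
      fragment_id = fid, species = frag$amino_acid,
      carbons = paste(frag$carbons, collapse = ","), kind = "mid",
      index = paste0("M", 0:n), value = unname(x),
      sd = rows$sd[order(shift)][seq_len(n + 1L)], ion_count = rows$ion_count[1],
      stringsAsFactors = FALSE)
  }
  ms <- measurement_set(do.call(rbind, out))
  attr(ms, "flagged") <- flagged
  ms
}

#' Fractional 13C enrichment of a MID
#'
#' Mean fraction of 13C per backbone carbon: sum(i * Mi) / n.  Inputs are
#' not clamped: noisy MIDs with negative entries (an artefact of baseline
#' correction at low ion counts) may yield negative enrichments, and these
#' are returned as-is.
#'
#' @param mid Numeric MID vector (M0..Mn).
#' @return Enrichment in (-Inf, 1].
#' @export
fractional_enrichment <- function(mid) {
  n <- length(mid) - 1L
  if (n == 0L) stop("MID must have at least two entries")
  sum((0:n) * mid) / n
}

#' Ion-count quality-control rule
#' @param min_ion_count Minimum acceptable total ion count (default 1e5, the
#'   empirical reliability threshold for fractional-abundance measurements).
#' @export
qc_rule <- function(min_ion_count = 1e5) {
  stopifnot(min_ion_count > 0)
  structure(list(min_ion_count = min_ion_count), class = "qc_rule")
}

#' Filter a measurement set by ion count
#'
#' @param ms A \code{\link{measurement_set}}.
#' @param rule A \code{\link{qc_rule}}.
#' @return The retained rows; the number of removed fragments is reported in
#'   a message and stored in attribute "removed".
#' @export
filter_by_ion_count <- function(ms, rule = qc_rule()) {
  stopifnot(inherits(ms, "measurement_set"))
  keep <- ms$ion_count >= rule$min_ion_count
  removed <- unique(ms$fragment_id[!keep])
  out <- measurement_set(ms[keep, , drop = FALSE])
  if (length(removed)) {
    message(length(removed), " fragment(s) below ",
            format(rule$min_ion_count, scientific = TRUE), " ion counts removed")
  }
  attr(out, "removed") <- removed
  out
}

#' Weighted average of measurement sets
#'
#' Averages per-isotopomer abundances across datasets fragment by fragment;
#' this is the "measured" dataset of a mixed population of cell types whose
#' members contribute the given weights.
#'
#' @param sets List of \code{\link{measurement_set}} objects over identical
#'   fragment panels (same fragment_id/index rows).
#' @param weights Numeric weights summing to 1.
#' @return A \code{measurement_set}; values are weighted means, sds are
#'   propagated as sqrt(sum(w^2 sd^2)), ion counts weighted means.
#' @export
average_measurement_sets <- function(sets, weights) {
  stopifnot(length(sets) >= 1, length(weights) == length(sets))
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  ref <- sets[[1]]
  key <- function(s) paste(s$fragment_id, s$index)
  for (s in sets[-1]) {
    miss <- setdiff(key(ref), key(s))
    if (length(miss) || nrow(s) != nrow(ref)) {
      stop("measurement sets have mismatched panels; missing: ",
           paste(utils::head(miss, 3), collapse = ", "))
    }
  }
  out <- ref
  ord <- lapply(sets, function(s) match(key(ref), key(s)))
  out$value <- Reduce(`+`, Map(function(s, o, w) w * s$value[o], sets, ord,
                               as.list(weights)))
  out$sd <- sqrt(Reduce(`+`, Map(function(s, o, w) w^2 * s$sd[o]^2, sets, ord,
                                 as.list(weights))))
  out$ion_count <- Reduce(`+`, Map(function(s, o, w) w * s$ion_count[o], sets,
                                   ord, as.list(weights)))
  measurement_set(out)
}
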
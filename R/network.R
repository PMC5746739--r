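# Internal representation
# -----------------------
# An atom-transition network ("atn") is a list:
#   name        - character scalar
#   metabolites - data.frame(name, n_carbons, role) with role in
#                 {"substrate","internal","sink"}
#   reactions   - named list; each reaction is a list(name, reversible,
#                 reactants, products, cofactors) where reactants/products are
#                 lists of instances list(met = <name>, atoms = <chr vector of
#                 atom letters, length n_carbons>).  Stoichiometric
#                 coefficients > 1 are represented by repeated instances.
#   symmetric   - character vector of rotationally symmetric metabolites
#                 (e.g. succinate, fumarate); consumption of these is
#                 scrambled over both carbon orientations at half weight.
#   constraints - data.frame(reaction, value, prop_to, coef): either a fixed
#                 net flux (prop_to == NA, reaction.net = value) or a
#                 proportionality (reaction.net = coef * prop_to.net).
#   free        - data.frame(name, reaction, type ("net"/"xch"), lo, hi)

.atn_roles <- c("substrate", "internal", "sink")

new_atn <- function(name, metabolites, reactions, symmetric = character(),
                    constraints = NULL, free = NULL) {
  if (is.null(constraints)) {
    constraints <- data.frame(reaction = character(), value = numeric(),
                              prop_to = character(), coef = numeric(),
                              stringsAsFactors = FALSE)
  }
  if (is.null(free)) {
    free <- data.frame(name = character(), reaction = character(),
                       type = character(), lo = numeric(), hi = numeric(),
                       stringsAsFactors = FALSE)
  }
  structure(list(name = name, metabolites = metabolites,
                 reactions = reactions, symmetric = symmetric,
                 constraints = constraints, free = free),
            class = "atn")
}

#' @export
print.atn <- function(x, ...) {
  cat("Atom-transition network '", x$name, "'\n", sep = "")
  cat("  ", nrow(x$metabolites), " metabolites (",
      sum(x$metabolites$role == "internal"), " internal), ",
      length(x$reactions), " reactions (",
      sum(vapply(x$reactions, function(r) r$reversible, logical(1))),
      " reversible)\n", sep = "")
  if (nrow(x$free)) {
    cat("  free fluxes:", paste(x$free$name, collapse = ", "), "\n")
  }
  invisible(x)
}

n_carbons <- function(net, met) {
  net$metabolites$n_carbons[match(met, net$metabolites$name)]
}

met_role <- function(net, met) {
  net$metabolites$role[match(met, net$metabolites$name)]
}

reaction_names <- function(net) names(net$reactions)

#' Parse an atom-transition network document
#'
#' Reads the package's plain-text network format.  The format has five
#' sections introduced by the uppercase keywords \code{METABOLITES},
#' \code{REACTIONS}, \code{COFACTORS}, \code{SYMMETRIC}, \code{CONSTRAINTS}
#' and \code{FREE}; \code{#} starts a comment and blank lines are ignored.
#'
#' \preformatted{
#' NETWORK toy
#' METABOLITES
#'   S  2  substrate
#'   A  2  internal
#'   B  1  internal
#'   Bout 1 sink
#' REACTIONS
#'   R0: S (ab) -> A (ab)
#'   R1: A (ab) -> B (a) + C (b) rev
#' COFACTORS
#'   R1: NADH +1
#' CONSTRAINTS
#'   R0.net = 1
#'   R4.net = 0.5 * R3.net
#' FREE
#'   R1.net [0, 1]
#'   R1.xch [0, 0.99]
#' }
#'
#' Atom maps use one lowercase letter per carbon; the multiset of reactant
#' letters must equal the multiset of product letters (carbon is conserved
#' within every reaction).  Metabolites with zero carbons are written without
#' a parenthesised atom list.  Repeated instances express stoichiometric
#' coefficients greater than one (e.g. \code{PYR (abc) + PYR (def)}).
#'
#' @param text Character scalar (whole document) or character vector of lines.
#' @param name Fallback network name if the document has no NETWORK line.
#' @return A validated network object of class \code{atn}.
#' @export
parse_network <- function(text, name = "network") {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }
  lines <- sub("#.*$", "", lines)
  section <- NA_character_
  mets <- list(); rxns <- list(); symmetric <- character()
  cons <- list(); free <- list()
  perr <- function(i, msg) {
    stop(sprintf("network parse error (line %d): %s", i, msg), call. = FALSE)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    if (grepl("^NETWORK\\s+", ln)) { name <- trimws(sub("^NETWORK", "", ln)); next }
    if (ln %in% c("METABOLITES", "REACTIONS", "COFACTORS", "SYMMETRIC",
                  "CONSTRAINTS", "FREE")) { section <- ln; next }
    if (is.na(section)) perr(i, "content before any section keyword")
    if (section == "METABOLITES") {
      f <- strsplit(ln, "\\s+")[[1]]
      if (length(f) != 3L) perr(i, "expected: <name> <n_carbons> <role>")
      nc <- suppressWarnings(as.integer(f[2]))
      if (is.na(nc) || nc < 0) perr(i, "n_carbons must be a non-negative integer")
      if (!f[3] %in% .atn_roles) {
        perr(i, paste0("role must be one of ", paste(.atn_roles, collapse = "/")))
      }
      mets[[length(mets) + 1L]] <- list(name = f[1], n_carbons = nc, role = f[3])
    } else if (section == "REACTIONS") {
      rx <- tryCatch(parse_reaction_line(ln), error = function(e) {
        perr(i, conditionMessage(e))
      })
      rxns[[rx$name]] <- rx
    } else if (section == "COFACTORS") {
      m <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
      if (length(m) != 3L) perr(i, "expected: <reaction>: <species> <+/-count>, ...")
      rid <- trimws(m[2])
      if (is.null(rxns[[rid]])) perr(i, paste0("cofactors for undeclared reaction '", rid, "'"))
      for (part in strsplit(m[3], ",")[[1]]) {
        pm <- strsplit(trimws(part), "\\s+")[[1]]
        if (length(pm) != 2L) perr(i, "expected '<species> <signed count>' pairs")
        cnt <- suppressWarnings(as.numeric(pm[2]))
        if (is.na(cnt)) perr(i, "cofactor count must be numeric")
        rxns[[rid]]$cofactors[pm[1]] <- cnt
      }
    } else if (section == "SYMMETRIC") {
      symmetric <- c(symmetric, strsplit(ln, "\\s+")[[1]])
    } else if (section == "CONSTRAINTS") {
      m <- regmatches(ln, regexec(
        "^(\\S+)\\.net\\s*=\\s*([0-9eE.+-]+)(\\s*\\*\\s*(\\S+)\\.net)?$", ln))[[1]]
      if (length(m) == 0L) perr(i, "expected 'R.net = <value>' or 'R.net = <coef> * R2.net'")
      cons[[length(cons) + 1L]] <- list(
        reaction = m[2], value = as.numeric(m[3]),
        prop_to = if (nzchar(m[5])) m[5] else NA_character_,
        coef = if (nzchar(m[5])) as.numeric(m[3]) else NA_real_)
    } else if (section == "FREE") {
      m <- regmatches(ln, regexec(
        "^(\\S+)\\.(net|xch)\\s*\\[\\s*([0-9eE.+-]+)\\s*,\\s*([0-9eE.+-]+)\\s*\\]$", ln))[[1]]
      if (length(m) == 0L) perr(i, "expected 'R.net [lo, hi]' or 'R.xch [lo, hi]'")
      free[[length(free) + 1L]] <- list(
        name = paste0(m[2], ".", m[3]), reaction = m[2], type = m[3],
        lo = as.numeric(m[4]), hi = as.numeric(m[5]))
    }
  }
  metabolites <- do.call(rbind, lapply(mets, function(m) {
    data.frame(name = m$name, n_carbons = m$n_carbons, role = m$role,
               stringsAsFactors = FALSE)
  }))
  constraints <- if (length(cons)) {
    do.call(rbind, lapply(cons, function(cc) {
      data.frame(reaction = cc$reaction, value = cc$value, prop_to = cc$prop_to,
                 coef = cc$coef, stringsAsFactors = FALSE)
    }))
  } else NULL
  freedf <- if (length(free)) {
    do.call(rbind, lapply(free, function(fr) {
      data.frame(name = fr$name, reaction = fr$reaction, type = fr$type,
                 lo = fr$lo, hi = fr$hi, stringsAsFactors = FALSE)
    }))
  } else NULL
  net <- new_atn(name, metabolites, rxns, unique(symmetric), constraints, freedf)
  validate_network(net)
}

parse_reaction_line <- function(ln) {
  reversible <- grepl("\\s+rev\\s*$", ln)
  if (reversible) ln <- sub("\\s+rev\\s*$", "", ln)
  m <- regmatches(ln, regexec("^(\\S+)\\s*:\\s*(.*)->(.*)$", ln))[[1]]
  if (length(m) == 0L) stop("expected '<name>: <lhs> -> <rhs> [rev]'")
  parse_side <- function(s) {
    if (!nzchar(trimws(s))) stop("empty reaction side")
    out <- list()
    for (term in strsplit(s, "+", fixed = TRUE)[[1]]) {
      term <- trimws(term)
      tm <- regmatches(term, regexec("^([A-Za-z0-9_]+)\\s*(\\(([a-z]*)\\))?$", term))[[1]]
      if (length(tm) == 0L || !nzchar(tm[2])) {
        stop(sprintf("cannot parse reaction term '%s'", term))
      }
      atoms <- if (nzchar(tm[3])) strsplit(tm[4], "")[[1]] else character()
      out[[length(out) + 1L]] <- list(met = tm[2], atoms = atoms)
    }
    out
  }
  list(name = m[2], reversible = reversible,
       reactants = parse_side(m[3]), products = parse_side(m[4]),
       cofactors = numeric())
}

#' Validate an atom-transition network
#'
#' Checks metabolite uniqueness, atom-map bijectivity (carbon is conserved
#' within every reaction), that all referenced metabolites are declared with
#' matching carbon counts, and that every internal metabolite is both produced
#' and consumed.
#'
#' @param net An \code{atn} object.
#' @return The network, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_network <- function(net) {
  mets <- net$metabolites
  if (is.null(mets) || nrow(mets) == 0L) stop("network has no metabolites")
  if (anyDuplicated(mets$name)) {
    stop("duplicate metabolite names: ",
         paste(unique(mets$name[duplicated(mets$name)]), collapse = ", "))
  }
  if (length(net$reactions) == 0L) stop("network validation failed: no reactions")
  if (anyDuplicated(names(net$reactions))) stop("duplicate reaction names")
  for (rx in net$reactions) {
    all_letters <- function(side, what) {
      unlist(lapply(side, function(inst) {
        idx <- match(inst$met, mets$name)
        if (is.na(idx)) {
          stop(sprintf("reaction %s references undeclared metabolite '%s'",
                       rx$name, inst$met))
        }
        if (length(inst$atoms) != mets$n_carbons[idx]) {
          stop(sprintf(
            "reaction %s: atom map for %s has %d carbons, metabolite declares %d",
            rx$name, inst$met, length(inst$atoms), mets$n_carbons[idx]))
        }
        inst$atoms
      }))
    }
    la <- all_letters(rx$reactants, "reactant")
    lb <- all_letters(rx$products, "product")
    if (anyDuplicated(la) || anyDuplicated(lb)) {
      stop(sprintf("reaction %s: repeated atom letter within one side", rx$name))
    }
    if (length(la) != length(lb) || !setequal(la, lb)) {
      stop(sprintf(
        "reaction %s: carbon-balance error, atom map is not a bijection (reactant atoms {%s} vs product atoms {%s})",
        rx$name, paste(sort(la), collapse = ""), paste(sort(lb), collapse = "")))
    }
    for (inst in rx$reactants) {
      if (met_role(net, inst$met) == "sink") {
        stop(sprintf("reaction %s consumes sink metabolite %s", rx$name, inst$met))
      }
    }
    for (inst in rx$products) {
      if (met_role(net, inst$met) == "substrate") {
        stop(sprintf("reaction %s produces substrate metabolite %s", rx$name, inst$met))
      }
    }
  }
  for (s in net$symmetric) {
    if (!s %in% mets$name) stop("symmetric declaration for undeclared metabolite ", s)
  }
  internal <- mets$name[mets$role == "internal"]
  produced <- consumed <- character()
  for (rx in net$reactions) {
    consumed <- c(consumed, vapply(rx$reactants, `[[`, "", "met"))
    produced <- c(produced, vapply(rx$products, `[[`, "", "met"))
    if (rx$reversible) {
      consumed <- c(consumed, vapply(rx$products, `[[`, "", "met"))
      produced <- c(produced, vapply(rx$reactants, `[[`, "", "met"))
    }
  }
  orphan <- setdiff(internal, intersect(produced, consumed))
  # zero-carbon bookkeeping pools may legitimately be one-sided
  orphan <- orphan[n_carbons(net, orphan) > 0]
  if (length(orphan)) {
    stop("internal metabolite(s) not both produced and consumed: ",
         paste(orphan, collapse = ", "))
  }
  bad <- setdiff(net$constraints$reaction, names(net$reactions))
  bad <- c(bad, setdiff(stats::na.omit(net$constraints$prop_to), names(net$reactions)))
  bad <- c(bad, setdiff(net$free$reaction, names(net$reactions)))
  if (length(bad)) {
    stop("constraint/free declaration references undeclared reaction(s): ",
         paste(unique(bad), collapse = ", "))
  }
  xch_free <- net$free$reaction[net$free$type == "xch"]
  for (r in xch_free) {
    if (!net$reactions[[r]]$reversible) {
      stop("exchange flux declared free for irreversible reaction ", r)
    }
  }
  invisible(net)
}

#' Stoichiometric matrix of the net fluxes
#'
#' @param net An \code{atn} object.
#' @return Numeric matrix, one row per internal metabolite, one column per
#'   reaction; entry (m, r) is the net stoichiometric coefficient of m in r.
#' @export
stoichiometric_matrix <- function(net) {
  internal <- net$metabolites$name[net$metabolites$role == "internal"]
  rn <- reaction_names(net)
  S <- matrix(0, nrow = length(internal), ncol = length(rn),
              dimnames = list(internal, rn))
  for (rx in net$reactions) {
    for (inst in rx$reactants) {
      if (inst$met %in% internal) S[inst$met, rx$name] <- S[inst$met, rx$name] - 1
    }
    for (inst in rx$products) {
      if (inst$met %in% internal) S[inst$met, rx$name] <- S[inst$met, rx$name] + 1
    }
  }
  S
}

#' Read a network document from a file
#' @param path Path to a network-format text file.
#' @param ... Passed to \code{\link{parse_network}}.
#' @export
read_network <- function(path, ...) {
  parse_network(readLines(path, warn = FALSE), ...)
}
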
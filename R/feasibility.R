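# Loop-length feasibility. Each loop geometry has a minimal nucleotide
# length: diagonal loops need >= 3 nt, lateral loops >= 2 nt (a single
# solved structure with a 1-nt +l loop motivates a relaxation switch),
# short-distance propellers manage with 1 nt, and long-distance propellers
# need >= 5 nt. Which propellers are long-distance depends on topology and
# helicity, so feasibility couples loop lengths to the geometric
# classification.

#' Loop-length rule set
#'
#' @param min_lateral_nt minimum lateral loop length, nt (default 2).
#' @param min_diagonal_nt minimum diagonal loop length, nt (default 3).
#' @param min_sd_propeller_nt minimum short-distance propeller length, nt
#'   (default 1).
#' @param min_ld_propeller_nt minimum long-distance propeller length, nt
#'   (default 5).
#' @param strict_lateral when \code{FALSE}, laterals are allowed down to
#'   1 nt regardless of \code{min_lateral_nt}.
#' @return object of class \code{g4_rules}.
#' @export
g4_rules <- function(min_lateral_nt = 2, min_diagonal_nt = 3,
                     min_sd_propeller_nt = 1, min_ld_propeller_nt = 5,
                     strict_lateral = TRUE) {
  rules <- list(min_lateral_nt = min_lateral_nt,
                min_diagonal_nt = min_diagonal_nt,
                min_sd_propeller_nt = min_sd_propeller_nt,
                min_ld_propeller_nt = min_ld_propeller_nt,
                strict_lateral = isTRUE(strict_lateral))
  minima <- unlist(rules[1:4])
  if (any(is.na(minima)) || any(minima < 1)) {
    stop("all loop-length minima must be >= 1")
  }
  if (rules$min_ld_propeller_nt < rules$min_sd_propeller_nt) {
    stop("min_ld_propeller_nt must be >= min_sd_propeller_nt")
  }
  structure(rules, class = "g4_rules")
}

#' Serialise / restore a rule set as JSON
#'
#' @param rules a \code{g4_rules} object.
#' @param path optional file path; when omitted the JSON string is returned.
#' @return JSON string (or the path, invisibly, when writing to file).
#' @export
rules_to_json <- function(rules, path = NULL) {
  stopifnot(inherits(rules, "g4_rules"))
  js <- jsonlite::toJSON(unclass(rules), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname rules_to_json
#' @param json JSON string or file path to read.
#' @export
rules_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  do.call(g4_rules, x)
}

#' Per-position minimal loop lengths of a topology
#'
#' @param topology topology string or token triple.
#' @param helicity \code{"RH"} or \code{"LH"}.
#' @param rules a \code{g4_rules} rule set.
#' @return numeric vector of three minimal lengths (nt).
#' @export
loop_minimum_lengths <- function(topology, helicity = c("RH", "LH"),
                                 rules = g4_rules()) {
  helicity <- match.arg(helicity)
  tokens <- as_loop_tokens(topology)
  geometry <- classify_propellers_rule(tokens, helicity)
  lateral_min <- if (rules$strict_lateral) rules$min_lateral_nt else 1
  vapply(1:3, function(k) {
    switch(loop_kind(tokens[k]),
           lateral = lateral_min,
           diagonal = rules$min_diagonal_nt,
           propeller = if (geometry[k] == "LD") rules$min_ld_propeller_nt
                       else rules$min_sd_propeller_nt)
  }, numeric(1))
}

#' Can a conformation's loop lengths support its topology?
#'
#' @param topology topology string or token triple.
#' @param loop_lengths integer triple of loop lengths (nt), positions
#'   I, II, III.
#' @param helicity \code{"RH"} or \code{"LH"}.
#' @param rules a \code{g4_rules} rule set.
#' @return list with \code{feasible} (logical) and \code{violations}
#'   (data.frame of offending positions: token, geometry label, length and
#'   required minimum; zero rows when feasible).
#' @export
is_feasible <- function(topology, loop_lengths, helicity = c("RH", "LH"),
                        rules = g4_rules()) {
  helicity <- match.arg(helicity)
  tokens <- as_loop_tokens(topology)
  stopifnot(length(loop_lengths) == 3L, all(loop_lengths >= 1))
  minima <- loop_minimum_lengths(tokens, helicity, rules)
  geometry <- classify_propellers_rule(tokens, helicity)
  bad <- which(loop_lengths < minima)
  violations <- data.frame(
    position = c("I", "II", "III")[bad],
    token = tokens[bad],
    geometry = geometry[bad],
    length = as.integer(loop_lengths[bad]),
    min_required = minima[bad],
    stringsAsFactors = FALSE
  )
  list(feasible = length(bad) == 0L, violations = violations)
}

#' Topologies feasible for a loop-length triple
#'
#' @inheritParams is_feasible
#' @param details when \code{TRUE}, return a data.frame over all 26
#'   topologies with a \code{feasible} flag and violation diagnostics
#'   instead of the feasible subset.
#' @return character vector of feasible topology strings (or the detailed
#'   data.frame).
#' @export
feasible_topologies <- function(loop_lengths, helicity = c("RH", "LH"),
                                rules = g4_rules(), details = FALSE) {
  helicity <- match.arg(helicity)
  topologies <- enumerate_topologies()
  res <- lapply(topologies, is_feasible, loop_lengths = loop_lengths,
                helicity = helicity, rules = rules)
  feasible <- vapply(res, `[[`, logical(1), "feasible")
  if (!details) return(topologies[feasible])
  diag <- vapply(res, function(r) {
    if (r$feasible) "" else
      paste(sprintf("%s:%s(%s)%d<%g", r$violations$position,
                    r$violations$token, r$violations$geometry,
                    r$violations$length, r$violations$min_required),
            collapse = ";")
  }, character(1))
  data.frame(topology = topologies, helicity = helicity,
             len_I = loop_lengths[1], len_II = loop_lengths[2],
             len_III = loop_lengths[3], feasible = feasible,
             violations = diag, stringsAsFactors = FALSE)
}

#' Search loop-length designs that select a target topology
#'
#' Enumerates all loop-length triples up to \code{max_len} at which the
#' target topology is feasible, and ranks them by how few competing
#' topologies remain feasible (ties broken by smaller total loop length,
#' then lexicographically).
#'
#' @param target topology string or token triple.
#' @param helicity \code{"RH"} or \code{"LH"}.
#' @param rules a \code{g4_rules} rule set.
#' @param max_len maximal per-loop length to consider (default 4).
#' @return data.frame ranked best first: \code{len_I}, \code{len_II},
#'   \code{len_III}, \code{n_competitors}, \code{total_length},
#'   \code{competitors} (comma-separated); zero rows when the target is
#'   never feasible.
#' @export
design_search <- function(target, helicity = c("RH", "LH"),
                          rules = g4_rules(), max_len = 4) {
  helicity <- match.arg(helicity)
  target <- format_topology(as_loop_tokens(target))
  stopifnot(is_valid_topology(target), max_len >= 1)
  grid <- expand.grid(len_III = 1:max_len, len_II = 1:max_len,
                      len_I = 1:max_len)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    lens <- c(grid$len_I[i], grid$len_II[i], grid$len_III[i])
    feas <- feasible_topologies(lens, helicity, rules)
    if (!target %in% feas) return(NULL)
    comp <- setdiff(feas, target)
    data.frame(len_I = lens[1], len_II = lens[2], len_III = lens[3],
               n_competitors = length(comp), total_length = sum(lens),
               competitors = paste(comp, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(len_I = integer(), len_II = integer(),
                      len_III = integer(), n_competitors = integer(),
                      total_length = integer(), competitors = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$n_competitors, out$total_length,
                   out$len_I, out$len_II, out$len_III), , drop = FALSE]
  rownames(out) <- NULL
  out
}
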